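#' @name synthetic-generator
#' @title Synthetic MRI exam-log generator
#'
#' @description
#' Generates seeded, fully synthetic modality-log datasets with the
#' statistical structure the prediction pipeline assumes: per-exam sequence
#' lists with plausible acquisition parameters, scanner-table traces,
#' contrast events, approximate ages, and count-valued billing labelsets
#' with main/auxiliary code dependencies. Eight procedure templates span
#' the discriminating axes of the feature set -- contrast use, the high
#' idle-to-acquisition ratio of MR-guided biopsies, the long table sweep of
#' whole-body exams, and the many-code labelsets of neck exams. The default
#' template mix is calibrated so the expected label cardinality of the
#' imaging-related codes is about 4.1 charged units per exam.
#'
#' Labelsets are drawn first (template base codes, contrast-conditional
#' codes, auxiliary surcharges conditional on their main code), then the
#' sequence list is emitted consistently with them: every auxiliary count
#' leaves a footprint in the log (extra series repeats, angiography runs,
#' post-contrast series), so labels are identifiable from log features
#' alone. Auxiliary codes are never drawn marginally -- only via their
#' conditional rules -- which is what makes chain classifiers able to beat
#' binary relevance on these data.
#'
#' Raw sequence names are decorated with the site-specific token classes a
#' standardizer must remove (body region, slice thickness, post-contrast
#' delay, accelerator tags) in shuffled positions, so the value of
#' parameter-based name standardization is exercised.
NULL

# twelve parameter archetypes; standardized names are derived from the
# parameters, never from the raw-name base tokens
sequence_archetypes <- function() {
  tibble::tribble(
    ~archetype,      ~technique, ~tr_ms, ~te_ms, ~ti_ms, ~orientation, ~fs,  ~bh,  ~diff, ~dur_s, ~base_tokens,
    "loc",           "gre",        8.6,    4.0,  NA,     "tra",        FALSE, FALSE, FALSE,  18,   "localizer_gre",
    "t1_se_sag",     "se",       520,     11,    NA,     "sag",        FALSE, FALSE, FALSE, 170,   "t1_se_sag",
    "t2_tse_tra",    "tse",     4200,     93,    NA,     "tra",        FALSE, FALSE, FALSE, 190,   "t2_tse_tra",
    "t2_tse_fs_sag", "tse",     3900,     88,    NA,     "sag",        TRUE,  FALSE, FALSE, 200,   "t2_tse_fs_sag",
    "flair_tra",     "tirm",    8500,    120,    2450,   "tra",        FALSE, FALSE, FALSE, 210,   "t2_tirm_tra_dark-fluid",
    "stir_cor",      "tirm",    4600,     42,    160,    "cor",        FALSE, FALSE, FALSE, 180,   "stir_tirm_cor",
    "ep2d_diff",     "ep2d",    5300,     70,    NA,     "tra",        FALSE, FALSE, TRUE,  230,   "ep2d_diff_b50_300_800_tra",
    "t1_vibe_fs",    "vibe",       4.4,    2.0,  NA,     "tra",        TRUE,  TRUE,  FALSE,  16,   "t1_vibe_fs_tra",
    "t2_haste_fs",   "haste",   2200,     95,    NA,     "tra",        TRUE,  TRUE,  FALSE,  25,   "t2_haste_fs_tra_mbh",
    "pd_tse_fs_cor", "tse",     2800,     27,    NA,     "cor",        TRUE,  FALSE, FALSE, 190,   "pd_tse_fs_cor",
    "t1_tse_fs",     "tse",      640,      9.8,  NA,     "tra",        TRUE,  FALSE, FALSE, 160,   "t1_tse_fs_tra",
    "trufi_cor_bh",  "trufi",      3.9,    1.7,  NA,     "cor",        FALSE, TRUE,  FALSE,  20,   "trufi_cor_bh"
  )
}

DECOR_THICKNESS <- c("3mm", "4mm", "5mm")
DECOR_EXTRA <- c("p2", "p3", "caipi", "4Scan", "tgv", "iso")

decorate_raw_name <- function(base_tokens, region, post_cm = FALSE) {
  tokens <- strsplit(base_tokens, "_", fixed = TRUE)[[1]]
  decor <- character()
  if (runif(1) < 0.5) decor <- c(decor, region)
  if (runif(1) < 0.4) decor <- c(decor, sample(DECOR_THICKNESS, 1))
  if (runif(1) < 0.4) decor <- c(decor, sample(DECOR_EXTRA, 1))
  if (post_cm && runif(1) < 0.4) decor <- c(decor, sample(c("15 min", "5min"), 1))
  for (d in decor) {
    pos <- sample(seq_len(length(tokens)), 1)  # never before the first token
    tokens <- append(tokens, d, after = pos)
  }
  paste(tokens, collapse = "_")
}

draw_count <- function(dist) {
  # dist: named numeric, names = count values, values = probabilities
  vals <- as.integer(names(dist))
  if (length(vals) == 1) return(vals)
  sample(vals, 1, prob = dist)
}

#' Procedure templates of the synthetic generator
#'
#' Eight MRI procedure archetypes with sequence plans, idle-time and
#' table-movement behaviour, contrast probability, base labelsets and
#' conditional auxiliary-code rules. The distributions are declared
#' generator configuration, not claims about any real site.
#'
#' @return Named list of template definitions.
#' @export
procedure_templates <- function() {
  list(
    head = list(
      weight = 0.20, region = "Head", coils = "Head32", age = c(25, 85),
      base_plan = c("loc", "t1_se_sag", "t2_tse_tra", "flair_tra", "ep2d_diff"),
      base_labels = c("39.0255" = 1L),
      contrast_prob = 0.25,
      cm_series_dist = c("1" = 1),
      rules = list(
        list(code = "39.0260", dist = c("0" = .75, "1" = .25), marker = "stir_cor"),
        list(code = "39.5010", dist = c("0" = .05, "1" = .40, "2" = .40, "3" = .15),
             marker = "t2_tse_fs_sag"),
        list(code = "39.5020", dist = c("0" = .7, "1" = .3), given_cm = TRUE,
             marker = "trufi_cor_bh")
      ),
      post_cm = "t1_tse_fs", noise_pool = "t1_se_sag",
      table = list(pattern = "static", start = -900),
      gap = c(15, 60), prep = c(180, 420)
    ),
    head_cm = list(
      weight = 0.12, region = "Head", coils = "Head32", age = c(30, 85),
      base_plan = c("loc", "t1_se_sag", "t2_tse_tra", "flair_tra", "ep2d_diff"),
      base_labels = c("39.0255" = 1L),
      contrast_prob = 1,
      cm_series_dist = c("1" = .7, "2" = .3),
      rules = list(
        list(code = "39.5010", dist = c("0" = .1, "1" = .3, "2" = .4, "3" = .2),
             marker = "t2_tse_fs_sag"),
        list(code = "39.5020", dist = c("0" = .4, "1" = .5, "2" = .1),
             given_cm = TRUE, marker = "trufi_cor_bh")
      ),
      post_cm = "t1_tse_fs", noise_pool = "t1_se_sag",
      table = list(pattern = "static", start = -900),
      gap = c(15, 60), prep = c(180, 420)
    ),
    neck_cm = list(
      weight = 0.10, region = "Neck", coils = "HeadNeck20", age = c(30, 80),
      base_plan = c("loc", "t1_se_sag", "t2_tse_tra", "stir_cor"),
      base_labels = c("39.0270" = 1L),
      contrast_prob = 1,
      cm_series_dist = c("1" = .8, "2" = .2),
      rules = list(
        list(code = "39.0305", dist = c("0" = .4, "1" = .6), marker = "t2_tse_tra"),
        list(code = "39.5010", dist = c("1" = .2, "2" = .5, "3" = .3),
             marker = "t2_tse_fs_sag"),
        list(code = "39.5020", dist = c("0" = .2, "1" = .5, "2" = .3),
             given_cm = TRUE, marker = "trufi_cor_bh"),
        list(code = "39.5200", dist = c("0" = .75, "1" = .25),
             marker = "loc", marker_n = 2L)
      ),
      post_cm = "t1_tse_fs", noise_pool = "t1_se_sag",
      table = list(pattern = "static", start = -700),
      gap = c(15, 60), prep = c(180, 420)
    ),
    spine = list(
      weight = 0.18, region = "Spine", coils = "Spine32", age = c(25, 80),
      base_plan = c("loc", "t1_se_sag", "t2_tse_tra", "stir_cor"),
      base_labels = c("39.0305" = 1L),
      contrast_prob = 0.15,
      cm_series_dist = c("1" = 1),
      rules = list(
        list(code = "39.0310", dist = c("0" = .25, "1" = .5, "2" = .25),
             marker = "segment"),
        list(code = "39.5010", dist = c("0" = .2, "1" = .6, "2" = .2),
             marker = "t2_tse_fs_sag")
      ),
      post_cm = "t1_tse_fs", noise_pool = "loc",
      table = list(pattern = "stepped", start = -400, step = 350),
      gap = c(15, 60), prep = c(180, 420)
    ),
    knee = list(
      weight = 0.15, region = "Knee", coils = "Flex16", age = c(15, 65),
      base_plan = c("loc", "pd_tse_fs_cor", "t1_se_sag", "stir_cor"),
      base_labels = setNames(integer(), character()),
      contrast_prob = 0.10,
      cm_series_dist = c("1" = 1),
      rules = list(
        list(code = "39.0360", dist = c("1" = .75, "2" = .25), marker = "bilateral"),
        list(code = "39.0410", dist = c("0" = .7, "1" = .3),
             marker = "t1_vibe_fs", marker_n = 2L),
        list(code = "39.5010", dist = c("0" = .2, "1" = .6, "2" = .2),
             marker = "t2_tse_fs_sag"),
        # rare tail: contralateral long-bone or hand/foot regions in the
        # same session, too infrequent for the training data to support
        list(code = "39.0365", dist = c("0" = .988, "1" = .012), marker = NULL),
        list(code = "39.0370", dist = c("0" = .988, "1" = .012), marker = NULL)
      ),
      post_cm = "t1_tse_fs", noise_pool = "t1_se_sag",
      table = list(pattern = "static", start = 450),
      gap = c(15, 60), prep = c(180, 420)
    ),
    abdomen_cm = list(
      weight = 0.10, region = "Abdomen", coils = "Body18", age = c(30, 85),
      base_plan = c("loc", "t2_haste_fs", "ep2d_diff", "t1_vibe_fs"),
      base_labels = c("39.0340" = 1L),
      contrast_prob = 1,
      cm_series_dist = c("1" = .7, "2" = .3),
      rules = list(
        list(code = "39.0345", dist = c("0" = .5, "1" = .5),
             marker = "t2_haste_fs", marker_n = 2L),
        list(code = "39.5010", dist = c("1" = .2, "2" = .5, "3" = .3),
             marker = "t2_tse_fs_sag"),
        list(code = "39.5020", dist = c("0" = .6, "1" = .4),
             given_cm = TRUE, marker = "trufi_cor_bh")
      ),
      post_cm = "t1_vibe_fs", noise_pool = "ep2d_diff",
      table = list(pattern = "static", start = -100),
      gap = c(20, 70), prep = c(180, 420)
    ),
    whole_body = list(
      weight = 0.07, region = "WB", coils = c("Body18", "Spine32"),
      age = c(40, 80),
      base_plan = c("loc", "t2_haste_fs", "stir_cor", "t2_haste_fs",
                    "stir_cor", "t2_haste_fs", "stir_cor", "t2_haste_fs",
                    "stir_cor", "t2_haste_fs", "stir_cor"),
      base_labels = c("39.5100" = 1L, "39.0330" = 1L, "39.0340" = 1L,
                      "39.0320" = 1L),
      contrast_prob = 0.8,
      cm_series_dist = c("1" = 1),
      rules = list(
        list(code = "39.5010", dist = c("0" = .2, "1" = .6, "2" = .2),
             marker = "t2_tse_fs_sag"),
        list(code = "39.5020", dist = c("0" = .4, "1" = .6),
             given_cm = TRUE, marker = "trufi_cor_bh"),
        # rare tail: screening add-on region
        list(code = "39.0380", dist = c("0" = .98, "1" = .02), marker = NULL)
      ),
      post_cm = "t1_vibe_fs", noise_pool = "loc",
      table = list(pattern = "sweep", start = -900, step = 300, per = 2),
      gap = c(15, 50), prep = c(240, 480)
    ),
    mr_biopsy = list(
      weight = 0.08, region = "Abdomen", coils = "Body18", age = c(45, 85),
      base_plan = c("loc", rep("t1_vibe_fs", 10)),
      n_extra_interventional = c(0, 4),   # extra guidance acquisitions
      base_labels = c("39.5300" = 1L, "39.0340" = 1L),
      contrast_prob = 0.30,
      cm_series_dist = c("1" = 1),
      rules = list(
        list(code = "39.5010", dist = c("0" = .2, "1" = .6, "2" = .2),
             marker = "t2_tse_fs_sag"),
        list(code = "00.0020", dist = c("0" = .4, "1" = .6), marker = NULL)
      ),
      post_cm = "t1_tse_fs", noise_pool = "loc",
      table = list(pattern = "cycles", inside = 0, outside = 420),
      gap = c(200, 420), prep = c(300, 600)
    )
  )
}

#' Generator configuration
#'
#' @param n_exams Number of exams.
#' @param mix Named template proportions (must sum to 1); default is the
#'   calibrated mix of [procedure_templates()].
#' @param seed Integer seed; all generator randomness flows from it.
#' @param start_time ISO-8601 start of the simulated period.
#' @param forget_rate,add_rate Label-noise rates handed to
#'   [simulate_technologist()] by pipeline drivers; 0 = clean labels.
#' @return A list of class `mri_generator_config`.
#' @export
generator_config <- function(n_exams = 1000, mix = NULL, seed = 1,
                             start_time = "2024-01-01T07:00:00",
                             forget_rate = 0, add_rate = 0) {
  templates <- procedure_templates()
  mix <- mix %||% vapply(templates, `[[`, numeric(1), "weight")
  if (abs(sum(mix) - 1) > 1e-8) abort("template mix must sum to 1")
  if (!all(names(mix) %in% names(templates))) abort("unknown template in mix")
  if (forget_rate < 0 || forget_rate > 1 || add_rate < 0 || add_rate > 1) {
    abort("noise rates must be in [0, 1]")
  }
  structure(list(n_exams = as.integer(n_exams), mix = mix, seed = seed,
                 start_time = start_time, forget_rate = forget_rate,
                 add_rate = add_rate),
            class = "mri_generator_config")
}

draw_labelset <- function(tpl, contrast) {
  labels <- tpl$base_labels
  extras <- list()   # marker plan additions: list of (archetype, n)
  bilateral <- FALSE
  segments <- 0L
  for (rule in tpl$rules) {
    if (isTRUE(rule$given_cm) && !contrast) next
    k <- draw_count(rule$dist)
    if (k == 0) next
    labels[rule$code] <- max(labels[rule$code], 0L, na.rm = TRUE) + k
    if (is.null(rule$marker)) next
    if (rule$marker == "segment") segments <- k
    else if (rule$marker == "bilateral") { if (k >= 2) bilateral <- TRUE }
    else extras[[length(extras) + 1L]] <-
        list(archetype = rule$marker, n = k * (rule$marker_n %||% 1L))
  }
  cm_series <- 0L
  if (contrast) {
    cm_series <- draw_count(tpl$cm_series_dist)
    labels["39.5050"] <- cm_series
    labels["00.0010"] <- 1L
  }
  list(labels = labels[labels > 0], extras = extras, bilateral = bilateral,
       segments = segments, cm_series = cm_series)
}

build_plan <- function(tpl, drawn, contrast) {
  plan <- tpl$base_plan
  if (!is.null(tpl$n_extra_interventional)) {
    plan <- c(plan, rep("t1_vibe_fs",
                        sample(seq(tpl$n_extra_interventional[1],
                                   tpl$n_extra_interventional[2]), 1)))
  }
  if (drawn$segments > 0) {
    # one extra sagittal/axial block per additional spine segment
    plan <- c(plan, rep(c("t1_se_sag", "t2_tse_tra"), drawn$segments))
  }
  if (drawn$bilateral) plan <- c(plan, tpl$base_plan[-1])
  for (ex in drawn$extras) plan <- c(plan, rep(ex$archetype, ex$n))
  if (runif(1) < 0.3) plan <- c(plan, tpl$noise_pool)
  n_post <- if (contrast) 2L * drawn$cm_series else 0L
  list(pre = plan, post = rep(tpl$post_cm, n_post))
}

table_positions_for <- function(tpl, n_seq, segments = 0L, bilateral = FALSE) {
  tab <- tpl$table
  pos <- switch(tab$pattern,
    static = rep(tab$start, n_seq),
    stepped = {
      stations <- 1L + segments
      st <- tab$start + tab$step * (seq_len(stations) - 1L)
      rep(st, length.out = n_seq, each = ceiling(n_seq / stations))[seq_len(n_seq)]
    },
    sweep = {
      tab$start + tab$step * ((seq_len(n_seq) - 1L) %/% tab$per)
    },
    cycles = {
      ifelse(seq_len(n_seq) %% 2 == 1, tab$outside, tab$inside)
    }
  )
  if (bilateral && tab$pattern == "static") {
    half <- ceiling(n_seq / 2)
    pos[(half + 1):n_seq] <- pos[(half + 1):n_seq] + 40
  }
  pos
}

#' Generate the events and true labelset of one exam
#'
#' @param template A template definition from [procedure_templates()].
#' @param exam_id Exam identifier (becomes the registration subject token).
#' @param scanner_id Scanner identifier.
#' @param t0 Registration time (POSIXct).
#' @return A list with `events` (tibble), `labels` (named integer vector of
#'   code counts) and `end_time`.
#' @export
generate_exam <- function(template, exam_id, scanner_id, t0) {
  arch <- sequence_archetypes()
  contrast <- runif(1) < template$contrast_prob
  drawn <- draw_labelset(template, contrast)
  plan <- build_plan(template, drawn, contrast)
  full_plan <- c(plan$pre, plan$post)
  n_seq <- length(full_plan)
  positions <- table_positions_for(template, n_seq,
                                   segments = drawn$segments,
                                   bilateral = drawn$bilateral)
  age <- round(runif(1, template$age[1], template$age[2]))

  kinds <- character(); times <- numeric(); payloads <- list()
  push <- function(kind, ts, payload) {
    i <- length(kinds) + 1L
    kinds[i] <<- kind
    times[i] <<- as.numeric(ts)
    payloads[[i]] <<- payload
  }
  push("registration", t0,
       list(subject_token = exam_id, approximate_age_years = age))
  t <- t0 + round(runif(1, template$prep[1], template$prep[2]))
  push("table_move", t - 5, list(position_mm = positions[1]))
  cm_emitted <- FALSE
  for (i in seq_len(n_seq)) {
    a <- arch[arch$archetype == full_plan[i], ]
    is_post <- i > length(plan$pre)
    if (is_post && !cm_emitted) {
      push("contrast_injection", t, list(agent = "gadolinium"))
      t <- t + round(runif(1, 30, 90))
      cm_emitted <- TRUE
    }
    if (i > 1 && positions[i] != positions[i - 1]) {
      push("table_move", t, list(position_mm = positions[i]))
      t <- t + round(runif(1, 10, 25))
    }
    # technique dropout: the structured field is occasionally unreliable,
    # forcing the standardizer's raw-name fallback
    technique <- if (a$archetype != "loc" && runif(1) < 0.05) "other" else a$technique
    payload <- normalize_payload("sequence_start", list(
      raw_name = decorate_raw_name(a$base_tokens, template$region, is_post),
      tr_ms = a$tr_ms, te_ms = a$te_ms,
      ti_ms = if (is.na(a$ti_ms)) NULL else a$ti_ms,
      technique = technique,
      dimensionality = if (a$technique %in% c("vibe", "trufi")) "3d" else "2d",
      orientation = a$orientation,
      fat_saturation = a$fs, breath_hold = a$bh,
      b_values = if (a$diff) c(50, 300, 800) else numeric(),
      fov_mm = round(runif(1, 200, 420)),
      slice_thickness_mm = sample(c(3, 4, 5), 1),
      coil_ids = template$coils,
      table_position_mm = positions[i]
    ))
    start <- t
    dur <- max(5, round(a$dur_s * runif(1, 0.8, 1.2)))
    push("sequence_start", start, payload)
    push("sequence_end", start + dur, list(raw_name = payload$raw_name))
    t <- start + dur + round(runif(1, template$gap[1], template$gap[2]))
  }
  events <- tibble(
    event_kind = kinds,
    timestamp = as.POSIXct(times, origin = "1970-01-01", tz = "UTC"),
    scanner_id = scanner_id, payload = payloads)
  list(events = events, labels = drawn$labels,
       end_time = max(events$timestamp))
}

#' Generate a full synthetic log dataset
#'
#' Draws `n_exams` exams from the template mix, schedules them back-to-back
#' on two scanners, and returns the event stream, the true billing records
#' and a template-provenance sidecar. Reproducible: the same config yields
#' identical output.
#'
#' @param config A [generator_config()].
#' @return A list with `events` (event tibble, timestamp-ordered), `truth`
#'   (long labelset tibble `exam_id`, `code_id`, `count`), and `provenance`
#'   (`exam_id`, `template`, `registration_time`, `scanner_id`).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "mri_generator_config")) {
    config <- do.call(generator_config, config)
  }
  set.seed(config$seed)
  templates <- procedure_templates()[names(config$mix)]
  t_start <- parse_timestamp(config$start_time)
  clock <- c(MR1 = t_start, MR2 = t_start + 600)
  tpl_draw <- sample(names(templates), config$n_exams, replace = TRUE,
                     prob = config$mix)
  out_events <- vector("list", config$n_exams)
  out_truth <- vector("list", config$n_exams)
  prov <- vector("list", config$n_exams)
  for (i in seq_len(config$n_exams)) {
    sc <- if (i %% 2 == 1) "MR1" else "MR2"
    exam_id <- sprintf("E%05d", i)
    t0 <- clock[[sc]]
    g <- generate_exam(templates[[tpl_draw[i]]], exam_id, sc, t0)
    clock[[sc]] <- g$end_time + round(runif(1, 300, 1200))
    out_events[[i]] <- g$events
    out_truth[[i]] <- tibble(exam_id = exam_id, code_id = names(g$labels),
                             count = as.integer(g$labels))
    prov[[i]] <- tibble(exam_id = exam_id, template = tpl_draw[i],
                        registration_time = t0, scanner_id = sc)
  }
  events <- dplyr::bind_rows(out_events)
  events <- events[order(events$timestamp), ]
  list(events = events,
       truth = dplyr::bind_rows(out_truth),
       provenance = dplyr::bind_rows(prov))
}

#' Write a generated dataset to disk in the package's file dialects
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `events.jsonl`, `truth.csv` (header
#'   `exam_id,code_id,count`) and `provenance.csv`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_events(dataset$events, file.path(dir, "events.jsonl"))
  readr::write_csv(dataset$truth, file.path(dir, "truth.csv"))
  prov <- dataset$provenance
  prov$registration_time <- format_timestamp(prov$registration_time)
  readr::write_csv(prov, file.path(dir, "provenance.csv"))
  invisible(dir)
}

#' Read a billing-record CSV
#'
#' Accepts the `exam_id,code_id,count` and `timestamp,code_id,count`
#' dialects.
#'
#' @param path CSV path.
#' @return A billing tibble for [merge_billing()].
#' @export
read_billing <- function(path) {
  b <- readr::read_csv(path, show_col_types = FALSE)
  if (!"count" %in% names(b)) abort("billing CSV needs a count column")
  if ("timestamp" %in% names(b) && is.character(b$timestamp)) {
    b$timestamp <- parse_timestamp(b$timestamp)
  }
  b
}

#' Simulate technologist coding errors
#'
#' Each truly charged unit is independently forgotten with probability
#' `forget_rate` (auxiliary surcharge codes with an elevated rate,
#' `forget_rate * aux_forget_multiplier`, reflecting that manually added
#' auxiliary codes dominate real coding errors); spurious units of a
#' random imaging code are added with probability `add_rate` per exam.
#' With forgetting dominating addition, the simulated coder shows the
#' characteristic manual-coding asymmetry: precision above recall.
#'
#' @param labelsets True labelsets (long tibble).
#' @param code_defs Code-definition table (for auxiliary flags and the
#'   addable code universe).
#' @param forget_rate,add_rate Error rates in \[0, 1\].
#' @param aux_forget_multiplier Multiplier on `forget_rate` for auxiliary
#'   codes (capped so the rate stays at most 1).
#' @param exam_ids Exam universe for spurious additions; defaults to the
#'   exams present in `labelsets`.
#' @return The miscoded labelsets (long tibble).
#' @export
simulate_technologist <- function(labelsets, code_defs, forget_rate = 0.05,
                                  add_rate = 0.01,
                                  aux_forget_multiplier = 3,
                                  exam_ids = NULL) {
  if (forget_rate < 0 || forget_rate > 1 || add_rate < 0 || add_rate > 1) {
    abort("rates must be in [0, 1]")
  }
  code_defs <- validate_code_defs(code_defs)
  aux <- setNames(code_defs$auxiliary, code_defs$code_id)
  rate <- ifelse(!is.na(aux[labelsets$code_id]) & aux[labelsets$code_id],
                 pmin(1, forget_rate * aux_forget_multiplier), forget_rate)
  kept <- rbinom(nrow(labelsets), labelsets$count, 1 - rate)
  out <- labelsets
  out$count <- as.integer(kept)
  out <- out[out$count > 0, , drop = FALSE]
  exam_ids <- exam_ids %||% unique(labelsets$exam_id)
  addable <- code_defs$code_id[code_defs$imaging_related]
  add_hit <- runif(length(exam_ids)) < add_rate
  if (any(add_hit)) {
    adds <- tibble(exam_id = exam_ids[add_hit],
                   code_id = sample(addable, sum(add_hit), replace = TRUE),
                   count = 1L)
    out <- dplyr::bind_rows(out, adds) |>
      dplyr::group_by(.data$exam_id, .data$code_id) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
  }
  dplyr::arrange(as_tibble(out), .data$exam_id, .data$code_id)
}
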