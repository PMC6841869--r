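#' @name log-events
#' @title MRI modality log events
#'
#' @description
#' The package ingests scanner activity as a flat stream of timestamped
#' events, one JSON object per line:
#'
#' * `registration` -- a subject is registered on the MRI host computer;
#'   payload `subject_token`, `approximate_age_years`.
#' * `sequence_start` / `sequence_end` -- execution of one MR sequence;
#'   the start payload carries the acquisition parameters (`raw_name`,
#'   `tr_ms`, `te_ms`, `ti_ms`, `technique`, `dimensionality`,
#'   `orientation`, `fat_saturation`, `breath_hold`, `b_values`, `fov_mm`,
#'   `slice_thickness_mm`, `coil_ids`, `table_position_mm`), the end payload
#'   repeats `raw_name` for pairing.
#' * `table_move` -- payload `position_mm`.
#' * `contrast_injection` -- contrast medium given.
#'
#' Events are represented in R as a tibble with columns `event_kind`,
#' `timestamp` (POSIXct, UTC, second resolution), `scanner_id` and a
#' `payload` list-column.
NULL

EVENT_KINDS <- c("registration", "sequence_start", "sequence_end",
                 "table_move", "contrast_injection")

TECHNIQUES <- c("se", "tse", "gre", "vibe", "haste", "ep2d", "trufi",
                "tirm", "other")
ORIENTATIONS <- c("tra", "sag", "cor", "oblique")

SEQUENCE_PAYLOAD_FIELDS <- c(
  "raw_name", "tr_ms", "te_ms", "ti_ms", "technique", "dimensionality",
  "orientation", "fat_saturation", "breath_hold", "b_values", "fov_mm",
  "slice_thickness_mm", "coil_ids", "table_position_mm"
)

new_events <- function(event_kind, timestamp, scanner_id, payload) {
  tibble(event_kind = event_kind, timestamp = timestamp,
         scanner_id = scanner_id, payload = payload)
}

#' Read modality log events from a JSON-lines file
#'
#' Each line is parsed and validated independently; malformed lines
#' (unparseable JSON, unknown `event_kind`, bad timestamp, payload fields
#' inconsistent with the kind) are collected into a rejects report attached
#' to the result (`side_report(events, "rejects")`, columns `line_no`,
#' `reason`) rather than silently dropped. An empty stream yields an empty
#' event tibble.
#'
#' @param path Path to a JSON-lines event file (see [log-events]).
#' @return A tibble of events ordered by timestamp, with a rejects report
#'   attached.
#' @seealso [write_events()], [assemble_exams()]
#' @export
read_events <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- vector("list", length(lines))
  rejects <- list()
  for (i in seq_along(lines)) {
    parsed <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
      error = function(e) NULL
    )
    reason <- validate_event(parsed)
    if (!is.null(reason)) {
      rejects[[length(rejects) + 1L]] <- tibble(line_no = i, reason = reason)
      next
    }
    rows[[i]] <- tibble(
      event_kind = parsed$event_kind,
      timestamp = parse_timestamp(parsed$timestamp),
      scanner_id = as.character(parsed$scanner_id %e% NA_character_),
      payload = list(normalize_payload(parsed$event_kind, parsed$payload))
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  events <- if (length(rows)) dplyr::bind_rows(rows) else
    new_events(character(), as.POSIXct(character(), tz = "UTC"),
               character(), list())
  events <- events[order(events$timestamp), , drop = FALSE]
  rejects <- if (length(rejects)) dplyr::bind_rows(rejects) else
    tibble(line_no = integer(), reason = character())
  set_side_report(events, "rejects", rejects)
}

validate_event <- function(parsed) {
  if (is.null(parsed) || !is.list(parsed)) return("unparseable JSON")
  kind <- parsed$event_kind
  if (is.null(kind) || !is.character(kind) || length(kind) != 1 ||
      !kind %in% EVENT_KINDS) {
    return(sprintf("unknown event_kind '%s'", paste0(kind, collapse = ",")))
  }
  ts <- parsed$timestamp
  if (is.null(ts) || is.na(parse_timestamp(ts[1]))) {
    return("unparseable timestamp")
  }
  pl <- parsed$payload
  required <- switch(kind,
    registration = "subject_token",
    sequence_start = c("raw_name", "tr_ms", "te_ms"),
    sequence_end = "raw_name",
    table_move = "position_mm",
    contrast_injection = character()
  )
  missing <- setdiff(required, names(pl))
  if (length(missing)) {
    return(sprintf("payload missing field(s) %s for event_kind %s",
                   paste(missing, collapse = ", "), kind))
  }
  if (kind == "sequence_start") {
    if (!is.numeric(pl$tr_ms) || !is.numeric(pl$te_ms) ||
        pl$tr_ms[1] <= 0 || pl$te_ms[1] <= 0) {
      return("nonpositive or non-numeric TR/TE")
    }
  }
  if (kind == "table_move" && !is.numeric(pl$position_mm)) {
    return("non-numeric position_mm")
  }
  NULL
}

normalize_payload <- function(kind, pl) {
  pl <- as.list(pl)
  if (kind == "sequence_start") {
    pl$ti_ms <- if (is.null(pl$ti_ms) || all(is.na(pl$ti_ms))) NA_real_ else as.numeric(pl$ti_ms[1])
    pl$b_values <- as.numeric(pl$b_values %e% numeric())
    pl$coil_ids <- as.character(pl$coil_ids %e% character())
    pl$technique <- as.character(pl$technique %e% "other")
    if (!pl$technique %in% TECHNIQUES) pl$technique <- "other"
    pl$dimensionality <- as.character(pl$dimensionality %e% "2d")
    pl$orientation <- as.character(pl$orientation %e% "tra")
    pl$fat_saturation <- isTRUE(as.logical(pl$fat_saturation %e% FALSE))
    pl$breath_hold <- isTRUE(as.logical(pl$breath_hold %e% FALSE))
    pl$fov_mm <- as.numeric(pl$fov_mm %e% NA_real_)
    pl$slice_thickness_mm <- as.numeric(pl$slice_thickness_mm %e% NA_real_)
    pl$table_position_mm <- as.numeric(pl$table_position_mm %e% 0)
  }
  pl
}

#' Write modality log events to a JSON-lines file
#'
#' Inverse of [read_events()]: every schema-conforming event list survives a
#' write/read round trip unchanged.
#'
#' @param events An event tibble (see [log-events]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  lines <- vapply(seq_len(nrow(events)), function(i) {
    jsonlite::toJSON(list(
      event_kind = events$event_kind[[i]],
      timestamp = format_timestamp(events$timestamp[[i]]),
      scanner_id = events$scanner_id[[i]],
      payload = events$payload[[i]]
    ), auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

sequence_from_payload <- function(pl, start_time, end_time) {
  tibble(
    raw_name = pl$raw_name,
    start_time = start_time,
    end_time = end_time,
    tr_ms = pl$tr_ms, te_ms = pl$te_ms, ti_ms = pl$ti_ms,
    technique = pl$technique,
    dimensionality = pl$dimensionality,
    orientation = pl$orientation,
    fat_saturation = pl$fat_saturation,
    breath_hold = pl$breath_hold,
    b_values = list(pl$b_values),
    fov_mm = pl$fov_mm,
    slice_thickness_mm = pl$slice_thickness_mm,
    coil_ids = list(pl$coil_ids),
    table_position_mm = pl$table_position_mm
  )
}

empty_sequences <- function() {
  sequence_from_payload(
    normalize_payload("sequence_start",
                      list(raw_name = "x", tr_ms = 1, te_ms = 1)),
    as.POSIXct(character(), tz = "UTC"), as.POSIXct(character(), tz = "UTC")
  )[0, ]
}

#' Assemble raw events into exam instances
#'
#' Each `registration` event opens a new exam on its scanner; all later
#' events on that scanner up to the next registration belong to it, with the
#' exam time span running from registration to the end of the last MR
#' sequence. Exams with zero completed sequences (aborted before diagnostic
#' images were acquired) are retained and flagged `aborted`. A `sequence_end`
#' with the same timestamp as the next registration closes the earlier exam.
#'
#' Events arriving before any registration on their scanner, and
#' `sequence_end` events without a matching open `sequence_start`, are
#' collected into a rejects report (`side_report(exams, "rejects")`).
#'
#' @param events An event tibble, e.g. from [read_events()] or
#'   [generate_dataset()].
#' @return A tibble with one row per exam: `exam_id`, `scanner_id`,
#'   `registration_time`, `end_time`, `approximate_age_years`,
#'   `contrast_given`, `n_sequences`, `aborted`, plus list-columns
#'   `sequences` (one tibble of sequence records per exam, sorted by start
#'   time) and `table_positions` (tibble `timestamp`, `position_mm`).
#' @export
assemble_exams <- function(events) {
  # same-timestamp tie-break: close the running exam before opening the next
  kind_rank <- c(sequence_end = 0, table_move = 1, contrast_injection = 1,
                 sequence_start = 2, registration = 3)
  events <- events[order(events$timestamp, kind_rank[events$event_kind]), ]
  rejects <- list()
  exams <- list()
  seen_ids <- character()

  for (sc in unique(events$scanner_id)) {
    ev <- events[events$scanner_id == sc, ]
    reg_idx <- which(ev$event_kind == "registration")
    if (length(reg_idx) == 0 || (length(reg_idx) && reg_idx[1] > 1)) {
      pre <- if (length(reg_idx)) seq_len(reg_idx[1] - 1L) else seq_len(nrow(ev))
      for (j in pre) {
        rejects[[length(rejects) + 1L]] <- tibble(
          scanner_id = sc, timestamp = ev$timestamp[[j]],
          event_kind = ev$event_kind[[j]], reason = "event before any registration")
      }
    }
    if (length(reg_idx) == 0) next
    bounds <- c(reg_idx, nrow(ev) + 1L)
    for (k in seq_along(reg_idx)) {
      block <- ev[seq(bounds[k], bounds[k + 1L] - 1L), ]
      reg <- block$payload[[1]]
      open <- list()         # unmatched sequence_start payloads (+ time)
      done <- list()         # completed sequence tibble rows
      tpos <- list()
      contrast <- FALSE
      for (j in seq_len(nrow(block))[-1]) {
        kind <- block$event_kind[[j]]
        pl <- block$payload[[j]]
        ts <- block$timestamp[[j]]
        if (kind == "sequence_start") {
          open[[length(open) + 1L]] <- list(payload = pl, start = ts)
        } else if (kind == "sequence_end") {
          match_i <- NULL
          for (o in rev(seq_along(open))) {
            if (identical(open[[o]]$payload$raw_name, pl$raw_name)) { match_i <- o; break }
          }
          if (is.null(match_i)) {
            rejects[[length(rejects) + 1L]] <- tibble(
              scanner_id = sc, timestamp = ts, event_kind = kind,
              reason = sprintf("sequence_end '%s' without matching sequence_start",
                               pl$raw_name %e% "?"))
          } else {
            done[[length(done) + 1L]] <-
              sequence_from_payload(open[[match_i]]$payload,
                                    open[[match_i]]$start, ts)
            open[[match_i]] <- NULL
          }
        } else if (kind == "table_move") {
          tpos[[length(tpos) + 1L]] <- tibble(timestamp = ts,
                                              position_mm = pl$position_mm)
        } else if (kind == "contrast_injection") {
          contrast <- TRUE
        }
      }
      for (o in seq_along(open)) {
        rejects[[length(rejects) + 1L]] <- tibble(
          scanner_id = sc, timestamp = open[[o]]$start,
          event_kind = "sequence_start",
          reason = sprintf("sequence_start '%s' without matching sequence_end",
                           open[[o]]$payload$raw_name))
      }
      seqs <- if (length(done)) dplyr::bind_rows(done) else empty_sequences()
      seqs <- seqs[order(seqs$start_time), ]
      exam_id <- as.character(reg$subject_token %e% sprintf("%s_%05d", sc, k))
      if (exam_id %in% seen_ids) {
        exam_id <- sprintf("%s.%d", exam_id, sum(startsWith(seen_ids, exam_id)) + 1L)
      }
      seen_ids <- c(seen_ids, exam_id)
      exams[[length(exams) + 1L]] <- tibble(
        exam_id = exam_id,
        scanner_id = sc,
        registration_time = block$timestamp[[1]],
        end_time = if (nrow(seqs)) max(seqs$end_time) else block$timestamp[[1]],
        approximate_age_years = as.numeric(reg$approximate_age_years %e% NA_real_),
        contrast_given = contrast,
        n_sequences = nrow(seqs),
        aborted = nrow(seqs) == 0L,
        sequences = list(seqs),
        table_positions = list(if (length(tpos)) dplyr::bind_rows(tpos) else
          tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                 position_mm = numeric()))
      )
    }
  }
  out <- if (length(exams)) dplyr::bind_rows(exams) else
    tibble(exam_id = character(), scanner_id = character(),
           registration_time = as.POSIXct(character(), tz = "UTC"),
           end_time = as.POSIXct(character(), tz = "UTC"),
           approximate_age_years = numeric(), contrast_given = logical(),
           n_sequences = integer(), aborted = logical(),
           sequences = list(), table_positions = list())
  out <- out[order(out$registration_time, out$exam_id), ]
  rejects <- if (length(rejects)) dplyr::bind_rows(rejects) else
    tibble(scanner_id = character(),
           timestamp = as.POSIXct(character(), tz = "UTC"),
           event_kind = character(), reason = character())
  set_side_report(out, "rejects", rejects)
}

#' Merge billing records into assembled exams
#'
#' Billing records are keyed either by `exam_id` (joined directly) or by
#' `timestamp` (matched to the exam whose time span, widened by
#' `tolerance_s`, contains the timestamp). Counts are aggregated per exam
#' and code into the `labelset` list-column (named integer vectors). Exams
#' with no billing match keep an empty labelset and are flagged
#' `has_billing = FALSE`; records matching no exam are collected into an
#' `unmatched` side report. A timestamp-keyed record matching two exams is
#' an ambiguity error naming both candidates.
#'
#' @param exams Exam tibble from [assemble_exams()].
#' @param billing A tibble with columns `code_id`, `count` and either
#'   `exam_id` or `timestamp` (POSIXct or ISO-8601 string). An optional
#'   `scanner_id` column disambiguates timestamp matches between exams
#'   running concurrently on different scanners.
#' @param tolerance_s Widening of the exam span for timestamp matching, in
#'   seconds (default 1800 = 30 minutes).
#' @return `exams` with `labelset` and `has_billing` columns added and an
#'   `unmatched` side report attached.
#' @export
merge_billing <- function(exams, billing, tolerance_s = 1800) {
  billing <- as_tibble(billing)
  if (!all(c("code_id", "count") %in% names(billing))) {
    abort("billing needs `code_id` and `count` columns")
  }
  if (any(billing$count < 1)) abort("billing counts must be >= 1")
  by_id <- "exam_id" %in% names(billing)
  if (!by_id && !"timestamp" %in% names(billing)) {
    abort("billing needs an `exam_id` or `timestamp` key column")
  }

  if (!by_id) {
    ts <- billing$timestamp
    if (is.character(ts)) ts <- parse_timestamp(ts)
    lo <- exams$registration_time - tolerance_s
    hi <- exams$end_time + tolerance_s
    assigned <- character(nrow(billing))
    # disambiguate concurrent scanners by scanner_id when the records carry it
    sc <- if ("scanner_id" %in% names(billing)) billing$scanner_id else
      rep(NA_character_, nrow(billing))
    for (i in seq_len(nrow(billing))) {
      hit <- which(ts[i] >= lo & ts[i] <= hi &
                     (is.na(sc[i]) | exams$scanner_id == sc[i]))
      if (length(hit) > 1) {
        abort(sprintf(
          "billing record %d (%s) matches %d exams within tolerance: %s",
          i, billing$code_id[i], length(hit),
          paste(exams$exam_id[hit], collapse = ", ")))
      }
      assigned[i] <- if (length(hit) == 1) exams$exam_id[hit] else NA_character_
    }
    billing$exam_id <- assigned
  }

  unmatched <- billing[is.na(billing$exam_id) |
                         !billing$exam_id %in% exams$exam_id, , drop = FALSE]
  matched <- billing[!is.na(billing$exam_id) &
                       billing$exam_id %in% exams$exam_id, , drop = FALSE]
  agg <- matched |>
    dplyr::group_by(.data$exam_id, .data$code_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")

  exams$labelset <- lapply(exams$exam_id, function(id) {
    sub <- agg[agg$exam_id == id, ]
    setNames(as.integer(sub$count), sub$code_id)
  })
  exams$has_billing <- vapply(exams$labelset, length, integer(1)) > 0L
  set_side_report(exams, "unmatched", as_tibble(unmatched))
}

#' Extract labelsets from merged exams as a long tibble
#'
#' @param exams Exam tibble with a `labelset` column (from
#'   [merge_billing()] or [generate_dataset()]).
#' @return A tibble `exam_id`, `code_id`, `count` with one row per charged
#'   code; exams with empty labelsets contribute no rows.
#' @export
exam_labelsets <- function(exams) {
  rows <- purrr::map2(exams$exam_id, exams$labelset, function(id, ls) {
    if (length(ls) == 0) return(NULL)
    tibble(exam_id = id, code_id = names(ls), count = as.integer(ls))
  })
  rows <- purrr::compact(rows)
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble(exam_id = character(), code_id = character(), count = integer())
}
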