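#' Acquisition and idle-time features
#'
#' For each exam: the total acquisition time ACQ (sum of sequence execution
#' times, the scanner's value-added time), the user-operating time UOP (exam
#' span minus ACQ, i.e. scanner idle time; the span runs from registration
#' to the end of the last sequence), and the UOP-to-ACQ ratio. The ratio
#' separates MR-guided biopsies -- where short acquisition cycles punctuate
#' long intervention pauses -- from diagnostic exams. UOP is clipped at zero
#' (overlapping acquisitions cannot produce negative idle time), and an
#' aborted exam with ACQ = 0 gets ratio 0; its `aborted` flag carries the
#' signal instead of an infinity.
#'
#' @param exams Exam tibble from [assemble_exams()].
#' @return A tibble `exam_id`, `acq_s`, `uop_s`, `uop_acq_ratio` (seconds).
#' @export
compute_timing <- function(exams) {
  purrr::map2_dfr(exams$exam_id, seq_len(nrow(exams)), function(id, i) {
    seqs <- exams$sequences[[i]]
    durs <- as.numeric(difftime(seqs$end_time, seqs$start_time, units = "secs"))
    if (any(durs < 0)) abort(sprintf("negative sequence duration in exam %s", id))
    acq <- sum(durs)
    span <- if (nrow(seqs)) {
      as.numeric(difftime(max(seqs$end_time), exams$registration_time[[i]],
                          units = "secs"))
    } else 0
    uop <- max(0, span - acq)
    tibble(exam_id = id, acq_s = acq, uop_s = uop,
           uop_acq_ratio = if (acq > 0) uop / acq else 0)
  })
}

#' Scanner-table movement features
#'
#' The position series per exam is the recorded `table_move` samples,
#' falling back to the table position at each sequence start when no move
#' events were logged. Total movement is the summed absolute step over
#' consecutive samples; min/max are over samples; `table_mean_step_mm` is
#' the mean absolute difference between the table positions at consecutive
#' sequence starts. An empty series yields all zeros.
#'
#' @param exams Exam tibble from [assemble_exams()].
#' @return A tibble `exam_id`, `table_total_movement_mm`, `table_min_mm`,
#'   `table_max_mm`, `table_mean_step_mm`.
#' @export
table_features <- function(exams) {
  purrr::map_dfr(seq_len(nrow(exams)), function(i) {
    tp <- exams$table_positions[[i]]
    tp <- tp[order(tp$timestamp), ]
    seqs <- exams$sequences[[i]]
    seqs <- seqs[order(seqs$start_time), ]   # canonical order
    series <- if (nrow(tp)) tp$position_mm else seqs$table_position_mm
    if (length(series) == 0) {
      return(tibble(exam_id = exams$exam_id[[i]], table_total_movement_mm = 0,
                    table_min_mm = 0, table_max_mm = 0, table_mean_step_mm = 0))
    }
    steps <- abs(diff(series))
    seq_steps <- abs(diff(seqs$table_position_mm))
    tibble(
      exam_id = exams$exam_id[[i]],
      table_total_movement_mm = if (length(steps)) sum(steps) else 0,
      table_min_mm = min(series),
      table_max_mm = max(series),
      table_mean_step_mm = if (length(seq_steps)) mean(seq_steps) else 0
    )
  })
}

#' Default coil grouping
#'
#' Coil element identifiers are site- and scanner-specific; features use
#' coarse anatomical groups so the indicator set stays stable across
#' scanners. Each group is a case-insensitive regular expression matched
#' against coil ids; unmatched coils fall into `other`.
#'
#' @return Named list of regular expressions.
#' @export
coil_groups <- function() {
  list(
    head = "^(he|head|hc)",
    spine = "^(sp|spine)",
    body = "^(bo|body)",
    extremity = "^(ex|flex|tx|knee|shoulder)",
    breast = "^(br|breast)"
  )
}

#' Fit the sequence-name vocabulary on training exams
#'
#' The fitted vocabulary fixes the set and order of per-sequence count
#' features. It must be fitted on training exams only; names first seen at
#' prediction time are counted in a reserved overflow bin so the feature
#' vector length never changes.
#'
#' @param exams Training exam tibble.
#' @param rules Standardizer rule table ([standardizer_rules()]).
#' @return An object of class `mri_vocabulary`.
#' @export
fit_vocabulary <- function(exams, rules = standardizer_rules()) {
  all_seqs <- dplyr::bind_rows(exams$sequences)
  names <- if (nrow(all_seqs)) sort(unique(standardize_names(all_seqs, rules)))
           else character()
  structure(list(names = names, rules = rules), class = "mri_vocabulary")
}

#' @export
print.mri_vocabulary <- function(x, ...) {
  cat("<mri_vocabulary> ", length(x$names),
      " standardized sequence names + overflow bin\n", sep = "")
  invisible(x)
}

feature_col_name <- function(x) paste0("seq_", gsub("[^a-z0-9]+", "_", x))

#' Turn exams into the fixed-length numeric feature table
#'
#' One row per exam: per-vocabulary standardized-sequence counts (repeat
#' acquisitions are informative for surcharge codes, so counts rather than
#' presence), an overflow count for names unseen at fit time, timing
#' features ([compute_timing()]), table-movement features
#' ([table_features()]), the contrast flag, approximate patient age, coarse
#' coil-group indicators and the sequence count. No scaling happens here;
#' standardization is owned by the model pipeline so cross-validation folds
#' can fit it on training data only.
#'
#' All features are order-insensitive aggregates of the exam, so the
#' result is invariant to permutations of the stored sequence list (the
#' mean table step uses start-time order, which is canonical).
#'
#' @param exams Exam tibble.
#' @param vocabulary Fitted [fit_vocabulary()] object.
#' @param coil_group_rules Named list of regexes, see [coil_groups()].
#' @return A tibble with `exam_id` followed by numeric feature columns; the
#'   column set and order are fully determined by the vocabulary.
#' @export
featurize <- function(exams, vocabulary, coil_group_rules = coil_groups()) {
  if (!inherits(vocabulary, "mri_vocabulary")) {
    abort("`vocabulary` must come from fit_vocabulary(); fit it on training exams first")
  }
  timing <- compute_timing(exams)
  tabf <- table_features(exams)
  counts <- purrr::map_dfr(seq_len(nrow(exams)), function(i) {
    seqs <- exams$sequences[[i]]
    std <- if (nrow(seqs)) standardize_names(seqs, vocabulary$rules) else character()
    known <- table(factor(std[std %in% vocabulary$names],
                          levels = vocabulary$names))
    row <- as.list(as.integer(known))
    names(row) <- feature_col_name(vocabulary$names)
    row$seq_OTHER <- sum(!std %in% vocabulary$names)
    coils <- tolower(unique(unlist(seqs$coil_ids)))
    grp <- lapply(coil_group_rules, function(rx) {
      as.integer(any(grepl(rx, coils, ignore.case = TRUE)))
    })
    names(grp) <- paste0("coil_", names(coil_group_rules))
    grp$coil_other <- as.integer(length(coils) > 0 && any(!Reduce(`|`, lapply(
      coil_group_rules, function(rx) grepl(rx, coils, ignore.case = TRUE)))))
    as_tibble(c(list(exam_id = exams$exam_id[[i]]), row, grp))
  })
  out <- counts |>
    dplyr::left_join(timing, by = "exam_id") |>
    dplyr::left_join(tabf, by = "exam_id") |>
    dplyr::mutate(
      contrast_given = as.integer(exams$contrast_given),
      approximate_age_years = as.numeric(exams$approximate_age_years),
      n_sequences = as.integer(exams$n_sequences),
      aborted = as.integer(exams$aborted)
    )
  # fixed column order: id, sequence counts, overflow, coils, timing, table,
  # context
  ord <- c("exam_id", feature_col_name(vocabulary$names), "seq_OTHER",
           paste0("coil_", c(names(coil_group_rules), "other")),
           "acq_s", "uop_s", "uop_acq_ratio",
           "table_total_movement_mm", "table_min_mm", "table_max_mm",
           "table_mean_step_mm", "contrast_given", "approximate_age_years",
           "n_sequences", "aborted")
  out[, ord]
}
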