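# Hand-built exams, sequences and labelsets used across test files.

ts_utc <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")

# a sequence-record tibble with sensible defaults, overridable per field
make_sequences <- function(n = 1, raw_name = paste0("seq", seq_len(n)),
                           start = ts_utc("2024-01-01T08:05:00") + (seq_len(n) - 1) * 400,
                           duration_s = 300,
                           tr_ms = 4000, te_ms = 90, ti_ms = NA_real_,
                           technique = "tse", orientation = "tra",
                           fat_saturation = FALSE, breath_hold = FALSE,
                           b_values = rep(list(numeric()), n),
                           coil_ids = rep(list("Head32"), n),
                           table_position_mm = 0) {
  tibble::tibble(
    raw_name = raw_name, start_time = start, end_time = start + duration_s,
    tr_ms = tr_ms, te_ms = te_ms, ti_ms = ti_ms, technique = technique,
    dimensionality = "2d", orientation = orientation,
    fat_saturation = fat_saturation, breath_hold = breath_hold,
    b_values = b_values, fov_mm = 250, slice_thickness_mm = 4,
    coil_ids = coil_ids, table_position_mm = table_position_mm
  )
}

make_exam <- function(exam_id = "E1", sequences = make_sequences(),
                      registration = ts_utc("2024-01-01T08:00:00"),
                      table_positions = NULL, contrast = FALSE, age = 50) {
  tibble::tibble(
    exam_id = exam_id, scanner_id = "MR1",
    registration_time = registration,
    end_time = if (nrow(sequences)) max(sequences$end_time) else registration,
    approximate_age_years = age, contrast_given = contrast,
    n_sequences = nrow(sequences), aborted = nrow(sequences) == 0,
    sequences = list(sequences),
    table_positions = list(
      table_positions %||%
        tibble::tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                       position_mm = numeric()))
  )
}

`%||%` <- rlang::`%||%`

# random long-form labelsets over small universes (counts up to 3)
random_labelsets <- function(n_exams = 8, codes = c("A", "B", "C", "D", "E"),
                             p_present = 0.4, max_count = 3) {
  rows <- list()
  for (i in seq_len(n_exams)) {
    for (code in codes) {
      if (runif(1) < p_present) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          exam_id = sprintf("X%03d", i), code_id = code,
          count = sample.int(max_count, 1))
      }
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(exam_id = character(), code_id = character(),
                   count = integer())
}

# shared small synthetic dataset, generated once per test run
cached_dataset <- local({
  cache <- new.env(parent = emptyenv())
  function(n_exams = 300, seed = 20240101) {
    key <- sprintf("d%d_%d", n_exams, seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- generate_dataset(generator_config(n_exams = n_exams,
                                                        seed = seed))
    }
    cache[[key]]
  }
})
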