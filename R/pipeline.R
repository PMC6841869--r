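#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run: generator settings, label
#' cleaning, model and evaluation options. Unknown names are rejected so
#' config typos fail before any stage runs.
#'
#' @param n_exams Number of synthetic exams to generate.
#' @param seed Master seed; stage seeds are derived from it.
#' @param mix Optional template mix (see [generator_config()]).
#' @param test_fraction Held-out fraction (default 0.3).
#' @param split `"temporal"` (default; the test set is the final contiguous
#'   fraction by registration time, mirroring a held-out final month) or
#'   `"random"`.
#' @param min_instances Rare-code pruning threshold on the training data.
#' @param spec Base-classifier [base_spec()].
#' @param method `"ecc"` (default) or `"br"`.
#' @param n_chains Chains in the ensemble.
#' @param forget_rate,add_rate Technologist-simulator noise applied to the
#'   *reported* labels; the evaluation truth stays clean. With both 0 the
#'   reported labels equal the truth.
#' @param include_aborted Keep zero-sequence (aborted) exams in the
#'   modelling data; default drops them, as they carry empty labelsets.
#' @return A list of class `mri_pipeline_config`.
#' @export
pipeline_config <- function(n_exams = 500, seed = 1, mix = NULL,
                            test_fraction = 0.3,
                            split = c("temporal", "random"),
                            min_instances = 20,
                            spec = base_spec("mlp"),
                            method = c("ecc", "br"), n_chains = 10,
                            forget_rate = 0, add_rate = 0,
                            include_aborted = FALSE) {
  split <- match.arg(split)
  method <- match.arg(method)
  structure(list(n_exams = n_exams, seed = seed, mix = mix,
                 test_fraction = test_fraction, split = split,
                 min_instances = min_instances, spec = spec,
                 method = method, n_chains = n_chains,
                 forget_rate = forget_rate, add_rate = add_rate,
                 include_aborted = include_aborted),
            class = "mri_pipeline_config")
}

config_digest <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  unname(tools::md5sum(tf))
}

#' Run the full prediction pipeline on a seeded synthetic dataset
#'
#' Executes simulate -> assemble -> merge billing -> clean labels ->
#' standardize/featurize -> train -> predict -> evaluate, optionally
#' writing the evaluation report, per-code table and a run manifest to
#' `out_dir`. The whole run is a deterministic function of the config:
#' re-running with an identical config reproduces every metric (and every
#' written byte) exactly.
#'
#' Training-time discipline: the sequence-name vocabulary, the rare-code
#' list and all feature scalers are fitted on the training split only; the
#' test split is cleaned with the tariff rules (mirroring manual
#' ground-truthing of a held-out month) and restricted to the training
#' code universe.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; created if needed.
#' @return A list with the fitted `model`, `report` (an `mri_eval_report`
#'   for the automated coder), `manual_report` and `comparison` (present
#'   when noise rates are positive), the `split` ids, and bookkeeping
#'   (`config`, `digest`, `kept_codes`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "mri_pipeline_config"))
  ds <- generate_dataset(generator_config(
    n_exams = config$n_exams, mix = config$mix, seed = config$seed))
  exams <- assemble_exams(ds$events)
  exams <- merge_billing(exams, ds$truth)
  if (!config$include_aborted) exams <- exams[!exams$aborted, ]

  # split before any fitting; temporal = final contiguous fraction by time
  n <- nrow(exams)
  n_test <- max(1L, round(config$test_fraction * n))
  if (config$split == "temporal") {
    ord <- order(exams$registration_time)
    test_ids <- exams$exam_id[ord][(n - n_test + 1L):n]
  } else {
    set.seed(config$seed + 1L)
    test_ids <- sample(exams$exam_id, n_test)
  }
  train <- exams[!exams$exam_id %in% test_ids, ]
  test <- exams[exams$exam_id %in% test_ids, ]

  defs <- example_code_defs()
  truth_all <- exam_labelsets(exams)
  y_train <- clean_labelsets(truth_all[truth_all$exam_id %in% train$exam_id, ],
                             defs, min_instances = config$min_instances)
  kept <- side_report(y_train, "kept")
  y_test <- truth_all[truth_all$exam_id %in% test$exam_id, ]
  y_test <- enforce_max_counts(exclude_nonimaging(y_test, defs), defs)
  y_test <- y_test[y_test$code_id %in% kept, ]

  # reported (possibly miscoded) training labels; evaluation truth is clean
  set.seed(config$seed + 2L)
  y_train_reported <- if (config$forget_rate > 0 || config$add_rate > 0) {
    simulate_technologist(y_train, defs, config$forget_rate,
                          config$add_rate, exam_ids = train$exam_id)
  } else y_train

  vocab <- fit_vocabulary(train)
  x_train <- featurize(train, vocab)
  x_test <- featurize(test, vocab)

  set.seed(config$seed + 3L)
  model <- if (config$method == "ecc") {
    fit_ecc(x_train, y_train_reported, spec = config$spec,
            n_chains = config$n_chains, codes = kept)
  } else {
    fit_binary_relevance(x_train, y_train_reported, spec = config$spec,
                         codes = kept)
  }
  pred <- predict(model, x_test)
  report <- evaluate_predictions(
    label_matrix(y_test, exam_ids = test$exam_id, code_ids = kept), pred,
    code_defs = defs, prevalence_labelsets = y_train,
    n_exams_prevalence = nrow(train))

  manual_report <- comparison <- NULL
  if (config$forget_rate > 0 || config$add_rate > 0) {
    set.seed(config$seed + 4L)
    y_test_manual <- simulate_technologist(y_test, defs, config$forget_rate,
                                           config$add_rate,
                                           exam_ids = test$exam_id)
    truth_m <- label_matrix(y_test, exam_ids = test$exam_id, code_ids = kept)
    manual_m <- label_matrix(
      y_test_manual[y_test_manual$code_id %in% kept, ],
      exam_ids = test$exam_id, code_ids = kept)
    manual_report <- evaluate_predictions(truth_m, manual_m, code_defs = defs)
    comparison <- paired_comparison(truth_m, pred, manual_m)
  }

  result <- list(model = model, report = report,
                 manual_report = manual_report, comparison = comparison,
                 kept_codes = kept, test_ids = sort(test_ids),
                 config = config, digest = config_digest(config))
  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

report_to_list <- function(report) {
  list(
    micro = as.list(report$micro),
    macro = as.list(report$macro),
    subset_accuracy = report$subset_accuracy,
    n_exams = report$n_exams, n_codes = report$n_codes,
    cardinality_truth = report$cardinality_truth,
    cardinality_pred = report$cardinality_pred,
    density_pred = report$density_pred,
    diversity_pred = report$diversity_pred
  )
}

write_run <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_to_list(result$report),
                       file.path(out_dir, "eval_report.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(result$report$per_code, file.path(out_dir, "per_code.csv"))
  manifest <- list(config = unclass(result$config),
                   config_digest = result$digest,
                   kept_codes = result$kept_codes,
                   n_test = length(result$test_ids))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(out_dir)
}
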