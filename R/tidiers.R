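#' Tidy an evaluation report into the per-code table
#'
#' @param x An `mri_eval_report` from [evaluate_predictions()].
#' @param ... Unused.
#' @return A tibble with one row per code: `code_id`, `prevalence`,
#'   confusion counts and `precision`/`recall`/`f1`.
#' @method tidy mri_eval_report
#' @export
tidy.mri_eval_report <- function(x, ...) {
  x$per_code
}

#' One-row summary of an evaluation report
#'
#' @inheritParams tidy.mri_eval_report
#' @return A one-row tibble with micro/macro scores, subset accuracy and
#'   the prediction label metrics.
#' @method glance mri_eval_report
#' @export
glance.mri_eval_report <- function(x, ...) {
  tibble(
    micro_precision = x$micro$precision, micro_recall = x$micro$recall,
    micro_f1 = x$micro$f1,
    macro_precision = x$macro$precision, macro_recall = x$macro$recall,
    macro_f1 = x$macro$f1,
    subset_accuracy = x$subset_accuracy,
    cardinality_pred = x$cardinality_pred,
    density_pred = x$density_pred,
    diversity_pred = x$diversity_pred,
    n_exams = x$n_exams, n_codes = x$n_codes
  )
}

#' Per-code prevalence versus F1 plot
#'
#' Visualizes the relationship driving the prevalence--performance
#' correlation: codes that are rare in the training data tend to be
#' predicted worse.
#'
#' @param object An `mri_eval_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mri_eval_report
#' @export
autoplot.mri_eval_report <- function(object, ...) {
  ggplot2::ggplot(object$per_code,
                  ggplot2::aes(x = .data$prevalence, y = .data$f1)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "code prevalence in reference exams (log scale)",
                  y = "per-code F1",
                  title = "Code prevalence vs prediction quality") +
    ggplot2::theme_minimal()
}

#' Tidy an ensemble of classifier chains
#'
#' @param x An `mri_ecc` from [fit_ecc()].
#' @param ... Unused.
#' @return A tibble `chain`, `position`, `code_id` giving each chain's
#'   label order.
#' @method tidy mri_ecc
#' @export
tidy.mri_ecc <- function(x, ...) {
  purrr::map_dfr(seq_along(x$chains), function(i) {
    tibble(chain = i,
           position = seq_along(x$chains[[i]]$label_order),
           code_id = x$chains[[i]]$label_order)
  })
}

#' One-row summary of an ensemble of classifier chains
#'
#' @inheritParams tidy.mri_ecc
#' @return A one-row tibble with the ensemble shape.
#' @method glance mri_ecc
#' @export
glance.mri_ecc <- function(x, ...) {
  tibble(n_chains = x$n_chains, n_codes = length(x$codes),
         base_family = x$spec$family,
         n_features = length(x$feature_names))
}

#' Distribution of charged codes per exam
#'
#' Bar chart of the number of charged units per exam, including exams with
#' empty labelsets (aborted exams) when `n_exams` exceeds the number of
#' exams present in the labelsets.
#'
#' @param labelsets Long labelset tibble.
#' @param n_exams Total exam count (to include empty labelsets).
#' @return A ggplot.
#' @export
plot_code_distribution <- function(labelsets, n_exams = NULL) {
  per_exam <- labelsets |>
    dplyr::group_by(.data$exam_id) |>
    dplyr::summarise(n_codes = sum(.data$count), .groups = "drop")
  m <- n_exams %||% nrow(per_exam)
  if (m > nrow(per_exam)) {
    per_exam <- dplyr::bind_rows(
      per_exam,
      tibble(exam_id = sprintf(".empty%d", seq_len(m - nrow(per_exam))),
             n_codes = 0L))
  }
  ggplot2::ggplot(per_exam, ggplot2::aes(x = .data$n_codes)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "charged units per exam", y = "exams",
                  title = "Billing-code counts per exam") +
    ggplot2::theme_minimal()
}
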