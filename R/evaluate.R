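#' @name metrics
#' @title Multi-output evaluation metrics
#'
#' @description
#' Metrics operate on count-valued labelsets, given either as long tibbles
#' (`exam_id`, `code_id`, `count`) or as exams-by-codes count matrices
#' ([label_matrix()]). Per-code confusion counts use a unit-expansion
#' convention: with truth count t and predicted count p for a code with
#' maximum K, TP = min(t, p), FP = max(0, p - t), FN = max(0, t - p), and
#' TN = K - max(t, p) unit slots. Precision, recall and F1 depend only on
#' TP/FP/FN, so the TN convention does not affect any reported score.
NULL

as_count_matrix <- function(x, exam_ids = NULL, code_ids = NULL) {
  if (is.matrix(x)) {
    m <- x
    if (!is.null(exam_ids) || !is.null(code_ids)) {
      m <- label_matrix(matrix_to_labelsets(x),
                        exam_ids = exam_ids %||% rownames(x),
                        code_ids = code_ids %||% colnames(x))
    }
    return(m)
  }
  label_matrix(x, exam_ids = exam_ids, code_ids = code_ids)
}

align_label_universe <- function(...) {
  inputs <- list(...)
  exam_ids <- sort(unique(unlist(lapply(inputs, function(x) {
    if (is.matrix(x)) rownames(x) else unique(x$exam_id)
  }))))
  code_ids <- sort(unique(unlist(lapply(inputs, function(x) {
    if (is.matrix(x)) colnames(x) else unique(x$code_id)
  }))))
  lapply(inputs, as_count_matrix, exam_ids = exam_ids, code_ids = code_ids)
}

#' Label cardinality: mean charged units per exam
#'
#' Sum of all label counts divided by the number of exams, so a
#' twice-charged code contributes two. Measures the degree of
#' multi-labeledness of a dataset.
#'
#' @param labelsets Long labelset tibble or count matrix.
#' @param n_exams Number of exams; needed with long input when some exams
#'   have empty labelsets (they contribute zero but must be counted).
#' @return A single number.
#' @export
label_cardinality <- function(labelsets, n_exams = NULL) {
  if (is.matrix(labelsets)) return(sum(labelsets) / nrow(labelsets))
  m <- n_exams %||% dplyr::n_distinct(labelsets$exam_id)
  if (m == 0) return(0)
  sum(labelsets$count) / m
}

#' Label density: cardinality normalized by the code universe size
#'
#' @inheritParams label_cardinality
#' @param n_codes Total number of possible codes (the label-space size
#'   used for normalization is stated explicitly rather than inferred,
#'   since conventions differ on whether it counts codes or unit slots).
#' @return A single number.
#' @export
label_density <- function(labelsets, n_codes, n_exams = NULL) {
  stopifnot_scalar_number(n_codes, "n_codes", min = 1)
  label_cardinality(labelsets, n_exams) / n_codes
}

#' Label diversity: number of distinct labelsets
#'
#' Full code -> count maps are compared for equality; the empty labelset is
#' one distinct value.
#'
#' @inheritParams label_cardinality
#' @return An integer.
#' @export
label_diversity <- function(labelsets, n_exams = NULL) {
  if (is.matrix(labelsets)) {
    return(nrow(unique(labelsets)))
  }
  keys <- labelsets |>
    dplyr::filter(.data$count > 0) |>
    dplyr::arrange(.data$exam_id, .data$code_id) |>
    dplyr::group_by(.data$exam_id) |>
    dplyr::summarise(
      key = paste(.data$code_id, .data$count, sep = ":", collapse = "|"),
      .groups = "drop")
  n_distinct_nonempty <- dplyr::n_distinct(keys$key)
  m <- n_exams %||% dplyr::n_distinct(labelsets$exam_id)
  has_empty <- m > nrow(keys)
  n_distinct_nonempty + as.integer(has_empty)
}

#' Per-code confusion counts for count-valued predictions
#'
#' @param truth,pred Labelsets (long tibble or count matrix); the exam and
#'   code universes are aligned to their union.
#' @param code_defs Optional code-definition table supplying `max_count`
#'   for the TN unit-slot bound; without it TN uses the largest observed
#'   count per code.
#' @return A tibble `code_id`, `tp`, `fp`, `fn`, `tn` (summed over exams).
#' @export
count_confusion <- function(truth, pred, code_defs = NULL) {
  al <- align_label_universe(truth, pred)
  t <- al[[1]]; p <- al[[2]]
  kmax <- if (!is.null(code_defs)) {
    code_defs <- validate_code_defs(code_defs)
    k <- setNames(code_defs$max_count, code_defs$code_id)[colnames(t)]
    ifelse(is.na(k), pmax(apply(t, 2, max), apply(p, 2, max), 1), k)
  } else {
    pmax(apply(t, 2, max), apply(p, 2, max), 1)
  }
  tp <- colSums(pmin(t, p))
  fp <- colSums(pmax(p - t, 0))
  fn <- colSums(pmax(t - p, 0))
  tn <- colSums(matrix(rep(kmax, each = nrow(t)), nrow = nrow(t)) - pmax(t, p))
  tibble(code_id = colnames(t), tp = as.numeric(tp), fp = as.numeric(fp),
         fn = as.numeric(fn), tn = as.numeric(tn))
}

prf <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Micro-averaged precision, recall and F1
#'
#' Pools TP/FP/FN over all codes before applying the binary metric, so
#' frequent codes dominate. Empty denominators yield 0 with a warning.
#'
#' @param confusion Per-code confusion tibble from [count_confusion()].
#' @return A one-row tibble `precision`, `recall`, `f1`.
#' @export
micro_metrics <- function(confusion) {
  tp <- sum(confusion$tp); fp <- sum(confusion$fp); fn <- sum(confusion$fn)
  if (tp + fp == 0 || tp + fn == 0) {
    warn("empty denominator in micro metrics; undefined rates reported as 0")
  }
  as_tibble(as.list(prf(tp, fp, fn)))
}

#' Macro-averaged precision, recall and F1
#'
#' Applies the binary metric per code and averages with equal weight, so
#' rare codes count as much as frequent ones.
#'
#' @inheritParams micro_metrics
#' @return A one-row tibble `precision`, `recall`, `f1`.
#' @export
macro_metrics <- function(confusion) {
  per <- t(mapply(prf, confusion$tp, confusion$fp, confusion$fn))
  as_tibble(as.list(colMeans(per)))
}

#' Subset accuracy (exact labelset match)
#'
#' Fraction of exams whose entire predicted labelset -- all codes, all
#' counts -- equals the truth.
#'
#' @inheritParams count_confusion
#' @return A single fraction.
#' @export
subset_accuracy <- function(truth, pred) {
  al <- align_label_universe(truth, pred)
  mean(rowSums(al[[1]] != al[[2]]) == 0)
}

#' Spearman correlation between code prevalence and per-code F1
#'
#' Restricted to codes with imperfect F1 (< 1), since codes already
#' predicted perfectly carry no information about what more training data
#' could buy. Ties are handled with average ranks; the p-value is the
#' two-sided asymptotic one.
#'
#' @param per_code A tibble with columns `prevalence` and `f1`.
#' @return A one-row tibble `rho`, `p_value`, `n_codes`.
#' @export
prevalence_f1_correlation <- function(per_code) {
  sub <- per_code[per_code$f1 < 1, , drop = FALSE]
  if (nrow(sub) < 3) {
    warn("fewer than 3 imperfect codes; correlation not estimable")
    return(tibble(rho = NA_real_, p_value = NA_real_, n_codes = nrow(sub)))
  }
  ct <- suppressWarnings(
    cor.test(sub$prevalence, sub$f1, method = "spearman", exact = FALSE))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n_codes = nrow(sub))
}

#' Reimbursement impact of coding errors
#'
#' Values every unit of every code at its tariff points.
#' `undercoding_loss_frac` is the share of truly earned points lost to
#' missed units (truth above coded); `overcoding_excess_frac` is the share
#' of falsely charged extra points (coded above truth). Both are
#' normalized by the total points of the true labelsets.
#'
#' @param truth,coded Labelsets (long tibble or count matrix).
#' @param code_defs Code-definition table with `tariff_points`.
#' @return A one-row tibble `undercoding_loss_frac`,
#'   `overcoding_excess_frac`.
#' @export
reimbursement_delta <- function(truth, coded, code_defs) {
  code_defs <- validate_code_defs(code_defs)
  al <- align_label_universe(truth, coded)
  t <- al[[1]]; p <- al[[2]]
  pts <- setNames(code_defs$tariff_points, code_defs$code_id)[colnames(t)]
  if (any(is.na(pts))) abort("missing tariff_points for some charged codes")
  total <- sum(t %*% pts)
  if (total == 0) abort("truth labelsets carry zero tariff points")
  under <- sum(pmax(t - p, 0) %*% pts) / total
  over <- sum(pmax(p - t, 0) %*% pts) / total
  tibble(undercoding_loss_frac = under, overcoding_excess_frac = over)
}

#' Exam-wise comparison of two coders against ground truth
#'
#' Classifies every exam by the exact-match correctness of an automated
#' and a manual coder, yielding the Venn-style quadrant fractions
#' both-correct / auto-only / manual-only / neither (summing to 1).
#'
#' @param truth,pred_auto,pred_manual Labelsets (long tibble or matrix).
#' @return A one-row tibble `both_correct`, `auto_only`, `manual_only`,
#'   `neither`.
#' @export
paired_comparison <- function(truth, pred_auto, pred_manual) {
  al <- align_label_universe(truth, pred_auto, pred_manual)
  t <- al[[1]]
  ok_a <- rowSums(al[[2]] != t) == 0
  ok_m <- rowSums(al[[3]] != t) == 0
  tibble(both_correct = mean(ok_a & ok_m),
         auto_only = mean(ok_a & !ok_m),
         manual_only = mean(!ok_a & ok_m),
         neither = mean(!ok_a & !ok_m))
}

#' Evaluate predicted labelsets against ground truth
#'
#' Bundles the full report: micro and macro precision/recall/F1, subset
#' accuracy, label cardinality/density/diversity of the predictions, and a
#' per-code table with prevalence (fraction of reference exams charging
#' the code, taken from `prevalence_labelsets` -- typically the training
#' data) and per-code F1.
#'
#' @param truth,pred Labelsets (long tibble or count matrix).
#' @param code_defs Optional code-definition table.
#' @param prevalence_labelsets Labelsets used for the prevalence column;
#'   defaults to `truth`.
#' @param n_exams_prevalence Exam count behind `prevalence_labelsets`
#'   (needed if it is long-form with empty-labelset exams).
#' @return An object of class `mri_eval_report`; see [tidy.mri_eval_report()].
#' @export
evaluate_predictions <- function(truth, pred, code_defs = NULL,
                                 prevalence_labelsets = NULL,
                                 n_exams_prevalence = NULL) {
  al <- align_label_universe(truth, pred)
  t <- al[[1]]; p <- al[[2]]
  conf <- count_confusion(t, p, code_defs)
  per <- t(mapply(prf, conf$tp, conf$fp, conf$fn))
  prev_src <- prevalence_labelsets %||% t
  prev_m <- as_count_matrix(prev_src, code_ids = colnames(t))
  n_prev <- n_exams_prevalence %||% nrow(prev_m)
  per_code <- tibble(
    code_id = conf$code_id,
    prevalence = colSums(prev_m > 0) / n_prev,
    tp = conf$tp, fp = conf$fp, fn = conf$fn,
    precision = per[, "precision"], recall = per[, "recall"], f1 = per[, "f1"]
  )
  structure(list(
    micro = micro_metrics(conf),
    macro = macro_metrics(conf),
    subset_accuracy = subset_accuracy(t, p),
    n_exams = nrow(t),
    n_codes = ncol(t),
    cardinality_truth = label_cardinality(t),
    cardinality_pred = label_cardinality(p),
    density_pred = label_density(p, ncol(t)),
    diversity_pred = label_diversity(p),
    per_code = per_code
  ), class = "mri_eval_report")
}

#' @export
print.mri_eval_report <- function(x, ...) {
  cat("<mri_eval_report> ", x$n_exams, " exams, ", x$n_codes, " codes\n", sep = "")
  cat(sprintf("  micro  P %.3f  R %.3f  F1 %.3f\n",
              x$micro$precision, x$micro$recall, x$micro$f1))
  cat(sprintf("  macro  P %.3f  R %.3f  F1 %.3f\n",
              x$macro$precision, x$macro$recall, x$macro$f1))
  cat(sprintf("  subset accuracy %.3f\n", x$subset_accuracy))
  cat(sprintf("  predicted cardinality %.2f, density %.3f, diversity %d\n",
              x$cardinality_pred, x$density_pred, x$diversity_pred))
  invisible(x)
}
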