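#' @name labelsets
#' @title Count-valued billing labelsets
#'
#' @description
#' The multi-output target for one exam is a map code -> count (how many
#' times each billing code was charged); codes not listed are implicitly 0.
#' Across a dataset, labelsets are represented as a long tibble with columns
#' `exam_id`, `code_id`, `count` (rows only for charged codes), convertible
#' to a dense exams-by-codes integer matrix with [label_matrix()].
NULL

#' Convert long labelsets to a dense exams-by-codes count matrix
#'
#' @param labelsets Long labelset tibble (see [labelsets]).
#' @param exam_ids Row universe; defaults to the exams present.
#' @param code_ids Column universe; defaults to the codes present.
#' @return Integer matrix with `exam_ids` rownames and `code_ids` colnames.
#' @export
label_matrix <- function(labelsets, exam_ids = NULL, code_ids = NULL) {
  exam_ids <- exam_ids %||% sort(unique(labelsets$exam_id))
  code_ids <- code_ids %||% sort(unique(labelsets$code_id))
  m <- matrix(0L, nrow = length(exam_ids), ncol = length(code_ids),
              dimnames = list(exam_ids, code_ids))
  keep <- labelsets$exam_id %in% exam_ids & labelsets$code_id %in% code_ids
  ls <- labelsets[keep, ]
  if (nrow(ls)) m[cbind(ls$exam_id, ls$code_id)] <- as.integer(ls$count)
  m
}

#' Convert a count matrix back to a long labelset tibble
#'
#' @param m Integer matrix with exam rownames and code colnames.
#' @return Long labelset tibble (zero counts dropped).
#' @export
matrix_to_labelsets <- function(m) {
  idx <- which(m > 0, arr.ind = TRUE)
  out <- tibble(exam_id = rownames(m)[idx[, 1]],
                code_id = colnames(m)[idx[, 2]],
                count = as.integer(m[idx]))
  dplyr::arrange(out, .data$exam_id, .data$code_id)
}

#' Drop non-imaging-related billing codes
#'
#' Codes flagged `imaging_related = FALSE` (i.v. access, sedation
#' surcharges, physician services in absence of the patient, ...) are not
#' predictable from modality logs and are removed before modelling. Every
#' code present must have a definition.
#'
#' @param labelsets Long labelset tibble.
#' @param code_defs Code-definition table ([example_code_defs()]).
#' @return The filtered labelset tibble.
#' @export
exclude_nonimaging <- function(labelsets, code_defs) {
  code_defs <- validate_code_defs(code_defs)
  unknown <- setdiff(unique(labelsets$code_id), code_defs$code_id)
  if (length(unknown)) {
    abort(sprintf("labelsets contain codes without a definition: %s",
                  paste(unknown, collapse = ", ")))
  }
  imaging <- code_defs$code_id[code_defs$imaging_related]
  labelsets[labelsets$code_id %in% imaging, , drop = FALSE]
}

#' Enforce per-code maximum charge counts
#'
#' Counts above a code's `max_count` violate the tariff's charging rules
#' and are truncated to the allowed quantity. Every truncation is recorded
#' in a `corrections` side report (`exam_id`, `code_id`, `before`, `after`,
#' `rule`).
#'
#' @inheritParams exclude_nonimaging
#' @return The corrected labelset tibble with a `corrections` side report.
#' @export
enforce_max_counts <- function(labelsets, code_defs) {
  code_defs <- validate_code_defs(code_defs)
  kmax <- setNames(code_defs$max_count, code_defs$code_id)
  out <- labelsets
  limit <- unname(kmax[out$code_id])
  if (any(is.na(limit))) {
    abort("labelsets contain codes without a definition")
  }
  over <- which(out$count > limit)
  corrections <- tibble(
    exam_id = out$exam_id[over], code_id = out$code_id[over],
    before = as.integer(out$count[over]), after = as.integer(limit[over]),
    rule = rep("max_count", length(over))
  )
  out$count[over] <- limit[over]
  set_side_report(out, "corrections", corrections)
}

#' Discard rarely charged codes from training labelsets
#'
#' A code is kept iff it appears (count >= 1) in at least `min_instances`
#' training exams; rarer codes cannot be learned reliably and are deleted
#' from all labelsets. "Instances" are exams containing the code, not
#' charged units. Apply to training data only -- the kept-code list then
#' defines the label space for the test set too.
#'
#' @param labelsets Long labelset tibble (training data).
#' @param min_instances Minimum exam count, default 20.
#' @return The pruned labelset tibble with side reports `kept` and
#'   `removed` (character vectors of code ids).
#' @export
prune_rare_codes <- function(labelsets, min_instances = 20) {
  stopifnot_scalar_number(min_instances, "min_instances", min = 1)
  per_code <- labelsets |>
    dplyr::filter(.data$count >= 1) |>
    dplyr::distinct(.data$exam_id, .data$code_id) |>
    dplyr::count(.data$code_id, name = "n_exams")
  kept <- per_code$code_id[per_code$n_exams >= min_instances]
  removed <- sort(setdiff(unique(labelsets$code_id), kept))
  out <- labelsets[labelsets$code_id %in% kept, , drop = FALSE]
  out <- set_side_report(out, "kept", sort(kept))
  set_side_report(out, "removed", removed)
}

#' Reimbursement share of removed codes
#'
#' Fraction of total tariff points in the (training) labelsets that the
#' removed codes account for; used to check that rare-code pruning is
#' economically negligible.
#'
#' @param removed_codes Character vector of removed code ids.
#' @param labelsets The unpruned labelset tibble the share refers to.
#' @param code_defs Code-definition table with `tariff_points`.
#' @return A single fraction in \[0, 1\].
#' @export
removed_reimbursement_share <- function(removed_codes, labelsets, code_defs) {
  code_defs <- validate_code_defs(code_defs)
  pts <- setNames(code_defs$tariff_points, code_defs$code_id)
  occ <- pts[labelsets$code_id] * labelsets$count
  if (any(is.na(occ))) abort("missing tariff_points for some charged codes")
  total <- sum(occ)
  if (total == 0) return(0)
  sum(occ[labelsets$code_id %in% removed_codes]) / total
}

#' Full label-cleaning pipeline
#'
#' Fixed, idempotent order: drop non-imaging codes, truncate counts above
#' the per-code maximum, prune rare codes. Pruning is meant for training
#' labelsets; disable it (`prune = FALSE`) when cleaning held-out data with
#' an externally supplied kept-code list.
#'
#' @inheritParams exclude_nonimaging
#' @param min_instances Pruning threshold, see [prune_rare_codes()].
#' @param prune Whether to prune rare codes.
#' @return Cleaned labelset tibble; side reports `corrections`, `kept`,
#'   `removed` are carried over.
#' @export
clean_labelsets <- function(labelsets, code_defs, min_instances = 20,
                            prune = TRUE) {
  out <- exclude_nonimaging(labelsets, code_defs)
  out <- enforce_max_counts(out, code_defs)
  corrections <- side_report(out, "corrections")
  if (prune) {
    pruned <- prune_rare_codes(out, min_instances)
    pruned <- set_side_report(pruned, "corrections", corrections)
    return(pruned)
  }
  out
}
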