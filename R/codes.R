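#' Billing-code definition table
#'
#' Per-code metadata used throughout the pipeline: the maximum number of
#' times a code may be charged for one exam (`max_count`, the per-label
#' class-range bound K_j), whether the service is imaging-related (only
#' imaging-related codes are predictable from modality logs), the tariff
#' points that determine reimbursement, and whether the code is an auxiliary
#' surcharge charged alongside a main procedure code (e.g. an additional
#' series, an arthrogram, or an MR angiography surcharge).
#'
#' `example_code_defs()` returns a synthetic 24-code table: 22 imaging-related
#' codes (fourteen chargeable once, six twice, two up to four times) plus two
#' non-imaging codes (i.v. access, sedation surcharge) that exercise the
#' exclusion rule. Code ids follow the Tarmed chapter-39 numbering style but
#' the table is a structural stand-in, not the real tariff catalogue.
#'
#' @return A tibble with columns `code_id`, `max_count`, `imaging_related`,
#'   `tariff_points`, `auxiliary`, `description`.
#' @export
#' @examples
#' example_code_defs()
example_code_defs <- function() {
  defs <- tibble::tribble(
    ~code_id,  ~max_count, ~imaging_related, ~tariff_points, ~auxiliary, ~description,
    "39.0255", 1L, TRUE,  750, FALSE, "MRI head",
    "39.0260", 1L, TRUE,  700, FALSE, "MRI orbits / inner ear",
    "39.0270", 1L, TRUE,  680, FALSE, "MRI neck soft tissue",
    "39.0305", 1L, TRUE,  720, FALSE, "MRI cervical spine",
    "39.0310", 2L, TRUE,  720, FALSE, "MRI spine, further segment",
    "39.0320", 1L, TRUE,  740, FALSE, "MRI pelvis",
    "39.0330", 1L, TRUE,  760, FALSE, "MRI thorax",
    "39.0340", 1L, TRUE,  780, FALSE, "MRI abdomen",
    "39.0345", 1L, TRUE,  790, FALSE, "MRI liver, dedicated",
    "39.0350", 1L, TRUE,  950, FALSE, "MRI heart",
    "39.0360", 2L, TRUE,  640, FALSE, "MRI large joint / extremity",
    "39.0365", 2L, TRUE,  620, FALSE, "MRI long bone",
    "39.0370", 2L, TRUE,  600, FALSE, "MRI hand / foot",
    "39.0380", 1L, TRUE,  700, FALSE, "MRI breast",
    "39.0410", 2L, TRUE,  260, TRUE,  "Arthrogram surcharge",
    "39.5010", 4L, TRUE,  200, TRUE,  "Surcharge, additional series",
    "39.5020", 4L, TRUE,  240, TRUE,  "MR angiography surcharge",
    "39.5050", 2L, TRUE,  180, FALSE, "Contrast-medium series surcharge",
    "39.5100", 1L, TRUE,  900, FALSE, "Whole-body MRI surcharge",
    "39.5110", 1L, TRUE,  880, FALSE, "Cardiac stress protocol surcharge",
    "39.5200", 1L, TRUE,  560, FALSE, "MR spectroscopy",
    "39.5300", 1L, TRUE, 1100, FALSE, "MR-guided biopsy",
    "00.0010", 1L, FALSE,  30, FALSE, "Establishing intravenous access",
    "00.0020", 1L, FALSE,  90, FALSE, "Surcharge, sedated patient"
  )
  validate_code_defs(defs)
}

#' Validate a code-definition table
#'
#' @param code_defs A data frame with at least `code_id` and `max_count`;
#'   missing `imaging_related`, `tariff_points` or `auxiliary` columns are
#'   filled with permissive defaults.
#' @return The validated table as a tibble.
#' @export
validate_code_defs <- function(code_defs) {
  code_defs <- as_tibble(code_defs)
  if (!all(c("code_id", "max_count") %in% names(code_defs))) {
    abort("code_defs needs at least `code_id` and `max_count` columns")
  }
  if (anyDuplicated(code_defs$code_id)) abort("duplicate code_id in code_defs")
  if (any(code_defs$max_count < 1)) abort("max_count must be >= 1 for every code")
  if (!"imaging_related" %in% names(code_defs)) code_defs$imaging_related <- TRUE
  if (!"tariff_points" %in% names(code_defs)) code_defs$tariff_points <- NA_real_
  if (!"auxiliary" %in% names(code_defs)) code_defs$auxiliary <- FALSE
  code_defs$max_count <- as.integer(code_defs$max_count)
  code_defs
}
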