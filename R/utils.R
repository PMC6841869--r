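#' Retrieve a side report attached to a result
#'
#' Several pipeline steps (event ingestion, exam assembly, billing merge,
#' label cleaning) attach diagnostic tables -- rejected records, truncation
#' corrections, removed codes -- to their main return value as attributes so
#' that results stay pipeable. `side_report()` extracts one of them.
#'
#' @param x A result object returned by a mricoder function.
#' @param which Report name, e.g. `"rejects"`, `"corrections"`, `"removed"`,
#'   `"unmatched"`.
#' @return The report (usually a tibble), or `NULL` if absent.
#' @export
side_report <- function(x, which) {
  attr(x, paste0("mricoder_", which), exact = TRUE)
}

set_side_report <- function(x, which, value) {
  attr(x, paste0("mricoder_", which)) <- value
  x
}

# All log timestamps are second-resolution ISO-8601, handled in UTC.
parse_timestamp <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

format_timestamp <- function(x) {
  format(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

`%e%` <- function(x, y) if (is.null(x) || length(x) == 0 || all(is.na(x))) y else x

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s", name, format(min)))
  }
  invisible(x)
}
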