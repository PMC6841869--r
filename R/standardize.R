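#' Standardizer rule table
#'
#' Thresholds and token rules for heuristic sequence-name standardization.
#' Weighting is derived from acquisition parameters, never from the
#' user-defined raw name: diffusion if any b-values are present; FLAIR/STIR
#' by the inversion-time band; otherwise by the TR/TE quadrant. Defaults are
#' conventional 1.5--3 T bands and are deliberately configurable, since the
#' TR/TE ranges that separate T1 from T2 weighting shift with field strength
#' and sequence family.
#'
#' @param t1_tr_max,t1_te_max T1: TR below and TE below (ms). Default 800/30.
#' @param t2_tr_min,t2_te_min T2: TR at least and TE at least (ms). Default 2000/60.
#' @param pd_tr_min,pd_te_max Proton density: long TR, short TE (ms).
#' @param flair_ti,stir_ti Inversion-time bands (ms), length-2 ranges.
#' @return A named list of rules.
#' @export
standardizer_rules <- function(t1_tr_max = 800, t1_te_max = 30,
                               t2_tr_min = 2000, t2_te_min = 60,
                               pd_tr_min = 2000, pd_te_max = 30,
                               flair_ti = c(1800, 3000),
                               stir_ti = c(100, 250)) {
  list(t1_tr_max = t1_tr_max, t1_te_max = t1_te_max,
       t2_tr_min = t2_tr_min, t2_te_min = t2_te_min,
       pd_tr_min = pd_tr_min, pd_te_max = pd_te_max,
       flair_ti = flair_ti, stir_ti = stir_ti)
}

#' Derive the weighting token for MR sequences
#'
#' Rule order: diffusion (non-empty b-value list) beats inversion bands
#' (FLAIR, then STIR) beats the TR/TE quadrant (t1 / t2 / pd); parameter
#' combinations falling in none of the bands yield `"none"`.
#'
#' @param sequences A sequence tibble (columns `tr_ms`, `te_ms`, `ti_ms`,
#'   list-column `b_values`).
#' @param rules Rule table from [standardizer_rules()].
#' @return Character vector, one of `t1, t2, pd, flair, stir, diff, none`
#'   per row.
#' @export
derive_weighting <- function(sequences, rules = standardizer_rules()) {
  tr <- sequences$tr_ms
  te <- sequences$te_ms
  if (any(!is.finite(tr)) || any(!is.finite(te)) || any(tr <= 0) || any(te <= 0)) {
    abort("TR and TE must be positive for weighting derivation")
  }
  ti <- if ("ti_ms" %in% names(sequences)) sequences$ti_ms else
    rep(NA_real_, length(tr))
  bv <- if ("b_values" %in% names(sequences)) sequences$b_values else
    rep(list(numeric()), length(tr))
  has_b <- lengths(bv) > 0
  w <- rep("none", length(tr))
  w[!is.na(ti) & ti >= rules$stir_ti[1] & ti <= rules$stir_ti[2]] <- "stir"
  w[!is.na(ti) & ti >= rules$flair_ti[1] & ti <= rules$flair_ti[2]] <- "flair"
  quadrant <- is.na(ti) | (w == "none")
  w[quadrant & tr < rules$t1_tr_max & te < rules$t1_te_max] <- "t1"
  w[quadrant & tr >= rules$t2_tr_min & te >= rules$t2_te_min] <- "t2"
  w[quadrant & tr >= rules$pd_tr_min & te < rules$pd_te_max] <- "pd"
  w[has_b] <- "diff"
  w
}

#' Standardize MR sequence names from acquisition parameters
#'
#' Builds a canonical, comparable sequence name for each record from its
#' intrinsic acquisition parameters, so that user-defined raw-name variants
#' of the same sequence (shuffled token order, body-region tags, slice
#' thickness, post-contrast delay annotations) collapse to one name. Token
#' order is fixed: weighting, technique, `fs`, orientation, `bh`, rendered
#' lowercase with single spaces. Diffusion EPI is rendered as the fused
#' token `ep2d_diff` with no separate weighting token. The raw name is never
#' consulted except as a last-resort keyword scan when the structured
#' technique field is `"other"`.
#'
#' @param sequences A sequence tibble (see [log-events] for the columns).
#' @param rules Rule table from [standardizer_rules()].
#' @return Character vector of standardized names, one per row.
#' @export
#' @examples
#' seqs <- tibble::tibble(
#'   raw_name = "t2_haste_fs_tra_3mm_mbh",
#'   tr_ms = 2200, te_ms = 95, ti_ms = NA_real_,
#'   technique = "haste", orientation = "tra",
#'   fat_saturation = TRUE, breath_hold = TRUE,
#'   b_values = list(numeric())
#' )
#' standardize_names(seqs)  # "t2 haste fs tra bh"
standardize_names <- function(sequences, rules = standardizer_rules()) {
  n <- nrow(sequences)
  if (n == 0) return(character())
  weighting <- derive_weighting(sequences, rules)
  technique <- sequences$technique %e% rep("other", n)
  raw <- sequences$raw_name %e% rep("", n)
  # last-resort keyword scan when the structured technique field is unusable
  scan <- technique == "other"
  if (any(scan)) {
    known <- setdiff(TECHNIQUES, "other")
    technique[scan] <- vapply(raw[scan], function(nm) {
      hit <- known[stringr::str_detect(tolower(nm),
                                       stringr::fixed(known))]
      if (length(hit)) hit[which.max(nchar(hit))] else "other"
    }, character(1))
  }
  orientation <- sequences$orientation %e% rep("tra", n)
  # oblique slabs render as the dominant axis; with no axis recorded the
  # tie-break is transverse
  orientation[orientation == "oblique" | !orientation %in% ORIENTATIONS] <- "tra"
  fs <- isTRUE_vec(sequences$fat_saturation %e% rep(FALSE, n))
  bh <- isTRUE_vec(sequences$breath_hold %e% rep(FALSE, n))

  vapply(seq_len(n), function(i) {
    if (weighting[i] == "diff" && technique[i] == "ep2d") {
      tokens <- "ep2d_diff"
    } else {
      w <- if (weighting[i] == "none") character() else weighting[i]
      tokens <- c(w, technique[i])
    }
    if (fs[i]) tokens <- c(tokens, "fs")
    tokens <- c(tokens, orientation[i])
    if (bh[i]) tokens <- c(tokens, "bh")
    tolower(paste(tokens, collapse = " "))
  }, character(1))
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Vocabulary compression achieved by name standardization
#'
#' @param sequences A nonempty sequence tibble.
#' @param rules Rule table from [standardizer_rules()].
#' @return A tibble with `n_raw_unique`, `n_standardized_unique` and
#'   `reduction_fraction` = 1 - standardized/raw.
#' @export
vocabulary_stats <- function(sequences, rules = standardizer_rules()) {
  if (nrow(sequences) == 0) abort("vocabulary_stats needs at least one sequence")
  n_raw <- dplyr::n_distinct(sequences$raw_name)
  n_std <- dplyr::n_distinct(standardize_names(sequences, rules))
  tibble(n_raw_unique = n_raw, n_standardized_unique = n_std,
         reduction_fraction = 1 - n_std / n_raw)
}
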