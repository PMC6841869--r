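# Brute-force reference implementations for the evaluation metrics,
# deliberately written as plain loops, independent of the package's
# vectorized code paths.

oracle_confusion <- function(tm, pm, kmax) {
  out <- data.frame(code_id = colnames(tm), tp = 0, fp = 0, fn = 0, tn = 0)
  for (j in seq_len(ncol(tm))) {
    for (i in seq_len(nrow(tm))) {
      t <- tm[i, j]; p <- pm[i, j]
      out$tp[j] <- out$tp[j] + min(t, p)
      out$fp[j] <- out$fp[j] + max(0, p - t)
      out$fn[j] <- out$fn[j] + max(0, t - p)
      out$tn[j] <- out$tn[j] + kmax[j] - max(t, p)
    }
  }
  out
}

oracle_prf <- function(tp, fp, fn) {
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  rc <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  c(pr, rc, f1)
}

oracle_micro <- function(conf) {
  oracle_prf(sum(conf$tp), sum(conf$fp), sum(conf$fn))
}

oracle_macro <- function(conf) {
  vals <- sapply(seq_len(nrow(conf)),
                 function(j) oracle_prf(conf$tp[j], conf$fp[j], conf$fn[j]))
  rowMeans(vals)
}

oracle_subset <- function(tm, pm) {
  hits <- 0
  for (i in seq_len(nrow(tm))) {
    if (all(tm[i, ] == pm[i, ])) hits <- hits + 1
  }
  hits / nrow(tm)
}

oracle_diversity <- function(m) {
  length(unique(apply(m, 1, paste, collapse = ",")))
}

oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

random_count_matrix <- function(n_exams, codes, max_count = 3) {
  m <- matrix(sample(0:max_count, n_exams * length(codes), replace = TRUE,
                     prob = c(0.55, 0.25, 0.12, 0.08)[1:(max_count + 1)]),
              nrow = n_exams, dimnames = list(sprintf("x%02d", seq_len(n_exams)),
                                              codes))
  storage.mode(m) <- "integer"
  m
}
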