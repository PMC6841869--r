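# Constructed learning scenarios for the multi-output classifiers.

# Main label A is predictable from a single feature (three interval classes
# along x1); auxiliary label B = indicator(A >= 1). For a minimal monotone
# learner, the multi-class boundary of A is representable but the two-sided
# region of B is not, so B is learnable through A (chain) but not directly
# from the features (binary relevance): the constructed dependency-advantage
# scenario.
make_dependency_scenario <- function(n) {
  x <- runif(n, -2, 2)
  a <- ifelse(abs(x) < 1, 0L, ifelse(x > 1, 1L, 2L))
  b <- as.integer(a >= 1)
  features <- tibble::tibble(exam_id = sprintf("S%05d", seq_len(n)),
                             x1 = x, x2 = rnorm(n), x3 = rnorm(n))
  y <- matrix(c(a, b), ncol = 2,
              dimnames = list(features$exam_id, c("A", "B")))
  list(features = features, y = y)
}

dep_spec <- function() base_spec("mlp", size = 1, maxit = 300, decay = 1e-4)

# Two labels driven by disjoint feature blocks; each is independently
# learnable, so binary relevance should get both right.
make_disjoint_scenario <- function(n) {
  x1 <- runif(n, -1, 1)
  x2 <- runif(n, -1, 1)
  a <- as.integer(x1 > 0)
  b <- as.integer(x2 > 0.3) + as.integer(x2 > 0.6)
  features <- tibble::tibble(exam_id = sprintf("S%05d", seq_len(n)),
                             x1 = x1, x2 = x2)
  y <- matrix(c(a, b), ncol = 2,
              dimnames = list(features$exam_id, c("A", "B")))
  list(features = features, y = y)
}
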