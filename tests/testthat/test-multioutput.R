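test_that("binary relevance learns separable labels and degenerate labels exactly", {
  set.seed(21)
  sc <- make_disjoint_scenario(200)
  # add a label that is constantly zero in training
  y <- cbind(sc$y, C = 0L)
  fit <- fit_binary_relevance(sc$features, matrix_to_labelsets(y),
                              spec = base_spec("random_forest", ntree = 100),
                              codes = c("A", "B", "C"))
  pred <- predict(fit, sc$features)
  expect_equal(pred[, "A"], y[, "A"])      # separable -> exact on training
  expect_equal(unname(pred[, "C"]), rep(0L, 200))

  held <- make_disjoint_scenario(300)
  pred_h <- predict(fit, held$features)
  expect_gte(mean(pred_h[, "A"] == held$y[, "A"]), 0.95)
  expect_gte(mean(pred_h[, "B"] == held$y[, "B"]), 0.95)
})

test_that("empty training sets and malformed label orders are errors", {
  sc <- make_disjoint_scenario(10)
  expect_error(fit_binary_relevance(sc$features[0, ],
                                    matrix_to_labelsets(sc$y)),
               "empty")
  expect_error(fit_chain(sc$features, matrix_to_labelsets(sc$y),
                         label_order = c("A", "A"), codes = c("A", "B")),
               "permutation")
  expect_error(fit_chain(sc$features, matrix_to_labelsets(sc$y),
                         label_order = c("A", "Z"), codes = c("A", "B")),
               "permutation")
})

test_that("a chain of length one equals binary relevance", {
  set.seed(22)
  sc <- make_disjoint_scenario(150)
  y1 <- sc$y[, "A", drop = FALSE]
  set.seed(1)
  br <- fit_binary_relevance(sc$features, matrix_to_labelsets(y1),
                             spec = base_spec("random_forest", ntree = 50),
                             codes = "A")
  set.seed(1)
  ch <- fit_chain(sc$features, matrix_to_labelsets(y1),
                  spec = base_spec("random_forest", ntree = 50), codes = "A")
  expect_equal(predict(ch, sc$features), predict(br, sc$features))
})

test_that("chains exploit the label dependency that binary relevance misses", {
  set.seed(23)
  tr <- make_dependency_scenario(500)
  te <- make_dependency_scenario(500)
  chain <- fit_chain(tr$features, matrix_to_labelsets(tr$y),
                     label_order = c("A", "B"), spec = dep_spec(),
                     codes = c("A", "B"))
  acc_chain_b <- mean(predict(chain, te$features)[, "B"] == te$y[, "B"])
  br <- fit_binary_relevance(tr$features, matrix_to_labelsets(tr$y),
                             spec = dep_spec(), codes = c("A", "B"))
  acc_br_b <- mean(predict(br, te$features)[, "B"] == te$y[, "B"])
  expect_gte(acc_chain_b, 0.95)
  expect_lt(acc_br_b, acc_chain_b)
})

test_that("ensemble voting is unanimous-consistent and ties break to the smaller count", {
  expect_equal(mricoder:::majority_vote(c(1L, 1L, 2L)), 1L)
  expect_equal(mricoder:::majority_vote(c(2L, 2L, 2L)), 2L)
  expect_equal(mricoder:::majority_vote(c(1L, 2L)), 1L)          # tie
  expect_equal(mricoder:::majority_vote(c(3L, 0L, 3L, 0L)), 0L)  # tie
  expect_equal(mricoder:::majority_vote(c(2L)), 2L)

  # on separable data every chain agrees, so the ensemble equals any chain
  set.seed(24)
  sc <- make_disjoint_scenario(200)
  ecc <- fit_ecc(sc$features, matrix_to_labelsets(sc$y),
                 spec = base_spec("random_forest", ntree = 50),
                 n_chains = 3, codes = c("A", "B"), seed = 7)
  pred <- predict(ecc, sc$features)
  expect_equal(pred[, "A"], sc$y[, "A"])
  one_chain <- predict(ecc$chains[[1]], sc$features)
  expect_equal(pred, one_chain)
})

test_that("ensemble fits are reproducible for a fixed seed", {
  set.seed(25)
  sc <- make_disjoint_scenario(150)
  e1 <- fit_ecc(sc$features, matrix_to_labelsets(sc$y),
                spec = base_spec("mlp", size = 2, maxit = 100),
                n_chains = 4, codes = c("A", "B"), seed = 99)
  e2 <- fit_ecc(sc$features, matrix_to_labelsets(sc$y),
                spec = base_spec("mlp", size = 2, maxit = 100),
                n_chains = 4, codes = c("A", "B"), seed = 99)
  expect_equal(predict(e1, sc$features), predict(e2, sc$features))
  expect_equal(lapply(e1$chains, `[[`, "label_order"),
               lapply(e2$chains, `[[`, "label_order"))
})

test_that("prediction rejects feature sets that do not match training", {
  sc <- make_disjoint_scenario(50)
  fit <- fit_binary_relevance(sc$features, matrix_to_labelsets(sc$y),
                              spec = base_spec("random_forest", ntree = 20))
  bad <- sc$features
  names(bad)[2] <- "x_renamed"
  expect_error(predict(fit, bad), "feature columns")
})

test_that("all three base-classifier families train and predict in range", {
  set.seed(26)
  sc <- make_disjoint_scenario(150)
  for (fam in list(base_spec("mlp", size = 2, maxit = 80),
                   base_spec("svm_rbf"),
                   base_spec("random_forest", ntree = 30))) {
    fit <- fit_binary_relevance(sc$features, matrix_to_labelsets(sc$y),
                                spec = fam, codes = c("A", "B"))
    pred <- predict(fit, sc$features)
    expect_true(all(pred[, "A"] %in% 0:1))
    expect_true(all(pred[, "B"] %in% 0:2))
    expect_gte(mean(pred[, "A"] == sc$y[, "A"]), 0.9)
  }
})

test_that("grid tuning picks the dominant spec and is seed-deterministic", {
  set.seed(27)
  sc <- make_disjoint_scenario(150)
  ls <- matrix_to_labelsets(sc$y)
  one <- tune_base_spec(sc$features, ls,
                        grid = list(base_spec("random_forest", ntree = 30)),
                        folds = 5, seed = 3)
  expect_equal(one$best_index, 1)

  grid <- list(base_spec("mlp", size = 1, maxit = 1),  # deliberately crippled
               base_spec("random_forest", ntree = 60))
  tuned <- tune_base_spec(sc$features, ls, grid = grid, folds = 5, seed = 3)
  expect_equal(tuned$best_index, 2)
  again <- tune_base_spec(sc$features, ls, grid = grid, folds = 5, seed = 3)
  expect_equal(tuned$cv, again$cv)

  expect_error(tune_base_spec(sc$features[1:3, ], ls, grid = grid, folds = 5),
               "fewer")
})

test_that("model objects expose tidy and glance views", {
  set.seed(28)
  sc <- make_disjoint_scenario(80)
  ecc <- fit_ecc(sc$features, matrix_to_labelsets(sc$y),
                 spec = base_spec("random_forest", ntree = 10),
                 n_chains = 3, codes = c("A", "B"), seed = 1)
  td <- tidy(ecc)
  expect_equal(nrow(td), 6)  # 3 chains x 2 labels
  expect_setequal(unique(td$code_id), c("A", "B"))
  g <- glance(ecc)
  expect_equal(g$n_chains, 3)
  expect_equal(g$n_codes, 2)
})
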