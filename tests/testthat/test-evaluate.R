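test_that("label cardinality, density and diversity match hand computations", {
  ls <- dplyr::bind_rows(
    tibble::tibble(exam_id = "e1", code_id = c("A", "B"), count = c(2L, 1L)),
    tibble::tibble(exam_id = "e2", code_id = "A", count = 1L))
  expect_equal(label_cardinality(ls), 2)
  expect_equal(label_density(ls, n_codes = 22), 2 / 22)
  expect_equal(label_diversity(ls), 2L)

  # empty labelsets contribute to the denominator and one distinct set
  expect_equal(label_cardinality(ls, n_exams = 4), 1)
  expect_equal(label_diversity(ls, n_exams = 4), 3L)
  empty <- ls[0, ]
  expect_equal(label_cardinality(empty, n_exams = 5), 0)

  m <- matrix(0L, 3, 2, dimnames = list(paste0("e", 1:3), c("A", "B")))
  expect_equal(label_cardinality(m), 0)
  expect_equal(label_diversity(m), 1L)
})

test_that("count confusion uses the unit-expansion convention", {
  t1 <- tibble::tibble(exam_id = "e1", code_id = "A", count = 2L)
  p1 <- tibble::tibble(exam_id = "e1", code_id = "A", count = 1L)
  conf <- count_confusion(t1, p1)
  expect_equal(conf$tp, 1)
  expect_equal(conf$fn, 1)
  expect_equal(conf$fp, 0)

  conf2 <- count_confusion(t1, t1)
  expect_equal(conf2$fp + conf2$fn, 0)

  conf3 <- count_confusion(t1[0, ], p1)
  expect_equal(conf3$fp, 1)
})

test_that("micro equals macro for a single code and both hit 1 on perfect predictions", {
  m <- random_count_matrix(6, "A")
  conf <- count_confusion(m, m)
  expect_equal(micro_metrics(conf), macro_metrics(conf))
  expect_equal(micro_metrics(conf)$f1, 1)

  set.seed(7)
  p <- random_count_matrix(6, "A")
  conf2 <- count_confusion(m, p)
  expect_equal(micro_metrics(conf2), macro_metrics(conf2))
})

test_that("undefined rates are reported as 0 with a warning", {
  t0 <- matrix(0L, 2, 1, dimnames = list(c("a", "b"), "A"))
  expect_warning(mm <- micro_metrics(count_confusion(t0, t0)), "denominator")
  expect_equal(mm$precision, 0)
})

test_that("subset accuracy is the exact-match fraction and 1 iff micro F1 is 1", {
  t4 <- random_count_matrix(4, c("A", "B"))
  p4 <- t4
  p4[1, 1] <- p4[1, 1] + 1L  # one count off on one exam of four
  expect_equal(subset_accuracy(t4, p4), 0.75)
  expect_equal(subset_accuracy(t4, t4), 1)
  conf <- count_confusion(t4, p4)
  expect_lt(micro_metrics(conf)$f1, 1)
})

test_that("all metrics equal brute-force oracles on random small datasets", {
  set.seed(123)
  for (trial in 1:60) {
    n <- sample(2:10, 1)
    q <- sample(1:5, 1)
    codes <- LETTERS[seq_len(q)]
    kmax <- setNames(sample(3:5, q, replace = TRUE), codes)
    defs <- tibble::tibble(code_id = codes, max_count = kmax,
                           imaging_related = TRUE, tariff_points = 1,
                           auxiliary = FALSE)
    tm <- random_count_matrix(n, codes)
    pm <- random_count_matrix(n, codes)
    conf <- count_confusion(tm, pm, defs)
    oc <- oracle_confusion(tm, pm, kmax)
    expect_equal(conf$tp, oc$tp)
    expect_equal(conf$fp, oc$fp)
    expect_equal(conf$fn, oc$fn)
    expect_equal(conf$tn, oc$tn)
    expect_equal(suppressWarnings(unlist(micro_metrics(conf))),
                 oracle_micro(conf), ignore_attr = TRUE)
    expect_equal(unlist(macro_metrics(conf)), oracle_macro(conf),
                 ignore_attr = TRUE)
    expect_equal(subset_accuracy(tm, pm), oracle_subset(tm, pm))
    expect_equal(label_cardinality(tm), mean(rowSums(tm)))
    expect_equal(label_diversity(tm), oracle_diversity(tm))
    # long-form route agrees with the matrix route
    expect_equal(label_cardinality(matrix_to_labelsets(tm), n_exams = n),
                 label_cardinality(tm))
  }
})

test_that("prevalence-F1 correlation is Spearman with average-rank ties", {
  mono <- tibble::tibble(prevalence = 1:10 / 20, f1 = (1:10) / 11)
  expect_equal(prevalence_f1_correlation(mono)$rho, 1)
  rev <- tibble::tibble(prevalence = 1:10 / 20, f1 = (10:1) / 11)
  expect_equal(prevalence_f1_correlation(rev)$rho, -1)

  set.seed(9)
  rand <- tibble::tibble(prevalence = sample(1:5, 10, TRUE) / 10,
                         f1 = sample(1:8, 10, TRUE) / 9)
  expect_equal(prevalence_f1_correlation(rand)$rho,
               oracle_spearman(rand$prevalence, rand$f1))

  # codes at F1 = 1 are excluded before correlating
  with_perfect <- dplyr::bind_rows(rand, tibble::tibble(prevalence = 0.9, f1 = 1))
  expect_equal(prevalence_f1_correlation(with_perfect)$rho,
               prevalence_f1_correlation(rand)$rho)
})

test_that("reimbursement deltas value missed and excess units at tariff points", {
  defs <- tibble::tibble(code_id = c("A", "B"), max_count = c(2L, 1L),
                         imaging_related = TRUE, tariff_points = c(10, 90),
                         auxiliary = FALSE)
  truth <- tibble::tibble(exam_id = c("e1", "e1", "e2"),
                          code_id = c("A", "B", "B"), count = c(1L, 1L, 1L))
  expect_equal(unlist(reimbursement_delta(truth, truth, defs)),
               c(undercoding_loss_frac = 0, overcoding_excess_frac = 0))

  # one missed 10-point unit on a 190-point corpus
  coded <- truth[-1, ]
  d <- reimbursement_delta(truth, coded, defs)
  expect_equal(d$undercoding_loss_frac, 10 / 190)
  expect_equal(d$overcoding_excess_frac, 0)

  # symmetric swap of equal-point codes
  defs2 <- tibble::tibble(code_id = c("A", "B"), max_count = 1L,
                          imaging_related = TRUE, tariff_points = 10,
                          auxiliary = FALSE)
  truth2 <- tibble::tibble(exam_id = "e1", code_id = "A", count = 1L)
  coded2 <- tibble::tibble(exam_id = "e1", code_id = "B", count = 1L)
  d2 <- reimbursement_delta(truth2, coded2, defs2)
  expect_equal(d2$undercoding_loss_frac, d2$overcoding_excess_frac)
})

test_that("paired comparison yields quadrant fractions that partition the exams", {
  t4 <- random_count_matrix(4, c("A", "B"))
  expect_equal(unlist(paired_comparison(t4, t4, t4)),
               c(both_correct = 1, auto_only = 0, manual_only = 0, neither = 0))

  # disjoint correctness on 4 exams (2 vs 2)
  pa <- t4; pm <- t4
  pa[1:2, 1] <- pa[1:2, 1] + 1L
  pm[3:4, 1] <- pm[3:4, 1] + 1L
  expect_equal(unlist(paired_comparison(t4, pa, pm)),
               c(both_correct = 0, auto_only = 0.5, manual_only = 0.5,
                 neither = 0))

  set.seed(11)
  q <- paired_comparison(random_count_matrix(8, "A"),
                         random_count_matrix(8, "A"),
                         random_count_matrix(8, "A"))
  expect_equal(sum(unlist(q)), 1)
})

test_that("the bundled report exposes tidy and glance views", {
  set.seed(5)
  tm <- random_count_matrix(10, c("A", "B", "C"))
  pm <- tm; pm[1, ] <- pm[1, ] + 1L
  rep <- evaluate_predictions(tm, pm)
  expect_s3_class(rep, "mri_eval_report")
  expect_equal(nrow(tidy(rep)), 3)
  g <- glance(rep)
  expect_true(all(c("micro_f1", "subset_accuracy", "diversity_pred") %in% names(g)))
  expect_true(all(g$micro_f1 >= 0 & g$micro_f1 <= 1))
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
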