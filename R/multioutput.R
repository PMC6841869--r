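#' Base-classifier specification
#'
#' A pluggable description of the per-label multi-class learner used inside
#' binary relevance and classifier chains. Supported families: a single
#' hidden-layer feed-forward neural network (`mlp`, via \pkg{nnet}), an RBF
#' support vector machine (`svm_rbf`, via \pkg{e1071}), and a random forest
#' (`random_forest`, via \pkg{randomForest}). Feature standardization
#' (z-score, fitted on the training rows only) is applied inside the model
#' for `mlp` and `svm_rbf`; trees are left unscaled.
#'
#' @param family One of `"mlp"`, `"svm_rbf"`, `"random_forest"`.
#' @param ... Hyperparameters overriding the family defaults
#'   (mlp: `size = 16`, `decay = 1e-3`, `maxit = 200`;
#'   svm_rbf: `cost = 1`, `gamma = NULL` for 1/n-features;
#'   random_forest: `ntree = 200`).
#' @return An object of class `mri_base_spec`.
#' @export
base_spec <- function(family = c("mlp", "svm_rbf", "random_forest"), ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    mlp = list(size = 16, decay = 1e-3, maxit = 200),
    svm_rbf = list(cost = 1, gamma = NULL),
    random_forest = list(ntree = 200)
  )
  hp <- utils::modifyList(defaults, list(...))
  structure(list(family = family, hyperparameters = hp),
            class = "mri_base_spec")
}

#' @export
print.mri_base_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, function(v)
                if (is.null(v)) "auto" else format(v), character(1)),
              sep = "=", collapse = ", ")
  cat("<mri_base_spec> ", x$family, " (", hp, ")\n", sep = "")
  invisible(x)
}

# ---- single per-label learner ------------------------------------------

fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(x, scaler) {
  scale(x, center = scaler$center, scale = scaler$scale)
}

fit_base <- function(x, y, spec) {
  classes <- sort(unique(as.integer(y)))
  if (length(classes) == 1L) {
    return(structure(list(kind = "constant", value = classes),
                     class = "mri_base_fit"))
  }
  yf <- factor(as.integer(y), levels = classes)
  hp <- spec$hyperparameters
  fit <- switch(spec$family,
    mlp = {
      scaler <- fit_scaler(x)
      xs <- apply_scaler(x, scaler)
      df <- data.frame(.y = yf, xs, check.names = FALSE)
      m <- nnet::nnet(.y ~ ., data = df, size = hp$size, decay = hp$decay,
                      maxit = hp$maxit, trace = FALSE, MaxNWts = 1e5)
      list(kind = "mlp", model = m, scaler = scaler)
    },
    svm_rbf = {
      scaler <- fit_scaler(x)
      xs <- apply_scaler(x, scaler)
      gamma <- hp$gamma %||% (1 / ncol(x))
      m <- e1071::svm(xs, yf, kernel = "radial", cost = hp$cost,
                      gamma = gamma, scale = FALSE)
      list(kind = "svm_rbf", model = m, scaler = scaler)
    },
    random_forest = {
      m <- randomForest::randomForest(x, yf, ntree = hp$ntree)
      list(kind = "random_forest", model = m)
    }
  )
  fit$classes <- classes
  structure(fit, class = "mri_base_fit")
}

predict_base <- function(fit, x) {
  if (fit$kind == "constant") return(rep(fit$value, nrow(x)))
  if (fit$kind == "mlp") {
    xs <- apply_scaler(x, fit$scaler)
    df <- data.frame(xs, check.names = FALSE)
    cls <- predict(fit$model, newdata = df, type = "class")
  } else if (fit$kind == "svm_rbf") {
    xs <- apply_scaler(x, fit$scaler)
    cls <- as.character(predict(fit$model, xs))
  } else {
    cls <- as.character(predict(fit$model, x))
  }
  as.integer(cls)
}

# ---- data preparation ---------------------------------------------------

as_feature_matrix <- function(features) {
  features <- as_tibble(features)
  if (!"exam_id" %in% names(features)) {
    abort("features must contain an `exam_id` column (see featurize())")
  }
  ids <- features$exam_id
  x <- as.matrix(features[setdiff(names(features), "exam_id")])
  storage.mode(x) <- "double"
  rownames(x) <- ids
  x
}

prepare_xy <- function(features, labelsets, codes = NULL) {
  x <- as_feature_matrix(features)
  codes <- codes %||% sort(unique(
    if (is.matrix(labelsets)) colnames(labelsets) else labelsets$code_id))
  if (length(codes) == 0) abort("no codes to learn: empty label space")
  y <- as_count_matrix(labelsets, exam_ids = rownames(x), code_ids = codes)
  if (nrow(x) == 0) abort("empty training set")
  list(x = x, y = y)
}

check_features <- function(x, feature_names) {
  if (!identical(colnames(x), feature_names)) {
    abort(paste0("feature columns do not match the model's training features; ",
                 "featurize with the same fitted vocabulary"))
  }
}

# ---- binary relevance ---------------------------------------------------

#' Fit a binary-relevance multi-output model
#'
#' One independent multi-class classifier per billing code, predicting the
#' charge count in its observed range; labels with a single observed value
#' in training become constant predictors. Label dependencies are ignored
#' by construction.
#'
#' @param features Feature tibble from [featurize()] (`exam_id` + numeric
#'   columns).
#' @param labelsets Training labelsets (long tibble or count matrix);
#'   exams absent from it count as all-zero.
#' @param spec Base-classifier [base_spec()].
#' @param codes Optional character vector fixing the label space; defaults
#'   to the codes present in `labelsets`.
#' @return An object of class `mri_br`.
#' @seealso [fit_chain()], [fit_ecc()]
#' @export
fit_binary_relevance <- function(features, labelsets, spec = base_spec("mlp"),
                                 codes = NULL) {
  d <- prepare_xy(features, labelsets, codes)
  models <- lapply(colnames(d$y), function(code) fit_base(d$x, d$y[, code], spec))
  names(models) <- colnames(d$y)
  structure(list(models = models, codes = colnames(d$y),
                 feature_names = colnames(d$x), spec = spec),
            class = "mri_br")
}

#' @export
predict.mri_br <- function(object, features, ...) {
  x <- as_feature_matrix(features)
  check_features(x, object$feature_names)
  out <- vapply(object$codes,
                function(code) predict_base(object$models[[code]], x),
                integer(nrow(x)))
  out <- matrix(as.integer(out), nrow = nrow(x),
                dimnames = list(rownames(x), object$codes))
  out
}

# ---- classifier chain ---------------------------------------------------

#' Fit a single classifier chain
#'
#' Classifiers are arranged along `label_order`; the classifier at position
#' p consumes the base features plus the label values at earlier positions
#' -- the true values during training (hard labels), the chain's own
#' sequential predictions at inference. This lets a downstream label
#' exploit its dependency on upstream labels.
#'
#' @inheritParams fit_binary_relevance
#' @param label_order Permutation of the code list; default = codes in
#'   column order.
#' @return An object of class `mri_chain`.
#' @export
fit_chain <- function(features, labelsets, label_order = NULL,
                      spec = base_spec("mlp"), codes = NULL) {
  d <- prepare_xy(features, labelsets, codes)
  codes <- colnames(d$y)
  label_order <- label_order %||% codes
  if (!setequal(label_order, codes) || length(label_order) != length(codes)) {
    abort("`label_order` must be a permutation of the code list")
  }
  x_aug <- d$x
  models <- vector("list", length(label_order))
  names(models) <- label_order
  for (p in seq_along(label_order)) {
    code <- label_order[p]
    models[[code]] <- fit_base(x_aug, d$y[, code], spec)
    aug <- matrix(as.numeric(d$y[, code]), ncol = 1,
                  dimnames = list(NULL, paste0("chain_", code)))
    x_aug <- cbind(x_aug, aug)
  }
  structure(list(models = models, label_order = label_order, codes = codes,
                 feature_names = colnames(d$x), spec = spec),
            class = "mri_chain")
}

#' @export
predict.mri_chain <- function(object, features, ...) {
  x <- as_feature_matrix(features)
  check_features(x, object$feature_names)
  preds <- matrix(0L, nrow = nrow(x), ncol = length(object$codes),
                  dimnames = list(rownames(x), object$codes))
  x_aug <- x
  for (code in object$label_order) {
    yhat <- predict_base(object$models[[code]], x_aug)
    preds[, code] <- yhat
    aug <- matrix(as.numeric(yhat), ncol = 1,
                  dimnames = list(NULL, paste0("chain_", code)))
    x_aug <- cbind(x_aug, aug)
  }
  preds
}

# ---- ensemble of classifier chains --------------------------------------

#' Fit an ensemble of classifier chains
#'
#' `n_chains` chains with independently drawn random label orders
#' (duplicate orders are allowed); the ensemble prediction for each label
#' is the per-label majority vote over the chain outputs. Vote ties are
#' broken toward the smallest count -- deliberately conservative coding:
#' when the ensemble is undecided, prefer undercharging to overcharging.
#'
#' @inheritParams fit_binary_relevance
#' @param n_chains Number of chains (default 10).
#' @param seed Optional integer seeding the label-order draws and base
#'   learners for reproducibility.
#' @return An object of class `mri_ecc`.
#' @export
fit_ecc <- function(features, labelsets, spec = base_spec("mlp"),
                    n_chains = 10, codes = NULL, seed = NULL) {
  if (n_chains < 1) abort("n_chains must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  d <- prepare_xy(features, labelsets, codes)
  codes <- colnames(d$y)
  chains <- lapply(seq_len(n_chains), function(i) {
    fit_chain(features, labelsets, label_order = sample(codes),
              spec = spec, codes = codes)
  })
  structure(list(chains = chains, codes = codes, n_chains = n_chains,
                 feature_names = chains[[1]]$feature_names, spec = spec,
                 seed = seed),
            class = "mri_ecc")
}

majority_vote <- function(values) {
  # values: integer vector of one label's predictions across chains;
  # ties break toward the smallest count (conservative coding)
  tab <- table(values)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)
}

#' @export
predict.mri_ecc <- function(object, features, ...) {
  per_chain <- lapply(object$chains, predict, features = features)
  out <- per_chain[[1]]
  for (j in seq_along(object$codes)) {
    votes <- vapply(per_chain, function(p) p[, j], integer(nrow(out)))
    votes <- matrix(votes, nrow = nrow(out))
    out[, j] <- apply(votes, 1, majority_vote)
  }
  out
}

#' @export
print.mri_br <- function(x, ...) {
  cat("<mri_br> binary relevance, ", length(x$codes), " codes, base ",
      x$spec$family, "\n", sep = ""); invisible(x)
}

#' @export
print.mri_chain <- function(x, ...) {
  cat("<mri_chain> classifier chain over ", length(x$codes),
      " codes, base ", x$spec$family, "\n", sep = ""); invisible(x)
}

#' @export
print.mri_ecc <- function(x, ...) {
  cat("<mri_ecc> ensemble of ", x$n_chains, " classifier chains, ",
      length(x$codes), " codes, base ", x$spec$family, "\n", sep = "")
  invisible(x)
}

# ---- hyperparameter tuning ----------------------------------------------

#' Tune the base classifier by cross-validated micro F1
#'
#' Exhaustive evaluation of a spec grid with k-fold cross-validation on
#' the training data; the winner is the spec with the highest mean
#' micro-averaged F1 across folds. Fold assignment and model fits are
#' seeded, so repeated calls with the same seed return an identical CV
#' table.
#'
#' @inheritParams fit_binary_relevance
#' @param grid A list of [base_spec()] objects.
#' @param method `"br"` (fast, default for tuning) or `"ecc"`.
#' @param folds Number of CV folds (default 10).
#' @param n_chains Chains per ensemble when `method = "ecc"`.
#' @param seed Integer seed.
#' @return A list with `best_spec`, `best_index` and the full `cv` tibble
#'   (`spec_index`, `family`, `fold`, `micro_f1`).
#' @export
tune_base_spec <- function(features, labelsets, grid,
                           method = c("br", "ecc"), folds = 10,
                           n_chains = 10, codes = NULL, seed = 1) {
  method <- match.arg(method)
  d <- prepare_xy(features, labelsets, codes)
  n <- nrow(d$x)
  if (n < folds) abort("fewer training rows than folds")
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  feats <- as_tibble(features)
  rows <- list()
  for (g in seq_along(grid)) {
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      set.seed(seed + 1000L * g + f)
      fit <- if (method == "br") {
        fit_binary_relevance(feats[tr, ],
                             matrix_to_labelsets(d$y[tr, , drop = FALSE]),
                             spec = grid[[g]], codes = colnames(d$y))
      } else {
        fit_ecc(feats[tr, ], matrix_to_labelsets(d$y[tr, , drop = FALSE]),
                spec = grid[[g]], n_chains = n_chains,
                codes = colnames(d$y))
      }
      pred <- predict(fit, feats[!tr, ])
      conf <- count_confusion(d$y[!tr, , drop = FALSE], pred)
      rows[[length(rows) + 1L]] <- tibble(
        spec_index = g, family = grid[[g]]$family, fold = f,
        # a candidate predicting nothing on a fold scores 0, silently
        micro_f1 = suppressWarnings(micro_metrics(conf)$f1))
    }
  }
  cv <- dplyr::bind_rows(rows)
  means <- cv |>
    dplyr::group_by(.data$spec_index) |>
    dplyr::summarise(mean_micro_f1 = mean(.data$micro_f1), .groups = "drop")
  best <- means$spec_index[which.max(means$mean_micro_f1)]
  list(best_spec = grid[[best]], best_index = best, cv = cv,
       summary = means)
}
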