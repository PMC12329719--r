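ARE_FAMILIES <- c("xgboost", "rf", "knn", "svr", "knnboost")
ARE_SEARCHES <- c("grid", "random", "bayes")

#' Fit one removal-efficiency learner
#'
#' Low-level fit of a single model family on a transformed feature matrix.
#' Families: `xgboost` (gradient-boosted trees), `rf` (random forest),
#' `knn` (k-nearest-neighbour regression), `svr` (eps-regression SVM with
#' RBF kernel), and `knnboost` (stage-1 KNN, stage-2 boosted trees fitted to
#' the KNN residuals). All fits are single-threaded and deterministic given
#' `seed`.
#'
#' @param x Numeric feature matrix (from [apply_transform()]).
#' @param y Numeric target (ARE, percent).
#' @param family One of `"xgboost"`, `"rf"`, `"knn"`, `"svr"`, `"knnboost"`.
#' @param params Named list of hyperparameters (see [search_space()]).
#' @param seed Integer seed.
#' @return Object of class `are_fit`.
#' @export
are_fit <- function(x, y, family, params = list(), seed = 1) {
  family <- match_family(family)
  p <- utils::modifyList(default_params(family), params)
  model <- switch(family,
    xgboost = fit_xgb(x, y, p, seed),
    rf = ranger::ranger(x = x, y = y, num.trees = p$num_trees, mtry = min(p$mtry, ncol(x)),
                        min.node.size = p$min_node_size, num.threads = 1,
                        seed = derive_seed(seed, 3)),
    knn = caret::knnreg(as.data.frame(x), y, k = p$k),
    svr = e1071::svm(x = x, y = y, type = "eps-regression", kernel = "radial",
                     cost = p$cost, gamma = p$gamma, epsilon = p$epsilon),
    knnboost = {
      knn <- caret::knnreg(as.data.frame(x), y, k = p$k)
      res <- y - stats::predict(knn, as.data.frame(x))
      list(knn = knn, boost = fit_xgb(x, res, p, seed))
    }
  )
  structure(list(family = family, params = p, model = model,
                 feature_names = colnames(x)),
            class = "are_fit")
}

fit_xgb <- function(x, y, p, seed) {
  set.seed(derive_seed(seed, 5))
  d <- xgboost::xgb.DMatrix(x, label = y)
  booster <- p[setdiff(names(p), c("nrounds", "k"))]
  xgboost::xgb.train(
    params = c(booster, list(objective = "reg:squarederror", nthread = 1,
                             seed = derive_seed(seed, 5))),
    data = d, nrounds = p$nrounds, verbose = 0
  )
}

match_family <- function(family) {
  if (length(family) != 1 || !family %in% ARE_FAMILIES)
    stopf("unknown model family '%s' (use one of: %s)",
          paste(family, collapse = ","), paste(ARE_FAMILIES, collapse = ", "))
  family
}

default_params <- function(family) {
  switch(family,
    xgboost = list(nrounds = 400, max_depth = 2, eta = 0.05, subsample = 0.8,
                   colsample_bytree = 0.8, min_child_weight = 20, lambda = 120),
    rf = list(num_trees = 300, mtry = 8, min_node_size = 5),
    knn = list(k = 7),
    svr = list(cost = 3, gamma = 0.02, epsilon = 0.1),
    knnboost = list(k = 10, nrounds = 200, max_depth = 2, eta = 0.05,
                    subsample = 0.8, colsample_bytree = 0.8,
                    min_child_weight = 20, lambda = 120)
  )
}

#' @export
predict.are_fit <- function(object, x, ...) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x) || ncol(x) != length(object$feature_names))
    stopf("feature matrix must be numeric with %d columns",
          length(object$feature_names))
  switch(object$family,
    xgboost = stats::predict(object$model, xgboost::xgb.DMatrix(x)),
    rf = stats::predict(object$model, data = x, num.threads = 1)$predictions,
    knn = stats::predict(object$model, as.data.frame(x)),
    svr = as.numeric(stats::predict(object$model, x)),
    knnboost = stats::predict(object$model$knn, as.data.frame(x)) +
      stats::predict(object$model$boost, xgboost::xgb.DMatrix(x))
  )
}

#' Hyperparameter search space of a model family
#'
#' Each entry gives the bounds used by random and Bayesian search (`lower`,
#' `upper`, optional log scaling and integer rounding); `grid()` on the
#' returned object is the small default grid. Spaces are deliberately compact
#' so a full five-family comparison stays desk-scale.
#'
#' @param family Model family name.
#' @return list with elements `grid` (data.frame) and `bounds` (named list).
#' @export
search_space <- function(family) {
  family <- match_family(family)
  switch(family,
    xgboost = list(
      grid = expand.grid(nrounds = c(250, 400),
                         min_child_weight = c(10, 20, 30),
                         lambda = c(120, 180)),
      bounds = list(nrounds = list(lower = 150, upper = 500, integer = TRUE),
                    min_child_weight = list(lower = 5, upper = 40, integer = TRUE),
                    lambda = list(lower = 60, upper = 400, log = TRUE))),
    rf = list(
      grid = expand.grid(mtry = c(4, 8, 14), min_node_size = c(3, 10, 25)),
      bounds = list(mtry = list(lower = 2, upper = 16, integer = TRUE),
                    min_node_size = list(lower = 2, upper = 30, integer = TRUE))),
    knn = list(
      grid = data.frame(k = c(3, 5, 7, 10, 15)),
      bounds = list(k = list(lower = 2, upper = 25, integer = TRUE))),
    svr = list(
      grid = expand.grid(cost = c(1, 3, 10, 30), gamma = c(0.01, 0.02, 0.05)),
      bounds = list(cost = list(lower = 0.5, upper = 100, log = TRUE),
                    gamma = list(lower = 0.005, upper = 0.1, log = TRUE))),
    knnboost = list(
      grid = expand.grid(k = c(5, 10), nrounds = c(150, 300),
                         lambda = c(120, 180)),
      bounds = list(k = list(lower = 2, upper = 20, integer = TRUE),
                    nrounds = list(lower = 50, upper = 400, integer = TRUE),
                    lambda = list(lower = 60, upper = 400, log = TRUE)))
  )
}

# 5-fold assignment with fold sizes differing by at most 1.
cv_folds <- function(n, nfolds, seed) {
  set.seed(derive_seed(seed, 59))
  sample(rep(seq_len(nfolds), length.out = n))
}

# Mean per-fold R2 and RMSE of one hyperparameter configuration.
cv_score <- function(x, y, family, params, folds, seed) {
  r2 <- rm <- numeric(max(folds))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    fit <- are_fit(x[tr, , drop = FALSE], y[tr], family, params,
                   seed = derive_seed(seed, f))
    p <- predict(fit, x[!tr, , drop = FALSE])
    r2[f] <- r_squared(y[!tr], p)
    rm[f] <- rmse(y[!tr], p)
  }
  list(cv_r2 = mean(r2), cv_rmse = mean(rm), fold_r2 = r2, fold_rmse = rm)
}

draw_params <- function(bounds, n, seed) {
  set.seed(derive_seed(seed, 61))
  out <- lapply(bounds, function(b) {
    u <- stats::runif(n)
    v <- if (isTRUE(b$log)) exp(log(b$lower) + u * (log(b$upper) - log(b$lower)))
         else b$lower + u * (b$upper - b$lower)
    if (isTRUE(b$integer)) round(v) else v
  })
  as.data.frame(out)
}

# Bayesian optimisation with a Gaussian-process surrogate (expected
# improvement over a random candidate pool).
bayes_propose <- function(evaluated, scores, bounds, seed, pool = 200) {
  enc <- function(df) {
    m <- as.matrix(df)
    for (j in seq_along(bounds)) if (isTRUE(bounds[[j]]$log)) m[, j] <- log(m[, j])
    scale(m, center = TRUE, scale = apply(m, 2, function(v) max(stats::sd(v), 1e-9)))
  }
  cand <- draw_params(bounds, pool, seed)
  all <- rbind(evaluated, cand)
  z <- enc(all)
  ztr <- z[seq_len(nrow(evaluated)), , drop = FALSE]
  zc <- z[-seq_len(nrow(evaluated)), , drop = FALSE]
  gp <- tryCatch(
    kernlab::gausspr(x = ztr, y = scores, variance.model = TRUE,
                     kpar = list(sigma = 1), scaled = FALSE),
    error = function(e) NULL)
  if (is.null(gp)) return(cand[sample.int(pool, 1), , drop = FALSE])
  mu <- as.numeric(kernlab::predict(gp, zc))
  sdv <- pmax(as.numeric(kernlab::predict(gp, zc, type = "sdeviation")), 1e-9)
  best <- max(scores)
  d <- (mu - best) / sdv
  ei <- sdv * (d * stats::pnorm(d) + stats::dnorm(d))
  cand[which.max(ei), , drop = FALSE]
}

#' Tune and train one candidate model
#'
#' Chooses hyperparameters by 5-fold cross-validation (training folds split
#' 4:1 into pretraining and validation parts), maximising the mean
#' cross-validated R2, via one of three search methods: exhaustive small
#' grid, random draws from the family bounds, or Bayesian optimisation with
#' a Gaussian-process surrogate. The winning configuration is refit on the
#' full training set.
#'
#' @param x,y Transformed training features and target (>= 25 rows).
#' @param family Model family, see [are_fit()].
#' @param search `"grid"`, `"random"` or `"bayes"`.
#' @param seed Integer seed.
#' @param nfolds Folds, default 5.
#' @param n_random Draws for random search, default 10.
#' @param n_bayes_init,n_bayes_iter Initial draws and surrogate iterations
#'   for Bayesian search.
#' @return Object of class `are_candidate`: the refit model, chosen
#'   hyperparameters, and CV statistics.
#' @export
tune_and_train <- function(x, y, family, search = "grid", seed = 1, nfolds = 5,
                           n_random = 10, n_bayes_init = 5, n_bayes_iter = 6) {
  family <- match_family(family)
  if (length(search) != 1 || !search %in% ARE_SEARCHES)
    stopf("unknown search method '%s' (use one of: %s)",
          paste(search, collapse = ","), paste(ARE_SEARCHES, collapse = ", "))
  if (nrow(x) < 5 * nfolds)
    stopf("need at least %d training rows for %d-fold CV", 5 * nfolds, nfolds)
  space <- search_space(family)
  folds <- cv_folds(nrow(x), nfolds, seed)

  configs <- switch(search,
    grid = space$grid,
    random = draw_params(space$bounds, n_random, seed),
    bayes = draw_params(space$bounds, n_bayes_init, seed))
  scores <- vapply(seq_len(nrow(configs)), function(i)
    cv_score(x, y, family, as.list(configs[i, , drop = FALSE]), folds, seed)$cv_r2,
    numeric(1))
  if (search == "bayes") {
    for (b in seq_len(n_bayes_iter)) {
      prop <- bayes_propose(configs, scores, space$bounds,
                            derive_seed(seed, 900 + b))
      configs <- rbind(configs, prop)
      scores <- c(scores, cv_score(x, y, family, as.list(prop), folds, seed)$cv_r2)
    }
  }
  best_i <- which.max(scores)
  best_params <- lapply(as.list(configs[best_i, , drop = FALSE]), as.numeric)
  cv <- cv_score(x, y, family, best_params, folds, seed)
  fit <- are_fit(x, y, family, best_params, seed = seed)
  structure(list(family = family, search = search, params = fit$params,
                 tuned = best_params, cv_r2 = cv$cv_r2, cv_rmse = cv$cv_rmse,
                 fold_r2 = cv$fold_r2, folds = folds, fit = fit,
                 n_configs = nrow(configs), seed = seed,
                 train_r2 = r_squared(y, predict(fit, x)),
                 train_rmse = rmse(y, predict(fit, x)),
                 test_r2 = NA_real_, test_rmse = NA_real_),
            class = "are_candidate")
}

#' @export
predict.are_candidate <- function(object, x, ...) predict(object$fit, x, ...)

#' @export
print.are_candidate <- function(x, ...) {
  cat(sprintf("ARE candidate: %s (%s search, %d configs)\n",
              x$family, x$search, x$n_configs))
  cat(sprintf("  CV R2 %.3f  CV RMSE %.2f  train R2 %.3f", x$cv_r2, x$cv_rmse,
              x$train_r2))
  if (!is.na(x$test_r2)) cat(sprintf("  test R2 %.3f", x$test_r2))
  cat("\n")
  invisible(x)
}

# Fill held-out metrics for one candidate.
evaluate_candidate <- function(cand, x_test, y_test) {
  p <- predict(cand, x_test)
  cand$test_r2 <- r_squared(y_test, p)
  cand$test_rmse <- rmse(y_test, p)
  cand$overfit_gap <- cand$train_r2 - cand$test_r2
  cand
}

#' Select the best candidate model
#'
#' Winner: highest held-out R2, ties broken by lower held-out RMSE. Any
#' candidate whose train-test R2 gap reaches 0.15 is flagged as an
#' overfitting risk in the attached report.
#'
#' @param candidates List of evaluated [tune_and_train()] candidates.
#' @param gap_threshold Overfit-gap flag threshold, default 0.15.
#' @return The winning candidate, with a `selection_report` data.frame
#'   attribute (one row per candidate).
#' @export
select_best <- function(candidates, gap_threshold = 0.15) {
  if (length(candidates) == 0) stopf("no candidates supplied")
  report <- do.call(rbind, lapply(candidates, function(cn) data.frame(
    family = cn$family, search = cn$search, cv_r2 = cn$cv_r2,
    cv_rmse = cn$cv_rmse, train_r2 = cn$train_r2, test_r2 = cn$test_r2,
    test_rmse = cn$test_rmse,
    overfit_gap = cn$train_r2 - cn$test_r2,
    overfit_flag = (cn$train_r2 - cn$test_r2) >= gap_threshold,
    stringsAsFactors = FALSE)))
  if (anyNA(report$test_r2))
    stopf("all candidates must carry held-out metrics before selection")
  ord <- order(-report$test_r2, report$test_rmse)
  best <- candidates[[ord[1]]]
  attr(best, "selection_report") <- report[ord, ]
  best
}
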