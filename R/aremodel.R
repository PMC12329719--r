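#' Fit the wetland antibiotic-removal efficiency model
#'
#' End-to-end fit on an experiment table: iterative random-forest imputation
#' of missing numeric cells, an 80/20 train/test split, z-score +
#' one-hot transform fitted on the training part, 5-fold cross-validated
#' hyperparameter search over the requested model families and search
#' methods, selection of the best candidate by held-out R2, and a bootstrap
#' ensemble of the winning configuration for prediction intervals.
#'
#' @param formula Model formula; only the left-hand side (the target column)
#'   and, if not `.`, the subset of schema features on the right-hand side
#'   are used. Default `are ~ .`.
#' @param data Experiment table (see [gen_experiments()]).
#' @param schema Feature schema, default [default_schema()].
#' @param families Model families to compare, default all five.
#' @param search Search methods to run per family (`"grid"`, `"random"`,
#'   `"bayes"`); one candidate is tuned per family x method.
#' @param B Bootstrap ensemble size, default 100.
#' @param train_frac Training fraction, default 0.8.
#' @param impute Impute missing cells with [impute_missforest()], default TRUE.
#' @param seed Integer seed controlling the imputation, split, CV folds and
#'   bootstrap streams.
#' @param nfolds CV folds, default 5.
#' @return Object of class `are_model` with components `candidates`, `best`,
#'   `ensemble`, `transform`, `metrics`, `split` and the processed `data`.
#' @seealso [predict.are_model()], [validate_shuffle()],
#'   [validate_external()], [attribute()]
#' @export
#' @examples
#' \donttest{
#' x <- gen_experiments(120, seed = 1, missing_rate = 0)
#' m <- are_model(are ~ ., x, families = "xgboost", B = 10, seed = 1)
#' summary(m)
#' }
are_model <- function(formula = are ~ ., data, schema = default_schema(),
                      families = ARE_FAMILIES, search = "grid", B = 100,
                      train_frac = 0.8, impute = TRUE, seed = 1, nfolds = 5) {
  target <- all.vars(formula[[2]])
  if (length(target) != 1 || !target %in% names(data))
    stopf("formula must name one target column present in the data")
  rhs <- attr(stats::terms(formula, data = data[0, setdiff(names(data), target)]),
              "term.labels")
  if (length(rhs) && !identical(rhs, ".")) {
    keep <- intersect(schema$name, rhs)
    if (length(keep) == 0) stopf("no schema features on the formula RHS")
    schema <- schema[schema$name %in% keep, , drop = FALSE]
  }
  if (anyNA(data[[target]])) stopf("missing values in the target are not allowed")

  if (impute && anyNA(data[, schema$name])) {
    data[, c(schema$name, target)] <-
      impute_missforest(data[, c(schema$name, target)], seed = seed)
  }
  sp <- split_table(data, seed, train_frac)
  transform <- fit_encode_scale(sp$train, schema)
  x_train <- apply_transform(sp$train, transform)
  x_test <- apply_transform(sp$test, transform)
  y_train <- sp$train[[target]]
  y_test <- sp$test[[target]]

  candidates <- list()
  for (fam in families) for (srch in search) {
    cand <- tune_and_train(x_train, y_train, fam, srch,
                           seed = derive_seed(seed, 97))
    candidates[[paste(fam, srch, sep = ".")]] <-
      evaluate_candidate(cand, x_test, y_test)
  }
  best <- select_best(candidates)
  ensemble <- bootstrap_ensemble(x_train, y_train, best$family, best$tuned,
                                 B = B, seed = derive_seed(seed, 101))
  metrics <- list(
    family = best$family, search = best$search,
    train_r2 = best$train_r2, test_r2 = best$test_r2,
    train_rmse = best$train_rmse, test_rmse = best$test_rmse,
    cv_r2 = best$cv_r2, overfit_gap = best$overfit_gap, B = B
  )
  structure(list(call = match.call(), target = target, schema = schema,
                 transform = transform, split = sp, data = data,
                 candidates = candidates, best = best, ensemble = ensemble,
                 metrics = metrics, seed = seed),
            class = "are_model")
}

#' Predict removal efficiency for new trials
#'
#' @param object A fitted [are_model()].
#' @param newdata data.frame on the raw feature scale.
#' @param interval If `TRUE` (default) return the bootstrap mean, standard
#'   deviation and 95% percentile interval per row; otherwise the mean only.
#' @param level Interval coverage, default 0.95.
#' @param ... Unused.
#' @return data.frame (`mean`, `sd`, `lwr`, `upr`) or numeric vector.
#' @export
predict.are_model <- function(object, newdata, interval = TRUE, level = 0.95, ...) {
  x <- apply_transform(newdata, object$transform)
  out <- predict(object$ensemble, x, level = level)
  if (interval) out else out$mean
}

#' @export
print.are_model <- function(x, ...) {
  m <- x$metrics
  cat("Wetland antibiotic removal efficiency model\n")
  cat(sprintf("  selected: %s (%s search) from %d candidate(s)\n",
              m$family, m$search, length(x$candidates)))
  cat(sprintf("  train R2 %.3f | test R2 %.3f | test RMSE %.2f | gap %.3f\n",
              m$train_r2, m$test_r2, m$test_rmse, m$overfit_gap))
  cat(sprintf("  bootstrap ensemble: B = %d\n", m$B))
  invisible(x)
}

#' @export
summary.are_model <- function(object, ...) {
  structure(list(metrics = object$metrics,
                 report = attr(object$best, "selection_report"),
                 n_train = nrow(object$split$train),
                 n_test = nrow(object$split$test)),
            class = "summary.are_model")
}

#' @export
print.summary.are_model <- function(x, ...) {
  cat(sprintf("Candidates (train n = %d, test n = %d):\n", x$n_train, x$n_test))
  print(x$report, row.names = FALSE, digits = 3)
  cat(sprintf("\nSelected %s: test R2 %.3f, RMSE %.2f, overfit gap %.3f\n",
              x$metrics$family, x$metrics$test_r2, x$metrics$test_rmse,
              x$metrics$overfit_gap))
  invisible(x)
}

#' @export
fitted.are_model <- function(object, ...) {
  predict(object, object$split$train, interval = FALSE)
}

#' @export
residuals.are_model <- function(object, ...) {
  object$split$train[[object$target]] - fitted(object)
}

#' Observed-versus-predicted plot
#'
#' @param x A fitted [are_model()].
#' @param which `"test"` (default) or `"train"` partition.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.are_model <- function(x, which = c("test", "train"), ...) {
  which <- match.arg(which)
  d <- x$split[[which]]
  obs <- d[[x$target]]
  pred <- predict(x, d, interval = FALSE)
  graphics::plot(obs, pred, xlab = "Observed ARE (%)",
                 ylab = "Predicted ARE (%)",
                 main = sprintf("%s partition (R2 = %.2f)", which,
                                r_squared(obs, pred)), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
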