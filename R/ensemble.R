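#' Bootstrap ensemble of removal-efficiency models
#'
#' Fits `B` copies of one model configuration, each on a with-replacement
#' resample of the training rows (Monte Carlo bootstrap), to quantify
#' prediction uncertainty. Member `b` uses the RNG stream `seed + b`, so the
#' ensemble is reproducible and members are exchangeable.
#'
#' @param x,y Transformed training features and target.
#' @param family Model family (see [are_fit()]).
#' @param params Hyperparameters for every member.
#' @param B Number of members, default 100.
#' @param seed Integer seed.
#' @return Object of class `are_ensemble`.
#' @export
bootstrap_ensemble <- function(x, y, family, params = list(), B = 100, seed = 1) {
  if (B < 1) stopf("B must be >= 1")
  family <- match_family(family)
  n <- nrow(x)
  members <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed + b, 71))
    idx <- sample.int(n, n, replace = TRUE)
    members[[b]] <- are_fit(x[idx, , drop = FALSE], y[idx], family, params,
                            seed = derive_seed(seed + b, 73))
  }
  structure(list(members = members, B = B, family = family,
                 params = members[[1]]$params, seed = seed,
                 feature_names = colnames(x)),
            class = "are_ensemble")
}

# B x n matrix of member predictions, clipped to the ARE range [0, 100].
member_predictions <- function(ensemble, x, clip = TRUE) {
  m <- t(vapply(ensemble$members, function(f) predict(f, x), numeric(nrow(x))))
  if (clip) m <- clip_pct(m)
  m
}

#' Predict with a bootstrap ensemble
#'
#' Member predictions are clipped to \[0, 100\] (ARE is a percentage) before
#' aggregation. The reported mean is the arithmetic mean of member
#' predictions; the confidence interval uses the 2.5/97.5 member percentiles
#' (for `level = 0.95`), so the mean always lies inside the interval.
#'
#' @param object An [bootstrap_ensemble()] object.
#' @param x Transformed feature matrix.
#' @param level Interval coverage, default 0.95.
#' @param ... Unused.
#' @return data.frame with columns `mean`, `sd`, `lwr`, `upr` (percent).
#' @export
predict.are_ensemble <- function(object, x, level = 0.95, ...) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x) || ncol(x) != length(object$feature_names))
    stopf("feature matrix must be numeric with %d columns",
          length(object$feature_names))
  m <- member_predictions(object, x)
  a <- (1 - level) / 2
  data.frame(
    mean = colMeans(m),
    sd = if (nrow(m) > 1) apply(m, 2, stats::sd) else rep(0, ncol(m)),
    lwr = apply(m, 2, stats::quantile, probs = a),
    upr = apply(m, 2, stats::quantile, probs = 1 - a)
  )
}

#' @export
print.are_ensemble <- function(x, ...) {
  cat(sprintf("Bootstrap ARE ensemble: %d x %s member(s)\n", x$B, x$family))
  invisible(x)
}

# Permutation-based R2 drop for a raw-table predictor. `predict_fun` maps a
# feature data.frame to point predictions; shuffling happens on the raw
# column so all one-hot indicators of a categorical move together.
shuffle_delta_r2 <- function(predict_fun, data, y, features, repeats, seed) {
  base <- r_squared(y, predict_fun(data))
  out <- matrix(NA_real_, length(features), repeats,
                dimnames = list(features, NULL))
  for (r in seq_len(repeats)) {
    set.seed(derive_seed(seed, 83 + r))
    perm <- sample.int(nrow(data))
    for (j in features) {
      d <- data
      d[[j]] <- d[[j]][perm]
      out[j, r] <- base - r_squared(y, predict_fun(d))
    }
  }
  data.frame(feature = features, delta_r2 = rowMeans(out),
             base_r2 = base, stringsAsFactors = FALSE)
}

#' Feature-shuffling validation
#'
#' For each raw feature, the held-out R2 drop after permuting that column
#' within the test table (all indicator columns of a categorical are
#' permuted together), averaged over `repeats` permutations. Features the
#' model relies on produce large drops; pure-noise features produce drops
#' near zero.
#'
#' @param object A fitted [are_model()].
#' @param data Test table (raw feature scale) including the target column.
#' @param repeats Permutations per feature, default 5.
#' @param seed Integer seed.
#' @return data.frame with `feature`, `delta_r2`, `base_r2`.
#' @export
validate_shuffle <- function(object, data, repeats = 5, seed = 1) {
  stopifnot(inherits(object, "are_model"))
  if (nrow(data) < 10) stopf("need at least 10 rows for shuffle validation")
  y <- data[[object$target]]
  pf <- function(d) predict(object, d, interval = FALSE)
  shuffle_delta_r2(pf, data, y, object$schema$name, repeats, seed)
}

#' External (independent-dataset) validation
#'
#' Absolute prediction errors, in ARE percentage points, of the ensemble mean
#' on a complete independent table.
#'
#' @param object A fitted [are_model()].
#' @param data Complete table with feature columns and the target.
#' @return list with `errors` (per row), `mean_error`, `max_error`.
#' @export
validate_external <- function(object, data) {
  stopifnot(inherits(object, "are_model"))
  if (anyNA(data)) stopf("independent validation table must be complete")
  p <- predict(object, data, interval = FALSE)
  err <- abs(p - data[[object$target]])
  list(errors = err, mean_error = mean(err), max_error = max(err))
}
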