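# --- Exact TreeSHAP for gradient-boosted trees ------------------------------
#
# Path-dependent TreeSHAP computed in double precision over the dumped tree
# structure, so local accuracy (sum of attributions + base = tree-walk
# prediction) holds to machine precision. xgboost's built-in predcontrib is
# float32 and serves as an independent cross-check in the tests.

# Round to float32: xgboost stores split thresholds and compares feature
# values in single precision, so split decisions must be made on the
# float32-rounded values to reproduce its routing exactly.
as_float32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4), "numeric",
          n = length(v), size = 4)
}

# Parse an xgboost booster into per-tree arrays (1-indexed nodes).
parse_xgb_trees <- function(booster, feature_names) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  node_of <- function(id) as.integer(sub(".*-", "", id)) + 1L
  trees <- lapply(split(dt, dt$Tree), function(tr) {
    tr <- tr[order(tr$Node), ]
    leaf <- tr$Feature == "Leaf"
    list(
      feature = ifelse(leaf, NA_integer_, match(tr$Feature, feature_names)),
      split = as_float32(tr$Split),
      yes = ifelse(leaf, NA_integer_, node_of(tr$Yes)),
      no = ifelse(leaf, NA_integer_, node_of(tr$No)),
      value = ifelse(leaf, tr$Gain, NA_real_),
      cover = tr$Cover,
      leaf = leaf
    )
  })
  cfg <- xgboost::xgb.config(booster)
  base <- as.numeric(cfg$learner$learner_model_param$base_score)
  list(trees = trees, base_score = base)
}

# Double-precision evaluation of the dumped trees (float32 split routing).
tree_walk_predict <- function(parsed, x) {
  x <- matrix(as_float32(x), nrow(x), ncol(x), dimnames = dimnames(x))
  out <- rep(parsed$base_score, nrow(x))
  for (tr in parsed$trees) {
    for (r in seq_len(nrow(x))) {
      j <- 1L
      while (!tr$leaf[j]) {
        j <- if (x[r, tr$feature[j]] < tr$split[j]) tr$yes[j] else tr$no[j]
      }
      out[r] <- out[r] + tr$value[j]
    }
  }
  out
}

# Cover-weighted expectation of one tree (the tree's share of the base value).
tree_expectation <- function(tr) {
  sum(tr$value[tr$leaf] * tr$cover[tr$leaf]) / tr$cover[1]
}

shap_extend <- function(m, pz, po, pi) {
  l <- length(m$w)
  m$d <- c(m$d, pi); m$z <- c(m$z, pz); m$o <- c(m$o, po)
  m$w <- c(m$w, if (l == 0) 1 else 0)
  if (l > 0) for (i in l:1) {
    m$w[i + 1] <- m$w[i + 1] + po * m$w[i] * i / (l + 1)
    m$w[i] <- pz * m$w[i] * (l + 1 - i) / (l + 1)
  }
  m
}

shap_unwind <- function(m, i) {
  l <- length(m$w)
  n <- m$w[l]
  if (l > 1) for (j in (l - 1):1) {
    if (m$o[i] != 0) {
      t <- m$w[j]
      m$w[j] <- n * l / (j * m$o[i])
      n <- t - m$w[j] * m$z[i] * (l - j) / l
    } else {
      m$w[j] <- m$w[j] * l / (m$z[i] * (l - j))
    }
  }
  keep <- setdiff(seq_len(l), i)
  list(d = m$d[keep], z = m$z[keep], o = m$o[keep], w = m$w[seq_len(l - 1)])
}

shap_unwound_sum <- function(m, i) {
  l <- length(m$w)
  n <- m$w[l]
  total <- 0
  if (l > 1) for (j in (l - 1):1) {
    if (m$o[i] != 0) {
      t <- n * l / (j * m$o[i])
      total <- total + t
      n <- m$w[j] - t * m$z[i] * (l - j) / l
    } else {
      total <- total + m$w[j] * l / (m$z[i] * (l - j))
    }
  }
  total
}

# SHAP values of one tree for one instance; phi accumulated in env.
tree_shap_recurse <- function(tr, xrow, phi_env, j, m, pz, po, pi) {
  m <- shap_extend(m, pz, po, pi)
  if (tr$leaf[j]) {
    l <- length(m$w)
    if (l >= 2) for (i in 2:l) {
      w <- shap_unwound_sum(m, i)
      f <- m$d[i]
      phi_env$phi[f] <- phi_env$phi[f] + w * (m$o[i] - m$z[i]) * tr$value[j]
    }
    return(invisible())
  }
  hot <- if (xrow[tr$feature[j]] < tr$split[j]) tr$yes[j] else tr$no[j]
  cold <- if (hot == tr$yes[j]) tr$no[j] else tr$yes[j]
  iz <- 1; io <- 1
  k <- match(tr$feature[j], m$d)
  if (!is.na(k)) {
    iz <- m$z[k]; io <- m$o[k]
    m <- shap_unwind(m, k)
  }
  rj <- tr$cover[j]
  tree_shap_recurse(tr, xrow, phi_env, hot, m, iz * tr$cover[hot] / rj, io,
                    tr$feature[j])
  tree_shap_recurse(tr, xrow, phi_env, cold, m, iz * tr$cover[cold] / rj, 0,
                    tr$feature[j])
  invisible()
}

# Exact TreeSHAP attribution matrix (rows x columns) plus base value.
tree_shap <- function(booster, x, feature_names = colnames(x)) {
  parsed <- parse_xgb_trees(booster, feature_names)
  pred <- tree_walk_predict(parsed, x)
  x <- matrix(as_float32(x), nrow(x), ncol(x), dimnames = dimnames(x))
  phi <- matrix(0, nrow(x), length(feature_names),
                dimnames = list(NULL, feature_names))
  for (r in seq_len(nrow(x))) {
    acc <- new.env()
    acc$phi <- numeric(length(feature_names))
    for (tr in parsed$trees) {
      if (all(tr$leaf)) next  # constant tree contributes only to the base
      tree_shap_recurse(tr, x[r, ], acc, 1L,
                        list(d = numeric(), z = numeric(), o = numeric(),
                             w = numeric()),
                        1, 1, 0)
    }
    phi[r, ] <- acc$phi
  }
  base <- parsed$base_score +
    sum(vapply(parsed$trees, tree_expectation, numeric(1)))
  list(phi = phi, base = base, prediction = pred)
}

# --- Sampling Shapley for non-tree models ------------------------------------
#
# Monte Carlo permutation estimator with a shared background sample. The
# telescoping construction makes attributions sum exactly to
# f(x) - mean(f(background)) regardless of the number of permutations.
sampling_shap <- function(pred_fun, x, background, nperm = 8, n_background = 15,
                          seed = 1) {
  M <- ncol(x)
  set.seed(derive_seed(seed, 151))
  bg <- background[sample.int(nrow(background), min(n_background, nrow(background))),
                   , drop = FALSE]
  perms <- lapply(seq_len(nperm), function(i) sample.int(M))
  phi <- matrix(0, nrow(x), M, dimnames = list(NULL, colnames(x)))
  base <- mean(pred_fun(bg))
  for (r in seq_len(nrow(x))) {
    # all intermediate instances for every (permutation, background) pair
    inst <- matrix(0, nperm * nrow(bg) * (M + 1), M)
    row_i <- 0
    for (p in perms) for (b in seq_len(nrow(bg))) {
      z <- bg[b, ]
      inst[row_i + 1, ] <- z
      for (s in seq_len(M)) {
        z[p[s]] <- x[r, p[s]]
        inst[row_i + 1 + s, ] <- z
      }
      row_i <- row_i + M + 1
    }
    colnames(inst) <- colnames(x)
    f <- pred_fun(inst)
    row_i <- 0
    for (p in perms) for (b in seq_len(nrow(bg))) {
      d <- diff(f[row_i + seq_len(M + 1)])
      phi[r, p] <- phi[r, p] + d
      row_i <- row_i + M + 1
    }
  }
  phi <- phi / (nperm * nrow(bg))
  list(phi = phi, base = base, prediction = as.numeric(pred_fun(x)))
}

#' Additive (SHAP) feature attributions
#'
#' Per-row, per-feature additive attributions of the selected model's
#' predictions: attributions plus a base value reproduce each prediction
#' (local accuracy). Gradient-boosted-tree models get exact path-dependent
#' TreeSHAP computed in double precision; other families get a seeded
#' permutation-sampling Shapley estimate against a background sample.
#' One-hot indicator columns are summed back onto their parent categorical
#' feature.
#'
#' @param object A fitted [are_model()] (attribution uses the selected
#'   candidate's point model) or a bare [are_fit()].
#' @param data Rows to attribute: a raw-scale data.frame for an `are_model`
#'   (default: its held-out test partition), or a transformed matrix for an
#'   `are_fit`.
#' @param background Background rows for the sampling estimator (default: the
#'   training partition / `data`).
#' @param nperm,n_background Sampling-Shapley effort (non-tree families).
#' @param seed Integer seed (sampling estimator only).
#' @return Object of class `are_attribution`: `phi` (rows x schema features,
#'   ARE percentage points), `phi_cols` (rows x transformed columns), `base`,
#'   `prediction`, `method`, `mean_abs` (per-feature mean absolute
#'   attribution).
#' @export
attribute <- function(object, data = NULL, background = NULL, nperm = 8,
                      n_background = 15, seed = 1) {
  if (inherits(object, "are_model")) {
    if (is.null(data)) data <- object$split$test
    x <- apply_transform(data, object$transform)
    bg <- apply_transform(if (is.null(background)) object$split$train else background,
                          object$transform)
    fit <- object$best$fit
    fmap <- transform_feature_map(object$transform)
  } else if (inherits(object, "are_fit")) {
    if (is.null(data)) stopf("data (transformed matrix) required for an are_fit")
    x <- as.matrix(data)
    bg <- if (is.null(background)) x else as.matrix(background)
    fit <- object
    fmap <- stats::setNames(colnames(x), colnames(x))
  } else stopf("object must be an are_model or are_fit")

  if (fit$family == "xgboost") {
    res <- tree_shap(fit$model, x)
    method <- "treeshap"
  } else {
    res <- sampling_shap(function(m) predict(fit, m), x, bg,
                         nperm = nperm, n_background = n_background, seed = seed)
    method <- "sampling"
  }
  parents <- unname(fmap[colnames(res$phi)])
  feats <- unique(parents)
  phi <- matrix(0, nrow(res$phi), length(feats), dimnames = list(NULL, feats))
  for (f in feats)
    phi[, f] <- rowSums(res$phi[, parents == f, drop = FALSE])
  structure(list(phi = phi, phi_cols = res$phi, base = res$base,
                 prediction = res$prediction, method = method,
                 mean_abs = colMeans(abs(phi))),
            class = "are_attribution")
}

#' @export
print.are_attribution <- function(x, ...) {
  cat(sprintf("Additive attributions (%s) for %d rows, %d features; base %.2f\n",
              x$method, nrow(x$phi), ncol(x$phi), x$base))
  top <- sort(x$mean_abs, decreasing = TRUE)[seq_len(min(8, ncol(x$phi)))]
  cat("Top mean |attribution| (ARE points):\n")
  print(round(top, 3))
  invisible(x)
}

#' Category-level attribution shares
#'
#' Share of total mean absolute attribution carried by each feature group of
#' the schema (water quality, artificial configuration, hydraulics and
#' temperature, construction characteristics). Shares sum to 100.
#'
#' @param attribution An [attribute()] result.
#' @param schema Feature schema mapping features to groups.
#' @return Named numeric vector of percentages (one per group).
#' @export
category_shares <- function(attribution, schema = default_schema()) {
  feats <- colnames(attribution$phi)
  grp <- schema$group[match(feats, schema$name)]
  if (anyNA(grp))
    stopf("feature(s) not mapped to a category: %s",
          paste(feats[is.na(grp)], collapse = ", "))
  totals <- tapply(attribution$mean_abs, factor(grp, levels = unique(schema$group)),
                   sum, default = 0)
  totals[is.na(totals)] <- 0
  100 * totals / sum(totals)
}

#' Permutation feature importance
#'
#' Mean held-out R2 drop after permuting each raw feature column (all one-hot
#' indicators of a categorical move together), averaged over `repeats`
#' seeded permutations of the selected candidate's point predictions. The
#' model-agnostic cross-check for the SHAP ranking.
#'
#' @param object A fitted [are_model()].
#' @param data Table with features and target (default: test partition).
#' @param repeats Permutations per feature, default 10.
#' @param seed Integer seed.
#' @return data.frame `feature`, `importance` (R2 drop), sorted decreasing,
#'   with a `rank` column.
#' @export
permutation_importance <- function(object, data = NULL, repeats = 10, seed = 1) {
  stopifnot(inherits(object, "are_model"))
  if (repeats < 1) stopf("repeats must be >= 1")
  if (is.null(data)) data <- object$split$test
  y <- data[[object$target]]
  fit <- object$best$fit
  pf <- function(d) predict(fit, apply_transform(d, object$transform))
  res <- shuffle_delta_r2(pf, data, y, object$schema$name, repeats, seed)
  res <- res[order(-res$delta_r2), c("feature", "delta_r2")]
  names(res)[2] <- "importance"
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Rank agreement between attribution and permutation rankings
#'
#' Spearman correlation between the per-feature mean absolute attribution and
#' the permutation importance.
#'
#' @param attribution An [attribute()] result.
#' @param importance A [permutation_importance()] result.
#' @return Spearman rho.
#' @export
rank_agreement <- function(attribution, importance) {
  shared <- intersect(colnames(attribution$phi), importance$feature)
  stats::cor(attribution$mean_abs[shared],
             importance$importance[match(shared, importance$feature)],
             method = "spearman")
}
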