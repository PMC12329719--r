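#' Mean antibiotic removal efficiency of a trial
#'
#' For a trial treating several antibiotics simultaneously, the single
#' training target is computed from the summed influent and effluent
#' concentrations: `ARE = 100 * (1 - sum(c_eff) / sum(c_inf))`. Negative
#' values (effluent exceeding influent, which occurs in practice) are allowed
#' and flagged with a warning. Setting `remaining = TRUE` returns the literal
#' remaining fraction `100 * sum(c_eff) / sum(c_inf)` instead.
#'
#' @param c_inf Influent concentrations (ug/L), one per antibiotic, all > 0.
#' @param c_eff Effluent concentrations (ug/L), aligned with `c_inf`, all >= 0.
#' @param remaining Return the remaining (not removed) percentage.
#' @return Percentage (scalar).
#' @export
#' @examples
#' mean_are(c(8, 2), c(2, 0.5))  # 75
mean_are <- function(c_inf, c_eff, remaining = FALSE) {
  if (length(c_inf) != length(c_eff))
    stopf("c_inf and c_eff must have equal length")
  if (length(c_inf) == 0 || any(c_inf <= 0))
    stopf("all influent concentrations must be > 0")
  if (any(c_eff < 0)) stopf("effluent concentrations must be >= 0")
  frac <- sum(c_eff) / sum(c_inf)
  out <- if (remaining) 100 * frac else 100 * (1 - frac)
  if (!remaining && out < 0)
    warnf("negative removal efficiency (%.2f%%): effluent exceeds influent", out)
  out
}

#' Iterative random-forest imputation of missing numeric cells
#'
#' missForest-style imputation: missing cells are initialised with column
#' means, then each missing-bearing numeric column (visited in order of
#' increasing missingness) is regressed on all other columns with a random
#' forest and its missing entries replaced by forest predictions. Iteration
#' stops when the normalised squared difference between successive imputed
#' matrices first increases (the previous iterate is returned) or after
#' `max_iter` sweeps. Observed cells are never modified.
#'
#' @param data data.frame; numeric columns may contain `NA`, categorical
#'   columns must be complete.
#' @param seed Integer seed (imputation is deterministic given data + seed).
#' @param max_iter Maximum sweeps, default 10.
#' @param num_trees Trees per forest, default 100.
#' @return The completed data.frame, with attribute `diagnostics`: a list
#'   holding `iterations` (sweeps accepted) and `diff` (the convergence
#'   statistic trajectory).
#' @export
impute_missforest <- function(data, seed = 1, max_iter = 10, num_trees = 100) {
  is_num <- vapply(data, is.numeric, logical(1))
  na_count <- vapply(data, function(x) sum(is.na(x)), integer(1))
  if (any(na_count[!is_num] > 0))
    stopf("missing values in non-numeric columns are not supported")
  if (any(na_count == nrow(data)))
    stopf("column(s) entirely missing: %s",
          paste(names(data)[na_count == nrow(data)], collapse = ", "))
  miss_cols <- names(data)[is_num & na_count > 0]
  if (length(miss_cols) == 0) {
    attr(data, "diagnostics") <- list(iterations = 0L, diff = numeric())
    return(data)
  }
  if (all(na_count > 0)) stopf("at least one fully observed column is required")
  miss_cols <- miss_cols[order(na_count[miss_cols])]
  na_idx <- lapply(miss_cols, function(j) which(is.na(data[[j]])))
  names(na_idx) <- miss_cols

  cur <- data
  for (j in miss_cols) cur[[j]][na_idx[[j]]] <- mean(data[[j]], na.rm = TRUE)

  imputed_vec <- function(d) unlist(lapply(miss_cols, function(j) d[[j]][na_idx[[j]]]))
  diffs <- numeric()
  prev <- cur
  for (it in seq_len(max_iter)) {
    new <- prev
    for (k in seq_along(miss_cols)) {
      j <- miss_cols[k]
      obs <- setdiff(seq_len(nrow(data)), na_idx[[j]])
      rf <- ranger::ranger(
        x = new[obs, setdiff(names(data), j), drop = FALSE],
        y = new[[j]][obs],
        num.trees = num_trees, num.threads = 1,
        seed = derive_seed(seed, it * 100 + k)
      )
      new[[j]][na_idx[[j]]] <- stats::predict(
        rf, data = new[na_idx[[j]], setdiff(names(data), j), drop = FALSE],
        num.threads = 1
      )$predictions
    }
    v_new <- imputed_vec(new); v_prev <- imputed_vec(prev)
    d <- sum((v_new - v_prev)^2) / sum(v_new^2)
    if (it > 1 && d > diffs[length(diffs)]) break  # criterion rose: keep prev
    diffs <- c(diffs, d)
    prev <- new
  }
  attr(prev, "diagnostics") <- list(iterations = length(diffs), diff = diffs)
  prev
}

#' Fit the encoding + scaling transform on a training table
#'
#' Numeric features are z-score standardised with training means and standard
#' deviations; categorical features are one-hot encoded (one indicator column
#' per level). The transform is fitted on the training partition only and
#' reused unchanged on any other table. A zero-variance numeric column maps
#' to all zeros with a warning; an unseen categorical level at apply time
#' maps to all-zero indicators with a warning.
#'
#' @param table Training data.frame containing the schema features.
#' @param schema Feature schema, see [default_schema()].
#' @return Object of class `are_transform`.
#' @export
fit_encode_scale <- function(table, schema = default_schema()) {
  missing_cols <- setdiff(schema$name, names(table))
  if (length(missing_cols))
    stopf("table lacks schema columns: %s", paste(missing_cols, collapse = ", "))
  num <- schema$name[schema$kind == "numeric"]
  cat <- schema$name[schema$kind == "categorical"]
  center <- vapply(table[num], mean, numeric(1))
  scale <- vapply(table[num], stats::sd, numeric(1))
  if (any(scale == 0))
    warnf("zero-variance numeric column(s) mapped to zeros: %s",
          paste(num[scale == 0], collapse = ", "))
  levels <- lapply(table[cat], function(x) levels(factor(x)))
  structure(list(schema = schema, numeric = num, categorical = cat,
                 center = center, scale = scale, levels = levels),
            class = "are_transform")
}

#' Apply a fitted transform to a table
#'
#' @param table data.frame with the schema feature columns.
#' @param transform An [fit_encode_scale()] object.
#' @return Numeric model matrix (z-scored numerics + one-hot indicators).
#' @export
apply_transform <- function(table, transform) {
  stopifnot(inherits(transform, "are_transform"))
  missing_cols <- setdiff(c(transform$numeric, transform$categorical), names(table))
  if (length(missing_cols))
    stopf("table lacks feature columns: %s", paste(missing_cols, collapse = ", "))
  n <- nrow(table)
  sc <- ifelse(transform$scale == 0, 1, transform$scale)
  numm <- sweep(sweep(as.matrix(table[transform$numeric]), 2, transform$center),
                2, sc, "/")
  numm[, transform$scale == 0] <- 0
  cats <- lapply(transform$categorical, function(j) {
    lv <- transform$levels[[j]]
    x <- as.character(table[[j]])
    unseen <- !is.na(x) & !(x %in% lv)
    if (any(unseen))
      warnf("unseen level(s) in '%s' mapped to all-zero indicators: %s",
            j, paste(unique(x[unseen]), collapse = ", "))
    m <- matrix(0, n, length(lv), dimnames = list(NULL, paste(j, lv, sep = ".")))
    hit <- match(x, lv)
    ok <- which(!is.na(hit))
    m[cbind(ok, hit[ok])] <- 1
    m
  })
  out <- do.call(cbind, c(list(numm), cats))
  rownames(out) <- NULL
  out
}

#' Invert the numeric part of a transform
#'
#' @param mat Matrix produced by [apply_transform()].
#' @param transform The fitting transform.
#' @return data.frame of the numeric features on their original scale.
#' @export
invert_transform <- function(mat, transform) {
  sc <- ifelse(transform$scale == 0, 1, transform$scale)
  out <- sweep(sweep(mat[, transform$numeric, drop = FALSE], 2, sc, "*"),
               2, transform$center, "+")
  as.data.frame(out)
}

# Map transformed column names back to schema feature names (one-hot columns
# collapse onto their categorical parent).
transform_feature_map <- function(transform) {
  cols <- c(transform$numeric,
            unlist(lapply(transform$categorical, function(j)
              paste(j, transform$levels[[j]], sep = "."))))
  parent <- c(transform$numeric,
              unlist(lapply(transform$categorical, function(j)
                rep(j, length(transform$levels[[j]])))))
  stats::setNames(parent, cols)
}

#' Random train/test split
#'
#' @param table data.frame with at least 5 rows.
#' @param seed Integer seed.
#' @param train_frac Training fraction in (0, 1); the train size is
#'   `floor(n * train_frac + 0.5)` (round half up).
#' @return list with `train`, `test`, and the integer index `train_idx`.
#' @export
split_table <- function(table, seed, train_frac = 0.8) {
  n <- nrow(table)
  if (n < 5) stopf("need at least 5 rows to split (got %d)", n)
  if (train_frac <= 0 || train_frac >= 1) stopf("train_frac must be in (0, 1)")
  set.seed(derive_seed(seed, 41))
  n_train <- floor(n * train_frac + 0.5 + 1e-9)  # half-up, guard float noise
  idx <- sample.int(n, n_train)
  list(train = table[idx, , drop = FALSE],
       test = table[-idx, , drop = FALSE],
       train_idx = sort(idx))
}
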