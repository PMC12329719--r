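test_that("mean ARE follows the pooled-concentration definition", {
  expect_equal(mean_are(c(10), c(0)), 100)
  expect_equal(mean_are(c(10, 10), c(10, 10)), 0)
  expect_equal(mean_are(c(8, 2), c(2, 0.5)), 75)
  # scale invariance
  expect_equal(mean_are(c(8, 2) * 7, c(2, 0.5) * 7), 75)
  # literal remaining-fraction form
  expect_equal(mean_are(c(8, 2), c(2, 0.5), remaining = TRUE), 25)
  expect_warning(out <- mean_are(c(1), c(1.5)), "negative removal")
  expect_equal(out, -50)
  expect_error(mean_are(c(1, 2), c(0)), "equal length")
  expect_error(mean_are(c(0, 0), c(0, 0)), "> 0")
  expect_error(mean_are(c(1), c(-0.1)), ">= 0")
})

test_that("imputation fills numeric cells, never touches observed ones", {
  x <- gen_experiments(120, seed = 3, missing_rate = 0.15)
  obs <- !is.na(x)
  xi <- impute_missforest(x, seed = 1)
  expect_false(anyNA(xi))
  num <- names(x)[sapply(x, is.numeric)]
  for (j in num)
    expect_identical(xi[[j]][obs[, j]], x[[j]][obs[, j]])
  d <- attr(xi, "diagnostics")
  expect_gte(d$iterations, 1)
  expect_identical(impute_missforest(x, seed = 1), xi)

  # complete table returned unchanged with 0 iterations
  x0 <- gen_experiments(50, seed = 4, missing_rate = 0)
  xi0 <- impute_missforest(x0, seed = 1)
  expect_equal(attr(xi0, "diagnostics")$iterations, 0L)
  attr(xi0, "diagnostics") <- NULL
  expect_identical(xi0, x0)
})

test_that("imputation recovers a strong linear relationship", {
  set.seed(7)
  x <- runif(200, 1, 10)
  d <- data.frame(x = x, y = 2 * x + rnorm(200, 0, 0.5))
  miss <- sample(200, 20)
  d$y[miss] <- NA
  di <- impute_missforest(d, seed = 2)
  relerr <- abs(di$y[miss] - 2 * x[miss]) / (2 * x[miss])
  expect_lt(median(relerr), 0.1)
})

test_that("imputation rejects degenerate inputs", {
  d <- data.frame(a = c(NA_real_, NA_real_, NA_real_), b = 1:3)
  expect_error(impute_missforest(d), "entirely missing")
  d2 <- data.frame(a = c(NA, 1, 2), b = c(1, NA, 3))
  expect_error(impute_missforest(d2), "fully observed")
  d3 <- data.frame(a = factor(c("x", NA, "y")), b = 1:3)
  expect_error(impute_missforest(d3), "non-numeric")
})

test_that("encode/scale transform standardises train and carries to test", {
  x <- gen_experiments(200, seed = 5, missing_rate = 0)
  sp <- split_table(x, seed = 5)
  tr <- fit_encode_scale(sp$train)
  m <- apply_transform(sp$train, tr)
  num <- tr$numeric
  expect_lt(max(abs(colMeans(m[, num]))), 1e-9)
  expect_lt(max(abs(apply(m[, num], 2, sd) - 1)), 1e-9)
  # one indicator per level, rows sum to 1 within each categorical
  for (j in tr$categorical) {
    cols <- paste(j, tr$levels[[j]], sep = ".")
    expect_true(all(cols %in% colnames(m)))
    expect_true(all(rowSums(m[, cols]) == 1))
  }
  # test table transformed with train statistics: means generally non-zero
  mt <- apply_transform(sp$test, tr)
  expect_gt(max(abs(colMeans(mt[, num]))), 1e-4)
  # inverse recovers original numerics
  inv <- invert_transform(m, tr)
  expect_lt(max(abs(as.matrix(inv) - as.matrix(sp$train[num]))), 1e-9)
})

test_that("transform flags zero-variance columns and unseen levels", {
  x <- gen_experiments(50, seed = 6, missing_rate = 0)
  x$tp <- 1
  expect_warning(tr <- fit_encode_scale(x), "zero-variance")
  m <- apply_transform(x, tr)
  expect_true(all(m[, "tp"] == 0))

  x2 <- gen_experiments(30, seed = 7, missing_rate = 0)
  tr2 <- fit_encode_scale(x2)
  x3 <- x2[1:3, ]
  levels(x3$structural_type) <- c(levels(x3$structural_type), "floating")
  x3$structural_type[1] <- "floating"
  expect_warning(m3 <- apply_transform(x3, tr2), "unseen")
  cols <- paste("structural_type", tr2$levels$structural_type, sep = ".")
  expect_equal(sum(m3[1, cols]), 0)
  expect_equal(sum(m3[2, cols]), 1)
})

test_that("train/test split is a seeded half-up-rounded partition", {
  x <- gen_experiments(100, seed = 8, missing_rate = 0)
  sp <- split_table(x, seed = 1)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_equal(sort(c(rownames(sp$train), rownames(sp$test))),
               sort(rownames(x)))
  expect_identical(split_table(x, seed = 1)$train_idx, sp$train_idx)
  # round-half-up: 45 * 0.7 = 31.5 -> 32
  expect_equal(nrow(split_table(x[1:45, ], seed = 2, train_frac = 0.7)$train), 32)
  expect_error(split_table(x[1:4, ], seed = 1), "at least 5")
  expect_error(split_table(x, seed = 1, train_frac = 1), "train_frac")
})
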