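test_that("tree attributions agree with the booster's own contributions", {
  set.seed(1)
  x <- matrix(rnorm(150 * 6), 150, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- 50 + 12 * x[, 1] - 9 * x[, 2] + 4 * x[, 3] + rnorm(150, 0, 3)
  fit <- are_fit(x, y, "xgboost",
                 params = list(nrounds = 120, lambda = 5, min_child_weight = 3),
                 seed = 1)
  at <- attribute(fit, x[1:25, ])
  expect_equal(at$method, "treeshap")
  # exact local accuracy in double precision
  expect_lt(max(abs(rowSums(at$phi_cols) + at$base - at$prediction)), 1e-9)
  # independent cross-check: xgboost's float32 TreeSHAP
  pc <- predict(fit$model, x[1:25, ], predcontrib = TRUE)
  expect_lt(max(abs(at$phi_cols - pc[, colnames(at$phi_cols)])), 1e-3)
  expect_lt(abs(at$base - pc[1, "(Intercept)"]), 1e-3)
  # and the double tree walk agrees with the float32 predictions
  expect_lt(max(abs(at$prediction - predict(fit, x[1:25, ]))), 1e-3)
})

test_that("constant and single-feature models have closed-form attributions", {
  set.seed(2)
  x <- matrix(rnorm(80 * 3), 80, 3, dimnames = list(NULL, paste0("f", 1:3)))
  fit0 <- are_fit(x, rep(55, 80), "xgboost", params = list(nrounds = 10),
                  seed = 1)
  at0 <- attribute(fit0, x[1:10, ])
  expect_lt(max(abs(at0$phi)), 1e-9)
  # single informative feature: attribution = prediction - mean prediction
  x1 <- matrix(seq(-2, 2, length.out = 100), 100, 1,
               dimnames = list(NULL, "f1"))
  y1 <- 40 + 20 * x1[, 1]
  fit1 <- are_fit(x1, y1, "xgboost",
                  params = list(nrounds = 200, eta = 0.3, lambda = 0.1,
                                min_child_weight = 1, subsample = 1,
                                colsample_bytree = 1), seed = 1)
  at1 <- attribute(fit1, x1)
  expect_equal(at1$phi[, "f1"], at1$prediction - at1$base, tolerance = 1e-9)
})

test_that("attributions of features absent from all splits are exactly zero", {
  set.seed(3)
  x <- matrix(rnorm(120 * 4), 120, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- 30 * x[, 1]  # f2..f4 pure noise with tiny amplitude target
  fit <- are_fit(x, y, "xgboost",
                 params = list(nrounds = 60, colsample_bytree = 1,
                               lambda = 1, min_child_weight = 5), seed = 1)
  used <- unique(xgboost::xgb.model.dt.tree(model = fit$model)$Feature)
  absent <- setdiff(paste0("f", 1:4), c(used, "f1"))
  at <- attribute(fit, x[1:15, ])
  for (f in absent) expect_true(all(at$phi[, f] == 0))
})

test_that("sampling attributions are exactly additive for non-tree models", {
  set.seed(4)
  x <- matrix(runif(90 * 4), 90, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- 50 + 20 * x[, 1] - 10 * x[, 2] + rnorm(90)
  fit <- are_fit(x, y, "knn", params = list(k = 5))
  at <- attribute(fit, x[1:6, ], background = x, nperm = 4, n_background = 8,
                  seed = 1)
  expect_equal(at$method, "sampling")
  expect_lt(max(abs(rowSums(at$phi_cols) + at$base - at$prediction)), 1e-9)
  # seeded determinism
  at2 <- attribute(fit, x[1:6, ], background = x, nperm = 4, n_background = 8,
                   seed = 1)
  expect_identical(at$phi, at2$phi)
})

test_that("category shares sum to 100 and track the drivers of the response", {
  m <- fixture_model()
  at <- attribute(m)
  sh <- category_shares(at, m$schema)
  expect_equal(sum(sh), 100, tolerance = 1e-9)
  expect_setequal(names(sh), unique(default_schema()$group))
  # water quality carries the concentration + chemistry effects and dominates
  expect_equal(unname(which.max(sh)), which(names(sh) == "water_quality"))
  # one-hot columns folded back onto schema features
  expect_setequal(colnames(at$phi), m$schema$name)
  bad <- at
  colnames(bad$phi)[1] <- "mystery"
  expect_error(category_shares(bad, m$schema), "not mapped")
})

test_that("category shares isolate a single-group driver", {
  # response driven only by water-quality features
  x <- gen_experiments(250, seed = 11, missing_rate = 0)
  x$are <- clip_pct(60 - 25 * (1 - exp(-x$antibiotic_conc / 150)) +
                      15 * x$tetracycline_pct / 100 +
                      rnorm(250, 0, 2))
  m <- are_model(are ~ ., x, families = "xgboost", B = 2, seed = 2)
  sh <- category_shares(attribute(m), m$schema)
  expect_gt(sh[["water_quality"]], 80)
})

test_that("permutation importance reconfirms the attribution ranking", {
  m <- fixture_model()
  pi <- permutation_importance(m, repeats = 10, seed = 1)
  expect_setequal(pi$feature, default_schema()$name)
  expect_equal(pi$rank, seq_len(nrow(pi)))
  # inert features score near zero
  expect_lt(max(abs(pi$importance[pi$feature %in%
                                    c("tp", "aspect_ratio", "wetland_area")])),
            0.02)
  at <- attribute(m)
  expect_gte(rank_agreement(at, pi), 0.6)
  # deterministic per seed
  pi2 <- permutation_importance(m, repeats = 2, seed = 9)
  pi3 <- permutation_importance(m, repeats = 2, seed = 9)
  expect_identical(pi2, pi3)
})
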