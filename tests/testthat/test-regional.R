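test_that("surplus concentration and risk quotient arithmetic", {
  expect_equal(conc_surplus(10, 1), 0)
  expect_equal(conc_surplus(10, 0.75), 2.5)
  expect_error(conc_surplus(10, 1.2), "fraction")
  expect_error(conc_surplus(-1, 0.5), ">= 0")

  expect_equal(rq_total(6, 1, 3), 2)
  expect_equal(rq_total(0, 5, 3), 0)
  expect_equal(rq_total(3, 1, 3), 1)
  expect_error(rq_total(1, 0, 3), "n must be")
  expect_error(rq_total(1, 1, 0), "pnec_min")
  # linear in c_surp, inverse in n and pnec_min
  expect_equal(rq_total(12, 1, 3), 2 * rq_total(6, 1, 3))
  expect_equal(rq_total(6, 2, 3), rq_total(6, 1, 3) / 2)
  expect_equal(rq_total(6, 1, 6), rq_total(6, 1, 3) / 2)
})

test_that("risk bands follow the strict RQ > 1 high rule", {
  b <- classify_risk(c(0.005, 0.05, 0.5, 1, 1.01, 25))
  expect_equal(as.character(b), c("no", "low", "medium", "medium", "high", "high"))
  expect_equal(as.character(classify_risk(0.01)), "no")
  expect_equal(as.character(classify_risk(0.1)), "low")
  expect_error(classify_risk(-0.1), ">= 0")
})

test_that("allocation modes distribute emissions as specified", {
  w1 <- toy_county("natural", 2)
  for (mode in c("NM", "IM")) {
    a <- allocate(100, w1, mode)
    expect_equal(a$ai_t, 100)
    expect_equal(a$stage, 1L)
  }
  # IM: whole emission to constructed first, surplus split equally after
  w <- toy_county(c("constructed", "natural", "natural"), c(1, 2, 4))
  a <- allocate(100, w, "IM")
  expect_equal(a$ai_t[a$stage == 1], 100)
  expect_equal(sum(a$stage == 2), 2)
  rs <- removal_and_surplus(100, w, a, function(df) rep(0.7, nrow(df)))
  s2 <- rs$wetlands[rs$wetlands$stage == 2, ]
  expect_equal(s2$ai_t, c(15, 15))
  expect_equal(rs$removal_t, 70 + 2 * 15 * 0.7)
  # NM is area-proportional in one stage
  an <- allocate(70, w, "NM")
  expect_equal(an$ai_t, 70 * c(1, 2, 4) / 7)
  # IM with no constructed wetlands falls back to NM
  wn <- toy_county(c("natural", "reservoir"), c(1, 3))
  expect_equal(allocate(50, wn, "IM")$ai_t, allocate(50, wn, "NM")$ai_t)
  expect_true(attr(allocate(50, wn, "IM"), "fallback"))
  # no wetlands: warning, empty allocation, full surplus
  w0 <- toy_county(character(), numeric())
  expect_warning(a0 <- allocate(10, w0, "NM"), "no wetlands")
  expect_equal(nrow(a0), 0)
  rs0 <- removal_and_surplus(10, w0, suppressWarnings(allocate(10, w0, "NM")),
                             truth_frac)
  expect_equal(rs0$surplus_t, 10)
})

test_that("removal is ARE times input and the mass balance closes", {
  w <- toy_county("constructed", 5)
  rs <- removal_and_surplus(10, w, allocate(10, w, "NM"),
                            function(df) rep(0.722, nrow(df)))
  expect_equal(rs$wetlands$ar_t, 7.22)
  expect_equal(rs$surplus_t, 2.78)
  # ARE = 1 everywhere -> zero surplus; ARE = 0 -> full surplus
  w2 <- toy_county(c("constructed", "natural"), c(1, 1))
  rs1 <- removal_and_surplus(8, w2, allocate(8, w2, "IM"),
                             function(df) rep(1, nrow(df)))
  expect_equal(rs1$surplus_t, 0)
  rs0 <- removal_and_surplus(8, w2, allocate(8, w2, "IM"),
                             function(df) rep(0, nrow(df)))
  expect_equal(rs0$surplus_t, 8)
  expect_equal(rs0$removal_t, 0)
})

test_that("county-level assessment equals the per-county allocation chain", {
  r <- gen_region(12, seed = 21)
  for (mode in c("NM", "IM")) {
    a <- assess_region(r, mode, truth_frac)
    for (cty in r$counties$county) {
      w <- r$wetlands[r$wetlands$county == cty, , drop = FALSE]
      e <- r$counties$emission_t[r$counties$county == cty]
      rs <- suppressWarnings(
        removal_and_surplus(e, w, suppressWarnings(allocate(e, w, mode)),
                            truth_frac))
      got <- a$counties[a$counties$county == cty, ]
      expect_equal(got$removal_t, rs$removal_t, tolerance = 1e-10)
      expect_equal(got$surplus_t, rs$surplus_t, tolerance = 1e-10)
    }
  }
})

test_that("assessment wetland records satisfy stage-wise mass identities", {
  r <- fixture_region()
  for (mode in c("NM", "IM")) {
    a <- assess_region(r, mode, truth_frac)
    wl <- a$wetlands
    expect_true(all(wl$ar_t <= wl$ai_t + 1e-12))
    expect_true(all(wl$ai_t >= 0))
    expect_equal(wl$ar_t, wl$ai_t * wl$are, tolerance = 1e-12)
    for (cty in unique(wl$county)) {
      wc <- wl[wl$county == cty, ]
      e <- r$counties$emission_t[r$counties$county == cty]
      expect_equal(sum(wc$ai_t[wc$stage == 1]), e, tolerance = 1e-9 * e)
      if (any(wc$stage == 2))
        expect_equal(sum(wc$ai_t[wc$stage == 2]),
                     e - sum(wc$ar_t[wc$stage == 1]), tolerance = 1e-9 * e)
    }
    expect_equal(a$totals$emission_t,
                 a$totals$removal_t + a$totals$surplus_t,
                 tolerance = 1e-9 * a$totals$emission_t)
  }
})

test_that("high-risk county area counts natural-class wetlands only", {
  r <- gen_region(8, seed = 31)
  a <- assess_region(r, "NM", truth_frac)
  # manual recomputation from the wetland table
  wl <- a$wetlands
  hi <- unique(wl$county[wl$band == "high" &
                           wl$class %in% c("natural", "reservoir")])
  expect_equal(hra(a), sum(r$counties$area_km2[r$counties$county %in% hi]))
  # a county whose only high-risk wetland is constructed is excluded
  w <- toy_county(c("constructed", "natural"), c(1, 100))
  w$county <- "c1"
  r2 <- list(counties = data.frame(county = "c1", area_km2 = 100,
                                   emission_t = 5),
             wetlands = w, inventory = gen_inventory(10, seed = 1))
  class(r2) <- "wet_region"
  # class-dependent removal: constructed passes load through, natural removes
  cls_fun <- function(df) ifelse(df$class == "constructed", 0, 0.999)
  a2 <- assess_region(r2, "NM", cls_fun)
  expect_equal(as.character(a2$wetlands$band[a2$wetlands$class == "constructed"]),
               "high")
  expect_equal(hra(a2), 0)
  # no high-risk wetlands anywhere -> 0
  r3 <- r
  r3$counties$emission_t <- r3$counties$emission_t * 1e-9
  expect_equal(hra(assess_region(r3, "NM", truth_frac)), 0)
  # reservoir rule switch
  a4 <- assess_region(r, "NM", truth_frac, include_reservoirs = FALSE)
  expect_lte(hra(a4), hra(a))
  expect_equal(hra(a, include_reservoirs = FALSE), hra(a4))
})
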