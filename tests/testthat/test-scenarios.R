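test_that("the scenario grid enumerates the 18 policy combinations", {
  g <- scenario_grid()
  expect_equal(nrow(g), 18)
  expect_equal(anyDuplicated(g$id), 0)
  expect_true("IM-WR3-60" %in% g$id)
  expect_setequal(unique(g$management), c("NM", "IM"))
  expect_setequal(unique(g$restoration), c("WR1", "WR2", "WR3"))
  expect_setequal(unique(g$abatement), c(0.2, 0.4, 0.6))
  # pairing counts used by the contribution analysis
  expect_equal(sum(g$management == "IM"), 9)
  expect_equal(sum(g$restoration == "WR2"), 6)
  expect_equal(sum(g$abatement == 0.6), 6)
})

test_that("participation ramps 10%/yr to 2025 then 5%/yr to 2035", {
  expect_equal(participation(2020), 0)
  expect_equal(participation(2025), 0.5)
  expect_equal(participation(2035), 1)
  expect_equal(participation(2023), 0.3)
  expect_equal(participation(2030), 0.75)
  p <- participation(2020:2035)
  expect_true(all(diff(p) > 0 | p[-1] == 1))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(participation(2019), "2020-2035")
  expect_error(participation(2036), "2020-2035")
})

test_that("effective emissions scale with participation and abatement", {
  expect_equal(effective_emissions(100, 0.6, 2035), 40)
  expect_equal(effective_emissions(100, 0, 2030), 100)
  expect_equal(effective_emissions(100, 0.2, 2025), 90)
  expect_error(effective_emissions(-1, 0.2, 2025), ">= 0")
  expect_error(effective_emissions(10, 1.2, 2025), "abatement")
})

test_that("restoration adds exactly the annual expansion area", {
  r <- fixture_region()
  a0 <- sum(r$wetlands$area_km2)
  expect_equal(sum(expand_wetlands(r, "WR1")$wetlands$area_km2), a0)
  r2 <- expand_wetlands(r, "WR2")
  expect_equal(sum(r2$wetlands$area_km2), a0 + 180, tolerance = 1e-9)
  expect_true(all(r2$wetlands$class[grepl("-R$", r2$wetlands$wetland)] ==
                    "natural"))
  # cumulative expansion over 15 years
  rr <- r
  for (i in 1:15) rr <- expand_wetlands(rr, "WR2")
  expect_equal(sum(rr$wetlands$area_km2), a0 + 2700, tolerance = 1e-6)
  # WR3 with no high-risk counties equals a WR2 step
  r3 <- expand_wetlands(r, "WR3", high_risk_counties = character())
  expect_equal(sum(r3$wetlands$area_km2), sum(r2$wetlands$area_km2))
  expect_equal(r3$wetlands$area_km2, r2$wetlands$area_km2)
  # WR3 targets the named counties equally
  r4 <- expand_wetlands(r, "WR3", high_risk_counties = r$counties$county[1:3])
  added <- setdiff(r4$wetlands$wetland, r$wetlands$wetland)
  expect_equal(sort(r4$wetlands$county[r4$wetlands$wetland %in% added]),
               sort(r$counties$county[1:3]))
  expect_equal(r4$wetlands$area_km2[r4$wetlands$wetland %in% added],
               rep(60, 3))
})

test_that("restored wetlands carry county-median feature attributes", {
  r <- fixture_region()
  r2 <- expand_wetlands(r, "WR2")
  new <- r2$wetlands[grepl("-R$", r2$wetlands$wetland), ][1, ]
  src <- r$wetlands[r$wetlands$county == new$county, ]
  expect_equal(new$ph, median(src$ph))
  expect_equal(new$temperature, median(src$temperature))
  expect_equal(new$wetland_area, new$area_km2 * 1e6)
})

test_that("projection runs the yearly chain and respects fixture orderings", {
  r <- fixture_region()
  best <- project_scenario(list(management = "IM", restoration = "WR3",
                                abatement = 0.6), r, truth_frac)
  worst <- project_scenario(list(management = "NM", restoration = "WR1",
                                 abatement = 0.2), r, truth_frac)
  expect_equal(best$year, 2021:2035)
  expect_equal(nrow(best), 15)
  expect_true(all(best$lwr <= best$hra & best$hra <= best$upr))
  # deterministic predictor: band collapses onto the trajectory
  expect_equal(best$lwr, best$hra)
  # monotone drivers give a non-increasing high-risk area
  expect_true(all(diff(best$hra) <= 1e-9))
  # the weakest scenario never beats the strongest
  expect_true(all(worst$hra >= best$hra))
})

test_that("contribution analysis matches hand-computed efficiencies", {
  g <- scenario_grid()
  # identical series -> all efficiencies zero
  flat <- lapply(seq_len(nrow(g)), function(i)
    data.frame(year = 2021:2035, hra = rep(100, 15)))
  names(flat) <- g$id
  c0 <- contribution_analysis(flat)
  expect_equal(c0$paired$efficiency, rep(0, 5))
  # IM exactly halves every value -> management efficiency 0.5
  half <- lapply(seq_len(nrow(g)), function(i)
    data.frame(year = 2021:2035,
               hra = rep(if (g$management[i] == "IM") 50 else 100, 15)))
  names(half) <- g$id
  c1 <- contribution_analysis(half)
  expect_equal(c1$paired$efficiency[c1$paired$level == "IM"], 0.5)
  expect_equal(c1$vs_baseline$efficiency[c1$vs_baseline$level == "IM"], 0.5)
  expect_equal(c1$paired$efficiency[c1$paired$level == "WR2"], 0)
  expect_setequal(c1$by_measure$measure,
                  c("management", "restoration", "abatement"))
  expect_error(contribution_analysis(flat[1:17]), "missing")
})
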