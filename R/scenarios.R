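#' The full policy scenario grid
#'
#' All 18 combinations of wetland management (NM, IM), wetland restoration
#' (WR1 no expansion; WR2 proportional expansion; WR3 expansion targeted at
#' high-risk counties, both at 180 km2/yr) and antibiotic abatement rate
#' (20%, 40%, 60%), in a fixed deterministic order with unique ids such as
#' `"IM-WR3-60"`.
#'
#' @return data.frame with columns `id`, `management`, `restoration`,
#'   `abatement`.
#' @export
#' @examples
#' nrow(scenario_grid())
scenario_grid <- function() {
  g <- expand.grid(management = c("NM", "IM"),
                   restoration = c("WR1", "WR2", "WR3"),
                   abatement = c(0.2, 0.4, 0.6),
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g$id <- sprintf("%s-%s-%.0f", g$management, g$restoration, 100 * g$abatement)
  g[, c("id", "management", "restoration", "abatement")]
}

#' Farm participation in the antibiotic-reduction action
#'
#' Participation starts at 0 in 2020, rises by 10 percentage points per year
#' to 50% in 2025, then by 5 points per year to 100% in 2035.
#'
#' @param year Year(s) in 2020-2035.
#' @return Fraction(s) in \[0, 1\].
#' @export
#' @examples
#' participation(c(2020, 2025, 2035))
participation <- function(year) {
  if (any(year < 2020 | year > 2035))
    stopf("year must be within 2020-2035")
  pmin(1, 0.10 * pmin(year - 2020, 5) + 0.05 * pmax(year - 2025, 0))
}

#' Effective emissions under an abatement scenario
#'
#' `E = E0 x (1 - participation(year) x abatement)`: abatement applies only
#' to the participating share of farms.
#'
#' @param e0 Baseline emission (t/yr, >= 0).
#' @param abatement Abatement rate in \[0, 1\].
#' @param year Year in 2020-2035.
#' @return Effective emission (t/yr).
#' @export
#' @examples
#' effective_emissions(100, 0.2, 2025)  # 90
effective_emissions <- function(e0, abatement, year) {
  if (any(e0 < 0)) stopf("e0 must be >= 0")
  if (any(abatement < 0 | abatement > 1)) stopf("abatement must be in [0, 1]")
  e0 * (1 - participation(year) * abatement)
}

# County medians of the wetland feature attributes (modal level for
# categoricals), used to equip newly restored wetland area.
median_features <- function(wetlands) {
  sch <- default_schema()
  out <- list()
  for (i in seq_len(nrow(sch))) {
    nm <- sch$name[i]
    out[[nm]] <- if (sch$kind[i] == "numeric") stats::median(wetlands[[nm]])
      else {
        tb <- table(wetlands[[nm]])
        factor(names(tb)[which.max(tb)], levels = feature_levels()[[nm]])
      }
  }
  as.data.frame(out)
}

#' Apply one year of wetland restoration to a region
#'
#' `WR1` leaves the region unchanged. `WR2` adds `rate_km2` of natural-class
#' wetland area, distributed across counties proportional to their existing
#' wetland area. `WR3` splits the same annual area equally among the counties
#' currently classified high-risk (falling back to the WR2 distribution when
#' none are). Restored area accrues to one "restored" natural wetland per
#' county, created on first allocation with the county's median wetland
#' feature attributes (region-wide medians for counties without wetlands).
#'
#' @param region A [gen_region()] state.
#' @param mode `"WR1"`, `"WR2"` or `"WR3"`.
#' @param high_risk_counties County ids currently classified high-risk
#'   (used by WR3; refreshed each simulated year by [project_scenario()]).
#' @param rate_km2 Net annual expansion, default 180 km2.
#' @return The updated region state.
#' @export
expand_wetlands <- function(region, mode = c("WR1", "WR2", "WR3"),
                            high_risk_counties = character(), rate_km2 = 180) {
  mode <- match.arg(mode)
  if (mode == "WR1") return(region)
  co <- region$counties
  wl <- region$wetlands
  if (mode == "WR3" && length(high_risk_counties) > 0) {
    delta <- stats::setNames(rep(0, nrow(co)), co$county)
    delta[high_risk_counties] <- rate_km2 / length(high_risk_counties)
  } else {
    w_area <- tapply(wl$area_km2, factor(wl$county, levels = co$county), sum,
                     default = 0)
    w_area[is.na(w_area)] <- 0
    delta <- if (sum(w_area) > 0) rate_km2 * w_area / sum(w_area)
      else stats::setNames(rep(rate_km2 / nrow(co), nrow(co)), co$county)
  }
  for (cty in names(delta)[delta > 0]) {
    rid <- paste0(cty, "-R")
    hit <- which(wl$wetland == rid)
    if (length(hit)) {
      wl$area_km2[hit] <- wl$area_km2[hit] + delta[cty]
      wl$wetland_area[hit] <- wl$area_km2[hit] * 1e6
    } else {
      src <- wl[wl$county == cty, , drop = FALSE]
      feats <- median_features(if (nrow(src)) src else wl)
      new <- cbind(data.frame(wetland = rid, county = cty, class = "natural",
                              area_km2 = delta[[cty]], stringsAsFactors = FALSE),
                   feats)
      new$wetland_area <- new$area_km2 * 1e6
      extra <- setdiff(names(wl), names(new))
      for (e in extra) new[[e]] <- NA
      wl <- rbind(wl, new[, names(wl)])
    }
  }
  region$wetlands <- wl
  region
}

# One simulated 2021-2035 trajectory of the high-risk county area for a
# given ARE predictor function.
hra_chain <- function(region, spec, fun, years, hlr_m_day, include_reservoirs,
                      rate_km2 = 180) {
  e0 <- region$counties$emission_t
  base <- assess_region(region, spec$management, fun, hlr_m_day,
                        include_reservoirs)
  high <- base$counties$county[base$counties$high_risk]
  out <- numeric(length(years))
  for (i in seq_along(years)) {
    region <- expand_wetlands(region, spec$restoration, high, rate_km2)
    region$counties$emission_t <-
      effective_emissions(e0, spec$abatement, years[i])
    a <- assess_region(region, spec$management, fun, hlr_m_day,
                       include_reservoirs)
    out[i] <- a$totals$hra_km2
    high <- a$counties$county[a$counties$high_risk]
  }
  out
}

#' Project the high-risk county area under one policy scenario
#'
#' Simulates 2021-2035 year by year: restoration expands the wetland stock
#' (WR3 retargets to the current high-risk counties each year), abatement
#' scales emissions through the participation ramp, the management mode
#' allocates emissions to wetlands, the ARE model predicts removal, and the
#' cask-effect risk quotients yield the year's high-risk county area (HRA).
#'
#' Uncertainty: the whole chain is repeated with individual bootstrap
#' members of the fitted model; the reported point estimate is the member
#' median (which by construction lies inside the 2.5/97.5 percentile band)
#' and `hra_mean_are` is the trajectory driven by the full ensemble-mean
#' prediction. With a plain function predictor the band collapses onto the
#' single deterministic trajectory.
#'
#' @param spec One row of [scenario_grid()] (or a list with `management`,
#'   `restoration`, `abatement`).
#' @param region A [gen_region()] state (2020 baseline).
#' @param are A fitted [are_model()] or a `function(features) -> fraction`.
#' @param seed Integer seed (member subsampling).
#' @param members Number of bootstrap members propagated for the band,
#'   default 25 (capped at the ensemble size).
#' @param years Projection years, default 2021:2035.
#' @param hlr_m_day,include_reservoirs Passed to [assess_region()].
#' @param rate_km2 Annual restoration area, default 180.
#' @return data.frame of class `hra_projection`: `year`, `hra` (km2), `lwr`,
#'   `upr` (95% band), `hra_mean_are`; attribute `spec`.
#' @export
project_scenario <- function(spec, region, are, seed = 1, members = 25,
                             years = 2021:2035, hlr_m_day = 0.05,
                             include_reservoirs = TRUE, rate_km2 = 180) {
  if (is.data.frame(spec)) spec <- as.list(spec[1, ])
  if (inherits(are, "are_model")) {
    B <- are$ensemble$B
    set.seed(derive_seed(seed, 131))
    pick <- if (members >= B) seq_len(B) else sort(sample.int(B, members))
    chains <- vapply(pick, function(b)
      hra_chain(region, spec, member_are_predictor(are, b), years,
                hlr_m_day, include_reservoirs, rate_km2),
      numeric(length(years)))
    mean_chain <- hra_chain(region, spec, are_predictor(are), years,
                            hlr_m_day, include_reservoirs, rate_km2)
    out <- data.frame(
      year = years,
      hra = apply(chains, 1, stats::median),
      lwr = apply(chains, 1, stats::quantile, probs = 0.025),
      upr = apply(chains, 1, stats::quantile, probs = 0.975),
      hra_mean_are = mean_chain
    )
  } else {
    h <- hra_chain(region, spec, are_predictor(are), years, hlr_m_day,
                   include_reservoirs, rate_km2)
    out <- data.frame(year = years, hra = h, lwr = h, upr = h,
                      hra_mean_are = h)
  }
  attr(out, "spec") <- spec
  class(out) <- c("hra_projection", "data.frame")
  out
}

#' Project the full 18-scenario grid
#'
#' @inheritParams project_scenario
#' @param grid Scenario grid, default [scenario_grid()].
#' @return Named list of [project_scenario()] results, keyed by scenario id.
#' @export
project_grid <- function(region, are, seed = 1, members = 25,
                         grid = scenario_grid(), ...) {
  out <- lapply(seq_len(nrow(grid)), function(i)
    project_scenario(as.list(grid[i, ]), region, are, seed = seed,
                     members = members, ...))
  names(out) <- grid$id
  out
}

#' Per-measure HRA reduction efficiency (control-variable analysis)
#'
#' For each measure level (IM against NM; WR2 and WR3 against WR1; 40% and
#' 60% abatement against 20%), the mean over all scenario pairs identical in
#' the other two factors and over all projection years of
#' `(HRA_reference - HRA_measure) / HRA_reference` (pairs whose reference
#' HRA is zero are dropped). A second table references everything against
#' the common NM-WR1-20 baseline with only the one factor changed.
#'
#' @param projections Named list from [project_grid()] covering all 18 ids.
#' @return list with `paired` and `vs_baseline` data.frames (`measure`,
#'   `level`, `reference`, `efficiency`) and `by_measure` (mean efficiency
#'   per measure family).
#' @export
contribution_analysis <- function(projections) {
  grid <- scenario_grid()
  if (!all(grid$id %in% names(projections)))
    stopf("projections must cover all %d scenario ids (missing: %s)",
          nrow(grid),
          paste(setdiff(grid$id, names(projections)), collapse = ", "))
  hra_of <- function(id) projections[[id]]$hra
  pair_eff <- function(ref_id, alt_id) {
    r <- hra_of(ref_id); a <- hra_of(alt_id)
    ok <- r > 0
    if (!any(ok)) return(numeric())
    (r[ok] - a[ok]) / r[ok]
  }
  comparisons <- list(
    list(measure = "management", level = "IM", ref = "NM", factor = "management"),
    list(measure = "restoration", level = "WR2", ref = "WR1", factor = "restoration"),
    list(measure = "restoration", level = "WR3", ref = "WR1", factor = "restoration"),
    list(measure = "abatement", level = "AR40", ref = "AR20", factor = "abatement"),
    list(measure = "abatement", level = "AR60", ref = "AR20", factor = "abatement")
  )
  level_value <- function(factor, label) {
    if (factor == "abatement") as.numeric(sub("AR", "", label)) / 100 else label
  }
  paired <- do.call(rbind, lapply(comparisons, function(cp) {
    others <- setdiff(c("management", "restoration", "abatement"), cp$factor)
    refs <- grid[grid[[cp$factor]] == level_value(cp$factor, cp$ref), ]
    effs <- unlist(lapply(seq_len(nrow(refs)), function(i) {
      alt <- grid$id[grid[[cp$factor]] == level_value(cp$factor, cp$level) &
                     grid[[others[1]]] == refs[[others[1]]][i] &
                     grid[[others[2]]] == refs[[others[2]]][i]]
      pair_eff(refs$id[i], alt)
    }))
    data.frame(measure = cp$measure, level = cp$level, reference = cp$ref,
               efficiency = mean(effs), stringsAsFactors = FALSE)
  }))
  baseline_id <- "NM-WR1-20"
  vs_baseline <- do.call(rbind, lapply(comparisons, function(cp) {
    base <- grid[grid$id == baseline_id, ]
    alt <- base
    alt[[cp$factor]] <- level_value(cp$factor, cp$level)
    alt_id <- grid$id[grid$management == alt$management &
                      grid$restoration == alt$restoration &
                      grid$abatement == alt$abatement]
    data.frame(measure = cp$measure, level = cp$level, reference = baseline_id,
               efficiency = mean(pair_eff(baseline_id, alt_id)),
               stringsAsFactors = FALSE)
  }))
  by_measure <- stats::aggregate(efficiency ~ measure, paired, mean)
  list(paired = paired, vs_baseline = vs_baseline, by_measure = by_measure)
}
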