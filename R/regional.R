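CONSTRUCTED_CLASSES <- c("constructed", "CPW")
NATURAL_CLASSES <- c("natural", "reservoir")

#' Concentration model: antibiotic input to influent concentration
#'
#' Converts an annual antibiotic mass assigned to a wetland into an influent
#' concentration through the annual hydraulic volume
#' `V = HLR x area x 1 yr`: `c = AI / V`. This stands behind a single
#' function so a site-specific concentration model can be substituted.
#'
#' @param ai_t Antibiotic input (t/yr).
#' @param area_km2 Wetland area (km2).
#' @param hlr_m_day Hydraulic loading rate (m/d), default 0.05.
#' @return Influent concentration (ug/L).
#' @export
ai_to_conc <- function(ai_t, area_km2, hlr_m_day = 0.05) {
  if (any(area_km2 <= 0) || hlr_m_day <= 0)
    stopf("areas and hydraulic loading rate must be > 0")
  v_l <- area_km2 * 1e6 * hlr_m_day * 365 * 1e3  # m2 * m/yr * L/m3
  ai_t * 1e12 / v_l
}

#' Concentration surplus after treatment
#'
#' `c_surp = c * (1 - ARE)`, the residual concentration leaving a wetland.
#'
#' @param c Influent concentration (any concentration unit, typically ng/L).
#' @param are Removal efficiency as a fraction in \[0, 1\].
#' @return Surplus concentration in the unit of `c`.
#' @export
#' @examples
#' conc_surplus(10, 0.75)  # 2.5
conc_surplus <- function(c, are) {
  if (any(c < 0)) stopf("concentrations must be >= 0")
  if (any(are < 0 | are > 1)) stopf("are must be a fraction in [0, 1]")
  c * (1 - are)
}

#' Cask-effect total risk quotient
#'
#' Aggregate risk of a multi-antibiotic surplus, governed by the most
#' sensitive ("shortest stave") antibiotic:
#' `RQ_total = c_surp / (n x PNEC_min)`, with `c_surp` the total surplus
#' concentration, `n` the number of discharged antibiotic types, and
#' `PNEC_min` the minimum algal predicted no-effect concentration in the
#' emission inventory.
#'
#' @param c_surp Surplus concentration (ng/L).
#' @param n Number of antibiotic types (>= 1).
#' @param pnec_min Minimum PNEC (ng/L, > 0).
#' @return Dimensionless risk quotient.
#' @export
#' @examples
#' rq_total(6, 1, 3)  # 2
rq_total <- function(c_surp, n, pnec_min) {
  if (any(n < 1)) stopf("n must be >= 1")
  if (any(pnec_min <= 0)) stopf("pnec_min must be > 0")
  if (any(c_surp < 0)) stopf("c_surp must be >= 0")
  c_surp / (n * pnec_min)
}

#' Risk band of a risk quotient
#'
#' High risk is the strict `RQ > 1` rule; sub-unity bands follow conventional
#' risk-quotient banding: medium for `0.1 < RQ <= 1`, low for
#' `0.01 < RQ <= 0.1`, no risk otherwise.
#'
#' @param rq Non-negative risk quotient(s).
#' @return factor with levels `no`, `low`, `medium`, `high`.
#' @export
#' @examples
#' classify_risk(c(0.005, 0.05, 1, 1.01))
classify_risk <- function(rq) {
  if (any(rq < 0)) stopf("rq must be >= 0")
  factor(ifelse(rq > 1, "high",
         ifelse(rq > 0.1, "medium",
         ifelse(rq > 0.01, "low", "no"))),
         levels = c("no", "low", "medium", "high"))
}

# Normalise the ARE predictor argument: a function(features df) -> fraction,
# an are_model (ensemble mean), or a single are_fit + transform pair.
are_predictor <- function(are) {
  if (is.function(are)) return(function(df) pmin(pmax(are(df), 0), 1))
  if (inherits(are, "are_model"))
    return(function(df) predict(are, df, interval = FALSE) / 100)
  stopf("'are' must be a function(features)->fraction or an are_model")
}

# Predictor using one bootstrap member of a fitted are_model.
member_are_predictor <- function(model, b) {
  stopifnot(inherits(model, "are_model"))
  fit <- model$ensemble$members[[b]]
  function(df) clip_pct(predict(fit, apply_transform(df, model$transform))) / 100
}

#' Allocate a county's antibiotic emission across its wetlands
#'
#' Two allocation modes. `NM` (no management): the county emission is
#' distributed across all wetlands proportional to wetland area in a single
#' stage. `IM` (improved, multistage): the entire emission is first
#' distributed across constructed wetlands (constructed + CPW classes,
#' excluding reservoirs) proportional to area; the summed first-stage surplus
#' is then split in equal mass shares across the remaining wetlands (natural
#' and reservoir) as second-stage treatment units. Counties with no
#' constructed wetlands fall back to NM; counties with no wetlands at all
#' return an empty allocation with a warning (the full emission becomes
#' surplus).
#'
#' Second-stage inputs depend on first-stage removal, so they are left `NA`
#' here and filled by [removal_and_surplus()].
#'
#' @param emission_t County emission (t/yr, >= 0).
#' @param wetlands data.frame of the county's wetlands (`wetland`, `class`,
#'   `area_km2`, feature columns).
#' @param mode `"NM"` or `"IM"`.
#' @return data.frame `wetland`, `stage`, `ai_t` with attribute `fallback`.
#' @export
allocate <- function(emission_t, wetlands, mode = c("NM", "IM")) {
  mode <- match.arg(mode)
  if (emission_t < 0) stopf("emission must be >= 0")
  if (nrow(wetlands) == 0) {
    warnf("county has no wetlands: full emission (%.3g t) remains as surplus",
          emission_t)
    return(structure(data.frame(wetland = character(), stage = integer(),
                                ai_t = numeric()), fallback = FALSE))
  }
  constructed <- wetlands$class %in% CONSTRUCTED_CLASSES
  fallback <- mode == "IM" && !any(constructed)
  if (mode == "NM" || fallback) {
    out <- data.frame(wetland = wetlands$wetland, stage = 1L,
                      ai_t = emission_t * wetlands$area_km2 / sum(wetlands$area_km2))
  } else {
    a1 <- wetlands$area_km2[constructed]
    out <- rbind(
      data.frame(wetland = wetlands$wetland[constructed], stage = 1L,
                 ai_t = emission_t * a1 / sum(a1)),
      if (any(!constructed))
        data.frame(wetland = wetlands$wetland[!constructed], stage = 2L,
                   ai_t = NA_real_)
    )
  }
  structure(out, fallback = fallback)
}

#' Removal and mass-balance surplus for one county
#'
#' Applies the predicted removal efficiency to an allocation: each wetland's
#' influent concentration is recomputed from its assigned input via
#' [ai_to_conc()], its ARE predicted, and its removal `AR = AI x ARE`
#' evaluated. For multistage allocations the summed first-stage surplus is
#' split in equal mass shares over the second-stage wetlands before their
#' removal is evaluated. The county surplus is the mass balance
#' `AS = emission - sum(AR)`.
#'
#' @param emission_t County emission (t/yr).
#' @param wetlands County wetlands table (as in [allocate()]).
#' @param allocation Result of [allocate()].
#' @param are ARE predictor: a `function(features df) -> fraction` or a
#'   fitted [are_model()].
#' @param hlr_m_day Hydraulic loading rate for the concentration model.
#' @return list of class `allocation_result`: `wetlands` (per-wetland `stage`,
#'   `ai_t`, `conc_ug_l`, `are`, `ar_t`), `emission_t`, `removal_t`,
#'   `surplus_t`.
#' @export
removal_and_surplus <- function(emission_t, wetlands, allocation, are,
                                hlr_m_day = 0.05) {
  fun <- are_predictor(are)
  if (nrow(allocation) == 0) {
    return(structure(list(wetlands = cbind(allocation,
                                           data.frame(conc_ug_l = numeric(),
                                                      are = numeric(),
                                                      ar_t = numeric())),
                          emission_t = emission_t, removal_t = 0,
                          surplus_t = emission_t),
                     class = "allocation_result"))
  }
  w <- wetlands[match(allocation$wetland, wetlands$wetland), , drop = FALSE]
  out <- allocation
  out$conc_ug_l <- out$are <- out$ar_t <- NA_real_
  eval_stage <- function(rows) {
    feats <- w[rows, , drop = FALSE]
    feats$antibiotic_conc <- ai_to_conc(out$ai_t[rows], feats$area_km2, hlr_m_day)
    list(conc = feats$antibiotic_conc, are = fun(feats))
  }
  s1 <- which(out$stage == 1L)
  e1 <- eval_stage(s1)
  out$conc_ug_l[s1] <- e1$conc
  out$are[s1] <- e1$are
  out$ar_t <- out$ai_t * out$are
  s2 <- which(out$stage == 2L)
  if (length(s2)) {
    surplus1 <- max(emission_t - sum(out$ar_t[s1]), 0)
    out$ai_t[s2] <- surplus1 / length(s2)
    e2 <- eval_stage(s2)
    out$conc_ug_l[s2] <- e2$conc
    out$are[s2] <- e2$are
    out$ar_t[s2] <- out$ai_t[s2] * out$are[s2]
  }
  removal <- sum(out$ar_t)
  structure(list(wetlands = out, emission_t = emission_t,
                 removal_t = removal, surplus_t = emission_t - removal),
            class = "allocation_result")
}

#' @export
print.allocation_result <- function(x, ...) {
  cat(sprintf("Allocation: emission %.3g t, removal %.3g t, surplus %.3g t (%d wetlands)\n",
              x$emission_t, x$removal_t, x$surplus_t, nrow(x$wetlands)))
  invisible(x)
}

#' Regional risk assessment
#'
#' Propagates every county's emission through its wetland inventory under one
#' management mode, computes each wetland's surplus concentration (Eq.
#' `c_surp = c x (1 - ARE)`, ng/L), the cask-effect risk quotient
#' [rq_total()], risk bands, county mass balances and the high-risk county
#' area [hra()].
#'
#' @param region A [gen_region()] state.
#' @param mode `"NM"` or `"IM"`.
#' @param are ARE predictor (see [removal_and_surplus()]).
#' @param hlr_m_day Hydraulic loading rate (m/d).
#' @param include_reservoirs Count reservoirs as natural-class wetlands for
#'   the HRA definition, default TRUE.
#' @return list of class `risk_assessment`: `wetlands` (per-wetland results
#'   incl. `rq`, `band`), `counties` (per-county `removal_t`, `surplus_t`,
#'   `high_risk`), `totals` (emission, removal, surplus, `hra_km2`, band
#'   counts), `mode`.
#' @export
assess_region <- function(region, mode = c("NM", "IM"), are,
                          hlr_m_day = 0.05, include_reservoirs = TRUE) {
  mode <- match.arg(mode)
  fun <- are_predictor(are)
  co <- region$counties
  wl <- region$wetlands
  n_ab <- nrow(region$inventory)
  pn <- pnec_min(region$inventory)

  # stage-1 assignment, vectorised across counties
  wl$emission_t <- co$emission_t[match(wl$county, co$county)]
  constructed <- wl$class %in% CONSTRUCTED_CLASSES
  has_constructed <- tapply(constructed, wl$county, any)
  single_stage <- as.vector(mode == "NM" | !has_constructed[wl$county])
  stage1 <- single_stage | constructed
  denom_area <- ifelse(single_stage,
                       stats::ave(wl$area_km2, wl$county, FUN = sum),
                       stats::ave(wl$area_km2 * constructed, wl$county, FUN = sum))
  wl$stage <- ifelse(stage1, 1L, 2L)
  wl$ai_t <- ifelse(stage1, wl$emission_t * wl$area_km2 / denom_area, NA_real_)

  eval_rows <- function(rows) {
    feats <- wl[rows, , drop = FALSE]
    feats$antibiotic_conc <- ai_to_conc(wl$ai_t[rows], feats$area_km2, hlr_m_day)
    list(conc = feats$antibiotic_conc, are = fun(feats))
  }
  wl$conc_ug_l <- wl$are <- wl$ar_t <- NA_real_
  s1 <- which(stage1)
  if (length(s1)) {
    e1 <- eval_rows(s1)
    wl$conc_ug_l[s1] <- e1$conc; wl$are[s1] <- e1$are
    wl$ar_t[s1] <- wl$ai_t[s1] * wl$are[s1]
  }
  s2 <- which(!stage1)
  if (length(s2)) {
    ar1_by_cty <- tapply(wl$ar_t[s1], wl$county[s1], sum)
    m_by_cty <- table(wl$county[s2])
    surplus1 <- pmax(co$emission_t[match(names(m_by_cty), co$county)] -
                       as.numeric(ar1_by_cty[names(m_by_cty)]), 0)
    share <- surplus1 / as.numeric(m_by_cty)
    wl$ai_t[s2] <- share[match(wl$county[s2], names(m_by_cty))]
    e2 <- eval_rows(s2)
    wl$conc_ug_l[s2] <- e2$conc; wl$are[s2] <- e2$are
    wl$ar_t[s2] <- wl$ai_t[s2] * wl$are[s2]
  }
  wl$c_surp_ng_l <- conc_surplus(wl$conc_ug_l * 1000, wl$are)
  wl$rq <- rq_total(wl$c_surp_ng_l, n_ab, pn)
  wl$band <- classify_risk(wl$rq)

  removal <- tapply(wl$ar_t, factor(wl$county, levels = co$county), sum,
                    default = 0)
  removal[is.na(removal)] <- 0
  natural_set <- if (include_reservoirs) NATURAL_CLASSES else "natural"
  hi_nat <- wl$band == "high" & wl$class %in% natural_set
  high_by_cty <- tapply(hi_nat, factor(wl$county, levels = co$county), any,
                        default = FALSE)
  high_by_cty[is.na(high_by_cty)] <- FALSE
  counties <- data.frame(
    county = co$county, area_km2 = co$area_km2, emission_t = co$emission_t,
    removal_t = as.numeric(removal),
    surplus_t = co$emission_t - as.numeric(removal),
    high_risk = as.logical(high_by_cty), stringsAsFactors = FALSE
  )
  totals <- list(
    emission_t = sum(co$emission_t), removal_t = sum(counties$removal_t),
    surplus_t = sum(counties$surplus_t),
    hra_km2 = sum(counties$area_km2[counties$high_risk]),
    band_counts = table(wl$band)
  )
  structure(list(wetlands = wl, counties = counties, totals = totals,
                 mode = mode, include_reservoirs = include_reservoirs),
            class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  t <- x$totals
  cat(sprintf("Risk assessment (%s): emission %.2f t, removal %.2f t (%.1f%%), surplus %.2f t\n",
              x$mode, t$emission_t, t$removal_t, 100 * t$removal_t / t$emission_t,
              t$surplus_t))
  cat(sprintf("  high-risk county area: %.0f km2 (%d of %d counties)\n",
              t$hra_km2, sum(x$counties$high_risk), nrow(x$counties)))
  invisible(x)
}

#' High-risk county area
#'
#' Total land area of counties containing at least one high-risk (RQ > 1)
#' natural-class wetland. By default reservoirs count as natural-class.
#'
#' @param assessment A [assess_region()] result.
#' @param include_reservoirs Override the assessment's reservoir rule.
#' @return Area in km2.
#' @export
hra <- function(assessment, include_reservoirs = NULL) {
  stopifnot(inherits(assessment, "risk_assessment"))
  if (is.null(include_reservoirs))
    return(sum(assessment$counties$area_km2[assessment$counties$high_risk]))
  natural_set <- if (include_reservoirs) NATURAL_CLASSES else "natural"
  wl <- assessment$wetlands
  hi <- wl$band == "high" & wl$class %in% natural_set
  cty <- unique(wl$county[hi])
  sum(assessment$counties$area_km2[assessment$counties$county %in% cty])
}
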