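#' Generate a synthetic wetland-antibiotics experiment table
#'
#' Emulates a literature-compiled dataset of wetland antibiotic-removal
#' trials: 16 numeric and 3 categorical features per trial plus a mean
#' removal-efficiency target (`are`, percent). The target is the noiseless
#' response surface [are_truth()] plus Gaussian noise, clipped to
#' \[0, 100\]. Missing values are inserted completely at random into numeric
#' feature cells only, never into the target or the categoricals.
#'
#' @param n Number of trials (>= 10).
#' @param seed Integer seed; identical arguments reproduce the table exactly.
#' @param missing_rate Fraction of numeric feature cells set to `NA`
#'   (0 <= rate < 0.5).
#' @param noise_sd Standard deviation of the additive ARE noise
#'   (percentage points). Default 8.
#' @return data.frame with 19 feature columns and an `are` column.
#' @export
#' @examples
#' x <- gen_experiments(337, seed = 1, missing_rate = 0.1)
#' dim(x)
#' mean(is.na(x))
gen_experiments <- function(n, seed, missing_rate = 0.1, noise_sd = 8) {
  if (n < 10) stopf("n must be >= 10 (got %d)", n)
  if (missing_rate < 0 || missing_rate >= 0.5)
    stopf("missing_rate must be in [0, 0.5) (got %g)", missing_rate)
  set.seed(derive_seed(seed, 11))
  df <- sample_features(n)
  df$are <- clip_pct(are_truth(df) + stats::rnorm(n, 0, noise_sd))
  if (missing_rate > 0) {
    num <- default_schema()$name[default_schema()$kind == "numeric"]
    cells <- expand.grid(row = seq_len(n), col = num, stringsAsFactors = FALSE)
    hit <- stats::runif(nrow(cells)) < missing_rate
    for (k in which(hit)) df[cells$row[k], cells$col[k]] <- NA
  }
  df
}

#' Generate an independent validation table
#'
#' Complete (no missing cells) trials drawn from the same response surface as
#' [gen_experiments()] but from a disjoint random stream, so rows never
#' coincide with a training table generated from any seed.
#'
#' @inheritParams gen_experiments
#' @return data.frame as in [gen_experiments()] with no `NA`s.
#' @export
gen_independent_validation <- function(n, seed, noise_sd = 8) {
  gen_experiments(n, derive_seed(seed, 777777), missing_rate = 0,
                  noise_sd = noise_sd)
}

#' Generate a synthetic antibiotic inventory
#'
#' Per-antibiotic emission shares (Dirichlet-distributed, summing to 1) and
#' predicted no-effect concentrations for algae (PNEC, ng/L). The smallest
#' PNEC is pinned at `pnec_min` (default 3 ng/L, the tiamulin-like most
#' sensitive entry that drives the cask-effect risk quotient); all other
#' entries are drawn log-normally above 5 ng/L.
#'
#' @param n_antibiotics Number of antibiotic types (>= 1). Default 80.
#' @param seed Integer seed.
#' @param pnec_min Minimum PNEC in the inventory (ng/L), default 3.
#' @return data.frame of class `antibiotic_inventory` with columns `name`,
#'   `pnec_ng_l`, `share`.
#' @export
#' @examples
#' inv <- gen_inventory(80, seed = 1)
#' min(inv$pnec_ng_l)
gen_inventory <- function(n_antibiotics = 80, seed = 1, pnec_min = 3) {
  if (n_antibiotics < 1) stopf("n_antibiotics must be >= 1")
  if (pnec_min <= 0) stopf("pnec_min must be > 0")
  set.seed(derive_seed(seed, 23))
  share <- stats::rgamma(n_antibiotics, shape = 0.8)
  share <- share / sum(share)
  pnec <- pmax(exp(stats::rnorm(n_antibiotics, log(300), 1)), 5)
  pnec[which.min(pnec)] <- pnec_min
  inv <- data.frame(
    name = sprintf("AB%03d", seq_len(n_antibiotics)),
    pnec_ng_l = pnec, share = share, stringsAsFactors = FALSE
  )
  class(inv) <- c("antibiotic_inventory", "data.frame")
  inv
}

#' Minimum PNEC of an inventory
#' @param inventory An [gen_inventory()] table.
#' @return Smallest PNEC (ng/L).
#' @export
pnec_min <- function(inventory) min(inventory$pnec_ng_l)

#' Generate a synthetic regional state
#'
#' Abstract counties with land areas, heavy-tailed (log-normal) annual
#' antibiotic emission masses, and 0 to `max_wetlands` wetlands each
#' (classes: natural, reservoir, constructed, CPW) with positive areas and
#' per-wetland feature attributes drawn within the experiment feature
#' ranges. A Gaussian-copula knob (`mismatch_rho`) sets the correlation
#' between county emissions and wetland abundance; the weak default mimics
#' the spatial disconnect between antibiotic sources and wetland resources.
#'
#' @param n_counties Number of counties (>= 1).
#' @param seed Integer seed.
#' @param n_antibiotics Inventory size, default 80.
#' @param max_wetlands Upper bound on wetlands per county, default 6.
#' @param pnec_min Inventory minimum PNEC (ng/L), default 3.
#' @param emission_meanlog,emission_sdlog Log-normal parameters of county
#'   emissions (t/yr). Defaults log(2.5) and 1.5, calibrated so baseline
#'   county risk quotients span all risk bands.
#' @param mismatch_rho Copula correlation between emissions and wetland
#'   abundance, default 0.2 (weak).
#' @return list of class `wet_region` with elements `counties` (id, area_km2,
#'   emission_t), `wetlands` (id, county, class, area_km2 + feature columns),
#'   and `inventory`.
#' @export
#' @examples
#' r <- gen_region(10, seed = 1)
#' nrow(r$counties)
gen_region <- function(n_counties, seed, n_antibiotics = 80,
                       max_wetlands = 6, pnec_min = 3,
                       emission_meanlog = log(2.5), emission_sdlog = 1.5,
                       mismatch_rho = 0.2) {
  if (n_counties < 1) stopf("n_counties must be >= 1")
  if (n_antibiotics < 1) stopf("n_antibiotics must be >= 1")
  inventory <- gen_inventory(n_antibiotics, seed, pnec_min)
  set.seed(derive_seed(seed, 37))
  z_e <- stats::rnorm(n_counties)
  z_w <- mismatch_rho * z_e + sqrt(1 - mismatch_rho^2) * stats::rnorm(n_counties)
  counties <- data.frame(
    county = sprintf("C%04d", seq_len(n_counties)),
    area_km2 = exp(stats::rnorm(n_counties, log(2000), 0.5)),
    emission_t = exp(emission_meanlog + emission_sdlog * z_e),
    stringsAsFactors = FALSE
  )
  n_w <- pmin(stats::rpois(n_counties, exp(0.4 * z_w + log(3))), max_wetlands)
  total_w <- sum(n_w)
  classes <- c("natural", "reservoir", "constructed", "CPW")
  wet <- if (total_w > 0) {
    w <- sample_features(total_w)
    w$area_km2 <- pmin(pmax(exp(stats::rnorm(total_w, log(20), 0.7)), 0.5), 200)
    # keep the trial-scale area feature consistent with the physical area
    w$wetland_area <- w$area_km2 * 1e6
    w$class <- sample(classes, total_w, TRUE, prob = c(0.4, 0.2, 0.3, 0.1))
    w$county <- rep(counties$county, n_w)
    w$wetland <- sprintf("W%05d", seq_len(total_w))
    w[, c("wetland", "county", "class", "area_km2",
          setdiff(names(w), c("wetland", "county", "class", "area_km2")))]
  } else {
    cbind(data.frame(wetland = character(), county = character(),
                     class = character(), area_km2 = numeric()),
          sample_features(0))
  }
  structure(list(counties = counties, wetlands = wet, inventory = inventory),
            class = "wet_region")
}

#' @export
print.wet_region <- function(x, ...) {
  cat(sprintf("Synthetic region: %d counties, %d wetlands, %d antibiotics\n",
              nrow(x$counties), nrow(x$wetlands), nrow(x$inventory)))
  cat(sprintf("Total emission %.2f t/yr; wetland area %.1f km2; min PNEC %g ng/L\n",
              sum(x$counties$emission_t), sum(x$wetlands$area_km2),
              pnec_min(x$inventory)))
  invisible(x)
}

#' Write / read a regional state as plain-text files
#'
#' One CSV per entity (`counties.csv`, `emissions.csv`, `wetlands.csv`,
#' `pnec.csv`) plus a JSON manifest.
#'
#' @param region A [gen_region()] object.
#' @param dir Output directory (created if absent).
#' @param manifest Named list stored in `manifest.json` (e.g. seed, config).
#' @return `dir`, invisibly.
#' @export
write_region <- function(region, dir, manifest = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(region$counties[, c("county", "area_km2")],
                   file.path(dir, "counties.csv"), row.names = FALSE)
  utils::write.csv(region$counties[, c("county", "emission_t")],
                   file.path(dir, "emissions.csv"), row.names = FALSE)
  utils::write.csv(region$wetlands, file.path(dir, "wetlands.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(region$inventory),
                   file.path(dir, "pnec.csv"), row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_region
#' @export
read_region <- function(dir) {
  co <- utils::read.csv(file.path(dir, "counties.csv"), stringsAsFactors = FALSE)
  em <- utils::read.csv(file.path(dir, "emissions.csv"), stringsAsFactors = FALSE)
  counties <- merge(co, em, by = "county", sort = FALSE)
  wet <- utils::read.csv(file.path(dir, "wetlands.csv"), stringsAsFactors = FALSE)
  lv <- feature_levels()
  for (nm in names(lv)) if (nm %in% names(wet))
    wet[[nm]] <- factor(wet[[nm]], levels = lv[[nm]])
  inv <- utils::read.csv(file.path(dir, "pnec.csv"), stringsAsFactors = FALSE)
  class(inv) <- c("antibiotic_inventory", "data.frame")
  structure(list(counties = counties, wetlands = wet, inventory = inv),
            class = "wet_region")
}
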