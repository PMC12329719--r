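# Shared fixtures, built once per test run. The canonical modelling fixture is
# the complete-data experiment table (n = 337, noise sd 8, seed 1); the
# canonical region has 40 counties (seed 3).
.fixtures <- new.env()

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

fixture_experiments <- function() {
  memo("experiments", gen_experiments(337, seed = 1, missing_rate = 0))
}

fixture_model <- function() {
  memo("model", are_model(are ~ ., fixture_experiments(), B = 100, seed = 1))
}

fixture_region <- function() memo("region", gen_region(40, seed = 3))

# Deterministic removal-efficiency predictor (noiseless truth, as a fraction).
truth_frac <- function(df) are_truth(df) / 100

# A single-county wetland table with given classes and areas; other feature
# attributes are drawn but irrelevant to predictors that only read
# antibiotic_conc and area.
toy_county <- function(classes, areas, seed = 1) {
  set.seed(seed)
  w <- wetrisk:::sample_features(length(classes))
  w$area_km2 <- areas
  w$class <- classes
  w$wetland <- sprintf("w%d", seq_along(classes))
  w
}

# Monotone non-increasing removal responses with positive floors, used by the
# allocation-dominance enumeration.
floor_are_funs <- function() {
  out <- list()
  for (p in list(c(0.15, 0.9), c(0.3, 0.7), c(0.1, 0.5)))
    for (ch in c(5, 20, 80))
      out[[length(out) + 1]] <- local({
        lo <- p[1]; hi <- p[2]; cc <- ch
        function(df) lo + (hi - lo) * exp(-df$antibiotic_conc / cc)
      })
  out
}
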