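#' Default pipeline configuration
#'
#' All knobs of the end-to-end run, fanned out from one global seed into
#' per-stage streams. The defaults are the study conditions the synthetic
#' fixture emulates: a 337-trial experiment table with 10% missing numeric
#' cells and noise sd 8 ARE points, five model families compared by 5-fold
#' CV, a 100-member bootstrap ensemble, an 80-antibiotic inventory with
#' minimum PNEC 3 ng/L, and the full 18-scenario 2021-2035 grid.
#'
#' @param seed Global seed.
#' @return Named list (fully JSON-serialisable).
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    experiments = list(n = 337, missing_rate = 0.1, noise_sd = 8),
    validation_n = 40,
    model = list(families = ARE_FAMILIES, search = c("grid", "random", "bayes"),
                 B = 100, train_frac = 0.8, nfolds = 5),
    region = list(n_counties = 40, n_antibiotics = 80, pnec_min = 3,
                  hlr_m_day = 0.05),
    scenarios = list(members = 10, years = c(2021, 2035), rate_km2 = 180),
    interpret = list(repeats = 10),
    schema_version = "1.0"
  )
}

#' Run the full analysis pipeline
#'
#' Generate -> prepare/fit -> assess (NM and IM) -> scenarios -> interpret.
#' Writes per-stage CSV artifacts and one machine-readable `summary.json`
#' (schema-versioned, free of timestamps so identical configs give
#' byte-identical summaries) under `out_dir`.
#'
#' @param config A [default_config()]-style list.
#' @param out_dir Output directory; default a fresh temporary directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the run `summary`, the fitted `model`,
#'   `region`, baseline assessments, `projections`, `contributions` and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("wetrisk_"),
                         quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  seed <- config$seed

  say("[synthgen] generating experiments and region")
  experiments <- stage("synthgen", gen_experiments(
    config$experiments$n, seed = derive_seed(seed, 1),
    missing_rate = config$experiments$missing_rate,
    noise_sd = config$experiments$noise_sd))
  independent <- stage("synthgen", gen_independent_validation(
    config$validation_n, seed = derive_seed(seed, 2),
    noise_sd = config$experiments$noise_sd))
  region <- stage("synthgen", gen_region(
    config$region$n_counties, seed = derive_seed(seed, 3),
    n_antibiotics = config$region$n_antibiotics,
    pnec_min = config$region$pnec_min))
  utils::write.csv(experiments, file.path(out_dir, "experiments.csv"),
                   row.names = FALSE)
  write_region(region, file.path(out_dir, "region"),
               manifest = list(seed = seed, config = config$region))

  say("[prep/aremodel] fitting %d family(ies) x %d search method(s)",
      length(config$model$families), length(config$model$search))
  model <- stage("aremodel", are_model(
    are ~ ., experiments, families = config$model$families,
    search = config$model$search, B = config$model$B,
    train_frac = config$model$train_frac, nfolds = config$model$nfolds,
    seed = derive_seed(seed, 4)))
  ext <- stage("aremodel", validate_external(model, independent))
  shuffle <- stage("aremodel", validate_shuffle(model, model$split$test,
                                                seed = derive_seed(seed, 5)))

  say("[regional] baseline NM and IM assessment")
  nm <- stage("regional", assess_region(region, "NM", model,
                                        hlr_m_day = config$region$hlr_m_day))
  im <- stage("regional", assess_region(region, "IM", model,
                                        hlr_m_day = config$region$hlr_m_day))
  utils::write.csv(nm$counties, file.path(out_dir, "assessment_nm.csv"),
                   row.names = FALSE)
  utils::write.csv(im$counties, file.path(out_dir, "assessment_im.csv"),
                   row.names = FALSE)

  say("[scenarios] projecting the 18-scenario grid")
  years <- seq(config$scenarios$years[1], config$scenarios$years[2])
  projections <- stage("scenarios", project_grid(
    region, model, seed = derive_seed(seed, 6),
    members = config$scenarios$members, years = years,
    hlr_m_day = config$region$hlr_m_day,
    rate_km2 = config$scenarios$rate_km2))
  for (id in names(projections))
    utils::write.csv(as.data.frame(projections[[id]]),
                     file.path(out_dir, sprintf("scenario_%s.csv", id)),
                     row.names = FALSE)
  contributions <- stage("scenarios", contribution_analysis(projections))

  say("[interpret] attributions and permutation importance")
  attribution <- stage("interpret", attribute(model, seed = derive_seed(seed, 7)))
  shares <- stage("interpret", category_shares(attribution, model$schema))
  importance <- stage("interpret", permutation_importance(
    model, repeats = config$interpret$repeats, seed = derive_seed(seed, 8)))
  utils::write.csv(data.frame(feature = colnames(attribution$phi),
                              mean_abs_shap = attribution$mean_abs),
                   file.path(out_dir, "shap_importance.csv"), row.names = FALSE)
  utils::write.csv(importance, file.path(out_dir, "permutation_importance.csv"),
                   row.names = FALSE)

  summary <- list(
    schema_version = config$schema_version,
    seed = seed,
    n_experiments = nrow(experiments),
    model = model$metrics,
    candidates = attr(model$best, "selection_report"),
    external_validation = list(mean_error = ext$mean_error,
                               max_error = ext$max_error),
    shuffle_top = shuffle[order(-shuffle$delta_r2), ][1:5, ],
    baseline = list(
      emission_t = nm$totals$emission_t,
      nm = list(removal_t = nm$totals$removal_t,
                surplus_t = nm$totals$surplus_t, hra_km2 = nm$totals$hra_km2),
      im = list(removal_t = im$totals$removal_t,
                surplus_t = im$totals$surplus_t, hra_km2 = im$totals$hra_km2)
    ),
    hra_final_year = vapply(projections, function(p) p$hra[nrow(p)], numeric(1)),
    contributions = contributions$paired,
    category_shares = as.list(shares),
    rank_agreement = rank_agreement(attribution, importance)
  )
  validate_summary(summary)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  say("done: %s", out_dir)
  invisible(list(summary = summary, model = model, region = region,
                 experiments = experiments, nm = nm, im = im,
                 projections = projections, contributions = contributions,
                 attribution = attribution, importance = importance,
                 out_dir = out_dir))
}

# Minimal schema check on write: required top-level fields present and typed.
validate_summary <- function(s) {
  need <- c("schema_version", "seed", "model", "baseline", "hra_final_year",
            "contributions", "category_shares")
  miss <- setdiff(need, names(s))
  if (length(miss)) stopf("summary schema violation, missing: %s",
                          paste(miss, collapse = ", "))
  if (!is.numeric(s$model$test_r2)) stopf("summary schema violation: model.test_r2")
  invisible(TRUE)
}
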