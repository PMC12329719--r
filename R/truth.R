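#' Default feature schema for wetland antibiotic-removal experiments
#'
#' Sixteen numeric and three categorical features describing one wetland
#' trial, each assigned to one of four interpretation groups: water quality
#' properties, artificial configuration parameters, hydraulic conditions and
#' temperature, and wetland construction characteristics. The target column
#' (mean antibiotic removal efficiency, percent) is named `are`.
#'
#' @return A data.frame with columns `name`, `kind` ("numeric" or
#'   "categorical") and `group`.
#' @export
#' @examples
#' s <- default_schema()
#' table(s$kind)
default_schema <- function() {
  data.frame(
    name = c(
      "antibiotic_conc", "tetracycline_pct", "ph", "nh4_n", "cod", "tn",
      "tp", "do",
      "planting_density", "water_depth", "aspect_ratio",
      "hrt", "hlr", "influent_flow", "temperature",
      "wetland_area",
      "modified_substrate", "aeration", "structural_type"
    ),
    kind = c(rep("numeric", 16), rep("categorical", 3)),
    group = c(
      rep("water_quality", 8),
      rep("artificial_config", 3),
      rep("hydraulic_temp", 4),
      "construction",
      "artificial_config", "artificial_config", "construction"
    ),
    stringsAsFactors = FALSE
  )
}

# Sampling ranges for each numeric feature (units in comments) and level sets
# for the categoricals. Log-uniform sampling for quantities spanning decades.
feature_ranges <- function() {
  list(
    antibiotic_conc  = list(min = 0.1, max = 1000, log = TRUE),   # ug/L
    tetracycline_pct = list(min = 0, max = 100, log = FALSE),     # % of load
    ph               = list(min = 5.5, max = 9.5, log = FALSE),
    nh4_n            = list(min = 0.1, max = 60, log = FALSE),    # mg/L
    cod              = list(min = 5, max = 600, log = FALSE),     # mg/L
    tn               = list(min = 1, max = 80, log = FALSE),      # mg/L
    tp               = list(min = 0.1, max = 15, log = FALSE),    # mg/L
    do               = list(min = 0.5, max = 12, log = FALSE),    # mg/L
    planting_density = list(min = 0, max = 150, log = FALSE),     # plants/m2
    water_depth      = list(min = 0.1, max = 2, log = FALSE),     # m
    aspect_ratio     = list(min = 1, max = 20, log = FALSE),
    hrt              = list(min = 0.1, max = 30, log = TRUE),     # d
    hlr              = list(min = 0.01, max = 1, log = TRUE),     # m/d
    influent_flow    = list(min = 0.1, max = 1e4, log = TRUE),    # m3/d
    temperature      = list(min = 5, max = 35, log = FALSE),      # degC
    wetland_area     = list(min = 1, max = 1e6, log = TRUE)       # m2
  )
}

feature_levels <- function() {
  list(
    modified_substrate = c("no", "yes"),
    aeration = c("no", "yes"),
    structural_type = c("surface", "subsurface", "hybrid", "pond")
  )
}

#' Noiseless removal-efficiency response surface
#'
#' Deterministic expected ARE (percent) given a table of trial features.
#' Encodes the qualitative relationships the field reports for treatment
#' wetlands: removal falls monotonically with influent antibiotic
#' concentration; rises with planting density but saturates above 100
#' plants/m2; is unimodal in pH (optimum band 7.2-8) and temperature
#' (optimum 25-30 C); rises with NH4+-N and COD at the low end (nutrient
#' supply for the microbial community); rises with the tetracycline share of
#' the load (photodegradable class); rises with hydraulic retention time
#' (saturating above 10 d) and falls with hydraulic loading rate; has small
#' positive TN and DO effects; modified substrate and hybrid or subsurface
#' structures carry positive offsets. Total phosphorus, aspect ratio, water
#' depth, influent flow and wetland area are deliberately inert (pure-noise
#' features). Output clipped to [0, 100].
#'
#' @param df data.frame with the feature columns of [default_schema()].
#' @return Numeric vector of expected ARE (percent).
#' @export
#' @examples
#' x <- gen_experiments(20, seed = 1, missing_rate = 0)
#' range(are_truth(x))
are_truth <- function(df) {
  struct_offset <- c(surface = 0, subsurface = 10.5, hybrid = 13.5, pond = -4.5)
  y <- -5 -
    52 * (1 - exp(-df$antibiotic_conc / 150)) +
    21 * df$tetracycline_pct / 100 +
    18 * exp(-((df$ph - 7.6) / 0.9)^2) +
    18 * exp(-((df$temperature - 27.5) / 5)^2) +
    12 * pmin(df$nh4_n, 30) / 30 +
    12 * pmin(df$cod, 300) / 300 +
    27 * pmin(df$planting_density, 100) / 100 +
    15 * pmin(df$hrt, 10) / 10 -
    6 * (log10(df$hlr) + 1) +
    6 * pmin(df$tn, 40) / 40 +
    6 * pmin(df$do, 8) / 8 +
    18 * (as.character(df$modified_substrate) == "yes") +
    struct_offset[as.character(df$structural_type)] +
    4.5 * (as.character(df$aeration) == "yes")
  unname(clip_pct(y))
}

# Draw n feature vectors uniformly (log-uniform where flagged) within the
# schema ranges. Returns a data.frame with factor categoricals.
sample_features <- function(n) {
  rng <- feature_ranges()
  out <- lapply(rng, function(r) {
    if (r$log) exp(stats::runif(n, log(r$min), log(r$max)))
    else stats::runif(n, r$min, r$max)
  })
  out <- as.data.frame(out)
  lv <- feature_levels()
  out$modified_substrate <- factor(sample(lv$modified_substrate, n, TRUE,
                                          prob = c(0.6, 0.4)),
                                   levels = lv$modified_substrate)
  out$aeration <- factor(sample(lv$aeration, n, TRUE, prob = c(0.7, 0.3)),
                         levels = lv$aeration)
  out$structural_type <- factor(sample(lv$structural_type, n, TRUE,
                                       prob = c(0.35, 0.35, 0.15, 0.15)),
                                levels = lv$structural_type)
  out[, default_schema()$name]
}
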