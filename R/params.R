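#' @keywords internal
"_PACKAGE"

# Layer order used throughout: total retina first, then inner-to-outer
# individual layers, then the two aggregate layers.
pp_layer_names <- c("Retina", "RNFL", "GCL", "IPL", "INL",
                    "OPL", "ONL", "RPE", "IRL", "ORL")

pp_sector_names <- c("PMB", "TI", "T", "TS", "NI", "N", "NS", "G")

#' Reference posterior-pole layer thickness distributions
#'
#' Group means and standard deviations (micrometres) of the ten
#' posterior-pole retinal layer thicknesses reported for ADOA patients and
#' healthy controls, used as the marginal distributions of the synthetic
#' cohort generator.
#'
#' @return A data.frame with one row per layer and columns `layer`,
#'   `mean_ADOA`, `sd_ADOA`, `mean_control`, `sd_control`.
#' @keywords internal
pp_layer_table <- function() {
  data.frame(
    layer        = pp_layer_names,
    mean_ADOA    = c(262.76, 22.77, 21.45, 18.92, 30.88,
                     26.40, 60.50, 13.70, 183.80, 78.50),
    sd_ADOA      = c(24.29, 13.61, 4.662, 4.68, 6.52,
                     3.80, 12.20, 3.20, 51.27, 3.81),
    mean_control = c(299.46, 42.24, 33.61, 27.86, 32.01,
                     25.70, 58.10, 13.90, 219.97, 79.35),
    sd_control   = c(34.53, 28.15, 10.41, 9.82, 5.27,
                     3.20, 10.40, 2.02, 33.09, 5.12),
    stringsAsFactors = FALSE
  )
}

#' Reference peripapillary RNFL sector distributions
#'
#' Group means and standard deviations (micrometres) of the eight
#' peripapillary RNFL sectors (papillo-macular bundle, temporal-inferior,
#' temporal, temporal-superior, nasal-inferior, nasal, nasal-superior,
#' global). The nasal-to-temporal ratio is derived per record, not drawn.
#'
#' @return A data.frame with one row per sector.
#' @keywords internal
pp_sector_table <- function() {
  data.frame(
    sector       = pp_sector_names,
    mean_ADOA    = c(20.22, 92.38, 27.00, 67.67, 73.00, 55.28, 82.50, 60.06),
    sd_ADOA      = c(6.025, 19.01, 5.77, 18.62, 12.99, 10.72, 18.83, 8.46),
    mean_control = c(51.8, 143.2, 66.8, 137.3, 117.1, 76.6, 107.6, 99.0),
    sd_control   = c(5.5, 13.0, 5.4, 19.5, 24.3, 17.9, 28.3, 12.4),
    stringsAsFactors = FALSE
  )
}

# 64-point differential light sensitivity reference maps (dB).
# Row-major storage: row 1 (superior) first, column 1 (nasal) first, i.e.
# the layout of the published 8x8 sensitivity tables with margins
# N (left), S (top), T (right), I (bottom) in right-eye orientation.
pp_point_means_adoa <- c(
  11.45, 12.23, 14.18, 15.23, 14.18, 14.41, 13.77, 12.64,
  12.64, 14.05, 14.82, 16.23, 15.32, 15.50, 14.86, 14.68,
  13.18, 14.68, 15.50, 15.41, 16.82, 17.41, 15.64, 15.05,
  12.27, 14.32, 15.41, 14.86, 15.41, 17.41, 16.64, 16.41,
   6.22, 11.32, 12.28, 11.23, 16.64, 16.91, 17.36, 16.00,
   9.40,  9.54, 11.50, 12.50, 15.23, 16.45, 15.68, 14.77,
   9.09, 10.82, 12.82, 12.00, 14.73, 14.73, 15.50, 14.23,
   8.54, 10.23, 10.00, 11.68, 12.86, 13.64, 12.68, 12.45)

pp_point_sds_adoa <- c(
  3.44, 3.07, 3.11, 2.32, 2.95, 1.65, 2.63, 4.46,
  4.16, 3.69, 3.67, 3.61, 4.45, 3.73, 3.28, 3.10,
  4.15, 4.47, 5.44, 6.13, 2.42, 3.94, 4.35, 4.20,
  4.69, 5.82, 4.95, 5.31, 5.22, 4.81, 3.30, 2.26,
  6.69, 6.29, 6.78, 8.92, 4.81, 4.23, 3.09, 3.13,
  6.63, 7.20, 7.20, 7.54, 5.84, 5.16, 3.16, 3.81,
  6.42, 7.06, 6.65, 6.90, 5.47, 4.78, 4.24, 3.66,
  6.82, 6.41, 5.36, 6.38, 5.72, 4.08, 5.05, 3.66)

pp_point_means_control <- c(
  16.28, 16.06, 16.83, 16.61, 17.78, 17.22, 16.44, 16.67,
  16.61, 17.61, 18.17, 18.44, 18.44, 18.22, 17.33, 18.00,
  17.56, 18.83, 19.67, 19.56, 19.67, 19.67, 19.33, 18.67,
  18.50, 19.56, 19.89, 19.67, 19.89, 19.89, 19.67, 19.67,
  18.89, 19.89, 19.89, 19.89, 20.00, 20.00, 19.56, 19.56,
  18.78, 19.44, 19.78, 20.00, 19.78, 19.78, 19.78, 19.22,
  17.67, 19.00, 19.61, 20.00, 20.00, 19.89, 19.78, 19.78,
  17.39, 18.50, 19.00, 19.67, 19.56, 18.44, 19.33, 19.56)

pp_point_sds_control <- c(
  2.95, 2.34, 2.12, 1.91, 2.16, 2.18, 2.62, 2.47,
  2.25, 2.15, 1.54, 1.62, 1.62, 1.80, 1.68, 2.28,
  2.12, 1.54, 0.77, 0.86, 0.77, 0.77, 1.68, 1.68,
  1.38, 0.86, 0.47, 1.03, 0.47, 0.47, 0.77, 0.77,
  1.57, 0.47, 0.47, 0.47, 0.00, 0.00, 0.86, 1.29,
  1.40, 0.92, 0.65, 0.00, 0.65, 0.65, 0.65, 1.70,
  2.40, 1.24, 0.92, 0.00, 0.00, 0.47, 0.65, 0.94,
  1.58, 1.62, 1.41, 1.03, 1.10, 4.20, 1.19, 0.86)

#' Reference 64-point sensitivity distributions
#'
#' Per-point means and standard deviations (dB, 0-20 instrument scale) of
#' the 64-point posterior-pole sensitivity pattern for ADOA and control
#' groups, in row-major right-eye orientation (row 1 superior, column 1
#' nasal).
#'
#' @return A data.frame with 64 rows and columns `point_id` (0-63), `row`,
#'   `col`, `mean_ADOA`, `sd_ADOA`, `mean_control`, `sd_control`.
#' @keywords internal
pp_point_table <- function() {
  data.frame(
    point_id     = 0:63,
    row          = rep(1:8, each = 8),
    col          = rep(1:8, times = 8),
    mean_ADOA    = pp_point_means_adoa,
    sd_ADOA      = pp_point_sds_adoa,
    mean_control = pp_point_means_control,
    sd_control   = pp_point_sds_control,
    stringsAsFactors = FALSE
  )
}

#' Demographic resampling pool for simulated ADOA subjects
#'
#' Clinical and demographic rows (sex, age in years, per-eye visual acuity
#' in logMAR) of the eleven ADOA patients, used as a resampling pool for
#' simulated subject covariates. Covariates never enter the generative
#' model; they exist so downstream partial-correlation interfaces have
#' realistic age/sex columns.
#'
#' @return A data.frame with 11 rows.
#' @keywords internal
pp_demographics <- function() {
  data.frame(
    family  = c("A", "A", "B", "C", "C", "C", "C", "C", "C", "D", "E"),
    patient = 1:11,
    sex     = c("F", "M", "M", "M", "F", "F", "M", "F", "F", "F", "M"),
    age     = c(11, 48, 26, 51, 43, 22, 22, 66, 60, 32, 22),
    bcva_od = c(0.2, 0.0, 0.4, 0.7, 0.1, 0.5, 1.0, 0.1, 0.4, 1.2, 0.5),
    bcva_os = c(0.1, 0.1, 0.4, 0.7, 0.1, 0.5, 0.7, 0.2, 0.4, 1.2, 0.4),
    stringsAsFactors = FALSE
  )
}

#' Default cohort generator parameters
#'
#' Assembles the full parameter set of the synthetic cohort generator: the
#' marginal layer/sector/point distributions, the shared-severity loadings
#' (0.5 everywhere except 0.798 for posterior-pole RNFL and the global
#' peripapillary sector, which fixes their cross-map correlation at 0.798
#' by construction), the spatial jitter of the 64-cell maps, the
#' ganglion-cell-layer (GCL) scotoma link (threshold 23.5 um, logistic
#' slope 1.5 um, calibrated weight), calibrated group sensitivity offsets,
#' fixation dispersion per group, and the 0-20 dB integer instrument scale.
#'
#' The sensitivity offsets `sens_offset` and the scotoma weight
#' `scotoma_weight` are calibrated package constants: they were fitted once
#' with [calibrate_defaults()] so that the generator's expected analysis-eye
#' grand mean sensitivity is 12.86 dB (ADOA) and 18.76 dB (control) and the
#' expected ADOA fraction of 0-dB points is 7.8%. The scotoma threshold is
#' never calibrated, so recovering it by ROC analysis is a genuine test of
#' the analysis code.
#'
#' @param calibrated Logical; if `FALSE` the uncalibrated raw parameters
#'   (zero offsets, scotoma weight 0.1) are returned, e.g. as a starting
#'   point for [calibrate_defaults()].
#' @return An object of class `pp_cohort_params` (a named list).
#' @seealso [generate_cohort()], [calibrate_defaults()]
#' @export
#' @examples
#' p <- default_cohort_params()
#' p$scotoma_threshold
default_cohort_params <- function(calibrated = TRUE) {
  layers <- pp_layer_table()
  layers$loading <- ifelse(layers$layer == "RNFL", 0.798, 0.5)
  sectors <- pp_sector_table()
  sectors$loading <- ifelse(sectors$sector == "G", 0.798, 0.5)
  params <- list(
    layers = layers,
    sectors = sectors,
    points = pp_point_table(),
    sens_loading = 0.5,
    jitter_sd = 5,
    scotoma_threshold = 23.5,
    scotoma_slope = 1.5,
    scotoma_weight = 0.1,
    sens_offset = c(ADOA = 0, control = 0),
    gcl_pattern = TRUE,
    gcl_pattern_sd = 4,
    fixation = list(
      ADOA    = c(sigma_x = 1.2, sigma_y = 0.9, rho = 0.2),
      control = c(sigma_x = 0.4, sigma_y = 0.3, rho = 0.0)
    ),
    fixation_n = 100,
    db_step = 1,
    db_range = c(0, 20),
    demographics = pp_demographics()
  )
  if (calibrated) {
    params$sens_offset <- pp_calibrated_constants$sens_offset
    params$scotoma_weight <- pp_calibrated_constants$scotoma_weight
  }
  class(params) <- "pp_cohort_params"
  validate_params(params)
  params
}

# Calibrated link/offset constants, frozen from a calibrate_defaults() run
# (20000 subjects/group, tolerances 0.01 dB and 0.05 percentage points).
# The control offset mainly compensates the 20-dB ceiling of the instrument
# scale; the ADOA offset reconciles the 64-point reference map with the
# printed grand mean.
pp_calibrated_constants <- list(
  sens_offset = c(ADOA = 0.077364, control = 0.064853),
  scotoma_weight = 0.101175
)

#' Validate a cohort parameter object
#'
#' Checks the structural invariants of a `pp_cohort_params` object: positive
#' (or zero, for the printed point table) SDs, loadings and scotoma weight
#' in `[0, 1]`, a positive scotoma threshold and slope, positive-definite
#' fixation dispersion, and a sane dB range.
#'
#' @param params A `pp_cohort_params` object.
#' @return `params`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "pp_cohort_params"))
  lay <- params$layers
  if (any(lay$sd_ADOA <= 0) || any(lay$sd_control <= 0))
    stop("layer SDs must be > 0")
  if (any(params$sectors$sd_ADOA <= 0) || any(params$sectors$sd_control <= 0))
    stop("sector SDs must be > 0")
  if (nrow(params$points) != 64)
    stop("point table must have 64 rows")
  if (any(params$points$sd_ADOA < 0) || any(params$points$sd_control < 0))
    stop("point SDs must be >= 0")
  if (any(lay$loading < 0 | lay$loading > 1) ||
      any(params$sectors$loading < 0 | params$sectors$loading > 1))
    stop("shared-severity loadings must lie in [0, 1]")
  if (params$sens_loading < 0 || params$sens_loading > 1)
    stop("sens_loading must lie in [0, 1]")
  if (params$scotoma_weight < 0 || params$scotoma_weight > 1)
    stop("scotoma_weight must lie in [0, 1]")
  if (!is.finite(params$scotoma_threshold) || params$scotoma_threshold <= 0)
    stop("scotoma_threshold must be a positive length (um)")
  if (params$scotoma_slope <= 0)
    stop("scotoma_slope must be > 0")
  if (params$jitter_sd < 0)
    stop("jitter_sd must be >= 0")
  for (g in names(params$fixation)) {
    fx <- params$fixation[[g]]
    if (fx[["sigma_x"]] <= 0 || fx[["sigma_y"]] <= 0)
      stop("fixation dispersion must be positive for group ", g)
    if (abs(fx[["rho"]]) >= 1)
      stop("fixation correlation must lie in (-1, 1) for group ", g)
  }
  if (diff(params$db_range) <= 0 || params$db_step <= 0)
    stop("invalid dB scale")
  invisible(params)
}

# Deterministic sub-seeds for named random substreams. Consecutive user
# seeds are scattered through two Lehmer-style multiplicative steps modulo
# the Mersenne prime 2^31 - 1 (exact in doubles, result < 2^31): streams
# seeded with consecutive integers share correlated early output, which
# would bias many-cohort Monte-Carlo protocols.
substream_seed <- function(seed, name) {
  offs <- c(cohort = 0, eyes = 1, calibration = 2,
            fixation = 3, power = 4, pipeline = 5)
  k <- if (name %in% names(offs)) offs[[name]] else
    sum(utf8ToInt(name)) %% 97
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% (m - 1)) + 1
  x <- (x * 48271) %% m
  x <- (x + k * 1299709) %% m
  as.integer((x * 69621) %% m)
}

# Seed the RNG for a named substream and warm it up. The first draws of a
# freshly seeded Mersenne-Twister state are insufficiently mixed, which
# measurably biases many-cohort Monte-Carlo summaries; discarding an
# initial block removes this.
seed_stream <- function(seed, name) {
  set.seed(substream_seed(seed, name))
  invisible(stats::runif(1000))
}
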