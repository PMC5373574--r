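#' Generate a synthetic ADOA/control cohort
#'
#' Simulates `n_per_group` subjects per group (ADOA and control), two eyes
#' each, with the statistical structure of the reference tables:
#'
#' * Each subject carries a latent shared factor `z ~ N(0, 1)`. Every layer
#'   and peripapillary sector value is
#'   `mu + sd * (sqrt(f) * z + sqrt(1 - f) * eps)` with independent
#'   `eps ~ N(0, 1)`, so each marginal reproduces the printed mean/SD while
#'   any two quantities with loadings `f1`, `f2` correlate at
#'   `sqrt(f1 * f2)` across subjects. The posterior-pole RNFL layer and the
#'   global peripapillary sector both load at 0.798, fixing their
#'   correlation at 0.798 by construction.
#' * Each eye's 64-cell thickness map is the subject-level value plus
#'   independent spatial jitter (`jitter_sd`, default 5 um), truncated at
#'   zero. For the ADOA ganglion cell layer an optional mean-zero spatial
#'   profile proportional to the normalized 64-point sensitivity deficit
#'   pattern (scaled to SD `gcl_pattern_sd`) concentrates thinning
#'   infero-nasally, as in the disease.
#' * Point sensitivities are
#'   `round(clamp(m_p + delta_g + s_p * (sqrt(f_s) * z + sqrt(1 - f_s) * eps), 0, 20))`
#'   on the integer dB instrument scale; afterwards each point is forced to
#'   0 dB (an absolute scotoma) with probability
#'   `scotoma_weight * plogis((threshold - GCL_cell) / slope)`, linking
#'   scotomas to local GCL thinning. The link is a disease mechanism and is
#'   applied to the ADOA group only; control zeros can arise solely from
#'   the instrument floor and are practically absent, matching the clinical
#'   observation.
#' * Fixation traces are i.i.d. bivariate normal samples with the group's
#'   dispersion parameters.
#'
#' All maps are stored in right-eye (laterality-normalized) orientation,
#' row-major with row 1 superior and column 1 nasal. One eye per subject is
#' selected for analysis from a dedicated random substream. The generator
#' is reproducible: the same seed yields an identical cohort.
#'
#' @param params A [default_cohort_params()] object.
#' @param n_per_group Number of subjects per group (>= 2; default 11).
#' @param seed Integer seed driving all randomness.
#' @param spec The [grid_spec()] of the test pattern.
#' @return An object of class `pp_cohort`: a list with elements `subjects`,
#'   `eyes`, `thickness` (eyes x layers x 64 array, um), `sectors`
#'   (eyes x 9 matrix, the 8 sectors plus the derived nasal/temporal ratio
#'   `NT`), `sensitivity` (eyes x 64 integer dB matrix), `forced` (logical
#'   matrix of link-forced scotomas), `fixation` (list of per-eye traces),
#'   `subject_layers`, `subject_sectors`, `params`, `seed`, `grid`.
#' @export
#' @examples
#' coh <- generate_cohort(n_per_group = 3, seed = 1)
#' coh
generate_cohort <- function(params = default_cohort_params(),
                            n_per_group = 11L, seed = 1L,
                            spec = grid_spec()) {
  validate_params(params)
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  n <- as.integer(n_per_group)
  groups <- c("ADOA", "control")
  layers <- params$layers$layer
  sect <- params$sectors$sector
  nL <- length(layers); nS <- length(sect); nP <- 64L
  n_eyes_g <- 2L * n
  tot_eyes <- 2L * n_eyes_g
  tot_subj <- 2L * n

  thickness <- array(NA_real_, c(tot_eyes, nL, nP),
                     dimnames = list(NULL, layers, NULL))
  sectors_m <- matrix(NA_real_, tot_eyes, nS + 1L,
                      dimnames = list(NULL, c(sect, "NT")))
  sensitivity <- matrix(NA_integer_, tot_eyes, nP)
  forced <- matrix(FALSE, tot_eyes, nP)
  fixation <- vector("list", tot_eyes)
  subject_layers <- matrix(NA_real_, tot_subj, nL,
                           dimnames = list(NULL, layers))
  subject_sectors <- matrix(NA_real_, tot_subj, nS,
                            dimnames = list(NULL, sect))
  subj_rows <- list(); eye_rows <- list()

  gcl_profile <- gcl_deficit_profile(params)
  seed_stream(seed, "cohort")

  for (gi in seq_along(groups)) {
    g <- groups[gi]
    mu_l <- params$layers[[paste0("mean_", g)]]
    sd_l <- params$layers[[paste0("sd_", g)]]
    f_l <- params$layers$loading
    mu_s <- params$sectors[[paste0("mean_", g)]]
    sd_s <- params$sectors[[paste0("sd_", g)]]
    f_s <- params$sectors$loading
    m_p <- params$points[[paste0("mean_", g)]]
    s_p <- params$points[[paste0("sd_", g)]]

    z <- stats::rnorm(n)
    epsL <- matrix(stats::rnorm(n * nL), n, nL)
    subjL <- matrix(mu_l, n, nL, byrow = TRUE) +
      matrix(sd_l, n, nL, byrow = TRUE) *
      (outer(z, sqrt(f_l)) + epsL * matrix(sqrt(1 - f_l), n, nL, byrow = TRUE))
    epsS <- matrix(stats::rnorm(n * nS), n, nS)
    subjS <- matrix(mu_s, n, nS, byrow = TRUE) +
      matrix(sd_s, n, nS, byrow = TRUE) *
      (outer(z, sqrt(f_s)) + epsS * matrix(sqrt(1 - f_s), n, nS, byrow = TRUE))

    eye_subj <- rep(seq_len(n), each = 2L)          # within-group subject
    jit <- array(stats::rnorm(n_eyes_g * nL * nP, 0, params$jitter_sd),
                 c(n_eyes_g, nL, nP))
    thick_g <- array(NA_real_, c(n_eyes_g, nL, nP))
    for (li in seq_len(nL)) {
      base <- subjL[eye_subj, li]
      prof <- if (layers[li] == "GCL" && g == "ADOA" &&
                  isTRUE(params$gcl_pattern)) gcl_profile else rep(0, nP)
      thick_g[, li, ] <- pmax(outer(base, prof, `+`) + jit[, li, ], 0)
    }

    eps_p <- matrix(stats::rnorm(n_eyes_g * nP), n_eyes_g, nP)
    raw <- matrix(m_p + params$sens_offset[[g]], n_eyes_g, nP, byrow = TRUE) +
      matrix(s_p, n_eyes_g, nP, byrow = TRUE) *
      (sqrt(params$sens_loading) * z[eye_subj] +
         sqrt(1 - params$sens_loading) * eps_p)
    lo <- params$db_range[1]; hi <- params$db_range[2]
    val <- round(pmin(pmax(raw, lo), hi) / params$db_step) * params$db_step
    u <- matrix(stats::runif(n_eyes_g * nP), n_eyes_g, nP)
    if (g == "ADOA") {
      # disease-mechanism link: thin GCL cells lose all response. Healthy
      # eyes show no absolute scotomas, and their wide between-subject GCL
      # dispersion reflects macular topography rather than pathology, so
      # the forcing is gated on the disease group.
      gcl_cells <- thick_g[, match("GCL", layers), ]
      p_force <- params$scotoma_weight *
        stats::plogis((params$scotoma_threshold - gcl_cells) /
                        params$scotoma_slope)
      forced_g <- u < p_force
      val[forced_g] <- 0
    } else {
      forced_g <- matrix(FALSE, n_eyes_g, nP)
    }

    fx <- params$fixation[[g]]
    Sigma <- fixation_cov(fx)
    fix_g <- lapply(seq_len(n_eyes_g), function(i)
      MASS::mvrnorm(params$fixation_n, c(0, 0), Sigma))

    demo <- params$demographics
    di <- sample.int(nrow(demo), n, replace = TRUE)
    age <- demo$age[di]
    sex <- demo$sex[di]
    if (g == "ADOA") {
      bcva_od <- demo$bcva_od[di]; bcva_os <- demo$bcva_os[di]
    } else {
      bcva_od <- rep(0, n); bcva_os <- rep(0, n)
    }

    subj_id <- sprintf("%s_%02d", g, seq_len(n))
    g_subj <- (gi - 1L) * n + seq_len(n)
    g_eyes <- (gi - 1L) * n_eyes_g + seq_len(n_eyes_g)
    subject_layers[g_subj, ] <- subjL
    subject_sectors[g_subj, ] <- subjS
    thickness[g_eyes, , ] <- thick_g
    sectors_m[g_eyes, seq_len(nS)] <- subjS[eye_subj, ]
    sectors_m[g_eyes, nS + 1L] <- subjS[eye_subj, match("N", sect)] /
      subjS[eye_subj, match("T", sect)]
    sensitivity[g_eyes, ] <- as.integer(val)
    forced[g_eyes, ] <- forced_g
    fixation[g_eyes] <- fix_g

    subj_rows[[g]] <- data.frame(
      subject_id = subj_id, group = g, age = age, sex = sex,
      bcva_od = bcva_od, bcva_os = bcva_os, stringsAsFactors = FALSE)
    eye_rows[[g]] <- data.frame(
      eye_index = g_eyes, subject_id = subj_id[eye_subj], group = g,
      eye = rep(c("OD", "OS"), times = n), stringsAsFactors = FALSE)
  }

  subjects <- do.call(rbind, subj_rows)
  eyes <- do.call(rbind, eye_rows)
  rownames(subjects) <- rownames(eyes) <- NULL

  seed_stream(seed, "eyes")
  subjects$analysis_eye <- sample(c("OD", "OS"), tot_subj, replace = TRUE)
  eyes$is_analysis <- eyes$eye ==
    subjects$analysis_eye[match(eyes$subject_id, subjects$subject_id)]

  structure(list(
    subjects = subjects, eyes = eyes,
    thickness = thickness, sectors = sectors_m,
    sensitivity = sensitivity, forced = forced,
    fixation = fixation,
    subject_layers = subject_layers, subject_sectors = subject_sectors,
    params = params, seed = as.integer(seed), n_per_group = n,
    grid_spec = spec, grid = generate_pp_grid(spec)
  ), class = "pp_cohort")
}

# Mean-zero 64-cell GCL spatial profile (um): minus the normalized
# control-minus-ADOA sensitivity deficit pattern, scaled to gcl_pattern_sd.
gcl_deficit_profile <- function(params) {
  if (!isTRUE(params$gcl_pattern) || params$gcl_pattern_sd == 0)
    return(rep(0, 64))
  d <- params$points$mean_control - params$points$mean_ADOA
  -params$gcl_pattern_sd * (d - mean(d)) / stats::sd(d)
}

fixation_cov <- function(fx) {
  sx <- fx[["sigma_x"]]; sy <- fx[["sigma_y"]]; r <- fx[["rho"]]
  matrix(c(sx^2, r * sx * sy, r * sx * sy, sy^2), 2, 2)
}

#' @export
print.pp_cohort <- function(x, ...) {
  cat(sprintf("Synthetic posterior-pole cohort: %d subjects/group, %d eyes, seed %d\n",
              x$n_per_group, nrow(x$eyes), x$seed))
  cat(sprintf("  layers: %s\n", paste(dimnames(x$thickness)[[2]], collapse = " ")))
  nz <- sum(x$sensitivity[x$eyes$group == "ADOA", ] == 0)
  cat(sprintf("  ADOA 0-dB points (both eyes): %d (%.1f%%)\n", nz,
              100 * nz / sum(x$eyes$group == "ADOA") / 64))
  invisible(x)
}

#' Generate a fixation trace
#'
#' Draws `n_samples` i.i.d. bivariate-normal fixation positions (degrees,
#' relative to the fixation target) with the dispersion parameters of the
#' requested group. ADOA defaults have strictly larger dispersion than
#' control defaults, reproducing the poorer fixation stability of the
#' disease.
#'
#' @param params A [default_cohort_params()] object.
#' @param group `"ADOA"` or `"control"`.
#' @param n_samples Number of samples (>= 10; default `params$fixation_n`).
#' @param seed Integer seed.
#' @return An `n_samples` x 2 matrix of (x, y) positions in degrees.
#' @export
generate_fixation_trace <- function(params = default_cohort_params(),
                                    group = c("ADOA", "control"),
                                    n_samples = params$fixation_n,
                                    seed = 1L) {
  group <- match.arg(group)
  if (n_samples < 10) stop("n_samples must be >= 10")
  fx <- params$fixation[[group]]
  if (fx[["sigma_x"]] <= 0 || fx[["sigma_y"]] <= 0)
    stop("fixation dispersion must be positive")
  seed_stream(seed, "fixation")
  tr <- MASS::mvrnorm(n_samples, c(0, 0), fixation_cov(fx))
  colnames(tr) <- c("x", "y")
  tr
}

#' Eye-level posterior-pole layer map means
#'
#' Mean over the 64 cells of one layer's thickness map, per eye.
#'
#' @param cohort A `pp_cohort`.
#' @param layer Layer name (e.g. `"Retina"`, `"RNFL"`, `"GCL"`).
#' @param eyes `"analysis"` (one randomly selected eye per subject) or
#'   `"both"`.
#' @return A data.frame with `eye_index`, `subject_id`, `group`, `value`.
#' @export
layer_map_means <- function(cohort, layer, eyes = c("analysis", "both")) {
  eyes <- match.arg(eyes)
  li <- match(layer, dimnames(cohort$thickness)[[2]])
  if (is.na(li)) stop("unknown layer: ", layer)
  idx <- if (eyes == "analysis") which(cohort$eyes$is_analysis)
         else seq_len(nrow(cohort$eyes))
  m <- cohort$thickness[idx, li, , drop = FALSE]
  dim(m) <- c(length(idx), dim(cohort$thickness)[3])
  data.frame(eye_index = idx,
             subject_id = cohort$eyes$subject_id[idx],
             group = cohort$eyes$group[idx],
             value = rowMeans(m),
             stringsAsFactors = FALSE)
}

#' Eye-level peripapillary sector values
#'
#' @param cohort A `pp_cohort`.
#' @param sector Sector name (`"PMB"`, ..., `"G"`, or the derived ratio
#'   `"NT"`).
#' @param eyes `"analysis"` or `"both"`.
#' @return A data.frame with `eye_index`, `subject_id`, `group`, `value`.
#' @export
sector_values <- function(cohort, sector, eyes = c("analysis", "both")) {
  eyes <- match.arg(eyes)
  si <- match(sector, colnames(cohort$sectors))
  if (is.na(si)) stop("unknown sector: ", sector)
  idx <- if (eyes == "analysis") which(cohort$eyes$is_analysis)
         else seq_len(nrow(cohort$eyes))
  data.frame(eye_index = idx,
             subject_id = cohort$eyes$subject_id[idx],
             group = cohort$eyes$group[idx],
             value = cohort$sectors[idx, si],
             stringsAsFactors = FALSE)
}
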