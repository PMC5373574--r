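#' Compare a variable between groups by one-way ANOVA
#'
#' Performs the two-group one-way ANOVA on a cohort variable (a layer map
#' mean, a peripapillary sector, or the per-eye grand mean sensitivity),
#' with a Bonferroni adjustment over `n_tests` simultaneous comparisons
#' (`p_adj = min(1, p * n_tests)`). With two groups the ANOVA F equals the
#' squared pooled-variance two-sample t statistic.
#'
#' @param cohort A `pp_cohort`.
#' @param variable A layer name, a sector name (including the derived
#'   `"NT"` ratio), or `"sensitivity"`.
#' @param n_tests Number of simultaneous tests in the family (default 1).
#' @param eyes `"analysis"` (default, one eye per subject) or `"both"`.
#' @return An object of class `pp_group_comparison`: a list with the
#'   variable name, per-group `n`, means and SDs, `F`, `p`, `p_adj`, and a
#'   `degenerate` flag set when both groups have zero within-group variance
#'   but unequal means (p is then reported as 0 with the flag).
#' @export
compare_groups <- function(cohort, variable, n_tests = 1,
                           eyes = c("analysis", "both")) {
  eyes <- match.arg(eyes)
  df <- cohort_variable(cohort, variable, eyes)
  if (min(table(df$group)) < 2)
    stop("need at least 2 observations per group")
  out <- anova_two_groups(df$value, df$group, n_tests)
  out$variable <- variable
  class(out) <- "pp_group_comparison"
  out
}

cohort_variable <- function(cohort, variable, eyes) {
  if (variable %in% dimnames(cohort$thickness)[[2]])
    layer_map_means(cohort, variable, eyes)
  else if (variable %in% colnames(cohort$sectors))
    sector_values(cohort, variable, eyes)
  else if (identical(variable, "sensitivity")) {
    idx <- if (eyes == "analysis") which(cohort$eyes$is_analysis)
           else seq_len(nrow(cohort$eyes))
    data.frame(eye_index = idx, subject_id = cohort$eyes$subject_id[idx],
               group = cohort$eyes$group[idx],
               value = rowMeans(cohort$sensitivity[idx, , drop = FALSE]),
               stringsAsFactors = FALSE)
  } else stop("unknown variable: ", variable)
}

# Core one-way two-group ANOVA used by group and pointwise comparisons.
anova_two_groups <- function(values, groups, n_tests = 1) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2L)
  ns <- tapply(values, groups, length)
  means <- tapply(values, groups, mean)
  sds <- tapply(values, groups, stats::sd)
  degenerate <- FALSE
  if (diff(range(values)) == 0) {
    Fst <- 0; p <- 1
  } else if (all(sds == 0, na.rm = TRUE) && diff(range(means)) > 0) {
    Fst <- Inf; p <- 0; degenerate <- TRUE
  } else {
    fit <- stats::anova(stats::lm(values ~ groups))
    Fst <- fit[["F value"]][1]
    p <- fit[["Pr(>F)"]][1]
  }
  list(n = as.vector(ns), groups = levels(groups),
       means = as.vector(means), sds = as.vector(sds),
       F = Fst, p = p, p_adj = min(1, p * n_tests),
       n_tests = n_tests, degenerate = degenerate)
}

#' @export
print.pp_group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s %.2f +/- %.2f vs %s %.2f +/- %.2f; F = %.3g, p = %.3g (adj %.3g over %d tests)\n",
              x$variable, x$groups[1], x$means[1], x$sds[1],
              x$groups[2], x$means[2], x$sds[2], x$F, x$p, x$p_adj, x$n_tests))
  if (x$degenerate) cat("  [degenerate: zero within-group variance]\n")
  invisible(x)
}

#' Compare all posterior-pole layers between groups
#'
#' Runs [compare_groups()] for each of the ten layers with a Bonferroni
#' family of 10 (configurable), mirroring the layer-thickness comparison
#' table.
#'
#' @param cohort A `pp_cohort`.
#' @param n_tests Bonferroni family size (default 10).
#' @param eyes `"analysis"` or `"both"`.
#' @return A data.frame with one row per layer.
#' @export
compare_layers <- function(cohort, n_tests = 10, eyes = "analysis") {
  layers <- dimnames(cohort$thickness)[[2]]
  do.call(rbind, lapply(layers, function(l) {
    cmp <- compare_groups(cohort, l, n_tests, eyes)
    data.frame(variable = l,
               mean_ADOA = cmp$means[1], sd_ADOA = cmp$sds[1],
               mean_control = cmp$means[2], sd_control = cmp$sds[2],
               F = cmp$F, p = cmp$p, p_adj = cmp$p_adj,
               stringsAsFactors = FALSE)
  }))
}

#' Compare all peripapillary sectors between groups
#'
#' @param cohort A `pp_cohort`.
#' @param n_tests Bonferroni family size (default 9: the eight sectors plus
#'   the nasal/temporal ratio).
#' @param eyes `"analysis"` or `"both"`.
#' @return A data.frame with one row per sector (including `"NT"`).
#' @export
compare_sectors <- function(cohort, n_tests = 9, eyes = "analysis") {
  secs <- colnames(cohort$sectors)
  do.call(rbind, lapply(secs, function(s) {
    cmp <- compare_groups(cohort, s, n_tests, eyes)
    data.frame(variable = s,
               mean_ADOA = cmp$means[1], sd_ADOA = cmp$sds[1],
               mean_control = cmp$means[2], sd_control = cmp$sds[2],
               F = cmp$F, p = cmp$p, p_adj = cmp$p_adj,
               stringsAsFactors = FALSE)
  }))
}

#' Pointwise comparison of the 64 sensitivity test points
#'
#' For each of the 64 test points, compares ADOA and control sensitivities
#' across analysis eyes with the same one-way ANOVA machinery as the layer
#' comparisons, Bonferroni-corrected over the 64 simultaneous tests. Also
#' emits the per-group 8 x 8 mean maps (attribute `mean_maps`) in the
#' published table layout and the mean-difference map.
#'
#' @param cohort A `pp_cohort`.
#' @param n_tests Bonferroni family size (default 64).
#' @param eyes `"analysis"` or `"both"`.
#' @return A data.frame with one row per point (`point_id`, `row`, `col`,
#'   group means/SDs, `F`, `p`, `p_adj`, `diff`), with attribute
#'   `mean_maps`: a list of 8 x 8 matrices `ADOA`, `control`, `diff`.
#' @export
pointwise_compare <- function(cohort, n_tests = 64, eyes = "analysis") {
  eyes <- match.arg(eyes, c("analysis", "both"))
  idx <- if (eyes == "analysis") which(cohort$eyes$is_analysis)
         else seq_len(nrow(cohort$eyes))
  grp <- factor(cohort$eyes$group[idx])
  sens <- cohort$sensitivity[idx, , drop = FALSE]
  res <- lapply(seq_len(ncol(sens)), function(p) {
    a <- anova_two_groups(sens[, p], grp, n_tests)
    data.frame(point_id = p - 1L,
               mean_ADOA = a$means[1], sd_ADOA = a$sds[1],
               mean_control = a$means[2], sd_control = a$sds[2],
               F = a$F, p = a$p, p_adj = a$p_adj)
  })
  out <- do.call(rbind, res)
  out$row <- cohort$grid$row[match(out$point_id, cohort$grid$id)]
  out$col <- cohort$grid$col[match(out$point_id, cohort$grid$id)]
  out$diff <- out$mean_ADOA - out$mean_control
  attr(out, "mean_maps") <- list(
    ADOA = matrix(out$mean_ADOA, 8, 8, byrow = TRUE),
    control = matrix(out$mean_control, 8, 8, byrow = TRUE),
    diff = matrix(out$diff, 8, 8, byrow = TRUE))
  out
}

#' Pearson and partial Pearson correlation
#'
#' With covariates, residualizes `x` and `y` on the covariate columns by
#' least squares and correlates the residuals, with degrees of freedom
#' reduced by the number of covariates; with no covariates this reduces to
#' the plain Pearson correlation test.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data.frame or matrix of covariates (factors
#'   allowed in a data.frame).
#' @return A list with `r`, `p`, `n`, and residual `df`.
#' @export
#' @examples
#' partial_pearson(1:10, (1:10) * 2)$r  # 1
partial_pearson <- function(x, y, covariates = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  k <- 0L
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    if (nrow(cv) != n) stop("covariates must have one row per observation")
    mm <- stats::model.matrix(~ ., data = cv)
    qr_mm <- qr(mm)
    if (qr_mm$rank < ncol(mm)) {
      drop_col <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
      stop("rank-deficient covariates; collinear column(s): ",
           paste(drop_col, collapse = ", "))
    }
    k <- ncol(mm) - 1L
    x <- stats::residuals(stats::lm(x ~ mm - 1))
    y <- stats::residuals(stats::lm(y ~ mm - 1))
  }
  if (n <= k + 2L) stop("need n > number of covariates + 2")
  r <- stats::cor(x, y)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, p = p, n = n, df = df)
}

#' Mean sensitivity over a region of the map
#'
#' Unweighted mean of the sensitivities of the points selected by a region
#' of interest: either a set of point ids or a polygon in visual-field
#' degrees (the software analogue of the device's "polygon tool").
#'
#' @param map A `pp_combined_map` (or any data.frame with `point_id`,
#'   `x_deg`, `y_deg`, `sensitivity_db`).
#' @param region Either an integer vector of point ids (0-63), or a
#'   two-column matrix of polygon vertices (degrees). `NULL` selects the
#'   whole map.
#' @return Mean sensitivity in dB.
#' @export
mean_sensitivity <- function(map, region = NULL) {
  if (is.null(region)) {
    sel <- rep(TRUE, nrow(map))
  } else if (is.matrix(region) || is.data.frame(region)) {
    region <- as.matrix(region)
    if (ncol(region) != 2) stop("polygon region must be a 2-column matrix")
    sel <- as.logical(pracma::inpolygon(map$x_deg, map$y_deg,
                                        region[, 1], region[, 2],
                                        boundary = TRUE))
  } else {
    sel <- map$point_id %in% region
  }
  if (!any(sel)) stop("region selects no points")
  mean(map$sensitivity_db[sel])
}

#' Count absolute scotomas in a cohort
#'
#' An absolute scotoma is a test point with no response at maximal stimulus
#' intensity, i.e. a sensitivity of exactly 0 dB. The denominator (all
#' points of both eyes, or of the analysis eyes only) is an explicit
#' argument because published percentages do not state it.
#'
#' @param cohort A `pp_cohort`.
#' @param group `"ADOA"` or `"control"`.
#' @param eyes `"both"` (default) or `"analysis"`.
#' @return A list with `count`, `total`, and `fraction`.
#' @export
count_absolute_scotomas <- function(cohort, group = "ADOA",
                                    eyes = c("both", "analysis")) {
  eyes <- match.arg(eyes)
  idx <- which(cohort$eyes$group == group &
                 (eyes == "both" | cohort$eyes$is_analysis))
  s <- cohort$sensitivity[idx, , drop = FALSE]
  list(count = sum(s == 0), total = length(s),
       fraction = sum(s == 0) / length(s))
}

#' Fixation stability: bivariate contour ellipse area
#'
#' Computes the BCEA of a fixation trace: the area of the ellipse covering
#' a fraction `P` of fixation positions under a bivariate normal model,
#' `area = pi * chi2_2(P) * sd_x * sd_y * sqrt(1 - rho^2)` with
#' `chi2_2(P) = -2 log(1 - P)`, together with the major/minor full axis
#' lengths `2 * sqrt(chi2_2(P) * lambda_i)` (covariance eigenvalues
#' `lambda_1 >= lambda_2`) and the orientation of the leading eigenvector.
#'
#' @param trace An n x 2 matrix or data.frame of fixation positions
#'   (degrees); n >= 10.
#' @param P Coverage probability in (0, 1); default 0.682, the one-sigma
#'   convention of the fixation literature.
#' @return An object of class `pp_bcea`: list with `area` (deg^2), `major`,
#'   `minor` (deg), `orientation` (deg), `P`, `sigma_x`, `sigma_y`, `rho`,
#'   `n`.
#' @export
#' @examples
#' tr <- generate_fixation_trace(n_samples = 500, seed = 2)
#' compute_bcea(tr)$area
compute_bcea <- function(trace, P = 0.682) {
  trace <- as.matrix(trace)
  if (ncol(trace) != 2) stop("trace must have two columns (x, y)")
  if (nrow(trace) < 10) stop("need at least 10 fixation samples")
  if (P <= 0 || P >= 1) stop("P must lie in (0, 1)")
  sx <- stats::sd(trace[, 1]); sy <- stats::sd(trace[, 2])
  if (sx == 0 || sy == 0) stop("degenerate trace: zero variance")
  rho <- stats::cor(trace[, 1], trace[, 2])
  bcea_from_moments(sx, sy, rho, P, n = nrow(trace))
}

#' BCEA from distribution moments
#'
#' Closed-form BCEA for given dispersion parameters; [compute_bcea()] calls
#' this with sample moments.
#'
#' @param sigma_x,sigma_y Standard deviations (deg).
#' @param rho Correlation.
#' @param P Coverage probability.
#' @param n Optional sample size to record.
#' @return A `pp_bcea` object.
#' @export
bcea_from_moments <- function(sigma_x, sigma_y, rho, P = 0.682, n = NA) {
  if (sigma_x <= 0 || sigma_y <= 0) stop("dispersion must be positive")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  chi2 <- -2 * log(1 - P)
  area <- pi * chi2 * sigma_x * sigma_y * sqrt(1 - rho^2)
  S <- matrix(c(sigma_x^2, rho * sigma_x * sigma_y,
                rho * sigma_x * sigma_y, sigma_y^2), 2, 2)
  ev <- eigen(S, symmetric = TRUE)
  axes <- 2 * sqrt(chi2 * ev$values)
  orientation <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
  structure(list(area = area, major = axes[1], minor = axes[2],
                 orientation = orientation, P = P,
                 sigma_x = sigma_x, sigma_y = sigma_y, rho = rho, n = n),
            class = "pp_bcea")
}

#' @export
print.pp_bcea <- function(x, ...) {
  cat(sprintf("BCEA(%.1f%%): %.3f deg^2; axes %.3f x %.3f deg, orientation %.1f deg\n",
              100 * x$P, x$area, x$major, x$minor, x$orientation))
  invisible(x)
}

#' Monte-Carlo power of the two-group comparison
#'
#' Estimates the power of the two-group one-way ANOVA (equivalently the
#' pooled-variance t test) to detect a difference between two normal
#' populations at level `alpha`, by simulation.
#'
#' @param mu1,sd1,mu2,sd2 Group means and SDs.
#' @param n Subjects per group.
#' @param alpha Significance level (default 0.05).
#' @param reps Number of Monte-Carlo replicates (>= 100).
#' @param seed Integer seed.
#' @return Estimated power (fraction of replicates with p < alpha).
#' @export
#' @examples
#' simulate_power(262.76, 24.29, 299.46, 34.53, n = 11, reps = 500, seed = 1)
simulate_power <- function(mu1, sd1, mu2, sd2, n, alpha = 0.05,
                           reps = 1000, seed = 1L) {
  if (reps < 100) stop("reps must be >= 100")
  seed_stream(seed, "power")
  x <- matrix(stats::rnorm(n * reps, mu1, sd1), n, reps)
  y <- matrix(stats::rnorm(n * reps, mu2, sd2), n, reps)
  mx <- colMeans(x); my <- colMeans(y)
  vx <- apply(x, 2, stats::var); vy <- apply(y, 2, stats::var)
  sp2 <- ((n - 1) * vx + (n - 1) * vy) / (2 * n - 2)
  tstat <- (mx - my) / sqrt(sp2 * 2 / n)
  p <- 2 * stats::pt(-abs(tstat), 2 * n - 2)
  mean(p < alpha)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS distance of the sample to the normal distribution with the
#' sample mean and SD, with the standard asymptotic p value. Because the
#' parameters are estimated from the same sample, the p value is
#' approximate (anti-conservative); it is used here, as in common clinical
#' practice, as a screening statistic. D is invariant under affine
#' transformations of the sample.
#'
#' @param sample Numeric vector, n >= 5.
#' @return A list with `D`, `p`, `n`.
#' @export
normality_check <- function(sample) {
  sample <- sample[is.finite(sample)]
  if (length(sample) < 5) stop("need n >= 5")
  if (stats::sd(sample) == 0) stop("constant sample")
  kt <- suppressWarnings(
    stats::ks.test(sample, "pnorm", mean(sample), stats::sd(sample)))
  list(D = unname(kt$statistic), p = kt$p.value, n = length(sample))
}

#' Cross-map correlation between posterior-pole and peripapillary RNFL
#'
#' Pearson correlation, within one group, between each subject's
#' posterior-pole RNFL map mean and the global peripapillary RNFL sector of
#' the analysis eye.
#'
#' @param cohort A `pp_cohort`.
#' @param group `"ADOA"` (default) or `"control"`.
#' @return A list with `r`, `p`, `n` (from [partial_pearson()]).
#' @export
rnfl_cross_correlation <- function(cohort, group = "ADOA") {
  pp <- layer_map_means(cohort, "RNFL", "analysis")
  pr <- sector_values(cohort, "G", "analysis")
  sel <- pp$group == group
  partial_pearson(pp$value[sel], pr$value[sel])
}
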