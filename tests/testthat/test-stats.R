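test_that("two-group ANOVA equals the squared pooled t statistic", {
  # identical groups: no between-group variance
  a <- ppmap:::anova_two_groups(c(1, 2, 3, 1, 2, 3),
                                rep(c("a", "b"), each = 3))
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  set.seed(17)
  for (i in 1:100) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    v <- c(rnorm(n1, 0, 1), rnorm(n2, sample(0:2, 1), 1.5))
    gr <- rep(c("a", "b"), c(n1, n2))
    a <- ppmap:::anova_two_groups(v, gr)
    tt <- t.test(v ~ gr, var.equal = TRUE)
    expect_equal(a$F, unname(tt$statistic^2), tolerance = 1e-9)
    expect_equal(a$p, tt$p.value, tolerance = 1e-9)
  }
})

test_that("degenerate zero-variance comparisons are flagged", {
  a <- ppmap:::anova_two_groups(c(1, 1, 1, 2, 2, 2),
                                rep(c("a", "b"), each = 3))
  expect_true(a$degenerate)
  expect_equal(a$p, 0)
  expect_true(is.infinite(a$F))
})

test_that("Bonferroni adjustment is monotone and never below raw p", {
  set.seed(4)
  praw <- sort(runif(30))
  for (k in c(1, 10, 64)) {
    padj <- pmin(1, praw * k)
    expect_true(all(diff(padj) >= 0))
    expect_true(all(padj >= praw))
    expect_true(all(padj <= 1))
  }
  coh <- generate_cohort(fast_params(), n_per_group = 5, seed = 2)
  cmp1 <- compare_groups(coh, "GCL", n_tests = 1)
  cmp10 <- compare_groups(coh, "GCL", n_tests = 10)
  expect_equal(cmp10$p_adj, min(1, cmp1$p * 10))
  expect_gte(cmp10$p_adj, cmp10$p)
})

test_that("layer and sector tables separate the groups as published", {
  coh <- generate_cohort(fast_params(), n_per_group = 60, seed = 6)
  lt <- compare_layers(coh)
  expect_equal(lt$variable, c("Retina", "RNFL", "GCL", "IPL", "INL",
                              "OPL", "ONL", "RPE", "IRL", "ORL"))
  # inner layers thinner in ADOA, strongly significant at this n
  for (l in c("Retina", "RNFL", "GCL", "IPL", "IRL")) {
    row <- lt[lt$variable == l, ]
    expect_lt(row$mean_ADOA, row$mean_control)
    expect_lt(row$p_adj, 1e-3)
  }
  # outer layers thicker in ADOA (OPL, ONL), RPE/ORL near-equivalent
  expect_gt(lt$mean_ADOA[lt$variable == "ONL"],
            lt$mean_control[lt$variable == "ONL"])
  st <- compare_sectors(coh)
  expect_equal(nrow(st), 9)
  expect_lt(st$mean_ADOA[st$variable == "PMB"],
            st$mean_control[st$variable == "PMB"])
  # nasal-to-temporal ratio runs the other way: higher in ADOA
  expect_gt(st$mean_ADOA[st$variable == "NT"],
            st$mean_control[st$variable == "NT"])
})

test_that("pointwise comparison reproduces the spatial deficit pattern", {
  coh <- generate_cohort(fast_params(), n_per_group = 40, seed = 8)
  pw <- pointwise_compare(coh)
  expect_equal(nrow(pw), 64)
  expect_true(all(pw$p_adj >= pw$p))
  # per-point means track the reference map almost exactly at this n
  m <- default_cohort_params()$points$mean_ADOA
  expect_gt(cor(pw$mean_ADOA, m), 0.9)
  # deepest ADOA deficit in the infero-nasal corner (row 5, col 1)
  expect_equal(pw$point_id[which.min(pw$mean_ADOA)], 32L)
  maps <- attr(pw, "mean_maps")
  expect_equal(dim(maps$ADOA), c(8, 8))
  expect_equal(maps$ADOA[5, 1], pw$mean_ADOA[pw$point_id == 32])
})

test_that("partial Pearson reduces to plain Pearson and controls covariates", {
  x <- 1:10
  expect_equal(partial_pearson(x, 2 * x)$r, 1)
  set.seed(10)
  a <- rnorm(1e4); b <- rnorm(1e4)
  expect_lt(abs(partial_pearson(a, b)$r), 0.05)
  # no-covariate p matches cor.test exactly
  x2 <- rnorm(30); y2 <- 0.5 * x2 + rnorm(30)
  pp <- partial_pearson(x2, y2)
  ct <- cor.test(x2, y2)
  expect_equal(pp$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(pp$p, ct$p.value, tolerance = 1e-12)
  # a shared covariate induces correlation that partialling removes
  age <- rnorm(500)
  u <- 2 * age + rnorm(500); v <- -2 * age + rnorm(500)
  expect_lt(partial_pearson(u, v)$r, -0.5)
  expect_lt(abs(partial_pearson(u, v, data.frame(age = age))$r), 0.15)
  dup <- data.frame(a = age, b = age)
  expect_error(partial_pearson(u, v, dup), "collinear")
  expect_error(partial_pearson(1:3, 1:3, data.frame(a = rnorm(3))), "need n")
})

test_that("posterior-pole RNFL tracks the peripapillary global sector", {
  coh <- generate_cohort(fast_params(), n_per_group = 2000, seed = 12)
  r <- rnfl_cross_correlation(coh, "ADOA")
  expect_lt(abs(r$r - 0.798), 0.03)
  expect_lt(r$p, 1e-10)
})

test_that("mean sensitivity supports ids and polygon regions", {
  g <- generate_pp_grid()
  m <- overlay(list(GCL = rep(30, 64)), rep(20L, 64), g)
  expect_equal(mean_sensitivity(m), 20)
  # the reference ADOA map averages to 13.78 dB over the full grid
  p <- default_cohort_params()
  m2 <- overlay(list(GCL = rep(30, 64)), p$points$mean_ADOA, g)
  expect_equal(mean_sensitivity(m2), 13.78, tolerance = 0.005)
  # nasal half-grid selected by polygon (x < 0 after rotation-safe margin)
  poly <- cbind(c(-30, 0, 0, -30), c(-30, -30, 30, 30))
  nasal <- mean_sensitivity(m2, poly)
  temporal <- mean_sensitivity(m2, m$point_id[g$x > 0])
  expect_lt(nasal, temporal)
  expect_error(mean_sensitivity(m2, integer(0)), "no points")
})

test_that("nasal deficit exceeds temporal deficit across cohorts", {
  g <- generate_pp_grid()
  nasal_ids <- g$id[g$col <= 4]
  temp_ids <- g$id[g$col > 4]
  worse <- 0
  for (k in 1:50) {
    coh <- generate_cohort(fast_params(), n_per_group = 11, seed = 100 + k)
    ad <- which(coh$eyes$group == "ADOA" & coh$eyes$is_analysis)
    mm <- colMeans(coh$sensitivity[ad, ])
    worse <- worse + (mean(mm[nasal_ids + 1]) < mean(mm[temp_ids + 1]))
  }
  expect_gt(worse, 47)
})

test_that("absolute scotomas are counted with an explicit denominator", {
  s <- rep(20L, 64); s[c(3, 10, 40)] <- 0L
  coh <- fake_cohort(s)
  res <- count_absolute_scotomas(coh, "ADOA", "both")
  expect_equal(res$count, 3)
  expect_equal(res$fraction, 3 / 64)
  none <- count_absolute_scotomas(fake_cohort(rep(20L, 64)), "ADOA")
  expect_equal(none$count, 0)
  expect_equal(none$fraction, 0)
})

test_that("BCEA follows the closed form and its axes", {
  b <- bcea_from_moments(1, 1, 0, P = 0.682)
  expect_equal(b$area, pi * (-2 * log(1 - 0.682)), tolerance = 1e-12)
  expect_equal(b$area, 7.1987, tolerance = 1e-3)
  # doubling one dispersion doubles the area; area = pi/4 * major * minor
  b2 <- bcea_from_moments(2, 1, 0, P = 0.682)
  expect_equal(b2$area, 2 * b$area)
  b3 <- bcea_from_moments(1.3, 0.7, 0.4, P = 0.95)
  expect_equal(pi / 4 * b3$major * b3$minor, b3$area, tolerance = 1e-12)
  expect_gte(b3$major, b3$minor)
  # vanishing dispersion collapses the ellipse
  expect_lt(bcea_from_moments(1e-6, 1e-6, 0)$area, 1e-10)
  expect_error(compute_bcea(matrix(0, 20, 2)), "degenerate")
  expect_error(compute_bcea(matrix(rnorm(10), 5, 2)), "at least 10")
})

test_that("the P-ellipse covers the stated fraction of samples", {
  set.seed(23)
  S <- matrix(c(1.2^2, 0.3 * 1.2 * 0.8, 0.3 * 1.2 * 0.8, 0.8^2), 2)
  tr <- MASS::mvrnorm(1e4, c(0, 0), S)
  b <- compute_bcea(tr, P = 0.682)
  Shat <- cov(tr)
  d2 <- rowSums((tr %*% solve(Shat)) * tr)
  inside <- mean(d2 <= -2 * log(1 - 0.682))
  expect_lt(abs(inside - 0.682), 0.02)
  # and the sample area matches the population area within a few percent
  pop <- bcea_from_moments(1.2, 0.8, 0.3, P = 0.682)
  expect_lt(abs(b$area / pop$area - 1), 0.05)
})

test_that("Monte-Carlo power behaves like a test of its size and grows", {
  expect_lt(abs(simulate_power(0, 1, 0, 1, n = 20, reps = 4000, seed = 3) -
                  0.05), 0.015)
  expect_gt(simulate_power(0, 1, 5, 1, n = 20, reps = 500, seed = 3), 0.999)
  # total-retina parameters at the study size give power near 80%
  pw <- simulate_power(262.76, 24.29, 299.46, 34.53, n = 11,
                       alpha = 0.05, reps = 4000, seed = 1)
  expect_gt(pw, 0.75); expect_lt(pw, 0.90)
  expect_error(simulate_power(0, 1, 0, 1, 5, reps = 10), ">= 100")
})

test_that("KS normality screening detects gross non-normality", {
  set.seed(33)
  x <- rnorm(1e4)
  nk <- normality_check(x)
  expect_lt(nk$D, 0.02)
  u <- runif(1e4)
  expect_lt(normality_check(u)$p, 0.001)
  # D is invariant under affine transforms
  expect_equal(normality_check(5 - 3 * x)$D, nk$D, tolerance = 1e-12)
  expect_error(normality_check(rep(1, 10)), "constant")
  expect_error(normality_check(1:4), "n >= 5")
})
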