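test_that("the generator is deterministic in its seed", {
  a <- generate_cohort(fast_params(), n_per_group = 4, seed = 7)
  b <- generate_cohort(fast_params(), n_per_group = 4, seed = 7)
  expect_identical(a$thickness, b$thickness)
  expect_identical(a$sensitivity, b$sensitivity)
  expect_identical(a$sectors, b$sectors)
  expect_identical(a$fixation, b$fixation)
  expect_identical(a$subjects, b$subjects)
  c2 <- generate_cohort(fast_params(), n_per_group = 4, seed = 8)
  expect_false(identical(a$sensitivity, c2$sensitivity))
})

test_that("degenerate dispersion collapses every cell onto the table means", {
  coh <- generate_cohort(degenerate_params(), n_per_group = 3, seed = 1)
  ad <- coh$eyes$group == "ADOA"
  retina <- coh$thickness[ad, "Retina", ]
  expect_true(all(abs(retina - 262.76) < 1e-3))
  ctrl_retina <- coh$thickness[!ad, "Retina", ]
  expect_true(all(abs(ctrl_retina - 299.46) < 1e-3))
  pmb <- coh$sectors[ad, "PMB"]
  expect_true(all(abs(pmb - 20.22) < 1e-3))
  # sensitivities equal the rounded clamped point means
  m <- default_cohort_params()$points$mean_ADOA
  expect_true(all(coh$sensitivity[which(ad)[1], ] == round(m)))
})

test_that("generated records respect the instrument and tissue ranges", {
  coh <- generate_cohort(fast_params(), n_per_group = 11, seed = 3)
  expect_true(all(coh$sensitivity >= 0 & coh$sensitivity <= 20))
  expect_type(coh$sensitivity[1], "integer")
  expect_true(all(coh$thickness >= 0))
  expect_true(all(is.finite(coh$thickness)))
  # exactly one analysis eye per subject
  tab <- table(coh$eyes$subject_id[coh$eyes$is_analysis])
  expect_true(all(tab == 1))
  expect_equal(length(tab), 22)
  # forced scotomas are 0 dB and sit on finite GCL cells
  expect_true(all(coh$sensitivity[coh$forced] == 0))
  # N/T ratio is derived from the same record's sectors
  expect_equal(coh$sectors[, "NT"],
               coh$sectors[, "N"] / coh$sectors[, "T"])
  expect_error(generate_cohort(fast_params(), n_per_group = 1), ">= 2")
})

test_that("sample means recover the table parameters at large n", {
  coh <- generate_cohort(fast_params(), n_per_group = 200, seed = 5)
  gcl <- layer_map_means(coh, "GCL", "analysis")
  m <- mean(gcl$value[gcl$group == "ADOA"])
  expect_lt(abs(m - 21.45), 3 * 4.662 / sqrt(200))
  ret <- layer_map_means(coh, "Retina", "analysis")
  expect_lt(abs(mean(ret$value[ret$group == "control"]) - 299.46),
            3 * 34.53 / sqrt(200))
})

test_that("shared-severity loadings fix the RNFL cross-map correlation", {
  # by construction the subject-level correlation equals the 0.798 loading
  coh <- generate_cohort(fast_params(), n_per_group = 5000, seed = 9)
  grp <- coh$subjects$group
  r <- cor(coh$subject_layers[grp == "ADOA", "RNFL"],
           coh$subject_sectors[grp == "ADOA", "G"])
  expect_lt(abs(r - 0.798), 0.015)
  # other layer pairs correlate near sqrt(f1 f2) = 0.5
  r2 <- cor(coh$subject_layers[grp == "ADOA", "GCL"],
            coh$subject_layers[grp == "ADOA", "INL"])
  expect_lt(abs(r2 - 0.5), 0.03)
})

test_that("the ADOA GCL spatial profile mirrors the deficit pattern", {
  p <- default_cohort_params()
  prof <- ppmap:::gcl_deficit_profile(p)
  expect_equal(mean(prof), 0, tolerance = 1e-12)
  expect_equal(sd(prof), p$gcl_pattern_sd, tolerance = 1e-12)
  # deepest thinning at the largest sensitivity deficit (row 5, col 1)
  expect_equal(which.min(prof), 33L)
})

test_that("fixation traces are reproducible with calibrated dispersion", {
  expect_identical(generate_fixation_trace(seed = 4),
                   generate_fixation_trace(seed = 4))
  p <- default_cohort_params()
  p$fixation$control <- c(sigma_x = 1e-4, sigma_y = 1e-4, rho = 0)
  tr0 <- generate_fixation_trace(p, "control", 100, seed = 1)
  expect_true(all(abs(tr0) < 1e-3))
  tr <- generate_fixation_trace(group = "control", n_samples = 1e4, seed = 2)
  expect_lt(abs(sd(tr[, 1]) / 0.4 - 1), 0.05)
  expect_lt(abs(sd(tr[, 2]) / 0.3 - 1), 0.05)
  # ADOA dispersion strictly exceeds control dispersion by default
  fx <- default_cohort_params()$fixation
  expect_true(all(fx$ADOA[c("sigma_x", "sigma_y")] >
                    fx$control[c("sigma_x", "sigma_y")]))
  expect_error(generate_fixation_trace(n_samples = 5), ">= 10")
})

test_that("parameter validation rejects broken configurations", {
  p <- default_cohort_params()
  p$scotoma_weight <- 1.5
  expect_error(validate_params(p), "scotoma_weight")
  p <- default_cohort_params()
  p$layers$sd_ADOA[1] <- -1
  expect_error(validate_params(p), "layer SDs")
  p <- default_cohort_params()
  p$fixation$ADOA["rho"] <- 1
  expect_error(validate_params(p), "correlation")
})
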