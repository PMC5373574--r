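test_that("perfectly separated classes give AUC 1 and a cutoff between them", {
  r <- roc_curve(c(10, 12, 15, 30, 33, 35),
                 c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  expect_gt(r$youden_cutoff, 15)
  expect_lt(r$youden_cutoff, 30)
  expect_equal(r$capture_rate, 1)
  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
  expect_error(roc_curve(c(1, NA), c(TRUE, FALSE)), "finite")
})

test_that("uninformative values give a chance-level ROC", {
  set.seed(41)
  v <- rnorm(1e4, 25, 5)
  lab <- runif(1e4) < 0.1
  r <- roc_curve(v, lab)
  expect_lt(abs(r$auc - 0.5), 0.02)
})

test_that("trapezoid AUC equals pair-counting, exhaustively and at random", {
  # exhaustive: every label pattern over a fixed tied value multiset, n = 8
  vals <- c(1, 1, 2, 2, 3, 3, 4, 4)
  for (mask in 1:254) {
    lab <- as.logical(bitwAnd(mask, 2^(0:7)))
    r <- roc_curve(vals, lab)
    expect_equal(r$auc, auc_pairs(vals, lab), tolerance = 1e-12)
  }
  set.seed(43)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    v <- round(rnorm(n, 20, 6), sample(0:1, 1))  # induce ties
    lab <- runif(n) < 0.4
    if (!any(lab) || all(lab)) next
    expect_equal(roc_curve(v, lab)$auc, auc_pairs(v, lab),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(47)
  for (i in 1:10) {
    v <- rnorm(300, 25, 6)
    lab <- runif(300) < plogis((23.5 - v) / 2)
    if (!any(lab) || all(lab)) next
    mine <- roc_curve(v, lab)$auc
    ref <- suppressMessages(
      as.numeric(pROC::auc(pROC::roc(response = lab, predictor = v,
                                     direction = ">"))))
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("AUC is invariant under monotone transforms; cutoff is equivariant", {
  set.seed(51)
  v <- rnorm(200, 25, 5)
  lab <- runif(200) < plogis((23.5 - v) / 1.5)
  if (!any(lab)) lab[which.min(v)] <- TRUE
  r <- roc_curve(v, lab)
  expect_equal(roc_curve(exp(v / 10), lab)$auc, r$auc, tolerance = 1e-12)
  expect_equal(roc_curve(v^3, lab)$auc, r$auc, tolerance = 1e-12)
  shifted <- roc_curve(v + 10, lab)
  expect_equal(shifted$youden_cutoff, r$youden_cutoff + 10,
               tolerance = 1e-9)
  expect_equal(youden_cutoff(r), r$youden_cutoff)
})

test_that("capture rate counts scotoma points below the cutoff", {
  v <- c(10, 15, 20, 30)
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(capture_rate(v, lab, 25), 1)
  expect_equal(capture_rate(v, lab, 12), 0.5)
  expect_equal(capture_rate(v, lab, 5), 0)
  expect_error(capture_rate(v, c(FALSE, FALSE, FALSE, FALSE), 25),
               "undefined")
  expect_error(capture_rate(v, lab, Inf), "finite")
})

test_that("a sharp link recovers the 23.5 um threshold from pooled points", {
  # slope -> 0 turns the scotoma link into a step at the true threshold;
  # the Youden cutoff of the pooled ROC then sits on the step
  p <- default_cohort_params()
  p$scotoma_slope <- 1e-3
  p$fixation_n <- 10
  for (k in 1:3) {
    r <- scotoma_roc(generate_cohort(p, n_per_group = 400, seed = k))
    expect_lt(abs(r$youden_cutoff - 23.5), 0.5)
  }
})

test_that("cohort-level ROC wrappers pool points and summarize patients", {
  coh <- generate_cohort(fast_params(), n_per_group = 30, seed = 19)
  r <- scotoma_roc(coh)
  expect_s3_class(r, "pp_roc")
  expect_equal(r$n_pos + r$n_neg, 30 * 64)
  expect_gt(r$auc, 0.6)
  cp <- cohort_capture_rate(coh, r$youden_cutoff, unit = "points")
  expect_equal(cp, r$capture_rate)
  cpat <- cohort_capture_rate(coh, r$youden_cutoff, unit = "patients")
  expect_gte(cpat, cp - 1e-9)  # any-point capture is easier per patient
  # absolute scotomas are essentially an ADOA phenomenon: the control
  # zero rate is negligible (the link is numerically inert at control
  # GCL thicknesses)
  ctrl <- coh$sensitivity[coh$eyes$group == "control", ]
  expect_lt(mean(ctrl == 0), 0.002)
  f <- tempfile(fileext = ".csv")
  write_roc_csv(r, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), length(r$thresholds))
  expect_equal(tab$J, r$sensitivity + r$specificity - 1, tolerance = 1e-9)
})
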