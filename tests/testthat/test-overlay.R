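test_that("pattern points map back to their own grid cells", {
  for (rot in c(0, 7, -7)) {
    spec <- grid_spec(rotation = rot)
    g <- generate_pp_grid(spec)
    cells <- point_to_cell(g, spec)
    expect_true(all(cells$in_area))
    expect_equal(cells$row, g$row)
    expect_equal(cells$col, g$col)
  }
  # a small displacement stays within the cell (half-pitch 1.875 deg)
  g <- generate_pp_grid()
  g$x <- g$x + 0.07; g$y <- g$y - 0.07   # 0.1 deg along the diagonal
  cells <- point_to_cell(g)
  expect_equal(cells$row, g$row)
  expect_equal(cells$col, g$col)
})

test_that("boundary points go to the lower-indexed cell; outside is flagged", {
  spec <- grid_spec(rotation = 0)
  # exact boundary between columns 1 and 2 at x = -15 + 3.75
  p <- data.frame(x = -15 + 3.75, y = 10)
  expect_equal(point_to_cell(p, spec)$col, 1L)
  # exact boundary between rows 1 and 2 at y = 12.5 - 3.125
  p2 <- data.frame(x = 0, y = 12.5 - 3.125)
  expect_equal(point_to_cell(p2, spec)$row, 1L)
  # outer edges belong to the nearest cell
  edge <- data.frame(x = c(-15, 15), y = c(12.5, -12.5))
  ce <- point_to_cell(edge, spec)
  expect_equal(ce$col, c(1L, 8L))
  expect_equal(ce$row, c(1L, 8L))
  out <- point_to_cell(data.frame(x = 15.2, y = 0), spec)
  expect_false(out$in_area)
  expect_true(is.na(out$col))
})

test_that("pairing is a permutation for jittered patterns", {
  set.seed(21)
  spec <- grid_spec()
  g <- generate_pp_grid(spec)
  for (i in 1:200) {
    gj <- g
    jit <- rotate_point(cbind(runif(64, -1.8, 1.8), runif(64, -1.5, 1.5)),
                        spec$rotation)
    gj$x <- g$x + jit[, 1]
    gj$y <- g$y + jit[, 2]
    cells <- point_to_cell(gj, spec)
    cell_id <- (cells$row - 1L) * 8L + cells$col
    expect_equal(sort(cell_id), 1:64)
  }
})

test_that("overlay pairs values without altering them", {
  g <- generate_pp_grid()
  m <- overlay(list(Retina = rep(100, 64)), rep(20, 64), g)
  expect_s3_class(m, "pp_combined_map")
  expect_equal(nrow(m), 64)
  expect_true(all(m$Retina_um == 100 & m$sensitivity_db == 20))
  # identity permutation: cell id order equals point id order
  expect_equal((m$row - 1) * 8 + m$col - 1, m$point_id)
  # distinct per-cell values land on their own points untouched
  th <- seq_len(64) * 1.5
  m2 <- overlay(list(GCL = th), 64:1, g)
  expect_equal(m2$GCL_um, th)
  expect_equal(m2$sensitivity_db, 64:1)
  expect_error(overlay(list(GCL = th[-1]), 64:1, g), "64 entries")
  bad <- g; bad$x[2] <- bad$x[1]; bad$y[2] <- bad$y[1]
  expect_error(overlay(list(GCL = th), 64:1, bad), "same cell")
  far <- g; far$x[1] <- 40
  expect_error(overlay(list(GCL = th), 64:1, far), "outside")
})

test_that("overlay commutes with laterality normalization", {
  spec <- grid_spec()
  g <- generate_pp_grid(spec)
  set.seed(31)
  th_od <- rnorm(64, 30, 5)
  sens_od <- sample(0:20, 64, replace = TRUE)
  # fabricate the same eye seen in OS-native orientation: mirrored ids
  mir <- (g$row - 1L) * 8L + (8L - g$col)        # 0-based mirrored id
  th_os <- th_od[order(mir)]
  sens_os <- sens_od[order(mir)]
  # mirroring the OD grid yields the OS-native pattern, whose effective
  # fovea-to-disc rotation has the opposite sign
  g_os <- normalize_laterality(g, "OS", spec)
  spec_os <- grid_spec(rotation = -spec$rotation)
  # path A: normalize first, then overlay in right-eye orientation
  a <- overlay(list(GCL = th_od), sens_od, g, spec)
  # path B: overlay the OS-native data in its native orientation
  b <- overlay(list(GCL = th_os), sens_os, g_os, spec_os)
  b_mirrored <- b[match(mir, b$point_id), ]
  expect_equal(a$GCL_um, b_mirrored$GCL_um)
  expect_equal(a$sensitivity_db, b_mirrored$sensitivity_db)
})

test_that("cohort combined maps carry the eye's own values", {
  coh <- generate_cohort(fast_params(), n_per_group = 3, seed = 2)
  m <- combined_map(coh, 1, layers = c("Retina", "GCL"))
  expect_equal(m$GCL_um, coh$thickness[1, "GCL", ])
  expect_equal(m$sensitivity_db, coh$sensitivity[1, ])
  expect_error(combined_map(coh, 99), "out of range")
  expect_error(combined_map(coh, 1, layers = "Sclera"), "unknown layer")
})

test_that("forced scotomas sit on locally thin GCL", {
  # group means: cells holding forced 0-dB points are thinner on average
  coh <- generate_cohort(fast_params(), n_per_group = 50, seed = 13)
  ad <- which(coh$eyes$group == "ADOA")
  gcl <- coh$thickness[ad, "GCL", ]
  forced <- coh$forced[ad, ]
  expect_gt(mean(gcl[!forced]) - mean(gcl[forced]), 2)
})
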