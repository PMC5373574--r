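# Shared helpers: parameter variants and small fabricated objects used
# across test files. All fixtures are built in code.

# Default params with a short fixation trace, for speed in loops.
fast_params <- function() {
  p <- default_cohort_params()
  p$fixation_n <- 10
  p
}

# Near-degenerate params: negligible dispersion, no jitter, no forced
# scotomas, no offsets -- every draw collapses onto the table means.
degenerate_params <- function() {
  p <- default_cohort_params(calibrated = FALSE)
  eps <- 1e-9
  p$layers$sd_ADOA[] <- eps; p$layers$sd_control[] <- eps
  p$sectors$sd_ADOA[] <- eps; p$sectors$sd_control[] <- eps
  p$points$sd_ADOA[] <- 0; p$points$sd_control[] <- 0
  p$jitter_sd <- 0
  p$scotoma_weight <- 0
  p$gcl_pattern <- FALSE
  p$fixation_n <- 10
  p
}

# Minimal hand-built cohort: one ADOA eye with a given sensitivity map.
fake_cohort <- function(sens_row) {
  stopifnot(length(sens_row) == 64)
  structure(list(
    eyes = data.frame(eye_index = 1L, subject_id = "ADOA_01",
                      group = "ADOA", eye = "OD", is_analysis = TRUE,
                      stringsAsFactors = FALSE),
    sensitivity = matrix(as.integer(sens_row), 1, 64),
    thickness = array(30, c(1, 1, 64), dimnames = list(NULL, "GCL", NULL)),
    grid = generate_pp_grid(), grid_spec = grid_spec()
  ), class = "pp_cohort")
}

# Brute-force AUC oracle: pair counting with ties scored 1/2, positive
# class = low value.
auc_pairs <- function(values, labels) {
  pos <- values[as.logical(labels)]
  neg <- values[!as.logical(labels)]
  cmp <- outer(pos, neg, function(a, b) (a < b) + 0.5 * (a == b))
  mean(cmp)
}
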