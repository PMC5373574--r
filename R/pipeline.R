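#' Default pipeline configuration
#'
#' The run configuration is a plain serializable list: one master seed
#' (from which the cohort, eye-selection and any calibration substreams
#' are derived), the cohort size, grid geometry, calibration targets, and
#' the set of analyses to run.
#'
#' @param seed Master seed (default 1).
#' @param n_per_group Subjects per group (default 11).
#' @param rotation Grid rotation in degrees (default 7).
#' @param analyses Character vector of stages to run; any of `"layers"`,
#'   `"sectors"`, `"pointwise"`, `"sensitivity"`, `"scotoma"`, `"bcea"`,
#'   `"correlation"`, `"roc"` (default all).
#' @param bcea_coverage BCEA coverage probability (default 0.682).
#' @return A list of class `pp_run_config`.
#' @export
default_run_config <- function(seed = 1L, n_per_group = 11L, rotation = 7,
                               analyses = c("layers", "sectors", "pointwise",
                                            "sensitivity", "scotoma", "bcea",
                                            "correlation", "roc"),
                               bcea_coverage = 0.682) {
  structure(list(seed = as.integer(seed),
                 n_per_group = as.integer(n_per_group),
                 rotation = rotation, analyses = analyses,
                 bcea_coverage = bcea_coverage,
                 targets = list(grand_mean_ADOA = 12.86,
                                grand_mean_control = 18.76,
                                scotoma_fraction = 0.078)),
            class = "pp_run_config")
}

#' Run the full reproduction pipeline
#'
#' Executes, deterministically for a given seed: cohort generation with the
#' calibrated defaults, the layer and sector group-comparison tables, the
#' 64-point pointwise comparison, grand-mean sensitivity, absolute-scotoma
#' counting, per-group BCEA, the posterior-pole/peripapillary RNFL
#' correlation, and the pooled GCL scotoma ROC with its Youden cutoff. All
#' table analogues are written as CSV beside a `summary.json` with the
#' headline statistics, and the configuration snapshot is written beside
#' the outputs. Stage failures are propagated with the stage name.
#'
#' @param config A [default_run_config()].
#' @param outdir Output directory (created if missing); `NULL` to skip
#'   writing files.
#' @return The summary list, invisibly when writing, with elements
#'   `layer_means`, `sensitivity`, `scotomas`, `correlation_r`,
#'   `gcl_cutoff`, `auc`, `capture_rate_points`, `bcea`, and `warnings`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(default_run_config(seed = 1), outdir = NULL)
#' res$gcl_cutoff
#' }
run_pipeline <- function(config = default_run_config(), outdir = NULL) {
  stopifnot(inherits(config, "pp_run_config"))
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  }
  emit_csv <- function(x, name) {
    if (!is.null(outdir))
      utils::write.csv(x, file.path(outdir, name), row.names = FALSE,
                       quote = FALSE)
  }
  warnings <- character()
  spec <- grid_spec(rotation = config$rotation)
  params <- default_cohort_params()
  cohort <- stage("generate",
                  generate_cohort(params, config$n_per_group, config$seed,
                                  spec))
  if (config$n_per_group < 8) {
    pw <- stage("power", simulate_power(
      params$layers$mean_ADOA[1], params$layers$sd_ADOA[1],
      params$layers$mean_control[1], params$layers$sd_control[1],
      n = config$n_per_group, reps = 1000, seed = config$seed))
    if (pw < 0.8) {
      w <- sprintf("low power: %.0f%% to detect the total-retina group difference at n = %d",
                   100 * pw, config$n_per_group)
      warnings <- c(warnings, w)
      warning(w, call. = FALSE)
    }
  }
  summary <- list(seed = config$seed, n_per_group = config$n_per_group,
                  warnings = warnings)

  if ("layers" %in% config$analyses) {
    tab <- stage("layers", compare_layers(cohort))
    emit_csv(tab, "layers.csv")
    summary$layer_means <- stats::setNames(
      lapply(seq_len(nrow(tab)), function(i)
        list(ADOA = tab$mean_ADOA[i], control = tab$mean_control[i],
             p_adj = tab$p_adj[i])), tab$variable)
  }
  if ("sectors" %in% config$analyses) {
    tab <- stage("sectors", compare_sectors(cohort))
    emit_csv(tab, "sectors.csv")
    summary$sector_means <- stats::setNames(
      lapply(seq_len(nrow(tab)), function(i)
        list(ADOA = tab$mean_ADOA[i], control = tab$mean_control[i],
             p_adj = tab$p_adj[i])), tab$variable)
  }
  if ("pointwise" %in% config$analyses) {
    pw <- stage("pointwise", pointwise_compare(cohort))
    emit_csv(pw, "pointwise.csv")
    summary$pointwise_significant <- sum(pw$p_adj < 0.05)
  }
  if ("sensitivity" %in% config$analyses) {
    cmp <- stage("sensitivity", compare_groups(cohort, "sensitivity"))
    summary$sensitivity <- list(
      grand_mean_ADOA = cmp$means[1], sd_ADOA = cmp$sds[1],
      grand_mean_control = cmp$means[2], sd_control = cmp$sds[2],
      p = cmp$p)
    emit_csv(data.frame(group = cmp$groups, mean = cmp$means, sd = cmp$sds,
                        F = cmp$F, p = cmp$p), "sensitivity.csv")
  }
  if ("scotoma" %in% config$analyses) {
    sc <- stage("scotoma", count_absolute_scotomas(cohort, "ADOA", "both"))
    sc_c <- stage("scotoma", count_absolute_scotomas(cohort, "control", "both"))
    summary$scotomas <- list(ADOA_count = sc$count,
                             ADOA_fraction = sc$fraction,
                             control_count = sc_c$count)
  }
  if ("bcea" %in% config$analyses) {
    bc <- stage("bcea", {
      idx <- which(cohort$eyes$is_analysis)
      by_g <- split(idx, cohort$eyes$group[idx])
      lapply(by_g, function(ii) {
        res <- lapply(cohort$fixation[ii], compute_bcea,
                      P = config$bcea_coverage)
        list(mean_area = mean(vapply(res, `[[`, numeric(1), "area")),
             mean_major = mean(vapply(res, `[[`, numeric(1), "major")),
             mean_minor = mean(vapply(res, `[[`, numeric(1), "minor")))
      })
    })
    summary$bcea <- bc
    emit_csv(data.frame(group = names(bc),
                        mean_area = vapply(bc, `[[`, numeric(1), "mean_area"),
                        mean_major = vapply(bc, `[[`, numeric(1), "mean_major"),
                        mean_minor = vapply(bc, `[[`, numeric(1), "mean_minor")),
             "bcea.csv")
  }
  if ("correlation" %in% config$analyses) {
    if (config$n_per_group < 3) {
      w <- "correlation skipped: fewer than 3 subjects per group"
      warnings <- c(warnings, w)
      warning(w, call. = FALSE)
      summary$correlation_r <- NA_real_
    } else {
      cr <- stage("correlation", rnfl_cross_correlation(cohort, "ADOA"))
      summary$correlation_r <- cr$r
      summary$correlation_p <- cr$p
    }
  }
  if ("roc" %in% config$analyses) {
    ad <- which(cohort$eyes$group == "ADOA" & cohort$eyes$is_analysis)
    zeros <- cohort$sensitivity[ad, , drop = FALSE] == 0
    if (all(zeros) || !any(zeros)) {
      w <- "ROC skipped: scotoma and non-scotoma points are not both present"
      warnings <- c(warnings, w)
      warning(w, call. = FALSE)
      summary$gcl_cutoff <- NA_real_
    } else {
      roc <- stage("roc", scotoma_roc(cohort))
      summary$gcl_cutoff <- roc$youden_cutoff
      summary$auc <- roc$auc
      summary$capture_rate_points <- roc$capture_rate
      if (!is.null(outdir)) write_roc_csv(roc, file.path(outdir, "roc.csv"))
    }
  }
  summary$warnings <- warnings
  if (!is.null(outdir)) {
    write_json_report(unclass(config), file.path(outdir, "config.json"))
    write_json_report(summary, file.path(outdir, "summary.json"))
    invisible(summary)
  } else summary
}

#' Command-line interface dispatcher
#'
#' Thin command dispatcher over the package functions, used by the
#' `inst/cli/ppmap` Rscript wrapper. Subcommands: `grid`, `simulate`,
#' `calibrate`, `overlay`, `stats`, `pointwise`, `bcea`, `roc`,
#' `reproduce`. Common flags: `--seed`, `--n` (subjects/group), `--out`
#' (output directory), `--eye` (OD/OS for `grid`), `--rotation`,
#' `--cohort` (a cohort CSV to analyse instead of simulating),
#' `--verbose`.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the result of the dispatched command.
#' @export
#' @examples
#' \donttest{
#' out <- tempfile()
#' pp_cli(c("grid", "--out", out))
#' }
pp_cli <- function(args) {
  if (!length(args)) stop("usage: ppmap <grid|simulate|calibrate|overlay|stats|pointwise|bcea|roc|reproduce> [--seed N] [--n N] [--out DIR] ...")
  cmd <- args[1]
  opt <- parse_cli_args(args[-1])
  seed <- as.integer(opt$seed %||% 1L)
  n <- as.integer(opt$n %||% 11L)
  outdir <- opt$out %||% "."
  verbose <- isTRUE(opt$verbose)
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  get_cohort <- function() {
    if (!is.null(opt$cohort)) read_cohort_csv(opt$cohort, opt$params)
    else generate_cohort(default_cohort_params(), n, seed)
  }
  t0 <- proc.time()[["elapsed"]]
  res <- switch(cmd,
    grid = {
      spec <- grid_spec(rotation = as.numeric(opt$rotation %||% 7))
      g <- generate_pp_grid(spec)
      if (!is.null(opt$eye)) g <- normalize_laterality(g, opt$eye, spec)
      write_grid_csv(g, file.path(outdir, "grid.csv"))
      write_grid_spec_json(spec, file.path(outdir, "grid_spec.json"))
      g
    },
    simulate = {
      coh <- generate_cohort(default_cohort_params(), n, seed)
      write_cohort_csv(coh, file.path(outdir, "cohort.csv"),
                       file.path(outdir, "params.json"))
      write_fixation_csv(coh, file.path(outdir, "fixation.csv"))
      coh
    },
    calibrate = {
      cal <- calibrate_defaults(
        seed = seed,
        n_subjects = as.integer(opt$`n-subjects` %||% 1000L),
        verbose = verbose)
      write_params_json(cal$params, file.path(outdir, "calibrated_params.json"))
      write_json_report(cal[c("converged", "iterations", "achieved")],
                        file.path(outdir, "calibration_report.json"))
      cal
    },
    overlay = {
      coh <- get_cohort()
      ei <- as.integer(opt$`eye-index` %||% 1L)
      m <- combined_map(coh, ei)
      write_map_csv(m, file.path(outdir, "combined_map.csv"))
      m
    },
    stats = {
      coh <- get_cohort()
      lt <- compare_layers(coh); st <- compare_sectors(coh)
      utils::write.csv(lt, file.path(outdir, "layers.csv"), row.names = FALSE)
      utils::write.csv(st, file.path(outdir, "sectors.csv"), row.names = FALSE)
      list(layers = lt, sectors = st)
    },
    pointwise = {
      coh <- get_cohort()
      pw <- pointwise_compare(coh)
      utils::write.csv(pw, file.path(outdir, "pointwise.csv"),
                       row.names = FALSE)
      pw
    },
    bcea = {
      coh <- get_cohort()
      idx <- which(coh$eyes$is_analysis)
      out <- do.call(rbind, lapply(idx, function(i) {
        b <- compute_bcea(coh$fixation[[i]])
        data.frame(subject = coh$eyes$subject_id[i],
                   group = coh$eyes$group[i], area = b$area,
                   major = b$major, minor = b$minor,
                   orientation = b$orientation)
      }))
      utils::write.csv(out, file.path(outdir, "bcea.csv"), row.names = FALSE)
      out
    },
    roc = {
      coh <- get_cohort()
      r <- scotoma_roc(coh)
      write_roc_csv(r, file.path(outdir, "roc.csv"))
      write_json_report(list(auc = r$auc, youden_cutoff = r$youden_cutoff,
                             youden_j = r$youden_j,
                             capture_rate = r$capture_rate),
                        file.path(outdir, "roc_summary.json"))
      r
    },
    reproduce = run_pipeline(default_run_config(seed = seed, n_per_group = n),
                             outdir),
    stop("unknown subcommand: ", cmd)
  )
  say("%s finished in %.2f s (seed %d)", cmd,
      proc.time()[["elapsed"]] - t0, seed)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_cli_args <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (key %in% c("verbose", "v")) {
      opt$verbose <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) stop("missing value for --", key)
      opt[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opt
}
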