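#' Read a flat pipeline configuration file
#'
#' The configuration is a plain-text file of \code{key: value} lines
#' (\code{#} comments and blank lines ignored). Exactly one input mode must
#' be active: either \code{ramet_csv} (with optional \code{calibration_csv})
#' for real data, or \code{n_ramets} for synthetic mode.
#'
#' Recognised keys: \code{ramet_csv}, \code{calibration_csv},
#' \code{raw_areas} (logical; sizes in the CSV are raw m^2 and must be
#' calibrated and log-transformed), \code{n_ramets}, \code{size_min},
#' \code{size_max}, \code{L}, \code{U}, \code{padding}, \code{n_mesh},
#' \code{n_boot}, \code{n_perturb}, \code{seed}, \code{out}.
#'
#' @param path configuration file path.
#' @return a named list of class \code{"pipeline_config"}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 0L) != 3L]
  if (length(bad)) stop("malformed config line(s): ", paste(bad, collapse = "; "))
  cfg <- stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, "", 2L))
  num_keys <- c("n_ramets", "size_min", "size_max", "L", "U", "padding",
                "n_mesh", "n_boot", "n_perturb", "seed")
  for (k in intersect(num_keys, names(cfg))) cfg[[k]] <- as.numeric(cfg[[k]])
  if (!is.null(cfg$raw_areas))
    cfg$raw_areas <- tolower(cfg$raw_areas) %in% c("true", "yes", "1")
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param config a named list of configuration values.
#' @export
validate_pipeline_config <- function(config) {
  has_file <- !is.null(config$ramet_csv)
  has_synth <- !is.null(config$n_ramets)
  if (has_file == has_synth)
    stop("config must set exactly one of 'ramet_csv' (file mode) or ",
         "'n_ramets' (synthetic mode)")
  if (!is.null(config$n_mesh) && config$n_mesh < 2)
    stop("n_mesh must be >= 2")
  structure(config, class = "pipeline_config")
}

cfg_get <- function(config, key, default) {
  v <- config[[key]]
  if (is.null(v) || (length(v) == 1L && is.na(v))) default else v
}

#' Run the full demographic analysis pipeline
#'
#' Orchestrates every stage end to end: load (and optionally calibrate) or
#' simulate the ramet table, fit all vital rates, run AIC model selection,
#' assemble and analyse the IPM, bootstrap confidence intervals, run the
#' flower-model perturbation analysis, and write the JSON results file.
#' Each stage is logged to \code{stderr}; any stage error aborts with the
#' stage name, and no partial results file is written.
#'
#' @param config a \code{"pipeline_config"} (see [read_pipeline_config()])
#'   or a plain named list with the same keys.
#' @param seed integer seed overriding the config; stage-local seeds are
#'   derived from it by fixed offsets so stages are independently
#'   reproducible.
#' @param out output JSON path overriding the config.
#' @return the fitted \code{"ramet_ipm"} with bootstrap CIs attached
#'   (invisibly); side effect: the results file, if a path was given.
#' @export
run_pipeline <- function(config, seed = NULL, out = NULL) {
  config <- validate_pipeline_config(config)
  seed <- as.integer(if (!is.null(seed)) seed else cfg_get(config, "seed", 1L))
  out <- if (!is.null(out)) out else config$out
  log_stage <- function(...) message(format(Sys.time(), "%H:%M:%S"), " [",
                                     ..., "]")
  stage <- function(name, expr) {
    log_stage(name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  data <- if (!is.null(config$ramet_csv)) {
    stage("load", {
      d <- read_ramet_table(config$ramet_csv)
      if (isTRUE(config$raw_areas)) {
        if (is.null(config$calibration_csv))
          stop("raw_areas = true needs 'calibration_csv'")
        cal_tab <- utils::read.csv(config$calibration_csv)
        cal <- calibrate_sizes(cal_tab$measured, cal_tab$true)
        d <- apply_size_correction(d, cal)
      }
      d
    })
  } else {
    stage("simulate", {
      simulate_ramets(reference_params(),
                      n_ramets = cfg_get(config, "n_ramets", 276L),
                      size_range = c(cfg_get(config, "size_min", -6.04),
                                     cfg_get(config, "size_max", 3.31)),
                      seed = seed + 101L)
    })
  }

  fit <- stage("fit", {
    n_t <- sum(data$is_recruit %in% 0L)
    f <- ipm_fit(data,
                 n_mesh = cfg_get(config, "n_mesh", 100L),
                 padding = cfg_get(config, "padding", 0.8),
                 L = config$L, U = config$U, select = TRUE)
    message("  n_t = ", n_t, ", lambda = ", signif(f$lambda, 6),
            ", e_P = ", signif(f$e_P, 4), ", e_F = ", signif(f$e_F, 4))
    for (s in f$selection)
      message("  ", s$rate, ": selected ", s$selected)
    f
  })

  n_boot <- cfg_get(config, "n_boot", 1000L)
  if (n_boot >= 1) {
    bt <- stage("bootstrap", ipm_boot(fit, n_reps = n_boot,
                                      seed = seed + 202L))
    fit <- add_boot_ci(fit, bt)
    message("  lambda CI (", signif(fit$ci_lambda[1], 4), ", ",
            signif(fit$ci_lambda[2], 4), "), ", bt$n_failed,
            " failed replicates")
  }

  n_perturb <- cfg_get(config, "n_perturb", 0L)
  if (n_perturb >= 1) {
    fit$perturb <- stage("perturb",
                         perturb_flower_model(fit, n_draws = n_perturb,
                                              seed = seed + 303L))
  }

  if (!is.null(out)) {
    stage("write", write_ipm_results(fit, out, seed = seed,
                                     parameterization = if (is.null(config$ramet_csv))
                                       "synthetic-reference" else "fitted"))
    message("  wrote ", out)
  }
  invisible(fit)
}

#' Plain-text summary of an IPM analysis
#'
#' Renders the growth rate with its confidence interval, the sub-kernel
#' elasticities, any AIC selection tables, and an optional mesh-convergence
#' table. Every number comes straight from the supplied objects; nothing is
#' recomputed.
#'
#' @param result a \code{"ramet_ipm"}.
#' @param mesh_table optional data.frame from [mesh_convergence()].
#' @return a single character string (cat-ready).
#' @export
report_summary <- function(result, mesh_table = NULL) {
  stopifnot(inherits(result, "ramet_ipm"))
  fmt_ci <- function(ci) if (is.null(ci)) "not computed"
    else sprintf("(%.3g, %.3g)", ci[1], ci[2])
  lines <- c(
    "Ramet IPM analysis summary",
    "==========================",
    sprintf("per-capita growth rate lambda: %.3g", result$lambda),
    sprintf("  95%% CI: %s", fmt_ci(result$ci_lambda)),
    sprintf("sub-kernel elasticities: e_P = %.3g %s, e_F = %.3g %s",
            result$e_P, fmt_ci(result$ci_e_P),
            result$e_F, fmt_ci(result$ci_e_F)),
    sprintf("grid: [%.4g, %.4g], %d meshpoints",
            result$grid$L, result$grid$U, result$grid$n_mesh))
  if (!is.null(result$selection)) {
    lines <- c(lines, "", "AIC model selection:")
    for (s in result$selection) {
      lines <- c(lines, sprintf("  %s (selected: %s)", s$rate, s$selected))
      ok <- !is.na(s$candidates$aic)
      lines <- c(lines, sprintf("    %-10s k=%d AIC=%.2f dAIC=%.2f",
                                s$candidates$label[ok], s$candidates$k[ok],
                                s$candidates$aic[ok],
                                s$candidates$delta_aic[ok]))
    }
  }
  if (!is.null(mesh_table) && nrow(mesh_table)) {
    lines <- c(lines, "", "mesh convergence:",
               sprintf("  n_mesh=%d lambda=%.8f delta=%s",
                       mesh_table$n_mesh, mesh_table$lambda,
                       ifelse(is.na(mesh_table$delta), "-",
                              sprintf("%.2e", mesh_table$delta))))
  }
  paste(lines, collapse = "\n")
}
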