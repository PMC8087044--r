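#' Fit a ramet integral projection model
#'
#' The main entry point of the package: fits all size-dependent vital rates
#' on a one-transition ramet table, assembles the two-sub-kernel IPM
#' \deqn{n(z', t+1) = \int_L^U [P(z', z) + F(z', z)]\, n(z, t)\, dz,}
#' discretises it by the midpoint rule, and performs the asymptotic
#' analysis: per-capita growth rate \eqn{\lambda}, stable size distribution,
#' reproductive value, sensitivity and elasticity kernels, and sub-kernel
#' elasticities.
#'
#' The domain defaults to the observed size range padded by \code{padding}
#' on each side; growth densities are renormalised on the domain and the
#' recruit density truncated to it, so no probability mass is evicted at
#' the boundaries.
#'
#' @param data a ramet \code{data.frame} (schema of [simulate_ramets()]),
#'   sizes already on the natural-log m^2 scale (see
#'   [apply_size_correction()] for raw areas).
#' @param n_mesh number of meshpoints (default 100).
#' @param padding domain padding beyond the observed size range (log m^2).
#' @param L,U explicit domain bounds, overriding \code{padding}.
#' @param select run [select_by_aic()] for each regression rate and keep the
#'   tables on the result (the kernel itself always uses the linear forms,
#'   the structure the vital-rate parameterisation defines).
#' @return An object of class \code{"ramet_ipm"}; see Details.
#' @details The returned object has fields \code{lambda}, \code{w},
#'   \code{v}, \code{sensitivity}, \code{elasticity}, \code{e_P},
#'   \code{e_F}, \code{kernels}, \code{grid}, \code{params}, \code{fits}
#'   (NULL when built from parameters alone), \code{selection} (optional
#'   AIC tables), \code{data}, and optional bootstrap fields
#'   \code{ci_lambda}, \code{ci_e_P}, \code{ci_e_F} filled in by
#'   [ipm_boot()]. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{plot}, \code{simulate}.
#' @examples
#' d <- simulate_ramets(reference_params(), 1000, seed = 1)
#' fit <- ipm_fit(d)
#' fit$lambda
#' @seealso [ipm_from_params()], [ipm_boot()], [mesh_convergence()]
#' @export
ipm_fit <- function(data, n_mesh = 100L, padding = 0.8, L = NULL, U = NULL,
                    select = FALSE) {
  validate_ramet_table(data)
  rng <- range(c(data$size_t, data$size_t1), na.rm = TRUE)
  if (is.null(L)) L <- rng[1] - padding
  if (is.null(U)) U <- rng[2] + padding
  fits <- fit_vital_rates(data, recruit_bounds = c(L, U))
  params <- params_from_fits(fits)
  obj <- ipm_from_params(params, ipm_grid(L, U, n_mesh))
  obj$fits <- fits
  obj$data <- data
  if (select)
    obj$selection <- lapply(
      stats::setNames(nm = c("survival", "growth", "flowering",
                             "flower_count")),
      function(r) select_by_aic(data, r))
  obj$call <- match.call()
  obj
}

#' Model-implied IPM from a parameter set
#'
#' Builds and analyses the IPM directly from a [vital_rate_params()] object,
#' with no data: useful for the generating model of a simulation study or
#' for perturbation analyses.
#'
#' @param params a [vital_rate_params()] object.
#' @param grid an [ipm_grid()].
#' @return A \code{"ramet_ipm"} object (with \code{fits = NULL}).
#' @export
ipm_from_params <- function(params, grid) {
  kern <- build_kernels(params, grid)
  eig <- asymptotic_growth_rate(kern)
  sens <- sensitivity_kernel(eig$v, eig$w, grid$h)
  elas <- elasticity_kernel(kern$K, eig$lambda, sens, grid$h)
  esub <- subkernel_elasticities(kern$P, kern$F, elas, grid$h)
  structure(list(lambda = eig$lambda, w = eig$w, v = eig$v,
                 sensitivity = sens, elasticity = elas,
                 e_P = unname(esub["e_P"]), e_F = unname(esub["e_F"]),
                 kernels = kern, grid = grid, params = params,
                 fits = NULL, data = NULL,
                 ci_lambda = NULL, ci_e_P = NULL, ci_e_F = NULL),
            class = "ramet_ipm")
}

#' @export
print.ramet_ipm <- function(x, ...) {
  cat("Ramet integral projection model\n")
  print(x$grid)
  ci <- if (!is.null(x$ci_lambda))
    sprintf(" (95%% CI %.3f, %.3f)", x$ci_lambda[1], x$ci_lambda[2]) else ""
  cat(sprintf("  lambda = %.4f%s\n", x$lambda, ci))
  cat(sprintf("  sub-kernel elasticities: e_P = %.4f, e_F = %.4f\n",
              x$e_P, x$e_F))
  invisible(x)
}

#' @export
summary.ramet_ipm <- function(object, ...) {
  structure(list(ipm = object), class = "summary.ramet_ipm")
}

#' @export
print.summary.ramet_ipm <- function(x, ...) {
  print(x$ipm)
  if (!is.null(x$ipm$fits)) {
    cat("\nVital-rate fits:\n")
    print(x$ipm$fits)
  } else {
    cat("\nParameterisation:\n")
    print(x$ipm$params)
  }
  if (!is.null(x$ipm$selection)) {
    cat("\n")
    for (s in x$ipm$selection) print(s)
  }
  invisible(x)
}

#' @export
coef.ramet_ipm <- function(object, ...) {
  p <- unclass(object$params)
  unlist(p)
}

#' Predict vital rates from a fitted IPM
#'
#' @param object a \code{"ramet_ipm"}.
#' @param newdata numeric vector of sizes (log m^2), or a data.frame with a
#'   \code{size} column.
#' @param rate which vital rate to evaluate: survival or flowering
#'   probability, growth mean or SD, or expected flower count.
#' @param ... unused.
#' @return numeric vector of predictions at the given sizes.
#' @export
predict.ramet_ipm <- function(object, newdata,
                              rate = c("survival", "growth_mean", "growth_sd",
                                       "flowering", "flower_count"), ...) {
  rate <- match.arg(rate)
  z <- if (is.data.frame(newdata)) newdata$size else newdata
  p <- object$params
  switch(rate,
         survival = sv_prob(p, z),
         growth_mean = gr_mean(p, z),
         growth_sd = gr_sd(p, z),
         flowering = fl_prob(p, z),
         flower_count = fc_mean(p, z))
}

#' @export
plot.ramet_ipm <- function(x, which = c("elasticity", "sensitivity",
                                        "kernel", "stable"), ...) {
  which <- match.arg(which)
  z <- x$grid$meshpoints
  if (which == "stable") {
    graphics::plot(z, x$w, type = "l", xlab = "size z (log m²)",
                   ylab = "stable size density w(z)", ...)
    return(invisible(x))
  }
  M <- switch(which, elasticity = x$elasticity, sensitivity = x$sensitivity,
              kernel = x$kernels$K)
  graphics::image(z, z, t(M), xlab = "size z at t (log m²)",
                  ylab = "size z' at t+1 (log m²)",
                  main = paste(which, "surface"), ...)
  invisible(x)
}

#' Simulate datasets from a fitted IPM
#'
#' Draws new one-transition ramet tables from the fitted (or supplied)
#' parameterisation, mirroring the design of the original data.
#'
#' @param object a \code{"ramet_ipm"}.
#' @param nsim number of datasets.
#' @param seed optional integer seed.
#' @param n_ramets ramets per dataset; defaults to the number of time-t rows
#'   of the fitting data, or 276 for a parameter-only model.
#' @param ... passed to [simulate_ramets()].
#' @return a list of \code{nsim} data.frames (a single data.frame if
#'   \code{nsim = 1}).
#' @export
simulate.ramet_ipm <- function(object, nsim = 1, seed = NULL,
                               n_ramets = NULL, ...) {
  if (is.null(n_ramets))
    n_ramets <- if (!is.null(object$data))
      sum(object$data$is_recruit %in% 0L) else 276L
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(i)
    simulate_ramets(object$params, n_ramets, ...))
  if (nsim == 1) out[[1]] else out
}
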