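#' Vital-rate regression fits
#'
#' Each \code{fit_*()} function fits one size-dependent vital rate by
#' maximum likelihood on the appropriate subset of a ramet table and returns
#' a \code{"vital_rate_fit"} object carrying named coefficients, standard
#' errors, the log-likelihood, AIC, sample size and (for flower counts) the
#' quasi-Poisson dispersion. Recruits (rows with \code{is_recruit == 1})
#' never enter the regression fits; only their \code{size_t1} feeds
#' [fit_recruit_size()].
#'
#' @name vital_rate_fits
#' @seealso [fit_vital_rates()] to fit everything at once, [select_by_aic()]
#'   for model selection among candidate forms.
NULL

new_vr_fit <- function(rate, coefficients, se, logLik, aic, n,
                       dispersion = NULL, vcov = NULL, formula = "~ size",
                       converged = TRUE) {
  structure(list(rate = rate, coefficients = coefficients,
                 standard_errors = se, logLik = logLik, aic = aic, n = n,
                 dispersion = dispersion, vcov = vcov, formula = formula,
                 converged = converged),
            class = "vital_rate_fit")
}

#' @export
print.vital_rate_fit <- function(x, ...) {
  cat(sprintf("Vital-rate fit: %s (%s), n = %d\n", x$rate, x$formula, x$n))
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$standard_errors)
  print(round(tab, 4))
  cat(sprintf("  logLik = %.3f, AIC = %.2f", x$logLik, x$aic))
  if (!is.null(x$dispersion))
    cat(sprintf(", dispersion = %.3f", x$dispersion))
  cat("\n")
  invisible(x)
}

#' @export
coef.vital_rate_fit <- function(object, ...) object$coefficients

#' @export
logLik.vital_rate_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients), class = "logLik")
}

# shared logistic-regression backbone for survival and flowering
fit_logistic <- function(z, y, rate, coef_names) {
  keep <- !is.na(z) & !is.na(y)
  z <- z[keep]; y <- y[keep]
  if (length(y) < 2) stop(rate, " fit needs at least 2 records")
  if (length(unique(y)) < 2)
    stop(rate, " response is constant (degenerate); both outcomes required")
  # separation is diagnosed explicitly below; glm's own warning adds noise
  fit <- suppressWarnings(stats::glm(y ~ z, family = stats::binomial()))
  if (!fit$converged || any(abs(stats::coef(fit)) > 15))
    stop(rate, " fit shows complete or quasi-complete separation ",
         "(coefficients diverge); check the data")
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  names(cf) <- names(se) <- coef_names
  V <- stats::vcov(fit); dimnames(V) <- list(coef_names, coef_names)
  ll <- as.numeric(stats::logLik(fit))
  new_vr_fit(rate, cf, se, ll, -2 * ll + 2 * length(cf), length(y), vcov = V)
}

#' @rdname vital_rate_fits
#' @param data a ramet \code{data.frame} (see [simulate_ramets()] for the
#'   schema).
#' @return A \code{"vital_rate_fit"} object.
#' @examples
#' d <- simulate_ramets(reference_params(), 1000, seed = 1)
#' fit_survival(d)
#' @export
fit_survival <- function(data) {
  est <- data$is_recruit %in% 0L
  fit_logistic(data$size_t[est], data$survived[est], "survival",
               c("beta0_s", "beta1_s"))
}

#' @rdname vital_rate_fits
#' @export
fit_flowering <- function(data) {
  est <- data$is_recruit %in% 0L
  fit_logistic(data$size_t[est], data$flowered[est], "flowering",
               c("beta0_pr", "beta1_pr"))
}

#' @rdname vital_rate_fits
#' @details \code{fit_growth()} jointly maximises the Gaussian likelihood of
#' size at t+1 with mean \eqn{\beta_{0,g} + \beta_{1,g} z} and standard
#' deviation \eqn{\sigma_{0,g} e^{\beta_{\sigma,g} z}}; with
#' \code{betasigma_g = 0} it reduces exactly to ordinary least squares.
#' Optimisation is BFGS on \eqn{(\beta_{0,g}, \beta_{1,g}, \log\sigma_{0,g},
#' \beta_{\sigma,g})} started from the OLS solution; standard errors come
#' from the numerically differentiated Hessian at the optimum
#' (delta-method back-transformed for \code{sigma0_g}).
#' @export
fit_growth <- function(data) {
  est <- data$is_recruit %in% 0L
  keep <- est & !is.na(data$size_t) & data$survived %in% 1L &
    !is.na(data$size_t1)
  z <- data$size_t[keep]; y <- data$size_t1[keep]
  if (length(y) < 3) stop("growth fit needs at least 3 survivor records")
  ols <- stats::lm(y ~ z)
  r <- stats::resid(ols)
  if (stats::sd(r) < 1e-12)
    stop("growth fit rejected: zero residual variance")
  nll <- function(th) {
    sdv <- exp(th[3] + th[4] * z)
    -sum(stats::dnorm(y, th[1] + th[2] * z, sdv, log = TRUE))
  }
  start <- c(stats::coef(ols), log(stats::sd(r)), 0)
  opt <- stats::optim(start, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("growth likelihood optimisation failed to converge (optim code ",
         opt$convergence, "): ", opt$message)
  th <- opt$par
  V <- tryCatch(solve(opt$hessian), error = function(e)
    stop("growth fit: singular Hessian, standard errors unavailable"))
  se <- sqrt(pmax(diag(V), 0))
  cf <- c(th[1], th[2], exp(th[3]), th[4])
  se <- c(se[1], se[2], exp(th[3]) * se[3], se[4])  # delta method for sigma0
  nms <- c("beta0_g", "beta1_g", "sigma0_g", "betasigma_g")
  names(cf) <- names(se) <- nms
  dimnames(V) <- list(nms, nms)  # vcov on the (b0, b1, log sigma0, bsg) scale
  ll <- -opt$value
  new_vr_fit("growth", cf, se, ll, -2 * ll + 2 * 4, length(y), vcov = V)
}

#' @rdname vital_rate_fits
#' @details \code{fit_flower_count()} fits the log-linear Poisson mean
#' structure on flowering ramets only (the conditional-on-flowering mean),
#' then estimates the dispersion \eqn{\phi} as the Pearson chi-square over
#' residual degrees of freedom and scales the standard errors by
#' \eqn{\sqrt{\phi}} (quasi-Poisson).
#' @export
fit_flower_count <- function(data) {
  est <- data$is_recruit %in% 0L
  keep <- est & data$flowered %in% 1L & !is.na(data$n_flowers) &
    !is.na(data$size_t)
  z <- data$size_t[keep]; y <- data$n_flowers[keep]
  if (length(y) < 2) stop("flower-count fit needs at least 2 flowering records")
  if (stats::var(y) == 0)
    stop("flower-count dispersion undefined: all counts equal")
  fit <- stats::glm(y ~ z, family = stats::poisson())
  phi <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit))) * sqrt(phi)
  nms <- c("beta0_rs", "beta1_rs")
  names(cf) <- names(se) <- nms
  V <- stats::vcov(fit) * phi; dimnames(V) <- list(nms, nms)
  ll <- as.numeric(stats::logLik(fit))
  new_vr_fit("flower_count", cf, se, ll, -2 * ll + 2 * 2, length(y),
             dispersion = phi, vcov = V)
}

#' Truncated-normal recruit-size fit
#'
#' Maximum-likelihood location and scale of a normal distribution truncated
#' to \code{bounds}, for the sizes of newly recruited ramets. With very wide
#' bounds the estimates coincide with the untruncated sample ML (mean and
#' the 1/n-denominator SD).
#'
#' @param recruit_sizes numeric vector of recruit sizes (log m^2), length
#'   >= 2, all inside \code{bounds}.
#' @param bounds length-2 numeric truncation interval, typically the IPM
#'   domain \code{c(L, U)}.
#' @return A \code{"vital_rate_fit"} with coefficients \code{mu_rd},
#'   \code{sigma_rd}.
#' @export
fit_recruit_size <- function(recruit_sizes, bounds) {
  x <- recruit_sizes
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  if (length(x) < 2) stop("recruit-size fit needs at least 2 sizes")
  out <- which(x < bounds[1] | x > bounds[2])
  if (length(out))
    stop("recruit sizes outside bounds at position(s): ",
         paste(out, collapse = ", "))
  if (stats::sd(x) < 1e-10)
    stop("recruit-size fit degenerate: zero sample variance")
  nll <- function(th) {
    mu <- th[1]; sg <- exp(th[2])
    Z <- stats::pnorm(bounds[2], mu, sg) - stats::pnorm(bounds[1], mu, sg)
    if (Z <= 0) return(1e10)
    -sum(stats::dnorm(x, mu, sg, log = TRUE)) + length(x) * log(Z)
  }
  start <- c(mean(x), log(stats::sd(x)))
  opt <- stats::optim(start, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("recruit-size optimisation failed to converge (optim code ",
         opt$convergence, ")")
  th <- opt$par
  V <- tryCatch(solve(opt$hessian),
                error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(V), 0))
  cf <- c(mu_rd = th[1], sigma_rd = exp(th[2]))
  se <- c(mu_rd = se[1], sigma_rd = exp(th[2]) * se[2])
  ll <- -opt$value
  new_vr_fit("recruit_size", cf, se, ll, -2 * ll + 2 * 2, length(x), vcov = V)
}

#' Recruits-per-flower rate
#'
#' The establishment rate converting flower production into new ramets:
#' the number of recruits observed at t+1 divided by the total number of
#' flowers produced at t (flower production is assumed roughly time
#' invariant over the one-year recruitment lag).
#'
#' @param n_recruits nonnegative recruit count at t+1.
#' @param total_flowers positive total flower count at t.
#' @return the rate \code{n_recruits / total_flowers}.
#' @examples
#' estimate_recruitment_rate(10, 1000)   # 0.01
#' @export
estimate_recruitment_rate <- function(n_recruits, total_flowers) {
  stopifnot(n_recruits >= 0)
  if (is.na(total_flowers) || total_flowers < 1)
    stop("recruitment rate undefined: total_flowers must be >= 1")
  n_recruits / total_flowers
}

#' AIC model selection among candidate size dependencies
#'
#' Fits intercept-only, linear and quadratic size dependencies for the named
#' vital rate and selects the most parsimonious adequate model: the
#' candidate with the fewest parameters whose AIC lies within
#' \code{tie_delta} of the minimum. For \code{flower_count} the selection
#' uses the Poisson AIC of the mean structure (quasi-likelihood has no AIC);
#' the dispersion is then estimated on the selected model. Candidate fit
#' failures are recorded and selection proceeds over the successes.
#'
#' @param data a ramet \code{data.frame}.
#' @param rate one of \code{"survival"}, \code{"growth"}, \code{"flowering"},
#'   \code{"flower_count"}.
#' @param tie_delta AIC margin treated as a tie (default 2).
#' @return An object of class \code{"model_selection"}: a list with a
#'   \code{candidates} data.frame (label, k, aic, delta_aic, error) and the
#'   \code{selected} label.
#' @export
select_by_aic <- function(data, rate = c("survival", "growth", "flowering",
                                         "flower_count"), tie_delta = 2) {
  rate <- match.arg(rate)
  est <- data$is_recruit %in% 0L
  sub <- switch(rate,
    survival = list(z = data$size_t[est], y = data$survived[est],
                    fam = stats::binomial()),
    flowering = list(z = data$size_t[est], y = data$flowered[est],
                     fam = stats::binomial()),
    flower_count = {
      k <- est & data$flowered %in% 1L
      list(z = data$size_t[k], y = data$n_flowers[k], fam = stats::poisson())
    },
    growth = {
      k <- est & data$survived %in% 1L & !is.na(data$size_t1)
      list(z = data$size_t[k], y = data$size_t1[k], fam = NULL)
    })
  keep <- !is.na(sub$z) & !is.na(sub$y)
  z <- sub$z[keep]; y <- sub$y[keep]
  labels <- c("intercept", "linear", "quadratic")
  fit_one <- function(degree) {
    X <- switch(degree + 1L, y ~ 1, y ~ z, y ~ z + I(z^2))
    if (rate == "growth") {
      # Gaussian with SD sigma0 * exp(bsg * z); mean structure varies
      nll <- function(th) {
        k <- degree + 1L
        mu <- th[1] + if (degree >= 1) th[2] * z else 0
        if (degree >= 2) mu <- mu + th[3] * z^2
        sdv <- exp(th[k + 1] + th[k + 2] * z)
        -sum(stats::dnorm(y, mu, sdv, log = TRUE))
      }
      start <- c(stats::coef(stats::lm(X)), log(stats::sd(y)), 0)
      opt <- stats::optim(start, nll, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12))
      if (opt$convergence != 0) stop("optim code ", opt$convergence)
      k <- degree + 3L
      list(aic = 2 * opt$value + 2 * k, k = k)
    } else {
      f <- stats::glm(X, family = sub$fam)
      list(aic = stats::AIC(f), k = length(stats::coef(f)))
    }
  }
  cand <- data.frame(label = labels, k = NA_real_, aic = NA_real_,
                     error = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(labels)) {
    res <- tryCatch(fit_one(i - 1L), error = function(e) e)
    if (inherits(res, "error")) cand$error[i] <- conditionMessage(res)
    else { cand$aic[i] <- res$aic; cand$k[i] <- res$k }
  }
  if (all(is.na(cand$aic))) stop("all candidate fits failed for ", rate)
  cand$delta_aic <- cand$aic - min(cand$aic, na.rm = TRUE)
  ok <- which(!is.na(cand$aic) & cand$delta_aic <= tie_delta)
  selected <- cand$label[ok[which.min(cand$k[ok])]]
  structure(list(rate = rate, candidates = cand, selected = selected,
                 tie_delta = tie_delta),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("AIC model selection for", x$rate, "\n")
  print(x$candidates[c("label", "k", "aic", "delta_aic")], row.names = FALSE,
        digits = 6)
  cat("selected:", x$selected, "\n")
  invisible(x)
}

#' Fit all vital rates of the ramet IPM
#'
#' Convenience wrapper running [fit_survival()], [fit_growth()],
#' [fit_flowering()], [fit_flower_count()], [fit_recruit_size()] (on the
#' sizes of recruit rows) and [estimate_recruitment_rate()] on one dataset.
#'
#' @param data a ramet \code{data.frame}.
#' @param recruit_bounds truncation interval for the recruit-size fit,
#'   typically the IPM domain. Defaults to the observed size range padded by
#'   \code{padding}.
#' @param padding domain padding (log m^2) used when \code{recruit_bounds}
#'   is not given.
#' @param strict_recruits if \code{FALSE}, a degenerate recruit-size fit
#'   (fewer than two distinct sizes) yields \code{recruit_size = NULL}
#'   instead of an error, letting the caller substitute fallback values;
#'   used by the bootstrap, where tiny recruit samples are routinely
#'   resampled into identical copies.
#' @return A list of class \code{"vital_rate_fits"} with one element per
#'   rate plus \code{r_r}, \code{n_recruits} and \code{total_flowers}.
#' @export
fit_vital_rates <- function(data, recruit_bounds = NULL, padding = 0.8,
                            strict_recruits = TRUE) {
  if (is.null(recruit_bounds)) {
    rng <- range(c(data$size_t, data$size_t1), na.rm = TRUE)
    recruit_bounds <- c(rng[1] - padding, rng[2] + padding)
  }
  rec <- data$is_recruit %in% 1L
  total_flowers <- sum(data$n_flowers[data$is_recruit %in% 0L], na.rm = TRUE)
  fits <- list(
    survival = fit_survival(data),
    growth = fit_growth(data),
    flowering = fit_flowering(data),
    flower_count = fit_flower_count(data),
    recruit_size = if (sum(rec) >= 2) {
      if (strict_recruits) fit_recruit_size(data$size_t1[rec], recruit_bounds)
      else tryCatch(fit_recruit_size(data$size_t1[rec], recruit_bounds),
                    error = function(e) NULL)
    } else NULL,
    r_r = if (total_flowers >= 1)
      estimate_recruitment_rate(sum(rec), total_flowers) else NA_real_,
    n_recruits = sum(rec),
    total_flowers = total_flowers,
    recruit_bounds = recruit_bounds)
  class(fits) <- "vital_rate_fits"
  fits
}

#' @export
print.vital_rate_fits <- function(x, ...) {
  for (nm in c("survival", "growth", "flowering", "flower_count",
               "recruit_size"))
    if (!is.null(x[[nm]])) { print(x[[nm]]); cat("\n") }
  cat(sprintf("recruits per flower r_r = %g (%d recruits / %d flowers)\n",
              x$r_r, x$n_recruits, x$total_flowers))
  invisible(x)
}

#' Assemble a parameter set from fitted vital rates
#'
#' @param fits a [fit_vital_rates()] result.
#' @param fallback a [vital_rate_params()] object supplying values for any
#'   component that could not be fitted (e.g. recruit sizes when no recruits
#'   were observed); defaults to [reference_params()].
#' @return A [vital_rate_params()] object built from the estimates.
#' @export
params_from_fits <- function(fits, fallback = reference_params()) {
  stopifnot(inherits(fits, "vital_rate_fits"))
  cf <- function(fit, nm) unname(fit$coefficients[nm])
  rs <- fits$recruit_size
  vital_rate_params(
    beta0_s = cf(fits$survival, "beta0_s"),
    beta1_s = cf(fits$survival, "beta1_s"),
    beta0_g = cf(fits$growth, "beta0_g"),
    beta1_g = cf(fits$growth, "beta1_g"),
    sigma0_g = cf(fits$growth, "sigma0_g"),
    betasigma_g = cf(fits$growth, "betasigma_g"),
    beta0_pr = cf(fits$flowering, "beta0_pr"),
    beta1_pr = cf(fits$flowering, "beta1_pr"),
    beta0_rs = cf(fits$flower_count, "beta0_rs"),
    beta1_rs = cf(fits$flower_count, "beta1_rs"),
    phi = fits$flower_count$dispersion,
    mu_rd = if (!is.null(rs)) cf(rs, "mu_rd") else fallback$mu_rd,
    sigma_rd = if (!is.null(rs)) cf(rs, "sigma_rd") else fallback$sigma_rd,
    r_r = if (is.finite(fits$r_r)) fits$r_r else fallback$r_r)
}
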