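#' Simulate a one-transition ramet dataset
#'
#' Generates a year-over-year table of ramet fates with exactly the
#' statistical structure the demographic analysis assumes: sizes at time t
#' drawn uniformly over \code{size_range}, logistic survival, Gaussian growth
#' with exponentially size-varying residual SD, logistic flowering,
#' overdispersed flower counts conditioned on flowering, and Poisson
#' recruitment with truncated-normal recruit sizes.
#'
#' Flower counts for flowering ramets are drawn from a zero-truncated count
#' distribution whose *conditional* mean equals
#' \eqn{e^{\beta_{0,rs} + \beta_{1,rs} z}}, so the log-linear count
#' regression is the exact estimand of a (quasi-)Poisson refit. Where the
#' target mean admits the nominal dispersion \code{phi} the distribution is a
#' zero-truncated negative binomial with untruncated variance
#' \eqn{\phi \mu}; a zero-truncated count with variance \eqn{\phi\mu} cannot
#' have conditional mean below \eqn{(\phi-1)/\log\phi}, so below that the
#' generator falls back to a zero-truncated Poisson (mean floor 1), and
#' target means below 1 — unattainable for any count that is at least 1 —
#' are floored at 1. See the package vignette for the rationale.
#'
#' @param params a [vital_rate_params()] object.
#' @param n_ramets number of ramets alive at time t (>= 1).
#' @param size_range length-2 numeric, the support of sizes at t
#'   (natural-log m^2). Default is the observed range of the reference
#'   study, \code{c(-6.04, 3.31)}.
#' @param seed optional integer; when given the output is reproducible
#'   bit-for-bit.
#' @param year_t,year_t1 labels stored as attributes.
#' @return A \code{data.frame} with one row per ramet (time-t ramets first,
#'   then recruits) and columns \code{ramet_id}, \code{size_t},
#'   \code{survived}, \code{size_t1}, \code{flowered}, \code{n_flowers},
#'   \code{is_recruit}. Recruits have \code{size_t}, \code{survived},
#'   \code{flowered} and \code{n_flowers} set to \code{NA}.
#' @examples
#' d <- simulate_ramets(reference_params(), 276, seed = 1)
#' table(d$survived, useNA = "ifany")
#' @export
simulate_ramets <- function(params, n_ramets,
                            size_range = c(-6.04, 3.31), seed = NULL,
                            year_t = 2018L, year_t1 = 2019L) {
  validate_params(params)
  stopifnot(n_ramets >= 1, length(size_range) == 2, all(is.finite(size_range)),
            size_range[1] < size_range[2])
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_ramets)
  z <- stats::runif(n, size_range[1], size_range[2])
  survived <- stats::rbinom(n, 1L, sv_prob(params, z))
  size_t1 <- rep(NA_real_, n)
  alive <- survived == 1L
  size_t1[alive] <- stats::rnorm(sum(alive), gr_mean(params, z[alive]),
                                 gr_sd(params, z[alive]))
  flowered <- stats::rbinom(n, 1L, fl_prob(params, z))
  n_flowers <- rep(0L, n)
  fl <- flowered == 1L
  if (any(fl))
    n_flowers[fl] <- rcount_conditional(fc_mean(params, z[fl]), params$phi)

  total_flowers <- sum(n_flowers)
  n_rec <- stats::rpois(1L, params$r_r * total_flowers)
  rec_sizes <- if (n_rec > 0)
    rtrunc_norm(n_rec, params$mu_rd, params$sigma_rd,
                size_range[1], size_range[2]) else numeric(0)

  out <- data.frame(
    ramet_id = c(sprintf("R%04d", seq_len(n)),
                 if (n_rec > 0) sprintf("N%04d", seq_len(n_rec))),
    size_t = c(z, rep(NA_real_, n_rec)),
    survived = c(survived, rep(NA_integer_, n_rec)),
    size_t1 = c(size_t1, rec_sizes),
    flowered = c(flowered, rep(NA_integer_, n_rec)),
    n_flowers = c(n_flowers, rep(NA_integer_, n_rec)),
    is_recruit = c(rep(0L, n), rep(1L, n_rec)),
    stringsAsFactors = FALSE)
  attr(out, "year_t") <- year_t
  attr(out, "year_t1") <- year_t1
  out
}

#' Zero-truncated count draws with a log-linear conditional mean
#'
#' Internal sampler behind [simulate_ramets()]. Draws counts \eqn{\ge 1}
#' whose conditional mean equals \code{target_mean} elementwise wherever a
#' zero-truncated count can attain it (i.e. \code{target_mean} > 1).
#'
#' @param target_mean vector of desired conditional means.
#' @param phi nominal untruncated dispersion (variance = phi * mean).
#' @return integer vector of counts, all >= 1.
#' @keywords internal
rcount_conditional <- function(target_mean, phi) {
  m <- pmax(target_mean, 1 + 1e-9)
  nb_floor <- if (phi > 1) (phi - 1) / log(phi) else 1
  use_nb <- phi > 1 & m > nb_floor + 1e-9
  mu <- numeric(length(m))
  if (any(use_nb))  mu[use_nb]  <- solve_untrunc_mean(m[use_nb], phi)
  if (any(!use_nb)) mu[!use_nb] <- solve_untrunc_mean(m[!use_nb], 1)
  # inverse CDF on the upper tail: q = (1 - u) * P(Y >= 1) stays strictly
  # positive even where P(Y >= 1) is at the edge of double precision, so
  # the quantile never degenerates to Inf at tiny means
  u <- stats::runif(length(m))
  y <- integer(length(m))
  if (any(!use_nb)) {               # zero-truncated Poisson
    p_pos <- -expm1(-mu[!use_nb])
    y[!use_nb] <- stats::qpois((1 - u[!use_nb]) * p_pos, mu[!use_nb],
                               lower.tail = FALSE)
  }
  if (any(use_nb)) {                # zero-truncated NB, size = mu/(phi-1)
    sz <- mu[use_nb] / (phi - 1)
    p_pos <- 1 - phi^(-mu[use_nb] / (phi - 1))
    y[use_nb] <- stats::qnbinom((1 - u[use_nb]) * p_pos,
                                mu = mu[use_nb], size = sz,
                                lower.tail = FALSE)
  }
  as.integer(pmax(y, 1))
}

# Solve for the untruncated mean mu such that the zero-truncated mean
# mu / (1 - P(0)) equals m. P(0) is exp(-mu) for Poisson (phi = 1) and
# phi^(-mu/(phi-1)) for the NB with variance phi*mu. Vectorised bisection;
# the truncated mean is strictly increasing in mu.
solve_untrunc_mean <- function(m, phi) {
  p0 <- if (phi > 1) function(mu) phi^(-mu / (phi - 1)) else function(mu) exp(-mu)
  lo <- rep(1e-12, length(m))
  hi <- pmax(m, 1e-6)
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    too_big <- mid / (1 - p0(mid)) > m
    hi[too_big] <- mid[too_big]
    lo[!too_big] <- mid[!too_big]
  }
  (lo + hi) / 2
}

#' Truncated-normal random draws
#'
#' Inverse-CDF sampler for a normal distribution truncated to
#' \code{[lower, upper]}; used for recruit sizes.
#'
#' @param n number of draws.
#' @param mean,sd untruncated location and scale.
#' @param lower,upper truncation bounds.
#' @return numeric vector of length \code{n}, all inside the bounds.
#' @export
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  stopifnot(sd > 0, lower < upper)
  plo <- stats::pnorm(lower, mean, sd)
  phi_ <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi_ - plo), mean, sd)
}

#' Simulate a ground-truth size calibration table
#'
#' Emulates the field procedure of placing targets of known area in the
#' imaged scene and re-measuring them from the orthomosaic: measured areas
#' are the true areas times a multiplicative bias times multiplicative
#' noise \eqn{1 + \epsilon} with \eqn{\epsilon} normal, mean 0 and SD
#' \code{noise_sd}.
#'
#' @param true_areas vector of known target areas (m^2, all > 0).
#' @param bias_ratio multiplicative measurement bias (> 0); 0.88 emulates a
#'   ~12 percent underestimate.
#' @param noise_sd relative measurement noise SD (>= 0).
#' @param seed optional integer seed.
#' @return A \code{data.frame} with columns \code{measured} and \code{true}.
#' @examples
#' simulate_ground_truth(c(1, 2), bias_ratio = 0.88, noise_sd = 0)
#' @export
simulate_ground_truth <- function(true_areas, bias_ratio = 0.88,
                                  noise_sd = 0.02, seed = NULL) {
  if (length(true_areas) == 0) stop("'true_areas' must be non-empty")
  if (any(true_areas <= 0)) stop("'true_areas' must all be > 0")
  if (bias_ratio <= 0) stop("'bias_ratio' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  eps <- stats::rnorm(length(true_areas), 0, noise_sd)
  data.frame(measured = true_areas * bias_ratio * (1 + eps),
             true = true_areas)
}
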