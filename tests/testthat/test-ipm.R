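test_that("midpoint grid satisfies its defining arithmetic", {
  g <- ipm_grid(-6.84, 4.11, 100)
  expect_equal(g$h, 0.1095)
  expect_equal(g$meshpoints[1], -6.78525)
  expect_equal(g$meshpoints, g$L + (1:100 - 0.5) * g$h)

  g2 <- ipm_grid(0, 1, 2)
  expect_equal(g2$meshpoints, c(0.25, 0.75))
  expect_equal(g2$h, 0.5)

  g3 <- ipm_grid(0, 1, 100)
  expect_true(all(diff(g3$meshpoints) > 0))
  expect_true(all(g3$meshpoints > 0 & g3$meshpoints < 1))

  expect_error(ipm_grid(1, 0, 10), "L < U")
  expect_error(ipm_grid(0, 1, 1), ">= 2")
})

test_that("eviction correction forces P column sums to the survival
           probabilities", {
  g <- ipm_grid(-6.84, 4.11, 100)
  k <- build_kernels(ref, g)
  s <- plogis(ref$beta0_s + ref$beta1_s * g$meshpoints)
  expect_equal(colSums(k$P) * g$h, s, tolerance = 1e-12)
  expect_true(all(k$P >= 0) && all(k$F >= 0))
  expect_equal(k$K, k$P + k$F)
})

test_that("fecundity kernel is separable and vanishes when recruitment is
           zero", {
  g <- ipm_grid(-6.84, 4.11, 50)
  k <- build_kernels(ref, g)
  d <- rametipm:::rd_dens(ref, g$meshpoints, g$L, g$U)
  ratio <- sweep(k$F, 1, d, "/")
  expected <- plogis(ref$beta0_pr + ref$beta1_pr * g$meshpoints) *
    exp(ref$beta0_rs + ref$beta1_rs * g$meshpoints) * ref$r_r
  for (j in c(1, 25, 50))
    expect_equal(ratio[, j], rep(expected[j], 50), tolerance = 1e-12)

  p0 <- ref; p0$r_r <- 0
  k0 <- build_kernels(p0, g)
  expect_true(all(k0$F == 0))
  expect_equal(k0$K, k0$P)
  ip0 <- ipm_from_params(p0, g)
  expect_equal(ip0$e_P, 1, tolerance = 1e-12)
  expect_equal(ip0$e_F, 0, tolerance = 1e-12)
})

test_that("asymptotic growth rate matches closed forms on small matrices", {
  expect_equal(asymptotic_growth_rate(matrix(0.7))$lambda, 0.7)
  r <- asymptotic_growth_rate(matrix(c(0.5, 0.1, 0.2, 0.4), 2, 2))
  expect_equal(r$lambda, 0.6, tolerance = 1e-12)   # (tr + sqrt(tr^2-4det))/2
  d <- asymptotic_growth_rate(diag(c(0.5, 0.3)))
  expect_equal(d$lambda, 0.5)
  expect_gt(d$w[1], 0.99 * sum(d$w))               # mass on cell 1
})

test_that("power iteration agrees with the dense eigendecomposition and
           respects column-sum bounds", {
  for (s in 1:5) {
    set.seed(s)
    n <- 30
    K <- matrix(rexp(n * n), n, n)
    h <- 0.25
    r <- asymptotic_growth_rate(K, h = h)
    expect_equal(r$lambda, r$lambda_eigen, tolerance = 1e-10)
    cs <- colSums(h * K)
    expect_gte(r$lambda, min(cs) - 1e-12)
    expect_lte(r$lambda, max(cs) + 1e-12)
    # eigenvector normalisations
    expect_equal(h * sum(r$w), 1, tolerance = 1e-12)
    expect_equal(h * sum(r$v * r$w), 1, tolerance = 1e-12)
  }
  g <- ipm_grid(-6.84, 4.11, 100)
  r <- asymptotic_growth_rate(build_kernels(ref, g))
  expect_equal(r$lambda, r$lambda_eigen, tolerance = 1e-10)
})

test_that("sensitivity kernel matches finite-difference perturbations of
           the iteration matrix", {
  set.seed(9)
  n <- 10
  K <- matrix(rexp(n * n, rate = 2), n, n)
  h <- 0.5
  r <- asymptotic_growth_rate(K, h = h)
  sens <- sensitivity_kernel(r$v, r$w, h)
  expect_true(all(sens >= 0))
  expect_equal(sens, outer(r$v, r$w), tolerance = 1e-12)  # <v,w> = 1 form
  A <- h * K
  eps <- 1e-7
  lam0 <- max(Re(eigen(A, only.values = TRUE)$values))
  for (idx in list(c(1, 1), c(3, 7), c(10, 10), c(5, 2))) {
    A1 <- A
    A1[idx[1], idx[2]] <- A1[idx[1], idx[2]] + eps
    lam1 <- max(Re(eigen(A1, only.values = TRUE)$values))
    fd <- (lam1 - lam0) / eps
    expect_equal(fd, h * sens[idx[1], idx[2]], tolerance = 1e-3)
  }
  expect_error(sensitivity_kernel(1:3, 1:4, 1), "same length")
})

test_that("uniform eigenvectors give a constant sensitivity surface", {
  U <- 4; L <- 0; n <- 8; h <- (U - L) / n
  v <- rep(1, n)
  w <- rep(1 / (U - L), n)
  sens <- sensitivity_kernel(v, w, h)
  expect_equal(unique(as.numeric(sens)), 1 / (U - L), tolerance = 1e-12)
})

test_that("elasticities integrate to one and split exactly between the
           sub-kernels", {
  g <- ipm_grid(-6.84, 4.11, 100)
  ip <- ipm_from_params(ref, g)
  expect_equal(g$h^2 * sum(ip$elasticity), 1, tolerance = 1e-10)
  expect_true(all(ip$elasticity >= 0))
  expect_equal(ip$e_P + ip$e_F, 1, tolerance = 1e-12)
  expect_true(all(ip$elasticity[ip$kernels$K == 0] == 0))

  # random valid kernels partition as well
  for (s in 1:5) {
    set.seed(s)
    n <- 12; h <- 0.3
    P <- matrix(rexp(n * n), n, n); Fm <- matrix(rexp(n * n, 5), n, n)
    K <- P + Fm
    r <- asymptotic_growth_rate(K, h = h)
    sens <- sensitivity_kernel(r$v, r$w, h)
    el <- elasticity_kernel(K, r$lambda, sens, h)
    expect_equal(h^2 * sum(el), 1, tolerance = 1e-10)
    es <- subkernel_elasticities(P, Fm, el, h)
    expect_equal(unname(es["e_P"] + es["e_F"]), 1, tolerance = 1e-12)
  }
})

test_that("elasticities match finite-difference log-derivatives on the 2x2
           worked kernel", {
  K <- matrix(c(0.5, 0.1, 0.2, 0.4), 2, 2)
  r <- asymptotic_growth_rate(K)
  sens <- sensitivity_kernel(r$v, r$w, 1)
  el <- elasticity_kernel(K, r$lambda, sens, 1)
  for (i in 1:2) for (j in 1:2) {
    K1 <- K
    K1[i, j] <- K1[i, j] * (1 + 1e-6)
    lam1 <- max(Re(eigen(K1, only.values = TRUE)$values))
    dloglog <- (log(lam1) - log(r$lambda)) / 1e-6
    expect_equal(dloglog, el[i, j], tolerance = 1e-4)
  }
})

test_that("lambda is mesh-invariant for a constant kernel and converged for
           the reference model", {
  # constant kernel K(z', z) = c / (U - L): lambda = c at every mesh size
  cval <- 0.85; L <- 0; U <- 2
  for (m in c(10, 37, 100)) {
    K <- matrix(cval / (U - L), m, m)
    expect_equal(asymptotic_growth_rate(K, h = (U - L) / m)$lambda, cval,
                 tolerance = 1e-12)
  }
  tab <- mesh_convergence(ref, -6.84, 4.11, c(100, 150, 200))
  expect_true(all(tab$delta[-1] <= 1e-5))
  expect_true(all(diff(tab$delta[-1]) <= 0))     # refinement shrinks error
})

test_that("increasing baseline survival strictly increases lambda", {
  g <- ipm_grid(-6.84, 4.11, 60)
  lams <- vapply(c(-0.5, -0.25, 0, 0.25, 0.5), function(off) {
    p <- ref; p$beta0_s <- p$beta0_s + off
    asymptotic_growth_rate(build_kernels(p, g))$lambda
  }, 0)
  expect_true(all(diff(lams) > 0))
})

test_that("the full pipeline recovers the generating model's growth rate
           at n = 5000", {
  d <- simulate_ramets(ref, 5000, seed = 12)
  fit <- ipm_fit(d, L = -6.84, U = 4.11)
  gen <- ipm_from_params(ref, fit$grid)
  expect_within(fit$lambda, gen$lambda, 0.02)
  expect_gt(fit$e_P, fit$e_F)
})
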