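test_that("constant signal yields a vanishing potential", {
  g <- radial_grid(128)
  phi <- solve_chemo_potential(g, K = 0.3, sigma = rep(2.5, g$M))
  expect_lt(max(abs(phi$values)), 1e-12)
})

test_that("potential matches the nested radial quadrature oracle", {
  g <- radial_grid(128)
  K <- 0.05
  sigma <- form_function(1, 0.1)
  phi <- solve_chemo_potential(g, K, sigma)
  ## oracle: Phi(r) = -(1/K) int_0^r (1/s) int_0^s rho rhs(rho) drho ds on a
  ## 10x finer grid, gauge shifted to zero disk mean
  gf <- radial_grid(1280)
  s <- form_values(sigma, gf$r)
  rhs <- s - sum(gf$w * s) / sum(gf$w)
  inner <- cumsum(gf$r * rhs * gf$dr)              # int_0^s rho rhs drho
  phi_ref <- -cumsum(inner / pmax(gf$r, gf$dr / 2) * gf$dr) / K
  phi_ref <- phi_ref - sum(gf$w * phi_ref) / sum(gf$w)
  ## compare at the coarse centers (exact index mapping: factor-10 refinement)
  idx <- 10 * seq_len(g$M) - 5
  expect_lt(max(abs(phi$values - phi_ref[idx])) / diff(range(phi_ref)), 5e-3)
  ## Neumann character: interior flux is continuous, boundary gradient ~ 0
  grad_b <- (phi$values[g$M] - phi$values[g$M - 1]) / g$dr
  expect_lt(abs(grad_b) / max(abs(phi$values)), 0.05)
})

test_that("zero tumor mass means no immune cells; chi = 0 response is linear in mass", {
  g <- radial_grid(128)
  params <- immune_parameters()
  phi <- solve_chemo_potential(g, params$K, form_function(5e-17, 0.1))
  C0 <- solve_immune_concentration(g, params, phi, 0)
  expect_equal(max(abs(C0$values)), 0)
  params0 <- immune_parameters(chi = 0)
  C1 <- solve_immune_concentration(g, params0, phi, 1)
  Cm <- solve_immune_concentration(g, params0, phi, 3.7e-5)
  expect_equal(Cm$values, 3.7e-5 * C1$values, tolerance = 1e-12)
})

test_that("chi = 0 concentration matches the modified-Bessel closed form", {
  ## gamma C - D lap C = S with C(radius) = 0 has the radial solution
  ## C = (S/gamma) (1 - I0(r/l) / I0(radius/l)), l = sqrt(D/gamma)
  g <- radial_grid(400)
  params <- immune_parameters(chi = 0, D = 1e-3, gamma = 0.1, R_influx = 1e-9)
  phi <- solve_chemo_potential(g, params$K, form_function(5e-17, 0.1))
  mu1 <- 2
  C <- solve_immune_concentration(g, params, phi, mu1)
  S <- mu1 * params$R_influx * 1e9
  l <- sqrt(params$D / params$gamma)
  Cex <- (S / params$gamma) * (1 - besselI(g$r / l, 0) / besselI(1 / l, 0))
  expect_lt(max(abs(C$values - Cex)) / max(Cex), 5e-4)
})

test_that("scheme order: closed-form error decreases under grid refinement", {
  params <- immune_parameters(chi = 0, D = 1e-3, gamma = 0.1, R_influx = 1e-9)
  err <- vapply(c(100, 200, 400), function(M) {
    g <- radial_grid(M)
    phi <- solve_chemo_potential(g, params$K, form_function(5e-17, 0.1))
    C <- solve_immune_concentration(g, params, phi, 1)
    S <- params$R_influx * 1e9
    l <- sqrt(params$D / params$gamma)
    Cex <- (S / params$gamma) * (1 - besselI(g$r / l, 0) / besselI(1 / l, 0))
    max(abs(C$values - Cex)) / max(Cex)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_gt(err[1] / err[3], 4)          # at least first order over a 4x refinement
})

test_that("death-rate functional is the linear disk quadrature of delta times C", {
  g <- radial_grid(400)
  Cfun <- function(r) 1 - r^2                       # smooth tabulated field
  Cv <- Cfun(g$r)
  expect_equal(effective_death_rate(Cv, form_function(0, 0.1), g), 0)
  d1 <- effective_death_rate(Cv, form_function(2, 0.1), g)
  d10 <- effective_death_rate(Cv, form_function(20, 0.1), g)
  expect_equal(d10, 10 * d1, tolerance = 1e-12)
  ## adaptive-quadrature oracle: the midpoint rule is second order, so the
  ## coarse grid sits within its O(dr^2) band and a 10x refinement lands
  ## within 1e-6 relative
  f <- form_function(2, 0.1)
  oracle <- stats::integrate(function(r) form_values(f, r) * Cfun(r) * 2 * pi * r,
                             0, 1, rel.tol = 1e-10)$value
  expect_lt(abs(d1 - oracle) / oracle, 1e-4)
  gf <- radial_grid(4000)
  d1f <- effective_death_rate(Cfun(gf$r), f, gf)
  expect_lt(abs(d1f - oracle) / oracle, 1e-6)
  expect_gt(abs(d1 - oracle) / abs(d1f - oracle), 50)  # ~dr^2 convergence
})

test_that("maximum principle holds across random parameter draws", {
  set.seed(42)
  g <- radial_grid(96)
  for (k in 1:15) {
    params <- immune_parameters(chi = runif(1, 86.4, 8.64e6),
                                D = runif(1, 8.64e-5, 1e-3),
                                gamma = runif(1, 0.02, 1),
                                K = runif(1, 0.01, 1),
                                R_influx = exp(runif(1, log(1e-7), log(1e-5))))
    phi <- solve_chemo_potential(g, params$K,
                                 form_function(runif(1, 5e-17, 6.25e-17), 0.1))
    C <- solve_immune_concentration(g, params, phi, 10^runif(1, -6, -2))
    expect_true(all(C$values >= 0))
    expect_lt(C$values[g$M], max(C$values) + 1e-15)  # boundary value is smallest side
  }
})
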