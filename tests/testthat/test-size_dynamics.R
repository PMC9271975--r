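test_that("shift lower bound matches literal evaluation of its defining sums", {
  ## constant growth rate: the velocity ratio collapses to one, so the bound
  ## is the gain-row maximum minus the smallest division rate
  grid <- size_grid(5, 1000)
  spec <- growth_division_spec(V = 0.6, a = 4, kernel = "mitosis")
  ## brute-force oracle: literal summation over the quadrature weights
  z <- grid$z; h <- grid$h
  gain_row_sum <- vapply(seq_len(grid$I), function(k) {
    j <- 2L * k - 1L
    if (j <= grid$I) 4 * 4 else 0   # h * a_j * k collapses to 4 a for the Dirac
  }, numeric(1))
  oracle <- 1 * max(gain_row_sum) - 4
  expect_equal(shift_lower_bound(spec, grid), oracle, tolerance = 1e-12)
  expect_equal(oracle, 3 * 4)       # mitosis with constant rates: 3 a

  ## kernel engineered so every gain-row sum is at most 2 a: bound <= a,
  ## checked by enumeration on a 10-point grid
  g10 <- size_grid(1, 10)
  a0 <- 0.5
  spec2 <- growth_division_spec(V = 1, a = a0, kernel = "custom",
                                kernel_fn = function(z, zp) rep(2 / g10$R_max, length(z)))
  W <- matrix(0, 10, 10)
  for (j in 1:10) W[1:j, j] <- g10$h * a0 * 2 / g10$R_max
  expect_true(all(rowSums(W) <= 2 * a0 + 1e-12))
  expect_lte(shift_lower_bound(spec2, g10), a0)

  ## nonpositive growth rate is an invalid spec for the bound
  expect_error(shift_lower_bound(growth_division_spec(0, 1, "mitosis"), g10),
               "positive")
})

test_that("operator assembly matches the discrete scheme entry by entry", {
  ## no growth, no division: h times the identity on rows 2..I
  g <- size_grid(1, 6)
  op0 <- assemble_shifted_operator(growth_division_spec(0, 0, "mitosis"),
                                   g, Lambda = 1, check_bound = FALSE)
  expect_equal(op0$matrix[2:6, 2:6], diag(g$h, 5))
  expect_equal(op0$matrix[1, ], c(g$h, rep(0, 5)))

  ## Dirac mitosis kernel: one gain entry per row, weight -4 h a, in the
  ## column where 2 z_i sits
  g <- size_grid(2, 8)
  a0 <- 1.5
  op <- assemble_shifted_operator(growth_division_spec(1, a0, "mitosis"),
                                  g, Lambda = 10)
  for (i in 2:8) {
    j <- 2L * i - 1L
    gains <- op$matrix[i, -c(i, i - 1)]
    if (j <= 8) {
      expect_equal(op$matrix[i, j], -4 * g$h * a0)
      expect_equal(sum(gains != 0), 1L)
    } else {
      expect_true(all(gains == 0))
    }
  }

  ## uniform kernel, I = 5, a(z) = z, V = 1, Lambda = 3: every entry against
  ## an independently hand-coded evaluation of the scheme
  g5 <- size_grid(5, 5)
  spec <- growth_division_spec(1, function(z) z, "uniform")
  op5 <- assemble_shifted_operator(spec, g5, Lambda = 3, check_bound = FALSE)
  h <- g5$h; z <- g5$z
  Tref <- matrix(0, 5, 5)
  for (i in 2:5) {
    Tref[i, i] <- Tref[i, i] + 1 + h * (3 + z[i])      # V_{i+1/2} + h (Lambda + a_i)
    Tref[i, i - 1] <- Tref[i, i - 1] - 1               # -V_{i-1/2}
    for (j in i:5) if (z[j] > 0)
      Tref[i, j] <- Tref[i, j] - h^2 * z[j] * (2 / z[j])
  }
  Tref[1, 1] <- 1 + h * (3 + z[1])
  expect_equal(op5$matrix, Tref, tolerance = 1e-14)

  ## a shift at or below the bound is refused with a diagnostic
  gm <- size_grid(5, 100)
  specm <- growth_division_spec(0.6, 4, "mitosis")
  expect_error(assemble_shifted_operator(specm, gm, Lambda = 11),
               "lower bound")
})

test_that("inverse power iteration agrees with a dense eigensolver and is seed independent", {
  for (case_name in c("mitosis", "uniform_ex1")) {
    case <- validation_cases()[[case_name]]
    grid <- size_grid(5, 200)
    spec <- spec_for_case(case)
    Lambda <- 1.05 * shift_lower_bound(spec, grid)
    op <- assemble_shifted_operator(spec, grid, Lambda)
    eig <- solve_leading_eigenpair(op, eps = 1e-13, seed = 1, max_iter = 20000)
    ## oracle: leading eigenvalue of the explicitly inverted dense matrix
    ev <- eigen(solve(op$matrix / grid$h), only.values = TRUE)$values
    mu_star <- ev[which.max(Mod(ev))]
    expect_lt(abs(Im(mu_star)), 1e-10)
    lam_dense <- Lambda - 1 / Re(mu_star)
    expect_lt(abs(eig$lam - lam_dense) / abs(lam_dense), 1e-10)
    ## the leading eigenvalue does not depend on the start vector
    eig2 <- solve_leading_eigenpair(op, eps = 1e-13, seed = 99, max_iter = 20000)
    expect_lt(abs(eig$lam - eig2$lam) / abs(eig$lam), 1e-12)
  }
})

test_that("converged profiles are positive, normalized and vanish at the origin", {
  for (case_name in names(validation_cases())) {
    res <- solve_analytic_case(validation_cases()[[case_name]], I = 400, R_max = 5)
    p <- res$numeric$profile
    expect_equal(p[1], 0)
    expect_true(all(p >= 0))
    expect_true(all(p[-1] > 0))                       # strict positivity inside
    expect_equal(res$grid$h * sum(p), 1, tolerance = 1e-12)
    expect_gt(res$numeric$lam, 0)
  }
})

test_that("analytic eigenpairs carry the closed-form eigenvalues and unit mass", {
  g <- size_grid(5, 2000)
  expect_equal(analytic_eigenpair(analytic_case("mitosis_const", 4, 0.6), g)$lam, 4)
  expect_equal(analytic_eigenpair(analytic_case("uniform_Vconst_alinear", 4, 0.6), g)$lam,
               sqrt(4 * 0.6))
  expect_equal(analytic_eigenpair(analytic_case("uniform_Vlinear_apower", 4, 0.6, n = 1), g)$lam,
               0.6)
  for (case in validation_cases()) {
    ae <- analytic_eigenpair(case, g)
    expect_equal(g$h * sum(ae$profile), 1, tolerance = 1e-12)
    expect_true(all(ae$profile >= 0))
  }
})

test_that("error metrics follow their definitions exactly", {
  g <- size_grid(5, 500)
  case <- analytic_case("mitosis_const", 4, 0.6)
  ae <- analytic_eigenpair(case, g)
  expect_equal(eigen_errors(ae, ae, g), c(E_lambda = 0, E_V = 0))
  ## a +delta perturbation of one cell moves E_V by exactly h * delta
  pert <- ae
  delta <- 0.037
  pert$profile[100] <- pert$profile[100] + delta
  expect_equal(eigen_errors(pert, ae, g)[["E_V"]], g$h * delta, tolerance = 1e-12)
  ## mismatched grids are refused
  expect_error(eigen_errors(ae, analytic_eigenpair(case, size_grid(5, 400)), g),
               "grid")
})

test_that("solver reproduces analytic cases on moderate grids", {
  err_mit <- eigen_case_errors("mitosis", 1000)
  expect_lt(err_mit[["E_lambda"]], 1e-4)
  err_ex1 <- eigen_case_errors("uniform_ex1", 1000)
  expect_lt(err_ex1[["E_lambda"]], 2e-2)
  expect_lt(err_ex1[["E_V"]], 2e-2)
  err_n1 <- eigen_case_errors("uniform_ex2_n1", 1000)
  expect_lt(err_n1[["E_lambda"]], 8e-2)
})

test_that("eigenvalue is insensitive to the truncation radius once the tail is resolved", {
  case <- analytic_case("mitosis_const", 4, 0.6)
  lam5 <- solve_analytic_case(case, I = 1000, R_max = 5, eps = 1e-10)$numeric$lam
  lam7 <- solve_analytic_case(case, I = 1400, R_max = 7, eps = 1e-10)$numeric$lam
  expect_lt(abs(lam5 - lam7) / lam5, 1e-6)
})
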