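test_that("multi-index bookkeeping matches the closed-form counts", {
  expect_equal(build_basis(8, 5)$size, choose(13, 5))             # 1287
  b <- build_basis(8, 5, max_interaction = 2, oversampling = 2)
  expect_equal(b$size, 321)
  expect_equal(b$design_size, 642)
  expect_equal(build_basis(1, 3)$size, 4)
  ## indices are unique, the constant term present, constraints respected
  key <- apply(b$indices, 1, paste, collapse = ",")
  expect_equal(anyDuplicated(key), 0L)
  expect_true(any(rowSums(b$indices) == 0))
  expect_true(all(rowSums(b$indices) <= 5))
  expect_true(all(rowSums(b$indices > 0) <= 2))
})

test_that("space-filling draws respect supports, log moments and determinism", {
  sp <- parameter_space()
  s1 <- sample_parameters(sp, 4000, seed = 7)
  s2 <- sample_parameters(sp, 4000, seed = 7)
  expect_identical(s1$theta, s2$theta)
  s3 <- sample_parameters(sp, 4000, seed = 8)
  expect_false(identical(s1$theta$A, s3$theta$A))
  th <- s1$theta
  expect_true(all(th$A >= 2 & th$A <= 57.6))
  expect_true(all(th$gamma >= 0.02 & th$gamma <= 1))
  expect_true(all(th$chi >= 86.4 & th$chi <= 8.64e6))
  ## log-normal marginals: empirical meanlog within 3 standard errors
  expect_lt(abs(mean(log(th$a)) - log(0.12)), 3 * 0.20 / sqrt(4000))
  expect_lt(abs(mean(log(th$R)) - log(2.2e-6)), 3 * 0.84 / sqrt(4000))
})

test_that("surrogate exactly recovers a representable polynomial; short designs are refused", {
  sp <- parameter_space()
  basis <- build_basis(8, 3, max_interaction = 2, oversampling = 2)
  des <- sample_parameters(sp, basis$design_size, seed = 2)
  ## target: a function already in the span of the basis
  set.seed(4)
  truth <- structure(list(coefficients = stats::rnorm(basis$size), basis = basis,
                          dists = vapply(sp, function(m) m$dist, character(1)),
                          loo = 0, residual_sd = 0),
                     class = "gpc_surrogate")
  y <- evaluate_surrogate(truth, des$u)
  fit <- fit_log_surrogate(des$u, y, basis, sp)
  expect_lt(max(abs(fit$coefficients - truth$coefficients)), 1e-9)
  expect_lt(fit$loo, 1e-9)
  expect_error(fit_log_surrogate(des$u[1:100, ], y[1:100], basis, sp),
               "at least")
})

test_that("smooth multiplicative toy model is fitted below one percent held-out error", {
  sp <- parameter_space()
  basis <- build_basis(8, 5, max_interaction = 2, oversampling = 2)
  des <- sample_parameters(sp, basis$design_size, seed = 3)
  ## additive log-model: smooth analytic functions of the standardized
  ## coordinates, pairwise interaction included
  toy <- function(u) 0.6 * sin(2 * u[, 1]) + cos(2 * u[, 2]) -
    0.4 * u[, 3]^3 + 0.5 * u[, 4] * u[, 5] + 0.8 * u[, 7]^2 + exp(u[, 8])
  y <- toy(des$u)
  fit <- fit_log_surrogate(des$u, y, basis, sp)
  expect_lt(fit$loo, 0.01)
  ## held-out oracle
  hold <- sample_parameters(sp, 2000, seed = 31)
  pred <- evaluate_surrogate(fit, hold$u)
  expect_lt(sqrt(mean((pred - toy(hold$u))^2)) / sd(y), 0.01)
})

test_that("pick-freeze estimators recover an additive linear decomposition", {
  sp <- parameter_space()
  basis <- build_basis(8, 2, max_interaction = 2, oversampling = 3)
  des <- sample_parameters(sp, basis$design_size, seed = 5)
  bcoef <- c(3, 2, 1, 0.5, 0, 0, 0, 0)
  ## centered so the product estimators are not dominated by the mean term
  lin <- function(u) as.numeric((u - 0.5) %*% bcoef)
  fit <- fit_log_surrogate(des$u, lin(des$u), basis, sp)
  rep <- sobol_indices(fit, N_mc = 4e5, seed = 9, transform = identity)
  S_true <- bcoef^2 / sum(bcoef^2)       # equal uniform variances factor out
  expect_lt(max(abs(rep$first - S_true)), 0.02)
  expect_lt(max(abs(rep$total - S_true)), 0.02)
  expect_lt(max(abs(rep$second)), 0.02)
  ## variance decomposition closes: every first-order estimation error
  ## re-enters the 28 pairwise terms with weight -(k - 2), so the Monte
  ## Carlo standard error of the sum is ~6x that of one index
  expect_lt(abs(sum(rep$first) + sum(rep$second) - 1), 0.12)
})

test_that("indices respect definitional bounds and totals dominate first order", {
  sp <- parameter_space()
  basis <- build_basis(8, 2, max_interaction = 2, oversampling = 3)
  des <- sample_parameters(sp, basis$design_size, seed = 6)
  f <- function(u) u[, 1] + 0.5 * u[, 2] + 2 * u[, 1] * u[, 2] + 0.2 * u[, 3]
  fit <- fit_log_surrogate(des$u, f(des$u), basis, sp)
  rep1 <- sobol_indices(fit, N_mc = 5e4, seed = 12, transform = identity)
  eps_mc <- 0.03
  expect_true(all(rep1$first >= -eps_mc & rep1$first <= 1 + eps_mc))
  expect_true(all(rep1$total >= rep1$first - eps_mc))
  ## interaction shows up in the pair and in both totals
  expect_gt(rep1$second[["a:A"]], 0.03)
  expect_gt(rep1$total[["a"]], rep1$first[["a"]] + 0.02)
  ## determinism for a fixed seed
  rep2 <- sobol_indices(fit, N_mc = 5e4, seed = 12, transform = identity)
  expect_identical(rep1$first, rep2$first)
})

test_that("the equilibrium model responds like its closed-form skeleton", {
  ## mu1 is close to multiplicative in (a, gamma, 1/A, 1/R) over the ranges:
  ## doubling a doubles mu1; doubling A halves it (weak drift corrections)
  th <- c(a = 0.1, A = 4, R = 2e-7, chi = 86.4, D = 8.64e-5,
          A_sigma = 5e-17, gamma = 0.05, K = 0.1)
  base <- equilibrium_model(th)
  th2 <- th; th2[["a"]] <- 0.2
  expect_equal(equilibrium_model(th2) / base, 2, tolerance = 1e-3)
  th3 <- th; th3[["A"]] <- 8
  expect_equal(equilibrium_model(th3) / base, 0.5, tolerance = 1e-3)
})
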