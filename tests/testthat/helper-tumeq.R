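## Shared fixtures and a cache for the expensive eigen validation table.
## Everything here is generated in code at test time.

.tumeq_cache <- new.env(parent = emptyenv())

validation_cases <- function() {
  list(
    mitosis = analytic_case("mitosis_const", a0 = 4, V0 = 0.6),
    uniform_ex1 = analytic_case("uniform_Vconst_alinear", a0 = 4, V0 = 0.6),
    uniform_ex2_n1 = analytic_case("uniform_Vlinear_apower", a0 = 4, V0 = 0.6, n = 1),
    uniform_ex2_n2 = analytic_case("uniform_Vlinear_apower", a0 = 4, V0 = 0.6, n = 2))
}

## E_lambda / E_V for one validation case at one resolution, memoized across
## test files (several acceptance criteria share these solves)
eigen_case_errors <- function(case_name, I) {
  key <- sprintf("%s_%d", case_name, I)
  if (!is.null(.tumeq_cache[[key]])) return(.tumeq_cache[[key]])
  res <- solve_analytic_case(validation_cases()[[case_name]], I = I, R_max = 5)
  out <- c(res$errors, iterations = res$numeric$iterations,
           lambda = res$numeric$lam)
  .tumeq_cache[[key]] <- out
  gc(FALSE)
  out
}

baseline_forms <- function(A = 2, A_sigma = 5e-17, theta = 0.1)
  list(delta = form_function(A, theta), sigma = form_function(A_sigma, theta))

## closed-form equilibrium mass for chi = 0, where the stationary problem is
## linear in the mass: mu1 = lambda / int(delta C_1) with C_1 the unit-mass
## concentration (independent single-solve oracle, no bisection)
chi0_closed_form <- function(lambda, params, forms, grid) {
  phi <- solve_chemo_potential(grid, params$K, forms$sigma)
  C1 <- solve_immune_concentration(grid, params, phi, 1)
  lambda / effective_death_rate(C1, forms$delta, grid)
}

## log-log least-squares slope
loglog_slope <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, log(x)), log(y))
  fit$coefficients[2]
}
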