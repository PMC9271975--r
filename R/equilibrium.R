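## Power-dichotomy prediction of the equilibrium tumor mass.

#' Predict the residual tumor mass at equilibrium
#'
#' Implements the dichotomy half of the power-dichotomy procedure: given the
#' Malthusian eigenvalue `lambda` of the growth-division equation, find the
#' residual mass `mu1` such that the stationary immune field it induces
#' satisfies the constraint `int delta C_{mu1} = lambda`.
#'
#' The potential shape is computed once; each bisection step solves one
#' stationary drift-diffusion equation and evaluates
#' `I(mu1) = int delta C_{mu1} - lambda`, replacing the lower bracket edge
#' when `I < 0` and the upper edge otherwise, until the relative bracket
#' width `(mu_b - mu_a)/mu_a` falls below `eps_d`. If the initial bracket
#' does not straddle the root it is expanded geometrically (factor 10, up to
#' `max_expand` times each way) before failing.
#'
#' @param eig an `eigenpair` from [solve_leading_eigenpair()], or a single
#'   positive number taken as `lambda` directly.
#' @param params an [immune_parameters()].
#' @param forms list with components `delta` and `sigma`
#'   ([form_function()]s).
#' @param grid a [radial_grid()].
#' @param bracket initial mass bracket `c(mu_a, mu_b)` in mm^3
#'   (default `c(1e-10, 10)`).
#' @param eps_d relative bracket tolerance (default `1e-8`).
#' @param max_expand maximum geometric bracket expansions (default 6).
#' @return An object of class `equilibrium_result`: `mu1` (mm^3),
#'   `diameter` (mm, equivalent sphere), `lambda`, `bracket_history`,
#'   `iterations`, `converged`, and the final concentration field `C`.
#' @export
predict_equilibrium <- function(eig, params, forms, grid,
                                bracket = c(1e-10, 10), eps_d = 1e-8,
                                max_expand = 6L) {
  lam <- if (inherits(eig, "eigenpair")) eig$lam else as.numeric(eig)
  stopifnot(lam > 0, length(bracket) == 2, bracket[1] > 0,
            bracket[1] < bracket[2], eps_d > 0)
  phi <- solve_chemo_potential(grid, params$K, forms$sigma)
  Ifun <- function(mu)
    effective_death_rate(solve_immune_concentration(grid, params, phi, mu),
                         forms$delta, grid) - lam
  mu_a <- bracket[1]; mu_b <- bracket[2]
  Ia <- Ifun(mu_a); Ib <- Ifun(mu_b)
  ## root already at an edge, to solver tolerance
  if (abs(Ia) <= eps_d * lam)
    return(.equilibrium_result(mu_a, lam, list(c(mu_a, mu_b)), 0L, TRUE,
                               params, forms, grid, phi))
  if (abs(Ib) <= eps_d * lam)
    return(.equilibrium_result(mu_b, lam, list(c(mu_a, mu_b)), 0L, TRUE,
                               params, forms, grid, phi))
  expand <- 0L
  while (sign(Ia) == sign(Ib) && expand < max_expand) {
    if (Ia > 0) { mu_a <- mu_a / 10; Ia <- Ifun(mu_a) }
    else        { mu_b <- mu_b * 10; Ib <- Ifun(mu_b) }
    expand <- expand + 1L
  }
  if (sign(Ia) == sign(Ib))
    stop(sprintf(paste0("no equilibrium in range: I(mu) has the same sign at ",
                        "mu_a = %g and mu_b = %g after %d expansions"),
                 mu_a, mu_b, expand))
  if (Ia > 0 || Ib < 0)
    stop("death-rate functional is not increasing over the bracket; dichotomy ill-posed")
  history <- list(c(mu_a, mu_b))
  iter <- 0L
  while ((mu_b - mu_a) / mu_a >= eps_d) {
    mu1 <- (mu_a + mu_b) / 2
    if (Ifun(mu1) < 0) mu_a <- mu1 else mu_b <- mu1
    iter <- iter + 1L
    history[[length(history) + 1L]] <- c(mu_a, mu_b)
    if (iter > 400L) stop("dichotomy failed to contract (tolerance too tight?)")
  }
  .equilibrium_result((mu_a + mu_b) / 2, lam, history, iter, TRUE,
                      params, forms, grid, phi)
}

.equilibrium_result <- function(mu1, lam, history, iter, converged,
                                params, forms, grid, phi) {
  C <- solve_immune_concentration(grid, params, phi, mu1)
  structure(list(mu1 = mu1, diameter = mass_to_diameter(mu1), lambda = lam,
                 bracket_history = history, iterations = iter,
                 converged = converged, C = C, phi = phi),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("equilibrium: mu1 = %.6e mm^3, diameter = %.4g mm (lambda = %.4g, %d bisections)\n",
              x$mu1, x$diameter, x$lambda, x$iterations))
  invisible(x)
}

#' Equivalent spherical diameter of a tumor mass
#'
#' Converts a volume to the diameter of the sphere of equal volume,
#' `d = (6 mu1 / pi)^(1/3)` (same length unit as the cube root of the
#' volume unit: mm^3 to mm, um^3 to um).
#'
#' @param mu1 nonnegative volume.
#' @export
mass_to_diameter <- function(mu1) {
  if (any(mu1 < 0)) stop("volume must be nonnegative")
  (6 * mu1 / pi)^(1 / 3)
}

#' Sweep a biological parameter and record the equilibrium
#'
#' Repeats [predict_equilibrium()] over a list of values of one parameter,
#' recomputing the eigenvalue when the division rate `a` (or growth rate
#' `V`) varies. Any single failure is recorded in the corresponding row and
#' the sweep continues.
#'
#' @param vary parameter name: one of `"a"`, `"A"`, `"R"`, `"gamma"`,
#'   `"chi"`, `"D"`, `"K"`, `"A_sigma"`.
#' @param values numeric vector of positive values.
#' @param config base configuration as returned by [equilibrium_config()].
#' @return A data.frame with columns `parameter`, `value`, `mu1_mm3`,
#'   `diameter_mm`, `lambda`, `error` (NA when the row succeeded).
#' @export
parameter_sweep <- function(vary, values, config = equilibrium_config()) {
  choices <- c("a", "A", "R", "gamma", "chi", "D", "K", "A_sigma")
  vary <- match.arg(vary, choices)
  stopifnot(is.numeric(values), all(values > 0))
  out <- data.frame(parameter = vary, value = values, mu1_mm3 = NA_real_,
                    diameter_mm = NA_real_, lambda = NA_real_,
                    error = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(values)) {
    cfg <- config
    v <- values[i]
    switch(vary,
      a = { cfg$a <- v },
      A = { cfg$A <- v },
      R = { cfg$R_influx <- v },
      gamma = { cfg$gamma <- v },
      chi = { cfg$chi <- v },
      D = { cfg$D <- v },
      K = { cfg$K <- v },
      A_sigma = { cfg$A_sigma <- v })
    res <- tryCatch(equilibrium_from_config(cfg), error = function(e) e)
    if (inherits(res, "error")) {
      out$error[i] <- conditionMessage(res)
    } else {
      out$mu1_mm3[i] <- res$mu1
      out$diameter_mm[i] <- res$diameter
      out$lambda[i] <- res$lambda
    }
  }
  out
}

#' Baseline equilibrium configuration
#'
#' Bundles the tumor growth parameters, immune parameters, form functions
#' and numerical settings of an equilibrium computation. Defaults follow the
#' study baseline: lower bounds of the biological parameter ranges, division
#' rate `a = 0.1`/day, growth rate `V = 713.61` um^3/day, mitosis kernel.
#'
#' @param a,V tumor division and growth rates (constant).
#' @param chi,D,gamma,K,R_influx immune parameters (see
#'   [immune_parameters()]).
#' @param A,theta amplitude and width of the killing form function `delta`.
#' @param A_sigma,theta_sigma amplitude and width of the signal form
#'   function `sigma`.
#' @param M radial cells; `radius` domain radius.
#' @param lambda_mode `"analytic"` uses `lambda = a` (exact for the constant
#'   rate mitosis kernel); `"numeric"` computes the eigenvalue with the
#'   inverse power solver on a size grid with `I` cells.
#' @param I,eps_eig,seed size-grid cells, eigen tolerance and seed for
#'   `lambda_mode = "numeric"`.
#' @param bracket,eps_d dichotomy settings.
#' @export
equilibrium_config <- function(a = 0.1, V = 713.61,
                               chi = 86.4, D = 8.64e-5, gamma = 0.02,
                               K = 0.01, R_influx = 1.74e-7,
                               A = 2, theta = 0.1,
                               A_sigma = 5e-17, theta_sigma = 0.1,
                               M = 128L, radius = 1,
                               lambda_mode = c("analytic", "numeric"),
                               I = 2000L, eps_eig = 1e-8, seed = 1L,
                               bracket = c(1e-10, 10), eps_d = 1e-8) {
  list(a = a, V = V, chi = chi, D = D, gamma = gamma, K = K,
       R_influx = R_influx, A = A, theta = theta, A_sigma = A_sigma,
       theta_sigma = theta_sigma, M = M, radius = radius,
       lambda_mode = match.arg(lambda_mode), I = I, eps_eig = eps_eig,
       seed = seed, bracket = bracket, eps_d = eps_d)
}

#' Run one equilibrium prediction from a configuration
#' @param cfg a list from [equilibrium_config()].
#' @export
equilibrium_from_config <- function(cfg) {
  lam <- if (identical(cfg$lambda_mode, "numeric")) {
    case <- analytic_case("mitosis_const", a0 = cfg$a, V0 = cfg$V)
    spec <- spec_for_case(case)
    sg <- size_grid(default_R_max(case), cfg$I)
    op <- assemble_shifted_operator(spec, sg,
                                    1.05 * shift_lower_bound(spec, sg))
    solve_leading_eigenpair(op, eps = cfg$eps_eig, seed = cfg$seed)$lam
  } else cfg$a
  params <- immune_parameters(chi = cfg$chi, D = cfg$D, gamma = cfg$gamma,
                              K = cfg$K, R_influx = cfg$R_influx)
  forms <- list(delta = form_function(cfg$A, cfg$theta),
                sigma = form_function(cfg$A_sigma, cfg$theta_sigma))
  grid <- radial_grid(cfg$M, cfg$radius)
  predict_equilibrium(lam, params, forms, grid,
                      bracket = cfg$bracket, eps_d = cfg$eps_d)
}
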