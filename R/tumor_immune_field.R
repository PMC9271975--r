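## Stationary immune-cell field on the unit disk.
##
## With centered Gaussian form functions, a space-homogeneous influx rate and
## a disk domain, the stationary chemoattractive potential and immune-cell
## concentration are radially symmetric; both solvers are 1-D radial finite
## volume schemes. Lengths are in mm (domain radius 1), times in days, and
## the tumor mass mu1 enters in mm^3 with the influx rate R converted from
## its native per-um^3 units.

#' Radial finite-volume grid on the disk
#'
#' `M` annular cells on `[0, radius]` with faces `r_{m-1/2} = (m-1) dr`
#' (so `r_{1/2} = 0`, `r_{M+1/2} = radius`) and centers
#' `r_m = (m - 1/2) dr`. The disk-area quadrature weights are
#' `w_m = 2 pi r_m dr` (they sum exactly to `pi radius^2`).
#'
#' @param M number of radial cells.
#' @param radius domain radius (default 1, the unit disk).
#' @return An object of class `radial_grid` with fields `M`, `radius`, `dr`,
#'   `r` (centers), `rf` (faces, length `M + 1`), `w` (area weights).
#' @export
radial_grid <- function(M, radius = 1) {
  stopifnot(M >= 2, M == round(M), radius > 0)
  dr <- radius / M
  rf <- (0:M) * dr
  r <- (seq_len(M) - 0.5) * dr
  structure(list(M = as.integer(M), radius = radius, dr = dr,
                 r = r, rf = rf, w = 2 * pi * r * dr),
            class = "radial_grid")
}

#' @export
print.radial_grid <- function(x, ...) {
  cat(sprintf("radial grid: M = %d cells on [0, %g]\n", x$M, x$radius))
  invisible(x)
}

#' Centered Gaussian form function
#'
#' The killing-efficacy profile `delta` and the chemical-signal profile
#' `sigma` are centered Gaussians
#' `f(x) = A / (theta sqrt(2 pi)) exp(-|x|^2 / (2 theta^2))`,
#' parameterized by an amplitude and a width (in domain-radius units).
#'
#' @param amplitude nonnegative amplitude (`A` or `A_sigma`).
#' @param width positive width (`theta` or `theta_sigma`), default 0.1.
#' @return An object of class `form_function`; evaluate with
#'   [form_values()].
#' @export
form_function <- function(amplitude, width = 0.1) {
  stopifnot(amplitude >= 0, width > 0)
  structure(list(amplitude = amplitude, width = width), class = "form_function")
}

#' Evaluate a form function at radii
#' @param f a [form_function()].
#' @param r radii.
#' @export
form_values <- function(f, r) {
  f$amplitude / (f$width * sqrt(2 * pi)) * exp(-r^2 / (2 * f$width^2))
}

#' Immune-cell and signal parameters
#'
#' Physical coefficients of the immune-cell drift-diffusion equation and the
#' potential equation, in the study's units: `chi` (mm^2 mmol^-1 day^-1),
#' `D` (mm^2/day), `gamma` (1/day), `K` (mm^2/day), and `R_influx`, the
#' influx rate of effector cells per unit tumor mass, in the native
#' per-(cell um^3 day) units (it is converted internally to the mm^3 mass
#' convention).
#'
#' @param chi chemotactic coefficient.
#' @param D immune-cell diffusion coefficient.
#' @param gamma natural death rate of effector cells.
#' @param K diffusion coefficient of the chemoattractant potential.
#' @param R_influx influx rate (scalar, space-homogeneous).
#' @return An object of class `immune_params`.
#' @export
immune_parameters <- function(chi = 86.4, D = 8.64e-5, gamma = 0.02,
                              K = 0.01, R_influx = 1.74e-7) {
  vals <- c(chi = chi, D = D, gamma = gamma, K = K, R_influx = R_influx)
  if (any(!is.finite(vals)) || any(vals[c("D", "gamma", "K")] <= 0) ||
      chi < 0 || R_influx < 0)
    stop("immune parameters must be finite with D, gamma, K > 0")
  structure(as.list(vals), class = "immune_params")
}

#' Stationary chemoattractive potential
#'
#' Solves the mean-corrected diffusion equation for the potential shape
#' `Phi` on the disk,
#' `-K lap(Phi) = sigma - |Omega|^{-1} int sigma`,
#' with zero-flux boundary and regularity at the origin, by a radial finite
#' volume scheme. The right-hand side is projected to discrete zero disk
#' mean so the singular (constant) mode is harmless, and the solution is
#' gauge-fixed to zero disk mean. The full potential of the coupled model is
#' `phi = mu1 * Phi`; the tumor mass only scales it and never changes its
#' shape, so `Phi` is computed once per configuration.
#'
#' @param grid a [radial_grid()].
#' @param K potential diffusion coefficient (> 0).
#' @param sigma a [form_function()] (signal shape), or a numeric vector of
#'   values at the cell centers.
#' @return An object of class `scalar_field` (`kind = "potential"`).
#' @export
solve_chemo_potential <- function(grid, K, sigma) {
  stopifnot(inherits(grid, "radial_grid"), K > 0)
  s <- if (inherits(sigma, "form_function")) form_values(sigma, grid$r) else sigma
  stopifnot(length(s) == grid$M)
  rhs <- s - sum(grid$w * s) / sum(grid$w)
  M <- grid$M; dr <- grid$dr
  ## interior face conductances K * r_f / dr; no flux through r = 0 and r = radius
  cond <- K * grid$rf / dr
  lo <- -cond[1:M]                 # coupling to cell m-1 through face m
  up <- -cond[2:(M + 1)]           # coupling to cell m+1 through face m+1
  lo[1] <- 0; up[M] <- 0
  di <- -(lo + up)
  b <- rhs * grid$r * dr
  ## replace the last equation (redundant: weighted rows sum to zero) by the
  ## zero-disk-mean gauge; solve the resulting tridiagonal-plus-full-row
  ## system densely (M is small)
  A <- matrix(0, M, M)
  A[cbind(1:M, 1:M)] <- di
  A[cbind(2:M, 1:(M - 1))] <- lo[2:M]
  A[cbind(1:(M - 1), 2:M)] <- up[1:(M - 1)]
  A[M, ] <- grid$w
  b[M] <- 0
  phi <- tryCatch(solve(A, b), error = function(e)
    stop("potential solve failed beyond the gauge null-space: ", conditionMessage(e)))
  phi <- phi - sum(grid$w * phi) / sum(grid$w)
  structure(list(values = phi, kind = "potential", grid = grid),
            class = "scalar_field")
}

## Tridiagonal finite-volume operator of the stationary immune-cell equation
## gamma C - div(D grad C) + mu1 div(chi C grad Phi) = mu1 R, C(radius) = 0.
## Returns the tridiagonal bands and the source vector b such that
## A(mu1) C = mu1 * b. Advection is first-order upwind on face velocities
## u_f = mu1 chi dPhi/dr; the half-cell Dirichlet closure is used at the
## outer boundary.
immune_operator <- function(grid, params, phi, mu1) {
  M <- grid$M; dr <- grid$dr
  pv <- if (inherits(phi, "scalar_field")) phi$values else phi
  dphi <- diff(pv) / dr                     # interior face gradients, faces 2..M
  lo <- numeric(M); di <- numeric(M); up <- numeric(M)
  di <- params$gamma * grid$r * dr
  ## interior faces m = 2..M separate cells (m-1, m)
  rf <- grid$rf[2:M]
  dif <- params$D * rf / dr
  u <- mu1 * params$chi * dphi              # outward face velocity
  up_flux <- pmax(u, 0); dn_flux <- pmin(u, 0)
  ## contribution to cell m-1 (face is its east face):
  di[1:(M - 1)] <- di[1:(M - 1)] + dif + rf * up_flux
  up[1:(M - 1)] <- up[1:(M - 1)] - dif + rf * dn_flux
  ## contribution to cell m (face is its west face):
  di[2:M] <- di[2:M] + dif - rf * dn_flux
  lo[2:M] <- lo[2:M] - dif - rf * up_flux
  ## outer boundary face: C = 0 at r = radius, half-cell distance
  rb <- grid$rf[M + 1]
  difb <- params$D * rb / (dr / 2)
  ub <- mu1 * params$chi * (0 - pv[M]) / (dr / 2)
  di[M] <- di[M] + difb + rb * max(ub, 0)   # outflow carries C_M, inflow carries 0
  b <- params$R_influx * .tumeq_const$um3_per_mm3 * grid$r * dr
  list(lo = lo, di = di, up = up, b = b)
}

#' Stationary immune-cell concentration
#'
#' Solves the stationary drift-diffusion equation for the effector immune
#' cell concentration at a given residual tumor mass `mu1` (mm^3):
#' `gamma C - div(D grad C) + mu1 div(chi C grad Phi) = mu1 R`, with
#' `C = 0` on the boundary. First-order upwinding of the chemotactic drift
#' preserves positivity.
#'
#' @param grid a [radial_grid()].
#' @param params an [immune_parameters()].
#' @param phi potential shape from [solve_chemo_potential()] on the same grid.
#' @param mu1 residual tumor mass (mm^3, `>= 0`).
#' @return An object of class `scalar_field` (`kind = "concentration"`,
#'   units cell/mm^3).
#' @export
solve_immune_concentration <- function(grid, params, phi, mu1) {
  stopifnot(inherits(grid, "radial_grid"), inherits(params, "immune_params"),
            mu1 >= 0)
  opr <- immune_operator(grid, params, phi, mu1)
  C <- thomas_solve(opr$lo, opr$di, opr$up, mu1 * opr$b)
  if (any(!is.finite(C)))
    stop("immune concentration solve did not converge (non-finite values)")
  if (min(C) < -1e-12 * max(abs(C), 1))
    stop(sprintf("scheme violation: negative concentration %.3e", min(C)))
  structure(list(values = pmax(C, 0), kind = "concentration", grid = grid),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("scalar field (%s): M = %d, range [%.4g, %.4g]\n",
              x$kind, x$grid$M, min(x$values), max(x$values)))
  invisible(x)
}

#' Effective immune-induced death rate
#'
#' Evaluates `mu_bar_c = int_Omega delta(y) C(y) dy` by the disk-area
#' quadrature `sum(delta(r_m) C_m 2 pi r_m dr)`. At equilibrium this
#' size-uniform killing rate balances the Malthusian eigenvalue.
#'
#' @param C a concentration `scalar_field` (or numeric vector at centers).
#' @param delta a [form_function()] (killing-efficacy shape).
#' @param grid the [radial_grid()].
#' @return Scalar death rate (1/day).
#' @export
effective_death_rate <- function(C, delta, grid) {
  cv <- if (inherits(C, "scalar_field")) C$values else C
  if (length(cv) != grid$M) stop("field and grid sizes do not match")
  sum(form_values(delta, grid$r) * cv * grid$w)
}
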