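## Time integration of the coupled tumor-immune system, used to verify that
## the dynamics converge to the equilibrium predicted by the power-dichotomy
## procedure.
##
## Discretization is deliberately consistent with the stationary solvers:
## the size step reuses the same upwind transport and division quadrature as
## the eigen operator, and the implicit immune-cell step reuses the same
## radial finite-volume operator as the stationary concentration solve, so
## the discrete fixed point of the evolution coincides with the discrete
## equilibrium the predictor finds.

#' Initial state for the coupled simulation
#'
#' Default: one tumor cell placed as a narrow bump at the volume of a single
#' spherical cell of radius 15 um (14137.2 um^3), no activated immune cells.
#'
#' @param size_grid a [size_grid()].
#' @param radial_grid a [radial_grid()].
#' @param mu0 initial cell count (default 1).
#' @param z0 initial cell volume (um^3).
#' @return List with `n` (size density, cells/um^3) and `c` (immune
#'   concentration).
#' @export
initial_state <- function(size_grid, radial_grid, mu0 = 1,
                          z0 = .tumeq_const$cell_volume_um3) {
  n <- numeric(size_grid$I)
  i0 <- which.min(abs(size_grid$z - z0))
  n[i0] <- mu0 / size_grid$h
  list(n = n, c = numeric(radial_grid$M))
}

#' Integrate the coupled tumor-immune system
#'
#' Advances the size density by an explicit upwind step (transport +
#' division + immune-induced death `-mu_bar_c n`) and the immune
#' concentration by a backward-Euler step of the drift-diffusion equation
#' with source `mu1(t) R`, the potential shape being computed once. The
#' splitting is first order, matching the spatial orders.
#'
#' @param spec a [growth_division_spec()] (constant or size-dependent rates).
#' @param params an [immune_parameters()].
#' @param forms list with `delta` and `sigma` [form_function()]s.
#' @param size_grid,radial_grid discretization grids.
#' @param state initial state from [initial_state()].
#' @param T_end horizon (days).
#' @param dt time step; `NULL` (default) picks `0.8 h / max V` from the
#'   explicit transport stability bound, and any user value is reduced to
#'   that bound if it exceeds it.
#' @param record_every record the moment trajectories every this many steps
#'   (default: about 400 records over the run).
#' @return An object of class `evolution_run`: data.frame `series` with
#'   columns `t`, `mu0`, `mu1` (mm^3), `mubar_c`, `diameter_mm`; final
#'   `state`; the grids; and the step actually used.
#' @export
run_evolution <- function(spec, params, forms, size_grid, radial_grid,
                          state = initial_state(size_grid, radial_grid),
                          T_end = 1000, dt = NULL, record_every = NULL) {
  h <- size_grid$h; z <- size_grid$z; I <- size_grid$I
  Vh <- spec$V(z + h / 2)
  a <- spec$a(z)
  dt_max <- 0.8 * h / max(Vh)
  dt <- if (is.null(dt)) dt_max else min(dt, dt_max)
  nsteps <- ceiling(T_end / dt)
  if (is.null(record_every)) record_every <- max(1L, nsteps %/% 400L)
  direct <- spec$kernel == "mitosis" && spec$kernel_mode == "direct"
  if (!direct) W <- gain_weights(spec, size_grid)
  jmap <- 2L * seq_len(I) - 1L
  ok <- jmap <= I
  phi <- solve_chemo_potential(radial_grid, params$K, forms$sigma)
  delta_w <- form_values(forms$delta, radial_grid$r) * radial_grid$w
  mdr <- radial_grid$r * radial_grid$dr
  n <- state$n; cvec <- state$c
  rec_t <- rec_mu0 <- rec_mu1 <- rec_mub <- numeric(0)
  um3 <- .tumeq_const$um3_per_mm3
  for (s in seq_len(nsteps)) {
    mu1 <- h * sum(z * n) / um3             # mm^3
    mubar <- sum(delta_w * cvec)
    ## size step (explicit)
    Fo <- Vh * n
    Fi <- c(0, Fo[-I])
    gain <- numeric(I)
    if (direct) gain[ok] <- 4 * a[jmap[ok]] * n[jmap[ok]]
    else gain <- as.numeric(W %*% n)
    n <- n - (dt / h) * (Fo - Fi) + dt * (gain - a * n) - dt * mubar * n
    n[1] <- 0
    if (anyNA(n) || any(n < -1e-8 * max(abs(n))))
      stop(sprintf("instability at t = %.2f: reduce dt", s * dt))
    n[n < 0] <- 0
    ## immune step (implicit), with the mass after the size update
    mu1 <- h * sum(z * n) / um3
    opr <- immune_operator(radial_grid, params, phi, mu1)
    cvec <- thomas_solve(opr$lo, opr$di + mdr / dt, opr$up,
                         (mdr / dt) * cvec + mu1 * opr$b)
    if (s %% record_every == 0L || s == nsteps) {
      rec_t <- c(rec_t, s * dt)
      rec_mu0 <- c(rec_mu0, h * sum(n))
      rec_mu1 <- c(rec_mu1, mu1)
      rec_mub <- c(rec_mub, sum(delta_w * cvec))
    }
  }
  series <- data.frame(t = rec_t, mu0 = rec_mu0, mu1 = rec_mu1,
                       mubar_c = rec_mub,
                       diameter_mm = mass_to_diameter(rec_mu1))
  structure(list(series = series, state = list(n = n, c = cvec),
                 size_grid = size_grid, radial_grid = radial_grid,
                 dt = dt, T_end = nsteps * dt),
            class = "evolution_run")
}

#' @export
print.evolution_run <- function(x, ...) {
  k <- nrow(x$series)
  cat(sprintf("evolution run to t = %.1f days (dt = %.3g): final mu1 = %.4e mm^3, mubar_c = %.6g\n",
              x$T_end, x$dt, x$series$mu1[k], x$series$mubar_c[k]))
  invisible(x)
}

#' Discrepancy between simulated and predicted equilibrium mass
#'
#' Checks that the run reached a quasi-steady state (relative drift of
#' `mu1` below `drift_tol` over the last 10% of the horizon) and returns
#' `E_mu1 = |mu1_f - mu1_pd| / mu1_f`, the relative difference between the
#' final simulated mass and the dichotomy prediction.
#'
#' @param run an [run_evolution()] result.
#' @param prediction an `equilibrium_result`, or a number (`mu1_pd`, mm^3).
#' @param drift_tol quasi-steady threshold (default `1e-6`).
#' @export
compare_with_prediction <- function(run, prediction, drift_tol = 1e-6) {
  mu_pd <- if (inherits(prediction, "equilibrium_result")) prediction$mu1
           else as.numeric(prediction)
  s <- run$series
  tail_idx <- which(s$t >= 0.9 * max(s$t))
  drift <- diff(range(s$mu1[tail_idx])) / s$mu1[length(s$mu1)]
  if (!is.finite(drift) || drift > drift_tol)
    stop(sprintf("run is not quasi-steady: relative mu1 drift %.3e over the last 10%% of the horizon (tolerance %.1e)",
                 drift, drift_tol))
  mu_f <- s$mu1[length(s$mu1)]
  abs(mu_f - mu_pd) / mu_f
}
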