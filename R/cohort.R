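## Reduced tumor-growth model and synthetic mouse cohorts.
##
## The immune-free reduced dynamics follow the closed moment system
## d mu0/dt = a mu0, d mu1/dt = V mu0, dc/dt = R mu1. Individual parameters
## (a, V, R) are log-normal around population values with a correlation
## between a and R on the log scale; measurements carry proportional noise
## and may be left-censored at a limit of quantification.

#' Population parameters of the mouse tumor-growth study
#'
#' Fixed effects, log-scale random-effect standard deviations, the
#' correlation of the `a` and `R` random effects and the proportional-error
#' factors for the three measurement types (0: cell count, 1: tumor volume,
#' 2: immune concentration).
#'
#' @param a_pop,V_pop,R_pop fixed effects (defaults 0.12, 816.33, 2.2e-6).
#' @param omega_a,omega_V,omega_R log-scale random-effect SDs
#'   (defaults 0.20, 0.51, 0.84).
#' @param rho_aR correlation of the `a` and `R` random effects (default 0.8).
#' @param b proportional-error factors, length 3 (defaults 0.37, 0.17, 0.18).
#' @return An object of class `population_params`.
#' @export
population_parameters <- function(a_pop = 0.12, V_pop = 816.33, R_pop = 2.2e-6,
                                  omega_a = 0.20, omega_V = 0.51,
                                  omega_R = 0.84, rho_aR = 0.8,
                                  b = c(0.37, 0.17, 0.18)) {
  stopifnot(a_pop > 0, V_pop > 0, R_pop > 0, omega_a >= 0, omega_V >= 0,
            omega_R >= 0, abs(rho_aR) < 1, length(b) == 3, all(b >= 0))
  structure(list(a_pop = a_pop, V_pop = V_pop, R_pop = R_pop,
                 omega_a = omega_a, omega_V = omega_V, omega_R = omega_R,
                 rho_aR = rho_aR, b = b),
            class = "population_params")
}

#' Closed-form reduced moments
#'
#' Evaluates the immune-free moment system at times `t`:
#' `mu0 = mu0(0) exp(a t)`,
#' `mu1 = mu1(0) + (V/a) mu0(0) (exp(a t) - 1)`,
#' `c = c(0) + R (mu1(0) t + (V/a) mu0(0) ((exp(a t) - 1)/a - t))`.
#' The `a -> 0` limits (`mu1` linear, `c` quadratic in `t`) are used below
#' a small threshold.
#'
#' @param t times (days, nonnegative).
#' @param a,V,R individual parameters (`a >= 0`).
#' @param ics named initial conditions `c(mu0 = , mu1 = , c0 = )`; defaults
#'   to the study's inoculum: 5e5 cells of 15 um radius (7.1 mm^3 expressed
#'   in um^3) and no activated immune cells.
#' @return data.frame with columns `t`, `mu0`, `mu1`, `c`.
#' @export
reduced_moments <- function(t, a, V, R,
                            ics = c(mu0 = 5e5,
                                    mu1 = 5e5 * .tumeq_const$cell_volume_um3,
                                    c0 = 0)) {
  stopifnot(all(t >= 0), a >= 0)
  mu0_0 <- ics[["mu0"]]; mu1_0 <- ics[["mu1"]]; c0 <- ics[["c0"]]
  if (a > 1e-12) {
    e <- exp(a * t)
    mu0 <- mu0_0 * e
    mu1 <- mu1_0 + (V / a) * mu0_0 * (e - 1)
    cc <- c0 + R * (mu1_0 * t + (V / a) * mu0_0 * ((e - 1) / a - t))
  } else {
    mu0 <- rep(mu0_0, length(t))
    mu1 <- mu1_0 + V * mu0_0 * t
    cc <- c0 + R * (mu1_0 * t + V * mu0_0 * t^2 / 2)
  }
  data.frame(t = t, mu0 = mu0, mu1 = mu1, c = cc)
}

#' Simulate a synthetic mouse cohort
#'
#' Draws per-mouse `(a, V, R)` log-normally around the population values
#' with `covar(log a, log R) = rho_aR omega_a omega_R`, evaluates the
#' reduced-moment trajectories at the observation schedule, adds
#' proportional noise `value * (1 + b_k eps)`, `eps ~ N(0,1)`, and flags
#' observations falling below the limit of quantification as left-censored
#' (the recorded interval is `[0, loq_k]`; censored rows carry no value).
#'
#' @param pop a [population_parameters()].
#' @param n_mice number of mice.
#' @param schedule list of three numeric vectors of observation times
#'   (days), one per measurement type `0:2`.
#' @param loq limits of quantification per type (length 3; `NA` disables
#'   censoring for that type). Default: no censoring.
#' @param ics initial conditions as in [reduced_moments()].
#' @param seed integer seed.
#' @return List with `observations` (long data.frame: `mouse`, `type`,
#'   `t`, `value`, `censored`, `interval_lo`, `interval_hi`) and `truth`
#'   (data.frame of the true per-mouse parameters).
#' @export
simulate_cohort <- function(pop, n_mice,
                            schedule = list(type0 = c(7, 14, 21, 28),
                                            type1 = c(7, 14, 21, 28),
                                            type2 = c(7, 14, 21, 28)),
                            loq = c(NA, NA, NA),
                            ics = c(mu0 = 5e5,
                                    mu1 = 5e5 * .tumeq_const$cell_volume_um3,
                                    c0 = 0),
                            seed = 1L) {
  stopifnot(inherits(pop, "population_params"), n_mice >= 1,
            length(schedule) == 3, length(loq) == 3)
  if (!is.null(seed)) set.seed(seed)
  Sig <- diag(c(pop$omega_a, pop$omega_V, pop$omega_R)^2)
  Sig[1, 3] <- Sig[3, 1] <- pop$rho_aR * pop$omega_a * pop$omega_R
  if (min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
    stop("invalid random-effect covariance matrix")
  eta <- MASS::mvrnorm(n_mice, mu = c(0, 0, 0), Sigma = Sig)
  if (n_mice == 1) eta <- matrix(eta, nrow = 1)
  truth <- data.frame(mouse = seq_len(n_mice),
                      a = pop$a_pop * exp(eta[, 1]),
                      V = pop$V_pop * exp(eta[, 2]),
                      R = pop$R_pop * exp(eta[, 3]))
  rows <- vector("list", n_mice * 3L)
  ri <- 0L
  for (i in seq_len(n_mice)) {
    tr <- truth[i, ]
    for (k in 0:2) {
      tt <- schedule[[k + 1L]]
      if (length(tt) == 0) next
      f <- reduced_moments(tt, tr$a, tr$V, tr$R, ics)[[c("mu0", "mu1", "c")[k + 1L]]]
      y <- f * (1 + pop$b[k + 1L] * rnorm(length(tt)))
      cen <- !is.na(loq[k + 1L]) & y < loq[k + 1L]
      ri <- ri + 1L
      rows[[ri]] <- data.frame(mouse = i, type = k, t = tt,
                               value = ifelse(cen, NA_real_, y),
                               censored = cen,
                               interval_lo = ifelse(cen, 0, NA_real_),
                               interval_hi = ifelse(cen, loq[k + 1L], NA_real_))
    }
  }
  list(observations = do.call(rbind, rows[seq_len(ri)]), truth = truth)
}

#' Per-individual parameter recovery fit
#'
#' Weighted least squares on the log-transformed trajectories of one mouse
#' (the proportional error model is homoscedastic on the log scale), fitted
#' sequentially: `a` from the cell-count trajectory (exact linear
#' regression of `log mu0` on `t`), then `V` from the volume trajectory
#' given `a`, then `R` from the concentration trajectory given `(a, V)`.
#' Censored observations are excluded.
#'
#' @param observations long-format rows of one mouse (as produced by
#'   [simulate_cohort()]).
#' @param ics initial conditions as in [reduced_moments()].
#' @return Named vector `c(a = , V = , R = )`.
#' @export
fit_individual <- function(observations,
                           ics = c(mu0 = 5e5,
                                   mu1 = 5e5 * .tumeq_const$cell_volume_um3,
                                   c0 = 0)) {
  ## censored rows carry no value; nonpositive noisy values cannot enter a
  ## log-scale fit and are dropped the same way
  obs <- observations[!observations$censored & !is.na(observations$value) &
                        observations$value > 0, ]
  o0 <- obs[obs$type == 0, ]
  if (nrow(o0) < 2 || length(unique(o0$t)) < 2)
    stop("insufficient data: need >= 2 uncensored cell-count (type 0) observations at distinct times")
  ## log mu0 = log mu0(0) + a t, with mu0(0) known
  a_hat <- sum(o0$t * (log(o0$value) - log(ics[["mu0"]]))) / sum(o0$t^2)
  a_hat <- max(a_hat, 1e-8)
  o1 <- obs[obs$type == 1, ]
  obj1 <- function(V) {
    f <- reduced_moments(o1$t, a_hat, V, 1, ics)$mu1
    sum((log(o1$value) - log(f))^2)
  }
  V_hat <- if (nrow(o1) >= 1)
    optimize(obj1, interval = c(1e-6, 1e7))$minimum else NA_real_
  o2 <- obs[obs$type == 2, ]
  R_hat <- if (nrow(o2) >= 1 && !is.na(V_hat)) {
    ## c is proportional to R (c0 = 0): log R enters additively
    g <- reduced_moments(o2$t, a_hat, V_hat, 1, ics)$c
    keep <- g > 0 & o2$value > 0
    if (any(keep)) exp(mean(log(o2$value[keep]) - log(g[keep]))) else NA_real_
  } else NA_real_
  missing <- c("volume (type 1)", "concentration (type 2)")[c(nrow(o1) == 0, nrow(o2) == 0)]
  if (length(missing))
    stop("insufficient data: no uncensored observations of ",
         paste(missing, collapse = " and "))
  c(a = a_hat, V = V_hat, R = R_hat)
}
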