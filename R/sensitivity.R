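## Global sensitivity analysis of the equilibrium mass: parameter
## distributions, space-filling design, polynomial-chaos surrogate of
## ln(mu1) and pick-freeze Sobol indices of exp(surrogate).

#' Uncertain-parameter space of the equilibrium model
#'
#' The eight inputs of `mu1 = f(a, A, R, chi, D, A_sigma, gamma, K)` with
#' their study distributions: uniform over the tabulated ranges for
#' `A, chi, D, A_sigma, gamma, K` and log-normal for the estimated tumor
#' parameters `a` (meanlog `log(0.12)`, sdlog `0.20`) and `R`
#' (meanlog `log(2.2e-6)`, sdlog `0.84`). All eight are treated as
#' independent. For the standardized-cube representation the log-normal
#' marginals are truncated at their 0.1%/99.9% quantiles (symmetric in
#' probability, so log-scale means are preserved).
#'
#' @return An object of class `parameter_space`: a named list of marginals,
#'   each with `dist` (`"uniform"` or `"lognormal"`) and its parameters.
#' @export
parameter_space <- function() {
  sp <- list(
    a       = list(dist = "lognormal", meanlog = log(0.12), sdlog = 0.20),
    A       = list(dist = "uniform", lo = 2, hi = 57.6),
    R       = list(dist = "lognormal", meanlog = log(2.2e-6), sdlog = 0.84),
    chi     = list(dist = "uniform", lo = 86.4, hi = 8.64e6),
    D       = list(dist = "uniform", lo = 8.64e-5, hi = 1e-3),
    A_sigma = list(dist = "uniform", lo = 5e-17, hi = 6.25e-17),
    gamma   = list(dist = "uniform", lo = 0.02, hi = 1),
    K       = list(dist = "uniform", lo = 0.01, hi = 1))
  structure(sp, class = "parameter_space")
}

#' @export
print.parameter_space <- function(x, ...) {
  for (nm in names(x)) {
    m <- x[[nm]]
    if (m$dist == "uniform")
      cat(sprintf("  %-8s uniform [%g, %g]\n", nm, m$lo, m$hi))
    else
      cat(sprintf("  %-8s log-normal (meanlog %.4g, sdlog %.3g)\n",
                  nm, m$meanlog, m$sdlog))
  }
  invisible(x)
}

## map standardized-cube coordinates u in (0,1) to physical values; the
## log-normal marginals are truncated at their 0.1% / 99.9% quantiles so the
## standardized space is a bounded cube (one Legendre family serves every
## input, and the polynomial surrogate is never evaluated outside the range
## its design covered)
.lognormal_trunc <- c(lo = 0.001, hi = 0.999)
marginal_quantile <- function(m, u) {
  if (m$dist == "uniform") m$lo + u * (m$hi - m$lo)
  else qlnorm(.lognormal_trunc[["lo"]] +
                u * diff(.lognormal_trunc)[[1]],
              meanlog = m$meanlog, sdlog = m$sdlog)
}

#' Truncated total-degree multi-index basis
#'
#' Enumerates all multi-indices `alpha` in `N^k` with total degree
#' `sum(alpha) <= p` and at most `max_interaction` nonzero components. The
#' unrestricted basis has `choose(k + p, p)` terms; restricting the
#' interaction order shrinks the regression design accordingly. The design
#' size is `oversampling` times the basis size.
#'
#' @param k number of inputs (default 8).
#' @param p maximal total degree (default 5).
#' @param max_interaction maximal number of jointly active inputs per basis
#'   term (default `k`, i.e. unrestricted).
#' @param oversampling design-size multiplier (default 2).
#' @return An object of class `gpc_basis`: integer matrix `indices`
#'   (terms by k), `size`, `design_size`, and the settings.
#' @export
build_basis <- function(k = 8L, p = 5L, max_interaction = k, oversampling = 2) {
  stopifnot(k >= 1, p >= 1, max_interaction >= 1)
  idx <- list(integer(k))
  ## enumerate by choice of active dimensions (at most max_interaction) and
  ## positive degrees summing to <= p
  add_terms <- function(dims, degs) idx[[length(idx) + 1L]] <<- {
    v <- integer(k); v[dims] <- degs; v
  }
  active_sets <- function(r) utils::combn(k, r, simplify = FALSE)
  for (r in seq_len(min(max_interaction, k, p))) {
    degsets <- compositions_leq(r, p)
    for (dims in active_sets(r))
      for (degs in degsets) add_terms(dims, degs)
  }
  M <- do.call(rbind, idx)
  structure(list(indices = M, size = nrow(M),
                 design_size = ceiling(oversampling * nrow(M)),
                 k = k, p = p, max_interaction = max_interaction,
                 oversampling = oversampling),
            class = "gpc_basis")
}

## all vectors of r positive integers with sum <= p
compositions_leq <- function(r, p) {
  if (r > p) return(list())
  out <- list()
  rec <- function(prefix, remaining, left) {
    if (left == 0L) { out[[length(out) + 1L]] <<- prefix; return() }
    for (d in seq_len(remaining - (left - 1L)))
      rec(c(prefix, d), remaining - d, left - 1L)
  }
  rec(integer(0), p, r)
  out
}

#' @export
print.gpc_basis <- function(x, ...) {
  cat(sprintf("gPC basis: k = %d, degree <= %d, interaction <= %d: %d terms (design %d)\n",
              x$k, x$p, x$max_interaction, x$size, x$design_size))
  invisible(x)
}

#' Space-filling sample of the parameter space
#'
#' Latin hypercube draws in the standardized unit cube, mapped through each
#' marginal's quantile function. Reproducible for a given seed.
#'
#' @param space a [parameter_space()].
#' @param n number of draws.
#' @param seed integer seed.
#' @return List with `u` (n-by-k matrix in the unit cube) and `theta`
#'   (data.frame of physical values, named after the space).
#' @export
sample_parameters <- function(space, n, seed = 1L) {
  stopifnot(inherits(space, "parameter_space"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- length(space)
  u <- lhs::randomLHS(n, k)
  colnames(u) <- names(space)
  theta <- as.data.frame(
    lapply(names(space), function(nm) marginal_quantile(space[[nm]], u[, nm])))
  names(theta) <- names(space)
  list(u = u, theta = theta)
}

## orthonormal shifted Legendre polynomials on [0, 1]: every marginal is
## mapped isoprobabilistically to the unit cube (with the log-normals
## truncated, see above), so one family serves all eight inputs
poly_values <- function(u, p, dist) {
  x <- 2 * u - 1
  P <- matrix(0, length(u), p + 1)
  P[, 1] <- 1
  if (p >= 1) P[, 2] <- x
  if (p >= 2) for (m in 1:(p - 1))
    P[, m + 2] <- ((2 * m + 1) * x * P[, m + 1] - m * P[, m]) / (m + 1)
  sweep(P, 2, sqrt(2 * (0:p) + 1), "*")
}

basis_matrix <- function(u, basis, dists) {
  idx <- basis$indices
  L <- lapply(seq_len(basis$k),
              function(d) poly_values(u[, d], basis$p, dists[d]))
  X <- matrix(1, nrow(u), basis$size)
  for (t in seq_len(basis$size)) {
    al <- idx[t, ]
    for (d in which(al > 0L)) X[, t] <- X[, t] * L[[d]][, al[d] + 1L]
  }
  X
}

#' Fit the polynomial-chaos surrogate of ln(mu1)
#'
#' Least-squares regression of the log equilibrium mass on orthonormal
#' polynomials of the standardized inputs. The goodness of fit is measured
#' by leave-one-out cross validation (computed in closed form from the
#' regression hat values).
#'
#' @param u design points in the unit cube (from [sample_parameters()]).
#' @param log_mu1 log of the model output at the design points.
#' @param basis a [build_basis()].
#' @param space the [parameter_space()] (supplies the marginal families).
#' @return An object of class `gpc_surrogate`: `coefficients`, `basis`,
#'   `dists`, `loo` (relative leave-one-out RMSE), `residual_sd`.
#' @export
fit_log_surrogate <- function(u, log_mu1, basis, space = parameter_space()) {
  stopifnot(inherits(basis, "gpc_basis"), nrow(u) == length(log_mu1))
  if (nrow(u) < basis$size)
    stop(sprintf("need at least %d evaluations for %d basis terms; increase oversampling",
                 basis$size, basis$size))
  dists <- vapply(space, function(m) m$dist, character(1))
  X <- basis_matrix(u, basis, dists)
  fit <- lm.fit(X, log_mu1)
  if (fit$rank < basis$size)
    stop("rank-deficient design; increase oversampling")
  hat <- rowSums(qr.Q(fit$qr)^2)
  loo_resid <- fit$residuals / pmax(1 - hat, .Machine$double.eps)
  structure(list(coefficients = fit$coefficients, basis = basis,
                 dists = dists,
                 loo = sqrt(mean(loo_resid^2)) / sd(log_mu1),
                 residual_sd = sd(fit$residuals)),
            class = "gpc_surrogate")
}

#' @export
print.gpc_surrogate <- function(x, ...) {
  cat(sprintf("gPC surrogate: %d terms, relative LOO error %.3g\n",
              x$basis$size, x$loo))
  invisible(x)
}

#' Evaluate the surrogate
#'
#' @param surrogate a [fit_log_surrogate()] result.
#' @param u points in the unit cube (matrix, k columns).
#' @param exponentiate return `exp` of the surrogate (the mass itself)
#'   rather than its log (default FALSE).
#' @export
evaluate_surrogate <- function(surrogate, u, exponentiate = FALSE) {
  b <- surrogate$basis
  q <- surrogate$coefficients
  L <- lapply(seq_len(b$k),
              function(d) poly_values(u[, d], b$p, surrogate$dists[d]))
  y <- rep(q[1], nrow(u))
  idx <- b$indices
  for (t in 2:b$size) {
    al <- idx[t, ]
    nz <- which(al > 0L)
    v <- L[[nz[1]]][, al[nz[1]] + 1L]
    if (length(nz) > 1L)
      for (d in nz[-1]) v <- v * L[[d]][, al[d] + 1L]
    y <- y + q[t] * v
  }
  if (exponentiate) exp(y) else y
}

#' Sobol indices of the equilibrium mass by pick-freeze Monte Carlo
#'
#' First-order, second-order and total Sobol indices of
#' `f = exp(surrogate)` (the mass itself, not its log, since the variance
#' decomposition of interest is that of `mu1`), computed with the
#' two-sample pick-freeze estimators: with independent sample matrices A
#' and B,
#' `V_i = mean(f(A) f(B with column i from A)) - f0^2`,
#' `V_ij = mean(f(A) f(B with columns i,j from A)) - f0^2 - V_i - V_j`,
#' and the total index `S_Ti = 1 - V_{-i}/V` with
#' `V_{-i} = mean(f(A) f(A with column i from B)) - f0^2`.
#' Sobol indices are invariant under the monotone marginal transforms, so
#' the estimators run directly on the standardized cube.
#'
#' @param surrogate a [fit_log_surrogate()] result.
#' @param N_mc Monte Carlo sample size (default `1e5`).
#' @param seed integer seed.
#' @param second_order compute the pairwise second-order indices
#'   (default TRUE).
#' @param transform function applied to the surrogate value before the
#'   variance decomposition; `exp` (default) yields the indices of the mass
#'   itself when the surrogate models its log. Use `identity` to decompose
#'   the surrogate output directly.
#' @return An object of class `sobol_report`: `first`, `total` (named
#'   vectors), `second` (named vector over pairs), `f0`, `variance`, `N`,
#'   `lognormality_p` (Shapiro-Wilk p-value of the log output on a
#'   subsample, a diagnostic of the log-normal output shape).
#' @export
sobol_indices <- function(surrogate, N_mc = 1e5, seed = 1L,
                          second_order = TRUE, transform = exp) {
  k <- surrogate$basis$k
  nms <- names(surrogate$dists)
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(runif(N_mc * k), N_mc, k)
  B <- matrix(runif(N_mc * k), N_mc, k)
  f <- function(u) transform(evaluate_surrogate(surrogate, u))
  fA <- f(A)
  f0 <- mean(fA)
  V <- mean(fA^2) - f0^2
  if (V <= 0) stop("degenerate output variance")
  Si <- Sti <- setNames(numeric(k), nms)
  for (i in seq_len(k)) {
    Bi <- B; Bi[, i] <- A[, i]
    Si[i] <- (mean(fA * f(Bi)) - f0^2) / V
    Ai <- A; Ai[, i] <- B[, i]
    Sti[i] <- 1 - (mean(fA * f(Ai)) - f0^2) / V
  }
  second <- NULL
  if (second_order) {
    pairs <- utils::combn(k, 2)
    second <- setNames(numeric(ncol(pairs)),
                       apply(pairs, 2, function(ij)
                         paste(nms[ij], collapse = ":")))
    for (c0 in seq_len(ncol(pairs))) {
      ij <- pairs[, c0]
      Bij <- B; Bij[, ij] <- A[, ij]
      second[c0] <- (mean(fA * f(Bij)) - f0^2) / V - Si[ij[1]] - Si[ij[2]]
    }
  }
  lp <- tryCatch(suppressWarnings({
    lf <- log(fA[seq_len(min(5000, N_mc))])
    if (all(is.finite(lf))) shapiro.test(lf)$p.value else NA_real_
  }), error = function(e) NA_real_)
  structure(list(first = Si, total = Sti, second = second, f0 = f0,
                 variance = V, N = N_mc, seed = seed, lognormality_p = lp),
            class = "sobol_report")
}

#' @export
print.sobol_report <- function(x, ...) {
  cat(sprintf("Sobol report (pick-freeze, N = %g):\n", x$N))
  m <- rbind(first = round(x$first, 4), total = round(x$total, 4))
  print(m)
  if (!is.null(x$second)) {
    cat("leading second-order pairs:\n")
    print(round(sort(x$second, decreasing = TRUE)[1:6], 4))
  }
  invisible(x)
}

#' Equilibrium mass as a function of the eight uncertain parameters
#'
#' The model behind the sensitivity analysis: one power-dichotomy
#' equilibrium prediction per parameter vector (full stationary solver,
#' no linear shortcut).
#'
#' @param theta named numeric vector or one-row data.frame with entries
#'   `a, A, R, chi, D, A_sigma, gamma, K`.
#' @param M radial resolution (default 96; the sensitivity study trades a
#'   little spatial resolution for many model runs).
#' @param eps_d dichotomy tolerance.
#' @return Equilibrium mass `mu1` (mm^3).
#' @export
equilibrium_model <- function(theta, M = 96L, eps_d = 1e-8) {
  th <- unlist(theta)
  cfg <- equilibrium_config(a = th[["a"]], chi = th[["chi"]], D = th[["D"]],
                            gamma = th[["gamma"]], K = th[["K"]],
                            R_influx = th[["R"]], A = th[["A"]],
                            A_sigma = th[["A_sigma"]], M = M, eps_d = eps_d)
  equilibrium_from_config(cfg)$mu1
}

#' Full sensitivity pipeline
#'
#' Design, model evaluations, surrogate fit and Sobol indices in one call.
#'
#' @param space a [parameter_space()].
#' @param basis a [build_basis()] (default: degree 5, interaction order 2,
#'   oversampling 2, i.e. a 642-run design).
#' @param N_mc Monte Carlo sample size for the indices.
#' @param seed integer seed (drives design and Monte Carlo).
#' @param model function mapping a named parameter vector to `mu1`
#'   (default [equilibrium_model()]).
#' @return List with `design`, `mu1`, `surrogate`, `report`.
#' @export
run_sensitivity <- function(space = parameter_space(),
                            basis = build_basis(8L, 5L, 2L, 2),
                            N_mc = 1e5, seed = 1L,
                            model = equilibrium_model) {
  des <- sample_parameters(space, basis$design_size, seed = seed)
  mu1 <- vapply(seq_len(nrow(des$theta)),
                function(i) model(des$theta[i, , drop = FALSE]), numeric(1))
  sur <- fit_log_surrogate(des$u, log(mu1), basis, space)
  rep <- sobol_indices(sur, N_mc = N_mc, seed = seed + 1000L)
  list(design = des, mu1 = mu1, surrogate = sur, report = rep)
}
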