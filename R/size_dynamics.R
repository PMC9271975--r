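## Size axis, growth-division specification and the discrete shifted operator.
##
## The size variable z is the cell volume (um^3 in the biological setting,
## dimensionless in the analytic validation cases). The truncated axis [0, R]
## is discretized into I cells of constant width h = R/I with nodes
## z_i = (i-1) h, so the boundary condition N(0) = 0 sits on the grid.

#' Uniform size grid
#'
#' Truncated, uniformly discretized size axis for the growth-division
#' operator. The grid carries `I` nodes `z_i = (i-1) h`, `h = R_max / I`,
#' starting at the origin where the boundary condition `N(0) = 0` applies.
#'
#' @param R_max truncation of the size axis (volume units). Must be large
#'   enough that the eigenprofile is negligible at `R_max`; see
#'   [default_R_max()] for the analytic cases.
#' @param I number of grid cells (positive integer).
#' @return An object of class `size_grid` with fields `R_max`, `I`, `h`, `z`.
#' @examples
#' g <- size_grid(5, 1000)
#' g$h            # 0.005
#' @export
size_grid <- function(R_max, I) {
  stopifnot(is.numeric(R_max), length(R_max) == 1, R_max > 0,
            is.numeric(I), length(I) == 1, I >= 2, I == round(I))
  h <- R_max / I
  structure(list(R_max = R_max, I = as.integer(I), h = h,
                 z = (seq_len(I) - 1) * h),
            class = "size_grid")
}

#' @export
print.size_grid <- function(x, ...) {
  cat(sprintf("size grid: I = %d cells, h = %g, z in [0, %g]\n",
              x$I, x$h, x$R_max))
  invisible(x)
}

#' Growth-division specification
#'
#' Growth rate, division rate and fragmentation kernel of the size-structured
#' tumor-cell equation. Two built-in kernels are provided:
#'
#' * `"mitosis"`: symmetric binary division, two daughters of half the
#'   mother's size (a Dirac kernel). Handled either by direct index mapping
#'   (`kernel_mode = "direct"`, the default: `2 z_i` is always a grid node
#'   for the grid convention used here) or by a peaked-Gaussian
#'   regularization of the Dirac mass (`kernel_mode = "gaussian"`).
#' * `"uniform"`: uniform binary fragmentation, `k(z | z') = 2/z'` for
#'   `0 <= z <= z'`. Each division produces two daughters whose sizes are
#'   uniformly distributed below the mother's size, so number doubles and
#'   mass is conserved (`int z k dz = z'`).
#'
#' A `"custom"` kernel is a vectorized function `k(z, zprime)`.
#'
#' @param V growth rate: a positive constant or a function of size.
#' @param a division rate: a nonnegative constant or a function of size,
#'   not identically zero for eigenvalue computations.
#' @param kernel one of `"mitosis"`, `"uniform"`, `"custom"`.
#' @param kernel_fn for `kernel = "custom"`, a function `k(z, zprime)` of a
#'   vector of daughter sizes `z` and a scalar mother size `zprime`, giving
#'   the daughter-size distribution (support `z <= zprime`).
#' @param kernel_mode for the mitosis kernel: `"direct"` or `"gaussian"`.
#' @param gaussian_width standard deviation of the Gaussian regularization of
#'   the Dirac mass, in multiples of the grid step `h` (default 2).
#' @return An object of class `gd_spec`.
#' @examples
#' spec <- growth_division_spec(V = 0.6, a = 4, kernel = "mitosis")
#' @export
growth_division_spec <- function(V, a,
                                 kernel = c("mitosis", "uniform", "custom"),
                                 kernel_fn = NULL,
                                 kernel_mode = c("direct", "gaussian"),
                                 gaussian_width = 2) {
  kernel <- match.arg(kernel)
  kernel_mode <- match.arg(kernel_mode)
  Vf <- if (is.function(V)) V else { V0 <- V; function(z) rep(V0, length(z)) }
  af <- if (is.function(a)) a else { a0 <- a; function(z) rep(a0, length(z)) }
  if (kernel == "custom" && !is.function(kernel_fn))
    stop("kernel = \"custom\" requires a kernel_fn(z, zprime) function")
  structure(list(V = Vf, a = af, kernel = kernel, kernel_fn = kernel_fn,
                 kernel_mode = kernel_mode, gaussian_width = gaussian_width),
            class = "gd_spec")
}

## Quadrature weights of the division gain term: W[i, j] approximates
## h * a(z_j) k(z_i | z_j) so that (W N)_i ~ int_z^inf a(z') k(z|z') N(z') dz'.
## For the Dirac mitosis kernel in direct mode the integral is the point
## evaluation 4 a(2 z_i) N(2 z_i), i.e. a single entry of weight 4 a per row.
gain_weights <- function(spec, grid) {
  I <- grid$I; h <- grid$h; z <- grid$z
  a <- spec$a(z)
  if (any(a < 0)) stop("division rate a must be nonnegative on the grid")
  W <- matrix(0, I, I)
  if (spec$kernel == "mitosis" && spec$kernel_mode == "direct") {
    i <- seq_len(I); j <- 2L * i - 1L          # z_j = 2 z_i
    ok <- j <= I
    W[cbind(i[ok], j[ok])] <- 4 * a[j[ok]]
  } else if (spec$kernel == "mitosis") {       # peaked-Gaussian Dirac
    w <- spec$gaussian_width * h
    for (j in seq_len(I)) {
      ## k(z | z') = 2 * N(z; z'/2, w) as a function of z (daughters below
      ## the mother's size: rows 1..j)
      W[1:j, j] <- h * a[j] * 2 * dnorm(z[1:j] - z[j] / 2, sd = w)
    }
  } else if (spec$kernel == "uniform") {
    for (j in seq_len(I)) {
      if (z[j] > 0) W[1:j, j] <- h * a[j] * 2 / z[j]
    }
  } else {
    for (j in seq_len(I)) {
      W[1:j, j] <- h * a[j] * spec$kernel_fn(z[1:j], z[j])
    }
  }
  W
}

#' Lower bound on the admissible shift
#'
#' Evaluates the a priori bound under which the shifted discrete
#' growth-division operator is invertible and an inverse-power iteration
#' converges to a positive eigenvector:
#' \deqn{\Lambda_{\min} = \frac{\|V\|_\infty}{\min_j |V_{j+1/2}|}
#'   \max_k \Big(h \sum_{j=k}^I a_j k(z_k|z_j)\Big) - \min_j |a_j|.}
#' The bound is a property of the continuous operator; grid refinement does
#' not tighten or loosen it beyond quadrature error.
#'
#' @param spec a [growth_division_spec()].
#' @param grid a [size_grid()].
#' @return The shift lower bound (1/time units).
#' @export
shift_lower_bound <- function(spec, grid) {
  Vh <- spec$V(grid$z + grid$h / 2)
  if (any(Vh <= 0))
    stop("invalid spec: growth rate V must be positive on all half-grid points ",
         "for the shift bound (vanishing V requires a user-chosen shift)")
  W <- gain_weights(spec, grid)
  a <- spec$a(grid$z)
  max(abs(spec$V(grid$z)), Vh) / min(abs(Vh)) * max(rowSums(W)) - min(abs(a))
}

#' Assemble the discrete shifted growth-division operator
#'
#' Builds the I-by-I matrix of the truncated, shifted operator with upwind
#' transport, left-endpoint rectangle quadrature of the division gain and the
#' boundary condition `N(0) = 0` enforced in the first row:
#' \deqn{(T_\Lambda^h N)_i = F_i - F_{i-1} + h(\Lambda + a_i) N_i
#'   - h^2 \sum_{j \ge i} a_j k(z_i|z_j) N_j,\qquad F_i = V_{i+1/2} N_i.}
#'
#' @param spec a [growth_division_spec()].
#' @param grid a [size_grid()].
#' @param Lambda the shift (1/time). Must exceed [shift_lower_bound()] when
#'   that bound is computable; pass `check_bound = FALSE` to skip the check
#'   for coefficients outside its hypotheses (e.g. vanishing growth rate).
#' @param check_bound verify `Lambda > shift_lower_bound` (default TRUE).
#' @return An object of class `shifted_op` with the dense `matrix`, the
#'   `grid`, the shift `Lambda` and the gain-weight matrix `W`.
#' @export
assemble_shifted_operator <- function(spec, grid, Lambda, check_bound = TRUE) {
  stopifnot(inherits(spec, "gd_spec"), inherits(grid, "size_grid"),
            is.numeric(Lambda), length(Lambda) == 1)
  if (check_bound) {
    bound <- tryCatch(shift_lower_bound(spec, grid), error = function(e) NA_real_)
    if (!is.na(bound) && Lambda <= bound)
      stop(sprintf(paste0("shift Lambda = %g does not exceed the lower bound %g; ",
                          "inverse-power convergence is not guaranteed"),
                   Lambda, bound))
  }
  I <- grid$I; h <- grid$h; z <- grid$z
  a <- spec$a(z)
  Vh <- spec$V(z + h / 2)                     # V_{i+1/2}
  W <- gain_weights(spec, grid)
  Tm <- -h * W
  diag(Tm) <- diag(Tm) + Vh + h * (Lambda + a)
  Tm[cbind(2:I, 1:(I - 1))] <- Tm[cbind(2:I, 1:(I - 1))] - Vh[1:(I - 1)]
  ## boundary row: N_1 = N(0) = 0 (kept scaled like the other rows so the
  ## spurious mode it introduces never dominates the inverse iteration)
  Tm[1, ] <- 0
  Tm[1, 1] <- Vh[1] + h * (Lambda + a[1])
  structure(list(matrix = Tm, grid = grid, Lambda = Lambda, spec = spec),
            class = "shifted_op")
}

#' @export
print.shifted_op <- function(x, ...) {
  cat(sprintf("shifted growth-division operator: I = %d, Lambda = %g, kernel = %s\n",
              x$grid$I, x$Lambda, x$spec$kernel))
  invisible(x)
}

#' Leading eigenpair by inverse power iteration
#'
#' Computes the Malthusian growth rate `lambda` and the normalized asymptotic
#' size profile of the immune-free tumor population as the leading eigenpair
#' of the shifted discrete operator. The matrix (scaled by `1/h` so that its
#' spectrum is `Lambda - lambda_k`) is LU-factorized once, exploiting its
#' upper-Hessenberg structure, and the iteration
#' `q <- solve(N); N <- q / ||q||` runs from a random positive start vector
#' until the relative sup-norm change of the normalized vector falls below
#' `eps`. The eigenvalue is extracted as `lambda = Lambda - 1/mu` with
#' `mu = (q . N) / (N . N)`.
#'
#' @param op a [assemble_shifted_operator()] result.
#' @param eps relative stopping tolerance on the normalized vector (default
#'   `1e-6`).
#' @param seed integer seed for the random start vector. The converged
#'   eigenvalue does not depend on it.
#' @param max_iter iteration cap (default 5000).
#' @return An object of class `eigenpair`: `lam` (leading eigenvalue),
#'   `profile` (nonnegative, normalized to `h * sum(profile) = 1`),
#'   `iterations`, `residual` (last relative change), `grid`, `Lambda`.
#' @export
solve_leading_eigenpair <- function(op, eps = 1e-6, seed = 1L, max_iter = 5000L) {
  stopifnot(inherits(op, "shifted_op"), eps > 0, eps < 1)
  lu <- hessenberg_lu(op$matrix / op$grid$h)
  if (!is.null(seed)) set.seed(seed)
  I <- op$grid$I
  N <- runif(I)
  N <- N / sqrt(sum(N^2))
  rel <- Inf
  iter <- 0L
  for (k in seq_len(max_iter)) {
    q <- hessenberg_solve(lu$U, lu$m, N)
    Nn <- q / sqrt(sum(q^2))
    if (sum(Nn) < 0) Nn <- -Nn                # eigenvectors defined up to sign
    rel <- max(abs(Nn - N)) / max(abs(N))
    N <- Nn
    iter <- k
    if (rel <= eps) break
  }
  if (rel > eps)
    stop(sprintf("inverse power iteration did not converge in %d iterations (last relative change %.3e)",
                 max_iter, rel))
  if (min(N) < -1e-8 * max(abs(N)))
    stop("converged vector is sign-indefinite: the leading mode is not the Perron eigenvector (shift too small?)")
  q <- hessenberg_solve(lu$U, lu$m, N)
  mu <- sum(q * N) / sum(N * N)
  lam <- op$Lambda - 1 / mu
  prof <- pmax(N, 0)
  prof[1] <- 0                               # boundary condition N(0) = 0
  prof <- prof / (op$grid$h * sum(prof))
  structure(list(lam = lam, profile = prof, iterations = iter, residual = rel,
                 grid = op$grid, Lambda = op$Lambda),
            class = "eigenpair")
}

#' @export
print.eigenpair <- function(x, ...) {
  cat(sprintf("eigenpair: lambda = %.8g (%d iterations, residual %.2e), I = %d\n",
              x$lam, x$iterations, x$residual, x$grid$I))
  invisible(x)
}

#' Default truncation of the size axis
#'
#' Chooses `R_max` so that the analytic eigenprofile at `R_max` is below
#' `tail` times its maximum, using the slowest-decaying mode of each case.
#'
#' @param case an [analytic_case()].
#' @param tail relative tail threshold (default `1e-10`).
#' @export
default_R_max <- function(case, tail = 1e-10) {
  L <- -log(tail)
  switch(case$id,
    mitosis_const = L * case$V0 / (2 * case$a0),
    uniform_Vconst_alinear = {                # N ~ exp(-t^2/2), t = sqrt(a0/V0) z
      sqrt(2 * L / (case$a0 / case$V0)) * 1.2
    },
    uniform_Vlinear_apower = (L * case$n * case$V0 / case$a0)^(1 / case$n),
    stop("unknown case id"))
}

#' Analytic eigenpair catalog
#'
#' Closed-form eigenpairs used to validate the numerical solver.
#'
#' * `mitosis_const`: constant growth rate `V0` and division rate `a0` with
#'   the binary mitosis kernel. `lambda = a0` and the profile is the
#'   alternating exponential series with coefficients `alpha_0 = 1`,
#'   `alpha_n = 2 alpha_{n-1} / (2^n - 1)`.
#' * `uniform_Vconst_alinear`: uniform binary fragmentation
#'   (`k = 2/z'`), `V = V0`, `a = a0 z`. `lambda = sqrt(a0 V0)` and
#'   `N(z)` is proportional to `u exp(-u)` with `u = t + t^2/2`,
#'   `t = sqrt(a0/V0) z`.
#' * `uniform_Vlinear_apower`: uniform binary fragmentation, `V = V0 z`,
#'   `a = a0 z^n`. `lambda = V0` and
#'   `N(z)` is proportional to `exp(-a0 z^n / (n V0))`.
#'
#' @param id case identifier.
#' @param a0,V0 positive rate constants.
#' @param n power of the division rate (third case only).
#' @return An object of class `analytic_case`.
#' @export
analytic_case <- function(id = c("mitosis_const", "uniform_Vconst_alinear",
                                 "uniform_Vlinear_apower"),
                          a0, V0, n = 1L) {
  id <- match.arg(id)
  stopifnot(a0 > 0, V0 > 0, n >= 1)
  structure(list(id = id, a0 = a0, V0 = V0, n = n), class = "analytic_case")
}

#' Growth-division spec matching an analytic case
#' @param case an [analytic_case()].
#' @export
spec_for_case <- function(case) {
  switch(case$id,
    mitosis_const = growth_division_spec(case$V0, case$a0, "mitosis"),
    uniform_Vconst_alinear = {
      a0 <- case$a0
      growth_division_spec(case$V0, function(z) a0 * z, "uniform")
    },
    uniform_Vlinear_apower = {
      a0 <- case$a0; V0 <- case$V0; n <- case$n
      growth_division_spec(function(z) V0 * z, function(z) a0 * z^n, "uniform")
    })
}

#' Tabulate a closed-form eigenpair on a grid
#'
#' @param case an [analytic_case()].
#' @param grid a [size_grid()].
#' @param series_tol relative truncation threshold for the mitosis series
#'   (default `1e-13`: the dropped tail is negligible at double precision).
#' @return An `eigenpair` with the exact eigenvalue and the closed-form
#'   profile normalized to `h * sum(profile) = 1`.
#' @export
analytic_eigenpair <- function(case, grid, series_tol = 1e-13) {
  stopifnot(inherits(case, "analytic_case"), inherits(grid, "size_grid"))
  z <- grid$z
  if (case$id == "mitosis_const") {
    lam <- case$a0
    b <- case$a0 / case$V0
    alpha <- 1
    N <- exp(-2 * b * z)
    n <- 1
    repeat {
      alpha <- 2 * alpha / (2^n - 1)
      term <- (-1)^n * alpha * exp(-2^(n + 1) * b * z)
      N <- N + term
      if (alpha * exp(-2^(n + 1) * b * z[2]) < series_tol) break
      n <- n + 1
      if (n > 200) stop("mitosis series failed to reach the truncation tolerance")
    }
  } else if (case$id == "uniform_Vconst_alinear") {
    lam <- sqrt(case$a0 * case$V0)
    u <- sqrt(case$a0 / case$V0) * z
    u <- u + u^2 / 2
    N <- u * exp(-u)
  } else {
    lam <- case$V0
    c0 <- case$a0 / (case$n * case$V0)
    N <- exp(-c0 * z^case$n)
  }
  N <- pmax(N, 0)
  N <- N / (grid$h * sum(N))
  structure(list(lam = lam, profile = N, iterations = 0L, residual = 0,
                 grid = grid, Lambda = NA_real_),
            class = "eigenpair")
}

#' Eigenpair validation errors
#'
#' Relative eigenvalue error and L1 profile error between a numerical and an
#' analytic eigenpair on the same grid:
#' \deqn{E_\lambda = \frac{|\lambda - \tilde\lambda|}{\tilde\lambda},\qquad
#'   E_V = h \sum_i |N_i - N(z_i)|,}
#' both profiles being normalized by `h * sum(N) = 1`.
#'
#' @param numeric,analytic `eigenpair` objects on the same grid; `numeric`
#'   supplies `\tilde\lambda`.
#' @param grid the common [size_grid()].
#' @return Named vector `c(E_lambda =, E_V =)`.
#' @export
eigen_errors <- function(numeric, analytic, grid) {
  stopifnot(inherits(numeric, "eigenpair"), inherits(analytic, "eigenpair"))
  if (numeric$grid$I != grid$I || analytic$grid$I != grid$I ||
      abs(numeric$grid$R_max - grid$R_max) > 1e-12 * grid$R_max)
    stop("eigenpairs are not tabulated on the supplied grid")
  c(E_lambda = abs(analytic$lam - numeric$lam) / numeric$lam,
    E_V = grid$h * sum(abs(numeric$profile - analytic$profile)))
}

#' Solve an analytic validation case numerically
#'
#' Convenience driver: builds the spec and grid for an [analytic_case()],
#' picks an admissible shift, runs the inverse power iteration and returns
#' both eigenpairs with their errors.
#'
#' The shift is `shift_safety` times the a priori lower bound where that
#' bound applies. For the `uniform_Vlinear_apower` cases the growth rate
#' vanishes at the origin and the bound degenerates; a fixed moderate shift
#' (default 10) is used there and the solver's positivity check guards the
#' result.
#'
#' @param case an [analytic_case()].
#' @param I number of grid cells.
#' @param R_max truncation; default from [default_R_max()].
#' @param eps,seed,max_iter passed to [solve_leading_eigenpair()].
#' @param shift_safety multiplicative safety margin on the shift bound.
#' @param shift optional explicit shift overriding the default choice.
#' @return List with `numeric`, `analytic` (eigenpairs), `errors`, `grid`.
#' @export
solve_analytic_case <- function(case, I, R_max = default_R_max(case),
                                eps = 1e-6, seed = 1L, max_iter = 5000L,
                                shift_safety = 1.05, shift = NULL) {
  grid <- size_grid(R_max, I)
  spec <- spec_for_case(case)
  vanishing_V <- case$id == "uniform_Vlinear_apower"
  if (is.null(shift)) {
    shift <- if (vanishing_V) 10 * case$V0       # moderate fixed shift > lambda
             else shift_safety * shift_lower_bound(spec, grid)
  }
  op <- assemble_shifted_operator(spec, grid, shift, check_bound = !vanishing_V)
  num <- solve_leading_eigenpair(op, eps = eps, seed = seed, max_iter = max_iter)
  an <- analytic_eigenpair(case, grid)
  list(numeric = num, analytic = an,
       errors = eigen_errors(num, an, grid), grid = grid)
}
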