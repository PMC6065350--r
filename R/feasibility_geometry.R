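#' The feasibility cone of an interaction matrix
#'
#' \eqn{D_F(A)} is the open cone of strictly positive combinations of the
#' columns \eqn{v_i} of \eqn{A}: exactly the growth-rate vectors whose
#' equilibrium abundances are all positive.
#'
#' @param A interaction matrix (`feasnet_matrix` or numeric matrix).
#' @return an object of class `feasnet_cone` with fields `basis` (the
#'   columns of `A`) and `n`.
#' @export
feasibility_cone <- function(A) {
  if (inherits(A, "feasnet_matrix")) A <- A$A
  check_square_numeric(A, "cone basis")
  structure(list(basis = A, n = nrow(A)), class = "feasnet_cone")
}

#' Linear-programming membership oracle for the feasibility cone
#'
#' Decides whether `r` is a strictly positive combination of the cone's basis
#' columns by solving a phase-one linear program (via [boot::simplex()]) for
#' coefficients bounded below by a positivity margin. This route never
#' inverts the matrix, so it serves as an independent cross-check of
#' [is_feasible()]; the two agree away from the cone boundary. Intended for
#' small instances (testing); dimensions above `max_n` are rejected.
#'
#' @param cone a [feasibility_cone()].
#' @param r growth-rate vector to test.
#' @param margin strict-positivity margin required of every combination
#'   coefficient.
#' @param max_n largest dimension accepted (default 6).
#' @return `TRUE` iff a combination with all coefficients `>= margin` exists.
#' @export
cone_membership_oracle <- function(cone, r, margin = 1e-9, max_n = 6L) {
  stopifnot(inherits(cone, "feasnet_cone"))
  if (length(r) != cone$n) stop_config("r has wrong dimension")
  if (cone$n > max_n) {
    stop_config("oracle restricted to n <= ", max_n, " (small-instance testing)")
  }
  V <- cone$basis
  # substitute x = y + margin (y >= 0): V y = r - margin * V 1
  b <- r - margin * rowSums(V)
  # boot::simplex needs nonnegative right-hand sides; flip rows as required
  flip <- b < 0
  V[flip, ] <- -V[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  sol <- boot::simplex(
    a = rep(0, cone$n),
    A3 = V, b3 = b,
    eps = 1e-10
  )
  sol$solved == 1
}

#' Border angles of a two-species feasibility cone
#'
#' For `n = 2` the feasibility domain is the planar wedge between the two
#' basis columns. Returns their polar angles ordered so that the cone is
#' swept counter-clockwise from `angle_low` to `angle_high` within a
#' half-turn (the sweep equals the cone's opening angle).
#'
#' @param cone a 2-dimensional [feasibility_cone()].
#' @param tol tolerance for rejecting degenerate (parallel or antiparallel)
#'   bases.
#' @return named numeric vector `c(angle_low, angle_high)` in radians.
#' @export
cone_border_angles_2d <- function(cone, tol = 1e-12) {
  stopifnot(inherits(cone, "feasnet_cone"))
  if (cone$n != 2) stop_config("border angles are defined for n = 2 only")
  v1 <- cone$basis[, 1]
  v2 <- cone$basis[, 2]
  if (sum(v1^2) < tol || sum(v2^2) < tol) stop_config("degenerate basis: zero column")
  cross <- v1[1] * v2[2] - v1[2] * v2[1]
  dot <- sum(v1 * v2)
  sweep <- atan2(cross, dot) # signed angle from v1 to v2, in (-pi, pi]
  if (abs(cross) < tol * sqrt(sum(v1^2) * sum(v2^2))) {
    stop_config("degenerate basis: columns are parallel or antiparallel")
  }
  low <- if (sweep > 0) atan2(v1[2], v1[1]) else atan2(v2[2], v2[1])
  c(angle_low = low, angle_high = low + abs(sweep))
}

#' Parametric environment distributions over growth-rate space
#'
#' An environment distribution \eqn{\Xi} encodes the range of
#' environment-dependent parameter values (intrinsic growth rates) expected
#' in a location, as a sampleable probability distribution. Three families
#' are provided: multivariate gaussian, uniform over an axis-aligned box, and
#' a point mass.
#'
#' @param mean,cov mean vector and (symmetric positive semidefinite)
#'   covariance matrix of the gaussian.
#' @param lower,upper component-wise corners of the uniform box
#'   (`lower <= upper`).
#' @param location the point-mass location.
#' @return an object of class `feasnet_environment` with fields `kind`,
#'   `params`, and `n`.
#' @name environment_distribution
NULL

#' @rdname environment_distribution
#' @export
environment_gaussian <- function(mean, cov) {
  cov <- as.matrix(cov)
  check_square_numeric(cov, "covariance")
  if (length(mean) != nrow(cov)) stop_config("mean and covariance dimensions differ")
  if (max(abs(cov - t(cov))) > 1e-8) stop_config("covariance must be symmetric")
  if (min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop_config("covariance must be positive semidefinite")
  }
  structure(
    list(kind = "gaussian", params = list(mean = mean, cov = cov), n = length(mean)),
    class = "feasnet_environment"
  )
}

#' @rdname environment_distribution
#' @export
environment_uniform_box <- function(lower, upper) {
  if (length(lower) != length(upper)) stop_config("corner dimensions differ")
  if (any(lower > upper)) stop_config("box corners must satisfy lower <= upper")
  structure(
    list(kind = "uniform_box", params = list(lower = lower, upper = upper), n = length(lower)),
    class = "feasnet_environment"
  )
}

#' @rdname environment_distribution
#' @export
environment_point_mass <- function(location) {
  structure(
    list(kind = "point_mass", params = list(location = location), n = length(location)),
    class = "feasnet_environment"
  )
}

#' Sample growth-rate vectors from an environment distribution
#'
#' @param xi a `feasnet_environment`.
#' @param n_samples number of independent draws.
#' @param seed RNG seed; sampling is deterministic given the seed.
#' @return an `n_samples x n` matrix, one draw per row.
#' @export
sample_environment <- function(xi, n_samples, seed = 1L) {
  stopifnot(inherits(xi, "feasnet_environment"))
  if (n_samples < 1) stop_config("n_samples must be >= 1")
  n <- xi$n
  with_seed(seed, switch(xi$kind,
    gaussian = {
      s <- MASS::mvrnorm(n_samples, mu = xi$params$mean, Sigma = xi$params$cov)
      matrix(s, nrow = n_samples, ncol = n)
    },
    uniform_box = {
      lo <- xi$params$lower
      hi <- xi$params$upper
      s <- matrix(runif(n_samples * n), n_samples, n)
      sweep(sweep(s, 2, hi - lo, `*`), 2, lo, `+`)
    },
    point_mass = matrix(xi$params$location, n_samples, n, byrow = TRUE)
  ))
}

#' Overlap between a feasibility domain and an environment distribution
#'
#' Monte Carlo estimate of
#' \eqn{\Gamma(D_F(A) \cap \Xi) = vol(D_F(A) \cap \Xi) / vol(\Xi)}: the
#' probability mass of \eqn{\Xi} lying inside the feasibility domain of `A`.
#' For a uniform-box \eqn{\Xi} this is literally the volume ratio; for other
#' distributions it generalizes it as \eqn{\Xi}-probability. Draws landing
#' numerically on the cone boundary (any equilibrium component within
#' `boundary_tol` of 0) count as outside, honouring the strict positivity in
#' the domain's definition.
#'
#' @param A interaction matrix (`feasnet_matrix` or numeric matrix).
#' @param xi a `feasnet_environment` of matching dimension.
#' @param n_samples Monte Carlo draws.
#' @param seed RNG seed.
#' @param boundary_tol positivity threshold separating inside from boundary.
#' @return an object of class `feasnet_gamma`: list with `gamma`, binomial
#'   `se = sqrt(gamma (1 - gamma) / n_samples)`, `n_samples`, `seed`.
#' @export
estimate_gamma <- function(A, xi, n_samples = 1e4, seed = 1L,
                           boundary_tol = 1e-12) {
  A <- as_interaction_matrix(A)
  stopifnot(inherits(xi, "feasnet_environment"))
  if (xi$n != nrow(A)) stop_config("environment dimension does not match matrix")
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1e-12) {
    stop_degenerate(sprintf("degenerate interaction matrix (rcond = %.3g)", rc), rcond = rc)
  }
  draws <- sample_environment(xi, n_samples, seed)
  nstar <- solve(A, t(draws)) # n x n_samples equilibria
  inside <- colSums(nstar > boundary_tol) == nrow(A)
  g <- mean(inside)
  structure(
    list(
      gamma = g, se = sqrt(g * (1 - g) / n_samples),
      n_samples = as.integer(n_samples), seed = as.integer(seed)
    ),
    class = "feasnet_gamma"
  )
}

#' Relative size of the feasibility cone
#'
#' Fraction of directions drawn uniformly on the unit sphere that fall inside
#' the feasibility cone — a normalized solid-angle estimate in `[0, 1]`. The
#' identity matrix (the positive orthant) gives \eqn{2^{-n}}. Invariant under
#' positive rescaling of the basis columns.
#'
#' @inheritParams estimate_gamma
#' @return an object of class `feasnet_gamma` (same fields; `gamma` holds
#'   the cone-size estimate).
#' @export
relative_cone_size <- function(A, n_samples = 1e4, seed = 1L,
                               boundary_tol = 1e-12) {
  A <- as_interaction_matrix(A)
  n <- nrow(A)
  dirs <- with_seed(seed, {
    z <- matrix(rnorm(n_samples * n), n_samples, n)
    z / sqrt(rowSums(z^2))
  })
  nstar <- solve(A, t(dirs))
  inside <- colSums(nstar > boundary_tol) == n
  g <- mean(inside)
  structure(
    list(
      gamma = g, se = sqrt(g * (1 - g) / n_samples),
      n_samples = as.integer(n_samples), seed = as.integer(seed)
    ),
    class = "feasnet_gamma"
  )
}

#' @export
print.feasnet_gamma <- function(x, ...) {
  cat(sprintf(
    "<feasnet_gamma> gamma = %.4f (se %.4f, %d draws, seed %d)\n",
    x$gamma, x$se, x$n_samples, x$seed
  ))
  invisible(x)
}
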