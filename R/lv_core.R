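#' Equilibrium abundances of the Lotka-Volterra model
#'
#' Solves \eqn{A N^* = r} for the interior equilibrium of
#' \eqn{\dot N = N (r - A N)}. The matrix is rejected as degenerate when its
#' reciprocal condition estimate falls below `1 / condition_bound`, signalling
#' an unusable community draw that callers should resample.
#'
#' @param A interaction matrix (a `feasnet_matrix` or plain numeric matrix).
#' @param r growth-rate vector of length `n`.
#' @param condition_bound condition-number bound beyond which the matrix is
#'   declared degenerate (default `1e12`).
#' @return the equilibrium abundance vector `N*`.
#' @export
equilibrium_abundances <- function(A, r, condition_bound = 1e12) {
  A <- as_interaction_matrix(A)
  if (length(r) != nrow(A)) stop_config("length(r) must equal nrow(A)")
  rc <- rcond(A)
  if (!is.finite(rc) || rc < 1 / condition_bound) {
    stop_degenerate(
      sprintf("interaction matrix is numerically singular (rcond = %.3g)", rc),
      rcond = rc
    )
  }
  solve(A, r)
}

# Accept a feasnet_matrix or a bare square numeric matrix.
as_interaction_matrix <- function(A) {
  if (inherits(A, "feasnet_matrix")) A <- A$A
  check_square_numeric(A, "interaction matrix")
  if (any(diag(A) <= 0)) stop_config("interaction matrix diagonal must be strictly positive")
  A
}

#' Is a growth-rate vector inside the feasibility domain?
#'
#' The feasibility domain \eqn{D_F(A)} is the set of growth-rate vectors
#' whose equilibrium \eqn{A^{-1} r} is strictly positive in every component
#' (all species coexist at equilibrium). Strict positivity is checked against
#' the threshold `eps_pos` (default 0: components must be `> 0` exactly;
#' raise it to study numerical borderline cases).
#'
#' @inheritParams equilibrium_abundances
#' @param eps_pos positivity threshold for each equilibrium component.
#' @return `TRUE` iff every component of `solve(A, r)` exceeds `eps_pos`.
#' @export
is_feasible <- function(A, r, eps_pos = 0, condition_bound = 1e12) {
  nstar <- equilibrium_abundances(A, r, condition_bound = condition_bound)
  all(nstar > eps_pos)
}

#' Sample a lognormal abundance distribution
#'
#' @param n number of species.
#' @param meanlog,sdlog parameters of the lognormal law on the log scale.
#' @param seed RNG seed.
#' @return a strictly positive abundance vector of length `n`.
#' @export
sample_lognormal_abundances <- function(n, meanlog = 0, sdlog = 1, seed = 1L) {
  if (sdlog < 0) stop_config("sdlog must be >= 0")
  with_seed(seed, rlnorm(n, meanlog = meanlog, sdlog = sdlog))
}

#' Initialize a community inside its feasibility domain
#'
#' Draws a lognormal abundance vector \eqn{N^*} and back-solves the growth
#' rates as \eqn{r = A N^*}, so the community starts at a feasible interior
#' equilibrium by construction: `is_feasible(A, r)` is guaranteed `TRUE`.
#' Paired communities initialized with the same seed share the identical
#' abundance vector, which is the controlled comparison used throughout the
#' perturbation experiment.
#'
#' @inheritParams equilibrium_abundances
#' @inheritParams sample_lognormal_abundances
#' @param abundances optional pre-drawn abundance vector (overrides sampling);
#'   used to share one draw across paired structures.
#' @return a list with components `r` (growth rates) and `N_star`
#'   (equilibrium abundances).
#' @export
initialize_feasible_community <- function(A, meanlog = 0, sdlog = 1, seed = 1L,
                                          abundances = NULL) {
  A <- as_interaction_matrix(A)
  n <- nrow(A)
  N_star <- abundances %||% sample_lognormal_abundances(n, meanlog, sdlog, seed)
  if (length(N_star) != n) stop_config("abundances length must equal n")
  if (any(N_star <= 0)) stop_config("abundances must be strictly positive")
  list(r = drop(A %*% N_star), N_star = N_star)
}
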