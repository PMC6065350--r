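# Shared fixtures for the suite: small deterministic communities and a
# generator of random well-conditioned interaction matrices.

default_specs <- function(seed = 1L) {
  list(
    modular = structure_spec(structure = "modular", seed = seed),
    nested = structure_spec(structure = "nested", seed = seed),
    random = structure_spec(structure = "random", seed = seed)
  )
}

# random diagonally-dominated matrix with rcond and interior-equilibrium
# filters, for oracle cross-checks
random_community <- function(n, rng, min_rcond = 1e-6, interior_tol = 0) {
  repeat {
    A <- matrix(rng(n * n), n, n)
    diag(A) <- abs(diag(A)) + 1
    r <- rng(n)
    if (rcond(A) < min_rcond) next
    if (interior_tol > 0 && any(abs(solve(A, r)) < interior_tol)) next
    return(list(A = A, r = r))
  }
}

tiny_config <- function(n_reps = 20L, seed = 1L, magnitude = 0.5) {
  experiment_config(n_reps = n_reps, seed = seed, magnitude = magnitude)
}
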