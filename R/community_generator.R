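#' Specify a binary interaction topology
#'
#' A `structure_spec` describes how presence/absence interactions are
#' arranged among `n` species: packed into modules, nested by degree, or
#' placed uniformly at random. All three structures built from one spec share
#' the same off-diagonal link budget `round(connectance * n * (n - 1) / 2)`,
#' so they differ only in the arrangement of interactions, not their number.
#'
#' @param n species count. The default 21 divides evenly into 3 modules of 7.
#' @param structure one of `"modular"`, `"nested"`, `"random"`.
#' @param n_modules number of modules (modular only); must divide `n`.
#' @param connectance target fraction of realized off-diagonal species pairs,
#'   in (0, 1].
#' @param within_between_ratio target ratio of within-module to between-module
#'   link probability (modular only).
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return an object of class `feasnet_structure_spec`.
#' @export
structure_spec <- function(n = 21L, structure = c("modular", "nested", "random"),
                           n_modules = 3L, connectance = 0.3,
                           within_between_ratio = 8, seed = 1L) {
  structure <- match.arg(structure)
  if (length(n) != 1L || n < 2 || n != round(n)) {
    stop_config("n must be an integer >= 2")
  }
  if (!is.numeric(connectance) || connectance <= 0 || connectance > 1) {
    stop_config("connectance must lie in (0, 1]")
  }
  if (structure == "modular") {
    if (n_modules < 1 || n %% n_modules != 0) {
      stop_config("n (", n, ") must be divisible by n_modules (", n_modules, ")")
    }
    if (within_between_ratio <= 0) stop_config("within_between_ratio must be > 0")
  }
  structure(
    list(
      n = as.integer(n), structure = structure,
      n_modules = as.integer(n_modules), connectance = connectance,
      within_between_ratio = within_between_ratio, seed = as.integer(seed)
    ),
    class = "feasnet_structure_spec"
  )
}

#' Specify the distribution of interaction strengths
#'
#' Nonzero off-diagonal interaction strengths are independent draws from a
#' normal distribution truncated below at 0 (competition coefficients stay
#' nonnegative; negative draws are resampled). The same spec applied to
#' paired structures gives matrices with matching strength moments.
#'
#' @param mean mean of the (untruncated) normal law for nonzero strengths.
#' @param sd standard deviation of the same; must be nonnegative.
#' @param diag_value self-regulation strength placed on the diagonal
#'   (strictly positive).
#' @param seed RNG seed.
#' @return an object of class `feasnet_strength_spec`.
#' @export
strength_spec <- function(mean = 0.15, sd = 0.05, diag_value = 1, seed = 1L) {
  if (sd < 0) stop_config("sd must be >= 0")
  if (diag_value <= 0) stop_config("diag_value must be > 0")
  structure(
    list(mean = mean, sd = sd, diag_value = diag_value, seed = as.integer(seed)),
    class = "feasnet_strength_spec"
  )
}

# Undirected off-diagonal link budget implied by a spec.
link_budget <- function(spec) {
  as.integer(round(spec$connectance * spec$n * (spec$n - 1) / 2))
}

# All unordered species pairs as a 2-column matrix (i < j).
species_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[, c("row", "col"), drop = FALSE]
}

new_topology <- function(adjacency, structure_label, spec, module_partition = NULL) {
  n <- nrow(adjacency)
  diag(adjacency) <- 1L
  dimnames(adjacency) <- NULL
  structure(
    list(
      n = n,
      adjacency = adjacency,
      structure_label = structure_label,
      module_partition = module_partition,
      n_links = sum(adjacency[upper.tri(adjacency)]),
      spec = spec
    ),
    class = "feasnet_topology"
  )
}

adjacency_from_pairs <- function(n, pairs) {
  adj <- matrix(0L, n, n)
  adj[pairs] <- 1L
  adj[pairs[, c(2, 1), drop = FALSE]] <- 1L
  diag(adj) <- 1L
  adj
}

#' Generate a binary interaction topology
#'
#' Dispatches on `spec$structure` to [generate_modular_topology()],
#' [generate_nested_topology()], or [generate_random_topology()]. All three
#' generators are deterministic given the spec's seed and produce symmetric
#' adjacency matrices with unit diagonal (self-regulation is always present)
#' and identical off-diagonal link counts for a common spec.
#'
#' @param spec a [structure_spec()].
#' @return an object of class `feasnet_topology` with fields `n`,
#'   `adjacency` (n x n 0/1, diagonal 1), `structure_label`,
#'   `module_partition` (modular only), and `n_links` (undirected
#'   off-diagonal link count).
#' @export
generate_topology <- function(spec) {
  switch(spec$structure,
    modular = generate_modular_topology(spec),
    nested = generate_nested_topology(spec),
    random = generate_random_topology(spec)
  )
}

#' @rdname generate_topology
#' @details
#' `generate_modular_topology` partitions the species into `n_modules` equal
#' blocks and splits the link budget between within-module and between-module
#' pair classes so that the within density exceeds the between density by the
#' requested ratio (exactly in expectation, up to integer rounding). Requests
#' whose rounded class allocations exceed the available pairs raise a
#' configuration error naming the feasible connectance range.
#' @export
generate_modular_topology <- function(spec) {
  if (spec$structure != "modular") stop_config("spec$structure must be 'modular'")
  n <- spec$n
  k <- spec$n_modules
  size <- n %/% k
  partition <- rep(seq_len(k), each = size)
  pairs <- species_pairs(n)
  within <- partition[pairs[, 1]] == partition[pairs[, 2]]
  W <- sum(within)
  B <- sum(!within)
  L <- link_budget(spec)
  rho <- spec$within_between_ratio
  # split L so that (links_w / W) / (links_b / B) = rho
  l_w <- as.integer(round(L * rho * W / (rho * W + B)))
  l_b <- L - l_w
  if (l_w > W || l_b > B || l_b < 0) {
    c_max <- min((W * (rho * W + B) / (rho * W)), W + B) / (W + B)
    stop_config(
      "connectance ", spec$connectance, " unreachable at ratio ", rho,
      "; feasible connectance range is (0, ", signif(c_max, 4), "]"
    )
  }
  adj <- with_seed(spec$seed, {
    wi <- which(within)
    bi <- which(!within)
    chosen <- c(
      if (l_w > 0) wi[sample.int(W, l_w)] else integer(),
      if (l_b > 0) bi[sample.int(B, l_b)] else integer()
    )
    adjacency_from_pairs(n, pairs[chosen, , drop = FALSE])
  })
  new_topology(adj, "modular", spec, module_partition = partition)
}

#' @rdname generate_topology
#' @details
#' `generate_nested_topology` fills species pairs in the maximally nested
#' order: pairs `(i, j)` sorted by increasing index sum `i + j` (ties broken
#' by the lower species index), i.e. the upper-left triangle of the
#' degree-sorted matrix, until the shared link budget is spent. The result is
#' a threshold-type graph: each species' neighbour set contains the neighbour
#' set of every lower-degree species, which is the defining containment
#' property of nestedness. The construction is deterministic (the seed only
#' tags the object).
#' @export
generate_nested_topology <- function(spec) {
  if (spec$structure != "nested") stop_config("spec$structure must be 'nested'")
  n <- spec$n
  pairs <- species_pairs(n)
  ord <- order(pairs[, 1] + pairs[, 2], pairs[, 1])
  L <- link_budget(spec)
  adj <- adjacency_from_pairs(n, pairs[ord[seq_len(L)], , drop = FALSE])
  new_topology(adj, "nested", spec)
}

#' @rdname generate_topology
#' @details
#' `generate_random_topology` places the same number of links uniformly at
#' random over the off-diagonal pairs: the standard null model of no
#' structure.
#' @export
generate_random_topology <- function(spec) {
  if (spec$structure != "random") stop_config("spec$structure must be 'random'")
  n <- spec$n
  pairs <- species_pairs(n)
  L <- link_budget(spec)
  adj <- with_seed(
    spec$seed,
    adjacency_from_pairs(n, pairs[sample.int(nrow(pairs), L), , drop = FALSE])
  )
  new_topology(adj, "random", spec)
}

#' Dress a binary topology with interaction strengths
#'
#' Every off-diagonal 1 of the topology receives an independent draw from a
#' normal law truncated below at zero (negative draws are resampled, so the
#' competition sign convention of the dynamics \eqn{\dot N = N(r - A N)} is
#' preserved); the draws for `(i, j)` and `(j, i)` are independent. Zeros
#' stay exactly zero and the diagonal is set to the self-regulation strength.
#' The realized mean and sd of nonzero off-diagonal entries are attached so
#' paired structures can be moment-checked.
#'
#' @param topology a `feasnet_topology`.
#' @param strengths a [strength_spec()].
#' @return an object of class `feasnet_matrix` with fields `n`, `A`,
#'   `structure_label`, and `realized` (list with `mean`, `sd`, `n_entries`
#'   of the nonzero off-diagonal entries).
#' @export
assign_interaction_strengths <- function(topology, strengths) {
  stopifnot(inherits(topology, "feasnet_topology"))
  if (!inherits(strengths, "feasnet_strength_spec")) {
    stop_config("strengths must be a strength_spec()")
  }
  n <- topology$n
  A <- matrix(0, n, n)
  off <- topology$adjacency == 1L
  diag(off) <- FALSE
  m <- sum(off)
  vals <- with_seed(strengths$seed, {
    v <- rnorm(m, strengths$mean, strengths$sd)
    while (any(neg <- v < 0)) {
      v[neg] <- rnorm(sum(neg), strengths$mean, strengths$sd)
    }
    v
  })
  A[off] <- vals
  diag(A) <- strengths$diag_value
  structure(
    list(
      n = n, A = A, structure_label = topology$structure_label,
      realized = list(
        mean = if (m > 0) mean(vals) else NA_real_,
        sd = if (m > 1) sd(vals) else NA_real_,
        n_entries = m
      ),
      strength_spec = strengths
    ),
    class = "feasnet_matrix"
  )
}

#' Nestedness of a binary matrix (NODF)
#'
#' NODF (nestedness metric based on overlap and decreasing fill) over both
#' rows and columns: each pair of rows (and of columns) contributes
#' `100 * |shared 1s| / min(fill)` when the two fills differ and 0 when they
#' are equal, averaged over all pairs. Ranges from 0 (e.g. all-equal degrees)
#' to 100 (perfect nesting with strictly decreasing fills).
#'
#' For a `feasnet_topology` the score is computed on the off-diagonal
#' adjacency (the mandatory self-loop diagonal is ignored).
#'
#' @param x a `feasnet_topology` or a binary matrix.
#' @return a score in `[0, 100]`.
#' @export
nestedness_nodf <- function(x) UseMethod("nestedness_nodf")

#' @export
nestedness_nodf.feasnet_topology <- function(x) {
  adj <- x$adjacency
  diag(adj) <- 0L
  nodf_score(adj)
}

#' @export
nestedness_nodf.matrix <- function(x) {
  if (!all(x %in% c(0, 1))) stop_config("matrix must be binary")
  nodf_score(x)
}

nodf_score <- function(m) {
  paired <- function(mm) {
    fills <- rowSums(mm)
    nr <- nrow(mm)
    if (nr < 2) return(numeric())
    ov <- mm %*% t(mm) # shared-1 counts between rows
    out <- numeric(0)
    for (i in seq_len(nr - 1)) {
      for (j in (i + 1):nr) {
        lo <- min(fills[i], fills[j])
        out <- c(out, if (fills[i] == fills[j] || lo == 0) 0 else 100 * ov[i, j] / lo)
      }
    }
    out
  }
  contribs <- c(paired(m), paired(t(m)))
  if (length(contribs) == 0) return(0)
  mean(contribs)
}

#' Within- versus between-module link density
#'
#' Ratio of realized within-module to between-module off-diagonal link
#' density for a topology carrying a module partition. A value of 1 means no
#' modular contrast; the default modular generator targets the configured
#' `within_between_ratio`. When no between-module link exists the ratio is
#' unbounded and `Inf` is returned, flagged with attribute
#' `no_between_links = TRUE`.
#'
#' @param topology a `feasnet_topology` with a `module_partition`; for
#'   non-modular topologies a partition can be supplied explicitly.
#' @param partition optional integer vector assigning each species a module.
#' @return a nonnegative ratio (possibly `Inf`).
#' @export
modularity_contrast <- function(topology, partition = NULL) {
  stopifnot(inherits(topology, "feasnet_topology"))
  partition <- partition %||% topology$module_partition
  if (is.null(partition)) {
    stop_config("topology carries no module_partition and none was supplied")
  }
  if (length(partition) != topology$n) stop_config("partition length must equal n")
  pairs <- species_pairs(topology$n)
  within <- partition[pairs[, 1]] == partition[pairs[, 2]]
  linked <- topology$adjacency[pairs] == 1L
  d_w <- sum(linked & within) / sum(within)
  d_b <- sum(linked & !within) / sum(!within)
  if (d_b == 0) {
    return(structure(Inf, no_between_links = TRUE))
  }
  d_w / d_b
}

#' @export
print.feasnet_topology <- function(x, ...) {
  cat(sprintf(
    "<feasnet_topology> %s, n = %d, links = %d (connectance %.3f)\n",
    x$structure_label, x$n, x$n_links, x$n_links / (x$n * (x$n - 1) / 2)
  ))
  invisible(x)
}

#' @export
print.feasnet_matrix <- function(x, ...) {
  cat(sprintf(
    "<feasnet_matrix> %s, n = %d, nonzero offdiag = %d (mean %.4f, sd %.4f)\n",
    x$structure_label, x$n, x$realized$n_entries,
    x$realized$mean, x$realized$sd
  ))
  invisible(x)
}
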