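test_that("modular generator honours block structure, budget, and determinism", {
  # extreme probabilities force pure block-diagonal structure
  sp <- structure_spec(
    n = 6, structure = "modular", n_modules = 2,
    connectance = 6 / 15, within_between_ratio = 1e9, seed = 1
  )
  topo <- generate_modular_topology(sp)
  blocks <- kronecker(diag(2), matrix(1, 3, 3))
  expect_equal(topo$adjacency, matrix(as.integer(blocks), 6, 6))

  # default 21-species community: diagonal all 1, connectance on target
  t21 <- generate_modular_topology(structure_spec(structure = "modular", seed = 3))
  expect_equal(dim(t21$adjacency), c(21, 21))
  expect_true(all(diag(t21$adjacency) == 1))
  expect_true(all(t21$adjacency %in% 0:1))
  expect_equal(t21$adjacency, t(t21$adjacency))
  realized <- t21$n_links / (21 * 20 / 2)
  expect_lt(abs(realized - 0.3), 0.01)
  expect_equal(sort(unique(t21$module_partition)), 1:3)
  expect_equal(as.vector(table(t21$module_partition)), rep(7L, 3))

  # pure function of the spec
  expect_identical(
    generate_modular_topology(structure_spec(structure = "modular", seed = 9))$adjacency,
    generate_modular_topology(structure_spec(structure = "modular", seed = 9))$adjacency
  )

  expect_error(
    structure_spec(n = 10, structure = "modular", n_modules = 3),
    class = "feasnet_config_error"
  )
  expect_error(
    generate_modular_topology(structure_spec(
      n = 6, structure = "modular", n_modules = 2,
      connectance = 0.9, within_between_ratio = 100
    )),
    "feasible connectance range"
  )
})

test_that("nested generator fills by degree with containment of sparser rows", {
  # 3 species, 2 links: generalist species 1 linked to both others
  sp <- structure_spec(n = 3, structure = "nested", connectance = 2 / 3)
  topo <- generate_nested_topology(sp)
  off <- topo$adjacency
  diag(off) <- 0L
  expect_equal(which(off[1, ] == 1), 2:3)
  expect_equal(which(off[2, ] == 1), 1L)
  expect_equal(which(off[3, ] == 1), 1L)

  # support containment: sorted by degree, each sparser row's partners are a
  # subset of every denser row's partners (up to the pair itself)
  t21 <- generate_nested_topology(structure_spec(structure = "nested"))
  adj <- t21$adjacency
  diag(adj) <- 0L
  deg <- rowSums(adj)
  ord <- order(deg, decreasing = TRUE)
  for (a in seq_len(20)) {
    for (b in (a + 1):21) {
      i <- ord[a]
      j <- ord[b] # deg[i] >= deg[j]
      partners_j <- setdiff(which(adj[j, ] == 1), i)
      expect_true(all(adj[i, partners_j] == 1))
    }
  }
  expect_equal(adj, t(adj))
})

test_that("the three structures share one off-diagonal link budget", {
  for (seed in c(1, 7, 23)) {
    topos <- lapply(default_specs(seed), generate_topology)
    links <- vapply(topos, function(t) t$n_links, numeric(1))
    expect_true(all(links == links[1]))
  }
  # complete graph at connectance 1
  full <- generate_random_topology(structure_spec(n = 5, structure = "random", connectance = 1))
  expect_true(all(full$adjacency == 1))
})

test_that("random generator varies with the seed", {
  diffs <- vapply(1:10, function(s) {
    a <- generate_random_topology(structure_spec(structure = "random", seed = s))
    b <- generate_random_topology(structure_spec(structure = "random", seed = s + 100))
    sum(a$adjacency != b$adjacency)
  }, numeric(1))
  expect_true(any(diffs > 0))
})

test_that("strength assignment preserves zeros and matches moments across structures", {
  # all-zero off-diagonal topology -> pure self-regulation matrix
  empty <- structure(
    list(
      n = 4, adjacency = diag(1L, 4), structure_label = "random",
      module_partition = NULL, n_links = 0,
      spec = structure_spec(n = 4, structure = "random", connectance = 0.01)
    ),
    class = "feasnet_topology"
  )
  A0 <- assign_interaction_strengths(empty, strength_spec(diag_value = 2))
  expect_equal(A0$A, diag(2, 4))

  # sd = 0 -> every realized interaction exactly the mean
  topo <- generate_topology(structure_spec(structure = "nested"))
  Am <- assign_interaction_strengths(topo, strength_spec(mean = 0.2, sd = 0))
  off <- topo$adjacency == 1L
  diag(off) <- FALSE
  expect_true(all(Am$A[off] == 0.2))
  absent <- !off
  diag(absent) <- FALSE
  expect_true(all(Am$A[absent] == 0))

  # zeros exactly preserved, all strengths nonnegative
  tm <- generate_topology(structure_spec(structure = "modular", seed = 5))
  M <- assign_interaction_strengths(tm, strength_spec(seed = 5))
  zero_mask <- tm$adjacency == 0L
  expect_true(all(M$A[zero_mask] == 0))
  expect_true(all(M$A >= 0))
  expect_true(all(diag(M$A) == 1))

  # paired structures under one strength seed: moments agree closely
  tn <- generate_topology(structure_spec(structure = "nested", seed = 5))
  N <- assign_interaction_strengths(tn, strength_spec(seed = 5))
  expect_gte(M$realized$n_entries, 100)
  expect_lt(abs(M$realized$mean - N$realized$mean), 1e-2)
  expect_lt(abs(M$realized$sd - N$realized$sd), 1e-2)

  expect_error(strength_spec(sd = -1), class = "feasnet_config_error")
})

test_that("NODF matches hand oracles and the vegan reference", {
  # perfect nesting with strictly decreasing fills scores 100
  perfect <- matrix(
    c(
      1, 1, 1, 1,
      1, 1, 1, 0,
      1, 1, 0, 0,
      1, 0, 0, 0
    ),
    4, 4,
    byrow = TRUE
  )
  expect_equal(nestedness_nodf(perfect), 100)

  # equal fills contribute nothing
  checker <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(nestedness_nodf(checker), 0)

  # cross-check against the independent vegan implementation
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(rbinom(48, 1, 0.45), 6, 8)
    ref <- unname(vegan::nestednodf(m, order = TRUE)$statistic["NODF"])
    expect_equal(nestedness_nodf(m), ref, tolerance = 1e-10)
  }
})

test_that("nested construction out-scores shuffled null models of itself", {
  topo <- generate_nested_topology(structure_spec(structure = "nested"))
  adj <- topo$adjacency
  diag(adj) <- 0L
  observed <- nestedness_nodf(adj)

  # a threshold graph is the unique realization of its degree sequence, so a
  # degree-preserving rewire must return it unchanged ...
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  set.seed(7)
  rewired <- igraph::rewire(g, igraph::keeping_degseq(niter = 500))
  expect_equal(
    igraph::as_adjacency_matrix(rewired, sparse = FALSE),
    unname(igraph::as_adjacency_matrix(g, sparse = FALSE))
  )

  # ... the null model of no structure is therefore the link-count-matched
  # uniform shuffle, which the nested construction beats on every draw
  n_links <- sum(adj) / 2
  shuffled <- vapply(1:100, function(i) {
    gs <- igraph::sample_gnm(21, n_links)
    nestedness_nodf(igraph::as_adjacency_matrix(gs, sparse = FALSE))
  }, numeric(1))
  expect_true(all(observed > shuffled))
})

test_that("structural metrics separate the generated structures", {
  # over 20 seeds: nested out-scores modular on NODF, modular on contrast
  partition <- rep(1:3, each = 7)
  for (seed in 1:20) {
    tm <- generate_topology(structure_spec(structure = "modular", seed = seed))
    tn <- generate_topology(structure_spec(structure = "nested", seed = seed))
    expect_gt(nestedness_nodf(tn), nestedness_nodf(tm))
    expect_gt(modularity_contrast(tm), modularity_contrast(tn, partition = partition))
    expect_gt(modularity_contrast(tm), 1)
  }
})

test_that("modularity contrast handles extremes and the null case", {
  # block-diagonal: no between links -> flagged Inf
  sp <- structure_spec(
    n = 6, structure = "modular", n_modules = 2,
    connectance = 6 / 15, within_between_ratio = 1e9
  )
  topo <- generate_modular_topology(sp)
  mc <- modularity_contrast(topo)
  expect_true(is.infinite(mc) && mc > 0)
  expect_true(attr(mc, "no_between_links"))

  # uniform random topology with an imposed partition: ratio near 1
  partition <- rep(1:3, each = 7)
  ratios <- vapply(1:50, function(s) {
    tr <- generate_topology(structure_spec(structure = "random", seed = s))
    modularity_contrast(tr, partition = partition)
  }, numeric(1))
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1), 3 * se + 0.05)

  tn <- generate_topology(structure_spec(structure = "nested"))
  expect_error(modularity_contrast(tn), class = "feasnet_config_error")
})
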