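#' Specify an external perturbation scenario
#'
#' A perturbation targets either the interaction matrix or the growth-rate
#' vector, and acts either randomly (on all nonzero elements of the target)
#' or directionally (on a single species: one column of `A`, or one component
#' of `r`). The magnitude is expressed as a multiple of the empirical
#' standard deviation of the unperturbed nonzero entries of the target, so
#' one magnitude is comparable across targets and structures.
#'
#' @param target `"interactions"` or `"growth_rates"`.
#' @param mode `"random"` or `"directional"`.
#' @param focal_rule directional mode only: `"most_connected"`,
#'   `"least_connected"`, or an explicit species index.
#' @param magnitude nonnegative perturbation scale `sigma_p` (noise sd =
#'   `magnitude *` sd of the target's unperturbed nonzero entries).
#' @param id optional scenario label (the canonical six are `"a"`-`"f"`).
#' @return an object of class `feasnet_perturbation_spec`.
#' @export
perturbation_spec <- function(target = c("interactions", "growth_rates"),
                              mode = c("random", "directional"),
                              focal_rule = NULL, magnitude = 0.5, id = NULL) {
  target <- match.arg(target)
  mode <- match.arg(mode)
  if (magnitude < 0) stop_config("magnitude must be >= 0")
  if (mode == "directional") {
    ok <- (is.character(focal_rule) &&
      focal_rule %in% c("most_connected", "least_connected")) ||
      (is.numeric(focal_rule) && focal_rule >= 1)
    if (is.null(focal_rule) || !ok) {
      stop_config("directional mode needs focal_rule: most_connected, least_connected, or an index")
    }
  } else if (!is.null(focal_rule)) {
    stop_config("focal_rule is only meaningful for directional mode")
  }
  structure(
    list(
      target = target, mode = mode, focal_rule = focal_rule,
      magnitude = magnitude, id = id %||% paste(target, mode, sep = "_")
    ),
    class = "feasnet_perturbation_spec"
  )
}

#' The six canonical perturbation scenarios
#'
#' Scenarios a-f cross target and mode: (a) random on interactions, (b)
#' random on growth rates, (c)/(d) directional on the interactions of the
#' most/least connected species, (e)/(f) directional on the growth rate of
#' the most/least connected species.
#'
#' @param magnitude perturbation scale applied to every scenario.
#' @return a named list of six [perturbation_spec()] objects.
#' @export
canonical_scenarios <- function(magnitude = 0.5) {
  list(
    a = perturbation_spec("interactions", "random", magnitude = magnitude, id = "a"),
    b = perturbation_spec("growth_rates", "random", magnitude = magnitude, id = "b"),
    c = perturbation_spec("interactions", "directional", "most_connected", magnitude, id = "c"),
    d = perturbation_spec("interactions", "directional", "least_connected", magnitude, id = "d"),
    e = perturbation_spec("growth_rates", "directional", "most_connected", magnitude, id = "e"),
    f = perturbation_spec("growth_rates", "directional", "least_connected", magnitude, id = "f")
  )
}

#' Pick the focal species for a directional perturbation
#'
#' Degree is the off-diagonal degree (number of interaction partners,
#' excluding self-regulation). Ties are broken by the lowest species index.
#'
#' @param topology a `feasnet_topology`.
#' @param rule `"most_connected"`, `"least_connected"`, or an explicit index.
#' @return a species index.
#' @export
select_focal_species <- function(topology, rule) {
  stopifnot(inherits(topology, "feasnet_topology"))
  if (is.numeric(rule)) {
    k <- as.integer(rule)
    if (k < 1 || k > topology$n) stop_config("focal index out of range")
    return(k)
  }
  adj <- topology$adjacency
  diag(adj) <- 0L
  deg <- rowSums(adj)
  switch(rule,
    most_connected = which.max(deg), # which.max/min take the first (lowest index) tie
    least_connected = which.min(deg),
    stop_config("unknown focal rule: ", rule)
  )
}

#' Apply a perturbation to a community's parameters
#'
#' Random interaction perturbations add independent zero-mean gaussian noise
#' (sd = `magnitude *` sd of the nonzero off-diagonal entries of `A`) to
#' every nonzero off-diagonal entry; structural zeros and the self-regulation
#' diagonal are never touched, so the topology is preserved. Directional
#' interaction perturbations restrict the noise to the focal species' column.
#' Growth-rate perturbations analogously use sd = `magnitude * sd(r)`, on all
#' components (random) or the focal component only (directional). Perturbed
#' interaction entries that would turn negative are clamped at 0 (competition
#' cannot silently flip to facilitation); clamping events are counted.
#'
#' @param A interaction matrix (`feasnet_matrix` or numeric matrix).
#' @param r growth-rate vector.
#' @param spec a [perturbation_spec()].
#' @param topology the `feasnet_topology` underlying `A` (defines the
#'   preserved zero pattern and degrees for focal selection).
#' @param seed RNG seed; the perturbation is deterministic given the seed.
#' @return a list with `A`, `r` (perturbed copies), `focal` (species index
#'   or `NA`), and `clamped` (count of entries clamped at 0).
#' @export
apply_perturbation <- function(A, r, spec, topology, seed = 1L) {
  stopifnot(inherits(spec, "feasnet_perturbation_spec"))
  A <- as_interaction_matrix(A)
  n <- nrow(A)
  if (length(r) != n || topology$n != n) stop_config("dimension mismatch")
  off <- topology$adjacency == 1L
  diag(off) <- FALSE
  focal <- NA_integer_
  clamped <- 0L
  if (spec$target == "interactions") {
    entries <- A[off]
    scale <- spec$magnitude * if (length(entries) > 1) sd(entries) else 0
    mask <- off
    if (spec$mode == "directional") {
      focal <- select_focal_species(topology, spec$focal_rule)
      keep <- matrix(FALSE, n, n)
      keep[, focal] <- TRUE
      mask <- off & keep
    }
    m <- sum(mask)
    if (m > 0 && scale > 0) {
      noise <- with_seed(seed, rnorm(m, 0, scale))
      newv <- A[mask] + noise
      clamped <- sum(newv < 0)
      A[mask] <- pmax(newv, 0)
    }
  } else {
    scale <- spec$magnitude * if (length(r) > 1) sd(r) else 0
    if (spec$mode == "directional") {
      focal <- select_focal_species(topology, spec$focal_rule)
      if (scale > 0) r[focal] <- r[focal] + with_seed(seed, rnorm(1, 0, scale))
    } else if (scale > 0) {
      r <- r + with_seed(seed, rnorm(n, 0, scale))
    }
  }
  list(A = A, r = r, focal = focal, clamped = clamped)
}

#' Configuration of the persistence experiment
#'
#' Bundles everything one run needs: the paired community specification,
#' strength and abundance distributions, the scenario list, replicate count,
#' and the master seed (fanned out to per-replicate, per-scenario sub-seeds
#' by [sub_seed()], so the random stream of one scenario never depends on
#' the presence of another).
#'
#' @param n species count (default 21).
#' @param n_modules modules of the modular structure (default 3).
#' @param connectance shared off-diagonal connectance (default 0.3).
#' @param within_between_ratio modular density contrast (default 8).
#' @param strength_mean,strength_sd,diag_value interaction-strength law
#'   (defaults 0.15, 0.05, 1).
#' @param meanlog,sdlog lognormal abundance parameters (defaults 0, 1).
#' @param magnitude perturbation scale `sigma_p` (default 0.5).
#' @param n_reps replicates per scenario (default 5000).
#' @param structures which paired structures to run (default modular and
#'   nested; `"random"` may be added).
#' @param scenarios list of [perturbation_spec()]s (default the canonical
#'   six of [canonical_scenarios()]).
#' @param seed master seed.
#' @param condition_bound condition-number bound for declaring a community
#'   draw degenerate.
#' @param max_retries resampling budget per replicate for degenerate draws.
#' @return an object of class `feasnet_experiment_config`.
#' @export
experiment_config <- function(n = 21L, n_modules = 3L, connectance = 0.3,
                              within_between_ratio = 8,
                              strength_mean = 0.15, strength_sd = 0.05,
                              diag_value = 1, meanlog = 0, sdlog = 1,
                              magnitude = 0.5, n_reps = 5000L,
                              structures = c("modular", "nested"),
                              scenarios = NULL, seed = 1L,
                              condition_bound = 1e12, max_retries = 100L) {
  if (n_reps < 1) stop_config("n_reps must be >= 1")
  structures <- match.arg(structures, c("modular", "nested", "random"), several.ok = TRUE)
  scenarios <- scenarios %||% canonical_scenarios(magnitude)
  if (!all(vapply(scenarios, inherits, TRUE, "feasnet_perturbation_spec"))) {
    stop_config("scenarios must be perturbation_spec objects")
  }
  # validate the structure geometry once, up front
  structure_spec(
    n = n, structure = "modular", n_modules = n_modules,
    connectance = connectance, within_between_ratio = within_between_ratio
  )
  structure(
    list(
      n = as.integer(n), n_modules = as.integer(n_modules),
      connectance = connectance, within_between_ratio = within_between_ratio,
      strength_mean = strength_mean, strength_sd = strength_sd,
      diag_value = diag_value, meanlog = meanlog, sdlog = sdlog,
      magnitude = magnitude, n_reps = as.integer(n_reps),
      structures = structures, scenarios = scenarios,
      seed = as.integer(seed), condition_bound = condition_bound,
      max_retries = as.integer(max_retries)
    ),
    class = "feasnet_experiment_config"
  )
}

#' Run the perturbation/persistence experiment
#'
#' Per replicate: draw the paired structures (identical link budget) and
#' independent moment-matched strengths, initialize every structure at the
#' same lognormal abundance vector via \eqn{r = A N^*} (guaranteed feasible),
#' then apply each scenario's perturbation independently — both structures
#' receive the same scenario sub-seed stream, so within a replicate any
#' persistence difference is attributable to structure alone. A replicate
#' persists under a scenario iff the perturbed community is still feasible
#' (the new equilibrium \eqn{A'^{-1} r'} is strictly positive). Community
#' draws with numerically singular matrices are resampled (up to
#' `max_retries`) and counted in `degenerate`.
#'
#' @param config an [experiment_config()].
#' @param progress print a progress line every 500 replicates.
#' @return a persistence table: a `data.frame` of class
#'   `feasnet_persistence` with one row per structure x scenario
#'   (`structure`, `scenario`, `persisted`, `n_reps`, `degenerate`, `seed`)
#'   and attributes `clamped` (clamp counts per row) and `config`.
#' @export
run_persistence_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "feasnet_experiment_config"))
  structures <- config$structures
  scen <- config$scenarios
  n_sc <- length(scen)
  counts <- matrix(0L, length(structures), n_sc,
    dimnames = list(structures, names(scen) %||% seq_len(n_sc))
  )
  clamps <- counts
  degenerate <- 0L
  perturbed_singular <- 0L
  master <- config$seed

  for (rep_i in seq_len(config$n_reps)) {
    comm <- NULL
    for (attempt in 0:config$max_retries) {
      slot0 <- attempt * 20L
      specs <- lapply(structures, function(s) {
        structure_spec(
          n = config$n, structure = s, n_modules = config$n_modules,
          connectance = config$connectance,
          within_between_ratio = config$within_between_ratio,
          seed = sub_seed(master, rep_i, slot0 + match(s, structures))
        )
      })
      topos <- lapply(specs, generate_topology)
      mats <- lapply(seq_along(topos), function(k) {
        assign_interaction_strengths(
          topos[[k]],
          strength_spec(
            mean = config$strength_mean, sd = config$strength_sd,
            diag_value = config$diag_value,
            seed = sub_seed(master, rep_i, slot0 + 5L + k)
          )
        )
      })
      rcs <- vapply(mats, function(m) rcond(m$A), numeric(1))
      if (all(is.finite(rcs) & rcs >= 1 / config$condition_bound)) {
        Nstar <- sample_lognormal_abundances(
          config$n, config$meanlog, config$sdlog,
          seed = sub_seed(master, rep_i, slot0 + 9L)
        )
        comm <- list(topos = topos, mats = mats, Nstar = Nstar)
        break
      }
      degenerate <- degenerate + 1L
    }
    if (is.null(comm)) {
      stop(
        "replicate ", rep_i, ": no nonsingular community draw within ",
        config$max_retries, " retries (", degenerate, " degenerate draws so far)"
      )
    }
    for (j in seq_len(n_sc)) {
      seed_j <- sub_seed(master, rep_i, 1000L + j)
      for (k in seq_along(structures)) {
        A <- comm$mats[[k]]$A
        r <- drop(A %*% comm$Nstar)
        pert <- apply_perturbation(A, r, scen[[j]], comm$topos[[k]], seed = seed_j)
        ok <- tryCatch(
          is_feasible(pert$A, pert$r, condition_bound = config$condition_bound),
          feasnet_degenerate_error = function(e) {
            perturbed_singular <<- perturbed_singular + 1L
            FALSE
          }
        )
        counts[k, j] <- counts[k, j] + ok
        clamps[k, j] <- clamps[k, j] + pert$clamped
      }
    }
    if (progress && rep_i %% 500L == 0L) {
      message("replicate ", rep_i, "/", config$n_reps)
    }
  }

  tab <- data.frame(
    structure = rep(structures, times = n_sc),
    scenario = rep(colnames(counts), each = length(structures)),
    persisted = as.vector(counts),
    n_reps = config$n_reps,
    degenerate = degenerate,
    seed = master,
    stringsAsFactors = FALSE
  )
  class(tab) <- c("feasnet_persistence", "data.frame")
  attr(tab, "clamped") <- clamps
  attr(tab, "perturbed_singular") <- perturbed_singular
  attr(tab, "config") <- config
  tab
}

#' Replicate the six-panel perturbation-tolerance comparison
#'
#' Runs [run_persistence_experiment()] on modular versus nested structures
#' under the six canonical scenarios and renders the grouped bar chart:
#' per-scenario persistence counts for each structure, the machine-readable
#' analogue of comparing bar heights panel by panel. The headline phenomenon
#' is rank reversal: which structure looks "more robust" flips between
#' scenarios, so no structure is more tolerant per se.
#'
#' @param config an [experiment_config()]; its scenarios are replaced by the
#'   canonical six if it carries a different list.
#' @param progress forwarded to [run_persistence_experiment()].
#' @return a list of class `feasnet_figure2` with `table` (the persistence
#'   table) and `plot` (a ggplot object).
#' @export
replicate_figure2 <- function(config = experiment_config(), progress = FALSE) {
  stopifnot(inherits(config, "feasnet_experiment_config"))
  canonical <- names(canonical_scenarios())
  if (!identical(names(config$scenarios), canonical)) {
    config$scenarios <- canonical_scenarios(config$magnitude)
  }
  if (!all(c("modular", "nested") %in% config$structures)) {
    stop_config("the six-panel comparison needs modular and nested structures")
  }
  tab <- run_persistence_experiment(config, progress = progress)
  scenario_labels <- c(
    a = "a: random, interactions",
    b = "b: random, growth rates",
    c = "c: directional, interactions, most connected",
    d = "d: directional, interactions, least connected",
    e = "e: directional, growth rates, most connected",
    f = "f: directional, growth rates, least connected"
  )
  pdat <- as.data.frame(tab)
  pdat$panel <- scenario_labels[pdat$scenario]
  plt <- ggplot2::ggplot(
    pdat,
    ggplot2::aes(x = .data$structure, y = .data$persisted, fill = .data$structure)
  ) +
    ggplot2::geom_col(width = 0.7, show.legend = FALSE) +
    ggplot2::facet_wrap(~panel, nrow = 2, labeller = ggplot2::label_wrap_gen(28)) +
    ggplot2::labs(
      x = NULL,
      y = sprintf("perturbations tolerated (out of %d)", tab$n_reps[1]),
      title = "Perturbation tolerance is perturbation-dependent"
    ) +
    ggplot2::theme_minimal()
  structure(list(table = tab, plot = plt), class = "feasnet_figure2")
}

#' Two-proportion comparison of persistence between structures
#'
#' For each scenario, tests whether modular and nested persistence
#' proportions differ ([stats::prop.test()] without continuity correction)
#' and reports which structure leads.
#'
#' @param table a `feasnet_persistence` table with two structures.
#' @return a `data.frame` with one row per scenario: counts, proportions,
#'   the leading structure, and the two-sided p-value.
#' @export
persistence_contrast <- function(table) {
  stopifnot(inherits(table, "feasnet_persistence"))
  structures <- unique(table$structure)
  if (length(structures) != 2) stop_config("contrast needs exactly two structures")
  out <- lapply(split(as.data.frame(table), table$scenario), function(d) {
    x <- setNames(d$persisted, d$structure)[structures]
    n <- d$n_reps[1]
    p <- if (all(x %in% c(0, n)) && x[1] == x[2]) {
      1 # both saturated: no evidence of difference
    } else {
      suppressWarnings(prop.test(x, c(n, n), correct = FALSE)$p.value)
    }
    data.frame(
      scenario = d$scenario[1],
      t(x / n),
      leader = if (x[1] == x[2]) NA_character_ else structures[which.max(x)],
      p_value = p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  names(out)[2:3] <- paste0("prop_", structures)
  out
}
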