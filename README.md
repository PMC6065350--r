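# feasnet

Does a "good" network structure make an ecological community robust?
`feasnet` is a simulation toolkit for showing that the answer is
perturbation-dependent: which interaction structure (modular vs nested)
better tolerates an external perturbation flips with the type, direction,
and magnitude of that perturbation, so structure alone predicts little about
persistence. The package is aimed at community ecologists and theoreticians
studying structural stability of species interaction networks.

## The model

Communities follow generalized Lotka-Volterra competition dynamics

    dN/dt = N ∘ (r − A N)

with abundances `N`, intrinsic growth rates `r` (the environment-dependent
parameters), and interaction matrix `A` (nonnegative competition
coefficients, unit self-regulation on the diagonal). The community persists
— no species goes extinct at equilibrium — iff the equilibrium
`N* = A⁻¹ r` is strictly positive, i.e. iff `r` lies in the **feasibility
domain**

    D_F(A) = { r = N₁* v₁ + … + Nₙ* vₙ : Nᵢ* > 0 },

the open cone spanned by the columns `vᵢ` of `A`.

On top of this the package implements:

* **Synthetic communities** — 21-species modular, nested, and random binary
  topologies with an identical off-diagonal link budget, dressed with
  moment-matched truncated-normal interaction strengths; NODF and a
  within/between density ratio verify the structures are distinct.
* **The six-scenario perturbation experiment** — communities initialized at
  a shared lognormal abundance vector via `r = A N*`, then hit with random
  or directional perturbations on `A` or `r` (directional = one species:
  the most or least connected). Persistence is counted over 5,000
  replicates per scenario for each structure.
* **The environment overlap statistic** — for an environment distribution
  Ξ over growth-rate space,

      Γ(D_F(A) ∩ Ξ) = vol(D_F(A) ∩ Ξ) / vol(Ξ)

  estimated by Monte Carlo as the Ξ-probability mass inside the cone. A
  community with a *smaller* feasibility domain can have a *larger* Γ when
  the local environment sits inside its cone — persistence is a property of
  the structure–environment pair.

## Worked example

```r
library(feasnet)

tm <- generate_topology(structure_spec(structure = "modular", seed = 1))
tn <- generate_topology(structure_spec(structure = "nested",  seed = 1))
tm; tn
#> <feasnet_topology> modular, n = 21, links = 63 (connectance 0.300)
#> <feasnet_topology> nested, n = 21, links = 63 (connectance 0.300)
cat("NODF modular:", round(nestedness_nodf(tm), 1),
    " nested:",      round(nestedness_nodf(tn), 1), "\n")
#> NODF modular: 25.6  nested: 50.5

cfg <- experiment_config(n_reps = 1000, seed = 2026)
tab <- run_persistence_experiment(cfg)
persistence_contrast(tab)
#>   scenario prop_modular prop_nested  leader      p_value
#> 1        a        0.689       0.701  nested 5.600240e-01
#> 2        b        0.027       0.017 modular 1.274042e-01
#> 3        c        0.982       0.970 modular 7.956473e-02
#> 4        d        0.988       1.000  nested 5.117283e-04
#> 5        e        0.733       0.611 modular 6.223792e-09
#> 6        f        0.808       0.804 modular 8.210523e-01
```

The rank reversal is the point: under directional interaction perturbations
of the least connected species (scenario d) the nested structure persists
significantly more often, while under directional growth-rate perturbations
of the most connected species (scenario e) the modular structure does —
each scenario alone would support the opposite conclusion about which
structure "matters". `replicate_figure2(cfg)` returns the same table plus a
grouped bar chart of the six panels.

The overlap statistic:

```r
A  <- matrix(c(1, 0.4, 0.1, 1), 2, 2)
xi <- environment_gaussian(mean = c(1, 1), cov = 0.05 * diag(2))
estimate_gamma(A, xi, n_samples = 1e5, seed = 1)
#> <feasnet_gamma> gamma = 0.9936 (se 0.0003, 100000 draws, seed 1)
```

Almost all of this environment's mass lies inside the community's
feasibility cone: Γ ≈ 0.99 is the probability the local conditions support
full coexistence.

A thin command-line front end over the same functions lives at
`inst/cli/feasnet.R`, with subcommands `generate`, `experiment`, `gamma`,
and `fixtures` (the two-species worked cone geometry).

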