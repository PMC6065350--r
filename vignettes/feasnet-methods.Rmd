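---
title: "Methods: feasibility domains, perturbation tolerance, and environment overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feasibility domains, perturbation tolerance, and environment overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feasnet)
```

## The model and the persistence criterion

`feasnet` works with generalized Lotka-Volterra competition dynamics
$\dot N = N(r - AN)$: $N$ are species abundances, $r$ the intrinsic growth
rates, and $A$ the interaction matrix with nonnegative competition
coefficients and strictly positive self-regulation on the diagonal. The
interior equilibrium is $N^* = A^{-1} r$, and the persistence criterion used
throughout is **feasibility**: every component of $N^*$ strictly positive.
Geometrically, the feasible growth-rate vectors form the open cone of
strictly positive combinations of the columns of $A$ — the feasibility
domain $D_F(A)$. We deliberately do not require local dynamical stability
of the equilibrium: the headline persistence counts record extinction
avoidance at the new equilibrium only, which keeps the criterion a pure
function of $(A, r)$ and makes the two membership routes below directly
comparable. Users who want to audit the effect of adding a stability check
can do so on the returned matrices; time integration of the ODEs is out of
scope by design.

Two independent routes decide membership of $r$ in $D_F(A)$:

* `is_feasible()` solves $A N^* = r$ and checks strict positivity
  (threshold `eps_pos = 0`, exposed for studying borderline cases; matrices
  with reciprocal condition below $10^{-12}$ are rejected as degenerate
  rather than trusted);
* `cone_membership_oracle()` asks a phase-one linear program (via
  `boot::simplex`) whether $r$ is a positive combination of the columns,
  with a positivity margin of $10^{-9}$, never inverting the matrix.

The two agree exactly away from the cone boundary; the test suite
cross-checks them on $10^4$ random small instances after excluding
equilibria with components within $10^{-6}$ of zero, where the two
tolerances could legitimately disagree.

## Synthetic communities

The generator emulates 21-species competition communities whose interaction
*arrangement* — not amount — differs:

* **Modular**: 3 modules of 7 species; the link budget is split between
  within- and between-module pair classes so within-module density exceeds
  between-module density by a factor of 8 (integer-rounded; infeasible
  combinations raise an error naming the feasible connectance range).
* **Nested**: species pairs $(i, j)$ filled in order of increasing $i + j$
  (ties to the lower index) until the budget is spent — the upper-left
  triangle of the degree-sorted matrix. This is a threshold graph, the
  maximally nested arrangement: each species' partner set contains that of
  every lower-degree species.
* **Random**: the same number of links placed uniformly — the standard
  null model of no structure.

All three share the off-diagonal link budget
$L = \mathrm{round}(C \cdot n(n-1)/2)$ at connectance $C = 0.3$. Matching
$L$ across structures is a deliberate strengthening of the moment-matching
idea: with both the number of links and the strength distribution held
fixed, any persistence difference is attributable to arrangement alone.
Adjacency is symmetric (interaction presence is mutual) with a mandatory
unit diagonal; strengths for $(i,j)$ and $(j,i)$ are independent draws.

Strengths are normal with mean 0.15 and sd 0.05, truncated below at 0 by
resampling: under the competition sign convention a negative coefficient
would silently flip the interaction to facilitation. With these defaults
the truncation triggers for roughly 0.1% of draws, so realized moments sit
essentially on the nominal ones; the realized mean/sd are attached to every
matrix for pairwise moment checks. The diagonal is 1, making $A$ diagonally
dominant in expectation and invertibility a near-certainty (degenerate
draws are counted and resampled in the experiment). Two metrics verify the
structures are what they claim: NODF (0–100, computed over rows and columns
of the off-diagonal adjacency, equal fills contributing zero) and the
within/between density ratio (flagged `Inf` when no between-module link
exists). Under the defaults, nested NODF ≈ 50 vs modular ≈ 23–26, and the
modular contrast ratio ≈ 8.

One consequence of the maximally nested fill at connectance 0.3 is that the
least connected species is *isolated* (degree 0, self-regulation only).
This is the extreme of "specialists interact almost exclusively with
generalists" and it matters for directional perturbations targeting that
species: perturbing its (nonexistent) interactions is a no-op, and
perturbing its growth rate decouples from the rest of the community. The
tests assert this behaviour explicitly rather than hiding it.

## Initialization and the perturbation experiment

Each replicate draws fresh paired structures and strengths, then
initializes every structure at the *same* lognormal abundance vector
($\mathrm{meanlog} = 0$, $\mathrm{sdlog} = 1$; the literature motivates
lognormal abundance distributions but pins no parameters, so these are the
package's fixed choice) and back-solves $r = A N^*$. Initial feasibility is
thus guaranteed by construction, and sharing the identical abundance vector
across structures is the strongest controlled comparison consistent with
"same abundance distribution"; a same-distribution-different-draws variant
is available by initializing each structure separately.

Six perturbation scenarios cross target × mode:

| id | target | mode | focal species |
|----|--------|------|---------------|
| a | interactions | random (all nonzero off-diagonal) | — |
| b | growth rates | random (all components) | — |
| c | interactions | directional (one column) | most connected |
| d | interactions | directional (one column) | least connected |
| e | growth rates | directional (one component) | most connected |
| f | growth rates | directional (one component) | least connected |

Noise is additive, zero-mean gaussian with sd equal to
$\sigma_p \times$ (empirical sd of the unperturbed nonzero entries of the
target), default $\sigma_p = 0.5$ — large enough that random scenarios leave
the cone often, small enough that directional ones usually do not, which is
the regime where rank reversals are visible; magnitude sweeps are ordinary
configuration. "All the elements" is implemented as all *nonzero*
off-diagonal elements: perturbing structural zeros would rewire the network
and conflate structural change with parameter change (perturbing the zeros
is a different experiment, not a different magnitude). Perturbed
interaction entries that would turn negative are clamped at 0 and the
clamping events counted in the run metadata. Directional interaction
perturbations act on the focal species' *column* — the cone-basis vector
associated with that species.

Randomness is fanned out from one master seed by a counter-based scheme
(`sub_seed(master, replicate, slot)`), with the same scenario sub-seed
reused for both structures in a replicate: differences within a replicate
are attributable to structure alone, adding scenarios never shifts other
scenarios' streams, and whole runs are bit-identical given the master seed.
Replicates whose drawn matrix fails the condition bound are resampled (with
a retry budget) and counted.

The defaults — 21 species, 5,000 replicates per scenario — are the study
conditions the experiment is designed around; a full default run is about
60,000 21×21 linear solves and completes in well under a minute. The
acceptance checks use 1,000 replicates for the rank-reversal significance
test and 5,000 for the bookkeeping echo.

## The environment overlap statistic Γ

$\Gamma(D_F(A) \cap \Xi) = \mathrm{vol}(D_F(A) \cap \Xi)/\mathrm{vol}(\Xi)$
is estimated as the probability mass of the environment distribution $\Xi$
falling inside the cone — the Monte Carlo fraction of $\Xi$-draws whose
equilibrium is strictly positive. Reading the volume ratio as probability
mass generalizes it to non-uniform $\Xi$ and reduces to the literal ratio
for a uniform box. Three $\Xi$ families are provided — gaussian, uniform
box, point mass — as the package's own choice of parametric stand-ins for
location-specific environmental estimates; mapping real climate variables
to growth rates is explicitly out of scope. Estimation is Monte Carlo only
(no quadrature): the intended dimension is 21, where deterministic
integration over cones is impractical. Binomial standard errors
$\sqrt{\gamma(1-\gamma)/n}$ accompany every estimate; draws whose
equilibrium has any component within $10^{-12}$ of zero count as outside,
honouring strict positivity. `relative_cone_size()` applies the same
machinery to directions uniform on the unit sphere, giving a normalized
solid-angle measure of the cone itself (identity matrix → $2^{-n}$).

Numerical anchor points used by the tests: identity cone with an
origin-centred isotropic gaussian gives $\Gamma \to 2^{-n}$; a point mass
at an interior point gives $\Gamma = 1$ exactly; and an explicit 2-D pair —
wide cone below the diagonal, narrow cone hugging it, environment centred
in the narrow one — demonstrates that the smaller domain can overlap the
environment more ($\Gamma_{\text{narrow}} > \Gamma_{\text{wide}}$ at more
than 3 combined standard errors). Membership and both estimators are
invariant under positive rescaling of the cone's columns, and feasibility
along any ray from an interior point switches off at most once (cone
convexity); both properties are asserted over batteries of random
instances.

## What the synthetic data does and does not show

The generator reproduces the *design* of the simulation study: matched link
budgets, matched strength moments, shared abundance draws, and clearly
separated structures. It does not emulate empirical networks — no
heavy-tailed degree distributions, no asymmetric or sign-mixed
interactions, no correlation between strength and degree, no bipartite
mutualistic geometry. Passing tests therefore certify the internal logic of
the pipeline (the rank-reversal phenomenon among these controlled
structures, the geometry of the feasibility cone), not any claim about a
particular empirical community. Panel-by-panel bar orderings depend on
unpublished simulation constants (connectance, $\sigma_p$) and are not
treated as fixed truths anywhere in the package; the robust, tested claim
is the existence of reversals in both directions.

## Known limitations

* Persistence is feasibility of the post-perturbation equilibrium; a
  feasible-but-dynamically-unstable equilibrium counts as persistent.
* Monte Carlo Γ at dimension 21 has high variance when the cone is thin;
  no importance sampling is provided.
* The nested generator's isolated specialists (above) make directional
  scenarios targeting the least connected nested species degenerate by
  construction; interpret scenario d/f contrasts accordingly.
* The LP membership oracle is restricted to small dimensions (default
  $n \le 6$) — it exists to validate the inverse-based test, not to replace
  it.
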