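---
title: "Assembly maps for microbiome communities: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly maps for microbiome communities: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glvmap)
```

## The model

Community dynamics follow the generalized Lotka-Volterra (gLV) equations.
For species $i$ in a pool of size $S$,

$$\frac{dX_i}{dt} \;=\; X_i\Big((r_i + f) - s_i X_i +
\sum_{j \ne i} a_{ij} X_j\Big),$$

where $r_i$ is the intrinsic growth rate (1/time), $s_i > 0$ the
self-regulation (per abundance per time), $a_{ij}$ the per-abundance
effect of species $j$ on $i$ (zero diagonal), and $f \ge 0$ an optional
host-feeding supplement added uniformly to every intrinsic rate. On top of
this we impose a total-population cap $K^T$: once $\sum_i X_i \ge K^T$,
each species grows at its per-capita rate *minus the community mean
per-capita rate*, so the total derivative is exactly zero and species
compete zero-sum for space. We use the abundance-weighted mean because it
is the only choice that makes the total derivative vanish identically at
the cap (the unweighted mean is available via
`sim_settings(cap_weighted = FALSE)`). The cap both prevents the unbounded
growth that strong mutualism otherwise produces and introduces a
higher-order competition that can stabilize strongly cooperative
communities. Default $K^T = 10{,}000$.

A subcommunity is **viable** when it has an equilibrium with every member
present and the community returns to it after perturbation:

* *Interior case* (equilibrium total below the cap): solve
  $(\mathrm{diag}(s) - A)\,x^\ast = r + f$ on the subset; feasibility
  requires every $x^\ast_i$ to exceed the extinction threshold, and
  stability is linear asymptotic stability of the gLV Jacobian
  ($J_{ij} = x_i a_{ij}$, $J_{ii} = -s_i x_i$), with "stable" meaning the
  largest real part is below $-10^{-9}$. Marginal spectra (within
  $10^{-9}$ of zero) are reported non-viable.
* *Cap case*: when the interior total reaches the cap, when the linear
  system is singular, or when the interior exists but is unstable or
  infeasible while mutualism outruns self-regulation, we simulate the
  capped dynamics from near-cap abundances and accept the settled state if
  every member persists and the state returns after perturbing each
  species by $\pm 5\%$ *individually*. (A joint rescaling of all species
  is annulled by the cap projection and would test nothing.)

The last clause is a deliberate deviation from a purely
interior-first rule: obligate mutualists with $a_{ij}a_{ji} > s_is_j$ have
an unstable (or even infeasible) interior equilibrium yet hold a perfectly
good stable state pressed against the cap, and both the capped model's
intent and the package's own archetypes (`obligate_pair`,
`mutualist_triangle`) require those to count as viable.

The empty community is viable by convention; single species are viable
exactly when $r_i + f > 0$.

## Assembly maps

For a viable climax community we enumerate all $2^S$ subsets ($S \le 16$
by default), keep the viable ones as nodes, and resolve every invasion of
each node by each absent species: residents start at equilibrium, the
invader at low density, and the capped dynamics run to convergence. The
surviving set labels a directed edge as *augment* (everyone persists),
*replace* (diversity maintained, membership changed), or *crash* (multiple
members lost); an invasion that changes nothing is a *fail* and produces
no edge. `map_metrics()` reports the node and edge counts, whether a
directed path exists from the empty set to the climax (`can_assemble`),
the number of distinct simple paths, `predictability = 1/n_paths`, and the
count of secondary colonizers (climax members whose singleton is not
viable). Because the field does not fix a unique predictability formula,
the metric is isolated in one function and the path-entropy alternative
(`log n_paths`) and the secondary-colonizer fraction are reported
alongside.

## Occupancy as a Markov chain

Treating gain and loss of species as rare events, the map becomes a
continuous-time Markov chain over viable states: each absent species
arrives at rate $\gamma$ (moving the chain along the corresponding
invasion edge; failed invasions contribute nothing), and each present
species is lost at rate $\delta$, after which the remainder relaxes under
the capped dynamics — possibly cascading further extinctions — to a
viable state. Simultaneous events are excluded. The stationary
distribution of the generator, restricted to the states reachable from the
uncolonized state, gives the long-run probability of observing each
subcommunity; for non-interacting species it reduces to the product form
$P(\text{present}) = \gamma/(\gamma + \delta)$ per species, which the test
suite verifies to $10^{-10}$ at the two plotted regimes
$\gamma/\delta \in \{2, 20\}$.

Arrival pressure is per absent species (total pressure scales with pool
size); the alternative (total rate $\gamma$ split uniformly) differs by a
constant and is available via `arrival_mode = "uniform"`.

## Random communities

`sample_climax_community()` rejection-samples on full-community
viability. Each unordered pair interacts with probability $C$; an
interacting pair is one-sided (amensal/commensal) or bidirectional with
probability `amensal_prob` (default 0.5, giving all five interaction forms
+/-, -/-, +/+, +/0, -/0); magnitudes are half-normal with scale $\sigma$;
matrices start purely inhibitory and `apply_facilitation()` flips a
proportion $P_m$ of the nonzero terms positive, keeping magnitudes fixed
so $P_m$ sweeps are magnitude-controlled. Intrinsic rates default to
$r \sim U(-0.5, 1)$ — some species must lack independent growth for
secondary colonizers to exist at all — and $s \equiv 1$. Both are
configurable and should be regarded as stand-ins: the generating
distributions behind the published heatmaps are not printed in the text we
implement from.

## Host interventions

`augment_with_consortia()` adds edges for joint arrivals of up to $m$
species; it never removes base structure, so `can_assemble` can only flip
from false to true. `build_multilayer_feeding_map()` builds unfed
($f = 0$) and fed ($f > 0$) assembly maps; subcommunities viable in both
layers are interlayer nodes where the host can switch feeding on or off
without losing a member. `multilayer_can_assemble()` searches for a path
from the uncolonized state to the *unfed* climax using intra-layer edges
plus free switches at interlayer nodes — the "feed early, then wean"
strategy appears as a witness path with at least one switch. Default
$f = 0.1$ and $\sigma = 0.05$ for sweeps; the magnitude of $f$ is not
printed in the source material and is always reported in outputs.

## Numerical choices

* Integration is an adaptive Cash-Karp Runge-Kutta pair (C++), relative
  tolerance $10^{-8}$. The cap regime is decided once per step — the
  weighted zero-sum rates conserve the total exactly, so stage
  derivatives stay consistent — and cap-regime steps are renormalized to
  $\sum x = K^T$ exactly; extinction clamps are the only exit from the
  cap. Trajectory states are projected to be nonnegative.
* Extinction threshold $10^{-6} K^T$; abundances below it are clamped to
  zero during integration and equilibria below it are infeasible (keeping
  the analytic and simulated routes consistent).
* Convergence: the largest per-capita rate among extant species stays
  below $10^{-8}$ for 10 time units. Cap-pinned states are stiff for an
  explicit method — tolerance-scale wobble keeps raw rates above any
  absolute threshold — so a second detector declares convergence when
  consecutive 10-time-unit window averages agree to $10^{-8}$ relative
  *and* rates are small relative to the Jacobian scale
  $\max_i (s_i + \sum_j |a_{ij}|) \cdot \max x$. Limit cycles fail both
  detectors and run to the horizon (default $10^4$), ending non-converged
  and non-viable, which matches the point-equilibrium notion of viability
  used throughout.
* Invader density defaults to $10^{-3} K^T$, additionally capped at 1% of
  the smallest resident abundance (and floored at twice the extinction
  threshold). The uncapped default would exceed typical resident
  abundances in the sampled worlds ($s = 1$, abundances $O(1)$), turning
  "introduction at low density" into a large-propagule experiment.
* Invasion outcomes that settle on a state outside the viable-node list
  are re-integrated with a 10-fold horizon and then raise an error —
  never silently coerced.
* Ties in `most_likely_size` resolve to the larger size with a flag.

## The synthetic infant cohort

`simulate_cohort()` emulates the kind of data the clinical module
analyses: ~13 preterm infants sampled daily for ~6 weeks, genus-level
absolute abundances, staggered colonization, antibiotic exposure. Eight
genera carry a known sparse interaction network
(`preterm_cohort_params()`): early facultative colonizers
(*Staphylococcus*, *Enterococcus*, *Escherichia*, *Enterobacter*), two
genera with strong one-way dependencies (*Klebsiella* benefits from
*Staphylococcus*; *Veillonella* from *Klebsiella* — the cross-feeding
chain that makes colonization order predictable), and later anaerobes with
weak links. Species are first exposed at a drawn arrival day and
re-exposed weekly until established (propagule pressure); dynamics between
events are capped gLV; observations get multiplicative lognormal noise
(sdlog 0.1) — abundances are positive and heavy-tailed, so multiplicative
noise is the natural model — then censoring at the detection limit.
Two antibiotic courses are modelled: an empiric course at birth and a
late-onset-sepsis evaluation around days 15-28. The second course is not
decoration: mid-study perturbations of *established* partners are what
makes interaction coefficients identifiable from observational time
series at all, exactly as antibiotic perturbations drive identifiability
in real preterm cohorts.

What the generator does *not* emulate: sequencing depth and
compositionality, strain-level variation, within-day dynamics,
immigration from unmeasured taxa. A green parameter-recovery test
therefore establishes that the regression machinery works on data obeying
its own model class with realistic noise and sampling — not that it would
recover interactions from arbitrary real sequencing data.

## The colonization pipeline

Colonization time is the first sampling time at which a genus reaches the
detection threshold (inclusive). The interaction fit is gradient
matching on the discrete gLV equation: the response is
$\Delta \ln X_i(t_l) / \Delta t_l$ across consecutive windows, the design
holds windowed geometric-mean abundances of every genus (the self column
absorbs $-s_i$) and antibiotic covariates. The published analysis used a
Bayesian spike-and-slab sampler; we fit the same equation with lasso-based
stability selection (penalty cross-validated once, selection frequency
over 30 half-subsamples, OLS refit on the stable support) — the result the
downstream statistics need is the fitted network, not the sampler. On
noise-free data generated from the regression equation itself the `"ols"`
path recovers coefficients to $10^{-6}$.

Known limitation, measured honestly: with 10% observation noise the two
strong benefit links are attenuated roughly 5-10-fold
(errors-in-variables, compounded by antibiotic courses synchronizing the
partner and self columns). Sign recovery of strong interactions is 100%
across probe seeds, but the rank agreement between true and estimated
coefficients over all ordered pairs stays near Spearman 0.45, below the
0.7 one might hope for; the corresponding check is deliberately left
failing in the acceptance test file rather than weakened. Sparser fits
(lasso 1se, best-subset BIC, post-refit t-pruning) raise rank agreement
but start dropping true strong links, which is the property the analysis
actually depends on.

Pair predictability is the proportion of subjects in which the focal
genus first colonizes *with or after* the partner; subjects enter the
denominator when the focal is detected, and a partner never detected
counts as focal-first. Both conventions are recorded in output
provenance; ties qualify ("with"). The one-sample permutation test
reflects scores about 0.5 (`score -> 1 - score`), the standard sign-flip
construction, with $p = (1 + \#\{\bar s^\ast \ge \bar s\}) / (1 + B)$.
Interaction magnitudes are normalized by the network's maximum absolute
off-diagonal entry — the source text says "normalized magnitude" without
a formula — and 0.1 separates weak from strong. The mixed model
$\text{score}_{fp} = \beta_0 + \beta_1 \alpha_{fp} + u_f + u_p + e$ uses a
single genus-level random effect entering through both roles
(multimembership), fitted by a Gibbs sampler (diffuse normal on fixed
effects, inverse-gamma(0.001, 0.001) on both variances, 10,000 iterations,
20% burn-in) reporting the posterior mean and 95% credible interval of
$\beta_1$ with an initial-positive-sequence effective-sample-size
diagnostic.

## Archetypes

`fixture_community()` returns six hand-built worlds with asserted map
structure, including `humpty_dumpty`: a five-species community whose
climax is viable but unreachable by single arrivals. The fractured core is
realized as cyclic competition (stable trio, pairwise exclusion) rather
than a cooperative core: a cap-pinned +/+ core monopolizes the zero-sum
regime and excludes independent climax members, so a pure-mutualist
five-species humpty-dumpty with a viable climax does not exist in this
model family at these scales — itself a small but real finding about the
capped dynamics.

## What the scaled tests do and do not establish

The acceptance sweeps run at $S = 6$ with 30-50 replicate communities.
At that scale the edge-thinning effects of interaction strength and
facilitation, the rise of secondary colonizers, the drop in occupied
diversity (at $\gamma/\delta = 2$; at 20 the chain sits on the climax for
almost every community), and the monotone benefits of consortium arrivals
and feeding all reproduce. The decrease of *assembly probability* with interaction strength is
present but shallow at $S = 6$ (fractions 1.00 vs 0.93 across the two
$\sigma$ arms): with only ~2.5 links per species, dependencies remain
satisfiable by single partners, so most of the signal lives in the edge
counts rather than in outright assembly failure; the test asserts the
direction and carries the significance claim on the edge-count rank test.
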