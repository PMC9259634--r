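---
title: "Eco-evolutionary dynamics on spatial graphs: models and methods"
author: "graphevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-evolutionary dynamics on spatial graphs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(graphevo)
```

## The model

`graphevo` studies how landscape structure shapes phenotypic differentiation.
A landscape is an undirected connected graph \(G\): vertices are habitat
patches, edges the corridors along which individuals can move. Each vertex
\(v_i\) hosts a local population of haploid, asexually reproducing
individuals carrying a vector of \(d\) *neutral* traits \(u\) and, under
heterogeneous selection, one *adaptive* trait \(s\).

Individuals on \(v_i\):

* **give birth** at rate \(b^{(i)}(s) = b\,(1 - p\,(s - \Theta_i)^2)\)
  (clamped at zero), where \(\Theta_i\) is the local environmental optimum
  and \(p\) the selection strength. Without selection the rate is the
  constant \(b\) and traits are purely neutral.
* **die** at per-capita rate \(N^{(i)}/K\): traits do not enter mortality,
  only local crowding relative to the carrying capacity \(K\).
* **mutate at birth**: each trait component of the offspring is displaced
  independently, with probability \(\mu\), by a Normal\((0, \sigma_\mu^2)\)
  step (continuum-of-alleles model).
* **migrate at birth**: with probability \(m\) the offspring takes one step
  of a simple random walk, i.e. settles on a uniformly chosen neighbour of
  the natal vertex. Parents never move.

Simulation is exact (Gillespie): waiting times are exponential in the total
event rate and events are drawn proportionally to their rates. The default
parameters used throughout the package — \(b = 1\), \(K = 150\), \(p = 1\),
\(\mu = 0.1\), \(\sigma_\mu = 0.05\), \(\theta = 0.5\) — are the study
conditions for all shipped experiments; two-type landscapes use symmetric
optima \(\Theta_i \in \{-\theta, +\theta\}\).

Differentiation is measured by
\(Q_{ST} = \sigma_B^2 / (\sigma_B^2 + \sigma_W^2)\), the share of trait
variance lying between local populations. Conventions (fixed and
documented, since they change third decimals): population variances
(divide by \(n\)); the grand mean is the unweighted mean of vertex means;
vertices that are momentarily empty are excluded from both components;
\(Q_{ST,u}\) is averaged over the \(d\) neutral trait dimensions, which
shrinks its sampling variance roughly like \(1/d\); trajectories are
summarised by averaging the per-record \(Q_{ST}\) over the closing 10% of
the time span (the published analyses say only "the last time steps"; the
window is our choice).

## Landscape metrics

Three metrics summarise a (labeled) landscape:

* **average path length** \(\langle l\rangle\): mean shortest-path distance
  over vertex pairs; high values mean poorly connected, easily isolated
  populations.
* **degree homogeneity**
  \(h_d = \langle\sqrt k\rangle^2 / \langle k\rangle \le 1\), with equality
  exactly on regular graphs. Under a degree-based mean-field closure the
  equilibrium mean population size at full migration is \(bK\,h_d\):
  irregular graphs push highly connected vertices above their carrying
  capacity, depress the total population, and thereby strengthen drift.
* **habitat assortativity** \(r_\Theta\): Pearson correlation of the
  habitat values at the two ends of each edge (both orientations of every
  edge are counted, making the measure symmetric). For two-type labelings
  it coincides with \(2(P(\mathbf{I},\mathbf{I}) -
  P(\mathbf{I},\mathbf{II}))\) exactly when the two types hold equal shares
  of the directed edge endpoints (equal degree sums). That condition — not
  merely equal vertex counts — is the graph analogue of "habitats
  homogeneously distributed"; the package provides both forms and the test
  suite verifies their agreement exhaustively on edge-balanced labelings of
  all graphs with up to 6 vertices.

Graph ensembles are enumerated exhaustively up to isomorphism by vertex
augmentation with canonical labeling (BLISS via igraph): all isomorphism
classes on \(m\) vertices are extended by one vertex in every possible way
and deduplicated; connectivity is imposed only at the target size. The
counts 1, 1, 2, 6, 21, 112, 853 for \(M = 1..7\) are asserted in the test
suite; an independent naive-scan oracle cross-checks \(M = 4\).

## Deterministic approximations

**Population sizes (no selection).** Competition makes population-size
fluctuations small at large \(K\), and the counts follow
\[
\partial_t N^{(i)} = N^{(i)}\Big[b(1-m) - \tfrac{N^{(i)}}{K}\Big]
 + m\,b \sum_{j\neq i} \tfrac{a_{ij}}{d_j}\,N^{(j)} ,
\]
logistic growth plus random-walk-routed migrant gains. `solve_equilibrium()`
integrates this to steady state (lsoda, residual below `1e-10` times
\(bK\) in sup norm). The degree-class mean-field reduction closes these
dynamics over vertices of equal degree; at \(m = 1\) it yields the closed
form \(\bar N = bK\,h_d\), and for \(m < 1\) `mean_field_equilibrium()`
solves the stationary class system by damped fixed-point iteration (each
class equation is a quadratic solved exactly given the current mean). The
closed form is exact on regular graphs and approximate elsewhere — the
star graph, maximally degree-correlated, is its worst case in the small
ensembles (≈11% relative deviation), while the ensemble-wide mean
deviation at \(M \le 6\) is ≈1%.

**Trait distributions (heterogeneous selection).** Selection stabilises
the adaptive-trait dynamics, giving per-vertex densities \(n^{(i)}(s)\)
that obey a reaction–(mutation-)diffusion equation: local logistic growth
with trait-dependent birth rate, migrant inflow \(m \sum_j b^{(j)}(s)
\frac{a_{ij}}{d_j} n^{(j)}(s)\), and a mutation operator
\(\frac{1}{2}\mu\sigma_\mu^2\,\Delta_s[b^{(i)}(s)\,n^{(i)}(s)]\).
For balanced two-type landscapes a habitat mean-field closure reduces this
to two coupled densities \(\bar n^{\mathbf I}, \bar n^{\mathbf{II}}\) in
which migrants mix across habitats with weights \((1 \mp r_\Theta)/2\) —
the only place the landscape enters is through \(r_\Theta\).

Numerical choices for the solver:

* The birth-rate coefficient inside the mutation operator (and everywhere
  else in the PDE) is the clamped profile \(\max(0, b(1 - p(s-\Theta)^2))\).
  This is the deterministic image of the individual-level rates, and it is
  also required for well-posedness: with the raw parabola the mutation term
  has a negative coefficient far from the optima and acts as
  anti-diffusion, which blows up at any resolution.
* Uniform grid of 501 points on \([-L, L]\) with
  \(L = 4\theta + 10\sigma_\mu\) (2.5 for the default parameters); a guard
  errors the solve if the boundary density exceeds \(10^{-8}\) of the peak.
  Convergence was checked by halving the spacing.
* The mutation operator is discretised in flux form with no-flux
  boundaries, so it conserves mass exactly under the Riemann quadrature
  used for population sizes (asserted in the tests).
* Method of lines with adaptive `lsoda`, integrating in chunks until the
  sup-norm residual falls below \(10^{-9}\) (the densities are \(O(10^3)\),
  so this is conservative); the integrator works on the smooth field and
  positivity is only enforced on the reported state (undershoots observed
  are \(O(10^{-70})\)).
* Initial condition: Gaussian bump at \(s = 0\) with s.d. \(\sigma_\mu\)
  and mass \(K\) per habitat, mirroring the IBM initialisation.

## Adaptive dynamics and the critical migration rate

In the trait-substitution regime (rare mutations, no mutation term) the
fate of a rare type with trait \(s\) in the two-habitat reduction is
governed by a \(2\times2\) projection matrix whose leading eigenvalue is
the invasion fitness. By symmetry the singular strategy is the habitat
midpoint \(s^* = 0\) with per-habitat equilibrium \(bK(1 - p\theta^2)\).
Whether \(s^*\) is a fitness maximum (one generalist) or a branching point
(two specialists) switches at the critical migration rate
\[
m^\star = \frac{1}{1 - r_\Theta}\,\frac{4 p \theta^2}{1 + 3 p \theta^2}.
\]
The package never trusts this formula blindly: `stability_threshold()`
locates the sign change of the fitness curvature \(\partial^2\lambda/
\partial y^2\) at \(s^*\) numerically (central differences with step
\(10^{-5}\) on the closed-form \(2\times2\) eigenvalue, curvature scanned
on a log-spaced migration grid and the first crossing polished by root
bracketing), and the test suite demands agreement with the closed form to
better than \(10^{-6}\) relative error across a parameter grid. Two domain
notes: the derivation presumes a demographically viable generalist,
\(p\theta^2 < 1\) — beyond that the "equilibrium" \(bK(1-p\theta^2)\) is
negative, the resident no longer has zero fitness, and the curvature can
cross zero a second time at large \(m\); the validation grid is therefore
restricted to \(p\theta^2 < 1\). And at \(r_\Theta = 1\) habitats decouple
and the threshold is infinite (adaptation is never lost). Curvatures
within \(10^{-8}\) of zero are reported as "marginal" rather than forced
into a boolean.

Above \(m^\star\) the PDE steady state is unimodal at \(s = 0\) in both
habitats and \(Q_{ST,s}\) essentially vanishes; slightly above the
threshold a residual \(Q_{ST,s}\) of order \(10^{-3}\) remains because at
finite mutation variance each habitat's density is marginally skewed
towards its own optimum — this decays to zero as \(m \to 1\) and is a
property of the model, not solver error. The demographic equilibrium
approaches \(bK(1 - p\theta^2)\) minus a small mutation load (≈1% at the
default parameters).

## Ensemble experiments

`run_neutral_ensemble()` and `run_selection_ensemble()` orchestrate the
meta-analysis: enumerate the \(M = 7\) ensemble, stratify, simulate,
summarise, regress. Stratification choices:

* Graph sampling strata are **edge-count classes** — within a fixed-M
  ensemble, edge count is the natural integer invariant to balance over
  (the alternative reading, "equal number of vertices", is vacuous within
  fixed M); at most a fixed number of graphs is drawn per class without
  replacement.
* Habitat labelings are drawn uniformly over the two-type assignments
  (constant assignments rejected), then stratified by **quartiles of
  \(r_\Theta\)** so that the assortativity axis is covered evenly rather
  than concentrated at typical values.

Effects of \(\langle l\rangle\), \(h_d\) and \(r_\Theta\) on \(Q_{ST}\) are
estimated by ordinary least squares on z-scored predictors and response,
fitted independently per migration regime ("low" \(m \le 0.05\), "high"
\(m \ge 0.1\)); 95% confidence intervals and \(R^2\) are reported, and
collinearity is surfaced through the design condition number.

**Problem sizes.** The shipped default campaign is desk-sized: 60 graphs
stratified from the 853, 3 labelings per graph, 3 replicates,
\(t_{\text{end}} = 300\), 30 neutral traits. The full published-scale
campaign (all 853 graphs, 5 replicates, \(t = 1000\), \(d = 300\)) is a
straightforward config override but a cluster-sized computation. At the
desk scale the *sign structure* of the standardized effects is stable and
is what the acceptance suite asserts; the \(R^2\) values are somewhat
attenuated relative to the full campaign because shorter horizons leave a
larger share of transient variance in the response, and single-trait
\(Q_{ST,u}\) averaged over 30 rather than 300 traits is noisier.

Every stochastic component draws its seed deterministically from the
campaign master seed, so campaigns are byte-reproducible; seeds stay below
\(2^{31}\).

## What the generator does and does not emulate

The synthetic landscapes are exhaustive or stratified samples of *all*
small connected graphs with two-type habitat labelings — they cover
topology space evenly, which real landscapes do not. Not emulated: degree
distributions of real habitat networks, continuous habitat gradients
(two-type only in the shipped experiments; the machinery accepts arbitrary
\(\Theta\) vectors), landscape dynamics, diploid or sexual genetics, and
trait-dependent competition kernels. Passing tests therefore demonstrate
internal consistency of simulator, theory and meta-analysis under the
stated model — not transferability to any particular empirical landscape.

## Known limitations

* The mean-field population-size law degrades on strongly
  degree-correlated graphs (stars); the package reports both the exact ODE
  equilibrium and the mean-field prediction so the gap is visible.
* The two-habitat reduction assumes balanced, homogeneously distributed
  habitats; on unbalanced labelings it is only a guide, and the IBM is the
  reference.
* Near \(m^\star\) the PDE relaxation time diverges (critical slowing
  down); steady-state solves close to the threshold need patience or a
  looser tolerance.
* Neutral differentiation is intrinsically stochastic; its analysis rests
  on simulation, and desk-scale replicate counts leave visible Monte Carlo
  error in single rows of the ensemble tables.
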