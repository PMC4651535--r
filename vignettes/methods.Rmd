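---
title: "Methods: pairwise interspecific spatial association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise interspecific spatial association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interspat)
```

## The question and the data

In species-rich forests, whether pairs of tree species attract or repel
each other in space — and whether those relationships shift across
developmental stages — bears directly on the roles of facilitation,
competition and habitat filtering in community assembly. `interspat`
analyses stem-mapped censuses: one row per free-standing woody plant,
with plot, coordinates in metres inside a rectangular window, species
and DBH in centimetres. The window origin sits at the plot's lower-left
corner; duplicate coordinates are allowed and every row is treated as
one individual (field protocols differ on collapsing multi-stemmed
plants; this package does not collapse).

Only abundant species enter the pairwise analysis: a species is kept if
it has *strictly more than* `min_n = 60` individuals per plot in at
least `min_plots` plots (default: all but one plot, so a three-plot
census tolerates one deficient plot; a single-plot census requires the
one plot). For a kept species, deficient plots are dropped from its
replicate set rather than dropping the species. Sixty stems per hectare
is the customary floor below which second-order statistics of a single
species become too noisy to interpret.

## Estimators

### Intertype L-type function

For species $r, s$ with $n_r, n_s$ stems in a window of area $A$ and
intensities $\lambda = n/A$:

$$\hat L_{rs}(d) = \frac{1}{(\lambda_r+\lambda_s)(n_r+n_s)\pi}
 \left(\frac{\sum_{i}^{n_r}\sum_{j}^{n_s}\omega_{ij}(d)}{n_r}
 + \frac{\sum_{i}^{n_s}\sum_{j}^{n_r}\omega_{ij}(d)}{n_s}\right)$$

$\omega_{ij}(d)$ is the indicator of $d_{ij} \le d$ (closed ball: pairs
at exactly $d$ count), centred on the focal stem of each directional
sum. Two edge-correction modes are supported and recorded in every
output:

* `ripley_isotropic` (default): each indicator is divided by the
  fraction of the circle of radius $d_{ij}$, centred on the focal stem,
  lying inside the window — the classical isotropic correction for a
  rectangular window, computed in closed form (edge arcs minus
  double-counted corner wedges) and validated in the tests against
  numerical arc integration. The closed form is exact for
  $d \le \min(W,H)/2$, which the distance grid enforces.
* `none`: the formula exactly as printed, a pure indicator. Useful for
  reproducibility checks; the curve is then monotone non-decreasing.

Under independence of two completely random patterns,
$E[\hat L_{rs}(d)] \approx d^2/(n_r+n_s)$; the uncorrected estimator's
exact expectation involves the disc–window overlap integral
$G(d) = \pi d^2 L^2 - \tfrac{8}{3} d^3 L + d^4/2$ for an $L \times L$
window. Both limits are verified by Monte Carlo in the test suite
(1,000 realisations at $n = 100$). The estimator is exactly symmetric
in its two arguments: internally the pair is put into a canonical
order, fixing the floating-point summation order.

### Intertype mark-correlation function

DBH serves as a surrogate of developmental stage. Marks are
standardised per species and per plot, $\tilde m = (m - \bar m)/s$,
with $s$ the *sample* standard deviation ($n-1$ denominator — the
conventional estimate of dispersion; the choice only rescales the
curve and cancels entirely in the rank-based inference). Then

$$\hat K^{mm}_{rs}(d) = \frac{\sum\sum \omega_{ij}(d)\,\tilde m_i
\tilde m_j + \sum\sum \omega_{ji}(d)\,\tilde m_i \tilde m_j}
{\sum\sum \omega_{ij}(d) + \sum\sum \omega_{ji}(d)}$$

a weighted average of cross-species standardised mark products over all
intertype pairs within $d$. Per-species standardisation makes the
function invariant under positive affine transforms of either species'
marks (so species with very different diameter ranges are comparable),
and a lag with no intertype pair yet is *undefined* (`NA`), never zero
— zero is a meaningful value (no mark association). Interpretation of
deviations from the null band: positive = similar-stage attraction
(cohorts), negative = opposite-stage attraction (nurseries); the sign
never refers to attraction or repulsion of the stems themselves.

## Null models, envelopes and p-values

* **Toroidal shift** (for $\hat L_{rs}$): one species' entire pattern
  is translated by a uniform random vector with wrap-around, preserving
  each marginal pattern's internal structure exactly while randomising
  the cross-pattern alignment. The species with fewer individuals is
  the one shifted (the statistic is symmetric, so the choice is free;
  it is recorded in the envelope object).
* **Random marking** (for $\hat K^{mm}_{rs}$): locations fixed, marks
  permuted uniformly *within* each species. Cross-species permutation
  would alter each species' mark distribution and contradict the
  per-species standardisation.

Envelopes use `n_sim = 399` simulations by default and pointwise
rank-based bounds: the $k$-th smallest and largest simulated values
with $k = \lfloor \alpha (n_\text{sim}+1)/2 \rfloor$ (at least 1). At
$\alpha = 0.05$ this gives the 10th-lowest/highest of 399, and min/max
of 19 — the standard conventions. Under exchangeability the pointwise
two-sided level is exactly $2k/(n_\text{sim}+1)$ (4% at
$n_\text{sim} = 99$, 5% at 399), verified by a 500-pair calibration
experiment in the tests. Pointwise envelopes imply multiple testing
across pairs; no correction is applied beyond reporting the expected
number of false positives, $\alpha \times$ (number of pairs), in the
run manifest — the protocol's own bookkeeping.

The quasi p-value at a lag is the Monte Carlo rank
$p = (1 + \#\{\text{sims at least as extreme, on the empirical
deviation's side}\})/(n_\text{sim}+1)$, so $p \in
[1/(n_\text{sim}+1), 1]$. The side is "high" when the empirical value
is at or above the simulated median. The original protocol cites an
external method for its quasi p-values whose details are not given
in-text; this rank form is the package's documented choice, applied
pointwise at the representative distance with acceptance at
$p \le 0.01$ (whether the original threshold was pointwise or
interval-wise is not stated; pointwise is implemented and a global
rank-envelope test deliberately is not).

## Replication across plots

Each plot's empirical curve is mapped onto its own null band by
$\hat F_{st}(d) = a(d) + b(d)\hat F(d)$ with
$b(d) = 2/(N_{\sup}(d) - N_{\inf}(d))$ and
$a(d) = 1 - b(d) N_{\sup}(d)$: the band becomes exactly $[-1, 1]$ at
every lag (an algebraic identity, asserted to $10^{-12}$ in the
tests). Lags with a degenerate band carry `NA`. The overall curve is
the per-lag arithmetic mean over the replicates with a defined value —
with three replicates all sitting on their upper bounds the pooled
value is 1, which is the only reading of "divide by the number of
replicates" consistent with that boundary behaviour; the divisor
generalises from 3 to however many plots remain usable after
filtering.

Casual single-plot excursions are suppressed by the **strict
coincidence rule** (default): a lag counts as significant only when the
pooled curve exits $[-1,1]$ *and* every usable replicate exits on the
same side at that lag. The relaxed pooled-only rule is available
(`rule = "pooled"`); whether the original "only coincident results"
required all plots or a majority is not stated, so both variants are
exposed and the stricter is the default.

For the pooled analysis the quasi p-value at the representative
distance ranks the pooled standardised empirical value against pooled
standardised null curves: simulation $k$ of each replicate is mapped
through that replicate's own band transform and the results averaged
over the replicates where the lag is defined. With one replicate this
is identical to the plain envelope rank p (the band transform is
strictly increasing). An earlier design — the maximum of per-replicate
pointwise p-values — was rejected: it demands each plot individually
reach the null's top 1%, which a genuine signal spread across three
plots routinely fails.

## From curves to associations

Significant intervals are maximal runs of consecutive lags outside the
band, signed. Each pair contributes at most one record per statistic:
the **representative distance** $d^\*$ maximises the exceedance
$|\hat F_{st}(d)| - 1$ over in-interval lags. Because the
standardisation already divides by the local band width, this weighs
the raw deviation by the width of the acceptance region at each
distance — the implemented reading of "greatest deviation weighed by
the acceptance area"; alternatives (e.g. integrating exceedance over
the interval) exist, so the rule is recorded in output metadata. Exact
ties break toward the smallest distance.

The association matrix carries signed representative distances, L-type
records in the lower-left triangle and mark-correlation records in the
upper-right, with per-species counts; guild cross-tabs count
associations by trait similarity (life form, shade tolerance,
dispersal) and sign, excluding a pair only from the cross-tab of a
trait it lacks; habitat concordance marks a positive association
concordant when both species share an associated habitat and a
negative one when one species is associated with a habitat the other
avoids, with species absent from the habitat table treated as having
no relation. The habitat table is an external input — this package
never computes habitat classifications.

## Distance grid and defaults

The default grid is 100 lags of 0.5 m up to 50 m — half the shorter
side of a 1-ha plot, the usual upper bound for second-order analysis,
with a 0.5 m step consistent with association distances reported at
that resolution. Published representative distances such as 7.1 m or
9.6 m are not multiples of 0.5 m, so the original grid may have been
finer or adaptive; the grid here is fully configurable
(`distance_grid()`). Analysis defaults: `n_sim = 399`,
`alpha = 0.05`, `p_threshold = 0.01`, Ripley isotropic correction,
strict coincidence rule, top-level seed with per-(pair, plot,
statistic) sub-seeds derived by a rolling string hash so any single
pair re-runs bit-identically, in any order, under any scheduling.

## The synthetic-stand generator

Every pipeline stage is testable without real data via
`synthetic_config()` / `generate_stand()` / `generate_replicates()`:

* **Locations.** CSR, or Thomas clusters: a Poisson number of uniform
  parents, exactly `n` offspring assigned to random parents with
  isotropic Gaussian displacement (σ in metres), wrapped toroidally to
  preserve intensity. Thomas clustering (not Matérn) matches the
  dispersal-limited clustering reported for tropical tree species.
* **Planted attraction** (`linked_clusters`): the two species share one
  parent set; each marginal pattern remains an ordinary Thomas pattern
  (verified distributionally in the tests), only the cross-structure
  changes.
* **Planted repulsion** (`repulsion_hardcore`): the second species is
  rejection-sampled outside the hardcore distance of the first; an
  unreachable target count raises an error.
* **Marks.** Lognormal DBH, default meanlog 2.3 and sdlog 0.6 on the
  log-cm scale — median ≈ 10 cm with a realistic right skew for a stand
  including saplings. Spatial mark structure via a smooth Gaussian-bump
  random field shared by a pair: `cohort` gives both species marks
  rising with the field (planted positive mark correlation), `nursery`
  flips the partner's sign (planted negative).

The generator emulates clustered multi-species stands with controllable
cross-structure; it does **not** emulate habitat heterogeneity,
terrain, size-dependent thinning, or the long-tailed species-abundance
distributions of real censuses. Passing recovery tests therefore shows
the pipeline detects the planted effect classes at realistic densities
— not that real-forest effect sizes are detectable, which depends on
the census at hand.

`simulate_bnc_like_census()` is a clearly labelled **synthetic
surrogate** for a replicated three-plot, 1-ha cloud-forest census whose
real counterpart is distributed as supplementary data with its paper
and is not shipped here. It reproduces that census's reported abundance
structure — 50 species, 20 of them with more than 60 stems per plot
(one deficient in a single plot), the abundant set carrying ≈93% of
stems — with clustered locations and independent lognormal marks, and
carries no planted interactions. It exists to exercise the filter and
the pipeline at realistic scale; its association output is noise by
construction.

## Numerical choices and degenerate inputs

* Pairs at exactly $d_{ij} = d$ are included (closed ball), as printed.
* Constant marks (zero SD) raise an error naming the species; patterns
  need at least two marked stems for the mark correlation.
* Empty patterns raise an error naming the species for both
  estimators; an empty census filters to an empty species list without
  error.
* Undefined mark-correlation lags propagate as `NA` through envelopes
  (excluded from bound computation per lag), standardisation, pooling
  (per-lag replicate counts recorded) and p-values (a replicate with no
  intertype pair at $d^\*$ contributes nothing to the pooled null).
* Degenerate null bands ($N_{\sup} = N_{\inf}$) make the standardised
  value undefined at that lag rather than infinite.
* The toroidal wrap reduces coordinates with an explicit
  floor-based reduction, mapping results equal to the window dimension
  back to 0 so shifted stems stay inside the half-open window.

## Problem sizes used in the shipped checks

The test suite and acceptance script scale the Monte Carlo work to
what the checks need rather than to the full field protocol: envelope
calibration uses 500 independent pairs of $n = 100$ CSR patterns at 99
simulations; recovery experiments use 100 seeds per planted-effect
class at 99 simulations; pooled-rule recovery uses 50 three-plot
stands; oracle-equivalence sweeps use 1,000 (tests) and 200 (script)
small patterns. The full protocol (399 simulations, all pairs of 20
species in three plots) is what `run_bnc()` executes on a real census
and takes tens of minutes on one CPU.

## Known limitations

* Inference is pointwise; no simultaneous (global rank) envelope test,
  and no multiple-testing correction across pairs beyond reporting the
  expected false-positive count.
* Homogeneous intensities are assumed within a plot; no inhomogeneous
  variants, no pair-correlation (ring) estimators, no 3-D coordinates,
  no GIS formats, no slope correction of coordinates.
* Replicates are pooled unweighted; plots of unequal size or abundance
  receive equal weight.
* The L-type statistic is implemented exactly as printed in its source,
  without the square-root variance stabilisation of the classical
  bivariate $L$; whether the original analysis applied a root is not
  stated, and the standardised-band inference is invariant to any
  monotone rescaling at a fixed lag, so the choice does not affect
  detected associations.
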