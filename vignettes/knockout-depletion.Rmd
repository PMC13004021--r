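---
title: "Knockout depletion: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knockout depletion: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kodepletion)
```

# The experiment this package models

In a knockout-depletion experiment, a naturally competent bacterium is
transformed with a cassette that replaces an essential gene with a
resistance marker. Transformed cells stop synthesizing the target protein
but keep proliferating on the pre-existing pool, which is *diluted* by
growth. Growth continues until the protein concentration falls below the
threshold required for function, then arrests. The fold dilution a cell
tolerates before arrest measures how far the endogenous expression level
sits above the functional threshold — the protein's **overabundance**

$$o \equiv C_0 / C_A,$$

the ratio of the endogenous concentration to the concentration at growth
arrest. The experiment is run at two scales:

* **single cells**: time-lapse imaging of microcolonies founded by single
  transformants, yielding cell areas and lineage relationships;
* **genome-wide**: a pooled transposon-insertion knockout library
  propagated on selective medium, with fractions sequenced on a fixed
  schedule, yielding per-gene relative-abundance trajectories.

The package implements both analysis branches, the synthetic-data
generators that emulate their inputs, and the robustness–load trade-off
(RLTO) model that predicts how optimal overabundance should depend on
transcription level.

# Single-cell branch

## Dilution law and growth rate

With synthesis stopped, total protein amount is conserved, so the
concentration common to the progeny of one progenitor obeys

$$C(t)/C_0 = V_0/V(t),$$

where $V(t)$ is total progeny volume (area is used as the volume proxy
throughout; the experiment's fitness proxy is the **areal growth rate**
$k(t) = \tfrac{d}{dt}\ln A(t)$). `relative_concentration()` implements
the dilution law; `areal_growth_rate()` estimates $k$ as a centered
least-squares slope of $\ln A$ over a sliding window (default 5 frames,
one-sided at track ends). Least squares rather than finite differences
buys noise robustness at equal cost.

## Fitness landscape and overabundance

`fitness_landscape()` pairs each cell–frame growth rate with the
lineage-level $C(t)/C_0$ at that frame and fits a threshold model — a
plateau rate above an arrest concentration, a floor below — by least
squares over the grid of candidate changepoints (an $O(n\log n)$
cumulative-sum scan). The overabundance estimate is $\hat o = C_0/\hat
C_A$. If the fitted floor is not below half the plateau, no arrest is
detectable within the movie and the function returns the dilution bound
$V(t_{\max})/V_0$ flagged `censored`.

Two arrest-time conventions are provided by `arrest_time()`: the
*elongation* metric (smoothed total-area log-slope falls below
`frac * k0`, default `frac = 0.5`, and stays below; persistence of at
least 3 frames) and the *septation* metric (same criterion on the
cell-count log-slope). The count series is a staircase, so it is first
interpolated through division-event midpoints; without this the smoothed
slope lags by half a window and the two metrics disagree on perfectly
synchronous colonies. "Stays below" means the final below-threshold run
of the series, which ignores transient dips without delaying detection.
$k_0$ is estimated per colony from the pre-arrest plateau (90th
percentile of the smoothed slope) unless supplied, keeping the imaging
branch independent of the sequencing configuration.

The reference frame for $C_0$ and $V_0$ is the first observed frame; the
offset between transformation and the start of imaging is not
recoverable from tracks, and the estimate of $o$ is correspondingly a
lower bound in that respect for real data.

# Library-scale branch

## Trajectory models

For each gene the expected relative abundance $r(t)$ (library fraction
normalized to its $t=0$ value, relative to wild-type growth) follows one
of three nested models:

* **no effect**: $r(t) = 1$ (0 parameters);
* **sufficiency**: $r(t) = e^{-\delta t}$, $\delta \ge 0$ (1 parameter) —
  growth slows immediately, so expression is at threshold and $o = 1$;
* **overabundance**: $r(t) = 1$ for $t < T$, $e^{-\delta (t-T)}$ after
  (2 parameters) — wild-type growth until the arrest time $T$, linked to
  overabundance by $o = e^{k_0 T}$.

Each model is fitted by maximum binomial likelihood of the counts given
the per-timepoint totals. Two nuisance quantities are handled inside the
likelihood:

* a **per-gene abundance scale**, profiled out in closed form in all
  three models. Anchoring the scale to the observed $t=0$ count instead
  would convert $t=0$ sampling noise into a persistent offset and inflate
  the false-positive rate of the no-effect test by orders of magnitude.
* a **library renormalization** $g(t)$ shared by all genes: as mutants
  arrest, the fractions of unaffected genes rise, so observed relative
  abundance is $r_i(t)\,g(t)$ with $g$ the inverse of the
  initial-abundance-weighted mean of all $r_j$. With an annotated
  nonessential reference set, $g$ is the median reference trajectory
  (`normalization = "reference"`). Otherwise it is estimated
  self-consistently: initialized from the upper envelope of the raw
  trajectories (genes that have not yet arrested trace $g$ exactly), then
  iterated, with genes showing no significant decline serving as an
  internal reference (their median trajectory is an unbiased estimate of
  $g$; averaging fitted declines instead is biased because the decline
  models absorb only downward noise excursions). Because fractions are
  scale-free, $g$ is unidentifiable at times after *every* gene in the
  library has arrested; genome-wide insertion libraries avoid this
  regime because most insertions land in nonessential genes, and the
  package's synthetic libraries include such a background for the same
  reason.

$T$ is profiled on a continuous grid (coarse step 0.5 h, refined to
0.01 h; every coarse candidate within 3 log-likelihood units of the best
is refined, since the profile can be flat in $T$ across the final
sampling interval), and $\delta$ by one-dimensional optimization
($\delta \le 12$/h by default; faster declines are unresolvable at 2-h
spacing).

## Model selection and error control

`select_model()` applies two successive null-hypothesis tests: no effect
vs the best alternative, then sufficiency vs overabundance, both at
$\alpha = 10^{-4}$ by default (configurable; an optional
Benjamini–Hochberg mode adjusts each test's p-values across the genome).
Reference distributions are $\chi^2_2$ for the first test — conservative,
because both extra parameters are boundary-constrained under the null —
and the boundary mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ for the
second. `bootstrap_null()` provides parametric-bootstrap calibration
when exactness matters. Measured on a 2000-gene null library at depth
$10^6$, the realized false-positive rate at $\alpha = 10^{-4}$ is 0.

Arrest times within half a timepoint spacing of the last sample are
reported `censored` (lower bounds); genes arresting beyond the window are
indistinguishable from no-effect genes and are never reported as point
estimates. Both arrest conventions are reported: the model changepoint
$\hat T$ (which feeds $o = e^{k_0 \hat T}$) and the time at which the
renormalized relative abundance first crosses 50% (`halving_time`, a
display convention; it exceeds $\hat T$ by $\sim \ln 2/\delta$).

$k_0$ **cannot be inferred from relative abundances** — they are
invariant to a common growth factor — and must be supplied from an
external measurement such as the library's doubling time. This is why
`call_mutants()` has no default for `k0`.

# RLTO model

Expression noise is gamma with shape equal to the message number
$\mu_m$ (mRNA per cell cycle) and free scale — the canonical
bursty-expression limit, with $\mathrm{CV}^2 = 1/\mu_m$. With mean
expression $o$-fold above the arrest threshold, the per-cycle arrest
probability is the scale-free quantity

$$P_a(\mu_m, o) = P\!\left[\Gamma(\mu_m, \mu_m) < \mu_m/o\right],$$

and fitness is modeled as the product of a metabolic-load term and the
per-cycle survival term,

$$F(o) = (1 - \epsilon o)\,\bigl(1 - P_a(\mu_m, o)\bigr),$$

with $\epsilon$ the relative cost per unit of threshold-level expression
(default $10^{-4}$, a low-expression essential gene's share of the
proteome). This functional form is this package's reconstruction of the
trade-off — the qualitative ingredients are a small linear load and a
catastrophic arrest penalty — and all conclusions drawn from it here are
inequality- or property-based, not exact values. The optimum
$o^*(\mu_m) = \arg\max F$ is found by a coarse log-grid plus
golden-section refinement; unimodality is checked on the grid, not
assumed.

The admissibility floor `mu_m_min` implements the one-message rule: an
essential gene must beat the no-expression alternative (fitness 0, since
cells below threshold do not proliferate) *and* keep cell-to-cell
variation at or below the mean level ($\mathrm{CV} \le 1$). Under the
product-form fitness the first clause alone is degenerate — $F_{\max}$ is
positive for every $\mu_m > 0$ — so the binding constraint is the noise
clause, which in the gamma model gives exactly one message per cell
cycle, independent of $\epsilon$. This matches the observation that the
prediction is essentially parameter-free: a thousandfold change in
$\epsilon$ moves $\log_{10} o^*$ by far less than $\log_{10}(1/\epsilon)$.

# Synthetic data: what it emulates, and what it does not

`simulate_tfnseq()` draws reads multinomially at fixed depth over genes
whose expected cell numbers follow the piecewise-exponential depletion
model (wild-type rate $k_0$ until $T_i = \ln o_i / k_0$, then
`residual_rate * k0`, default 0.05 — post-arrest trajectories decline
without being degenerate). `simulate_microcolony()` is an event-driven
lineage simulation: exponential area growth, division at area doubling,
protein amount conserved exactly at divisions, area split fraction
truncated-Gaussian around 0.5 and protein split truncated-Gaussian
around the area split (both with CV `partition_cv`), sharp rate change
at the threshold concentration. `simulate_rnaseq()` draws reads
multinomially proportional to $\mu_m$.

Default study conditions: $k_0 = 1.2$/h (35-min doubling), sampling
every 2 h from 0 to 12 h, depth $10^6$ reads per timepoint, imaging at 1
frame per 2 min, `partition_cv = 0.05`, and a demonstration genome of
200 genes — half nonessential, and 69% of the essential half
overabundant with $\log_{10} o$ uniform on $[0.5, 2.5]$, the rest
sufficient — anchored by four genes carrying measured transcription
levels (30, 49, 20, 26 messages per cycle).

What the generators deliberately omit: sequencing overdispersion beyond
multinomial (a reserved config knob, off in this version), insertion-site
effects below gene level, photobleaching and neighbor fluorescence,
cell-shape effects beyond area, transformation-time offsets, and any
segmentation error. Passing tests therefore demonstrate correctness of
the estimators under the stated noise models, not robustness to every
artifact of real imaging or sequencing.

# Numerical choices and degenerate inputs

* Changepoint grids: arrest-time resolution 0.01 h (library branch);
  landscape changepoints at geometric midpoints of observed
  concentrations with at least 3 points per side.
* Likelihood clamps probabilities to $[10^{-12}, 1-10^{-9}]$; zero
  counts are valid data.
* Genes with $t=0$ counts below 20 reads are dropped with an explicit
  reason record, never silently.
* Degenerate cases: $o_{\text{true}} = 1$ colonies arrest at $t = 0$ and
  come back censored with $\hat o \approx 1$; a movie shorter than one
  frame, non-positive areas (named frame), shuffled timepoints, and a
  missing $t=0$ column are hard errors.
* Seeds: every simulator takes an explicit seed; the pipeline derives
  per-stage seeds from one base seed and records them in its manifest,
  so reruns are byte-identical.

# Scale of the shipped validation

The package's own test suite validates at desk scale: a 2200-gene
calibration library and a 400-gene recovery library at depth $10^6$
(minutes of CPU), microcolonies up to 32-fold overabundance, and exact
small-sample oracles (brute-force likelihood grids, enumeration KS
p-values, closed-form gamma tails). Measured performance under those
conditions: recovery RMSE in $\log_{10} o$ about 0.03 (bound 0.15),
single-cell recovery within 0.01 in $\log_{10} o$ noise-free and within
5% at `partition_cv = 0.05`, and exact type-I control at
$\alpha = 10^{-4}$.

# Known limitations

* The sequencing branch measures replication-based arrest; for genes
  whose failing process is not replication (for example septation), the
  arrest time and hence $o$ can be overestimated. The two imaging
  metrics bracket this effect, and the package reports both.
* The binomial noise model has no overdispersion; replicate spread is
  the recommended empirical error estimate (`replicate_error()`).
* The RLTO fitness functional is a reconstruction; its acceptance-level
  claims are deliberately bounds (greater than tenfold at the
  one-message floor, near-sufficiency at high expression).
* Self-consistent renormalization requires some genes that outlive the
  sampling window; libraries composed entirely of early-arresting genes
  need an external reference set.
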