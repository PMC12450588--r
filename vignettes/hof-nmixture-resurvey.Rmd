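---
title: "HOF N-mixture models for two-period resurveys: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HOF N-mixture models for two-period resurveys: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hofnmix)
```

This vignette records how `hofnmix` models two-period point-count resurvey
data, why its defaults are what they are, and what its validation does and
does not demonstrate.

## The model and its assumptions

Counts from repeated point counts underestimate abundance because birds
present at a station go undetected. The binomial N-mixture model separates
the two processes: within survey period $i$ and station $j$ the true
abundance $N_{ij}$ is assumed closed across the replicate sub-counts $k$,
each of which detects every individual independently with probability $p$:

$$y_{ijk} \sim \mathrm{Binomial}(N_{ij}, p), \qquad
  N_{ij} \sim \mathrm{Poisson}(\lambda_{ij}).$$

Abundance varies along the gradient through a Huisman–Olff–Fresco (HOF)
response curve on standardized elevation $x_j$:

$$\lambda_{ij} = M_i\,
  \frac{1}{1 + e^{a_i + b_i x_j}}\,
  \frac{1}{1 + e^{c_i - d_i x_j}},$$

a two-logistic product that can be flat, monotone or unimodal, so the same
functional form serves low-elevation, broad and high-elevation species.
Each period gets its own curve $\{M, a, b, c, d\}$ as fixed effects; $p$ is
shared across periods and elevations within a species. That sharing is a
strong but deliberate simplification: with few visits per station in the
modern period, a period-specific $p$ would be confounded with the abundance
change the analysis is trying to measure. Species are fitted independently;
there are no detection covariates, no spatial random effects, and no model
selection among HOF sub-types (the full five-parameter form is always
fitted).

Key assumptions inherited from this structure: closure within a
station-period (no movement between sub-counts), equal per-individual
detectability across stations, elevations and eras, and Poisson (not
overdispersed) latent abundance around the curve.

### Standardization

Elevation is centered at the mean of the station elevations and scaled by
two standard deviations (`elev_standardizer`), the common convention for
putting regression inputs on a roughly unit scale. The standardizer
computed from the *fitted station set* is reused for every prediction grid;
mixing standardizers silently changes the curve and is the main foot-gun
the object exists to prevent.

## Inference

### Marginalized likelihood

The latent $N_{ij}$ are summed out of the likelihood rather than sampled:

$$P(y_{ij\cdot}) = \sum_{N = \max_k y_{ijk}}^{K}
  \mathrm{Pois}(N; \lambda_{ij}) \prod_k \mathrm{Bin}(y_{ijk}; N, p),$$

computed in log-space with a truncation bound $K$ of `max(y)` at the
station plus `K_extra = 50`. For per-replicate abundances realistic for
point counts ($\lambda \le 10$), the neglected tail mass is below
$10^{-15}$, and tests verify that doubling the margin changes station
log-likelihoods by less than $10^{-8}$. The binomial-coefficient sums per
(station, $N$) are parameter-free and tabulated once per dataset, which
makes a likelihood evaluation a few floating-point operations per $N$ —
the design that allows full MCMC in seconds per species.

We marginalize because sampling hundreds of discrete latent abundances
one at a time mixes very poorly for this curve family: the HOF parameters
are strongly correlated a posteriori, and conditional-on-$N$ updates of
single parameters barely move. (This was measured, not assumed, during
development with a Gibbs-style latent-$N$ sampler.)

### Sampler

The 11-dimensional posterior ($\log M_i$, shapes, $\mathrm{logit}\,p$) is
explored with an adaptive random-walk Metropolis sampler written in C++:
Haario-style running-covariance adaptation plus a global scale factor tuned
toward 23% acceptance, both adapted during warm-up only and frozen
afterwards so the retained draws come from a valid fixed-kernel chain.
Defaults mirror a conventional configuration: 4 chains × 2000 iterations,
first half discarded as warm-up, 4000 retained draws. Because random-walk
moves are small, each retained iteration corresponds to `thin` (default 40)
internal proposals; reducing `thin` trades effective sample size for speed
and is what the test suite does.

Starting values come from a quadratic Poisson GLM of per-replicate mean
counts on standardized elevation: its vertex seeds the curve's peak
location and height, jittered per chain.

### Priors

The priors are weakly informative and configurable:
$p \sim \mathrm{Uniform}(0,1)$; $M \sim \text{half-Normal}$ with scale
$\max(5, 2\max y)$ so the abundance scale is a priori consistent with the
observed counts under moderate detection; $a,b,c,d \sim \mathrm{N}(0,5)$,
wide enough for near-step-function logistic terms across a $|x| \lesssim 1$
gradient while discouraging astronomically sharp cliffs no survey could
resolve.

### Convergence diagnostics and identifiability

The HOF parameterization has an exact mirror symmetry — swapping the
logistic terms, $(a,b,c,d) \to (c,d,a,b)$ with $x \to -x$, yields the same
curve — so chains can settle in parameter modes that disagree numerically
while describing identical abundance surfaces. Split-Rhat is therefore
computed on mirror-invariant quantities: $p$ and $\lambda$ at five
elevations per period. `assess_identifiability` flags a species as
`poorly_defined` when its optimum-elevation 89% HDI spans more than 75% of
the gradient or the fit's max split-Rhat exceeds 1.05; cross-species
summaries use the well-defined subset, formalizing the usual practice of
restricting such averages to species with narrow, well-defined intervals.

## Derived quantities

All intervals are 89% highest-density intervals (HDIs), computed with
`coda::HPDinterval` — one consistent convention for curve bands, optima and
community metrics.

**Optimum elevation.** Per draw, the grid elevation maximizing that draw's
curve (grid search, ties to the lowest elevation; draws with $M = 0$ are
excluded with a count). The *point estimate* is the optimum of the
per-elevation posterior-median curve; the median of per-draw optima is
available by argument. The two conventions differ for skewed posteriors
and the choice is genuinely open; the median-curve reading was adopted
because it matches "the elevation at which the model predicts maximum
abundance" and is stable when optimum draws are multimodal. The prediction
grid defaults to 1-m steps over 201–1443 m (the sampled gradient); the
step, not the span, is the resolution limit on shift estimates.

**Range limits.** The lowest and highest grid elevations where the median
curve exceeds 0.2 birds per sub-count *or* 15% of its maximum. The
absolute arm keeps ubiquitous species' limits from chasing noise in near-
zero tails; the relative arm keeps genuinely sparse species from losing
their range entirely. A 0.1 absolute variant is available via
`range_rule(abs_threshold = 0.1)` because both thresholds are in
circulation for this analysis style; the stricter pair is the default. The
phrase "15th percentile of its maximum" in some descriptions is read as
15% *of* the maximum — a scalar has no percentile — and both readings
collapse to the same default here.

**Change classes.** At each grid elevation inside both periods' ranges,
the two 89% HDIs either overlap (`stable`) or the modern interval sits
entirely above (`increase`) or below (`decrease`). Elevations inside only
the modern range are `range_expansion`; only the historical,
`range_contraction`. The classifier is anti-symmetric under period swap,
which the tests enforce.

**Scenarios.** The six response labels are assigned by explicit rules
(documented in `?assign_scenario`) over the change classes, with
precedence shift-up > high-elevation contraction > expansion-up >
expansion-down > decline > stable and a majority-side fallback, so the
labeling is total and reproducible. Visual inspection of profile plots can
reasonably disagree near rule boundaries; the rules are a formalization,
not a claim that marginal species have a unique true label.

**Cross-species means.** The mean optimum (or limit) shift is propagated
draw-wise: for each retained draw, the mean across species of that draw's
shifts; the summary is the median and 89% HDI of those means. A bootstrap
over species' point shifts is available as an alternative convention.
Species absent or nearly absent from one period (empty modeled range) are
excluded from means — their "shift" is an artifact of fitting a curve to
near-zero data.

**Community curves.** Total abundance sums species' $\lambda$ draw-wise.
Richness follows the generative model: per draw, elevation and species, a
Poisson abundance is drawn, converted to presence/absence and summed;
the analytic expectation $\sum_s (1 - e^{-\lambda_s})$ is kept only as a
cross-check, and tests confirm the Monte-Carlo curve matches it. The
richness seed is explicit because these Poisson draws are the only
randomness downstream of the fits. The irruptive-species sensitivity
(`irruptive_sensitivity`) defaults to the irruptive finches of the
motivating community — Pine Siskin, Red Crossbill, Evening Grosbeak —
a documented assumption, as "irruptive finches" names a guild, not a list.

## The synthetic-data generator

`simulate_dataset` inverts the model exactly: uniform station elevations
over 201–1443 m (the design gives a range, not a spacing); visits per
station drawn as $1 + \mathrm{Poisson}(\mu - 1)$ with $\mu = 3.6$
(historical) and $1.9$ (modern), never below one visit and matching the
means exactly; three 4-min sub-counts per visit (the replicate unit shared
by both eras — 12-min counts split in three, with modern 2-min halves
summed in pairs by `build_count_matrices` when data arrive at that
resolution); one latent $N$ per species × station × period; binomial
thinning per sub-count. A truth ledger (latent $N$, $\lambda$, curve
parameters) is returned for recovery tests, and output is bit-reproducible
under the configured seed.

`demo_species_set()` provides a six-species community spanning the
response types of interest — a sharply peaked species with a +150 m
translation, a broad stable species, low- and high-elevation margin
species, a uniform decliner, and a sparse weakly-identified species — with
peak abundances 0.4–5 per sub-count and detection probabilities 0.35–0.6,
the ranges typical of common forest songbirds on point counts.

What the generator does *not* emulate: spatial autocorrelation among
stations, habitat covariates, temporary emigration or within-period
population trends, distance-dependent detection, observer differences, and
between-year irruptive dynamics. Passing recovery tests therefore show the
estimator is consistent with its own assumptions at the study's design and
effort — not that those assumptions hold in any particular field dataset.

## Filtering conventions

`filter_surveys` drops (1) historical records before a May 23 month-day
cutoff (possible migrants, applied to the historical period only, exactly
as stated for the motivating campaign), (2) detections beyond 75 m, with
distance 80 m encoding ">75 m" and an exemption list defaulting to Sooty
Grouse, whose booming display is reliably detected far beyond 75 m, and
(3) stations not surveyed in both periods. Zero-count effort rows are never
dropped, so effort survives filtering; removals are counted by reason and
surface in the run manifest. Filtering is idempotent, and count-matrix
totals reconcile exactly with the filtered records (tested invariants).
Whether historical 12-min visits should be analyzed as three 4-min
replicates or pooled per visit is not decidable from the design
description; the `replicate_unit` switch exposes both, with the sub-count
default because it is the unit common to both eras.

## Climate module

Warming rates are estimated by OLS on *yearly* aggregates (annual or
May–July means) — daily fits would understate the standard error through
autocorrelation. Isotherm displacement is `slope × span / lapse`, lapse
defaulting to 0.006 °C/m.

The default `span_years = 30.25` deserves a note. The interval between a
1990–1993 historical campaign and a 2023 resurvey is ambiguous at the
±1-yr level ("three decades"); back-calculating from the reported annual
(~166 m) and breeding-season (~306 m) displacements at the reported slopes
gives mutually inconsistent implied spans (~31.1 and ~30.1 yr), so no
single span reproduces both exactly. 30.25 yr sits inside the stated
"three decades", reproduces both displacements and the ~1.8 °C
breeding-season warming within rounding, and is configurable wherever it
is used.

## Problem sizes and numerical choices

The test suite and the acceptance script scale Monte-Carlo work to what
their checks need: recovery runs use 2 chains × 1000 iterations with
`thin = 20` (a configuration whose split-Rhat on invariant summaries stays
near 1.03–1.15), 8–10 simulated repeats at the full 112-station design,
and 4–8-m prediction grids; property tests use coarser grids still. These
are the package's validation sizes — production fits should use the
defaults (4 × 2000, `thin = 40`, 1-m grid), which take on the order of a
minute per species. Tie-breaks (lowest elevation at optimum ties),
degenerate inputs (all-zero species refused; $M = 0$ draws excluded with
counts; empty ranges as `NA` sentinels) and overflow-safe logistic
evaluation are all exercised directly in the tests.

## Known limitations

- Constant $p$ across eras is untestable from within this design; if
  detectability changed systematically (observers, equipment, phenology),
  abundance changes absorb it.
- The closure assumption over a 12-min count is mild, but closure across
  visits within a period is stronger and standard for N-mixture models.
- Random-walk Metropolis needs long chains for sharp, correlated
  posteriors; the mirror-invariant Rhat guards against the symmetric-mode
  pathology but, as always, cannot prove convergence.
- Sparse species (a handful of detections) yield optimum HDIs spanning
  most of the gradient; they are flagged rather than dropped, and belong
  outside cross-species means.
- The scenario rules are one defensible formalization of a judgment call;
  labels for marginal species should be read with their per-elevation
  class vectors, not alone.
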