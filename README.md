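# hofnmix

Detection-corrected abundance change along elevational gradients, for
two-period point-count resurveys.

Mountain birds (and other gradient-dwelling taxa) are expected to respond to
warming by moving upslope — either by shifting their whole elevational range
("escalator to extinction"), by increasing in abundance near the top of a
stable range ("upslope lean"), or not at all ("persist in place"). Telling
these apart needs *abundance*, not just presence/absence, and abundance from
point counts is contaminated by imperfect detection. `hofnmix` is built for
ecologists analyzing historical-vs-modern resurveys of fixed stations: it
estimates each species' abundance–elevation curve in each survey period
while correcting for detection, then derives the change metrics those three
hypotheses predict.

## The model

For species *s* (fitted independently), survey period *i*, station *j* and
replicate sub-count *k*:

```
y_ijk ~ Binomial(N_ij, p)          # counts thin the true abundance
N_ij  ~ Poisson(lambda_ij)         # latent abundance, closed within a period
lambda_ij = M_i * 1/(1 + exp(a_i + b_i x_j)) * 1/(1 + exp(c_i - d_i x_j))
```

where `x_j` is elevation standardized to (mean, 2 sd) of the station set and
the abundance surface is a Huisman–Olff–Fresco (HOF) curve — a product of
two logistic terms that can be flat, monotone, or unimodal. Curve parameters
`{M, a, b, c, d}` are period-specific; the detection probability `p` is
shared across periods within a species. The latent `N_ij` are marginalized
out of the likelihood by truncated summation (computed in C++), and the
joint posterior is sampled with an adaptive random-walk Metropolis sampler
(4 chains × 2000 iterations, half warm-up, 4000 retained draws by default).
Priors are weakly informative: `p ~ U(0,1)`, `M ~ half-Normal`,
`a,b,c,d ~ N(0,5)`.

From the posterior the package derives, with 89% highest-density intervals
throughout:

- per-elevation expected-abundance profiles on a 1-m grid (201–1443 m by
  default) and HDI-overlap **change classes** (stable / increase / decrease /
  range expansion / range contraction);
- **optimum elevations** (elevation of peak abundance) per period and their
  shift;
- threshold-based **range limits** (abundance > 0.2 or > 15% of the curve
  maximum) and their shifts, plus low/broad/high range categories;
- rule-based **response scenarios** (stable, abundance expansion up/down,
  abundance shift up, high-elevation contraction, decline);
- **community curves**: summed expected abundance, and species richness via
  Poisson draws converted to presence/absence, propagated through all
  retained draws;
- the climate-side yardstick: expected **isotherm displacement** from a
  warming trend and a lapse rate.

A synthetic-resurvey generator (`simulate_dataset`) reproduces the whole
data-generating process for validation by parameter recovery.

## Worked example

Simulate a resurvey with the design of a 112-station, two-period campaign
(historical visit mean 3.6, modern 1.9, three 4-min sub-counts per visit),
with one species whose optimum is translated +150 m, then fit and summarize
it:

```r
library(hofnmix)

spp <- demo_species_set(optimum_shift_m = 150)[c("PKUP", "LOWE")]
sim <- simulate_dataset(sim_config(species = spp, seed = 42))
cms <- build_count_matrices(filter_surveys(sim$records))

ctrl <- nmix_control(n_chains = 2, n_iter = 1000, thin = 20) # reduced, for speed
set.seed(1)
fit <- fit_species(cms$PKUP, sim$standardizer, ctrl)
fit
#> HOF N-mixture fit: PKUP
#>   2 chains x 500 retained draws; acceptance 0.21-0.24
#>   max split-Rhat 1.031, min ESS 148
#>   p: median 0.512 (89% HDI 0.489-0.532)

ch <- summarize_species_change(fit, elevation_grid(by = 4))
ch$summary[, c("optimum_hist_m", "optimum_mod_m", "optimum_shift_m", "scenario")]
#>   optimum_hist_m optimum_mod_m optimum_shift_m           scenario
#> 1            893          1069             176 abundance_shift_up
```

The true detection probability (0.5) sits inside the 89% HDI, and the
estimated optimum shift of +176 m (89% HDI 80–292 m) covers the simulated
+150 m translation. For the climate side:

```r
isotherm_shift(0.032)   # annual warming trend, C/yr
#> $shift_m   161.3
#> $warming_C 0.968
```

i.e. a 0.032 °C/yr warming over the ~30-yr survey interval, divided by the
0.6 °C/100 m lapse rate, predicts isotherms ~160 m upslope — the
displacement against which species' shifts are compared.

`run_pipeline(records, out_dir, seed)` chains
filter → fit → derive → community on a whole survey table and writes
per-species change summaries, per-elevation class tables, community curves
and a reproducibility manifest.

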