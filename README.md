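# pbsn

Sociospatial analysis of GPS-collared animals: proximity-based social
networks, kernel home ranges and overlap, interannual site fidelity, a
data-stream permutation null, and seasonal mixed models — with a movement
simulator for end-to-end validation.

## The problem

Gregarious ungulates such as woodland caribou may find forage either by
tracking the distribution of resources directly (resource dispersion) or by
using conspecifics as cues (conspecific attraction). These mechanisms leave
different seasonal fingerprints in telemetry data: conspecific attraction
predicts low interannual site fidelity, high home-range overlap, and
social association stronger than chance when resources are patchy (winter);
resource dispersion predicts associations indistinguishable from chance
when resources are homogeneous (summer). Testing this requires a chain of
estimators — simultaneous-fix detection, chain-rule grouping, association
indices, utilization distributions, overlap, and permutation nulls — that
`pbsn` packages as composable, data-frame-first functions.

## The statistics at the core

- **Association**: fixes within 5 min of the same whole hour form a round;
  animals within 50 m chain into groups; the dyadic simple ratio index is
  `SRI = x / (x + y_AB + y_A + y_B)`, and **graph strength** is each
  animal's summed edge weights per herd-season-year network.
- **Space use**: kernel UDs with the reference bandwidth
  `h = sigma * n^(-1/6)`; 95% isopleth home-range areas; pairwise
  `UDOI = A_12 * integral(UD1 * UD2)` spatial networks; site fidelity as
  within-individual UDOI across consecutive years.
- **Null model**: each animal's daily trajectories are shuffled
  independently (within-day paths preserved), decoupling simultaneity while
  leaving every individual's space use untouched; observed strengths and
  seasonal model coefficients are compared to the resulting null bands.
- **Inference**: four REML mixed models (fidelity, spatial strength,
  social strength observed vs null, home-range area) with season fixed and
  herd / animal-in-herd / year random intercepts.

## Worked example

Simulate the default two-season study (3 herds x 10 collared animals,
2007-2009, winter conspecific attraction on a patchy landscape, independent
summer movement), build the networks, and test the seasonal contrast
against the permutation null:

```r
library(pbsn)

fx  <- simulate_study(seed = 42, years = 2007:2008)
fx  <- build_rounds(fx)
net <- build_pbsn(fx)
glance(net)
#> # A tibble: 12 x 8
#>    herd  season  year n_nodes mean_strength n_edges  mean_sri n_groups
#>  1 herdA summer  2007      10      0.00171       45 0.000190         5
#>  3 herdA winter  2007      10      0.0483        45 0.00537        139
#>  5 herdB summer  2007      10      0.00511       45 0.000568        15
#>  7 herdB winter  2007      10      0.0686        45 0.00762        183
#>  ...
```

Mean social strength is an order of magnitude higher in winter than in
summer, and winter networks contain ~140-190 groups of two or more collared
animals against ~5-15 in summer — the fission-fusion signature the winter
attraction mechanism plants. The permutation null shows the contrast is
nonrandom:

```r
en <- run_ensemble(fx, n_iter = 100, seed = 7)
coefficient_null(en)$summary
#> # A tibble: 2 x 6
#>   term         observed null_mean null_lo null_hi outside
#> 1 (Intercept)     -6.24     -6.23   -6.38   -6.06 FALSE
#> 2 seasonwinter     3.36      2.23    2.05    2.42 TRUE
```

The observed winter coefficient (3.36) lies far outside the null band
[2.05, 2.42]: winter association exceeds what shared space use alone
produces. `run_pipeline(pipeline_config(...))` chains all stages (screening,
networks, home ranges, fidelity, ensemble, the four-model suite) and writes
CSVs plus a manifest; `plot_strength()`, `plot_fidelity()`,
`plot_coefficient_null()` and `plot_ud()` draw the standard displays.

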