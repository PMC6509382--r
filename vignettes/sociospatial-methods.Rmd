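---
title: "Methods: proximity-based social networks, space-use overlap, and the day-shuffling null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proximity-based social networks, space-use overlap, and the day-shuffling null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pbsn` implements a complete sociospatial analysis for GPS-collared
animals, of the kind used to ask whether a gregarious ungulate finds forage
by following conspecifics (conspecific attraction) or by tracking the
dispersion of resources directly. This vignette is the package's account of
the methods: the statistics it computes, the assumptions they carry, the
tunable parameters and their defaults, what the bundled movement simulator
does and does not emulate, and the numerical choices made where the
literature leaves the details open.

## The analysis in one paragraph

Telemetry fixes (projected planar coordinates, fixed 1- or 2-hour schedule)
are screened for positional errors, cut into two discrete seasonal windows —
winter (15 January–3 March) and summer (15 July–1 September) — and aligned
into simultaneous *rounds*. Within a round, animals are grouped by the
50-m chain rule; dyadic association across rounds is summarised by the
simple ratio index (SRI) and assembled into one weighted social network per
herd-season-year, with per-animal *graph strength* (summed edge weights) as
the sociality index. In parallel, each animal's seasonal utilization
distribution (UD) is estimated by kernel density with the reference
bandwidth; 95% isopleths give home-range areas, pairwise utilization
distribution overlap indices (UDOI) give a *spatial network*, and
within-individual UDOI across consecutive years gives interannual *site
fidelity*. A data-stream permutation null — shuffling each animal's daily
trajectories independently while preserving the within-day path — yields
null distributions of strength and of seasonal model coefficients. Four
linear mixed models then contrast seasons: fidelity, spatial strength,
social strength (observed versus null, paired within animal), and home-range
area with social strength as a covariate.

## Sampling rounds and the chain rule

Two fixes are treated as simultaneous when both fall within 5 minutes of
the same whole hour; rounds anchor to the top of the hour so that mixed
1-h and 2-h collar schedules never merge distinct schedule points. When an
animal contributes two fixes to a round the nearer is kept, so a round has
at most one fix per animal.

Group assignment within a round follows the chain rule: animals are
adjacent when within `assoc_dist` (default 50 m) of each other, and a
group is a connected component of that adjacency graph — individuals can
share a group without being mutually within 50 m. Because the grouping
literature states the criterion both as "within 50 m of one another" and as
"50-m buffers contiguous" (which would imply 100 m between centres), the
package adopts the dyadic ≤ 50 m criterion — the form in which the
association counts are defined — and exposes the distance as a parameter.

Association is group co-membership, not raw dyadic distance: in a chain
A–B–C with 80 m between A and C, the A–C dyad still counts as associated.
For a dyad the SRI is

$$\mathrm{SRI} = \frac{x}{x + y_{AB} + y_A + y_B}$$

with \(x\) the rounds grouped together, \(y_{AB}\) the rounds both observed
but separated, and \(y_A, y_B\) the rounds only one was observed. Dyads with
an empty denominator (never observed) contribute *no* edge rather than a
zero edge; this preserves strength sums and flags, rather than hides, the
absence of sampling. Graph strength is the sum of incident SRI weights,
zero for an observed animal with no edges.

## Fix screening

Positional screening is a deliberately simple two-rule filter: a *spike*
(out-and-back excursion) is removed when both the step in and the step out
exceed `max_step` (default 10,000 m), and a fix is removed as a *speed
violation* when the speed from the last retained fix exceeds `max_speed`
(default 15,000 m/hr — far above sustained caribou travel). The full
screening statistics of the dedicated collar-screening literature are out
of scope; the filter is configurable and idempotent, and retained plus
rejected fixes always partition the input.

## Kernel home ranges, UDOI, and site fidelity

UDs use an isotropic bivariate normal kernel with the reference bandwidth

$$h_{\mathrm{ref}} = \sigma\, n^{-1/6}, \qquad
  \sigma = \sqrt{\tfrac{1}{2}\,(\mathrm{var}(x) + \mathrm{var}(y))},$$

the convention the home-range literature denotes "href". Kernel mass is
integrated exactly over each grid cell (separable Gaussian cell integrals,
not point evaluation) and renormalized; estimation fails loudly if more
than 1% of mass falls off the grid. The grid uses cell size \(h/4\) and a
\(3h\) margin, and is shared across all animals of a herd-season-year so
that overlap integrals compare like with like. A minimum of 5 fixes per
animal-season-year is required — the conventional floor below which the
bandwidth and the UD degenerate.

The home range is the smallest set of highest-density cells reaching 95%
of mass; its area is the summed cell area. Overlap uses

$$\mathrm{UDOI} = A_{1,2} \iint \mathrm{UD}_1(x,y)\,\mathrm{UD}_2(x,y)\,dx\,dy,$$

where \(A_{1,2}\) is the intersection area of the two 95% home ranges.
By default each UD is masked to its own 95% home range and renormalized
before the product integral; this is the convention under which the
index's calibration case — two identical uniform distributions — equals
exactly 1 (area \(A\) times density product \(1/A^2\) times area \(A\)).
Whether the original overlap software restricted UDs this way is not
documented; a full-grid variant (`restrict = FALSE`) is provided, which for
the identical-uniform case yields 0.95 (the isopleth mass) instead. Spatial
graph strength is the sum of incident UDOI edges. UDOI is non-negative,
symmetric, and can exceed 1 for strongly concentrated mutual overlap.

Site fidelity is the within-individual, within-season UDOI between
consecutive years only (the "2007–2008" reading of cross-year comparison);
all-pairs comparison would inflate the sample with non-independent,
increasingly distant pairs. The two years of a pair are estimated on their
own shared grid.

Because the per-network grid geometry depends on which animals are present
(the shared cell size follows the largest bandwidth), adding or removing an
animal can perturb discretized UDOI values by a fraction of a percent;
halving the cell size changes UDOI by well under 5% on smooth surfaces.

## The day-shuffling permutation null

Node permutations are known to be anticonservative for GPS-derived
networks, so the null is built on the data stream itself: within each
animal-season-year, the calendar dates of the animal's daily trajectory
blocks are permuted uniformly at random — independently across animals —
while each day's internal fix sequence and time-of-day offsets are kept
(a 13:00 fix stays at 13:00 on its new date). This preserves every spatial
property of individual movement (each animal's fix multiset modulo date,
hence its UD, home range and spatial strength, are exactly invariant) while
destroying the temporal alignment between animals; what survives in the
null is co-occurrence through shared space, what dies is coordination in
time. A day is a calendar date; partial days at window edges are blocks
like any other. The ensemble repeats this `n_iter` times (1,000 at full
scale), rebuilding rounds, networks and strengths each time, and pairs each
animal's observed strength with its null mean. Iteration `i` seeds its own
substream as `seed + i`, making results order-insensitive and reproducible.

Whether "reordering" should be a uniform permutation or some rotation
scheme is not specified in the randomization literature the procedure
follows; the uniform permutation is the maximal-entropy choice and is used
here.

The coefficient-level comparison refits the seasonal strength model to each
iteration's strengths (via a response-only refit on the observed model
frame, which is exact and fast), collects the intercept and season
coefficients, and calls the observed coefficient nonrandom when it falls
outside the empirical 95% band of the null draws. The same log offset
(below) is shared between observed and null fits so coefficients are
commensurable.

## The four seasonal models

All responses are log-transformed. Strengths and UDOI can be exactly zero,
and the source analyses do not state their zero-handling; the package adds
half the minimum positive value of each response — a scale-respecting
offset that is configurable. One further filtering rule precedes modelling:
any animal whose *summer* home range exceeds 4,000 km² is removed from all
analyses (the rule keys on summer only; winter-only exceedances are kept).

Each model is a Gaussian REML fit with season (summer as reference) as the
fixed effect and random intercepts for herd, animal nested in herd, and
year; the fidelity model replaces year with the year *pair* over which
fidelity was measured. The social model adds a `source` factor (observed
vs. permutation null mean, paired one-to-one within animal-season-year) in
interaction with season — the interaction is the test of within-season
nonrandomness. The area model adds log observed social strength as a
covariate. P-values use the Satterthwaite approximation (and are labelled
as such); near-zero variance components are expected in these designs
(herd and year variances of order 10⁻¹⁵ occur in the motivating analyses)
and are tolerated and flagged, not treated as failures. Random terms whose
grouping factor has a single observed level in a reduced dataset are
dropped with a message rather than crashing the fit.

## What the simulator emulates

The generator exists so that every downstream stage is testable without
field data. It emulates: several herds of collared females; multi-year
deployments; the two 48-day seasonal windows on a fixed 1- or 2-h schedule
with optional missingness; winter-like movement (conspecific attraction on
a patchy landscape, low interannual fidelity) versus summer-like movement
(independent central-place walks on a homogeneous landscape, high
fidelity).

Movement is a biased correlated random walk stepped at the fix interval.
Step lengths are gamma(shape 2, scale `step_scale`/2), mean `step_scale`;
headings are drawn wrapped-normal around a steering direction with
concentration `turn_concentration` (sd \(= 1/\sqrt{\kappa}\); a
von-Mises-style pull implemented with the simpler wrapped-normal law, since
only occupancy statistics matter downstream). The steering direction is the
angle of a weighted sum of unit vectors: previous heading (weight 1,
persistence), range centre (weight 1, the home-range mechanism), nearest
patch centre (weight `patch_attraction` × patch value), and nearest
same-herd conspecific (weight `social_attraction`, evaluated synchronously
each step — the minimal mechanism that produces chain-rule groups).
Between years each agent keeps its range centre with probability
`fidelity`, else draws a new one uniformly; this single dial produces the
interannual overlap contrast.

Default study conditions: 3 herds × 10 agents, years 2007–2009, a 5 km ×
5 km landscape, 2-h fixes, 5% missingness, winter attraction weights
(social 8, patch 4, 8 patches of 300 m radius) against summer weights of
zero, fidelity 0.1 (winter) vs 0.9 (summer), `step_scale` 150 m. These are
deliberately scaled-down problem sizes — home ranges of a few km² rather
than hundreds — chosen so that a full pipeline run takes seconds to
minutes; the seasonal *contrasts* (winter strength and overlap far above
summer, summer fidelity far above winter) reproduce the qualitative
structure of real caribou data at a tractable scale. All randomness flows
from one seed through a single stream consumed in a fixed step-major,
agent-vectorised order, which gives bit-reproducible output with less
machinery than formally split per-agent substreams.

Two behaviours of the mechanism are worth knowing. First, association
strength *saturates* in `social_attraction`: beyond roughly the point where
every agent is already steering at its nearest neighbour (≈ 4 under the
defaults), more pull changes nothing, so monotonicity of strength in
attraction holds in the responsive regime and flattens after it. Second,
the calendar is honest: the summer window (15 July–1 September, end dates
inclusive) spans 49 days and leap-year winters span 49, so schedule
arithmetic uses true window lengths, not a nominal 48.

What the simulator does **not** emulate: calving and rut (fixes are only
generated inside the two windows), predation, energetics, collar failure
beyond i.i.d. missingness, habitat structure beyond disc patches, and
landscape-scale range sizes. Passing tests therefore demonstrate that the
*estimators and null model* behave correctly under controlled conditions
with known truth — not that any particular field system satisfies the
generative assumptions.

## Numerical choices and degenerate inputs

- Rounds: fixes farther than the tolerance from any whole hour are dropped
  with a message (they cannot be placed on the simultaneity schedule).
- Bandwidth: fewer than 5 fixes, or zero spatial variance, is an error;
  the animal-season-year is excluded upstream with a report.
- Isopleth ties (uniform surfaces) resolve by accumulation order after a
  stable sort on density; the cumulative-mass threshold uses a 10⁻¹²
  slack against floating-point shortfall.
- UDOI on different grids is an error, never a silent resample.
- Single-level random effects are pruned with a message (see above);
  permutation iterations whose refit fails are dropped, and the ensemble is
  invalid if more than 5% fail.
- Empty-denominator dyads carry no edge; single-animal networks warn and
  return a node with strength 0.
- The pipeline writes every stage's output with a manifest (stage, file,
  row count, md5, parameters) and aborts with a stage-named error, keeping
  partial outputs.

## Known limitations

- The chain rule is evaluated per round; there is no temporal smoothing of
  group membership across rounds.
- UDOI here is grid-based; polygon-exact overlap would differ at the cell
  scale. The shared-grid convention makes overlap comparable within a
  herd-season-year but means results are not bit-identical across different
  animal subsets.
- The permutation preserves day-level spatial content only: within-day
  autocorrelation survives the null, between-day structure does not. Nulls
  for processes operating at sub-daily scales would need finer blocks.
- Strength models treat animal-season-years as exchangeable given the
  random effects; true collar schedules that differ systematically between
  seasons would need observation-effort covariates, which the simple ratio
  index only partially absorbs.
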