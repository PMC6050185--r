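---
title: "Methods: the spatial Lambda-Fleming-Viot simulator and its inference machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the spatial Lambda-Fleming-Viot simulator and its inference machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

The spatial Lambda-Fleming-Viot (SLFV) process describes a population spread
continuously over a landscape in which reproduction happens through
localized *events* rather than synchronized generations. Backward in time,
the genealogy of a sample is built by iterating one step:

1. An event arrives after an exponential waiting time with rate
   `rate_density` per unit time per unit area (weighted by a raster
   intensity map on heterogeneous landscapes), centered at a point drawn
   with density proportional to that map.
2. Every extant ancestral lineage is selected independently with the
   kernel's selection probability: `impact` (written `u`) inside a disc of
   radius `r` for disc kernels, or `u * exp(-d^2 / 2r^2)` for Gaussian
   kernels.
3. If no lineage is selected the event has no effect. A single selected
   lineage *moves*: its location is resampled from the event's replacement
   distribution (uniform on the disc, or Gaussian around the center). Two or
   more selected lineages *coalesce* into one ancestor placed by the same
   replacement distribution — multiple mergers are a native feature, not an
   approximation.
4. Iterate until one lineage remains: the sample's most recent common
   ancestor.

Assumptions inherited from this construction: selective neutrality, a
single haploid locus per genealogy (multilocus data are unlinked loci on
independent genealogies), homogeneous impact and radius in space, and no
recombination. Landscapes are 1- or 2-dimensional tori: periodic boundaries
remove edge effects, which is the cleanest setting for the homogeneous
theory; reflecting or absorbing boundaries are intentionally out of scope.
The general SLFV framework also allows the selection probability to depend
on individual states; the kernels here ignore state, and the hook is simply
that `selection_probability()` is the single place such dependence would be
added.

Mutation is overlaid on the finished genealogy rather than applied during
the event loop. For neutral, state-independent mutation the two orderings
are equivalent, and the overlay keeps the event loop free of per-site
state.

## Simulation engines

`simulate_genealogy()` exposes three engines that sample from the same law:

* **thinned** (default): only events whose support can touch a lineage
  matter. For a homogeneous disc kernel with `r < min(extent)/2` the
  package simulates candidate events at rate `lambda * k * pi r^2`
  (`k` = current lineage count), proposes the center uniformly in the disc
  around a uniformly chosen lineage, and accepts with probability `1/m`,
  where `m` is the number of lineages within `r` of the proposed center.
  Accepted centers form exactly the Poisson process restricted to the union
  of lineage-centered discs, so the joint law of (waiting time, center,
  affected set) is identical to global sampling with far events discarded.
* **naive**: global event sampling. Exact for every configuration,
  including Gaussian kernels (whose support is unbounded), raster
  heterogeneity, and radii at or beyond half the extent (panmictic
  regimes), at the cost of many no-op events when kernels are small.
* **reference**: a pure-R loop composed from the exported operations
  (`sample_event()`, `select_affected()`, `apply_event()`). It exists so
  the compiled engines can be cross-checked against an independent
  implementation; the test suite compares all engines by
  Kolmogorov-Smirnov tests on pairwise coalescence times, and separately
  against a forward-in-time Moran-style dual simulation written from
  scratch in the tests.

The self-overlap constraint `radius < min(extent)/2` keeps the wrapped
uniform proposal exact for the thinned engine. Configurations that *want* a
torus-covering event (the panmictic corner of the structure spectrum) opt
out with `allow_large_radius = TRUE` and run on the naive engine.

Movement events update the lineage's location in place and create no
genealogy node: downstream consumers (mutation, summaries) need topology,
times and birth locations only. Full spatial paths would multiply memory
by the movement rate for no inferential gain. Lineage counts are
non-increasing; a merger of `m` lineages decreases the count by `m - 1`
and nothing else changes it.

`max_events` (default 1e7 loop iterations) bounds the work; exhausting it
returns an explicit non-coalesced status carrying the surviving roots —
never a silently truncated tree. Ties in event times have probability zero;
if a generator ever produced one, events are processed in generation
order.

## From neighborhood size and dispersal radius to kernel parameters

The estimable parameters follow the event-based convention: the dispersal
radius is the disc radius `r` (the farthest an event can move anyone), and
the neighborhood size is the expected number of individuals within one
event's area, `N_s = d * pi r^2`, with `d` the effective density.

The homogeneous disc SLFV fixes that density implicitly. A lineage jumps at
rate `lambda * u * pi r^2` with per-axis squared displacement `r^2/2` per
jump (center and destination each contribute `r^2/4`), giving per-axis
dispersal variance per unit time `sigma_t^2 = lambda * u * pi * r^4 / 2`.
Two coincident lineages coalesce at rate `lambda * u^2 * pi r^2` and the
integral of the pair-coalescence rate over separations is
`Gamma = lambda * u^2 * (pi r^2)^2`. Matching the Wright-Malecot theory,
the effective density is `d_eff = 1/Gamma` and the Wright neighborhood
size `4 pi sigma_t^2 d_eff` collapses to the classical disc-model value
`2/u`.

`(lambda, u)` therefore hold two degrees of freedom for one density
constraint, and the package resolves the surplus in the unique way that
makes the two neighborhood conventions — event-based `d_eff * pi r^2` and
Wright's `2/u` — coincide:

```
u = 2 / N_s,     lambda = N_s / (4 pi r^2).
```

Under this convention every lineage jumps at rate 1/2 per unit model time
whatever the parameters (model time is calibrated to movement), the
per-axis dispersal variance per unit time is `r^2/4`, coincident pairs
coalesce at rate `1/N_s`, and the impact — hence the intensity of multiple
mergers — is a direct expression of neighborhood size: small neighborhoods
produce strongly skewed, multifurcating genealogies, large neighborhoods
approach the Kingman limit. That last point matters for inference: the
across-locus spread of diversity and the haplotype-count summaries read
the merger skew and thereby neighborhood size itself, not only the
compound `N_s / (pi r^2)` that overall diversity measures.
`kernel_for_parameters()` applies the inversion; `slfv_parameters()`
reads it back from any disc kernel.

## Mutation models

`k2p_transition_matrix()` implements the Kimura two-parameter closed form
with the rate matrix normalized so `mu` is the expected number of
substitutions per site per unit model time and `kappa` is the
transition/transversion *rate* ratio (`kappa = 1` is Jukes-Cantor; the
common "ts/tv count ratio" of real data corresponds to `kappa/2` at
stationarity). The root sequence is stationary-uniform. The test suite
checks the closed form against a matrix-exponential oracle at 1e-9 and the
`kappa = 1` reduction against the Jukes-Cantor law.

The infinite-sites overlay drops `Poisson(mu * L * branch length)`
mutations per branch, each on a fresh site; it refuses datasets whose
mutation count would exceed the locus length rather than silently recycling
sites. Alignments under this model always pass the four-gamete test.

## Summary statistics

`compute_summaries()` condenses one georeferenced multilocus dataset into a
fixed-schema vector: across-locus mean and SD of per-locus pairwise
diversity and of Watterson's estimator; total segregating sites, mean
distinct haplotypes per locus and the fraction of polymorphic loci (these
three carry the low-diversity end of the parameter range, where per-site
rates are all nearly zero and the discrete counts are what differ); the
isolation-by-distance regression slope and intercept of pairwise genetic
distance on minimal-image torus distance; and a 10-bin distance-class
variogram with fixed edges covering (0, max torus distance], so vectors
are comparable across simulations. Geographic distance uses the same torus
metric as the simulator. The set is the package's own choice, made once:
the source framework does not prescribe ABC summaries, and the vector is
deliberately standard population-genetic fare rather than anything tuned
to a particular landscape.

Empty variogram bins (possible for a fixed sample sheet whose pair
distances avoid a bin) are NA and are dropped — and logged — by the ABC
distance, along with any zero-spread column.

## Rejection ABC and its validation

`build_reference_table()` draws (neighborhood size, dispersal radius) from
independent priors — log-uniform for `N_s` (a scale parameter spanning
decades), uniform for `r` — maps them through `kernel_for_parameters()`,
simulates a full dataset for the same sample sheet as the observed data,
and stores parameters plus summaries. Draws that fail to coalesce within
the work bound are redrawn and counted. `rejection_abc()` scales each
summary by its table median absolute deviation, ranks Euclidean distances,
and accepts the nearest `ceiling(tolerance * n)` rows, ties broken by row
order. Point estimates are posterior medians (robust to the skew typical
of log-scale parameters); intervals are highest-posterior-density intervals
(`hpdi()`, the shortest contiguous window holding the requested mass). No
regression adjustment is applied — the method is deliberately plain
rejection.

`loo_cv_r2()` validates the estimator the standard way: hold out a table
row, treat its summaries as observed data, estimate from the remaining
rows, and regress estimates on truths over many replicates. The package's
reference validation — 8 individuals, 10 unlinked 1-kb loci, 2D unit
torus, and a reference table of several thousand simulations — recovers
neighborhood size with a leave-one-out R-squared computed by
`scripts/acceptance.R` and by the acceptance tests; the cross-validation
also reports a permuted-truth baseline, which sits near zero for both
parameters — neighborhood size and dispersal radius are separately
identifiable, diversity carrying most of the former and the spatial decay
of genetic distance the latter. Estimates shrink toward the prior center
at both ends of the range, as expected for rejection ABC with a finite
table; the shrinkage shrinks as the table grows.

## Default study conditions

The scenario generator fixes the validation design at 8 individuals
sampled at 10 unlinked 1,000-bp loci on a homogeneous unit 2D torus with
disc events. The remaining defaults were chosen once, on first-principles
grounds:

* `ns_bounds = (5, 158)`: 1.5 decades of neighborhood size, from
  near-panmictic handfuls to strongly structured hundreds; the lower bound
  keeps `u <= 1` feasible across the radius prior.
* `r_bounds = (0.05, 0.15)`: radii small enough relative to the torus for
  isolation by distance to develop, large enough that a 28-pair sample
  sheet senses them.
* `rate_density = 50`: time-unit convention (see above).
* `mu = 2.5e-6` per site per unit model time: pairwise coalescence times
  under these priors span roughly 1e2-2e4 time units, so expected pairwise
  diversity runs from about 5e-4 to 1e-1 per site with about 5e-3 at the
  prior center — typical nuclear-sequence polymorphism, clear of K2P
  saturation at the deep end.
* `kappa = 3`: an ordinary nuclear transition bias.

What the generator emulates — and what it does not: data are perfectly
georeferenced, loci are truly unlinked and neutrally evolving, the
landscape is homogeneous with known geometry, and every individual is
sequenced without error. Passing tests therefore certify the machinery and
the estimator under the model's own assumptions; they say nothing about
robustness to selection, recombination, habitat heterogeneity,
genotyping error or misregistered coordinates in real data.

## Numerical choices and degenerate inputs

* All randomness flows through R's RNG (the compiled code draws from the
  same stream), so `set.seed()` makes every pipeline byte-reproducible.
* Coordinates live in `[0, extent)`; wrapped draws that land exactly on
  the boundary by floating rounding are folded back in.
* The ABC distance drops, and records, zero-spread and non-finite summary
  columns; an all-degenerate summary set is an explicit error.
* `n = 1` samples yield a trivial single-node genealogy; `mu = 0` yields
  monomorphic alignments; non-coalescence is a classed condition
  (`slfv_not_coalesced`) that reference-table construction catches and
  redraws.
* Variogram bin edges default to 10 equal bins and are configuration-fixed
  so summary vectors remain comparable across a table.

## Problem sizes

The shipped validation runs use a reference table of 2,000 simulations of
the 8 x 10 x 1 kb design (the acceptance script rebuilds it from scratch
at each run; a few minutes on one core), 150 leave-one-out replicates at
5% tolerance, and 2,000-replicate Monte-Carlo checks for the
distributional properties (engine equivalence, the Kingman limit,
isolation by distance). These sizes are the package's chosen compromise
between Monte-Carlo error on the reported R-squared and a test suite that
runs in minutes; enlarging the table to 6,000 simulations moves the
cross-validation R-squared by less than its replicate-to-replicate spread,
so the extra compute buys no information at this dataset size.

## Known limitations

* Sexual (two-parent) events, recombination, selection and
  state-dependent kernels are out of scope; the single-parent haploid
  event is the entire genealogical model.
* Heterogeneity enters only as a piecewise-constant raster multiplying
  event *intensity* — not radius or impact — which keeps thinning and
  rate computations exact; continuous intensity surfaces and spatially
  varying kernels are not supported.
* Gaussian kernels are untruncated; whether a truncated variant is more
  faithful is genuinely open, and the choice is flagged here rather than
  silently equated with the disc model. The ancestor location for
  Gaussian events is centered on the event center; centering on the
  centroid of the affected set is a documented alternative that was not
  adopted.
* The rejection-ABC validation is a scaled-down reproduction of a study
  design two orders of magnitude larger; its R-squared is bounded by
  table size and by the intrinsic noise of 10-locus, 8-individual
  datasets.
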