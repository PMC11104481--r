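---
title: "Modelling larval connectivity on synthetic coastal fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling larval connectivity on synthetic coastal fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(larvconnect)
```

## The problem

Blue mussels (*Mytilus* spp.) are sessile as adults; the connections between
mussel beds are made by pelagic larvae that drift passively with coastal
currents for roughly a month before they are able to settle. Which beds seed
which, how much of a bed's production returns to it (local retention), and
whether beds tucked behind land masses are effectively isolated are questions
about the *transport* of larvae, and they can be asked of a circulation model
long before genetic data exist. `larvconnect` implements that analysis as a
desk-scale pipeline: it builds a synthetic coastal ocean with known structure,
releases parameterized virtual larvae, advects them forward (to find sinks) or
backward (to find sources), scores settlement on a regular grid, and reduces
the result to site-to-site connectivity matrices, source/sink summaries,
interpolated surfaces and inner-vs-outer archipelago contrasts. A companion
module applies the standard sample-filtering rules used when the complementary
population-genomic data *are* analysed: coverage outliers,
identity-by-state (IBS) pruning of technical replicates and close relatives,
locus presence/minor-allele-count filters, and admixture-threshold lineage
assignment.

Everything runs on synthetic inputs generated by the package itself, so every
stage is testable without downloads; the generators are first-class, seeded,
documented code, not test fixtures.

## The transport model

Larvae are passive fixed-depth drifters. A particle at position
$\mathbf{x}(t)$ with drift depth $z$ obeys

$$ d\mathbf{x} = \mathbf{u}(\mathbf{x}, z, t)\,dt + \sqrt{2 K_h\,dt}\;
\boldsymbol{\eta}, \qquad \boldsymbol{\eta} \sim \mathcal{N}(0, I_2), $$

integrated with a fourth-order Runge-Kutta scheme (default step 30 min;
`euler` available) on an equirectangular local metric: metres per degree are
$R\,\pi/180$ in latitude and $R\cos\varphi\,\pi/180$ in longitude with a
spherical Earth, $R = 6371.009$ km. On a 2-degree domain the error against
full geodesics is below the physical uncertainty of everything else in the
model (the spherical-vs-ellipsoid difference alone is ~0.25%, which is why
tests check against spherical great circles). Velocity sampling is bilinear
in the horizontal with land cells removed from the stencil and the weights
renormalized, nearest depth level in the vertical (larvae hold a fixed band),
and linear in time.

Backward tracing integrates the same equations with the field clock running
in reverse — the exact adjoint of the deterministic part. Diffusion is a
forward random walk in both modes; reversing noise is neither possible nor
meaningful. Coastline contact is handled by specular reflection off the
crossed cell face (default) or by halting; particles leaving the open
boundary are flagged `lost_domain` and frozen. Reflection guarantees no
stored position is ever on land, which tests assert as an invariant.

## Releases and development

Release schedules reproduce the spawning parameterization exactly rather than
in expectation:

* Two forward windows (15 May–14 July at 75%, 15 July–14 August at 25%) and
  the mirrored backward windows one month later; window counts are
  round-half-up of fraction x total with the remainder in the first window.
* Within a window, each hour slot `[h, h+1)` receives
  $\lfloor N_w/H_w \rfloor$ events and the remainder is spread at evenly
  spaced hour indices, so the at-least-one-per-hour rule holds by
  construction (3000 larvae per site in the defaults).
* Drift depths follow exact largest-remainder quotas over the bands
  40% 0–10 m, 40% 10–20 m, 20% 20–30 m; bed depths (used as backward release
  depths) are 70% 0.5 m and 10% each at 2, 4, 6 m. Randomness only places a
  depth *within* a ranged band, so the printed proportions are integers and
  testable (1200/1200/600 of 3000).

Deterministic quotas instead of multinomial draws are a deliberate choice:
the parameterization is a study condition, not a source of sampling noise.

Development time until settlement competency follows the fitted logarithmic
temperature response $y = -28.06 \ln x + 101.32$ days ($R^2 = 0.7545$),
exposed both pointwise (`development_time()`) and averaged over hourly
modeled temperatures at a site (`site_mean_development_time()`). The drifting
egg phase (1–2 days) is not modelled separately; the competency window is
measured from release. By default settlement competency is the fixed window
of days 27–33 after release; the site-specific $N \pm 3$-day variant can be
had by passing a different window to `settlement_grid_spec()`.

## Settlement scoring and connectivity

During the competency window each larva's hourly positions are binned onto a
0.015-degree grid (cells are half-open intervals; a position exactly on an
upper edge belongs to the next cell). The settlement weight of larva $\ell$
in cell $c$ is the fraction of the *whole* window spent in $c$ where water
depth is under 10 m — a larva spending half the window over one shallow cell
and a tenth over another scores 0.50 and 0.10 there, exactly. Weights of
larvae lost from the domain (or halted ashore) are zero; tracks shorter than
the window start are flagged immature. Per-larva weights sum to at most 1 and
cellwise sums are conserved, which the tests verify by brute-force recount.

Site-to-site transfer needs a mapping from grid cells to named sites. The
package uses circular catchments: cells whose centre lies within 0.03 degrees
(two cells) of the site and whose depth is under the threshold. The radius is
configurable and recorded with the output; overlapping catchments are
warned about. The connectivity entry is

$$ C_{ij} = 100 \times \frac{\sum_{\ell \in i} \sum_{c \in j} w_{\ell c}}
{\text{released}(i)} \, , $$

normalized by larvae released (the alternative, normalizing by settled
larvae, is a flag away since the matrix and release counts are both kept).
The diagonal is local retention. Donor/recipient degrees use a two-decimal
display threshold — a transfer that would print as 0.00 in a connectivity
table is not an edge — so degree counts can be reproduced from printed
matrices. Backward runs are scored with the same time-fraction operator over
the mirrored window (days 27–33 of backward time); rows are then settlement
sites and columns inferred sources.

Connectivity values are interpolated to a finer 0.01-degree surface by
ordinary kriging: an exponential variogram
$\gamma(h) = n + s(1 - e^{-h/r})$ fitted to the binned empirical
semivariogram by Cressie-weighted least squares, then the standard ordinary
kriging system per prediction point. With zero nugget the predictor is exact
at the sites; a singular system (duplicated sites, degenerate geometry) falls
back to inverse-distance weighting with a warning; a constant input field
short-circuits to a constant surface. No installed package provides
variogram-WLS ordinary kriging, so this component is implemented here.

## Inner vs. outer archipelago statistics

Sites are classified `inner` (fjord-basin sites, where land restricts access
to open water) or `outer`. For the five per-site responses — donated-to
degree, received-from degree, exported mass, imported mass, and retention as
a success/failure pair — `fit_group_comparison()` fits a GLM of the response
on the category with quasi-Poisson (log link) or quasi-binomial (logit link)
errors. The quasi families estimate dispersion by Pearson $\chi^2 / $df and
only inflate standard errors: point estimates equal the plain Poisson or
binomial fits, which the tests assert by refitting. Tests use residual
degrees of freedom ($n_\text{sites} - 2$), the standard quasi-GLM choice.
Results print as "estimate ± SE, t, p", and `tidy()`/`glance()` return the
usual tidier tables.

## What the synthetic generators emulate — and what they do not

`make_coastal_bathymetry()` builds a land-framed basin with islands, a
shallow coastal fringe (depth grows ~2.5 m per cell away from any coast,
capped at 60 m) and semi-enclosed fjords: a shallow rectangular basin buried
in the land frame, reached only through a narrow strait (default one cell
wide, five long). `make_flow_field()` derives the deterministic flow from a
streamfunction — a basin-scale counterclockwise gyre plus a
coastline-following jet decaying offshore with a 10-km e-folding — so its
discrete spherical divergence is zero by construction; optional
streamfunction noise adds divergence-free eddies. Fjord interiors are
sheltered (velocities scaled by 0.1) and their straits carry a prescribed
0.01 m/s net seaward residual representing estuarine exchange; without that
residual a quiescent strait acts as a pure diffusion trap and unrealistically
funnels passing larvae into the basin. The residual is prescribed directly,
the one place the flow is not streamfunction-derived. Temperature is a
seasonal sinusoid attenuated with depth and spatially uniform; it feeds only
development-time diagnostics.

What is deliberately absent: tides, wind and wave forcing, stratification,
river plumes and any feedback of hydrography on the flow; larval behaviour
(swimming, vertical migration), growth and mortality. Passing the package's
tests therefore demonstrates that the *method* recovers structure a known
circulation imposes — directional transport, isolation of enclosed basins —
not that any particular real coastline behaves this way.

For genetics, `simulate_genotypes()` draws ancestral allele frequencies from
Uniform(0.05, 0.95), drifts them into K populations under the
Balding–Nichols model (Beta with mean $p$ and variance $F p (1-p)$), and
samples diploid dosages binomially through ancestry-weighted frequencies.
The default lineage structure mirrors a north-European mussel setting — a
dominant local *M. edulis* lineage, a second *M. edulis* lineage, and the
divergent *M. trossulus* and *M. galloprovincialis* — with admixed
individuals, six technical replicate pairs, parent–offspring pairs, and
coverage profiles including low-coverage outliers. The drift defaults
F = (0.3, 0.3, 0.45, 0.45) come from an analytic constraint: under the
expected-IBS metric the distance of a technical replicate pair is half its
heterozygosity, $\approx 0.18(1-F)$, while unrelated within-population pairs
sit at $\approx 0.37(1-F)$. Keeping every $F$ inside (0.18, 0.59) therefore
places replicates below and everyone else above the 0.15 pruning threshold
with several standard errors to spare at 2000 loci; parent–offspring pairs
land near 0.19, intentionally on the "kept" side in the defaults. What the
generator does not emulate: sequencing reads, genotype likelihoods, linkage,
selection, or spatially continuous isolation-by-distance.

## Genomic filtering rules

* **Coverage**: discard individuals whose depth fraction (share of loci at
  depth >= 5 reads) is more than 3 population SDs below the mean, in a single
  pass with statistics computed once.
* **IBS distance**: default is the deterministic expectation
  $\overline{p_1(1-p_2) + p_2(1-p_1)}$ over co-called loci
  ($p = \text{dosage}/2$); a seeded sampled mode draws one allele per
  individual per locus, emulating single-read IBS sampling, and its mean
  provably matches the expectation (tested by Monte Carlo). Identical
  heterozygotes contribute 1/2 per locus, so even perfect replicates have
  nonzero expected distance.
* **Pruning**: single-linkage clusters cut strictly below 0.15 — implemented
  as union-find connected components of the sub-threshold pair graph, which
  is exactly the single-linkage cut (tested against `hclust`) — keep the
  highest-coverage member, ties broken by smallest id.
* **Locus filters**: keep loci called in at least half the individuals with
  minor allele count of at least 5 (so MAC 4 drops, MAC 5 stays); the filter
  is idempotent.
* **Lineage assignment**: an individual belongs to every admixture cluster
  with coefficient >= 0.25; the pure-target subset requires summed
  non-target ancestry below 0.25.

## The bundled gyre experiment

`run_gyre_experiment()` freezes the study conditions used by the package's
end-to-end tests: the default 2 x 2 degree domain at 0.015 degrees (133 x 133
cells), 28 sites — 27 spread evenly along the outer coast, one in the fjord
basin — 500 larvae per site over a 20-day release season split 75/25 (the
full three-month season at 500 larvae would violate the one-per-hour rule,
so the season is shortened rather than the rule relaxed), steady flow with
gyre 0.01 m/s and jet 0.015 m/s, $K_h = 5$ m²/s, hourly RK4 steps, 33-day
horizon. These sizes keep the experiment around a minute on one CPU.

The scaling that fixed the flow: coastal speeds span roughly 0.006–0.023 m/s,
so during the day 27–33 competency window larvae sit 0.12–0.65 degrees
downstream of their origin — reaching the site *two* positions downstream
(0.5 degrees) for essentially every origin, with spread from cross-shore
shear covering neighbours one and three. The testable signature of a
counterclockwise coastal jet is therefore: every separation-2 coastal pair
transfers strictly more downstream than upstream, no pair at any separation
is upstream-dominated, the fjord site retains far more than any open-coast
site (whose plumes have left the 0.03-degree catchment long before
competency), and the fjord receives from fewer sites than anyone else.
Adjacent-pair transfers can be legitimately zero — larvae are still
pre-competent while passing the nearest neighbour, the familiar hole at the
origin of a dispersal kernel.

```{r, eval = FALSE}
res <- run_gyre_experiment(seed = 1)
retention(res$cm)              # fjord site ~ 39%, open coast ~ 0
connectivity_degrees(res$cm)   # fjord: 0 donors
summarize_sites(res$cm, res$sites) |>
  fit_group_comparison("retention")
autoplot(res$cm)
```

## Numerical choices and degenerate inputs

* Half-open binning everywhere (`[edge, edge)`) so no position is ever in two
  cells; `findInterval()` does the binning, not floating-point division.
* RK4 stages that stray onto land or outside the domain fall back to the
  Euler stage for that substep; the step's end-point land handling then
  applies.
* Largest-remainder apportionment resolves quota ties in band order;
  round-half-up (not banker's rounding) fixes window counts.
* Variogram fitting optimizes log-parameters by Nelder-Mead with Cressie
  weights; fewer than three empirical lags collapses to a one-lag moment
  match; fewer than four sites is an error; zero-variance inputs return a
  constant surface without touching the solver.
* The kriging left-hand side uses $\gamma(0) = 0$ on the diagonal, so the
  zero-nugget predictor honours the data exactly; with a positive nugget it
  smooths, as it should.
* All generators take a seed and restore the caller's RNG state; identical
  configuration and seed give bitwise-identical output.
* Temperature is only defined for positive Celsius in the development model;
  non-positive temperatures are a domain error, not an extrapolation.

## Known limitations

The equirectangular metric and the barotropic, steady synthetic circulation
limit the package to idealized or desk-scale studies; plugging in a real
hindcast would need only a `flow_field` reader (the NetCDF layout is CF-ish
and documented) but no code changes to the tracker or scoring. Settlement
weights ignore substrate beyond the depth threshold. The IBS expectation on
called dosages is a declared approximation to read-sampled IBS; with
genotype dosages as input it is exact in expectation but ignores
genotype-calling error. Admixture coefficients are consumed, not estimated:
the package filters on coefficients from its own simulation truth or from an
external table, and does not reimplement admixture inference.
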