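# larvconnect

Desk-scale biophysical modelling of blue-mussel (*Mytilus* spp.) larval
dispersal and connectivity, with a companion population-genomics filtering
toolkit. Mussel beds exchange individuals only through pelagic larvae that
drift passively with coastal currents for about a month before becoming
competent to settle. `larvconnect` answers the transport questions that
frame such systems — which beds seed which, how much is locally retained,
and whether enclosed (inner-archipelago) beds are effectively isolated — on
fully synthetic coastal ocean fields with known structure, so every stage of
the analysis is reproducible and testable offline.

The pipeline:

1. **Synthetic environment** — `make_coastal_bathymetry()` (land frame,
   islands, semi-enclosed fjords, shallow fringe), `make_flow_field()`
   (streamfunction-derived counterclockwise gyre + coastal jet, seasonal
   temperature), `place_sites()`, `simulate_genotypes()`.
2. **Releases** — `schedule_releases()` encodes the spawning
   parameterization exactly: 3000 larvae/site split 75/25 across two seasonal
   windows with at least one release per hour, drift depths 40/40/20% in the
   0–10/10–20/20–30 m bands, mussel-bed depths 70% at 0.5 m. The
   temperature–development model is `y = -28.06 ln(x) + 101.32` days.
3. **Transport** — `advect()`: a minimal passive Lagrangian tracker (RK4,
   horizontal diffusion `sqrt(2 Kh dt)` per axis, reflective coastline),
   forward to find sinks or backward in reversed field time to find sources.
4. **Settlement & connectivity** — time-fraction scoring on a 0.015° grid:
   each larva's settlement weight in a cell is the fraction of the day-27–33
   competency window spent there over water shallower than 10 m (a larva
   spending 50% / 10% of the window in two shallow cells scores 0.50 / 0.10).
   `connectivity_matrix()` turns summed weights into site×site percentages of
   released larvae, with local retention on the diagonal and donor/recipient
   degrees under a two-decimal display threshold; `krige_surface()`
   interpolates site values to 0.01° by ordinary kriging (exponential
   variogram, WLS fit).
5. **Statistics** — `summarize_sites()` + `fit_group_comparison()`:
   inner-vs-outer archipelago contrasts by quasi-Poisson / quasi-binomial
   GLMs, reported as estimate ± SE with t and p on n − 2 df.
6. **Genomic filtering** — `coverage_filter()` (mean − 3 SD rule on the
   fraction of loci at depth ≥ 5), `ibs_distance()` (expected or sampled
   identity-by-state), `prune_relatives()` (single-linkage cut at IBS 0.15,
   one representative kept), `locus_filters()` (≥ 50% presence, minor allele
   count ≥ 5), `assign_lineages()` (admixture-coefficient threshold 0.25).

## Worked example

The bundled experiment puts 28 sites on the default 2°×2° domain (27 along
the open coast, one inside a fjord), releases 500 larvae per site over a
20-day season into a steady counterclockwise coastal circulation, and builds
the forward connectivity matrix (about a minute on one CPU):

```r
library(larvconnect)
res <- run_gyre_experiment(seed = 1)

round(sort(retention(res$cm), decreasing = TRUE)[1:4], 2)
#>     1     2     3     4
#> 38.69  0.00  0.00  0.00

head(connectivity_degrees(res$cm), 3)
#>   site_id n_donated_to n_received_from
#> 1       1            2               0
#> 2       2            1               2
#> 3       3            2               2

glance(res$cm)
#>   n_sites direction mean_retention_pct total_transfer_pct median_donors median_recipients
#> 1      28   forward               1.38               8.95             2                 2
```

Site 1 is the fjord site: it retains 38.7% of its larvae (every open-coast
site retains ~0%, their plumes having drifted 0.1–0.7° downstream before
competency) and receives larvae from no other site, while typical coastal
sites have 2 donors — the transport signature of an enclosed basin. Exports
run strictly downstream along the jet: for every pair of coastal sites two
steps apart in flow order, transfer with the current exceeds transfer against
it (the latter is zero everywhere).

The genetics side, on a simulated four-lineage dataset with planted technical
replicates, relatives and coverage outliers:

```r
g <- simulate_genotypes(seed = 1)
g
#> <genotype_dataset> 92 individuals x 2000 loci; 4 source populations; 6 technical replicate(s)

res <- filter_pipeline(g)
length(res$kept_individuals)   # 84 of 92: 2 coverage outliers, 6 replicates removed
length(res$kept_loci)          # 1833 of 2000 pass presence/MAC filters

sum(assign_lineages(g$true_admixture, target = "edulis_skagerrak")$pure_target)
#> 49   # individuals with < 0.25 non-Skagerrak ancestry
```

And the development model:

```r
development_time(c(10, 15, 20))
#> 36.70946 25.33211 17.25975   # days to settlement at 10/15/20 degrees C
```

See `vignettes/larval-connectivity.Rmd` for the model, its assumptions, the
design of the synthetic generators and the numerical choices.

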