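# commassembly

Community-assembly inference for multi-group soil metacommunities.

Amplicon surveys of soil biota routinely profile several taxonomic groups
(bacteria, fungi, protists, nematodes, invertebrates) over one landscape and
ask which assembly processes — dispersal, ecological drift, environmental
selection — structure each group, and which individual taxa are locally
adapted to a habitat type. `commassembly` implements the standard inference
chain for that question as tested, reusable R functions:

* **Sloan neutral community model** — fits the occurrence-frequency curve
  $\hat f(p) = 1 - I_{d}(Nm\,p,\ Nm(1-p))$ by bounded least squares,
  estimates the immigration parameter $Nm$, reports $R^2$, and partitions
  taxa against a 95% prediction band (above / neutral / below).
* **Modified Raup–Crick null deviation** — a presence-based, richness-
  preserving null with occurrence-frequency weighting; pair scores in
  $[-1, 1]$, with the mean classified into homogenizing dispersal
  ($\le -0.95$), drift, or environmental selection ($\ge 0.95$).
* **Levins' niche breadth** — $B_j = 1/\sum_i P_{ij}^2$ per taxon,
  community-level $B_{com}$ per sample, and a multinomial-redistribution
  randomization test labelling habitat specialists and generalists.
* **Distance–decay and Mantel tests** — Bray–Curtis / Jaccard matrices,
  haversine geographic and log-transformed environmental distances,
  seed-deterministic permutation tests, log-scale decay regressions.
* **Locally-adapted taxa** — the intersection of habitat specialists with
  taxa outside the neutral band, assigned to the ecosystem type (urban /
  suburban / forest) where their mean relative abundance peaks.
* **Synthetic metacommunity generator** — a seeded landscape (11 sites over
  ~27 km, 33 samples, 20,000 reads/sample) with Sloan sampling, zero-sum
  neutral drift, Gaussian niche filtering, and a five-group mixed scenario
  graded from dispersal- to selection-dominated, with a ground-truth record.
* **Pipeline driver** — `run_pipeline()` runs every stage per group from one
  configuration (YAML or list) with derived per-stage seeds, cached
  intermediates (`resume = TRUE`), and TSV/JSON reports.

See the methods vignette (`vignettes/community-assembly-methods.Rmd`) for
the models, their assumptions, and the calibration caveats.

## Worked example

Generate the five-group mixed scenario and analyse its dispersal-dominated
group:

```r
library(commassembly)

ms  <- mixed_scenario(scenario_config(regime = "mixed", n_taxa = 600,
                                      seed = 11))
tab <- ms$tables$bacteria_like

fit <- ncm_fit(occurrence_stats(tab))
fit
#> Sloan neutral model: Nm = 621.9 (m = 0.0311, N = 20000), R2 = 0.961, S = 33
#>   partition: below 3.7%, neutral 93.1%, above 3.2% of 432 taxa

raup_crick_matrix(tab, n_randomizations = 1000, seed = 1)
#> Raup-Crick null deviation: mean = -1.000 over 33 samples -> homogenizing dispersal
#>   pair fractions: dispersal 100.0%, drift 0.0%, selection 0.0%

nb <- classify_specialists(tab, n_randomizations = 999, seed = 2)
nb
#> niche breadth: 432 taxa; specialists 407, generalists 0 (alpha = 0.05, 999 randomizations)
#>   mean community breadth (Bcom) = 16.82

assign_ecosystem(intersect_filters(fit, nb), tab, ms$meta,
                 ncm = fit, niche = nb)
#> locally-adapted taxa: 30 (6.94% of the 432-taxon regional pool)
#>    urban suburban   forest
#>       13        5       12
```

Reading the numbers: this group was generated with $Nm = 556$ and no
selection, and the fit recovers a high $Nm$ (622) with $R^2 = 0.96$ and
~7% of taxa outside the band (near the nominal false-positive rate). The
Raup–Crick mean of $-1$ says every sample pair shares more taxa than the
randomized pool expects — the signature of a well-mixed, fully
dispersal-coupled region. The large specialist count illustrates the
documented caveat that the occupancy-randomization test reads
dispersal-limited aggregation as specialization; the neutral-band
intersection cuts those 407 candidates down to 30 locally-adapted taxa.
On the selection-dominated group of the same scenario the picture inverts:
$R^2$ drops below 0.5, the Raup–Crick mean rises toward 0, community niche
breadth narrows, and the intersection recovers >90% of the planted
habitat specialists.

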