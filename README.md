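# difcycle

Quantitative tools for the question of *when* the replication terminus
(*ter*) of a bacterial chromosome segregates relative to cell division —
the window that decides whether the septum-located translocase FtsK can
activate XerCD recombination at *dif*. The package is aimed at
microbiologists running dif-cassette plating assays and single-cell
fluorescence time-lapse/snapshot experiments on rod-shaped bacteria
(*E. coli*, *V. cholerae* and relatives).

Two analyses are implemented end to end:

* **Cassette-excision plating assays.** A *dif*-cassette interrupting
  *lacZ* is excised by XerCD once per event per lineage; blue/white colony
  counts before and after growth give the per-generation excision
  frequency

  `f = 1 − exp(ln(Rf / Ri) / n)`,  with  `n = ln(Nf / Ni) / ln 2`

  divisions, plus the *recA*-dependency `1 − f(recA−)/f(recA+)` — the
  fraction of excision attributable to homologous-recombination-generated
  chromosome dimers. Replicate tables, bootstrap confidence intervals and
  broom-style `tidy()`/`glance()` methods are included.

* **Single-cell choreography.** From movies consisting of a fluorescence
  channel (a labelled *ter*-proximal locus) and a bright-field defocus
  stack per frame: shape-image reconstruction, cell segmentation, lineage
  tracking with pole polarity, per-cell cycle-normalised kymographs
  (old pole → new pole, birth → division) compiled into population
  consensus images, septation-onset detection from mid-cell intensity
  dips, Laplacian-of-Gaussian focus detection, and septation-aligned
  focus-count statistics (1/2/3+ focus frequencies, median positions,
  mid-cell fractions, duplication rates in % per minute).

A stochastic simulator (`simulate_population()`, `render_movie()`,
`simulate_plating()`) generates growing, dividing cells with programmed
separation/constriction timing, renders realistic movies, and exposes the
full latent truth, so every analysis stage is validated by
simulation-recovery and oracle-equivalence tests.

## Worked example: an excision assay

```r
library(difcycle)

# three replicate platings of an E. coli LB culture
counts <- tibble::tibble(
  replicate = 1:3,
  Ni = 1e6, Nf = 1e6 * 2^19.3,          # cells/ml before and after
  colonies_total_f = 500,
  colonies_white_f = c(310, 320, 325))  # white = recombined

fit <- estimate_excision(counts)
fit
#> Cassette excision estimate (per_replicate aggregation)
#>   f = 0.0511 per generation (sd 0.0021, 3 replicates)
#>   n = 19.30 divisions
```

`f ≈ 0.05`: the cassette is excised in about 5% of cells per generation.
Against a ΔrecA control measured the same way:

```r
reca_dependency(f_plus = 0.0510, f_minus = 0.0113)
#> [1] 0.7784314
```

about 78% of excision in this condition requires RecA, i.e. chromosome
dimers.

## Worked example: simulated choreography

```r
cfg <- sim_config("Ec-slow")            # 92 min generation time, 4 min frames
pop <- simulate_population(cfg, duration = 2.3 * cfg$generation_time,
                           seed = 1, n_founders = 20)
pa  <- process_population(pop)          # render + segment + track + measure
cons <- consensus_image(pa$kymo_fluor)
estimate_split_time(cons)
#> [1] 0.82
```

Sister termini separate at ~80% of the cell cycle in this slow-growth
preset, coincident with constriction onset — the signature that
distinguishes slow from fast growth, where separation precedes
constriction by a third of a cycle. `autoplot(cons)` draws the consensus
image; `align_to_septation()` and `duplication_rate()` give the
septation-aligned statistics.

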