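# cargrammar

Decoding the combinatorial "grammar" of signaling motifs in CAR
costimulatory domains.

## The problem

Anti-CD19 chimeric antigen receptors (CARs) pair the CD3ζ chain with a
costimulatory domain whose short linear motifs recruit downstream signaling
proteins (PLCγ1, TRAFs, Grb2, GADS, SHP-1, Vav1, PI3K, Lck, Pellino). A
combinatorial library inserts 1–3 motifs from 13 parts (M1–M12 signaling
motifs plus the spacer M13) into slots i, j, k, giving
`13 + 13² + 13³ = 2379` candidate domains. An arrayed screen measures, per
construct, **cytotoxicity** (1 − Nalm 6 target-cell survival, scale 0–1)
and **stemness** (% IL7Rα⁺/KLRG1⁻ cells, scale 0–100).

`cargrammar` is for computational biologists and receptor engineers who
want to go from such a screen table to design rules:

* enumerate and one-hot encode the full combinatorial library;
* train an ensemble of 10 feed-forward neural-network regressors per
  phenotype (mean ± s.e.m. across members is the prediction);
* percentile-rank the predicted library — with
  percentile = (rank − ½)/N × 100 the mean is exactly 50, the built-in
  null — and summarise motif, motif-pair (12 × 12), and position (motif ×
  slot) effects as mean percentiles;
* rank pairs jointly by the sum of their cytotoxicity and stemness mean
  percentiles;
* query designs in silico: select 4-1BB-like (TRAF-only) or CD28-like
  (PI3K/Grb2/Lck-class) subsets and predict the effect of appending a
  motif at the C-terminus;
* simulate arrayed screens from planted ground truth (additive +
  positional + pairwise effects with Gaussian noise) and score how well
  the whole pipeline recovers what was planted.

## Worked example

```r
library(cargrammar)

lib     <- motif_library()            # 13 parts x 3 slots
domains <- enumerate_domains(lib)
nrow(domains)
#> [1] 2379

# a synthetic arrayed screen standing in for measured data
screen  <- generate_screen(ground_truth_regime("default"), domains,
                           n_records = 246, seed = 1, library = lib)
records <- average_replicates(normalize_phenotypes(screen))
split   <- split_screen(records, n_test = 25, seed = 1)

fit <- train_ensemble(split$train, "cytotoxicity", lib, master_seed = 1)
fit
#> <car_ensemble> 10-member cytotoxicity ensemble trained on 221 records (seed 1)
evaluate_ensemble(fit, split$test)
#> # A tibble: 1 × 4
#>   phenotype        n   rmse r_squared
#>   <chr>        <int>  <dbl>     <dbl>
#> 1 cytotoxicity    25 0.0926     0.422

# refit on all records, predict the full library, rank, and read the grammar
refit  <- train_ensemble(records, "cytotoxicity", lib, master_seed = 1)
ranked <- percentile_rank(predict(refit, domains))
motif_enrichment(ranked, lib) |> dplyr::arrange(dplyr::desc(mean_percentile))
#> # A tibble: 3 × 4   (top rows)
#>   motif mean_percentile n_domains   sem
#>   <chr>           <dbl>     <int> <dbl>
#> 1 M9               73.5       495 0.471
#> 2 M10              66.9       495 0.510
#> 3 M11              63.8       495 0.486
```

The test RMSE (0.093) sits just above the screen's measurement noise
(σ = 0.08): the ensemble explains the motif-driven signal without beating
irreducible noise. The enrichment table reads as design rules: domains
containing the TRAF-recruiting motifs M9/M10/M11 concentrate in the top of
the ranked library (mean percentile ≫ 50), while the SHP-1 motif M6 (mean
percentile 22.7) marks inhibitory designs.

`run_pipeline(pipeline_config(...))` chains every stage (load/simulate →
normalize → split → train → evaluate → predict library → enrichment →
design rules) and writes TSV/JSON artifacts plus a manifest; reruns with
the same config and master seed are byte-identical.

## Package layout

* `R/` — library enumeration/encoding, screen-table IO, the ensemble
  regressor, distribution analyses, design-rule queries, synthetic-screen
  generator, pipeline orchestration, plots.
* `inst/extdata/motif_parts_synthetic.tsv` — the parts fixture (binder
  classes; placeholder entries are labelled synthetic and overridable).
* `vignettes/motif-grammar-methods.Rmd` — models, assumptions, parameter
  choices, and limitations.
* `tests/testthat/` — unit, property, and end-to-end acceptance tests,
  including brute-force oracles for every enrichment statistic.
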