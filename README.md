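# soluq

Quality-oriented curation and consensus modelling of multi-source
aqueous solubility (LogS) data.

Public solubility collections merge sources whose internal errors range
from replicate-grade (~0.2 LogS) to worse than half a log unit. Because
a model's *observed* error on a test set with internal error ε is
floored at ε (a perfect model scores ε; a model of actual RMSE *a*
scores √(a² + ε²)), both which source you test on and which sources you
train on matter as much as the learning algorithm. `soluq` is for
cheminformaticians building solubility predictors from such
multi-source tables. It provides:

* **Quality estimation** — per-source pooled standard deviation of
  multi-lab measurements. Compounds are matched across sources by
  InChIKey; values within 0.01 LogS collapse as duplicates
  (single-linkage); for source *s*, each multi-lab group contributes
  *s*'s distinct values with deviations about the group consensus mean:

  SD_s = sqrt( Σ_g Σ_{v∈s,g} (v − v̄_g)² / Σ_g m_{s,g}(n_g−1)/n_g ),
  N(SD)_s = Σ_g m_{s,g}

* **Misprint detection** — advisory flags for values deviating ≥ 1 LogS
  from their group's (peeled, leave-one-out) median, with decade-shift
  and sign-flip annotations.
* **Quality-driven selection** — the lowest-SD source of sufficient size
  becomes the test set; sources above an SD cutoff are excluded; the
  rest merge into a leakage-free training table with reliability-ranked
  disagreement resolution.
* **A consensus regressor** — ANN + random forest + gradient boosting
  over LASSO- or correlation-selected 2D descriptors (123-descriptor
  RDKit-backed manifest), predicting LogS with a per-compound
  uncertainty (the member SD).
* **Diagnostics** — k-NN chemical-space coverage of the test set,
  two-sample KS compatibility of LogS distributions, seeded t-SNE maps.
* **A synthetic generator** — multi-source universes with known noise
  SDs, overlaps, duplicates and misprints, so the whole pipeline is
  testable without downloading anything.

## Worked example

Simulate a four-source study (noise SDs 0.7 / 0.4 / 0.3 / 0.25, half
coverage each), assess quality, select by it, and train the consensus:

```r
library(soluq)

cfg     <- synth_config(n_compounds = 800, seed = 42)
u       <- generate_universe(cfg)
sources <- sample_sources(u)

tab <- quality_table(sources)
tab[, c("source_id", "size", "n_sd", "sd")]
#>   source_id size n_sd    sd
#> 1        S1  398  343 0.605
#> 2        S2  404  343 0.452
#> 3        S3  394  341 0.377
#> 4        S4  400  347 0.370
#> 5       All  757 1363 0.461
```

The estimated SDs recover the true noise ordering (0.7 > 0.4 > 0.3 >
0.25). Selection picks the best source as the test set and drops the
worst from training:

```r
per      <- tab[tab$source_id != "All", ]
test_src <- select_test_set(per, size_floor = 200)   # "S4" (sd 0.370)
plan     <- exclude_low_quality(per[per$source_id != test_src, ],
                                sd_cutoff = 0.5)     # excludes S1
test_keys <- unique(sources[[test_src]]$inchikey)
tt <- build_training_table(sources[plan$retained], per,
                           test_keys = test_keys)
nrow(tt)                        #> 303 compounds, 295 excluded for leakage

m <- train_consensus(u$descriptors[match(tt$inchikey, u$keys), ],
                     tt$logs, consensus_config_light(), seed = 1)
m
#> Consensus solubility model (ANN + RF + XGB)
#>   20 features, 303 training compounds, seed 1
#>   in-sample RMSE (LogS): ann 0.263, rf 0.450, xgb 0.215, consensus 0.214
```

Predictions carry a per-compound uncertainty — the SD of the three
member predictions — which tracks where the members disagree:

```r
p <- predict(m, u$descriptors[match(test_keys, u$keys), ])
round(head(p, 3), 3)
#>     mean uncertainty    ann     rf    xgb
#> 1 -1.769       0.569 -2.154 -2.037 -1.116
#> 2 -4.032       0.340 -4.124 -4.316 -3.655
#> 3 -4.276       0.540 -4.206 -3.774 -4.848
```

Evaluating the consensus against the test source's observed values
gives `MAE 0.529  RMSE 0.727  R2 0.894` — remember the test labels
themselves carry ~0.37 LogS of internal error, which floors what any
model can show here.

A command-line front end (`inst/cli/soluq`) wraps the same functions:
`assess-quality`, `select`, `featurize`, `train`, `cross-validate`,
`predict`, `simulate`, `diagnose`, `run-experiment`.

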