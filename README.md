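# mtperm

Curation, leakage-aware splitting and masked multitask modeling of
permeability and efflux assay data.

## What this is for

Intestinal-permeability programs measure compounds in several related
cell-monolayer assays: Caco-2 apparent permeability (P_app, in
1e-6 cm/s), and efflux ratios (ER = P_app(b-a) / P_app(a-b)) in Caco-2,
MDCK-MDR1 and NIH MDCK-MDR1 cells. The resulting tables are sparse —
most compounds have data for a single endpoint — noisy in a
value-dependent way, and accumulate over years, with whole assays
appearing mid-timeline. `mtperm` is for modelers who want to train one
multitask regressor across such endpoints and, more importantly, to
*validate it honestly*: quantifying exactly when a test compound's other
endpoints were allowed into training (leaky vs all-for-one temporal
splits), keeping scaffolds disjoint, and measuring what multitask
cross-learning actually buys over single-task baselines.

The package implements:

* **Curation** — structure standardization (canonical, neutralized,
  salt-stripped SMILES), `<`/`>` qualifier parsing, log10 transform,
  replicate aggregation, and a heteroscedastic outlier filter: per
  endpoint, replicate SD is regressed on the mean log value
  (`sigma_hat(m) = a + b*m`, floored), and a record is removed when its
  observed SD exceeds `k * sigma_hat` (default `k = 2`). Output is a
  compounds x 4 `multitask_table` with an observation mask, in the fixed
  column order `Caco2ER, Caco2Papp, MDCKER, NIHMDCKER`.
* **Splitting** — stratified-random repeated holdout, scaffold-balanced
  (Bemis-Murcko groups assigned whole, zero scaffold overlap), leaky and
  all-for-one temporal rounds over a 16/32/48/64/80% training schedule,
  modality-grouped and plain k-fold CV — plus `leakage_report()`, which
  tabulates per endpoint and round the test-set percentage and the
  fraction of test compounds whose SMILES appears anywhere in training.
* **Modeling** — a masked-loss multitask feed-forward regressor over
  pluggable molecular features (1024-bit atom-pair fingerprints by
  default), with per-task target standardization, early stopping, a
  shared-plus-task-specific output head that gives well-defined
  zero-shot predictions for endpoints without training data, and
  optional descriptor augmentation (physchem proxies, or proxies plus
  eight structural descriptors). A 500-tree random-forest single-task
  baseline and permutation-importance descriptor ranking round out the
  comparison; `benchmark()` runs models x split plans and reports
  RMSE mean +/- SD per endpoint.
* **Synthetic data** — `generate(generator_config(...))` produces raw
  measurement tables with the structure all of the above is tested on:
  57/37/5/1% endpoint coverage, correlated endpoint truths derived from
  each molecule's own descriptors, permeability noise that grows at low
  values, a late-starting NIH MDCK assay, censored readings and mixed
  modalities, from a packaged fragment grammar (no downloads).

## Worked example

```r
library(mtperm)

ds <- generate(generator_config(n_compounds = 500, seed = 7))
cur <- curate(ds$measurements, sigma_k = 2)
print(cur)
#> curation_result: 1213 accepted measurements -> 740 records (15 outliers removed, 0 raw rows rejected)
#> multitask_table: 492 compounds x 4 endpoints, 740 observed cells
#>   per endpoint: Caco2ER=258, Caco2Papp=268, MDCKER=124, NIHMDCKER=90

round(100 * coverage_summary(cur$table), 1)
#>    1    2    3    4
#> 57.5 35.8  5.5  1.2
```

1213 raw measurements collapse to 740 (compound, endpoint) records; 15
replicate groups whose SD exceeded twice the predicted noise at their
mean were removed, and the endpoint-count mix reproduces the intended
sparsity pattern. Now the temporal view, which is where multitask
validation gets interesting:

```r
recs <- transform(as.data.frame(cur$table), date = earliest_date)
plan <- temporal_rounds(recs, n_rounds = 5, mode = "leaky")
subset(leakage_report(plan, cur$table), endpoint == "NIHMDCKER")
#>     endpoint round  test_pct train_overlap_pct n_test
#>  NIHMDCKER     1 100.00000          24.44444     90
#>  NIHMDCKER     2 100.00000          38.88889     90
#>  NIHMDCKER     3  96.66667          49.42529     87
#>  NIHMDCKER     4  66.66667          51.66667     60
#>  NIHMDCKER     5  34.44444          61.29032     31
```

The late-starting assay sits at (nearly) 100% test occupancy in the
early rounds — the model has no training rows for it — while up to 61%
of its test compounds train on *other* endpoints: exactly the leaky
cross-learning regime. Switching to `mode = "all_for_one"` drives every
`train_overlap_pct` to exactly 0. Fitting and comparing models on any
plan is then:

```r
fc <- benchmark_features(rownames(cur$table$mask), c("rf", "mtl"))
res <- benchmark(cur$table, plan, models = c("rf", "mtl"), seed = 1,
                 feature_cache = fc)
summarize_benchmark(res)
```

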