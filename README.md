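# fiemspipe

An R package for untargeted metabolomics analysis of **flow-infusion
electrospray ionisation mass spectrometry (FIE-MS)** fingerprints collected
across ordered process stages — the design used to follow tea manufacture
(picking → withering → fixation/rolling → oxidation → roasting), where
enzymatic oxidation of catechins and related polyphenols reshapes the leaf
metabolome stage by stage.

It is written for analysts who have per-sample centroided mzML files (or an
already-binned intensity matrix), a sample table with stage/arm/replicate
structure and extraction weights, and local compound/knowledge-graph
snapshots, and who want a reproducible, seeded path from raw scans to
stage-discriminatory features, trend clusters, and pathway/class enrichment.

## What it computes

| Step | Method |
|---|---|
| Spectral binning | 0.01 Da half-up bins per polarity; feature value = mean over plateau scans (TIC ≥ 50% of max) of per-scan sums; intensity-weighted accurate m/z kept per bin |
| Filtering | within-class occupancy ≥ 2/3; pooled-QC RSD ≤ 0.5 |
| Normalisation | intensities scaled to the sample of lowest dry-mass equivalent, `extract_weight × (1 − moisture)` |
| Stage model | random-forest regression on the ordinal stage index; OOB `R² = 1 − MSE/Var(y)`; permutation p for the model and per-feature %IncMSE, `p = (1 + #{null ≥ obs})/(B + 1)` |
| Trend clustering | k-means (k-means++ init, best of 25 restarts) on percentage relative abundance profiles; silhouette + WCSS diagnostics for k |
| Formula assignment | adduct-rule inversion (`ion m/z = (nM + Δ)/z`) at 3 ppm with RDBE-filtered CHNOPS enumeration; tiered compound matching; ≥66% consensus taxonomy classification |
| Functional enrichment | personalized PageRank (d = 0.85) from matched compounds over a compound–reaction–enzyme–module–pathway graph; empirical p-scores from 1000 resampled seed sets |
| Structural enrichment | one-sided Fisher's exact test per consensus class, BH-adjusted |
| Arm comparison | Welch's t-test per feature between 4 h and overnight oxidation arms, BH-FDR, direction-split enrichment |

A seeded synthetic-data module (`simulate_dataset()` and friends) generates
complete datasets — design, feature matrix with planted trend clusters,
centroided spectra, compound library, knowledge graph with a planted
pathway — with full ground truth, and is the basis of the validation suite.

## Worked example

A green-tea style run on a synthetic dataset with 300 features, of which 30
carry planted stage trends in 3 clusters, and a knowledge graph whose
planted pathway is wired to the compounds behind those features:

```r
library(fiemspipe)

cfg <- sim_config(seed = 42, n_features = 300, n_informative = 30,
                  n_trend_clusters = 3, noise_sigma = 0.05,
                  n_compounds = 60, n_pathways = 5)
ds <- simulate_dataset(cfg)

pc <- pipeline_config(ds, stages = green_stages(), k = 3,
                      rf = rf_config(n_trees = 200, n_trees_perm = 200,
                                     n_permutations = 100, seed = 42),
                      enrich = enrichment_config(n_null = 1000, seed = 42),
                      seed = 42)
report <- run_green(pc)
print(report)
#> fiemspipe run report
#>   features_binned: 300
#>   features_after_occupancy: 300
#>   features_after_qc: 300
#>   features_selected: 51

sel <- report$arms[[1]]$selection
sprintf("model OOB R2 = %.3f (permutation p = %.4f)", sel$r2, sel$model_p)
#> "model OOB R2 = 0.849 (permutation p = 0.0099)"

fe <- report$arms[[1]]$functional
fe[fe$type == "pathway", c("cluster", "node", "label", "p_score")]
#>   cluster   node       label    p_score
#> 1       1 PTH001 pathway 001 0.04095904
```

Reading the output: the stage-regression forest explains 84.9% of the
out-of-bag variance in the stage index and is significant at the smallest
p attainable with 100 permutations (1/101 ≈ 0.0099); 51 features pass the
per-feature permutation test at α = 0.05 (mostly the 30 planted ones);
and diffusion enrichment of the largest trend cluster ranks the planted
pathway `PTH001` as significant (empirical p-score 0.041). The class
frequency table and Sankey flow input come from
`class_frequency_table(report$assignments)` and
`summarise_classes(report$assignments)`.

A black-tea style run (`run_black()` with `sim_config_black()`) adds the
4 h / overnight oxidation arms and Welch/BH differential reports per
branched stage, split by direction of change.

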