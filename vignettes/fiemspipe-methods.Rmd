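---
title: "Methods: untargeted FIE-MS fingerprint analysis of tea processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: untargeted FIE-MS fingerprint analysis of tea processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiemspipe)
```

## The analysis

`fiemspipe` analyses flow-infusion electrospray ionisation mass spectrometry
(FIE-MS) fingerprints collected across the ordered stages of tea manufacture
(picking, withering, fixation/rolling, oxidation, roasting). FIE-MS acquires
both ionisation polarities in a single run without chromatographic
separation, so a sample is characterised by a metabolite fingerprint: the
set of centroided m/z peaks accumulated over the infusion profile. The
pipeline turns raw per-sample scans into statements about which m/z features
track the manufacturing process, how those features group into temporal
trends, and which metabolic pathways and structural chemical classes those
trends implicate.

The stages are, in order:

1. **Spectral binning** — centroided scans are aggregated into fixed-width
   m/z bins to give features comparable across samples.
2. **Normalisation and filtering** — intensities are adjusted for the amount
   of material extracted; unreliable features are removed by occupancy and
   pooled-QC filters.
3. **Feature selection** — random-forest regression of the ordered stage
   index on all features, with permutation tests for the model and for each
   feature's importance.
4. **Trend clustering** — k-means on the percentage relative abundance
   profiles of the selected features.
5. **Molecular formula assignment** — adduct-rule inversion of bin m/z to
   candidate neutral formulas, compound matching with tiered database
   fallback, and consensus structural classification.
6. **Enrichment** — personalized-PageRank diffusion on a compound knowledge
   graph (functional) and one-sided Fisher tests on consensus classes
   (structural).
7. **Differential analysis** — Welch's t-tests with Benjamini–Hochberg FDR
   between process arms (4 h versus overnight oxidation) at the branched
   stages.

Because the raw study data are not publicly deposited, the package ships a
first-class synthetic-data module that generates complete datasets with
known ground truth; every stage of the pipeline is validated against that
truth.

## Spectral binning

Flow infusion produces a total-ion-current (TIC) profile that ramps up to a
plateau and decays. Quantification averages the plateau: the default scan
window is the contiguous block of scans around the TIC maximum whose TIC is
at least 50% of that maximum; a fixed window can be supplied instead. Within
the window, each peak's m/z is rounded **half-up** to the bin precision
(0.01 Da by default, the established convention for FIE-MS binning at
high-resolution acquisition), intensities landing in the same bin within a
scan are summed, and the feature value is the mean of those per-scan sums
across retained scans. Averaging (rather than summing) across scans makes
the value independent of the window length. Peaks outside the acquisition
window (m/z 55–1200 by default) are dropped. Features are tagged `p`/`n` by
polarity so both modes coexist in one matrix.

Two filters follow. The **occupancy filter** keeps a feature only if it is
detected (intensity > 0) in at least a fraction `threshold` (default 2/3 —
two of three replicates) of the samples of at least one sample class. The
**QC filter** uses pooled-QC injections: features with a relative standard
deviation above 0.5 across QC injections, or with QC occupancy below the
threshold, are removed. The thresholds are declared package defaults, not
values inferred from any particular study; both are configurable and are
recorded in the matrix provenance.

## Normalisation and trend profiles

Samples collected at different stages differ in moisture and in the amount
of material extracted. Moisture is measured once per sample type as
`(fresh − dry) / fresh` from a weighed, freeze-dried replicate and
propagated to that type's replicates. Each sample's **dry-mass equivalent**
is `extract_weight × (1 − moisture)`; intensities are scaled by
`min(d) / d_i`, so every sample is referred to the sample of lowest
(moisture-corrected) weight. We interpret "lowest weight" as lowest
dry-mass equivalent because the correction is explicitly for both weight
*and* moisture; a plain extract-weight mode is available via
`mode = "raw-weight"`.

Trend displays and clustering operate on **percentage relative abundance**
profiles: per-feature stage means (arithmetic mean over replicates, QCs
excluded) rescaled to sum to 100 across stages. The percentage is taken
over stages, not samples; this makes profiles of features with very
different absolute intensities directly comparable and is invariant to any
per-feature rescaling.

## Random-forest stage selection

Stages are encoded as equally spaced ordinal integers (0, 1, 2, …) in
temporal order; for branched designs an arm filter keeps the shared early
stages plus one arm's branched stages. A regression forest (`ranger`,
`mtry = ⌊p/3⌋`, seeded, single-threaded for reproducibility) yields the
out-of-bag R² `1 − OOB-MSE / Var(y)` and per-feature permutation
importances expressed as %IncMSE, the percentage increase in OOB MSE when
the feature's values are permuted.

Significance is assessed by permuting the response: `n_permutations` refits
on shuffled stage labels give null distributions for the model R² and for
every feature's importance, and add-one p-values
`p = (1 + #{null ≥ observed}) / (B + 1)` (so p is never 0). Two choices
matter here:

- Importances are compared on the **%IncMSE scale** — each fit's raw
  permutation importance divided by that fit's own OOB MSE. Under a global
  null this is a per-fit monotone transform, so observed and null values
  remain exchangeable and the selection is calibrated (the type-I fraction
  at `alpha = 0.05` with B = 100 is 5/101 ≈ 0.0495 by construction; the
  test suite verifies this empirically over 200 seeded null datasets).
- The observed importances used in the permutation comparison come from a
  forest with the **same tree count** as the null refits
  (`n_trees_perm`, default 200); the headline model fit may use more trees
  (`n_trees`, default 1000). Comparing importances estimated at different
  tree counts would break exchangeability.

A known limitation, quantified during development: strongly correlated
informative features (members of one trend cluster) partially mask each
other's permutation importance — the forest concentrates on whichever
sibling fits the sample best. Recovery of planted features is essentially
complete when adjacent stages are separated by about 3 noise standard
deviations, but drops towards 50% when the whole trend spans only 3σ.

## Trend clustering

k-means (Lloyd's algorithm with k-means++ seeding, best of `n_init = 25`
restarts by within-cluster sum of squares) is run on the percentage
profiles with plain Euclidean distance — the profiles already share a
0–100 scale, so no z-scoring is applied by default. Cluster labels are
canonicalised by descending cluster size for stable reporting. `select_k()`
tabulates the mean silhouette coefficient and WCSS over a k range and
recommends the silhouette argmax; the final k remains an analyst choice
(larger studies conventionally use k = 15), balancing silhouette, the WCSS
elbow, and interpretability of the resulting trends.

## Molecular formula assignment

Adduct rules are data, not code: each rule is a mass transform
`ion m/z = (n·M + Δ) / z` plus applicability conditions. The default set
covers the common positive products ([M+H]+, [M+Na]+, [M+K]+, [M+NH4]+,
[2M+H]+, water loss, ammonia loss) and negative products ([M−H]−, [M+Cl]−,
[M+HCOO]−, [2M−H]−); a TSV loader makes the set extensible. A rule is
rejected when the formula lacks a required element (a nitrogen-free
molecule cannot lose ammonia) or when it needs a mobile-phase ion (NH4+,
formate) that the declared context does not supply. The proton mass
1.007276 Da handles charge bookkeeping.

For a feature, each polarity-matching rule is inverted to a neutral mass
and candidate CHNOPS formulas are enumerated within the ppm tolerance
(default 3 ppm, the centre of the instrument's 3 (±1) ppm accuracy;
presets 2 and 4 give strict/loose variants). Enumeration prunes with
ring-plus-double-bond equivalents: RDBE ≥ 0 and integer-valued, as required
for an even-electron neutral species. Candidates are ranked by absolute ppm
error.

Compound matching uses a local two-tier snapshot: primary-tier matches
(curated pathway database) are returned when any exist, otherwise
fallback-tier matches (broader structure database). The candidate used for
classification is the best-supported one — primary-tier matches beat
fallback-tier, then smaller |ppm| wins. **Consensus classification**
descends the chemical taxonomy level by level, keeping the modal label among
surviving paths iff its frequency over *all* matched compounds reaches 66%;
ties for the modal label stop the descent (we prefer no class claim to an
arbitrary one). Each feature is assigned independently; correlation-based
adduct/isotope grouping across features is a deliberate simplification and
out of scope.

## Enrichment

**Functional enrichment** diffuses from the matched compound nodes of a
feature set over a typed compound–reaction–enzyme–module–pathway graph by
personalized PageRank: the fixed point of `s = (1−d)·r + d·Wᵀs` with
damping `d = 0.85`, restart vector uniform over the seed compounds, and
row-normalised adjacency; mass on degree-0 nodes is redistributed to the
restart vector. Significance is an empirical p-score: the observed score of
each node is compared with `n_null = 1000` runs seeded on uniformly
resampled compound sets of the same size, with the add-one tail formula, so
the smallest attainable p-score is 1/1001. Pathway and module nodes at or
below the threshold are reported, unadjusted — the convention of
diffusion-based enrichment tools, since the per-node nulls are not
independent. A normal-approximation null is deliberately not provided.

**Structural enrichment** tests each consensus-class label at a chosen
taxonomy level with a one-sided Fisher's exact test (hypergeometric upper
tail) of cluster membership against the background, BH-adjusted across the
labels of the run. Features whose consensus does not reach the level are
excluded from both margins.

## Differential analysis between arms

At each branched stage, every feature is tested with Welch's
unequal-variance t-test (two-sided; the Welch–Satterthwaite degrees of
freedom) between the two arms, and p-values are BH-adjusted across
features. Significant features are partitioned into increased/decreased by
the sign of the mean difference, and each direction set is passed to
functional and structural enrichment. Degenerate inputs follow fixed
conventions: two constant equal groups give p = 1; constant groups with
unequal means are an error (the statistic is undefined).

## The synthetic-data module

The generators emulate the study design so that every downstream stage has
ground truth:

- **Design**: 6 ordered stages (green template) or 7 stages with 4 h /
  overnight arms branching at oxidation and roasting (black template),
  3 replicates per stage, plus pooled-QC injections. Fresh weights around
  1 g, moisture following each stage's physical target (90/85/70/60%
  withering levels, near-dry roasting), extract weights around the 50 mg
  milling target.
- **Feature matrix**: log-normal intensities (multiplicative noise is the
  simplest model preserving positivity and the heteroscedasticity of MS
  intensities). Informative features add a per-stage trend template on the
  log scale; templates are canonical shapes (monotone up/down, mid peak,
  mid valley, late rise, early fall). The default amplitude separates
  adjacent stages by 3 noise standard deviations. Every sample is
  multiplied by its dry-mass equivalent relative to the smallest sample,
  emulating raw extracts of differing material amounts — weight
  normalisation removes this factor exactly. Ground-truth templates are
  stored as percentage profiles, which the zero-noise limit reproduces
  exactly.
- **Spectra**: per sample and polarity, 10 centroided scans follow a
  flow-infusion TIC profile whose ramps sit below the 50% window threshold
  and whose plateau is exactly flat, so re-binning reproduces the matrix
  exactly when mass jitter is off. Peak m/z is jittered per scan as
  `mz·(1+ε)`, `ε ~ N(0, ppm·10⁻⁶)`; features whose true m/z sits within
  4σ of a bin boundary are reported in a warning, since at 0.01 Da bins a
  3 ppm jitter inevitably crosses boundaries above roughly m/z 800.
- **Compound library and knowledge graph**: compounds carry plausible CHNO
  formulas, two database tiers and taxonomy paths from a small synthetic
  chemical ontology; some formulas are shared by several compounds
  (including one trio agreeing only to depth 2) to exercise consensus
  logic. The layered graph wires one planted pathway to the planted
  compound set — the compounds whose formulas are carried by informative
  features — so diffusion from a recovered cluster should rank it first.

What the generators do **not** emulate: chromatographic separation, isotope
envelopes, in-source fragmentation, adduct correlation structure between
features, batch/drift effects beyond the pooled QC, and realistic KEGG-scale
graph topology. Passing tests therefore demonstrate the correctness and
calibration of the algorithms under the stated statistical model, not
instrument-level fidelity.

## Numerical choices and degenerate inputs

- Bin rounding is half-up (not banker's rounding) for platform-stable bin
  edges.
- Permutation p-values use the add-one formula and can never be 0; with
  B = 100 the floor is 1/101, with B = 3000 it is 1/3001.
- PageRank iterates to `max|Δs| < 1e-10` (cap 1000 iterations); scores sum
  to 1 within 1e-8 and match a dense linear solve on small graphs.
- k-means restarts draw k-means++ centres per restart; duplicate initial
  centres are jittered apart by 1e-8. Singleton clusters score silhouette 0;
  an all-singleton clustering is an error.
- All-zero feature profiles cannot be converted to percentages and raise an
  error rather than returning NaN.
- Every stochastic step (generators, forests, permutations, null seed sets,
  k-means restarts) takes an explicit integer seed; sub-streams are derived
  with a fixed linear hash so results are byte-identical across reruns.

## Problem sizes used in validation

The shipped test-suite and acceptance script run at desk scale, chosen as
the smallest sizes at which the statistical claims are meaningful rather
than as emulations of the full study: 60–500 features, 6–7 stages × 3
replicates, 100 permutations (calibration checked over 200 seeded null
datasets of 500 features), 1000 null seed sets for p-scores, forests of
50–1000 trees. The same code paths scale to study-sized inputs (thousands
of bins, 3000 permutations, k = 15) by changing configuration values only.

## Known limitations

- Per-feature permutation p-values inherit the masking behaviour of
  permutation importance for strongly correlated features (quantified
  above); group-aware importance is future work.
- The empirical p-score null (resampled same-size compound seed sets) is a
  documented stand-in for the null of whichever diffusion tool a user may
  compare against; p-scores are tool-relative quantities.
- Consensus classification depends entirely on the quality and coverage of
  the local compound snapshot; features are assigned independently of one
  another.
- The occupancy and QC-RSD defaults (2/3, 0.5) are package conventions to
  be revisited per study.
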