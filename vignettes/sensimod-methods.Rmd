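---
title: "Models and methods behind sensimod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sensimod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensimod)
```

sensimod implements two linked analyses of receptor-tyrosine-kinase
signaling in cultured hemocyte-like cells: a *sensitized* (differential)
RNAi modifier screen, and six-state TMT phosphoproteomics with differential
set classification. This vignette describes the statistical models, the
tunable parameters and their defaults, what the synthetic-data generators
emulate, and the numerical choices made where the design was open.

## The sensitized screen model

Each 384-well plate is read under two backgrounds — receptor knockdown
("sensitized", Pvr RNAi) and a neutral control (GFP RNAi) — in duplicate.
Every well's luminescence (ATP content, a cell-number proxy) is
standardized against the control wells of its own plate, condition and
replicate:

$$z = \frac{\chi - \mu}{\sigma},$$

with $\mu$ and $\sigma$ the mean and *sample* ($n-1$) standard deviation of
the control wells. Scoring per plate × condition × replicate removes plate
and run effects; the sample SD is used because control sets are small
(dozens of wells). By construction the control wells of every plate have z
mean exactly 0 and SD exactly 1, which `plate_zscores()` is tested against.

The differential score is $Z_{diff} = Z_{sens} - Z_{ctrl}$. Replicates are
merged by averaging $Z$ per background and re-differencing; with equal
replicate counts this equals averaging per-replicate $Z_{diff}$.

### Hit calling and the three signature classes

Amplicons with merged $Z_{diff} \ge 2$ or $\le -2$ (inclusive) are primary
hits. Hits fall into three signature classes:

* **Enhancer** — $Z_{diff} \le -2$: worsens the sensitized phenotype.
* **Upstream** — $Z_{diff} \ge 2$ and $Z_{ctrl} \le -2$: kills control
  cells but barely affects the already-silenced background, the behavior
  expected of genes required to produce or activate the receptor itself.
* **Suppressor** — the remaining positive hits: rescue specifically under
  receptor loss.

The original analysis separated these classes by hierarchical clustering of
$(Z_{sens}, Z_{ctrl}, Z_{diff})$ with centered-correlation distance and
complete linkage; the numeric boundary it induced between Suppressor and
Upstream is not recoverable, so the rule above (control floor $-2$, a
tunable in `screen_thresholds()`) is our declared approximation, and the
clustering path ships alongside (`cluster_signatures()`) with clusters
mapped to classes through their centroids.

A caution on the clustering path: the three scores are linearly dependent
($Z_{diff} = Z_{sens} - Z_{ctrl}$), so after centering, every signature
lies on a circle, where the Suppressor and Upstream prototypes are only
about 30° apart and Enhancer is antipodal. With strong, well-separated
signature groups the flat 3-cut reproduces the rules essentially exactly
(this is tested); when weak borderline hits are included, their angular
noise bridges the 30° gap and complete linkage can merge
Suppressor/Upstream clouds. The rule-based path is therefore the default
throughout the pipeline.

### Gene-level verification and error rates

Verification amplicons are pooled with the primary ones and every
amplicon's $Z_{diff}$ for a gene is averaged *equally* into
$Z_{diff}^{final}$. High-confidence calls use $Z_{diff}^{final} \ge 1.6$
(suppressors) and $\le -1.2$ (enhancers), both inclusive. The asymmetry
reflects the published calibration of the cutoffs against genes with known
pathway roles.

`estimate_screen_error_rates()` implements the reference-list arithmetic:
the false-positive rate is the fraction of known-unexpressed genes that
nevertheless score; the false-negative rate is the fraction of all library
amplicons targeting high-confidence genes that failed to score in the
primary screen.

### Complex enrichment

`complex_enrichment()` scores a protein complex as the mean $|Z_{diff}^{final}|$
of its members detected in the screen (undetected members are ignored), and
compares it with `n_random = 1000` same-size gene sets drawn uniformly
without replacement from the scored universe. The plus-one permutation
p-value $(1 + \#\{\text{random} \ge \text{obs}\})/(n_{random}+1)$ is never
zero and bounded below by $1/(n_{random}+1)$. The published analysis used
an external enrichment server whose exact statistic is not reproduced here;
mean absolute phenotype strength with matched-size gene resampling is our
declared reading, and it is validated against an exhaustive
subset-enumeration oracle in the tests.

## The phosphoproteomics model

Six signaling states — {high, low Pvr} × {low InR, high InR (insulin),
low EcR} — are quantified by six-plex TMT reporter ions. Three experiments
mirror the published channel layouts: experiment 1 carries the high-Pvr
background in biological duplicate (channels 126/127 = low InR,
128/129 = high InR, 130/131 = low EcR), experiment 2 the low-Pvr
background likewise, and experiment 3 all six states in a single run.
Replicates therefore live in channels, not separate rows, and the design
table maps (experiment, channel) → (condition, replicate).

Quantification stages, in order:

1. **PSM filters** — phosphosite localization AScore > 13 (p < 0.05) and
   isolation specificity > 0.75, both strict, per the published wording
   "greater than".
2. **Target-decoy FDR** — scan score cutoffs from the top; keep the largest
   set with decoy/target ≤ 1%; drop decoys.
3. **Impurity correction** — reporter channels leak isotopic signal into
   neighbours; with observed $= M \,\cdot$ true, `correct_impurities()`
   solves the full linear system rather than nearest-neighbour
   subtraction — exact for the stated mixing model and valid for any
   invertible matrix. Negative solutions and sub-tolerance solver residue
   (below $10^{-9}$ of the row maximum) are clamped to zero so that a
   channel with no true signal is exactly zero, which matters because
   detection is defined as "> 0 after correction" (the data carry no
   published noise floor).
4. **Channel normalization** — divide by each channel's summed intensity,
   rescale by the mean total: corrects label-loading differences, leaves
   all channel totals equal, and is idempotent.
5. **Replicate averaging** — peptides with detectable signal in only one
   replicate are excluded; per-condition averages require both replicates.
   The single-run experiment 3 passes through.
6. **Site collapsing** — intensities of all peptides covering a
   (protein, residue, position) site are summed per condition;
   multiply-phosphorylated peptides contribute to each constituent site.

### Differential sets

Fold changes are ratios of replicate-averaged normalized intensities,
called **up** when ratio > 1.5 and **down** when ratio < 1/1.5 (both
strict; the reciprocal down-bound keeps up/down symmetric on the log
scale). Within-background comparisons (insulin response per Pvr state, EcR
knockdown response) use the replicated experiments; **cross-background
comparisons — the Pvr-dependent set, the common Pvr∧InR set, the
receptor-specific sets, the rescue fraction and profile clustering — use
experiment 3**, because only there is every ratio within one TMT mixture
and hence peptide-matched. Comparing across separate mixtures would
confound set calls with differences in which peptides were sampled.

The common set defaults to *reciprocal* logic — down under receptor loss
AND restored (up) by insulin in the low-Pvr background, or the mirrored
pairing — with a *shared-direction* mode available
(`define_common_set(mode = "shared")`), since the published description
("common directionality of change") admits both readings. Receptor-specific
sets compare the two single-receptor-active states and exclude the common
set; their labels are mutually exclusive by construction.

`kmeans_profiles()` reproduces the published profile clustering: each
site's profile is divided by its row median, then clustered with Euclidean
k-means, K = 10. Division (not subtraction) by the median on the linear
scale is our declared reading of "normalized to the median change".
Initial centers are drawn by D²-weighted (kmeans++) sampling with Lloyd
refinement, keeping the best of 25 restarts: with ten similar-sized
clusters, uniformly sampled starts rarely cover all groups and k-means
then sticks in merged/split optima, which kmeans++ avoids; the whole
procedure is deterministic given `seed`.

## What the synthetic generators emulate

`generate_screen_plates()` emulates a candidate-enriched verification-style
screen: duplicate 384-well plates under both backgrounds, 32 control wells
in fixed leading wells of each plate (arrayed-library practice; the
published layout is not stated, so this default is declared, not
inferred), log-normal multiplicative well noise (CV 10% — luminescence
counts are strictly positive), and planted classes with multiplicative
effects per background (suppressor ×1.8 sensitized; enhancer ×0.5
sensitized; upstream ×0.5 control). Class fractions default to
suppressor 0.25 / enhancer 0.22 / upstream 0.13 / null 0.40. The
composition is deliberately candidate-enriched rather than genome-wide: a
null amplicon's merged $Z_{diff}$ has heavier-than-normal tails (the
control SD is itself estimated), leaving ~3% of nulls beyond each cutoff,
so at genome-wide null fractions (~95%) no threshold-based caller can
reach 90% precision — the planted-class recovery properties are
meaningful only for a hit-enriched plate set, which is what verification
screens are.

`generate_phospho_experiment()` plants insulin-responsive sites (10% of
sites, split evenly up/down — real responses go both ways, and a one-sided
plant would bias channel totals and hence the normalization),
receptor-dependent sites (10%, down in every low-Pvr state), common
targets (5%, down on receptor loss but restored by insulin) and
EcR-responsive sites (1%, split up/down), at fold 2.5, with log-normal
intensity noise (CV 10%), 2% adjacent-channel leakage, whole-replicate
peptide dropout (5%) and 10% decoy PSMs whose search scores sit well below
the target distribution so a 1% FDR cutoff exists. Site baselines are
log-normal (CV 0.8) around 10^6, and each site's peptide roster (1 +
Poisson, mean 2) is drawn once and shared across experiments, as it is a
property of the protein. `planted_set_truth()` derives, in closed form
from the noise-free effect model, the set memberships the pipeline should
recover — the oracle used by the recovery tests.

What the generators do **not** emulate: plate spatial artifacts (edge
effects, gradients), off-target reagent effects, co-isolation interference
beyond the purity filter, retention-time or run-order drift, and
peptide-level missingness that is correlated with abundance. Passing the
recovery suite therefore demonstrates the pipeline's correctness under the
stated error model, not robustness to every artifact of real plates or
spectra.

## Numerical choices and degenerate inputs

* Thresholds are inclusive (≥ / ≤) exactly as published for screen scores,
  strict (> / <) for the fold-change and PSM filters, again as published.
* Plates without ≥ 2 control wells, or with zero control spread, raise
  classed errors rather than producing NaN scores.
* A constant hit-signature row has undefined correlation distance; it is
  excluded from clustering and reported.
* Fold calls with a missing or non-positive denominator are `not_callable`
  and never enter set counts; `up + down + unchanged + not_callable`
  always partitions the sites.
* The FDR scan only places cutoffs at distinct score boundaries, so ties
  are handled consistently; with no achievable cutoff the accept set is
  empty with a warning.
* All randomness flows through a single seed per generator or operation;
  identical seeds give byte-identical outputs.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run the screen at 2 plates × 352
candidate wells (704 amplicons, duplicate readings in two backgrounds),
the phosphoproteome at 400 sites across three experiments, enrichment with
1000 random sets, and profile clustering on 250 sites in 10 planted
groups — sizes at which every planted-recovery property has comfortable
statistical margin while a full pipeline run completes in seconds.

## Known limitations

* The Suppressor/Upstream boundary is a declared rule, not the published
  cluster boundary; genes near $Z_{ctrl} = -2$ can legitimately differ
  from the original class lists.
* Protein-level abundance is deliberately not normalized out of the
  phospho signal (as in the original analysis); a fold change may reflect
  protein amount rather than phosphorylation stoichiometry.
* The enrichment statistic approximates the external server's; p-values
  agree with exchangeable-resampling logic, not with that tool's exact
  null.
* Cross-background sets require the single-mixture experiment; designs
  lacking it cannot compute the Pvr/common/receptor-specific sets without
  accepting peptide-roster confounding.
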