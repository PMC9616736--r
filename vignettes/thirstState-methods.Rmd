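---
title: "Models and methods behind thirstState"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thirstState}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

thirstState re-implements, as a tested multi-stage pipeline, the
bespoke computations used to characterize the thirst state of the
*Drosophila* brain across four data modalities: droplet single-cell
RNA-seq of whole brains, two-photon calcium imaging of astrocytes
during bath drug application, electron-microscopy reconstructions of
astrocytes with automatically detected synapses, and simple behavioral
counts. Each stage is exercisable end-to-end on synthetic data with
planted ground truth, so every statistical property claimed here is
checked by the test suite rather than asserted.

This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic generators do
and do not emulate.

## Single-cell QC and doublet detection

**Barcode filtering.** A cell barcode is kept when its detected
feature count lies in [300, 4500], its UMI total is at most 20,000,
and its mitochondrial, rRNA, and ribosomal-protein expression
fractions are at most 0.15, 0.10, and 0.15. The rule is defined by
its strict discards (fewer than 300 or more than 4,500 features, and
so on), so boundary values are kept; `filterBarcodes()` implements
exactly this semantics and is idempotent. The three housekeeping gene
sets are selected by configurable name-prefix patterns (`^mt:`,
`^rRNA`, `^Rp[LS]`) because no fixed enumeration generalizes across
annotation versions.

**Bimodal thresholds.** Marker-based doublet detection needs a
per-gene threshold above which a marker counts as "highly expressed".
`estimateBimodalThreshold()` computes a Gaussian kernel density
estimate over the *non-zero* values of the normalized/scaled layer and
returns the abscissa of the density minimum between the two highest
local maxima — the saddle between the leaky/ambient mode and the
genuinely expressing mode. Scott's bandwidth rule is the default
(matching the KDE convention used elsewhere in the pipeline), with
Silverman's rule or a numeric bandwidth as alternatives, because
threshold placement is ultimately a judgement call on the density
shape and the estimator must be tunable. Unimodal genes yield no
threshold and are flagged as such. On two-Gaussian mixtures the
estimate converges to the analytic density minimum (tested against a
grid-search oracle).

**Co-expression doublets.** The class markers `nrv2` (glia), `VAChT`
(cholinergic), `VGlut` (glutamatergic) and `Gad1` (GABAergic) are
mutually exclusive in real cells, so a barcode with two or more of
them above threshold (strictly above — the threshold is the value
*above which* the gene counts as highly expressed) is flagged as a
doublet, with a reason code recording which markers fired. Within
cells designated as Kenyon cells, the same logic applies to the
subtype markers `Ca-alpha1T`, `ab` and `CG8641` (default thresholds
1.5, 1.5, 2.2, with 3 / 1.5 / 2.1 / 2.3 for the class markers — the
reference values estimated from the bimodal distributions of a
whole-brain atlas dataset; on any other data they must be
re-estimated). `mergeDoubletCalls()` unions
these flags with an optional external doublet-score call set (e.g.
from a simulation-based doublet scorer run upstream) and reports
counts per method, overlap, and the removed fraction.

The definition of the normalized/scaled layer is deliberately *not*
fixed by the doublet logic: thresholds apply to whatever layer is
passed. The synthetic generator uses log-normalization
(`log1p(count/libsize * 1e4)`) followed by per-gene z-scaling, a
standard and transparent stand-in for variance-stabilizing
transformations; whether covariates were regressed out before
thresholding is an upstream decision the module does not take.

## Cluster-tree fusion

Clusters produced by any upstream graph clustering are deliberately
over-clustered and then fused. `buildClusterTree()` places each
cluster at its centroid in the embedding (e.g. PCA) space and builds
an average-linkage tree on Euclidean centroid distances.
`fuseClusters()` walks sibling leaf pairs from the lowest merge
height upward — most similar pairs first, before fusions invalidate
the tree — and tests each pair gene-by-gene with a two-sample
Wilcoxon rank-sum test on the normalized layer. Tested genes are the
protein-coding genes detected in at least one cell of the pair;
p-values are Benjamini–Hochberg adjusted within that tested set. A
pair with fewer than 10 genes at adjusted p < 0.05 is fused, the tree
is rebuilt, and the process repeats to a fixed point. The merged
cluster keeps the larger member's label. Cluster count never
increases, and at most (initial clusters − 1) fusions can occur.

Two open choices were resolved as follows. Pipeline descriptions in
this setting sometimes label the pair test a "signed-rank" test, but
pairing is undefined between two independent cell groups; the
two-sample rank-sum test is the standard marker test here and is what
the module uses.
Second, the BH adjustment is applied within the tested
(protein-coding, detected) gene set of each pair, since that is the
family of hypotheses actually tested.

## Zero-inflation-aware differential expression

Droplet scRNA-seq counts carry excess zeros ("dropout") that bias
bulk-style negative binomial tests for weakly expressed genes. The
pipeline models each gene independently as a zero-inflated negative
binomial: a count is zero with probability $\pi$, otherwise drawn
from $\mathrm{NB}(\mu, \theta)$.

`fitZinb()` maximizes the ZINB likelihood by EM. The E-step assigns
each zero its posterior probability of arising from the inflation
component, $z = \pi / (\pi + (1-\pi) f_{NB}(0))$ with
$f_{NB}(0) = (\theta/(\theta+\mu))^\theta$. The M-step updates $\pi$
as the mean posterior (closed form), $\mu$ as the $(1-z)$-weighted
mean — which is the exact weighted NB maximum-likelihood solution for
an intercept-only model, independent of $\theta$ — and $\theta$ by a
one-dimensional profile maximization on the log scale. The
observed-data log-likelihood is asserted non-decreasing at every
iteration. Iteration stops when it changes by less than $10^{-6}$;
the default budget is 2000 iterations because genes whose fitted
$\pi$ approaches the zero boundary converge sublinearly and routinely
need several hundred.

`observationalWeights()` converts the fit into per-observation
weights: exactly 1 for non-zero counts and the posterior NB
probability for zeros. This is a deliberate simplification of the
full factor-model weighting scheme it emulates: the pipeline uses the
weights only to downweight excess zeros, and the independent per-gene
posterior has the same contract while being verifiable in closed
form (for $\mu=5,\ \theta=2,\ \pi=0.3$ the zero weight is exactly
$0.7\,(2/7)^2 / (0.3 + 0.7\,(2/7)^2) = 0.16$).

`weightedNbTest()` is a weighted NB likelihood-ratio test with log
library-size offsets: one intercept per condition under the
alternative, a common intercept under the null, dispersion profiled
by weighted ML under the alternative and shared by both fits (so the
effective sample size entering the dispersion estimate is the sum of
the weights), and $2\Delta\ell$ referred to $\chi^2_1$. This replaces
the moderated-F machinery of the bulk DE tools this weighting scheme
is usually paired with; with
all weights equal to 1 it reduces exactly to the ordinary unweighted
NB LRT, which the tests verify against an independent `glm.nb`-based
oracle. Monte-Carlo checks show the test holds its nominal size
(empirical type-I error within [0.03, 0.07] at $\alpha=0.05$ on 1000
null ZINB genes with 100 cells per arm) and detects a planted
four-fold change with power above 0.9 and median estimated log2 fold
change within 0.3 of the truth.

A DE *event* is a (gene, cluster) pair with $|\log_2 FC| > 1$ and
BH-adjusted p < 0.05; `summarizeDe()` counts events per class split
by direction and reports genes passing in at least one cluster, with
union semantics when several independent result tables are supplied.

## Calcium-trace response classification

Traces are acquired at 5.92 Hz. `computeDff()` takes the baseline
$F_0$ as the mean over the 14 s immediately before drug onset — 83
frames, rounding the window to the nearest frame (round, not floor or
ceiling, to avoid a systematic half-frame bias) — and returns
$(F - F_0)/F_0$, which makes every downstream statistic invariant to
raw fluorescence rescaling.

`classifyResponses()` implements the windowed rule: with each cell's
pre-drug mean normalized to 0, a cell is *activated* when its mean
over the 25 s from drug onset exceeds the pre-window standard
deviation, *inhibited* when it falls below its negative, and
*no change* otherwise. The sample (n−1) standard deviation of the raw
per-frame dF/F0 values is used; computing sigma on smoothed traces
would shrink the band, and raw frames are the more conservative
choice. A zero-variance pre window with equal means is
classified as no change.

`traceAuc()` integrates dF/F0 by the trapezoid rule at the frame
spacing, over the drug window ("during") or from drug offset to the
end of the recording ("after"), optionally shifting each cell's
series so its value at drug onset is 0. Window boundaries are mapped
to frame indices so that adjacent windows share their boundary frame,
making areas exactly additive.

`responseContingency()` cross-tabulates two drugs' calls per cell. By
default it restricts to the activated/inhibited axes (the 2×2 of
direction under drug A by direction under drug B), reports the
cross-product odds ratio ad/bc — with a Haldane–Anscombe 0.5
correction and a flag when the table contains zeros — and a
two-sided exact p-value summed directly from the hypergeometric
distribution (verified against the standard exact test on thousands
of tables). A 3×3 agreement mode with a chi-square test is available
but not the default, since the correspondence of interest is on the
excitation/inhibition axes. `proportionShiftTest()` compares
responsive proportions across internal states with pairwise exact
tests and Bonferroni correction (p times the number of comparisons,
capped at 1).

## Astrocyte–synapse vicinity statistics

Skeletonized astrocytes are node clouds with local radii in nm.
`fineProcessNodes()` keeps nodes with radius strictly below 300 nm,
excluding somata and main branches; the 300 nm radius bound is
equivalent to the 600 nm process-diameter phrasing used elsewhere,
and the module exposes it as a single radius parameter. Synapses are
kept when CleftScore ≥ 50 and ConnectionScore ≥ 33 (inclusive).

`vicinityProfile()` restricts synapses to the direct vicinity of the
fine processes. The default gate is the union of axis-aligned boxes
of 2 µm half-width centred on the fine nodes, following the
bounding-box phrasing of the procedure; a 2 µm-radius spherical mode
is provided because the figure legend describes a radius, and results
should state the mode used. Each candidate's shortest Euclidean
distance to any fine node is computed by exhaustive search (chunked
for memory; any accelerated index must agree exactly with exhaustive
search, and the tests enforce this). Distances are node-centre to
synapse-point; the node radius is not subtracted. Per transmitter,
the distances get a Gaussian KDE with Scott's bandwidth rule.

`bootstrapMeanTest()` implements the field's bootstrap-of-means
significance procedure: 10,000 bootstrap resamples of each group's distances, and a two-sided
Welch t-test comparing the two bootstrap-mean distributions. Treating
10,000 resample means as independent observations inflates the
degrees of freedom roughly nBoot/n-fold; for two samples drawn from
the *same* population the mean difference is of order
$\sqrt{2}\,\mathrm{SEM}$ while the test's null standard error is
$\mathrm{SEM}/\sqrt{n_\mathrm{boot}}$, so the procedure rejects
almost surely under the null. It is reported as `p.boot` —
it is the procedure being reproduced, and at atlas-scale sample
sizes, where effects dwarf the SEM, the inflation is inconsequential
— but a plain two-sample Welch t-test on the raw
distances is always reported alongside as `p.raw`, and it is the
calibrated quantity used wherever type-I error matters (the null
calibration tests use it). Resampling indices are derived from the
seed per group, so identical input vectors produce identical
bootstrap distributions (p.boot = 1) and reruns are reproducible.
Bootstrap resamples pool all synapses rather than stratifying per
astrocyte, following the pooled phrasing of the procedure.

A synapse is a tripartite synapse (TPS) when an astrocyte id appears
among its postsynaptic partners. `transmitterRatios()` reports, per
transmitter, its share among TPS synapses and among all vicinity
synapses, plus the ratio of the two shares (enrichment).

## The synthetic-data generators

The generators define the conditions under which every stage is
tested; their defaults are fixed once and stated here.

**Counts** (`simulateCounts()`): per-gene ZINB with baseline means
log-normal around 1.5 (log-sd 0.5), dispersion $\theta = 2$, dropout
$\pi = 0.1$; 2000 genes including 20 mitochondrial, 10 rRNA and 30
ribosomal-protein genes scaled to 5% / 3% / 7% of total expression
(safely inside the QC limits); four equal-fraction marker classes
(glia / cholinergic / glutamatergic / GABAergic), each with one
exclusive marker expressed at mean 100 with $\theta = 5$ and no
dropout within the class and exactly zero outside it — the
mutual-exclusivity idealization that makes co-expression doublet
calling exact. Doublets (default 5%) are sums of two freshly drawn
singlets of different classes, the standard mixture assumption behind
co-expression detection. A condition effect multiplies $\mu$ by
$2^{\log_2 FC}$ for listed genes. Planted QC violators are clear
violations of exactly one rule each. The generator also derives
marker thresholds on its own scaled layer (midpoint between the zero
background and the lowest expressing value), so threshold recovery
and doublet recovery are deterministic given the seed. Not emulated:
library-size and batch structure, ambient RNA, UMI saturation — so
passing tests certify the *rules*, not robustness to those artifacts.

**Traces** (`simulateTraces()`): Gaussian per-frame noise (sd 0.1 in
dF/F0 units) around a constant baseline, with a sustained step of
+0.5 / 0 / −0.5 during the drug window for activated / no-change /
inhibited cells — five times the noise sd, and a sustained step
rather than a kinetic transient because the windowed-mean rule is
insensitive to shape. Default category fractions (18% / 48% / 34%)
follow the response proportions observed for glutamate in sated
animals. Segments are 20 s baseline, 25 s drug, 20 s post at 5.92 Hz.

**Anatomy** (`simulateAnatomy()`): a branched random walk (2000
nodes, per-axis step sd 2.5 µm, branch probability 0.1) — not a
biological arbor; only node positions and radii matter downstream.
The step size is chosen so typical inter-node spacing exceeds the
planted synapse offsets; with a denser skeleton the nearest node to a
synapse would usually not be its anchor and the planted
per-transmitter offsets would be flattened in the realized distances
(they still shrink by roughly 5–10%, which the tests account for by
testing ordering and shifts rather than absolute planted values). 5%
of nodes get radii in [300, 1000] nm (excluded somata/main branches),
the rest in [20, 299] nm. Synapses are placed at planted distance
(per-transmitter offset + Gaussian noise, sd 300 nm) from a random
fine node in a random direction; default offsets 962 / 971 / 1061 nm
for glutamate / GABA / acetylcholine follow the magnitudes reported
for the fly protocerebrum. Scores are clipped normals straddling the
quality thresholds. A configurable fraction of synapses (default
10%) is planted as TPS with exact per-transmitter counts.

## Pipeline and reproducibility

`runPipeline()` ties the stages together from a single nested
configuration (R list or YAML): a global seed fans out
deterministically into per-stage seeds, every output file is recorded
in a manifest with record counts and a config hash, identical
configurations give byte-identical outputs, and individual stages can
be deleted and re-run in isolation. All thresholds appearing in this
vignette are configuration defaults, not hard-coded values. The
package's functions are the interface; the pipeline runner is a thin
orchestration layer over them.

## Problem sizes and limitations

The test suite and the acceptance script run at desk scale: 1000-cell
/ 2000-gene simulations for QC, 20-seed replicates for estimator
recovery, 1000 null genes at 100 cells per arm for test calibration,
50 nodes × 200 synapses for exact-distance oracles, and 500 distances
per transmitter group for the bootstrap procedure. Atlas-scale
quantities (tens of thousands of cells, hundreds of clusters, exact
DE gene lists, exact EM distance means) depend on full deposited
datasets and EM volumes and are out of scope; what the
package certifies is that every rule, estimator and test behaves as
specified on data whose truth is known.

Known limitations: the per-gene ZINB ignores gene–gene and cell-level
covariance (no factor model, no covariates beyond the library-size
offset); the fusion test treats cells as exchangeable within
clusters; the bootstrap-of-means Welch test is anticonservative by
construction (see above) and should be read alongside `p.raw`; and
the synthetic generators idealize marker exclusivity, so real-data
doublet detection will be noisier than the planted-truth recovery
rates suggest.
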