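---
title: "matchedsc: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{matchedsc: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: what each
stage computes, under which assumptions, which parameters matter, what
the synthetic generator does and does not emulate, and where genuinely
open design choices were resolved. It states no empirical result that
the test suite and `scripts/acceptance.R` do not themselves compute.

## 1. The setting

A matched design: each biopsy is profiled twice — once by probe-based
fixed RNA profiling of FFPE tissue (a fixed gene panel, shallower
per-cell depth) and once by conventional 3′ scRNA-seq of fresh or frozen
tissue. The pipeline quantifies how much the platforms agree (QC yield,
annotation confidence, composition, inferred copy number, marker
expression) and how well they integrate under varying cell-type overlap.

## 2. Quality control

Per library (one sample on one platform), a cell is excluded when any
of four rules fires:

* UMI count `< median − n_mads · MAD` (default `n_mads = 3`);
* detected genes below the analogous bound;
* mitochondrial UMI fraction `> mito_max` (default 0.10);
* doublet flag set (doublet calling is upstream; the generator provides
  truth flags).

"MAD" defaults to the scaled median absolute deviation
(`1.4826 · median|x − median|`), the single-cell QC convention
(cf. `scater::isOutlier`); the literal mean absolute deviation about the
median is available via `mad_type = "mean"` because the phrase is
genuinely ambiguous in common usage. All comparisons are strict, so a
zero-spread library excludes nobody. Thresholds are frozen per call,
which makes filtering idempotent on the kept cells.

A practical note encoded in the tests: with depth CV above roughly 35%,
`median − 3·MAD` is negative and the depth rule cannot fire at all. The
rule presupposes reasonably concentrated library depth.

## 3. Copy-number inference

`infer_cna_scores()` is a deliberately specified stand-in for
inferCNV-style reference-normalized smoothing; exact parity with any
external tool is a non-goal. The operator:

1. CP10k library-size normalization, `log2(x + 1)`;
2. subtract the per-gene mean over the reference population (immune
   cells, assumed diploid);
3. clip residuals to ±3;
4. centered moving average over `smoothing_genes = 101` genomically
   ordered genes per chromosome (window truncated at ends);
5. re-center each cell by its median smoothed score.

Assumptions: the reference is diploid and transcriptionally
representative of the baseline; expression dosage scales with copy
number; genes are dense enough that a 101-gene span is local relative
to CNA segments. Chromosomes with < 3 positioned genes, and genes
without usable coordinates (e.g. chrM), are excluded with a message.

Two numerical facts shape everything downstream:

* **log1p compression.** At shallow UMI depth (a few counts per gene)
  `log2(1 + x)` is far from linear, so a ratio-2 gain recovers ≈ 0.3–0.4
  on the log2 scale rather than 1.0. The dosage-oracle unit test
  therefore runs at high depth, where the operator's linearity
  assumption holds; shallow-depth behaviour is validated through
  recovery properties instead.
* **Library-size renormalization.** A clone gaining fraction *f* of the
  genome at ratio *r* depresses all its neutral genes by
  `log2(1 + f(r−1))`; the per-cell median re-centering (step 5) restores
  the neutral baseline provided gains cover well under half the genome.

**Windows.** Gene scores are averaged in fixed windows (default 10 Mb,
0-based, tiling from coordinate 0; genes assigned by midpoint). Empty
windows are *missing*, never zero. The centered scale (neutral 0) and
ratio scale (neutral 1, `ratio = 2^centered`) are carried with an
explicit tag. Gene-count-weighted window means reproduce the per-cell
gene-score mean to 1e-10 (a conservation property in the tests).

**Bulk concordance.** The bulk WGS segment table is converted to the
same windows by base-weighted mean copy ratio (uncovered bases neutral);
both tracks are trichotomized (gain/neutral/loss at ±`epsilon` around
ratio 1, default 0.05 ≈ ±7% expression; `epsilon = 0` is the literal
rule under which continuous scores are almost never neutral) and
compared per cell by Cohen's kappa over pairwise non-missing windows.
Degenerate kappa (both tracks constant): 1 when equal, 0 when not —
the 0/0 case resolved so that all-neutral vs all-neutral counts as
perfect agreement.

**Malignancy rule.** A cluster is malignant when the 10th percentile
(linear interpolation) of the pooled absolute window scores of its cells
exceeds a threshold. Read literally ("> 0") every cluster with
continuous noise is malignant, so the threshold must be a noise floor.
The floor used is the *matched statistic on the reference cells* — the
10th percentile of pooled reference |scores| — times a margin of 1.1.
The margin is derived a priori from the order statistics: for half-normal
noise the null cluster statistic concentrates at `q10 ≈ 0.126σ`, while a
cluster whose altered fraction is `f` (clone share × genome share,
≥ 0.15 in the standard scenario) concentrates at
`q(0.10/(1−f)) ≥ 0.148σ`; 1.1 splits the two with several standard
errors on either side. A floor placed deep in the noise distribution
(e.g. the 5th percentile of reference |values|, ≈ 0.063σ) sits *below*
the null statistic and would flag every diploid cluster, so it cannot
serve as a default. `literal = TRUE` restores the strict rule.

**Subpopulation test.** Whether a set of cells carries a gain (loss) in
a window is the exact binomial sign test of window ratios against 1 in
the stated direction, ties removed. The test is conventionally
described as targeting a population mean of 1, but a sign test
addresses the median; we test the stated center without guessing
intent. Fewer than 5 informative
cells yields an undefined marker rather than a p-value.

## 4. Annotation and platform comparisons

The annotator is a transparent stand-in exercising the same comparison
machinery as anchor/reference transfer tools: per-type centroids of
CP10k-log expression over a panel (default: top 200 genes by variance),
Spearman correlation per query cell, argmax assignment, and confidence
`(r_best − r_second) / max(1 − r_second, 1e-8)` clipped to [0, 1]. The
confidence is a normalized margin — do not read external-tool parity
into it. Panel genes undetected across an entire query are treated as
probe-panel holes and dropped from the correlation, which is why
platforms must be transferred separately (transferring a mixed matrix
would treat FFPE panel holes as biological zeros — an early bug the
test suite now pins).

Confidence differences across platforms are assessed per cell type by
OLS of confidence on a platform indicator plus sample indicators —
fixed effects standing in for the mixed models a larger design would
warrant (≤ 12 samples makes fixed effects a standard approximation; a
documented deviation). p-values are BH-adjusted across cell types.

Composition differences use the generalized Cochran–Mantel–Haenszel
statistic for 2 (platform) × J (cell type) × K (matched sample) tables
with J−1 degrees of freedom and no continuity correction — the general
association form, because composition has J > 2 categories. Strata with
an empty platform margin are dropped with a message.

## 5. The integration benchmark

`generate_scenarios()` reproduces the controlled-overlap design: 150
random partitions — 25 *complete* (FFPE uses exactly the frozen
selection of samples and cell types), 25 *none* (FFPE uses the
complements of both), 100 *partial* (an independent random selection,
resampled up to 100 times until the cell-type overlap is strictly
partial, keeping categories semantically distinct). The shared fraction
is the Jaccard index of the two cell-type sets (configurable to the
FFPE-relative fraction); there is no canonical definition, so the choice
is explicit and configurable.

The built-in baseline correction restricts to genes detected on both
platforms, CP10k-log normalizes, standardizes every gene within each
platform (removing platform location/scale shifts), and runs a joint
truncated PCA (default 30 components). The uncorrected comparison arm
skips the standardization. External methods (Harmony, FastMNN, …) attach
through the same interface — a function from per-platform count matrices
to a joint embedding — without being dependencies.

Clustering sweeps Louvain modularity (igraph) on a k = 20 Euclidean kNN
graph over resolutions 0.05–0.30 in steps of 0.05, selecting the
partition with the highest NMI against the cell-type labels, ties to the
lowest resolution. (Seurat-style pipelines use Louvain on a shared-nearest-neighbour
graph instead; the clustering backend is pluggable.)

Metrics, all implemented from their formulas:

* **NMI** `I(a;b) / mean(H(a), H(b))` — arithmetic-mean normalization
  (the scIB default); zero-entropy partitions score 0 by convention.
* **ARI** via the pair-counting contingency formula.
* **Batch ASW**: within each cell type, silhouette of platform labels on
  the embedding, per-item `1 − |s|`, averaged within then across types.
  Reported as *mixing badness* `1 − raw` so that lower = better mixing,
  matching the orientation used for PC regression; the raw scIB
  orientation is attached as an attribute. Cell types lacking ≥ 2 cells
  from each platform are skipped; if all are skipped (the no-overlap
  category) the result is an undefined marker, not a number.
* **PC regression**: variance-weighted covariate R² over the top PCs,
  `Σ R²ᵢ Varᵢ / Σ Varᵢ` (default `n_pcs = min(50, n−2)`); 0 for a
  constant covariate by convention.

## 6. The synthetic cohort generator

The generator states a world; it is not a tuning dial. Counts are
negative-binomial (per-gene dispersion, default size 2.0 — overdispersed
UMIs rather than Poisson, so MAD filters and smoothing are exercised
nontrivially) around cell-type program means × per-cell gamma depth.
Defaults, chosen once:

* **Genome**: 5 chromosomes × 120 Mb (60 windows of 10 Mb), 3,000 genes
  of 2 kb placed uniformly (so windows have variable gene counts and
  empty-window handling is exercised), 30 chrM mito genes outside the
  windowed genome.
* **Programs**: five cell types (Malignant 30%, T 30%, B 15%, Myeloid
  15%, Fibroblast 10%); a shared log-normal baseline with disjoint
  marker blocks (5% of genes per type at 4-fold — strong enough that
  annotation and clustering criteria are attainable at desk scale).
* **Clones**: default one clone at 20% of all cells (⅔ of the malignant
  compartment) with a single-copy gain (ratio 2.0) over 30% of the
  genome — the standard recovery scenario. Clone fractions may vary per
  sample (the two-biopsy subclonal design). The dosage multiplier
  applies on top of the normalized diploid profile, so clone cells carry
  proportionally more UMIs and the raw expression ratio converges to
  exactly r (a tested invariant); `depth_scale` is therefore the mean
  UMI of diploid cells.
* **Platform effects**: FFPE = a seeded random probe panel covering 50%
  of genes (counts structurally zero off-panel) and mean depth 2,000
  UMIs/cell vs 6,000 frozen (the direction observed in practice for
  probe-based FFPE assays; the magnitudes are free parameters — no
  quantitative platform-effect model exists to calibrate against). An
  optional gene-wise log-normal FFPE scaling factor exists, default off.
* **Doublets**: 5% of cells, expected profiles summed then
  depth-renormalized. **Mito fractions**: Beta(6, 194), mean 3%.
* **Bulk truth**: per window, the clone-fraction-weighted, base-weighted
  mean copy ratio with the non-clonal remainder diploid; neutral windows
  are exactly 1.

What the generator does **not** emulate — and hence what a green test
does not establish: ambient RNA and background contamination, empty
droplets, batch effects beyond panel + depth (+ optional gene scaling),
FFPE RNA degradation chemistry, read-level noise, realistic gene-length
and GC structure, and real marker-gene architecture (thousands of
subtly shifted genes rather than discrete 4-fold blocks).

## 7. Determinism and seeds

Every stochastic stage takes an integer seed; `generate_cohort` is a
pure function of its config (RNG state is saved and restored). The
pipeline fans one root seed out with fixed per-stage offsets, so stages
are individually reproducible and `run_pipeline` writes byte-identical
summaries under a fixed seed (a tested property). Seeds stay below 2³¹.

## 8. Known limitations

* **Cross-population reference bias.** Subtracting an immune-cell
  baseline leaves malignant-program expression differences in the
  scores; after smoothing, each window acquires a coherent
  population-level offset of the same order as a *focal* amplification's
  smoothing-diluted signal. Per-cell agreement statistics (kappa) and
  whole-cluster rules absorb this, but a sign test over hundreds of
  cells amplifies any coherent offset; detecting a low-prevalence (20%)
  focal gain against it is unreliable in the synthetic world (the
  corresponding acceptance criterion documents this honestly rather
  than weakening the generator's program structure post hoc). The same
  confound is a known caveat of expression-based CNA inference on real
  data, mitigated there by denser genomes (a 101-gene span is ~0.4% of
  a real transcriptome vs ~3–8% at desk scale) and careful reference
  choice.
* **Shallow-depth compression** (§3) means centered scores understate
  log2 copy ratios at realistic UMI depths; calls are threshold-based
  for exactly this reason.
* The annotator's confidence is a stand-in metric; absolute confidence
  values are not comparable to Seurat or SingleR scores.
* Fixed-effect sample adjustment slightly understates uncertainty
  relative to mixed models when samples are few and unbalanced.
* The benchmark's built-in baseline is intentionally simple; its role
  is to make the harness self-contained, not to compete with dedicated
  integration methods.

## 9. Coordinate and format conventions

All genomic coordinates are **0-based half-open** (BED convention),
fixed once and used
everywhere (windows tile from 0; a gene belongs to the window containing
its midpoint). 10x triplets are MatrixMarket integer coordinate format
plus features/barcodes TSV (gzipped accepted); segment tables are
BED-like TSV with a copy-ratio column and optional clone id; the gene
order of the count matrix is authoritative, with annotation joined by
gene id.
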