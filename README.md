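# matchedsc

Concordance analysis of matched FFPE and fresh-frozen single-cell RNA-seq
cohorts.

## The problem

Archival tumour tissue is stored as formalin-fixed paraffin-embedded (FFPE)
blocks, which modern probe-based assays (10x Flex–style fixed RNA
profiling) can now profile at single-cell resolution — but through a fixed
probe panel, at lower per-cell depth, from chemically modified RNA. Before
archival cohorts can be pooled with conventional 3′ scRNA-seq of
fresh-frozen tissue from the same biopsies, one has to ask: do the two
platforms agree on cell-type composition, annotation confidence, inferred
copy-number structure, and clinically relevant markers — and how well do
they integrate?

`matchedsc` implements that comparison pipeline end to end, with every
statistic written from first principles, plus a seeded synthetic
matched-cohort generator (shared cell-type programs, clonal CNA segments,
probe-panel restriction, depth differences, doublets, mitochondrial
content) so every stage is validated against known ground truth.

## What is computed

* **QC** — per-library exclusion of cells with UMI count or detected genes
  below `median − 3·MAD`, mitochondrial fraction > 10%, or a doublet flag
  (MAD = scaled median absolute deviation, constant 1.4826; a literal
  mean-absolute-deviation mode is available).
* **CNA inference** — a reference-normalized smoothing operator:
  CP10k → log2 → subtract immune-reference per-gene mean → clip ±3 →
  101-gene moving average per chromosome → per-cell median re-centering.
  Gene scores are averaged in 10 Mb windows, trichotomized
  (gain > 1+ε, loss < 1−ε, neutral otherwise on the ratio scale), and
  compared per cell against a bulk WGS segment track by Cohen's kappa
  κ = (p_o − p_e)/(1 − p_e). Clusters are called malignant when the 10th
  percentile of pooled |window scores| exceeds a reference-derived noise
  floor; subpopulation gains/losses use the exact binomial sign test
  against the neutral ratio 1.
* **Annotation** — correlation-centroid label transfer (Spearman to
  per-type CP10k-log centroids) with a normalized-margin confidence,
  compared across platforms per cell type by OLS with sample fixed
  effects and Benjamini–Hochberg FDR; composition compared by the
  generalized 2×J×K Cochran–Mantel–Haenszel test stratified by matched
  sample.
* **Integration benchmark** — 150 random cohort partitions (25 complete /
  25 none / 100 partial cell-type overlap between platforms), a built-in
  correction baseline (per-platform gene standardization + joint PCA)
  with a pluggable method interface, kNN-Louvain clustering with the
  resolution (0.05–0.30, step 0.05) selected by NMI against cell types,
  and four metrics: NMI, ARI, batch average silhouette width (reported as
  mixing badness: lower = better) and principal-component regression
  Σ R²ᵢ·Varᵢ / Σ Varᵢ.
* **Markers** — marker-set scoring (mean CP10k-log), margin-based T-cell
  subtyping, and cross-platform per-sample correlation of a single marker
  gene (the PDCD1-style analysis).

## Worked example

```r
library(matchedsc)

## generate a small matched cohort: 2 biopsies, both platforms,
## one ratio-2 clone over 30% of the genome in 20% of cells
cfg    <- synth_config(n_samples = 2, n_cells = 500, n_genes = 2000, seed = 1)
cohort <- generate_cohort(cfg)
cm     <- cbind_cm(cohort$matrices)
md     <- cohort$truth$cells

## per-cell QC with the 3-MAD / 10%-mito / doublet rules
qc <- qc_cohort(cm, cohort$annotation, cohort$metadata)

## CNA inference against the immune reference, 10 Mb windows
ref    <- md$barcode[md$cell_type %in% c("Tcell", "Bcell", "Myeloid")]
scores <- infer_cna_scores(cm, cohort$annotation, ref)
prof   <- window_profile(scores, genome = cohort$truth$genome)

## per-cell Cohen's kappa against the derived bulk CNA truth
bulk  <- derive_bulk_cna(cohort$truth)
calls <- trichotomize(prof, epsilon = 0.05)
bt    <- trichotomize(window_profile_obj(bulk$windows,
                                         bulk$values[1, , drop = FALSE],
                                         "S1", "ratio"), 0.05)
kap   <- cell_bulk_kappa(calls[md$sample_id == "S1", ], bt)

## malignancy classification and a subclonal gain test
mal <- classify_malignant_clusters(prof, md$cell_type, reference_cells = ref)
p   <- subpop_cna_test(prof, md$barcode[md$cell_type == "Malignant"],
                       "chr1:50000000-60000000", "gain")
```

Output (seed 1):

```
QC kept 1885 of 2000 cells
median kappa: clone cells 0.38, normal cells 0.00
     cluster      score malignant
1  Malignant 0.01855705      TRUE
2      Tcell 0.01458345     FALSE
3      Bcell 0.01412300     FALSE
4    Myeloid 0.01409278     FALSE
5 Fibroblast 0.01424182     FALSE
subclonal gain sign-test p = 3.23e-52
```

Reading: QC removes doublets and low-quality cells (5.75% here); clone
cells agree with the bulk CNA track far better than diploid cells
(median κ 0.38 vs 0.00); only the malignant cluster's 10th-percentile
score clears the reference noise floor; and the ratio-2 gain is detected
in the malignant population with overwhelming significance.

The full study — QC → annotation → CNA → benchmark → markers on a
simulated cohort, with per-stage TSVs and a reproducible JSON summary —
runs via

```r
run_pipeline(run_config(seed = 7), out_dir = "run7")
```

or from the command line: `exec/matchedsc reproduce --seed 7 --out run7`
(subcommands: `simulate`, `qc`, `annotate`, `cna`, `bench`, `markers`,
`reproduce`).

## Documentation

`vignettes/matchedsc-methods.Rmd` describes the models and their
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, and known limitations
(in particular the cross-population reference bias inherent to
expression-based CNA inference).
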