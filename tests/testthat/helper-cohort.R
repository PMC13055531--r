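# Shared fixtures, generated in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

# small matched cohort with one clone on chr1 (1/3 of the genome)
tiny_cohort <- function() cached_fixture("tiny", function() {
  cfg <- synth_config(
    n_samples = 2, n_cells = 300, n_genes = 600, n_mito_genes = 10,
    genome = data.frame(chrom = paste0("chr", 1:3), length = rep(100e6, 3)),
    clones = list(list(
      clone_id = "cloneA", fraction = 0.2,
      segments = data.frame(chrom = "chr1", start = 0, end = 100e6,
                            copy_ratio = 2.0))),
    seed = 42)
  generate_cohort(cfg)
})

tiny_cm <- function() cbind_cm(tiny_cohort()$matrices)

tiny_ref_cells <- function() {
  md <- tiny_cohort()$truth$cells
  md$barcode[md$cell_type %in% c("Tcell", "Bcell", "Myeloid")]
}

tiny_scores <- function() cached_fixture("tiny_scores", function()
  suppressMessages(infer_cna_scores(tiny_cm(), tiny_cohort()$annotation,
                                    tiny_ref_cells(),
                                    smoothing_genes = 51)))

# hand-built gene-score object for windowing edge cases
toy_scores <- function(values, chrom, start) {
  ann <- data.frame(gene_id = paste0("g", seq_along(chrom)), chrom = chrom,
                    start = start, end = start + 1000, is_mito = FALSE,
                    stringsAsFactors = FALSE)
  structure(list(scores = matrix(values, ncol = 1,
                                 dimnames = list(ann$gene_id, "cell1")),
                 annotation = ann), class = "cna_scores")
}

expect_exit_ok <- function(x) expect_identical(as.integer(x), 0L)
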