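test_that("generation is a deterministic function of the config", {
  cfg <- synth_config(n_samples = 1, n_cells = 60, n_genes = 150,
                      n_mito_genes = 5, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(lapply(a$matrices, function(m) as.matrix(m$counts)),
                   lapply(b$matrices, function(m) as.matrix(m$counts)))
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(a$annotation, b$annotation)
  # a different seed changes the draw
  c2 <- generate_cohort(synth_config(n_samples = 1, n_cells = 60,
                                     n_genes = 150, n_mito_genes = 5,
                                     seed = 100))
  expect_false(identical(as.matrix(a$matrices[[1]]$counts),
                         as.matrix(c2$matrices[[1]]$counts)))
})

test_that("config invariants are enforced", {
  ct <- data.frame(name = c("A", "B"), proportion = c(0.6, 0.6))
  expect_error(synth_config(cell_types = ct), "sum to 1")
  expect_error(synth_config(ffpe_panel_fraction = 0), "\\(0, 1\\]")
  expect_error(synth_config(clones = list(list(
    clone_id = "c", fraction = 0.9,
    segments = data.frame(chrom = "chr1", start = 0, end = 1e6,
                          copy_ratio = 2)))), "exceed")
  expect_error(synth_config(depth_scale = c(FFPE = 100)), "FROZEN")
})

test_that("clone-free cohorts give an all-neutral bulk profile", {
  cfg <- synth_config(n_samples = 2, n_cells = 20, n_genes = 100,
                      clones = list(), seed = 5)
  co <- generate_cohort(cfg)
  expect_true(all(is.na(co$truth$cells$clone_id)))
  bulk <- derive_bulk_cna(co$truth)
  expect_true(all(bulk$values == 1))
  expect_equal(bulk$scale, "ratio")
})

test_that("derive_bulk_cna mixes clone fractions base-weighted", {
  mk_truth <- function(fraction, start, end, ratio) {
    cfg <- synth_config(
      n_samples = 1, n_cells = 40, n_genes = 100,
      genome = data.frame(chrom = "chr1", length = 30e6),
      clones = list(list(clone_id = "c1", fraction = fraction,
                         segments = data.frame(chrom = "chr1",
                                               start = start, end = end,
                                               copy_ratio = ratio))),
      cell_types = data.frame(name = c("Malignant", "Tcell"),
                              proportion = c(0.5, 0.5)),
      seed = 2)
    generate_cohort(cfg)$truth
  }
  # full 10 Mb window, fraction 1 of a pure-malignant... fraction 0.5
  b1 <- derive_bulk_cna(mk_truth(0.5, 0, 10e6, 2.0))
  expect_equal(b1$values[1, 1], 1.5)       # linear mixing
  expect_equal(b1$values[1, 2], 1.0)       # untouched window neutral
  # clone at fraction 0.5 covering half a window at ratio 3:
  # base-weighted window mean for the clone = 2.0, mixed = 1.5
  b2 <- derive_bulk_cna(mk_truth(0.5, 0, 5e6, 3.0))
  expect_equal(b2$values[1, 1], 0.5 * 2.0 + 0.5 * 1.0)
  expect_error(derive_bulk_cna(mk_truth(0.5, 0, 10e6, 2.0), 0), "positive")
})

test_that("clone fraction 1 of a full window recovers the pure ratio", {
  cfg <- synth_config(
    n_samples = 1, n_cells = 40, n_genes = 100,
    genome = data.frame(chrom = "chr1", length = 30e6),
    cell_types = data.frame(name = c("Malignant", "Tcell"),
                            proportion = c(1 - 1e-9, 1e-9)),
    clones = list(list(clone_id = "c1", fraction = 1.0,
                       segments = data.frame(chrom = "chr1", start = 0,
                                             end = 10e6, copy_ratio = 2))),
    seed = 2)
  expect_equal(derive_bulk_cna(generate_cohort(cfg)$truth)$values[1, 1], 2.0)
})

test_that("degenerate platform effect makes platforms exchangeable in law", {
  cfg <- synth_config(n_samples = 1, n_cells = 400, n_genes = 200,
                      ffpe_panel_fraction = 1,
                      depth_scale = c(FFPE = 3000, FROZEN = 3000),
                      clones = list(), doublet_rate = 0, seed = 8)
  co <- generate_cohort(cfg)
  expect_true(all(co$truth$panel$in_panel))
  tot_f <- Matrix::colSums(co$matrices[["S1_FFPE"]]$counts)
  tot_z <- Matrix::colSums(co$matrices[["S1_FROZEN"]]$counts)
  # same generator law: mean depths agree within Monte Carlo error
  expect_lt(abs(mean(tot_f) - mean(tot_z)) / mean(tot_z), 0.1)
})

test_that("mean counts recover program mean x depth (law of large numbers)", {
  cfg <- synth_config(
    n_samples = 1, n_cells = 5000, n_genes = 250, n_mito_genes = 5,
    cell_types = data.frame(name = c("A", "B"), proportion = c(1, 0),
                            stringsAsFactors = FALSE),
    malignant_type = "A", clones = list(), doublet_rate = 0,
    depth_scale = c(FFPE = 500, FROZEN = 2000), seed = 17)
  co <- generate_cohort(cfg)
  truth <- co$truth
  # expected relative profile for a diploid type-A frozen cell, computed
  # independently from the stored program means and the mito-beta mean
  B <- truth$gene_means[, "A"]
  mito <- co$annotation$is_mito
  m_bar <- cfg$mito_beta[1] / sum(cfg$mito_beta)
  p <- numeric(length(B))
  p[!mito] <- (1 - m_bar) * B[!mito] / sum(B[!mito])
  p[mito] <- m_bar * B[mito] / sum(B[mito])
  expected <- 2000 * p
  got <- Matrix::rowMeans(co$matrices[["S1_FROZEN"]]$counts)
  top <- expected > 5          # genes with enough signal for a 5% check
  expect_true(all(abs(got[top] - expected[top]) / expected[top] < 0.05))
})

test_that("dosage effect: clone/normal mean expression ratio converges to r", {
  cfg <- synth_config(
    n_samples = 1, n_cells = 4000, n_genes = 300, n_mito_genes = 0,
    genome = data.frame(chrom = paste0("chr", 1:2), length = rep(60e6, 2)),
    cell_types = data.frame(name = c("Malignant", "Tcell"),
                            proportion = c(0.8, 0.2)),
    clones = list(list(clone_id = "c1", fraction = 0.4,
                       segments = data.frame(chrom = "chr1", start = 0,
                                             end = 60e6, copy_ratio = 2))),
    doublet_rate = 0, ffpe_panel_fraction = 1, seed = 23)
  co <- generate_cohort(cfg)
  md <- co$truth$cells
  frozen <- md$platform == "FROZEN"
  clone <- frozen & !is.na(md$clone_id)
  norm <- frozen & is.na(md$clone_id) & md$cell_type == "Malignant"
  seg_genes <- co$annotation$chrom == "chr1"
  m <- co$matrices[["S1_FROZEN"]]$counts
  in_lib <- function(sel) md$barcode[sel]
  r_hat <- sum(m[seg_genes, in_lib(clone)]) / sum(clone) /
    (sum(m[seg_genes, in_lib(norm)]) / sum(norm))
  expect_equal(r_hat, 2.0, tolerance = 0.05)
})

test_that("FFPE panel restriction zeroes off-panel genes", {
  co <- tiny_cohort()
  off <- !co$truth$panel$in_panel
  expect_gt(sum(off), 0)
  expect_equal(sum(co$matrices[["S1_FFPE"]]$counts[off, ]), 0)
  expect_gt(sum(co$matrices[["S1_FROZEN"]]$counts[off, ]), 0)
})

test_that("write_cohort emits a loadable standard layout", {
  d <- withr::local_tempdir()
  co <- tiny_cohort()
  write_cohort(co, d)
  md <- read_cell_metadata(file.path(d, "cells.tsv"))
  expect_equal(nrow(md), nrow(co$metadata))
  ann <- read_gene_annotation(file.path(d, "genes.bed.tsv"))
  expect_equal(ann$gene_id, co$annotation$gene_id)
  back <- read_10x_triplet(file.path(d, "S1_FFPE"))
  expect_identical(as.matrix(back$counts),
                   as.matrix(co$matrices[["S1_FFPE"]]$counts))
})
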