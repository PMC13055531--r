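test_that("windowing: singleton mean, empty-window NA, cancellation", {
  # two chr1 genes in window 1 scoring +1/-1, one chr2 gene scoring 0.8,
  # and an empty second chr1 window
  sc <- toy_scores(c(1, -1, 0.8), c("chr1", "chr1", "chr2"),
                   c(1e6, 2e6, 1e6))
  genome <- data.frame(chrom = c("chr1", "chr2"), length = c(20e6, 10e6))
  p <- window_profile(sc, width = 10e6, genome = genome)
  expect_equal(p$scale, "centered")
  expect_equal(unname(p$values[1, ]), c(0, NA, 0.8))
  # ratio scale is 2^centered
  pr <- profile_as_scale(p, "ratio")
  expect_equal(unname(pr$values[1, ]), c(1, NA, 2^0.8))
  expect_error(window_profile(sc, width = 0), "positive")
})

test_that("windowing conserves mass (gene-count weighted mean)", {
  sc <- tiny_scores()
  p <- window_profile(sc, genome = tiny_cohort()$truth$genome)
  w <- p$gene_count
  for (i in c(1, 50, 200)) {
    cell_mean <- mean(sc$scores[, i])
    win_mean <- sum(p$values[i, w > 0] * w[w > 0]) / sum(w)
    expect_equal(win_mean, cell_mean, tolerance = 1e-10)
  }
})

test_that("null limit: identically distributed cells score ~0 per gene", {
  # a single program, no clones, no platform effect: every cell follows
  # the reference law exactly, so smoothed scores concentrate at 0
  cfg <- synth_config(n_samples = 1, n_cells = 600, n_genes = 400,
                      n_mito_genes = 0, clones = list(), doublet_rate = 0,
                      ffpe_panel_fraction = 1,
                      depth_scale = c(FFPE = 4000, FROZEN = 4000),
                      cell_types = data.frame(name = c("Malignant", "x"),
                                              proportion = c(1, 0)),
                      genome = data.frame(chrom = paste0("chr", 1:2),
                                          length = rep(100e6, 2)),
                      seed = 61)
  co <- generate_cohort(cfg)
  cm <- cbind_cm(co$matrices)
  ref <- co$truth$cells$barcode[1:300]
  sc <- suppressMessages(infer_cna_scores(cm, co$annotation, ref,
                                          smoothing_genes = 51))
  gene_means <- rowMeans(sc$scores)
  expect_lt(max(abs(gene_means)), 0.05)
})

test_that("dosage oracle: ratio-2 clone recovers ~1 on the log2 scale", {
  # high depth so log2(1 + x) is effectively linear; clone covers all of
  # chr1 (~1/3 of genes), well beyond the smoothing span
  cfg <- synth_config(
    n_samples = 1, n_cells = 300, n_genes = 420, n_mito_genes = 0,
    genome = data.frame(chrom = paste0("chr", 1:3), length = rep(70e6, 3)),
    cell_types = data.frame(name = c("Malignant", "Tcell"),
                            proportion = c(0.5, 0.5)),
    clones = list(list(clone_id = "c1", fraction = 0.5,
                       segments = data.frame(chrom = "chr1", start = 0,
                                             end = 70e6, copy_ratio = 2))),
    doublet_rate = 0, ffpe_panel_fraction = 1, mito_beta = c(1, 999),
    depth_scale = c(FFPE = 5e4, FROZEN = 5e4), nb_size = 2, seed = 67)
  co <- generate_cohort(cfg)
  cm <- cbind_cm(co$matrices)
  md <- co$truth$cells
  ref <- md$barcode[md$cell_type == "Tcell"]
  sc <- suppressMessages(infer_cna_scores(cm, co$annotation, ref,
                                          smoothing_genes = 101))
  ann <- sc$annotation
  interior <- which(ann$chrom == "chr1")
  interior <- interior[interior > 55 & interior < (max(interior) - 55)]
  clone_cells <- colnames(sc$scores) %in% md$barcode[!is.na(md$clone_id)]
  amp <- mean(sc$scores[interior, clone_cells])
  expect_equal(amp, 1.0, tolerance = 0.3)
  # reference cells stay near zero in the same region
  refsel <- colnames(sc$scores) %in% ref
  expect_lt(abs(mean(sc$scores[interior, refsel])), 0.15)
})

test_that("infer_cna_scores enforces its contracts", {
  co <- tiny_cohort()
  cm <- tiny_cm()
  expect_error(infer_cna_scores(cm, co$annotation, character()), "empty")
  expect_error(infer_cna_scores(cm, co$annotation, "nope"), "missing")
  expect_error(infer_cna_scores(cm, co$annotation, tiny_ref_cells(),
                                smoothing_genes = 50), "odd")
  # chrM genes are excluded from the genomic ordering
  expect_false(any(tiny_scores()$annotation$chrom == "chrM"))
})

test_that("trichotomize: boundary handling and literal mode", {
  p <- window_profile_obj(data.frame(chrom = "chr1", start = 0, end = 1e7),
                          matrix(c(1.0, 1.5, 0.9, 1.04), 4),
                          paste0("c", 1:4), scale = "ratio")
  calls <- trichotomize(p, 0.05)
  expect_equal(unname(calls[, 1]), c("neutral", "gain", "loss", "neutral"))
  lit <- trichotomize(p, 0)
  expect_equal(unname(lit[, 1]), c("neutral", "gain", "loss", "gain"))
  expect_error(trichotomize(p, -0.1), "non-negative")
})

test_that("cell_bulk_kappa: identity, constant convention, missing windows", {
  w <- data.frame(chrom = "chr1", start = (0:3) * 1e7, end = (1:4) * 1e7)
  cells <- window_profile_obj(w, rbind(c(2, 1, 0.5, 1), c(1, 1, 1, 1),
                                       c(2, 1, NA, 1)),
                              paste0("c", 1:3), scale = "ratio")
  bulk <- window_profile_obj(w, matrix(c(2, 1, 0.5, 1), 1), "bulk",
                             scale = "ratio")
  ck <- trichotomize(cells, 0.05)
  bk <- trichotomize(bulk, 0.05)
  kap <- cell_bulk_kappa(ck, bk)
  expect_equal(unname(kap["c1"]), 1)            # identical tracks
  expect_equal(unname(kap["c3"]), 1)            # NA window dropped pairwise
  # all-neutral cell vs all-neutral bulk: constant-equal convention
  bk2 <- trichotomize(window_profile_obj(w, matrix(1, 1, 4), "bulk",
                                         scale = "ratio"), 0.05)
  expect_equal(unname(cell_bulk_kappa(ck, bk2)["c2"]), 1)
})

test_that("malignancy classification: null case and order-statistic bound", {
  w <- data.frame(chrom = "chr1", start = (0:9) * 1e7, end = (1:10) * 1e7)
  zero <- window_profile_obj(w, matrix(0, 6, 10), paste0("c", 1:6),
                             scale = "centered")
  r0 <- classify_malignant_clusters(zero, rep("k", 6), literal = TRUE)
  expect_false(r0$malignant)                     # 10th pct 0, not > 0

  # >= 95% of values at |v| >= 0.5 -> malignant for any threshold < 0.5
  vals <- matrix(0.6, 4, 10)
  vals[1, 1:2] <- 0
  hot <- window_profile_obj(w, vals, paste0("c", 1:4), scale = "centered")
  r1 <- classify_malignant_clusters(hot, rep("k", 4), threshold = 0.4)
  expect_true(r1$malignant)
  expect_error(classify_malignant_clusters(hot, rep("k", 4)), "required")
})

test_that("subpop_cna_test: directional consistency and undefined marker", {
  w <- data.frame(chrom = "chr1", start = 0, end = 1e7)
  p <- window_profile_obj(w, matrix(seq(0.5, 0.9, length.out = 8), 8),
                          paste0("c", 1:8), scale = "ratio")
  # all values < 1: gain direction gives the whole tail
  expect_equal(subpop_cna_test(p, paste0("c", 1:8), 1, "gain"), 1)
  expect_equal(subpop_cna_test(p, paste0("c", 1:8), 1, "loss"), 0.5^8)
  # fewer than min_cells informative -> NA
  expect_true(is.na(subpop_cna_test(p, paste0("c", 1:3), 1, "gain")))
  expect_error(subpop_cna_test(p, paste0("c", 1:8), "chrX:0-1", "gain"),
               "unknown window")
})

test_that("bulk_window_track matches the synthetic derivation operator", {
  seg <- validate_segments(data.frame(chrom = "chr1", start = 0, end = 5e6,
                                      copy_ratio = 3))
  genome <- data.frame(chrom = "chr1", length = 20e6)
  bt <- bulk_window_track(seg, genome)
  expect_equal(unname(bt$values[1, ]), c(2.0, 1.0))  # half-window at 3
})
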