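## Expression-based copy-number inference and bulk-concordance scoring.
##
## The inference operator is a deliberate, documented simplification of the
## reference-normalized smoothing approach used by inferCNV-style tools:
## CP10k -> log2 -> subtract reference-cell mean per gene -> clip +/-3 ->
## centered moving average over genomically ordered genes (per chromosome)
## -> per-cell median re-centering. Exact parity with any external tool is
## a non-goal; the operator's behaviour is fully specified here.

#' Construct a genomic window profile
#'
#' A per-entity (cell, sample or bulk) vector of CNA values over fixed
#' windows tiling the genome. Values are either on the `ratio` scale
#' (neutral = 1) or the `centered` log2 scale (neutral = 0); the scale is
#' carried explicitly.
#'
#' @param windows data.frame(chrom, start, end) tiling each chromosome
#'   without overlap.
#' @param values numeric matrix, entities x windows; `NA` marks windows
#'   with no information (e.g., no genes).
#' @param entities entity identifiers (row names).
#' @param scale `"ratio"` or `"centered"`.
#' @param gene_count optional genes per window (used by windowing).
#' @return an object of class `window_profile`.
#' @export
window_profile_obj <- function(windows, values, entities,
                               scale = c("centered", "ratio"),
                               gene_count = NULL) {
  scale <- match.arg(scale)
  values <- matrix(values, nrow = length(entities))
  if (ncol(values) != nrow(windows))
    stop("values columns must match window count", call. = FALSE)
  rownames(values) <- entities
  colnames(values) <- sprintf("%s:%d-%d", windows$chrom,
                              as.integer(windows$start),
                              as.integer(windows$end))
  structure(list(windows = windows, values = values, entities = entities,
                 scale = scale, gene_count = gene_count),
            class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat("window_profile: ", length(x$entities), " entities x ",
      nrow(x$windows), " windows (", x$scale, " scale)\n", sep = "")
  invisible(x)
}

#' Convert a window profile between ratio and centered scales
#' @param profile a `window_profile`.
#' @param scale target scale.
#' @return the converted profile (`ratio = 2^centered`).
#' @export
profile_as_scale <- function(profile, scale = c("ratio", "centered")) {
  scale <- match.arg(scale)
  if (profile$scale == scale) return(profile)
  v <- if (scale == "ratio") 2^profile$values else log2(profile$values)
  window_profile_obj(profile$windows, v, profile$entities, scale,
                     profile$gene_count)
}

#' Infer per-gene CNA scores from expression
#'
#' Reference-normalized smoothed expression deviations: cells of the
#' reference population (typically immune cells, assumed diploid) define
#' the per-gene baseline. Steps: CP10k log2 normalization; subtraction of
#' the reference-cell mean per gene; clipping to `[-clip, clip]`; a
#' centered moving average of `smoothing_genes` genes along each
#' chromosome (window truncated at chromosome ends); per-cell re-centering
#' by the cell's median smoothed score. Genes without coordinates on a
#' retained chromosome, and chromosomes with fewer than 3 positioned
#' genes, are excluded (reported via message).
#'
#' @param cm a [CountMatrix].
#' @param annotation gene annotation (gene_id, chrom, start, end).
#' @param reference_cells barcodes of the reference (diploid) population.
#' @param smoothing_genes odd moving-average span (default 101 genes).
#' @param clip residual clip bound on the log2 scale (default 3).
#' @param exclude_chroms chromosomes never used (default `"chrM"`).
#' @param chrom_order optional chromosome order; defaults to order of
#'   first appearance in `annotation`.
#' @return an object of class `cna_scores`: list(scores = genes x cells
#'   centered log2 matrix in genomic order, annotation = the retained,
#'   ordered annotation).
#' @export
infer_cna_scores <- function(cm, annotation, reference_cells,
                             smoothing_genes = 101, clip = 3,
                             exclude_chroms = "chrM",
                             chrom_order = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (!length(reference_cells)) stop("empty reference set", call. = FALSE)
  if (!all(reference_cells %in% cm$barcodes))
    stop("reference barcodes missing from matrix", call. = FALSE)
  if (smoothing_genes < 1 || smoothing_genes %% 2 == 0)
    stop("smoothing_genes must be a positive odd integer", call. = FALSE)
  ann <- annotation[match(cm$gene_ids, annotation$gene_id), ]
  keep <- !is.na(ann$gene_id) & !(ann$chrom %in% exclude_chroms)
  n_drop <- sum(!keep)
  if (n_drop) message("infer_cna_scores: excluding ", n_drop,
                      " genes without usable coordinates")
  ann <- ann[keep, ]
  tab <- table(ann$chrom)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    message("infer_cna_scores: excluding chromosomes with < 3 genes: ",
            paste(small, collapse = ", "))
    keep2 <- !(ann$chrom %in% small)
    ann <- ann[keep2, ]
  }
  if (is.null(chrom_order)) chrom_order <- unique(annotation$chrom)
  o <- order(match(ann$chrom, chrom_order), ann$start)
  ann <- ann[o, ]
  if (nrow(ann) < smoothing_genes)
    stop("fewer positioned genes than the smoothing span", call. = FALSE)

  E <- cp10k_log(cm)[ann$gene_id, , drop = FALSE]
  ref_mean <- rowMeans(E[, reference_cells, drop = FALSE])
  R <- E - ref_mean
  R[R > clip] <- clip
  R[R < -clip] <- -clip

  h <- (smoothing_genes - 1) / 2
  S <- R
  for (ch in unique(ann$chrom)) {
    idx <- which(ann$chrom == ch)
    g <- length(idx)
    ## running row sums without apply()'s aperm overhead
    cs <- matrix(0, g + 1L, ncol(R))
    for (r in seq_len(g)) cs[r + 1L, ] <- cs[r, ] + R[idx[r], ]
    i <- seq_len(g)
    lo <- pmax(1L, i - h)
    hi <- pmin(g, i + h)
    S[idx, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1)
  }
  med <- apply(S, 2, stats::median)
  S <- sweep(S, 2, med, `-`)
  structure(list(scores = S, annotation = ann), class = "cna_scores")
}

#' Average gene-level CNA scores into fixed genomic windows
#'
#' Genes are assigned to the window containing their midpoint; a window's
#' value is the unweighted mean of its member genes' scores. Windows
#' without genes are `NA` (missing, not neutral) and are excluded from
#' downstream kappa computations.
#'
#' @param scores a `cna_scores` object.
#' @param width window width in bp (default 10 Mb).
#' @param out_scale `"centered"` (log2, neutral 0) or `"ratio"`
#'   (`2^centered`, neutral 1).
#' @param genome optional data.frame(chrom, length); defaults to the span
#'   of annotated genes rounded up to whole windows.
#' @return a `window_profile` with one entity per cell.
#' @export
window_profile <- function(scores, width = 10e6,
                           out_scale = c("centered", "ratio"),
                           genome = NULL) {
  out_scale <- match.arg(out_scale)
  if (width <= 0) stop("window width must be positive", call. = FALSE)
  ann <- scores$annotation
  if (is.null(genome)) {
    chroms <- unique(ann$chrom)
    genome <- data.frame(
      chrom = chroms,
      length = vapply(chroms, function(ch)
        ceiling(max(ann$end[ann$chrom == ch]) / width) * width, numeric(1)),
      stringsAsFactors = FALSE)
  }
  windows <- make_windows(genome, width)
  mid <- (ann$start + ann$end) / 2
  widx <- rep(NA_integer_, nrow(ann))
  for (w in seq_len(nrow(windows))) {
    hit <- ann$chrom == windows$chrom[w] & mid >= windows$start[w] &
      mid < windows$end[w]
    widx[hit] <- w
  }
  n_cells <- ncol(scores$scores)
  vals <- matrix(NA_real_, n_cells, nrow(windows))
  counts <- integer(nrow(windows))
  for (w in seq_len(nrow(windows))) {
    g <- which(widx == w)
    counts[w] <- length(g)
    if (length(g))
      vals[, w] <- colMeans(scores$scores[g, , drop = FALSE])
  }
  prof <- window_profile_obj(windows, vals,
                             entities = colnames(scores$scores),
                             scale = "centered", gene_count = counts)
  profile_as_scale(prof, out_scale)
}

#' Window profile of a bulk copy-number segment table
#'
#' Base-weighted mean copy ratio of the segments over each window;
#' uncovered bases are neutral (ratio 1). The same operator used to derive
#' synthetic bulk truth, applied to an observed bulk WGS segment table.
#'
#' @param segments a `SegmentTable` (chrom, start, end, copy_ratio).
#' @param genome data.frame(chrom, length).
#' @param width window width in bp (default 10 Mb).
#' @return a one-entity `window_profile` on the ratio scale.
#' @export
bulk_window_track <- function(segments, genome, width = 10e6) {
  windows <- make_windows(genome, width)
  vals <- .segment_window_means(segments, windows)
  window_profile_obj(windows, matrix(vals, 1), entities = "bulk",
                     scale = "ratio")
}

#' Classify window values as gain / neutral / loss
#'
#' On the ratio scale: gain if value > 1 + epsilon, loss if value <
#' 1 - epsilon, neutral otherwise (so a value of exactly 1 is neutral).
#' `epsilon = 0` is the literal trichotomy, under which continuous scores
#' are almost never neutral; the default 0.05 treats ratios within 5% of
#' diploid as neutral.
#'
#' @param profile a `window_profile` (converted to ratio scale if needed).
#' @param epsilon non-negative neutral half-width on the ratio scale.
#' @return matrix (entities x windows) of calls in
#'   `{"gain","neutral","loss"}`; `NA` propagated.
#' @export
trichotomize <- function(profile, epsilon = 0.05) {
  if (epsilon < 0) stop("epsilon must be non-negative", call. = FALSE)
  v <- profile_as_scale(profile, "ratio")$values
  calls <- matrix(NA_character_, nrow(v), ncol(v), dimnames = dimnames(v))
  calls[!is.na(v)] <- "neutral"
  calls[!is.na(v) & v > 1 + epsilon] <- "gain"
  calls[!is.na(v) & v < 1 - epsilon] <- "loss"
  calls
}

#' Per-cell Cohen's kappa against a bulk call track
#'
#' For each cell, agreement between its gain/neutral/loss track and the
#' bulk track over the windows non-missing in both; fewer than 2 shared
#' windows yields `NA`. Constant-and-equal tracks (e.g., all-neutral vs
#' all-neutral) score 1 by the degenerate-kappa convention.
#'
#' @param cell_calls call matrix from [trichotomize()] (cells x windows).
#' @param bulk_calls one-row call matrix over the same windows.
#' @return named numeric vector of kappa per cell.
#' @export
cell_bulk_kappa <- function(cell_calls, bulk_calls) {
  if (is.matrix(bulk_calls)) bulk_calls <- bulk_calls[1, ]
  if (length(bulk_calls) != ncol(cell_calls))
    stop("window sets differ between cell and bulk tracks", call. = FALSE)
  apply(cell_calls, 1, function(cc) {
    ok <- !is.na(cc) & !is.na(bulk_calls)
    if (sum(ok) < 2) return(NA_real_)
    cohens_kappa(cc[ok], bulk_calls[ok])
  })
}

#' Data-driven malignancy threshold from reference cells
#'
#' The malignancy rule compares a cluster's 10th percentile of absolute
#' window scores against a noise floor. The floor is that same statistic
#' computed on the pooled reference (diploid) cells, inflated by a small
#' margin for sampling fluctuation. See the package vignette for why the
#' floor must sit at the matched percentile rather than deep in the noise
#' distribution.
#'
#' @param profile a centered-scale `window_profile` over all cells.
#' @param reference_cells barcodes of the reference population.
#' @param percentile percentile used by the rule (default 10).
#' @param margin multiplicative safety margin (default 1.1).
#' @return the threshold on the absolute centered score scale.
#' @export
malignancy_threshold <- function(profile, reference_cells, percentile = 10,
                                 margin = 1.1) {
  profile <- profile_as_scale(profile, "centered")
  v <- profile$values[rownames(profile$values) %in% reference_cells, ,
                      drop = FALSE]
  if (!length(v)) stop("no reference cells in profile", call. = FALSE)
  margin * stats::quantile(abs(v), percentile / 100, na.rm = TRUE,
                           names = FALSE)
}

#' Flag malignant clusters by the percentile rule
#'
#' A cluster is malignant when the `percentile`-th percentile (linear
#' interpolation) of the absolute values of all its cells' window scores
#' exceeds `threshold`. With `literal = TRUE` the threshold is 0, the
#' strict reading of the rule, under which any continuous noise flags
#' every cluster; the default uses a reference-derived noise floor
#' ([malignancy_threshold()]).
#'
#' @param profile a centered-scale `window_profile` over all cells.
#' @param clusters cluster label per cell (aligned with profile entities).
#' @param percentile percentile of pooled absolute scores (default 10).
#' @param threshold noise floor; if `NULL`, computed from
#'   `reference_cells`.
#' @param reference_cells reference barcodes (needed when `threshold` is
#'   `NULL` and `literal` is `FALSE`).
#' @param margin passed to [malignancy_threshold()].
#' @param literal use the strict `> 0` rule.
#' @return data.frame(cluster, score, threshold, malignant); empty
#'   clusters are skipped.
#' @export
classify_malignant_clusters <- function(profile, clusters, percentile = 10,
                                        threshold = NULL,
                                        reference_cells = NULL,
                                        margin = 1.1, literal = FALSE) {
  profile <- profile_as_scale(profile, "centered")
  if (length(clusters) != length(profile$entities))
    stop("clusters must align with profile entities", call. = FALSE)
  if (literal) threshold <- 0
  if (is.null(threshold)) {
    if (is.null(reference_cells))
      stop("either threshold or reference_cells is required", call. = FALSE)
    threshold <- malignancy_threshold(profile, reference_cells, percentile,
                                      margin)
  }
  out <- lapply(unique(as.character(clusters)), function(cl) {
    v <- abs(profile$values[clusters == cl, , drop = FALSE])
    v <- v[!is.na(v)]
    if (!length(v)) {
      message("classify_malignant_clusters: skipping empty cluster ", cl)
      return(NULL)
    }
    q <- stats::quantile(v, percentile / 100, names = FALSE)
    data.frame(cluster = cl, score = q, threshold = threshold,
               malignant = q > threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Directional sign test for a subpopulation's gain or loss
#'
#' Tests whether the named cells' window values sit above (gain) or below
#' (loss) the neutral ratio 1, by the exact one-sample sign test. Cells
#' with a missing value in the window are dropped; fewer than `min_cells`
#' informative cells yields `NA` (undefined).
#'
#' @param profile a `window_profile` (ratio scale; converted if centered).
#' @param cells barcodes of the subpopulation.
#' @param window window index or `"chrom:start-end"` label.
#' @param direction `"gain"` or `"loss"`.
#' @param min_cells minimum informative cells (default 5).
#' @return the sign-test p-value, or `NA` if undefined.
#' @export
subpop_cna_test <- function(profile, cells, window,
                            direction = c("gain", "loss"), min_cells = 5) {
  direction <- match.arg(direction)
  profile <- profile_as_scale(profile, "ratio")
  w <- if (is.character(window)) match(window, colnames(profile$values))
       else as.integer(window)
  if (is.na(w) || w < 1 || w > ncol(profile$values))
    stop("unknown window: ", window, call. = FALSE)
  v <- profile$values[rownames(profile$values) %in% cells, w]
  v <- v[!is.na(v)]
  if (length(v) < min_cells) return(NA_real_)
  sign_test(v, 1, if (direction == "gain") "greater" else "less")
}
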