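## Correlation-centroid cell-type annotation with a confidence score, the
## cross-platform confidence comparison, and the composition test. The
## annotator is a stand-in exercising the same comparison machinery as
## anchor- or reference-based transfer tools; its confidence is a
## normalized correlation margin, not any external tool's score.

#' Build reference centroids
#'
#' Per cell type, the mean CP10k-log expression over a gene panel; the
#' default panel is the `n_panel` most variable genes of the reference.
#'
#' @param reference a [CountMatrix] of labelled reference cells.
#' @param labels cell-type label per reference cell (no NAs; every type
#'   needs >= 2 cells).
#' @param panel optional explicit gene panel; default: top `n_panel` genes
#'   by variance of CP10k-log expression.
#' @param n_panel panel size when `panel` is `NULL` (default 200).
#' @return list(centroids = genes x types matrix, panel = gene ids).
#' @export
build_centroids <- function(reference, labels, panel = NULL,
                            n_panel = 200) {
  stopifnot(inherits(reference, "CountMatrix"))
  if (anyNA(labels)) stop("unlabeled reference cells", call. = FALSE)
  if (length(labels) != length(reference$barcodes))
    stop("labels must align with reference cells", call. = FALSE)
  tab <- table(labels)
  if (any(tab < 2))
    stop("every label needs >= 2 cells; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  E <- cp10k_log(reference)
  if (is.null(panel)) {
    v <- apply(E, 1, stats::var)
    panel <- reference$gene_ids[order(v, decreasing = TRUE)[
      seq_len(min(n_panel, nrow(E)))]]
  } else if (!all(panel %in% reference$gene_ids)) {
    stop("panel genes missing from reference", call. = FALSE)
  }
  Ep <- E[panel, , drop = FALSE]
  cents <- vapply(sort(unique(labels)), function(l)
    rowMeans(Ep[, labels == l, drop = FALSE]), numeric(length(panel)))
  list(centroids = cents, panel = panel)
}

#' Transfer labels to query cells by centroid correlation
#'
#' Per query cell, the Spearman correlation of its CP10k-log panel-gene
#' expression with each centroid; the assigned type is the argmax and the
#' confidence is the normalized margin
#' `(r_best - r_second) / max(1 - r_second, 1e-8)` clipped to `[0, 1]`.
#' Panel genes absent from the query (FFPE panel restriction) are dropped;
#' fewer than `min_overlap` of the panel remaining is an error. Ties are
#' broken towards the lexicographically first type (reported via message).
#'
#' @param query a [CountMatrix].
#' @param centroids output of [build_centroids()].
#' @param min_overlap minimum retained panel fraction (default 0.25).
#' @return data.frame(barcode, cell_type, confidence).
#' @export
transfer_labels <- function(query, centroids, min_overlap = 0.25) {
  stopifnot(inherits(query, "CountMatrix"))
  shared <- intersect(centroids$panel, query$gene_ids)
  ## panel genes undetected across the whole query are structural holes
  ## (probe-panel restriction), not biology: drop them from the
  ## correlation. Transfer platforms separately so holes are per-assay.
  detected <- query$gene_ids[Matrix::rowSums(query$counts) > 0]
  n_hole <- length(setdiff(shared, detected))
  if (n_hole)
    message("transfer_labels: dropping ", n_hole,
            " panel genes undetected in the query")
  shared <- intersect(shared, detected)
  frac <- length(shared) / length(centroids$panel)
  if (frac < min_overlap)
    stop(sprintf(
      "only %.0f%% of the %d panel genes are present in the query (need %.0f%%)",
      100 * frac, length(centroids$panel), 100 * min_overlap),
      call. = FALSE)
  E <- cp10k_log(subset_cm(query, genes = shared))
  C <- centroids$centroids[shared, , drop = FALSE]
  types <- colnames(C)
  if (length(types) == 1)
    return(data.frame(barcode = query$barcodes, cell_type = types,
                      confidence = 1, stringsAsFactors = FALSE))
  r <- stats::cor(E, C, method = "spearman")   # cells x types
  r[is.na(r)] <- 0                              # constant cells
  best <- max.col(r, ties.method = "first")
  n_tied <- sum(apply(r, 1, function(z) sum(z == max(z)) > 1))
  if (n_tied)
    message("transfer_labels: ", n_tied,
            " cells with tied best correlation; lexicographic tie-break")
  second <- vapply(seq_len(nrow(r)), function(i)
    max(r[i, -best[i]]), numeric(1))
  rb <- r[cbind(seq_len(nrow(r)), best)]
  conf <- (rb - second) / pmax(1 - second, 1e-8)
  conf <- pmin(1, pmax(0, conf))
  data.frame(barcode = query$barcodes, cell_type = types[best],
             confidence = conf, stringsAsFactors = FALSE)
}

#' Compare annotation confidence across platforms per cell type
#'
#' Per cell type, an ordinary least-squares fit of confidence on a
#' platform indicator plus sample indicators (fixed-effect adjustment for
#' the matched design; a deliberate, documented simplification of
#' mixed-model fits). The platform effect is reported with its two-sided
#' t-test p-value, and q-values across cell types come from [bh_fdr()].
#' Cell types observed on one platform only are skipped.
#'
#' @param annotation data.frame(barcode, cell_type, confidence) covering
#'   both platforms (e.g., row-bound [transfer_labels()] outputs).
#' @param metadata per-cell metadata (barcode, sample_id, platform).
#' @return data.frame(cell_type, effect_ffpe, p, q, n_ffpe, n_frozen);
#'   effect > 0 means higher confidence on FFPE.
#' @export
compare_confidence <- function(annotation, metadata) {
  md <- metadata[match(annotation$barcode, metadata$barcode), ]
  rows <- lapply(sort(unique(annotation$cell_type)), function(ct) {
    sel <- annotation$cell_type == ct
    pf <- md$platform[sel]
    if (length(unique(pf)) < 2) {
      message("compare_confidence: '", ct, "' on one platform only; skipped")
      return(NULL)
    }
    d <- data.frame(conf = annotation$confidence[sel],
                    ffpe = as.numeric(pf == "FFPE"),
                    sample = factor(md$sample_id[sel]))
    fit <- if (nlevels(d$sample) > 1)
      stats::lm(conf ~ ffpe + sample, data = d)
    else stats::lm(conf ~ ffpe, data = d)
    co <- summary(fit)$coefficients
    if (!("ffpe" %in% rownames(co))) return(NULL)
    data.frame(cell_type = ct, effect_ffpe = co["ffpe", 1],
               p = co["ffpe", 4], n_ffpe = sum(d$ffpe),
               n_frozen = sum(1 - d$ffpe), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no cell type present on both platforms",
                         call. = FALSE)
  out$q <- bh_fdr(out$p)
  out[, c("cell_type", "effect_ffpe", "p", "q", "n_ffpe", "n_frozen")]
}

#' Test cell-type composition differences between platforms
#'
#' Builds the 2 (platform) x J (cell type) x K (matched sample) stratified
#' table and applies the generalized Cochran-Mantel-Haenszel test
#' ([cmh_test()]). Samples present on a single platform are dropped.
#'
#' @param metadata per-cell metadata with sample_id, platform, cell_type.
#' @return list(statistic, df, p.value, n_strata_used).
#' @export
composition_test <- function(metadata) {
  if (is.null(metadata$cell_type))
    stop("metadata lacks cell_type", call. = FALSE)
  types <- sort(unique(metadata$cell_type))
  tabs <- list()
  for (s in unique(metadata$sample_id)) {
    m <- metadata[metadata$sample_id == s, ]
    if (length(unique(m$platform)) < 2) {
      message("composition_test: sample ", s,
              " on one platform only; stratum dropped")
      next
    }
    t <- matrix(0, 2, length(types),
                dimnames = list(c("FROZEN", "FFPE"), types))
    cnt <- table(m$platform, m$cell_type)
    t[rownames(cnt), colnames(cnt)] <- cnt
    tabs[[s]] <- t
  }
  if (!length(tabs)) stop("no matched sample pairs", call. = FALSE)
  cmh_test(tabs)
}
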