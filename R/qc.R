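## Per-cell quality control: metrics and the four exclusion rules
## (low UMI, low gene count, high mitochondrial fraction, doublet).

#' Compute per-cell QC metrics
#'
#' @param cm a [CountMatrix].
#' @param annotation gene annotation with `is_mito`; genes absent from the
#'   annotation count as non-mitochondrial (reported via message).
#' @param doublet_flags optional logical per cell (aligned with barcodes);
#'   doublet calling itself happens upstream.
#' @return data.frame(barcode, umi_count, genes_detected, mito_fraction,
#'   doublet_flag).
#' @export
compute_qc_metrics <- function(cm, annotation, doublet_flags = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  is_mito <- annotation$is_mito[match(cm$gene_ids, annotation$gene_id)]
  n_missing <- sum(is.na(is_mito))
  if (n_missing)
    message("compute_qc_metrics: ", n_missing,
            " genes not in annotation; treated as non-mitochondrial")
  is_mito[is.na(is_mito)] <- FALSE
  umi <- Matrix::colSums(cm$counts)
  genes <- Matrix::colSums(cm$counts > 0)
  mito_umi <- Matrix::colSums(cm$counts[is_mito, , drop = FALSE])
  mito_frac <- ifelse(umi > 0, mito_umi / umi, 0)
  if (is.null(doublet_flags)) doublet_flags <- rep(FALSE, length(umi))
  data.frame(barcode = cm$barcodes, umi_count = as.numeric(umi),
             genes_detected = as.numeric(genes),
             mito_fraction = as.numeric(mito_frac),
             doublet_flag = as.logical(doublet_flags),
             stringsAsFactors = FALSE)
}

## dispersion of x around its median: the scaled median absolute deviation
## (the scRNA-seq convention) or the literal mean absolute deviation
.mad_stat <- function(x, type, constant) {
  dev <- abs(x - stats::median(x))
  if (type == "median") constant * stats::median(dev) else mean(dev)
}

#' MAD-based per-library cell filtering
#'
#' A cell is excluded when any of: UMI count strictly below the library
#' median minus `n_mads` deviations; detected genes strictly below the
#' corresponding bound; mitochondrial fraction strictly above `mito_max`;
#' or it is flagged as a doublet. Thresholds are computed once per call
#' (per sample-by-platform library), so filtering is idempotent on the
#' kept cells under the frozen thresholds.
#'
#' "Deviation" defaults to the scaled median absolute deviation
#' (`constant` 1.4826, the single-cell QC convention); `mad_type = "mean"`
#' gives the literal mean absolute deviation about the median.
#'
#' @param metrics output of [compute_qc_metrics()] for ONE library.
#' @param n_mads number of deviations (default 3).
#' @param mito_max mitochondrial-fraction ceiling (default 0.10).
#' @param mad_type `"median"` (scaled MAD) or `"mean"`.
#' @param constant consistency constant for the scaled MAD.
#' @return data.frame(barcode, keep, reasons) plus attributes
#'   `thresholds` (the frozen cutoffs).
#' @export
mad_filter <- function(metrics, n_mads = 3, mito_max = 0.10,
                       mad_type = c("median", "mean"), constant = 1.4826) {
  mad_type <- match.arg(mad_type)
  if (!nrow(metrics)) stop("empty library", call. = FALSE)
  umi_cut <- stats::median(metrics$umi_count) -
    n_mads * .mad_stat(metrics$umi_count, mad_type, constant)
  gene_cut <- stats::median(metrics$genes_detected) -
    n_mads * .mad_stat(metrics$genes_detected, mad_type, constant)
  low_umi <- metrics$umi_count < umi_cut
  low_gene <- metrics$genes_detected < gene_cut
  high_mito <- metrics$mito_fraction > mito_max
  doublet <- isTRUE_vec(metrics$doublet_flag)
  reasons <- mapply(function(a, b, c, d)
    paste(c(if (a) "low_umi", if (b) "low_genes", if (c) "high_mito",
            if (d) "doublet"), collapse = ";"),
    low_umi, low_gene, high_mito, doublet)
  out <- data.frame(barcode = metrics$barcode,
                    keep = !(low_umi | low_gene | high_mito | doublet),
                    reasons = reasons, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(umi = umi_cut, genes = gene_cut,
                               mito = mito_max)
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Run QC per library over a whole cohort
#'
#' Splits cells by sample and platform, applies [mad_filter()] within each
#' library, and returns the combined table.
#'
#' @param cm a [CountMatrix] covering all cells.
#' @param annotation gene annotation.
#' @param metadata per-cell metadata (barcode, sample_id, platform,
#'   optional doublet_flag).
#' @param ... passed to [mad_filter()].
#' @return data.frame with per-cell metrics, keep flag and reasons.
#' @export
qc_cohort <- function(cm, annotation, metadata, ...) {
  metadata <- metadata[match(cm$barcodes, metadata$barcode), ]
  met <- compute_qc_metrics(cm, annotation, metadata$doublet_flag)
  lib <- paste(metadata$sample_id, metadata$platform, sep = "_")
  parts <- lapply(split(seq_len(nrow(met)), lib), function(idx) {
    f <- mad_filter(met[idx, ], ...)
    cbind(met[idx, ], f[, c("keep", "reasons")],
          library = lib[idx][1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out[match(cm$barcodes, out$barcode), ]
}
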