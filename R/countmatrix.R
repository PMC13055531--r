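#' Construct a CountMatrix
#'
#' The universal carrier of raw expression data between pipeline stages: a
#' sparse genes-by-cells matrix of non-negative integer UMI counts together
#' with gene identifiers, display symbols, and cell barcodes.
#'
#' @param counts a genes x cells matrix coercible to a sparse `dgCMatrix`;
#'   all entries must be non-negative integers.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param gene_symbols character vector of gene symbols, same length as
#'   `gene_ids`; defaults to `gene_ids`.
#' @param barcodes character vector of unique cell barcodes (columns).
#' @return an object of class `CountMatrix`.
#' @export
CountMatrix <- function(counts, gene_ids, gene_symbols = gene_ids, barcodes) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  gene_ids <- as.character(gene_ids)
  gene_symbols <- as.character(gene_symbols)
  barcodes <- as.character(barcodes)
  if (nrow(counts) != length(gene_ids))
    stop("counts has ", nrow(counts), " rows but ", length(gene_ids),
         " gene_ids", call. = FALSE)
  if (ncol(counts) != length(barcodes))
    stop("counts has ", ncol(counts), " columns but ", length(barcodes),
         " barcodes", call. = FALSE)
  if (length(gene_symbols) != length(gene_ids))
    stop("gene_symbols length differs from gene_ids", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_ids", call. = FALSE)
  if (anyDuplicated(barcodes))
    stop("duplicate barcodes", call. = FALSE)
  x <- counts@x
  if (length(x) && (min(x) < 0 || any(x != round(x))))
    stop("counts must be non-negative integers", call. = FALSE)
  dimnames(counts) <- list(gene_ids, barcodes)
  structure(list(counts = counts, gene_ids = gene_ids,
                 gene_symbols = gene_symbols, barcodes = barcodes),
            class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells (", length(x$counts@x), " stored counts)\n", sep = "")
  invisible(x)
}

#' Subset a CountMatrix by genes and/or cells
#'
#' @param x a `CountMatrix`.
#' @param genes gene ids or row indices to keep (default all).
#' @param cells barcodes or column indices to keep (default all).
#' @return a `CountMatrix` restricted to the selection, order as given.
#' @export
subset_cm <- function(x, genes = NULL, cells = NULL) {
  gi <- if (is.null(genes)) seq_along(x$gene_ids) else
    if (is.character(genes)) match(genes, x$gene_ids) else genes
  ci <- if (is.null(cells)) seq_along(x$barcodes) else
    if (is.character(cells)) match(cells, x$barcodes) else cells
  if (anyNA(gi)) stop("unknown gene id in selection", call. = FALSE)
  if (anyNA(ci)) stop("unknown barcode in selection", call. = FALSE)
  CountMatrix(x$counts[gi, ci, drop = FALSE], x$gene_ids[gi],
              x$gene_symbols[gi], x$barcodes[ci])
}

#' Column-bind CountMatrix objects sharing a gene universe
#'
#' @param ... `CountMatrix` objects with identical `gene_ids`.
#' @return the concatenated `CountMatrix`.
#' @export
cbind_cm <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && is.list(ms[[1]]) && !inherits(ms[[1]], "CountMatrix"))
    ms <- ms[[1]]
  ids <- ms[[1]]$gene_ids
  for (m in ms[-1])
    if (!identical(m$gene_ids, ids))
      stop("gene universes differ; cannot bind", call. = FALSE)
  CountMatrix(do.call(cbind, lapply(ms, `[[`, "counts")), ids,
              ms[[1]]$gene_symbols, unlist(lapply(ms, `[[`, "barcodes")))
}

#' Library-size normalized log expression
#'
#' Counts-per-10k followed by log2(x + 1), the normalization used by every
#' expression-level operation in the package (CNA scoring, centroids,
#' marker scores).
#'
#' @param x a `CountMatrix` or a sparse/dense numeric matrix (genes x cells).
#' @param scale library-size target (default 1e4).
#' @return a dense genes x cells matrix of log2 CP10k values; all-zero cells
#'   are left at zero.
#' @export
cp10k_log <- function(x, scale = 1e4) {
  m <- if (inherits(x, "CountMatrix")) x$counts else x
  tot <- Matrix::colSums(m)
  tot[tot == 0] <- 1
  out <- as.matrix(m %*% Matrix::Diagonal(x = scale / tot))
  dimnames(out) <- dimnames(m)
  log2(out + 1)
}
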