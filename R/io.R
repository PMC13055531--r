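## External formats. Coordinates are 0-based half-open (BED convention)
## throughout the package: a gene on [start, end) covers bases
## start .. end-1, and genomic windows tile from 0.

.open_maybe_gz <- function(dir, base) {
  for (f in file.path(dir, c(base, paste0(base, ".gz"))))
    if (file.exists(f)) return(f)
  stop("missing file '", base, "' (or '", base, ".gz') in ", dir,
       call. = FALSE)
}

#' Read a 10x-convention matrix triplet
#'
#' Reads `matrix.mtx`, `features.tsv` and `barcodes.tsv` (optionally
#' gzipped) from a directory, in the 10x Genomics CellRanger layout:
#' MatrixMarket integer coordinate matrix, features TSV with columns
#' (gene_id, gene_symbol[, feature_type]), one barcode per line.
#'
#' @param dir directory containing the three files.
#' @return a [CountMatrix].
#' @export
read_10x_triplet <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  mtx <- Matrix::readMM(.open_maybe_gz(dir, "matrix.mtx"))
  feats <- utils::read.table(.open_maybe_gz(dir, "features.tsv"),
                             sep = "\t", header = FALSE,
                             colClasses = "character", quote = "")
  bcs <- readLines(.open_maybe_gz(dir, "barcodes.tsv"))
  bcs <- bcs[nzchar(bcs)]
  if (nrow(feats) != nrow(mtx))
    stop("features.tsv has ", nrow(feats), " rows but matrix header says ",
         nrow(mtx), " genes", call. = FALSE)
  if (length(bcs) != ncol(mtx))
    stop("barcodes.tsv has ", length(bcs), " barcodes but matrix header ",
         "says ", ncol(mtx), " cells", call. = FALSE)
  sym <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
  CountMatrix(mtx, feats[[1]], sym, bcs)
}

#' Write a 10x-convention matrix triplet
#'
#' Inverse of [read_10x_triplet()]; files are written uncompressed as
#' integer MatrixMarket coordinate format plus features and barcodes TSV
#' (feature_type column fixed at "Gene Expression").
#'
#' @param x a [CountMatrix].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_10x_triplet <- function(x, dir) {
  stopifnot(inherits(x, "CountMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  m <- methods::as(x$counts, "TsparseMatrix")
  ## integer coordinate MatrixMarket, 1-based indices
  con <- file(file.path(dir, "matrix.mtx"), "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(m), ncol(m), length(m@x))), con)
  if (length(m@x)) {
    o <- order(m@j, m@i)
    writeLines(paste(m@i[o] + 1L, m@j[o] + 1L,
                     format(m@x[o], scientific = FALSE, trim = TRUE)), con)
  }
  close(con)
  utils::write.table(
    data.frame(x$gene_ids, x$gene_symbols, "Gene Expression"),
    file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  writeLines(x$barcodes, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a BED-like copy-number segment table
#'
#' Tab-separated columns: chrom, start, end, copy_ratio and optionally
#' clone_id. A leading '#'-prefixed header line is skipped. Coordinates are
#' 0-based half-open. Within one clone (or the unassigned bulk set),
#' segments on a chromosome must not overlap; the neutral copy ratio is 1.
#'
#' @param path file path.
#' @return a `data.frame` with columns chrom, start, end, copy_ratio,
#'   clone_id (`NA` when absent), classed `SegmentTable`.
#' @export
read_segments <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no records in ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 4)) stop("segment records need >= 4 tab-separated fields",
                          call. = FALSE)
  seg <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.numeric(vapply(parts, `[[`, "", 2L)),
    end = as.numeric(vapply(parts, `[[`, "", 3L)),
    copy_ratio = as.numeric(vapply(parts, `[[`, "", 4L)),
    clone_id = vapply(parts, function(p) if (length(p) >= 5) p[[5]]
                      else NA_character_, ""),
    stringsAsFactors = FALSE)
  validate_segments(seg)
}

#' Validate a segment table
#'
#' @param seg a data.frame with chrom, start, end, copy_ratio and optional
#'   clone_id columns.
#' @return the table, classed `SegmentTable`.
#' @export
validate_segments <- function(seg) {
  if (is.null(seg$clone_id)) seg$clone_id <- NA_character_
  if (anyNA(seg$start) || anyNA(seg$end) || anyNA(seg$copy_ratio))
    stop("non-numeric coordinate or copy_ratio field", call. = FALSE)
  if (any(seg$start >= seg$end))
    stop("segment with start >= end", call. = FALSE)
  if (any(seg$start < 0)) stop("negative segment start", call. = FALSE)
  if (any(seg$copy_ratio <= 0))
    stop("copy_ratio must be positive (neutral = 1)", call. = FALSE)
  grp <- paste(ifelse(is.na(seg$clone_id), "", seg$clone_id), seg$chrom)
  for (g in unique(grp)) {
    s <- seg[grp == g, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping segments within one clone on ", s$chrom[1],
           call. = FALSE)
  }
  class(seg) <- c("SegmentTable", "data.frame")
  seg
}

#' Write a segment table as BED-like TSV
#' @param seg a `SegmentTable` (or conforming data.frame).
#' @param path output path.
#' @export
write_segments <- function(seg, path) {
  con <- file(path, "w")
  writeLines("#chrom\tstart\tend\tcopy_ratio\tclone_id", con)
  writeLines(paste(seg$chrom, format(seg$start, scientific = FALSE, trim = TRUE),
                   format(seg$end, scientific = FALSE, trim = TRUE),
                   seg$copy_ratio,
                   ifelse(is.na(seg$clone_id), ".", seg$clone_id),
                   sep = "\t"), con)
  close(con)
  invisible(path)
}

#' Read per-gene genomic annotation
#'
#' TSV with header: gene_id, chrom, start, end, is_mito (logical or 0/1).
#' Coordinates 0-based half-open.
#'
#' @param path file path.
#' @return a `data.frame` (gene_id, chrom, start, end, is_mito).
#' @export
read_gene_annotation <- function(path) {
  a <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  validate_gene_annotation(a)
}

#' Validate gene annotation
#' @param a data.frame with gene_id, chrom, start, end, is_mito.
#' @return the validated data.frame.
#' @export
validate_gene_annotation <- function(a) {
  need <- c("gene_id", "chrom", "start", "end", "is_mito")
  if (!all(need %in% names(a)))
    stop("gene annotation needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(a$gene_id)) stop("duplicate gene_id in annotation",
                                     call. = FALSE)
  if (any(a$start < 0) || any(a$start >= a$end))
    stop("gene annotation requires 0 <= start < end", call. = FALSE)
  a$is_mito <- as.logical(a$is_mito)
  a
}

#' Read per-cell metadata
#'
#' TSV with header; requires barcode, sample_id, platform (FFPE/FROZEN);
#' optional doublet_flag, cell_type, cluster.
#'
#' @param path file path.
#' @return a `data.frame` of per-cell metadata.
#' @export
read_cell_metadata <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  validate_cell_metadata(m)
}

#' Validate per-cell metadata
#' @param m data.frame with barcode, sample_id, platform columns.
#' @return the validated data.frame.
#' @export
validate_cell_metadata <- function(m) {
  need <- c("barcode", "sample_id", "platform")
  if (!all(need %in% names(m)))
    stop("cell metadata needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(m$barcode)) stop("duplicate barcodes in metadata",
                                     call. = FALSE)
  bad <- setdiff(unique(m$platform), c("FFPE", "FROZEN"))
  if (length(bad))
    stop("platform must be FFPE or FROZEN; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(m$doublet_flag)) m$doublet_flag <- as.logical(m$doublet_flag)
  m
}

#' Write a data.frame as TSV with header
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
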