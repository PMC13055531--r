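## Marker-set scoring, margin-based T-cell subtyping, and the
## cross-platform per-sample marker correlation (the PDCD1-style analysis).

#' Read marker sets from a TSV config
#'
#' Two tab-separated columns: subtype and a comma-separated gene list.
#' The package ships a default config (`inst/extdata/marker_sets.tsv`)
#' with generic CD4/CD8/Treg/NK-like canonical sets and the exhaustion
#' panel (PDCD1, CTLA4, HAVCR2, LAG3, TIGIT, TOX); all user-replaceable.
#'
#' @param path TSV path; default the shipped config.
#' @return named list of character gene vectors.
#' @export
read_marker_sets <- function(path = system.file("extdata",
                                                "marker_sets.tsv",
                                                package = "matchedsc")) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  sets <- lapply(strsplit(d$genes, ","), trimws)
  names(sets) <- d$subtype
  if (any(!lengths(sets))) stop("empty marker set in config", call. = FALSE)
  sets
}

#' Score cells for a marker set
#'
#' Mean CP10k-log expression over the set genes present in the matrix;
#' missing genes (FFPE panel restriction) are dropped with a message, and
#' a set with no present genes is an error.
#'
#' @param cm a [CountMatrix].
#' @param genes character vector of set genes (ids or symbols).
#' @param set_name label used in messages.
#' @return named numeric score per cell.
#' @export
score_marker_set <- function(cm, genes, set_name = "marker set") {
  hit <- cm$gene_ids %in% genes | cm$gene_symbols %in% genes
  if (!any(hit))
    stop("no genes of '", set_name, "' present in the matrix",
         call. = FALSE)
  n_miss <- length(genes) - sum(genes %in% cm$gene_ids |
                                  genes %in% cm$gene_symbols)
  if (n_miss > 0)
    message("score_marker_set: ", n_miss, " of ", length(genes),
            " '", set_name, "' genes absent; dropped")
  E <- cp10k_log(cm)
  s <- colMeans(E[hit, , drop = FALSE])
  names(s) <- cm$barcodes
  s
}

#' Assign cells to marker-defined subtypes with a margin rule
#'
#' Each set's per-cell scores are z-scored across cells; a cell is
#' assigned the argmax set when the top score beats the runner-up by at
#' least `min_margin` standard units, otherwise `"unassigned"`. Sets with
#' constant scores carry no information and are excluded (message). This
#' margin rule replaces per-cluster differential expression.
#'
#' @param cm a [CountMatrix].
#' @param sets named list of gene vectors (>= 2 sets).
#' @param min_margin assignment margin in z-units (default 0.25).
#' @return data.frame(barcode, subtype, margin).
#' @export
subtype_cells <- function(cm, sets, min_margin = 0.25) {
  if (length(sets) < 2) stop("need at least 2 marker sets", call. = FALSE)
  S <- vapply(names(sets), function(nm)
    score_marker_set(cm, sets[[nm]], nm), numeric(length(cm$barcodes)))
  sds <- apply(S, 2, stats::sd)
  if (any(sds == 0)) {
    message("subtype_cells: excluding constant-score sets: ",
            paste(colnames(S)[sds == 0], collapse = ", "))
    S <- S[, sds > 0, drop = FALSE]
    if (ncol(S) < 2) stop("fewer than 2 informative sets", call. = FALSE)
  }
  Z <- scale(S)
  best <- max.col(Z, ties.method = "first")
  second <- vapply(seq_len(nrow(Z)), function(i) max(Z[i, -best[i]]),
                   numeric(1))
  margin <- Z[cbind(seq_len(nrow(Z)), best)] - second
  data.frame(barcode = cm$barcodes,
             subtype = ifelse(margin >= min_margin, colnames(Z)[best],
                              "unassigned"),
             margin = margin, stringsAsFactors = FALSE)
}

#' Cross-platform per-sample correlation of a marker gene
#'
#' Within a cell subset (e.g., CD8+ T cells), the per-sample mean
#' CP10k-log expression of one gene is computed on each platform; the
#' paired sample means are then correlated (Pearson, with t-test
#' p-value). Requires the gene on both platforms and at least 3 samples
#' with subset cells on both.
#'
#' @param cm a [CountMatrix] covering both platforms.
#' @param metadata per-cell metadata (barcode, sample_id, platform).
#' @param subset_barcodes barcodes of the cell subset.
#' @param gene gene id or symbol.
#' @return list(table = per-sample means, r, p.value).
#' @export
cross_platform_marker_cor <- function(cm, metadata, subset_barcodes, gene) {
  gi <- which(cm$gene_ids == gene | cm$gene_symbols == gene)
  if (!length(gi)) stop("gene not found: ", gene, call. = FALSE)
  gi <- gi[1]
  sub <- subset_cm(cm, cells = intersect(subset_barcodes, cm$barcodes))
  md <- metadata[match(sub$barcodes, metadata$barcode), ]
  ## a probe-panel hole shows up as a structural all-zero on one platform
  for (pf in c("FFPE", "FROZEN")) {
    cells <- md$platform == pf
    if (any(cells) && sum(sub$counts[gi, cells]) == 0 &&
        sum(sub$counts[gi, !cells]) > 0)
      stop("gene '", gene, "' undetected on platform ", pf,
           " (absent from its panel?)", call. = FALSE)
  }
  e <- cp10k_log(sub)[gi, ]
  key <- paste(md$sample_id, md$platform)
  means <- tapply(e, key, mean)
  samples <- sort(unique(md$sample_id))
  tab <- data.frame(
    sample_id = samples,
    frozen = as.numeric(means[paste(samples, "FROZEN")]),
    ffpe = as.numeric(means[paste(samples, "FFPE")]))
  ok <- stats::complete.cases(tab)
  if (sum(ok) < 3)
    stop("need >= 3 samples with the subset on both platforms",
         call. = FALSE)
  ans <- pearson_cor(tab$frozen[ok], tab$ffpe[ok])
  list(table = tab, r = ans$r, p.value = ans$p.value)
}
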