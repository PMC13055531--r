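## Synthetic matched-cohort generator. Emulates the structure of a matched
## FFPE (probe-panel, shallow) / fresh-frozen (whole-transcriptome, deeper)
## single-cell study: shared cell-type programs and clonal copy-number
## structure per biopsy, platform effects limited to panel restriction and
## per-cell depth, plus doublets and mitochondrial content. Counts are
## negative-binomial around cell-type program means scaled by per-cell
## depth; genes inside a clone's CNA segment have their means multiplied by
## the segment copy ratio for cells of that clone.

.default_genome <- function() {
  data.frame(chrom = paste0("chr", 1:5), length = rep(120e6, 5),
             stringsAsFactors = FALSE)
}

.default_cell_types <- function() {
  data.frame(
    name = c("Malignant", "Tcell", "Bcell", "Myeloid", "Fibroblast"),
    proportion = c(0.30, 0.30, 0.15, 0.15, 0.10),
    stringsAsFactors = FALSE)
}

## Default clonal scenario: one clone at 20% of all cells (2/3 of the
## malignant compartment) with a single-copy gain (ratio 2) over 30% of
## the genome (all of chr1 plus half of chr2).
.default_clones <- function() {
  list(list(
    clone_id = "cloneA", fraction = 0.2,
    segments = data.frame(chrom = c("chr1", "chr2"),
                          start = c(0, 0), end = c(120e6, 60e6),
                          copy_ratio = 2.0, stringsAsFactors = FALSE)))
}

#' Build a synthetic-cohort configuration
#'
#' Defaults describe a desk-scale matched cohort: a reduced 600 Mb genome
#' (5 chromosomes of 120 Mb), 3 biopsies profiled on both platforms, five
#' cell-type programs, one ratio-2 clone covering 30% of the genome at 20%
#' of cells, an FFPE probe panel covering half the genes, FFPE mean depth
#' 2,000 UMIs/cell versus 6,000 for frozen, 5% doublets and beta-distributed
#' mitochondrial fractions (mean 3%).
#'
#' @param n_samples number of matched biopsies.
#' @param n_cells cells per sample per platform.
#' @param cell_types data.frame(name, proportion); proportions sum to 1.
#' @param malignant_type the cell type that carries clones.
#' @param genome data.frame(chrom, length in bp).
#' @param n_genes autosomal genes, placed uniformly (2 kb length).
#' @param n_mito_genes mitochondrial genes (chrom "chrM", outside the
#'   windowed genome).
#' @param clones list of `list(clone_id, fraction, segments)` where
#'   `fraction` is the clone's share of ALL cells in a sample (scalar or
#'   one value per sample) and `segments` is a BED-like data.frame with
#'   copy_ratio; fractions must not exceed the malignant proportion.
#' @param ffpe_panel_fraction fraction of genes on the FFPE probe panel.
#' @param depth_scale named mean UMI per cell, `c(FFPE =, FROZEN =)`.
#' @param depth_shape gamma shape for per-cell depth variation.
#' @param mito_beta `c(alpha, beta)` of the per-cell mito-fraction Beta law.
#' @param doublet_rate fraction of cells that are doublets.
#' @param nb_size negative-binomial size (dispersion) parameter.
#' @param marker_frac,marker_fold fraction of genes assigned as markers of
#'   each type and their fold enrichment.
#' @param platform_gene_effect_sd sd of an optional log-normal gene-wise
#'   FFPE scaling factor (0 = none, the default).
#' @param seed integer seed; the cohort is a deterministic function of the
#'   configuration.
#' @return a `synth_config` list, validated.
#' @export
synth_config <- function(n_samples = 3, n_cells = 1000,
                         cell_types = .default_cell_types(),
                         malignant_type = "Malignant",
                         genome = .default_genome(),
                         n_genes = 3000, n_mito_genes = 30,
                         clones = .default_clones(),
                         ffpe_panel_fraction = 0.5,
                         depth_scale = c(FFPE = 2000, FROZEN = 6000),
                         depth_shape = 4,
                         mito_beta = c(6, 194),
                         doublet_rate = 0.05,
                         nb_size = 2.0,
                         marker_frac = 0.05, marker_fold = 4,
                         platform_gene_effect_sd = 0,
                         seed = 1L) {
  cfg <- list(n_samples = n_samples, n_cells = n_cells,
              cell_types = cell_types, malignant_type = malignant_type,
              genome = genome, n_genes = n_genes,
              n_mito_genes = n_mito_genes, clones = clones,
              ffpe_panel_fraction = ffpe_panel_fraction,
              depth_scale = depth_scale, depth_shape = depth_shape,
              mito_beta = mito_beta, doublet_rate = doublet_rate,
              nb_size = nb_size, marker_frac = marker_frac,
              marker_fold = marker_fold,
              platform_gene_effect_sd = platform_gene_effect_sd,
              seed = as.integer(seed))
  validate_synth_config(cfg)
}

#' @rdname synth_config
#' @param cfg a configuration list.
#' @export
validate_synth_config <- function(cfg) {
  if (abs(sum(cfg$cell_types$proportion) - 1) > 1e-8)
    stop("cell-type proportions must sum to 1", call. = FALSE)
  if (!(cfg$malignant_type %in% cfg$cell_types$name))
    stop("malignant_type not among cell types", call. = FALSE)
  if (cfg$ffpe_panel_fraction <= 0 || cfg$ffpe_panel_fraction > 1)
    stop("ffpe_panel_fraction must lie in (0, 1]", call. = FALSE)
  if (cfg$doublet_rate < 0 || cfg$doublet_rate >= 1)
    stop("doublet_rate must lie in [0, 1)", call. = FALSE)
  if (!all(c("FFPE", "FROZEN") %in% names(cfg$depth_scale)))
    stop("depth_scale needs FFPE and FROZEN entries", call. = FALSE)
  mal_prop <- cfg$cell_types$proportion[
    cfg$cell_types$name == cfg$malignant_type]
  fr <- .clone_fraction_matrix(cfg)
  if (any(rowSums(fr) > mal_prop + 1e-8))
    stop("clone fractions exceed the malignant-type proportion",
         call. = FALSE)
  for (cl in cfg$clones) validate_segments(cl$segments)
  class(cfg) <- "synth_config"
  cfg
}

## n_samples x n_clones matrix of per-sample clone fractions (of all cells)
.clone_fraction_matrix <- function(cfg) {
  k <- length(cfg$clones)
  fr <- matrix(0, cfg$n_samples, max(k, 1))
  if (k == 0) return(fr[, 0, drop = FALSE])
  for (j in seq_len(k)) {
    f <- cfg$clones[[j]]$fraction
    if (length(f) == 1) f <- rep(f, cfg$n_samples)
    if (length(f) != cfg$n_samples)
      stop("clone fraction must be scalar or one value per sample",
           call. = FALSE)
    fr[, j] <- f
  }
  colnames(fr) <- vapply(cfg$clones, `[[`, "", "clone_id")
  fr
}

.place_genes <- function(cfg) {
  glen <- 2000
  probs <- cfg$genome$length / sum(cfg$genome$length)
  chrom <- sample(cfg$genome$chrom, cfg$n_genes, replace = TRUE,
                  prob = probs)
  start <- floor(stats::runif(cfg$n_genes) *
                   (cfg$genome$length[match(chrom, cfg$genome$chrom)] - glen))
  o <- order(match(chrom, cfg$genome$chrom), start)
  ann <- data.frame(gene_id = sprintf("G%05d", seq_len(cfg$n_genes)),
                    chrom = chrom[o], start = start[o],
                    end = start[o] + glen, is_mito = FALSE,
                    stringsAsFactors = FALSE)
  if (cfg$n_mito_genes > 0) {
    ms <- seq_len(cfg$n_mito_genes) * 500
    ann <- rbind(ann, data.frame(
      gene_id = sprintf("MT-%02d", seq_len(cfg$n_mito_genes)),
      chrom = "chrM", start = ms, end = ms + 400, is_mito = TRUE,
      stringsAsFactors = FALSE))
  }
  ann
}

## per-gene copy-ratio multiplier for each clone (midpoint-in-segment rule)
.clone_multipliers <- function(cfg, ann) {
  k <- length(cfg$clones)
  mult <- matrix(1, nrow(ann), max(k, 0))
  if (k == 0) return(mult)
  mid <- (ann$start + ann$end) / 2
  for (j in seq_len(k)) {
    seg <- cfg$clones[[j]]$segments
    for (i in seq_len(nrow(seg))) {
      hit <- ann$chrom == seg$chrom[i] & mid >= seg$start[i] &
        mid < seg$end[i]
      mult[hit, j] <- seg$copy_ratio[i]
    }
  }
  colnames(mult) <- vapply(cfg$clones, `[[`, "", "clone_id")
  mult
}

## integer composition with exact total: floor + largest remainders
.exact_counts <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a matched FFPE/frozen synthetic cohort
#'
#' Draws one library per sample x platform under the configured generative
#' law (see [synth_config()]). Identical configuration (including seed)
#' yields bit-identical output.
#'
#' @param cfg a [synth_config()].
#' @return a list with elements
#'   \describe{
#'     \item{matrices}{named list of [CountMatrix], one per
#'       `<sample>_<platform>` library, sharing one gene universe}
#'     \item{metadata}{per-cell metadata data.frame (barcode, sample_id,
#'       platform, doublet_flag, cell_type)}
#'     \item{annotation}{per-gene annotation (gene_id, chrom, start, end,
#'       is_mito)}
#'     \item{truth}{ground truth: per-cell clone assignments, panel
#'       membership, clone segment table and fractions, program means,
#'       genome table and the generating config}
#'   }
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  ann <- .place_genes(cfg)
  ng <- nrow(ann)
  types <- cfg$cell_types$name
  ## program means: shared log-normal baseline, disjoint marker blocks
  base <- stats::rlnorm(ng, meanlog = 0, sdlog = 1)
  B <- matrix(base, ng, length(types), dimnames = list(ann$gene_id, types))
  n_marker <- round(cfg$marker_frac * ng)
  free <- which(!ann$is_mito)
  for (t in seq_along(types)) {
    pick <- sample(free, n_marker)
    B[pick, t] <- B[pick, t] * cfg$marker_fold
    free <- setdiff(free, pick)
  }
  mult <- .clone_multipliers(cfg, ann)
  panel <- rep(TRUE, ng)
  if (cfg$ffpe_panel_fraction < 1) {
    panel <- rep(FALSE, ng)
    panel[sample(ng, round(cfg$ffpe_panel_fraction * ng))] <- TRUE
  }
  ffpe_gene_scale <- rep(1, ng)
  if (cfg$platform_gene_effect_sd > 0)
    ffpe_gene_scale <- stats::rlnorm(ng, 0, cfg$platform_gene_effect_sd)

  fr <- .clone_fraction_matrix(cfg)
  mito <- ann$is_mito
  matrices <- list()
  meta_rows <- list()
  clone_rows <- list()

  for (s in seq_len(cfg$n_samples)) {
    sample_id <- sprintf("S%d", s)
    ## shared per-biopsy composition, realized exactly
    tc <- .exact_counts(cfg$cell_types$proportion, cfg$n_cells)
    cell_type <- rep(types, tc)
    ## clone labels live on malignant cells only
    clone <- rep(NA_character_, cfg$n_cells)
    mal_idx <- which(cell_type == cfg$malignant_type)
    if (ncol(fr) > 0) {
      off <- 0
      for (j in seq_len(ncol(fr))) {
        n_cl <- round(fr[s, j] * cfg$n_cells)
        if (n_cl > 0)
          clone[mal_idx[(off + 1):(off + n_cl)]] <- colnames(fr)[j]
        off <- off + n_cl
      }
    }
    for (pf in c("FROZEN", "FFPE")) {
      n <- cfg$n_cells
      bc <- sprintf("%s_%s_%04d", sample_id, pf, seq_len(n))
      ## relative expected profile per cell
      W <- B[, cell_type, drop = FALSE]
      if (pf == "FFPE") {
        W <- W * ffpe_gene_scale
        W[!panel, ] <- 0
      }
      ## normalize the diploid program to a per-cell relative profile with
      ## the configured mitochondrial share (column scaling via rep() to
      ## avoid sweep/aperm overhead on large matrices)
      m_c <- stats::rbeta(n, cfg$mito_beta[1], cfg$mito_beta[2])
      wm <- W * mito          # mito part
      wn <- W * (!mito)       # nuclear part
      sm <- colSums(wm); sn <- colSums(wn)
      m_eff <- ifelse(sm > 0, m_c, 0)
      P <- wn * rep(ifelse(sn > 0, (1 - m_eff) / sn, 0), each = ng)
      if (any(sm > 0))
        P <- P + wm * rep(ifelse(sm > 0, m_eff / sm, 0), each = ng)
      ## clone CNA dosage applies on top of the normalized diploid profile:
      ## gained genes gain transcripts, so clone cells run slightly deeper
      for (cl in unique(clone[!is.na(clone)])) {
        idx <- which(!is.na(clone) & clone == cl)
        P[, idx] <- P[, idx, drop = FALSE] * mult[, cl]
      }
      ## doublets: sum of two cells' expected profiles, then depth
      ## renormalization (total expectation back to one cell's depth)
      n_db <- round(cfg$doublet_rate * n)
      doublet <- rep(FALSE, n)
      if (n_db > 0) {
        di <- sample(n, n_db)
        partner <- vapply(di, function(i) sample(setdiff(seq_len(n), i), 1),
                          integer(1))
        Pd <- P[, di, drop = FALSE] + P[, partner, drop = FALSE]
        P[, di] <- Pd * rep(1 / colSums(Pd), each = ng)
        doublet[di] <- TRUE
      }
      depth <- stats::rgamma(n, shape = cfg$depth_shape,
                             rate = cfg$depth_shape / cfg$depth_scale[[pf]])
      mu <- P * rep(depth, each = ng)
      cnt <- matrix(stats::rnbinom(length(mu), size = cfg$nb_size,
                                   mu = as.vector(mu)), ng, n)
      matrices[[paste0(sample_id, "_", pf)]] <-
        CountMatrix(Matrix::Matrix(cnt, sparse = TRUE),
                    ann$gene_id, ann$gene_id, bc)
      meta_rows[[paste0(sample_id, "_", pf)]] <- data.frame(
        barcode = bc, sample_id = sample_id, platform = pf,
        doublet_flag = doublet, cell_type = cell_type,
        clone_id = clone, stringsAsFactors = FALSE)
    }
    if (length(cfg$clones))
      for (j in seq_along(cfg$clones)) {
        seg <- cfg$clones[[j]]$segments
        clone_rows[[paste(s, j)]] <- data.frame(
          sample_id = sample_id, clone_id = cfg$clones[[j]]$clone_id,
          fraction = fr[s, j], seg, stringsAsFactors = FALSE,
          row.names = NULL)
      }
  }
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  truth <- list(
    cells = meta,
    panel = data.frame(gene_id = ann$gene_id, in_panel = panel,
                       stringsAsFactors = FALSE),
    clone_segments = if (length(clone_rows)) do.call(rbind, clone_rows)
                     else NULL,
    clone_fractions = fr,
    gene_means = B,
    genome = cfg$genome,
    config = cfg)
  list(matrices = matrices,
       metadata = meta[, c("barcode", "sample_id", "platform",
                           "doublet_flag", "cell_type")],
       annotation = ann, truth = truth)
}

#' Tile a genome into fixed-width windows
#'
#' @param genome data.frame(chrom, length).
#' @param width window width in bp (default 10 Mb); the last window of a
#'   chromosome may be short.
#' @return data.frame(chrom, start, end) of 0-based half-open windows.
#' @export
make_windows <- function(genome, width = 10e6) {
  if (width <= 0) stop("window width must be positive", call. = FALSE)
  out <- lapply(seq_len(nrow(genome)), function(i) {
    starts <- seq(0, genome$length[i] - 1, by = width)
    data.frame(chrom = genome$chrom[i], start = starts,
               end = pmin(starts + width, genome$length[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## base-weighted mean copy ratio of a segment set over each window
## (uncovered bases are neutral, ratio 1)
.segment_window_means <- function(segments, windows) {
  vals <- rep(1, nrow(windows))
  for (w in seq_len(nrow(windows))) {
    sel <- segments$chrom == windows$chrom[w] &
      segments$start < windows$end[w] & segments$end > windows$start[w]
    if (!any(sel)) next
    seg <- segments[sel, , drop = FALSE]
    ov <- pmin(seg$end, windows$end[w]) - pmax(seg$start, windows$start[w])
    ww <- windows$end[w] - windows$start[w]
    vals[w] <- sum(ov * seg$copy_ratio, (ww - sum(ov)) * 1) / ww
  }
  vals
}

#' Derive the per-sample bulk CNA window profile from synthetic truth
#'
#' The bulk profile a whole-tissue WGS assay would see: per window, the
#' clone-fraction-weighted mean copy ratio, base-weighted within the
#' window, with the non-clonal remainder diploid (ratio 1). Neutral
#' windows are exactly 1.
#'
#' @param truth the `truth` element of [generate_cohort()] output.
#' @param window_width window width in bp (default 10 Mb).
#' @return a [window_profile_obj()] on the ratio scale, one entity per
#'   sample.
#' @export
derive_bulk_cna <- function(truth, window_width = 10e6) {
  windows <- make_windows(truth$genome, window_width)
  fr <- truth$clone_fractions
  n_s <- nrow(fr)
  vals <- matrix(1, n_s, nrow(windows))
  if (!is.null(truth$clone_segments) && ncol(fr) > 0) {
    clone_means <- sapply(colnames(fr), function(cl) {
      seg <- truth$clone_segments[
        truth$clone_segments$clone_id == cl &
          truth$clone_segments$sample_id ==
            truth$clone_segments$sample_id[1], ]
      .segment_window_means(seg, windows)
    })
    for (s in seq_len(n_s)) {
      tot <- rowSums(sweep(clone_means, 2, fr[s, ], `*`))
      vals[s, ] <- tot + (1 - sum(fr[s, ])) * 1
    }
  }
  window_profile_obj(windows, vals,
                     entities = sprintf("S%d", seq_len(n_s)),
                     scale = "ratio")
}

#' Write a generated cohort to disk in standard formats
#'
#' Emits one 10x triplet directory per library, `cells.tsv`,
#' `genes.bed.tsv`, `truth_cells.tsv`, `panel.tsv`, `genome.tsv` and the
#' per-sample derived bulk segment table `bulk_cna.tsv`.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort$matrices))
    write_10x_triplet(cohort$matrices[[nm]], file.path(dir, nm))
  write_tsv(cohort$metadata, file.path(dir, "cells.tsv"))
  write_tsv(cohort$annotation, file.path(dir, "genes.bed.tsv"))
  write_tsv(cohort$truth$cells, file.path(dir, "truth_cells.tsv"))
  write_tsv(cohort$truth$panel, file.path(dir, "panel.tsv"))
  write_tsv(cohort$truth$genome, file.path(dir, "genome.tsv"))
  if (!is.null(cohort$truth$clone_segments))
    write_tsv(cohort$truth$clone_segments, file.path(dir, "bulk_cna.tsv"))
  invisible(dir)
}
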