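## Controlled-overlap integration benchmark: random partitions of a
## matched cohort into per-platform subsets with complete / partial / no
## overlap in cell types, a built-in correction baseline (plus a pluggable
## method interface), NMI-selected modularity clustering, and the
## four-metric evaluation (NMI, ARI, batch ASW, PC regression).

.rand_subset <- function(x, allow_all = TRUE) {
  kmax <- if (allow_all) length(x) else length(x) - 1L
  k <- sample.int(kmax, 1)
  sort(sample(x, k))
}

.jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Generate controlled-overlap benchmark scenarios
#'
#' Draws `n_complete + n_none + n_partial` random partitions of the
#' cohort. Each scenario first selects random samples and cell types for
#' the FROZEN side; the FFPE side then reuses the exact same selection
#' (complete overlap), an independent random selection resampled until the
#' cell-type overlap is strictly partial (partial), or the complement of
#' the selected samples and cell types (no overlap). The shared fraction
#' is the Jaccard index of the two cell-type sets (configurable to the
#' FFPE-relative fraction).
#'
#' @param metadata per-cell metadata with sample_id, platform, cell_type.
#' @param n_complete,n_none,n_partial scenario counts (defaults 25/25/100).
#' @param seed integer seed.
#' @param shared_mode `"jaccard"` or `"b"` (relative to the FFPE set).
#' @param max_retry resampling cap for the partial category.
#' @return list of scenarios, each
#'   `list(id, category, samples_a, types_a, samples_b, types_b,
#'   shared_fraction)`, classed `scenario_set`.
#' @export
generate_scenarios <- function(metadata, n_complete = 25, n_none = 25,
                               n_partial = 100, seed = 1,
                               shared_mode = c("jaccard", "b"),
                               max_retry = 100) {
  shared_mode <- match.arg(shared_mode)
  both <- function(col) {
    x <- table(metadata[[col]], metadata$platform)
    rownames(x)[x[, "FFPE"] > 0 & x[, "FROZEN"] > 0]
  }
  samples <- both("sample_id")
  types <- both("cell_type")
  if (length(samples) < 2 || length(types) < 2)
    stop("need >= 2 samples and >= 2 cell types on both platforms",
         call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  shared <- function(a, b) if (shared_mode == "jaccard") .jaccard(a, b)
            else length(intersect(a, b)) / length(b)
  mk <- function(id, category) {
    if (category == "none") {
      sa <- .rand_subset(samples, allow_all = FALSE)
      ta <- .rand_subset(types, allow_all = FALSE)
      sb <- setdiff(samples, sa)
      tb <- setdiff(types, ta)
    } else if (category == "complete") {
      sa <- .rand_subset(samples); ta <- .rand_subset(types)
      sb <- sa; tb <- ta
    } else {
      for (i in seq_len(max_retry)) {
        sa <- .rand_subset(samples); ta <- .rand_subset(types)
        sb <- .rand_subset(samples); tb <- .rand_subset(types)
        f <- .jaccard(ta, tb)
        if (f > 0 && f < 1) break
        if (i == max_retry)
          stop("could not sample a partial-overlap scenario", call. = FALSE)
      }
    }
    list(id = id, category = category, samples_a = sa, types_a = ta,
         samples_b = sb, types_b = tb, shared_fraction = shared(ta, tb))
  }
  out <- c(
    lapply(seq_len(n_complete), function(i) mk(sprintf("complete_%02d", i),
                                               "complete")),
    lapply(seq_len(n_none), function(i) mk(sprintf("none_%02d", i), "none")),
    lapply(seq_len(n_partial), function(i) mk(sprintf("partial_%03d", i),
                                              "partial")))
  class(out) <- "scenario_set"
  out
}

#' Barcodes selected by a scenario
#'
#' FROZEN cells matching `(samples_a, types_a)` and FFPE cells matching
#' `(samples_b, types_b)`.
#'
#' @param metadata per-cell metadata.
#' @param scenario one scenario from [generate_scenarios()].
#' @return character vector of barcodes.
#' @export
scenario_cells <- function(metadata, scenario) {
  a <- metadata$platform == "FROZEN" &
    metadata$sample_id %in% scenario$samples_a &
    metadata$cell_type %in% scenario$types_a
  b <- metadata$platform == "FFPE" &
    metadata$sample_id %in% scenario$samples_b &
    metadata$cell_type %in% scenario$types_b
  metadata$barcode[a | b]
}

#' Built-in baseline batch correction
#'
#' Restrict to genes detected on both platforms, CP10k-log normalize,
#' center and unit-scale every gene WITHIN each platform (removing
#' platform-wise location/scale shifts from depth and panel chemistry),
#' concatenate cells, and run a joint PCA. A stand-in so the benchmark is
#' self-contained; external correction methods plug in through the same
#' interface (a function from per-platform [CountMatrix] to a joint
#' embedding).
#'
#' @param mats named list of [CountMatrix], one per platform (or any
#'   batch); a single matrix yields a plain PCA.
#' @param n_pcs embedding dimension (default 30).
#' @param standardize per-platform gene standardization (the corrective
#'   step; `FALSE` gives the uncorrected joint PCA).
#' @return embedding matrix (cells x n_pcs) with barcode rownames.
#' @export
baseline_correct <- function(mats, n_pcs = 30, standardize = TRUE) {
  if (inherits(mats, "CountMatrix")) mats <- list(mats)
  shared <- Reduce(intersect, lapply(mats, function(m)
    m$gene_ids[Matrix::rowSums(m$counts) > 0]))
  if (length(shared) < 50)
    stop("fewer than 50 shared detected genes across platforms",
         call. = FALSE)
  blocks <- lapply(mats, function(m) {
    E <- cp10k_log(subset_cm(m, genes = shared))
    if (standardize) {
      mu <- rowMeans(E)
      sd <- apply(E, 1, stats::sd)
      sd[sd == 0] <- 1
      E <- (E - mu) / sd
    }
    E
  })
  X <- t(do.call(cbind, blocks))
  k <- min(n_pcs, nrow(X) - 1, ncol(X))
  emb <- .pca_scores(X, k)
  rownames(emb) <- unlist(lapply(mats, `[[`, "barcodes"))
  emb
}

## truncated PCA scores via eigendecomposition of the smaller Gram matrix
## (avoids a full SVD on cells x genes matrices)
.pca_scores <- function(X, k) {
  Xc <- X - rep(colMeans(X), each = nrow(X))
  if (ncol(Xc) <= nrow(Xc)) {
    ev <- eigen(crossprod(Xc), symmetric = TRUE)
    scores <- Xc %*% ev$vectors[, seq_len(k), drop = FALSE]
  } else {
    ev <- eigen(tcrossprod(Xc), symmetric = TRUE)
    lam <- pmax(ev$values[seq_len(k)], 0)
    scores <- ev$vectors[, seq_len(k), drop = FALSE] *
      rep(sqrt(lam), each = nrow(Xc))
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Uncorrected joint PCA (comparison arm)
#'
#' Same pipeline as [baseline_correct()] without the per-platform gene
#' standardization.
#'
#' @inheritParams baseline_correct
#' @return embedding matrix (cells x n_pcs).
#' @export
joint_pca_uncorrected <- function(mats, n_pcs = 30) {
  baseline_correct(mats, n_pcs = n_pcs, standardize = FALSE)
}

.knn_graph <- function(embedding, k) {
  n <- nrow(embedding)
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(embedding))
  edges <- matrix(0L, n * k, 2)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1)]
    edges[((i - 1) * k + 1):(i * k), ] <- cbind(i, nb)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Resolution sweep with NMI-based selection
#'
#' Builds a k-nearest-neighbor graph (Euclidean, undirected union of
#' neighborhoods) on the embedding and runs modularity-based community
#' detection (Louvain) at each resolution; the partition with the highest
#' NMI against the reference cell types is returned, ties resolved to the
#' lowest resolution.
#'
#' @param embedding cells x dims matrix.
#' @param cell_types reference partition for selection.
#' @param resolutions resolutions swept (default 0.05 to 0.30 step 0.05).
#' @param neighbors kNN graph degree (default 20; reduced with a message
#'   when there are too few cells).
#' @param seed RNG seed for the community detection.
#' @return list(clusters, resolution, nmi, sweep = per-resolution table).
#' @export
cluster_sweep <- function(embedding, cell_types,
                          resolutions = seq(0.05, 0.30, by = 0.05),
                          neighbors = 20, seed = 1) {
  n <- nrow(embedding)
  if (n < neighbors + 1) {
    message("cluster_sweep: reducing neighbors to ", n - 1)
    neighbors <- n - 1
  }
  g <- .knn_graph(embedding, neighbors)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  best <- NULL
  sweep_rows <- list()
  for (r in resolutions) {
    set.seed(seed)
    cl <- igraph::cluster_louvain(g, resolution = r)
    part <- igraph::membership(cl)
    score <- nmi(part, cell_types)
    sweep_rows[[as.character(r)]] <- data.frame(
      resolution = r, n_clusters = length(unique(part)), nmi = score)
    if (is.null(best) || score > best$nmi + 1e-12)
      best <- list(clusters = as.integer(part), resolution = r, nmi = score)
  }
  best$sweep <- do.call(rbind, sweep_rows)
  rownames(best$sweep) <- NULL
  best
}

#' Evaluate one integrated scenario with the four metrics
#'
#' NMI and ARI between the selected clustering and the cell types
#' (bio-conservation), batch ASW of the platform labels within cell types
#' (mixing; `NA` when no cell type spans both platforms, as in no-overlap
#' scenarios), and PC regression of the embedding on platform (mixing).
#'
#' @param embedding cells x dims matrix.
#' @param clusters cluster label per cell.
#' @param cell_types cell-type label per cell.
#' @param platform platform label per cell.
#' @return one-row data.frame(nmi, ari, asw_badness, pcr).
#' @export
evaluate_scenario <- function(embedding, clusters, cell_types, platform) {
  asw <- batch_asw(embedding, platform, cell_types)
  data.frame(nmi = nmi(clusters, cell_types),
             ari = ari(clusters, cell_types),
             asw_badness = as.numeric(asw),
             pcr = pc_regression(embedding, platform))
}

#' Run the integration benchmark over a scenario set
#'
#' For each scenario and correction method: subset the cohort, embed,
#' sweep clustering resolutions with NMI selection, and evaluate the four
#' metrics.
#'
#' @param cm a [CountMatrix] covering all cells (e.g., [cbind_cm()] over
#'   libraries).
#' @param metadata per-cell metadata with sample_id, platform, cell_type.
#' @param scenarios a `scenario_set` from [generate_scenarios()].
#' @param methods named list of correction functions
#'   `function(mats, n_pcs) -> embedding`; default the built-in baseline
#'   and the uncorrected joint PCA.
#' @param n_pcs embedding dimension.
#' @param resolutions,neighbors passed to [cluster_sweep()].
#' @param seed RNG seed.
#' @return data.frame: scenario, category, method, nmi, ari, asw_badness,
#'   pcr, shared_fraction, chosen_resolution, n_cells.
#' @export
run_benchmark <- function(cm, metadata, scenarios,
                          methods = list(baseline = baseline_correct,
                                         uncorrected = joint_pca_uncorrected),
                          n_pcs = 30,
                          resolutions = seq(0.05, 0.30, by = 0.05),
                          neighbors = 20, seed = 1) {
  rows <- list()
  for (sc in scenarios) {
    bcs <- scenario_cells(metadata, sc)
    if (length(bcs) < 10) {
      message("run_benchmark: scenario ", sc$id, " has < 10 cells; skipped")
      next
    }
    md <- metadata[match(bcs, metadata$barcode), ]
    mats <- lapply(split(bcs, md$platform), function(b)
      subset_cm(cm, cells = b))
    for (mname in names(methods)) {
      emb <- methods[[mname]](mats, n_pcs = n_pcs)
      md2 <- metadata[match(rownames(emb), metadata$barcode), ]
      sw <- cluster_sweep(emb, md2$cell_type, resolutions, neighbors, seed)
      ev <- evaluate_scenario(emb, sw$clusters, md2$cell_type, md2$platform)
      rows[[paste(sc$id, mname)]] <- cbind(
        data.frame(scenario = sc$id, category = sc$category,
                   method = mname, stringsAsFactors = FALSE),
        ev, shared_fraction = sc$shared_fraction,
        chosen_resolution = sw$resolution, n_cells = nrow(emb))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between a benchmark metric and cell-type overlap
#'
#' Pearson correlation (with t-test p-value) of the shared cell-type
#' fraction against a metric column over the scenarios where that metric
#' is defined.
#'
#' @param results a [run_benchmark()] table (typically one method's rows).
#' @param metric one of `"nmi"`, `"ari"`, `"asw_badness"`, `"pcr"`.
#' @return list(r, p.value, n).
#' @export
overlap_correlation <- function(results, metric) {
  if (!metric %in% names(results)) stop("unknown metric: ", metric,
                                        call. = FALSE)
  ok <- !is.na(results[[metric]])
  if (sum(ok) < 3) stop("metric defined in fewer than 3 scenarios",
                        call. = FALSE)
  ans <- pearson_cor(results$shared_fraction[ok], results[[metric]][ok])
  c(ans, list(n = sum(ok)))
}
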