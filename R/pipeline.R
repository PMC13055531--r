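## End-to-end driver: simulate -> qc -> annotate -> cna -> bench ->
## markers on a synthetic matched cohort, with per-stage TSV outputs and
## a JSON summary. All randomness fans out from one root seed with fixed
## per-stage offsets, so stages are individually reproducible.

.stage_seed <- function(seed, stage) {
  offs <- c(simulate = 0L, qc = 11L, annotate = 23L, cna = 37L,
            bench = 53L, markers = 71L)
  (as.integer(seed) + offs[[stage]]) %% .Machine$integer.max
}

#' Build and validate a pipeline run configuration
#'
#' Unknown keys are rejected before any computation. Defaults mirror the
#' analysis conventions implemented across the package: 3 MADs and a 10%
#' mitochondrial ceiling for QC, 101-gene smoothing and 10 Mb windows for
#' CNA, trichotomization epsilon 0.05, the 10th-percentile malignancy
#' rule with a reference-derived noise floor, clustering resolutions 0.05
#' to 0.30 in steps of 0.05, and 25/100/25 complete/partial/none
#' benchmark scenarios.
#'
#' @param ... key = value overrides of the defaults.
#' @return a validated `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    synth = list(),                 # overrides for synth_config()
    n_mads = 3, mito_max = 0.10, mad_type = "median",
    mad_constant = 1.4826,
    smoothing_genes = 101, window_width = 10e6, epsilon = 0.05,
    percentile = 10, malignancy_margin = 1.1, literal = FALSE,
    reference_types = c("Tcell", "Bcell", "Myeloid"),
    n_pcs = 30, neighbors = 20,
    resolutions = seq(0.05, 0.30, by = 0.05),
    n_complete = 25, n_none = 25, n_partial = 100,
    bench_max_scenarios = 6,
    marker_set_path = NULL)
  ov <- list(...)
  if (length(ov) == 1 && is.list(ov[[1]]) && is.null(names(ov)))
    ov <- ov[[1]]
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, ov)
  stopifnot(cfg$n_mads >= 0, cfg$mito_max >= 0, cfg$mito_max <= 1,
            cfg$epsilon >= 0, cfg$percentile > 0, cfg$percentile < 100,
            cfg$window_width > 0, cfg$smoothing_genes %% 2 == 1)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from JSON or YAML
#'
#' @param path a `.json` or `.yaml`/`.yml` file whose keys match
#'   [run_config()] arguments.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package unavailable; use a JSON config", call. = FALSE)
    yaml::read_yaml(path)
  } else stop("config must be .json or .yaml", call. = FALSE)
  run_config(vals)
}

#' Run the full synthetic study end to end
#'
#' Simulates a matched cohort, applies QC, annotates cell types by
#' centroid transfer (frozen singlets as the reference), compares
#' annotation confidence and composition across platforms, infers CNAs and
#' scores per-cell concordance with the derived bulk truth, classifies
#' malignant clusters, tests the first clone's first segment window for a
#' subclonal gain, runs the scenario-based integration benchmark on a
#' bounded number of scenarios, and scores truth-derived marker sets.
#'
#' @param config a [run_config()].
#' @param out_dir output directory for per-stage TSVs and `summary.json`;
#'   `NULL` skips writing.
#' @return the summary list, invisibly when writing.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_lines <- c(sprintf("matchedsc %s | seed %d",
                         as.character(utils::packageVersion("matchedsc")),
                         config$seed))
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  ## -- simulate ------------------------------------------------------
  scfg <- do.call(synth_config, utils::modifyList(
    list(seed = .stage_seed(config$seed, "simulate")), config$synth))
  cohort <- generate_cohort(scfg)
  cm <- cbind_cm(cohort$matrices)
  truth <- cohort$truth
  say("simulate: %d genes x %d cells across %d libraries",
      nrow(cm$counts), ncol(cm$counts), length(cohort$matrices))

  ## -- qc ------------------------------------------------------------
  qc <- qc_cohort(cm, cohort$annotation, cohort$metadata,
                  n_mads = config$n_mads, mito_max = config$mito_max,
                  mad_type = config$mad_type,
                  constant = config$mad_constant)
  kept <- qc$barcode[qc$keep]
  say("qc: kept %d of %d cells", length(kept), nrow(qc))
  cmk <- subset_cm(cm, cells = kept)
  md <- truth$cells[match(kept, truth$cells$barcode), ]

  ## -- annotate ------------------------------------------------------
  ref_sel <- md$platform == "FROZEN" & !md$doublet_flag
  cents <- build_centroids(subset_cm(cmk, cells = md$barcode[ref_sel]),
                           md$cell_type[ref_sel])
  ann_res <- do.call(rbind, lapply(split(md$barcode, md$platform),
                                   function(b) suppressMessages(
                                     transfer_labels(
                                       subset_cm(cmk, cells = b), cents))))
  ann_res <- ann_res[match(md$barcode, ann_res$barcode), ]
  acc <- mean(ann_res$cell_type == md$cell_type)
  conf_cmp <- compare_confidence(ann_res, md)
  md_assigned <- md
  md_assigned$cell_type <- ann_res$cell_type
  comp <- composition_test(md_assigned)
  say("annotate: %.1f%% label recovery; composition CMH p = %.3g",
      100 * acc, comp$p.value)

  ## -- cna -----------------------------------------------------------
  ref_cells <- md$barcode[md$cell_type %in% config$reference_types]
  scores <- infer_cna_scores(cmk, cohort$annotation, ref_cells,
                             smoothing_genes = config$smoothing_genes)
  prof <- window_profile(scores, width = config$window_width,
                         genome = truth$genome)
  bulk <- derive_bulk_cna(truth, config$window_width)
  cell_calls <- trichotomize(prof, config$epsilon)
  kap <- rep(NA_real_, length(kept))
  for (s in unique(md$sample_id)) {
    bt <- trichotomize(window_profile_obj(
      bulk$windows, bulk$values[s, , drop = FALSE], s, "ratio"),
      config$epsilon)
    sel <- md$sample_id == s
    kap[sel] <- cell_bulk_kappa(cell_calls[sel, , drop = FALSE], bt)
  }
  emb <- baseline_correct(
    lapply(split(md$barcode, md$platform), function(b)
      subset_cm(cmk, cells = b)), n_pcs = config$n_pcs)
  md_e <- md[match(rownames(emb), md$barcode), ]
  sw <- cluster_sweep(emb, md_e$cell_type,
                      resolutions = config$resolutions,
                      neighbors = config$neighbors,
                      seed = .stage_seed(config$seed, "cna"))
  clusters <- sw$clusters[match(md$barcode, md_e$barcode)]
  mal <- classify_malignant_clusters(
    prof, clusters, percentile = config$percentile,
    reference_cells = ref_cells, margin = config$malignancy_margin,
    literal = config$literal)
  subclone_p <- NA_real_
  if (!is.null(truth$clone_segments)) {
    seg1 <- truth$clone_segments[1, ]
    wlab <- sprintf("%s:%d-%d", seg1$chrom,
                    as.integer(floor(seg1$start / config$window_width) *
                                 config$window_width),
                    as.integer(min(floor(seg1$start / config$window_width) *
                                     config$window_width +
                                     config$window_width,
                                   truth$genome$length[
                                     truth$genome$chrom == seg1$chrom])))
    mal_cells <- md$barcode[md$cell_type == scfg$malignant_type]
    subclone_p <- subpop_cna_test(prof, mal_cells, wlab,
                                  if (seg1$copy_ratio > 1) "gain" else "loss")
  }
  say("cna: %d/%d clusters malignant; subclone sign-test p = %.3g",
      sum(mal$malignant), nrow(mal), subclone_p)

  ## -- bench ---------------------------------------------------------
  scen <- generate_scenarios(md, n_complete = config$n_complete,
                             n_none = config$n_none,
                             n_partial = config$n_partial,
                             seed = .stage_seed(config$seed, "bench"))
  cat_counts <- table(vapply(scen, `[[`, "", "category"))
  run_idx <- unique(round(seq(1, length(scen),
                              length.out = min(config$bench_max_scenarios,
                                               length(scen)))))
  bench_res <- run_benchmark(cmk, md, scen[run_idx],
                             n_pcs = config$n_pcs,
                             resolutions = config$resolutions,
                             neighbors = config$neighbors,
                             seed = .stage_seed(config$seed, "bench"))
  say("bench: %d scenarios designed (%s); %d executed",
      length(scen),
      paste(names(cat_counts), as.integer(cat_counts), collapse = ", "),
      length(run_idx))

  ## -- markers -------------------------------------------------------
  sets <- if (!is.null(config$marker_set_path))
    read_marker_sets(config$marker_set_path)
  else {
    ## truth-derived sets: top 10 enriched genes per program
    B <- truth$gene_means
    rel <- B / rowMeans(B)
    lapply(stats::setNames(colnames(B), colnames(B)), function(t)
      rownames(B)[order(rel[, t], decreasing = TRUE)[1:10]])
  }
  sub <- subtype_cells(cmk, sets, min_margin = 0.25)
  assigned <- sub$subtype != "unassigned"
  sub_acc <- mean(sub$subtype[assigned] == md$cell_type[assigned])
  gene1 <- sets[[1]][1]
  xp <- tryCatch(cross_platform_marker_cor(
    cmk, md, md$barcode[md$cell_type == names(sets)[1]], gene1),
    error = function(e) list(r = NA_real_, p.value = NA_real_))
  say("markers: %.1f%% subtype accuracy among assigned; xplatform r = %.2f",
      100 * sub_acc, xp$r)

  summary <- list(
    seed = config$seed,
    n_cells_raw = ncol(cm$counts), n_cells_kept = length(kept),
    annotation_accuracy = acc,
    composition_cmh = list(statistic = comp$statistic, df = comp$df,
                           p = comp$p.value),
    confidence_comparison = conf_cmp,
    kappa_median_malignant = stats::median(
      kap[md$cell_type == scfg$malignant_type], na.rm = TRUE),
    kappa_median_normal = stats::median(
      kap[md$cell_type != scfg$malignant_type], na.rm = TRUE),
    n_clusters = nrow(mal), n_malignant_clusters = sum(mal$malignant),
    subclone_sign_p = subclone_p,
    scenario_counts = as.list(cat_counts),
    benchmark = bench_res,
    subtype_accuracy = sub_acc,
    xplatform_marker = list(gene = gene1, r = xp$r, p = xp$p.value),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    write_tsv(qc, file.path(out_dir, "qc.tsv"))
    write_tsv(cbind(ann_res, truth_type = md$cell_type),
              file.path(out_dir, "annotation.tsv"))
    write_tsv(conf_cmp, file.path(out_dir, "confidence_comparison.tsv"))
    write_tsv(data.frame(barcode = md$barcode, cluster = clusters,
                         kappa = kap), file.path(out_dir, "cna_cells.tsv"))
    write_tsv(mal, file.path(out_dir, "malignant_clusters.tsv"))
    write_tsv(bench_res, file.path(out_dir, "benchmark.tsv"))
    write_tsv(sub, file.path(out_dir, "subtypes.tsv"))
    s2 <- summary
    s2$elapsed_sec <- NULL        # keep the summary byte-reproducible
    jsonlite::write_json(s2, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
    return(invisible(summary))
  }
  summary
}
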