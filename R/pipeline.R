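#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]. Exactly one of `samples`
#' (real per-sample methylation tables) or `simulation` (a [sim_config()]) must
#' be given. All thresholds default to the stringent published criteria:
#' >= 4 CpGs, >= 0.30 group difference, 5x coverage in all samples, q <= 0.05
#' where available, within-group range <= 0.30, consensus support >= 3 of the
#' control methylomes, candidate pool of 1000 per simulated DMR.
#'
#' @param simulation A [sim_config()] for synthetic mode, or `NULL`.
#' @param samples Tibble `sample_id`, `group`, `path` (and optional `dialect`)
#'   for real mode, or `NULL`.
#' @param tracks Annotation track tibble (real mode; synthetic mode uses the
#'   generated truth tracks).
#' @param icr_track ICR track for the purity gate (synthetic mode defaults to
#'   the generated truth ICRs).
#' @param params [caller_params()].
#' @param segmentation List: `meth_cutoff`, `min_cpg`, `cpg_class_threshold`,
#'   `min_support`.
#' @param enrichment List: `n_sets` (desk-scale default 1e4; raise towards 1e6
#'   for publication-grade empirical p resolution), `pool_size`.
#' @param purity List: `tolerance`, `max_fail_frac`.
#' @param max_range Within-group range filter boundary.
#' @param seed Master seed for every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, samples = NULL, tracks = NULL,
                            icr_track = NULL,
                            params = caller_params(),
                            segmentation = list(meth_cutoff = 0.5, min_cpg = 4,
                                                cpg_class_threshold = 30,
                                                min_support = 3),
                            enrichment = list(n_sets = 1e4, pool_size = 1000),
                            purity = list(tolerance = 0.10, max_fail_frac = 0.10),
                            max_range = 0.30,
                            seed = 1L) {
  if (is.null(simulation) == is.null(samples)) {
    abort("exactly one of `simulation` or `samples` must be provided")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]: top-level keys `simulation` (fields of
#' [sim_config()]) or `samples` (list of records with sample_id/group/path),
#' plus optional `params`, `segmentation`, `enrichment`, `purity`,
#' `max_range`, `seed`.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$simulation)) args$simulation <- do.call(sim_config, y$simulation)
  if (!is.null(y$samples)) args$samples <- bind_rows(lapply(y$samples, as_tibble))
  if (!is.null(y$params)) args$params <- do.call(caller_params, y$params)
  for (k in c("segmentation", "enrichment", "purity")) {
    if (!is.null(y[[k]])) {
      def <- formals(pipeline_config)[[k]]
      merged <- utils::modifyList(eval(def), y[[k]])
      args[[k]] <- merged
    }
  }
  if (!is.null(y$max_range)) args$max_range <- y$max_range
  if (!is.null(y$seed)) args$seed <- as.integer(y$seed)
  do.call(pipeline_config, args)
}

#' Run the full case-control methylome pipeline
#'
#' Executes simulate/load -> purity gate -> segmentation + consensus tracks ->
#' dual-caller DMR discovery -> merge -> threshold filters -> range filter ->
#' direction test -> enrichment -> annotation -> gene association, writing
#' stage outputs under `outdir` and returning a machine-readable run manifest.
#' Samples failing the purity gate are excluded before DMR calling with a
#' logged reason. Rerunning with the same config and seed reproduces
#' byte-identical TSV/BED outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return The run manifest (list), invisibly written to
#'   `outdir/manifest.json`: config echo, per-stage counts (monotone across
#'   the DMR filter chain), excluded samples, seeds and output checksums.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[wgbsdmr] ", ...)
  counts <- list()

  # --- stage: inputs ---------------------------------------------------------
  if (!is.null(config$simulation)) {
    say("simulating cohort (seed ", config$simulation$seed, ")")
    sim <- simulate_cohort(config$simulation)
    cohort <- sim$cohort
    tracks <- sim$truth$tracks
    icr_track <- config$icr_track %||%
      tracks[tracks$feature_class == "ICR", ]
    truth <- sim$truth
  } else {
    say("reading ", nrow(config$samples), " sample tables")
    dialect <- if ("dialect" %in% names(config$samples)) {
      config$samples$dialect[[1]]
    } else "bedgraph_counts"
    cohort <- read_cohort(setNames(config$samples$path, config$samples$sample_id),
                          config$samples$group, dialect = dialect)
    tracks <- config$tracks
    icr_track <- config$icr_track
    truth <- NULL
  }
  counts$samples_in <- length(unique(cohort$sample_id))

  # --- stage: purity gate ----------------------------------------------------
  excluded <- tibble(sample_id = character(), reason = character())
  if (!is.null(icr_track) && nrow(icr_track) > 0) {
    rep <- purity_report(cohort, icr_track,
                         tolerance = config$purity$tolerance,
                         max_fail_frac = config$purity$max_fail_frac,
                         min_cov = config$params$min_cov)
    readr::write_tsv(rep, file.path(outdir, "purity.tsv"), progress = FALSE)
    fail <- rep$sample_id[!rep$pass]
    if (length(fail)) {
      say("excluding impure sample(s): ", paste(fail, collapse = ", "))
      excluded <- tibble(sample_id = fail,
                         reason = "failed ICR purity check")
      cohort <- cohort[!cohort$sample_id %in% fail, ]
    }
  }
  counts$samples_pass_purity <- length(unique(cohort$sample_id))

  # --- stage: CpG map --------------------------------------------------------
  cpg_map <- build_cpg_map(cohort, min_cov = config$params$min_cov)
  counts$cpgs_all_covered <- sum(cpg_map$all_covered)

  # --- stage: segmentation + consensus --------------------------------------
  segcfg <- config$segmentation
  say("segmenting methylomes")
  segs <- segment_cohort(cohort, meth_cutoff = segcfg$meth_cutoff,
                         min_cpg = segcfg$min_cpg,
                         cpg_class_threshold = segcfg$cpg_class_threshold,
                         min_cov = config$params$min_cov)
  write_bed(segs[c("chrom", "start", "end", "seg_class", "n_cpg",
                   "mean_meth", "sample_id")],
            file.path(outdir, "segments.bed"))
  ctr_ids <- unique(cohort$sample_id[cohort$group == "CTR"])
  consensus <- high_confidence_regions(segs[segs$sample_id %in% ctr_ids, ],
                                       min_support = segcfg$min_support)
  write_bed(consensus, file.path(outdir, "consensus_regions.bed"))
  counts$segments <- nrow(segs)
  counts$consensus_umr <- sum(consensus$seg_class == "UMR")
  counts$consensus_lmr <- sum(consensus$seg_class == "LMR")

  # --- stage: DMR calling ----------------------------------------------------
  say("calling DMRs (t-statistic caller)")
  dmr_t <- call_dmrs_tstat(cohort, cpg_map, config$params)
  say("calling DMRs (segmentation caller)")
  dmr_s <- call_dmrs_segmentation(cohort, cpg_map, config$params)
  counts$dmrs_tstat <- nrow(dmr_t)
  counts$dmrs_segmentation <- nrow(dmr_s)
  merged <- merge_dmr_sets(list(dmr_t, dmr_s), cohort, cpg_map)
  counts$dmrs_merged <- nrow(merged)
  thresholded <- apply_threshold_filters(merged, config$params)
  counts$dmrs_after_thresholds <- nrow(thresholded)
  final <- apply_range_filter(thresholded, config$max_range)
  counts$dmrs_after_range_filter <- nrow(final)
  stopifnot(counts$dmrs_merged >= counts$dmrs_after_thresholds,
            counts$dmrs_after_thresholds >= counts$dmrs_after_range_filter)
  final <- add_dmr_id(final)
  readr::write_tsv(flatten_dmrs(final), file.path(outdir, "dmrs.tsv"),
                   progress = FALSE)

  direction <- if (nrow(final)) direction_binomial_test(final) else
    tibble(n_hyper = 0L, n_total = 0L, p_value = NA_real_)

  # --- stage: enrichment -----------------------------------------------------
  enrich_tbl <- NULL
  if (nrow(final) >= 2) {
    say("enrichment over ", config$enrichment$n_sets, " matched sets")
    track_list <- split(tracks[c("chrom", "start", "end")], tracks$feature_class)
    if (nrow(consensus)) {
      for (cls in unique(consensus$seg_class)) {
        track_list[[cls]] <- consensus[consensus$seg_class == cls,
                                       c("chrom", "start", "end")]
      }
    }
    genes <- tracks[tracks$feature_class == "gene", c("chrom", "start", "end")]
    sizes <- tapply(c(cohort$pos, tracks$end), c(cohort$chrom, tracks$chrom), max) + 1000
    track_list$intergenic <- .complement_intervals(genes, sizes)
    withr::with_seed(config$seed + 1L, {
      enr <- enrichment_test(final, track_list, cpg_map,
                             n_sets = config$enrichment$n_sets,
                             pool_size = config$enrichment$pool_size)
    })
    enrich_tbl <- tidy(enr)
    readr::write_tsv(enrich_tbl, file.path(outdir, "enrichment.tsv"),
                     progress = FALSE)
  }

  # --- stage: annotation -----------------------------------------------------
  annotated <- annotate_dmrs(final, tracks)
  readr::write_tsv(annotated, file.path(outdir, "annotated_dmrs.tsv"),
                   progress = FALSE)
  assoc <- associate_genes(final, tracks)
  readr::write_tsv(assoc, file.path(outdir, "gene_associations.tsv"),
                   progress = FALSE)
  counts$dmrs_gene_associated <- length(unique(assoc$dmr_id))
  counts$genes_associated <- length(unique(assoc$gene_symbol))

  # --- manifest ---------------------------------------------------------------
  outputs <- list.files(outdir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest.json$", outputs)]
  manifest <- list(
    package = "wgbsdmr",
    version = as.character(utils::packageVersion("wgbsdmr")),
    seed = config$seed,
    mode = if (is.null(config$simulation)) "real" else "synthetic",
    counts = counts,
    direction_test = as.list(direction),
    excluded_samples = excluded,
    checksums = as.list(setNames(unname(tools::md5sum(sort(outputs))),
                                 basename(sort(outputs)))),
    config = .echo_config(config)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(manifest, list(dmrs = final, enrichment = enrich_tbl,
                             associations = assoc, truth = truth)))
}

.echo_config <- function(config) {
  cfg <- unclass(config)
  cfg$samples <- if (!is.null(cfg$samples)) as.list(cfg$samples)
  cfg$tracks <- NULL; cfg$icr_track <- NULL
  cfg$simulation <- if (!is.null(cfg$simulation)) unclass(cfg$simulation)
  cfg$params <- unclass(cfg$params)
  cfg
}
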