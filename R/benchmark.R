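#' Planted-truth recovery benchmark
#'
#' Runs the complete discovery chain (dual callers, merge, threshold filters,
#' within-group range filter) on a synthetic cohort with known ground truth and
#' scores it against the planted regions: sensitivity and precision versus the
#' planted DMRs (any-bp overlap), plus how the range filter treats planted
#' genotype-driven (meQTL-like) regions versus true DMRs.
#'
#' @param config A [sim_config()]; the defaults are the study conditions the
#'   generator emulates (4 vs 4 samples, ~14x coverage, 20 planted DMRs of
#'   effect 0.4 over 8-16 CpGs, 10 meQTL regions, 10 Mb toy genome).
#' @param params [caller_params()].
#' @param max_range Range-filter boundary.
#' @return List with `sensitivity`, `precision`, `n_true`, `n_final`,
#'   `meqtl_called`, `meqtl_removed_frac`, `true_called`, `true_retained_frac`,
#'   and the underlying `dmrs_thresholded`, `dmrs_final`, `truth` objects.
#' @export
benchmark_dmr_recovery <- function(config = sim_config(seed = 1),
                                   params = caller_params(), max_range = 0.30) {
  sim <- simulate_cohort(config)
  map <- build_cpg_map(sim$cohort, params$min_cov)
  d1 <- call_dmrs_tstat(sim$cohort, map, params)
  d2 <- call_dmrs_segmentation(sim$cohort, map, params)
  merged <- merge_dmr_sets(list(d1, d2), sim$cohort, map)
  thresholded <- apply_threshold_filters(merged, params)
  final <- apply_range_filter(thresholded, max_range)

  hit_any <- function(regions, called) {
    vapply(seq_len(nrow(regions)), function(i) {
      any(called$chrom == regions$chrom[i] & called$start < regions$end[i] &
            called$end > regions$start[i])
    }, logical(1))
  }
  truth <- sim$truth$true_dmrs
  meqtl <- sim$truth$meqtl$regions
  sens <- mean(hit_any(truth, final))
  prec <- if (nrow(final)) {
    mean(hit_any(final, truth))
  } else NA_real_
  mq_called <- hit_any(meqtl, thresholded)
  mq_final <- hit_any(meqtl, final)
  tr_called <- hit_any(truth, thresholded)
  tr_final <- hit_any(truth, final)
  list(
    sensitivity = sens,
    precision = prec,
    n_true = nrow(truth),
    n_final = nrow(final),
    meqtl_called = sum(mq_called),
    meqtl_removed_frac = if (any(mq_called)) {
      mean(!mq_final[mq_called])
    } else NA_real_,
    true_called = sum(tr_called),
    true_retained_frac = if (any(tr_called)) {
      mean(tr_final[tr_called])
    } else NA_real_,
    dmrs_thresholded = thresholded,
    dmrs_final = final,
    truth = sim$truth
  )
}

#' Somatic-fraction recovery benchmark
#'
#' Simulates the four-locus amplicon purity panel across a grid of true somatic
#' fractions and reports the recovery error of [estimate_somatic_fraction()].
#'
#' @param fractions True mixing fractions.
#' @param reads_per_locus Panel depth.
#' @param seed Seed for the panel draws.
#' @return Tibble `fraction`, `f_hat`, `abs_error`.
#' @export
benchmark_contamination <- function(fractions = seq(0.1, 0.5, by = 0.1),
                                    reads_per_locus = 1000, seed = 1) {
  rows <- withr::with_seed(seed, lapply(fractions, function(f) {
    pan <- simulate_amplicon_panel(fraction = f,
                                   reads_per_locus = reads_per_locus)
    fh <- estimate_somatic_fraction(pan)
    tibble(fraction = f, f_hat = fh, abs_error = abs(fh - f))
  }))
  list_rbind(rows)
}

#' Build the positive-control enrichment fixture
#'
#' Constructs, on an existing cohort CpG map, a feature track tiling roughly
#' `frac` of the covered CpG space and a query DMR set planted entirely inside
#' the feature windows, for positive-control enrichment checks.
#'
#' @param map [build_cpg_map()] object.
#' @param n_dmrs Query DMRs to plant.
#' @param n_cpg CpGs per planted DMR.
#' @param frac Approximate fraction of CpG space the feature occupies.
#' @return List with `track` and `dmrs` tibbles.
#' @export
planted_enrichment_fixture <- function(map, n_dmrs = 20, n_cpg = 6, frac = 0.10) {
  keep <- all_covered_positions(map)
  idx <- split(seq_len(nrow(keep)), keep$chrom)
  # windows of `win` consecutive covered CpGs, spaced to occupy ~frac of CpGs
  win <- 50L
  step <- as.integer(win / frac)
  wins <- list()
  for (ch in names(idx)) {
    starts <- seq(1L, length(idx[[ch]]) - win, by = step)
    wins[[ch]] <- tibble(chrom = ch,
                         start = keep$pos[idx[[ch]][starts]],
                         end = keep$pos[idx[[ch]][starts + win - 1L]] + 1L,
                         start_idx = idx[[ch]][starts])
  }
  wins <- list_rbind(wins)
  pick <- wins[sample.int(nrow(wins), n_dmrs, replace = TRUE), ]
  off <- sample.int(win - n_cpg, n_dmrs, replace = TRUE)
  dmrs <- tibble(
    chrom = pick$chrom,
    start = keep$pos[pick$start_idx + off],
    end = keep$pos[pick$start_idx + off + n_cpg - 1L] + 1L,
    n_cpg = as.integer(n_cpg)
  )
  list(track = wins[c("chrom", "start", "end")], dmrs = dmrs)
}
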