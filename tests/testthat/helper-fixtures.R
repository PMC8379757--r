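# Shared fixtures, built in code at test time.

# Deterministic hand-built single-sample methylome: `levels` is a per-CpG
# methylation proportion; counts are exact (n_meth = round(level * cov)).
make_methylome <- function(levels, cov = 10, chrom = "chr1", spacing = 100,
                           start = 1000, sample_id = "S1", group = "CTR") {
  pos <- start + spacing * (seq_along(levels) - 1L)
  tibble::tibble(
    sample_id = sample_id, group = group, chrom = chrom, pos = as.integer(pos),
    n_meth = as.integer(round(levels * cov)), n_total = as.integer(rep(cov, length(levels)))
  )
}

# Deterministic two-group cohort from a matrix of per-sample levels
# (CpGs x samples); column names are sample ids, groups from `groups`.
make_cohort <- function(level_mat, groups, cov = 10, chrom = "chr1",
                        spacing = 100, start = 1000) {
  ids <- colnames(level_mat)
  purrr::map(seq_along(ids), function(j) {
    make_methylome(level_mat[, j], cov = cov, chrom = chrom, spacing = spacing,
                   start = start, sample_id = ids[j], group = groups[j])
  }) |> purrr::list_rbind()
}

# Small, quick synthetic cohort used across module tests.
small_sim <- function(seed = 101, ...) {
  simulate_cohort(sim_config(
    seed = seed, n_chrom = 1L, chrom_len = 1e6, n_islands = 4L, n_lmr_like = 4L,
    n_true_dmrs = 4L, n_meqtl_regions = 2L, n_icr = 4L,
    n_genes_per_chrom = 10L, n_enhancers_per_chrom = 4L, ...))
}

# Any-bp overlap between one interval and a table of intervals (oracle-grade
# arithmetic, no package code).
overlaps_tbl <- function(chrom, start, end, tbl) {
  any(tbl$chrom == chrom & tbl$start < end & tbl$end > start)
}

# Fraction of truth intervals hit by >= 1 called interval, and vice versa.
recall_precision <- function(called, truth) {
  sens <- mean(vapply(seq_len(nrow(truth)), function(i) {
    overlaps_tbl(truth$chrom[i], truth$start[i], truth$end[i], called)
  }, logical(1)))
  prec <- if (nrow(called) == 0) NA_real_ else
    mean(vapply(seq_len(nrow(called)), function(i) {
      overlaps_tbl(called$chrom[i], called$start[i], called$end[i], truth)
    }, logical(1)))
  c(sensitivity = sens, precision = prec)
}

# Independent oracle for the two-sided binomial direction test: explicit
# summation of Binomial(n, 1/2) masses over each tail, minimum tail doubled.
binom_two_sided_oracle <- function(k, n) {
  masses <- vapply(0:n, function(i) dbinom(i, n, 0.5), double(1))
  lower <- sum(masses[seq_len(k + 1)])
  upper <- sum(masses[seq(k + 1, n + 1)])
  min(1, 2 * min(lower, upper))
}

# Calibration fixture for the matched-randomizer uniformity check: a track
# tiling half of every chromosome and a large bank of CpG-count templates, so
# the overlap-count statistic is fine-grained enough for a KS comparison.
calibration_fixture <- function(map, n_templates = 400, seed = 4) {
  keep <- all_covered_positions(map)
  chroms <- unique(keep$chrom)
  span <- max(keep$pos)
  w <- 4000
  starts <- seq(0, span - w, by = 2 * w)
  track <- purrr::map(chroms, function(ch) {
    tibble::tibble(chrom = ch, start = as.integer(starts), end = as.integer(starts + w))
  }) |> purrr::list_rbind()
  templates <- withr::with_seed(seed, tibble::tibble(
    chrom = chroms[1], start = 0L, end = 1L,
    n_cpg = sample(4:16, n_templates, replace = TRUE)))
  model <- fit_length_model(withr::with_seed(seed, stats::rlnorm(500, log(800), 0.5)))
  list(track = track, templates = templates, model = model)
}
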