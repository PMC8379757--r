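test_that("both callers recover a planted region and respect the effect floor", {
  sim <- small_sim(seed = 23)
  map <- build_cpg_map(sim$cohort, 5)
  truth <- sim$truth$true_dmrs
  d1 <- call_dmrs_tstat(sim$cohort, map)
  d2 <- call_dmrs_segmentation(sim$cohort, map)
  merged <- merge_dmr_sets(list(d1, d2), sim$cohort, map)
  for (i in seq_len(nrow(truth))) {
    hit <- merged[merged$chrom == truth$chrom[i] & merged$start < truth$end[i] &
                    merged$end > truth$start[i], ]
    expect_gte(nrow(hit), 1)
    expect_true(all(hit$direction == truth$direction[i]))
  }
})

test_that("effects below the 0.30 difference threshold are never called", {
  sim <- simulate_cohort(sim_config(seed = 29, n_chrom = 1, chrom_len = 1e6,
                                    n_islands = 2, n_lmr_like = 2, n_icr = 2,
                                    n_meqtl_regions = 0, n_true_dmrs = 6,
                                    dmr_effect = 0.1))
  map <- build_cpg_map(sim$cohort, 5)
  truth <- sim$truth$true_dmrs
  called <- dplyr::bind_rows(call_dmrs_tstat(sim$cohort, map),
                             call_dmrs_segmentation(sim$cohort, map))
  for (i in seq_len(nrow(truth))) {
    expect_false(overlaps_tbl(truth$chrom[i], truth$start[i], truth$end[i], called))
  }
})

test_that("a null cohort produces essentially no DMRs", {
  sim <- simulate_cohort(sim_config(seed = 37, n_chrom = 1, chrom_len = 2e6,
                                    n_islands = 4, n_lmr_like = 4, n_icr = 2,
                                    n_true_dmrs = 0, n_meqtl_regions = 0))
  map <- build_cpg_map(sim$cohort, 5)
  d1 <- call_dmrs_tstat(sim$cohort, map)
  d2 <- call_dmrs_segmentation(sim$cohort, map)
  # tolerance: at most 1 spurious call per 10 Mb, i.e. 0 expected on 2 Mb
  expect_lte(nrow(d1), 1)
  expect_lte(nrow(d2), 1)
})

test_that("segmentation caller locates boundaries within two CpGs", {
  # clean planted region: low noise, high coverage
  sim <- simulate_cohort(sim_config(seed = 41, n_chrom = 1, chrom_len = 1e6,
                                    n_islands = 0, n_lmr_like = 0, n_icr = 0,
                                    n_meqtl_regions = 0, n_true_dmrs = 1,
                                    dmr_n_cpg_range = c(12L, 12L),
                                    coverage_mean = 30, bio_dispersion = 0.005))
  map <- build_cpg_map(sim$cohort, 5)
  truth <- sim$truth$true_dmrs
  d <- call_dmrs_segmentation(sim$cohort, map)
  expect_equal(nrow(d), 1)
  pos <- all_covered_positions(map)
  pos <- pos$pos[pos$chrom == truth$chrom[1]]
  start_off <- abs(findInterval(d$start, pos) - findInterval(truth$start[1], pos))
  end_off <- abs(findInterval(d$end, pos) - findInterval(truth$end[1], pos))
  expect_lte(start_off, 2)
  expect_lte(end_off, 2)
})

test_that("adjacent opposite-direction signals give two opposite DMRs", {
  set.seed(61)
  n <- 60
  base <- 0.5
  lv_ctr <- rep(base, n)
  lv_cz <- lv_ctr
  lv_cz[21:30] <- base + 0.4   # hyper block
  lv_cz[31:40] <- base - 0.4   # immediately adjacent hypo block
  jitter <- function(x) pmin(0.99, pmax(0.01, x + stats::rnorm(n, 0, 0.02)))
  lm <- cbind(sapply(1:4, function(i) jitter(lv_ctr)),
              sapply(1:4, function(i) jitter(lv_cz)))
  colnames(lm) <- c(paste0("CTR", 1:4), paste0("CZ", 1:4))
  co <- make_cohort(lm, rep(c("CTR", "CZ"), each = 4), cov = 50, spacing = 50)
  map <- build_cpg_map(co, 5)
  d <- call_dmrs_segmentation(co, map)
  expect_equal(nrow(d), 2)
  expect_setequal(d$direction, c("hyper_in_cz", "hypo_in_cz"))
})

test_that("merging unions overlaps and recomputes statistics from raw data", {
  sim <- small_sim(seed = 43)
  map <- build_cpg_map(sim$cohort, 5)
  mk <- function(start, end, q, caller) {
    tibble::tibble(chrom = "chr1", start = start, end = end, n_cpg = 5L,
                   per_sample_mean = list(NULL), mean_ctr = 0, mean_cz = 0,
                   diff = 0.5, direction = "hyper_in_cz", range_ctr = 0,
                   range_cz = 0, q_value = q, callers = caller)
  }
  # identical interval from both callers -> one DMR with joint provenance
  a <- mk(10000L, 12000L, NA_real_, "tstat")
  b <- mk(10000L, 12000L, 0.01, "segmentation")
  m <- merge_dmr_sets(list(a, b), sim$cohort, map)
  expect_equal(nrow(m), 1)
  expect_equal(m$callers, "segmentation;tstat")
  expect_equal(m$q_value, 0.01)

  # disjoint intervals pass through unchanged
  m2 <- merge_dmr_sets(list(mk(10000L, 12000L, NA, "tstat"),
                            mk(50000L, 52000L, NA, "tstat")), sim$cohort, map)
  expect_equal(nrow(m2), 2)

  # overlapping intervals union, statistics recomputed over the union
  m3 <- merge_dmr_sets(list(mk(10000L, 12000L, NA, "tstat"),
                            mk(11000L, 14000L, 0.2, "segmentation")),
                       sim$cohort, map)
  expect_equal(nrow(m3), 1)
  expect_equal(m3$start, 10000L)
  expect_equal(m3$end, 14000L)
  # direct recomputation oracle over the union interval
  keep <- all_covered_positions(map)
  keep <- keep[keep$chrom == "chr1" & keep$pos >= 10000 & keep$pos < 14000, ]
  sub <- dplyr::semi_join(sim$cohort, keep, by = c("chrom", "pos"))
  psm <- sub |>
    dplyr::summarise(m = sum(n_meth) / sum(n_total), .by = c(sample_id, group))
  expect_equal(m3$n_cpg, nrow(keep))
  expect_equal(m3$diff, mean(psm$m[psm$group == "CZ"]) - mean(psm$m[psm$group == "CTR"]))
  expect_equal(m3$range_ctr, diff(range(psm$m[psm$group == "CTR"])))
  expect_equal(sort(m3$per_sample_mean[[1]]), sort(setNames(psm$m, psm$sample_id)))
})

test_that("the range filter is inclusive at the boundary and demands means", {
  mk_dmr <- function(ctr, cz) {
    psm <- setNames(c(ctr, cz), c(paste0("CTR", seq_along(ctr)),
                                  paste0("CZ", seq_along(cz))))
    tibble::tibble(chrom = "chr1", start = 1L, end = 2L, n_cpg = 5L,
                   per_sample_mean = list(psm),
                   mean_ctr = mean(ctr), mean_cz = mean(cz),
                   diff = mean(cz) - mean(ctr), direction = "hyper_in_cz",
                   range_ctr = diff(range(ctr)), range_cz = diff(range(cz)),
                   q_value = NA_real_, callers = "tstat")
  }
  kept <- mk_dmr(c(0.1, 0.2, 0.15, 0.35), c(0.6, 0.62, 0.58, 0.61))  # range .25
  gone <- mk_dmr(c(0.1, 0.1, 0.1, 0.1), c(0.1, 0.5, 0.2, 0.2))       # cz range .4
  edge <- mk_dmr(c(0.1, 0.4, 0.2, 0.2), c(0.6, 0.6, 0.6, 0.6))       # exactly .3
  out <- apply_range_filter(dplyr::bind_rows(kept, gone, edge), max_range = 0.30)
  expect_equal(nrow(out), 2)
  expect_false(0.5 %in% unlist(out$per_sample_mean))

  bad <- kept
  bad$per_sample_mean <- list(c(CTR1 = NA_real_))
  expect_error(apply_range_filter(bad), "missing")
})

test_that("every emitted DMR satisfies the published constraints", {
  sim <- small_sim(seed = 47)
  map <- build_cpg_map(sim$cohort, 5)
  d1 <- call_dmrs_tstat(sim$cohort, map)
  d2 <- call_dmrs_segmentation(sim$cohort, map)
  final <- apply_range_filter(apply_threshold_filters(
    merge_dmr_sets(list(d1, d2), sim$cohort, map)))
  expect_gt(nrow(final), 0)
  expect_true(all(final$n_cpg >= 4))
  expect_true(all(abs(final$diff) >= 0.3))
  expect_true(all(is.na(final$q_value) | final$q_value <= 0.05))
  expect_true(all(final$range_ctr <= 0.3 & final$range_cz <= 0.3))
  expect_true(all((final$diff > 0) == (final$direction == "hyper_in_cz")))
  # all constituent CpGs covered >= 5x in every sample, by construction of the
  # map; verify against the raw table for a few DMRs
  for (i in seq_len(min(3, nrow(final)))) {
    keep <- all_covered_positions(map)
    keep <- keep[keep$chrom == final$chrom[i] & keep$pos >= final$start[i] &
                   keep$pos < final$end[i], ]
    sub <- dplyr::semi_join(sim$cohort, keep, by = c("chrom", "pos"))
    expect_true(all(sub$n_total >= 5))
    expect_equal(nrow(sub), final$n_cpg[i] * 8)
  }
})

test_that("the exact binomial direction test matches enumeration and published skews", {
  # symmetric case
  expect_equal(direction_binomial_test(n_hyper = 2, n_total = 4)$p_value, 1.0)
  # published direction skews, recomputed from the printed counts
  expect_equal(signif(direction_binomial_test(n_hyper = 63, n_total = 67)$p_value, 4),
               1.107e-14)
  expect_lt(direction_binomial_test(n_hyper = 238, n_total = 271)$p_value, 2.2e-16)
  # independent exact-summation oracle across a spread of n and k
  for (n in c(1, 2, 5, 17, 67, 128, 300)) {
    for (k in unique(c(0, 1, n %/% 3, n %/% 2, n - 1, n))) {
      expect_equal(direction_binomial_test(n_hyper = k, n_total = n)$p_value,
                   binom_two_sided_oracle(k, n), tolerance = 1e-12)
    }
  }
  # tibble input path
  d <- tibble::tibble(direction = c("hyper_in_cz", "hyper_in_cz", "hypo_in_cz"))
  expect_equal(direction_binomial_test(d)$n_hyper, 2L)
})
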