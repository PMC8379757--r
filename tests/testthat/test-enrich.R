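test_that("the log-normal length model is the MLE of log lengths", {
  m <- fit_length_model(c(exp(1), exp(3)))
  expect_equal(m$meanlog, 2)
  expect_equal(m$sdlog, sd(c(1, 3)))
  expect_warning(m0 <- fit_length_model(rep(100, 5)), "degenerate")
  expect_equal(m0$sdlog, 1e-6)
  expect_equal(m0$meanlog, log(100))
  expect_error(fit_length_model(100), "at least 2")
  expect_error(fit_length_model(c(0, 10)), "positive")
  # parameter recovery on a large simulated draw
  set.seed(1)
  mr <- fit_length_model(rlnorm(1000, 5, 0.7))
  expect_lt(abs(mr$meanlog - 5), 0.1)
  expect_lt(abs(mr$sdlog - 0.7), 0.1)
  # broom-style accessors
  expect_equal(tidy(m)$term, c("meanlog", "sdlog"))
  expect_equal(glance(m)$n, 2L)
})

test_that("matched sets preserve each template's CpG count exactly", {
  sim <- small_sim(seed = 53)
  map <- build_cpg_map(sim$cohort, 5)
  set.seed(2)
  tmpl <- tibble::tibble(chrom = "chr1", start = 0L, end = 1L,
                         n_cpg = sample(4:20, 30, replace = TRUE))
  model <- fit_length_model(rlnorm(100, log(1000), 0.4))
  keep <- all_covered_positions(map)
  for (r in 1:5) {
    s <- simulate_matched_set(tmpl, map, model, pool_size = 50)
    expect_identical(s$n_cpg, tmpl$n_cpg)
    # every simulated interval covers exactly n consecutive all-covered CpGs
    for (i in seq_len(5)) {
      inside <- keep[keep$chrom == s$chrom[i] & keep$pos >= s$start[i] &
                       keep$pos < s$end[i], ]
      expect_equal(nrow(inside), s$n_cpg[i])
      expect_equal(min(inside$pos), s$start[i])
      expect_equal(max(inside$pos) + 1L, s$end[i])
    }
  }
})

test_that("uniform spacing collapses the length weighting to uniform choice", {
  # a map with exactly equal spacing: all candidates share one length, so the
  # selection is uniform over starts and lengths are constant
  co <- make_cohort(matrix(0.5, nrow = 200, ncol = 4,
                           dimnames = list(NULL, c("CTR1", "CTR2", "CZ1", "CZ2"))),
                    groups = c("CTR", "CTR", "CZ", "CZ"), cov = 10, spacing = 100)
  map <- build_cpg_map(co, 5)
  tmpl <- tibble::tibble(chrom = "chr1", start = 0L, end = 1L, n_cpg = c(5L, 5L))
  model <- fit_length_model(c(300, 500, 400))
  set.seed(3)
  s <- purrr::map(1:50, ~simulate_matched_set(tmpl, map, model, pool_size = 20)) |>
    purrr::list_rbind()
  expect_true(all(s$end - s$start == 401L))
})

test_that("selection matches the exhaustive density-weighted oracle", {
  # heterogeneous 50-CpG toy map: enumerate every candidate placement of n
  # consecutive CpGs, weight by the log-normal density of its length, and
  # compare the mean simulated length to the weighted mean
  set.seed(4)
  gaps <- sample(c(20, 50, 100, 400, 800), 49, replace = TRUE)
  pos <- cumsum(c(1000, gaps))
  lv <- rep(0.5, 50)
  co <- purrr::map(c(CTR1 = "CTR", CTR2 = "CTR", CZ1 = "CZ", CZ2 = "CZ"),
                   \(g) NULL)
  co <- purrr::imap(list(CTR1 = "CTR", CTR2 = "CTR", CZ1 = "CZ", CZ2 = "CZ"),
    function(g, id) tibble::tibble(sample_id = id, group = g, chrom = "chr1",
                                   pos = as.integer(pos), n_meth = 5L,
                                   n_total = 10L)) |> purrr::list_rbind()
  map <- build_cpg_map(co, 5)
  n <- 8L
  model <- fit_length_model(rlnorm(50, log(1500), 0.3))
  starts <- seq_len(50 - n + 1)
  cand_len <- pos[starts + n - 1] - pos[starts] + 1
  w <- dlnorm(cand_len, model$meanlog, model$sdlog)
  oracle_mean <- sum(w * cand_len) / sum(w)
  tmpl <- tibble::tibble(chrom = "chr1", start = 0L, end = 1L, n_cpg = n)
  set.seed(5)
  sims <- replicate(600, {
    s <- simulate_matched_set(tmpl, map, model, pool_size = 1000)
    s$end - s$start
  })
  expect_lt(abs(mean(sims) - oracle_mean) / oracle_mean, 0.05)
})

test_that("degenerate tracks give saturated or empty overlap with p = 1", {
  sim <- small_sim(seed = 59)
  map <- build_cpg_map(sim$cohort, 5)
  dmrs <- simulate_matched_set(
    tibble::tibble(chrom = "chr1", start = 0L, end = 1L, n_cpg = rep(6L, 10)),
    map, fit_length_model(rlnorm(50, log(600), 0.3)), pool_size = 50)
  whole <- tibble::tibble(chrom = unique(map$positions$chrom), start = 0L, end = 10^7L)
  empty <- whole[0, ]
  set.seed(6)
  e <- enrichment_test(dmrs, list(whole = whole, empty = empty), map,
                       n_sets = 200, pool_size = 50)
  ew <- e[e$track == "whole", ]
  expect_equal(ew$observed, 10L)
  expect_equal(ew$null_mean, 10)
  expect_equal(ew$p_enrich, 1)
  expect_equal(ew$odds_ratio, 1)
  ee <- e[e$track == "empty", ]
  expect_equal(ee$observed, 0L)
  expect_equal(ee$p_deplete, 1)
  expect_equal(ee$odds_ratio, 1)
  # empirical p can never be zero
  expect_true(all(e$p_enrich >= 1 / 201 & e$p_deplete >= 1 / 201))
  expect_error(enrichment_test(dmrs, list(whole = whole), map, n_sets = 50),
               "at least 100")
})

test_that("planted feature enrichment is detected with a large odds ratio", {
  sim <- small_sim(seed = 67)
  map <- build_cpg_map(sim$cohort, 5)
  truth <- sim$truth$true_dmrs
  d1 <- call_dmrs_tstat(sim$cohort, map)
  d2 <- call_dmrs_segmentation(sim$cohort, map)
  final <- apply_range_filter(apply_threshold_filters(
    merge_dmr_sets(list(d1, d2), sim$cohort, map)))
  # feature track = padded truth regions (a small fraction of CpG space)
  feat <- dplyr::mutate(truth[c("chrom", "start", "end")],
                        start = pmax(0L, start - 500L), end = end + 500L)
  set.seed(7)
  e <- enrichment_test(final, list(planted = feat), map, n_sets = 1000,
                       pool_size = 200)
  expect_equal(e$direction, "enriched")
  expect_lte(e$p_enrich, 0.01)
  expect_gt(e$odds_ratio, 5)
})
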