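mk_tracks <- function() {
  dplyr::bind_rows(
    tibble::tibble(feature_class = "gene", chrom = "chr1", start = 1000L,
                   end = 9000L, name = "A", strand = "+", gene_symbol = "A",
                   target_genes = NA_character_),
    tibble::tibble(feature_class = "exon", chrom = "chr1",
                   start = c(1000L, 8000L), end = c(1500L, 9000L),
                   name = c("A_ex1", "A_ex2"), strand = "+", gene_symbol = "A",
                   target_genes = NA_character_),
    tibble::tibble(feature_class = "intron", chrom = "chr1", start = 1500L,
                   end = 8000L, name = "A_int", strand = "+", gene_symbol = "A",
                   target_genes = NA_character_),
    tibble::tibble(feature_class = "promoter", chrom = "chr1", start = 0L,
                   end = 2000L, name = "A_prom", strand = "+", gene_symbol = "A",
                   target_genes = NA_character_),
    tibble::tibble(feature_class = "enhancer", chrom = "chr1", start = 20000L,
                   end = 21000L, name = "E1", strand = "*",
                   gene_symbol = NA_character_, target_genes = "A;B")
  )
}

mk_dmr <- function(chrom, start, end, direction = "hyper_in_cz") {
  tibble::tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
                 n_cpg = 5L, diff = ifelse(direction == "hyper_in_cz", 0.4, -0.4),
                 direction = direction)
}

test_that("the overlap matrix respects containment and half-open boundaries", {
  tracks <- mk_tracks()
  inside_intron <- mk_dmr("chr1", 3000, 3500)
  ann <- annotate_dmrs(inside_intron, tracks)
  expect_true(ann$gene); expect_true(ann$intron)
  expect_false(ann$exon); expect_false(ann$intergenic)

  # shared boundary only: gene ends at 9000, DMR starts at 9000 -> no overlap
  abutting <- mk_dmr("chr1", 9000, 9500)
  ann2 <- annotate_dmrs(abutting, tracks)
  expect_false(ann2$gene)
  expect_true(ann2$intergenic)

  expect_error(annotate_dmrs(mk_dmr("chrX", 1, 10), tracks), "chrX")
})

test_that("the overlap matrix equals the quadratic brute-force oracle", {
  set.seed(8)
  n <- 300
  rnd_iv <- function(n, cls) {
    s <- sample.int(5e4, n)
    tibble::tibble(feature_class = cls, chrom = sample(c("chr1", "chr2"), n, TRUE),
                   start = s, end = s + sample.int(2000, n),
                   gene_symbol = NA_character_, target_genes = NA_character_)
  }
  tracks <- dplyr::bind_rows(rnd_iv(n, "gene"), rnd_iv(n, "CGI"))
  s <- sample.int(5e4, 100)
  dmrs <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 100, TRUE),
                         start = s, end = s + sample.int(1500, 100))
  ann <- annotate_dmrs(dmrs, tracks)
  for (cls in c("gene", "CGI")) {
    tr <- tracks[tracks$feature_class == cls, ]
    oracle <- vapply(seq_len(nrow(dmrs)), function(i) {
      any(tr$chrom == dmrs$chrom[i] & tr$start < dmrs$end[i] &
            tr$end > dmrs$start[i])
    }, logical(1))
    expect_identical(unname(ann[[cls]]), oracle)
  }
})

test_that("gene association joins gene-body, promoter and enhancer evidence", {
  tracks <- mk_tracks()
  # enhancer targeting A and B -> two associations with enhancer evidence
  d_enh <- mk_dmr("chr1", 20500, 20600)
  a <- associate_genes(d_enh, tracks)
  expect_equal(nrow(a), 2)
  expect_setequal(a$gene_symbol, c("A", "B"))
  expect_true(all(a$evidence == "enhancer_target"))

  # promoter of A also inside A's gene body -> combined evidence string
  d_prom <- mk_dmr("chr1", 1200, 1400)
  b <- associate_genes(d_prom, tracks)
  expect_equal(b$gene_symbol, "A")
  expect_equal(b$evidence, "gene_body;promoter")

  # association is independent of track row order
  a2 <- associate_genes(d_enh, tracks[sample.int(nrow(tracks)), ])
  expect_identical(a, a2)
})

test_that("planted DMR-gene links are fully recovered on synthetic truth", {
  sim <- small_sim(seed = 71)
  genes <- sim$truth$tracks[sim$truth$tracks$feature_class == "gene", ]
  # place one DMR inside each of 6 genes
  dmrs <- genes[seq_len(6), ] |>
    dplyr::transmute(chrom, start = start + 100L, end = start + 600L)
  assoc <- associate_genes(dmrs, sim$truth$tracks)
  hit <- dplyr::semi_join(
    tibble::tibble(dmr_id = paste0(dmrs$chrom, ":", dmrs$start, "-", dmrs$end),
                   gene_symbol = genes$gene_symbol[seq_len(6)]),
    assoc, by = c("dmr_id", "gene_symbol"))
  expect_equal(nrow(hit), 6)
})

test_that("gene-list intersections count union and shared-all after synonyms", {
  res <- intersect_gene_lists(c("A", "B", "C", "D"),
                              list(l1 = c("A", "B"), l2 = c("B", "C"), l3 = "B"))
  expect_equal(res$per_list$n_hits, c(2L, 2L, 1L))
  expect_equal(res$union_hits, 3)
  expect_equal(res$shared_all, 1)
  expect_equal(res$genes_shared, "B")

  # synonym normalization applies before the set operations
  res2 <- intersect_gene_lists(c("Aold", "B"), list(l1 = "A"),
                               synonym_map = c(Aold = "A"))
  expect_equal(res2$union_hits, 1)
  expect_equal(res2$genes_union, "A")

  res3 <- intersect_gene_lists(c("A", "B"), list())
  expect_equal(res3$union_hits, 0)
  expect_equal(res3$shared_all, 0)
})

test_that("direction skew of an association subset uses the exact binomial", {
  dmrs <- add_dmr_id(dplyr::bind_rows(
    mk_dmr("chr1", 1, 100), mk_dmr("chr1", 200, 300),
    mk_dmr("chr1", 400, 500), mk_dmr("chr1", 600, 700)))
  assoc <- tibble::tibble(dmr_id = dmrs$dmr_id, gene_symbol = "A",
                          evidence = "gene_body")
  # all four hyper: p = 2 * (1/2)^4 = 0.125
  expect_equal(subset_direction_test(assoc, dmrs)$p_value, 0.125)
  # one of two: p = 1
  dmrs2 <- dmrs[1:2, ]
  dmrs2$direction[2] <- "hypo_in_cz"
  expect_equal(subset_direction_test(assoc[1:2, ], dmrs2)$p_value, 1.0)
  # the published subset: 63 hyper of 67
  dmrs67 <- add_dmr_id(purrr::map(1:67, function(i) {
    mk_dmr("chr1", i * 1000, i * 1000 + 100,
           direction = if (i <= 63) "hyper_in_cz" else "hypo_in_cz")
  }) |> purrr::list_rbind())
  assoc67 <- tibble::tibble(dmr_id = dmrs67$dmr_id, gene_symbol = "G",
                            evidence = "gene_body")
  expect_equal(signif(subset_direction_test(assoc67, dmrs67)$p_value, 4), 1.107e-14)
})
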