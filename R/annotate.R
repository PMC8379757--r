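#' Overlap DMRs with annotation tracks
#'
#' Computes the per-DMR boolean overlap matrix over the feature classes of an
#' annotation track table (any-bp overlap, 0-based half-open: intervals sharing
#' only a boundary do not overlap). When a `gene` class is present an
#' `intergenic` column is derived as "overlaps no gene".
#'
#' @param dmrs DMR tibble (a `dmr_id` column is added if absent).
#' @param tracks Annotation tibble: `feature_class`, `chrom`, `start`, `end`,
#'   plus attribute columns (`gene_symbol`, `target_genes`, ...).
#' @return Tibble: `dmr_id`, `chrom`, `start`, `end`, `direction` (if present)
#'   and one logical column per feature class.
#' @export
annotate_dmrs <- function(dmrs, tracks) {
  if (!"dmr_id" %in% names(dmrs)) dmrs <- add_dmr_id(dmrs)
  if (nrow(dmrs)) {
    missing_chrom <- setdiff(unique(dmrs$chrom), unique(tracks$chrom))
    if (length(missing_chrom)) {
      abort(paste0("DMR chromosome(s) absent from annotation tracks: ",
                   paste(missing_chrom, collapse = ", ")))
    }
  }
  out <- dmrs[intersect(c("dmr_id", "chrom", "start", "end", "direction"),
                        names(dmrs))]
  for (cls in sort(unique(tracks$feature_class))) {
    out[[cls]] <- .overlaps_any(dmrs, tracks[tracks$feature_class == cls, ])
  }
  if ("gene" %in% names(out)) out$intergenic <- !out$gene
  out
}

#' Associate DMRs with genes
#'
#' A DMR is associated with a gene when it overlaps the gene body, the gene's
#' promoter, or an enhancer whose target list names the gene. One record per
#' (DMR, gene) pair; the evidence column collects the supporting routes.
#' Deterministic and independent of track row order.
#'
#' @param dmrs DMR tibble.
#' @param tracks Annotation tibble; `gene` and `promoter` rows carry
#'   `gene_symbol`, `enhancer` rows carry semicolon-separated `target_genes`.
#' @return Tibble: `dmr_id`, `gene_symbol`, `evidence`
#'   (";"-joined subset of gene_body/promoter/enhancer_target).
#' @export
associate_genes <- function(dmrs, tracks) {
  if (!"dmr_id" %in% names(dmrs)) dmrs <- add_dmr_id(dmrs)
  pair_hits <- function(sub, label, symbols) {
    if (nrow(sub) == 0 || nrow(dmrs) == 0) {
      return(tibble(dmr_id = character(), gene_symbol = character(),
                    evidence = character()))
    }
    h <- GenomicRanges::findOverlaps(.as_gr(dmrs), .as_gr(sub))
    tibble(dmr_id = dmrs$dmr_id[S4Vectors::queryHits(h)],
           gene_symbol = symbols[S4Vectors::subjectHits(h)],
           evidence = label)
  }
  genes <- tracks[tracks$feature_class == "gene", ]
  proms <- tracks[tracks$feature_class == "promoter", ]
  enh <- tracks[tracks$feature_class == "enhancer", ]
  recs <- bind_rows(
    pair_hits(genes, "gene_body", genes$gene_symbol),
    pair_hits(proms, "promoter", proms$gene_symbol),
    pair_hits(enh, "enhancer_target", enh$target_genes)
  )
  if (nrow(recs)) {
    # expand semicolon-separated enhancer targets into one row per gene
    recs <- recs |>
      mutate(gene_symbol = strsplit(.data$gene_symbol, ";", fixed = TRUE)) |>
      unnest("gene_symbol") |>
      dplyr::filter(!is.na(.data$gene_symbol), .data$gene_symbol != "")
  }
  recs |>
    group_by(.data$dmr_id, .data$gene_symbol) |>
    summarise(evidence = paste(sort(unique(.data$evidence)), collapse = ";"),
              .groups = "drop") |>
    arrange(.data$dmr_id, .data$gene_symbol)
}

#' Intersect DMR-associated genes with external gene lists
#'
#' Normalizes symbols through a synonym map (old -> approved), then reports the
#' per-list hit counts, the union count ("in at least one list") and the full
#' intersection ("shared between all lists") against the DMR-associated genes.
#'
#' @param dmr_genes Character vector of DMR-associated gene symbols.
#' @param external_lists Named list of character vectors.
#' @param synonym_map Optional two-column tibble (`old`, `approved`) or named
#'   character vector mapping old symbols to approved ones.
#' @return List: `per_list` (tibble `list_name`, `n_hits`, `genes`),
#'   `union_hits`, `shared_all`, `genes_union`, `genes_shared`.
#' @export
intersect_gene_lists <- function(dmr_genes, external_lists, synonym_map = NULL) {
  normalize <- function(x) {
    x <- unique(x[!is.na(x)])
    if (is.null(synonym_map) || length(synonym_map) == 0) return(x)
    m <- if (is.data.frame(synonym_map)) {
      setNames(synonym_map$approved, synonym_map$old)
    } else synonym_map
    hit <- x %in% names(m)
    x[hit] <- unname(m[x[hit]])
    unique(x)
  }
  dg <- normalize(dmr_genes)
  lists <- lapply(external_lists, normalize)
  hits <- lapply(lists, function(l) intersect(dg, l))
  per_list <- tibble(
    list_name = names(external_lists) %||% paste0("list", seq_along(lists)),
    n_hits = unname(vapply(hits, length, integer(1))),
    genes = unname(vapply(hits, function(g) paste(sort(g), collapse = ";"),
                          character(1)))
  )
  genes_union <- sort(unique(unlist(hits)))
  genes_shared <- if (length(hits)) sort(Reduce(intersect, hits)) else character()
  list(per_list = per_list,
       union_hits = length(genes_union),
       shared_all = length(genes_shared),
       genes_union = genes_union,
       genes_shared = genes_shared)
}

#' Direction skew of the DMRs behind a gene subset
#'
#' Counts the unique DMRs appearing in an association table (optionally
#' restricted to a gene set) by direction and applies the exact two-sided
#' binomial test of [direction_binomial_test()].
#'
#' @param associations Output of [associate_genes()].
#' @param dmrs DMR tibble carrying `dmr_id` and `direction`.
#' @param genes Optional gene symbols to restrict the associations to.
#' @return One-row tibble: `n_hyper`, `n_total`, `p_value`.
#' @export
subset_direction_test <- function(associations, dmrs, genes = NULL) {
  if (!"dmr_id" %in% names(dmrs)) dmrs <- add_dmr_id(dmrs)
  sub <- associations
  if (!is.null(genes)) sub <- sub[sub$gene_symbol %in% genes, ]
  ids <- unique(sub$dmr_id)
  d <- dmrs[dmrs$dmr_id %in% ids, ]
  if (nrow(d) == 0) abort("no DMRs in the association subset")
  direction_binomial_test(d)
}
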