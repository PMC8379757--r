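#' Segment a methylome into UMRs and LMRs
#'
#' Simplified MethylSeekR-style segmentation. Per-CpG methylation is the
#' posterior mean under add-one smoothing, `(n_meth + 1) / (n_total + 2)`,
#' passed through a 3-CpG running median. Maximal runs of consecutive covered
#' CpGs whose smoothed level stays below `meth_cutoff` become segments, trimmed
#' to the first/last CpG, and must contain at least `min_cpg` CpGs and have a
#' raw coverage-weighted mean below the cutoff. Segments with at least
#' `cpg_class_threshold` CpGs are classified as unmethylated regions (UMRs,
#' proximal-regulatory proxies), the rest as low-methylated regions (LMRs,
#' distal-regulatory proxies). No PMD masking is performed: the germ-cell
#' methylomes this models are treated as PMD-free.
#'
#' @param meth One sample's methylome tibble.
#' @param meth_cutoff Methylation threshold below which CpGs are segment
#'   material.
#' @param min_cpg Minimum CpGs per segment.
#' @param cpg_class_threshold UMR/LMR class split on CpG count.
#' @param min_cov Minimum coverage for a CpG to be considered.
#' @param sample_id Optional id stamped on the output.
#' @return Tibble: `chrom`, `start`, `end`, `seg_class` ("UMR"/"LMR"),
#'   `n_cpg`, `mean_meth`, `sample_id`. Segments never overlap within a
#'   sample.
#' @export
segment_methylome <- function(meth, meth_cutoff = 0.5, min_cpg = 4,
                              cpg_class_threshold = 30, min_cov = 5,
                              sample_id = NULL) {
  validate_methylome(meth)
  sample_id <- sample_id %||%
    (if ("sample_id" %in% names(meth) && nrow(meth)) meth$sample_id[[1]] else NA_character_)
  meth <- meth[meth$n_total >= min_cov, ] |> arrange(.data$chrom, .data$pos)
  out <- list()
  for (ch in unique(meth$chrom)) {
    sub <- meth[meth$chrom == ch, ]
    if (nrow(sub) == 0) next
    post <- (sub$n_meth + 1) / (sub$n_total + 2)
    sm <- if (length(post) >= 3) as.numeric(runmed(post, 3, endrule = "median")) else post
    low <- sm < meth_cutoff
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_cpg)) {
      i <- starts[k]:ends[k]
      mu <- sum(sub$n_meth[i]) / sum(sub$n_total[i])
      if (mu >= meth_cutoff) next
      out[[length(out) + 1L]] <- tibble(
        chrom = ch, start = sub$pos[i[1]], end = sub$pos[i[length(i)]] + 1L,
        seg_class = if (length(i) >= cpg_class_threshold) "UMR" else "LMR",
        n_cpg = length(i), mean_meth = mu, sample_id = sample_id
      )
    }
  }
  if (!length(out)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  seg_class = character(), n_cpg = integer(),
                  mean_meth = double(), sample_id = character()))
  }
  list_rbind(out) |> arrange(.data$chrom, .data$start)
}

#' Segment every sample of a cohort
#'
#' @param cohort Long cohort tibble.
#' @param ... Passed to [segment_methylome()].
#' @return Row-bound segment tibble across samples.
#' @export
segment_cohort <- function(cohort, ...) {
  ids <- unique(cohort$sample_id)
  purrr::map(ids, function(id) {
    segment_methylome(cohort[cohort$sample_id == id, ], ..., sample_id = id)
  }) |> list_rbind()
}

#' High-confidence consensus regions across samples
#'
#' Builds the consensus track of segments supported by at least `min_support`
#' samples, per segment class. The default interpretation is base-pair-wise:
#' maximal intervals where the per-base count of samples whose segment covers
#' the base reaches `min_support`. The alternative `"region"` method keeps
#' whole segments overlapped (any bp) by segments of the same class from at
#' least `min_support` distinct samples, then unions them.
#'
#' @param segments Segment tibble with `sample_id` and `seg_class` (from
#'   [segment_cohort()]); typically restricted to the control group.
#' @param min_support Minimum number of supporting samples.
#' @param method `"basepair"` (default) or `"region"`.
#' @return Tibble `chrom`, `start`, `end`, `seg_class`.
#' @export
high_confidence_regions <- function(segments, min_support = 3,
                                    method = c("basepair", "region")) {
  method <- match.arg(method)
  n_samples <- length(unique(segments$sample_id))
  if (min_support > n_samples) {
    abort(paste0("min_support (", min_support, ") exceeds number of samples (",
                 n_samples, ")"))
  }
  out <- list()
  for (cls in sort(unique(segments$seg_class))) {
    sub <- segments[segments$seg_class == cls, ]
    if (nrow(sub) == 0) next
    gr <- .as_gr(sub)
    res <- if (method == "basepair") {
      cov <- GenomicRanges::coverage(gr)
      GenomicRanges::GRanges(IRanges::slice(cov, lower = min_support,
                                            rangesOnly = TRUE))
    } else {
      support <- vapply(seq_along(gr), function(i) {
        hits <- IRanges::overlapsAny(gr, gr[i])
        length(unique(sub$sample_id[hits]))
      }, integer(1))
      GenomicRanges::reduce(gr[support >= min_support])
    }
    if (length(res)) {
      tb <- .gr_as_tbl(res)
      tb$seg_class <- cls
      out[[length(out) + 1L]] <- tb
    }
  }
  if (!length(out)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  seg_class = character()))
  }
  list_rbind(out) |> arrange(.data$seg_class, .data$chrom, .data$start)
}
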