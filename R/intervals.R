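# Internal interval helpers. All package coordinates are 0-based half-open
# (BED convention); GRanges are 1-based closed, so conversion happens only
# inside these wrappers.

.as_gr <- function(x) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}

.gr_as_tbl <- function(gr) {
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr))
}

# points (positions) as width-1 GRanges
.pos_gr <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos + 1L, x$pos + 1L))
}

# any-bp overlap indicator of query intervals against subject intervals
.overlaps_any <- function(query, subject) {
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  if (nrow(query) == 0) return(logical())
  IRanges::overlapsAny(.as_gr(query), .as_gr(subject))
}

#' Merge overlapping intervals
#'
#' Unions any-bp-overlapping intervals across one or more interval tables
#' (0-based half-open). Book-ended intervals (shared boundary) are not merged.
#'
#' @param ... Tibbles with `chrom`, `start`, `end`.
#' @return Tibble of maximal merged intervals, sorted.
#' @export
merge_intervals <- function(...) {
  x <- bind_rows(...)
  if (nrow(x) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  .gr_as_tbl(GenomicRanges::reduce(.as_gr(x))) |>
    arrange(.data$chrom, .data$start, .data$end)
}

# complement of intervals within chromosome bounds given by `sizes`
# (named vector chrom -> length in bp)
.complement_intervals <- function(x, sizes) {
  out <- list()
  for (ch in names(sizes)) {
    sub <- x[x$chrom == ch, , drop = FALSE]
    sub <- merge_intervals(sub)
    starts <- c(0L, sub$end)
    ends <- c(sub$start, as.integer(sizes[[ch]]))
    keep <- starts < ends
    out[[ch]] <- tibble(chrom = ch, start = starts[keep], end = ends[keep])
  }
  list_rbind(out)
}
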