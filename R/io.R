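#' Read a per-CpG methylation table
#'
#' Reads a MethylDackel-style per-CpG methylation table for one sample. Two
#' dialects are supported: `bedgraph_counts` (chrom, start, end, n_meth,
#' n_unmeth) and `percent_counts` (chrom, start, end, percent, n_meth,
#' n_unmeth). Coordinates are 0-based half-open; `pos` is the position of the
#' cytosine on the plus strand (counts are assumed already destranded
#' upstream). Inputs declared `one_based = TRUE` are shifted to 0-based.
#'
#' @param path Path to a tab-separated file without header.
#' @param dialect Column layout, see above.
#' @param sample_id Optional sample identifier added as a column.
#' @param group Optional group label (e.g. "CTR"/"CZ") added as a column.
#' @param one_based If `TRUE`, input start coordinates are 1-based and are
#'   shifted down by one.
#' @return A tibble with columns `chrom`, `pos`, `n_meth`, `n_total`, sorted by
#'   (chrom, pos), plus `sample_id`/`group` when supplied. Duplicate
#'   (chrom, pos) rows are an error, not merged: they indicate an upstream
#'   preprocessing fault.
#' @export
read_methylation_table <- function(path,
                                   dialect = c("bedgraph_counts", "percent_counts"),
                                   sample_id = NULL, group = NULL,
                                   one_based = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  cols <- switch(dialect,
    bedgraph_counts = c("chrom", "start", "end", "n_meth", "n_unmeth"),
    percent_counts  = c("chrom", "start", "end", "percent", "n_meth", "n_unmeth")
  )
  raw <- suppressWarnings(
    readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                    col_types = readr::cols(chrom = "c", .default = "d"),
                    progress = FALSE, comment = "#")
  )
  if (nrow(raw) == 0) {
    out <- tibble(chrom = character(), pos = integer(),
                  n_meth = integer(), n_total = integer())
    return(.stamp_sample(out, sample_id, group))
  }
  bad <- which(!stats::complete.cases(raw[c("chrom", "start", "n_meth", "n_unmeth")]) |
                 raw$n_meth < 0 | raw$n_unmeth < 0)
  if (length(bad) > 0) {
    abort(paste0("malformed row(s) in ", path, " at line(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  out <- tibble(
    chrom = raw$chrom,
    pos = as.integer(raw$start) - as.integer(one_based),
    n_meth = as.integer(raw$n_meth),
    n_total = as.integer(raw$n_meth) + as.integer(raw$n_unmeth)
  )
  dup <- duplicated(out[c("chrom", "pos")])
  if (any(dup)) {
    key <- paste0(out$chrom[dup], ":", out$pos[dup])
    abort(paste0("duplicate CpG position(s) in ", path, ": ",
                 paste(head(unique(key), 5), collapse = ", ")))
  }
  if (any(out$n_meth > out$n_total)) abort("n_meth exceeds n_total after reconstruction")
  out <- arrange(out, .data$chrom, .data$pos)
  .stamp_sample(out, sample_id, group)
}

.stamp_sample <- function(x, sample_id, group) {
  if (!is.null(sample_id)) x$sample_id <- if (nrow(x)) sample_id else character()
  if (!is.null(group)) x$group <- if (nrow(x)) group else character()
  x
}

#' Write a per-CpG methylation table
#'
#' Inverse of [read_methylation_table()]: writes one sample's records in the
#' requested dialect, sorted by (chrom, pos), 0-based half-open.
#'
#' @param meth Tibble with `chrom`, `pos`, `n_meth`, `n_total`.
#' @param path Output path.
#' @param dialect See [read_methylation_table()].
#' @return `path`, invisibly.
#' @export
write_methylation_table <- function(meth, path,
                                    dialect = c("bedgraph_counts", "percent_counts")) {
  dialect <- match.arg(dialect)
  validate_methylome(meth)
  meth <- arrange(meth, .data$chrom, .data$pos)
  out <- tibble(
    chrom = meth$chrom, start = meth$pos, end = meth$pos + 1L
  )
  if (dialect == "percent_counts") {
    out$percent <- ifelse(meth$n_total > 0, 100 * meth$n_meth / meth$n_total, 0)
  }
  out$n_meth <- meth$n_meth
  out$n_unmeth <- meth$n_total - meth$n_meth
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Validate a methylome table
#'
#' Checks the invariants every downstream stage relies on: required columns,
#' non-negative counts with `n_meth <= n_total`, and no duplicated
#' (sample, chrom, pos) key. Works for one sample or a long cohort table with a
#' `sample_id` column.
#'
#' @param meth Methylome tibble.
#' @return `meth`, invisibly; aborts on violation.
#' @export
validate_methylome <- function(meth) {
  need <- c("chrom", "pos", "n_meth", "n_total")
  miss <- setdiff(need, names(meth))
  if (length(miss)) abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  if (nrow(meth) == 0) return(invisible(meth))
  if (any(meth$n_meth < 0) || any(meth$n_total < 0) || any(meth$n_meth > meth$n_total)) {
    abort("invalid counts: need 0 <= n_meth <= n_total")
  }
  key <- if ("sample_id" %in% names(meth)) {
    paste(meth$sample_id, meth$chrom, meth$pos)
  } else {
    paste(meth$chrom, meth$pos)
  }
  if (anyDuplicated(key)) abort("duplicate (sample, chrom, pos) records")
  invisible(meth)
}

#' Assemble a cohort table from per-sample files
#'
#' @param paths Named character vector of file paths; names are sample ids.
#' @param groups Character vector of group labels, parallel to `paths`.
#' @param dialect,one_based Passed to [read_methylation_table()].
#' @return Long cohort tibble: `sample_id`, `group`, `chrom`, `pos`, `n_meth`,
#'   `n_total`.
#' @export
read_cohort <- function(paths, groups, dialect = "bedgraph_counts", one_based = FALSE) {
  stopifnot(length(paths) == length(groups))
  ids <- names(paths) %||% paste0("S", seq_along(paths))
  purrr::map2(seq_along(paths), ids, function(i, id) {
    read_methylation_table(paths[[i]], dialect = dialect, sample_id = id,
                           group = groups[[i]], one_based = one_based)
  }) |>
    list_rbind() |>
    select("sample_id", "group", "chrom", "pos", "n_meth", "n_total")
}

#' Write intervals as BED
#'
#' Writes 0-based half-open intervals as tab-separated BED, sorted by
#' (chrom, start, end). Any extra columns are written after the first three in
#' their input order.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optional extras.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) && any(intervals$start >= intervals$end)) {
    abort("invalid interval: need start < end")
  }
  extra <- setdiff(names(intervals), c("chrom", "start", "end"))
  out <- intervals[c("chrom", "start", "end", extra)] |>
    arrange(.data$chrom, .data$start, .data$end)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED-like annotation track
#'
#' Reads tab-separated BED with optional extra columns; column names beyond the
#' first three are taken from `extra_cols`.
#'
#' @param path Input path.
#' @param extra_cols Names of columns after chrom/start/end (in file order).
#' @return Tibble with `chrom`, `start`, `end` plus `extra_cols`.
#' @export
read_bed <- function(path, extra_cols = character()) {
  cols <- c("chrom", "start", "end", extra_cols)
  x <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE, progress = FALSE)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  as_tibble(x)
}
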