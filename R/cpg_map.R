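#' Build the cohort-wide CpG map
#'
#' The CpG map is the union of all CpG positions observed in any sample,
#' together with a per-sample coverage mask at the chosen minimum coverage.
#' All regional analyses (group comparison, DMR calling, matched
#' randomization) operate on the subset of positions covered at `min_cov` in
#' every sample, mirroring the usual "minimum coverage of five in all samples"
#' locus filter.
#'
#' @param cohort Long cohort tibble (see [read_cohort()]).
#' @param min_cov Minimum per-sample read count for a position to be flagged
#'   covered in that sample.
#' @return An object of class `cpg_map`: a list with `positions` (tibble
#'   `chrom`, `pos`), `covered` (logical matrix, positions x samples, sample
#'   columns sorted by id), `samples`, `groups` (named by sample), `min_cov`
#'   and `all_covered` (logical vector). Construction is independent of sample
#'   input order.
#' @export
build_cpg_map <- function(cohort, min_cov = 5) {
  validate_methylome(cohort)
  if (!"sample_id" %in% names(cohort)) cohort$sample_id <- "S1"
  samples <- sort(unique(cohort$sample_id))
  if (length(samples) < 1 || nrow(cohort) == 0) {
    m <- matrix(logical(), nrow = 0, ncol = length(samples),
                dimnames = list(NULL, samples))
    return(structure(list(positions = tibble(chrom = character(), pos = integer()),
                          covered = m, samples = samples,
                          groups = .cohort_groups(cohort, samples),
                          min_cov = min_cov, all_covered = logical()),
                     class = "cpg_map"))
  }
  wide <- cohort |>
    mutate(flag = .data$n_total >= min_cov) |>
    select("chrom", "pos", "sample_id", "flag") |>
    pivot_wider(names_from = "sample_id", values_from = "flag",
                values_fill = FALSE) |>
    arrange(.data$chrom, .data$pos)
  covered <- as.matrix(wide[, samples, drop = FALSE])
  rownames(covered) <- NULL
  structure(list(
    positions = wide[c("chrom", "pos")],
    covered = covered,
    samples = samples,
    groups = .cohort_groups(cohort, samples),
    min_cov = min_cov,
    all_covered = rowSums(covered) == length(samples)
  ), class = "cpg_map")
}

.cohort_groups <- function(cohort, samples) {
  if (!"group" %in% names(cohort)) {
    return(setNames(rep(NA_character_, length(samples)), samples))
  }
  g <- cohort |> distinct(.data$sample_id, .data$group)
  setNames(g$group, g$sample_id)[samples]
}

#' @export
print.cpg_map <- function(x, ...) {
  cat("<cpg_map> ", nrow(x$positions), " positions, ",
      length(x$samples), " samples, min_cov=", x$min_cov, "; ",
      sum(x$all_covered), " covered in all samples\n", sep = "")
  invisible(x)
}

#' Positions covered in all samples
#'
#' @param map A [build_cpg_map()] object.
#' @return Tibble `chrom`, `pos` of positions covered at `min_cov` in every
#'   sample of the cohort.
#' @export
all_covered_positions <- function(map) {
  stopifnot(inherits(map, "cpg_map"))
  map$positions[map$all_covered, ]
}

# Per-chromosome count/beta matrices on the all-covered CpG subset.
# Returns a list keyed by chromosome with pos, M (meth counts), Tt (totals)
# and B (beta values), columns ordered CTR samples then CZ samples.
.beta_matrices <- function(cohort, map, groups = NULL) {
  keep <- all_covered_positions(map)
  groups <- groups %||% map$groups
  sub <- cohort |> semi_join(keep, by = c("chrom", "pos"))
  meth_w <- sub |>
    select("chrom", "pos", "sample_id", "n_meth") |>
    pivot_wider(names_from = "sample_id", values_from = "n_meth") |>
    arrange(.data$chrom, .data$pos)
  tot_w <- sub |>
    select("chrom", "pos", "sample_id", "n_total") |>
    pivot_wider(names_from = "sample_id", values_from = "n_total") |>
    arrange(.data$chrom, .data$pos)
  samples <- map$samples
  M <- as.matrix(meth_w[, samples, drop = FALSE])
  Tt <- as.matrix(tot_w[, samples, drop = FALSE])
  chroms <- meth_w$chrom
  out <- list()
  for (ch in unique(chroms)) {
    i <- which(chroms == ch)
    out[[ch]] <- list(pos = meth_w$pos[i],
                      M = M[i, , drop = FALSE],
                      Tt = Tt[i, , drop = FALSE],
                      B = M[i, , drop = FALSE] / Tt[i, , drop = FALSE],
                      samples = samples,
                      groups = groups)
  }
  out
}
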