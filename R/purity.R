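#' Coverage-weighted mean methylation over an interval
#'
#' Computes `sum(n_meth) / sum(n_total)` over the CpGs of one sample falling in
#' a 0-based half-open interval, counting only CpGs with `n_total >= min_cov`.
#'
#' @param meth One sample's methylome tibble.
#' @param chrom,start,end Interval (0-based half-open).
#' @param min_cov Minimum coverage for a CpG to contribute.
#' @return A value in [0, 1], or `NA_real_` when the interval contains no
#'   covered CpG (a missing value, never zero).
#' @export
locus_mean_methylation <- function(meth, chrom, start, end, min_cov = 5) {
  sub <- meth[meth$chrom == chrom & meth$pos >= start & meth$pos < end &
                meth$n_total >= min_cov, ]
  if (nrow(sub) == 0) return(NA_real_)
  sum(sub$n_meth) / sum(sub$n_total)
}

#' Estimate the somatic DNA fraction of a sample
#'
#' Least-squares fit of `observed_i ~ (1 - f) * germ_i + f * somatic_i` over
#' the purity-panel loci, constrained to [0, 1]. Loci with missing observations
#' are dropped.
#'
#' @param observed Tibble `name`, `mean` of observed per-locus methylation.
#' @param expectations Tibble `name`, `germ_level`, `somatic_level`.
#' @return Estimated somatic fraction in [0, 1].
#' @export
estimate_somatic_fraction <- function(observed, expectations = default_purity_loci()) {
  d <- inner_join(observed, expectations, by = "name") |>
    dplyr::filter(!is.na(.data$mean))
  if (nrow(d) == 0) abort("no informative loci: no observations matched expectations")
  delta <- d$somatic_level - d$germ_level
  if (all(abs(delta) < 1e-12)) {
    abort("all loci uninformative: germ and somatic levels coincide")
  }
  f <- sum((d$mean - d$germ_level) * delta) / sum(delta^2)
  min(1, max(0, f))
}

#' Classify a sample's purity from the amplicon panel
#'
#' A sample is pure when every observed locus mean lies within `tolerance` of
#' its expected germ-cell level; the somatic fraction is estimated alongside.
#'
#' @param observed Tibble `name`, `mean` (see [simulate_amplicon_panel()]).
#' @param expectations Tibble `name`, `germ_level`, `somatic_level`.
#' @param tolerance Maximum absolute deviation from the germ level per locus.
#' @return One-row tibble: `pure`, `f_hat`, `max_deviation`, `n_loci`,
#'   `tolerance`.
#' @export
classify_purity <- function(observed, expectations = default_purity_loci(),
                            tolerance = 0.10) {
  d <- inner_join(observed, expectations, by = "name")
  dev <- abs(d$mean - d$germ_level)
  tibble(
    pure = all(dev <= tolerance),
    f_hat = estimate_somatic_fraction(observed, expectations),
    max_deviation = max(dev),
    n_loci = nrow(d),
    tolerance = tolerance
  )
}

#' Imprinting-control-region contamination check
#'
#' In pure male germ-cell samples, maternally methylated ICRs (oocyte DMRs) are
#' unmethylated and paternally methylated ICRs (sperm DMRs) fully methylated.
#' Somatic admixture pulls both towards 0.5. This check reports the
#' coverage-weighted mean of each ICR against its parent-of-origin expectation
#' and an overall pass/fail; a small fraction of deviant ICRs (possible
#' methylation polymorphisms) does not fail a sample.
#'
#' @param meth One sample's methylome tibble.
#' @param icr_track Tibble `chrom`, `start`, `end`, `parent_of_origin`
#'   (`"maternal"`/`"paternal"`), optional `name`.
#' @param tolerance Maximum absolute deviation from the expected germ level.
#' @param max_fail_frac Sample fails when more than this fraction of evaluable
#'   ICRs deviates beyond `tolerance`.
#' @param min_cov Minimum CpG coverage within an ICR.
#' @return List with `per_icr` (tibble: name, parent_of_origin, mean, expected,
#'   deviation, flagged) and `pass` (logical).
#' @export
icr_check <- function(meth, icr_track, tolerance = 0.10, max_fail_frac = 0.10,
                      min_cov = 5) {
  if (is.null(icr_track) || nrow(icr_track) == 0) abort("empty ICR track")
  if (!"parent_of_origin" %in% names(icr_track)) {
    abort("ICR track must provide parent_of_origin")
  }
  per <- icr_track |>
    mutate(
      name = if ("name" %in% names(icr_track)) .data$name
             else paste0(.data$chrom, ":", .data$start, "-", .data$end),
      mean = pmap(list(.data$chrom, .data$start, .data$end),
                  function(c, s, e) locus_mean_methylation(meth, c, s, e, min_cov)) |>
        unlist(),
      expected = ifelse(.data$parent_of_origin == "maternal", 0, 1),
      deviation = abs(.data$mean - .data$expected),
      flagged = !is.na(.data$deviation) & .data$deviation > tolerance
    ) |>
    select("name", "parent_of_origin", "chrom", "start", "end",
           "mean", "expected", "deviation", "flagged")
  evaluable <- sum(!is.na(per$deviation))
  pass <- evaluable > 0 && sum(per$flagged) / evaluable <= max_fail_frac
  list(per_icr = per, pass = pass)
}

#' Purity report for a cohort
#'
#' Runs the ICR check on every sample of a cohort and, when an amplicon panel
#' per sample is provided, the four-locus classification too.
#'
#' @param cohort Long cohort tibble.
#' @param icr_track See [icr_check()].
#' @param panels Optional named list of per-sample amplicon panel tibbles.
#' @param expectations Panel expectations for [classify_purity()].
#' @param tolerance,max_fail_frac,min_cov Passed through.
#' @return Tibble, one row per sample: `sample_id`, `group`, `icr_pass`,
#'   `n_icr_flagged`, plus `pure` and `f_hat` when panels are given; the
#'   overall `pass` column gates DMR calling.
#' @export
purity_report <- function(cohort, icr_track, panels = NULL,
                          expectations = default_purity_loci(),
                          tolerance = 0.10, max_fail_frac = 0.10, min_cov = 5) {
  samples <- cohort |> distinct(.data$sample_id, .data$group)
  rows <- purrr::pmap(samples, function(sample_id, group) {
    meth <- cohort[cohort$sample_id == sample_id, ]
    chk <- icr_check(meth, icr_track, tolerance, max_fail_frac, min_cov)
    row <- tibble(sample_id = sample_id, group = group,
                  icr_pass = chk$pass, n_icr_flagged = sum(chk$per_icr$flagged))
    if (!is.null(panels) && sample_id %in% names(panels)) {
      cls <- classify_purity(panels[[sample_id]], expectations, tolerance)
      row$pure <- cls$pure
      row$f_hat <- cls$f_hat
    }
    row
  })
  out <- list_rbind(rows)
  out$pass <- out$icr_pass & (if ("pure" %in% names(out)) out$pure else TRUE)
  out
}
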