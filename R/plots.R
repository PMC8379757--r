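#' Scatter plot of within-group methylation ranges per DMR
#'
#' Mirrors the diagnostic used to justify the range filter: each DMR is a
#' point at (CTR range, CZ range); points outside the `max_range` box are the
#' candidates a genotype-driven confounder would produce.
#'
#' @param dmrs DMR tibble with `range_ctr`, `range_cz`.
#' @param max_range Filter boundary drawn on both axes.
#' @return A ggplot object.
#' @export
plot_dmr_ranges <- function(dmrs, max_range = 0.30) {
  kept <- dmrs$range_ctr <= max_range & dmrs$range_cz <= max_range
  ggplot2::ggplot(dplyr::mutate(dmrs, kept = kept),
                  ggplot2::aes(x = .data$range_ctr, y = .data$range_cz,
                               colour = .data$kept)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = max_range, linetype = 2) +
    ggplot2::geom_hline(yintercept = max_range, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#00798c", `FALSE` = "grey55"),
                                 name = paste0("range ≤ ", max_range)) +
    ggplot2::labs(x = "methylation range within CTR",
                  y = "methylation range within CZ") +
    ggplot2::theme_minimal()
}

#' @describeIn enrichment_test Null-versus-observed overlap histogram per track.
#' @param object A `dmr_enrichment` object.
#' @param ... Ignored.
#' @export
autoplot.dmr_enrichment <- function(object, ...) {
  nulls <- attr(object, "null_counts")
  long <- as_tibble(as.data.frame(nulls)) |>
    pivot_longer(dplyr::everything(), names_to = "track", values_to = "count")
  obs <- tibble(track = object$track, observed = object$observed)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$observed),
                        colour = "#d1495b") +
    ggplot2::facet_wrap(~track, scales = "free") +
    ggplot2::labs(x = "DMRs overlapping track", y = "simulated sets") +
    ggplot2::theme_minimal()
}

#' Per-sample methylation profile of a region
#'
#' @param cohort Long cohort tibble.
#' @param chrom,start,end Region to draw (0-based half-open).
#' @param min_cov Minimum coverage per CpG.
#' @return A ggplot object: per-CpG methylation by sample, coloured by group.
#' @export
plot_region <- function(cohort, chrom, start, end, min_cov = 5) {
  sub <- cohort[cohort$chrom == chrom & cohort$pos >= start &
                  cohort$pos < end & cohort$n_total >= min_cov, ]
  sub$beta <- sub$n_meth / sub$n_total
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$pos, y = .data$beta,
                                    group = .data$sample_id,
                                    colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(CTR = "#00798c", CZ = "#8d5a97")) +
    ggplot2::labs(x = paste0(chrom, " position"), y = "methylation") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
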