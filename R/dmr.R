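#' DMR caller parameters
#'
#' Shared parameters of both native DMR callers. The binding, literature-level
#' constraints are the defaults: DMRs must cover at least 4 CpGs, show at least
#' a 0.30 group methylation difference (inclusive), be built from CpGs covered
#' at 5x in every sample, and (where a q-value exists) satisfy q <= 0.05.
#' Caller internals (smoothing window, t cutoff, variance floor, gap limit,
#' split threshold) are exposed here and documented in the methods vignette.
#'
#' @param min_cpg Minimum CpGs per DMR.
#' @param min_diff Minimum absolute group methylation difference (inclusive).
#' @param min_cov Minimum per-sample coverage for a CpG to enter the analysis.
#' @param max_q Maximum q-value, applied where a caller provides one.
#' @param max_gap Maximum bp gap between consecutive DMR CpGs.
#' @param t_threshold t-statistic cutoff of the t-statistic caller.
#' @param smooth_window CpG window of the running-mean smoother (t caller).
#' @param sd_floor Floor on the pooled per-CpG standard deviation (t caller);
#'   prevents near-zero within-group variance from inflating t.
#' @param split_threshold Minimum between-sub-block difference in mean signal
#'   for a recursive split (segmentation caller).
#' @param flank_cpgs CpGs per side used as rank-sum background (segmentation
#'   caller).
#' @return List of class `caller_params`.
#' @export
caller_params <- function(min_cpg = 4, min_diff = 0.30, min_cov = 5,
                          max_q = 0.05, max_gap = 300, t_threshold = 4.6,
                          smooth_window = 5, sd_floor = 0.1,
                          split_threshold = 0.1, flank_cpgs = 50) {
  stopifnot(min_diff > 0, min_diff <= 1, min_cpg >= 2)
  structure(as.list(environment()), class = "caller_params")
}

# centered running mean with shrinking windows at the edges
.runmean <- function(x, k) {
  n <- length(x)
  if (n == 0 || k <= 1) return(x)
  h <- (k - 1) %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Recompute full DMR statistics from raw counts over given intervals.
# `mats` is the .beta_matrices() list; intervals is a tibble chrom/start/end.
.dmr_stats <- function(intervals, mats, groups) {
  if (nrow(intervals) == 0) return(.empty_dmr_tbl())
  rows <- vector("list", nrow(intervals))
  for (r in seq_len(nrow(intervals))) {
    ch <- intervals$chrom[r]
    m <- mats[[ch]]
    if (is.null(m)) { rows[[r]] <- NULL; next }
    i <- which(m$pos >= intervals$start[r] & m$pos < intervals$end[r])
    if (length(i) == 0) { rows[[r]] <- NULL; next }
    ms <- colSums(m$M[i, , drop = FALSE])
    ts <- colSums(m$Tt[i, , drop = FALSE])
    psm <- ms / ts
    is_ctr <- m$groups[m$samples] == "CTR"
    mean_ctr <- mean(psm[is_ctr]); mean_cz <- mean(psm[!is_ctr])
    diff <- mean_cz - mean_ctr
    rows[[r]] <- tibble(
      chrom = ch, start = intervals$start[r], end = intervals$end[r],
      n_cpg = length(i),
      per_sample_mean = list(psm),
      mean_ctr = mean_ctr, mean_cz = mean_cz, diff = diff,
      direction = if (diff >= 0) "hyper_in_cz" else "hypo_in_cz",
      range_ctr = max(psm[is_ctr]) - min(psm[is_ctr]),
      range_cz = max(psm[!is_ctr]) - min(psm[!is_ctr]),
      q_value = NA_real_, callers = NA_character_
    )
  }
  done <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
  if (is.null(done) || nrow(done) == 0) .empty_dmr_tbl() else
    arrange(done, .data$chrom, .data$start)
}

.empty_dmr_tbl <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         n_cpg = integer(), per_sample_mean = list(),
         mean_ctr = double(), mean_cz = double(), diff = double(),
         direction = character(), range_ctr = double(), range_cz = double(),
         q_value = double(), callers = character())
}

.check_two_groups <- function(map) {
  g <- map$groups
  if (sum(g == "CTR") < 2 || sum(g == "CZ") < 2) {
    abort("need at least 2 samples per group (CTR and CZ)")
  }
}

#' t-statistic DMR caller
#'
#' Native caller in the bsmooth/camel family. Per-sample methylation levels
#' (restricted to CpGs covered at `min_cov` in every sample) are smoothed with
#' a running mean over `smooth_window` CpGs; a pooled two-sample t-statistic is
#' computed per CpG with the pooled standard deviation floored at `sd_floor`.
#' Maximal runs of at least `min_cpg` consecutive qualifying CpGs
#' (`|t| >= t_threshold`, consistent sign, inter-CpG gap <= `max_gap`) whose
#' raw group difference reaches `min_diff` become DMRs. This caller family
#' provides no q-values, so `q_value` is `NA`.
#'
#' @param cohort Long cohort tibble with `group` in `{CTR, CZ}`.
#' @param map [build_cpg_map()] object at `min_cov`.
#' @param params [caller_params()].
#' @return DMR tibble (see [merge_dmr_sets()] for the column contract).
#' @export
call_dmrs_tstat <- function(cohort, map, params = caller_params()) {
  .check_two_groups(map)
  mats <- .beta_matrices(cohort, map)
  is_ctr <- map$groups[map$samples] == "CTR"
  n1 <- sum(is_ctr); n2 <- sum(!is_ctr)
  cand <- list()
  for (ch in names(mats)) {
    m <- mats[[ch]]
    if (length(m$pos) < params$min_cpg) next
    S <- apply(m$B, 2, .runmean, k = params$smooth_window)
    if (is.null(dim(S))) S <- matrix(S, nrow = 1)
    m1 <- rowMeans(S[, is_ctr, drop = FALSE])
    m2 <- rowMeans(S[, !is_ctr, drop = FALSE])
    v1 <- apply(S[, is_ctr, drop = FALSE], 1, var)
    v2 <- apply(S[, !is_ctr, drop = FALSE], 1, var)
    sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
    sp <- pmax(sp, params$sd_floor)
    t <- (m2 - m1) / (sp * sqrt(1 / n1 + 1 / n2))
    qual <- abs(t) >= params$t_threshold
    sgn <- sign(t)
    # break runs at sign changes and large gaps
    brk <- c(TRUE, sgn[-1] != sgn[-length(sgn)] |
               diff(m$pos) > params$max_gap)
    run_id <- cumsum(brk)
    grp <- ifelse(qual, run_id, NA_integer_)
    for (id in unique(grp[!is.na(grp)])) {
      i <- which(grp == id)
      # qualifying CpGs within a run are consecutive unless interrupted
      splits <- cumsum(c(1L, diff(i) != 1L))
      for (s in unique(splits)) {
        j <- i[splits == s]
        if (length(j) >= params$min_cpg) {
          cand[[length(cand) + 1L]] <- tibble(
            chrom = ch, start = m$pos[j[1]], end = m$pos[j[length(j)]] + 1L)
        }
      }
    }
  }
  cand <- if (length(cand)) list_rbind(cand) else
    tibble(chrom = character(), start = integer(), end = integer())
  out <- .dmr_stats(cand, mats, map$groups)
  out <- out[abs(out$diff) >= params$min_diff & out$n_cpg >= params$min_cpg, ]
  out$callers <- if (nrow(out)) "tstat" else character()
  out
}

#' Binary-segmentation DMR caller
#'
#' Native caller in the metilene family. The per-CpG group mean-difference
#' signal (CZ minus CTR) is cut into blocks at inter-CpG gaps above `max_gap`,
#' then recursively split at the point maximizing the difference between the
#' two sub-block means, stopping when a block has fewer than `2 * min_cpg`
#' CpGs or no split improves by `split_threshold`. Leaf blocks whose mean
#' signal reaches `min_diff` are candidate DMRs, scored by a rank-sum test of
#' their per-CpG differences against up to `flank_cpgs` flanking CpGs per side;
#' p-values are Benjamini-Hochberg corrected genome-wide and regions pass with
#' `q <= max_q` (kept with `q = NA` when no flanking background exists),
#' `|diff| >= min_diff` and `n_cpg >= min_cpg`.
#'
#' @inheritParams call_dmrs_tstat
#' @return DMR tibble.
#' @export
call_dmrs_segmentation <- function(cohort, map, params = caller_params()) {
  .check_two_groups(map)
  mats <- .beta_matrices(cohort, map)
  is_ctr <- map$groups[map$samples] == "CTR"
  cand <- list()
  for (ch in names(mats)) {
    m <- mats[[ch]]
    if (length(m$pos) < params$min_cpg) next
    d <- rowMeans(m$B[, !is_ctr, drop = FALSE]) -
         rowMeans(m$B[, is_ctr, drop = FALSE])
    blk <- cumsum(c(1L, as.integer(diff(m$pos) > params$max_gap)))
    for (b in unique(blk)) {
      i <- which(blk == b)
      if (length(i) < params$min_cpg) next
      leaves <- .binseg(d[i], params$min_cpg, params$split_threshold)
      for (lf in leaves) {
        j <- i[lf[1]:lf[2]]
        if (length(j) >= params$min_cpg && abs(mean(d[j])) >= params$min_diff) {
          # flanking background on the same chromosome, outside the candidate
          left <- setdiff(seq(max(1, j[1] - params$flank_cpgs), j[1] - 1), j)
          right <- setdiff(seq(j[length(j)] + 1,
                               min(length(d), j[length(j)] + params$flank_cpgs)), j)
          fl <- c(left[left >= 1], right[right <= length(d)])
          p <- if (length(fl) >= 5) {
            suppressWarnings(wilcox.test(d[j], d[fl], exact = FALSE)$p.value)
          } else NA_real_
          cand[[length(cand) + 1L]] <- tibble(
            chrom = ch, start = m$pos[j[1]], end = m$pos[j[length(j)]] + 1L,
            p_value = p)
        }
      }
    }
  }
  if (!length(cand)) return(.empty_dmr_tbl())
  cand <- list_rbind(cand)
  cand$q_value <- NA_real_
  has_p <- !is.na(cand$p_value)
  cand$q_value[has_p] <- p.adjust(cand$p_value[has_p], method = "BH")
  out <- .dmr_stats(cand[c("chrom", "start", "end")], mats, map$groups)
  out$q_value <- cand$q_value[match(paste(out$chrom, out$start),
                                    paste(cand$chrom, cand$start))]
  out <- out[abs(out$diff) >= params$min_diff & out$n_cpg >= params$min_cpg &
               (is.na(out$q_value) | out$q_value <= params$max_q), ]
  out$callers <- if (nrow(out)) "segmentation" else character()
  out
}

# Recursive binary segmentation of a numeric signal; returns list of
# c(start, end) index pairs (leaves), 1-based within the block.
.binseg <- function(d, min_cpg, split_threshold) {
  n <- length(d)
  leaves <- list()
  stack <- list(c(1L, n))
  cs <- cumsum(d)
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- node[1]; hi <- node[2]
    len <- hi - lo + 1L
    if (len < 2L * min_cpg) { leaves[[length(leaves) + 1L]] <- node; next }
    s_seq <- (lo + min_cpg - 1L):(hi - min_cpg)
    sum_lo <- if (lo > 1L) cs[lo - 1L] else 0
    left_mean <- (cs[s_seq] - sum_lo) / (s_seq - lo + 1L)
    right_mean <- (cs[hi] - cs[s_seq]) / (hi - s_seq)
    gain <- abs(left_mean - right_mean)
    k <- which.max(gain)
    if (gain[k] < split_threshold) {
      leaves[[length(leaves) + 1L]] <- node
    } else {
      s <- s_seq[k]
      stack[[length(stack) + 1L]] <- c(lo, s)
      stack[[length(stack) + 1L]] <- c(s + 1L, hi)
    }
  }
  leaves
}

#' Merge DMR sets from multiple callers
#'
#' Unions any-bp-overlapping intervals across caller outputs and recomputes
#' every statistic of the merged DMR from raw counts on the union interval
#' (the range filter must see per-sample means of the final interval, so
#' merged statistics are never averaged from the inputs). Caller provenance is
#' the union of contributing callers; the q-value is the minimum contributing
#' q-value where any exists.
#'
#' @param sets List of DMR tibbles (from the callers).
#' @param cohort,map As in the callers.
#' @return Merged DMR tibble.
#' @export
merge_dmr_sets <- function(sets, cohort, map) {
  sets <- sets[vapply(sets, nrow, integer(1)) > 0]
  if (!length(sets)) return(.empty_dmr_tbl())
  all_in <- list_rbind(lapply(sets, \(s) s[c("chrom", "start", "end", "q_value", "callers")]))
  merged <- merge_intervals(all_in)
  mats <- .beta_matrices(cohort, map)
  out <- .dmr_stats(merged, mats, map$groups)
  # provenance + q from contributing intervals
  hits <- GenomicRanges::findOverlaps(.as_gr(all_in), .as_gr(out))
  from <- S4Vectors::queryHits(hits); to <- S4Vectors::subjectHits(hits)
  out$callers <- vapply(seq_len(nrow(out)), function(i) {
    paste(sort(unique(all_in$callers[from[to == i]])), collapse = ";")
  }, character(1))
  out$q_value <- vapply(seq_len(nrow(out)), function(i) {
    q <- all_in$q_value[from[to == i]]
    if (all(is.na(q))) NA_real_ else min(q, na.rm = TRUE)
  }, double(1))
  out
}

#' Apply the headline DMR threshold filters
#'
#' Keeps DMRs with `n_cpg >= min_cpg`, `|diff| >= min_diff` (both inclusive)
#' and, where a q-value is available, `q <= max_q`.
#'
#' @param dmrs DMR tibble.
#' @param params [caller_params()].
#' @return Filtered DMR tibble.
#' @export
apply_threshold_filters <- function(dmrs, params = caller_params()) {
  dmrs[dmrs$n_cpg >= params$min_cpg & abs(dmrs$diff) >= params$min_diff &
         (is.na(dmrs$q_value) | dmrs$q_value <= params$max_q), ]
}

#' Within-group methylation-range filter
#'
#' Removes DMRs whose per-sample means spread more than `max_range` within
#' either group (boundary inclusive: range equal to `max_range` is kept). Such
#' spread is the signature of genotype-driven (meQTL-like) methylation rather
#' than a group effect: a local variant can put individual samples at low,
#' intermediate or high methylation irrespective of diagnosis.
#'
#' @param dmrs DMR tibble with populated `per_sample_mean`, `range_ctr`,
#'   `range_cz`.
#' @param max_range Maximum within-group range of per-sample means.
#' @return Filtered DMR tibble.
#' @export
apply_range_filter <- function(dmrs, max_range = 0.30) {
  if (nrow(dmrs) == 0) return(dmrs)
  bad <- vapply(dmrs$per_sample_mean, function(p) any(is.na(p)), logical(1))
  if (any(bad) || any(is.na(dmrs$range_ctr)) || any(is.na(dmrs$range_cz))) {
    abort("missing per-sample means; recompute DMR statistics before filtering")
  }
  tol <- 1e-9  # keep the inclusive boundary robust to float rounding
  dmrs[dmrs$range_ctr <= max_range + tol & dmrs$range_cz <= max_range + tol, ]
}

#' Exact two-sided binomial p-value by minimum-tail doubling
#'
#' `p = min(1, 2 * min(P(X <= k), P(X >= k)))` with `X ~ Binomial(n, 1/2)`.
#' Vectorized over `k`.
#'
#' @param k Number of successes (e.g. hypermethylated DMRs).
#' @param n Number of trials (total DMRs).
#' @return Numeric vector of p-values.
#' @export
binomial_direction_p <- function(k, n) {
  stopifnot(all(n >= 1), all(k >= 0), all(k <= n))
  pmin(1, 2 * pmin(pbinom(k, n, 0.5), pbinom(n - k, n, 0.5)))
}

#' Exact binomial test of direction skew
#'
#' Two-sided exact binomial test of hyper- vs hypomethylated DMR counts against
#' equal probability, computed by minimum-tail doubling (see
#' [binomial_direction_p()]).
#'
#' @param dmrs DMR tibble with a `direction` column, or `NULL` when `n_hyper`
#'   and `n_total` are given directly.
#' @param n_hyper,n_total Direct counts (used when `dmrs` is `NULL`).
#' @return One-row tibble: `n_hyper`, `n_total`, `p_value`.
#' @export
direction_binomial_test <- function(dmrs = NULL, n_hyper = NULL, n_total = NULL) {
  if (!is.null(dmrs)) {
    n_hyper <- sum(dmrs$direction == "hyper_in_cz")
    n_total <- nrow(dmrs)
  }
  tibble(n_hyper = as.integer(n_hyper), n_total = as.integer(n_total),
         p_value = binomial_direction_p(n_hyper, n_total))
}

#' Add a stable DMR identifier
#'
#' @param dmrs DMR tibble.
#' @return Same tibble with a `dmr_id` ("chrom:start-end") first column.
#' @export
add_dmr_id <- function(dmrs) {
  dmrs$dmr_id <- paste0(dmrs$chrom, ":", dmrs$start, "-", dmrs$end)
  relocate(dmrs, "dmr_id")
}

#' Flatten a DMR tibble for TSV output
#'
#' Expands the `per_sample_mean` list-column into one `mean_<sample>` column
#' per sample so the table round-trips through plain TSV.
#'
#' @param dmrs DMR tibble.
#' @return Flat tibble.
#' @export
flatten_dmrs <- function(dmrs) {
  if (nrow(dmrs) == 0) return(select(dmrs, -"per_sample_mean"))
  wide <- purrr::map(dmrs$per_sample_mean, \(p) as_tibble(as.list(p))) |> list_rbind()
  names(wide) <- paste0("mean_", names(wide))
  bind_cols(select(dmrs, -"per_sample_mean"), wide)
}
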