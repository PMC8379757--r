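#' Fit a log-normal model of DMR lengths
#'
#' Maximum-likelihood log-normal fit to the nucleotide lengths of a DMR set:
#' `meanlog`/`sdlog` are the mean and standard deviation of the log lengths.
#' Degenerate sets (all lengths equal) get `sdlog` floored at 1e-6 with a
#' warning.
#'
#' @param dmrs DMR tibble (uses `end - start`), or a numeric vector of lengths.
#' @return Object of class `dmr_length_model` with elements `meanlog`, `sdlog`,
#'   `n`. Has [tidy()] and [glance()] methods.
#' @export
fit_length_model <- function(dmrs) {
  len <- if (is.numeric(dmrs)) dmrs else dmrs$end - dmrs$start
  if (length(len) < 2) abort("need at least 2 DMRs to fit a length model")
  if (any(len <= 0)) abort("all lengths must be positive")
  mu <- mean(log(len))
  sigma <- sd(log(len))
  if (!is.finite(sigma) || sigma < 1e-6) {
    warn("degenerate length distribution; sdlog floored at 1e-6")
    sigma <- 1e-6
  }
  structure(list(meanlog = mu, sdlog = sigma, n = length(len)),
            class = "dmr_length_model")
}

#' @export
print.dmr_length_model <- function(x, ...) {
  cat("<dmr_length_model> meanlog=", signif(x$meanlog, 4),
      " sdlog=", signif(x$sdlog, 4), " (n=", x$n, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.dmr_length_model <- function(x, ...) {
  tibble(term = c("meanlog", "sdlog"), estimate = c(x$meanlog, x$sdlog))
}

#' @export
glance.dmr_length_model <- function(x, ...) {
  tibble(meanlog = x$meanlog, sdlog = x$sdlog, n = x$n,
         median_length = exp(x$meanlog))
}

# Concatenated index over the all-covered CpG map: for a template of n CpGs,
# valid starts are positions whose (start + n - 1)-th neighbour lies on the
# same chromosome. Candidate intervals run first CpG to last CpG (+1, half
# open); candidate length is the covered-nucleotide span.
.matched_index <- function(map) {
  keep <- all_covered_positions(map)
  if (nrow(keep) == 0) abort("CpG map has no positions covered in all samples")
  list(chrom = keep$chrom, pos = keep$pos,
       chrom_rle = rle(keep$chrom))
}

.valid_starts <- function(idx, n) {
  ends <- cumsum(idx$chrom_rle$lengths)
  starts <- ends - idx$chrom_rle$lengths + 1L
  ok <- idx$chrom_rle$lengths >= n
  if (!any(ok)) {
    abort(paste0("no chromosome holds ", n, " consecutive covered CpGs"))
  }
  unlist(lapply(which(ok), function(k) seq(starts[k], ends[k] - n + 1L)),
         use.names = FALSE)
}

#' Simulate one CpG-count- and length-matched DMR set
#'
#' For each actual DMR with `n` covered CpGs, draws `pool_size` uniform random
#' placements on the cohort CpG map (a placement is `n` consecutive covered
#' CpGs on one chromosome, interval spanning first to last CpG), then selects
#' one candidate with probability proportional to the fitted log-normal density
#' at its nucleotide length. The simulated set therefore preserves the multiset
#' of per-DMR CpG counts exactly while matching the actual length distribution.
#'
#' @param dmrs DMR tibble with `n_cpg`.
#' @param map [build_cpg_map()] object.
#' @param model [fit_length_model()] result (default: fitted from `dmrs`).
#' @param pool_size Candidates drawn per DMR.
#' @return Tibble `chrom`, `start`, `end`, `n_cpg`, one row per input DMR.
#' @export
simulate_matched_set <- function(dmrs, map, model = NULL, pool_size = 1000) {
  model <- model %||% fit_length_model(dmrs)
  idx <- .matched_index(map)
  rows <- vector("list", nrow(dmrs))
  for (r in seq_len(nrow(dmrs))) {
    n <- dmrs$n_cpg[r]
    vs <- .valid_starts(idx, n)
    pick <- vs[sample.int(length(vs), pool_size, replace = TRUE)]
    len <- idx$pos[pick + n - 1L] - idx$pos[pick] + 1L
    w <- dlnorm(len, model$meanlog, model$sdlog)
    if (!any(w > 0)) w <- rep(1, length(w))
    s <- pick[sample.int(pool_size, 1L, prob = w)]
    rows[[r]] <- tibble(chrom = idx$chrom[s], start = idx$pos[s],
                        end = idx$pos[s + n - 1L] + 1L, n_cpg = n)
  }
  list_rbind(rows)
}

# Prepared matched sampler: precomputes, per distinct CpG count among the
# templates, the valid placements, their log-normal log-weights and their
# per-track overlap indicators. The returned closure draws `n_sets` matched
# sets and returns the per-set, per-track overlap-count matrix. Selection
# among each uniform candidate pool uses the Gumbel-max trick, an exact
# weighted pick among the pool.
.prepare_matched_sampler <- function(dmrs, map, model, tracks_list, pool_size,
                                     chunk_cols = 20000L) {
  idx <- .matched_index(map)
  prep <- list()
  for (n in sort(unique(dmrs$n_cpg))) {
    vs <- .valid_starts(idx, n)
    len <- idx$pos[vs + n - 1L] - idx$pos[vs] + 1L
    logw <- dlnorm(len, model$meanlog, model$sdlog, log = TRUE)
    if (all(!is.finite(logw))) logw <- rep(0, length(logw))
    cand <- tibble(chrom = idx$chrom[vs], start = idx$pos[vs],
                   end = idx$pos[vs + n - 1L] + 1L)
    ov <- vapply(tracks_list, function(tr) .overlaps_any(cand, tr),
                 logical(length(vs)))
    if (is.null(dim(ov))) ov <- matrix(ov, nrow = length(vs))
    prep[[as.character(n)]] <- list(
      n_templates = sum(dmrs$n_cpg == n), n_cand = length(vs),
      logw = logw, ov = ov)
  }
  function(n_sets) {
    n_sets <- as.integer(n_sets)
    counts <- matrix(0L, nrow = n_sets, ncol = length(tracks_list),
                     dimnames = list(NULL, names(tracks_list)))
    for (p in prep) {
      total_draws <- p$n_templates * n_sets
      done <- 0L
      while (done < total_draws) {
        nd <- as.integer(min(chunk_cols, total_draws - done))
        pick <- sample.int(p$n_cand, pool_size * nd, replace = TRUE)
        # exact weighted pick among each pool via the Gumbel-max race,
        # laid out draw-major so no transpose is needed
        keys <- matrix(p$logw[pick] - log(stats::rexp(pool_size * nd)),
                       nrow = nd)
        slot <- max.col(keys, ties.method = "first")
        sel <- pick[(slot - 1L) * nd + seq_len(nd)]
        draw_set <- ((done + seq_len(nd)) - 1L) %% n_sets + 1L
        agg <- rowsum(p$ov[sel, , drop = FALSE] + 0L, group = draw_set)
        rows_at <- as.integer(rownames(agg))
        counts[rows_at, ] <- counts[rows_at, , drop = FALSE] + agg
        done <- done + nd
      }
    }
    counts
  }
}

.matched_overlap_counts <- function(dmrs, map, model, tracks_list, n_sets,
                                    pool_size, chunk_cols = 20000L) {
  sampler <- .prepare_matched_sampler(dmrs, map, model, tracks_list, pool_size,
                                      chunk_cols)
  sampler(n_sets)
}

#' Monte Carlo enrichment of DMRs in genomic feature tracks
#'
#' Tests whether the actual DMR set overlaps each feature track more (or less)
#' often than CpG-count- and length-matched random DMR sets. For each track the
#' observed statistic is the number of DMRs overlapping at least one track
#' interval; the null distribution is the same count over `n_sets` simulated
#' sets from [simulate_matched_set()]'s sampling scheme. Empirical p-values use
#' the add-one estimator `(1 + #{null >= obs}) / (1 + n_sets)` (enrichment
#' tail; mirrored for depletion), so they are never zero; the reported
#' direction is the smaller tail and `p_two_sided = min(1, 2 * min(tails))`.
#' The odds ratio is `[obs / (N - obs)] / [mean_null / (N - mean_null)]` with
#' Haldane 0.5 continuity correction when any cell is zero.
#'
#' @param dmrs DMR tibble with `n_cpg`.
#' @param tracks Named list of interval tibbles (`chrom`, `start`, `end`), or a
#'   single tibble with a `feature_class` column (split automatically).
#' @param map [build_cpg_map()] object.
#' @param n_sets Number of simulated sets (>= 100).
#' @param pool_size Candidates per DMR per set.
#' @param model Optional pre-fitted [fit_length_model()].
#' @return Object of class `dmr_enrichment`: a tibble with one row per track
#'   (`track`, `observed`, `n_dmrs`, `null_mean`, `p_enrich`, `p_deplete`,
#'   `p_empirical`, `p_two_sided`, `direction`, `odds_ratio`) carrying the
#'   null count matrix in `attr(, "null_counts")`. Has [tidy()], [glance()]
#'   and [autoplot()] methods.
#' @export
enrichment_test <- function(dmrs, tracks, map, n_sets = 1e6, pool_size = 1000,
                            model = NULL) {
  if (n_sets < 100) abort("n_sets must be at least 100")
  if (nrow(dmrs) == 0) abort("no DMRs to test")
  tracks_list <- if (is.data.frame(tracks)) {
    split(tracks[c("chrom", "start", "end")], tracks$feature_class)
  } else tracks
  model <- model %||% fit_length_model(dmrs)
  N <- nrow(dmrs)
  observed <- vapply(tracks_list, function(tr) sum(.overlaps_any(dmrs, tr)),
                     integer(1))
  null_counts <- .matched_overlap_counts(dmrs, map, model, tracks_list,
                                         as.integer(n_sets), pool_size)
  rows <- imap(tracks_list, function(tr, nm) {
    obs <- observed[[nm]]
    nc <- null_counts[, nm]
    p_enr <- (1 + sum(nc >= obs)) / (1 + n_sets)
    p_dep <- (1 + sum(nc <= obs)) / (1 + n_sets)
    mu <- mean(nc)
    cell <- c(obs, N - obs, mu, N - mu)
    if (min(cell) == 0) cell <- cell + 0.5
    tibble(track = nm, observed = obs, n_dmrs = N, null_mean = mu,
           p_enrich = p_enr, p_deplete = p_dep,
           p_empirical = min(p_enr, p_dep),
           p_two_sided = min(1, 2 * min(p_enr, p_dep)),
           direction = if (p_enr <= p_dep) "enriched" else "depleted",
           odds_ratio = (cell[1] / cell[2]) / (cell[3] / cell[4]))
  }) |> list_rbind()
  structure(rows, class = c("dmr_enrichment", class(rows)),
            null_counts = null_counts, n_sets = n_sets, pool_size = pool_size)
}

#' @export
tidy.dmr_enrichment <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @export
glance.dmr_enrichment <- function(x, ...) {
  tibble(n_tracks = nrow(x), n_dmrs = x$n_dmrs[1],
         n_sets = attr(x, "n_sets"), pool_size = attr(x, "pool_size"))
}

#' Null calibration of the enrichment p-value
#'
#' Runs `n_reps` independent simulated enrichment experiments in which the
#' query DMR set is itself drawn from the matched randomizer: each repetition
#' draws a fresh null of `n_sets` matched sets plus one query set and records
#' the enrichment-tail empirical p-value of the query. Since query and null are
#' exchangeable, these p-values are uniform on the add-one lattice
#' `{k / (n_sets + 1)}` up to the slight conservativeness of tied counts.
#'
#' @param dmrs Template DMR tibble.
#' @param track One interval tibble.
#' @param map,model,pool_size As in [enrichment_test()].
#' @param n_sets Null sets per repetition.
#' @param n_reps Number of simulated experiments.
#' @return Numeric vector of `n_reps` empirical p-values.
#' @export
enrichment_null_calibration <- function(dmrs, track, map, n_sets = 1000,
                                        n_reps = 200, pool_size = 1000,
                                        model = NULL) {
  model <- model %||% fit_length_model(dmrs)
  sampler <- .prepare_matched_sampler(dmrs, map, model, list(track = track),
                                      pool_size)
  vapply(seq_len(n_reps), function(r) {
    counts <- sampler(n_sets + 1L)[, 1]
    null <- counts[seq_len(n_sets)]
    (1 + sum(null >= counts[n_sets + 1L])) / (1 + n_sets)
  }, double(1))
}
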