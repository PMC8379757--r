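#' Simulation configuration
#'
#' Builds the configuration for [simulate_cohort()]. Defaults emulate the study
#' design the package targets: two groups of four purified germ-cell samples
#' sequenced at ~14x coverage, a high-methylation background (~0.8) punctuated
#' by unmethylated CpG islands and low-methylated distal elements, planted
#' group-level DMRs, genotype-driven (meQTL-like) trimodal regions, imprinting
#' control regions with parent-of-origin methylation, and optional somatic-DNA
#' admixture.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param n_chrom Number of simulated chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param cpg_spacing_mean Mean inter-CpG gap in bp (geometric gaps, minimum 2).
#' @param n_per_group Samples per group (CTR and CZ).
#' @param coverage_mean,coverage_dispersion Negative-binomial coverage mean and
#'   size parameter per CpG per sample.
#' @param baseline_meth Background methylation level.
#' @param bio_dispersion Beta-binomial dispersion (beta variance scale) for
#'   biological replicate noise.
#' @param n_islands,island_n_cpg,island_level Unmethylated CpG-island-like
#'   regions (UMR precursors).
#' @param n_lmr_like,lmr_n_cpg,lmr_level Low-methylated distal elements (LMR
#'   precursors).
#' @param n_true_dmrs Number of planted group-level DMRs.
#' @param dmr_effect Methylation difference planted in the CZ group.
#' @param dmr_n_cpg_range Range (min, max) of CpGs per planted DMR.
#' @param n_meqtl_regions Number of genotype-driven trimodal regions.
#' @param meqtl_levels Methylation level per genotype (0, 1, 2 alt alleles).
#' @param meqtl_allele_freq Alt-allele frequency for Hardy-Weinberg genotype
#'   draws.
#' @param meqtl_n_cpg_range Range of CpGs per meQTL region.
#' @param n_icr Number of imprinting control regions (alternating maternal /
#'   paternal).
#' @param icr_n_cpg CpGs per ICR.
#' @param icr_germ_levels Germ-cell methylation for maternal and paternal ICRs.
#' @param icr_somatic_level Somatic methylation at ICRs (hemimethylated, 0.5).
#' @param somatic_baseline Somatic methylation outside ICRs/islands, used when
#'   contamination is simulated.
#' @param contamination Numeric vector of per-sample somatic fractions in
#'   [0, 1), recycled across the 2 * n_per_group samples.
#' @param n_genes_per_chrom,n_enhancers_per_chrom Annotation-track richness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_len = 5e6,
                       cpg_spacing_mean = 100,
                       n_per_group = 4L,
                       coverage_mean = 14,
                       coverage_dispersion = 15,
                       baseline_meth = 0.8,
                       bio_dispersion = 0.02,
                       n_islands = 24L,
                       island_n_cpg = 40L,
                       island_level = 0.03,
                       n_lmr_like = 24L,
                       lmr_n_cpg = 10L,
                       lmr_level = 0.15,
                       n_true_dmrs = 20L,
                       dmr_effect = 0.4,
                       dmr_n_cpg_range = c(8L, 16L),
                       n_meqtl_regions = 10L,
                       meqtl_levels = c(0.05, 0.5, 0.95),
                       meqtl_allele_freq = 0.5,
                       meqtl_n_cpg_range = c(8L, 16L),
                       n_icr = 10L,
                       icr_n_cpg = 20L,
                       icr_germ_levels = c(maternal = 0.02, paternal = 0.98),
                       icr_somatic_level = 0.5,
                       somatic_baseline = 0.75,
                       contamination = 0,
                       n_genes_per_chrom = 40L,
                       n_enhancers_per_chrom = 12L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_per_group >= 1, cfg$chrom_len > 0, cfg$n_chrom >= 1)
  probs <- c(cfg$baseline_meth, cfg$island_level, cfg$lmr_level, cfg$dmr_effect,
             cfg$meqtl_levels, cfg$icr_germ_levels, cfg$icr_somatic_level,
             cfg$somatic_baseline)
  if (any(probs < 0 | probs > 1)) abort("all methylation levels must be in [0, 1]")
  if (any(cfg$contamination < 0 | cfg$contamination >= 1)) {
    abort("contamination fractions must be in [0, 1)")
  }
  structure(cfg, class = "sim_config")
}

# Allocate k non-overlapping windows (widths in CpG counts) among n_cpg
# indexed positions, keeping a buffer of `buffer` CpGs between windows.
# Returns integer start indices aligned with `widths`.
.allocate_windows <- function(n_cpg, widths, buffer = 30L) {
  k <- length(widths)
  if (k == 0) return(integer())
  need <- sum(widths) + (k + 1L) * buffer
  if (need > n_cpg) {
    abort(paste0("region demand (", need, " CpGs) exceeds chromosome capacity (",
                 n_cpg, " CpGs)"))
  }
  slack <- n_cpg - need
  # random composition of the slack into k+1 gaps
  cuts <- sort(sample.int(slack + k, k, replace = FALSE))
  gaps <- diff(c(0L, cuts, slack + k + 1L)) - 1L
  ord <- sample.int(k)  # shuffle which region gets which slot
  starts <- integer(k)
  cursor <- 0L
  for (j in seq_len(k)) {
    cursor <- cursor + gaps[j] + buffer
    starts[ord[j]] <- cursor + 1L
    cursor <- cursor + widths[ord[j]]
  }
  starts
}

# Beta-binomial draw: coverage vector n, target level p (vector), dispersion d.
.rbetabinom <- function(n, p, d) {
  pi <- p
  v <- pmin(d, 0.66 * p * (1 - p))
  ok <- v > 1e-8 & p > 0 & p < 1
  if (any(ok)) {
    s <- p[ok] * (1 - p[ok]) / v[ok] - 1
    pi[ok] <- rbeta(sum(ok), p[ok] * s, (1 - p[ok]) * s)
  }
  rbinom(length(n), n, pi)
}

#' Simulate a two-group WGBS cohort with known ground truth
#'
#' Generates per-CpG methylation counts for `2 * n_per_group` samples on a toy
#' genome. Coverage is negative-binomial; methylated counts are beta-binomial
#' around a regional target level: background, island/LMR dips, group-shifted
#' planted DMRs, genotype-level meQTL regions, and parent-of-origin ICR levels.
#' Per-sample somatic contamination shifts every target level towards a somatic
#' profile. Deterministic under a fixed config seed.
#'
#' @param config A [sim_config()] object.
#' @return A list with `cohort` (long tibble: sample_id, group, chrom, pos,
#'   n_meth, n_total; zero-coverage CpGs are omitted per sample) and `truth`, a
#'   list with `cpg` (all simulated CpG positions), `true_dmrs`, `meqtl`
#'   (including the per-sample genotype level matrix), `icr`, `tracks` (gene /
#'   exon / intron / promoter / CGI / enhancer annotation), `samples`, and the
#'   echoed `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  spacing_p <- 1 / max(cfg$cpg_spacing_mean - 2, 1)

  # --- CpG positions per chromosome ------------------------------------------
  pos_by_chrom <- lapply(chroms, function(ch) {
    n_guess <- ceiling(cfg$chrom_len / cfg$cpg_spacing_mean * 1.2) + 100L
    gaps <- 2L + rgeom(n_guess, spacing_p)
    pos <- cumsum(gaps) + 500L
    pos[pos < cfg$chrom_len - 500L]
  })
  names(pos_by_chrom) <- chroms
  n_cpg <- vapply(pos_by_chrom, length, integer(1))

  # --- distribute special regions across chromosomes -------------------------
  rint <- function(n, rng) {
    if (n == 0) return(integer())
    v <- seq(rng[1], rng[2])
    v[sample.int(length(v), n, replace = TRUE)]
  }
  specs <- tibble(
    type = c(rep("island", cfg$n_islands), rep("lmr_like", cfg$n_lmr_like),
             rep("dmr", cfg$n_true_dmrs), rep("meqtl", cfg$n_meqtl_regions),
             rep("icr", cfg$n_icr)),
    width = c(rep(cfg$island_n_cpg, cfg$n_islands),
              rep(cfg$lmr_n_cpg, cfg$n_lmr_like),
              rint(cfg$n_true_dmrs, cfg$dmr_n_cpg_range),
              rint(cfg$n_meqtl_regions, cfg$meqtl_n_cpg_range),
              rep(cfg$icr_n_cpg, cfg$n_icr))
  )
  if (nrow(specs)) {
    specs$chrom <- sample(chroms, nrow(specs), replace = TRUE)
    specs$id <- paste0(specs$type, "_", stats::ave(seq_len(nrow(specs)),
                                                   specs$type, FUN = seq_along))
  } else {
    specs$chrom <- character(); specs$id <- character()
  }
  specs$start_idx <- NA_integer_
  for (ch in chroms) {
    i <- which(specs$chrom == ch)
    specs$start_idx[i] <- .allocate_windows(n_cpg[[ch]], specs$width[i])
  }
  specs$end_idx <- specs$start_idx + specs$width - 1L
  # bp intervals (half-open: last CpG + 1)
  specs$start <- as.integer(mapply(function(ch, i) pos_by_chrom[[ch]][i],
                                   specs$chrom, specs$start_idx))
  specs$end <- as.integer(mapply(function(ch, i) pos_by_chrom[[ch]][i] + 1L,
                                 specs$chrom, specs$end_idx))

  # --- region attributes ------------------------------------------------------
  samples <- c(paste0("CTR", seq_len(cfg$n_per_group)),
               paste0("CZ", seq_len(cfg$n_per_group)))
  groups <- setNames(rep(c("CTR", "CZ"), each = cfg$n_per_group), samples)
  n_s <- length(samples)
  frac <- rep_len(cfg$contamination, n_s)
  names(frac) <- samples

  dmrs <- specs[specs$type == "dmr", ]
  if (nrow(dmrs)) {
    dmrs$direction <- sample(c("hyper_in_cz", "hypo_in_cz"), nrow(dmrs), replace = TRUE)
    dmrs$ctr_level <- ifelse(dmrs$direction == "hyper_in_cz", 0.35, 0.85)
    dmrs$cz_level <- pmin(1, pmax(0, dmrs$ctr_level +
      ifelse(dmrs$direction == "hyper_in_cz", cfg$dmr_effect, -cfg$dmr_effect)))
  }
  meqtl <- specs[specs$type == "meqtl", ]
  geno <- NULL
  if (nrow(meqtl)) {
    geno <- matrix(rbinom(nrow(meqtl) * n_s, 2, cfg$meqtl_allele_freq),
                   nrow = nrow(meqtl), dimnames = list(meqtl$id, samples))
  }
  icr <- specs[specs$type == "icr", ]
  if (nrow(icr)) {
    icr$parent_of_origin <- rep(c("maternal", "paternal"), length.out = nrow(icr))
    icr$germ_level <- unname(cfg$icr_germ_levels[icr$parent_of_origin])
    icr$somatic_level <- cfg$icr_somatic_level
  }

  # --- per-sample target levels and draws ------------------------------------
  somatic_level_of <- function(type) {
    switch(type, island = cfg$island_level, icr = cfg$icr_somatic_level,
           cfg$somatic_baseline)
  }
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n_s)
  cohort <- vector("list", n_s)
  for (si in seq_len(n_s)) {
    sm <- samples[si]
    withr::local_seed(sample_seeds[si])
    per_chrom <- lapply(chroms, function(ch) {
      pos <- pos_by_chrom[[ch]]
      lev <- rep(cfg$baseline_meth, length(pos))
      soma <- rep(cfg$somatic_baseline, length(pos))
      sp <- specs[specs$chrom == ch, ]
      for (r in seq_len(nrow(sp))) {
        idx <- sp$start_idx[r]:sp$end_idx[r]
        lev[idx] <- switch(sp$type[r],
          island = cfg$island_level,
          lmr_like = cfg$lmr_level,
          dmr = {
            d <- dmrs[dmrs$id == sp$id[r], ]
            if (groups[[sm]] == "CZ") d$cz_level else d$ctr_level
          },
          meqtl = cfg$meqtl_levels[geno[sp$id[r], sm] + 1L],
          icr = icr$germ_level[icr$id == sp$id[r]]
        )
        soma[idx] <- somatic_level_of(sp$type[r])
      }
      f <- frac[[sm]]
      if (f > 0) lev <- (1 - f) * lev + f * soma
      cov <- rnbinom(length(pos), mu = cfg$coverage_mean, size = cfg$coverage_dispersion)
      keep <- cov > 0
      tibble(sample_id = sm, group = unname(groups[[sm]]), chrom = ch,
             pos = pos[keep],
             n_meth = .rbetabinom(cov[keep], lev[keep], cfg$bio_dispersion),
             n_total = cov[keep])
    })
    cohort[[si]] <- list_rbind(per_chrom)
  }
  cohort <- list_rbind(cohort)

  tracks <- .simulate_tracks(chroms, cfg, specs)
  if (nrow(icr)) {
    tracks <- bind_rows(tracks, tibble(
      feature_class = "ICR", chrom = icr$chrom, start = icr$start, end = icr$end,
      name = icr$id, strand = "*", gene_symbol = NA_character_,
      target_genes = NA_character_, parent_of_origin = icr$parent_of_origin
    ))
  }

  truth <- list(
    cpg = list_rbind(imap(pos_by_chrom, function(p, ch) tibble(chrom = ch, pos = p))),
    true_dmrs = if (nrow(dmrs)) {
      dmrs[c("id", "chrom", "start", "end", "width", "direction",
             "ctr_level", "cz_level")]
    } else {
      tibble(id = character(), chrom = character(), start = integer(),
             end = integer(), width = integer(), direction = character(),
             ctr_level = double(), cz_level = double())
    },
    meqtl = list(regions = meqtl[c("id", "chrom", "start", "end", "width")],
                 genotypes = geno, levels = cfg$meqtl_levels),
    icr = if (nrow(icr)) icr[c("id", "chrom", "start", "end", "width",
                               "parent_of_origin", "germ_level", "somatic_level")]
          else icr,
    tracks = tracks,
    samples = tibble(sample_id = samples, group = unname(groups),
                     contamination = unname(frac)),
    config = cfg
  )
  list(cohort = cohort, truth = truth)
}

# Gene / exon / intron / promoter / CGI / enhancer tracks on the toy genome.
.simulate_tracks <- function(chroms, cfg, specs) {
  out <- list()
  gid <- 0L
  for (ch in chroms) {
    n_g <- cfg$n_genes_per_chrom
    if (n_g == 0) next
    slot <- floor(cfg$chrom_len / n_g)
    for (k in seq_len(n_g)) {
      gid <- gid + 1L
      sym <- sprintf("G%04d", gid)
      lo <- (k - 1L) * slot
      glen <- round(runif(1, 0.25, 0.6) * slot)
      gstart <- lo + round(runif(1, 0.05, 0.3) * slot)
      gend <- min(gstart + glen, lo + slot - 1000L)
      if (gend - gstart < 3000L) next
      strand <- sample(c("+", "-"), 1)
      n_ex <- max(2L, round((gend - gstart) / 8000))
      ex_starts <- sort(round(seq(gstart, gend - 500L, length.out = n_ex)))
      ex_ends <- pmin(ex_starts + round(runif(n_ex, 120, 400)), gend)
      tss <- if (strand == "+") gstart else gend
      out[[length(out) + 1L]] <- bind_rows(
        tibble(feature_class = "gene", chrom = ch, start = gstart, end = gend,
               name = sym, strand = strand, gene_symbol = sym),
        tibble(feature_class = "exon", chrom = ch, start = ex_starts, end = ex_ends,
               name = paste0(sym, "_ex", seq_len(n_ex)), strand = strand,
               gene_symbol = sym),
        tibble(feature_class = "promoter", chrom = ch,
               start = max(0L, tss - 1000L), end = tss + 1000L,
               name = paste0(sym, "_prom"), strand = strand, gene_symbol = sym)
      )
    }
  }
  tracks <- list_rbind(out)
  genes <- tracks[tracks$feature_class == "gene", ]

  # introns = gene minus exons
  if (nrow(genes)) {
    g_gr <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$start + 1L, genes$end))
    ex <- tracks[tracks$feature_class == "exon", ]
    e_gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end))
    intr <- GenomicRanges::setdiff(g_gr, GenomicRanges::reduce(e_gr))
    hit <- GenomicRanges::findOverlaps(intr, g_gr, select = "first")
    tracks <- bind_rows(tracks, tibble(
      feature_class = "intron",
      chrom = as.character(GenomicRanges::seqnames(intr)),
      start = GenomicRanges::start(intr) - 1L,
      end = GenomicRanges::end(intr),
      name = paste0(genes$gene_symbol[hit], "_int"),
      strand = genes$strand[hit], gene_symbol = genes$gene_symbol[hit]
    ))
  }

  # CGI track mirrors the planted unmethylated islands
  isl <- specs[specs$type == "island", ]
  if (nrow(isl)) {
    tracks <- bind_rows(tracks, tibble(
      feature_class = "CGI", chrom = isl$chrom, start = isl$start, end = isl$end,
      name = isl$id, strand = "*", gene_symbol = NA_character_
    ))
  }

  # enhancers in gene-free space, targeting the nearest gene(s)
  enh <- list()
  for (ch in chroms) {
    n_e <- cfg$n_enhancers_per_chrom
    if (n_e == 0) next
    gch <- genes[genes$chrom == ch, ]
    cand_start <- round(runif(n_e * 4, 1000, cfg$chrom_len - 3000))
    width <- round(runif(n_e * 4, 800, 1500))
    keep <- rep(TRUE, length(cand_start))
    if (nrow(gch)) {
      for (j in seq_along(cand_start)) {
        keep[j] <- !any(cand_start[j] < gch$end & cand_start[j] + width[j] > gch$start)
      }
    }
    cand_start <- head(cand_start[keep], n_e); width <- head(width[keep], n_e)
    if (!length(cand_start)) next
    tgt <- vapply(cand_start, function(s) {
      if (!nrow(gch)) return(NA_character_)
      d <- pmax(gch$start - s, s - gch$end, 0)
      gch$gene_symbol[which.min(d)]
    }, character(1))
    second <- vapply(cand_start, function(s) {
      if (nrow(gch) < 2) return(NA_character_)
      d <- pmax(gch$start - s, s - gch$end, 0)
      gch$gene_symbol[order(d)[2]]
    }, character(1))
    two <- runif(length(cand_start)) < 0.3 & !is.na(second)
    enh[[length(enh) + 1L]] <- tibble(
      feature_class = "enhancer", chrom = ch,
      start = as.integer(cand_start), end = as.integer(cand_start + width),
      name = paste0("ENH_", ch, "_", seq_along(cand_start)), strand = "*",
      gene_symbol = NA_character_,
      target_genes = ifelse(two, paste(tgt, second, sep = ";"), tgt)
    )
  }
  if (length(enh)) tracks <- bind_rows(tracks, list_rbind(enh))
  tracks$start <- as.integer(tracks$start)
  tracks$end <- as.integer(tracks$end)
  if (!"target_genes" %in% names(tracks)) tracks$target_genes <- NA_character_
  tracks
}

#' Mix somatic DNA into a germ-cell sample
#'
#' Redraws each CpG's methylated count from the mixture level
#' `(1 - fraction) * germ + fraction * somatic` at unchanged coverage. The germ
#' level is the sample's observed per-CpG proportion; the somatic level comes
#' from `somatic_profile` intervals, with `default_level` elsewhere.
#'
#' @param meth One sample's methylome tibble.
#' @param somatic_profile Tibble `chrom`, `start`, `end`, `level` of somatic
#'   methylation levels per region (may be empty).
#' @param fraction Somatic fraction in [0, 1].
#' @param default_level Somatic level outside profiled regions.
#' @param seed Optional seed for the redraw.
#' @return The sample tibble with redrawn `n_meth`.
#' @export
mix_somatic <- function(meth, somatic_profile = NULL, fraction,
                        default_level = 0.75, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  validate_methylome(meth)
  if (fraction == 0 || nrow(meth) == 0) return(meth)
  soma <- rep(default_level, nrow(meth))
  if (!is.null(somatic_profile) && nrow(somatic_profile)) {
    q <- GenomicRanges::GRanges(meth$chrom, IRanges::IRanges(meth$pos + 1L, meth$pos + 1L))
    s <- GenomicRanges::GRanges(somatic_profile$chrom,
                                IRanges::IRanges(somatic_profile$start + 1L,
                                                 somatic_profile$end))
    hit <- GenomicRanges::findOverlaps(q, s, select = "first")
    soma[!is.na(hit)] <- somatic_profile$level[hit[!is.na(hit)]]
  }
  germ <- ifelse(meth$n_total > 0, meth$n_meth / meth$n_total, 0)
  mix <- (1 - fraction) * germ + fraction * soma
  draw <- function() rbinom(nrow(meth), meth$n_total, mix)
  meth$n_meth <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  meth
}

#' Default purity-screen loci
#'
#' Expected germ-cell and somatic methylation levels for the four-locus deep
#' bisulfite sequencing purity panel: a maternally methylated imprinted locus
#' (MEST-like: 0 in male germ, 0.5 in soma), a paternally methylated imprinted
#' locus (H19-like: 1 in germ, 0.5 in soma), an X-inactivation locus
#' (XIST-like: 0 in male germ, ~1 in male soma), and a germline-specific
#' promoter (DDX4-like: 0 in germ, 1 in soma).
#'
#' @return Tibble `name`, `germ_level`, `somatic_level`.
#' @export
default_purity_loci <- function() {
  tibble(
    name = c("MEST", "H19", "XIST", "DDX4"),
    germ_level = c(0, 1, 0, 0),
    somatic_level = c(0.5, 0.5, 1, 1)
  )
}

#' Simulate a targeted amplicon purity panel
#'
#' Draws per-locus binomial read counts at the germ/somatic mixture level,
#' emulating deep bisulfite sequencing of the purity-screen amplicons.
#'
#' @param loci Tibble `name`, `germ_level`, `somatic_level` (see
#'   [default_purity_loci()]).
#' @param fraction Somatic fraction of the sample.
#' @param reads_per_locus Reads drawn per locus.
#' @param seed Optional seed.
#' @return Tibble `name`, `n_meth`, `n_total`, `mean`.
#' @export
simulate_amplicon_panel <- function(loci = default_purity_loci(), fraction = 0,
                                    reads_per_locus = 1000, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  draw <- function() {
    mix <- (1 - fraction) * loci$germ_level + fraction * loci$somatic_level
    n_meth <- rbinom(nrow(loci), reads_per_locus, mix)
    tibble(name = loci$name, n_meth = n_meth,
           n_total = as.integer(reads_per_locus),
           mean = n_meth / reads_per_locus)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
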