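---
title: "Methods: confounder-aware DMR discovery in germ-cell methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: confounder-aware DMR discovery in germ-cell methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`wgbsdmr` implements a complete case–control analysis chain for whole-genome
bisulfite sequencing (WGBS) of purified testicular germ cells: purity QC
against somatic-DNA admixture, methylome segmentation into regulatory-region
proxies, stringent consensus DMR discovery with a genotype-confounder filter,
CpG-matched Monte Carlo feature enrichment, and DMR-to-gene association. This
vignette explains the models, the tunable parameters and the design decisions;
the worked example in the README shows the code path.

## The scientific problem

Two confounders dominate small case–control methylation studies in germ cells.
First, residual somatic DNA: male germ cells carry extreme methylation states
at imprinting control regions (ICRs) — maternally methylated (oocyte) ICRs are
unmethylated, paternally methylated (sperm) ICRs fully methylated — while
somatic tissue sits near 0.5 at both, so even modest admixture pulls these
loci towards intermediate values. Second, genetic background: a local variant
can set the methylation of nearby CpGs to low, intermediate or high levels
depending on genotype (meQTL behaviour). In a 4-vs-4 design such trimodal
regions easily masquerade as group differences. The package operationalizes
both defences: a four-locus amplicon screen plus a genome-wide ICR check for
purity, and a within-group methylation-range filter against genotype-driven
regions.

## Purity QC

`locus_mean_methylation()` computes coverage-weighted means
(`sum(n_meth) / sum(n_total)` over CpGs with coverage ≥ `min_cov`; an interval
without covered CpGs is a missing value, never zero). The amplicon panel
(MEST-, H19-, XIST- and DDX4-like loci) has per-locus expected germ and
somatic levels; `estimate_somatic_fraction()` solves the one-parameter
least-squares mixture `obs ≈ (1−f)·germ + f·soma`, clamped to [0, 1]. A sample
is "pure" when every locus deviates from its germ expectation by at most the
tolerance (default 0.10 absolute — no numeric cutoff is standard in the field,
and 0.10 puts the detection edge near f ≈ 0.2 at the most informative loci).
The genome-wide `icr_check()` compares each ICR's mean to its parent-of-origin
expectation; a sample fails when more than 10% of evaluable ICRs deviate
beyond tolerance, so a single methylation polymorphism cannot fail a sample.
With ~50 ICRs this allows a handful of deviants; with very small ICR panels
the rule effectively allows none, which is why the tests use panels of 10–20.

## Segmentation into UMRs and LMRs

Regulatory-region annotation for germ cells is scarce, so low-methylation
segmentation is used as a proxy: unmethylated regions (UMRs, CpG-rich,
promoter-like) and low-methylated regions (LMRs, CpG-poorer, enhancer-like).
`segment_methylome()` is a deliberately simplified variant of the established
HMM-free cutoff procedure: per-CpG posterior-mean methylation with add-one
smoothing (`(n_meth+1)/(n_total+2)`), a 3-CpG running median, maximal runs of
consecutive covered CpGs below `meth_cutoff = 0.5`, a minimum of 4 CpGs per
segment, and a UMR/LMR class split at 30 CpGs. These are the published
defaults of the reference segmentation method; what is omitted is the
FDR-based calibration of the cutoff pair against CpG islands (it requires
training annotation the package does not assume) and the masking of partially
methylated domains (PMDs): germ-cell methylomes are modelled as PMD-free here,
a documented limitation for transfer to somatic tissues.

High-confidence consensus regions (`high_confidence_regions()`) keep, per
class, the maximal intervals supported base-pair-wise by at least
`min_support = 3` of the control methylomes. The base-pair interpretation is
parameter-free and order-independent; a whole-region interpretation
(`method = "region"`) is available since published descriptions are ambiguous
between the two.

## DMR discovery

The published criteria are the binding constraints: DMRs cover ≥ 4 CpGs, show
≥ 0.30 absolute group difference (inclusive, by the literal reading of
"at least"), use only CpGs covered ≥ 5× in every sample, and satisfy q ≤ 0.05
where the caller provides a q-value. Two callers of complementary design are
implemented natively:

* **t-statistic caller** (`call_dmrs_tstat()`, bsmooth/camel family):
  per-sample levels smoothed by a 5-CpG running mean; per-CpG pooled
  two-sample t with the pooled SD floored at `sd_floor = 0.1`; maximal runs of
  ≥ 4 consecutive qualifying CpGs (|t| ≥ 4.6, consistent sign, inter-CpG gap
  ≤ 300 bp). The variance floor is the one genuinely open internal: with n = 4
  per group, near-zero within-group variance after smoothing would otherwise
  let negligible differences produce enormous t values. A floor of 0.1 means
  only smoothed differences above ≈ 0.33 can qualify, aligning the caller's
  effective detection floor with the 0.30 published difference criterion. No
  q-values are produced, matching this caller family.
* **binary-segmentation caller** (`call_dmrs_segmentation()`, metilene
  family): the per-CpG mean-difference signal is cut into blocks at gaps
  > 300 bp, recursively split at the point maximizing the difference of
  sub-block means (stop below 8 CpGs or when no split improves by 0.1), and
  leaf blocks with |mean difference| ≥ 0.30 are scored by a rank-sum test
  against up to 50 flanking CpGs per side, with Benjamini–Hochberg correction
  across candidates. Published method descriptions conflict on the q
  threshold's direction; the acceptance reading (q ≤ 0.05) is implemented.
  Candidates without enough flanking background keep `q = NA` ("where
  available").

`merge_dmr_sets()` unions any-bp-overlapping intervals across callers and
**recomputes every statistic from raw counts on the union interval** — never
averaging caller outputs — because the downstream range filter must see
per-sample means of the final interval. `apply_range_filter()` then keeps DMRs
whose per-sample means span ≤ 0.30 within both groups (inclusive, with a 1e-9
float guard). Finally `direction_binomial_test()` tests hyper- versus
hypomethylation counts by the exact two-sided binomial with minimum-tail
doubling, `p = min(1, 2·min(P(X≤k), P(X≥k)))` at p = 1/2.

## CpG-count- and length-matched enrichment

Naive interval randomization misstates enrichment because DMRs concentrate in
CpG-dense sequence. The matched randomizer preserves, per actual DMR, the
exact number of covered CpGs: a placement is a run of n consecutive
all-sample-covered CpGs; `pool_size = 1000` placements are drawn uniformly and
one is selected with probability proportional to the log-normal density (fitted
to the actual DMR lengths by the closed-form MLE) at the candidate's nucleotide
length. "Selected according to a log-normal distribution" admits several
readings; density-weighted sampling among the pool is the only one that uses
both the pool and the fitted distribution, and it is implemented exactly (the
vectorized path uses the Gumbel-max trick, an exact weighted pick). Empirical
p-values use the add-one estimator `(1 + #{null ≥ obs})/(1 + n_sets)` per
tail, so p is never zero; the odds ratio compares observed odds to mean-null
odds with Haldane continuity correction (a pooled 2×2 across sets is a noted
alternative; mean-null is the default). The default `n_sets` for
`enrichment_test()` is 10^6 as in publication-scale use; the pipeline default
and all tests run at 10^2–10^4, which exercises the identical code path.

Null calibration (`enrichment_null_calibration()`) draws the query set from
the randomizer itself: each of 200 simulated experiments uses a fresh null of
1000 sets, and the resulting p-values are checked for uniformity by a KS test.
Because the overlap count is integer-valued, tied counts make the add-one
estimator slightly conservative; the calibration fixture therefore uses a
track covering about half the CpG space and several hundred templates so the
count statistic is fine-grained and the residual conservativeness stays well
inside the KS tolerance at 200 repetitions.

## The synthetic cohort generator

`simulate_cohort()` defines the study conditions every test runs under, fixed
a priori: two groups of 4 samples; negative-binomial coverage with mean 14
(size 15, putting ~90% of CpGs at ≥ 5× in all 8 samples); geometric inter-CpG
spacing with mean 100 bp on a 2 × 5 Mb toy genome; background methylation 0.8
with planted unmethylated islands (40 CpGs at 0.03, the CGI/UMR analogue) and
low-methylated elements (10 CpGs at 0.15, the LMR analogue); beta-binomial
biological noise with variance 0.02 — chosen so the within-group range of a
true DMR stays comfortably below the 0.3 filter at n = 4; 20 planted DMRs of
effect 0.4 over 8–16 CpGs (hyper: 0.35→0.75, hypo: 0.85→0.45); 10 meQTL-like
regions with genotype levels {0.05, 0.5, 0.95} under Hardy–Weinberg with
allele frequency 0.5 (maximizing mixed genotypes within groups — the
confounder the range filter targets); ICRs at 0.02/0.98 in germ (0.5 somatic);
and optional per-sample somatic admixture, which shifts every regional target
level towards a somatic profile. All randomness flows from the single config
seed, with per-sample sub-seeds drawn once from the master stream so sample
tables are individually reproducible.

What the generator does **not** emulate: PMDs, mappability and conversion
biases, strand-level counts, spatially correlated biological noise (noise is
independent per CpG, which if anything makes region-level averaging easier
than in real data), and realistic chromosome-scale CpG density variation.
Passing tests therefore demonstrate the correctness and calibration of the
machinery under the declared generative model, not performance on real WGBS.

## Numerical choices and degenerate inputs

Duplicate CpG positions are an error, not merged (they indicate upstream
preprocessing faults). Intervals are 0-based half-open everywhere; intervals
sharing only a boundary do not overlap. An interval without covered CpGs gives
a missing mean, never zero. The length model floors a degenerate `sdlog` at
1e-6 with a warning. Ties at `diff = 0` cannot pass the 0.30 difference
criterion, so direction is well-defined for every emitted DMR. The range and
difference boundaries are inclusive with a 1e-9 guard against float rounding.
Empirical p-values are bounded below by `1/(n_sets + 1)` by construction.

## Problem sizes

The test suite and the acceptance script run the full-scale benchmark on the
default 10 Mb toy genome (~100,000 CpGs, 8 samples), the null calibration at
1000 sets × 200 repetitions with a pool of 50, and the positive-control
enrichment at 10,000 sets with the default pool of 1000. These sizes exercise
every code path at full fidelity while keeping a complete run on a single CPU
in the minutes range.
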