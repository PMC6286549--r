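---
title: "Window-based differential methylation from MeDIP and MRE counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based differential methylation from MeDIP and MRE counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(winmeth)
```

## The problem and the measurement model

Two complementary sequencing assays probe a methylome from opposite sides.
MeDIP-seq immunoprecipitates methylated DNA fragments, so read counts rise
with methylation; MRE-seq sequences fragments cut by methylation-sensitive
restriction enzymes, which only cut unmethylated sites, so its counts rise
as methylation falls. Counting reads from both assays in fixed windows
gives, per window, a pair (MeDIP, MRE) whose balance reflects the local
methylation proportion: roughly `m = medip / (medip + mre)` after
library-size normalization.

`winmeth` turns this into a differential-methylation pipeline between two
conditions (called diets, "HF" vs "LF", after the obesity study design it
emulates, but any two-group labels work):

1. **Tiling.** The genome is partitioned into adjacent half-open windows of
   at most 500 bp (`tile_genome()`); the last window of each chromosome is
   truncated rather than dropped so the windows are an exact partition. All
   coordinates are 0-based half-open (BED convention) everywhere inside the
   package; 1-based inputs must be converted at the boundary.
2. **Per-window testing.** For each pair of one HF and one LF library,
   every window's normalized counts form a 2x2 table, rows = libraries,
   columns = (MeDIP, MRE), tested with a two-sided conditional exact test
   (`window_test()`).
3. **Combination.** The per-comparison p-values are pooled per window with
   Fisher's combined probability test, `X2 = -2 * sum(log(p_i)) ~
   chi-square(2k)` (`fisher_combine()`, `combine_windows()`).
4. **FDR and DMR calling.** Combined p-values are Benjamini-Hochberg
   adjusted (`bh_adjust()`) and windows with `q < 0.05` or `q < 0.01`
   (strict inequality) become differentially methylated regions
   (`call_dmrs()`). Windows are the DMR unit; adjacent significant windows
   are not merged.
5. **Annotation and enrichment.** DMRs are classified against gene models
   and regulatory features (`annotate_dmrs()`), summarized Table-style
   (`summarize_annotation()`), and tested for enrichment in regulatory
   regions (`regulatory_chi2()`) and in differentially expressed genes via
   an intergenic-constrained randomization (`constrained_randomize()`,
   `overlap_chi2()`).

`run_pipeline()` sequences the stages through declared TSV/BED files and a
JSON run manifest, so each stage is independently testable and a rerun with
the same configuration and seed is bit-identical.

## The per-window statistic

The window test conditions on all margins of the 2x2 table and sums
hypergeometric probabilities of every table with those margins whose
probability does not exceed the observed table's (the classic two-sided
exact construction). Its direction is the sign of the difference of the
two libraries' methylation estimates `medip / (medip + mre)`; it is "0"
when either library has no reads in the window or the estimates tie.

Assumptions and consequences worth knowing:

* **Conditioning.** Under independent Poisson counts with a common
  methylation level, the table is exactly hypergeometric given its margins,
  so the test is exact there. Overdispersion beyond Poisson (biological
  replicate noise) is *not* absorbed by the statistic — that is precisely
  why the pipeline tests library pairs and combines across them, and why
  `run_qc_within_group()` exists: replicate-vs-replicate comparisons
  estimate how much signal the noise alone produces.
* **Discreteness.** Like every exact test, it is conservative: under a
  Poisson null at realistic coverage (tens of reads per window) the
  fraction of windows with `p < 0.05` settles around 0.035-0.045, not
  0.05. The test suite asserts validity (the rate never exceeds the upper
  binomial bound) rather than two-sided equality with the nominal level,
  which discreteness makes unattainable at this coverage.
* **Normalization.** Before testing, each pair's counts are scaled to the
  arithmetic mean of the two libraries' totals (separately for MeDIP and
  MRE) and rounded half away from zero — a deterministic rule that is
  symmetric in the two libraries.

Windows with fewer than `min_cpg` CpG sites (default 1) or a combined
normalized count below `min_coverage` (default 4, the smallest total at
which a 2x2 exact test can reach `p < 0.05`... in fact the smallest at
which it has any resolution at all) are left untested. Untested windows
propagate `p = 1` and direction "0" so window indexing stays aligned
across comparisons.

## Combining comparisons

With two replicate libraries per group, "all pairs" pairing yields four
HF-vs-LF comparisons per stratum; `pairing = "disjoint_pairs"` instead
pairs replicate 1 with replicate 1 and replicate 2 with replicate 2, the
two-comparison design in which the combined p-values come from disjoint
data. Both modes are provided because the four overlapping pairs share
libraries, which violates the independence Fisher's method assumes and
makes the combined p-values somewhat anti-conservative; the disjoint mode
is the statistically cleaner choice, the all-pairs mode uses more of the
data and is the default. Neither is asserted to be "the" original design.

Three further conventions are deliberate decisions:

* A window counts as **tested overall** only if it was tested in every
  comparison, which keeps the chi-square degrees of freedom `2k` honest;
  partially tested windows get `q = NA`.
* The BH family size `m` is the number of fully tested windows —
  coverage-filtered windows are excluded *before* correction, and the
  output records this.
* `p = 0` from upstream underflow is clamped to the smallest positive
  double before the log, keeping `X2` finite; the count of clamped values
  is reported.

## Annotation rules

Promoters are strand-aware: 2000 bp upstream of the transcription start
site through 600 bp downstream of it (`[tx_start - 2000, tx_start + 600)`
on the + strand, mirrored on the - strand), clipped to the chromosome.
"Upstream" is meaningless without strand, which is why the promoter is not
a symmetric window around the TSS.

Each DMR gets exactly one of four categories — exon, intron, promoter,
intergenic — with exon taking precedence over intron when a window spans a
junction, and gene-body overlap taking precedence over promoter. A
separate boolean `promoter_flag` records promoter overlap regardless of
category, so a window in a first exon can be counted in both the exon and
promoter rows of a summary; this reconciles a mutually exclusive four-way
classification with summary tables whose rows are allowed to co-occur.
Regulatory overlap is any-overlap (at least 1 bp, half-open semantics) per
feature class. Nearest-gene distance is the gap in bp between half-open
intervals (0 for overlap or direct adjacency), with ties broken by smaller
`tx_start`, then lexicographic gene id.

Summary percentages are `100 * count / total` rounded **half up** to one
decimal — the convention that reproduces printed summary tables of this
kind; note that base R's `round()` (half to even) does not.

## Enrichment

Two procedures:

* **Regulatory chi-square.** A 1-df goodness-of-fit test of the observed
  (in-regulatory, not-in-regulatory) DMR split against expectations from
  the genome-wide fraction of windows overlapping the union of the four
  regulatory classes.
* **Intergenic-constrained randomization.** DMRs are under-represented in
  intergenic windows, so placing them uniformly would overstate expected
  overlap deficits elsewhere. Each randomization therefore places
  `round(f * n)` of the n DMRs uniformly without replacement among
  intergenic windows and the rest among non-intergenic windows, where f is
  the observed intergenic fraction of the real DMRs; per replicate it
  counts placements landing in windows that overlap a differentially
  expressed gene body (DE = `q < 0.05` in the supplied DE table). The
  chi-square against the null mean is reported together with the
  assumption-free empirical p-value `(1 + #{null >= obs}) / (1 + n_rand)`,
  which can never fall below `1 / (1 + n_rand)`. Sampling is without
  replacement because distinct DMRs occupy distinct windows. The default
  `n_rand = 1000` resolves empirical p down to about 0.001 in seconds at
  desk scale; the seed is a required argument.

## What the synthetic generator emulates — and what it does not

`simulate_inputs()` fabricates every pipeline input under one seeded
model; `simulation_config()` holds the dials. Per window w with `c_w` CpG
sites and methylation level `theta_w(group)`:

    MeDIP_w ~ NegBin(mean = s_medip * c_w * theta_w / Z,        size = dispersion)
    MRE_w   ~ NegBin(mean = s_mre   * c_w * (1 - theta_w) / Z', size = dispersion)

with Z, Z' normalizing means to the library totals. Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| `window_size` | 500 bp | the windowing the pipeline is built around |
| `cpg_density` | 10 CpGs/window (Poisson) | mammalian-scale CpG density at 500 bp |
| `baseline_meth_beta` | Beta(2, 2) | broad unimodal methylation levels on (0,1) |
| `library_size_*` | 30 reads/window expected | tens-of-millions-read libraries over millions of windows |
| `dispersion` (NB size) | 100 | pooled libraries (4 animals each) show mild overdispersion; this value reproduces the near-total replicate concordance the emulated study design implies, whereas strong overdispersion (size ~10) would make replicate comparisons as discordant as the diet comparisons. `Inf` gives the Poisson limit |
| `n_libraries_per_group` | 2 | two pooled biological replicates per group |
| `effect_delta` | 0.4 | additive shift of theta in the HF group at planted windows, clamped to [0.01, 0.99] |
| `fraction_regulatory` | 3.5 / 1.7 / 0.3 / 8.1 % | genome-wide coverage of the four regulatory classes at roughly mammalian scale |

The default genome is two 500-kb chromosomes (2000 windows) with 60
non-overlapping genes of 2-10 kb, 50 planted DMR windows and 20 planted DE
genes; a configurable fraction of planted DMRs is forced inside DE gene
bodies so the enrichment stage has a tunable true effect. The test suite
scales the genome per purpose: about 20,000 windows for null-calibration
properties, 2000 for power/recovery, a few hundred for orchestration
tests — sizes at which every property is measurable in seconds.

The generator deliberately does **not** model: read-level data (no FASTQ,
no alignment), the actual MRE restriction-site map (MRE means are a smooth
function of `1 - theta` scaled by CpG count, preserving the MeDIP/MRE
anticorrelation but not fragment-level structure), bimodal methylation
landscapes, spatial autocorrelation of methylation along the chromosome,
overlapping or nested genes, and sex strata (one simulation = one
stratum; run it twice for a two-sex design). Passing tests on synthetic
data therefore demonstrate the statistical machinery — calibration,
recovery of planted effects, exactness of the combinatorics — not
performance on any real methylome.

## Numerical choices

* Two-sided exact p-values include tables whose probability is within a
  `1e-7` relative tolerance of the observed table's, guarding against
  floating-point ties; when every table qualifies the p-value is set to
  exactly 1 rather than a sum's `1 - eps`.
* Normalized counts round half away from zero; summary percentages round
  half up; both are stated, deterministic tie rules.
* The intergenic allocation `round(f * n)` also rounds half away from
  zero for determinism.
* Degenerate inputs: an all-zero 2x2 table gives `p = 1`, direction "0";
  an empty assembly, an empty p-value list, a zero-library group, and a
  stratum smaller than its allocation are errors, not silent results.

## Limitations

* The per-window statistic is a fully specified conditional exact test,
  not one of the published joint MeDIP+MRE models ("M&M"-style
  statistics): it preserves the interface (a p-value and direction per
  window per comparison) but not those models' use of CpG- and
  restriction-site-count corrections inside the statistic. CpG content
  enters only through the `min_cpg` filter and the simulation.
* Fisher combination over all library pairs reuses each library in two
  comparisons; see the pairing discussion above.
* Exact-test conservativeness at moderate coverage depresses the null
  rejection rate below the nominal level; at the default coverage this is
  a 1-1.5 percentage-point deficit at the 5% level.
* No spatial merging of adjacent significant windows and no single-CpG
  resolution: the window is the unit of inference throughout.
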