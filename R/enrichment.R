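#' Chi-square enrichment of DMRs in regulatory regions
#'
#' One-degree-of-freedom goodness-of-fit test of the observed split of DMRs
#' into (in regulatory region, not in regulatory region) against the split
#' expected if DMRs fell on windows uniformly, taken from the genome-wide
#' fraction of windows overlapping the union of the regulatory classes.
#'
#' @param observed_in number of DMRs overlapping a regulatory region.
#' @param n_total total number of DMRs.
#' @param background_fraction genome-wide fraction of windows overlapping a
#'   regulatory region (in `[0, 1]`).
#' @return an `enrichment_result` list with `observed`, `expected`, `chi2`,
#'   `df`, `p_value`.
#' @examples
#' regulatory_chi2(30, 100, 0.2)  # chi2 = 6.25, p ~ 0.0124
#' @export
regulatory_chi2 <- function(observed_in, n_total, background_fraction) {
  if (observed_in < 0 || n_total < observed_in) {
    stop("need 0 <= observed_in <= n_total", call. = FALSE)
  }
  O <- c(observed_in, n_total - observed_in)
  E <- n_total * c(background_fraction, 1 - background_fraction)
  if (any(E == 0)) {
    stop("expected count of zero; pool regulatory classes or enlarge the ",
         "background before testing", call. = FALSE)
  }
  chi2 <- sum((O - E)^2 / E)
  structure(list(test = "regulatory_chi2", observed = O[1], expected = E[1],
                 n_total = n_total, chi2 = chi2, df = 1L,
                 p_value = pchisq(chi2, df = 1, lower.tail = FALSE)),
            class = "enrichment_result")
}

#' Intergenic-constrained randomization of DMR placement
#'
#' Re-places the n observed DMRs uniformly at random (without replacement)
#' among genome windows, holding the intergenic fraction fixed: each
#' replicate puts `round(f * n)` DMRs into intergenic windows and the rest
#' into non-intergenic windows, where f is the observed intergenic fraction
#' of the real DMRs. For each replicate it counts how many placements land
#' in windows overlapping differentially expressed gene bodies. This is the
#' null distribution for [overlap_chi2()]; constraining the intergenic
#' fraction accounts for the general under-representation of DMRs in
#' intergenic windows.
#'
#' @param dmr_idx integer indices (1-based rows into the window set) of the
#'   observed DMR windows.
#' @param intergenic logical vector over all windows: window is intergenic.
#' @param in_de_gene logical vector over all windows: window overlaps the
#'   body of a differentially expressed gene.
#' @param n_rand number of randomizations (default 1000).
#' @param seed RNG seed (required, for reproducibility).
#' @return integer vector of per-replicate overlap counts, with attributes
#'   `intergenic_fraction`, `n_intergenic` (allocation per replicate),
#'   `n_dmrs`, `seed`.
#' @export
constrained_randomize <- function(dmr_idx, intergenic, in_de_gene,
                                  n_rand = 1000, seed) {
  if (length(intergenic) != length(in_de_gene)) {
    stop("intergenic and in_de_gene must cover the same windows", call. = FALSE)
  }
  n <- length(dmr_idx)
  if (n == 0L) stop("no DMRs to randomize", call. = FALSE)
  .assert_scalar_number(seed, "seed")
  f <- mean(intergenic[dmr_idx])
  n_inter <- as.integer(.round_half_away(f * n))
  pool_i <- which(intergenic)
  pool_g <- which(!intergenic)
  if (n_inter > length(pool_i)) {
    stop("intergenic stratum smaller than its allocation", call. = FALSE)
  }
  if (n - n_inter > length(pool_g)) {
    stop("non-intergenic stratum smaller than its allocation", call. = FALSE)
  }
  set.seed(seed)
  counts <- integer(n_rand)
  for (r in seq_len(n_rand)) {
    placed <- c(if (n_inter > 0) pool_i[sample.int(length(pool_i), n_inter)],
                if (n - n_inter > 0) pool_g[sample.int(length(pool_g),
                                                       n - n_inter)])
    counts[r] <- sum(in_de_gene[placed])
  }
  structure(counts, intergenic_fraction = f, n_intergenic = n_inter,
            n_dmrs = n, seed = seed)
}

#' Chi-square and permutation test of DMR overlap with DE genes
#'
#' Compares the observed number of DMRs falling within differentially
#' expressed genes against the mean of the constrained-randomization null:
#' a 1-df goodness-of-fit chi-square on the (overlap, non-overlap) split,
#' plus the assumption-free empirical permutation p-value
#' `(1 + #\{null >= observed\}) / (1 + n_rand)`.
#'
#' @param observed observed overlap count.
#' @param rand_counts per-replicate null counts from
#'   [constrained_randomize()] (counts from several strata, e.g. the two
#'   sexes, may be summed replicate-wise before calling).
#' @param n_total total number of DMRs behind `observed`.
#' @return an `enrichment_result` list with `chi2`, `df`, `p_value`
#'   (chi-square), `p_empirical`, `expected`, `n_rand`.
#' @export
overlap_chi2 <- function(observed, rand_counts, n_total) {
  if (length(rand_counts) == 0L) stop("need at least one randomization",
                                      call. = FALSE)
  expected <- mean(rand_counts)
  O <- c(observed, n_total - observed)
  E <- c(expected, n_total - expected)
  if (any(E <= 0)) {
    stop("degenerate expectation; increase randomizations or total count",
         call. = FALSE)
  }
  chi2 <- sum((O - E)^2 / E)
  p_emp <- (1 + sum(rand_counts >= observed)) / (1 + length(rand_counts))
  structure(list(test = "overlap_chi2", observed = observed,
                 expected = expected, n_total = n_total, chi2 = chi2,
                 df = 1L, p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
                 p_empirical = p_emp, n_rand = length(rand_counts),
                 rand_counts = as.integer(rand_counts)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s: observed %.0f, expected %.2f (of %d), chi2 = %.4g (df %d), p = %.3g\n",
              x$test, x$observed, x$expected, x$n_total, x$chi2, x$df,
              x$p_value))
  if (!is.null(x$p_empirical)) {
    cat(sprintf("  empirical p = %.4g over %d randomizations\n",
                x$p_empirical, x$n_rand))
  }
  invisible(x)
}
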