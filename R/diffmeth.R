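#' Window count matrix for MeDIP and MRE libraries
#'
#' Bundles the tiled windows, per-window CpG counts, the library manifest
#' (library_id, sex, diet, replicate) and the MeDIP/MRE count matrices
#' (windows x libraries). Library totals are derived from the matrices.
#'
#' @param windows windows from [tile_genome()] (or a compatible frame).
#' @param cpg integer vector of CpG counts per window.
#' @param libraries manifest data frame with columns `library_id`, `sex`,
#'   `diet`, `replicate`.
#' @param medip,mre numeric matrices, one column per library in manifest
#'   order.
#' @return a `window_counts` object (list).
#' @export
window_counts <- function(windows, cpg, libraries, medip, mre) {
  medip <- as.matrix(medip)
  mre <- as.matrix(mre)
  n <- nrow(windows)
  if (length(cpg) != n || nrow(medip) != n || nrow(mre) != n) {
    stop("count vectors must have one entry per window", call. = FALSE)
  }
  if (ncol(medip) != nrow(libraries) || ncol(mre) != nrow(libraries)) {
    stop("count matrices must have one column per library", call. = FALSE)
  }
  if (any(medip < 0) || any(mre < 0) || any(cpg < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  colnames(medip) <- colnames(mre) <- libraries$library_id
  structure(list(windows = windows, cpg = as.numeric(cpg),
                 libraries = as.data.frame(libraries),
                 medip = medip, mre = mre,
                 medip_totals = colSums(medip),
                 mre_totals = colSums(mre)),
            class = "window_counts")
}

#' @export
print.window_counts <- function(x, ...) {
  cat(sprintf("window_counts: %d windows, %d libraries (%s)\n",
              nrow(x$windows), nrow(x$libraries),
              paste(x$libraries$library_id, collapse = ", ")))
  invisible(x)
}

#' Library-size normalization of a count
#'
#' Scales `x` by `reference_total / total` and rounds half away from zero to
#' an integer, so the exact window test can be applied to libraries of
#' unequal depth.
#'
#' @param x count(s) to scale.
#' @param total total reads of the library `x` comes from (> 0).
#' @param reference_total the total to scale to.
#' @return non-negative integer-valued vector.
#' @examples
#' normalize_counts(10, 2000, 1000)  # 5
#' normalize_counts(3, 2000, 1000)   # 2 (1.5 rounds away from zero)
#' @export
normalize_counts <- function(x, total, reference_total) {
  if (any(total <= 0)) stop("empty library: total must be > 0", call. = FALSE)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  .round_half_away(x * reference_total / total)
}

# Conditional exact test on one 2x2 table rows = (library A, library B),
# cols = (MeDIP, MRE). Two-sided by summing hypergeometric probabilities of
# all tables with the observed margins whose probability does not exceed the
# observed table's (with a 1e-7 relative tolerance for floating-point ties).
.window_test_one <- function(ma, ua, mb, ub) {
  r1 <- ma + ua
  r2 <- mb + ub
  c1 <- ma + mb
  tot <- r1 + r2
  if (tot == 0) {
    p <- 1
  } else {
    supp <- max(0, c1 - r2):min(r1, c1)
    d <- dhyper(supp, c1, tot - c1, r1)
    incl <- d <= dhyper(ma, c1, tot - c1, r1) * (1 + 1e-7)
    # when every table is included the sum is 1 by definition; do not let
    # floating-point summation report 1 - eps
    p <- if (all(incl)) 1 else min(1, sum(d[incl]))
  }
  if (r1 == 0 || r2 == 0) {
    dir <- 0L  # no methylation estimate for at least one library
  } else {
    dir <- .sign_int(ma / r1 - mb / r2)
  }
  c(p = p, direction = dir)
}

#' Per-window exact test of differential methylation
#'
#' Tests whether the methylation proportion differs between two libraries in
#' one window, integrating MeDIP (methylated) and MRE (unmethylated) counts.
#' The statistic is a two-sided conditional exact test on the 2x2 table with
#' rows (library A, library B) and columns (MeDIP, MRE): the p-value is the
#' sum of hypergeometric probabilities, over all tables with the observed
#' margins, whose probability does not exceed that of the observed table.
#' The direction is the sign of `medip_a/(medip_a+mre_a) -
#' medip_b/(medip_b+mre_b)`; it is `"0"` when either library has no reads or
#' the estimates are equal. Counts are expected to be library-size
#' normalized (see [normalize_counts()]).
#'
#' @param medip_a,mre_a,medip_b,mre_b non-negative integer vectors
#'   (recycled to a common length).
#' @return data frame with columns `p` and `direction` (`"+"`, `"-"`, `"0"`).
#' @examples
#' window_test(10, 2, 2, 10)   # p ~ 0.0033, direction "+"
#' window_test(5, 5, 5, 5)     # p = 1, direction "0"
#' @export
window_test <- function(medip_a, mre_a, medip_b, mre_b) {
  n <- max(length(medip_a), length(mre_a), length(medip_b), length(mre_b))
  ma <- rep_len(medip_a, n); ua <- rep_len(mre_a, n)
  mb <- rep_len(medip_b, n); ub <- rep_len(mre_b, n)
  if (any(c(ma, ua, mb, ub) < 0)) stop("counts must be non-negative", call. = FALSE)
  p <- numeric(n)
  dir <- integer(n)
  for (i in seq_len(n)) {
    r <- .window_test_one(ma[i], ua[i], mb[i], ub[i])
    p[i] <- r[["p"]]
    dir[i] <- r[["direction"]]
  }
  data.frame(p = p, direction = .dir_symbol(dir), stringsAsFactors = FALSE)
}

.pairwise_one <- function(counts, i, j, min_coverage, min_cpg) {
  ref_medip <- mean(counts$medip_totals[c(i, j)])
  ref_mre <- mean(counts$mre_totals[c(i, j)])
  ma <- normalize_counts(counts$medip[, i], counts$medip_totals[i], ref_medip)
  mb <- normalize_counts(counts$medip[, j], counts$medip_totals[j], ref_medip)
  ua <- normalize_counts(counts$mre[, i], counts$mre_totals[i], ref_mre)
  ub <- normalize_counts(counts$mre[, j], counts$mre_totals[j], ref_mre)
  tested <- counts$cpg >= min_cpg & (ma + mb + ua + ub) >= min_coverage
  out <- counts$windows[, c("chrom", "start", "end")]
  out$p <- rep(1, nrow(out))
  out$direction <- rep("0", nrow(out))
  out$tested <- tested
  if (any(tested)) {
    res <- window_test(ma[tested], ua[tested], mb[tested], ub[tested])
    out$p[tested] <- res$p
    out$direction[tested] <- res$direction
  }
  attr(out, "comparison_id") <- paste0(counts$libraries$library_id[i], "_vs_",
                                       counts$libraries$library_id[j])
  attr(out, "libraries") <- counts$libraries$library_id[c(i, j)]
  class(out) <- c("pairwise_result", "data.frame")
  out
}

#' Run all between-group pairwise window tests
#'
#' Applies [window_test()] to every (group A library, group B library) pair
#' (`pairing = "all_pairs"`; 4 comparisons for 2 x 2 libraries) or to
#' replicate-matched pairs only (`pairing = "disjoint_pairs"`; replicate 1
#' vs replicate 1, replicate 2 vs replicate 2, ...). For each pair, counts
#' are normalized to the arithmetic mean of the two libraries' totals,
#' separately for MeDIP and MRE. Windows with fewer than `min_cpg` CpG
#' sites or a combined normalized count below `min_coverage` are left
#' untested and carry p = 1 and direction "0" so window indexing stays
#' aligned across comparisons.
#'
#' @param counts a [window_counts()] object.
#' @param group_a,group_b diet/condition labels matched against the
#'   manifest's `diet` column; defaults to the first two labels in manifest
#'   order.
#' @param min_coverage minimum combined normalized count (default 4).
#' @param min_cpg minimum CpG sites per window (default 1).
#' @param pairing `"all_pairs"` or `"disjoint_pairs"`.
#' @return list of `pairwise_result` data frames, each with attribute
#'   `comparison_id`.
#' @export
run_pairwise <- function(counts, group_a = NULL, group_b = NULL,
                         min_coverage = 4, min_cpg = 1,
                         pairing = c("all_pairs", "disjoint_pairs")) {
  pairing <- match.arg(pairing)
  groups <- unique(counts$libraries$diet)
  if (is.null(group_a)) group_a <- groups[1]
  if (is.null(group_b)) group_b <- groups[2]
  ia <- which(counts$libraries$diet == group_a)
  ib <- which(counts$libraries$diet == group_b)
  if (length(ia) == 0L || length(ib) == 0L) {
    stop("each group needs at least one library", call. = FALSE)
  }
  if (pairing == "all_pairs") {
    pairs <- expand.grid(i = ia, j = ib)
  } else {
    ra <- counts$libraries$replicate[ia]
    rb <- counts$libraries$replicate[ib]
    common <- intersect(ra, rb)
    if (length(common) == 0L) {
      stop("disjoint_pairs pairing needs matching replicate labels", call. = FALSE)
    }
    pairs <- data.frame(i = ia[match(common, ra)], j = ib[match(common, rb)])
  }
  lapply(seq_len(nrow(pairs)), function(k) {
    .pairwise_one(counts, pairs$i[k], pairs$j[k], min_coverage, min_cpg)
  })
}

#' Replicate-vs-replicate comparisons within one group
#'
#' Applies the same per-window test to every pair of replicate libraries
#' within a single group. These comparisons capture technical and biological
#' noise; counting significant windows on the result (via
#' [combine_windows()] / [call_dmrs()] or directly on the p-values) gives
#' the replicate-noise baseline to hold between-group DMR counts against.
#'
#' @inheritParams run_pairwise
#' @param group diet/condition label with at least two libraries.
#' @return list of `pairwise_result` data frames (one per replicate pair).
#' @export
run_qc_within_group <- function(counts, group, min_coverage = 4, min_cpg = 1) {
  idx <- which(counts$libraries$diet == group)
  if (length(idx) < 2L) {
    stop("group '", group, "' has fewer than 2 libraries", call. = FALSE)
  }
  pairs <- combn(idx, 2)
  lapply(seq_len(ncol(pairs)), function(k) {
    .pairwise_one(counts, pairs[1, k], pairs[2, k], min_coverage, min_cpg)
  })
}

#' @rdname write_results_table
#' @param result a `pairwise_result` data frame.
#' @export
write_pairwise_table <- function(result, path) {
  write_results_table(as.data.frame(result), path)
}
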