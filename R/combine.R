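#' Fisher's combined probability test
#'
#' Combines k p-values with Fisher's method: `X2 = -2 * sum(log(p_i))` is
#' referred to a chi-square distribution with `2k` degrees of freedom and
#' the upper-tail probability is returned. p-values of exactly zero
#' (possible from numerical underflow upstream) are clamped to the smallest
#' positive double so X2 stays finite; the number clamped is reported.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`, length >= 1.
#' @return list with `X2`, `df` (= 2k), `p_combined`, `n_clamped`.
#' @examples
#' fisher_combine(c(0.05, 0.05))  # X2 ~ 11.98, df 4, p ~ 0.0175
#' fisher_combine(0.2)            # k = 1 identity: p_combined = 0.2
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) == 0L) stop("no p-values to combine", call. = FALSE)
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  zero <- p_values == 0
  p_values[zero] <- .Machine$double.xmin
  X2 <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(X2 = X2, df = df,
       p_combined = pchisq(X2, df = df, lower.tail = FALSE),
       n_clamped = sum(zero))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Computes BH q-values `q_(i) = min_{j >= i} p_(j) * m / j` (capped at 1)
#' mapped back to input order. `m` defaults to `length(p_values)` but may be
#' larger when the supplied p-values are a subset of a bigger family (it can
#' never be smaller).
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param m total number of tests in the family (default `length(p_values)`).
#' @return numeric vector of q-values in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p_values, m = length(p_values)) {
  n <- length(p_values)
  if (n == 0L) return(numeric(0))
  if (m < n) stop("m must be at least length(p_values)", call. = FALSE)
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  o <- order(p_values)
  q <- pmin(1, rev(cummin(rev(p_values[o] * m / seq_len(n)))))
  q[order(o)]
}

#' Combine pairwise comparisons per window
#'
#' Applies [fisher_combine()] window-by-window across a list of
#' [run_pairwise()] results, then BH-adjusts the combined p-values. A window
#' counts as tested only if it was tested in every comparison; untested
#' windows keep their propagated p = 1 values in the Fisher statistic but
#' receive `q = NA` and are excluded from the BH family size m. The combined
#' direction is the unanimous per-comparison sign (`"+"`, `"-"`, or `"0"`),
#' and `"mixed"` otherwise.
#'
#' @param pairwise list of `pairwise_result` frames over identical windows.
#' @return a `combined_windows` data frame with columns `chrom`, `start`,
#'   `end`, `k`, `X2`, `df`, `p_combined`, `q`, `direction`, `tested`.
#' @export
combine_windows <- function(pairwise) {
  if (length(pairwise) == 0L) stop("no comparisons to combine", call. = FALSE)
  n <- nrow(pairwise[[1]])
  for (r in pairwise) {
    if (nrow(r) != n || !identical(r$start, pairwise[[1]]$start)) {
      stop("pairwise results cover different windows", call. = FALSE)
    }
  }
  k <- length(pairwise)
  P <- vapply(pairwise, function(r) pmax(r$p, .Machine$double.xmin), numeric(n))
  dim(P) <- c(n, k)
  X2 <- -2 * rowSums(log(P))
  df <- 2L * k
  p_comb <- pchisq(X2, df = df, lower.tail = FALSE)
  tested <- Reduce(`&`, lapply(pairwise, `[[`, "tested"))
  dirs <- vapply(pairwise, function(r) r$direction, character(n))
  dim(dirs) <- c(n, k)
  direction <- apply(dirs, 1L, function(d) {
    u <- unique(d)
    if (length(u) == 1L) u else "mixed"
  })
  q <- rep(NA_real_, n)
  q[tested] <- bh_adjust(p_comb[tested], m = sum(tested))
  out <- pairwise[[1]][, c("chrom", "start", "end")]
  out$k <- k
  out$X2 <- X2
  out$df <- df
  out$p_combined <- p_comb
  out$q <- q
  out$direction <- direction
  out$tested <- tested
  attr(out, "comparisons") <- vapply(pairwise, attr, "", "comparison_id")
  class(out) <- c("combined_windows", "data.frame")
  out
}

#' Call DMRs at a q-value cutoff
#'
#' Returns the windows whose BH q-value is strictly below the cutoff
#' (untested windows, with `q = NA`, are never called).
#'
#' @param combined result of [combine_windows()].
#' @param q_cutoff q-value cutoff; the study's cutoffs are 0.05 and 0.01.
#' @return a `dmr_set` data frame with columns `chrom`, `start`, `end`,
#'   `q_value`, `direction`, `threshold`.
#' @export
call_dmrs <- function(combined, q_cutoff = 0.05) {
  .assert_scalar_number(q_cutoff, "q_cutoff", min = 0)
  keep <- !is.na(combined$q) & combined$q < q_cutoff
  out <- combined[keep, c("chrom", "start", "end")]
  out$q_value <- combined$q[keep]
  out$direction <- combined$direction[keep]
  out$threshold <- rep(q_cutoff, nrow(out))
  rownames(out) <- NULL
  class(out) <- c("dmr_set", "data.frame")
  out
}

#' Write DMR calls as BED6
#'
#' name = q-value, score = `-10 * log10(q)` capped at 1000, strand `"."`.
#'
#' @param dmrs a `dmr_set` from [call_dmrs()].
#' @param path output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  df <- data.frame(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
                   name = signif(dmrs$q_value, 6),
                   score = round(pmin(1000, -10 * log10(pmax(dmrs$q_value,
                                                             1e-100)))),
                   strand = ".", stringsAsFactors = FALSE)
  write_bed(df, path)
}
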