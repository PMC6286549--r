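# Independent oracles and toy-data generators used across the suite. Each
# oracle is written from the definition of the quantity, not from the
# package's code path, so agreement is an actual check.

# Benjamini-Hochberg step-up by direct enumeration of the definition:
# q_(i) = min over j >= i of p_(j) * m / j, capped at 1, in input order.
oracle_bh <- function(p, m = length(p)) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    q_sorted[i] <- min(1, min(p[o][i:n] * m / (i:n)))
  }
  q_sorted[order(o)]
}

# Quadratic nearest-gene scan with the stated tie-breaks (distance, then
# tx_start, then gene_id). Distance between half-open intervals is the gap.
oracle_nearest <- function(chrom, start, end, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0L) {
    return(list(gene_id = NA_character_, distance = NA_real_, within = FALSE))
  }
  dist <- numeric(nrow(g))
  within <- logical(nrow(g))
  for (i in seq_len(nrow(g))) {
    if (end > g$tx_start[i] && start < g$tx_end[i]) {
      dist[i] <- 0
      within[i] <- TRUE
    } else if (end <= g$tx_start[i]) {
      dist[i] <- g$tx_start[i] - end
    } else {
      dist[i] <- start - g$tx_end[i]
    }
  }
  o <- order(dist, g$tx_start, g$gene_id)[1]
  list(gene_id = g$gene_id[o], distance = dist[o], within = within[o])
}

# Brute-force four-way category for one window: loop every exon, gene body
# and promoter interval with half-open overlap.
oracle_classify <- function(chrom, start, end, genes, promoters) {
  ov <- function(s1, e1, s2, e2) e1 > s2 && s1 < e2
  in_exon <- FALSE
  in_body <- FALSE
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != chrom) next
    if (ov(start, end, genes$tx_start[i], genes$tx_end[i])) in_body <- TRUE
    es <- genes$exon_starts[[i]]
    ee <- genes$exon_ends[[i]]
    for (k in seq_along(es)) {
      if (ov(start, end, es[k], ee[k])) in_exon <- TRUE
    }
  }
  in_prom <- FALSE
  for (i in seq_len(nrow(promoters))) {
    if (promoters$chrom[i] != chrom) next
    if (ov(start, end, promoters$start[i], promoters$end[i])) in_prom <- TRUE
  }
  category <- if (in_exon) "exon" else if (in_body) "intron" else
    if (in_prom) "promoter" else "intergenic"
  list(category = category, promoter_flag = in_prom)
}

# Brute-force per-class regulatory overlap for one window.
oracle_regulatory <- function(chrom, start, end, features) {
  out <- stats::setNames(logical(4), regulatory_classes())
  for (i in seq_len(nrow(features))) {
    if (features$chrom[i] != chrom) next
    if (end > features$start[i] && start < features$end[i]) {
      out[[features$feature_class[i]]] <- TRUE
    }
  }
  out
}

# Random toy gene set on a single chromosome of the given length.
random_toy_genes <- function(n, chrom_len, chrom = "chrT") {
  tx_start <- sort(sample.int(chrom_len - 200, n))
  tx_end <- pmin(tx_start + sample(50:2000, n, replace = TRUE), chrom_len)
  exon_starts <- vector("list", n)
  exon_ends <- vector("list", n)
  for (i in seq_len(n)) {
    L <- tx_end[i] - tx_start[i]
    k <- sample(1:3, 1)
    k <- max(1L, min(k, floor((L - 1) / 2)))
    if (k == 1L) {
      exon_starts[[i]] <- tx_start[i]
      exon_ends[[i]] <- tx_end[i]
    } else {
      br <- tx_start[i] + sort(sample.int(L - 1, 2 * k - 2))
      edges <- c(tx_start[i], br, tx_end[i])
      exon_starts[[i]] <- edges[seq(1, 2 * k - 1, by = 2)]
      exon_ends[[i]] <- edges[seq(2, 2 * k, by = 2)]
    }
  }
  gene_models(sprintf("g%03d", seq_len(n)), rep(chrom, n),
              sample(c("+", "-"), n, replace = TRUE),
              tx_start, tx_end, exon_starts, exon_ends)
}

random_toy_features <- function(n, chrom_len, chrom = "chrT") {
  start <- sample.int(chrom_len - 100, n, replace = TRUE)
  regulatory_features(rep(chrom, n), start,
                      start + sample(20:800, n, replace = TRUE),
                      sample(regulatory_classes(), n, replace = TRUE))
}

# Minimal window_counts object built directly from matrices.
toy_counts <- function(medip, mre, cpg = NULL, diet = NULL,
                       window_size = 500) {
  medip <- as.matrix(medip)
  mre <- as.matrix(mre)
  n <- nrow(medip)
  J <- ncol(medip)
  if (is.null(cpg)) cpg <- rep(5, n)
  if (is.null(diet)) diet <- rep(c("HF", "LF"), each = ceiling(J / 2))[1:J]
  windows <- data.frame(chrom = "chrT",
                        start = (seq_len(n) - 1) * window_size,
                        end = seq_len(n) * window_size,
                        index = seq_len(n) - 1L)
  manifest <- data.frame(library_id = sprintf("L%d", seq_len(J)),
                         sex = "F", diet = diet,
                         replicate = stats::ave(seq_len(J), diet,
                                                FUN = seq_along))
  window_counts(windows, cpg, manifest, medip, mre)
}
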