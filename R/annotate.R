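# DMR annotation against gene models and regulatory features. Interval
# queries go through GenomicRanges/IRanges; all package-facing coordinates
# stay 0-based half-open and are shifted to 1-based closed only at the
# GRanges boundary.

.as_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1, end = end))
}

.exon_frame <- function(genes) {
  n <- vapply(genes$exon_starts, length, 1L)
  data.frame(chrom = rep(genes$chrom, n),
             start = unlist(genes$exon_starts),
             end = unlist(genes$exon_ends),
             gene_id = rep(genes$gene_id, n),
             stringsAsFactors = FALSE)
}

#' Promoter interval of a gene
#'
#' The promoter is the strand-aware region from 2000 bp upstream of the
#' transcription start site to 600 bp downstream of it: `[tx_start - 2000,
#' tx_start + 600)` on the + strand and `[tx_end - 600, tx_end + 2000)` on
#' the - strand, clipped to the chromosome.
#'
#' @param genes a [gene_models()] frame.
#' @param upstream bp upstream of the TSS (default 2000).
#' @param downstream bp downstream of the TSS (default 600).
#' @param assembly optional [genome_assembly()] used to clip at chromosome
#'   ends (clipping at 0 always happens).
#' @return data frame with `gene_id`, `chrom`, `start`, `end`.
#' @examples
#' g <- gene_models("g1", "chr1", "+", 10000, 20000, list(10000), list(20000))
#' promoter_intervals(g)  # [8000, 10600)
#' @export
promoter_intervals <- function(genes, upstream = 2000, downstream = 600,
                               assembly = NULL) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tx_start - upstream, genes$tx_end - downstream)
  end <- ifelse(plus, genes$tx_start + downstream, genes$tx_end + upstream)
  start <- pmax(start, 0)
  if (!is.null(assembly)) {
    len <- assembly$length[match(genes$chrom, assembly$chrom)]
    end <- pmin(end, len)
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Nearest gene to each region
#'
#' Distance is 0 when the region overlaps a gene body (its outermost
#' transcription bounds); otherwise it is the gap in bp to the nearer gene
#' edge. Ties are broken by smaller `tx_start`, then lexicographic
#' `gene_id`. Genes on other chromosomes are never matched; regions on a
#' chromosome without genes get `NA` and `no_gene = TRUE`.
#'
#' @param regions data frame with `chrom`, `start`, `end` (half-open).
#' @param genes a [gene_models()] frame.
#' @return data frame with `gene_id`, `distance_bp`, `within_gene`,
#'   `no_gene`, one row per region.
#' @export
nearest_gene <- function(regions, genes) {
  if (nrow(genes) == 0L) stop("no genes supplied", call. = FALSE)
  n <- nrow(regions)
  out <- data.frame(gene_id = rep(NA_character_, n),
                    distance_bp = rep(NA_real_, n),
                    within_gene = rep(FALSE, n),
                    no_gene = rep(TRUE, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (length(gi) == 0L) next
    # gap distance between half-open intervals; 0 on overlap or adjacency
    d_up <- outer(-regions$end[ri], genes$tx_start[gi], `+`)   # gene downstream
    d_dn <- outer(regions$start[ri], -genes$tx_end[gi], `+`)   # gene upstream
    D <- pmax(d_up, d_dn, 0)
    for (r in seq_along(ri)) {
      best <- order(D[r, ], genes$tx_start[gi], genes$gene_id[gi])[1]
      out$gene_id[ri[r]] <- genes$gene_id[gi[best]]
      out$distance_bp[ri[r]] <- D[r, best]
      out$no_gene[ri[r]] <- FALSE
      out$within_gene[ri[r]] <- d_up[r, best] < 0 && d_dn[r, best] < 0
    }
  }
  out
}

#' Annotate regions against gene models and regulatory features
#'
#' For each region (typically a DMR window) this computes:
#' * `category`: exactly one of `exon`, `intron`, `promoter`, `intergenic`.
#'   A region overlapping any exon is an exon (the exon-over-intron rule);
#'   otherwise overlapping any gene body is an intron; otherwise overlapping
#'   a promoter interval is a promoter; otherwise intergenic.
#' * `promoter_flag`: TRUE whenever the region overlaps any promoter
#'   interval, regardless of category, so promoter and exon membership can
#'   co-occur in summaries.
#' * one logical column per regulatory class (any-overlap, >= 1 bp,
#'   half-open semantics).
#' * nearest gene, distance and `within_gene` (see [nearest_gene()]).
#' * `in_de_gene`: region overlaps the gene body of a differentially
#'   expressed gene (`q < 0.05` in `de_table`), when a DE table is given.
#' * `disease_gene`: nearest gene is on the supplied disease-gene list.
#'
#' @param regions data frame with `chrom`, `start`, `end`.
#' @param genes a [gene_models()] frame.
#' @param regulatory a [regulatory_features()] frame (may have 0 rows).
#' @param de_table optional DE table (`gene_id`, `log2fc`, `p`, `q`).
#' @param disease_genes optional character vector of gene ids.
#' @param upstream,downstream promoter extent, see [promoter_intervals()].
#' @param assembly optional assembly for promoter clipping.
#' @return an `annotated_regions` data frame.
#' @export
annotate_dmrs <- function(regions, genes, regulatory,
                          de_table = NULL, disease_genes = NULL,
                          upstream = 2000, downstream = 600,
                          assembly = NULL) {
  n <- nrow(regions)
  q <- .as_granges(regions$chrom, regions$start, regions$end)
  exons <- .exon_frame(genes)
  in_exon <- GenomicRanges::countOverlaps(
    q, .as_granges(exons$chrom, exons$start, exons$end)) > 0
  in_body <- GenomicRanges::countOverlaps(
    q, .as_granges(genes$chrom, genes$tx_start, genes$tx_end)) > 0
  prom <- promoter_intervals(genes, upstream, downstream, assembly)
  in_prom <- GenomicRanges::countOverlaps(
    q, .as_granges(prom$chrom, prom$start, prom$end)) > 0
  category <- ifelse(in_exon, "exon",
                     ifelse(in_body, "intron",
                            ifelse(in_prom, "promoter", "intergenic")))
  out <- data.frame(regions[, c("chrom", "start", "end")],
                    category = category, promoter_flag = in_prom,
                    stringsAsFactors = FALSE)
  for (cl in regulatory_classes()) {
    f <- regulatory[regulatory$feature_class == cl, , drop = FALSE]
    out[[cl]] <- if (nrow(f)) {
      GenomicRanges::countOverlaps(q, .as_granges(f$chrom, f$start, f$end)) > 0
    } else rep(FALSE, n)
  }
  ng <- nearest_gene(regions, genes)
  out$nearest_gene <- ng$gene_id
  out$distance_bp <- ng$distance_bp
  out$within_gene <- ng$within_gene
  if (!is.null(de_table)) {
    de_genes <- de_table$gene_id[de_table$q < 0.05]
    db <- genes[genes$gene_id %in% de_genes, , drop = FALSE]
    out$in_de_gene <- if (nrow(db)) {
      GenomicRanges::countOverlaps(
        q, .as_granges(db$chrom, db$tx_start, db$tx_end)) > 0
    } else rep(FALSE, n)
  } else {
    out$in_de_gene <- NA
  }
  out$disease_gene <- if (!is.null(disease_genes)) {
    !is.na(ng$gene_id) & ng$gene_id %in% disease_genes
  } else NA
  class(out) <- c("annotated_regions", "data.frame")
  out
}

#' Summarize annotated regions, Table-1 style
#'
#' Counts, per region class, how many annotated regions overlap it, with
#' the percentage of the total (100 * count / total, rounded half up to one
#' decimal). Classes are the four regulatory classes (any overlap), the
#' promoter flag, and the exon/intron/intergenic categories; the regulatory
#' and promoter classes are not mutually exclusive with the categories. An
#' optional second annotated set (typically all genome windows) supplies
#' the background percentage column.
#'
#' @param annotated an `annotated_regions` frame from [annotate_dmrs()].
#' @param background optional `annotated_regions` frame for the whole
#'   genome (or any reference set).
#' @return data frame with `region`, `count`, `percent` and, when a
#'   background is given, `background_percent`. With zero regions the
#'   percentages are `NA`.
#' @export
summarize_annotation <- function(annotated, background = NULL) {
  count_classes <- function(a) {
    c(enhancer = sum(a$enhancer),
      ctcf_binding_site = sum(a$ctcf_binding_site),
      tf_binding_site = sum(a$tf_binding_site),
      promoter_flanking = sum(a$promoter_flanking),
      promoter = sum(a$promoter_flag),
      exon = sum(a$category == "exon"),
      intron = sum(a$category == "intron"),
      intergenic = sum(a$category == "intergenic"))
  }
  counts <- count_classes(annotated)
  total <- nrow(annotated)
  pct <- if (total > 0) round_half_up(100 * counts / total, 1) else
    rep(NA_real_, length(counts))
  out <- data.frame(region = names(counts), count = as.integer(counts),
                    percent = as.numeric(pct), stringsAsFactors = FALSE)
  if (!is.null(background)) {
    bc <- count_classes(background)
    bt <- nrow(background)
    out$background_percent <- if (bt > 0) {
      as.numeric(round_half_up(100 * bc / bt, 1))
    } else NA_real_
  }
  attr(out, "total") <- total
  rownames(out) <- NULL
  out
}
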