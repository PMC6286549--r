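#' Genome assembly: ordered chromosomes and their lengths
#'
#' A minimal assembly description: an ordered set of chromosome names and
#' lengths in base pairs. Chromosome order is preserved everywhere downstream
#' (window indices are assigned in this order).
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in bp (>= 1).
#' @return a `genome_assembly` data frame with columns `chrom`, `length`.
#' @examples
#' genome_assembly(c("chr1", "chr2"), c(1000, 250))
#' @export
genome_assembly <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) stop("assembly has no chromosomes", call. = FALSE)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique", call. = FALSE)
  if (any(is.na(length)) || any(length < 1)) {
    stop("chromosome lengths must be >= 1", call. = FALSE)
  }
  out <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  class(out) <- c("genome_assembly", "data.frame")
  out
}

#' Tile a genome into fixed-size windows
#'
#' Partitions every chromosome into adjacent, non-overlapping half-open
#' windows of at most `window_size` bp. The final window of each chromosome
#' is truncated at the chromosome end (never dropped), so the windows form an
#' exact partition of the genome. Coordinates are 0-based half-open
#' throughout (BED convention).
#'
#' @param assembly a [genome_assembly()].
#' @param window_size window width in bp (default 500).
#' @return a `genome_windows` data frame with columns `chrom`, `start`,
#'   `end`, and a 0-based genome-wide `index` contiguous in assembly order.
#' @examples
#' tile_genome(genome_assembly("chrT", 1234))
#' @export
tile_genome <- function(assembly, window_size = 500) {
  if (!inherits(assembly, "genome_assembly")) {
    assembly <- genome_assembly(assembly$chrom, assembly$length)
  }
  .assert_scalar_number(window_size, "window_size", min = 1)
  if (nrow(assembly) == 0L) stop("assembly has no chromosomes", call. = FALSE)
  parts <- lapply(seq_len(nrow(assembly)), function(i) {
    len <- assembly$length[i]
    starts <- seq.int(0, len - 1, by = window_size)
    data.frame(chrom = assembly$chrom[i],
               start = starts,
               end = pmin(starts + window_size, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out$index <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  class(out) <- c("genome_windows", "data.frame")
  out
}

#' CpG site map
#'
#' Positions of CpG sites (the position of the C on the forward strand),
#' 0-based, sorted strictly increasing within each chromosome.
#'
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 0-based positions.
#' @param assembly optional [genome_assembly()]; if given, positions are
#'   validated against chromosome lengths and names.
#' @return a `cpg_map` data frame with columns `chrom`, `pos`, sorted by
#'   chromosome (assembly order when given, first-appearance order otherwise)
#'   then position.
#' @export
cpg_map <- function(chrom, pos, assembly = NULL) {
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  if (length(chrom) != length(pos)) stop("chrom and pos differ in length", call. = FALSE)
  if (any(is.na(pos)) || any(pos < 0)) stop("CpG positions must be >= 0", call. = FALSE)
  chrom_levels <- unique(chrom)
  if (!is.null(assembly)) {
    unknown <- setdiff(chrom, assembly$chrom)
    if (length(unknown)) {
      stop("CpG site on unknown chromosome: ", unknown[1], call. = FALSE)
    }
    len <- assembly$length[match(chrom, assembly$chrom)]
    if (any(pos >= len)) {
      bad <- which(pos >= len)[1]
      stop(sprintf("CpG position %d exceeds length of %s", pos[bad], chrom[bad]),
           call. = FALSE)
    }
    chrom_levels <- assembly$chrom
  }
  ord <- order(match(chrom, chrom_levels), pos)
  out <- data.frame(chrom = chrom[ord], pos = pos[ord], stringsAsFactors = FALSE)
  dup <- duplicated(out)
  if (any(dup)) out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cpg_map", "data.frame")
  out
}

#' Count CpG sites per window
#'
#' Assigns each CpG site to the unique window with `start <= pos < end` and
#' returns per-window counts. The counts sum to the total number of sites.
#'
#' @param windows windows from [tile_genome()].
#' @param cpgs a [cpg_map()] (or data frame with `chrom`, `pos`).
#' @return integer vector of counts, one per window row.
#' @export
count_cpgs_per_window <- function(windows, cpgs) {
  counts <- integer(nrow(windows))
  if (nrow(cpgs) == 0L) return(counts)
  unknown <- setdiff(unique(cpgs$chrom), unique(windows$chrom))
  if (length(unknown)) {
    stop("CpG site on unknown chromosome: ", unknown[1], call. = FALSE)
  }
  for (ch in unique(cpgs$chrom)) {
    wi <- which(windows$chrom == ch)
    pos <- cpgs$pos[cpgs$chrom == ch]
    if (any(pos >= windows$end[wi[length(wi)]])) {
      stop(sprintf("CpG position exceeds tiled length of %s", ch), call. = FALSE)
    }
    # windows are adjacent and sorted, so interval lookup on starts suffices
    hit <- findInterval(pos, windows$start[wi])
    tab <- tabulate(hit, nbins = length(wi))
    counts[wi] <- counts[wi] + tab
  }
  counts
}

#' Gene models with exon structure
#'
#' Stranded gene bodies spanning the outermost transcription bounds, with
#' sorted non-overlapping exons. All coordinates 0-based half-open.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @param tx_start,tx_end outermost transcription bounds, half-open.
#' @param exon_starts,exon_ends lists of integer vectors, one per gene;
#'   exons must be sorted, non-overlapping and within `[tx_start, tx_end)`.
#' @return a `gene_models` data frame with list columns `exon_starts`,
#'   `exon_ends`.
#' @export
gene_models <- function(gene_id, chrom, strand, tx_start, tx_end,
                        exon_starts, exon_ends) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique", call. = FALSE)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
  if (any(tx_end <= tx_start)) stop("tx_end must exceed tx_start", call. = FALSE)
  exon_starts <- lapply(exon_starts, as.numeric)
  exon_ends <- lapply(exon_ends, as.numeric)
  for (i in seq_along(gene_id)) {
    es <- exon_starts[[i]]; ee <- exon_ends[[i]]
    if (length(es) != length(ee) || length(es) == 0L) {
      stop("gene ", gene_id[i], ": exon start/end lists malformed", call. = FALSE)
    }
    if (any(ee <= es)) stop("gene ", gene_id[i], ": empty exon", call. = FALSE)
    if (is.unsorted(es, strictly = TRUE) || any(es[-1] < ee[-length(ee)])) {
      stop("gene ", gene_id[i], ": exons must be sorted and non-overlapping",
           call. = FALSE)
    }
    if (es[1] < tx_start[i] || ee[length(ee)] > tx_end[i]) {
      stop("gene ", gene_id[i], ": exons outside transcription bounds",
           call. = FALSE)
    }
  }
  out <- data.frame(gene_id = gene_id, chrom = as.character(chrom),
                    strand = as.character(strand),
                    tx_start = as.numeric(tx_start), tx_end = as.numeric(tx_end),
                    stringsAsFactors = FALSE)
  out$exon_starts <- exon_starts
  out$exon_ends <- exon_ends
  class(out) <- c("gene_models", "data.frame")
  out
}

#' @rdname regulatory_features
#' @export
regulatory_classes <- function() {
  c("enhancer", "ctcf_binding_site", "tf_binding_site", "promoter_flanking")
}

#' Regulatory features
#'
#' Classed regulatory intervals (Ensembl regulatory-build style): enhancers,
#' CTCF binding sites, TF binding sites and promoter flanking regions.
#' Coordinates 0-based half-open.
#'
#' @param chrom,start,end interval coordinates.
#' @param feature_class one of `regulatory_classes()` per interval.
#' @return a `regulatory_features` data frame.
#' @export
regulatory_features <- function(chrom, start, end, feature_class) {
  feature_class <- as.character(feature_class)
  bad <- setdiff(unique(feature_class), regulatory_classes())
  if (length(bad)) {
    stop("unknown regulatory feature class: ", bad[1], call. = FALSE)
  }
  if (any(end <= start)) stop("regulatory feature with end <= start", call. = FALSE)
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end), feature_class = feature_class,
                    stringsAsFactors = FALSE)
  class(out) <- c("regulatory_features", "data.frame")
  out
}
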