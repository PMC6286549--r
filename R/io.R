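# Readers and writers for the plain-text formats the pipeline exchanges:
# chrom.sizes, BED3/BED4, refFlat-style gene tables, window count tables,
# library manifests, DE tables and generic results tables. All coordinates
# on disk are 0-based half-open (BED convention); readers validate eagerly
# and report the offending line.

.read_tokenized <- function(path, n_min, what) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(toks, length, 1L) < n_min)
  if (length(bad)) {
    stop(sprintf("%s: malformed %s line %d (expected >= %d fields)",
                 path, what, bad[1], n_min), call. = FALSE)
  }
  toks
}

.num_field <- function(toks, k, path, what) {
  x <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", k)))
  if (anyNA(x)) {
    stop(sprintf("%s: non-numeric field %d on %s line %d", path, k, what,
                 which(is.na(x))[1]), call. = FALSE)
  }
  x
}

#' Read a two-column chrom.sizes file
#'
#' @param path TSV with columns (chromosome name, length), no header.
#' @return a [genome_assembly()].
#' @export
read_chrom_sizes <- function(path) {
  toks <- .read_tokenized(path, 2L, "chrom.sizes")
  genome_assembly(vapply(toks, `[[`, "", 1L),
                  .num_field(toks, 2L, path, "chrom.sizes"))
}

#' @rdname read_chrom_sizes
#' @param assembly a [genome_assembly()] to write.
#' @export
write_chrom_sizes <- function(assembly, path) {
  write.table(assembly[, c("chrom", "length")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED4 file
#'
#' Intervals are 0-based half-open. With `assembly` given, coordinates are
#' validated against chromosome names and lengths.
#'
#' @param path BED file (no header).
#' @param assembly optional [genome_assembly()] for validation.
#' @return data frame with `chrom`, `start`, `end` and, when present, `name`.
#' @export
read_bed <- function(path, assembly = NULL) {
  toks <- .read_tokenized(path, 3L, "BED")
  out <- data.frame(chrom = vapply(toks, `[[`, "", 1L),
                    start = .num_field(toks, 2L, path, "BED"),
                    end = .num_field(toks, 3L, path, "BED"),
                    stringsAsFactors = FALSE)
  if (all(vapply(toks, length, 1L) >= 4L)) {
    out$name <- vapply(toks, `[[`, "", 4L)
  }
  bad <- which(out$end <= out$start)
  if (length(bad)) {
    stop(sprintf("%s: end <= start on BED line %d", path, bad[1]), call. = FALSE)
  }
  if (!is.null(assembly)) .validate_coords(out, assembly, path, "BED")
  out
}

.validate_coords <- function(df, assembly, path, what) {
  unknown <- setdiff(unique(df$chrom), assembly$chrom)
  if (length(unknown)) {
    stop(sprintf("%s: unknown chromosome '%s' in %s", path, unknown[1], what),
         call. = FALSE)
  }
  len <- assembly$length[match(df$chrom, assembly$chrom)]
  bad <- which(df$end > len)
  if (length(bad)) {
    stop(sprintf("%s: coordinate past end of %s on %s line %d",
                 path, df$chrom[bad[1]], what, bad[1]), call. = FALSE)
  }
  invisible(df)
}

#' @rdname read_bed
#' @param intervals data frame with `chrom`, `start`, `end` and optional
#'   further columns written as BED fields 4+.
#' @export
write_bed <- function(intervals, path) {
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  df <- as.data.frame(intervals)[, keep, drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read classed regulatory features from BED4
#'
#' Column 4 must hold one of `regulatory_classes()`.
#'
#' @inheritParams read_bed
#' @return a [regulatory_features()] frame.
#' @export
read_regulatory_bed <- function(path, assembly = NULL) {
  df <- read_bed(path, assembly)
  if (is.null(df$name)) {
    stop(path, ": regulatory BED needs a 4th column with the feature class",
         call. = FALSE)
  }
  regulatory_features(df$chrom, df$start, df$end, df$name)
}

#' @rdname read_regulatory_bed
#' @param features a [regulatory_features()] frame.
#' @export
write_regulatory_bed <- function(features, path) {
  write.table(features[, c("chrom", "start", "end", "feature_class")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a refFlat-style table or BED12
#'
#' The refFlat-style dialect has no header and columns gene_id, chrom,
#' strand, txStart, txEnd, exonCount, exonStarts, exonEnds with 0-based
#' half-open coordinates and comma-separated exon lists (trailing comma
#' tolerated). BED12 blocks are converted to exons relative to chromStart.
#'
#' @param path input file.
#' @param format `"refflat"` (default) or `"bed12"`.
#' @param assembly optional [genome_assembly()] for coordinate validation.
#' @return a [gene_models()] frame.
#' @export
read_gene_table <- function(path, format = c("refflat", "bed12"),
                            assembly = NULL) {
  format <- match.arg(format)
  if (format == "refflat") {
    toks <- .read_tokenized(path, 8L, "gene table")
    split_list <- function(k) {
      lapply(toks, function(t) as.numeric(strsplit(t[[k]], ",", fixed = TRUE)[[1]]))
    }
    genes <- gene_models(
      gene_id = vapply(toks, `[[`, "", 1L),
      chrom = vapply(toks, `[[`, "", 2L),
      strand = vapply(toks, `[[`, "", 3L),
      tx_start = .num_field(toks, 4L, path, "gene table"),
      tx_end = .num_field(toks, 5L, path, "gene table"),
      exon_starts = split_list(7L),
      exon_ends = split_list(8L))
    n_exp <- .num_field(toks, 6L, path, "gene table")
    n_got <- vapply(genes$exon_starts, length, 1L)
    if (any(n_exp != n_got)) {
      stop(sprintf("%s: exonCount mismatch on gene table line %d",
                   path, which(n_exp != n_got)[1]), call. = FALSE)
    }
  } else {
    toks <- .read_tokenized(path, 12L, "BED12")
    starts <- .num_field(toks, 2L, path, "BED12")
    sizes <- lapply(toks, function(t) as.numeric(strsplit(t[[11L]], ",")[[1]]))
    offs <- lapply(toks, function(t) as.numeric(strsplit(t[[12L]], ",")[[1]]))
    genes <- gene_models(
      gene_id = vapply(toks, `[[`, "", 4L),
      chrom = vapply(toks, `[[`, "", 1L),
      strand = vapply(toks, `[[`, "", 6L),
      tx_start = starts,
      tx_end = .num_field(toks, 3L, path, "BED12"),
      exon_starts = Map(function(s, o) s + o, starts, offs),
      exon_ends = Map(function(s, o, z) s + o + z, starts, offs, sizes))
  }
  if (!is.null(assembly)) {
    .validate_coords(data.frame(chrom = genes$chrom, start = genes$tx_start,
                                end = genes$tx_end), assembly, path, "gene table")
  }
  genes
}

#' @rdname read_gene_table
#' @param genes a [gene_models()] frame.
#' @export
write_gene_table <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    paste(genes$gene_id[i], genes$chrom[i], genes$strand[i],
          format(genes$tx_start[i], scientific = FALSE),
          format(genes$tx_end[i], scientific = FALSE),
          length(genes$exon_starts[[i]]),
          paste0(paste(format(genes$exon_starts[[i]], scientific = FALSE),
                       collapse = ","), ","),
          paste0(paste(format(genes$exon_ends[[i]], scientific = FALSE),
                       collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a window count table and library manifest
#'
#' The count table is a headered TSV with columns chrom, start, end, cpg,
#' then one `medip_<library_id>` and one `mre_<library_id>` column per
#' library. The manifest is a headered TSV with columns library_id, sex,
#' diet, replicate.
#'
#' @param counts_path,manifest_path file paths.
#' @param assembly optional [genome_assembly()] for validation.
#' @return a `window_counts` object (see [window_counts()]).
#' @export
read_counts_table <- function(counts_path, manifest_path, assembly = NULL) {
  # sex labels like "F" must not be parsed as logicals
  manifest <- read.delim(manifest_path, stringsAsFactors = FALSE,
                         colClasses = c(library_id = "character",
                                        sex = "character",
                                        diet = "character"))
  need <- c("library_id", "sex", "diet", "replicate")
  if (!all(need %in% names(manifest))) {
    stop(manifest_path, ": manifest needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  raw <- read.delim(counts_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("chrom", "start", "end", "cpg",
            paste0("medip_", manifest$library_id),
            paste0("mre_", manifest$library_id))
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop(counts_path, ": missing column ", miss[1], call. = FALSE)
  }
  to_num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(x)) {
      stop(sprintf("%s: non-numeric '%s' on counts line %d", counts_path, col,
                   which(is.na(x))[1] + 1L), call. = FALSE)
    }
    x
  }
  windows <- data.frame(chrom = raw$chrom, start = to_num("start"),
                        end = to_num("end"), stringsAsFactors = FALSE)
  if (!is.null(assembly)) .validate_coords(windows, assembly, counts_path, "counts")
  windows$index <- seq_len(nrow(windows)) - 1L
  medip <- vapply(paste0("medip_", manifest$library_id), to_num,
                  numeric(nrow(raw)))
  mre <- vapply(paste0("mre_", manifest$library_id), to_num,
                numeric(nrow(raw)))
  dim(medip) <- c(nrow(raw), nrow(manifest))
  dim(mre) <- c(nrow(raw), nrow(manifest))
  window_counts(windows, to_num("cpg"), manifest, medip, mre)
}

#' @rdname read_counts_table
#' @param counts a `window_counts` object.
#' @export
write_counts_table <- function(counts, counts_path, manifest_path) {
  df <- counts$windows[, c("chrom", "start", "end")]
  df$cpg <- counts$cpg
  for (j in seq_len(nrow(counts$libraries))) {
    df[[paste0("medip_", counts$libraries$library_id[j])]] <- counts$medip[, j]
  }
  for (j in seq_len(nrow(counts$libraries))) {
    df[[paste0("mre_", counts$libraries$library_id[j])]] <- counts$mre[, j]
  }
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(counts$libraries, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(counts_path)
}

#' Read a differential-expression table
#'
#' Headered TSV with columns gene_id, log2fc, p, q. Genes with `q < 0.05`
#' are treated as differentially expressed downstream.
#'
#' @param path file path.
#' @return data frame with those columns.
#' @export
read_de_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "p", "q")
  if (!all(need %in% names(df))) {
    stop(path, ": DE table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$q < 0 | df$q > 1, na.rm = TRUE)) {
    stop(path, ": q values outside [0,1]", call. = FALSE)
  }
  df
}

#' Write/read a generic results table (headered TSV)
#'
#' Write then read is the identity on the data frame contents (column
#' classes preserved for character/numeric/logical columns).
#'
#' @param df data frame.
#' @param path file path.
#' @export
write_results_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
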