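test_that("tiling produces truncated final windows and contiguous indices", {
  w <- tile_genome(genome_assembly("chrT", 1234))
  expect_equal(nrow(w), 3L)
  expect_equal(w$start, c(0, 500, 1000))
  expect_equal(w$end, c(500, 1000, 1234))

  w1 <- tile_genome(genome_assembly("chrT", 500))
  expect_equal(nrow(w1), 1L)
  expect_equal(c(w1$start, w1$end), c(0, 500))

  w2 <- tile_genome(genome_assembly(c("A", "B"), c(1000, 250)))
  expect_equal(nrow(w2), 3L)
  expect_equal(w2$index, 0:2)
  expect_equal(w2$chrom, c("A", "A", "B"))

  expect_error(genome_assembly(character(0), numeric(0)), "no chromosomes")
  expect_error(genome_assembly(c("a", "a"), c(10, 10)), "unique")
})

test_that("tiling partitions any assembly without gaps or overlaps", {
  set.seed(11)
  for (rep in 1:20) {
    n_chr <- sample(1:4, 1)
    lens <- sample(1:3000, n_chr)
    ws <- sample(c(1, 7, 100, 500), 1)
    asm <- genome_assembly(paste0("c", seq_len(n_chr)), lens)
    w <- tile_genome(asm, ws)
    expect_equal(sum(w$end - w$start), sum(lens))
    expect_true(all(w$end - w$start >= 1))
    expect_true(all(w$end - w$start <= ws))
    for (ch in asm$chrom) {
      wc <- w[w$chrom == ch, ]
      expect_equal(wc$start, c(0, head(wc$end, -1)))  # adjacency, no overlap
      expect_equal(tail(wc$end, 1), lens[match(ch, asm$chrom)])
      expect_equal(nrow(wc), ceiling(lens[match(ch, asm$chrom)] / ws))
    }
  }
})

test_that("CpG counting uses half-open windows and conserves the total", {
  w <- tile_genome(genome_assembly("chrT", 1500))
  cm <- cpg_map(rep("chrT", 3), c(10, 499, 500))
  expect_equal(count_cpgs_per_window(w, cm), c(2, 1, 0))

  empty <- cpg_map(character(0), numeric(0))
  expect_equal(count_cpgs_per_window(w, empty), c(0, 0, 0))

  set.seed(5)
  asm <- genome_assembly(c("A", "B"), c(4321, 999))
  wins <- tile_genome(asm, 500)
  chrom <- sample(c("A", "B"), 1000, replace = TRUE, prob = c(0.8, 0.2))
  pos <- floor(runif(1000, 0, asm$length[match(chrom, asm$chrom)]))
  cm2 <- cpg_map(chrom, pos, asm)
  counts <- count_cpgs_per_window(wins, cm2)
  expect_equal(sum(counts), nrow(cm2))
  # direct recount of one window
  i <- which.max(counts)
  expect_equal(counts[i], sum(cm2$chrom == wins$chrom[i] &
                                cm2$pos >= wins$start[i] &
                                cm2$pos < wins$end[i]))

  expect_error(count_cpgs_per_window(w, cpg_map("chrZ", 5)), "chrZ")
  expect_error(cpg_map("chrT", 2000, genome_assembly("chrT", 1500)),
               "exceeds length")
})

test_that("readers and writers round-trip the in-memory model", {
  tmp <- withr::local_tempdir()
  asm <- genome_assembly(c("chr1", "chr2"), c(10000, 5000))
  write_chrom_sizes(asm, file.path(tmp, "c.sizes"))
  expect_equal(read_chrom_sizes(file.path(tmp, "c.sizes")), asm)

  bed <- data.frame(chrom = c("chr1", "chr2"), start = c(0, 100),
                    end = c(500, 900), stringsAsFactors = FALSE)
  write_bed(bed, file.path(tmp, "a.bed"))
  expect_equal(read_bed(file.path(tmp, "a.bed")), bed)

  feats <- regulatory_features(c("chr1", "chr1"), c(10, 600), c(200, 900),
                               c("enhancer", "ctcf_binding_site"))
  write_regulatory_bed(feats, file.path(tmp, "r.bed"))
  expect_equal(read_regulatory_bed(file.path(tmp, "r.bed"), asm), feats)

  genes <- gene_models(c("gA", "gB"), c("chr1", "chr2"), c("+", "-"),
                       c(100, 1000), c(2100, 4000),
                       list(c(100, 1500), 1000), list(c(600, 2100), 4000))
  write_gene_table(genes, file.path(tmp, "g.refflat"))
  back <- read_gene_table(file.path(tmp, "g.refflat"), assembly = asm)
  expect_equal(back, genes)
  expect_equal(length(back$exon_starts[[1]]), 2L)

  set.seed(3)
  df <- data.frame(chrom = "chr1", start = 0:9 * 500, end = 1:10 * 500,
                   p = runif(10), direction = sample(c("+", "-", "0"), 10, TRUE),
                   tested = sample(c(TRUE, FALSE), 10, TRUE),
                   stringsAsFactors = FALSE)
  write_results_table(df, file.path(tmp, "res.tsv"))
  expect_equal(read_results_table(file.path(tmp, "res.tsv")), df)
})

test_that("counts table round-trips and malformed input is located by line", {
  tmp <- withr::local_tempdir()
  sim <- simulate_inputs(simulation_config(seed = 2, chrom_length = 5000,
                                           n_genes = 3, n_planted_dmrs = 2,
                                           n_de_genes = 1,
                                           gene_length_range = c(500, 1500)))
  paths <- write_simulation(sim, tmp)
  back <- read_counts_table(paths$counts, paths$manifest, sim$assembly)
  expect_equal(back$medip, sim$counts$medip)
  expect_equal(back$mre, sim$counts$mre)
  expect_equal(back$cpg, sim$counts$cpg)
  expect_equal(back$libraries, sim$counts$libraries)
  expect_equal(back$medip_totals, sim$counts$medip_totals)

  # corrupt one numeric field and expect the line to be named
  lines <- readLines(paths$counts)
  bad <- strsplit(lines[4], "\t")[[1]]
  bad[5] <- "oops"
  lines[4] <- paste(bad, collapse = "\t")
  writeLines(lines, file.path(tmp, "bad.tsv"))
  expect_error(read_counts_table(file.path(tmp, "bad.tsv"), paths$manifest),
               "line 4")

  writeLines(c("chr1\t0\t500", "chr1\tnope\t1000"), file.path(tmp, "bad.bed"))
  expect_error(read_bed(file.path(tmp, "bad.bed")), "line 2")
  writeLines("chr1\t100", file.path(tmp, "short.bed"))
  expect_error(read_bed(file.path(tmp, "short.bed")), "line 1")
  # coordinate past chromosome end
  writeLines("chr1\t0\t99999", file.path(tmp, "far.bed"))
  expect_error(read_bed(file.path(tmp, "far.bed"), sim$assembly), "past end")
})

test_that("gene-model invariants are enforced", {
  expect_error(gene_models("g", "c", "+", 0, 100, list(c(10, 5)), list(c(20, 50))),
               "sorted")
  expect_error(gene_models("g", "c", "+", 0, 100, list(c(0, 15)), list(c(20, 50))),
               "non-overlapping")
  expect_error(gene_models("g", "c", "+", 10, 100, list(0), list(50)),
               "outside")
  expect_error(regulatory_features("c", 10, 10, "enhancer"), "end <= start")
  expect_error(regulatory_features("c", 0, 10, "promoter"), "unknown")
})
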