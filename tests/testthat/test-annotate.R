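toy_gene <- function(strand = "+", tx_start = 10000, tx_end = 20000,
                     chrom = "chrT", id = "g1") {
  gene_models(id, chrom, strand, tx_start, tx_end,
              list(tx_start), list(tx_end))
}

test_that("promoter intervals are strand-aware and clipped", {
  p <- promoter_intervals(toy_gene("+"))
  expect_equal(c(p$start, p$end), c(8000, 10600))

  m <- promoter_intervals(toy_gene("-", tx_start = 1000, tx_end = 10000))
  expect_equal(c(m$start, m$end), c(9400, 12000))

  clip <- promoter_intervals(toy_gene("+", tx_start = 1000, tx_end = 5000))
  expect_equal(c(clip$start, clip$end), c(0, 1600))

  asm <- genome_assembly("chrT", 10300)
  clip2 <- promoter_intervals(toy_gene("-", tx_start = 1000, tx_end = 10000),
                              assembly = asm)
  expect_equal(c(clip2$start, clip2$end), c(9400, 10300))
})

test_that("classification follows the exon-over-intron precedence", {
  # gene with two exons; window spanning the exon/intron junction is an exon
  g <- gene_models("g1", "chrT", "+", 1000, 9000,
                   list(c(1000, 6000)), list(c(3000, 9000)))
  feats <- regulatory_features(character(0), numeric(0), numeric(0),
                               character(0))
  regions <- data.frame(chrom = "chrT",
                        start = c(2800, 4000, 50000, 500),
                        end = c(3300, 4500, 50500, 1000))
  ann <- annotate_dmrs(regions, g, feats)
  expect_equal(ann$category,
               c("exon",        # overlaps exon 1 and intron 1
                 "intron",      # between exons
                 "intergenic",  # far from everything
                 "promoter"))   # upstream window, inside [−2000, +600)
  expect_true(ann$promoter_flag[4])
  # promoter flag co-occurs with exon category at the gene start
  ann2 <- annotate_dmrs(data.frame(chrom = "chrT", start = 1000, end = 1500),
                        g, feats)
  expect_equal(ann2$category, "exon")
  expect_true(ann2$promoter_flag)
})

test_that("regulatory overlap is any-overlap with half-open boundaries", {
  g <- toy_gene()
  f <- regulatory_features(c("chrT", "chrT", "chrT"), c(499, 500, 450),
                           c(800, 800, 460),
                           c("enhancer", "enhancer", "ctcf_binding_site"))
  a1 <- annotate_dmrs(data.frame(chrom = "chrT", start = 0, end = 500),
                      g, f[1, ])
  expect_true(a1$enhancer)  # 1-bp overlap counts
  a2 <- annotate_dmrs(data.frame(chrom = "chrT", start = 0, end = 500),
                      g, f[2, ])
  expect_false(a2$enhancer)  # half-open: [0,500) vs [500,800) is disjoint
  a3 <- annotate_dmrs(data.frame(chrom = "chrT", start = 0, end = 500), g, f)
  expect_true(a3$enhancer && a3$ctcf_binding_site)
})

test_that("nearest_gene applies the distance and tie-break rules", {
  g2 <- gene_models(c("gA", "gB"), "chrT", c("+", "+"), c(0, 5000),
                    c(1000, 6000), list(0, 5000), list(1000, 6000))
  inside <- nearest_gene(data.frame(chrom = "chrT", start = 200, end = 700), g2)
  expect_equal(inside$gene_id, "gA")
  expect_equal(inside$distance_bp, 0)
  expect_true(inside$within_gene)

  # equidistant (100 bp to both): smaller tx_start wins
  tie <- nearest_gene(data.frame(chrom = "chrT", start = 1100, end = 4900), g2)
  expect_equal(tie$gene_id, "gA")
  expect_equal(tie$distance_bp, 100)
  expect_false(tie$within_gene)

  # other chromosomes never match
  other <- nearest_gene(data.frame(chrom = "chrZ", start = 0, end = 500), g2)
  expect_true(other$no_gene)
  expect_true(is.na(other$gene_id))
})

test_that("annotation agrees with quadratic brute-force scans", {
  set.seed(41)
  for (rep in 1:25) {
    chrom_len <- 50000
    genes <- random_toy_genes(sample(3:8, 1), chrom_len)
    feats <- random_toy_features(sample(5:20, 1), chrom_len)
    proms <- promoter_intervals(genes)
    n <- 40
    start <- sample.int(chrom_len - 500, n)
    regions <- data.frame(chrom = "chrT", start = start, end = start + 500)
    ann <- annotate_dmrs(regions, genes, feats)
    ng <- nearest_gene(regions, genes)
    for (i in seq_len(n)) {
      oc <- oracle_classify("chrT", regions$start[i], regions$end[i],
                            genes, proms)
      expect_equal(ann$category[i], oc$category)
      expect_equal(ann$promoter_flag[i], oc$promoter_flag)
      or <- oracle_regulatory("chrT", regions$start[i], regions$end[i], feats)
      expect_equal(unlist(ann[i, regulatory_classes()]),
                   or, ignore_attr = TRUE)
      on <- oracle_nearest("chrT", regions$start[i], regions$end[i], genes)
      expect_equal(ng$gene_id[i], on$gene_id)
      expect_equal(ng$distance_bp[i], on$distance)
      expect_equal(ng$within_gene[i], on$within)
    }
    # four-way category is exhaustive and exclusive by construction
    expect_true(all(ann$category %in% c("promoter", "exon", "intron",
                                        "intergenic")))
  }
})

test_that("DE and disease flags follow gene-body overlap and the list", {
  g2 <- gene_models(c("gA", "gB"), "chrT", c("+", "+"), c(0, 5000),
                    c(1000, 6000), list(0, 5000), list(1000, 6000))
  de <- data.frame(gene_id = c("gA", "gB"), log2fc = c(2, 0.1),
                   p = c(1e-6, 0.5), q = c(0.001, 0.9))
  feats <- regulatory_features(character(0), numeric(0), numeric(0),
                               character(0))
  regions <- data.frame(chrom = "chrT", start = c(200, 5200, 2500),
                        end = c(700, 5700, 3000))
  ann <- annotate_dmrs(regions, g2, feats, de_table = de,
                       disease_genes = "gB")
  expect_equal(ann$in_de_gene, c(TRUE, FALSE, FALSE))  # only gA has q < 0.05
  expect_equal(ann$disease_gene, c(FALSE, TRUE, FALSE))
})

test_that("summaries reproduce printed-percentage arithmetic", {
  expect_equal(round_half_up(100 * 180 / 1539, 1), 11.7)
  expect_equal(round_half_up(100 * 370 / 2356, 1), 15.7)

  mk_ann <- function(total, enh) {
    data.frame(chrom = "chrT", start = 0, end = 500,
               category = rep("intron", total), promoter_flag = FALSE,
               enhancer = c(rep(TRUE, enh), rep(FALSE, total - enh)),
               ctcf_binding_site = FALSE, tf_binding_site = FALSE,
               promoter_flanking = FALSE, stringsAsFactors = FALSE)
  }
  s <- summarize_annotation(mk_ann(1539, 180))
  expect_equal(s$percent[s$region == "enhancer"], 11.7)
  expect_equal(s$count[s$region == "enhancer"], 180L)
  s0 <- summarize_annotation(mk_ann(10, 0))
  expect_equal(s0$percent[s0$region == "enhancer"], 0)
  empty <- summarize_annotation(mk_ann(10, 0)[0, ])
  expect_true(all(is.na(empty$percent)))
})
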