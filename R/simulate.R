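#' Configuration of the synthetic methylome generator
#'
#' Defines the study conditions the generator emulates: a small multi-
#' chromosome assembly, CpG sites scattered with Poisson density, gene
#' models with exon structure, Ensembl-style regulatory features, two diet
#' groups ("HF" and "LF") with replicate MeDIP and MRE libraries whose
#' counts follow a negative-binomial model driven by per-window methylation
#' levels, planted differentially methylated windows, and a differential-
#' expression table with planted DE genes.
#'
#' Count model, per window w with c_w CpG sites and true methylation level
#' theta_w(group): MeDIP ~ NegBin(mean = s_medip * c_w * theta_w / Z,
#' size = dispersion) and MRE ~ NegBin(mean = s_mre * c_w * (1 - theta_w) /
#' Z', size = dispersion), where Z and Z' normalize the per-window means to
#' sum to the library's expected total. `dispersion = Inf` gives the
#' Poisson limit. MRE counts track (1 - theta) scaled by CpG count as a
#' proxy for unmethylated restriction sites, preserving the MeDIP/MRE
#' anticorrelation the inference exploits.
#'
#' Defaults describe two 500-kb chromosomes (2000 windows of 500 bp), 10
#' CpGs per window on average, 60 non-overlapping genes of 2-10 kb, the
#' four regulatory classes at roughly their mouse genome-wide coverage, two
#' replicate libraries per diet group, and library sizes giving an expected
#' 30 reads per window per assay (the coverage scale of tens-of-millions-
#' read libraries over a few million genome windows).
#'
#' @param seed integer RNG seed (the whole generator is deterministic
#'   given it).
#' @param n_chromosomes,chrom_length assembly shape.
#' @param window_size window width in bp (default 500).
#' @param cpg_density expected CpG sites per window (Poisson mean).
#' @param n_genes,gene_length_range,n_exons_range gene model shape.
#' @param fraction_regulatory named vector: target genome fraction covered
#'   per regulatory class.
#' @param n_libraries_per_group replicate libraries per diet group
#'   (default 2, two pooled biological replicates per group).
#' @param sex sex label written into the library manifest.
#' @param library_size_medip,library_size_mre expected library totals;
#'   default 30 reads/window times the number of windows.
#' @param dispersion negative-binomial size parameter; `Inf` = Poisson.
#' @param baseline_meth_beta shape parameters (a, b) of the Beta
#'   distribution of per-window methylation level theta.
#' @param n_planted_dmrs number of windows with a diet effect.
#' @param effect_delta additive shift of theta in the HF group at planted
#'   windows, clamped to `[0.01, 0.99]`.
#' @param n_de_genes number of planted differentially expressed genes.
#' @param fraction_dmr_in_de fraction of planted DMR windows forced inside
#'   planted DE gene bodies.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chrom_length = 5e5,
                              window_size = 500L,
                              cpg_density = 10,
                              n_genes = 60L,
                              gene_length_range = c(2000, 10000),
                              n_exons_range = c(2L, 8L),
                              fraction_regulatory = c(
                                enhancer = 0.035,
                                ctcf_binding_site = 0.017,
                                tf_binding_site = 0.003,
                                promoter_flanking = 0.081),
                              n_libraries_per_group = 2L,
                              sex = "F",
                              library_size_medip = NULL,
                              library_size_mre = NULL,
                              dispersion = 100,
                              baseline_meth_beta = c(2, 2),
                              n_planted_dmrs = 50L,
                              effect_delta = 0.4,
                              n_de_genes = 20L,
                              fraction_dmr_in_de = 0.25) {
  .assert_scalar_number(seed, "seed")
  .assert_scalar_number(n_chromosomes, "n_chromosomes", min = 1)
  .assert_scalar_number(chrom_length, "chrom_length", min = 1)
  .assert_scalar_number(window_size, "window_size", min = 1)
  .assert_scalar_number(cpg_density, "cpg_density", min = 0)
  .assert_scalar_number(n_libraries_per_group, "n_libraries_per_group", min = 1)
  .assert_scalar_number(dispersion, "dispersion", min = 0)
  .assert_scalar_number(n_planted_dmrs, "n_planted_dmrs", min = 0)
  .assert_scalar_number(n_de_genes, "n_de_genes", min = 0)
  if (abs(effect_delta) >= 1) stop("effect_delta must lie in (-1, 1)", call. = FALSE)
  if (fraction_dmr_in_de < 0 || fraction_dmr_in_de > 1) {
    stop("fraction_dmr_in_de must lie in [0, 1]", call. = FALSE)
  }
  if (any(baseline_meth_beta <= 0)) {
    stop("baseline_meth_beta shapes must be positive", call. = FALSE)
  }
  if (n_de_genes > n_genes) stop("n_de_genes exceeds n_genes", call. = FALSE)
  stopifnot(length(gene_length_range) == 2L, length(n_exons_range) == 2L)
  n_windows <- n_chromosomes * ceiling(chrom_length / window_size)
  if (is.null(library_size_medip)) library_size_medip <- 30 * n_windows
  if (is.null(library_size_mre)) library_size_mre <- 30 * n_windows
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length, window_size = window_size,
              cpg_density = cpg_density, n_genes = as.integer(n_genes),
              gene_length_range = gene_length_range,
              n_exons_range = n_exons_range,
              fraction_regulatory = fraction_regulatory,
              n_libraries_per_group = as.integer(n_libraries_per_group),
              sex = sex, library_size_medip = library_size_medip,
              library_size_mre = library_size_mre, dispersion = dispersion,
              baseline_meth_beta = baseline_meth_beta,
              n_planted_dmrs = as.integer(n_planted_dmrs),
              effect_delta = effect_delta, n_de_genes = as.integer(n_de_genes),
              fraction_dmr_in_de = fraction_dmr_in_de)
  class(cfg) <- "simulation_config"
  cfg
}

.sim_cpgs <- function(windows, density) {
  counts <- rpois(nrow(windows), density)
  width <- windows$end - windows$start
  counts <- pmin(counts, width)  # at most one site per bp
  chrom <- rep(windows$chrom, counts)
  pos <- unlist(lapply(which(counts > 0), function(i) {
    windows$start[i] + sort(sample.int(width[i], counts[i])) - 1
  }))
  if (is.null(pos)) pos <- numeric(0)
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

.sim_genes <- function(assembly, cfg) {
  placed <- vector("list", cfg$n_genes)
  occupied <- lapply(assembly$chrom, function(x) cbind(numeric(0), numeric(0)))
  names(occupied) <- assembly$chrom
  for (g in seq_len(cfg$n_genes)) {
    ok <- FALSE
    for (try in 1:500) {
      ci <- sample.int(nrow(assembly), 1, prob = assembly$length)
      L <- round(runif(1, cfg$gene_length_range[1], cfg$gene_length_range[2]))
      if (L >= assembly$length[ci]) next
      s <- floor(runif(1, 0, assembly$length[ci] - L))
      occ <- occupied[[ci]]
      if (nrow(occ) == 0L || all(s + L <= occ[, 1] | s >= occ[, 2])) {
        occupied[[ci]] <- rbind(occ, c(s, s + L))
        k <- sample(seq(cfg$n_exons_range[1], cfg$n_exons_range[2]), 1)
        k <- min(k, floor((L - 1) / 2))
        k <- max(k, 1L)
        if (k == 1L) {
          es <- s; ee <- s + L
        } else {
          # 2k-1 alternating segments exon/intron/.../exon
          br <- s + sort(sample.int(L - 1, 2 * k - 2))
          edges <- c(s, br, s + L)
          es <- edges[seq(1, 2 * k - 1, by = 2)]
          ee <- edges[seq(2, 2 * k, by = 2)]
        }
        placed[[g]] <- list(chrom = assembly$chrom[ci],
                            strand = sample(c("+", "-"), 1),
                            tx_start = s, tx_end = s + L,
                            exon_starts = es, exon_ends = ee)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place ", cfg$n_genes, " non-overlapping genes; ",
                  "reduce n_genes or gene lengths", call. = FALSE)
  }
  gene_models(gene_id = sprintf("gene%04d", seq_len(cfg$n_genes)),
              chrom = vapply(placed, `[[`, "", "chrom"),
              strand = vapply(placed, `[[`, "", "strand"),
              tx_start = vapply(placed, `[[`, 0, "tx_start"),
              tx_end = vapply(placed, `[[`, 0, "tx_end"),
              exon_starts = lapply(placed, `[[`, "exon_starts"),
              exon_ends = lapply(placed, `[[`, "exon_ends"))
}

.sim_regulatory <- function(assembly, fractions) {
  total <- sum(assembly$length)
  rows <- list()
  for (cl in names(fractions)) {
    target <- fractions[[cl]] * total
    mean_len <- 600
    n_feat <- max(0L, round(target / mean_len))
    if (n_feat == 0L) next
    ci <- sample.int(nrow(assembly), n_feat, replace = TRUE,
                     prob = assembly$length)
    len <- round(runif(n_feat, 200, 1000))
    start <- floor(runif(n_feat, 0, assembly$length[ci] - len))
    rows[[cl]] <- data.frame(chrom = assembly$chrom[ci], start = start,
                             end = start + len, feature_class = cl,
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(regulatory_features(character(0), numeric(0), numeric(0),
                               character(0)))
  }
  df <- do.call(rbind, rows)
  regulatory_features(df$chrom, df$start, df$end, df$feature_class)
}

.sim_de_table <- function(genes, n_de) {
  n <- nrow(genes)
  is_de <- rep(FALSE, n)
  if (n_de > 0) is_de[sample.int(n, n_de)] <- TRUE
  log2fc <- rnorm(n, 0, 0.2)
  log2fc[is_de] <- sample(c(-1, 1), sum(is_de), replace = TRUE) *
    rnorm(sum(is_de), 2, 0.5)
  q <- runif(n, 0.051, 1)
  q[is_de] <- runif(sum(is_de), 1e-8, 0.049)
  de <- data.frame(gene_id = genes$gene_id, log2fc = log2fc,
                   p = q * runif(n, 0.05, 1), q = q,
                   stringsAsFactors = FALSE)
  list(de_table = de, is_de = is_de)
}

.sim_counts_one <- function(mu_base, s_lib, dispersion) {
  Z <- sum(mu_base)
  mu <- if (Z > 0) s_lib * mu_base / Z else rep(0, length(mu_base))
  if (is.infinite(dispersion)) rpois(length(mu), mu)
  else rnbinom(length(mu), mu = mu, size = dispersion)
}

#' Generate every pipeline input under a seeded statistical model
#'
#' Produces, deterministically given `config$seed`: the assembly, CpG map,
#' gene models, regulatory features, a [window_counts()] object for all
#' MeDIP/MRE libraries, a differential-expression table, and a ground-truth
#' table recording per-window methylation levels and planted-DMR flags and
#' per-gene DE flags. See [simulation_config()] for the count model.
#'
#' @param config a [simulation_config()].
#' @return a `methylome_simulation` list with elements `assembly`, `windows`,
#'   `cpgs`, `genes`, `regulatory`, `counts`, `de_table`, `truth_windows`,
#'   `truth_genes`, `config`.
#' @export
simulate_inputs <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("config must come from simulation_config()", call. = FALSE)
  }
  set.seed(config$seed)
  assembly <- genome_assembly(sprintf("chr%d", seq_len(config$n_chromosomes)),
                              rep(config$chrom_length, config$n_chromosomes))
  windows <- tile_genome(assembly, config$window_size)
  n <- nrow(windows)
  cpgs <- .sim_cpgs(windows, config$cpg_density)
  cpgs <- cpg_map(cpgs$chrom, cpgs$pos, assembly)
  cpg <- count_cpgs_per_window(windows, cpgs)
  genes <- .sim_genes(assembly, config)
  regulatory <- .sim_regulatory(assembly, config$fraction_regulatory)
  de <- .sim_de_table(genes, config$n_de_genes)

  # plant DMRs, a configured fraction inside DE gene bodies
  theta <- rbeta(n, config$baseline_meth_beta[1], config$baseline_meth_beta[2])
  planted <- rep(FALSE, n)
  if (config$n_planted_dmrs > 0) {
    if (config$n_planted_dmrs > n) {
      stop("more planted DMRs than windows", call. = FALSE)
    }
    db <- genes[de$is_de, , drop = FALSE]
    wgr <- .as_granges(windows$chrom, windows$start, windows$end)
    in_de <- if (nrow(db)) {
      GenomicRanges::countOverlaps(
        wgr, .as_granges(db$chrom, db$tx_start, db$tx_end)) > 0
    } else rep(FALSE, n)
    n_in <- as.integer(.round_half_away(config$fraction_dmr_in_de *
                                        config$n_planted_dmrs))
    if (n_in > sum(in_de)) {
      stop("not enough windows inside DE genes to plant ", n_in, " DMRs",
           call. = FALSE)
    }
    pick <- if (n_in > 0) sample(which(in_de), n_in) else integer(0)
    rest_pool <- setdiff(seq_len(n), pick)
    n_rest <- config$n_planted_dmrs - n_in
    if (n_rest > length(rest_pool)) {
      stop("more planted DMRs than available windows", call. = FALSE)
    }
    pick <- c(pick, sample(rest_pool, n_rest))
    planted[pick] <- TRUE
  }
  theta_lf <- theta
  theta_hf <- theta
  theta_hf[planted] <- pmin(pmax(theta[planted] + config$effect_delta, 0.01),
                            0.99)

  reps <- seq_len(config$n_libraries_per_group)
  manifest <- data.frame(
    library_id = c(sprintf("HF_%s_%d", config$sex, reps),
                   sprintf("LF_%s_%d", config$sex, reps)),
    sex = config$sex,
    diet = rep(c("HF", "LF"), each = config$n_libraries_per_group),
    replicate = c(reps, reps), stringsAsFactors = FALSE)
  medip <- matrix(0, n, nrow(manifest))
  mre <- matrix(0, n, nrow(manifest))
  for (j in seq_len(nrow(manifest))) {
    th <- if (manifest$diet[j] == "HF") theta_hf else theta_lf
    medip[, j] <- .sim_counts_one(cpg * th, config$library_size_medip,
                                  config$dispersion)
    mre[, j] <- .sim_counts_one(cpg * (1 - th), config$library_size_mre,
                                config$dispersion)
  }
  counts <- window_counts(windows, cpg, manifest, medip, mre)
  truth_windows <- data.frame(index = windows$index, chrom = windows$chrom,
                              start = windows$start, end = windows$end,
                              theta_lf = theta_lf, theta_hf = theta_hf,
                              is_planted_dmr = planted,
                              stringsAsFactors = FALSE)
  truth_genes <- data.frame(gene_id = genes$gene_id, is_de = de$is_de,
                            stringsAsFactors = FALSE)
  structure(list(assembly = assembly, windows = windows, cpgs = cpgs,
                 genes = genes, regulatory = regulatory, counts = counts,
                 de_table = de$de_table, truth_windows = truth_windows,
                 truth_genes = truth_genes, config = config),
            class = "methylome_simulation")
}

#' Write a simulation to the pipeline's file formats
#'
#' Emits chrom.sizes, CpG BED3, refFlat-style gene table, regulatory BED4,
#' counts + manifest TSVs, the DE table, and the two truth TSVs into `dir`.
#'
#' @param sim a [simulate_inputs()] result.
#' @param dir output directory (created if needed).
#' @return named list of file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_chrom_sizes(sim$assembly, p("chrom.sizes"))
  write_bed(data.frame(chrom = sim$cpgs$chrom, start = sim$cpgs$pos,
                       end = sim$cpgs$pos + 2), p("cpg_sites.bed"))
  write_gene_table(sim$genes, p("genes.refflat"))
  write_regulatory_bed(sim$regulatory, p("regulatory.bed"))
  write_counts_table(sim$counts, p("counts.tsv"), p("manifest.tsv"))
  write_results_table(sim$de_table, p("de_genes.tsv"))
  write_results_table(sim$truth_windows, p("truth_windows.tsv"))
  write_results_table(sim$truth_genes, p("truth_genes.tsv"))
  invisible(list(chrom_sizes = p("chrom.sizes"), cpg_bed = p("cpg_sites.bed"),
                 genes = p("genes.refflat"), regulatory = p("regulatory.bed"),
                 counts = p("counts.tsv"), manifest = p("manifest.tsv"),
                 de_table = p("de_genes.tsv"),
                 truth_windows = p("truth_windows.tsv"),
                 truth_genes = p("truth_genes.tsv")))
}

#' Simulate glucose tolerance series
#'
#' Per-animal glucose measurements at the canonical tolerance-test minutes
#' (0, 30, 60, 120 by default): group mean curve plus independent Gaussian
#' noise, floored at zero. Defaults emulate an intraperitoneal glucose
#' tolerance test with a blunted recovery in the HF group.
#'
#' @param n_per_group animals per diet group.
#' @param minutes measurement times.
#' @param mean_hf,mean_lf group mean glucose (mg/dL) at those times.
#' @param sd measurement + animal noise SD (mg/dL).
#' @param test label written into the `test` column.
#' @param seed RNG seed.
#' @return long data frame (`animal_id`, `diet`, `test`, `minute`,
#'   `glucose`).
#' @export
simulate_phenotypes <- function(n_per_group = 10,
                                minutes = c(0, 30, 60, 120),
                                mean_hf = c(160, 380, 330, 230),
                                mean_lf = c(130, 280, 230, 160),
                                sd = 15, test = "ipgtt", seed = 1) {
  stopifnot(length(mean_hf) == length(minutes),
            length(mean_lf) == length(minutes))
  set.seed(seed)
  rows <- list()
  for (diet in c("HF", "LF")) {
    mu <- if (diet == "HF") mean_hf else mean_lf
    for (a in seq_len(n_per_group)) {
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = sprintf("%s_%02d", diet, a), diet = diet, test = test,
        minute = minutes,
        glucose = pmax(0, rnorm(length(minutes), mu, sd)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
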