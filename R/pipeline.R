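#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected.
#' With `input_dir = NULL` the pipeline generates its inputs with
#' [simulate_inputs()] (using `sim`, which may be a [simulation_config()]
#' or a named list of overrides to the defaults); with `input_dir` set it
#' reads chrom.sizes, counts.tsv, manifest.tsv, genes.refflat,
#' regulatory.bed and de_genes.tsv from that directory instead.
#'
#' @param out_dir output directory.
#' @param seed integer seed for every random stage.
#' @param input_dir optional directory of pre-existing inputs.
#' @param sim simulation settings (see above).
#' @param min_cpg,min_coverage window filters, see [run_pairwise()].
#' @param pairing `"all_pairs"` or `"disjoint_pairs"`.
#' @param q_cutoffs q-value cutoffs for DMR calling.
#' @param promoter_upstream,promoter_downstream promoter extent in bp.
#' @param n_rand randomizations for the DE-overlap test.
#' @param disease_genes optional path to a one-gene-per-line list.
#' @param log_level `"info"` or `"quiet"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, input_dir = NULL,
                            sim = list(), min_cpg = 1, min_coverage = 4,
                            pairing = "all_pairs",
                            q_cutoffs = c(0.05, 0.01),
                            promoter_upstream = 2000,
                            promoter_downstream = 600,
                            n_rand = 1000, disease_genes = NULL,
                            log_level = "info") {
  .assert_scalar_number(seed, "seed")
  if (!pairing %in% c("all_pairs", "disjoint_pairs")) {
    stop("pairing must be 'all_pairs' or 'disjoint_pairs'", call. = FALSE)
  }
  if (!log_level %in% c("info", "quiet")) {
    stop("log_level must be 'info' or 'quiet'", call. = FALSE)
  }
  if (any(q_cutoffs <= 0 | q_cutoffs > 1)) {
    stop("q_cutoffs must lie in (0, 1]", call. = FALSE)
  }
  if (is.list(sim) && !inherits(sim, "simulation_config")) {
    unknown <- setdiff(names(sim), names(formals(simulation_config)))
    if (length(unknown)) {
      stop("unknown simulation key: ", unknown[1], call. = FALSE)
    }
    sim <- do.call(simulation_config, c(sim, list(seed = as.integer(seed))))
  }
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              input_dir = input_dir, sim = sim, min_cpg = min_cpg,
              min_coverage = min_coverage, pairing = pairing,
              q_cutoffs = sort(q_cutoffs, decreasing = TRUE),
              promoter_upstream = promoter_upstream,
              promoter_downstream = promoter_downstream,
              n_rand = n_rand, disease_genes = disease_genes,
              log_level = log_level)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; the `sim` key holds
#' [simulation_config()] overrides. Unknown keys in either block are
#' rejected.
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file's values.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  dots <- list(...)
  raw[names(dots)] <- dots
  unknown <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(unknown)) {
    stop(path, ": unknown configuration key: ", unknown[1], call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

.stage <- function(name, cfg, expr) {
  if (cfg$log_level != "quiet") message("[", name, "] running")
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

.load_inputs <- function(dir) {
  assembly <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  counts <- read_counts_table(file.path(dir, "counts.tsv"),
                              file.path(dir, "manifest.tsv"), assembly)
  genes <- read_gene_table(file.path(dir, "genes.refflat"),
                           assembly = assembly)
  regulatory <- read_regulatory_bed(file.path(dir, "regulatory.bed"), assembly)
  de_table <- read_de_table(file.path(dir, "de_genes.tsv"))
  list(assembly = assembly, counts = counts, genes = genes,
       regulatory = regulatory, de_table = de_table)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> per-window pairwise tests -> Fisher
#' combination + BH + DMR calls -> annotation and Table-1-style summary ->
#' regulatory chi-square and intergenic-constrained DE-overlap enrichment,
#' writing every stage's output as TSV/BED under `config$out_dir` together
#' with a machine-readable JSON run manifest (configuration, seed, package
#' version, and MD5 checksum of every output file). A rerun with the same
#' configuration and seed is bit-identical. Any stage failure aborts with
#' an error naming the stage.
#'
#' @param config a [pipeline_config()].
#' @return named list of outputs (`dmrs` per cutoff, `summary`,
#'   `enrichment`, `paths`, ...), invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must come from pipeline_config()", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name, writer = write_results_table) {
    path <- file.path(config$out_dir, name)
    writer(df, path)
    paths[[name]] <<- path
    path
  }

  if (is.null(config$input_dir)) {
    sim <- .stage("simulate", config, simulate_inputs(config$sim))
    .stage("simulate", config,
           write_simulation(sim, file.path(config$out_dir, "inputs")))
    inputs <- list(assembly = sim$assembly, counts = sim$counts,
                   genes = sim$genes, regulatory = sim$regulatory,
                   de_table = sim$de_table)
  } else {
    sim <- NULL
    inputs <- .stage("load_inputs", config, .load_inputs(config$input_dir))
  }

  pairwise <- .stage("diffmeth", config,
                     run_pairwise(inputs$counts, min_coverage = config$min_coverage,
                                  min_cpg = config$min_cpg,
                                  pairing = config$pairing))
  for (r in pairwise) {
    emit(as.data.frame(r), paste0("pairwise_", attr(r, "comparison_id"), ".tsv"))
  }

  combined <- .stage("combine", config, combine_windows(pairwise))
  emit(as.data.frame(combined), "combined_windows.tsv")
  dmrs <- list()
  for (cut in config$q_cutoffs) {
    d <- .stage("combine", config, call_dmrs(combined, cut))
    dmrs[[as.character(cut)]] <- d
    emit(as.data.frame(d), sprintf("dmrs_q%s.tsv", cut))
    emit(d, sprintf("dmrs_q%s.bed", cut), write_dmr_bed)
  }

  disease <- if (!is.null(config$disease_genes)) {
    readLines(config$disease_genes)
  } else NULL
  annotate_set <- function(regions) {
    annotate_dmrs(regions, inputs$genes, inputs$regulatory,
                  de_table = inputs$de_table, disease_genes = disease,
                  upstream = config$promoter_upstream,
                  downstream = config$promoter_downstream,
                  assembly = inputs$assembly)
  }
  windows <- inputs$counts$windows  # background = the tiling itself
  genome_ann <- .stage("annotate", config, annotate_set(windows))
  annotated <- list()
  for (cut in names(dmrs)) {
    a <- .stage("annotate", config, annotate_set(dmrs[[cut]]))
    annotated[[cut]] <- a
    emit(as.data.frame(a), sprintf("annotated_dmrs_q%s.tsv", cut))
    emit(summarize_annotation(a, genome_ann),
         sprintf("annotation_summary_q%s.tsv", cut))
  }

  enrichment <- .stage("enrich", config, {
    # regulatory enrichment at the strictest cutoff (the summary table's set)
    strict <- annotated[[length(annotated)]]
    reg_union <- function(a) a$enhancer | a$ctcf_binding_site |
      a$tf_binding_site | a$promoter_flanking
    reg <- if (nrow(strict) > 0) {
      regulatory_chi2(sum(reg_union(strict)), nrow(strict),
                      mean(reg_union(genome_ann)))
    } else NULL
    # DE-gene overlap at the loosest cutoff, intergenic-constrained null
    loose <- annotated[[1]]
    loose_dmrs <- dmrs[[1]]
    de_overlap <- NULL
    if (nrow(loose) > 0) {
      widx <- match(paste(loose_dmrs$chrom, loose_dmrs$start),
                    paste(windows$chrom, windows$start))
      rand <- constrained_randomize(widx,
                                    genome_ann$category == "intergenic",
                                    genome_ann$in_de_gene,
                                    n_rand = config$n_rand,
                                    seed = config$seed)
      de_overlap <- overlap_chi2(sum(loose$in_de_gene), rand, nrow(loose))
    }
    list(regulatory = reg, de_overlap = de_overlap)
  })
  enr_rows <- list()
  for (e in enrichment) {
    if (is.null(e)) next
    enr_rows[[e$test]] <- data.frame(
      test = e$test, observed = e$observed, expected = e$expected,
      n_total = e$n_total, chi2 = e$chi2, df = e$df, p_chi2 = e$p_value,
      p_empirical = if (is.null(e$p_empirical)) NA else e$p_empirical,
      n_rand = if (is.null(e$n_rand)) NA else e$n_rand,
      seed = config$seed, stringsAsFactors = FALSE)
  }
  if (length(enr_rows)) {
    emit(do.call(rbind, enr_rows), "enrichment.tsv")
  }

  manifest <- list(
    package = "winmeth",
    version = as.character(packageVersion("winmeth")),
    seed = config$seed,
    config = unclass(config[setdiff(names(config), "sim")]),
    sim = if (inherits(config$sim, "simulation_config")) unclass(config$sim)
          else NULL,
    files = as.list(vapply(unlist(paths), function(p) unname(md5sum(p)), "")))
  manifest_path <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  if (config$log_level != "quiet") message("[done] manifest: ", manifest_path)
  invisible(list(simulation = sim, pairwise = pairwise, combined = combined,
                 dmrs = dmrs, annotated = annotated,
                 genome_annotation = genome_ann, enrichment = enrichment,
                 paths = c(paths, manifest = manifest_path)))
}
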