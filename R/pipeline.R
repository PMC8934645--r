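#' Assemble a pipeline run configuration
#'
#' Collects the simulation parameters, mining thresholds and output
#' location for [run_pipeline()]. Defaults equal the printed screening
#' values (300 aa, E < 0.001, coverage > 70%, 0.85 maximum difference,
#' more than two associated families, the summary-table activity
#' bands). A configuration can also be loaded from a YAML file whose
#' top-level keys mirror the arguments.
#'
#' @param seed global integer seed.
#' @param outdir output directory for artifacts.
#' @param stages subset of `c("simulate", "mine", "phylo", "quant")`.
#' @param sim named list of [sim_config()] overrides.
#' @param miner named list of [miner_params()] overrides.
#' @param assay named list: `true_activities` (named percent vector),
#'   `n_replicates`, `mean_cfu`.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = "acrmine-run",
                            stages = c("simulate", "mine", "phylo", "quant"),
                            sim = list(), miner = list(),
                            assay = list(), log_level = "info") {
  stages <- match.arg(stages, c("simulate", "mine", "phylo", "quant"),
                      several.ok = TRUE)
  assay_defaults <- list(true_activities = c(AcrA = 91, AcrB = 56, AcrC = 33),
                         n_replicates = 3L, mean_cfu = 200)
  assay <- utils::modifyList(assay_defaults, assay)
  structure(list(seed = as.integer(seed), outdir = outdir, stages = stages,
                 sim = sim, miner = miner, assay = assay,
                 log_level = log_level),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the configuration.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("seed", "outdir", "stages", "sim", "miner", "assay",
               "log_level")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0L) {
    stop("read_pipeline_config: unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' Run the full discovery pipeline on synthetic data
#'
#' Executes the configured stages in order — simulate genomes and
#' evidence, mine candidates via the search-validation loop seeded with
#' the first planted Acr family, build a distance tree for the largest
#' Acr family, and quantify simulated interference assays — writing all
#' artifacts plus a provenance block to the output directory. A fixed
#' seed makes the whole run deterministic.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) {
    if (!identical(config$log_level, "quiet")) message("[acrmine] ", ...)
  }
  results <- list()

  scfg <- do.call(sim_config, utils::modifyList(list(seed = config$seed),
                                                config$sim))
  params <- do.call(miner_params, config$miner)

  say("simulate: ", scfg$n_replicons, " replicons, seed ", scfg$seed)
  sim <- generate_genomes(scfg)
  hits <- generate_hit_table(sim)
  domains <- generate_domain_table(sim)
  results$sim <- sim
  if ("simulate" %in% config$stages) {
    write_genbank(sim$genes, file.path(config$outdir, "genomes.gbk"),
                  sim$replicon_lengths)
    write_gff_fasta(sim$genes, file.path(config$outdir, "genomes.gff3"),
                    file.path(config$outdir, "proteins.faa"))
    utils::write.table(hits, file.path(config$outdir, "hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(domains, file.path(config$outdir, "domains.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(sim$truth, file.path(config$outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }

  if ("mine" %in% config$stages) {
    seeds <- marker_set(acr = scfg$acr_families[1])
    say("mine: search-validation loop seeded with ", scfg$acr_families[1])
    loop <- search_validation_loop(seeds, sim$genes, hits, domains,
                                   validator = validator_from_truth(sim$truth),
                                   params = params)
    results$loop <- loop
    write_candidates(loop$candidates[loop$candidates$qualifies, ],
                     file.path(config$outdir, "candidates.tsv"))
    labels <- map_hits_to_genes(hits, sim$genes, params$evalue_max,
                                params$coverage_min)
    assoc <- build_association_graph(sim$genes, labels, loop$markers, params)
    jsonlite::write_json(assoc$pairs,
                         file.path(config$outdir, "association_graph.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(loop$audit,
                         file.path(config$outdir, "loop_audit.json"),
                         auto_unbox = TRUE, digits = NA)
    say("mine: ", sum(loop$candidates$qualifies), " candidate calls, ",
        nrow(loop$markers$families), " marker families")
  }

  if ("phylo" %in% config$stages) {
    fam_sizes <- table(sim$truth$family[sim$truth$true_class == "acr"])
    fam <- names(fam_sizes)[which.max(fam_sizes)]
    ids <- sim$truth$gene_id[!is.na(sim$truth$family) &
                               sim$truth$family == fam &
                               sim$truth$true_class == "acr"]
    say("phylo: family ", fam, " (", length(ids), " members)")
    if (length(ids) >= 3L) {
      fp <- family_tree_pipeline(sim$proteins[ids])
      results$phylo <- fp
      write_newick(fp$tree, file.path(config$outdir,
                                      paste0("tree_", fam, ".nwk")))
      jsonlite::write_json(fp$audit,
                           file.path(config$outdir, "phylo_audit.json"),
                           auto_unbox = TRUE, digits = NA)
    } else {
      say("phylo: skipped (largest family has fewer than 3 members)")
    }
  }

  if ("quant" %in% config$stages) {
    acts <- config$assay$true_activities
    tabs <- lapply(seq_along(acts), function(i) {
      simulate_assay_counts(acts[[i]],
                            n_replicates = config$assay$n_replicates,
                            mean_cfu = config$assay$mean_cfu,
                            seed = config$seed + i,
                            acr_label = names(acts)[i])
    })
    assay_tab <- do.call(rbind, tabs)
    summary <- summarize_assays(assay_tab)
    results$assay <- summary
    con <- file(file.path(config$outdir, "assay_summary.tsv"), "w")
    writeLines(c("# inhibitory activity (%) = 100 * cfu_matching / cfu_mismatching, mean over replicates",
                 "# symbol: <=20 '-', (20,50] '+', (50,80] '++', >80 '+++', ND not determined"),
               con)
    suppressWarnings(utils::write.table(summary, con, sep = "\t",
                                        quote = FALSE, row.names = FALSE))
    close(con)
    say("quant: ", nrow(summary), " assay combinations summarized")
  }

  cfg_path <- file.path(config$outdir, "config.yaml")
  yaml::write_yaml(list(seed = config$seed, stages = config$stages,
                        sim = config$sim, miner = config$miner,
                        assay = lapply(config$assay, as.list)), cfg_path)
  provenance <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    package = "acrmine",
    package_version = as.character(utils::packageVersion("acrmine")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(provenance, file.path(config$outdir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(results)
}
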