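#' Default pipeline configuration
#'
#' All defaults follow the method's stated working parameters: 50 kb flank,
#' neighborhood radius `d = 2`, increment rate `r = 0.1`, minimum module
#' size 5, significant-gene SNP cut 0.05, 10,000 resamples, pathway size
#' bounds 5-300.
#'
#' @param assoc,loci,genotypes,edges,sets Input file paths.
#' @param out_dir Output directory.
#' @param method Gene-wise method: `"all"`, `"top"` or `"minp"`.
#' @param fraction Top fraction for `method = "top"`.
#' @param flank_kb Flank in kb for SNP-gene mapping.
#' @param d,r,min_size Module search parameters.
#' @param alpha Module significance threshold.
#' @param B Resample count for the gene-set evaluation.
#' @param p_cut Significant-gene SNP p-value cut.
#' @param set_min,set_max Pathway size bounds.
#' @param n_sims,max_sims Gene-score simulation schedule.
#' @param seed Master seed.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(assoc = NULL, loci = NULL, genotypes = NULL,
                            edges = NULL, sets = NULL, out_dir = "netdms_out",
                            method = "all", fraction = 0.10, flank_kb = 50,
                            d = 2L, r = 0.1, min_size = 5L, alpha = 0.05,
                            B = 10000L, p_cut = 0.05, set_min = 5L,
                            set_max = 300L, n_sims = 1000L, max_sims = 1e5,
                            seed = 1L) {
  as.list(environment())
}

read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: gene scoring, network construction, restricted
#' module search, empirical-null module significance, SNP-resampling
#' gene-set evaluation of the pooled significant-module genes alongside the
#' pathway collection, and hypergeometric pathway enrichment of the pooled
#' genes. Writes one output file per stage plus a JSON run manifest
#' (parameter snapshot, per-file md5 digests, stage timings and counts).
#' Any stage failure aborts with the stage name; input files are checked
#' before any stage runs.
#'
#' @param config Configuration list from [pipeline_config()], or the path
#'   to a YAML file with the same fields.
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  need <- c("assoc", "loci", "edges", "sets")
  if (config$method != "minp") need <- c(need, "genotypes")
  for (f in need) {
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop_netdms("missing input file for '", f, "'",
                  class = "netdms_config_error")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  M <- new.env(parent = emptyenv())   # manifest accumulator
  M$stages <- list()
  M$counts <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop_netdms("stage '", name, "' failed: ", conditionMessage(e),
                  class = "netdms_stage_error"))
    M$stages[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
    message("[", name, "] done in ", M$stages[[name]], "s")
    res
  }
  out_file <- function(x) file.path(config$out_dir, x)

  scores <- stage("gene_score", {
    assoc <- read_assoc(config$assoc)
    loci <- read_gene_loci(config$loci)
    geno <- if (config$method != "minp") read_genotypes(config$genotypes)
    map <- map_snps_to_genes(assoc, loci,
                             flank_bp = as.integer(config$flank_kb * 1000))
    sc <- score_genes(assoc, loci, geno, map = map, method = config$method,
                      fraction = config$fraction, n_sims = config$n_sims,
                      max_sims = config$max_sims, seed = config$seed)
    M$counts$n_snps <- nrow(assoc)
    M$counts$n_genes_scored <- nrow(sc)
    write_gene_scores(sc, out_file("gene_scores.tsv"))
    list(scores = sc, assoc = assoc, map = map)
  })

  net <- stage("network_build", {
    pairs <- read_edge_list(config$edges)
    g <- build_network(pairs, scores$scores)
    s <- network_summary(g)
    M$counts$n_nodes <- s$n_nodes
    M$counts$n_edges <- s$n_edges
    g
  })

  modules <- stage("module_search", {
    params <- search_params(d = config$d, r = config$r,
                            min_size = config$min_size)
    restricted_search(net, params)
  })
  M$counts$n_modules <- length(modules)

  sig <- stage("significance", {
    zm <- vapply(modules, `[[`, 0, "Zm")
    fit <- if (length(zm) >= 20) fit_empirical_null(zm) else null_fit_exact(zm)
    mods <- module_pvalues(modules, fit)
    write_modules(mods, out_file("modules.tsv"))
    sel <- select_significant(mods, alpha = config$alpha)
    M$counts$n_significant_modules <- length(sel$modules)
    M$counts$n_module_genes <- length(sel$genes)
    if (length(sel$genes))
      write_gmt(list(list(name = "module_genes",
                          description = paste0("pooled ", config$method),
                          genes = sel$genes)),
                out_file("module_genes.gmt"))
    sel
  })

  stage("gene_set_eval", {
    sets <- read_gmt(config$sets)
    extra <- if (length(sig$genes))
      list(list(name = "module_genes", description = "pooled",
                genes = sig$genes)) else list()
    res <- evaluate_gene_sets(scores$assoc, scores$map, sets,
                              extra_sets = extra, B = config$B,
                              p_cut = config$p_cut,
                              min_size = config$set_min,
                              max_size = config$set_max, seed = config$seed)
    utils::write.table(res, out_file("gene_set_eval.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res
  })

  stage("enrichment", {
    sets <- read_gmt(config$sets)
    universe <- igraph::V(net)$name
    genes_in <- intersect(sig$genes, universe)
    res <- if (length(genes_in))
      enrich_gene_sets(genes_in, sets, universe)
    else data.frame(set = character(0), size_in_universe = integer(0),
                    overlap = integer(0), p = numeric(0),
                    p_bonferroni = numeric(0))
    utils::write.table(res, out_file("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res
  })

  outs <- list.files(config$out_dir, full.names = TRUE)
  outs <- outs[!grepl("manifest[.]json$", outs)]
  manifest <- list(tool = "netdms",
                   version = as.character(utils::packageVersion("netdms")),
                   config = config,
                   stages = M$stages, counts = M$counts,
                   files = as.list(tools::md5sum(outs)))
  jsonlite::write_json(manifest, out_file("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
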