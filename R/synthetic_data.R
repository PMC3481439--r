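#' Configuration for the synthetic-data generator
#'
#' The defaults describe the stated test world: 500 autosomal genes with
#' log-normal lengths, 3-8 SNPs per gene in one exchangeable-correlation LD
#' block (latent rho 0.7), a 1000-sample reference panel, a
#' preferential-attachment interaction network, one planted 8-gene module
#' whose SNP statistics are shifted by 3, and a pathway collection
#' containing one set built around the planted genes.
#'
#' @param n_samples Reference-panel sample count.
#' @param n_genes Number of genes.
#' @param snps_per_gene Length-2 integer range of SNPs per gene.
#' @param ld_block_rho Exchangeable latent correlation within a gene's LD
#'   block, in `[0, 1)`.
#' @param pa_power,pa_m Preferential-attachment exponent and edges added
#'   per node for the network model.
#' @param planted_module_size Number of genes in the planted module.
#' @param planted_effect Mean shift of the causal SNP statistics.
#' @param background_null When `TRUE`, no module-level signal is planted.
#' @param polygenic_frac Fraction of SNPs, scattered genome-wide, carrying
#'   a weak dispersed effect (default 0 = complete null). Emulates the
#'   weak-to-moderate polygenic background of a real GWAS without creating
#'   any module-level structure.
#' @param polygenic_effect Absolute mean shift of the dispersed weak
#'   effects (random sign; default 1.5).
#' @param n_pathways Number of random pathway sets (the planted set is
#'   added on top).
#' @param seed Master seed; every generator derives substreams from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 1000L, n_genes = 500L,
                             snps_per_gene = c(3L, 8L), ld_block_rho = 0.7,
                             pa_power = 1, pa_m = 2L,
                             planted_module_size = 8L, planted_effect = 3,
                             background_null = FALSE, polygenic_frac = 0,
                             polygenic_effect = 1.5, n_pathways = 40L,
                             seed = 1L) {
  assert_that(n_samples > 1 && n_genes > 0, "sizes must be positive")
  assert_that(ld_block_rho >= 0 && ld_block_rho < 1, "rho must be in [0, 1)")
  assert_that(length(snps_per_gene) == 2 && snps_per_gene[1] >= 1 &&
                snps_per_gene[1] <= snps_per_gene[2],
              "snps_per_gene must be an increasing length-2 range")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 snps_per_gene = as.integer(snps_per_gene),
                 ld_block_rho = ld_block_rho, pa_power = pa_power,
                 pa_m = as.integer(pa_m),
                 planted_module_size = as.integer(planted_module_size),
                 planted_effect = planted_effect,
                 background_null = isTRUE(background_null),
                 polygenic_frac = polygenic_frac,
                 polygenic_effect = polygenic_effect,
                 n_pathways = as.integer(n_pathways),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate gene loci
#'
#' Genes are laid out round-robin over the 22 autosomes with log-normal
#' lengths (median ~20 kb) and inter-gene gaps larger than twice the
#' default 50 kb flank, so flanked gene windows never overlap and SNP-gene
#' mapping is unambiguous.
#'
#' @param config A `synthetic_config`.
#' @return Gene locus `data.frame` (`gene_id`, `chrom`, `start`, `end`).
#' @export
simulate_loci <- function(config) {
  with_seed(derive_seed(config$seed, "loci"), {
    n <- config$n_genes
    len <- pmax(500L, as.integer(round(stats::rlnorm(n, log(2e4), 1))))
    chrom <- rep(AUTOSOMES, length.out = n)
    start <- integer(n)
    cursor <- stats::setNames(rep(1e6, 22), AUTOSOMES)
    for (i in seq_len(n)) {
      start[i] <- as.integer(cursor[chrom[i]])
      cursor[chrom[i]] <- cursor[chrom[i]] + len[i] + 120000
    }
    data.frame(gene_id = sprintf("G%04d", seq_len(n)), chrom = chrom,
               start = start, end = start + len - 1L,
               stringsAsFactors = FALSE)
  })
}

#' Simulate LD-block reference genotypes
#'
#' One LD block per gene: each SNP draws a minor-allele frequency in
#' `[0.05, 0.5]`; two independent latent haplotype vectors per sample share
#' an exchangeable correlation `ld_block_rho` across the block's SNPs and
#' are thresholded at the allele-frequency quantile, so genotypes are the
#' sum of two Hardy-Weinberg alleles with within-block LD. Blocks are
#' independent across genes.
#'
#' @param config A `synthetic_config`.
#' @param loci Gene loci (default: [simulate_loci()] of the same config).
#' @return A `genotype_ref`; the attribute `snp_info` holds the SNP table
#'   (`snp_id`, `chrom`, `pos`, `gene_id`).
#' @export
simulate_genotypes <- function(config, loci = simulate_loci(config)) {
  n <- config$n_samples
  rho <- config$ld_block_rho
  with_seed(derive_seed(config$seed, "genotypes"), {
    # SNP count grows monotonically with gene length (roughly uniform SNP
    # density along the genome), which is what couples gene length to the
    # minimum-P bias in real data.
    len_rank <- rank(loci$end - loci$start, ties.method = "first")
    k_per <- config$snps_per_gene[1] +
      as.integer(round((len_rank - 1) / max(1L, nrow(loci) - 1L) *
                         diff(config$snps_per_gene)))
    blocks <- vector("list", nrow(loci))
    info <- vector("list", nrow(loci))
    for (i in seq_len(nrow(loci))) {
      k <- k_per[i]
      maf <- stats::runif(k, 0.05, 0.5)
      thr <- stats::qnorm(maf)
      g <- matrix(0L, n, k)
      for (hap in 1:2) {
        u <- stats::rnorm(n)
        H <- sqrt(rho) * u + sqrt(1 - rho) * matrix(stats::rnorm(n * k), n, k)
        g <- g + (H < rep(thr, each = n))
      }
      ids <- sprintf("rs%04d_%02d", i, seq_len(k))
      colnames(g) <- ids
      blocks[[i]] <- g
      pos <- sort(as.integer(round(seq(loci$start[i], loci$end[i],
                                       length.out = k + 2L)[2:(k + 1L)])))
      info[[i]] <- data.frame(snp_id = ids, chrom = loci$chrom[i], pos = pos,
                              gene_id = loci$gene_id[i],
                              stringsAsFactors = FALSE)
    }
    geno <- genotype_ref(do.call(cbind, blocks))
    attr(geno, "snp_info") <- do.call(rbind, info)
    geno
  })
}

# Planted-module gene ids, derived deterministically from the config seed so
# every generator agrees on them.
planted_genes <- function(config, gene_ids) {
  if (config$background_null || config$planted_module_size == 0 ||
      config$planted_effect == 0)
    return(character(0))
  assert_that(length(gene_ids) >= config$planted_module_size,
              "fewer genes than planted_module_size")
  with_seed(derive_seed(config$seed, "planted"),
            sort(sample(gene_ids, config$planted_module_size)))
}

#' Simulate SNP association p-values
#'
#' Each gene's SNP statistics are one draw from a multivariate normal with
#' the block's observed genotype correlation matrix, so the simulated test
#' statistics carry exactly the LD that [estimate_ld()] later recovers from
#' the same reference panel (with `ld_block_rho = 0` this reduces to
#' independent standard-normal draws). Causal SNPs — those inside planted
#' genes when planting is active — are shifted by `planted_effect`.
#' P-values are two-sided; marginally they are exactly uniform under the
#' null.
#'
#' @param config A `synthetic_config`.
#' @param geno Genotypes from [simulate_genotypes()] (needs the `snp_info`
#'   attribute).
#' @return SNP association `data.frame` (`snp_id`, `chrom`, `pos`,
#'   `p_value`), with attribute `causal_snps`.
#' @export
simulate_assoc <- function(config, geno) {
  info <- attr(geno, "snp_info")
  assert_that(!is.null(info), "geno must come from simulate_genotypes")
  planted <- planted_genes(config, unique(info$gene_id))
  with_seed(derive_seed(config$seed, "assoc"), {
    stats_all <- numeric(nrow(info))
    for (g in unique(info$gene_id)) {
      rows <- which(info$gene_id == g)
      ids <- info$snp_id[rows]
      G <- geno$matrix[, ids, drop = FALSE]
      C <- suppressWarnings(stats::cor(G))
      C[is.na(C)] <- 0
      diag(C) <- 1
      L <- mvn_factor(repair_psd(C))
      s <- as.vector(L %*% stats::rnorm(length(rows)))
      if (g %in% planted) s <- s + config$planted_effect
      stats_all[rows] <- s
    }
    if (config$polygenic_frac > 0) {
      hit <- stats::runif(nrow(info)) < config$polygenic_frac
      stats_all[hit] <- stats_all[hit] +
        sample(c(-1, 1), sum(hit), replace = TRUE) * config$polygenic_effect
    }
    p <- 2 * stats::pnorm(-abs(stats_all))
    p <- pmax(p, 1e-300)
    out <- data.frame(snp_id = info$snp_id, chrom = info$chrom,
                      pos = info$pos, p_value = p, stringsAsFactors = FALSE)
    attr(out, "causal_snps") <- info$snp_id[info$gene_id %in% planted]
    out
  })
}

#' Simulate a scale-free interaction network with a planted module
#'
#' Preferential-attachment graph over the gene ids (gene-to-vertex
#' assignment randomized), with the planted genes additionally wired into a
#' connected dense subgraph: a ring plus second-neighbor chords, so every
#' planted gene is adjacent to at least two (in fact four) other planted
#' genes. Returned as a raw pair list — duplicates possible, cleaning is
#' [build_network()]'s job.
#'
#' @param config A `synthetic_config`.
#' @param gene_ids Character vector of gene ids.
#' @return `data.frame` with columns `a`, `b`.
#' @export
simulate_network <- function(config, gene_ids) {
  n <- length(gene_ids)
  planted <- planted_genes(config, gene_ids)
  with_seed(derive_seed(config$seed, "network"), {
    g <- igraph::sample_pa(n, power = config$pa_power, m = config$pa_m,
                           directed = FALSE)
    lab <- sample(gene_ids)
    el <- igraph::as_edgelist(g, names = FALSE)
    pairs <- data.frame(a = lab[el[, 1]], b = lab[el[, 2]],
                        stringsAsFactors = FALSE)
    if (length(planted) >= 3) {
      m <- length(planted)
      ring <- data.frame(a = planted, b = planted[c(2:m, 1)],
                         stringsAsFactors = FALSE)
      chord <- data.frame(a = planted, b = planted[c(3:m, 1, 2)],
                          stringsAsFactors = FALSE)
      pairs <- rbind(pairs, ring, chord)
    }
    pairs
  })
}

#' Simulate pathway gene sets
#'
#' Random gene sets with sizes drawn between 5 and
#' `min(300, n_genes)`, plus — when planting is active — one set containing
#' every planted gene padded with random background genes.
#'
#' @param config A `synthetic_config`.
#' @param gene_ids Character vector of gene ids.
#' @param planted Planted gene ids (default: derived from the config).
#' @return Named list of gene sets (GMT-style records).
#' @export
simulate_pathways <- function(config, gene_ids,
                              planted = planted_genes(config, gene_ids)) {
  with_seed(derive_seed(config$seed, "pathways"), {
    max_sz <- min(300L, length(gene_ids))
    sizes <- sample(5:min(60L, max_sz), config$n_pathways, replace = TRUE)
    sets <- lapply(seq_len(config$n_pathways), function(i)
      list(name = sprintf("PW%03d", i), description = "random",
           genes = sort(sample(gene_ids, sizes[i]))))
    if (length(planted)) {
      pad_n <- min(max(0L, 20L - length(planted)),
                   length(setdiff(gene_ids, planted)))
      pad <- sample(setdiff(gene_ids, planted), pad_n)
      sets <- c(sets, list(list(name = "PW_planted",
                                description = "contains planted module",
                                genes = sort(c(planted, pad)))))
    }
    names(sets) <- vapply(sets, `[[`, "", "name")
    sets
  })
}

#' Generate a full synthetic dataset
#'
#' Runs every generator coherently from one config and optionally writes
#' all the pipeline input files (association table, gene loci, genotype
#' TSV, edge list, pathway GMT) to a directory.
#'
#' @param config A `synthetic_config`.
#' @param out_dir Optional output directory (created if needed).
#' @return List with `config`, `loci`, `geno`, `assoc`, `pairs`, `sets`,
#'   `planted`, and — when written — `files`.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  loci <- simulate_loci(config)
  geno <- simulate_genotypes(config, loci)
  assoc <- simulate_assoc(config, geno)
  pairs <- simulate_network(config, loci$gene_id)
  planted <- planted_genes(config, loci$gene_id)
  sets <- simulate_pathways(config, loci$gene_id, planted)
  out <- list(config = config, loci = loci, geno = geno, assoc = assoc,
              pairs = pairs, sets = sets, planted = planted)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f <- function(x) file.path(out_dir, x)
    utils::write.table(
      data.frame(SNP = assoc$snp_id, CHR = assoc$chrom, BP = assoc$pos,
                 P = assoc$p_value),
      f("assoc.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      stats::setNames(loci, c("gene", "chrom", "start", "end")),
      f("loci.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write_genotypes(geno, f("genotypes.tsv"))
    utils::write.table(pairs, f("edges.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    write_gmt(sets, f("pathways.gmt"))
    out$files <- list(assoc = f("assoc.tsv"), loci = f("loci.tsv"),
                      geno = f("genotypes.tsv"), edges = f("edges.tsv"),
                      sets = f("pathways.gmt"))
  }
  out
}
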