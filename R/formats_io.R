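#' Read a SNP association table
#'
#' Reads a whitespace- or tab-delimited association file in the PLINK
#' `.assoc` style. The header must contain the columns `SNP`, `CHR`, `BP`
#' and `P` (any order; extra columns are ignored). Rows whose `P` is
#' non-numeric or outside `(0, 1]` are rejected; the number of rejected rows
#' is reported via a message and attached as the `n_rejected` attribute.
#'
#' @param path Path to the association file.
#' @return A `data.frame` with columns `snp_id`, `chrom`, `pos`, `p_value`,
#'   with attribute `n_rejected`.
#' @export
read_assoc <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  need <- c("SNP", "CHR", "BP", "P")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    format_error("association file missing required column(s): ",
                 paste(miss, collapse = ", "))
  p <- suppressWarnings(as.numeric(tab$P))
  pos <- suppressWarnings(as.numeric(tab$BP))
  bad <- is.na(p) | p <= 0 | p > 1 | is.na(pos) | pos < 1
  out <- data.frame(snp_id = as.character(tab$SNP[!bad]),
                    chrom = norm_chrom(tab$CHR[!bad]),
                    pos = as.integer(pos[!bad]),
                    p_value = p[!bad],
                    stringsAsFactors = FALSE)
  dup <- duplicated(out$snp_id)
  if (any(dup))
    validation_error("duplicate SNP id(s): ",
                     paste(utils::head(unique(out$snp_id[dup]), 5), collapse = ", "))
  n_rej <- sum(bad)
  if (n_rej > 0)
    message("read_assoc: rejected ", n_rej, " row(s) with invalid P or BP")
  attr(out, "n_rejected") <- n_rej
  out
}

#' Read a gene locus table
#'
#' Four-column TSV (`gene`, `chrom`, `start`, `end`), 1-based fully closed
#' coordinates, with a header line.
#'
#' @param path Path to the locus file.
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_loci <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4)
    format_error("gene locus file must have 4 columns (gene, chrom, start, end)")
  out <- data.frame(gene_id = as.character(tab[[1]]),
                    chrom = norm_chrom(tab[[2]]),
                    start = as.integer(tab[[3]]),
                    end = as.integer(tab[[4]]),
                    stringsAsFactors = FALSE)
  assert_that(!anyNA(out$start) && !anyNA(out$end), "non-integer gene coordinates")
  assert_that(all(out$start >= 1), "gene start must be >= 1")
  assert_that(all(out$start <= out$end), "gene start must be <= end")
  dup <- duplicated(out$gene_id)
  if (any(dup))
    validation_error("duplicate gene id(s): ",
                     paste(utils::head(unique(out$gene_id[dup]), 5), collapse = ", "))
  out
}

#' Read a protein-protein interaction edge list
#'
#' Two-column TSV, one interaction per line, no header. The reader keeps the
#' raw pair list as-is (self-interactions and duplicates included, order
#' preserved); cleaning happens in [build_network()].
#'
#' @param path Path to the edge list.
#' @return `data.frame` with character columns `a`, `b`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "[\t ]+")
  nf <- lengths(parts)
  if (any(nf != 2))
    format_error("edge list line ", which(nf != 2)[1], " has ", nf[nf != 2][1],
                 " field(s); expected 2")
  data.frame(a = vapply(parts, `[`, "", 1),
             b = vapply(parts, `[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: set name, description, then member gene ids, tab-separated.
#' Duplicate gene ids within a line are collapsed.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of gene sets; each element is a list with `name`,
#'   `description` and the character vector `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      format_error("GMT line ", i, " has fewer than 3 fields")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) format_error("GMT line ", i, " has an empty gene list")
    list(name = f[1], description = f[2], genes = genes)
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets List of gene sets as returned by [read_gmt()], or a single
#'   named character vector wrapped as `list(list(name=, description=, genes=))`.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description %||% ".", s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a reference genotype matrix
#'
#' TSV dialect: first row = SNP ids, each subsequent row = one sample of
#' additive genotype codes in `{0, 1, 2}`; missing values coded `NA`.
#'
#' @param path Path to the genotype TSV.
#' @return A `genotype_ref` object: list with `snp_ids` and the samples x
#'   SNPs integer `matrix` (colnames = SNP ids).
#' @export
read_genotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           na.strings = "NA")
  m <- as.matrix(tab)
  mode(m) <- "numeric"
  bad <- !(m %in% c(0, 1, 2) | is.na(m))
  if (any(bad))
    format_error("genotype matrix contains codes outside {0,1,2,NA}")
  if (nrow(m) < 2) validation_error("genotype reference needs >= 2 samples")
  genotype_ref(m)
}

#' Construct a genotype reference object
#'
#' @param matrix Samples x SNPs numeric matrix of additive codes with column
#'   names giving the SNP ids.
#' @return A `genotype_ref` object.
#' @export
genotype_ref <- function(matrix) {
  assert_that(!is.null(colnames(matrix)), "genotype matrix must have SNP ids as colnames")
  structure(list(snp_ids = colnames(matrix), matrix = matrix),
            class = "genotype_ref")
}

#' Write a genotype reference to the package TSV dialect
#'
#' @param geno A `genotype_ref` object.
#' @param path Output path.
#' @export
write_genotypes <- function(geno, path) {
  utils::write.table(geno$matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Write scored modules to TSV
#'
#' Columns: `module_id`, `seed_gene`, `k`, `member_genes` (comma-joined,
#' sorted), `Zm`, and — when present on the module objects — `ZS` and
#' `p_module`. Rows are ordered by descending `Zm`, ties broken by seed gene
#' id, and `module_id` is assigned in that order (`M1`, `M2`, ...).
#'
#' @param modules List of module objects (see [grow_module()]).
#' @param path Output path.
#' @export
write_modules <- function(modules, path) {
  cols <- c("module_id", "seed_gene", "k", "member_genes", "Zm", "ZS", "p_module")
  if (!length(modules)) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  zm <- vapply(modules, `[[`, 0, "Zm")
  seeds <- vapply(modules, `[[`, "", "seed")
  o <- order(-zm, seeds)
  modules <- modules[o]
  rows <- vapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    paste(c(paste0("M", i), m$seed, length(m$members),
            paste(sort(m$members), collapse = ","),
            format_num(m$Zm),
            if (!is.null(m$ZS)) format_num(m$ZS) else "NA",
            if (!is.null(m$p_module)) format_num(m$p_module) else "NA"),
          collapse = "\t")
  }, "")
  writeLines(c(paste(cols, collapse = "\t"), rows), path)
  invisible(path)
}

#' Read back a module TSV written by [write_modules()]
#'
#' @param path Path to a module TSV.
#' @return List of module objects.
#' @export
read_modules <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!nrow(tab)) return(list())
  lapply(seq_len(nrow(tab)), function(i) {
    m <- list(seed = tab$seed_gene[i],
              members = strsplit(tab$member_genes[i], ",", fixed = TRUE)[[1]],
              Zm = tab$Zm[i])
    if ("ZS" %in% names(tab) && !is.na(tab$ZS[i])) m$ZS <- tab$ZS[i]
    if ("p_module" %in% names(tab) && !is.na(tab$p_module[i]))
      m$p_module <- tab$p_module[i]
    class(m) <- "netdms_module"
    m
  })
}

#' Write a gene score table
#'
#' @param scores Gene score `data.frame` from [score_genes()].
#' @param path Output path.
#' @export
write_gene_scores <- function(scores, path) {
  out <- scores
  for (cc in c("p_gene", "z")) out[[cc]] <- format_num(out[[cc]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene score table written by [write_gene_scores()]
#'
#' @param path Path to a gene score TSV.
#' @return Gene score `data.frame`.
#' @export
read_gene_scores <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$gene_id <- as.character(tab$gene_id)
  tab
}
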