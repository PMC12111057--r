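# Tab-separated readers/writers for the pipeline's table formats.
# Convention: strains (or samples) as rows, first column the strain ID.

#' Write an expression matrix as TSV
#'
#' @param expr An `expr_matrix` or plain strains x genes matrix.
#' @param path Output file; a companion `<path>.annotation.tsv` is written
#'   when gene annotation is present.
#' @export
write_expression_tsv <- function(expr, path) {
  values <- if (inherits(expr, "expr_matrix")) expr$values else expr
  df <- data.frame(strain = rownames(values), values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (inherits(expr, "expr_matrix") && !is.null(expr$annotation))
    utils::write.table(expr$annotation, paste0(path, ".annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' @param path TSV with strain IDs in the first column; a companion
#'   annotation file written by [write_expression_tsv()] is picked up
#'   automatically.
#' @param tissue Tissue label for the result.
#' @return An `expr_matrix`.
#' @export
read_expression_tsv <- function(path, tissue = "tissue1") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  ann_path <- paste0(path, ".annotation.tsv")
  annotation <- if (file.exists(ann_path))
    utils::read.table(ann_path, sep = "\t", header = TRUE,
                      colClasses = c("character", "character", "numeric"),
                      stringsAsFactors = FALSE)
  else NULL
  structure(list(values = values, annotation = annotation, tissue = tissue),
            class = "expr_matrix")
}

#' Write genotypes and map as TSV
#'
#' @param genotypes A `strain_geno`.
#' @param geno_path,map_path Output files.
#' @export
write_genotypes_tsv <- function(genotypes, geno_path, map_path) {
  df <- data.frame(strain = rownames(genotypes$geno), genotypes$geno,
                   check.names = FALSE)
  utils::write.table(df, geno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(genotypes$map), map_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(geno_path)
}

#' Read genotypes and map from TSV
#'
#' @param geno_path Genotype TSV (strain ID first column, then 0/1 marker
#'   columns).
#' @param map_path Map TSV with columns `marker`, `chr`, `pos_mb`.
#' @return A `strain_geno`.
#' @export
read_genotypes_tsv <- function(geno_path, map_path) {
  gdf <- utils::read.table(geno_path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  geno <- as.matrix(gdf[, -1, drop = FALSE])
  storage.mode(geno) <- "integer"
  rownames(geno) <- gdf[[1]]
  if (!all(geno %in% c(0L, 1L)))
    stop("genotypes must be coded 0/1 (homozygous RI panel)")
  mdf <- utils::read.table(map_path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character",
                                          "numeric"),
                           stringsAsFactors = FALSE)
  map <- genetic_map(mdf$marker, mdf$chr, mdf$pos_mb)
  geno <- geno[, map$marker, drop = FALSE]
  structure(list(geno = geno, map = map), class = "strain_geno")
}

#' Read a strain x trait table from TSV
#'
#' @param path TSV with strain IDs in the first column; empty cells / NA
#'   allowed.
#' @return Data frame with strain IDs as row names.
#' @export
read_traits_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  out <- df[, -1, drop = FALSE]
  rownames(out) <- df[[1]]
  out
}

#' Read a flat gene list (one symbol per line)
#'
#' @param path Path to the list file; blank lines and `#` comments are
#'   ignored.
#' @return Character vector of unique symbols.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Write a synthetic cohort to a directory
#'
#' Writes every component of a [simulate_cohort()] result as plain-text
#' tables: genotypes + map, one expression TSV per tissue, traits, the PPI
#' edge list, the autism gene list, and the case/control matrix with its
#' group labels.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_tsv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes_tsv(cohort$genotypes, file.path(dir, "genotypes.tsv"),
                      file.path(dir, "map.tsv"))
  for (t_ in names(cohort$expression))
    write_expression_tsv(cohort$expression[[t_]],
                         file.path(dir, paste0("expression_", t_, ".tsv")))
  utils::write.table(
    data.frame(strain = rownames(cohort$traits), cohort$traits,
               check.names = FALSE),
    file.path(dir, "traits.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  el <- igraph::as_edgelist(cohort$ppi$graph)
  utils::write.table(el, file.path(dir, "ppi_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(cohort$autism_genes, file.path(dir, "autism_genes.txt"))
  cc <- data.frame(sample = rownames(cohort$case_control$values),
                   cohort$case_control$values, check.names = FALSE)
  utils::write.table(cc, file.path(dir, "case_control.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = rownames(cohort$case_control$values),
               group = as.character(cohort$case_control$groups)),
    file.path(dir, "case_control_groups.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
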