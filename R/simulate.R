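#' Simulation configuration for a synthetic RI cohort
#'
#' Bundles the parameters of the synthetic-cohort generator: panel size,
#' genetic map, a focal gene with a cis-acting locus, co-expressed partner
#' genes with target correlations, traits genetically correlated with the
#' focal gene, and case/control differential-expression shifts.
#'
#' Defaults emulate a BXD-like brain-expression study: a panel of a few
#' dozen fully homozygous RI strains, a focal gene whose expression is
#' cis-regulated at its own locus, downstream co-expressed genes with
#' moderate-to-strong correlations, and traits with genetic correlations
#' around -0.4 to -0.65.
#'
#' @param n_strains Number of RI strains (>= 10).
#' @param map A [genetic_map()]; default [default_genetic_map()].
#' @param focal_gene Symbol of the focal gene.
#' @param focal_chr,focal_mb Genomic locus of the focal gene.
#' @param cis_effect Additive allele effect on focal expression
#'   (log2 expression units per D allele).
#' @param noise_sd Residual SD of focal-gene expression (log2 units).
#' @param planted_correlates Data frame with columns `gene` and `r`: partner
#'   genes constructed to have the given expected Pearson correlation with
#'   the focal gene.
#' @param planted_trait_correlations Data frame with columns `trait` and
#'   `r`: traits with the given expected correlation with focal expression.
#' @param n_background Number of independent background genes.
#' @param de_genes Data frame with columns `gene` and `shift` (case-group
#'   shift in within-group SD units) for the case/control generator.
#' @param seed Master seed; every generator derives its stream from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 60,
                       map = default_genetic_map(),
                       focal_gene = "Focal1",
                       focal_chr = "11", focal_mb = 70.44,
                       cis_effect = 0.45,
                       noise_sd = 0.3,
                       planted_correlates = data.frame(
                         gene = c("CorA", "CorB", "CorC"),
                         r = c(0.8, 0.6, -0.45)),
                       planted_trait_correlations = data.frame(
                         trait = c("trait_learning", "trait_ppi_startle",
                                   "trait_vocalization"),
                         r = c(-0.6, -0.5, -0.4)),
                       n_background = 1000,
                       de_genes = data.frame(gene = "CorA", shift = 2),
                       seed = 1L) {
  stopifnot(inherits(map, "genetic_map"))
  if (n_strains < 10) stop("n_strains must be >= 10")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (nrow(planted_correlates) > 0 && any(abs(planted_correlates$r) > 1))
    stop("target correlations must lie in [-1, 1]")
  if (nrow(planted_trait_correlations) > 0 &&
      any(abs(planted_trait_correlations$r) > 1))
    stop("target correlations must lie in [-1, 1]")
  if (!focal_chr %in% map$chr)
    stop("focal_chr not present on the map")
  cfg <- list(n_strains = as.integer(n_strains), map = map,
              focal_gene = focal_gene, focal_chr = as.character(focal_chr),
              focal_mb = focal_mb, cis_effect = cis_effect,
              noise_sd = noise_sd,
              planted_correlates = planted_correlates,
              planted_trait_correlations = planted_trait_correlations,
              n_background = as.integer(n_background),
              de_genes = de_genes, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic per-component seed streams derived from the master seed,
# kept below 2^31.
derive_seed <- function(seed, stream) {
  offsets <- c(genotypes = 101L, expression = 211L, traits = 307L,
               ppi = 401L, case_control = 503L, annotation = 601L)
  (as.integer(seed) * 7919L + offsets[[stream]]) %% 2147483647L
}

#' Simulate recombinant inbred genotypes
#'
#' Each strain is fully homozygous; marker alleles are coded 0 (B parent)
#' and 1 (D parent).  Chromosomes are simulated as Markov chains along the
#' map: the first marker is a fair coin flip, and the genotype switches
#' between adjacent markers with probability equal to the RI-expanded
#' recombination fraction R = 4r/(1+6r), where the per-meiosis fraction r
#' comes from the inter-marker distance via Haldane's map function.  Mb are
#' converted to cM at the mouse genome-wide average of 0.5 cM/Mb.
#'
#' @param config A [sim_config()].
#' @param cm_per_mb Conversion from physical to genetic distance
#'   (default 0.5 cM/Mb).
#' @return A list of class `strain_geno` with elements `geno` (strains x
#'   markers 0/1 matrix) and `map` (the [genetic_map()]).
#' @export
simulate_ri_genotypes <- function(config, cm_per_mb = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_strains
  if (n < 2) stop("need at least 2 strains")
  map <- config$map
  set.seed(derive_seed(config$seed, "genotypes"))
  geno <- matrix(0L, nrow = n, ncol = nrow(map),
                 dimnames = list(sprintf("RI%03d", seq_len(n)), map$marker))
  for (c_ in unique(map$chr)) {
    idx <- which(map$chr == c_)
    d_cm <- diff(map$pos_mb[idx]) * cm_per_mb
    r_switch <- ri_expansion(haldane_rf(d_cm))
    g <- matrix(0L, nrow = n, ncol = length(idx))
    g[, 1] <- as.integer(stats::runif(n) < 0.5)
    if (length(idx) > 1) {
      for (j in seq_along(r_switch)) {
        flip <- stats::runif(n) < r_switch[j]
        g[, j + 1] <- ifelse(flip, 1L - g[, j], g[, j])
      }
    }
    geno[, idx] <- g
  }
  structure(list(geno = geno, map = map), class = "strain_geno")
}

#' @export
print.strain_geno <- function(x, ...) {
  cat("RI strain genotypes:", nrow(x$geno), "strains x", ncol(x$geno),
      "markers on", length(unique(x$map$chr)), "chromosomes\n")
  invisible(x)
}

# Index of the map marker nearest to a genomic position.
nearest_marker <- function(map, chr, mb) {
  idx <- which(map$chr == as.character(chr))
  if (length(idx) == 0) stop("chromosome ", chr, " not on map")
  idx[which.min(abs(map$pos_mb[idx] - mb))]
}

# Planted-correlate construction: y = r * z(x) + sqrt(1 - r^2) * eps gives
# expected Pearson correlation exactly r with x; then rescaled.
planted_correlate <- function(x, r, mean_out = 8, sd_out = 0.4) {
  z <- as.numeric(scale(x))
  y0 <- r * z + sqrt(1 - r^2) * stats::rnorm(length(x))
  mean_out + sd_out * y0
}

#' Simulate a tissue expression matrix with planted structure
#'
#' The focal gene is `baseline + cis_effect * allele + N(0, noise_sd)` with
#' the allele taken at the map marker nearest the focal locus, giving it a
#' cis-eQTL.  Each planted correlate is constructed to have expected Pearson
#' correlation with the focal gene equal to its target; background genes are
#' independent noise.  All values sit on a log2-like scale centered near 8
#' (the 2Z+8 display convention).
#'
#' @param genotypes A `strain_geno` from [simulate_ri_genotypes()].
#' @param config A [sim_config()].
#' @param tissue Tissue label stored on the result.
#' @param baseline Focal-gene baseline expression (default 8).
#' @param gene_sd SD of correlate/background genes (default 0.4).
#' @param strains Optional subset of strain IDs to include (per-tissue
#'   strain subsets; default all strains).
#' @return A list of class `expr_matrix`: `values` (strains x genes),
#'   `annotation` (gene, chr, pos_mb), `tissue`.
#' @export
simulate_expression <- function(genotypes, config, tissue = "tissue1",
                                baseline = 8, gene_sd = 0.4,
                                strains = NULL) {
  stopifnot(inherits(genotypes, "strain_geno"), inherits(config, "sim_config"))
  if (nrow(config$planted_correlates) > 0 &&
      any(abs(config$planted_correlates$r) > 1))
    stop("target correlations must lie in [-1, 1]")
  map <- genotypes$map
  geno <- genotypes$geno
  if (!is.null(strains)) {
    missing_ids <- setdiff(strains, rownames(geno))
    if (length(missing_ids) > 0)
      stop("unknown strains: ", paste(missing_ids, collapse = ", "))
    geno <- geno[strains, , drop = FALSE]
  }
  n <- nrow(geno)
  # per-tissue stream so tissues differ but the run is reproducible
  set.seed((derive_seed(config$seed, "expression") +
              sum(utf8ToInt(tissue))) %% 2147483647L)
  focal_idx <- nearest_marker(map, config$focal_chr, config$focal_mb)
  x_allele <- geno[, focal_idx]
  focal_values <- baseline + config$cis_effect * x_allele +
    stats::rnorm(n, 0, config$noise_sd)

  cor_genes <- config$planted_correlates
  genes <- c(config$focal_gene, cor_genes$gene,
             if (config$n_background > 0)
               sprintf("Bg%04d", seq_len(config$n_background)))
  values <- matrix(NA_real_, nrow = n, ncol = length(genes),
                   dimnames = list(rownames(geno), genes))
  values[, 1] <- focal_values
  for (i in seq_len(nrow(cor_genes)))
    values[, 1 + i] <- planted_correlate(focal_values, cor_genes$r[i],
                                         mean_out = baseline, sd_out = gene_sd)
  n_bg <- config$n_background
  if (n_bg > 0)
    values[, nrow(cor_genes) + 1 + seq_len(n_bg)] <-
      matrix(stats::rnorm(n * n_bg, baseline, gene_sd), nrow = n)

  # gene annotation: focal at its stated locus, others placed uniformly
  set.seed(derive_seed(config$seed, "annotation"))
  chr_len <- tapply(map$pos_mb, map$chr, max)
  ann_chr <- sample(names(chr_len), length(genes), replace = TRUE)
  ann_pos <- round(stats::runif(length(genes)) * chr_len[ann_chr], 3)
  annotation <- data.frame(gene = genes, chr = as.character(ann_chr),
                           pos_mb = as.numeric(ann_pos),
                           stringsAsFactors = FALSE)
  annotation$chr[1] <- config$focal_chr
  annotation$pos_mb[1] <- config$focal_mb
  structure(list(values = values, annotation = annotation, tissue = tissue),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix [", x$tissue, "]: ", nrow(x$values), " strains x ",
      ncol(x$values), " genes\n", sep = "")
  invisible(x)
}

#' Simulate traits genetically correlated with a focal expression vector
#'
#' Each configured trait is constructed to have expected Pearson correlation
#' with `focal_values` equal to its target; additional null traits are
#' independent.  An optional missing-data rate masks strain values at
#' random, as in sparse phenome archives.
#'
#' @param focal_values Named numeric vector of focal-gene expression
#'   (names = strain IDs).
#' @param config A [sim_config()]; targets come from
#'   `config$planted_trait_correlations`.
#' @param n_null_traits Number of extra independent traits (default 0).
#' @param missing_rate Fraction of values masked as NA (default 0).
#' @param trait_mean,trait_sd Scale of the simulated phenotype values.
#' @return A data frame (strains x traits) with strain IDs as row names.
#' @export
simulate_traits <- function(focal_values, config, n_null_traits = 0,
                            missing_rate = 0, trait_mean = 50,
                            trait_sd = 10) {
  if (length(focal_values) < 3) stop("need at least 3 strains")
  tgt <- config$planted_trait_correlations
  if (nrow(tgt) > 0 && any(abs(tgt$r) > 1))
    stop("target correlations must lie in [-1, 1]")
  set.seed(derive_seed(config$seed, "traits"))
  n <- length(focal_values)
  traits <- c(tgt$trait,
              if (n_null_traits > 0) sprintf("null_%03d", seq_len(n_null_traits)))
  out <- matrix(NA_real_, nrow = n, ncol = length(traits),
                dimnames = list(names(focal_values), traits))
  for (i in seq_len(nrow(tgt)))
    out[, i] <- planted_correlate(focal_values, tgt$r[i],
                                  mean_out = trait_mean, sd_out = trait_sd)
  if (n_null_traits > 0)
    out[, nrow(tgt) + seq_len(n_null_traits)] <-
      matrix(stats::rnorm(n * n_null_traits, trait_mean, trait_sd), nrow = n)
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(length(out)) < missing_rate, nrow = n)
    out[mask] <- NA_real_
  }
  as.data.frame(out)
}

#' Simulate a PPI graph with a planted ego neighborhood
#'
#' The focal gene is adjacent to exactly `planted_primary`; each
#' `planted_secondary` node attaches to one primary node (round-robin, so
#' every primary receives a secondary when there are enough), and never to
#' the focal gene.  Background edges are drawn among the remaining,
#' non-focal non-primary nodes so they cannot enlarge the radius-2 ego set.
#'
#' @param genes Node symbols.
#' @param focal Focal gene symbol (must be in `genes`).
#' @param planted_primary,planted_secondary Disjoint subsets of `genes`.
#' @param n_background_edges Random edges outside the ego neighborhood.
#' @param seed Integer seed.
#' @return A list of class `ppi_graph`: `graph` (igraph), `focal`.
#' @export
simulate_ppi <- function(genes, focal, planted_primary = character(),
                         planted_secondary = character(),
                         n_background_edges = 30, seed = 1L) {
  if (!focal %in% genes) stop("focal gene not in gene list")
  if (length(intersect(planted_primary, planted_secondary)) > 0)
    stop("planted_primary and planted_secondary must be disjoint")
  stopifnot(all(c(planted_primary, planted_secondary) %in% genes),
            !focal %in% c(planted_primary, planted_secondary))
  set.seed(seed)
  edges <- character(0)
  if (length(planted_primary) > 0)
    edges <- c(edges, rbind(focal, planted_primary))
  if (length(planted_secondary) > 0) {
    if (length(planted_primary) == 0)
      stop("secondary interactors require at least one primary interactor")
    host <- planted_primary[(seq_along(planted_secondary) - 1) %%
                              length(planted_primary) + 1]
    edges <- c(edges, rbind(host, planted_secondary))
  }
  pool <- setdiff(genes, c(focal, planted_primary))
  if (n_background_edges > 0 && length(pool) >= 2) {
    for (k in seq_len(n_background_edges)) {
      pair <- sample(pool, 2)
      edges <- c(edges, pair)
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(genes)
  if (length(edges) > 0)
    g <- igraph::add_edges(g, match(edges, genes))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  structure(list(graph = g, focal = focal), class = "ppi_graph")
}

#' Simulate a two-group case/control expression matrix
#'
#' Genes are i.i.d. normal across samples; `de_genes` are shifted in the
#' case group by the stated number of within-group SD units.
#'
#' @param genes Gene symbols.
#' @param de_genes Data frame with columns `gene`, `shift` (SD units).
#' @param n_per_group Samples per group (>= 3).
#' @param noise_sd Within-group SD (default 1, log2-like units).
#' @param baseline Mean expression (default 8).
#' @param seed Integer seed.
#' @return List with `values` (samples x genes matrix) and `groups`
#'   (factor, levels case/control).
#' @export
simulate_case_control <- function(genes, de_genes = NULL, n_per_group = 8,
                                  noise_sd = 1, baseline = 8, seed = 1L) {
  if (n_per_group < 3) stop("n_per_group must be >= 3")
  if (!is.null(de_genes) && nrow(de_genes) > 0) {
    unknown <- setdiff(de_genes$gene, genes)
    if (length(unknown) > 0)
      stop("shift specified for unknown gene(s): ",
           paste(unknown, collapse = ", "))
  }
  set.seed(seed)
  n <- 2L * n_per_group
  values <- matrix(stats::rnorm(n * length(genes), baseline, noise_sd),
                   nrow = n,
                   dimnames = list(c(sprintf("case_%02d", seq_len(n_per_group)),
                                     sprintf("ctrl_%02d", seq_len(n_per_group))),
                                   genes))
  groups <- factor(rep(c("case", "control"), each = n_per_group),
                   levels = c("case", "control"))
  if (!is.null(de_genes) && nrow(de_genes) > 0)
    for (i in seq_len(nrow(de_genes)))
      values[groups == "case", de_genes$gene[i]] <-
        values[groups == "case", de_genes$gene[i]] +
        de_genes$shift[i] * noise_sd
  list(values = values, groups = groups)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running every generator with one master seed:
#' genotypes, expression in each named tissue, traits, a PPI graph whose
#' primary interactors are the planted correlates, an autism-annotation
#' list, and a case/control expression set.
#'
#' @param config A [sim_config()].
#' @param tissues Character vector of tissue labels (default the four brain
#'   regions of a BXD brain survey).
#' @param autism_genes Genes flagged as autism-annotated (default: the
#'   planted correlates).
#' @return A list with elements `genotypes`, `expression` (named list of
#'   `expr_matrix`), `traits`, `ppi`, `autism_genes`, `case_control`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            tissues = c("amygdala", "cerebellum",
                                        "hippocampus", "prefrontal_cortex"),
                            autism_genes = config$planted_correlates$gene) {
  genotypes <- simulate_ri_genotypes(config)
  expression <- lapply(tissues, function(t_)
    simulate_expression(genotypes, config, tissue = t_))
  names(expression) <- tissues
  focal_values <- expression[[1]]$values[, config$focal_gene]
  traits <- simulate_traits(focal_values, config, n_null_traits = 20)
  genes <- expression[[1]]$annotation$gene
  primary <- config$planted_correlates$gene
  secondary <- utils::head(grep("^Bg", genes, value = TRUE),
                           max(2L, length(primary)))
  ppi <- simulate_ppi(genes, config$focal_gene, planted_primary = primary,
                      planted_secondary = secondary,
                      seed = derive_seed(config$seed, "ppi"))
  case_control <- simulate_case_control(
    genes, de_genes = config$de_genes, n_per_group = 8,
    seed = derive_seed(config$seed, "case_control"))
  list(genotypes = genotypes, expression = expression, traits = traits,
       ppi = ppi, autism_genes = autism_genes, case_control = case_control)
}
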