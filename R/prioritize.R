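#' Evidence components for one candidate gene
#'
#' The four evidence channels entering the composite score: connectivity in
#' the focal gene's PPI ego network, the number of tissues where the gene
#' is correlated with the focal gene at p < 0.05, membership in an
#' autism-annotation list, and a cross-cohort differential-expression flag.
#'
#' @param gene Gene symbol.
#' @param ppi_degree Node degree in the interactor network (>= 0).
#' @param n_tissues_correlated Count of tissues with correlation p < 0.05
#'   (0 .. number of tissues).
#' @param autism_annotated Logical flag.
#' @param differentially_expressed Logical flag.
#' @return One-row data frame of class `evidence_components`.
#' @export
evidence_components <- function(gene, ppi_degree, n_tissues_correlated,
                                autism_annotated, differentially_expressed) {
  if (any(ppi_degree < 0) || any(n_tissues_correlated < 0))
    stop("counts must be non-negative")
  out <- data.frame(gene = gene, ppi_degree = as.integer(ppi_degree),
                    n_tissues_correlated = as.integer(n_tissues_correlated),
                    autism_annotated = as.logical(autism_annotated),
                    differentially_expressed =
                      as.logical(differentially_expressed),
                    stringsAsFactors = FALSE)
  class(out) <- c("evidence_components", "data.frame")
  out
}

#' Composite candidate score (0-5)
#'
#' The weighted composite over four evidence channels:
#' \itemize{
#'   \item PPI degree > 1: 1 point;
#'   \item correlated (p < 0.05) with the focal gene in at least one
#'     tissue: 2 points (flat, regardless of how many tissues);
#'   \item autism-annotated: 1 point;
#'   \item differentially expressed in any case/control cohort: 1 point.
#' }
#' Candidates are selected at total >= 4 (80 percent of the maximum).
#'
#' @param components An `evidence_components` data frame (one or more
#'   rows).
#' @return Data frame of class `score_card`: the component columns plus
#'   `degree_score`, `tissue_score`, `autism_score`, `de_score`, `total`,
#'   `selected`.
#' @export
#' @examples
#' score_gene(evidence_components("Dnmt3a", 4, 3, TRUE, TRUE))$total  # 5
score_gene <- function(components) {
  stopifnot(is.data.frame(components))
  if (any(components$ppi_degree < 0) ||
      any(components$n_tissues_correlated < 0))
    stop("counts must be non-negative")
  out <- as.data.frame(components)
  out$degree_score <- as.integer(out$ppi_degree > 1)
  out$tissue_score <- 2L * as.integer(out$n_tissues_correlated >= 1)
  out$autism_score <- as.integer(out$autism_annotated)
  out$de_score <- as.integer(out$differentially_expressed)
  out$total <- out$degree_score + out$tissue_score + out$autism_score +
    out$de_score
  out$selected <- out$total >= 4L
  class(out) <- c("score_card", "data.frame")
  out
}

#' Assemble evidence components for an interactor gene
#'
#' The scoring universe is the focal gene's interactor set: genes outside
#' it are an error.  Tissue p-values come from per-tissue correlation
#' screens, the autism flag from a user-supplied annotation list, and the
#' DE flag from [overlap_with_interactors()].
#'
#' @param gene Gene symbol (must be a primary or secondary interactor).
#' @param interactors An `interactor_set` from [ego_interactors()].
#' @param tissue_pvalues Named numeric vector: correlation p-value of
#'   `gene` vs the focal gene per tissue (NA = not expressed there).
#' @param autism_list Character vector of autism-annotated symbols.
#' @param de_flags Named logical vector from [overlap_with_interactors()].
#' @param p_max Tissue-correlation significance level (default 0.05).
#' @return An `evidence_components` row.
#' @export
build_components <- function(gene, interactors, tissue_pvalues, autism_list,
                             de_flags, p_max = 0.05) {
  members <- c(interactors$primary, interactors$secondary)
  if (!gene %in% members)
    stop("gene ", gene, " is not a primary or secondary interactor; ",
         "the scoring universe is the interactor set")
  evidence_components(
    gene = gene,
    ppi_degree = unname(interactors$degrees[gene]),
    n_tissues_correlated = sum(tissue_pvalues < p_max, na.rm = TRUE),
    autism_annotated = gene %in% autism_list,
    differentially_expressed = isTRUE(unname(de_flags[gene])))
}

#' Select strong candidates from score cards
#'
#' @param cards A `score_card` data frame from [score_gene()].
#' @param min_total Selection threshold (default 4).
#' @return The selected rows, sorted by total descending then symbol.
#' @export
select_candidates <- function(cards, min_total = 4) {
  if (nrow(cards) == 0) return(cards)
  out <- cards[cards$total >= min_total, , drop = FALSE]
  out <- out[order(-out$total, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end candidate prioritization
#'
#' Runs the whole evidence pipeline on one cohort: per-tissue correlation
#' of every interactor gene with the focal gene, interactor extraction and
#' degrees from the PPI graph, the cross-cohort DE disjunction, and the
#' composite score with selection at `min_total`.  Optionally also maps the
#' focal gene's eQTL (reported in the manifest, not scored).
#'
#' @param expression Named list of `expr_matrix` objects (one per tissue).
#' @param ppi A `ppi_graph` whose focal gene is the study's focal gene.
#' @param autism_list Character vector of autism-annotated symbols.
#' @param de_tables List of `de_table` data frames (case/control cohorts).
#' @param genotypes Optional `strain_geno` for the focal-gene eQTL scan.
#' @param focal Focal gene symbol (default the PPI graph's focal).
#' @param p_max Tissue-correlation significance level (default 0.05).
#' @param min_total Selection threshold (default 4).
#' @param cis_window cis window in Mb for the focal eQTL call (default 10).
#' @return List of class `prioritization`: `scores` (all interactors),
#'   `selected`, `interactors`, `focal_eqtl` (an `eqtl_call` or NULL),
#'   `manifest` (thresholds and input sizes).
#' @export
run_prioritization <- function(expression, ppi, autism_list, de_tables,
                               genotypes = NULL, focal = ppi$focal,
                               p_max = 0.05, min_total = 4,
                               cis_window = 10) {
  interactors <- ego_interactors(ppi)
  members <- c(interactors$primary, interactors$secondary)
  de_flags <- overlap_with_interactors(de_tables, genes = members)

  tissue_p <- sapply(names(expression), function(t_) {
    values <- expression[[t_]]$values
    vapply(members, function(g) {
      if (!g %in% colnames(values)) return(NA_real_)
      tryCatch(pearson(values[, focal], values[, g])$p,
               error = function(e) NA_real_)
    }, numeric(1))
  })
  tissue_p <- matrix(tissue_p, nrow = length(members),
                     dimnames = list(members, names(expression)))

  comps <- do.call(rbind, lapply(members, function(g)
    build_components(g, interactors, tissue_p[g, ], autism_list, de_flags,
                     p_max = p_max)))
  scores <- score_gene(comps)
  scores <- scores[order(-scores$total, scores$gene), , drop = FALSE]
  rownames(scores) <- NULL

  focal_eqtl <- NULL
  if (!is.null(genotypes)) {
    expr1 <- expression[[1]]
    y <- expr1$values[, focal]
    scan <- lmm_scan(y, genotypes, loco = TRUE)
    ann <- expr1$annotation[expr1$annotation$gene == focal, ]
    focal_eqtl <- classify_eqtl(scan, ann$chr[1], ann$pos_mb[1],
                                cis_window = cis_window)
  }

  structure(list(
    scores = scores,
    selected = select_candidates(scores, min_total = min_total),
    interactors = interactors,
    focal_eqtl = focal_eqtl,
    manifest = list(focal = focal, tissues = names(expression),
                    n_interactors = length(members),
                    n_de_tables = length(de_tables),
                    p_max = p_max, min_total = min_total,
                    cis_window = cis_window)),
    class = "prioritization")
}

#' @export
print.prioritization <- function(x, ...) {
  cat("Candidate prioritization for focal gene", x$manifest$focal, "\n")
  cat("  interactor universe:", x$manifest$n_interactors, "genes\n")
  if (!is.null(x$focal_eqtl))
    cat("  focal eQTL:", x$focal_eqtl$classification, "\n")
  cat("  selected (total >=", x$manifest$min_total, "):",
      nrow(x$selected), "gene(s)\n")
  if (nrow(x$selected) > 0)
    print(x$selected[, c("gene", "ppi_degree", "n_tissues_correlated",
                         "autism_annotated", "differentially_expressed",
                         "total")])
  invisible(x)
}
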