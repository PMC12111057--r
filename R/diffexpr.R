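#' Two-group differential expression (Welch t)
#'
#' Per-gene Welch two-sample t-test (unequal variances) between case and
#' control samples, two-sided, with Benjamini-Hochberg FDR across genes.
#' Genes with zero variance in both groups are reported with p = 1.
#' Computation is matrix-wise; it matches [stats::t.test()] gene by gene.
#'
#' @param values Samples x genes numeric matrix (log2 scale).
#' @param groups Factor or character vector over samples with values
#'   "case"/"control"; each group needs >= 3 samples.
#' @param fdr_max Significance threshold on the FDR scale (default 0.1).
#' @return Data frame of class `de_table`, one row per gene, sorted by p:
#'   `gene`, `mean_diff` (case - control, log2 units), `t`, `df`, `p`,
#'   `fdr`, `significant`, `direction` ("up"/"down" in cases).
#' @export
de_test <- function(values, groups, fdr_max = 0.1) {
  groups <- as.character(groups)
  unknown <- setdiff(unique(groups), c("case", "control"))
  if (length(unknown) > 0)
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  if (length(groups) != nrow(values))
    stop("groups must label every sample row")
  n1 <- sum(groups == "case")
  n2 <- sum(groups == "control")
  if (n1 < 3 || n2 < 3) stop("each group needs at least 3 samples")
  a <- values[groups == "case", , drop = FALSE]
  b <- values[groups == "control", , drop = FALSE]
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- apply(a, 2, stats::var); v2 <- apply(b, 2, stats::var)
  diff <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  t <- ifelse(se2 > 0, diff / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t), df), 1)
  out <- data.frame(gene = colnames(values), mean_diff = diff, t = t,
                    df = df, p = p, fdr = bh_fdr(p),
                    stringsAsFactors = FALSE)
  out$significant <- out$fdr < fdr_max
  out$direction <- ifelse(out$mean_diff >= 0, "up", "down")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

#' Differential-expression flag across cohorts
#'
#' A gene is flagged if it is significant in ANY of the supplied DE tables
#' (the disjunction across tissues/cohorts used when combining human
#' case/control comparisons).  Genes absent from a table count as not
#' significant there.
#'
#' @param de_tables List of `de_table` data frames from [de_test()].
#' @param genes Genes to flag (default: union of all table genes); an
#'   `interactor_set` may be given, in which case its primary and
#'   secondary members are used.
#' @return Named logical vector over `genes`.
#' @export
overlap_with_interactors <- function(de_tables, genes = NULL) {
  if (length(de_tables) == 0) stop("need at least one DE table")
  if (inherits(genes, "interactor_set"))
    genes <- c(genes$primary, genes$secondary)
  if (is.null(genes))
    genes <- unique(unlist(lapply(de_tables, function(t_) t_$gene)))
  flag <- stats::setNames(rep(FALSE, length(genes)), genes)
  for (t_ in de_tables) {
    sig <- t_$gene[t_$significant]
    flag[genes %in% sig] <- TRUE
  }
  flag
}
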