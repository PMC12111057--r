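#' Pearson correlation with pairwise-complete deletion
#'
#' Product-moment correlation between two vectors after dropping pairs
#' with a missing value in either; the two-sided p-value comes from
#' `t = r * sqrt(n-2) / sqrt(1-r^2)` on n-2 degrees of freedom, as in the
#' GeneNetwork correlation tools.
#'
#' @param x,y Numeric vectors of equal length; NAs allowed.
#' @return A one-row data frame: `r`, `n` (complete pairs), `p`.
#' @export
#' @examples
#' pearson(1:5, c(2, 1, 4, 3, 6))  # r = 0.8220
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) stop("fewer than 3 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("correlation undefined for a constant vector")
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                        alternative = "two.sided")
  data.frame(r = unname(ct$estimate), n = n, p = ct$p.value)
}

#' Transcriptome-wide correlation screen against a focal gene
#'
#' Correlates the focal gene with every other gene in an expression matrix
#' and keeps the partners passing the co-expression screen:
#' `|r| >= r_min`, `p < p_max`, and partner mean expression `>= mean_min`.
#' Duplicate symbols (multiple probes) are collapsed beforehand by keeping
#' the column with the larger mean.  The focal gene never appears in its
#' own list.
#'
#' @param expr An `expr_matrix` (or plain strains x genes matrix).
#' @param focal Focal gene symbol.
#' @param r_min Minimum absolute correlation (default 0.3).
#' @param p_max Maximum p-value (default 0.05; no multiplicity correction —
#'   this screen is deliberately inclusive).
#' @param mean_min Minimum partner mean expression on the 2Z+8 scale
#'   (default 7.1, the conventional "expressed" floor).
#' @return Data frame sorted by p: `partner`, `r`, `n`, `p`,
#'   `partner_mean`.
#' @export
correlated_genes <- function(expr, focal, r_min = 0.3, p_max = 0.05,
                             mean_min = 7.1) {
  values <- if (inherits(expr, "expr_matrix")) expr$values else expr
  if (!focal %in% colnames(values)) stop("focal gene ", focal,
                                         " absent from expression matrix")
  means <- colMeans(values, na.rm = TRUE)
  # collapse duplicate probe columns per symbol by max mean
  if (anyDuplicated(colnames(values)) > 0) {
    keep <- vapply(split(seq_len(ncol(values)), colnames(values)),
                   function(ix) ix[which.max(means[ix])], integer(1))
    values <- values[, sort(keep), drop = FALSE]
    means <- colMeans(values, na.rm = TRUE)
  }
  focal_values <- values[, focal]
  partners <- setdiff(colnames(values), focal)
  rows <- lapply(partners, function(g) {
    res <- tryCatch(pearson(focal_values, values[, g]),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    cbind(data.frame(partner = g, stringsAsFactors = FALSE), res,
          data.frame(partner_mean = means[[g]]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(partner = character(), r = numeric(), n = integer(),
                      p = numeric(), partner_mean = numeric()))
  out <- out[abs(out$r) >= r_min & out$p < p_max & out$partner_mean >= mean_min,
             , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlate a focal expression vector with a trait panel
#'
#' One Pearson correlation per trait, using pairwise-complete strains.
#' Traits with fewer than 3 complete pairs (or constant values) are
#' skipped, not errors — phenome archives are sparse.
#'
#' @param focal_values Named numeric vector (names = strain IDs).
#' @param traits Data frame of traits (strains x traits, strain IDs as row
#'   names, NAs allowed).
#' @return Data frame: `trait`, `r`, `n`, `p`, sorted by p; skipped traits
#'   are listed in the `"skipped"` attribute.
#' @export
trait_correlations <- function(focal_values, traits) {
  if (ncol(traits) == 0) stop("empty trait table")
  common <- intersect(names(focal_values), rownames(traits))
  if (length(common) < 3) stop("fewer than 3 strains shared with trait table")
  skipped <- character(0)
  rows <- lapply(colnames(traits), function(tr) {
    res <- tryCatch(pearson(focal_values[common], traits[common, tr]),
                    error = function(e) NULL)
    if (is.null(res)) {
      skipped <<- c(skipped, tr)
      return(NULL)
    }
    cbind(data.frame(trait = tr, stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(trait = character(), r = numeric(), n = integer(),
                      p = numeric())
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Cross-tissue membership filter and overlap partition
#'
#' Given per-tissue gene lists (e.g. the per-region co-expression screens),
#' returns the genes present in at least `min_tissues` lists, plus the full
#' Venn partition (counts per membership pattern).
#'
#' @param lists Named list of character vectors.
#' @param min_tissues Minimum number of lists a gene must appear in
#'   (default 3, i.e. "at least three of four brain regions").
#' @return List with `genes` (sorted character vector) and `venn` (data
#'   frame: membership `pattern`, `count`); partition counts sum to the
#'   size of the union.
#' @export
cross_tissue_membership <- function(lists, min_tissues = 3) {
  if (min_tissues > length(lists))
    stop("min_tissues exceeds the number of lists supplied")
  if (is.null(names(lists)))
    names(lists) <- paste0("list", seq_along(lists))
  lists <- lapply(lists, unique)
  all_genes <- sort(unique(unlist(lists)))
  member <- vapply(lists, function(l) all_genes %in% l,
                   logical(length(all_genes)))
  member <- matrix(member, nrow = length(all_genes),
                   dimnames = list(all_genes, names(lists)))
  counts <- rowSums(member)
  pattern <- apply(member, 1, function(m)
    paste(names(lists)[m], collapse = "&"))
  venn <- as.data.frame(table(pattern = pattern), stringsAsFactors = FALSE)
  names(venn) <- c("pattern", "count")
  list(genes = all_genes[counts >= min_tissues], venn = venn)
}
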