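#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment (via [stats::p.adjust()]) with input validation:
#' all p-values must lie in (0, 1].  Order of inputs is preserved.
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Adjusted q-values, same order and length.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `set ID`,
#' `description`, then member symbols.  Duplicate members within a line
#' are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A named list of class `gene_set_collection`; each element has
#'   `description` and `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    sets[[fields[1]]] <- list(description = fields[2],
                              genes = unique(fields[-(1:2)]))
  }
  structure(sets, class = "gene_set_collection")
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected given the reference universe: upper-tail hypergeometric
#' `p = P(X >= x)` with `x` the overlap, `K` the set size within the
#' reference, `n` the query size, `N` the reference size.  Sets smaller
#' than `min_size` within the reference are dropped before testing; BH FDR
#' is computed across the tested sets.
#'
#' @param query Character vector of query gene symbols (must be a subset of
#'   `reference`).
#' @param reference Character vector: the reference universe (e.g. all
#'   genes on the platform).
#' @param sets A `gene_set_collection` from [read_gmt()] (or a named list
#'   of character vectors).
#' @param min_size Minimum set size within the reference (default 5).
#' @param fdr_max Significance threshold on the FDR scale (default 0.1).
#' @return Data frame sorted by p (ties: larger enrichment ratio, then set
#'   ID): `set`, `description`, `x`, `n`, `K`, `N`, `enrichment_ratio`
#'   (`(x/n)/(K/N)`), `p`, `fdr`, `significant`.
#' @export
ora <- function(query, reference, sets, min_size = 5, fdr_max = 0.1) {
  query <- unique(query)
  reference <- unique(reference)
  offenders <- setdiff(query, reference)
  if (length(offenders) > 0)
    stop("query genes absent from reference: ",
         paste(offenders, collapse = ", "))
  if (length(reference) < 2) stop("reference universe too small")
  N <- length(reference)
  n <- length(query)
  rows <- lapply(names(sets), function(id) {
    s <- sets[[id]]
    genes <- if (is.list(s)) s$genes else s
    desc <- if (is.list(s) && !is.null(s$description)) s$description else ""
    members <- intersect(unique(genes), reference)
    K <- length(members)
    if (K < min_size) return(NULL)
    x <- length(intersect(members, query))
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = id, description = desc, x = x, n = n, K = K, N = N,
               enrichment_ratio = (x / n) / (K / N), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set = character(), description = character(),
                      x = integer(), n = integer(), K = integer(),
                      N = integer(), enrichment_ratio = numeric(),
                      p = numeric(), fdr = numeric(),
                      significant = logical()))
  out$fdr <- bh_fdr(out$p)
  out$significant <- out$fdr < fdr_max
  out <- out[order(out$p, -out$enrichment_ratio, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
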