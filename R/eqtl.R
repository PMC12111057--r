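#' Marker-based kinship matrix
#'
#' Centered relatedness matrix `K = (1/M) * sum_m (x_m - xbar_m)(x_m -
#' xbar_m)'` over the M retained markers (the "centered" estimator used by
#' GEMMA).  With leave-one-chromosome-out (LOCO) mapping, the tested
#' marker's chromosome is excluded so the polygenic term does not absorb
#' the local signal.
#'
#' @param genotypes A `strain_geno` (see [simulate_ri_genotypes()]), or any
#'   list with elements `geno` (strains x markers 0/1 matrix) and `map`.
#' @param exclude_chromosome Chromosome label to leave out, or NULL.
#' @return A symmetric positive semi-definite strains x strains matrix with
#'   attribute `"excluded_chromosome"`.
#' @export
kinship_matrix <- function(genotypes, exclude_chromosome = NULL) {
  geno <- genotypes$geno
  map <- genotypes$map
  keep <- rep(TRUE, ncol(geno))
  if (!is.null(exclude_chromosome))
    keep <- map$chr != as.character(exclude_chromosome)
  if (sum(keep) < 2)
    stop("fewer than 2 markers remain after excluding chromosome ",
         exclude_chromosome)
  X <- scale(geno[, keep, drop = FALSE], center = TRUE, scale = FALSE)
  K <- tcrossprod(X) / ncol(X)
  dimnames(K) <- list(rownames(geno), rownames(geno))
  attr(K, "excluded_chromosome") <- exclude_chromosome
  K
}

# Profile ML log-likelihood of the rotated model at variance ratio
# delta = sigma_g^2 / sigma_e^2, with beta and sigma_e^2 profiled out.
# ys, Xs are U' y and U' X where K = U diag(lambda) U'.
lmm_profile_ll <- function(delta, lambda, ys, Xs) {
  w <- 1 / (lambda * delta + 1)
  A <- crossprod(Xs, w * Xs)
  b <- crossprod(Xs, w * ys)
  beta <- solve(A, b)
  r <- ys - Xs %*% beta
  rss <- sum(w * r^2)
  n <- length(ys)
  -0.5 * (n * log(2 * pi * rss / n) + sum(log(lambda * delta + 1)) + n)
}

# Fit one marker: ML over delta on a log10 grid (-5..5, 100 points) with
# local refinement, then a Wald F-test for the allele effect using the
# residual-df variance estimate (reduces exactly to the OLS F-test when K
# is the identity).
lmm_fit_marker <- function(lambda, ys, Xs) {
  n <- length(ys)
  grid <- 10^seq(-5, 5, length.out = 100)
  ll <- vapply(grid, lmm_profile_ll, numeric(1),
               lambda = lambda, ys = ys, Xs = Xs)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(ld) lmm_profile_ll(10^ld, lambda, ys, Xs),
                         lower = log10(lo), upper = log10(hi), maximum = TRUE)
  delta <- 10^opt$maximum
  if (opt$objective < ll[i]) delta <- grid[i]
  w <- 1 / (lambda * delta + 1)
  A <- crossprod(Xs, w * Xs)
  b <- crossprod(Xs, w * ys)
  beta <- solve(A, b)
  r <- ys - Xs %*% beta
  p_cov <- ncol(Xs)
  sigma2 <- sum(w * r^2) / (n - p_cov)
  V <- sigma2 * solve(A)
  Fstat <- beta[p_cov]^2 / V[p_cov, p_cov]
  p <- stats::pf(Fstat, 1, n - p_cov, lower.tail = FALSE)
  list(beta = beta[p_cov], se = sqrt(V[p_cov, p_cov]), p = p, delta = delta)
}

#' Genome scan with a linear mixed model
#'
#' For each marker fits `y = mu + x beta + g + e`, `g ~ N(0, sigma_g^2 K)`,
#' `e ~ N(0, sigma_e^2 I)`, by maximum likelihood (EMMA-style rotation: one
#' eigendecomposition of K per chromosome, 1-D optimization of the variance
#' ratio), and tests `beta = 0` with a Wald F-test.  With `loco = TRUE`
#' (default) the kinship for markers on chromosome c is built from all
#' other chromosomes.
#'
#' @param phenotype Named numeric vector (names = strain IDs); NAs dropped.
#' @param genotypes A `strain_geno`.
#' @param loco Use leave-one-chromosome-out kinship (default TRUE).
#' @param kinship Optional fixed kinship matrix (e.g. `diag(n)`), used for
#'   every marker; overrides `loco`.
#' @param suggestive,significant Reporting thresholds on the -log10(p)
#'   scale (defaults 2.5 and 4.0, the conventional genome-wide lines for
#'   BXD scans).
#' @return Data frame of class `assoc_scan` with columns `marker`, `chr`,
#'   `pos_mb`, `beta`, `se`, `logp`, plus attributes `peak` (row index of
#'   the maximum -log10(p)), `suggestive`, `significant`, `n`.
#' @export
lmm_scan <- function(phenotype, genotypes, loco = TRUE, kinship = NULL,
                     suggestive = 2.5, significant = 4.0) {
  geno <- genotypes$geno
  map <- genotypes$map
  if (is.null(names(phenotype)))
    stop("phenotype must be named by strain ID")
  phenotype <- phenotype[is.finite(phenotype)]
  unmatched <- setdiff(names(phenotype), rownames(geno))
  if (length(unmatched) > 0)
    stop("strains missing from genotypes: ", paste(unmatched, collapse = ", "))
  ids <- intersect(rownames(geno), names(phenotype))
  if (length(ids) < 10) stop("fewer than 10 strains with phenotype and genotypes")
  y <- phenotype[ids]
  if (stats::sd(y) == 0) stop("phenotype is constant")
  geno <- geno[ids, , drop = FALSE]
  sub <- structure(list(geno = geno, map = map), class = "strain_geno")
  n <- length(y)

  fit_chr <- function(markers_idx, K) {
    eig <- eigen(K, symmetric = TRUE)
    lambda <- pmax(eig$values, 0)
    U <- eig$vectors
    ys <- crossprod(U, y)
    ones_s <- crossprod(U, rep(1, n))
    out <- matrix(NA_real_, nrow = length(markers_idx), ncol = 3)
    for (k in seq_along(markers_idx)) {
      x <- geno[, markers_idx[k]]
      if (stats::sd(x) == 0) {         # monomorphic in this sample
        out[k, ] <- c(0, NA, 1)
        next
      }
      Xs <- cbind(ones_s, crossprod(U, x))
      fit <- lmm_fit_marker(lambda, ys, Xs)
      out[k, ] <- c(fit$beta, fit$se, fit$p)
    }
    out
  }

  res <- matrix(NA_real_, nrow = nrow(map), ncol = 3)
  if (!is.null(kinship)) {
    K <- if (is.null(dimnames(kinship))) {
      if (nrow(kinship) != n)
        stop("unnamed kinship matrix must match the analyzed strains (n = ",
             n, ")")
      kinship
    } else kinship[ids, ids, drop = FALSE]
    res[] <- fit_chr(seq_len(nrow(map)), K)
  } else if (loco && length(unique(map$chr)) > 1) {
    for (c_ in unique(map$chr)) {
      idx <- which(map$chr == c_)
      K <- kinship_matrix(sub, exclude_chromosome = c_)
      res[idx, ] <- fit_chr(idx, K)
    }
  } else {
    K <- kinship_matrix(sub)
    res[] <- fit_chr(seq_len(nrow(map)), K)
  }

  scan <- data.frame(marker = map$marker, chr = map$chr, pos_mb = map$pos_mb,
                     beta = res[, 1], se = res[, 2],
                     logp = -log10(pmax(res[, 3], .Machine$double.xmin)),
                     stringsAsFactors = FALSE)
  attr(scan, "peak") <- which.max(scan$logp)
  attr(scan, "suggestive") <- suggestive
  attr(scan, "significant") <- significant
  attr(scan, "n") <- n
  class(scan) <- c("assoc_scan", "data.frame")
  scan
}

#' Significant interval around the scan peak
#'
#' On the peak marker's chromosome, the Mb span of the contiguous run of
#' markers (through the peak) with `-log10(p) >= threshold`; NULL when the
#' peak itself is below threshold.
#'
#' @param scan An `assoc_scan` from [lmm_scan()].
#' @param threshold Significance line on the -log10(p) scale (default the
#'   scan's `significant` attribute, 4.0).
#' @return NULL, or a list `chr`, `start_mb`, `end_mb`, `peak_marker`.
#' @export
qtl_interval <- function(scan, threshold = attr(scan, "significant")) {
  if (nrow(scan) == 0) stop("empty scan")
  peak <- attr(scan, "peak")
  if (scan$logp[peak] < threshold) return(NULL)
  on_chr <- which(scan$chr == scan$chr[peak])
  above <- scan$logp[on_chr] >= threshold
  pos_in_chr <- match(peak, on_chr)
  run <- pos_in_chr
  while (run[1] > 1 && above[run[1] - 1]) run <- c(run[1] - 1, run)
  while (run[length(run)] < length(on_chr) && above[run[length(run)] + 1])
    run <- c(run, run[length(run)] + 1)
  idx <- on_chr[run]
  list(chr = scan$chr[peak], start_mb = min(scan$pos_mb[idx]),
       end_mb = max(scan$pos_mb[idx]), peak_marker = scan$marker[peak])
}

#' Classify an eQTL as cis, trans, or none
#'
#' cis: the significant interval (or the peak, when the interval is a
#' single marker) lies on the gene's own chromosome within `cis_window` Mb
#' of the gene position (distance 0 if the gene falls inside the interval);
#' trans: significant elsewhere; none: no marker reaches the threshold.
#'
#' @param scan An `assoc_scan`.
#' @param gene_chr,gene_mb Genomic position of the gene whose expression
#'   was scanned.
#' @param cis_window Maximum gene-to-interval distance in Mb still called
#'   cis (default 10, conventional for BXD mapping resolution).
#' @param threshold Significance line (default the scan's `significant`).
#' @return A list of class `eqtl_call`: `classification` ("cis", "trans",
#'   "none"), `interval`, `peak_marker`, `distance_mb`.
#' @export
classify_eqtl <- function(scan, gene_chr, gene_mb, cis_window = 10,
                          threshold = attr(scan, "significant")) {
  interval <- qtl_interval(scan, threshold)
  if (is.null(interval))
    return(structure(list(classification = "none", interval = NULL,
                          peak_marker = NA_character_,
                          distance_mb = NA_real_), class = "eqtl_call"))
  if (interval$chr == as.character(gene_chr)) {
    dist <- if (gene_mb >= interval$start_mb && gene_mb <= interval$end_mb) 0
            else min(abs(gene_mb - interval$start_mb),
                     abs(gene_mb - interval$end_mb))
  } else dist <- Inf
  cls <- if (is.finite(dist) && dist <= cis_window) "cis" else "trans"
  structure(list(classification = cls, interval = interval,
                 peak_marker = interval$peak_marker,
                 distance_mb = if (is.finite(dist)) dist else NA_real_),
            class = "eqtl_call")
}

#' @export
print.eqtl_call <- function(x, ...) {
  cat("eQTL call:", x$classification)
  if (!is.null(x$interval))
    cat(sprintf(" (chr%s: %.1f-%.1f Mb, peak %s)", x$interval$chr,
                x$interval$start_mb, x$interval$end_mb, x$peak_marker))
  cat("\n")
  invisible(x)
}

#' Single-locus phenome scan
#'
#' Tests one marker against every trait in a phenome table with the same
#' mixed model as [lmm_scan()] (LOCO kinship excluding the marker's
#' chromosome), then adjusts across traits with Benjamini-Hochberg.
#' Traits with fewer than `min_n` complete strains are skipped.
#'
#' @param genotypes A `strain_geno`.
#' @param locus_marker Marker ID on the map.
#' @param traits Data frame, strains x traits (strain IDs as row names).
#' @param min_n Minimum complete strains per trait (default 10).
#' @param q_max,q_stringent Reporting thresholds on the q-value scale
#'   (defaults 0.05 and 0.001).
#' @return Data frame: `trait`, `n`, `beta`, `logp`, `q`, `significant`
#'   (q < q_max), `stringent` (q < q_stringent); sorted by q.  Skipped
#'   traits in attribute `"skipped"`.
#' @export
phenome_scan <- function(genotypes, locus_marker, traits, min_n = 10,
                         q_max = 0.05, q_stringent = 0.001) {
  map <- genotypes$map
  geno <- genotypes$geno
  m_idx <- match(locus_marker, map$marker)
  if (is.na(m_idx)) stop("marker ", locus_marker, " not on map")
  marker_chr <- map$chr[m_idx]
  usable <- list()
  skipped <- character(0)
  for (tr in colnames(traits)) {
    vals <- traits[[tr]]
    names(vals) <- rownames(traits)
    vals <- vals[is.finite(vals)]
    ids <- intersect(rownames(geno), names(vals))
    if (length(ids) < min_n || stats::sd(vals[ids]) == 0) {
      skipped <- c(skipped, tr)
      next
    }
    usable[[tr]] <- vals[ids]
  }
  if (length(usable) == 0) stop("no usable traits (need >= ", min_n,
                                " complete strains each)")
  # cache eigendecompositions by strain subset (phenome tables often share
  # the same strain coverage across many traits)
  eig_cache <- new.env(parent = emptyenv())
  rows <- lapply(names(usable), function(tr) {
    y <- usable[[tr]]
    ids <- names(y)
    key <- paste(ids, collapse = ";")
    if (is.null(eig_cache[[key]])) {
      sub <- structure(list(geno = geno[ids, , drop = FALSE], map = map),
                       class = "strain_geno")
      K <- kinship_matrix(sub, exclude_chromosome = marker_chr)
      eig_cache[[key]] <- eigen(K, symmetric = TRUE)
    }
    eig <- eig_cache[[key]]
    lambda <- pmax(eig$values, 0)
    U <- eig$vectors
    x <- geno[ids, m_idx]
    if (stats::sd(x) == 0)
      return(data.frame(trait = tr, n = length(y), beta = 0, p = 1))
    Xs <- cbind(crossprod(U, rep(1, length(y))), crossprod(U, x))
    fit <- lmm_fit_marker(lambda, crossprod(U, y), Xs)
    data.frame(trait = tr, n = length(y), beta = fit$beta, p = fit$p)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$logp <- -log10(out$p)
  out$significant <- out$q < q_max
  out$stringent <- out$q < q_stringent
  out <- out[order(out$q, out$p), c("trait", "n", "beta", "logp", "q",
                                    "significant", "stringent")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
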