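#' Construct a genetic map
#'
#' A genetic map is a data frame with one row per marker, ordered by
#' chromosome and megabase position.  Positions must be strictly increasing
#' within each chromosome.
#'
#' @param marker Character vector of unique marker identifiers.
#' @param chr Chromosome label per marker (character or factor).
#' @param pos_mb Numeric physical position in megabases (Mb).
#'
#' @return A `data.frame` of class `genetic_map` with columns `marker`,
#'   `chr`, `pos_mb`.
#' @export
genetic_map <- function(marker, chr, pos_mb) {
  stopifnot(length(marker) == length(chr), length(chr) == length(pos_mb))
  if (anyDuplicated(marker) > 0)
    stop("duplicate marker identifiers in map")
  if (any(!is.finite(pos_mb)) || any(pos_mb < 0))
    stop("marker positions must be finite and non-negative")
  map <- data.frame(marker = as.character(marker), chr = as.character(chr),
                    pos_mb = as.numeric(pos_mb), stringsAsFactors = FALSE)
  map <- map[order(match(map$chr, unique(map$chr)), map$pos_mb), , drop = FALSE]
  rownames(map) <- NULL
  for (c_ in unique(map$chr)) {
    p <- map$pos_mb[map$chr == c_]
    if (any(diff(p) <= 0) && length(p) > 1)
      stop("positions must be strictly increasing within chromosome ", c_)
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Default desk-scale genetic map
#'
#' A mouse-autosome-like map: 19 chromosomes with a fixed number of evenly
#' spaced markers each.  Spacing of 10 Mb (roughly 5 cM at the genome-wide
#' average recombination rate) gives desk-scale scans that still show
#' linkage structure.
#'
#' @param n_chr Number of chromosomes (default 19, the mouse autosomes).
#' @param markers_per_chr Markers per chromosome (default 10).
#' @param spacing_mb Distance between adjacent markers in Mb (default 10).
#' @return A [genetic_map()].
#' @export
default_genetic_map <- function(n_chr = 19, markers_per_chr = 10,
                                spacing_mb = 10) {
  chr <- rep(as.character(seq_len(n_chr)), each = markers_per_chr)
  pos <- rep(seq(spacing_mb, by = spacing_mb, length.out = markers_per_chr),
             times = n_chr)
  marker <- sprintf("m%s_%02d", chr, rep(seq_len(markers_per_chr), n_chr))
  genetic_map(marker, chr, pos)
}

# Haldane map function: recombination fraction from genetic distance (cM).
haldane_rf <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))

# Expansion of the per-meiosis recombination fraction in recombinant inbred
# lines produced by repeated sibling mating: R = 4r / (1 + 6r).
ri_expansion <- function(r) 4 * r / (1 + 6 * r)
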