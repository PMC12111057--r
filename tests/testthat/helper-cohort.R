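# Shared fixtures: small configurations used across test files.

# Desk-scale config: defaults except where overridden.
quick_config <- function(seed = 1, n_strains = 60, n_background = 20, ...) {
  sim_config(seed = seed, n_strains = n_strains,
             n_background = n_background, ...)
}

# A single-chromosome map with the given inter-marker gaps (Mb).
gap_map <- function(gaps_mb, chr = "1") {
  pos <- cumsum(c(1, gaps_mb))
  genetic_map(sprintf("g%02d", seq_along(pos)), rep(chr, length(pos)), pos)
}

# OLS single-marker F-test -log10(p), the oracle for identity-kinship scans.
ols_logp <- function(y, x) {
  fit <- stats::lm(y ~ x)
  f <- stats::anova(fit)[1, "F value"]
  -log10(stats::pf(f, 1, length(y) - 2, lower.tail = FALSE))
}

# Write a temporary GMT file from a named list of character vectors.
write_tmp_gmt <- function(sets, desc = "desc") {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  lines <- vapply(names(sets), function(id)
    paste(c(id, desc, sets[[id]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  path
}
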