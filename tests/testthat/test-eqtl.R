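test_that("kinship matrix matches hand-computed centered relatedness", {
  geno <- matrix(c(0L, 1L, 0L,
                   0L, 1L, 1L), nrow = 3,
                 dimnames = list(c("s1", "s2", "s3"), c("mA", "mB")))
  map <- genetic_map(c("mA", "mB"), c("1", "2"), c(10, 10))
  g <- structure(list(geno = geno, map = map), class = "strain_geno")
  # centered columns: (-1/3, 2/3, -1/3) and (-2/3, 1/3, 1/3); K = mean outer
  K_hand <- (tcrossprod(c(-1, 2, -1) / 3) + tcrossprod(c(-2, 1, 1) / 3)) / 2
  expect_lt(max(abs(kinship_matrix(g) - K_hand)), 1e-12)
  expect_true(isSymmetric(unclass(kinship_matrix(g))))
})

test_that("identical strains share diagonal and off-diagonal kinship", {
  cfg <- quick_config(seed = 13, n_strains = 20)
  g <- simulate_ri_genotypes(cfg)
  g$geno[2, ] <- g$geno[1, ]  # make strain 2 a genetic copy of strain 1
  K <- kinship_matrix(g)
  expect_equal(K[1, 2], K[1, 1])
  expect_equal(K[1, 2], K[2, 2])
  # PSD: eigenvalues >= -1e-8
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
})

test_that("LOCO kinship excludes exactly the left-out chromosome", {
  cfg <- quick_config(seed = 14, n_strains = 30)
  g <- simulate_ri_genotypes(cfg)
  K_loco <- kinship_matrix(g, exclude_chromosome = "11")
  keep <- g$map$chr != "11"
  X <- scale(g$geno[, keep], center = TRUE, scale = FALSE)
  expect_lt(max(abs(K_loco - tcrossprod(X) / sum(keep))), 1e-12)
  one_chr <- structure(list(geno = g$geno[, g$map$chr == "1"],
                            map = g$map[g$map$chr == "1", ]),
                       class = "strain_geno")
  expect_error(kinship_matrix(one_chr, exclude_chromosome = "1"),
               "fewer than 2 markers")
})

test_that("identity-kinship mixed model reduces exactly to OLS", {
  map <- default_genetic_map(n_chr = 5, markers_per_chr = 10)
  cfg <- sim_config(seed = 15, n_strains = 40, map = map,
                    focal_chr = "1", focal_mb = 50, n_background = 0)
  g <- simulate_ri_genotypes(cfg)
  set.seed(16)
  y <- rnorm(40)
  names(y) <- rownames(g$geno)
  scan <- lmm_scan(y, g, kinship = diag(40))
  for (j in seq_len(nrow(g$map))) {
    x <- g$geno[, j]
    if (sd(x) == 0) next
    expect_lt(abs(scan$logp[j] - ols_logp(y, x)), 1e-6)
  }
})

test_that("scan p-values are invariant to consistent strain reordering", {
  cfg <- quick_config(seed = 17, n_strains = 30)
  g <- simulate_ri_genotypes(cfg)
  e <- simulate_expression(g, cfg, "t")
  y <- e$values[, cfg$focal_gene]
  scan1 <- lmm_scan(y, g, loco = TRUE)
  perm <- sample(length(y))
  g2 <- structure(list(geno = g$geno[perm, ], map = g$map),
                  class = "strain_geno")
  scan2 <- lmm_scan(y[perm], g2, loco = TRUE)
  expect_equal(scan1$logp, scan2$logp, tolerance = 1e-8)
})

test_that("scan input validation names the problem", {
  cfg <- quick_config(seed = 18, n_strains = 20)
  g <- simulate_ri_genotypes(cfg)
  y <- rep(1, 20)
  names(y) <- rownames(g$geno)
  expect_error(lmm_scan(y, g), "constant")
  y2 <- rnorm(20)
  names(y2) <- c(rownames(g$geno)[-1], "GHOST")
  expect_error(lmm_scan(y2, g), "GHOST")
  expect_error(lmm_scan(unname(rnorm(20)), g), "named")
})

test_that("permuted phenotypes rarely reach the significant threshold", {
  cfg <- quick_config(seed = 19, n_strains = 60)
  g <- simulate_ri_genotypes(cfg)
  e <- simulate_expression(g, cfg, "t")
  y <- e$values[, cfg$focal_gene]
  set.seed(20)
  clean <- 0
  for (i in 1:5) {
    y_perm <- setNames(sample(y), names(y))
    scan <- lmm_scan(y_perm, g, loco = TRUE)
    if (max(scan$logp) < 4.0) clean <- clean + 1
  }
  expect_gte(clean, 4)
})

test_that("interval extraction follows the contiguous run through the peak", {
  mk_scan <- function(logp, pos = seq(10, by = 10,
                                      length.out = length(logp))) {
    s <- data.frame(marker = sprintf("m%02d", seq_along(logp)), chr = "11",
                    pos_mb = pos, beta = 0, se = 1, logp = logp)
    attr(s, "peak") <- which.max(logp)
    attr(s, "significant") <- 4.0
    class(s) <- c("assoc_scan", "data.frame")
    s
  }
  expect_null(qtl_interval(mk_scan(c(1, 2, 3, 2, 1))))
  single <- qtl_interval(mk_scan(c(1, 5, 1)))
  expect_equal(c(single$start_mb, single$end_mb), c(20, 20))
  run <- qtl_interval(mk_scan(c(1, 2, 4.5, 5, 6, 4.2, 4.1, 2),
                              pos = c(40, 50, 60, 65, 70, 75, 80, 90)))
  expect_equal(c(run$start_mb, run$end_mb), c(60, 80))
  # a detached significant marker beyond a gap is not part of the interval
  gap <- qtl_interval(mk_scan(c(4.5, 1, 5, 4.2, 1),
                              pos = c(10, 20, 30, 40, 50)))
  expect_equal(c(gap$start_mb, gap$end_mb), c(30, 40))
})

test_that("cis/trans classification respects chromosome and window", {
  mk_scan <- function(chr, logp, pos) {
    s <- data.frame(marker = sprintf("m%02d", seq_along(logp)), chr = chr,
                    pos_mb = pos, beta = 0, se = 1, logp = logp)
    attr(s, "peak") <- which.max(logp)
    attr(s, "significant") <- 4.0
    class(s) <- c("assoc_scan", "data.frame")
    s
  }
  # peak exactly at the gene position
  at_gene <- mk_scan("11", c(1, 6, 1), c(60, 70.44, 80))
  expect_equal(classify_eqtl(at_gene, "11", 70.44)$classification, "cis")
  # significant peak on another chromosome
  elsewhere <- mk_scan("3", c(1, 6, 1), c(60, 70, 80))
  expect_equal(classify_eqtl(elsewhere, "11", 70.44)$classification,
               "trans")
  # no significance at all
  flat <- mk_scan("11", c(1, 2, 1), c(60, 70, 80))
  expect_equal(classify_eqtl(flat, "11", 70.44)$classification, "none")
  # same chromosome but outside the cis window
  far <- mk_scan("11", c(6, 1, 1), c(5, 50, 80))
  expect_equal(classify_eqtl(far, "11", 70.44)$classification, "trans")
  expect_equal(classify_eqtl(far, "11", 70.44,
                             cis_window = 80)$classification, "cis")
})

test_that("single-locus phenome scan flags strong signals and nulls honestly", {
  cfg <- quick_config(seed = 21, n_strains = 60)
  g <- simulate_ri_genotypes(cfg)
  marker <- "m5_03"
  allele <- g$geno[, marker]
  set.seed(22)
  traits <- data.frame(
    strong = allele + rnorm(60, 0, 0.25),
    matrix(rnorm(60 * 30), 60, dimnames = list(NULL,
                                               sprintf("n%02d", 1:30))),
    row.names = rownames(g$geno), check.names = FALSE)
  out <- phenome_scan(g, marker, traits)
  expect_lt(out$q[out$trait == "strong"], 0.001)
  expect_true(out$stringent[out$trait == "strong"])
  # single trait: BH with one test leaves q = p
  one <- phenome_scan(g, marker, traits[, "strong", drop = FALSE])
  expect_equal(one$q, 10^(-one$logp))
  # sparse traits are skipped, not errors
  traits$sparse <- c(rnorm(5), rep(NA, 55))
  out2 <- phenome_scan(g, marker, traits)
  expect_true("sparse" %in% attr(out2, "skipped"))
  expect_error(phenome_scan(g, "nope", traits), "not on map")
})
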