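test_that("RI genotypes are homozygous 0/1 with balanced allele frequencies", {
  cfg <- quick_config(seed = 11, n_strains = 200)
  g <- simulate_ri_genotypes(cfg)
  expect_true(all(g$geno %in% c(0L, 1L)))
  freq <- colMeans(g$geno)
  expect_true(all(abs(freq - 0.5) <= 0.12))

  # larger panel: frequencies tighten toward 0.5
  cfg500 <- quick_config(seed = 12, n_strains = 500)
  freq500 <- colMeans(simulate_ri_genotypes(cfg500)$geno)
  expect_true(all(abs(freq500 - 0.5) <= 0.08))
})

test_that("zero genetic distance gives identical genotype columns", {
  cfg <- quick_config(seed = 2, n_strains = 50)
  # cm_per_mb = 0 collapses every inter-marker distance to 0 cM
  g <- simulate_ri_genotypes(cfg, cm_per_mb = 0)
  for (c_ in unique(g$map$chr)) {
    cols <- g$geno[, g$map$chr == c_, drop = FALSE]
    expect_true(all(cols == cols[, 1]))
  }
})

test_that("genotype simulation is a pure function of config and seed", {
  cfg <- quick_config(seed = 42)
  expect_identical(simulate_ri_genotypes(cfg)$geno,
                   simulate_ri_genotypes(cfg)$geno)
  cfg2 <- quick_config(seed = 43)
  expect_false(identical(simulate_ri_genotypes(cfg)$geno,
                         simulate_ri_genotypes(cfg2)$geno))
})

test_that("adjacent-marker genotype correlation decays with map distance", {
  gaps <- c(1, 2, 4, 8, 12, 16, 24, 32, 48)  # Mb, = 0.5..24 cM
  map <- gap_map(gaps)
  avg <- rep(0, length(gaps))
  for (rep_i in 1:20) {
    cfg <- sim_config(seed = 100 + rep_i, n_strains = 150, map = map,
                      focal_chr = "1", focal_mb = 1, n_background = 0,
                      planted_correlates = data.frame(gene = character(),
                                                      r = numeric()),
                      planted_trait_correlations = data.frame(
                        trait = character(), r = numeric()))
    g <- simulate_ri_genotypes(cfg)$geno
    avg <- avg + vapply(seq_along(gaps), function(j)
      cor(g[, j], g[, j + 1]), numeric(1)) / 20
  }
  expect_true(all(diff(avg) < 0))
})

test_that("expression carries a recoverable cis effect at the focal locus", {
  cfg <- quick_config(seed = 5, n_strains = 100, cis_effect = 1.0,
                      noise_sd = 0.3)
  g <- simulate_ri_genotypes(cfg)
  e <- simulate_expression(g, cfg, "hippocampus")
  allele <- g$geno[, "m11_07"]  # nearest marker to the focal locus
  slope <- coef(lm(e$values[, cfg$focal_gene] ~ allele))[2]
  expect_lt(abs(slope - 1.0), 0.15)
})

test_that("planted correlates realize their target correlation", {
  cfg <- quick_config(seed = 6, n_strains = 100)
  g <- simulate_ri_genotypes(cfg)
  e <- simulate_expression(g, cfg, "amygdala")
  focal <- e$values[, cfg$focal_gene]
  expect_lt(abs(cor(focal, e$values[, "CorA"]) - 0.8), 0.12)
  expect_lt(abs(cor(focal, e$values[, "CorC"]) - (-0.45)), 0.15)
  # values live on the log2-like display scale near 8
  expect_lt(abs(mean(e$values) - 8), 0.5)
})

test_that("background genes are uncorrelated with the focal gene", {
  cfg <- quick_config(seed = 7, n_strains = 100, n_background = 200)
  g <- simulate_ri_genotypes(cfg)
  e <- simulate_expression(g, cfg, "cerebellum")
  focal <- e$values[, cfg$focal_gene]
  bg <- grep("^Bg", colnames(e$values), value = TRUE)
  r_bg <- vapply(bg, function(gene) cor(focal, e$values[, gene]), numeric(1))
  expect_gte(mean(abs(r_bg) < 0.3), 0.9)
})

test_that("expression rejects unattainable correlation targets", {
  cfg <- quick_config(seed = 1)
  cfg$planted_correlates$r[1] <- 1.5
  g <- simulate_ri_genotypes(quick_config(seed = 1))
  expect_error(simulate_expression(g, cfg), "\\[-1, 1\\]")
})

test_that("traits realize target genetic correlations; nulls stay null", {
  cfg <- quick_config(seed = 8)
  set.seed(99)
  focal <- rnorm(60, 8, 0.4)
  names(focal) <- sprintf("RI%03d", 1:60)
  traits <- simulate_traits(focal, cfg, n_null_traits = 50)
  expect_lt(abs(cor(focal, traits$trait_learning) - (-0.6)), 0.15)
  r_null <- vapply(grep("^null_", colnames(traits), value = TRUE),
                   function(tr) cor(focal, traits[[tr]]), numeric(1))
  expect_gte(mean(abs(r_null) < 0.25), 0.9)
  # determinism and missing-value masks
  expect_identical(traits, simulate_traits(focal, cfg, n_null_traits = 50))
  masked <- simulate_traits(focal, cfg, missing_rate = 0.3)
  expect_gt(sum(is.na(masked)), 0)
  expect_error(simulate_traits(focal[1:2], cfg), "at least 3")
})

test_that("planted PPI graph has exactly the planted ego neighborhood", {
  genes <- c("F", "A", "B", letters[1:10])
  ppi <- simulate_ppi(genes, "F", planted_primary = "A",
                      planted_secondary = "B", n_background_edges = 15,
                      seed = 3)
  ego <- ego_interactors(ppi)
  expect_identical(ego$primary, "A")
  expect_identical(ego$secondary, "B")
  expect_equal(unname(ego$degrees["F"]), 1)  # degree of focal = |primary|

  empty <- simulate_ppi(genes, "F", seed = 3)
  ego0 <- ego_interactors(empty)
  expect_length(ego0$primary, 0)
  expect_length(ego0$secondary, 0)
  expect_error(simulate_ppi(genes, "Zz", planted_primary = "A"),
               "focal")
  expect_error(simulate_ppi(genes, "F", planted_primary = "A",
                            planted_secondary = "A"), "disjoint")
})

test_that("case/control generator plants shifts only in the case group", {
  genes <- sprintf("G%03d", 1:50)
  de <- data.frame(gene = "G001", shift = 2)
  cc <- simulate_case_control(genes, de, n_per_group = 8, seed = 9)
  expect_identical(cc$values,
                   simulate_case_control(genes, de, n_per_group = 8,
                                         seed = 9)$values)
  diff_means <- colMeans(cc$values[cc$groups == "case", ]) -
    colMeans(cc$values[cc$groups == "control", ])
  expect_gt(diff_means["G001"], 1)            # planted shift visible
  expect_lt(max(abs(diff_means[-1])), 1.5)    # others unshifted
  expect_error(simulate_case_control(genes, data.frame(gene = "Nope",
                                                       shift = 1)),
               "unknown gene")
  expect_error(simulate_case_control(genes, n_per_group = 2), ">= 3")
})

test_that("per-tissue strain subsets restrict the expression matrix", {
  cfg <- quick_config(seed = 10, n_strains = 40)
  g <- simulate_ri_genotypes(cfg)
  sub <- rownames(g$geno)[1:25]
  e <- simulate_expression(g, cfg, "pfc", strains = sub)
  expect_identical(rownames(e$values), sub)
  expect_error(simulate_expression(g, cfg, strains = c("RI001", "XX")),
               "unknown strains")
})
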