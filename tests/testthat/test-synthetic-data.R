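# Generators: homozygous genotypes with controllable structure, planted
# methylomes, and traits with planted causal chains.

test_that("simulated genotypes are homozygous, respect the MAF floor, and are seed-stable", {
  cfg <- population_config(n_lines = 30, n_snps = 120, maf_floor = 0.1, seed = 5)
  gm1 <- simulate_population(cfg)
  gm2 <- simulate_population(cfg)
  expect_identical(gm1, gm2)
  expect_true(all(gm1$geno %in% c(0, 2)))
  expect_true(all(maf(gm1) >= 0.1))
  expect_equal(nrow(gm1$geno), 30)
  expect_setequal(unique(gm1$lines$subgroup), c("SS", "NSS", "TST"))
})

test_that("invalid population configs are rejected", {
  expect_error(population_config(subgroup_proportions = c(a = 0.5, b = 0.4)),
               "sum to 1")
  expect_error(population_config(n_lines = 5,
                                 subgroup_proportions = c(a = 0.5, b = 0.3, c = 0.2)),
               "fewer than 2")
  expect_error(population_config(divergence = 1), "divergence")
})

test_that("zero divergence leaves no systematic between-subgroup allele-frequency difference", {
  gm <- simulate_population(population_config(
    n_lines = 100, subgroup_proportions = c(A = 0.5, B = 0.5),
    n_snps = 400, divergence = 0, seed = 7))
  a <- gm$lines$line_id[gm$lines$subgroup == "A"]
  b <- gm$lines$line_id[gm$lines$subgroup == "B"]
  d_obs <- colMeans(gm$geno[a, ]) / 2 - colMeans(gm$geno[b, ]) / 2
  # per-marker differences should center on zero at binomial-noise scale
  expect_lt(abs(mean(d_obs)), 3 * sd(d_obs) / sqrt(length(d_obs)))
  p_bar <- colMeans(gm$geno) / 2
  expected_sd <- sqrt(p_bar * (1 - p_bar) * (1 / length(a) + 1 / length(b)))
  expect_lt(mean(abs(d_obs)) / mean(expected_sd), 1.15)
})

test_that("divergent subgroups separate on the first genotype PC (SVD oracle)", {
  gm <- simulate_population(population_config(
    n_lines = 60, subgroup_proportions = c(A = 0.5, B = 0.5),
    n_snps = 400, divergence = 0.2, seed = 9))
  # oracle: direct eigendecomposition of the centered genotype matrix
  xc <- scale(gm$geno, scale = FALSE)
  pc1 <- svd(xc, nu = 1, nv = 0)$u[, 1] * svd(xc)$d[1]
  lab <- gm$lines$subgroup
  sil <- vapply(seq_along(pc1), function(i) {
    own <- mean(abs(pc1[i] - pc1[lab == lab[i]][-match(i, which(lab == lab[i]))]))
    oth <- mean(abs(pc1[i] - pc1[lab != lab[i]]))
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("planted methylome respects kinds: stable background, deterministic cis linkage, binomial epiallele counts", {
  gm <- simulate_population(population_config(n_lines = 100, n_snps = 200, seed = 21))
  cfgs <- list(
    planted_dmr_config(n_regions = 2, kind = "tissue_stable_background",
                       contexts = "CG", high_level = 0.8, low_level = 0.8),
    planted_dmr_config(n_regions = 2, kind = "genetic_cis", contexts = "CG",
                       mef_target = 0.3),
    planted_dmr_config(n_regions = 4, kind = "pure_epigenetic", contexts = "CG",
                       mef_target = 0.2))
  panel <- simulate_methylome(gm, cfgs, seed = 22)
  truth <- panel$truth[!duplicated(panel$truth$region_id), ]

  stable <- truth$region_id[truth$kind == "tissue_stable_background"]
  expect_true(all(panel$epialleles[, stable] == "high"))

  cis <- truth[truth$kind == "genetic_cis", ]
  for (i in seq_len(nrow(cis))) {
    g <- gm$geno[, cis$snp_id[i]]
    minor <- if (mean(g) / 2 > 0.5) 0 else 2
    expect_identical(unname(panel$epialleles[, cis$region_id[i]] == "low"),
                     unname(g == minor))
  }

  epi <- truth$region_id[truth$kind == "pure_epigenetic"]
  counts <- colSums(panel$epialleles[, epi] == "low")
  lo <- qbinom(0.005, 100, 0.2)
  hi <- qbinom(0.995, 100, 0.2)
  expect_true(all(counts >= lo & counts <= hi))
})

test_that("overlapping planted regions are impossible and seeds reproduce the methylome", {
  sp <- small_panel()
  truth <- sp$panel$truth[!duplicated(sp$panel$truth$region_id), ]
  by_chrom <- split(truth, truth$chrom)
  for (tc in by_chrom) {
    tc <- tc[order(tc$start), ]
    if (nrow(tc) > 1) expect_true(all(tc$start[-1] >= tc$end[-nrow(tc)]))
  }
  again <- simulate_methylome(sp$gm, list(
    planted_dmr_config(n_regions = 3, kind = "genetic_cis", contexts = "CG",
                       mef_target = 0.3),
    planted_dmr_config(n_regions = 3, kind = "pure_epigenetic", contexts = "CG",
                       mef_target = 0.2),
    planted_dmr_config(n_regions = 2, kind = "pure_epigenetic", contexts = "CHH",
                       mef_target = 0.3),
    planted_dmr_config(n_regions = 2, kind = "tissue_stable_background",
                       contexts = "CG")), seed = 12)
  expect_identical(again$calls, sp$panel$calls)
})

test_that("planted config invariants mirror the caller's definitional thresholds", {
  expect_error(planted_dmr_config(kind = "pure_epigenetic", contexts = "CG",
                                  high_level = 0.5, low_level = 0.1),
               "> 0.6")
  expect_error(planted_dmr_config(kind = "pure_epigenetic", contexts = "CHH",
                                  high_level = 0.2, low_level = 0.01),
               "CHH")
  expect_error(planted_dmr_config(mef_target = 0.7), "mef_target")
})

test_that("noiseless causal chains satisfy the path-product identity (regression oracle)", {
  gm <- simulate_population(population_config(n_lines = 80, n_snps = 150, seed = 31))
  panel <- simulate_methylome(gm, list(
    planted_dmr_config(n_regions = 1, kind = "genetic_cis", contexts = "CG",
                       mef_target = 0.4)), seed = 32)
  tp <- simulate_traits(gm, panel, causal_chain_config(
    n_genes = 1, direction_model = "causal", beta_dmr_on_expr = 2,
    noise_sd = 1e-8, polygenic_heritability = 0), seed = 33)
  g <- gm$geno[, tp$truth$snp_id]
  m <- panel$levels[, tp$truth$region_id]
  y <- tp$expression[, 1]
  b_total <- coef(lm(y ~ g))[2]
  b_path <- coef(lm(m ~ g))[2] * coef(lm(y ~ m))[2]
  expect_equal(unname(b_total), unname(b_path), tolerance = 1e-6)
})

test_that("trait simulation is seed-stable and consequential chains couple DMR to expression", {
  gm <- simulate_population(population_config(n_lines = 60, n_snps = 150, seed = 41))
  panel <- simulate_methylome(gm, list(
    planted_dmr_config(n_regions = 1, kind = "pure_epigenetic", contexts = "CG",
                       mef_target = 0.3)), seed = 42)
  cfg <- causal_chain_config(n_genes = 1, direction_model = "consequential",
                             beta_snp_on_dmr = 0.8, beta_dmr_on_expr = 0.3,
                             noise_sd = 0.2)
  t1 <- simulate_traits(gm, panel, cfg, seed = 43)
  t2 <- simulate_traits(gm, panel, cfg, seed = 43)
  expect_identical(t1, t2)
  r <- cor(t1$dmr_levels[, t1$truth$region_id], t1$expression[, 1])
  expect_gt(r, 0.9)
  expect_error(simulate_traits(gm, panel, causal_chain_config(
    n_genes = 2, direction_model = "consequential")),
    "no remaining pure_epigenetic")
})
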