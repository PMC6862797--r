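# MAF filter, INT, thresholds, LD pruning, haplotype filter, distance
# classes, and the two-step residual association model.

test_that("printed Bonferroni thresholds are pure functions of (alpha, N)", {
  expect_equal(signif(bonferroni_threshold(0.05, 971267), 3), 5.15e-8)
  expect_equal(signif(bonferroni_threshold(0.05, 2711), 3), 1.84e-5)
  expect_equal(signif(bonferroni_threshold(0.01, 8864), 3), 1.13e-6)
  expect_equal(signif(bonferroni_threshold(0.01, 5075), 3), 1.97e-6)
})

test_that("MAF filter removes markers at or below the threshold, on analysis lines", {
  geno <- matrix(0, 100, 3, dimnames = list(sprintf("L%03d", 1:100),
                                            c("m5", "m6", "mono")))
  geno[1:5, "m5"] <- 2    # MAF 0.05 -> removed (strict >)
  geno[1:6, "m6"] <- 2    # MAF 0.06 -> kept
  gm <- structure(list(geno = geno,
                       map = data.frame(snp_id = colnames(geno), chrom = "chr1",
                                        pos = c(100L, 200L, 300L)),
                       lines = data.frame(line_id = rownames(geno), subgroup = "A")),
                  class = "genotype_matrix")
  out <- maf_filter(gm, 0.05)
  expect_equal(out$map$snp_id, "m6")
  # restricted to lines where m6 is monomorphic, it too is removed
  out2 <- maf_filter(gm, 0.05, lines = sprintf("L%03d", 7:100))
  expect_equal(ncol(out2$geno), 0)
})

test_that("inverse normal transform uses the Blom offset with average ties", {
  # odd n: the middle value maps to exactly 0
  x <- c(3, 1, 2, 5, 4)
  expect_equal(inverse_normal_transform(x)[1], 0)
  # n = 3 smallest value: qnorm(0.625/3.25)
  y <- inverse_normal_transform(c(10, 20, 30))
  expect_equal(y[1], qnorm(0.625 / 3.25))
  expect_equal(round(y[1], 4), -0.8694)
  # rank invariance under monotone transforms
  z <- rnorm(20)
  expect_equal(inverse_normal_transform(z), inverse_normal_transform(exp(z)))
  # ties share average ranks
  t1 <- inverse_normal_transform(c(1, 1, 2))
  expect_equal(t1[1], t1[2])
  expect_error(inverse_normal_transform(rep(1, 5)), "constant")
  expect_error(inverse_normal_transform(c(1, 2, NA)), ">= 3")
  # missing values pass through
  w <- inverse_normal_transform(c(1, 2, 3, NA, 4))
  expect_true(is.na(w[4]))
})

test_that("greedy LD pruning keeps the documented independent set", {
  set.seed(71)
  n <- 200
  # A and C independent; B is a coin-mixture of the two, so A-B and B-C
  # are both in LD while A-C is not
  a <- sample(c(0, 2), n, replace = TRUE)
  cc <- sample(c(0, 2), n, replace = TRUE)
  b <- ifelse(runif(n) < 0.5, a, cc)
  geno <- cbind(A = a, B = b, C = cc)
  rownames(geno) <- sprintf("L%03d", 1:n)
  r2 <- cor(geno)^2
  # construct the fixture until the intended LD pattern holds
  expect_gt(r2["A", "B"], 0.1); expect_gt(r2["B", "C"], 0.1)
  expect_lt(r2["A", "C"], 0.1)
  gm <- structure(list(geno = geno,
                       map = data.frame(snp_id = colnames(geno), chrom = "chr1",
                                        pos = c(1L, 2L, 3L))),
                  class = "genotype_matrix")
  expect_equal(ld_prune(c("A", "B", "C"), c(1e-10, 1e-8, 1e-6), gm), c("A", "C"))

  # perfectly correlated pair: only the more significant survives
  gm2 <- gm; gm2$geno[, "B"] <- gm2$geno[, "A"]
  expect_equal(ld_prune(c("A", "B"), c(1e-8, 1e-4), gm2), "A")
  # independent markers all survive
  expect_equal(sort(ld_prune(c("A", "C"), c(1e-8, 1e-4), gm)), c("A", "C"))
})

test_that("haplotype median filter demands > 0.05 median difference", {
  g <- rep(c(0, 2), each = 10)
  lv1 <- c(rep(0.50, 10), rep(0.60, 10))
  expect_true(haplotype_effect_filter(g, lv1)$pass)
  lv2 <- c(rep(0.50, 10), rep(0.54, 10))
  expect_false(haplotype_effect_filter(g, lv2)$pass)
  expect_false(haplotype_effect_filter(g, rep(0.5, 20))$pass)
  expect_false(haplotype_effect_filter(rep(0, 20), lv1)$pass)  # monomorphic
})

test_that("distance classes and DMR QTL categories follow the 10 Mb rule", {
  expect_equal(distance_class("chr1", 5e6, "chr1", 0), "local")
  expect_equal(distance_class("chr2", 5e6, "chr1", 0), "distal")
  expect_equal(distance_class("chr1", 5e7, "chr1", 0), "unclassified")
  expect_equal(categorize_dmr("local"), "Local_only")
  expect_equal(categorize_dmr(c("local", "distal")), "Both")
  expect_equal(categorize_dmr("distal"), "Distal_only")
  expect_equal(categorize_dmr(c("local", "unclassified")), "Unclassified")
  expect_equal(categorize_dmr(character(0)), "None")
})

test_that("mQTL scan finds the planted cis-SNP and classifies it local", {
  sp <- small_panel()
  d <- call_dmrs(sp$panel$calls, "CG", k = 8)
  gm_f <- maf_filter(sp$gm, 0.05)
  res <- suppressMessages(suppressWarnings(
    mqtl_scan(d, gm = gm_f, alpha = 0.05)))
  expect_equal(res$threshold, 0.05 / ncol(gm_f$geno))
  truth <- sp$panel$truth
  cis <- truth[truth$kind == "genetic_cis" & truth$context == "CG", ]
  # every cis DMR called should associate with its planted SNP
  for (i in seq_len(nrow(cis))) {
    hit <- d$regions$dmr_id[d$regions$chrom == cis$chrom[i] &
                              d$regions$start < cis$end[i] &
                              d$regions$end > cis$start[i]]
    rows <- res$results[res$results$dmr_id %in% hit, ]
    expect_true(cis$snp_id[i] %in% rows$snp_id,
                info = sprintf("planted SNP for %s", cis$region_id[i]))
    planted <- rows[rows$snp_id == cis$snp_id[i], ]
    expect_equal(unique(planted$class), "local")
    # direction: minor allele is the low epiallele, so beta sign matches truth
    g <- sp$gm$geno[, cis$snp_id[i]]
    lv <- d$levels[planted$dmr_id[1], ]
    expect_equal(sign(planted$beta[1]), sign(cor(g, lv, use = "complete.obs")))
  }
  expect_true(all(res$categories[res$categories != "None"] %in%
                    c("Local_only", "Both", "Unclassified", "Distal_only")))
})

test_that("two-step residual scan is null-calibrated and finds planted links", {
  set.seed(81)
  sk <- structured_kinship(80, seed = 82)
  n <- 80
  lines <- rownames(sk$K)
  # planted: one DMR drives trait 1; others null
  dmr_lv <- matrix(runif(5 * n), 5, n, dimnames = list(paste0("D", 1:5), lines))
  y1 <- 2 * dmr_lv[1, ] + rnorm(n, 0, 0.3)
  traits <- cbind(t1 = y1, t2 = rnorm(n))
  rownames(traits) <- lines
  res <- suppressMessages(dmr_trait_scan(traits, dmr_lv, K = sk$K, alpha = 0.01))
  expect_equal(res$threshold, 0.01 / 5)
  top <- res$results[res$results$trait_id == "t1", ]
  expect_equal(top$dmr_id[which.min(top$p)], "D1")
  expect_true(top$significant[top$dmr_id == "D1"])
  expect_gt(top$beta[top$dmr_id == "D1"], 0)
})

test_that("residual trait reduces variance and collapses under perfect confounding", {
  sk <- structured_kinship(60, seed = 91)
  lines <- rownames(sk$K)
  Q <- genotype_pcs(sk$gm$geno)
  set.seed(92)
  z <- scale(sk$gm$geno)
  u <- as.vector(z %*% rnorm(ncol(z))) / sqrt(ncol(z))
  y <- u + rnorm(60, 0, 0.3)
  names(y) <- lines
  yp <- residual_trait(y, sk$K, Q)
  expect_lt(var(yp), var(y))
  expect_lt(abs(mean(yp)), 0.15)

  # Y entirely generated by Q -> Y' ~ 0
  y2 <- as.vector(Q %*% c(1, -2, 0.5))
  names(y2) <- lines
  yp2 <- residual_trait(y2, diag(60), Q)
  expect_lt(sqrt(sum(yp2^2)) / sqrt(sum(y2^2)), 1e-6)
})
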