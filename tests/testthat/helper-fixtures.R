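# Fixture builders shared across test files.  Everything is generated in
# code at test time under fixed seeds.

# A random tiny DMR-calling instance: <= 5 lines, <= 30 windows, one
# chromosome, 1-3 cytosines of one context per window, block-structured
# bimodal methylation so that real chains appear with useful frequency.
random_tiny_instance <- function(seed) {
  set.seed(seed)
  context <- sample(c("CG", "CHG", "CHH"), 1)
  n_lines <- sample(4:5, 1)
  n_windows <- sample(10:30, 1)
  lines <- paste0("T", seq_len(n_lines))
  hi <- if (context == "CHH") 0.35 else 0.9
  lo <- 0.02
  # block structure: consecutive windows share a high/low line pattern
  n_blocks <- sample(2:5, 1)
  block_of <- sort(sample(seq_len(n_blocks), n_windows, replace = TRUE))
  pattern <- matrix(sample(c(hi, lo), n_blocks * n_lines, replace = TRUE,
                           prob = c(0.6, 0.4)),
                    n_blocks, n_lines)
  # cytosine positions are shared across lines (capture design)
  site_pos <- lapply(seq_len(n_windows), function(w)
    (w - 1) * 20 + sort(sample(0:19, sample(2:3, 1))))
  calls_list <- lapply(seq_len(n_lines), function(li) {
    rows <- lapply(seq_len(n_windows), function(w) {
      pos <- site_pos[[w]]
      ct <- rnbinom(length(pos), mu = 8, size = 3)
      level <- pattern[block_of[w], li] + rnorm(1, 0, 0.02)
      level <- min(max(level, 0), 1)
      cc <- rbinom(length(pos), ct, level)
      data.frame(chrom = "chr1", pos = pos, strand = "+", context = context,
                 C = cc, CT = ct, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out[out$CT > 0, , drop = FALSE]
  })
  names(calls_list) <- lines
  list(calls_list = lapply(calls_list, data.table::as.data.table),
       calls_df = calls_list, context = context,
       n_windows = n_windows, lines = lines,
       group1 = lines[1:2])
}

# A small simulated panel reused by several test files (built once).
.panel_cache <- new.env()
small_panel <- function() {
  if (is.null(.panel_cache$panel)) {
    gm <- simulate_population(population_config(
      n_lines = 40, n_snps = 200, n_chromosomes = 2,
      chromosome_length = 5e6, divergence = 0.15, seed = 11))
    cfgs <- list(
      planted_dmr_config(n_regions = 3, kind = "genetic_cis", contexts = "CG",
                         mef_target = 0.3),
      planted_dmr_config(n_regions = 3, kind = "pure_epigenetic", contexts = "CG",
                         mef_target = 0.2),
      planted_dmr_config(n_regions = 2, kind = "pure_epigenetic", contexts = "CHH",
                         mef_target = 0.3),
      planted_dmr_config(n_regions = 2, kind = "tissue_stable_background",
                         contexts = "CG"))
    panel <- simulate_methylome(gm, cfgs, seed = 12)
    .panel_cache$gm <- gm
    .panel_cache$panel <- panel
  }
  list(gm = .panel_cache$gm, panel = .panel_cache$panel)
}

# Structured kinship for mixed-model tests: block-diagonal relatedness
# from a quick genotype simulation.
structured_kinship <- function(n, seed = 42) {
  gm <- simulate_population(population_config(
    n_lines = n, n_snps = 300, divergence = 0.25, seed = seed))
  list(K = kinship_from_markers(gm$geno), gm = gm)
}

# Direction-recovery study for Mendelian randomization: simulate chains
# under one truth model, run the mQTL / eQTL scans and both MR models.
# Genes carry an independent eQTL (causal truth) and DMRs an independent
# mQTL (consequential truth), as real loci do, so the mismatched model
# has instruments to evaluate and its failure is measurable.
mr_direction_sim <- function(truth_model, seed, n_chains = 100, n_lines = 150) {
  gm <- simulate_population(population_config(
    n_lines = n_lines, n_snps = 400, n_chromosomes = 2,
    chromosome_length = 5e6, divergence = 0.15, seed = seed))
  kind <- if (truth_model == "causal") "genetic_cis" else "pure_epigenetic"
  panel <- simulate_methylome(gm, list(planted_dmr_config(
    n_regions = n_chains, kind = kind, contexts = "CG", mef_target = 0.3)),
    seed = seed + 1L)
  betas <- c(-1, -0.5, 0.5, 1)
  chains <- lapply(betas, function(b) causal_chain_config(
    n_genes = n_chains / 4, direction_model = truth_model,
    beta_dmr_on_expr = if (truth_model == "causal") b else b * 0.04,
    beta_snp_on_dmr = 0.25,
    beta_direct = if (truth_model == "causal") 0.8 else 0.3,
    noise_sd = if (truth_model == "causal") 1.5 else 0.5,
    polygenic_heritability = 0.2))
  tp <- simulate_traits(gm, panel, chains, seed = seed + 2L)

  dmr_levels <- t(tp$dmr_levels)  # regions x lines
  truth_reg <- panel$truth[!duplicated(panel$truth$region_id), ]
  regions <- data.frame(dmr_id = truth_reg$region_id, chrom = truth_reg$chrom,
                        start = truth_reg$start, end = truth_reg$end)
  gm_f <- maf_filter(gm, 0.05)
  K <- kinship_from_markers(gm_f$geno)
  Q <- genotype_pcs(gm_f$geno)
  mqtl <- suppressMessages(suppressWarnings(
    mqtl_scan(dmr_levels, regions, gm_f, K = K, Q = Q, apply_filters = FALSE)))
  eqtl <- expression_qtl(tp$expression, gm_f, K = K, Q = Q)
  pairs <- data.frame(dmr_id = tp$truth$region_id, trait_id = tp$truth$trait_id)
  mr <- run_mr(pairs, dmr_levels, regions, tp$expression, tp$trait_map, gm_f,
               mqtl$results, eqtl$results, K = K, Q = Q,
               n_dmrs = n_chains, n_genes = n_chains)
  list(mr = mr, cors = suppressWarnings(mr_compare_models(mr)),
       truth = tp$truth)
}
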