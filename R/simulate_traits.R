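# Synthetic quantitative traits (expression / metabolites) with planted
# SNP -> DMR -> trait causal chains, a polygenic term from genome-wide
# genotypes, and Gaussian noise.

#' Configuration for a batch of planted causal chains
#'
#' A chain links one planted DMR, one SNP and one simulated trait.  Under
#' the `causal` model the SNP drives the DMR (it must be a `genetic_cis`
#' region) and the DMR drives the trait; under the `consequential` model
#' the SNP drives the trait and the trait drives the DMR's methylation
#' level.
#'
#' @param n_genes number of traits generated from this configuration.
#' @param beta_dmr_on_expr methylation->trait effect per unit methylation
#'   (causal model), or trait->methylation effect (consequential model).
#' @param beta_snp_on_dmr SNP->methylation effect (causal; realized through
#'   the `genetic_cis` epiallele coupling), or SNP->trait effect per allele
#'   copy (consequential).
#' @param direction_model `"causal"` (SNP -> DMR -> trait) or
#'   `"consequential"` (SNP -> trait -> DMR).
#' @param beta_direct effect of an independent secondary SNP near the
#'   locus: under the causal model a direct eQTL of the trait (per allele
#'   copy), under the consequential model a direct methylation QTL of the
#'   DMR (methylation fraction per allele dose).  Real genes have eQTLs
#'   and real DMRs have mQTLs beyond any single causal path; 0 disables
#'   it.
#' @param noise_sd residual standard deviation of the trait.
#' @param polygenic_heritability fraction in `[0, 1)` of the non-planted
#'   trait variance explained by a genome-wide polygenic term drawn from
#'   the genotype matrix.
#' @param trait_type `"expression"` or `"metabolite"`.
#' @return an object of class `causal_chain_config`.
#' @export
causal_chain_config <- function(n_genes = 5L,
                                beta_dmr_on_expr = 1.0,
                                beta_snp_on_dmr = 1.0,
                                direction_model = c("causal", "consequential"),
                                beta_direct = 0,
                                noise_sd = 0.3,
                                polygenic_heritability = 0.2,
                                trait_type = c("expression", "metabolite")) {
  direction_model <- match.arg(direction_model)
  trait_type <- match.arg(trait_type)
  if (polygenic_heritability < 0 || polygenic_heritability >= 1)
    stop_popmeth("polygenic_heritability must be in [0, 1)")
  structure(list(n_genes = as.integer(n_genes),
                 beta_dmr_on_expr = beta_dmr_on_expr,
                 beta_snp_on_dmr = beta_snp_on_dmr,
                 direction_model = direction_model,
                 beta_direct = beta_direct,
                 noise_sd = noise_sd,
                 polygenic_heritability = polygenic_heritability,
                 trait_type = trait_type),
            class = "causal_chain_config")
}

# Polygenic term with variance h2 * sd^2, from standardized genotypes.
polygenic_term <- function(geno, h2, noise_sd) {
  if (h2 <= 0) return(rep(0, nrow(geno)))
  Z <- scale(geno)
  Z[is.na(Z)] <- 0
  u <- as.vector(Z %*% rnorm(ncol(Z))) / sqrt(ncol(Z))
  u * sqrt(h2) * noise_sd / max(sd(u), 1e-12)
}

#' Simulate expression and metabolite traits over a panel
#'
#' Each chain consumes one planted DMR: `causal` chains take `genetic_cis`
#' regions (so the SNP->DMR leg already exists in the methylome), while
#' `consequential` chains take `pure_epigenetic` regions and overwrite
#' their per-line methylation levels with the downstream trait effect.
#' The simulated gene is placed 50 kb from its DMR so local-association
#' and Mendelian-randomization distance rules apply.
#'
#' @param gm a `genotype_matrix`.
#' @param panel a `meth_panel` from [simulate_methylome()].
#' @param chains list of [causal_chain_config()] objects.
#' @param n_null_traits number of additional pure-noise expression traits
#'   (no planted effect) for calibration checks.
#' @param seed integer seed.
#' @return a `trait_panel`: list with `expression` and `metabolites`
#'   (lines x traits matrices), `trait_map` (trait_id, chrom, pos),
#'   `truth` (one row per chain: trait_id, region_id, snp_id, model and
#'   the planted betas), and `dmr_levels` (lines x regions matrix of true
#'   methylation levels after consequential feedback).
#' @export
simulate_traits <- function(gm, panel, chains, n_null_traits = 0L, seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(panel, "meth_panel"))
  if (inherits(chains, "causal_chain_config")) chains <- list(chains)
  set.seed(seed)
  truth_reg <- panel$truth[!duplicated(panel$truth$region_id), ]
  cis_pool <- truth_reg$region_id[truth_reg$kind == "genetic_cis"]
  epi_pool <- truth_reg$region_id[truth_reg$kind == "pure_epigenetic"]
  levels <- panel$levels
  n <- nrow(levels)
  line_id <- rownames(levels)

  traits <- list()
  map_rows <- list()
  truth_rows <- list()
  tid <- 0L
  for (cfg in chains) {
    for (g in seq_len(cfg$n_genes)) {
      tid <- tid + 1L
      if (cfg$direction_model == "causal") {
        if (length(cis_pool) == 0L)
          stop_popmeth("causal chain %d references no remaining genetic_cis DMR", tid)
        region <- cis_pool[1L]; cis_pool <- cis_pool[-1L]
      } else {
        if (length(epi_pool) == 0L)
          stop_popmeth("consequential chain %d references no remaining pure_epigenetic DMR", tid)
        region <- epi_pool[1L]; epi_pool <- epi_pool[-1L]
      }
      reg <- truth_reg[truth_reg$region_id == region, ]
      mid <- (reg$start + reg$end) / 2
      trait_id <- sprintf("%s%03d", if (cfg$trait_type == "expression") "gene" else "met", tid)
      gene_pos <- round(mid) + 50000L
      u <- polygenic_term(gm$geno, cfg$polygenic_heritability, cfg$noise_sd)
      eps <- rnorm(n, 0, cfg$noise_sd * sqrt(1 - cfg$polygenic_heritability))

      if (cfg$direction_model == "causal") {
        snp_id <- reg$snp_id
        m <- levels[, region]
        y <- cfg$beta_dmr_on_expr * m + u + eps
      } else {
        # nearest SNP to the region midpoint (same chromosome) is the driver
        cand <- which(gm$map$chrom == reg$chrom)
        snp_id <- gm$map$snp_id[cand[which.min(abs(gm$map$pos[cand] - mid))]]
        gsnp <- gm$geno[, snp_id]
        y <- cfg$beta_snp_on_dmr * gsnp + u + eps
        m_noise <- rnorm(n, 0, 0.02)
        levels[, region] <- 0.45 + cfg$beta_dmr_on_expr * (y - mean(y)) + m_noise
      }
      snp2_id <- NA_character_
      if (cfg$beta_direct != 0) {
        # an independent secondary SNP near the locus, in low LD with the
        # primary one
        g1 <- gm$geno[, snp_id]
        cand2 <- which(gm$map$chrom == reg$chrom &
                         abs(gm$map$pos - gene_pos) <= 9e5 &
                         gm$map$snp_id != snp_id)
        if (length(cand2)) {
          r2 <- vapply(cand2, function(j)
            suppressWarnings(cor(g1, gm$geno[, j]))^2, numeric(1))
          cand2 <- cand2[!is.na(r2) & r2 < 0.1]
          if (length(cand2)) {
            snp2_id <- gm$map$snp_id[cand2[which.min(abs(gm$map$pos[cand2] - gene_pos))]]
            g2 <- gm$geno[, snp2_id]
            if (cfg$direction_model == "causal") {
              y <- y + cfg$beta_direct * g2
            } else {
              levels[, region] <- levels[, region] +
                cfg$beta_direct * (g2 - mean(g2)) / 2
            }
          }
        }
      }
      traits[[trait_id]] <- y
      map_rows[[tid]] <- data.frame(trait_id = trait_id, type = cfg$trait_type,
                                    chrom = reg$chrom, pos = gene_pos,
                                    stringsAsFactors = FALSE)
      truth_rows[[tid]] <- data.frame(
        trait_id = trait_id, region_id = region, snp_id = snp_id,
        snp2_id = snp2_id, model = cfg$direction_model,
        beta_dmr_on_expr = cfg$beta_dmr_on_expr,
        beta_snp_on_dmr = cfg$beta_snp_on_dmr,
        beta_direct = cfg$beta_direct,
        stringsAsFactors = FALSE)
    }
  }
  if (n_null_traits > 0L) {
    for (g in seq_len(n_null_traits)) {
      tid <- tid + 1L
      trait_id <- sprintf("null%03d", g)
      traits[[trait_id]] <- rnorm(n)
      map_rows[[tid]] <- data.frame(trait_id = trait_id, type = "expression",
                                    chrom = gm$map$chrom[1L], pos = 1L,
                                    stringsAsFactors = FALSE)
    }
  }

  trait_map <- do.call(rbind, map_rows)
  all_traits <- do.call(cbind, traits)
  rownames(all_traits) <- line_id
  is_expr <- trait_map$type == "expression"
  structure(list(
    expression = all_traits[, trait_map$trait_id[is_expr], drop = FALSE],
    metabolites = all_traits[, trait_map$trait_id[!is_expr], drop = FALSE],
    trait_map = trait_map,
    truth = if (length(truth_rows)) do.call(rbind, truth_rows) else NULL,
    dmr_levels = levels),
    class = "trait_panel")
}
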