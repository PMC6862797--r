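# Two-model Mendelian randomization: is methylation a cause or a
# consequence of differential expression?
#
# Causal model (DMR -> expression): the instrument SNP must associate
# with methylation but not expression; beta_pred = beta_expr~DMR x
# beta_DMR~SNP is compared with the observed beta_expr~SNP.
#
# Consequential model (expression -> DMR): mirror image; the instrument
# associates with expression but not methylation, beta_pred =
# beta_expr~SNP x beta_DMR~expr is compared with beta_DMR~SNP.

#' Select the instrument SNP for one DMR-gene pair
#'
#' Candidates are the significant SNPs within 1 Mb of the exposure (the
#' DMR under the causal model, the gene under the consequential model).
#' SNPs significantly associated with the outcome (exclusion p below
#' `exclusion_p`) are filtered out; of the remainder the SNP most
#' significantly associated with the exposure is kept (ties broken by
#' ascending position, then id).
#'
#' @param candidates data.frame with snp_id, pos, exposure_p, outcome_p.
#' @param exclusion_p outcome-association exclusion threshold
#'   (0.05 / number of DMRs or genes).
#' @return the selected snp_id, or `NA_character_` when no candidate
#'   survives.
#' @export
select_instrument <- function(candidates, exclusion_p) {
  if (nrow(candidates) == 0L) return(NA_character_)
  ok <- candidates[candidates$outcome_p >= exclusion_p, , drop = FALSE]
  if (nrow(ok) == 0L) return(NA_character_)
  ok <- ok[order(ok$exposure_p, ok$pos, ok$snp_id), , drop = FALSE]
  ok$snp_id[1L]
}

#' Predicted effect under an MR model
#'
#' Causal: beta_pred = beta_expr~DMR x beta_DMR~SNP.
#' Consequential: beta_pred = beta_expr~SNP x beta_DMR~expr.
#'
#' @param beta_upstream,beta_downstream the two component effects along
#'   the modelled path (SNP->exposure, exposure->outcome).
#' @return their product.
#' @export
mr_predicted_effect <- function(beta_upstream, beta_downstream) {
  beta_upstream * beta_downstream
}

# Residual-model OLS of outcome on exposure.  Both sides are INT
# transformed (matching the scans that estimate the SNP-side components,
# so path products stay on one scale) and the outcome is kinship/
# structure-adjusted first.
residual_ols <- function(outcome, exposure, K, Q) {
  lines <- intersect(names(outcome)[!is.na(outcome)],
                     names(exposure)[!is.na(exposure)])
  y <- inverse_normal_transform(outcome[lines])
  yprime <- residual_trait(y, K[lines, lines],
                           if (is.null(Q)) NULL else Q[lines, , drop = FALSE])
  x <- inverse_normal_transform(exposure[lines])
  x <- x - mean(x)
  beta <- sum(x * (yprime - mean(yprime))) / sum(x^2)
  df <- length(lines) - 2L
  rss <- sum((yprime - mean(yprime) - beta * x)^2)
  se <- sqrt(rss / df / sum(x^2))
  list(beta = beta, p = 2 * pt(-abs(beta / se), df))
}

# Mixed-model effect of a SNP on a trait vector (INT-transformed).
mm_effect <- function(trait, snp, K, Q) {
  lines <- intersect(names(trait)[!is.na(trait)], names(snp))
  y <- inverse_normal_transform(trait[lines])
  fit <- fit_mlm(y, snp[lines], K[lines, lines],
                 if (is.null(Q)) NULL else Q[lines, , drop = FALSE])
  list(beta = fit$beta, p = fit$p)
}

#' Run both MR models over DMR-gene pairs
#'
#' @param pairs data.frame with dmr_id, trait_id; only pairs whose DMR
#'   and gene lie within `max_pair_bp` of each other are evaluated.
#' @param dmr_levels DMRs x lines methylation matrix.
#' @param dmr_regions data.frame: dmr_id, chrom, start, end.
#' @param traits lines x traits matrix (expression).
#' @param trait_map data.frame: trait_id, chrom, pos.
#' @param gm a `genotype_matrix` (analysis markers).
#' @param mqtl_results significant SNP-DMR associations (data.table from
#'   [mqtl_scan()], at least dmr_id, snp_id, pos, beta, p).
#' @param exprqtl_results significant SNP-trait associations (same shape,
#'   with trait_id in place of dmr_id).
#' @param K kinship matrix; `NULL` computes the standardized GRM.
#' @param Q structure covariates; `NULL` uses top-3 genotype PCs.
#' @param n_dmrs,n_genes test counts behind the exclusion thresholds
#'   (0.05 / count).
#' @param max_pair_bp maximum DMR-gene and SNP-exposure distance
#'   (default 1 Mb).
#' @return data.frame of `mr_result` rows: one per pair and model with
#'   instrument, component betas, beta_pred and beta_obs (`NA` when no
#'   instrument survived).
#' @export
run_mr <- function(pairs, dmr_levels, dmr_regions, traits, trait_map, gm,
                   mqtl_results, exprqtl_results, K = NULL, Q = NULL,
                   n_dmrs = nrow(dmr_levels), n_genes = ncol(traits),
                   max_pair_bp = 1e6) {
  # plain data.frames: the filters below use locals that shadow column
  # names, which data.table's scoping would capture instead
  mqtl_results <- as.data.frame(mqtl_results)
  exprqtl_results <- as.data.frame(exprqtl_results)
  lines <- intersect(colnames(dmr_levels), rownames(gm$geno))
  lines <- intersect(lines, rownames(traits))
  geno <- gm$geno[lines, , drop = FALSE]
  if (is.null(K)) K <- kinship_from_markers(geno)
  if (is.null(Q)) Q <- genotype_pcs(geno)
  K <- K[lines, lines]
  Q <- Q[lines, , drop = FALSE]
  excl_causal <- bonferroni_threshold(0.05, n_dmrs)
  excl_conseq <- bonferroni_threshold(0.05, n_genes)

  out <- list()
  for (i in seq_len(nrow(pairs))) {
    dmr_id <- pairs$dmr_id[i]
    trait_id <- pairs$trait_id[i]
    reg <- dmr_regions[dmr_regions$dmr_id == dmr_id, ]
    gpos <- trait_map[trait_map$trait_id == trait_id, ]
    if (nrow(reg) == 0L || nrow(gpos) == 0L) next
    dmr_mid <- (reg$start + reg$end) / 2
    if (reg$chrom != gpos$chrom || abs(dmr_mid - gpos$pos) > max_pair_bp) next
    m <- dmr_levels[dmr_id, lines]
    e <- traits[lines, trait_id]

    # --- causal model: SNP -> DMR -> expression -----------------------
    cand <- mqtl_results[mqtl_results$dmr_id == dmr_id, ]
    cand <- cand[abs(cand$pos - dmr_mid) <= max_pair_bp &
                   gm$map$chrom[match(cand$snp_id, gm$map$snp_id)] == reg$chrom, ]
    causal <- list(instrument = NA_character_)
    if (nrow(cand)) {
      expr_stats <- lapply(cand$snp_id, function(s)
        mm_effect(e, geno[, s], K, Q))
      cdf <- data.frame(snp_id = cand$snp_id, pos = cand$pos,
                        exposure_p = cand$p,
                        outcome_p = vapply(expr_stats, `[[`, 0, "p"))
      inst <- select_instrument(cdf, excl_causal)
      if (!is.na(inst)) {
        j <- match(inst, cdf$snp_id)
        b_dmr_snp <- cand$beta[j]
        b_expr_dmr <- residual_ols(e, m, K, Q)$beta
        causal <- list(instrument = inst,
                       beta_exposure_snp = b_dmr_snp,
                       beta_outcome_exposure = b_expr_dmr,
                       beta_pred = mr_predicted_effect(b_dmr_snp, b_expr_dmr),
                       beta_obs = mm_effect(e, geno[, inst], K, Q)$beta)
      }
    }

    # --- consequential model: SNP -> expression -> DMR ----------------
    cand2 <- exprqtl_results[exprqtl_results$trait_id == trait_id, ]
    cand2 <- cand2[abs(cand2$pos - gpos$pos) <= max_pair_bp &
                     gm$map$chrom[match(cand2$snp_id, gm$map$snp_id)] == gpos$chrom, ]
    conseq <- list(instrument = NA_character_)
    if (nrow(cand2)) {
      dmr_stats <- lapply(cand2$snp_id, function(s)
        mm_effect(m, geno[, s], K, Q))
      cdf2 <- data.frame(snp_id = cand2$snp_id, pos = cand2$pos,
                         exposure_p = cand2$p,
                         outcome_p = vapply(dmr_stats, `[[`, 0, "p"))
      inst2 <- select_instrument(cdf2, excl_conseq)
      if (!is.na(inst2)) {
        j2 <- match(inst2, cdf2$snp_id)
        b_expr_snp <- cand2$beta[j2]
        b_dmr_expr <- residual_ols(m, e, K, Q)$beta
        conseq <- list(instrument = inst2,
                       beta_exposure_snp = b_expr_snp,
                       beta_outcome_exposure = b_dmr_expr,
                       beta_pred = mr_predicted_effect(b_expr_snp, b_dmr_expr),
                       beta_obs = mm_effect(m, geno[, inst2], K, Q)$beta)
      }
    }

    for (model in c("causal", "consequential")) {
      r <- if (model == "causal") causal else conseq
      out[[length(out) + 1L]] <- data.frame(
        dmr_id = dmr_id, trait_id = trait_id, model = model,
        instrument = r$instrument,
        beta_exposure_snp = if (is.na(r$instrument)) NA_real_ else r$beta_exposure_snp,
        beta_outcome_exposure = if (is.na(r$instrument)) NA_real_ else r$beta_outcome_exposure,
        beta_pred = if (is.na(r$instrument)) NA_real_ else r$beta_pred,
        beta_obs = if (is.na(r$instrument)) NA_real_ else r$beta_obs,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(dmr_id = character(), trait_id = character(),
                      model = character(), instrument = character(),
                      beta_exposure_snp = numeric(),
                      beta_outcome_exposure = numeric(),
                      beta_pred = numeric(), beta_obs = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Compare predicted and observed effects per MR model
#'
#' @param mr_results data.frame from [run_mr()].
#' @param min_pairs below this many evaluable pairs per model a warning
#'   is attached (default 10).
#' @return named numeric vector of Pearson correlations
#'   `c(causal = ..., consequential = ...)`; `NA` when a model has < 3
#'   evaluable pairs.
#' @export
mr_compare_models <- function(mr_results, min_pairs = 10L) {
  vapply(c("causal", "consequential"), function(model) {
    sub <- mr_results[mr_results$model == model & !is.na(mr_results$beta_pred), ]
    if (nrow(sub) < min_pairs)
      warning(sprintf("%s model: only %d evaluable pairs", model, nrow(sub)))
    if (nrow(sub) < 3L) return(NA_real_)
    cor(sub$beta_pred, sub$beta_obs)
  }, numeric(1))
}
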