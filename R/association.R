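# mQTL mapping and DMR-trait association: MAF filter, rank-based inverse
# normal transform, Bonferroni thresholds, LD pruning, haplotype-effect
# filter, local/distal classification, and the two-step residual model.

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n number of tests.
#' @return alpha / n.
#' @export
bonferroni_threshold <- function(alpha, n) {
  if (n < 1) stop_popmeth("n must be positive")
  alpha / n
}

#' Filter markers by minor allele frequency
#'
#' Markers are kept when their MAF, computed on the analysis lines only,
#' strictly exceeds the threshold.
#'
#' @param gm a `genotype_matrix`.
#' @param threshold MAF cutoff (default 0.05; strict `>`).
#' @param lines optional line subset on which MAF is computed.
#' @return a `genotype_matrix` restricted to surviving markers.
#' @export
maf_filter <- function(gm, threshold = 0.05, lines = NULL) {
  keep <- maf(gm, lines = lines) > threshold
  out <- gm
  out$geno <- gm$geno[, keep, drop = FALSE]
  out$map <- gm$map[keep, , drop = FALSE]
  out
}

#' Rank-based inverse normal transformation
#'
#' Blom-offset INT: Phi^-1((rank - 3/8) / (n + 1/4)), with ties sharing
#' their average rank and missing values passed through.
#'
#' @param x numeric vector (>= 3 non-missing, non-constant values).
#' @return transformed vector, same length and names as `x`.
#' @export
inverse_normal_transform <- function(x) {
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 3L) stop_popmeth("inverse_normal_transform needs >= 3 non-missing values")
  if (length(unique(x[obs])) < 2L) stop_popmeth("constant input: ranks undefined")
  out <- x
  r <- rank(x[obs], ties.method = "average")
  out[obs] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Classify the distance between a marker and a target
#'
#' Local: same chromosome and within 10 Mb (measured from the target
#' midpoint); distal: different chromosome; unclassified: same chromosome
#' beyond 10 Mb.
#'
#' @param snp_chrom,snp_pos marker coordinates.
#' @param target_chrom,target_pos target coordinates (DMR midpoint or
#'   gene position).
#' @param local_max_bp local window (default 10 Mb).
#' @return character vector: "local", "distal", or "unclassified".
#' @export
distance_class <- function(snp_chrom, snp_pos, target_chrom, target_pos,
                           local_max_bp = 1e7) {
  ifelse(snp_chrom != target_chrom, "distal",
         ifelse(abs(snp_pos - target_pos) <= local_max_bp, "local", "unclassified"))
}

#' Greedy LD pruning of significant markers
#'
#' Markers are taken in order of ascending p (ties: ascending position,
#' then id); each is accepted only when its genotype r-squared with every
#' already-accepted marker is below `r2_max`.  r-squared is the squared
#' Pearson correlation of genotype codes, which is the haplotype r^2 for
#' fully inbred homozygous data.
#'
#' @param snp_ids candidate marker ids.
#' @param p their association p-values.
#' @param gm a `genotype_matrix` containing the markers.
#' @param r2_max LD ceiling (default 0.1; strict `<` acceptance).
#' @return character vector of accepted (LD-independent) marker ids.
#' @export
ld_prune <- function(snp_ids, p, gm, r2_max = 0.1) {
  if (length(snp_ids) == 0L) return(character(0))
  pos <- gm$map$pos[match(snp_ids, gm$map$snp_id)]
  ord <- order(p, pos, snp_ids)
  snp_ids <- snp_ids[ord]
  accepted <- snp_ids[1L]
  for (s in snp_ids[-1L]) {
    r2 <- cor(gm$geno[, s], gm$geno[, accepted, drop = FALSE])^2
    if (all(r2 < r2_max, na.rm = TRUE)) accepted <- c(accepted, s)
  }
  accepted
}

#' Haplotype median-effect filter
#'
#' The two homozygous allele classes must differ in median methylation by
#' more than `min_diff` for the association to stand.
#'
#' @param genotypes marker codes (0/2) per line.
#' @param levels methylation levels per line (same order).
#' @param min_diff minimum absolute median difference (default 0.05,
#'   strict `>`).
#' @return list with `pass` and `median_diff` (`NA` with `pass = FALSE`
#'   when an allele class has < 2 lines).
#' @export
haplotype_effect_filter <- function(genotypes, levels, min_diff = 0.05) {
  ok <- !is.na(genotypes) & !is.na(levels)
  g <- genotypes[ok]; lv <- levels[ok]
  alleles <- sort(unique(g))
  if (length(alleles) < 2L || any(table(g) < 2L))
    return(list(pass = FALSE, median_diff = NA_real_))
  d <- abs(median(lv[g == alleles[1L]]) - median(lv[g == alleles[2L]]))
  list(pass = d > min_diff, median_diff = d)
}

#' QTL category of a DMR from its surviving associations
#'
#' @param classes character vector of distance classes of the DMR's
#'   surviving marker associations.
#' @return one of "Local_only", "Distal_only", "Both", "Unclassified",
#'   "None".  Any unclassified-distance marker makes the DMR
#'   Unclassified.
#' @export
categorize_dmr <- function(classes) {
  if (length(classes) == 0L) return("None")
  if (any(classes == "unclassified")) return("Unclassified")
  has_local <- any(classes == "local")
  has_distal <- any(classes == "distal")
  if (has_local && has_distal) "Both"
  else if (has_local) "Local_only"
  else "Distal_only"
}

#' Genome-wide methylation QTL scan
#'
#' For each DMR: its per-line methylation is inverse-normal transformed,
#' the null mixed model (structure covariates Q, kinship K) is fitted
#' once by REML, and every marker is tested under the fixed variance
#' ratio.  Associations below the Bonferroni threshold alpha / n_markers
#' are kept, LD-pruned per DMR (r^2 < 0.1), filtered on the haplotype
#' median effect (> 0.05), and classified local/distal from the DMR
#' midpoint.
#'
#' @param dmr_levels DMRs x lines methylation matrix (e.g.
#'   `dmr_set$levels`), or a `dmr_set`.
#' @param dmr_regions data.frame with dmr_id, chrom, start, end (ignored
#'   when `dmr_levels` is a `dmr_set`).
#' @param gm a `genotype_matrix`, already MAF-filtered on analysis lines.
#' @param K kinship matrix; `NULL` computes the standardized GRM from
#'   `gm`.
#' @param Q structure covariates; `NULL` uses the top-3 genotype PCs.
#' @param alpha family-wise error rate (default 0.05).
#' @param apply_filters run LD pruning and the haplotype filter
#'   (default TRUE).
#' @param min_lines warn below this many shared lines (default 50).
#' @return list with `results` (data.table: dmr_id, snp_id, chrom, pos,
#'   beta, se, p, class, passed_ld_filter, passed_haplotype_filter),
#'   `categories` (named per-DMR QTL category), `threshold`, and
#'   `n_markers`.
#' @export
mqtl_scan <- function(dmr_levels, dmr_regions = NULL, gm, K = NULL, Q = NULL,
                      alpha = 0.05, apply_filters = TRUE, min_lines = 50L) {
  if (inherits(dmr_levels, "dmr_set")) {
    dmr_regions <- dmr_levels$regions
    dmr_levels <- dmr_levels$levels
  }
  lines <- intersect(colnames(dmr_levels), rownames(gm$geno))
  if (length(lines) < min_lines)
    warning(sprintf("only %d shared lines; association power will be low", length(lines)))
  geno <- gm$geno[lines, , drop = FALSE]
  if (is.null(K)) K <- kinship_from_markers(geno)
  if (is.null(Q)) Q <- genotype_pcs(geno)
  K <- K[lines, lines]
  Q <- Q[lines, , drop = FALSE]
  n_markers <- ncol(geno)
  threshold <- bonferroni_threshold(alpha, n_markers)
  message(sprintf("mQTL scan: %d DMRs x %d markers over %d lines; Bonferroni P < %.3g",
                  nrow(dmr_levels), n_markers, length(lines), signif(threshold, 3)))

  res_rows <- list()
  categories <- setNames(rep("None", nrow(dmr_levels)), rownames(dmr_levels))
  for (i in seq_len(nrow(dmr_levels))) {
    dmr_id <- rownames(dmr_levels)[i]
    lv <- dmr_levels[i, lines]
    obs <- !is.na(lv)
    if (sum(obs) < 10L) next
    y <- inverse_normal_transform(lv[obs])
    sub <- lines[obs]
    null <- fit_mlm_null(y, K[sub, sub], Q[sub, , drop = FALSE])
    scan <- mlm_scan(null, geno[sub, , drop = FALSE])
    sig <- which(!is.na(scan$p) & scan$p < threshold)
    if (length(sig) == 0L) next
    snp_ids <- gm$map$snp_id[sig]
    keep_ld <- if (apply_filters) ld_prune(snp_ids, scan$p[sig], gm) else snp_ids
    mid <- (dmr_regions$start[dmr_regions$dmr_id == dmr_id] +
              dmr_regions$end[dmr_regions$dmr_id == dmr_id]) / 2
    dmr_chrom <- dmr_regions$chrom[dmr_regions$dmr_id == dmr_id]
    rows <- data.table::data.table(
      dmr_id = dmr_id, snp_id = snp_ids,
      chrom = gm$map$chrom[sig], pos = gm$map$pos[sig],
      beta = scan$beta[sig], se = scan$se[sig], p = scan$p[sig])
    rows[, passed_ld_filter := snp_id %in% keep_ld]
    rows[, passed_haplotype_filter := vapply(snp_id, function(s)
      haplotype_effect_filter(geno[sub, s], lv[obs])$pass, logical(1))]
    rows[, class := distance_class(chrom, pos, dmr_chrom, mid)]
    res_rows[[length(res_rows) + 1L]] <- rows
    surviving <- rows[passed_ld_filter & passed_haplotype_filter]
    categories[dmr_id] <- categorize_dmr(surviving$class)
  }
  results <- if (length(res_rows)) data.table::rbindlist(res_rows) else
    data.table::data.table(dmr_id = character(), snp_id = character(),
                           chrom = character(), pos = integer(),
                           beta = numeric(), se = numeric(), p = numeric(),
                           passed_ld_filter = logical(),
                           passed_haplotype_filter = logical(),
                           class = character())
  list(results = results, categories = categories,
       threshold = threshold, n_markers = n_markers)
}

#' Two-step DMR-trait association scan
#'
#' Step 1 adjusts each inverse-normal-transformed trait for structure and
#' kinship ([residual_trait()]); step 2 regresses the residual on each
#' DMR's methylation by ordinary least squares.  Pairs sharing data in
#' fewer than `min_overlap` of the lines are skipped.  Significance is
#' Bonferroni at alpha / n_dmrs.
#'
#' @param traits lines x traits matrix (expression or metabolites).
#' @param dmr_levels DMRs x lines methylation matrix.
#' @param K kinship matrix over the trait lines.
#' @param Q structure covariates.
#' @param alpha family-wise error rate (default 0.01).
#' @param min_overlap minimum shared-line fraction per pair (default 0.6).
#' @return list with `results` (data.table: trait_id, dmr_id, beta, se,
#'   p, n, significant) and `threshold`.
#' @export
dmr_trait_scan <- function(traits, dmr_levels, K, Q = NULL, alpha = 0.01,
                           min_overlap = 0.6) {
  lines <- intersect(rownames(traits), colnames(dmr_levels))
  n_dmrs <- nrow(dmr_levels)
  threshold <- bonferroni_threshold(alpha, n_dmrs)
  message(sprintf("DMR-trait scan: %d traits x %d DMRs; Bonferroni P < %.3g",
                  ncol(traits), n_dmrs, signif(threshold, 3)))
  rows <- list()
  for (tj in seq_len(ncol(traits))) {
    yraw <- traits[lines, tj]
    obs_y <- !is.na(yraw)
    y <- inverse_normal_transform(yraw[obs_y])
    sub <- lines[obs_y]
    yprime <- residual_trait(y, K[sub, sub], if (is.null(Q)) NULL else Q[sub, , drop = FALSE])
    names(yprime) <- sub
    for (di in seq_len(n_dmrs)) {
      x <- dmr_levels[di, sub]
      ok <- !is.na(x)
      if (sum(ok) < min_overlap * length(lines) || sum(ok) < 4L) next
      xr <- x[ok] - mean(x[ok])
      if (sum(xr^2) < 1e-12) next
      yy <- yprime[ok] - mean(yprime[ok])
      beta <- sum(xr * yy) / sum(xr^2)
      df <- sum(ok) - 2L
      rss <- sum((yy - beta * xr)^2)
      se <- sqrt(rss / df / sum(xr^2))
      p <- 2 * pt(-abs(beta / se), df)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        trait_id = colnames(traits)[tj], dmr_id = rownames(dmr_levels)[di],
        beta = beta, se = se, p = p, n = sum(ok))
    }
  }
  results <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(trait_id = character(), dmr_id = character(),
                           beta = numeric(), se = numeric(), p = numeric(),
                           n = integer())
  results[, significant := p < threshold]
  list(results = results, threshold = threshold)
}
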