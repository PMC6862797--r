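# End-to-end pipeline driver: simulate -> window -> call DMRs ->
# epiallele stats -> relatedness -> mQTL -> trait association -> MR,
# with a JSON run manifest recording seeds and every threshold applied.

#' Run the full pipeline from a YAML configuration
#'
#' Stages run in dependency order; all randomness flows from the single
#' `seed`.  Re-running with an identical config and seed reproduces every
#' output byte for byte.
#'
#' @param config path to a YAML file or an equivalent nested list.  See
#'   `system.file("extdata", "demo_config.yaml", package = "popmeth")`
#'   for the schema: `population` ([population_config()] fields),
#'   `dmrs` (list of [planted_dmr_config()] field sets), `chains`
#'   (list of [causal_chain_config()] field sets), and optional
#'   `alpha_mqtl`, `alpha_trait`, `contexts`.
#' @param seed integer overriding the config seed (`NULL` keeps it).
#' @param out_dir directory for output artifacts (`NULL` skips writing).
#' @return list with `genotypes`, `methylome`, `traits`, `dmrs` (per
#'   context), `epialleles`, `kinship`, `mqtl`, `assoc`, `mr`,
#'   `mr_correlations`, and `manifest`.
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (key in c("population", "dmrs")) {
    if (is.null(cfg[[key]]))
      stop_popmeth("config is missing required key '%s'", key)
  }
  if (!is.null(seed)) cfg$population$seed <- as.integer(seed)
  pop_cfg <- do.call(population_config, cfg$population)
  gm <- simulate_population(pop_cfg)
  dmr_cfgs <- lapply(cfg$dmrs, function(d) do.call(planted_dmr_config, d))
  panel <- simulate_methylome(gm, dmr_cfgs, seed = pop_cfg$seed + 1L)
  traits <- NULL
  if (!is.null(cfg$chains)) {
    chain_cfgs <- lapply(cfg$chains, function(d) do.call(causal_chain_config, d))
    traits <- simulate_traits(gm, panel, chain_cfgs, seed = pop_cfg$seed + 2L)
  }

  contexts <- cfg$contexts %||% unique(panel$truth$context)
  manifest <- list(config = cfg, seed = pop_cfg$seed,
                   versions = list(popmeth = as.character(utils::packageVersion("popmeth")),
                                   R = R.version.string),
                   thresholds = list(), outputs = character())
  subgroups <- setNames(gm$lines$subgroup, gm$lines$line_id)

  dmrs <- list(); epistats <- list()
  for (ctx in contexts) {
    d <- call_dmrs(panel$calls, ctx, k = min(16L, pop_cfg$n_lines %/% 4L))
    dmrs[[ctx]] <- d
    if (nrow(d$regions))
      epistats[[ctx]] <- epiallele_summary(d, calls_list = panel$calls,
                                           subgroups = subgroups)
  }

  K_snp <- kinship_from_markers(gm$geno)
  kin <- list(snp = K_snp)
  for (ctx in names(dmrs)) {
    if (nrow(dmrs[[ctx]]$regions) >= 2L)
      kin[[paste0("meth_", ctx)]] <- kinship_from_markers(t(dmrs[[ctx]]$levels))
  }

  gm_f <- maf_filter(gm, 0.05, lines = rownames(gm$geno))
  Q <- genotype_pcs(gm_f$geno)
  alpha_mqtl <- cfg$alpha_mqtl %||% 0.05
  alpha_trait <- cfg$alpha_trait %||% 0.01
  mqtl <- list(); assoc <- list(); mr <- NULL; mr_cor <- NULL
  for (ctx in names(dmrs)) {
    d <- dmrs[[ctx]]
    if (nrow(d$regions) == 0L) next
    mqtl[[ctx]] <- mqtl_scan(d, gm = gm_f, K = K_snp, Q = Q, alpha = alpha_mqtl)
    manifest$thresholds[[paste0("mqtl_", ctx)]] <- signif(mqtl[[ctx]]$threshold, 3)
    if (!is.null(traits) && ncol(traits$expression) > 0L) {
      assoc[[ctx]] <- dmr_trait_scan(traits$expression, d$levels, K = K_snp,
                                     Q = Q, alpha = alpha_trait)
      manifest$thresholds[[paste0("assoc_", ctx)]] <- signif(assoc[[ctx]]$threshold, 3)
    }
  }

  if (!is.null(traits) && length(assoc)) {
    all_regions <- do.call(rbind, lapply(dmrs, function(d) d$regions))
    all_levels <- do.call(rbind, lapply(dmrs, function(d) d$levels))
    all_mqtl <- data.table::rbindlist(lapply(mqtl, function(m) m$results))
    sig_pairs <- data.table::rbindlist(lapply(assoc, function(a)
      a$results[a$results$significant, c("dmr_id", "trait_id")]))
    if (nrow(sig_pairs) && nrow(all_mqtl)) {
      exprqtl <- expression_qtl(traits$expression, gm_f, K_snp, Q, alpha = alpha_mqtl)
      mr <- run_mr(as.data.frame(sig_pairs), all_levels, all_regions,
                   traits$expression, traits$trait_map, gm_f,
                   all_mqtl, exprqtl$results, K = K_snp, Q = Q)
      if (nrow(mr)) mr_cor <- suppressWarnings(mr_compare_models(mr))
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genotypes(gm, tsv_path = file.path(out_dir, "genotypes.tsv"),
                    vcf_path = file.path(out_dir, "genotypes.vcf"))
    for (ctx in names(dmrs)) {
      if (nrow(dmrs[[ctx]]$regions) == 0L) next
      bed <- file.path(out_dir, sprintf("dmrs_%s.bed", ctx))
      write_dmr_bed(dmrs[[ctx]], bed)
      data.table::fwrite(data.table::as.data.table(dmrs[[ctx]]$levels,
                                                   keep.rownames = "dmr_id"),
                         file.path(out_dir, sprintf("dmr_levels_%s.tsv", ctx)),
                         sep = "\t")
      manifest$outputs <- c(manifest$outputs, bed)
    }
    manifest_path <- file.path(out_dir, "run_manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  }

  list(genotypes = gm, methylome = panel, traits = traits, dmrs = dmrs,
       epialleles = epistats, kinship = kin, mqtl = mqtl, assoc = assoc,
       mr = mr, mr_correlations = mr_cor, manifest = manifest)
}

#' Genome-wide expression QTL scan (mixed model)
#'
#' Same machinery as [mqtl_scan()] with traits as dependent variables;
#' used to find the consequential-model instrument candidates.
#'
#' @param traits lines x traits matrix.
#' @param gm a `genotype_matrix` (MAF-filtered).
#' @param K kinship matrix.
#' @param Q structure covariates.
#' @param alpha family-wise error rate (default 0.05).
#' @return list with `results` (data.table: trait_id, snp_id, chrom, pos,
#'   beta, se, p) restricted to significant associations, and
#'   `threshold`.
#' @export
expression_qtl <- function(traits, gm, K = NULL, Q = NULL, alpha = 0.05) {
  lines <- intersect(rownames(traits), rownames(gm$geno))
  geno <- gm$geno[lines, , drop = FALSE]
  if (is.null(K)) K <- kinship_from_markers(geno)
  if (is.null(Q)) Q <- genotype_pcs(geno)
  threshold <- bonferroni_threshold(alpha, ncol(geno))
  rows <- list()
  for (tj in seq_len(ncol(traits))) {
    yraw <- traits[lines, tj]
    obs <- !is.na(yraw)
    y <- inverse_normal_transform(yraw[obs])
    sub <- lines[obs]
    null <- fit_mlm_null(y, K[sub, sub], Q[sub, , drop = FALSE])
    scan <- mlm_scan(null, geno[sub, , drop = FALSE])
    sig <- which(!is.na(scan$p) & scan$p < threshold)
    if (length(sig))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        trait_id = colnames(traits)[tj], snp_id = gm$map$snp_id[sig],
        chrom = gm$map$chrom[sig], pos = gm$map$pos[sig],
        beta = scan$beta[sig], se = scan$se[sig], p = scan$p[sig])
  }
  results <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(trait_id = character(), snp_id = character(),
                           chrom = character(), pos = integer(),
                           beta = numeric(), se = numeric(), p = numeric())
  list(results = results, threshold = threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
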