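# Synthetic per-cytosine bisulfite calls with planted DMRs.
#
# Epialleles are binary per line per region (high/low methylation level);
# reads are sampled binomially around the line's level, with per-cytosine
# coverage drawn from an overdispersed negative-binomial model.  Inbred
# panels show strongly bimodal methylation at variable regions, which is
# what makes planted truth recoverable and assertable.

#' Configuration for one batch of planted regions
#'
#' @param n_regions number of regions of this kind.
#' @param region_length region length in bp; must be a multiple of 20.
#' @param contexts cytosine contexts simulated in the region
#'   (subset of CG/CHG/CHH).
#' @param kind `"genetic_cis"` (epiallele state copies a linked SNP),
#'   `"pure_epigenetic"` (epiallele state drawn independently of genotype),
#'   or `"tissue_stable_background"` (no variation; negative control).
#' @param high_level,low_level methylation fraction of the high/low
#'   epiallele.  For CG/CHG planted variation the difference must exceed
#'   0.6 and for CHH the low level must be < 0.05 with the high level
#'   > 0.25, so that planted truth satisfies the caller's definitional
#'   thresholds.
#' @param mef_target target minor-epiallele frequency in (0, 0.5].
#' @param linked_snp_distance bp between a genetic_cis region and its
#'   controlling SNP.
#' @param cytosine_density cytosines per 20-bp window per context.
#' @param coverage_mean,coverage_dispersion negative-binomial read-count
#'   model (`mu` and `size` of [stats::rnbinom()]).
#' @param missing_line_fraction fraction of lines with zero coverage over
#'   the whole region (exercises the >60%-of-lines QC filters).
#' @return an object of class `planted_dmr_config`.
#' @export
planted_dmr_config <- function(n_regions = 5L,
                               region_length = 120L,
                               contexts = "CG",
                               kind = c("pure_epigenetic", "genetic_cis",
                                        "tissue_stable_background"),
                               high_level = NULL,
                               low_level = NULL,
                               mef_target = 0.2,
                               linked_snp_distance = 1000L,
                               cytosine_density = 4L,
                               coverage_mean = 20,
                               coverage_dispersion = 5,
                               missing_line_fraction = 0) {
  kind <- match.arg(kind)
  contexts <- match.arg(contexts, METH_CONTEXTS, several.ok = TRUE)
  if (region_length %% WINDOW_BP != 0L)
    stop_popmeth("region_length must be a multiple of %d bp", WINDOW_BP)
  chh <- identical(contexts, "CHH")
  if (is.null(high_level)) high_level <- if (chh) 0.35 else 0.85
  if (is.null(low_level)) low_level <- if (chh) 0.02 else 0.05
  if (kind != "tissue_stable_background") {
    for (ctx in contexts) {
      if (ctx %in% c("CG", "CHG") && (high_level - low_level) <= 0.6)
        stop_popmeth("planted %s variation needs high_level - low_level > 0.6", ctx)
      if (ctx == "CHH" && !(low_level < 0.05 && high_level > 0.25))
        stop_popmeth("planted CHH variation needs low_level < 0.05 and high_level > 0.25")
    }
  }
  if (mef_target <= 0 || mef_target > 0.5)
    stop_popmeth("mef_target must be in (0, 0.5]")
  if (cytosine_density < 1L || cytosine_density > WINDOW_BP)
    stop_popmeth("cytosine_density must be in [1, %d]", WINDOW_BP)
  structure(list(n_regions = as.integer(n_regions),
                 region_length = as.integer(region_length),
                 contexts = contexts, kind = kind,
                 high_level = high_level, low_level = low_level,
                 mef_target = mef_target,
                 linked_snp_distance = as.integer(linked_snp_distance),
                 cytosine_density = as.integer(cytosine_density),
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 missing_line_fraction = missing_line_fraction),
            class = "planted_dmr_config")
}

# Place regions on the 20-bp grid without overlap.  genetic_cis regions sit
# `linked_snp_distance` downstream of their controlling SNP; others fill
# sequential slots left free by the cis placements.
place_regions <- function(gm, configs, chrom_lengths) {
  occupied <- list()  # per chrom: matrix of (start, end)
  overlaps <- function(chrom, start, end) {
    occ <- occupied[[chrom]]
    !is.null(occ) && any(start < occ[, 2] & end > occ[, 1])
  }
  claim <- function(chrom, start, end) {
    occupied[[chrom]] <<- rbind(occupied[[chrom]], c(start, end))
  }
  placements <- list()
  rid <- 0L
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    for (r in seq_len(cfg$n_regions)) {
      rid <- rid + 1L
      if (cfg$kind == "genetic_cis") {
        cand <- order(abs(maf(gm) - cfg$mef_target))
        placed <- FALSE
        for (j in cand) {
          chrom <- gm$map$chrom[j]
          start <- (gm$map$pos[j] + cfg$linked_snp_distance) %/% WINDOW_BP * WINDOW_BP
          end <- start + cfg$region_length
          if (start >= 0 && end <= chrom_lengths[[chrom]] && !overlaps(chrom, start, end)) {
            claim(chrom, start, end)
            placements[[rid]] <- list(region_id = sprintf("dmr%03d", rid),
                                      config_idx = ci, chrom = chrom,
                                      start = start, end = end,
                                      snp_id = gm$map$snp_id[j])
            placed <- TRUE
            break
          }
        }
        if (!placed) stop_popmeth("could not place genetic_cis region %d without overlap", rid)
      } else {
        chroms <- names(chrom_lengths)
        chrom <- chroms[(rid - 1L) %% length(chroms) + 1L]
        start <- 0L
        step <- cfg$region_length + 2000L
        repeat {
          end <- start + cfg$region_length
          if (end > chrom_lengths[[chrom]])
            stop_popmeth("chromosome %s too short to place region %d", chrom, rid)
          if (!overlaps(chrom, start, end)) break
          start <- start + step
        }
        claim(chrom, start, end)
        placements[[rid]] <- list(region_id = sprintf("dmr%03d", rid),
                                  config_idx = ci, chrom = chrom,
                                  start = start, end = end, snp_id = NA_character_)
      }
    }
  }
  placements
}

#' Simulate a capture-style methylome with planted DMRs
#'
#' Emits methratio-style per-cytosine calls for every line over the planted
#' regions, together with a truth table.  Epiallele states per region:
#' `genetic_cis` regions copy a linked SNP (the minor allele carries the
#' low/rare epiallele), `pure_epigenetic` regions assign the low epiallele
#' independently of genotype with probability `mef_target`, and
#' `tissue_stable_background` regions have no variation at all.
#'
#' @param gm a `genotype_matrix` from [simulate_population()].
#' @param dmr_configs list of [planted_dmr_config()] objects; their regions
#'   must fit on the simulated chromosomes without overlap.
#' @param chrom_lengths named lengths of the chromosomes; defaults to the
#'   configuration used by [simulate_population()].
#' @param seed integer seed for read sampling and epiallele assignment.
#' @return a `meth_panel`: list with `calls` (named list, one coordinate-
#'   sorted data.table of cytosine calls per line), `truth` (data.frame:
#'   region_id, chrom, start, end, context, kind, snp_id, high_level,
#'   low_level), `epialleles` (lines x regions matrix, "high"/"low"),
#'   `levels` (lines x regions matrix of true methylation levels),
#'   `lines`, and `chrom_lengths`.
#' @export
simulate_methylome <- function(gm, dmr_configs, chrom_lengths = NULL, seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (inherits(dmr_configs, "planted_dmr_config")) dmr_configs <- list(dmr_configs)
  set.seed(seed)
  if (is.null(chrom_lengths)) {
    chroms <- unique(gm$map$chrom)
    chrom_lengths <- setNames(rep(max(gm$map$pos) + 1e5, length(chroms)), chroms)
  }
  placements <- place_regions(gm, dmr_configs, chrom_lengths)
  n_lines <- nrow(gm$geno)
  line_id <- rownames(gm$geno)
  n_reg <- length(placements)

  epi <- matrix("high", n_lines, n_reg,
                dimnames = list(line_id, vapply(placements, `[[`, "", "region_id")))
  lev <- matrix(NA_real_, n_lines, n_reg, dimnames = dimnames(epi))
  truth_rows <- list()
  calls_per_line <- replicate(n_lines, list(), simplify = FALSE)

  for (ri in seq_len(n_reg)) {
    pl <- placements[[ri]]
    cfg <- dmr_configs[[pl$config_idx]]
    state <- switch(cfg$kind,
      genetic_cis = {
        g <- gm$geno[, pl$snp_id]
        minor <- if (mean(g) / 2 > 0.5) 0 else 2
        ifelse(g == minor, "low", "high")
      },
      pure_epigenetic = ifelse(rbinom(n_lines, 1L, cfg$mef_target) == 1L, "low", "high"),
      tissue_stable_background = rep("high", n_lines))
    epi[, ri] <- state
    lev[, ri] <- ifelse(state == "high", cfg$high_level, cfg$low_level)

    n_windows <- cfg$region_length %/% WINDOW_BP
    # fixed cytosine layout per region, shared by all lines (capture design)
    ctx_sites <- lapply(cfg$contexts, function(ctx) {
      offs <- unlist(lapply(seq_len(n_windows) - 1L, function(w)
        w * WINDOW_BP + sort(sample.int(WINDOW_BP, cfg$cytosine_density) - 1L)))
      data.table::data.table(
        chrom = pl$chrom, pos = pl$start + offs,
        strand = sample(c("+", "-"), length(offs), replace = TRUE),
        context = ctx)
    })
    sites <- data.table::rbindlist(ctx_sites)
    n_sites <- nrow(sites)

    zero_lines <- if (cfg$missing_line_fraction > 0) {
      sample.int(n_lines, round(cfg$missing_line_fraction * n_lines))
    } else integer(0)

    for (li in seq_len(n_lines)) {
      ct <- if (li %in% zero_lines) rep(0L, n_sites) else {
        rnbinom(n_sites, mu = cfg$coverage_mean, size = cfg$coverage_dispersion)
      }
      cc <- rbinom(n_sites, ct, lev[li, ri])
      keep <- ct > 0L
      if (any(keep)) {
        tab <- sites[keep]
        tab[, `:=`(C = cc[keep], CT = ct[keep])]
        calls_per_line[[li]][[length(calls_per_line[[li]]) + 1L]] <- tab
      }
    }
    for (ctx in cfg$contexts) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        region_id = pl$region_id, chrom = pl$chrom, start = pl$start,
        end = pl$end, context = ctx, kind = cfg$kind, snp_id = pl$snp_id,
        high_level = cfg$high_level, low_level = cfg$low_level,
        stringsAsFactors = FALSE)
    }
  }

  calls <- lapply(calls_per_line, function(tabs) {
    if (length(tabs) == 0L) {
      return(data.table::data.table(chrom = character(), pos = integer(),
                                    strand = character(), context = character(),
                                    C = integer(), CT = integer()))
    }
    out <- data.table::rbindlist(tabs)
    data.table::setorder(out, chrom, pos)
    out
  })
  names(calls) <- line_id

  structure(list(calls = calls,
                 truth = do.call(rbind, truth_rows),
                 epialleles = epi,
                 levels = lev,
                 lines = gm$lines,
                 chrom_lengths = chrom_lengths),
            class = "meth_panel")
}

#' @export
print.meth_panel <- function(x, ...) {
  cat(sprintf("meth_panel: %d lines, %d planted region-contexts (%s)\n",
              length(x$calls), nrow(x$truth),
              paste(unique(x$truth$kind), collapse = ", ")))
  invisible(x)
}
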