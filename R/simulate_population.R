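# Synthetic inbred panel: homozygous SNP genotypes with subgroup structure.

#' Configuration for a simulated inbred panel
#'
#' Describes a panel of fully inbred lines split into subgroups (e.g. the
#' stiff-stalk / non-stiff-stalk / tropical subdivisions of a maize
#' association panel) with Balding-Nichols-style allele-frequency drift
#' between subgroups.
#'
#' @param n_lines total number of inbred lines.
#' @param subgroup_proportions named numeric vector summing to 1; one entry
#'   per subgroup. Default emulates a three-subgroup panel.
#' @param n_snps number of biallelic markers.
#' @param n_chromosomes number of chromosomes markers are spread over.
#' @param chromosome_length length of each chromosome in bp.
#' @param divergence between-subgroup allele-frequency drift (Fst-like),
#'   in `[0, 1)`. 0 gives a panmictic panel.
#' @param maf_floor minimum panel-wide minor allele frequency; markers
#'   below it are redrawn.
#' @param seed integer seed; all downstream simulation reproducibility
#'   flows from it.
#' @return an object of class `population_config`.
#' @export
population_config <- function(n_lines = 263L,
                              subgroup_proportions = c(SS = 0.25, NSS = 0.40, TST = 0.35),
                              n_snps = 500L,
                              n_chromosomes = 2L,
                              chromosome_length = 5e6,
                              divergence = 0.15,
                              maf_floor = 0.05,
                              seed = 1L) {
  subgroup_proportions <- unlist(subgroup_proportions)  # YAML maps arrive as lists
  if (abs(sum(subgroup_proportions) - 1) > 1e-8)
    stop_popmeth("subgroup_proportions must sum to 1 (got %.4f)", sum(subgroup_proportions))
  if (is.null(names(subgroup_proportions)))
    names(subgroup_proportions) <- paste0("G", seq_along(subgroup_proportions))
  if (n_lines < 2L * length(subgroup_proportions))
    stop_popmeth("n_lines = %d leaves fewer than 2 lines in some subgroup", n_lines)
  if (divergence < 0 || divergence >= 1)
    stop_popmeth("divergence must be in [0, 1)")
  if (n_snps < 1L || n_chromosomes < 1L)
    stop_popmeth("n_snps and n_chromosomes must be positive")
  structure(
    list(n_lines = as.integer(n_lines),
         subgroup_proportions = subgroup_proportions,
         n_snps = as.integer(n_snps),
         n_chromosomes = as.integer(n_chromosomes),
         chromosome_length = chromosome_length,
         divergence = divergence,
         maf_floor = maf_floor,
         seed = as.integer(seed)),
    class = "population_config")
}

#' Simulate homozygous genotypes for an inbred panel
#'
#' Draws an ancestral allele frequency per marker, perturbs it per subgroup
#' with a Balding-Nichols beta model at the configured divergence, and
#' samples one allele per line (inbred lines are fully homozygous, coded
#' 0/2).  Markers whose realized panel MAF falls below `maf_floor` are
#' redrawn, so population structure is a controllable confounding axis
#' while every marker stays informative.
#'
#' @param config a [population_config()].
#' @return a `genotype_matrix`: list with `geno` (lines x markers matrix of
#'   0/2, dimnames set), `map` (data.frame: snp_id, chrom, pos), and
#'   `lines` (data.frame: line_id, subgroup).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  props <- config$subgroup_proportions
  n_sub <- length(props)
  sizes <- floor(config$n_lines * props)
  # distribute the rounding remainder to the largest subgroups
  rem <- config$n_lines - sum(sizes)
  if (rem > 0) {
    ord <- order(props, decreasing = TRUE)
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
  }
  if (any(sizes < 2L))
    stop_popmeth("subgroup '%s' has fewer than 2 lines", names(sizes)[which.min(sizes)])
  subgroup <- rep(names(props), times = sizes)
  line_id <- sprintf("L%03d", seq_len(config$n_lines))

  F <- config$divergence
  m <- config$n_snps
  n <- config$n_lines
  geno <- matrix(NA_real_, n, m)
  draw_marker <- function(k) {
    # k markers at once; returns n x k allele matrix coded 0/2
    p_anc <- runif(k, 0.1, 0.9)
    out <- matrix(NA_real_, n, k)
    for (s in names(props)) {
      idx <- which(subgroup == s)
      p_s <- if (F > 0) {
        rbeta(k, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
      } else p_anc
      # guard the beta draw against exact 0/1
      p_s <- pmin(pmax(p_s, 1e-4), 1 - 1e-4)
      out[idx, ] <- 2 * matrix(rbinom(length(idx) * k, 1L, rep(p_s, each = length(idx))),
                               length(idx), k)
    }
    out
  }
  todo <- seq_len(m)
  guard <- 0L
  while (length(todo) > 0L && guard < 50L) {
    geno[, todo] <- draw_marker(length(todo))
    af <- colMeans(geno[, todo, drop = FALSE]) / 2
    maf <- pmin(af, 1 - af)
    todo <- todo[maf < config$maf_floor]
    guard <- guard + 1L
  }
  if (length(todo) > 0L)
    stop_popmeth("could not satisfy maf_floor = %.3f for %d markers", config$maf_floor, length(todo))

  chrom <- sort(rep_len(seq_len(config$n_chromosomes), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(idx) {
    sort(sample.int(config$chromosome_length - 1L, length(idx)))
  }), use.names = FALSE)
  map <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
                    chrom = paste0("chr", chrom),
                    pos = pos,
                    stringsAsFactors = FALSE)
  dimnames(geno) <- list(line_id, map$snp_id)
  structure(list(geno = geno,
                 map = map,
                 lines = data.frame(line_id = line_id, subgroup = subgroup,
                                    stringsAsFactors = FALSE)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d inbred lines x %d markers (%s)\n",
              nrow(x$geno), ncol(x$geno),
              paste(sprintf("%s=%d", names(table(x$lines$subgroup)),
                            as.integer(table(x$lines$subgroup))), collapse = ", ")))
  invisible(x)
}

#' Minor allele frequencies of a genotype matrix
#' @param gm a `genotype_matrix` or a plain 0/2 lines x markers matrix.
#' @param lines optional character vector restricting to a line subset.
#' @return numeric vector of per-marker MAF.
#' @export
maf <- function(gm, lines = NULL) {
  g <- if (inherits(gm, "genotype_matrix")) gm$geno else gm
  if (!is.null(lines)) g <- g[lines, , drop = FALSE]
  af <- colMeans(g, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

#' Write genotypes as a lines x markers TSV and a minimal VCF
#'
#' @param gm a `genotype_matrix`.
#' @param tsv_path,vcf_path output paths (`NULL` to skip either).
#' @return invisibly, the paths written.
#' @export
write_genotypes <- function(gm, tsv_path = NULL, vcf_path = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.null(tsv_path)) {
    dt <- data.table::as.data.table(gm$geno, keep.rownames = "line_id")
    data.table::fwrite(dt, tsv_path, sep = "\t")
  }
  if (!is.null(vcf_path)) {
    gt <- ifelse(t(gm$geno) == 2, "1/1", "0/0")  # markers x lines
    header <- c("##fileformat=VCFv4.2",
                sprintf("##contig=<ID=%s>", unique(gm$map$chrom)),
                "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", rownames(gm$geno)), collapse = "\t"))
    body <- cbind(gm$map$chrom, gm$map$pos + 1L, gm$map$snp_id, "A", "G",
                  ".", "PASS", ".", "GT", gt)
    writeLines(c(header, apply(body, 1, paste, collapse = "\t")), vcf_path)
  }
  invisible(c(tsv = tsv_path, vcf = vcf_path))
}
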