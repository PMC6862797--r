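# Context-specificity classification, minor epiallele frequency (MEF),
# and subgroup-specific DMR tests.

#' Classify a CG or CHG DMR's cross-context behaviour
#'
#' A CG DMR whose CHG methylation also varies strongly (second-rank
#' difference > 0.6) and tracks the CG level (squared Pearson r > 0.8) is
#' a CG_CHG DMR; one whose CHG level is flat (difference < 0.2) and
#' uncorrelated (r-squared < 0.2) is CG_only.  Symmetric for CHG DMRs.
#' Everything in between is unclassified.
#'
#' @param own_levels named per-line region methylation in the DMR's own
#'   context.
#' @param other_levels named per-line region methylation in the companion
#'   context (CHG for a CG DMR and vice versa).
#' @param context the DMR's own context, `"CG"` or `"CHG"`.
#' @return list with `class` (`CG_CHG`, `CG_only`, `CHG_only`, or
#'   `unclassified`), `cross_context_diff`, `cross_context_r2`, and
#'   `reason` when data were insufficient.
#' @export
classify_context <- function(own_levels, other_levels, context = c("CG", "CHG")) {
  context <- match.arg(context)
  shared <- intersect(names(own_levels)[!is.na(own_levels)],
                      names(other_levels)[!is.na(other_levels)])
  if (length(shared) < 4L) {
    return(list(class = "unclassified", cross_context_diff = NA_real_,
                cross_context_r2 = NA_real_,
                reason = "fewer than 4 lines with data in both contexts"))
  }
  sr <- second_rank(other_levels[shared])
  diff <- sr$second_high - sr$second_low
  r2 <- if (sd(own_levels[shared]) == 0 || sd(other_levels[shared]) == 0) 0 else
    cor(own_levels[shared], other_levels[shared])^2
  cls <- if (diff > 0.6 && r2 > 0.8) "CG_CHG"
  else if (diff < 0.2 && r2 < 0.2) paste0(context, "_only")
  else "unclassified"
  list(class = cls, cross_context_diff = diff, cross_context_r2 = r2,
       reason = NA_character_)
}

#' Minor epiallele frequency of a DMR
#'
#' Lines are split into High and Low epiallele groups around the midpoint
#' of the second-highest and second-lowest levels; a line is assigned only
#' when its contrast with the opposite second extreme satisfies the
#' context's pairwise difference rule (CG/CHG: > 0.6 difference; CHH:
#' > 0.25 for High, < 0.05 for Low).  A record is returned only when more
#' than half of the lines with data could be assigned; MEF is the size of
#' the smaller group over the sum of both.
#'
#' @param levels named per-line region methylation vector.
#' @param context one of CG/CHG/CHH.
#' @return list with `n_high`, `n_low`, `assignable_fraction`, `mef`, and
#'   `groups` (named factor High/Low/unassigned), or `NULL` when fewer
#'   than half the lines are assignable or a group is empty.
#' @export
compute_mef <- function(levels, context) {
  context <- match_context(context)
  x <- levels[!is.na(levels)]
  n <- length(x)
  if (n < 4L) return(NULL)
  sr <- second_rank(x)
  mid <- (sr$second_high + sr$second_low) / 2
  if (context %in% c("CG", "CHG")) {
    high <- x >= mid & (x - sr$second_low) > 0.6
    low <- x < mid & (sr$second_high - x) > 0.6
  } else {
    high <- x > 0.25
    low <- x < 0.05
  }
  assignable <- (sum(high) + sum(low)) / n
  if (assignable <= 0.5) return(NULL)
  n_high <- sum(high); n_low <- sum(low)
  if (n_high == 0L || n_low == 0L) return(NULL)
  groups <- rep("unassigned", n)
  groups[high] <- "High"; groups[low] <- "Low"
  names(groups) <- names(x)
  list(n_high = n_high, n_low = n_low, assignable_fraction = assignable,
       mef = min(n_high, n_low) / (n_high + n_low), groups = groups)
}

#' Test a DMR for subgroup specificity
#'
#' One-way ANOVA of region methylation on subgroup; DMRs significant at
#' P < 0.001 go to Tukey HSD post hoc comparisons (Tukey-Kramer for
#' unequal group sizes), and a DMR is subgroup-specific when some pair of
#' subgroups differs at P < 0.001.
#'
#' @param levels named per-line region methylation vector.
#' @param subgroups named character vector of subgroup labels (same line
#'   ids).
#' @param alpha significance level (default 0.001).
#' @return list with `anova_p`, `pairwise_tukey_p` (named vector, `NULL`
#'   unless the ANOVA was significant), and `subgroup_specific`.
#' @export
subgroup_anova <- function(levels, subgroups, alpha = 0.001) {
  shared <- intersect(names(levels)[!is.na(levels)], names(subgroups))
  y <- levels[shared]
  g <- subgroups[shared]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning(sprintf("subgroup(s) %s have < 2 lines with data; excluded",
                    paste(small, collapse = ", ")))
    keep <- !g %in% small
    y <- y[keep]; g <- g[keep]
  }
  if (length(unique(g)) < 2L || length(y) < 4L) {
    return(list(anova_p = NA_real_, pairwise_tukey_p = NULL, subgroup_specific = FALSE))
  }
  g <- factor(g)
  if (sd(y) == 0) {
    return(list(anova_p = 1, pairwise_tukey_p = NULL, subgroup_specific = FALSE))
  }
  fit <- aov(y ~ g)
  p <- summary(fit)[[1]][["Pr(>F)"]][1L]
  tukey <- NULL
  specific <- FALSE
  if (!is.na(p) && p < alpha) {
    tk <- TukeyHSD(fit)$g
    tukey <- setNames(tk[, "p adj"], rownames(tk))
    specific <- any(tukey < alpha)
  }
  list(anova_p = p, pairwise_tukey_p = tukey, subgroup_specific = specific)
}

#' Epiallele statistics for every DMR in a set
#'
#' Convenience driver: MEF and (for CG/CHG sets given a companion context)
#' context classification per DMR, plus subgroup tests when labels are
#' supplied.
#'
#' @param dmrs a `dmr_set`.
#' @param calls_list per-line call tables (needed for cross-context
#'   levels); `NULL` skips classification.
#' @param subgroups named subgroup labels; `NULL` skips the ANOVA.
#' @return data.frame keyed by dmr_id with mef, n_high, n_low,
#'   assignable_fraction, context_class, cross_context_diff,
#'   cross_context_r2, anova_p, subgroup_specific.
#' @export
epiallele_summary <- function(dmrs, calls_list = NULL, subgroups = NULL) {
  reg <- dmrs$regions
  other_ctx <- c(CG = "CHG", CHG = "CG")[dmrs$context]
  out <- lapply(seq_len(nrow(reg)), function(i) {
    lv <- dmrs$levels[i, ]
    mef <- compute_mef(lv, dmrs$context)
    row <- data.frame(dmr_id = reg$dmr_id[i],
                      mef = if (is.null(mef)) NA_real_ else mef$mef,
                      n_high = if (is.null(mef)) NA_integer_ else mef$n_high,
                      n_low = if (is.null(mef)) NA_integer_ else mef$n_low,
                      assignable_fraction = if (is.null(mef)) NA_real_ else mef$assignable_fraction,
                      context_class = NA_character_,
                      cross_context_diff = NA_real_, cross_context_r2 = NA_real_,
                      anova_p = NA_real_, subgroup_specific = NA,
                      stringsAsFactors = FALSE)
    if (!is.null(calls_list) && !is.na(other_ctx)) {
      other <- region_levels(reg[i, ], calls_list, other_ctx)
      cc <- classify_context(lv, other, dmrs$context)
      row$context_class <- cc$class
      row$cross_context_diff <- cc$cross_context_diff
      row$cross_context_r2 <- cc$cross_context_r2
    }
    if (!is.null(subgroups)) {
      sg <- subgroup_anova(lv, subgroups)
      row$anova_p <- sg$anova_p
      row$subgroup_specific <- sg$subgroup_specific
    }
    row
  })
  do.call(rbind, out)
}
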