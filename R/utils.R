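# Shared helpers: second-rank statistics, context thresholds, misc.

# Width of the fixed analysis window in bp.  The whole pipeline tiles
# chromosomes into non-overlapping windows of this size anchored at 0.
WINDOW_BP <- 20L

METH_CONTEXTS <- c("CG", "CHG", "CHH")

#' Second-highest and second-lowest values of a numeric vector
#'
#' Rank statistics used throughout DMR calling: requiring a methylation
#' contrast between the *second* extremes (rather than min/max) means a
#' single outlier line can never create a DMR on its own.
#'
#' @param x numeric vector; `NA`s are dropped.
#' @return list with `second_high`, `second_low`, and `n` (values used).
#'   Both statistics are `NA` when fewer than 4 values remain, since the
#'   second extremes are then not distinct from the extremes themselves.
#' @export
second_rank <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4L) {
    return(list(second_high = NA_real_, second_low = NA_real_, n = n))
  }
  s <- sort(unname(x))
  list(second_high = s[n - 1L], second_low = s[2L], n = n)
}

# Context-specific pairwise contrast rule on two window/region levels.
# CG/CHG: absolute difference > 0.6.  CHH: difference > 0.2 with one level
# below 0.05 and the other above 0.25.  Returns TRUE/FALSE (never NA for
# non-missing inputs).
context_contrast <- function(a, b, context) {
  if (is.na(a) || is.na(b)) return(NA)
  if (context %in% c("CG", "CHG")) {
    abs(a - b) > 0.6
  } else {
    abs(a - b) > 0.2 && min(a, b) < 0.05 && max(a, b) > 0.25
  }
}

# Second-rank call rule per context, applied to a vector of per-line levels.
# Returns TRUE when the region qualifies as a DMR in its context.
context_second_rank_ok <- function(second_high, second_low, context) {
  if (is.na(second_high) || is.na(second_low)) return(FALSE)
  if (context %in% c("CG", "CHG")) {
    (second_high - second_low) > 0.6
  } else {
    second_high > 0.25 && second_low < 0.05
  }
}

match_context <- function(context) {
  match.arg(context, METH_CONTEXTS)
}

stop_popmeth <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
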