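# Two-step population DMR identification.
#
# Step 1: each of k reference lines (group I) is contrasted with every
# other line (group II); per 20-bp window a context-specific difference
# rule marks significant windows, which are chained (gap <= 50 bp, same
# direction) and emitted as candidates when >= 3 significant windows chain
# together.
#
# Step 2: candidates from all comparisons are union-merged (gap <= 200 bp);
# per-window support (fraction of contrasting pairs significant) is
# normalized to the region's best window; windows below 0.4 normalized
# support are dropped and runs of >= 3 consecutive eligible windows are
# kept.  Surviving regions must pass per-line coverage QC in > 60% of
# lines and a second-rank methylation contrast over the whole region, so
# no single line can create a DMR.

#' Select the group-I reference lines
#'
#' Deterministic: lines are ranked by their fraction of non-missing
#' windows; the best-covered line seeds the set and each subsequent pick
#' maximizes the minimum kinship distance to the lines already picked
#' (ties broken by coverage rank, then input order).  Lines with no data
#' are never selected.
#'
#' @param wm a `windowed_methylome`.
#' @param kinship lines x lines relationship matrix (any source); `NULL`
#'   computes one from the window levels.
#' @param k number of reference lines (default 16).
#' @return character vector of selected line ids, in pick order.
#' @export
select_group_one <- function(wm, kinship = NULL, k = 16L) {
  lines <- colnames(wm$levels)
  n <- length(lines)
  if (k >= n) stop_popmeth("k = %d must be smaller than the number of lines (%d)", k, n)
  cover <- colMeans(!is.na(wm$levels))
  eligible <- which(cover > 0)
  if (length(eligible) < k)
    stop_popmeth("only %d lines have any windowed data; cannot pick k = %d", length(eligible), k)
  if (is.null(kinship)) kinship <- kinship_from_markers(t(wm$levels))
  K <- kinship[lines, lines]
  # squared kinship distance d(i,j) = K_ii + K_jj - 2 K_ij
  D <- outer(diag(K), diag(K), "+") - 2 * K
  rank_order <- order(-cover, seq_len(n))  # coverage desc, then input order
  rank_pos <- integer(n); rank_pos[rank_order] <- seq_len(n)
  picked <- rank_order[rank_order %in% eligible][1L]
  while (length(picked) < k) {
    cand <- setdiff(eligible, picked)
    mind <- apply(D[cand, picked, drop = FALSE], 1, min)
    best <- cand[order(-mind, rank_pos[cand])][1L]
    picked <- c(picked, best)
  }
  lines[picked]
}

#' Pairwise window difference test
#'
#' CG/CHG windows are significant when the two lines differ by more than
#' 0.6; CHH windows when they differ by more than 0.2 with one line below
#' 0.05 and the other above 0.25.
#'
#' @param level_a,level_b window methylation levels (vectors allowed;
#'   `NA` = missing).
#' @param context one of CG/CHG/CHH.
#' @return character vector of verdicts: `"a_higher"`, `"b_higher"`,
#'   `"none"`, or `"missing"`.
#' @export
pairwise_window_test <- function(level_a, level_b, context) {
  context <- match_context(context)
  miss <- is.na(level_a) | is.na(level_b)
  d <- level_a - level_b
  if (context %in% c("CG", "CHG")) {
    sig <- abs(d) > 0.6
  } else {
    sig <- abs(d) > 0.2 & pmin(level_a, level_b) < 0.05 & pmax(level_a, level_b) > 0.25
  }
  out <- rep("none", length(d))
  out[sig & d > 0] <- "a_higher"
  out[sig & d < 0] <- "b_higher"
  out[miss] <- "missing"
  out
}

#' Chain significant windows from one pairwise comparison
#'
#' Significant windows within 50 bp of each other (gap between window end
#' and next window start) and with the same direction are merged; chains
#' with at least three significant windows become candidate DMRs.
#'
#' @param windows data.frame with `chrom`, `start` (sorted) for each
#'   tested window.
#' @param verdicts verdict vector from [pairwise_window_test()], aligned
#'   with `windows`.
#' @return data.table of candidates: chrom, start, end, direction,
#'   n_windows.
#' @export
merge_step1 <- function(windows, verdicts) {
  sig <- verdicts %in% c("a_higher", "b_higher")
  if (!any(sig)) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), direction = character(),
                                  n_windows = integer()))
  }
  w <- data.table::data.table(chrom = windows$chrom[sig],
                              start = as.integer(windows$start[sig]),
                              dir = verdicts[sig])
  data.table::setorder(w, chrom, start)
  gap_break <- c(TRUE, w$chrom[-1] != w$chrom[-nrow(w)] |
                   w$dir[-1] != w$dir[-nrow(w)] |
                   (w$start[-1] - (w$start[-nrow(w)] + WINDOW_BP)) > 50L)
  w[, chain := cumsum(gap_break)]
  out <- w[, .(chrom = chrom[1L], start = start[1L],
               end = start[.N] + WINDOW_BP, direction = dir[1L],
               n_windows = .N), by = chain][n_windows >= 3L]
  out[, chain := NULL]
  out[]
}

# Union-merge intervals per chromosome with gap <= max_gap.
merge_intervals <- function(dt, max_gap) {
  data.table::setorder(dt, chrom, start)
  brk <- c(TRUE, dt$chrom[-1] != dt$chrom[-nrow(dt)] |
             dt$start[-1] - cummax_by(dt$end, dt$chrom)[-nrow(dt)] > max_gap)
  dt[, grp := cumsum(brk)]
  out <- dt[, .(chrom = chrom[1L], start = min(start), end = max(end)), by = grp]
  out[, grp := NULL]
  out[]
}

# running max of `end` within chrom blocks (intervals may nest)
cummax_by <- function(x, g) {
  unlist(lapply(split(x, factor(g, levels = unique(g))), cummax), use.names = FALSE)
}

#' Consensus across comparisons (step 2)
#'
#' Candidates from all pairwise comparisons are union-merged when within
#' 200 bp; each merged region is re-divided into 20-bp windows whose
#' support (fraction of contrasting pairs with data that called the window
#' significant) is normalized to the region's best window.  Windows with
#' normalized support below 0.4 are dropped; every maximal run of at least
#' three consecutive eligible windows is kept as a provisional DMR,
#' trimmed to the run's span.
#'
#' @param candidates data.table of step-1 candidates (all comparisons).
#' @param windows data.frame of tested windows (chrom, start).
#' @param n_sig,n_data integer vectors aligned with `windows`: per window,
#'   the number of contrasting pairs significant / with data in both lines.
#' @param min_norm_support normalized-support floor (default 0.4).
#' @return data.table of provisional regions: chrom, start, end, n_windows.
#' @export
consensus_step2 <- function(candidates, windows, n_sig, n_data,
                            min_norm_support = 0.4) {
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), n_windows = integer())
  if (nrow(candidates) == 0L) return(empty)
  merged <- merge_intervals(data.table::copy(candidates[, .(chrom, start, end)]), 200L)
  support_key <- setNames(ifelse(n_data > 0, n_sig / n_data, 0),
                          paste(windows$chrom, windows$start))
  out <- list()
  for (i in seq_len(nrow(merged))) {
    starts <- seq.int(merged$start[i], merged$end[i] - WINDOW_BP, by = WINDOW_BP)
    supp <- support_key[paste(merged$chrom[i], starts)]
    supp[is.na(supp)] <- 0
    if (max(supp) <= 0) next
    elig <- (supp / max(supp)) >= min_norm_support
    r <- rle(elig)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    keep <- which(r$values & r$lengths >= 3L)
    for (j in keep) {
      out[[length(out) + 1L]] <- data.table::data.table(
        chrom = merged$chrom[i],
        start = starts[starts_idx[j]],
        end = starts[ends_idx[j]] + WINDOW_BP,
        n_windows = r$lengths[j])
    }
  }
  if (length(out) == 0L) return(empty)
  data.table::rbindlist(out)
}

#' Per-line coverage QC over a region
#'
#' The region's cytosine census is the union of reported positions of the
#' context across the panel (the assay design).  A line passes when the
#' census has at least 6 sites, at least 2/3 of them carry >= 2 reads in
#' that line, and the line's mean per-site coverage over the census is at
#' least 2.
#'
#' @param region list/row with `chrom`, `start`, `end`.
#' @param calls_list named list of per-line call tables.
#' @param context one of CG/CHG/CHH.
#' @return list with `qc_pass_fraction` (over all lines), `n_cytosines`
#'   (census size), and `pass` (named logical per line).
#' @export
per_line_qc <- function(region, calls_list, context) {
  context <- match_context(context)
  per_line <- lapply(calls_list, function(calls) {
    calls[calls$context == context & calls$chrom == region$chrom &
            calls$pos >= region$start & calls$pos < region$end]
  })
  census <- sort(unique(unlist(lapply(per_line, `[[`, "pos"), use.names = FALSE)))
  n_cyt <- length(census)
  pass <- vapply(per_line, function(sub) {
    if (n_cyt < 6L) return(FALSE)
    covered <- sum(sub$CT >= 2L)
    covered / n_cyt >= 2 / 3 && sum(sub$CT) / n_cyt >= 2
  }, logical(1))
  list(qc_pass_fraction = mean(pass), n_cytosines = n_cyt, pass = pass)
}

#' Region-level methylation per line
#'
#' Pooled counts over the region's cytosines with >= 2 reads.
#'
#' @inheritParams per_line_qc
#' @return named numeric vector of levels (`NA` when a line has no covered
#'   cytosine in the region).
#' @export
region_levels <- function(region, calls_list, context) {
  context <- match_context(context)
  vapply(calls_list, function(calls) {
    sub <- calls[calls$context == context & calls$chrom == region$chrom &
                   calls$pos >= region$start & calls$pos < region$end &
                   calls$CT >= 2L]
    if (nrow(sub) == 0L) NA_real_ else sum(sub$C) / sum(sub$CT)
  }, numeric(1))
}

#' Final second-rank call on a provisional region
#'
#' CG/CHG regions are kept when the second-highest and second-lowest lines
#' differ by more than 0.6; CHH regions when the second-highest line is
#' above 0.25 and the second-lowest below 0.05.  Requires at least 4 lines
#' with data so the second extremes are distinct from the extremes.
#'
#' @param levels named per-line region methylation vector.
#' @param context one of CG/CHG/CHH.
#' @return list with `keep` (logical), `second_high`, `second_low`,
#'   `n_lines`, and `reason` when rejected.
#' @export
final_call <- function(levels, context) {
  context <- match_context(context)
  sr <- second_rank(levels)
  if (sr$n < 4L) {
    return(list(keep = FALSE, second_high = NA_real_, second_low = NA_real_,
                n_lines = sr$n, reason = "fewer than 4 lines with data"))
  }
  keep <- context_second_rank_ok(sr$second_high, sr$second_low, context)
  list(keep = keep, second_high = sr$second_high, second_low = sr$second_low,
       n_lines = sr$n,
       reason = if (keep) NA_character_ else "second-rank contrast below context threshold")
}

#' Call DMRs across a panel with the two-step algorithm
#'
#' @param calls_list named list of per-line cytosine call tables (e.g.
#'   `meth_panel$calls`).
#' @param context one of CG/CHG/CHH.
#' @param group1 explicit character vector of group-I line ids, or `NULL`
#'   to select `k` lines with [select_group_one()].
#' @param k size of group I when auto-selecting.
#' @param kinship optional relationship matrix for group-I selection.
#' @param min_qc_fraction per-line QC pass fraction a DMR must exceed
#'   (default 0.6).
#' @param verbose print the per-stage funnel of surviving region counts.
#' @return a `dmr_set`: list with `regions` (data.frame: dmr_id, chrom,
#'   start, end, context, n_windows, n_cytosines, second_high, second_low,
#'   qc_pass_fraction) and `levels` (DMRs x lines region methylation
#'   matrix).
#' @export
call_dmrs <- function(calls_list, context, group1 = NULL, k = 16L,
                      kinship = NULL, min_qc_fraction = 0.6, verbose = FALSE) {
  context <- match_context(context)
  wm <- windowed_methylome(calls_list, context)
  lines <- colnames(wm$levels)
  if (is.null(group1)) {
    k <- min(k, max(2L, length(lines) - 1L))
    group1 <- select_group_one(wm, kinship = kinship, k = k)
  }
  if (!all(group1 %in% lines)) stop_popmeth("group1 contains unknown line ids")
  group2 <- setdiff(lines, group1)
  if (length(group2) == 0L) stop_popmeth("no group-II lines left")

  nw <- nrow(wm$levels)
  n_sig <- integer(nw)
  n_data <- integer(nw)
  cand_all <- list()
  for (a in group1) {
    la <- wm$levels[, a]
    for (b in group2) {
      v <- pairwise_window_test(la, wm$levels[, b], context)
      n_data <- n_data + (v != "missing")
      n_sig <- n_sig + (v %in% c("a_higher", "b_higher"))
      cand <- merge_step1(wm$windows, v)
      if (nrow(cand)) cand_all[[length(cand_all) + 1L]] <- cand
    }
  }
  candidates <- if (length(cand_all)) data.table::rbindlist(cand_all) else
    data.table::data.table(chrom = character(), start = integer(),
                           end = integer(), direction = character(),
                           n_windows = integer())
  provisional <- consensus_step2(candidates, wm$windows, n_sig, n_data)
  if (verbose)
    message(sprintf("[%s] %d step-1 candidates -> %d provisional regions",
                    context, nrow(candidates), nrow(provisional)))

  rows <- list(); levs <- list()
  for (i in seq_len(nrow(provisional))) {
    region <- provisional[i]
    qc <- per_line_qc(region, calls_list, context)
    if (qc$qc_pass_fraction <= min_qc_fraction) next
    lv <- region_levels(region, calls_list, context)
    fc <- final_call(lv, context)
    if (!fc$keep) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = region$chrom, start = region$start, end = region$end,
      context = context, n_windows = region$n_windows,
      n_cytosines = qc$n_cytosines,
      second_high = fc$second_high, second_low = fc$second_low,
      qc_pass_fraction = qc$qc_pass_fraction, stringsAsFactors = FALSE)
    levs[[length(levs) + 1L]] <- lv
  }
  if (length(rows) == 0L) {
    regions <- data.frame(dmr_id = character(), chrom = character(),
                          start = integer(), end = integer(), context = character(),
                          n_windows = integer(), n_cytosines = integer(),
                          second_high = numeric(), second_low = numeric(),
                          qc_pass_fraction = numeric(), stringsAsFactors = FALSE)
    levels_mat <- matrix(NA_real_, 0, length(lines), dimnames = list(NULL, lines))
  } else {
    regions <- do.call(rbind, rows)
    regions <- cbind(dmr_id = sprintf("%s_DMR_%04d", context, seq_len(nrow(regions))),
                     regions, stringsAsFactors = FALSE)
    levels_mat <- do.call(rbind, levs)
    rownames(levels_mat) <- regions$dmr_id
  }
  if (verbose)
    message(sprintf("[%s] %d DMRs after QC and second-rank call", context, nrow(regions)))
  structure(list(regions = regions, levels = levels_mat, context = context,
                 group1 = group1),
            class = "dmr_set")
}

#' @export
print.dmr_set <- function(x, ...) {
  cat(sprintf("dmr_set (%s): %d DMRs x %d lines\n",
              x$context, nrow(x$regions), ncol(x$levels)))
  invisible(x)
}
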