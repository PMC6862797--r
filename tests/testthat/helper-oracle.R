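# Brute-force DMR-calling oracle: a direct, naive transcription of the
# printed two-step rules, written independently of the package internals
# (plain loops over data.frames, no shared helpers).  Used to check the
# production caller on tiny instances.

oracle_window_level <- function(calls, chrom, wstart, context) {
  sub <- calls[calls$context == context & calls$chrom == chrom &
                 calls$pos >= wstart & calls$pos < wstart + 20 &
                 calls$CT >= 2, , drop = FALSE]
  if (nrow(sub) == 0) NA_real_ else sum(sub$C) / sum(sub$CT)
}

oracle_sig <- function(a, b, context) {
  if (is.na(a) || is.na(b)) return(FALSE)
  if (context %in% c("CG", "CHG")) return(abs(a - b) > 0.6)
  abs(a - b) > 0.2 && min(a, b) < 0.05 && max(a, b) > 0.25
}

# Full two-step caller by brute force.  calls_list: named list of
# data.frames (chrom, pos, strand, context, C, CT).  Assumes one
# chromosome and windows on [0, n_windows*20).
oracle_call_dmrs <- function(calls_list, context, group1, n_windows,
                             chrom = "chr1") {
  lines <- names(calls_list)
  group2 <- setdiff(lines, group1)
  wstarts <- (seq_len(n_windows) - 1) * 20
  lev <- sapply(lines, function(ln)
    sapply(wstarts, function(ws) oracle_window_level(calls_list[[ln]], chrom, ws, context)))

  # step 1: per comparison, chain significant same-direction windows
  candidates <- list()
  for (a in group1) for (b in group2) {
    sig_idx <- c(); sig_dir <- c()
    for (w in seq_len(n_windows)) {
      la <- lev[w, a]; lb <- lev[w, b]
      if (oracle_sig(la, lb, context)) {
        sig_idx <- c(sig_idx, w)
        sig_dir <- c(sig_dir, if (la > lb) "a" else "b")
      }
    }
    if (length(sig_idx) == 0) next
    chain_start <- 1
    for (k in seq_along(sig_idx)) {
      end_of_chain <- k == length(sig_idx) ||
        (wstarts[sig_idx[k + 1]] - (wstarts[sig_idx[k]] + 20)) > 50 ||
        sig_dir[k + 1] != sig_dir[k]
      if (end_of_chain) {
        members <- chain_start:k
        if (length(members) >= 3) {
          candidates[[length(candidates) + 1]] <-
            c(wstarts[sig_idx[members[1]]], wstarts[sig_idx[members[length(members)]]] + 20)
        }
        chain_start <- k + 1
      }
    }
  }
  if (length(candidates) == 0) return(data.frame(start = numeric(0), end = numeric(0)))

  # step 2a: union-merge candidates with gap <= 200
  iv <- do.call(rbind, candidates)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  merged <- list(iv[1, ])
  if (nrow(iv) > 1) for (k in 2:nrow(iv)) {
    last <- merged[[length(merged)]]
    if (iv[k, 1] - last[2] <= 200) {
      merged[[length(merged)]] <- c(last[1], max(last[2], iv[k, 2]))
    } else merged[[length(merged) + 1]] <- iv[k, ]
  }

  # step 2b: per-window support, normalize, 0.4 floor, runs >= 3
  provisional <- list()
  for (reg in merged) {
    ws <- seq(reg[1], reg[2] - 20, by = 20)
    supp <- sapply(ws, function(w0) {
      n_pair <- 0; n_sig <- 0
      for (a in group1) for (b in group2) {
        wi <- which(wstarts == w0)
        la <- if (length(wi)) lev[wi, a] else NA
        lb <- if (length(wi)) lev[wi, b] else NA
        if (!is.na(la) && !is.na(lb)) {
          n_pair <- n_pair + 1
          if (oracle_sig(la, lb, context)) n_sig <- n_sig + 1
        }
      }
      if (n_pair == 0) 0 else n_sig / n_pair
    })
    if (max(supp) <= 0) next
    elig <- supp / max(supp) >= 0.4
    run_start <- NULL
    for (k in seq_along(elig)) {
      if (elig[k] && is.null(run_start)) run_start <- k
      if ((!elig[k] || k == length(elig)) && !is.null(run_start)) {
        run_end <- if (elig[k]) k else k - 1
        if (run_end - run_start + 1 >= 3) {
          provisional[[length(provisional) + 1]] <- c(ws[run_start], ws[run_end] + 20)
        }
        run_start <- NULL
      }
    }
  }

  # step 2c: per-line QC (>60% of lines) and second-rank final call
  kept <- list()
  for (reg in provisional) {
    census <- sort(unique(unlist(lapply(calls_list, function(d)
      d$pos[d$context == context & d$chrom == chrom &
              d$pos >= reg[1] & d$pos < reg[2]]))))
    n_pass <- 0
    for (ln in lines) {
      d <- calls_list[[ln]]
      d <- d[d$context == context & d$chrom == chrom &
               d$pos >= reg[1] & d$pos < reg[2], , drop = FALSE]
      ok <- length(census) >= 6 &&
        sum(d$CT >= 2) / length(census) >= 2 / 3 &&
        sum(d$CT) / length(census) >= 2
      if (ok) n_pass <- n_pass + 1
    }
    if (n_pass / length(lines) <= 0.6) next
    rl <- sapply(lines, function(ln) {
      d <- calls_list[[ln]]
      d <- d[d$context == context & d$chrom == chrom &
               d$pos >= reg[1] & d$pos < reg[2] & d$CT >= 2, , drop = FALSE]
      if (nrow(d) == 0) NA_real_ else sum(d$C) / sum(d$CT)
    })
    rl <- rl[!is.na(rl)]
    if (length(rl) < 4) next
    s <- sort(rl)
    hi2 <- s[length(s) - 1]; lo2 <- s[2]
    keep <- if (context %in% c("CG", "CHG")) (hi2 - lo2) > 0.6 else (hi2 > 0.25 && lo2 < 0.05)
    if (keep) kept[[length(kept) + 1]] <- reg
  }
  if (length(kept) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  out <- as.data.frame(do.call(rbind, kept))
  names(out) <- c("start", "end")
  out[order(out$start), , drop = FALSE]
}
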