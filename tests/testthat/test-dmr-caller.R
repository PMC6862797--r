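# The two-step DMR caller: unit rules, oracle equivalence on tiny
# instances, and planted-truth recovery.

test_that("pairwise window rules follow the context thresholds", {
  expect_equal(pairwise_window_test(0.95, 0.30, "CG"), "a_higher")  # diff 0.65 > 0.6
  expect_equal(pairwise_window_test(0.85, 0.30, "CG"), "none")      # 0.55 <= 0.6
  expect_equal(pairwise_window_test(0.30, 0.06, "CHH"), "none")     # 0.06 not < 0.05
  expect_equal(pairwise_window_test(0.30, 0.03, "CHH"), "a_higher")
  expect_equal(pairwise_window_test(0.5, 0.5, "CHG"), "none")
  expect_equal(pairwise_window_test(NA, 0.5, "CG"), "missing")
  expect_equal(pairwise_window_test(c(0.95, 0.2), c(0.1, 0.9), "CG"),
               c("a_higher", "b_higher"))
})

test_that("step-1 chaining merges within 50 bp, same direction, >= 3 windows", {
  win <- data.frame(chrom = "chr1", start = c(0L, 40L, 80L))
  out <- merge_step1(win, rep("a_higher", 3))
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start, out$end, out$n_windows), c(0, 100, 3))

  out2 <- merge_step1(data.frame(chrom = "chr1", start = c(0L, 40L)),
                      rep("a_higher", 2))
  expect_equal(nrow(out2), 0)  # fewer than three windows

  win3 <- data.frame(chrom = "chr1", start = c(0L, 100L, 120L, 140L))
  out3 <- merge_step1(win3, rep("a_higher", 4))
  expect_equal(nrow(out3), 1)  # gap 80 bp breaks the first window off
  expect_equal(c(out3$start, out3$end), c(100, 160))

  # opposite directions never chain
  out4 <- merge_step1(data.frame(chrom = "chr1", start = c(0L, 20L, 40L)),
                      c("a_higher", "b_higher", "a_higher"))
  expect_equal(nrow(out4), 0)
})

test_that("step-2 consensus drops low-support windows and requires 3 consecutive eligible ones", {
  win <- data.frame(chrom = "chr1", start = seq(0L, 80L, by = 20L))
  cand <- data.table::data.table(chrom = "chr1", start = 0L, end = 100L)
  n_data <- rep(10L, 5)

  # normalized supports 1.0 / 0.45 / 0.41: all eligible, kept intact
  out <- consensus_step2(data.table::data.table(chrom = "chr1", start = 0L, end = 60L),
                         win[1:3, ], c(100L, 45L, 41L), rep(100L, 3))
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start, out$end), c(0, 60))

  # supports 1 1 .3 1 1 -> middle window breaks the run, both sides too short
  out2 <- consensus_step2(cand, win, c(10L, 10L, 3L, 10L, 10L), n_data)
  expect_equal(nrow(out2), 0)

  # single comparison, all significant -> self-normalized to 1 everywhere
  out3 <- consensus_step2(data.table::data.table(chrom = "chr1", start = 0L, end = 60L),
                          win[1:3, ], c(1L, 1L, 1L), rep(1L, 3))
  expect_equal(c(out3$start, out3$end), c(0, 60))

  # two eligible runs of >= 3 in one merged region are emitted separately
  win7 <- data.frame(chrom = "chr1", start = seq(0L, 120L, by = 20L))
  out4 <- consensus_step2(data.table::data.table(chrom = "chr1", start = 0L, end = 140L),
                          win7, c(10L, 10L, 10L, 1L, 10L, 10L, 10L), rep(10L, 7))
  expect_equal(nrow(out4), 2)
  expect_equal(out4$start, c(0, 80))
})

test_that("candidates within 200 bp are union-merged before support scoring", {
  win <- data.frame(chrom = "chr1", start = seq(0L, 400L, by = 20L))
  cand <- data.table::data.table(chrom = "chr1", start = c(0L, 260L),
                                 end = c(60L, 320L))
  n <- nrow(win)
  out <- consensus_step2(cand, win, rep(5L, n), rep(10L, n))
  expect_equal(nrow(out), 1)  # gap 200 bp merges; all windows eligible
  expect_equal(c(out$start, out$end), c(0, 320))
})

test_that("per-line QC counts the union census and the inclusive 2/3 bound", {
  region <- list(chrom = "chr1", start = 0L, end = 200L)
  mk <- function(pos, ct) data.table::data.table(
    chrom = "chr1", pos = as.integer(pos), strand = "+", context = "CG",
    C = 0L, CT = as.integer(ct))
  # census of 5 sites: every line fails however covered
  five <- list(a = mk(1:5 * 10, rep(10, 5)), b = mk(1:5 * 10, rep(10, 5)))
  qc5 <- per_line_qc(region, five, "CG")
  expect_equal(qc5$n_cytosines, 5)
  expect_equal(qc5$qc_pass_fraction, 0)

  # 9 sites, 6 covered at >= 2x: 6/9 = 2/3 passes (inclusive), provided
  # pooled coverage holds
  nine <- list(a = mk(1:9 * 10, c(rep(4, 6), rep(1, 3))))
  qc9 <- per_line_qc(region, nine, "CG")
  expect_equal(qc9$n_cytosines, 9)
  expect_true(qc9$pass[["a"]])

  # 5 of 9 covered -> below 2/3, fails
  nine2 <- list(a = mk(1:9 * 10, c(rep(4, 5), rep(1, 4))))
  expect_false(per_line_qc(region, nine2, "CG")$pass[["a"]])
})

test_that("final call applies the second-rank rule and kills single-line outliers", {
  lv <- c(0.98, 0.95, 0.90, 0.85, 0.10, 0.02)
  names(lv) <- paste0("L", 1:6)
  fc <- final_call(lv, "CG")
  expect_true(fc$keep)
  expect_equal(fc$second_high, 0.95)
  expect_equal(fc$second_low, 0.10)

  outlier <- c(0.95, rep(0.02, 5))
  names(outlier) <- paste0("L", 1:6)
  expect_false(final_call(outlier, "CG")$keep)

  chh <- c(0.35, 0.30, 0.01, 0.03)
  names(chh) <- paste0("L", 1:4)
  expect_true(final_call(chh, "CHH")$keep)

  expect_false(final_call(c(a = 0.9, b = 0.1, c = 0.5), "CG")$keep)
  expect_match(final_call(c(a = 0.9, b = 0.1, c = 0.5), "CG")$reason, "fewer than 4")
})

test_that("group-I selection is deterministic, skips empty lines, spans subgroups", {
  lv <- matrix(0.5, 10, 6, dimnames = list(paste("chr1", seq(0, 180, 20)),
                                           paste0("L", 1:6)))
  wm <- structure(list(levels = lv,
                       windows = data.frame(chrom = "chr1", start = seq(0L, 180L, 20L)),
                       context = "CG"), class = "windowed_methylome")
  K <- diag(6); dimnames(K) <- list(colnames(lv), colnames(lv))
  # identical coverage and kinship: first k lines in input order
  expect_equal(select_group_one(wm, K, k = 3), c("L1", "L2", "L3"))

  lv2 <- lv; lv2[, "L2"] <- NA
  wm2 <- wm; wm2$levels <- lv2
  expect_false("L2" %in% select_group_one(wm2, K, k = 3))
  expect_error(select_group_one(wm, K, k = 6), "smaller")

  sp <- small_panel()
  wm_cg <- windowed_methylome(sp$panel$calls, "CG")
  picked <- select_group_one(wm_cg, kinship_from_markers(sp$gm$geno), k = 6)
  sub <- sp$gm$lines$subgroup[match(picked, sp$gm$lines$line_id)]
  expect_setequal(unique(sub), unique(sp$gm$lines$subgroup))
})

test_that("two-step caller matches the brute-force oracle on 50 tiny instances", {
  n_match <- 0
  for (seed in 1:50) {
    inst <- random_tiny_instance(seed)
    got <- call_dmrs(inst$calls_list, inst$context, group1 = inst$group1)
    want <- oracle_call_dmrs(inst$calls_df, inst$context, inst$group1,
                             inst$n_windows)
    expect_equal(nrow(got$regions), nrow(want),
                 info = sprintf("seed %d (%s): DMR count", seed, inst$context))
    if (nrow(want) > 0) {
      expect_equal(got$regions$start, want$start, info = sprintf("seed %d", seed))
      expect_equal(got$regions$end, want$end, info = sprintf("seed %d", seed))
    }
    if (nrow(want) > 0) n_match <- n_match + 1
  }
  # the instance generator must actually exercise non-trivial outputs
  expect_gt(n_match, 10)
})

test_that("planted DMRs are recovered with full recall and clean background", {
  sp <- small_panel()
  truth <- sp$panel$truth
  for (ctx in c("CG", "CHH")) {
    called <- call_dmrs(sp$panel$calls, ctx, k = 8)
    tv <- truth[truth$context == ctx & truth$kind != "tissue_stable_background", ]
    tb <- truth[truth$kind == "tissue_stable_background", ]
    hit <- vapply(seq_len(nrow(tv)), function(i) {
      any(called$regions$chrom == tv$chrom[i] &
            called$regions$start < tv$end[i] &
            called$regions$end > tv$start[i])
    }, logical(1))
    expect_true(all(hit), info = sprintf("recall in %s", ctx))
    bg_hit <- vapply(seq_len(nrow(tb)), function(i) {
      any(called$regions$chrom == tb$chrom[i] &
            called$regions$start < tb$end[i] &
            called$regions$end > tb$start[i])
    }, logical(1))
    expect_false(any(bg_hit), info = sprintf("background precision in %s", ctx))
  }
})

test_that("every emitted DMR re-validates against QC and the second-rank rule", {
  sp <- small_panel()
  called <- call_dmrs(sp$panel$calls, "CG", k = 8)
  for (i in seq_len(nrow(called$regions))) {
    reg <- called$regions[i, ]
    qc <- per_line_qc(reg, sp$panel$calls, "CG")
    expect_gt(qc$qc_pass_fraction, 0.6)
    fc <- final_call(region_levels(reg, sp$panel$calls, "CG"), "CG")
    expect_true(fc$keep)
    expect_equal(fc$second_high, reg$second_high)
    expect_equal(fc$second_low, reg$second_low)
  }
})
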