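# Reading/writing per-cytosine calls and 20-bp window summaries.
#
# Input dialect is the methratio TSV (chr, pos, strand, context, ratio,
# eff_CT_count, C_count, CT_count).  Only chr/pos/strand/context/C_count/
# CT_count are required; positions on disk are 1-based and converted to
# 0-based half-open internally.

METHRATIO_COLS <- c("chr", "pos", "strand", "context", "ratio",
                    "eff_CT_count", "C_count", "CT_count")

#' Read per-cytosine methylation calls
#'
#' @param path path to a methratio-dialect TSV; a header row is optional.
#' @return a data.table with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, `C` (methylated reads), `CT` (total reads), coordinate
#'   sorted on input order (which must already be sorted).
#' @export
read_cytosine_calls <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- length(first) > 0 && grepl("^chr\\b|\\bpos\\b", first)
  dt <- data.table::fread(path, sep = "\t", header = has_header)
  if (nrow(dt) == 0L) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(), context = character(),
                                  C = integer(), CT = integer()))
  }
  if (ncol(dt) < 6L)
    stop_popmeth("%s: expected >= 6 methratio columns, found %d", path, ncol(dt))
  if (has_header) {
    miss <- setdiff(c("chr", "pos", "strand", "context", "C_count", "CT_count"), names(dt))
    if (length(miss))
      stop_popmeth("%s: missing required columns: %s", path, paste(miss, collapse = ", "))
    out <- dt[, .(chrom = as.character(chr), pos = as.integer(pos),
                  strand = as.character(strand), context = as.character(context),
                  C = as.integer(C_count), CT = as.integer(CT_count))]
  } else {
    if (ncol(dt) == 6L) {
      out <- dt[, .(chrom = as.character(V1), pos = as.integer(V2),
                    strand = as.character(V3), context = as.character(V4),
                    C = as.integer(V5), CT = as.integer(V6))]
    } else {
      out <- dt[, .(chrom = as.character(V1), pos = as.integer(V2),
                    strand = as.character(V3), context = as.character(V4),
                    C = as.integer(V7), CT = as.integer(V8))]
    }
  }
  line_no <- seq_len(nrow(out)) + as.integer(has_header)
  bad_ctx <- which(!out$context %in% METH_CONTEXTS)
  if (length(bad_ctx))
    stop_popmeth("%s line %d: context '%s' not one of CG/CHG/CHH",
                 path, line_no[bad_ctx[1L]], out$context[bad_ctx[1L]])
  bad_cnt <- which(is.na(out$C) | is.na(out$CT) | out$C < 0L | out$C > out$CT)
  if (length(bad_cnt))
    stop_popmeth("%s line %d: methylated reads exceed total reads (or malformed counts)",
                 path, line_no[bad_cnt[1L]])
  bad_strand <- which(!out$strand %in% c("+", "-"))
  if (length(bad_strand))
    stop_popmeth("%s line %d: strand must be + or -", path, line_no[bad_strand[1L]])
  unsorted <- out[, any(diff(pos) < 0L), by = chrom][V1 == TRUE]
  if (nrow(unsorted))
    stop_popmeth("%s: positions on %s are not coordinate-sorted; sort the input first",
                 path, unsorted$chrom[1L])
  out[, pos := pos - 1L]  # methratio is 1-based
  out[]
}

#' Write per-cytosine calls in the methratio dialect
#'
#' @param calls a data.table as returned by [read_cytosine_calls()].
#' @param path output TSV path.
#' @export
write_cytosine_calls <- function(calls, path) {
  out <- data.table::data.table(
    chr = calls$chrom, pos = calls$pos + 1L, strand = calls$strand,
    context = calls$context,
    ratio = ifelse(calls$CT > 0, round(calls$C / calls$CT, 4), 0),
    eff_CT_count = calls$CT, C_count = calls$C, CT_count = calls$CT)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Summarize one line's calls into 20-bp windows
#'
#' A cytosine contributes only when it has at least 2 reads; the window
#' level is read-weighted (pooled methylated reads over pooled total reads
#' of contributing cytosines), and a window with no contributing cytosine
#' is absent from the output.
#'
#' @param calls coordinate-sorted calls data.table for one line.
#' @param context one of CG/CHG/CHH.
#' @param min_coverage per-cytosine read threshold (default 2).
#' @return data.table with `chrom`, `start` (window start, multiple of 20),
#'   `level`, `covered_cytosines`, `total_cytosines` (sites of the context
#'   reported in the window, before the coverage filter).
#' @export
window_methylation <- function(calls, context, min_coverage = 2L) {
  context <- match_context(context)
  sub <- calls[calls$context == context]
  if (nrow(sub) == 0L) {
    return(data.table::data.table(chrom = character(), start = integer(),
                                  level = numeric(), covered_cytosines = integer(),
                                  total_cytosines = integer()))
  }
  sub[, start := (pos %/% WINDOW_BP) * WINDOW_BP]
  out <- sub[, .(
    level = if (any(CT >= min_coverage)) sum(C[CT >= min_coverage]) / sum(CT[CT >= min_coverage]) else NA_real_,
    covered_cytosines = sum(CT >= min_coverage),
    total_cytosines = .N
  ), by = .(chrom, start)]
  out <- out[!is.na(level)]
  data.table::setorder(out, chrom, start)
  out[]
}

#' Build a windowed methylome across a panel of lines
#'
#' @param calls_list named list of per-line call tables (e.g.
#'   `meth_panel$calls` or tables from [read_cytosine_calls()]).
#' @param context one of CG/CHG/CHH.
#' @return a `windowed_methylome`: list with `levels` (windows x lines
#'   matrix, `NA` where a line has no covered cytosine in the window),
#'   `windows` (data.frame: chrom, start), and `context`.  Window rows are
#'   the union of windows with data in any line, coordinate sorted.
#' @export
windowed_methylome <- function(calls_list, context) {
  context <- match_context(context)
  per_line <- lapply(calls_list, window_methylation, context = context)
  keys <- unique(data.table::rbindlist(
    lapply(per_line, function(w) w[, .(chrom, start)])))
  if (nrow(keys) == 0L) {
    return(structure(list(levels = matrix(NA_real_, 0, length(calls_list),
                                          dimnames = list(NULL, names(calls_list))),
                          windows = data.frame(chrom = character(), start = integer()),
                          context = context),
                     class = "windowed_methylome"))
  }
  data.table::setorder(keys, chrom, start)
  key_id <- paste(keys$chrom, keys$start)
  levels <- matrix(NA_real_, nrow(keys), length(calls_list),
                   dimnames = list(key_id, names(calls_list)))
  for (li in seq_along(per_line)) {
    w <- per_line[[li]]
    if (nrow(w)) levels[paste(w$chrom, w$start), li] <- w$level
  }
  structure(list(levels = levels,
                 windows = as.data.frame(keys),
                 context = context),
            class = "windowed_methylome")
}

#' @export
print.windowed_methylome <- function(x, ...) {
  cat(sprintf("windowed_methylome (%s): %d windows x %d lines, %.1f%% observed\n",
              x$context, nrow(x$levels), ncol(x$levels),
              100 * mean(!is.na(x$levels))))
  invisible(x)
}

#' Write a windowed methylome as a wide TSV (window x line)
#' @param wm a `windowed_methylome`.
#' @param path output path.
#' @export
write_windowed_tsv <- function(wm, path) {
  dt <- data.table::data.table(chrom = wm$windows$chrom, start = wm$windows$start,
                               end = wm$windows$start + WINDOW_BP)
  dt <- cbind(dt, data.table::as.data.table(wm$levels))
  data.table::fwrite(dt, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Write called DMRs as BED6+
#'
#' Columns: chrom, start, end, name, score (mean inter-line range of
#' region methylation, scaled to 0-1000), strand ('.'), context,
#' n_windows, n_cytosines.
#'
#' @param dmrs a `dmr_set` from [call_dmrs()].
#' @param path output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  reg <- dmrs$regions
  rng <- apply(dmrs$levels, 1, function(v) diff(range(v, na.rm = TRUE)))
  bed <- data.table::data.table(
    chrom = reg$chrom, start = reg$start, end = reg$end, name = reg$dmr_id,
    score = as.integer(round(1000 * rng)), strand = ".",
    context = reg$context, n_windows = reg$n_windows,
    n_cytosines = reg$n_cytosines)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a methylome panel to per-line TSV files
#' @param panel a `meth_panel`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_methylome <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(panel$calls), function(ln) {
    p <- file.path(dir, paste0(ln, ".methratio.tsv"))
    write_cytosine_calls(panel$calls[[ln]], p)
    p
  }, character(1))
  invisible(paths)
}
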