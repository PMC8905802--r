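#' Configuration of the windowed DMR caller
#'
#' Defaults are the published cascade thresholds: the genome is tiled in
#' consecutive non-overlapping 100-bp windows; a window is eligible when it
#' has at least 6 context cytosines with data and mean coverage of at least
#' 3x (in both samples); candidate windows need a weighted-level difference
#' of at least 30% (CG/CHG) or 10% (CHH); at least 80% of co-covered
#' cytosines must individually differ by 20% (CG/CHG) or 10% (CHH) in the
#' window's direction; kept windows within 100 bp of each other (same
#' direction) are merged, levels recomputed over the merged span, and the
#' final difference must reach 60/50/20% (CG/CHG/CHH) for single-window
#' regions or 30/30/10% for longer regions.
#'
#' @param window_size tiling window width in bp.
#' @param min_sites minimum context cytosines with data per window.
#' @param min_mean_cov minimum mean coverage per window.
#' @param window_diff named per-context minimum window-level difference.
#' @param cytosine_diff named per-context minimum per-cytosine difference.
#' @param min_diff_cytosine_fraction minimum fraction of differential
#'   cytosines per window.
#' @param merge_gap maximum gap (bp) between merged windows.
#' @param final_diff_single per-context final threshold for regions of
#'   exactly one window.
#' @param final_diff_multi per-context final threshold for longer regions.
#' @return a `dmr_config` list.
#' @export
dmr_config <- function(window_size = 100L,
                       min_sites = 6L,
                       min_mean_cov = 3,
                       window_diff = c(CG = 0.30, CHG = 0.30, CHH = 0.10),
                       cytosine_diff = c(CG = 0.20, CHG = 0.20, CHH = 0.10),
                       min_diff_cytosine_fraction = 0.80,
                       merge_gap = 100L,
                       final_diff_single = c(CG = 0.60, CHG = 0.50, CHH = 0.20),
                       final_diff_multi = c(CG = 0.30, CHG = 0.30, CHH = 0.10)) {
  cfg <- list(window_size = as.integer(window_size),
              min_sites = as.integer(min_sites),
              min_mean_cov = min_mean_cov,
              window_diff = window_diff,
              cytosine_diff = cytosine_diff,
              min_diff_cytosine_fraction = min_diff_cytosine_fraction,
              merge_gap = as.integer(merge_gap),
              final_diff_single = final_diff_single,
              final_diff_multi = final_diff_multi)
  stopifnot(cfg$window_size > 0L, cfg$merge_gap >= 0L,
            all(cfg$window_diff > 0), all(cfg$window_diff <= 1),
            all(cfg$cytosine_diff > 0), all(cfg$cytosine_diff <= 1),
            cfg$min_diff_cytosine_fraction > 0,
            cfg$min_diff_cytosine_fraction <= 1)
  for (nm in c("window_diff", "cytosine_diff", "final_diff_single",
               "final_diff_multi"))
    if (!all(c("CG", "CHG", "CHH") %in% names(cfg[[nm]])))
      stop(nm, " must name all of CG, CHG, CHH")
  structure(cfg, class = "dmr_config")
}

#' Summarize per-cytosine calls into tiling windows
#'
#' Tiles each chromosome in consecutive non-overlapping windows and, for
#' one sequence context, reports per window the number of cytosines with
#' data, the mean coverage over those sites, the summed counts and the
#' weighted methylation level. Windows without any covered context
#' cytosine are not emitted.
#'
#' @param table a [methylome()] object.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param config a [dmr_config()].
#' @param chrom_sizes optional named vector of chromosome lengths; when
#'   given it must cover every chromosome in `table` and the last window of
#'   each chromosome is clipped to the chromosome end.
#' @return data.table with columns `chrom`, `start`, `end`, `context`,
#'   `n_sites`, `mean_cov`, `meth_sum`, `total_sum`, `level`.
#' @export
summarize_windows <- function(table, context, config = dmr_config(),
                              chrom_sizes = NULL) {
  stopifnot(context %in% c("CG", "CHG", "CHH"))
  ctx <- context
  dt <- data.table::as.data.table(table)
  dt <- dt[dt$context == ctx & dt$total_reads > 0L]
  if (!is.null(chrom_sizes)) {
    absent <- setdiff(unique(dt$chrom), names(chrom_sizes))
    if (length(absent))
      stop("chrom_sizes does not cover: ", paste(absent, collapse = ", "))
  }
  ws <- config$window_size
  if (nrow(dt) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), context = character(),
                                  n_sites = integer(), mean_cov = numeric(),
                                  meth_sum = integer(), total_sum = integer(),
                                  level = numeric()))
  dt[, win := (pos - 1L) %/% ws]
  out <- dt[, .(n_sites = .N,
                mean_cov = mean(total_reads),
                meth_sum = sum(meth_reads),
                total_sum = sum(total_reads)),
            by = .(chrom, win)]
  out[, `:=`(start = win * ws, end = (win + 1L) * ws,
             context = ctx, level = meth_sum / total_sum)]
  if (!is.null(chrom_sizes))
    out[, end := pmin(end, as.integer(chrom_sizes[chrom]))]
  data.table::setorder(out, chrom, start)
  out[, win := NULL]
  data.table::setcolorder(out, c("chrom", "start", "end", "context",
                                 "n_sites", "mean_cov", "meth_sum",
                                 "total_sum", "level"))
  out[]
}

#' Candidate differential windows between two samples
#'
#' Joins the two samples' window summaries on the common tiling and keeps
#' windows where both samples are eligible (`min_sites`, `min_mean_cov`)
#' and the absolute level difference reaches the per-context window
#' threshold. The difference is oriented as sample B minus sample A
#' (convention: B is the mutant / second sample).
#'
#' @param a,b window summaries from [summarize_windows()] on the same
#'   tiling.
#' @inheritParams summarize_windows
#' @return data.table of candidate windows with `level_a`, `level_b`,
#'   `delta`.
#' @export
candidate_windows <- function(a, b, context, config = dmr_config()) {
  stopifnot(context %in% c("CG", "CHG", "CHH"))
  ctx <- context
  a <- data.table::as.data.table(a)
  a <- a[a$context == ctx]
  b <- data.table::as.data.table(b)
  b <- b[b$context == ctx]
  m <- merge(a, b, by = c("chrom", "start"), suffixes = c("_a", "_b"))
  if (nrow(m) && any(m$end_a != m$end_b))
    stop("window tilings of the two samples do not match")
  m <- m[n_sites_a >= config$min_sites & n_sites_b >= config$min_sites &
           mean_cov_a >= config$min_mean_cov &
           mean_cov_b >= config$min_mean_cov]
  m[, delta := level_b - level_a]
  m <- m[abs(delta) >= config$window_diff[[context]]]
  out <- m[, .(chrom, start, end = end_a, context = ctx,
               n_sites_a, n_sites_b, mean_cov_a, mean_cov_b,
               level_a, level_b, delta)]
  data.table::setorder(out, chrom, start)
  out[]
}

#' Filter candidate windows by the fraction of differential cytosines
#'
#' For every candidate window, looks at the context cytosines covered in
#' both samples; a cytosine is differential when its per-site ratio
#' difference reaches the per-context cytosine threshold and agrees in
#' sign with the window-level difference. Windows are kept when the
#' differential fraction reaches `min_diff_cytosine_fraction`. Windows
#' with no co-covered cytosine are dropped with a warning.
#'
#' @param candidates output of [candidate_windows()].
#' @param table_a,table_b the two [methylome()] objects.
#' @inheritParams summarize_windows
#' @return the filtered candidate table with an added `diff_fraction`
#'   column.
#' @export
cytosine_fraction_filter <- function(candidates, table_a, table_b,
                                     config = dmr_config()) {
  if (nrow(candidates) == 0L) {
    out <- data.table::copy(data.table::as.data.table(candidates))
    out[, diff_fraction := numeric(0)]
    return(out[])
  }
  ctx <- candidates$context[1L]
  thr <- config$cytosine_diff[[ctx]]
  co <- co_covered_calls(table_a, table_b, ctx)
  cand <- data.table::as.data.table(candidates)
  co[, start := (pos - 1L) %/% config$window_size * config$window_size]
  stats <- co[cand[, .(chrom, start, wdelta = delta)],
              on = c("chrom", "start"), nomatch = NULL][
    , .(n_co = .N,
        n_diff = sum(abs(ratio_b - ratio_a) >= thr &
                       sign(ratio_b - ratio_a) == sign(wdelta))),
    by = .(chrom, start)]
  out <- merge(cand, stats, by = c("chrom", "start"), all.x = TRUE)
  if (anyNA(out$n_co)) {
    warning(sum(is.na(out$n_co)),
            " candidate window(s) had no co-covered cytosines and were dropped")
    out <- out[!is.na(n_co)]
  }
  out[, diff_fraction := n_diff / n_co]
  out <- out[diff_fraction >= config$min_diff_cytosine_fraction]
  out[, c("n_co", "n_diff") := NULL]
  data.table::setorder(out, chrom, start)
  out[]
}

# context cytosines covered (> 0 reads) in both samples, with per-site ratios
co_covered_calls <- function(table_a, table_b, ctx) {
  a <- data.table::as.data.table(table_a)
  a <- a[a$context == ctx & a$total_reads > 0L]
  b <- data.table::as.data.table(table_b)
  b <- b[b$context == ctx & b$total_reads > 0L]
  co <- merge(a[, .(chrom, pos, strand, ratio_a = meth_reads / total_reads)],
              b[, .(chrom, pos, strand, ratio_b = meth_reads / total_reads)],
              by = c("chrom", "pos", "strand"))
  co
}

#' Merge filtered windows and apply the final size-dependent thresholds
#'
#' Adjacent kept windows of the same direction with an inter-window gap of
#' at most `merge_gap` bp are merged; levels of each merged region are
#' recomputed by the weighted method over all context cytosines in the
#' merged span, and the region is retained when its absolute recomputed
#' difference reaches the single-window threshold (regions of exactly
#' `window_size` bp) or the multi-window threshold (longer regions).
#'
#' @param filtered output of [cytosine_fraction_filter()].
#' @inheritParams cytosine_fraction_filter
#' @return a DMR data.table: `chrom`, `start`, `end`, `context`,
#'   `level_a`, `level_b`, `delta`, `direction` (`hyper` = B above A),
#'   `n_windows`.
#' @export
merge_and_finalize <- function(filtered, table_a, table_b, context,
                               config = dmr_config()) {
  empty <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    context = character(), level_a = numeric(), level_b = numeric(),
    delta = numeric(), direction = character(), n_windows = integer())
  w <- data.table::as.data.table(filtered)
  if (nrow(w) == 0L) return(empty)
  data.table::setorder(w, chrom, start)
  w[, sign_a := sign(delta)]
  w[, run := cumsum(
    chrom != data.table::shift(chrom, fill = chrom[1L]) |
      sign_a != data.table::shift(sign_a, fill = sign_a[1L]) |
      start - data.table::shift(end, fill = start[1L]) > config$merge_gap)]
  reg <- w[, .(chrom = chrom[1L], start = min(start), end = max(end),
               n_windows = .N), by = run]

  ctx <- context
  ac <- data.table::as.data.table(table_a)
  ac <- ac[ac$context == ctx & ac$total_reads > 0L]
  bc <- data.table::as.data.table(table_b)
  bc <- bc[bc$context == ctx & bc$total_reads > 0L]
  span_level <- function(calls, r_chrom, r_start, r_end) {
    s <- calls[chrom == r_chrom & pos >= r_start + 1L & pos <= r_end]
    if (nrow(s) == 0L || sum(s$total_reads) == 0L) return(NA_real_)
    sum(as.numeric(s$meth_reads)) / sum(as.numeric(s$total_reads))
  }
  reg[, level_a := mapply(span_level, r_chrom = chrom, r_start = start,
                          r_end = end, MoreArgs = list(calls = ac))]
  reg[, level_b := mapply(span_level, r_chrom = chrom, r_start = start,
                          r_end = end, MoreArgs = list(calls = bc))]
  reg <- reg[!is.na(level_a) & !is.na(level_b)]
  if (nrow(reg) == 0L) return(empty)
  reg[, delta := level_b - level_a]
  thr_single <- config$final_diff_single[[context]]
  thr_multi <- config$final_diff_multi[[context]]
  reg[, keep := abs(delta) >=
        ifelse(end - start == config$window_size, thr_single, thr_multi)]
  reg <- reg[keep == TRUE & delta != 0]
  if (nrow(reg) == 0L) return(empty)
  reg[, `:=`(context = ctx,
             direction = ifelse(delta > 0, "hyper", "hypo"))]
  out <- reg[, .(chrom, start, end, context, level_a, level_b, delta,
                 direction, n_windows)]
  data.table::setorder(out, chrom, start)
  out[]
}

#' Call differentially methylated regions between two methylomes
#'
#' Runs the full cascade: window summarization, candidate-window selection,
#' per-cytosine differential-fraction filtering, merging and final
#' size-dependent thresholding. Direction is reported with respect to
#' sample B (`hyper` = higher methylation in B).
#'
#' @param table_a,table_b [methylome()] objects (A is the reference
#'   sample, e.g. wild type; B the contrast, e.g. mutant).
#' @inheritParams summarize_windows
#' @return a DMR data.table (see [merge_and_finalize()]).
#' @examples
#' sim <- simulate_methylome_pair(simulation_design(seed = 1))
#' dmrs <- call_dmrs(sim$a, sim$b, "CG")
#' @export
call_dmrs <- function(table_a, table_b, context, config = dmr_config(),
                      chrom_sizes = NULL) {
  wa <- summarize_windows(table_a, context, config, chrom_sizes)
  wb <- summarize_windows(table_b, context, config, chrom_sizes)
  cand <- candidate_windows(wa, wb, context, config)
  filt <- suppressWarnings(
    cytosine_fraction_filter(cand, table_a, table_b, config))
  merge_and_finalize(filt, table_a, table_b, context, config)
}

#' Write DMRs as BED6+ and read them back
#'
#' Columns: chrom, start, end, name (`context:direction`),
#' score (`round(1000 * |delta|)`), strand (`.`), then `level_a`,
#' `level_b`, `delta`, `n_windows`.
#'
#' @param dmrs a DMR data.table from [call_dmrs()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- data.table::data.table(
    chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
    name = paste0(dmrs$context, ":", dmrs$direction),
    score = round(1000 * abs(dmrs$delta)), strand = ".",
    level_a = dmrs$level_a, level_b = dmrs$level_b, delta = dmrs$delta,
    n_windows = dmrs$n_windows)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_dmr_bed
#' @export
read_dmr_bed <- function(path) {
  bed <- data.table::fread(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand", "level_a",
                                         "level_b", "delta", "n_windows"))
  parts <- data.table::tstrsplit(bed$name, ":", fixed = TRUE)
  out <- bed[, .(chrom, start, end, context = parts[[1L]], level_a, level_b,
                 delta, direction = parts[[2L]], n_windows)]
  data.table::setorder(out, chrom, start)
  out[]
}
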