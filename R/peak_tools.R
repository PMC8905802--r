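#' Shared peaks between two replicates
#'
#' Two peaks from different replicates are "shared" when the size of their
#' overlapping region exceeds `frac` of either peak — equivalently, of the
#' smaller of the two — and the overlap region itself represents the
#' shared peak. Overlapping emitted regions are merged in a final pass, so
#' the result is symmetric in the replicate order.
#'
#' @param rep1,rep2 peak tables (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param frac overlap fraction of the smaller peak (default 0.9, strict
#'   `>`).
#' @return data.table of shared regions (`chrom`, `start`, `end`).
#' @export
shared_peaks <- function(rep1, rep2, frac = 0.9) {
  r1 <- data.table::as.data.table(rep1)
  r2 <- data.table::as.data.table(rep2)
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer())
  if (nrow(r1) == 0L || nrow(r2) == 0L) return(empty)
  g1 <- as_gr(r1)
  g2 <- as_gr(r2)
  hits <- GenomicRanges::findOverlaps(g1, g2)
  if (!length(hits)) return(empty)
  p <- g1[S4Vectors::queryHits(hits)]
  q <- g2[S4Vectors::subjectHits(hits)]
  ov <- IRanges::pintersect(p, q)
  olen <- GenomicRanges::width(ov)
  shared <- olen > frac * pmin(GenomicRanges::width(p),
                               GenomicRanges::width(q))
  if (!any(shared)) return(empty)
  merged <- GenomicRanges::reduce(ov[shared])
  out <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged))
  data.table::setorder(out, chrom, start)
  out[]
}

#' Weighted methylation level inside each peak
#'
#' @param peaks peak table (`chrom`, `start`, `end`).
#' @param table a [methylome()] object.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @return `peaks` with an added `level` column (`NA` when a peak contains
#'   no covered context cytosine).
#' @export
peak_methylation <- function(peaks, table, context) {
  ctx <- context
  peaks <- data.table::as.data.table(peaks)
  out <- data.table::copy(peaks)
  calls <- data.table::as.data.table(table)
  calls <- calls[calls$context == ctx & calls$total_reads > 0L]
  if (nrow(out) == 0L) {
    out[, level := numeric(0)]
    return(out[])
  }
  if (nrow(calls) == 0L) {
    out[, level := NA_real_]
    return(out[])
  }
  cgr <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$pos, calls$pos))
  hits <- GenomicRanges::findOverlaps(as_gr(out), cgr)
  lev <- rep(NA_real_, nrow(out))
  if (length(hits)) {
    h <- data.table::data.table(p = S4Vectors::queryHits(hits),
                                m = calls$meth_reads[S4Vectors::subjectHits(hits)],
                                t = calls$total_reads[S4Vectors::subjectHits(hits)])
    agg <- h[, .(level = sum(as.numeric(m)) / sum(as.numeric(t))), by = p]
    lev[agg$p] <- agg$level
  }
  out[, level := lev]
  out[]
}

#' Compare peak methylation between genotypes in differential and
#' non-differential peaks
#'
#' For each peak group (differential vs non-differential binding), computes
#' per-peak weighted levels in both methylomes and compares them with a
#' two-sided rank-based test (Wilcoxon rank-sum by default, sign test on
#' the per-peak paired differences as an alternative). Groups smaller than
#' 3 peaks with data get `NA` p-values.
#'
#' @param diff_peaks,nondiff_peaks peak tables.
#' @param table_wt,table_mut [methylome()] objects.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param test `"wilcox"` (rank-sum) or `"sign"`.
#' @return data.table per group: `group`, `n`, `median_wt`, `median_mut`,
#'   `p`.
#' @export
compare_peak_methylation <- function(diff_peaks, nondiff_peaks, table_wt,
                                     table_mut, context,
                                     test = c("wilcox", "sign")) {
  test <- match.arg(test)
  one_group <- function(peaks, label) {
    wt <- peak_methylation(peaks, table_wt, context)$level
    mut <- peak_methylation(peaks, table_mut, context)$level
    ok <- !is.na(wt) & !is.na(mut)
    wt <- wt[ok]; mut <- mut[ok]
    p <- NA_real_
    if (length(wt) >= 3L) {
      if (test == "wilcox") {
        p <- suppressWarnings(
          stats::wilcox.test(wt, mut, alternative = "two.sided")$p.value)
      } else {
        d <- mut - wt
        d <- d[d != 0]
        p <- if (length(d)) stats::binom.test(sum(d > 0), length(d))$p.value
        else 1
      }
    }
    data.table::data.table(group = label, n = length(wt),
                           median_wt = stats::median(wt),
                           median_mut = stats::median(mut), p = p)
  }
  rbind(one_group(diff_peaks, "differential"),
        one_group(nondiff_peaks, "non_differential"))
}

#' Read peaks from BED
#'
#' @param path BED3+ file.
#' @return data.table `chrom`, `start`, `end` (0-based half-open).
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.table::data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                         start = GenomicRanges::start(gr) - 1L,
                         end = GenomicRanges::end(gr))
}
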