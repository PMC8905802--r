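# Independent brute-force oracles. These deliberately use plain loops and
# naive O(n^2) scans so they share no code path with the implementation.

# weighted methylation level by explicit accumulation
oracle_weighted_level <- function(meth, total) {
  sm <- 0
  st <- 0
  for (i in seq_along(meth)) {
    sm <- sm + meth[i]
    st <- st + total[i]
  }
  sm / st
}

# all-pairs overlap scan on 0-based half-open intervals of one chromosome
oracle_shared_flags <- function(x, y, min_overlap = 1L) {
  sapply(seq_len(nrow(x)), function(i) {
    for (j in seq_len(nrow(y))) {
      ov <- min(x$end[i], y$end[j]) - max(x$start[i], y$start[j])
      if (ov >= min_overlap) return(TRUE)
    }
    FALSE
  })
}

# bp gap to the nearest feature (0 when overlapping), naive scan
oracle_nearest_distance <- function(q_start, q_end, f_start, f_end) {
  sapply(seq_along(q_start), function(i) {
    best <- Inf
    for (j in seq_along(f_start)) {
      if (q_start[i] < f_end[j] && q_end[i] > f_start[j]) {
        gap <- 0
      } else if (q_end[i] <= f_start[j]) {
        gap <- f_start[j] - q_end[i]
      } else {
        gap <- q_start[i] - f_end[j]
      }
      best <- min(best, gap)
    }
    best
  })
}

# per-window differential-cytosine fraction, recomputed site by site
oracle_diff_fraction <- function(win_start, win_end, calls_a, calls_b,
                                 ctx, thr, window_delta_sign) {
  n_co <- 0
  n_diff <- 0
  for (i in seq_len(nrow(calls_a))) {
    if (calls_a$context[i] != ctx) next
    if (calls_a$pos[i] <= win_start || calls_a$pos[i] > win_end) next
    if (calls_a$total_reads[i] == 0) next
    j <- which(calls_b$pos == calls_a$pos[i] &
                 calls_b$strand == calls_a$strand[i] &
                 calls_b$chrom == calls_a$chrom[i])
    if (length(j) != 1 || calls_b$total_reads[j] == 0) next
    ra <- calls_a$meth_reads[i] / calls_a$total_reads[i]
    rb <- calls_b$meth_reads[j] / calls_b$total_reads[j]
    n_co <- n_co + 1
    if (abs(rb - ra) >= thr && sign(rb - ra) == window_delta_sign)
      n_diff <- n_diff + 1
  }
  if (n_co == 0) return(NA_real_)
  n_diff / n_co
}

# Yates-corrected two-sample chi-square from the textbook 2x2 formula; the
# correction is capped at |O - E| so it can never overshoot past zero
oracle_yates_chisq <- function(k1, n1, k2, n2) {
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  N <- sum(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  corr <- min(0.5, abs(tab[1, 1] - rs[1] * cs[1] / N))
  stat <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- rs[i] * cs[j] / N
    stat <- stat + (abs(tab[i, j] - e) - corr)^2 / e
  }
  list(statistic = unname(stat),
       p = stats::pchisq(unname(stat), df = 1, lower.tail = FALSE))
}

# build a small methylome table from vectors
mk_methylome <- function(pos, meth, total, chrom = "chr1", strand = "+",
                         context = "CG", ...) {
  methylome(data.frame(chrom = chrom, pos = pos, strand = strand,
                       context = context, meth_reads = meth,
                       total_reads = total), ...)
}

# reflect a methylome and a feature table through a genome of size G
reflect_methylome <- function(mt, G) {
  df <- as.data.frame(mt)
  df$pos <- G - df$pos + 1L
  df$strand <- ifelse(df$strand == "+", "-", "+")
  methylome(df)
}

reflect_features <- function(ft, G) {
  out <- data.table::copy(data.table::as.data.table(ft))
  s <- out$start
  out$start <- G - out$end
  out$end <- G - s
  out$strand <- ifelse(out$strand == "+", "-",
                       ifelse(out$strand == "-", "+", "."))
  out
}
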