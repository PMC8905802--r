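#' Assign a 100-bp window to a metaprofile bin
#'
#' Metaprofiles use 80 bins: 20 upstream flank bins (index 0-19, covering
#' -2000..0 bp from the 5' end in 100-bp steps), 40 body bins (index
#' 20-59, the feature body normalized to 4000 bp), and 20 downstream bins
#' (index 60-79). A window is anchored at its midpoint; minus-strand
#' features are mirrored so index 0 is always the bin farthest upstream of
#' the 5' end. Windows farther than 2 kb from the feature and outside the
#' body get `NA`.
#'
#' @param win_start,win_end window interval (0-based half-open).
#' @param f_start,f_end,f_strand feature interval and strand (`.` treated
#'   as `+`).
#' @param flank_bp flank width (default 2000).
#' @return integer bin index in 0..79, or `NA`.
#' @export
assign_window_to_bin <- function(win_start, win_end, f_start, f_end,
                                 f_strand = "+", flank_bp = 2000L) {
  mapply(function(ws, we, fs, fe, str) {
    m <- (ws + we) / 2
    plus <- !identical(str, "-")
    L <- fe - fs
    if (plus) {
      if (m >= fs && m < fe) {        # body
        d <- m - fs
        return(20L + min(39L, as.integer(floor(40 * d / L))))
      }
      if (m < fs) {                    # upstream
        dist <- fs - m
        if (dist > flank_bp) return(NA_integer_)
        return(as.integer(floor((flank_bp - dist) / 100)))
      }
      dist <- m - fe                   # downstream
      if (dist < 1 || dist > flank_bp) return(NA_integer_)
      return(60L + as.integer(floor((dist - 1) / 100)))
    } else {
      if (m > fs && m <= fe) {        # body (mirrored boundary rule)
        d <- fe - m
        return(20L + min(39L, as.integer(floor(40 * d / L))))
      }
      if (m > fe) {                    # upstream = right side
        dist <- m - fe
        if (dist > flank_bp) return(NA_integer_)
        return(as.integer(floor((flank_bp - dist) / 100)))
      }
      dist <- fs - m                   # downstream = left side
      if (dist < 1 || dist > flank_bp) return(NA_integer_)
      return(60L + as.integer(floor((dist - 1) / 100)))
    }
  }, win_start, win_end, f_start, f_end, f_strand, USE.NAMES = FALSE)
}

#' Metagene / meta-transposon methylation profile
#'
#' Tiles the methylome in 100-bp windows for one context, links every
#' window to its nearest feature (ties broken by smaller gap then
#' lexicographic feature id), keeps windows within 2 kb of the feature or
#' inside its body, assigns each to one of 80 bins
#' ([assign_window_to_bin()]), computes per feature per bin the weighted
#' level of the pooled window counts, and averages (unweighted) across
#' features per bin. Optionally grouped by feature `family` (e.g. TE
#' superfamily).
#'
#' @param table a [methylome()] object.
#' @param features feature table (see [read_features()]).
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param group_by_family if `TRUE`, one profile per feature family.
#' @param config a [dmr_config()] (supplies the window size).
#' @param flank_bp flank width (default 2000).
#' @return data.table with columns `group`, `context`, `bin_index`,
#'   `region` (upstream/body/downstream), `mean_level`, `n_features`.
#' @export
aggregate_profile <- function(table, features, context,
                              group_by_family = FALSE,
                              config = dmr_config(), flank_bp = 2000L) {
  ctx <- context
  features <- data.table::as.data.table(features)
  if (nrow(features) == 0L) stop("no features given")
  wins <- summarize_windows(table, context, config)
  empty <- data.table::data.table(group = character(), context = character(),
                                  bin_index = integer(), region = character(),
                                  mean_level = numeric(),
                                  n_features = integer())
  if (nrow(wins) == 0L) return(empty)

  # nearest feature per window, deterministic tie-break
  wgr <- as_gr(wins)
  fgr <- as_gr(features)
  nd <- GenomicRanges::distanceToNearest(wgr, fgr, select = "all")
  if (!length(nd)) return(empty)
  h <- data.table::data.table(q = S4Vectors::queryHits(nd),
                              s = S4Vectors::subjectHits(nd),
                              d = S4Vectors::mcols(nd)$distance,
                              fid = features$feature_id[S4Vectors::subjectHits(nd)])
  data.table::setorder(h, q, d, fid)
  h <- h[!duplicated(q)]
  w <- wins[h$q]
  w[, `:=`(f_idx = h$s, distance = h$d)]
  w <- w[distance <= flank_bp]
  if (nrow(w) == 0L) return(empty)
  w[, bin_index := assign_window_to_bin(
    start, end, features$start[f_idx], features$end[f_idx],
    features$strand[f_idx], flank_bp)]
  w <- w[!is.na(bin_index)]
  if (nrow(w) == 0L) return(empty)
  w[, feature_id := features$feature_id[f_idx]]
  w[, group := if (group_by_family)
    as.character(features$family[f_idx]) else "all"]

  per_feature <- w[, .(level = sum(as.numeric(meth_sum)) /
                         sum(as.numeric(total_sum))),
                   by = .(group, feature_id, bin_index)]
  prof <- per_feature[, .(mean_level = mean(level), n_features = .N),
                      by = .(group, bin_index)]
  prof[, `:=`(context = ctx,
              region = ifelse(bin_index < 20L, "upstream",
                              ifelse(bin_index < 60L, "body", "downstream")))]
  data.table::setorder(prof, group, bin_index)
  data.table::setcolorder(prof, c("group", "context", "bin_index", "region",
                                  "mean_level", "n_features"))
  prof[]
}

#' Write a metaprofile as TSV
#'
#' @param profile output of [aggregate_profile()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  data.table::fwrite(profile, path, sep = "\t")
  invisible(path)
}
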