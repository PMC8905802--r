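#' Intersect two DMR sets
#'
#' A DMR in set X is classified "shared" when it overlaps at least
#' `min_overlap_bp` with any DMR in set Y, and symmetrically for Y. This is
#' the comparison used to relate mutant-vs-wild-type DMRs to
#' tissue (endosperm-vs-embryo) DMRs.
#'
#' @param x,y DMR data.tables (at least `chrom`, `start`, `end`).
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @return a list with `shared_x`, `unique_x`, `shared_y`, `unique_y`
#'   (row subsets of the inputs) and a `counts` vector.
#' @export
intersect_dmr_sets <- function(x, y, min_overlap_bp = 1L) {
  x <- data.table::as.data.table(x)
  y <- data.table::as.data.table(y)
  if (nrow(x) == 0L || nrow(y) == 0L) {
    sx <- rep(FALSE, nrow(x)); sy <- rep(FALSE, nrow(y))
  } else {
    hits <- GenomicRanges::findOverlaps(as_gr(x), as_gr(y),
                                        minoverlap = as.integer(min_overlap_bp))
    sx <- seq_len(nrow(x)) %in% S4Vectors::queryHits(hits)
    sy <- seq_len(nrow(y)) %in% S4Vectors::subjectHits(hits)
  }
  list(shared_x = x[sx], unique_x = x[!sx],
       shared_y = y[sy], unique_y = y[!sy],
       counts = c(shared_x = sum(sx), unique_x = sum(!sx),
                  shared_y = sum(sy), unique_y = sum(!sy)))
}

#' Demethylase-sensitive DMRs
#'
#' The operational definition of a demethylase target region: a DMR that is
#' hypermethylated in the mutant (relative to wild type) in endosperm AND
#' overlaps a region hypomethylated in wild-type endosperm relative to
#' embryo. Returns the qualifying mutant-hyper DMRs.
#'
#' @param mutant_hyper DMRs with `direction == "hyper"` (mutant > WT).
#' @param tissue_hypo DMRs with `direction == "hypo"` (endosperm < embryo).
#' @param min_overlap_bp minimum overlap in bp.
#' @return the shared subset of `mutant_hyper`.
#' @export
sensitive_dmrs <- function(mutant_hyper, tissue_hypo, min_overlap_bp = 1L) {
  mutant_hyper <- data.table::as.data.table(mutant_hyper)
  tissue_hypo <- data.table::as.data.table(tissue_hypo)
  if (nrow(mutant_hyper) && !all(mutant_hyper$direction == "hyper"))
    stop("mutant_hyper must contain only hypermethylated DMRs")
  if (nrow(tissue_hypo) && !all(tissue_hypo$direction == "hypo"))
    stop("tissue_hypo must contain only hypomethylated DMRs")
  intersect_dmr_sets(mutant_hyper, tissue_hypo, min_overlap_bp)$shared_x
}

#' Assign DMRs to genomic feature categories
#'
#' Each DMR receives exactly one category under the precedence
#' genic > promoter/flank (within `flank_bp` of a gene) > TE > intergenic,
#' together with its nearest gene and the bp gap to it (0 when
#' overlapping). Distances are strand-ignorant interval gaps.
#'
#' @param dmrs DMR data.table.
#' @param genes,tes feature tables (see [read_features()]); `tes` may be
#'   `NULL`.
#' @param flank_bp flank width defining promoter/flank (default 2000).
#' @return `dmrs` with added `category`, `nearest_feature_id`, `distance`.
#' @export
assign_feature <- function(dmrs, genes, tes = NULL, flank_bp = 2000L) {
  dmrs <- data.table::as.data.table(dmrs)
  out <- data.table::copy(dmrs)
  n <- nrow(out)
  if (n == 0L) {
    out[, `:=`(category = character(0), nearest_feature_id = character(0),
               distance = integer(0))]
    return(out[])
  }
  genes <- data.table::as.data.table(genes)
  dgr <- as_gr(out)
  dist <- rep(NA_integer_, n)
  nid <- rep(NA_character_, n)
  nd <- NULL
  if (nrow(genes)) {
    ggr <- as_gr(genes)
    nd <- GenomicRanges::distanceToNearest(dgr, ggr, select = "all")
  }
  if (length(nd)) {
    h <- data.table::data.table(q = S4Vectors::queryHits(nd),
                                s = S4Vectors::subjectHits(nd),
                                d = S4Vectors::mcols(nd)$distance)
    h[, fid := genes$feature_id[s]]
    data.table::setorder(h, q, d, fid)
    h <- h[!duplicated(q)]
    dist[h$q] <- as.integer(h$d)
    nid[h$q] <- h$fid
  }
  in_gene <- if (nrow(genes)) IRanges::overlapsAny(dgr, as_gr(genes))
  else rep(FALSE, n)
  in_flank <- !is.na(dist) & dist > 0L & dist <= flank_bp
  in_te <- if (!is.null(tes) && nrow(tes))
    IRanges::overlapsAny(dgr, as_gr(tes)) else rep(FALSE, n)
  category <- ifelse(in_gene, "genic",
                     ifelse(in_flank, "promoter/flank",
                            ifelse(in_te, "TE", "intergenic")))
  out[, `:=`(category = category, nearest_feature_id = nid,
             distance = dist)]
  out[]
}

#' Draw random eligible control windows and feature-assign them
#'
#' Mirrors the randomized control used for the genomic-feature breakdown of
#' sensitive DMRs: draws `n` windows uniformly (with replacement when
#' fewer eligible windows exist) from the windows eligible in both samples
#' and assigns each to a feature category.
#'
#' @param eligible_windows window summaries restricted to eligible windows
#'   (e.g. the merge of both samples' [summarize_windows()] output after
#'   the `min_sites`/`min_mean_cov` filter).
#' @param n number of control windows (default 10000).
#' @inheritParams assign_feature
#' @return feature-assigned control windows.
#' @export
random_control_windows <- function(eligible_windows, genes, tes = NULL,
                                   n = 10000L, flank_bp = 2000L) {
  ew <- data.table::as.data.table(eligible_windows)
  if (nrow(ew) == 0L) stop("no eligible windows to sample from")
  idx <- sample.int(nrow(ew), n, replace = nrow(ew) < n)
  assign_feature(ew[idx, .(chrom, start, end)], genes, tes, flank_bp)
}

#' Link DMRs to nearby expressed genes
#'
#' A gene is linked when some DMR overlaps it or lies within `max_dist` bp
#' of it; only genes in `expressed_ids` are retained. This is the "within
#' 2 kb" rule used to connect demethylase-sensitive DMRs to genes.
#'
#' @param dmrs DMR data.table.
#' @param genes gene feature table.
#' @param expressed_ids character vector of expressed gene ids.
#' @param max_dist maximum bp gap (default 2000).
#' @return named list: gene id -> data.table of linked DMRs.
#' @export
link_dmrs_to_genes <- function(dmrs, genes, expressed_ids,
                               max_dist = 2000L) {
  dmrs <- data.table::as.data.table(dmrs)
  genes <- data.table::as.data.table(genes)
  genes <- genes[genes$feature_id %in% expressed_ids]
  if (nrow(dmrs) == 0L || nrow(genes) == 0L)
    return(stats::setNames(list(), character(0)))
  dgr <- as_gr(dmrs)
  ggr <- as_gr(genes)
  hits <- GenomicRanges::findOverlaps(ggr, dgr, maxgap = as.integer(max_dist))
  if (!length(hits)) return(stats::setNames(list(), character(0)))
  h <- data.table::data.table(g = S4Vectors::queryHits(hits),
                              d = S4Vectors::subjectHits(hits))
  split_d <- split(h$d, genes$feature_id[h$g])
  lapply(split_d, function(i) dmrs[sort(unique(i))])
}
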