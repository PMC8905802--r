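#' Filter genes with informative allelic coverage in a reciprocal pair
#'
#' A gene is informative when, in each of the two reciprocal crosses, at
#' least one allele has `min_reads` reads. The published rule ("at least 10
#' reads for one allele in both reciprocal crosses") is ambiguous; the
#' default `mode = "one_allele"` requires the better-covered allele to
#' reach `min_reads`, `"total"` requires maternal + paternal >= min_reads,
#' and `"both"` requires each allele to reach it.
#'
#' @param records allelic count table: `gene_id`, `cross_id`,
#'   `maternal_reads`, `paternal_reads`.
#' @param cross_pair the two reciprocal cross ids.
#' @param min_reads threshold (default 10).
#' @param mode `"one_allele"` (default), `"total"` or `"both"`.
#' @return character vector of informative gene ids.
#' @export
filter_informative <- function(records, cross_pair, min_reads = 10L,
                               mode = c("one_allele", "total", "both")) {
  mode <- match.arg(mode)
  rec <- data.table::as.data.table(records)
  rec <- rec[rec$cross_id %in% cross_pair]
  if (length(setdiff(cross_pair, unique(rec$cross_id))))
    stop("missing cross: ",
         paste(setdiff(cross_pair, unique(rec$cross_id)), collapse = ", "))
  rec[, keep := switch(mode,
    one_allele = pmax(maternal_reads, paternal_reads) >= min_reads,
    total = maternal_reads + paternal_reads >= min_reads,
    both = pmin(maternal_reads, paternal_reads) >= min_reads)]
  ok <- rec[, .(pass = all(keep) && .N == length(cross_pair)), by = gene_id]
  ok$gene_id[ok$pass]
}

#' Maternal read fraction of an allelic count record
#'
#' @param maternal_reads,paternal_reads non-negative counts.
#' @return maternal / (maternal + paternal); `NA` (with a warning) when the
#'   total is zero.
#' @export
maternal_fraction <- function(maternal_reads, paternal_reads) {
  tot <- maternal_reads + paternal_reads
  if (any(tot == 0, na.rm = TRUE))
    warning(sum(tot == 0), " record(s) with zero total reads: fraction NA")
  ifelse(tot > 0, maternal_reads / tot, NA_real_)
}

#' Classify imprinted genes from reciprocal wild-type crosses
#'
#' In triploid endosperm (two maternal : one paternal genome) the null
#' maternal read fraction is 2/3. A gene is a MEG when its maternal
#' fraction is at least `threshold` in BOTH reciprocal crosses, a PEG when
#' the paternal fraction is, and `none` otherwise.
#'
#' @param records allelic count table (see [filter_informative()]).
#' @param cross_pair the two reciprocal wild-type cross ids.
#' @param informative gene ids passing [filter_informative()]; computed
#'   with defaults when `NULL`.
#' @param threshold allelic-bias threshold (default 0.80).
#' @return data.table: `gene_id`, `status` (`MEG`/`PEG`/`none`),
#'   `frac_<cross>` columns, `passed_informative`.
#' @export
classify_imprinting <- function(records, cross_pair, informative = NULL,
                                threshold = 0.80) {
  rec <- data.table::as.data.table(records)
  rec <- rec[rec$cross_id %in% cross_pair]
  if (is.null(informative))
    informative <- filter_informative(rec, cross_pair)
  frac <- suppressWarnings(
    rec[, .(gene_id, cross_id,
            frac = maternal_fraction(maternal_reads, paternal_reads))])
  wide <- data.table::dcast(frac, gene_id ~ cross_id, value.var = "frac")
  data.table::setnames(wide, cross_pair, paste0("frac_", cross_pair))
  f1 <- wide[[paste0("frac_", cross_pair[1])]]
  f2 <- wide[[paste0("frac_", cross_pair[2])]]
  inf <- wide$gene_id %in% informative
  meg <- inf & !is.na(f1) & !is.na(f2) & f1 >= threshold & f2 >= threshold
  peg <- inf & !is.na(f1) & !is.na(f2) &
    (1 - f1) >= threshold & (1 - f2) >= threshold
  wide[, `:=`(status = ifelse(meg, "MEG", ifelse(peg, "PEG", "none")),
              passed_informative = inf)]
  data.table::setorder(wide, gene_id)
  wide[]
}

#' Remove candidate MEGs explained by maternal-tissue contamination
#'
#' Apparent maternal bias can come from contaminating maternal seed tissue
#' rather than imprinting. A MEG is removed when its expression in whole
#' seed is at least `fold` times its endosperm expression (an endosperm
#' value of zero with positive seed expression counts as removed). Genes
#' without expression values are retained with a warning.
#'
#' @param calls output of [classify_imprinting()].
#' @param seed_expr,endosperm_expr named numeric vectors (gene id ->
#'   expression).
#' @param fold removal fold (default 3).
#' @return `calls` with MEGs failing the filter set to `none` and a
#'   `removed_by_contamination` flag.
#' @export
contamination_filter <- function(calls, seed_expr, endosperm_expr,
                                 fold = 3) {
  out <- data.table::copy(data.table::as.data.table(calls))
  out[, removed_by_contamination := FALSE]
  megs <- which(out$status == "MEG")
  if (!length(megs)) return(out[])
  ids <- out$gene_id[megs]
  se <- seed_expr[ids]
  ee <- endosperm_expr[ids]
  known <- !is.na(se) & !is.na(ee)
  if (any(!known))
    warning(sum(!known), " MEG(s) without expression values retained")
  contaminated <- known & ((ee > 0 & se >= fold * ee) | (ee == 0 & se > 0))
  out$removed_by_contamination[megs[contaminated]] <- TRUE
  out$status[megs[contaminated]] <- "none"
  out[]
}

#' Loss of imprinting in the mutant-maternal cross
#'
#' For each gene imprinted in the wild-type classification, compares the
#' allelic fraction in the wild-type-maternal cross with the
#' mutant-maternal cross. A MEG loses imprinting when its maternal
#' fraction in the mutant cross drops below `threshold`; a PEG when its
#' paternal fraction does.
#'
#' @param records allelic count table containing both crosses.
#' @param calls output of [classify_imprinting()] (only MEG/PEG rows are
#'   used).
#' @param wt_cross,mut_cross cross ids of the wild-type-maternal and
#'   mutant-maternal cross.
#' @param threshold allelic-bias threshold (default 0.80).
#' @return data.table: `gene_id`, `status`, `fraction_wt`, `fraction_mut`,
#'   `lost_imprinting`.
#' @export
imprinting_shift <- function(records, calls, wt_cross, mut_cross,
                             threshold = 0.80) {
  rec <- data.table::as.data.table(records)
  imp <- data.table::as.data.table(calls)
  imp <- imp[imp$status %in% c("MEG", "PEG")]
  get_frac <- function(cr) {
    r <- rec[rec$cross_id == cr]
    suppressWarnings(stats::setNames(
      maternal_fraction(r$maternal_reads, r$paternal_reads), r$gene_id))
  }
  fw <- get_frac(wt_cross)
  fm <- get_frac(mut_cross)
  out <- imp[, .(gene_id, status)]
  out[, `:=`(fraction_wt = unname(fw[gene_id]),
             fraction_mut = unname(fm[gene_id]))]
  if (anyNA(out$fraction_mut) || anyNA(out$fraction_wt))
    warning("zero-total or missing records for some imprinted genes")
  out[, lost_imprinting := ifelse(status == "MEG",
                                  fraction_mut < threshold,
                                  (1 - fraction_mut) < threshold)]
  out[]
}

#' Read allelic count and cross metadata tables
#'
#' Allelic counts: TSV `gene_id`, `cross_id`, `maternal_reads`,
#' `paternal_reads`. Cross metadata: TSV `cross_id`, `female_parent`,
#' `male_parent`, `genotype_class` (`WT`/`mutant`). Maternal identity is
#' always taken from the metadata, never from column order.
#'
#' @param path TSV file.
#' @return data.table.
#' @export
read_allelic_counts <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("gene_id", "cross_id", "maternal_reads", "paternal_reads")
  stopifnot(all(need %in% names(dt)))
  stopifnot(all(dt$maternal_reads >= 0), all(dt$paternal_reads >= 0))
  dt[]
}

#' @rdname read_allelic_counts
#' @export
read_cross_metadata <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("cross_id", "female_parent", "male_parent", "genotype_class")
  stopifnot(all(need %in% names(dt)))
  dt[]
}
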