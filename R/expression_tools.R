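#' Classify endosperm specificity of gene expression
#'
#' For each gene, the expression in each tissue is the maximum over its
#' developmental stages; the endosperm ratio is endosperm expression
#' divided by the summed expression over all tissues. Classes follow the
#' published thresholds: `exclusive` at ratio >= 0.90, `preferential` at
#' ratio > 0.50, `non_specific` at ratio < 0.30, `intermediate` otherwise.
#' Genes with zero total expression get class `NA` and are flagged.
#'
#' @param expr numeric matrix or data.frame, genes x samples, with
#'   rownames as gene ids.
#' @param tissue character vector, one tissue label per column (must
#'   include `endosperm_tissue`).
#' @param endosperm_tissue label of the endosperm columns.
#' @return data.table with `gene_id`, `endosperm_ratio`, `class`.
#' @export
tissue_specificity <- function(expr, tissue,
                               endosperm_tissue = "endosperm") {
  expr <- as.matrix(expr)
  if (length(tissue) != ncol(expr))
    stop("tissue must label every column of expr")
  if (!endosperm_tissue %in% tissue)
    stop("no '", endosperm_tissue, "' columns in expr")
  if (any(expr < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  # per-tissue representative = max over stages
  tis <- unique(tissue)
  per_tissue <- sapply(tis, function(t)
    apply(expr[, tissue == t, drop = FALSE], 1L, max, na.rm = TRUE))
  per_tissue <- matrix(per_tissue, nrow = nrow(expr),
                       dimnames = list(rownames(expr), tis))
  total <- rowSums(per_tissue)
  r <- per_tissue[, endosperm_tissue] / total
  cls <- ifelse(r >= 0.90, "exclusive",
                ifelse(r > 0.50, "preferential",
                       ifelse(r < 0.30, "non_specific", "intermediate")))
  cls[total == 0] <- NA_character_
  r[total == 0] <- NA_real_
  if (any(total == 0))
    warning(sum(total == 0), " gene(s) with zero total expression flagged NA")
  data.table::data.table(gene_id = rownames(expr), endosperm_ratio = r,
                         class = cls)
}

#' Differential expression and downregulation along the specificity gradient
#'
#' Bins genes by their endosperm-expression ratio and reports, per bin, the
#' fraction of genes that are differentially expressed and, among DEGs, the
#' fraction downregulated.
#'
#' @param specificity output of [tissue_specificity()] (or any table with
#'   `gene_id` and `endosperm_ratio`).
#' @param degs DEG table with `gene_id`, `log2fc`, `padj`, `direction`.
#' @param gene_ids genes to consider (default: all in `specificity`).
#' @param breaks bin edges partitioning `[0, 1]` (default deciles).
#' @return data.table per bin: `bin`, `n`, `n_deg`, `pct_deg`, `n_down`,
#'   `pct_down` (`NA` when the bin or its DEG set is empty).
#' @export
specificity_gradient <- function(specificity, degs,
                                 gene_ids = specificity$gene_id,
                                 breaks = seq(0, 1, by = 0.1)) {
  stopifnot(breaks[1] == 0, breaks[length(breaks)] == 1)
  s <- data.table::as.data.table(specificity)
  s <- s[s$gene_id %in% gene_ids & !is.na(s$endosperm_ratio)]
  degs <- data.table::as.data.table(degs)
  s[, `:=`(is_deg = gene_id %in% degs$gene_id,
           is_down = gene_id %in% degs$gene_id[degs$direction == "down"])]
  s[, bin := cut(endosperm_ratio, breaks = breaks, include.lowest = TRUE)]
  out <- s[, .(n = .N, n_deg = sum(is_deg), n_down = sum(is_down)),
           by = bin]
  all_bins <- levels(s$bin)
  out <- merge(data.table::data.table(bin = factor(all_bins,
                                                   levels = all_bins)),
               out, by = "bin", all.x = TRUE)
  out[is.na(n), `:=`(n = 0L, n_deg = 0L, n_down = 0L)]
  out[, `:=`(pct_deg = ifelse(n > 0, 100 * n_deg / n, NA_real_),
             pct_down = ifelse(n_deg > 0, 100 * n_down / n_deg, NA_real_))]
  out[]
}

#' Two-sample proportion comparison
#'
#' The chi-square two-sample test of equal proportions with Yates
#' continuity correction (the default of the classical `prop.test`), used
#' for all count-proportion comparisons in the pipeline. An uncorrected
#' version is available via `correct = FALSE`.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @param correct apply the continuity correction (default `TRUE`).
#' @return list with `estimate1`, `estimate2`, `statistic`,
#'   `p_two_sided`.
#' @export
two_proportion_test <- function(k1, n1, k2, n2, correct = TRUE) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  ht <- stats::prop.test(c(k1, k2), c(n1, n2), correct = correct)
  list(estimate1 = k1 / n1, estimate2 = k2 / n2,
       statistic = unname(ht$statistic), p_two_sided = ht$p.value)
}

#' Cross-tabulate DMR-linked genes against differential expression
#'
#' Given the gene->DMR link map and a DEG table, counts linked genes that
#' are differentially expressed and their direction, and compares both the
#' DEG fraction and the downregulated fraction against supplied
#' genome-wide baselines with [two_proportion_test()].
#'
#' @param degs DEG table with `gene_id` and `direction`.
#' @param link_map named list from [link_dmrs_to_genes()].
#' @param baseline_deg optional `c(k, n)`: genome-wide DEGs over expressed
#'   genes.
#' @param baseline_down optional `c(k, n)`: genome-wide downregulated DEGs
#'   over all DEGs.
#' @return list with `n_linked`, `linked_deg`, `linked_down`, `linked_up`,
#'   and (when baselines given) `test_deg`, `test_down`.
#' @export
deg_dmr_direction_summary <- function(degs, link_map, baseline_deg = NULL,
                                      baseline_down = NULL) {
  degs <- data.table::as.data.table(degs)
  linked <- names(link_map)
  is_deg <- linked %in% degs$gene_id
  down_ids <- degs$gene_id[degs$direction == "down"]
  up_ids <- degs$gene_id[degs$direction == "up"]
  out <- list(n_linked = length(linked),
              linked_deg = sum(is_deg),
              linked_down = sum(linked %in% down_ids),
              linked_up = sum(linked %in% up_ids))
  if (!is.null(baseline_deg) && out$n_linked > 0)
    out$test_deg <- two_proportion_test(out$linked_deg, out$n_linked,
                                        baseline_deg[1], baseline_deg[2])
  if (!is.null(baseline_down) && out$linked_deg > 0)
    out$test_down <- two_proportion_test(out$linked_down, out$linked_deg,
                                         baseline_down[1], baseline_down[2])
  out
}

#' Read a DEG table
#'
#' TSV with columns `gene_id`, `log2fc`, `padj`; `direction` is derived
#' from the sign of `log2fc`.
#'
#' @param path TSV file.
#' @return data.table with `gene_id`, `log2fc`, `padj`, `direction`.
#' @export
read_degs <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(dt)))
  dt[, direction := ifelse(log2fc >= 0, "up", "down")]
  dt[]
}
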