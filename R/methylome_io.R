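#' Construct a methylome table from per-cytosine calls
#'
#' A methylome table is the atomic container of the package: one row per
#' cytosine with its methylated and total read counts. It is a
#' `data.table` with columns `chrom`, `pos` (1-based), `strand` (`+`/`-`),
#' `context` (`CG`, `CHG`, `CHH`), `meth_reads` and `total_reads`, sorted
#' by `chrom` then `pos`, with no duplicate `(chrom, pos, strand)` key.
#' Symmetric CpG sites on opposite strands are kept as separate records.
#'
#' @param calls data.frame with the six columns above (extra columns are
#'   dropped).
#' @param sample_id optional sample label stored as an attribute.
#' @param control_chrom optional name of an unmethylated control sequence
#'   (typically the chloroplast) used by [conversion_rate()].
#' @param validate if `TRUE` (default), enforce invariants; rows with
#'   invalid counts/context/position are rejected with a reported count.
#' @return a `methylome` object (a keyed `data.table`).
#' @examples
#' mt <- methylome(data.frame(
#'   chrom = "chr1", pos = c(10L, 12L), strand = "+",
#'   context = "CG", meth_reads = c(5L, 0L), total_reads = c(10L, 10L)))
#' weighted_level(mt)
#' @export
methylome <- function(calls, sample_id = NULL, control_chrom = NULL,
                      validate = TRUE) {
  cols <- c("chrom", "pos", "strand", "context", "meth_reads", "total_reads")
  missing <- setdiff(cols, names(calls))
  if (length(missing))
    stop("missing methylome columns: ", paste(missing, collapse = ", "))
  dt <- data.table::as.data.table(calls)[, cols, with = FALSE]
  dt[, `:=`(chrom = as.character(chrom), pos = as.integer(pos),
            strand = as.character(strand), context = as.character(context),
            meth_reads = as.integer(meth_reads),
            total_reads = as.integer(total_reads))]
  if (validate) {
    bad <- dt[, !(pos >= 1L & strand %in% c("+", "-") &
                    context %in% c("CG", "CHG", "CHH") &
                    meth_reads >= 0L & total_reads >= 0L &
                    meth_reads <= total_reads)]
    bad[is.na(bad)] <- TRUE
    if (any(bad)) {
      warning(sum(bad), " row(s) failed methylome invariants and were dropped")
      dt <- dt[!bad]
    }
    if (anyDuplicated(dt, by = c("chrom", "pos", "strand")))
      stop("duplicate (chrom, pos, strand) keys in methylome table")
  }
  data.table::setkeyv(dt, c("chrom", "pos"))
  data.table::setattr(dt, "sample_id", sample_id)
  data.table::setattr(dt, "control_chrom", control_chrom)
  data.table::setattr(dt, "class", c("methylome", class(dt)))
  dt[]
}

#' Read a per-cytosine methylation table
#'
#' Two dialects are supported. `canonical` is this package's six-column TSV
#' (`chrom`, `pos`, `strand`, `context`, `meth_reads`, `total_reads`, with
#' or without a header line). `methratio` is the BSMAP methratio output
#' (columns `chr`, `pos`, `strand`, `context`, `ratio`, `eff_CT_count`,
#' `C_count`, `CT_count`, ...); counts are taken from `C_count`/`CT_count`
#' and the pre-computed ratio column is ignored, so levels are always
#' recomputed from raw counts. methratio context strings longer than three
#' classes (e.g. the 5-mer column some versions emit) are collapsed onto
#' CG/CHG/CHH by their central trinucleotide.
#'
#' @param path TSV file path.
#' @param dialect `"canonical"` or `"methratio"`.
#' @inheritParams methylome
#' @return a [methylome()] object.
#' @export
read_methylome <- function(path, dialect = c("canonical", "methratio"),
                           sample_id = NULL, control_chrom = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) {
    warning("empty methylome file: ", path)
    return(methylome(data.frame(chrom = character(), pos = integer(),
                                strand = character(), context = character(),
                                meth_reads = integer(), total_reads = integer()),
                     sample_id = sample_id, control_chrom = control_chrom))
  }
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = "auto"),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  if (dialect == "canonical") {
    if (ncol(dt) < 6L)
      stop("canonical dialect needs 6 columns, got ", ncol(dt), " in ", path)
    dt <- dt[, 1:6]
    data.table::setnames(dt, c("chrom", "pos", "strand", "context",
                               "meth_reads", "total_reads"))
  } else {
    # methratio: chr pos strand context ratio eff_CT_count C_count CT_count ...
    if (ncol(dt) < 8L)
      stop("methratio dialect needs >= 8 columns, got ", ncol(dt), " in ", path)
    dt <- dt[, c(1:4, 7:8)]
    data.table::setnames(dt, c("chrom", "pos", "strand", "context",
                               "meth_reads", "total_reads"))
    dt[, context := collapse_context(context)]
  }
  methylome(dt, sample_id = sample_id, control_chrom = control_chrom)
}

# map methratio 5-mer context strings onto CG/CHG/CHH by central trinucleotide
collapse_context <- function(x) {
  x <- as.character(x)
  tri <- ifelse(nchar(x) == 5L, substr(x, 3L, 5L), x)
  out <- ifelse(tri %in% c("CG", "CHG", "CHH"), tri,
                ifelse(substr(tri, 2L, 2L) == "G", "CG",
                       ifelse(substr(tri, 3L, 3L) == "G", "CHG", "CHH")))
  out
}

#' Write a methylome table in the canonical TSV dialect
#'
#' @param x a [methylome()] object.
#' @param path output file.
#' @param header write a header line (default `TRUE`).
#' @return invisibly, `path`.
#' @export
write_methylome <- function(x, path, header = TRUE) {
  data.table::fwrite(data.table::as.data.table(x), path, sep = "\t",
                     col.names = header)
  invisible(path)
}

#' Weighted methylation level
#'
#' The count-weighted level of a set of cytosines: total methylated reads
#' divided by total covering reads, i.e. each cytosine contributes in
#' proportion to its coverage rather than as an average of per-site ratios.
#'
#' @param x a [methylome()] object or any data.frame with `meth_reads` and
#'   `total_reads` columns.
#' @return a proportion in `[0, 1]`.
#' @export
weighted_level <- function(x) {
  tot <- sum(as.numeric(x$total_reads))
  if (nrow(x) == 0L || tot == 0)
    stop("weighted_level undefined: no covered cytosines")
  sum(as.numeric(x$meth_reads)) / tot
}

#' Bisulfite conversion rate from an unmethylated control chromosome
#'
#' Reads mapped to a genome known to be unmethylated (the chloroplast in
#' plant WGBS) estimate the conversion efficiency: the rate is one minus
#' the weighted methylation level over all contexts on that chromosome.
#'
#' @param x a [methylome()] object.
#' @param control_chrom control sequence name; defaults to the table's
#'   `control_chrom` attribute.
#' @return conversion rate in `[0, 1]`.
#' @export
conversion_rate <- function(x, control_chrom = attr(x, "control_chrom")) {
  if (is.null(control_chrom)) stop("no control_chrom given")
  ctl <- x[x$chrom == control_chrom, ]
  if (nrow(ctl) == 0L)
    stop("control chromosome '", control_chrom, "' absent from table")
  1 - weighted_level(ctl)
}

#' Read gene or transposon annotations as a feature table
#'
#' Genes are read from GFF3 (rows with type `gene`); transposons from BED6,
#' with the TE superfamily taken from the BED name field (`id:family` or
#' just a family string). Output is a data.table with columns `chrom`,
#' `start`, `end` (0-based half-open), `strand`, `feature_id`, `kind`,
#' `family`.
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"bed"`.
#' @param kind feature kind label, e.g. `"gene"` or `"TE"`.
#' @return a feature data.table.
#' @export
read_features <- function(path, format = c("gff3", "bed"), kind = "gene") {
  format <- match.arg(format)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) == "gene"]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
      as.character(gr$Name)
    out <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      feature_id = ids, kind = kind, family = NA_character_)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    nm <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0(kind, "_", seq_along(gr))
    fam <- ifelse(grepl(":", nm), sub("^[^:]*:", "", nm), NA_character_)
    id <- sub(":.*$", "", nm)
    out <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      feature_id = id, kind = kind, family = fam)
  }
  if (anyDuplicated(out$feature_id))
    stop("duplicate feature_id in ", path)
  stopifnot(all(out$start < out$end))
  out$strand[!out$strand %in% c("+", "-")] <- "."
  out[]
}

# internal: features/intervals (0-based half-open) -> GRanges (1-based closed)
as_gr <- function(df, use_strand = FALSE) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (use_strand && !is.null(df$strand)) {
      s <- df$strand; s[!s %in% c("+", "-")] <- "*"; s
    } else "*")
}
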