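# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation design for synthetic pipeline inputs
#'
#' One object states the whole synthetic world: genome, cytosine densities,
#' coverage, per-context baseline methylation, planted DMRs, planted
#' imprinted genes, planted endosperm-specific genes and DEGs, and peak
#' geometry. All generators are pure functions of the design (including its
#' seed): the same design replays byte-identically.
#'
#' Defaults emulate a maize-like WGBS contrast at desk scale: one 1-Mb
#' chromosome plus a 100-kb unmethylated chloroplast control, CHH the most
#' abundant context, mean depth 30, baselines CG 0.80 / CHG 0.60 /
#' CHH 0.05, Poisson coverage, binomially sampled methylated reads. The
#' default planted-DMR set is 50 hypermethylated plus 50 hypomethylated
#' single-window CG DMRs with levels 0.05 vs 0.95 and 10 sites each; the
#' default imprinting panel is 30 MEGs (maternal fraction 0.97), 30 PEGs
#' (0.03) and 940 null genes at the triploid 2:1 baseline (2/3), depth 50.
#'
#' @param chrom_sizes named integer vector of chromosome sizes.
#' @param control_chrom name/size of the unmethylated control chromosome
#'   (`NULL` to omit).
#' @param site_density named per-context expected cytosines per 100 bp.
#' @param depth mean sequencing depth (Poisson).
#' @param baseline named per-context methylation level used outside planted
#'   DMRs (both samples).
#' @param planted_dmrs data.frame `chrom`, `start`, `end`, `context`,
#'   `level_a`, `level_b`; `NULL` for the default panel,
#'   a 0-row data.frame for a null design.
#' @param dmr_sites context cytosines planted inside each DMR window.
#' @param n_genes,n_tes annotation sizes for [simulate_features()].
#' @param imprinting list: `n_null`, `n_meg`, `n_peg`, `meg_f`, `peg_f`,
#'   `null_f`, `depth`, `n_shift`, `shift_f`.
#' @param expression list: `n_genes`, `n_specific`, `n_deg`,
#'   `frac_deg_down`, `tissues`, `n_stages`.
#' @param peaks list: `n`, `len`, `spacing`, `jitter` (fraction of peak
#'   length the second replicate is shifted; recycled per peak).
#' @param seed integer seed.
#' @return a `simulation_design` list.
#' @export
simulation_design <- function(chrom_sizes = c(chr1 = 1000000L),
                              control_chrom = c(chrC = 100000L),
                              site_density = c(CG = 8, CHG = 8, CHH = 24),
                              depth = 30,
                              baseline = c(CG = 0.80, CHG = 0.60, CHH = 0.05),
                              planted_dmrs = NULL,
                              dmr_sites = 10L,
                              n_genes = 60L,
                              n_tes = 40L,
                              imprinting = list(n_null = 940L, n_meg = 30L,
                                                n_peg = 30L, meg_f = 0.97,
                                                peg_f = 0.03, null_f = 2 / 3,
                                                depth = 50, n_shift = 10L,
                                                shift_f = 0.5),
                              expression = list(n_genes = 1000L,
                                                n_specific = 50L,
                                                n_deg = 200L,
                                                frac_deg_down = 0.6,
                                                tissues = c("endosperm",
                                                            "embryo", "seed",
                                                            "leaf", "root"),
                                                n_stages = 3L),
                              peaks = list(n = 100L, len = 300L,
                                           spacing = 3000L, jitter = 0.02),
                              seed = 1L) {
  if (is.null(planted_dmrs))
    planted_dmrs <- default_planted_dmrs(chrom_sizes, n_hyper = 50L,
                                         n_hypo = 50L)
  planted_dmrs <- data.table::as.data.table(planted_dmrs)
  if (nrow(planted_dmrs)) {
    stopifnot(all(planted_dmrs$chrom %in% names(chrom_sizes)),
              all(planted_dmrs$end <= chrom_sizes[planted_dmrs$chrom]),
              all(planted_dmrs$level_a >= 0 & planted_dmrs$level_a <= 1),
              all(planted_dmrs$level_b >= 0 & planted_dmrs$level_b <= 1))
  }
  structure(list(chrom_sizes = chrom_sizes, control_chrom = control_chrom,
                 site_density = site_density, depth = depth,
                 baseline = baseline, planted_dmrs = planted_dmrs,
                 dmr_sites = as.integer(dmr_sites), n_genes = n_genes,
                 n_tes = n_tes, imprinting = imprinting,
                 expression = expression, peaks = peaks,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

#' Evenly spaced planted single-window DMRs
#'
#' Convenience constructor for a planted-truth table: `n_hyper` windows
#' where sample B is high (`level_a` -> `level_b` = 0.05 -> 0.95) followed
#' by `n_hypo` windows with the levels swapped, every `spacing`-th window
#' on the first chromosome so planted regions never merge.
#'
#' @param chrom_sizes named chromosome sizes; the first is used.
#' @param n_hyper,n_hypo planted counts per direction.
#' @param level_low,level_high the two methylation levels.
#' @param window_size window width in bp.
#' @param spacing gap between planted windows, in windows.
#' @return a planted-DMR data.table for [simulation_design()].
#' @export
default_planted_dmrs <- function(chrom_sizes, n_hyper, n_hypo,
                                 level_low = 0.05, level_high = 0.95,
                                 window_size = 100L, spacing = 5L) {
  n <- n_hyper + n_hypo
  chrom <- names(chrom_sizes)[1L]
  n_windows <- chrom_sizes[[1L]] %/% window_size
  stopifnot(n * spacing <= n_windows)
  win <- seq(spacing, by = spacing, length.out = n)
  data.table::data.table(
    chrom = chrom,
    start = as.integer((win - 1L) * window_size),
    end = as.integer(win * window_size),
    context = "CG",
    level_a = c(rep(level_low, n_hyper), rep(level_high, n_hypo)),
    level_b = c(rep(level_high, n_hyper), rep(level_low, n_hypo)))
}

#' Simulate a pair of methylomes with planted DMRs
#'
#' Cytosine positions are placed uniformly per context density (background
#' sites are excluded from planted intervals, which carry exactly
#' `dmr_sites` context cytosines each); per cytosine and sample, depth is
#' Poisson(`depth`) and methylated reads are Binomial(depth, level), with
#' level taken from the context baseline outside planted DMRs and from
#' `level_a`/`level_b` inside. The control chromosome is fully unmethylated
#' in both samples.
#'
#' @param design a [simulation_design()].
#' @return list with methylomes `a`, `b` and `truth` (the planted DMR table
#'   with a `direction` column, hyper = higher in `b`).
#' @export
simulate_methylome_pair <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  with_seed(design$seed, {
    sizes <- design$chrom_sizes
    if (!is.null(design$control_chrom))
      sizes <- c(sizes, design$control_chrom)
    planted <- design$planted_dmrs
    rows <- list()
    for (chrom in names(sizes)) {
      size <- sizes[[chrom]]
      is_control <- !is.null(design$control_chrom) &&
        chrom %in% names(design$control_chrom)
      pl <- if (is_control) planted[0L] else planted[planted$chrom == chrom]
      # background cytosines: one joint draw over all contexts so the
      # (chrom, pos) keys are unique; planted intervals are kept clean
      dens <- design$site_density
      n_bg <- round(size / 100 * sum(dens))
      pos <- sort(sample.int(size, min(n_bg, size)))
      if (nrow(pl)) {
        in_planted <- rep(FALSE, length(pos))
        for (i in seq_len(nrow(pl)))
          in_planted <- in_planted | (pos > pl$start[i] & pos <= pl$end[i])
        pos <- pos[!in_planted]
      }
      ctx <- sample(names(dens), length(pos), replace = TRUE,
                    prob = dens / sum(dens))
      base <- if (is_control) rep(0, length(pos)) else
        unname(design$baseline[ctx])
      lev_a <- base
      lev_b <- base
      if (nrow(pl)) {
        for (i in seq_len(nrow(pl))) {
          width <- pl$end[i] - pl$start[i]
          k <- min(design$dmr_sites, width)
          site <- pl$start[i] + sort(sample.int(width, k))
          pos <- c(pos, site)
          ctx <- c(ctx, rep(pl$context[i], k))
          lev_a <- c(lev_a, rep(pl$level_a[i], k))
          lev_b <- c(lev_b, rep(pl$level_b[i], k))
        }
      }
      o <- order(pos)
      pos <- pos[o]; ctx <- ctx[o]; lev_a <- lev_a[o]; lev_b <- lev_b[o]
      n <- length(pos)
      if (!n) next
      strand <- sample(c("+", "-"), n, replace = TRUE)
      da <- stats::rpois(n, design$depth)
      db <- stats::rpois(n, design$depth)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = chrom, pos = as.integer(pos), strand = strand,
        context = ctx,
        meth_a = stats::rbinom(n, da, lev_a), total_a = da,
        meth_b = stats::rbinom(n, db, lev_b), total_b = db)
    }
    all <- data.table::rbindlist(rows)
    ctl <- if (!is.null(design$control_chrom))
      names(design$control_chrom) else NULL
    a <- methylome(all[, .(chrom, pos, strand, context,
                           meth_reads = meth_a, total_reads = total_a)],
                   sample_id = "sample_a", control_chrom = ctl,
                   validate = FALSE)
    b <- methylome(all[, .(chrom, pos, strand, context,
                           meth_reads = meth_b, total_reads = total_b)],
                   sample_id = "sample_b", control_chrom = ctl,
                   validate = FALSE)
    truth <- data.table::copy(design$planted_dmrs)
    if (nrow(truth))
      truth[, direction := ifelse(level_b > level_a, "hyper", "hypo")]
    list(a = a, b = b, truth = truth)
  })
}

#' Simulate gene and transposon annotations
#'
#' Places non-overlapping genes (2-4 kb) and transposons (0.5-2 kb) with
#' random strands on the design's genome; transposons get one of four
#' superfamily labels.
#'
#' @param design a [simulation_design()].
#' @return list with `genes` and `tes` feature tables.
#' @export
simulate_features <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  with_seed(design$seed + 101L, {
    chrom <- names(design$chrom_sizes)[1L]
    size <- design$chrom_sizes[[1L]]
    n <- design$n_genes + design$n_tes
    slot <- size %/% n
    lens_g <- sample(2000:4000, design$n_genes, replace = TRUE)
    lens_t <- sample(500:2000, design$n_tes, replace = TRUE)
    lens <- c(lens_g, lens_t)
    kind <- c(rep("gene", design$n_genes), rep("TE", design$n_tes))
    ord <- sample.int(n)
    lens <- lens[ord]; kind <- kind[ord]
    start <- (seq_len(n) - 1L) * slot +
      sapply(pmax(slot - lens, 1L), function(m) sample.int(m, 1L))
    end <- pmin(start + lens, size)
    fam <- sample(c("Gypsy", "Copia", "hAT", "Mutator"), n, replace = TRUE)
    dt <- data.table::data.table(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      strand = sample(c("+", "-"), n, replace = TRUE),
      kind = kind,
      family = ifelse(kind == "TE", fam, NA_character_))
    dt[, feature_id := paste0(ifelse(kind == "gene", "gene_", "te_"),
                              seq_len(.N)), by = kind]
    data.table::setcolorder(dt, c("chrom", "start", "end", "strand",
                                  "feature_id", "kind", "family"))
    list(genes = dt[dt$kind == "gene"], tes = dt[dt$kind == "TE"])
  })
}

#' Simulate reciprocal-cross allelic counts with planted imprinting
#'
#' Endosperm is triploid (two maternal genomes to one paternal), so null
#' genes draw maternal reads at fraction 2/3. Planted MEGs/PEGs use the
#' design's biased fractions in all crosses with a wild-type female; in the
#' mutant-female cross, the first `n_shift` MEGs shift to `shift_f`
#' (modelling loss of maternal-allele demethylation). Per gene and cross,
#' total reads are Poisson and maternal reads Binomial.
#'
#' @param design a [simulation_design()].
#' @param cross_plan data.frame `cross_id`, `female_parent`, `male_parent`,
#'   `genotype_class` (`WT`/`mutant`) and `mutant_female` (logical).
#'   Default: `BM`, `MB` (wild type), `bM` (mutant female), `Mb` (mutant
#'   male).
#' @return list with `records` (allelic count table), `cross_plan`, and
#'   `truth` (`gene_id`, `status`, `f`, `shifted`).
#' @export
simulate_allelic_counts <- function(design, cross_plan = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  imp <- design$imprinting
  if (is.null(cross_plan))
    cross_plan <- data.table::data.table(
      cross_id = c("BM", "MB", "bM", "Mb"),
      female_parent = c("B73", "Mo17", "b73_mut", "Mo17"),
      male_parent = c("Mo17", "B73", "Mo17", "b73_mut"),
      genotype_class = c("WT", "WT", "mutant", "mutant"),
      mutant_female = c(FALSE, FALSE, TRUE, FALSE))
  cross_plan <- data.table::as.data.table(cross_plan)
  with_seed(design$seed + 202L, {
    n <- imp$n_null + imp$n_meg + imp$n_peg
    status <- c(rep("MEG", imp$n_meg), rep("PEG", imp$n_peg),
                rep("none", imp$n_null))
    f <- c(rep(imp$meg_f, imp$n_meg), rep(imp$peg_f, imp$n_peg),
           rep(imp$null_f, imp$n_null))
    gene_id <- sprintf("gene_%04d", seq_len(n))
    shifted <- rep(FALSE, n)
    shifted[seq_len(min(imp$n_shift, imp$n_meg))] <- TRUE
    truth <- data.table::data.table(gene_id = gene_id, status = status,
                                    f = f, shifted = shifted)
    recs <- lapply(seq_len(nrow(cross_plan)), function(i) {
      fr <- f
      if (isTRUE(cross_plan$mutant_female[i]))
        fr[shifted] <- imp$shift_f
      tot <- stats::rpois(n, imp$depth)
      mat <- stats::rbinom(n, tot, fr)
      data.table::data.table(gene_id = gene_id,
                             cross_id = cross_plan$cross_id[i],
                             maternal_reads = mat,
                             paternal_reads = tot - mat)
    })
    list(records = data.table::rbindlist(recs), cross_plan = cross_plan,
         truth = truth)
  })
}

#' Simulate a tissue expression matrix and a DEG table
#'
#' Expression is log-normal across a tissue x stage panel. Planted
#' endosperm-specific genes receive at least a 90% endosperm share
#' (exclusive class); planted DEGs get a log2 fold change beyond the usual
#' 0.5 cutoff with adjusted p below 0.01, with a stated fraction
#' downregulated.
#'
#' @param design a [simulation_design()].
#' @return list with `expr` (matrix), `tissue` (column labels), `stage`,
#'   `degs` (DEG table) and `truth` (`gene_id`, `specific`, `is_deg`,
#'   `direction`).
#' @export
simulate_expression <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  ex <- design$expression
  with_seed(design$seed + 303L, {
    n <- ex$n_genes
    gene_id <- sprintf("gene_%04d", seq_len(n))
    tissue <- rep(ex$tissues, each = ex$n_stages)
    stage <- rep(paste0("stage", seq_len(ex$n_stages)),
                 times = length(ex$tissues))
    expr <- matrix(stats::rlnorm(n * length(tissue), meanlog = log(10),
                                 sdlog = 1),
                   nrow = n, dimnames = list(gene_id, paste(tissue, stage,
                                                            sep = ".")))
    spec <- seq_len(min(ex$n_specific, n))
    # endosperm >= 90% of the summed per-tissue maxima: boost endosperm,
    # damp the rest
    expr[spec, tissue != "endosperm"] <- stats::rlnorm(
      length(spec) * sum(tissue != "endosperm"), meanlog = log(0.1),
      sdlog = 0.3)
    other_max <- sapply(setdiff(ex$tissues, "endosperm"), function(t)
      apply(expr[spec, tissue == t, drop = FALSE], 1L, max))
    need <- 9 * rowSums(matrix(other_max, nrow = length(spec)))
    endo_cols <- which(tissue == "endosperm")
    expr[spec, endo_cols[1L]] <- pmax(expr[spec, endo_cols[1L]],
                                      need * 1.1)
    deg_idx <- sample.int(n, min(ex$n_deg, n))
    n_down <- round(length(deg_idx) * ex$frac_deg_down)
    dir <- c(rep("down", n_down), rep("up", length(deg_idx) - n_down))
    lfc <- (0.5 + stats::rlnorm(length(deg_idx), log(0.8), 0.5)) *
      ifelse(dir == "down", -1, 1)
    degs <- data.table::data.table(
      gene_id = gene_id[deg_idx], log2fc = lfc,
      padj = stats::runif(length(deg_idx), 0, 0.009), direction = dir)
    truth <- data.table::data.table(
      gene_id = gene_id,
      specific = seq_len(n) %in% spec,
      is_deg = seq_len(n) %in% deg_idx,
      direction = NA_character_)
    truth$direction[deg_idx] <- dir
    list(expr = expr, tissue = tissue, stage = stage, degs = degs,
         truth = truth)
  })
}

#' Simulate replicate peak sets with controlled overlap
#'
#' Base peaks are laid out with fixed spacing; replicate 1 is the base set
#' and replicate 2 is shifted by `round(jitter * len)` bp (alternating
#' sign), so the overlap fraction of the smaller peak is controlled
#' exactly. Truth records which pairs exceed the 0.9 sharing rule.
#'
#' @param design a [simulation_design()].
#' @return list with `rep1`, `rep2` (peak tables) and `truth` (per base
#'   peak: `overlap_frac`, `shared`).
#' @export
simulate_peaks <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  pk <- design$peaks
  with_seed(design$seed + 404L, {
    chrom <- names(design$chrom_sizes)[1L]
    size <- design$chrom_sizes[[1L]]
    n <- pk$n
    stopifnot(n * pk$spacing + pk$len <= size)
    start <- as.integer(seq(0L, by = pk$spacing, length.out = n))
    jit <- rep_len(pk$jitter, n)
    shift <- as.integer(round(jit * pk$len)) *
      rep_len(c(1L, -1L), n)
    rep1 <- data.table::data.table(chrom = chrom, start = start,
                                   end = start + pk$len,
                                   replicate_id = "rep1")
    rep2 <- data.table::data.table(chrom = chrom, start = start + shift,
                                   end = start + shift + pk$len,
                                   replicate_id = "rep2")
    rep2[, `:=`(start = pmax(start, 0L), end = pmin(end, size))]
    ov <- pmax(0L, pmin(rep1$end, rep2$end) - pmax(rep1$start, rep2$start))
    small <- pmin(rep1$end - rep1$start, rep2$end - rep2$start)
    truth <- data.table::data.table(
      chrom = chrom, start = start, end = start + pk$len,
      overlap_frac = ov / small, shared = ov > 0.9 * small)
    list(rep1 = rep1, rep2 = rep2, truth = truth)
  })
}
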