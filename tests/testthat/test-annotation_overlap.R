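iv <- function(start, end, direction = "hyper", chrom = "chr1")
  data.table::data.table(chrom = chrom, start = start, end = end,
                         context = "CG", level_a = 0.1, level_b = 0.9,
                         delta = ifelse(direction == "hyper", 0.8, -0.8),
                         direction = direction, n_windows = 1L)

gene_tab <- function(start, end, strand = "+", id = NULL) {
  n <- length(start)
  data.table::data.table(chrom = "chr1", start = start, end = end,
                         strand = rep_len(strand, n),
                         feature_id = if (is.null(id))
                           sprintf("g%03d", seq_len(n)) else id,
                         kind = "gene", family = NA_character_)
}

test_that("intersect_dmr_sets classifies shared and unique DMRs", {
  x <- iv(0, 100)
  y <- iv(50, 150)
  cmp <- intersect_dmr_sets(x, y)
  expect_equal(unname(cmp$counts["shared_x"]), 1L)
  expect_equal(unname(cmp$counts["shared_y"]), 1L)
  cmp2 <- intersect_dmr_sets(iv(0, 100), iv(100, 200))  # abutting, 0 bp
  expect_equal(unname(cmp2$counts["shared_x"]), 0L)
  # partition: shared + unique = input size
  expect_equal(nrow(cmp$shared_x) + nrow(cmp$unique_x), nrow(x))
})

test_that("shared classification matches the all-pairs brute-force scan", {
  set.seed(13)
  x <- iv(start = sample(0:100000, 500), end = 0)
  x$end <- x$start + sample(50:500, 500, replace = TRUE)
  y <- iv(start = sample(0:100000, 500), end = 0)
  y$end <- y$start + sample(50:500, 500, replace = TRUE)
  cmp <- intersect_dmr_sets(x, y)
  flags <- oracle_shared_flags(x, y)
  expect_equal(nrow(cmp$shared_x), sum(flags))
  expect_equal(sort(cmp$shared_x$start), sort(x$start[flags]))
  # symmetric in the pair existence
  expect_equal(nrow(cmp$shared_y), sum(oracle_shared_flags(y, x)))
})

test_that("sensitive_dmrs returns the mutant-hyper DMRs shared with
           tissue-hypo DMRs and validates directions", {
  mut <- rbind(iv(0, 100), iv(1000, 1100), iv(5000, 5200))
  tis <- rbind(iv(50, 150, "hypo"), iv(5100, 5300, "hypo"))
  sens <- sensitive_dmrs(mut, tis)
  expect_equal(sens$start, c(0L, 5000L))
  expect_error(sensitive_dmrs(rbind(mut, iv(9, 10, "hypo")), tis),
               "hyper")
  expect_equal(nrow(sensitive_dmrs(mut, tis[0])), 0L)
})

test_that("feature categories follow the genic > flank > TE > intergenic
           precedence and are exhaustive", {
  genes <- gene_tab(10000, 14000)
  tes <- data.table::data.table(chrom = "chr1", start = c(11000, 15000),
                                end = c(11500, 15400), strand = "+",
                                feature_id = c("te1", "te2"), kind = "TE",
                                family = "Gypsy")
  dmrs <- rbind(iv(12000, 12100),   # inside gene (and inside flank of none)
                iv(9400, 9500),     # 500 bp upstream, not TE
                iv(11050, 11150),   # in TE but also genic -> genic
                iv(15100, 15200),   # in TE, > 2 kb right of gene end? gap 1100 -> flank
                iv(50000, 50100))   # far away
  got <- assign_feature(dmrs, genes, tes)
  expect_equal(got$category,
               c("genic", "promoter/flank", "genic", "promoter/flank",
                 "intergenic"))
  expect_equal(got$distance[1], 0L)
  expect_equal(got$distance[2], 500L)
  expect_equal(got$nearest_feature_id[1], "g001")
  # TE category only outside gene flanks
  far_te <- assign_feature(iv(15100, 15200), genes[, ][0], tes)
  # no genes at all -> TE wins
  expect_equal(far_te$category, "TE")
  expect_equal(sum(table(got$category)), nrow(dmrs))
})

test_that("nearest distances equal the brute-force oracle on random layouts", {
  set.seed(17)
  genes <- gene_tab(start = sort(sample(seq(0, 400000, by = 4000), 50)),
                    end = 0)
  genes$end <- genes$start + sample(1000:3000, 50, replace = TRUE)
  dmrs <- iv(start = sample(0:400000, 1000, replace = TRUE), end = 0)
  dmrs$end <- dmrs$start + 100L
  got <- assign_feature(dmrs, genes)
  want <- oracle_nearest_distance(dmrs$start, dmrs$end, genes$start,
                                  genes$end)
  expect_equal(got$distance, as.integer(want))
})

test_that("link_dmrs_to_genes applies the 2-kb rule with exact boundaries", {
  genes <- gene_tab(start = c(10000, 50000), end = c(12000, 53000))
  # gaps of 1999, 2000, 2001 bp downstream of gene 1
  dmrs <- rbind(iv(13999, 14099), iv(14000, 14100), iv(14001, 14101))
  links <- link_dmrs_to_genes(dmrs[1], genes, genes$feature_id)
  expect_equal(names(links), "g001")
  links2 <- link_dmrs_to_genes(dmrs[2], genes, genes$feature_id)
  expect_equal(names(links2), "g001")  # exactly 2000 bp: within 2 kb
  links3 <- link_dmrs_to_genes(dmrs[3], genes, genes$feature_id)
  expect_equal(length(links3), 0L)
  # only expressed genes are retained
  over <- iv(50100, 50200)
  expect_equal(length(link_dmrs_to_genes(over, genes,
                                         expressed_ids = "g001")), 0L)

  # random layout equals brute-force distance oracle
  set.seed(23)
  dmr_r <- iv(start = sample(0:200000, 300, replace = TRUE), end = 0)
  dmr_r$end <- dmr_r$start + 100L
  gene_r <- gene_tab(start = sort(sample(seq(0, 200000, by = 2500), 40)),
                     end = 0)
  gene_r$end <- gene_r$start + 1500L
  lk <- link_dmrs_to_genes(dmr_r, gene_r, gene_r$feature_id)
  for (g in seq_len(nrow(gene_r))) {
    d <- oracle_nearest_distance(dmr_r$start, dmr_r$end,
                                 gene_r$start[g], gene_r$end[g])
    linked <- gene_r$feature_id[g] %in% names(lk)
    expect_equal(linked, any(d <= 2000))
    if (linked)
      expect_equal(nrow(lk[[gene_r$feature_id[g]]]), sum(d <= 2000))
  }
})

test_that("random control windows are reproducible under a fixed seed and
           feature-assigned exhaustively", {
  ew <- data.table::data.table(chrom = "chr1",
                               start = seq(0L, 99900L, by = 100L))
  ew$end <- ew$start + 100L
  genes <- gene_tab(start = c(20000, 60000), end = c(24000, 61000))
  set.seed(31)
  c1 <- random_control_windows(ew, genes, n = 500L)
  set.seed(31)
  c2 <- random_control_windows(ew, genes, n = 500L)
  expect_equal(c1, c2)
  expect_equal(nrow(c1), 500L)
  expect_true(all(c1$category %in% c("genic", "promoter/flank", "TE",
                                     "intergenic")))
})
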