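# Feature counting, normalization, filtering, significance calling and the
# 3'UTR producer report.

test_that("count_features honours strand modes and multi-overlap", {
  utr <- tibble::tibble(chrom = "c", start = 50L, end = 200L, strand = "+",
                        name = "utrA")
  read <- mk_reads("c", 100, 26, "+")
  expect_equal(count_features(read, utr, "sense")$count, 1L)
  expect_equal(count_features(read, utr, "antisense")$count, 0L)
  expect_equal(count_features(read, utr, "both")$count, 1L)
  # two overlapping features both get the read
  two <- dplyr::bind_rows(utr, tibble::tibble(chrom = "c", start = 90L,
                                              end = 300L, strand = "+",
                                              name = "utrB"))
  expect_equal(count_features(read, two, "both")$count, c(1L, 1L))
  unstranded <- tibble::tibble(chrom = "c", start = 0L, end = 10L,
                               strand = "*", name = "u")
  expect_error(count_features(read, unstranded, "sense"), "stranded")
})

test_that("counts over a disjoint tiling conserve the read total", {
  set.seed(12)
  feats <- tibble::tibble(chrom = "c", start = seq(0L, 900L, 100L),
                          end = seq(100L, 1000L, 100L), strand = "+",
                          name = paste0("t", 1:10))
  # reads fully inside single tiles
  reads <- mk_reads("c", sample(0:70, 200, TRUE) +
                      100 * sample(0:9, 200, TRUE), 26)
  expect_equal(sum(count_features(reads, feats)$count), 200L)
})

test_that("TE expression splits sense/antisense and excludes 21-nt siRNAs", {
  reads <- dplyr::bind_rows(
    mk_reads("ZAM", 10, 26, "+", space = "te_consensus"),
    mk_reads("ZAM", 40, 26, "-", space = "te_consensus"),
    mk_reads("ZAM", 80, 21, "+", space = "te_consensus"))
  te <- te_expression(reads, c("ZAM", "gypsy"))
  zam <- te[te$te == "ZAM", ]
  expect_equal(zam$sense, 1L)
  expect_equal(zam$antisense, 1L)
  expect_equal(te[te$te == "gypsy", ]$sense, 0L)
  expect_error(te_expression(reads, "gypsy"), "unknown TE")
})

test_that("CPM is count/denominator x 1e6 and ratio-invariant", {
  counts <- tibble::tibble(feature_id = "f", sample_id = c("a", "b"),
                           count = c(50L, 0L))
  x <- cpm(counts, tibble::tibble(sample_id = c("a", "b"),
                                  denominator = c(1e6, 2e6)))
  expect_equal(x$cpm, c(50, 0))
  scaled <- cpm(dplyr::mutate(counts, count = .data$count * 7L),
                tibble::tibble(sample_id = c("a", "b"),
                               denominator = c(7e6, 1.4e7)))
  expect_equal(scaled$cpm, x$cpm, tolerance = 1e-12)
  expect_error(cpm(counts, tibble::tibble(sample_id = c("a", "b"),
                                          denominator = c(0, 1))), "> 0")
})

test_that("RPKM follows the standard formula", {
  counts <- tibble::tibble(feature_id = c("f", "g"), sample_id = "a",
                           count = c(10L, 1L))
  lens <- tibble::tibble(feature_id = c("f", "g"), length = c(2000L, 1000L))
  x <- rpkm(counts, lens, 1e6)
  expect_equal(x$rpkm[x$feature_id == "f"], 5)
  expect_equal(x$rpkm[x$feature_id == "g"], 1)   # count = total/1e6, len 1 kb
  x2 <- rpkm(counts, lens, 2e6)
  expect_equal(x2$rpkm, x$rpkm / 2)
  expect_error(rpkm(counts, lens[1, ], 1e6), "missing length")
})

test_that("miRNA denominators drop the most differential miRNAs", {
  grid <- tidyr::expand_grid(feature_id = paste0("mir", 1:6),
                             sample_id = c("a1", "a2", "b1", "b2"))
  counts <- dplyr::mutate(grid, count = 100L)
  groups <- tibble::tibble(sample_id = c("a1", "a2", "b1", "b2"),
                           condition = c("A", "A", "B", "B"))
  eq <- mirna_denominators(counts, groups)
  expect_true(all(eq$denominator == eq$denominator[1]))
  expect_equal(eq$denominator[1], 400L)   # 6 miRNAs - 2 excluded, 100 each

  # mir1 100-fold higher in group B -> excluded
  spiked <- dplyr::mutate(counts, count = dplyr::if_else(
    .data$feature_id == "mir1" & .data$sample_id %in% c("b1", "b2"),
    10000L, .data$count))
  d <- mirna_denominators(spiked, groups)
  expect_true("mir1" %in% attr(d, "excluded"))

  none <- mirna_denominators(counts, groups, n_exclude = 0L)
  expect_equal(none$denominator[1], 600L)

  one_group <- tibble::tibble(sample_id = c("a1", "a2", "b1", "b2"),
                              condition = "A")
  expect_warning(mirna_denominators(counts, one_group), "variance")
})

test_that("spike-in factors invert spike totals with geometric mean one", {
  eq <- spikein_factors(tibble::tibble(sample_id = c("a", "b"),
                                       spike_id = "s1",
                                       count = c(1000L, 1000L)))
  expect_equal(eq$norm_factor, c(1, 1))
  half <- spikein_factors(tibble::tibble(sample_id = c("a", "b"),
                                         spike_id = "s1",
                                         count = c(1000L, 500L)))
  expect_equal(half$norm_factor[2] / half$norm_factor[1], 2)
  expect_equal(exp(mean(log(half$norm_factor))), 1, tolerance = 1e-12)
  eff <- spikein_factors(tibble::tibble(sample_id = c("a", "b"),
                                        spike_id = "s1",
                                        count = c(1000L, 500L)),
                         tibble::tibble(sample_id = c("a", "b"),
                                        total_mapped = c(1e6, 1e6)))
  expect_equal(eff$effective_lib_size[2] / eff$effective_lib_size[1], 2)
  expect_error(spikein_factors(tibble::tibble(sample_id = "a",
                                              spike_id = "s1", count = 0L)),
               "zero spike")
})

test_that("expression filter keeps features above cutoff in enough samples", {
  # 5 features x 6 samples; denominator 1e6 so CPM == count
  counts <- tidyr::expand_grid(feature_id = paste0("f", 1:5),
                               sample_id = paste0("s", 1:6))
  counts$count <- 0L
  set_count <- function(counts, f, samples, value) {
    dplyr::mutate(counts, count = dplyr::if_else(
      .data$feature_id == f & .data$sample_id %in% samples,
      as.integer(value), .data$count))
  }
  counts <- counts |>
    set_count("f1", paste0("s", 1:6), 100) |>  # passes everywhere
    set_count("f2", paste0("s", 1:3), 100) |>  # passes in exactly 3
    set_count("f3", paste0("s", 1:2), 100) |>  # passes in exactly 2
    set_count("f4", paste0("s", 1:6), 20)      # CPM == cutoff, not >
  kept <- expression_filter(counts, 1e6, cpm_cutoff = 20, min_samples = 3L)
  expect_setequal(unique(kept$feature_id), c("f1", "f2"))
})

test_that("BH q-values match the brute-force step-up on random vectors", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(1.0), 1.0)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(14)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    q <- benjamini_hochberg(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))   # monotone in ranked p
  }
})

test_that("significance calls use inclusive fold-change and FDR thresholds", {
  calls <- call_significant(log2fc = c(1.0, 0.9, -3, -1, 0.5),
                            qvalues = c(0.05, 0.001, 0.2, 0.05, 0.01))
  expect_equal(calls, c("up", "ns", "ns", "down", "ns"))
})

test_that("the binomial stand-in test behaves at the extremes and is symmetric", {
  expect_gt(two_group_test(c(50, 50), c("A", "B"), c(1e6, 1e6)), 0.9)
  expect_lt(two_group_test(c(1000, 0), c("A", "B"), c(1e6, 1e6)), 1e-6)
  p1 <- two_group_test(c(30, 70), c("A", "B"), c(1e6, 1e6))
  p2 <- two_group_test(c(30, 70), c("B", "A"), c(1e6, 1e6))
  expect_equal(p1, p2)
  expect_equal(two_group_test(c(0, 0), c("A", "B"), c(1e6, 1e6)), 1)
})

test_that("3'UTR producer classes follow strand and min_count rules", {
  ann <- tiny_ann()   # gA: + strand, utr3 [7000,7400); gB: - strand [9000,9400)
  reads <- dplyr::bind_rows(
    mk_reads("chr1", 7100, 26, "-", read_id = "anti1"),   # antisense for gA
    mk_reads("chr1", 9100, 26, "-", read_id = "sense_gB"),
    mk_reads("chr1", 9150, 26, "+", read_id = "anti_gB"))
  rep1 <- utr3_pirna_report(reads, ann, min_count = 1L)
  gA <- rep1[rep1$gene_id == "gA", ]
  expect_equal(gA$antisense_count, 1L)
  expect_equal(gA$producer_class, "antisense")
  gB <- rep1[rep1$gene_id == "gB", ]
  expect_equal(gB$sense_count, 1L)
  expect_equal(gB$antisense_count, 1L)
  expect_equal(gB$producer_class, "both")
  # min_count above the counts -> none
  rep2 <- utr3_pirna_report(reads, ann, min_count = 2L)
  expect_true(all(rep2$producer_class == "none"))
  expect_false(any(rep1$has_te_fragment))   # no TE overlapping these UTRs
})

test_that("3'UTRs overlapping TE insertions are flagged", {
  genes <- tibble::tibble(gene_id = "gT", chrom = "c", start = 0L,
                          end = 2400L, strand = "+")
  ann <- annotation_set(
    genes = genes, exons = genes,
    utr3 = tibble::tibble(gene_id = "gT", chrom = "c", start = 2000L,
                          end = 2400L, strand = "+"),
    te_insertions = tibble::tibble(chrom = "c", start = 2100L, end = 2300L,
                                   strand = "+", name = "TE1"))
  rep <- utr3_pirna_report(mk_reads("c", 1, 26)[0, ], ann)
  expect_true(rep$has_te_fragment)
  expect_equal(rep$producer_class, "none")
})

test_that("dge_binomial composes the rules and reports through tidy/glance", {
  set.seed(15)
  grid <- tidyr::expand_grid(feature_id = paste0("f", 1:20),
                             sample_id = c("g1", "g2", "s1", "s2"))
  # features f1..f5 are 4-fold up in condition G
  counts <- dplyr::mutate(grid, count = as.integer(
    rpois(nrow(grid), 200) *
      dplyr::if_else(.data$feature_id %in% paste0("f", 1:5) &
                       .data$sample_id %in% c("g1", "g2"), 4L, 1L)))
  groups <- tibble::tibble(sample_id = c("g1", "g2", "s1", "s2"),
                           condition = c("G", "G", "S", "S"))
  fit <- dge_binomial(counts, groups, 1e6, dge_params(cpm_cutoff = 1),
                      reference = "S")
  tab <- tidy(fit)
  expect_setequal(tab$feature_id[tab$call == "up"], paste0("f", 1:5))
  g <- glance(fit)
  expect_equal(g$n_up, 5L)
  expect_equal(g$test, "binomial_standin")
})
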