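# Sliding-window cluster discovery against the brute-force oracle,
# canonical fragment harmonization, and reference comparison.

test_that("dedupe collapses identical alignments and keeps multiplicity", {
  five <- mk_reads("c", rep(100, 5), 26, "+")
  u <- dedupe_reads(five)
  expect_equal(nrow(u), 1L)
  expect_equal(u$multiplicity, 5L)
  two <- dplyr::bind_rows(mk_reads("c", 100, 26), mk_reads("c", 100, 27))
  expect_equal(nrow(dedupe_reads(two)), 2L)
  expect_equal(nrow(dedupe_reads(five[0, ])), 0L)
})

test_that("a regular 100-read comb merges into one cluster with the known density", {
  reads <- mk_reads("c", seq(0, 9900, by = 100), 25, "+")
  cl <- discover_clusters(reads)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 0L)
  expect_equal(cl$end, 9925L)
  expect_equal(cl$n_unique_reads, 100L)
  expect_equal(cl$density, 100 / 9.925, tolerance = 1e-12)
})

test_that("two dense 1.5-kb regions 500 nt apart merge into one 3.5-kb cluster", {
  mk_region <- function(off) mk_reads("c", off + seq(0, 1470, by = 70), 30, "+")
  reads <- dplyr::bind_rows(mk_region(0), mk_region(2000))
  cl <- discover_clusters(reads)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$end - cl$start, 3500L)
})

test_that("the size filter is strict and the density filter literal", {
  # a tiling that forms a single region of exactly 2,000 nt is dropped
  tiling <- mk_reads("c", seq(0, 1975, by = 25), 25, "+")
  expect_equal(nrow(discover_clusters(tiling)), 0L)
  # one extra base pushes it over the strict threshold
  over <- dplyr::bind_rows(tiling, mk_reads("c", 1976, 25))
  expect_equal(nrow(discover_clusters(over)), 1L)
  # a single 2,500-nt region holding 7 unique reads (density 2.8/kb) is
  # removed by the density step; wide footprints realise this arithmetic
  starts <- round(seq(0, 2500 - 358, length.out = 7))
  wide <- mk_reads("c", starts, 358)
  wide$end[7] <- 2500L
  expect_equal(nrow(discover_clusters(wide)), 0L)
})

test_that("discovery is interval-identical to the brute-force oracle", {
  for (seed in 1:10) {
    reads <- random_read_set(seed)
    got <- discover_clusters(reads)
    want <- oracle_discover(reads)
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    if (nrow(got)) {
      expect_equal(got$start, as.integer(want$start), info = paste("seed", seed))
      expect_equal(got$end, as.integer(want$end), info = paste("seed", seed))
    }
  }
})

test_that("discovery is idempotent and order-invariant", {
  reads <- random_read_set(99, n_reads = 400, contig_len = 50000)
  cl <- discover_clusters(reads)
  # restrict to reported clusters and re-run
  keep <- rep(FALSE, nrow(reads))
  for (i in seq_len(nrow(cl)))
    keep <- keep | (reads$start < cl$end[i] & reads$end > cl$start[i])
  cl2 <- discover_clusters(reads[keep, ])
  expect_equal(cl2[, c("chrom", "start", "end")],
               cl[, c("chrom", "start", "end")])
  shuf <- reads[sample.int(nrow(reads)), ]
  expect_equal(discover_clusters(shuf), cl)
})

test_that("planted clusters are recovered exactly with zero background", {
  cfg <- synthetic_config(
    seed = 21,
    contigs = tibble::tibble(name = "chrP", length = 300000L),
    planted_clusters = tibble::tibble(
      contig = "chrP", start = c(10000L, 60000L, 150000L),
      length = c(5000L, 12000L, 30000L),
      reads_per_kb = c(10, 25, 8),
      strand_mode = c("dual", "uni_plus", "dual"),
      pingpong_fraction = 0),
    n_premirna = 0L, n_endosirna = 0L, n_structural = 0L,
    n_te_insertions = 0L, n_genes = 0L, background_reads_per_kb = 0,
    mirna_reads = 0L, sirna_reads = 0L, structural_reads = 0L,
    te_pirna_reads = 0L, utr3_pirna_reads = 0L,
    samples = tibble::tibble(sample_id = "s1", condition = "A",
                             global_scale = 1, spike_total = 1000L,
                             pingpong = FALSE))
  g <- generate_genome(cfg)
  lib <- generate_library(cfg, g, cfg$samples[1, ], seed = 5)
  cl <- discover_clusters(lib$reads)
  truth <- g$truth$planted_clusters
  rep <- compare_to_reference(cl, truth)
  expect_equal(rep$reference_covered_fraction, 1)
  expect_equal(rep$novel_call_fraction, 0)
  expect_equal(nrow(cl), nrow(truth))
})

test_that("canonical fragments merge under 25 kb, otherwise the largest is kept", {
  merged <- harmonize_canonical(tibble::tibble(
    name = "cl", chrom = "c", start = c(10000L, 30000L),
    end = c(20000L, 45000L)))
  expect_equal(merged$start, 10000L)
  expect_equal(merged$end, 45000L)

  kept <- harmonize_canonical(tibble::tibble(
    name = "cl", chrom = "c", start = c(0L, 40000L), end = c(5000L, 42000L)))
  expect_equal(kept$start, 0L)
  expect_equal(kept$end, 5000L)

  # strictness: a gap of exactly 25,000 is NOT merged
  exact <- harmonize_canonical(tibble::tibble(
    name = "cl", chrom = "c", start = c(0L, 30000L), end = c(5000L, 40000L)))
  expect_equal(exact$end - exact$start, 10000L)   # larger fragment kept

  single <- harmonize_canonical(tibble::tibble(
    name = "solo", chrom = "c", start = 100L, end = 900L))
  expect_equal(single$start, 100L)
  expect_equal(single$end, 900L)

  # tie on length -> smaller start
  tie <- harmonize_canonical(tibble::tibble(
    name = "t", chrom = "c", start = c(50000L, 0L), end = c(55000L, 5000L)))
  expect_equal(tie$start, 0L)
})

test_that("reference comparison counts >=1 bp overlaps", {
  calls <- tibble::tibble(chrom = "c", start = c(0L, 10000L),
                          end = c(5000L, 12000L), strand = "*")
  rep_same <- compare_to_reference(calls, calls)
  expect_equal(rep_same$reference_covered_fraction, 1)
  expect_equal(rep_same$novel_call_fraction, 0)

  far <- tibble::tibble(chrom = "c", start = 50000L, end = 60000L, strand = "*")
  rep_disj <- compare_to_reference(calls, far)
  expect_equal(rep_disj$reference_covered_fraction, 0)
  expect_equal(rep_disj$novel_call_fraction, 1)

  onebp <- tibble::tibble(chrom = "c", start = 4999L, end = 9000L, strand = "*")
  rep_1bp <- compare_to_reference(calls, onebp)
  expect_equal(rep_1bp$reference_covered_fraction, 1)
  expect_equal(rep_1bp$per_reference$best_overlap_bp, 1L)
})

test_that("strandedness thresholds apply literally at 0.9/0.1", {
  cl <- tibble::tibble(chrom = "c", start = 0L, end = 10000L, strand = "*")
  mk <- function(n_plus, n_minus) {
    p <- if (n_plus > 0) mk_reads("c", seq_len(n_plus) * 50, 26, "+")
    m <- if (n_minus > 0) mk_reads("c", 5000 + seq_len(n_minus) * 50, 26, "-")
    dplyr::bind_rows(p, m)
  }
  expect_equal(cluster_strandedness(cl, mk(10, 0))$strandedness, "uni_plus")
  expect_equal(cluster_strandedness(cl, mk(0, 10))$strandedness, "uni_minus")
  expect_equal(cluster_strandedness(cl, mk(5, 5))$strandedness, "dual")
  expect_equal(cluster_strandedness(cl, mk(89, 11))$strandedness, "dual")
  expect_equal(cluster_strandedness(cl, mk(90, 10))$strandedness, "uni_plus")
  expect_error(cluster_strandedness(cl, mk_reads("other", 1, 26)),
               "zero reads")
})
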