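# Ping-pong 5'-overlap histograms, the z10 enrichment score, per-cluster
# scans, and the first-10-nt base frequency matrix.

test_that("a plus 5' at 100 and a minus 5' at 109 score distance 10", {
  reads <- dplyr::bind_rows(mk_reads("c", 100, 26, "+"),
                            mk_reads("c", 84, 26, "-"))  # minus 5' = 109
  h <- tidy(ping_pong_histogram(reads))
  expect_equal(h$count[h$distance == 10], 1)
  expect_equal(sum(h$count), 1)
})

test_that("single-strand read sets produce an all-zero histogram", {
  h <- tidy(ping_pong_histogram(mk_reads("c", seq(0, 900, 30), 26, "+")))
  expect_true(all(h$count == 0))
})

test_that("constructed distance-10 pairs are all recovered, matching brute force", {
  set.seed(3)
  p5 <- sample.int(100000, 100)
  plus <- mk_reads("c", p5, 26, "+")
  minus <- mk_reads("c", p5 + 10 - 26, 26, "-")   # minus 5' = p5 + 9
  reads <- dplyr::bind_rows(plus, minus)
  h <- tidy(ping_pong_histogram(reads))
  # brute-force all-pairs enumeration
  brute <- integer(30)
  mq <- minus$end - 1L
  for (p in p5) for (q in mq) {
    d <- q - p + 1
    if (d >= 1 && d <= 30) brute[d] <- brute[d] + 1L
  }
  expect_equal(h$count, as.numeric(brute))
  expect_equal(h$count[h$distance == 10], 100)
})

test_that("histogram is invariant under strand swap + coordinate mirror", {
  set.seed(8)
  reads <- mk_reads("c", sample.int(5000, 80), sample(23:30, 80, TRUE),
                    sample(c("+", "-"), 80, TRUE))
  L <- 10000L
  mirrored <- dplyr::mutate(reads,
    start2 = L - .data$end, end = L - .data$start, start = .data$start2,
    strand = ifelse(.data$strand == "+", "-", "+"))
  mirrored$start2 <- NULL
  expect_equal(tidy(ping_pong_histogram(mirrored)),
               tidy(ping_pong_histogram(reads)))
})

test_that("z10 handles degenerate and flat backgrounds", {
  mk_prof <- function(counts) {
    structure(list(overlap_counts = tibble::tibble(distance = 1:30,
                                                   count = counts),
                   n_pairs_total = sum(counts), weighted = TRUE,
                   n_reads = 0L), class = "pingpong_profile")
  }
  spike <- rep(0, 30); spike[10] <- 100
  expect_true(is.na(ping_pong_zscore(mk_prof(spike))))
  expect_equal(ping_pong_zscore(mk_prof(rep(7, 30))), 0)
})

test_that("z10 exceeds 10 for a strong peak over Poisson background", {
  for (seed in 1:20) {
    set.seed(seed)
    counts <- rpois(30, 20); counts[10] <- 200
    prof <- structure(list(overlap_counts = tibble::tibble(distance = 1:30,
                                                           count = counts),
                           n_pairs_total = sum(counts), weighted = TRUE,
                           n_reads = 0L), class = "pingpong_profile")
    expect_gt(ping_pong_zscore(prof), 10)
  }
})

test_that("per-cluster scan counts distinct position pairs", {
  cl <- tibble::tibble(chrom = "c", start = 0L, end = 1000L, strand = "*",
                       name = "cl1")
  # two plus reads sharing a 5' position, one minus partner at distance 10
  reads <- dplyr::bind_rows(mk_reads("c", c(100, 100), c(26, 28), "+"),
                            mk_reads("c", 84, 26, "-"))
  scan <- ping_pong_scan(reads, cl)
  expect_equal(scan$signature_count, 1)
  # no minus reads -> zero
  scan0 <- ping_pong_scan(mk_reads("c", 100, 26, "+"), cl)
  expect_equal(scan0$signature_count, 0)
  over <- dplyr::bind_rows(cl, tibble::tibble(chrom = "c", start = 500L,
                                              end = 1500L, strand = "*",
                                              name = "cl2"))
  expect_error(ping_pong_scan(reads, over), "disjoint")
})

test_that("identical start sites give a one-hot frequency matrix", {
  genome <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 100)))
  reads <- mk_reads("c1", rep(40, 20), 26, "+")
  m <- first10_frequency_matrix(reads, genome)
  expect_equal(attr(m, "n_sites"), 1L)
  tenmer <- substr(strrep("ACGT", 100), 41, 50)
  for (i in 1:10) {
    want <- chartr("T", "U", substr(tenmer, i, i))
    expect_equal(m$freq[m$position == i & m$base == want], 1)
  }
})

test_that("minus-strand extraction equals the manual reverse complement", {
  set.seed(4)
  seqs <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(cx = seqs))
  # plus site at p and the mirrored minus site constructed so that the
  # minus 10-mer is the reverse complement of the plus 10-mer
  p <- 100L
  plus <- mk_reads("cx", p, 26, "+")
  minus <- mk_reads("cx", p - 16L, 26, "-")   # minus 5' = p + 9
  m_plus <- first10_frequency_matrix(plus, genome)
  m_minus <- first10_frequency_matrix(minus, genome)
  ten_plus <- substr(seqs, p + 1, p + 10)
  manual_rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(
    substr(seqs, p + 1, p + 10), "")[[1]]), collapse = ""))
  # one-hot rows must match the manual sequences
  for (i in 1:10) {
    want_p <- chartr("T", "U", substr(ten_plus, i, i))
    want_m <- chartr("T", "U", substr(manual_rc, i, i))
    expect_equal(m_plus$freq[m_plus$position == i & m_plus$base == want_p], 1)
    expect_equal(m_minus$freq[m_minus$position == i & m_minus$base == want_m], 1)
  }
})

test_that("frequency matrix rows sum to one on random libraries", {
  set.seed(10)
  genome <- Biostrings::DNAStringSet(c(cz = paste(
    sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")))
  for (rep in 1:5) {
    reads <- mk_reads("cz", sample.int(19000, 300), sample(23:30, 300, TRUE),
                      sample(c("+", "-"), 300, TRUE))
    m <- first10_frequency_matrix(reads, genome)
    sums <- tapply(m$freq, m$position, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("sites too close to a contig end are skipped; none usable errors", {
  genome <- Biostrings::DNAStringSet(c(ce = strrep("A", 100)))
  edge <- mk_reads("ce", 95 - 26, 26, "-")   # minus 5' at 94, needs 85..94: fine
  expect_silent(first10_frequency_matrix(edge, genome))
  near <- dplyr::bind_rows(mk_reads("ce", 95, 5 + 16, "+"),  # 5' at 95, needs 96..105 > 100
                           mk_reads("ce", 20, 26, "+"))
  expect_warning(m <- first10_frequency_matrix(near, genome), "skipped")
  expect_equal(attr(m, "n_sites"), 1L)
  only_bad <- mk_reads("ce", 95, 21, "+")
  expect_error(suppressWarnings(first10_frequency_matrix(only_bad, genome)),
               "no usable")
})
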