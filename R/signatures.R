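# Ping-pong 5'-overlap signatures and first-10-nt nucleotide bias.
#
# 5'-overlap convention: for a plus-strand read with 5' end at p and a
# minus-strand read with 5' end at q (its rightmost aligned base, q =
# end - 1 in 0-based coordinates), the overlap distance is d = q - p + 1.
# The ping-pong amplification loop cleaves at the 10th nucleotide, so
# genuine ping-pong pairs sit at d = 10.

# collapse reads to unique (chrom, 5' position, strand) with multiplicity
five_prime_sites <- function(reads) {
  if (!nrow(reads))
    return(tibble(chrom = character(), pos = integer(), strand = character(),
                  multiplicity = integer()))
  pos <- if_else(reads$strand == "+", reads$start, reads$end - 1L)
  sites <- tibble(chrom = reads$chrom, pos = pos, strand = reads$strand)
  count(sites, .data$chrom, .data$pos, .data$strand, name = "multiplicity")
}

#' Ping-pong 5'-overlap histogram
#'
#' Counts (plus-read, minus-read) pairs whose 5' ends overlap by d
#' nucleotides, for d in 1..`max_distance`. Reads are collapsed to unique
#' 5' sites first; with `weighted = TRUE` (default) each site pair
#' contributes the product of the two sites' read multiplicities, with
#' `weighted = FALSE` each distinct position pair contributes 1.
#'
#' @param reads Genome-space piRNA read tibble (both strands).
#' @param max_distance Largest overlap distance tallied (default 30).
#' @param weighted Multiplicity-weighted pair counting (default TRUE).
#' @return A `pingpong_profile` object: histogram tibble (`distance`,
#'   `count`), total pair count, and the counting mode.
#' @export
ping_pong_histogram <- function(reads, max_distance = 30L, weighted = TRUE) {
  reads <- filter(reads, .data$strand %in% c("+", "-"))
  sites <- five_prime_sites(reads)
  p <- filter(sites, .data$strand == "+")
  m <- filter(sites, .data$strand == "-")
  counts <- numeric(max_distance)
  if (nrow(p) && nrow(m)) {
    for (d in seq_len(max_distance)) {
      j <- inner_join(p, mutate(m, pos = .data$pos - d + 1L),
                      by = c("chrom", "pos"), suffix = c("_p", "_m"))
      counts[d] <- if (weighted)
        sum(as.numeric(j$multiplicity_p) * j$multiplicity_m) else nrow(j)
    }
  }
  structure(list(
    overlap_counts = tibble(distance = seq_len(max_distance), count = counts),
    n_pairs_total = sum(counts),
    weighted = weighted,
    n_reads = nrow(reads)),
    class = "pingpong_profile")
}

#' Ping-pong enrichment z-score at distance 10
#'
#' z10 = (c10 - mean(c_d, d != 10)) / sd(c_d, d != 10), with the sample
#' standard deviation over the background distances 1..max excluding 10.
#' Returns `NA` when the background sd is zero (degenerate histogram);
#' this is a defined outcome, not an error. This statistic is this
#' package's own definition ("piratlas z10") and is named as such in all
#' outputs.
#'
#' @param profile A `pingpong_profile` from [ping_pong_histogram()].
#' @return A single numeric z-score, or `NA` if undefined.
#' @export
ping_pong_zscore <- function(profile) {
  stopifnot(inherits(profile, "pingpong_profile"))
  h <- profile$overlap_counts
  c10 <- h$count[h$distance == 10]
  bg <- h$count[h$distance != 10]
  s <- sd(bg)
  if (!isTRUE(s > 0)) {
    # flat background: a perfectly flat histogram has zero enrichment;
    # any other zero-sd background leaves the score undefined
    return(if (isTRUE(all.equal(c10, mean(bg)))) 0 else NA_real_)
  }
  (c10 - mean(bg)) / s
}

#' @export
print.pingpong_profile <- function(x, ...) {
  z <- ping_pong_zscore(x)
  cat(sprintf("ping-pong profile: %s pairs over %d reads; z10 = %s (%s)\n",
              format(x$n_pairs_total), x$n_reads,
              ifelse(is.na(z), "undefined", sprintf("%.2f", z)),
              ifelse(x$weighted, "multiplicity-weighted", "distinct positions")))
  invisible(x)
}

#' @describeIn ping_pong_histogram tidy(): the overlap histogram as a tibble.
#' @param x A `pingpong_profile`.
#' @param ... Unused.
#' @method tidy pingpong_profile
#' @export
tidy.pingpong_profile <- function(x, ...) x$overlap_counts

#' @describeIn ping_pong_histogram glance(): one-row summary with `z10`,
#'   `count10`, `n_pairs_total`, `n_reads`.
#' @method glance pingpong_profile
#' @export
glance.pingpong_profile <- function(x, ...) {
  h <- x$overlap_counts
  tibble(z10 = ping_pong_zscore(x),
         count10 = h$count[h$distance == 10],
         n_pairs_total = x$n_pairs_total,
         n_reads = x$n_reads)
}

#' Per-cluster ping-pong signature scan
#'
#' For each cluster: the signature count is the number of *distinct*
#' (plus 5' position, minus 5' position) pairs at exact distance 10 within
#' the cluster, and z10 is the enrichment z-score of the cluster's
#' (unweighted) overlap histogram.
#'
#' @param reads Genome-space piRNA read tibble.
#' @param clusters Disjoint cluster tibble.
#' @param max_distance Histogram span for the z-score background.
#' @return Tibble `cluster`, `chrom`, `start`, `end`, `signature_count`,
#'   `z10`, sorted by `signature_count` descending.
#' @export
ping_pong_scan <- function(reads, clusters, max_distance = 30L) {
  gr <- as_granges(clusters)
  if (length(gr) &&
      any(count_overlaps_q(gr, gr) > 1))
    abort("ping_pong_scan: clusters must be disjoint")
  gread <- as_granges(reads)
  id <- if ("name" %in% names(clusters)) clusters$name
        else sprintf("%s:%d-%d", clusters$chrom, clusters$start, clusters$end)
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    hits <- S4Vectors::subjectHits(
      find_overlaps_q(gr[i], gread))
    prof <- ping_pong_histogram(reads[hits, ], max_distance, weighted = FALSE)
    tibble(cluster = id[i], chrom = clusters$chrom[i],
           start = clusters$start[i], end = clusters$end[i],
           signature_count = prof$overlap_counts$count[
             prof$overlap_counts$distance == 10],
           z10 = ping_pong_zscore(prof))
  })
  out <- bind_rows(rows)
  if (!nrow(out))
    return(tibble(cluster = character(), chrom = character(),
                  start = integer(), end = integer(),
                  signature_count = numeric(), z10 = numeric()))
  arrange(out, desc(.data$signature_count))
}

#' First-10-nt nucleotide frequency matrix (1U bias)
#'
#' Reads are collapsed to unique (chrom, 5' position, strand) start sites;
#' for each site the 10-nt genomic sequence starting at the 5' position in
#' read orientation is extracted (reverse-complemented for minus-strand
#' sites) and per-position base fractions tallied, reporting T as U.
#' Sites within 10 nt of a contig end are skipped with a warning.
#'
#' @param reads Genome-space piRNA read tibble.
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @return A `nt_freq_matrix`: tibble `position` (1..10) x `base`
#'   (A, C, G, U) with column `freq`; fractions at each position sum to 1
#'   (N bases excluded from the tally). Attribute `n_sites` records the
#'   unique start sites used.
#' @export
first10_frequency_matrix <- function(reads, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  sites <- five_prime_sites(reads)
  missing_chrom <- setdiff(unique(sites$chrom), names(genome))
  if (length(missing_chrom))
    abort(paste0("first10_frequency_matrix: contigs absent from genome: ",
                 paste(missing_chrom, collapse = ", ")))
  clen <- setNames(Biostrings::width(genome), names(genome))[sites$chrom]
  ok <- if_else(sites$strand == "+",
                sites$pos + 10L <= clen,
                sites$pos - 9L >= 0L)
  if (any(!ok))
    warn(sprintf("first10_frequency_matrix: %d site(s) within 10 nt of a contig end skipped",
                 sum(!ok)))
  sites <- sites[ok, ]
  if (!nrow(sites)) abort("first10_frequency_matrix: no usable start sites")
  s1 <- if_else(sites$strand == "+", sites$pos + 1L, sites$pos - 8L)
  tenmers <- Biostrings::DNAStringSet(Biostrings::subseq(
    genome[sites$chrom], start = s1, end = s1 + 9L))
  neg <- sites$strand == "-"
  if (any(neg))
    tenmers[neg] <- Biostrings::reverseComplement(tenmers[neg])
  cm <- Biostrings::consensusMatrix(tenmers)[c("A", "C", "G", "T"), , drop = FALSE]
  frac <- sweep(cm, 2, colSums(cm), "/")
  out <- tibble(position = rep(1:10, each = 4),
                base = rep(c("A", "C", "G", "U"), 10),
                freq = as.numeric(frac))
  structure(out, n_sites = nrow(sites),
            class = c("nt_freq_matrix", class(out)))
}
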