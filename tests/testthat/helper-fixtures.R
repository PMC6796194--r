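# Shared fixture builders and independent reference implementations
# ("oracles") used across the suite. The oracles are deliberately written
# in plain base R, without IRanges/GenomicRanges, so they stay independent
# of the code paths they check.

mk_reads <- function(chrom, start, len = 26L, strand = "+", n_hits = 1L,
                     space = "genome", read_id = NULL) {
  n <- max(length(chrom), length(start), length(len), length(strand))
  tibble::tibble(
    read_id = read_id %||% sprintf("r%04d", seq_len(n)),
    chrom = rep_len(chrom, n),
    start = as.integer(rep_len(start, n)),
    end = as.integer(rep_len(start, n) + rep_len(len, n)),
    strand = rep_len(strand, n),
    n_hits = as.integer(rep_len(n_hits, n)),
    space = rep_len(space, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# annotation set with one feature per category at known, disjoint spots
tiny_ann <- function() {
  iv <- function(chrom, start, end, strand = "+", name = "x")
    tibble::tibble(chrom = chrom, start = as.integer(start),
                   end = as.integer(end), strand = strand, name = name)
  genes <- tibble::tibble(gene_id = c("gA", "gB"),
                          chrom = "chr1", start = c(5000L, 9000L),
                          end = c(7400L, 11400L), strand = c("+", "-"))
  utr3 <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                         start = c(7000L, 9000L), end = c(7400L, 9400L),
                         strand = c("+", "-"))
  annotation_set(
    pre_mirna = iv("chr1", 100, 180, "+", "mir1"),
    endo_sirna = iv("chr1", 500, 900, "+", "esi1"),
    rrna = iv("chr1", 1500, 3000, "+", "rRNA1"),
    trna = iv("chr1", 3500, 3580, "-", "tRNA1"),
    snorna = iv("chr1", 4000, 4150, "+", "sno1"),
    snrna = iv("chr1", 4500, 4650, "+", "snR1"),
    te_insertions = iv("chr1", 12000, 15000, "+", "TEx_ins1"),
    canonical_clusters = iv("chr1", 20000, 30000, "*", "clusterA"),
    genes = genes, exons = genes, utr3 = utr3,
    te_consensus_names = c("TEx", "TEy"),
    spike_in_ids = paste0("spike", 1:4))
}

# --- independent biotype oracle: plain nested conditionals -----------------

oracle_classify <- function(len, flags, te_space = FALSE) {
  if (flags[["rrna"]] || flags[["trna"]] || flags[["snorna"]] || flags[["snrna"]]) {
    "structural_excluded"
  } else if (len <= 24 && flags[["pre_mirna"]]) {
    "miRNA"
  } else if ((len <= 22 && flags[["endo_sirna"]]) ||
             (len == 21 && (te_space || flags[["te_insertion"]]))) {
    "siRNA"
  } else if (len >= 23 && len <= 30) {
    "piRNA"
  } else {
    "other"
  }
}

# annotation set in which the categories named in `on` all cover
# [1000, 1100) on contig "cT"; a read inside that window overlaps exactly
# those categories
stacked_ann <- function(on) {
  iv <- function(cat) {
    if (cat %in% on)
      tibble::tibble(chrom = "cT", start = 1000L, end = 1100L,
                     strand = "+", name = cat)
    else
      tibble::tibble(chrom = character(), start = integer(),
                     end = integer(), strand = character(),
                     name = character())
  }
  annotation_set(pre_mirna = iv("pre_mirna"), endo_sirna = iv("endo_sirna"),
                 rrna = iv("rrna"), trna = iv("trna"),
                 snorna = iv("snorna"), snrna = iv("snrna"),
                 te_insertions = iv("te_insertion"))
}

# --- brute-force cluster discovery oracle ----------------------------------
# Materialises per-base read presence and applies the five steps literally,
# with explicit pairwise gap scanning for every merge.

oracle_merge_by_gap <- function(regs, gap) {
  if (!nrow(regs)) return(regs)
  regs <- regs[order(regs$start), , drop = FALSE]
  out <- regs[1, , drop = FALSE]
  for (i in seq_len(nrow(regs))[-1]) {
    if (regs$start[i] - out$end[nrow(out)] <= gap) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], regs$end[i])
    } else {
      out <- rbind(out, regs[i, , drop = FALSE])
    }
  }
  out
}

oracle_discover <- function(reads, seed_gap = 250, min_density = 3,
                            region_gap = 1000, min_size = 2000) {
  u <- unique(reads[, c("chrom", "start", "end", "strand")])
  res <- NULL
  for (ct in sort(unique(u$chrom))) {
    d <- u[u$chrom == ct, , drop = FALSE]
    lo <- min(d$start); hi <- max(d$end)
    covered <- logical(hi - lo)
    for (i in seq_len(nrow(d)))
      covered[(d$start[i] - lo + 1):(d$end[i] - lo)] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    regs <- data.frame(start = lo + starts[r$values] - 1,
                       end = lo + ends[r$values])            # step 1
    regs <- oracle_merge_by_gap(regs, seed_gap)              # step 2
    n_in <- vapply(seq_len(nrow(regs)), function(i)
      sum(d$start < regs$end[i] & d$end > regs$start[i]), integer(1))
    dens <- n_in / ((regs$end - regs$start) / 1000)
    regs <- regs[dens >= min_density, , drop = FALSE]        # step 3
    regs <- oracle_merge_by_gap(regs, region_gap)            # step 4
    regs <- regs[regs$end - regs$start > min_size, , drop = FALSE]  # step 5
    if (nrow(regs)) res <- rbind(res, cbind(chrom = ct, regs))
  }
  if (is.null(res))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  res[order(res$chrom, res$start), , drop = FALSE]
}

# step-3 certification detail for a final call: the density-filtered
# regions that built the call, recomputed by the oracle
oracle_step3_regions <- function(reads, seed_gap = 250, min_density = 3) {
  u <- unique(reads[, c("chrom", "start", "end", "strand")])
  res <- NULL
  for (ct in sort(unique(u$chrom))) {
    d <- u[u$chrom == ct, , drop = FALSE]
    lo <- min(d$start); hi <- max(d$end)
    covered <- logical(hi - lo)
    for (i in seq_len(nrow(d)))
      covered[(d$start[i] - lo + 1):(d$end[i] - lo)] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    regs <- data.frame(start = lo + starts[r$values] - 1,
                       end = lo + ends[r$values])
    regs <- oracle_merge_by_gap(regs, seed_gap)
    n_in <- vapply(seq_len(nrow(regs)), function(i)
      sum(d$start < regs$end[i] & d$end > regs$start[i]), integer(1))
    dens <- n_in / ((regs$end - regs$start) / 1000)
    regs <- regs[dens >= min_density, , drop = FALSE]
    if (nrow(regs)) res <- rbind(res, cbind(chrom = ct, regs,
                                            density = dens[dens >= min_density]))
  }
  res
}

# random read set on one contig, for oracle-equivalence checks
random_read_set <- function(seed, n_reads = 200, contig_len = 100000) {
  set.seed(seed)
  start <- sort(sample.int(contig_len - 40L, n_reads, replace = TRUE)) - 1L
  len <- sample(23:35, n_reads, replace = TRUE)
  mk_reads("cR", start, len, sample(c("+", "-"), n_reads, replace = TRUE))
}

# --- brute-force Benjamini-Hochberg ---------------------------------------

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q_sorted[i] <- min(1, min(m / js * p[o][js]))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# minimal single-cluster generator config used by several tests
one_cluster_config <- function(seed, contig_len = 120000L, cl_start = 30000L,
                               cl_len = 20000L, reads_per_kb = 30,
                               strand_mode = "dual", pingpong_fraction = 0,
                               pingpong = TRUE, background = 0, scale = 1,
                               spike_total = 20000L) {
  synthetic_config(
    seed = seed,
    contigs = tibble::tibble(name = "chrT", length = contig_len),
    planted_clusters = tibble::tibble(
      contig = "chrT", start = cl_start, length = cl_len,
      reads_per_kb = reads_per_kb, strand_mode = strand_mode,
      pingpong_fraction = pingpong_fraction),
    n_premirna = 0L, n_endosirna = 0L, n_structural = 0L,
    n_te_insertions = 0L, n_genes = 0L,
    background_reads_per_kb = background,
    mirna_reads = 0L, sirna_reads = 0L, structural_reads = 0L,
    te_pirna_reads = 0L, utr3_pirna_reads = 0L,
    samples = tibble::tibble(sample_id = "s1", condition = "A",
                             global_scale = scale,
                             spike_total = spike_total,
                             pingpong = pingpong))
}
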