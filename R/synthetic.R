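# Deterministic generator of toy genomes, annotations and small-RNA
# libraries with the statistical structure the analysis assumes: clustered
# piRNA origin (uni- and dual-strand), 23-30 nt lengths peaking at 24-27,
# 1U bias, exact 10-nt ping-pong partners, 22-nt-peaked miRNAs, 21-nt
# siRNAs, structural-RNA contamination, TE-consensus reads and per-sample
# spike-ins. Ground truth (per-read provenance, planted intervals, true
# scales) is returned for recovery tests.
#
# Contig sequences are held as raw byte vectors during generation so that
# the per-site 1U edits are O(1); they are materialised as a DNAStringSet
# only when writing FASTA / extracting read sequences.

DEFAULT_PIRNA_LENGTHS <- c(`23` = 0.10, `24` = 0.17, `25` = 0.22, `26` = 0.22,
                           `27` = 0.17, `28` = 0.07, `29` = 0.03, `30` = 0.02)
MIRNA_LENGTHS <- c(`21` = 0.15, `22` = 0.60, `23` = 0.15, `24` = 0.10)

#' Synthetic study configuration
#'
#' All knobs of the generator, validated. The defaults describe a minimal
#' single-contig setup; [default_study_config()] builds the full six-sample
#' two-condition study.
#'
#' @param seed Integer RNG seed; every random choice flows from it.
#' @param contigs Tibble `name`, `length` (nt).
#' @param planted_clusters Tibble `contig`, `start`, `length`,
#'   `reads_per_kb`, `strand_mode` ("uni_plus"/"uni_minus"/"dual"),
#'   `pingpong_fraction` in \[0, 1\]. Clusters must fit their contig and be
#'   pairwise separated by more than 2 kb.
#' @param length_distribution Named probabilities over piRNA read lengths;
#'   must sum to 1.
#' @param u1_prob Probability that a piRNA 5' site carries U at position 1
#'   (default 0.8).
#' @param n_premirna,n_endosirna,n_structural,n_te_insertions,n_genes
#'   Feature counts placed outside planted clusters.
#' @param te_consensus Tibble `name`, `length` of TE consensus sequences.
#' @param background_reads_per_kb Unclustered genome-wide piRNA background.
#' @param mirna_reads,sirna_reads,structural_reads,te_pirna_reads,utr3_pirna_reads
#'   Per-sample read counts for the non-cluster biotypes (scaled by each
#'   sample's `global_scale` only for piRNA-class reads).
#' @param spike_ids Spike-in identifiers.
#' @param samples Tibble `sample_id`, `condition`, `global_scale`,
#'   `spike_total`, `pingpong` (logical; switches cluster ping-pong pairing
#'   on/off for the sample).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    contigs = tibble(name = "chrS", length = 200000L),
    planted_clusters = tibble(contig = "chrS", start = 50000L,
                              length = 10000L, reads_per_kb = 20,
                              strand_mode = "dual", pingpong_fraction = 0.3),
    length_distribution = DEFAULT_PIRNA_LENGTHS,
    u1_prob = 0.8,
    n_premirna = 4L, n_endosirna = 2L, n_structural = 4L,
    n_te_insertions = 3L, n_genes = 6L,
    te_consensus = tibble(name = c("TEsyn1", "TEsyn2"),
                          length = c(4000L, 3000L)),
    background_reads_per_kb = 0.1,
    mirna_reads = 500L, sirna_reads = 200L, structural_reads = 200L,
    te_pirna_reads = 300L, utr3_pirna_reads = 100L,
    spike_ids = paste0("spike", 1:8),
    samples = tibble(sample_id = c("s1", "s2"), condition = c("A", "B"),
                     global_scale = c(1, 1), spike_total = c(20000L, 20000L),
                     pingpong = c(TRUE, TRUE))) {
  cfg <- list(seed = as.integer(seed), contigs = contigs,
              planted_clusters = planted_clusters,
              length_distribution = length_distribution, u1_prob = u1_prob,
              n_premirna = n_premirna, n_endosirna = n_endosirna,
              n_structural = n_structural, n_te_insertions = n_te_insertions,
              n_genes = n_genes, te_consensus = te_consensus,
              background_reads_per_kb = background_reads_per_kb,
              mirna_reads = mirna_reads, sirna_reads = sirna_reads,
              structural_reads = structural_reads,
              te_pirna_reads = te_pirna_reads,
              utr3_pirna_reads = utr3_pirna_reads,
              spike_ids = spike_ids, samples = samples)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (abs(sum(cfg$length_distribution) - 1) > 1e-9)
    abort("synthetic_config: length_distribution must sum to 1")
  if (cfg$u1_prob < 0 || cfg$u1_prob > 1)
    abort("synthetic_config: u1_prob must lie in [0, 1]")
  pc <- cfg$planted_clusters
  if (nrow(pc)) {
    if (any(!pc$pingpong_fraction >= 0 & pc$pingpong_fraction <= 1))
      abort("synthetic_config: pingpong_fraction must lie in [0, 1]")
    if (!all(pc$strand_mode %in% c("uni_plus", "uni_minus", "dual")))
      abort("synthetic_config: bad strand_mode")
    j <- left_join(pc, cfg$contigs, by = c(contig = "name"))
    if (anyNA(j$length.y) || any(j$start < 0 | j$start + j$length.x > j$length.y))
      abort("synthetic_config: planted cluster outside contig bounds")
    for (ct in unique(pc$contig)) {
      d <- arrange(filter(pc, .data$contig == ct), .data$start)
      if (nrow(d) > 1) {
        gaps <- d$start[-1] - (d$start[-nrow(d)] + d$length[-nrow(d)])
        if (any(gaps <= 2000))
          abort("synthetic_config: planted clusters must be separated by > 2 kb")
      }
    }
  }
  if (anyDuplicated(cfg$samples$sample_id))
    abort("synthetic_config: duplicate sample ids")
  if (!nrow(cfg$samples)) abort("synthetic_config: at least one sample required")
  invisible(cfg)
}

#' Default two-condition synthetic study
#'
#' Six samples: three germline-stem-cell-like ("GSC", piRNA content scaled
#' 3x, ping-pong pairing on) and three somatic-cell-like ("SC", baseline
#' scale, ping-pong off), over a two-contig 1.1-Mb toy genome with ten
#' planted clusters (3-25 kb, 10-40 unique reads/kb, uni- and dual-strand).
#' The fixture keeps the unclustered background at zero so that discovered
#' clusters correspond one-to-one to planted truth; background behaviour is
#' exercised separately via the `background_reads_per_kb` knob.
#'
#' @param seed Integer RNG seed.
#' @return A `synthetic_config`.
#' @export
default_study_config <- function(seed = 1L) {
  synthetic_config(
    seed = seed,
    contigs = tibble(name = c("chr2L_syn", "chr3R_syn"),
                     length = c(600000L, 500000L)),
    planted_clusters = tibble(
      contig = c(rep("chr2L_syn", 6), rep("chr3R_syn", 4)),
      start = c(20000L, 60000L, 100000L, 150000L, 200000L, 300000L,
                30000L, 80000L, 150000L, 250000L),
      length = c(12000L, 5000L, 8000L, 20000L, 3000L, 10000L,
                 6000L, 15000L, 4000L, 25000L),
      reads_per_kb = c(40, 30, 25, 15, 35, 30, 35, 20, 40, 10),
      strand_mode = c("dual", "uni_plus", "dual", "dual", "uni_minus",
                      "dual", "dual", "dual", "uni_plus", "dual"),
      pingpong_fraction = c(0.3, 0, 0.3, 0.2, 0, 0.3, 0.3, 0.25, 0, 0.2)),
    n_premirna = 8L, n_endosirna = 4L, n_structural = 8L,
    n_te_insertions = 6L, n_genes = 12L,
    te_consensus = tibble(name = paste0("TEsyn", 1:4),
                          length = c(5000L, 4000L, 3000L, 6000L)),
    background_reads_per_kb = 0,
    mirna_reads = 3000L, sirna_reads = 800L, structural_reads = 800L,
    te_pirna_reads = 2000L, utr3_pirna_reads = 300L,
    samples = tibble(
      sample_id = c("GSC1", "GSC2", "GSC3", "SC1", "SC2", "SC3"),
      condition = rep(c("GSC", "SC"), each = 3),
      global_scale = rep(c(3, 1), each = 3),
      spike_total = 50000L,
      pingpong = rep(c(TRUE, FALSE), each = 3)))
}

BASES <- c("A", "C", "G", "T")
rand_dna_raw <- function(n) charToRaw(paste(sample(BASES, n, replace = TRUE),
                                            collapse = ""))

# rejection-sample a width-w interval on a contig avoiding `occupied`
place_feature <- function(contig_len, w, occupied, tries = 2000L) {
  for (i in seq_len(tries)) {
    s <- sample.int(contig_len - w, 1L) - 1L
    ok <- !nrow(occupied) || all(s + w <= occupied$start | s >= occupied$end)
    if (ok) return(c(s, s + w))
  }
  abort("generate_genome: could not place features without overlap; use a larger genome")
}

#' Generate a toy genome with annotations and ground truth
#'
#' Random contig sequences (seeded), non-overlapping annotation features
#' placed uniformly outside the planted clusters, TE consensus sequences
#' with mutated (1% per base) genomic insertion copies, and gene models
#' whose last 400 nt form the 3'UTR.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional directory; when given, `genome.fa`,
#'   `annotations.gff3` and `annotations.bed` are written there.
#' @return A list of class `synthetic_genome`: `contigs` (named list of raw
#'   byte vectors), `te_seqs` ([Biostrings::DNAStringSet]), `ann`
#'   (an [annotation_set()]), and `truth` (planted clusters and feature
#'   placements).
#' @export
generate_genome <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  contigs <- setNames(lapply(config$contigs$length, rand_dna_raw),
                      config$contigs$name)
  clens <- setNames(config$contigs$length, config$contigs$name)
  occupied <- lapply(clens, function(...) tibble(start = integer(), end = integer()))
  pc <- config$planted_clusters
  for (i in seq_len(nrow(pc)))
    occupied[[pc$contig[i]]] <- bind_rows(occupied[[pc$contig[i]]],
                                          tibble(start = pc$start[i],
                                                 end = pc$start[i] + pc$length[i]))
  place_many <- function(n, w) {
    rows <- vector("list", n)
    for (k in seq_len(n)) {
      ct <- sample(names(clens), 1L, prob = clens)
      se <- place_feature(clens[[ct]], w, occupied[[ct]])
      occupied[[ct]] <<- bind_rows(occupied[[ct]],
                                   tibble(start = se[1], end = se[2]))
      rows[[k]] <- tibble(chrom = ct, start = se[1], end = se[2],
                          strand = sample(c("+", "-"), 1L))
    }
    bind_rows(rows) %||% empty_ivl()
  }
  named <- function(tb, prefix) {
    if (!nrow(tb)) return(empty_ivl())
    mutate(tb, name = paste0(prefix, row_number()))
  }
  pre_mirna <- named(place_many(config$n_premirna, 80L), "mir")
  endo_sirna <- named(place_many(config$n_endosirna, 400L), "esi")
  n_each <- diff(round(seq(0, config$n_structural, length.out = 5)))
  rrna <- named(place_many(n_each[1], 1500L), "rRNA")
  trna <- named(place_many(n_each[2], 80L), "tRNA")
  snorna <- named(place_many(n_each[3], 150L), "snoRNA")
  snrna <- named(place_many(n_each[4], 150L), "snRNA")

  te_seqs <- Biostrings::DNAStringSet(setNames(
    vapply(config$te_consensus$length,
           function(w) rawToChar(rand_dna_raw(w)), character(1)),
    config$te_consensus$name))
  te_rows <- vector("list", config$n_te_insertions)
  for (k in seq_len(config$n_te_insertions)) {
    j <- sample.int(nrow(config$te_consensus), 1L)
    w <- config$te_consensus$length[j]
    ct <- sample(names(clens), 1L, prob = clens)
    se <- place_feature(clens[[ct]], w, occupied[[ct]])
    occupied[[ct]] <- bind_rows(occupied[[ct]], tibble(start = se[1], end = se[2]))
    copy <- charToRaw(as.character(te_seqs[[j]]))
    nmut <- rpois(1, 0.01 * w)
    if (nmut > 0) {
      at <- sample.int(w, min(nmut, w))
      copy[at] <- charToRaw(paste(sample(BASES, length(at), replace = TRUE),
                                  collapse = ""))
    }
    contigs[[ct]][(se[1] + 1):se[2]] <- copy
    te_rows[[k]] <- tibble(chrom = ct, start = se[1], end = se[2],
                           strand = "+",
                           name = paste0(config$te_consensus$name[j], "_ins", k))
  }
  te_insertions <- bind_rows(te_rows) %||% empty_ivl()
  if (!nrow(te_insertions)) te_insertions <- empty_ivl()

  gene_tb <- place_many(config$n_genes, 2400L)
  genes <- exons <- utr3 <- empty_gene()
  if (nrow(gene_tb)) {
    gene_tb$gene_id <- paste0("gene", seq_len(nrow(gene_tb)))
    genes <- select(gene_tb, "gene_id", "chrom", "start", "end", "strand")
    exons <- genes
    utr3 <- mutate(genes,
                   start = if_else(.data$strand == "+", .data$end - 400L, .data$start),
                   end = if_else(.data$strand == "+", .data$end, .data$start + 400L))
  }
  ann <- annotation_set(pre_mirna = pre_mirna, endo_sirna = endo_sirna,
                        rrna = rrna, trna = trna, snorna = snorna,
                        snrna = snrna, te_insertions = te_insertions,
                        genes = genes, exons = exons, utr3 = utr3,
                        te_consensus_names = config$te_consensus$name,
                        spike_in_ids = config$spike_ids)
  truth <- list(planted_clusters = mutate(pc,
                  cluster_id = paste0("planted", seq_len(nrow(pc))),
                  chrom = .data$contig, end = .data$start + .data$length))
  g <- structure(list(contigs = contigs, te_seqs = te_seqs, ann = ann,
                      truth = truth), class = "synthetic_genome")
  if (!is.null(out_dir)) write_synthetic_genome(g, out_dir)
  g
}

contigs_to_dss <- function(contigs) {
  Biostrings::DNAStringSet(setNames(vapply(contigs, rawToChar, character(1)),
                                    names(contigs)))
}

write_synthetic_genome <- function(g, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(contigs_to_dss(g$contigs),
                              file.path(out_dir, "genome.fa"))
  write_annotation_gff3(g$ann, file.path(out_dir, "annotations.gff3"))
  flat <- annotation_bed(g$ann)
  if (nrow(flat)) write_bed(flat, file.path(out_dir, "annotations.bed"))
  invisible(out_dir)
}

annotation_bed <- function(ann) {
  cats <- c("pre_mirna", "endo_sirna", "rrna", "trna", "snorna", "snrna",
            "te_insertions", "canonical_clusters")
  bind_rows(lapply(cats, function(s) {
    d <- ann[[s]]
    if (!nrow(d)) return(NULL)
    mutate(d, name = paste0(s, ":", .data$name), score = 0)
  }))
}

write_annotation_gff3 <- function(ann, path) {
  mk <- function(tb, type, id = NULL, parent = NULL) {
    if (!nrow(tb)) return(NULL)
    gr <- as_granges(tb)
    S4Vectors::mcols(gr)$type <- type
    S4Vectors::mcols(gr)$ID <- id %||% paste0(type, seq_along(gr))
    S4Vectors::mcols(gr)$Name <- tb[["name"]] %||% S4Vectors::mcols(gr)$ID
    if (!is.null(parent)) S4Vectors::mcols(gr)$Parent <- parent
    gr
  }
  parts <- list(
    mk(ann$pre_mirna, "pre_miRNA"), mk(ann$endo_sirna, "endo_siRNA"),
    mk(ann$rrna, "rRNA"), mk(ann$trna, "tRNA"), mk(ann$snorna, "snoRNA"),
    mk(ann$snrna, "snRNA"), mk(ann$te_insertions, "transposable_element"),
    mk(ann$canonical_clusters, "piRNA_cluster"),
    mk(ann$genes, "gene", id = ann$genes$gene_id),
    mk(mutate(ann$exons, name = NA_character_), "exon",
       id = paste0(ann$exons$gene_id, ":exon"), parent = ann$exons$gene_id),
    mk(mutate(ann$utr3, name = NA_character_), "three_prime_UTR",
       id = paste0(ann$utr3$gene_id, ":utr3"), parent = ann$utr3$gene_id))
  parts <- parts[!vapply(parts, is.null, logical(1))]
  gr <- if (length(parts)) suppressWarnings(do.call(c, parts)) else
    GenomicRanges::GRanges()
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

# draw read lengths from a named probability vector
draw_lengths <- function(n, dist) {
  as.integer(sample(names(dist), n, replace = TRUE, prob = dist))
}

# Decide once per unique 5' site whether position 1 is U and edit the
# genome byte accordingly; decisions persist in site_map across samples so
# repeated sites agree and the frequency over unique sites is Binomial.
apply_u1 <- function(contigs, chrom, pos, strand, u1_prob, site_map) {
  for (i in seq_along(pos)) {
    key <- paste0(chrom[i], "|", pos[i])
    if (is.null(site_map[[key]])) {
      # first decision at a genome position wins; an opposite-strand site
      # landing on the same base later reads through the existing edit
      is_u <- runif(1) < u1_prob
      b <- if (strand[i] == "+") {
        if (is_u) "T" else sample(c("A", "C", "G"), 1L)
      } else {
        if (is_u) "A" else sample(c("C", "G", "T"), 1L)
      }
      contigs[[chrom[i]]][pos[i] + 1L] <- charToRaw(b)
      site_map[[key]] <- TRUE
    }
  }
  contigs
}

#' Generate one synthetic small-RNA library
#'
#' Planted-cluster piRNA reads are Poisson
#' (`reads_per_kb x length/1000 x global_scale`) with lengths from the
#' configured distribution, strands per the cluster's strand mode, and a
#' first-position U forced with probability `u1_prob` (the genome is
#' locally rewritten at each chosen 5' site so that sequence extraction
#' reproduces the bias). When the sample's `pingpong` flag is on, a
#' `pingpong_fraction` of cluster reads receive an opposite-strand partner
#' with an exact 10-nt 5' overlap. Background, miRNA, siRNA, structural,
#' 3'UTR and TE-consensus reads are placed on their annotations with the
#' correct length windows.
#'
#' @param config A [synthetic_config()].
#' @param genome A `synthetic_genome` from [generate_genome()] (its
#'   `contigs` may already carry edits from earlier samples).
#' @param sample One row of `config$samples`.
#' @param site_map Environment carrying per-site U decisions across
#'   samples.
#' @param seed Optional seed (set by [generate_study()]).
#' @return List: `reads` (read tibble with `provenance` and `sample_id`),
#'   `spikes` (tibble `sample_id`, `spike_id`, `count`), `genome` (with
#'   accumulated 1U edits), `truth_pairs` (ping-pong partner read ids).
#' @export
generate_library <- function(config, genome, sample, site_map = new.env(),
                             seed = NULL) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (!is.null(seed)) set.seed(seed)
  contigs <- genome$contigs
  clens <- vapply(contigs, length, integer(1))
  sid <- sample$sample_id
  scale <- sample$global_scale
  ann <- genome$ann
  rows <- list()
  pairs <- list()
  rid <- 0L
  new_ids <- function(n) {
    out <- sprintf("%s_r%06d", sid, rid + seq_len(n))
    rid <<- rid + n
    out
  }

  pirna_reads <- function(chrom, lo, hi, n, strand_mode, provenance) {
    if (n <= 0) return(NULL)
    len <- draw_lengths(n, config$length_distribution)
    hi_eff <- pmin(hi, clens[[chrom]])
    start <- lo + floor(runif(n) * pmax(1, hi_eff - lo - len))
    strand <- switch(strand_mode,
                     uni_plus = rep("+", n), uni_minus = rep("-", n),
                     dual = sample(c("+", "-"), n, replace = TRUE))
    tibble(read_id = new_ids(n), chrom = chrom, start = as.integer(start),
           end = as.integer(start + len), strand = strand, n_hits = 1L,
           space = "genome", provenance = provenance)
  }

  # planted clusters (+ ping-pong partners)
  pc <- genome$truth$planted_clusters
  for (i in seq_len(nrow(pc))) {
    lambda <- pc$reads_per_kb[i] * pc$length[i] / 1000 * scale
    n <- rpois(1, lambda)
    base <- pirna_reads(pc$chrom[i], pc$start[i], pc$end[i], n,
                        pc$strand_mode[i], paste0("cluster:", pc$cluster_id[i]))
    rows[[length(rows) + 1L]] <- base
    frac <- if (isTRUE(sample$pingpong)) pc$pingpong_fraction[i] else 0
    npp <- round(frac * n)
    if (npp > 0 && !is.null(base)) {
      idx <- sample.int(n, npp)
      plen <- draw_lengths(npp, config$length_distribution)
      b <- base[idx, ]
      p5 <- if_else(b$strand == "+", b$start, b$end - 1L)
      q5 <- if_else(b$strand == "+", p5 + 9L, p5 - 9L)
      pstrand <- if_else(b$strand == "+", "-", "+")
      pstart <- if_else(pstrand == "-", q5 + 1L - plen, q5)
      pend <- pstart + plen
      ok <- pstart >= 0 & pend <= clens[[pc$chrom[i]]]
      partners <- tibble(read_id = new_ids(sum(ok)), chrom = pc$chrom[i],
                         start = as.integer(pstart[ok]),
                         end = as.integer(pend[ok]),
                         strand = pstrand[ok], n_hits = 1L, space = "genome",
                         provenance = paste0("cluster:", pc$cluster_id[i]))
      rows[[length(rows) + 1L]] <- partners
      pairs[[length(pairs) + 1L]] <- tibble(base_id = b$read_id[ok],
                                            partner_id = partners$read_id)
    }
  }

  # unclustered background
  nbg <- rpois(1, config$background_reads_per_kb * sum(clens) / 1000 * scale)
  if (nbg > 0) {
    ct <- sample(names(clens), nbg, replace = TRUE, prob = clens)
    for (cn in unique(ct)) {
      k <- sum(ct == cn)
      rows[[length(rows) + 1L]] <-
        pirna_reads(cn, 0L, clens[[cn]], k, "dual", "background")
    }
  }

  # feature-anchored reads: placed fully within a feature interval
  on_features <- function(tb, n, len_fun, provenance, strand_fun) {
    if (n <= 0 || !nrow(tb)) return(NULL)
    j <- sample.int(nrow(tb), n, replace = TRUE)
    len <- len_fun(n)
    w <- tb$end[j] - tb$start[j]
    len <- pmin(len, w)
    start <- tb$start[j] + floor(runif(n) * (w - len + 1))
    tibble(read_id = new_ids(n), chrom = tb$chrom[j],
           start = as.integer(start), end = as.integer(start + len),
           strand = strand_fun(tb$strand[j], n), n_hits = 1L,
           space = "genome", provenance = provenance)
  }
  own_strand <- function(s, n) s
  rand_strand <- function(s, n) sample(c("+", "-"), n, replace = TRUE)
  rows[[length(rows) + 1L]] <- on_features(
    ann$pre_mirna, config$mirna_reads,
    function(n) draw_lengths(n, MIRNA_LENGTHS), "mirna", own_strand)
  rows[[length(rows) + 1L]] <- on_features(
    ann$endo_sirna, config$sirna_reads,
    function(n) rep(21L, n), "sirna", rand_strand)
  structural_tb <- bind_rows(ann$rrna, ann$trna, ann$snorna, ann$snrna)
  rows[[length(rows) + 1L]] <- on_features(
    structural_tb, config$structural_reads,
    function(n) sample(23:30, n, replace = TRUE), "structural", rand_strand)
  rows[[length(rows) + 1L]] <- on_features(
    ann$utr3, round(config$utr3_pirna_reads * scale),
    function(n) draw_lengths(n, config$length_distribution), "utr3",
    rand_strand)

  # TE-consensus-space reads (23-30 nt piRNAs)
  nte <- round(config$te_pirna_reads * scale)
  if (nte > 0 && length(genome$te_seqs)) {
    tlen <- Biostrings::width(genome$te_seqs)
    j <- sample.int(length(genome$te_seqs), nte, replace = TRUE)
    len <- draw_lengths(nte, config$length_distribution)
    start <- floor(runif(nte) * (tlen[j] - len))
    rows[[length(rows) + 1L]] <- tibble(
      read_id = new_ids(nte), chrom = names(genome$te_seqs)[j],
      start = as.integer(start), end = as.integer(start + len),
      strand = sample(c("+", "-"), nte, replace = TRUE, prob = c(0.4, 0.6)),
      n_hits = 1L, space = "te_consensus", provenance = "te")
  }

  reads <- bind_rows(rows)
  reads$sample_id <- sid
  reads$condition <- sample$condition

  # 1U bias on piRNA-class genome reads (clusters, background, 3'UTR)
  pir <- reads$space == "genome" &
    reads$provenance %in% c("background", "utr3") |
    startsWith(reads$provenance, "cluster:")
  if (any(pir)) {
    p5 <- if_else(reads$strand[pir] == "+", reads$start[pir],
                  reads$end[pir] - 1L)
    contigs <- apply_u1(contigs, reads$chrom[pir], p5, reads$strand[pir],
                        config$u1_prob, site_map)
  }
  genome$contigs <- contigs

  spike <- as.integer(rmultinom(1, sample$spike_total,
                                rep(1, length(config$spike_ids))))
  spikes <- tibble(sample_id = sid, spike_id = config$spike_ids,
                   count = spike)
  list(reads = reads, spikes = spikes, genome = genome,
       truth_pairs = bind_rows(pairs))
}

#' Fill read sequences from the (edited) genome
#'
#' @param reads Read tibble.
#' @param genome A `synthetic_genome` (or DNAStringSet for genome-space
#'   only).
#' @return `reads` with `sequence` set to each read's 5'-to-3' sequence.
#' @export
extract_read_sequences <- function(reads, genome) {
  dss <- if (inherits(genome, "synthetic_genome"))
    c(contigs_to_dss(genome$contigs), genome$te_seqs) else genome
  s <- character(nrow(reads))
  if (nrow(reads)) {
    views <- Biostrings::DNAStringSet(Biostrings::subseq(
      dss[reads$chrom], start = reads$start + 1L, end = reads$end))
    neg <- reads$strand == "-"
    if (any(neg)) views[neg] <- Biostrings::reverseComplement(views[neg])
    s <- as.character(views)
  }
  reads$sequence <- unname(s)
  reads
}

#' Write reads as a SAM file
#'
#' Minimal single-end SAM: primary alignments only, `NH` tag from
#' `n_hits`, SEQ on the reference forward strand (reads' own orientation
#' is recovered on re-ingest by [read_alignments()]).
#'
#' @param reads Read tibble with sequences.
#' @param contig_lengths Named integer vector for the `@SQ` header lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, contig_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                       as.integer(contig_lengths))), con)
  if (nrow(reads)) {
    seq_fwd <- reads$sequence
    neg <- reads$strand == "-"
    if (any(neg) && !anyNA(seq_fwd[neg]))
      seq_fwd[neg] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads$sequence[neg])))
    seq_fwd[is.na(seq_fwd)] <- "*"
    len <- reads$end - reads$start
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
                       reads$read_id, if_else(neg, 16L, 0L), reads$chrom,
                       reads$start + 1L, len, seq_fwd, reads$n_hits), con)
  }
  invisible(path)
}

#' Generate a complete synthetic study
#'
#' One call produces everything the pipeline needs: genome FASTA,
#' annotation GFF3/BED, one SAM (+ BED6 mirror) per sample per alignment
#' space, a spike-in TSV, a ground-truth JSON and a manifest with file
#' checksums. Identical config + seed gives byte-identical outputs.
#'
#' @param config A [synthetic_config()] (>= 1 sample; duplicate sample ids
#'   are rejected).
#' @param out_dir Output directory (created).
#' @return Invisible list: `dir`, `manifest`, `genome` (final edited
#'   `synthetic_genome`), `reads` (all samples), `spikes`, `truth`.
#' @export
generate_study <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- generate_genome(config)
  site_map <- new.env(parent = emptyenv())
  all_reads <- list(); all_spikes <- list(); all_pairs <- list()
  for (i in seq_len(nrow(config$samples))) {
    lib <- generate_library(config, genome, config$samples[i, ], site_map,
                            seed = (config$seed + 7919L * i) %% 2147483647L)
    genome <- lib$genome
    all_reads[[i]] <- lib$reads
    all_spikes[[i]] <- lib$spikes
    all_pairs[[i]] <- lib$truth_pairs
  }
  reads <- extract_read_sequences(bind_rows(all_reads), genome)
  spikes <- bind_rows(all_spikes)
  write_synthetic_genome(genome, out_dir)
  clens <- vapply(genome$contigs, length, integer(1))
  telens <- setNames(Biostrings::width(genome$te_seqs),
                     names(genome$te_seqs))
  files <- c(genome = "genome.fa", annotations = "annotations.gff3",
             annotation_bed = "annotations.bed", spikes = "spikes.tsv",
             truth = "truth.json")
  readr::write_tsv(spikes, file.path(out_dir, "spikes.tsv"))
  sample_files <- list()
  for (sid in config$samples$sample_id) {
    rg <- filter(reads, .data$sample_id == sid, .data$space == "genome")
    rt <- filter(reads, .data$sample_id == sid, .data$space == "te_consensus")
    fg <- paste0(sid, ".genome.sam"); ft <- paste0(sid, ".te.sam")
    fb <- paste0(sid, ".genome.bed")
    write_sam(rg, clens, file.path(out_dir, fg))
    write_sam(rt, telens, file.path(out_dir, ft))
    write_bed(mutate(rg, name = .data$read_id, score = 0),
              file.path(out_dir, fb))
    sample_files[[sid]] <- list(genome_sam = fg, te_sam = ft, genome_bed = fb)
  }
  truth <- list(
    planted_clusters = genome$truth$planted_clusters,
    samples = config$samples,
    pingpong_pairs = bind_rows(all_pairs),
    provenance = count(reads, .data$sample_id, .data$provenance))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE)
  all_files <- c(unname(files), unlist(lapply(sample_files, unlist)))
  manifest <- list(seed = config$seed,
                   files = as.list(setNames(
                     unname(tools::md5sum(file.path(out_dir, all_files))),
                     all_files)),
                   samples = sample_files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dir = out_dir, manifest = manifest, genome = genome,
                 reads = reads, spikes = spikes, truth = truth))
}
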