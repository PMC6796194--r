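# Core coordinate conventions and format I/O.
#
# All intervals in this package are 0-based half-open (BED-compatible):
# `start` is the first covered base, `end` is one past the last. GFF3 input
# (1-based inclusive) is converted on ingest and never stored. Strand is one
# of "+", "-", "*".

VALID_STRANDS <- c("+", "-", "*")

#' Build an interval tibble
#'
#' Intervals are the common currency of the package: a tibble with columns
#' `chrom`, `start`, `end` (0-based half-open) and `strand` ("+", "-", "*").
#' This constructor validates the invariants (`0 <= start < end`, non-empty
#' `chrom`) and is used internally by all readers.
#'
#' @param chrom Character vector of contig names.
#' @param start,end Integer vectors, 0-based half-open.
#' @param strand Character vector over "+", "-", "*". Recycled if length 1.
#' @param ... Further columns (e.g. `name`) passed to [tibble::tibble()].
#' @return A tibble with at least columns `chrom`, `start`, `end`, `strand`.
#' @export
interval_tbl <- function(chrom, start, end, strand = "*", ...) {
  out <- tibble(chrom = as.character(chrom), start = as.integer(start),
                end = as.integer(end), strand = strand, ...)
  validate_intervals(out)
  out
}

validate_intervals <- function(x, what = "interval") {
  if (!all(c("chrom", "start", "end", "strand") %in% names(x)))
    abort(paste0(what, " table must have columns chrom, start, end, strand"))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    abort(sprintf("%s %d: invalid coordinates (need 0 <= start < end, got [%s, %s))",
                  what, bad[1], x$start[bad[1]], x$end[bad[1]]))
  if (any(!nzchar(x$chrom)) || anyNA(x$chrom))
    abort(paste0(what, ": chrom must be non-empty"))
  if (!all(x$strand %in% VALID_STRANDS))
    abort(paste0(what, ': strand must be one of "+", "-", "*"'))
  invisible(x)
}

# interval tibble -> GRanges (1-based closed internally to Bioconductor)
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = x[["strand"]] %||% "*"
  )
}

# findOverlaps/countOverlaps across tables whose contig universes differ
# legitimately (e.g. reads vs a single-category annotation) warn about
# disjoint seqlevels; these wrappers silence only that notice.
find_overlaps_q <- function(query, subject) {
  suppressWarnings(GenomicRanges::findOverlaps(query, subject,
                                               ignore.strand = TRUE))
}
count_overlaps_q <- function(query, subject) {
  suppressWarnings(GenomicRanges::countOverlaps(query, subject,
                                                ignore.strand = TRUE))
}

granges_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Read a BED3/BED6 file into an interval tibble
#'
#' @param path Path to a BED file. Coordinates are kept exactly as BED
#'   encodes them (0-based half-open); strand "." becomes "*".
#' @return Interval tibble with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) abort(paste0("BED parse error in ", path, ": ",
                                                  conditionMessage(e))))
  w <- IRanges::width(gr)
  if (any(w <= 0))
    abort(sprintf("BED parse error in %s, record %d: zero-length interval",
                  path, which(w <= 0)[1]))
  out <- granges_to_tbl(gr)
  nm <- S4Vectors::mcols(gr)$name
  sc <- S4Vectors::mcols(gr)$score
  out$name <- if (is.null(nm)) paste0("iv", seq_len(nrow(out))) else as.character(nm)
  out$score <- if (is.null(sc)) 0 else as.numeric(sc)
  select(out, "chrom", "start", "end", "name", "score", "strand")
}

#' Write an interval tibble as BED6
#'
#' @param x Interval tibble (columns `chrom`, `start`, `end`, `strand`;
#'   optional `name`, `score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  gr <- as_granges(x)
  S4Vectors::mcols(gr)$name <- if ("name" %in% names(x)) x$name else paste0("iv", seq_len(nrow(x)))
  S4Vectors::mcols(gr)$score <- if ("score" %in% names(x)) x$score else 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read GFF3 features into an interval tibble
#'
#' Coordinates are converted from GFF3's 1-based inclusive convention to the
#' package's 0-based half-open convention on ingest.
#'
#' @param path Path to a GFF3 file.
#' @param feature_types Optional character vector; keep only these `type`s.
#' @return Tibble with columns `chrom`, `start`, `end`, `strand`, `type`,
#'   `ID`, `Parent`, `name`.
#' @export
read_gff3 <- function(path, feature_types = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  gr <- tryCatch(rtracklayer::import(path, format = "GFF3"),
                 error = function(e) abort(paste0("GFF3 parse error in ", path, ": ",
                                                  conditionMessage(e))))
  out <- granges_to_tbl(gr)
  mc <- S4Vectors::mcols(gr)
  out$type <- as.character(mc$type)
  out$ID <- if (is.null(mc$ID)) NA_character_ else as.character(mc$ID)
  par <- mc$Parent
  out$Parent <- if (is.null(par)) NA_character_ else
    vapply(as.list(par), function(p) if (length(p)) as.character(p)[1] else NA_character_, character(1))
  out$name <- if (is.null(mc$Name)) out$ID else dplyr::coalesce(as.character(mc$Name), out$ID)
  if (!is.null(feature_types)) out <- filter(out, .data$type %in% feature_types)
  out
}

#' Assemble an annotation set
#'
#' The annotation universe used by classification and quantification:
#' interval tibbles per category plus gene models with 3'UTRs, the TE
#' consensus name set, and spike-in identifiers.
#'
#' @param pre_mirna,endo_sirna,rrna,trna,snorna,snrna,te_insertions,canonical_clusters
#'   Interval tibbles (possibly empty).
#' @param genes Tibble `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param exons,utr3 Tibbles like `genes` with one row per exon / 3'UTR
#'   interval (column `gene_id` links to `genes`).
#' @param te_consensus_names Character vector of TE family names.
#' @param spike_in_ids Character vector of spike-in identifiers.
#' @return An object of class `annotation_set` (a named list).
#' @export
annotation_set <- function(pre_mirna = empty_ivl(), endo_sirna = empty_ivl(),
                           rrna = empty_ivl(), trna = empty_ivl(),
                           snorna = empty_ivl(), snrna = empty_ivl(),
                           te_insertions = empty_ivl(),
                           canonical_clusters = empty_ivl(),
                           genes = empty_gene(), exons = empty_gene(),
                           utr3 = empty_gene(),
                           te_consensus_names = character(),
                           spike_in_ids = character()) {
  ann <- list(pre_mirna = pre_mirna, endo_sirna = endo_sirna, rrna = rrna,
              trna = trna, snorna = snorna, snrna = snrna,
              te_insertions = te_insertions,
              canonical_clusters = canonical_clusters,
              genes = genes, exons = exons, utr3 = utr3,
              te_consensus_names = te_consensus_names,
              spike_in_ids = spike_in_ids)
  for (cat in ANNOTATION_CATEGORIES)
    if (nrow(ann[[cat_slot(cat)]])) validate_intervals(ann[[cat_slot(cat)]], cat)
  if (nrow(ann$utr3)) {
    chk <- inner_join(ann$utr3, ann$genes, by = "gene_id",
                      suffix = c("", ".gene"))
    if (any(chk$start < chk$start.gene | chk$end > chk$end.gene))
      abort("annotation_set: 3'UTR intervals must lie within their gene span")
  }
  contigs <- unique(unlist(lapply(ann[vapply(ann, is.data.frame, logical(1))],
                                  function(d) d$chrom)))
  if (length(intersect(spike_in_ids, contigs)))
    abort("annotation_set: spike_in_ids must be disjoint from contig names")
  structure(ann, class = "annotation_set")
}

empty_ivl <- function() tibble(chrom = character(), start = integer(),
                               end = integer(), strand = character(),
                               name = character())
empty_gene <- function() tibble(gene_id = character(), chrom = character(),
                                start = integer(), end = integer(),
                                strand = character())

ANNOTATION_CATEGORIES <- c("pre_mirna", "endo_sirna", "rrna", "trna",
                           "snorna", "snrna", "te_insertion", "utr3",
                           "exon", "canonical_cluster")

cat_slot <- function(cat) {
  switch(cat, te_insertion = "te_insertions",
         canonical_cluster = "canonical_clusters", exon = "exons", cat)
}

#' Read an annotation set from a GFF3 file
#'
#' Recognised feature types: `pre_miRNA`, `endo_siRNA`, `rRNA`, `tRNA`,
#' `snoRNA`, `snRNA`, `transposable_element`, `piRNA_cluster`, `gene`,
#' `exon`, `three_prime_UTR`. Gene rows must carry an `ID` attribute and
#' exon/UTR rows a `Parent` attribute.
#'
#' @param path GFF3 path.
#' @param te_consensus_names,spike_in_ids Passed through to
#'   [annotation_set()].
#' @return An `annotation_set`.
#' @export
read_annotations <- function(path, te_consensus_names = character(),
                             spike_in_ids = character()) {
  g <- read_gff3(path)
  if (!nrow(g)) return(annotation_set(te_consensus_names = te_consensus_names,
                                      spike_in_ids = spike_in_ids))
  take <- function(tp) {
    d <- filter(g, .data$type == tp)
    tibble(chrom = d$chrom, start = d$start, end = d$end, strand = d$strand,
           name = dplyr::coalesce(d$name, paste0(tp, seq_len(nrow(d)))))
  }
  gene_rows <- filter(g, .data$type == "gene")
  if (nrow(gene_rows) && anyNA(gene_rows$ID))
    abort("GFF3 parse error: gene record without ID attribute")
  genes <- tibble(gene_id = gene_rows$ID, chrom = gene_rows$chrom,
                  start = gene_rows$start, end = gene_rows$end,
                  strand = gene_rows$strand)
  child <- function(tp) {
    d <- filter(g, .data$type == tp)
    if (nrow(d) && anyNA(d$Parent))
      abort(paste0("GFF3 parse error: ", tp, " record without Parent attribute"))
    tibble(gene_id = d$Parent, chrom = d$chrom, start = d$start,
           end = d$end, strand = d$strand)
  }
  annotation_set(
    pre_mirna = take("pre_miRNA"), endo_sirna = take("endo_siRNA"),
    rrna = take("rRNA"), trna = take("tRNA"), snorna = take("snoRNA"),
    snrna = take("snRNA"), te_insertions = take("transposable_element"),
    canonical_clusters = take("piRNA_cluster"),
    genes = genes, exons = child("exon"), utr3 = child("three_prime_UTR"),
    te_consensus_names = te_consensus_names, spike_in_ids = spike_in_ids
  )
}

#' Read aligned small-RNA reads from SAM/BAM or BED
#'
#' One row per primary alignment. Strand comes from the SAM flag, `n_hits`
#' from the `NH` tag when present (1 otherwise); unmapped and secondary
#' records are skipped and alignments of length <= 15 nt are dropped (the
#' post-trimming small-RNA range starts above 15 nt). The stored `sequence`
#' is the read in its own 5'-to-3' orientation (reverse-complemented from
#' the SAM field for minus-strand alignments).
#'
#' @param path SAM, BAM, or BED6 file.
#' @param space `"genome"` or `"te_consensus"` -- which reference the reads
#'   were aligned against. For TE-consensus space, `chrom` holds TE names.
#' @return A read tibble: `read_id`, `chrom`, `start`, `end`, `strand`,
#'   `n_hits`, `space`, `sequence`.
#' @export
read_alignments <- function(path, space = c("genome", "te_consensus")) {
  space <- match.arg(space)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    b <- read_bed(path)
    out <- tibble(read_id = b$name, chrom = b$chrom, start = b$start,
                  end = b$end, strand = b$strand, n_hits = 1L,
                  space = space, sequence = NA_character_)
    return(filter(out, .data$end - .data$start > 15L))
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE),
      error = function(e) abort(paste0("SAM parse error in ", path, ": ",
                                       conditionMessage(e))))
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE),
    what = c("qname", "seq"), tag = "NH")
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  if (!length(ga)) {
    return(tibble(read_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  n_hits = integer(), space = character(),
                  sequence = character()))
  }
  seqs <- S4Vectors::mcols(ga)$seq
  str <- as.character(GenomicAlignments::strand(ga))
  # SAM stores SEQ on the reference forward strand; recover read orientation
  bio <- as.character(seqs)
  neg <- str == "-"
  if (any(neg))
    bio[neg] <- as.character(Biostrings::reverseComplement(seqs[neg]))
  bio[!nzchar(bio) | bio == "*"] <- NA_character_
  nh <- S4Vectors::mcols(ga)$NH
  out <- tibble(
    read_id = S4Vectors::mcols(ga)$qname,
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga) - 1L,
    end = GenomicAlignments::end(ga),
    strand = str,
    n_hits = as.integer(if (is.null(nh)) 1L else dplyr::coalesce(nh, 1L)),
    space = space,
    sequence = bio)
  filter(out, .data$end - .data$start > 15L)
}

#' Read a spike-in count table
#'
#' @param path TSV with columns `sample_id`, `spike_id`, `count`.
#' @return Tibble with those columns; counts validated non-negative.
#' @export
read_spike_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), spike_id = readr::col_character(),
    count = readr::col_integer()))
  if (any(x$count < 0)) abort("spike table: counts must be >= 0")
  x
}

#' Flag annotation-category overlaps per read
#'
#' Adds one logical column per annotation category (`pre_mirna`,
#' `endo_sirna`, `rrna`, `trna`, `snorna`, `snrna`, `te_insertion`, `utr3`,
#' `exon`, `canonical_cluster`): TRUE when the read shares >= 1 bp with any
#' interval of that category on the same contig. Overlap is strand-blind at
#' this layer; strand is interpreted by downstream callers. TE-consensus
#' space reads get all-FALSE flags (TE annotations live in genome space).
#'
#' @param reads Read tibble (see [read_alignments()]).
#' @param ann An [annotation_set()].
#' @return `reads` with the ten flag columns appended.
#' @export
annotate_reads <- function(reads, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  if (!nrow(reads)) {
    for (cat in ANNOTATION_CATEGORIES) reads[[cat]] <- logical(0)
    return(reads)
  }
  gr <- as_granges(reads)
  genome_space <- reads$space == "genome"
  for (cat in ANNOTATION_CATEGORIES) {
    tab <- ann[[cat_slot(cat)]]
    if (nrow(tab)) {
      hit <- count_overlaps_q(gr, as_granges(tab)) > 0
      reads[[cat]] <- hit & genome_space
    } else {
      reads[[cat]] <- FALSE
    }
  }
  reads
}

#' Annotation categories overlapping one read
#'
#' @param read A one-row read tibble in genome space.
#' @param ann An [annotation_set()].
#' @return Character vector of category labels overlapping the read by
#'   >= 1 bp (strand-blind).
#' @export
overlapping_categories <- function(read, ann) {
  stopifnot(nrow(read) == 1)
  if (read$space != "genome")
    abort("overlapping_categories: read must be in genome space")
  flags <- annotate_reads(read, ann)
  ANNOTATION_CATEGORIES[vapply(ANNOTATION_CATEGORIES,
                               function(cat) isTRUE(flags[[cat]][1]), logical(1))]
}

#' Per-base read coverage over a region
#'
#' @param reads Read tibble.
#' @param region One-row interval tibble (or list with `chrom`, `start`,
#'   `end`).
#' @param strand_mode Count reads on `"both"` strands (default), or only
#'   `"plus"` / `"minus"`.
#' @param pseudo_count Constant added at every position (a pseudo-count of
#'   one is the convention for log-transformed coverage displays).
#' @return Integer vector of length `end - start`; position `i` is the
#'   number of selected reads covering base `start + i - 1`, plus
#'   `pseudo_count`.
#' @export
coverage_track <- function(reads, region, strand_mode = c("both", "plus", "minus"),
                           pseudo_count = 0L) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(pseudo_count >= 0)
  width <- region$end[1] - region$start[1]
  sel <- filter(reads, .data$chrom == region$chrom[1])
  if (strand_mode == "plus") sel <- filter(sel, .data$strand == "+")
  if (strand_mode == "minus") sel <- filter(sel, .data$strand == "-")
  if (!nrow(sel)) return(rep(as.integer(pseudo_count), width))
  ir <- IRanges::IRanges(start = sel$start + 1L, end = sel$end)
  ir <- IRanges::restrict(ir, start = region$start[1] + 1L, end = region$end[1])
  ir <- ir[IRanges::width(ir) > 0]
  cvg <- IRanges::coverage(IRanges::shift(ir, -region$start[1]), width = width)
  as.integer(cvg) + as.integer(pseudo_count)
}
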