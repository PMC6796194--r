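# Small-RNA biotype classification by length + annotation rules.

#' Classifier length windows
#'
#' The length windows the biotype rules use, in nucleotides: miRNAs are
#' reads of 24 nt or shorter over annotated pre-miRNA loci; endo-siRNAs are
#' 22 nt or shorter over endo-siRNA loci, or exactly 21 nt on transposons;
#' piRNAs are the remaining 23-30 nt reads; cluster discovery draws its own
#' wider 23-35 nt window.
#'
#' @param mirna_max_len,sirna_max_len,sirna_te_exact_len,pirna_min_len,pirna_max_len,discovery_max_len
#'   Integer window bounds (defaults 24, 22, 21, 23, 30, 35).
#' @return A list of class `classifier_params`.
#' @export
classifier_params <- function(mirna_max_len = 24L, sirna_max_len = 22L,
                              sirna_te_exact_len = 21L, pirna_min_len = 23L,
                              pirna_max_len = 30L, discovery_max_len = 35L) {
  p <- list(mirna_max_len = as.integer(mirna_max_len),
            sirna_max_len = as.integer(sirna_max_len),
            sirna_te_exact_len = as.integer(sirna_te_exact_len),
            pirna_min_len = as.integer(pirna_min_len),
            pirna_max_len = as.integer(pirna_max_len),
            discovery_max_len = as.integer(discovery_max_len))
  if (any(unlist(p) <= 0)) abort("classifier_params: all windows must be positive")
  if (!(p$pirna_min_len <= p$pirna_max_len &&
        p$pirna_max_len <= p$discovery_max_len))
    abort("classifier_params: need pirna_min_len <= pirna_max_len <= discovery_max_len")
  structure(p, class = "classifier_params")
}

BIOTYPE_LABELS <- c("structural_excluded", "miRNA", "siRNA", "piRNA", "other")

#' Classify reads into small-RNA biotypes
#'
#' Rules fire in fixed precedence per read: (1) overlap with any structural
#' RNA annotation (rRNA, tRNA, snoRNA, snRNA) excludes the read; (2) reads
#' of `mirna_max_len` or shorter overlapping a pre-miRNA are miRNAs;
#' (3) reads of `sirna_max_len` or shorter overlapping an endo-siRNA locus,
#' or exactly `sirna_te_exact_len` nt on a transposon (TE-consensus
#' alignment or genomic TE insertion), are siRNAs; (4) remaining reads of
#' `pirna_min_len`-`pirna_max_len` nt are piRNAs; (5) anything else is
#' `other`. Overlap tests are strand-blind.
#'
#' @param reads Read tibble ([read_alignments()]); all lengths must exceed
#'   15 nt.
#' @param ann An [annotation_set()].
#' @param params A [classifier_params()].
#' @return `reads` with columns `biotype` (factor over the five labels) and
#'   `basis` (the rule code that fired) appended.
#' @export
classify_reads <- function(reads, ann, params = classifier_params()) {
  f <- annotate_reads(reads, ann)
  len <- f$end - f$start
  if (any(len <= 15)) abort("classify_reads: read lengths must exceed 15 nt")
  structural <- f$rrna | f$trna | f$snorna | f$snrna
  mirna <- !structural & len <= params$mirna_max_len & f$pre_mirna
  on_te <- f$space == "te_consensus" | f$te_insertion
  sirna <- !structural & !mirna &
    ((len <= params$sirna_max_len & f$endo_sirna) |
       (len == params$sirna_te_exact_len & on_te))
  pirna <- !structural & !mirna & !sirna &
    len >= params$pirna_min_len & len <= params$pirna_max_len
  label <- rep("other", nrow(f))
  label[pirna] <- "piRNA"
  label[sirna] <- "siRNA"
  label[mirna] <- "miRNA"
  label[structural] <- "structural_excluded"
  basis <- dplyr::case_when(
    structural ~ "structural_overlap",
    mirna ~ "len<=miRNA_max & pre_miRNA",
    sirna & len == params$sirna_te_exact_len & on_te &
      !(len <= params$sirna_max_len & f$endo_sirna) ~ "len==21 & transposon",
    sirna ~ "len<=siRNA_max & endo_siRNA",
    pirna ~ "piRNA_length_window",
    .default = "no_rule"
  )
  reads$biotype <- factor(label, levels = BIOTYPE_LABELS)
  reads$basis <- basis
  reads
}

#' Per-biotype read counts for a library
#'
#' @param reads Read tibble; a `sample_id` column, if present, is kept as a
#'   grouping variable.
#' @param ann An [annotation_set()].
#' @param params A [classifier_params()].
#' @return Tibble with one row per (sample, biotype), columns `biotype` and
#'   `n`; every biotype appears (zero-filled), and counts sum to the number
#'   of reads.
#' @export
classify_library <- function(reads, ann, params = classifier_params()) {
  cl <- classify_reads(reads, ann, params)
  grp <- intersect("sample_id", names(cl))
  out <- count(cl, across(dplyr::all_of(c(grp, "biotype"))), .drop = FALSE)
  arrange(out, across(dplyr::all_of(c(grp, "biotype"))))
}

#' Select putative piRNA reads for counting or discovery
#'
#' Two read universes are used downstream: feature *counting* uses
#' uniquely-mapping reads classified as piRNA (23-30 nt, `n_hits == 1`);
#' cluster *discovery* uses the wider 23-35 nt window, keeps multi-mappers,
#' and excludes only reads claimed by the structural/miRNA/siRNA rules.
#'
#' @param reads Genome-space read tibble.
#' @param ann An [annotation_set()].
#' @param params A [classifier_params()].
#' @param purpose `"counting"` or `"discovery"`.
#' @return The selected subset of `reads` (with `biotype` column attached).
#' @export
select_putative_pirnas <- function(reads, ann, params = classifier_params(),
                                   purpose = c("counting", "discovery")) {
  purpose <- match.arg(purpose)
  cl <- classify_reads(reads, ann, params)
  cl <- filter(cl, .data$space == "genome")
  len <- cl$end - cl$start
  if (purpose == "counting") {
    filter(cl, .data$biotype == "piRNA",
           .data$end - .data$start >= params$pirna_min_len,
           .data$end - .data$start <= params$pirna_max_len,
           .data$n_hits == 1L)
  } else {
    filter(cl, !(.data$biotype %in% c("structural_excluded", "miRNA", "siRNA")),
           .data$end - .data$start >= params$pirna_min_len,
           .data$end - .data$start <= params$discovery_max_len)
  }
}
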