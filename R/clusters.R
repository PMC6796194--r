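# De novo piRNA cluster discovery by sliding-window read-density scan,
# canonical-cluster fragment harmonization, and reference comparison.

#' Cluster discovery parameters
#'
#' Defaults follow the published procedure: read regions within 250 nt of
#' one another are merged; regions with fewer than three unique piRNA reads
#' per kilobase are discarded; surviving regions within 1,000 nt are merged;
#' and only clusters strictly greater than 2,000 nt are retained. Canonical
#' cluster fragments separated by less than 25 kb are collapsed.
#'
#' @param seed_merge_gap,region_merge_gap Merge gaps in nt (inclusive: a gap
#'   of exactly the value is merged).
#' @param min_density Minimum unique reads per kilobase.
#' @param min_size Minimum cluster length, nt; strict (a final region of
#'   exactly `min_size` is dropped).
#' @param canonical_collapse_gap Canonical fragment collapse gap, nt;
#'   strict (a gap of exactly the value is *not* merged).
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(seed_merge_gap = 250L, min_density = 3.0,
                           region_merge_gap = 1000L, min_size = 2000L,
                           canonical_collapse_gap = 25000L) {
  p <- list(seed_merge_gap = as.integer(seed_merge_gap),
            min_density = as.numeric(min_density),
            region_merge_gap = as.integer(region_merge_gap),
            min_size = as.integer(min_size),
            canonical_collapse_gap = as.integer(canonical_collapse_gap))
  if (any(unlist(p) < 0) || p$min_size <= 0)
    abort("cluster_params: gaps/density must be >= 0 and min_size > 0")
  structure(p, class = "cluster_params")
}

#' Collapse reads to unique alignments
#'
#' "Unique reads" for density purposes are distinct
#' (chrom, start, end, strand) tuples; `multiplicity` records how many
#' input alignments collapsed onto each.
#'
#' @param reads Genome-space read tibble.
#' @return Tibble `chrom`, `start`, `end`, `strand`, `multiplicity`.
#' @export
dedupe_reads <- function(reads) {
  if (!nrow(reads))
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), multiplicity = integer()))
  out <- count(reads, .data$chrom, .data$start, .data$end, .data$strand,
               name = "multiplicity")
  arrange(out, .data$chrom, .data$start, .data$end, .data$strand)
}

# merge intervals whose gap (0-based half-open) is <= gap, per chrom
reduce_gap <- function(gr, gap) {
  GenomicRanges::reduce(gr, min.gapwidth = gap + 1L, ignore.strand = TRUE)
}

#' Discover piRNA clusters by read-density scan
#'
#' The scan works per contig on deduplicated reads: (1) seed regions are
#' the union of read footprints; (2) seeds within `seed_merge_gap` nt are
#' merged; (3) regions with fewer than `min_density` unique reads per kb
#' are discarded; (4) survivors within `region_merge_gap` nt are merged;
#' (5) only regions strictly longer than `min_size` nt are kept. Counts
#' and density are recomputed over each final extent.
#'
#' @param reads Putative piRNA reads for discovery (23-35 nt; see
#'   [select_putative_pirnas()]). Multi-mappers are welcome here.
#' @param params A [cluster_params()].
#' @return Tibble of cluster calls sorted by (chrom, start), columns
#'   `chrom`, `start`, `end`, `strand` ("*"), `n_unique_reads`, `density`
#'   (unique reads per kb), `n_total_reads`, `plus_fraction`, `source`
#'   ("discovered"). Intervals are non-overlapping.
#' @export
discover_clusters <- function(reads, params = cluster_params()) {
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), n_unique_reads = integer(),
                  density = numeric(), n_total_reads = integer(),
                  plus_fraction = numeric(), source = character())
  uni <- dedupe_reads(reads)
  if (!nrow(uni)) return(empty)
  gr <- as_granges(uni)
  seeds <- GenomicRanges::reduce(gr, ignore.strand = TRUE)          # step 1
  merged <- reduce_gap(seeds, params$seed_merge_gap)                # step 2
  n_uni <- count_overlaps_q(merged, gr)
  dens <- n_uni / (GenomicRanges::width(merged) / 1000)
  merged <- merged[dens >= params$min_density]                      # step 3
  merged <- reduce_gap(merged, params$region_merge_gap)             # step 4
  merged <- merged[GenomicRanges::width(merged) > params$min_size]  # step 5
  if (!length(merged)) return(empty)
  n_uni <- count_overlaps_q(merged, gr)
  hits <- find_overlaps_q(merged, gr)
  mult <- uni$multiplicity
  plus <- uni$strand == "+"
  tot <- as.integer(tapply(mult[S4Vectors::subjectHits(hits)],
                           factor(S4Vectors::queryHits(hits), seq_along(merged)),
                           sum, default = 0L))
  plus_tot <- as.numeric(tapply(mult[S4Vectors::subjectHits(hits)] *
                                  plus[S4Vectors::subjectHits(hits)],
                                factor(S4Vectors::queryHits(hits), seq_along(merged)),
                                sum, default = 0))
  out <- granges_to_tbl(merged)
  out$strand <- "*"
  out$n_unique_reads <- n_uni
  out$density <- n_uni / ((out$end - out$start) / 1000)
  out$n_total_reads <- tot
  out$plus_fraction <- ifelse(tot > 0, plus_tot / tot, NA_real_)
  out$source <- "discovered"
  arrange(out, .data$chrom, .data$start)
}

#' Harmonize canonical piRNA cluster fragments
#'
#' Per cluster name: overlapping fragments are collapsed, fragments
#' separated by less than `collapse_gap` are merged, and among the
#' remaining disjoint fragments only the largest is kept (ties broken by
#' smaller start coordinate).
#'
#' @param fragments Tibble with columns `name`, `chrom`, `start`, `end`
#'   (strand optional).
#' @param collapse_gap Merge threshold in nt, strict (default 25,000).
#' @return Tibble with one row per cluster name: `name`, `chrom`, `start`,
#'   `end`, `strand`. Names with no fragments are omitted with a warning.
#' @export
harmonize_canonical <- function(fragments, collapse_gap = 25000L) {
  stopifnot(all(c("name", "chrom", "start", "end") %in% names(fragments)))
  if (!"strand" %in% names(fragments)) fragments$strand <- "*"
  nms <- unique(fragments$name)
  rows <- lapply(nms, function(nm) {
    fr <- filter(fragments, .data$name == nm)
    if (!nrow(fr)) {
      warn(paste0("harmonize_canonical: no fragments for ", nm, "; omitted"))
      return(NULL)
    }
    # merge iff gap < collapse_gap (strict), i.e. gap <= collapse_gap - 1
    merged <- granges_to_tbl(reduce_gap(as_granges(fr), collapse_gap - 1L))
    merged <- arrange(merged, desc(.data$end - .data$start), .data$start)
    mutate(merged[1, ], name = nm, strand = "*")
  })
  out <- bind_rows(rows)
  if (!nrow(out)) return(tibble(name = character(), chrom = character(),
                                start = integer(), end = integer(),
                                strand = character()))
  select(out, "name", "chrom", "start", "end", "strand")
}

#' Compare discovered clusters against a reference set
#'
#' @param calls Cluster tibble (e.g. from [discover_clusters()]).
#' @param reference Interval tibble of reference clusters.
#' @return A list of class `overlap_report`: `reference_covered_fraction`
#'   (fraction of reference clusters overlapped >= 1 bp by some call),
#'   `novel_call_fraction` (fraction of calls overlapping no reference),
#'   and `per_reference` (tibble with each reference interval's best
#'   overlap length in bp).
#' @export
compare_to_reference <- function(calls, reference) {
  gc <- as_granges(calls)
  gref <- as_granges(reference)
  ref_cov <- if (length(gref))
    mean(count_overlaps_q(gref, gc) > 0) else NA_real_
  novel <- if (length(gc))
    mean(count_overlaps_q(gc, gref) == 0) else NA_real_
  best <- rep(0L, length(gref))
  if (length(gref) && length(gc)) {
    hits <- find_overlaps_q(gref, gc)
    if (length(hits)) {
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(gref)[S4Vectors::queryHits(hits)],
        IRanges::ranges(gc)[S4Vectors::subjectHits(hits)]))
      agg <- tapply(ov, factor(S4Vectors::queryHits(hits), seq_along(gref)),
                    max, default = 0L)
      best <- as.integer(agg)
    }
  }
  per_ref <- granges_to_tbl(gref)
  per_ref$best_overlap_bp <- best
  structure(list(reference_covered_fraction = ref_cov,
                 novel_call_fraction = novel,
                 per_reference = per_ref),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("cluster overlap report: %.1f%% of reference covered; %.1f%% of calls novel\n",
              100 * x$reference_covered_fraction, 100 * x$novel_call_fraction))
  invisible(x)
}

#' @method glance overlap_report
#' @export
glance.overlap_report <- function(x, ...) {
  tibble(reference_covered_fraction = x$reference_covered_fraction,
         novel_call_fraction = x$novel_call_fraction,
         n_reference = nrow(x$per_reference))
}

#' Classify cluster strand composition
#'
#' Clusters with >= 90% of reads on the plus strand are uni-strand plus,
#' <= 10% uni-strand minus, anything in between dual-strand.
#'
#' @param clusters Cluster tibble.
#' @param reads Read tibble used to compute per-cluster plus fractions
#'   (multiplicity-weighted over reads overlapping each cluster). If
#'   `clusters` already carries `plus_fraction` and `reads` is NULL, that
#'   column is used.
#' @return `clusters` with a `strandedness` column in
#'   {"uni_plus", "uni_minus", "dual"}.
#' @export
cluster_strandedness <- function(clusters, reads = NULL) {
  pf <- clusters[["plus_fraction"]]
  if (!is.null(reads)) {
    gr <- as_granges(clusters)
    gread <- as_granges(reads)
    hits <- find_overlaps_q(gr, gread)
    plus <- reads$strand == "+"
    nread <- as.integer(tapply(rep(1L, length(hits)),
                               factor(S4Vectors::queryHits(hits), seq_along(gr)),
                               sum, default = 0L))
    nplus <- as.integer(tapply(plus[S4Vectors::subjectHits(hits)],
                               factor(S4Vectors::queryHits(hits), seq_along(gr)),
                               sum, default = 0L))
    if (any(nread == 0))
      abort("cluster_strandedness: cluster with zero reads; cannot assess")
    pf <- nplus / nread
  }
  if (is.null(pf) || anyNA(pf))
    abort("cluster_strandedness: need reads or a plus_fraction column")
  clusters$strandedness <- dplyr::case_when(
    pf >= 0.9 ~ "uni_plus",
    pf <= 0.1 ~ "uni_minus",
    .default = "dual")
  clusters
}
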