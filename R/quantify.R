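# Feature counting, CPM/RPKM, miRNA/spike-in normalization, expression
# filtering, fold-change + BH-FDR significance calling, and the 3'UTR
# piRNA producer-class report.

#' Differential-expression parameters
#'
#' @param fc_threshold Minimum absolute fold change (default 2; inclusive).
#' @param fdr_threshold Maximum BH FDR (default 0.05; inclusive).
#' @param cpm_cutoff CPM expression cutoff (the published small-RNA
#'   analyses used 20 for piRNA clusters, 700 for antisense 3'UTRs and
#'   1,000 for sense 3'UTRs; mRNA used 10).
#' @param min_samples Minimum number of samples above the CPM cutoff
#'   (default 3: features above the cutoff in fewer than three samples are
#'   excluded).
#' @param pseudo_count Pseudo-count for log transforms (default 1).
#' @return A list of class `dge_params`.
#' @export
dge_params <- function(fc_threshold = 2, fdr_threshold = 0.05,
                       cpm_cutoff = 20, min_samples = 3L, pseudo_count = 1) {
  if (fc_threshold < 1) abort("dge_params: fc_threshold must be >= 1")
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    abort("dge_params: fdr_threshold must be in (0, 1)")
  structure(list(fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
                 cpm_cutoff = cpm_cutoff, min_samples = as.integer(min_samples),
                 pseudo_count = pseudo_count), class = "dge_params")
}

#' Count reads over features
#'
#' A read increments every feature it overlaps by >= 1 bp (no fractional
#' assignment; overlapping features each get the read). `strand_mode`
#' restricts to reads on the feature's strand ("sense"), the opposite
#' strand ("antisense"), or either ("both").
#'
#' @param reads Read tibble (for the published counting rules, pass the
#'   deduplicated unique-genomic 23-30 nt piRNA set). If a `sample_id`
#'   column is present counts are per sample.
#' @param features Interval tibble with a `name` (or `feature_id`) column.
#' @param strand_mode `"both"`, `"sense"`, or `"antisense"`.
#' @return Long count tibble: `feature_id`, (`sample_id`,) `count`; every
#'   feature appears (zero-filled).
#' @export
count_features <- function(reads, features, strand_mode = c("both", "sense", "antisense")) {
  strand_mode <- match.arg(strand_mode)
  fid <- features[["feature_id"]] %||% features[["name"]]
  if (is.null(fid)) abort("count_features: features need a name or feature_id column")
  if (strand_mode != "both" && any(features$strand == "*"))
    abort("count_features: sense/antisense counting needs stranded features")
  per_sample <- "sample_id" %in% names(reads)
  samples <- if (per_sample) unique(reads$sample_id) else "library"
  gf <- as_granges(features)
  gr <- as_granges(reads)
  hits <- find_overlaps_q(gf, gr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (strand_mode != "both" && length(hits)) {
    same <- features$strand[qi] == reads$strand[si]
    keep <- if (strand_mode == "sense") same else !same
    qi <- qi[keep]; si <- si[keep]
  }
  long <- tibble(feature_id = fid[qi],
                 sample_id = if (per_sample) reads$sample_id[si]
                             else "library")
  grid <- tidyr::expand_grid(feature_id = fid, sample_id = samples)
  out <- left_join(grid, count(long, .data$feature_id, .data$sample_id),
                   by = c("feature_id", "sample_id"))
  out$count <- dplyr::coalesce(out$n, 0L)
  out <- select(out, "feature_id", "sample_id", "count")
  if (!per_sample) out$sample_id <- NULL
  out
}

#' Sense/antisense TE expression counts
#'
#' For reads aligned to TE consensus sequences: plus-strand alignments are
#' sense, minus-strand antisense. Reads of exactly 21 nt are excluded from
#' piRNA TE counts -- on transposons they are siRNAs.
#'
#' @param reads TE-consensus-space read tibble (`chrom` holds TE names).
#' @param te_names Character vector of known TE family names.
#' @param exclude_21nt Drop exactly-21-nt reads (default TRUE; set FALSE
#'   when counting mRNA-derived reads).
#' @return Tibble `te`, (`sample_id`,) `sense`, `antisense`; every TE name
#'   appears (zero-filled).
#' @export
te_expression <- function(reads, te_names, exclude_21nt = TRUE) {
  unknown <- setdiff(unique(reads$chrom), te_names)
  if (length(unknown))
    abort(paste0("te_expression: unknown TE name(s): ",
                 paste(unknown, collapse = ", ")))
  if (exclude_21nt) reads <- filter(reads, .data$end - .data$start != 21L)
  per_sample <- "sample_id" %in% names(reads)
  if (!per_sample) reads$sample_id <- "library"
  samples <- unique(reads$sample_id)
  if (!length(samples)) samples <- "library"
  tal <- summarise(group_by(reads, te = .data$chrom, .data$sample_id),
                   sense = sum(.data$strand == "+"),
                   antisense = sum(.data$strand == "-"), .groups = "drop")
  grid <- tidyr::expand_grid(te = te_names, sample_id = samples)
  out <- left_join(grid, tal, by = c("te", "sample_id"))
  out <- mutate(out, sense = dplyr::coalesce(.data$sense, 0L),
                antisense = dplyr::coalesce(.data$antisense, 0L))
  if (!per_sample) out$sample_id <- NULL
  out
}

#' Counts per million of a chosen denominator
#'
#' CPM = count / denominator x 1e6. The denominator is whatever the
#' analysis normalizes to: total mapped reads, total miRNA counts
#' ([mirna_denominators()]), or a spike-in effective library size
#' ([spikein_factors()]).
#'
#' @param counts Long count tibble (`feature_id`, `sample_id`, `count`).
#' @param denominators Tibble `sample_id`, `denominator` (> 0), or a single
#'   number applied to all samples.
#' @return `counts` with a `cpm` column appended.
#' @export
cpm <- function(counts, denominators) {
  if (is.numeric(denominators))
    denominators <- tibble(sample_id = unique(counts$sample_id),
                           denominator = denominators)
  if (any(denominators$denominator <= 0))
    abort("cpm: denominators must be > 0")
  out <- left_join(counts, denominators, by = "sample_id")
  if (anyNA(out$denominator)) abort("cpm: missing denominator for some samples")
  mutate(out, cpm = .data$count / .data$denominator * 1e6,
         denominator = NULL)
}

#' Reads per kilobase per million mapped
#'
#' RPKM = count / (length/1000) / (library_total/1e6).
#'
#' @param counts Long count tibble.
#' @param feature_lengths Tibble `feature_id`, `length` (nt).
#' @param library_totals Tibble `sample_id`, `total`, or a single number.
#' @return `counts` with an `rpkm` column appended.
#' @export
rpkm <- function(counts, feature_lengths, library_totals) {
  if (is.numeric(library_totals))
    library_totals <- tibble(sample_id = unique(counts$sample_id),
                             total = library_totals)
  out <- left_join(counts, feature_lengths, by = "feature_id")
  if (anyNA(out$length)) abort("rpkm: missing length for some features")
  out <- left_join(out, library_totals, by = "sample_id")
  mutate(out, rpkm = .data$count / (.data$length / 1000) / (.data$total / 1e6),
         length = NULL, total = NULL)
}

#' miRNA-count normalization denominators
#'
#' Per-sample denominators equal to the summed miRNA counts after dropping
#' the `n_exclude` most differentially expressed miRNAs, ranked by absolute
#' log2 ratio of group-mean counts (pseudo-count applied). Raw counts are
#' used for the ranking rather than miRNA-normalized CPM: normalizing a
#' miRNA by a total that contains it masks its own differential expression
#' and inflates everyone else's. This denominator absorbs global shifts in
#' piRNA abundance that would distort total-count normalization. With fewer
#' than two condition groups the ranking falls back to cross-sample
#' log-count variance, with a warning.
#'
#' @param mirna_counts Long count tibble of miRNA features.
#' @param groups Tibble `sample_id`, `condition`.
#' @param n_exclude Number of top-ranked miRNAs to drop (default 2).
#' @param pseudo_count Added before log ratios (default 1).
#' @return Tibble `sample_id`, `denominator`, plus an `excluded` attribute
#'   naming the dropped miRNAs.
#' @export
mirna_denominators <- function(mirna_counts, groups, n_exclude = 2L,
                               pseudo_count = 1) {
  feats <- unique(mirna_counts$feature_id)
  if (length(feats) < n_exclude + 1)
    abort("mirna_denominators: need more miRNA features than n_exclude")
  totals <- summarise(group_by(mirna_counts, .data$sample_id),
                      denominator = sum(.data$count), .groups = "drop")
  excluded <- character()
  if (n_exclude > 0) {
    x <- left_join(mirna_counts, groups, by = "sample_id")
    conds <- unique(groups$condition)
    if (length(conds) >= 2) {
      gm <- summarise(group_by(x, .data$feature_id, .data$condition),
                      mu = mean(.data$count), .groups = "drop")
      wide <- tidyr::pivot_wider(filter(gm, .data$condition %in% conds[1:2]),
                                 names_from = "condition", values_from = "mu")
      score <- abs(log2((wide[[conds[1]]] + pseudo_count) /
                          (wide[[conds[2]]] + pseudo_count)))
      ranked <- wide$feature_id[order(-score)]
    } else {
      warn("mirna_denominators: fewer than two groups; ranking by log-count variance")
      v <- summarise(group_by(x, .data$feature_id),
                     s2 = var(log2(.data$count + pseudo_count)), .groups = "drop")
      ranked <- v$feature_id[order(-v$s2)]
    }
    excluded <- head(ranked, n_exclude)
  }
  kept <- filter(mirna_counts, !(.data$feature_id %in% excluded))
  out <- summarise(group_by(kept, .data$sample_id),
                   denominator = sum(.data$count), .groups = "drop")
  attr(out, "excluded") <- excluded
  out
}

#' Spike-in normalization factors and effective library sizes
#'
#' Factors are proportional to 1 / spike total, rescaled so their geometric
#' mean is 1; the effective library size is the total mapped read count
#' multiplied by the factor.
#'
#' @param spike_counts Tibble `sample_id`, `spike_id`, `count`, or already
#'   aggregated `sample_id`, `spike_total`.
#' @param total_mapped Optional tibble `sample_id`, `total_mapped`.
#' @return Tibble `sample_id`, `spike_total`, `norm_factor`, and (when
#'   `total_mapped` given) `effective_lib_size`.
#' @export
spikein_factors <- function(spike_counts, total_mapped = NULL) {
  tot <- if ("spike_total" %in% names(spike_counts)) {
    select(spike_counts, "sample_id", "spike_total")
  } else {
    summarise(group_by(spike_counts, .data$sample_id),
              spike_total = sum(.data$count), .groups = "drop")
  }
  if (any(tot$spike_total <= 0))
    abort("spikein_factors: zero spike-in total for some sample")
  raw <- 1 / tot$spike_total
  tot$norm_factor <- raw / exp(mean(log(raw)))
  if (!is.null(total_mapped)) {
    tot <- left_join(tot, total_mapped, by = "sample_id")
    tot$effective_lib_size <- tot$total_mapped * tot$norm_factor
    tot$total_mapped <- NULL
  }
  tot
}

#' Filter features by CPM expression cutoff
#'
#' Keeps features with CPM strictly above `cpm_cutoff` in at least
#' `min_samples` samples (features above the cutoff in fewer samples are
#' excluded).
#'
#' @param counts Long count tibble.
#' @param denominators As for [cpm()].
#' @param cpm_cutoff,min_samples Filter thresholds.
#' @return The surviving rows of `counts`.
#' @export
expression_filter <- function(counts, denominators, cpm_cutoff = 20,
                              min_samples = 3L) {
  x <- cpm(counts, denominators)
  keep <- summarise(group_by(x, .data$feature_id),
                    n_pass = sum(.data$cpm > cpm_cutoff), .groups = "drop")
  keep <- filter(keep, .data$n_pass >= min_samples)
  filter(counts, .data$feature_id %in% keep$feature_id)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: q_(i) = min over j >= i of (m/j) p_(j), clipped
#' at 1, returned in input order.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return q-values, same length and order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE) || anyNA(pvalues))
    abort("benjamini_hochberg: p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Call significant features by fold change and FDR
#'
#' Both thresholds are inclusive: |log2 FC| >= log2(fc_threshold) and
#' q <= fdr_threshold.
#'
#' @param log2fc,qvalues Aligned per-feature vectors.
#' @param params A [dge_params()].
#' @return Character vector in {"up", "down", "ns"}.
#' @export
call_significant <- function(log2fc, qvalues, params = dge_params()) {
  stopifnot(length(log2fc) == length(qvalues))
  lfc <- log2(params$fc_threshold)
  dplyr::case_when(
    log2fc >= lfc & qvalues <= params$fdr_threshold ~ "up",
    log2fc <= -lfc & qvalues <= params$fdr_threshold ~ "down",
    .default = "ns")
}

#' Exact binomial two-group test on pooled counts
#'
#' A deliberately simple stand-in inferential test (the published analyses
#' used an edgeR GLM, which is outside this package's scope): the pooled
#' group-A count is tested against the proportion implied by the two
#' groups' summed denominators with a two-sided exact binomial test.
#' Outputs are labelled `binomial_standin` wherever this p-value appears.
#'
#' @param counts Per-sample counts (named by sample or aligned with
#'   `groups`).
#' @param groups Character vector of two group labels, aligned to `counts`.
#' @param denominators Per-sample denominators, aligned to `counts`.
#' @return Two-sided p-value; 1 when the total count is zero.
#' @export
two_group_test <- function(counts, groups, denominators) {
  g <- unique(groups)
  if (length(g) != 2) abort("two_group_test: exactly two groups required")
  xa <- sum(counts[groups == g[1]])
  n <- sum(counts)
  if (n == 0) return(1)
  pr <- sum(denominators[groups == g[1]]) / sum(denominators)
  binom.test(xa, n, p = pr, alternative = "two.sided")$p.value
}

#' Group-mean log2 fold change with pseudo-count
#'
#' @param cpm_values,groups Aligned vectors; fold change is group 1 over
#'   group 2 in `unique(groups)` order unless `reference` names the
#'   denominator group.
#' @param pseudo_count Added to both group means (default 1).
#' @param reference Optional denominator group label.
#' @return A single log2 fold change.
#' @export
log2_fold_change <- function(cpm_values, groups, pseudo_count = 1,
                             reference = NULL) {
  g <- unique(groups)
  if (length(g) != 2) abort("log2_fold_change: exactly two groups required")
  if (!is.null(reference)) g <- c(setdiff(g, reference), reference)
  log2((mean(cpm_values[groups == g[1]]) + pseudo_count) /
         (mean(cpm_values[groups == g[2]]) + pseudo_count))
}

#' Two-group differential expression over a count table
#'
#' Composes the package's normalization and calling rules: CPM on the given
#' denominators, expression filter, per-feature group-mean log2 fold
#' change, the exact-binomial stand-in test, BH FDR, and up/down/ns calls
#' at |FC| >= 2 and FDR <= 0.05 (defaults).
#'
#' @param counts Long count tibble (`feature_id`, `sample_id`, `count`).
#' @param groups Tibble `sample_id`, `condition` (two conditions).
#' @param denominators As for [cpm()].
#' @param params A [dge_params()].
#' @param reference Optional condition treated as the fold-change
#'   denominator.
#' @return Object of class `pirna_dge` with a per-feature table; see
#'   [tidy.pirna_dge()] and [glance.pirna_dge()].
#' @export
dge_binomial <- function(counts, groups, denominators, params = dge_params(),
                         reference = NULL) {
  kept <- expression_filter(counts, denominators, params$cpm_cutoff,
                            params$min_samples)
  x <- cpm(kept, denominators)
  x <- left_join(x, groups, by = "sample_id")
  den <- if (is.numeric(denominators))
    tibble(sample_id = unique(counts$sample_id), denominator = denominators)
    else denominators
  x <- left_join(x, den, by = "sample_id")
  per <- x |>
    group_by(.data$feature_id) |>
    summarise(
      log2fc = log2_fold_change(.data$cpm, .data$condition,
                                params$pseudo_count, reference),
      p_value = two_group_test(.data$count, .data$condition,
                               .data$denominator),
      .groups = "drop")
  per$q_value <- benjamini_hochberg(per$p_value)
  per$call <- call_significant(per$log2fc, per$q_value, params)
  structure(list(table = per, params = params, test = "binomial_standin",
                 n_filtered = length(unique(counts$feature_id)) -
                   length(unique(kept$feature_id))),
            class = "pirna_dge")
}

#' @export
print.pirna_dge <- function(x, ...) {
  n <- table(factor(x$table$call, c("up", "down", "ns")))
  cat(sprintf("two-group small-RNA DGE (%s): %d up, %d down, %d ns; %d features filtered\n",
              x$test, n[["up"]], n[["down"]], n[["ns"]], x$n_filtered))
  invisible(x)
}

#' Tidy a `pirna_dge` fit
#'
#' @param x A `pirna_dge` object from [dge_binomial()].
#' @param ... Unused.
#' @return Per-feature tibble: `feature_id`, `log2fc`, `p_value`,
#'   `q_value`, `call`.
#' @method tidy pirna_dge
#' @export
tidy.pirna_dge <- function(x, ...) x$table

#' One-row summary of a `pirna_dge` fit
#'
#' @param x A `pirna_dge` object.
#' @param ... Unused.
#' @return Tibble with `n_features`, `n_up`, `n_down`, `n_filtered`,
#'   `test`.
#' @method glance pirna_dge
#' @export
glance.pirna_dge <- function(x, ...) {
  tibble(n_features = nrow(x$table),
         n_up = sum(x$table$call == "up"),
         n_down = sum(x$table$call == "down"),
         n_filtered = x$n_filtered,
         test = x$test)
}

#' 3'UTR piRNA producer-class report
#'
#' Per gene: piRNA reads overlapping the gene's 3'UTR on the gene strand
#' are sense, on the opposite strand antisense; a gene is a sense,
#' antisense, or both-strand producer when the respective counts reach
#' `min_count`. `has_te_fragment` flags 3'UTRs overlapping an annotated TE
#' insertion.
#'
#' @param reads piRNA read tibble (counting universe: unique-genomic
#'   23-30 nt).
#' @param ann An [annotation_set()] with gene models and 3'UTRs.
#' @param min_count Minimum reads to claim a producer class (default 1).
#' @return Tibble `gene_id`, `sense_count`, `antisense_count`,
#'   `producer_class` in {"sense", "antisense", "both", "none"},
#'   `has_te_fragment`.
#' @export
utr3_pirna_report <- function(reads, ann, min_count = 1L) {
  genes <- ann$genes
  utr <- ann$utr3
  base <- tibble(gene_id = genes$gene_id, sense_count = 0L,
                 antisense_count = 0L, has_te_fragment = FALSE)
  if (nrow(utr)) {
    gutr <- as_granges(utr)
    if (nrow(reads)) {
      gr <- as_granges(reads)
      hits <- find_overlaps_q(gutr, gr)
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      same <- utr$strand[qi] == reads$strand[si]
      tal <- tibble(gene_id = utr$gene_id[qi], sense = same) |>
        dplyr::distinct(.data$gene_id, read = si, .data$sense) |>
        group_by(.data$gene_id) |>
        summarise(sense_count = sum(.data$sense),
                  antisense_count = sum(!.data$sense), .groups = "drop")
      base <- rows_update_counts(base, tal)
    }
    if (nrow(ann$te_insertions)) {
      hit_te <- count_overlaps_q(gutr, as_granges(ann$te_insertions)) > 0
      te_genes <- unique(utr$gene_id[hit_te])
      base$has_te_fragment <- base$gene_id %in% te_genes
    }
  }
  mutate(base, producer_class = dplyr::case_when(
    .data$sense_count >= min_count & .data$antisense_count >= min_count ~ "both",
    .data$sense_count >= min_count ~ "sense",
    .data$antisense_count >= min_count ~ "antisense",
    .default = "none"))
}

rows_update_counts <- function(base, tal) {
  j <- left_join(select(base, -"sense_count", -"antisense_count"), tal,
                 by = "gene_id")
  mutate(j, sense_count = dplyr::coalesce(as.integer(.data$sense_count), 0L),
         antisense_count = dplyr::coalesce(as.integer(.data$antisense_count), 0L))
}
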