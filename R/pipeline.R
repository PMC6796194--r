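# End-to-end orchestration: classify -> discover -> pingpong -> quantify
# -> logo, driven by a YAML run config, with a machine-readable JSON run
# report. The companion command-line driver lives in inst/cli/piratlas.R.

RUN_STAGES <- c("classify", "discover", "pingpong", "quantify", "logo")

#' Validate a pipeline run configuration
#'
#' Reads a YAML config (or takes an equivalent list) and checks every
#' constraint at once, reporting all violations together. Relative paths
#' are resolved against the config file's directory.
#'
#' Expected fields: `genome` (FASTA), `annotations` (GFF3), optional
#' `spike_table` (TSV), `samples` (list of `sample_id`, `condition`,
#' `genome_alignments`, optional `te_alignments`), `normalization`
#' ("mirna", "spikein" or "total"), `out_dir`, `seed`, and optional
#' `classifier` / `cluster` / `dge` parameter overrides.
#'
#' @param config YAML file path or a list.
#' @return A validated list of class `run_config`.
#' @export
validate_config <- function(config) {
  base <- "."
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("no such config file: ", config))
    base <- dirname(normalizePath(config))
    config <- tryCatch(yaml::read_yaml(config),
                       error = function(e) abort(paste0("config parse error: ",
                                                        conditionMessage(e))))
  }
  errs <- character()
  need <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  resolve <- function(p) if (is.null(p) || grepl("^/", p)) p else file.path(base, p)
  config$genome <- resolve(config$genome)
  config$annotations <- resolve(config$annotations)
  config$spike_table <- resolve(config$spike_table)
  need(!is.null(config$genome) && file.exists(config$genome),
       "genome: missing or nonexistent FASTA path")
  need(!is.null(config$annotations) && file.exists(config$annotations),
       "annotations: missing or nonexistent GFF3 path")
  if (!is.null(config$spike_table))
    need(file.exists(config$spike_table), "spike_table: nonexistent path")
  config$normalization <- config$normalization %||% "total"
  need(config$normalization %in% c("mirna", "spikein", "total"),
       "normalization: must be one of mirna, spikein, total")
  if (config$normalization == "spikein")
    need(!is.null(config$spike_table), "normalization spikein needs a spike_table")
  need(length(config$samples) >= 1, "samples: at least one required")
  ids <- vapply(config$samples, function(s) s$sample_id %||% NA_character_,
                character(1))
  need(!anyNA(ids), "samples: every sample needs a sample_id")
  need(!anyDuplicated(ids), "samples: duplicate sample_id")
  for (i in seq_along(config$samples)) {
    s <- config$samples[[i]]
    config$samples[[i]]$genome_alignments <- resolve(s$genome_alignments)
    config$samples[[i]]$te_alignments <- resolve(s$te_alignments)
    need(!is.null(s$genome_alignments) &&
           file.exists(resolve(s$genome_alignments)),
         sprintf("samples[%d]: missing or nonexistent genome_alignments", i))
    if (!is.null(s$te_alignments))
      need(file.exists(resolve(s$te_alignments)),
           sprintf("samples[%d]: nonexistent te_alignments", i))
    need(!is.null(s$condition), sprintf("samples[%d]: missing condition", i))
  }
  params_or <- function(block, fn) {
    tryCatch(do.call(fn, config[[block]] %||% list()),
             error = function(e) {
               errs <<- c(errs, paste0(block, ": ", conditionMessage(e)))
               NULL
             })
  }
  config$classifier <- params_or("classifier", classifier_params)
  config$cluster <- params_or("cluster", cluster_params)
  config$dge <- params_or("dge", dge_params)
  config$out_dir <- config$out_dir %||% "piratlas_out"
  config$seed <- as.integer(config$seed %||% 1L)
  if (length(errs))
    abort(paste0("invalid run config:\n", paste0("  - ", errs, collapse = "\n")))
  structure(config, class = "run_config")
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[piratlas:%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full small-RNA pipeline
#'
#' Executes classify, discover, pingpong, quantify and logo in order and
#' writes TSV/BED outputs plus a JSON run report (parameters, per-stage
#' counts, conservation checks) into the config's `out_dir`. Outputs are a
#' pure function of (inputs, config, seed).
#'
#' @param config A `run_config` (from [validate_config()]) or a YAML path.
#' @param stages Subset of stages to run (dependencies are computed as
#'   needed regardless).
#' @return Invisible list with the run report and the main in-memory
#'   results (`reads`, `clusters`, `pingpong`, `counts`, `dge`,
#'   `utr3_report`, `logo`).
#' @export
run_all <- function(config, stages = RUN_STAGES) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  stages <- match.arg(stages, RUN_STAGES, several.ok = TRUE)
  set.seed(config$seed)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = list(
    classifier = unclass(config$classifier),
    cluster = unclass(config$cluster), dge = unclass(config$dge),
    normalization = config$normalization, seed = config$seed))
  ann <- read_annotations(config$annotations)
  samples <- bind_rows(lapply(config$samples, function(s)
    tibble(sample_id = s$sample_id, condition = s$condition)))

  stage_log("ingest", "reading alignments for %d sample(s)", nrow(samples))
  reads <- bind_rows(lapply(config$samples, function(s) {
    g <- mutate(read_alignments(s$genome_alignments, "genome"),
                sample_id = s$sample_id, condition = s$condition)
    t <- if (!is.null(s$te_alignments))
      mutate(read_alignments(s$te_alignments, "te_consensus"),
             sample_id = s$sample_id, condition = s$condition)
    bind_rows(g, t)
  }))
  report$ingest <- list(n_reads = nrow(reads))

  classified <- classify_reads(reads, ann, config$classifier)
  res <- list(reads = classified)
  if ("classify" %in% stages) {
    counts <- classify_library(reads, ann, config$classifier)
    readr::write_tsv(counts, file.path(out, "biotype_counts.tsv"))
    report$classify <- list(
      n_classified = nrow(classified),
      conservation_ok = nrow(classified) == nrow(reads),
      by_biotype = setNames(as.list(tapply(counts$n, counts$biotype, sum)),
                            levels(counts$biotype)))
    stage_log("classify", "%d reads classified", nrow(classified))
  }

  disc_reads <- select_putative_pirnas(reads, ann, config$classifier,
                                       "discovery")
  clusters <- discover_clusters(disc_reads, config$cluster)
  if ("discover" %in% stages) {
    if (nrow(clusters))
      write_bed(mutate(clusters,
                       name = sprintf("cluster%04d", row_number()),
                       score = .data$n_unique_reads),
                file.path(out, "clusters.bed"))
    readr::write_tsv(clusters, file.path(out, "clusters.tsv"))
    report$discover <- list(n_discovery_reads = nrow(disc_reads),
                            n_clusters = nrow(clusters))
    stage_log("discover", "%d clusters from %d discovery reads",
              nrow(clusters), nrow(disc_reads))
  }
  res$clusters <- clusters

  count_reads <- select_putative_pirnas(reads, ann, config$classifier,
                                        "counting")
  if ("pingpong" %in% stages) {
    per_sample <- samples |>
      group_by(.data$sample_id, .data$condition) |>
      dplyr::group_modify(function(key, grp) {
        glance(ping_pong_histogram(
          filter(count_reads, .data$sample_id == grp$sample_id)))
      }) |> ungroup()
    scan <- ping_pong_scan(count_reads, clusters)
    readr::write_tsv(per_sample, file.path(out, "pingpong_samples.tsv"))
    readr::write_tsv(scan, file.path(out, "pingpong_clusters.tsv"))
    report$pingpong <- list(n_clusters_scanned = nrow(scan),
                            sample_z10 = setNames(as.list(per_sample$z10),
                                                  per_sample$sample_id))
    res$pingpong <- list(per_sample = per_sample, per_cluster = scan)
    stage_log("pingpong", "scanned %d clusters", nrow(scan))
  }

  if ("quantify" %in% stages) {
    feats <- if (nrow(clusters))
      mutate(clusters, name = sprintf("cluster%04d", row_number())) else clusters
    counts <- count_features(count_reads, feats, "both")
    denoms <- switch(config$normalization,
      total = count(reads, .data$sample_id, name = "n") |>
        mutate(denominator = .data$n, n = NULL),
      mirna = {
        mir <- count_features(
          filter(classified, .data$biotype == "miRNA"),
          mutate(ann$pre_mirna, feature_id = .data$name), "both")
        mirna_denominators(mir, samples)
      },
      spikein = {
        sp <- spikein_factors(read_spike_table(config$spike_table),
                              count(reads, .data$sample_id, name = "total_mapped"))
        tibble(sample_id = sp$sample_id,
               denominator = sp$effective_lib_size)
      })
    # samples with zero reads in a space would drop out of denominators
    denoms <- filter(denoms, .data$sample_id %in% samples$sample_id)
    withcpm <- cpm(counts, denoms)
    readr::write_tsv(withcpm, file.path(out, "cluster_counts.tsv"))
    dge <- NULL
    if (length(unique(samples$condition)) == 2 && nrow(feats)) {
      dge <- dge_binomial(counts, samples, denoms, config$dge)
      readr::write_tsv(tidy(dge), file.path(out, "cluster_dge.tsv"))
    }
    te_reads <- filter(reads, .data$space == "te_consensus",
                       .data$end - .data$start >= config$classifier$pirna_min_len,
                       .data$end - .data$start <= config$classifier$pirna_max_len)
    te_names <- union(ann$te_consensus_names, unique(te_reads$chrom))
    te_counts <- if (nrow(te_reads))
      te_expression(te_reads, te_names) else NULL
    if (!is.null(te_counts))
      readr::write_tsv(te_counts, file.path(out, "te_counts.tsv"))
    utr <- utr3_pirna_report(count_reads, ann)
    readr::write_tsv(utr, file.path(out, "utr3_report.tsv"))
    report$quantify <- list(
      n_count_reads = nrow(count_reads),
      n_features = nrow(feats),
      dge = if (!is.null(dge)) as.list(glance(dge)) else NULL,
      utr3_producers = as.list(table(utr$producer_class)))
    res$counts <- withcpm; res$dge <- dge; res$utr3_report <- utr
    res$te_counts <- te_counts
    stage_log("quantify", "%d features x %d samples", nrow(feats),
              nrow(samples))
  }

  if ("logo" %in% stages) {
    logo <- first10_frequency_matrix(count_reads, config$genome)
    readr::write_tsv(tidyr::pivot_wider(logo, names_from = "base",
                                        values_from = "freq"),
                     file.path(out, "logo_matrix.tsv"))
    report$logo <- list(n_sites = attr(logo, "n_sites"),
                        u1 = logo$freq[logo$position == 1 & logo$base == "U"])
    res$logo <- logo
    stage_log("logo", "%d unique start sites; U1 = %.3f",
              attr(logo, "n_sites"), report$logo$u1)
  }

  report$stages_completed <- stages
  jsonlite::write_json(report, file.path(out, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$report <- report
  invisible(res)
}
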