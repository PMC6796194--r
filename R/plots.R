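# ggplot2 displays for the main result types.

#' Plot a ping-pong 5'-overlap histogram
#'
#' Bar chart of pair counts by overlap distance with the d = 10 bin
#' highlighted; the subtitle reports the z10 enrichment.
#'
#' @param object A `pingpong_profile` from [ping_pong_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pingpong_profile
#' @export
autoplot.pingpong_profile <- function(object, ...) {
  h <- object$overlap_counts
  z <- ping_pong_zscore(object)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$distance, y = .data$count,
                                  fill = .data$distance == 10)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "5' overlap distance (nt)", y = "pair count",
                  title = "Ping-pong signature",
                  subtitle = sprintf("z10 = %s",
                                     ifelse(is.na(z), "undefined",
                                            sprintf("%.2f", z)))) +
    ggplot2::theme_minimal()
}

#' Plot a first-10-nt nucleotide frequency matrix
#'
#' Stacked per-position base fractions over the first ten nucleotides of
#' unique piRNA start sites; a strong U at position 1 is the expected
#' piRNA signature.
#'
#' @param object A `nt_freq_matrix` from [first10_frequency_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nt_freq_matrix
#' @export
autoplot.nt_freq_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$position),
                                       y = .data$freq, fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "position", y = "fraction",
                  title = sprintf("First-10-nt base composition (%d sites)",
                                  attr(object, "n_sites"))) +
    ggplot2::theme_minimal()
}

#' Read length distribution plot
#'
#' @param reads Read tibble; facetted by `sample_id` when present.
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(reads) {
  d <- mutate(reads, length = .data$end - .data$start)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "read length (nt)", y = "reads") +
    ggplot2::theme_minimal()
  if ("sample_id" %in% names(d))
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$sample_id))
  p
}

#' Cluster density vs size scatter plot
#'
#' @param clusters Cluster tibble from [discover_clusters()].
#' @return A ggplot object.
#' @export
plot_cluster_calls <- function(clusters) {
  d <- mutate(clusters, size_kb = (.data$end - .data$start) / 1000)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$size_kb, y = .data$density)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cluster size (kb)", y = "unique reads / kb",
                  title = "Discovered piRNA clusters") +
    ggplot2::theme_minimal()
}
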