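# ggplot2 views of the main result types.

#' Plot a fragment-length histogram
#'
#' @param histogram tibble from [length_histogram()].
#' @param log_y log10-scale the counts (default TRUE, making the nucleosomal
#'   ladder visible against the exponential decay).
#' @return a ggplot.
#' @export
plot_length_histogram <- function(histogram, log_y = TRUE) {
  p <- ggplot2::ggplot(histogram, ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "fragment length (bp)", y = "fragments") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @method autoplot fatac_period
#' @export
autoplot.fatac_period <- function(object, ...) {
  ggplot2::ggplot(object$acf, ggplot2::aes(x = .data$lag, y = .data$acf)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$period, linetype = 2, colour = "red") +
    ggplot2::labs(x = "lag (bp)", y = "autocorrelation",
                  title = sprintf("period %d bp (confidence %.2f)",
                                  object$period, object$confidence)) +
    ggplot2::theme_minimal()
}

#' @method autoplot fatac_tss_matrix
#' @export
autoplot.fatac_tss_matrix <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$offset, y = .data$mean_count)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "offset from TSS (bp)",
                  y = "mean insertions per gene",
                  title = paste0("TSS profile (", object$size_class, " fragments)")) +
    ggplot2::theme_minimal()
}

#' @method autoplot fatac_strand_profile
#' @export
autoplot.fatac_strand_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(object$profile, c("f_plus", "f_minus"),
                            names_to = "strand", values_to = "f")
  df$strand <- ifelse(df$strand == "f_plus", "+ strand", "- strand")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$f,
                                   colour = .data$strand)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c("+ strand" = "#c0392b",
                                            "- strand" = "#2980b9")) +
    ggplot2::labs(x = "offset from motif centre (bp)",
                  y = "mean insertions / instance / bp", colour = NULL) +
    ggplot2::theme_minimal()
}

#' MA plot for a differential-accessibility result
#'
#' @param da a `fatac_da` tibble.
#' @param fdr significance threshold for highlighting (default 0.05).
#' @return a ggplot.
#' @export
plot_ma <- function(da, fdr = 0.05) {
  df <- mutate(as_tibble(da),
               mean_cpm = (.data$mean_a + .data$mean_b) / 2,
               significant = .data$FDR < fdr)
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$mean_cpm + 1),
                                   y = .data$log2FC,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "#c0392b")) +
    ggplot2::labs(x = "log2 mean CPM", y = "log2 fold change",
                  colour = paste0("FDR < ", fdr)) +
    ggplot2::theme_minimal()
}

#' Barplot of peak feature categories
#'
#' @param annotation tibble from [annotate_peaks()].
#' @return a ggplot.
#' @export
plot_peak_categories <- function(annotation) {
  df <- count(annotation, .data$category)
  df$category <- factor(df$category,
                        levels = c("promoter", "TTS", "exon", "intron", "intergenic"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "#34495e") +
    ggplot2::labs(x = NULL, y = "peaks") +
    ggplot2::theme_minimal()
}

#' Histogram of footprint-to-TSS distances
#'
#' @param distances tibble from [footprint_tss_distances()].
#' @param binwidth histogram bin width in bp.
#' @return a ggplot.
#' @export
plot_footprint_distances <- function(distances, binwidth = 100) {
  ggplot2::ggplot(distances, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "#34495e") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "footprint midpoint - TSS (bp, signed along gene)",
                  y = "footprints") +
    ggplot2::theme_minimal()
}
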