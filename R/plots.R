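# ggplot2 views of the main result tables.

#' Call-rate distributions by input type
#'
#' Histogram of per-sample call rates faceted by input type, with the pass
#' threshold marked.
#'
#' @param call_rates Output of [compute_call_rates()].
#' @param threshold Threshold line (default 0.95).
#' @return A ggplot.
#' @export
plot_call_rates <- function(call_rates, threshold = 0.95) {
  ggplot2::ggplot(call_rates, ggplot2::aes(x = .data$call_rate)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey35") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$input_type), ncol = 1) +
    ggplot2::labs(x = "call rate", y = "samples")
}

#' Heterozygosity rates by input type and pass status
#'
#' @param het Output of [compute_heterozygosity()] (optionally with
#'   `is_outlier`).
#' @param call_rates Output of [compute_call_rates()].
#' @return A ggplot.
#' @export
plot_heterozygosity <- function(het, call_rates) {
  x <- dplyr::left_join(
    het, call_rates[, c("sample_id", "input_type", "passes")],
    by = "sample_id")
  ggplot2::ggplot(x, ggplot2::aes(x = .data$input_type, y = .data$het_rate,
                                  colour = .data$passes)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "darkgreen",
                                            `FALSE` = "red")) +
    ggplot2::labs(x = NULL, y = "heterozygosity rate",
                  colour = "call rate ≥ threshold")
}

#' Replicate concordance by pair type
#'
#' @param pairs Output of [compute_pair_concordance()].
#' @return A ggplot.
#' @export
plot_concordance <- function(pairs) {
  x <- dplyr::filter(pairs, !.data$excluded)
  ggplot2::ggplot(x, ggplot2::aes(x = .data$pair_type,
                                  y = 100 * .data$concordance)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = "concordance (%)")
}

#' Failing-locus counts in genomic windows
#'
#' Per-chromosome bar map of failing loci per window, by failure class;
#' the signature view for spotting subtelomeric under-amplification.
#'
#' @param windows Output of [window_failure_counts()].
#' @return A ggplot.
#' @export
plot_window_failures <- function(windows) {
  x <- windows |>
    tidyr::pivot_longer(c("n_failed_all", "n_failed_wga_only"),
                        names_to = "class", values_to = "n") |>
    dplyr::mutate(class = dplyr::recode(.data$class,
                                        n_failed_all = "all samples",
                                        n_failed_wga_only = "wgaDNA only"))
  ggplot2::ggplot(x, ggplot2::aes(x = .data$window_start / 1e6, y = .data$n,
                                  fill = .data$class)) +
    ggplot2::geom_col(position = "identity", alpha = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chromosome), scales = "free_x") +
    ggplot2::scale_fill_manual(values = c("all samples" = "darkorange",
                                          "wgaDNA only" = "forestgreen")) +
    ggplot2::labs(x = "position (Mb)", y = "failing loci / window",
                  fill = "failure class")
}

#' LRR standard deviation before vs after wave correction
#'
#' @param sds Output of [sd_report()].
#' @param cohort Optional sample sheet to colour by input type.
#' @return A ggplot.
#' @export
plot_sd_reduction <- function(sds, cohort = NULL) {
  x <- sds
  if (!is.null(cohort)) {
    x <- dplyr::left_join(x, cohort[, c("sample_id", "input_type")],
                          by = "sample_id")
  } else {
    x$input_type <- "all"
  }
  ggplot2::ggplot(x, ggplot2::aes(x = .data$lrr_sd_raw,
                                  y = .data$lrr_sd_adjusted,
                                  colour = .data$input_type)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "LRR sd (raw)", y = "LRR sd (wave-corrected)",
                  colour = NULL)
}

#' LRR and BAF along one sample chromosome
#'
#' Two-panel view of a sample's LRR and BAF with detected events overlaid,
#' the standard inspection plot for CNV review.
#'
#' @param calls Call table.
#' @param manifest Probe manifest.
#' @param sample One sample id.
#' @param chromosome One chromosome label.
#' @param events Optional event tibble to overlay.
#' @return A ggplot.
#' @export
plot_sample_chromosome <- function(calls, manifest, sample, chromosome,
                                   events = NULL) {
  i <- match(calls$probe_id, manifest$probe_id)
  x <- calls |>
    dplyr::mutate(chromosome = manifest$chromosome[i],
                  position = manifest$position[i]) |>
    dplyr::filter(.data$sample_id == sample,
                  .data$chromosome == chromosome) |>
    tidyr::pivot_longer(c("lrr", "baf"), names_to = "track")
  p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$position / 1e6,
                                       y = .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$track), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "position (Mb)", y = NULL,
                  title = paste(sample, "chr", chromosome))
  if (!is.null(events) && nrow(events)) {
    ev <- dplyr::filter(events, .data$sample_id == sample,
                        .data$chromosome == !!chromosome)
    if (nrow(ev)) {
      p <- p + ggplot2::geom_rect(
        data = ev,
        ggplot2::aes(xmin = .data$start_bp / 1e6, xmax = .data$end_bp / 1e6),
        ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red",
        inherit.aes = FALSE)
    }
  }
  p
}
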