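# Probe/locus failure classification and windowed failure maps.

#' Classify probe failures
#'
#' `failed_all`: no genotype in any sample. `failed_wga_only`: no genotype
#' in any wgaDNA sample but at least one gDNA call. Everything else is `ok`.
#' The classification is idempotent and invariant to sample order.
#'
#' @param calls Call table.
#' @param cohort Sample sheet tibble.
#' @return Tibble `probe_id`, `class`.
#' @export
classify_probe_failures <- function(calls, cohort) {
  input_of <- setNames(cohort$input_type, cohort$sample_id)
  calls |>
    dplyr::mutate(input_type = input_of[.data$sample_id]) |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(
      any_gdna = any(.data$genotype != "NC" & .data$input_type == "gDNA"),
      any_wga = any(.data$genotype != "NC" & .data$input_type == "wgaDNA")) |>
    dplyr::mutate(class = dplyr::case_when(
      !.data$any_gdna & !.data$any_wga ~ "failed_all",
      .data$any_gdna & !.data$any_wga ~ "failed_wga_only",
      .default = "ok")) |>
    dplyr::select("probe_id", "class")
}

#' Collapse probe failures to unique loci
#'
#' A locus is failed in a class only if all of its constituent probes are
#' failed in that class (the conservative reading: a locus with one working
#' probe still yields genotypes).
#'
#' @param classes Output of [classify_probe_failures()].
#' @param manifest Probe manifest.
#' @return Tibble `locus_id`, `chromosome`, `position`, `n_probes`, `class`.
#' @export
collapse_to_loci <- function(classes, manifest) {
  absent <- setdiff(classes$probe_id, manifest$probe_id)
  if (length(absent)) {
    stop("probe(s) absent from manifest: ",
         paste(head(absent, 5), collapse = ", "), call. = FALSE)
  }
  classes |>
    dplyr::left_join(manifest[, c("probe_id", "locus_id", "chromosome",
                                  "position")], by = "probe_id") |>
    dplyr::group_by(.data$locus_id, .data$chromosome, .data$position) |>
    dplyr::summarise(
      n_probes = dplyr::n(),
      class = dplyr::case_when(
        all(.data$class == "failed_all") ~ "failed_all",
        all(.data$class != "ok") ~ "failed_wga_only",
        .default = "ok"),
      .groups = "drop") |>
    dplyr::arrange(as.integer(.data$chromosome), .data$position)
}

#' 50-kb window failure counts
#'
#' Every locus is assigned to exactly one half-open, genome-anchored window
#' by `floor((position - 1) / window_size)`; only covered windows (>= 1
#' locus) are returned, with per-class failed-locus counts and the mean GC
#' fraction of member loci.
#'
#' @param locus_classes Output of [collapse_to_loci()].
#' @param manifest Probe manifest (for GC fractions).
#' @param window_size Window width in bp (default 50000).
#' @return Tibble `chromosome`, `window_start` (1-based), `n_loci_total`,
#'   `n_failed_all`, `n_failed_wga_only`, `gc_mean`.
#' @export
window_failure_counts <- function(locus_classes, manifest,
                                  window_size = 50000L) {
  if (window_size <= 0) stop("window_size must be positive", call. = FALSE)
  gc_of <- manifest |>
    dplyr::distinct(.data$locus_id, .keep_all = TRUE) |>
    dplyr::select("locus_id", "gc_fraction")
  locus_classes |>
    dplyr::left_join(gc_of, by = "locus_id") |>
    dplyr::mutate(window_start =
                    floor((.data$position - 1) / window_size) * window_size + 1) |>
    dplyr::group_by(.data$chromosome, .data$window_start) |>
    dplyr::summarise(
      n_loci_total = dplyr::n(),
      n_failed_all = sum(.data$class == "failed_all"),
      n_failed_wga_only = sum(.data$class == "failed_wga_only"),
      gc_mean = mean(.data$gc_fraction), .groups = "drop") |>
    dplyr::arrange(as.integer(.data$chromosome), .data$window_start)
}

#' Flag subtelomeric windows
#'
#' Marks the terminal `k_terminal` covered windows (>= 1 locus) at each end
#' of each chromosome. "Chromosome end covered by probes" is operationalized
#' as the first/last covered windows, so coverage ending mid-arm flags the
#' last covered windows.
#'
#' @param windows Output of [window_failure_counts()].
#' @param k_terminal Windows per end (default 3).
#' @return `windows` with an `is_subtelomeric` column.
#' @export
flag_subtelomeric <- function(windows, k_terminal = 3L) {
  windows |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::arrange(.data$window_start, .by_group = TRUE) |>
    dplyr::mutate(is_subtelomeric =
                    dplyr::row_number() <= k_terminal |
                    dplyr::row_number() > dplyr::n() - k_terminal) |>
    dplyr::ungroup()
}

#' Window failure / GC-content association
#'
#' Pearson and Spearman correlation between the per-window failure fraction
#' (failing loci of `class` over total loci) and mean GC fraction, with a
#' bootstrap percentile confidence interval for the Pearson r. Zero-variance
#' input yields NA correlations with `defined = FALSE`.
#'
#' @param windows Output of [window_failure_counts()].
#' @param class Failure class for the numerator (default `failed_wga_only`).
#' @param n_boot Bootstrap replicates (default 500).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @return List `pearson`, `spearman`, `ci` (length-2), `n_windows`,
#'   `defined`.
#' @export
gc_association <- function(windows, class = "failed_wga_only", n_boot = 500L,
                           conf = 0.95, seed = 1L) {
  if (nrow(windows) < 10) stop("need >= 10 windows", call. = FALSE)
  frac <- switch(class,
                 failed_wga_only = windows$n_failed_wga_only,
                 failed_all = windows$n_failed_all,
                 stop("unknown class ", class, call. = FALSE)) /
    windows$n_loci_total
  gc <- windows$gc_mean
  if (sd(frac) == 0 || sd(gc) == 0) {
    return(list(pearson = NA_real_, spearman = NA_real_,
                ci = c(NA_real_, NA_real_), n_windows = nrow(windows),
                defined = FALSE))
  }
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(length(frac), replace = TRUE)
      if (sd(frac[idx]) == 0 || sd(gc[idx]) == 0) NA_real_
      else cor(frac[idx], gc[idx])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  list(pearson = cor(frac, gc),
       spearman = cor(frac, gc, method = "spearman"),
       ci = unname(quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE)),
       n_windows = nrow(windows), defined = TRUE)
}
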