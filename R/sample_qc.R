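# Per-sample completion and heterozygosity QC.

#' Input-type completion denominators
#'
#' Call-rate denominators are the number of non-missing probes per input
#' type: the gDNA denominator excludes probes that failed completely (no
#' genotype in any sample of either input type); the wgaDNA denominator
#' additionally excludes probes that failed in every wgaDNA sample.
#' `denominators_from_counts()` performs the same arithmetic directly from
#' probe counts.
#'
#' @param calls Call table.
#' @param cohort Sample sheet tibble.
#' @return Tibble `input_type`, `n_probes_total`, `n_excluded`, `denominator`.
#' @export
compute_denominators <- function(calls, cohort) {
  if (nrow(calls) == 0) stop("empty call table", call. = FALSE)
  classes <- classify_probe_failures(calls, cohort)
  denominators_from_counts(
    n_probes = nrow(classes),
    n_failed_all = sum(classes$class == "failed_all"),
    n_failed_wga_only = sum(classes$class == "failed_wga_only"))
}

#' @rdname compute_denominators
#' @param n_probes Total probes on the array.
#' @param n_failed_all Probes with no genotype in any sample.
#' @param n_failed_wga_only Additional probes failing all wgaDNA samples.
#' @export
denominators_from_counts <- function(n_probes, n_failed_all,
                                     n_failed_wga_only) {
  tibble::tibble(
    input_type = c("gDNA", "wgaDNA"),
    n_probes_total = as.numeric(n_probes),
    n_excluded = c(n_failed_all, n_failed_all + n_failed_wga_only),
    denominator = n_probes - .data$n_excluded)
}

#' Per-sample call rates
#'
#' Call rate = informative (non-NC) probes per sample divided by the
#' input-type denominator. A rate exactly at the threshold passes; "less
#' than 95%" fails.
#'
#' @param calls Call table.
#' @param denominators Output of [compute_denominators()].
#' @param cohort Sample sheet tibble.
#' @param threshold Pass boundary (default 0.95).
#' @return Tibble `sample_id`, `input_type`, `n_informative`,
#'   `n_denominator`, `call_rate`, `passes`.
#' @export
compute_call_rates <- function(calls, denominators, cohort, threshold = 0.95) {
  if (any(denominators$denominator <= 0)) {
    stop("denominators must be positive", call. = FALSE)
  }
  per_sample <- calls |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_informative = sum(.data$genotype != "NC"),
                     n_nonmissing = dplyr::n())
  if (any(per_sample$n_nonmissing == 0)) {
    stop("sample with zero non-missing probes", call. = FALSE)
  }
  per_sample |>
    dplyr::left_join(cohort[, c("sample_id", "input_type")], by = "sample_id") |>
    dplyr::left_join(denominators[, c("input_type", "denominator")],
                     by = "input_type") |>
    dplyr::transmute(
      .data$sample_id, .data$input_type, .data$n_informative,
      n_denominator = .data$denominator,
      call_rate = .data$n_informative / .data$denominator,
      passes = .data$call_rate >= threshold)
}

#' Chip- and plate-level systematic failure detection
#'
#' A chip on which all 4 samples fail the call-rate threshold is marked for
#' exclusion (systematic error); a chip with 3 of 4 failing is flagged but
#' its samples retained. A plate whose failing fraction exceeds the cohort
#' failure rate with binomial tail probability below `plate_tail_p` is
#' flagged for manual review.
#'
#' @param call_rates Output of [compute_call_rates()].
#' @param cohort Sample sheet tibble.
#' @param plate_tail_p Binomial-tail threshold (default 1e-4).
#' @return Tibble `unit_type` (chip/plate), `unit_id`, `n_samples`,
#'   `n_failing`, `action` (exclude / flag / none), `tail_p` (plates only).
#' @export
detect_systematic_failures <- function(call_rates, cohort,
                                       plate_tail_p = 1e-4) {
  x <- dplyr::left_join(
    call_rates,
    cohort[, c("sample_id", "chip_id", "plate_id")], by = "sample_id")
  chips <- x |>
    dplyr::group_by(unit_id = .data$chip_id) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     n_failing = sum(!.data$passes)) |>
    dplyr::mutate(
      unit_type = "chip",
      action = dplyr::case_when(
        .data$n_failing == 4 & .data$n_samples == 4 ~ "exclude",
        .data$n_failing == 3 & .data$n_samples == 4 ~ "flag",
        .default = "none"),
      tail_p = NA_real_)
  overall_rate <- mean(!x$passes)
  plates <- x |>
    dplyr::group_by(unit_id = .data$plate_id) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     n_failing = sum(!.data$passes)) |>
    dplyr::mutate(
      unit_type = "plate",
      tail_p = 1 - pbinom(.data$n_failing - 1, .data$n_samples, overall_rate),
      action = ifelse(.data$tail_p < plate_tail_p, "flag", "none"))
  dplyr::bind_rows(chips, plates) |>
    dplyr::filter(.data$action != "none") |>
    dplyr::select("unit_type", "unit_id", "n_samples", "n_failing", "action",
                  "tail_p")
}

#' Per-sample heterozygosity rates
#'
#' Fraction of called genotypes that are heterozygous (AB), by default over
#' autosomal probes only (chromosomes other than X/Y/XY/MT) to avoid
#' sex-chromosome artifacts.
#'
#' @param calls Call table.
#' @param manifest Probe manifest.
#' @param autosomes_only Restrict to autosomes (default TRUE).
#' @return Tibble `sample_id`, `n_het`, `n_called`, `het_rate`.
#' @export
compute_heterozygosity <- function(calls, manifest, autosomes_only = TRUE) {
  probes <- manifest
  if (autosomes_only) {
    probes <- dplyr::filter(probes,
                            !.data$chromosome %in% c("X", "Y", "XY", "MT"))
  }
  res <- calls |>
    dplyr::filter(.data$probe_id %in% probes$probe_id,
                  .data$genotype != "NC") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_het = sum(.data$genotype == "AB"),
                     n_called = dplyr::n()) |>
    dplyr::mutate(het_rate = .data$n_het / .data$n_called)
  missing <- setdiff(unique(calls$sample_id), res$sample_id)
  if (length(missing)) {
    stop("sample(s) with zero called genotypes: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  res
}

#' Flag heterozygosity outliers with Tukey fences
#'
#' A sample is an outlier when its heterozygosity rate lies outside
#' `[Q1 - k*IQR, Q3 + k*IQR]` (default `k = 3`).
#'
#' @param het_results Output of [compute_heterozygosity()].
#' @param k Fence multiplier.
#' @return Input with an `is_outlier` column.
#' @export
flag_het_outliers <- function(het_results, k = 3) {
  if (nrow(het_results) < 5) {
    stop("need at least 5 samples to flag outliers", call. = FALSE)
  }
  qs <- quantile(het_results$het_rate, c(0.25, 0.75), names = FALSE)
  iqr <- qs[2] - qs[1]
  dplyr::mutate(het_results,
                is_outlier = .data$het_rate < qs[1] - k * iqr |
                  .data$het_rate > qs[2] + k * iqr)
}

#' Stratified sample failure report
#'
#' Counts and failure percentages per (input type, source material) stratum,
#' per input type overall, and for the whole cohort. `pct_failing` retains
#' full precision; round to 2 decimals for display.
#'
#' @param call_rates Output of [compute_call_rates()].
#' @param cohort Sample sheet tibble.
#' @return Tibble `input_type`, `source_material` ("all" for margins),
#'   `n_samples`, `n_failing`, `pct_failing`.
#' @export
failure_rate_report <- function(call_rates, cohort) {
  x <- dplyr::left_join(
    call_rates, cohort[, c("sample_id", "source_material")], by = "sample_id")
  strata <- x |>
    dplyr::group_by(.data$input_type, .data$source_material) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     n_failing = sum(!.data$passes), .groups = "drop")
  by_input <- x |>
    dplyr::group_by(.data$input_type) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     n_failing = sum(!.data$passes)) |>
    dplyr::mutate(source_material = "all")
  overall <- tibble::tibble(
    input_type = "all", source_material = "all",
    n_samples = nrow(x), n_failing = sum(!x$passes))
  dplyr::bind_rows(strata, by_input, overall) |>
    dplyr::mutate(pct_failing = 100 * .data$n_failing / .data$n_samples) |>
    dplyr::select("input_type", "source_material", "n_samples", "n_failing",
                  "pct_failing")
}

#' Select samples for repeat genotyping
#'
#' Union of call-rate failures and heterozygosity outliers that passed the
#' call-rate threshold, deduplicated, each tagged with its reason(s).
#'
#' @param call_rates Output of [compute_call_rates()].
#' @param het_results Output of [flag_het_outliers()].
#' @return Tibble `sample_id`, `reasons` (semicolon-joined).
#' @export
select_repeats <- function(call_rates, het_results) {
  low <- call_rates$sample_id[!call_rates$passes]
  out <- het_results$sample_id[het_results$is_outlier]
  ids <- union(low, out)
  tibble::tibble(
    sample_id = ids,
    reasons = vapply(ids, function(id) {
      paste(c(if (id %in% low) "low_call_rate",
              if (id %in% out) "het_outlier"), collapse = ";")
    }, character(1), USE.NAMES = FALSE))
}
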