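# Identifiler-style 16-marker STR comparison of gDNA vs wgaDNA profiles.

parse_allele_sets <- function(profile) {
  sets <- strsplit(profile$alleles, ",", fixed = TRUE)
  sets[profile$alleles == "" | is.na(profile$alleles)] <- list(character(0))
  setNames(lapply(sets, function(a) sort(unique(a))), profile$marker)
}

#' Compare a gDNA / wgaDNA STR profile pair
#'
#' Per marker: fully concordant (equal allele sets), allele drop-out (the
#' wgaDNA set is a strict non-empty subset of the gDNA set), marker failure
#' (empty wgaDNA set), or otherwise discordant. A sample is flagged as
#' contaminated when more than 2 alleles are observed at two or more
#' autosomal markers. The AMEL marker checks sex against `reported_sex`
#' (X,Y for male, X for female).
#'
#' @param gdna,wga Profile tibbles (`marker`, `alleles`) for one individual;
#'   all 16 panel markers must be present in each.
#' @param reported_sex "M", "F" or "unknown".
#' @param thresholds Category thresholds passed to [quality_category()].
#' @return One-row tibble: `n_markers_compared`, `n_fully_concordant`,
#'   `n_dropout`, `n_discordant_other`, `n_marker_failures`,
#'   `contamination_flag`, `sex_concordant`, `quality_category`.
#' @export
compare_str_profiles <- function(gdna, wga, reported_sex = "unknown",
                                 thresholds = list()) {
  g <- parse_allele_sets(gdna)
  w <- parse_allele_sets(wga)
  if (!setequal(names(g), STR_PANEL) || !setequal(names(w), STR_PANEL)) {
    stop("panel mismatch: both profiles must cover the 16-marker panel",
         call. = FALSE)
  }
  stat <- vapply(STR_PANEL, function(mk) {
    gs <- g[[mk]]; ws <- w[[mk]]
    if (length(ws) == 0) "failure"
    else if (setequal(gs, ws)) "concordant"
    else if (all(ws %in% gs) && length(ws) < length(gs)) "dropout"
    else "discordant"
  }, character(1))
  autosomal <- setdiff(STR_PANEL, "AMEL")
  n_multi <- sum(vapply(autosomal, function(mk) length(w[[mk]]) > 2, logical(1)))
  contamination <- n_multi >= 2
  sex_conc <- if (reported_sex == "M") setequal(w[["AMEL"]], c("X", "Y"))
  else if (reported_sex == "F") setequal(w[["AMEL"]], "X")
  else NA
  cmp <- tibble::tibble(
    n_markers_compared = length(STR_PANEL),
    n_fully_concordant = sum(stat == "concordant"),
    n_dropout = sum(stat == "dropout"),
    n_discordant_other = sum(stat == "discordant"),
    n_marker_failures = sum(stat == "failure"),
    contamination_flag = contamination,
    sex_concordant = sex_conc)
  cmp$quality_category <- quality_category(cmp, thresholds)
  cmp
}

#' STR quality category
#'
#' Default rule: `high` when at least `high_min_concordant` (15) markers are
#' fully concordant and there are no marker failures; `poor` when there are
#' at least `poor_min_dropouts` (3) drop-outs, at least `poor_min_failures`
#' (2) marker failures, or contamination; otherwise `intermediate`.
#'
#' @param comparison Row(s) from [compare_str_profiles()].
#' @param thresholds Named list overriding the cutpoints above.
#' @return Character vector of categories.
#' @export
quality_category <- function(comparison, thresholds = list()) {
  th <- utils::modifyList(
    list(high_min_concordant = 15L, high_max_failures = 0L,
         poor_min_dropouts = 3L, poor_min_failures = 2L), thresholds)
  dplyr::case_when(
    comparison$n_dropout >= th$poor_min_dropouts |
      comparison$n_marker_failures >= th$poor_min_failures |
      comparison$contamination_flag ~ "poor",
    comparison$n_fully_concordant >= th$high_min_concordant &
      comparison$n_marker_failures <= th$high_max_failures ~ "high",
    .default = "intermediate")
}

#' Compare all gDNA / wgaDNA profile pairs in a cohort
#'
#' Pairs every wgaDNA sample's profile with its individual's gDNA profile.
#'
#' @param profiles Long profile tibble (as from [simulate_str_profiles()]).
#' @param cohort Sample sheet tibble (for reported sex).
#' @param thresholds Category thresholds.
#' @return Tibble: `individual_id`, `sample_id` (the wgaDNA sample) plus the
#'   [compare_str_profiles()] columns.
#' @export
compare_str_cohort <- function(profiles, cohort, thresholds = list()) {
  sex_of <- cohort |>
    dplyr::distinct(.data$individual_id, .data$reported_sex)
  wga <- dplyr::filter(profiles, .data$input_type == "wgaDNA")
  gdna <- dplyr::filter(profiles, .data$input_type == "gDNA")
  purrr::map_dfr(unique(wga$sample_id), function(sid) {
    wp <- dplyr::filter(wga, .data$sample_id == sid)
    ind <- wp$individual_id[1]
    gp <- dplyr::filter(gdna, .data$individual_id == ind)
    if (nrow(gp) == 0) return(NULL)
    sex <- sex_of$reported_sex[match(ind, sex_of$individual_id)]
    if (is.na(sex)) sex <- "unknown"
    dplyr::bind_cols(
      tibble::tibble(individual_id = ind, sample_id = sid),
      compare_str_profiles(gp, wp, reported_sex = sex,
                           thresholds = thresholds))
  })
}

#' STR-screen cross-tabulation and counterfactual failure rate
#'
#' Cross-tabulates array call-rate failure by STR quality category and
#' source material, and computes the counterfactual wgaDNA failure rate had
#' poor-category samples been screened out before genotyping.
#'
#' @param comparisons Output of [compare_str_cohort()] (wgaDNA samples).
#' @param call_rates Output of [compute_call_rates()].
#' @param cohort Sample sheet tibble.
#' @return List `by_category` (tibble: category x source failure rates),
#'   `observed` and `counterfactual` (tibbles with overall and per-source
#'   wgaDNA failure percentages).
#' @export
screen_report <- function(comparisons, call_rates, cohort) {
  x <- comparisons |>
    dplyr::left_join(call_rates[, c("sample_id", "passes")], by = "sample_id") |>
    dplyr::left_join(cohort[, c("sample_id", "source_material")],
                     by = "sample_id") |>
    dplyr::filter(!is.na(.data$passes))
  by_category <- x |>
    dplyr::group_by(.data$quality_category, .data$source_material) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     n_failing = sum(!.data$passes), .groups = "drop") |>
    dplyr::mutate(pct_failing = 100 * .data$n_failing / .data$n_samples)
  rate_tbl <- function(d) {
    per_source <- d |>
      dplyr::group_by(source_material = .data$source_material) |>
      dplyr::summarise(n_samples = dplyr::n(),
                       n_failing = sum(!.data$passes), .groups = "drop")
    dplyr::bind_rows(
      tibble::tibble(source_material = "all", n_samples = nrow(d),
                     n_failing = sum(!d$passes)),
      per_source) |>
      dplyr::mutate(pct_failing = 100 * .data$n_failing / .data$n_samples)
  }
  list(by_category = by_category,
       observed = rate_tbl(x),
       counterfactual = rate_tbl(dplyr::filter(x, .data$quality_category != "poor")))
}
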