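# End-to-end orchestration: simulate -> sample QC -> concordance ->
# locus QC -> wave normalization -> CNV -> STR screen.

#' Aggregate matched-pair CNV concordance across individuals
#'
#' For every individual with at least one analyzed sample of each input
#' type, events of the first analyzed gDNA sample are taken as reference
#' and compared against the first analyzed wgaDNA sample with
#' [match_events()]; counts are summed across individuals and the aggregate
#' concordance rate is `sum(TP) / sum(reference events)`.
#'
#' @param events Event tibble from [call_cnv_events()] (determined classes
#'   only are compared; events flagged `needs_review` are dropped, matching
#'   manual-review exclusion of unclear calls).
#' @param cohort Sample sheet tibble.
#' @param analyzed_samples Character vector of samples that went through
#'   CNV calling (needed so an event-free sample counts as zero events).
#' @param min_reciprocal_overlap Passed to [match_events()].
#' @return Tibble `n_individuals`, `n_events_reference`, `n_tp`, `n_fn`,
#'   `n_fp`, `concordance_rate`.
#' @export
cnv_matched_concordance <- function(events, cohort, analyzed_samples,
                                    min_reciprocal_overlap = 0.5) {
  events <- dplyr::filter(events, !.data$needs_review)
  an <- cohort |>
    dplyr::filter(.data$sample_id %in% analyzed_samples) |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      gdna = dplyr::first(.data$sample_id[.data$input_type == "gDNA"]),
      wga = dplyr::first(.data$sample_id[.data$input_type == "wgaDNA"])) |>
    dplyr::filter(!is.na(.data$gdna), !is.na(.data$wga))
  acc <- purrr::map_dfr(seq_len(nrow(an)), function(i) {
    match_events(
      dplyr::filter(events, .data$sample_id == an$gdna[i]),
      dplyr::filter(events, .data$sample_id == an$wga[i]),
      min_reciprocal_overlap)
  })
  n_ref <- sum(acc$n_events_reference)
  tibble::tibble(
    n_individuals = nrow(an),
    n_events_reference = n_ref,
    n_tp = sum(acc$n_tp), n_fn = sum(acc$n_fn), n_fp = sum(acc$n_fp),
    concordance_rate = if (n_ref > 0) sum(acc$n_tp) / n_ref else NA_real_)
}

#' Run the full QC pipeline on a synthetic study
#'
#' Orchestrates every stage with one pair of configs and returns a
#' consolidated report. When `out_dir` is given, stage tables are written
#' as TSV and the headline metrics as JSON.
#'
#' @param config A [sim_config()] describing the study to simulate, or an
#'   existing [simulate_study()] result.
#' @param qc A [qc_config()].
#' @param out_dir Optional output directory.
#' @param run_cnv Set FALSE to skip the (slower) CNV stage.
#' @return List of class `arrayqc_report`.
#' @export
run_pipeline <- function(config = sim_config(), qc = qc_config(),
                         out_dir = NULL, run_cnv = TRUE) {
  sim <- if (inherits(config, "arrayqc_sim")) config else simulate_study(config)
  calls <- sim$calls
  cohort <- sim$cohort
  manifest <- sim$manifest

  # --- sample QC
  denominators <- compute_denominators(calls, cohort)
  call_rates <- compute_call_rates(calls, denominators, cohort,
                                   threshold = qc$call_rate_threshold)
  systematic <- detect_systematic_failures(call_rates, cohort,
                                           plate_tail_p = qc$plate_tail_p)
  het <- compute_heterozygosity(calls, manifest) |>
    flag_het_outliers(k = qc$het_fence_k)
  failure_report <- failure_rate_report(call_rates, cohort)
  repeats <- select_repeats(call_rates, het)

  # --- replicate concordance
  pairs <- pair_replicates(cohort, call_rates) |>
    compute_pair_concordance(calls, pairs = _)
  concordance_summary <- summarize_concordance(pairs,
                                               floor = qc$concordance_floor)

  # --- locus QC + duplicate loci
  probe_classes <- classify_probe_failures(calls, cohort)
  locus_classes <- collapse_to_loci(probe_classes, manifest)
  windows <- window_failure_counts(locus_classes, manifest,
                                   window_size = qc$window_size_bp) |>
    flag_subtelomeric(k_terminal = qc$subtelomere_k)
  gc_assoc <- gc_association(windows, seed = qc$seed)
  maf <- compute_maf(calls, cohort, manifest)
  dup <- duplicate_locus_concordance(
    calls, manifest, cohort, maf_table = maf,
    threshold = qc$duplicate_concordance_threshold)
  dup_summary <- summarize_duplicate_concordance(dup)

  # --- wave normalization
  wave <- fit_wave_model(calls, manifest, cohort, degree = qc$wave_degree)
  adjusted <- correct_waves(calls, wave, manifest)
  sds <- sd_report(calls, adjusted, manifest)

  # --- CNV on matched-pair samples
  cnv <- NULL
  if (run_cnv) {
    gate <- noise_gate(sds, threshold = qc$lrr_sd_gate)
    pass <- call_rates$sample_id[call_rates$passes]
    matched_inds <- cohort |>
      dplyr::filter(.data$sample_id %in% pass) |>
      dplyr::distinct(.data$individual_id, .data$input_type) |>
      dplyr::count(.data$individual_id) |>
      dplyr::filter(.data$n == 2) |>
      dplyr::pull(.data$individual_id)
    eligible <- cohort |>
      dplyr::filter(.data$individual_id %in% matched_inds,
                    .data$sample_id %in% pass,
                    .data$sample_id %in% gate$sample_id[gate$eligible]) |>
      dplyr::pull(.data$sample_id)
    events <- call_cnv_events(
      adjusted, manifest, eligible, alpha = qc$cbs_alpha,
      n_permutations = qc$cbs_n_permutations,
      min_probes = qc$cbs_min_probes, seed = qc$seed, delta = qc$baf_delta)
    cnv <- list(
      eligible_samples = eligible, events = events,
      concordance = cnv_matched_concordance(events, cohort, eligible,
                                            qc$cnv_overlap))
  }

  # --- STR screen
  str_report <- NULL
  if (!is.null(sim$str) && nrow(sim$str$profiles) > 0) {
    comparisons <- compare_str_cohort(sim$str$profiles, cohort)
    str_report <- list(comparisons = comparisons,
                       screen = screen_report(comparisons, call_rates, cohort))
  }

  report <- structure(list(
    config = sim$config, qc = qc, sim = sim,
    denominators = denominators, call_rates = call_rates,
    systematic = systematic, heterozygosity = het,
    failure_report = failure_report, repeats = repeats,
    pairs = pairs, concordance_summary = concordance_summary,
    windows = windows, gc_association = gc_assoc,
    maf = maf, duplicate_loci = dup, duplicate_summary = dup_summary,
    wave_model = wave, sd_report = sds, cnv = cnv, str = str_report
  ), class = "arrayqc_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Stage tables as TSV, window map as BED, headline metrics as JSON.
#'
#' @param report An `arrayqc_report`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_tsv(x, file.path(out_dir, name))
  w(report$call_rates, "call_rates.tsv")
  w(report$failure_report, "failure_rates.tsv")
  w(report$heterozygosity, "heterozygosity.tsv")
  w(report$pairs, "replicate_pairs.tsv")
  w(report$duplicate_loci, "duplicate_loci.tsv")
  w(report$windows, "window_failures.tsv")
  w(report$sd_report, "sd_report.tsv")
  if (!is.null(report$cnv)) w(report$cnv$events, "cnv_events.tsv")
  write_window_bed(report$windows, file.path(out_dir, "window_failures.bed"),
                   window_size = report$qc$window_size_bp)
  jsonlite::write_json(report_metrics(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Headline metrics of a pipeline report
#'
#' @param report An `arrayqc_report`.
#' @return Named list of scalar metrics and small tables.
#' @export
report_metrics <- function(report) {
  fr <- report$failure_report
  pct <- function(it, sm) {
    v <- fr$pct_failing[fr$input_type == it & fr$source_material == sm]
    if (length(v)) v else NA_real_
  }
  cs <- report$concordance_summary$summary
  conc <- function(type) {
    v <- cs$mean_concordance[cs$pair_type == type]
    if (length(v)) 100 * v else NA_real_
  }
  list(
    denominators = as.list(setNames(report$denominators$denominator,
                                    report$denominators$input_type)),
    failure_pct = list(overall = pct("all", "all"),
                       gdna = pct("gDNA", "all"),
                       wga = pct("wgaDNA", "all")),
    median_heterozygosity = median(report$heterozygosity$het_rate),
    mean_concordance_pct = list(gg = conc("gDNA-gDNA"),
                                gw = conc("gDNA-wgaDNA"),
                                ww = conc("wgaDNA-wgaDNA")),
    gc_association_r = report$gc_association$pearson,
    mean_lrr_sd = list(raw = mean(report$sd_report$lrr_sd_raw),
                       adjusted = mean(report$sd_report$lrr_sd_adjusted)),
    cnv_concordance = if (!is.null(report$cnv)) {
      as.list(report$cnv$concordance)
    },
    str_counterfactual_failure_pct = if (!is.null(report$str)) {
      obs <- report$str$screen$observed
      cf <- report$str$screen$counterfactual
      list(observed = obs$pct_failing[obs$source_material == "all"],
           counterfactual = cf$pct_failing[cf$source_material == "all"])
    }
  )
}

#' @export
print.arrayqc_report <- function(x, ...) {
  m <- report_metrics(x)
  cat("arrayqc pipeline report\n")
  cat(sprintf("  samples: %d (%d individuals); probes: %d\n",
              nrow(x$sim$cohort), dplyr::n_distinct(x$sim$cohort$individual_id),
              nrow(x$sim$manifest)))
  cat(sprintf("  denominators: gDNA %s / wgaDNA %s\n",
              format(m$denominators$gDNA, big.mark = ","),
              format(m$denominators$wgaDNA, big.mark = ",")))
  cat(sprintf("  failure rate: overall %.2f%% (gDNA %.2f%%, wgaDNA %.2f%%)\n",
              m$failure_pct$overall, m$failure_pct$gdna, m$failure_pct$wga))
  cat(sprintf("  median heterozygosity: %.3f\n", m$median_heterozygosity))
  cat(sprintf("  mean concordance: gg %.2f%% | gw %.2f%% | ww %.2f%%\n",
              m$mean_concordance_pct$gg, m$mean_concordance_pct$gw,
              m$mean_concordance_pct$ww))
  if (!is.null(m$cnv_concordance) && !is.na(m$cnv_concordance$concordance_rate)) {
    cat(sprintf("  CNV matched-pair concordance: %.1f%% (%d TP / %d ref, %d FP)\n",
                100 * m$cnv_concordance$concordance_rate,
                m$cnv_concordance$n_tp, m$cnv_concordance$n_events_reference,
                m$cnv_concordance$n_fp))
  }
  invisible(x)
}
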