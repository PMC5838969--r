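# Replicate-pair and duplicate-locus genotype concordance.

#' Enumerate within-individual replicate pairs
#'
#' All unordered pairs of samples from the same individual, typed as
#' gDNA-gDNA, gDNA-wgaDNA or wgaDNA-wgaDNA. If `call_rates` is supplied,
#' pairs where either sample fails the call-rate threshold are marked
#' excluded.
#'
#' @param cohort Sample sheet tibble.
#' @param call_rates Optional output of [compute_call_rates()].
#' @return Tibble `individual_id`, `sample_a`, `sample_b`, `pair_type`,
#'   `excluded`.
#' @export
pair_replicates <- function(cohort, call_rates = NULL) {
  pairs <- cohort |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(pair = list({
      sid <- .data$sample_id
      ity <- .data$input_type
      cmb <- utils::combn(seq_along(sid), 2)
      tibble::tibble(sample_a = sid[cmb[1, ]], sample_b = sid[cmb[2, ]],
                     type_a = ity[cmb[1, ]], type_b = ity[cmb[2, ]])
    })) |>
    tidyr::unnest("pair") |>
    dplyr::mutate(pair_type = dplyr::case_when(
      .data$type_a == "gDNA" & .data$type_b == "gDNA" ~ "gDNA-gDNA",
      .data$type_a == "wgaDNA" & .data$type_b == "wgaDNA" ~ "wgaDNA-wgaDNA",
      .default = "gDNA-wgaDNA")) |>
    dplyr::select(-"type_a", -"type_b")
  if (is.null(call_rates)) {
    pairs$excluded <- FALSE
  } else {
    pass <- setNames(call_rates$passes, call_rates$sample_id)
    pairs$excluded <- !(pass[pairs$sample_a] & pass[pairs$sample_b])
  }
  pairs
}

#' Genotype concordance of replicate pairs
#'
#' Compared over probes where both samples have a genotype (neither NC);
#' concordant means identical AA/AB/BB class. Symmetric in the pair.
#'
#' @param calls Call table.
#' @param pairs Output of [pair_replicates()] (excluded pairs are skipped
#'   but kept in the output with NA metrics).
#' @return `pairs` with `n_both_called`, `n_concordant`, `concordance`.
#' @export
compute_pair_concordance <- function(calls, pairs) {
  g <- calls[calls$genotype != "NC", c("sample_id", "probe_id", "genotype")]
  gs <- split(g[, c("probe_id", "genotype")], g$sample_id)
  res <- purrr::pmap_dfr(
    pairs[, c("sample_a", "sample_b", "excluded")],
    function(sample_a, sample_b, excluded) {
      if (excluded) {
        return(tibble::tibble(n_both_called = NA_integer_,
                              n_concordant = NA_integer_,
                              concordance = NA_real_))
      }
      a <- gs[[sample_a]]
      b <- gs[[sample_b]]
      m <- match(a$probe_id, b$probe_id)
      both <- !is.na(m)
      n_both <- sum(both)
      if (n_both == 0) {
        stop("no co-called probes for pair ", sample_a, " / ", sample_b,
             call. = FALSE)
      }
      n_conc <- sum(a$genotype[both] == b$genotype[m[both]])
      tibble::tibble(n_both_called = n_both, n_concordant = n_conc,
                     concordance = n_conc / n_both)
    })
  dplyr::bind_cols(pairs, res)
}

#' Summarize replicate concordance by pair type
#'
#' Means and minima over included (non-excluded) pairs; pairs below
#' `floor` are listed as outliers.
#'
#' @param pairs Output of [compute_pair_concordance()].
#' @param floor Outlier floor (default 0.995).
#' @return List with `summary` (tibble per pair type: `n_pairs`,
#'   `mean_concordance`, `min_concordance`, `n_outliers`) and `outliers`
#'   (the offending pairs).
#' @export
summarize_concordance <- function(pairs, floor = 0.995) {
  inc <- dplyr::filter(pairs, !.data$excluded)
  if (nrow(inc) == 0) stop("no included pairs", call. = FALSE)
  summary <- inc |>
    dplyr::group_by(.data$pair_type) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     mean_concordance = mean(.data$concordance),
                     min_concordance = min(.data$concordance),
                     n_outliers = sum(.data$concordance < floor))
  list(summary = summary,
       outliers = dplyr::filter(inc, .data$concordance < floor))
}

#' Minor allele frequencies from genotype counts
#'
#' Computed over one sample per individual: gDNA preferred, then the sample
#' with the highest call rate. The B-allele frequency is
#' `(n_AB + 2 n_BB) / (2 n_called)`; MAF is folded to `[0, 0.5]`.
#'
#' @param calls Call table.
#' @param cohort Sample sheet tibble.
#' @param manifest Probe manifest (duplicate probes of one locus are
#'   represented by their first probe).
#' @return Tibble `locus_id`, `maf`, `f_b`, `n_individuals`.
#' @export
compute_maf <- function(calls, cohort, manifest) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  rate <- calls |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(rate = mean(.data$genotype != "NC"))
  chosen <- cohort |>
    dplyr::left_join(rate, by = "sample_id") |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::arrange(.data$input_type != "gDNA", dplyr::desc(.data$rate),
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::pull(.data$sample_id)
  first_probe <- manifest |>
    dplyr::distinct(.data$locus_id, .keep_all = TRUE)
  calls |>
    dplyr::filter(.data$sample_id %in% chosen,
                  .data$probe_id %in% first_probe$probe_id,
                  .data$genotype != "NC") |>
    dplyr::left_join(first_probe[, c("probe_id", "locus_id")], by = "probe_id") |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      f_b = (sum(.data$genotype == "AB") + 2 * sum(.data$genotype == "BB")) /
        (2 * dplyr::n()),
      n_individuals = dplyr::n()) |>
    dplyr::mutate(maf = pmin(.data$f_b, 1 - .data$f_b)) |>
    dplyr::select("locus_id", "maf", "f_b", "n_individuals")
}

#' Duplicate-locus concordance by input type
#'
#' For every locus assayed by two or more probes, and separately for gDNA
#' and wgaDNA samples: over samples in which all the locus's probes are
#' called, the fraction whose probe calls all agree. Aggregation is
#' within-sample across probes first, then across samples. Loci are classed
#' at the concordance threshold (default 0.99, "greater than" = high):
#' `both_high`, `both_low`, `low_gdna_only`, `low_wga_only`; the class is
#' defined only where both input types could be evaluated.
#'
#' @param calls Call table.
#' @param manifest Probe manifest.
#' @param cohort Sample sheet tibble.
#' @param maf_table Optional output of [compute_maf()], joined in.
#' @param threshold High-concordance boundary (default 0.99).
#' @return Tibble `locus_id`, `n_probes`, `concordance_gdna`,
#'   `concordance_wga`, `n_samples_gdna`, `n_samples_wga`, `class`,
#'   and `maf` when supplied.
#' @export
duplicate_locus_concordance <- function(calls, manifest, cohort,
                                        maf_table = NULL, threshold = 0.99) {
  dup_loci <- manifest |>
    dplyr::count(.data$locus_id) |>
    dplyr::filter(.data$n >= 2)
  if (nrow(dup_loci) == 0) stop("no duplicate loci in manifest", call. = FALSE)
  dup_probes <- manifest |>
    dplyr::filter(.data$locus_id %in% dup_loci$locus_id) |>
    dplyr::select("probe_id", "locus_id")
  input_of <- setNames(cohort$input_type, cohort$sample_id)
  x <- calls |>
    dplyr::inner_join(dup_probes, by = "probe_id") |>
    dplyr::mutate(input_type = input_of[.data$sample_id]) |>
    dplyr::group_by(.data$locus_id, .data$sample_id, .data$input_type) |>
    dplyr::summarise(
      all_called = all(.data$genotype != "NC") &
        dplyr::n() >= 2,
      agree = .data$all_called && dplyr::n_distinct(.data$genotype) == 1,
      .groups = "drop") |>
    dplyr::filter(.data$all_called) |>
    dplyr::group_by(.data$locus_id, .data$input_type) |>
    dplyr::summarise(concordance = mean(.data$agree),
                     n_samples = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "input_type",
                       values_from = c("concordance", "n_samples"))
  for (col in c("concordance_gDNA", "concordance_wgaDNA",
                "n_samples_gDNA", "n_samples_wgaDNA")) {
    if (!col %in% names(x)) x[[col]] <- NA_real_
  }
  out <- x |>
    dplyr::transmute(
      .data$locus_id,
      concordance_gdna = .data$concordance_gDNA,
      concordance_wga = .data$concordance_wgaDNA,
      n_samples_gdna = .data$n_samples_gDNA,
      n_samples_wga = .data$n_samples_wgaDNA,
      class = dplyr::case_when(
        is.na(.data$concordance_gDNA) | is.na(.data$concordance_wgaDNA) ~
          NA_character_,
        .data$concordance_gDNA > threshold &
          .data$concordance_wgaDNA > threshold ~ "both_high",
        .data$concordance_gDNA <= threshold &
          .data$concordance_wgaDNA <= threshold ~ "both_low",
        .data$concordance_gDNA <= threshold ~ "low_gdna_only",
        .default = "low_wga_only")) |>
    dplyr::left_join(dup_loci |> dplyr::rename(n_probes = "n"),
                     by = "locus_id") |>
    dplyr::relocate("n_probes", .after = "locus_id")
  if (!is.null(maf_table)) {
    out <- dplyr::left_join(out, maf_table[, c("locus_id", "maf")],
                            by = "locus_id")
  }
  out
}

#' Summary of duplicate-locus concordance
#'
#' Class proportions over evaluable loci, MAF strata counts (<= 5%, <= 1%)
#' and the squared Pearson correlation of concordance with MAF per input
#' type.
#'
#' @param dup Output of [duplicate_locus_concordance()] including `maf`.
#' @return List `class_table`, `maf_strata`, `r_squared`.
#' @export
summarize_duplicate_concordance <- function(dup) {
  ev <- dplyr::filter(dup, !is.na(.data$class))
  class_table <- ev |>
    dplyr::count(.data$class) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n))
  maf_strata <- if ("maf" %in% names(dup)) {
    tibble::tibble(
      stratum = c("maf_le_5pct", "maf_le_1pct"),
      n_loci = c(sum(ev$maf <= 0.05, na.rm = TRUE),
                 sum(ev$maf <= 0.01, na.rm = TRUE)))
  } else {
    tibble::tibble(stratum = character(), n_loci = integer())
  }
  r2 <- function(conc, maf) {
    ok <- complete.cases(conc, maf)
    if (sum(ok) < 3 || sd(conc[ok]) == 0 || sd(maf[ok]) == 0) {
      return(NA_real_)
    }
    cor(conc[ok], maf[ok])^2
  }
  r_squared <- if ("maf" %in% names(dup)) {
    c(gdna = r2(ev$concordance_gdna, ev$maf),
      wga = r2(ev$concordance_wga, ev$maf))
  } else {
    c(gdna = NA_real_, wga = NA_real_)
  }
  list(class_table = class_table, maf_strata = maf_strata,
       r_squared = r_squared)
}
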