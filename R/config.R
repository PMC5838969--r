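#' Configuration for the synthetic Infinium-style study generator
#'
#' Builds and validates the single configuration object consumed by all
#' `simulate_*()` generators. Defaults describe a scaled-down two-input
#' (gDNA / wgaDNA) cohort drawn from three biospecimen sources with the
#' artifact structure of whole-genome-amplified input: a rare-variant-heavy
#' MAF spectrum (expected heterozygosity ~0.137), per-source sample quality,
#' locus-specific allele drop-out in wgaDNA, subtelomeric under-amplification,
#' chip/plate systematic failures, GC/CpG waves on the Log R Ratio and
#' injected copy-number / mosaic events with truth tables.
#'
#' Sample quality `q` in `[0, 1]` is the latent driver of every per-sample
#' artifact: the GC-score distribution (hence call rate), allele drop-out,
#' LRR noise and STR drop-out. Under the default GC-score model a sample
#' crosses the 95% call-rate threshold near `q = 0.30`, so the per-stratum
#' `quality_model` means/sds are calibrated to reproduce the intended
#' failure-rate gradient (wgaDNA: buccal > blood > Oragene; gDNA uniform).
#'
#' @param seed Integer seed; identical seed + config gives identical output.
#' @param n_chromosomes Number of simulated autosomes (labelled "1", "2", ...).
#' @param chromosome_length_bp Length of each chromosome in bp.
#' @param n_loci Total number of probes on the simulated array.
#' @param duplicate_locus_fraction Fraction of probes that are duplicate
#'   copies of another probe's locus (duplicate pairs share locus id,
#'   position and alleles).
#' @param maf_params List with `rare`, `common` (Beta shape pairs) and
#'   `weight_rare`; minor allele frequency is `0.5 * Beta` draws from the
#'   mixture. Defaults give expected heterozygosity 0.137.
#' @param n_individuals Number of distinct individuals.
#' @param replicate_design Named integer vector: `full` individuals get
#'   2 gDNA + 2 wgaDNA samples, `gw` 1 gDNA + 1 wgaDNA, `gg` 2 gDNA,
#'   `ww` 2 wgaDNA; remaining individuals get a single sample.
#' @param gdna_fraction Probability a singleton individual contributes a gDNA
#'   (rather than wgaDNA) sample.
#' @param source_mix Named proportions over blood/buccal/oragene; must sum
#'   to 1.
#' @param quality_model Tibble with columns `input_type`, `source_material`,
#'   `q_mean`, `q_sd` giving the per-stratum quality distribution
#'   (Normal, truncated to `[0.02, 0.98]`).
#' @param gc_score_model List `a`, `b`, `phi`: GC scores are
#'   `Beta(mu * phi, (1 - mu) * phi)` with `mu = a + b * q` (clamped); the
#'   no-call threshold is applied downstream, not baked in.
#' @param gc_score_threshold GC-score no-call threshold used when forcing
#'   systematic failures to appear as no-calls.
#' @param genotype_error_rate Probability a called genotype is replaced by
#'   one of the other two classes (uniformly).
#' @param dropout_model List `prone_fraction` (fraction of loci prone to
#'   allele drop-out, each with a fixed weaker allele), `base_prob`
#'   (drop-out probability per prone heterozygous wgaDNA call at reference
#'   quality), `quality_slope` and `q_ref` (drop-out probability is
#'   `base_prob + quality_slope * (q_ref - q)`, clamped to `[0, 1]`).
#' @param probe_fail_rates Named vector `all` / `wga_only`: per-probe
#'   probability of complete failure (all samples) and of baseline
#'   wgaDNA-only failure outside subtelomeres.
#' @param subtelomere_windows Number of terminal 50-kb windows per chromosome
#'   arm subject to under-amplification in wgaDNA.
#' @param subtelomere_affected_prob Probability a given chromosome end is
#'   under-amplified at all.
#' @param subtelomere_fail_prob Probability a locus inside an affected
#'   terminal window fails all wgaDNA samples.
#' @param window_size_bp Window size used for the subtelomere model (matches
#'   the 50-kb analysis windows).
#' @param chip_fail_rate Probability a chip suffers a systematic failure
#'   (all 4 samples degraded to `q = 0.10`).
#' @param plate_fail_rate Same, per plate.
#' @param gc_wave_amplitude LRR units per unit GC deviation from the cohort
#'   mean (per-sample wave scale drawn from `wave_scale_range`).
#' @param cpg_wave_amplitude LRR units per unit CpG-density deviation.
#' @param wave_scale_range Per-sample multiplier range for the wave term.
#' @param chip_offset_sd SD of the per-chip additive LRR offset.
#' @param lrr_noise_sd Baseline LRR noise SD; per-sample SD is
#'   `lrr_noise_sd * (1 + noise_quality_slope * (1 - q))`.
#' @param noise_quality_slope See `lrr_noise_sd`.
#' @param baf_noise_sd Named vector `het` / `hom`: BAF noise SDs.
#' @param cnv_spec Tibble of injected event types with columns `class`
#'   (gain / loss / mosaic_cnloh), `n_probes`, `mosaic_fraction` (NA unless
#'   mosaic), `n_carriers`. Carriers are drawn from individuals that have
#'   both gDNA and wgaDNA samples so matched-pair concordance has support.
#' @param wga_event_attenuation Probability an injected event is attenuated
#'   (shift scaled by 0.25) in a given wgaDNA sample, producing false
#'   negatives in matched-pair CNV comparison.
#' @param str_dropout_slope,str_fail_slope STR drop-out / marker-failure
#'   probabilities are `pmax(0, slope * (q0 - q))` with `q0 = 0.5` (drop-out)
#'   and `0.35` (failure).
#' @param str_contamination_rate Probability a wgaDNA sample is contaminated
#'   (third alleles injected at >= 2 autosomal markers).
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 4L,
                       chromosome_length_bp = 5e6,
                       n_loci = 4000L,
                       duplicate_locus_fraction = 0.015,
                       maf_params = list(rare = c(0.25, 8), common = c(1.4, 1.1),
                                         weight_rare = 0.68),
                       n_individuals = 300L,
                       replicate_design = c(full = 12L, gw = 6L, gg = 4L, ww = 3L),
                       gdna_fraction = 0.63,
                       source_mix = c(blood = 0.22, buccal = 0.28, oragene = 0.50),
                       quality_model = default_quality_model(),
                       gc_score_model = list(a = 0.3765, b = 0.75, phi = 5),
                       gc_score_threshold = 0.25,
                       genotype_error_rate = 5e-5,
                       dropout_model = list(prone_fraction = 0.0055,
                                            base_prob = 0.8,
                                            quality_slope = 0.3,
                                            q_ref = 0.55),
                       probe_fail_rates = c(all = 0.002, wga_only = 0.0005),
                       subtelomere_windows = 3L,
                       subtelomere_affected_prob = 0.5,
                       subtelomere_fail_prob = 0.7,
                       window_size_bp = 50000L,
                       chip_fail_rate = 0.002,
                       plate_fail_rate = 0.002,
                       gc_wave_amplitude = 0.20,
                       cpg_wave_amplitude = 1.0,
                       wave_scale_range = c(0.5, 1.5),
                       chip_offset_sd = 0.03,
                       lrr_noise_sd = 0.12,
                       noise_quality_slope = 1.0,
                       baf_noise_sd = c(het = 0.03, hom = 0.012),
                       cnv_spec = default_cnv_spec(),
                       wga_event_attenuation = 0.1,
                       str_dropout_slope = 0.5,
                       str_fail_slope = 0.3,
                       str_contamination_rate = 0.01) {
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_bp = chromosome_length_bp, n_loci = as.integer(n_loci),
    duplicate_locus_fraction = duplicate_locus_fraction,
    maf_params = maf_params, n_individuals = as.integer(n_individuals),
    replicate_design = replicate_design, gdna_fraction = gdna_fraction,
    source_mix = source_mix, quality_model = quality_model,
    gc_score_model = gc_score_model, gc_score_threshold = gc_score_threshold,
    genotype_error_rate = genotype_error_rate, dropout_model = dropout_model,
    probe_fail_rates = probe_fail_rates,
    subtelomere_windows = as.integer(subtelomere_windows),
    subtelomere_affected_prob = subtelomere_affected_prob,
    subtelomere_fail_prob = subtelomere_fail_prob,
    window_size_bp = as.integer(window_size_bp),
    chip_fail_rate = chip_fail_rate, plate_fail_rate = plate_fail_rate,
    gc_wave_amplitude = gc_wave_amplitude,
    cpg_wave_amplitude = cpg_wave_amplitude,
    wave_scale_range = wave_scale_range, chip_offset_sd = chip_offset_sd,
    lrr_noise_sd = lrr_noise_sd, noise_quality_slope = noise_quality_slope,
    baf_noise_sd = baf_noise_sd, cnv_spec = cnv_spec,
    wga_event_attenuation = wga_event_attenuation,
    str_dropout_slope = str_dropout_slope, str_fail_slope = str_fail_slope,
    str_contamination_rate = str_contamination_rate
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
default_quality_model <- function() {
  tibble::tribble(
    ~input_type, ~source_material, ~q_mean, ~q_sd,
    "gDNA",    "blood",   0.572, 0.15,
    "gDNA",    "buccal",  0.560, 0.15,
    "gDNA",    "oragene", 0.563, 0.15,
    "wgaDNA",  "blood",   0.541, 0.18,
    "wgaDNA",  "buccal",  0.452, 0.22,
    "wgaDNA",  "oragene", 0.538, 0.16
  )
}

#' @rdname sim_config
#' @export
default_cnv_spec <- function() {
  tibble::tribble(
    ~class,          ~n_probes, ~mosaic_fraction, ~n_carriers,
    "gain",          30L,       NA_real_,         5L,
    "gain",          45L,       NA_real_,         3L,
    "loss",          40L,       NA_real_,         4L,
    "mosaic_cnloh",  160L,      0.4,              2L
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$chromosome_length_bp <= 0) {
    stop("invalid config: chromosome_length_bp must be positive", call. = FALSE)
  }
  if (cfg$n_loci < 100) {
    stop("invalid config: n_loci must be >= 100", call. = FALSE)
  }
  if (cfg$duplicate_locus_fraction < 0 || cfg$duplicate_locus_fraction >= 0.5) {
    stop("invalid config: duplicate_locus_fraction must be in [0, 0.5)",
         call. = FALSE)
  }
  props <- c(cfg$duplicate_locus_fraction, cfg$gdna_fraction,
             cfg$subtelomere_affected_prob, cfg$subtelomere_fail_prob,
             cfg$chip_fail_rate, cfg$plate_fail_rate,
             cfg$genotype_error_rate, cfg$wga_event_attenuation,
             cfg$probe_fail_rates, cfg$source_mix)
  if (any(props < 0 | props > 1)) {
    stop("invalid config: proportions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$source_mix) - 1) > 1e-8) {
    stop("invalid config: source_mix must sum to 1", call. = FALSE)
  }
  if (!all(c("blood", "buccal", "oragene") %in% names(cfg$source_mix))) {
    stop("invalid config: source_mix must name blood, buccal, oragene",
         call. = FALSE)
  }
  n_rep <- sum(cfg$replicate_design[c("full", "gw", "gg", "ww")], na.rm = TRUE)
  if (n_rep > cfg$n_individuals) {
    stop("invalid config: replicate design exceeds cohort size", call. = FALSE)
  }
  if (nrow(cfg$cnv_spec) > 0 && any(cfg$cnv_spec$n_probes < 1)) {
    stop("invalid config: every injected event needs size >= 1 probe",
         call. = FALSE)
  }
  cfg
}

#' Configuration for the end-to-end QC pipeline
#'
#' Collects the analysis thresholds used by [run_pipeline()]. Defaults follow
#' common Infinium QC practice: GC-score no-call threshold 0.25, 95% call-rate
#' pass boundary, 99% duplicate-locus concordance threshold, 50-kb windows,
#' CBS with permutation alpha 0.01 and a 20-probe minimum segment.
#'
#' @param gc_score_threshold GC-score below which a call is a no-call.
#' @param call_rate_threshold Pass boundary; a rate exactly at the threshold
#'   passes ("less than 95%" fails).
#' @param het_fence_k Tukey fence multiplier for heterozygosity outliers.
#' @param duplicate_concordance_threshold Duplicate-locus "high concordance"
#'   boundary (strictly greater passes).
#' @param window_size_bp Window size for locus-failure maps.
#' @param subtelomere_k Terminal covered windows flagged per chromosome end.
#' @param cbs_alpha,cbs_n_permutations,cbs_min_probes CBS parameters.
#' @param baf_delta Informative-BAF interval half-width: probes with BAF in
#'   `(delta, 1 - delta)` (or called AB) enter the mirrored-BAF series.
#' @param cnv_overlap Minimum reciprocal overlap for matched-pair CNV events.
#' @param lrr_sd_gate Post-normalization LRR SD above which a sample is
#'   excluded from CNV calling.
#' @param wave_degree Polynomial degree of the GC/CpG wave regression.
#' @param concordance_floor Replicate pairs below this concordance are listed
#'   as outliers.
#' @param plate_tail_p Binomial-tail p-value below which a plate's excess
#'   failure rate is flagged.
#' @param seed Seed used by seeded analysis steps (CBS permutations).
#'
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(gc_score_threshold = 0.25,
                      call_rate_threshold = 0.95,
                      het_fence_k = 3,
                      duplicate_concordance_threshold = 0.99,
                      window_size_bp = 50000L,
                      subtelomere_k = 3L,
                      cbs_alpha = 0.01,
                      cbs_n_permutations = 200L,
                      cbs_min_probes = 20L,
                      baf_delta = 0.15,
                      cnv_overlap = 0.5,
                      lrr_sd_gate = 0.30,
                      wave_degree = 2L,
                      concordance_floor = 0.995,
                      plate_tail_p = 1e-4,
                      seed = 1L) {
  cfg <- list(
    gc_score_threshold = gc_score_threshold,
    call_rate_threshold = call_rate_threshold,
    het_fence_k = het_fence_k,
    duplicate_concordance_threshold = duplicate_concordance_threshold,
    window_size_bp = as.integer(window_size_bp),
    subtelomere_k = as.integer(subtelomere_k),
    cbs_alpha = cbs_alpha,
    cbs_n_permutations = as.integer(cbs_n_permutations),
    cbs_min_probes = as.integer(cbs_min_probes),
    baf_delta = baf_delta,
    cnv_overlap = cnv_overlap,
    lrr_sd_gate = lrr_sd_gate,
    wave_degree = as.integer(wave_degree),
    concordance_floor = concordance_floor,
    plate_tail_p = plate_tail_p,
    seed = as.integer(seed)
  )
  thr <- c(cfg$gc_score_threshold, cfg$call_rate_threshold,
           cfg$duplicate_concordance_threshold, cfg$cbs_alpha)
  if (any(thr <= 0 | thr > 1)) {
    stop("invalid config: thresholds must lie in (0, 1]", call. = FALSE)
  }
  class(cfg) <- "qc_config"
  cfg
}
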