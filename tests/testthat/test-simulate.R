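test_that("manifest has the configured probe and duplicate-locus counts", {
  cfg <- sim_config(n_loci = 1000, duplicate_locus_fraction = 0.015,
                    n_individuals = 10, replicate_design = c(full = 1))
  man <- simulate_manifest(cfg)
  expect_equal(nrow(man), 1000)
  expect_equal(sum(duplicated(man$locus_id)), 15)
  # sorted by chromosome then position
  expect_true(all(unlist(tapply(man$position, man$chromosome,
                                function(p) diff(p) >= 0))))
  # duplicate probes share position and alleles
  dups <- man[man$locus_id %in% man$locus_id[duplicated(man$locus_id)], ]
  per <- split(dups, dups$locus_id)
  expect_true(all(vapply(per, function(d) {
    length(unique(d$position)) == 1 && length(unique(d$allele_a)) == 1 &&
      length(unique(d$allele_b)) == 1 && length(unique(d$probe_id)) == nrow(d)
  }, logical(1))))
  expect_true(all(man$allele_a != man$allele_b))
})

test_that("generators are deterministic for identical seed and config", {
  cfg <- tiny_config(seed = 9)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$str$profiles, s2$str$profiles)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(chromosome_length_bp = -1), "chromosome_length_bp")
  expect_error(sim_config(n_loci = 50), "n_loci")
  expect_error(sim_config(duplicate_locus_fraction = 0.7), "duplicate")
  expect_error(sim_config(source_mix = c(blood = 0.5, buccal = 0.5,
                                         oragene = 0.5)), "sum to 1")
  expect_error(sim_config(n_individuals = 5,
                          replicate_design = c(full = 10)),
               "replicate design")
})

test_that("cohort realizes the replicate design and chip layout", {
  cfg <- sim_config(n_individuals = 12, n_loci = 400,
                    replicate_design = c(full = 2, gw = 2, gg = 1, ww = 1),
                    gdna_fraction = 1)
  coh <- simulate_cohort(cfg)
  per_ind <- split(coh$input_type, coh$individual_id)
  full <- vapply(per_ind, function(x) sum(x == "gDNA") == 2 &&
                   sum(x == "wgaDNA") == 2, logical(1))
  expect_equal(sum(full), 2)
  gw <- vapply(per_ind, function(x) length(x) == 2 &&
                 setequal(x, c("gDNA", "wgaDNA")), logical(1))
  expect_equal(sum(gw), 2)
  # full replicates yield 1 gg, 4 gw, 1 ww pair
  pairs <- pair_replicates(coh)
  full_id <- names(per_ind)[full][1]
  pt <- table(pairs$pair_type[pairs$individual_id == full_id])
  expect_equal(as.integer(pt[c("gDNA-gDNA", "gDNA-wgaDNA", "wgaDNA-wgaDNA")]),
               c(1L, 4L, 1L))
  # at most 4 samples per chip, positions 1..n within chip
  expect_true(all(table(coh$chip_id) <= 4))
  expect_true(all(coh$chip_position %in% 1:4))
  # a multiple of 4 samples fills chips exactly
  if (nrow(coh) %% 4 == 0) expect_true(all(table(coh$chip_id) == 4))
})

test_that("artifact-free configuration gives zero LRR and full concordance", {
  cfg <- tiny_config(seed = 5, gc_wave_amplitude = 0, cpg_wave_amplitude = 0,
                     lrr_noise_sd = 0, chip_offset_sd = 0,
                     genotype_error_rate = 0,
                     dropout_model = list(prone_fraction = 0, base_prob = 0,
                                          quality_slope = 0, q_ref = 0.55),
                     probe_fail_rates = c(all = 0, wga_only = 0),
                     subtelomere_affected_prob = 0, chip_fail_rate = 0,
                     plate_fail_rate = 0)
  sim <- simulate_study(cfg)
  expect_true(all(sim$calls$lrr == 0))
  pairs <- compute_pair_concordance(sim$calls, pair_replicates(sim$cohort))
  expect_true(all(pairs$concordance == 1))
})

test_that("no-call conservation: NC count = forced mask + threshold no-calls", {
  sim <- tiny_sim()
  calls <- sim$calls
  truth <- sim$truth
  is_wga <- sim$cohort$input_type[match(calls$sample_id,
                                        sim$cohort$sample_id)] == "wgaDNA"
  forced <- calls$probe_id %in% truth$failed_all_probes |
    (is_wga & calls$probe_id %in% truth$wga_fail_probes)
  n_thresh <- sum(!forced & calls$gc_score < sim$config$gc_score_threshold)
  expect_equal(sum(calls$genotype == "NC"), sum(forced) + n_thresh)
  # forced entries are always no-calls
  expect_true(all(calls$genotype[forced] == "NC"))
})

test_that("allele drop-out follows its closed form: observed het = h(1 - d)", {
  d <- 0.4
  cfg <- tiny_config(
    seed = 31, n_individuals = 40, n_loci = 2000, n_chromosomes = 2,
    replicate_design = c(full = 2),
    dropout_model = list(prone_fraction = 1, base_prob = d,
                         quality_slope = 0, q_ref = 0.55),
    genotype_error_rate = 0, probe_fail_rates = c(all = 0, wga_only = 0),
    subtelomere_affected_prob = 0, chip_fail_rate = 0, plate_fail_rate = 0)
  sim <- simulate_study(cfg)
  het <- compute_heterozygosity(sim$calls, sim$manifest) |>
    dplyr::left_join(sim$cohort[, c("sample_id", "input_type")],
                     by = "sample_id")
  h_g <- mean(het$het_rate[het$input_type == "gDNA"])
  h_w <- mean(het$het_rate[het$input_type == "wgaDNA"])
  # dropped hets are reported homozygous, so they stay in the denominator
  expect_equal(h_w, h_g * (1 - d), tolerance = 0.05)
})

test_that("configured wgaDNA failure-rate ordering over sources is recovered", {
  wga_failure_pct <- function(cfg) {
    sim <- simulate_study(cfg)
    den <- compute_denominators(sim$calls, sim$cohort)
    cr <- compute_call_rates(sim$calls, den, sim$cohort)
    fr <- failure_rate_report(cr, sim$cohort)
    wga <- fr[fr$input_type == "wgaDNA" & fr$source_material != "all", ]
    setNames(wga$pct_failing, wga$source_material)
  }
  # default quality gradient: buccal clearly worst (its gap is large);
  # the blood/oragene gap is ~2 points and needs a bigger cohort to resolve
  pct <- wga_failure_pct(sim_config(
    seed = 13, n_individuals = 400, n_loci = 1200,
    replicate_design = c(full = 4, gw = 2, gg = 1, ww = 1),
    source_mix = c(blood = 1 / 3, buccal = 1 / 3, oragene = 1 / 3)))
  expect_gt(pct[["buccal"]], pct[["blood"]])
  expect_gt(pct[["buccal"]], pct[["oragene"]])
  # a sharper configured gradient is recovered in full order
  qm <- default_quality_model()
  qm$q_mean[qm$input_type == "wgaDNA"] <-
    c(0.50, 0.35, 0.65)[match(qm$source_material[qm$input_type == "wgaDNA"],
                              c("blood", "buccal", "oragene"))]
  pct2 <- wga_failure_pct(sim_config(
    seed = 14, n_individuals = 300, n_loci = 800,
    replicate_design = c(full = 2), quality_model = qm,
    source_mix = c(blood = 1 / 3, buccal = 1 / 3, oragene = 1 / 3)))
  expect_gt(pct2[["buccal"]], pct2[["blood"]])
  expect_gt(pct2[["blood"]], pct2[["oragene"]])
})

test_that("STR profiles inherit truth exactly when quality artifacts are off", {
  cfg <- tiny_config(seed = 8, str_dropout_slope = 0, str_fail_slope = 0,
                     str_contamination_rate = 0)
  coh <- simulate_cohort(cfg)
  strp <- simulate_str_profiles(coh, cfg)
  prof <- strp$profiles
  wga <- prof[prof$input_type == "wgaDNA", ]
  truth <- strp$truth$profiles
  m <- dplyr::left_join(wga, truth, by = c("individual_id", "marker"),
                        suffix = c("", "_truth"))
  expect_true(all(m$alleles == m$alleles_truth))
  # AMEL reflects reported sex
  sex <- coh$reported_sex[match(wga$individual_id, coh$individual_id)]
  amel <- wga$alleles[wga$marker == "AMEL"]
  expect_true(all(amel[sex[wga$marker == "AMEL"] == "M"] == "X,Y"))
  expect_true(all(amel[sex[wga$marker == "AMEL"] == "F"] == "X"))
})

test_that("STR drop-out count matches its binomial expectation", {
  q_fix <- 0.2   # drop-out probability 0.5 * (0.5 - q) = 0.15 per het marker
  cfg <- sim_config(seed = 77, n_individuals = 150, n_loci = 400,
                    replicate_design = c(gw = 150), str_fail_slope = 0,
                    str_contamination_rate = 0, str_dropout_slope = 0.5)
  coh <- simulate_cohort(cfg)
  quality <- tibble::tibble(sample_id = coh$sample_id, q = q_fix,
                            chip_failed = FALSE, plate_failed = FALSE)
  strp <- simulate_str_profiles(coh, cfg, quality)
  d <- 0.5 * (0.5 - q_fix)
  truth_het <- strp$truth$profiles |>
    dplyr::filter(marker != "AMEL") |>
    dplyr::mutate(het = lengths(strsplit(alleles, ",")) == 2)
  n_het <- sum(truth_het$het)    # one wgaDNA sample per individual here
  n_dropped <- sum(strp$truth$dropout$dropped)
  expect_equal(n_dropped, d * n_het, tolerance = 3 / sqrt(d * n_het))
})
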