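test_that("pair concordance counts mismatches over co-called probes", {
  g <- rep("AB", 1000)
  g2 <- g; g2[1:3] <- "AA"
  calls <- make_calls(rbind(A1 = g, A2 = g2),
                      sample_ids = c("A1", "A2"))
  pairs <- tibble::tibble(individual_id = "A", sample_a = "A1",
                          sample_b = "A2", pair_type = "gDNA-gDNA",
                          excluded = FALSE)
  res <- compute_pair_concordance(calls, pairs)
  expect_equal(res$n_both_called, 1000)
  expect_equal(res$concordance, 0.997)
  # identical tables give 1.0 and the measure is symmetric
  res2 <- compute_pair_concordance(
    calls, dplyr::mutate(pairs, sample_a = "A2", sample_b = "A1"))
  expect_equal(res2$concordance, res$concordance)
  # NC in either sample removes the probe from the denominator
  g3 <- g; g3[1:10] <- "NC"
  calls3 <- make_calls(rbind(A1 = g, A2 = g3))
  expect_equal(compute_pair_concordance(calls3, pairs)$n_both_called, 990)
  # no co-called probes is an error
  calls4 <- make_calls(rbind(A1 = c("AA", "NC"), A2 = c("NC", "AA")))
  expect_error(compute_pair_concordance(calls4, pairs), "co-called")
})

test_that("symmetric genotype errors match the (1-e)^2 + e^2/2 expectation", {
  e <- 0.02
  cfg <- tiny_config(
    seed = 19, n_individuals = 30, n_loci = 2500, n_chromosomes = 2,
    replicate_design = c(gg = 12), genotype_error_rate = e,
    dropout_model = list(prone_fraction = 0, base_prob = 0,
                         quality_slope = 0, q_ref = 0.55),
    probe_fail_rates = c(all = 0, wga_only = 0),
    subtelomere_affected_prob = 0, chip_fail_rate = 0, plate_fail_rate = 0)
  sim <- simulate_study(cfg)
  pairs <- compute_pair_concordance(sim$calls, pair_replicates(sim$cohort))
  expected <- (1 - e)^2 + e^2 / 2
  n_calls <- sum(pairs$n_both_called)
  mc_sd <- sqrt(expected * (1 - expected) / n_calls)
  expect_equal(mean(pairs$concordance), expected, tolerance = 4 * mc_sd)
})

test_that("wgaDNA het drop-out hits gw pairs at het sites only", {
  d <- 0.3
  cfg <- tiny_config(
    seed = 23, n_individuals = 24, n_loci = 2000, n_chromosomes = 2,
    replicate_design = c(gw = 12), genotype_error_rate = 0,
    dropout_model = list(prone_fraction = 1, base_prob = d,
                         quality_slope = 0, q_ref = 0.55),
    probe_fail_rates = c(all = 0, wga_only = 0),
    subtelomere_affected_prob = 0, chip_fail_rate = 0, plate_fail_rate = 0)
  sim <- simulate_study(cfg)
  pairs <- pair_replicates(sim$cohort) |>
    dplyr::filter(pair_type == "gDNA-wgaDNA")
  g <- sim$calls[sim$calls$genotype != "NC", ]
  input_of <- setNames(sim$cohort$input_type, sim$cohort$sample_id)
  deficits <- purrr::pmap_dbl(pairs[, c("sample_a", "sample_b")],
    function(sample_a, sample_b) {
      if (input_of[[sample_a]] != "gDNA") {
        tmp <- sample_a; sample_a <- sample_b; sample_b <- tmp
      }
      a <- g[g$sample_id == sample_a, ]   # a is the gDNA sample
      b <- g[g$sample_id == sample_b, ]
      m <- match(a$probe_id, b$probe_id)
      ok <- !is.na(m)
      a <- a[ok, ]; b <- b[m[ok], ]
      hom <- a$genotype != "AB"
      # concordance restricted to gDNA-homozygous sites stays ~1
      expect_gt(mean(a$genotype[hom] == b$genotype[hom]), 0.999)
      het <- !hom
      1 - mean(a$genotype[het] == b$genotype[het])
    })
  # at gDNA het sites the mismatch fraction is the drop-out rate
  expect_equal(mean(deficits), d, tolerance = 0.05)
})

test_that("MAF follows the allele-count formula and the dedup rule", {
  man <- make_manifest(1)
  g <- c(rep("AA", 70), rep("AB", 20), rep("BB", 10))
  ids <- sprintf("S%03d", seq_along(g))
  calls <- make_calls(matrix(g, ncol = 1, dimnames = list(ids, "P0001")))
  cohort <- make_cohort(ids, "gDNA")
  maf <- compute_maf(calls, cohort, man)
  expect_equal(maf$f_b, 0.2)
  expect_equal(maf$maf, 0.2)
  # all AA -> 0; all AB -> 0.5
  calls$genotype <- "AA"
  expect_equal(compute_maf(calls, cohort, man)$maf, 0)
  calls$genotype <- "AB"
  expect_equal(compute_maf(calls, cohort, man)$maf, 0.5)
  # one sample per individual: a duplicated wgaDNA sample must not change MAF
  cohort2 <- dplyr::bind_rows(cohort,
                              make_cohort("X1", "wgaDNA",
                                          individual_ids = ids[1]))
  calls2 <- dplyr::bind_rows(
    dplyr::mutate(calls, genotype = g),
    make_calls(matrix("BB", ncol = 1, dimnames = list("X1", "P0001"))))
  expect_equal(compute_maf(calls2, cohort2, man)$f_b, 0.2)
})

test_that("duplicate-locus concordance classifies by the 99% threshold", {
  # two probes of one locus over 150 gDNA + 150 wgaDNA samples
  man <- make_manifest(2, locus_ids = c("L1", "L1"))
  man$position <- c(1000, 1000)
  n <- 150
  ids_g <- sprintf("G%03d", 1:n); ids_w <- sprintf("W%03d", 1:n)
  geno <- matrix("AB", nrow = 2 * n, ncol = 2,
                 dimnames = list(c(ids_g, ids_w), man$probe_id))
  geno[ids_w[1:6], 2] <- "AA"     # wgaDNA agreement 144/150 = 0.96
  calls <- make_calls(geno)
  cohort <- make_cohort(c(ids_g, ids_w), rep(c("gDNA", "wgaDNA"), each = n))
  dup <- duplicate_locus_concordance(calls, man, cohort)
  expect_equal(dup$concordance_gdna, 1)
  expect_equal(dup$concordance_wga, 0.96)
  expect_equal(dup$class, "low_wga_only")
  # perfect agreement in both input types
  geno[, 2] <- "AB"
  dup2 <- duplicate_locus_concordance(make_calls(geno), man, cohort)
  expect_equal(dup2$class, "both_high")
  # a sample with an uncalled probe drops from the locus denominator
  geno[ids_g[1], 1] <- "NC"
  dup3 <- duplicate_locus_concordance(make_calls(geno), man, cohort)
  expect_equal(dup3$n_samples_gdna, n - 1)
  expect_error(duplicate_locus_concordance(calls, make_manifest(2), cohort),
               "no duplicate loci")
})

test_that("pair counts by type match the replicate-design combinatorics", {
  cfg <- tiny_config(seed = 3)
  coh <- simulate_cohort(cfg)
  pairs <- pair_replicates(coh)
  rd <- cfg$replicate_design
  # full: C(4,2) = 6 pairs each (1 gg + 4 gw + 1 ww)
  expect_equal(sum(pairs$pair_type == "gDNA-gDNA"),
               unname(rd["full"] * 1 + rd["gg"]))
  expect_equal(sum(pairs$pair_type == "gDNA-wgaDNA"),
               unname(rd["full"] * 4 + rd["gw"]))
  expect_equal(sum(pairs$pair_type == "wgaDNA-wgaDNA"),
               unname(rd["full"] * 1 + rd["ww"]))
})

test_that("concordance summary reports means and outliers over included pairs", {
  pairs <- tibble::tibble(
    individual_id = c("A", "B", "C"), sample_a = c("a1", "b1", "c1"),
    sample_b = c("a2", "b2", "c2"),
    pair_type = c("gDNA-gDNA", "gDNA-gDNA", "gDNA-wgaDNA"),
    excluded = c(FALSE, FALSE, TRUE),
    n_both_called = c(1000, 1000, NA), n_concordant = c(1000, 990, NA),
    concordance = c(1, 0.99, NA))
  s <- summarize_concordance(pairs, floor = 0.995)
  gg <- s$summary[s$summary$pair_type == "gDNA-gDNA", ]
  expect_equal(gg$mean_concordance, 0.995)
  expect_equal(gg$n_outliers, 1)
  expect_false("gDNA-wgaDNA" %in% s$summary$pair_type)   # excluded pair
  expect_equal(s$outliers$individual_id, "B")
})
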