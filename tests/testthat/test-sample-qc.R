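test_that("denominators follow the completion arithmetic", {
  # no failing probes: both denominators equal the probe count
  d0 <- denominators_from_counts(100, 0, 0)
  expect_equal(d0$denominator, c(100, 100))
  # probes failing everywhere shrink both; wgaDNA-only failures shrink wgaDNA
  g <- c("AA", "AB", "BB")
  calls <- make_calls(rbind(
    S1 = c("AA", "NC", "AA", "NC"),
    S2 = c("AB", "NC", "AB", "NC"),
    S3 = c("BB", "NC", "NC", "AA"),
    S4 = c("AA", "NC", "NC", "NC")))
  cohort <- make_cohort(paste0("S", 1:4),
                        c("gDNA", "gDNA", "wgaDNA", "wgaDNA"))
  den <- compute_denominators(calls, cohort)
  # P2 failed everywhere; P3 failed in all wgaDNA but called in gDNA
  expect_equal(den$denominator[den$input_type == "gDNA"], 3)
  expect_equal(den$denominator[den$input_type == "wgaDNA"], 2)
  expect_error(compute_denominators(calls[0, ], cohort), "empty")
})

test_that("call rates use input-type denominators and the 95% boundary passes", {
  geno <- matrix("AA", nrow = 2, ncol = 100,
                 dimnames = list(c("S1", "S2"), NULL))
  geno["S2", 1:5] <- "NC"   # 95 informative of 100
  calls <- make_calls(geno)
  cohort <- make_cohort(c("S1", "S2"), c("gDNA", "gDNA"))
  den <- denominators_from_counts(100, 0, 0)
  cr <- compute_call_rates(calls, den, cohort)
  expect_equal(cr$call_rate[cr$sample_id == "S1"], 1.0)
  expect_equal(cr$call_rate[cr$sample_id == "S2"], 0.95)
  expect_true(all(cr$passes))   # exactly 95% passes; "less than 95%" fails
  cr94 <- compute_call_rates(make_calls(rbind(S2 = c(rep("NC", 6),
                                                     rep("AA", 94)))),
                             den, cohort[2, ])
  expect_false(cr94$passes)
})

test_that("chips with all or most samples failing are excluded or flagged", {
  ids <- sprintf("S%02d", 1:12)
  cr <- tibble::tibble(
    sample_id = ids, input_type = "gDNA",
    n_informative = 90, n_denominator = 100,
    call_rate = c(rep(0.85, 4),            # chip 1: 4/4 failing
                  0.85, 0.85, 0.85, 0.99,  # chip 2: 3/4 failing
                  rep(0.99, 4)),           # chip 3: fine
    passes = call_rate >= 0.95)
  cohort <- make_cohort(ids, "gDNA")
  rep <- detect_systematic_failures(cr, cohort)
  chips <- rep[rep$unit_type == "chip", ]
  expect_equal(chips$action[chips$unit_id == "C01"], "exclude")
  expect_equal(chips$action[chips$unit_id == "C02"], "flag")
  expect_false("C03" %in% chips$unit_id)
  # all passing: nothing reported
  cr$passes <- TRUE
  expect_equal(nrow(detect_systematic_failures(cr, cohort)), 0)
})

test_that("plate-level excess failure is caught by the binomial tail rule", {
  ids <- sprintf("S%03d", 1:192)
  cohort <- make_cohort(ids, "gDNA")
  cohort$plate_id <- rep(c("PL01", "PL02"), each = 96)
  cr <- tibble::tibble(sample_id = ids, input_type = "gDNA",
                       n_informative = 99, n_denominator = 100,
                       call_rate = 0.99, passes = TRUE)
  cr$passes[cohort$plate_id == "PL02"][1:40] <- FALSE
  rep <- detect_systematic_failures(cr, cohort)
  plates <- rep[rep$unit_type == "plate", ]
  expect_true("PL02" %in% plates$unit_id)
  expect_false("PL01" %in% plates$unit_id)
})

test_that("heterozygosity handles trivial and HWE cases", {
  man <- make_manifest(200)
  calls <- make_calls(rbind(S1 = rep("AA", 200)),
                      probe_ids = man$probe_id)
  het <- compute_heterozygosity(calls, man)
  expect_equal(het$het_rate, 0)
  # HWE at p = 0.5: het rate ~ 0.5 within binomial error
  set.seed(4)
  g <- sample(c("AA", "AB", "AB", "BB"), 200, replace = TRUE)
  het2 <- compute_heterozygosity(
    make_calls(rbind(S1 = g), probe_ids = man$probe_id), man)
  expect_equal(het2$het_rate, 0.5, tolerance = 3 * sqrt(0.25 / 200) / 0.5)
  # all no-calls is an error
  expect_error(compute_heterozygosity(
    make_calls(rbind(S1 = rep("NC", 200)), probe_ids = man$probe_id), man),
    "zero called")
})

test_that("Tukey-fence outlier flagging behaves at its limits", {
  het <- tibble::tibble(sample_id = paste0("S", 1:10),
                        n_het = 10, n_called = 100,
                        het_rate = c(rep(0.137, 9), 0.716))
  out <- flag_het_outliers(het, k = 3)
  expect_equal(sum(out$is_outlier), 1)
  expect_true(out$is_outlier[out$het_rate == 0.716])
  # all equal: none; enormous fence swallows everything once IQR > 0
  het$het_rate <- 0.137
  expect_equal(sum(flag_het_outliers(het, k = 3)$is_outlier), 0)
  het$het_rate <- c(seq(0.13, 0.145, length.out = 9), 0.716)
  expect_equal(sum(flag_het_outliers(het, k = 1e6)$is_outlier), 0)
  expect_error(flag_het_outliers(het[1:3, ]), "at least 5")
})

test_that("failure report strata reweight to the overall percentage", {
  sim <- tiny_sim()
  den <- compute_denominators(sim$calls, sim$cohort)
  cr <- compute_call_rates(sim$calls, den, sim$cohort)
  fr <- failure_rate_report(cr, sim$cohort)
  strata <- fr[fr$source_material != "all" & fr$input_type != "all", ]
  overall <- fr[fr$source_material == "all" & fr$input_type == "all", ]
  expect_equal(sum(strata$n_failing), overall$n_failing)
  expect_equal(sum(strata$n_samples), overall$n_samples)
  expect_equal(
    sum(strata$pct_failing * strata$n_samples) / sum(strata$n_samples),
    overall$pct_failing)
  # single stratum with no failures reads 0.00
  cr1 <- cr[cr$sample_id == cr$sample_id[which(cr$passes)[1]], ]
  fr1 <- failure_rate_report(cr1, sim$cohort)
  expect_true(all(fr1$pct_failing == 0))
})

test_that("call rates are invariant to call-table row order", {
  sim <- tiny_sim()
  den <- compute_denominators(sim$calls, sim$cohort)
  cr1 <- compute_call_rates(sim$calls, den, sim$cohort)
  shuffled <- sim$calls[sample.int(nrow(sim$calls)), ]
  cr2 <- compute_call_rates(shuffled, den, sim$cohort)
  expect_equal(dplyr::arrange(cr1, sample_id), dplyr::arrange(cr2, sample_id))
})

test_that("informative counts recover the simulation truth exactly", {
  sim <- tiny_sim()
  den <- compute_denominators(sim$calls, sim$cohort)
  cr <- compute_call_rates(sim$calls, den, sim$cohort)
  truth_informative <- sim$calls |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(n = sum(genotype != "NC"))
  m <- match(cr$sample_id, truth_informative$sample_id)
  expect_identical(cr$n_informative, truth_informative$n[m])
})

test_that("repeat selection unions failures and passing outliers with reasons", {
  cr <- tibble::tibble(sample_id = c("A", "B", "C", "D"),
                       passes = c(FALSE, TRUE, TRUE, FALSE))
  het <- tibble::tibble(sample_id = c("A", "B", "C", "D"),
                        is_outlier = c(TRUE, TRUE, FALSE, FALSE))
  rep <- select_repeats(cr, het)
  expect_setequal(rep$sample_id, c("A", "B", "D"))
  expect_equal(rep$reasons[rep$sample_id == "A"], "low_call_rate;het_outlier")
  expect_equal(rep$reasons[rep$sample_id == "B"], "het_outlier")
  expect_equal(rep$reasons[rep$sample_id == "D"], "low_call_rate")
  expect_false("C" %in% rep$sample_id)
})
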