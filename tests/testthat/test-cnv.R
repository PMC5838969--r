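# helpers to build dense synthetic series for one sample-chromosome
lrr_series <- function(n, events = NULL, sd = 0.15, spacing = 1000) {
  v <- rnorm(n, 0, sd)
  if (!is.null(events)) {
    for (r in seq_len(nrow(events))) {
      idx <- events$start[r]:events$end[r]
      v[idx] <- v[idx] + events$shift[r]
    }
  }
  tibble::tibble(position = seq_len(n) * spacing, value = v)
}

mbaf_series_from <- function(n, events = NULL, baf_sd = 0.04, spacing = 2000) {
  baf <- 0.5 + rnorm(n, 0, baf_sd)
  if (!is.null(events)) {
    for (r in seq_len(nrow(events))) {
      idx <- events$start[r]:events$end[r]
      baf[idx] <- baf[idx] + sample(c(-1, 1), length(idx), TRUE) *
        events$shift[r]
    }
  }
  tibble::tibble(position = seq_len(n) * spacing,
                 mbaf = pmax(baf, 1 - baf))
}

test_that("mirrored BAF keeps hets and the informative interval only", {
  man <- make_manifest(4)
  calls <- tibble::tibble(
    sample_id = "S1", probe_id = man$probe_id,
    genotype = c("AB", "AA", "BB", "AA"), gc_score = 0.9,
    x_raw = 1, y_raw = 1, lrr = 0,
    baf = c(0.5, 0.2, 0.99, 0.05))
  mb <- mirrored_baf(calls, man, delta = 0.15)
  # het kept; baf 0.2 inside (0.15, 0.85) kept; 0.99 and 0.05 excluded
  expect_equal(mb$mbaf, c(0.5, 0.8))
  expect_equal(mb$position, man$position[1:2])
})

test_that("segment classification follows the threshold table", {
  n <- 300
  set.seed(21)
  # gain: elevated LRR with mBAF ~ 2/3 at the same span
  ev_l <- tibble::tibble(start = 101, end = 150, shift = 0.3)
  ls <- lrr_series(n, ev_l, sd = 0.1)
  lseg <- cbs_segment(ls, n_permutations = 100, seed = 1)
  mb <- mbaf_series_from(150, tibble::tibble(start = 51, end = 75,
                                             shift = 1 / 6), baf_sd = 0.03)
  mseg <- cbs_segment(mb |> dplyr::rename(value = "mbaf"),
                      n_permutations = 100, min_probes = 20, seed = 1)
  ev <- classify_segments(lseg, mseg, mbaf_series = mb,
                          chromosome = "1", sample_id = "S1")
  gain <- ev[ev$class == "gain", ]
  expect_equal(nrow(gain), 1)
  expect_equal(gain$mean_lrr, 0.3, tolerance = 0.1)

  # mosaic CN-LOH: neutral LRR, mBAF 0.6 -> fraction 0.2
  ls0 <- lrr_series(n, sd = 0.1)
  lseg0 <- cbs_segment(ls0, n_permutations = 100, seed = 2)
  mb2 <- mbaf_series_from(150, tibble::tibble(start = 51, end = 100,
                                              shift = 0.1), baf_sd = 0.03)
  mseg2 <- cbs_segment(mb2 |> dplyr::rename(value = "mbaf"),
                       n_permutations = 100, min_probes = 20, seed = 2)
  ev2 <- classify_segments(lseg0, mseg2, mbaf_series = mb2,
                           chromosome = "1", sample_id = "S1")
  mos <- ev2[ev2$class == "mosaic_cnloh", ]
  expect_equal(nrow(mos), 1)
  expect_lt(abs(mos$mosaic_fraction - 0.2), 0.05)
  expect_equal(mos$mosaic_fraction, 2 * (mos$mean_mbaf - 0.5))

  # loss: deep LRR drop over a het desert
  ev_loss <- tibble::tibble(start = 101, end = 150, shift = -0.45)
  ls3 <- lrr_series(n, ev_loss, sd = 0.1)
  lseg3 <- cbs_segment(ls3, n_permutations = 100, seed = 3)
  mb3 <- mbaf_series_from(150, baf_sd = 0.03)
  mb3 <- mb3[mb3$position < 101 * 1000 | mb3$position > 150 * 1000, ]
  ev3 <- classify_segments(lseg3, cbs_segment(
    mb3 |> dplyr::rename(value = "mbaf"), n_permutations = 100, seed = 3),
    mbaf_series = mb3, chromosome = "1", sample_id = "S1")
  expect_true("loss" %in% ev3$class)

  # all-neutral input yields no events
  ev4 <- classify_segments(
    cbs_segment(lrr_series(n, sd = 0.1), n_permutations = 100, seed = 4),
    mseg2[0, ], mbaf_series = mbaf_series_from(150, baf_sd = 0.03),
    chromosome = "1", sample_id = "S1")
  expect_equal(nrow(ev4), 0)
})

test_that("event matching applies class, overlap and anti-symmetry rules", {
  ref <- tibble::tibble(
    sample_id = "g", chromosome = c("1", "1", "2"),
    start_bp = c(100, 5000, 100), end_bp = c(1000, 6000, 900),
    n_probes = 30L, mean_lrr = 0.3, mean_mbaf = 0.6,
    class = c("gain", "loss", "gain"), mosaic_fraction = NA_real_,
    needs_review = FALSE)
  # identical lists: all TP, no FP
  m0 <- match_events(ref, ref)
  expect_equal(m0$concordance_rate, 1)
  expect_equal(m0$n_fp, 0)
  # same span, different class: FN + FP
  test1 <- dplyr::mutate(ref[1, ], class = "loss")
  m1 <- match_events(ref[1, ], test1)
  expect_equal(c(m1$n_tp, m1$n_fn, m1$n_fp), c(0L, 1L, 1L))
  # reciprocal overlap below 50% does not match
  test2 <- dplyr::mutate(ref[1, ], start_bp = 800, end_bp = 3000)
  expect_equal(match_events(ref[1, ], test2)$n_tp, 0L)
  test3 <- dplyr::mutate(ref[1, ], start_bp = 300, end_bp = 1100)
  expect_equal(match_events(ref[1, ], test3)$n_tp, 1L)
  # anti-symmetry: swapping reference and test swaps FN and FP
  test4 <- ref[1:2, ]
  m_ab <- match_events(ref, test4)
  m_ba <- match_events(test4, ref)
  expect_equal(m_ab$n_fn, m_ba$n_fp)
  expect_equal(m_ab$n_fp, m_ba$n_fn)
})

test_that("noise gate excludes samples above the LRR sd ceiling", {
  sds <- tibble::tibble(sample_id = c("a", "b", "c"),
                        lrr_sd_adjusted = c(0.1, 0.5, 0.30))
  g <- noise_gate(sds, threshold = 0.30)
  expect_equal(g$eligible, c(TRUE, FALSE, TRUE))
  expect_true(all(noise_gate(sds, threshold = Inf)$eligible))
})

test_that("injected study events are recovered through the full CNV path", {
  cfg <- sim_config(
    seed = 101, n_individuals = 16, n_loci = 2000, n_chromosomes = 2,
    replicate_design = c(gw = 8),
    cnv_spec = tibble::tibble(class = c("gain", "loss"),
                              n_probes = c(40L, 40L),
                              mosaic_fraction = NA_real_,
                              n_carriers = c(2L, 2L)),
    wga_event_attenuation = 0)
  sim <- simulate_study(cfg)
  wave <- fit_wave_model(sim$calls, sim$manifest, sim$cohort)
  adj <- correct_waves(sim$calls, wave, sim$manifest)
  carriers <- unique(sim$truth$cnv_events$individual_id)
  samples <- sim$cohort$sample_id[sim$cohort$individual_id %in% carriers]
  ev <- call_cnv_events(adj, sim$manifest, samples, n_permutations = 100,
                        seed = 9)
  ev <- ev[!ev$needs_review, ]
  truth <- sim$truth$cnv_events
  hits <- purrr::map_lgl(seq_len(nrow(truth)), function(r) {
    smp <- sim$cohort$sample_id[sim$cohort$individual_id ==
                                  truth$individual_id[r]]
    any(ev$sample_id %in% smp & ev$chromosome == truth$chromosome[r] &
          ev$class == truth$class[r] &
          pmin(ev$end_bp, truth$end_bp[r]) >
            pmax(ev$start_bp, truth$start_bp[r]))
  })
  expect_true(all(hits))
})
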