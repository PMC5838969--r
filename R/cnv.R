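# CNV / allelic-imbalance detection from segmented LRR and mirrored BAF,
# and matched-pair event concordance.

#' Mirrored-BAF series of informative probes
#'
#' Informative probes are heterozygous calls plus any probe whose BAF lies
#' in the open interval `(delta, 1 - delta)` (default `delta = 0.15`), so
#' hets shifted by mosaic events are retained; mirrored BAF is
#' `max(baf, 1 - baf)`. Returned ordered by chromosome and position per
#' sample.
#'
#' @param calls Call table.
#' @param manifest Probe manifest.
#' @param delta Informative-interval half-width.
#' @return Tibble `sample_id`, `chromosome`, `position`, `mbaf`.
#' @export
mirrored_baf <- function(calls, manifest, delta = 0.15) {
  i <- match(calls$probe_id, manifest$probe_id)
  calls |>
    dplyr::mutate(chromosome = manifest$chromosome[i],
                  position = manifest$position[i]) |>
    dplyr::filter(.data$genotype == "AB" |
                    (.data$baf > delta & .data$baf < 1 - delta)) |>
    dplyr::transmute(.data$sample_id, .data$chromosome, .data$position,
                     mbaf = pmax(.data$baf, 1 - .data$baf)) |>
    dplyr::arrange(.data$sample_id, as.integer(.data$chromosome),
                   .data$position)
}

#' Classify intersected LRR / mirrored-BAF segments into CNV events
#'
#' LRR and mBAF segmentations of one sample-chromosome are intersected and
#' each intersected interval is classified. Because informative (BAF-
#' heterozygous) probes are sparse (~1 in 7 at typical heterozygosity),
#' allelic-imbalance evidence for an interval is taken locally from the
#' mirrored-BAF series inside the interval, judged against the sample's
#' baseline mirrored BAF (its series median) plus a margin:
#'
#' * gain: `mean_lrr >= lrr_gain`, mBAF elevated or no mBAF evidence;
#' * loss: `mean_lrr <= lrr_loss`, mBAF ~1, a "het desert" (an interval
#'   large enough that informative probes were expected but none remain —
#'   how a deletion presents in single-sample data), or no evidence;
#' * cnloh: neutral LRR with mBAF >= `mbaf_full` on real informative probes;
#' * mosaic_cnloh: neutral LRR with intermediate elevated mBAF; mosaic
#'   fraction `2 * (mbaf - 0.5)`.
#'
#' Intervals with conflicting evidence get class `undetermined` and are
#' flagged for manual review; LRR-neutral, mBAF-quiet intervals are dropped.
#'
#' @param lrr_segments [cbs_segment()] output for the LRR series of one
#'   sample-chromosome (positions in bp).
#' @param mbaf_segments [cbs_segment()] output for the mirrored-BAF series
#'   (may be NULL when too few informative probes exist).
#' @param mbaf_series The mirrored-BAF series (tibble `position`, `mbaf`)
#'   used for local evidence and the baseline.
#' @param chromosome,sample_id Labels attached to the output.
#' @param thresholds Named list overriding any of `lrr_gain` (0.10),
#'   `lrr_loss` (-0.15), `lrr_neutral` (0.05), `mbaf_elevated` (0.55),
#'   `mbaf_full` (0.95), `mbaf_margin` (0.05), `min_informative` (5),
#'   `informative_fraction` (0.10, used by the het-desert expectation).
#' @param min_probes Minimum LRR probes per reported event (default 20).
#' @return Tibble `sample_id`, `chromosome`, `start_bp`, `end_bp`,
#'   `n_probes`, `mean_lrr`, `mean_mbaf`, `class`, `mosaic_fraction`,
#'   `needs_review`.
#' @export
classify_segments <- function(lrr_segments, mbaf_segments,
                              mbaf_series = NULL,
                              chromosome = NA_character_,
                              sample_id = NA_character_,
                              thresholds = list(), min_probes = 20L) {
  th <- utils::modifyList(
    list(lrr_gain = 0.10, lrr_loss = -0.15, lrr_neutral = 0.05,
         mbaf_elevated = 0.55, mbaf_full = 0.95, mbaf_margin = 0.05,
         min_informative = 5L, informative_fraction = 0.10),
    thresholds)
  if (is.null(lrr_segments) || nrow(lrr_segments) == 0) return(empty_events())
  if (is.null(mbaf_segments) || nrow(mbaf_segments) == 0) {
    mbaf_segments <- tibble::tibble(
      start_position = min(lrr_segments$start_position),
      end_position = max(lrr_segments$end_position))
  }
  baseline <- if (!is.null(mbaf_series) && nrow(mbaf_series) > 0) {
    median(mbaf_series$mbaf)
  } else {
    0.5
  }
  elevated_cut <- max(th$mbaf_elevated, baseline + th$mbaf_margin)

  out <- list()
  for (a in seq_len(nrow(lrr_segments))) {
    for (b in seq_len(nrow(mbaf_segments))) {
      lo <- max(lrr_segments$start_position[a], mbaf_segments$start_position[b])
      hi <- min(lrr_segments$end_position[a], mbaf_segments$end_position[b])
      if (lo > hi) next
      out[[length(out) + 1]] <- tibble::tibble(
        start_bp = lo, end_bp = hi,
        mean_lrr = lrr_segments$mean_value[a], lrr_seg = a)
    }
  }
  iv <- dplyr::bind_rows(out)
  # probe support on the LRR grid: proportional share of the parent segment
  seg_n <- lrr_segments$n_probes
  seg_span <- pmax(lrr_segments$end_position - lrr_segments$start_position, 1)
  iv$n_probes <- pmax(1L, round(as.numeric(seg_n[iv$lrr_seg]) *
                                  (as.numeric(iv$end_bp) - iv$start_bp) /
                                  seg_span[iv$lrr_seg]))
  # local mBAF evidence
  if (!is.null(mbaf_series) && nrow(mbaf_series) > 0) {
    iv$n_informative <- vapply(seq_len(nrow(iv)), function(r) {
      sum(mbaf_series$position >= iv$start_bp[r] &
            mbaf_series$position <= iv$end_bp[r])
    }, integer(1))
    iv$mean_mbaf <- vapply(seq_len(nrow(iv)), function(r) {
      w <- mbaf_series$position >= iv$start_bp[r] &
        mbaf_series$position <= iv$end_bp[r]
      if (any(w)) mean(mbaf_series$mbaf[w]) else NA_real_
    }, numeric(1))
  } else {
    iv$n_informative <- 0L
    iv$mean_mbaf <- NA_real_
  }
  has_evidence <- iv$n_informative >= th$min_informative
  expected_inf <- iv$n_probes * th$informative_fraction
  desert <- !has_evidence & expected_inf >= th$min_informative
  mb <- iv$mean_mbaf
  lrr <- iv$mean_lrr

  cls <- character(nrow(iv))
  for (r in seq_len(nrow(iv))) {
    neutral_lrr <- abs(lrr[r]) < th$lrr_neutral
    if (lrr[r] >= th$lrr_gain) {
      cls[r] <- if (!has_evidence[r] || mb[r] >= elevated_cut) "gain"
      else "undetermined"
    } else if (lrr[r] <= th$lrr_loss) {
      cls[r] <- if (!has_evidence[r] || mb[r] >= th$mbaf_full) "loss"
      else "undetermined"
    } else if (neutral_lrr) {
      if (has_evidence[r] && mb[r] >= th$mbaf_full) {
        cls[r] <- "cnloh"
      } else if (has_evidence[r] && mb[r] >= elevated_cut) {
        cls[r] <- "mosaic_cnloh"
      } else if (desert[r]) {
        cls[r] <- "undetermined"   # LRR-neutral het desert: review manually
      } else {
        cls[r] <- "neutral"
      }
    } else {
      # intermediate LRR shift: review unless allelically quiet
      cls[r] <- if (has_evidence[r] && mb[r] < elevated_cut) "neutral"
      else "undetermined"
    }
  }
  iv$class <- cls
  iv$mosaic_fraction <- ifelse(cls == "mosaic_cnloh",
                               pmin(pmax(2 * (mb - 0.5), 0), 1), NA_real_)
  iv$needs_review <- cls == "undetermined"
  iv |>
    dplyr::filter(.data$class != "neutral", .data$n_probes >= min_probes) |>
    dplyr::mutate(sample_id = sample_id, chromosome = chromosome) |>
    dplyr::select("sample_id", "chromosome", "start_bp", "end_bp",
                  "n_probes", "mean_lrr", "mean_mbaf", "class",
                  "mosaic_fraction", "needs_review")
}

empty_events <- function() {
  tibble::tibble(sample_id = character(), chromosome = character(),
                 start_bp = numeric(), end_bp = numeric(),
                 n_probes = integer(), mean_lrr = numeric(),
                 mean_mbaf = numeric(), class = character(),
                 mosaic_fraction = numeric(), needs_review = logical())
}

#' Matched-pair CNV concordance
#'
#' A reference event is a true positive when a test event on the same
#' chromosome with the same class overlaps it with reciprocal overlap at
#' least `min_reciprocal_overlap` (greedy one-to-one matching); unmatched
#' reference events are false negatives, unmatched test events false
#' positives. The concordance rate is `TP / n_reference`. Swapping the
#' reference and test sets swaps FN and FP.
#'
#' @param reference,test Event tibbles (from [classify_segments()]).
#' @param min_reciprocal_overlap Default 0.5.
#' @return Tibble `n_events_reference`, `n_tp`, `n_fn`, `n_fp`,
#'   `concordance_rate`.
#' @export
match_events <- function(reference, test, min_reciprocal_overlap = 0.5) {
  n_ref <- nrow(reference)
  used <- logical(nrow(test))
  tp <- 0L
  if (n_ref > 0 && nrow(test) > 0) {
    for (r in seq_len(n_ref)) {
      for (t in seq_len(nrow(test))) {
        if (used[t]) next
        if (!identical(reference$chromosome[r], test$chromosome[t])) next
        if (!identical(reference$class[r], test$class[t])) next
        lo <- max(reference$start_bp[r], test$start_bp[t])
        hi <- min(reference$end_bp[r], test$end_bp[t])
        if (lo > hi) next
        ov <- hi - lo + 1
        len_r <- reference$end_bp[r] - reference$start_bp[r] + 1
        len_t <- test$end_bp[t] - test$start_bp[t] + 1
        if (ov / len_r >= min_reciprocal_overlap &&
            ov / len_t >= min_reciprocal_overlap) {
          tp <- tp + 1L
          used[t] <- TRUE
          break
        }
      }
    }
  }
  tibble::tibble(
    n_events_reference = n_ref, n_tp = tp, n_fn = n_ref - tp,
    n_fp = nrow(test) - tp,
    concordance_rate = if (n_ref > 0) tp / n_ref else NA_real_)
}

#' Noise gate for CNV eligibility
#'
#' Samples whose post-normalization LRR SD exceeds the threshold are
#' excluded from CNV analysis as too noisy for accurate calling.
#'
#' @param sd_table Tibble with `sample_id` and `lrr_sd_adjusted` (or
#'   `lrr_sd`).
#' @param threshold SD ceiling (default 0.30).
#' @return `sd_table` with an `eligible` column.
#' @export
noise_gate <- function(sd_table, threshold = 0.30) {
  col <- if ("lrr_sd_adjusted" %in% names(sd_table)) "lrr_sd_adjusted"
  else "lrr_sd"
  dplyr::mutate(sd_table, eligible = .data[[col]] <= threshold)
}

#' Segment and classify CNV events for a set of samples
#'
#' Convenience wrapper: per sample and chromosome, runs [cbs_segment()] on
#' the LRR series and on the mirrored-BAF series, then
#' [classify_segments()]. Samples should already be call-rate-passing and
#' noise-gated.
#'
#' @param calls Call table (wave-corrected LRR recommended).
#' @param manifest Probe manifest.
#' @param sample_ids Samples to analyze.
#' @param alpha,n_permutations,min_probes,seed CBS parameters.
#' @param delta Informative-BAF interval half-width.
#' @param thresholds Classification threshold overrides.
#' @return Event tibble as from [classify_segments()].
#' @export
call_cnv_events <- function(calls, manifest, sample_ids,
                            alpha = 0.01, n_permutations = 200L,
                            min_probes = 20L, seed = 1L, delta = 0.15,
                            thresholds = list()) {
  mb_all <- mirrored_baf(calls, manifest, delta)
  i <- match(calls$probe_id, manifest$probe_id)
  calls <- dplyr::mutate(calls, chromosome = manifest$chromosome[i],
                         position = manifest$position[i])
  out <- list()
  for (sid in sample_ids) {
    cs <- calls |>
      dplyr::filter(.data$sample_id == sid, !is.na(.data$lrr)) |>
      dplyr::arrange(as.integer(.data$chromosome), .data$position)
    mbs <- dplyr::filter(mb_all, .data$sample_id == sid)
    for (chr in unique(cs$chromosome)) {
      lrr_series <- cs |>
        dplyr::filter(.data$chromosome == chr) |>
        dplyr::transmute(position = .data$position, value = .data$lrr)
      mb_series <- mbs |>
        dplyr::filter(.data$chromosome == chr) |>
        dplyr::transmute(position = .data$position, value = .data$mbaf)
      lrr_seg <- cbs_segment(lrr_series, alpha, n_permutations, min_probes,
                             seed = seed)
      mb_seg <- if (nrow(mb_series) >= min_probes) {
        cbs_segment(mb_series, alpha, n_permutations, min_probes, seed = seed)
      } else {
        NULL
      }
      ev <- classify_segments(
        lrr_seg, mb_seg,
        mbaf_series = dplyr::rename(mb_series, mbaf = "value"),
        chromosome = chr, sample_id = sid, thresholds = thresholds,
        min_probes = min_probes)
      out[[length(out) + 1]] <- ev
    }
  }
  if (length(out)) dplyr::bind_rows(out) else empty_events()
}
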