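# LRR/BAF computation, quantile normalization of intensities, and the
# GC/CpG wave regression model.

#' Compute LRR and BAF from raw intensities and cluster positions
#'
#' For each call, `theta = (2/pi) * atan2(y, x)` and `R = x + y`. Expected
#' intensity is linearly interpolated between the flanking genotype-cluster
#' centroids (flat beyond the outer clusters); `lrr = log2(R / R_expected)`.
#' BAF is piecewise-linear in theta between the centroids, clamped to
#' `[0, 1]`. Calls with `x = y = 0` get NA for both.
#'
#' @param calls Call table with `x_raw`, `y_raw`.
#' @param clusters Cluster model (see [default_cluster_model()]).
#' @return `calls` with recomputed `lrr` and `baf`.
#' @export
compute_lrr_baf <- function(calls, clusters) {
  miss <- setdiff(unique(calls$probe_id), clusters$probe_id)
  if (length(miss)) {
    stop("cluster model missing probe(s): ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  }
  i <- match(calls$probe_id, clusters$probe_id)
  taa <- clusters$theta_aa[i]; tab <- clusters$theta_ab[i]
  tbb <- clusters$theta_bb[i]
  raa <- clusters$r_aa[i]; rab <- clusters$r_ab[i]; rbb <- clusters$r_bb[i]
  theta <- (2 / pi) * atan2(calls$y_raw, calls$x_raw)
  r <- calls$x_raw + calls$y_raw
  r_exp <- r_expected_at(theta, taa, tab, tbb, raa, rab, rbb)
  baf <- dplyr::case_when(
    theta <= taa ~ 0,
    theta >= tbb ~ 1,
    theta <= tab ~ 0.5 * (theta - taa) / (tab - taa),
    .default = 0.5 + 0.5 * (theta - tab) / (tbb - tab))
  undef <- calls$x_raw == 0 & calls$y_raw == 0
  calls$lrr <- ifelse(undef, NA_real_, log2(r / r_exp))
  calls$baf <- ifelse(undef, NA_real_, pmin(pmax(baf, 0), 1))
  calls
}

#' Quantile-normalize a vector against a reference distribution
#'
#' Output order statistics equal the reference's exactly; tied input values
#' receive the mean of the tied reference positions.
#'
#' @param x Numeric vector.
#' @param reference Numeric vector of the same length.
#' @return Normalized vector (same order as `x`).
#' @export
quantile_normalize <- function(x, reference) {
  if (length(x) != length(reference)) {
    stop("reference length must equal vector length", call. = FALSE)
  }
  ref_sorted <- sort(reference)
  r <- rank(x, ties.method = "average")
  lo <- floor(r); hi <- ceiling(r)
  (ref_sorted[lo] + ref_sorted[hi]) / 2
}

#' Quantile-normalize total intensities across samples
#'
#' Normalizes each sample's total intensity `R = x + y` to the cohort
#' reference distribution (per-rank median across samples), rescales x and y
#' proportionally, and recomputes LRR/BAF from the cluster model. Genotype
#' calls are untouched.
#'
#' @param calls Call table.
#' @param clusters Cluster model.
#' @return `calls` with normalized `x_raw`, `y_raw` and recomputed
#'   `lrr`/`baf`.
#' @export
renormalize_intensities <- function(calls, clusters) {
  calls <- dplyr::arrange(calls, .data$sample_id, .data$probe_id)
  r <- calls$x_raw + calls$y_raw
  rs <- split(r, calls$sample_id)
  if (length(unique(lengths(rs))) != 1) {
    stop("all samples must cover the same probe set", call. = FALSE)
  }
  sorted <- vapply(rs, sort, numeric(length(rs[[1]])))
  reference <- apply(sorted, 1, median)
  r_new <- unsplit(lapply(rs, quantile_normalize, reference = reference),
                   calls$sample_id)
  scale <- ifelse(r > 0, r_new / r, 1)
  calls$x_raw <- calls$x_raw * scale
  calls$y_raw <- calls$y_raw * scale
  compute_lrr_baf(calls, clusters)
}

#' Fit the per-sample GC/CpG wave model
#'
#' Per-sample least-squares regression of LRR on polynomial terms of the
#' probe-window GC fraction and CpG density (degree `degree`, terms
#' centered), with a per-chip rescaling factor: a multiplicative intensity
#' rescale is additive in log2 units, so it is carried by the intercept and
#' summarized per chip as `2^(mean intercept of the chip's samples)`. If the
#' design is rank-deficient (e.g. constant GC), the degree is lowered with a
#' warning.
#'
#' @param calls Call table.
#' @param manifest Probe manifest (GC/CpG tracks).
#' @param cohort Sample sheet tibble (chip assignments).
#' @param degree Polynomial degree (default 2).
#' @return Object of class `wave_model`: list with `coefficients` (tibble of
#'   per-sample terms), `chip_rescale` (tibble `chip_id`, `rescale`),
#'   `residual_sd` (tibble per sample), `degree`, `centers`.
#' @export
fit_wave_model <- function(calls, manifest, cohort, degree = 2L) {
  if (degree < 1) stop("degree must be >= 1", call. = FALSE)
  n_per <- min(table(calls$sample_id))
  if (n_per < 100) stop("need >= 100 probes per sample", call. = FALSE)
  i <- match(calls$probe_id, manifest$probe_id)
  gc0 <- mean(manifest$gc_fraction)
  cpg0 <- mean(manifest$cpg_density)
  dat <- tibble::tibble(
    sample_id = calls$sample_id, lrr = calls$lrr,
    gc = manifest$gc_fraction[i] - gc0,
    cpg = manifest$cpg_density[i] - cpg0)

  build_design <- function(d, deg) {
    cols <- list()
    for (k in seq_len(deg)) {
      cols[[paste0("gc", k)]] <- d$gc^k
      cols[[paste0("cpg", k)]] <- d$cpg^k
    }
    as.data.frame(cols)
  }
  fit_one <- function(d) {
    deg <- degree
    repeat {
      X <- build_design(d, deg)
      fit <- lm(d$lrr ~ ., data = X)
      if (!anyNA(coef(fit)) || deg == 1) break
      warning("rank-deficient wave design; lowering degree to ", deg - 1,
              call. = FALSE)
      deg <- deg - 1
    }
    co <- coef(fit)
    co[is.na(co)] <- 0
    tibble::tibble(term = c("(Intercept)", names(X)),
                   estimate = unname(co[c("(Intercept)", names(X))]),
                   degree_used = deg,
                   residual_sd = sd(stats::residuals(fit)))
  }
  coefs <- dat |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(~ fit_one(.x)) |>
    dplyr::ungroup()
  coefs$estimate[is.na(coefs$estimate)] <- 0
  intercepts <- coefs |>
    dplyr::filter(.data$term == "(Intercept)") |>
    dplyr::left_join(cohort[, c("sample_id", "chip_id")], by = "sample_id")
  chip_rescale <- intercepts |>
    dplyr::group_by(.data$chip_id) |>
    dplyr::summarise(rescale = 2^mean(.data$estimate))
  residual_sd <- coefs |>
    dplyr::distinct(.data$sample_id, .data$residual_sd)
  structure(list(coefficients = coefs[, c("sample_id", "term", "estimate")],
                 chip_rescale = chip_rescale, residual_sd = residual_sd,
                 degree = degree, centers = c(gc = gc0, cpg = cpg0)),
            class = "wave_model")
}

wave_fitted_values <- function(calls, model, manifest) {
  i <- match(calls$probe_id, manifest$probe_id)
  gc <- manifest$gc_fraction[i] - model$centers[["gc"]]
  cpg <- manifest$cpg_density[i] - model$centers[["cpg"]]
  wide <- model$coefficients |>
    tidyr::pivot_wider(names_from = "term", values_from = "estimate")
  j <- match(calls$sample_id, wide$sample_id)
  if (anyNA(j)) stop("model lacks coefficients for some samples", call. = FALSE)
  fitted <- wide$`(Intercept)`[j]
  for (k in seq_len(model$degree)) {
    gcol <- paste0("gc", k); ccol <- paste0("cpg", k)
    if (gcol %in% names(wide)) fitted <- fitted + wide[[gcol]][j] * gc^k
    if (ccol %in% names(wide)) fitted <- fitted + wide[[ccol]][j] * cpg^k
  }
  fitted
}

#' Subtract the fitted wave term from LRR
#'
#' Adjusted LRR = LRR minus the per-sample fitted wave (including the
#' intercept, so the adjusted per-sample mean is ~0). Genotype calls and BAF
#' are never modified by the correction.
#'
#' @param calls Call table.
#' @param model A [fit_wave_model()] fit on the same manifest.
#' @param manifest Probe manifest.
#' @return `calls` with adjusted `lrr`.
#' @export
correct_waves <- function(calls, model, manifest) {
  calls$lrr <- calls$lrr - wave_fitted_values(calls, model, manifest)
  calls
}

#' Per-sample LRR/BAF standard deviation report
#'
#' SD over autosomal probes, before and after wave correction. BAF SD is
#' computed over genotype-conditional deviations (residuals from the 0, 0.5,
#' 1 cluster means of called genotypes) so the three-cluster structure does
#' not dominate.
#'
#' @param raw Call table before correction.
#' @param adjusted Call table after correction (same row order).
#' @param manifest Probe manifest.
#' @return Tibble `sample_id`, `lrr_sd_raw`, `lrr_sd_adjusted`,
#'   `baf_sd_raw`, `baf_sd_adjusted`.
#' @export
sd_report <- function(raw, adjusted, manifest) {
  if (nrow(raw) != nrow(adjusted) ||
      !identical(raw$sample_id, adjusted$sample_id)) {
    stop("raw and adjusted tables must be aligned", call. = FALSE)
  }
  autosomal <- manifest$probe_id[
    !manifest$chromosome %in% c("X", "Y", "XY", "MT")]
  keep <- raw$probe_id %in% autosomal
  baf_resid <- function(genotype, baf) {
    center <- dplyr::case_match(genotype, "AA" ~ 0, "AB" ~ 0.5, "BB" ~ 1,
                                .default = NA_real_)
    baf - center
  }
  tibble::tibble(sample_id = raw$sample_id[keep],
                 lrr_raw = raw$lrr[keep], lrr_adj = adjusted$lrr[keep],
                 baf_raw = baf_resid(raw$genotype[keep], raw$baf[keep]),
                 baf_adj = baf_resid(adjusted$genotype[keep],
                                     adjusted$baf[keep])) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      lrr_sd_raw = sd(.data$lrr_raw, na.rm = TRUE),
      lrr_sd_adjusted = sd(.data$lrr_adj, na.rm = TRUE),
      baf_sd_raw = sd(.data$baf_raw, na.rm = TRUE),
      baf_sd_adjusted = sd(.data$baf_adj, na.rm = TRUE))
}

#' @exportS3Method generics::tidy
#' @rdname fit_wave_model
#' @param x A `wave_model`.
#' @param ... Unused.
tidy.wave_model <- function(x, ...) x$coefficients

#' @exportS3Method generics::glance
#' @rdname fit_wave_model
glance.wave_model <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$residual_sd),
    degree = x$degree,
    mean_residual_sd = mean(x$residual_sd$residual_sd),
    max_residual_sd = max(x$residual_sd$residual_sd),
    n_chips = nrow(x$chip_rescale))
}

#' @export
print.wave_model <- function(x, ...) {
  cat("GC/CpG wave model: degree", x$degree, "fit on",
      nrow(x$residual_sd), "samples,", nrow(x$chip_rescale), "chips\n")
  cat("mean residual sd:", signif(mean(x$residual_sd$residual_sd), 4), "\n")
  invisible(x)
}
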