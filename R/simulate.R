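# Synthetic Infinium-style study generator.
#
# All generators are deterministic for a fixed (seed, config): each one runs
# under its own seed derived from config$seed, so the generators can be called
# in any order (or individually) and still reproduce byte-identical output.

seed_offset <- function(config, k) (config$seed %% 100000L) * 13L + k

#' Generate a synthetic probe manifest
#'
#' Produces the array annotation consumed by the rest of the pipeline:
#' probes sorted by (chromosome, position) with locus ids, A/B alleles, a
#' smooth positional GC-fraction track and a CpG-density track. A configured
#' fraction of probes are duplicate copies of another probe's locus
#' (sharing locus id, position and alleles), mirroring the duplicate-locus
#' content of real high-density arrays (~1.5% of probes).
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `probe_id`, `locus_id`, `chromosome`,
#'   `position` (1-based bp), `allele_a`, `allele_b`, `gc_fraction`,
#'   `cpg_density`.
#' @export
simulate_manifest <- function(config) {
  validate_sim_config(config)
  withr::with_seed(seed_offset(config, 101L), {
    n_dup <- round(config$n_loci * config$duplicate_locus_fraction)
    n_unique <- config$n_loci - n_dup
    per_chrom <- diff(round(seq(0, n_unique, length.out = config$n_chromosomes + 1)))
    chrom_labels <- as.character(seq_len(config$n_chromosomes))

    loci <- purrr::map2_dfr(chrom_labels, per_chrom, function(chr, n) {
      pos <- sort(sample.int(config$chromosome_length_bp, n))
      tibble::tibble(chromosome = chr, position = pos)
    })
    phase1 <- runif(config$n_chromosomes, 0, 2 * pi)
    phase2 <- runif(config$n_chromosomes, 0, 2 * pi)
    ci <- match(loci$chromosome, chrom_labels)
    loci$gc_fraction <- pmin(pmax(
      0.41 + 0.07 * sin(2 * pi * loci$position / 1.2e6 + phase1[ci]) +
        rnorm(nrow(loci), 0, 0.02), 0.25), 0.65)
    loci$cpg_density <- pmin(pmax(
      0.012 + 0.08 * abs(sin(2 * pi * loci$position / 8e5 + phase2[ci])) +
        rnorm(nrow(loci), 0, 0.003), 0.001), 0.2)
    nts <- c("A", "C", "G", "T")
    a_idx <- sample.int(4, nrow(loci), replace = TRUE)
    b_off <- sample.int(3, nrow(loci), replace = TRUE)
    loci$allele_a <- nts[a_idx]
    loci$allele_b <- nts[(a_idx + b_off - 1L) %% 4L + 1L]
    loci <- dplyr::arrange(loci, as.integer(.data$chromosome), .data$position)
    loci$locus_id <- sprintf("L%06d", seq_len(nrow(loci)))

    dup_rows <- if (n_dup > 0) {
      loci[sort(sample.int(nrow(loci), n_dup)), , drop = FALSE]
    } else {
      loci[0, , drop = FALSE]
    }
    manifest <- dplyr::bind_rows(loci, dup_rows) |>
      dplyr::arrange(as.integer(.data$chromosome), .data$position, .data$locus_id)
    manifest$probe_id <- sprintf("P%06d", seq_len(nrow(manifest)))
    dplyr::select(manifest, "probe_id", "locus_id", "chromosome", "position",
                  "allele_a", "allele_b", "gc_fraction", "cpg_density")
  })
}

#' Generate a synthetic cohort / sample sheet
#'
#' Builds the study design: individuals with a source material
#' (blood / buccal / Oragene), replicate structure (full QC replicates with
#' 2 gDNA + 2 wgaDNA samples, plus partial gDNA-wgaDNA, gDNA-gDNA and
#' wgaDNA-wgaDNA replicates), singleton samples, and plate/chip layout
#' (4 samples per chip, samples shuffled across plates so replicates are
#' interspersed).
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `sample_id`, `individual_id`, `input_type`,
#'   `source_material`, `plate_id`, `chip_id`, `chip_position`,
#'   `reported_sex`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  withr::with_seed(seed_offset(config, 201L), {
    n <- config$n_individuals
    rd <- config$replicate_design
    rd <- setNames(as.integer(rd[c("full", "gw", "gg", "ww")]),
                   c("full", "gw", "gg", "ww"))
    rd[is.na(rd)] <- 0L
    ind <- tibble::tibble(
      individual_id = sprintf("I%05d", seq_len(n)),
      source_material = sample(names(config$source_mix), n, replace = TRUE,
                               prob = config$source_mix),
      reported_sex = sample(c("M", "F"), n, replace = TRUE)
    )
    design <- rep(c("full", "gw", "gg", "ww", "single"),
                  c(rd, n - sum(rd)))
    inputs_for <- function(d, u) switch(
      d,
      full = c("gDNA", "gDNA", "wgaDNA", "wgaDNA"),
      gw = c("gDNA", "wgaDNA"),
      gg = c("gDNA", "gDNA"),
      ww = c("wgaDNA", "wgaDNA"),
      single = if (u < config$gdna_fraction) "gDNA" else "wgaDNA"
    )
    u_single <- runif(n)
    samples <- purrr::pmap_dfr(
      list(ind$individual_id, design, u_single),
      function(id, d, u) {
        inp <- inputs_for(d, u)
        tibble::tibble(
          individual_id = id, input_type = inp,
          sample_id = paste0(id, "_", ifelse(inp == "gDNA", "g", "w"),
                             stats::ave(seq_along(inp), inp, FUN = seq_along))
        )
      }
    ) |>
      dplyr::left_join(ind, by = "individual_id")
    # interspersed plate/chip layout: shuffle, then 4 per chip, 24 chips/plate
    samples <- samples[sample.int(nrow(samples)), , drop = FALSE]
    idx <- seq_len(nrow(samples))
    samples$chip_id <- sprintf("C%04d", (idx - 1L) %/% 4L + 1L)
    samples$chip_position <- (idx - 1L) %% 4L + 1L
    samples$plate_id <- sprintf("PL%03d", (idx - 1L) %/% 96L + 1L)
    dplyr::select(samples, "sample_id", "individual_id", "input_type",
                  "source_material", "plate_id", "chip_id", "chip_position",
                  "reported_sex") |>
      dplyr::arrange(.data$chip_id, .data$chip_position)
  })
}

#' Draw latent per-sample quality scores
#'
#' Sample quality `q` in `[0, 1]` drives call rate, allele drop-out, LRR
#' noise and STR drop-out. Scores are drawn per (input type, source
#' material) stratum from the config's `quality_model` and degraded to 0.10
#' for samples on chips/plates hit by a simulated systematic failure.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param config A [sim_config()].
#' @return Tibble `sample_id`, `q`, `chip_failed`, `plate_failed`.
#' @export
simulate_sample_quality <- function(cohort, config) {
  withr::with_seed(seed_offset(config, 251L), {
    qm <- config$quality_model
    x <- dplyr::left_join(cohort, qm, by = c("input_type", "source_material"))
    if (anyNA(x$q_mean)) {
      stop("quality_model is missing strata present in the cohort", call. = FALSE)
    }
    x$q <- pmin(pmax(rnorm(nrow(x), x$q_mean, x$q_sd), 0.02), 0.98)
    chips <- unique(cohort$chip_id)
    plates <- unique(cohort$plate_id)
    failed_chips <- chips[runif(length(chips)) < config$chip_fail_rate]
    failed_plates <- plates[runif(length(plates)) < config$plate_fail_rate]
    x$chip_failed <- x$chip_id %in% failed_chips
    x$plate_failed <- x$plate_id %in% failed_plates
    x$q[x$chip_failed | x$plate_failed] <- 0.10
    dplyr::select(x, "sample_id", "q", "chip_failed", "plate_failed")
  })
}

#' Default genotype cluster model
#'
#' Constant-centroid cluster positions used both to synthesize raw
#' intensities and to recompute LRR/BAF from them: theta centroids at
#' 0.06 / 0.50 / 0.94 (in `(2/pi) * atan2(y, x)` units) and unit expected
#' total intensity for each genotype cluster.
#'
#' @param manifest A probe manifest.
#' @return Tibble `probe_id`, `theta_aa`, `theta_ab`, `theta_bb`, `r_aa`,
#'   `r_ab`, `r_bb`.
#' @export
default_cluster_model <- function(manifest) {
  tibble::tibble(
    probe_id = manifest$probe_id,
    theta_aa = 0.06, theta_ab = 0.50, theta_bb = 0.94,
    r_aa = 1.0, r_ab = 1.05, r_bb = 1.0
  )
}

# piecewise-linear theta for a given BAF under a cluster model (vectorized)
theta_from_baf <- function(baf, taa, tab, tbb) {
  ifelse(baf <= 0.5,
         taa + (baf / 0.5) * (tab - taa),
         tab + ((baf - 0.5) / 0.5) * (tbb - tab))
}

# expected total intensity at theta by linear interpolation between centroids
r_expected_at <- function(theta, taa, tab, tbb, raa, rab, rbb) {
  lo <- theta <= taa
  hi <- theta >= tbb
  mid1 <- theta > taa & theta <= tab
  r <- numeric(length(theta))
  r[lo] <- raa[lo]
  r[hi] <- rbb[hi]
  r[mid1] <- raa[mid1] + (theta[mid1] - taa[mid1]) / (tab[mid1] - taa[mid1]) *
    (rab[mid1] - raa[mid1])
  mid2 <- !(lo | hi | mid1)
  r[mid2] <- rab[mid2] + (theta[mid2] - tab[mid2]) / (tbb[mid2] - tab[mid2]) *
    (rbb[mid2] - rab[mid2])
  r
}

#' Generate the per-call table with WGA artifacts, plus truth tables
#'
#' Simulates one genotyping call per (sample, probe): genotype class
#' (AA/AB/BB/NC), GC score, raw intensities, Log R Ratio and B-allele
#' frequency. The generative order is: HWE genotypes per individual from a
#' rare-heavy MAF mixture; locus-specific allele drop-out in wgaDNA;
#' uniform genotype-calling errors; systematic probe failures (complete,
#' baseline wgaDNA-only, and subtelomeric under-amplification in affected
#' chromosome ends); GC scores from a quality-dependent Beta model with the
#' no-call threshold applied afterwards; LRR as a per-sample GC/CpG wave
#' plus chip offset, injected copy-number event shift and noise; BAF
#' consistent with the (post-drop-out) genotype and any event, with
#' injected events optionally attenuated in wgaDNA samples.
#'
#' @param manifest Output of [simulate_manifest()].
#' @param cohort Output of [simulate_cohort()].
#' @param config The same [sim_config()] used for both.
#' @param quality Optional output of [simulate_sample_quality()]; generated
#'   from `config` if omitted.
#' @return List with `calls` (tibble: `sample_id`, `probe_id`, `genotype`,
#'   `gc_score`, `x_raw`, `y_raw`, `lrr`, `baf`) and `truth` (list of truth
#'   tables: `sample_quality`, `locus_maf`, `dropout_loci`,
#'   `failed_all_probes`, `wga_fail_probes`, `genotype_errors`,
#'   `cnv_events`, `cnv_attenuation`, `wave`).
#' @export
simulate_calls <- function(manifest, cohort, config, quality = NULL) {
  validate_sim_config(config)
  if (is.null(quality)) quality <- simulate_sample_quality(cohort, config)
  quality <- quality[match(cohort$sample_id, quality$sample_id), ]

  withr::with_seed(seed_offset(config, 301L), {
    m <- nrow(manifest)
    s <- nrow(cohort)
    loci <- dplyr::distinct(manifest, .data$locus_id, .keep_all = TRUE)
    nu <- nrow(loci)
    locus_of_probe <- match(manifest$locus_id, loci$locus_id)

    # --- per-locus truth: MAF mixture, B-allele frequency, drop-out proneness
    mp <- config$maf_params
    is_rare <- runif(nu) < mp$weight_rare
    maf <- 0.5 * ifelse(is_rare,
                        rbeta(nu, mp$rare[1], mp$rare[2]),
                        rbeta(nu, mp$common[1], mp$common[2]))
    f_b <- ifelse(runif(nu) < 0.5, maf, 1 - maf)
    prone <- runif(nu) < config$dropout_model$prone_fraction
    dropped_allele <- ifelse(runif(nu) < 0.5, "A", "B")
    dropped_allele[!prone] <- NA_character_

    # --- per-individual HWE genotypes (shared by replicate samples)
    inds <- unique(cohort$individual_id)
    ni <- length(inds)
    g_mat <- matrix(rbinom(ni * nu, 2L, rep(f_b, each = ni)), nrow = ni)
    ind_of_sample <- match(cohort$individual_id, inds)
    # direction of any allelic imbalance at a locus (which allele is lost /
    # over-represented): a property of the individual's cells, so it must be
    # shared by every replicate sample of that individual
    u_mat <- matrix(runif(ni * nu) < 0.5, nrow = ni)

    # --- systematic probe failures
    pf <- config$probe_fail_rates
    failed_all <- runif(nu) < pf[["all"]]
    wga_base <- runif(nu) < pf[["wga_only"]]
    sub_span <- config$subtelomere_windows * config$window_size_bp
    chrom_labels <- unique(manifest$chromosome)
    end_affected <- matrix(
      runif(2 * length(chrom_labels)) < config$subtelomere_affected_prob,
      nrow = 2, dimnames = list(c("p", "q"), chrom_labels))
    ci <- match(loci$chromosome, chrom_labels)
    in_p <- loci$position <= sub_span & end_affected["p", ][ci]
    in_q <- loci$position > config$chromosome_length_bp - sub_span &
      end_affected["q", ][ci]
    sub_fail <- (in_p | in_q) & runif(nu) < config$subtelomere_fail_prob
    wga_fail <- (wga_base | sub_fail) & !failed_all

    # --- CNV truth: events placed on matched individuals
    matched <- cohort |>
      dplyr::distinct(.data$individual_id, .data$input_type) |>
      dplyr::count(.data$individual_id) |>
      dplyr::filter(.data$n == 2) |>
      dplyr::pull(.data$individual_id)
    cnv_truth <- place_cnv_events(config, loci, matched)

    # --- per-sample and per-chip nuisance parameters
    q <- quality$q
    wave_scale <- runif(s, config$wave_scale_range[1], config$wave_scale_range[2])
    chips <- unique(cohort$chip_id)
    chip_offset <- setNames(rnorm(length(chips), 0, config$chip_offset_sd), chips)
    lrr_sd <- config$lrr_noise_sd * (1 + config$noise_quality_slope * (1 - q))
    gm <- config$gc_score_model
    mu <- pmin(pmax(gm$a + gm$b * q, 0.02), 0.98)

    gc_dev <- loci$gc_fraction - mean(loci$gc_fraction)
    cpg_dev <- loci$cpg_density - mean(loci$cpg_density)
    wave_locus <- config$gc_wave_amplitude * gc_dev +
      config$cpg_wave_amplitude * cpg_dev

    # --- assemble the long call table sample-block by sample-block
    is_wga <- cohort$input_type == "wgaDNA"
    dm <- config$dropout_model
    drop_prob <- pmin(pmax(dm$base_prob + dm$quality_slope * (dm$q_ref - q), 0), 1)

    err_list <- vector("list", s)
    blocks <- vector("list", s)
    att_list <- vector("list", s)
    ev_by_ind <- split(seq_len(nrow(cnv_truth)), cnv_truth$individual_id)

    for (si in seq_len(s)) {
      g_true <- g_mat[ind_of_sample[si], ][locus_of_probe]
      g_rep <- g_true
      # allele drop-out: wgaDNA heterozygotes at prone loci lose a fixed allele
      if (is_wga[si]) {
        het_prone <- g_true == 1L & prone[locus_of_probe]
        do <- het_prone & runif(m) < drop_prob[si]
        g_rep[do & dropped_allele[locus_of_probe] == "A"] <- 2L
        g_rep[do & dropped_allele[locus_of_probe] == "B"] <- 0L
      }
      baf_base <- g_rep / 2
      lrr_shift <- numeric(m)
      geno <- c("AA", "AB", "BB")[g_rep + 1L]

      # injected events for this sample's individual
      evs <- ev_by_ind[[cohort$individual_id[si]]]
      atts <- logical(length(evs))
      if (length(evs)) {
        for (k in seq_along(evs)) {
          ev <- cnv_truth[evs[k], ]
          att <- is_wga[si] && runif(1) < config$wga_event_attenuation
          atts[k] <- att
          f <- if (att) 0.25 else 1
          rows <- which(manifest$chromosome == ev$chromosome &
                          manifest$position >= ev$start_bp &
                          manifest$position <= ev$end_bp)
          het <- rows[g_rep[rows] == 1L]
          u <- u_mat[ind_of_sample[si], ][locus_of_probe[het]]
          if (ev$class == "gain") {
            lrr_shift[rows] <- lrr_shift[rows] + f * 0.32
            baf_base[het] <- 0.5 + f * ifelse(u, 1 / 6, -1 / 6)
          } else if (ev$class == "loss") {
            lrr_shift[rows] <- lrr_shift[rows] - f * 0.45
            baf_base[het] <- 0.5 + f * ifelse(u, 0.5, -0.5)
            if (!att) geno[het] <- ifelse(u, "BB", "AA")
          } else if (ev$class == "mosaic_cnloh") {
            mfrac <- f * ev$mosaic_fraction
            baf_base[het] <- 0.5 + ifelse(u, mfrac / 2, -mfrac / 2)
          }
        }
      }
      att_list[[si]] <- tibble::tibble(
        sample_id = cohort$sample_id[si],
        event_id = cnv_truth$event_id[evs], attenuated = atts)

      # genotype-calling errors (uniform over the two other classes)
      err <- runif(m) < config$genotype_error_rate
      if (any(err)) {
        shift <- sample.int(2L, sum(err), replace = TRUE)
        cur <- match(geno[err], c("AA", "AB", "BB"))
        geno[err] <- c("AA", "AB", "BB")[(cur - 1L + shift) %% 3L + 1L]
        err_list[[si]] <- tibble::tibble(sample_id = cohort$sample_id[si],
                                         probe_id = manifest$probe_id[err])
      }

      # GC scores; forced systematic failures appear as sub-threshold scores
      gc_score <- rbeta(m, mu[si] * gm$phi, (1 - mu[si]) * gm$phi)
      forced <- failed_all[locus_of_probe] |
        (is_wga[si] & wga_fail[locus_of_probe])
      gc_score[forced] <- runif(sum(forced), 0, 0.8 * config$gc_score_threshold)
      geno[gc_score < config$gc_score_threshold] <- "NC"

      # LRR and BAF
      true_het <- g_rep == 1L
      lrr <- wave_scale[si] * wave_locus[locus_of_probe] +
        chip_offset[[cohort$chip_id[si]]] + lrr_shift + rnorm(m, 0, lrr_sd[si])
      baf_sd <- ifelse(true_het, config$baf_noise_sd[["het"]],
                       config$baf_noise_sd[["hom"]])
      baf <- pmin(pmax(baf_base + rnorm(m, 0, baf_sd), 0), 1)

      blocks[[si]] <- tibble::tibble(
        sample_id = cohort$sample_id[si], probe_id = manifest$probe_id,
        genotype = geno, gc_score = gc_score, lrr = lrr, baf = baf)
    }

    calls <- dplyr::bind_rows(blocks)

    # raw intensities consistent with (lrr, baf) under the default clusters
    cl <- default_cluster_model(manifest)
    taa <- rep(cl$theta_aa, s); tab <- rep(cl$theta_ab, s)
    tbb <- rep(cl$theta_bb, s)
    raa <- rep(cl$r_aa, s); rab <- rep(cl$r_ab, s); rbb <- rep(cl$r_bb, s)
    theta <- theta_from_baf(calls$baf, taa, tab, tbb)
    r_exp <- r_expected_at(theta, taa, tab, tbb, raa, rab, rbb)
    r_obs <- r_exp * 2^calls$lrr
    phi_ang <- theta * pi / 2
    x <- r_obs / (1 + tan(phi_ang))
    calls$x_raw <- x
    calls$y_raw <- r_obs - x

    calls <- dplyr::select(calls, "sample_id", "probe_id", "genotype",
                           "gc_score", "x_raw", "y_raw", "lrr", "baf")

    truth <- list(
      sample_quality = dplyr::bind_cols(
        cohort[, c("sample_id", "individual_id", "input_type",
                   "source_material")],
        quality[, c("q", "chip_failed", "plate_failed")],
        tibble::tibble(wave_scale = wave_scale,
                       gc_wave_coef = wave_scale * config$gc_wave_amplitude,
                       lrr_noise_sd = lrr_sd)),
      locus_maf = tibble::tibble(locus_id = loci$locus_id, maf = maf,
                                 f_b = f_b),
      dropout_loci = tibble::tibble(locus_id = loci$locus_id[prone],
                                    dropped_allele = dropped_allele[prone]),
      failed_all_probes = manifest$probe_id[failed_all[locus_of_probe]],
      wga_fail_probes = manifest$probe_id[wga_fail[locus_of_probe]],
      genotype_errors = dplyr::bind_rows(err_list),
      cnv_events = cnv_truth,
      cnv_attenuation = dplyr::bind_rows(att_list),
      wave = list(gc_amplitude = config$gc_wave_amplitude,
                  cpg_amplitude = config$cpg_wave_amplitude,
                  chip_offset = chip_offset)
    )
    list(calls = calls, truth = truth)
  })
}

# choose non-overlapping event intervals for each configured event type;
# carriers are individuals with both input types (matched pairs)
place_cnv_events <- function(config, loci, matched_individuals) {
  spec <- config$cnv_spec
  empty <- tibble::tibble(event_id = character(), individual_id = character(),
                          class = character(), chromosome = character(),
                          start_bp = numeric(), end_bp = numeric(),
                          n_probes = integer(), mosaic_fraction = numeric())
  if (is.null(spec) || nrow(spec) == 0 || length(matched_individuals) == 0) {
    return(empty)
  }
  by_chrom <- split(seq_len(nrow(loci)), loci$chromosome)
  taken <- list()
  out <- list()
  eid <- 0L
  for (r in seq_len(nrow(spec))) {
    carriers <- sample(matched_individuals,
                       min(spec$n_carriers[r], length(matched_individuals)))
    for (ind in carriers) {
      placed <- FALSE
      for (try in 1:50) {
        chr <- sample(names(by_chrom), 1)
        idx <- by_chrom[[chr]]
        np <- spec$n_probes[r]
        if (length(idx) <= np) next
        st <- sample.int(length(idx) - np, 1)
        rows <- idx[st:(st + np - 1L)]
        iv <- c(loci$position[rows[1]], loci$position[rows[np]])
        prev <- taken[[ind]]
        clash <- !is.null(prev) && any(prev$chromosome == chr &
                                         prev$start <= iv[2] & prev$end >= iv[1])
        if (clash) next
        taken[[ind]] <- dplyr::bind_rows(
          prev, tibble::tibble(chromosome = chr, start = iv[1], end = iv[2]))
        eid <- eid + 1L
        out[[eid]] <- tibble::tibble(
          event_id = sprintf("E%03d", eid), individual_id = ind,
          class = spec$class[r], chromosome = chr,
          start_bp = iv[1], end_bp = iv[2], n_probes = np,
          mosaic_fraction = spec$mosaic_fraction[r])
        placed <- TRUE
        break
      }
      if (!placed) warning("could not place event for ", ind, call. = FALSE)
    }
  }
  if (length(out) == 0) empty else dplyr::bind_rows(out)
}

#' Generate Identifiler-style STR profiles with truth
#'
#' For every individual that contributed a wgaDNA sample, a ground-truth
#' 16-marker profile (15 autosomal STRs + AMEL) is drawn; the gDNA profile
#' reproduces the truth and each wgaDNA sample's profile inherits it with
#' quality-dependent allele drop-out (heterozygous markers lose one allele),
#' marker failure (empty allele set) and optional contamination (third
#' alleles at two or more autosomal markers). AMEL follows reported sex:
#' X,Y for males, X,X for females.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param config A [sim_config()].
#' @param quality Optional output of [simulate_sample_quality()].
#' @return List with `profiles` (tibble: `sample_id`, `individual_id`,
#'   `input_type`, `marker`, `alleles` — comma-joined, "" = marker failure)
#'   and `truth` (individual-level true profiles plus per-sample drop-out /
#'   contamination truth).
#' @export
simulate_str_profiles <- function(cohort, config, quality = NULL) {
  validate_sim_config(config)
  if (is.null(quality)) quality <- simulate_sample_quality(cohort, config)
  withr::with_seed(seed_offset(config, 401L), {
    wga <- dplyr::filter(cohort, .data$input_type == "wgaDNA")
    inds <- unique(wga$individual_id)
    if (length(inds) == 0) {
      return(list(profiles = tibble::tibble(), truth = list()))
    }
    ind_info <- cohort |>
      dplyr::distinct(.data$individual_id, .data$reported_sex) |>
      dplyr::filter(.data$individual_id %in% inds)

    auto <- setdiff(STR_PANEL, "AMEL")
    truth_profiles <- purrr::map_dfr(seq_len(nrow(ind_info)), function(i) {
      al <- purrr::map_chr(auto, function(mk) {
        a <- sort(sample(6:15, 2, replace = TRUE))
        paste(unique(a), collapse = ",")
      })
      amel <- if (ind_info$reported_sex[i] == "M") "X,Y" else "X"
      tibble::tibble(individual_id = ind_info$individual_id[i],
                     marker = c(auto, "AMEL"), alleles = c(al, amel))
    })

    qv <- setNames(quality$q, quality$sample_id)
    # gDNA profile: one per individual, attached to a gDNA sample when one
    # was genotyped, otherwise to a reference id for the source material
    gd <- cohort |>
      dplyr::filter(.data$input_type == "gDNA",
                    .data$individual_id %in% inds) |>
      dplyr::distinct(.data$individual_id, .keep_all = TRUE)
    gd_id <- setNames(gd$sample_id, gd$individual_id)
    gdna_profiles <- truth_profiles |>
      dplyr::mutate(
        sample_id = dplyr::coalesce(gd_id[.data$individual_id],
                                    paste0(.data$individual_id, "_gref")),
        input_type = "gDNA") |>
      dplyr::select("sample_id", "individual_id", "input_type", "marker",
                    "alleles")

    contam_samples <- wga$sample_id[runif(nrow(wga)) <
                                      config$str_contamination_rate]
    dropout_truth <- vector("list", nrow(wga))
    wga_profiles <- purrr::map_dfr(seq_len(nrow(wga)), function(i) {
      sid <- wga$sample_id[i]
      q <- qv[[sid]]
      d <- pmin(pmax(config$str_dropout_slope * (0.5 - q), 0), 0.9)
      f <- pmin(pmax(config$str_fail_slope * (0.35 - q), 0), 0.9)
      prof <- dplyr::filter(truth_profiles,
                            .data$individual_id == wga$individual_id[i])
      sets <- strsplit(prof$alleles, ",", fixed = TRUE)
      is_auto <- prof$marker != "AMEL"
      het <- lengths(sets) == 2 & is_auto
      drop <- het & runif(16) < d
      sets[drop] <- purrr::map(sets[drop], function(a) sample(a, 1))
      fail <- is_auto & runif(16) < f
      sets[fail] <- list(character(0))
      if (sid %in% contam_samples) {
        cands <- which(is_auto & !fail)
        hit <- sample(cands, min(2, length(cands)))
        sets[hit] <- purrr::map(sets[hit], function(a) {
          extra <- sample(setdiff(as.character(6:15), a), 1)
          sort(unique(c(a, extra)))
        })
      }
      dropout_truth[[i]] <<- tibble::tibble(
        sample_id = sid, marker = prof$marker, dropped = drop, failed = fail)
      tibble::tibble(sample_id = sid,
                     individual_id = wga$individual_id[i],
                     input_type = "wgaDNA", marker = prof$marker,
                     alleles = purrr::map_chr(sets, paste, collapse = ","))
    })

    list(
      profiles = dplyr::bind_rows(gdna_profiles, wga_profiles),
      truth = list(profiles = truth_profiles,
                   dropout = dplyr::bind_rows(dropout_truth),
                   contaminated_samples = contam_samples)
    )
  })
}

#' Run every generator with one config
#'
#' Convenience wrapper producing the full synthetic study: manifest, cohort,
#' latent sample quality, call table with truth tables, and STR profiles.
#'
#' @param config A [sim_config()].
#' @return List of class `arrayqc_sim` with elements `config`, `manifest`,
#'   `cohort`, `quality`, `calls`, `truth`, `str`.
#' @export
simulate_study <- function(config = sim_config()) {
  manifest <- simulate_manifest(config)
  cohort <- simulate_cohort(config)
  quality <- simulate_sample_quality(cohort, config)
  ct <- simulate_calls(manifest, cohort, config, quality)
  str <- simulate_str_profiles(cohort, config, quality)
  structure(list(config = config, manifest = manifest, cohort = cohort,
                 quality = quality, calls = ct$calls, truth = ct$truth,
                 str = str),
            class = "arrayqc_sim")
}
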