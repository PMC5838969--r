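# Shared fixtures, built in code.

# small but structurally complete study config; any sim_config() argument
# can be overridden
tiny_config <- function(seed = 42L, ...) {
  args <- list(
    seed = seed,
    n_individuals = 24L, n_loci = 600L, n_chromosomes = 3L,
    chromosome_length_bp = 2e6,
    replicate_design = c(full = 3L, gw = 2L, gg = 1L, ww = 1L),
    cnv_spec = tibble::tibble(class = character(), n_probes = integer(),
                              mosaic_fraction = numeric(),
                              n_carriers = integer())
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# one cached small clean study per session (no artifacts beyond defaults)
.fixture_env <- new.env(parent = emptyenv())
tiny_sim <- function() {
  if (is.null(.fixture_env$sim)) .fixture_env$sim <- simulate_study(tiny_config())
  .fixture_env$sim
}

# handcrafted call table: one row per sample x probe from a genotype matrix
# (rows = samples, cols = probes); "NC" entries get gc_score below threshold
make_calls <- function(genotypes, sample_ids = rownames(genotypes),
                       probe_ids = colnames(genotypes)) {
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(genotypes)))
  if (is.null(probe_ids)) probe_ids <- paste0("P", seq_len(ncol(genotypes)))
  g <- as.vector(t(genotypes))
  tibble::tibble(
    sample_id = rep(sample_ids, each = length(probe_ids)),
    probe_id = rep(probe_ids, length(sample_ids)),
    genotype = g,
    gc_score = ifelse(g == "NC", 0.1, 0.9),
    x_raw = 0.5, y_raw = 0.5,
    lrr = 0, baf = dplyr::case_match(g, "AA" ~ 0, "AB" ~ 0.5, "BB" ~ 1,
                                     .default = 0.5))
}

make_cohort <- function(sample_ids, input_types,
                        individual_ids = sample_ids,
                        sources = "blood",
                        chip_ids = NULL) {
  n <- length(sample_ids)
  if (is.null(chip_ids)) chip_ids <- sprintf("C%02d", (seq_len(n) - 1) %/% 4 + 1)
  tibble::tibble(
    sample_id = sample_ids, individual_id = individual_ids,
    input_type = input_types,
    source_material = rep_len(sources, n),
    plate_id = "PL01", chip_id = chip_ids,
    chip_position = stats::ave(seq_len(n), chip_ids, FUN = seq_along),
    reported_sex = "F")
}

make_manifest <- function(n, chromosome = "1", spacing = 1000L,
                          locus_ids = NULL) {
  tibble::tibble(
    probe_id = sprintf("P%04d", seq_len(n)),
    locus_id = if (is.null(locus_ids)) sprintf("L%04d", seq_len(n)) else locus_ids,
    chromosome = chromosome,
    position = seq_len(n) * spacing,
    allele_a = "A", allele_b = "C",
    gc_fraction = 0.4, cpg_density = 0.02)
}

# full 16-marker STR profile tibble from a named list of allele strings
make_profile <- function(sample_id, alleles = NULL, sex = "F") {
  base <- setNames(rep("10,12", 16), str_panel())
  base[["AMEL"]] <- if (sex == "M") "X,Y" else "X"
  if (!is.null(alleles)) base[names(alleles)] <- unlist(alleles)
  tibble::tibble(sample_id = sample_id, marker = names(base),
                 alleles = unname(base))
}
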