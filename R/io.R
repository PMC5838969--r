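# Tabular formats: GenomeStudio-style Final Report dialect, manifest CSV,
# sample sheet TSV, STR profile TSV, BED window output.
#
# Dialect notes (declared, not inferred from any vendor file):
#  - Final Report: a [Header] block of "key\tvalue" lines, then a [Data]
#    line, then a tab-delimited table with columns Sample ID, SNP Name,
#    Allele1, Allele2, GC Score, X, Y, Log R Ratio, B Allele Freq.
#  - Genotypes are stored A/B-relative (AA/AB/BB); no-calls are "--"/"--".
#  - Floats print with 4 decimals (GC score, X, Y, LRR, BAF).
#  - Coordinates are 1-based inclusive throughout the package; BED output
#    converts to 0-based half-open on write.

FR_COLUMNS <- c("Sample ID", "SNP Name", "Allele1", "Allele2", "GC Score",
                "X", "Y", "Log R Ratio", "B Allele Freq")

#' Write a call table in the Final-Report dialect
#'
#' Deterministic column order and float formatting (4 decimals); no-call
#' rows emit `--`/`--` alleles. An empty table writes the header block only.
#'
#' @param calls Call table (`sample_id`, `probe_id`, `genotype`, `gc_score`,
#'   `x_raw`, `y_raw`, `lrr`, `baf`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_final_report <- function(calls, path) {
  n_snps <- dplyr::n_distinct(calls$probe_id)
  n_samples <- dplyr::n_distinct(calls$sample_id)
  header <- c("[Header]",
              "GSGT Version\tarrayqc-sim",
              "Content\tsynthetic",
              paste0("Num SNPs\t", n_snps),
              paste0("Num Samples\t", n_samples),
              "[Data]",
              paste(FR_COLUMNS, collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(calls) > 0) {
    a1 <- dplyr::case_match(calls$genotype,
                            "AA" ~ "A", "AB" ~ "A", "BB" ~ "B", "NC" ~ "--")
    a2 <- dplyr::case_match(calls$genotype,
                            "AA" ~ "A", "AB" ~ "B", "BB" ~ "B", "NC" ~ "--")
    lines <- paste(calls$sample_id, calls$probe_id, a1, a2,
                   sprintf("%.4f", calls$gc_score),
                   sprintf("%.4f", calls$x_raw),
                   sprintf("%.4f", calls$y_raw),
                   sprintf("%.4f", calls$lrr),
                   sprintf("%.4f", calls$baf),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a Final-Report file into a call table
#'
#' Parses the `[Header]`/`[Data]` block structure, maps allele pairs back to
#' A/B-relative genotype classes, and maps calls whose GC score falls below
#' `threshold` to `NC`. Malformed rows (non-numeric GC score or unparseable
#' alleles) are dropped from the table but reported, with their line
#' numbers, in the `problems` attribute and a warning; row count is
#' otherwise preserved.
#'
#' @param path Final-Report file.
#' @param threshold GC-score no-call threshold (default 0.25).
#' @return Call tibble; attribute `problems` holds a tibble of skipped rows.
#' @export
read_final_report <- function(path, threshold = 0.25) {
  lines <- readLines(path)
  data_at <- which(lines == "[Data]")
  if (length(data_at) != 1) {
    stop("format error: no [Data] block in ", path, call. = FALSE)
  }
  header_line <- lines[data_at + 1]
  cols <- strsplit(header_line, "\t", fixed = TRUE)[[1]]
  missing <- setdiff(FR_COLUMNS, cols)
  if (length(missing)) {
    stop("format error: missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  body <- lines[-seq_len(data_at + 1)]
  if (length(body) == 0) {
    out <- tibble::tibble(sample_id = character(), probe_id = character(),
                          genotype = character(), gc_score = numeric(),
                          x_raw = numeric(), y_raw = numeric(),
                          lrr = numeric(), baf = numeric())
    attr(out, "problems") <- tibble::tibble(line = integer(), reason = character())
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  idx <- match(FR_COLUMNS, cols)
  get <- function(rows, j) vapply(fields[rows], `[[`, character(1), idx[j])
  ok_len <- nf >= length(cols)
  rows <- which(ok_len)
  num <- function(v) suppressWarnings(as.numeric(v))
  gc <- num(get(rows, 5))
  a1 <- get(rows, 3); a2 <- get(rows, 4)
  allele_ok <- (a1 %in% c("A", "B") & a2 %in% c("A", "B")) |
    (a1 == "--" & a2 == "--")
  bad <- is.na(gc) | !allele_ok
  problems <- dplyr::bind_rows(
    tibble::tibble(line = data_at + 1L + which(!ok_len),
                   reason = "wrong field count"),
    tibble::tibble(line = data_at + 1L + rows[bad],
                   reason = as.character(ifelse(is.na(gc[bad]),
                                                "non-numeric GC score",
                                                "unrecognized alleles")))
  )
  keep <- rows[!bad]
  genotype <- dplyr::case_when(
    get(keep, 3) == "--" ~ "NC",
    get(keep, 3) == "A" & get(keep, 4) == "A" ~ "AA",
    get(keep, 3) == "B" & get(keep, 4) == "B" ~ "BB",
    .default = "AB"
  )
  gc_keep <- num(get(keep, 5))
  genotype[gc_keep < threshold] <- "NC"
  out <- tibble::tibble(
    sample_id = get(keep, 1), probe_id = get(keep, 2), genotype = genotype,
    gc_score = gc_keep, x_raw = num(get(keep, 6)), y_raw = num(get(keep, 7)),
    lrr = num(get(keep, 8)), baf = num(get(keep, 9)))
  if (nrow(problems)) {
    warning(nrow(problems), " malformed row(s) skipped; see attr(, 'problems')",
            call. = FALSE)
  }
  attr(out, "problems") <- problems
  out
}

#' Read / write the probe manifest (CSV)
#'
#' Columns: `probe_id`, `locus_id`, `chromosome`, `position` (1-based),
#' `allele_a`, `allele_b`, `gc_fraction`, `cpg_density`. On read, the
#' manifest invariants are enforced: positions >= 1, distinct alleles, and
#' probes sharing a locus id must agree on chromosome, position and alleles.
#'
#' @param path File path.
#' @return `read_manifest()`: manifest tibble. `write_manifest()`: `path`.
#' @export
read_manifest <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chromosome = readr::col_character(),
                         position = readr::col_double()))
  req <- c("probe_id", "locus_id", "chromosome", "position", "allele_a",
           "allele_b", "gc_fraction", "cpg_density")
  if (!all(req %in% names(x))) {
    stop("format error: manifest missing column(s): ",
         paste(setdiff(req, names(x)), collapse = ", "), call. = FALSE)
  }
  if (any(x$position < 1)) stop("format error: positions must be >= 1",
                                call. = FALSE)
  if (any(x$allele_a == x$allele_b)) {
    stop("format error: allele_a must differ from allele_b", call. = FALSE)
  }
  if (anyDuplicated(x$probe_id)) {
    stop("format error: duplicate probe_id", call. = FALSE)
  }
  bad <- x |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(ok = dplyr::n_distinct(.data$chromosome, .data$position,
                                            .data$allele_a, .data$allele_b) == 1) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    stop("format error: probes sharing a locus_id disagree on position or ",
         "alleles: ", paste(head(bad$locus_id, 5), collapse = ", "),
         call. = FALSE)
  }
  x
}

#' @rdname read_manifest
#' @param manifest Manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path)
  invisible(path)
}

#' Read / write the sample sheet (TSV)
#'
#' Columns: `sample_id`, `individual_id`, `input_type` (gDNA/wgaDNA),
#' `source_material` (blood/buccal/oragene), `plate_id`, `chip_id`,
#' `chip_position` (1-4), `reported_sex` (M/F/unknown). Enforces unique
#' sample ids and at most 4 samples per chip.
#'
#' @param path File path.
#' @return `read_sample_sheet()`: cohort tibble. `write_sample_sheet()`: `path`.
#' @export
read_sample_sheet <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("sample_id", "individual_id", "input_type", "source_material",
           "plate_id", "chip_id", "chip_position", "reported_sex")
  if (!all(req %in% names(x))) {
    stop("format error: sample sheet missing column(s): ",
         paste(setdiff(req, names(x)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x$sample_id)) {
    stop("format error: duplicate sample_id", call. = FALSE)
  }
  if (!all(x$input_type %in% c("gDNA", "wgaDNA"))) {
    stop("format error: input_type must be gDNA or wgaDNA", call. = FALSE)
  }
  over <- x |> dplyr::count(.data$chip_id) |> dplyr::filter(.data$n > 4)
  if (nrow(over)) {
    stop("format error: more than 4 samples on chip(s): ",
         paste(head(over$chip_id, 5), collapse = ", "), call. = FALSE)
  }
  x
}

#' @rdname read_sample_sheet
#' @param cohort Cohort tibble.
#' @export
write_sample_sheet <- function(cohort, path) {
  readr::write_tsv(cohort, path)
  invisible(path)
}

#' Read / write STR profiles (TSV)
#'
#' Long format: `sample_id`, `individual_id`, `input_type`, `marker`,
#' `alleles` (comma-joined; empty string means the marker failed).
#'
#' @param path File path.
#' @return `read_str_profiles()`: profile tibble. `write_str_profiles()`: `path`.
#' @export
read_str_profiles <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(alleles = readr::col_character()))
  x$alleles[is.na(x$alleles)] <- ""
  bad <- setdiff(unique(x$marker), STR_PANEL)
  if (length(bad)) {
    stop("format error: unknown STR marker(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

#' @rdname read_str_profiles
#' @param profiles Profile tibble.
#' @export
write_str_profiles <- function(profiles, path) {
  readr::write_tsv(profiles, path)
  invisible(path)
}

#' Write window failure counts as BED3+
#'
#' Internal 1-based half-open windows `[start, start + size)` convert to
#' 0-based half-open BED intervals. Extra columns carry the per-window locus
#' and failure counts.
#'
#' @param windows Output of [window_failure_counts()].
#' @param path Output file.
#' @param window_size Window width in bp (default 50000).
#' @return `path`, invisibly.
#' @export
write_window_bed <- function(windows, path, window_size = 50000L) {
  bed <- tibble::tibble(
    chrom = windows$chromosome,
    start = windows$window_start - 1L,
    end = windows$window_start - 1L + window_size,
    n_loci_total = windows$n_loci_total,
    n_failed_all = windows$n_failed_all,
    n_failed_wga_only = windows$n_failed_wga_only)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
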