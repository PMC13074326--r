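#' Select a core marker panel for fingerprinting
#'
#' Per chromosome, markers (biallelic by default) are ranked by PIC
#' descending with marker name as the tie-break; `per_chrom_min` are taken
#' from each chromosome, then the panel is filled to `total` by next-best
#' PIC overall while respecting `per_chrom_max`. Chromosomes with fewer
#' eligible markers than `per_chrom_min` contribute what they have and the
#' shortfall is reported. Panel order (chromosome, then rank) is fixed:
#' fingerprint digit i always corresponds to panel marker i.
#'
#' @param summaries data frame with `marker`, `chromosome`,
#'   `allele_number`, `pic` columns (e.g. [tomato_marker_pic()] or a
#'   [summarize_markers()] result joined with chromosomes).
#' @param per_chrom_min,per_chrom_max markers taken per chromosome
#'   (defaults 2 and 3).
#' @param total panel size (default 24).
#' @param max_alleles maximum allele number for eligibility (default 2,
#'   i.e. biallelic).
#' @return tibble of class `core_panel`: `order`, `marker`, `chromosome`,
#'   `pic`.
#' @export
select_core_markers <- function(summaries, per_chrom_min = 2,
                                per_chrom_max = 3, total = 24,
                                max_alleles = 2) {
  need <- c("marker", "chromosome", "allele_number", "pic")
  if (!all(need %in% names(summaries))) {
    abort(sprintf("`summaries` needs columns: %s.", paste(need, collapse = ", ")))
  }
  el <- summaries |>
    filter(.data$allele_number <= max_alleles, !is.na(.data$pic)) |>
    arrange(.data$chromosome, desc(.data$pic), .data$marker) |>
    group_by(.data$chromosome) |>
    mutate(rank_in_chrom = row_number()) |>
    ungroup()
  base <- filter(el, .data$rank_in_chrom <= per_chrom_min)
  short <- base |>
    count(.data$chromosome) |>
    filter(.data$n < per_chrom_min)
  if (nrow(short)) {
    inform(sprintf("Chromosome(s) %s have fewer than %d eligible markers.",
                   paste(short$chromosome, collapse = ", "), per_chrom_min))
  }
  panel <- base
  if (nrow(panel) < total) {
    extra <- el |>
      filter(.data$rank_in_chrom > per_chrom_min,
             .data$rank_in_chrom <= per_chrom_max) |>
      arrange(desc(.data$pic), .data$marker)
    need_n <- total - nrow(panel)
    panel <- bind_rows(panel, head(extra, need_n))
  }
  if (nrow(panel) < total) {
    inform(sprintf("Panel has %d markers; %d requested but no more eligible.",
                   nrow(panel), total))
  }
  out <- panel |>
    arrange(.data$chromosome, .data$rank_in_chrom) |>
    mutate(order = row_number()) |>
    select("order", "marker", "chromosome", "pic")
  class(out) <- c("core_panel", class(out))
  out
}

#' Encode accessions as fingerprint digit strings
#'
#' Concatenates each accession's band codes in panel order — pure
#' transcription, no recoding. The inverse, [decode_fingerprints()],
#' recovers the genotype columns from the strings.
#'
#' @param genotypes genotype tibble containing every panel marker.
#' @param panel a `core_panel` or character vector of marker names in
#'   digit order.
#' @return tibble with `accession_id` and `fingerprint` (digit string over
#'   0-4, length = panel size).
#' @export
encode_fingerprints <- function(genotypes, panel) {
  markers <- if (is.data.frame(panel)) panel$marker else panel
  check_genotypes(genotypes)
  missing <- setdiff(markers, names(genotypes))
  if (length(missing)) {
    abort(sprintf("Markers absent from the genotype table: %s.",
                  paste(missing, collapse = ", ")))
  }
  codes <- as.matrix(genotypes[markers])
  if (anyNA(codes)) abort("Panel markers contain NA codes; use 0 for missing.")
  tibble(accession_id = genotypes$accession_id,
         fingerprint = apply(codes, 1, paste, collapse = ""))
}

#' @rdname encode_fingerprints
#' @param fingerprints tibble with `accession_id` and `fingerprint`.
#' @return `decode_fingerprints()`: a genotype tibble with one column per
#'   panel marker.
#' @export
decode_fingerprints <- function(fingerprints, panel) {
  markers <- if (is.data.frame(panel)) panel$marker else panel
  len <- nchar(fingerprints$fingerprint)
  if (any(len != length(markers))) {
    abort("Fingerprint length does not match the panel size.")
  }
  digits <- do.call(rbind, strsplit(fingerprints$fingerprint, ""))
  if (!all(digits %in% as.character(0:4))) {
    abort("Fingerprints contain characters outside 0-4.")
  }
  codes <- as.data.frame(matrix(as.integer(digits), nrow = nrow(digits)))
  names(codes) <- markers
  bind_cols(tibble(accession_id = fingerprints$accession_id),
            as_tibble(codes))
}

#' Audit fingerprint uniqueness
#'
#' Partitions accessions by identical fingerprint strings and returns the
#' groups with more than one member; an empty result means every
#' accession is uniquely identified by the panel. Duplicates are reported,
#' never collapsed.
#'
#' @param fingerprints tibble with `accession_id` and `fingerprint`
#'   columns (equal-length strings).
#' @return tibble with `fingerprint`, `n` and `accessions` (comma-joined
#'   ids), one row per duplicate group.
#' @export
check_uniqueness <- function(fingerprints) {
  len <- unique(nchar(fingerprints$fingerprint))
  if (length(len) > 1) abort("Fingerprints have unequal lengths.")
  fingerprints |>
    group_by(.data$fingerprint) |>
    summarise(n = n(),
              accessions = paste(sort(.data$accession_id), collapse = ","),
              .groups = "drop") |>
    filter(.data$n > 1)
}

#' Hamming distance between two fingerprint strings
#'
#' @param fp_a,fp_b equal-length digit strings.
#' @return count of differing positions (0 iff identical).
#' @examples
#' fingerprint_hamming("1111", "2222")
#' @export
fingerprint_hamming <- function(fp_a, fp_b) {
  if (nchar(fp_a) != nchar(fp_b)) abort("Fingerprints must have equal length.")
  sum(strsplit(fp_a, "")[[1]] != strsplit(fp_b, "")[[1]])
}

#' Write a fingerprint table as two-column TSV
#'
#' @param fingerprints tibble with `accession_id`, `fingerprint`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fingerprints, path) {
  readr::write_tsv(fingerprints, path, progress = FALSE)
  invisible(path)
}
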