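#' Published tomato marker tables shipped with the package
#'
#' Accessors for the three published summary tables of the tomato InDel
#' marker study that the package's statistics are checked against:
#' per-chromosome InDel counts, per-marker allele numbers and PIC for the
#' 63 core markers, and the 24-digit DNA fingerprints of the 52 accessions.
#' The tables are stored as plain TSV under `inst/extdata`.
#'
#' @return A tibble:
#' * `tomato_indel_counts()`: chromosome, n_insertion, n_deletion.
#' * `tomato_marker_pic()`: chromosome, marker, allele_number, pic.
#' * `tomato_fingerprints()`: accession, fingerprint (24-digit string).
#' * `tomato_core_panel()`: order, marker — the published 24-marker panel.
#' @examples
#' tomato_marker_pic()
#' @name tomato_tables
NULL

extdata_tsv <- function(file, col_types) {
  path <- system.file("extdata", file, package = "indelfp", mustWork = TRUE)
  readr::read_tsv(path, col_types = col_types, progress = FALSE)
}

#' @rdname tomato_tables
#' @export
tomato_indel_counts <- function() {
  extdata_tsv("tomato_table1_indel_counts.tsv", "cii")
}

#' @rdname tomato_tables
#' @export
tomato_marker_pic <- function() {
  extdata_tsv("tomato_table2_marker_pic.tsv", "ccid")
}

#' @rdname tomato_tables
#' @export
tomato_fingerprints <- function() {
  extdata_tsv("tomato_table3_fingerprints.tsv", "cc")
}

#' @rdname tomato_tables
#' @export
tomato_core_panel <- function() {
  extdata_tsv("tomato_core_panel.tsv", "ic")
}
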