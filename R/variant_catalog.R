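#' Read InDel variants from a VCF file
#'
#' Parses a VCF 4.x file (plain or gzipped) and returns one row per
#' length-changing REF/ALT pair. Multi-allelic records are split into one
#' variant per ALT allele. SNPs, equal-length substitutions and symbolic
#' alleles (e.g. `<DEL>`) are skipped; the number skipped is reported and
#' attached as the `n_skipped` attribute.
#'
#' Coordinates are 1-based inclusive as in VCF. A missing QUAL (`.`)
#' retains the variant with `qual = NA` and `qual_known = FALSE`.
#'
#' @param path path to a VCF file.
#' @param verbose report skip counts with a message (default TRUE).
#' @return A tibble with columns `chrom`, `pos`, `ref_allele`, `alt_allele`,
#'   `qual`, `qual_known`, `indel_type` ("insertion"/"deletion") and
#'   `indel_len` (absolute length difference in bp), in file order.
#' @export
read_indel_vcf <- function(path, verbose = TRUE) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- tibble(chrom = character(), pos = integer(), ref_allele = character(),
                  alt_allele = character(), qual = double(), qual_known = logical(),
                  indel_type = character(), indel_len = integer())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos)) {
    abort(sprintf("Malformed VCF: non-numeric POS at record %d.",
                  which(is.na(pos))[1]))
  }
  bad_ref <- !grepl("^[ACGTNacgtn]+$", fix$REF)
  if (any(bad_ref)) {
    abort(sprintf("Malformed VCF: invalid REF allele at record %d.",
                  which(bad_ref)[1]))
  }
  recs <- tibble(
    chrom = fix$CHROM, pos = pos, ref_allele = toupper(fix$REF),
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL))
  )
  recs$qual_known <- !is.na(recs$qual) & !is.na(fix$QUAL) & fix$QUAL != "."
  # split multi-allelic ALT
  long <- tidyr::separate_rows(recs, "alt", sep = ",")
  symbolic <- grepl("[<>\\[\\]*.]", long$alt) | long$alt == ""
  same_len <- !symbolic & nchar(long$alt) == nchar(long$ref_allele)
  keep <- !symbolic & !same_len
  n_skipped <- sum(!keep)
  out <- long[keep, , drop = FALSE]
  out <- mutate(out,
    alt_allele = toupper(.data$alt),
    indel_len = abs(nchar(.data$alt_allele) - nchar(.data$ref_allele)),
    indel_type = ifelse(nchar(.data$alt_allele) > nchar(.data$ref_allele),
                        "insertion", "deletion")
  )
  out <- select(out, "chrom", "pos", "ref_allele", "alt_allele", "qual",
                "qual_known", "indel_type", "indel_len")
  if (verbose && n_skipped > 0) {
    inform(sprintf("Skipped %d non-InDel allele(s) (SNPs, MNPs or symbolic).",
                   n_skipped))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Classify REF/ALT pairs as insertions or deletions
#'
#' Adds `indel_type` and `indel_len` columns to a variant table with
#' `ref_allele`/`alt_allele` columns. Complex substitutions (both alleles
#' longer than 1 bp, unequal length) are classified by net length change.
#' Equal-length pairs are rejected.
#'
#' @param variants data frame with `ref_allele` and `alt_allele` columns.
#' @return the input tibble with `indel_type` and `indel_len` columns.
#' @export
classify_indels <- function(variants) {
  dl <- nchar(variants$alt_allele) - nchar(variants$ref_allele)
  if (any(dl == 0L)) {
    abort("Some records have equal-length REF and ALT; not InDels.")
  }
  mutate(as_tibble(variants),
         indel_type = ifelse(dl > 0, "insertion", "deletion"),
         indel_len = abs(dl))
}

#' Per-chromosome InDel summary
#'
#' Counts insertions, deletions and totals per chromosome and each
#' chromosome's share of the genome-wide total, mirroring the layout of a
#' published per-chromosome InDel table (with a grand-total row).
#' Percentages are rounded half-up to two decimals.
#'
#' @param variants tibble with `chrom` and `indel_type` columns (e.g. from
#'   [read_indel_vcf()]), or a per-chromosome count table with columns
#'   `chromosome`, `n_insertion`, `n_deletion`.
#' @return tibble with columns `chromosome`, `n_insertion`, `n_deletion`,
#'   `n_total`, `pct_of_total`, one row per chromosome plus a `"Total"` row.
#' @examples
#' summarize_indels(tomato_indel_counts())
#' @export
summarize_indels <- function(variants) {
  if (all(c("chromosome", "n_insertion", "n_deletion") %in% names(variants))) {
    per <- as_tibble(variants[c("chromosome", "n_insertion", "n_deletion")])
  } else {
    if (nrow(variants) == 0L) {
      return(tibble(chromosome = "Total", n_insertion = 0L, n_deletion = 0L,
                    n_total = 0L, pct_of_total = NA_real_))
    }
    per <- variants |>
      count(chromosome = .data$chrom, type = .data$indel_type) |>
      tidyr::pivot_wider(names_from = "type", values_from = "n",
                         values_fill = 0L)
    if (!"insertion" %in% names(per)) per$insertion <- 0L
    if (!"deletion" %in% names(per)) per$deletion <- 0L
    per <- tibble(chromosome = per$chromosome,
                  n_insertion = as.integer(per$insertion),
                  n_deletion = as.integer(per$deletion))
  }
  per <- per |>
    mutate(n_total = .data$n_insertion + .data$n_deletion) |>
    arrange(.data$chromosome)
  grand <- sum(per$n_total)
  per$pct_of_total <- round_half_up(100 * per$n_total / grand, 2)
  bind_rows(per, tibble(
    chromosome = "Total",
    n_insertion = sum(per$n_insertion),
    n_deletion = sum(per$n_deletion),
    n_total = grand,
    pct_of_total = round_half_up(100, 2)
  ))
}

#' Write a per-chromosome InDel summary as TSV
#'
#' Columns are written in the published order: Chromosome, Insertion,
#' Deletion, Total, InDel/%.
#'
#' @param summary output of [summarize_indels()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_indel_summary <- function(summary, path) {
  out <- tibble(
    Chromosome = summary$chromosome,
    Insertion = summary$n_insertion,
    Deletion = summary$n_deletion,
    Total = summary$n_total,
    `InDel/%` = sprintf("%.2f", summary$pct_of_total)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
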