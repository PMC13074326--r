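# File-format plumbing shared across modules.
#
# Interval conventions: BED on disk is 0-based half-open; in memory every
# interval tibble is 1-based inclusive (chrom, start, end). The conversion
# happens exactly once, at read/write time.

#' Read a BED file as 1-based inclusive intervals
#'
#' @param path 3+ column BED file (0-based half-open).
#' @return tibble with `chrom`, `start`, `end` (1-based inclusive) and
#'   `name` when a fourth column is present.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                         progress = FALSE, comment = "#")
  if (ncol(raw) < 3) abort(sprintf("BED file %s has fewer than 3 columns.", path))
  out <- tibble(chrom = as.character(raw[[1]]),
                start = as.integer(raw[[2]]) + 1L,
                end = as.integer(raw[[3]]))
  if (ncol(raw) >= 4) out$name <- as.character(raw[[4]])
  out
}

#' Write 1-based inclusive intervals as BED (0-based half-open)
#'
#' @param intervals tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  out <- data.frame(intervals$chrom, intervals$start - 1L, intervals$end)
  if ("name" %in% names(intervals)) out$name <- intervals$name
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# 1-based inclusive interval tibble -> GRanges.
intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end)
  )
}

#' Write an InDel variant table as VCF 4.2
#'
#' Emits a minimal site-only VCF (CHROM, POS, ID, REF, ALT, QUAL, FILTER,
#' INFO) readable by standard VCF tooling.
#'
#' @param variants tibble with `chrom`, `pos`, `ref_allele`, `alt_allele`,
#'   `qual` columns.
#' @param path output file.
#' @param contigs optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_indel_vcf <- function(variants, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=indelfp")
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  qual <- ifelse(is.na(variants$qual), ".", format(variants$qual, trim = TRUE))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\t.",
                  variants$chrom, variants$pos, variants$ref_allele,
                  variants$alt_allele, qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read and write band-code genotype matrices as TSV
#'
#' Rows are accessions, the first column is `accession_id`, remaining
#' columns are markers holding band codes 0-4 (0 = missing/no band,
#' 1 = reference-type band, 2 = InDel band, 3 = heterozygous double band,
#' 4 = second length-distinct InDel band).
#'
#' @param path TSV file.
#' @return `read_genotypes()`: a validated genotype tibble.
#' @export
read_genotypes <- function(path) {
  g <- readr::read_tsv(path, col_types = readr::cols(
    accession_id = readr::col_character(), .default = readr::col_integer()
  ), progress = FALSE)
  check_genotypes(g)
  g
}

#' @rdname read_genotypes
#' @param genotypes genotype tibble.
#' @return `write_genotypes()`: `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  check_genotypes(genotypes)
  readr::write_tsv(genotypes, path, progress = FALSE)
  invisible(path)
}

#' Write a distance matrix as PHYLIP-style square TSV
#'
#' @param d a `dist` object, e.g. from [genetic_distance()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  out <- cbind(tibble(accession_id = rownames(m)), as.data.frame(m))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
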