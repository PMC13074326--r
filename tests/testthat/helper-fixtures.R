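# Shared fixture builders: everything is generated in code, seeded.

# genotype tibble from a plain matrix of band codes
g_tbl <- function(codes, ids = NULL, markers = NULL) {
  codes <- as.matrix(codes)
  ids <- ids %||% sprintf("A%02d", seq_len(nrow(codes)))
  markers <- markers %||% sprintf("M%02d", seq_len(ncol(codes)))
  out <- tibble::as_tibble(as.data.frame(codes), .name_repair = ~markers)
  dplyr::bind_cols(tibble::tibble(accession_id = ids), out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# write a site-only VCF body with a standard header, return the path
write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               lines), path)
  path
}

# minimal variant tibble for screening tests
v_tbl <- function(chrom, pos, ref = "ATCGTTG", alt = "A", qual = 50) {
  n <- max(length(chrom), length(pos))
  tibble::tibble(
    chrom = rep_len(chrom, n), pos = rep_len(pos, n),
    ref_allele = rep_len(ref, n), alt_allele = rep_len(alt, n),
    qual = rep_len(qual, n)
  ) |>
    indelfp::classify_indels()
}

# independent naive PIC: direct double loop over the formula
pic_naive <- function(p) {
  out <- 1 - sum(p^2)
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      if (j > i) out <- out - 2 * p[i]^2 * p[j]^2
    }
  }
  out
}

# brute-force check that no retained pair on one chromosome is closer
# than min_spacing
spacing_ok <- function(cand, min_spacing) {
  kept <- cand[cand$status == "pass", ]
  all(vapply(split(kept$pos, kept$chrom), function(p) {
    length(p) < 2 || min(diff(sort(p))) >= min_spacing
  }, logical(1)))
}

# independent greedy left-to-right scan oracle
greedy_thin_oracle <- function(pos, min_spacing) {
  pos <- sort(pos)
  keep <- pos[1]
  last <- pos[1]
  for (p in pos[-1]) {
    if (p - last >= min_spacing) {
      keep <- c(keep, p)
      last <- p
    }
  }
  keep
}
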