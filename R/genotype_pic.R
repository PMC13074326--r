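#' Allele frequencies from a column of band codes
#'
#' Band codes score gel phenotypes: 0 = no band (missing), 1 = band
#' matching the reference variety, 2 = InDel band, 3 = heterozygous double
#' band, 4 = second, length-distinct InDel band. The default `"diploid"`
#' counting treats each accession as two allele copies: code 1 contributes
#' two reference alleles, 2 two alternate alleles, 4 two second-alternate
#' alleles, 3 one reference plus one alternate; 0 is excluded from the
#' denominator. The `"band"` mode counts each visible band once
#' (haploid presence scoring), provided for sensitivity checks.
#'
#' @param codes integer vector of band codes 0-4.
#' @param counting `"diploid"` (default) or `"band"`.
#' @return named numeric vector of frequencies over the observed alleles
#'   (subset of `ref`, `alt`, `alt2`), summing to 1.
#' @examples
#' codes_to_allele_freqs(c(1, 1, 2, 2))
#' codes_to_allele_freqs(c(1, 3))
#' @export
codes_to_allele_freqs <- function(codes, counting = c("diploid", "band")) {
  counting <- match.arg(counting)
  codes <- codes[!is.na(codes)]
  if (!all(codes %in% 0:4)) abort("Band codes must be integers 0-4.")
  codes <- codes[codes != 0]
  if (length(codes) == 0L) abort("All band codes are missing for this marker.")
  if (counting == "diploid") {
    counts <- c(
      ref = 2 * sum(codes == 1) + sum(codes == 3),
      alt = 2 * sum(codes == 2) + sum(codes == 3),
      alt2 = 2 * sum(codes == 4)
    )
  } else {
    counts <- c(
      ref = sum(codes == 1) + sum(codes == 3),
      alt = sum(codes == 2) + sum(codes == 3),
      alt2 = sum(codes == 4)
    )
  }
  counts <- counts[counts > 0]
  counts / sum(counts)
}

#' Polymorphism information content
#'
#' The Botstein PIC statistic
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`, where `p_i` are
#' allele frequencies at the marker. Zero for a monomorphic marker,
#' approaching 1 for many equifrequent alleles, and never exceeding the
#' expected heterozygosity `1 - sum(p_i^2)`.
#'
#' @param freqs numeric vector of allele frequencies (non-negative,
#'   summing to 1 within 1e-9).
#' @return PIC value in `[0, 1)`.
#' @examples
#' pic(c(0.5, 0.5)) # 0.375, the biallelic maximum
#' @export
pic <- function(freqs) {
  if (any(is.na(freqs)) || any(freqs < 0) || abs(sum(freqs) - 1) > 1e-9) {
    abort("`freqs` must be non-negative allele frequencies summing to 1.")
  }
  p2 <- freqs^2
  het <- 1 - sum(p2)
  cross <- (sum(p2)^2 - sum(p2^2)) / 2  # sum over i<j of p_i^2 p_j^2
  het - 2 * cross
}

#' Per-marker allele number, PIC and missing rate
#'
#' Summarises a band-code genotype matrix marker by marker. Aggregate
#' statistics (mean/min/max PIC at the printed precisions, maximum allele
#' number, count of markers above a PIC threshold) are available through
#' [glance()] on the returned object.
#'
#' @param genotypes genotype tibble (see [read_genotypes()]).
#' @param counting allele counting mode passed to
#'   [codes_to_allele_freqs()].
#' @return tibble of class `marker_summary` with columns `marker`,
#'   `allele_number`, `pic`, `missing_rate` (PIC `NA` for all-missing
#'   markers, which are reported).
#' @export
summarize_markers <- function(genotypes, counting = c("diploid", "band")) {
  counting <- match.arg(counting)
  check_genotypes(genotypes)
  codes <- code_matrix(genotypes)
  rows <- lapply(colnames(codes), function(mk) {
    col <- codes[, mk]
    miss <- mean(col == 0 | is.na(col))
    if (all(col == 0 | is.na(col))) {
      warn(sprintf("Marker %s has no observed bands; PIC undefined.", mk))
      return(tibble(marker = mk, allele_number = NA_integer_,
                    pic = NA_real_, missing_rate = miss))
    }
    f <- codes_to_allele_freqs(col, counting)
    tibble(marker = mk, allele_number = length(f), pic = pic(f),
           missing_rate = miss)
  })
  out <- bind_rows(rows)
  class(out) <- c("marker_summary", class(out))
  out
}

#' @describeIn summarize_markers aggregate statistics over markers with a
#'   defined PIC: `mean_pic` (4 decimals), `min_pic`, `max_pic`,
#'   `max_allele_number`, `n_markers` and `n_high_pic` (PIC above
#'   `threshold`).
#' @param x a `marker_summary` tibble.
#' @param threshold PIC threshold for `n_high_pic` (default 0.25).
#' @param ... unused.
#' @export
glance.marker_summary <- function(x, threshold = 0.25, ...) {
  ok <- !is.na(x$pic)
  tibble(
    n_markers = sum(ok),
    mean_pic = round_half_up(mean(x$pic[ok]), 4),
    min_pic = min(x$pic[ok]),
    max_pic = max(x$pic[ok]),
    max_allele_number = max(x$allele_number[ok]),
    n_high_pic = sum(x$pic[ok] > threshold)
  )
}

#' Write a marker summary as TSV
#'
#' Columns mirror the published per-marker table: Marker, Allele Number,
#' PIC (3 decimals), plus the missing rate.
#'
#' @param summary a `marker_summary` tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_marker_summary <- function(summary, path) {
  out <- tibble(
    Marker = summary$marker,
    `Allele Number` = summary$allele_number,
    PIC = sprintf("%.3f", summary$pic),
    `Missing Rate` = sprintf("%.3f", summary$missing_rate)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
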