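# Shared small helpers.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed tables in the field
#' conventionally round half up. This helper rounds ties away from zero at
#' the requested number of decimals.
#'
#' @param x numeric vector.
#' @param digits integer, decimals to keep.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Validate a rectangular band-code genotype tibble: first column accession_id,
# remaining columns integer codes in 0..4.
check_genotypes <- function(genotypes, arg = "genotypes") {
  if (!is.data.frame(genotypes) || !"accession_id" %in% names(genotypes)) {
    abort(sprintf("`%s` must be a data frame with an `accession_id` column.", arg))
  }
  if (anyDuplicated(genotypes$accession_id)) {
    abort(sprintf("`%s` has duplicated accession ids.", arg))
  }
  mk <- setdiff(names(genotypes), "accession_id")
  if (length(mk) == 0L) abort(sprintf("`%s` has no marker columns.", arg))
  codes <- as.matrix(genotypes[mk])
  if (!all(codes %in% 0:4 | is.na(codes))) {
    abort(sprintf("`%s` contains band codes outside 0-4.", arg))
  }
  invisible(genotypes)
}

# Marker columns of a genotype tibble, in order.
marker_names <- function(genotypes) setdiff(names(genotypes), "accession_id")

# Band codes as an integer matrix (accessions x markers), NA preserved.
code_matrix <- function(genotypes) {
  m <- as.matrix(genotypes[marker_names(genotypes)])
  storage.mode(m) <- "integer"
  rownames(m) <- genotypes$accession_id
  m
}

# Map band codes to biallelic alternate-allele dosage: 1 -> 0, 3 -> 1,
# 2 -> 2, 4 -> 2 (second InDel allele collapsed to "non-reference"),
# 0 -> NA. Used by PCA and the admixture model.
dosage_matrix <- function(genotypes) {
  codes <- code_matrix(genotypes)
  d <- matrix(NA_real_, nrow(codes), ncol(codes), dimnames = dimnames(codes))
  d[codes == 1L] <- 0
  d[codes == 3L] <- 1
  d[codes == 2L] <- 2
  d[codes == 4L] <- 2
  d
}

# Impute missing dosages with the column mean (columns with no data -> 0).
impute_col_mean <- function(d) {
  mu <- colMeans(d, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- mu[idx[, 2]]
  d
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# reverse complement of plain character sequences (fast path for the
# thousands of short primer windows the design scan examines)
revcomp <- function(seq) {
  comp <- chartr("ACGTacgtN", "TGCAtgcaN", seq)
  vapply(strsplit(comp, ""), function(b) paste(rev(b), collapse = ""),
         character(1), USE.NAMES = FALSE)
}
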