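#' Primer design configuration
#'
#' Constraint windows for PCR primer search around screened InDel loci.
#' Defaults follow the published design parameters: primer length 21-30 bp,
#' melting temperature 57-62 degrees C, GC content 40-70 percent, product
#' size 70-150 bp on the reference allele, and rejection of primer pairs
#' forming dimers or hairpins with themselves or each other.
#'
#' @param primer_len length range in bp, `c(min, max)`.
#' @param tm_range melting temperature window in degrees C.
#' @param gc_range GC content window in percent.
#' @param product_range amplicon size window in bp on the reference allele.
#' @param max_dimer_run a pair fails when a perfect reverse-complement run
#'   of at least this many bp exists between primers (or within one).
#' @param max_hairpin_stem a primer fails when it can fold back on itself
#'   with a perfect stem of at least this many bp and a loop of >= 3 nt.
#' @param end_window length of the 3'-terminal window that must not
#'   perfectly complement any window of the partner primer.
#' @param tm_method `"nearest_neighbor"` (default) or `"wallace"`.
#' @param na_molar monovalent cation concentration (mol/L).
#' @param primer_molar total primer concentration (mol/L).
#' @return a `primer_config` list.
#' @export
primer_config <- function(primer_len = c(21, 30), tm_range = c(57, 62),
                          gc_range = c(40, 70), product_range = c(70, 150),
                          max_dimer_run = 6, max_hairpin_stem = 5,
                          end_window = 5,
                          tm_method = c("nearest_neighbor", "wallace"),
                          na_molar = 0.05, primer_molar = 250e-9) {
  tm_method <- match.arg(tm_method)
  stopifnot(primer_len[1] <= primer_len[2], tm_range[1] <= tm_range[2],
            gc_range[1] <= gc_range[2], product_range[1] <= product_range[2])
  structure(list(primer_len = primer_len, tm_range = tm_range,
                 gc_range = gc_range, product_range = product_range,
                 max_dimer_run = max_dimer_run,
                 max_hairpin_stem = max_hairpin_stem,
                 end_window = end_window, tm_method = tm_method,
                 na_molar = na_molar, primer_molar = primer_molar),
            class = "primer_config")
}

#' GC content of a DNA sequence
#'
#' @param seq character vector of ACGT sequences.
#' @return percent G+C, `100 * (G + C) / length`.
#' @examples
#' gc_content("ATGC")
#' @export
gc_content <- function(seq) {
  if (any(!grepl("^[ACGT]+$", seq))) {
    abort("gc_content() requires non-empty ACGT sequences.")
  }
  vapply(strsplit(seq, ""), function(b) 100 * mean(b %in% c("G", "C")),
         numeric(1))
}

# Unified nearest-neighbor parameters (Allawi & SantaLucia 1997):
# dH in kcal/mol, dS in cal/(mol K), one row per dinucleotide step.
nn_unified <- local({
  steps <- c(AA = 1, AC = 2, AG = 3, AT = 4, CA = 5, CC = 6, CG = 7, CT = 8,
             GA = 9, GC = 10, GG = 11, GT = 12, TA = 13, TC = 14, TG = 15,
             TT = 16)
  dH <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
          CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
          GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
          TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
  dS <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
          CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
          GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
          TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
  list(dH = dH, dS = dS,
       init = list(AT = c(dH = 2.3, dS = 4.1), GC = c(dH = 0.1, dS = -2.8)))
})

#' Primer melting temperature
#'
#' `"nearest_neighbor"` uses the unified nearest-neighbor thermodynamic
#' parameters with duplex initiation terms, the SantaLucia entropy salt
#' correction `0.368 (N-1) ln[Na+]`, and
#' `Tm = 1000 dH / (dS + R ln(CT/4)) - 273.15` for non-self-complementary
#' duplexes at total strand concentration `CT`. `"wallace"` is the
#' `2(A+T) + 4(G+C)` rule, useful as a fast cross-check.
#'
#' @param seq character vector of ACGT sequences (10-40 nt for the
#'   nearest-neighbor method).
#' @param method `"nearest_neighbor"` or `"wallace"`.
#' @param na_molar monovalent cation concentration, mol/L.
#' @param primer_molar total primer concentration, mol/L.
#' @return melting temperature(s) in degrees C.
#' @examples
#' melting_temp("ATGCATGCATGCATGCATGCA")
#' melting_temp("ATGCATGCATGCATGCATGC", method = "wallace")
#' @export
melting_temp <- function(seq, method = c("nearest_neighbor", "wallace"),
                         na_molar = 0.05, primer_molar = 250e-9) {
  method <- match.arg(method)
  if (any(!grepl("^[ACGT]+$", seq))) {
    abort("melting_temp() requires ACGT sequences.")
  }
  if (method == "wallace") {
    return(vapply(strsplit(seq, ""), function(b) {
      2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
    }, numeric(1)))
  }
  n <- nchar(seq)
  if (any(n < 10 | n > 40)) {
    abort("nearest_neighbor melting_temp() requires 10-40 nt sequences.")
  }
  R <- 1.987  # cal / (mol K)
  vapply(seq, function(s) {
    b <- strsplit(s, "")[[1]]
    di <- paste0(b[-length(b)], b[-1])
    dH <- sum(nn_unified$dH[di])
    dS <- sum(nn_unified$dS[di])
    for (term in b[c(1, length(b))]) {
      init <- if (term %in% c("A", "T")) nn_unified$init$AT else nn_unified$init$GC
      dH <- dH + init["dH"]
      dS <- dS + init["dS"]
    }
    dS <- dS + 0.368 * (length(b) - 1) * log(na_molar)
    unname(1000 * dH / (dS + R * log(primer_molar / 4)) - 273.15)
  }, numeric(1), USE.NAMES = FALSE)
}

# longest common substring length between two short sequences (O(nm) DP)
longest_common_run <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  best <- 0L
  prev <- integer(length(y))
  for (i in seq_along(x)) {
    cur <- integer(length(y))
    match_j <- x[i] == y
    cur[match_j] <- c(1L, prev[-length(prev)] + 1L)[match_j]
    best <- max(best, cur)
    prev <- cur
  }
  best
}

#' Dimer and hairpin screen for primer sequences
#'
#' A pair (or a single primer against itself) fails when any of:
#' (a) the longest perfect reverse-complement run between the two
#' sequences is at least `max_dimer_run` bp; (b) the 3'-terminal
#' `end_window` bases of either primer perfectly complement any window of
#' the other; (c) either sequence can fold into a hairpin with a perfect
#' stem of at least `max_hairpin_stem` bp enclosing a loop of >= 3 nt.
#'
#' @param seq_a,seq_b ACGT sequences; omit `seq_b` (or pass the same
#'   sequence) for a self check.
#' @param config a [primer_config()].
#' @return list with logical `pass` and a character `reason` (`NA` when
#'   passing).
#' @export
dimer_hairpin_check <- function(seq_a, seq_b = NULL, config = primer_config()) {
  if (is.null(seq_b)) seq_b <- seq_a
  if (!grepl("^[ACGT]+$", seq_a) || !grepl("^[ACGT]+$", seq_b)) {
    abort("dimer_hairpin_check() requires ACGT sequences.")
  }
  fail <- function(reason) list(pass = FALSE, reason = reason)
  # (a) longest complementary run: common substring of a and revcomp(b)
  if (longest_common_run(seq_a, revcomp(seq_b)) >= config$max_dimer_run) {
    return(fail("dimer"))
  }
  # (b) 3'-end complementarity
  w <- config$end_window
  end_a <- substring(seq_a, nchar(seq_a) - w + 1L, nchar(seq_a))
  end_b <- substring(seq_b, nchar(seq_b) - w + 1L, nchar(seq_b))
  if (grepl(revcomp(end_a), seq_b, fixed = TRUE) ||
      grepl(revcomp(end_b), seq_a, fixed = TRUE)) {
    return(fail("3'-end complementarity"))
  }
  # (c) hairpin: perfect stem of exactly max_hairpin_stem (any longer stem
  # contains one) with loop >= 3
  if (has_hairpin(seq_a, config$max_hairpin_stem) ||
      (seq_b != seq_a && has_hairpin(seq_b, config$max_hairpin_stem))) {
    return(fail("hairpin"))
  }
  list(pass = TRUE, reason = NA_character_)
}

has_hairpin <- function(seq, stem, min_loop = 3L) {
  n <- nchar(seq)
  if (n < 2L * stem + min_loop) return(FALSE)
  starts <- seq_len(n - stem + 1L)
  wins <- substring(seq, starts, starts + stem - 1L)
  # revcomp of window [s, s+stem-1] = window of revcomp(seq) starting at
  # n - (s + stem - 1) + 1, so one revcomp serves all windows
  rcseq <- revcomp(seq)
  rc <- substring(rcseq, n - (starts + stem - 1L) + 1L, n - starts + 1L)
  for (i in seq_along(wins)) {
    # partner window must start after the stem plus the minimum loop
    j_min <- i + stem + min_loop
    if (j_min > length(wins)) break
    if (any(rc[j_min:length(wins)] == wins[i])) return(TRUE)
  }
  FALSE
}

#' Extract the primer design template around a screened locus
#'
#' Template = `flank` bp of upstream reference, the reference allele, and
#' `flank` bp downstream. The offset of the InDel segment within the
#' template is recorded for product-size arithmetic.
#'
#' @param locus one-row data frame with `chrom`, `pos`, `ref_allele`.
#' @param reference named `DNAStringSet` or FASTA path.
#' @param flank flank length in bp (default 250).
#' @return list with `template` (character), `indel_start` (first base of
#'   the reference allele within the template, = `flank + 1`) and
#'   `ref_len`.
#' @export
extract_design_template <- function(locus, reference, flank = 250) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  chrom_seq <- reference[[locus$chrom]]
  if (is.null(chrom_seq)) abort(sprintf("Chromosome %s not in reference.", locus$chrom))
  ref_len <- nchar(locus$ref_allele)
  lstart <- locus$pos - flank
  rend <- locus$pos + ref_len - 1L + flank
  if (lstart < 1L || rend > length(chrom_seq)) {
    abort(sprintf("Locus %s:%d has insufficient flank for a %d bp template.",
                  locus$chrom, locus$pos, flank))
  }
  template <- as.character(Biostrings::subseq(chrom_seq, lstart, rend))
  obs <- substring(template, flank + 1L, flank + ref_len)
  if (obs != toupper(locus$ref_allele)) {
    abort(sprintf("Reference allele mismatch at %s:%d.", locus$chrom, locus$pos))
  }
  list(template = template, indel_start = flank + 1L, ref_len = ref_len)
}

# enumerate windows of the template that qualify as single primers
qualifying_windows <- function(template, starts, lens, config, reverse) {
  grid <- expand.grid(start = starts, len = lens)
  grid$end <- grid$start + grid$len - 1L
  grid <- grid[grid$end <= nchar(template) & grid$start >= 1L, , drop = FALSE]
  if (nrow(grid) == 0L) return(grid)
  seqs <- substring(template, grid$start, grid$end)
  if (reverse) seqs <- vapply(seqs, revcomp, character(1), USE.NAMES = FALSE)
  ok_acgt <- grepl("^[ACGT]+$", seqs)
  grid$seq <- seqs
  grid <- grid[ok_acgt, , drop = FALSE]
  if (nrow(grid) == 0L) return(grid)
  grid$gc <- gc_content(grid$seq)
  grid <- grid[grid$gc >= config$gc_range[1] & grid$gc <= config$gc_range[2], ,
               drop = FALSE]
  if (nrow(grid) == 0L) return(grid)
  grid$tm <- melting_temp(grid$seq, config$tm_method, config$na_molar,
                          config$primer_molar)
  grid <- grid[grid$tm >= config$tm_range[1] & grid$tm <= config$tm_range[2], ,
               drop = FALSE]
  if (nrow(grid) == 0L) return(grid)
  self_ok <- vapply(grid$seq, function(s) dimer_hairpin_check(s, config = config)$pass,
                    logical(1))
  grid[self_ok, , drop = FALSE]
}

#' Search for the best qualifying primer pair around an InDel
#'
#' Exhaustively scans all forward/reverse primer windows such that the
#' forward primer lies entirely upstream of the InDel segment, the reverse
#' primer entirely downstream, and the reference-allele product size falls
#' within `product_range`. Every primer must individually satisfy the
#' length, GC, Tm and self-structure constraints, and the pair must pass
#' the cross-dimer screen. Among qualifying pairs the one minimising
#' `|Tm_f - Tm_r|` is returned, ties broken by smaller product, then by
#' leftmost forward start; `NULL` when no pair qualifies.
#'
#' @param template,indel_start,ref_len from [extract_design_template()].
#' @param alt_len length of the alternate allele (for the alternate-allele
#'   product size).
#' @param config a [primer_config()].
#' @return one-row tibble with forward/reverse sequences, Tm, GC and both
#'   product sizes, or `NULL`.
#' @export
design_primer_pair <- function(template, indel_start, ref_len, alt_len,
                               config = primer_config()) {
  lens <- seq(config$primer_len[1], config$primer_len[2])
  indel_end <- indel_start + ref_len - 1L
  # forward windows end before the indel; only starts that can reach the
  # product window are enumerated
  f_starts <- seq(max(1L, indel_end + 1L - config$product_range[2] +
                        config$primer_len[1]),
                  indel_start - config$primer_len[1])
  if (length(f_starts) == 0L || f_starts[1] > tail(f_starts, 1)) return(NULL)
  fwd <- qualifying_windows(template, f_starts, lens, config, reverse = FALSE)
  fwd <- fwd[fwd$end < indel_start, , drop = FALSE]
  if (nrow(fwd) == 0L) return(NULL)
  r_starts <- seq(indel_end + 1L,
                  min(nchar(template), indel_start + config$product_range[2]))
  rev <- qualifying_windows(template, r_starts, lens, config, reverse = TRUE)
  if (nrow(rev) == 0L) return(NULL)

  pairs <- merge(fwd, rev, by = NULL, suffixes = c("_f", "_r"))
  pairs$product_ref <- pairs$end_r - pairs$start_f + 1L
  pairs <- pairs[pairs$product_ref >= config$product_range[1] &
                   pairs$product_ref <= config$product_range[2], , drop = FALSE]
  if (nrow(pairs) == 0L) return(NULL)
  pairs$dtm <- abs(pairs$tm_f - pairs$tm_r)
  pairs <- pairs[order(pairs$dtm, pairs$product_ref, pairs$start_f,
                       pairs$start_r), , drop = FALSE]
  for (i in seq_len(nrow(pairs))) {
    if (dimer_hairpin_check(pairs$seq_f[i], pairs$seq_r[i], config)$pass) {
      p <- pairs[i, ]
      return(tibble(
        forward_seq = p$seq_f, reverse_seq = p$seq_r,
        tm_f = p$tm_f, tm_r = p$tm_r, gc_f = p$gc_f, gc_r = p$gc_r,
        product_size_ref = p$product_ref,
        product_size_alt = p$product_ref + (alt_len - ref_len),
        forward_start = p$start_f, reverse_end = p$end_r
      ))
    }
  }
  NULL
}

#' Marker name from chromosome index and position
#'
#' Names follow the "chromosome token + position token" convention:
#' chromosomes 1-9 map to `T1`-`T9` and 10, 11, 12 to `Ta`, `Tb`, `Tc`;
#' the position token is `M` plus `floor(pos / 10 kb)` zero-padded to four
#' digits (so `T1M0546` sits near 5.46 Mb on chromosome 1).
#'
#' @param chrom_index integer 1-12.
#' @param pos 1-based position in bp.
#' @return marker name string.
#' @examples
#' name_marker(1, 5460000)
#' name_marker(10, 6412345)
#' @export
name_marker <- function(chrom_index, pos) {
  if (any(chrom_index < 1 | chrom_index > 12)) {
    abort("chrom_index must be between 1 and 12.")
  }
  tokens <- c(paste0("T", 1:9), "Ta", "Tb", "Tc")
  sprintf("%sM%04d", tokens[chrom_index], pos %/% 10000)
}

# chromosome index from a label like "Chr09", "chr9", "9"
chrom_index_from_label <- function(chrom) {
  idx <- suppressWarnings(as.integer(sub("^[^0-9]*", "", chrom)))
  if (anyNA(idx)) abort("Cannot derive a chromosome index from the chromosome label.")
  idx
}

#' Design primers for all passing screened loci
#'
#' Batch wrapper: extracts templates, runs the pair search and assigns
#' marker names. Loci without a qualifying pair are dropped (reported via
#' a message), mirroring the protocol's "sites for which qualified primers
#' could not be designed were excluded".
#'
#' @param candidates screened candidate tibble (rows with `status ==
#'   "pass"` are used).
#' @param reference named `DNAStringSet` or FASTA path.
#' @param config a [primer_config()].
#' @param flank design template flank in bp.
#' @return primer table tibble: marker, chrom, pos, sequences, Tm, GC and
#'   product sizes.
#' @export
design_primers <- function(candidates, reference, config = primer_config(),
                           flank = 250) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  loci <- filter(as_tibble(candidates), .data$status == "pass")
  rows <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    tmpl <- tryCatch(extract_design_template(locus, reference, flank),
                     error = function(e) NULL)
    if (is.null(tmpl)) next
    pair <- design_primer_pair(tmpl$template, tmpl$indel_start, tmpl$ref_len,
                               nchar(locus$alt_allele), config)
    if (is.null(pair)) next
    rows[[i]] <- dplyr::bind_cols(
      tibble(marker = name_marker(chrom_index_from_label(locus$chrom), locus$pos),
             chrom = locus$chrom, pos = locus$pos),
      pair
    )
  }
  out <- bind_rows(rows)
  inform(sprintf("Designed primers for %d of %d passing loci.",
                 nrow(out), nrow(loci)))
  out
}
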