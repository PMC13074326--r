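#' Screening configuration for InDel marker candidates
#'
#' Thresholds of the stepwise marker screen. Defaults follow the published
#' protocol: quality >= 30, InDel length >= 6 bp, 200 bp flanks checked for
#' single-copy context, and a 100 kb minimum spacing between retained loci.
#'
#' @param qual_min minimum Phred-scaled variant quality (inclusive).
#' @param len_min minimum InDel length in bp (inclusive).
#' @param flank_len flank length in bp used for the single-copy check.
#' @param min_spacing minimum distance in bp between retained neighbours.
#' @param genic_ratio_mode `"observed"` keeps the genic/intergenic mix as
#'   observed (pass-through); `"fixed"` retains a set ratio.
#' @param genic_ratio target genic fraction when `genic_ratio_mode = "fixed"`.
#' @param n_target total budget when `genic_ratio_mode = "fixed"`.
#' @param k_check k-mer size for the flank uniqueness check.
#' @param max_ambiguous_frac maximum tolerated fraction of non-ACGT bases
#'   in a flank before it fails outright.
#' @return a `screen_config` list.
#' @export
screen_config <- function(qual_min = 30, len_min = 6, flank_len = 200,
                          min_spacing = 1e5,
                          genic_ratio_mode = c("observed", "fixed"),
                          genic_ratio = 0.5, n_target = NULL,
                          k_check = 31, max_ambiguous_frac = 0.1) {
  genic_ratio_mode <- match.arg(genic_ratio_mode)
  stopifnot(qual_min > 0, len_min > 0, flank_len > 0, min_spacing > 0,
            k_check > 0, genic_ratio >= 0, genic_ratio <= 1)
  structure(list(qual_min = qual_min, len_min = len_min,
                 flank_len = flank_len, min_spacing = min_spacing,
                 genic_ratio_mode = genic_ratio_mode,
                 genic_ratio = genic_ratio, n_target = n_target,
                 k_check = k_check, max_ambiguous_frac = max_ambiguous_frac),
            class = "screen_config")
}

# reference footprint of a variant on the reference sequence
variant_footprint <- function(variants) {
  tibble(chrom = variants$chrom, start = variants$pos,
         end = variants$pos + nchar(variants$ref_allele) - 1L)
}

#' Stage 1 screen: quality, length and repeat-region filters
#'
#' A variant passes iff `qual >= qual_min`, `indel_len >= len_min` and its
#' reference footprint (`[pos, pos + nchar(ref) - 1]`) does not overlap any
#' repeat interval. Each failing variant gets the first applicable flag in
#' the order quality, length, repeat; unknown quality fails the quality
#' test. Later stages never re-examine loci that already failed.
#'
#' @param variants variant tibble from [read_indel_vcf()].
#' @param config a [screen_config()].
#' @param repeat_intervals repeat regions as a 1-based inclusive interval
#'   tibble (see [read_bed()]); `NULL` for none.
#' @return the variants with a `status` column (`"pass"`, `"fail_qual"`,
#'   `"fail_length"`, `"fail_repeat"`).
#' @export
filter_basic <- function(variants, config = screen_config(),
                         repeat_intervals = NULL) {
  v <- as_tibble(variants)
  in_repeat <- rep(FALSE, nrow(v))
  if (!is.null(repeat_intervals) && nrow(repeat_intervals) > 0 && nrow(v) > 0) {
    extra <- setdiff(unique(repeat_intervals$chrom), unique(v$chrom))
    if (length(extra)) {
      warn(sprintf("Repeat intervals on chromosome(s) %s match no variants; ignored.",
                   paste(extra, collapse = ", ")))
    }
    hits <- GenomicRanges::countOverlaps(
      intervals_to_granges(variant_footprint(v)),
      intervals_to_granges(repeat_intervals)
    )
    in_repeat <- hits > 0
  }
  qual_ok <- !is.na(v$qual) & v$qual >= config$qual_min
  len_ok <- v$indel_len >= config$len_min
  v$status <- dplyr::case_when(
    !qual_ok ~ "fail_qual",
    !len_ok ~ "fail_length",
    in_repeat ~ "fail_repeat",
    TRUE ~ "pass"
  )
  v
}

# k-mers of a sequence (ACGT only)
seq_kmers <- function(seq, k) {
  n_k <- nchar(seq) - k + 1L
  if (n_k < 1L) return(character(0))
  kmers <- substring(seq, seq_len(n_k), seq_len(n_k) + k - 1L)
  unique(kmers[grepl("^[ACGT]+$", kmers)])
}

# occurrence counts of many k-mers in the reference, both strands, with a
# single dictionary scan
kmer_counts_in_reference <- function(kmers, reference, k) {
  if (length(kmers) == 0L) return(integer(0))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  counts <- rowSums(Biostrings::vcountPDict(pd, reference)) +
    rowSums(Biostrings::vcountPDict(
      pd, Biostrings::reverseComplement(reference)))
  setNames(counts, kmers)
}

#' Stage 2 screen: flank single-copy check
#'
#' Extracts flanks of `flank_len` bp on both sides of each passing locus
#' and requires every k-mer (length `k_check`) of both flanks to occur
#' exactly once in the whole reference, counting both strands — an exact
#' proxy for "located in a non-repetitive, single-copy region". Loci too
#' close to a chromosome end for full flanks fail, as do flanks whose
#' non-ACGT fraction exceeds `max_ambiguous_frac`.
#'
#' @param candidates output of [filter_basic()].
#' @param reference a named `DNAStringSet` or path to a FASTA file.
#' @param config a [screen_config()].
#' @return candidates with `left_flank`/`right_flank` columns and failing
#'   loci flagged `"fail_flank_copy"`.
#' @export
check_flank_uniqueness <- function(candidates, reference,
                                   config = screen_config()) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  v <- as_tibble(candidates)
  v$left_flank <- NA_character_
  v$right_flank <- NA_character_
  todo <- which(v$status == "pass")
  kmer_sets <- vector("list", nrow(v))
  for (i in todo) {
    chrom <- v$chrom[i]
    if (!chrom %in% names(reference)) {
      abort(sprintf("Chromosome %s not in reference.", chrom))
    }
    chrom_seq <- reference[[chrom]]
    ref_end <- v$pos[i] + nchar(v$ref_allele[i]) - 1L
    lstart <- v$pos[i] - config$flank_len
    rend <- ref_end + config$flank_len
    if (lstart < 1L || rend > length(chrom_seq)) {
      v$status[i] <- "fail_flank_copy"
      next
    }
    lf <- as.character(Biostrings::subseq(chrom_seq, lstart, v$pos[i] - 1L))
    rf <- as.character(Biostrings::subseq(chrom_seq, ref_end + 1L, rend))
    v$left_flank[i] <- lf
    v$right_flank[i] <- rf
    amb <- function(s) mean(strsplit(s, "")[[1]] %notin% c("A", "C", "G", "T"))
    if (amb(lf) > config$max_ambiguous_frac ||
        amb(rf) > config$max_ambiguous_frac) {
      v$status[i] <- "fail_flank_copy"
      next
    }
    km <- c(seq_kmers(lf, config$k_check), seq_kmers(rf, config$k_check))
    if (length(km) == 0L) {
      v$status[i] <- "fail_flank_copy"
      next
    }
    kmer_sets[[i]] <- km
  }
  # one dictionary scan of the whole reference for every flank k-mer
  all_kmers <- unique(unlist(kmer_sets))
  if (length(all_kmers)) {
    counts <- kmer_counts_in_reference(all_kmers, reference, config$k_check)
    for (i in which(lengths(kmer_sets) > 0)) {
      if (any(counts[kmer_sets[[i]]] != 1L)) v$status[i] <- "fail_flank_copy"
    }
  }
  v
}

`%notin%` <- function(x, table) !x %in% table

#' Stage 3 screen: spacing thinning
#'
#' Within each chromosome, retained loci must be pairwise at least
#' `min_spacing` bp apart. The scan is greedy left-to-right: keep the first
#' passing locus, then keep each next one only if it is `>= min_spacing`
#' from the last kept locus. Deterministic given sorted input; input is
#' sorted by (chrom, pos) internally.
#'
#' @param candidates candidate tibble with a `status` column.
#' @param min_spacing minimum spacing in bp (default from [screen_config()]).
#' @return candidates with too-close loci flagged `"fail_spacing"`.
#' @export
thin_by_spacing <- function(candidates, min_spacing = 1e5) {
  v <- arrange(as_tibble(candidates), .data$chrom, .data$pos)
  for (chrom in unique(v$chrom)) {
    idx <- which(v$chrom == chrom & v$status == "pass")
    if (length(idx) < 2L) next
    last_kept <- v$pos[idx[1]]
    for (i in idx[-1]) {
      if (v$pos[i] - last_kept >= min_spacing) {
        last_kept <- v$pos[i]
      } else {
        v$status[i] <- "fail_spacing"
      }
    }
  }
  v
}

#' Classify loci as genic or intergenic
#'
#' A locus is genic when its reference footprint overlaps any gene
#' interval (exonic vs intronic is not distinguished).
#'
#' @param candidates candidate tibble.
#' @param gene_intervals 1-based inclusive interval tibble; `NULL` marks
#'   everything intergenic.
#' @return candidates with a `region_class` column.
#' @export
classify_region <- function(candidates, gene_intervals = NULL) {
  v <- as_tibble(candidates)
  genic <- rep(FALSE, nrow(v))
  if (!is.null(gene_intervals) && nrow(gene_intervals) > 0 && nrow(v) > 0) {
    genic <- GenomicRanges::countOverlaps(
      intervals_to_granges(variant_footprint(v)),
      intervals_to_granges(gene_intervals)) > 0
  }
  v$region_class <- ifelse(genic, "genic", "intergenic")
  v
}

#' Stage 4 screen: genic/intergenic balance
#'
#' With `genic_ratio_mode = "observed"` this is a pass-through. With
#' `"fixed"`, retains `round(n_target * genic_ratio)` genic and
#' `n_target - round(n_target * genic_ratio)` intergenic loci among the
#' passing candidates, chosen by descending quality with position as the
#' tie-break. When a class has fewer loci than requested, all available
#' are taken and the shortfall is reported.
#'
#' @param candidates candidate tibble with `status` and `region_class`.
#' @param config a [screen_config()].
#' @return candidates with unselected loci flagged `"fail_balance"`.
#' @export
balance_genic <- function(candidates, config = screen_config()) {
  v <- as_tibble(candidates)
  if (config$genic_ratio_mode == "observed") return(v)
  if (is.null(config$n_target)) {
    abort("`n_target` must be set when genic_ratio_mode = \"fixed\".")
  }
  n_genic <- round(config$n_target * config$genic_ratio)
  n_inter <- config$n_target - n_genic
  pick <- function(class, n_want) {
    idx <- which(v$status == "pass" & v$region_class == class)
    if (length(idx) < n_want) {
      inform(sprintf("Requested %d %s loci but only %d available.",
                     n_want, class, length(idx)))
      n_want <- length(idx)
    }
    ord <- idx[order(-v$qual[idx], v$chrom[idx], v$pos[idx])]
    head(ord, n_want)
  }
  keep <- c(pick("genic", n_genic), pick("intergenic", n_inter))
  drop <- setdiff(which(v$status == "pass"), keep)
  v$status[drop] <- "fail_balance"
  v
}

#' Run the full stepwise marker screen
#'
#' Chains the stages in the fixed published order: basic filters (quality,
#' length, repeat), flank single-copy check, spacing thinning, genic
#' balance. Each stage only examines loci still passing, so every locus
#' carries exactly one terminal disposition. Input/output counts per stage
#' are reported via messages.
#'
#' @param variants variant tibble from [read_indel_vcf()].
#' @param reference named `DNAStringSet` or FASTA path; `NULL` skips the
#'   flank check.
#' @param repeat_intervals,gene_intervals 1-based inclusive interval
#'   tibbles (or `NULL`).
#' @param config a [screen_config()].
#' @param validation optional external (wet-lab) validation results: a data
#'   frame with `marker`/`validated` columns merged by marker name after
#'   screening; loci with `validated = FALSE` are flagged
#'   `"fail_validation"`. Requires a `marker` column on the candidates.
#' @return candidate tibble with `status`, `region_class` and flank columns.
#' @export
screen_markers <- function(variants, reference = NULL,
                           repeat_intervals = NULL, gene_intervals = NULL,
                           config = screen_config(), validation = NULL) {
  stage <- function(tag, v) {
    inform(sprintf("%s: %d passing / %d loci", tag,
                   sum(v$status == "pass"), nrow(v)))
    v
  }
  v <- stage("basic filters", filter_basic(variants, config, repeat_intervals))
  if (!is.null(reference)) {
    v <- stage("flank single-copy", check_flank_uniqueness(v, reference, config))
  }
  v <- stage("spacing", thin_by_spacing(v, config$min_spacing))
  v <- classify_region(v, gene_intervals)
  v <- stage("genic balance", balance_genic(v, config))
  if (!is.null(validation)) {
    if (!"marker" %in% names(v)) abort("Candidates need a `marker` column to merge validation results.")
    bad <- validation$marker[!validation$validated]
    v$status[v$status == "pass" & v$marker %in% bad] <- "fail_validation"
    v <- stage("external validation", v)
  }
  v
}

#' Write retained screening candidates as TSV
#'
#' @param candidates screened candidate tibble.
#' @param path output file.
#' @param all write all loci (default) or only passing ones.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path, all = TRUE) {
  v <- as_tibble(candidates)
  if (!all) v <- filter(v, .data$status == "pass")
  cols <- intersect(c("chrom", "pos", "indel_type", "indel_len", "qual",
                      "region_class", "status"), names(v))
  readr::write_tsv(v[cols], path, progress = FALSE)
  invisible(path)
}
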