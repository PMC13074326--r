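# Seeded generators for every input the pipeline consumes: reference
# sequences with implanted repeats and gene intervals, InDel catalogues
# with known truth, and structured band-code genotype matrices. All
# generators are pure functions of their arguments plus the seed, and the
# returned truth tables are sufficient to compute every downstream
# expectation independently of the pipeline.

#' Simulate a reference genome with repeats and genes
#'
#' Generates random chromosome sequences at a stated GC content, implants
#' exact duplicated substrings as repeat regions (at least two verbatim
#' copies of each unit, so flank single-copy checks genuinely fail
#' there), and lays down non-overlapping gene intervals covering
#' approximately `gene_fraction` of each chromosome.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param repeat_fraction fraction of each chromosome covered by repeats.
#' @param gene_fraction fraction covered by gene intervals.
#' @param gc_content GC fraction of the random background (default 0.36,
#'   a typical plant-genome value).
#' @param repeat_unit_len length of one repeat unit in bp.
#' @param seed integer seed.
#' @return list with `sequences` (named `DNAStringSet`), `repeats` and
#'   `genes` (1-based inclusive interval tibbles).
#' @export
simulate_reference <- function(n_chrom = 2, chrom_length = 2e5,
                               repeat_fraction = 0.05, gene_fraction = 0.3,
                               gc_content = 0.36, repeat_unit_len = 400,
                               seed = 1) {
  stopifnot(repeat_fraction >= 0, gene_fraction >= 0,
            repeat_fraction + gene_fraction <= 1 || gene_fraction <= 1,
            gc_content > 0, gc_content < 1)
  if (repeat_fraction > 0.5) abort("repeat_fraction above 0.5 is infeasible.")
  with_seed(seed, {
    chroms <- sprintf("Chr%02d", seq_len(n_chrom))
    seqs <- character(n_chrom)
    repeats <- list()
    genes <- list()
    for (ci in seq_len(n_chrom)) {
      s <- strsplit(random_dna(chrom_length, gc_content), "")[[1]]
      # repeats: plant pairs of verbatim copies of random units
      occupied <- matrix(numeric(0), ncol = 2)
      target <- repeat_fraction * chrom_length
      planted <- 0
      reps <- list()
      while (planted < target) {
        unit <- strsplit(random_dna(repeat_unit_len, gc_content), "")[[1]]
        pos <- place_nonoverlapping(2, repeat_unit_len, chrom_length, occupied)
        if (is.null(pos)) break
        for (p in pos) {
          s[p:(p + repeat_unit_len - 1L)] <- unit
          reps[[length(reps) + 1L]] <- c(p, p + repeat_unit_len - 1L)
        }
        occupied <- rbind(occupied, cbind(pos, pos + repeat_unit_len - 1L))
        planted <- planted + 2 * repeat_unit_len
      }
      # genes: non-overlapping intervals, last one clipped to hit the target
      gtarget <- gene_fraction * chrom_length
      gtotal <- 0
      gv <- list()
      gocc <- matrix(numeric(0), ncol = 2)
      while (gtotal < gtarget) {
        glen <- min(sample(2000:4000, 1), ceiling(gtarget - gtotal))
        pos <- place_nonoverlapping(1, glen, chrom_length, gocc)
        if (is.null(pos)) break
        gv[[length(gv) + 1L]] <- c(pos, pos + glen - 1L)
        gocc <- rbind(gocc, c(pos, pos + glen - 1L))
        gtotal <- gtotal + glen
      }
      seqs[ci] <- paste(s, collapse = "")
      to_tbl <- function(lst) {
        if (!length(lst)) {
          return(tibble(chrom = character(), start = integer(), end = integer()))
        }
        m <- do.call(rbind, lst)
        tibble(chrom = chroms[ci], start = as.integer(m[, 1]),
               end = as.integer(m[, 2])) |> arrange(.data$start)
      }
      repeats[[ci]] <- to_tbl(reps)
      genes[[ci]] <- to_tbl(gv)
    }
    sequences <- Biostrings::DNAStringSet(seqs)
    names(sequences) <- chroms
    list(sequences = sequences, repeats = bind_rows(repeats),
         genes = bind_rows(genes))
  })
}

# sample `n` non-overlapping start positions for intervals of `len` on a
# chromosome of `total` bp, avoiding rows of `occupied`; NULL when space
# cannot be found in a bounded number of attempts
place_nonoverlapping <- function(n, len, total, occupied, max_try = 200) {
  out <- integer(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_try)) {
      p <- sample.int(total - len + 1L, 1)
      e <- p + len - 1L
      clash <- nrow(occupied) > 0 &&
        any(p <= occupied[, 2] & e >= occupied[, 1])
      if (!clash && !(length(out) &&
                      any(p <= out + len - 1L & e >= out))) {
        ok <- TRUE
        break
      }
    }
    if (!ok) return(NULL)
    out <- c(out, p)
    occupied <- rbind(occupied, c(p, e))
  }
  out
}

#' Write a simulated reference to FASTA and BED files
#'
#' @param sim output of [simulate_reference()].
#' @param dir output directory (created if needed).
#' @return named list of the three file paths, invisibly.
#' @export
write_sim_reference <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(sim$sequences, fasta)
  rep_bed <- file.path(dir, "repeats.bed")
  gene_bed <- file.path(dir, "genes.bed")
  write_bed(sim$repeats, rep_bed)
  write_bed(sim$genes, gene_bed)
  invisible(list(fasta = fasta, repeats = rep_bed, genes = gene_bed))
}

#' Implant InDels into a simulated reference
#'
#' Places `n` insertion/deletion variants uniformly at random with
#' non-overlapping reference footprints and a margin from chromosome
#' ends, drawing lengths and qualities uniformly from the given ranges.
#' The returned truth table records, per variant, its repeat and gene
#' context, so each screening criterion can be evaluated independently of
#' the pipeline.
#'
#' @param sim output of [simulate_reference()].
#' @param n number of InDels to implant.
#' @param length_range InDel length range in bp (uniform integer draw).
#' @param qual_range Phred quality range (uniform draw, 1 decimal).
#' @param margin minimum distance from chromosome ends in bp.
#' @param min_gap minimum gap between implanted footprints in bp.
#' @param seed integer seed.
#' @return list with `variants` (tibble: chrom, pos, ref_allele,
#'   alt_allele, qual, indel_type, indel_len) and `truth` (variants plus
#'   `in_repeat` and `genic` flags).
#' @export
implant_indels <- function(sim, n, length_range = c(1, 30),
                           qual_range = c(10, 60), margin = 300,
                           min_gap = 0, seed = 1) {
  with_seed(seed, {
    chroms <- names(sim$sequences)
    rows <- list()
    occupied <- lapply(chroms, function(x) matrix(numeric(0), ncol = 2))
    names(occupied) <- chroms
    tries <- 0
    while (length(rows) < n) {
      tries <- tries + 1
      if (tries > 50 * n) abort("Could not place the requested number of InDels.")
      chrom <- sample(chroms, 1)
      chrom_seq <- sim$sequences[[chrom]]
      len <- sample(seq(length_range[1], length_range[2]), 1)
      type <- sample(c("insertion", "deletion"), 1)
      foot <- if (type == "deletion") len + 1L else 1L
      lo <- margin + 1L
      hi <- length(chrom_seq) - margin - foot
      if (hi <= lo) next
      pos <- sample(lo:hi, 1)
      occ <- occupied[[chrom]]
      if (nrow(occ) > 0 &&
          any(pos - min_gap <= occ[, 2] & pos + foot - 1L + min_gap >= occ[, 1])) next
      ref <- as.character(Biostrings::subseq(chrom_seq, pos, pos + foot - 1L))
      alt <- if (type == "deletion") substring(ref, 1, 1) else
        paste0(ref, random_dna(len, 0.5))
      occupied[[chrom]] <- rbind(occ, c(pos, pos + foot - 1L))
      rows[[length(rows) + 1L]] <- tibble(
        chrom = chrom, pos = pos, ref_allele = ref, alt_allele = alt,
        qual = round(runif(1, qual_range[1], qual_range[2]), 1),
        indel_type = type, indel_len = len
      )
    }
    variants <- arrange(bind_rows(rows), .data$chrom, .data$pos)
    truth <- classify_region(variants, sim$genes)
    truth <- rename(truth, genic = "region_class")
    truth$genic <- truth$genic == "genic"
    fp <- intervals_to_granges(variant_footprint(variants))
    truth$in_repeat <- if (nrow(sim$repeats)) {
      GenomicRanges::countOverlaps(fp, intervals_to_granges(sim$repeats)) > 0
    } else FALSE
    list(variants = variants, truth = truth)
  })
}

#' Simulate a structured band-code genotype panel
#'
#' Population structure follows the Balding-Nichols F-model: each marker
#' has an ancestral alternate-allele frequency `p ~ Uniform(0.1, 0.9)`
#' and each of the `K_true` subpopulations draws its own frequency from
#' `Beta(p (1-F)/F, (1-p) (1-F)/F)` with differentiation `F` (FST).
#' Accessions are split evenly across subpopulations; each draws a
#' diploid genotype from its subpopulation frequency under a partially
#' inbred model: with probability `het_rate` the two allele copies are
#' drawn independently, otherwise a single draw is doubled (germplasm
#' panels are dominated by inbred lines). Genotypes are rendered as band
#' codes (hom-ref 1, het 3, hom-alt 2); markers gain a third,
#' length-distinct allele with probability `third_allele_rate` (alternate
#' copies then split between the two InDel alleles; its homozygote is
#' code 4), and `missing_rate` of cells are blanked to 0. Defaults mirror
#' the published study panel: 52 accessions, 63 markers, four
#' subpopulations.
#'
#' @param n_accessions number of accessions.
#' @param K_true number of subpopulations (>= 1).
#' @param fst differentiation parameter F in `[0, 1)`.
#' @param n_markers number of markers.
#' @param het_rate probability an accession is outbred at a marker.
#' @param third_allele_rate probability a marker carries a third allele.
#' @param missing_rate probability a cell is missing (code 0).
#' @param seed integer seed.
#' @return list with `genotypes` (tibble: accession_id + marker columns),
#'   `membership` (named integer vector), `true_freqs` (K x markers
#'   matrix of alternate-allele frequencies), `marker_info` (tibble:
#'   marker, chromosome, pos).
#' @export
simulate_population <- function(n_accessions = 52, K_true = 4, fst = 0.3,
                                n_markers = 63, het_rate = 0.1,
                                third_allele_rate = 0.05,
                                missing_rate = 0.02, seed = 1) {
  stopifnot(K_true >= 1, fst >= 0, fst < 1, n_accessions >= 1,
            n_markers >= 1, het_rate >= 0, het_rate <= 1,
            third_allele_rate >= 0, third_allele_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  with_seed(seed, {
    p_anc <- runif(n_markers, 0.1, 0.9)
    P <- matrix(0, K_true, n_markers)
    for (j in seq_len(n_markers)) {
      P[, j] <- if (fst == 0) p_anc[j] else
        stats::rbeta(K_true, p_anc[j] * (1 - fst) / fst,
                     (1 - p_anc[j]) * (1 - fst) / fst)
    }
    membership <- sort(rep(seq_len(K_true), length.out = n_accessions))
    third <- runif(n_markers) < third_allele_rate
    codes <- matrix(0L, n_accessions, n_markers)
    for (i in seq_len(n_accessions)) {
      pk <- P[membership[i], ]
      outbred <- runif(n_markers) < het_rate
      a1 <- rbinom(n_markers, 1, pk)
      a2 <- ifelse(outbred, rbinom(n_markers, 1, pk), a1)
      # split alternate copies between the two InDel alleles at third-allele
      # markers: allele 1 = "alt", allele 2 = "alt2"
      t1 <- ifelse(a1 == 1 & third & runif(n_markers) < 0.5, 2L, a1)
      t2 <- ifelse(a2 == 1 & third & runif(n_markers) < 0.5, 2L, a2)
      codes[i, ] <- dplyr::case_when(
        t1 == 0L & t2 == 0L ~ 1L,  # hom reference
        t1 == 1L & t2 == 1L ~ 2L,  # hom first InDel allele
        t1 == 2L & t2 == 2L ~ 4L,  # hom second InDel allele
        TRUE ~ 3L                  # any heterozygote: double band
      )
    }
    miss <- matrix(runif(n_accessions * n_markers) < missing_rate,
                   n_accessions, n_markers)
    codes[miss] <- 0L
    chrom_idx <- rep(1:12, length.out = n_markers)
    slot <- stats::ave(seq_len(n_markers), chrom_idx, FUN = seq_along)
    pos <- slot * 510000L
    markers <- name_marker(chrom_idx, pos)
    g <- as_tibble(as.data.frame(codes), .name_repair = ~markers)
    g <- bind_cols(tibble(accession_id = sprintf("A%02d", seq_len(n_accessions))), g)
    list(genotypes = g,
         membership = setNames(membership, g$accession_id),
         true_freqs = P,
         marker_info = tibble(marker = markers,
                              chromosome = sprintf("Ch%02d", chrom_idx),
                              pos = pos))
  })
}

#' Write a complete toy dataset to a directory
#'
#' Convenience generator chaining [simulate_reference()],
#' [implant_indels()] and [simulate_population()]: writes reference FASTA,
#' repeat/gene BED, variant VCF, truth table and genotype TSV.
#'
#' @param dir output directory.
#' @param n_indels number of implanted InDels.
#' @param seed integer seed.
#' @param ... passed to [simulate_population()].
#' @return named list of file paths, invisibly.
#' @export
make_fixtures <- function(dir, n_indels = 60, seed = 1, ...) {
  sim <- simulate_reference(seed = seed)
  paths <- write_sim_reference(sim, dir)
  ind <- implant_indels(sim, n = n_indels, seed = seed + 1)
  paths$vcf <- file.path(dir, "indels.vcf")
  contigs <- setNames(Biostrings::width(sim$sequences), names(sim$sequences))
  write_indel_vcf(ind$variants, paths$vcf, contigs = contigs)
  paths$truth <- file.path(dir, "indel_truth.tsv")
  readr::write_tsv(ind$truth, paths$truth, progress = FALSE)
  pop <- simulate_population(seed = seed + 2, ...)
  paths$genotypes <- file.path(dir, "genotypes.tsv")
  write_genotypes(pop$genotypes, paths$genotypes)
  paths$membership <- file.path(dir, "membership.tsv")
  readr::write_tsv(tibble(accession_id = names(pop$membership),
                          subpopulation = pop$membership),
                   paths$membership, progress = FALSE)
  invisible(paths)
}
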