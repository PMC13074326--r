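test_that("GC content is exact and rejects ambiguous bases", {
  expect_equal(gc_content(c("ATGC", "GGCC", "ATAT")), c(50, 100, 0))
  expect_error(gc_content("ATNG"), "ACGT")
  expect_error(gc_content(""), "ACGT")
})

test_that("Wallace melting temperature follows 2(A+T) + 4(G+C)", {
  s <- paste0(strrep("AT", 5), strrep("GC", 5))  # 10 A/T + 10 G/C
  expect_equal(melting_temp(s, method = "wallace"), 2 * 10 + 4 * 10)
  expect_equal(melting_temp(strrep("A", 20), method = "wallace"), 40)
  # monotone in GC count at fixed length
  tms <- vapply(0:10, function(g) {
    melting_temp(paste0(strrep("G", g), strrep("A", 20 - g)),
                 method = "wallace")
  }, numeric(1))
  expect_true(all(diff(tms) >= 0))
})

test_that("nearest-neighbor Tm matches an independent implementation of the
           unified parameter table", {
  # values computed once with an independent implementation of the same
  # published parameters (50 mM Na+, 250 nM primer, CT/4 convention)
  frozen <- c(ATGCATGCATGCATGCATGCA = 59.10585,
              GCGTACGTTAGCCTAGGCATAGC = 59.396007,
              AAAAAAAAAATTTTTTTTTT = 37.775301)
  got <- melting_temp(names(frozen))
  expect_equal(unname(got), unname(frozen), tolerance = 1e-5)
  expect_error(melting_temp("ACGTACG"), "10-40")
  expect_error(melting_temp(strrep("ACGT", 11)), "10-40")
})

test_that("dimer and hairpin screens detect planted structures", {
  cfg <- primer_config(max_dimer_run = 5, max_hairpin_stem = 5)
  # a sequence and its exact reverse complement: maximal dimer
  s <- "ATCGGCTAGCTAAGCTGGAT"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_false(dimer_hairpin_check(s, rc, cfg)$pass)
  # dissimilar alternating sequences pass (brute-force: no complementary
  # run of length >= 5 exists between them)
  expect_true(dimer_hairpin_check("ATATATAT", "GCGCGCGC", cfg)$pass)
  # planted hairpin: stem GGGGG, loop AAA, stem CCCCC (fails; the
  # self-complementary stem also registers as a self-dimer at this run
  # threshold, which is checked first)
  expect_false(dimer_hairpin_check("GGGGGAAACCCCC", config = cfg)$pass)
  # with the dimer threshold above the stem length, the fold is reported
  # as a hairpin (3' tail keeps the stem away from the end-window check)
  cfg6 <- primer_config(max_dimer_run = 6, max_hairpin_stem = 5)
  expect_equal(dimer_hairpin_check("GGGGGAAACCCCCTT", config = cfg6)$reason,
               "hairpin")
  # loop of only 2 nt is not a hairpin under the >= 3 rule
  expect_true(dimer_hairpin_check("GGGGGAACCCCC",
                                  config = primer_config(max_dimer_run = 20,
                                                         end_window = 12,
                                                         max_hairpin_stem = 5))$pass)
})

test_that("3'-end complementarity fails a pair", {
  cfg <- primer_config(max_dimer_run = 12, max_hairpin_stem = 8)
  a <- "ATCATCATCATCATCGGACT"   # 3' end GGACT
  b <- paste0("TTTTTAGTCCTTTTTTTTTT")  # contains AGTCC = revcomp(GGACT)
  res <- dimer_hairpin_check(a, b, cfg)
  expect_false(res$pass)
  expect_match(res$reason, "3'")
})

test_that("design template extraction enforces flank bounds", {
  set.seed(5)
  genome <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  ref <- Biostrings::DNAStringSet(c(Chr01 = genome))
  locus <- tibble::tibble(chrom = "Chr01", pos = 300L,
                          ref_allele = substr(genome, 300, 307))
  tm <- extract_design_template(locus, ref, flank = 250)
  expect_equal(nchar(tm$template), 250 + 8 + 250)
  expect_equal(tm$indel_start, 251)
  expect_equal(substr(tm$template, 251, 258), locus$ref_allele)
  locus_edge <- tibble::tibble(chrom = "Chr01", pos = 100L,
                               ref_allele = substr(genome, 100, 100))
  expect_error(extract_design_template(locus_edge, ref, flank = 250),
               "insufficient flank")
})

test_that("primer pair search equals an exhaustive independent scan", {
  set.seed(31)
  genome <- paste(sample(c("A", "C", "G", "T"), 620, TRUE,
                         prob = c(0.27, 0.23, 0.23, 0.27)), collapse = "")
  ref_allele <- substr(genome, 251, 260)  # 10 bp deletion footprint
  cfg <- primer_config()
  got <- design_primer_pair(genome, indel_start = 251, ref_len = 10,
                            alt_len = 1, config = cfg)
  expect_false(is.null(got))
  # every individual constraint re-validates (idempotent check)
  for (p in c(got$forward_seq, got$reverse_seq)) {
    expect_gte(nchar(p), 21); expect_lte(nchar(p), 30)
    expect_gte(gc_content(p), 40); expect_lte(gc_content(p), 70)
    expect_gte(melting_temp(p), 57); expect_lte(melting_temp(p), 62)
    expect_true(dimer_hairpin_check(p, config = cfg)$pass)
  }
  expect_true(dimer_hairpin_check(got$forward_seq, got$reverse_seq, cfg)$pass)
  expect_gte(got$product_size_ref, 70)
  expect_lte(got$product_size_ref, 150)
  # amplicon arithmetic: alt product differs by the allele length change
  expect_equal(got$product_size_alt - got$product_size_ref, 1 - 10)
  # independent exhaustive scan with direct constraint evaluation
  qualify <- function(s) {
    gc_content(s) >= 40 && gc_content(s) <= 70 &&
      melting_temp(s) >= 57 && melting_temp(s) <= 62 &&
      dimer_hairpin_check(s, config = cfg)$pass
  }
  fwd <- list()
  for (fs in seq_len(230)) for (fl in 21:30) {
    fe <- fs + fl - 1
    if (fe >= 251) next
    f <- substr(genome, fs, fe)
    if (qualify(f)) fwd[[length(fwd) + 1]] <- list(seq = f, fs = fs)
  }
  revs <- list()
  for (re in 281:410) for (rl in 21:30) {
    rs <- re - rl + 1
    if (rs <= 260 || re > 620) next
    r <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(genome, rs, re))))
    if (qualify(r)) revs[[length(revs) + 1]] <- list(seq = r, re = re)
  }
  best <- NULL
  for (f in fwd) for (r in revs) {
    prod <- r$re - f$fs + 1
    if (prod < 70 || prod > 150) next
    if (!dimer_hairpin_check(f$seq, r$seq, cfg)$pass) next
    cand <- list(f = f$seq, r = r$seq,
                 dtm = abs(melting_temp(f$seq) - melting_temp(r$seq)),
                 prod = prod, fs = f$fs)
    if (is.null(best) ||
        cand$dtm < best$dtm - 1e-12 ||
        (abs(cand$dtm - best$dtm) < 1e-12 && cand$prod < best$prod) ||
        (abs(cand$dtm - best$dtm) < 1e-12 && cand$prod == best$prod &&
           cand$fs < best$fs)) {
      best <- cand
    }
  }
  expect_equal(got$forward_seq, best$f)
  expect_equal(got$reverse_seq, best$r)
  # determinism: identical call returns the identical pair
  again <- design_primer_pair(genome, 251, 10, 1, cfg)
  expect_identical(got, again)
  # homopolymer template: GC constraint unsatisfiable, absence is a value
  expect_null(design_primer_pair(strrep("A", 620), 251, 10, 1, cfg))
})

test_that("marker names follow the chromosome-token position convention", {
  expect_equal(name_marker(1, 5460000), "T1M0546")
  expect_equal(name_marker(10, 6412345), "TaM0641")
  expect_equal(name_marker(12, 0), "TcM0000")
  expect_equal(name_marker(12, 9999), "TcM0000")
  expect_equal(name_marker(11, 7240000), "TbM0724")
  expect_error(name_marker(13, 1), "between 1 and 12")
  expect_error(name_marker(0, 1), "between 1 and 12")
})
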