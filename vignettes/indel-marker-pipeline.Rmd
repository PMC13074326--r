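---
title: "From InDel catalogue to DNA fingerprint: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From InDel catalogue to DNA fingerprint: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

indelfp implements a complete marker-development and germplasm-analysis
pipeline for insertion/deletion (InDel) polymorphisms of the kind scored on
silver-stained polyacrylamide gels: cataloguing variants from a VCF,
screening loci for marker suitability, designing PCR primers, summarising
marker informativeness (PIC), analysing accession diversity (distances,
UPGMA and neighbor-joining trees, PCA), inferring population structure with
a simplified admixture model, and condensing a panel's band codes into
digit-string DNA fingerprints. This vignette explains the models and the
choices behind them; the README shows a worked end-to-end example.

```{r setup}
library(indelfp)
```

## Band codes: the data model

All population-level computations start from a genotype table of *band
codes*, one row per accession, one column per marker. A band code records a
gel phenotype:

| code | meaning |
|------|---------|
| 0 | no band (missing data) |
| 1 | band matching the reference variety |
| 2 | InDel band (length shift relative to reference) |
| 3 | heterozygous double band |
| 4 | second InDel band, length-distinct from code 2 |

Codes are transcription of what a gel shows, not inferred genotypes. Where
a computation needs alleles, the package counts diploid copies: code 1 is
two reference alleles, 2 two alternate alleles, 4 two second-alternate
alleles, and 3 one reference plus one alternate; code 0 leaves the
denominator. A band-presence (haploid) counting mode exists for sensitivity
checks (`codes_to_allele_freqs(..., counting = "band")`). One ambiguity is
inherent: a gel cannot distinguish which two distinct alleles make up a
double band, so any heterozygote renders as code 3 and the diploid counting
of code 3 assumes the reference/alternate combination, by far the most
common in inbred panels.

## Variant cataloguing

`read_indel_vcf()` keeps every REF/ALT pair that changes length, splits
multi-allelic records, classifies by net length change (insertions have a
longer ALT), and skips SNPs and symbolic alleles with a reported count.
Coordinates are 1-based inclusive as in VCF; BED input is 0-based half-open
and converted once at read time (`read_bed()`). Complex substitutions
(both alleles > 1 bp, unequal lengths) are classified by their net length
change, because the downstream gel assay only sees a length shift.
Percentages in `summarize_indels()` are rounded half-up to two decimals to
match how such tables are conventionally printed.

## The marker screen

`screen_markers()` chains four stages in a fixed order; a locus failing a
stage is never re-examined, so each carries exactly one terminal
disposition:

1. **Basic filters** — quality ≥ 30 (Phred), InDel length ≥ 6 bp
   (inclusive thresholds), and no overlap between the variant's reference
   footprint `[pos, pos + len(REF) − 1]` and a repeat annotation. 6 bp is
   the smallest length difference reliably resolved on an 8%
   polyacrylamide gel; flanks are not repeat-tested, only the footprint.
2. **Flank single-copy check** — 200 bp flanks on both sides must consist
   of k-mers (k = 31) that each occur exactly once in the whole reference,
   counting both strands. Exact k-mer counting is a deliberate,
   reproducible proxy for "aligns to a single-copy region": it needs no
   external aligner, and it is conservative — a flank can be unique as a
   200-mer yet contain a duplicated 31-mer near a repeat boundary, in
   which case it fails. With k = 31 no k-mer is its own reverse
   complement, so "exactly one occurrence over both strands" is the right
   count for a unique locus. Loci closer than one flank length to a
   chromosome end fail, as do flanks with more than 10% non-ACGT bases.
3. **Spacing thinning** — within each chromosome a greedy left-to-right
   scan keeps a locus only if it lies ≥ 100 kb beyond the last kept one.
   Greedy leftmost-first is deterministic given sorted input; a
   maximum-cardinality selection would be as defensible but harder to
   reason about and was not chosen.
4. **Genic balance** — loci are classed genic when their footprint
   overlaps any gene interval (exons and introns are not distinguished).
   The default mode keeps the observed genic/intergenic mix; a fixed-ratio
   mode retains `round(n·r)` genic loci by descending quality with
   position as tie-break, for panels that must control functional
   composition. Both interpretations are exposed because "retained in
   proportion" admits either reading.

Wet-lab validation (amplification quality, band clarity) cannot be
computed; `screen_markers(validation = ...)` merges an externally supplied
pass/fail list by marker name instead.

## Primer design

For each surviving locus, a design template of 250 bp flank + reference
allele + 250 bp flank is scanned exhaustively: all primer windows of
21–30 bp, GC 40–70%, melting temperature 57–62 °C, forward entirely
upstream and reverse entirely downstream of the InDel, reference-allele
product within 70–150 bp. Melting temperatures use the unified
nearest-neighbor thermodynamic parameters with duplex-initiation terms,
the entropy salt correction `0.368 (N−1) ln[Na+]` at 50 mM monovalent
salt, and total strand concentration 250 nM under the CT/4 convention; the
Wallace `2(A+T) + 4(G+C)` rule is available as a fast cross-check
(`melting_temp()`).

Pairs are rejected when a perfect reverse-complement run of ≥ 6 bp exists
between the primers (or within one), when the 3′-terminal 5 bases of
either primer complement any window of the other (3′ extensibility is what
makes primer dimers amplify), or when either primer can fold into a
hairpin with a perfect stem ≥ 5 bp around a loop of ≥ 3 nt. These
thresholds are conventional mid-stringency values; no published values
existed to adopt. Among qualifying pairs the one minimising |Tm_f − Tm_r|
wins, ties broken by smaller product then leftmost forward start — a
ranking chosen for determinism; a thermodynamic penalty model would be
heavier without changing which loci are designable. Absence of a
qualifying pair is a value (`NULL`), not an error: such loci are excluded,
mirroring practice.

Marker names are "chromosome token + position token": chromosomes 1–9 map
to `T1`–`T9`, chromosomes 10–12 to `Ta`/`Tb`/`Tc`, and the position token
is `M` + `floor(pos / 10 kb)` zero-padded to four digits. The position
unit is a convention adopted here (it reproduces the shape of names like
`TaM0641` at chromosome scale) and is isolated in `name_marker()`.

## Marker informativeness

`pic()` implements the Botstein polymorphism information content,

$$\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2\, p_i^2 p_j^2,$$

from allele frequencies; it is 0 for monomorphic markers, at most the
expected heterozygosity, and maximal (0.375) for a balanced biallelic
marker. Per-marker PIC is printed at 3 decimals and aggregates at 4,
matching the precision such tables are reported at.

## Diversity analysis

The default genetic distance is simple matching on band codes — `1 −
matches/comparable`, missing cells removed pairwise — which is the natural
dissimilarity for codominant gel phenotypes and needs no evolutionary
model. UPGMA trees come from average-linkage agglomeration (ultrametric by
construction, branch lengths half the merge heights); neighbor joining
uses the Saitou–Nei Q-criterion and then clamps any negative branch to
zero, transferring the magnitude to its sibling so tip-to-tip path lengths
through the parent are preserved. PCA maps codes to alternate-allele
dosage (0/1/2; the rare second InDel allele collapses to dosage 2),
imputes missing cells with the marker mean, and eigendecomposes the
centred covariance; component signs are fixed by making each component's
largest-magnitude loading positive so coordinates are reproducible.

## Population structure and choosing K

`fit_admixture_em()` estimates the admixture model — accession *i* draws
each allele copy at marker *j* from ancestral cluster *k* with probability
*q<sub>ik</sub>*, the copy being the alternate allele with probability
*p<sub>kj</sub>*, so dosage is Binomial(2, [QP]<sub>ij</sub>) — by
expectation-maximisation from a seeded random start. This is a deliberate
substitution of maximum likelihood for the Bayesian MCMC of the classical
structure programs: it is deterministic per seed, runs in milliseconds at
panel scale, and yields the same two model-selection statistics. The EM
log-likelihood sequence is non-decreasing (a property the tests assert);
membership rows remain on the simplex after every step; allele frequencies
are clamped to [10⁻⁹, 1 − 10⁻⁹] inside the likelihood for numerical
safety. K = 1 is closed-form.

Two selectors are reported side by side, as both appear in practice:

* **Cross-validation error** (`cv_error()`): mask a random fold of
  observed genotype cells, refit, and score the mean squared difference
  between predicted dosage expectation 2·QP and the held-out dosage;
  5 folds by default. The minimising K is the selected model.
* **Evanno ΔK** (`evanno_delta_k()`): the mean absolute second difference
  of replicate log-likelihoods across K, normalised by the replicate
  standard deviation at K.

The ΔK statistic assumes between-run scatter of the likelihood estimate.
An EM fitter run to convergence has essentially none at small K — all
random starts find the same optimum and the replicate standard deviation
collapses to the stopping tolerance — so the raw ratio explodes at the
first K with any curvature. `evanno_delta_k()` therefore takes an
`sd_floor` (default 0, the classical statistic); `selection_table()` uses
a floor of one log-likelihood unit, below which replicates are treated as
numerically identical and the statistic falls back to the raw curvature
|L″(K)|. On seeded F-model simulations (FST 0.3, 60 accessions × 60
markers, 10 seeds per condition) the CV minimum recovers the planted K in
every seed at K_true ∈ {2, 3, 4}; the floored ΔK maximum does so in a
clear majority at K_true 2 and 3 but in under half the seeds at K_true 4,
reflecting the statistic's known bias toward the strongest hierarchical
split. At the 52-accession panel scale, ΔK remains seed-sensitive even
with ten replicate runs per K, while the CV curve is stable — which is
why the CV minimum should be treated as the decisive selector, with ΔK as
corroboration.

## Fingerprinting

`select_core_markers()` builds the core panel: per chromosome, biallelic
markers ranked by PIC (names break ties), a minimum of two taken per
chromosome, then filled to the target size (24) by next-best PIC while
respecting a per-chromosome maximum of three. The panel order is fixed and
persisted: digit *i* of every fingerprint always corresponds to panel
marker *i*. `encode_fingerprints()` is pure transcription of band codes in
panel order — no recoding — so `decode_fingerprints()` inverts it exactly.
`check_uniqueness()` partitions accessions by identical strings and
reports duplicate groups; duplicates are never silently collapsed, because
a 24-digit panel can legitimately fail to separate closely related
accessions that a full marker set would distinguish. `fingerprint_hamming()`
counts differing digit positions.

## The synthetic-data generators

Real germplasm genotypes and gel images for such studies are typically not
deposited, so the package generates every input it consumes, with ground
truth retained for testing:

* `simulate_reference()` — random chromosomes at a set GC content (default
  0.36, a typical plant value), repeats realised as *exact duplicated
  substrings* (≥ 2 verbatim copies of each 400 bp unit, so the flank
  single-copy check genuinely fails inside them), and non-overlapping gene
  intervals covering a target fraction.
* `implant_indels()` — uniformly placed insertions/deletions with
  non-overlapping footprints, uniform lengths and qualities, VCF-consistent
  alleles, and a truth table carrying each locus's repeat/genic context so
  every screening criterion can be evaluated independently of the
  pipeline.
* `simulate_population()` — the Balding–Nichols F-model: per marker an
  ancestral frequency p ~ U(0.1, 0.9) and subpopulation frequencies
  Beta(p(1−F)/F, (1−p)(1−F)/F) at differentiation F; the F-model operates
  at exactly the marker-frequency level the pipeline sees, which is why it
  was preferred to a coalescent simulator. Accessions are split evenly
  across subpopulations and are inbred with probability 1 − `het_rate` at
  each marker (a single allele draw doubled), reflecting that germplasm
  panels are dominated by inbred lines.

Defaults mirror the study panel this pipeline addresses: 52 accessions, 63
markers, four subpopulations, FST 0.3 (a typical separation between
cultivated groups and wild relatives), `het_rate` 0.10,
`third_allele_rate` 0.05 and `missing_rate` 0.02 — the latter three chosen
once to match how sparse codes 3, 4 and 0 are in published fingerprint
tables of inbred tomato panels. What the generator does **not** emulate:
linkage between markers, genotyping error structure, null alleles,
realistic chromosome lengths or gene models, and gel-scoring ambiguity.
Passing recovery tests on these simulations therefore demonstrates
correctness of the algorithms under the stated model, not robustness to
every artefact of real gel data.

## Numerical conventions and degenerate inputs

* Printed percentages round half away from zero (`round_half_up()`);
  half-to-even would disagree with published tables in edge cases.
* Allele-frequency vectors must sum to 1 within 10⁻⁹ (`pic()` errors
  otherwise); all-missing markers get `NA` PIC with a warning.
* Accession pairs with no comparable marker get `NA` distance with a
  warning; trees refuse matrices with undefined entries.
* Agglomeration and the primer search break ties lexicographically
  (smallest index / leftmost position) for determinism; re-running any
  stage with identical inputs and seeds is byte-identical.
* All simulators restore the caller's RNG state.

## Problem sizes used in the test suite

The shipped tests run the screening oracle on 50–60 implanted InDels in
0.1–0.2 Mb genomes, the primer-search equivalence proof on one 620 bp
template against a full exhaustive scan, and the K-recovery study at 60
accessions × 60 markers over K ∈ 1..6 with 10 seeds — sizes chosen so the
whole suite completes in a few minutes while still exercising every code
path at meaningful scale.

## Known limitations

* The flank single-copy rule is stricter than aligner-based uniqueness;
  near repeat boundaries it rejects loci an aligner might accept.
* PIC from band codes inherits the code-3 ambiguity described above.
* The admixture model ignores linkage and treats the second InDel allele
  as the first (biallelic collapse) — adequate for unlinked, mostly
  biallelic panels, not for dense maps.
* ΔK with an sd floor is an adaptation; when comparing against runs of
  MCMC-based programs, use `sd_floor = 0` for the classical statistic.
* Primer checks are exact-complementarity heuristics, not free-energy
  calculations; they rank as Primer-style tools do but will not match a
  thermodynamic ensemble model on borderline structures.
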