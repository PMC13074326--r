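# Command-line workflow: a thin dispatcher over the module functions so
# the stages can be chained from a shell. The package functions remain the
# primary interface; see the vignette.

#' Read and validate a pipeline configuration file
#'
#' YAML with optional sections `screen` (arguments of [screen_config()]),
#' `primer` (arguments of [primer_config()]) and `seed`. Unknown sections
#' or keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML file, or `NULL` for all defaults.
#' @return list with `screen` (a `screen_config`), `primer` (a
#'   `primer_config`) and `seed`.
#' @export
pipeline_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  bad <- setdiff(names(raw), c("screen", "primer", "seed"))
  if (length(bad)) {
    abort(sprintf("Unknown config section(s): %s.", paste(bad, collapse = ", ")))
  }
  check_keys <- function(given, allowed, section) {
    bad <- setdiff(names(given), allowed)
    if (length(bad)) {
      abort(sprintf("Unknown key(s) in config section `%s`: %s.",
                    section, paste(bad, collapse = ", ")))
    }
    given
  }
  screen_args <- check_keys(raw$screen %||% list(),
                            names(formals(screen_config)), "screen")
  primer_args <- check_keys(raw$primer %||% list(),
                            names(formals(primer_config)), "primer")
  list(screen = do.call(screen_config, screen_args),
       primer = do.call(primer_config, primer_args),
       seed = raw$seed %||% 1L)
}

cli_usage <- function() {
  paste(
    "usage: indelfp <subcommand> [key=value ...]",
    "",
    "subcommands:",
    "  simulate     out=DIR [n_indels=60] [seed=1]       write a toy dataset",
    "  catalog      vcf=FILE out=FILE                     per-chromosome InDel summary",
    "  screen       vcf=FILE fasta=FILE out=FILE [repeats=BED] [genes=BED] [config=YAML]",
    "  design       vcf=FILE fasta=FILE out=FILE [config=YAML]  screen + primer design",
    "  stats        genotypes=TSV out=FILE                per-marker allele number and PIC",
    "  diversity    genotypes=TSV out=PREFIX              distance matrix, UPGMA + NJ newick, PCA",
    "  structure    genotypes=TSV out=PREFIX [kmax=6] [nrep=3] [seed=1]  admixture scan + selection",
    "  fingerprint  genotypes=TSV out=PREFIX [total=24]   core panel + fingerprints",
    sep = "\n")
}

parse_kv <- function(args) {
  if (!length(args)) return(list())
  kv <- strsplit(args, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) abort(sprintf("Arguments must be key=value; offending: %s",
                              paste(args[bad], collapse = " ")))
  setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, character(1), 1))
}

need <- function(opts, keys) {
  missing <- setdiff(keys, names(opts))
  if (length(missing)) {
    abort(sprintf("Missing required argument(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  for (k in intersect(names(opts), c("vcf", "fasta", "genotypes", "repeats",
                                     "genes", "config"))) {
    if (!file.exists(opts[[k]])) abort(sprintf("Input file not found: %s", opts[[k]]))
  }
  opts
}

#' Run the command-line workflow
#'
#' Dispatches `indelfp <subcommand> key=value ...`; see
#' `run_cli("help")` for the subcommand list. Intended to be called from
#' the `inst/scripts/indelfp` Rscript; returns instead of quitting so it
#' can be tested in-process.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly (0 on success).
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("help", "--help", "-h")) {
    cat(cli_usage(), "\n")
    return(invisible(if (length(args)) 0L else 1L))
  }
  sub <- args[1]
  known <- c("simulate", "catalog", "screen", "design", "stats", "diversity",
             "structure", "fingerprint")
  if (!sub %in% known) {
    message(sprintf("Unknown subcommand: %s\n%s", sub, cli_usage()))
    return(invisible(1L))
  }
  status <- tryCatch({
    opts <- parse_kv(args[-1])
    switch(sub,
      simulate = {
        need(opts, "out")
        make_fixtures(opts$out, n_indels = as.integer(opts$n_indels %||% 60),
                      seed = as.integer(opts$seed %||% 1))
        inform(sprintf("Toy dataset written under %s", opts$out))
      },
      catalog = {
        need(opts, c("vcf", "out"))
        v <- read_indel_vcf(opts$vcf)
        write_indel_summary(summarize_indels(v), opts$out)
        inform(sprintf("%d InDel(s) catalogued -> %s", nrow(v), opts$out))
      },
      screen = {
        need(opts, c("vcf", "fasta", "out"))
        cfg <- pipeline_config(opts$config)
        v <- read_indel_vcf(opts$vcf)
        cand <- screen_markers(
          v, reference = opts$fasta,
          repeat_intervals = if (!is.null(opts$repeats)) read_bed(opts$repeats),
          gene_intervals = if (!is.null(opts$genes)) read_bed(opts$genes),
          config = cfg$screen)
        write_candidates(cand, opts$out)
      },
      design = {
        need(opts, c("vcf", "fasta", "out"))
        cfg <- pipeline_config(opts$config)
        v <- read_indel_vcf(opts$vcf)
        cand <- screen_markers(v, reference = opts$fasta, config = cfg$screen)
        primers <- design_primers(cand, opts$fasta, cfg$primer)
        readr::write_tsv(primers, opts$out, progress = FALSE)
      },
      stats = {
        need(opts, c("genotypes", "out"))
        sm <- summarize_markers(read_genotypes(opts$genotypes))
        write_marker_summary(sm, opts$out)
        agg <- glance(sm)
        inform(sprintf("PIC mean %.4f, range %.3f-%.3f over %d markers",
                       agg$mean_pic, agg$min_pic, agg$max_pic, agg$n_markers))
      },
      diversity = {
        need(opts, c("genotypes", "out"))
        g <- read_genotypes(opts$genotypes)
        d <- genetic_distance(g)
        write_distance_matrix(d, paste0(opts$out, "_dist.tsv"))
        ape::write.tree(upgma_tree(d), paste0(opts$out, "_upgma.nwk"))
        ape::write.tree(nj_tree(d), paste0(opts$out, "_nj.nwk"))
        p <- pca_genotypes(g)
        readr::write_tsv(p$coordinates, paste0(opts$out, "_pca.tsv"),
                         progress = FALSE)
      },
      structure = {
        need(opts, c("genotypes", "out"))
        g <- read_genotypes(opts$genotypes)
        seed <- as.integer(opts$seed %||% 1)
        scan <- admixture_scan(g, K_range = seq_len(as.integer(opts$kmax %||% 6)),
                               n_rep = as.integer(opts$nrep %||% 3), seed = seed)
        tab <- selection_table(scan, g, seed = seed)
        readr::write_tsv(tab, paste0(opts$out, "_selection.tsv"),
                         progress = FALSE)
        best_k <- attr(tab, "k_cv") %||% attr(tab, "k_delta")
        best <- filter(scan, .data$K == best_k) |>
          slice(which.max(.data$loglik))
        write_q_matrix(best$fit[[1]], paste0(opts$out, "_Q.tsv"))
        inform(sprintf("Selected K = %d (CV error), delta-K peak at K = %d",
                       attr(tab, "k_cv") %||% NA_integer_,
                       attr(tab, "k_delta") %||% NA_integer_))
      },
      fingerprint = {
        need(opts, c("genotypes", "out"))
        g <- read_genotypes(opts$genotypes)
        sm <- summarize_markers(g)
        sm$chromosome <- substr(sm$marker, 1, 2)
        panel <- select_core_markers(sm, total = as.integer(opts$total %||% 24))
        readr::write_tsv(panel, paste0(opts$out, "_panel.tsv"), progress = FALSE)
        fps <- encode_fingerprints(g, panel)
        write_fingerprints(fps, paste0(opts$out, "_fingerprints.tsv"))
        dup <- check_uniqueness(fps)
        if (nrow(dup)) {
          inform(sprintf("%d duplicate fingerprint group(s) detected.", nrow(dup)))
        } else {
          inform("All fingerprints unique.")
        }
      }
    )
    0L
  }, error = function(e) {
    message("Error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
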