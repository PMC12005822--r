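# Deterministic synthetic-input generation: toy vectors and error-bearing
# sequencing reads with truth tables, so every analysis is testable without
# external data.

#' Build a minimal linearized vector around given tags
#'
#' Constructs plus-strand termini that encode the N-terminal tag in frame at
#' the end of the upstream terminus (preceded by a fixed ribosome-binding
#' pad) and the C-terminal tag, followed by a stop codon and pad, at the
#' start of the downstream terminus. With the default tags the termini
#' reproduce the MK / WPTHHHHHH arrangement used for protein-polymer
#' expression constructs.
#'
#' @param n_term_tag Peptide tag ending the upstream terminus (must start
#'   with M; default `"MK"`).
#' @param c_term_tag Peptide tag starting the downstream terminus (default
#'   `"WPTHHHHHH"`).
#' @return A [vector_spec()].
#' @export
make_toy_vector <- function(n_term_tag = "MK", c_term_tag = "WPTHHHHHH") {
  n_term_tag <- check_pep(n_term_tag)
  c_term_tag <- check_pep(c_term_tag)
  if (!startsWith(n_term_tag, "M"))
    stop("n_term_tag must start with M (the start codon)", call. = FALSE)
  up_pad <- "GTTTAACTTTAAGAAGGAGATATACAT"   # RBS-style pad
  down_pad <- "GATCCGGCTGCTAACAAAGCC"
  up <- paste0(up_pad, reverse_translate(n_term_tag))
  down <- paste0(reverse_translate(c_term_tag), "TAA", down_pad)
  vector_spec(up, down, n_term_tag = n_term_tag, c_term_tag = c_term_tag,
              cds_start = nchar(up_pad) + 1L)
}

#' Specification for a synthetic read set
#'
#' @param design A [library_design()] (the degenerate unit being read).
#' @param abundances Named numeric vector: planted variant -> relative
#'   abundance (normalized to sum 1). Names must be concrete expansions of
#'   the design. Alternatively an unnamed count `k` to plant `k` variants
#'   drawn uniformly from the library at Dirichlet-like random abundances.
#' @param n_reads Number of reads (default 50000).
#' @param n_units Repeats per gene (default 5).
#' @param sub_rate Per-base substitution error rate in \[0, 0.1\]
#'   (default 0.003).
#' @param indel_rate Per-base indel rate (default 0; substitutions dominate
#'   amplification error).
#' @param flanks List `f5`/`f3` of constant flanking sequences; defaults
#'   are primer-derived 18-mers.
#' @param seed Seed; the same spec yields byte-identical outputs.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(design, abundances = 20L, n_reads = 50000L,
                         n_units = 5L, sub_rate = 0.003,
                         indel_rate = 0, flanks = NULL, seed = 1L) {
  stopifnot(inherits(design, "library_design"),
            sub_rate >= 0, sub_rate <= 0.1,
            indel_rate >= 0, indel_rate <= 0.1,
            n_reads >= 1L, n_units >= 1L)
  if (is.null(flanks))
    flanks <- list(f5 = "TGTAGGTGTCCCAGGTGT", f3 = "ACCAGGAACACCAACACC")
  if (is.null(names(abundances))) {
    k <- as.integer(abundances)
    variants <- with_seed(seed, {
      lib <- expand_degenerate(design$unit$dna)
      v <- sample(lib, k)
      w <- stats::rgamma(k, shape = 1)   # Dirichlet(1) abundances
      stats::setNames(w / sum(w), v)
    })
    abundances <- variants
  } else {
    bad <- vapply(names(abundances), classify_unit, "",
                  design = design) != "mutant"
    if (any(bad))
      stop("planted variant(s) incompatible with the design: ",
           paste(substr(names(abundances)[bad], 1, 12), collapse = ", "),
           call. = FALSE)
    abundances <- abundances / sum(abundances)
  }
  structure(list(design = design, abundances = abundances,
                 n_reads = as.integer(n_reads),
                 n_units = as.integer(n_units),
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 flanks = flanks, seed = as.integer(seed)),
            class = "fixture_spec")
}

# vectorized per-base substitution: each base mutates to one of the three
# others with total probability rate
.add_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

# per-base indels: at each position, deletion or a 1-nt insertion with
# probability rate/2 each
.add_indels <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    u <- stats::runif(length(ch))
    out <- character(0)
    for (i in seq_along(ch)) {
      if (u[i] < rate / 2) next                       # deletion
      out <- c(out, ch[i])
      if (u[i] >= rate / 2 && u[i] < rate)            # insertion
        out <- c(out, sample(bases, 1L))
    }
    paste(out, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Generate synthetic reads of repeat-library genes
#'
#' Each read is `f5 + n_units x (planted variant) + f3` -- one variant per
#' molecule, repeated processively -- with independent per-base substitution
#' errors and a random strand. The truth table records the planted
#' abundances and per-read variants, sufficient to verify any downstream
#' statistic.
#'
#' @param spec A [fixture_spec()].
#' @param fastq Optional path; when given, reads are written as FASTQ
#'   (constant quality) and the truth table as TSV alongside
#'   (`<path>.truth.tsv`).
#' @return List with `reads` (named character vector), `truth` (data frame
#'   `read_id`, `variant`, `strand`) and `abundances` (the planted vector).
#' @export
make_reads <- function(spec, fastq = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    vars <- names(spec$abundances)
    planted <- sample(vars, spec$n_reads, replace = TRUE,
                      prob = spec$abundances)
    genes <- paste0(spec$flanks$f5,
                    vapply(planted, function(v)
                      strrep(v, spec$n_units), "", USE.NAMES = FALSE),
                    spec$flanks$f3)
    genes <- .add_substitutions(genes, spec$sub_rate)
    genes <- .add_indels(genes, spec$indel_rate)
    minus <- stats::runif(spec$n_reads) < 0.5
    reads <- genes
    reads[minus] <- .rc_vec(genes[minus])
    ids <- sprintf("read%06d", seq_len(spec$n_reads))
    names(reads) <- ids
    truth <- data.frame(read_id = ids, variant = planted,
                        strand = ifelse(minus, "-", "+"),
                        stringsAsFactors = FALSE)
    if (!is.null(fastq)) {
      con <- file(fastq, "w")
      qual <- vapply(nchar(reads), function(n)
        strrep("I", n), "", USE.NAMES = FALSE)
      writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), con)
      close(con)
      utils::write.table(truth, paste0(fastq, ".truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    list(reads = reads, truth = truth, abundances = spec$abundances)
  })
}
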