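# -- IUPAC nucleotide algebra ------------------------------------------------

#' IUPAC ambiguity sets
#'
#' Named list mapping each of the 15 IUPAC nucleotide codes to the sorted
#' character vector of concrete bases it stands for. `N` covers all four
#' bases, `D` is \{A,G,T\}, `Y` is \{C,T\}, `W` is \{A,T\}, and so on; the
#' four concrete bases map to themselves.
#'
#' @format Named list of character vectors.
#' @export
IUPAC_SETS <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  m <- m[names(m) != "U" & nchar(names(m)) == 1L]
  sets <- lapply(strsplit(unname(m), ""), sort)
  names(sets) <- names(m)
  sets
})

#' Validate a DNA sequence
#'
#' @param x Character scalar.
#' @param degenerate Allow IUPAC ambiguity codes beyond A/C/G/T?
#' @param what Label used in error messages.
#' @return The validated, upper-cased sequence (invisibly usable).
#' @export
check_dna <- function(x, degenerate = FALSE, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a single nonempty character string", call. = FALSE)
  x <- toupper(x)
  alphabet <- if (degenerate) names(IUPAC_SETS) else c("A", "C", "G", "T")
  bad <- setdiff(unique(strsplit(x, "")[[1]]), alphabet)
  if (length(bad))
    stop(what, " contains invalid characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  x
}

#' Validate a peptide sequence
#'
#' @param x Character scalar over the 20 one-letter amino-acid codes
#'   (`*` permitted only when `allow_stop = TRUE`).
#' @param allow_stop Permit the stop symbol `*`?
#' @return The validated, upper-cased sequence.
#' @export
check_pep <- function(x, allow_stop = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop("peptide must be a single nonempty character string", call. = FALSE)
  x <- toupper(x)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (allow_stop) aa <- c(aa, "*")
  bad <- setdiff(unique(strsplit(x, "")[[1]]), aa)
  if (length(bad))
    stop("peptide contains invalid characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  x
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick reverse complement; IUPAC ambiguity codes are complemented
#' to their partner codes (e.g. `R` <-> `Y`, `D` <-> `H`, `N` -> `N`).
#'
#' @param seq DNA string (may carry IUPAC codes).
#' @return Reverse-complemented string.
#' @examples
#' revcomp("AAAC")      # "GTTT"
#' revcomp("ACGT")      # self reverse-complementary
#' @export
revcomp <- function(seq) {
  seq <- check_dna(seq, degenerate = TRUE)
  fr <- "ACGTRYSWKMBDHVN"
  to <- "TGCAYRSWMKVHDBN"
  paste(rev(strsplit(chartr(fr, to, seq), "")[[1]]), collapse = "")
}

#' Translate DNA to peptide
#'
#' Standard genetic code, complete codons only. A stop codon is rendered as
#' `*` and raises a warning; trailing bases short of a codon are dropped.
#'
#' @param seq DNA string over A/C/G/T.
#' @param frame 0-based frame offset (0, 1 or 2).
#' @return Peptide string (possibly containing `*`).
#' @examples
#' translate_dna("GTTGGTGTTCCAGGT")  # "VGVPG"
#' @export
translate_dna <- function(seq, frame = 0L) {
  seq <- check_dna(seq)
  stopifnot(frame %in% 0:2)
  seq <- substr(seq, frame + 1L, nchar(seq))
  n_codon <- nchar(seq) %/% 3L
  if (n_codon < 1L) stop("no complete codon to translate", call. = FALSE)
  starts <- 3L * seq_len(n_codon) - 2L
  codons <- substring(seq, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  pep <- paste(aa, collapse = "")
  if (grepl("*", pep, fixed = TRUE))
    warning("translation contains a stop codon", call. = FALSE)
  pep
}

#' Per-position degeneracy of an IUPAC sequence
#'
#' @param dseq IUPAC DNA string.
#' @return Integer vector, one entry per position (N = 4, D = 3, Y = W = 2,
#'   concrete base = 1).
#' @export
site_degeneracies <- function(dseq) {
  dseq <- check_dna(dseq, degenerate = TRUE)
  vapply(strsplit(dseq, "")[[1]], function(b) length(IUPAC_SETS[[b]]), 1L,
         USE.NAMES = FALSE)
}

#' Expand a degenerate (mixed-base) sequence
#'
#' Enumerates every concrete sequence compatible with an IUPAC string, in
#' lexicographic order. The expansion count is the product of per-position
#' degeneracies and is refused above `cap`.
#'
#' @param dseq IUPAC DNA string.
#' @param cap Maximum number of expansions (default 1e6).
#' @return Character vector of concrete sequences, lexicographically sorted,
#'   duplicate-free.
#' @examples
#' expand_degenerate("NDT")   # the 12 NDT codons
#' @export
expand_degenerate <- function(dseq, cap = 1e6) {
  dseq <- check_dna(dseq, degenerate = TRUE)
  deg <- site_degeneracies(dseq)
  count <- prod(deg)
  if (count > cap)
    stop("expansion count ", format(count, scientific = FALSE),
         " exceeds cap ", format(cap, scientific = FALSE), call. = FALSE)
  sets <- IUPAC_SETS[strsplit(dseq, "")[[1]]]
  # expand.grid with the last factor varying slowest gives lexicographic
  # order when we vary the FIRST position slowest instead: build reversed.
  grid <- expand.grid(rev(sets), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  out <- do.call(paste0, rev(grid))
  sort(out)
}

# -- Protein physicochemistry ------------------------------------------------

#' Default pKa table (EMBOSS values)
#'
#' Side-chain and terminal pKa values used for Henderson-Hasselbalch net
#' charge. Entries: D, E, C, Y (acidic side chains), H, K, R (basic side
#' chains), `Nterm` and `Cterm`.
#'
#' @return Named numeric vector.
#' @export
default_pka <- function() {
  c(C = 8.5, D = 3.9, E = 4.1, Y = 10.1,
    H = 6.5, K = 10.8, R = 12.5,
    Nterm = 8.6, Cterm = 3.6)
}

.check_pka <- function(pka) {
  need <- c("D", "E", "C", "Y", "H", "K", "R", "Nterm", "Cterm")
  if (!is.numeric(pka) || !all(need %in% names(pka)))
    stop("pKa table must be a named numeric vector with entries ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(pka <= 0 | pka >= 14))
    stop("pKa values must lie in (0, 14)", call. = FALSE)
  pka
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over ionizable groups: each basic group (H, K,
#' R, N-terminus) contributes `+1 / (1 + 10^(pH - pKa))`, each acidic group
#' (D, E, C, Y, C-terminus) contributes `-1 / (1 + 10^(pKa - pH))`. Both
#' termini are always included.
#'
#' @param pep Peptide string.
#' @param pH pH in (0, 14).
#' @param pka Named pKa vector, see [default_pka()].
#' @return Net charge in elementary-charge units.
#' @examples
#' net_charge("VGVPG", 7.4)
#' @export
net_charge <- function(pep, pH = 7.4, pka = default_pka()) {
  pep <- check_pep(pep)
  stopifnot(is.numeric(pH), length(pH) == 1L, pH > 0, pH < 14)
  pka <- .check_pka(pka)
  res <- strsplit(pep, "")[[1]]
  basic_frac <- function(pk) 1 / (1 + 10^(pH - pk))
  acid_frac  <- function(pk) -1 / (1 + 10^(pk - pH))
  charge <- basic_frac(pka[["Nterm"]]) + acid_frac(pka[["Cterm"]])
  for (r in c("H", "K", "R"))
    charge <- charge + sum(res == r) * basic_frac(pka[[r]])
  for (r in c("D", "E", "C", "Y"))
    charge <- charge + sum(res == r) * acid_frac(pka[[r]])
  unname(charge)
}

#' Kyte-Doolittle hydropathy scale
#' @return Named numeric vector over the 20 amino acids.
#' @export
kyte_doolittle <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

#' Mean hydropathy (GRAVY) of a peptide
#'
#' Arithmetic mean of per-residue Kyte-Doolittle scores over the whole
#' sequence.
#'
#' @param pep Peptide string.
#' @return GRAVY value (Kyte-Doolittle units).
#' @examples
#' mean_hydropathy("VGVPG")  # 1.2
#' @export
mean_hydropathy <- function(pep) {
  pep <- check_pep(pep)
  mean(kyte_doolittle()[strsplit(pep, "")[[1]]])
}

#' GC fraction of a DNA sequence
#' @param seq DNA string.
#' @return Fraction in \[0, 1\].
#' @export
gc_fraction <- function(seq) {
  seq <- check_dna(seq)
  mean(strsplit(seq, "")[[1]] %in% c("G", "C"))
}

#' Simple GC-based melting-temperature estimate
#'
#' Wallace rule for short oligos (< 14 nt), otherwise the standard
#' `64.9 + 41 * (GC - 16.4/N)` length-corrected formula. A rough guide for
#' checking primer compatibility with the 60 degree isothermal reaction; no
#' nearest-neighbor thermodynamics.
#'
#' @param seq DNA string.
#' @return Estimated melting temperature in degrees Celsius.
#' @export
melting_temp <- function(seq) {
  seq <- check_dna(seq)
  n <- nchar(seq)
  gc <- sum(strsplit(seq, "")[[1]] %in% c("G", "C"))
  at <- n - gc
  if (n < 14) 2 * at + 4 * gc else 64.9 + 41 * (gc - 16.4) / n
}

# -- FASTA / FASTQ IO --------------------------------------------------------

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @param type `"dna"` or `"peptide"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "peptide")) {
  type <- match.arg(type)
  ss <- if (type == "dna") Biostrings::readDNAStringSet(path)
        else Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- names(ss)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @param type `"dna"` or `"peptide"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "peptide")) {
  type <- match.arg(type)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  ss <- if (type == "dna") Biostrings::DNAStringSet(seqs)
        else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# vectorized reverse complement over concrete ACGT sequences (fast path
# for read sets)
.rc_vec <- function(seqs) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
}

# run expr with a private RNG stream; caller's .Random.seed is untouched
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
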