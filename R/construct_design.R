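# Ring-template, primer and split-oligo design for SCRCA.
#
# Geometry used throughout: the linear (5'-phosphorylated) form of a ring is
# the plus strand of the repeat unit, written so that position 1 is a codon
# boundary. The junction closed by ligation lies between the last and first
# base of that linear form. The reverse primer anneals across the junction
# (and therefore doubles as the split oligo used to template cyclization);
# the forward primer anneals at the start of the plus strand. Both primers
# carry 5' overlap extensions that become the seamless-cloning homology with
# the linearized vector.

# most-frequent E. coli codon per amino acid
.ecoli_codons <- c(
  A = "GCG", R = "CGC", N = "AAC", D = "GAT", C = "TGC",
  Q = "CAG", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
  L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCG",
  S = "AGC", T = "ACC", W = "TGG", Y = "TAT", V = "GTG")

#' Reverse-translate a peptide to DNA
#'
#' Deterministic reverse translation under a one-codon-per-residue policy.
#' The default table uses the most frequent E. coli codon for each amino
#' acid; a user-supplied table takes precedence.
#'
#' @param pep Peptide string.
#' @param codon_table Named character vector residue -> codon; default the
#'   built-in E. coli-frequent table.
#' @return DNA string of length `3 * nchar(pep)` whose translation
#'   round-trips to `pep`, with attribute `gc` giving its GC fraction.
#' @examples
#' reverse_translate("VGVPG")
#' @export
reverse_translate <- function(pep, codon_table = NULL) {
  pep <- check_pep(pep)
  tab <- if (is.null(codon_table)) .ecoli_codons else codon_table
  res <- strsplit(pep, "")[[1]]
  unknown <- setdiff(res, names(tab))
  if (length(unknown))
    stop("no codon for residue(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (any(nchar(tab[res]) != 3L))
    stop("codon table entries must be 3 nt", call. = FALSE)
  dna <- paste(tab[res], collapse = "")
  structure(dna, gc = gc_fraction(dna))
}

#' Define a repeat unit
#'
#' A repeat unit couples a peptide monomer with its DNA encoding, optionally
#' carrying degenerate (mixed-base) codons at selected positions.
#'
#' @param peptide Peptide string (e.g. `"VGVPGVGVPG..."`).
#' @param dna Optional DNA (possibly IUPAC-degenerate) of length
#'   `3 * nchar(peptide)`; reverse-translated from `peptide` when omitted.
#' @param degenerate_positions Integer vector of 1-based codon indices whose
#'   codons in `dna` are degenerate; inferred from `dna` when omitted.
#' @param name Unit label.
#' @return Object of class `repeat_unit`.
#' @examples
#' elp <- repeat_unit(strrep("VGVPG", 6), name = "E")
#' @export
repeat_unit <- function(peptide, dna = NULL, degenerate_positions = NULL,
                        name = "unit") {
  peptide <- check_pep(peptide)
  if (is.null(dna)) dna <- as.character(reverse_translate(peptide))
  dna <- check_dna(dna, degenerate = TRUE, what = "unit dna")
  if (nchar(dna) != 3L * nchar(peptide))
    stop("dna length must be 3 x peptide length", call. = FALSE)
  deg <- site_degeneracies(dna)
  deg_codons <- which(vapply(seq_len(nchar(peptide)), function(i)
    any(deg[(3L * i - 2L):(3L * i)] > 1L), logical(1)))
  if (is.null(degenerate_positions)) degenerate_positions <- deg_codons
  if (!setequal(degenerate_positions, deg_codons))
    stop("degenerate_positions disagree with IUPAC codes in dna",
         call. = FALSE)
  # every expansion must match the peptide at non-degenerate codons
  fixed <- setdiff(seq_len(nchar(peptide)), deg_codons)
  if (length(fixed)) {
    starts <- 3L * fixed - 2L
    codons <- substring(dna, starts, starts + 2L)
    aa <- Biostrings::GENETIC_CODE[codons]
    want <- substring(peptide, fixed, fixed)
    if (any(aa != want))
      stop("dna does not encode peptide at fixed position(s): ",
           paste(fixed[aa != want], collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, peptide = peptide, dna = dna,
                 degenerate_positions = sort(degenerate_positions)),
            class = "repeat_unit")
}

#' @export
print.repeat_unit <- function(x, ...) {
  cat("Repeat unit '", x$name, "': ", nchar(x$peptide), " aa / ",
      nchar(x$dna), " nt", sep = "")
  if (length(x$degenerate_positions))
    cat("; degenerate codon(s) at ",
        paste(x$degenerate_positions, collapse = ", "), sep = "")
  cat("\n  peptide: ", x$peptide, "\n  dna:     ", x$dna, "\n", sep = "")
  invisible(x)
}

#' Declare a linearized expression vector
#'
#' @param upstream_end Plus-strand sequence of the vector's upstream
#'   terminus (ends immediately before the insert; must end at a codon
#'   boundary of the CDS).
#' @param downstream_end Plus-strand sequence of the downstream terminus
#'   (begins immediately after the insert).
#' @param n_term_tag,c_term_tag Peptide tags the termini encode around the
#'   insert (e.g. `"MK"` and `"WPTHHHHHH"`).
#' @param cds_start 1-based position of the CDS start codon within
#'   `upstream_end`.
#' @return Object of class `vector_spec`.
#' @seealso [make_toy_vector()]
#' @export
vector_spec <- function(upstream_end, downstream_end,
                        n_term_tag = "MK", c_term_tag = "WPTHHHHHH",
                        cds_start = NULL) {
  upstream_end <- check_dna(upstream_end, what = "upstream_end")
  downstream_end <- check_dna(downstream_end, what = "downstream_end")
  n_term_tag <- check_pep(n_term_tag)
  c_term_tag <- check_pep(c_term_tag)
  if (is.null(cds_start)) {
    ntag_dna_len <- 3L * nchar(n_term_tag)
    cds_start <- nchar(upstream_end) - ntag_dna_len + 1L
  }
  cds_up <- substr(upstream_end, cds_start, nchar(upstream_end))
  if (nchar(cds_up) %% 3L != 0L ||
      translate_dna(cds_up) != n_term_tag)
    stop("upstream_end does not end with an in-frame n_term_tag",
         call. = FALSE)
  ctag <- suppressWarnings(
    translate_dna(substr(downstream_end, 1L, 3L * nchar(c_term_tag))))
  if (ctag != c_term_tag)
    stop("downstream_end does not begin with c_term_tag", call. = FALSE)
  structure(list(upstream_end = upstream_end,
                 downstream_end = downstream_end,
                 n_term_tag = n_term_tag, c_term_tag = c_term_tag,
                 cds_start = cds_start),
            class = "vector_spec")
}

#' Design configuration for ring/primer construction
#'
#' @param overlap_len Length (nt) of the 5' overlap extensions that become
#'   the seamless-cloning homology; 12-25, default 15.
#' @param anneal_len Length (nt) of each primer's 3' annealing region;
#'   default 20.
#' @param min_half Minimum number of annealed nt on each side of the ring
#'   junction for the junction-spanning reverse primer; default 8.
#' @param vector Optional [vector_spec()] supplying the overlap sequences.
#' @return List of class `design_config`.
#' @export
design_config <- function(overlap_len = 15L, anneal_len = 20L,
                          min_half = 8L, vector = NULL) {
  stopifnot(overlap_len >= 12L, overlap_len <= 25L,
            anneal_len >= 2L * min_half, min_half >= 1L)
  structure(list(overlap_len = as.integer(overlap_len),
                 anneal_len = as.integer(anneal_len),
                 min_half = as.integer(min_half),
                 vector = vector),
            class = "design_config")
}

.tail_str <- function(x, n) substr(x, nchar(x) - n + 1L, nchar(x))
.head_str <- function(x, n) substr(x, 1L, n)

# overlap extensions implied by a vector spec (or placeholders without one)
.overlaps_for <- function(cfg) {
  ov <- cfg$overlap_len
  if (is.null(cfg$vector)) {
    list(fwd = strrep("A", ov), rev_plus = strrep("T", ov))
  } else {
    list(fwd = .tail_str(cfg$vector$upstream_end, ov),
         rev_plus = .head_str(cfg$vector$downstream_end, ov))
  }
}

#' Design a single-unit ssDNA ring with primers and split oligo
#'
#' Places the ligation junction so that the reverse primer anneals across it
#' with `anneal_len / 2` nt on each side (at least `min_half`), making the
#' reverse primer double as the split oligo for cyclization. The forward
#' primer anneals at the start of the plus strand. Both primers carry 5'
#' overlap extensions of `overlap_len` nt taken from the vector termini:
#' the forward extension equals the upstream terminus tail, the reverse
#' extension is the reverse complement of the downstream terminus head.
#'
#' @param unit A [repeat_unit()].
#' @param cfg A [design_config()].
#' @return Object of class `ring_design` with fields `ring_linear` (linear
#'   plus-strand form; junction after its last base), `ring_size`, `unit`,
#'   `fwd_primer`, `rev_primer`, `split_oligo` (= `rev_primer` here),
#'   `fwd_overlap`, `rev_overlap` (both 5' extensions as written in the
#'   primers), `junction_halves`, and the configuration.
#' @examples
#' d <- design_ring(repeat_unit(strrep("VGVPG", 6), name = "E"))
#' d$ring_size                      # 90
#' nchar(d$rev_primer)              # overlap_len + anneal_len
#' @export
design_ring <- function(unit, cfg = design_config()) {
  stopifnot(inherits(unit, "repeat_unit"), inherits(cfg, "design_config"))
  ring <- unit$dna
  s <- nchar(ring)
  half <- cfg$anneal_len %/% 2L
  if (s < cfg$anneal_len + cfg$min_half)
    stop("unit too short for anneal_len ", cfg$anneal_len, call. = FALSE)
  if (half < cfg$min_half)
    stop("anneal_len/2 below min_half", call. = FALSE)
  ovl <- .overlaps_for(cfg)
  # reverse primer spans the junction: suffix(half) + prefix(anneal-half)
  junction_window <- paste0(.tail_str(ring, half),
                            .head_str(ring, cfg$anneal_len - half))
  rev_anneal <- revcomp(junction_window)
  fwd_anneal <- .head_str(ring, cfg$anneal_len)
  if (grepl(ovl$fwd, ring, fixed = TRUE) && s >= cfg$overlap_len)
    warning("forward overlap extension occurs inside the ring; ",
            "homology may be ambiguous", call. = FALSE)
  rev_primer <- paste0(revcomp(ovl$rev_plus), rev_anneal)
  fwd_primer <- paste0(ovl$fwd, fwd_anneal)
  structure(list(
    ring_linear = ring, ring_size = s, unit = unit,
    fwd_primer = fwd_primer, rev_primer = rev_primer,
    split_oligo = rev_primer,
    fwd_overlap = ovl$fwd, rev_overlap = revcomp(ovl$rev_plus),
    junction_halves = c(upstream = half,
                        downstream = cfg$anneal_len - half),
    anneal_tm = c(fwd = melting_temp(gsub("[^ACGT]", "A", fwd_anneal)),
                  rev = melting_temp(gsub("[^ACGT]", "A", rev_anneal))),
    cfg = cfg), class = "ring_design")
}

#' @export
print.ring_design <- function(x, ...) {
  cat("SCRCA ring design (", x$unit$name, "): ring ", x$ring_size,
      " nt, primers ", nchar(x$fwd_primer), "/", nchar(x$rev_primer),
      " nt (", x$cfg$overlap_len, " nt overlap + ", x$cfg$anneal_len,
      " nt anneal)\n", sep = "")
  cat("  fwd primer: ", x$fwd_primer, "\n  rev primer: ", x$rev_primer,
      "  (also split oligo)\n", sep = "")
  if (!is.null(x$split_junction))
    cat("  inter-unit split oligo: ", x$split_junction, "\n", sep = "")
  invisible(x)
}

#' Design a large (multi-unit) ring
#'
#' One circular template concatenating several repeat units. A dedicated
#' split oligo spans the junction between the last and first unit of the
#' concatenation order given (reverse complement of suffix + prefix across
#' it), mirroring the split DNA used to cyclize two ssDNA oligos into one
#' ring; the reverse primer spans the other inter-unit junction.
#'
#' @param units List of two or more [repeat_unit()] objects.
#' @param cfg A [design_config()].
#' @param split_len Total length of the dedicated split oligo (default 24,
#'   half on each side of the junction).
#' @return A `ring_design` whose `unit` is the fused unit; `split_oligo` is
#'   the dedicated inter-unit oligo, distinct from `rev_primer`.
#' @examples
#' r <- repeat_unit(strrep("GRGDSPYS", 4), name = "R")
#' e <- repeat_unit(strrep("VGVPG", 6), name = "E")
#' design_large_ring(list(r, e))$ring_size   # 96 + 90
#' @export
design_large_ring <- function(units, cfg = design_config(),
                              split_len = 24L) {
  if (!is.list(units) || length(units) < 2L)
    stop("a large ring needs at least 2 units", call. = FALSE)
  stopifnot(all(vapply(units, inherits, logical(1), "repeat_unit")))
  fused <- repeat_unit(
    peptide = paste(vapply(units, `[[`, "", "peptide"), collapse = ""),
    dna = paste(vapply(units, `[[`, "", "dna"), collapse = ""),
    name = paste(vapply(units, `[[`, "", "name"), collapse = "+"))
  des <- design_ring(fused, cfg)
  # dedicated split oligo across the junction closed by ligation (between
  # the final and the first unit of the concatenation)
  half <- split_len %/% 2L
  ring <- fused$dna
  window <- paste0(.tail_str(ring, half),
                   .head_str(ring, split_len - half))
  des$split_junction <- revcomp(window)
  des$split_oligo <- des$split_junction
  des$component_units <- units
  des
}

#' Homology length between two primers at a designed junction
#'
#' Longest `L` such that the first `L` nt of one primer equal the reverse
#' complement of the first `L` nt of the other; this is the terminal
#' homology the two amplicons will share at their junction.
#'
#' @param primer_a,primer_b Primer sequences (5'->3').
#' @return Integer homology length (0 if the 5' termini are not
#'   complementary at all).
#' @examples
#' junction_homology("GACACCTACTGAGTAAGGTGAATCACCACGACC",
#'                   "TACTCAGTAGGTGTCCCAGGTGTCGG")   # 15
#' @export
junction_homology <- function(primer_a, primer_b) {
  primer_a <- check_dna(primer_a)
  primer_b <- check_dna(primer_b)
  lmax <- min(nchar(primer_a), nchar(primer_b))
  L <- 0L
  for (k in seq_len(lmax)) {
    if (.head_str(primer_a, k) == revcomp(.head_str(primer_b, k))) L <- k
  }
  L
}

#' Design primer pairs for simultaneous two-block cloning
#'
#' For a two-fragment (block-copolymer) assembly `vector-up | A | B |
#' vector-down`, the outer primers carry the vector overlaps while the two
#' inner primers share `overlap_len` of homology spanning the A/B boundary:
#' block A's reverse primer carries the reverse complement of block B
#' amplicon's 5' terminus as its extension.
#'
#' @param block_a,block_b `ring_design` objects for the upstream (A) and
#'   downstream (B) blocks.
#' @param vector A [vector_spec()].
#' @param overlap_len Junction homology length, >= 12 (default 15).
#' @param anneal_len Primer annealing length (default 20).
#' @return List with elements `a` and `b`, each a list `fwd`/`rev` of primer
#'   sequences, plus `junction` (the shared boundary 15-mer on the plus
#'   strand) and `junction_split` (nt taken from A's tail vs B's head).
#' @export
design_block_primers <- function(block_a, block_b, vector,
                                 overlap_len = 15L, anneal_len = 20L) {
  stopifnot(inherits(block_a, "ring_design"),
            inherits(block_b, "ring_design"),
            inherits(vector, "vector_spec"))
  if (overlap_len < 12L)
    stop("overlap_len must be >= 12", call. = FALSE)
  A <- block_a$ring_linear
  B <- block_b$ring_linear
  j1 <- overlap_len %/% 2L          # nt of A tail in the junction
  j2 <- overlap_len - j1            # nt of B head in the junction
  junction <- paste0(.tail_str(A, j1), .head_str(B, j2))
  a_fwd <- paste0(.tail_str(vector$upstream_end, overlap_len),
                  .head_str(A, anneal_len))
  # extension = revcomp of B amplicon's 5' terminus (the junction)
  a_rev <- revcomp(paste0(.tail_str(A, anneal_len), .head_str(B, j2)))
  b_fwd <- paste0(.tail_str(A, j1), .head_str(B, anneal_len))
  b_rev <- paste0(revcomp(.head_str(vector$downstream_end, overlap_len)),
                  revcomp(paste0(.tail_str(B, anneal_len %/% 2L),
                                 .head_str(B, anneal_len - anneal_len %/% 2L))))
  for (blk in list(c(junction, A), c(junction, B))) {
    hits <- gregexpr(blk[1], blk[2], fixed = TRUE)[[1]]
    if (length(hits[hits > 0]) > 1L)
      warning("junction overlap maps to multiple loci within a block",
              call. = FALSE)
  }
  if (junction_homology(a_rev, b_fwd) < overlap_len)
    stop("internal error: designed junction homology too short")
  list(a = list(fwd = a_fwd, rev = a_rev),
       b = list(fwd = b_fwd, rev = b_rev),
       junction = junction,
       junction_split = c(a_tail = j1, b_head = j2))
}

#' Derive a next-round library unit from a selected winner
#'
#' Fixes the winner's residues everywhere except at `new_positions`, whose
#' codons are replaced by `degen_codon` (e.g. `"YWY"`), producing the
#' template for the next directed-evolution round.
#'
#' @param winner A [repeat_unit()] (typically a concrete, non-degenerate
#'   selected mutant).
#' @param new_positions 1-based codon indices to randomize; must be disjoint
#'   from codons that are already degenerate.
#' @param degen_codon IUPAC codon (3 nt) to place at each new position.
#' @param name Name for the derived unit.
#' @return A [repeat_unit()] with degenerate codons at `new_positions`.
#' @export
design_next_round <- function(winner, new_positions, degen_codon = "YWY",
                              name = NULL) {
  stopifnot(inherits(winner, "repeat_unit"))
  degen_codon <- check_dna(degen_codon, degenerate = TRUE,
                           what = "degen_codon")
  if (nchar(degen_codon) != 3L)
    stop("degen_codon must be a single codon (3 nt)", call. = FALSE)
  new_positions <- as.integer(new_positions)
  if (length(new_positions) == 0L) return(winner)
  if (any(new_positions < 1L | new_positions > nchar(winner$peptide)))
    stop("new_positions out of range", call. = FALSE)
  if (length(intersect(new_positions, winner$degenerate_positions)))
    stop("new_positions overlap already-degenerate codons", call. = FALSE)
  dna <- strsplit(winner$dna, "")[[1]]
  for (i in new_positions)
    dna[(3L * i - 2L):(3L * i)] <- strsplit(degen_codon, "")[[1]]
  # peptide at randomized codons: keep the winner's residue as the label of
  # the backbone (degenerate codons are exempt from the encode check)
  repeat_unit(peptide = winner$peptide, dna = paste(dna, collapse = ""),
              degenerate_positions = sort(c(winner$degenerate_positions,
                                            new_positions)),
              name = if (is.null(name))
                paste0(winner$name, "-", length(new_positions), degen_codon)
              else name)
}

#' Serialize a ring design to JSON
#'
#' @param design A `ring_design`.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
design_to_json <- function(design, path = NULL) {
  stopifnot(inherits(design, "ring_design"))
  x <- list(unit = design$unit$name,
            ring_linear = design$ring_linear,
            ring_size = design$ring_size,
            junction_halves = as.list(design$junction_halves),
            fwd_primer = design$fwd_primer,
            rev_primer = design$rev_primer,
            split_oligo = design$split_oligo,
            fwd_overlap = design$fwd_overlap,
            rev_overlap = design$rev_overlap,
            overlap_len = design$cfg$overlap_len,
            anneal_len = design$cfg$anneal_len)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Write all oligos of a design to FASTA
#'
#' @param design A `ring_design`.
#' @param path Output FASTA.
#' @return `path`, invisibly.
#' @export
design_to_fasta <- function(design, path) {
  stopifnot(inherits(design, "ring_design"))
  seqs <- c(ring_linear = design$ring_linear,
            fwd_primer = design$fwd_primer,
            rev_primer = design$rev_primer,
            split_oligo = design$split_oligo)
  seqs <- gsub("[^ACGTRYSWKMBDHVN]", "N", seqs)
  write_fasta(seqs, path, type = "dna")
}
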