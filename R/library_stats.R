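# Degenerate repeat-unit library enumeration, theoretical diversity, and
# synthesis simulation with per-site base bias.

#' Define a degenerate repeat-unit library
#'
#' @param unit A [repeat_unit()] whose DNA carries IUPAC mixed-base codons.
#' @param name Library label.
#' @return Object of class `library_design` with
#'   `nucleotide_variant_count` (product of site degeneracies) and
#'   `aa_variant_count` (distinct peptide translations; `NA` above
#'   `aa_cap`).
#' @param aa_cap Expansion cap above which the amino-acid count is not
#'   enumerated (default 1e6).
#' @examples
#' e3ndt <- library_design(ndt_library_unit())
#' e3ndt$nucleotide_variant_count  # 1728
#' @export
library_design <- function(unit, name = unit$name, aa_cap = 1e6) {
  stopifnot(inherits(unit, "repeat_unit"))
  deg <- site_degeneracies(unit$dna)
  nt_count <- prod(deg)
  aa_count <- NA_integer_
  if (nt_count <= aa_cap) {
    aa_count <- length(unique(.translate_codon_combos(unit)))
  }
  structure(list(unit = unit, name = name,
                 nucleotide_variant_count = nt_count,
                 aa_variant_count = aa_count),
            class = "library_design")
}

# distinct peptides reachable at the degenerate codons (cross product over
# per-codon amino-acid sets; avoids expanding the full nucleotide space)
.translate_codon_combos <- function(unit) {
  pos <- unit$degenerate_positions
  if (!length(pos)) return(unit$peptide)
  aa_sets <- lapply(pos, function(i) {
    codon <- substr(unit$dna, 3L * i - 2L, 3L * i)
    unique(unname(Biostrings::GENETIC_CODE[expand_degenerate(codon)]))
  })
  grid <- expand.grid(aa_sets, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  base <- strsplit(unit$peptide, "")[[1]]
  apply(grid, 1L, function(row) {
    p <- base; p[pos] <- unlist(row); paste(p, collapse = "")
  })
}

#' @export
print.library_design <- function(x, ...) {
  cat("Degenerate library '", x$name, "': ",
      format(x$nucleotide_variant_count, big.mark = ","),
      " nucleotide variants", sep = "")
  if (!is.na(x$aa_variant_count))
    cat(" / ", x$aa_variant_count, " amino-acid variants", sep = "")
  cat("; degenerate codons at ",
      paste(x$unit$degenerate_positions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' The E-3NDT library unit
#'
#' The 30-residue elastin-like unit (VGVPG)x6 with the codons of the first
#' three guest V positions (codons 1, 6 and 11 of the unit, i.e. the first V
#' of repeats 1-3) replaced by NDT. NDT encodes one of 12 diverse amino
#' acids, so three sites give 12^3 = 1728 amino-acid combinations over
#' 12^3 nucleotide variants.
#'
#' @param guest_codons Codon indices to randomize (default `c(1, 6, 11)`).
#' @param degen_codon Mixed-base codon (default `"NDT"`).
#' @return A [repeat_unit()].
#' @export
ndt_library_unit <- function(guest_codons = c(1L, 6L, 11L),
                             degen_codon = "NDT") {
  e <- repeat_unit(strrep("VGVPG", 6L), name = "E")
  design_next_round(e, guest_codons, degen_codon,
                    name = paste0("E-", length(guest_codons), degen_codon))
}

#' Enumerate all variants of a degenerate library
#'
#' Complete, duplicate-free, lexicographic enumeration of the nucleotide
#' variants with their peptide translations.
#'
#' @param design A [library_design()].
#' @param cap Expansion cap (default 1e6).
#' @return Data frame with columns `dna` and `peptide`.
#' @export
enumerate_library <- function(design, cap = 1e6) {
  stopifnot(inherits(design, "library_design"))
  dna <- expand_degenerate(design$unit$dna, cap = cap)
  peptide <- vapply(dna, function(s)
    suppressWarnings(translate_dna(s)), "", USE.NAMES = FALSE)
  data.frame(dna = dna, peptide = peptide, stringsAsFactors = FALSE)
}

#' Ideal per-variant abundance
#'
#' The abundance every nucleotide variant would have in a perfectly uniform
#' library: `100 / nucleotide_variant_count` percent, reported to three
#' significant figures.
#'
#' @param design A [library_design()] (or a variant count).
#' @return Percentage.
#' @examples
#' ideal_abundance(1728)  # 0.0579 -> printed as 0.058
#' @export
ideal_abundance <- function(design) {
  k <- if (inherits(design, "library_design"))
    design$nucleotide_variant_count else design
  stopifnot(k >= 1)
  signif(100 / k, 3)
}

#' Simulate mixed-base oligo synthesis
#'
#' Draws `n_molecules` oligos with independent per-site base incorporation
#' (optionally biased) at the degenerate sites, then summarizes realized
#' variant abundances.
#'
#' @param design A [library_design()].
#' @param n_molecules Number of molecules (default 1e6).
#' @param base_bias Per-site bias as in [rca_params()]: a list of named
#'   probability vectors over each degenerate site's allowed bases; `NULL`
#'   for uniform incorporation.
#' @param seed Seed.
#' @return An `abundance_report`, see [diversity_report()]. Synthesis draws
#'   only legal bases, so every molecule is a mutant (error fraction 0).
#' @export
simulate_synthesis <- function(design, n_molecules = 1e6,
                               base_bias = NULL, seed = NULL) {
  stopifnot(inherits(design, "library_design"), n_molecules >= 1)
  variants <- with_seed(seed,
    .draw_variants(design$unit$dna, as.integer(n_molecules), base_bias))
  counts <- table(variants)
  tab <- data.frame(variant = names(counts),
                    count5 = as.integer(counts),
                    count3 = as.integer(counts),
                    stringsAsFactors = FALSE)
  .abundance_report(tab, design,
                    class_of = rep("mutant", nrow(tab)))
}

# shared summary: tab has variant/count5/count3; class_of in {mutant,error}
.abundance_report <- function(tab, design, class_of) {
  total <- sum(tab$count5 + tab$count3)
  if (total == 0) stop("empty counts", call. = FALSE)
  per_var <- tab$count5 + tab$count3
  is_mut <- class_of == "mutant"
  mutant_reads <- sum(per_var[is_mut])
  pct_all <- 100 * per_var / total
  # mutant-level stats use mutant reads as denominator
  pct_mut <- if (mutant_reads > 0) 100 * per_var / mutant_reads
             else rep(NA_real_, length(per_var))
  k <- design$nucleotide_variant_count
  observed_mut <- sum(is_mut)
  structure(list(
    per_variant = data.frame(
      variant = tab$variant, count5 = tab$count5, count3 = tab$count3,
      count = per_var, class = class_of,
      pct = ifelse(is_mut, pct_mut, NA_real_),
      pct_of_all = pct_all, stringsAsFactors = FALSE),
    n_reads = total,
    max_occupancy = if (observed_mut) max(pct_mut[is_mut]) else NA_real_,
    median_abundance = if (observed_mut) stats::median(pct_mut[is_mut])
                       else NA_real_,
    ideal_abundance = ideal_abundance(design),
    mutant_fraction = 100 * mutant_reads / total,
    error_fraction = 100 * (total - mutant_reads) / total,
    observed_variants = observed_mut,
    missing_variants = k - observed_mut,
    design = design), class = "abundance_report")
}

#' @export
print.abundance_report <- function(x, ...) {
  cat("Library abundance report (", x$design$name, ")\n", sep = "")
  cat(sprintf("  reads (both ends): %d; observed mutant variants: %d of %d (%d missing)\n",
              x$n_reads, x$observed_variants,
              x$design$nucleotide_variant_count, x$missing_variants))
  cat(sprintf("  mutant / error fraction: %.1f%% / %.1f%%\n",
              x$mutant_fraction, x$error_fraction))
  cat(sprintf("  max occupancy: %.3g%%; median abundance: %.3g%% (ideal %.3g%%)\n",
              x$max_occupancy, x$median_abundance, x$ideal_abundance))
  invisible(x)
}

#' Diversity statistics from a unit count table
#'
#' Computes the library's diversity summary from observed terminal-unit
#' counts: maximum occupancy and median abundance over observed mutant
#' variants (error reads excluded from these denominators), and
#' mutant/error fractions of all reads. Invariant to row order.
#'
#' @param counts A `unit_count_table` from [count_units()] (classified
#'   against `design`), or a data frame with columns `variant`, `count5`,
#'   `count3` and optionally `class`.
#' @param design The [library_design()].
#' @return An `abundance_report`.
#' @export
diversity_report <- function(counts, design) {
  stopifnot(inherits(design, "library_design"))
  tab <- as.data.frame(counts, stringsAsFactors = FALSE)
  if (!all(c("variant", "count5", "count3") %in% names(tab)))
    stop("counts needs columns variant, count5, count3", call. = FALSE)
  if (nrow(tab) == 0L) stop("empty counts", call. = FALSE)
  tab <- tab[order(tab$variant), , drop = FALSE]
  class_of <- if ("class" %in% names(tab)) tab$class
              else vapply(tab$variant, classify_unit, "", design = design)
  .abundance_report(tab, design, class_of)
}
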