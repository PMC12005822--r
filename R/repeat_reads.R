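# Sequencing-read analysis of repeat-library genes: flank anchoring within
# the reliable end windows, terminal-unit extraction, counting with a
# minimum-count filter, mutant/error classification, position frequency
# matrices and 5'/3' concordance.

#' Read-analysis configuration
#'
#' @param end_window Number of nt at each read end trusted for unit
#'   extraction (default 90; the middle of a repeat gene is unreliable and
#'   ignored).
#' @param max_mismatch Mismatches tolerated when locating a flank
#'   (default 1).
#' @param min_count Minimum per-variant count to keep (default 6).
#' @return List of class `reads_config`.
#' @export
reads_config <- function(end_window = 90L, max_mismatch = 1L,
                         min_count = 6L) {
  stopifnot(end_window >= 1L, max_mismatch >= 0L, min_count >= 1L)
  structure(list(end_window = as.integer(end_window),
                 max_mismatch = as.integer(max_mismatch),
                 min_count = as.integer(min_count)),
            class = "reads_config")
}

#' Read sequencing reads from FASTQ or FASTA
#'
#' @param path File path; format inferred from the extension (`.fastq`,
#'   `.fq` vs `.fasta`, `.fa`).
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

# first match position of `pattern` in each of `seqs` allowing mismatches,
# restricted to start positions within [1, max_start]; NA when absent
.find_flank <- function(seqs, pattern, max_mismatch, max_start) {
  hits <- Biostrings::vmatchPattern(
    pattern, Biostrings::DNAStringSet(seqs),
    max.mismatch = max_mismatch, with.indels = FALSE)
  vapply(Biostrings::startIndex(hits), function(st) {
    st <- st[st >= 1L & st <= max_start]
    if (length(st)) min(st) else NA_integer_
  }, 1L)
}

#' Extract terminal repeat units from reads
#'
#' Locates the 5' flank (primer-derived constant sequence upstream of the
#' first unit) on either strand with at most `max_mismatch` mismatches,
#' orients each read to the plus strand, and takes the unit-length window
#' immediately after the flank, provided the flank starts within the
#' trusted `end_window`. Symmetrically, the 3' flank anchors the last unit
#' at the other end. Unreadable sides yield `NA`; reads with no flank on
#' either strand are counted as unanchored.
#'
#' @param reads Character vector of read sequences (or a FASTQ/FASTA path).
#' @param design A [library_design()] (supplies the unit length).
#' @param flanks List with `f5` and `f3`: the constant sequences
#'   immediately flanking the repeat tract.
#' @param cfg A [reads_config()].
#' @return Data frame with columns `unit5`, `unit3` (NA when unreadable)
#'   and `strand`; attribute `n_unanchored`.
#' @export
extract_terminal_units <- function(reads, design, flanks,
                                   cfg = reads_config()) {
  stopifnot(inherits(design, "library_design"),
            all(c("f5", "f3") %in% names(flanks)))
  if (length(reads) == 1L && file.exists(reads)) reads <- read_reads(reads)
  reads <- toupper(reads)
  unit_len <- nchar(design$unit$dna)
  f5 <- check_dna(flanks$f5, what = "f5")
  f3 <- check_dna(flanks$f3, what = "f3")
  mm <- cfg$max_mismatch

  # orient: a read is plus if f5 matches it, minus if f5 matches its rc
  win5 <- cfg$end_window + nchar(f5)
  p_plus <- .find_flank(reads, f5, mm, win5)
  rc_reads <- .rc_vec(reads)
  p_minus <- .find_flank(rc_reads, f5, mm, win5)
  strand <- ifelse(!is.na(p_plus), "+", ifelse(!is.na(p_minus), "-", NA))
  oriented <- ifelse(strand == "-", rc_reads, reads)
  pos5 <- ifelse(strand == "-", p_minus, p_plus)

  n <- length(reads)
  unit5 <- rep(NA_character_, n)
  unit3 <- rep(NA_character_, n)
  anchored <- !is.na(strand)
  if (any(anchored)) {
    st <- pos5[anchored] + nchar(f5)
    u5 <- substr(oriented[anchored], st, st + unit_len - 1L)
    ok <- nchar(u5) == unit_len & !grepl("[^ACGT]", u5)
    unit5[anchored][ok] <- u5[ok]

    # 3' side: anchor on the rc'd oriented read so the window logic mirrors
    or_rc <- .rc_vec(oriented[anchored])
    f3rc <- revcomp(f3)
    win3 <- cfg$end_window + nchar(f3)
    pos3 <- .find_flank(or_rc, f3rc, mm, win3)
    st3 <- pos3 + nchar(f3)
    u3rc <- substr(or_rc, st3, st3 + unit_len - 1L)
    ok3 <- !is.na(pos3) & nchar(u3rc) == unit_len & !grepl("[^ACGT]", u3rc)
    unit3[anchored][ok3] <- .rc_vec(u3rc[ok3])
  }
  out <- data.frame(unit5 = unit5, unit3 = unit3, strand = strand,
                    stringsAsFactors = FALSE)
  attr(out, "n_unanchored") <- sum(!anchored)
  out
}

#' Tally terminal units into a count table
#'
#' Exact per-variant tallies at the 5' and 3' ends; variants whose counts
#' fall below `min_count` at both ends are dropped (sequences with low
#' counts lack reliability) and reported via the `dropped` attribute.
#'
#' @param units Data frame from [extract_terminal_units()] (columns `unit5`,
#'   `unit3`).
#' @param design Optional [library_design()]; when given, each variant is
#'   classified `mutant`/`error` and its peptide added.
#' @param min_count Minimum count (default 6).
#' @return Object of class `unit_count_table`: data frame `variant`,
#'   `count5`, `count3`, and (with a design) `class`, `peptide`.
#' @export
count_units <- function(units, design = NULL, min_count = 6L) {
  stopifnot(min_count >= 1L)
  u5 <- units$unit5[!is.na(units$unit5)]
  u3 <- units$unit3[!is.na(units$unit3)]
  all_var <- sort(unique(c(u5, u3)))
  if (!length(all_var)) stop("no units to count", call. = FALSE)
  c5 <- table(factor(u5, levels = all_var))
  c3 <- table(factor(u3, levels = all_var))
  tab <- data.frame(variant = all_var,
                    count5 = as.integer(c5), count3 = as.integer(c3),
                    stringsAsFactors = FALSE)
  low <- tab$count5 < min_count & tab$count3 < min_count
  dropped <- tab[low, , drop = FALSE]
  tab <- tab[!low, , drop = FALSE]
  if (!is.null(design)) {
    stopifnot(inherits(design, "library_design"))
    tab$class <- vapply(tab$variant, classify_unit, "", design = design)
    tab$peptide <- vapply(tab$variant, function(v)
      suppressWarnings(translate_dna(v)), "")
  }
  rownames(tab) <- NULL
  structure(tab, dropped = dropped, min_count = as.integer(min_count),
            class = c("unit_count_table", "data.frame"))
}

#' @export
print.unit_count_table <- function(x, ...) {
  cat("Unit count table: ", nrow(x), " variants (min count ",
      attr(x, "min_count"), "; ", nrow(attr(x, "dropped")),
      " dropped)\n", sep = "")
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Classify a unit sequence as mutant or error
#'
#' A unit is a `mutant` iff it matches the degenerate template at every
#' position: exact equality at fixed positions and membership of the IUPAC
#' set at degenerate positions. Anything else -- including length variants
#' -- is an `error`. Classification uses the sequence only, never its
#' count.
#'
#' @param u Unit DNA string.
#' @param design A [library_design()].
#' @return `"mutant"` or `"error"` (with attribute `reason` on errors).
#' @export
classify_unit <- function(u, design) {
  stopifnot(inherits(design, "library_design"))
  tmpl <- design$unit$dna
  if (!is.character(u) || length(u) != 1L || is.na(u))
    return(structure("error", reason = "not a sequence"))
  u <- toupper(u)
  if (nchar(u) != nchar(tmpl))
    return(structure("error", reason = "length mismatch"))
  ub <- strsplit(u, "")[[1]]
  tb <- strsplit(tmpl, "")[[1]]
  for (i in seq_along(tb)) {
    if (!ub[i] %in% IUPAC_SETS[[tb[i]]])
      return(structure("error",
                       reason = sprintf("position %d: %s not in %s",
                                        i, ub[i], tb[i])))
  }
  "mutant"
}

#' Concordance of 5' and 3' terminal-unit counts
#'
#' Pearson correlation between the per-variant counts observed at the two
#' read ends, over variants present at either end (absent = 0). High
#' concordance indicates that single nucleotide repeat units are repeated
#' processively through each gene.
#'
#' @param tab A `unit_count_table`.
#' @return Correlation in \[-1, 1\], or `NA` with a warning when either
#'   vector has zero variance.
#' @export
end_concordance <- function(tab) {
  if (nrow(tab) < 3L)
    stop("need at least 3 variants for a correlation", call. = FALSE)
  if (stats::sd(tab$count5) == 0 || stats::sd(tab$count3) == 0) {
    warning("degenerate variance; concordance undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(tab$count5, tab$count3)
}

#' Position frequency matrix of aligned sequences
#'
#' Column-normalized symbol frequencies of equal-length sequences
#' (nucleotide or amino-acid alphabet), the numeric backbone of a sequence
#' logo.
#'
#' @param seqs Character vector of equal-length sequences.
#' @param alphabet `"nt"` or `"aa"`.
#' @param design Optional [library_design()]; when given (nt alphabet),
#'   degenerate template positions are flagged in the `degenerate`
#'   attribute.
#' @param weights Optional per-sequence counts (default 1 each).
#' @return Matrix symbols x positions, each column summing to 1; class
#'   `position_frequency_matrix`.
#' @export
frequency_matrix <- function(seqs, alphabet = c("nt", "aa"),
                             design = NULL, weights = NULL) {
  alphabet <- match.arg(alphabet)
  stopifnot(length(seqs) >= 1L)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences must have uniform length", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(seqs))
  stopifnot(length(weights) == length(seqs), all(weights >= 0))
  symbols <- if (alphabet == "nt") c("A", "C", "G", "T")
             else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  L <- lens[1]
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  m <- vapply(seq_len(L), function(j) {
    col <- tapply(weights, factor(chars[, j], levels = symbols), sum)
    col[is.na(col)] <- 0
    col / sum(weights)
  }, numeric(length(symbols)))
  rownames(m) <- symbols
  colnames(m) <- seq_len(L)
  deg <- NULL
  if (!is.null(design) && alphabet == "nt") {
    ds <- site_degeneracies(design$unit$dna)
    if (length(ds) == L) deg <- which(ds > 1L)
  }
  structure(m, degenerate = deg, class = "position_frequency_matrix")
}

#' @export
print.position_frequency_matrix <- function(x, digits = 3, ...) {
  cat("Position frequency matrix (", nrow(x), " symbols x ", ncol(x),
      " positions)\n", sep = "")
  print(round(unclass(x), digits))
  deg <- attr(x, "degenerate")
  if (length(deg))
    cat("degenerate design positions: ", paste(deg, collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Write a unit count table to TSV
#' @param tab A `unit_count_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
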