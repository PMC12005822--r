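# In-silico overlap-directed (seamless) assembly of amplicons into the
# linearized vector, hybrid (block-copolymer) formation between
# incomplete-end amplicons, ORF/tag verification, and screening bookkeeping.

.fragment_seq <- function(frag) {
  if (is.character(frag)) return(check_dna(frag, what = "fragment"))
  if (is.list(frag) && !is.null(frag$sequence)) return(frag$sequence)
  stop("fragment must be a DNA string or a list with $sequence",
       call. = FALSE)
}

.fragment_meta <- function(frag) {
  if (is.list(frag))
    list(n_repeats = frag$n_repeats %||% NA_integer_,
         unit_variants = frag$unit_variants %||% list())
  else list(n_repeats = NA_integer_, unit_variants = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pick rows of an amplicon_pool into plain fragment lists
#' Extract fragments from an amplicon pool
#'
#' @param pool An `amplicon_pool`.
#' @param rows Row indices (default all).
#' @return List of fragments (each with `sequence`, `n_repeats`,
#'   `unit_variants`, `mult`) suitable for [infusion_assemble()].
#' @export
pool_fragments <- function(pool, rows = seq_len(nrow(pool))) {
  lapply(rows, function(i)
    list(sequence = amplicon_sequence(pool, i),
         n_repeats = pool$n_repeats[i],
         unit_variants = pool$unit_variants[[i]],
         mult = pool$mult[i]))
}

#' Seamless (overlap-directed) assembly of fragments into a vector
#'
#' Assembly succeeds only if a chain `vector-upstream -> fragment(s) ->
#' vector-downstream` exists in which every junction shares exact terminal
#' homology of `overlap_len` nt. Orientation is enforced by the homology: a
#' reverse-complemented fragment exposes non-matching termini and never
#' joins. With two fragments the order is forced by the designed junction
#' homology, so input order is irrelevant. At most two inserts are
#' supported.
#'
#' @param fragments A fragment, or list of 1-2 fragments (DNA strings or
#'   lists with `$sequence` and optional repeat metadata, e.g. from
#'   [pool_fragments()]).
#' @param vector A [vector_spec()].
#' @param overlap_len Homology length (default 15).
#' @return List of `recombinant` objects (empty, with attribute
#'   `diagnostics`, if no valid chain exists). Each recombinant has the
#'   assembled `cds` (vector upstream CDS + insert core + downstream),
#'   `insert`, `n_repeats`, `unit_variants` and frame/tag fields filled by
#'   [verify_orf()].
#' @export
infusion_assemble <- function(fragments, vector, overlap_len = 15L) {
  stopifnot(inherits(vector, "vector_spec"))
  if (!is.list(fragments) || !is.null(fragments$sequence))
    fragments <- list(fragments)
  if (length(fragments) < 1L || length(fragments) > 2L)
    stop("1 or 2 fragments supported", call. = FALSE)
  up_h <- .tail_str(vector$upstream_end, overlap_len)
  down_h <- .head_str(vector$downstream_end, overlap_len)
  seqs <- vapply(fragments, .fragment_seq, "")
  diagnostics <- character(0)

  heads <- vapply(seqs, .head_str, "", n = overlap_len)
  tails <- vapply(seqs, .tail_str, "", n = overlap_len)

  # find an ordering: first fragment's head matches vector upstream tail,
  # chained by terminal homology, last fragment's tail matches downstream
  orders <- if (length(seqs) == 1L) list(1L) else list(c(1L, 2L), c(2L, 1L))
  chain <- NULL
  for (ord in orders) {
    ok <- heads[ord[1]] == up_h
    if (!ok) diagnostics <- c(diagnostics, sprintf(
      "fragment %d 5' terminus does not match vector upstream homology",
      ord[1]))
    if (ok && length(ord) == 2L) {
      ok <- tails[ord[1]] == heads[ord[2]]
      if (!ok) diagnostics <- c(diagnostics, sprintf(
        "no junction homology between fragments %d and %d",
        ord[1], ord[2]))
    }
    if (ok) {
      ok <- tails[ord[length(ord)]] == down_h
      if (!ok) diagnostics <- c(diagnostics, sprintf(
        "fragment %d 3' terminus does not match vector downstream homology",
        ord[length(ord)]))
    }
    if (ok) { chain <- ord; break }
  }
  if (is.null(chain))
    return(structure(list(), diagnostics = unique(diagnostics)))

  # merge the chain on its shared homologies
  merged <- seqs[chain[1]]
  if (length(chain) == 2L)
    merged <- paste0(merged,
                     substr(seqs[chain[2]], overlap_len + 1L,
                            nchar(seqs[chain[2]])))
  # insert core: between the two vector homologies
  core <- substr(merged, overlap_len + 1L, nchar(merged) - overlap_len)
  metas <- lapply(fragments[chain], .fragment_meta)
  n_rep <- sum(vapply(metas, `[[`, 1L, "n_repeats"))
  uv <- do.call(c, lapply(metas, `[[`, "unit_variants"))
  rec <- structure(list(
    insert = core,
    cds = NULL,
    n_repeats = n_rep,
    unit_variants = uv,
    reading_frame_ok = NA,
    tags_found = NULL), class = "recombinant")
  list(verify_orf(rec, vector))
}

#' Verify reading frame and tags of a recombinant
#'
#' Translates the assembled CDS (vector upstream tag + insert core +
#' downstream terminus) and records whether the open reading frame is
#' intact: translation must start with the vector's N-terminal tag, contain
#' the C-terminal tag, and carry no internal stop before the tag.
#'
#' @param rec A `recombinant` (with `insert` set), or a bare DNA insert.
#' @param vector A [vector_spec()].
#' @return The updated `recombinant` with `reading_frame_ok`, `tags_found`,
#'   `peptide` and, on failure, `frame_problem` (reason and position).
#' @export
verify_orf <- function(rec, vector) {
  stopifnot(inherits(vector, "vector_spec"))
  if (is.character(rec))
    rec <- structure(list(insert = check_dna(rec), n_repeats = NA_integer_,
                          unit_variants = list(), reading_frame_ok = NA,
                          tags_found = NULL), class = "recombinant")
  up_cds <- substr(vector$upstream_end, vector$cds_start,
                   nchar(vector$upstream_end))
  cds <- paste0(up_cds, rec$insert, vector$downstream_end)
  rec$cds <- cds
  rec$reading_frame_ok <- FALSE
  rec$tags_found <- NULL
  if (nchar(cds) %% 3L != 0L &&
      (nchar(up_cds) + nchar(rec$insert)) %% 3L != 0L) {
    rec$frame_problem <- list(reason = "insert length shifts frame",
                              position = nchar(rec$insert))
    rec$peptide <- NA_character_
    return(rec)
  }
  pep <- suppressWarnings(
    translate_dna(substr(cds, 1L, nchar(cds) - nchar(cds) %% 3L)))
  rec$peptide <- pep
  ntag <- vector$n_term_tag
  ctag <- vector$c_term_tag
  ctag_at <- regexpr(ctag, pep, fixed = TRUE)
  stop_at <- regexpr("*", pep, fixed = TRUE)
  if (!startsWith(pep, ntag)) {
    rec$frame_problem <- list(reason = "N-terminal tag absent",
                              position = 1L)
  } else if (ctag_at < 0) {
    rec$frame_problem <- list(reason = "C-terminal tag absent",
                              position = NA_integer_)
  } else if (stop_at > 0 && stop_at < ctag_at + nchar(ctag)) {
    rec$frame_problem <- list(reason = "internal stop codon",
                              position = as.integer(stop_at))
  } else {
    rec$reading_frame_ok <- TRUE
    rec$tags_found <- c(n_term = ntag, c_term = ctag)
    rec$frame_problem <- NULL
  }
  rec
}

#' @export
print.recombinant <- function(x, ...) {
  cat("Recombinant: insert ", nchar(x$insert), " nt, ",
      if (is.na(x$n_repeats)) "?" else x$n_repeats, " repeat(s); frame ",
      if (isTRUE(x$reading_frame_ok)) "OK" else "BROKEN", "\n", sep = "")
  if (!is.null(x$frame_problem))
    cat("  problem: ", x$frame_problem$reason, "\n", sep = "")
  if (!is.null(x$tags_found))
    cat("  tags: ", x$tags_found[["n_term"]], " ... ",
        x$tags_found[["c_term"]], "\n", sep = "")
  invisible(x)
}

#' Anneal incomplete-end amplicons into block-copolymer hybrids
#'
#' Pairs one `ss3prime` molecule (3'-recessed partner exposing a plus-strand
#' tail) with one `ss5prime` molecule (exposing a minus-strand tail at the
#' gene's 5' end). A pair joins with probability `p_anneal` when their
#' single-stranded regions are complementary over at least `min_anneal` nt,
#' which for tandem repeats means the last `min_anneal` nt of the 3' parent's
#' terminal unit occur within the 5' parent's first unit (offset annealing).
#' The joined molecule is a single longer amplicon whose unit list
#' concatenates both parents' units -- a block-copolymer gene when the
#' parents carried different variants. Unpaired molecules pass through
#' unchanged; the nick is assumed repaired during the seamless-cloning
#' reaction, so the hybrid's ends are blunt.
#'
#' @param pool An `amplicon_pool`.
#' @param p_anneal Probability in \[0, 1\] that a compatible pair joins.
#' @param min_anneal Minimum complementary stretch (nt), default 15.
#' @param seed Seed for pairing order and join draws.
#' @return An `amplicon_pool` containing hybrids and pass-through
#'   molecules.
#' @export
form_hybrids <- function(pool, p_anneal = 0.5, min_anneal = 15L,
                         seed = NULL) {
  stopifnot(inherits(pool, "amplicon_pool"),
            p_anneal >= 0, p_anneal <= 1)
  design <- attr(pool, "design")
  if (p_anneal == 0 || nrow(pool) == 0L) return(pool)
  # expand classes to individual molecules
  idx <- rep(seq_len(nrow(pool)), pool$mult)
  mol <- data.frame(class = idx,
                    n = pool$n_repeats[idx],
                    variant = pool$unit_variant[idx],
                    end = pool$end_state[idx],
                    stringsAsFactors = FALSE)
  with_seed(seed, {
    i3 <- sample(which(mol$end == "ss3prime"))
    i5 <- sample(which(mol$end == "ss5prime"))
    k <- min(length(i3), length(i5))
    joined3 <- integer(0); joined5 <- integer(0)
    hybrids <- list()
    if (k > 0) for (j in seq_len(k)) {
      a <- i3[j]; b <- i5[j]
      tail_a <- .tail_str(mol$variant[a], min_anneal)
      compatible <- grepl(tail_a, mol$variant[b], fixed = TRUE)
      if (compatible && stats::runif(1) < p_anneal) {
        joined3 <- c(joined3, a); joined5 <- c(joined5, b)
        hybrids[[length(hybrids) + 1L]] <- list(
          n_repeats = mol$n[a] + mol$n[b],
          unit_variants = c(rep(mol$variant[a], mol$n[a]),
                            rep(mol$variant[b], mol$n[b])))
      }
    }
    keep <- setdiff(seq_len(nrow(mol)), c(joined3, joined5))
    rows <- c(
      lapply(keep, function(i) list(
        n_repeats = mol$n[i],
        unit_variants = rep(mol$variant[i], mol$n[i]),
        end_state = mol$end[i])),
      lapply(hybrids, function(h) c(h, list(end_state = "blunt"))))
    ot <- nchar(design$fwd_overlap) + nchar(design$rev_overlap)
    key <- vapply(rows, function(r)
      paste(r$end_state, paste(r$unit_variants, collapse = "|")), "")
    first <- !duplicated(key)
    mult <- as.integer(table(key)[key[first]])
    out <- data.frame(
      n_repeats = vapply(rows[first], `[[`, 1L, "n_repeats"),
      unit_variant = vapply(rows[first], function(r)
        r$unit_variants[1], ""),
      end_state = vapply(rows[first], `[[`, "", "end_state"),
      ss_len = 0L, mult = mult, stringsAsFactors = FALSE)
    out$ss_len <- ifelse(out$end_state == "blunt", 0L, design$ring_size)
    out$length <- out$n_repeats * design$ring_size + ot
    out$unit_variants <- lapply(rows[first], `[[`, "unit_variants")
    out <- out[order(out$n_repeats, out$unit_variant, out$end_state), ]
    rownames(out) <- NULL
    structure(out, design = design, params = attr(pool, "params"),
              class = c("amplicon_pool", "data.frame"))
  })
}

#' Screening tally (colony PCR and sequencing)
#'
#' @param pcr_pos,pcr_tests Colony-PCR positives and tests.
#' @param seq_pos,seq_tests Sanger-sequencing positives and tests.
#' @return Object of class `screening_tally`.
#' @export
screening_tally <- function(pcr_pos, pcr_tests, seq_pos, seq_tests) {
  v <- c(pcr_pos, pcr_tests, seq_pos, seq_tests)
  if (any(v < 0) || pcr_tests == 0 || seq_tests == 0)
    stop("tests must be positive and counts nonnegative", call. = FALSE)
  if (pcr_pos > pcr_tests || seq_pos > seq_tests)
    stop("positives cannot exceed tests", call. = FALSE)
  structure(list(colony_pcr = c(positives = pcr_pos, tests = pcr_tests),
                 sequencing = c(positives = seq_pos, tests = seq_tests)),
            class = "screening_tally")
}

#' Positivity rate of a gene synthesis screen
#'
#' `100 x (PCR positives / PCR tests) x (sequencing positives / sequencing
#' tests)` -- the product of the two pass fractions.
#'
#' @param tally A [screening_tally()].
#' @return Percentage.
#' @examples
#' positivity_rate(screening_tally(8, 10, 5, 8))  # 50
#' @export
positivity_rate <- function(tally) {
  stopifnot(inherits(tally, "screening_tally"))
  100 *
    (tally$colony_pcr[["positives"]] / tally$colony_pcr[["tests"]]) *
    (tally$sequencing[["positives"]] / tally$sequencing[["tests"]])
}

#' Colony-PCR amplicon length implied by a recombinant
#'
#' Length of the product the screening primer pair would amplify from the
#' construct: the assembled CDS plus the flanking distances to the primer
#' sites recorded in the vector (defaults approximate T7 promoter/terminator
#' positions).
#'
#' @param rec A verified `recombinant`.
#' @param flank5,flank3 Distance (nt) from each primer site to the CDS.
#' @return Length in bp.
#' @export
colony_pcr_length <- function(rec, flank5 = 100L, flank3 = 80L) {
  stopifnot(inherits(rec, "recombinant"), !is.null(rec$cds))
  nchar(rec$cds) + flank5 + flank3
}
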