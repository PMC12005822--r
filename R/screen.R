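# Mutant screening for directed evolution: pH-dependent net-charge shift,
# hydropathy, composition flags, block structure, and construct-level
# composition metrics.

#' Build mutant records from candidates
#'
#' Populates, for each candidate, the repeat-tract peptide, net charges at
#' the two screening pHs, their difference, GRAVY hydropathy, a cysteine
#' flag and a block-copolymer flag (two or more distinct unit variants).
#' Untranslatable candidates are skipped with a message.
#'
#' @param candidates Named list of candidates: `recombinant` objects, or
#'   lists with `peptide` (repeat-tract peptide) and optional
#'   `unit_variants`.
#' @param ph_pair The two pHs, default `c(7.4, 6.5)` (biological vs
#'   slightly acidic environment).
#' @param pka pKa table, see [default_pka()].
#' @return Data frame of class `mutant_records`: `id`, `charge_a`,
#'   `charge_b`, `delta_charge` (`charge_a - charge_b`), `gravy`,
#'   `has_cys`, `is_block`, `peptide`.
#' @export
build_records <- function(candidates, ph_pair = c(7.4, 6.5),
                          pka = default_pka()) {
  stopifnot(length(ph_pair) == 2L)
  if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
    names(candidates) <- sprintf("m%d", seq_along(candidates))
  rows <- lapply(names(candidates), function(id) {
    cand <- candidates[[id]]
    pep <- if (is.character(cand)) cand
           else if (!is.null(cand$peptide) && !is.na(cand$peptide))
             cand$peptide
           else NA_character_
    uv <- if (is.list(cand)) cand$unit_variants %||% list() else list()
    if (is.na(pep) || inherits(try(check_pep(pep), silent = TRUE),
                               "try-error")) {
      message("skipping untranslatable candidate ", id)
      return(NULL)
    }
    ca <- net_charge(pep, ph_pair[1], pka)
    cb <- net_charge(pep, ph_pair[2], pka)
    data.frame(id = id,
               charge_a = ca, charge_b = cb, delta_charge = ca - cb,
               gravy = mean_hydropathy(pep),
               has_cys = grepl("C", pep, fixed = TRUE),
               is_block = length(unique(unlist(uv))) >= 2L,
               peptide = pep, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  structure(out, ph_pair = ph_pair,
            class = c("mutant_records", "data.frame"))
}

#' Rank screening candidates
#'
#' Filters (optionally excluding cysteine-containing mutants, which risk
#' irreversible aggregation, and block copolymers, which complicate
#' next-round template design), then sorts descending by `|delta_charge|`
#' -- the pH-responsiveness proxy -- breaking ties by id for determinism.
#'
#' @param records A [build_records()] result.
#' @param exclude_cys Drop cysteine-containing records (default TRUE).
#' @param exclude_block Drop block-copolymer records (default TRUE).
#' @param top_k Keep at most this many (default all).
#' @param key Ranking key: function of the record data frame returning a
#'   numeric vector; default `abs(delta_charge)`.
#' @return Filtered, ordered `mutant_records` (possibly empty, with
#'   attribute `diagnostic`).
#' @export
rank_candidates <- function(records, exclude_cys = TRUE,
                            exclude_block = TRUE, top_k = Inf,
                            key = function(df) abs(df$delta_charge)) {
  stopifnot(inherits(records, "mutant_records"))
  df <- as.data.frame(records)
  if (nrow(df)) {
    if (exclude_cys) df <- df[!df$has_cys, , drop = FALSE]
    if (exclude_block) df <- df[!df$is_block, , drop = FALSE]
  }
  if (!nrow(df)) {
    out <- df
    attr(out, "diagnostic") <- "no candidates survive the filters"
  } else {
    kv <- key(df)
    out <- df[order(-kv, df$id), , drop = FALSE]
    if (is.finite(top_k)) out <- utils::head(out, top_k)
  }
  rownames(out) <- NULL
  structure(out, ph_pair = attr(records, "ph_pair"),
            class = c("mutant_records", "data.frame"))
}

#' @export
print.mutant_records <- function(x, ...) {
  ph <- attr(x, "ph_pair")
  cat("Mutant records (", nrow(x), " candidates",
      if (!is.null(ph)) sprintf("; pH %.1f vs %.1f", ph[1], ph[2]),
      ")\n", sep = "")
  if (nrow(x))
    print(utils::head(as.data.frame(
      x[, setdiff(names(x), "peptide")]), 15))
  d <- attr(x, "diagnostic")
  if (!is.null(d)) cat("  ", d, "\n", sep = "")
  invisible(x)
}

#' ELP fraction of a construct
#'
#' Percentage of repeat-tract residues contributed by ELP-class units:
#' `100 * ELP residues / total repeat residues`. Each distinct unit variant
#' must be assigned a class.
#'
#' @param construct A `recombinant` (its `unit_variants` are used) or a
#'   character vector of unit peptide/DNA sequences.
#' @param unit_classes Named character vector mapping each unit sequence to
#'   `"ELP"` or `"RLP"` (any non-ELP class counts as non-ELP).
#' @return Percentage in \[0, 100\].
#' @export
elp_fraction <- function(construct, unit_classes) {
  units <- if (inherits(construct, "recombinant"))
    unlist(construct$unit_variants) else construct
  if (!length(units)) stop("construct has no units", call. = FALSE)
  unknown <- setdiff(unique(units), names(unit_classes))
  if (length(unknown))
    stop("unclassified unit(s): ",
         paste(substr(unknown, 1, 12), collapse = ", "), call. = FALSE)
  lens <- nchar(units)
  elp <- unit_classes[units] == "ELP"
  100 * sum(lens[elp]) / sum(lens)
}

#' Export (gravy, net charge) pairs for a charge-hydropathy scatter
#'
#' @param records A [build_records()] result.
#' @param path Optional TSV path.
#' @return Data frame `id`, `gravy`, `charge_a`, `charge_b`, `is_block`.
#' @export
charge_hydropathy_table <- function(records, path = NULL) {
  stopifnot(inherits(records, "mutant_records"))
  out <- as.data.frame(records)[, c("id", "gravy", "charge_a",
                                    "charge_b", "is_block")]
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
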