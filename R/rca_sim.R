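# Theoretical amplicon ladder and stochastic simulation of the isothermal
# rolling-circle amplification product pool.
#
# An amplicon is modeled on its plus strand as
#   fwd_overlap + n x (concrete unit) + rev_overlap_plus
# where rev_overlap_plus is the reverse complement of the reverse primer's
# 5' extension, i.e. the head of the vector's downstream terminus. Predicted
# length is therefore n * ring_size + overlap_total.

#' Predict the theoretical amplicon ladder
#'
#' Each rung is one repeat number: `length(n) = n * ring_size +
#' overlap_total`, with `overlap_total` the summed lengths of the two primer
#' overlap extensions.
#'
#' @param design A `ring_design`.
#' @param n_max Largest repeat number (>= 1).
#' @return Object of class `scrca_ladder`: data frame with columns `n` and
#'   `length`, plus attributes `ring_size` and `overlap_total`.
#' @examples
#' d <- design_ring(repeat_unit(strrep("VGVPG", 6), name = "E"))
#' predict_ladder(d, 6)$length[6]   # 90 * 6 + 30 = 570
#' @export
predict_ladder <- function(design, n_max = 12L) {
  stopifnot(inherits(design, "ring_design"), n_max >= 1L)
  ot <- nchar(design$fwd_overlap) + nchar(design$rev_overlap)
  n <- seq_len(n_max)
  out <- data.frame(n = n, length = n * design$ring_size + ot)
  structure(out, ring_size = design$ring_size, overlap_total = ot,
            class = c("scrca_ladder", "data.frame"))
}

#' Assign observed band sizes to ladder repeat numbers
#'
#' Each observed band (bp estimate, e.g. from gel densitometry) is mapped to
#' the nearest ladder rung if the relative error is within `tol`, otherwise
#' left unassigned (`NA`).
#'
#' @param observed Numeric vector of bp estimates.
#' @param ladder A [predict_ladder()] result.
#' @param tol Relative tolerance in (0, 0.2], default 0.05.
#' @return Data frame with columns `observed`, `n` (NA when unassigned),
#'   `expected`, `rel_error`.
#' @export
assign_bands <- function(observed, ladder, tol = 0.05) {
  stopifnot(inherits(ladder, "scrca_ladder"),
            is.numeric(observed), tol > 0, tol <= 0.2)
  idx <- vapply(observed, function(b) which.min(abs(ladder$length - b)), 1L)
  expected <- ladder$length[idx]
  rel <- abs(observed - expected) / expected
  n <- ifelse(rel <= tol, ladder$n[idx], NA_integer_)
  data.frame(observed = observed, n = n,
             expected = ifelse(rel <= tol, expected, NA_real_),
             rel_error = rel)
}

#' Estimate ring size from band positions
#'
#' Linear regression of band length on repeat number; the slope estimates
#' the ring size and the intercept the total overlap contribution. With
#' exact theoretical lengths the fit is perfect by construction; with
#' measurement noise of a percent or so the slope still recovers the ring
#' size closely (band ladders are highly linear).
#'
#' @param n Repeat numbers.
#' @param lengths Band lengths (bp).
#' @return List with `ring_size`, `overlap_total` (intercept) and
#'   `r` (Pearson correlation of the fit).
#' @export
estimate_ring_size <- function(n, lengths) {
  stopifnot(length(n) == length(lengths), length(n) >= 3L)
  fit <- stats::lm(lengths ~ n)
  list(ring_size = unname(stats::coef(fit)[2]),
       overlap_total = unname(stats::coef(fit)[1]),
       r = stats::cor(n, lengths))
}

#' Simulation parameters for the amplification pool
#'
#' @param n_molecules Number of product molecules to draw.
#' @param repeat_dist Either a probability vector over repeat numbers
#'   `1..length(repeat_dist)`, or `NULL` for the default truncated geometric
#'   over `1..n_max` with success probability `geom_p`.
#' @param n_max Truncation for the default distribution (default 20).
#' @param geom_p Geometric decay parameter of the default distribution
#'   (default 0.25).
#' @param p_ss_end Probability that a molecule carries an incomplete
#'   (single-stranded) end; split evenly between 3'- and 5'-recessed ends.
#'   Default 0.2.
#' @param ss_len Length (nt) of the single-stranded region on incomplete
#'   ends; default one repeat-unit length (set at simulation time when
#'   `NULL`).
#' @param base_bias Optional per-site base bias for degenerate rings: a list
#'   (one element per degenerate site, in order of appearance of degenerate
#'   bases in the ring) of named probability vectors over that site's
#'   allowed bases. `NULL` means uniform.
#' @return List of class `rca_params`.
#' @export
rca_params <- function(n_molecules = 1000L, repeat_dist = NULL,
                       n_max = 20L, geom_p = 0.25, p_ss_end = 0.2,
                       ss_len = NULL, base_bias = NULL) {
  stopifnot(n_molecules >= 1L, p_ss_end >= 0, p_ss_end <= 1)
  if (is.null(repeat_dist)) {
    repeat_dist <- stats::dgeom(0:(n_max - 1L), prob = geom_p)
    repeat_dist <- repeat_dist / sum(repeat_dist)
  }
  if (any(repeat_dist < 0) || abs(sum(repeat_dist) - 1) > 1e-8)
    stop("repeat_dist must be a probability distribution over n >= 1",
         call. = FALSE)
  structure(list(n_molecules = as.integer(n_molecules),
                 repeat_dist = repeat_dist, p_ss_end = p_ss_end,
                 ss_len = ss_len, base_bias = base_bias),
            class = "rca_params")
}

# draw n_mol concrete expansions of a degenerate sequence, one per molecule;
# per-site independent draws, optional per-site bias
.draw_variants <- function(dseq, n_mol, base_bias = NULL) {
  bases <- strsplit(dseq, "")[[1]]
  deg_sites <- which(vapply(bases, function(b)
    length(IUPAC_SETS[[b]]) > 1L, logical(1)))
  if (!length(deg_sites)) return(rep(dseq, n_mol))
  if (!is.null(base_bias) && length(base_bias) != length(deg_sites))
    stop("base_bias must have one entry per degenerate site",
         call. = FALSE)
  draws <- lapply(seq_along(deg_sites), function(k) {
    allowed <- IUPAC_SETS[[bases[deg_sites[k]]]]
    p <- if (is.null(base_bias)) NULL else {
      pb <- base_bias[[k]]
      if (!all(allowed %in% names(pb)) || any(pb < 0) ||
          abs(sum(pb[allowed]) - 1) > 1e-8)
        stop("base_bias[[", k, "]] is not a distribution over {",
             paste(allowed, collapse = ","), "}", call. = FALSE)
      pb[allowed]
    }
    sample(allowed, n_mol, replace = TRUE, prob = p)
  })
  # interleave constant segments with the per-molecule site draws
  seg_start <- c(1L, deg_sites + 1L)
  seg_end <- c(deg_sites - 1L, length(bases))
  segs <- substring(dseq, seg_start, seg_end)
  pieces <- vector("list", 2L * length(deg_sites) + 1L)
  pieces[seq(1L, length(pieces), by = 2L)] <- as.list(segs)
  pieces[seq(2L, length(pieces), by = 2L)] <- draws
  do.call(paste0, pieces)
}

#' Simulate the rolling-circle amplification product pool
#'
#' Draws molecules independently: a repeat number from `repeat_dist`, a
#' single concrete expansion of the (possibly degenerate) ring per molecule
#' -- one circular template is copied processively, so all units within a
#' molecule are identical -- and an end state (`blunt`, or `ss3prime` /
#' `ss5prime` each with probability `p_ss_end / 2`). Identical molecules are
#' collapsed with multiplicities.
#'
#' @param design A `ring_design`.
#' @param params An [rca_params()].
#' @param seed Integer seed; the pool is reproducible given `seed`.
#' @return Object of class `amplicon_pool`: a data frame with one row per
#'   distinct molecule class (`n_repeats`, `unit_variant`, `end_state`,
#'   `ss_len`, `length`, `mult`) plus attributes `design` and `params`.
#' @export
simulate_rca <- function(design, params = rca_params(), seed = NULL) {
  stopifnot(inherits(design, "ring_design"), inherits(params, "rca_params"))
  with_seed(seed, {
    nm <- params$n_molecules
    ns <- sample(seq_along(params$repeat_dist), nm, replace = TRUE,
                 prob = params$repeat_dist)
    variants <- .draw_variants(design$ring_linear, nm, params$base_bias)
    u <- stats::runif(nm)
    end_state <- ifelse(u < params$p_ss_end / 2, "ss3prime",
                 ifelse(u < params$p_ss_end, "ss5prime", "blunt"))
    ss_len <- ifelse(end_state == "blunt", 0L,
                     if (is.null(params$ss_len)) design$ring_size
                     else params$ss_len)
    ot <- nchar(design$fwd_overlap) + nchar(design$rev_overlap)
    df <- stats::aggregate(
      list(mult = rep(1L, nm)),
      by = list(n_repeats = ns, unit_variant = variants,
                end_state = end_state, ss_len = ss_len),
      FUN = sum)
    df$length <- df$n_repeats * design$ring_size + ot
    df$unit_variants <- lapply(seq_len(nrow(df)), function(i)
      rep(df$unit_variant[i], df$n_repeats[i]))
    df <- df[order(df$n_repeats, df$unit_variant, df$end_state), ]
    rownames(df) <- NULL
    structure(df, design = design, params = params, seed = seed,
              class = c("amplicon_pool", "data.frame"))
  })
}

#' @export
print.amplicon_pool <- function(x, ...) {
  cat("SCRCA amplicon pool: ", sum(x$mult), " molecules in ", nrow(x),
      " classes; repeat numbers ", min(x$n_repeats), "-", max(x$n_repeats),
      "\n", sep = "")
  tb <- tapply(x$mult, x$n_repeats, sum)
  cat("  molecules per repeat number:\n")
  print(tb)
  invisible(x)
}

#' Plus-strand sequence of an amplicon class
#'
#' @param pool An `amplicon_pool`.
#' @param i Row index.
#' @return DNA string `fwd_overlap + units + rev_overlap_plus`.
#' @export
amplicon_sequence <- function(pool, i) {
  design <- attr(pool, "design")
  paste0(design$fwd_overlap,
         paste(pool$unit_variants[[i]], collapse = ""),
         revcomp(design$rev_overlap))
}

#' Size-select amplicons from a pool
#'
#' Keeps classes whose predicted length falls inside a window (the in-silico
#' counterpart of excising a gel band). Supply either a target repeat
#' number, or an explicit bp window; optional Gaussian measurement noise can
#' be applied to the lengths before windowing.
#'
#' @param pool An `amplicon_pool`.
#' @param target_n Target repeat number; the window is its ladder length
#'   `+/- half_width`.
#' @param window Numeric length-2 bp window (used when `target_n` missing).
#' @param half_width Half-width (bp) around the target rung, default half a
#'   ring size.
#' @param noise_sd SD of Gaussian length measurement noise (bp), default 0.
#' @param seed Seed for the measurement noise.
#' @return Filtered `amplicon_pool` (empty, with a warning, when nothing
#'   survives).
#' @export
size_select <- function(pool, target_n = NULL, window = NULL,
                        half_width = NULL, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(pool, "amplicon_pool"))
  design <- attr(pool, "design")
  if (is.null(window)) {
    if (is.null(target_n)) stop("give target_n or window", call. = FALSE)
    ot <- nchar(design$fwd_overlap) + nchar(design$rev_overlap)
    centre <- target_n * design$ring_size + ot
    if (is.null(half_width)) half_width <- design$ring_size / 2
    window <- c(centre - half_width, centre + half_width)
  }
  if (window[2] < window[1]) stop("empty window", call. = FALSE)
  measured <- with_seed(seed,
    pool$length + stats::rnorm(nrow(pool), 0, noise_sd))
  keep <- measured >= window[1] & measured <= window[2]
  out <- pool[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no amplicons in the selected window", call. = FALSE)
  rownames(out) <- NULL
  structure(out, design = design, params = attr(pool, "params"),
            class = c("amplicon_pool", "data.frame"))
}
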