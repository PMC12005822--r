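---
title: "Designing and simulating repetitive-sequence gene synthesis with scrca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and simulating repetitive-sequence gene synthesis with scrca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrca)
```

## The problem

Protein polymers -- elastin-like (ELP) and resilin-like (RLP) polypeptides
and their block copolymers -- are encoded by genes that repeat a short unit
(e.g. `(VGVPG)6` or `(GRGDSPYS)4`) tens of times. Such genes defeat ordinary
synthesis tools: there are almost no unique primer or restriction sites
inside a repeat tract. The SCRCA workflow (seamless cloning of
rolling-circle amplicons) solves this by circularizing a single
5'-phosphorylated ssDNA oligo encoding one repeat unit, amplifying it
isothermally with a strand-displacing polymerase into a ladder of tandem
concatemers, excising the rung with the desired repeat number, and joining
it to a linearized vector through short terminal homologies carried in as
5' primer extensions. Because one mixed-base oligo encodes an entire
repeat-unit library, the same workflow supports cheap directed evolution of
protein polymers.

`scrca` implements the computational side of this platform end to end:
template/primer design, amplicon-pool prediction and simulation, in-silico
seamless assembly with reading-frame verification, degenerate-library
combinatorics and diversity statistics, sequencing-read analysis of repeat
libraries, and charge/hydropathy screening of library mutants.

## Design geometry

A ring is represented by its linear plus-strand form, written to start at a
codon boundary; the ligation junction sits between its last and first base.
Three constraints fix the oligo set (`design_ring()`):

* the **reverse primer** anneals across the junction, `anneal_len/2` nt on
  each side (at least `min_half = 8`). Because it bridges the two ends of
  the linear oligo it doubles as the **split oligo** that templates
  cyclization -- one oligo fewer to order.
* the **forward primer** anneals at the start of the plus strand, so the
  amplicon's repeat tract begins on a codon boundary.
* both primers carry 5' **overlap extensions** of `overlap_len` nt copied
  from the linearized vector's termini. These become the terminal homology
  used by the seamless-cloning reaction and are what make the insertion
  site and orientation unambiguous.

Defaults: `overlap_len = 15` (the homology length the cloning chemistry is
designed for; configurable 12--25) and `anneal_len = 20`. A GC-based
melting-temperature estimate is recorded for each annealing region as a
sanity check against the 60 degree isothermal reaction; no nearest-neighbor
thermodynamics is attempted. Junction placement at the midpoint of the
reverse-primer annealing region is a choice -- any placement with
`min_half` nt per side would satisfy the annealing requirement -- made for
symmetry and determinism.

Large (multi-unit) rings concatenate unit DNAs; a dedicated 24-nt split
oligo (12 nt per side, the shape of the published RE-ring split DNA) spans
the inter-unit junction closed by ligation, while the reverse primer spans
the other junction. For simultaneous two-block cloning,
`design_block_primers()` gives block A's reverse primer a 5' extension equal
to the reverse complement of block B's amplicon terminus, so the two
amplicons share exactly `overlap_len` of homology across the A/B boundary
(split half/half; the published primer pair splits it 6/9, which the
homology check accepts equally).

Reverse translation uses one fixed codon per residue (most frequent in
E. coli) unless the user supplies a table. The published ring sequences
live in supporting material that prints only the primers, so the package
regenerates unit DNA from the peptide; all printed primer and tag sequences
are used verbatim where a check against published reagents is wanted.

## The amplicon model

An amplicon is modeled on its plus strand as

```
fwd_overlap + n x unit + rev_overlap      (length = n x ring_size + 30)
```

which is the product the primer design aims at, and the model under which
the published ladder rule (repeat number x ring size + overlapping bases)
is exact. The half-annealing-length remainder that a literal polymerase
trace would leave at one junction is deliberately not modeled: real primer
placement absorbs it into the repeat frame, and modeling it would only
shift every length by a constant. `predict_ladder()` tabulates the rungs;
`assign_bands()` maps measured band sizes to repeat numbers by
nearest-rung-within-tolerance (default 5% relative); `estimate_ring_size()`
recovers the ring size as the slope of length on repeat number -- with
band noise of 1% the slope stays within 2% of truth, mirroring the
near-perfect linearity of the published ladders.

`simulate_rca()` draws molecules independently:

* **repeat number** from a named distribution. The experiments show ladders
  but report no abundance model, so the default is a truncated geometric
  over `1..20` with decay 0.25 -- shorter products are more frequent, as
  expected when elongation can terminate anywhere -- and the distribution
  is an explicit parameter, not a claim.
* **unit variant**: for degenerate rings each molecule draws ONE concrete
  expansion and repeats it `n` times, because a single circular template is
  copied processively. Cross-molecule variant mixing can only happen later,
  via hybrid formation.
* **end state**: `blunt`, or single-stranded at the 3' or 5' end, each
  incomplete state with probability `p_ss_end/2`. `p_ss_end = 0.2` is a
  package default (the incomplete-intermediate rate is not measured in the
  source experiments); it only controls how many hybrid candidates exist
  downstream and is exposed in `rca_params()`.

Gel mobility is not modeled; `size_select()` filters on true lengths with
optional Gaussian measurement noise, because gels are used only to pick a
repeat number.

## Assembly, hybrids and verification

`infusion_assemble()` joins at most two fragments into the vector iff a
chain upstream-terminus, fragment(s), downstream-terminus exists in which
every junction shares *exact* terminal homology of `overlap_len`
(the cloning enzyme tolerates some mismatch in reality, but no mismatch
model is published, and exact matching is what the designer guarantees).
Orientation control falls out of the homology: a flipped fragment exposes
reverse-complemented termini and never joins, and with two fragments the
designed junction forces their order regardless of input order.

`form_hybrids()` models block-copolymer formation between one 3'-recessed
and one 5'-recessed amplicon. For tandem repeats, offset annealing is
possible wherever the last `min_anneal` nt (default 15) of one parent's
terminal unit occur inside the other parent's first unit; compatible pairs
join with probability `p_anneal`, the nick being repaired during the
cloning reaction. The child's unit list concatenates both parents' units,
so total repeat count is conserved -- an invariant the tests check. This
is a deliberately minimal annealing model: no branch migration, no partial
duplexes, no three-way hybrids.

`verify_orf()` translates upstream tag + insert + downstream terminus and
requires the N-terminal tag (`MK`) at the start, the C-terminal tag
(`WPTHHHHHH`) before the first stop, and no internal stop. The end-to-end
property -- design, amplify without incomplete ends, select each rung
1..12, assemble, verify -- yields 100% in-frame constructs for every
tested unit, which is the internal-consistency claim of the whole design
module. `positivity_rate()` implements the published screening bookkeeping
(product of colony-PCR and sequencing pass fractions).

## Degenerate libraries

Mixed-base codons are expanded by per-position cross product over the
IUPAC sets, lexicographically, and refused above a configurable cap
(default 1e6). The two codons that matter here: `NDT` (4 x 3 x 1 = 12
codons, 12 distinct amino acids spanning charged, polar, aromatic and
aliphatic chemistry), and `YWY` (2 x 2 x 2 = 8 codons, 4 amino acids:
F, Y, L, H). Three NDT sites in the 30-mer ELP unit give 12^3 = 1728
variants with ideal per-variant abundance 100/1728 = 0.058%; three YWY
sites give 512 nucleotide / 64 amino-acid variants.
`design_next_round()` builds the follow-up template by freezing a winner
everywhere except newly randomized codons, the directed-evolution step
between rounds.

`simulate_synthesis()` draws bases independently per degenerate site
(optionally biased), reflecting how mixed bases are physically incorporated
during oligo synthesis; per-site independence is the natural model for a
synthesizer and the only one the source data motivate. Uniform
incorporation at 1e6 molecules reproduces the ideal median abundance to
within Monte-Carlo error; any bias strictly drags the median below the
ideal, which is the qualitative explanation offered for the observed
deviation (0.035% measured vs 0.058% ideal) -- the vendor's actual bias is
unknown, so no attempt is made to match the measured value.

## Read analysis

The published sequencing analysis trusts only the first and last 90 bp of
each amplicon (repetitive middles cluster poorly), counts terminal repeat
units, and keeps variants with at least 6 counts. `extract_terminal_units()`
anchors on the known primer-derived flanks with at most 1 mismatch --
alignment is unnecessary for short fixed flanks designed in-house -- on
either strand, orients the read, and takes the unit-length window inside
the 90-bp end window; `count_units()` applies the count filter;
`classify_unit()` calls a unit a *mutant* iff it matches the degenerate
template position-by-position (IUPAC membership at randomized sites), else
an *error* -- length variants included, with the reason recorded. A
variant's classification never uses its count. `end_concordance()` is the
Pearson correlation of 5' and 3' counts (the published R = 0.991 is the
wet-lab analogue; with error-free simulated reads it is exactly 1), and
`frequency_matrix()` produces the column-normalized logo matrix.

Diversity statistics follow the two-denominator convention of the source
figures: mutant/error fractions are shares of all counted reads, while
max occupancy and median abundance are computed over observed mutant
variants only, with zero-count variants reported as missing rather than
imputed.

## The fixture generator

`make_reads()` emulates the sequencing input: each read is
`flank + 5 x variant + flank` (full-length, so the end-window logic is
actually exercised), one variant per molecule (processivity), independent
per-base substitutions (default 0.3%, the scale of amplification+sequencing
error after trimming), optional indels (default 0 -- the source error
discussion centers on substitutions), and a random strand. All randomness
descends from one seed; the truth table (planted abundances, per-read
variants) is a sufficient statistic for every downstream check. What the
generator does *not* emulate: quality-score structure, adapter read-through,
cluster-formation failures in repetitive middles (the motivation for the
90-bp windows), or chimeric reads. Passing tests therefore validate the
analysis logic, not robustness to instrument pathologies.

One subtlety the fixtures expose: substitution errors landing on a
degenerate site can convert one legal variant into another, so recovered
planted abundances are compared within the planted set, and low-count
"neighbor" mutants are an expected by-product rather than a bug.

## Screening

`build_records()` computes, per candidate, net charge at pH 7.4 and 6.5
(Henderson-Hasselbalch over D, E, C, Y, H, K, R and both termini), their
difference, and GRAVY mean hydropathy. The default pH pair brackets the
biological-vs-tumor-microenvironment contrast the screening targets; the
charge shift across it is dominated by histidine (pKa 6.5), which is why
His-substituted mutants rank highly. The shipped pKa set is the EMBOSS
table; the published calculations delegate to web calculators whose
constants are not printed, so third-decimal agreement with the published
charge figures is not expected and user overrides are accepted.
`rank_candidates()` mechanizes the published selection narrative: exclude
cysteine-containing mutants (irreversible aggregation risk) and block
copolymers (next-round template complexity), sort by `|delta charge|`,
ties broken by id. No threshold for "changed significantly" is published,
so ranking plus `top_k` is the faithful mechanization.
`elp_fraction()` reports the residue share of ELP-class units (the
composition covariate of the copolymer set; an R6E6-style construct gives
100 x 180/372 = 48.4%). No phase-transition temperature prediction is
attempted: transition temperatures are wet-lab measurements, and the
package reproduces only the computational selection step that precedes
purification.

## Numerical and testing choices

Tolerances: band assignment 5% relative by default (capped at 20%); ladder
noise recovery asserts the slope within 2% under 1% band noise; synthesis
medians are compared within 3x the Monte-Carlo scale at the simulated
depth; planted-abundance recovery within 3 binomial standard errors plus a
1-count cushion. Expansion caps refuse rather than truncate. Degenerate
expansions and enumeration are lexicographic so outputs are reproducible
byte for byte. Empty assemblies return diagnostics rather than errors;
empty size selections warn and return an empty pool.

Problem sizes in the shipped tests and acceptance script -- 1e6 molecules
for synthesis simulation, 50,000 reads at 15 planted variants for read
recovery, 400-600 molecules for pool-level properties -- were chosen so
the full suite illustrates every statistical claim at meaningful depth
while running in well under a minute per component on a laptop-class
machine.

## A worked example

```{r example, eval = FALSE}
vec <- make_toy_vector()                       # MK ... WPTHHHHHH termini
e   <- repeat_unit(strrep("VGVPG", 6), name = "E")
d   <- design_ring(e, design_config(vector = vec))
predict_ladder(d, 6)                           # 120, 210, ..., 570 bp

pool <- simulate_rca(d, rca_params(n_molecules = 1000, p_ss_end = 0),
                     seed = 1)
sel  <- size_select(pool, target_n = 6)
rec  <- infusion_assemble(pool_fragments(sel)[[1]], vec)[[1]]
rec$reading_frame_ok                           # TRUE
rec$tags_found                                 # MK / WPTHHHHHH

e3ndt <- library_design(ndt_library_unit())
ideal_abundance(e3ndt)                         # 0.0579 (%)
simulate_synthesis(e3ndt, n_molecules = 1e6, seed = 1)
```

## Known limitations

* No thermodynamic model: primer quality is a GC-based estimate; hairpins,
  mispriming and vendor synthesis constraints are not screened.
* The hybrid model joins at most two parents and treats annealing as exact
  substring matching within terminal units.
* Wet-lab success rates, measured library bias, and phase-separation
  behavior are outside the model by construction; the package computes the
  quantities that are analytic or simulable, and treats the published
  wet-lab numbers as qualitative anchors only.
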