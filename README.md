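# scrca

Design and simulation of repetitive-sequence gene synthesis by **seamless
cloning of rolling-circle amplicons (SCRCA)** — for protein-polymer
engineers building elastin-like (ELP) and resilin-like (RLP) polypeptides,
block copolymers, and degenerate repeat-unit libraries for directed
evolution.

Genes encoding protein polymers repeat a short unit (e.g. `(VGVPG)6`,
`(GRGDSPYS)4`) dozens of times, leaving no unique primer or restriction
sites for conventional synthesis. SCRCA circularizes one 5'-phosphorylated
ssDNA oligo per repeat unit, amplifies it isothermally with a
strand-displacing polymerase into a ladder of tandem concatemers, excises
the desired rung, and clones it seamlessly through 15-nt terminal
homologies added as 5' primer extensions. `scrca` implements the
computational substance of that platform:

* **Design** (`design_ring`, `design_large_ring`, `design_block_primers`,
  `design_next_round`): ring templates, a junction-spanning reverse primer
  that doubles as the split oligo for cyclization, overlap extensions
  matched to the vector termini, two-block cloning primer sets, and
  next-round degenerate templates.
* **Amplification** (`predict_ladder`, `assign_bands`, `simulate_rca`,
  `size_select`): the theoretical ladder *length(n) = n x ring_size +
  overlap bases*, band-to-repeat assignment, and a stochastic amplicon-pool
  simulator with processive within-molecule unit identity and
  incomplete-end intermediates.
* **Assembly** (`infusion_assemble`, `form_hybrids`, `verify_orf`,
  `positivity_rate`): orientation-controlled overlap-directed assembly,
  block-copolymer hybrid formation between incomplete-end amplicons,
  reading-frame/tag verification (`MK` ... `WPTHHHHHH`), and screening
  bookkeeping.
* **Libraries** (`library_design`, `enumerate_library`, `ideal_abundance`,
  `simulate_synthesis`, `diversity_report`): mixed-base codon
  combinatorics (NDT → 12 amino acids; three sites → 1728 variants at
  0.058% ideal abundance; YWY → F/Y/L/H), synthesis simulation with
  per-site base bias, and the two-denominator diversity statistics.
* **Read analysis** (`extract_terminal_units`, `count_units`,
  `classify_unit`, `end_concordance`, `frequency_matrix`): terminal-unit
  extraction from the reliable 90-bp end windows, a ≥6-count filter,
  mutant/error classification against the degenerate template, 5'/3'
  concordance, and logo matrices.
* **Screening** (`build_records`, `rank_candidates`, `elp_fraction`):
  Henderson–Hasselbalch net charge at pH 7.4 vs 6.5, Kyte–Doolittle GRAVY,
  cysteine/block-copolymer exclusion, and |Δcharge| ranking for the next
  evolution round.
* **Fixtures** (`make_toy_vector`, `fixture_spec`, `make_reads`): seeded
  synthetic vectors and error-bearing read sets with truth tables.

A thin CLI over these functions ships at `inst/scripts/scrca`
(subcommands `design`, `ladder`, `simulate`, `library-stats`,
`analyze-reads`, `make-fixtures`, `screen`).

## Worked example

```r
library(scrca)

vec <- make_toy_vector()                       # termini encoding MK / WPTHHHHHH
e   <- repeat_unit(strrep("VGVPG", 6), name = "E")
d   <- design_ring(e, design_config(vector = vec))
d
#> SCRCA ring design (E): ring 90 nt, primers 35/35 nt (15 nt overlap + 20 nt anneal)
#>   fwd primer: GATATACATATGAAAGTGGGTGTGCCGGGTGTGGG
#>   rev primer: ATGATGGGTCGGCCAGCACACCCACACCCGGCACA  (also split oligo)

predict_ladder(d, 6)$length                    # 120 210 300 390 480 570

pool <- simulate_rca(d, rca_params(n_molecules = 1000, p_ss_end = 0), seed = 1)
rec  <- infusion_assemble(pool_fragments(size_select(pool, target_n = 6))[[1]],
                          vec)[[1]]
rec
#> Recombinant: insert 540 nt, 6 repeat(s); frame OK
#>   tags: MK ... WPTHHHHHH

e3ndt <- library_design(ndt_library_unit())
e3ndt
#> Degenerate library 'E-3NDT': 1,728 nucleotide variants / 1728 amino-acid
#> variants; degenerate codons at 1, 6, 11
ideal_abundance(e3ndt)                         # 0.0579  (percent per variant)

simulate_synthesis(e3ndt, n_molecules = 1e6, seed = 1)
#> Library abundance report (E-3NDT)
#>   reads (both ends): 2000000; observed mutant variants: 1728 of 1728 (0 missing)
#>   mutant / error fraction: 100.0% / 0.0%
#>   max occupancy: 0.0659%; median abundance: 0.0579% (ideal 0.0579%)
```

The ladder is the gel you would run (570 bp is the six-repeat E gene with
both 15-nt overlaps); the recombinant is the in-frame expression construct
the wet workflow aims for; the abundance report shows that uniform
mixed-base incorporation reproduces the ideal per-variant abundance, so any
measured shortfall reflects synthesis bias.

## Scope

The package models what is analytic or simulable: no polymerase kinetics,
no gel-mobility model, no thermodynamic primer screening, and no
phase-separation prediction. Wet-lab success rates and measured library
bias are treated as qualitative anchors, not targets. See the methods
vignette (`vignettes/scrca-methods.Rmd`) for the models, defaults and
their rationale.
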