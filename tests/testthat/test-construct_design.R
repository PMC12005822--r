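test_that("reverse translation round-trips and is deterministic", {
  dna <- reverse_translate("VGVPG")
  expect_identical(nchar(as.character(dna)), 15L)
  expect_identical(translate_dna(as.character(dna)), "VGVPG")
  expect_identical(as.character(reverse_translate("VGVPG")),
                   as.character(dna))
  expect_equal(attr(dna, "gc"),
               gc_fraction(as.character(dna)), tolerance = 1e-12)
  expect_error(reverse_translate("VGX"), "invalid")
  # user table takes precedence
  tab <- c(V = "GTT", G = "GGA", P = "CCC")
  expect_identical(as.character(reverse_translate("VGVPG", tab)),
                   "GTTGGAGTTCCCGGA")
})

test_that("single-unit ring design places a junction-spanning reverse primer", {
  cfg <- design_config(overlap_len = 15, anneal_len = 20,
                       vector = toy_vector())
  d <- design_ring(elp_unit(), cfg)
  expect_s3_class(d, "ring_design")
  expect_identical(d$ring_size, 90L)
  expect_identical(nchar(d$fwd_primer), 35L)
  expect_identical(nchar(d$rev_primer), 35L)
  expect_identical(d$split_oligo, d$rev_primer)

  # independent suffix/prefix oracle: the rev primer's 3' 20-mer must be
  # the reverse complement of (last 10 + first 10) of the linear ssDNA
  ring <- d$ring_linear
  window <- paste0(substr(ring, 81, 90), substr(ring, 1, 10))
  expect_identical(substr(d$rev_primer, 16, 35), oracle_revcomp(window))
  # fwd primer 3' 20-mer matches the ring plus strand
  expect_identical(substr(d$fwd_primer, 16, 35), substr(ring, 1, 20))
  # overlap extensions come from the vector termini
  vec <- toy_vector()
  expect_identical(substr(d$fwd_primer, 1, 15),
                   substr(vec$upstream_end,
                          nchar(vec$upstream_end) - 14,
                          nchar(vec$upstream_end)))
  expect_identical(substr(d$rev_primer, 1, 15),
                   oracle_revcomp(substr(vec$downstream_end, 1, 15)))
  # determinism
  expect_identical(design_ring(elp_unit(), cfg), d)
  # too-short unit refused
  expect_error(design_ring(repeat_unit("VGVPG"), cfg), "too short")
})

test_that("degenerate rings keep the wild-type backbone at fixed positions", {
  wt <- design_ring(elp_unit())
  lib <- design_ring(ndt_library_unit())
  wt_b <- strsplit(wt$ring_linear, "")[[1]]
  lib_b <- strsplit(lib$ring_linear, "")[[1]]
  deg <- which(lib_b %in% c("N", "D"))
  expect_identical(sort(unique(ceiling(deg / 3))), c(1, 6, 11))
  # outside the randomized codons the backbone is the wild-type ring
  outside <- setdiff(seq_along(wt_b),
                     unlist(lapply(c(1, 6, 11), function(i)
                       (3 * i - 2):(3 * i))))
  expect_identical(lib_b[outside], wt_b[outside])
  # within a randomized codon every expansion still encodes a V option
  expect_true("GTT" %in% expand_degenerate(substr(lib$ring_linear, 1, 3)))
})

test_that("large rings concatenate units and carry a dedicated split oligo", {
  d <- design_large_ring(list(rlp_unit(), elp_unit()))
  expect_identical(d$ring_size, 96L + 90L)
  expect_identical(nchar(d$split_oligo), 24L)
  expect_false(identical(d$split_oligo, d$rev_primer))
  # split oligo spans the R+E / start junction with 12 nt on each side
  ring <- d$ring_linear
  window <- paste0(substr(ring, 186 - 11, 186), substr(ring, 1, 12))
  expect_identical(d$split_oligo, oracle_revcomp(window))
  expect_error(design_large_ring(list(elp_unit())), "at least 2")
})

test_that("block primers reproduce the published 15-nt junction homology", {
  # printed RLP-block reverse / ELP-block forward primer pair
  rlp_rev <- "GACACCTACTGAGTAAGGTGAATCACCACGACC"
  elp_fwd <- "TACTCAGTAGGTGTCCCAGGTGTCGG"
  expect_identical(junction_homology(rlp_rev, elp_fwd), 15L)

  vec <- toy_vector()
  bp <- design_block_primers(design_ring(rlp_unit()),
                             design_ring(elp_unit()), vec)
  expect_gte(junction_homology(bp$a$rev, bp$b$fwd), 15L)
  expect_identical(sum(bp$junction_split), 15L)
  expect_error(design_block_primers(design_ring(rlp_unit()),
                                    design_ring(elp_unit()), vec,
                                    overlap_len = 11), ">= 12")
})

test_that("next-round templates fix the winner except at the new sites", {
  e <- elp_unit()
  e3 <- design_next_round(e, c(1, 6, 11), "NDT")
  expect_identical(prod(site_degeneracies(e3$dna)), 1728)
  expect_identical(library_design(e3)$nucleotide_variant_count, 1728)

  # an m10-like winner: concrete unit with three remaining V sites
  m10 <- repeat_unit(strrep("VGVPG", 6L), name = "m10")
  m10_3ywy <- design_next_round(m10, c(16, 21, 26), "YWY")
  ld <- library_design(m10_3ywy)
  expect_identical(ld$nucleotide_variant_count, 8^3)
  expect_identical(ld$aa_variant_count, 64L)
  # untouched codons identical to the winner
  expect_identical(substr(m10_3ywy$dna, 1, 45), substr(m10$dna, 1, 45))

  expect_identical(design_next_round(e, integer(0)), e)
  expect_error(design_next_round(e3, c(6, 16), "YWY"), "overlap")
})

test_that("designs serialize to JSON and FASTA", {
  d <- design_ring(elp_unit(), design_config(vector = toy_vector()))
  js <- jsonlite::fromJSON(design_to_json(d))
  expect_identical(js$ring_size, d$ring_size)
  expect_identical(js$rev_primer, d$rev_primer)
  tmp <- withr::local_tempfile(fileext = ".fasta")
  design_to_fasta(d, tmp)
  seqs <- read_fasta(tmp)
  expect_identical(unname(seqs["ring_linear"]), d$ring_linear)
})
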