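test_that("overlap homology controls assembly success and orientation", {
  vec <- toy_vector()
  d <- design_ring(elp_unit(), design_config(vector = vec))
  pool <- simulate_rca(d, rca_params(n_molecules = 50, p_ss_end = 0),
                       seed = 2)
  frag <- pool_fragments(size_select(pool, target_n = 3))[[1]]

  recs <- infusion_assemble(frag, vec)
  expect_length(recs, 1L)
  expect_true(recs[[1]]$reading_frame_ok)
  expect_identical(recs[[1]]$n_repeats, 3L)

  # reverse-complemented fragment exposes the wrong termini: no assembly
  flipped <- frag
  flipped$sequence <- revcomp(frag$sequence)
  none <- infusion_assemble(flipped, vec)
  expect_length(none, 0L)
  expect_true(length(attr(none, "diagnostics")) > 0)
})

test_that("two-block assembly is order-independent and forced by homology", {
  vec <- toy_vector()
  da <- design_ring(rlp_unit())
  db <- design_ring(elp_unit())
  bp <- design_block_primers(da, db, vec)
  A <- da$ring_linear
  B <- db$ring_linear
  ov <- 15L
  j2 <- bp$junction_split[["b_head"]]
  j1 <- bp$junction_split[["a_tail"]]
  # amplicons implied by the primer design (3 repeats each)
  up <- substr(vec$upstream_end, nchar(vec$upstream_end) - ov + 1,
               nchar(vec$upstream_end))
  down <- substr(vec$downstream_end, 1, ov)
  ampA <- list(sequence = paste0(up, strrep(A, 3), substr(B, 1, j2)),
               n_repeats = 3L, unit_variants = rep(A, 3))
  ampB <- list(sequence = paste0(substr(A, 96 - j1 + 1, 96),
                                 strrep(B, 3), down),
               n_repeats = 3L, unit_variants = rep(B, 3))

  r1 <- infusion_assemble(list(ampA, ampB), vec)
  r2 <- infusion_assemble(list(ampB, ampA), vec)
  expect_length(r1, 1L)
  expect_identical(r1[[1]]$insert, r2[[1]]$insert)
  expect_identical(r1[[1]]$n_repeats, 6L)
  expect_true(r1[[1]]$reading_frame_ok)
  # the merged insert is up-homology-free: R block then E block
  expect_identical(r1[[1]]$unit_variants, c(rep(A, 3), rep(B, 3)))
})

test_that("ORF verification translates tags and catches frameshifts", {
  vec <- toy_vector()
  d <- design_ring(elp_unit(), design_config(vector = vec))
  pool <- simulate_rca(d, rca_params(n_molecules = 60, p_ss_end = 0),
                       seed = 4)
  frag <- pool_fragments(size_select(pool, target_n = 6))[[1]]
  rec <- infusion_assemble(frag, vec)[[1]]
  expect_true(rec$reading_frame_ok)
  expect_true(startsWith(rec$peptide, paste0("MK", strrep("VGVPG", 36))))
  expect_true(grepl("WPTHHHHHH", rec$peptide, fixed = TRUE))
  expect_identical(rec$tags_found[["n_term"]], "MK")
  expect_identical(rec$tags_found[["c_term"]], "WPTHHHHHH")

  # a 1-nt deletion inside the insert shifts the frame
  broken <- rec
  broken$insert <- paste0(substr(rec$insert, 1, 40),
                          substr(rec$insert, 42, nchar(rec$insert)))
  broken <- verify_orf(broken, vec)
  expect_false(broken$reading_frame_ok)

  # empty insert: vector self-translation only (tags abut, still in frame)
  empty <- verify_orf(structure(list(insert = "", n_repeats = 0L,
                                     unit_variants = list()),
                                class = "recombinant"), vec)
  expect_true(startsWith(empty$peptide, "MKWPTHHHHHH"))
})

test_that("hybrid formation conserves repeats and concatenates blocks", {
  d <- design_ring(ndt_library_unit(), design_config(vector = toy_vector()))
  params <- rca_params(n_molecules = 400, p_ss_end = 0.6)
  pool <- simulate_rca(d, params, seed = 21)

  # p_anneal = 0: pool unchanged
  expect_identical(form_hybrids(pool, p_anneal = 0, seed = 1), pool)

  hyb <- form_hybrids(pool, p_anneal = 0.5, min_anneal = 15, seed = 1)
  # total unit count conserved
  expect_identical(sum(hyb$n_repeats * hyb$mult),
                   sum(pool$n_repeats * pool$mult))
  # every multi-block molecule is a concatenation of two parents' runs
  multi <- which(vapply(hyb$unit_variants, function(v)
    length(unique(v)) > 1L, logical(1)))
  for (i in multi) {
    uv <- hyb$unit_variants[[i]]
    runs <- rle(uv)
    expect_identical(length(runs$values), 2L)
    # annealing compatibility: 3' parent's unit tail occurs in 5' unit
    tail15 <- substr(runs$values[1], nchar(runs$values[1]) - 14,
                     nchar(runs$values[1]))
    expect_true(grepl(tail15, runs$values[2], fixed = TRUE))
  }
  expect_true(all(hyb$end_state[multi] == "blunt"))
})

test_that("fully compatible pools join min(n3, n5) pairs at p_anneal = 1", {
  # non-degenerate design: all molecules identical, always compatible
  d <- design_ring(elp_unit(), design_config(vector = toy_vector()))
  pool <- simulate_rca(d, rca_params(n_molecules = 200, p_ss_end = 0.5),
                       seed = 8)
  n3 <- sum(pool$mult[pool$end_state == "ss3prime"])
  n5 <- sum(pool$mult[pool$end_state == "ss5prime"])
  hyb <- form_hybrids(pool, p_anneal = 1, seed = 3)
  expect_identical(sum(pool$mult) - sum(hyb$mult), min(n3, n5))
})

test_that("positivity rate is the product of the two pass fractions", {
  expect_equal(positivity_rate(screening_tally(8, 10, 5, 8)), 50)
  expect_equal(positivity_rate(screening_tally(10, 10, 8, 8)), 100)
  expect_equal(positivity_rate(screening_tally(0, 10, 5, 8)), 0)
  expect_error(screening_tally(5, 0, 1, 1), "positive")
  expect_error(screening_tally(11, 10, 1, 1), "exceed")
})
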