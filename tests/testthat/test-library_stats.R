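test_that("library enumeration matches the analytic combinatorics", {
  e3ndt <- library_design(ndt_library_unit())
  expect_identical(e3ndt$nucleotide_variant_count, 12^3)
  lib <- enumerate_library(e3ndt)
  expect_identical(nrow(lib), 1728L)
  expect_identical(anyDuplicated(lib$dna), 0L)
  expect_identical(lib$dna, sort(lib$dna))
  # 12 amino acids per NDT site -> 12^3 distinct peptides
  expect_identical(length(unique(lib$peptide)), 1728L)
  expect_identical(e3ndt$aa_variant_count, 1728L)

  m10_3ywy <- library_design(
    design_next_round(repeat_unit(strrep("VGVPG", 6), name = "m10"),
                      c(16, 21, 26), "YWY"))
  expect_identical(m10_3ywy$nucleotide_variant_count, 8^3)
  expect_identical(m10_3ywy$aa_variant_count, 64L)

  plain <- library_design(elp_unit())
  expect_identical(plain$nucleotide_variant_count, 1)
  expect_identical(nrow(enumerate_library(plain)), 1L)
})

test_that("enumeration count equals the degeneracy product for random designs", {
  set.seed(7)
  for (i in 1:50) {
    d <- random_degenerate(30)
    k <- prod(site_degeneracies(d))
    if (k > 1e4) next
    expect_length(expand_degenerate(d, cap = 1e4), k)
  }
})

test_that("ideal abundance is 100 / variant count to 3 significant figures", {
  expect_equal(ideal_abundance(library_design(ndt_library_unit())), 0.0579)
  expect_identical(signif(ideal_abundance(1728), 2), 0.058)
  expect_equal(ideal_abundance(1), 100)
  expect_equal(ideal_abundance(64), signif(1.5625, 3))
})

test_that("synthesis simulation reflects base bias", {
  ld <- library_design(ndt_library_unit())

  # all bias mass on one base per site -> a single variant at 100%
  deg_sites <- which(site_degeneracies(ld$unit$dna) > 1)
  bias <- lapply(deg_sites, function(i) {
    b <- strsplit(ld$unit$dna, "")[[1]][i]
    allowed <- IUPAC_SETS[[b]]
    stats::setNames(c(1, rep(0, length(allowed) - 1)), allowed)
  })
  rep1 <- simulate_synthesis(ld, n_molecules = 500, base_bias = bias,
                             seed = 1)
  expect_identical(rep1$observed_variants, 1L)
  expect_equal(rep1$max_occupancy, 100)
  expect_equal(rep1$mutant_fraction, 100)

  # uniform bias at moderate depth: median near the ideal value
  rep_u <- simulate_synthesis(ld, n_molecules = 2e5, seed = 2)
  expect_lt(abs(rep_u$median_abundance - rep_u$ideal_abundance),
            0.3 * rep_u$ideal_abundance)

  # skewed bias strictly reduces the median below ideal
  skew <- lapply(deg_sites, function(i) {
    b <- strsplit(ld$unit$dna, "")[[1]][i]
    allowed <- IUPAC_SETS[[b]]
    w <- c(10, rep(1, length(allowed) - 1))
    stats::setNames(w / sum(w), allowed)
  })
  rep_s <- simulate_synthesis(ld, n_molecules = 2e5, base_bias = skew,
                              seed = 2)
  expect_lt(rep_s$median_abundance, rep_u$median_abundance)
  expect_lt(rep_s$median_abundance, rep_s$ideal_abundance)
})

test_that("diversity reports recompute from raw counts and ignore row order", {
  ld <- library_design(ndt_library_unit())
  lib <- enumerate_library(ld)
  set.seed(5)
  vars <- sample(lib$dna, 40)
  counts <- data.frame(variant = vars,
                       count5 = rpois(40, 50) + 6L,
                       count3 = rpois(40, 50) + 6L,
                       stringsAsFactors = FALSE)
  rep1 <- diversity_report(counts, ld)
  rep2 <- diversity_report(counts[rev(seq_len(40)), ], ld)
  expect_equal(rep1$median_abundance, rep2$median_abundance)
  expect_equal(rep1$max_occupancy, rep2$max_occupancy)

  # independent tally oracle
  total <- sum(counts$count5 + counts$count3)
  pct <- 100 * (counts$count5 + counts$count3) / total
  expect_equal(rep1$max_occupancy, max(pct))
  expect_equal(rep1$median_abundance, stats::median(pct))
  expect_equal(rep1$mutant_fraction, 100)

  # uniform counts over K variants -> median exactly 100 / K
  uni <- data.frame(variant = vars, count5 = 10L, count3 = 10L)
  rep_u <- diversity_report(uni, ld)
  expect_equal(rep_u$median_abundance, 100 / 40)
  expect_equal(rep_u$max_occupancy, 100 / 40)

  # one variant at half of all reads -> 50% occupancy
  half <- data.frame(variant = vars[1:2],
                     count5 = c(30L, 30L), count3 = c(30L, 30L))
  half$count5[1] <- 30L; half$count3[1] <- 30L
  rep_h <- diversity_report(half, ld)
  expect_equal(rep_h$max_occupancy, 50)

  # error rows excluded from mutant-level stats, included in fractions
  err <- rbind(counts[1:10, ],
               data.frame(variant = strrep("A", 90),
                          count5 = 50L, count3 = 50L))
  rep_e <- diversity_report(err, ld)
  expect_identical(rep_e$observed_variants, 10L)
  tot_e <- sum(err$count5 + err$count3)
  expect_equal(rep_e$error_fraction, 100 * 100 / tot_e)
  mut_reads <- sum(err$count5[1:10] + err$count3[1:10])
  expect_equal(rep_e$max_occupancy,
               100 * max(err$count5[1:10] + err$count3[1:10]) / mut_reads)

  expect_error(diversity_report(counts[0, ], ld), "empty")
})
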