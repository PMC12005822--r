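# small helper: one synthetic read around a planted variant
planted_read <- function(variant, flanks, n_units = 5L) {
  paste0(flanks$f5, strrep(variant, n_units), flanks$f3)
}

test_that("terminal units are recovered from reads on either strand", {
  ld <- library_design(ndt_library_unit())
  flanks <- list(f5 = "TGTAGGTGTCCCAGGTGT", f3 = "ACCAGGAACACCAACACC")
  v <- expand_degenerate(ld$unit$dna)[17]
  read <- planted_read(v, flanks)

  got <- extract_terminal_units(c(read, revcomp(read)), ld, flanks)
  expect_identical(got$unit5, c(v, v))
  expect_identical(got$unit3, c(v, v))
  expect_identical(got$strand, c("+", "-"))

  # one mismatch in the flank tolerated, two are not
  mm1 <- read
  substr(mm1, 2, 2) <- ifelse(substr(mm1, 2, 2) == "A", "C", "A")
  got1 <- extract_terminal_units(mm1, ld, flanks)
  expect_identical(got1$unit5, v)
  mm2 <- mm1
  substr(mm2, 4, 4) <- ifelse(substr(mm2, 4, 4) == "A", "C", "A")
  got2 <- extract_terminal_units(mm2, ld, flanks)
  expect_true(is.na(got2$unit5))
  expect_identical(attr(got2, "n_unanchored"), 1L)
})

test_that("unit counting applies the minimum-count filter deterministically", {
  ld <- library_design(ndt_library_unit())
  vs <- expand_degenerate(ld$unit$dna)[c(1, 2)]
  units <- data.frame(
    unit5 = c(rep(vs[1], 10), rep(vs[2], 5)),
    unit3 = c(rep(vs[1], 10), rep(vs[2], 5)),
    stringsAsFactors = FALSE)

  tab <- count_units(units, ld, min_count = 6)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$variant, vs[1])
  expect_identical(c(tab$count5, tab$count3), c(10L, 10L))
  expect_identical(attr(tab, "dropped")$variant, vs[2])
  expect_identical(tab$class, "mutant")

  # shuffled input order gives the identical table
  shuf <- units[sample(nrow(units)), ]
  expect_identical(as.data.frame(count_units(shuf, ld, min_count = 6)),
                   as.data.frame(tab))
})

test_that("units classify as mutant iff they match the degenerate template", {
  ld <- library_design(ndt_library_unit())
  lib <- enumerate_library(ld)
  set.seed(2)
  for (v in sample(lib$dna, 25))
    expect_identical(classify_unit(v, ld), "mutant")

  # substitution at a fixed backbone position
  v <- lib$dna[1]
  fixed_pos <- which(site_degeneracies(ld$unit$dna) == 1L)[5]
  bad <- v
  substr(bad, fixed_pos, fixed_pos) <-
    setdiff(c("A", "C", "G", "T"),
            substr(ld$unit$dna, fixed_pos, fixed_pos))[1]
  expect_identical(as.character(classify_unit(bad, ld)), "error")

  # base outside the IUPAC set at a degenerate position: C at a D site
  d_site <- which(strsplit(ld$unit$dna, "")[[1]] == "D")[1]
  bad2 <- v
  substr(bad2, d_site, d_site) <- "C"
  cls <- classify_unit(bad2, ld)
  expect_identical(as.character(cls), "error")
  expect_match(attr(cls, "reason"), "not in D")

  # length variants are errors
  expect_identical(as.character(classify_unit(substr(v, 1, 89), ld)),
                   "error")
})

test_that("end concordance is the Pearson correlation over variants", {
  ld <- library_design(ndt_library_unit())
  vs <- expand_degenerate(ld$unit$dna)[1:5]
  tab <- data.frame(variant = vs,
                    count5 = c(40L, 30L, 20L, 10L, 8L),
                    count3 = c(40L, 30L, 20L, 10L, 8L))
  expect_equal(end_concordance(tab), 1)

  anti <- data.frame(variant = vs,
                     count5 = c(40L, 30L, 20L, 10L, 8L),
                     count3 = c(8L, 10L, 20L, 30L, 40L))
  # closed-form Pearson oracle
  x <- anti$count5; y <- anti$count3
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(end_concordance(anti), r_oracle)
  expect_lt(end_concordance(anti), 0)

  flat <- data.frame(variant = vs, count5 = 5L, count3 = 1:5)
  expect_warning(r <- end_concordance(flat), "variance")
  expect_true(is.na(r))
  expect_error(end_concordance(tab[1:2, ]), "3 variants")
})

test_that("error-free processive reads give perfect end concordance", {
  ld <- library_design(ndt_library_unit())
  spec <- fixture_spec(ld, abundances = 12L, n_reads = 1500,
                       sub_rate = 0, seed = 31)
  rs <- make_reads(spec)
  units <- extract_terminal_units(rs$reads, ld, spec$flanks)
  tab <- count_units(units, ld, min_count = 6)
  expect_equal(end_concordance(tab), 1)
  expect_true(all(tab$class == "mutant"))
})

test_that("frequency matrices are column-normalized with flagged sites", {
  ld <- library_design(ndt_library_unit())
  v <- expand_degenerate(ld$unit$dna)[3]
  m <- frequency_matrix(rep(v, 4), design = ld)
  expect_true(all(abs(colSums(m) - 1) < 1e-9))
  expect_true(all(apply(unclass(m), 2, max) == 1))  # one-hot columns
  expect_identical(attr(m, "degenerate"),
                   which(site_degeneracies(ld$unit$dna) > 1L))

  # uniform draw over NDT expansions: multinomial expectation per column
  codons <- expand_degenerate("NDT")
  mc <- frequency_matrix(codons)
  expect_equal(unname(mc[, 1]), rep(0.25, 4))
  expect_equal(unname(mc[, 2]), c(1/3, 0, 1/3, 1/3))  # A,C,G,T; no C
  expect_equal(unname(mc[, 3]), c(0, 0, 0, 1))        # always T

  # amino-acid alphabet
  ma <- frequency_matrix(c("VGVPG", "VGVPG", "AGVPG"), alphabet = "aa")
  expect_true(all(abs(colSums(ma) - 1) < 1e-9))
  expect_equal(ma["V", 1], 2/3)
  expect_error(frequency_matrix(c("AC", "ACG")), "uniform")
})

test_that("reverse-complementing every read leaves all outputs unchanged", {
  ld <- library_design(ndt_library_unit())
  spec <- fixture_spec(ld, abundances = 10L, n_reads = 800,
                       sub_rate = 0.003, seed = 17)
  rs <- make_reads(spec)
  fwd <- extract_terminal_units(rs$reads, ld, spec$flanks)
  rcr <- vapply(rs$reads, revcomp, "", USE.NAMES = FALSE)
  rev <- extract_terminal_units(rcr, ld, spec$flanks)

  expect_identical(fwd$unit5, rev$unit5)
  expect_identical(fwd$unit3, rev$unit3)
  tf <- count_units(fwd, ld)
  tr <- count_units(rev, ld)
  expect_identical(as.data.frame(tf), as.data.frame(tr))
  expect_equal(end_concordance(tf), end_concordance(tr))
})
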