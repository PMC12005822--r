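# Shared fixtures: the two published repeat units, the toy expression
# vector, and small independent oracles used across test files.

elp_unit <- function() repeat_unit(strrep("VGVPG", 6L), name = "E")
rlp_unit <- function() repeat_unit(strrep("GRGDSPYS", 4L), name = "R")

toy_vector <- function() make_toy_vector()

# independent character-map reverse complement (oracle; deliberately not
# the package implementation)
oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(x, "")[[1]]]), collapse = "")
}

# recursive degenerate expansion (oracle for expand_degenerate /
# enumerate_library counts)
oracle_expand <- function(dseq) {
  sets <- lapply(strsplit(dseq, "")[[1]], function(b)
    sort(Biostrings::IUPAC_CODE_MAP[[b]] |> strsplit("") |> unlist()))
  rec <- function(i) {
    if (i > length(sets)) return("")
    rest <- rec(i + 1L)
    as.vector(vapply(sets[[i]], function(b) paste0(b, rest), rest))
  }
  sort(rec(1L))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# mostly-concrete degenerate strings so full expansion stays tractable
random_degenerate <- function(n) {
  codes <- c("A", "C", "G", "T", "N", "D", "Y", "W", "R", "S")
  probs <- c(rep(0.2, 4), 0.03, 0.03, 0.045, 0.045, 0.03, 0.02)
  paste(sample(codes, n, replace = TRUE, prob = probs), collapse = "")
}
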