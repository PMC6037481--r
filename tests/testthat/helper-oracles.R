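# Independent oracles and random-instance generators used across tests.

can_pair_chr <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

# Exhaustive max-pair count over all nested structures (min hairpin
# loop 3). Plain recursion, deliberately independent of the package's
# dynamic programs.
enum_max_pairs <- function(ch, i = 1L, j = length(ch)) {
  if (j - i < 4L) return(0L)
  best <- enum_max_pairs(ch, i + 1L, j)
  for (k in (i + 4L):j) {
    if (can_pair_chr(ch[i], ch[k])) {
      v <- 1L + enum_max_pairs(ch, i + 1L, k - 1L) +
        (if (k + 1L <= j) enum_max_pairs(ch, k + 1L, j) else 0L)
      if (v > best) best <- v
    }
  }
  best
}

random_rna <- function(n, bases = c("A", "C", "G", "U")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# A loop of size L carrying the given 3-mer across the centre bond
# (all other loop positions A, so no competing motif or pairing).
centred_loop <- function(L, motif = c("U", "G", "C")) {
  m <- (L - 1L) %/% 2L + 1L
  loop <- rep("A", L)
  loop[(m - 1L):(m + 1L)] <- motif
  paste(loop, collapse = "")
}

expect_loop_sizes <- function(structure, sizes) {
  expect_identical(sort(hairpin_loops(structure)$size), sort(as.integer(sizes)))
}
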