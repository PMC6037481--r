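fx <- load_hairpin_fixtures()

test_that("unpairable and short sequences fold to all-unpaired with zero energy", {
  st <- fold_mfe("AAAAAAAAAA")
  expect_identical(st$pair_table, integer(10))
  expect_identical(st$energy, 0)
  expect_identical(fold_mfe("ACG")$pair_table, integer(3))
})

test_that("the four printed hairpin substrates fold to their reported loops", {
  stb <- fold_mfe(fx$BIP1)
  lb <- hairpin_loops(stb)
  expect_identical(nrow(lb), 1L)
  expect_identical(lb$size, 9L)
  expect_identical(c(lb$loop_start, lb$loop_end), c(12L, 20L))

  sts <- fold_mfe(fx$SPAC4G9.15)
  ls <- hairpin_loops(sts)
  expect_identical(ls$size, 3L)
  expect_identical(c(ls$loop_start, ls$loop_end), c(14L, 16L))

  sth <- fold_mfe(fx$HAC1_3SS)
  lh <- hairpin_loops(sth)
  expect_identical(lh$size, 7L)
  # closing pair is the U11.G19 wobble
  ch <- seq_chars(fx$HAC1_3SS)
  expect_identical(ch[lh$closing_i], "U")
  expect_identical(ch[lh$closing_j], "G")

  stx <- fold_mfe(fx$XBP1)
  lx <- hairpin_loops(stx)
  expect_identical(lx$size, 7L)
  expect_identical(c(lx$loop_start, lx$loop_end), c(8L, 14L))
})

test_that("the energy model rejects the bulged extra pair that pair-maximisation adds to XBP1", {
  expect_gt(n_pairs(fold_maxpair(fx$XBP1)), n_pairs(fold_mfe(fx$XBP1)))
  expect_identical(n_pairs(fold_mfe(fx$XBP1)), 7L)
})

test_that("maxpair mode maximises pairs and respects constraints", {
  st <- fold_maxpair("GGGAAACCC")
  expect_identical(n_pairs(st), 3L)
  expect_identical(st$pair_table[4:6], integer(3)) # loop AAA unpaired
  expect_lte(n_pairs(fold_maxpair("GGGAAACCC", constraints = 2L)), 2L)
})

test_that("maxpair equals exhaustive enumeration on random sequences", {
  withr::local_seed(7)
  for (rep in 1:60) {
    n <- sample(5:15, 1)
    s <- random_rna(n)
    expect_identical(n_pairs(fold_maxpair(s)),
                     enum_max_pairs(strsplit(s, "")[[1]]),
                     label = s)
  }
})

test_that("constrained positions are never paired and constraints cannot lower the energy", {
  withr::local_seed(11)
  for (rep in 1:20) {
    n <- sample(15:40, 1)
    s <- random_rna(n)
    free <- fold_mfe(s)
    forced <- sort(sample(n, max(1, n %/% 6)))
    con <- fold_mfe(s, constraints = forced)
    expect_identical(con$pair_table[forced], integer(length(forced)))
    expect_gte(con$energy, free$energy - 1e-9)
    # same for the pair-maximisation mode
    expect_identical(fold_maxpair(s, constraints = forced)$pair_table[forced],
                     integer(length(forced)))
  }
})

test_that("reported energy equals the loop-decomposition sum and folding is deterministic", {
  withr::local_seed(23)
  for (rep in 1:20) {
    s <- random_rna(sample(15:45, 1))
    st1 <- fold_mfe(s)
    st2 <- fold_mfe(s)
    expect_identical(st1$pair_table, st2$pair_table)
    expect_equal(st1$energy, structure_energy(s, st1), tolerance = 1e-6)
  }
})

test_that("loop sizes of the printed hairpins are confirmed by an independent folder", {
  # RNAfold (ViennaRNA) as an external oracle: parameterisations differ,
  # but the hairpin-loop sizes of these designed substrates should agree.
  rnafold <- Sys.which("RNAfold")
  expect_true(nzchar(rnafold))
  for (nm in names(fx)) {
    out <- system2(rnafold, "--noPS", stdout = TRUE,
                   input = seq_residues(fx[[nm]]))
    db <- strsplit(out[2], " ", fixed = TRUE)[[1]][1]
    oracle <- hairpin_loops(parse_dotbracket(db))
    ours <- hairpin_loops(fold_mfe(fx[[nm]]))
    expect_identical(ours$size, oracle$size, label = nm)
  }
})

test_that("scissile-bond context reports loop geometry in bonds from the centre", {
  stx <- fold_mfe(fx$XBP1)
  ctx <- scissile_bond_context(stx, 10L)
  expect_true(ctx$in_loop)
  expect_identical(ctx$loop_size, 7L)
  expect_identical(ctx$bond_ordinal, 3L)
  expect_equal(ctx$center_offset, 0.5)

  stb <- fold_mfe(fx$BIP1)
  ctb <- scissile_bond_context(stb, 16L)
  expect_identical(ctb$loop_size, 9L)
  expect_identical(ctb$bond_ordinal, 5L)
  expect_equal(ctb$center_offset, 0.5)

  # a bond inside the stem is not in any loop
  expect_false(scissile_bond_context(stx, 2L)$in_loop)
})

test_that("all-unpaired structures have no hairpin loops", {
  expect_identical(nrow(hairpin_loops(rna_structure(integer(12)))), 0L)
})
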