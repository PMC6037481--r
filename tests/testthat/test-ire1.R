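fx <- load_hairpin_fixtures()

test_that("motif scanning finds every UG|C bond in XBP1 and none in HAC1 3'SS", {
  hits <- scan_motifs(fx$XBP1, species_rule("sp"))
  expect_identical(hits$bond_index, c(2L, 10L, 19L))
  expect_true(all(hits$matched_motif == "UG|C"))
  expect_identical(nrow(scan_motifs(fx$HAC1_3SS, species_rule("sp"))), 0L)
  expect_identical(nrow(scan_motifs("AAAA", species_rule("sp"))), 0L)
})

test_that("the XBP1 central bond satisfies both species; a stem UGC does not", {
  st <- fold_mfe(fx$XBP1)
  expect_setequal(dual_specificity(fx$XBP1, st, 10L),
                  c("S_cerevisiae", "S_pombe"))
  sc <- classify_site(fx$XBP1, st, 10L, species_rule("sc"))
  expect_identical(sc$verdict, "substrate")
  expect_identical(sc$matched_motif, "CUG|CAGC")
  expect_identical(sc$bond_ordinal, 3L) # loop positions 3|4 register
  # U1 G2 | C3 sits in the closing stem
  stem <- classify_site(fx$XBP1, st, 2L, species_rule("sp"))
  expect_identical(stem$verdict, "non-substrate")
  expect_identical(stem$reason, "not in loop")
})

test_that("species verdicts on the four substrates reproduce the cleavage pattern", {
  stb <- fold_mfe(fx$BIP1)
  expect_identical(dual_specificity(fx$BIP1, stb, 16L), "S_pombe")
  sc_b <- classify_site(fx$BIP1, stb, 16L, species_rule("sc"))
  expect_identical(sc_b$loop_size_check, "fail") # 9-loop, not the strict 7

  sts <- fold_mfe(fx$SPAC4G9.15)
  expect_identical(dual_specificity(fx$SPAC4G9.15, sts, 15L), "S_pombe")
  sc_s <- classify_site(fx$SPAC4G9.15, sts, 15L, species_rule("sc"))
  expect_identical(sc_s$verdict, "non-substrate")
  expect_identical(sc_s$loop_size_check, "fail") # 3-loop

  sth <- fold_mfe(fx$HAC1_3SS)
  expect_identical(dual_specificity(fx$HAC1_3SS, sth, 14L), "S_cerevisiae")
  sc_h <- classify_site(fx$HAC1_3SS, sth, 14L, species_rule("sc"))
  expect_identical(sc_h$matched_motif, "CCG|AAGC") # the CNG|ANGN alternative
})

test_that("minimal motif restoration finds the single A->U edit and confirms it", {
  # AG|C hairpin: one substitution away from the S. pombe motif
  hyb <- make_hairpin(hairpin_spec(stem_length = 10,
                                   loop_sequence = "AAAGCAA",
                                   flank_lengths = c(5, 5)), seed = 41)
  st <- fold_mfe(hyb$seq)
  before <- classify_site(hyb$seq, st, hyb$scissile_bond, species_rule("sp"))
  expect_identical(before$verdict, "non-substrate")
  expect_identical(before$reason, "motif fail")

  fix <- mutate_to_motif(hyb$seq, hyb$scissile_bond, species_rule("sp"))
  expect_identical(nrow(fix$substitutions), 1L)
  expect_identical(fix$substitutions$from, "A")
  expect_identical(fix$substitutions$to, "U")
  expect_identical(fix$substitutions$position, hyb$scissile_bond - 1L)
  expect_identical(fix$call$verdict, "substrate")
  # every other position untouched
  diff <- which(seq_chars(fix$mutated_seq) != seq_chars(hyb$seq))
  expect_identical(diff, hyb$scissile_bond - 1L)
})

test_that("motif restoration handles already-matching and two-edit sites", {
  ok <- make_hairpin(hairpin_spec(stem_length = 10, loop_sequence = "AAUGCAA"),
                     seed = 43)
  res <- mutate_to_motif(ok$seq, ok$scissile_bond, species_rule("sp"))
  expect_identical(nrow(res$substitutions), 0L)

  # loop reading G G | G around the bond needs two edits (G->U at -1, G->C at +1)
  gg <- make_hairpin(hairpin_spec(stem_length = 10, loop_sequence = "AAGGGAA"),
                     seed = 47)
  res2 <- mutate_to_motif(gg$seq, gg$scissile_bond, species_rule("sp"))
  expect_identical(nrow(res2$substitutions), 2L)
  expect_identical(res2$substitutions$to, c("U", "C"))
  expect_identical(res2$substitutions$position,
                   c(gg$scissile_bond - 1L, gg$scissile_bond + 1L))
})

test_that("extending the closing stem by 4 pairs changes no verdict", {
  withr::local_seed(53)
  for (rep in 1:12) {
    L <- sample(c(3, 5, 7, 9), 1)
    hp <- make_hairpin(hairpin_spec(stem_length = sample(8:11, 1),
                                    loop_sequence = centred_loop(L),
                                    flank_lengths = c(0, 0)),
                       seed = 600 + rep)
    ext <- paste(sample(c("G", "C", "G", "A"), 4, TRUE), collapse = "")
    longer <- rna_sequence(paste0(ext, seq_residues(hp$seq), rna_revcomp(ext)))
    for (rule in list(species_rule("sc"), species_rule("sp"))) {
      v1 <- classify_site(hp$seq, fold_mfe(hp$seq), hp$scissile_bond, rule)
      v2 <- classify_site(longer, fold_mfe(longer), hp$scissile_bond + 4L, rule)
      expect_identical(v2$verdict, v1$verdict)
      expect_identical(v2$loop_size, v1$loop_size)
    }
  }
})

test_that("motif scan candidates always contain the substrate calls", {
  withr::local_seed(59)
  for (rep in 1:10) {
    s <- random_rna(sample(25:45, 1))
    st <- fold_mfe(s)
    for (rule in list(species_rule("sc"), species_rule("sp"))) {
      cand <- scan_motifs(s, rule)$bond_index
      subs <- purrr::keep(seq_len(nchar(s) - 1L), function(b) {
        classify_site(s, st, b, rule)$verdict == "substrate"
      })
      expect_true(all(subs %in% cand))
    }
  }
})

test_that("implanted UG|C loops are always called; AG|C implants never are", {
  withr::local_seed(61)
  n_each <- 60
  rule <- species_rule("sp")
  sens <- spec <- logical(n_each)
  for (q in seq_len(n_each)) {
    L <- sample(3:9, 1)
    hp <- make_hairpin(hairpin_spec(stem_length = sample(9:12, 1),
                                    loop_sequence = centred_loop(L),
                                    flank_lengths = c(5, 5)),
                       seed = 2000 + q)
    sens[q] <- classify_site(hp$seq, hp$structure, hp$scissile_bond,
                             rule)$verdict == "substrate"
    hp2 <- make_hairpin(hairpin_spec(stem_length = sample(9:12, 1),
                                     loop_sequence = centred_loop(L, c("A", "G", "C")),
                                     flank_lengths = c(5, 5)),
                        seed = 4000 + q)
    spec[q] <- classify_site(hp2$seq, hp2$structure, hp2$scissile_bond,
                             rule)$verdict == "non-substrate"
  }
  expect_identical(mean(sens), 1) # sensitivity
  expect_identical(mean(spec), 1) # specificity
})
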