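mk_records <- function(bases, raws, positions = seq_along(bases)) {
  tibble::tibble(position = positions, base = bases, raw_signal = raws)
}

test_that("normalisation scales the window maximum to 1 proportionally", {
  rec <- normalize_window(mk_records(c("A", "C", "A"), c(10, 50, 25)))
  expect_equal(rec$normalized_signal, c(0.2, 1.0, 0.5))
  # all-zero window normalises to zeros, not NaN
  z <- normalize_window(mk_records(c("A", "C"), c(0, 0)))
  expect_identical(z$normalized_signal, c(0, 0))
  # a single record becomes the maximum
  expect_equal(normalize_window(mk_records("A", 7))$normalized_signal, 1)
})

test_that("constraints require signal strictly above threshold and an A or C base", {
  rec <- normalize_window(mk_records(c("A", "A", "G", "C"), c(25, 20, 90, 100)))
  con <- derive_constraints(rec)
  # A at 0.25 constrained; A at exactly 0.20 not; G at 0.9 never
  expect_identical(as.integer(con), c(1L, 4L))
  expect_error(derive_constraints(mk_records("A", 5)), "not normalised")
})

test_that("constraints are invariant to rescaling raw signals", {
  withr::local_seed(5)
  for (rep in 1:20) {
    n <- 20
    rec <- mk_records(sample(c("A", "C", "G", "U"), n, TRUE), runif(n, 0, 100))
    base_con <- derive_constraints(normalize_window(rec))
    for (c_scale in c(0.01, 3, 1e4)) {
      scaled <- rec
      scaled$raw_signal <- scaled$raw_signal * c_scale
      expect_identical(as.integer(derive_constraints(normalize_window(scaled))),
                       as.integer(base_con))
    }
  }
})

test_that("probe_and_fold recovers an implanted hairpin from simulated counts", {
  hp <- make_hairpin(hairpin_spec(stem_length = 11, loop_sequence = "UGGUGCUUU",
                                  flank_lengths = c(8, 8)), seed = 19)
  rec <- simulate_dms(hp$seq, hp$structure, seed = 20)
  pf <- probe_and_fold(hp$seq, rec, hp$scissile_bond)
  loops <- hairpin_loops(pf$structure)
  expect_identical(loops$size, 9L)
  expect_identical(loops$loop_start + pf$offset, hp$loop_start)
})

test_that("zero signal folds unconstrained; saturating A/C signal forbids all pairing", {
  hp <- make_hairpin(hairpin_spec(stem_length = 10, flank_lengths = c(9, 10)), seed = 3)
  n <- seq_length(hp$seq)
  zero <- mk_records(seq_chars(hp$seq), rep(0, n))
  pf <- suppressWarnings(probe_and_fold(hp$seq, zero, hp$scissile_bond))
  sub <- rna_subseq(hp$seq, pf$window[1], pf$window[2])
  expect_identical(pf$structure$pair_table, fold_mfe(sub)$pair_table)

  # every A/C hot on an A/C-only sequence: everything is constrained
  ac_only <- rna_sequence(paste(rep(c("A", "C"), 10), collapse = ""))
  hot_ac <- mk_records(seq_chars(ac_only), rep(100, 20))
  pf2 <- suppressWarnings(probe_and_fold(ac_only, hot_ac, 10L))
  expect_identical(n_pairs(pf2$structure), 0L)
})

test_that("windows are clipped at sequence ends with a warning, never negative-length", {
  rec <- mk_records(rep("A", 30), runif(30, 1, 10))
  s <- rna_sequence(strrep("A", 30))
  expect_warning(reactivity_window(rec, 5L, 30L), "clipped")
  expect_error(suppressWarnings(probe_and_fold(s, rec, 29L, halfwidth = 19L)), NA)
  short <- rna_sequence("ACGUACGUAC")
  expect_error(suppressWarnings(
    probe_and_fold(short, mk_records(seq_chars(short), rep(1, 10)), 9L, halfwidth = 2L)
  ), "shorter than 10")
})

test_that("paired A/C stay unconstrained and constrained folds match truth", {
  withr::local_seed(31)
  n_fix <- 30
  frac_paired_ok <- numeric(n_fix)
  acc <- numeric(n_fix)
  for (q in seq_len(n_fix)) {
    L <- sample(c(3, 5, 7, 9), 1)
    hp <- make_hairpin(hairpin_spec(stem_length = sample(9:12, 1),
                                    loop_sequence = centred_loop(L),
                                    flank_lengths = c(8, 8)),
                       seed = 500 + q)
    rec <- simulate_dms(hp$seq, hp$structure, seed = 900 + q)
    pf <- suppressWarnings(probe_and_fold(hp$seq, rec, hp$scissile_bond))
    win <- pf$window[1]:pf$window[2]
    truth_paired <- hp$structure$pair_table[win] > 0
    ch <- seq_chars(hp$seq)[win]
    ac_paired <- truth_paired & ch %in% c("A", "C")
    con_local <- as.integer(pf$constraints)
    frac_paired_ok[q] <- if (any(ac_paired)) {
      mean(!(which(ac_paired) %in% con_local))
    } else 1
    acc[q] <- mean((pf$structure$pair_table > 0) == truth_paired)
  }
  expect_gte(mean(frac_paired_ok), 0.95)
  expect_gte(mean(acc), 0.90)
})
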