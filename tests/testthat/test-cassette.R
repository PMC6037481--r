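test_that("region replacement splices, deletes and validates coordinates", {
  host <- rna_sequence("ACGUACGUAC", id = "h")
  same_len <- replace_site(host, 5, 7, "UUU")
  expect_identical(seq_length(same_len$seq), 10L)
  expect_identical(same_len$shift, 0L)
  expect_identical(rna_subseq(same_len$seq, 5, 7), "UUU")

  del <- replace_site(host, 5, 7, "")
  expect_identical(seq_length(del$seq), 7L)
  expect_identical(del$shift, -3L)

  expect_error(replace_site(host, 0, 3, "A"), "out of range")
  expect_error(replace_site(host, 8, 12, "A"), "out of range")
})

test_that("the reference cassette design has the pruned-intron architecture", {
  d <- design_cassette()
  expect_identical(d$intron_length, 30L)
  expect_identical(nchar(d$intron), 30L)
  expect_identical(d$cut3 - d$cut5, 30L)
  # both junction hairpins fold as designed in isolation
  for (range_name in c("stemloop1", "stemloop2")) {
    r <- d[[range_name]]
    h <- substr(d$cassette_seq, r[1], r[2])
    expect_identical(hairpin_loops(fold_mfe(h))$size, 7L)
  }
  expect_error(design_cassette(loop = "AAAGCAA"), "UGC")
})

test_that("cassette insertion into a benign 3' UTR validates both junctions", {
  host <- rna_sequence(strrep("A", 80), id = "polyA_host")
  eng <- insert_cassette(host, 40, utr = c(30, 80))
  expect_true(eng$valid)
  expect_identical(eng$validation$verdict, c("substrate", "substrate"))
  expect_identical(eng$cut3 - eng$cut5, 30L)

  pr <- predict_splice_product(eng$seq, eng$cut5, eng$cut3)
  expect_identical(seq_length(pr$excised_intron), 30L)
})

test_that("a host tract complementary to junction 1 defeats validation, reported not thrown", {
  design <- design_cassette(stem1 = "GCAUAU", stem2 = "UAGCAU")
  hostA <- strrep("A", 80)
  clean <- rna_sequence(hostA, id = "clean")
  expect_true(insert_cassette(clean, 40, design = design, utr = c(30, 80))$valid)

  adv <- rna_sequence(paste0(substr(hostA, 1, 33), "UUGCAUU",
                             substr(hostA, 41, 80)), id = "adversarial")
  res <- insert_cassette(adv, 40, design = design, utr = c(30, 80))
  expect_false(res$valid)
  expect_identical(res$validation$reason[1], "not in loop")
})

test_that("the cassette also validates in an unrelated U-rich UTR context", {
  withr::local_seed(3)
  utr2 <- paste(sample(c("U", "A", "C"), 60, replace = TRUE,
                       prob = c(.5, .3, .2)), collapse = "")
  host2 <- rna_sequence(paste0(strrep("A", 20), utr2), id = "tubulin_like_utr")
  eng2 <- insert_cassette(host2, 50, utr = c(21, 80))
  expect_true(eng2$valid)
})

test_that("splice products conserve length and round-trip the intron", {
  withr::local_seed(67)
  for (rep in 1:20) {
    n <- sample(40:120, 1)
    s <- rna_sequence(random_rna(n))
    ij <- sort(sample(n - 1, 2))
    pr <- suppressWarnings(predict_splice_product(s, ij[1], ij[2]))
    expect_identical(seq_length(pr$spliced) + seq_length(pr$excised_intron), n)
    # re-inserting the excised intron at the junction reconstructs the input
    back <- replace_site(pr$spliced, pr$junction_coordinate + 1L,
                         pr$junction_coordinate,
                         seq_residues(pr$excised_intron))
    expect_identical(seq_residues(back$seq), seq_residues(s))
  }

  s100 <- rna_sequence(strrep("ACGU", 25))
  pr <- predict_splice_product(s100, 20, 50)
  expect_identical(seq_length(pr$spliced), 70L)
  tiny <- predict_splice_product(s100, 29, 30)
  expect_identical(seq_length(tiny$excised_intron), 1L)
  expect_error(predict_splice_product(s100, 50, 50), "5'")
})
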