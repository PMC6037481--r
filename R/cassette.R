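#' Replace a region of a sequence
#'
#' Splices `replacement` in place of positions `region_start` to
#' `region_end` (1-based, inclusive). An empty replacement deletes the
#' region; `region_end = region_start - 1` denotes the empty region
#' before `region_start`, so a non-empty replacement there is a pure
#' insertion. Coordinates of features downstream of the region shift
#' by `nchar(replacement) - (region_end - region_start + 1)`.
#'
#' @param host RNA sequence.
#' @param region_start,region_end Region to replace.
#' @param replacement Replacement sequence (may be "").
#' @return A list: `seq` (the new `rna_sequence`) and `shift` (the
#'   coordinate shift for downstream features).
#' @export
replace_site <- function(host, region_start, region_end, replacement) {
  host <- as_rna(host)
  n <- seq_length(host)
  if (region_start < 1L || region_end > n || region_start > region_end + 1L) {
    abort(sprintf("region [%d, %d] out of range for length %d",
                  region_start, region_end, n))
  }
  repl <- if (nchar(replacement)) canonicalize_rna(replacement) else ""
  new <- paste0(rna_subseq(host, 1L, region_start - 1L), repl,
                rna_subseq(host, region_end + 1L, n))
  list(seq = rna_sequence(new, id = paste0(seq_id(host), "_edit")),
       shift = as.integer(nchar(repl) - (region_end - region_start + 1)))
}

#' Reference S. pombe-optimised splicing cassette
#'
#' A synthetic splicing cassette designed by this package (its
#' sequence is a repository artifact, not a measured construct): two
#' stem-loops, each presenting a UG|C scissile bond near the centre of
#' a 7-membered loop (so each junction satisfies the S. pombe Ire1
#' rule), flanking a 30-nt intron — the pruned-intron architecture of
#' the engineered non-conventional splicing substrate. Cleavage at the
#' two bonds excises exactly 30 nt.
#'
#' @param intron_length Intron length in nt (default 30).
#' @param stem1,stem2 5' arms of the two junction stems (defaults:
#'   distinct strong 8-bp stems).
#' @param loop Loop sequence shared by both junctions; must present
#'   UG|C with the G one position 3' of the loop midpoint (default
#'   "AAUGCAA").
#' @return A `cassette_design` list: `cassette_seq`, `cut5`, `cut3`
#'   (cassette-local scissile bonds), `exon1_junction`, `intron`,
#'   `exon2_junction`, `stemloop1`, `stemloop2` (cassette-local
#'   ranges), `intron_length`.
#' @export
design_cassette <- function(intron_length = 30L, stem1 = "GCCACGGC",
                            stem2 = "GGCAUCGG", loop = "AAUGCAA") {
  stem1 <- canonicalize_rna(stem1); stem2 <- canonicalize_rna(stem2)
  loop <- canonicalize_rna(loop)
  if (nchar(stem1) != nchar(stem2)) abort("the two stems must have equal length")
  gpos <- (nchar(loop) - 1L) %/% 2L + 1L
  if (gpos < 2L || substr(loop, gpos - 1L, gpos + 1L) != "UGC") {
    abort("loop must read UGC across its central scissile bond (UG|C)")
  }
  h1 <- paste0(stem1, loop, rna_revcomp(stem1))
  h2 <- paste0(stem2, loop, rna_revcomp(stem2))
  cut_in_hairpin <- nchar(stem1) + gpos # the G of UG|C
  # spacer sized so that exactly `intron_length` nt separate the two cuts
  between <- (nchar(h1) - cut_in_hairpin) + cut_in_hairpin # intron nt inside hairpins
  spacer_len <- intron_length - between
  if (spacer_len < 0L) abort("intron too short for the junction stem-loops")
  spacer <- paste(rep(c("A", "A", "U", "A", "C", "A"), length.out = spacer_len),
                  collapse = "")
  cassette <- paste0(h1, spacer, h2)
  cut5 <- cut_in_hairpin
  cut3 <- cut5 + intron_length
  structure(list(
    cassette_seq = cassette,
    cut5 = cut5, cut3 = cut3,
    exon1_junction = substr(cassette, 1L, cut5),
    intron = substr(cassette, cut5 + 1L, cut3),
    exon2_junction = substr(cassette, cut3 + 1L, nchar(cassette)),
    stemloop1 = c(1L, nchar(h1)),
    stemloop2 = c(nchar(h1) + spacer_len + 1L, nchar(cassette)),
    intron_length = as.integer(intron_length)
  ), class = "cassette_design")
}

#' @export
print.cassette_design <- function(x, ...) {
  cat(sprintf("<cassette_design> %d nt, cuts at %d|%d and %d|%d, intron %d nt\n%s\n",
              nchar(x$cassette_seq), x$cut5, x$cut5 + 1L, x$cut3, x$cut3 + 1L,
              x$intron_length, x$cassette_seq))
  invisible(x)
}

#' Insert a splicing cassette into a host 3' UTR
#'
#' Inserts the cassette after `position` (a bond in the host 3' UTR),
#' then validates the design in its new context: the probing window
#' around each junction's scissile bond is refolded and the bond
#' classified under the S. pombe rule. Validation failure is reported,
#' not thrown — designs are iterated.
#'
#' @param host Host RNA sequence.
#' @param position Host bond after which the cassette is inserted;
#'   must lie inside `utr`.
#' @param design A [design_cassette()] object.
#' @param utr 1-based (start, end) interval annotating the host 3'
#'   UTR.
#' @param model Energy model for validation folds.
#' @return A list: `seq` (engineered sequence), `cut5`, `cut3` (global
#'   scissile bonds), `validation` (tibble, one row per junction),
#'   `valid` (both junctions substrates?), `design`.
#' @export
insert_cassette <- function(host, position, design = design_cassette(),
                            utr = NULL, model = energy_model()) {
  host <- as_rna(host)
  n <- seq_length(host)
  if (is.null(utr)) utr <- c(1L, n)
  if (position < utr[1L] || position > utr[2L] || position >= n + 1L) {
    abort(sprintf("insertion bond %d outside the 3' UTR [%d, %d]",
                  position, utr[1L], utr[2L]))
  }
  eng <- paste0(rna_subseq(host, 1L, position), design$cassette_seq,
                rna_subseq(host, position + 1L, n))
  eng <- rna_sequence(eng, id = paste0(seq_id(host), "_cassette"))
  cut5 <- as.integer(position) + design$cut5
  cut3 <- as.integer(position) + design$cut3

  rule <- species_rule("S_pombe")
  validate_one <- function(bond, junction) {
    win <- window_fold(eng, bond, model = model)
    call <- classify_site(win$seq, win$structure, bond - win$offset, rule)
    mutate(call, junction = junction, bond_global = bond, .before = 1L)
  }
  validation <- bind_rows(validate_one(cut5, "exon1|intron"),
                          validate_one(cut3, "intron|exon2"))
  list(seq = eng, cut5 = cut5, cut3 = cut3,
       validation = validation,
       valid = all(validation$verdict == "substrate"),
       design = design)
}

# Fold the 38-nt window centred on a bond (no probing constraints).
window_fold <- function(seq, bond, model = energy_model(), halfwidth = 19L) {
  n <- seq_length(seq)
  lo <- max(1L, bond - (halfwidth - 1L))
  hi <- min(n, bond + halfwidth)
  sub <- rna_sequence(rna_subseq(seq, lo, hi),
                      id = sprintf("%s_win%d-%d", seq_id(seq), lo, hi))
  list(seq = sub, structure = fold_mfe(sub, model = model), offset = lo - 1L)
}

#' Predict the product of non-conventional splicing
#'
#' Cleavage at two scissile bonds `i < j` followed by exon ligation:
#' the spliced RNA is `seq[1..i] + seq[j+1..end]`, the excised intron
#' `seq[i+1..j]`, and the splice junction sits after position `i` of
#' the spliced product. Lengths are conserved:
#' `length(spliced) + length(intron) == length(input)`.
#'
#' @param seq RNA sequence (the engineered construct).
#' @param bond5,bond3 5' and 3' scissile bonds (`bond5 < bond3`).
#' @return A list: `spliced` (`rna_sequence`), `excised_intron`
#'   (`rna_sequence`), `junction_coordinate` (position in the spliced
#'   sequence).
#' @export
predict_splice_product <- function(seq, bond5, bond3) {
  seq <- as_rna(seq)
  n <- seq_length(seq)
  i <- as.integer(bond5); j <- as.integer(bond3)
  if (i >= j) abort("bond5 must lie 5' of bond3")
  if (i < 1L || j >= n + 1L || j > n) abort("bonds outside sequence")
  spliced <- paste0(rna_subseq(seq, 1L, i), rna_subseq(seq, j + 1L, n))
  intron <- rna_subseq(seq, i + 1L, j)
  list(spliced = rna_sequence(spliced, id = paste0(seq_id(seq), "_spliced")),
       excised_intron = rna_sequence(intron, id = paste0(seq_id(seq), "_intron")),
       junction_coordinate = i)
}
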