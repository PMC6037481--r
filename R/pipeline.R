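#' Characterise candidate Ire1 cleavage sites in sequences
#'
#' The structure-then-classify workflow over a set of sequences: each
#' sequence is folded (DMS-constrained when reactivity records are
#' supplied: signals are max-normalised, reactive A/C positions become
#' single-stranded constraints), every motif-matching bond for the
#' requested species is located, and each candidate is classified
#' against loop geometry.
#'
#' @param seqs A list of `rna_sequence` (e.g. from [read_fasta()]), a
#'   single `rna_sequence`, or a character vector.
#' @param reactivity Optional named list of raw reactivity tibbles
#'   (names matching sequence ids), or a single tibble when one
#'   sequence is given.
#' @param species `"sc"`, `"sp"` or `"both"` (default).
#' @param threshold DMS constraint threshold (default 0.2).
#' @param model An [energy_model()].
#' @return A tibble with one row per (sequence, candidate bond,
#'   species): sequence id, fold energy, candidate geometry, checks
#'   and verdicts, as returned by [classify_site()].
#' @export
characterize_sequences <- function(seqs, reactivity = NULL,
                                   species = c("both", "sc", "sp"),
                                   threshold = 0.2, model = energy_model()) {
  species <- match.arg(species)
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  if (is.character(seqs)) seqs <- lapply(seqs, rna_sequence)
  rules <- switch(species,
                  both = list(species_rule("S_cerevisiae"), species_rule("S_pombe")),
                  sc = list(species_rule("S_cerevisiae")),
                  sp = list(species_rule("S_pombe")))
  if (!is.null(reactivity) && is.data.frame(reactivity)) {
    if (length(seqs) != 1L) abort("give reactivity as a named list for multiple sequences")
    reactivity <- setNames(list(reactivity), seq_id(seqs[[1L]]))
  }

  out <- list()
  for (s in seqs) {
    id <- seq_id(s)
    constraints <- NULL
    rec <- reactivity[[id]]
    if (!is.null(rec)) {
      if (any(rec$position < 1L | rec$position > seq_length(s))) {
        abort(sprintf("reactivity for '%s' references positions beyond the sequence", id))
      }
      constraints <- derive_constraints(normalize_window(rec), threshold = threshold)
    }
    st <- fold_mfe(s, constraints = constraints, model = model)
    for (rule in rules) {
      cand <- scan_motifs(s, rule)
      if (nrow(cand) == 0L) next
      calls <- bind_rows(lapply(cand$bond_index, function(b) {
        classify_site(s, st, b, rule)
      }))
      out[[length(out) + 1L]] <- mutate(calls, seq_id = id, energy = st$energy,
                                        dms_constrained = !is.null(constraints),
                                        .before = 1L)
    }
  }
  if (length(out) == 0L) {
    return(tibble(seq_id = character(), energy = numeric(),
                  dms_constrained = logical(), species = character(),
                  bond_index = integer(), matched_motif = character(),
                  verdict = character(), reason = character()))
  }
  bind_rows(out)
}

#' Engineer a host mRNA with a splicing cassette
#'
#' Inserts a splicing cassette into a host 3' UTR, validates both
#' junctions under the S. pombe rule in their new sequence context,
#' and predicts the splice product.
#'
#' @param host Host `rna_sequence`.
#' @param utr 1-based (start, end) interval of the host 3' UTR.
#' @param position Host bond after which the cassette is inserted
#'   (default: the midpoint of the UTR).
#' @param design A [design_cassette()] (default: the reference
#'   cassette).
#' @param model An [energy_model()].
#' @return A list: `engineered` (the [insert_cassette()] result),
#'   `product` (the [predict_splice_product()] result, NULL when
#'   validation failed), `valid`.
#' @export
engineer_splicing <- function(host, utr, position = NULL,
                              design = design_cassette(), model = energy_model()) {
  host <- as_rna(host)
  if (missing(utr) || is.null(utr) || length(utr) != 2L) {
    abort("a (start, end) 3' UTR interval is required")
  }
  utr <- as.integer(utr)
  if (utr[1L] < 1L || utr[2L] > seq_length(host) || utr[1L] > utr[2L]) {
    abort("UTR interval outside the host sequence")
  }
  if (is.null(position)) position <- (utr[1L] + utr[2L]) %/% 2L
  eng <- insert_cassette(host, position, design = design, utr = utr, model = model)
  product <- if (eng$valid) predict_splice_product(eng$seq, eng$cut5, eng$cut3)
  list(engineered = eng, product = product, valid = eng$valid)
}

#' Write a site report or design report as JSON
#'
#' Versioned JSON serialisation of a characterisation or engineering
#' result, with the configuration that produced it.
#'
#' @param report A tibble from [characterize_sequences()] or a list
#'   from [engineer_splicing()].
#' @param path Output path.
#' @param config Optional named list recorded in the header (seeds,
#'   thresholds).
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, config = list()) {
  payload <- list(schema = "ire1rna/report/1", config = config)
  if (is.data.frame(report)) {
    payload$sites <- report
  } else {
    eng <- report$engineered
    payload$design <- list(
      cassette_seq = eng$design$cassette_seq,
      intron_length = eng$design$intron_length,
      cut5 = eng$cut5, cut3 = eng$cut3, valid = eng$valid)
    payload$validation <- eng$validation
    if (!is.null(report$product)) {
      payload$product <- list(
        spliced = seq_residues(report$product$spliced),
        excised_intron = seq_residues(report$product$excised_intron),
        junction_coordinate = report$product$junction_coordinate)
    }
    payload$engineered_seq <- seq_residues(eng$seq)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
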