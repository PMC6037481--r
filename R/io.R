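#' Read RNA sequences from FASTA
#'
#' Reads a FASTA file (via Biostrings) and canonicalises every record
#' to the RNA alphabet: lowercase raised, `T` converted to `U`. Record
#' ids are taken from the header up to the first whitespace. Any
#' residue other than A/C/G/U after canonicalisation is an error
#' naming the record and position.
#'
#' @param path Path to a FASTA file.
#' @return A list of `rna_sequence` objects (empty list for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (file.size(path) == 0L) return(list())
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(list())
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (k in seq_along(set)) {
    out[[k]] <- tryCatch(
      rna_sequence(as.character(set[[k]]), id = ids[k]),
      error = function(e) abort(sprintf("record '%s': %s", ids[k], conditionMessage(e)))
    )
  }
  out
}

#' Write sequences to FASTA
#'
#' @param seqs A list of `rna_sequence` objects (or one such object).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  lines <- unlist(lapply(seqs, function(s) c(paste0(">", seq_id(s)), seq_residues(s))))
  writeLines(lines, path)
  invisible(path)
}

#' Write a structure in dot-bracket format
#'
#' Emits the Vienna three-line form: `>id`, residues, dot-bracket.
#' `read_dotbracket()` is its inverse.
#'
#' @param seq RNA sequence.
#' @param structure An `rna_structure` of the same length.
#' @param path Optional output path; if NULL the lines are returned.
#' @return Character vector of the three lines (invisibly when written
#'   to `path`).
#' @export
write_dotbracket <- function(seq, structure, path = NULL) {
  seq <- as_rna(seq)
  if (seq_length(seq) != structure$length) {
    abort(sprintf("sequence length %d != structure length %d",
                  seq_length(seq), structure$length))
  }
  lines <- c(paste0(">", seq_id(seq)), seq_residues(seq), dot_bracket(structure))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' @rdname write_dotbracket
#' @return `read_dotbracket()`: a list with elements `seq`
#'   (`rna_sequence`) and `structure` (`rna_structure`).
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L || !startsWith(lines[1L], ">")) {
    abort("expected three lines: >id, residues, dot-bracket")
  }
  seq <- rna_sequence(lines[2L], id = sub("^>", "", lines[1L]))
  list(seq = seq, structure = parse_dotbracket(lines[3L]))
}

#' Write / read a structure in CT (connectivity table) format
#'
#' Columns: index, base, index-1, index+1, pair partner (0 if
#' unpaired), index. Pair content round-trips and agrees with the
#' dot-bracket writer.
#'
#' @inheritParams write_dotbracket
#' @return `write_ct()` returns `path` invisibly; `read_ct()` a list
#'   with `seq` and `structure`.
#' @export
write_ct <- function(seq, structure, path) {
  seq <- as_rna(seq)
  if (seq_length(seq) != structure$length) abort("sequence/structure length mismatch")
  n <- structure$length
  df <- data.frame(i = seq_len(n), base = seq_chars(seq),
                   prev = seq_len(n) - 1L, nxt = c(seq_len(n)[-1L], 0L),
                   pair = structure$pair_table, idx = seq_len(n))
  header <- sprintf("%d %s", n, seq_id(seq))
  writeLines(c(header, apply(df, 1L, paste, collapse = "\t")), path)
  invisible(path)
}

#' @rdname write_ct
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- as.integer(header[1L])
  id <- if (length(header) > 1L) header[2L] else "seq"
  body <- do.call(rbind, strsplit(trimws(lines[1L + seq_len(n)]), "\\s+"))
  seq <- rna_sequence(paste(body[, 2L], collapse = ""), id = id)
  list(seq = seq, structure = rna_structure(as.integer(body[, 5L])))
}

#' Read a per-base DMS reactivity table (TSV)
#'
#' Expected columns: `position`, `base`, `raw_signal`, optionally
#' `normalized_signal`. Records are returned ordered by position.
#' Duplicate positions, negative raw signals, or normalised signals
#' outside \[0, 1\] are errors.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble with one row per position.
#' @export
read_reactivity_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("position", "base", "raw_signal")
  if (!all(need %in% names(df))) {
    abort(sprintf("reactivity TSV must have columns %s", paste(need, collapse = ", ")))
  }
  df$position <- as.integer(df$position)
  if (anyDuplicated(df$position)) abort("duplicate positions in reactivity table")
  if (any(df$raw_signal < 0)) abort("raw_signal must be non-negative")
  if (!all(df$base %in% c("A", "C", "G", "U"))) abort("base must be one of A/C/G/U")
  if ("normalized_signal" %in% names(df)) {
    ns <- df$normalized_signal
    if (any(!is.na(ns) & (ns < 0 | ns > 1))) abort("normalized_signal must lie in [0, 1]")
  }
  arrange(as_tibble(df), .data$position)
}

#' Read a cleavage time course (CSV)
#'
#' Expected columns: `time_s` (seconds, non-negative, strictly
#' increasing after ordering) and `fraction_cleaved` in \[0, 1\].
#'
#' @param path Path to a comma-separated file with a header row.
#' @return A tibble with columns `time_s`, `fraction_cleaved`.
#' @export
read_timecourse_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_s", "fraction_cleaved")
  if (!all(need %in% names(df))) {
    abort(sprintf("time-course CSV must have columns %s", paste(need, collapse = ", ")))
  }
  df <- arrange(as_tibble(df[need]), .data$time_s)
  validate_timecourse(df)
  df
}

validate_timecourse <- function(tc) {
  if (any(tc$time_s < 0)) abort("times must be non-negative")
  if (any(diff(tc$time_s) <= 0)) abort("times must be strictly increasing")
  if (any(tc$fraction_cleaved < 0 | tc$fraction_cleaved > 1)) {
    abort("fraction_cleaved must lie in [0, 1]")
  }
  invisible(tc)
}

#' Bundled hairpin substrate fixtures
#'
#' Path to (or parsed records of) the FASTA file of the four hairpin
#' oligo substrates used in the in-vitro cleavage assays: the S. pombe
#' BIP1 and SPAC4G9.15 Ire1 cleavage-site hairpins, the S. cerevisiae
#' HAC1 3' splice-site hairpin, and the human XBP1 3' splice-site
#' hairpin.
#'
#' @return `hairpin_fixture_path()`: the file path;
#'   `load_hairpin_fixtures()`: a named list of `rna_sequence`.
#' @export
hairpin_fixture_path <- function() {
  system.file("extdata", "hairpin_substrates.fasta", package = "ire1rna", mustWork = TRUE)
}

#' @rdname hairpin_fixture_path
#' @export
load_hairpin_fixtures <- function() {
  seqs <- read_fasta(hairpin_fixture_path())
  setNames(seqs, vapply(seqs, seq_id, character(1)))
}
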