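#' RNA sequence objects
#'
#' An `rna_sequence` is an identified RNA string over the alphabet
#' \{A, C, G, U\} with 1-based coordinates. On construction, DNA-style
#' input is canonicalised: lowercase is raised and `T` becomes `U`.
#' Any other letter is an error that names the offending position.
#'
#' @param residues Character scalar, the sequence (ACGU/acgt mix accepted).
#' @param id Character scalar identifier.
#' @return An `rna_sequence` object (character scalar with `id` attribute).
#' @examples
#' rna_sequence("ACGT", id = "x") # canonicalised to ACGU
#' @export
rna_sequence <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1L)
  res <- canonicalize_rna(residues)
  structure(res, id = as.character(id), class = "rna_sequence")
}

canonicalize_rna <- function(x) {
  res <- chartr("acgut", "ACGUU", x)
  res <- gsub("T", "U", res, fixed = TRUE)
  bad <- regexpr("[^ACGU]", res)
  if (bad > 0L) {
    abort(sprintf(
      "non-ACGU residue '%s' at position %d after canonicalization",
      substr(res, bad, bad), bad
    ))
  }
  res
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %s (%d nt)\n%s\n",
              seq_id(x), nchar(x), unclass(x)))
  invisible(x)
}

#' Sequence accessors
#'
#' @param x An `rna_sequence` (or plain character scalar).
#' @return `seq_id()` the identifier; `seq_length()` the length in nt;
#'   `seq_residues()` the plain character string; `seq_chars()` a
#'   character vector of single bases.
#' @export
seq_id <- function(x) attr(x, "id") %||% "seq"

#' @rdname seq_id
#' @export
seq_length <- function(x) nchar(unclass(x))

#' @rdname seq_id
#' @export
seq_residues <- function(x) unclass(x)[[1L]]

#' @rdname seq_id
#' @export
seq_chars <- function(x) strsplit(seq_residues(x), "", fixed = TRUE)[[1L]]

`%||%` <- function(a, b) if (is.null(a)) b else a

as_rna <- function(x, id = NULL) {
  if (inherits(x, "rna_sequence")) return(x)
  rna_sequence(x, id = id %||% "seq")
}

RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

#' Reverse complement of an RNA string
#'
#' @param x RNA sequence (character or `rna_sequence`).
#' @return Character scalar, the reverse complement.
#' @export
rna_revcomp <- function(x) {
  ch <- seq_chars(as_rna(x))
  paste(rev(unname(RNA_COMPLEMENT[ch])), collapse = "")
}

#' Extract a subsequence (1-based, inclusive)
#'
#' @param x RNA sequence.
#' @param start,end 1-based bounds.
#' @return Character scalar.
#' @export
rna_subseq <- function(x, start, end) {
  n <- seq_length(as_rna(x))
  if (start < 1L || end > n || start > end + 1L) {
    abort(sprintf("subsequence [%d, %d] out of range for length %d", start, end, n))
  }
  if (start > end) return("")
  substr(seq_residues(as_rna(x)), start, end)
}
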