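#' Extract the probing window around a scissile bond
#'
#' The analysis window spans `anchor - (halfwidth - 1)` to
#' `anchor + halfwidth` (38 nt for the default halfwidth of 19),
#' where `anchor` is the nucleotide 5' of the scissile bond. Windows
#' are clipped at sequence ends with a warning.
#'
#' @param records Tibble of per-base reactivity records (`position`,
#'   `base`, `raw_signal`, optionally `normalized_signal`).
#' @param anchor_bond 1-based index of the nucleotide 5' of the bond.
#' @param seq_length Length of the parent sequence (for clipping).
#' @param halfwidth Window halfwidth in nt (default 19).
#' @return The records restricted to the window, with attributes
#'   `anchor_bond` and `window` (the position range kept).
#' @export
reactivity_window <- function(records, anchor_bond, seq_length = NULL,
                              halfwidth = 19L) {
  lo <- anchor_bond - (halfwidth - 1L)
  hi <- anchor_bond + halfwidth
  lo_c <- max(1L, lo)
  hi_c <- if (is.null(seq_length)) hi else min(seq_length, hi)
  if (lo_c > lo || hi_c < hi) {
    warn(sprintf("probing window clipped to [%d, %d] at sequence bounds", lo_c, hi_c))
  }
  out <- records[records$position >= lo_c & records$position <= hi_c, ]
  attr(out, "anchor_bond") <- as.integer(anchor_bond)
  attr(out, "window") <- c(lo_c, hi_c)
  out
}

#' Max-normalise DMS signals over a window
#'
#' The most reactive base in the window gets a normalised signal of 1
#' and all other raw signals are scaled proportionally
#' (`raw / max(raw)`). An all-zero window normalises to all zeros.
#' Normalisation is invariant to rescaling all raw signals by any
#' positive constant.
#'
#' @param records Tibble with `position`, `base`, `raw_signal` (window
#'   attributes from [reactivity_window()] are preserved).
#' @return The same tibble with a `normalized_signal` column.
#' @export
normalize_window <- function(records) {
  if (nrow(records) == 0L) abort("cannot normalise an empty window")
  if (any(records$raw_signal < 0)) abort("raw signals must be non-negative")
  m <- max(records$raw_signal)
  out <- mutate(records,
                normalized_signal = if (m > 0) .data$raw_signal / m else 0)
  attributes(out)[c("anchor_bond", "window")] <-
    attributes(records)[c("anchor_bond", "window")]
  out
}

#' Derive folding constraints from normalised DMS signals
#'
#' Positions whose normalised DMS modification signal strictly exceeds
#' `threshold` are forced single-stranded. Only adenine and cytosine
#' can report DMS modification, so G/U positions are never constrained
#' regardless of signal.
#'
#' @param records Normalised reactivity records (must carry
#'   `normalized_signal`; see [normalize_window()]).
#' @param threshold Reactivity cutoff (default 0.2, strict `>`).
#' @return A [fold_constraints()] vector of global (sequence)
#'   positions.
#' @export
derive_constraints <- function(records, threshold = 0.2) {
  if (!"normalized_signal" %in% names(records)) {
    abort("records are not normalised; run normalize_window() first")
  }
  sel <- records$normalized_signal > threshold & records$base %in% c("A", "C")
  fold_constraints(records$position[sel])
}

#' Probe-directed folding of a scissile-bond window
#'
#' The full probing-to-structure procedure for one candidate cleavage
#' site: extract the window around the bond, max-normalise the raw DMS
#' signals, convert reactive A/C positions (normalised signal >
#' `threshold`) into single-stranded constraints, and fold the window
#' subsequence under those constraints.
#'
#' @param seq The parent RNA sequence.
#' @param records Raw per-base reactivity records for (at least) the
#'   window around the bond.
#' @param bond_index Scissile bond: index of the nucleotide 5' of the
#'   cut.
#' @param model An [energy_model()].
#' @param threshold Reactivity cutoff (default 0.2).
#' @param halfwidth Window halfwidth in nt (default 19).
#' @return A list with `structure` (window-local `rna_structure`),
#'   `offset` (add to window-local positions to get sequence
#'   positions), `window` (position range), `constraints`
#'   (window-local), `records` (the normalised window records).
#' @export
probe_and_fold <- function(seq, records, bond_index, model = energy_model(),
                           threshold = 0.2, halfwidth = 19L) {
  seq <- as_rna(seq)
  n <- seq_length(seq)
  if (bond_index < 1L || bond_index >= n) abort("bond index outside sequence")
  if (any(records$position < 1L | records$position > n)) {
    abort("reactivity records reference positions beyond the sequence")
  }
  win <- reactivity_window(records, bond_index, seq_length = n, halfwidth = halfwidth)
  span <- attr(win, "window")
  if (span[2L] - span[1L] + 1L < 10L) {
    abort("probing window shorter than 10 nt after clipping")
  }
  norm <- normalize_window(win)
  global_constraints <- derive_constraints(norm, threshold = threshold)
  offset <- span[1L] - 1L
  local_constraints <- fold_constraints(as.integer(global_constraints) - offset)
  sub <- rna_sequence(rna_subseq(seq, span[1L], span[2L]),
                      id = sprintf("%s_win%d-%d", seq_id(seq), span[1L], span[2L]))
  st <- fold_mfe(sub, constraints = local_constraints, model = model)
  list(structure = st, offset = offset, window = span,
       constraints = local_constraints, records = norm)
}
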