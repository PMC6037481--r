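#' RNA secondary structure objects
#'
#' An `rna_structure` holds a nested (pseudoknot-free) base-pair table
#' over a sequence of length `n`: entry `i` of `pair_table` is the
#' partner of position `i`, or 0 if unpaired. Structures carry the free
#' energy (kcal/mol) assigned by the energy model that produced them.
#'
#' Invariants enforced at construction:
#' * involution: `pair_table[pair_table[i]] == i` for every paired `i`;
#' * nestedness: no crossing pairs;
#' * minimum hairpin loop of 3 unpaired bases (`j - i >= 4`).
#'
#' @param pair_table Integer vector; `pair_table[i]` is the partner of
#'   position `i` or 0.
#' @param energy Free energy in kcal/mol.
#' @return An `rna_structure`.
#' @export
rna_structure <- function(pair_table, energy = NA_real_) {
  pt <- as.integer(pair_table)
  n <- length(pt)
  paired <- which(pt > 0L)
  if (any(pt < 0L) || any(pt > n)) abort("pair_table entries must lie in [0, n]")
  if (!all(pt[pt[paired]] == paired)) abort("pair_table is not an involution")
  if (any(pt[paired] == paired)) abort("a position cannot pair with itself")
  ii <- paired[paired < pt[paired]]
  jj <- pt[ii]
  if (any(jj - ii < 4L)) abort("hairpin loop smaller than 3 unpaired bases")
  if (is_crossing(ii, jj)) abort("pair table contains crossing pairs (pseudoknot)")
  structure(list(pair_table = pt, energy = as.numeric(energy), length = n),
            class = "rna_structure")
}

is_crossing <- function(ii, jj) {
  k <- length(ii)
  if (k < 2L) return(FALSE)
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      i <- ii[a]; j <- jj[a]; p <- ii[b]; q <- jj[b]
      if ((i < p && p < j && j < q) || (p < i && i < q && q < j)) return(TRUE)
    }
  }
  FALSE
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("<rna_structure> %d nt, %d pairs, %.2f kcal/mol\n%s\n",
              x$length, sum(x$pair_table > 0L) %/% 2L, x$energy, dot_bracket(x)))
  invisible(x)
}

#' Dot-bracket string for a structure
#'
#' @param structure An `rna_structure`.
#' @return Character scalar in Vienna dot-bracket notation.
#' @export
dot_bracket <- function(structure) {
  pt <- structure$pair_table
  ch <- rep(".", structure$length)
  ch[pt > 0L & seq_along(pt) < pt] <- "("
  ch[pt > 0L & seq_along(pt) > pt] <- ")"
  paste(ch, collapse = "")
}

#' Parse a dot-bracket string into a pair table
#'
#' @param db Character scalar of `.`, `(` and `)`.
#' @param energy Optional energy to attach.
#' @return An `rna_structure`.
#' @export
parse_dotbracket <- function(db, energy = NA_real_) {
  ch <- strsplit(db, "", fixed = TRUE)[[1L]]
  if (!all(ch %in% c(".", "(", ")"))) abort("dot-bracket may contain only . ( )")
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) abort(sprintf("unmatched ')' at position %d", i))
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack) > 0L) abort(sprintf("unmatched '(' at position %d", stack[1L]))
  rna_structure(pt, energy = energy)
}

#' Enumerate hairpin loops of a structure
#'
#' A hairpin loop is a pair (i, j) with every position i+1..j-1
#' unpaired. Loops are reported 5' to 3' by closing-pair position.
#'
#' @param structure An `rna_structure`.
#' @return A tibble with columns `closing_i`, `closing_j`, `loop_start`,
#'   `loop_end`, `size` (nt in the loop).
#' @export
hairpin_loops <- function(structure) {
  pt <- structure$pair_table
  out <- list()
  for (i in seq_along(pt)) {
    j <- pt[i]
    if (j > i && all(pt[(i + 1L):(j - 1L)] == 0L)) {
      out[[length(out) + 1L]] <- tibble(
        closing_i = i, closing_j = j,
        loop_start = i + 1L, loop_end = j - 1L, size = j - i - 1L
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(closing_i = integer(), closing_j = integer(),
                  loop_start = integer(), loop_end = integer(), size = integer()))
  }
  bind_rows(out)
}

#' Loop context of a scissile bond
#'
#' A scissile bond is identified by the index `i` of the nucleotide 5'
#' of the cut (the bond joins `i` and `i + 1`). If both flanking
#' positions lie unpaired in the same hairpin loop of size `L`, the
#' bond's ordinal among the loop's `L - 1` internal bonds is
#' `b = i - loop_start + 1` and its offset from the loop centre is
#' `|b - L/2|` (in bonds).
#'
#' @param structure An `rna_structure`.
#' @param bond_index Integer, 1 <= i < length.
#' @return A one-row tibble with `bond_index`, `in_loop`, and (when in a
#'   loop) `loop_start`, `loop_end`, `loop_size`, `bond_ordinal`,
#'   `center_offset`; NA geometry columns otherwise.
#' @export
scissile_bond_context <- function(structure, bond_index) {
  i <- as.integer(bond_index)
  if (i < 1L || i >= structure$length) {
    abort(sprintf("bond index %d outside [1, %d)", i, structure$length))
  }
  loops <- hairpin_loops(structure)
  hit <- loops[loops$loop_start <= i & i + 1L <= loops$loop_end, ]
  if (nrow(hit) == 0L) {
    return(tibble(bond_index = i, in_loop = FALSE,
                  loop_start = NA_integer_, loop_end = NA_integer_,
                  loop_size = NA_integer_, bond_ordinal = NA_integer_,
                  center_offset = NA_real_))
  }
  b <- i - hit$loop_start[1L] + 1L
  L <- hit$size[1L]
  tibble(bond_index = i, in_loop = TRUE,
         loop_start = hit$loop_start[1L], loop_end = hit$loop_end[1L],
         loop_size = L, bond_ordinal = b,
         center_offset = abs(b - L / 2))
}
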