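#' Nearest-neighbour RNA energy model (37 degrees C)
#'
#' Versioned parameter table for the minimum-free-energy folding
#' engine: Watson-Crick/wobble stacking free energies, hairpin, bulge
#' and internal-loop initiation terms tabulated for loop lengths up to
#' 30 with a `1.75 * RT * log(n/30)` extrapolation beyond, an affine
#' multibranch-loop penalty, and an internal-loop asymmetry penalty.
#' All energies are in kcal/mol at 37 degrees C (RT = 0.6163 kcal/mol).
#'
#' The set deliberately omits dangling ends, coaxial stacking, special
#' tetraloop bonuses and terminal AU/GU helix-end penalties, keeping
#' the dynamic program and its loop-decomposition audit small; absolute
#' energies therefore differ from full Turner-parameter folders, while
#' loop-size outcomes on short stem-loops are the intended accuracy
#' surface (see the methods vignette).
#'
#' @param max_interior Maximum total unpaired length of a bulge or
#'   internal loop considered by the folding engine (default 30).
#' @return An object of class `energy_model`: a list with elements
#'   `stack` (6x6 matrix over pair types AU, UA, CG, GC, GU, UG),
#'   `hairpin`, `bulge`, `internal` (initiation tables), `asym_per_nt`,
#'   `asym_max`, `multibranch` (a = closing, b = per branch, c = per
#'   unpaired nt), `rt`, `max_interior`, `version`, `temperature_label`.
#' @export
energy_model <- function(max_interior = 30L) {
  rt <- 0.6163
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  S <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  base <- c(
    "AU:AU" = -0.93, "AU:CG" = -2.24, "AU:GC" = -2.08, "AU:UA" = -1.10,
    "UA:AU" = -1.33, "UA:CG" = -2.35, "UA:GC" = -2.11,
    "CG:CG" = -3.26, "CG:GC" = -2.36, "GC:CG" = -3.42,
    "AU:GU" = -0.55, "AU:UG" = -1.36, "UA:GU" = -1.00, "UA:UG" = -1.27,
    "CG:GU" = -1.41, "CG:UG" = -2.11, "GC:GU" = -1.53, "GC:UG" = -2.51,
    "GU:GU" = -0.50, "GU:UG" = 1.29, "UG:GU" = 0.30
  )
  revp <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (nm in names(base)) {
    p <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    S[p[1L], p[2L]] <- base[[nm]]
    S[revp(p[2L]), revp(p[1L])] <- base[[nm]]
  }
  stopifnot(!anyNA(S))

  extrap <- function(anchor_n, anchor_g, n) anchor_g + 1.75 * rt * log(n / anchor_n)
  hp <- c(`3` = 5.4, `4` = 5.6, `5` = 5.7, `6` = 5.4, `7` = 6.0, `8` = 5.5, `9` = 6.4)
  hairpin <- setNames(numeric(28), as.character(3:30))
  hairpin[names(hp)] <- hp
  for (n in 10:30) hairpin[as.character(n)] <- extrap(9, hp[["9"]], n)

  bl <- c(`1` = 3.8, `2` = 2.8, `3` = 3.2, `4` = 3.6, `5` = 4.0, `6` = 4.4)
  bulge <- setNames(numeric(30), as.character(1:30))
  bulge[names(bl)] <- bl
  for (n in 7:30) bulge[as.character(n)] <- extrap(6, bl[["6"]], n)

  il <- c(`2` = 1.7, `3` = 1.8, `4` = 1.7, `5` = 2.0, `6` = 2.0)
  internal <- setNames(numeric(29), as.character(2:30))
  internal[names(il)] <- il
  for (n in 7:30) internal[as.character(n)] <- extrap(6, il[["6"]], n)

  structure(list(
    stack = S,
    hairpin = hairpin, bulge = bulge, internal = internal,
    asym_per_nt = 0.6, asym_max = 3.0,
    multibranch = c(a = 3.4, b = 0.4, c = 0.0),
    rt = rt, max_interior = as.integer(max_interior),
    version = "v1", temperature_label = "37C"
  ), class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model %s> nearest-neighbour, %s, max interior %d nt\n",
              x$version, x$temperature_label, x$max_interior))
  invisible(x)
}

PAIR_TYPE <- local({
  m <- matrix(NA_character_, 4, 4, dimnames = list(c("A", "C", "G", "U"), c("A", "C", "G", "U")))
  m["A", "U"] <- "AU"; m["U", "A"] <- "UA"
  m["C", "G"] <- "CG"; m["G", "C"] <- "GC"
  m["G", "U"] <- "GU"; m["U", "G"] <- "UG"
  m
})

pair_type <- function(a, b) PAIR_TYPE[a, b]

can_pair_bases <- function(a, b) !is.na(PAIR_TYPE[cbind(a, b)])

hairpin_term <- function(model, size) {
  if (size < 3L) return(Inf)
  if (size <= 30L) model$hairpin[[as.character(size)]]
  else model$hairpin[["30"]] + 1.75 * model$rt * log(size / 30)
}

bulge_term <- function(model, size) {
  if (size <= 30L) model$bulge[[as.character(size)]]
  else model$bulge[["30"]] + 1.75 * model$rt * log(size / 30)
}

internal_term <- function(model, l1, l2) {
  n <- l1 + l2
  init <- if (n <= 30L) model$internal[[as.character(n)]]
          else model$internal[["30"]] + 1.75 * model$rt * log(n / 30)
  init + min(model$asym_max, model$asym_per_nt * abs(l1 - l2))
}

# Energy of the loop closed by pair (i, j) given the directly enclosed
# pairs (k, l); ch is the character vector of the sequence.
loop_term <- function(model, ch, i, j, k = NULL, l = NULL) {
  outer <- pair_type(ch[i], ch[j])
  if (is.null(k) || length(k) == 0L) return(hairpin_term(model, j - i - 1L))
  if (length(k) == 1L) {
    inner <- pair_type(ch[k], ch[l])
    l1 <- k - i - 1L; l2 <- j - l - 1L
    if (l1 == 0L && l2 == 0L) return(model$stack[outer, inner])
    if (l1 == 0L || l2 == 0L) {
      e <- bulge_term(model, l1 + l2)
      # a single-nucleotide bulge preserves the helical stack
      if (l1 + l2 == 1L) e <- e + model$stack[outer, inner]
      return(e)
    }
    return(internal_term(model, l1, l2))
  }
  mb <- model$multibranch
  unpaired <- (j - i - 1L) - sum(l - k + 1L)
  mb[["a"]] + mb[["b"]] * (length(k) + 1L) + mb[["c"]] * unpaired
}

#' Recompute a structure's energy from its loop decomposition
#'
#' Walks the pair table, classifies every loop (hairpin, stack, bulge,
#' internal, multibranch; the exterior loop contributes 0) and sums the
#' model terms. Used as an audit that the folding engine's reported
#' energy equals the sum of its parts.
#'
#' @param seq RNA sequence.
#' @param structure An `rna_structure` for that sequence.
#' @param model An `energy_model`.
#' @return Energy in kcal/mol.
#' @export
structure_energy <- function(seq, structure, model = energy_model()) {
  seq <- as_rna(seq)
  ch <- seq_chars(seq)
  pt <- structure$pair_table
  stopifnot(length(pt) == length(ch))
  total <- 0
  opens <- which(pt > seq_along(pt))
  for (i in opens) {
    j <- pt[i]
    kids_k <- integer(0); kids_l <- integer(0)
    p <- i + 1L
    while (p < j) {
      if (pt[p] > p) {
        kids_k <- c(kids_k, p); kids_l <- c(kids_l, pt[p])
        p <- pt[p] + 1L
      } else p <- p + 1L
    }
    total <- total + loop_term(model, ch, i, j, kids_k, kids_l)
  }
  total
}
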