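#' Fold constraints
#'
#' A set of 1-based positions forced to stay single-stranded (hard
#' constraint, mirroring "force unpaired" in constraint-aware folding
#' programs): a constrained position is excluded from every base pair.
#'
#' @param forced_single_stranded Integer vector of 1-based positions.
#' @param length Sequence length the constraints refer to (optional;
#'   checked at fold time in any case).
#' @return An integer vector of class `fold_constraints`.
#' @export
fold_constraints <- function(forced_single_stranded = integer(), length = NULL) {
  p <- sort(unique(as.integer(forced_single_stranded)))
  if (length(p) && (any(p < 1L) || (!is.null(length) && any(p > length)))) {
    abort("constrained positions outside [1, length]")
  }
  structure(p, class = "fold_constraints")
}

check_constraints <- function(constraints, n) {
  p <- sort(unique(as.integer(constraints %||% integer())))
  if (length(p) && (p[1L] < 1L || p[length(p)] > n)) {
    abort(sprintf("constrained positions outside [1, %d]", n))
  }
  p
}

# ---- Minimum-free-energy folding (Zuker-style) ------------------------------

#' Constrained minimum-free-energy secondary structure
#'
#' Nested secondary-structure prediction by dynamic programming over
#' the nearest-neighbour [energy_model()]: hairpin, stacking, bulge,
#' internal (total unpaired length capped at `model$max_interior`) and
#' affine multibranch loop terms. Watson-Crick (AU, UA, CG, GC) and
#' wobble (GU, UG) pairs are allowed; hairpin loops hold at least 3
#' unpaired bases. Positions listed in `constraints` are excluded from
#' all pairs. Traceback is deterministic: among co-optimal branches it
#' prefers, in order, stacking, the 5'-most interior pair, the 5'-most
#' multibranch split, and only then closing a hairpin, so ties resolve
#' toward more-paired, 5'-first structures.
#'
#' @param seq RNA sequence (character or `rna_sequence`).
#' @param constraints Positions forced single-stranded
#'   ([fold_constraints()] or plain integer vector), or NULL.
#' @param model An [energy_model()].
#' @return An `rna_structure` whose `energy` is the minimum free energy
#'   (0 for sequences shorter than 5 nt, returned all-unpaired).
#' @examples
#' fold_mfe("GGGGAAACCCC")
#' @export
fold_mfe <- function(seq, constraints = NULL, model = energy_model()) {
  seq <- as_rna(seq)
  ch <- seq_chars(seq)
  n <- length(ch)
  forced <- check_constraints(constraints, max(n, 1L))
  if (n < 5L) return(rna_structure(integer(n), energy = 0))

  maxint <- model$max_interior
  mb <- model$multibranch
  S <- model$stack

  ok <- outer(ch, ch, can_pair_bases)
  if (length(forced)) { ok[forced, ] <- FALSE; ok[, forced] <- FALSE }
  span_ok <- ok & (outer(seq_len(n), seq_len(n), function(i, j) j - i >= 4L))

  INF <- Inf
  V <- matrix(INF, n, n)
  WM <- matrix(INF, n, n)
  # precompute loop-length tables as plain vectors for speed
  hp_tab <- vapply(3:max(3L, n), function(s) hairpin_term(model, s), numeric(1))
  bu_tab <- vapply(1:max(1L, n), function(s) bulge_term(model, s), numeric(1))

  ptype <- function(i, j) PAIR_TYPE[ch[i], ch[j]]

  for (d in 4L:(n - 1L)) {
    for (i in seq_len(n - d)) {
      j <- i + d
      if (span_ok[i, j]) {
        best <- hp_tab[j - i - 1L - 2L]
        # stack
        if (j - i >= 6L && span_ok[i + 1L, j - 1L]) {
          e <- S[ptype(i, j), ptype(i + 1L, j - 1L)] + V[i + 1L, j - 1L]
          if (e < best) best <- e
        }
        # bulge / internal loops (total unpaired 1..maxint)
        kmax <- min(i + 1L + maxint, j - 5L)
        {
          for (k in (i + 1L):max(i + 1L, kmax)) {
            l1 <- k - i - 1L
            if (l1 > maxint) break
            lmin <- max(k + 4L, j - 1L - (maxint - l1))
            lmax <- j - 1L
            if (lmin > lmax) next
            ls <- lmin:lmax
            ls <- ls[span_ok[k, ls] & !(l1 == 0L & ls == j - 1L)]
            if (length(ls) == 0L) next
            l2 <- j - ls - 1L
            if (l1 == 0L) {
              e <- bu_tab[l2] + V[k, ls]
              one <- which(l2 == 1L)
              if (length(one)) {
                e[one] <- e[one] + S[ptype(i, j), ptype(k, ls[one])]
              }
            } else {
              e <- numeric(length(ls))
              zero2 <- l2 == 0L
              if (any(zero2)) {
                e[zero2] <- bu_tab[l1] + V[k, ls[zero2]] +
                  if (l1 == 1L) S[ptype(i, j), ptype(k, ls[zero2])] else 0
              }
              if (any(!zero2)) {
                nz <- which(!zero2)
                e[nz] <- vapply(nz, function(q) internal_term(model, l1, l2[q]), numeric(1)) +
                  V[k, ls[nz]]
              }
            }
            m <- min(e)
            if (m < best) best <- m
          }
        }
        # multibranch
        if (j - i >= 10L) {
          ms <- (i + 1L):(j - 2L)
          if (length(ms) > 1L) {
            em <- WM[i + 1L, ms] + WM[cbind(ms + 1L, rep(j - 1L, length(ms)))]
            m <- suppressWarnings(min(em))
            if (mb[["a"]] + mb[["b"]] + m < best) best <- mb[["a"]] + mb[["b"]] + m
          }
        }
        V[i, j] <- best
      }
      # WM over the same span
      w <- INF
      if (span_ok[i, j] && V[i, j] + mb[["b"]] < w) w <- V[i, j] + mb[["b"]]
      if (WM[i + 1L, j] < w) w <- WM[i + 1L, j]
      if (WM[i, j - 1L] < w) w <- WM[i, j - 1L]
      if (j - i >= 9L) {
        ks <- (i + 4L):(j - 5L)
        if (length(ks)) {
          es <- WM[i, ks] + WM[cbind(ks + 1L, rep(j, length(ks)))]
          m <- suppressWarnings(min(es))
          if (m < w) w <- m
        }
      }
      WM[i, j] <- w
    }
  }

  # exterior loop
  W <- numeric(n + 1L) # W[j+1] = min energy of prefix 1..j
  for (j in seq_len(n)) {
    w <- W[j]
    if (j >= 5L) {
      is <- 1L:(j - 4L)
      cand <- W[is] + V[cbind(is, rep(j, length(is)))]
      m <- suppressWarnings(min(cand))
      if (m < w) w <- m
    }
    W[j + 1L] <- w
  }

  eps <- 1e-7
  pt <- integer(n)

  trace_v <- function(i, j) {
    pt[i] <<- j; pt[j] <<- i
    target <- V[i, j]
    # stack
    if (j - i >= 6L && span_ok[i + 1L, j - 1L]) {
      e <- S[ptype(i, j), ptype(i + 1L, j - 1L)] + V[i + 1L, j - 1L]
      if (e <= target + eps) return(trace_v(i + 1L, j - 1L))
    }
    # interior
    kmax <- min(i + 1L + maxint, j - 5L)
    for (k in (i + 1L):max(i + 1L, kmax)) {
      l1 <- k - i - 1L
      if (l1 > maxint) break
      lmax <- j - 1L
      lmin <- max(k + 4L, j - 1L - (maxint - l1))
      if (lmin > lmax) next
      for (l in lmax:lmin) {
        if (!span_ok[k, l] || (l1 == 0L && l == j - 1L)) next
        e <- loop_term(model, ch, i, j, k, l) + V[k, l]
        if (e <= target + eps) return(trace_v(k, l))
      }
    }
    # multibranch
    if (j - i >= 10L) {
      for (m in (i + 1L):(j - 2L)) {
        if (is.finite(WM[i + 1L, m]) && is.finite(WM[m + 1L, j - 1L]) &&
            mb[["a"]] + mb[["b"]] + WM[i + 1L, m] + WM[m + 1L, j - 1L] <= target + eps) {
          trace_wm(i + 1L, m); trace_wm(m + 1L, j - 1L)
          return(invisible())
        }
      }
    }
    invisible() # hairpin: nothing enclosed
  }

  trace_wm <- function(i, j) {
    target <- WM[i, j]
    if (span_ok[i, j] && V[i, j] + mb[["b"]] <= target + eps) return(trace_v(i, j))
    if (j - i >= 9L) {
      for (k in (i + 4L):(j - 5L)) {
        if (WM[i, k] + WM[k + 1L, j] <= target + eps) {
          trace_wm(i, k); trace_wm(k + 1L, j)
          return(invisible())
        }
      }
    }
    if (WM[i + 1L, j] <= target + eps) return(trace_wm(i + 1L, j))
    if (WM[i, j - 1L] <= target + eps) return(trace_wm(i, j - 1L))
    abort("internal error: multiloop traceback failed")
  }

  trace_w <- function(j) {
    while (j >= 5L) {
      target <- W[j + 1L]
      if (target >= W[j] - eps && target <= W[j] + eps) {
        # check whether a pair ending at j attains the optimum 5'-first
        paired <- FALSE
        for (i in 1L:(j - 4L)) {
          if (span_ok[i, j] && W[i] + V[i, j] <= target + eps) {
            trace_v(i, j); j <- i - 1L; paired <- TRUE; break
          }
        }
        if (!paired) j <- j - 1L
      } else {
        done <- FALSE
        for (i in 1L:(j - 4L)) {
          if (span_ok[i, j] && W[i] + V[i, j] <= target + eps) {
            trace_v(i, j); j <- i - 1L; done <- TRUE; break
          }
        }
        if (!done) abort("internal error: exterior traceback failed")
      }
    }
  }
  trace_w(n)

  rna_structure(pt, energy = if (is.finite(W[n + 1L])) W[n + 1L] else 0)
}

# ---- Base-pair maximisation (Nussinov-style oracle mode) --------------------

#' Maximum base-pair structure (Nussinov-style)
#'
#' Maximises the number of base pairs under the same pairing rules
#' (WC + wobble, minimum hairpin loop 3, hard single-stranded
#' constraints) with no energy model. Intended as a cross-check target
#' for the thermodynamic folder and for enumeration oracles in tests;
#' never used in the analysis pipeline.
#'
#' @inheritParams fold_mfe
#' @return An `rna_structure`; its `energy` field is `NA` (pair count
#'   is the objective, not an energy).
#' @export
fold_maxpair <- function(seq, constraints = NULL) {
  seq <- as_rna(seq)
  ch <- seq_chars(seq)
  n <- length(ch)
  forced <- check_constraints(constraints, max(n, 1L))
  if (n < 5L) return(rna_structure(integer(n), energy = NA_real_))

  ok <- outer(ch, ch, can_pair_bases)
  if (length(forced)) { ok[forced, ] <- FALSE; ok[, forced] <- FALSE }

  M <- matrix(0L, n, n)
  for (d in 4L:(n - 1L)) {
    for (i in seq_len(n - d)) {
      j <- i + d
      best <- M[i, j - 1L]
      ks <- i:(j - 4L)
      ks <- ks[ok[ks, j]]
      for (k in ks) {
        left <- if (k > i) M[i, k - 1L] else 0L
        inner <- if (j - k >= 5L) M[k + 1L, j - 1L] else 0L
        cand <- left + 1L + inner
        if (cand > best) best <- cand
      }
      M[i, j] <- best
    }
  }

  pt <- integer(n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    while (j - i >= 4L) {
      if (M[i, j] == M[i, j - 1L]) { j <- j - 1L; next }
      ks <- i:(j - 4L)
      ks <- ks[ok[ks, j]]
      for (k in ks) {
        left <- if (k > i) M[i, k - 1L] else 0L
        inner <- if (j - k >= 5L) M[k + 1L, j - 1L] else 0L
        if (left + 1L + inner == M[i, j]) {
          pt[k] <- j; pt[j] <- k
          if (j - k >= 5L) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
          j <- k - 1L
          break
        }
      }
      if (j < i) break
    }
  }

  rna_structure(pt, energy = NA_real_)
}

#' Count pairs of a structure
#' @param structure An `rna_structure`.
#' @return Integer number of base pairs.
#' @export
n_pairs <- function(structure) sum(structure$pair_table > 0L) %/% 2L
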