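#' Species-specific Ire1 recognition rules
#'
#' Executable form of the sequence + structure requirements that
#' distinguish the two yeast Ire1 RNases:
#'
#' * **S. cerevisiae**: consensus `CNG|CNGN` or `CNG|ANGN` (`|` marks
#'   the scissile bond, N any base) situated in a strictly conserved
#'   7-membered loop, read in register: the 7-nt loop itself must spell
#'   the consensus with the bond between loop positions 3 and 4.
#' * **S. pombe**: the trinucleotide `UG|C`, in a hairpin loop of
#'   tolerated size 3 to 9 nt, with the bond near the loop centre
#'   (offset at most `center_tolerance` = 1 bond); no register
#'   requirement.
#'
#' A motif is given as upstream/downstream templates around the bond
#' over \{A, C, G, U, N\}.
#'
#' @param species `"S_cerevisiae"` or `"S_pombe"` (abbreviations `sc`,
#'   `sp` accepted).
#' @param loop_size_range Inclusive loop-size bounds (nt); default per
#'   species.
#' @param center_tolerance Maximum allowed bond offset from the loop
#'   centre, in bonds (`Inf` disables the check when a register is
#'   enforced instead).
#' @return A `species_rule` list with elements `species`, `motifs`
#'   (list of `list(up, down)` templates), `loop_size_range`,
#'   `center_tolerance`, `register` (`"loop3|4"` or `"free"`).
#' @export
species_rule <- function(species = c("S_cerevisiae", "S_pombe", "sc", "sp"),
                         loop_size_range = NULL, center_tolerance = NULL) {
  species <- match.arg(species)
  if (species %in% c("sc", "sp")) {
    species <- c(sc = "S_cerevisiae", sp = "S_pombe")[[species]]
  }
  if (species == "S_cerevisiae") {
    rule <- list(
      species = species,
      motifs = list(list(up = "CNG", down = "CNGN"), list(up = "CNG", down = "ANGN")),
      loop_size_range = loop_size_range %||% c(7L, 7L),
      center_tolerance = center_tolerance %||% Inf,
      register = "loop3|4"
    )
  } else {
    rule <- list(
      species = species,
      motifs = list(list(up = "UG", down = "C")),
      loop_size_range = loop_size_range %||% c(3L, 9L),
      center_tolerance = center_tolerance %||% 1,
      register = "free"
    )
  }
  structure(rule, class = "species_rule")
}

#' @export
print.species_rule <- function(x, ...) {
  pats <- vapply(x$motifs, function(m) paste0(m$up, "|", m$down), character(1))
  cat(sprintf("<species_rule> %s: motif %s, loop %d-%d nt, register %s\n",
              x$species, paste(pats, collapse = " or "),
              x$loop_size_range[1L], x$loop_size_range[2L], x$register))
  invisible(x)
}

template_matches <- function(chars, template) {
  tch <- strsplit(template, "", fixed = TRUE)[[1L]]
  length(chars) == length(tch) && all(tch == "N" | tch == chars)
}

# Returns the matched motif string around bond i, or NA.
motif_at_bond <- function(ch, i, rule) {
  for (m in rule$motifs) {
    lu <- nchar(m$up); ld <- nchar(m$down)
    if (i - lu + 1L < 1L || i + ld > length(ch)) next
    up <- ch[(i - lu + 1L):i]
    down <- ch[(i + 1L):(i + ld)]
    if (template_matches(up, m$up) && template_matches(down, m$down)) {
      return(paste0(paste(up, collapse = ""), "|", paste(down, collapse = "")))
    }
  }
  NA_character_
}

#' Scan a sequence for motif-matching bonds
#'
#' Pure sequence scan: every scissile bond whose flanking residues
#' match the rule's motif (no structural filtering).
#'
#' @param seq RNA sequence.
#' @param rule A [species_rule()].
#' @return A tibble with `bond_index` and `matched_motif`.
#' @export
scan_motifs <- function(seq, rule = species_rule("S_pombe")) {
  ch <- seq_chars(as_rna(seq))
  n <- length(ch)
  hits <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      m <- motif_at_bond(ch, i, rule)
      if (!is.na(m)) hits[[length(hits) + 1L]] <- tibble(bond_index = i, matched_motif = m)
    }
  }
  if (length(hits) == 0L) return(tibble(bond_index = integer(), matched_motif = character()))
  bind_rows(hits)
}

#' Classify a candidate cleavage site
#'
#' Combines the sequence motif with loop geometry: a bond is called a
#' substrate iff (1) the motif matches, (2) both bond-flanking
#' nucleotides are unpaired inside the same hairpin loop, (3) the loop
#' size lies in the rule's range, and (4) the register requirement (S.
#' cerevisiae: bond between loop positions 3 and 4) or the centrality
#' requirement (offset from the loop centre at most
#' `center_tolerance`) is met.
#'
#' @param seq RNA sequence.
#' @param structure Its `rna_structure`.
#' @param bond_index Scissile bond (nt 5' of the cut).
#' @param rule A [species_rule()].
#' @return A one-row tibble: `species`, `bond_index`, `matched_motif`,
#'   check columns (`motif`, `in_loop`, `loop_size`, `centrality`,
#'   each "pass"/"fail"/"skipped"), loop geometry columns, and
#'   `verdict` ("substrate"/"non-substrate") with `reason` (first
#'   failing check or "pass").
#' @export
classify_site <- function(seq, structure, bond_index, rule = species_rule("S_pombe")) {
  seq <- as_rna(seq)
  ch <- seq_chars(seq)
  i <- as.integer(bond_index)
  if (i < 1L || i >= length(ch)) abort("bond index outside sequence")
  if (structure$length != length(ch)) abort("structure length != sequence length")

  motif <- motif_at_bond(ch, i, rule)
  ctx <- scissile_bond_context(structure, i)

  checks <- c(motif = if (!is.na(motif)) "pass" else "fail",
              in_loop = if (ctx$in_loop) "pass" else "fail",
              loop_size = "skipped", centrality = "skipped")
  if (ctx$in_loop) {
    ok_size <- ctx$loop_size >= rule$loop_size_range[1L] &&
      ctx$loop_size <= rule$loop_size_range[2L]
    checks[["loop_size"]] <- if (ok_size) "pass" else "fail"
    ok_center <- if (rule$register == "loop3|4") {
      ctx$bond_ordinal == 3L
    } else {
      ctx$center_offset <= rule$center_tolerance
    }
    checks[["centrality"]] <- if (ok_center) "pass" else "fail"
  }
  verdict <- if (all(checks %in% c("pass"))) "substrate" else "non-substrate"
  failing <- names(checks)[checks == "fail"]
  reason <- if (length(failing)) failing[1L] else "pass"
  reason <- c(motif = "motif fail", in_loop = "not in loop",
              loop_size = "loop size", centrality = "centrality",
              pass = "pass")[[reason]]

  tibble(species = rule$species, bond_index = i,
         matched_motif = motif,
         motif = checks[["motif"]], in_loop = checks[["in_loop"]],
         loop_size_check = checks[["loop_size"]], centrality = checks[["centrality"]],
         loop_size = ctx$loop_size, bond_ordinal = ctx$bond_ordinal,
         center_offset = ctx$center_offset,
         verdict = verdict, reason = reason)
}

#' Which species call a bond a substrate?
#'
#' Applies both default species rules to the same site.
#'
#' @inheritParams classify_site
#' @return Character vector, a subset of
#'   `c("S_cerevisiae", "S_pombe")`.
#' @export
dual_specificity <- function(seq, structure, bond_index) {
  calls <- bind_rows(
    classify_site(seq, structure, bond_index, species_rule("S_cerevisiae")),
    classify_site(seq, structure, bond_index, species_rule("S_pombe"))
  )
  calls$species[calls$verdict == "substrate"]
}

#' Minimal substitutions that install a cleavage motif
#'
#' Finds the smallest set of point substitutions around a bond that
#' makes the rule's motif match, searching every motif alternative and
#' breaking ties toward 5'-most edits. The mutated sequence is
#' refolded and the site reclassified so the caller can confirm the
#' edit preserved the stem-loop.
#'
#' @inheritParams classify_site
#' @param model Energy model used for the confirmation refold.
#' @return A list with `substitutions` (tibble `position`, `from`,
#'   `to`; zero rows when the motif already matches), `mutated_seq`,
#'   and `call` (reclassification of the mutated sequence at the same
#'   bond).
#' @export
mutate_to_motif <- function(seq, bond_index, rule = species_rule("S_pombe"),
                            model = energy_model()) {
  seq <- as_rna(seq)
  ch <- seq_chars(seq)
  i <- as.integer(bond_index)

  best <- NULL
  for (m in rule$motifs) {
    lu <- nchar(m$up); ld <- nchar(m$down)
    if (i - lu + 1L < 1L || i + ld > length(ch)) next
    pos <- (i - lu + 1L):(i + ld)
    tch <- strsplit(paste0(m$up, m$down), "", fixed = TRUE)[[1L]]
    need <- tch != "N" & tch != ch[pos]
    cand <- tibble(position = pos[need], from = ch[pos][need], to = tch[need])
    if (is.null(best) || nrow(cand) < nrow(best) ||
        (nrow(cand) == nrow(best) && nrow(cand) > 0L &&
         isTRUE(cand$position[1L] < best$position[1L]))) {
      best <- cand
    }
  }
  if (is.null(best)) abort("bond too close to the sequence end for this motif")

  mch <- ch
  if (nrow(best) > 0L) mch[best$position] <- best$to
  mutated <- rna_sequence(paste(mch, collapse = ""), id = paste0(seq_id(seq), "_mut"))
  st <- fold_mfe(mutated, model = model)
  list(substitutions = best, mutated_seq = mutated,
       call = classify_site(mutated, st, i, rule))
}
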