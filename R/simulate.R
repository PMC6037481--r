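#' Simulation parameters for DMS count profiles
#'
#' Three-channel Poisson model of per-base DMS reverse-transcription
#' stop counts: unpaired (exposed) A/C bases modify strongly, paired
#' A/C weakly, and G/U essentially not at all. Defaults put the
#' channels far enough apart that, after max-normalisation, the 0.2
#' constraint threshold cleanly separates pairing states at nominal
#' coverage.
#'
#' @param lambda_exposed Mean count for unpaired A/C (default 50).
#' @param lambda_protected Mean count for paired A/C (default 3).
#' @param lambda_gu Mean count for G/U (default 0.5).
#' @param coverage Nominal read coverage (informational; default 1000).
#' @return A `dms_sim_params` list.
#' @export
dms_sim_params <- function(lambda_exposed = 50, lambda_protected = 3,
                           lambda_gu = 0.5, coverage = 1000) {
  if (!(lambda_exposed > lambda_protected && lambda_protected >= lambda_gu &&
        lambda_gu >= 0)) {
    abort("need lambda_exposed > lambda_protected >= lambda_gu >= 0")
  }
  structure(list(lambda_exposed = lambda_exposed,
                 lambda_protected = lambda_protected,
                 lambda_gu = lambda_gu, coverage = coverage),
            class = "dms_sim_params")
}

#' Simulate a per-base DMS count profile from a known structure
#'
#' Draws each position's raw signal from a Poisson law whose mean is
#' set by the base and its true pairing state (see
#' [dms_sim_params()]). Byte-reproducible under `seed`.
#'
#' @param seq RNA sequence.
#' @param structure The true `rna_structure` for `seq`.
#' @param params A [dms_sim_params()].
#' @param seed Integer seed.
#' @return A tibble of raw reactivity records: `position`, `base`,
#'   `raw_signal`.
#' @export
simulate_dms <- function(seq, structure, params = dms_sim_params(), seed = 1L) {
  seq <- as_rna(seq)
  ch <- seq_chars(seq)
  if (structure$length != length(ch)) abort("structure length != sequence length")
  lambda <- ifelse(ch %in% c("A", "C"),
                   ifelse(structure$pair_table > 0L,
                          params$lambda_protected, params$lambda_exposed),
                   params$lambda_gu)
  withr::with_seed(as.integer(seed), {
    counts <- rpois(length(ch), lambda)
  })
  tibble(position = seq_along(ch), base = ch, raw_signal = as.numeric(counts))
}

#' Simulate a noisy first-order cleavage time course
#'
#' `f_j = clamp(1 - exp(-k t_j) + e_j, 0, 1)` with
#' `e_j ~ Normal(0, sigma)` (additive truncated-Gaussian noise, the
#' gel-densitometry error model). Byte-reproducible under `seed`.
#'
#' @param k Rate constant (1/s, >= 0).
#' @param times Strictly increasing non-negative times (s).
#' @param sigma Noise standard deviation on the fraction scale.
#' @param seed Integer seed.
#' @return A tibble with `time_s`, `fraction_cleaved`.
#' @export
simulate_timecourse <- function(k, times = seq(0, 3600, length.out = 8),
                                sigma = 0.02, seed = 1L) {
  if (k < 0) abort("k must be non-negative")
  if (any(times < 0) || any(diff(times) <= 0)) {
    abort("times must be non-negative and strictly increasing")
  }
  mu <- 1 - exp(-k * times)
  withr::with_seed(as.integer(seed), {
    eps <- rnorm(length(times), 0, sigma)
  })
  tibble(time_s = times, fraction_cleaved = pmin(1, pmax(0, mu + eps)))
}

#' Specification of a synthetic stem-loop
#'
#' @param stem_length Stem length in bp (>= 4).
#' @param loop_sequence Loop sequence (>= 3 nt); place a motif here to
#'   implant a cleavage site (e.g. "AAUGCAA" carries UG|C at the
#'   central bond).
#' @param flank_lengths Length of the 5' and 3' random flanks (length-2
#'   integer vector or scalar).
#' @param gc_bias Probability that a stem pair is G-C (default 0.7;
#'   strong stems keep the intended fold dominant).
#' @return A `hairpin_spec` list.
#' @export
hairpin_spec <- function(stem_length = 10L, loop_sequence = "AAUGCAA",
                         flank_lengths = c(6L, 6L), gc_bias = 0.7) {
  loop_sequence <- canonicalize_rna(loop_sequence)
  if (nchar(loop_sequence) < 3L) abort("loop must hold at least 3 nt")
  if (stem_length < 4L) abort("stem must be at least 4 bp")
  if (length(flank_lengths) == 1L) flank_lengths <- rep(flank_lengths, 2L)
  structure(list(stem_length = as.integer(stem_length),
                 loop_sequence = loop_sequence,
                 flank_lengths = as.integer(flank_lengths),
                 gc_bias = gc_bias),
            class = "hairpin_spec")
}

#' Generate a random sequence containing a designed stem-loop
#'
#' Builds `5' flank + stem + loop + revcomp(stem) + 3' flank` with a
#' perfectly complementary Watson-Crick stem and rejection-samples the
#' random parts until the MFE fold of the full sequence reproduces the
#' intended hairpin loop exactly (at most `max_attempts` attempts).
#' Flanks are drawn A/U-rich so they rarely compete with the stem.
#'
#' @param spec A [hairpin_spec()].
#' @param seed Integer seed (attempt `a` uses `seed + a - 1`).
#' @param model Energy model used for the verification fold.
#' @param max_attempts Rejection budget (default 100).
#' @return A list: `seq` (`rna_sequence`), `structure` (true
#'   `rna_structure` of the full sequence), `loop_start`, `loop_end`
#'   (global loop coordinates), `scissile_bond` (centre bond of the
#'   loop, the implant anchor), `attempts`.
#' @export
make_hairpin <- function(spec = hairpin_spec(), seed = 1L,
                         model = energy_model(), max_attempts = 100L) {
  loop_len <- nchar(spec$loop_sequence)
  for (a in seq_len(max_attempts)) {
    withr::with_seed(as.integer(seed) + a - 1L, {
      top <- sample(c("A", "C", "G", "U"), spec$stem_length, replace = TRUE,
                    prob = c((1 - spec$gc_bias) / 2, spec$gc_bias / 2,
                             spec$gc_bias / 2, (1 - spec$gc_bias) / 2))
      f5 <- sample(c("A", "U", "C", "G"), spec$flank_lengths[1L], replace = TRUE,
                   prob = c(0.4, 0.4, 0.1, 0.1))
      f3 <- sample(c("A", "U", "C", "G"), spec$flank_lengths[2L], replace = TRUE,
                   prob = c(0.4, 0.4, 0.1, 0.1))
    })
    stem5 <- paste(top, collapse = "")
    full <- paste0(paste(f5, collapse = ""), stem5, spec$loop_sequence,
                   rna_revcomp(stem5), paste(f3, collapse = ""))
    seq <- rna_sequence(full, id = sprintf("hairpin_s%d", seed))
    loop_start <- spec$flank_lengths[1L] + spec$stem_length + 1L
    loop_end <- loop_start + loop_len - 1L

    st <- fold_mfe(seq, model = model)
    loops <- hairpin_loops(st)
    hit <- loops[loops$loop_start == loop_start & loops$loop_end == loop_end, ]
    if (nrow(hit) == 1L) {
      bond <- loop_start + (loop_len - 1L) %/% 2L
      return(list(seq = seq, structure = st,
                  loop_start = loop_start, loop_end = loop_end,
                  scissile_bond = bond, attempts = a))
    }
  }
  abort(sprintf(
    "no fold reproduced the intended loop in %d attempts; use a longer stem",
    max_attempts))
}
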