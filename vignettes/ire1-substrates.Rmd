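---
title: "Ire1 substrate stem-loops: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ire1 substrate stem-loops: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ire1rna)
library(tibble)
```

## The biological problem

Ire1 is the ER-membrane kinase/endoribonuclease at the heart of the
unfolded protein response (UPR). Its cytosolic kinase/RNase (KR) domain
cleaves specific phosphodiester bonds — scissile bonds, written `UG|C`
with `|` at the cut — presented in mRNA stem-loops. The two yeast
lineages have split this activity into two modes: *S. cerevisiae* Ire1
is a stringent splicing enzyme whose only cellular substrate is *HAC1*
mRNA, while *S. pombe* Ire1 is a promiscuous RIDD nuclease that
initiates decay of many ER-targeted mRNAs. `ire1rna` makes the
recognition rules that separate these modes executable, along with the
surrounding quantitative workflow: structure probing to constrained
folding, cleavage-site classification, first-order cleavage kinetics,
and the design of synthetic non-conventional splicing cassettes.

## Constrained MFE folding

`fold_mfe()` is a nested (pseudoknot-free) minimum-free-energy dynamic
program over a nearest-neighbour model at 37 °C (`energy_model()`):
stacking terms for all Watson–Crick and G·U wobble pair combinations,
hairpin/bulge/internal-loop initiation tables for lengths up to 30 with
`1.75·RT·ln(n/30)` extrapolation beyond, an internal-loop asymmetry
penalty (0.6 kcal/mol per nt, capped at 3.0), and an affine multibranch
penalty (offset 3.4, 0.4 per branch). Hairpin loops keep at least 3
unpaired bases. The parameter table is versioned (`v1`) and embedded in
code, so folds are reproducible against a fixed, auditable set.

Several refinements are deliberately omitted: dangling ends, coaxial
stacking, tetraloop bonuses, and terminal AU/GU helix-end penalties.
They are not needed to discriminate the loop sizes of short Ire1
substrate hairpins — the accuracy surface this package targets — and
omitting them keeps the audit exact: `structure_energy()` recomputes
any returned structure's energy from its loop decomposition and must
match the DP's number to 1e-6, which is enforced in the tests. The
trade-off is that *absolute* energies differ from full
Turner-parameter folders such as mfold or RNAfold; loop geometry, not
free energy, is the quantity we reproduce (a test cross-checks loop
sizes, not energies, against RNAfold where it is installed).

Why an energy model at all? Pure base-pair maximisation
(`fold_maxpair()`, a Nussinov-style mode kept strictly as a testing
oracle) provably over-pairs real substrates. The human *XBP1* 3'
splice-site hairpin is the clean example: maximisation buys an eighth
pair by pinching the 7-membered loop into a 3-loop plus a 1×1 internal
loop, but under the energy model that costs an internal-loop initiation
plus a worse hairpin term than it recovers in stacking, so the
7-membered loop stands:

```{r xbp1}
xbp1 <- load_hairpin_fixtures()$XBP1
fold_mfe(xbp1)
n_pairs(fold_maxpair(xbp1))
```

Hard constraints (`fold_constraints()`) remove positions from all
pairs, mirroring "force unpaired" in constraint-aware folders.
Traceback ties are broken deterministically — stacking first, then the
5'-most interior pair, then the 5'-most multibranch split, then hairpin
closure — a fixed branch order that favours more-paired, 5'-first
structures without tracking an exact pair-count among co-optimals; two
runs on the same input always give the same pair table.

## From DMS probing signals to constraints

Dimethyl sulfate methylates solvent-exposed, unpaired adenines and
cytosines; reverse transcription stops at the adducts, so per-base stop
counts report pairing state for A/C only. The normalisation is the
max-anchored one: within the 38-nt window centred on the scissile bond
(19 nt either side; `reactivity_window()`), the most reactive base is
set to 1 and the rest scaled proportionally (`normalize_window()`).
Positions with normalised signal strictly greater than 0.2 — and only
A/C positions — become single-stranded constraints
(`derive_constraints()`), and the window is refolded under them
(`probe_and_fold()`). The 0.2 threshold and the 19-nt halfwidth are
exposed as arguments with these defaults. Because the normalisation is
scale-invariant, any non-negative per-base score (counts, count/coverage
ratios) gives identical constraints; the package therefore does not
prescribe an upstream read-processing pipeline.

Windows are clipped at transcript ends with a warning (3' UTR cleavage
sites can sit near the end); a clipped window shorter than 10 nt is an
error.

## The species rules

`species_rule()` encodes the two recognition modes:

* **S. cerevisiae** — motif `CNG|CNGN` or `CNG|ANGN` in a strictly
  conserved 7-membered loop, read in register: the loop itself must
  spell the 7-nt consensus with the bond between loop positions 3
  and 4.
* **S. pombe** — motif `UG|C` in a loop of 3 to 9 nt, bond near the
  loop centre, no register requirement.

"Near the centre" is formalised as the bond's offset from the loop
midpoint, in bonds: a loop of size L has L−1 internal bonds with
ordinals b = 1..L−1, and the offset is |b − L/2|; the default tolerance
is 1 bond. All three verifiable printed substrates (the *XBP1* 7-loop,
the *SPAC4G9.15* 3-loop, the *BIP1* 9-loop) place their scissile bond
at offset 0.5. The 9-nt ceiling on the *S. pombe* loop range is the
largest observed loop, not a mechanistic bound, so it is configurable.
Loops closed by a G·U wobble count as loops — the *HAC1* 3' splice-site
hairpin requires this, its 7-loop being closed by U·G. A site is a
substrate only when both bond-flanking nucleotides are unpaired in the
same hairpin loop; a motif half-buried in a stem fails as "not in
loop", the strictest reading of loop presentation.

`classify_site()` reports every check separately (motif, in-loop, loop
size, centrality/register) so a failed design explains itself;
`mutate_to_motif()` searches the minimal point-substitution set that
installs a motif (ties resolved 5'-first) and refolds to confirm the
stem-loop survived the edit.

## Cleavage kinetics

Gel-quantified cleavage time courses (fraction cleaved vs time) are
fitted by `fit_kobs()` to the one-phase first-order model
`f(t) = 1 − exp(−k·t)` with the plateau fixed at 1 (complete
cleavage); a floating plateau is available for robustness studies but
is not the default model. When the whole course stays below 10%
cleavage the substrate concentration is effectively constant, and the
course is fitted instead to the initial-rate line `f = k·t` through
the origin — the documented linear-regime fallback for very slow
enzyme/substrate pairs. The nonlinear fit starts from the linear slope
of the first half of the course, removing initialisation sensitivity;
the reported uncertainty is the square root of the covariance diagonal
(SE of fit — where published "±" values are reproduced they are
treated as this quantity, the natural reading for single-course fits).
`fold_difference()` forms rate ratios with first-order error
propagation and returns an above-detection-limit sentinel when the
denominator rate is zero, mirroring how undetectable cleavage is
reported.

In the linear regime the slope estimator carries a small deterministic
bias (the curve is concave, so the line underestimates k by roughly
kT/2 at course length T — about 2–3% for the slowest substrates over an
hour); this is a property of the published fitting recipe itself and is
well inside the 10% recovery tolerance used throughout.

## Synthetic data: what it emulates and what it does not

The generator module provides every input with known truth:

* `simulate_dms()` — three-channel Poisson counts with means 50
  (unpaired A/C), 3 (paired A/C) and 0.5 (G/U). The channels encode
  only the qualitative contrast that probing detects exposed A/C; the
  default separation makes the 0.2 threshold essentially error-free at
  these means, which is what the probing-recovery tests measure.
  Real DMS-seq data add coverage gradients, RT-stop positional bias,
  protein protection and replicate variability, none of which are
  modelled — passing tests show the normalisation/constraint/folding
  logic is correct, not that real libraries reach the same accuracy.
* `simulate_timecourse()` — first-order curves with additive Gaussian
  noise (default σ = 0.02 on the fraction scale, a typical
  densitometry error), clamped to [0, 1].
* `make_hairpin()` — random flanks around a perfectly complementary
  stem and a designed loop, rejection-sampled until the full-sequence
  MFE fold reproduces the intended loop; defaults (stems of 8–13 bp
  with 70% GC, A/U-rich flanks) make rejection rare. Real cleavage
  sites sit in imperfect stems with bulges; the generator's perfect
  stems are deliberately idealised ground truth.

All generators are byte-reproducible under an explicit integer seed.

## The splicing cassette

`design_cassette()` emits the package's reference synthetic splicing
cassette: two stem-loops, each presenting `UG|C` near the centre of a
7-membered loop (so each junction independently satisfies the
*S. pombe* rule), flanking a 30-nt intron — the pruned-intron
architecture of the engineered non-conventional splicing substrate.
The published construct's nucleotide sequence is not printed anywhere,
so the shipped cassette is a repository artifact designed and
validated by this package's own folding and classification modules,
not a reconstruction of the original. The two stems are distinct
8-bp sequences to prevent cross-pairing between junctions; the spacer
is A/U-rich and unstructured. `insert_cassette()` refolds each
junction's 38-nt window *in its host context* and reports per-junction
verdicts rather than throwing, because design iteration against
adversarial hosts (e.g. a UTR tract complementary to a junction loop)
is the intended workflow. `predict_splice_product()` performs the
cut-and-ligate arithmetic; spliced plus intron lengths always conserve
the input length, and re-inserting the excised intron reconstructs the
input exactly.

## Numerical and design choices, in brief

* Coordinates are 1-based; a scissile bond is the index of the
  nucleotide 5' of the cut. `T` is accepted on input and silently
  converted to `U` (oligo vendors mix alphabets); any other letter is
  an error naming the position.
* Interior loops are capped at 30 unpaired nt total (standard DP
  practice); the minimum hairpin loop is 3 nt.
* Sequences shorter than 5 nt fold trivially to all-unpaired, energy 0.
* Co-optimal folds resolve by the fixed traceback order above;
  determinism is tested, and structures round-trip exactly through
  dot-bracket and CT writers.
* Problem sizes in the test-suite properties were chosen to make each
  check statistically meaningful at interactive runtimes: 200 random
  sequences (n ≤ 18) against the exhaustive enumeration oracle, 100
  synthetic 38-nt probing windows for end-to-end structure recovery,
  and 500 simulated courses (k from 1e-5 to 5e-3 s⁻¹, log-uniform,
  sampling horizon matched to 3/k as an experimenter would) for fitter
  bias and confidence-interval calibration.

## Known limitations

* The folder handles no pseudoknots, suboptimal ensembles, partition
  functions or temperatures other than 37 °C.
* Absolute folding energies are not comparable to Turner-complete
  folders; only structure (loop geometry) is the supported output.
* The classifier is structural and qualitative: it predicts
  substrate/non-substrate, not cleavage rates, and encodes no
  oligomerisation, docking or membrane-targeting biology.
* The *S. pombe* loop-size ceiling (9) and centre tolerance (1 bond)
  are calibrated on few printed examples; both are arguments, not
  constants, for exactly that reason.

## A compact worked example

```{r worked}
fx <- load_hairpin_fixtures()
characterize_sequences(fx, species = "both") |>
  dplyr::filter(verdict == "substrate") |>
  dplyr::select(seq_id, species, bond_index, matched_motif, loop_size)

tc <- simulate_timecourse(9.4e-4, seq(0, 3600, length.out = 8),
                          sigma = 0.02, seed = 1)
glance(fit_kobs(tc))
```
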