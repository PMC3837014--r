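---
title: "Detecting alpha-solenoid repeats with a sliding-window neural network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alpha-solenoid repeats with a sliding-window neural network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The detection problem

Alpha-solenoids — HEAT, Armadillo, TPR, ankyrin and related repeat folds —
are stacks of helix–linker–helix units whose member sequences diverge
beyond the reach of profile and homology methods. What *is* conserved is
architecture: two roughly 19-residue amphipathic helices around a 1–3
residue turn, repeated with a unit period of some 30–40 residues.
`solenoidscan` detects that architecture directly. A small neural network
scores every residue of a query as a candidate *linker midpoint*, and a
protein is called a solenoid when enough high-scoring positions recur with
the expected periodicity.

## Model and assumptions

The scorer is a fixed 780–3–1 multilayer perceptron with logistic
activations throughout. The input is a one-hot encoding of 39 sequence
positions (19 + center + 19) over the 20 canonical residues. The output is
trained by online back-propagation on squared error, target 1 at annotated
linker midpoints and 0 elsewhere. Implied assumptions:

- *Locality*: whether a residue is a linker midpoint is decidable from its
  39-position context. Long-range structure is deliberately ignored; the
  periodicity requirement at calling time compensates.
- *Regression framing*: squared error on 0/1 targets, not cross-entropy —
  the output behaves as a score, and calling thresholds live in the upper
  tail (0.80–0.90) rather than at 0.5.
- *Variable linkers by window shift*: at scan time each helix window may be
  displaced one residue outward from the center, so four shift
  combinations (0,0), (1,0), (0,1), (1,1) realize linkers of 1–3 residues.
  The central residue always stays the 20th encoded position and the
  residues stepped over by a shifted window are simply not encoded,
  keeping the input at exactly 39 × 20. Only outward shifts are tested: a
  shift toward the center would overlap the linker rather than lengthen
  it.
- Non-canonical residues (X, B, Z, U, O, J) encode as all-zero blocks: a
  database scan must never abort mid-sequence, and an uninformative input
  is the honest representation of an unknown residue.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| score threshold | 0.87 | score in (0,1) | published operating point; 0.86 variant selectable |
| minimum chained hits | 3 | hits | fewer than 3 periodic units is weak evidence of a solenoid |
| spacing interval | [30, 135] | residues | consecutive chained hits; one unit period up to a few skipped units |
| suppression radius | 10 | residues | merges adjacent above-threshold scores from one linker; < 30 so true consecutive repeats are never merged |
| epochs | 500 | passes | small network, small corpus; converges well before this |
| learning rate | 0.1 | — | standard for online SGD on one-hot inputs of this size |
| negative examples | all eligible windows | — | see below |
| init scale | 0.1 | weight range | uniform [-0.1, 0.1]; symmetric, small |

The spacing rule constrains *consecutive members of the chain*, not all
hit pairs: an all-pairs reading would cap chains at about five hits and
contradict long solenoids. One consequence worth knowing: hits spaced
uniformly 29 apart *do* produce a positive call, because alternate hits
are 58 apart and chain validly. The chain is found by an O(n²) dynamic
program over position-sorted hits — the longest subsequence whose
consecutive gaps fall inside the interval, ties broken by higher total
score and then by smaller start position, endpoints inclusive.

## Training-set construction

One positive example per annotated midpoint (unshifted window). Negatives
are windows whose center lies more than 2 residues from every annotated
midpoint of their sequence — positions at ±1–2 are ambiguous given 1–3
residue linkers and belong to neither class. By default **every** eligible
window becomes a negative example rather than a small sample. This is a
deliberate design decision: with a few thousand sampled negatives the
separable synthetic task saturates the network while leaving the decision
boundary under-constrained, and held-out non-repeat sequence then chains
occasional false hits anywhere in the 0.80–0.90 threshold band. Training
on all negatives (~140k windows at the standard study scale) constrains
the boundary; the compiled SGD inner loop (Rcpp) keeps 500 epochs at this
scale around a minute. A finite `neg_ratio` remains available for
exploratory fits.

## The synthetic generator

`make_corpus()` stands in for the unpublished annotated training set. It
emulates: amphipathic helices (hydrophobics L/A/I/V/M/F on heptad-like a/d
positions approximating the 3.6-residue turn, polar/charged elsewhere, no
proline), turn-biased linkers drawn from G/P/D/N/S, inter-unit spacers of
0–2 residues, flanks and background of average globular composition, and
exact midpoint annotations (left-of-center for even linker lengths — a
fixed convention the window-shift scheme absorbs).

Helix length defaults to 16 so that unit periods land at 33–37 residues,
inside the expected 30–40 periodic range; the 19-residue *detection*
window then deliberately overhangs into neighbouring units, as it does on
real solenoids. (Two 19-residue helices plus a linker would force periods
of 39+, outside the canonical range — the 19 of the architecture is a
window length, not a helix length.)

What the generator does *not* emulate: homology between units or between
proteins, family-specific sequence signatures (HEAT vs ARM vs TPR),
insertions within solenoids, compositional drift of real proteomes, or
structured non-solenoid negatives (coiled coils are the natural hard
case). Passing tests therefore demonstrate that the machinery — encoding,
scanning, shifting, chaining, sweeping — behaves correctly and that the
pipeline can learn a clean architectural signal end-to-end; they do not
certify detection performance on real proteomes.

## Numerical and degenerate-input choices

- Shift ties prefer the smaller implied linker: (0,0), (1,0), (0,1), (1,1).
- Centers where only some shift combinations fit are scored over the
  in-bounds subset; scorable centers are exactly those admitting the
  unshifted window (20 … L−19), so sequences shorter than 39 residues
  yield an empty profile, written as a header-only TSV.
- Precision at zero predictions is `NA`, never 0 or 1 — an extreme
  threshold must not masquerade as a full-precision operating point. The
  operating-point rule falls back to the highest-precision point, flagged
  with a warning attribute, when no full-precision point exists.
- Model files serialize doubles as 17-significant-digit decimal strings,
  so save/load round-trips are bit-identical; files with mismatched
  architecture or parameter counts are rejected at load.
- A single seed drives initialization, negative sampling and per-epoch
  shuffling sequentially (one RNG stream), making fits and the full
  simulate→train→evaluate pipeline byte-reproducible.

## Problem sizes used by the test suite

The standard synthetic study is 200 solenoids of 3–10 units plus 800
background sequences of 150–500 residues, split 50/50, trained 500 epochs,
swept over thresholds 0.80–0.90; the suite requires full precision with at
least half the held-out solenoids recovered at the selected operating
point, and that window-shift recall on a linker-2/3 corpus is never below
fixed-window recall. Unit tests use miniature corpora (tens of sequences,
tens of epochs); the chain caller is validated against exhaustive
subsequence enumeration on 500 random hit sets, and the back-propagation
gradient against central finite differences at relative error < 1e-4.

## Known limitations

- Scores saturate near 0/1 on cleanly separable synthetic data, so the
  0.80–0.90 threshold band discriminates less than it would on real,
  noisier corpora.
- The caller reports one best chain; it does not delimit domain
  boundaries, count repeats beyond the chain, or type the repeat family.
- Training assumes midpoint annotations are exact to ±0 residues (the
  generator guarantees this; curated real corpora may not).
- The published large-scale benchmark (19,769 redundancy-reduced PDB
  clusters) is not reproducible here — it requires external clustering
  and curation pipelines — so quantitative claims are restricted to the
  synthetic study and printed-count arithmetic.
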