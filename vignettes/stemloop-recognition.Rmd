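---
title: "Recognizing 3'-end stem-loops: models, encodings and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing 3'-end stem-loops: models, encodings and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`stemloopr` asks whether the hairpin found near the 3′ end of a
retrotransposon-like sequence is *recognizable* — separable, by a
classifier, from the hairpins that arise by chance in sequences of identical
dinucleotide composition. This vignette records the science and the design
decisions behind each stage; the README shows the user-facing workflow.

## 1. The detection model

A stem-loop is parameterized by a loop interval, a stem of $k$ paired
positions per arm, and at most one bulge run per arm, strictly interior to
the arm. Pairing is canonical Watson–Crick on the DNA alphabet (A·T, C·G);
G·T wobble can be enabled (`allow_wobble`), but mismatch counts are defined
against Watson–Crick by default because that is how the annotation
constraints we inherit were stated. N never pairs and counts as a mismatch
inside a stem. All coordinates are 0-based and half-open.

Constraints (defaults in parentheses, all in `hairpin_params()`):
stem length 10–20 paired bp; loop length `loop_min`–`loop_max` (3–10 nt —
the 10-nt maximum is the annotation setting we inherit, the 3-nt minimum is
the smallest sterically sensible hairpin loop and is our choice, since only
the maximum was specified upstream); at most 5 mismatched stem positions;
at most one bulge run of ≤ 3 nt per arm. The 3-slot-per-arm bulge encoding
(Section 3) is why bulges are capped at 3 nt and why bulge nucleotides do
not consume the mismatch budget: they are unpaired by construction, not
mispaired.

**Search semantics.** The search enumerates every candidate loop interval
and bulge layout, and extends the stem outward from the loop with an
incremental mismatch count (a banded search: the band is the set of
diagonals reachable with one bulge run per arm). Three rules make the
output well-defined rather than a flood of overlapping sub-alignments:

* *Terminal pairs must match.* A stem opens and closes on a paired
  position; a trailing mismatch is not part of a helix, it is flank.
* *Best-per-loop.* For each loop interval, only configurations achieving
  the best (stem length ↓, mismatches ↑, total bulge ↑) triple are kept.
  The triple — rather than a finer tiebreak — is deliberate: it is
  invariant under strand reflection, so the output of a sequence maps,
  coordinate-reflected, onto the output of its reverse complement. Ties on
  the triple (different bulge layouts of equal quality) are all reported.
* *Maximality.* An annotation whose paired positions are all contained in
  another annotation's is dropped. This is what makes a perfect hairpin one
  annotation rather than a nest of sub-stems.

The same definition is implemented twice: an optimized C++ search
(`find_stem_loops()`) and an independently coded brute-force enumerator
(`stem_loops_exhaustive()`) that reconstructs and tests every partition
from scratch. The test suite asserts exact agreement on hundreds of random
sequences; the enumerator is the package's reference semantics.

**Terminal selection.** `select_terminal_stemloops()` keeps, per sequence,
the single best hairpin whose full span lies inside the terminal window
(50 nt by default) — containment, not mere overlap, because one feature
vector per element is wanted and a hairpin extending outside the window is
not a property of that window. Ranking: stem length ↓, mismatches ↑,
proximity to the terminus, then loop start (determinism).

**A property worth knowing:** under these permissive constraints (up to 5
mismatches in a 10-bp stem) qualifying hairpins are *abundant* — random
50-nt windows almost always contain one. The discriminative question is
therefore never "is there a hairpin?" but "what are its properties?", which
is exactly what the structure-based encoding measures. Consequently the
mismatch-relaxation monotonicity one might expect ("relaxing constraints
never removes a hairpin") holds only in restricted forms: maximality means
a relaxed, longer stem can *replace* stricter sub-annotations. The tests
pin down the two forms that do hold: the longest reported stem is monotone
under relaxation, and with a fixed stem length (where no annotation can
dominate another) the set of reported loops grows monotonically with the
mismatch budget.

## 2. The negative class: dinucleotide-preserving shuffling

Negatives are Altschul–Erikson shuffles: the sequence is an Eulerian walk
on its dinucleotide multigraph; a random last-edge arborescence toward the
final nucleotide is drawn (resampled until it spans), remaining edges are
permuted uniformly, and the walk is re-emitted. Length, endpoints, and the
exact multiset of overlapping dinucleotides — hence all mononucleotide
counts — are preserved; longer-range structure, including any planted
hairpin, is destroyed. This is the appropriate null for the claim that the
models read *structure*, not composition. Sequences containing N are
shuffled over the observed five-letter alphabet, preserving N-containing
dinucleotide counts, rather than distorting the alphabet by dropping them.
Each record's shuffle derives its seed as `seed + (i-1)*n_shuffles + (k-1)`,
so output is a pure function of (input, seed) and independent of batch
composition. One shuffle per positive (balanced classes) is the default.

## 3. Feature encodings

**Sequence-based (80 features).** Overlapping di- and trinucleotide counts
at step 1, each width divided by its window count (`length - k + 1`).
Normalizing by window count (rather than raw counts) removes length
dependence when windows are clipped below 50 nt; tree models are
insensitive to the choice, which is why it was safe to make. Windows
containing N are counted in the denominator but never in a numerator.
Feature order is fixed: lexicographic within width, dinucleotides first.

**Structure-based (134 features).** From each selected hairpin:

* *Stem block (90).* The ten loop-proximal paired bases of the **5′ (left)
  arm**, read 5′→3′ with T mapped to U, are split into nine overlapping
  dinucleotide steps indexed LS0 (loop-adjacent) to LS8. Each step emits
  ten property values in fixed order. Using the 5′ arm is a convention we
  fixed (the upstream description shows a single stem track); it is
  recorded in the feature names and applied uniformly to both classes, so
  no information asymmetry can result.
* *Loop block (20).* One-hot quartets over (A, C, G, T) for loop positions
  LP0–LP4 — only the first five positions, which is also why hairpins with
  loops shorter than 5 nt are ineligible for this representation.
* *Bulge block (24).* One-hot quartets for up to three bulge nucleotides
  per arm (LB0–LB2, RB0–RB2), filled loop-proximal first, zero-padded;
  hairpins without bulges contribute 24 zeros.

Eligibility (paired stem ≥ 10, loop ≥ 5, bulges ≤ 3) is applied
*identically* to positive and shuffled classes (`eligible_stemloops()`), so
the classifier cannot learn the filter instead of the structure. Because
the structure representation requires loops ≥ 5 anyway, the pipeline
detects with `loop_min = 5` for structure-scheme runs: otherwise the
best-per-loop rule may prefer a short-loop reading of a hairpin whose
loop-≥5 reading would have been eligible.

**The property table.** `dinuc_property_table()` ships 16 RNA dinucleotides
× 10 properties. Enthalpy (kcal/mol), entropy (cal/(mol·K)) and free energy
(kcal/mol, 37 °C) are the Watson–Crick nearest-neighbor parameters from
optical melting of RNA duplexes (Xia et al. 1998), in which each step
equals its reverse complement — a symmetry the tests assert. Hydrophilicity
follows the Weber–Lacey dinucleoside scale. The six helical step parameters
are transcribed A-form RNA crystallographic survey averages; they are
rounded survey means not tied to a specific database record, and the
bundled TSV says so in its provenance header. Values are used raw: random
forests are invariant to monotone per-feature rescaling, so only the
*ordering* of dinucleotides within each property matters, and that is what
the sources establish. A user can substitute their own table via the `path`
argument, subject to the same 16 × 10 validation.

## 4. Classification protocol

Probability random forests (`ranger`, 2000 trees, single-threaded, seeded).
The upstream experimental design reports single metric values without a
stated validation protocol; we chose seeded stratified 5-fold
cross-validation with across-fold means and standard deviations as a
defensible default at these dataset sizes. Per fold: ROC-AUC (via `pROC`,
direction fixed so random scores give ≈ 0.5) and accuracy, precision and
recall at a probability threshold of 0.5 (no calibration procedure was
specified, so none is invented); each fold's confusion matrix is exported
so every threshold metric can be recomputed exactly — a test does.
Importances are normalized impurity (Gini) importances from a final forest
on all data, summing to 1 — the stock measure of the ecosystem this design
originates from. `cross_apply()` scores a foreign feature set and reports
the fraction with positive-class probability ≥ 0.5;
`summarize_importances()` splits top-10 feature names into
`position:property` and tallies both parts across experiments (for loop and
bulge features the "property" is the one-hot nucleotide).

Degenerate inputs fail loudly: one-class datasets, classes with fewer than
two instances per fold, feature-name or scheme mismatches between classes
or between a model and a foreign set.

## 5. What the synthetic generator emulates — and what it does not

`synthesize_stemloop_set()` produces the study design in miniature:
sequences with a hairpin planted entirely inside the terminal 50 nt, with
controllable stem length, loop length or motif, interior mismatches, bulge
sizes, and an optional first-order dinucleotide bias for the stem arm.
Background is i.i.d. uniform ACGT — deliberately *not* genome-like, so the
null is clean and background hairpin rates are estimable. It does not
emulate poly-A tails, family phylogenies, truncation, or the shared
ancestry that makes real L1/Alu 3′ ends mutually similar; a passing test on
synthetic data therefore demonstrates that the machinery recovers signals
of the stated kind, not that real elements carry them.

Three guards make planted hairpins *exactly* recoverable, which the
round-trip tests require: (i) certified plants draw the loop from the
mutually non-pairing alphabet {A, C}, with boundary bases additionally
avoiding partners of the adjacent stem bases, so the detector cannot close
extra pairs inside the loop; (ii) the `max_mismatches + max_bulge` flanking
bases on each side are drawn from {A, C} on both sides, so every potential
extension pair — bulged or not — is a mismatch and no extension can satisfy
the terminal-match rule within the budget; (iii) with `certify = TRUE` the
sequence is re-detected after assembly (on a slack-padded terminal region,
which is equivalent for the terminal verdict and cheaper) and resampled
until the planted hairpin is exactly the top-ranked terminal stem-loop.
Without such guards no extension-maximal detector could return planted
coordinates exactly: chance background pairing extends a planted stem about
a third of the time. Mismatches are planted at interior stem positions
only, since a terminal mismatch by definition shortens the detected stem.
With a strongly self-similar stem bias (e.g. hard GG/CC), the planted
hairpin is inherently ambiguous — near-equivalent shifted readings exist —
so certification may not converge and should be disabled (`certify =
FALSE`); the classification experiments do exactly that, since they need
representative biased stems, not exact coordinates.

## 6. Problem sizes and numerical choices

Sizes used by the test suite and acceptance script (chosen as a scale at
which every estimate is stable yet a desktop run stays comfortable):
oracle-equivalence on 500 random sequences of 30–60 nt; shuffle
conservation on 1000 random 50-mers plus a 10,000-seed uniformity check on
a two-outcome case; null calibration with 250 + 250 identically distributed
sequences, 2000 trees, 5-fold CV; planted-bias recovery over 20 seeded
replicates of 100 positives (300 nt) against two shuffles each. The
planted-bias sequences are 300 nt so that shuffling dilutes the GC-rich
stem into the background — in short sequences the shuffled class inherits
the stem's composition and the structural signal is masked, which is a
property of the null, not a bug. For model building, detection runs on the
extracted terminal windows (where the models look); this is several-fold
faster than full-length detection and equivalent for window-contained
hairpins.

The null-calibration band (mean CV AUC in [0.45, 0.55] at n = 500) spans
roughly ±1.9 standard errors of the null sampling distribution: a correctly
calibrated pipeline will land outside it for a few percent of seeds, which
is the expected false-alarm rate of that check, not a defect.

Numerical conventions: feature matrices are written with `%.17g` formatting
and read with the base-R parser so that text round trips are bit-exact;
reports serialize with full precision and stable key order, making seeded
pipeline reruns byte-identical (a test asserts this through the `pipeline`
CLI subcommand). All randomness flows from explicit `seed` arguments
through derived per-record seeds; nothing reads or perturbs the global RNG
state outside `withr::with_seed()`.

## 7. Known limitations

* No thermodynamic folding: hairpins are called by combinatorial
  constraints, not minimum free energy; multibranch structures and
  pseudoknots are out of scope.
* The detector is exhaustive within its constraint set; external annotation
  tools with the same nominal parameters may report sparser calls, so
  absolute background rates are tool-relative (comparisons against shuffled
  controls, the package's core design, are unaffected).
* The helical parameters in the bundled table are rounded survey averages;
  analyses that depend on their absolute scale (none in this package —
  forests are scale-free) should source exact values.
* Importance tallies inherit the usual caveats of impurity importance
  (bias toward features with many split points); within a fixed encoding
  this affects comparisons between binary one-hot and continuous property
  features more than comparisons among property channels.
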