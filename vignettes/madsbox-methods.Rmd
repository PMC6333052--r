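---
title: "madsbox: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{madsbox: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records how the classifier works, which knobs matter, what
the synthetic benchmark does and does not demonstrate, and the design
decisions taken where the problem left genuine choices open.

## The two-stage model

MIKC-type MADS-box proteins share an N-to-C architecture of four
domains: the DNA-binding MADS (M) domain, a short intervening (I)
domain, the keratin-like (K) domain that forms a leucine-zipper-like
coiled-coil, and a variable C-terminal (C) domain. The system exploits
this architecture twice.

**Stage 1 — domain judgement.** A sequence is accepted as MIKC-type if
and only if it matches the configured M-domain PROSITE pattern; the
first (leftmost) match anchors the M span, extended to `m_length`
residues (default 57, the canonical MADS-domain length, truncated at the
sequence end). The K span is found by the in-package coiled-coil engine
(below); the I domain is the M-to-K gap when at least `min_i_length`
(default 5) residues long, and C is everything after K. Sequences
without an M match are rejected before any feature is computed; no
domain spans are reported for them.

The shipped M pattern covers the invariant core of the plant MADS
DNA-binding helix (the `KRIEN ... RQVT[FY] ... KRR` stretch). It is a
configuration file, not a fixed constant: stage-1 sensitivity on real
data is governed entirely by this pattern, and users working outside
flowering plants should review it.

**Stage 2 — feature encoding and routed classification.** Five
region-restricted reference databases (whole sequence, M, I, K, C) are
derived from the labeled training set. For a query region, alignment
against every member of each class database yields per-class average
bit scores (the eight-dimensional class-similarity vector); the M domain
additionally gets a per-position physicochemical encoding and the K
domain an aggregated coiled-coil probability triple. Nine feature
recipes — five per-region similarity models, M-physicochemical,
K-coiled-coil, and the two combinations — each train one multi-class
SVM. At prediction time a filtration step inspects the query's detected
domain content and routes it to the feasible model with the highest
recorded cross-validated accuracy. Whole-sequence models count as
feasible only for architecturally complete (M+I+K+C) queries, which is
what makes fragment inputs profit from the domain models.

## Alignment scoring

The similarity engine is optimal local alignment (Smith–Waterman) under
BLOSUM62 with affine gap costs: a gap of length L costs
`gap_open + L * gap_extend` with defaults 11/1. The dynamic program is
delegated to `Biostrings::pairwiseAlignment`; the statistics layer is
package code. Raw scores map to bit scores via the Karlin–Altschul
parameters λ = 0.267 nats and K = 0.041 (the standard published values
for gapped BLOSUM62-11/1), and e-values use a per-pair search space
`E = m·n·2^(−bits)`. Per-pair statistics (rather than database-summed
lengths) are the consistent choice here because features average
per-subject scores; the absolute e-value gate (1e-5) should be read
against that convention. `X` scores 0 against every residue, so
ambiguity neither rewards nor penalizes an alignment.

The e-value gate contract: a hit contributes to a class feature only
when its e-value is below the threshold; a class with no passing hit
scores exactly 0. Relaxing the threshold can therefore only add hits,
never remove them.

## The coiled-coil engine

For each window width w ∈ {14, 21, 28} and each placement, the window
score is the weighted geometric mean of per-residue propensities at
their heptad positions, with weights a,d = 2.5 and b,c,e,f,g = 1.0,
maximized over the 7 possible heptad frames. Each residue receives the
best score among windows covering it, the score maps to a probability
through a two-Gaussian likelihood ratio `P = G_cc/(G_cc + G_glob)`, and
the final per-residue probability is the maximum over the three widths.
Sequences shorter than the smallest window are flagged and scored 0.

The propensity table is package-authored (shipped as
`coils_propensity_synthetic.tsv`, and so labelled): it encodes the
canonical preferences — aliphatic hydrophobics strongly favored at a/d,
charged residues at e/g, proline strongly disfavored everywhere — rather
than reproducing any particular published matrix, whose exact values are
not redistributable here. The per-width Gaussian parameters were
calibrated once by a fixed procedure (`scratch/calibrate_coils.R`):
"coiled-coil" windows are sampled per heptad position with probability ∝
propensity² × background (concentrating on strongly preferred residues,
as in genuine coiled-coil segments), "globular" windows from background
composition alone, and a normal distribution is fitted to each score
sample per width. All tests of the engine are parameterized over
whatever table is loaded, so replacing the tables with other calibrated
values is supported.

**K-span boundaries.** The K domain is reported as the contiguous block
of window placements (at the largest feasible width) scoring within 90%
of the best placement downstream of M, with each end then trimmed at
residue level while the outermost four residues average below a weighted
log-propensity of 0.25 under the best heptad frame. The best placement
must reach coiled-coil probability ≥ 0.5 for a K span to be reported at
all. Two properties follow. First, on constructs with coil-neutral
flanks the recovered boundary sits within about ±3 residues of a planted
heptad block. Second, boundaries are *conservative*: in noisy regions
the span shrinks toward the strongest coiled-coil block rather than
expanding into ambiguous flanks. A consequence worth knowing: when
random flanking sequence happens to place hydrophobics at heptad spacing
the detected span legitimately extends into it — the signal is really
there — so planted-boundary recovery is only a well-posed expectation
when the flanks carry no coil signal.

Because detected K spans are conservative, training re-runs stage-1
detection on its own reference sequences by default (`rescan = TRUE` in
`mads_train`), so that reference databases and query features are built
from identically segmented regions. Training on externally curated spans
is available but mixes segmentation conventions between training and
prediction.

## The M-domain physicochemical encoding

The M domain's DNA-binding character is encoded per position as a
triplet of residue scales: side-chain pKa (non-ionizable side chains
fixed at neutral 7.0), Kyte–Doolittle hydropathy, and average residue
mass, each min-max normalized over the 20 residues. The layout is fixed
at 57 positions (171 values); shorter M regions are zero-padded and `X`
encodes as the per-scale means. This is a deliberately simple, fully
reproducible surrogate for retired black-box DNA-binding predictors: it
preserves the per-position physicochemical information such predictors
consume without depending on unpublished trained weights.

## Classifier, scaling and hyperparameters

Features are scaled to [0,1] per dimension with training-set min/max
(constant features collapse to 0; queries are clamped into the range).
The classifier is the LIBSVM C-SVC with RBF kernel via e1071, with
one-vs-one pairwise-coupled probability estimates — the eight confidence
scores are these coupled probabilities, renormalized, and the predicted
class is their argmax with ties broken by the fixed class order
(A, B12, B34, BPI, C, D, E, AGL6).

Hyperparameters are grid-searched under stratified 3-fold CV over a
coarse log-2 grid (C ∈ 2^{−5..15}, γ ∈ 2^{−15..3}, step 2⁴). Accuracy
ties — common on separable data — are re-scored by the cross-validated
mean probability assigned to the true class, because heavily
under-regularized settings can tie on hard predictions while producing
nearly flat probability estimates; remaining ties prefer the least
extreme settings. The recorded per-recipe CV accuracy used for routing
comes from an outer, leakage-free 3-fold CV in which the reference
databases themselves are rebuilt per fold from that fold's training
split, so held-out sequences never sit in the databases they are scored
against. Self-comparisons are excluded when encoding training sequences
against their own class.

All stochastic steps (fold assignment, SVM probability calibration, the
generator) run under explicit seeds; retraining with the same data and
seed reproduces identical predictions.

## The synthetic benchmark

The generator emulates an eight-class MIKC family at fixed study
conditions: 10 members per class; region lengths M = 57, I = 30, K = 70,
C = 60; within-class substitution rate 0.10 per site from each class
ancestor; and per-region extra divergence of the class ancestors from a
common root of M = 0.05, I = 0.25, K = 0.20, C = 0.40 — reproducing the
C > I > K > M diversity ordering observed in real MIKC families, where
the M domain is strongly conserved and the C domain most variable.
Substitutions are BLOSUM62-conditional (probability ∝ exp(s/2) for
replacements), keeping alignment statistics and the e-value gate
realistic. The M pattern site is repaired after mutation so every
simulated protein is pattern-positive, the K region is built from heptad
repeats with hydrophobic a/d positions, and each class carries a
mutation-exempt signature 8-mer in its C region that guarantees
learnable class signal concentrated where real families are most
discriminable.

What passing the synthetic benchmark shows: the pipeline's plumbing is
sound end to end — domain detection feeds feature encoding, routing
respects domain content, no information leaks across CV folds, and the
classifier recovers a class structure whose signal-to-noise roughly
matches a curated reference family. What it does not show: performance
on real MADS-box proteins, which have indels, length variation, rate
heterogeneity, and no planted signatures. The benchmark figures are
properties of the generator's conditions, not estimates of biological
accuracy. Problem sizes were chosen to mirror a realistic curated
reference set (~80 sequences) while keeping a full training run around
half a minute.

## Conservation module

Per-region diversity is summarized as the mean uncorrected p-distance
over all unordered pairs (pairwise deletion of gap/X columns), with the
pair-distance variance and a bootstrap standard error over alignment
columns (500 replicates, seeded). p-distance was chosen over
model-corrected distances because the quantity of interest is a bounded
[0,1] diversity ranking, not an evolutionary rate. The module expects
pre-aligned, equal-length rows; generator output satisfies this natively
(fixed region lengths, no indels) and real data should be aligned per
region with a standard aligner first — no aligner is bundled, since
alignment construction quality is outside this package's scope. The
`conservation_vs_accuracy` pairing reports the Spearman rank correlation
between region mean distance and the corresponding similarity model's
CV accuracy; on the generator it is positive by construction (divergence
is concentrated in C, where the signatures also live), which mirrors —
but does not independently confirm — the diversity–discriminability
correlation seen in real families.

## Degenerate inputs and edge rules

* Empty sequences, empty residue strings and unknown residue characters
  are rejected at parse time with the record named; B/Z/U/J/O/`*` map to
  `X` with a warning.
* Multiple M-pattern matches: the leftmost wins (the M domain is
  N-terminal).
* Coordinates are 0-based half-open everywhere; spans must be ordered
  M < I < K < C and non-overlapping, and `is_mikc` is true exactly when
  an M span exists.
* A query whose detected regions satisfy no model raises a routing
  error listing the regions present; non-MIKC queries are reported as
  rejected rows by the CLI rather than dropped.
* Fragment truncation requires a contiguous block of domains in
  architectural order (an M+C fragment without I and K is not a
  construct the system models).

## Known limitations

* Stage-1 sensitivity is bounded by one PROSITE pattern; deeply
  diverged M domains (or M-type, non-MIKC proteins, which the package
  deliberately does not model) fall outside it.
* Detected K boundaries are conservative and can truncate noisy K
  domains; downstream features tolerate this, but span coordinates
  should not be read as precise domain calls.
* The alignment engine is exact Smith–Waterman without heuristic
  acceleration; it is comfortable at reference-set scale (10² sequences)
  but not designed for genome-wide scans.
* Confidence calibration rests on LIBSVM's pairwise coupling with small
  per-class counts; confidences are comparable within a run and usable
  as a ranking, but are not guaranteed to be well-calibrated
  posteriors.
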