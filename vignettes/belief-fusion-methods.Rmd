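---
title: "Methods: similarity and machine-learning belief fusion for off-target liability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: belief fusion for off-target liability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

A compound progressing through a discovery program may bind proteins other
than its intended target; some of those off-targets (e.g. the serotonin 2B
receptor, hERG) carry well-known safety liabilities. This package estimates,
per safety-panel target, the likelihood that a query molecule is active —
defined throughout as IC50 ≤ 100 nM. The 100 nM cutoff captures clinically
relevant high-affinity interactions; micromolar interactions are deliberately
not flagged, since their clinical relevance is uncertain and including them
degrades dataset balance.

Two beliefs are computed and fused.

### The similarity belief

Across many targets, pairs of structurally similar molecules tend to share
activity. That tendency is quantified empirically: compound pairs are formed
from curated per-target data, binned by ECFP Tanimoto similarity into ten
bins of width 0.1, and the per-bin fraction of *active* pairs is fitted with

$$B_{ECFP}(x) = \frac{F_{max}}{1 + 10^{(SC_{50}-x)\cdot slope}}.$$

Pair classes follow the printed definitions exactly, read literally:

* **active pair** — at least one member active, |Δlog10 IC50| **<** 1;
* **inactive pair** — at least one member inactive, |Δlog10 IC50| **>** 1;
* **random pair** — one active and one decoy; counted as non-active evidence.

Both inequalities are strict, so pairs at exactly one log unit fall in
neither class, and two weak inactives within one log unit of each other are
used by neither rule — the definitions do not cover them, and we exclude
rather than reinterpret. Pairs are built within one target only and pooled
across targets for a single global curve; per-target curves are supported as
a diagnostic, but per-target pair counts vary by orders of magnitude and the
global fit is the served default. The shipped parameters
(`defaultCurveParams()`: F~max~ 0.842, SC~50~ 0.281, slope 3.417) are the
global fit over pooled safety-panel training pairs.

At prediction time the curve is evaluated at the *highest* similarity between
the query and the target's library of known actives — the query needs only
one close active analogue for strong evidence.

### The machine-learning belief

Per target, a binary classifier is trained on 2D physicochemical descriptors
(OpenBabel whole-molecule properties plus molecular-graph counts; see
`computeDescriptors()`). Descriptors are pruned in three stages — variance
below 1e-5, absolute pairwise Pearson correlation above 0.95 (the
later-ordered column is dropped, a deterministic tie-break), then the top 50
by impurity importance from a seeded random forest. Thresholds are
configurable; the source protocol names the stages but no values, so the
defaults are the common QSAR choices.

Six probability-emitting algorithms are tried: logistic regression, random
forest, extremely randomized trees, gradient-boosted trees, an RBF SVM
(scored through the logistic of its decision value, since libsvm's internal
probability fit is not reproducible from R), and a single-hidden-layer
neural network. The roster is an argument: any subset can be used, and the
original protocol does not enumerate its six, so the slot-in design is
deliberate. Each algorithm gets a small grid (≤ 2 combinations) and is
evaluated by stratified 5-fold cross-validation repeated 3 times with
identical, seeded folds; the active class is weighted by
n~inactive~/n~active~. The winner is the configuration with the highest mean
MCC — chosen over accuracy because panel datasets are imbalanced — and the
exported classifier is the winning configuration's single fold-model with
the highest fold MCC. Mean accuracy ≥ 0.75 and mean MCC ≥ 0.4 are recorded
as advisory flags in the bundle metadata, not enforced as gates.

Raw classifier scores are relative confidences, not probabilities, and the
fusion rule below assumes probabilities, so scores are calibrated. The
default is isotonic regression — a non-decreasing step function fit by
pool-adjacent-violators — with Platt (sigmoid) scaling available. Calibrators
are always fit on out-of-fold scores (5 folds): calibrating on scores the
classifier produced for its own training data would inherit its optimism.
Tied scores are pooled (mean label, weight = count) before the PAVA pass,
which gives the exact least-squares monotone fit; queries outside the fitted
support clamp to the nearest fitted value.

### Fusion and the applicability domain

Beliefs are combined by Hooper's rule,

$$joint = 1 - (1 - B_{ECFP})(1 - B_{icML}),$$

the probability that at least one of two independent evidence sources is
right. It is commutative, bounded below by the larger belief and above by
their sum, and monotone in each argument. Independence is why the classifier
is trained on descriptors rather than fingerprints: fingerprint-trained
models would duplicate the similarity evidence and the product rule would
overcount. `redundancyDiagnostics()` (Spearman ρ and a 10×10 equal-width
mutual-information estimate, in bits) quantifies residual redundancy, and
`fitStacking()` provides the logistic-with-interaction meta-model as an
evaluation-time comparator that can learn redundancy weights; Hooper fusion
of the isotonic-calibrated belief is the served combination.

Predictions are only served inside the applicability domain: the query's
best similarity to the target's active library must reach the user's
threshold (default 0.7; 0 disables the gate). Out-of-domain reports still
carry the nearest active neighbor, so an abstention is inspectable. A target
with actives but too few labeled records per class (< 10 by default) for
training is served similarity-only (`joint = B_ECFP`) with a flag.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| activity threshold | 100 | nM | clinically relevant affinity; fixed by the labeling rule |
| IC50 retrieval ceiling | 10,000 | nM | curation cut for retrieved data; configurable |
| fingerprint radius | 6 | bonds | the source protocol's literal "radius of six"; see below |
| fingerprint length | 2048 | bits | standard folded length; power of two enforced |
| similarity bins | 10 × 0.1 | — | fixed by the curve procedure |
| slope bound | (0, 50] | — | keeps the fit away from step-function degeneracy |
| AD threshold | 0.7 | Tanimoto | recommended gate; user-overridable per prediction |
| CV geometry | 5 × 3 | folds × repeats | matches the training protocol |
| pruning | var 1e-5, cor 0.95, top-50 | — | common QSAR hygiene; protocol states no values |
| decoy ceiling (synthetic) | 0.4 | Tanimoto | enforces structural separation of decoys |

**The radius convention.** "ECFP with radius 6" is ambiguous in the field:
the ECFP_6 naming convention means *diameter* 6, i.e. radius 3. The literal
wording is followed (radius = 6 bonds) as the default, and the other
convention is one argument away (`radius = 3`). The fingerprint itself is a
standard Morgan-style iterative neighborhood hash (atomic number, heavy
degree, H count, formal charge, ring membership as atom invariants;
neighbor sets sorted before hashing so atom order cannot matter), folded
modulo the bit length.

## Numerical choices

* **Curve fit.** Bounded Levenberg–Marquardt least squares of fraction-active
  against the **bin midpoint** (0.05, 0.15, …, 0.95) — the procedure does not
  state the bin representative, and midpoints match how the binned points are
  plotted. Unweighted by default (per-bin counts vary over orders of
  magnitude and the reference fit is to the binned fractions); count-weighted
  fitting is an option. Empty bins are skipped, never imputed as zero; at
  least four occupied bins are required for three parameters. Initialization
  is fixed (F~max~ = max observed fraction, SC~50~ = 0.5, slope = 3), so fits
  are deterministic. A flat response (sd of fractions < 1e-8) is returned as
  the plateau value with a `degenerate` flag instead of a spurious slope.
* **Duplicate IC50s.** Replicates of one canonical SMILES aggregate by
  geometric mean — potencies are log-distributed — and the label is assigned
  *after* aggregation. When internal and public measurements conflict, only
  the internal ones are used, reflecting the higher-quality internal assay
  provenance. The aggregation rule is this package's choice; the source
  states precedence but not the numeric merge.
* **Tie-breaks.** Nearest-neighbor ties resolve to the first library entry;
  correlation-pruning ties drop the later-ordered descriptor; model selection
  ties keep the earlier algorithm/grid entry.
* **Zero denominators.** precision/recall/F1 are 0 when undefined; MCC and
  kappa are 0 on degenerate marginals; AUC is NA (with a message) for
  single-class truth.
* **Seeds.** Every stochastic step (fold assignment, forests, decoy
  rejection, generator draws) takes an explicit integer seed; derived seeds
  stay far below 2^31.

## The synthetic generator

No proprietary assay data can ship, so `generateTargetLibrary()` emulates
the structure the method relies on: scaffold families (a fixed vocabulary of
nine drug-like cores × 25 substituents) so that within-family Tanimoto
similarity exceeds between-family similarity; family-level potency, with
active-leaning families drawing log10 IC50 from N(1.3, 0.3) (≈ 20 nM) and
weak families from N(3.2, 0.5) (≈ 1600 nM), both in log10 nM — values chosen
once as typical of a potency-separated series; and decoys from disjoint
aliphatic cores, rejection-sampled to stay below 0.4 similarity to every
active (decoy sets in virtual-screening benchmarks are property-matched but
topologically dissimilar; the ceiling is the synthetic stand-in for that).
Defaults (8 families × 25 compounds, half the families potent, 100 decoys)
give ~200-compound targets — sized like a mid-sized panel target and small
enough that the full pipeline runs in minutes on one CPU; the end-to-end
benchmark uses 3 such targets with a 30% stratified hold-out.

What the generator does **not** emulate: assay noise and inter-laboratory
variability, activity cliffs (near-identical structures with divergent
potency), series bias from medicinal-chemistry optimization, tautomers and
salts, and any realistic descriptor–activity relationship beyond what the
scaffold/potency coupling induces. Passing tests therefore establish that the
machinery is correct and self-consistent — pair rules, curve recovery,
calibration properties, fusion bounds, domain gating — not that the shipped
defaults reach any particular accuracy on real assay data.

## Known limitations

* The similarity evidence is only as good as the active library: a liability
  with no structurally similar known active yields an out-of-domain
  abstention, not a warning.
* Canonicalization is the only structure standardization; salts and
  tautomers are not normalized beyond what the canonical form does.
* The fingerprint is binary; count-based fingerprints and 3D shape
  similarity are out of scope.
* Hooper fusion assumes belief independence; it is served with
  descriptor-trained classifiers precisely to support that assumption, but
  residual redundancy (measurable via `redundancyDiagnostics()`) will
  inflate joint beliefs somewhat.
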