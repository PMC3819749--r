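---
title: "Predicting peptide aggregation propensity from physicochemical property scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting peptide aggregation propensity from physicochemical property scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggprop)
library(dplyr)
```

## The model

Short sequence stretches, not whole proteins, nucleate most protein
aggregation: peptides as short as four residues form fibrils, and
grafting an aggregation-prone segment onto a non-amyloidogenic homolog
can transfer amyloidogenicity. `aggprop` therefore models aggregation
propensity at the peptide/window level and treats whole-protein
prediction as a scan.

The core representation is deliberately simple. Every property scale
assigns one number to each of the 20 canonical residues (AAindex-style);
after min–max scaling each scale over its 20 residue values, a peptide's
feature on scale $s$ is

$$x_s(\text{peptide}) \;=\; \frac{1}{|R_s|}\sum_{r \in R_s} u_s(r),$$

where $R_s$ is the multiset of the peptide's residues that have an
observed value on $s$ and $u_s$ the unit-scaled values. Three
consequences are worth keeping in mind:

* features live in $[0,1]$ by construction (convex combinations of
  unit-scaled values);
* the encoding is *composition-only*: residue order is invisible, so
  `encode("AG") == encode("GA")` and a homopolymer of any length encodes
  like its single residue. This is an inherent modeling limitation, not
  a defect to be patched with k-mer features — the propensity of a short
  window is being modeled as a property of its average physicochemistry;
* a residue missing on a scale shrinks that scale's denominator rather
  than contributing an imputed value. If *every* residue of a peptide is
  missing on a scale the cell falls back to 0.5 (the midpoint of the
  unit range) with a warning; real AAindex data essentially never
  triggers this, but non-canonical letters (B, J, O, U, X, Z), which are
  treated as missing on every scale, can.

Scaling each property over its own 20 residue values — rather than over
the columns of some training matrix — was a deliberate choice: it makes
the encoding of a sequence independent of whatever dataset happens to be
loaded, so a profile computed today and one computed after retraining
are on the same scale.

## Feature selection

Both selection methods are wrappers around the actual classifiers, run
on the encoded training matrix:

* **SVM-RFE** fits a linear soft-margin SVM, ranks features by the
  squared coefficient $w_j^2$ of the decision function, and drops the
  lowest-ranked feature; one-at-a-time by default, or a fixed fraction
  per iteration (`drop_frac = 0.2` gives subset sizes 560, 448, 358, …
  from a 560-scale collection) when starting from hundreds of features.
  The cost parameter stays fixed at $C = 1$ inside the loop: RFE
  rankings are insensitive to $C$ at the scales involved, and retuning
  at every iteration would multiply runtime for no measurable change in
  the trace. Each iteration records the 10-fold cross-validated error of
  the surviving subset, with the fold split drawn once per trace so that
  error differences across iterations reflect the subsets rather than
  fold noise.
* **RF-IS** builds a 500-tree random forest, drops the 20% of features
  with the smallest mean decrease in Gini impurity, refits a 200-tree
  forest, re-estimates importances from it (recomputation can be turned
  off), and records each forest's out-of-bag error.

Ties in either ranking are broken by eliminating the feature later in
the collection order first, which makes traces bit-reproducible under a
fixed seed even with duplicated columns.

**Choosing the subset.** The published ProA subsets (7 and 10 features)
were read off an error-versus-size figure as the "first significant
minimum"; a figure is not machine-executable, so `choose_subset()`
formalizes the idea: take the smallest subset whose error is within
$c \cdot \widehat{\sigma}$ of the global minimum, $c = 1$ by default
(the `c.sd = 1` convention of iterative RF selection). The dispersion
$\widehat{\sigma}$ is taken at the global-minimum iteration; for RF
traces it is the binomial standard error of the OOB error, and for
SVM-RFE traces the standard error of the fold-mean CV error. Using the
standard error rather than the raw across-fold standard deviation is
intentional: the rule compares *mean* error estimates, and a band as
wide as the fold scatter would routinely wave through subsets that have
genuinely lost signal.

## Predictors, calibration, validation

The two deployed predictors mirror the selection methods. The linear SVM
tunes its cost over $\{0.25, 0.5, 1, 2, 4, 8\}$ by an inner 10-fold
cross-validation of the training data (ties go to the smaller, i.e.
more regularized, cost) and emits class probabilities via the standard
sigmoid (Platt) calibration — the natural reading of "outputs scaled to
[0, 1]" that does not invent a new scheme. The random forest uses 500
trees with $\lfloor\sqrt{M}\rfloor$ candidate variables per split and
scores by the fraction of trees voting for the aggregating class, so
its scores are intrinsically in $[0,1]$ on a $1/500$ grid.

Validation is nested: every tuning decision happens inside the
outer-training data. Outer folds are unstratified random tenths.
Leave-one-protein-out (LOPO) validation instead makes one fold per
source protein, with all de novo peptides (reserved group token
`de_novo`) forming a single extra fold; no protein contributes to both
sides of any fold. This matters because peptides from one protein are
not independent — a k-fold estimate quietly benefits from within-protein
similarity. The package's acceptance checks demonstrate the machinery
does what it claims by construction: on a fixture whose labels are
constant within proteins and whose only signal is protein identity,
k-fold accuracy is inflated well above the LOPO estimate (a gap of
0.2–0.35 at the fixture's conditions), while LOPO stays at or below
chance.

Thresholding is strict everywhere: a score exactly equal to the 0.5
default is a negative call. The MCC denominator convention is the common
one (any zero factor gives MCC 0), and a precision with an empty call
set returns 0 with a warning rather than NaN. The ROC curve sweeps all
distinct score thresholds and its trapezoidal area equals the
Mann–Whitney pair statistic with ties counted one half; the test suite
holds this identity to $10^{-12}$ against a brute-force pair-counting
oracle on hundreds of random instances.

## The synthetic study system

The generator (`fixture_spec()`, `sim_fixture()`) exists so that every
claim above can be tested without downloading anything. Its defaults
reproduce the composition of the AP1 aggregation-peptide dataset the
ProA predictors were developed on: 354 peptides, 184 aggregating and 170
not, 37 source proteins plus 57 de novo peptides, lengths about 12.7
residues (sd 7, bounded 4–30), and a 560-scale collection with ~2% of
residue cells missing.

Signal is planted through *residue-composition bias*, not by writing
feature values: aggregating peptides draw residues from the uniform
distribution exponentially tilted toward residues that score high on the
designated informative scales, non-aggregating peptides with the
opposite tilt. The tilt magnitude is solved numerically (against the
theoretical length distribution) so the between-class gap of the
informative-scale peptide averages equals the requested `effect_size` in
within-class standard deviations; an empirical check over seeds
reproduces the requested effect to within a few percent. An exponential
rather than additive tilt is used because an additive perturbation of
the uniform distribution cannot exceed a standardized effect of about 1
at AP1-like peptide lengths before probabilities leave $[0,1]$; a
degenerate request (informative scales with no residue contrast) still
errors. Noise scales are projected orthogonal to the class-difference
vector of the two residue distributions — renormalized over each scale's
*observed* residues, because the encoder's missing-value rule averages
over exactly that distribution — so they carry no expected class signal,
and their univariate AUCs stay within sampling noise of 0.5.

What the generator does *not* emulate: real amyloid physics, position
effects (gatekeeper charges flanking APRs), correlations between
property scales as they occur in AAindex, or AP1's actual sequences.
Passing the recovery and accuracy tests therefore shows the pipeline's
*machinery* is sound — it finds planted composition signal and respects
validation boundaries — not that the shipped synthetic predictors are
biologically meaningful. Biological performance claims rest on the
published evaluation counts (`proa_reference_counts()`), whose metric
arithmetic the package reproduces exactly; one printed value (the RF
LOPO MCC, 0.5527) is a truncation of the computed 0.55275 rather than a
rounding.

The group-confounded variant (`confound_groups = TRUE`) drops the
class-linked tilt entirely: labels are constant per protein group and
each group has its own random residue composition (Dirichlet-distributed),
so class is learnable only by memorizing proteins — the designed
worst case for k-fold validation and the clean test bed for LOPO.

## Profiling choices

Window size 7 is the field's usual compromise (shorter windows give
ragged profiles; longer ones span multiple APRs) and must be odd so the
window has a central residue; even sizes are rejected rather than
rounded. Terminal residues get *no* score — the first and last
$\lfloor w/2\rfloor$ positions are undefined rather than padded, because
truncated windows would silently change the averaging denominator and
make edge scores incommensurable with interior ones. A window-7 profile
of a length-$L$ protein therefore has exactly $L-6$ scores at positions
$4 \dots L-3$. Coordinates are 1-based inclusive in all reports; BED
export converts to 0-based half-open.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run the full pipeline at
deliberately moderate sizes — 50-scale / 300-peptide fixtures for the
20-seed recovery study, 240 peptides across 12 proteins for the
confounding study, 12 scales for profiling round trips — sizes at which
the planted effects are comfortably detectable and a complete run takes
about a minute. Every function that touches randomness takes an explicit
seed and is bit-reproducible given (data, seed); fold splits, forests,
SVM probability calibration and the generator all run under that
discipline, which the determinism tests enforce with `identical()`.

## Known limitations

* Composition-only encoding cannot distinguish permutations of a
  window; sequence-order effects are outside the model class.
* The first-significant-minimum rule is a formalization of a judgment
  call; on real data with flat error curves, the chosen size is
  sensitive to the dispersion estimate (that is why `c_sd` is exposed).
* Sigmoid calibration of SVM outputs is fitted on training data and can
  be optimistic for small training sets; scores near 0.5 should not be
  over-interpreted.
* LOPO estimates remain honest only if the protein grouping is honest:
  peptides mapped to the wrong source protein re-open the leak the
  scheme exists to close.
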