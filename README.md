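# aggprop

Sequence-based prediction of peptide aggregation propensity and detection
of aggregation-prone regions (APRs) in proteins.

Protein aggregation — amyloid fibrils as well as amorphous aggregates — is
typically nucleated by short sequence segments while the rest of the
protein stays native-like. `aggprop` implements the ProA approach to this
problem for people who study aggregation-prone peptides or need to scan
candidate proteins (e.g. biopharmaceutical formulation, amyloid biology):
instead of a handful of hand-picked physicochemical properties, it starts
from a large collection of per-residue property scales, lets two wrapper
feature-selection methods find the aggregation-relevant ones, and trains
calibrated machine-learning predictors on the selected subset.

## The method

**Encoding.** Each of the 20 canonical residues has a numeric value on
every property scale (AAindex-format scales plus literature-derived
scales). Scales are min–max scaled over their 20 residue values so every
value lies in [0, 1]; a peptide's feature on a scale is the arithmetic
mean of its residues' values, residues with a missing (`NA`) value being
excluded from that scale's mean. A peptide thus becomes a fixed-length
vector in [0, 1]^S regardless of its length.

**Feature selection.** Two elimination methods produce an error-vs-size
trace:

* *SVM-RFE* — repeatedly fit a linear soft-margin SVM and discard the
  feature with the smallest squared weight `w_j^2` in the decision
  function, recording the cross-validated classification error of each
  surviving subset;
* *RF-IS* — build a 500-tree random forest, repeatedly drop the 20% of
  features with the smallest mean decrease in Gini impurity, refit a
  200-tree forest, and record its out-of-bag (OOB) error.

The working subset is the *first significant minimum* of the trace: the
smallest subset whose error is within one dispersion unit of the global
minimum (`choose_subset()`).

**Predictors and validation.** Two deployed predictors emit propensities
in [0, 1]: a linear SVM with sigmoid (Platt) probability calibration and
a 500-tree random forest scored by tree-vote fraction. Validation uses
nested 10-fold cross-validation (all tuning inside the outer-training
folds) and leave-one-protein-out (LOPO) cross-validation, where folds
are source proteins (plus one pooled fold of de novo peptides) so
within-protein similarity can never leak between training and test.
Performance is reported as accuracy, per-class precisions, AUC, and the
Matthews correlation coefficient

```
MCC = (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)) ∈ [−1, 1].
```

**Profiling.** A whole protein is scanned with a symmetric 7-residue
sliding window; each window is encoded like a peptide, its propensity is
assigned to the central residue, and maximal runs of positions scoring
strictly above 0.5 are called as aggregation-prone regions.

The frozen feature subsets behind the published ProA predictors (7 scales
by SVM-RFE, 10 by RF-IS, union 16 — dominated by hydrophobicity and
β-sheet propensity) ship as `proa_subsets()`, and the published
evaluation confusion counts as `proa_reference_counts()`.

## Worked example

The synthetic-fixture generator plants a known class signal through
residue-composition bias — positives prefer residues with high values on
designated "informative" scales — so the whole pipeline can be exercised
and checked end to end:

```r
library(aggprop)

spec <- fixture_spec(n_scales = 50, n_informative = 2, effect_size = 2,
                     n_peptides = 300, seed = 1)
fx      <- sim_fixture(spec)
scales  <- scale_unit(fx$scales)
encoded <- encode_peptides(fx$peptides, scales)

subset <- choose_subset(rf_importance_selection(encoded, seed = 1))
subset
#> # Selected feature subset (rf_is, c_sd = 1): 7 feature(s)
#> SYN0001, SYN0002, SYN0007, SYN0008, SYN0016, SYN0017, SYN0043
```

Both planted scales (`SYN0001`, `SYN0002`) are recovered. Nested 10-fold
cross-validation of a linear SVM on the chosen subset:

```r
glance(nested_cv(encoded, subset$features, "svm", seed = 1))
#>   scheme n_folds    tp    fn    fp    tn accuracy   mcc precision_pos ...
#> 1 kfold       10   145    11    15   129    0.913 0.826         0.906
```

Pooled accuracy 0.913 and MCC 0.826, consistent with the Bayes rate
implied by the planted effect of 2 within-class standard deviations on
each informative scale. Scanning a
concatemer of the fixture peptides and calling regions:

```r
model <- train_propensity(encoded, subset$features, method = "svm", seed = 1)
prof  <- profile_protein(paste(fx$peptides$sequence[1:6], collapse = ""),
                         model, scales)
call_regions(prof, threshold = 0.5)
#>   id    start   end length  peak  mean
#> 1 seq1      4     5      2 0.807 0.755
#> 2 seq1     21    29      9 0.915 0.792
#> 3 seq1     31    46     16 1.000 0.973
#> 4 seq1     61    65      5 0.993 0.869
```

Each region is a maximal run of central residues whose window propensity
exceeds 0.5; `peak` and `mean` summarize the scores inside the region.

Real data enter through `read_aaindex()` (AAindex1 flat files),
`read_literature_scales()` (delimited per-residue tables),
`read_peptides()` (labeled peptide TSV/CSV) and `read_fasta()`. A thin
command-line front end over the same functions lives at
`inst/cli/aggprop.R` (subcommands `encode`, `select`, `train`,
`evaluate`, `profile`).

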