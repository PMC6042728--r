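---
title: "slimscan: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{slimscan: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimscan)
```

# The prediction problem

SH3, WW and PDZ domains are peptide-recognition modules that bind short
linear motifs: proline-rich internal peptides for SH3 and WW, and
predominantly C-terminal peptides for PDZ. slimscan predicts candidate
ligand windows in query sequences with four independent strategies and
reports their union. The methods make different bias/variance trade-offs:
exact instance matching (MIM) generalizes not at all, regular-expression
scanning (RES) generalizes only through wildcard positions, a frequency
PSSM assumes positional independence, and the composition SVM learns
arbitrary (smooth) decision surfaces over k-mer composition space but
discards most positional information. Agreement among methods is
therefore informative rather than redundant.

Window lengths are fixed per domain: 6-mers for SH3 and WW, 4-mers for
PDZ. These are the most common ligand lengths for the respective domain
classes and are the lengths at which the composition models have the most
training support.

# Feature encoding

A peptide of length $L$ is encoded as percentage compositions:

* AAC (20 values): $100\,n_i/L$ for each amino acid $i$ in fixed
  alphabetical order;
* DPC (400 values): $100\,n_j/(L-1)$ over the $L-1$ *overlapping*
  dipeptides, lexicographic order;
* TPC (one value per selected tripeptide): $100\,n_k/(L-2)$ over the
  $L-2$ overlapping tripeptides;
* CTERM (1 value, PDZ schemes only): 1 iff the window ends at its parent
  protein's C-terminus.

Two readings deserve a note because they are genuinely ambiguous:

* **Over-represented tripeptides.** "Occurring in more than one ligand"
  is implemented as *present in at least two distinct positive peptides*;
  repeated occurrences within a single peptide do not qualify a
  tripeptide. The selected list is sorted lexicographically so that a
  serialized model is independent of training-set order.
* **Denominators.** Dipeptide and tripeptide totals are the overlapping
  counts $L-1$ and $L-2$, the standard sliding-window reading. With this
  choice AAC and DPC blocks each sum to exactly 100, which the test suite
  asserts.
* **Standalone peptides.** A peptide submitted on its own has no parent
  protein; its last residue *is* its terminus, so `encode()` defaults
  `is_c_terminal` to `TRUE` (overridable).

The default feature combinations are AAC+DPC+TPC for SH3 and WW and
AAC+TPC+CTERM for PDZ — the combinations that perform best for the
respective classes.

# The four predictors

## Composition SVM

An RBF-kernel C-SVM (via libsvm/e1071, `scale = FALSE` since all features
share the 0–100 percentage scale). Two defaults matter:

* **Kernel width.** `gamma = 1 / (p · var(x))` where `p` is the feature
  count and `var(x)` the overall feature variance. The common `1/p`
  default assumes unit-scaled features; on percentage-scaled vectors it
  collapses the kernel to near-diagonal and the model to the majority
  class. The variance-scaled heuristic (the same one scikit-learn calls
  `gamma = "scale"`) is deterministic given the data and adapts to any
  feature scheme.
* **Class weights.** Unbalanced bundles weight the positive class by
  `n_neg/n_pos`, so the nominal 0.00 decision threshold is a usable
  operating point on 1:4 … 1:2 data. The threshold is a free post-hoc
  parameter; raising it trades sensitivity for specificity and never
  retrains.

`tune_hyperparameters()` grid-searches (gamma, cost) by stratified CV
accuracy; ties are broken towards smaller cost, then smaller gamma
(preferring the less complex model), then grid order.

## Frequency PSSM

`PS(i,p) = n(i,p)/N` over the aligned positives; queries are scored by
multiplying position scores. The raw product of frequencies is bounded by
the per-position maxima, so useful thresholds depend strongly on `N` and
`L` and a threshold of 1 is attainable only by a unanimous consensus
sequence. The default `background_odds` mode therefore divides each
factor by the uniform background 1/20: a score of 1 means "as likely as a
random peptide", making thresholds in the 0.5–1 range meaningful
operating points across domains. `raw` mode is retained for fidelity to
the plain frequency-product definition; both modes order queries
identically (they differ by the constant $20^L$), so ROC/AUC is
mode-invariant. A residue never observed at a position scores 0 and
zeroes the product; no pseudocounts are added, which is what makes the
fold-locality (leakage) test exact.

## RES and MIM

RES anchors each pattern at every start position, so overlapping matches
are all reported and `$`-anchored patterns match only at the sequence
terminus (the PDZ case). The shipped pattern lists are canonical
literature motifs and are explicitly replaceable defaults
(`read_regex_library()`); they are not a curated, validated library.
MIM reports every exact substring occurrence of every instance.

# Dataset construction

Positives are collapsed on (sequence, protein, start): identical entries
are redundant, but the same sequence at a different position or in a
different protein is an independent motif occurrence and is retained.

Negatives for a domain are the union of the other two domains' positives
plus a random-peptide background — unbalanced: all of them; balanced:
uniform subsamples without replacement under a caller-supplied seed, with
default quotas 30+30+55 (SH3), 45+45+50 (WW), 50+50+65 (PDZ). Using other
domains' ligands as negatives forces the models to separate true binders
from motif-bearing non-binders, not merely from random sequence.

**Length reconciliation.** Cross-class negatives must be re-cut to the
target window: 6-mers used as PDZ negatives keep their last 4 residues
(the C-terminal side, where the PDZ signal lives); 4-mers used as SH3/WW
negatives are extended to 6 using their stored sequence context
(`ext_sequence`), again anchored at the C-terminal end. This is a genuine
design decision — nothing forces the C-terminal anchoring for the 6→4
direction — but it is the biologically sensible one and is applied
uniformly.

# Cross-validation and metrics

Folds are stratified (positives and negatives partitioned separately,
sizes within a stratum differing by at most one), so each fold preserves
the class ratio. Confusion counts are pooled (micro-averaged) across the
five test folds rather than averaging per-fold ratios; with pooled counts
`TP+TN+FP+FN` equals the dataset size exactly and small folds cannot
produce undefined per-fold ratios.

Everything that can leak is computed fold-locally: tripeptide selection
and SVM fitting use only the training folds, and the PSSM is rebuilt per
fold. For MIM the default CV library is the training fold's positives — a
test peptide is recovered only if its exact sequence recurs in training
data, which is the honest cross-validated reading of an exact-matching
method (a fixed external library can be supplied instead, but using the
full positive set would score every test positive against itself). RES
libraries are external resources and are applied as given.

MCC is reported on $[-1, 1]$ using the standard rooted denominator
$\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}$, defined as 0 when any factor is
zero. ROC/AUC uses the threshold sweep with tie groups collapsed;
the trapezoidal area then equals the Mann–Whitney pair-counting
probability with ties counted ½, which the tests verify to 1e-12 against
a brute-force oracle and an independent ROC implementation. Binary
methods (RES/MIM) get no ROC: their score is the 0/1 call.

Thresholds are boundary-inclusive everywhere (`score >= t` is positive).
`select_threshold()` maximizes accuracy and breaks ties towards higher
specificity, then towards the larger threshold — preferring the more
conservative operating point.

# The synthetic generator

`generate_bundle()` emulates the statistical structure the predictors
assume, with class sizes 115 (SH3), 140 (WW), 165 (PDZ) and 120
background peptides by default, giving unbalanced negative sets of
425/400/375:

* per-position motif templates — `[RK]xPxxP`-style for SH3, `PPxY`-style
  for WW, `x[ST]x[VIL]` for PDZ — with probability mass `signal_strength`
  (default 0.9, a strongly conserved motif) on the template residues and
  the remainder uniform;
* PDZ positives are C-terminal with probability 0.9 and carry a 6-mer
  sequence context so they can serve as 6-mer negatives;
* background peptides are uniform over the 20-letter alphabet;
* a disjointness guarantee (default on, by rejection sampling): no
  negative of a domain exactly matches any same-domain positive, in
  either the 6-mer or the 4-mer projection. Exact matching then has zero
  false positives *by construction*, which is what the acceptance script
  measures.

What the generator does **not** emulate: real amino-acid background
composition (plant or otherwise — the background is uniform), disorder
context, motif flanking preferences, homology structure between peptides,
and domain-subtype specificities. Passing benchmarks on generated bundles
therefore demonstrates that the machinery is correct and that the methods
rank as expected on clean planted signal; it says nothing quantitative
about performance on curated experimental ligand sets.

Benchmark problem sizes used in the test suite: the full 540/540/540-
example bundles for the method-ranking and label-shuffling checks (a few
seconds per CV run), 500-peptide sets for frequency-recovery checks, and
1000+ random (matrix, query) pairs for the scoring oracles.

# Known limitations

* The shipped regex libraries are minimal canonical defaults; RES
  performance is entirely a function of the supplied library.
* PSSM positional independence ignores residue covariation; no
  pseudocounts means rare residues zero the score, which is intended for
  leak-checking but conservative for real scanning.
* The SVM models are generalized per domain class, not per domain
  subtype/paralog.
* Windows are fixed-length; variable-length candidate regions are handled
  by the any-window union rule (`peptide_level_call()`), not by merging
  overlapping hits into regions.
* `collapse_redundant()` treats missing start coordinates as equal, so
  synthetic entries without provenance deduplicate on sequence alone.
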