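---
title: "Classifying DnaJ/HSP40 types from imbalanced sequence data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying DnaJ/HSP40 types from imbalanced sequence data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnajtype)
```

## The problem

J-proteins (DnaJ/HSP40 co-chaperones of Hsp70) are partitioned into four
structural types by domain architecture: type I has the J-domain,
Gly/Phe-rich region, zinc finger and C-terminal domain; type II drops the
zinc finger; type III keeps only the J-domain; type IV has a degenerate HPD
motif. Curated sequence collections are dominated by type III (on the order
of a thousand sequences against tens for each other type), so the
scientific difficulty is not raw accuracy — always predicting type III is
very accurate — but achieving usable *sensitivity for every type*. The
package therefore optimises and reports AvgSn, the unweighted mean of the
four one-versus-rest sensitivities, alongside Sn/Sp per class and overall
accuracy.

## Feature model

Three feature blocks are concatenated into one vector with a frozen global
ordering (SAAC, then PseAAC property-major, then PSSM-AC column-major, lags
ascending within each unit), so that ranked feature indices are portable
across runs.

**Split amino acid composition (60 features).** Terminal regions of
J-proteins carry compositional signal that whole-sequence composition
dilutes, so the sequence is split into the N-terminal `lnc` residues, the
centre, and the C-terminal `lnc` residues, and a 20-letter frequency vector
is computed per part. `lnc = 22` is the default, the terminal length at
which type discrimination peaks on real data. Sequences shorter than
`2*lnc + 1` are rejected during training (`policy = "error"`) or split into
three near-equal contiguous thirds (`policy = "thirds"`), the
prediction-time default; the thirds rule preserves the three-part
composition idea without overlapping segments, a choice the source
description of the method leaves open.

**Pseudo amino acid composition (96 features).** Twelve physicochemical
properties — hydrophobicity, hydrophilicity, average accessible surface
area, average flexibility, net charge, side chain volume, polarity, heat
capacity, isoelectric point, transfer free energy to surface, van der Waals
volume, side chain interaction parameter — are taken from one published
AAindex scale each (accessions in `attr(aa_properties(), "property_ids")`).
For property *j* and lag γ the feature is the mean-centred lagged
autocovariance of the property profile along the sequence. Two documented
assumptions: (a) the property values themselves are not fixed by the method
description, so any faithful reimplementation can differ in the third
decimal of PseAAC values — exact numeric replication on real data is not
claimed; (b) each scale is z-standardised over the 20 residues before use,
the established PseAAC convention, which makes the features invariant to
each index's arbitrary units (a tested property). One correlation factor
per (property, lag) pair at γ_max = 8 gives 96 features; this reading is
forced by the dimension arithmetic 256 = 60 + 96 + 100 at the default
parameters. The classic AAC block of PseAAC is deliberately absent —
composition information already lives in the SAAC block.

**PSSM autocovariance (100 features).** The L×20 PSI-BLAST log-odds matrix
is normalised elementwise by the sigmoid 1/(1+e^(−x)) *before*
autocovariance extraction (normalisation precedes covariance in the method;
column means are taken on the normalised matrix), then each residue column
is summarised at lags λ = 1…5. Columns are remapped from the PSI-BLAST
header order (`A R N D C Q E G H I L K M F P S T W Y V`) to alphabetical
order at parse time, removing a silent-corruption hazard between file
dialects. A sequence with no usable profile receives an all-zero fallback
matrix, applied exactly once at dataset assembly; its normalised matrix is
constant 0.5, so the whole block vanishes — the model then relies on the
sequence-derived blocks. The fallback count is recorded on the dataset.

## Feature selection

Symmetric uncertainty `SU = 2·IG/(H(f)+H(C))` (base-2 entropies; empty
cells contribute zero) scores each feature against the class after
supervised discretization. The discretizer is Fayyad–Irani recursive
entropy/MDL partitioning — the standard default behaviour for SU attribute
evaluation on numeric data; the exact discretizer is not pinned down by the
method description, so an unsupervised equal-frequency fallback
(`method = "eqfreq"`, 10 bins) is also provided. A feature with no
MDL-accepted cut collapses to a single bin and scores SU = 0, which is the
desired behaviour for uninformative features. Ranking sorts by decreasing
SU with ties kept in original index order (bit-for-bit reproducible).

Incremental feature selection walks ranked prefixes and keeps the best
AvgSn, breaking ties towards the *smaller* prefix, since the procedure
exists to find the lowest dimension achieving the best score. The faithful
evaluator (`evaluator_ensemble()`) trains the full ensemble under
cross-validation per prefix, which is expensive (N prefixes × k folds × 20
subclassifiers); a clearly-labelled cheap surrogate
(`evaluator_centroid()`, stratified CV nearest-centroid) and a `step`
parameter are provided for desk-scale scans. Ranking is computed once on
the full dataset, matching the original protocol of ranking before
cross-validation; users wanting leakage-safe selection can re-rank inside
training folds using the exported building blocks, and should be aware the
default mildly optimistic protocol is inherited deliberately.

## Imbalance handling and the ensemble

Training balances the data from both ends:

* **SMOTE** expands the rarest type to `smote_target` (default 60) rows;
  each synthetic row is `x + u·(nn − x)` for a random real row `x`, one of
  its `k = 5` nearest same-class neighbours `nn`, and `u ~ U[0,1]`.
  Originals are always retained and every synthetic point lies on a segment
  between two real points (a tested invariant).
* **Undersampling** splits the majority type into `n_subsets = 20` random
  near-equal subparts; subdataset *i* is all non-majority rows plus subpart
  *i*, so each subclassifier sees roughly balanced classes while the
  ensemble as a whole wastes no majority row.

"Twenty subclassifiers" is taken literally: the four learner families (RBF
network, random forest, naive Bayes, logistic regression) are assigned
round-robin, five subclassifiers each, all wrapped one-versus-rest.
Learners are specified by family and interface, not implementation:
`randomForest::randomForest`, `e1071::naiveBayes` (with class-conditional
standard deviations floored at 1e-6, since zero-variance features inside a
small subdataset otherwise produce NaN densities), binomial `stats::glm`
(separation warnings expected and suppressed on small balanced
subdatasets), and an RBF network realised as a Gaussian kernel layer over
k-means centres (bandwidth = median inter-centre distance) with logistic
readouts. Hyperparameters not fixed by the method description
(`rf_ntree = 200`, `rbf_centers = 10`) are frozen in `ensemble_config()`.

Prediction is majority vote; tallies always sum to `n_subsets`. When two or
more classes tie for the top vote count, the winner is the tied class whose
*training centroid* is nearest (Euclidean) to the query vector — the
method's "nearest distance" tie-break names neither metric nor reference
point, and class centroids are the simplest class-level referent. All
randomness (SMOTE, partition, learner seeds) derives from `config$seed`;
refitting with the same seed reproduces predictions exactly.

**SMOTE scope.** The original protocol expands the rare class once, before
cross-validation folds are drawn (`smote_scope = "paper_faithful_pre_cv"`,
the default), which means synthetic rows appear in test folds and sit close
to training rows — an optimistic bias for the rare class that is part of
the protocol being reproduced. `cross_validate()` therefore also reports
`pooled_real` (real rows only), and a leakage-free
`smote_scope = "train_fold_only"` is provided; reports name the scope used.
The chance-level null check in the test suite uses the leakage-free scope,
because under the pre-CV scope even label-free data scores above chance on
the rare class purely through oversampling leakage — an instructive
artefact, not signal.

## Evaluation

`make_fold_plan()` stratifies by class: each class is permuted and split
into k near-equal parts, so every fold tests every class. Metrics follow
the one-versus-rest definitions (Sn = TP/(TP+FN), Sp = TN/(TN+FP),
Acc = ΣTP/N, AvgSn = mean Sn). Pooled-prediction metrics are the default
report because per-fold sensitivity of a two-sample class is unstable;
fold-mean values are emitted alongside, since the original protocol
averages the ten fold results. Display rounding is half-away-from-zero to
3 decimals (`round_half_up()`), matching how such tables are conventionally
printed; a class absent from the truth vector is excluded from AvgSn with a
warning.

## Synthetic benchmark

`simulate_dataset()` generates the four classes with the canonical
imbalance (63/55/1061/20 by default), sequence lengths uniform in a
configurable range, per-class letter distributions
`(1 − w)·uniform + w·Dirichlet(1)` with `w = composition_bias`, optional
planted N-terminal motifs, and synthetic PSSMs as integer log-odds in
[−6, 8] built from class-level column shifts (sd `pssm_signal`) plus cell
noise. The generator emulates the statistical *shape* of the problem —
imbalance, compositional bias, profile signal — not J-protein biology:
there are no domains, no homology structure, no HPD motifs unless planted.
Passing tests therefore demonstrate that the pipeline machinery behaves
correctly in the intended regime, not that any particular real-data
accuracy is reproduced; the published real-data benchmark figures depend on
an external curated dataset and PSI-BLAST profiles and are deliberately out
of scope. Defaults `composition_bias = 0.3` and `pssm_signal = 1.5` were
chosen once as a realistic middle ground — learnable but far from
saturated — and are not tuned.

Generation is byte-identical under a fixed seed, and `write_dataset()`
round-trips through the package's own readers (tested).

## Problem sizes used in the tests

The packaged benchmark used by the behavioural tests is a one-third-scale
replica of the canonical imbalance (21/18/354/7; SMOTE target scaled
60 → 20) with a reduced feature configuration (`lnc = 15`, γ_max = 4,
λ_max = 3 → 168 features) under 3-fold cross-validation. One-third scale
preserves the within-subdataset class mixture of the full protocol (each
balanced subdataset is roughly one-quarter majority rows), which smaller
replicas distort badly — with, say, a 160-sequence majority, the 20
subparts shrink to under ten rows and the ensemble over-corrects against
the majority class. On this benchmark the ensemble's cross-validated
minority sensitivities dominate those of a single unbalanced random forest
(which collapses to the majority class at chance-level AvgSn), and a
no-signal replica scores inside a generous chance band around 0.25. These
are the problem sizes the test suite and the worked example in the README
state; nothing in the package depends on them.

## Numerical choices and degenerate inputs

* Entropies are in bits everywhere; 0·log 0 = 0; SU returns 0 when
  H(f)+H(C) = 0 and is clipped to [0, 1] against rounding error.
* Autocovariances of constant profiles (homopolymers, fallback PSSMs) are
  exactly 0 by construction, not by thresholding.
* SMOTE clips `k` to class size − 1 with a warning; a one-row class cannot
  be expanded (error); `target == current size` is a no-op.
* Majority partition sizes differ by at most 1 (larger groups first);
  `which.max`-style argmax choices (vote resolution without ties, IFS best
  prefix) take the first optimum for determinism.
* One-vs-rest learners never see a single-level response because every
  subdataset contains all four classes by construction (validated).
* All seed-taking functions restore the caller's RNG state
  (`.Random.seed`) on exit.

## Known limitations

* PSI-BLAST itself is out of scope: profiles are read from ASCII PSSM
  files, or replaced by the zero fallback. Provenance of profiles
  (database, iterations, E-value) is the user's to track.
* The PseAAC property scales are one defensible choice among several; the
  per-feature values (not the machinery) would shift under different
  AAindex selections.
* The default pre-CV SMOTE scope inherits the optimism discussed above; use
  `train_fold_only` and `pooled_real` for unbiased estimates.
* The RBF-network learner is a standard kernel-layer construction, not a
  re-implementation of any specific legacy tool; no attempt is made to
  reproduce the degenerate majority-collapse behaviour such tools can show.
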