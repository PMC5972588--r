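---
title: "Evaluating co-complex protein pairs from ontology annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating co-complex protein pairs from ontology annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocomplex)
```

## The problem

High-throughput interaction screens (affinity purification followed by
mass spectrometry in particular) report many protein pairs that are not
genuine co-complex partners. cocomplex scores a candidate pair of
proteins for co-complex membership using nothing but curated annotation:
the three Gene Ontology branches (biological process, cellular component,
molecular function) and InterPro domain assignments. The package covers
the full workflow: building a labelled training set from a complex
catalogue, representing each pair in a combinatorial annotation feature
space, training four classifier families, and assessing them with a
repeated stratified hold-out protocol.

## Pair representation

A gene's annotation in one source is a set of terms; in `all_parents`
mode each set is closed over the ontology's `is_a` and `part_of`
relations (InterPro's parent relation for domains), so a specific term
brings its entire ancestral chain up to the namespace root. A protein
pair (g1, g2) is then represented, per source, by the cross product of
the two term sets: every combination of one term from each protein is
one binary pair feature. Because the protein pair is unordered, the term
pair is stored in canonical (sorted) order — without this, results would
depend on input column order. Sources are never mixed inside a feature;
combining sources (`GO`, `GO-IP`) only widens the feature set.

Two consequences of the all-parents design are worth naming. Root–root
features occur in essentially every annotated pair, so they are
frequent, carry almost no information, and end up with near-zero
weights — a built-in sanity check on the weighting scheme. And the
feature space is large but extremely sparse, which is why everything
downstream works on sparse matrices and kernel matrices rather than
dense feature tables.

## Classifiers

**GIS-MaxEnt.** The core model is a conditional maximum-entropy
classifier over the classes {positive, negative} with binary feature
functions `f_i(x, y)` (pair feature i active AND class y), trained by
Generalized Iterative Scaling:

    lambda_i <- lambda_i + (1/C) * log(E_emp[f_i] / E_model[f_i])

Classically C must bound the per-example active-feature count and a
slack feature fills each example up to C (`correction = "max"`). The
default here (`correction = "mean"`) replaces C by the *mean* number of
annotation features per training example. This takes much larger steps —
on sparse annotation data the mean count is far below the maximum — at
the cost of the classic monotone-likelihood guarantee, which does not
survive the substitution. Training therefore records the log-likelihood
trace and counts any decrease (`glance()` exposes `ll_decreases`); on
all fixtures we tested both modes reach the same fixed point, the mean
mode in fewer sweeps, and the unit tests verify both against an exact
maximum-likelihood oracle (BFGS on the conditional log-likelihood,
agreement within 1e-3 on predicted probabilities, moment-matching gap
below 1e-4).

An always-on intercept feature per class absorbs the class prior, so a
pair with no recognised annotation scores at the prior rather than an
arbitrary 0.5. Features with zero empirical count for a class are
skipped rather than epsilon-floored, keeping fixed points exact on small
problems. No smoothing is applied by default (a Gaussian prior is
available via `maxent_config(gaussian_prior = )`).

**Tanimoto-kernel SVM.** The linear kernel on binary pair-feature
vectors counts shared features. Feature-wise standardization would
destroy sparsity, so normalization happens on the kernel matrix instead:

    K'(x, x') = K(x, x') / (K(x, x) + K(x', x') - K(x, x'))

which for binary data is exactly the Jaccard similarity of the two
feature sets and is itself a valid (PSD) kernel. Pairs with empty
feature sets are defined to have similarity 0 against everything —
a convention that keeps the matrix usable where a 0/0 would otherwise
appear. Normalization is not idempotent; a guard attribute refuses
double application. The soft-margin SVM on K' is solved by libsvm on an
exact eigen-feature map of the kernel (negative eigenvalues, which can
only arise from a construction error, are reported and clipped);
prediction uses the dual coefficients against the test-by-train
cross-kernel directly. The soft-margin parameter defaults to `cost = 1`
and is deliberately not tuned per dataset. Decision values serve for
ranking (AUC); thresholded metrics for probability-scale systems use a
Platt-style logistic calibration.

**Stacked ensemble.** One GIS-MaxEnt base per source (GO-BP, GO-CC,
GO-MF, IP); the four base probabilities on the training pairs feed a
linear SVM decision layer. The layer is trained on in-sample base
predictions — the straightforward construction, whose optimism we keep
faithfully; an out-of-fold mode (`out_of_fold = TRUE`) is available but
off by default.

**l2-norm MKL.** One Tanimoto kernel per source, combined as
`K'' = sum_i beta_i K'_i` with `beta >= 0` and `||beta||_2 = 1`, trained
by the standard lp-norm wrapper with p = 2: alternately solve the SVM on
the current combination, then update `beta_i` proportional to
`||w_i||^(2/3)` from the per-kernel margin contributions, renormalized
to unit l2 norm. The update is damped (factor 0.5) because the inner
solver's discrete support-vector set makes the raw alternation jitter at
the 1e-3 level; iteration stops at a 1e-4 change in beta or, in
practice, when the change stops improving on its running minimum for
three consecutive iterations (the jitter floor), within a cap of 50
outer iterations. Beta is reported raw on the unit-l2 scale, with no
simplex renormalization.

## Training-set construction

From a complex catalogue (CYC2008-style), `matrix_expand()` converts
every complex of n members into all n(n-1)/2 unordered pairs,
deduplicating pairs shared by overlapping complexes and keeping every
contributing complex as provenance; `spoke_expand()` is the conservative
bait–prey alternative. `transfer_by_homology()` maps pairs through a
many-to-many homolog table (interologs), dropping unmapped pairs and
self-pair collapses. `exclude_gene_families()` removes pairs touching a
user-supplied blocklist (histone and ribosomal families dominate
complex-derived positive sets otherwise), and `sample_negatives()` draws
the negative class from the same gene universe, excluding known pairs.
All sampling is seeded and reproducible bit-exactly.

Negative sampling is uniform by default, matching the plain reading of
random pair sampling from the positive set's genes. A `weights` argument
provides degree-matched sampling: matrix expansion gives genes of large
complexes many positive pairs, so under uniform negatives the per-gene
class ratio itself predicts the label, and *any* gene-identifying
annotation leaks that signal. Degree matching removes the confound; it
is the default in the synthetic benchmark (below) precisely so that a
no-signal dataset scores at chance.

## Evaluation protocol

`make_splits()` draws repeated stratified partitions — by default 50
runs of 90% train / 10% test, each preserving the class proportions to
within one example per class, derived deterministically from a master
seed. Feature spaces, kernels and models are rebuilt from each run's
training partition only; test pairs map onto the frozen training space
and unseen features are dropped, so test pairs made entirely of unseen
term combinations fall back to the prior. Metrics are ACC, MCC, F1,
recall, precision (threshold 0.5 for probability systems, 0 for margin
systems) and AUC computed from the rank-sum statistic with midranks,
which equals trapezoidal ROC integration exactly. System comparisons use
the unpaired two-sample Wilcoxon rank-sum test on per-run metric values
(normal approximation with tie correction at the protocol's n = 50;
exact enumeration at small tie-free n). Aggregation reports mean,
standard deviation and median over runs; no multiple-testing correction
is applied.

`complex_term_audit()` implements the vocabulary sanity check: it counts
each term's occurrences among the genes of positive versus negative
pairs and rank-sum-tests (a) only terms whose name matches a pattern
(default "complex") and (b) all terms. A classifier that merely reads
off complex-naming vocabulary would show the pattern test significant;
the intended outcome on a sound training set is a non-significant
pattern test alongside an overall vocabulary difference.

## The synthetic benchmark

Every input format the pipeline reads — OBO, GAF 2.x with evidence
codes, InterPro hierarchy and assignments, complex and homolog TSVs — is
emulated by `generate_bundle()`, fully seeded and byte-reproducible, so
the whole system is testable offline. The generated files deliberately
exercise the unglamorous paths: a configurable fraction of GAF rows
carry excluded evidence codes (IEA, NAS, ND, NR) or NOT qualifiers and
must be dropped by the real filter.

The default ("paper-shaped") conditions: 60 complexes with a size
profile dominated by 2-member complexes and a long tail (sizes 2–16,
226 genes), matrix-expanded and subsampled to 500 positive pairs, with
500 degree-matched negatives; four annotation sources; a background
vocabulary of 60/40/40/60 terms (BP/CC/MF/IP) arranged in random
ontologies with about 20% `part_of` edges; per-gene background
annotation counts drawn from a truncated geometric distribution (sparse,
2 asserted terms per gene-source typically, closed to roughly 10–15).
The vocabulary is sized so a typical term annotates several genes, the
shared-vocabulary character of real GO annotation — a vocabulary of
near-private terms would fingerprint individual genes, and gene identity
interacts with the split structure rather than with co-membership.

The planted signal mimics how co-complex membership actually surfaces in
annotation: complexes belong to functional modules (20 by default,
assigned independently per source), each module owns a small coherent
block of terms per source (3 by default — think of a complex's
localization, process and function terms), and with probability `signal`
a positive pair carries its module's block on both members in that
source. Module terms recur across the complexes of a module, so the
signal generalizes to held-out pairs instead of acting as a memorizable
per-complex tag; negatives pick the same features up only through
same-module coincidences, about 1/20 per source. At `signal = 0` no
module terms are planted anywhere and the labels are independent of all
annotation.

What passing on this benchmark does and does not show: it demonstrates
end-to-end correctness of parsing, closure, featurization, training and
evaluation, correct null behaviour, and the expected ordering
(all-source models at least as good as single sources; combiners
competitive with the best single source). It does not certify
performance on real annotation, whose term dependence, depth profile and
biases the generator does not attempt to reproduce.

## Problem sizes and numerical choices

The shipped checks run the full protocol (50 stratified runs) for the
five maximum-entropy systems and the stacked ensemble, and score the
kernel systems (SVM on all sources, MKL) on the first 10 of those runs;
one MKL fit costs several SVM solves on a 900-by-900 kernel, and 10 runs
estimate its mean AUC to well under a point of the band being checked.
GIS runs at its default cap of 100 iterations in the protocol;
oracle-equivalence tests run it to numerical convergence (tolerance
1e-13 on the likelihood delta). Convergence tolerances, the eigenvalue
clipping threshold (-1e-9 relative), the zero-kernel convention and the
correction-constant fallback (C = 1 on an annotation-free matrix) are
each tested explicitly. Maximum-entropy weights persist to JSON with 17
significant digits, which round-trips IEEE doubles exactly; reloaded
models predict bit-identically.

## Known limitations

- The mean-correction GIS has no convergence theorem; the monitor makes
  violations visible rather than impossible.
- In-sample stacking reproduces the reference construction faithfully,
  including its optimism on small training sets.
- The SVM cost parameter and the score calibration are pragmatic
  defaults, not reproductions of any published setting.
- The generator emulates formats and signal structure, not real GO
  semantics: no term co-occurrence structure, no depth-dependent
  information content, no annotation bias toward well-studied genes.
- Homology transfer consumes a homolog table as given; no orthology
  inference is performed.
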