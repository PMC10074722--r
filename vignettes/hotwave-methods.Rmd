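---
title: "Methods: wavelet features, balancing, selection and boosting for interface hot spots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet features, balancing, selection and boosting for interface hot spots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotwave)
```

## The problem and the data model

Hot spots are interface residues whose alanine mutation changes protein–DNA
binding free energy by ΔΔG ≥ 1.0 kcal/mol; the boundary value is a hot spot.
The pipeline starts from a per-residue table of 43 "traditional" structural
descriptors, consumed as numbers (the structure tools that produce them are
out of scope): 24 solvent-accessibility values (absolute and relative ASA for
four atomic property classes — all atoms, nonpolar side chain, polar side
chain, all side chains — in monomer state, complex state, and as relative
change), 6 secondary-structure values, 12 depth/protrusion (DPX/CX) values
(mean over all atoms and SD over side-chain atoms, bound and unbound, plus
relative changes), and one hydrogen-bond count.

The source material fixes these *counts* but not the column identities or
their order, so the canonical 43-name vocabulary in `traditional_columns()`
(exported as a JSON sidecar in `inst/extdata/`) is a convention of this
package. A deterministic order is not cosmetic: the wavelet transforms below
read each block as an *ordered* signal, so any reordering changes features.
Missing values are rejected rather than imputed, because no imputation rule
is defined for this problem and silent imputation would corrupt the signals.

## Wavelet feature expansion

Four blocks are treated as digital signals: ASA (monomer, length 8), uASA
(complex, 8), dASA (relative change, 8) and DSSP (6). Each is analysed with
the orthonormal Haar (db1) filter pair g = (1, 1)/√2, h = (1, −1)/√2 — the
named wavelet family fixes the filters up to sign convention; we use the
standard analysis pair.

**Boundary rule.** Odd-length vectors are extended by repeating the last
sample before each convolution–decimation. This keeps three full
decomposition levels defined for the length-6 DSSP signal (6 → 3 → 2 → 1)
while leaving power-of-two signals untouched, so Parseval's identity holds
exactly (tested at 1e−9) for the length-8 groups.

**DWT descriptors (11 per group).** For the 3-level DWT we report the
approximation energy share per level,
Ea_j = 100·E(A_j) / (E(A_j) + Σ_{i≤j} E(D_i)), the mean and *population*
(divisor-n) standard deviation of the three Ea values, and the detail share
Ed = 100 − Ea₃. The source text gives the dimensionalities ("Ea, 3; Ed, 1")
without defining the normalisation; the per-level-share reading adopted here
is the one that makes Ea₃ + Ed = 100 an exact identity, which the tests
assert. The five wavelet entropies are computed on the concatenated DWT
coefficients (A₃, D₃, D₂, D₁) — the coefficient vector is the natural
"coefficients in an orthogonal basis" input for additive cost functions;
whether the reference computed them on coefficients or raw signals is not
stated, and coefficients were chosen.

**WPT descriptors (22 per group).** The level-3 wavelet packet transform
splits *both* branches at every level, giving 8 terminal sub-bands in
natural (filter) order. We report their relative energies (summing to 100),
absolute energies, the absolute energy sum, and the five entropies of the
concatenated terminal coefficients.

**Entropies.** All five are additive costs with E(0) = 0: Shannon
−Σ s²ln(s²) and log-energy Σ ln(s²) with zero coefficients contributing 0;
threshold entropy #{|s| > 0.2}; SURE entropy n − #{|s| ≤ 3} + Σ min(s², 9)
(the standard additive SURE cost — the reference names only the threshold,
3); norm entropy Σ|s|^1.3. Natural logarithms throughout. These conventions
make every entropy invariant under zero-padding, which the tests verify.

All-zero signal groups are an error, not a NaN: energy percentages are
undefined at zero energy and silent NaNs would poison feature selection.

The result is 43 + 4·11 + 4·22 = 175 features per residue. DPX/CX and the
hydrogen-bond count contribute no signal group (they lack a natural serial
order) and enter the model only as raw columns.

## Class balancing

SMOTE synthesises minority samples until the classes are equal:
`X_new = X + u·(X_n − X)` with u ~ U(0, 1) and X_n one of the k = 5 nearest
minority neighbours by Euclidean distance. The reference prints the formula
with |X − X_n|, which for signed differences would leave the segment joining
the two points; since it describes standard SMOTE and cites the original
method, the signed form is implemented, and every synthetic point is verified
(brute force, all pairs) to lie on a minority–minority segment. The
reproducibility constant 114 in the reference is read as the RNG seed and is
the default. k = 5 is the original SMOTE default; the reference gives no
value. A random-repeat oversampling baseline (`random_oversample()`) is
provided for comparison.

## Feature selection

mRMR uses the MID (difference) criterion with plug-in mutual information on
a three-bin discretization at μ ± σ (population σ; outer bins closed). The
first feature maximises I(f; y); each next feature maximises
I(f; y) − mean_{s∈S} I(f; s). Ties break to the lexicographically smallest
name, making the ranking fully deterministic. The greedy output is tested
against an exhaustive re-evaluation of the criterion on small instances.

Sequential forward selection then walks the ranking once, keeping a feature
iff it *strictly* improves the mean stratified 10-fold CV AUC; fold
assignment is fixed by the seed so all candidate subsets are compared on
identical folds. Balancing happens inside training folds only. Because the
wrapper performs O(p) cross-validated fits, its default booster is
deliberately lighter (200 trees, 8 leaves, depth 5) than the final model;
the classifier configuration is an explicit parameter, so the full-size
booster can be requested. The exact feature subset reported for the real
benchmark is dataset-dependent and not a target here.

## Classifier

No gradient-boosting package is available in the supported environment, so
the package ships its own: second-order (Newton) logistic boosting over
regression trees grown leaf-wise (best-first) under `num_leaves` and
`max_depth` caps, exact greedy splits over presorted features, no
subsampling — deterministic by construction. Defaults are the reference
hyperparameters max_depth = 15, num_leaves = 50, n_estimators = 1000, plus
learning rate 0.1 and min_data_in_leaf = 20 (the conventional defaults of
histogram-GBDT frameworks, which the reference leaves unstated). The
classifier sits behind a fit/score-probability plug-in contract, and unit
tests exercise the contract with a trivial stand-in model.

## Evaluation

SEN, SPE, PRE, F1, ACC and MCC follow their defining confusion-matrix
formulas with the decision rule score ≥ 0.5 → positive (the threshold is
unstated in the reference; 0.5 with the ≥ boundary is documented and
tested). Degenerate denominators return 0 with a warning so batch
experiments keep running. AUC is the tie-aware Mann–Whitney rank statistic.
Cross-validation is stratified; metrics are computed on pooled out-of-fold
predictions per repeat; repeat r uses seed + r − 1. Balancing inside
training folds is the default because balancing before the split lets
synthetic points leak held-out information; the reference does not state
which it did, so the leakage-prone variant is available as
`balance_before_cv = TRUE` but is never the default.

## Synthetic data: what it does and does not establish

`simulate_table()` draws every feature N(0, σ²), shifts a chosen informative
subset by `effect_size·σ` in the positive class (default: the dASA block,
the descriptor family most associated with interface hot spots), rounds the
hydrogen-bond column to non-negative integers, and draws ΔΔG as 1 + Exp(1)
kcal/mol for positives and U(−1, 0.999) for negatives so the labeling rule
reproduces the generating class exactly. Defaults are the benchmark
training-set sizes (101/170) with a 2σ effect, σ = 1.

This stated world exercises SMOTE geometry, MI-based ranking, wrapper
selection and classifier margins, and the end-to-end test requires mean
tenfold-CV AUC > 0.9 over 5 seeds on it. It deliberately does *not* emulate
real marginal distributions, inter-feature correlation, or the
protein-complex grouping of real benchmarks — so a green end-to-end test
establishes that the machinery recovers a planted signal, not that the
biological performance of the reference is reproduced. The reference's
headline test metrics depend on its specific curated dataset and are not
desk-reproducible; no numeric acceptance targets are defined.

## Numerical and design notes

- Seeds: every stochastic operation takes an explicit seed and restores the
  caller's RNG state; derived seeds (`seed + r`, `seed + 1000·fold`) stay
  far below 2³¹.
- CSV round trips write numerics with 17 significant digits, so
  write-then-read is the identity at full double precision.
- The `ea_std` descriptor uses the population SD — a fixed choice needed for
  bit-reproducible features.
- `discretize_feature` closes its outer bins (≤ μ−σ, ≥ μ+σ): for continuous
  data the boundary has measure zero, and the closed form handles two-point
  vectors sensibly.
- Known limitations: no inverse transforms or wavelets beyond Haar; no
  ADASYN/undersampling; no comparator selectors or classifiers; complex-level
  (grouped) cross-validation is not implemented — folds stratify by label
  only, as in the reference protocol.
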