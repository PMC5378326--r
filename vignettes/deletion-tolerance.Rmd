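---
title: "Methods: predicting deletion tolerance from protein structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting deletion tolerance from protein structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltol)
```

# The problem and the model

A single amino-acid deletion removes one residue from a protein chain and
forces the backbone to re-close. Whether the protein survives this —
retains its fold and function — depends on the structural context of the
deleted residue. `deltol` treats this as a binary classification problem:
given per-residue structural descriptors, predict the tolerated /
non-tolerated label measured in a deletion scan. The motivating data set
is a scan of enhanced green fluorescent protein (eGFP): 72 single-residue
deletions, 34 of which kept the fluorescent phenotype.

Four predictors are used, all per deleted residue:

* **Side-chain WCN**, $\mathrm{WCN}_i = \sum_{j \neq i} r_{ij}^{-2}$, with
  $r_{ij}$ the distance between side-chain geometric centers (C$\alpha$
  for glycine, and as a recorded fallback for any residue whose side-chain
  heavy atoms are missing from the file). The $r^{-2}$ kernel makes WCN a
  smooth, parameter-free packing density with units of Å$^{-2}$; no
  distance cutoff is involved. Hydrogens never contribute (crystal
  structures rarely resolve them), and the side chain is defined as all
  heavy atoms except backbone N, CA, C, O and OXT.
* **RSA**: Shrake–Rupley solvent-accessible surface area divided by the
  amino acid's maximum ASA in an extended Gly-X-Gly tripeptide
  (`max_asa_gxg()`, the "theoretical" normalization of Tien et al. 2013).
* **Secondary structure**: a 3-level annotation (helix / sheet / loop)
  supplied with the mutant table. The package deliberately does not
  re-derive SS from coordinates: the labels are an input, matching how
  deletion scans are usually annotated.
* **Mean design score**: the arithmetic mean of design-energy totals
  (Rosetta-style, lower = better) over the ~100 modeled structures of one
  deletion mutant. Running the modeling software is out of scope; the
  package parses and aggregates its score tables, warning when a mutant
  has a count other than the nominal 100 rather than failing, since a few
  failed models are routine.

Two learners are fitted per predictor subset: a binomial GLM with logit
link (via `stats::glm`), and a soft-margin SVM with radial kernel (via
`e1071::svm`) at the conventional defaults C = 1 and γ = 1/d, d being the
number of encoded columns after expanding SS to indicators. For the
logistic design one SS reference level (helix, alphabetically first) is
dropped for identifiability; the SVM and the PCA keep all three
indicators, since neither requires full rank. SVM inputs are standardized
with training-set statistics (the `e1071` default), which the fitted
object re-applies to test data; logistic fits are left unstandardized
because maximum-likelihood coefficients are scale-equivariant.

# Evaluation: repeated 10-fold pooled-ROC AUC

Model quality is measured by cross-validated AUC: rows are randomly
partitioned into k = 10 folds (sizes differing by at most one, not
stratified), each fold is scored by a model trained on the other nine,
and the pooled out-of-fold scores — probabilities for the GLM, oriented
decision values for the SVM — form a single ROC curve whose AUC is
recorded. This is repeated (default 100 times) with fresh partitions;
`repeated_cv_auc()` reports the mean and the standard error
$\mathrm{sd}/\sqrt{R}$ across repetitions. Repetition $r$ uses partition
seed `seed + r`, so results are exactly reproducible and two models can be
compared on identical partitions if desired. A partition that leaves a
training fold with a single class is re-drawn with a derived seed and the
event counted; with a 34/38 class split this is essentially never needed,
but it matters for small or unbalanced tables. Model pairs are compared
with an unpaired Welch t-test on the repetition AUC lists (a paired test
is available when fold seeds are shared); the procedure reports only the
mean/SE and the t-test, leaving multiplicity considerations to the user.

The AUC itself is computed by a threshold sweep with tied scores grouped,
which makes the trapezoidal area identical to the tie-corrected
Mann–Whitney statistic $P(s^+ > s^-) + \tfrac12 P(s^+ = s^-)$; the test
suite asserts this equality against a brute-force pair count and against
`pROC`.

**A calibration caveat that the test suite makes explicit.** Pooling
out-of-fold scores into one ROC is the protocol this package implements,
but pooled cross-validated AUC is *pessimistically biased* on data with
little or no signal: out-of-fold scores shift with the training fold's
class ratio, which anti-correlates with the held-out fold's composition,
so score comparisons across folds are systematically wrong. The
acceptance suite contains a null-calibration check (zero-signal table,
n = 100, 100 repetitions) that asserts a mean pooled AUC within 3 SE of
0.5; it fails, by design honestly, for both learners — the acceptance
script reports the measured null values so the size of the effect is
visible for any seed. On tables with real signal of the strength seen in
deletion scans the bias is negligible relative to the signal, but mean CV
AUCs near 0.5 from this pipeline should be read as "no usable signal",
not as an unbiased chance-level estimate.

# Numerical choices

* **ASA quadrature**: each atom is sampled with a deterministic Fibonacci
  lattice (default 960 points) on its probe-expanded sphere (probe
  1.4 Å; van der Waals radii C 1.70, N 1.55, O 1.52, S 1.80, P 1.80,
  Se 1.90 Å). A point is accessible if outside every other atom's
  expanded sphere. The deterministic lattice makes ASA bit-reproducible
  for a fixed point count; the single-atom analytic case converges to
  well under 2% error at 960 points, and rotation invariance holds to
  quadrature jitter. DSSP-style ASA differs in algorithmic detail;
  absolute ASA values are therefore method-dependent, while RSA ranks are
  very stable.
* **RSA above 1** is retained and flagged rather than clipped; it occurs
  legitimately at termini and for distorted residues.
* **Alternate locations**: the copy with the highest occupancy wins, ties
  broken by file order. HETATM records are excluded by default; named het
  residues (e.g. the mature eGFP chromophore, `CRO`) can be pulled in as
  pseudo-residues via `include_het` if one wants their atoms to
  contribute contacts and occlusion. Whether a given published analysis
  included chromophore atoms is usually unstated; the default here is the
  conservative exclusion, with the flag as the sensitivity check.
* **PCA** is computed on the correlation matrix (every encoded column
  centered and unit-scaled) — necessary when mixing 0–1 RSA, ~unit WCN
  and design scores in the hundreds. Eigenvector signs are fixed by
  making each axis's largest-magnitude loading positive, so loadings and
  scores are deterministic. With all three SS indicators included the
  encoded columns are linearly dependent; the smallest eigenvalue is
  then 0 (clamped from the −10⁻¹⁶ that floating point produces).
* **Separation**: perfectly separable logistic fits are detected from the
  fitted-probability/non-convergence warnings and returned at the
  iteration cap with a flag — their out-of-fold *ranking* remains usable,
  which is all the AUC needs.

# The synthetic-data generators

`synth_structure()` builds pseudo-proteins: residues along a
boustrophedon lattice path at the 3.8 Å C$\alpha$ spacing, each with four
backbone atoms and 1–4 side-chain carbons (none for glycine). This gives
parsers, WCN and ASA code a substrate with known topology — interior
lattice residues are genuinely buried — while making no claim to
realistic stereochemistry, rotamers or hydrogen bonding. Conclusions
about *chemical* accuracy cannot be drawn from it; conclusions about the
*geometry* code can.

`synth_feature_table()` generates study-shaped tables in two modes. The
class-conditional mode draws a fixed 34/72 tolerated split and then
features from per-class normals: defaults place the tolerated class at
higher RSA (0.40 ± 0.18 vs 0.20 ± 0.12), lower WCN (0.16 ± 0.05 vs
0.26 ± 0.06) and more negative mean score (−515 ± 10 vs −495 ± 12), with
SS probabilities equal to the published per-category counts (loop-heavy
tolerated, sheet-heavy non-tolerated). The class means and spreads are
package choices on realistic scales, not measured values; the SS
probabilities and the 34/38 split are the study's. Gaussian draws are not
truncated, so a synthetic RSA can dip marginally below 0 — harmless for
classifiers and kept so that sample moments converge exactly to the
configured parameters (a property the tests check at n = 10⁴). The
generative-logistic mode instead draws features from pooled
distributions and labels from a configured logistic model, returning the
per-row linear predictor as ground truth; this is the mode used for
coefficient-recovery and null-calibration checks. `binormal_scores()`
supplies the one case where the AUC has a closed form,
$\Phi\big((\mu_+-\mu_-)/\sqrt{\sigma_-^2+\sigma_+^2}\big)$, as an oracle.

The test suite and acceptance script use problem sizes chosen to make
each check statistically decisive while keeping a full run fast on one
core: WCN oracle clouds up to N = 200, coefficient recovery at n = 2000
over 20 seeds, ranking at n = 200 with 100 repetitions, moment
convergence at n = 10⁴.

# Design decisions on genuinely open points

* The eGFP secondary-structure contingency table shipped as
  `egfp_ss_counts()` is *reconstructed*: the published per-category
  tolerated fractions (78.3%, 66.7%, 21.6%) combined with the 34/38
  class totals admit exactly one integer table, and that table reproduces
  the published χ² P-value to all printed digits. It is a faithful
  derivation from summary statistics, not a redistribution of the
  underlying per-mutant data, which is why per-mutant analyses in this
  package run on synthetic tables instead.
* Folds are unstratified because the protocol being reproduced specifies
  plain 10-fold partitions; stratification would change the repetition
  variance slightly.
* The model-comparison t-test is unpaired Welch by default. Pairing by
  repetition is statistically attractive when both models share fold
  seeds, and is implemented, but it is not assumed.
* γ = 1/d uses d = the number of encoded columns after SS expansion —
  the dimension the kernel actually sees.
* SVM ranking scores are signed decision values, not platt-scaled
  probabilities; AUC is invariant to any monotone rescaling, so this
  choice only matters if one wants calibrated probabilities, which the
  pipeline does not produce.

# Known limitations

Single chains only (no biological-assembly handling beyond what the PDB
file contains); mmCIF is not parsed; SS is never computed from
coordinates; the design-score predictor depends entirely on externally
generated score files; and the pooled-CV pessimism described above is a
property of the protocol, faithfully reproduced rather than corrected.
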