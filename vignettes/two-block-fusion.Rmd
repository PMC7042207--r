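---
title: "Two-block infrared data fusion: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-block infrared data fusion: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irfusion)
```

## The problem

Plant raw material accumulates secondary metabolites in proportions that
depend on where it grew — temperature, precipitation, elevation, soil. Two
complementary vibrational fingerprints of the powdered material, a
near-infrared block (overtones and combination bands, 10,000–4,000 cm⁻¹)
and an ATR mid-infrared block (fundamentals of polysaccharides, amides,
lipids, flavones, 4,000–650 cm⁻¹), each carry part of that geographic
signature. `irfusion` implements the complete authentication pipeline for a
13-region design with 187 samples measured in triplicate on both
instruments, and a synthetic generator that stands in for the
(non-deposited) original spectra.

## Pretreatment

**MSC.** Powder measurements suffer multiplicative (path-length,
particle-size) and additive scatter. Each spectrum is least-squares fitted
to a reference, `x ≈ a·ref + b`, and replaced by `(x − b)/a`; both slope
and offset are corrected (the full MSC definition, the standard one where
the variant is unstated). The reference is the *calibration-set* mean,
frozen before validation spectra are corrected, so the correction cannot
leak validation information. A fitted slope below `1e-8` in magnitude is
not inverted; the spectrum is mean-centred and a warning names the sample.

**Second derivative.** A Savitzky–Golay filter (default `window = 11`
points, `poly_order = 2`; no smoothing parameters are prescribed by the
protocol, these are conventional values for ~2 cm⁻¹-spaced spectra)
differentiates twice with respect to the wavenumber axis, removing baseline
offset and slope and sharpening overlapping bands. The axis must be
uniformly spaced — region exclusion therefore happens *after*
derivative filtering in the pipeline. Edge points come from the filter's
polynomial edge fits, so a quadratic input yields its exact second
derivative everywhere, which is how the filter is tested.

**Order.** The chain is MSC first, then derivative, following the
protocol's name ("MSC + SD"); the order is not otherwise specified.

**Region exclusion.** Closed intervals (both endpoints inclusive) are
dropped from the MIR block by default: 4,000–3,700, 2,799–1,800 and
682–653 cm⁻¹ — baseline area, diamond-crystal/CO₂ absorbance, and the
low-end cutoff.

**`[-1, 1]` scaling.** Before any fusion, every variable is mapped by
`2(x − min)/(max − min) − 1` with min/max learned on calibration rows only.
Constant columns map to 0; validation values may leave `[-1, 1]` (no
clipping). Scaling is per variable; the protocol states only that the
dataset was normalised to `[-1, 1]`.

## Kennard–Stone splitting

The split is deterministic: the first two picks are the pair at maximum
Euclidean distance, each later pick maximises its minimum distance to the
selected set, all ties resolve to the lowest row index. The default is
*per-class* selection of `round(2·n_g/3)` calibration samples (round half
away from zero): applied to the design's class sizes
(11, 31, 10, 21, 7, 20, 16, 30, 5, 10, 6, 10, 10) this yields 126
calibration and 61 validation samples — the totals implied by the published
accuracy denominators, which a pooled `round(2·187/3) = 125` split would
not reproduce. Distances are computed on the preprocessed, scaled,
low-level-fused matrix. Because the modelling MSC reference is
calibration-only while the split must precede it, the pipeline places the
split using a provisional global-mean-reference pretreatment, then refits
the final pretreatment with the calibration-only reference; cells of the
experiment grid share this split and preprocessing but no fitted state.

## PLS-DA

Class labels are one-hot encoded into a dummy matrix `Y`; NIPALS PLS2
extracts latent variables (LVs) from column-centred `X` (unit-variance
scaling optional, off by default — second-derivative spectra are already on
a common scale). The LV count is chosen by a significant-component rule:
component *a*'s eigenvalue is its explained X sum of squares in
average-variable units, `SS_a / (SS_total / p)`, and leading components
with eigenvalue > 1 are kept, capped at `max_lv` (default 15). The rule's
base quantity is ambiguous in the protocol ("eigenvalue > 1" without a
stated matrix or scaling), so the convention is configurable (`n_lv`
overrides it entirely). One floor is applied: a G-class dummy response
spans up to G − 1 directions, and retaining fewer LVs provokes the
classical masking pathology of least-squares classification on indicator
matrices — with 13 classes, even perfectly separated data plateaued near
91% when the eigenvalue rule kept 7 LVs. The retained count is therefore
never below `min(G − 1, max_lv, rank)`.

Cross-validation uses 7-fold venetian blinds over the class-sorted sample
order, keeping folds class-balanced. `Q²Y = 1 − PRESS/TSS`; `RMSEE` uses
denominator `n − n_LV − 1` per response column (fitted-parameter
correction), while `RMSECV`/`RMSEP` use plain `n` — the statistics are
named but not defined in the protocol, and these are the conventional
choices.

Prediction: hard labels by argmax of the predicted dummy vector (ties to
the lowest class index, flagged); soft class memberships by clipping the
dummy predictions to `[0, 1]` and renormalising to sum 1 (an all-zero row
becomes uniform). The permutation test refits the model at the original LV
count under 20 uniformly random label permutations and regresses
`R²`/`Q²` on the absolute correlation between permuted and original dummy
matrices (the original model enters at correlation 1); a valid model has
all permuted `Q²` below the original and a negative `Q²`-intercept.

## Random forest

The tree inducer is the `randomForest` package — the implementation used in
the original protocol; the package owns the protocol around it. Tuning is
sequential on out-of-bag (OOB) error: scan tree counts at the default
`mtry` (reading the cumulative OOB-error curve of one forest grown to the
largest grid value, which is what the tuning curves display), fix the
minimiser (ties to the smallest), then scan `mtry` at that tree count.
Variable importance is the *raw* mean decrease in OOB accuracy under
single-variable permutation (z-scored available by flag); variable
selection ranks by importance and picks the smallest top-k set whose
10-fold cross-validated accuracy is within one standard error of the best.
Soft memberships are class-vote fractions — OOB votes for training samples,
full-ensemble votes for new samples — and rows sum to 1 exactly. A fixed
seed makes votes, importance and OOB error bit-reproducible.

## Fusion

*Low-level*: `[-1, 1]`-scaled variables of both blocks concatenated
NIR-first, with column provenance recorded. *Mid-level*: per block, PCA on
the calibration rows of the `[-1, 1]`-scaled variables; components with
covariance eigenvalue > 1 retained (or a fixed count); validation rows
projected with calibration loadings. The prescaling matters: raw
second-derivative spectra have covariance eigenvalues of order 10⁻⁴, and
the threshold of 1 is only meaningful on the normalised scale. The
eigenvalue rule typically retains ~5 components per block here, which is
why mid-level fusion — squeezing 13 classes through ~10 feature dimensions
— is structurally the weakest cell, for PLS-DA especially (the masking
issue above).

*High-level*: per sample, if the two single-block classifiers agree, their
label stands. Otherwise the two membership vectors are combined by the four
fuzzy connection operators — elementwise minimum, maximum, average, product,
each renormalised — and the majority over the four operator labels decides,
with ties broken by the average operator's label. The majority is over
operators only (they are invoked precisely for the inconsistent samples);
counting the source labels too is available by flag. The protocol mentions
re-weighting the two vote vectors without defining weights; equal weights
are the default and a weight parameter is exposed on the average operator.
Argmax ties always resolve to the lowest class index.

## Evaluation

One-vs-rest counts per class (TP + FN = class size; TP + FP + TN + FN = n,
asserted invariants), then `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`,
`PRE = TP/(TP+FP)` in percent. Efficiency is implemented as the geometric
mean `EFF = √(SEN·SPE)`: the protocol prints the formula as a bare product,
but every published EFF cell equals the root of the product (e.g.
SEN = 1/3, SPE = 1 gives 57.74, and 100 × 96.08 gives 98.02), so the
printed formula is read as an omitted radical — the verification is encoded
in the test suite. `PRE` is undefined for a class never predicted and such
cells are excluded from the macro averages, matching the published row
averages. Values are stored at full precision; reporting rounds to two
decimals half-away-from-zero. Full precision matters: the EFF of the
printed pair (33.33, 100.00) rounds to 57.73, while the underlying exact
ratio 1/3 gives the published 57.74.

## Exploratory analysis

PCA scores are sign-fixed by the largest-loading-positive rule. Ward
linkage (`ward.D2`) on Euclidean distances is the HCA default — no linkage
is named in the protocol — and merge heights are rescaled linearly to
`[0, 25]`, the dendrogram convention of the statistics package whose
distance thresholds (10, 9) the protocol quotes; `cut_clusters()` operates
on that axis. t-SNE is implemented exactly (dense affinities, perplexity
matched by bisection, early exaggeration, momentum with gain adaptation and
a final annealing phase), deterministic under a fixed seed, and quadratic
in n — adequate to a few hundred samples. Exact duplicate inputs embed as
tight mutual nearest neighbours but, as in reference implementations, not
fully coincident (a few percent of the embedding diameter at small
perplexity). `covariate_overlay()` joins cluster labels to the per-site
environmental table for the per-cluster summaries behind statements like
"the isolated branch is the arid, high-latitude region".

## The synthetic generator

`synthetic_spec()` encodes the study design: 13 classes with the published
per-region sample counts (187 samples), 3 replicates each, Gaussian bands
at the published NIR and MIR peak positions (widths and base amplitudes
typical of plant powders: broad NIR overtones, narrow MIR fundamentals).
For sample *s* of class *g*, replicate *r*:

    x(ν) = m·[b₀ + b₁t + Σₖ Aₖ exp(−(ν − μₖ)²/(2σₖ²))] + o + ε(ν)
    Aₖ   = αₖ + w_b·(βₖᵀ z_g + u_{g,k}) + v_{s,k}

with `z_g` the standardised class covariates (temperature, precipitation,
elevation; defaults follow the published site table where given, coarse
climate-zone values otherwise), `u`/`v` class- and sample-level random
effects, `m ~ U(1 ± 0.15)` and `o ~ U(±0.05)` per-replicate scatter (so MSC
has real work to do), and i.i.d. noise `ε`. Covariate effects enter
*linearly* on peak amplitudes — the minimal testable form of the
qualitative environment–composition link. The block weight `w_b`
(normalised by per-block peak count) partitions discriminative variance so
`info_split` is the fraction carried by NIR; `split_block_information()`
exposes it for fusion experiments. Everything is deterministic given the
seed.

The default axis spacing, 1.93 cm⁻¹, approximately reproduces the
published variable counts (~3,098 NIR; ~1,047 MIR after region exclusion);
the stated 4 cm⁻¹ instrument resolution would give 1,501 NIR points, so
the true digitisation interval is evidently finer and unstated — the
spacing is a configuration value, not a claim. Tests and examples use
coarser spacings (15–60 cm⁻¹, giving 100–230 variables per block) to keep
full-pipeline runs fast; peak widths are large relative to even the coarse
spacings, so no structure is lost.

**Presets.** `separable` (large class effects, low noise) drives every
grid cell to 100%; `chance` (zero class-discriminative terms) puts
classifiers at the no-information level; `paperlike` — the default effect
scales — is calibrated so single-block PLS-DA validation accuracy lands in
the 75–90% regime with headroom for fusion: at the test problem scale the
NIR block averages ≈ 76% and MIR ≈ 90%, and high-level fusion of the two
single-block forests matched or beat the better block in 20 of 20 seeds
(strictly better in 17). These scales were fixed once from that
calibration target.

**What the generator does not emulate** — and therefore what passing tests
do not establish about real data: physical lineshapes (Voigt profiles,
instrument response functions), wavelength-dependent scatter, water-vapour
interference bands, nonlinear detector response, correlated (pink) noise,
and any nonlinear environment–composition relationship. The published
headline accuracies of the real study are outcomes on unavailable raw
spectra and are out of scope as target numbers; what the package
establishes is the machinery and its qualitative behaviour (fusion benefit,
chance levels, permutation validity, covariate-driven cluster isolation).

## Numerical choices and degenerate inputs

- Wavenumber axes are stored strictly descending; ascending input is
  reversed on construction, so file order cannot cause misalignment.
- Interval endpoints of excluded regions are inclusive on both sides
  (ranges are printed as closed).
- All argmax ties, everywhere, resolve to the lowest class index and are
  flagged where a caller could care.
- `round(2n/3)` rounds half away from zero, as does all 2-decimal
  reporting (base R rounds half to even).
- Kennard–Stone handles duplicate rows through the lowest-index tie rule;
  a single-member class is forced into calibration with a warning.
- MSC with a near-zero fitted slope falls back to mean-centring (warning);
  a zero-variance reference is an error.
- The derivative filter refuses non-uniform axes (relative spacing
  deviation above `1e-6`) rather than silently mis-scaling.
- Constant columns scale to 0 in the `[-1, 1]` map; validation rows are
  not clipped.
- An all-zero clipped PLS-DA dummy row becomes a uniform membership.
- The experiment grid embeds its seed and a configuration hash in every
  report for provenance.

## Problem sizes

Tests and the acceptance script run the full pipeline at 13 classes × 187
samples × 3 replicates with 100–230 variables per block (axis spacings of
15–60 cm⁻¹), forests of 150–500 trees, 20-seed repetition for the
stochastic properties, and exhaustive oracle checks on instances of up to 8
points. The complete suite runs in about a minute on one core.

## Known limitations

- PLS-DA memberships are clipped least-squares dummy predictions, not
  calibrated probabilities; decision fusion with a much weaker partner
  block can cost the stronger block a sample or two under equal weighting
  (the weight parameter exists for exactly that case).
- High-level fusion is implemented for exactly two blocks, as in the
  protocol.
- The LV eigenvalue rule and the mid-level component rule are conventions
  chosen among defensible readings; both are configurable, and conclusions
  that depend on them should be checked under the alternatives.
- t-SNE is exact (O(n²)) and not intended beyond a few hundred samples.
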