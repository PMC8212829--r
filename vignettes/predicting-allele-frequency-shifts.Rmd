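---
title: "Predicting population-level allele-frequency shifts under changed climates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting population-level allele-frequency shifts under changed climates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clineshift)
library(dplyr)
```

## The problem

Populations of a species sampled along environmental gradients differ in the
frequencies of alleles at loci associated with climate adaptation. If the
baseline association between climate and allele frequency is taken as a
predictor, one can ask: *what allele frequencies would each population need
under a changed (future or paleo) climate?* The answer informs assisted
migration and seed-sourcing decisions, and quantifies the genomic offset
between what a population has and what its future site may favour.

`clineshift` implements this prediction as a two-step pipeline over
population-level allele count tables (rows = populations, paired columns =
the two alleles of each biallelic locus) and aligned population-by-climate
tables.

## The model

### Step 1 — redundancy analysis of allele counts

Let $Y$ be the $g \times 2L$ matrix of allele counts ($g$ populations, $L$
loci, two columns per locus) and $X$ the $g \times p$ matrix of baseline
climate variables. Redundancy analysis (RDA) is the PCA of the fitted values
of the multivariate least-squares regression of column-centered $Y$ on
column-centered $X$:

$$\hat Y = X_c B + \bar y, \qquad B = (X_c^\top X_c)^{-1} X_c^\top Y_c ,$$

followed by an SVD of $X_c B$. RDA preserves Euclidean distances among rows,
which is also the distance underlying analysis of molecular variance
(AMOVA); `amova_rda()` exploits this by regressing individual-by-allele
counts on population indicators, recovering the among/within sum-of-squares
partition and $\Phi_{ST}$ directly from the constrained and residual inertia.
Inertia is scaled by $n - 1$ (the variance convention), so AMOVA sums of
squares are inertia times $n - 1$; the test suite verifies the partition
against a brute-force pairwise squared-distance computation and verifies that
population frequency profiles sit at the centroids of their individuals'
dosage profiles.

Prediction inserts the changed-climate values into the fitted regression.
Because each population's total sampled alleles $N$ is known and fixed, the
raw predicted pair $(a, b)$ of each population and locus is rescaled
proportionally so that $A_p + B_p = N$ exactly:

$$A_p = \frac{a N}{a + b}, \qquad B_p = \frac{b N}{a + b}.$$

The rescaling is per (population, locus) pair because each locus has its own
predicted pair; the observable contract is that the predicted pair restores
$N$ exactly, including when one member is negative. A pair whose raw sum is
not positive has no meaningful rescaling and is reported as an error. Raw
predictions are deliberately *not* clamped: a linear model extrapolated to a
new climate can and does predict negative counts (equivalently frequencies
outside $[0,1]$), and repairing that is the second step's job, not a
truncation's.

An optional canonical correspondence analysis (CCA) variant is provided for
comparison with the chi-square-profile protocol used elsewhere in the
literature: profiles $Q = (P - rc^\top)/\sqrt{rc^\top}$ are regressed on
row-weight-standardized climate variables and fitted profiles are
back-transformed at the calibration row and column masses. When all
populations have equal sample sizes the chi-square standardization is an
affine transform of each column and CCA predictions coincide with RDA; with
unequal $N$ they differ. CCA predictions can equally be negative and are
flagged.

### Step 2 — binomial smooth correction

For each locus, the observed baseline minor-allele frequency (as a
successes/failures pair, so populations are weighted by $N$) is regressed on
the RDA-predicted baseline minor-allele count through a binomial GAM with
logit link (`mgcv::gam`, penalized cubic regression spline):

$$\mathrm{logit}\, f = s(A_p^{\text{baseline}}).$$

Predictions for any climate evaluate the smooth at that climate's $A_p$.
Because the inverse link is the logistic function, corrected frequencies
(`Freq.e2`) and their confidence limits are guaranteed to lie in $[0,1]$ no
matter how far the count predictions stray. The 95% limits are computed on
the link scale as the linear predictor $\pm 1.96$ standard errors and
back-transformed, which preserves the ordering
$\mathrm{LCL} \le \mathrm{Freq.e2} \le \mathrm{UCL}$.

The output table carries, per population and locus: `N`, `Allele.freq`
(observed baseline minor-allele frequency), `A`, `B`, `Ap`, `Bp`, `N.e1`
($=A_p+B_p$), `Freq.e1` ($=A_p/N.e1$, unbounded), `Freq.e2`, `LCL`, `UCL`
and `increasing` (`Freq.e2 > Allele.freq`). All counts in this table are
oriented so that the `A` side is the minor allele — the allele with the
smaller summed count across populations in the baseline data, with ties
labelled A.

## Tunable parameters

* **VIF threshold** (`vif_subset`, default 20): retained explanatory
  variables must have variance inflation factors at or below this ceiling,
  the usual working bound for collinearity in this kind of regression-based
  modelling. Reduction is two-step: variables correlated above `cor_cut`
  with any force-kept variable are dropped first, then the worst-VIF
  variable is removed iteratively. `cor_cut` (default 0.9) is a separate
  parameter: a correlation cannot meaningfully be compared with a VIF
  threshold, so the correlation screen needs its own cutoff.
* **Smooth basis dimension** (`freq_model`, default
  `min(4, populations - 1)`): these designs often have only 10–30
  populations, so a small basis guards against overfitting; values below 3
  fall back to an ordinary (linear-in-link) logistic regression and the
  basis is reduced automatically when populations are few. The default was
  fixed before any accuracy measurement and is not tuned per dataset.
* **Confidence level**: fixed at 95%.
* **Prediction rank** (`predict` on an RDA fit, default `"full"`): the
  constrained solution can optionally be projected onto the leading
  ordination axes; no axis-selection rule is imposed by default.
* **Novelty scoring** (`environmental_novel`): a changed value is novel only
  when strictly outside the baseline range (boundary values are familiar,
  hence inclusive); the tail probability is one-sided on the violated side,
  using the baseline column mean and *sample* (n−1) standard deviation. The
  smallest tail probability across variables is the population's novelty
  score.

## The synthetic-data generator

`cline_scenario()`/`generate_dataset()` emulate the study design the
pipeline targets: populations evenly spaced along a dominant climate driver,
logistic allele-frequency clines
$f_{pl} = \mathrm{logit}^{-1}(\beta_{0l} + \beta_{1l} x_p)$, binomial
sampling of $N$ alleles per population, a uniform climate shift $\Delta$,
and nuisance climate variables correlated with the driver to exercise the
collinearity tooling. The reference conditions — 20 populations, $N = 100$
alleles each, 4 loci, driver spanning $[-2, 2]$, $\Delta = 0.5$ — are the
defaults used throughout the tests; the shift is a strong but
within-calibration-range displacement of a quarter of the gradient
half-width. Randomness is keyed by `(seed, population, locus)` counters, so
a fixed seed gives byte-identical output and adding loci never perturbs
existing columns.

What the generator does **not** emulate: genetic drift across generations,
linkage between loci, dominance or epistasis, spatially autocorrelated
sampling noise, the heavy-tailed correlation structure of real bioclim
variable sets, or migration between populations. Passing the recovery tests
therefore shows that the estimator chain is correct and numerically stable
under its own assumptions — frequencies monotone in a climate driver,
independent binomial sampling — not that real future allele frequencies will
be predicted to the same accuracy. Under the reference conditions the
pipeline recovers shifted-climate frequencies with mean absolute error well
under 0.02 without sampling noise and under 0.05 with binomial noise at
$N = 100$; both figures are recomputed by the test suite and the acceptance
script rather than asserted here.

## Numerical choices and degenerate inputs

* Centering only (no standardization of $Y$ or $X$) for the RDA fit; fitted
  values are invariant to explanatory scaling.
* Rank-deficient explanatory matrices are an error naming the dependent
  columns; a zero-column matrix degenerates to PCA of the response.
* Ties in the minor-allele definition go to allele A; output ordering is by
  locus then population, deterministically.
* Loci fixed at frequency 0 or 1 in the baseline cannot support a binomial
  fit and are modelled as constants with a warning; zero-variance predictors
  likewise collapse to intercept-only fits.
* AMOVA with one population is an error (no among-population degrees of
  freedom); identical individuals give zero sums of squares and an undefined
  $\Phi_{ST}$, reported as missing with a warning. The indicator coding
  drops one level; sums of squares are coding-invariant and tested as such.
* Waffle grids round half-up (62.5 cells → 63) and fill row-major from the
  top-left on a fixed 10×10 layout; pie arcs are measured clockwise from
  12 o'clock; moon glyphs use a terminator semi-axis of $1 - 2f$ so the lit
  *area* fraction equals the frequency exactly. Trend colours are fixed:
  red = decreasing, green = increasing.
* Geographic surfaces use a thin-plate smooth with basis dimension growing
  with the number of locations (`min(10, n - 1)`); with fewer than five
  locations the smoother reduces to a plane, and fewer than three or
  collinear locations are an error.

## Design choices where the design was open

* **Per-locus frequency models.** One pooled smooth across alleles would
  share information but couple unrelated loci; independent per-locus models
  keep the correction local and are the package's choice.
* **How `N.e1` equals `N`.** Proportional pairwise rescaling was adopted
  because the published worked example shows $A_p + B_p = N$ exactly for
  every population, including one with a negative predicted count — a
  property proportional rescaling preserves and clamping would not.
* **`increasing`** compares the corrected changed-climate frequency with the
  *observed* baseline frequency, consistent with all rows of the published
  worked example.
* **Column naming.** The canonical plain text format names allele columns
  `<locus>.A` / `<locus>.B` with a leading `population` column — minimal,
  lossless and diff-friendly. Missing data are rejected, not imputed;
  records with missing genotypes or climate values should be removed before
  analysis.

## Problem sizes in the test suite

The suite and the acceptance script run on deliberately small instances: the
reference 20-population scenario for end-to-end recovery; 100 random
10-population scenarios for the count-conservation property; 50 random AMOVA
instances of at most 10 populations × 10 individuals × 10 loci against the
brute-force distance oracle; and the published four-population worked
example for the arithmetic identities. These sizes were chosen as the
smallest that exercise every code path with comfortable margins.

## Known limitations

The method is correlative, exactly as correlative species distribution
models are: it will happily extrapolate into climates far outside the
calibration range and return confident-looking frequencies there. Use
`environmental_novel()` to flag populations whose changed climate leaves the
calibration range, and treat predictions for them with proportionate
suspicion. The approach also assumes allelic effects are independent and
additive (no epistasis or dominance), that baseline spatial gradients are a
valid proxy for temporal change, and that the loci supplied were correctly
identified as climate-associated by an upstream association analysis. None
of these assumptions are checked by the software.
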