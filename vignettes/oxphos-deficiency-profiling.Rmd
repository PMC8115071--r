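---
title: "Single-neuron OxPhos deficiency profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-neuron OxPhos deficiency profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxphosimc)
```

## The problem

Imaging mass cytometry (IMC) images post-mortem midbrain sections at roughly
1 µm² per pixel, one channel per metal-tagged antibody. With a panel covering
subunits of all five oxidative-phosphorylation (OxPhos) complexes —
NDUFB8/NDUFA13 (complex I), SDHA (CII), UqCRC2 (CIII), MTCO1/COX4 (CIV),
ATP5B/OSCP (CV) — plus the mitochondrial mass marker VDAC1 (porin), tyrosine
hydroxylase, Histone H3 and an Ir DNA intercalator, each manually outlined
dopaminergic neuron yields one mean cytoplasmic intensity per target. The
scientific question is which neurons express an OxPhos subunit *less than
their mitochondrial mass predicts*, how deficiencies combine across
complexes within single neurons, and how disease groups (Parkinson's
disease, POLG-mutation mitochondrial disease) differ from controls.

This package implements that analysis end to end, plus a synthetic cohort
and image generator so every stage is testable without tissue data.

## Pixel segmentation and quantification

Within each neuron outline, pixels are classed cytoplasmic unless their
intensity exceeds a threshold (default 5 raw counts, strict `>`) on an
exclusion channel. The exclusion channels default to Histone H3 (nucleus)
and Ir (nucleus and neuromelanin), matching the stated purpose of the rule;
both the channels and the threshold are configurable because the published
rule names only the threshold. Each target's per-neuron value is the
arithmetic mean over cytoplasmic pixels; neurons with zero cytoplasmic
pixels are dropped and logged, never imputed.

Rasterization uses a fixed, documented convention: 0-based coordinates,
x = column, y = row, and pixel-center inclusion under the even-odd rule. The
convention is arbitrary but must be pinned for reproducibility; tests check
it against an independently coded per-pixel oracle.

## The normative control model

All deficiency calls are made against pooled control neurons (one
regression per subunit, all control cases together). With
$x = \ln(\text{VDAC1})$ and $y = \ln(\text{subunit})$, ordinary least
squares gives $\hat y = a + b x$, residual SD $s$ (denominator $n-2$).
Neurons with non-positive intensity in either channel are excluded and
counted; taking logs of pseudocounted zeros is refused by design.

Two derived quantities coexist because they serve different displays:

* **Perpendicular z-score** (used for distribution plots and group
  contrasts): the signed orthogonal distance
  $d = (y - a - b x)/\sqrt{1+b^2}$ divided by the $n-1$ SD of $d$ over the
  control neurons. Control z-scores therefore self-standardize (mean 0,
  SD 1) by construction; a config switch selects the vertical-residual
  z-score for sensitivity analyses, since the reference web tool's exact
  definition is not published.
* **80% prediction interval** (used for the deficiency call): a neuron is
  "decreased" for a subunit iff its $y$ falls strictly below
  $\hat y_0 - t_{0.90,\,n-2}\, s \sqrt{1 + 1/n + (x_0-\bar x)^2/S_{xx}}$.
  Ties exactly on the limit are not decreased. Under the generating model
  this lower limit flags 10% of fresh control neurons one-sided, which is
  the property the acceptance suite checks.

The mitochondrial-mass z-score is $(\ln v - m)/s$ with $m, s$ the mean and
$n-1$ SD of $\ln$ VDAC1 over pooled controls; the natural-log scale was
chosen for consistency with the regressions (the source is silent) and is
switchable in principle by scoring raw values externally.

## Complex-level calls and severity

Complexes with two assayed subunits are represented by one of them:
NDUFA13 (CI), MTCO1 (CIV), ATP5B (CV); SDHA and UqCRC2 represent their
single-subunit complexes trivially. Non-representative subunits are still
flagged and reported at subunit level. A neuron's severity category is the
number of complexes called decreased (0–5). A neuron missing any
representative measurement gets no category and is logged — the source does
not state how such neurons were handled, so this is recorded as an
implementation decision. Per-case percentages are computed as plain ratios;
group displays aggregate cases by median. Conditional co-deficiency tables
split each case's neurons by an anchor complex's call and exclude cases
with an empty stratum.

## Bayesian two-group estimation

Group contrasts use the robust two-group model
$y_{gi} \sim \mathrm{StudentT}(\nu, \mu_g, \sigma_g)$ with the canonical
broad priors: $\mu_g \sim N(\text{pooled mean}, (1000\,\text{pooled SD})^2)$,
$\sigma_g \sim U(\text{pooled SD}/1000, 1000\,\text{pooled SD})$, and
$\nu \sim 1 + \mathrm{Exp}(\text{mean } 29)$ shared across groups. The
source names only the method and package it used; the prior constants follow
that package's published model definition and are echoed in every report.

Sampling is a partially collapsed Gibbs scheme written for this package:

1. $\nu$ is updated by adaptive random-walk Metropolis on
   $\log(\nu - 1)$ against the *marginal* Student-t likelihood (latent
   scales integrated out). Updating $\nu$ against the latent scales instead
   mixes an order of magnitude worse (effective sample sizes of tens rather
   than thousands in our diagnostics), which is why the collapsed update
   was chosen.
2. Per-observation latent precisions $\lambda_{gi} \sim$ Gamma are then
   regenerated from their full conditional, making step 1 valid.
3. $\mu_g$ and $\sigma_g^2$ have conjugate updates given $\lambda$; the
   uniform-on-$\sigma$ prior enters as a truncated Gamma draw on the
   precision via inverse-CDF sampling.

Runs are rejected unless split-chain R-hat < 1.01 on $\mu_1, \mu_2,
\mu_1-\mu_2$ and the effective sample size of $\mu_1-\mu_2$ is at least
200. Defaults are 4 chains × (2000 warmup + 5000 draws); the pipeline's
many per-case contrasts default to 2 × (500 + 1500), which passes the same
gates on all test fixtures while keeping end-to-end runs inside desk-scale
budgets. The 95% highest density interval follows the canonical
shortest-window convention: endpoints are sorted draws
$\lceil 0.95 n \rceil$ apart, first window on ties (so the interval spans
one more draw than the mass strictly requires — this matches the reference
implementation and the worked example both). Effect size is
$(\mu_1-\mu_2)/\sqrt{(\sigma_1^2+\sigma_2^2)/2}$ per draw. Per-case
mass contrasts (decreased vs normal neurons) require at least 3 neurons per
stratum, enforced by the pipeline caller, not by `best_fit()`.

## Classical statistics

Mann–Whitney U counts pairs where the first group's value beats the
second's (ties half); p is exact from the full null distribution of U
(subset-count dynamic programming over rank sums) when
$n_a n_b \le 400$ with no ties, otherwise a tie- and continuity-corrected
normal approximation. Spearman's r uses midranks, with an exact permutation
p for $n \le 9$ without ties. The 95% confidence ellipse is the data
ellipse: covariance eigendecomposition with squared-radius multiplier
$\chi^2_{2,0.95} = 5.991$; the small-sample F form is available by
argument. Count summaries use the $n-1$ SD and round only at report time.
No multiple-testing correction is applied, matching the source convention
of reporting unadjusted pairwise tests.

## The synthetic cohort: what it emulates, and what a green test means

The generator produces the statistical structure the analysis *assumes*:

* $\ln V \sim N(m_V, s_V)$ with defaults $m_V = 5$, $s_V = 0.5$;
  each subunit $\ln I_k = a_k + b_k \ln V + \varepsilon$,
  $\varepsilon \sim N(0, s_k)$, defaults $a = 0, b = 1, s = 0.25$ —
  ln-intensity units, free simulation parameters rather than estimates of
  tissue biology.
* Deficits act multiplicatively on the raw scale (a subtraction
  $\delta_c$ in ln units from every subunit of an affected complex), which
  keeps intensities positive and matches the ln-ln analysis. The default
  $\delta = 1$ equals 4 residual SDs, a comfortably detectable effect; the
  source provides no ln-scale effect size, so $\delta$ is explicitly a
  free parameter.
* Deficiency labels are Bernoulli per complex per neuron
  ($\pi_c$; group defaults 0 / 0.25 / 0.5 for control / PD / POLG), with
  an optional Gaussian-copula correlation $\rho$ (default 0) because the
  source reports combined deficiencies without specifying a generative
  dependence.
* Per-case neuron counts are rounded normals truncated at 5, with group
  means/SDs taken from the published cohort summary (35.1 ± 9.6 for 9 PD
  cases, 39.0 ± 11.7 for 4 POLG, 43.6 ± 4.7 for 10 controls); ages follow
  the published group means/SDs, truncated to 18–95 years.
* One master seed drives independent substreams for counts, ages, labels
  and noise, so each layer is reproducible in isolation.

Synthetic images place star-shaped, pairwise-disjoint cell polygons with a
nucleus disc and a neuromelanin blob inside each, paint cytoplasm pixels at
the per-neuron target means (optionally with relative Gaussian noise), and
mark nucleus/neuromelanin pixels above the exclusion threshold on the
marker channels.

What the generator deliberately does **not** emulate: mass-cytometry
physics (isotope spillover, detector dead time), spatial neighbourhood
structure, heteroplasmy gradients, irregular real cell morphology, or
positively skewed z distributions seen in tissue. A green test therefore
establishes that the pipeline's machinery is correct under its own model
assumptions — not that those assumptions hold in tissue.

## Numerical choices and test-design notes

* ln of non-positive intensities is refused; affected neurons are dropped
  with logged reasons at every stage.
* Degenerate fits (zero residual SD, constant covariate, singular
  covariance) raise typed errors rather than producing zero-width
  intervals.
* The TIFF layer is a minimal uncompressed multi-page float32 codec (no
  TIFF library ships with this R installation); bytes are verified against
  an independent Python reader in the test suite.
* Two statistically subtle test calibrations are worth recording. First,
  the prediction-interval coverage band [0.08, 0.12] is a property of the
  PI *procedure*; the realized flag fraction conditional on one control fit
  fluctuates with the fit's own estimation error (SD ≈ 0.011 at 450 control
  neurons), so the coverage test fits on 5000 simulated controls to isolate
  the property being claimed. Second, recovery of a unit group shift is
  tested on moment-standardized samples, because the raw data draw alone
  would contribute SD 0.1 to the group difference and dominate the ±0.15
  recovery band; standardization realizes the stated populations exactly.
* All pipeline stages are deterministic given the config seed; re-running
  reproduces every CSV byte-identically.

## Known limitations

* The per-complex call inherits everything from one representative subunit;
  discordant subunit pairs (which the source itself flags for complex V)
  are visible only at subunit level.
* The exact z-score definition of the original web tool is unverifiable;
  the perpendicular reading is a documented decision with a vertical-mode
  switch.
* The exclusion threshold is treated as raw counts; if a dataset's
  intensities are rescaled, the threshold must be rescaled with them.
* Published headline percentages that depend on the deposited tissue
  dataset are outside what a synthetic cohort can or should reproduce; the
  package reproduces the published cohort count summaries exactly and all
  procedure-level properties, nothing more.
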