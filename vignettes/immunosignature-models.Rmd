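---
title: "Latent-factor models of immunosignature peptide arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-factor models of immunosignature peptide arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunosig)
```

## The measurement problem

An immunosignature array presents thousands of random-sequence peptides
(mimotopes) to the circulating antibody repertoire of a serum sample.
Each spot's fluorescence is a 16-bit scanner intensity (RFU, 0-65,500)
reflecting how much antibody bound that peptide. Two features make these
arrays statistically unusual compared to nucleic-acid microarrays: a
single antibody binds many peptides, and several antibodies can bind the
same peptide. Binding is therefore *indirect* evidence about unobserved
antibodies — exactly the situation latent-variable models were built
for. The working hypothesis throughout this package is that a latent
factor extracted from correlated peptides corresponds to an antibody (or
a tightly co-varying antibody set) whose abundance differs across
disease states.

`immunosig` implements the full analysis chain around that hypothesis:

1. intensity import (delimited tables or a minimal GenePix `.gpr`
   dialect) into a `PeptideArrayExperiment`, a
   `SummarizedExperiment` subclass;
2. per-slide median normalization and `log10` transformation;
3. per-peptide Welch-Satterthwaite screening with Bonferroni control;
4. exploratory factor analysis (principal axis factoring) with
   Varimax/Promax/Geomin rotation, in either orientation: samples as
   variables (to classify sera) or peptides as variables (to infer
   antibody structure);
5. confirmatory factor models fitted by maximum likelihood with
   chi-square, RMSEA, and SRMR fit indices;
6. structural models regressing disease status on the latent factors
   (odds ratios), either two-stage via Bartlett scores or jointly by
   Gauss-Hermite quadrature;
7. exploratory factor mixture models with BIC class enumeration;
8. a synthetic-data generator and an orchestrated `discoverAntibodies()`
   pipeline tying the steps together.

## Preprocessing model

Raw arrays differ in overall brightness, so each slide is rescaled so
its median equals the grand median of slide medians, then `log10`
transformed. Analysis on the log scale treats antibody effects as
multiplicative on RFU, which matches the 3+ logs of dynamic range of
the assay. No background subtraction is performed: empty spots on these
arrays show low (roughly 150-300 RFU) and spatially consistent
background, and subtracting it degrades reproducibility. Zeros cannot
be log-transformed; entries equal to 0 are replaced by `zeroOffset`
(default 1 RFU) before scaling. Exact zeros are essentially absent at
realistic background levels, so this guard is inert on real-scale data;
setting `zeroOffset = 0` turns it into an error instead. Group
descriptive statistics (`describeGroups()`) are computed on the *raw*
RFU scale, pooling every spot of every sample in a group, because floor
suppression and ceiling utilization — the biologically interesting
dispersion differences between disease groups — are only visible there.

## Exploratory factoring

The common-factor decomposition of a correlation matrix is
\(R = A R_f A' + D^2\), with pattern loadings \(A\), factor correlation
\(R_f\), and a diagonal uniqueness matrix \(D^2\); setting
\(D^2 = 0\) recovers PCA, which `pafFit(..., method = "pca")` exposes
for comparison. Estimation is ordinary least squares: principal axis
factoring with squared multiple correlations as starting communalities,
iterated until the largest communality change falls below `tol`
(default `1e-6`, up to 200 iterations). Communality estimates that
exceed 1 (Heywood cases) are clipped to `1 - 1e-6` and flagged rather
than aborting, since they are a diagnostic in their own right — the
package's own two-factor analyses of one-factor peptide sets produce
them, as expected.

Three rotations are provided, all leaving the communalities and the
reconstruction \(A R_f A'\) unchanged:

* **Varimax** (orthogonal): gradient-projection maximization of the
  variance of squared loadings, with Kaiser row normalization.
* **Promax** (oblique): the varimax pattern raised element-wise to the
  power `kappa` (default 4, the classic choice) forms a
  simple-structure target; an oblique least-squares Procrustes step
  rotates to it and yields the factor correlation.
* **Geomin** (oblique): gradient-projection minimization of the geomin
  criterion with smoothing `geominEpsilon = 0.01`, using 30 random
  orthogonal starts (seeded, best criterion kept) because the geomin
  surface has local minima.

Each factor's sign is normalized so its largest-magnitude loading is
positive, making output deterministic.

**Orientation matters.** To classify sera, the *samples* are the
variables and the peptides the observations (the Q-technique
orientation). Ordinary Pearson correlation is used deliberately: all
samples share the array's baseline binding profile and therefore
correlate positively, and under an *oblique* rotation that shared
component is absorbed into the factor correlation, leaving
group-specific structure in the pattern loadings. This is why Promax
(or Geomin) rather than an orthogonal rotation is the right default for
classification. A `center = "double"` option removes the per-peptide
mean profile first, but with only two groups the centering constraint
forces the two groups' mean deviation profiles to be antiparallel,
collapsing the group contrast into one bipolar factor and defeating
largest-|loading| assignment — the option exists for exploration, not
for the default pipeline.

A sample is assigned to the factor with its largest absolute pattern
loading when that loading reaches the threshold (default 0.3, the
conventional salience cutoff); below-threshold samples stay
unclassified and count as incorrect. Factors are mapped to disease
groups by the permutation maximizing agreement with the known labels
(exhaustive, since group counts here are small), and samples exceeding
the threshold on several factors are reported as cross-loading — they
are never removed, since cross-loading sera may be biologically
transitional cases.

The scree-based factor-count suggestion is a stated convention: the
largest *relative* eigenvalue drop among eigenvalues of at least 1.
Published analyses of this assay type rely on visual scree inspection,
which a pipeline cannot do; the rule is advisory and always
user-overridable (`nFactors`).

## Confirmatory models and fit indices

The measurement model is \(x = \Lambda \xi + \Delta\) with a free/fixed
loading pattern, one residual variance per indicator, and a free/fixed
factor covariance matrix; identification requires a marker loading
fixed at 1 or a fixed factor variance per factor. Estimation minimizes
the normal-theory discrepancy

\[ F_{ML} = \ln|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1})
   - \ln|S| - v \]

by BFGS from moment-based starting values, with variances parameterized
on the log scale (convergence tolerance `1e-8`, at most 500
iterations); \(\chi^2 = (n-1)F_{ML}\). RMSEA is
\(\sqrt{\max(0, (\chi^2/df - 1)/(n-1))}\) — clamped at zero, as the
non-centrality can be negative in samples — and SRMR is the root mean
square of the residuals \((S - \Sigma)\) standardized by
\(\sqrt{S_{ii}S_{jj}}\), diagonal included. For just-identified models
(df = 0) the p-value and RMSEA are reported as `NA` and SRMR is still
computed. Point estimates are plain ML; `robust = TRUE` adds
Huber-White sandwich standard errors from casewise score contributions
(a scaled chi-square is deliberately out of scope, so fit indices
always use the plain ML statistic).

Two modelling choices deserve explanation:

* **Structural direction.** The scientific claim is about risk:
  carrying the latent antibody changes the odds of disease. The
  structural part therefore models `disease ~ factor` by logistic (or
  multinomial, with a declared reference group) regression, which is
  the only direction that yields odds ratios. Odds ratios are reported
  per unit of the factor on its scaling metric, with a per-SD column
  alongside since the scaling metric is arbitrary. The default
  `two_stage` route regresses on Bartlett factor scores — unbiased
  given the measurement model, though regression on estimated scores
  attenuates coefficients when measurement reliability is low, which is
  why the joint `quadrature_ml` route (15-node Gauss-Hermite, single
  factor, binary outcome) exists as a cross-check.
* **Second-order models.** With exactly two first-order factors, a
  second-order factor with free disturbances is covariance-equivalent
  to simply letting the factors correlate — it cannot be tested. The
  testable question is whether one common construct *fully* accounts
  for both factors, so with two first-order factors
  `secondOrderFit()` fixes the disturbances at zero; a large RMSEA
  then rejects the common-construct hypothesis. With three or more
  first-order factors the standard free-disturbance hierarchy is used.

`cfaClassify()` turns CFA into a diagnostic screen: reference samples
of known status are the indicators of group factors (one randomly
chosen, seed-controlled reference per factor fixed at 1), and a
held-out sample gets free loadings on every factor; it is assigned to
the factor with the largest absolute standardized loading above the
threshold.

## Factor mixture models

The exploratory factor mixture model assumes a categorical latent class
\(C\) with class-specific intercepts \(V_k\) and a within-class factor
structure, estimated by EM. The default constraint is the minimal model
in which the class-indexed parameter is the intercept vector: loadings
and residual variances are shared across classes (class-specific
covariances via `classSpecific = TRUE`), and the factor covariance is
fixed at the identity for identification, with a Geomin-rotated copy of
the loadings reported for interpretation (Promax fallback). `m = 0`
degenerates to a diagonal Gaussian mixture, which is the hook the test
suite uses to cross-check the EM against an independent implementation.
Estimation uses `nStarts` (default 20) perturbed initializations around
a K-means partition, with start seeds derived from the user seed; every
start's final log-likelihood is retained so local solutions can be
inspected, the EM trace is asserted non-decreasing at every iteration,
and classes are relabeled by descending weight for deterministic
output. Model choice across class counts uses
\(BIC = -2LL + p\ln n\) (natural log), and the average latent class
probability matrix — mean posterior of each class among observations
modally assigned to it — summarizes how crisp the classification is.

## The synthetic generator

Because no raw immunosignature dataset of this design is publicly
deposited, every estimator is exercised against a generator that
embodies the latent-antibody model: log10 intensity of sample *i* on
peptide *p* is

\[ y_{ip} = b_p + \sum_f \lambda_{pf}\,\eta_{fi} + \varepsilon_{ip}, \]

with per-peptide baselines \(b_p \sim N(2.45, 0.35)\) (typical
brightness near 280 RFU with several logs of spread), factor scores
\(\eta_{fi} \sim N(\delta_{f,g(i)}, 1)\) shifted by the sample's
disease group, and noise \(\varepsilon \sim N(0, 0.1)\). Values are
back-transformed to RFU and clipped to the 65,500 ceiling; empty spots
are uniform background on 150-300 RFU. The default design mirrors the
reference study: groups of 52/98/21 (normal, single tumor, second
tumor), 10,375 peptides with 1,172 empty spots, and one antibody
factor per group with 50 loading peptides, loadings uniform on
[0.3, 0.7] log10 units and a +3 SD score shift — a strong-separation
regime in which exploratory classification is expected to exceed 95%,
matching the regime the published classification rates imply.
Competitive binding is represented only through its variance footprint
(extra noise), not as explicit ligand competition: the estimators under
test only ever see second moments. `tableOneLikeConfig()` is a variant
with per-group noise scaling (and milder antibody effects, so maxima
stay below scanner saturation) that reproduces the qualitative
dispersion ordering second tumor > single tumor > normal.

What passing tests on these data do **not** show: robustness to
spatial artifacts, batch effects, heavy-tailed or skewed binding
distributions, peptide-sequence-dependent affinity structure, or
overlapping antibody peptide sets — none of which the generator
emulates. Results on synthetic data certify the estimators, not the
assay.

## The discovery pipeline

`discoverAntibodies()` chains the steps into the multi-step
antibody-discovery procedure: normalize; transposed EFA with rotation
as a group-separability sanity check; Welch screen with Bonferroni
control (the pipeline stops, explicitly and without error, when
nothing is significant, or when fewer than three peptides are — too
few to support any factor); EFA of the significant peptides with the
eigenvalue-drop suggestion; a CFA measurement model over the
per-factor peptide blocks; the structural model with odds ratios; and
direction annotation (increased/decreased in disease) from group
means. Two pragmatic rules come from the high-dimensional regime:
indicator sets are capped (default 8 peptides per factor, the most
significant by |t|) when peptides outnumber samples, and when two
factors' score correlation exceeds 0.9 the report flags
multicollinearity and additionally fits per-factor structural models,
since a joint regression splits shared variance arbitrarily. Reports
(`writeReport()`) are plain text/TSV/JSON with deterministic ordering;
identical inputs and seed give byte-identical files.

## Numerical choices and problem sizes

Tolerances: PAF communality iteration `1e-6`; rotation gradient
projection `1e-8`; CFA discrepancy `1e-8`; mixture EM relative
log-likelihood `1e-8`. Ties in the peptide screen are broken by |t|
descending then peptide id, so ranked output is reproducible. All
stochastic steps take explicit seeds, and RNG state is restored after
seeded internals so library calls do not disturb a user's stream.

The test and acceptance suites run the estimators at reduced but
representative sizes — hundreds to low thousands of observations,
6-16 indicators, 400-10,375 peptides, tens of replicates — chosen so
each property is measured with adequate Monte Carlo precision while the
whole suite stays comfortably within a routine CI run; the full-size
default design (171 samples x 10,375 peptides) is exercised directly
where it matters (generation, screening, transposed EFA).

## Known limitations

* ML fit statistics assume multivariate normality; group-structured
  synthetic data are normal mixtures, so measurement-model chi-squares
  on pooled groups run high even when the loading structure is correct
  (real sera data behave the same way). RMSEA/SRMR are reported
  alongside for that reason.
* The joint quadrature route covers one factor and a binary outcome;
  multi-factor or multinomial structural models use the two-stage
  route.
* Bonferroni control is deliberately conservative; no FDR alternative
  is offered because familywise control is the convention this
  analysis framework commits to.
* `cfaClassify()` refits one model per held-out sample, which is
  O(samples) CFA fits; it is intended for reference panels of tens of
  samples, not hundreds.

## A worked example

```{r example, eval = FALSE}
cfg <- syntheticConfig(seed = 11)
sim <- simulateImmunosignature(cfg)
x <- medianNormalizeLog10(sim$experiment)

describeGroups(sim$experiment)

res <- testAllPeptides(x, "normal", "single_tumor")
head(res)

rep <- discoverAntibodies(sim$experiment, c("normal", "single_tumor"),
                          seed = 11)
rep
writeReport(rep, "discovery_report")
```
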