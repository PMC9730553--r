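---
title: "Measurement methodology behind the fdd11 package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement methodology behind the fdd11 package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdd11)
```

## The measurement model

The FDD11 asks eleven ordinal questions about difficulties in everyday
functioning. The package treats the instrument under the Partial Credit
Model (PCM), the Rasch-family model for ordered polytomous responses: item
$i$ with categories $0,\dots,m_i$ has thresholds
$\tau_{i1},\dots,\tau_{im_i}$ on the latent logit continuum, and

$$P(X_{ni}=k \mid \theta_n) \;=\;
  \frac{\exp\sum_{j\le k}(\theta_n-\tau_{ij})}{\sum_{l=0}^{m_i}
  \exp\sum_{j\le l}(\theta_n-\tau_{ij})},$$

with the empty sum equal to zero. Each threshold is the point where two
adjacent categories are equally likely; the item location $\delta_i$ is the
mean of its thresholds. The Rasch structure buys two things that matter for
a disaggregation instrument: the recoded sum score is *sufficient* for
$\theta$, so scoring can be published as a fixed score-to-measure table, and
item calibration can proceed by *conditional* maximum likelihood (CML)
without any assumption about the population's ability distribution.

Modelling disability as a single hierarchical construct is an assumption,
not a fact about health: a person can have a severe hearing problem and no
mobility problem. The model is defensible because functioning problems
co-occur strongly in general populations, and the package ships the
machinery to interrogate the assumption on any dataset (residual
correlations, bi-factor comparison, fit statistics) rather than presuming
it.

## Conditional calibration (`pcm_fit`)

The conditional likelihood of a response vector given its sum score factors
through the polytomous elementary symmetric functions
$\gamma_r(\boldsymbol\beta)$, where $\beta_{ik}=\sum_{j\le k}\tau_{ij}$.
These are computed by the summation recursion — sequential polynomial
convolution over items — entirely in log space, which is stable for any
threshold magnitudes that arise in practice. Persons with extreme scores
(0 or the maximum) carry no conditional information and are dropped
internally; persons with missing responses contribute through the
conditional likelihood of their answered item subset (each distinct
answered-pattern group gets its own ESF).

CML identifies thresholds only up to an additive constant: the package fixes
the mean of all thresholds to zero and reports the subtracted constant as
`$shift`. Published calibrations are generally *not* mean-zero (the
convention of the original software is unknowable from the printed tables),
so recovery comparisons in the test-suite always center both sets first.
Scoring is unaffected by the constraint because it consumes thresholds
as printed.

Optimization is BFGS on the negative conditional log-likelihood with the
analytic gradient (observed minus conditionally expected category counts),
followed by Newton polishing with the numerically differentiated Hessian
until the mean absolute gradient per retained person falls below `gtol`
(default $10^{-8}$), capped at `max_iter = 200` iterations. Threshold
standard errors come from the Moore–Penrose inverse of the observed
information, projected through the centering constraint. Categories never
observed in the data make the conditional likelihood unbounded, so they are
collapsed onto their lower neighbour first — with a warning by default,
or an error under `collapse = "error"`.

## Person estimation and the published score table

For an interior sum score $s$ the ML ability solves
$E(\text{score}\mid\theta)=s$; the package brackets the root on
$[-10, 10]$ logits and iterates Newton steps (the derivative of the expected
score is the test information) with bisection fallback, to a tolerance of
$10^{-8}$ in the expected score. The standard error is
$I(\hat\theta)^{-1/2}$.

No ML estimate exists at the extreme scores. When a calibration artifact
supplies anchors the extremes take those published values (−3.71 and 4.18
for the FDD11, whose own extrapolation method is not stated and is therefore
treated as a constant of the published scale); without anchors the package
extrapolates by solving at fractional scores `extreme_adjust` and
`max − extreme_adjust` (default 0.3), always flagging the result. Persons
with missing responses are scored by ML over their answered items only; the
published lookup table applies only to complete recoded patterns. This
available-item choice is the package's own documented convention — how the
original analysis scored partially missing respondents is not stated.

Computing the table from the published thresholds reproduces the published
conversion closely: abilities agree within ±0.005 logits, standard errors
within ±0.001, transformed scores within ±0.02 points (the residual slack
comes from the inputs being printed to two decimals). The third severity
cut-off (40.8) falls between the transformed scores of sum scores 8 and 9,
reproducing exactly the published sum-score ranges No {0}, Mild 1–2,
Moderate 3–8, Severe 9–30.

## Recoding, the emotion testlet, missingness

The shipped recode maps collapse each item's five original response options
to the categories of the final calibration (`fdd11_recode_map()`), giving a
maximum recoded sum of 30. The two emotion questions ("sad, low or
depressed"; "worried, nervous or anxious") are locally dependent; the
instrument combines them into a testlet by summing the two 0–4 responses
and folding the 0–8 sum back to five categories (0→0, 1–2→1, 3–4→2, 5–6→3,
7–8→4). Twelve-column input files (`Q09a`/`Q09b`) are detected by name and
routed through the testlet automatically; in eleven-column files the single
emotion item is already on the 5-point scale and the recode is the identity.
Respondents with more than two missing items are excluded and logged, per
the instrument's retention rule. Input coding 0–4 or 1–5 is accepted
(auto-detected by default); internal representation is 0-based.

## The 0–100 metric and severity cut-offs

Abilities are transformed by the affine map sending the extreme-score
anchors to 0 and 100, clamped outside. Severity cut-offs are the population
mean of the transformed score minus one SD, the mean, and the mean plus one
SD; `derive_cutoffs()` uses the sample SD (denominator $n-1$ — at the sample
sizes involved the choice is immaterial, but it is fixed and documented).
Levels use left-closed intervals: No $[0,c_1)$, Mild $[c_1,c_2)$, Moderate
$[c_2,c_3)$, Severe $[c_3,100]$. The published ranges print touching
endpoints and never show a score exactly on a cut-off; the left-closed
convention is consistent with every published table row.

## Fit diagnostics

*Standardized residuals* are $(x-E)/\sqrt{V}$ with conditional PCM moments
at the person's estimated ability; extreme-score persons are excluded
because their abilities are anchors, not estimates. *Infit* is the
information-weighted mean square $\sum(x-E)^2/\sum V$, computed over persons
within item (flagging outside $[0.7, 1.3]$) or over items within person
(misfit above 2). Infit uses ML person estimates — configurable inputs, but
that is the default and the convention documented here.

One property of this estimator deserves emphasis: because the ML ability
solves $\sum_i(x_i - E_i(\hat\theta)) = 0$ within each person, residuals
lose roughly one degree of freedom per person, and with $p$ items the
*expected* item infit under a perfectly fitting model is about $1 - 1/p$
(≈ 0.91 for eleven items), not 1. The package's calibration tests therefore
check unbiasedness (mean infit within $[0.95, 1.05]$) against the *true*
simulated abilities, and separately verify the direction of the shrinkage
under estimated abilities. Published item infits for this instrument average
≈ 0.93, consistent with that arithmetic.

*Local dependence* is flagged when the Pearson correlation of two items'
standardized residuals (pairwise-complete; the original's missing-data
handling is unstated) reaches 0.2 above the mean off-diagonal residual
correlation — the relative rule used for this instrument, which puts the
threshold near 0.11 when residual correlations average slightly negative,
as they do under the within-person constraint.

*Threshold ordering* flags items whose thresholds are not strictly
increasing. `suggest_collapse()` restores ordering iteratively: at each
round it refits, finds the worst inversion, and merges the category whose
bounding thresholds are inverted into its upper neighbour — the minimal
single-category change — until ordered or exhausted, returning cumulative
monotone recode maps and a per-iteration log. The proposal is a monotone
coarsening; it need not equal the recoding a human analyst would choose.

*Targeting* summarises person and threshold locations (mean, SD, range) and
exports person–item map data (`plot()` on a fitted model draws it). One
note on the published summary: the item row of the published targeting
table (mean 0.2863, SD 0.7788 over all thresholds) was evidently computed
from unrounded thresholds; the two-decimal printed thresholds give
0.2867 / 0.7798, so the package's tests assert agreement to ±0.005 rather
than print precision. The range (−1.48 to 1.74) reproduces exactly.

*Person separation index.* Several PSI variants circulate; the package
defines, over persons with non-extreme scores,
$$\mathrm{PSI}=\frac{\operatorname{var}(\hat\theta)-\overline{SE^2}}
 {\operatorname{var}(\hat\theta)},$$
floored at zero. This is the package's fixed definition (the original
software's variant is not stated).

### Why the normal-population PSI surrogate reads ≈ 0.70, not 0.82

The real pooled survey microdata are available only on request, so the
reliability figure of 0.82 can only be approached through a surrogate
population. The published person-location summary (mean −1.2733, SD 1.0822)
describes *estimated* abilities of retained non-extreme respondents of a
strongly skewed general population — its printed range equals the score-1
and score-29 table entries. Drawing *latent* abilities from a normal with
those parameters and scoring them under this calibration yields
$\operatorname{var}(\hat\theta)\approx 1.14$ but mean squared SE ≈ 0.35,
hence PSI ≈ 0.70: a population centred at $\hat\theta=-1.27$ sits mostly on
sum scores 1–5, where standard errors are 0.48–1.02. Reaching 0.82 under
this calibration requires either a much wider latent spread (SD ≈ 1.7) or
the heavy-tailed shape of the real data — neither of which the published
summary statistics license. The surrogate is therefore reported as computed
(≈ 0.70), and the gap is a property of the surrogate, not of the scoring
machinery, whose deterministic outputs match the published tables to print
precision.

## Differential item functioning

The DIF screen is a two-way ANOVA of each item's standardized residuals on
group and ability class interval, reporting the group main effect with
numerator df = groups − 1 (df = 10 for eleven country groups, matching the
published test shape). Class intervals default to six ability-quantile
bins; the group effect is assessed after the interval effect (sequential
sums of squares) so composition differences are absorbed first, and
intervals with empty group cells are merged with a warning. Simulations at
$N = 5000$ with eleven groups hold the null rejection rate near the nominal
5% and detect a 0.5-logit uniform shift on one item with power above 90%
(at $\alpha = 0.05$; such shifts typically reach $p < 0.001$). No DIF
*resolution* (item splitting or removal) is implemented: for this
instrument cross-country DIF was judged plausible and deliberately left
unresolved, and resolving it would manufacture a different scale per
implementation.

## Dimensionality

Polychoric correlations use the two-step estimator: thresholds from the
cumulative margins, then the latent correlation maximizing the
bivariate-normal cell likelihood, with the bivariate normal CDF evaluated
by 48-node Gauss–Legendre quadrature over the correlation parameter
(accurate to ~10⁻¹⁰, no external dependency). Non-PSD matrices are repaired
by eigenvalue clipping with a warning. Factor retention uses Horn's
parallel analysis with principal-component eigenvalues against the 95th
percentile of 100 standard-normal reference datasets of the same shape
(whether the original analysis used PCA or principal-axis eigenvalues is
unstated; PCA is this package's documented default, and reps/quantile are
configurable and logged). Counting stops at the first non-exceeding
eigenvalue, so pure noise returns 0. The bi-factor check is exploratory:
ML factor analysis with the retained number of first-order factors, promax
rotation, a single second-order factor on the factor correlations (for two
first-order factors the loading is $\sqrt{\phi_{12}}$ by convention, zero
if $\phi_{12}\le 0$), and Schmid–Leiman orthogonalization. The scale is
declared unidimensional when every item's general loading exceeds its
largest specific loading in absolute value. Heywood-boundary items are
reported, never silently clipped. Confirmatory bi-factor models are out of
scope.

## The synthetic-data generator

`fdd11_simulate()` emulates what matters for exercising the pipeline:
PCM-true responses at a known calibration (default: the shipped published
thresholds, so simulated data are on the recoded scale), a right-skewed
ability distribution, country-like groups with injectable uniform DIF
shifts, MCAR missingness, and a twelve-question mode in which the two
emotion source items share a person-level latent component. Defaults, fixed
once and documented here:

- ability model: 25% floor mass at θ = −3.5 plus a Normal(−1.0, 1.1) bulk —
  a general-population shape in which most respondents report no or little
  difficulty; the real mixture is unpublished, so this is a labelled
  synthetic default, fully configurable;
- missingness: MCAR only (no mechanism is stated for the real data);
  sparse rates (~2%) in examples;
- twelve-item mode: both source items use the testlet's thresholds (the
  original items' parameters are unpublished) and share a Normal(0, 1.8)
  person component, calibrated so their residual correlation is ≈ 0.4
  after an unrestricted 12-item fit, matching the dependence that motivated
  the testlet; weight 0 removes the dependence flag.

What the generator does *not* emulate: survey design effects, household
clustering, non-random missingness, cross-cultural response styles beyond a
uniform threshold shift, and the real ability distribution's unknown tail.
Passing tests on synthetic data therefore validate the estimation and
scoring machinery, not any claim about the real pooled survey sample.

## Problem sizes and numerical choices in the test-suite

The suite calibrates at $N$ = 500–8000 (parameter recovery within three
estimated SEs after centering, with error decreasing in $N$), runs
diagnostic simulations at $N = 5000$, DIF null/power studies at $N = 5000$
across 20 and 10 seeded replicates, dimensionality replicates at
$N = 5000$, and the PSI surrogate at $N = 10{,}000$ — sizes at which
Monte-Carlo error is small relative to every asserted tolerance while the
whole suite runs in about two minutes. The dichotomous CML path is verified
against a brute-force conditional likelihood that enumerates all response
patterns — an oracle sharing no code with the package's ESF recursion.
Recovery assertions over 30 simultaneous thresholds use family-wise bounds
(all within 4 SEs, ≥ 90% within 3) in the unit tests.

## Known limitations

- CML scales comfortably to the instrument sizes it targets (tens of items,
  tens of thousands of persons); it is not engineered for hundred-item
  banks.
- Marginal maximum likelihood, discrimination parameters (2PL/GPCM) and
  Bayesian estimation are out of scope; the generalized-PCM direction
  appears only as a misfit generator in the tests.
- The extreme-score anchors of the published scale are treated as
  constants; re-deriving them would require the original software's
  unstated extrapolation.
- Outfit statistics, bootstrap fit distributions and the Andersen LR test
  are intentionally absent.
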