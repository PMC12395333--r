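---
title: "Methods: cost-based PNEC_res estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-based PNEC_res estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnecres)
```

## The selection model

A bacteriostatic dose–response curve links the growth rate of a strain to
the antibiotic concentration $c$:

$$\mu(c) = \mu^0 \max\left(0,\; 1 - (c/\mathrm{MIC})^\kappa\right)$$

with intrinsic rate $\mu^0$ (h$^{-1}$), minimum inhibitory concentration
MIC (mg/l) and curvature exponent $\kappa$ ($\kappa = 1$: the linear
consensus model used by default). Rates are clipped at zero above the MIC:
environmental concentrations rarely exceed the MIC of susceptible strains,
so bactericidal kill kinetics are deliberately out of scope, and clipping
keeps $\mu$ continuous and non-negative.

For an isogenic pair, the resistant variant pays a fitness cost
($\mu^0_{res} = \mu^0_{sus}(1-\mathrm{cost})$) and gains a resistance level
$f = \mathrm{MIC}_{res}/\mathrm{MIC}_{sus}$. The minimum selective
concentration (MSC) is where the two growth curves intersect. Under linear
curves this has the closed form implemented in `msc_normalized()`:

$$\frac{\mathrm{MSC}}{\mathrm{MIC}_{sus}} =
  \frac{\mathrm{cost}}{1 - (1-\mathrm{cost})/f}$$

For $f > 10$ and costs up to 10% the normalized MSC exceeds the cost by at
most a factor $1/(1 - 1/f) \le 1.12$, which justifies the working
approximation $\mathrm{MSC} \approx \mathrm{MIC}_{sus} \times \mathrm{cost}$
(`msc_approx()`). `msc_numeric()` solves the growth-rate equality by plain
bisection to a relative bracket width of $10^{-12}$; it is the independent
route used to validate the closed form and the only route for
$\kappa \neq 1$. Since the exact shape of nonlinear curves is
antibiotic-specific and rarely known, the package exposes a single-exponent
power-law family and reports the induced shift of the MSC as a ratio
(`bias_under_shape()`); convex curves ($\kappa > 1$) push the MSC up
relative to the linear formula, concave ones push it down, so no universal
correction factor exists.

A non-positive cost is a typed condition (`pnecres_unselectable`), not a
number: when carrying the determinant is free or beneficial, no
concentration threshold can prevent selection, and downstream code should
see that outcome explicitly rather than a `NaN`.

## Competition-assay analysis

Intrinsic rates are estimated as the maximum slope of natural-log OD600
against time over sliding windows of 5 points (`window`), ignoring readings
at or below a detection floor of 0.005 OD units (`floor`); a window
$R^2 < 0.98$ triggers a warning, not an error, because a mediocre window can
still carry the true maximum. Both knobs exist because plate readers differ
in noise floor and sampling interval.

The fitness ratio of one competition cycle is defined as the ratio of
realized Malthusian parameters,
$fr = \ln(a_{res}^T/a_{res}^0) / \ln(a_{sus}^T/a_{sus}^0)$. This choice
(over the simple fold-change ratio, which remains available via
`method = "fold"`) is deliberate: under exponential growth it reduces to
$\mu_{res}/\mu_{sus}$, so $fr = 1$ coincides exactly with the growth-rate
equality that defines the MSC. Replicates are aggregated by geometric mean
(a ratio-scale quantity; arithmetic mean selectable), the $fr(c)$ knots are
interpolated by a monotone cubic Hermite spline with Fritsch–Carlson
tangents (`stats::splinefun(method = "monoH.FC")`, which cannot overshoot
the knot range), and the MSC is the bisection root of $fr = 1$ between the
bracketing knots — unique because the spline is monotone between knots. The
antibiotic-free control enters as the $c = 0$ knot on the linear
concentration axis. When no knot pair brackets 1, the result is a censored
status rather than an error — `above-highest-tested` when the curve heads
toward 1 with increasing concentration, `below-lowest-tested` otherwise —
so that a screening grid (factor-5 spacing around the approximate MSC) can
be refined around the first estimate. The accuracy checks in the test suite
use exactly this two-pass design: a factor-5 screen followed by a factor-2
grid around the first root, which brings interpolation error below 2% even
for low-level resistance ($f = 10$), where a single coarse grid can miss by
more.

Agreement between computed and empirical MSCs is summarized on the decadic
log scale (`validation_stats()`): mean error, mean absolute error, and the
fraction of pairs within a factor $k$ (boundary inclusive), the natural
resolution given that MIC testing itself works on a two-fold scale.

## Lowest MICs from distribution tables

For each species the robust minimum is the lowest dilution bin holding at
least `max(2, 1%)` of that species' observations — singleton observations at
extreme bins are commonly transcription or assay artefacts. The rule is a
package choice and is pluggable (`rule` argument) so alternative published
rules can be registered. The minimum over species is the preliminary
MIC$_{lowest}$; species with no qualifying bin are skipped with a warning
and logged.

Testing fewer species biases the preliminary value upward. The correction
subtracts whole two-fold dilution steps (results must stay on the test
scale):
$\mathrm{steps}(n) = \lfloor s_{max} e^{-n/n_{scale}} + 0.5 \rfloor$,
calibrated so the continuous value is exactly 1.0 at $n = 29$ and 0.49 at
$n = 40$ — one step of correction for around 30 tested species, none from 40
upward, decaying smoothly for sparser coverage (about 6 steps for a single
species). The half-up rounding keeps the step count monotone in $n$. The
older discontinuous rule (scale by $n/40$ for $n < 40$, then snap down to
the two-fold grid) is available as `model = "linear"`; both models agree on
the two calibration anchors.

## The cost mixture model

Empirical resistance costs are modelled as
$w\,\mathrm{Exp}(\lambda) + (1-w)\,\mathcal{N}(0, \sigma)$: the exponential
component carries the true, strictly positive cost of resistance; the
zero-centred Gaussian absorbs measurement noise and fitness changes that
coincide with, but are not caused by, the resistance determinant (about 10%
of literature costs are negative). The Gaussian mean is fixed at zero by
construction — a free mean would let the noise component absorb genuine
cost signal. Records with $|\mathrm{cost}|$ strictly above 0.25 are treated
as outliers by default (a record exactly at the bound is kept), and the
default regulatory fit uses plasmid-borne records only, reflecting the
greater mobility and slightly lower cost of plasmid-encoded resistance; both
filters are explicit configuration.

The three parameters are fitted by direct numerical maximum likelihood on
an unconstrained scale (logit $w$, $\log\lambda$, $\log\sigma$) with BFGS
from five deterministic data-derived starting points; the best of the
converged starts wins and per-start diagnostics are retained. Direct
optimization was preferred over EM for a three-parameter problem (an EM
implementation serves as an independent cross-check in the tests). The
fitted weight is clamped to $(10^{-12}, 1-10^{-12})$ because the logistic
transform saturates in double precision. Samples under 30 records or with
no positive costs are rejected up front.

Regulatory quantiles come from the exponential component alone:
$Q_p = -\ln(1-p)/\lambda$, with $p$ the tolerated fraction of determinants
cheaper than $Q_p$. Quantile ratios are parameter-free
($Q_{.50}/Q_{.05} = \ln 0.5/\ln 0.95 \approx 13.5$), which makes the
tabulated probability grid internally consistent by construction.
Uncertainty is quantified two ways: ordinary bootstrap over records
(percentile interval, default $B = 1000$; replicate fits warm-started at
the full-data optimum, with failure of more than 20% of replicates an
error), and a profile-likelihood interval for $\lambda$ (re-optimizing $w$
and $\sigma$, cut at $\chi^2_1(0.95)/2 = 1.9207$ below the maximum,
one-sided results flagged). Costs are handled as fractions throughout and
multiplied by 100 only at the reporting layer; the bootstrap resamples
records rather than studies, the simpler assumption given that study
identity is metadata only. Plasmid and chromosomal groups are compared with
a two-sided Wilcoxon rank-sum test (`stats::wilcox.test`).

## From MIC and cost to PNEC_res

$\mathrm{PNEC}_{res} = \mathrm{MIC}_{lowest} \times Q_p(\mathrm{cost})$,
with the quantile's confidence interval propagated by interval arithmetic.
Reported values follow two conventions that coexist in practice: legacy
fixed-factor results are rounded to one significant figure, cost-based
results to two (so a value like 0.032 survives reporting); rounding is half
away from zero, and both figures counts are overridable, with a two-fold
snap mode as alternative. The reciprocal of the quantile is also reported
as a conversion factor (rounded to the nearest 10 when large) because
thresholds are commonly communicated as "MIC$_{lowest}$/250". At
$p = 0.05$ the default mixture implies a factor near 250 — 25-fold below
the conventional assessment factor of 10.

The pipeline (`run_pipeline()`) chains these stages per antibiotic, skips
antibiotics that fail with a logged reason, and serializes the full
configuration into the output for provenance. All randomness (bootstrap
resampling) flows from the single configured seed.

## Synthetic data and what the tests show

The generators encode the study conditions: costs from the mixture with
$w = 0.7$, $\sigma = 0.05$ and the exponential median at 5.4% cost (placing
roughly 10% of records below zero, sample sizes near the curated
collection's ~130 plasmid records); competition assays as 24-hour
exponential-growth cycles at factor-5 concentration grids around the
approximate MSC with six replicates and lognormal counting noise (sd 0.1 on
the log scale, multiplicative errors being the natural model for plate
counts); MIC tables as multinomial allocations of ~200 isolates per species
around species-specific modal bins, with the designed floor anchored by one
maximally sensitive species. Every generator returns (and can write) its
ground truth alongside the data, and all downstream checks consume truth
through that channel.

What passing tests demonstrate is therefore internal consistency: the
estimators recover known truth under the generating assumptions
(exponential growth, lognormal noise, mixture-distributed costs).
Real-world features the generators do not emulate include density-dependent
and community-context fitness effects, plasmid loss and conjugative
transfer during competition, correlated measurement error across a plate,
taxonomic bias in which species get tested, and cost amelioration over
evolutionary time. Conclusions about real data rest on the framework's own
empirical validation, not on these simulations.

Problem sizes in the test suite were chosen to make the stochastic checks
sharp but cheap: 1000 random draws for the closed-form/bisection
equivalence, 5000 records for parameter recovery (±10%), 100 repetitions of
$n = 200$ records at $B = 200$ for bootstrap coverage, and 100 seeds for
the noisy-MSC recovery study.

## Known limitations

* The power-law shape family is a stand-in for antibiotic-specific
  dose–response forms; `bias_under_shape()` quantifies the sensitivity but
  cannot replace per-class curve fitting.
* The exponential+Gaussian decomposition is identifiable only with enough
  records on both sides of zero; small or all-positive samples push the
  weight to a boundary, which is surfaced in the fit diagnostics rather
  than hidden.
* MIC$_{lowest}$ inherits the taxonomic coverage of the source database;
  the coverage correction compensates on average, not per antibiotic.
* The choice of the probability threshold $p$ is a risk-management
  decision outside the package; defaults expose it, they do not justify it.
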