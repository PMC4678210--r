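---
title: "Segmenting phenological and temperature series: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting phenological and temperature series: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phenoseg analyses short annual series — flowering dates of fruit trees
recorded as day-of-year, and mean temperatures over the chill-accumulation
(CA) and heat-accumulation (HA) periods that govern dormancy release — for
abrupt changes and linear trends. This vignette is the package's own account
of the statistics it implements, the parameters that matter, and the design
decisions taken where more than one reasonable choice existed.

## The model

A series $x_1, \dots, x_T$ (typically 25–56 annual values) is modelled as a
homoscedastic Gaussian multiple change-point process: there exist
$J - 1$ instants $\tau_1 < \dots < \tau_{J-1}$ (with $\tau_0 = 0$,
$\tau_J = T$) such that for $\tau_j \le t < \tau_{j+1}$

$$E(X_t) = \alpha_j + \beta_j t, \qquad \mathrm{Var}(X_t) = \sigma^2,$$

with $\beta_j \equiv 0$ for the *constant* family and free slopes for the
*linear* family. The variance is pooled across segments. On series this
short, heteroscedastic variants tend to manufacture artefactual short
segments out of local variance fluctuations, and a common variance is also
what makes likelihoods comparable across segmentations, which the posterior
computations below require. The regression function is deliberately *not*
constrained to be continuous at change points — this is not broken-line
(segmented) regression; an abrupt level shift is exactly what a regime change
in flowering behaviour looks like.

Within-segment fits are ordinary least squares with missing years skipped and
counts adjusted; missing annual observations are never interpolated (daily
temperature records are the only place interpolation is allowed, see below).
The pooled variance uses the maximum-likelihood divisor $n$ (not $n - p$):
the likelihoods of models with different $J$ must be computed on the same
footing for the mBIC and the posterior weights to be meaningful. The
log-likelihood of a segmentation $s$ has the closed form
$-\tfrac{n}{2}(\log 2\pi\hat\sigma^2 + 1)$ with
$\hat\sigma^2 = \mathrm{RSS}(s)/n$.

The optimal segmentation for each $J$ is computed by dynamic programming over
a precomputed segment-cost matrix (prefix sums give each segment's RSS in
constant time), so the exact RSS optimum is found, with ties broken toward the
earliest change point for determinism. A zero-RSS fit (e.g. a noiseless
constant series) has unbounded Gaussian likelihood; it is signalled as a
condition of class `phenoseg_degenerate` rather than propagated as infinity.

## Choosing the number of segments: mBIC

The number of segments is selected by a modified Bayesian information
criterion for Gaussian homoscedastic change-point models, kept on the
$2\log$ scale:

$$\mathrm{mBIC}(J) = 2\log L_J(s^*, x;\hat\theta)
  - \Big[\, d \sum_{j=1}^{J} \log n_j \;+\; \log n \;+\; 2(J-1)\log n \,\Big],$$

where $d$ is the number of within-segment mean parameters (1 constant,
2 linear), $n_j$ the non-missing count of segment $j$. Each segment's mean
parameters are informed only by their own segment, hence the per-segment
$\log n_j$ terms; the pooled variance contributes one $\log n$; each change
point's discrete location contributes $2\log n$ — the feature that
distinguishes this criterion from a naive BIC, which under-penalises the
locations and over-segments. The penalty lives in one function
(`mbic_penalty()`) so alternates can be swapped.

Two models are compared by Jeffreys' rule of thumb: the higher mBIC wins
*substantially* only when the difference reaches $2\log 100 = 9.2$
(inclusive), i.e. a Bayes factor of 100. Within a family, model posterior
probabilities under equal priors follow from the same scale,
$P(M_J \mid x) \propto \exp(\mathrm{mBIC}_J / 2)$, computed with
max-shifting; a 9.2 gap thus maps to posterior odds of 100 (0.990 / 0.010),
and three candidates at mBIC $(0, -9.21, -9.21)$ get weights
$(0.980, 0.0098, 0.0098)$.

`J_max` defaults to 3: on 25–56-year series, more segments than that are
rarely interpretable and the mBIC's indication for the number of segments
should in any case be read as indicative, not sharp.

## Segmentation uncertainty

For a fixed $J$, the weight of the optimal segmentation among all
segmentations,

$$P(s^* \mid x; J) = L_J(s^*, x;\hat\theta) \Big/ \sum_s L_J(s, x;\hat\theta),$$

quantifies how well-defined the segmentation is. With a single change point
($J = 2$) each segmentation is identified by its change point, so the same
normalisation yields the full change-point posterior distribution over the
$T-1$ candidate instants, whose mode is the optimal change point.

Because the series are short and $J \le 3$, the package enumerates the
segmentations outright (a cap, default $T \le 100$, guards the combinatorial
growth) instead of implementing the top-$N$ dynamic programming algorithm
that the enumeration would reduce to at these sizes. Each candidate
segmentation is refitted with its own parameter estimates — $\hat\theta$ in
the expressions above is the estimate *under that segmentation*, not the
optimal one's (both conventions agree in the well-separated limit, and the
refit reading matches the likelihood notation). Accumulation is in the log
domain with max-shift; the distribution normalises to 1 within $10^{-10}$.
Degenerate zero-RSS candidates are excluded with a warning and the weights
renormalised.

A practical reading used throughout: a change point is trustworthy when its
amplitude clearly exceeds the global standard deviation and the posterior
mass concentrates near the mode; a posterior spread across many instants
(mode probability of order $1/(T-1)$) means the data do not pin the instant
down.

## Constant vs linear, and the residual procedure

On many flowering series the 2-segment constant model and the plain linear
trend ($J = 1$, linear) are statistically indiscernible — an abrupt advance
of amplitude comparable to the noise looks like a downward trend. The
package's working rule, after the cross-family Jeffreys comparison:

* the **constant family is primary**: the retained model is the
  constant-family mBIC selection, and the linear family replaces it only when
  its winner is *substantially* better (difference $\ge 9.2$);
* on a stalemate between 2-segment-constant and 1-segment-linear, the
  **residual procedure** adjudicates: fit the global line, extract the
  residual series, and select the best piecewise *linear* model for the
  residuals by mBIC. A residual change point between two rising within-segment
  trends is the signature of a level shift hiding inside an apparent trend
  (removing a fitted global decline from a step leaves exactly that pattern);
  a stationary residual series supports the plain trend.

A related device works in the opposite direction: when the linear family
selects a 2-segment model whose slopes are not significantly different from
zero (per-segment two-sided t-tests with the pooled variance,
`slope_significance()`), the series is effectively 2-segment constant.

## Interpretability filtering

A statistically optimal change point that isolates one or two years at the
end of a series means nothing agronomically. Any segment shorter than
`min_interpretable` (default 5 years — published analyses discarded 1–2-year
segments outright and flagged 3–6-year leading segments as unreliable) flags
the segmentation; the fallback removes the change point bounding the short
segment — a leading short segment merges into its successor, a trailing one
into its predecessor — and refits, repeating if necessary. Alongside the
mBIC-selected model, `analyze_series()` always reports the 2-segment constant
summary (change year, amplitude with the post-minus-pre sign convention so
advances are negative, global standard deviation, $P(s^*\mid x;2)$ and
$P(M_2\mid x)$) for cross-location comparability, and marks it `supported`
when $P(M_2 \mid x) \ge 1/3$ and no short-segment flag fires — the retention
rule used when reporting temperature-series steps.

## CA/HA temperature aggregation

Daily records (`date, tmin, tmax`, with `tmean = (tmin + tmax)/2`) are
aggregated into one value per phenological year: the arithmetic mean of
`tmean` over the period window. Conventions:

* a window crossing the calendar-year boundary (Northern-Hemisphere CA,
  October–January) is labelled by the year containing its **end** — the
  flowering year it feeds into — so CA values align with that year's
  flowering date in correlations;
* "mid-April" ends mean April 15 inclusive; month ends are resolved per
  calendar (leap Februaries included);
* presets: Europe CA Oct–Jan / HA Feb–Apr; Morocco CA Oct–Jan / HA
  Mar–mid-Apr (the start taken as March 1); Brazil CA Apr–Jul / HA Aug–Oct;
* short runs of missing days are filled by linear interpolation of `tmin`
  and `tmax` separately (`tmean` recomputed), capped at 10 consecutive days —
  beyond that the year is invalidated rather than fabricated — and boundary
  gaps are refused;
* a year with incomplete window coverage after interpolation becomes missing,
  with a warning, rather than a mean over a partial window.

Flowering dates are kept as day-of-year integers across leap years; all
comparisons are within-season, where the one-day offset is irrelevant.

Correlations between flowering dates and period means are Pearson by default
(the field's default estimator; Spearman is available behind an argument),
two-sided, starred `**`/`*`/`n.s.` at the 1%/5% levels with no
multiple-testing correction, matching the reporting convention of the
phenoclimatic literature.

Flowering durations (stage BBCH 65 minus stage 61 dates over common years)
are analysed with the same model selection; when no change point or trend is
found they are treated as plain frequency samples: cultivars at a location
are pooled only if a Kruskal–Wallis rank test cannot tell their distributions
apart ($p \ge 0.05$), and regimes are compared through empirical cumulative
distribution functions ordered by sample mean.

## The synthetic generators

The generators draw from the fitted model class itself — Gaussian i.i.d.
noise around piecewise constant/linear means — so that tests measure the
method's operating characteristics under its own assumptions. The daily
temperature generator builds a seasonal sinusoid, shifts each period window
by a constant so the window mean equals the prescribed annual value, and adds
daily noise; with zero daily noise the aggregation recovers the targets
exactly, and with noise the annual means pick up only
$\mathrm{sd}/\sqrt{\text{window length}} \approx 0.2\,^\circ$C.

Three frozen scenario bundles emulate contrasting regimes. Magnitudes follow
the ranges typical of published long apple series: flowering advances of
$-5$ to $-15$ days against annual noise of 5–11 days, HA warming steps near
$+1.3\,^\circ$C against 0.9–1.2 $^\circ$C noise, temperate flowering
durations of 3–4.5 days versus 9–14 days in mild climates.

* **european** (T = 40, of the typical 25–56 range): flowering mean 110 with
  a $-8$-day step at mid-series and $\sigma = 6.7$ (the median of European
  flowering-series standard deviations), an HA step $+1.3\,^\circ$C at the
  same year ($\sigma = 0.95$), a mild CA trend, and a within-segment coupling
  of flowering to HA anomalies of $-0.75$ correlation (about $-5$ days per
  degree) — heat drives flowering;
* **brazilian**: everything stationary; flowering ($\sigma = 10$) is
  positively coupled to the CA mean at correlation $0.7$ — insufficient chill
  delays flowering; long durations;
* **mediterranean**: HA steps up by $+1.31\,^\circ$C ($\sigma = 0.88$) and CA
  warms, but flowering responds only to HA *anomalies about the segment
  means* (correlation $-0.7$), i.e. the step's pull toward earlier flowering
  is compensated by the concurrent chill decline, leaving flowering
  stationary; short durations.

The noise scale of the European flowering scenario deserves a remark: at a
step-to-noise ratio of $8/6.7 \approx 1.2$, detection through mBIC selection
is genuinely borderline — the same ambiguity the residual procedure exists
for — so end-to-end discrimination rates for this scenario sit near, not
comfortably above, 80%.

What the generators do *not* emulate: autocorrelated or heavy-tailed
interannual noise, observation-protocol drift, spatial correlation between
locations, and real weather structure beyond the seasonal cycle (a Student-t
contamination switch exists for robustness probing but defaults off). Passing
tests therefore demonstrate correctness of the machinery and calibration
under the model's own assumptions, not robustness to every feature of field
data.

## Numerical and testing choices

* Tolerances: posterior normalisation $10^{-10}$; oracle equivalence checks
  $10^{-8}$ relative; OLS closed forms $10^{-10}$ relative.
* Tie-breaks: equal-RSS segmentations resolve to the earliest change point.
* Degenerate inputs (zero residual variance) raise `phenoseg_degenerate`
  conditions; pipeline reports carry a `degenerate` flag instead of numbers.
* Feasibility floors: a constant segment needs 1 non-missing point, a linear
  segment 2 with distinct times; the optimiser additionally enforces raw
  minimum segment lengths of 2 (constant) and 3 (linear) by default, while
  the posterior enumeration defaults to minimum length 1 so that all $T-1$
  single-change-point candidates are weighed.
* Problem sizes in the test-suite simulations — 500 replicates for
  change-point recovery, 200 for selection operating characteristics, 1000
  for the two type-I calibrations, 100 per scenario for end-to-end
  discrimination — were chosen to give Monte-Carlo standard errors of 1–3
  percentage points on the rates they estimate.

## Known limitations

* The mBIC penalty is one principled form of the modified-BIC family; other
  penalty variants would shift absolute mBIC values (selection behaviour, the
  quantity the tests pin down, is less sensitive). It is isolated so
  alternates can be swapped.
* Exhaustive enumeration limits posterior computations to $T \le 100$ and
  $J \le 3$; larger problems need the top-$N$ segmentation algorithm, which
  is out of scope.
* The maximum-likelihood change-point estimator's sampling distribution has
  heavy tails at moderate separation: at amplitude $2\sigma$ and $T = 40$ the
  estimate falls within $\pm 1$ year of the truth in roughly 85% of
  replicates (the tests report the exact seeded rates) — users should read
  change years together with their posterior distributions, not as exact.
* Pooling the variance across segments is an assumption, not a test result;
  inspect per-segment spreads on long segments before trusting it.
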