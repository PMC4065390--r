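---
title: "Modelling birthdate distributions to detect systemic contamination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling birthdate distributions to detect systemic contamination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Person-level databases — electronic health records, controlled-drug
registries, claims databases — routinely contain incorrect birthdates. The
errors are rarely random: missing values get replaced by software zero dates
(1899-12-30 from spreadsheet epochs, 1970-01-01 from Unix time), clerks enter
dates in the wrong geographic dialect ("02/01/2010" is January 2 in
Britain and February 1 in North America), patients round a self-reported
birthday to January 1, auto-complete widgets repeat the previous patient's
date, and other date columns (e.g. a dispensing date) occasionally leak into
the birthdate field. Every one of these mechanisms concentrates errors on
*particular calendar days*, so a contaminated database over-represents a
small set of birthdates. birthgam detects that signature.

## The count model

Let $N(d)$ be the number of individuals in the database born on day $d$.
Treating inclusion in the database as a Poisson point process with a slowly
varying intensity, the daily counts are independently Poisson,
$$N(d) \sim \mathrm{Poisson}(\lambda(d)),$$
where $\lambda(d)$ is shaped by demography (age profile of the population and
of the disease), seasonality of births, and the weekly cycle: modern
hospital births are scheduled on weekdays, so weekends (and public holidays)
show a reduction that has *grown over the decades*. This motivates the
additive structure
$$\log \lambda(d) = s_1(d) + I(d \in \text{weekend/holiday}) \cdot s_2(d),$$
with $s_1$ a smooth trend-plus-seasonality term and $s_2$ a smooth weekend
log-ratio. The log link guarantees positivity; $e^{s_2(d)}$ is the
multiplicative weekend factor at time $d$. A negative binomial variant would
tolerate over-dispersion at the cost of an extra parameter; with no practical
way to assess over-dispersion day-by-day we keep the simpler Poisson
assumption, as the flagging rule below is in any case used at extremely small
thresholds.

A date is flagged when its observed count is improbable under the fitted
intensity:
$$P(K \ge N(d) \mid \hat\lambda(d)) = \sum_{k = N(d)}^{\infty}
  \frac{\hat\lambda(d)^k e^{-\hat\lambda(d)}}{k!} < c,$$
with $c = 10^{-4}$ by default (the complement of the pointwise 99.99th
percentile). The tail is computed through the regularized incomplete gamma
function (`ppois(..., lower.tail = FALSE)`), with a log-scale variant for
ranking dates whose tail probabilities underflow. Because the criterion is
*pointwise*, it behaves correctly at the sparse ends of the birthdate range:
with $\lambda = 0.05$, a single observed birth has tail probability
$1 - e^{-0.05} \approx 0.049$ and is (rightly) not flagged, while a fill-in
spike of 30 is astronomically unlikely and is flagged. Global-threshold
detectors cannot make this distinction — that is the core advantage of the
model-based approach, and the package ships two such baselines
(`detect_sarima()`, `detect_mad()`) to demonstrate it.

## Fitting: penalized splines, IRLS, GCV

Both smooths are penalized regression splines. The default basis is a cubic
B-spline system on an equally spaced knot grid over the normalized day index
$x \in [0, 1]$, with a second-order difference penalty on the coefficients
(whose null space contains linear trends). An alternative reduced-rank
thin-plate basis (radial kernel $r^3/12$ over representative centres,
eigen-truncated, with the polynomial null space $\{1, x\}$ explicit) is
available through `gam_control(basis = "thin_plate")`; the two agree closely
in practice and the cubic basis is preferred because its design matrix is
banded, which keeps a 45,000-day fit in seconds.

Identifiability: the trend smooth carries a sum-to-zero constraint (absorbed
by dropping one basis column and centering, implemented as a rank-one
correction so the design stays sparse) and the intercept carries the overall
level. The weekend smooth is *not* constrained: it only enters the linear
predictor multiplied by the indicator, which identifies its level, and
$\hat s_2(d)$ is therefore directly interpretable as the weekend log-ratio
at time $d$. Constraining it would require a separate weekend main-effect
term foreign to the model above.

The penalized Poisson likelihood is maximized by iteratively reweighted
least squares, initialized at the working response $\log(N(d) + 0.5)$, with
step halving to enforce a monotone decrease of the penalized deviance, a
ridge fallback for singular working systems (reported by warning), and
convergence declared when the relative deviance change drops below
$10^{-8}$ (at most 200 iterations; non-convergence is reported, never
silent). Smoothing parameters minimize the generalized cross-validation
score
$$\mathrm{GCV}(\rho) = \frac{n\, D(\rho)}{(n - \mathrm{tr}\,A(\rho))^2},$$
where $D$ is the Poisson deviance and $\mathrm{tr}\,A$ the effective degrees
of freedom, searched on the $\log_{10}$ scale over $[-8, 8]$ (a coarse grid
followed by coordinate golden-section refinement, with warm-started IRLS).
The bounds are on the $\log_{10}$ scale because optimal penalties for tens
of thousands of observations routinely exceed $e^8$.

### Ranks

The trend rank defaults to $\min(\lceil 2 \cdot \text{years covered}\rceil,
200)$: two degrees of freedom per year is the minimum that leaves room for
annual seasonality, while the cap keeps century-long series tractable and
matches the upper bound used in the motivating application. For a
120-year register the cap binds, so the fitted trend resolves features of
roughly a fortnight and wider — intentional: contamination lives on single
days, far below that resolution. The weekend smooth models a secular,
gradual change, so its rank defaults to 10.

### Masking and refitting

An extreme spike drags the local fit upward and can hide smaller outliers
nearby. `detect_birthdate_outliers()` therefore refits after flagging
(`max_refit_iterations = 1` by default): flagged dates get weight zero —
rows are never deleted, so the covariate grid is preserved — and all dates
are re-flagged under the refitted intensity. Refits reuse iteration 0's
GCV-selected smoothing parameters: removing a handful of spikes should
change the flag set, not the smoothness class of the trend. The report
records the iteration at which each flag first appeared.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `c` (`detection_config`) | $10^{-4}$ | pointwise tail-probability threshold; the 99.99th-percentile rule |
| `max_refit_iterations` | 1 | fit–flag–refit rounds against masking |
| `criterion` | `"tail_prob"` | the tail inequality; `"quantile"` flags strict exceedance of the $1-c$ quantile (differs only by discreteness at the boundary) |
| `max_rank_s1` | $\min(2\cdot\text{years}, 200)$ | trend basis rank (degrees of freedom ceiling) |
| `rank_s2` | 10 | weekend-smooth rank |
| `weekend_days` | Sat, Sun | ISO weekdays carrying the indicator |
| `treat_holidays_as_weekend` | `TRUE` | holidays share the weekend smooth (one indicator, no third term) |
| SARIMA orders | $(0,1,5)\times(0,0,2)_7$ | the high-order weekly model selected in the motivating application |
| MAD `half_width` | 7 days | sliding window half-width (centre excluded) |

No multiple-testing correction is applied by default — the pointwise rule is
used as-is, matching practice where a ranked shortlist goes to data-cleaning
staff; a Bonferroni mode (`bonferroni = TRUE`, threshold $c/n$) exists for
users who want family-wise control. Holiday calendars default to empty
because the appropriate calendar is jurisdiction-specific; supply one via
`read_holidays()`.

## The baselines, and why they fail where they fail

`detect_sarima()` fits a seasonal ARIMA with fixed orders by maximum
likelihood and flags one-step residuals above a single global
$\text{location} + z_{0.9999}\cdot\text{scale}$ line (one-sided:
contamination inflates counts). Location and scale default to the mean and
standard deviation of the post-warm-up residuals — the estimator implied by
the normality assumption of the rule; a median/MAD option exists. Two
consequences follow. First, large spikes inflate the global scale, raising
the threshold everywhere. Second, no pointwise threshold exists, so a
30-count fill at a sparse range end (residual ≈ 30) hides below a threshold
calibrated to the noisy mid-range — exactly the failure the pointwise
Poisson criterion avoids. Non-stationary or non-invertible fits are
rejected with the offending roots named.

`detect_mad()` estimates the signal at each position as the median of its
windowed neighbours (centre excluded — including it would dilute single-day
spikes) and the spread as the median absolute deviation from that median.
Where most neighbours are zero both medians degenerate to zero, and the
degenerate policy — flag anything different from the signal — then flags
every nonzero count: for $(0,0,0,900,0,1,0)$ with a full-sequence window,
both the 900 and the 1 are flagged. This is implemented deliberately, as
the canonical illustration of why sparse tails need a count model.

## The synthetic register generator

Real registers of this kind are person-identifiable and private, so the
package ships a generator (`generate_register()`) whose defaults emulate the
structure the model assumes, at the scale of the motivating application: a
123-year range (1890–2012) normalized to 40,000 expected individuals; a
natural-cubic-spline trend through control points on the log scale encoding
a depression-era dip (1933–34), a post-war boom plateau (1946–1961) and an
ageing-out decline toward the recent end; an annual sinusoid of amplitude
0.05 on the log scale; and a weekend log-ratio drifting from $+0.05$ before
1920 to $-0.6$ by 2012 (weekend births were slightly *more* common before
hospital deliveries became the norm). Natural cubic splines are used rather
than shape-preserving monotone cubics because the model assumes a twice
differentiable log-intensity and monotone interpolants are only $C^1$; on
the log scale overshoot is harmless. The control-point values are scenario
choices: they were fixed once so that the scenario exhibits the features
the detectors are meant to distinguish (a boom peak above $\lambda = 3$ on
weekdays, range-end intensities below $0.1$), and they are claims about no
real data set.

Typed contamination is injected with exact labels: zero-date fills at the
sparse left end (1899-12-30, 1900-01-01, 1901-01-01, magnitudes 30–45), a
Unix-epoch fill (1970-01-01, 150), year/age confusion (1911-01-01), decade
and new-year roundings at 20× the local intensity, one duplicated identity
(count × 30), and a 20-date block of dispensing-date leakage (mean 600 per
date) at the recent end. Magnitudes mix absolute spike sizes and multiples
of local $\lambda$ to span easy and hard regimes. The generator draws
everything from a single seeded RNG stream and records the seed, so dumps
are byte-reproducible.

What the generator does *not* emulate: over-dispersion, day-of-month
artefacts in genuine births, correlated errors across neighbouring dates,
or record-level structure (names, addresses, linkage). Tests passing on
synthetic registers therefore certify the statistical machinery under the
model's own assumptions, not performance on any particular real database.

## Numerical choices and degenerate inputs

* Dense day grid required; gaps are an error, zero-count days are data.
* The IRLS linear predictor is capped at 35 during step evaluation to avoid
  transient overflow; fitted intensities are always strictly positive.
* Tail probabilities are computed on the log scale for ranking; ties among
  underflowed values are broken by $\log(N(d)/\hat\lambda(d))$, then date.
* Zero counts can never be flagged ($P(K \ge 0) = 1$).
* An all-zero indicator drops the weekend smooth instead of fitting a
  singular design. Series shorter than the requested ranks trigger rank
  reduction with a warning; fewer than 10 days is an error.
* Prediction outside the fitted range errors unless `extrapolate = TRUE`,
  which holds the smooths constant at the range ends (splines extrapolate
  wildly; a constant is the honest default).
* Model dumps serialize at 17 significant digits, so a reloaded model
  reproduces intensities bit-for-bit through `predict_intensity()`.

## Problem sizes used by the test-suite simulations

The operating-characteristic checks run the detectors on full-scale
registers (~44,925 days): 20 clean registers for false-positive control and
refit stability, 20 contaminated registers for detection power and the
GAM-versus-SARIMA comparison (AUC over the first 10), and 10 replicates of
a 2,200-day parameter-recovery scenario with $\lambda \in [5, 50]$ and a
constant weekend log-ratio of $-0.5$. These sizes were chosen to match the
scale of the motivating application while keeping a full suite run inside a
coffee break on one core.

## Known limitations

* A date that is *both* genuinely popular and contaminated is detected only
  to the extent the excess clears the pointwise percentile; the method
  estimates dates, not which records on a date are wrong.
* Under-representation (missing births) is not flagged; the detector is
  one-sided by design, and missingness is reported upstream by the parser.
* Sensitivity at the extreme range ends is limited by information: a spike
  of 2 on a $\lambda = 0.01$ day is suspicious but cannot clear $c=10^{-4}$.
* The SARIMA baseline's behaviour depends on its global scale estimator;
  with the robust option it catches moderate sparse-end fills that the
  moment estimator misses — the shipped default is the moment
  estimator that the rule's normality assumption implies.
* GCV occasionally undersmooths short, noisy series; the GCV profile is
  returned (`fit$gcv_profile`) for inspection.
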