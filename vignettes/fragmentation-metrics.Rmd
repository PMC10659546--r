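---
title: "Rest-activity fragmentation metrics: models, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rest-activity fragmentation metrics: models, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragmetrics)
```

## The three views of a recording

A week of wrist accelerometry is represented three ways, and each metric is
defined on exactly one of them:

* **x** — the acceleration series, one non-negative value per epoch
  (`accel_series`; nominally ENMO in milligravity at 60-second epochs, so a
  7-day record has T = 10080 epochs). Detrended fluctuation analysis works
  on x.
* **y** — the binary rest/activity series (`state_series`), obtained by
  thresholding x: an epoch is *active* iff its acceleration strictly
  exceeds the threshold (default 40 mg, the conventional boundary between
  sedentary behaviour and light activity at the wrist). Epochs exactly at
  the threshold are rest. All transition-probability estimators work on y.
* **z** — the hourly proportion of active epochs (`hourly_profile`,
  P = 168 values for a week). Inter-daily stability, intradaily
  variability and the AR(1) diagnostic work on z, and only on z: the range
  results below fail on the raw series, so the package deliberately offers
  no shortcut for computing them on x.

States are carried as an explicit two-label alphabet rather than as 0/1
numerics so a thresholded series can never be thresholded again by
accident.

## IS and IV

With D days of H hours (P = DH hours total),

$$\mathrm{IS}(z) =
  \frac{P\sum_{h=1}^{H}(\bar z_h-\bar z)^2}{H\sum_{p=1}^{P}(z_p-\bar z)^2},
\qquad
\mathrm{IV}(z) =
  \frac{P\sum_{p=2}^{P}(z_p-z_{p-1})^2}{(P-1)\sum_{p=1}^{P}(z_p-\bar z)^2},$$

where $\bar z_h$ is the mean of hour *h* across days. IS is the fraction
of total variance explained by the mean 24-hour profile: 1 when every day
repeats exactly, near 1/D for structureless noise (the exact iid
expectation ratio is $\tfrac{H-1}{H}\tfrac{P}{P-1}\tfrac 1 D \approx
0.138$ for a week, which the test suite checks by simulation). IV is the
normalised mean squared successive difference, taken across the whole
series including day boundaries.

Under a stationary AR(1) working model for z with autocorrelation
$\phi \in [0, 1)$, IV converges to $2(1-\phi)$ as P grows: 2 for
uncorrelated noise, 0 for a perfectly smooth rhythm. Values above 2 are
possible for short series or $\phi < 0$ (ultradian rhythmicity); they are
reported as-is, never clipped, and `estimate_phi()` — the lag-1 sample
autocorrelation, the simplest consistent estimator under the working
model — flags $\hat\phi < 0$ as ultradian. Constant profiles make both
formulas 0/0 and raise an error rather than returning a sentinel; callers
assembling a panel get an `NA` with a reason code via `compute_all()`.

The AR(1) generator `gen_ar1_hourly()` is parameterised by the
*stationary mean* (`mu`, default 0.5) rather than the regression
intercept, so the default (mu = 0.5, sigma = 0.1) is a sensible
proportion-like series for every $\phi$; the two parameterisations differ
only by the constant $\mu/(1-\phi)$ and every property tested is a
function of $\phi$ and deviations alone. Clipping to [0, 1] is off by
default so the theoretical limits are undistorted; with clipping on, the
clipped fraction is reported and is below 1% at the defaults.

## Bouts and transition probabilities

Run-length encoding of y gives rest bouts $r_1,\dots,r_{n_r}$ and activity
bouts $a_1,\dots,a_{n_a}$, with per-state totals $T_r, T_a$ and survival
counts $N_r(s)$ = number of rest bouts of duration at least s. The final
bout of the series is censored — we never see it end — so starred
("terminal-corrected") tallies drop one bout and one epoch from the
terminal state: $n^* = n - 1$, $T^* = T - 1$, and $N^*(s)$ omits the last
bout entirely.

Four estimator families are provided, all per-epoch switch probabilities:

* **Maximum likelihood (order 1)**: $\hat\pi_{ra} = n_r^*/T_r^*$,
  $\hat\pi_{ar} = n_a^*/T_a^*$. When one state has no corrected
  observation time the pair is still returned with that direction `NA`
  and a warning (the Bayesian estimator is the recommended fallback);
  only a series in which neither direction is estimable errors.
* **Bayesian (Beta-Binomial)**: $(n^* + \lambda)/(T^* + \lambda)$ with
  pseudo-count $\lambda$. Default $\lambda = 0.5$; $\lambda = 1$ is the
  uniform prior, and $\lambda = 10^{-6}$ is numerically indistinguishable
  from ML. Always defined: a state absent from the data yields
  $\lambda/\lambda = 1$, encoding that a visit to the missing state would
  immediately revert.
* **RAD** (reciprocal average duration): the uncorrected $n/T$. It equals
  ML for the direction whose origin state does not end the series and
  strictly exceeds it for the other whenever that state has any bout
  longer than one epoch.
* **Duration-dependent curve**: $\hat\pi(s) = \Delta^*(s)/N^*(s)$ for
  $s = 1..S-1$, plus the gap-bridging heuristic
  $(N(s)-N(s+d))/(dN(s))$ with the smallest d giving a positive drop.
  The heuristic stays strictly inside (0, 1) but is biased wherever
  $d > 1$, which gaps in the observed bout lengths force.

### The weighted summary and its closed form

Weighting the ML curve by surviving-bout counts,
$\bar\pi = \sum_s \hat\pi(s)\,N^*(s)/\sum_s N^*(s)$, telescopes to
$(n^* - N^*(S))\,/\,(\sum_{s \le S} N^*(s) - N^*(S))$. The package
returns the conventional closed form $(n^*-N^*(S))/(T^*-N^*(S))$, which
replaces $\sum_s N^*(s)$ by $T^*$. The two denominators differ by
(length of the censored terminal bout − 1), so closed form and explicit
weighted sum coincide exactly only when the origin state does not end the
series or its final bout lasts one epoch; `tp_weighted_summary()` exposes
the explicit sum as an attribute and the tests assert equality precisely
in the cases where it holds. On long series with many short bouts
($n^* \gg N^*(S)$) both versions converge to the order-1 ML estimate —
the justification for reporting order-1 TPs as summaries of the whole
duration profile, verified on simulated Markov chains at T = 10080 to
within 0.01.

### Window splits

The headline per-subject metrics are the four Bayesian TPs computed
separately within awake and sleep windows. Each window interval is an
independent sequence: bouts are cut at window boundaries, every window
contributes its own terminal-bout correction (keeping the Bernoulli
argument behind the ML estimator valid within windows), and a label's
tallies are pooled starred counts — not averages of per-window TPs —
before the pseudo-count is added. $\lambda$ is restricted to (0, 1]
here. A typical consolidated sleeper shows
$TP_{ar,s} > TP_{ar,w}$ and $TP_{ra,w} > TP_{ra,s}$.

## DFA and the activity balance index

The acceleration series is integrated about its mean,
$c_t = \sum_{i\le t}(x_i - \bar x)$, cut into $B = \lfloor T/n\rfloor$
non-overlapping boxes of n epochs, and detrended per box by a
least-squares polynomial of order l (default 1, classic DFA-1). The RMS
residual F(n) over the first Bn points is evaluated on a log-spaced grid
of box sizes in $[4, \lfloor T/4\rfloor]$ (30 requested sizes by
default; duplicates after integer rounding are dropped), and the scaling
exponent $\hat\alpha$ is the OLS slope of $\log F(n)$ on $\log n$, each
grid point weighted equally. Numerical choices: when n does not divide
T the trailing remainder is discarded and the RMS is normalised by Bn
(no backward-window averaging); grid points with F(n) = 0 — perfectly
detrended boxes — are dropped from the fit with a warning rather than
propagating $-\infty$; a constant series has no defined exponent and
errors.

Calibration: $\hat\alpha \approx 0.5$ for white noise, $\approx H$ for
fractional Gaussian noise with Hurst exponent H (generated by exact
circulant embedding of the fGn autocovariance), $\approx 1.5$ for a
random walk — all verified by Monte-Carlo in the tests at T = 10080.
$\hat\alpha$ is invariant to positive rescaling of x, and coarsening the
epoch length smooths the signal, never pulling $\hat\alpha$ down toward
the white-noise value.

The activity balance index maps the exponent onto (0, 1]:

$$\mathrm{ABI}(\hat\alpha) = \exp\!\left(-\,|\hat\alpha - 1|\,e^{2}\right).$$

It is 1 exactly at the fractal point $\alpha = 1$, symmetric in both
directions of departure, and falls to $e^{-e^2} \approx 0.0006$ at the
theoretical extremes $\alpha \in \{0, 2\}$. The scale constant $e^2$ is
exposed as an argument; it is the value consistent with those limits.
Exponents outside (0, 2) are transformed anyway with a warning.

## What the generators emulate — and what they do not

`gen_markov_states()` (geometric bouts), `gen_semi_markov_states()`
(lognormal or user-supplied durations, giving non-flat, typically
unimodal duration-dependent TP curves), `gen_noise_accel()`
(white/fGn/random-walk), and `gen_ar1_hourly()` each realise exactly the
model their estimator assumes, so parameter recovery is a meaningful
test. `gen_weekly_profile()` composes them into a 7-day record starting
at waking onset: a two-state chain whose transition probabilities switch
between awake values (rest→active 0.10, active→rest 0.28) and sleep
values (0.007, 0.77) — fixed at typical older-adult cohort levels — with
acceleration drawn strictly below the threshold for rest epochs and
strictly above it for active ones, so binarisation recovers the simulated
states exactly.

Real data differ in ways these generators do not imitate: non-wear
segments, device calibration error, threshold misclassification (real
acceleration is not separated from the threshold), gradual sleep onset,
napping, and day-to-day schedule variation. Passing tests therefore
validate the estimators under their stated models, not the metrics'
epidemiological behaviour. All generators are seed-deterministic.

Problem sizes used in the test and acceptance runs — chosen as the
smallest at which the asymptotic statements are visibly tight — are
P = 100000 with 20 replicates for the IV limit, T = 10080 (one week)
with 20 seeds for the DFA calibrations, and 100-series batteries for the
range properties.

## Known limitations

* IS/IV are defined at the 1-hour bin width only; multiscale or
  high-frequency IV variants are out of scope.
* The duration-dependent ML curve returns the computed ratio even when
  $\Delta^*(s) = N^*(s)$ yields exactly 1 (all surviving bouts end at s);
  the nominal open range [0, 1) is not enforced by clipping.
* Cohort-scale values of $\hat\alpha$ depend on the exact box-size grid,
  which published analyses rarely pin down; comparisons across software
  should fix the grid explicitly.
* Raw-signal processing (ENMO derivation, calibration, non-wear and
  sleep-window detection) is upstream of this package: inputs are
  epoch-level CSVs plus externally supplied awake/sleep windows.
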