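---
title: "Cumulative exposure effects with constrained additive single-index models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative exposure effects with constrained additive single-index models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casim)
```

## The model

`casim` addresses a standard problem in environmental epidemiology: daily
counts of a health outcome (say, respiratory hospital admissions) respond to
air-pollutant concentrations and weather not just on the same day but over a
window of preceding days, and the dependence is nonlinear.  The model fitted
by `casim_fit()` is, on the log scale,

$$\log Y_t \;=\; \mu + \lambda(t) + S(t) +
  \sum_{j=1}^{p} g_j\!\Big(\sum_{\tau=0}^{L_j}\theta_{j,\tau}X_{j,t-\tau}\Big)
  + \varepsilon_t ,$$

with

* $\mu$ — the expected log count on the default weekday, pre-intervention,
  at zero (centred) cumulative effects;
* $S(t)=\sum_{k=1}^{6}\alpha_k D_{k,t}$ — a day-of-week effect, pinned to 0
  on a configurable default day (Friday by default);
* $\lambda(t)$ — a four-parameter logistic growth curve describing a
  sustained level shift after an excluded intervention period (in the
  motivating setting, the 2003 SARS epidemic and the public-health measures
  it triggered): $\lambda = 0$ up to the window start and
  $\xi_1+\xi_3/(1+e^{-\xi_2(\tau-\xi_4)})$ from the window end, $\tau$
  counting days since the window end;
* one *single-index* term per covariate: the lag window enters only through
  the scalar weighted average $\theta_j^T X_{j,t}$, and the unknown smooth
  $g_j$ is estimated by cubic B-spline regression.

Two constraint families carry the scientific content.  The lag weights live
on the **ordered unit simplex** ($\theta_{j,0}\ge\cdots\ge\theta_{j,L_j}\ge
0$, $\sum_\tau\theta_{j,\tau}=1$): recent exposure never matters less than
older exposure, and the unit sum fixes the index scale.  Pollutant effect
curves are restricted to be **monotone non-decreasing** (more pollution
never lowers risk), enforced through non-decreasing spline coefficients —
a sufficient condition for a non-decreasing spline.  Weather covariates are
exempt from the curve constraint because their effects are typically
U-shaped (comfort range in the middle, risk at both extremes).

Errors are treated as Gaussian on the log scale and fitted by least
squares; no Poisson/negative-binomial likelihood is attempted.

## Estimation

### Index transform and spline spaces

For a fixed $\theta_j$ the index $v=\theta_j^T X_{j,t}$ is carried to
$[0,1]$ by the CDF of a symmetric Beta$\{(d+1)/2,(d+1)/2\}$-type law
rescaled and centred on $[-a,a]$, with $d=L_j$ and $a$ the empirical 95th
percentile (nearest-rank rule) of the per-day sup norms
$\max(|X_{j,t}|,\dots,|X_{j,t-L_j}|)$.  We evaluate this CDF through the
regularized incomplete beta function (`pbeta`), which is exact; the test
suite confirms agreement with adaptive quadrature of the density to
1e-10.  Because $a$ is a percentile rather than a maximum, a few index
values fall outside $[-a,a]$; they are clamped to the boundary, where the
spline uses its boundary basis.  The transform derivative is zero there,
so clamped points simply do not inform the weight gradient.

The spline space is fixed, not tuned: $N=\max(\lfloor n^{1/5.5}\rfloor,5)$
interior knots placed at the $j/(N+1)$ empirical quantiles of the
transformed index (so each segment holds roughly equally many
observations), boundary knots repeated to the cubic order.  Duplicate
knots from heavily tied indices are collapsed with a warning.  One
percentile definition — nearest-rank, `quantile(type = 1)` — is used
everywhere a quantile appears.

### Constrained fits

*Monotone spline regression* is solved exactly as a non-negativity
constrained least-squares problem: coefficient differences are
reparametrised as non-negative, the free level is profiled out via the
partition of unity, and the reduced problem goes to Lawson–Hanson NNLS.
*Ordered-simplex projection* is computed exactly in two steps — isotonic
regression onto the non-increasing cone (PAVA) followed by a closed-form
water-filling shift-and-clip solving the scalar dual of the sum
constraint.  Both are verified in the tests against brute-force active-set
QP oracles.

*One single-index block* alternates (i) rebuilding the transform and knots
for the current weights and re-fitting the spline, and (ii) projected
gradient steps on the weights through the frozen spline, with an analytic
gradient (spline derivative times Beta density times lag window), Armijo
backtracking (halving, at most 30 steps), at most 50 weight steps per
alternation, and convergence at relative RSS change below `tol` (1e-6 by
default).  A knot refresh that would increase the objective is rolled
back, so the block objective never increases.

### Backfitting

`casim_fit()` initialises the parametric part ($\mu$, $\alpha$, $\xi$) by
profiled least squares — the model is linear in everything except
$(\xi_2,\xi_4)$, which are found by a coarse multi-start grid plus
Nelder–Mead polish — then initialises the blocks sequentially on running
partial residuals.  Cycles then re-fit the parametric part on the outcome
net of all cumulative effects and re-estimate each block on its partial
residual, warm-starting everything.

One design choice deserves a note.  During the *initialisation* sweep the
partial residual for block $j$ can only subtract blocks $1..j{-}1$ (the
rest do not exist yet).  For the *iteration* sweeps we subtract the
current estimates of **all other** blocks — classic backfitting — rather
than re-deriving the whole decomposition from the parametric residual each
sweep.  With warm starts this makes the overall RSS provably
non-increasing (each block update minimises the same overall objective
over a set containing its previous value), which is the property the test
suite asserts to 1e-8.  The purely sequential variant is available as
`update = "sequential"` but carries no descent guarantee.

Each fitted $g_j$ is centred to mean zero over the used sample, the offset
being absorbed into $\mu$, which resolves the additive-model location
indeterminacy ("zero cumulative effects" defines $\mu$).  The alternative
normalisation $g_j(0)=0$ would shift $\mu$ by a constant per block and is
not otherwise different.

Rows are used only if the full lag window fits inside one contiguous
calendar segment and does not touch the excluded intervention window; the
window interior itself is never fitted.  Counts of zero are rejected at
load time (the log transform requires positivity); an optional $+0.5$
offset is available but off by default.

Two further conventions are needed because the growth curve is defined
relative to the window.  The time origin for $\tau$ is the window **end**
(making a midpoint $\xi_4$ of a couple of hundred days interpretable), and
the weekday indices $k=1..6$ map to Saturday through Thursday when Friday
is the default day (the mapping follows the calendar starting the day
after the default day, and is configurable).

### Lag selection

`select_lags()` minimises the AIC over lag vectors in two stages: a
common-lag scan over the grid $1, 1{+}l, \dots \le K$ (defaults $l=10$,
$K=200$) and then coordinate descent, replacing one $L_j$ at a time by the
AIC-minimiser over $[L_j-d, L_j+d]$ (default $d=5$) until a full cycle
changes nothing.  At fixed sample size the AIC reduces to $\log(\mathrm
{MSE}) + 2m/n$ with $m = 1 + 6 + 4 + \sum_j L_j$ (constant, weekly,
growth-curve, and per-block free weights under the sum constraint); spline
coefficients are excluded because their number never varies across
candidates.  Every fit during the search is trimmed by the global bound
$K$ so $n$ — and hence the AIC — is comparable across candidates; the
final selected model is re-fitted on the maximal usable rows and both AICs
are reported.  Ties break toward smaller lags, and evaluated lag vectors
are memoised, which makes the accepted AIC path exactly non-increasing.
The search grid may start at 0 (contemporaneous-only) via `lag_min`/
`grid_start`, though the default grid starts at 1.

### Uncertainty

`bootstrap_casim()` implements the residual bootstrap on the log scale:
resample residuals i.i.d. with replacement, add them back to the fitted
log series, re-fit with the lags held fixed at the point estimate (warm
started).  Re-selecting lags inside each replicate would multiply the cost
by the size of the search and is not attempted.  A moving-block variant
(`method = "block"`) is available for autocorrelated residuals, off by
default.  `confidence_bounds()` applies the percentile method — nearest-
rank quantiles at $(1-\text{level})/2$ and $1-(1-\text{level})/2$ — plus
the bootstrap SD; curve bands are pointwise on a fixed index grid, not
simultaneous.  The percentile method can leave the point estimate outside
its own interval; this is flagged, not corrected.

## The synthetic-data generator

Because the motivating hospital-admission data are not publicly
deposited, every estimation stage is validated on synthetic studies with
known truth from `simulate_casim()`.  The generator reproduces the
statistical structure the model assumes: positive autocorrelated exposure
series (lognormal-marginal AR(1) for pollutant-like series; a bounded
probit-marginal AR(1) for the humidity-like series, since relative
humidity is physically confined to an interval — an unbounded marginal
would place mass at impossible values and make the upper tail of the
U-shaped curve dominate), geometric-decay lag weights on the ordered
simplex, monotone-saturating pollutant curves and a U-shaped weather
curve, a weekly admission pattern, a logistic post-intervention level
shift with a 107-day excluded window, and Gaussian noise on the log scale
(default SD 0.15, echoing the residual scale typical of such studies).
Counts are the rounded exponential of the log signal; rounding can be
disabled for exact-recovery experiments.  All components are stored so
tests can assert the exact bookkeeping identity (components sum to the
log signal).

What the generator does **not** emulate — seasonal cycles, covariate
cross-correlation (pollutants are generated independently), measurement
error in exposures, overdispersed counts — bounds what passing tests show
about real data: they validate the estimator under its own assumptions,
not the assumptions themselves.

## Validation problem sizes

The test suite exercises: parameter recovery on 20 replicates of the
default study ($n=1500$, $p=3$, true lags $(6,4,3)$, noise SD 0.05),
asserting mean per-block sup-error of the weights $\le 0.08$, weekly
effects within two empirical SDs, centred effect curves within sup-norm
0.15 on the central 90% of the index range, and an essentially exact fit
(MSE $\le 10^{-4}$) of a noiseless replicate; lag recovery within $\pm1$
in at least 15 of 20 replicates of a two-covariate study ($n=500$, gentle
weight decay 0.9 so that the terminal lag carries detectable mass) with a
scaled-down search ($l=2$, $K=20$, $d=3$); bootstrap coverage of the
first weekly effect in $[0.85, 1]$ over 50 replicates at $B=200$ on a
small lag-0 study; and oracle agreement for every constrained primitive.
These sizes were chosen as the smallest at which the statistical
assertions are stable.

## Known limitations

* The backfit finds a local optimum; the weight problem is non-convex and
  a poor initialisation could in principle matter, though equal weights
  have proven robust in all seeded experiments.
* AIC coordinate descent is a local search on the lag lattice; it is only
  guaranteed to find a coordinate-wise minimum.
* Confidence bands are pointwise percentile bands; no asymptotic or
  simultaneous inference is provided.
* Gap-free daily coverage per segment is required; missing covariate days
  must be handled upstream (or declared as segment breaks).
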