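---
title: "Methods: attractant freshness, survey effort, and detection at baited camera traps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attractant freshness, survey effort, and detection at baited camera traps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lurefx)
```

## The problem

Edible baits and scent lures ("attractants") are placed at camera-trap
stations to raise the detection rates of elusive species, especially
small carnivores. But an attractant is not a constant stimulus: it
desiccates, is consumed, and its scent dissipates between servicing
visits. If animals respond to attractant *freshness*, detection
probability varies systematically within each servicing cycle, and
species may transiently avoid or seek out stations just after baiting.
`lurefx` quantifies both phenomena from standard camera-trap logs:

1. a **detection-model track** — single-season occupancy models in which
   daily detection probability depends on the age of the attractant and
   on survey effort, compared by AICc; and
2. a **visitation track** — a randomization test asking whether a
   species visits stations more or less often than expected in each of
   the seven 24-h periods after attractant refresh.

## Data model and event processing

Three tables describe a survey: a capture log (species, station,
timestamp), a deployment log (station, start/end dates, inactive dates),
and an attractant refresh log (station, servicing timestamps).
Timestamps are naive local clock time: the surveys these methods target
are single-site, and diel analysis needs one consistent clock, so no
timezone arithmetic is ever applied.

*Independent captures.* A photo event is an independent site visit if at
least one hour (configurable) has elapsed since the previously
**retained** capture of the same species at the same station. Anchoring
on the retained event rather than the raw previous photo makes the
filter idempotent and guarantees retained events are pairwise at least
one window apart; with a burst of photos every 45 minutes, the
alternative raw-anchor rule would discard everything after the first
event no matter how long the burst lasted.

*Occasions.* The detection model uses an occasion length of one calendar
day, with the boundary at local midnight — the only unambiguous
realisation of a daily occasion. A cell of the detection matrix is
missing exactly when the station was not active that date (outside its
deployment or a logged failure day); missing occasions contribute
nothing to likelihoods and are excluded from naive-detection
denominators.

*Covariates.* Three observation-level detection covariates are built on
the same station-by-date grid: `attractant_age` (whole days since the
most recent refresh date — the model is daily, so age is evaluated at
the occasion's start-of-day and is 0 on refresh dates),
`incremental_effort` (days the station had been effectively active, 1 up
to its total trap-days, skipping failure days), and `total_effort` (the
station's total active trap-days, constant per station).

*Day bins.* For the visitation track, each independent capture is
assigned the elapsed time since the most recent refresh at its station
and binned into half-open 24-h intervals: bin $d$ covers
$[24(d-1), 24d)$ hours, $d = 1,\dots,7$. Events at or beyond 168 h are
excluded from the bins (the analysis targets short-term response) but
still count in the denominator of the observed proportions, which are
defined as bin count over *total* independent captures of the species.
A mid-day refresh does not split its occasion; the day's captures keep
their exact elapsed hours.

## The occupancy-detection model

For species occupancy $\psi$ and daily detection $p_{ij}$ at station $i$
on occasion $j$,

$$L(\psi, \beta) = \prod_i \Big[ \psi \prod_{j}
  p_{ij}^{y_{ij}} (1 - p_{ij})^{1 - y_{ij}}
  + (1 - \psi)\, I\{\text{all } y_{ij} = 0\} \Big],$$

with $\mathrm{logit}(\psi) = \beta_\psi$ constant (the focus is
detection, not occupancy structure) and
$\mathrm{logit}(p_{ij}) = \beta_0 + \sum_t \beta_t x_{tij}$ over the
chosen covariates. The candidate set combines attractant age with each
effort measure univariately and additively — six models, no
interactions, the two effort parameterizations never combined with each
other — ranked by
$\mathrm{AICc} = -2\ell + 2K + 2K(K+1)/(n - K - 1)$ with $n$ the number
of stations, the standard effective-sample-size convention for
site-structured data.

Numerical choices: parameters live on the logit scale; covariates are
z-scored internally for conditioning and coefficients mapped back to the
natural scale (the covariance matrix transformed by the same linear
map); optimization is BFGS with an analytic gradient from five
deterministic starts, followed by damped Newton steps until the gradient
max-norm is below $10^{-4}$; standard errors come from the inverse
numerical Hessian (central differences of the analytic gradient). A fit
is reported `converged` only if the optimizer succeeded, the gradient
tolerance is met, and the Hessian is invertible with positive variances;
estimates beyond $\pm 8$ on the standardized logit scale set a separate
`boundary` flag (an all-ones detection history, for instance, drives
$\hat\psi, \hat p \to 1$). An all-zero history returns a non-converged
fit with a warning rather than pretending $\psi$ is estimable.
Predicted detection curves use the delta method on the logit scale and
transform the endpoints, so intervals respect $(0, 1)$.

## Diel activity and the randomization null

The visitation track needs a null distribution for "how often is a
species at a station $d$ days after baiting, absent any response". A
random capture is assembled by drawing a station uniformly from the
stations at which the species was actually captured, a date uniformly
from that station's active dates, and a time-of-day from the species'
diel activity density; elapsed time since refresh is then computed
exactly as for real captures. This preserves the species' spatial
footprint, each station's refresh schedule, and the species' diel
rhythm — without it, a nocturnal species serviced at midday would show
spurious structure in the elapsed-time distribution — while severing any
link between visitation and attractant age.

The diel density is a von Mises kernel density on the 24-h circle,
$\hat f(\theta) = n^{-1} \sum_k \mathrm{vM}(\theta; \theta_k, \kappa)$,
with $\kappa$ set by the von Mises rule-of-thumb bandwidth of Taylor
(2008) from the maximum-likelihood concentration of the data (Best &
Fisher approximation). The exact bandwidth rule used in any given field
study is rarely reported, so `bw` is exposed as an argument; the
rule-of-thumb is the default of the kernel-density family these analyses
conventionally use. The density is evaluated on a 512-point grid
(normalization holds to $10^{-6}$ by construction), sampled by
inverse-CDF with linear interpolation, and degenerate all-identical
inputs cap $\kappa$ at 500 to avoid overflow. Densities need at least 10
observations; below that the fit errors rather than returning something
meaninglessly spiky.

With $N$ random histories of the observed sample size (default
$N = 1000$), the per-bin p-value is the rank probability

$$p_d = \frac{\#\{r : r < o_d\} + \tfrac12\,\#\{r = o_d\} + 1}{N + 1},$$

so low $p_d$ means the species visited less often than the null predicts
and high $p_d$ more often; at $\alpha = 0.05$ the two-tailed rule
classifies $p < 0.025$ as `decreased` and $p > 0.975$ as `increased`.
Ties count half because the proportions are discrete (multiples of one
over the capture count); without the correction, heavily tied bins would
be biased toward one tail. Random histories are *not* passed back
through the 1-h independence filter — they are draws of independent
visits by construction, and the observed proportions they are compared
with are computed from already-filtered captures.

## What the synthetic generator emulates

`generate_survey()` draws a full survey with known truth: ~45 stations
(configurable), deployments of 60–90 days with staggered starts, a small
daily probability (0.02) that a station is non-functional, servicing
intervals of $3 + \mathrm{Gamma}(2.5, \text{scale } 2)$ days clipped to
3–27 d (mean 8 d, matching a roughly weekly servicing cadence with
occasional long gaps), installation baiting at deployment start, and
per-species truth: occupancy $\psi$, baseline detection logit $\beta_0$,
a linear per-day attractant-age effect $\beta_{\text{attract}}$ on the
detection logit, and a 1–2 component von Mises diel mixture. Detected
days emit one capture plus an optional $\mathrm{Poisson}$ count of
extra same-day visits.

Two deliberate simplifications keep the calibration experiments
well-posed. First, detection is conditionally independent across days
given occupancy — exactly the occupancy model's own assumption — so
parameter-recovery and coverage runs test the estimator, not a
model-data mismatch. Second, the extra-visit count defaults to zero:
within-day repeat visits are a clustering stressor that violates the
exchangeability the randomization test presumes (clustered observed
counts are over-dispersed relative to independently drawn null counts,
inflating both tails), and such behavioural autocorrelation is kept off
by default and switched on explicitly when robustness is the question.
Real data will have some of both features, plus movement, home-range
structure and inter-species interactions the generator does not attempt;
passing calibration here shows the machinery is correct under its own
assumptions, not that field data satisfy them.

The linear-in-age logit is the same functional form the detection model
fits. An exponential-freshness variant can be emulated by supplying a
transformed covariate, but the default keeps generator and model
aligned so that recovery experiments have a defined truth.

## Study sizes used by the verification suite

The packaged experiments use: likelihood-oracle equivalence on every
two-station, three-occasion history; parameter recovery and Wald
coverage on 200 replicates of 200 stations × 70 occasions at
$\psi = 0.6$, $p_0 = 0.25$, $\beta_{\text{attract}} = -0.15$/day;
type-I calibration of the randomization test on 500 null species over a
45-station survey at $N = 1000$ (per-bin flag rate checked against a
[0.03, 0.08] band and p-values against uniformity); and power on 50
replicates with $\beta_{\text{attract}} = -0.3$/day, where the top AICc
model should include attractant age and day-1 visitation should classify
as increased. These sizes give Monte-Carlo error small enough for the
stated bands while keeping a full run in minutes on one core.

## Known limitations

- Occupancy is constant by design; habitat covariates on $\psi$ are out
  of scope.
- One capture log, one local clock: multi-timezone or multi-season
  designs are not handled.
- The randomization null conditions on the set of captured stations;
  species captured at very few stations yield coarse, heavily tied null
  distributions, and the test loses resolution below a few dozen
  captures.
- Wald intervals and the delta method are asymptotic in the number of
  stations; at a few dozen stations with rare species, profile or
  bootstrap intervals would be more defensible than the defaults.
- The attractant-age covariate is whole days; sub-daily freshness
  dynamics are invisible at the daily occasion length (a shorter
  occasion would change the likelihood's missing-data structure, not
  just the covariate).
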