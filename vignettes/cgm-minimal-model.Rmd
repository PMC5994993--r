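---
title: "A minimal model for personalizing CGM records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal model for personalizing CGM records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmpulse)
library(dplyr)
```

## The problem

A continuous glucose monitor (CGM) reports subcutaneous glucose roughly
every 15 minutes for about two weeks while the wearer goes about their
life. The record is rich — post-meal excursions, overnight decays, a strong
circadian rhythm driven by the periodicity of eating — but it measures only
glucose. The quantities a clinician actually reasons about, insulin
sensitivity, secretory capacity, the insulin response to a given food and
the rate at which a meal delivers glucose into the blood, are all latent.

`cgmpulse` addresses this with a deliberately minimal dynamical model that
can be identified from a CGM record plus two cheap laboratory numbers
(fasting glucose and fasting insulin) and a food diary. Large multi-compartment
postprandial models are excellent in tracer-instrumented studies but their
parameters cannot be identified from glucose alone; a minimal model can be.

## The model

Digested food is described by a linear two-compartment cascade — stomach
content $q_{sto}$ empties into a lumped "gut" $q_{gut}$, from which glucose
is absorbed into blood:

$$
\frac{dq_{sto}}{dt} = -k_{sto}\, q_{sto}, \qquad
\frac{dq_{gut}}{dt} = k_{sto}\, q_{sto} - k_{gut}\, q_{gut}.
$$

A meal taken at time $t_i$ is an *impulse*: $q_{sto} \mapsto q_{sto} +
food_i$. Liquid meals empty with a characteristic rate $k_{gut,l}$; mixed
meals are described on average by a slower rate $k_{gut,mm}$. The glucose
and insulin core is the fast subsystem of the Topp model:

$$
\frac{dG}{dt} = R_0 - (E_{G0} + S_I I)\,G + k_{gut} q_{gut}, \qquad
\frac{dI}{dt} = I_{max}\frac{G^2}{\alpha + G^2} - k_I I,
$$

with $G$ in mg/dl, $I$ in µU/ml and time in minutes. $R_0$ is basal hepatic
glucose production, $E_{G0}$ insulin-independent clearance, $S_I$ insulin
sensitivity, $I_{max}$ the maximal pancreatic secretion rate with
half-saturation constant $\alpha$, and $k_I$ the insulin clearance rate.
The amplitudes $food_i$ are glucose-equivalent quantities in the same
concentration-like units as the $q$ compartments, chosen so that
$k_{gut} q_{gut}$ has units mg dl$^{-1}$ min$^{-1}$.

Meals are implemented exactly as state resets: integration (adaptive
`lsoda`, relative tolerance $10^{-8}$, absolute $10^{-10}$) restarts at
each meal time with the stomach content incremented, rather than
approximating the impulse by a stiff forcing spike. Internally every meal
is carried in its own $(q_{sto}, q_{gut})$ pair — the cascade is linear, so
this superposition is exact and lets liquid and mixed meals with different
absorption rates coexist in one window.

```{r simulate}
p <- reference_parameters("non_diabetic")
day <- meal_events(
  time_min = c(450, 1051, 1260),
  amplitude = c(50, 177, 316),
  meal_class = c("liquid", "mixed", "mixed")
)
traj <- simulate_glucose(p, day, t_end = 1440)
range(traj$G)
```

## Identifiability and personalization

Not everything in the model can be learned from glucose alone:

* **$E_{G0}$ and $\alpha$ are held fixed** (numerical experiments show they
  are not identifiable from a CGM segment). $E_{G0}$ can instead be
  estimated directly from a decaying late-night segment, when insulin
  action is weak and the glucose equation collapses to
  $G(t) = G_\infty + (G_0 - G_\infty)e^{-E_{G0}t}$; see
  `estimate_eg0_night()`.
* **$k_I$ is never free.** At a fasting steady state the insulin equation
  forces $k_I = I_{max}G_{ss}^2/(\alpha + G_{ss}^2)/I_{ss}$, so the
  laboratory fasting pair $(G_{ss}, I_{ss})$ pins it. `fit_segment()`
  recomputes $k_I$ from this identity every time a candidate moves
  $I_{max}$, which both removes a parameter and keeps the laboratory
  anchors an exact equilibrium of the insulin equation.
* **The cascade rates have an exchange symmetry.** The forcing seen by
  glucose after a single impulse is
  $k_{gut}q_{gut}(t) = A\,k_{sto}k_{gut}\,
  (e^{-k_{gut}t} - e^{-k_{sto}t})/(k_{sto}-k_{gut})$, which is symmetric
  under $k_{sto} \leftrightarrow k_{gut}$: glucose data *cannot* order the
  two rates. This is why the fit runs under box constraints; bounds tight
  enough to exclude the swapped mode restore a unique optimum. The
  defaults place the box a factor of 10 either side of the starting
  bundle; recovery experiments in the test suite use a factor of 2.

Meal *times* come from the food diary and are never optimized (start times
are what a diary records reliably); meal *amplitudes* are part of the
optimization, so the method does not need to know how much was eaten.

The fit minimizes the weighted squared difference between the CGM samples
and the simulated glucose sampled at the same timestamps. The anchor of the
whole procedure is an *isolated liquid meal*: liquids pass through the gut
in a stereotyped way, so that single pulse identifies the full parameter
set, much like a free-living oral glucose tolerance test. A configurable
weight window (`pulse_window`, default multiplier 5) lets that pulse
dominate the cost when mixed meals share the segment.

Optimisation is a seeded two-stage search in log-parameter space: a
derivative-free Hooke–Jeeves pattern search followed by a bounded
quasi-Newton polish (`nlminb`), iterated until the relative change of every
parameter falls below $10^{-6}$ (iteration caps: 8 outer passes, 2000
pattern-search evaluations per pass, 500 local iterations — generous for a
5–8 dimensional problem). Log-space makes the multiplicative box symmetric
and keeps every candidate positive. The segment's initial state is the
candidate's fasting steady state unless the segment starts mid-excursion
(first sample more than 5% from the candidate's resting glucose), in which
case $G(0)$ is pinned to the first sample and $I(0)$ to its quasi-steady
value — a convention that makes fits reproducible.

## The fasting steady state

With the gut empty, insulin at quasi-steady state is $I_\infty(G) =
I_{max}G^2/(\alpha+G^2)/k_I$ and fasting glucose solves the scalar balance
$R_0 = (E_{G0} + S_I I_\infty(G))\,G$, found by Brent's method on
$(0, R_0/E_{G0}]$ — the insulin-free ceiling $R_0/E_{G0}$ must bracket any
physical equilibrium. Note that the model's own resting point is *not*
required to coincide with the laboratory anchors: for the shipped
non-diabetic bundle the model rests near 71 mg/dl and 9.3 µU/ml, a little
below the laboratory fasting values (90, 12.4) — fasting measurements are
taken in the morning, not at the overnight minimum, and the two quantities
are deliberately kept distinct.

```{r equilibrium}
fasting_steady_state(p)
```

## Reconstructing insulin and the rate of appearance

Because no technology measures insulin continuously, the package estimates
it with a *state observer*: a copy of the insulin equation driven by the
measured glucose,

$$
\frac{d\hat I}{dt} = I_{max}\frac{G_{data}(t)^2}{\alpha + G_{data}(t)^2}
  - k_I \hat I .
$$

When $G_{data}$ equals the true glucose, the error $e = I - \hat I$ obeys
$\dot e = -k_I e$ exactly — the estimate converges exponentially with time
constant $1/k_I$ regardless of initialization, and needs no knowledge of
the food intake. Outputs flag the first $3/k_I$ minutes of each window as
transient. The default initialization is the laboratory anchor $I_{ss}$,
whose typical ~30% mismatch with the resting insulin means the estimate is
within about 2% of the truth three time constants in and under 1% from
four onward; the suite verifies the decay law itself to integrator
accuracy. Between samples $G_{data}$ is a monotone piecewise-cubic
interpolant (no overshoot between 15-minute samples; linear interpolation
is available). Sampling gaps longer than 60 minutes split the record
rather than being interpolated through.

The *input observer* then inverts the glucose balance for the exogenous
forcing — the rate of appearance of glucose due to food:

$$
R_a = \frac{dG_{data}}{dt} - R_0 + (E_{G0} + S_I\hat I)\,G_{data}.
$$

The derivative is taken from a smoothing spline (smoothing chosen by
generalized cross-validation; `all.knots = TRUE`, because knot thinning
biases the derivative at meal onsets), which suppresses the noise
amplification of finite differences. On fasting segments $R_a$ is zero up
to noise; after a meal it tracks the true gut outflow $k_{gut}q_{gut}$ and
its time integral returns the meal amplitude — mass conservation is the
end-to-end oracle for the whole pipeline.

One honest resolution limit: $R_a$ has a slope discontinuity at each meal
onset, and a spline derivative through 15-minute samples necessarily
smears it over the adjacent one or two samples. On noiseless
model-generated data the reconstruction error is concentrated entirely
there; at a 2-minute cadence the L2 error falls below 5%. Away from
onsets, and for the integral of $R_a$, the 15-minute cadence is adequate.

```{r observers}
nd <- reference_day("non_diabetic")
obs <- insulin_observer(nd$cgm_true, p)
ra <- ra_observer(nd$cgm_true, obs, p)
summary(ra$ra)
```

## The synthetic-data generator

No patient records ship with the package, so validation rests on a
generator with full ground truth. A `cgm_scenario()` is a virtual subject:
a parameter bundle, a daily meal schedule repeated for `n_days` (default
14, the nominal sensor lifetime), a 15-minute sampling cadence, and
multiplicative Gaussian sensor noise $G_{obs} = G(1 + c_v\varepsilon)$.
The default $c_v = 5\%$ is a conservative reading of reported sensor
accuracy (a mean absolute relative difference around 11% between sensor
and reference mixes both instruments' errors; the sensor-only scatter is
smaller). Optional day-to-day jitter (meal times SD 15 min, amplitudes CV
10%) is off by default so fixtures stay exact. Two canonical single-day
fixtures accompany the reference bundles (`reference_day()`): a
non-diabetic day with a liquid breakfast at 450 min (amplitude 50) and
mixed meals at 1051 and 1260 (amplitudes 177, 316), and a diabetic day
with one isolated liquid meal at 1200 min (amplitude 230).

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: interstitial-vs-blood calibration and
the ~5-minute sensor lag, sensor dropout and compression artifacts,
autocorrelated sensor error, unlogged meals, exercise, stress, dawn
phenomenon, and hypoglycemic counter-regulation. Parameter recovery on
synthetic records shows the *procedure* is sound, not that every patient
segment is as well-behaved as an isolated liquid pulse.

## Spectral characterization

`psd_glucose()` is a single-taper (Hann) periodogram with an explicit
normalization: one-sided power scaled so that the spectrum integrates to
the variance of the detrended series (exactly, for the untapered case; the
suite checks the tapered estimate to 1% on a long record). The record is
regridded to its nominal cadence, with gaps up to 60 minutes bridged
linearly and longer gaps refused, and the mean removed. A two-week record
with a repeating meal schedule shows its dominant peak at a period of 24
hours; `dominant_period()` reports the peak in a band (default 16–32 h)
together with the frequency-bin width converted to hours — the honest
uncertainty of a periodogram peak — and a peak-prominence ratio (peak over
median band power, threshold 10) that separates a real circadian rhythm
from the band maximum of white noise.

```{r spectrum}
sc <- cgm_scenario(
  p,
  tibble::tibble(
    clock_min = c(450, 780, 1200), amplitude = c(60, 150, 250),
    meal_class = c("liquid", "mixed", "mixed")
  ),
  n_days = 14, noise_cv = 0.05, grid_step = 15
)
tb <- generate_cgm(sc, seed = 1)
dominant_period(psd_glucose(tb$cgm))
```

## Numerical choices and problem sizes

* ODE integration: `lsoda`, rtol $10^{-8}$ / atol $10^{-10}$; at these
  tolerances the simulated cascade matches its closed-form exponentials to
  better than $10^{-6}$ relative error, so closed-form oracles are
  meaningful.
* Root finding for the equilibrium: Brent on $(0, R_0/E_{G0}]$ with a
  residual check at $10^{-8}$ on both right-hand sides.
* Fit termination: relative parameter change $< 10^{-6}$, matching the
  reported cost landscape's flatness near an optimum; a failed simulation
  inside the cost returns `Inf` rather than erroring, so the pattern
  search can probe aggressive candidates safely.
* Degenerate inputs fail loudly: meal-free segments are refused by the
  fitter (fitting food to noise is not a fit), non-decaying night segments
  are refused by the $E_{G0}$ estimator, records shorter than two days are
  refused by the periodogram.
* Test problem sizes: recovery experiments use one-day, one-meal segments
  at 15-minute cadence; the Monte-Carlo noisy-recovery study uses 8
  replicates at CV 5%; spectral checks use 14-day records (1344 samples,
  which places the 24-hour period exactly on a Fourier bin). These sizes
  were chosen as the smallest that exercise each property cleanly.

## Known limitations

* Hypoglycemia is outside the model: there is no glucagon or
  counter-regulatory dynamics, so segments with lows are fit "in an
  average sense" at best.
* Mixed meals are described by a single effective absorption rate; their
  postprandial tails are more complex than the model can express.
* The $k_{sto}/k_{gut}$ exchange symmetry means absolute interpretation of
  the two cascade rates leans on the prior bounds, not the data.
* Sensor calibration and lag are ignored: laboratory and sensor glucose
  are treated as directly compatible.
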