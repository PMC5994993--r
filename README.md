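# cgmpulse

Minimal-model analysis of continuous glucose monitoring (CGM) records in
type 2 diabetes.

A CGM sensor reports glucose every ~15 minutes for about two weeks, but
glucose is all it measures. `cgmpulse` is for researchers and modellers who
want to pull the latent physiology out of that record: insulin sensitivity
and secretory capacity, a continuous insulin time series, and the rate at
which each meal actually delivered glucose into the blood — using nothing
beyond the CGM trace, a food diary, and one laboratory fasting glucose +
insulin pair.

## The model

Food is a linear two-compartment cascade driven by impulses (a meal at
time $t_i$ resets $q_{sto} \mapsto q_{sto} + food_i$):

$$\dot q_{sto} = -k_{sto} q_{sto}, \qquad
  \dot q_{gut} = k_{sto} q_{sto} - k_{gut} q_{gut},$$

with a fast absorption rate $k_{gut,l}$ for liquid meals and a slower
effective $k_{gut,mm}$ for mixed meals. Glucose and insulin follow the
fast subsystem of the Topp model:

$$\dot G = R_0 - (E_{G0} + S_I I)G + k_{gut} q_{gut}, \qquad
  \dot I = I_{max}\frac{G^2}{\alpha + G^2} - k_I I.$$

Three ideas make this identifiable from a CGM record alone:

1. **Steady-state anchoring.** $k_I = I_{max}G_{ss}^2/(\alpha +
   G_{ss}^2)/I_{ss}$ is pinned by the laboratory fasting pair, and the
   non-identifiable $E_{G0}$, $\alpha$ stay fixed ($E_{G0}$ can be read
   off a decaying late-night segment instead).
2. **Liquid-meal landmarks.** Liquids traverse the gut in a stereotyped
   way, so one isolated liquid pulse — a free-living analogue of an oral
   glucose tolerance test — identifies the remaining parameters and the
   meal amplitudes by weighted least squares.
3. **Observers.** A copy of the insulin equation driven by the measured
   glucose converges to the true insulin exponentially (error
   $\dot e = -k_I e$), with no knowledge of the meals; inverting the
   glucose balance with a smoothing-spline derivative then reconstructs
   the rate of appearance $R_a = \dot G_{data} - R_0 +
   (E_{G0} + S_I\hat I)G_{data}$.

Because no patient records ship with the package, a synthetic generator
(`cgm_scenario()` / `generate_cgm()`) produces two-week CGM records with
full ground truth (dense trajectory, insulin, $R_a$, meals) for validating
every step, plus canonical one-day fixtures (`reference_day()`).

## Worked example

Personalize the model on a synthetic day with one liquid meal (amplitude
50 at minute 450), starting the search from a bundle displaced ~30% from
the truth:

```r
library(cgmpulse)
library(dplyr)

p <- reference_parameters("non_diabetic")
fasting_steady_state(p)
#> # A tibble: 1 × 2
#>   G_star I_star
#>    <dbl>  <dbl>
#> 1   71.2   9.32
```

The bundle rests near 71 mg/dl glucose and 9.3 µU/ml insulin — a little
below its laboratory fasting anchors (90, 12.4), as expected of an
overnight resting point.

```r
tb <- generate_cgm(
  cgm_scenario(p,
    tibble(clock_min = 450, amplitude = 50, meal_class = "liquid"),
    n_days = 1, noise_cv = 0, grid_step = 1),
  seed = 1)
seg <- filter(as_tibble(tb$cgm_true), time_min >= 300, time_min <= 900)
seg <- cgm_series(seg$time_min, seg$glucose, source = "synthetic")

start <- cgm_parameters(
  R0 = p$R0, EG0 = p$EG0, SI = p$SI * 1.3, alpha = p$alpha,
  Imax = p$Imax * 0.8, ksto = p$ksto * 1.3,
  kgut_liquid = p$kgut_liquid * 0.77, kgut_mixed = p$kgut_mixed,
  Gss = p$Gss, Iss = p$Iss)

fit <- fit_segment(seg, meal_events(450, 80, "liquid"), start,
  free = c("SI", "Imax", "ksto", "kgut_liquid"),
  bounds_factor = 2, seed = 1)
fit
#> <cgm_fit> cost 1.347e-05 (from 2713), 1892 evaluations, converged: TRUE
#> Fitted parameters:
#> # A tibble: 12 × 3
#>    term           estimate fixed
#>  3 SI              0.00306 FALSE
#>  5 Imax            0.280   FALSE
#>  6 ksto            0.0360  FALSE
#>  7 kgut_liquid     0.0981  FALSE
#> 12 amp_1          50.0     FALSE
#> # (fixed rows omitted)
```

The cost falls from 2713 to 1.3e-5 (mg/dl)² and every free parameter —
including the unknown meal size — is recovered to within a fraction of a
percent ($S_I = 0.00306$, $I_{max} = 0.280$, $k_{sto} = 0.036$,
$k_{gut,l} = 0.098$, amplitude 50.0). `tidy()` and `glance()` return the
same information as tibbles; `autoplot(fit)` overlays the fitted
simulation on the data.

Reconstruct insulin and the meal's rate of appearance from glucose alone:

```r
obs <- insulin_observer(tb$cgm_true, p)   # needs no meal information
ra  <- ra_observer(tb$cgm_true, obs, p)
keep <- !obs$in_transient & !ra$edge      # mask the observer transient
t <- ra$time_min[keep]; r <- ra$ra[keep]
sum(diff(t) * (head(r, -1) + tail(r, -1)) / 2)
#> [1] 53.2
```

The integrated rate of appearance returns the 50-unit meal (the ~3-unit
excess is the tail of the observer's initialization transient decaying at
rate $k_I$).

Finally, the circadian structure of a two-week record:

```r
sc <- cgm_scenario(p,
  tibble(clock_min = c(450, 780, 1200), amplitude = c(60, 150, 250),
         meal_class = c("liquid", "mixed", "mixed")),
  n_days = 14, noise_cv = 0.05, grid_step = 15)
spec <- psd_glucose(generate_cgm(sc, seed = 1)$cgm)
dominant_period(spec)
#> # A tibble: 1 × 6
#>   period_hours frequency_per_min  power uncertainty_hours prominence prominent
#>          <dbl>             <dbl>  <dbl>             <dbl>      <dbl> <lgl>
#> 1           24          0.000694 92713.             0.858       278. TRUE
```

The dominant spectral peak sits at a period of 24 hours — the rhythm of
the meal schedule — with the honest uncertainty of one frequency bin.

A thin command-line wrapper over these functions ships in
`inst/cli/cgmpulse-cli.R` (subcommands `generate`, `simulate`, `fit`,
`observe`, `ra`, `spectrum`; every run writes a JSON manifest with input
hashes and the seed).

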