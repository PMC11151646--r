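---
title: "Population-based threshold models for seed germination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-based threshold models for seed germination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germtime)
```

## The models

Seed lots do not germinate all at once. Population-based threshold
models explain the spread with a simple idea: every seed accumulates
"physiological time" at a rate set by its environment, and germinates
when its personal threshold is reached. `germtime` implements the three
classical members of this family for a lot incubated at temperature
$T$ (°C) on a medium of water potential $\psi$ (MPa, $\le 0$; in
practice imposed with PEG-6000):

* **Thermal time.** Below the optimum temperature the fraction $g$ of
  the lot germinates when $(T - T_b)\,t_g$ reaches $\theta_{T1}$;
  above it, when $(T_c - T)\,t_g$ reaches $\theta_{T2}$. $T_b$ and
  $T_c$ are the base and ceiling cardinal temperatures — no
  germination outside $(T_b, T_c)$ — and the germination rate
  $GR(g) = 1/t_g$ is linear in $T$ on each side, which is how the
  cardinal temperatures are estimated.
* **Hydrotime.** At fixed $T$, fraction $g$ germinates when
  $(\psi - \psi_b(g))\,t_g$ reaches the lot constant $\theta_H$
  (MPa h). The threshold (base) water potential $\psi_b$ varies among
  seeds.
* **Hydrothermal time.** Both factors multiply:
  $\theta_{HT} = (\psi - \psi_b)(T - T_b)\,t_g$ (MPa °C h), for
  sub-optimal temperatures $T \le T_o$.

The single distributional assumption is that base water potentials are
Gaussian across the lot, $\psi_b \sim N(\psi_{b(50)},
\sigma_{\psi b})$. The cumulative germinated fraction then lies on a
probit surface,

$$\mathrm{probit}(g) \;=\;
  \frac{\psi - \theta_{HT}/\big((T-T_b)\,t_g\big) - \psi_{b(50)}}
       {\sigma_{\psi b}},$$

which `predict_fraction()` evaluates with the standard normal CDF
(`probit(g)` is plainly $\Phi^{-1}(g)$ here, with no historical +5
offset) and `predict_time()` inverts in closed form. Above the optimum
temperature the standard extension shifts the median threshold,
$\psi_{b(50)}(T) = \psi_{b(50)} + k_T\,(T - T_o)$, while thermal time
stops accumulating beyond $T_o$ (width $T_o - T_b$). The shift slope
$k_T$ (MPa/°C) is optional: when it is not supplied the model simply
declines to predict above $T_o$, because extrapolating the
supra-optimal branch without it would be invention.

## From counts to percentiles

Input data are cumulative counts per dish at scheduled observation
times (hours since imbibition; daily data are converted on ingest).
Germination times of percentiles, $t(g)$, are obtained by linear
interpolation of the cumulative fraction against time, starting from
the implicit origin at $t = 0$. Linear interpolation is the standard
choice in germination analysis; on flat segments the earliest time is
returned, and a percentile above the final fraction of a dish is
reported as unreachable rather than extrapolated. Fractions use seeds
sown as the denominator, with no viability correction — this matches
the usual definition of germination percentage, and the Gaussian
threshold model itself accounts for the seeds that never germinate at
a given $\psi$.

Replicate dishes of a treatment are pooled by summing counts and seeds
sown (fractions are thereby weighted by dish size). Percentiles can
also be taken per dish; pooling is the default because 10-seed dishes
make per-dish percentiles very coarse (each seed is 10 percentage
points).

## The repeated probit regression

$\theta_H$ (or $\theta_{HT}$) cannot be estimated by one regression
because it sits inside the predictor. The estimator is the classical
repeated-probit scheme: for a candidate $\theta$, form
$x = \psi - \theta/t_g$ (hydrotime) or
$x = \psi - \theta/\big((T - T_b)\,t_g\big)$ (hydrothermal) for every
percentile observation, regress $\Phi^{-1}(g)$ on $x$ by ordinary
least squares, and score the candidate by $R^2$. The winning line
yields $\psi_{b(50)} = -\mathrm{intercept}/\mathrm{slope}$ and
$\sigma_{\psi b} = 1/\mathrm{slope}$, and is reported with the usual
regression statistics ($R^2$, residual SE, the slope $t$ and its
two-sided $p$, and $F = t^2$; these are internally consistent by
construction).

Numerical choices, all deterministic:

* **Percentiles.** Deciles $\{0.1, \dots, 0.9\}$ intersected with what
  each treatment actually reaches. A single percentile per treatment
  would leave the population spread unidentified; multiple percentiles
  per treatment is standard repeated-probit practice. Fractions of
  exactly 0 or 1 never enter probit space.
* **Search.** A 64-point log-spaced grid on $[1, 10^5]$ (natural
  units), then golden-section refinement in the bracketing interval to
  a relative tolerance of $10^{-4}$, ties broken toward smaller
  $\theta$. $R^2(\theta)$ is smooth and, in every dataset we generate,
  unimodal over the bracket; the test suite nevertheless checks the
  optimizer against exhaustive enumeration rather than trusting that.
* **Base temperature.** Either fixed by the caller or profiled: a
  0.5 °C grid from 0 up to just below the coldest sub-optimal
  treatment, each candidate scored by its own 1-D $\theta$ search,
  then golden-section refinement of the profile.
* **Sub/supra split.** Treatments warmer than $T_o$ are excluded from
  the core hydrothermal fit (the model is stated for $T \le T_o$);
  $T_o$ defaults to the temperature with the fastest median
  germination. $k_T$ is estimated afterwards, if at least two
  supra-optimal temperatures have usable median times, by back-solving
  $\psi_{b(50)}(T)$ from those times and regressing on $T - T_o$.
* **Weighting.** Unweighted OLS in probit space. A seed-count
  weighting could be argued for, but the bench designs this package
  targets are balanced, where it changes nothing.

Cardinal temperatures come from the two-branch linear regression of
$GR(50)$ on $T$: $T_b$ and $T_c$ are the x-intercepts of the rising
and falling branches, $T_o$ their intersection, and
$\theta_{T1} = 1/\mathrm{slope}_{sub}$,
$\theta_{T2} = -1/\mathrm{slope}_{supra}$. A branch with fewer than
two temperatures is reported absent rather than guessed.

## The synthetic-experiment generator

`simulate_experiment()` draws each seed's $\psi_b$ from
$N(\psi_{b(50)}, \sigma_{\psi b})$, computes its exact germination
time from the hydrothermal law, and then *censors* it to the scoring
schedule: fitting only ever sees cumulative counts at scheduled times,
exactly as a technician scoring dishes would record them. The default
design is the standard osmotic-stress bench layout: 6 temperatures
(15–40 °C) × 5 water potentials (0 to −1.2 MPa) × 3 replicate dishes
of 10 seeds, scored daily for 14 days. The default truth used in the
recovery studies is $\theta_{HT} = 1500$ MPa °C h, $T_b = 10$ °C,
$\psi_{b(50)} = -1.2$ MPa, $\sigma_{\psi b} = 0.19$ MPa, $T_o =
35$ °C — a parameter set typical of a fast-germinating legume lot.

The generator reproduces the model's own law (the test suite checks
the empirical CDF of a $10^4$-seed dish against `predict_fraction()`
to a Kolmogorov–Smirnov distance below 0.02) and distinguishes, in its
optional truth records, seeds that are non-viable from seeds whose
threshold simply exceeds the medium's potential — observationally
identical, mechanistically different. What it deliberately does *not*
emulate: dormancy loss or induction, seed-to-seed variation in
$\theta_{HT}$ itself, dish position effects, fungal losses, or scoring
mistakes. Passing recovery tests therefore show that the estimator
inverts the assumed law faithfully, not that real seed lots obey it.

### What interval censoring does to the estimates

One generator finding is worth stating plainly: with daily scoring and
linear interpolation, percentile times carry a small systematic error
(the cumulative curve is convex early and concave late), which
propagates into a $\psi_{b(50)}$ offset of roughly 0.03 MPa and a few
percent on $\theta_{HT}$ — regardless of how many seeds are in the
dish. This is a property of daily germination data in general, not of
this implementation. Consequently the noise-free recovery studies
score on a 4–6-hourly schedule, where the recovery is essentially
exact ($\theta_{HT}$ to ±0.2 %, $\psi_{b(50)}$ and $\sigma_{\psi b}$
to ±0.005 MPa at $10^4$ seeds per dish), while the bench-design study
(10 seeds × 3 dishes, daily) keeps the realistic schedule and absorbs
the censoring offset into its ±0.15 MPa recovery band. Test problem
sizes — $10^4$ seeds for law checks and noise-free recovery, 20 seeded
runs for the bench design, 1000-case property sweeps for the index
identities — were chosen so each check is decisively more precise than
the tolerance it asserts.

## Germination indices

The classical descriptive indices are computed from daily incremental
counts (hourly schedules are resampled through the step function at
24 h marks): germination percentage and energy, mean germination time
and its reciprocal rate, the weighted germination index (weights
$D - j + 1$ on day $j$, generalizing the traditional 10-day weights to
any assay length $D$), the germination rate index, the Timson index,
two seedling-vigor indices, and moisture content. Two readings of the
Timson index circulate; the default here averages *cumulative* daily
percentages over the assay (the common reading), and the incremental
reading — which collapses to $G\%/D$ — is available via
`mode = "incremental"`. Undefined values (a mean germination time with
zero germination) are `NA`, never 0: a dish that never germinated is
slow in no meaningful amount.

## A worked run

```{r, eval = FALSE}
truth <- htt_params(theta_HT = 1500, Tb = 10, psi_b50 = -1.2,
                    sigma_psib = 0.19, To = 35)
ds <- simulate_experiment(truth, simulation_design(), seed = 101)
fit <- fit_htt(ds, Tb = 10)
fit$params           # theta_HT, psi_b50, sigma_psib recovered
germination_indices(ds)[1:4, ]
```

## Known limitations

* The probit surface assumes a *common* $\theta_{HT}$ with all
  seed-to-seed variation in $\psi_b$; lots with rate variation will
  show lack of fit that the $R^2$ honestly reports but the model
  cannot absorb.
* $k_T$ estimation rests on median times at supra-optimal
  temperatures only, and is absent (not zero) when fewer than two such
  temperatures germinate to 50 %.
* Percentile extraction interpolates linearly; with coarse (daily)
  scoring this bounds the achievable accuracy of any downstream
  estimate, as quantified above. Score more often than the fastest
  treatment's spread if parameter precision matters.
* No dormancy, priming or after-ripening extensions are provided.
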