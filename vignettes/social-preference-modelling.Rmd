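---
title: "Modelling costly punishment and prefrontal hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling costly punishment and prefrontal hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroequity)
```

## The task and its economics

`neuroequity` analyses a norm-compliance variant of the ultimatum game. Both
players start with 30 points; the proposer additionally receives 100 points
and transfers 0, 10, 20, 30, 40 or 50 of them to the responder. The responder
may then spend up to 30 points of their own endowment on punishment; every
point spent removes five points from the proposer (floored at zero). Final
payoffs classify each trial as advantageous inequality (AI: responder ahead),
equality (E) or disadvantageous inequality (DI: responder behind). After a
transfer of 20 the proposer holds 110 points against the responder's 50, and
exactly 22 punishment points drive the proposer to zero:

```{r task}
compute_payoffs(20, 0)
min_punishment_to_zero(20)
```

## The competing utility models

Nine models map a trial's post-punishment payoffs (and optionally its
response time) to a scalar utility. The central pair is the Fehr--Schmidt
inequity-aversion form

$$U = P \cdot X_r - \alpha \max(X_p - X_r, 0) - \beta \max(X_r - X_p, 0),$$

fitted once without constraints (allowing AI *seeking*, $\beta < 0$) and once
under the classical constraints $\alpha \ge \beta$, $0 \le \beta < 1$.
Component models (total reward, reward difference, proposer reward, linear
combination), the Charness--Rabin efficiency/reciprocity model (with
misbehavior defined as any transfer below 50), and two response-time-aware
variants (the RT-enhanced Fehr--Schmidt model, subtracting $P_{RT}\cdot RT$,
and an RT-only model) complete the set. All models are linear in their
parameters, which the fitting layer exploits: every model is represented by
a design matrix plus (for Charness--Rabin) a fixed offset $X_r$.

Following the printed equations, no model contains an intercept. This is a
consequential choice: the RT regressor, whose deterministic component is
bounded away from zero, partly plays the role of the missing intercept in
model comparisons, and the Charness--Rabin model predicts exactly $X_r$ on
equal-payoff trials with no free scale, which inflates its residuals on
standardized data. Both effects are properties of the published equations
that we reproduce rather than repair.

## Fitting

Behavioral fits regress each participant's punishment amounts, rescaled to
$[-1, 1]$ by min--max standardization, on the model's design by nonlinear
least squares with 20 seeded uniform start locations (ranges $[-2, 2]$ for
inequity and reciprocity weights, $[-1, 1]$ for reward and RT weights;
optimizer tolerance $10^{-10}$). For the linear-in-parameters models this
agrees with the closed-form least-squares solution to $10^{-10}$ in residual
sum of squares, and the closed form is available as a fast path. The
constrained Fehr--Schmidt model is optimized under box bounds through the
reparameterization $\alpha = \beta + \delta$, $\delta \ge 0$,
$\beta \in [0, 1 - 10^{-6}]$.

Agents that always punish to the proposer-zero point make the DI regressor
identically zero and the AI regressor collinear with own payoff; aliased
coefficients are set to zero by pivoting so that every fit is defined.

Neural fits use iteratively reweighted least squares with the fair weight
function $w(r) = 1/(1 + |r/(c\,s)|)$, $c = 1.3998$, robust scale
$s = \mathrm{MAD}/0.6745$, at most 50 iterations and coefficient tolerance
$10^{-8}$. Each regression's dependent variable -- the mean total-hemoglobin
change of one channel (or region) in one sliding window -- is standardized
to $[-1, 1]$ across trials, exactly as the punishment vector is per
participant. We standardize per window rather than per whole channel: with
a single scale per channel, quiet baseline windows have tiny absolute
residuals and mechanically win any AIC comparison, whereas the per-window
scale makes the AIC-by-window profile reflect how much of each window's
variance the model explains, peaking where the hemodynamic response peaks.
The constrained Fehr--Schmidt model is not fitted to neural data.

## Model comparison

Fits are compared by the least-squares information criterion
$\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2(k + 1)$, counting the residual
variance as a fitted parameter; the same formula is used in both domains so
orderings are comparable. MSEs are additionally compared by one-way ANOVA
with Bonferroni-corrected pairwise tests against a null model that draws
uniform$(-1, 1)$ responses (expected MSE $1/3$ against centered data).
Nested models are tested by the F statistic
$F = [(\mathrm{RSS}_r - \mathrm{RSS}_f)/df_1]\,/\,[\mathrm{RSS}_f/(n-k_f)]$;
nesting is decided by regressor-span inclusion on a probe grid of trials, so
it is insensitive to sign conventions.

A subtlety of F-test calibration: simply switching the generating RT weight
off does **not** make the test's null hypothesis true, because the response
time still varies with transfer and outcome inequality and therefore proxies
residual structure (and any physical, positive-mean RT also supplies the
missing intercept). `nested_f_calibration()` therefore holds a realized
design fixed and simulates responses from the fitted reduced model plus
Gaussian noise -- the reduced model is then literally true, and the measured
rejection rate at the 5% level sits near nominal.

## The synthetic cohort

The generator replaces data collection. Each agent holds RT-enhanced
Fehr--Schmidt preferences and chooses punishment by softmax (temperature
$\tau = 0.1$ utility units) over the utilities of all 31 admissible
punishments; the anticipated deterministic response time of each candidate
outcome (slower for unequal outcomes) enters the utility, so deliberation
cost is genuinely generative. Response times follow an inverted U over
transfers (base 1.5 s, peak 4 s at transfer 20, width 15 points, +0.3 s on
unequal outcomes, Gaussian jitter 0.35 s, clipped to the 7 s window).

Cohort preferences lie on a latent social-attentiveness continuum:
$\alpha$ spans $[-0.033, 0.153]$, and only attentive agents
($\alpha \ge 0.03$) draw a substantive AI-seeking weight
$\beta \sim U[-1, -0.1]$, the remainder being near-AI-neutral
($\beta \sim U[-0.03, 0]$); the own-reward weight is
$P \sim U[0.04, 0.06]$. Because the utility is piecewise linear in
punishment, optimal choices are corner solutions (accept, punish to
equality, punish to the proposer-zero point), and this structure is what
makes the cohort reproduce the study-level regularities: mean punishment
decreasing in transfer, AI-creating trials punished most, equality trials
next, a punishment rate near 0.9, and response times slowest at intermediate
transfers. Weak low-$\alpha$/mid-$\beta$ agents would accept the most unfair
transfer yet punish milder ones (the proposer-zero point is cheapest to
reach, relative to its AI benefit, at high transfers); restricting strong AI
seeking to attentive agents removes that inversion.

Hemodynamics are simulated forward: per trial, an amplitude proportional to
the standardized generating utility is placed at the transfer onset and
convolved with a canonical double-gamma HRF (peak 6 s -- mid-range of the
5--7 s prefrontal peaks -- undershoot at 15 s, ratio 1/6). Oxygenated
hemoglobin carries the response; deoxygenated hemoglobin is $-1/3$ of it.
Concentrations map to 760/850 nm optical densities through the forward
modified Beer--Lambert law with absorption coefficients 1486/2526 (O2Hb)
and 3843/1798 (HHb), pathlength factors 7.25/6.38 and a 30 mm
source--detector distance; linear drift, a 1 Hz cardiac sinusoid and white
noise (s.d. 2 OD units) are added, and a 60 s event-free baseline precedes
the first trial. dlPFC channels (1--8) couple to utility with gain
$5\times10^{-6}$; dmPFC channels (9--16) couple with half that gain, 1.5
times the noise, and track an even mixture of utility and choice difficulty
(standardized RT), reflecting that region's stronger association with
conflict monitoring than with social valuation. The gains are calibrated
only so that window-level fits are informative at the stated noise (dlPFC
window SNR near 7, dmPFC near 2); no printed effect size constrains them.
With a pure gain difference the region comparison is uninformative: both
regions' fitted-utility series live in the span of the same four
regressors, whose dominant direction aligns with the behavioral fit almost
regardless of the coefficients, so even a noise-only region "predicts" well.
The difficulty admixture is what gives the dlPFC its genuine advantage.

What the generator does **not** emulate: motion artifacts (beyond the
optional MAD despiker's test cases), scalp physiology and superficial-layer
contamination, proposer behavior (transfers are a fixed balanced schedule),
session-level nonstationarity, and any coupling between decision noise and
hemodynamic noise. Passing tests therefore demonstrate the correctness and
calibration of the analysis machinery on data with the assumed structure,
not that real prefrontal signals obey these models.

## Known limitations

The fitting procedure regresses standardized punishment on post-punishment
payoffs, which are deterministic functions of the punishment itself; the
identity $p = (160 - 2X_r - \mathrm{DI} + \mathrm{AI})/6$ holds on every
trial of the default task. The fitted coefficients therefore describe the
participant's punishment *profile*, not the weights of an underlying choice
process: in the noiseless limit the punish-to-equality profile has
DI = AI = 0 on every trial and the punish-to-zero profile has
$X_p \equiv 0$, leaving $\hat\alpha$ and $\hat\beta$ aliased or mechanically
tied to the punishment range. Simulation shows the consequence plainly:
rank correlations between generating softmax-utility weights and fitted
regression coefficients across agents are near zero or negative across the
entire plausible noise range. Users should read the fitted $\hat\alpha$,
$\hat\beta$ as descriptive preference indices (their group-level contrasts
-- $\hat\alpha > \hat\beta$, prevalence of $\hat\beta < 0$ -- are
meaningful) and not as estimates of generative decision parameters.

The window grid is 40 windows of 2.5 s stepped by 0.18 s; the final window
therefore starts 7.02 s after transfer onset and the grid spans 9.52 s of
response. The grid is configurable where a longer span is wanted.

## Problem sizes

The shipped tests run the behavioral analyses on cohorts of 24--48 agents of
60 trials and the fNIRS analyses on 6--48 agents (the region-prediction
comparison at the study's own sample size of 48), with replicate studies of
20 cohorts and 500-draw calibration of the F-test; the demo pipeline
(`run_pipeline(run_config(n_participants = 8))`) completes in well under a
minute on a laptop. All randomness descends from explicit integer seeds, and
identical configurations reproduce byte-identical artifacts.
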