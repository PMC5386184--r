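---
title: "Temporal expert advice: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal expert advice: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teacast)
```

## The problem

A clinician following a patient after prostate surgery sees a handful of PSA
(prostate-specific antigen) measurements and must judge where the marker is
heading. Three or six points are far too few to fit a dynamical model of the
tumour outright, but the clinician is not starting from zero: previous
patients' trajectories carry transferable information. `teacast` formalises
this as *online prediction with expert advice*: a pool of reference
predictors (the **experts** — past series, or model simulations conditioned
on past patients' parameters) each advise a value for the next step, and a
forecaster aggregates the advice with weights that reflect each expert's
loss history on the target so far.

The same machinery applies to any short, unstable scalar series; the package
ships chaotic-map generators (Hénon, Ikeda) as a fully controlled test bed.

## The forecasters

Let $f_{i,t}$ be expert $i$'s advice at step $t$, $y_t$ the observation, and
$l(\cdot,\cdot)$ a convex loss (absolute error by default). All three
variants accumulate coefficient-weighted losses
$L_{i,t} = \sum_{k\le t} a_k(t)\, l(f_{i,k}, y_k)$, weight the experts as
$w_{i,t} \propto \exp(-\eta L_{i,t})$, and predict the convex combination
$p_{t+q} = \sum_i w_{i,t} f_{i,t+q}$:

* **standard** — $a_k(t) = 1$: the classical exponentially weighted average
  forecaster;
* **temporal** (`"tea"`) — $a_k(t) = \lambda^{k-1}$ (or $\lambda^k$),
  $\lambda > 1$: losses suffered recently dominate, which is what unstable
  dynamics demand — on a chaotic orbit or a rising tumour marker, agreement
  long ago says little about agreement now;
* **discounted** (`"cz"`) — $a_k(t) = \rho^{t-k-1}$, $0<\rho<1$: the
  Chernov–Zhdanov discount, implemented incrementally as
  $L \leftarrow \rho L + \rho^{-1} l_t$.

The two recency conventions are algebraically linked: with
$\lambda = \rho^{-1}$ and $a_k = \lambda^k$, the discounted losses are
exactly $\rho^{\,t-1}$ times the temporal ones, so the temporal weights
equal the discounted weights raised to the power $\rho^{-(t-1)} \ge 1$ and
renormalised — the temporal forecaster concentrates *harder* on currently
reliable experts. The $\lambda^{k-1}$ convention is used for the regret
bounds and the map experiments; $\lambda^k$ is the natural choice when the
learning series is very short (the PSA route), and both are exposed via
`tea_exponent`.

Numerically, weights live in the log domain and only loss *differences*
enter the exponentials (the minimum accumulated loss is subtracted before
exponentiation), since $\eta\,\lambda^{t-1}\,l$ overflows naive
exponentials long before the coefficients themselves overflow; a coefficient
that is no longer representable raises an error that names the offending
step. Temporal weighting with $\lambda = 1$ reproduces the standard
forecaster bit for bit, which the test suite asserts.

Experts built from finite windows stop advising when their window ends;
they are excluded from the prediction sum and the surviving weights are
renormalised, preserving the convex-combination contract. It is an error if
no expert survives.

## Regret bounds

Performance is measured by regret — the forecaster's accumulated loss minus
the best single expert's — in the *same* coefficient weighting. A Hoeffding
argument gives the two-term bound
$\ln(N)/\eta + \eta\,\varepsilon^2 S / 8$ with
$S = \sum_k a_k(t)^2$ and $\varepsilon$ the loss range, minimised at
$\eta^* = \sqrt{8\ln N / (\varepsilon^2 S)}$ with minimum
$B^* = \varepsilon\sqrt{S \ln N / 2}$. For the temporal scheme
$S = (\lambda^{2t}-1)/(\lambda^2-1)$, recovering
$\varepsilon\sqrt{(t/2)\ln N}$ as $\lambda \to 1$; for the discount,
$S = \rho^{-2}(1-\rho^{2t})/(1-\rho^2)$. The closed forms are guarded by a
test that minimises the two-term bound numerically on a parameter grid
(relative agreement $10^{-6}$), so any transcription error would surface
rather than be silently absorbed.

The temporal bound grows like $\lambda^t$ — an artefact of the exponential
loss scale. Multiplying by $\rho^{\,t-1}$ (with $\lambda=\rho^{-1}$) brings
it onto the discounted scale, where it simplifies to
$\varepsilon\sqrt{(1-\rho^{2t})\ln N / (2(1-\rho^2))}$ — exactly $\rho$
times the discounted bound, hence strictly smaller for every
$0 < \rho < 1$ and converging to it (and to the standard bound) as
$\rho \to 1$. `bound_comparison()` checks the inequality numerically; the
suite sweeps it over a grid and a thousand random draws.

These bounds assume losses inside an interval of width $\varepsilon$.
$\varepsilon$ is configuration, not estimation: it defaults to 1 and is
*not* inferred from data, because in the clinical application the absolute
PSA error is unbounded in principle; losses exceeding $\varepsilon$ warn
rather than stop.

## Choosing the learning rate

The package default `eta = "auto"` resolves to the constant bound-optimal
$\eta^*(N, T, \varepsilon, \lambda)$ for the run length $T$. For strongly
decaying coefficients this constant is tiny ($\eta^* \sim \lambda^{-T}$),
so early in the run the temporal forecaster is nearly uniform and wastes
the learning phase. `eta = "auto_t"` therefore re-evaluates the
bound-optimal rate at every step $t$ — the usual time-varying schedule for
anytime operation. The chaotic-map comparison below applies the schedule to
*every* forecaster being compared, so no method gains an unfair tuning
advantage. The regret-bound guarantee is stated for the constant $\eta^*$;
the schedule is a forecasting choice, not a bound claim.

For the short-series (PSA) route, the decay rate is data-driven:
`select_lambda()` trains on the first $K-1$ learning points, predicts the
$K$-th, and picks the $\lambda$ minimising that final absolute error over a
grid of 100 equally spaced candidates strictly inside $(1, 2)$ — the range
that gives better predictions for these series — breaking ties toward the
smallest candidate (mildest decay).

## Distribution prediction

Each expert's advice is taken as disturbed by Gaussian error, so the
predictive distribution is the weighted mixture
$\sum_i w_{i,t}\, \mathcal N(f_{i,t+q}, \sigma^2)$; its mean equals the
point prediction. Quantiles $u_t(Q)$ solve mixture-CDF$(u) = Q$ by bracket
expansion plus bisection, tight enough that the CDF identity holds to about
$10^{-8}$; the seven reporting levels are
$Q \in \{0.975, 0.875, 0.75, 0.65, 0.60, 0.55, 0.525\}$, the upper half of
the distribution, because *under*-predicting a rising tumour marker is the
clinically costly direction.

Two $\sigma$ estimators are provided. `"final_point"` is the absolute error
at the last learning point. `"psa_learning_mean"` is the mean absolute
error between the mixture median and the observation over the learning
period; since the median itself depends on $\sigma$, a provisional value
from the final-point rule is used and refined once. A floor
(`sigma_min`, default $10^{-6}$) prevents a degenerate zero-width mixture
when the learning error is exactly zero. Proper behaviour at the floor
matters more than its value: any strictly positive floor leaves quantile
calibration intact.

## The prostate-cancer model and model-based experts

The cell-population model has three compartments: androgen-dependent cells
$x_1$, reversibly androgen-independent cells $x_2$, and irreversibly
independent cells $x_3$; a PSA measurement is $x_1+x_2+x_3$. During hormone
therapy $x_1$ converts toward $x_2$ and $x_3$ (six rates $d_1..d_6$); off
therapy $x_2$ may revert to $x_1$ while $x_3$ cannot (four rates
$e_1..e_4$):

$$\text{on: } \dot x_1 = d_1 x_1,\quad \dot x_2 = d_2 x_1 + d_3 x_2,\quad
\dot x_3 = d_4 x_1 + d_5 x_2 + d_6 x_3$$
$$\text{off: } \dot x_1 = e_1 x_1 + e_2 x_2,\quad \dot x_2 = e_3 x_2,\quad
\dot x_3 = e_4 x_3$$

This is the only triangular placement consistent with a 6/4 parameter split
and the biology (irreversibility of $x_3$). Time is continuous, in days;
measurement times are arbitrary reals, matching irregular clinical
sampling. Each linear piece is integrated by matrix exponential — exact for
linear systems — and cross-checked in the tests against an adaptive ODE
integrator. Only the off-treatment phase is exercised in the analyses here
(post-operative follow-up), needing 4 rates plus 3 initial conditions.

Model-based experts import the ten rates from each previous patient and fit
only the initial state to the target's first $K \ge 3$ observations (three
state dimensions force $K \ge 3$), minimising summed absolute discrepancy
plus the penalty $h(x) = 10^{15}(1-x)$ for any negative state entry,
applied at every evaluated time and at $t=0$ — effectively a hard
nonnegativity constraint. The optimiser is a derivative-free simplex search
with 20 seed-controlled multi-starts drawn from $[0, y_1]^3$. Two numerical
hardenings proved necessary: the simplex is restarted from its own solution
until it stops improving (it stalls on the kinks of the absolute-error
cost, which is convex but nonsmooth), and one start is the least-squares
solution — PSA at the learning times is *linear* in the initial state, so
this closed-form start is exact whenever a perfect fit exists. A parameter
set whose fit fails is skipped with a warning; the panel shrinks rather
than the pipeline aborting.

## Synthetic study conditions

No patient recordings (nor the violin/squid-axon series) ship with the
package; seed-controlled generators emulate the study conditions instead.

`toy_database()` reproduces the chaotic-map conditions: Hénon parameters
uniform on $a \in [1.3, 1.4]$, $b \in [0.1, 0.2]$, initial conditions on
$[-0.02, 0.02]^2$, a 1000-step discarded transient, observable $x + y$, and
$M$ parameter sets $\times$ $S$ initial conditions as experts (the target
uses $a = 1.35, b = 0.15$, a chaotic regime). Diverging orbits are redrawn
with a warning. The scaled-down experiment in the acceptance suite uses
$M = 20 \times S = 50$ experts and length-50 targets — sizes chosen so the
whole suite runs on a laptop core in minutes while preserving the
qualitative regime (hundreds of experts, short targets).

`synthetic_cohort()` emulates an off-treatment PSA cohort: self-rates
$e_1, e_3, e_4$ uniform on $[-0.1, 0.1]$/day with at least one positive
growth mode per patient (the clinically interesting mixed regime), the
$x_2 \to x_1$ reversion coupling $e_2$ on $[0, 0.1]$/day — a transfer rate
must be nonnegative, which also keeps the state orthant invariant —
irregular visit gaps uniform on 2–6 days, initial compartments on
$[0.5, 5]$ (PSA-equivalent units), and additive Gaussian observation noise
clipped at zero, consistent with the Gaussian error kernel of the
distribution predictor. These are synthetic conditions, not estimates from
any dataset: passing tests show the pipeline recovers what it planted under
its own model, not that the model is adequate for real patients.

## What the tests establish

* Hand-traceable updates: two-expert, three-step traces match a literal
  application of the update formulas; the discounted recursion matches the
  direct discounted sum.
* Regret: over random instances with losses in $[0,1]$ and $\eta = \eta^*$,
  the observed exponential regret never exceeded the optimal bound; the
  closed forms agree with numeric minimisation; the normalised-bound
  inequality held on every grid cell and random draw.
* Calibration: mixture CDF∘quantile identity to $10^{-8}$; on a 200-subject
  synthetic cohort whose next observations are drawn from their own
  predictive mixtures, coverage sits within $\pm 0.05$ of each of the seven
  $Q$ levels. Coverage proportions are averaged over 5 seeded draw
  replicates: with a single draw per subject the per-level binomial noise
  (sd $\approx 0.035$) makes a $\pm 0.05$ check fail for roughly a third of
  seeds even though calibration is exact by construction; averaging reduces
  only that Monte Carlo noise, not any real miscalibration.
* Recovery: on noise-free cohorts the generating parameter row took the top
  weight in 100% of 50 replicates, and refitting a noise-free trajectory
  recovers its initial state to cost $< 10^{-6}$.
* Chaotic-map comparison: with both forecasters under the per-step optimal
  rate, the temporal forecaster's accumulated absolute error was at most
  the standard forecaster's in 20 of 20 seeded replicates.

## A worked miniature

```{r example}
set.seed(42)
# experts run 5 steps past the target so the fit can look ahead
td <- toy_database("henon", M = 10, S = 20, n = 45, seed = 42)
target <- henon_series(a = 1.35, b = 0.15, x0 = 0.01, y0 = -0.01, n = 40)
fit <- tea(target, td$panel, variant = "tea", lambda = 1/0.9,
           eta = "auto_t", burn_in = 10)
summary(fit)
predict(fit, q = 1)
predict(fit, q = 1, type = "quantile", sigma = 0.2,
        probs = c(0.525, 0.75, 0.975))
```

## Known limitations

* No specialist/sleeping-expert or tracking variants; losses are absolute
  or squared only; error kernels are homoscedastic Gaussian.
* The regret bounds assume losses within $[0, \varepsilon]$ and the constant
  $\eta^*$; no anytime or high-probability bounds are provided.
* Treatment scheduling is user-supplied; the package does not optimise
  on/off switching policies.
* The synthetic cohort shares the forecaster's own noise model, so its
  calibration results are a consistency check, not clinical validation;
  real PSA series bring model misspecification the generator cannot emulate.
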