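---
title: "Modelling the radiotherapy / NK-cell evolutionary double bind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the radiotherapy / NK-cell evolutionary double bind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nkbind)
```

## The scientific problem

An *evolutionary double bind* is a two-treatment strategy in which
adapting to the first therapy makes cells more vulnerable to the
second. The motivating system is prostate cancer: a radiation-resistant
line (derived by fractionated irradiation) up-regulates stress ligands
that natural-killer (NK) cells recognise, so NK cells preferentially
kill exactly the cells that escape radiotherapy. `nkbind` provides the
quantitative machinery for this question: a mechanistic model of mixed
cultures of radiation-sensitive (S) and radiation-resistant (R) tumour
cells challenged with NK cells (N), a synthetic-data generator that
emulates the co-culture imaging assay, a staged fitting pipeline that
turns growth curves into interpretable parameters, diagnostics that
decide whether a double bind is present, and a reduced model for
reasoning about treatment design.

## The full model

Abundances are in units of $10^5$ cells and time in hours (the assay
images every 6 h; rates are therefore per hour). The three populations
follow a Lotka–Volterra competition system with logistic NK growth:

$$
\begin{aligned}
\frac{dS}{dt} &= r_S S \left(1 - \frac{S + \alpha_{SR} R}{K_S}\right)
  - \lambda_{SN} S N \\
\frac{dR}{dt} &= r_R R \left(1 - \frac{R + \alpha_{RS} S}{K_R}\right)
  - \lambda_{RN} R N \\
\frac{dN}{dt} &= r_N N \left(1 - \frac{N}{K_N}\right)
\end{aligned}
$$

$r_i$ are intrinsic growth rates (bounded $[0,1]$ /h), $K_i$ carrying
capacities (bounded $(0,10]$ in $10^5$-cell units, i.e. up to $10^6$
cells), $\alpha_{ij}$ the competitive effect of population $j$ on
population $i$ (positive = suppression), and $\lambda_{SN},
\lambda_{RN}$ the per-capita NK kill rates (first index = target; both
$\alpha$ and $\lambda$ bounded $[-15,15]$). Assumptions worth keeping
in mind:

* NK cells receive **no feedback** from the tumour: no stimulation,
  exhaustion or depletion terms. This keeps the N channel a closed
  logistic equation — useful for validation (below) but a known
  simplification of real NK biology.
* Radiotherapy is not given an explicit dose term in the full model;
  each treatment arm (UT, RT, NK, RT+NK) is fit with its own
  condition-specific rates, and the dose-effect fraction
  $\delta = 1 - r_S'/r_S$ is recovered afterwards with
  `delta_from_rates()`. The explicit $\delta$ appears only in the
  reduced model.
* Because imaging never observes N, $K_N$ is fixed at 1 ($10^5$ cells)
  throughout. Only the products $\lambda_{iN} N$ are identifiable; the
  fitted kill rates are therefore per unit of this conventional NK
  scale. The signs of all interaction parameters are unaffected by the
  convention, and a scale-covariance test (rescaling all $K$, the
  initial state, and $1/\lambda$ by a common factor) guards the unit
  convention.

## What the synthetic generator emulates

No raw co-culture counts are packaged, so the generator is the study's
stand-in for the imaging assay, reproducing its design exactly:
seven initial resistant fractions $f = 0, 0.1, 0.25, 0.5, 0.75, 0.9,
1$; 12 replicates; images every 6 h for 150 h (26 time points); 2000
tumour cells seeded per well, split $S(0) = (1-f)\cdot 2000$,
$R(0) = f \cdot 2000$; NK effectors seeded at a 5:1 effector:target
ratio, giving $N(0) = 10^4$ cells $= 0.1$ in model units (the assay
protocol implies this initial condition; it is not separately
tunable per well).

Observation noise is multiplicative lognormal, mean one, applied
independently per observation with a default coefficient of variation
of 0.10: imaging counts have roughly proportional error and can never
go negative, which an additive Gaussian law would violate at low
counts. `noise_model("none")` returns the exact forward simulation.

The generator does **not** emulate: segmentation artefacts at
confluence, well-position/edge effects, temporally correlated errors,
cell debris mislabelled by channel, or NK counts (never observed).
Passing the recovery tests therefore demonstrates that the *pipeline*
is self-consistent and well-identified under the assay's design — not
that the model is correct for any particular real dataset.

## The staged fitting procedure

One *fitting batch* is a single replicate observed across all seeding
fractions simultaneously (364 residuals: 7 fractions × 26 times × 2
channels, unweighted, both channels equal — no variance model is
imposed because none is identifiable from counts alone). Fitting is
bounded Levenberg–Marquardt least squares (`minpack.lm::nls.lm`).

Staging addresses a structural identifiability problem: under
treatment, populations may never approach their carrying capacities,
leaving $K$ unconstrained. Therefore:

1. **Stage 1 (UT):** free $r_S, r_R, K_S, K_R, \alpha_{SR},
   \alpha_{RS}$; NK parameters structurally zero.
2. **Stage 2 (RT, NK, RT+NK):** $K_S, K_R$ fixed at the untreated
   across-replicate means; RT frees only growth and competition terms;
   NK and RT+NK additionally free $r_N, \lambda_{SN}, \lambda_{RN}$.

The interaction bound $[-15, 15]$ is applied to both $\alpha$ and
$\lambda$; competition coefficients must be allowed negative because
facilitation cannot be excluded a priori (and fitted intervals can
straddle zero).

Starts: the first start is data-driven — early log-linear slopes of the
monoculture channels for growth rates, the observed plateau for
capacities, neutral values ($\alpha = 1$, $\lambda = 0.01$,
$r_N = 0.02$) for interactions. Remaining starts jitter it
log-uniformly by a factor in $[1/2, 2]$, clipped to bounds, and the
best of `n_multistart` losses wins; the jitter stream is seeded, so
fits are exactly reproducible and the best loss is monotone
non-increasing in the number of starts. The default is 8 starts; the
package's own validation runs use 2–4 (noiseless losses agree across
starts to optimizer tolerance, so extra starts buy nothing there).

Summaries report mean ± SEM (sample sd / $\sqrt{n}$) per parameter per
condition over converged replicates; non-converged replicates are
dropped with a warning. Hold-out validation (`holdout_validate()`)
refits on a training subset of replicates and scores held-out
replicates at the training parameter means, reporting per-replicate
mean SSE on both sides so the two numbers are directly comparable.

## Numerical choices

* **Integration** uses `deSolve::ode` with `lsoda` at `rtol = 1e-8`,
  `atol = 1e-10`. lsoda's compiled, stiffness-switching core is
  several-fold faster than an explicit Runge–Kutta on the stacked
  system the fitter integrates (all seven fractions as one 15-state
  ODE, sharing the one NK channel — NK dynamics are well-independent),
  and it absorbs the stiff trial parameter sets ($\lambda$ near 15)
  that multi-start visits. Accuracy is checked against an independent
  closed form: the N channel must match
  $K N_0 e^{rt} / (K + N_0(e^{rt} - 1))$ to $10^{-6}$ relative on 100
  random draws.
* **Nonnegativity**: every per-capita rate is finite at zero, so exact
  solutions cannot cross zero; solver undershoot is clipped to 0.
* **Blow-up safeguard**: mutually negative competition coefficients
  admit finite-time blow-up. Positive growth is tapered linearly to
  zero above $10^3$ model units ($10^8$ cells) — two orders of
  magnitude beyond the admissible capacity range — so that trial
  parameter sets cannot overflow the integrator. The taper is
  unreachable from any data-compatible state and changes no reported
  dynamics.
* **Degenerate inputs**: all-zero states are fixed points and simulate
  to identically zero; monoculture wells ($f = 0$ or $1$) stay pure by
  construction; fits error informatively when every start fails or the
  untreated arm is absent.

## Double-bind diagnostics

From fitted parameters (`analyze_summary()`):

* **Double-bind score** $\lambda_{RN} - \lambda_{SN}$: positive means
  NK cells preferentially kill radiation-resistant cells — the double
  bind. Its dispersion is computed per replicate and then summarized,
  not propagated from parameter means.
* **Cost of resistance** $r_S - r_R$: negative means resistance
  confers an intrinsic growth *benefit*. A double bind does not
  require a classical cost; the packaged reference estimates show a
  negative cost in all four arms, offset by a lower resistant carrying
  capacity ($K_R < K_S$ — an $r$/$K$ trade-off).
* **Competition regime**: the $(\alpha_{SR}, \alpha_{RS})$ quadrant
  with a dead zone of half-width `tol = 0.05` (the published quadrant
  plot draws no dead zone; 0.05 is small relative to every fitted
  coefficient of interest and makes the classification stable to
  sub-tolerance perturbations). Under this model's sign convention a
  positive coefficient is suppressive, so both positive =
  `competition`, both negative = `mutualism`, suppression of S only =
  `sensitive_antagonism`, of R only = `resistant_antagonism`. The
  reference estimates classify as competition with
  $\alpha_{SR} \gg \alpha_{RS}$: competitive exclusion of sensitive by
  resistant cells.

## The reduced model

For treatment-design intuition the system is stripped to shared-$K$
logistic growth plus two treatment dials:

$$
\begin{aligned}
\frac{dS}{dt} &= r_S (1 - \delta\,\mathrm{rt}) \, S
  \left(1 - \frac{S+R}{K}\right) - \lambda S (1 - B)\,\mathrm{nk} \\
\frac{dR}{dt} &= r_R R \left(1 - \frac{R+S}{K}\right)
  - \lambda R B\,\mathrm{nk}
\end{aligned}
$$

with $r_R = r_S(1 - c)$ for cost fraction $c$, radiotherapy dose
effect $\delta$ (values above 1 are net kill), total NK kill rate
$\lambda$, and the double-bind parameter $B \in [0,1]$: the fraction
of the kill effect aimed at resistant cells ($B = 0$ spares R
entirely, $B = 1$ spares S). The resistant kill term is taken
proportional to $R$ — the form under which $B$ genuinely re-targets
the kill effect and the strong-bind regime suppresses resistance; an
alternative form with the flux proportional to $S$ is retained behind
`reduced_rates(literal_kill = TRUE)` for auditability, but it makes
$B$ act as an S-dependent drain on R rather than a retargeting dial
and is not used anywhere else. Consistency with the full model is
tested: with constant NK level, $\alpha = 1$ and equal capacities, the
two models' trajectories agree to solver tolerance.

Sweep defaults (stated values from the published sweep figure where
given, the package's own choices otherwise): $\lambda = 0.05$,
$K = 10^5$ cells and the dose grid $\delta = 0.5, 1, 1.5, 2, 2.5$ are
the published sweep settings; initial conditions and horizon are not
published, so the package uses $(S, R)(0) = (900, 100)$ cells (a 10%
resistant minority at a realistic seeding density), a 500 h horizon
(long enough for every sweep to approach its attractor), $r_S = 0.032$
/h (the untreated sensitive estimate) and $c = 0.1$ (a modest
classical cost, the conservative choice for double-bind claims since
it already handicaps R). Treatment flags are constant within a run
(continuous dosing); sequential schedules are composed by chaining
`simulate_reduced()` calls with state hand-off.

Two monotonicities summarize the design space, and are verified on
dense grids: increasing $\delta$ (RT alone) weakly decreases final S
and weakly increases the final resistant fraction — dose escalation
selects for resistance; increasing $B$ (NK on) weakly increases final
S and weakly decreases final R — screening second-line agents for
large $B$ is the actionable recommendation.

## Validation strategy and problem sizes

The test suite validates by *self-consistency recovery*: the published
per-condition parameter means were estimated from unreleased raw data,
so the pipeline generates noiseless trajectories from those means with
its own forward model and must re-estimate every free parameter —
growth rates and capacities within 1%, competition coefficients within
2%, NK rates within 5% (the $\lambda$–$r_N$ ridge makes the NK channel
the softest direction); observed recovery error is at machine-level
($\sim 10^{-13}$ relative). Under noise (cv 0.10, 12 replicates, the
full 4-condition design) every across-replicate mean must fall within
3 SEM of the generating truth. Structure tests use a compact design (3
fractions, 13 time points, 2 replicates) where only plumbing, not
precision, is at stake; the noisy recovery run uses 2 optimizer starts
and completes in about a minute.

## Known limitations

* No tumour→NK feedback; NK exhaustion and stimulation are out of
  scope, and $\lambda$ estimates inherit the $K_N$ convention.
* Unweighted least squares has no likelihood interpretation; SEMs are
  empirical across replicates, not profile intervals, and no
  hypothesis test is attached to the double-bind score (its sign and
  dispersion are reported).
* The generator's lognormal noise is an idealisation of imaging error;
  real confluence artefacts are systematic, not independent.
* Fits consume unnormalized counts. Time-zero normalisation (counts
  divided by their initial value) is treated as a plotting convention:
  it would discard the absolute scale on which the carrying capacities
  are identified.
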