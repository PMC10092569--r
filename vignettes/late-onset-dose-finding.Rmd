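---
title: "Dose-finding designs for late-onset toxicities: models, data generation and simulation engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-finding designs for late-onset toxicities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latetox)
```

## The problem

Phase I oncology trials search for the maximum tolerated dose (MTD): the
highest dose whose probability of a dose-limiting toxicity (DLT, a grade
3+ adverse event) does not exceed a target $\tau$.  When treatment runs
over several cycles, a large share of DLTs occur after cycle 1, so a
design that only watches the first cycle misjudges risk — but waiting for
full multi-cycle follow-up before every escalation decision would make
trials unacceptably long.  `latetox` simulates the compromise used in
practice: *rolling enrollment*.  A new cohort enters at every cycle
boundary and each decision uses all data observable at that calendar
time, with recent cohorts only partially followed up.

The reference configuration mirrors a radiopharmaceutical first-in-human
setting: six doses (1.5, 2.5, 3.5, 4.5, 6.0, 7.0 MBq), cohorts of 3, at
most 30 patients, three cycles of six weeks, and a cycle-1 DLT target of
0.3, which under the data-generating mechanism below corresponds to a
three-cycle target of $\tau = 0.391$.

## Data generation

Each simulated patient $i$ carries a single latent toxicity variable
$z_i \sim U(0,1)$ that fixes their outcome on **every** dose — the basis
for the paired comparison of designs and for the empirical benchmark.
The per-cycle DLT hazard decays geometrically with factor $1/3$, so the
cumulative DLT probability after cycle $s$ at a dose with cycle-1
probability $p_1$ is
$p_s = p_{s-1} + (1 - p_{s-1})\,p_1 (1/3)^{s-1}$; for three cycles
$p_3 = p_1 + (1-p_1)p_1/3 + (1-p_1)(1-p_1/3)p_1/9$, which maps
$p_1 = 0.3$ to $p_3 = 0.391$.  A DLT occurs in the unique cycle $s$ with
$p_{s-1} < 1 - z_i \le p_s$ (half-open intervals, so boundary values are
deterministic).

Grades are generated consistently with the binary mechanism.  In cycle 1
the maximum grade follows a piecewise distribution in which grades 3 and
4 each carry mass $p_1/2$ (`grade_distribution()`); the thresholds stack
downward from grade 4, so smaller $1 - z_i$ means a worse grade and
grade $\ge 3$ coincides exactly with a cycle-1 DLT.  For later cycles
the published scaling multiplies the cycle-1 masses by the survivor
fraction $1 - p_{s-1}$.  That scaling gives grade-$\ge 3$ mass
$(1-p_{s-1})\,p_1$ in cycle $s$, while the hazard recursion implies the
smaller mass $(1-p_{s-1})\,p_1(1/3)^{s-1}$; the two are not mutually
consistent and we resolve the conflict in favour of the hazard
recursion, which defines the binary process the targets are built on:
DLT timing always follows the cumulative intervals; within a non-DLT
later cycle the non-DLT grades 0–2 are drawn from the scaled masses
renormalised over survivors; a later DLT cycle is grade 3 or 4 with
equal probability.  Grade/type triples (renal, hematological,
neurological; 125 combinations) are uniform within the set fixed by the
maximum grade.  Auxiliary uniforms for these residual choices come from
a per-patient stream drawn once per replicate, so no design choice can
perturb outcome draws.

The nTTP (normalized total toxicity profile) of a grade triple is a
weighted Euclidean norm scaled into $[0,1]$.  The published weight
values for the three types are not reproduced here; the package ships a
synthetic default table (weights 0.5/0.75/1.0/1.5 for grades 1–4 of
every type, `nttp_weights_synthetic.csv`) that is monotone in grade and
symmetric in type, and every nTTP-consuming function accepts a custom
table.  The nTTP target defaults to the expected cycle-1 nTTP at a dose
sitting exactly on the cycle-1 DLT target (`tau_nttp_default()`,
`r round(tau_nttp_default(), 3)` under the default weights) — the paper
never prints its value, so the package derives it from the generative
mechanism itself.

## The eight designs

**1-parameter TITE-CRM.** Weighted power model
$G(d, w, \beta) = w\,d^{\exp(\beta)}$ on the skeleton scale with weights
$u/S$ (1 after a DLT) and a $N(0, \sigma^2)$ prior.  The posterior mean
of $\beta$ is computed by dense trapezoidal quadrature on $[-10, 10]$
(2001 nodes, agreeing with an adaptive-quadrature oracle to $10^{-6}$).
Until the first DLT anywhere, the dose escalates one level per decision.

**2-parameter TITE-CRM.** Logistic model on the real dose values with
$a_0 \sim N(-1, 1/0.3)$ and $\log a_1 \sim N(\log 0.2, 1/0.3)$ (the
calibrated values are printed as precisions).  The posterior is
integrated on a fixed 2-D grid over $(a_0, \log a_1)$ rather than
sampled by MCMC: a two-parameter posterior is cheap to integrate
exactly, and removing Monte-Carlo error makes every dose decision a
deterministic function of the data — the design decision cannot flip
between reruns.

**ICSDP.** Interval-censored survival model with complementary log-log
link $\log(-\log(1 - \pi_{j,s})) = \gamma_s + \theta \log d_j$, fitted
by maximising the likelihood augmented with fractional pseudo-patients
at the lowest and highest dose (`icsdp_pseudo_data()`); per-cycle
anchors decay geometrically with the data-generation factor, a choice
exposed in the prior configuration since only "decreasing" is
prescribed.  With three cycles the six anchor cells overdetermine the
four parameters, so the pseudo-data-only fit reproduces the anchors to
about two decimals rather than exactly.  Dose selection maximises the
gain $1/(\tau - \hat\rho_j)^2$ where
$\hat\rho_j = 1 - \prod_s (1 - \hat\pi_{j,s})$.  Uncertainty summaries
(safety and precision rules) use normal draws at the penalised-ML mode
with the inverse observed Hessian.

**POMM.** Three-level ordinal response (grade $\le 1$ / grade 2 / grade
$\ge 3$).  Up to subject 15, a weighted ML logistic fit of the cycle-1
DLT indicator against dose, stabilised by the cycle-1 layer of the
pseudo-data, targets the cycle-1 probability 0.3.  From subject 16, a
Bayesian proportional-odds mixed model
$\mathrm{logit}\,P(Y_{i,s} \le k) = \alpha_k - \beta_1 d_j - \beta_2 s - u_i$
is sampled with JAGS (the fractional pseudo-data enter as a power
likelihood via the zeros trick; $\alpha_1 < \alpha_2$ is enforced by
construction) and targets the whole-follow-up DLT probability of a
median patient, $1 - \prod_s P(Y \le 2 \mid d_j, s, u = 0)$.  The total
pseudo-weight $n_0 = 2$ is spread evenly over the $6 \times 3$
dose-cycle cells; the five printed grade-2 ratio anchors are recycled to
the six doses.  Convergence is gated by the potential scale reduction
factor ($< 1.01$) of the fixed effects that enter the decision — not of
the random-effect variance, whose mixing on a handful of patients is
poor without affecting the decision — with "retain the current dose" as
the fallback.

**nTTP design.** Linear mixed model
$y_{i,s} = \beta_0 + \beta_1 x_i + \beta_2 s + \gamma_i + \epsilon_{i,s}$
on the observed per-cycle nTTP values with normal priors on the
coefficients and IG(0.001, 0.001) priors on both variances.  Two
implementation choices matter here.  First, the dose covariate is the
dose standardized by the largest dose on the grid: the calibrated slope
prior (mean 0.5) adds half the endpoint's full range per *standardized*
unit, which is coherent, whereas on raw MBq doses it would add 0.5 per
MBq to a $[0,1]$ endpoint and the design could never escalate off the
lowest dose (a flag restores raw doses).  Second, conditional on the two
variances the model is conjugate, so the posterior is computed exactly
on a log-spaced variance grid with closed-form normal updates instead of
MCMC.  Early in a trial all data sit at one dose and the slope direction
is unidentified; samplers cannot pass a strict convergence gate there,
while exact integration returns the correct prior-anchored posterior
with zero Monte-Carlo error.

**TITE-BOIN, TITE-mTPI2, R-mTPI2.** Interval designs with precomputable
decision tables (`assisted_decision_table()`).  TITE-BOIN compares the
imputed rate $m/(m + c + \mathrm{STFT})$ — DLTs and completed non-DLT
patients count fully, pending patients by their follow-up fraction —
with the closed-form boundaries $\lambda_e, \lambda_d$; an observed rate
$m/n \ge \lambda_d$ de-escalates regardless of pending data, and accrual
is suspended when more than half the patients at the current dose are
pending.  TITE-mTPI2 computes the Beta posterior from the effective
counts and moves toward the strongest key; keys tile $[0,1]$ outward
from the calibrated target key $(\tau_1, \tau_2)$, end keys absorbing
the remainders.  R-mTPI2 cascades: complete-data keyboard decision when
nothing is pending; best/worst-case imputation of the pending patients
when the two agree; otherwise the consecutive-assignment rule (keep
enrolling at the current dose below 6 consecutive patients, suspend at
6 or more).  The full rule tables of the cited designs are not
reproduced in the source material, so the rule constants (pending
fraction 0.5, consecutive limit 6) are configuration with these
defaults.  Final selection for all three is isotonic regression (PAVA
with n-weighted pooling of Beta posterior means); among equally close
doses the highest is recommended when its pooled estimate is below
target and the lowest otherwise — with fractional priors, a strict
lowest-dose tie rule would prefer a barely-tested low dose over a
well-tested safe one and collapses the selection accuracy in flat
scenarios.

## Engine, enforcement and stopping rules

At every cycle boundary the engine builds the observable dataset (no
future leakage by construction), lets the design propose a dose or
suspend, enforces exclusions and the 2-fold escalation cap (an
inadmissible proposal maps to the nearest admissible lower dose), then
evaluates the stopping rules, and only then enrolls the next cohort.
The sufficient-information rule stops the trial when the dose about to
be assigned already carries 9 treated patients — checked before the
cohort enrolls, which is the reading consistent with the reference
trial sizes in the near-deterministic scenarios.  Setting 1 activates
only the 2-fold cap, sufficient information and the 30-patient maximum;
setting 2 adds hard safety (Beta(1,1) posterior exclusion at
$P(p_1 > 0.3) > 0.95$, giving the dividing triples 3/3, 4/6, 5/9),
posterior safety stops at the lowest and highest dose (threshold 0.80;
evaluated with the design's own one-cycle model where it has one — a
follow-up-restricted refit for the CRM variants, asymptotic draws for
ICSDP, model draws for POMM — and with the Beta-binomial model for the
model-assisted designs and the nTTP design, whose endpoint has no
design-side DLT probability), and the precision stop
$\mathrm{CV}(\mathrm{MTD}) < 0.30$ with CV the 1.4826-adjusted MAD over
the median of MTD posterior draws on the dose scale, active once 9
patients have at least one cycle and only for model-based designs.
Strict inequalities apply throughout; boundary equality never triggers.

When enrollment stops, already-enrolled patients complete follow-up (a
DLT ends a patient's follow-up at that cycle) and the trial duration is
the completion week of the last patient; a configuration flag instead
stops the clock at the stopping decision, because the published
durations do not let one convention be confirmed on every design (see
Limitations).

## Calibration and benchmark

`calibrate_design()` scores each hyper-parameter candidate by the
geometric mean — zero-propagating, to penalise a collapse in any one
scenario — of its per-scenario proportions of correct outcomes over the
calibration scenarios (`calibration_scenarios()`: four MTD-position
scenarios in setting 1, plus an all-unsafe and an all-very-safe scenario
in setting 2), and returns the argmax, ties to the first candidate in
grid order.  The scorer is pluggable, so the harness itself is validated
with deterministic stub policies of known per-scenario accuracy.  The
shipped design constructors default to the calibrated hyper-parameter
values for each setting (`standard_design()`).

The empirical benchmark exploits the shared latents: every patient's
response on every dose is known, so the benchmark picks the dose whose
mean full-period response over the 30 patients is closest to the target
(full-period DLT indicator against $\tau$, or cycle-1 nTTP against the
nTTP target).  It uses the same per-replicate populations as the
designs, and bounds the achievable selection accuracy in a scenario.

## Numerical choices and degenerate inputs

Quadrature: CRM on 2001 nodes over $[-10, 10]$; CRM2 on a
$121 \times 121$ grid spanning $\pm 7$ prior SDs per axis; nTTP variance
grid $25 \times 25$ log-spaced on $[10^{-4}, 1]$.  ICSDP is maximised
with BFGS from anchor-based starting values; a singular Hessian disables
the draw-based rules for that interim rather than failing the trial.
All "closest to target" criteria break exact ties toward the lower dose,
except the isotonic final selection and the benchmark as described
above.  De-escalation at dose 1 means staying at dose 1; escalation at
the top dose stays.  A design that cannot produce a usable fit (ML
non-convergence, PSRF failure) retains the current dose.  Patients with
zero observed cycles contribute a unit likelihood factor.  An all-DLT
first cohort under setting 2 excludes every dose and ends the trial with
no recommendation after 3 patients.

## What the simulations do and do not show

The generator emulates the study conditions: cycle-discretised DLT
times, a single latent driving all doses, decay factor 1/3, and the
grade mechanism above.  It does not model continuous within-cycle event
times, dropout unrelated to toxicity, inter-patient heterogeneity beyond
the latent, or efficacy.  Passing tests therefore validate the designs'
decision logic and operating characteristics *under this mechanism*, not
performance on real trial data, where the decay structure and the
grade/type independence assumptions may fail.

Problem sizes were chosen so the whole suite runs on a laptop core:
1000 replicates for the scenario-D trial-size checks (Monte-Carlo error
well below the comparison tolerance of one patient), $2 \times 10^5$
draws for the DLT-cycle frequency check, parameter recovery at
$n = 300$–$500$, slope-coverage over 25 replicates at $n = 120$, and
exhaustive decision-rule checks up to $n = 12$ with PAVA equivalence
exhaustive at 3 doses plus 200 random 5-dose instances.

## Known limitations

* The TITE-BOIN suspension constant reproduces the reference trial
  sizes in scenario D (mean 24 patients) but yields longer durations
  (~93 weeks vs the published 49); no suspension reading we could
  construct matches both the published patient counts and durations
  simultaneously, and the discrepancy is confined to the duration
  metric of the suspending designs.
* The exact published nTTP weights and the supplementary calibration
  grids are not reproduced; both are configuration.
* MCMC-based POMM decisions are stochastic given the data; all other
  designs are deterministic, which the permutation- and determinism
  tests exploit.
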