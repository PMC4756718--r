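---
title: "Methods: route-specific biomarker discovery with RMS permutation tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: route-specific biomarker discovery with RMS permutation tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
options(rmsperm.quiet = TRUE)
library(rmsperm)
```

`rmsperm` asks whether bulk tumor expression can identify ovarian-cancer
patients who derive no benefit, or harm, from intraperitoneal (IP) relative
to intravenous (IV) adjuvant chemotherapy. This vignette documents the
statistical model behind each stage, the parameters that matter, the design
decisions that were genuinely open, and what the synthetic-data experiments
do and do not establish.

## Cohort model and preprocessing

A cohort is one row per case: chemotherapy route (IP means *any*
intraperitoneal administration, since nearly all IP-treated patients also
receive IV drug), age, surgical stage, histologic grade, cytoreduction
status (optimal ⇔ residual disease ≤ 10 mm), race, and two censored
time-to-event endpoints in months — progression-free survival (PFS) and
overall survival (OS).

Two rules are applied before any model:

* **Administrative truncation at 60 months** (`truncate_survival()`):
  events after the horizon become censored observations *at* the horizon.
  The horizon equals the restriction time used for all restricted-mean
  calculations, so no comparison is driven by a handful of long
  survivors. Truncation is idempotent.
* **Per-analysis listwise deletion** (`analysis_subset()`): each model
  uses the cases complete on *its* variables, and reports how many were
  omitted. No imputation is ever performed, so the per-model omission
  counts are an honest summary of data completeness.

Descriptive arm comparisons use a two-sample t-test for continuous
variables, Kruskal–Wallis on level scores (with the standard tie
correction) for ordered factors, and Fisher's exact test for unordered
factors. For tables too large for exact enumeration the Fisher p-value is
estimated by seeded Monte Carlo (10^5 draws); which route was taken is a
function of the table dimensions, not of the data values. Percentages are
always over non-missing denominators.

## Survival machinery

Kaplan–Meier estimation, the log-rank test and Cox partial-likelihood
maximization are delegated to the `survival` package (Efron tie
correction by default, Breslow available; convergence tolerance 1e-9).
Medians are read off the KM step function as the first time survival
reaches 0.5 or below — no interpolation, matching months-scale reporting.

On top of the fitted coefficients the package computes its own
**Breslow-type baseline cumulative hazard** at covariate value zero,
$H_0(t) = \sum_{t_i \le t} d_i / \sum_{j \in R(t_i)} e^{\beta' x_j}$, the
predicted survival $S(t\,|\,x) = \exp(-H_0(t)\,e^{\beta' x})$, and the
**restricted mean survival time** as the exact area under the
right-continuous step function up to $\tau$ (sum of step widths × heights,
last value carried to $\tau$). Correctness anchors in the test suite: a
hand product-limit computation, a 1-D grid search of the exact partial
likelihood (agreement to 1e-4), a bisection root of the score equation,
and the closed-form exponential RMS $30(1 - e^{-2})$ on a fine grid
(agreement to 1e-3 months).

Covariate encoding is a modelling choice the data do not dictate: stage
and grade enter as ordered integer scores, cytoreduction as a binary
indicator, race as one-hot indicators against the most frequent level.
The encoding is centralized in `encode_covariates()` and can be bypassed
by passing any numeric design matrix.

## Discovery and validation

Within each arm, cases are stratified at **12 months** of PFS — tumors
progressing earlier are plausibly chemoresistant, and twelve months is
roughly six months past the end of first-line chemotherapy, the
conventional platinum-sensitivity landmark. The boundary case (PFS = 12.0)
belongs to the upper stratum. The observed, possibly censored, PFS time is
used; a case censored before 12 months is therefore assigned to the early
stratum even though its true progression time is unknown. This is a known
limitation of landmark stratification on observed times; with the default
censoring rate about one case in eight is affected.

Each gene is compared between strata with a **Welch t-test** (the strata
are typically very unbalanced, e.g. 9 vs 81, so the unequal-variance form
is the safer default; the pooled form is available). Fold change is the
ratio of arithmetic stratum means on the supplied expression scale.
P-values are Benjamini–Hochberg adjusted **within each arm** — the two
arms are separate discovery experiments with separate gene counts — and
genes with adjusted p < 0.05 are called differentially expressed.

Validation enters each discovered gene as a continuous covariate in
per-arm Cox models of PFS and OS, adjusted for age, stage and grade, on
both expression platforms. Expression is scaled by the SD of the analysis
subset, so hazard ratios read *per 1 SD of expression* and are invariant
to linear rescaling of the raw values (verified to 1e-8). The
dual-platform gate requires raw p < 0.05 for at least one endpoint on
*each* platform ("OS and/or PFS on both"); an endpoint-matched variant is
available behind a flag.

## RMS curves and the quantile-window permutation test

Expression is rank-normalized per gene over the pooled analyzed cohort:
$q_i = (\mathrm{rank}_i - 1)/(n - 1)$ with average ranks for ties, so
$q$ is invariant to any monotone transform of the raw measurements —
important when comparing microarray and RNA-Seq scales.

`rms_curve()` plots the relationship between expression and survival
without dichotomization: a univariate within-arm Cox fit on $q$, with
$\mathrm{RMS}(q) = \int_0^{60} S(t\,|\,q)\,dt$ evaluated on a grid, and
pointwise 95% bands from a seeded case-resampling bootstrap (percentile
method, default B = 200; the bootstrap was chosen over a delta-method
band because the estimator composes a partial-likelihood fit, a baseline
estimator and an integral).

`adjusted_rms_per_case()` fits, within each arm, a multivariate Cox model
on $(q, \text{age}, \text{stage}, \text{grade})$ and integrates each
case's predicted survival to $\tau = 60$. Within a closed quantile window
(defaults: bottom and top deciles, $[0, 0.1]$ and $[0.9, 1]$, over the
pooled cohort), the statistic is
$\Delta = \overline{\mathrm{RMS}}_{IP} - \overline{\mathrm{RMS}}_{IV}$ in
months, and significance comes from permuting the arm labels of window
members with two-tailed $p = (1 + \#\{|\Delta^*| \ge |\Delta|\})/(B + 1)$
(so $p > 0$ always; 10,000 permutations for reported analyses). Exact
enumeration over all $\binom{n}{n_{IP}}$ assignments replaces sampling for
small windows and serves as the oracle in tests.

### Why the permutation refits

The per-case RMS values are *model predictions*: every IP case's value
comes from the IP-arm fit, every IV case's from the IV-arm fit. Each
fitted model carries estimation noise — in the baseline hazard and in the
coefficients — that shifts *all* of an arm's predictions together.
Shuffling labels over fixed values treats that shared shift as if it were
evidence of a treatment effect, and the test suite's negative control
shows the consequence: on null cohorts (no route or gene effect) the
fixed-value permutation rejects at several times the nominal 5% rate.

The default mode therefore **refits both per-arm Cox models under every
permuted labeling** (labels outside the window stay fixed) before
recomputing $\Delta^*$. The acceptance suite measures the resulting size
on 200 null cohorts of 100 cases per arm at 500 permutations: the
rejection rate at $\alpha = 0.05$ falls within [0.02, 0.08]. Refitting
costs roughly a millisecond per permutation at these sizes via the
low-level fitter; the fixed mode remains available (`mode = "fixed"`) as
a fast, explicitly anticonservative approximation for exploration.

### Candidate calls, and what "no significant benefit" can and cannot do

A platform *flags* a gene in a window when IP survival is either
significantly decreased ($\Delta < 0$, $p < \alpha$) or **not
significantly different** ($p \ge \alpha$); a clear significant IP
benefit blocks the flag. A gene flagged on both platforms for the same
endpoint and window is a candidate biomarker. This encodes the working
hypothesis that IP benefit is the norm — which the route-level analysis
supports — so its *absence* in an expression stratum is the interesting
signal.

Treating non-rejection as evidence has a structural consequence that the
synthetic experiments quantify. With a planted IV-arm-only resistance
gene (log HR 0.5 per SD, 200 cases per arm) the pipeline calls the gene a
candidate in essentially every replicate — low expressors of the gene
show no IP benefit, and the test correctly declines to find one. But a
purely *prognostic* gene (same effect in both arms) is also called in
roughly half to two-thirds of replicates: confirming the true ~12-month
in-window IP benefit at $p < 0.05$ requires more power than a calibrated
permutation test has in a ~40-case decile window, and every
non-significant window raises a flag. The two goals — a correctly sized
test and a low false-candidate rate for prognostic genes — pull in
opposite directions at these sample sizes, and only an anticonservative
test would deliver the latter. Users should read candidate lists
accordingly: they enumerate strata where IP benefit is *not established*,
which at small window sizes includes power failures, and they warrant
experimental follow-up rather than clinical conclusions. Equivalence-style
designs (testing whether the benefit exceeds a margin) would be the
principled refinement and are out of scope here.

## The synthetic-cohort generator

`simulate_cohort()` draws survival by inverse transform from the
cumulative baseline hazard, giving exact proportional-hazards structure:
$h(t\,|\,x) = h_0(t)\exp(\beta_{route} \mathbb{1}[IP] + \sum_g \beta_g x_g
+ \text{covariate effects})$, with arm-specific gene coefficients for
predictive (route-specific) genes. Expression is marginally standard
normal, so per-SD hazard ratios equal $e^{\beta_g}$ directly; the RNA-Seq
platform re-measures a subset of cases (defaults 34/90 IP and 187/398 IV)
with additive noise (SD 0.6). Censoring is independent exponential
(default rate 0.012/month, chosen to yield roughly a third of OS
observations censored within the 60-month window); a shared censoring
time ends follow-up for both endpoints. Missingness is applied per field
after generation (defaults 5–20%, heaviest for OS and cytoreduction,
mirroring typical registry completeness).

Default baselines are Weibull with increasing hazard — PFS shape 2.5 with
median 16 months, OS shape 2 with median 38.2 months in the IV arm, route
hazard ratio 0.45. The shapes are a deliberate compromise: under any
proportional-hazards Weibull model the reference cohort's arm medians and
its early-progression fractions imply *different* shape parameters
(roughly 1.6 from the median ratio, 3.8 from the 12-month fractions), so
no Weibull reproduces both exactly. Shape 2.5 keeps the IV median at 16
months, puts the IP PFS median near 22 months (reported: 26.7), the IP
12-month progression fraction near 15–20% (reported: 10%), and the IP OS
median inside the 60-month window. An increasing hazard is also the
clinically sensible choice — progression risk immediately after surgery
and during first-line chemotherapy is low and rises afterwards.

What the generator does **not** emulate: microarray normalization
artifacts or RNA-Seq count distributions (expression is Gaussian by
design), dependence between PFS and OS (they are drawn independently
given the linear predictor, so OS < PFS can occur), informative censoring,
and batch or site structure. Passing tests therefore demonstrate that the
*statistical machinery* behaves as specified under the assumed model —
calibration, parameter recovery, invariances — not that the pipeline is
robust to the messiness of real platform data.

## Numerical choices and degenerate inputs

* Cox ties: Efron (default) / Breslow; Newton convergence at 1e-9;
  suspected separation is flagged (`unstable`), and covariate columns that
  are constant within a resampled arm are treated as dropped
  (coefficient 0) inside bootstrap/permutation loops, matching `coxph`'s
  aliasing convention.
* Windows are closed on both ends; boundary ties are all included
  (deterministic, at the cost of occasionally selecting a case or two
  more than a tenth).
* All-identical expression values cannot be rank-normalized and raise an
  error; zero-variance genes in both strata get t = 0, p = 1 with a
  `degenerate` flag rather than an error, so one flat gene cannot abort a
  genome-wide scan.
* A window empty in either arm yields a not-computable result that
  propagates as a non-candidate; a window admitting fewer than two label
  assignments yields p = 1.
* Every stochastic stage (generation streams, bootstrap, permutation,
  Monte-Carlo Fisher) takes an explicit seed; the pipeline derives
  per-stage seeds from one root seed, and rerunning with the same
  configuration is byte-identical.

## Problem sizes used by the checks

Simulation-backed checks run at deliberately modest scale, chosen so the
full suite completes in minutes while keeping Monte-Carlo error small
relative to the tested margins: calibration uses 200 null cohorts of
100 cases per arm at 500 permutations; candidate recovery uses 50 cohorts
of 200 cases per arm; parameter-recovery fits use 2000–4000 cases; the
acceptance script repeats the calibration (100 cohorts) and recovery
(25 cohorts) from a user-supplied seed. Reported analyses should use the
10,000-permutation default.
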