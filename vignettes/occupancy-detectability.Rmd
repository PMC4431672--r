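---
title: "Occupancy under imperfect detection: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy under imperfect detection: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occuseed)
```

## The estimation problem

A survey records, for each of *n* host trees, whether mistletoe seeds were
found by each of several independent observers. Detection is imperfect: an
occupied host can yield an all-zero history. The single-season occupancy
model separates the state process (host occupied with probability
$\psi_i$) from the observation process (per-survey detection with
probability $p_i$ given occupancy) using the information in the repeat
surveys. The likelihood contribution of host $i$ with history $h_i$ over its
surveyed occasions is

$$
\Pr(h_i) =
\begin{cases}
\psi_i \prod_j p_i^{y_{ij}} (1-p_i)^{1-y_{ij}} & \text{if } \sum_j y_{ij} > 0,\\[4pt]
\psi_i \prod_j (1-p_i) + (1-\psi_i) & \text{if all } y_{ij} = 0,
\end{cases}
$$

and occasions that were not surveyed contribute no factor — the standard
unequal-effort convention, needed here because part of the design uses two
observers per host and part uses three. Both parameters are logit-linear in
site covariates: $\mathrm{logit}(\psi_i) = \beta_0 + \beta_1 x_{i1} + \dots$
and likewise for $p_i$. Because only site (host) covariates enter, $p_i$ is
constant across a host's occasions and the per-host likelihood depends on
the history only through its detection and non-detection counts, which is
what the implementation exploits.

### Model assumptions

* Closure: a host's occupancy state does not change between its surveys
  (the surveys here are near-simultaneous observer visits, so closure is
  essentially exact by design).
* Independence of surveys given the state — observers search without
  communicating.
* No false positives: a detection proves occupancy.
* Site covariates only; no observer or occasion effects on $p$.

## Covariates, candidate set and ranking

Three host covariates are available: crown diameter (`size`, metres),
presence of an infected fruiting neighbour within 50 m (`neighbor`, 0/1) and
presence of an adult fruiting infection on the focal host (`infection`,
0/1). Each may enter the occupancy term, the detectability term, both or
neither, except that `size` and `infection` may not share a term: adult
infections sit disproportionately on large hosts and the two are too
collinear to separate. That leaves $6 \times 6 = 36$ candidate models
(`enumerate_models()`); disabling the exclusion gives the full
$8 \times 8 = 64$.

Models are ranked by the small-sample-corrected criterion
$\mathrm{AICc} = -2l + 2K + 2K(K+1)/(n - K - 1)$ with $n$ = number of
sites (hosts), the standard occupancy convention. Akaike weights
$w_i \propto \exp(-\Delta_i/2)$ are computed over **all** converged
candidates, not only the displayed head of the table: per-model weights then
do not sum to one within any truncated display, which is the behaviour a
reader of such tables expects. A fit that failed to converge keeps its row
(flagged) but is excluded from the weight normalization, since its AICc is
meaningless. The selection table carries both raw AICc and $\Delta$AICc
columns so no reader has to guess which is which. Ties in AICc are broken by
smaller $K$, then by canonical candidate order, making the ranking
deterministic.

Model-averaged predictions (`model_average_predictions()`) average
real-scale $\hat\psi$ and $\hat p$ with the weights, either over all
converged models or over the $\Delta \mathrm{AICc} \le 2$ confidence set
with renormalized weights; averaging on the probability scale keeps the
result inside the convex hull of the member predictions.

## Fitting: numerical choices

* **Optimizer.** BFGS on the unconstrained logit scale with the analytic
  gradient of the likelihood, objective tolerance `reltol = 1e-12`,
  at most 1000 iterations.
* **Starts.** A deterministic five-point list: all zeros; intercepts at
  $\pm 1$; a warm start whose occupancy block is the IRLS logistic fit of
  the detected-at-least-once indicator and whose detection intercept is the
  logit of the per-survey hit rate among detected hosts; and the same warm
  start with the detection block zeroed. The best optimum by likelihood
  wins. Multimodality is rare in this model class but cheap to guard
  against.
* **Variance.** The coefficient variance matrix is the inverse of the
  numerically differenced (central-difference) Hessian of the negative
  log-likelihood at the optimum. If the optimizer reports failure or the
  information matrix is singular or has negative diagonal elements after
  inversion — the signature of boundary estimates, e.g. every host detected
  — the fit is returned with `converged = FALSE`, its estimates intact and
  its intervals suppressed (`NA`), never as an exception.
* **Intervals.** 95% Wald intervals on the logit scale, back-transformed.
  They respect $[0,1]$ by construction and match common occupancy-software
  practice; profile-likelihood intervals are out of scope.
* **Covariate scaling.** Covariates are used raw (metres, 0/1), not
  z-scored. Predictions are invariant to this choice, and raw-scale
  coefficients remain directly comparable with published logistic
  equations. (PRESENCE-style software sometimes standardizes internally;
  if coefficient-scale agreement with such output is needed, standardize
  the covariates before building the dataset.)
* **Degenerate inputs.** Histories with a detection after $p$ is driven to
  1 get likelihood zero (objective `Inf`), which the optimizer simply moves
  away from; all-`NA` histories, non-binary detections, non-positive sizes
  and duplicate host ids are rejected at container construction with named
  errors.

The naive fit (`fit_naive()`) collapses each history to a single binary
"detected at least once" occasion and maximizes the same likelihood with
$p \equiv 1$, which is exactly logistic regression; a damped Newton polish
after BFGS brings it to IRLS-level precision (the test suite checks
agreement with `glm` to $10^{-6}$). Complete separation is flagged via
unbounded linear predictors, not thrown.

## The synthetic survey generator

`sim_config()` / `simulate_dataset()` emulate the structure of a 130-host
cashew survey: five host populations, three surveyed by two observers
(27 + 27 + 26 hosts) and two by three observers (25 + 25), so 80 hosts carry
a structurally missing third occasion. Crown diameters are drawn from
$\mathcal N(5.3, 2.5^2)$ m truncated to $[0.5, 15]$ m — the truncation
prevents non-physical negative diameters while barely moving the first two
moments; 40% of hosts get an infected neighbour and 9% an adult infection.
Defaults for the coefficient vectors are
$\beta_\psi = (0.25, 0.18, 1.0, 0)$ and $\beta_p = (1.75, -0.15, 0.8, 0)$
over (intercept, size, neighbor, infection): occupancy rising with size and
neighbour infection, detectability near 0.78 at the covariate means, falling
with size and rising with neighbour infection — the effect directions a
seed-dispersal mechanism predicts (birds perch on large trees; large crowns
dilute the searcher's attention; dispersal distances are short).

One integer seed drives a single RNG stream, with draws consumed in a fixed
block order (sizes, neighbours, infections, latent states, detections
occasion by occasion), so a seed plus a configuration reproduces the dataset
bit for bit. The latent states and generating probabilities travel in a
separate truth attribute (`sim_truth()`): parameter-recovery tests read it,
fitting code cannot.

What the generator does **not** emulate: spatial autocorrelation between
neighbouring hosts, observer heterogeneity, occasion effects, overdispersion
from seed clumping within crowns, or any mismatch between the logit-linear
model and nature. Tests passing on simulated data therefore demonstrate
correctness of the estimation machinery under the model's own assumptions —
not robustness of the model on real surveys.

## What the test suite establishes

* The history probabilities are a distribution (they sum to one over all
  $2^T$ possible histories on a $\psi \times p$ grid) and the likelihood
  equals an independent latent-state enumeration oracle to $10^{-10}$ on
  randomly generated small datasets.
* The intercept-only MLE matches an independent two-parameter grid search,
  and the $p \equiv 1$ reduction matches IRLS logistic regression.
* Over 50 simulated surveys of 2000 hosts with three occasions, every
  coefficient's mean estimate lies within 3 Monte-Carlo standard errors of
  its generating value and pooled 95% Wald coverage over the
  $6 \times 50$ intervals lies in $[0.90, 0.99]$. Coverage is assessed
  pooled because per-coefficient coverage from 50 replicates has a
  Monte-Carlo standard error of about 0.03, too coarse for that band. The
  problem sizes (50 replicates, 2000 hosts) keep the recovery study's
  Monte-Carlo error well below the assertion tolerances while the whole
  suite stays interactive.
* The detection-corrected intercept-only occupancy never falls below the
  naive detected fraction — the direction of the false-absence bias — and
  swapping the two models in the comparison flips every per-host difference
  exactly.
* Model-selection arithmetic reproduces a published five-row selection
  table's AICc values exactly from the printed $-2l$ and $K$ at $n = 130$,
  confirming both the AICc closed form and the sites-as-$n$ convention.

One reproduction test needs the original 130-host field spreadsheet, which
is not redistributed with the package; with that file converted to the
canonical CSV dialect and installed as `inst/extdata/s1_dataset.csv`, it
checks the constant-model detectability, the identity and weight of the
best model, the covariate summaries and the mean naive-vs-corrected
difference against the published values.

## Interpretation choices for the comparison stage

The "underestimation of occupancy" is the mean of
$(\hat\psi_{\text{corrected}} - \hat\psi_{\text{naive}})$ over the sampled
hosts' covariate values, in percentage points. Averaging over the sampled
hosts (rather than a uniform covariate grid) is the natural reading of an
"average" bias for a specific survey; a profile grid over size × neighbour
is also produced for curve-style comparisons, with any remaining covariate
fixed at its modal class. Published relative statements about detectability
("x% higher near infected neighbours", "falls from smallest to largest
hosts") are ambiguous between absolute and relative scales, so the package
reports predictions from which either contrast can be formed and the tests
assert only the directions.

A published naive-logistic equation for this system prints a negative
neighbour coefficient while the accompanying analysis argues the neighbour
effect on occupancy is positive; the coding of that printed equation is
unresolved (plausibly 1 = no infected neighbour), so coefficient-level
agreement with it is deliberately not asserted anywhere.

## Known limitations

* Single season only: no colonization/extinction dynamics.
* No observer- or occasion-varying detectability, no random effects, no
  overdispersion adjustment (c-hat), and no goodness-of-fit bootstrap.
* Wald intervals can be poor near boundaries; such fits are flagged rather
  than repaired.
* The XLSX ingestion path shells out to Python's openpyxl and exists for
  one-off conversion of deposited spreadsheets; the canonical interchange
  format is the plain CSV dialect.
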