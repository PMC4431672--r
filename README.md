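# occuseed

Single-season site-occupancy models for repeated detection/non-detection
surveys of mistletoe seeds on host trees.

## The problem

Mistletoe seeds are bird-deposited on host-tree branches, and a host recorded
with no seeds is not necessarily seed-free: an observer can simply miss them.
Treating non-detection as absence ("naive occupancy") biases metapopulation
quantities downward, and the bias is worst exactly where it matters — large,
isolated hosts where seeds are hard to find. When the same hosts are searched
independently by two or three observers, the pattern of detections and misses
identifies the per-survey detectability and lets occupancy be corrected for it.

`occuseed` is aimed at plant-ecology and epidemiological surveys that record
repeated presence/absence of a parasite on discrete hosts: it fits the
latent-state occupancy model, ranks covariate models by small-sample AIC, and
quantifies how much ignoring detectability underestimates occupancy.

## The model

Each host *i* has a detection history *h<sub>i</sub>* over 2–3 survey
occasions (missing occasions simply contribute no factor). With occupancy
probability ψ<sub>i</sub> and per-survey detectability p<sub>i</sub>,

- a history with at least one detection, e.g. `010`, has probability
  ψ<sub>i</sub> (1−p<sub>i</sub>) p<sub>i</sub> (1−p<sub>i</sub>);
- an all-zero history confounds true absence with missed presence:
  Pr(000) = ψ<sub>i</sub> ∏<sub>j</sub>(1−p<sub>i</sub>) + (1−ψ<sub>i</sub>).

Both parameters take logit-linear site covariates —
logit(ψ<sub>i</sub>) = β₀ + β₁x<sub>i1</sub> + … — with host crown diameter
(m), presence of an infected neighbour within 50 m, and presence of an adult
infection on the focal host as the candidate covariates. The product of the
history probabilities over hosts is maximized numerically (BFGS with analytic
gradients, deterministic multi-start); candidate models are ranked by
AICc = −2l + 2K + 2K(K+1)/(n−K−1) with Akaike weights
w<sub>i</sub> ∝ exp(−ΔAICc<sub>i</sub>/2). Covariate subsets containing both
host size and adult infection in one term are excluded as collinear, giving
36 candidate models from the three covariates.

The naive comparison refits the occupancy term with p fixed at 1 (a logistic
regression of the detected-at-least-once indicator) and reports the per-host
difference between corrected and naive occupancy in percentage points.

## Worked example

```r
library(occuseed)

ds <- simulate_dataset(sim_config(seed = 42))   # 130 hosts, 5 populations
summarize_dataset(ds)
#> n = 130 hosts
#> crown diameter: 5.68 +/- 2.43 m
#> without infected neighbor: 84 (65%)
#> with adult infection: 16 (12%)
#> naive occupancy (>=1 detection): 0.800

sel <- run_selection(ds)                        # fit and rank all 36 models
best <- best_model(sel)
best
#> Occupancy model: psi(neighbor) p(size+neighbor)
#>                 estimate     se
#> psi_(Intercept)   1.2123 0.2965
#> psi_neighbor      1.9714 1.0767
#> p_(Intercept)     1.9689 0.4666
#> p_size           -0.1835 0.0738
#> p_neighbor        0.6549 0.3777
#> -2l = 361.06, K = 5, AICc = 371.54, n = 130, converged: TRUE

compare_naive(ds, best, fit_naive(ds, best$spec$psi_terms))
#> Naive vs detection-corrected occupancy over 130 hosts
#>   mean difference (corrected - naive): 3.78 percentage points
#>   max difference:                      4.45 percentage points
```

The selection table ranks models by AICc (best first, Δ = 0) with weights
summing to one over converged fits. The best model here puts the infected
neighbour in the occupancy term and size plus neighbour in the detectability
term: detectability falls with host size (−0.18 per metre on the logit scale)
and rises near infected neighbours, so the naive logistic fit underestimates
occupancy by 3.8 percentage points on average across these 130 hosts.

`run_pipeline()` chains the stages (read/simulate → summary → 36-model
selection → prediction grids → naive comparison) and writes
`selection.csv`, `predictions.csv`, `comparison.json`, `summary.json` and a
run log; `inst/cli/occuseed.R` is a thin command-line wrapper with
`simulate` / `fit` / `select` / `compare-naive` / `run` subcommands.

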