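---
title: "Planning trial invitations by dynamic stratified sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning trial invitations by dynamic stratified sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratinvite)
```

## The problem

Postal invitation from population registers is the standard way to recruit
large screening trials, and it reliably over-recruits the healthy and the
affluent. The consequences are a shortage of primary-outcome events (lost
power) and poor representation of deprived and minority groups (lost
generalisability and equity). `stratinvite` treats the invitation step as a
constrained allocation problem: each wave of invitations is the solution of
a linear programme whose objective prefers high-risk, under-served strata
and whose constraints guarantee slots fill, no practice is swamped, sexes
balance, all age bands are represented, and the booked cohort's expected
event rate clears a floor.

## Model and assumptions

A site is served by $J$ clusters split into $K$ bands (bands $1..K/2$ male,
$K/2+1..K$ female, paired by age). The decision variable is the proportion
$x_{jk}$ of the eligible list $n_{jk}$ to invite. Planning relies on two
nuisance inputs treated as known at plan time:

* **uptake** $u_{jk}$ — the probability an invited person books. Before any
  feedback this is a flat 0.1 (`flat_uptake()`); once bookings accrue it is
  the fit of $\mathrm{logit}(u_{jk}) = \beta_k + \gamma_1 z_{j1} +
  \gamma_2 z_{j2} + \gamma_3 z_{j2}^2$ by binomial maximum likelihood
  (`fit_uptake()`). $z_1$ is the cluster's deprivation score standardised
  across the supplied cluster set (the normalisation is a package choice);
  $z_2$ is bowel-screening uptake, a strong proxy for engagement with
  preventive care, kept with its quadratic term fixed (no variable
  selection).
* **event rate** $e_{jk}$ — expected primary-outcome events per booked
  participant over the trial horizon, obtained by mixing an age/sex ×
  deprivation-quintile table over each cluster's quintile composition
  (`expected_event_rate()`). The package requires $e$ and the event-floor
  configuration to be in the same per-participant unit; it does not convert
  between annual incidence and horizon risk.

Expected bookings per cell are $n_{jk} u_{jk} x_{jk}$, which assumes
independent booking decisions (a product-binomial response); household or
practice-level response clustering is not modelled, and the closed-loop
simulator makes the same assumption, so simulation results say nothing about
such clustering in real data.

## The wave programme

`build_wave_lp()` encodes: box bounds; headroom $x_{jk} + a_{jk} \le 1$
against the cumulative invited proportion $a_{jk}$; the booking equality
$\sum n u x = B_i$; per-cluster caps $\sum_k x_{jk} n_{jk} \le G_j \sum_k
n_{jk}$; age-band minima $\ge d_{ik}$; sex-parity equalities per age pair;
and the event floor $\sum e n u x \ge E_i$ (implemented as $\ge$, the usual
LP reading of a strict bound). Costs are
$c_{jk} = e_{jk}^{-1} + (1 + \max e^{-1})\,\tilde c_j$ with $\tilde c_j$ the
cluster preference rank; the multiplier uses the *global* maximum of
$e^{-1}$, which is what makes rank dominance hold for every pair of cells.
Rates are floored at $10^{-6}$ before inversion so degenerate inputs cannot
produce infinite costs.

Design choices where the design was genuinely open:

* **Parity is aggregated over clusters** (one equality per age pair, summing
  $j$), matching the constraint's purpose — the expected proportion of men
  who book is $S$ — rather than a per-cluster balance, which would be far
  more restrictive than the stated goal.
* **Band minima apply per age band**, summing the male and female halves;
  with exact parity the per-sex alternative ($D_k/2$ each) is equivalent and
  is available via `minima_by = "sex_band"`.
* **Infeasibility is reported, never relaxed.** `solve_wave()` signals a
  typed condition carrying the constraint families whose necessary
  conditions fail (capacity, minima, parity headroom, a greedy upper bound
  for the event floor). Silently shrinking a target is the wrong behaviour
  for a recruitment system; the operator must decide.
* **Determinism.** The simplex method is deterministic, and a lexicographic
  perturbation of $10^{-9}$ per variable index is added to the objective so
  that degenerate optima resolve the same way on any platform; identical
  inputs give byte-identical request files.
* **$a_{jk}$ counts requested invitations** (after opt-out inflation)
  divided by $n_{jk}$, because that is what the planner can observe;
  opt-out removal happens after the request, so the nominal proportion can
  overshoot 1 and is capped with a warning.

Solved proportions become integer requests by largest-remainder
apportionment within each cluster (ties broken by band index), capped at the
eligible headroom, then inflated by the cluster's opt-out factor and rounded
up.

## The dynamic policy

`policy_config()` holds the control rules. Defaults, with units:

| parameter | default | meaning |
|---|---|---|
| $D_k$ | 0.07, 0.08, 0.10, 0.12, 0.12, 0.06 | minimum share of bookings per age band |
| $S$ | 0.5 | target male share of expected bookings |
| $G_j$ | 0.5 | max proportion of a cluster invited per wave |
| E multiplier | 1.2 | event-rate floor = 1.2 × population rate |
| uptake adjustment | 1.0 | multiplier on predicted uptake |
| max waves | 4 | invitation rounds per site |

Wave targets: $B_1 = T/2$, $B_2 = (T-t_{++})/2$, $B_3 = 1.1(T-t_{++})$,
$B_4 = T-t_{++}$, floored at zero on overshoot (the overshoot case is a
package decision; the policy rules do not address it). Band minima:
$d_{1k} = D_k B_1$, later $d_{ik} = \max\{0, D_k(t_{++}+B_i) - t_{+k}\}$.
Event floor: $E_i = E(t_{++}+B_i) - \sum e_{jk} t_{jk}$, so a cohort already
booked at high risk relaxes the wave's requirement. The population rate
behind $E$ is the eligible-count-weighted mean of $e_{jk}$ over the site's
clusters — a package definition, since "the population at the site" admits
several readings. Wave 4 runs only if bookings after wave-3 feedback are
below 98% of capacity (threshold configurable; the policy's own trigger for
a fourth wave is simply "if required").

## What the synthetic generator emulates

`generate_site()` produces sites with the statistical structure the planner
assumes: log-normal cluster list sizes (mean ≈ 2000 eligible) with Dirichlet
age/sex composition around a national-like profile; a per-cluster
deprivation-quintile mix tilted by a latent deprivation propensity; a
bowel-screening covariate negatively correlated with deprivation; true
uptake from the logistic model with baseline ≈ 0.1, $\gamma_1 = -0.35$
(deprivation depresses uptake), $\gamma_2 = 1.2$, $\gamma_3 = -0.3$
(engagement raises it, mildly concave); and a rate table rising with age
(≈ 0.006 → 0.03 events per booked participant over the horizon, the
magnitude of 3-year advanced-cancer risk at these ages) and with deprivation
(≈ 35% Q1→Q5). Magnitudes are illustrative; directions match what trial
feedback data show. What it does **not** emulate: real geography, correlated
response behaviour, list-inflation error in $n_{jk}$, or capacity shocks —
passing closed-loop tests therefore demonstrates the controller's logic, not
field performance.

`rank_clusters_example()` is an explicitly illustrative ranking (distance
order with a diversity promotion); real deployments supply ranks as input
from their own rules.

## Numerical choices and problem sizes

The simplex solve uses the two-phase method from the `boot` package at
feasibility tolerance $10^{-10}$, audited post hoc at $10^{-6}$ relative;
a J = 50, K = 12 wave (≈ 600 variables) solves in about a second. The test
suite checks the solver against an exhaustive vertex-enumeration oracle on
100 random 4-variable instances, runs 50 closed-loop campaigns at J = 40,
T = 1000, and fits the uptake model at J = 200 with 500 invitations per
cell — sizes chosen to exercise every constraint at desk scale. Stochastic
closed-loop checks allow binomial sampling slack (two standard errors of the
relevant mean) around the expectation-level guarantees, since the policy's
floors constrain expectations while simulated bookings are random.

## Known limitations

* Uptake and event-rate inputs are treated as known; planning error from
  estimating them propagates unexamined (the uptake adjustment is the manual
  remedy).
* The programme optimises expectations; no chance constraints, so a small
  site can miss $B_i$ badly by luck.
* Continuous proportions are rounded post hoc rather than solving an integer
  programme; with cluster-level totals in the hundreds the gap is
  negligible.
* One site at a time; no joint optimisation across sites sharing clusters.
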