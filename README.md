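# stratinvite

Dynamic stratified-sampling invitation planning for trial recruitment.

Participants who volunteer for screening trials and cohorts are usually
healthier and less deprived than the population they are meant to represent.
This *healthy volunteer effect* erodes study power (too few primary-outcome
events in the control arm) and equity (under-representation of deprived and
minority groups). `stratinvite` is for trial units that recruit by postal
invitation from population registers and want the invitation step itself to
correct for both problems.

The package plans invitations for one recruitment **site** (a clinic location
or time window) served by **clusters** of potential participants (general
practices, say), each split into demographic **groups** (by default 12 bands:
six age bands 50–54 … 75–77 crossed with sex). Invitations go out in up to
four **waves**, with booking feedback between waves.

## The model

For wave *i*, choose the proportion `x_jk ∈ [0,1]` of the eligible list
`n_jk` to invite from cluster *j* and band *k*, minimising the expected cost
of bookings

    min Σ_jk c_jk · n_jk · u_jk · x_jk

where `u_jk` is expected uptake, subject to seven constraint families:

1. `0 ≤ x_jk ≤ 1`;
2. cumulative headroom `x_jk + a_jk ≤ 1` (`a_jk` = proportion already
   invited in earlier waves);
3. expected bookings hit the wave target: `Σ n_jk u_jk x_jk = B_i`;
4. no cluster has more than `G_j` of its list invited per wave (default 0.5);
5. each age band contributes at least `d_ik` expected bookings;
6. expected male and female bookings balance at target share `S`
   (default 0.5);
7. expected primary-outcome events among bookings reach a floor:
   `Σ e_jk n_jk u_jk x_jk ≥ E_i`.

Costs encode the recruitment priorities:

    c_jk = 1/e_jk + (1 + max 1/e) · rank_j

so low event-rate strata are expensive (mitigating the healthy volunteer
effect) and any invitation in a higher-preference cluster is cheaper than
any in a lower-preference one (rank dominance), letting local knowledge and
diversity goals drive cluster ordering. The dynamic policy sets
`B_1 = T/2`, `B_2 = (T − t₊₊)/2`, `B_3 = 1.1 (T − t₊₊)` and, if needed,
`B_4 = T − t₊₊` for capacity `T` and bookings-to-date `t₊₊`; band minima top
up toward overall shares `D_k` and the event floor tops up toward an overall
rate 20% above the site's population rate.

Uptake is predicted by a binomial-logistic model fitted to booking feedback,

    logit(u_jk) = β_k + γ1 z_j1 + γ2 z_j2 + γ3 z_j2²

with `z1` the cluster's normalised deprivation score and `z2` its
bowel-screening-uptake covariate. Event rates `e_jk` come from an
age/sex × deprivation-quintile rate table mixed over each cluster's quintile
composition.

## Worked example

```r
library(stratinvite)

gs <- generate_site(synthetic_scenario(J = 50, capacity = 1000), seed = 1)
plan <- plan_wave(gs$site, gs$state)   # wave 1, default policy
plan
#> Wave invitation plan
#>   expected bookings: 500.0 (target 500.0)
#>   expected events:   12.255
#>   objective value:   2.031e+05
#>   invitations requested: 4847 (pre-inflation 4533)
#>   constraints satisfied: TRUE
summary(plan)
#> Wave plan constraint audit
#>   bookings: achieved 500.00 vs target 500.00 [ok]
#>   max cluster invited proportion: 0.500 [ok]
#>   male booking share: 0.5000 [ok]
#>   expected events: 12.255 (floor 10.977) [ok]
#>   band minima: ok
```

The wave-1 target is half the 1000-slot capacity; at ~10% uptake that means
about 4,500 letters (4,847 after opt-out inflation). The plan drives the
preferred clusters to their 50% caps, balances expected male and female
bookings exactly, and books a cohort whose expected event rate (12.26/500)
exceeds the floor set 20% above the site's population rate.

Closing the loop:

```r
camp <- run_campaign(gs$site, 1000, policy_config(),
                     function(req, seed) simulate_bookings(req, gs$site$u, seed),
                     seed = 7)
camp
#> Invitation campaign: 3 wave(s), capacity 1000
#>   wave 1:   4847 requested,   528 booked
#>   wave 2:   2520 requested,   266 booked
#>   wave 3:   2433 requested,   228 booked
#>   final fill: 1022 / 1000 (102.2%)
```

A command-line front end (`plan`, `simulate`, `fit-uptake`, `validate`)
ships at `inst/cli/stratinvite`; see `?stratinvite_main`.

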