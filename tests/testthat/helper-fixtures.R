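# Shared fixtures, generated in code at test time.

# A tiny hand-specified site: 3 clusters, default 12-band scheme.
toy_site <- function(K = 12) {
  scheme <- group_scheme()
  mk <- function(id, rank, base, mix, z1, z2, oo = 1) {
    cluster_profile(id, rank, n = rep(base, K), imd_mix = mix,
                    z1 = z1, z2 = z2, optout_factor = oo)
  }
  clusters <- list(
    mk("A", 1L, 100, c(0.2, 0.2, 0.2, 0.2, 0.2), z1 = 0.0, z2 = 0.6),
    mk("B", 2L, 150, c(0.5, 0.3, 0.1, 0.1, 0.0), z1 = -1.0, z2 = 0.7, oo = 1.1),
    mk("C", 2L, 80, c(0.0, 0.1, 0.1, 0.3, 0.5), z1 = 1.0, z2 = 0.4, oo = 1.25)
  )
  r <- outer(seq(0.005, 0.03, length.out = K), seq(1, 1.4, length.out = 5))
  rates <- rate_table(r)
  site <- build_site(clusters, scheme, rates, uptake = 0.1)
  state <- site_state(200, 3, K)
  list(clusters = clusters, scheme = scheme, rates = rates,
       site = site, state = state)
}

# A minimal 2-band scheme (one age band x 2 sexes) for small LP instances.
tiny_scheme <- function() group_scheme(age_labels = "50-54")

# Random small wave LP (J clusters x 2 bands => 2J variables) built through
# the package's own constructor, plus the raw pieces the oracle needs.
random_tiny_lp <- function(seed, J = 2, with_events = TRUE) {
  set.seed(seed)
  scheme <- tiny_scheme()
  n <- matrix(sample(10:50, J * 2, replace = TRUE), J, 2)
  u <- matrix(runif(J * 2, 0.05, 0.5), J, 2)
  e <- matrix(runif(J * 2, 0.1, 1), J, 2)
  a <- matrix(runif(J * 2, 0, 0.4), J, 2)
  ranks <- sample(1:3, J, replace = TRUE)
  cap <- n * u * (1 - a)
  male_cap <- sum(cap[, 1]); female_cap <- sum(cap[, 2])
  B <- 0.6 * 2 * min(male_cap, female_cap)
  d <- 0.4 * B
  E_floor <- if (with_events) 0.8 * mean(e) * B else -Inf
  wc <- wave_constraints(B = B, d = d, E_floor = E_floor,
                         G = runif(1, 0.6, 1), S = 0.5)
  costs <- compute_costs(e, ranks)
  lp <- build_wave_lp(n, u, e, a, costs, wc, scheme)
  list(lp = lp, n = n, u = u, e = e, a = a, wc = wc, scheme = scheme)
}

# Deterministic site on which every constraint family binds: male uptake is
# about half of female (parity active), event rates climb steeply with age
# (young-band minima active), the event floor uses the default 20% enrichment
# rule, and the single rank-1 cluster is far too small to supply the wave-1
# booking target alone (its cluster cap binds).
binding_site <- function(seed = 101, J = 50, capacity = 1000) {
  H <- 6
  female_u <- seq(0.12, 0.18, length.out = H)
  beta <- qlogis(c(female_u / 2, female_u)) - 1.2 * 0.6 + 0.3 * 0.36
  sc <- synthetic_scenario(
    J = J, capacity = capacity,
    beta = beta, gamma1 = -0.35, gamma2 = 1.2, gamma3 = -0.3,
    rate_base = c(0.004, 0.007, 0.012, 0.019, 0.028, 0.038),
    rate_imd_gradient = 1.1
  )
  gs <- generate_site(sc, seed = seed)
  # one small, clearly preferred cluster; everyone else ranked below it
  sizes <- rowSums(gs$site$n)
  small <- which.min(sizes)
  ranks <- rank(replace(sizes, small, -Inf), ties.method = "first")
  gs$site$rank <- as.integer(ranks)
  for (j in seq_len(J)) gs$clusters[[j]]$rank <- gs$site$rank[j]
  gs
}
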