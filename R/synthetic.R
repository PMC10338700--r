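#' Synthetic site scenario
#'
#' Describes the statistical structure of a generated recruitment site. The
#' generator emulates the public data sources a live deployment would draw
#' on: cluster list sizes by age/sex, a deprivation-quintile mix per cluster,
#' a bowel-screening-uptake covariate, and an age/sex/deprivation event-rate
#' table.
#'
#' Defaults reflect the planning assumptions for an English multi-cancer
#' screening trial: cluster eligible-list sizes log-normal around ~2000;
#' age/sex composition Dirichlet around a national-like profile; uptake near
#' 0.1 at baseline, lower in deprived clusters and higher where
#' bowel-screening engagement is high; 3-year advanced-cancer risk per booked
#' participant rising with age (about 0.006 to 0.03) and deprivation (about
#' 35\% higher in the most deprived quintile than the least).
#'
#' @param J Number of clusters.
#' @param capacity Site capacity T.
#' @param scheme A \code{group_scheme}.
#' @param mean_list_size Mean eligible list size per cluster.
#' @param list_sdlog Log-scale SD of cluster list sizes.
#' @param age_profile Length-K/2 national-like age composition (summing to 1).
#' @param male_share Male proportion within each age band.
#' @param dirichlet_conc Concentration of the per-cluster age/sex Dirichlet.
#' @param imd_conc Base concentration of the per-cluster quintile Dirichlet.
#' @param imd_tilt Strength of the per-cluster deprivation tilt.
#' @param beta Length-K true uptake band intercepts (logit scale).
#' @param gamma1,gamma2,gamma3 True uptake covariate coefficients.
#' @param rate_base Length-K/2 baseline event risk per age band (quintile-3
#'   level).
#' @param rate_imd_gradient Multiplicative rate step per quintile of
#'   deprivation.
#' @param male_rate_excess Multiplier on male rates relative to female.
#' @param optout_range Range of opt-out inflation factors.
#' @return Object of class \code{synthetic_scenario}.
#' @export
synthetic_scenario <- function(J = 50L, capacity = 1000L,
                               scheme = group_scheme(),
                               mean_list_size = 2000,
                               list_sdlog = 0.45,
                               age_profile = c(0.21, 0.20, 0.18, 0.16, 0.15, 0.10),
                               male_share = 0.49,
                               dirichlet_conc = 300,
                               imd_conc = 2,
                               imd_tilt = 0.9,
                               beta = NULL,
                               gamma1 = -0.35, gamma2 = 1.2, gamma3 = -0.3,
                               rate_base = c(0.006, 0.009, 0.013, 0.018, 0.024, 0.030),
                               rate_imd_gradient = 1.078,
                               male_rate_excess = 1.1,
                               optout_range = c(1.0, 1.1)) {
  H <- scheme$K / 2L
  stopifnot(length(age_profile) == H, length(rate_base) == H)
  if (is.null(beta)) {
    # baseline uptake ~ 0.1, rising modestly with age; identical by sex.
    base_u <- seq(0.08, 0.13, length.out = H)
    beta <- stats::qlogis(rep(base_u, 2)) - gamma2 * 0.6 - gamma3 * 0.36
  }
  stopifnot(length(beta) == scheme$K)
  structure(list(J = as.integer(J), capacity = as.numeric(capacity),
                 scheme = scheme, mean_list_size = mean_list_size,
                 list_sdlog = list_sdlog,
                 age_profile = age_profile / sum(age_profile),
                 male_share = male_share, dirichlet_conc = dirichlet_conc,
                 imd_conc = imd_conc, imd_tilt = imd_tilt,
                 beta = beta, gamma1 = gamma1, gamma2 = gamma2,
                 gamma3 = gamma3, rate_base = rate_base,
                 rate_imd_gradient = rate_imd_gradient,
                 male_rate_excess = male_rate_excess,
                 optout_range = optout_range),
            class = "synthetic_scenario")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha / sum(alpha) else g <- g / sum(g)
  g
}

#' Generate a synthetic recruitment site
#'
#' Reproducible from the seed. The generated rate table increases strictly
#' with age within each sex and is non-decreasing in deprivation quintile;
#' true uptake decreases with deprivation and increases with the
#' bowel-screening covariate, matching the directions observed in trial
#' feedback data.
#'
#' @param scenario A \code{synthetic_scenario}.
#' @param seed Integer seed.
#' @return List with \code{clusters} (list of \code{cluster_profile}),
#'   \code{rates} (a \code{rate_table}), \code{true_uptake} (an
#'   \code{uptake_params}), \code{state} (a fresh wave-1 \code{site_state}),
#'   \code{site} (the assembled planning object using true uptake) and
#'   \code{scenario}.
#' @export
generate_site <- function(scenario = synthetic_scenario(), seed = 1L) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario; scheme <- sc$scheme
  H <- scheme$K / 2L
  set.seed(seed)
  # rate table: rows = bands (male 1..H then female), cols = quintiles
  r <- matrix(0, scheme$K, 5)
  for (h in seq_len(H)) {
    quint <- sc$rate_base[h] * sc$rate_imd_gradient^(0:4)
    r[h, ] <- quint * sc$male_rate_excess
    r[h + H, ] <- quint
  }
  rates <- rate_table(r)
  # per-cluster structure
  dep <- stats::rnorm(sc$J)                  # latent deprivation propensity
  dist_proxy <- stats::runif(sc$J, 0, 20)    # km to site, for example ranking
  clusters <- vector("list", sc$J)
  band_profile <- c(sc$age_profile * sc$male_share,
                    sc$age_profile * (1 - sc$male_share))
  for (j in seq_len(sc$J)) {
    size <- stats::rlnorm(1, log(sc$mean_list_size), sc$list_sdlog)
    comp <- rdirichlet1(band_profile * sc$dirichlet_conc)
    n <- round(size * comp)
    alpha <- sc$imd_conc * exp(sc$imd_tilt * dep[j] * ((1:5) - 3) / 2)
    w <- rdirichlet1(alpha)
    z2 <- stats::plogis(stats::qlogis(0.6) - 0.5 * dep[j] +
                          stats::rnorm(1, 0, 0.3))
    clusters[[j]] <- cluster_profile(
      cluster_id = sprintf("GP%03d", j), rank = 1L, n = n, imd_mix = w,
      z1 = 0,  # filled after normalisation below
      z2 = z2,
      optout_factor = stats::runif(1, sc$optout_range[1], sc$optout_range[2])
    )
  }
  # z1: normalised deprivation summary = standardised mean quintile
  mq <- vapply(clusters, function(cl) sum(cl$imd_mix * (1:5)), numeric(1))
  z1 <- if (sc$J > 1 && stats::sd(mq) > 0) (mq - mean(mq)) / stats::sd(mq) else mq * 0
  for (j in seq_len(sc$J)) clusters[[j]]$z1 <- z1[j]
  # example ranking: distance then diversity promotion
  ranks <- rank_clusters_example(dist_proxy, diversity = pmax(z1, 0))
  for (j in seq_len(sc$J)) clusters[[j]]$rank <- ranks[j]
  true_uptake <- uptake_params(sc$beta, sc$gamma1, sc$gamma2, sc$gamma3)
  site <- build_site(clusters, scheme, rates, true_uptake)
  state <- site_state(sc$capacity, sc$J, scheme$K)
  list(clusters = clusters, rates = rates, true_uptake = true_uptake,
       state = state, site = site, scenario = sc, dist_proxy = dist_proxy)
}

#' Simulate booking feedback
#'
#' Bookings per cell are independent Binomial(requests_jk, u*_jk) draws,
#' matching the product-binomial likelihood the uptake model assumes.
#'
#' @param requests J x K non-negative integer matrix.
#' @param u J x K true uptake probabilities.
#' @param seed Integer seed.
#' @return J x K integer matrix of bookings.
#' @export
simulate_bookings <- function(requests, u, seed = 1L) {
  requests <- as.matrix(requests)
  if (any(requests < 0)) stop("requests must be non-negative")
  u <- as.matrix(u)
  stopifnot(all(dim(u) == dim(requests)), all(u >= 0), all(u <= 1))
  set.seed(seed)
  matrix(stats::rbinom(length(requests), as.vector(requests), as.vector(u)),
         nrow(requests), ncol(requests))
}

#' Example cluster ranking: distance with diversity promotion
#'
#' An illustrative stand-in for site-specific preference rules (which in
#' practice combine location, ethnicity and deprivation): clusters are
#' ordered by distance, then any cluster whose diversity proxy exceeds
#' \code{promote_above} is promoted by \code{promote_by} positions. Ties are
#' broken by position (cluster order), making the result deterministic.
#'
#' @param distance Per-cluster distance proxy (smaller = nearer = preferred).
#' @param diversity Per-cluster diversity proxy (larger = promoted).
#' @param promote_above Threshold above which promotion applies.
#' @param promote_by Number of rank positions a promoted cluster gains.
#' @return Integer vector of ranks (1 = highest preference).
#' @export
rank_clusters_example <- function(distance, diversity = rep(0, length(distance)),
                                  promote_above = 1, promote_by = 5L) {
  J <- length(distance)
  base <- rank(distance, ties.method = "first")
  score <- base - ifelse(diversity > promote_above, promote_by, 0)
  as.integer(rank(score, ties.method = "first"))
}
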