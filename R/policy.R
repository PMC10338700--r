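#' Invitation policy configuration
#'
#' The dynamic control rules of the invitation process: per-wave booking
#' targets, minimum representation by age band, the cluster cap, sex parity
#' and the event-rate floor.
#'
#' Defaults are the trial's working values: minimum booking shares per age
#' band of 7, 8, 10, 12, 12 and 6 per cent (youngest to oldest); equal male
#' and female bookings (S = 0.5); at most half of any cluster's list invited
#' per wave (G = 0.5); and a minimum expected event rate among bookings 20 per
#' cent above the site's population rate (E_multiplier = 1.2).
#'
#' @param D Minimum booking proportions per age band (length K/2).
#' @param S Target male share of expected bookings.
#' @param G Cluster cap: maximum proportion of a cluster's list invited per
#'   wave (scalar, or one value per cluster).
#' @param E_multiplier Event-floor multiplier on the site's population event
#'   rate (>= 1; 1.2 means 20\% enrichment).
#' @param max_waves Maximum number of invitation waves.
#' @param uptake_adjustment Positive multiplier applied to predicted uptake
#'   (2.0 doubles it); used when feedback shows the uptake assumption is
#'   poorly calibrated.
#' @param minima_by Whether the band minima apply per age band (summing both
#'   sexes; default) or per sex band (half each).
#' @param wave4_threshold Wave 4 is planned only if bookings after wave-3
#'   feedback are below this fraction of capacity.
#' @return Object of class \code{policy_config}.
#' @export
policy_config <- function(D = c(0.07, 0.08, 0.10, 0.12, 0.12, 0.06),
                          S = 0.5, G = 0.5, E_multiplier = 1.2,
                          max_waves = 4L, uptake_adjustment = 1.0,
                          minima_by = c("age_band", "sex_band"),
                          wave4_threshold = 0.98) {
  minima_by <- match.arg(minima_by)
  if (any(D < 0) || sum(D) > 1 + 1e-12)
    stop("band minima D must be non-negative and sum to at most 1")
  if (S <= 0 || S >= 1) stop("S must lie in (0, 1)")
  if (any(G <= 0 | G > 1)) stop("G must lie in (0, 1]")
  if (E_multiplier < 1) stop("E_multiplier must be >= 1")
  if (uptake_adjustment <= 0) stop("uptake_adjustment must be positive")
  structure(list(D = D, S = S, G = G, E_multiplier = E_multiplier,
                 max_waves = as.integer(max_waves),
                 uptake_adjustment = uptake_adjustment,
                 minima_by = minima_by,
                 wave4_threshold = wave4_threshold),
            class = "policy_config")
}

#' Per-wave booking target
#'
#' B_1 = T/2; B_2 = (T - t++)/2; B_3 = 1.1 (T - t++); B_4 = T - t++. Wave 3
#' deliberately overshoots remaining capacity by 10\% so that slots fill even
#' when some who book cannot attend. Targets are floored at zero when a site
#' has over-booked.
#'
#' @param wave Wave index in 1..max_waves.
#' @param capacity Total slots T.
#' @param booked Total bookings to date t++.
#' @param max_waves Maximum wave count.
#' @return The target expected bookings B_i for the wave.
#' @export
booking_target <- function(wave, capacity, booked = 0, max_waves = 4L) {
  if (wave < 1 || wave > max_waves)
    stop("wave must lie in 1..", max_waves)
  remaining <- capacity - booked
  B <- switch(wave,
              capacity / 2,
              remaining / 2,
              1.1 * remaining,
              remaining)
  if (is.null(B)) B <- remaining   # waves beyond 4 under a larger max_waves
  max(0, B)
}

#' Per-wave band minimum expected bookings
#'
#' Wave 1: d_k = D_k B_1. Later waves top up toward the overall target share:
#' d_k = max(0, D_k (t++ + B_i) - t+k), with t+k the bookings to date in age
#' band k (both sexes).
#'
#' @param wave Wave index.
#' @param policy A \code{policy_config}.
#' @param B The wave's booking target.
#' @param t_band Bookings to date per age band (length K/2; both sexes
#'   summed). Ignored at wave 1.
#' @param t_total Total bookings to date.
#' @return Numeric vector of minima d_k, one per age band.
#' @export
group_minimums <- function(wave, policy, B, t_band = NULL, t_total = 0) {
  D <- policy$D
  if (wave == 1L) return(D * B)
  if (is.null(t_band) || length(t_band) != length(D))
    stop("t_band must have one entry per age band (", length(D), ")")
  pmax(0, D * (t_total + B) - t_band)
}

#' Per-wave minimum expected events
#'
#' The floor is set so that, if met exactly each wave, the final expected
#' event rate among bookings is at least E = E_multiplier x the population
#' rate: E_i = E (t++ + B_i) - sum_jk e_jk t_jk. A cohort already booked at
#' high risk reduces (possibly below zero, making the constraint vacuous) the
#' events required from the current wave.
#'
#' @param policy A \code{policy_config}.
#' @param population_rate The site's general-population event rate, in the
#'   same per-participant unit as \code{e}.
#' @param B The wave's booking target.
#' @param ledger J x K bookings to date.
#' @param e J x K expected event rates.
#' @return The event floor E_i (may be <= 0).
#' @export
event_floor <- function(policy, population_rate, B, ledger, e) {
  E <- policy$E_multiplier * population_rate
  t_total <- sum(ledger)
  E * (t_total + B) - sum(e * ledger)
}

#' Site population event rate
#'
#' The eligible-population-weighted mean of the expected event rates over all
#' clusters serving the site.
#'
#' @param n J x K eligible counts.
#' @param e J x K expected event rates.
#' @return Scalar rate.
#' @export
population_event_rate <- function(n, e) {
  if (sum(n) == 0) stop("site has no eligible population")
  sum(n * e) / sum(n)
}

#' Plan one invitation wave
#'
#' Composes the dynamic policy rules (booking target, band minima, event
#' floor), the cost construction and the linear programme into a solved,
#' rounded invitation plan. Predicted uptake is multiplied by the policy's
#' uptake adjustment before planning.
#'
#' @param site A site object as returned by \code{\link{build_site}} (or any
#'   list with elements \code{ids}, \code{rank}, \code{n}, \code{optout},
#'   \code{e}, \code{u}, \code{scheme}).
#' @param state A \code{site_state}.
#' @param policy A \code{policy_config}.
#' @param wave Wave index; defaults to the state's current wave.
#' @return A \code{wave_plan} with integer \code{requests} filled in.
#' @export
plan_wave <- function(site, state, policy = policy_config(),
                      wave = state$wave) {
  scheme <- site$scheme
  u <- site$u * policy$uptake_adjustment
  if (any(u > 1)) u <- pmin(u, 1)
  tot <- booking_totals(state)
  B <- booking_target(wave, state$capacity, tot$total,
                      max_waves = policy$max_waves)
  t_band <- as.numeric(collapse_sexes(matrix(tot$per_group, 1), scheme))
  d <- group_minimums(wave, policy, B, t_band = t_band, t_total = tot$total)
  pop_rate <- population_event_rate(site$n, site$e)
  E_i <- event_floor(policy, pop_rate, B, state$ledger, site$e)
  wc <- wave_constraints(B = B, d = d, E_floor = E_i, G = policy$G,
                         S = policy$S, minima_by = policy$minima_by)
  costs <- compute_costs(site$e, site$rank)
  lp <- build_wave_lp(site$n, u, site$e, state$invited, costs, wc, scheme)
  plan <- solve_wave(lp)
  plan <- round_invitations(plan, site$optout)
  plan$wave <- wave
  plan$population_rate <- pop_rate
  plan
}

#' Assemble a site object for planning
#'
#' Bundles cluster profiles with their derived event-rate and uptake matrices
#' into the flat structure the planner consumes.
#'
#' @param clusters List of \code{cluster_profile} objects.
#' @param scheme A \code{group_scheme}.
#' @param rates A \code{rate_table} (used to derive e_jk), or a precomputed
#'   J x K matrix \code{e}.
#' @param uptake An \code{uptake_params} (used to derive u_jk), a precomputed
#'   J x K matrix, or a single proportion for flat uptake.
#' @return A list with cluster matrices plus \code{e}, \code{u}, \code{scheme}.
#' @export
build_site <- function(clusters, scheme, rates, uptake) {
  sm <- site_matrices(clusters, scheme)
  e <- if (inherits(rates, "rate_table")) event_rate_matrix(rates, clusters)
       else as.matrix(rates)
  u <- if (inherits(uptake, "uptake_params")) uptake_matrix(uptake, clusters)
       else if (length(uptake) == 1L) flat_uptake(uptake, length(clusters), scheme$K)
       else as.matrix(uptake)
  stopifnot(all(dim(e) == dim(sm$n)), all(dim(u) == dim(sm$n)))
  c(sm, list(e = e, u = u, scheme = scheme, clusters = clusters))
}

#' Run a closed-loop invitation campaign
#'
#' Plans wave 1, simulates (or observes, via the supplied simulator) booking
#' feedback, updates the state, and repeats until capacity is filled or the
#' wave limit is reached. Wave 4 is planned only when bookings after wave-3
#' feedback fall below \code{policy$wave4_threshold} of capacity. The history
#' is fully reproducible from the seed.
#'
#' @param site A site object (see \code{\link{build_site}}).
#' @param capacity Total slots T.
#' @param policy A \code{policy_config}.
#' @param booking_simulator Function \code{(requests, seed)} returning a J x K
#'   matrix of bookings; see \code{\link{simulate_bookings}}.
#' @param seed Integer seed governing all randomness in the campaign.
#' @param refit_uptake If TRUE, the uptake model is refitted from cumulative
#'   invitations and bookings after each wave and used for the next.
#' @return Object of class \code{campaign}: per-wave plans and feedback, the
#'   final state, and fill/representation summaries.
#' @export
run_campaign <- function(site, capacity, policy = policy_config(),
                         booking_simulator, seed = 1L,
                         refit_uptake = FALSE) {
  scheme <- site$scheme
  J <- nrow(site$n); K <- scheme$K
  if (capacity <= 0) {
    return(structure(list(waves = list(),
                          state = NULL, capacity = capacity),
                     class = "campaign"))
  }
  state <- site_state(capacity, J, K, max_waves = policy$max_waves)
  waves <- list()
  cum_req <- matrix(0, J, K); cum_bk <- matrix(0, J, K)
  for (w in seq_len(policy$max_waves)) {
    tot <- booking_totals(state)
    if (tot$total >= capacity) break
    if (w == policy$max_waves &&
        tot$total >= policy$wave4_threshold * capacity) break
    plan <- plan_wave(site, state, policy, wave = w)
    bookings <- booking_simulator(plan$requests, seed = seed * 1000L + w)
    bookings <- pmin(bookings, plan$requests)
    cum_req <- cum_req + plan$requests; cum_bk <- cum_bk + bookings
    waves[[length(waves) + 1L]] <- list(wave = w, plan = plan,
                                        requests = plan$requests,
                                        bookings = bookings)
    if (w < policy$max_waves) {
      state <- apply_feedback(state, plan$requests, bookings, site$n)
      if (refit_uptake && sum(cum_req) > 0) {
        fit <- fit_uptake(cum_req, cum_bk, site$z1, site$z2)
        site$u <- uptake_matrix(fit$params, site$clusters)
      }
    } else {
      state$ledger <- state$ledger + bookings
    }
  }
  structure(list(waves = waves, state = state, capacity = capacity,
                 policy = policy, seed = seed),
            class = "campaign")
}

#' @export
print.campaign <- function(x, ...) {
  cat("Invitation campaign:", length(x$waves), "wave(s), capacity",
      x$capacity, "\n")
  for (wv in x$waves) {
    cat(sprintf("  wave %d: %6d requested, %5d booked\n",
                wv$wave, sum(wv$requests), sum(wv$bookings)))
  }
  if (!is.null(x$state)) {
    tot <- booking_totals(x$state)
    cat(sprintf("  final fill: %d / %d (%.1f%%)\n", as.integer(tot$total),
                as.integer(x$capacity), 100 * tot$total / x$capacity))
  }
  invisible(x)
}

#' @export
summary.campaign <- function(object, ...) {
  if (!length(object$waves)) return(invisible(NULL))
  scheme <- object$waves[[1]]$plan$lp$scheme
  tot <- booking_totals(object$state)
  band <- as.numeric(collapse_sexes(matrix(tot$per_group, 1), scheme))
  res <- list(
    fill = tot$total / object$capacity,
    band_shares = if (tot$total > 0) band / tot$total else band * 0,
    total_requested = sum(vapply(object$waves, function(w) sum(w$requests), numeric(1))),
    total_booked = tot$total
  )
  cat(sprintf("fill %.1f%%; band shares: %s\n", 100 * res$fill,
              paste(sprintf("%.3f", res$band_shares), collapse = " ")))
  invisible(res)
}
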