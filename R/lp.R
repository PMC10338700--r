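#' Invitation cost matrix
#'
#' Builds the relative cost c_jk of recruiting one booking from cluster j,
#' band k:
#' \deqn{c_{jk} = e_{jk}^{-1} + \{1 + \max(e^{-1})\}\,\tilde c_j}
#' where the maximum runs over all clusters and bands and \eqn{\tilde c_j} is
#' the cluster's preference rank (1 = highest). The first term makes low
#' event-rate strata expensive; the second enforces rank dominance: every cost
#' in a rank-r cluster is strictly below every cost in a rank-(r+1) cluster,
#' so the optimum exhausts higher-preference clusters before touching lower
#' ones. Rates are floored at \code{rate_floor} before inversion so that
#' near-zero rates cannot produce infinite costs.
#'
#' @param e J x K matrix of expected event rates (per booked participant).
#' @param ranks Integer vector of J cluster preference ranks (>= 1).
#' @param rate_floor Lower floor applied to \code{e} before inversion.
#' @return Object of class \code{cost_matrix} with element \code{c} (J x K).
#' @export
compute_costs <- function(e, ranks, rate_floor = 1e-6) {
  e <- as.matrix(e)
  if (any(!is.finite(e)) || any(e < 0))
    stop("event rates must be finite and non-negative")
  if (any(e <= 0))
    e <- pmax(e, rate_floor)
  if (any(e < rate_floor)) e <- pmax(e, rate_floor)
  if (any(ranks < 1) || any(ranks != round(ranks)))
    stop("ranks must be positive integers")
  inv <- 1 / e
  M <- 1 + max(inv)
  cc <- sweep(inv, 1, M * as.numeric(ranks), `+`)
  structure(list(c = cc, rate_floor = rate_floor), class = "cost_matrix")
}

#' Per-wave constraint set
#'
#' @param B Target expected bookings for the wave.
#' @param d Minimum expected bookings per age band (length K/2 when minima are
#'   applied at the age-band level, length K for per-sex-band minima).
#' @param E_floor Minimum expected events among the wave's expected bookings;
#'   non-positive values make the constraint vacuous.
#' @param G Per-cluster cap on the proportion of the cluster's list invited in
#'   the wave; scalar or length-J vector, in (0, 1].
#' @param S Target expected male share of bookings, in (0, 1).
#' @param minima_by Either \code{"age_band"} (default: the male and female
#'   halves of an age pair share one minimum) or \code{"sex_band"}.
#' @return Object of class \code{wave_constraints}.
#' @export
wave_constraints <- function(B, d, E_floor = -Inf, G = 0.5, S = 0.5,
                             minima_by = c("age_band", "sex_band")) {
  minima_by <- match.arg(minima_by)
  if (B < 0) stop("booking target B must be non-negative")
  if (any(d < 0)) stop("band minima d must be non-negative")
  if (any(G <= 0 | G > 1)) stop("cluster caps G must lie in (0, 1]")
  if (S <= 0 || S >= 1) stop("male share target S must lie in (0, 1)")
  structure(list(B = B, d = d, E_floor = E_floor, G = G, S = S,
                 minima_by = minima_by), class = "wave_constraints")
}

#' Build the per-wave linear programme
#'
#' Encodes the invitation problem: choose proportions x_jk in [0, 1] to
#' minimise expected booking cost sum c n u x subject to seven constraint
#' families: (1) box bounds; (2) cumulative-invitation headroom
#' x_jk <= 1 - a_jk; (3) expected bookings sum n u x = B; (4) per-cluster cap
#' sum_k x n <= G_j sum_k n; (5) band minima sum n u x >= d; (6) sex parity,
#' for each age pair sum_j (n u x)_male (1-S)/S = sum_j (n u x)_female;
#' (7) expected events sum e n u x >= E_floor. Cells with n_jk = 0 or no
#' headroom are fixed at 0 and dropped from the programme. A lexicographic
#' tie-break perturbation of 1e-9 per variable index is added to the objective
#' so that degenerate optima resolve deterministically.
#'
#' @param n,u,e J x K matrices: eligible counts, expected uptake, event rates.
#' @param a J x K matrix of cumulative invited proportions.
#' @param costs A \code{cost_matrix} (or bare J x K matrix).
#' @param wc A \code{wave_constraints}.
#' @param scheme A \code{group_scheme}.
#' @return Object of class \code{wave_lp}: objective, constraint systems and
#'   the index map back to the J x K grid.
#' @export
build_wave_lp <- function(n, u, e, a, costs, wc, scheme) {
  n <- as.matrix(n); u <- as.matrix(u); e <- as.matrix(e); a <- as.matrix(a)
  cc <- if (inherits(costs, "cost_matrix")) costs$c else as.matrix(costs)
  J <- nrow(n); K <- ncol(n)
  stopifnot(K == scheme$K, all(dim(u) == c(J, K)), all(dim(e) == c(J, K)),
            all(dim(a) == c(J, K)), all(dim(cc) == c(J, K)))
  ub <- pmax(0, 1 - a)                      # constraint 2 folded into bounds
  active <- which(n > 0 & ub > 1e-12)       # linear indices into J x K grid
  nv <- length(active)
  nux <- (n * u)[active]                    # expected bookings per unit x
  idx <- arrayInd(active, c(J, K))
  obj <- (cc * n * u)[active] + 1e-9 * ((idx[, 1] - 1) * K + idx[, 2])
  # inequality systems, rows as lists then rbind once
  A1 <- list(); b1 <- numeric(0)            # <=
  A2 <- list(); b2 <- numeric(0)            # >=
  A3 <- list(); b3 <- numeric(0)            # ==
  # (1,2) upper bounds
  if (nv > 0) {
    A1 <- c(A1, list(diag(nv)))
    b1 <- c(b1, ub[active])
  }
  # (3) bookings equality
  A3 <- c(A3, list(matrix(nux, 1))); b3 <- c(b3, wc$B)
  # (4) cluster caps
  G <- rep(wc$G, length.out = J)
  for (j in seq_len(J)) {
    sel <- idx[, 1] == j
    if (any(sel)) {
      row <- numeric(nv); row[sel] <- n[active[sel]]
      A1 <- c(A1, list(matrix(row, 1))); b1 <- c(b1, G[j] * sum(n[j, ]))
    }
  }
  # (5) band minima
  H <- K %/% 2L
  if (wc$minima_by == "age_band") {
    if (length(wc$d) != H) stop("d must have one entry per age band (", H, ")")
    for (h in seq_len(H)) {
      sel <- idx[, 2] == h | idx[, 2] == h + H
      row <- numeric(nv); row[sel] <- nux[sel]
      A2 <- c(A2, list(matrix(row, 1))); b2 <- c(b2, wc$d[h])
    }
  } else {
    if (length(wc$d) != K) stop("d must have one entry per band (", K, ")")
    for (k in seq_len(K)) {
      sel <- idx[, 2] == k
      row <- numeric(nv); row[sel] <- nux[sel]
      A2 <- c(A2, list(matrix(row, 1))); b2 <- c(b2, wc$d[k])
    }
  }
  # (6) sex parity per age pair
  for (h in seq_len(H)) {
    m_sel <- idx[, 2] == h; f_sel <- idx[, 2] == h + H
    row <- numeric(nv)
    row[m_sel] <- nux[m_sel] * (1 - wc$S) / wc$S
    row[f_sel] <- -nux[f_sel]
    A3 <- c(A3, list(matrix(row, 1))); b3 <- c(b3, 0)
  }
  # (7) event floor
  if (is.finite(wc$E_floor) && wc$E_floor > 0) {
    A2 <- c(A2, list(matrix(e[active] * nux, 1))); b2 <- c(b2, wc$E_floor)
  }
  structure(list(
    obj = obj, active = active, dim = c(J, K),
    A1 = do.call(rbind, A1), b1 = b1,
    A2 = if (length(A2)) do.call(rbind, A2) else NULL, b2 = b2,
    A3 = do.call(rbind, A3), b3 = b3,
    n = n, u = u, e = e, a = a, wc = wc, scheme = scheme
  ), class = "wave_lp")
}

#' Solve the per-wave linear programme
#'
#' Solves with the two-phase simplex method. On success returns a
#' \code{wave_plan} holding the solved proportions, the expected bookings and
#' events they imply, the objective value and a per-constraint slack report.
#' On infeasibility a typed condition of class
#' \code{stratinvite_infeasible} is signalled, carrying a structured report of
#' the constraint families whose necessary conditions fail (no silent
#' relaxation ever occurs).
#'
#' @param lp A \code{wave_lp}.
#' @param tol Relative feasibility tolerance for the post-solve audit.
#' @return Object of class \code{wave_plan}.
#' @export
solve_wave <- function(lp, tol = 1e-6) {
  stopifnot(inherits(lp, "wave_lp"))
  J <- lp$dim[1]; K <- lp$dim[2]
  x <- matrix(0, J, K)
  if (length(lp$active) == 0L) {
    if (lp$wc$B > tol) stop(infeasibility_condition(lp, NULL))
    return(new_wave_plan(x, lp, objective = 0))
  }
  if (lp$wc$B <= tol) {
    # zero booking target forces x = 0; feasible only if nothing else is owed
    if (all(lp$wc$d <= tol) &&
        (!is.finite(lp$wc$E_floor) || lp$wc$E_floor <= tol))
      return(new_wave_plan(x, lp, objective = 0))
    stop(infeasibility_condition(lp, NULL))
  }
  res <- boot::simplex(a = lp$obj,
                       A1 = lp$A1, b1 = lp$b1,
                       A2 = lp$A2, b2 = lp$b2,
                       A3 = lp$A3, b3 = lp$b3,
                       maxi = FALSE, n.iter = 100 * (length(lp$obj) + 20),
                       eps = 1e-10)
  if (res$solved != 1) stop(infeasibility_condition(lp, res))
  x[lp$active] <- pmin(pmax(unname(res$soln), 0), 1)
  new_wave_plan(x, lp, objective = unname(res$value))
}

new_wave_plan <- function(x, lp, objective) {
  nu <- lp$n * lp$u
  eb <- sum(nu * x)
  ev <- sum(lp$e * nu * x)
  structure(list(
    x = x, objective_value = objective,
    expected_bookings = eb, expected_events = ev,
    requests = NULL,
    diagnostics = audit_wave_plan_matrices(x, lp),
    lp = lp
  ), class = "wave_plan")
}

# Build the infeasibility report: which families' necessary conditions fail.
infeasibility_condition <- function(lp, res) {
  n <- lp$n; u <- lp$u; e <- lp$e; a <- lp$a; wc <- lp$wc
  ub <- pmax(0, 1 - a)
  cap <- n * u * ub                       # max expected bookings per cell
  fams <- character(0)
  if (sum(cap) < wc$B)
    fams <- c(fams, sprintf(
      "bookings: target B = %.6g exceeds maximum achievable expected bookings %.6g",
      wc$B, sum(cap)))
  H <- ncol(n) %/% 2L
  if (wc$minima_by == "age_band") {
    for (h in seq_len(H)) {
      avail <- sum(cap[, c(h, h + H)])
      if (avail < wc$d[h])
        fams <- c(fams, sprintf("band minima: age band %d needs %.6g, at most %.6g achievable",
                                h, wc$d[h], avail))
    }
  }
  if (sum(wc$d) > wc$B)
    fams <- c(fams, sprintf("band minima: sum of minima %.6g exceeds booking target %.6g",
                            sum(wc$d), wc$B))
  # parity: male share S of B must be achievable within male/female headroom
  male_cap <- sum(cap[, seq_len(H)]); female_cap <- sum(cap[, H + seq_len(H)])
  if (male_cap < wc$S * wc$B)
    fams <- c(fams, "sex parity: male headroom below S * B")
  if (female_cap < (1 - wc$S) * wc$B)
    fams <- c(fams, "sex parity: female headroom below (1 - S) * B")
  if (is.finite(wc$E_floor) && wc$E_floor > 0) {
    # greedy upper bound on achievable events at expected bookings B
    ord <- order(e, decreasing = TRUE)
    take <- cumsum(cap[ord]); w <- which(take >= wc$B)
    emax <- if (length(w)) {
      i <- w[1]
      sum((e * cap)[ord[seq_len(i - 1)]]) +
        e[ord[i]] * (wc$B - if (i > 1) take[i - 1] else 0)
    } else sum(e * cap)
    if (emax < wc$E_floor)
      fams <- c(fams, sprintf("event floor: at most %.6g expected events achievable, floor is %.6g",
                              emax, wc$E_floor))
  }
  if (!length(fams))
    fams <- "infeasible through interaction of constraint families (no single family's necessary condition fails)"
  structure(class = c("stratinvite_infeasible", "error", "condition"),
            list(message = paste0("wave LP infeasible:\n  ",
                                  paste(fams, collapse = "\n  ")),
                 call = NULL, families = fams))
}

# Recompute satisfaction of all seven constraint families from raw inputs.
audit_wave_plan_matrices <- function(x, lp, tol = 1e-6) {
  n <- lp$n; u <- lp$u; e <- lp$e; a <- lp$a; wc <- lp$wc
  nu <- n * u
  B_hat <- sum(nu * x)
  rel <- function(v, ref) abs(v) / max(1, abs(ref))
  out <- list()
  out$bounds_ok <- all(x >= -tol) && all(x <= 1 + tol)
  out$history_ok <- all(x + a <= 1 + tol)
  out$bookings <- c(target = wc$B, achieved = B_hat)
  out$bookings_ok <- rel(B_hat - wc$B, wc$B) <= tol
  G <- rep(wc$G, length.out = nrow(n))
  cl_inv <- rowSums(x * n); cl_cap <- G * rowSums(n)
  out$cluster_cap <- cbind(invited = cl_inv, cap = cl_cap)
  out$cluster_cap_ok <- all(cl_inv <= cl_cap * (1 + tol) + tol)
  H <- ncol(n) %/% 2L
  if (wc$minima_by == "age_band") {
    band_book <- vapply(seq_len(H), function(h) sum(nu[, c(h, h + H)] * x[, c(h, h + H)]),
                        numeric(1))
  } else {
    band_book <- colSums(nu * x)
  }
  out$band_minima <- cbind(achieved = band_book, minimum = wc$d)
  out$band_minima_ok <- all(band_book >= wc$d * (1 - tol) - tol)
  male <- sum(nu[, seq_len(H)] * x[, seq_len(H)])
  out$male_share <- if (B_hat > 0) male / B_hat else NA_real_
  out$parity_ok <- all(vapply(seq_len(H), function(h) {
    m <- sum(nu[, h] * x[, h]); f <- sum(nu[, h + H] * x[, h + H])
    abs(m * (1 - wc$S) / wc$S - f) <= tol * max(1, m + f)
  }, logical(1)))
  ev <- sum(e * nu * x)
  out$events <- c(floor = wc$E_floor, achieved = ev)
  out$event_floor_ok <- !is.finite(wc$E_floor) || wc$E_floor <= 0 ||
    ev >= wc$E_floor * (1 - tol)
  out$all_ok <- out$bounds_ok && out$history_ok && out$bookings_ok &&
    out$cluster_cap_ok && out$band_minima_ok && out$parity_ok &&
    out$event_floor_ok
  out
}

#' Audit a solved plan against all constraint families
#'
#' Independently re-evaluates the seven constraint families from the raw
#' inputs stored with the plan.
#'
#' @param plan A \code{wave_plan}.
#' @param tol Relative tolerance.
#' @return The diagnostics list; element \code{all_ok} is TRUE when every
#'   family is satisfied.
#' @export
audit_wave_plan <- function(plan, tol = 1e-6) {
  audit_wave_plan_matrices(plan$x, plan$lp, tol = tol)
}

#' Convert solved proportions to integer invitation requests
#'
#' Within each cluster, raw counts x_jk n_jk are apportioned to integers by
#' the largest-remainder method so that the cluster total equals the rounded
#' cluster sum; counts are capped at the pre-wave eligible headroom
#' floor(n_jk (1 - a_jk)); finally each cluster's counts are inflated by its
#' opt-out factor and rounded up, since opted-out patients are removed only
#' after a request is made.
#'
#' @param plan A \code{wave_plan}.
#' @param optout_factor Per-cluster inflation factors (length J, >= 1).
#' @return The plan with \code{requests} (J x K integer matrix, inflated) and
#'   \code{requests_raw} (pre-inflation) filled in.
#' @export
round_invitations <- function(plan, optout_factor = rep(1, nrow(plan$x))) {
  x <- plan$x; n <- plan$lp$n; a <- plan$lp$a
  J <- nrow(x); K <- ncol(x)
  optout_factor <- rep(optout_factor, length.out = J)
  if (any(optout_factor < 1)) stop("optout factors must be >= 1")
  headroom <- floor(n * pmax(0, 1 - a) + 1e-9)
  raw <- x * n
  req <- matrix(0L, J, K)
  for (j in seq_len(J)) {
    req[j, ] <- largest_remainder(raw[j, ], round(sum(raw[j, ])))
  }
  req <- pmin(req, headroom)
  inflated <- ceiling(req * matrix(optout_factor, J, K) - 1e-9)
  plan$requests_raw <- req
  plan$requests <- inflated
  plan
}

# Apportion non-negative reals to integers summing to `total` by largest remainder.
# Ties broken by position (earlier index wins), making the result deterministic.
largest_remainder <- function(v, total) {
  fl <- floor(v + 1e-12)
  rem <- total - sum(fl)
  if (rem > 0) {
    frac <- v - fl
    ord <- order(frac, decreasing = TRUE)   # stable: ties by index
    fl[ord[seq_len(min(rem, length(v)))]] <- fl[ord[seq_len(min(rem, length(v)))]] + 1
  } else if (rem < 0) {
    frac <- v - fl
    ord <- order(frac, fl > 0)              # remove from smallest fractions first
    pos <- ord[fl[ord] > 0]
    take <- pos[seq_len(min(-rem, length(pos)))]
    fl[take] <- fl[take] - 1
  }
  as.integer(fl)
}

#' @export
print.wave_plan <- function(x, ...) {
  cat("Wave invitation plan\n")
  cat(sprintf("  expected bookings: %.1f (target %.1f)\n",
              x$expected_bookings, x$lp$wc$B))
  cat(sprintf("  expected events:   %.3f\n", x$expected_events))
  cat(sprintf("  objective value:   %.4g\n", x$objective_value))
  if (!is.null(x$requests))
    cat(sprintf("  invitations requested: %d (pre-inflation %d)\n",
                sum(x$requests), sum(x$requests_raw)))
  cat("  constraints satisfied:", x$diagnostics$all_ok, "\n")
  invisible(x)
}

#' @export
summary.wave_plan <- function(object, ...) {
  d <- object$diagnostics
  cat("Wave plan constraint audit\n")
  cat(sprintf("  bookings: achieved %.2f vs target %.2f [%s]\n",
              d$bookings["achieved"], d$bookings["target"],
              if (d$bookings_ok) "ok" else "VIOLATED"))
  cat(sprintf("  max cluster invited proportion: %.3f [%s]\n",
              max(d$cluster_cap[, "invited"] / pmax(1, rowSums(object$lp$n))),
              if (d$cluster_cap_ok) "ok" else "VIOLATED"))
  cat(sprintf("  male booking share: %.4f [%s]\n", d$male_share,
              if (d$parity_ok) "ok" else "VIOLATED"))
  cat(sprintf("  expected events: %.3f (floor %.3f) [%s]\n",
              d$events["achieved"], d$events["floor"],
              if (d$event_floor_ok) "ok" else "VIOLATED"))
  cat("  band minima:", if (d$band_minima_ok) "ok" else "VIOLATED", "\n")
  invisible(d)
}
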