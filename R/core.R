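#' Cluster profile
#'
#' One cluster (e.g. a general practice) serving a recruitment site: its
#' eligible population by band, its preference rank, deprivation composition,
#' uptake covariates and opt-out inflation factor.
#'
#' @param cluster_id Opaque identifier (coerced to character).
#' @param rank Positive integer preference rank; 1 is the highest preference.
#' @param n Non-negative integer vector of length K: eligible counts per band.
#' @param imd_mix Five non-negative weights summing to 1: the cluster's
#'   deprivation-quintile composition (quintile 1 = least deprived).
#' @param z1 Normalised deprivation score of the cluster.
#' @param z2 Bowel-screening-uptake covariate in [0, 1].
#' @param optout_factor Multiplier (>= 1) by which invitation requests are
#'   inflated to compensate for patients removed post-request under national
#'   data opt-outs.
#' @return An object of class \code{cluster_profile}.
#' @export
cluster_profile <- function(cluster_id, rank, n, imd_mix,
                            z1 = 0, z2 = 0.5, optout_factor = 1) {
  obj <- structure(list(
    cluster_id = as.character(cluster_id)[1],
    rank = as.integer(rank),
    n = as.numeric(n),
    imd_mix = as.numeric(imd_mix),
    z1 = as.numeric(z1)[1],
    z2 = as.numeric(z2)[1],
    optout_factor = as.numeric(optout_factor)[1]
  ), class = "cluster_profile")
  probs <- cluster_problems(obj)
  if (length(probs)) stop("invalid cluster_profile: ", paste(probs, collapse = "; "))
  obj
}

cluster_problems <- function(cl) {
  p <- character(0)
  if (length(cl$imd_mix) != 5L || any(cl$imd_mix < 0) ||
      abs(sum(cl$imd_mix) - 1) > 1e-9)
    p <- c(p, "imd_mix must be 5 non-negative weights summing to 1")
  if (any(cl$n < 0) || any(cl$n != round(cl$n)))
    p <- c(p, "eligible counts n must be non-negative integers")
  if (is.na(cl$rank) || cl$rank < 1L) p <- c(p, "rank must be >= 1")
  if (is.na(cl$optout_factor) || cl$optout_factor < 1)
    p <- c(p, "optout_factor must be >= 1")
  if (!is.finite(cl$z1)) p <- c(p, "z1 must be finite")
  if (!is.finite(cl$z2) || cl$z2 < 0 || cl$z2 > 1)
    p <- c(p, "z2 must lie in [0, 1]")
  p
}

#' Site recruitment state
#'
#' Tracks a site's capacity, booking ledger, cumulative invited proportions and
#' current wave. At wave 1 nothing has been invited or booked.
#'
#' @param capacity Positive integer: total appointment slots T.
#' @param J Number of clusters.
#' @param K Number of bands.
#' @param ledger J x K matrix of bookings to date (default all zero).
#' @param invited J x K matrix of cumulative invited proportions in [0, 1]
#'   (default all zero).
#' @param wave Current wave index (default 1).
#' @param max_waves Maximum number of waves (default 4).
#' @return An object of class \code{site_state}.
#' @export
site_state <- function(capacity, J, K,
                       ledger = matrix(0, J, K),
                       invited = matrix(0, J, K),
                       wave = 1L, max_waves = 4L) {
  stopifnot(capacity > 0, capacity == round(capacity))
  ledger <- as.matrix(ledger); invited <- as.matrix(invited)
  if (!all(dim(ledger) == c(J, K)) || !all(dim(invited) == c(J, K)))
    stop("ledger and invited must both be ", J, " x ", K, " matrices")
  if (any(ledger < 0)) stop("ledger entries must be non-negative")
  if (any(invited < 0 | invited > 1))
    stop("invited proportions must lie in [0, 1]")
  if (wave < 1L || wave > max_waves)
    stop("wave must lie in 1..", max_waves)
  if (wave == 1L && (any(ledger != 0) || any(invited != 0)))
    stop("at wave 1 the ledger and invited proportions must be zero")
  structure(list(capacity = as.numeric(capacity), ledger = ledger,
                 invited = invited, wave = as.integer(wave),
                 max_waves = as.integer(max_waves)),
            class = "site_state")
}

#' Booking totals by band and overall
#'
#' @param state A \code{site_state} (or a bare J x K ledger matrix).
#' @return List with \code{per_group} (length-K band totals t+k) and
#'   \code{total} (grand total t++).
#' @export
booking_totals <- function(state) {
  ledger <- if (inherits(state, "site_state")) state$ledger else state
  if (length(dim(ledger)) != 2L) stop("ledger must be a J x K matrix")
  ledger <- as.matrix(ledger)
  per_group <- colSums(ledger)
  list(per_group = per_group, total = sum(per_group))
}

#' Apply between-wave booking feedback
#'
#' Advances the site to the next wave: the ledger gains the observed bookings
#' and the cumulative invited proportions gain requests / n per cell. The
#' invited proportion is capped at 1 (with a warning) because opt-out removal
#' after a request can make the nominal requested proportion overshoot.
#'
#' @param state A \code{site_state}.
#' @param requests J x K integer matrix of invitations requested this wave.
#' @param bookings J x K integer matrix of bookings observed; elementwise
#'   \code{bookings <= requests}.
#' @param n J x K eligible counts (denominator for the invited proportion).
#' @return The updated \code{site_state} at the next wave.
#' @export
apply_feedback <- function(state, requests, bookings, n) {
  stopifnot(inherits(state, "site_state"))
  requests <- as.matrix(requests); bookings <- as.matrix(bookings)
  n <- as.matrix(n)
  if (!all(dim(requests) == dim(state$ledger)) ||
      !all(dim(bookings) == dim(state$ledger)))
    stop("requests and bookings must match the ledger's dimensions")
  if (any(bookings > requests))
    stop("bookings cannot exceed requests in any cell")
  if (any(requests < 0) || any(bookings < 0))
    stop("requests and bookings must be non-negative")
  if (state$wave >= state$max_waves)
    stop("site is already at the final wave (", state$max_waves, ")")
  prop <- matrix(0, nrow(n), ncol(n))
  prop[n > 0] <- requests[n > 0] / n[n > 0]
  if (any(requests[n == 0] > 0)) stop("requests positive where n is zero")
  a_new <- state$invited + prop
  if (any(a_new > 1 + 1e-12)) {
    warning("invited proportion exceeded 1 in ",
            sum(a_new > 1 + 1e-12), " cell(s); capped at 1")
  }
  a_new <- pmin(a_new, 1)
  state$ledger <- state$ledger + bookings
  state$invited <- a_new
  state$wave <- state$wave + 1L
  state
}

#' Validate a site's data structures
#'
#' Report-based validation: returns a character vector of violated invariants,
#' empty if and only if the site is consistent.
#'
#' @param clusters List of \code{cluster_profile} objects.
#' @param state A \code{site_state}.
#' @param scheme A \code{group_scheme}.
#' @return Character vector of violation messages (possibly empty).
#' @export
validate_site <- function(clusters, state, scheme) {
  report <- character(0)
  J <- length(clusters); K <- scheme$K
  for (cl in clusters) {
    probs <- cluster_problems(cl)
    if (length(probs))
      report <- c(report, paste0("cluster ", cl$cluster_id, ": ", probs))
    if (length(cl$n) != K)
      report <- c(report, paste0("cluster ", cl$cluster_id,
                                 ": n has length ", length(cl$n),
                                 ", scheme has K = ", K))
  }
  if (!all(dim(state$ledger) == c(J, K)))
    report <- c(report, sprintf("ledger is %d x %d, expected %d x %d",
                                nrow(state$ledger), ncol(state$ledger), J, K))
  if (any(state$invited > 1))
    report <- c(report, "invited proportion > 1")
  if (any(state$invited < 0))
    report <- c(report, "invited proportion < 0")
  if (any(state$ledger < 0))
    report <- c(report, "negative booking counts")
  report
}

# Assemble the matrix view of a site that the planner works on.
# clusters: list of cluster_profile; returns J x K matrices and per-cluster vectors.
site_matrices <- function(clusters, scheme) {
  K <- scheme$K
  n <- do.call(rbind, lapply(clusters, function(cl) cl$n))
  list(
    ids = vapply(clusters, function(cl) cl$cluster_id, character(1)),
    rank = vapply(clusters, function(cl) cl$rank, integer(1)),
    n = n,
    optout = vapply(clusters, function(cl) cl$optout_factor, numeric(1)),
    z1 = vapply(clusters, function(cl) cl$z1, numeric(1)),
    z2 = vapply(clusters, function(cl) cl$z2, numeric(1))
  )
}
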