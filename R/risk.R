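#' Deprivation-stratified event-rate table
#'
#' Expected primary-outcome events per booked participant over the trial
#' horizon, by band k and deprivation quintile q (quintile 1 = least
#' deprived). Cluster-level expected rates are obtained by mixing the table
#' over each cluster's quintile composition.
#'
#' @param r K x 5 matrix of non-negative finite rates.
#' @param unit Character label declaring the rate unit; must match the unit of
#'   the event floor configuration (default \code{"per_participant"}).
#' @return Object of class \code{rate_table}.
#' @export
rate_table <- function(r, unit = "per_participant") {
  r <- as.matrix(r)
  if (ncol(r) != 5L) stop("rate table must have 5 quintile columns")
  if (any(!is.finite(r)) || any(r < 0))
    stop("rate table entries must be finite and non-negative")
  structure(list(r = r, unit = unit), class = "rate_table")
}

#' Expected event rates for a cluster
#'
#' Mixes the quintile-stratified rate table over the cluster's deprivation
#' composition: e_k = sum_q w_q r_kq. Each result lies between the smallest
#' and largest quintile rate for its band.
#'
#' @param table A \code{rate_table}.
#' @param cluster A \code{cluster_profile} (its \code{imd_mix} is used).
#' @return Numeric vector of K expected rates.
#' @export
expected_event_rate <- function(table, cluster) {
  stopifnot(inherits(table, "rate_table"))
  w <- cluster$imd_mix
  if (abs(sum(w) - 1) > 1e-9 || any(w < 0))
    stop("cluster imd_mix must be a valid 5-point composition")
  as.numeric(table$r %*% w)
}

#' Event-rate matrix for a set of clusters
#'
#' @param table A \code{rate_table}.
#' @param clusters List of \code{cluster_profile} objects.
#' @return J x K matrix of expected rates e_jk.
#' @export
event_rate_matrix <- function(table, clusters) {
  t(vapply(clusters, function(cl) expected_event_rate(table, cl),
           numeric(nrow(table$r))))
}

#' Uptake model parameters
#'
#' Parameters of the binomial-logistic uptake model
#' logit(u_jk) = beta_k + gamma1 z_j1 + gamma2 z_j2 + gamma3 z_j2^2,
#' where z1 is the cluster's normalised deprivation score and z2 its
#' bowel-screening-uptake covariate.
#'
#' @param beta Numeric vector of K band intercepts.
#' @param gamma1,gamma2,gamma3 Coefficients on z1, z2 and z2^2.
#' @return Object of class \code{uptake_params}.
#' @export
uptake_params <- function(beta, gamma1 = 0, gamma2 = 0, gamma3 = 0) {
  if (any(!is.finite(c(beta, gamma1, gamma2, gamma3))))
    stop("uptake parameters must be finite")
  structure(list(beta = as.numeric(beta), gamma1 = gamma1,
                 gamma2 = gamma2, gamma3 = gamma3),
            class = "uptake_params")
}

#' Predict uptake for a cluster
#'
#' @param params An \code{uptake_params}.
#' @param cluster A \code{cluster_profile} (covariates z1, z2 are used).
#' @return Numeric vector of K uptake probabilities, strictly in (0, 1).
#' @export
predict_uptake <- function(params, cluster) {
  stopifnot(inherits(params, "uptake_params"))
  eta <- params$beta + params$gamma1 * cluster$z1 +
    params$gamma2 * cluster$z2 + params$gamma3 * cluster$z2^2
  stats::plogis(eta)
}

#' Uptake matrix for a set of clusters
#'
#' @param params An \code{uptake_params}.
#' @param clusters List of \code{cluster_profile} objects.
#' @return J x K matrix of uptake probabilities u_jk.
#' @export
uptake_matrix <- function(params, clusters) {
  t(vapply(clusters, function(cl) predict_uptake(params, cl),
           numeric(length(params$beta))))
}

#' Flat uptake matrix
#'
#' The pre-data assumption: the same uptake everywhere. The trial planning
#' default before any booking feedback is 0.1.
#'
#' @param value Uptake proportion, strictly between 0 and 1.
#' @param J,K Dimensions of the matrix.
#' @return J x K matrix filled with \code{value}.
#' @export
flat_uptake <- function(value = 0.1, J, K) {
  if (!is.finite(value) || value <= 0 || value >= 1)
    stop("flat uptake must lie strictly between 0 and 1")
  matrix(value, J, K)
}

#' Fit the binomial-logistic uptake model
#'
#' Maximum-likelihood fit of bookings_jk ~ Binomial(invites_jk, u_jk) with
#' logit(u_jk) = beta_k + gamma1 z1 + gamma2 z2 + gamma3 z2^2, via the
#' canonical-link binomial GLM. Bands with no invitations anywhere are flagged
#' as non-estimable (their intercept is NA) rather than reported at +/- Inf.
#'
#' @param invites J x K matrix of invitations sent.
#' @param bookings J x K matrix of bookings observed; \code{bookings <= invites}.
#' @param z1,z2 Per-cluster covariate vectors of length J.
#' @return Object of class \code{uptake_fit}: the fitted \code{params}, a
#'   coefficient table with standard errors, the log-likelihood, and the names
#'   of any non-estimable bands.
#' @export
fit_uptake <- function(invites, bookings, z1, z2) {
  invites <- as.matrix(invites); bookings <- as.matrix(bookings)
  if (!all(dim(invites) == dim(bookings)))
    stop("invites and bookings must have the same dimensions")
  if (any(bookings > invites)) stop("bookings cannot exceed invites")
  J <- nrow(invites); K <- ncol(invites)
  if (length(z1) != J || length(z2) != J)
    stop("z1 and z2 must have one value per cluster")
  dat <- data.frame(
    band = factor(rep(seq_len(K), each = J), levels = seq_len(K)),
    inv = as.vector(invites), bk = as.vector(bookings),
    z1 = rep(z1, times = K), z2 = rep(z2, times = K)
  )
  dat$z2sq <- dat$z2^2
  band_tot <- tapply(dat$inv, dat$band, sum)
  dead <- as.integer(names(band_tot)[band_tot == 0])
  fitdat <- dat[dat$inv > 0, , drop = FALSE]
  if (nrow(fitdat) == 0L) stop("no invitations: uptake model is not estimable")
  # explicit band indicators: robust when only one band carries data
  for (k in seq_len(K))
    fitdat[[paste0("band", k)]] <- as.numeric(fitdat$band == k)
  form <- stats::reformulate(c(paste0("band", seq_len(K)), "z1", "z2", "z2sq"),
                             response = "cbind(bk, inv - bk)",
                             intercept = FALSE)
  fit <- stats::glm(form, family = stats::binomial(), data = fitdat)
  cf <- stats::coef(summary(fit))
  beta <- rep(NA_real_, K); se_beta <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    nm <- paste0("band", k)
    if (nm %in% rownames(cf)) {
      beta[k] <- cf[nm, "Estimate"]; se_beta[k] <- cf[nm, "Std. Error"]
    }
  }
  # detect separation: a fitted intercept driven to the boundary
  sep <- which(!is.na(beta) & abs(beta) > 20)
  if (length(sep)) { beta[sep] <- NA_real_; se_beta[sep] <- NA_real_ }
  gpick <- function(nm) if (nm %in% rownames(cf)) cf[nm, c("Estimate", "Std. Error")] else c(NA, NA)
  g1 <- gpick("z1"); g2 <- gpick("z2"); g3 <- gpick("z2sq")
  # params carry 0 where a term is non-estimable; the NA stays in the table
  zna <- function(v) if (is.na(v)) 0 else unname(v)
  params <- uptake_params(ifelse(is.na(beta), 0, beta), gamma1 = zna(g1[1]),
                          gamma2 = zna(g2[1]), gamma3 = zna(g3[1]))
  coefs <- data.frame(
    term = c(paste0("beta_", seq_len(K)), "gamma1", "gamma2", "gamma3"),
    estimate = c(beta, g1[1], g2[1], g3[1]),
    se = c(se_beta, g1[2], g2[2], g3[2])
  )
  structure(list(params = params, coefficients = coefs,
                 logLik = as.numeric(stats::logLik(fit)),
                 non_estimable = union(dead, sep),
                 glm = fit),
            class = "uptake_fit")
}

#' @export
print.uptake_fit <- function(x, ...) {
  cat("Binomial-logistic uptake model fit\n")
  cat("  log-likelihood:", format(x$logLik), "\n")
  if (length(x$non_estimable))
    cat("  non-estimable bands:", paste(x$non_estimable, collapse = ", "), "\n")
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.uptake_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Log-likelihood of uptake data under given parameters
#'
#' Product-binomial log-likelihood of the observed bookings given invites and
#' uptake parameters; useful for comparing a fit against known truth.
#'
#' @inheritParams fit_uptake
#' @param params An \code{uptake_params}.
#' @return Scalar log-likelihood (up to the binomial-coefficient constant,
#'   which is included).
#' @export
uptake_loglik <- function(params, invites, bookings, z1, z2) {
  J <- nrow(invites); K <- ncol(invites)
  u <- t(vapply(seq_len(J), function(j) {
    stats::plogis(params$beta + params$gamma1 * z1[j] +
                  params$gamma2 * z2[j] + params$gamma3 * z2[j]^2)
  }, numeric(K)))
  keep <- invites > 0
  sum(stats::dbinom(bookings[keep], invites[keep], u[keep], log = TRUE))
}
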