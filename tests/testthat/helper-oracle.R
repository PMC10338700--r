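# Independent LP oracle by exhaustive vertex enumeration.
#
# Solves min obj'x subject to A1 x <= b1, A2 x >= b2, A3 x = b3, x >= 0 by
# enumerating all basic solutions: every choice of (nv - n_eq) inequality
# rows held active, solved as a square linear system together with the
# equalities, then checked against all constraints. Exact up to linear-solve
# round-off; usable only for a handful of variables.
oracle_lp <- function(obj, A1 = NULL, b1 = NULL, A2 = NULL, b2 = NULL,
                      A3 = NULL, b3 = NULL, tol = 1e-8) {
  nv <- length(obj)
  ineqA <- rbind(A1, if (!is.null(A2)) -A2, -diag(nv))
  ineqb <- c(b1, if (!is.null(b2)) -b2, rep(0, nv))
  eqA <- A3; eqb <- b3
  n_eq <- if (is.null(eqA)) 0L else nrow(eqA)
  need <- nv - n_eq
  best <- Inf; best_x <- NULL
  feasible <- function(x) {
    all(ineqA %*% x <= ineqb + tol * pmax(1, abs(ineqb))) &&
      (n_eq == 0 || all(abs(eqA %*% x - eqb) <= tol * pmax(1, abs(eqb))))
  }
  if (need == 0) {
    x <- tryCatch(solve(eqA, eqb), error = function(e) NULL)
    if (!is.null(x) && feasible(x)) { best <- sum(obj * x); best_x <- x }
  } else {
    combs <- utils::combn(nrow(ineqA), need)
    for (ci in seq_len(ncol(combs))) {
      rows <- combs[, ci]
      A <- rbind(eqA, ineqA[rows, , drop = FALSE])
      b <- c(eqb, ineqb[rows])
      x <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(x) || any(!is.finite(x))) next
      if (feasible(x)) {
        v <- sum(obj * x)
        if (v < best - 1e-12) { best <- v; best_x <- x }
      }
    }
  }
  list(value = best, x = best_x, feasible = is.finite(best))
}

# Oracle applied to a wave_lp built by the package (same matrices, so only
# the *solver* is cross-checked; the formulation itself is checked separately
# against raw-input audits).
oracle_wave_lp <- function(lp) {
  oracle_lp(lp$obj, A1 = lp$A1, b1 = lp$b1, A2 = lp$A2, b2 = lp$b2,
            A3 = lp$A3, b3 = lp$b3)
}
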