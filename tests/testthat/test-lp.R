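test_that("cost construction matches the closed form and floors rates", {
  # single cluster, rank 1, e = (0.5, 1): max 1/e = 2 so multiplier is 3
  cm <- compute_costs(matrix(c(0.5, 1), 1, 2), ranks = 1L)
  expect_equal(as.numeric(cm$c), c(1 / 0.5 + 3, 1 / 1 + 3))
  # equal rates: within a rank all costs equal; ordering purely by rank
  cm2 <- compute_costs(matrix(0.2, 3, 4), ranks = c(2L, 1L, 3L))
  expect_true(all(cm2$c[2, ] < cm2$c[1, ]))
  expect_true(all(cm2$c[1, ] < cm2$c[3, ]))
  expect_equal(length(unique(round(cm2$c[1, ], 12))), 1L)
  # zero rates are floored, not inverted to Inf
  cm3 <- compute_costs(matrix(c(0, 0.5), 1, 2), ranks = 1L)
  expect_true(all(is.finite(cm3$c)))
  expect_error(compute_costs(matrix(-1, 1, 2), 1L), "non-negative")
})

test_that("rank dominance holds for arbitrary rate configurations", {
  set.seed(77)
  for (i in 1:20) {
    J <- sample(2:6, 1); K <- 4
    e <- matrix(runif(J * K, 0.001, 0.1), J, K)
    ranks <- sample(1:3, J, replace = TRUE)
    cm <- compute_costs(e, ranks)
    for (r in 1:2) {
      hi <- cm$c[ranks == r, , drop = FALSE]
      lo <- cm$c[ranks == r + 1, , drop = FALSE]
      if (length(hi) && length(lo)) expect_lt(max(hi), min(lo))
    }
    # within a rank, cost is decreasing in the event rate
    for (r in unique(ranks)) {
      sel <- which(ranks == r)
      ord <- order(e[sel, ])
      expect_true(all(diff(cm$c[sel, ][ord]) <= 0))
    }
  }
})

test_that("the wave LP encodes bounds, history and cluster caps", {
  scheme <- tiny_scheme()
  n <- matrix(c(600, 400), 1, 2)
  u <- matrix(0.1, 1, 2); e <- matrix(c(0.01, 0.012), 1, 2)
  a <- matrix(c(0.6, 0), 1, 2)
  wc <- wave_constraints(B = 30, d = 0, G = 0.5, S = 0.5)
  lp <- build_wave_lp(n, u, e, a, compute_costs(e, 1L), wc, scheme)
  expect_length(lp$obj, 2)
  # upper bound on the invited proportion is the remaining headroom 0.4
  expect_equal(lp$b1[1], 0.4)
  # cluster cap: sum_k x n <= 0.5 * 1000
  cap_row <- nrow(lp$A1)
  expect_equal(lp$b1[cap_row], 500)
  expect_equal(as.numeric(lp$A1[cap_row, ]), c(600, 400))
  # booking equality and one parity equality
  expect_equal(nrow(lp$A3), 2)
  expect_equal(lp$b3, c(30, 0))
})

test_that("cells with no population or no headroom are fixed to zero", {
  scheme <- tiny_scheme()
  n <- matrix(c(100, 0, 100, 100), 2, 2)
  u <- matrix(0.2, 2, 2); e <- matrix(0.01, 2, 2)
  a <- matrix(c(0, 0, 1, 0), 2, 2)
  wc <- wave_constraints(B = 10, d = 0, G = 1, S = 0.5)
  lp <- build_wave_lp(n, u, e, a, compute_costs(e, c(1L, 1L)), wc, scheme)
  expect_length(lp$obj, 2)     # only (1,1) and (2,2) remain free
  plan <- solve_wave(lp)
  expect_equal(plan$x[2, 1], 0)
  expect_equal(plan$x[1, 2], 0)
})

test_that("solved plans satisfy every constraint family on audit", {
  for (seed in 1:10) {
    inst <- random_tiny_lp(seed, J = 3)
    plan <- solve_wave(inst$lp)
    expect_true(plan$diagnostics$all_ok)
    expect_equal(plan$expected_bookings, inst$wc$B,
                 tolerance = 1e-6)
  }
})

test_that("solver matches the vertex-enumeration oracle on tiny instances", {
  n_feasible <- 0
  for (seed in 1:100) {
    inst <- random_tiny_lp(seed, J = 2)
    orc <- oracle_wave_lp(inst$lp)
    plan <- tryCatch(solve_wave(inst$lp), stratinvite_infeasible = function(e) e)
    if (inherits(plan, "stratinvite_infeasible")) {
      expect_false(orc$feasible)
    } else {
      expect_true(orc$feasible)
      expect_equal(plan$objective_value, orc$value,
                   tolerance = 1e-4)
      n_feasible <- n_feasible + 1
    }
  }
  expect_gte(n_feasible, 80)   # the suite must mostly exercise real solves
})

test_that("infeasible programmes raise a typed report naming the family", {
  scheme <- tiny_scheme()
  n <- matrix(50, 1, 2); u <- matrix(0.1, 1, 2); e <- matrix(0.01, 1, 2)
  a <- matrix(0, 1, 2)
  # B far beyond sum n u headroom
  wc <- wave_constraints(B = 100, d = 0, G = 1, S = 0.5)
  lp <- build_wave_lp(n, u, e, a, compute_costs(e, 1L), wc, scheme)
  err <- tryCatch(solve_wave(lp), stratinvite_infeasible = function(e) e)
  expect_s3_class(err, "stratinvite_infeasible")
  expect_true(any(grepl("bookings", err$families)))
})

test_that("raising the event floor never lowers the achieved event rate", {
  set.seed(123)
  inst <- random_tiny_lp(3, J = 3, with_events = FALSE)
  lp <- inst$lp
  base_rate <- NULL; last <- -Inf
  emax <- sum(inst$e * inst$n * inst$u)   # loose upper bound
  for (f in seq(0, 0.9, by = 0.15)) {
    wc <- inst$wc; wc$E_floor <- f * mean(inst$e) * inst$wc$B * 1.5
    lp2 <- build_wave_lp(inst$n, inst$u, inst$e, inst$a,
                         compute_costs(inst$e, rep(1L, 3)), wc, inst$scheme)
    plan <- tryCatch(solve_wave(lp2), stratinvite_infeasible = function(e) NULL)
    if (is.null(plan)) break
    rate <- plan$expected_events / plan$expected_bookings
    expect_gte(rate, last - 1e-9)
    last <- rate
  }
})

test_that("rank-1 clusters absorb all invitations when they can", {
  scheme <- tiny_scheme()
  J <- 4
  n <- matrix(500, J, 2); u <- matrix(0.2, J, 2)
  e <- matrix(runif(J * 2, 0.01, 0.02), J, 2)
  a <- matrix(0, J, 2)
  ranks <- c(1L, 1L, 2L, 2L)
  # B small enough for the two rank-1 clusters under G = 0.5
  wc <- wave_constraints(B = 60, d = 0.2 * 60, G = 0.5, S = 0.5)
  lp <- build_wave_lp(n, u, e, a, compute_costs(e, ranks), wc, scheme)
  plan <- solve_wave(lp)
  expect_equal(sum(plan$x[3:4, ]), 0, tolerance = 1e-9)
  expect_gt(sum(plan$x[1:2, ]), 0)
})

test_that("parity holds exactly whenever bookings are positive", {
  for (seed in 11:20) {
    inst <- random_tiny_lp(seed, J = 3)
    plan <- tryCatch(solve_wave(inst$lp),
                     stratinvite_infeasible = function(e) NULL)
    if (is.null(plan)) next
    nu <- inst$n * inst$u
    male <- sum(nu[, 1] * plan$x[, 1])
    expect_equal(male / plan$expected_bookings, 0.5, tolerance = 1e-6)
  }
})

test_that("largest-remainder rounding preserves cluster totals", {
  expect_equal(largest_remainder(c(2, 3), 5), c(2L, 3L))
  expect_equal(largest_remainder(c(1.4, 1.6), 3), c(1L, 2L))
  expect_equal(largest_remainder(c(0.5, 0.5, 2), 3), c(1L, 0L, 2L))  # tie: first wins
  set.seed(6)
  for (i in 1:20) {
    v <- runif(8, 0, 10)
    tot <- round(sum(v))
    r <- largest_remainder(v, tot)
    expect_equal(sum(r), tot)
    expect_true(all(abs(r - v) < 1))
  }
})

test_that("invitation rounding respects headroom and opt-out inflation", {
  inst <- random_tiny_lp(2, J = 2)
  plan <- solve_wave(inst$lp)
  plan <- round_invitations(plan, optout_factor = c(1, 1.25))
  headroom <- floor(inst$n * (1 - inst$a) + 1e-9)
  expect_true(all(plan$requests_raw <= headroom))
  expect_equal(plan$requests[2, ], as.integer(ceiling(plan$requests_raw[2, ] * 1.25 - 1e-9)))
  expect_equal(plan$requests[1, ], plan$requests_raw[1, ])
  # 100 pre-inflation at factor 1.25 -> 125
  expect_equal(ceiling(100 * 1.25 - 1e-9), 125)
})
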