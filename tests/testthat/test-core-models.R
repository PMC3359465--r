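test_that("Model 1 potential: barrier height, flat ramp at zero drift, ramp arithmetic", {
  cfg <- model_config(1, f_d = 0)
  st <- walker_state(cfg)
  expect_equal(potential_m1(0, cfg, st) - potential_m1(-1.5, cfg, st), 1.0)
  xs <- seq(st$b1, -1.5, by = 0.25)
  expect_equal(potential_m1(xs, cfg, st), rep(0, length(xs)))

  cfg2 <- model_config(1, f_d = 0.40)
  expect_equal(potential_m1(-4, cfg2, walker_state(cfg2)), 3 * 0.40)

  # continuity at the segment joins
  cfgd <- model_config(1, f_d = -0.25)
  std <- walker_state(cfgd)
  for (j in c(-1.5, 0, 1.5)) {
    expect_equal(potential_m1(j - 1e-9, cfgd, std),
                 potential_m1(j + 1e-9, cfgd, std), tolerance = 1e-6)
  }
})

test_that("Model 2 potential: bare tent at zero drift, mirror symmetry, slope arithmetic", {
  cfg <- model_config(2)
  st0 <- walker_state(cfg, drift_slope = 0)
  expect_equal(potential_m2(0, cfg, st0) - potential_m2(-1.5, cfg, st0), 0.2)
  expect_equal(potential_m2(-5, cfg, st0), 0)    # flat outside the tent

  stA <- walker_state(cfg, drift_slope = 0.20)
  expect_equal(potential_m2(-10, cfg, stA), 8 * 0.20)
  xs <- seq(0.5, 17.5, by = 0.5)
  expect_equal(potential_m2(-xs, cfg, stA), potential_m2(xs, cfg, stA))

  cfg7 <- model_config(2, tp = 7)
  st7 <- walker_state(cfg7, drift_slope = -0.1)
  xp <- seq(0.5, 10.5, by = 0.5)
  expect_equal(potential_m2(7 - xp, cfg7, st7), potential_m2(7 + xp, cfg7, st7))
})

test_that("potential evaluation outside the accessible range is a domain error", {
  cfg <- model_config(1)
  expect_error(potential_m1(8, cfg, walker_state(cfg)), "outside")
  cfg2 <- model_config(2)
  expect_error(potential_m2(-19, cfg2, walker_state(cfg2)), "outside")
})

test_that("step probabilities follow p = 1/2 - dU/4 and conserve probability", {
  expect_equal(step_probabilities(0), list(p = 0.5, q = 0.5))
  expect_equal(step_probabilities(2), list(p = 0, q = 1))
  expect_equal(step_probabilities(0.4), list(p = 0.4, q = 0.6))
  du <- seq(-2, 2, by = 0.01)
  pq <- step_probabilities(du)
  expect_equal(pq$p + pq$q, rep(1, length(du)))
  expect_true(all(pq$p >= 0 & pq$p <= 1))
  expect_warning(out <- step_probabilities(3), "clamped")
  expect_equal(out$p, 0)
})

test_that("boundary updates shrink/expand synchronously and reflect at the limits", {
  cfg <- model_config(1)
  # identify the branch the next uniform draw selects, then replay it
  branch_of <- function(seed) { set.seed(seed); if (runif(1) < 0.5) "shrink" else "expand" }
  seeds <- 1:20
  shrink_seed <- seeds[vapply(seeds, branch_of, "") == "shrink"][1]
  expand_seed <- seeds[vapply(seeds, branch_of, "") == "expand"][1]

  st <- walker_state(cfg, rc = 3, b1 = -7, b2 = 7)
  set.seed(shrink_seed)
  s1 <- update_boundaries_m1(st, cfg)
  expect_equal(c(s1$b1, s1$b2), c(-6L, 6L))
  set.seed(expand_seed)
  s2 <- update_boundaries_m1(st, cfg)
  expect_equal(c(s2$b1, s2$b2), c(-8L, 8L))

  # expansion reflects at b_max; shrinking reflects at |b2| = 2
  wide <- walker_state(cfg, rc = 3, b1 = -14, b2 = 14)
  set.seed(expand_seed)
  expect_equal(update_boundaries_m1(wide, cfg)$b2, 14L)
  narrow <- walker_state(cfg, rc = 1, b1 = -2, b2 = 2)
  set.seed(shrink_seed)
  expect_equal(update_boundaries_m1(narrow, cfg)$b2, 2L)

  # rc is clamped into the shrunk range
  edge <- walker_state(cfg, rc = 7, b1 = -7, b2 = 7)
  set.seed(shrink_seed)
  expect_equal(update_boundaries_m1(edge, cfg)$rc, 6L)
})

test_that("boundary half-width visits {2..14} uniformly in the long run", {
  # Reflected unbiased walk: the exact stationary law is computed from the
  # 13-state chain; rejection at the limits makes the matrix symmetric.
  P <- matrix(0, 13, 13)
  for (i in 1:13) {
    up <- min(i + 1, 13); dn <- max(i - 1, 1)
    P[i, up] <- P[i, up] + 0.5
    P[i, dn] <- P[i, dn] + 0.5
  }
  pi_exact <- oracle_stationary(P)
  expect_equal(pi_exact, rep(1 / 13, 13), tolerance = 1e-10)

  cfg <- model_config(1, t_b = 1)     # boundary update every step
  gt <- simulate_gating(cfg, 1e6, seed = 11, record_paths = TRUE)
  emp <- tabulate(gt$b2 - 1L, nbins = 13) / length(gt$b2)
  expect_lt(max(abs(emp - pi_exact)), 0.015)
})

test_that("drift updates step on an exact 0.005 grid and reflect at +/- 0.20", {
  cfg <- model_config(2)
  st <- walker_state(cfg, drift_slope = 0)
  set.seed(5)
  seen <- numeric(0)
  for (i in 1:2000) {
    st <- update_drift_m2(st, cfg)
    seen <- c(seen, st$drift_slope)
  }
  lv <- round(seen / 0.005)
  expect_identical(seen, lv * 0.005)            # exact grid, no FP drift
  expect_true(any(abs(seen) == 0.20))           # both limits reachable...
  expect_lte(max(abs(seen)), 0.20)              # ...and never exceeded

  # a rejected move at the limit leaves the slope exactly at the limit
  at_max <- walker_state(cfg, drift_slope = 0.20)
  reps <- replicate(20, { set.seed(sample.int(1e6, 1)); update_drift_m2(at_max, cfg)$drift_slope })
  expect_true(all(reps %in% c(0.195, 0.20)))
})

test_that("simulation is deterministic per seed and respects the trace contract", {
  cfg <- model_config(1)
  a <- simulate_gating(cfg, 5e4, seed = 99, record_paths = TRUE)
  b <- simulate_gating(cfg, 5e4, seed = 99, record_paths = TRUE)
  expect_identical(a$states, b$states)
  expect_identical(a$rc, b$rc)
  expect_identical(a$b2, b$b2)
  expect_true(all(a$states %in% 0:1))
  expect_true(all(a$rc != 0))                       # threshold node never occupied
  expect_true(all(a$rc >= -14 & a$rc <= 14))
  expect_identical(a$states, as.integer(a$rc > 0))  # open iff rc > tp

  c2 <- simulate_gating(model_config(2, tp = 7), 5e4, seed = 3, record_paths = TRUE)
  expect_true(all(c2$rc != 7))
  expect_true(all(abs(c2$drift) <= 0.20 + 1e-12))
  expect_identical(c2$states, as.integer(c2$rc > 7))
})

test_that("unbiased configurations give open probability 1/2 within 3 standard errors", {
  gt1 <- simulate_gating(model_config(1, f_d = 0), 1e6, seed = 21)
  se1 <- batch_se(gt1$states)
  expect_lt(abs(open_probability(gt1) - 0.5), 3 * se1)

  gt2 <- simulate_gating(model_config(2, tp = 0), 1e6, seed = 22)
  se2 <- batch_se(gt2$states)
  expect_lt(abs(open_probability(gt2) - 0.5), 3 * se2)
})

test_that("negating the regulator mirrors the dynamics exactly in law", {
  # P_{+reg}(x -> y) must equal P_{-reg}(-x -> -y), node for node
  mirror_ok <- function(cfg_p, cfg_m, st_p, st_m) {
    Pp <- oracle_transition_matrix(cfg_p, st_p)
    Pm <- oracle_transition_matrix(cfg_m, st_m)
    idx <- rev(seq_len(nrow(Pm)))             # -x ordering
    expect_equal(unname(Pp), unname(Pm[idx, idx]), tolerance = 1e-12)
  }
  c1p <- model_config(1, f_d = 0.3); c1m <- model_config(1, f_d = -0.3)
  mirror_ok(c1p, c1m, walker_state(c1p), walker_state(c1m))
  c2p <- model_config(2, tp = 7); c2m <- model_config(2, tp = -7)
  mirror_ok(c2p, c2m, walker_state(c2p, drift_slope = 0.1),
            walker_state(c2m, drift_slope = 0.1))
})

test_that("negating the drift mirrors the sampled open/closed statistics", {
  # single-run scatter at the reference length is ~1-2 % for Model 1
  n <- 6e6
  gp <- simulate_gating(model_config(1, f_d = 0.2), n, seed = 31)
  gm <- simulate_gating(model_config(1, f_d = -0.2), n, seed = 32)
  expect_lt(abs(open_probability(gp) + open_probability(gm) - 1), 0.04)
  dp <- extract_dwells(gp); dm <- extract_dwells(gm)
  expect_lt(abs(mean_dwell(dp, "open") / mean_dwell(dm, "closed") - 1), 0.15)
  expect_lt(abs(mean_dwell(dp, "closed") / mean_dwell(dm, "open") - 1), 0.15)
})

test_that("frozen-boundary occupancy matches the exact transition-matrix solution", {
  # 8-node lattice, slow process frozen, nonzero drift so the law is nontrivial
  cfg <- model_config(1, b_max = 8, f_d = 0.3, t_b = 2^30)
  st <- walker_state(cfg)
  pi_exact <- oracle_stationary(oracle_transition_matrix(cfg, st))
  gt <- simulate_gating(cfg, 1e6, seed = 41, record_paths = TRUE)
  nodes <- setdiff(st$b1:st$b2, cfg$tp)
  for (i in seq_along(nodes)) {
    ind <- as.numeric(gt$rc == nodes[i])
    expect_lt(abs(mean(ind) - pi_exact[i]), 3 * batch_se(ind) + 1e-4)
  }
})

test_that("frozen-lattice mean dwell times match absorbing-chain expectations", {
  cfg <- model_config(1, b_max = 8, f_d = 0.3, t_b = 2^30)
  exact_open <- oracle_mean_dwell(cfg, open = TRUE)
  exact_closed <- oracle_mean_dwell(cfg, open = FALSE)
  per_rep <- vapply(1:5, function(r) {
    ds <- extract_dwells(simulate_gating(cfg, 4e5, seed = 50 + r))
    c(open = mean(ds$duration[ds$state == 1]),
      closed = mean(ds$duration[ds$state == 0]))
  }, numeric(2))
  se <- apply(per_rep, 1, sd) / sqrt(5)
  expect_lt(abs(mean(per_rep["open", ]) - exact_open), 3 * se["open"])
  expect_lt(abs(mean(per_rep["closed", ]) - exact_closed), 3 * se["closed"])
})

test_that("configuration validation rejects inconsistent parameters", {
  expect_error(model_config(3), "must be 1 or 2")
  expect_error(model_config(1, tp = 2), "tp = 0")
  expect_error(model_config(2, tp = 20), "b1 < tp < b2")
  expect_error(model_config(1, u_barrier = -1), "u_barrier")
  expect_error(model_config(1, dt = 0), "dt")
  expect_error(simulate_gating(model_config(1), 0), "n_steps")
  expect_error(walker_state(model_config(1), rc = 0), "threshold")
})
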