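make_bimodal <- function(n = 2e5, level = 18.848, sd = 1.8848, p_open = 0.5,
                         seed = 7) {
  set.seed(seed)
  states <- rbinom(n, 1, p_open)
  current_trace(states * level + rnorm(n, 0, sd))
}

test_that("Epanechnikov KDE is normalized and recovers simple densities", {
  set.seed(1)
  k <- kde_pdf(runif(1e5))
  dx <- diff(k$grid[1:2])
  integral <- (sum(k$density) - (k$density[1] + k$density[length(k$density)]) / 2) * dx
  expect_lt(abs(integral - 1), 1e-3)
  sel <- k$grid > 0.1 & k$grid < 0.9
  expect_lt(max(abs(k$density[sel] - 1)), 0.05)

  # bimodal mixture: detected modes sit at the injected means within a bandwidth
  set.seed(2)
  mix <- c(rnorm(5e4, 2, 0.4), rnorm(5e4, 10, 0.8))
  km <- kde_pdf(mix)
  peaks <- km$grid[which(diff(sign(diff(c(-Inf, km$density, -Inf)))) < 0)]
  peaks <- peaks[order(-km$density[match(peaks, km$grid)])][1:2]
  expect_lt(abs(sort(peaks)[1] - 2), km$bandwidth)
  expect_lt(abs(sort(peaks)[2] - 10), km$bandwidth)

  expect_error(kde_pdf(rep(1, 200)), "zero variance")
  expect_error(kde_pdf(rnorm(50)), "at least 100")
})

test_that("power-law-intersection threshold lands between the two current levels", {
  tr <- make_bimodal(n = 1e5, level = 18, sd = 0.5)
  fit <- threshold_kde(tr)
  expect_gt(fit$threshold, 6)
  expect_lt(fit$threshold, 12)
  expect_gt(fit$fits$lower$r2, 0.9)
  expect_gt(fit$fits$upper$r2, 0.9)
  expect_true(fit$threshold > fit$modes[1] && fit$threshold < fit$modes[2])
})

test_that("unimodal input is rejected as non-bimodal", {
  set.seed(3)
  expect_error(threshold_kde(current_trace(rnorm(1e4, 10, 1))), "no bimodality")
})

test_that("double-Gaussian threshold matches closed-form crossings", {
  # equal weights and sigmas: crossing at the midpoint of the means
  tr <- make_bimodal(n = 1e5, level = 18, sd = 1.5, seed = 11)
  thr <- threshold_double_gaussian(tr)
  expect_lt(abs(thr - 9), 0.1 * 1.5)

  # unequal weights: crossing shifts toward the minor mode, matching the
  # numerically solved equal-density point of the true mixture
  tr2 <- make_bimodal(n = 2e5, level = 18, sd = 1.5, p_open = 0.1, seed = 12)
  thr2 <- threshold_double_gaussian(tr2)
  truth <- uniroot(function(x) 0.9 * dnorm(x, 0, 1.5) - 0.1 * dnorm(x, 18, 1.5),
                   c(0, 18))$root
  expect_gt(truth, 9)                      # sanity: shifted toward minor mode
  expect_lt(abs(thr2 - truth), 0.5)

  # noiseless two-level trace: exact midpoint
  expect_equal(threshold_double_gaussian(rep(c(0, 18.848), 100)), 9.424)
})

test_that("kernel-density and double-Gaussian thresholds agree within 5 percent", {
  tr <- make_bimodal()        # the standard fixture: SNR 10, p_open 0.5
  t_kde <- threshold_kde(tr)$threshold
  t_dg <- threshold_double_gaussian(tr)
  expect_lt(abs(t_kde - t_dg) / t_dg, 0.05)
})

test_that("idealization recovers states and propagates metadata", {
  # noiseless alternating levels: exact recovery
  states <- rep(c(0L, 1L, 1L, 0L, 1L), 40)
  tr <- current_trace(states * 18.848, dt = 5e-5)
  expect_identical(idealize(tr, threshold = 9)$states, states)
  expect_equal(idealize(tr, threshold = 9)$dt, 5e-5)

  # all samples below threshold: all closed
  expect_identical(idealize(current_trace(rnorm(200, 1, 0.1)), threshold = 5)$states,
                   rep(0L, 200))

  # SNR 10 fixture: per-sample agreement at least 99 percent
  set.seed(13)
  truth <- rbinom(1e5, 1, 0.5)
  tr3 <- current_trace(truth * 18.848 + rnorm(1e5, 0, 1.8848))
  expect_gte(mean(idealize(tr3, threshold = 9.424)$states == truth), 0.99)

  expect_error(idealize(tr, threshold = Inf), "finite")
})

test_that("dwell extraction is exact run-length encoding", {
  expect_equal(
    ds_frame(extract_dwells(gating_trace(c(0, 0, 1, 1, 1, 0)))),
    data.frame(state = c(0L, 1L, 0L), duration = c(2L, 3L, 1L)))
  expect_equal(
    ds_frame(extract_dwells(gating_trace(rep(1L, 17)))),
    data.frame(state = 1L, duration = 17L))

  set.seed(14)
  for (i in 1:20) {
    states <- rbinom(50, 1, runif(1, 0.2, 0.8))
    ds <- extract_dwells(gating_trace(states))
    expect_equal(ds_frame(ds), oracle_rle(states))
    expect_equal(sum(ds$duration), 50)                     # durations cover trace
    if (nrow(ds) > 1) expect_true(all(diff(ds$state) != 0)) # strict alternation
  }
})

test_that("idealize after render is the identity on noiseless synthetic traces", {
  gt <- simulate_gating(model_config(1), 2e4, seed = 15)
  spec <- recording_spec(noise_sd = 0)
  tr <- render_current(gt, spec)
  expect_identical(idealize(tr, threshold = spec$open_level / 2)$states, gt$states)
})
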