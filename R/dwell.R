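#' Extract the dwell-time series from a gating trace
#'
#' Run-length encodes the dichotomous state series into the ordered,
#' strictly alternating sequence of (state, duration) events. Durations
#' are in samples; the sampling interval is carried along so they can be
#' expressed in milliseconds.
#'
#' @param gt A [gating_trace()].
#' @return A `dwell_series`: a data frame with columns `state` (0/1) and
#'   `duration` (samples), with attribute `dt`.
#' @examples
#' extract_dwells(gating_trace(c(0, 0, 1, 1, 1, 0)))
#' @export
extract_dwells <- function(gt) {
  stopifnot(inherits(gt, "gating_trace"))
  r <- .rle_core(gt$states)
  structure(data.frame(state = r$state, duration = r$duration),
            dt = gt$dt, class = c("dwell_series", "data.frame"))
}

#' Open-state probability of a gating trace
#'
#' Fraction of samples spent in the open state. Equals the
#' duration-weighted open fraction of the extracted dwell series exactly.
#'
#' @param gt A [gating_trace()].
#' @return A probability in `[0, 1]`.
#' @export
open_probability <- function(gt) {
  stopifnot(inherits(gt, "gating_trace"))
  mean(gt$states)
}

state_code <- function(state) {
  if (is.character(state)) state <- match.arg(state, c("closed", "open")) == "open"
  as.integer(state)
}

#' Mean dwell time in one state
#'
#' @param ds A `dwell_series` from [extract_dwells()].
#' @param state `"open"`/`"closed"` (or 1/0).
#' @return Mean dwell time in milliseconds.
#' @export
mean_dwell <- function(ds, state = "open") {
  stopifnot(inherits(ds, "dwell_series"))
  s <- state_code(state)
  d <- ds$duration[ds$state == s]
  if (length(d) == 0) stop("no events in the requested state")
  mean(d) * attr(ds, "dt") * 1000
}

#' Log-binned dwell-time histogram
#'
#' Builds a dwell-time histogram with logarithmically spaced bins, counts
#' converted to probability mass per bin. When a list of replicate dwell
#' series is supplied, a shared bin grid spanning the pooled range is used
#' and the per-bin mean probability and population standard deviation
#' across replicates are returned (the latter feeds [chi2_exp()]).
#'
#' @param ds A `dwell_series`, or a list of them (replicates).
#' @param state `"open"`/`"closed"` (or 1/0).
#' @param n_bins Number of logarithmic bins.
#' @param breaks Optional explicit bin edges in ms (overrides `n_bins`);
#'   use to evaluate different series on a shared grid, e.g. for
#'   [chi2_sim()].
#' @return A `dwell_histogram`: list with `breaks` (ms), `mids` (ms), `p`
#'   (probability mass per bin, summing to 1), `sd` (per-bin replicate SD,
#'   or `NULL`), `state`, `n_events`.
#' @export
dwell_histogram <- function(ds, state = "open", n_bins = 20, breaks = NULL) {
  s <- state_code(state)
  reps <- if (inherits(ds, "dwell_series")) list(ds) else ds
  stopifnot(all(vapply(reps, inherits, TRUE, "dwell_series")))
  durs <- lapply(reps, function(d) {
    x <- d$duration[d$state == s] * attr(d, "dt") * 1000
    if (length(x) == 0) stop("no events in the requested state")
    x
  })
  if (is.null(breaks)) {
    rng <- range(unlist(durs))
    breaks <- exp(seq(log(rng[1] * 0.999), log(rng[2] * 1.001),
                      length.out = n_bins + 1))
  }
  if (any(diff(breaks) <= 0)) stop("`breaks` must be strictly increasing")
  nb <- length(breaks) - 1
  pm <- vapply(durs, function(x) {
    idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(idx, nbins = nb) / length(x)
  }, numeric(nb))
  pm <- matrix(pm, nrow = nb)
  sdv <- if (length(reps) > 1) apply(pm, 1, function(r) sqrt(mean((r - mean(r))^2)))
  structure(list(breaks = breaks,
                 mids = sqrt(breaks[-1] * breaks[-length(breaks)]),
                 p = rowMeans(pm), sd = sdv, state = s,
                 n_events = sum(lengths(durs))),
            class = "dwell_histogram")
}

#' @export
print.dwell_histogram <- function(x, ...) {
  cat(sprintf("<dwell_histogram> %s state, %d bins over [%.3g, %.3g] ms, %d events\n",
              ifelse(x$state == 1, "open", "closed"), length(x$p),
              min(x$breaks), max(x$breaks), x$n_events))
  invisible(x)
}

check_shared_bins <- function(a, b) {
  if (length(a$breaks) != length(b$breaks) ||
      max(abs(a$breaks - b$breaks)) > 1e-9 * max(a$breaks))
    stop("histograms are not on shared bins")
}

#' Replicate scatter of experimental dwell histograms
#'
#' The mean over bins of the squared per-bin standard deviation across
#' replicate histograms: the intrinsic scatter of the reference data that
#' the simulated-histogram discrepancy ([chi2_sim()]) is compared against
#' in the fitting error functional.
#'
#' @param hists A list of >= 2 `dwell_histogram`s on shared bins, or a
#'   single replicate-built histogram carrying a per-bin `sd`.
#' @return Mean squared per-bin replicate SD.
#' @export
chi2_exp <- function(hists) {
  if (inherits(hists, "dwell_histogram")) {
    if (is.null(hists$sd)) stop("histogram carries no replicate SD; supply >= 2 replicates")
    return(mean(hists$sd^2))
  }
  if (length(hists) < 2) stop("at least 2 replicate histograms are required")
  for (h in hists[-1]) check_shared_bins(hists[[1]], h)
  pm <- vapply(hists, `[[`, numeric(length(hists[[1]]$p)), "p")
  mean(apply(matrix(pm, nrow = length(hists[[1]]$p)), 1,
             function(r) mean((r - mean(r))^2)))
}

#' Discrepancy between reference and simulated dwell histograms
#'
#' Mean over bins of the squared per-bin probability difference between a
#' reference (e.g. experimental) histogram and a simulated one, both on
#' shared bins.
#'
#' @param exp_hist,sim_hist `dwell_histogram`s on shared bins.
#' @return Mean squared per-bin probability difference (0 iff equal).
#' @export
chi2_sim <- function(exp_hist, sim_hist) {
  stopifnot(inherits(exp_hist, "dwell_histogram"),
            inherits(sim_hist, "dwell_histogram"))
  check_shared_bins(exp_hist, sim_hist)
  mean((exp_hist$p - sim_hist$p)^2)
}

#' Compare power-law and exponential descriptions of a dwell-time tail
#'
#' Qualitative discriminator between the two canonical dwell-distribution
#' shapes, evaluated on the empirical survivor function (complementary
#' CDF) of one state's dwell times: `log S(t)` is regressed against
#' `log t` (power law) and against `t` (single exponential) on a
#' log-spaced grid spanning the `q_lo`-to-`q_hi` quantile range, and the
#' shape with the smaller residual sum of squares wins. The survivor
#' function is used rather than a binned histogram because it is free of
#' binning noise in the sparse tail, where the two shapes differ most.
#'
#' @param ds A `dwell_series` from [extract_dwells()].
#' @param state `"open"`/`"closed"` (or 1/0).
#' @param q_lo,q_hi Quantile range of the dwell durations over which the
#'   survivor function is fitted.
#' @param n_grid Number of log-spaced evaluation points.
#' @return A list: `sse_power`, `sse_exp`, `better` (`"power"` or
#'   `"exponential"`), and `n_events`.
#' @export
tail_fit <- function(ds, state = "open", q_lo = 0.5, q_hi = 0.9995,
                     n_grid = 20) {
  stopifnot(inherits(ds, "dwell_series"))
  s <- state_code(state)
  d <- ds$duration[ds$state == s]
  if (length(d) < 100) stop("need at least 100 events for a tail comparison")
  qs <- stats::quantile(d, c(q_lo, q_hi), names = FALSE)
  if (qs[1] <= 0 || qs[2] <= qs[1]) stop("degenerate quantile range")
  tg <- exp(seq(log(qs[1]), log(qs[2]), length.out = n_grid))
  surv <- vapply(tg, function(t) mean(d > t), 0)
  keep <- surv > 0
  if (sum(keep) < 5) stop("fewer than 5 usable survivor points")
  lp <- log(surv[keep])
  t <- tg[keep]
  sse <- function(x) sum(stats::lm.fit(cbind(1, x), lp)$residuals^2)
  sp <- sse(log(t)); se <- sse(t)
  list(sse_power = sp, sse_exp = se,
       better = if (sp < se) "power" else "exponential",
       n_events = length(d))
}
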