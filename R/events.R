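#' Noisy single-channel current trace
#'
#' @param current Numeric vector of currents in pA.
#' @param dt Seconds per sample.
#' @param voltage Holding potential in mV (metadata only).
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(current, dt = 5e-5, voltage = NA_real_) {
  if (length(current) == 0) stop("`current` must be non-empty")
  if (dt <= 0) stop("`dt` must be > 0")
  structure(list(current = as.numeric(current), dt = dt, voltage = voltage),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples at dt = %g s (V = %s mV), mean |I| = %.2f pA\n",
              length(x$current), x$dt,
              ifelse(is.na(x$voltage), "?", format(x$voltage)), mean(abs(x$current))))
  invisible(x)
}

#' Kernel density estimate of the current magnitude distribution
#'
#' Estimates the probability density of `|I|` with an Epanechnikov kernel
#' (`K(u) = 3/4 (1 - u^2)` on `|u| <= 1`). Magnitudes are used so the
#' log-log representation needed by the power-law threshold construction is
#' defined for either polarity of the holding potential. The default
#' bandwidth is Silverman's rule on `|I|`.
#'
#' Kernel mass spilling below zero magnitude is reflected back across the
#' origin, so the returned density integrates to 1 over the grid.
#'
#' @param trace A [current_trace()] (or bare numeric vector of pA values).
#' @param bandwidth Kernel bandwidth in pA, or `NULL` for Silverman's rule.
#' @param n_grid Number of evaluation points.
#' @return A list with `grid` (pA), `density`, and `bandwidth`.
#' @export
kde_pdf <- function(trace, bandwidth = NULL, n_grid = 512) {
  x <- abs(if (inherits(trace, "current_trace")) trace$current else trace)
  if (length(x) < 100) stop("at least 100 samples are required")
  if (sd(x) == 0) stop("degenerate data: zero variance")
  if (is.null(bandwidth)) bandwidth <- bw.nrd0(x)
  hi <- max(x) + 3 * bandwidth
  d <- density(x, bw = bandwidth, kernel = "epanechnikov", n = 4 * n_grid,
               from = -3 * bandwidth, to = hi)
  grid <- seq(0, hi, length.out = n_grid)
  y <- stats::approx(d$x, d$y, grid, rule = 2)$y +
    stats::approx(d$x, d$y, -grid, yleft = 0, yright = 0, rule = 1)$y
  y[is.na(y)] <- 0
  list(grid = grid, density = y, bandwidth = d$bw)
}

# Indices of local density maxima (boundaries included).
local_maxima <- function(y) {
  which(diff(sign(diff(c(-Inf, y, -Inf)))) < 0)
}

# Best straight-line fit (in log-log space) over contiguous windows of at
# least `min_points` grid points: returns c(intercept, slope, i, j, r2).
best_powerlaw_window <- function(lx, ly, min_points) {
  n <- length(lx)
  if (n < min_points) return(NULL)
  best <- NULL; best_r2 <- -Inf
  for (i in seq_len(n - min_points + 1)) {
    for (j in seq(i + min_points - 1, n)) {
      fit <- stats::lm.fit(cbind(1, lx[i:j]), ly[i:j])
      tss <- sum((ly[i:j] - mean(ly[i:j]))^2)
      if (tss == 0) next
      r2 <- 1 - sum(fit$residuals^2) / tss
      if (r2 > best_r2) { best_r2 <- r2; best <- c(fit$coefficients, i, j, r2) }
    }
  }
  best
}

#' Threshold current from the kernel-density power-law intersection
#'
#' Implements the nonparametric threshold construction for bimodal current
#' distributions: the density of `|I|` is estimated with an Epanechnikov
#' kernel and examined on log-log axes, where each modal component shows an
#' approximately power-law inner flank. Straight lines are fitted by least
#' squares over contiguous windows (of at least `min_points` grid points)
#' on the two inner flanks, keeping the window with maximal r-squared, and
#' the abscissa of the intersection of the two fitted lines is returned as
#' the threshold.
#'
#' @inheritParams kde_pdf
#' @param min_points Minimum window length (grid points) for the flank fits.
#' @return An object of class `threshold_fit`: `threshold` (pA), the two
#'   flank `fits` (intercept, slope, fitted log-range, r-squared),
#'   `modes` (pA), and `bandwidth`.
#' @export
threshold_kde <- function(trace, bandwidth = NULL, min_points = 10) {
  k <- kde_pdf(trace, bandwidth)
  g <- k$grid; f <- k$density
  lm_idx <- local_maxima(f)
  lm_idx <- lm_idx[f[lm_idx] > 0.05 * max(f)]   # ignore sparse-tail bumps
  ord <- lm_idx[order(f[lm_idx], decreasing = TRUE)]
  if (length(ord) < 2) stop("no bimodality: fewer than two density modes")
  sep <- which(abs(g[ord] - g[ord[1]]) > 2 * k$bandwidth)
  if (length(sep) == 0) stop("no bimodality: modes closer than twice the bandwidth")
  modes <- sort(c(ord[1], ord[sep[1]]))
  trough <- modes[1] + which.min(f[modes[1]:modes[2]]) - 1L

  fit_flank <- function(idx) {
    keep <- idx[f[idx] > 0 & g[idx] > 0]
    lx <- log(g[keep])
    b <- best_powerlaw_window(lx, log(f[keep]), min_points)
    if (is.null(b)) return(NULL)
    list(intercept = unname(b[1]), slope = unname(b[2]),
         range = exp(c(lx[b[3]], lx[b[4]])), r2 = unname(b[5]))
  }
  lo <- fit_flank(modes[1]:trough)   # descending inner flank of the lower mode
  hi <- fit_flank(trough:modes[2])   # ascending inner flank of the upper mode
  if (is.null(lo) || is.null(hi)) stop("flank too short for a power-law fit")
  if (abs(lo$slope - hi$slope) < 1e-12) stop("no intersection: parallel flank fits")
  threshold <- exp((hi$intercept - lo$intercept) / (lo$slope - hi$slope))
  if (threshold <= g[modes[1]] || threshold >= g[modes[2]])
    stop("no intersection between the two modes")
  fits <- list(lower = lo, upper = hi)
  structure(list(threshold = threshold, fits = fits,
                 modes = g[modes], bandwidth = k$bandwidth),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("<threshold_fit> threshold = %.3f pA (modes at %.2f / %.2f pA, bw = %.3f)\n",
              x$threshold, x$modes[1], x$modes[2], x$bandwidth))
  cat(sprintf("  flank fits: slopes %.2f / %.2f, r2 %.4f / %.4f\n",
              x$fits$lower$slope, x$fits$upper$slope,
              x$fits$lower$r2, x$fits$upper$r2))
  invisible(x)
}

#' Threshold current from a double-Gaussian fit
#'
#' Fits a two-component Gaussian mixture to the current samples and returns
#' the equal-posterior crossing between the two component means, i.e. the
#' current at which the weighted component densities are equal. Serves as
#' the cross-check for [threshold_kde()]; the two estimates agree within a
#' few percent on well-separated bimodal traces.
#'
#' @param trace A [current_trace()] (or numeric vector of pA values).
#' @param max_fit_samples Mixture fitting is performed on at most this many
#'   samples (drawn deterministically) to keep large traces tractable.
#' @return Threshold in pA.
#' @export
threshold_double_gaussian <- function(trace, max_fit_samples = 1e5) {
  x <- if (inherits(trace, "current_trace")) trace$current else as.numeric(trace)
  n <- length(x)
  if (n < 100) stop("at least 100 samples are required")
  if (length(unique(x)) == 2)                  # noiseless two-level trace
    return(mean(range(x)))
  xs <- if (n > max_fit_samples) x[round(seq(1, n, length.out = max_fit_samples))] else x
  fit <- mclust::Mclust(xs, G = 2, modelNames = "V", verbose = FALSE,
                        initialization = list(
                          subset = round(seq(1, length(xs),
                                             length.out = min(2000, length(xs))))))
  if (is.null(fit)) stop("double-Gaussian fit did not converge")
  mu <- fit$parameters$mean
  sg <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sg) == 1) sg <- rep(sg, 2)
  pr <- fit$parameters$pro
  if (abs(diff(mu)) < 1e-8)
    stop("double-Gaussian fit did not separate two components (means coincide)")
  dens_gap <- function(z) pr[1] * dnorm(z, mu[1], sg[1]) - pr[2] * dnorm(z, mu[2], sg[2])
  lo <- min(mu); hi <- max(mu)
  if (dens_gap(lo) * dens_gap(hi) > 0)
    stop("double-Gaussian fit has no equal-density crossing between the means")
  uniroot(dens_gap, c(lo, hi), tol = 1e-10)$root
}

#' Idealize a current trace into a gating trace
#'
#' Thresholds the current magnitudes: a sample is open when `|I|` exceeds
#' the threshold. When no threshold is supplied it is estimated from the
#' trace by the requested method.
#'
#' @param trace A [current_trace()].
#' @param threshold Threshold in pA, or `NULL` to estimate it.
#' @param method Threshold estimator used when `threshold` is `NULL`:
#'   `"kde"` ([threshold_kde()]) or `"gauss2"`
#'   ([threshold_double_gaussian()]).
#' @return A [gating_trace()] of the same length and `dt`.
#' @export
idealize <- function(trace, threshold = NULL, method = c("kde", "gauss2")) {
  stopifnot(inherits(trace, "current_trace"))
  if (is.null(threshold)) {
    method <- match.arg(method)
    threshold <- if (method == "kde") threshold_kde(trace)$threshold
                 else threshold_double_gaussian(trace)
  }
  if (!is.finite(threshold)) stop("`threshold` must be finite")
  gating_trace(as.integer(abs(trace$current) > threshold), dt = trace$dt)
}
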