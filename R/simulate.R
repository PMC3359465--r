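#' Dichotomous gating trace
#'
#' Container for an open/closed state series at fixed sampling interval,
#' optionally carrying the aligned reaction-coordinate, boundary, or drift
#' side-channels recorded during simulation.
#'
#' @param states Integer vector of 0 (closed) / 1 (open).
#' @param dt Seconds per sample.
#' @param rc,b2,drift Optional side-channels of the same length.
#' @return An object of class `gating_trace`.
#' @export
gating_trace <- function(states, dt = 5e-5, rc = NULL, b2 = NULL, drift = NULL) {
  states <- as.integer(states)
  if (length(states) == 0) stop("`states` must be non-empty")
  if (!all(states %in% c(0L, 1L))) stop("`states` must contain only 0/1")
  if (dt <= 0) stop("`dt` must be > 0")
  for (side in list(rc, b2, drift))
    if (!is.null(side) && length(side) != length(states))
      stop("side-channels must match the state series length")
  structure(list(states = states, dt = dt, rc = rc, b2 = b2, drift = drift),
            class = "gating_trace")
}

#' @export
print.gating_trace <- function(x, ...) {
  n <- length(x$states)
  cat(sprintf("<gating_trace> %d samples (%.3g s at dt = %g s), open fraction %.3f\n",
              n, n * x$dt, x$dt, mean(x$states)))
  invisible(x)
}

#' Simulate a gating trace
#'
#' Runs the discrete random walk of the reaction coordinate under the
#' configured model. Each step evaluates the potential difference across
#' one lattice step centred on the current position, draws an up/down move
#' with probabilities `1/2 -/+ du/4`, reflects at the boundaries (a
#' rejected move leaves the coordinate in place), and skips the excluded
#' threshold node (a move onto it continues one node further in the same
#' direction, so a single accepted move crosses the barrier peak). Every
#' `t_b` (Model 1) or `t_df` (Model 2) steps the slow process updates the
#' boundaries or the drift slope, consuming the next draw of the same
#' random stream. The sample is open when the coordinate sits above the
#' threshold point.
#'
#' Identical `(cfg, n_steps, seed)` reproduce the trace bit-for-bit.
#'
#' @param cfg A [model_config()].
#' @param n_steps Number of steps (= samples) to simulate.
#' @param seed Optional integer seed (`set.seed()` is called when given).
#' @param record_paths Record the reaction-coordinate path plus the
#'   boundary (Model 1) or drift (Model 2) path alongside the states.
#' @param burn_in Steps to simulate and discard before recording. Default 0:
#'   the walk starts one node below the threshold, so at the reference
#'   series length the transient is negligible.
#' @return A [gating_trace()].
#' @examples
#' gt <- simulate_gating(model_config(1), 1e4, seed = 1)
#' open_probability(gt)
#' @export
simulate_gating <- function(cfg, n_steps, seed = NULL, record_paths = FALSE,
                            burn_in = 0) {
  stopifnot(inherits(cfg, "model_config"))
  if (n_steps < 1) stop("`n_steps` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  slow <- if (cfg$model == 1) cfg$t_b else cfg$t_df
  res <- .sim_core(cfg$model, n_steps + burn_in, cfg$tp, cfg$b1, cfg$b2,
                   cfg$b_max, cfg$u_barrier, cfg$f_d, cfg$drift_step,
                   cfg$drift_max, slow, record_paths)
  keep <- if (burn_in > 0) -seq_len(burn_in) else TRUE
  gating_trace(res$states[keep], dt = cfg$dt,
               rc = if (record_paths) res$rc[keep],
               b2 = if (record_paths && cfg$model == 1) res$b2[keep],
               drift = if (record_paths && cfg$model == 2) res$drift[keep])
}
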