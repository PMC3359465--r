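#' Model configuration for the gating random walk
#'
#' Bundles the lattice, potential and time-scale parameters of one model
#' variant. Model 1 confines the reaction coordinate (RC) between moveable,
#' mirror-symmetric boundaries whose synchronized fluctuations (period `t_b`
#' steps) carry the slow membrane-density process; a constant drift force
#' `f_d` stands in for sensor activation. Model 2 keeps the boundaries
#' (`b1`, `b2`) fixed and instead lets the drift slope perform its own
#' unbiased random walk (increment `drift_step`, reflecting at
#' `+/- drift_max`, period `t_df` steps); sensor activation is a shifted
#' threshold point `tp`.
#'
#' The lattice nodes are the integers of `[b1, b2]` excluding the threshold
#' node itself; the channel is open when RC > `tp`. The barrier separating
#' the open and closed manifolds is a tent of height `u_barrier` (kT)
#' peaking at `tp`, with flanks of half-width 1.5 rcu.
#'
#' @param model 1 (fluctuating boundaries) or 2 (fluctuating drift force).
#' @param b_max Model 1: maximum half-width of the conformational space, in
#'   rcu. The full lattice has `2 * b_max` occupiable nodes.
#' @param b1,b2 Model 2: fixed boundary positions in rcu (`b1 < tp < b2`).
#' @param tp Threshold point in rcu. Fixed at 0 for Model 1; one of
#'   `c(-14, -7, 0, 7, 14)` in the Model 2 reference runs.
#' @param u_barrier Barrier height `U(tp) - U(tp - 1.5)` in kT. Defaults to
#'   1.0 (Model 1) or 0.2 (Model 2).
#' @param f_d Model 1 only: constant drift slope in kT/rcu. Positive values
#'   tilt the potential up toward the open side, favouring closed states.
#' @param drift_step Model 2: increment of the drift slope per slow update,
#'   kT/rcu.
#' @param drift_max Model 2: reflecting limit on the drift slope, kT/rcu.
#' @param t_b Model 1: number of RC steps between boundary updates (the
#'   ratio of the RC and boundary diffusion coefficients).
#' @param t_df Model 2: number of RC steps between drift updates.
#' @param dt Real time per simulation step, seconds (the 20 kHz sampling of
#'   the emulated recordings gives `5e-5`).
#' @return An object of class `model_config`.
#' @examples
#' model_config(1)                 # Model 1 reference parameters
#' model_config(2, tp = -14)      # Model 2, strongly open-biased threshold
#' @export
model_config <- function(model = 1,
                         b_max = 14,
                         b1 = -18, b2 = 18,
                         tp = 0,
                         u_barrier = NULL,
                         f_d = 0,
                         drift_step = 0.005,
                         drift_max = 0.20,
                         t_b = 600,
                         t_df = 1200,
                         dt = 5e-5) {
  if (!model %in% c(1, 2)) stop("`model` must be 1 or 2")
  if (is.null(u_barrier)) u_barrier <- if (model == 1) 1.0 else 0.2
  if (u_barrier < 0) stop("`u_barrier` must be >= 0")
  if (dt <= 0) stop("`dt` must be > 0")
  if (model == 1) {
    tp <- as.integer(tp)
    if (tp != 0L) stop("Model 1 uses a fixed central threshold (tp = 0)")
    b_max <- as.integer(b_max)
    if (b_max < 2L) stop("`b_max` must be >= 2")
    if (t_b < 1) stop("`t_b` must be >= 1")
    if (abs(f_d) > 2) stop("|f_d| > 2 kT/rcu leaves the step probabilities outside [0, 1]")
    b1_init <- as.integer(floor(-b_max / 2))
    b2_init <- as.integer(floor(b_max / 2))
  } else {
    tp <- as.integer(tp)
    b1 <- as.integer(b1); b2 <- as.integer(b2)
    if (!(b1 < tp && tp < b2)) stop("Model 2 requires b1 < tp < b2")
    if (t_df < 1) stop("`t_df` must be >= 1")
    if (drift_step <= 0 || drift_max <= 0) stop("`drift_step` and `drift_max` must be > 0")
    b1_init <- b1
    b2_init <- b2
  }
  structure(
    list(model = as.integer(model), b_max = as.integer(b_max),
         b1 = b1_init, b2 = b2_init, tp = tp,
         u_barrier = u_barrier, f_d = f_d,
         drift_step = drift_step, drift_max = drift_max,
         t_b = as.integer(t_b), t_df = as.integer(t_df),
         rc_init = tp - 1L, dt = dt),
    class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> Model %d\n", x$model))
  if (x$model == 1) {
    cat(sprintf("  lattice +/-%d rcu (boundaries start at %+d/%+d), tp = %d\n",
                x$b_max, x$b1, x$b2, x$tp))
    cat(sprintf("  barrier %.2f kT, drift f_d = %+.3f kT/rcu, boundary period %d steps\n",
                x$u_barrier, x$f_d, x$t_b))
  } else {
    cat(sprintf("  boundaries %+d/%+d rcu, tp = %+d\n", x$b1, x$b2, x$tp))
    cat(sprintf("  barrier %.2f kT, drift walk |dk| = %.3f up to %.2f kT/rcu, period %d steps\n",
                x$u_barrier, x$drift_step, x$drift_max, x$t_df))
  }
  cat(sprintf("  dt = %g s/step, initial RC = %d rcu\n", x$dt, x$rc_init))
  invisible(x)
}

#' Instantaneous state of the gating walker
#'
#' Holds the quantities that evolve during a simulation: the reaction
#' coordinate, the current boundaries (Model 1) and the current drift slope
#' (Model 2). Mostly useful for evaluating the potential at a given moment
#' and for unit-testing the slow updates; [simulate_gating()] manages the
#' state internally.
#'
#' @param cfg A [model_config()].
#' @param rc Reaction coordinate, integer rcu; defaults to the configured
#'   initial position `tp - 1`.
#' @param b1,b2 Current boundaries (Model 1 defaults to the initial
#'   half-width positions).
#' @param drift_slope Current drift slope A in kT/rcu (Model 2).
#' @param step_index Simulation step counter.
#' @return An object of class `walker_state`.
#' @export
walker_state <- function(cfg, rc = cfg$rc_init, b1 = cfg$b1, b2 = cfg$b2,
                         drift_slope = 0, step_index = 0L) {
  rc <- as.integer(rc); b1 <- as.integer(b1); b2 <- as.integer(b2)
  if (rc < b1 || rc > b2) stop("`rc` must lie within [b1, b2]")
  if (rc == cfg$tp) stop("the threshold node is not occupiable")
  if (abs(drift_slope) > cfg$drift_max + 1e-12)
    stop("|drift_slope| exceeds `drift_max`")
  structure(list(rc = rc, b1 = b1, b2 = b2, drift_slope = drift_slope,
                 step_index = as.integer(step_index)),
            class = "walker_state")
}
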