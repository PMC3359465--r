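# Piecewise-linear conformational potential, R reference implementation.
# The C++ engine re-implements the same formulas for speed; tests compare
# the two routes through exact Markov-chain oracles.

pot_eval <- function(x, b1, tp, slope_a, u_barrier, model) {
  bslope <- u_barrier / 1.5
  u_tpm <- (tp - 1.5 - b1) * slope_a          # U(tp - 1.5), with U(b1) = 0
  a_out <- if (model == 1) slope_a else -slope_a
  ifelse(x < tp - 1.5,
         (x - b1) * slope_a,
  ifelse(x < tp,
         u_tpm + (x - (tp - 1.5)) * bslope,
  ifelse(x <= tp + 1.5,
         u_tpm + 1.5 * bslope - (x - tp) * bslope,
         u_tpm + (x - (tp + 1.5)) * a_out)))
}

#' Conformational potential of Model 1
#'
#' Evaluates the piecewise-linear potential `U(x)` (in kT) of the
#' fluctuating-boundary model: a linear ramp of slope `f_d` on both outer
#' segments, interrupted by a tent barrier of height `u_barrier` peaking at
#' the threshold point, with flanks of half-width 1.5 rcu. `U(b1) = 0` by
#' convention and the segments join continuously.
#'
#' @param x Position(s) in rcu (real-valued; half-steps are meaningful).
#' @param cfg A [model_config()] with `model = 1`.
#' @param state A [walker_state()] carrying the current boundaries.
#' @return Potential energy in kT, same length as `x`.
#' @examples
#' cfg <- model_config(1, f_d = 0)
#' st <- walker_state(cfg)
#' potential_m1(0, cfg, st) - potential_m1(-1.5, cfg, st)  # barrier height, 1 kT
#' @export
potential_m1 <- function(x, cfg, state = walker_state(cfg)) {
  if (cfg$model != 1) stop("`cfg` is not a Model 1 configuration")
  if (any(x < state$b1 | x > state$b2))
    stop("`x` outside the accessible range [b1, b2]")
  pot_eval(x, state$b1, cfg$tp, cfg$f_d, cfg$u_barrier, 1L)
}

#' Conformational potential of Model 2
#'
#' As [potential_m1()], but the outer segments carry antisymmetric slopes
#' `+A` (left) and `-A` (right), where `A = state$drift_slope` is the
#' current value of the slowly fluctuating drift force. The potential is
#' mirror-symmetric about the threshold point: positive `A` pushes the
#' reaction coordinate toward the boundaries, negative `A` pulls it toward
#' the threshold.
#'
#' @inheritParams potential_m1
#' @param cfg A [model_config()] with `model = 2`.
#' @return Potential energy in kT, same length as `x`.
#' @export
potential_m2 <- function(x, cfg, state = walker_state(cfg)) {
  if (cfg$model != 2) stop("`cfg` is not a Model 2 configuration")
  if (any(x < state$b1 | x > state$b2))
    stop("`x` outside the accessible range [b1, b2]")
  pot_eval(x, state$b1, cfg$tp, state$drift_slope, cfg$u_barrier, 2L)
}

#' Single-step transition probabilities
#'
#' Converts the potential difference `du = U(x + 1/2) - U(x - 1/2)` across
#' one lattice step (in kT) into the probabilities of the reaction
#' coordinate increasing (`p = 1/2 - du/4`) or decreasing
#' (`q = 1/2 + du/4`). Valid for `|du| <= 2`; larger differences are
#' clamped to `{0, 1}` with a warning (the reference parameter ranges never
#' reach them).
#'
#' @param du Potential difference(s) in kT.
#' @return A list with components `p` and `q` (`p + q = 1`).
#' @examples
#' step_probabilities(0)    # unbiased: p = q = 0.5
#' step_probabilities(0.4)  # p = 0.4, q = 0.6
#' @export
step_probabilities <- function(du) {
  if (any(abs(du) > 2)) {
    warning("|du| > 2 kT: step probabilities clamped to {0, 1}")
    du <- pmin(pmax(du, -2), 2)
  }
  list(p = 0.5 - du / 4, q = 0.5 + du / 4)
}

# Oriented potential difference deciding the move from integer node `x`.
# Centred difference except next to the threshold, where the jump across
# the excluded tp node is gated by the uphill half-step into the barrier.
du_at <- function(x, b1, tp, slope_a, u_barrier, model) {
  if (x == tp - 1L) {
    pot_eval(tp, b1, tp, slope_a, u_barrier, model) -
      pot_eval(tp - 0.5, b1, tp, slope_a, u_barrier, model)
  } else if (x == tp + 1L) {
    pot_eval(tp + 0.5, b1, tp, slope_a, u_barrier, model) -
      pot_eval(tp, b1, tp, slope_a, u_barrier, model)
  } else {
    pot_eval(x + 0.5, b1, tp, slope_a, u_barrier, model) -
      pot_eval(x - 0.5, b1, tp, slope_a, u_barrier, model)
  }
}

#' Slow boundary update of Model 1
#'
#' Performs one event of the slow membrane-density process: with
#' probability 1/2 both half-spaces shrink (`b1 + 1`, `b2 - 1`), with
#' probability 1/2 both expand, keeping `b1 = -b2`. Moves that would exceed
#' `b_max` or reduce `b2` below 2 are rejected (the state is returned
#' unchanged); if the reaction coordinate falls outside the new range it is
#' clamped to the nearest in-range node. Draws one uniform variate from the
#' R random number stream.
#'
#' @param state A [walker_state()].
#' @param cfg The [model_config()] (Model 1).
#' @return The updated `walker_state`.
#' @export
update_boundaries_m1 <- function(state, cfg) {
  if (cfg$model != 1) stop("`cfg` is not a Model 1 configuration")
  if (runif(1) < 0.5) {                      # shrink
    if (state$b2 - 1L >= 2L) {
      state$b1 <- state$b1 + 1L
      state$b2 <- state$b2 - 1L
    }
  } else {                                   # expand
    if (state$b2 + 1L <= cfg$b_max) {
      state$b1 <- state$b1 - 1L
      state$b2 <- state$b2 + 1L
    }
  }
  if (state$rc > state$b2) state$rc <- state$b2
  if (state$rc < state$b1) state$rc <- state$b1
  state
}

#' Slow drift update of Model 2
#'
#' Performs one event of the slow drift-force walk: the slope moves by
#' `+/- drift_step` with probability 1/2 each; moves beyond `+/- drift_max`
#' are rejected. The slope is tracked as an integer multiple of
#' `drift_step`, so the reflecting limits are hit exactly. Draws one
#' uniform variate from the R random number stream.
#'
#' @param state A [walker_state()].
#' @param cfg The [model_config()] (Model 2).
#' @return The updated `walker_state`.
#' @export
update_drift_m2 <- function(state, cfg) {
  if (cfg$model != 2) stop("`cfg` is not a Model 2 configuration")
  lvl <- round(state$drift_slope / cfg$drift_step)
  lvl_max <- round(cfg$drift_max / cfg$drift_step)
  dl <- if (runif(1) < 0.5) 1L else -1L
  if (abs(lvl + dl) <= lvl_max) lvl <- lvl + dl
  state$drift_slope <- lvl * cfg$drift_step
  state
}
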