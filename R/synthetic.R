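#' Patch-clamp recording specification
#'
#' Parameters of the emulated recording rig: Ohmic open-channel current
#' `I = g (V - V_rev)` (235.6 pS conductance and a reversal potential near
#' 0 mV are typical BK values in symmetric potassium), additive Gaussian
#' noise, and 20 kHz sampling. The default noise level is a tenth of the
#' open-channel current (signal-to-noise ratio about 10).
#'
#' @param voltage Holding potential, mV.
#' @param conductance Single-channel conductance, pS.
#' @param reversal Reversal potential, mV.
#' @param noise_sd Noise standard deviation, pA; default `NULL` means one
#'   tenth of the open-level magnitude.
#' @param sampling Sampling frequency, Hz.
#' @param seed Optional seed for the noise draw.
#' @return An object of class `recording_spec`.
#' @export
recording_spec <- function(voltage = 80, conductance = 235.6, reversal = 0,
                           noise_sd = NULL, sampling = 20000, seed = NULL) {
  if (sampling <= 0) stop("`sampling` must be > 0")
  level <- conductance * (voltage - reversal) / 1000   # pS * mV -> pA
  if (is.null(noise_sd)) noise_sd <- abs(level) / 10
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(voltage = voltage, conductance = conductance,
                 reversal = reversal, open_level = level,
                 noise_sd = noise_sd, sampling = sampling, seed = seed),
            class = "recording_spec")
}

#' Render a gating trace as a noisy current trace
#'
#' Maps each open sample to the Ohmic open-channel level and each closed
#' sample to 0 pA, then adds white Gaussian noise of the specified
#' standard deviation. Deterministic for a given `spec$seed`.
#'
#' @param gt A [gating_trace()]; its `dt` must match `1/spec$sampling`.
#' @param spec A [recording_spec()].
#' @return A [current_trace()].
#' @export
render_current <- function(gt, spec) {
  stopifnot(inherits(gt, "gating_trace"), inherits(spec, "recording_spec"))
  if (abs(gt$dt - 1 / spec$sampling) > 1e-12 * gt$dt)
    stop("`gt$dt` is inconsistent with `spec$sampling`")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  i <- gt$states * spec$open_level
  if (spec$noise_sd > 0) i <- i + rnorm(length(i), 0, spec$noise_sd)
  current_trace(i, dt = gt$dt, voltage = spec$voltage)
}

#' Simulated patch-clamp fixture with ground truth
#'
#' Couples a gating simulation to the current renderer, returning both the
#' noisy analog trace and the generating state series, so idealization and
#' downstream dwell/Hurst analyses can be validated end to end. The
#' default length of 6e6 samples at 20 kHz emulates a 300 s recording.
#'
#' @param model 1 or 2 (ignored when `cfg` is given).
#' @param n_steps Samples to simulate.
#' @param seed Integer seed governing both the walk and the noise.
#' @param cfg Optional [model_config()] overriding `model`'s defaults.
#' @param spec Optional [recording_spec()]; its seed is derived from
#'   `seed` when unset.
#' @param ... Passed to [model_config()] when `cfg` is `NULL` (e.g. `tp`,
#'   `f_d`).
#' @return A list with `current` (a [current_trace()]) and `truth` (the
#'   generating [gating_trace()]).
#' @export
make_fixture <- function(model = 1, n_steps = 6e6, seed = 1, cfg = NULL,
                         spec = NULL, ...) {
  if (is.null(cfg)) cfg <- model_config(model, ...)
  if (is.null(spec)) spec <- recording_spec()
  if (is.null(spec$seed)) spec$seed <- seed + 500009L
  if (abs(cfg$dt - 1 / spec$sampling) > 1e-12 * cfg$dt)
    stop("`cfg$dt` is inconsistent with `spec$sampling`")
  truth <- simulate_gating(cfg, n_steps, seed = seed)
  list(current = render_current(truth, spec), truth = truth)
}
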