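# gatewalk

Random-walk models of BK-channel activation-gate dynamics with
long-term memory, plus the analysis chain to validate them.

## The problem

Dwell-time series from single-channel patch-clamp recordings of
large-conductance voltage- and Ca²⁺-activated potassium (BK) channels
are long-range correlated: rescaled-range (R/S) analysis of the
alternating open/closed duration sequence gives Hurst exponents of
0.6–0.8 at every holding potential, where a memoryless process gives
H = 0.5. Finite-state Markov gating schemes reproduce dwell-time
*distributions* but not this memory. `gatewalk` is for biophysicists and
modellers who want a minimal, testable mechanism: the gate's reaction
coordinate x performs a nearest-neighbour random walk on an integer
lattice in a piecewise-linear potential U(x), with step probabilities

    p = 1/2 − ΔU/4kT   (up),   q = 1/2 + ΔU/4kT   (down),

a tent barrier of height U_TP − U_TP−1.5 separating the closed (x < TP)
and open (x > TP) manifolds, and **one slow, synchronized degree of
freedom** representing local membrane-density fluctuations:

- **Model 1** — the space boundaries B1 = −B2 shrink/expand together
  (period D_RC/D_B = 600 steps); sensor bias is a constant drift force
  F_d ∈ {±0.4, ±0.2, 0} kT/rcu.
- **Model 2** — fixed boundaries ±18; the drift slope itself random-walks
  (increment 0.005 kT/rcu, reflecting at ±0.2, period D_RC/D_DF = 1200);
  sensor bias is a shifted threshold TP ∈ {±14, ±7, 0}.

The package also provides: Epanechnikov-kernel / power-law-intersection
and double-Gaussian threshold idealization of noisy current traces,
dwell statistics and log-binned histograms, R/S Hurst analysis with
shuffle controls, the four-term relative-error functional
E = E_H + E_pop + E_dw,open + E_dw,closed with coordinate-descent
fitting (accept when each term < 5 % and E < 10 %), closed-form physical
scale estimates (apparent diffusion coefficients, the (D/D_S)^(3/5) mass
ratio, membrane/gate volumes), and a synthetic patch-clamp renderer
(235.6 pS, 20 kHz, SNR ≈ 10) for end-to-end testing.

## Worked example

One reference-scale Model 1 run (6×10⁶ samples ≙ 300 s at 20 kHz) and a
noisy synthetic recording pushed back through the idealizer:

```r
library(gatewalk)

cfg <- model_config(1)                        # barrier 1 kT, f_d = 0, t_b = 600
gt  <- simulate_gating(cfg, 6e6, seed = 1)
ds  <- extract_dwells(gt)
open_probability(gt)                          # 0.502
mean_dwell(ds, "open")                        # 0.783 ms
hurst_exponent(ds)                            # H = 0.815 (r2 = 0.9916),
                                              #   384,478 dwell events
shuffle_control(ds, seed = 2)$H               # 0.532 — memory gone

fx  <- make_fixture(1, n_steps = 1e6, seed = 3)   # 18.85 pA open level, SNR 10
thr <- threshold_kde(fx$current)              # threshold = 9.515 pA
threshold_double_gaussian(fx$current)         # 9.406 pA  (< 5 % apart)
mean(idealize(fx$current, threshold = thr$threshold)$states
     == fx$truth$states)                      # 0.999999
```

Read: at zero drift the channel is open half the time, dwell series are
strongly persistent (H ≈ 0.82, far above the 0.5 of a memoryless gate)
yet shuffling the same durations returns H ≈ 0.5, so the memory lives in
the ordering; and the two independent threshold estimators agree to ~1 %
on the synthetic recording, which the idealizer recovers essentially
exactly at SNR 10.

`reference_sweep(model, reps = 5, steps = 6e6, seed = ...)` runs the
full reference batch (five replicate series per regulatory value) and
returns mean ± SD of p_o, H, mean dwell times and the shuffled-H
control for each drift/threshold setting.

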