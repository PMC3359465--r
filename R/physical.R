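#' Physical length of one reaction-coordinate unit
#'
#' Maps the lattice onto a physical distance: one S6 inner helix of a
#' tetrameric channel has roughly half the vestibule diameter `d` of room
#' to move, projected on a lattice of `lattice_span` nodes, giving
#' `delta = d / (2 * lattice_span)` angstroms per rcu.
#'
#' @param d Vestibule diameter in angstroms (about 20 for the BK pore).
#' @param lattice_span Number of lattice nodes the movement is projected
#'   on (`2 * b_max` for Model 1).
#' @return Angstroms per rcu.
#' @examples
#' rcu_length(20, 40)       # 0.25 A, the published chain
#' rcu_length(20, 2 * 14)   # 0.357 A with the Model 1 half-width of 14
#' @export
rcu_length <- function(d, lattice_span) d / (2 * lattice_span)

#' Apparent diffusion coefficient at the sampling scale
#'
#' `D = delta^2 / (6 tau)` for step length `delta` (m) and time per step
#' `tau` (s). With the recording-limited `tau` this is an apparent, not a
#' thermal-scale, diffusivity.
#'
#' @param delta Step length in metres.
#' @param tau Seconds per step.
#' @return Diffusion coefficient in m^2/s.
#' @export
apparent_diffusion <- function(delta, tau) delta^2 / (6 * tau)

#' Mass ratio implied by a diffusion-coefficient ratio
#'
#' Within a collision-scaling picture (collision rate proportional to
#' surface area, mass proportional to volume, thermal velocities by
#' equipartition), the mass of a diffusing object scales as `D^(-3/5)`,
#' so the mass ratio of a slow and a fast object is
#' `(D_fast / D_slow)^(3/5)`.
#'
#' @param d_fast,d_slow Diffusion coefficients in consistent units.
#' @return The dimensionless mass ratio m_slow / m_fast.
#' @examples
#' mass_ratio_from_diffusion(4e-12, 1.73e-20)   # about 1.04e5
#' @export
mass_ratio_from_diffusion <- function(d_fast, d_slow) {
  if (any(c(d_fast, d_slow) <= 0)) stop("diffusion coefficients must be > 0")
  (d_fast / d_slow)^(3 / 5)
}

#' Cylinder volume (helix spanning the membrane)
#'
#' @param r Radius in angstroms.
#' @param h Height in angstroms (e.g. membrane thickness).
#' @return Volume in cubic angstroms.
#' @export
cylinder_volume <- function(r, h) pi * r^2 * h

#' Slab volume (membrane patch)
#'
#' @param s Surface area in square angstroms.
#' @param h Thickness in angstroms.
#' @return Volume in cubic angstroms.
#' @export
slab_volume <- function(s, h) s * h

#' Published intermediate values of the scale-bridging chain
#'
#' The printed constants of the physical-scale argument: rcu length,
#' sampling time, apparent gate diffusivity, membrane-helix diffusivity,
#' helix radius, membrane thickness, and patch surface area. Shipping them
#' as data lets the published chain be replayed verbatim alongside the
#' formula-derived one (see [physical_chain()]); the printed `d_cg`
#' differs from `delta^2/(6 tau)` evaluated at the printed `delta` and
#' `tau`, so the two chains are kept distinct.
#'
#' @return A named list of constants (angstroms, seconds, m^2/s).
#' @export
printed_scales <- function() {
  list(delta_angstrom = 0.25,      # printed rcu length
       tau_s = 5e-5,               # seconds per step (20 kHz sampling)
       d_cg = 1.04e-17,            # printed apparent gate diffusivity, m^2/s
       d_helix = 4e-12,            # membrane helix diffusivity, m^2/s
       d_s_printed = 1.73e-20,     # printed surrounding diffusivity, m^2/s
       slow_factor = 600,          # Model 1 time-scale ratio
       vestibule_d = 20,           # vestibule diameter, A
       helix_r = 2.5,              # S6 helix radius, A
       membrane_thickness = 70,    # A
       patch_area = 1e8)           # patch surface, A^2
}

#' Replay the physical scale-bridging chain
#'
#' Chains the closed-form estimates from the rcu length to the fraction of
#' the patch volume that must fluctuate to act as the channel gate's
#' "surrounding": rcu length, apparent gate diffusion coefficient, the
#' surrounding's diffusion coefficient (slower by the model's time-scale
#' factor), the implied mass ratio, the helix and patch volumes, their
#' ratio, and the patch-volume fraction (mass ratio / volume ratio).
#'
#' `chain = "printed"` replays the chain from the published intermediate
#' values of [printed_scales()]; `chain = "formula"` derives every link
#' from the formulas (note the published rcu length corresponds to a
#' 40-node lattice, whereas `2 * b_max = 28` with the Model 1 half-width;
#' both are therefore reported).
#'
#' @param chain `"printed"` or `"formula"`.
#' @param b_max Model half-width used by the formula chain.
#' @param slow_factor Time-scale ratio between the reaction coordinate and
#'   the slow process (600 for Model 1, 1200 for Model 2).
#' @return A named list: `delta_angstrom`, `d_cg`, `d_s`, `mass_ratio`,
#'   `v_helix`, `v_patch`, `volume_ratio`, `patch_fraction_percent`.
#' @export
physical_chain <- function(chain = c("printed", "formula"), b_max = 14,
                           slow_factor = 600) {
  chain <- match.arg(chain)
  k <- printed_scales()
  if (chain == "printed") {
    delta <- k$delta_angstrom
    d_cg <- k$d_cg
  } else {
    delta <- rcu_length(k$vestibule_d, 2 * b_max)
    d_cg <- apparent_diffusion(delta * 1e-10, k$tau_s)
  }
  d_s <- d_cg / slow_factor
  mass_ratio <- mass_ratio_from_diffusion(k$d_helix, d_s)
  v_helix <- cylinder_volume(k$helix_r, k$membrane_thickness)
  v_patch <- slab_volume(k$patch_area, k$membrane_thickness)
  volume_ratio <- v_patch / v_helix
  list(delta_angstrom = delta, d_cg = d_cg, d_s = d_s,
       mass_ratio = mass_ratio, v_helix = v_helix, v_patch = v_patch,
       volume_ratio = volume_ratio,
       patch_fraction_percent = 100 * mass_ratio / volume_ratio)
}
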