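# Calibrated detector-scale constants (T0 = 1 V convention, fs = 10 kHz,
# 1 kHz Gaussian filter, 0.1 s sliding-RMS window). The position
# responsivity is set so the residual fluctuation floor (trap hydrodynamics
# + instrument noise, conformational term off) has a median sliding RMS of
# 5.4 mV; the apo conformational amplitude then brings the trapped apo
# median to 6.8 mV, the control amplitudes to 14/15 mV. Values frozen from
# the package calibration run (see the methods vignette).
.cal <- list(
  instrument_noise = 3e-3,        # V RMS per sample at fs = 10 kHz
  position_responsivity = 131083, # V/m
  conf_amp_apo = 0.00421725,      # V RMS (band 3-150 Hz)
  holo_amp_factor = 0.79,         # holo conformational amplitude vs apo
  conf_amp_control = 0.0132518,   # ferric-control pre-exposure amplitude
  control_post_factor = 1.08345   # post/pre amplitude ratio for control
)

#' Protein signal preset
#'
#' Bundles the physical and signal parameters of one ferritin isoform:
#' geometry and dielectric properties (for the polarizability model), the
#' fractional transmission step contrast `step_contrast` (= deltaT/T0)
#' produced when the protein is trapped, and the amplitude and band of the
#' conformational fluctuation noise it adds to the detector signal.
#'
#' @param name preset name.
#' @param radius_nm outer radius, nm.
#' @param eps_particle,eps_medium relative permittivities.
#' @param core_conductivity S/m; 0 for an iron-free core.
#' @param step_contrast dimensionless deltaT/T0 (>= 0).
#' @param conf_amp_trapped RMS of the conformational fluctuation term at
#'   the detector, volts (at the T0 = 1 V scale).
#' @param conf_band numeric length-2, fluctuation band (Hz).
#' @return A list of class `protein_preset`.
#' @export
protein_preset <- function(name, radius_nm, eps_particle = 2.1,
                           eps_medium = 1.77, core_conductivity = 0,
                           step_contrast = 0.05,
                           conf_amp_trapped = 4.5e-3,
                           conf_band = c(3, 150)) {
  if (radius_nm <= 0) abort("`radius_nm` must be positive.",
                            class = "ferrotrace_invalid_parameter")
  if (eps_medium <= 0) abort("`eps_medium` must be positive.",
                             class = "ferrotrace_invalid_parameter")
  if (step_contrast < 0) abort("`step_contrast` must be >= 0.",
                               class = "ferrotrace_invalid_parameter")
  if (length(conf_band) != 2 || conf_band[1] <= 0 || conf_band[1] >= conf_band[2]) {
    abort("`conf_band` must be (f_lo, f_hi) with 0 < f_lo < f_hi.",
          class = "ferrotrace_invalid_parameter")
  }
  structure(
    list(name = name, radius_nm = radius_nm, eps_particle = eps_particle,
         eps_medium = eps_medium, core_conductivity = core_conductivity,
         step_contrast = step_contrast, conf_amp_trapped = conf_amp_trapped,
         conf_band = conf_band),
    class = "protein_preset")
}

#' Shipped isoform presets
#'
#' `preset_apo()`: the iron-free isoform — 6 nm radius, dielectric core,
#' step contrast 0.05, strong conformational fluctuations in the 3–150 Hz
#' band (the unfolded 3-fold channels make the apo shell floppy).
#' `preset_holo()`: the mineral-loaded isoform — about 1 nm larger radius
#' and a conductive ferrihydrite core give a 41% larger step contrast
#' (0.0705); the iron-stabilised shell fluctuates less (amplitude 0.79x
#' apo). `preset_ferric_control()`: a trapped protein exposed to ferric
#' (Fe3+) solution — no pore gating, constant large-amplitude
#' fluctuations calibrated to a 14 mV median sliding RMS before exposure
#' (15 mV after, via [simulate_control_experiment()]).
#'
#' @return A `protein_preset`.
#' @export
preset_apo <- function() {
  protein_preset("apo", radius_nm = 6, eps_particle = 2.1,
                 core_conductivity = 0, step_contrast = 0.05,
                 conf_amp_trapped = .cal$conf_amp_apo)
}

#' @rdname preset_apo
#' @export
preset_holo <- function() {
  protein_preset("holo", radius_nm = 7, eps_particle = 2.1,
                 core_conductivity = 1e4, step_contrast = 0.05 * 1.41,
                 conf_amp_trapped = .cal$conf_amp_apo * .cal$holo_amp_factor)
}

#' @rdname preset_apo
#' @export
preset_ferric_control <- function() {
  protein_preset("ferric_control", radius_nm = 6, eps_particle = 2.1,
                 core_conductivity = 0, step_contrast = 0.05,
                 conf_amp_trapped = .cal$conf_amp_control)
}

#' Two-state gating kinetics of iron loading
#'
#' Parameters of the phenomenological on–off process driven by folding and
#' unfolding of the ferritin 3-fold channels during Fe2+ loading: an
#' alternating Markov renewal process with exponential dwell times (means
#' `tau_on`, `tau_off`), state-dependent fluctuation amplitude multipliers
#' (`amp_on` for the unfolded, high-fluctuation state; `amp_off` for the
#' folded state), and a slow exponential decay of the overall
#' conformational amplitude with time constant `mineralization_tau` as the
#' mineral core grows and rigidifies the shell.
#'
#' @param tau_on,tau_off mean dwell times, seconds (> 0).
#' @param amp_on,amp_off amplitude multipliers; `amp_off < amp_on`.
#' @param mineralization_tau amplitude decay time constant, seconds.
#' @param loading_start absolute time at which iron loading (gating +
#'   mineralization) begins, seconds.
#' @return A list of class `gating_kinetics`.
#' @export
gating_kinetics <- function(tau_on = 3.5, tau_off = 3.5,
                            amp_on = 1, amp_off = 0.25,
                            mineralization_tau = 600, loading_start = 65) {
  if (tau_on <= 0 || tau_off <= 0) {
    abort("dwell means must be positive.", class = "ferrotrace_invalid_parameter")
  }
  if (!(amp_off < amp_on)) {
    abort("`amp_off` must be smaller than `amp_on`.",
          class = "ferrotrace_invalid_parameter")
  }
  structure(
    list(tau_on = tau_on, tau_off = tau_off, amp_on = amp_on,
         amp_off = amp_off, mineralization_tau = mineralization_tau,
         loading_start = loading_start),
    class = "gating_kinetics")
}

#' Trace generation configuration
#'
#' Sampling and schedule parameters for one synthetic experiment: sampling
#' rate, duration, the baseline transmission level `T0`, white instrument
#' noise, and the trapping/release times. The default rate of 10 kHz keeps
#' long traces desk-scale while leaving the 1 kHz analysis filter far
#' below Nyquist; the instrument's native MHz rate is configurable.
#'
#' @param fs sampling rate, Hz.
#' @param duration trace length, s.
#' @param T0 baseline transmission level, V.
#' @param instrument_noise white detector noise RMS per sample, V.
#' @param t_trap trapping time, s.
#' @param t_release release time, s, or `NULL` for no release.
#' @param seed integer seed.
#' @return A list of class `trace_config`.
#' @export
trace_config <- function(fs = 1e4, duration = 60, T0 = 1.0,
                         instrument_noise = .cal$instrument_noise,
                         t_trap = 5, t_release = NULL, seed = 1) {
  if (fs <= 0 || duration <= 0 || T0 <= 0) {
    abort("`fs`, `duration` and `T0` must be positive.",
          class = "ferrotrace_invalid_parameter")
  }
  if (!is.null(t_release)) {
    if (!(t_trap < t_release && t_release <= duration)) {
      abort("need 0 <= t_trap < t_release <= duration.",
            class = "ferrotrace_invalid_parameter")
    }
  }
  if (t_trap < 0 || t_trap >= duration) {
    abort("`t_trap` must lie inside [0, duration).",
          class = "ferrotrace_invalid_parameter")
  }
  structure(
    list(fs = fs, duration = duration, T0 = T0,
         instrument_noise = instrument_noise, t_trap = t_trap,
         t_release = t_release, seed = as.integer(seed)),
    class = "trace_config")
}
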