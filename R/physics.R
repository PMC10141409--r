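#' Clausius-Mossotti polarizability of a (possibly conductive) sphere
#'
#' Quasi-static polarizability of a homogeneous sphere of radius `radius` in
#' a medium of relative permittivity `eps_medium`,
#' \deqn{\alpha = 4\pi\varepsilon_0 r^3
#'       \frac{\tilde\varepsilon_p - \varepsilon_m}
#'            {\tilde\varepsilon_p + 2\varepsilon_m},}
#' where the particle permittivity is complex,
#' \eqn{\tilde\varepsilon_p = \varepsilon_p + i\,\sigma/(\omega\varepsilon_0)}
#' (Drude-type conduction term), and \eqn{\omega = 2\pi c/\lambda}. A
#' conductive mineral core therefore increases the magnitude of the
#' polarizability — the physical basis for the larger dielectric-loading
#' step of holo-ferritin.
#'
#' @param radius sphere radius in metres (> 0).
#' @param eps_particle real part of the particle relative permittivity.
#' @param eps_medium relative permittivity of the surrounding medium (> 0).
#' @param core_conductivity conductivity in S/m (0 for a pure dielectric).
#' @param wavelength vacuum wavelength in metres (> 0).
#' @return Complex polarizability in C m^2 / V.
#' @examples
#' # index-matched particle has zero polarizability
#' polarizability(6e-9, 1.77, 1.77, 0, 852e-9)
#' @export
polarizability <- function(radius, eps_particle, eps_medium,
                           core_conductivity = 0, wavelength = 852e-9) {
  if (!is.numeric(radius) || radius <= 0) {
    abort("`radius` must be positive.", class = "ferrotrace_invalid_parameter")
  }
  if (!is.numeric(wavelength) || wavelength <= 0) {
    abort("`wavelength` must be positive.", class = "ferrotrace_invalid_parameter")
  }
  omega <- 2 * pi * .c_light / wavelength
  eps_p <- complex(real = eps_particle,
                   imaginary = core_conductivity / (omega * .eps0))
  4 * pi * .eps0 * radius^3 * (eps_p - eps_medium) / (eps_p + 2 * eps_medium)
}

#' Fractional transmission step from polarizability
#'
#' Maps a polarizability to the dielectric-loading step contrast
#' \eqn{\delta = \Delta T/T_0} through a linear instrument responsivity:
#' `delta = loading_responsivity * Re(alpha) / (4 pi eps0 (1 nm)^3)`.
#' The normalisation makes the responsivity a dimensionless number per
#' cubic nanometre of Clausius-Mossotti volume, so presets remain readable.
#'
#' @param alpha complex polarizability (C m^2/V), e.g. from
#'   [polarizability()].
#' @param loading_responsivity positive scale factor mapping normalised
#'   polarizability to fractional transmission change.
#' @return Dimensionless step contrast `delta`.
#' @export
delta_from_polarizability <- function(alpha, loading_responsivity) {
  if (!is.numeric(loading_responsivity) || loading_responsivity <= 0) {
    abort("`loading_responsivity` must be positive.",
          class = "ferrotrace_invalid_parameter")
  }
  loading_responsivity * Re(alpha) / (4 * pi * .eps0 * (1e-9)^3)
}

#' Trap physics parameters
#'
#' Hydrodynamic parameters of the optical trap: an overdamped bead of
#' radius `radius` in a harmonic potential of stiffness `kappa`, with
#' Stokes drag `gamma = 6 pi eta r`, coupled to the detector through a
#' linear position responsivity `position_responsivity` (V/m). The trapped
#' particle position follows an Ornstein-Uhlenbeck process with corner
#' frequency `kappa / (2 pi gamma)`.
#'
#' @param kappa trap stiffness, N/m.
#' @param temperature absolute temperature, K.
#' @param viscosity medium dynamic viscosity, Pa s.
#' @param radius hydrodynamic radius of the particle, m.
#' @param position_responsivity detector coupling, V/m.
#' @return A list of class `trap_physics` with the parameters plus the
#'   derived `gamma` (kg/s) and `corner_hz`.
#' @export
trap_physics <- function(kappa = 1e-6, temperature = 298, viscosity = 8.9e-4,
                         radius = 6e-9, position_responsivity = 131083) {
  stopifnot(kappa > 0, temperature > 0, viscosity > 0, radius > 0)
  gamma <- 6 * pi * viscosity * radius
  structure(
    list(kappa = kappa, temperature = temperature, viscosity = viscosity,
         radius = radius, gamma = gamma,
         position_responsivity = position_responsivity,
         corner_hz = kappa / (2 * pi * gamma)),
    class = "trap_physics")
}
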