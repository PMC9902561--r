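#' Physical constants used throughout the package
#'
#' Fixed constants in the unit system of the package interface: forces in
#' piconewtons, distances in nanometres, energies in kcal/mol, SI internally.
#'
#' @return A named list with components `gas_constant` (kcal mol^-1 K^-1),
#'   `boltzmann` (pN nm K^-1) and `standard_gravity` (m s^-2). The list is
#'   rebuilt on each call so callers cannot mutate shared state.
#' @examples
#' physical_constants()$gas_constant
#' @export
physical_constants <- function() {
  list(
    gas_constant     = 1.9872e-3,   # kcal mol^-1 K^-1
    boltzmann        = 1.380649e-2, # pN nm K^-1
    standard_gravity = 9.80665      # m s^-2
  )
}

#' Acquisition configuration for a constant-force CFM run
#'
#' Bundles the spin and imaging parameters that convert centrifuge RPM into
#' tether force and define the time base of the saved frames. Defaults are
#' the calibration of a 2.8 um streptavidin bead (buoyancy-corrected mass
#' 6.9e-15 kg) spun at rotor radius 0.133 m, imaged at 1 frame/s with every
#' fifth frame saved, at room temperature (21 C).
#'
#' @param rpm Centrifuge speed, revolutions per minute (>= 0).
#' @param rotor_radius Distance from rotor centre to the sample chamber, metres.
#' @param bead_mass_eff Buoyancy-corrected bead mass, kilograms.
#' @param temperature Absolute temperature, kelvin.
#' @param frame_interval Seconds between saved frames.
#' @return An object of class `acquisition_config` (a validated list).
#' @examples
#' cfg <- acquisition_config(rpm = 1221)
#' rpm_to_force(1221, cfg)
#' @export
acquisition_config <- function(rpm = 0,
                               rotor_radius = 0.133,
                               bead_mass_eff = 6.9e-15,
                               temperature = 294.15,
                               frame_interval = 5) {
  stopifnot(
    is.numeric(rpm), length(rpm) == 1L, is.finite(rpm), rpm >= 0,
    is.numeric(rotor_radius), rotor_radius > 0,
    is.numeric(bead_mass_eff), bead_mass_eff > 0,
    is.numeric(temperature), temperature > 0,
    is.numeric(frame_interval), frame_interval > 0
  )
  structure(
    list(rpm = rpm, rotor_radius = rotor_radius,
         bead_mass_eff = bead_mass_eff, temperature = temperature,
         frame_interval = frame_interval),
    class = "acquisition_config"
  )
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat("CFM acquisition config\n")
  cat(sprintf("  rpm: %g  (force %.2f pN, RCF %.0f g)\n",
              x$rpm, rpm_to_force(x$rpm, x), rpm_to_rcf(x$rpm, x)))
  cat(sprintf("  rotor radius: %g m, bead mass (eff): %g kg\n",
              x$rotor_radius, x$bead_mass_eff))
  cat(sprintf("  temperature: %g K, frame interval: %g s\n",
              x$temperature, x$frame_interval))
  invisible(x)
}

check_rpm <- function(rpm) {
  if (!is.numeric(rpm) || any(!is.finite(rpm)) || any(rpm < 0))
    stop("`rpm` must be finite and non-negative", call. = FALSE)
  rpm
}

#' Convert centrifuge speed to tether force
#'
#' The centrifugal force on a tethered bead is F = m * omega^2 * r with
#' m the buoyancy-corrected bead mass, omega the angular velocity derived
#' from the spin rate, and r the rotor radius.
#'
#' @param rpm Spin rate(s), revolutions per minute (vectorised).
#' @param cfg An [acquisition_config()] supplying `bead_mass_eff` and
#'   `rotor_radius`.
#' @return Force in piconewtons, same length as `rpm`.
#' @examples
#' rpm_to_force(1410, acquisition_config()) # ~20 pN
#' @export
rpm_to_force <- function(rpm, cfg = acquisition_config()) {
  check_rpm(rpm)
  omega <- 2 * pi * rpm / 60
  cfg$bead_mass_eff * omega^2 * cfg$rotor_radius * 1e12
}

#' Convert centrifuge speed to relative centrifugal field
#'
#' The RCF is the centripetal acceleration omega^2 * r expressed in
#' multiples of standard gravity.
#'
#' @inheritParams rpm_to_force
#' @return RCF in multiples of g, same length as `rpm`.
#' @examples
#' rpm_to_rcf(1410, acquisition_config()) # ~296 g
#' @export
rpm_to_rcf <- function(rpm, cfg = acquisition_config()) {
  check_rpm(rpm)
  omega <- 2 * pi * rpm / 60
  omega^2 * cfg$rotor_radius / physical_constants()$standard_gravity
}

#' Spin rate required for a target tether force
#'
#' Closed-form inverse of [rpm_to_force()]; useful for planning a
#' constant-force run at a chosen force.
#'
#' @param force Target force(s) in piconewtons (>= 0, vectorised).
#' @param cfg An [acquisition_config()].
#' @return Spin rate in revolutions per minute.
#' @examples
#' force_to_rpm(15, acquisition_config()) # ~1221 rpm
#' @export
force_to_rpm <- function(force, cfg = acquisition_config()) {
  if (!is.numeric(force) || any(!is.finite(force)) || any(force < 0))
    stop("`force` must be finite and non-negative", call. = FALSE)
  omega <- sqrt(force * 1e-12 / (cfg$bead_mass_eff * cfg$rotor_radius))
  omega * 60 / (2 * pi)
}

#' Thermal energy k_B * T in pN nm
#'
#' @param temperature Absolute temperature in kelvin; must be at least 1 K
#'   (the sub-kelvin regime is outside the domain of this assay).
#' @return k_B * T in pN nm (about 4.06 pN nm at 294.15 K).
#' @examples
#' thermal_energy(294.15)
#' @export
thermal_energy <- function(temperature) {
  if (!is.numeric(temperature) || any(!is.finite(temperature)) ||
      any(temperature < 1))
    stop("`temperature` must be finite and >= 1 K", call. = FALSE)
  physical_constants()$boltzmann * temperature
}

#' Molar thermal energy R * T in kcal/mol
#'
#' Convenience used by the stacking-energy computation
#' (about 0.5845 kcal/mol at 294.15 K).
#'
#' @inheritParams thermal_energy
#' @return R * T in kcal/mol.
#' @export
rt_kcal <- function(temperature) {
  if (!is.numeric(temperature) || any(!is.finite(temperature)) ||
      any(temperature <= 0))
    stop("`temperature` must be finite and positive", call. = FALSE)
  physical_constants()$gas_constant * temperature
}
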