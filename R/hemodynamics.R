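# Dimensionless hemodynamics of pulsatile flow in an arteriovenous access.
#
# Conventions: the measurement tables exchanged with sonographers keep
# velocities in cm/s and diameters in mm; every function below that computes a
# dimensionless number works in SI (m/s, m), and the table-facing helpers
# (`hemodynamic_profile()`, `featurize()`) do the conversion.

#' Physical properties of blood
#'
#' Container for the fluid constants entering the Reynolds, Womersley and
#' Strouhal numbers. Defaults are the standard whole-blood values at body
#' temperature for a normal adult hematocrit.
#'
#' @param density Blood density in kg/m^3 (default 1055).
#' @param viscosity Dynamic viscosity in N s/m^2 (default 0.01063,
#'   whole blood; plasma alone is about 0.0035).
#' @param hematocrit Red-cell volume fraction, informational only
#'   (default 0.40).
#' @return An object of class `fluid_properties` with fields `density`,
#'   `viscosity`, `hematocrit` and the derived kinematic viscosity `nu`
#'   (m^2/s).
#' @export
#' @examples
#' fluid_properties()$nu # kinematic viscosity of whole blood
fluid_properties <- function(density = 1055, viscosity = 0.01063,
                             hematocrit = 0.40) {
  .check_positive(density, "density")
  .check_positive(viscosity, "viscosity")
  if (!is.finite(hematocrit) || hematocrit < 0 || hematocrit > 1) {
    stop("`hematocrit` must be a fraction in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      density = density, viscosity = viscosity, hematocrit = hematocrit,
      nu = viscosity / density
    ),
    class = "fluid_properties"
  )
}

#' Acoustic configuration of the Doppler measurement
#'
#' @param sound_speed Speed of sound in tissue, m/s (nominal 1540).
#' @param center_frequency Transducer center frequency f0 in Hz
#'   (default 7.5 MHz).
#' @param doppler_angle Angle between the acoustic beam and the flow axis,
#'   degrees; must be in `[0, 90)` so that cos(theta) > 0. Clinical probes
#'   work around 45--60 degrees.
#' @return An object of class `acoustic_config`.
#' @export
acoustic_config <- function(sound_speed = 1540, center_frequency = 7.5e6,
                            doppler_angle = 60) {
  .check_positive(sound_speed, "sound_speed")
  .check_positive(center_frequency, "center_frequency")
  if (!is.finite(doppler_angle) || doppler_angle < 0 || doppler_angle >= 90) {
    stop("`doppler_angle` must be in [0, 90) degrees (cos(theta) > 0)",
      call. = FALSE
    )
  }
  structure(
    list(
      sound_speed = sound_speed, center_frequency = center_frequency,
      doppler_angle = doppler_angle
    ),
    class = "acoustic_config"
  )
}

#' Flow velocity from the Doppler frequency shift
#'
#' Converts a Doppler shift `f_d` into the flow velocity within the sample
#' volume, `V = f_d * c / (2 * f0 * cos(theta))`.
#'
#' @param f_d Doppler shift frequency in Hz (>= 0, vectorized).
#' @param config An [acoustic_config()].
#' @return Velocity in m/s, same length as `f_d`.
#' @export
#' @examples
#' doppler_velocity(4870, acoustic_config(center_frequency = 7.5e6,
#'                                        doppler_angle = 60))
doppler_velocity <- function(f_d, config = acoustic_config()) {
  stopifnot(inherits(config, "acoustic_config"))
  .check_nonnegative(f_d, "f_d")
  f_d * config$sound_speed /
    (2 * config$center_frequency * cos(config$doppler_angle * pi / 180))
}

#' Resistive index
#'
#' `Res = (V_p - V_m) / V_p`, the classic unit-free indicator of vascular
#' resistance: it rises as the diastolic velocity collapses relative to the
#' systolic peak. The normal range for an access waveform is about
#' 0.50--0.65; higher values indicate disease or stenosis.
#'
#' @param v_p Peak-systolic velocity (> 0); any velocity unit, as long as
#'   `v_m` uses the same one.
#' @param v_m Peak-diastolic velocity, `0 <= v_m <= v_p`.
#' @return The resistive index in `[0, 1)`. Vectorized.
#' @export
#' @examples
#' resistive_index(103.20, 37.00)
resistive_index <- function(v_p, v_m) {
  .check_positive(v_p, "v_p")
  .check_nonnegative(v_m, "v_m")
  if (any(v_m > v_p)) {
    stop("`v_m` must not exceed `v_p` (peak-systolic and peak-diastolic ",
      "velocities look swapped)",
      call. = FALSE
    )
  }
  (v_p - v_m) / v_p
}

#' Peak pressure drop across a lesion
#'
#' The simplified Bernoulli relation `delta_P = 4 * V_p^2` mapping the
#' peak-systolic velocity (m/s) to a pressure drop in mmHg.
#'
#' @param v_p Peak-systolic velocity in m/s (>= 0, vectorized).
#' @return Pressure drop in mmHg.
#' @export
pressure_drop <- function(v_p) {
  .check_nonnegative(v_p, "v_p")
  4 * v_p^2
}

#' Reynolds number for pipe flow
#'
#' `Re = rho * V * D_H / mu`, the ratio of inertial to viscous forces.
#'
#' @param v Flow velocity in m/s (> 0).
#' @param d_h Hydraulic diameter in m (> 0).
#' @param fluid A [fluid_properties()].
#' @return Dimensionless Reynolds number. Vectorized over `v` and `d_h`.
#' @export
reynolds_number <- function(v, d_h, fluid = fluid_properties()) {
  stopifnot(inherits(fluid, "fluid_properties"))
  .check_positive(v, "v")
  .check_positive(d_h, "d_h")
  v * d_h * fluid$density / fluid$viscosity
}

#' Womersley number of pulsatile flow
#'
#' `alpha = (D_H / 2) * sqrt(2 * pi * f / nu)`, the ratio of unsteady to
#' viscous forces, with `f` the heart rate and `nu` the kinematic viscosity.
#'
#' @param d_h Hydraulic diameter in m (> 0).
#' @param heart_rate Pulse frequency in Hz (> 0).
#' @inheritParams reynolds_number
#' @return Dimensionless Womersley number. Vectorized.
#' @export
womersley_number <- function(d_h, heart_rate, fluid = fluid_properties()) {
  stopifnot(inherits(fluid, "fluid_properties"))
  .check_positive(d_h, "d_h")
  .check_positive(heart_rate, "heart_rate")
  (d_h / 2) * sqrt(2 * pi * heart_rate / fluid$nu)
}

#' Strouhal number of oscillating flow
#'
#' `St = f * D_H / V`, the ratio of oscillatory to convective inertial
#' forces; also a dimensionless stroke volume.
#'
#' @inheritParams womersley_number
#' @param v Flow velocity in m/s (> 0).
#' @return Dimensionless Strouhal number. Vectorized.
#' @export
strouhal_number <- function(heart_rate, d_h, v) {
  .check_positive(heart_rate, "heart_rate")
  .check_positive(d_h, "d_h")
  .check_positive(v, "v")
  heart_rate * d_h / v
}

#' Critical peak Reynolds number
#'
#' The power-law transition threshold for pulsatile flow instability,
#' `Re_peak = 169 * alpha^0.83 * St^-0.27`: the Reynolds number at the
#' systolic peak above which the flow trips from transition to turbulence.
#'
#' @param alpha Womersley number (> 0).
#' @param st Strouhal number (> 0).
#' @return Dimensionless critical peak Reynolds number. Vectorized.
#' @export
#' @examples
#' critical_peak_reynolds(1, 1) # the bare power-law coefficient, 169
critical_peak_reynolds <- function(alpha, st) {
  .check_positive(alpha, "alpha")
  .check_positive(st, "st")
  169 * alpha^0.83 * st^-0.27
}

#' Supracritical Reynolds number
#'
#' `Re_supra = |Re - Re_peak|`, the distance of the measured Reynolds number
#' from the critical transition threshold.
#'
#' @param re Reynolds number (>= 0).
#' @param re_peak Critical peak Reynolds number (> 0).
#' @return `|re - re_peak|`. Vectorized.
#' @export
supracritical_reynolds <- function(re, re_peak) {
  .check_nonnegative(re, "re")
  .check_positive(re_peak, "re_peak")
  abs(re - re_peak)
}

#' Hydraulic diameter of a noncircular duct
#'
#' `D_H = 4 * A / P` with `P` the wetted perimeter, supplied as the sum of
#' discretized surface segment lengths. For a circular duct `D_H` equals the
#' diameter.
#'
#' @param area Cross-sectional area in m^2 (> 0).
#' @param perimeter_segments Lengths of the surface segments in contact with
#'   the fluid, m (each > 0); their sum is the wetted perimeter.
#' @return Hydraulic diameter in m.
#' @export
#' @examples
#' hydraulic_diameter(1, rep(1, 4)) # unit square duct -> 1
hydraulic_diameter <- function(area, perimeter_segments) {
  .check_positive(area, "area")
  .check_positive(perimeter_segments, "perimeter_segments")
  4 * area / sum(perimeter_segments)
}

#' Degree of stenosis
#'
#' `DOS = 1 - (d_H / D_H)^2`, the areal luminal reduction of the stenotic
#' lesion (`d_H`) relative to the adjacent normal vessel (`D_H`). `DOS = 1`
#' is total occlusion. Class bands: Class I `DOS < 0.30`, Class II
#' `0.30 < DOS < 0.50`, Class III `DOS > 0.50`.
#'
#' @param d_h Hydraulic diameter of the stenotic lesion, `0 <= d_h <= D_H`.
#' @param D_h Hydraulic diameter of the normal vessel (> 0).
#' @return DOS in `[0, 1]`. Vectorized.
#' @export
degree_of_stenosis <- function(d_h, D_h) {
  .check_nonnegative(d_h, "d_h")
  .check_positive(D_h, "D_h")
  if (any(d_h > D_h)) {
    stop("`d_h` must not exceed `D_h`", call. = FALSE)
  }
  1 - (d_h / D_h)^2
}

#' Stenosis class from the degree of stenosis
#'
#' @param dos Degree of stenosis in `[0, 1]` (vectorized).
#' @return Factor with levels `I`, `II`, `III` (boundaries 0.30 and 0.50;
#'   a value exactly on a boundary is assigned to the milder class).
#' @export
dos_class <- function(dos) {
  if (any(!is.finite(dos)) || any(dos < 0) || any(dos > 1)) {
    stop("`dos` must be in [0, 1]", call. = FALSE)
  }
  cls <- ifelse(dos > 0.50, "III", ifelse(dos > 0.30, "II", "I"))
  factor(cls, levels = CLASS_LEVELS)
}

#' Per-unit supracritical-Reynolds ratios
#'
#' Normalizes the supracritical Reynolds numbers of the three measurement
#' sites by the loop-site value, so the loop ratio is 1 by construction and
#' the arterial/venous ratios read as per-unit departures from it.
#'
#' @param re_supra_a,re_supra_l,re_supra_v Supracritical Reynolds numbers at
#'   the arterial anastomosis, loop, and venous anastomosis sites (>= 0).
#' @param tol Smallest loop-site value accepted as a per-unit base
#'   (default 1e-9): a loop site sitting exactly on the transition threshold
#'   has no meaningful per-unit basis.
#' @return Named numeric vector `c(ratio_A, ratio_L, ratio_V)` with
#'   `ratio_L == 1` exactly.
#' @export
supra_ratios <- function(re_supra_a, re_supra_l, re_supra_v, tol = 1e-9) {
  .check_nonnegative(re_supra_a, "re_supra_a")
  .check_nonnegative(re_supra_l, "re_supra_l")
  .check_nonnegative(re_supra_v, "re_supra_v")
  if (re_supra_l < tol) {
    stop("loop-site supracritical Reynolds number is ~0 (flow at the ",
      "transition threshold); per-unit ratios are undefined",
      call. = FALSE
    )
  }
  c(
    ratio_A = re_supra_a / re_supra_l,
    ratio_L = 1,
    ratio_V = re_supra_v / re_supra_l
  )
}

#' Dimensionless hemodynamic profile of one measurement site
#'
#' Computes, from one site's Doppler velocimetry record, the full set of
#' dimensionless numbers used by the screening pipeline: Reynolds (at the
#' systolic peak), Womersley, Strouhal, critical peak Reynolds,
#' supracritical Reynolds, resistive index, and the simplified-Bernoulli
#' pressure drop.
#'
#' @param v_p_cm_s Peak-systolic velocity, cm/s (> 0).
#' @param v_m_cm_s Peak-diastolic velocity, cm/s (`0 < v_m <= v_p`).
#' @param heart_rate_hz Heart rate, Hz (> 0).
#' @param d_h_mm Hydraulic diameter of the site, mm (> 0).
#' @param fluid A [fluid_properties()].
#' @return A data frame (one row per input element) with columns `Re`,
#'   `alpha`, `St`, `Re_peak`, `Re_supra`, `Res`, `delta_P_mmHg`.
#' @export
#' @examples
#' hemodynamic_profile(103.2, 37.0, 1.1, 5.0)
hemodynamic_profile <- function(v_p_cm_s, v_m_cm_s, heart_rate_hz, d_h_mm,
                                fluid = fluid_properties()) {
  v_p <- v_p_cm_s / 100 # m/s
  d_h <- d_h_mm / 1000 # m
  re <- reynolds_number(v_p, d_h, fluid)
  alpha <- womersley_number(d_h, heart_rate_hz, fluid)
  st <- strouhal_number(heart_rate_hz, d_h, v_p)
  re_peak <- critical_peak_reynolds(alpha, st)
  data.frame(
    Re = re,
    alpha = alpha,
    St = st,
    Re_peak = re_peak,
    Re_supra = supracritical_reynolds(re, re_peak),
    Res = resistive_index(v_p_cm_s, v_m_cm_s),
    delta_P_mmHg = pressure_drop(v_p)
  )
}
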