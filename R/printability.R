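#' Fluid/jet configuration for droplet printability analysis
#'
#' Bundles the physical properties of a bioink (here, cell-laden culture
#' medium) and the jetting configuration of a droplet-based bioprinter.
#' All quantities are SI; [read_fluid_spec()] converts common lab units.
#'
#' @param viscosity dynamic viscosity \eqn{\eta} (Pa·s).
#' @param surface_tension surface tension \eqn{\gamma} (N/m).
#' @param density fluid density \eqn{\rho} (kg/m³).
#' @param orifice_diameter nozzle orifice inner diameter \eqn{L} (m).
#' @param droplet_velocity droplet velocity \eqn{U} (m/s); may be 0 when only
#'   velocity-independent numbers (Oh, Z, Bo) are needed.
#' @param gravity gravitational acceleration \eqn{g} (m/s²).
#' @return an object of class `fluid_jet_spec`.
#' @examples
#' water_like_medium()
#' @export
fluid_jet_spec <- function(viscosity, surface_tension, density,
                           orifice_diameter, droplet_velocity = 0,
                           gravity = 9.81) {
  .check_positive(viscosity = viscosity, surface_tension = surface_tension,
                  density = density, orifice_diameter = orifice_diameter,
                  gravity = gravity)
  .check_nonnegative(droplet_velocity = droplet_velocity)
  structure(
    list(viscosity = viscosity, surface_tension = surface_tension,
         density = density, orifice_diameter = orifice_diameter,
         droplet_velocity = droplet_velocity, gravity = gravity),
    class = "fluid_jet_spec")
}

#' @export
print.fluid_jet_spec <- function(x, ...) {
  cat("Fluid/jet spec (SI units)\n")
  cat(sprintf("  viscosity        %.4g Pa.s\n", x$viscosity))
  cat(sprintf("  surface tension  %.4g N/m\n", x$surface_tension))
  cat(sprintf("  density          %.4g kg/m^3\n", x$density))
  cat(sprintf("  orifice diameter %.4g m\n", x$orifice_diameter))
  cat(sprintf("  droplet velocity %.4g m/s\n", x$droplet_velocity))
  invisible(x)
}

#' Documented water-like culture-medium default configuration
#'
#' Cell culture media are dilute aqueous solutions, so their physical
#' properties sit close to water at room temperature: viscosity 1.0 mPa·s,
#' surface tension 72.8 mN/m, density 998 kg/m³. Combined with a 250 µm
#' nozzle and a 2 m/s droplet velocity this gives a reference configuration
#' for examples and tests.
#'
#' @param droplet_velocity droplet velocity (m/s).
#' @return a [fluid_jet_spec()].
#' @export
water_like_medium <- function(droplet_velocity = 2) {
  fluid_jet_spec(viscosity = 1.0e-3, surface_tension = 0.0728,
                 density = 998, orifice_diameter = 250e-6,
                 droplet_velocity = droplet_velocity)
}

.as_spec <- function(spec) {
  if (!inherits(spec, "fluid_jet_spec"))
    stop("'spec' must be a fluid_jet_spec object")
  spec
}

#' Ohnesorge number
#'
#' \eqn{Oh = \eta / \sqrt{\gamma \rho L}}; the jettability number
#' \eqn{Z = 1/Oh}. Oh is independent of the droplet velocity, and for
#' \eqn{U > 0} equals \eqn{\sqrt{We}/Re}.
#'
#' @param spec a [fluid_jet_spec()].
#' @return dimensionless Ohnesorge number.
#' @export
ohnesorge <- function(spec) {
  spec <- .as_spec(spec)
  spec$viscosity /
    sqrt(spec$surface_tension * spec$density * spec$orifice_diameter)
}

#' Weber number: \eqn{We = \rho U^2 L / \gamma}
#' @inheritParams ohnesorge
#' @return dimensionless Weber number.
#' @export
weber <- function(spec) {
  spec <- .as_spec(spec)
  spec$density * spec$droplet_velocity^2 * spec$orifice_diameter /
    spec$surface_tension
}

#' Reynolds number: \eqn{Re = \rho U L / \eta}
#' @inheritParams ohnesorge
#' @return dimensionless Reynolds number.
#' @export
reynolds <- function(spec) {
  spec <- .as_spec(spec)
  spec$density * spec$droplet_velocity * spec$orifice_diameter /
    spec$viscosity
}

#' Froude number: \eqn{Fr = U / \sqrt{g L}}
#' @inheritParams ohnesorge
#' @return dimensionless Froude number.
#' @export
froude <- function(spec) {
  spec <- .as_spec(spec)
  spec$droplet_velocity / sqrt(spec$gravity * spec$orifice_diameter)
}

#' Bond number: \eqn{Bo = \rho g L^2 / \gamma}
#'
#' Ratio of gravitational to surface-tension forces at the nozzle scale.
#' `Bo < 1` marks gravity as negligible for droplet spreading, so
#' deposition is driven by inertial/capillary forces.
#'
#' @inheritParams ohnesorge
#' @return dimensionless Bond number.
#' @export
bond <- function(spec) {
  spec <- .as_spec(spec)
  spec$density * spec$gravity * spec$orifice_diameter^2 /
    spec$surface_tension
}

#' Splashing parameter: \eqn{K_{sp} = \sqrt{We \sqrt{Re}}}
#'
#' Droplet impacts with \eqn{K_{sp} < 57.7} do not splash significantly;
#' the classification boundary is exactly 57.7, with the splashing side
#' taken as \eqn{K_{sp} \ge 57.7}. See [is_splashing()].
#'
#' @inheritParams ohnesorge
#' @return dimensionless splashing parameter (0 when the velocity is 0).
#' @export
splashing_parameter <- function(spec) {
  spec <- .as_spec(spec)
  sqrt(weber(spec) * sqrt(reynolds(spec)))
}

#' Splashing classification at the K_sp = 57.7 boundary
#' @param k_sp splashing parameter value(s).
#' @return logical: `TRUE` when `k_sp >= 57.7` (significant splashing).
#' @export
is_splashing <- function(k_sp) {
  if (any(!is.finite(k_sp) | k_sp < 0)) stop("'k_sp' must be non-negative")
  k_sp >= 57.7
}

#' Full dimensionless printability profile
#'
#' Aggregates Oh, We, Re, Fr, Bo, Z = 1/Oh and K_sp, with the two regime
#' flags used to judge deposition behavior: `gravity_negligible`
#' (Bo < 1) and `splashing` (K_sp >= 57.7).
#'
#' @inheritParams ohnesorge
#' @return an object of class `printability_profile` (a named list).
#' @examples
#' printability_profile(water_like_medium())
#' @export
printability_profile <- function(spec) {
  spec <- .as_spec(spec)
  oh <- ohnesorge(spec)
  ksp <- splashing_parameter(spec)
  bo <- bond(spec)
  structure(
    list(Oh = oh, We = weber(spec), Re = reynolds(spec),
         Fr = froude(spec), Bo = bo, Z = 1 / oh, K_sp = ksp,
         gravity_negligible = bo < 1, splashing = is_splashing(ksp)),
    class = "printability_profile")
}

#' @export
print.printability_profile <- function(x, ...) {
  cat("Dimensionless printability profile\n")
  for (nm in c("Oh", "We", "Re", "Fr", "Bo", "Z", "K_sp"))
    cat(sprintf("  %-5s %12.5g\n", nm, x[[nm]]))
  cat(sprintf("  gravity negligible (Bo < 1):   %s\n", x$gravity_negligible))
  cat(sprintf("  splashing (K_sp >= 57.7):      %s\n", x$splashing))
  invisible(x)
}

#' @export
as.data.frame.printability_profile <- function(x, ...) {
  data.frame(Oh = x$Oh, We = x$We, Re = x$Re, Fr = x$Fr, Bo = x$Bo,
             Z = x$Z, K_sp = x$K_sp,
             gravity_negligible = x$gravity_negligible,
             splashing = x$splashing)
}

#' Per-droplet volume and equivalent-sphere diameter from gravimetry
#'
#' A dispensed batch of `droplet_count` droplets is weighed; the mean
#' droplet volume is mass / (density × count) and the equivalent spherical
#' diameter is \eqn{(6V/\pi)^{1/3}}.
#'
#' @param total_mass mass of the dispensed batch (kg).
#' @param droplet_count number of droplets dispensed (>= 1).
#' @param density fluid density (kg/m³).
#' @return list with `volume` (m³ per droplet) and `diameter` (m).
#' @examples
#' droplet_volume(1.0e-5, 1000, 1000)  # 10 nl, ~267 um
#' @export
droplet_volume <- function(total_mass, droplet_count, density) {
  .check_positive(total_mass = total_mass, density = density)
  if (!is.numeric(droplet_count) || length(droplet_count) != 1L ||
      droplet_count < 1 || droplet_count != round(droplet_count))
    stop("'droplet_count' must be an integer >= 1")
  volume <- total_mass / (density * droplet_count)
  list(volume = volume, diameter = (6 * volume / pi)^(1 / 3))
}

#' Droplet velocity from tracked positions
#'
#' Least-squares slope of displacement versus time for a droplet tracked
#' over uniformly spaced video frames. The regression slope is robust to
#' per-frame jitter in the tracked centroid.
#'
#' @param positions displacements along the flight path (m), one per frame.
#' @param frame_interval time between frames (s).
#' @return velocity (m/s).
#' @examples
#' droplet_velocity(c(0, 2e-3, 4e-3), 1e-3)  # 2 m/s
#' @export
droplet_velocity <- function(positions, frame_interval) {
  if (!is.numeric(positions) || length(positions) < 2L)
    stop("need at least 2 tracked positions")
  .check_positive(frame_interval = frame_interval)
  t <- (seq_along(positions) - 1) * frame_interval
  unname(stats::coef(stats::lm(positions ~ t))[2])
}
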