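# Hydrodynamic force model for flow-stretching: plane-Poiseuille profile in
# a shallow rectangular channel plus Stokes drag on a tethered micron bead.
# SI units internally; forces reported in pN.

#' Flow-chamber geometry and fluid properties
#'
#' Defaults describe a shallow PDMS channel (15 mm x 1 mm x 0.06 mm), water
#' at room temperature and a 1 um streptavidin bead tethered at the surface,
#' so the particle centre sits one radius above the wall.
#'
#' @param width_m Channel width, m.
#' @param height_m Channel height, m.
#' @param length_m Channel length, m (informational).
#' @param viscosity_Pa_s Dynamic viscosity, Pa s.
#' @param particle_radius_m Bead radius, m.
#' @param particle_height_m Height of the bead centre above the surface, m.
#' @param faxen_factor Optional drag multiplier for wall proximity; the
#'   default 1 applies unmodified Stokes drag.
#' @return An object of class `flow_chamber`.
#' @export
flow_chamber <- function(width_m = 1e-3, height_m = 6e-5, length_m = 15e-3,
                         viscosity_Pa_s = 8.9e-4, particle_radius_m = 0.5e-6,
                         particle_height_m = particle_radius_m,
                         faxen_factor = 1) {
  out <- list(
    width_m = check_scalar(width_m, "width_m", lower = 0, strict = TRUE),
    height_m = check_scalar(height_m, "height_m", lower = 0, strict = TRUE),
    length_m = check_scalar(length_m, "length_m", lower = 0, strict = TRUE),
    viscosity_Pa_s = check_scalar(viscosity_Pa_s, "viscosity_Pa_s", lower = 0, strict = TRUE),
    particle_radius_m = check_scalar(particle_radius_m, "particle_radius_m",
                                     lower = 0, strict = TRUE),
    particle_height_m = check_scalar(particle_height_m, "particle_height_m",
                                     lower = 0, strict = TRUE),
    faxen_factor = check_scalar(faxen_factor, "faxen_factor", lower = 0, strict = TRUE)
  )
  if (out$particle_height_m >= out$height_m) {
    stop_validation("Particle centre (%g m) must sit inside the channel (height %g m).",
                    out$particle_height_m, out$height_m)
  }
  if (out$particle_radius_m >= out$height_m / 2) {
    stop_validation("Particle radius must be smaller than half the channel height.")
  }
  structure(out, class = "flow_chamber")
}

#' Maximum velocity of the parabolic channel profile
#'
#' `v_max = 3 Q / (2 w h)` for fully developed flow between parallel plates.
#'
#' @param Q Volumetric flow rate, m^3/s.
#' @param width_m,height_m Channel cross-section, m.
#' @return Velocity, m/s.
#' @export
v_max <- function(Q, width_m, height_m) {
  Q <- check_scalar(Q, "Q", lower = 0)
  width_m <- check_scalar(width_m, "width_m", lower = 0, strict = TRUE)
  height_m <- check_scalar(height_m, "height_m", lower = 0, strict = TRUE)
  3 * Q / (2 * width_m * height_m)
}

#' Velocity at height z of the parabolic profile
#'
#' `v(z) = 4 v_max (z/h) (1 - z/h)`: zero at the walls, `v_max` at mid-height.
#'
#' @param z Height above the lower wall, m (0 <= z <= h).
#' @param vmax Profile maximum, m/s.
#' @param height_m Channel height, m.
#' @return Velocity, m/s.
#' @export
velocity_at <- function(z, vmax, height_m) {
  height_m <- check_scalar(height_m, "height_m", lower = 0, strict = TRUE)
  if (any(z < 0 | z > height_m)) {
    stop_validation("z must lie inside the channel, 0 <= z <= %g m.", height_m)
  }
  4 * vmax * (z / height_m) * (1 - z / height_m)
}

#' Stokes drag force on a sphere, in pN
#'
#' `F = 6 pi eta r v`, converted from N to pN.
#'
#' @param viscosity_Pa_s Dynamic viscosity, Pa s.
#' @param radius_m Sphere radius, m.
#' @param velocity_m_s Flow velocity at the sphere centre, m/s.
#' @return Force, pN.
#' @export
stokes_force <- function(viscosity_Pa_s, radius_m, velocity_m_s) {
  if (any(c(viscosity_Pa_s, radius_m, velocity_m_s) < 0)) {
    stop_validation("Stokes-law arguments must be non-negative.")
  }
  6 * pi * viscosity_Pa_s * radius_m * velocity_m_s * 1e12
}

#' Convert a volumetric flow rate to the drag force on the tethered bead
#'
#' Chains the three maps: flow rate -> profile maximum -> velocity at the
#' bead centre -> Stokes drag. All three are linear, so the force is linear
#' in the flow rate at fixed geometry.
#'
#' @param Q_ul_min Flow rate in ul/min.
#' @param chamber A [flow_chamber()].
#' @return Force in pN.
#' @export
#' @examples
#' flow_to_force(1300)
flow_to_force <- function(Q_ul_min, chamber = flow_chamber()) {
  stopifnot(inherits(chamber, "flow_chamber"))
  Q <- ul_min_to_m3_s(check_scalar(Q_ul_min, "Q_ul_min", lower = 0))
  vm <- v_max(Q, chamber$width_m, chamber$height_m)
  v <- velocity_at(chamber$particle_height_m, vm, chamber$height_m)
  chamber$faxen_factor *
    stokes_force(chamber$viscosity_Pa_s, chamber$particle_radius_m, v)
}

ul_min_to_m3_s <- function(Q_ul_min) Q_ul_min * 1e-9 / 60

#' Step-wise force schedules
#'
#' `force_schedule()` validates and assembles a schedule tibble;
#' `schedule_default()` returns the standard protocol: forward loading from
#' 5 pN in 5 pN increments every 10 s up to 65 pN (13 steps, 130 s),
#' followed by a reversed-flow phase from 5 to 35 pN used for the
#' symmetric-reversal quality check.
#'
#' @param forward_forces,reverse_forces Plateau forces, pN.
#' @param step_duration_s Duration of each plateau, s.
#' @return Tibble with columns `phase` (`"forward"`/`"reverse"`),
#'   `force_pN`, `duration_s`.
#' @export
#' @examples
#' schedule_default()
force_schedule <- function(forward_forces, reverse_forces = numeric(),
                           step_duration_s = 10) {
  if (any(forward_forces <= 0) || any(reverse_forces <= 0)) {
    stop_validation("Schedule forces must be positive.")
  }
  if (is.unsorted(forward_forces)) {
    stop_validation("Forward-phase forces must be non-decreasing.")
  }
  tibble(
    phase = c(rep("forward", length(forward_forces)),
              rep("reverse", length(reverse_forces))),
    force_pN = c(as.numeric(forward_forces), as.numeric(reverse_forces)),
    duration_s = as.numeric(step_duration_s)
  )
}

#' @rdname force_schedule
#' @export
schedule_default <- function() {
  force_schedule(seq(5, 65, by = 5), seq(5, 35, by = 5), step_duration_s = 10)
}
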