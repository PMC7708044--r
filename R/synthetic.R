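# Ground-truth-known synthetic flow-stretching trajectories. The tether is
# an extensible worm-like chain: entropic slack dominates below ~10 pN,
# backbone stretching with apparent stiffness K_true dominates above 15 pN,
# matching the two-regime shape the extraction pipeline assumes.

#' Tether model for synthetic trajectories
#'
#' @param L0 Contour length, nm.
#' @param K_true True apparent stretch stiffness, pN.
#' @param Lp Persistence length, nm (100 nm: roughly a two-fold increase
#'   over plain dsDNA, as reported for DX-tile beams).
#' @param kBT Thermal energy, pN nm.
#' @param noise_sigma Tracking noise per frame, nm.
#' @param frame_rate Camera frame rate, 1/s.
#' @param bad_tether If `TRUE` the particle is attached non-specifically:
#'   its reversed-flow displacement is scaled by `reverse_asymmetry`.
#' @param reverse_asymmetry Scaling of the reverse-phase displacement for a
#'   bad tether (must be < 1).
#' @return An object of class `tether_model`.
#' @export
tether_model <- function(L0 = 1224, K_true = 181, Lp = 100, kBT = 4.1,
                         noise_sigma = 20, frame_rate = 5,
                         bad_tether = FALSE, reverse_asymmetry = 1) {
  bad_tether <- check_flag(bad_tether, "bad_tether")
  out <- list(
    L0 = check_scalar(L0, "L0", lower = 0, strict = TRUE),
    K_true = check_scalar(K_true, "K_true", lower = 0, strict = TRUE),
    Lp = check_scalar(Lp, "Lp", lower = 0, strict = TRUE),
    kBT = check_scalar(kBT, "kBT", lower = 0, strict = TRUE),
    noise_sigma = check_scalar(noise_sigma, "noise_sigma", lower = 0),
    frame_rate = check_scalar(frame_rate, "frame_rate", lower = 0, strict = TRUE),
    bad_tether = bad_tether,
    reverse_asymmetry = check_scalar(reverse_asymmetry, "reverse_asymmetry",
                                     lower = 0, upper = 1)
  )
  if (bad_tether && out$reverse_asymmetry >= 1) {
    stop_validation("A bad tether needs reverse_asymmetry < 1.")
  }
  structure(out, class = "tether_model")
}

#' Mean extension of the extensible worm-like chain
#'
#' `x(F) = L0 * (1 - 0.5 * sqrt(kBT / (F * Lp)) + F / K_true)`: the
#' high-force interpolation of the WLC plus a linear enthalpic term whose
#' slope tends to `L0 / K_true`.
#'
#' @param model A [tether_model()].
#' @param force Applied force, pN (> 0; vectorized).
#' @return Extension, nm.
#' @export
#' @examples
#' mean_extension(tether_model(K_true = 181), 20)
mean_extension <- function(model, force) {
  stopifnot(inherits(model, "tether_model"))
  if (any(force <= 0)) stop_validation("`force` must be positive.")
  model$L0 * (1 - 0.5 * sqrt(model$kBT / (force * model$Lp)) +
                force / model$K_true)
}

#' Simulate a tethered-particle displacement trajectory
#'
#' Produces frames at the model's frame rate: a pre-flow baseline at zero
#' displacement, then one plateau per schedule step with mean displacement
#' equal to the tether's mean extension at that force (the coiled, unloaded
#' tether holds the bead at the anchor, so displacement from the initial
#' position equals extension). The reverse phase mirrors the forward
#' response; a bad tether's reverse displacement is scaled by its
#' `reverse_asymmetry`. White Gaussian tracking noise is added per frame and
#' the result is reported as an absolute displacement. Deterministic given
#' `seed` (the global RNG state is left untouched).
#'
#' @param model A [tether_model()].
#' @param schedule A schedule tibble from [force_schedule()].
#' @param seed Integer seed.
#' @param baseline_s Pre-flow baseline duration, s.
#' @return Trajectory tibble: `time_s`, `displacement_nm`, `force_pN`,
#'   `phase` (`"pre"`/`"forward"`/`"reverse"`).
#' @export
#' @examples
#' traj <- simulate_trajectory(tether_model(K_true = 181), seed = 1)
#' head(traj)
simulate_trajectory <- function(model, schedule = schedule_default(),
                                seed = 1L, baseline_s = 10) {
  stopifnot(inherits(model, "tether_model"))
  seed <- check_scalar(seed, "seed", integer = TRUE)
  baseline_s <- check_scalar(baseline_s, "baseline_s", lower = 0)

  fr <- model$frame_rate
  n_pre <- round(baseline_s * fr)
  seg_frames <- round(schedule$duration_s * fr)

  phase <- c(rep("pre", n_pre), rep(schedule$phase, seg_frames))
  force <- c(rep(0, n_pre), rep(schedule$force_pN, seg_frames))

  mean_disp <- numeric(length(force))
  active <- force > 0
  mean_disp[active] <- mean_extension(model, force[active])
  rev_scale <- if (model$bad_tether) model$reverse_asymmetry else 1
  mean_disp[phase == "reverse"] <- mean_disp[phase == "reverse"] * rev_scale

  noise <- withr::with_seed(seed, {
    if (model$noise_sigma > 0) stats::rnorm(length(force), 0, model$noise_sigma)
    else numeric(length(force))
  })

  tibble(
    time_s = (seq_along(force) - 1) / fr,
    displacement_nm = abs(mean_disp + noise),
    force_pN = force,
    phase = phase
  )
}

#' Generate a cohort of synthetic tethered particles
#'
#' A mixed cohort of well-tethered and (optionally) badly tethered
#' particles, with the ground truth recorded per particle so the quality
#' filter and the stiffness extraction can be scored. Particle seeds are
#' spawned from `seed` by a fixed offset.
#'
#' @param n Number of particles.
#' @param K_true True apparent stiffness handed to every tether, pN.
#' @param bad_fraction Fraction of badly tethered particles (placed first).
#' @param seed Integer cohort seed.
#' @param reverse_asymmetry Reverse-phase scaling of bad tethers.
#' @param schedule Force schedule.
#' @param ... Further arguments to [tether_model()].
#' @return Tibble with one row per particle: `particle_id`, `seed`,
#'   `K_true`, `bad_tether` (the ground-truth sidecar) and a `trajectory`
#'   list-column.
#' @export
generate_cohort <- function(n, K_true, bad_fraction = 0, seed = 1L,
                            reverse_asymmetry = 0.5,
                            schedule = schedule_default(), ...) {
  n <- check_scalar(n, "n", lower = 0, integer = TRUE)
  bad_fraction <- check_scalar(bad_fraction, "bad_fraction", lower = 0, upper = 1)
  seed <- check_scalar(seed, "seed", integer = TRUE)
  if (n == 0L) {
    return(tibble(particle_id = integer(), seed = integer(),
                  K_true = numeric(), bad_tether = logical(),
                  trajectory = list()))
  }
  n_bad <- round(n * bad_fraction)
  bad <- seq_len(n) <= n_bad
  purrr::map_dfr(seq_len(n), function(i) {
    model <- tether_model(K_true = K_true, bad_tether = bad[i],
                          reverse_asymmetry = if (bad[i]) reverse_asymmetry else 1,
                          ...)
    tibble(
      particle_id = i,
      seed = seed + i,
      K_true = K_true,
      bad_tether = bad[i],
      trajectory = list(simulate_trajectory(model, schedule, seed = seed + i))
    )
  })
}
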