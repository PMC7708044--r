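# Stiffness extraction from particle displacement time series: plateau
# averaging per force step, symmetric-reversal quality control, unstretched
# length at the 10 pN plateau, and the enthalpic-regime slope fit above
# 15 pN (stiffness = slope x length).

#' Per-plateau mean displacement
#'
#' Aggregates a trajectory into one row per (phase, force) plateau. The
#' first `settle_s` seconds of each force step are dropped (mechanical
#' settling); the pre-flow baseline keeps all frames.
#'
#' @param traj Trajectory tibble with `time_s`, `displacement_nm`,
#'   `force_pN`, `phase`.
#' @param settle_s Settling time discarded at the start of each step, s.
#' @return Tibble: `phase`, `force_pN`, `mean_displacement_nm`, `n_frames`.
#' @export
plateau_means <- function(traj, settle_s = 2) {
  settle_s <- check_scalar(settle_s, "settle_s", lower = 0)
  traj |>
    dplyr::group_by(.data$phase, .data$force_pN) |>
    dplyr::summarise(
      mean_displacement_nm = {
        keep <- .data$phase[1L] == "pre" |
          .data$time_s >= min(.data$time_s) + settle_s
        if (!any(keep)) keep <- rep(TRUE, length(keep))
        mean(.data$displacement_nm[keep])
      },
      n_frames = dplyr::n(),
      .groups = "drop"
    )
}

#' Symmetric-reversal quality control
#'
#' A well-tethered particle mirrors its forward-flow displacement when the
#' flow is reversed. The check compares plateau-mean displacement at every
#' force level present in both phases and scores the worst relative
#' mismatch; the particle passes if the score is at most `tolerance`.
#' Trajectories lacking one of the phases are reported as not evaluable,
#' distinct from a failure.
#'
#' @param traj Trajectory tibble.
#' @param tolerance Maximum tolerated relative mismatch.
#' @param settle_s Settling time passed to [plateau_means()].
#' @return One-row tibble: `status` (`"pass"`/`"fail"`/`"not_evaluable"`),
#'   `pass` (logical, `NA` when not evaluable), `score`, `n_matched`.
#' @export
qc_symmetric_reversal <- function(traj, tolerance = 0.2, settle_s = 2) {
  tolerance <- check_scalar(tolerance, "tolerance", lower = 0)
  pm <- plateau_means(traj, settle_s)
  fw <- pm[pm$phase == "forward", ]
  rv <- pm[pm$phase == "reverse", ]
  matched <- dplyr::inner_join(fw, rv, by = "force_pN", suffix = c("_fw", "_rv"))
  if (nrow(fw) == 0L || nrow(rv) == 0L || nrow(matched) == 0L) {
    return(tibble(status = "not_evaluable", pass = NA, score = NA_real_,
                  n_matched = 0L))
  }
  score <- max(abs(matched$mean_displacement_nm_rv - matched$mean_displacement_nm_fw) /
                 abs(matched$mean_displacement_nm_fw))
  tibble(status = if (score <= tolerance) "pass" else "fail",
         pass = score <= tolerance, score = score, n_matched = nrow(matched))
}

#' Unstretched length from the 10 pN plateau
#'
#' The tether is straightened but not yet stretched at 10 pN, so its
#' unstretched length is the particle displacement between the pre-flow
#' baseline and the 10 pN forward plateau.
#'
#' @param traj Trajectory tibble.
#' @param reference_force Straightening force, pN.
#' @param settle_s Settling time passed to [plateau_means()].
#' @return Unstretched length L0, nm (scalar).
#' @export
unstretched_length <- function(traj, reference_force = 10, settle_s = 2) {
  pm <- plateau_means(traj, settle_s)
  pre <- pm[pm$phase == "pre", ]
  ref <- pm[pm$phase == "forward" & pm$force_pN == reference_force, ]
  if (nrow(pre) == 0L) {
    stop_config("Trajectory has no pre-flow baseline frames.")
  }
  if (nrow(ref) == 0L) {
    stop_config("Schedule has no %g pN forward plateau; cannot anchor L0.",
                reference_force)
  }
  ref$mean_displacement_nm[1L] - pre$mean_displacement_nm[1L]
}

#' Enthalpic-regime stiffness fit
#'
#' Ordinary least squares of plateau-mean force on plateau-mean displacement
#' over forward plateaus with force strictly above `force_threshold`
#' (default 15 pN, past the entropic regime). The axial stiffness is the
#' fitted slope multiplied by the unstretched length.
#'
#' @param traj Trajectory tibble.
#' @param L0 Unstretched length, nm; computed with [unstretched_length()]
#'   when `NULL`.
#' @param force_threshold Only plateaus with force strictly above this value
#'   enter the fit, pN.
#' @param settle_s Settling time passed to [plateau_means()].
#' @return One-row tibble: `stiffness_pN`, `slope_pN_per_nm`, `L0_nm`,
#'   `n_plateaus`.
#' @export
fit_stiffness <- function(traj, L0 = NULL, force_threshold = 15, settle_s = 2) {
  if (is.null(L0)) L0 <- unstretched_length(traj, settle_s = settle_s)
  pm <- plateau_means(traj, settle_s)
  fit_pts <- pm[pm$phase == "forward" & pm$force_pN > force_threshold, ]
  if (nrow(fit_pts) < 3L) {
    stop_insufficient("Only %d plateau(s) above %g pN; at least 3 required.",
                      nrow(fit_pts), force_threshold)
  }
  slope <- unname(coef(lm(force_pN ~ mean_displacement_nm, data = fit_pts))[2L])
  tibble(stiffness_pN = slope * L0, slope_pN_per_nm = slope,
         L0_nm = L0, n_plateaus = nrow(fit_pts))
}

#' Full per-particle extraction
#'
#' Runs the symmetric-reversal check, the L0 anchor and the slope fit on one
#' trajectory and returns everything in a single row.
#'
#' @param traj Trajectory tibble.
#' @param tolerance QC tolerance.
#' @param force_threshold Slope-fit threshold, pN.
#' @param settle_s Settling time, s.
#' @return One-row tibble combining the QC columns and the fit columns.
#' @export
extract_stiffness <- function(traj, tolerance = 0.2, force_threshold = 15,
                              settle_s = 2) {
  qc <- qc_symmetric_reversal(traj, tolerance, settle_s)
  fit <- fit_stiffness(traj, force_threshold = force_threshold,
                       settle_s = settle_s)
  dplyr::bind_cols(
    dplyr::rename(qc, qc_status = "status", qc_pass = "pass",
                  qc_score = "score", qc_n_matched = "n_matched"),
    fit
  )
}

#' Extract stiffness for a whole cohort
#'
#' Maps [extract_stiffness()] over the `trajectory` list-column of a cohort
#' generated with [generate_cohort()] (or any tibble of the same shape) and
#' keeps the ground-truth columns alongside the results.
#'
#' @param cohort Cohort tibble with a `trajectory` list-column.
#' @param ... Passed to [extract_stiffness()].
#' @return Tibble with one row per particle.
#' @export
extract_cohort <- function(cohort, ...) {
  res <- purrr::map_dfr(cohort$trajectory, extract_stiffness, ...)
  dplyr::bind_cols(dplyr::select(cohort, -"trajectory"), res)
}
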