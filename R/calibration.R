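# Two-step calibration of the local degradation factors:
# alpha from a ligated construct, then beta from its nicked counterpart with
# alpha held fixed. The order matters and is enforced: the ligated beam
# carries no nicks, so its stiffness identifies alpha alone.

bisect_increasing <- function(f, target, bracket = c(1e-6, 1),
                              tol = 1e-8, max_iter = 200L, label = "parameter") {
  lo <- bracket[1L]
  hi <- bracket[2L]
  f_lo <- f(lo)
  f_hi <- f(hi)
  if (target < f_lo || target > f_hi) {
    stop_range(
      "Target %.6g pN outside attainable range [%.6g, %.6g] pN for %s in [%g, %g].",
      target, f_lo, f_hi, label, lo, hi)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
    if ((hi - lo) <= tol * mid) break
  }
  (lo + hi) / 2
}

#' Calibrate the Holliday-junction degradation factor alpha
#'
#' Finds `alpha` such that the simulated apparent stiffness of a ligated
#' (nick-free) design matches a measured target, by bisection on the
#' strictly increasing map `alpha -> K`.
#'
#' @param target_K Measured axial stiffness to match, pN.
#' @param design A ligated [nanobeam_design()] (junctions, no nicks).
#' @param material A [material_params()]; its `alpha` is ignored, `beta` is
#'   irrelevant for a nick-free design.
#' @param bracket Search interval for alpha.
#' @param tol Relative tolerance on alpha.
#' @param max_iter Maximum bisection iterations.
#' @return The calibrated alpha (scalar).
#' @export
#' @examples
#' calibrate_alpha(181, design_preset("C170L"))
calibrate_alpha <- function(target_K, design, material = material_params(),
                            bracket = c(1e-6, 1), tol = 1e-8, max_iter = 200L) {
  target_K <- check_scalar(target_K, "target_K", lower = 0, strict = TRUE)
  if (nrow(design$junctions) == 0L) {
    stop_validation("Design '%s' has no junctions; alpha is unidentifiable.", design$name)
  }
  if (nrow(design$nicks) > 0L) {
    stop_validation("Design '%s' has nicks; calibrate alpha on the ligated construct.",
                    design$name)
  }
  f <- function(a) {
    m <- material
    m$alpha <- a
    stiffness_scalar(design, m)
  }
  bisect_increasing(f, target_K, bracket, tol, max_iter, label = "alpha")
}

#' Calibrate the nick degradation factor beta with alpha fixed
#'
#' @param target_K Measured axial stiffness to match, pN.
#' @param design A nicked [nanobeam_design()].
#' @param material A [material_params()].
#' @param alpha Fixed Holliday-junction factor (from [calibrate_alpha()]).
#' @inheritParams calibrate_alpha
#' @return The calibrated beta (scalar).
#' @export
calibrate_beta <- function(target_K, design, material = material_params(),
                           alpha = material$alpha,
                           bracket = c(1e-6, 1), tol = 1e-8, max_iter = 200L) {
  target_K <- check_scalar(target_K, "target_K", lower = 0, strict = TRUE)
  if (nrow(design$nicks) == 0L) {
    stop_validation("Design '%s' has no nicks; beta is unidentifiable.", design$name)
  }
  alpha <- check_scalar(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  f <- function(b) {
    m <- material
    m$alpha <- alpha
    m$beta <- b
    stiffness_scalar(design, m)
  }
  bisect_increasing(f, target_K, bracket, tol, max_iter, label = "beta")
}

#' Confidence interval for a degradation factor
#'
#' Repeats the calibration at `mean_K - sd_K` and `mean_K + sd_K` (the
#' spread of the measured stiffness) and returns the resulting parameter
#' interval; the map target -> parameter is increasing, so the interval is
#' ordered automatically.
#'
#' @param mean_K,sd_K Mean and spread of the measured stiffness, pN.
#' @param design The design used for the calibration.
#' @param what `"alpha"` or `"beta"`.
#' @param material A [material_params()].
#' @param alpha Fixed alpha (required when `what = "beta"`).
#' @return Named numeric vector `c(lo, hi)`.
#' @export
calibration_interval <- function(mean_K, sd_K, design, what = c("alpha", "beta"),
                                 material = material_params(), alpha = NULL) {
  what <- match.arg(what)
  sd_K <- check_scalar(sd_K, "sd_K", lower = 0)
  fit <- function(target) {
    if (target <= 0) {
      stop_range("Interval endpoint %.4g pN is not a positive stiffness.", target)
    }
    if (what == "alpha") calibrate_alpha(target, design, material)
    else calibrate_beta(target, design, material, alpha = alpha)
  }
  c(lo = fit(mean_K - sd_K), hi = fit(mean_K + sd_K))
}

#' Two-step calibration against a ligated/nicked construct pair
#'
#' Mirrors the measurement-driven procedure: `alpha` is fitted so the model
#' reproduces the ligated construct's mean measured stiffness, then `beta`
#' is fitted on the nicked counterpart with `alpha` held constant.
#' Confidence intervals come from re-fitting at mean +/- SD of each target.
#'
#' @param ligated,nicked The ligated and nicked [nanobeam_design()]s.
#' @param ligated_target,nicked_target Length-2 numeric `c(mean, sd)` of the
#'   measured stiffness, pN (sd may be 0).
#' @param material A [material_params()] with the intact-duplex properties.
#' @param ci Compute confidence intervals (4 extra calibrations)?
#' @return An object of class `nanobeam_calibration` with elements `alpha`,
#'   `beta`, `alpha_ci`, `beta_ci`, `material` (with the fitted factors
#'   inserted), `targets` (tibble) and `residuals_pN`. Supports [tidy()],
#'   [glance()] and [predict()].
#' @export
#' @examples
#' \donttest{
#' cal <- calibrate_nanobeam(design_preset("C170L"), design_preset("C170N"),
#'                           c(181, 82), c(108, 47))
#' tidy(cal)
#' }
calibrate_nanobeam <- function(ligated, nicked,
                               ligated_target, nicked_target,
                               material = material_params(), ci = TRUE) {
  stopifnot(length(ligated_target) >= 1, length(nicked_target) >= 1)
  lig_mean <- ligated_target[1L]
  lig_sd <- if (length(ligated_target) > 1L) ligated_target[2L] else 0
  nic_mean <- nicked_target[1L]
  nic_sd <- if (length(nicked_target) > 1L) nicked_target[2L] else 0

  alpha <- calibrate_alpha(lig_mean, ligated, material)
  beta <- calibrate_beta(nic_mean, nicked, material, alpha = alpha)

  fitted <- material
  fitted$alpha <- alpha
  fitted$beta <- beta

  alpha_ci <- beta_ci <- c(lo = NA_real_, hi = NA_real_)
  if (ci) {
    alpha_ci <- calibration_interval(lig_mean, lig_sd, ligated, "alpha", material)
    beta_ci <- calibration_interval(nic_mean, nic_sd, nicked, "beta", material,
                                    alpha = alpha)
  }

  k_lig <- stiffness_scalar(ligated, fitted)
  k_nic <- stiffness_scalar(nicked, fitted)
  residuals <- c(k_lig - lig_mean, k_nic - nic_mean)
  if (any(abs(residuals) > 1e-6 * c(lig_mean, nic_mean))) {
    stop_numeric("Calibration residuals exceed tolerance: %.3g, %.3g pN.",
                 residuals[1L], residuals[2L])
  }

  structure(
    list(
      alpha = alpha, beta = beta,
      alpha_ci = alpha_ci, beta_ci = beta_ci,
      material = fitted,
      targets = tibble(
        construct = c(ligated$name, nicked$name),
        role = c("ligated", "nicked"),
        target_mean_pN = c(lig_mean, nic_mean),
        target_sd_pN = c(lig_sd, nic_sd),
        fitted_pN = c(k_lig, k_nic)
      ),
      residuals_pN = residuals
    ),
    class = "nanobeam_calibration"
  )
}

#' @export
print.nanobeam_calibration <- function(x, ...) {
  cat("<nanobeam_calibration>\n")
  cat(sprintf("  alpha = %.5f  [%.5f, %.5f]\n", x$alpha, x$alpha_ci[1L], x$alpha_ci[2L]))
  cat(sprintf("  beta  = %.5f  [%.5f, %.5f]\n", x$beta, x$beta_ci[1L], x$beta_ci[2L]))
  cat(sprintf("  calibrated on %s (%g pN) and %s (%g pN)\n",
              x$targets$construct[1L], x$targets$target_mean_pN[1L],
              x$targets$construct[2L], x$targets$target_mean_pN[2L]))
  invisible(x)
}

#' @export
tidy.nanobeam_calibration <- function(x, ...) {
  tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta),
    conf.low = c(x$alpha_ci[["lo"]], x$beta_ci[["lo"]]),
    conf.high = c(x$alpha_ci[["hi"]], x$beta_ci[["hi"]])
  )
}

#' @export
glance.nanobeam_calibration <- function(x, ...) {
  tibble(
    EA_pN = x$material$EA,
    n_hj = x$material$n_hj,
    n_nick = x$material$n_nick,
    n_targets = nrow(x$targets),
    max_abs_residual_pN = max(abs(x$residuals_pN))
  )
}

#' Predict construct stiffness from a calibration
#'
#' @param object A `nanobeam_calibration`.
#' @param designs Character vector of [design_preset()] names and/or a list
#'   of [nanobeam_design()] objects.
#' @param ... Unused.
#' @return Tibble with one row per design: construct, geometry counts and
#'   the model stiffness in pN.
#' @export
predict.nanobeam_calibration <- function(object,
                                         designs = c("C85L", "C85N", "6HB", "10HB"),
                                         ...) {
  if (!is.list(designs)) designs <- as.list(designs)
  purrr::map_dfr(designs, function(d) {
    if (is.character(d)) d <- design_preset(d)
    stopifnot(inherits(d, "nanobeam_design"))
    dplyr::bind_cols(
      design_summary(d)[, c("name", "n_helices", "length_nm", "n_junctions", "n_nicks")],
      tibble(model_stiffness_pN = stiffness_scalar(d, object$material))
    )
  })
}

#' @rdname predict.nanobeam_calibration
#' @param calibration A `nanobeam_calibration`.
#' @export
predict_constructs <- function(calibration,
                               designs = c("C85L", "C85N", "6HB", "10HB")) {
  predict(calibration, designs)
}
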