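# End-to-end reproductions: the model-stiffness table for all six
# constructs, the bundle-size sweep, and the synthetic measurement round
# trip that validates the extraction pipeline against known ground truth.

#' Measured calibration targets for the two-helix constructs
#'
#' Mean and standard deviation of the axial stiffness measured by
#' flow-stretching for the four two-helix nanobeams. These are measurement
#' inputs to the calibration, not model outputs.
#'
#' @return Tibble: `construct`, `mean_stiffness_pN`, `sd_stiffness_pN`.
#' @export
calibration_targets <- function() {
  tibble(
    construct = c("C85L", "C85N", "C170L", "C170N"),
    mean_stiffness_pN = c(382, 206, 181, 108),
    sd_stiffness_pN = c(227, 131, 82, 47)
  )
}

#' Calibrate on the 21 bp-spacing pair and predict all constructs
#'
#' Fits `alpha` to the mean measured stiffness of the ligated 21 bp-spacing
#' beam (C170L) and `beta` to its nicked counterpart (C170N) with `alpha`
#' fixed, then predicts the model stiffness of all six constructs
#' (C85L, C85N, C170L, C170N, 6HB, 10HB). The calibration rows reproduce
#' their targets by construction; the rest are genuine predictions.
#'
#' @param material A [material_params()] with the intact-duplex properties.
#' @param targets Tibble in the shape of [calibration_targets()].
#' @param ci Compute confidence intervals for alpha and beta?
#' @return Tibble with one row per construct (geometry, measured mean/SD
#'   where available, `model_stiffness_pN`); the fitted
#'   `nanobeam_calibration` is attached as attribute `"calibration"`.
#' @export
#' @examples
#' \donttest{
#' tab <- run_table1()
#' tab
#' tidy(attr(tab, "calibration"))
#' }
run_table1 <- function(material = material_params(),
                       targets = calibration_targets(), ci = TRUE) {
  t_lig <- targets[targets$construct == "C170L", ]
  t_nic <- targets[targets$construct == "C170N", ]
  if (nrow(t_lig) != 1L || nrow(t_nic) != 1L) {
    stop_validation("`targets` must contain one C170L and one C170N row.")
  }
  cal <- calibrate_nanobeam(
    design_preset("C170L"), design_preset("C170N"),
    c(t_lig$mean_stiffness_pN, t_lig$sd_stiffness_pN),
    c(t_nic$mean_stiffness_pN, t_nic$sd_stiffness_pN),
    material = material, ci = ci
  )
  pred <- predict(cal, c("C85L", "C85N", "C170L", "C170N", "6HB", "10HB"))
  out <- pred |>
    dplyr::left_join(targets, by = c(name = "construct")) |>
    dplyr::rename(construct = "name",
                  measured_mean_pN = "mean_stiffness_pN",
                  measured_sd_pN = "sd_stiffness_pN")
  attr(out, "calibration") <- cal
  out
}

#' Bundle-size sweep with calibrated parameters
#'
#' Runs [bundle_sweep()] with the degradation factors taken from a
#' calibration (or an explicit [material_params()]).
#'
#' @param calibration A `nanobeam_calibration` from [calibrate_nanobeam()]
#'   or [run_table1()]; alternatively a [material_params()].
#' @inheritParams bundle_sweep
#' @return The [bundle_sweep()] tibble.
#' @export
run_bundle_sweep <- function(calibration, n_helices = c(2, 6, 9, 10, 16),
                             packing = c("honeycomb", "square"),
                             length_nm = 1224,
                             junctions_per_21bp = 1, nicks_per_21bp = 0.5) {
  material <- if (inherits(calibration, "nanobeam_calibration")) {
    calibration$material
  } else {
    stopifnot(inherits(calibration, "material_params"))
    calibration
  }
  bundle_sweep(n_helices, packing, material, length_nm,
               junctions_per_21bp, nicks_per_21bp)
}

#' Synthetic measurement round trip
#'
#' Generates cohorts of well-tethered synthetic particles at the given true
#' stiffness values, runs the QC filter and the extraction pipeline, and
#' summarizes how well the pipeline recovers the ground truth.
#'
#' @param K_true Named or unnamed vector of true stiffness values, pN.
#' @param n_per_construct Particles per cohort.
#' @param seed Integer seed; per-cohort seeds are spawned deterministically.
#' @param bad_fraction Fraction of badly tethered particles per cohort.
#' @param ... Passed to [generate_cohort()].
#' @return Tibble with one row per stiffness value: `K_true`, `n`,
#'   `qc_pass_rate`, `median_stiffness_pN`, `median_rel_error`.
#' @export
run_synthetic_roundtrip <- function(K_true = c(C85L = 328, C85N = 205,
                                               C170L = 181, C170N = 108),
                                    n_per_construct = 20, seed = 1L,
                                    bad_fraction = 0, ...) {
  seed <- check_scalar(seed, "seed", integer = TRUE)
  labels <- names(K_true) %||% as.character(K_true)
  purrr::imap_dfr(as.numeric(K_true), function(k, i) {
    idx <- if (is.character(i)) match(i, labels) else i
    cohort <- generate_cohort(n_per_construct, K_true = k,
                              bad_fraction = bad_fraction,
                              seed = seed + 10000L * idx, ...)
    res <- extract_cohort(cohort)
    good <- res[!res$bad_tether, ]
    tibble(
      construct = labels[idx],
      K_true = k,
      n = nrow(res),
      qc_pass_rate = mean(res$qc_pass, na.rm = TRUE),
      median_stiffness_pN = median(good$stiffness_pN),
      median_rel_error = median(abs(good$stiffness_pN - k) / k)
    )
  })
}
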