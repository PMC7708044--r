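# ggplot2 views of the main result types.

#' Plot a force-extension curve
#'
#' @param fe Tibble from [force_extension()] (columns `force_pN`,
#'   `extension_nm`), optionally row-bound across constructs with a
#'   `construct` column.
#' @return A ggplot object.
#' @export
plot_force_extension <- function(fe) {
  p <- ggplot2::ggplot(fe, ggplot2::aes(x = .data$extension_nm, y = .data$force_pN))
  if ("construct" %in% names(fe)) {
    p <- p + ggplot2::aes(colour = .data$construct)
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Extension (nm)", y = "Force (pN)")
}

#' Plot a particle displacement trajectory
#'
#' @param traj Trajectory tibble from [simulate_trajectory()].
#' @return A ggplot object with the displacement trace coloured by phase.
#' @export
plot_trajectory <- function(traj) {
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$time_s, y = .data$displacement_nm,
                                     colour = .data$phase)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Displacement (nm)", colour = "Phase")
}

#' Plot a bundle-size stiffness sweep
#'
#' @param sweep Tibble from [bundle_sweep()] / [run_bundle_sweep()].
#' @return A ggplot object of normalized stiffness versus helix count, one
#'   line per packing, with the intact-duplex level marked.
#' @export
plot_bundle_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$n_helices,
                                      y = .data$normalized_stiffness,
                                      colour = .data$packing)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Number of helices", y = "Stiffness / EA",
                  colour = "Packing")
}
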