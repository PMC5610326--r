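# Optional plotting helpers (ggplot2 in Suggests).

#' Plot the energy landscape or line tension of a trajectory
#'
#' @param traj `pore_trajectory`.
#' @param what `"energy"` (W vs r) or `"line_tension"` (gamma vs r with the
#'   large-radius asymptote as a dashed line).
#' @return a ggplot object.
#' @export
plot_trajectory <- function(traj, what = c("energy", "line_tension")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_trajectory requires the 'ggplot2' package")
  what <- match.arg(what)
  pts <- traj$points
  if (what == "energy") {
    p <- ggplot2::ggplot(pts, ggplot2::aes(x = r, y = W, colour = regime)) +
      ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey60") +
      ggplot2::geom_point(size = 1.2) +
      ggplot2::labs(x = "pore radius r (nm)", y = "W (kBT)",
                    title = paste0("Pore energy, ", traj$lipid$name))
  } else {
    p <- ggplot2::ggplot(pts, ggplot2::aes(x = r, y = gamma_pN)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = traj$features$gamma0_pN,
                          linetype = "dashed", colour = "grey40") +
      ggplot2::labs(x = "pore radius r (nm)", y = "line tension (pN)",
                    title = paste0("Line tension, ", traj$lipid$name))
  }
  p + ggplot2::theme_minimal()
}
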