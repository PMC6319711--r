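#' @importFrom ggplot2 ggplot aes geom_line geom_segment geom_tile geom_point
#'   facet_wrap labs scale_colour_manual arrow unit theme_minimal
#' @importFrom rlang .data
NULL

.opinion_colours <- c(X = "#1b7837", Y = "#762a83", Z = "#878787")

traj_long <- function(tr) {
  tidyr::pivot_longer(as_tibble(tr)[, c("t", "x", "y", "z")],
                      c("x", "y", "z"),
                      names_to = "opinion", values_to = "share")
}

#' Plot methods for simulation results
#'
#' `autoplot()` methods render each result type with ggplot2: trajectories
#' as per-opinion share curves, phase portraits as displacement quivers
#' over the simplex, sweeps and agreement studies as heat maps, and
#' equilibrium analyses as classified points on the simplex.
#'
#' @param object A result object from this package.
#' @param ... Unused.
#' @return A ggplot object.
#' @name crossinhib-plots
NULL

#' @rdname crossinhib-plots
#' @export
autoplot.ci_trajectory <- function(object, ...) {
  ggplot(traj_long(object), aes(.data$t, .data$share,
                                colour = toupper(.data$opinion))) +
    geom_line() +
    scale_colour_manual(values = .opinion_colours, name = "opinion") +
    labs(x = "step", y = "population share",
         title = "Mean-field opinion dynamics") +
    theme_minimal()
}

#' @rdname crossinhib-plots
#' @export
autoplot.ci_abm_trajectory <- function(object, ...) {
  ggplot(traj_long(object), aes(.data$t, .data$share,
                                colour = toupper(.data$opinion))) +
    geom_line() +
    scale_colour_manual(values = .opinion_colours, name = "opinion") +
    labs(x = "step", y = "population share",
         title = "Agent-based opinion dynamics") +
    theme_minimal()
}

#' @rdname crossinhib-plots
#' @export
autoplot.ci_phase_portrait <- function(object, ...) {
  ggplot(object, aes(.data$x, .data$y)) +
    geom_segment(aes(xend = .data$x + .data$dx, yend = .data$y + .data$dy),
                 arrow = arrow(length = unit(1.5, "mm")), alpha = 0.7) +
    labs(x = "x (share in X)", y = "y (share in Y)",
         title = "One-step displacement field") +
    theme_minimal()
}

#' @rdname crossinhib-plots
#' @export
autoplot.ci_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trajectories, c("x", "y", "z"),
                              names_to = "opinion", values_to = "share")
  long$source <- factor(long$source, c("mf", "abm"),
                        c("mean field", "agent-based"))
  ggplot(long, aes(.data$t, .data$share,
                   colour = toupper(.data$opinion))) +
    geom_line() +
    facet_wrap(~source) +
    scale_colour_manual(values = .opinion_colours, name = "opinion") +
    labs(x = "step", y = "population share",
         title = "Mean field vs agent-based process") +
    theme_minimal()
}

#' @rdname crossinhib-plots
#' @export
autoplot.ci_sweep <- function(object, ...) {
  ggplot(object, aes(.data$ratio_xz, .data$ratio_yz,
                     fill = .data$final_x_fraction)) +
    geom_tile() +
    labs(x = "a12 / a11", y = "a21 / a22", fill = "final X share",
         title = "Final X share over reward ratios") +
    theme_minimal()
}

#' @rdname crossinhib-plots
#' @export
autoplot.ci_agreement <- function(object, ...) {
  obj <- dplyr::mutate(as_tibble(object),
    ratio_mid = sqrt(.data$ratio_bin_low * .data$ratio_bin_high)
  )
  ggplot(obj, aes(factor(.data$K), factor(signif(.data$ratio_mid, 2)),
                  fill = .data$agreement_fraction)) +
    geom_tile() +
    labs(x = "degree K", y = "reward ratio a11 a21 / (a22 a12)",
         fill = "agreement",
         title = "Process agreement on small-world networks") +
    theme_minimal()
}

#' @rdname crossinhib-plots
#' @export
autoplot.ci_equilibria <- function(object, ...) {
  tbl <- object$table
  ggplot(tbl, aes(.data$x, .data$y,
                  shape = .data$label, colour = .data$classification)) +
    geom_segment(
      data = tibble(x = c(0, 1, 0), y = c(0, 0, 1),
                    xend = c(1, 0, 0), yend = c(0, 1, 0)),
      aes(x = .data$x, y = .data$y,
          xend = .data$xend, yend = .data$yend),
      inherit.aes = FALSE, colour = "grey70"
    ) +
    geom_point(size = 3) +
    labs(x = "x (share in X)", y = "y (share in Y)",
         title = "Equilibria of the mean-field dynamics") +
    theme_minimal()
}
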