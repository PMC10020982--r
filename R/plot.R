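#' Plot a niche trajectory
#'
#' Cell counts (and progenitor flux) over time, one facet per compartment,
#' coloured by clone.
#'
#' @param object A `niche_trajectory`.
#' @param compartments Compartments to show; default all present.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot niche_trajectory
#' @export
autoplot.niche_trajectory <- function(object, compartments = NULL, ...) {
  long <- tidy_trajectory(object)
  if (!is.null(compartments)) {
    long <- dplyr::filter(long, .data$compartment %in% compartments)
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     colour = .data$clone)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~compartment, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "cells (or cells/day for flux)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot clonal abundance in niche versus progenitor output
#'
#' @param traj A multi-clone `niche_trajectory`.
#' @return A ggplot comparing each clone's niche share with its share of
#'   progenitor production over time.
#' @export
plot_abundance <- function(traj) {
  ab <- abundance_metrics(traj)
  long <- tidyr::pivot_longer(ab, c("niche_fraction", "progenitor_fraction"),
                              names_to = "measure", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$fraction,
                                     colour = .data$clone,
                                     linetype = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "fraction",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}
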