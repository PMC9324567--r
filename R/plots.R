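# ggplot2 displays for census trajectories, growth fits and survival
# sweeps.

#' Plot a growth census
#'
#' Mean cell count over time across runs, with one thin line per run.
#'
#' @param census A census tibble with columns `run`, `iteration`,
#'   `cells`.
#' @return A ggplot object.
#' @export
plot_growth <- function(census) {
  m <- mean_census(census)
  ggplot2::ggplot(census, ggplot2::aes(x = .data$iteration, y = .data$cells)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$run), alpha = 0.2) +
    ggplot2::geom_line(data = m, linewidth = 1, colour = "firebrick") +
    ggplot2::labs(x = "iteration (min)", y = "cells",
                  title = "Simulated population growth") +
    ggplot2::theme_minimal()
}

#' @rdname plot_growth
#' @param object A `growth_fit`.
#' @param ... Unused.
#' @export
autoplot.growth_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- predict(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cells), size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "iteration (min)", y = "cells",
                  title = paste(object$model, "fit")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' Plot a survival sweep
#'
#' Survival probability against the number of simultaneous random
#' injuries.
#'
#' @param sweep A tibble from [survival_sweep()].
#' @return A ggplot object.
#' @export
plot_survival <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$n_injuries,
                                      y = .data$p_survive)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "simultaneous random injuries",
                  y = "probability of survival",
                  title = "Self-healing under simultaneous injuries") +
    ggplot2::theme_minimal()
}
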