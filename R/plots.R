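#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   scale_x_log10 facet_wrap theme_bw
#' @export
ggplot2::autoplot

#' Plot methods for strandex objects
#'
#' `autoplot()` draws the standard diagnostic figure for each result type:
#' species concentrations over time for trajectories, data with the fitted
#' curve and residuals for exchange fits, titration points with the fitted
#' Hill curve on a log concentration axis, and data-plus-fit for
#' association and dissociation traces.
#'
#' @param object A strandex object.
#' @param ... Unused.
#' @return A ggplot.
#' @name strandex-plots
NULL

#' @rdname strandex-plots
#' @method autoplot exchange_trajectory
#' @export
autoplot.exchange_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time_s",
                              names_to = "species", values_to = "nM")
  ggplot(long, aes(x = .data$time_s, y = .data$nM, colour = .data$species)) +
    geom_line() +
    labs(x = "time (s)", y = "concentration (nM)",
         title = sprintf("%s scheme", attr(object, "scheme"))) +
    theme_bw()
}

#' @rdname strandex-plots
#' @method autoplot exchange_fit
#' @export
autoplot.exchange_fit <- function(object, ...) {
  d <- tibble(time_s = rep(object$data$time_s, 2),
              value = c(object$data$value, object$fitted),
              what = rep(c("data", "fit"), each = nrow(object$data)))
  ggplot(d, aes(x = .data$time_s, y = .data$value, colour = .data$what)) +
    geom_line() +
    labs(x = "time (s)", y = sprintf("%s signal (%%)", object$assay)) +
    theme_bw()
}

#' @rdname strandex-plots
#' @method autoplot hill_fit
#' @export
autoplot.hill_fit <- function(object, ...) {
  grid <- exp(seq(log(min(object$data$concentration_uM)),
                  log(max(object$data$concentration_uM)), length.out = 200))
  curve <- tibble(concentration_uM = grid,
                  anisotropy = hill_curve(grid, object$baseline,
                                          object$amplitude, object$K_D, object$n))
  ggplot(object$data, aes(x = .data$concentration_uM, y = .data$anisotropy)) +
    geom_point() +
    geom_line(data = curve) +
    scale_x_log10() +
    labs(x = "[recombinase] (uM)", y = "anisotropy",
         title = sprintf("K_D = %.3g uM, n = %.2f", object$K_D, object$n)) +
    theme_bw()
}

#' @rdname strandex-plots
#' @method autoplot assoc_fit
#' @export
autoplot.assoc_fit <- function(object, ...) {
  p <- ggplot(object$data, aes(x = .data$time_s, y = .data$anisotropy)) +
    geom_point(size = 0.4, alpha = 0.5) +
    labs(x = "time (s)", y = "anisotropy") +
    theme_bw()
  if (is.finite(object$T_half)) {
    grid <- seq(min(object$data$time_s), max(object$data$time_s), length.out = 300)
    curve <- tibble(time_s = grid,
                    anisotropy = association_curve(grid, object$baseline,
                                                   object$amplitude,
                                                   object$T_half, object$n))
    p <- p + geom_line(data = curve, colour = "red")
  }
  p
}

#' @rdname strandex-plots
#' @method autoplot dissoc_fit
#' @export
autoplot.dissoc_fit <- function(object, ...) {
  grid <- seq(min(object$data$time_s), max(object$data$time_s), length.out = 300)
  curve <- tibble(time_s = grid,
                  anisotropy = object$amplitude * exp(-object$k_off * grid) +
                    object$baseline)
  ggplot(object$data, aes(x = .data$time_s, y = .data$anisotropy)) +
    geom_point(size = 0.4, alpha = 0.5) +
    geom_line(data = curve, colour = "red") +
    labs(x = "time (s)", y = "anisotropy",
         title = sprintf("k_off = %.3g /s", object$k_off)) +
    theme_bw()
}
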