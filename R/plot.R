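#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   facet_wrap theme_minimal
NULL

#' Plot a simulated trace
#'
#' Cytosolic calcium against time; further state variables can be added
#' with `vars`.
#'
#' @param object a `"ca_trace"` from [simulate_model()].
#' @param vars state variables to show (default just `c`).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ca_trace <- function(object, vars = "c", ...) {
  df <- tidyr::pivot_longer(object[, c("t", vars)], -"t",
                            names_to = "variable")
  ggplot(df, aes(x = .data$t, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~variable, scales = "free_y", ncol = 1) +
    labs(x = "time (s)", y = NULL,
         title = "whole-cell calcium model trace") +
    theme_minimal()
}

#' Plot an equilibrium branch
#'
#' Equilibrium cytosolic calcium against the scanned parameter, solid
#' where stable and dashed where unstable, with detected bifurcation
#' points marked.
#'
#' @param object a `"ca_branch"` from [scan_branch()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ca_branch <- function(object, ...) {
  br <- object$branch
  pts <- object$points
  g <- ggplot(br, aes(x = .data[[object$parameter]], y = .data$c)) +
    geom_line(aes(linetype = .data$stable), linewidth = 0.4) +
    ggplot2::scale_linetype_manual(
      values = c(`TRUE` = "solid", `FALSE` = "dashed"),
      labels = c(`TRUE` = "stable", `FALSE` = "unstable"),
      name = NULL) +
    labs(x = object$parameter, y = "equilibrium c (µM)",
         title = "equilibrium branch") +
    theme_minimal()
  hp <- pts[pts$kind %in% c("hopf", "fold"), ]
  if (nrow(hp)) {
    hp$c <- vapply(hp$value, function(v) {
      i <- which.min(abs(br[[object$parameter]] - v)); br$c[i]
    }, numeric(1))
    g <- g + geom_point(data = hp,
                        aes(x = .data$value, y = .data$c,
                            shape = .data$kind), size = 2)
  }
  g
}

#' Plot a periodic orbit
#'
#' One period of the orbit in the (c, ce) plane and as a time course.
#'
#' @param object a `"ca_orbit"` from [find_orbit()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ca_orbit <- function(object, ...) {
  ggplot(object$samples, aes(x = .data$t, y = .data$c)) +
    geom_line() +
    labs(x = "time (s)", y = "c (µM)",
         title = sprintf("periodic orbit, period %.3f s",
                         object$period)) +
    theme_minimal()
}

#' Plot a classified parameter grid
#'
#' Signal-class labels over one or two scanned parameters.
#'
#' @param grid_result tibble from [classify_parameter_grid()].
#' @param x,y parameter column names (`y` optional).
#' @return A ggplot object.
#' @export
plot_label_map <- function(grid_result, x, y = NULL) {
  if (is.null(y)) {
    ggplot(grid_result, aes(x = .data[[x]], y = .data$label,
                            colour = .data$label)) +
      geom_point(size = 2, show.legend = FALSE) +
      labs(x = x, y = NULL, title = "signal classes along the scan") +
      theme_minimal()
  } else {
    ggplot(grid_result, aes(x = .data[[x]], y = .data[[y]],
                            fill = .data$label)) +
      ggplot2::geom_tile() +
      labs(title = "signal-class map") +
      theme_minimal()
  }
}
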