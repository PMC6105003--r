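#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy and glance methods
#'
#' broom-style summaries for the package's result objects: `tidy()`
#' returns one row per meaningful component (bifurcation point, Floquet
#' multiplier, detected peak), `glance()` a one-row overview.
#'
#' @param x a `ca_branch`, `ca_orbit`, `ca_pd_scan` or
#'   `ca_classification` object.
#' @param ... unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.ca_branch <- function(x, ...) x$points

#' @rdname tidiers
#' @export
glance.ca_branch <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter,
    n_equilibria = nrow(x$branch),
    n_hopf = sum(x$points$kind == "hopf"),
    n_fold = sum(x$points$kind == "fold"),
    diverges = any(x$points$kind == "divergence"),
    divergence_at = if (any(x$points$kind == "divergence"))
      x$points$value[x$points$kind == "divergence"][1] else NA_real_)
}

#' @rdname tidiers
#' @export
tidy.ca_orbit <- function(x, ...) {
  tibble::tibble(multiplier = x$multipliers,
                 modulus = abs(x$multipliers),
                 trivial = seq_along(x$multipliers) ==
                   which.min(abs(x$multipliers - 1)))
}

#' @rdname tidiers
#' @export
glance.ca_orbit <- function(x, ...) {
  nontrivial <- x$multipliers[-which.min(abs(x$multipliers - 1))]
  tibble::tibble(period = x$period, amplitude = x$amplitude,
                 residual = x$residual, converged = x$converged,
                 max_nontrivial_modulus =
                   if (length(nontrivial)) max(abs(nontrivial)) else NA_real_)
}

#' @rdname tidiers
#' @export
tidy.ca_pd_scan <- function(x, ...) x$points

#' @rdname tidiers
#' @export
glance.ca_pd_scan <- function(x, ...) {
  tibble::tibble(parameter = x$parameter,
                 n_orbits = nrow(x$branch),
                 n_period_doubling = nrow(x$points),
                 first_pd = if (nrow(x$points)) min(x$points$value)
                            else NA_real_)
}

#' @rdname tidiers
#' @export
tidy.ca_classification <- function(x, ...) x$peaks

#' @rdname tidiers
#' @export
glance.ca_classification <- function(x, ...) {
  tibble::tibble(label = x$label, n_peaks = x$n_peaks,
                 n_amplitude_classes = x$n_amplitude_classes,
                 periodicity_score = x$periodicity_score,
                 period = x$period, amplitude = x$amplitude)
}
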