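#' Calcium flux terms
#'
#' Pure flux computations for every channel, pump and leak of the calcium
#' compartment. Each function maps concentrations (and, where relevant, the
#' amyloid-beta level `a`) to a flux in µM/s, so the same code serves the
#' ODE right-hand side, finite-difference Jacobians, and unit tests.
#'
#' * `j_in()` — membrane leak `a1 + a2*p + kbeta*a^m`; the `a^m` term models
#'   calcium entry through amyloid-beta plasma-membrane pores.
#' * `j_pm()` — plasma-membrane pump, Hill coefficient 2, saturating at
#'   `Vpm`.
#' * `j_serca()` — bidirectional SERCA pump
#'   `(c - K1*ce) / (K2 + K3*c + K4*ce + K5*c*ce)`; it reverses sign exactly
#'   at `c = K1*ce`.
#' * `ryr_rate()` — the CICR rate `k1 + k2*c^n / ((kd + kalpha*a)^n + c^n)`;
#'   amyloid-beta increases the RyR sensitivity through `kalpha*a`.
#' * `j_ryr()` — gradient-driven RyR flux `ryr_rate * (ce - c)`.
#' * `j_ipr()` — IP3-receptor flux `(kf*P0 + Jer) * (ce - c)` for an open
#'   probability `P0` in `[0, 1]`.
#'
#' All functions are vectorised over their concentration arguments.
#'
#' @param c cytosolic calcium (µM, nonnegative).
#' @param ce ER calcium (µM, nonnegative).
#' @param p IP3 concentration (µM, nonnegative).
#' @param a amyloid-beta level (nonnegative).
#' @param P0 IP3-receptor open probability in `[0, 1]`.
#' @param params parameter list from [model_params()].
#' @param check validate argument ranges (disable only in solver-internal
#'   hot loops, where transiently negative concentrations are clamped to 0).
#' @return Flux in µM/s (`ryr_rate()`: a rate in 1/s).
#' @examples
#' pr <- model_params()
#' j_in(p = 0, a = 0, params = pr)        # basal leak a1
#' j_pm(c = 0.425, params = pr)           # half of Vpm
#' j_serca(c = 0.05, ce = 10, params = pr)
#' @name fluxes
NULL

check_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args))
    if (any(args[[nm]] < 0))
      stop("`", nm, "` must be nonnegative", call. = FALSE)
  invisible(NULL)
}

#' @rdname fluxes
#' @export
j_in <- function(p, a, params, check = TRUE) {
  if (check) check_nonneg(p = p, a = a)
  params$a1 + params$a2 * p + params$kbeta * a^params$m
}

#' @rdname fluxes
#' @export
j_pm <- function(c, params, check = TRUE) {
  if (check) check_nonneg(c = c) else c <- pmax(c, 0)
  c2 <- c * c
  params$Vpm * c2 / (params$Kpm^2 + c2)
}

#' @rdname fluxes
#' @export
j_serca <- function(c, ce, params, check = TRUE) {
  if (check) check_nonneg(c = c, ce = ce) else {
    c <- pmax(c, 0); ce <- pmax(ce, 0)
  }
  den <- params$K2 + params$K3 * c + params$K4 * ce + params$K5 * c * ce
  if (any(den <= 0))
    stop("SERCA denominator must be positive", call. = FALSE)
  (c - params$K1 * ce) / den
}

#' @rdname fluxes
#' @export
ryr_rate <- function(c, a, params, check = TRUE) {
  if (check) check_nonneg(c = c, a = a) else c <- pmax(c, 0)
  n <- params$nryr
  cn <- c^n
  params$k1 + params$k2 * cn / ((params$kd + params$kalpha * a)^n + cn)
}

#' @rdname fluxes
#' @export
j_ryr <- function(c, ce, a, params, check = TRUE) {
  ryr_rate(c, a, params, check = check) * (ce - c)
}

#' @rdname fluxes
#' @export
j_ipr <- function(c, ce, P0, params, check = TRUE) {
  if (check) {
    if (any(P0 < 0 | P0 > 1))
      stop("`P0` must lie in [0, 1]", call. = FALSE)
  }
  (params$kf * P0 + params$Jer) * (ce - c)
}
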