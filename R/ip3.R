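#' Dynamic IP3 production and degradation
#'
#' Hybrid PLC model: calcium stimulates IP3 production through a Hill term
#' and modulates degradation through the 3-kinase pathway. The balance
#' equation is
#'
#' `tau_p * dp/dt = V_PLC(a) * c^2 / (D(a) + c^2)
#'                  - (eta * c^2 / (K3K^2 + c^2) + (1 - eta)) * p`
#'
#' with `tau_p = 1/(k3K + k5P)`, `eta = k3K/(k3K + k5P)` (both recomputed
#' from the rates, never set independently), amyloid-beta entering linearly
#' through `V_PLC(a) = vPLC + muPLC*a` and `K_PLC(a) = kPLC + kappaPLC*a`.
#' The production denominator is `D(a) = K_PLC(a)^2` when
#' `params$squared_sensitivity` is `TRUE` (the canonical configuration) and
#' `K_PLC(a)` otherwise; at the default `kPLC = 1` and `a = 0` the two
#' forms coincide.
#'
#' @param p IP3 concentration (µM).
#' @param c cytosolic calcium (µM).
#' @param a amyloid-beta level.
#' @param params parameter list from [model_params()].
#' @param check validate argument ranges.
#' @return `dp/dt` in µM/s.
#' @examples
#' pr <- model_params()
#' ip3_derivative(p = 0.01, c = 0.05, a = 0, params = pr)
#' ip3_tau_eta(pr)  # tau_p = 4/3 s, eta = 2/3 at defaults
#' @export
ip3_derivative <- function(p, c, a, params, check = TRUE) {
  if (check) check_nonneg(p = p, c = c, a = a) else {
    p <- pmax(p, 0); c <- pmax(c, 0)
  }
  te <- ip3_tau_eta(params)
  Vplc <- params$vPLC + params$muPLC * a
  Kplc <- params$kPLC + params$kappaPLC * a
  D <- if (isTRUE(params$squared_sensitivity)) Kplc^2 else Kplc
  c2 <- c * c
  production <- Vplc * c2 / (D + c2)
  degradation <- (te$eta * c2 / (params$K3K^2 + c2) + (1 - te$eta)) * p
  (production - degradation) / te$tau_p
}

#' @rdname ip3_derivative
#' @export
ip3_tau_eta <- function(params) {
  s <- params$k3K + params$k5P
  list(tau_p = 1 / s, eta = params$k3K / s)
}

## fixed point of p at frozen calcium: production/degradation balance
ip3_fixed_point <- function(c, a, params) {
  te <- ip3_tau_eta(params)
  Vplc <- params$vPLC + params$muPLC * a
  Kplc <- params$kPLC + params$kappaPLC * a
  D <- if (isTRUE(params$squared_sensitivity)) Kplc^2 else Kplc
  c2 <- c * c
  (Vplc * c2 / (D + c2)) /
    (te$eta * c2 / (params$K3K^2 + c2) + (1 - te$eta))
}
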