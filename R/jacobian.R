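#' Analytic Jacobian of the model right-hand side
#'
#' Closed-form Jacobian for the membrane-free variants (`constant_ip3`,
#' `dynamic_ip3`), used by the variational (monodromy) integration where
#' a finite-difference Jacobian inside the inner loop would dominate the
#' run time. The membrane-coupled variant falls back to central finite
#' differences. [eigenvalues_at()] deliberately keeps the
#' finite-difference route so the two derivations cross-check each other.
#'
#' @inheritParams cell_rhs
#' @return Jacobian matrix in the [state_layout()] ordering.
#' @export
cell_jacobian <- function(state, t = 0, params = model_params(),
                          config = model_config()) {
  if (config$variant == "with_membrane")
    return(jacobian_fd(function(y) cell_rhs(t, y, params, config),
                       state[state_layout(config)]))

  vars <- state_layout(config)
  dynp <- config$variant == "dynamic_ip3"
  cc <- max(state[["c"]], 0); ce <- max(state[["ce"]], 0)
  O <- state[["O"]]; A <- state[["A"]]
  a <- config$a
  p <- if (dynp) max(state[["p"]], 0) else config$p
  J <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))

  ## RyR rate and derivative
  n <- params$nryr
  kdn <- (params$kd + params$kalpha * a)^n
  cn <- cc^n
  k3 <- params$k1 + params$k2 * cn / (kdn + cn)
  dk3 <- params$k2 * n * cc^(n - 1) * kdn / (kdn + cn)^2

  ## open probability and derivative
  u <- params$alpha1 * O + params$alpha2 * A
  P0 <- u^4
  dP0 <- 4 * u^3

  rate <- params$kf * P0 + params$Jer + k3
  w <- ce - cc

  ## SERCA partials
  den <- params$K2 + params$K3 * cc + params$K4 * ce + params$K5 * cc * ce
  num <- cc - params$K1 * ce
  dJs_dc <- (den - num * (params$K3 + params$K5 * ce)) / den^2
  dJs_dce <- (-params$K1 * den - num * (params$K4 + params$K5 * cc)) / den^2

  ## pump derivative
  dJpm <- params$Vpm * 2 * cc * params$Kpm^2 / (params$Kpm^2 + cc^2)^2

  ## IPR rate functions and their c-derivatives
  r <- ipr_transition_rates(cc, params)
  L1 <- params$ipr_L1; L3 <- params$ipr_L3; L5 <- params$ipr_L5
  q1 <- params$ipr_k1 * L1 + params$ipr_l2
  b1 <- 1 + L1 / L3
  b2 <- 1 + L3 / L1
  dphi1  <- q1 * L1 / (L1 + b1 * cc)^2
  dphi2  <- L3 * (params$ipr_l4 - params$ipr_k2 * b2) / (L3 + b2 * cc)^2
  dphim2 <- (params$ipr_lm4 - params$ipr_km2 / L5) / (1 + cc / L5)^2
  dphi3  <- -params$ipr_k3 * L5 / (L5 + cc)^2
  dphi4  <- (params$ipr_k4 * L5 + params$ipr_l6) * L5 / (L5 + cc)^2
  dphim4 <- -L1 * (params$ipr_km4 + params$ipr_lm6) / (L1 + cc)^2
  dphi5  <- q1 * L1 / (L1 + cc)^2

  R <- state[["R"]]; I1 <- state[["I1"]]; I2 <- state[["I2"]]

  ## cytosolic calcium row
  J["c", "c"]  <- dk3 * w - rate - dJs_dc - dJpm
  J["c", "ce"] <- rate - dJs_dce
  J["c", "O"]  <- params$kf * dP0 * params$alpha1 * w
  J["c", "A"]  <- params$kf * dP0 * params$alpha2 * w
  if (dynp) J["c", "p"] <- params$a2

  ## ER row: -gamma * (ER-exchange part of the c row)
  J["ce", "c"]  <- -params$gamma * (dk3 * w - rate - dJs_dc)
  J["ce", "ce"] <- -params$gamma * (rate - dJs_dce)
  J["ce", "O"]  <- -params$gamma * params$kf * dP0 * params$alpha1 * w
  J["ce", "A"]  <- -params$gamma * params$kf * dP0 * params$alpha2 * w

  ## receptor block (S eliminated: S = 1 - R - O - A - I1 - I2)
  J["R", "R"] <- -r$phi2 * p - r$phi1
  J["R", "O"] <- r$phim2
  J["R", "I1"] <- r$g
  J["R", "c"] <- dphim2 * O - dphi2 * p * R - dphi1 * R

  J["O", "R"] <- r$phi2 * p - r$km3
  J["O", "O"] <- -(r$phim2 + r$phi4 + r$phi3) - r$km3
  J["O", "A"] <- r$phim4 - r$km3
  J["O", "I1"] <- -r$km3
  J["O", "I2"] <- -r$km3
  J["O", "c"] <- dphi2 * p * R - (dphim2 + dphi4 + dphi3) * O + dphim4 * A

  J["A", "O"] <- r$phi4
  J["A", "A"] <- -(r$phim4 + r$phi5)
  J["A", "I2"] <- r$g
  J["A", "c"] <- dphi4 * O - (dphim4 + dphi5) * A

  J["I1", "R"] <- r$phi1
  J["I1", "I1"] <- -r$g
  J["I1", "c"] <- dphi1 * R

  J["I2", "A"] <- r$phi5
  J["I2", "I2"] <- -r$g
  J["I2", "c"] <- dphi5 * A

  if (dynp) {
    J["R", "p"] <- -r$phi2 * R
    J["O", "p"] <- r$phi2 * R

    te <- ip3_tau_eta(params)
    Vplc <- params$vPLC + params$muPLC * a
    Kplc <- params$kPLC + params$kappaPLC * a
    D <- if (isTRUE(params$squared_sensitivity)) Kplc^2 else Kplc
    dprod <- Vplc * 2 * cc * D / (D + cc^2)^2
    deg <- te$eta * cc^2 / (params$K3K^2 + cc^2) + (1 - te$eta)
    ddeg <- te$eta * 2 * cc * params$K3K^2 / (params$K3K^2 + cc^2)^2
    J["p", "c"] <- (dprod - ddeg * p) / te$tau_p
    J["p", "p"] <- -deg / te$tau_p
  }
  J
}
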