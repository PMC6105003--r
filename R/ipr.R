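#' Six-state IP3-receptor gating kinetics
#'
#' The receptor occupies one of six states: resting `R`, open `O`, active
#' `A`, shut `S`, and two inactive states `I1`, `I2`. Transitions depend on
#' cytosolic calcium `c` and IP3 `p` through saturating rate functions
#' (Sneyd–Dufour receptor kinetics); IP3 binding drives `R -> O`, so the
#' channel cannot open at `p = 0` from the resting state. Occupancies sum
#' to one; `S` is eliminated by conservation so the model integrates five
#' independent ODEs.
#'
#' `ipr_transition_rates()` returns the seven calcium-dependent rate
#' functions evaluated at `c` (the `R -> O` rate is additionally
#' proportional to `p`). `ipr_derivatives()` gives the time-derivatives of
#' the five independent occupancies, `ipr_rate_matrix()` the full 6x6
#' generator at fixed `(c, p)`, and `ipr_stationary()` its unique
#' stationary distribution (null space of the generator, normalised to the
#' simplex).
#'
#' @param state named numeric vector with components `R`, `O`, `A`, `I1`,
#'   `I2` (occupancy fractions; `S` is `1 - sum`).
#' @param c cytosolic calcium (µM).
#' @param p IP3 concentration (µM).
#' @param params parameter list from [model_params()].
#' @return `ipr_derivatives()`: named vector of d/dt for `R, O, A, I1, I2`;
#'   `ipr_stationary()`: named length-6 occupancy vector summing to 1.
#' @examples
#' pr <- model_params()
#' eq <- ipr_stationary(c = 0.05, p = 10, params = pr)
#' sum(eq)
#' open_probability(eq[["O"]], eq[["A"]], pr)
#' @name ipr_gating
NULL

#' @rdname ipr_gating
#' @export
ipr_transition_rates <- function(c, params) {
  L1 <- params$ipr_L1; L3 <- params$ipr_L3; L5 <- params$ipr_L5
  list(
    phi1  = (params$ipr_k1 * L1 + params$ipr_l2) * c /
              (L1 + c * (1 + L1 / L3)),
    phi2  = (params$ipr_k2 * L3 + params$ipr_l4 * c) /
              (L3 + c * (1 + L3 / L1)),
    phim2 = (params$ipr_km2 + params$ipr_lm4 * c) / (1 + c / L5),
    phi3  = params$ipr_k3 * L5 / (L5 + c),
    phi4  = (params$ipr_k4 * L5 + params$ipr_l6) * c / (L5 + c),
    phim4 = L1 * (params$ipr_km4 + params$ipr_lm6) / (L1 + c),
    phi5  = (params$ipr_k1 * L1 + params$ipr_l2) * c / (L1 + c),
    km3   = params$ipr_km3,
    g     = params$ipr_km1 + params$ipr_lm2  # I1/I2 recovery rate
  )
}

#' @rdname ipr_gating
#' @export
ipr_derivatives <- function(state, c, p, params) {
  r <- ipr_transition_rates(c, params)
  R <- state[["R"]]; O <- state[["O"]]; A <- state[["A"]]
  I1 <- state[["I1"]]; I2 <- state[["I2"]]
  S <- 1 - R - O - A - I1 - I2
  c(R  = r$phim2 * O - r$phi2 * p * R + r$g * I1 - r$phi1 * R,
    O  = r$phi2 * p * R - (r$phim2 + r$phi4 + r$phi3) * O +
         r$phim4 * A + r$km3 * S,
    A  = r$phi4 * O - (r$phim4 + r$phi5) * A + r$g * I2,
    I1 = r$phi1 * R - r$g * I1,
    I2 = r$phi5 * A - r$g * I2)
}

#' @rdname ipr_gating
#' @export
ipr_rate_matrix <- function(c, p, params) {
  r <- ipr_transition_rates(c, params)
  states <- c("R", "O", "A", "S", "I1", "I2")
  Q <- matrix(0, 6, 6, dimnames = list(states, states))
  # Q[i, j]: rate from state j into state i (columns sum to zero)
  Q["O", "R"]  <- r$phi2 * p;  Q["R", "O"]  <- r$phim2
  Q["S", "O"]  <- r$phi3;      Q["O", "S"]  <- r$km3
  Q["A", "O"]  <- r$phi4;      Q["O", "A"]  <- r$phim4
  Q["I1", "R"] <- r$phi1;      Q["R", "I1"] <- r$g
  Q["I2", "A"] <- r$phi5;      Q["A", "I2"] <- r$g
  diag(Q) <- -colSums(Q)
  Q
}

#' @rdname ipr_gating
#' @export
ipr_stationary <- function(c, p, params) {
  Q <- ipr_rate_matrix(c, p, params)
  # replace one balance equation by the simplex constraint sum = 1
  A <- rbind(Q[-1, ], rep(1, 6))
  b <- c(rep(0, 5), 1)
  x <- solve(A, b)
  names(x) <- colnames(Q)
  x
}

#' IP3-receptor open probability
#'
#' The receptor conducts when all four identical subunits are open or
#' active: `P0 = (alpha1*O + alpha2*A)^4` with weights `alpha1 = 0.1`,
#' `alpha2 = 0.9` by default.
#'
#' @param O,A open- and active-state occupancies in `[0, 1]`.
#' @param params parameter list from [model_params()].
#' @return Open probability in `[0, 1]`.
#' @export
open_probability <- function(O, A, params) {
  (params$alpha1 * O + params$alpha2 * A)^4
}
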