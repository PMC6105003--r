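#' Membrane-potential compartment
#'
#' Hodgkin–Huxley-style voltage equation for a mostly potassium-conducting
#' (astrocyte-like) membrane:
#'
#' `Cm dV/dt = -I_kir - I_na - I_l - I_k - I_caT + I_app(t)`
#'
#' with an inward-rectifying potassium current `I_kir`, classical sodium /
#' delayed-rectifier / leak currents, and a low-threshold T-type calcium
#' current `I_caT = gcaT * mcaT^2 * hcaT * (V - Vca)` whose calcium entry
#' couples to the cytosolic compartment through [j_vca()] scaled by `ps`.
#' Gating variables follow first-order kinetics
#' `dx/dt = (x_inf(V) - x)/tau_x(V)`.
#'
#' Conventions: voltage in mV, time in seconds (HH rate functions, which
#' are natively per-millisecond, are converted internally). The printed
#' Kir conductance is in pS while the HH conductances are on the classical
#' mS-scale; `kir_scale` reconciles the two unit systems and is an
#' effective coefficient, as is `gcaT`. The delayed-rectifier current can
#' be switched off with `include_ik = FALSE`.
#'
#' @param V membrane potential (mV).
#' @param m,h,n,mcaT,hcaT gating variables in `[0, 1]`.
#' @param t time (s).
#' @param state named vector with components `V`, `m`, `h`, `n`, `mcaT`,
#'   `hcaT`.
#' @param params parameter list from [model_params()].
#' @param stimulus protocol from [stimulus_protocol()].
#' @param ps voltage-gated calcium flux scaling (dimensionless; absorbs
#'   the current-to-flux conversion 1/(2*F*w)).
#' @return Currents in the HH unit system; `j_vca()` a flux in µM/s;
#'   `membrane_derivatives()` a named vector of per-second derivatives.
#' @examples
#' pr <- model_params()
#' i_kir(-80.03, pr)   # zero at V = Vka + Va1
#' i_caT(100, 0.5, 0.5, pr)  # zero at the calcium Nernst potential
#' @name membrane
NULL

#' @rdname membrane
#' @export
i_kir <- function(V, params) {
  gate <- params$K0 / (1 + exp((V - params$Vka - params$Va2) / params$Va3))
  -params$gkir * params$kir_scale * gate * (V - params$Vka - params$Va1)
}

#' @rdname membrane
#' @export
i_na <- function(V, m, h, params) {
  params$gna * m^3 * h * (V - params$Vna)
}

#' @rdname membrane
#' @export
i_k <- function(V, n, params) {
  if (!isTRUE(params$include_ik)) return(0 * V)
  params$gk * n^4 * (V - params$Vk)
}

#' @rdname membrane
#' @export
i_leak <- function(V, params) {
  params$gl * (V - params$Vl)
}

#' @rdname membrane
#' @export
i_caT <- function(V, mcaT, hcaT, params) {
  params$gcaT * mcaT^2 * hcaT * (V - params$Vca)
}

#' @rdname membrane
#' @export
j_vca <- function(V, mcaT, hcaT, ps, params) {
  -ps * i_caT(V, mcaT, hcaT, params)
}

## classical HH rate functions (per ms); vtrap guards the 0/0 removable
## singularities of the alpha functions
vtrap <- function(x, y) ifelse(abs(x / y) < 1e-6, y * (1 - x / y / 2),
                               x / (exp(x / y) - 1))

hh_rates <- function(V) {
  list(
    am = 0.1 * vtrap(-(V + 40), 10),
    bm = 4 * exp(-(V + 65) / 18),
    ah = 0.07 * exp(-(V + 65) / 20),
    bh = 1 / (1 + exp(-(V + 35) / 10)),
    an = 0.01 * vtrap(-(V + 55), 10),
    bn = 0.125 * exp(-(V + 65) / 80)
  )
}

## low-threshold T-type kinetics (thalamic-relay formulation);
## steady states dimensionless, time constants in ms
tcaT_inf_tau <- function(V) {
  minf <- 1 / (1 + exp(-(V + 57) / 6.2))
  hinf <- 1 / (1 + exp((V + 81) / 4.03))
  taum <- 0.612 + 1 / (exp(-(V + 132) / 16.7) + exp((V + 16.8) / 18.2))
  tauh <- ifelse(V < -81, exp((V + 467) / 66.6),
                 28 + exp(-(V + 22) / 10.5))
  list(minf = minf, hinf = hinf, taum = taum, tauh = tauh)
}

#' @rdname membrane
#' @export
applied_current <- function(t, stimulus) {
  ifelse(t >= stimulus$t_on & t < stimulus$t_on + stimulus$duration,
         stimulus$amplitude, 0)
}

#' @rdname membrane
#' @export
membrane_derivatives <- function(state, t, params,
                                 stimulus = stimulus_protocol()) {
  V <- state[["V"]]
  m <- state[["m"]]; h <- state[["h"]]; n <- state[["n"]]
  mcaT <- state[["mcaT"]]; hcaT <- state[["hcaT"]]
  r <- hh_rates(V)
  tt <- tcaT_inf_tau(V)
  Iapp <- applied_current(t, stimulus)
  Isum <- i_kir(V, params) + i_na(V, m, h, params) +
    i_leak(V, params) + i_k(V, n, params) + i_caT(V, mcaT, hcaT, params)
  ms <- 1000  # HH kinetics are per-millisecond; model time is seconds
  c(V    = ms * (-Isum + Iapp) / params$Cm,
    m    = ms * (r$am * (1 - m) - r$bm * m),
    h    = ms * (r$ah * (1 - h) - r$bh * h),
    n    = ms * (r$an * (1 - n) - r$bn * n),
    mcaT = ms * (tt$minf - mcaT) / tt$taum,
    hcaT = ms * (tt$hinf - hcaT) / tt$tauh)
}
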