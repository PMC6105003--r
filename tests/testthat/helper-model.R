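# shared fixtures: short horizons keep the default suite fast while the
# dynamics of interest (second-scale oscillations) are fully resolved

quick_config <- function(...) model_config(tmax = 100, dt = 0.05, ...)

# six-state receptor ODE at frozen (c, p), integrated without the
# conservation elimination: an independent route used as oracle
integrate_ipr6 <- function(c, p, params, tmax = 400,
                           y0 = c(R = 1, O = 0, A = 0, S = 0,
                                  I1 = 0, I2 = 0)) {
  Q <- ipr_rate_matrix(c, p, params)
  sol <- deSolve::ode(y = y0, times = c(0, tmax),
                      func = function(t, y, parms) list(as.numeric(Q %*% y)),
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  st <- sol[nrow(sol), -1]
  names(st) <- names(y0)
  st
}
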