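#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

#' State layout and initial conditions
#'
#' `state_layout()` returns the names and order of the dynamic variables
#' for a configuration; all other modules use this single index map and
#' never hard-code positions. `initial_state()` returns the default
#' initial condition: `c = 0.05`, `ce = 10`, receptor fully in the resting
#' state (`R = 1`), `p = 0.01` for the dynamic-IP3 variant, and the
#' classical resting membrane values (`V = -65`, `m = 0.05`, `n = 0.32`,
#' `h = 0.6`, `mcaT = 0.29`, `hcaT = 0.01`) when the membrane is present.
#'
#' @param config configuration from [model_config()].
#' @return A character vector (`state_layout`) or named numeric vector
#'   (`initial_state`).
#' @export
state_layout <- function(config) {
  vars <- c("c", "ce", "R", "O", "A", "I1", "I2")
  if (config$variant == "dynamic_ip3") vars <- c(vars, "p")
  if (config$variant == "with_membrane")
    vars <- c(vars, "V", "m", "h", "n", "mcaT", "hcaT")
  vars
}

#' @rdname state_layout
#' @export
initial_state <- function(config) {
  y <- c(c = config$c0, ce = config$ce0,
         R = 1, O = 0, A = 0, I1 = 0, I2 = 0)
  if (config$variant == "dynamic_ip3") y <- c(y, p = config$p0)
  if (config$variant == "with_membrane")
    y <- c(y, V = -65, m = 0.05, h = 0.6, n = 0.32, mcaT = 0.29,
           hcaT = 0.01)
  y[state_layout(config)]
}

#' Full model right-hand side
#'
#' Assembles the calcium balance
#' `dc/dt = J_IPR + J_RyR - J_SERCA + J_in - J_pm + J_vca` and the ER
#' balance `dce/dt = -gamma * (J_IPR + J_RyR - J_SERCA)` with the
#' IP3-receptor gating ODEs and, depending on the variant, the dynamic-IP3
#' and membrane subsystems. Concentrations that go transiently negative
#' inside an adaptive solver step are clamped to zero for flux evaluation
#' only; the stored state is never altered.
#'
#' @param t time (s).
#' @param state named numeric vector ordered as [state_layout()].
#' @param params parameter list from [model_params()].
#' @param config configuration from [model_config()].
#' @return Named vector of time-derivatives in the layout order.
#' @export
cell_rhs <- function(t, state, params, config) {
  cc <- max(state[["c"]], 0)
  ce <- max(state[["ce"]], 0)
  a <- config$a
  p <- if (config$variant == "dynamic_ip3") max(state[["p"]], 0) else config$p

  ipr_state <- c(R = state[["R"]], O = state[["O"]], A = state[["A"]],
                 I1 = state[["I1"]], I2 = state[["I2"]])
  P0 <- open_probability(min(max(state[["O"]], 0), 1),
                         min(max(state[["A"]], 0), 1), params)

  Jipr   <- j_ipr(cc, ce, P0, params, check = FALSE)
  Jryr   <- j_ryr(cc, ce, a, params, check = FALSE)
  Jserca <- j_serca(cc, ce, params, check = FALSE)
  Jin    <- j_in(p, a, params, check = FALSE)
  Jpm    <- j_pm(cc, params, check = FALSE)

  Jvca <- 0
  dmem <- NULL
  if (config$variant == "with_membrane") {
    mem <- state[c("V", "m", "h", "n", "mcaT", "hcaT")]
    dmem <- membrane_derivatives(mem, t, params, config$stimulus)
    Jvca <- j_vca(mem[["V"]], mem[["mcaT"]], mem[["hcaT"]], config$ps,
                  params)
  }

  er_exchange <- Jipr + Jryr - Jserca
  dc  <- er_exchange + Jin - Jpm + Jvca
  dce <- -params$gamma * er_exchange
  dipr <- ipr_derivatives(ipr_state, cc, p, params)

  dy <- c(c = dc, ce = dce, dipr)
  if (config$variant == "dynamic_ip3")
    dy <- c(dy, p = ip3_derivative(p, cc, a, params, check = FALSE))
  if (config$variant == "with_membrane") dy <- c(dy, dmem)

  if (any(!is.finite(dy))) {
    fl <- c(J_IPR = Jipr, J_RyR = Jryr, J_SERCA = Jserca, J_in = Jin,
            J_pm = Jpm, J_vca = Jvca)
    bad <- names(fl)[!is.finite(fl)]
    if (!length(bad))
      bad <- paste("state derivative", names(dy)[!is.finite(dy)])
    stop("non-finite flux at t = ", t, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dy
}

#' Per-term flux breakdown
#'
#' Evaluates every flux of the calcium balance at a given state, for
#' diagnostics and conservation checks.
#'
#' @inheritParams cell_rhs
#' @return A one-row tibble with columns `J_IPR`, `J_RyR`, `J_SERCA`,
#'   `J_in`, `J_pm`, `J_vca` (µM/s).
#' @export
flux_breakdown <- function(state, t = 0, params = model_params(),
                           config = model_config()) {
  cc <- state[["c"]]; ce <- state[["ce"]]
  p <- if (config$variant == "dynamic_ip3") state[["p"]] else config$p
  P0 <- open_probability(state[["O"]], state[["A"]], params)
  Jvca <- if (config$variant == "with_membrane")
    j_vca(state[["V"]], state[["mcaT"]], state[["hcaT"]], config$ps, params)
  else 0
  tibble::tibble(
    J_IPR = j_ipr(cc, ce, P0, params), J_RyR = j_ryr(cc, ce, config$a, params),
    J_SERCA = j_serca(cc, ce, params), J_in = j_in(p, config$a, params),
    J_pm = j_pm(cc, params), J_vca = Jvca)
}

#' Simulate the whole-cell calcium model
#'
#' Integrates the configured variant with an adaptive solver
#' (`deSolve::lsoda` by default, which falls back to a stiff BDF method
#' automatically — the system mixes millisecond gating with ~100 s calcium
#' cycling) and returns the trace resampled at the configured output step.
#' When a stimulus pulse is active, integration is restarted at the pulse
#' edges so the current discontinuity never falls inside an adaptive step.
#'
#' @param config configuration from [model_config()].
#' @param params parameter list from [model_params()].
#' @param y0 optional initial state (defaults to [initial_state()]).
#' @param times optional output time grid (defaults to
#'   `seq(0, config$tmax, by = config$dt)`).
#' @param method a `deSolve` method name.
#' @return A tibble of class `"ca_trace"` with a `t` column, one column
#'   per dynamic variable, the derived shut-state occupancy `S`, and (for
#'   fixed-IP3 variants) the constant `p`. Attributes `params`, `config`
#'   and `solver` carry full provenance.
#' @examples
#' \donttest{
#' tr <- simulate_model(model_config(p = 5, tmax = 100))
#' range(tr$c)
#' }
#' @export
simulate_model <- function(config = model_config(),
                           params = model_params(),
                           y0 = NULL, times = NULL, method = "lsoda") {
  if (is.null(y0)) y0 <- initial_state(config)
  y0 <- y0[state_layout(config)]
  if (anyNA(y0)) stop("initial state incomplete for variant ",
                      config$variant, call. = FALSE)
  if (is.null(times)) times <- seq(0, config$tmax, by = config$dt)

  edges <- numeric(0)
  st <- config$stimulus
  if (config$variant == "with_membrane" && st$amplitude != 0 &&
      st$duration > 0)
    edges <- c(st$t_on, st$t_on + st$duration)
  edges <- sort(unique(edges[edges > min(times) & edges < max(times)]))

  segs <- split_times(times, edges)
  out <- NULL
  y <- y0
  for (seg in segs) {
    sol <- deSolve::ode(y = y, times = seg, method = method,
                        func = function(t, y, parms) list(cell_rhs(t, y, params, config)),
                        parms = NULL, rtol = config$rtol, atol = config$atol)
    if (attr(sol, "istate")[1] < 0)
      warning("solver stopped early at t = ", max(sol[, 1]))
    y <- sol[nrow(sol), -1]
    out <- if (is.null(out)) sol else rbind(out, sol[-1, , drop = FALSE])
  }

  df <- tibble::as_tibble(as.data.frame(out))
  names(df)[1] <- "t"
  df$S <- 1 - df$R - df$O - df$A - df$I1 - df$I2
  if (config$variant != "dynamic_ip3") df$p <- config$p
  df <- df[, intersect(c("t", "c", "ce", "p", "R", "O", "A", "I1", "I2",
                         "S", "V", "m", "h", "n", "mcaT", "hcaT"),
                       names(df))]
  structure(df, class = c("ca_trace", class(df)),
            params = params, config = config,
            solver = list(method = method, rtol = config$rtol,
                          atol = config$atol))
}

## partition an output grid at interior event times, keeping the events as
## segment endpoints so each deSolve call sees a clean interval
split_times <- function(times, edges) {
  if (!length(edges)) return(list(times))
  bounds <- c(min(times), edges, max(times))
  lapply(seq_len(length(bounds) - 1L), function(i) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    inner <- times[times > lo & times < hi]
    unique(c(lo, inner, hi))
  })
}

#' @export
print.ca_trace <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<ca_trace> variant:", cfg$variant, " a =", cfg$a,
      if (cfg$variant != "dynamic_ip3") paste(" p =", cfg$p),
      " |", nrow(x), "samples over", max(x$t), "s\n")
  NextMethod()
}
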