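#' Periodic orbits, Floquet multipliers and period-doubling detection
#'
#' Periodic orbits are located by single shooting against a Poincaré
#' section anchored to cytosolic calcium (the largest-amplitude
#' observable): the section is `c = c_sec` with positive crossing
#' orientation, and closure is required in the full state norm, so a
#' mixed-mode cycle that pierces the section several times per period is
#' still closed at its true (full-cycle) period. The monodromy matrix is
#' accumulated by integrating the variational equations alongside the
#' state, giving the shooting Jacobian and the Floquet multipliers in one
#' pass. Orbit stability follows the multipliers: all nontrivial
#' multipliers inside the unit circle for a stable cycle, a real
#' multiplier crossing -1 at a period-doubling bifurcation.
#'
#' @name orbits
NULL

## integrate state + variational equations; returns final state and the
## monodromy matrix dPhi_T/dy0
flow_with_monodromy <- function(y0, T, params, config,
                                rtol = NULL, atol = NULL) {
  n <- length(y0)
  rtol <- rtol %||% config$rtol
  atol <- atol %||% config$atol
  var_rhs <- function(t, z, parms) {
    y <- stats::setNames(z[seq_len(n)], names(y0))
    M <- matrix(z[-seq_len(n)], n, n)
    f <- cell_rhs(t, y, params, config)
    J <- cell_jacobian(y, t, params, config)
    list(c(f, J %*% M))
  }
  z0 <- c(y0, as.numeric(diag(n)))
  sol <- deSolve::ode(y = z0, times = c(0, T), func = var_rhs,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol, maxsteps = 20000)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < 2 ||
      sol[nrow(sol), 1] < T)
    stop("variational integration failed before t = ", T, call. = FALSE)
  zT <- sol[nrow(sol), -1]
  list(y = stats::setNames(zT[seq_len(n)], names(y0)),
       M = matrix(zT[-seq_len(n)], n, n))
}

## plain flow without variational system
flow_to <- function(y0, T, params, config) {
  sol <- deSolve::ode(y = y0, times = c(0, T),
                      func = function(t, y, parms)
                        list(cell_rhs(t, y, params, config)),
                      parms = NULL, method = "lsoda",
                      rtol = config$rtol, atol = config$atol)
  stats::setNames(sol[nrow(sol), -1], names(y0))
}

## seed an orbit from a simulated trace: last full return to the section
## c = mean(c) with increasing orientation
orbit_seed <- function(params, config, tmax = 250, transient = 0.5) {
  cfg <- config
  cfg$tmax <- tmax
  cfg$dt <- 0.02
  tr <- simulate_model(cfg, params)
  tr <- tr[tr$t >= transient * tmax, ]
  cs <- tr$c
  c_sec <- mean(range(cs))  # mid-range: crossed once per single-mode cycle
  up <- which(cs[-length(cs)] < c_sec & cs[-1] >= c_sec)
  if (length(up) < 3)
    stop("trace is not oscillatory enough to seed an orbit", call. = FALSE)
  i2 <- up[length(up)]; i1 <- up[length(up) - 1L]
  vars <- state_layout(config)
  y0 <- unlist(tr[i1, vars])
  list(y0 = y0, T = tr$t[i2] - tr$t[i1], c_sec = c_sec,
       amplitude = diff(range(cs)))
}

#' Locate a periodic orbit by shooting
#'
#' @param config,params model configuration and parameters (the system
#'   must be oscillatory at these values, or `seed` must be supplied).
#' @param seed optional warm start: a list with `y0` (state on the orbit)
#'   and `T` (period estimate), e.g. from a previous continuation step.
#'   By default a converged simulated trace provides the seed.
#' @param tol closure tolerance on the state norm.
#' @param max_iter Newton iterations.
#' @param tmax simulation horizon used when seeding from a trace.
#' @return A list of class `"ca_orbit"`: `period` (s), `y0` (state on the
#'   orbit), `amplitude` (max c - min c over one period), `multipliers`
#'   (Floquet multipliers from the monodromy matrix), `residual`,
#'   `converged`, and `samples` (tibble of one period of the orbit).
#' @examples
#' \donttest{
#' orb <- find_orbit(model_config(p = 5))
#' orb$period
#' }
#' @export
find_orbit <- function(config = model_config(), params = model_params(),
                       seed = NULL, tol = 1e-6, max_iter = 10,
                       tmax = 250) {
  if (is.null(seed)) seed <- orbit_seed(params, config, tmax = tmax)
  y <- seed$y0
  T <- seed$T
  T0 <- T
  n <- length(y)
  phase_i <- which(state_layout(config) == "c")
  M <- NULL
  converged <- FALSE
  res <- Inf
  for (it in seq_len(max_iter)) {
    if (T < 0.3 * T0 || T > 3 * T0)
      stop("shooting left the period's trust region (T = ",
           format(T, digits = 4), ")", call. = FALSE)
    fm <- flow_with_monodromy(y, T, params, config)
    G <- fm$y - y
    res_prev <- res
    res <- sqrt(sum(G^2))
    if (!is.finite(res))
      stop("shooting produced a non-finite residual", call. = FALSE)
    if (it > 3 && res > 10 * res_prev)
      stop("shooting residual diverging", call. = FALSE)
    if (res < tol) { M <- fm$M; converged <- TRUE; break }
    fT <- cell_rhs(0, fm$y, params, config)  # d(flow)/dT
    f0 <- cell_rhs(0, y, params, config)
    # Newton on [closure; phase]: phase condition fixes the c component
    A <- rbind(cbind(fm$M - diag(n), fT),
               c(replace(numeric(n), phase_i, 1), 0))
    b <- -c(G, 0)
    step <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(step)) break
    # damp long steps; period must stay positive
    sc <- min(1, 0.5 * T / (abs(step[n + 1L]) + 1e-12))
    y <- y + sc * unname(step[seq_len(n)])
    T <- T + sc * unname(step[n + 1L])
    if (T <= 0) { T <- abs(T) + 1e-3; break }
  }
  if (is.null(M)) {
    fm <- flow_with_monodromy(y, T, params, config)
    M <- fm$M
    res <- sqrt(sum((fm$y - y)^2))
    converged <- is.finite(res) && res < tol
  }
  samples <- orbit_samples(y, T, params, config)
  structure(list(period = T, y0 = y,
                 amplitude = max(samples$c) - min(samples$c),
                 multipliers = sort_multipliers(eigen(M, only.values = TRUE)$values),
                 residual = res, converged = converged,
                 samples = samples, config = config, params = params),
            class = "ca_orbit")
}

orbit_samples <- function(y0, T, params, config, n_out = 200) {
  times <- seq(0, T, length.out = n_out)
  sol <- deSolve::ode(y = y0, times = times,
                      func = function(t, y, parms)
                        list(cell_rhs(t, y, params, config)),
                      parms = NULL, method = "lsoda",
                      rtol = config$rtol, atol = config$atol)
  df <- tibble::as_tibble(as.data.frame(sol))
  names(df)[1] <- "t"
  df
}

sort_multipliers <- function(mu) mu[order(-abs(mu))]

#' Floquet multipliers of a periodic orbit
#'
#' Recomputes the monodromy matrix over one period by integrating the
#' variational equations and returns its eigenvalues. One multiplier must
#' equal +1 (the phase direction); its deviation from 1 is an
#' integration-accuracy certificate.
#'
#' @param orbit a `"ca_orbit"` from [find_orbit()].
#' @param params,config optional overrides (default: those of the orbit).
#' @return Complex vector of multipliers, decreasing in modulus, with
#'   attribute `trivial_error` = `|mu_trivial - 1|`.
#' @export
floquet_multipliers <- function(orbit, params = NULL, config = NULL) {
  params <- params %||% orbit$params
  config <- config %||% orbit$config
  fm <- flow_with_monodromy(orbit$y0, orbit$period, params, config)
  mu <- sort_multipliers(eigen(fm$M, only.values = TRUE)$values)
  structure(mu, trivial_error = min(abs(mu - 1)))
}

## real multiplier closest to -1 (candidate period-doubling indicator);
## the trivial +1 multiplier is excluded
pd_indicator <- function(mu) {
  mu <- mu[abs(Im(mu)) < 1e-6 & Re(mu) < 0.5]
  if (!length(mu)) return(NA_real_)
  Re(mu[which.min(abs(Re(mu) + 1))])
}

#' Period-doubling points along an orbit branch
#'
#' Continues the periodic orbit in a parameter with adaptive steps:
#' each orbit warm-starts the next shooting solve, a step is accepted
#' only when the orbit converges and its period stays continuous (within
#' 25% of the previous one), and the step is halved otherwise — the
#' transition into the mixed-mode regime is canard-sharp, with the
#' critical multiplier growing by orders of magnitude over a tiny
#' parameter window, so fixed-step tracking jumps branches. Along the
#' accepted branch the real Floquet multiplier closest to -1 is tracked
#' and each crossing of -1 is bisected (warm-started from the left) to
#' `refine_tol`. If the branch terminates (shooting stops converging at
#' the minimal step) before a crossing is seen, the termination point is
#' reported as kind `"branch_end"` with the last multiplier.
#'
#' @param parameter parameter name as in [scan_branch()].
#' @param range length-2 numeric scan interval (traversed upward).
#' @param steps nominal number of continuation steps (sets the initial
#'   step size).
#' @param config,params model configuration and parameters.
#' @param refine_tol bisection / minimal-step tolerance on the parameter.
#' @param verbose print each accepted continuation step.
#' @param max_points stop after this many period-doubling points.
#' @return A list of class `"ca_pd_scan"`: `branch` (tibble of parameter,
#'   period, amplitude, leading nontrivial multiplier and the -1-tracking
#'   multiplier) and `points` (tibble of period-doubling / branch-end
#'   locations).
#' @examples
#' \donttest{
#' pd <- find_period_doubling("kalpha", c(0.45, 0.65), steps = 8,
#'                            config = model_config(p = 10, a = 0.25))
#' pd$points
#' }
#' @export
find_period_doubling <- function(parameter, range, steps = 20,
                                 config = model_config(),
                                 params = model_params(),
                                 refine_tol = 1e-3, verbose = FALSE,
                                 max_points = Inf) {
  step0 <- (range[2] - range[1]) / steps
  at <- function(v) set_scan_value(parameter, v, params, config)
  orbit_at <- function(v, seed) {
    pc <- at(v)
    find_orbit(pc$config, pc$params, seed = seed)
  }

  rows <- list()
  points <- tibble::tibble(kind = character(), parameter = character(),
                           value = numeric(), multiplier = numeric())
  record <- function(v, orb) {
    nontrivial <- orb$multipliers[order(abs(abs(orb$multipliers) - 1))][-1]
    if (verbose)
      message(sprintf("  %s = %-8.5g T = %-8.5g mu_pd = %-10.4g",
                      parameter, v, orb$period,
                      pd_indicator(orb$multipliers)))
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      value = v, period = orb$period, amplitude = orb$amplitude,
      leading_multiplier = max(abs(nontrivial)),
      pd_multiplier = pd_indicator(orb$multipliers))
  }

  v <- range[1]
  orb <- tryCatch(orbit_at(v, NULL), error = function(e) NULL)
  if (is.null(orb) || !orb$converged)
    stop("no periodic orbit at ", parameter, " = ", v, call. = FALSE)
  record(v, orb)
  step <- step0

  while (v < range[2] - 1e-12) {
    v_try <- min(v + step, range[2])
    seed <- list(y0 = orb$y0, T = orb$period)
    orb_try <- tryCatch(orbit_at(v_try, seed), error = function(e) NULL)
    ok <- !is.null(orb_try) && orb_try$converged &&
      abs(orb_try$period / orb$period - 1) < 0.25
    if (!ok) {
      step <- step / 2
      if (step < refine_tol) {
        points <- rbind(points, tibble::tibble(
          kind = "branch_end", parameter = parameter, value = v,
          multiplier = pd_indicator(orb$multipliers)))
        break
      }
      next
    }
    ind_prev <- pd_indicator(orb$multipliers)
    ind_new <- pd_indicator(orb_try$multipliers)
    # a genuine -1 crossing is continuous in the multiplier; a jump
    # (e.g. the critical pair turning complex at branch loss) is not
    if (is.finite(ind_prev) && is.finite(ind_new) &&
        (ind_prev + 1) * (ind_new + 1) < 0 &&
        abs(ind_new - ind_prev) < 1) {
      pd <- bisect_pd(orbit_at, v, v_try, seed, ind_prev, refine_tol)
      points <- rbind(points, tibble::tibble(
        kind = "period_doubling", parameter = parameter,
        value = pd$value, multiplier = pd$multiplier))
      if (sum(points$kind == "period_doubling") >= max_points) {
        v <- v_try; orb <- orb_try; record(v, orb)
        break
      }
    }
    v <- v_try
    orb <- orb_try
    record(v, orb)
    step <- min(step0, step * 1.6)
  }
  branch <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble()
  if (nrow(branch)) names(branch)[1] <- parameter
  structure(list(branch = branch, points = points, parameter = parameter,
                 config = config, params = params),
            class = "ca_pd_scan")
}

## bisection on the sign of (multiplier + 1), warm-starting every solve
## from the converged orbit at the left end of the current bracket
bisect_pd <- function(orbit_at, lo, hi, seed_lo, ind_lo, refine_tol) {
  final <- NA_real_
  while (hi - lo > refine_tol) {
    mid <- (lo + hi) / 2
    orb <- tryCatch(orbit_at(mid, seed_lo), error = function(e) NULL)
    if (is.null(orb) || !orb$converged) { hi <- mid; next }
    ind <- pd_indicator(orb$multipliers)
    if (!is.finite(ind)) { hi <- mid; next }
    final <- ind
    if ((ind_lo + 1) * (ind + 1) <= 0) hi <- mid
    else {
      lo <- mid; ind_lo <- ind
      seed_lo <- list(y0 = orb$y0, T = orb$period)
    }
  }
  list(value = (lo + hi) / 2, multiplier = final)
}

#' @export
print.ca_orbit <- function(x, ...) {
  cat("<ca_orbit> period", format(x$period, digits = 6), "s, amplitude",
      format(x$amplitude, digits = 4), "µM,",
      if (x$converged) "converged" else "NOT converged",
      "(residual", format(x$residual, digits = 3), ")\n")
  cat("  |multipliers|:",
      paste(format(abs(x$multipliers), digits = 4), collapse = ", "), "\n")
  invisible(x)
}
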