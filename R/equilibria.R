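#' Steady states, linear stability and one-parameter bifurcation scans
#'
#' Equilibria of the model satisfy two decoupled balances: the plasma
#' membrane balance `J_in = J_pm` (which pins cytosolic calcium, and for
#' the dynamic-IP3 variant couples to the IP3 fixed point), and the ER
#' balance `J_IPR + J_RyR = J_SERCA` (which pins ER calcium given the
#' stationary receptor occupancies). `find_steady_state()` exploits this
#' structure to build a semi-analytic initial guess for the membrane-off
#' variants and then polishes it with a damped Newton iteration on the
#' full right-hand side.
#'
#' @name equilibria
NULL

#' Newton root of the model right-hand side
#'
#' @param params parameter list from [model_params()].
#' @param config configuration from [model_config()].
#' @param guess optional named initial state; when omitted a semi-analytic
#'   guess from the flux-balance structure is used.
#' @param tol residual infinity-norm tolerance.
#' @param max_iter maximal Newton iterations.
#' @return Named equilibrium state vector with attributes `residual`
#'   (infinity norm) and `converged`.
#' @examples
#' eq <- find_steady_state(model_config(p = 0, a = 0))
#' attr(eq, "residual")
#' @export
find_steady_state <- function(config = model_config(),
                              params = model_params(),
                              guess = NULL, tol = 1e-10, max_iter = 60) {
  f <- function(y) cell_rhs(0, y, params, config)
  if (is.null(guess)) guess <- equilibrium_guess(params, config)
  y <- guess[state_layout(config)]
  res_hist <- numeric(0)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    fy <- f(y)
    res <- max(abs(fy))
    res_hist <- c(res_hist, res)
    if (res < tol) { converged <- TRUE; break }
    J <- jacobian_fd(f, y)
    step <- tryCatch(solve(J, -fy), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {  # damped step: accept only residual decrease
      y_new <- y + lambda * step
      ok <- tryCatch(max(abs(f(y_new))) < res || lambda < 1e-4,
                     error = function(e) FALSE)
      if (ok) break
      lambda <- lambda / 2
    }
    y <- y + lambda * step
  }
  if (!converged) {
    fy <- f(y)
    if (max(abs(fy)) < tol) converged <- TRUE
  }
  structure(y, residual = max(abs(f(y))), converged = converged,
            residual_history = res_hist)
}

#' Finite-difference Jacobian
#'
#' Central differences with a per-variable step scaled to the magnitude of
#' the state component.
#'
#' @param f vector-valued function of a numeric vector.
#' @param y evaluation point.
#' @param eps base relative step.
#' @return Jacobian matrix `d f_i / d y_j`.
#' @export
jacobian_fd <- function(f, y, eps = 1e-6) {
  n <- length(y)
  f0 <- f(y)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- eps * max(abs(y[j]), 1e-3)
    yp <- y; yp[j] <- yp[j] + h
    ym <- y; ym[j] <- ym[j] - h
    J[, j] <- (f(yp) - f(ym)) / (2 * h)
  }
  dimnames(J) <- list(names(f0), names(y))
  J
}

#' Jacobian spectrum at a state
#'
#' @inheritParams find_steady_state
#' @param state equilibrium state (named vector in layout order).
#' @return Complex eigenvalues of the finite-difference Jacobian, sorted
#'   by decreasing real part.
#' @export
eigenvalues_at <- function(state, config = model_config(),
                           params = model_params()) {
  f <- function(y) cell_rhs(0, y, params, config)
  ev <- eigen(jacobian_fd(f, state[state_layout(config)]),
              only.values = TRUE)$values
  ev[order(-Re(ev))]
}

## ---- semi-analytic equilibrium structure (membrane-off variants) -------

## cytosolic calcium at the plasma-membrane balance J_in = J_pm; for
## dynamic IP3 the leak depends on c through the IP3 fixed point
solve_c_star <- function(params, config, c_upper = 50) {
  influx <- function(cc) {
    p <- if (config$variant == "dynamic_ip3")
      ip3_fixed_point(cc, config$a, params) else config$p
    j_in(p, config$a, params)
  }
  g <- function(cc) influx(cc) - j_pm(cc, params)
  if (g(c_upper) > 0) return(NULL)  # influx exceeds pump capacity: no root
  stats::uniroot(g, c(0, c_upper), tol = 1e-14)$root
}

## ER calcium at the ER balance given c and the stationary receptor
solve_ce_star <- function(cc, p, params, config) {
  st <- ipr_stationary(cc, p, params)
  P0 <- open_probability(st[["O"]], st[["A"]], params)
  rate <- params$kf * P0 + params$Jer + ryr_rate(cc, config$a, params)
  h <- function(ce) rate * (ce - cc) - j_serca(cc, ce, params)
  upper <- max(cc + 1, 2 * cc + 2)
  while (h(upper) < 0 && upper < 1e7) upper <- upper * 2
  stats::uniroot(h, c(cc, upper), tol = 1e-12)$root
}

equilibrium_guess <- function(params, config) {
  cc <- solve_c_star(params, config)
  if (is.null(cc))
    stop("no equilibrium: calcium influx exceeds pump capacity",
         call. = FALSE)
  p <- if (config$variant == "dynamic_ip3")
    ip3_fixed_point(cc, config$a, params) else config$p
  ce <- solve_ce_star(cc, p, params, config)
  st <- ipr_stationary(cc, p, params)
  y <- c(c = cc, ce = ce, R = st[["R"]], O = st[["O"]], A = st[["A"]],
         I1 = st[["I1"]], I2 = st[["I2"]])
  if (config$variant == "dynamic_ip3") y <- c(y, p = p)
  if (config$variant == "with_membrane") {
    mem <- membrane_rest(params)
    y <- c(y, mem)
  }
  y[state_layout(config)]
}

## resting state of the uncoupled membrane block (no applied current)
membrane_rest <- function(params) {
  y <- c(V = -65, m = 0.05, h = 0.6, n = 0.32, mcaT = 0.29, hcaT = 0.01)
  f <- function(x) membrane_derivatives(x, 0, params)
  for (i in 1:50) {
    fy <- f(y)
    if (max(abs(fy)) < 1e-9) break
    J <- jacobian_fd(f, y)
    step <- tryCatch(solve(J, -fy), error = function(e) rep(0, 6))
    y <- y + step
  }
  y
}

#' One-parameter equilibrium branch with bifurcation detection
#'
#' Natural-parameter continuation: the branch is traversed over `range`
#' in `steps` increments, each equilibrium warm-starting the next Newton
#' solve. Hopf points are detected as sign changes of the largest real
#' part over complex eigenvalue pairs and refined by bisection; folds as
#' sign changes through zero of a real eigenvalue; branch divergence
#' (equilibrium norm exceeding `diverge_at`, or loss of existence of the
#' flux balance) is localised by bisection on existence.
#'
#' @param parameter name of a model parameter (e.g. `"k2"`, `"kalpha"`) or
#'   one of the run conditions `"a"`, `"p"`, `"ps"`.
#' @param range length-2 numeric, scanned from `range[1]` to `range[2]`.
#' @param steps number of continuation steps.
#' @param config,params as in [find_steady_state()].
#' @param refine_tol bisection tolerance on the parameter.
#' @param diverge_at norm bound beyond which the branch is declared
#'   divergent.
#' @return A list of class `"ca_branch"`: `branch` (tibble with the
#'   parameter, equilibrium components, `max_re` over complex pairs and
#'   `stable`), `points` (tibble of detected bifurcations with kind
#'   `"hopf"`, `"fold"` or `"divergence"`), `parameter`, and the
#'   configuration.
#' @examples
#' \donttest{
#' br <- scan_branch("a", c(0, 1.25), steps = 60,
#'                   config = model_config(p = 0))
#' br$points
#' }
#' @export
scan_branch <- function(parameter, range, steps = 100,
                        config = model_config(), params = model_params(),
                        refine_tol = 1e-4, diverge_at = 1e4) {
  grid <- seq(range[1], range[2], length.out = steps + 1L)
  at <- function(val) set_scan_value(parameter, val, params, config)

  rows <- list(); eigs <- list()
  guess <- NULL
  last_ok <- NA_real_
  first_fail <- NA_real_
  for (v in grid) {
    pc <- at(v)
    eq <- tryCatch(
      find_steady_state(pc$config, pc$params, guess = guess),
      error = function(e) NULL)
    if (is.null(eq) || !isTRUE(attr(eq, "converged")) ||
        max(abs(eq)) > diverge_at) {
      # retry from a fresh semi-analytic guess before giving up
      eq <- tryCatch(find_steady_state(pc$config, pc$params),
                     error = function(e) NULL)
    }
    if (is.null(eq) || !isTRUE(attr(eq, "converged")) ||
        max(abs(eq)) > diverge_at) {
      first_fail <- v
      break
    }
    ev <- eigenvalues_at(eq, pc$config, pc$params)
    rows[[length(rows) + 1L]] <- c(value = v, eq,
                                   max_re = max(Re(ev)),
                                   max_re_cplx = max_re_complex(ev))
    eigs[[length(eigs) + 1L]] <- ev
    guess <- eq
    last_ok <- v
  }

  branch <- tibble::as_tibble(do.call(rbind, rows))
  names(branch)[1] <- parameter
  branch$stable <- branch$max_re < 0

  points <- detect_branch_points(branch, parameter, at, refine_tol)
  if (!is.na(first_fail) && !is.na(last_ok)) {
    vstar <- bisect_existence(at, last_ok, first_fail, diverge_at,
                              refine_tol)
    points <- rbind(points, tibble::tibble(
      kind = "divergence", parameter = parameter, value = vstar,
      eig_re = NA_real_, eig_im = NA_real_))
  }
  structure(list(branch = branch, points = points, parameter = parameter,
                 config = config, params = params),
            class = "ca_branch")
}

## largest real part over genuinely complex pairs (diagnostic column)
max_re_complex <- function(ev, im_tol = 1e-3) {
  sel <- abs(Im(ev)) > im_tol
  if (!any(sel)) return(-Inf)
  max(Re(ev[sel]))
}

## Stability changes are located on the overall max Re(lambda) signal; at
## the refined crossing the critical eigenvalue decides the kind: a
## complex pair (|Im| above im_tol) is a Hopf, a real eigenvalue crossing
## zero a fold-type neutral point. Tracking the overall maximum is robust
## against a complex pair splitting into two real eigenvalues between two
## continuation steps, which would defeat per-class tracking.
detect_branch_points <- function(branch, parameter, at, refine_tol,
                                 im_tol = 1e-3) {
  out <- tibble::tibble(kind = character(), parameter = character(),
                        value = numeric(), eig_re = numeric(),
                        eig_im = numeric())
  v <- branch[[parameter]]
  s <- sign(branch$max_re)
  idx <- which(!is.na(s[-1]) & !is.na(s[-length(s)]) &
                 s[-1] * s[-length(s)] < 0)
  for (i in idx) {
    ref <- bisect_eigen_crossing(at, v[i], v[i + 1L], refine_tol)
    if (!is.null(ref))
      out <- rbind(out, tibble::tibble(
        kind = if (ref$eig_im > im_tol) "hopf" else "fold",
        parameter = parameter, value = ref$value,
        eig_re = ref$eig_re, eig_im = ref$eig_im))
  }
  out
}

bisect_eigen_crossing <- function(at, lo, hi, refine_tol) {
  crit <- function(v) {
    pc <- at(v)
    eq <- find_steady_state(pc$config, pc$params)
    ev <- eigenvalues_at(eq, pc$config, pc$params)
    i <- which.max(Re(ev))
    list(re = Re(ev[i]), im = abs(Im(ev[i])))
  }
  flo <- tryCatch(crit(lo)$re, error = function(e) NA_real_)
  fhi <- tryCatch(crit(hi)$re, error = function(e) NA_real_)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NULL)
  while (hi - lo > refine_tol) {
    mid <- (lo + hi) / 2
    fm <- tryCatch(crit(mid)$re, error = function(e) NA_real_)
    if (is.na(fm)) break
    if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
  }
  fin <- crit((lo + hi) / 2)
  list(value = (lo + hi) / 2, eig_re = fin$re, eig_im = fin$im)
}

bisect_existence <- function(at, lo, hi, diverge_at, refine_tol) {
  exists_at <- function(v) {
    pc <- at(v)
    eq <- tryCatch(find_steady_state(pc$config, pc$params),
                   error = function(e) NULL)
    !is.null(eq) && isTRUE(attr(eq, "converged")) &&
      max(abs(eq)) <= diverge_at
  }
  while (hi - lo > refine_tol) {
    mid <- (lo + hi) / 2
    if (exists_at(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## route a scan parameter to either the config (run condition) or the
## parameter list
set_scan_value <- function(parameter, value, params, config) {
  if (parameter %in% c("a", "p", "ps")) {
    config[[parameter]] <- value
  } else if (parameter %in% names(params)) {
    params[[parameter]] <- value
  } else stop("unknown parameter: ", parameter, call. = FALSE)
  list(params = params, config = config)
}

#' Two-parameter bifurcation scan
#'
#' For each value of `param2`, runs [scan_branch()] in `param1` and
#' collects the detected points into loci.
#'
#' @param param1,param2 parameter names as in [scan_branch()].
#' @param range1 scan range for `param1`.
#' @param values2 grid of values for `param2`.
#' @param steps continuation steps per slice.
#' @inheritParams scan_branch
#' @return A list of class `"ca_two_par"`: `loci` (tibble of all detected
#'   points with both parameter values and the slice's Hopf count) and
#'   `failed` (values of `param2` whose continuation failed).
#' @export
two_parameter_scan <- function(param1, range1, param2, values2,
                               steps = 80, config = model_config(),
                               params = model_params(), ...) {
  res <- list(); failed <- numeric(0)
  for (v2 in values2) {
    pc <- set_scan_value(param2, v2, params, config)
    br <- tryCatch(
      scan_branch(param1, range1, steps = steps, config = pc$config,
                  params = pc$params, ...),
      error = function(e) NULL)
    if (is.null(br)) { failed <- c(failed, v2); next }
    pts <- br$points
    if (nrow(pts)) {
      pts[[param2]] <- v2
      pts$n_hopf <- sum(pts$kind == "hopf")
      res[[length(res) + 1L]] <- pts
    }
  }
  loci <- if (length(res)) dplyr::bind_rows(res) else
    tibble::tibble(kind = character(), parameter = character(),
                   value = numeric())
  structure(list(loci = loci, failed = failed,
                 param1 = param1, param2 = param2),
            class = "ca_two_par")
}

#' @export
print.ca_branch <- function(x, ...) {
  cat("<ca_branch> parameter:", x$parameter, "over",
      nrow(x$branch), "equilibria\n")
  if (nrow(x$points)) {
    cat("bifurcation points:\n")
    print(x$points)
  } else cat("no bifurcation points detected\n")
  invisible(x)
}
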