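#' Model parameters with literature defaults
#'
#' Builds the full parameter set of the whole-cell calcium model: calcium
#' compartment constants (IP3-receptor density, RyR kinetics, SERCA, plasma
#' membrane pump, leak, amyloid-beta pore term), the six-state IP3-receptor
#' gating constants, the dynamic-IP3 (PLC) production/degradation constants,
#' and the membrane-potential constants (Kir, Hodgkin–Huxley Na/K/leak,
#' T-type calcium channel). Any subset can be overridden by name; unknown
#' names are an error so typos cannot silently revert to defaults.
#'
#' Units: concentrations in µM, time in s, voltages in mV. Fluxes are
#' µM/s. `gamma` is the (dimensionless) cytosolic-to-ER volume ratio. The
#' amyloid-beta level `a` is not a parameter here; it is part of
#' [model_config()] because it is varied per run.
#'
#' @param ... named parameter overrides, e.g. `model_params(k2 = 0.5)`.
#' @return A named list of class `"ab_params"`.
#' @examples
#' p <- model_params()
#' p$Vpm
#' model_params(kalpha = 1.0)$kalpha
#' @export
model_params <- function(...) {
  defaults <- list(
    ## calcium compartment ------------------------------------------------
    kf     = 0.98,    # IPR density rate (1/s)
    Jer    = 0,       # explicit ER leak (1/s); baseline leak is carried by k1
    gamma  = 5.4,     # cytosol/ER volume ratio
    alpha1 = 0.1,     # open-state weight in the IPR open probability
    alpha2 = 0.9,     # active-state weight
    ## RyR (calcium-induced calcium release)
    k1     = 0.013,   # zero-calcium leak rate (1/s)
    k2     = 0.18,    # maximal RyR rate (1/s)
    kd     = 0.13,    # CICR sensitivity (µM)
    kalpha = 0.75,    # amyloid-beta -> RyR sensitivity coupling
    nryr   = 3,       # Hill exponent of the CICR rate
    ## SERCA (bidirectional four-state reduction)
    K1 = 1e-4, K2 = 0.007, K3 = 0.06, K4 = 0.0014, K5 = 0.007,
    ## membrane leak / amyloid pore / plasma-membrane pump
    a1    = 0.003,    # basal leak (µM/s)
    a2    = 0.02,     # IP3-dependent leak slope (1/s)
    kbeta = 1,        # amyloid pore rate constant
    m     = 4,        # amyloid pore cooperativity
    Vpm   = 2.8,      # pump maximal velocity (µM/s)
    Kpm   = 0.425,    # pump sensitivity (µM); Hill coefficient 2
    ## six-state IPR gating (Sneyd–Dufour receptor kinetics) ---------------
    ipr_k1 = 0.64,  ipr_km1 = 0.04,
    ipr_k2 = 37.4,  ipr_km2 = 1.4,
    ipr_k3 = 0.11,  ipr_km3 = 29.8,
    ipr_k4 = 4,     ipr_km4 = 0.54,
    ipr_L1 = 0.12,  ipr_L3  = 0.025, ipr_L5 = 54.7,
    ipr_l2 = 1.7,   ipr_lm2 = 0.8,
    ipr_l4 = 1.7,   ipr_lm4 = 2.5,
    ipr_l6 = 4707,  ipr_lm6 = 11.4,
    ## dynamic IP3 (PLC production, 3K/5P degradation) ---------------------
    vPLC = 1.5,       # baseline maximal production (µM/s)
    kPLC = 1,         # baseline PLC sensitivity (µM)
    muPLC = 1,        # amyloid-beta -> production coupling
    kappaPLC = 1,     # amyloid-beta -> sensitivity coupling
    k3K = 0.5,        # phosphorylation rate (1/s)
    k5P = 0.25,       # dephosphorylation rate (1/s)
    K3K = 0.4,        # degradation half-saturation (µM)
    squared_sensitivity = TRUE,  # PLC sensitivity enters squared (canonical)
    ## membrane potential --------------------------------------------------
    Cm   = 1,         # capacitance
    gkir = 60,        # Kir conductance scale, used with kir_scale below
    kir_scale = 1e-3, # unit reconciliation pS -> HH conductance scale
    K0   = 2,         # extracellular K+ (mM), held constant
    Va1  = -14.83, Va2 = 34, Va3 = 19.23, Vka = -65.2,
    gna = 120, Vna = 50,       # HH sodium
    gk  = 36,  Vk  = -77,      # HH delayed rectifier (switchable)
    gl  = 0.3, Vl  = -54.4,    # HH leak
    include_ik = TRUE,
    gcaT = 0.45, Vca = 100     # T-type VGCC
  )
  override_params(defaults, list(...), "model_params")
}

## merge overrides into a default list, rejecting unknown names and
## non-finite or negative values for quantities that must be nonnegative
override_params <- function(defaults, overrides, what) {
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(!nzchar(nm)))
      stop(what, ": all overrides must be named", call. = FALSE)
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown))
      stop(what, ": unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    defaults[nm] <- overrides
  }
  validate_params(defaults)
  structure(defaults, class = "ab_params")
}

# every rate/sensitivity that must be >= 0 (signed quantities: voltages)
.nonneg_params <- c(
  "kf", "Jer", "gamma", "alpha1", "alpha2", "k1", "k2", "kd", "kalpha",
  "nryr", "K1", "K2", "K3", "K4", "K5", "a1", "a2", "kbeta", "m",
  "Vpm", "Kpm", "vPLC", "kPLC", "muPLC", "kappaPLC", "k3K", "k5P", "K3K",
  "Cm", "gkir", "kir_scale", "K0", "gna", "gk", "gl", "gcaT",
  "ipr_k1", "ipr_km1", "ipr_k2", "ipr_km2", "ipr_k3", "ipr_km3",
  "ipr_k4", "ipr_km4", "ipr_L1", "ipr_L3", "ipr_L5",
  "ipr_l2", "ipr_lm2", "ipr_l4", "ipr_lm4", "ipr_l6", "ipr_lm6"
)

validate_params <- function(p) {
  num <- p[!vapply(p, is.logical, logical(1))]
  bad <- names(num)[!vapply(num, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(bad))
    stop("parameters must be finite scalars: ", paste(bad, collapse = ", "),
         call. = FALSE)
  neg <- intersect(.nonneg_params, names(p))
  neg <- neg[vapply(neg, function(nm) p[[nm]] < 0, logical(1))]
  if (length(neg))
    stop("parameters must be nonnegative: ", paste(neg, collapse = ", "),
         call. = FALSE)
  if (p$gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (p$nryr < 1 || p$m < 1) stop("nryr and m must be >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.ab_params <- function(x, ...) {
  cat("<ab_params> whole-cell calcium model parameters\n")
  nm <- names(x)
  val <- vapply(x, function(v) format(v, digits = 6), character(1))
  cat(paste0("  ", format(nm, width = max(nchar(nm))), " = ", val),
      sep = "\n")
  invisible(x)
}

#' Run configuration for the calcium model
#'
#' Selects one of the three studied model variants and the environmental
#' conditions of a run: constant IP3 with no membrane
#' (`variant = "constant_ip3"`, the default), dynamic IP3 production
#' (`"dynamic_ip3"`), or membrane-coupled (`"with_membrane"`, which requires
#' `ps > 0` so the voltage-gated calcium flux feeds back on cytosolic
#' calcium).
#'
#' @param variant one of `"constant_ip3"`, `"dynamic_ip3"`, `"with_membrane"`.
#' @param p fixed IP3 concentration (µM); used by `constant_ip3` and
#'   `with_membrane`, ignored (with a warning if non-default) by
#'   `dynamic_ip3`.
#' @param a amyloid-beta level (µM-scaled), constant over a run.
#' @param ps scaling of the voltage-gated calcium flux into the cytosol;
#'   `0` decouples the membrane entirely.
#' @param stimulus applied-current protocol from [stimulus_protocol()].
#' @param tmax simulation horizon (s).
#' @param dt output sampling step (s).
#' @param rtol,atol relative/absolute solver tolerances.
#' @param c0,ce0,p0 initial cytosolic calcium, ER calcium and IP3 (µM).
#' @return A list of class `"ab_config"`.
#' @examples
#' model_config(variant = "dynamic_ip3", a = 0.5, tmax = 200)
#' @export
model_config <- function(variant = c("constant_ip3", "dynamic_ip3",
                                     "with_membrane"),
                         p = 0, a = 0, ps = 0,
                         stimulus = stimulus_protocol(),
                         tmax = 300, dt = 0.05,
                         rtol = 1e-8, atol = 1e-10,
                         c0 = 0.05, ce0 = 10, p0 = 0.01) {
  variant <- match.arg(variant)
  if (a < 0) stop("a must be >= 0", call. = FALSE)
  if (ps < 0) stop("ps must be >= 0", call. = FALSE)
  # ps = 0 with the membrane present is allowed: the membrane is then
  # simulated but decoupled, which must reproduce the membrane-free trace
  if (variant != "with_membrane" && ps > 0)
    stop("ps > 0 requires variant = 'with_membrane'", call. = FALSE)
  if (variant == "dynamic_ip3" && !missing(p) && p != 0)
    warning("dynamic_ip3 ignores the fixed IP3 level `p`")
  structure(list(variant = variant, p = p, a = a, ps = ps,
                 stimulus = stimulus, tmax = tmax, dt = dt,
                 rtol = rtol, atol = atol,
                 c0 = c0, ce0 = ce0, p0 = p0),
            class = "ab_config")
}

#' Applied-current stimulus protocol
#'
#' A boxcar current pulse delivered to the membrane compartment: zero
#' current outside `[t_on, t_on + duration]`.
#'
#' @param amplitude pulse amplitude (current units of the membrane model).
#' @param t_on pulse onset time (s).
#' @param duration pulse length (s); `0` disables the stimulus.
#' @return A list of class `"ab_stimulus"`.
#' @export
stimulus_protocol <- function(amplitude = 0, t_on = 100, duration = 50) {
  if (duration < 0) stop("duration must be >= 0", call. = FALSE)
  structure(list(amplitude = amplitude, t_on = t_on, duration = duration),
            class = "ab_stimulus")
}

#' @export
print.ab_config <- function(x, ...) {
  cat("<ab_config> variant:", x$variant,
      " a =", x$a,
      if (x$variant == "constant_ip3" || x$variant == "with_membrane")
        paste(" p =", x$p),
      if (x$ps > 0) paste(" ps =", x$ps), "\n")
  if (x$stimulus$amplitude != 0)
    cat("  stimulus:", x$stimulus$amplitude, "units at t =",
        x$stimulus$t_on, "for", x$stimulus$duration, "s\n")
  cat("  horizon:", x$tmax, "s, output step", x$dt, "s\n")
  invisible(x)
}
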