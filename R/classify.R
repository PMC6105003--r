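#' Classify a calcium trace
#'
#' Operational taxonomy of simulated (or measured) cytosolic calcium
#' traces into four signal classes:
#'
#' * `steady` — after the transient, the trace stays within `eps_ss` of
#'   constant.
#' * `periodic` — single-mode oscillation: one peak-amplitude class and a
#'   high periodicity score.
#' * `mmo` — mixed-mode oscillation: at least two amplitude classes
#'   (large spikes interleaved with sub-threshold oscillations) whose
#'   cycle composition repeats (periodicity score at or above `theta`).
#' * `aberrant` — sustained non-periodic oscillation over the analysis
#'   window: five or more peaks whose amplitude/interval sequence does
#'   not repeat (score below `theta`).
#'
#' The pipeline: (i) drop the transient (first `transient_frac` of the
#' trace, or up to `transient_time` if given); (ii) detect peaks with
#' prominence at least `eps_peak`; (iii) cluster peak amplitudes by a
#' deterministic 1-D largest-gap split (gap threshold `delta_amp` as a
#' fraction of the overall amplitude); (iv) score periodicity as the
#' maximal nonzero-lag normalised autocorrelation of the joint
#' peak-amplitude / peak-interval sequence; (v) label per the rules
#' above. The classification is invariant under uniform amplitude
#' rescaling and time shifts.
#'
#' @param trace a data frame with columns `t` (uniformly sampled, s) and
#'   `c` (µM), e.g. a [simulate_model()] result, or any trace read from
#'   CSV.
#' @param transient_frac fraction of the trace discarded as transient.
#' @param transient_time optional absolute transient cutoff (s),
#'   overriding `transient_frac`.
#' @param eps_ss steady-state amplitude threshold (µM).
#' @param eps_peak minimal peak prominence, as an absolute value (µM).
#' @param delta_amp amplitude-class gap threshold (fraction of the
#'   post-transient amplitude).
#' @param theta periodicity-score threshold separating regular from
#'   aberrant oscillation.
#' @param min_window minimal post-transient duration (s) required.
#' @param smooth_window moving-average pre-filter width (s) applied
#'   before peak detection; suppresses sample-to-sample measurement
#'   noise without disturbing second-scale calcium peaks. `0` disables.
#' @return A list of class `"ca_classification"`: `label`, `n_peaks`,
#'   `n_amplitude_classes`, `periodicity_score`, `period` (s, `NA` when
#'   not oscillatory), `amplitude`, `transient_cutoff`, and `peaks`
#'   (tibble of peak times, values and prominences).
#' @examples
#' tt <- seq(0, 300, by = 0.05)
#' tr <- data.frame(t = tt, c = 0.3 + 0.2 * sin(2 * pi * tt / 10))
#' classify_trace(tr)$label
#' @export
classify_trace <- function(trace, transient_frac = 0.4,
                           transient_time = NULL, eps_ss = 0.005,
                           eps_peak = 0.01, delta_amp = 0.2,
                           theta = 0.9, min_window = 100,
                           smooth_window = 0.5) {
  stopifnot(is.data.frame(trace), all(c("t", "c") %in% names(trace)))
  tt <- trace$t; cc <- trace$c
  if (length(tt) < 10) stop("trace too short to classify", call. = FALSE)
  dt <- diff(tt)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("trace must be uniformly sampled", call. = FALSE)
  k <- 1L
  if (smooth_window > 0) {
    k <- max(1L, round(smooth_window / stats::median(dt)))
    if (k > 1) {
      k <- k + (k %% 2 == 0)  # odd width keeps peaks centred
      sm <- stats::filter(cc, rep(1 / k, k), sides = 2)
      cc <- ifelse(is.na(sm), cc, as.numeric(sm))
    }
  }
  # robust sample-to-sample noise estimate (differences kill the smooth
  # signal; the median absolute deviation resists genuine spikes); after
  # k-point averaging the surviving noise is sigma/sqrt(k), and its
  # excursions must stay below the peak-prominence threshold
  sigma_noise <- stats::mad(diff(trace$c)) / sqrt(2)
  eps_peak_eff <- max(eps_peak, 8 * sigma_noise / sqrt(k))

  cutoff <- if (!is.null(transient_time)) tt[1] + transient_time
            else tt[1] + transient_frac * (tt[length(tt)] - tt[1])
  keep <- tt >= cutoff
  if ((tt[length(tt)] - cutoff) < min_window)
    stop("post-transient window shorter than ", min_window,
         " s; simulate longer or lower the transient cutoff",
         call. = FALSE)
  tw <- tt[keep]; cw <- cc[keep]
  amp <- max(cw) - min(cw)

  out <- list(transient_cutoff = cutoff, amplitude = amp,
              n_peaks = 0L, n_amplitude_classes = 0L,
              periodicity_score = NA_real_, period = NA_real_,
              peaks = tibble::tibble(t = numeric(), c = numeric(),
                                     prominence = numeric()))
  if (amp < eps_ss) {
    out$label <- "steady"
    return(structure(out, class = "ca_classification"))
  }

  pk <- find_peaks(tw, cw, min_prominence = eps_peak_eff)
  out$peaks <- pk
  out$n_peaks <- nrow(pk)
  if (nrow(pk) < 2) {
    # a drifting but peak-free window: treat as (slowly) steady
    out$label <- "steady"
    return(structure(out, class = "ca_classification"))
  }

  classes <- cluster_amplitudes(pk$c, gap = delta_amp * amp)
  out$n_amplitude_classes <- max(classes)
  score <- periodicity_score(pk$c, diff(pk$t), classes)
  out$periodicity_score <- score$score
  out$period <- estimate_period(pk, classes, score$lag)

  out$label <-
    if (out$n_amplitude_classes >= 2 && score$score >= theta) "mmo"
    else if (out$n_amplitude_classes == 1 && score$score >= theta) "periodic"
    else if (nrow(pk) >= 5) "aberrant"
    else "periodic"  # few, regular-ish peaks: not sustained aberrance
  structure(out, class = "ca_classification")
}

#' Peak detection with prominence
#'
#' Local maxima whose prominence (height above the higher of the two
#' deepest flanking valleys, bounded by the nearer higher peak) reaches
#' `min_prominence`.
#'
#' @param t,x time and signal vectors of equal length.
#' @param min_prominence minimal prominence in signal units.
#' @return A tibble with columns `t`, `c` (peak value) and `prominence`.
#' @export
find_peaks <- function(t, x, min_prominence = 0) {
  n <- length(x)
  i_max <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(i_max))
    return(tibble::tibble(t = numeric(), c = numeric(),
                          prominence = numeric()))
  prom <- vapply(i_max, function(i) {
    # walk left/right until a higher point; prominence is peak minus the
    # higher of the two interval minima
    left <- x[seq_len(i - 1L)]
    hi_l <- which(left > x[i])
    lmin <- min(x[(if (length(hi_l)) max(hi_l) else 1L):i])
    right <- x[(i + 1L):n]
    hi_r <- which(right > x[i])
    rmin <- min(x[i:(i + (if (length(hi_r)) min(hi_r) else n - i))])
    x[i] - max(lmin, rmin)
  }, numeric(1))
  sel <- prom >= min_prominence
  idx <- i_max[sel]
  # sub-sample peak times by a parabola through the three top samples;
  # otherwise grid quantisation injects artificial interval jitter
  tp <- vapply(idx, function(i) {
    if (i <= 1L || i >= n) return(t[i])
    dx <- (x[i - 1L] - x[i + 1L]) / 2
    d2 <- x[i - 1L] - 2 * x[i] + x[i + 1L]
    if (d2 >= 0) return(t[i])
    t[i] + (t[2] - t[1]) * max(-0.5, min(0.5, dx / d2))
  }, numeric(1))
  tibble::tibble(t = tp, c = x[idx], prominence = prom[sel])
}

#' Deterministic 1-D amplitude clustering
#'
#' Sorts the values and opens a new class at every gap larger than
#' `gap`. No random initialisation, so results are reproducible
#' bit-for-bit.
#'
#' @param x numeric vector (peak amplitudes).
#' @param gap absolute gap threshold.
#' @return Integer class labels (1 = smallest-amplitude class), same
#'   order as `x`.
#' @export
cluster_amplitudes <- function(x, gap) {
  if (!length(x)) return(integer(0))
  o <- order(x)
  xs <- x[o]
  cls <- cumsum(c(1, diff(xs) > gap))
  out <- integer(length(x))
  out[o] <- cls
  out
}

#' Periodicity score of a peak sequence
#'
#' Joint normalised autocorrelation, maximised over nonzero lags, of the
#' standardised peak-amplitude and peak-interval sequences. A perfectly
#' repeating cycle (of any composition) scores 1; an irregular sequence
#' scores near 0. Zero-variance components (e.g. constant amplitudes of
#' a single-mode oscillation) count as perfectly correlated at every
#' lag.
#'
#' @param amps peak amplitudes.
#' @param intervals inter-peak intervals (length `length(amps) - 1`).
#' @param classes optional amplitude-class labels (unused in the score
#'   but reserved for symbol-sequence variants).
#' @return A list with `score` in `[0, 1]` and the maximising `lag`.
#' @export
periodicity_score <- function(amps, intervals, classes = NULL) {
  n <- length(amps)
  if (n < 3) return(list(score = 1, lag = 1L))
  max_lag <- max(1L, floor((n - 1) / 2))
  comp_cor <- function(x, l) {
    m <- length(x)
    if (m - l < 2) return(NA_real_)
    a <- x[1:(m - l)]; b <- x[(l + 1):m]
    # an effectively constant sequence (CV under 2%) is perfectly
    # periodic at every lag; without this floor, residual numerical
    # jitter would be standardised up into white noise
    if (stats::sd(x) < 0.02 * (abs(mean(x)) + 1e-12)) return(1)
    v <- stats::var(x)  # normalise by full-series variance, acf-style
    mean((a - mean(x)) * (b - mean(x))) / v
  }
  best <- -Inf; best_lag <- 1L
  for (l in seq_len(max_lag)) {
    r <- mean(c(comp_cor(amps, l), comp_cor(intervals, l)), na.rm = TRUE)
    if (is.finite(r) && r > best) { best <- r; best_lag <- l }
  }
  list(score = min(max(best, 0), 1), lag = best_lag)
}

## period from the maximising lag: mean time between same-phase peaks;
## for a single class at lag 1 this is the mean inter-peak interval
estimate_period <- function(pk, classes, lag) {
  tpk <- pk$t
  if (length(tpk) <= lag) return(NA_real_)
  mean(tpk[(lag + 1):length(tpk)] - tpk[1:(length(tpk) - lag)])
}

#' @export
print.ca_classification <- function(x, ...) {
  cat("<ca_classification>", x$label,
      "| peaks:", x$n_peaks,
      "| amplitude classes:", x$n_amplitude_classes,
      "| periodicity:", format(x$periodicity_score, digits = 4),
      "| period:", format(x$period, digits = 5), "s\n")
  invisible(x)
}

#' Classify the model over a parameter grid
#'
#' Simulates and classifies the model at every combination of the
#' supplied parameter values.
#'
#' @param grid a named list of parameter values, e.g.
#'   `list(p = c(5, 20, 26))`; names as in [scan_branch()].
#' @param config,params base configuration and parameters.
#' @param tmax simulation horizon per grid point (s).
#' @param ... forwarded to [classify_trace()].
#' @return A tibble with one row per grid point: the parameter columns,
#'   `label`, `n_peaks`, `n_amplitude_classes`, `periodicity_score`,
#'   `period`, `amplitude`. Failed simulations get label `"unresolved"`.
#' @export
classify_parameter_grid <- function(grid, config = model_config(),
                                    params = model_params(),
                                    tmax = 500, ...) {
  stopifnot(is.list(grid), !is.null(names(grid)))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  dots <- list(...)
  res <- purrr::pmap(combos, function(...) {
    vals <- list(...)
    pc <- list(params = params, config = config)
    for (nm in names(vals))
      pc <- set_scan_value(nm, vals[[nm]], pc$params, pc$config)
    pc$config$tmax <- tmax
    cl <- tryCatch({
      tr <- simulate_model(pc$config, pc$params)
      do.call(classify_trace, c(list(tr), dots))
    }, error = function(e) NULL)
    if (is.null(cl))
      return(tibble::tibble(label = "unresolved", n_peaks = NA_integer_,
                            n_amplitude_classes = NA_integer_,
                            periodicity_score = NA_real_,
                            period = NA_real_, amplitude = NA_real_))
    tibble::tibble(label = cl$label, n_peaks = cl$n_peaks,
                   n_amplitude_classes = cl$n_amplitude_classes,
                   periodicity_score = cl$periodicity_score,
                   period = cl$period, amplitude = cl$amplitude)
  })
  dplyr::bind_cols(tibble::as_tibble(combos), dplyr::bind_rows(res))
}
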