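#' Synthetic calcium-like waveforms with known labels
#'
#' Ground-truth test signals for the trace classifier, built as sums of
#' Gaussian spikes on a baseline. `make_periodic_wave()` repeats a single
#' spike amplitude at a fixed interval; `make_mmo_wave()` repeats a cycle
#' `composition` of large and small spikes (e.g. `c(1, 0.25, 0.25)` for
#' one large followed by two sub-threshold peaks); `make_aberrant_wave()`
#' draws amplitudes and jittered intervals at random so the cycle
#' composition never repeats. Gaussian measurement noise can be added
#' with `noise_sd`.
#'
#' @param tmax duration (s).
#' @param dt sampling step (s).
#' @param interval inter-spike interval (s).
#' @param amplitude spike amplitude (µM).
#' @param composition per-cycle relative spike amplitudes.
#' @param baseline resting level (µM).
#' @param width spike width (s).
#' @param noise_sd additive Gaussian noise standard deviation (µM).
#' @param jitter aberrant-wave relative interval jitter.
#' @param amp_levels aberrant-wave relative amplitude levels sampled at
#'   random.
#' @return A tibble with columns `t` and `c` and attribute `label`.
#' @examples
#' w <- make_mmo_wave(composition = c(1, 0.25, 0.25))
#' classify_trace(w)$label
#' @name synthetic_waves
NULL

wave_from_spikes <- function(times, amps, tmax, dt, baseline, width,
                             noise_sd) {
  tt <- seq(0, tmax, by = dt)
  x <- rep(baseline, length(tt))
  for (i in seq_along(times))
    x <- x + amps[i] * exp(-(tt - times[i])^2 / (2 * width^2))
  if (noise_sd > 0) x <- x + stats::rnorm(length(tt), sd = noise_sd)
  tibble::tibble(t = tt, c = x)
}

#' @rdname synthetic_waves
#' @export
make_periodic_wave <- function(tmax = 400, dt = 0.05, interval = 12,
                               amplitude = 0.6, baseline = 0.05,
                               width = 1, noise_sd = 0) {
  times <- seq(interval / 2, tmax, by = interval)
  w <- wave_from_spikes(times, rep(amplitude, length(times)), tmax, dt,
                        baseline, width, noise_sd)
  structure(w, label = "periodic")
}

#' @rdname synthetic_waves
#' @export
make_mmo_wave <- function(tmax = 400, dt = 0.05, interval = 12,
                          composition = c(1, 0.25, 0.25, 0.25),
                          amplitude = 0.6, baseline = 0.05, width = 1,
                          noise_sd = 0) {
  times <- seq(interval / 2, tmax, by = interval)
  amps <- amplitude * rep_len(composition, length(times))
  w <- wave_from_spikes(times, amps, tmax, dt, baseline, width, noise_sd)
  structure(w, label = "mmo")
}

#' @rdname synthetic_waves
#' @export
make_aberrant_wave <- function(tmax = 400, dt = 0.05, interval = 12,
                               amplitude = 0.6, baseline = 0.05,
                               width = 1, jitter = 0.35,
                               amp_levels = c(1, 0.25), noise_sd = 0) {
  times <- numeric(0)
  tcur <- interval / 2
  while (tcur < tmax) {
    times <- c(times, tcur)
    tcur <- tcur + interval * (1 + stats::runif(1, -jitter, jitter))
  }
  amps <- amplitude * sample(amp_levels, length(times), replace = TRUE)
  w <- wave_from_spikes(times, amps, tmax, dt, baseline, width, noise_sd)
  structure(w, label = "aberrant")
}

#' @rdname synthetic_waves
#' @export
make_steady_wave <- function(tmax = 400, dt = 0.05, baseline = 0.05,
                             noise_sd = 0) {
  w <- wave_from_spikes(numeric(0), numeric(0), tmax, dt, baseline, 0.1,
                        noise_sd)
  structure(w, label = "steady")
}
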