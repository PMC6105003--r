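test_that("constant and sinusoidal traces get the obvious labels", {
  tt <- seq(0, 400, by = 0.05)
  expect_equal(classify_trace(data.frame(t = tt, c = 0.07))$label, "steady")
  sin_tr <- data.frame(t = tt, c = 0.3 + 0.5 * sin(2 * pi * tt / 10))
  cl <- classify_trace(sin_tr)
  expect_equal(cl$label, "periodic")
  expect_equal(cl$n_amplitude_classes, 1)
  expect_equal(cl$period, 10, tolerance = 0.02)
})

test_that("repeating large/small compositions are MMO; shuffled ones aberrant", {
  w <- make_mmo_wave(composition = c(1, 0.25, 0.25, 0.25))
  cl <- classify_trace(w)
  expect_equal(cl$label, "mmo")
  expect_equal(cl$n_amplitude_classes, 2)
  expect_gte(cl$periodicity_score, 0.9)
  set.seed(7)
  a <- make_aberrant_wave()
  cla <- classify_trace(a)
  expect_equal(cla$label, "aberrant")
  expect_gte(cla$n_peaks, 5)
  expect_lt(cla$periodicity_score, 0.9)
})

test_that("classification is invariant to amplitude rescaling and time shifts", {
  w <- make_mmo_wave(composition = c(1, 0.3))
  base <- classify_trace(w)
  scaled <- w; scaled$c <- 3.7 * scaled$c
  shifted <- w; shifted$t <- shifted$t + 123.4
  for (v in list(scaled, shifted)) {
    cl <- classify_trace(v)
    expect_equal(cl$label, base$label)
    expect_equal(cl$n_amplitude_classes, base$n_amplitude_classes)
    expect_equal(cl$periodicity_score, base$periodicity_score,
                 tolerance = 1e-6)
  }
})

test_that("noiseless synthetic waveforms classify perfectly; 1% noise degrades gracefully", {
  set.seed(11)
  noiseless <- list(make_periodic_wave(),
                    make_mmo_wave(composition = c(1, 0.25, 0.25)),
                    make_mmo_wave(composition = c(1, 0.3)),
                    make_aberrant_wave(),
                    make_steady_wave())
  for (w in noiseless)
    expect_equal(classify_trace(w)$label, attr(w, "label"))

  # 1% of the 0.6 µM spike amplitude as additive noise
  set.seed(12)
  noisy <- c(
    replicate(8, make_periodic_wave(noise_sd = 0.006), simplify = FALSE),
    replicate(8, make_mmo_wave(composition = c(1, 0.25, 0.25),
                               noise_sd = 0.006), simplify = FALSE),
    replicate(8, make_aberrant_wave(noise_sd = 0.006), simplify = FALSE))
  hits <- vapply(noisy, function(w)
    classify_trace(w)$label == attr(w, "label"), logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("peak detection reports prominences, not just local maxima", {
  tt <- seq(0, 100, by = 0.05)
  x <- 0.5 * exp(-(tt - 25)^2 / 2) + 0.1 * exp(-(tt - 50)^2 / 2) +
    0.5 * exp(-(tt - 75)^2 / 2)
  pk <- find_peaks(tt, x, min_prominence = 0.3)
  expect_equal(nrow(pk), 2)  # the 0.1 bump is below the cutoff
  pk_all <- find_peaks(tt, x, min_prominence = 0.05)
  expect_equal(nrow(pk_all), 3)
  expect_equal(pk_all$t[2], 50, tolerance = 0.1)
})

test_that("gap clustering is deterministic and order-preserving", {
  x <- c(0.6, 0.15, 0.62, 0.14, 0.61, 0.16)
  cls <- cluster_amplitudes(x, gap = 0.2)
  expect_equal(max(cls), 2)
  expect_equal(cls, c(2, 1, 2, 1, 2, 1))
  expect_equal(cluster_amplitudes(x, gap = 0.9), rep(1L, 6))
})

test_that("under-sampled or short traces are rejected with guidance", {
  expect_error(classify_trace(data.frame(t = 1:5, c = 1:5)), "too short")
  tt <- seq(0, 50, by = 0.05)
  expect_error(classify_trace(data.frame(t = tt, c = sin(tt))),
               "window")
  irr <- data.frame(t = cumsum(runif(2000)), c = 1)
  expect_error(classify_trace(irr), "uniform")
})

test_that("grid classification labels the mixed-mode window at a = 0", {
  # around the upper Hopf of the a = 0 branch: single-mode below,
  # mixed-mode near p = 18.5
  res <- classify_parameter_grid(list(p = c(10, 18.5)),
                                 config = model_config(), tmax = 400)
  expect_equal(res$label[res$p == 10], "periodic")
  expect_equal(res$label[res$p == 18.5], "mmo")
})
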