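pr <- model_params()

test_that("membrane currents vanish at their reversal points", {
  expect_equal(i_kir(pr$Vka + pr$Va1, pr), 0)  # V = -80.03
  expect_equal(i_caT(pr$Vca, 0.5, 0.5, pr), 0)
  expect_equal(i_caT(-65, 0.3, 0, pr), 0)      # fully inactivated
  # direct arithmetic oracle at V = -65
  V <- -65
  gate <- pr$K0 / (1 + exp((V - pr$Vka - pr$Va2) / pr$Va3))
  expect_equal(i_kir(V, pr),
               -pr$gkir * pr$kir_scale * gate * (V - pr$Vka - pr$Va1))
  expect_equal(i_caT(V, 0.29, 0.01, pr),
               pr$gcaT * 0.29^2 * 0.01 * (V - pr$Vca))
})

test_that("Kir rectifies: the conductance gate closes at high voltage", {
  expect_lt(abs(i_kir(200, pr)), abs(i_kir(-60, pr)))
  expect_equal(i_kir(1e4, pr), 0, tolerance = 1e-8)
})

test_that("voltage-gated calcium flux scales linearly with ps", {
  expect_equal(j_vca(-30, 0.4, 0.3, 0, pr), 0)
  expect_equal(j_vca(pr$Vca, 0.4, 0.3, 1, pr), 0)
  one <- j_vca(-30, 0.4, 0.3, 1, pr)
  expect_gt(one, 0)  # inward calcium below the Nernst potential
  expect_equal(j_vca(-30, 0.4, 0.3, 2, pr), 2 * one)
})

test_that("with zero conductances and no stimulus the voltage is frozen", {
  pr0 <- model_params(gkir = 0, gna = 0, gk = 0, gl = 0, gcaT = 0)
  d <- membrane_derivatives(c(V = -50, m = 0.1, h = 0.5, n = 0.3,
                              mcaT = 0.2, hcaT = 0.1), 0, pr0)
  expect_equal(d[["V"]], 0)
})

test_that("unstimulated membrane rests near -65 mV and is stable", {
  y0 <- c(V = -65, m = 0.05, h = 0.6, n = 0.32, mcaT = 0.29, hcaT = 0.01)
  sol <- deSolve::ode(y = y0, times = seq(0, 3, by = 0.001),
                      func = function(t, y, parms)
                        list(membrane_derivatives(y, t, pr)),
                      parms = NULL, rtol = 1e-8, atol = 1e-10)
  V_end <- sol[nrow(sol), "V"]
  expect_lt(abs(V_end - (-65)), 5)
  gates <- sol[, c("m", "h", "n", "mcaT", "hcaT")]
  expect_true(all(gates >= -1e-9 & gates <= 1 + 1e-9))
  # linear stability at the rest point
  rest <- sol[nrow(sol), -1]
  J <- jacobian_fd(function(y) membrane_derivatives(y, 0, pr), rest)
  expect_lt(max(Re(eigen(J, only.values = TRUE)$values)), 0)
})

test_that("a sustained strong pulse drives a saturating depolarised plateau", {
  y0 <- c(V = -65, m = 0.05, h = 0.6, n = 0.32, mcaT = 0.29, hcaT = 0.01)
  stim <- stimulus_protocol(amplitude = 300, t_on = 1, duration = 19)
  sol <- deSolve::ode(y = y0, times = seq(0, 20, by = 0.002),
                      func = function(t, y, parms)
                        list(membrane_derivatives(y, t, pr, stim)),
                      parms = NULL, rtol = 1e-8, atol = 1e-10)
  late <- sol[sol[, 1] > 15, "V"]
  expect_gt(mean(late), -50)          # depolarised well above rest
  expect_lt(stats::sd(late), 0.5)     # saturated, not oscillating
})

test_that("boxcar stimulus switches on and off at the pulse edges", {
  stim <- stimulus_protocol(amplitude = 300, t_on = 100, duration = 50)
  expect_equal(applied_current(c(0, 99.9, 100, 125, 149.9, 150, 200), stim),
               c(0, 0, 300, 300, 300, 0, 0))
})
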