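pr <- model_params()

test_that("derived time constant and kinase fraction follow the rates", {
  te <- ip3_tau_eta(pr)
  expect_equal(te$tau_p, 4 / 3)
  expect_equal(te$eta, 2 / 3)
  te2 <- ip3_tau_eta(model_params(k3K = 1, k5P = 1))
  expect_equal(te2$tau_p, 0.5)
  expect_equal(te2$eta, 0.5)
})

test_that("IP3 decays without calcium and saturates with it", {
  te <- ip3_tau_eta(pr)
  # pure 5-phosphatase decay at c = 0
  for (p in c(0.01, 0.5, 2))
    expect_equal(ip3_derivative(p, 0, 0, pr),
                 -(1 - te$eta) * p / te$tau_p)
  # saturated production at large c and p = 0
  expect_equal(ip3_derivative(0, 1e5, 0, pr), pr$vPLC / te$tau_p,
               tolerance = 1e-6)
})

test_that("with frozen calcium, p relaxes to the unique fixed point", {
  for (cc in c(0.05, 0.3, 1)) {
    pstar <- abcalcium:::ip3_fixed_point(cc, 0, pr)
    expect_equal(ip3_derivative(pstar, cc, 0, pr), 0, tolerance = 1e-12)
    sol <- deSolve::ode(y = c(p = 2), times = c(0, 100),
                        func = function(t, y, parms)
                          list(ip3_derivative(y, cc, 0, pr)),
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
    expect_equal(sol[nrow(sol), "p"], c(p = pstar), tolerance = 1e-6)
  }
})

test_that("amyloid-beta coupling can be switched off", {
  pr0 <- model_params(muPLC = 0, kappaPLC = 0)
  for (a in c(0, 0.5, 1.2))
    expect_equal(ip3_derivative(0.4, 0.3, a, pr0),
                 ip3_derivative(0.4, 0.3, 0, pr0))
})

test_that("the PLC sensitivity denominator variant acts as documented", {
  prS <- model_params(squared_sensitivity = TRUE)
  prL <- model_params(squared_sensitivity = FALSE)
  a <- 0.5; cc <- 0.3
  Kplc <- prS$kPLC + prS$kappaPLC * a
  Vplc <- prS$vPLC + prS$muPLC * a
  te <- ip3_tau_eta(prS)
  prodS <- Vplc * cc^2 / (Kplc^2 + cc^2)
  prodL <- Vplc * cc^2 / (Kplc + cc^2)
  expect_equal(ip3_derivative(0, cc, a, prS), prodS / te$tau_p)
  expect_equal(ip3_derivative(0, cc, a, prL), prodL / te$tau_p)
  # at the default kPLC = 1 and a = 0 the two variants coincide
  expect_equal(ip3_derivative(0.2, cc, 0, prS),
               ip3_derivative(0.2, cc, 0, prL))
})
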