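pr <- model_params()

test_that("state layout matches the configured variant", {
  expect_equal(state_layout(model_config()),
               c("c", "ce", "R", "O", "A", "I1", "I2"))
  expect_equal(length(state_layout(model_config(variant = "dynamic_ip3"))), 8)
  expect_equal(length(state_layout(
    model_config(variant = "with_membrane", ps = 1))), 13)
  y <- initial_state(model_config(variant = "dynamic_ip3"))
  expect_equal(y[["c"]], 0.05)
  expect_equal(y[["ce"]], 10)
  expect_equal(y[["R"]], 1)
  expect_equal(y[["p"]], 0.01)
})

test_that("ER exchange is antisymmetric: total cell calcium only moves across the plasma membrane", {
  # d(c + ce/gamma)/dt = J_in - J_pm + J_vca exactly, term by term
  set.seed(42)
  for (variant in c("constant_ip3", "dynamic_ip3")) {
    cfg <- if (variant == "dynamic_ip3")
      model_config(variant = variant, a = 0.7)
    else model_config(p = 8, a = 0.3)
    for (i in 1:20) {
      y <- initial_state(cfg)
      y[["c"]] <- runif(1, 0.01, 2)
      y[["ce"]] <- runif(1, 0.5, 40)
      occ <- runif(5); occ <- occ / sum(occ) * runif(1, 0.2, 1)
      y[c("R", "O", "A", "I1", "I2")] <- occ
      if (variant == "dynamic_ip3") y[["p"]] <- runif(1, 0, 3)
      dy <- cell_rhs(0, y, pr, cfg)
      fl <- flux_breakdown(y, 0, pr, cfg)
      lhs <- dy[["c"]] + dy[["ce"]] / pr$gamma
      rhs <- fl$J_in - fl$J_pm + fl$J_vca
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  }
})

test_that("the assembled rhs equals the sum of the unit-tested fluxes", {
  cfg <- model_config(p = 10, a = 0.25)
  y <- initial_state(cfg)
  dy <- cell_rhs(0, y, pr, cfg)
  fl <- flux_breakdown(y, 0, pr, cfg)
  expect_equal(dy[["c"]],
               fl$J_IPR + fl$J_RyR - fl$J_SERCA + fl$J_in - fl$J_pm)
  expect_equal(dy[["ce"]],
               -pr$gamma * (fl$J_IPR + fl$J_RyR - fl$J_SERCA))
})

test_that("non-finite states abort with the offending term identified", {
  cfg <- model_config()
  y <- initial_state(cfg)
  y[["ce"]] <- Inf
  expect_error(cell_rhs(0, y, pr, cfg), "non-finite flux")
})

test_that("the resting model settles to a physiological low calcium state", {
  # the resting equilibrium itself sits at a physiological basal level
  cfg <- model_config(p = 0, a = 0)
  eq <- find_steady_state(cfg, pr)
  expect_gt(eq[["c"]], 0.01)
  expect_lt(eq[["c"]], 0.2)
  # the trajectory approaches it (the ER fills on a ~1000 s timescale,
  # so only proximity is asserted on a finite horizon)
  tr <- simulate_model(model_config(p = 0, a = 0, tmax = 2000, dt = 1), pr)
  expect_lt(abs(tail(tr$c, 1) - eq[["c"]]) / eq[["c"]], 0.2)
  expect_true(all(tail(tr$c, 500) > 0.005 & tail(tr$c, 500) < 0.2))
})

test_that("receptor occupancies stay on the simplex along oscillating traces", {
  tr <- simulate_model(quick_config(p = 5))
  occ <- as.matrix(tr[, c("R", "O", "A", "I1", "I2", "S")])
  expect_true(all(occ > -1e-6 & occ < 1 + 1e-6))
  expect_lt(max(abs(rowSums(occ) - 1)), 1e-9)  # S closes the simplex
  expect_true(all(tr$c >= 0 & tr$ce >= 0))
})

test_that("halving solver tolerances leaves the trace unchanged to 1e-4", {
  trA <- simulate_model(model_config(p = 5, tmax = 50))
  trB <- simulate_model(model_config(p = 5, tmax = 50,
                                     rtol = 5e-9, atol = 5e-11))
  expect_lt(max(abs(trA$c - trB$c)) / max(trA$c), 1e-4)
})

test_that("oscillation frequency increases from p = 5 to p = 10", {
  tr5 <- simulate_model(model_config(p = 5, tmax = 200))
  tr10 <- simulate_model(model_config(p = 10, tmax = 200))
  n5 <- nrow(classify_trace(tr5, min_window = 80)$peaks)
  n10 <- nrow(classify_trace(tr10, min_window = 80)$peaks)
  expect_gt(n10, n5)
})

test_that("a decoupled membrane (ps = 0) reproduces the membrane-free trace", {
  trM <- simulate_model(model_config(variant = "with_membrane", p = 5,
                                     ps = 0, tmax = 60))
  trC <- simulate_model(model_config(p = 5, tmax = 60))
  expect_lt(max(abs(trM$c - trC$c)), 1e-4)
})

test_that("stimulus edges are honoured without crossing an adaptive step", {
  stim <- stimulus_protocol(amplitude = 300, t_on = 10, duration = 5)
  cfg <- model_config(variant = "with_membrane", p = 5, ps = 1,
                      stimulus = stim, tmax = 30, dt = 0.05)
  tr <- simulate_model(cfg, pr)
  expect_equal(nrow(tr), length(seq(0, 30, by = 0.05)))
  # depolarisation during the pulse, recovery after
  expect_gt(max(tr$V[tr$t > 10 & tr$t < 15]), -50)
  expect_lt(tail(tr$V, 1), -55)
})
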