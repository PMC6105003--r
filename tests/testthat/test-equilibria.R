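pr <- model_params()

test_that("finite-difference Jacobian is exact on a known linear system", {
  A <- matrix(c(-2, 1, 0.5, -3), 2, 2)
  J <- jacobian_fd(function(y) as.numeric(A %*% y), c(x = 1, y = 2))
  expect_equal(unname(J), A, tolerance = 1e-8)
})

test_that("analytic and finite-difference Jacobians of the model agree", {
  for (variant in c("constant_ip3", "dynamic_ip3")) {
    cfg <- if (variant == "dynamic_ip3")
      model_config(variant = variant, a = 0.5)
    else model_config(p = 5, a = 0.3)
    y <- initial_state(cfg)
    y[["c"]] <- 0.21; y[["ce"]] <- 7.3
    y[c("R", "O", "A", "I1", "I2")] <- c(0.2, 0.2, 0.3, 0.1, 0.1)
    Ja <- cell_jacobian(y, 0, pr, cfg)
    Jf <- jacobian_fd(function(u) cell_rhs(0, u, pr, cfg), y)
    expect_lt(max(abs(Ja - Jf)), 1e-5)
  }
})

test_that("steady state matches long-time integration at rest", {
  cfg <- model_config(p = 0, a = 0)
  eq <- find_steady_state(cfg, pr)
  expect_true(attr(eq, "converged"))
  expect_lt(attr(eq, "residual"), 1e-10)
  # the ER fills slowly (the slowest eigenmode has a ~1000 s timescale),
  # so the integration oracle is compared at 2%
  tr <- simulate_model(model_config(p = 0, a = 0, tmax = 4000, dt = 2), pr)
  expect_equal(tail(tr$c, 1), eq[["c"]], tolerance = 0.02)
  expect_equal(tail(tr$ce, 1), eq[["ce"]], tolerance = 0.02)
  # receptor occupancies at equilibrium equal the stationary distribution
  st <- ipr_stationary(eq[["c"]], 0, pr)
  expect_equal(unname(eq[c("R", "O", "A", "I1", "I2")]),
               unname(st[c("R", "O", "A", "I1", "I2")]), tolerance = 1e-8)
  # rest is linearly stable
  expect_lt(max(Re(eigenvalues_at(eq, cfg, pr))), 0)
})

test_that("equilibrium cytosolic calcium obeys the membrane flux balance", {
  # at any equilibrium J_in = J_pm, an algebraic identity of the model
  for (a in c(0, 0.5, 1)) {
    cfg <- model_config(p = 0, a = a)
    eq <- find_steady_state(cfg, pr)
    expect_equal(j_in(0, a, pr), j_pm(eq[["c"]], pr), tolerance = 1e-9)
  }
})

test_that("branch scan finds the Hopf bubble and divergence in a at p = 0", {
  br <- scan_branch("a", c(0, 1.32), steps = 40,
                    config = model_config(p = 0), params = pr,
                    refine_tol = 1e-3)
  hopfs <- br$points$value[br$points$kind == "hopf"]
  expect_equal(length(hopfs), 2)
  # the oscillatory window contains a = 1.15
  expect_lt(hopfs[1], 1.15)
  expect_gt(hopfs[2], 1.15)
  # branch diverges at the analytic flux-balance root (pump saturation)
  a_star <- (pr$Vpm - pr$a1)^(1 / pr$m)
  div <- br$points$value[br$points$kind == "divergence"]
  expect_equal(div, a_star, tolerance = 2e-3)
  # the analytic root upper-bounds every computed equilibrium value of a
  expect_true(all(br$branch$a < a_star))
})

test_that("a detected Hopf point carries a sign-change certificate", {
  br <- scan_branch("a", c(0.9, 1.2), steps = 20,
                    config = model_config(p = 0), params = pr,
                    refine_tol = 1e-4)
  h <- br$points$value[br$points$kind == "hopf"][1]
  re_at <- function(a) {
    cfg <- model_config(p = 0, a = a)
    max(Re(eigenvalues_at(find_steady_state(cfg, pr), cfg, pr)))
  }
  expect_lt(re_at(h - 1e-3) * re_at(h + 1e-3), 0)
})

test_that("halving the scan step moves detected points by < 1e-3", {
  b1 <- scan_branch("a", c(0.9, 1.2), steps = 15,
                    config = model_config(p = 0), refine_tol = 1e-4)
  b2 <- scan_branch("a", c(0.9, 1.2), steps = 30,
                    config = model_config(p = 0), refine_tol = 1e-4)
  h1 <- b1$points$value[b1$points$kind == "hopf"][1]
  h2 <- b2$points$value[b2$points$kind == "hopf"][1]
  expect_lt(abs(h1 - h2), 1e-3)
})

test_that("a one-slice two-parameter scan reduces to scan_branch", {
  two <- two_parameter_scan("a", c(0.9, 1.2), "p", 0, steps = 15,
                            config = model_config(p = 0),
                            refine_tol = 1e-3)
  one <- scan_branch("a", c(0.9, 1.2), steps = 15,
                     config = model_config(p = 0), refine_tol = 1e-3)
  expect_equal(two$loci$value, one$points$value, tolerance = 1e-6)
  expect_equal(two$loci$kind, one$points$kind)
})
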