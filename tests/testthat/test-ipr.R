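pr <- model_params()

test_that("open probability follows the fourth-power subunit rule", {
  expect_equal(open_probability(1, 0, pr), 0.1^4)
  expect_equal(open_probability(0, 1, pr), 0.9^4)
  expect_equal(open_probability(0, 0, pr), 0)
})

test_that("receptor cannot open from rest without IP3", {
  d <- ipr_derivatives(c(R = 1, O = 0, A = 0, I1 = 0, I2 = 0),
                       c = 0.1, p = 0, params = pr)
  expect_equal(d[["O"]], 0)
  expect_equal(d[["A"]], 0)
})

test_that("the generator conserves total occupancy", {
  for (cp in list(c(0.05, 10), c(0.3, 1), c(2, 0.1))) {
    Q <- ipr_rate_matrix(cp[1], cp[2], pr)
    expect_equal(max(abs(colSums(Q))), 0, tolerance = 1e-12)
  }
  # the five reduced derivatives match the full generator restricted to
  # the simplex (S eliminated by conservation)
  st <- c(R = 0.3, O = 0.2, A = 0.1, I1 = 0.15, I2 = 0.05)
  S <- 1 - sum(st)
  full <- ipr_rate_matrix(0.2, 3, pr) %*%
    c(st[["R"]], st[["O"]], st[["A"]], S, st[["I1"]], st[["I2"]])
  d <- ipr_derivatives(st, 0.2, 3, pr)
  expect_equal(unname(d), unname(full[c(1, 2, 3, 5, 6), 1]),
               tolerance = 1e-12)
})

test_that("stationary distribution agrees with two independent routes", {
  for (cp in list(c(0.05, 10), c(0.5, 2), c(1.5, 0.3))) {
    st <- ipr_stationary(cp[1], cp[2], pr)
    expect_equal(sum(st), 1, tolerance = 1e-10)
    expect_true(all(st >= 0 & st <= 1))
    # route 1: eigenvector of the generator for eigenvalue zero
    Q <- ipr_rate_matrix(cp[1], cp[2], pr)
    e <- eigen(Q)
    v <- Re(e$vectors[, which.min(abs(e$values))])
    v <- v / sum(v)
    expect_equal(unname(st), unname(v), tolerance = 1e-8)
    # route 2: long-time integration of the full six-state system
    lt <- integrate_ipr6(cp[1], cp[2], pr)
    expect_equal(unname(st[names(lt)]), unname(lt), tolerance = 1e-6)
  }
})

test_that("occupancies stay on the simplex along the six-state flow", {
  Q <- ipr_rate_matrix(0.05, 10, pr)
  sol <- deSolve::ode(y = c(R = 1, O = 0, A = 0, S = 0, I1 = 0, I2 = 0),
                      times = seq(0, 200, by = 0.5),
                      func = function(t, y, parms) list(as.numeric(Q %*% y)),
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  occ <- sol[, -1]
  expect_lt(max(abs(rowSums(occ) - 1)), 1e-8)
  expect_true(all(occ > -1e-9 & occ < 1 + 1e-9))
})
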