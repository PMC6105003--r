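pr <- model_params()

test_that("membrane leak j_in follows a1 + a2*p + kbeta*a^m", {
  expect_equal(j_in(p = 0, a = 0, params = pr), 0.003)
  expect_equal(j_in(p = 10, a = 0, params = pr), 0.003 + 0.02 * 10)
  expect_equal(j_in(p = 0, a = 1, params = pr), 0.003 + 1 * 1^4)
  # strictly increasing in both arguments
  ps <- seq(0, 20, by = 0.5)
  expect_true(all(diff(j_in(ps, 0.3, pr)) > 0))
  as <- seq(0.01, 2, by = 0.05)
  expect_true(all(diff(j_in(1, as, pr)) > 0))
  expect_error(j_in(-1, 0, pr), "nonnegative")
  expect_error(j_in(0, -0.1, pr), "nonnegative")
})

test_that("plasma-membrane pump is a Hill-2 function bounded by Vpm", {
  expect_equal(j_pm(0, pr), 0)
  expect_equal(j_pm(pr$Kpm, pr), pr$Vpm / 2)  # half-max at Kpm
  expect_equal(j_pm(1e6, pr), pr$Vpm, tolerance = 1e-9)
  cs <- seq(0, 10, by = 0.05)
  v <- j_pm(cs, pr)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v <= pr$Vpm))
  expect_error(j_pm(-0.01, pr), "nonnegative")
})

test_that("SERCA flux is bidirectional with reversal at c = K1*ce", {
  expect_equal(j_serca(0.001, 10, pr), 0)  # c = K1 * ce exactly
  expect_equal(j_serca(0.05, 10, pr), 0.049 / 0.0275, tolerance = 1e-12)
  expect_lt(j_serca(0, 10, pr), 0)  # backward flux below reversal
  # sign equals sign of (c - K1*ce) across a grid
  grid <- expand.grid(c = c(0, 0.01, 0.1, 1), ce = c(0.5, 5, 50))
  s <- mapply(function(c, ce) j_serca(c, ce, pr), grid$c, grid$ce)
  expect_equal(sign(s), sign(grid$c - pr$K1 * grid$ce))
})

test_that("RyR rate is sigmoidal in c, desensitised by amyloid-beta", {
  expect_equal(ryr_rate(0, 0, pr), pr$k1)
  expect_equal(ryr_rate(1e5, 0, pr), pr$k1 + pr$k2, tolerance = 1e-9)
  # half-saturation at c = kd + kalpha*a
  for (a in c(0, 0.4, 1))
    expect_equal(ryr_rate(pr$kd + pr$kalpha * a, a, pr),
                 pr$k1 + pr$k2 / 2)
  cs <- seq(0, 3, by = 0.02)
  r <- ryr_rate(cs, 0.2, pr)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r >= pr$k1 & r <= pr$k1 + pr$k2))
  # for fixed c > 0 the rate decreases as a increases
  as <- seq(0, 2, by = 0.1)
  expect_true(all(diff(ryr_rate(0.2, as, pr)) < 0))
})

test_that("RyR flux is gradient-driven", {
  expect_equal(j_ryr(1, 1, 0, pr), 0)
  expect_equal(j_ryr(0.05, 10, 0, pr),
               ryr_rate(0.05, 0, pr) * 9.95)
  expect_lt(j_ryr(0.05, 0, 0, pr), 0)
})

test_that("IPR flux scales with open probability and gradient", {
  expect_equal(j_ipr(0.3, 8, 0, pr), 0)   # closed channel, Jer = 0
  expect_equal(j_ipr(0, 10, 1, pr), pr$kf * 10)
  expect_equal(j_ipr(2, 2, 0.5, pr), 0)   # no gradient
  expect_error(j_ipr(0, 1, 1.2, pr), "\\[0, 1\\]")
  expect_error(j_ipr(0, 1, -0.2, pr), "\\[0, 1\\]")
})

test_that("amyloid-beta terms vanish at a = 0, p = 0", {
  expect_equal(j_in(0, 0, pr), pr$a1)
  cs <- seq(0, 2, by = 0.1)
  base <- pr$k1 + pr$k2 * cs^3 / (pr$kd^3 + cs^3)  # unmodified CICR rate
  expect_equal(ryr_rate(cs, 0, pr), base)
})
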