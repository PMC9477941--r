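test_that("wall stiffness and viscosity coefficients follow the tube law", {
  expect_equal(stiffness_coefficients(0, 1.5e-3)$K, 0)
  expect_equal(stiffness_coefficients(0, 1.5e-3, 0)$G, 0)
  k <- stiffness_coefficients(0.25e6, 1.5e-3)
  expect_equal(k$K, 4 / 3 * sqrt(pi) * 0.25e6 * 1.5e-3)
  expect_equal(k$K, 886.2269, tolerance = 1e-6)
  # linear in E
  expect_equal(stiffness_coefficients(0.75e6, 1.5e-3)$K / k$K, 3)
  expect_equal(stiffness_coefficients(1e5, 2e-3, 3e3)$G,
               2 / 3 * sqrt(pi) * 3e3 * 2e-3)
  expect_error(stiffness_coefficients(1e5, 0), "thickness")
  expect_error(wall_properties(-1, 1e5, 1e-3), "A0")
})

test_that("pressure-area law: reference state, elastic term, viscous sign", {
  w <- wall_properties(pi * 1e-4, 0.25e6, 1.5e-3, phi_w = 1e3)
  expect_equal(pressure_from_area(w$A0, 0, w), w$P_ext)
  # closed-form elastic contribution at A = 1.1 A0
  we <- wall_properties(pi * 1e-4, 0.25e6, 1.5e-3)   # G = 0
  expect_equal(pressure_from_area(1.1 * we$A0, 5, we) - we$P_ext,
               we$K * (sqrt(1.1) - 1) * sqrt(we$A0) / we$A0)
  # viscous term raises pressure when the wall distends
  expect_gt(pressure_from_area(1.1 * w$A0, 1e-5, w),
            pressure_from_area(1.1 * w$A0, 0, w))
  expect_error(pressure_from_area(0, 0, w), "collapsed")
})

test_that("wave speed matches the closed form and its scalings", {
  w <- wall_properties(pi * 1e-4, 0.25e6, 1.5e-3)
  c0 <- wave_speed(w$A0, w)
  expect_equal(c0, sqrt(w$K / (2 * w$rho * sqrt(w$A0))))
  expect_equal(c0, 4.856429, tolerance = 1e-6)
  # monotone in A; quadrupling K doubles c0
  A <- w$A0 * seq(0.5, 2, length.out = 20)
  expect_true(all(diff(wave_speed(A, w)) > 0))
  w4 <- wall_properties(w$A0, 4 * 0.25e6, 1.5e-3)
  expect_equal(wave_speed(w4$A0, w4) / c0, 2)
  w0 <- wall_properties(w$A0, 0.25e6, 1.5e-3)
  w0$K <- 0
  expect_error(wave_speed(w$A0, w0), "wave speed")
})

test_that("wave speed is consistent with differentiating the tube law", {
  w <- wall_properties(pi * 1e-4, 0.25e6, 1.5e-3)
  eps <- 1e-10 * w$A0
  for (A in w$A0 * c(0.6, 1, 1.5)) {
    dPdA <- (pressure_from_area(A + eps, 0, w) -
               pressure_from_area(A - eps, 0, w)) / (2 * eps)
    c2 <- wave_speed(A, w)^2
    expect_lt(abs(c2 - A / w$rho * dPdA) / c2, 1e-6)
  }
})

test_that("characteristics invert exactly over the operating range", {
  w <- wall_properties(pi * 1e-4, 0.25e6, 1.5e-3)
  expect_equal(unlist(characteristics(w$A0, 0, w)), c(W_f = 0, W_b = 0))
  for (ra in c(0.5, 0.8, 1, 1.3, 2)) {
    for (u in c(-2, -0.5, 0, 1, 2)) {
      A <- ra * w$A0
      ch <- characteristics(A, u, w)
      inv <- invert_characteristics(ch$W_f, ch$W_b, w)
      expect_equal(inv$A, A, tolerance = 1e-12)
      expect_equal(inv$u, u, tolerance = 1e-12)
    }
  }
  c0 <- wave_speed(w$A0, w)
  expect_error(invert_characteristics(-5 * c0, 5 * c0, w), "unphysical")
})

test_that("small-amplitude characteristics linearise to pressure/(rho c0)", {
  w <- wall_properties(pi * 1e-4, 0.25e6, 1.5e-3)
  c0 <- wave_speed(w$A0, w)
  for (dA in c(-0.009, 0.005, 0.009)) {
    A <- w$A0 * (1 + dA)
    u <- 0.1
    Wf <- characteristics(A, u, w)$W_f
    lin <- u + (pressure_from_area(A, 0, w) - w$P_ext) / (w$rho * c0)
    expect_lt(abs(Wf - lin) / abs(lin - u), 0.01 + 1e-12)
  }
})
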