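test_that("windkessel boundary satisfies the lumped relation each step", {
  A0 <- pi * 1e-4
  w <- wall_properties(A0, 0.25e6, 1.5e-3)
  # pure resistor degeneration: P = P_out + (R + Z) Q instantaneously
  term <- windkessel_terminal(Z = 1e7, R = 1.5e8, C = 0, P_out = 500)
  st <- windkessel_step(term, c(1.05 * A0, 5e-5), w, dt = 1e-4)
  P <- pressure_from_area(st$A, 0, w)
  expect_equal(P, term$P_out + (term$R + term$Z) * st$Q, tolerance = 1e-10)
  expect_error(windkessel_terminal(Z = 1e7, R = 0, C = 1e-9), "R must be")
})

test_that("capacitor discharge follows exp(-t/RC) at first order in dt", {
  R <- 1e8; C <- 1e-8; P0 <- 1e4
  decay_err <- function(dt) {
    n <- round(2 / dt)
    P <- P0
    for (i in seq_len(n)) P <- cardiowave:::.cw_wk_update(P, 0, dt, R, C, 0)
    abs(P - P0 * exp(-2 / (R * C)))
  }
  tau_from <- function(dt) {
    n <- round(2 / dt)
    P <- P0
    for (i in seq_len(n)) P <- cardiowave:::.cw_wk_update(P, 0, dt, R, C, 0)
    -2 / log(P / P0)
  }
  expect_lt(abs(tau_from(1e-3) - R * C) / (R * C), 0.02)
  # implicit Euler: halving dt roughly halves the error
  r <- decay_err(2e-3) / decay_err(1e-3)
  expect_gt(r, 1.7)
  expect_lt(r, 2.3)
})

test_that("a continuation junction with equal walls is transparent", {
  A0 <- pi * 1e-4
  w <- wall_properties(A0, 0.25e6, 1.5e-3)
  st <- c(1.04 * A0, 8e-5)
  j <- junction_solve(st, matrix(st, 2, 1), w, list(w))
  expect_equal(j$parent, st, tolerance = 1e-12)
  expect_equal(unname(j$children[, 1]), st, tolerance = 1e-12)
  expect_lt(abs(j$mass_residual), 1e-10 * abs(st[2]))
})

test_that("a symmetric bifurcation splits flow exactly evenly", {
  A0 <- pi * 1e-4
  wp <- wall_properties(A0, 0.25e6, 1.5e-3)
  wc <- wall_properties(0.6 * A0, 0.4e6, 1.2e-3)
  child <- c(0.62 * A0, 2e-5)
  j <- junction_solve(c(1.05 * A0, 9e-5), cbind(child, child), wp,
                      list(wc, wc))
  expect_equal(j$children[2, 1], j$children[2, 2], tolerance = 1e-12)
  expect_lt(abs(j$mass_residual),
            1e-10 * max(abs(j$parent[2]), abs(j$children[2, ])))
  # total pressure is continuous across the junction
  Pp <- pressure_from_area(j$parent[1], 0, wp) +
    0.5 * wp$rho * (j$parent[2] / j$parent[1])^2
  Pc <- pressure_from_area(j$children[1, 1], 0, wc) +
    0.5 * wc$rho * (j$children[2, 1] / j$children[1, 1])^2
  expect_equal(Pp, Pc, tolerance = 1e-9)
})

test_that("stenosis pressure drop has the documented three-term form", {
  el <- stenosis_element(0.7, Ls = 0.02, Kv = 32, Kt = 1.52, Ku = 1.2)
  A0 <- pi * 1e-4; D0 <- 0.02; rho <- 1060; mu <- 4e-3
  expect_equal(stenosis_dp(el, 0, 0, rho, mu, A0, D0), 0)
  q <- 3e-4
  # odd symmetry of the turbulent term (with the linear term, full oddness
  # holds at zero acceleration)
  expect_equal(stenosis_dp(el, -q, 0, rho, mu, A0, D0),
               -stenosis_dp(el, q, 0, rho, mu, A0, D0))
  dqdt <- 0.5
  expected <- 32 * mu / (A0 * D0) * q +
    1.52 * rho / (2 * A0^2) * (1 / 0.7 - 1)^2 * q * abs(q) +
    1.2 * rho * el$Ls / A0 * dqdt
  expect_equal(stenosis_dp(el, q, dqdt, rho, mu, A0, D0), expected)
  expect_error(stenosis_element(1.2), "between 0 and 1")
})

test_that("the embedded stenosis interface carries equal flow and the drop", {
  A0 <- pi * 1e-4
  st <- cardiowave:::.cw_stenosis_solve(
    c(1.05 * A0, 2e-4), c(A0, 886.2269),
    c(1.01 * A0, 1.8e-4), c(A0, 886.2269),
    0.7, 0.02, 32, 1.52, 1.2, 1.9e-4, 1e-4, 1060, 0, 4e-3)
  wl <- wall_properties(A0, 0.25e6, 1.5e-3)
  el <- stenosis_element(0.7, Ls = 0.02, Kv = 32)
  dP <- pressure_from_area(st[["A_left"]], 0, wl) -
    pressure_from_area(st[["A_right"]], 0, wl)
  dp_model <- stenosis_dp(el, st[["q"]], (st[["q"]] - 1.9e-4) / 1e-4,
                          1060, 4e-3, A0, 0.02)
  expect_equal(dP, dp_model, tolerance = 1e-6)
})

test_that("inflow boundary conditions prescribe flow or pressure", {
  A0 <- pi * 1e-4
  w <- wall_properties(A0, 0.25e6, 1.5e-3)
  bc <- inflow_bc("flow", period = 1, fn = function(t) 1e-4 * sin(pi * t))
  st <- inflow_apply(bc, c(A0, 0), w, t = 0.5)
  expect_equal(st[["Q"]], 1e-4)
  # periodic wrap
  st2 <- inflow_apply(bc, c(A0, 0), w, t = 2.5)
  expect_equal(st2[["Q"]], 1e-4)
  # zero waveform reduces to a no-flow end
  bc0 <- inflow_bc("flow", period = 1, fn = function(t) rep(0, length(t)))
  st0 <- inflow_apply(bc0, c(1.02 * A0, 1e-5), w, t = 0.3)
  expect_equal(st0[["Q"]], 0)
  # pressure mode at P = P_ext pins the reference area
  bp <- inflow_bc("pressure", period = 1, fn = function(t) rep(w$P_ext, length(t)))
  stp <- inflow_apply(bp, c(A0, 0), w, t = 0.1)
  expect_equal(stp[["A"]], A0, tolerance = 1e-6)
})

test_that("a prescribed inflow waveform is reproduced in the first element", {
  net <- make_single_vessel(length = 0.2)
  bc <- net$inlet$waveform
  dt <- 1e-4
  out <- simulate_network(net, dt, n_steps = round(0.25 / dt),
                          probes = cbind(1L, 1L), record_every = 1L)
  rec <- out$records
  # compare at peak systole (t = T_sys / 2)
  Ts <- attr(bc, "t_systole")
  ipk <- which.min(abs(rec$t - Ts / 2))
  expect_equal(rec$Q_1[ipk], bc$fn(Ts / 2), tolerance = 0.01)
})
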