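test_that("stable time step follows the CFL bound", {
  A0 <- pi * 1e-4
  seg <- vessel_segment(1, 0.2, 20, A0)     # dx = 0.01
  w <- wall_properties(A0, 0.25e6, 1.5e-3)
  c0 <- wave_speed(A0, w)
  expect_equal(stable_dt(seg, 0.9), 0.9 * seg$dx / c0)
  seg2 <- vessel_segment(1, 0.2, 40, A0)    # doubling n halves dt
  expect_equal(stable_dt(seg2, 0.9), stable_dt(seg, 0.9) / 2)
  # robustness-benchmark discretisation: dx/(|u|+c) ~ 2e-3 s admits all of
  # the benchmark's 1D time steps
  expect_gt(seg$dx / c0, 1.9e-3)
  for (dt in c(5e-4, 1e-4, 5e-5)) expect_lte(dt, stable_dt(seg, 1))
})

test_that("the rest state is an exact fixed point of advance()", {
  seg <- vessel_segment(1, 0.1, 20, pi * 1e-4)
  out <- advance(seg, 1e-4,
                 list(left = c(seg$A0[1], 0), right = c(seg$A0[20], 0)),
                 n_steps = 50)
  expect_identical(out$A, seg$A0)
  expect_identical(out$Q, rep(0, 20))
})

test_that("volume change equals the boundary flux integral", {
  A0 <- pi * 1e-4
  seg <- vessel_segment(1, 0.2, 40, A0, mu = 4e-3)
  # non-trivial initial state
  seg$A <- A0 * (1 + 0.05 * exp(-(seg$x - 0.1)^2 / (2 * 0.02^2)))
  bl <- c(A0 * 1.01, 2e-5)
  br <- c(A0 * 0.99, -1e-5)
  n_steps <- 40L
  dt <- 0.3 * stable_dt(seg, 1)
  out <- advance(seg, dt, list(left = bl, right = br), n_steps = n_steps)
  dV <- sum(out$A - seg$A) * seg$dx
  bf <- attr(out, "boundary_flux_volumes")
  flux <- bf[["inflow"]] - bf[["outflow"]]
  expect_lt(abs(dV - flux) / abs(flux), 1e-10)
})

test_that("a small pulse propagates at the analytic wave speed", {
  m <- measure_transit_speed(E = 0.25e6)
  expect_lt(abs(m$c_measured - m$c0) / m$c0, 0.02)
})

test_that("with friction a steady flow satisfies the momentum balance", {
  net <- make_single_vessel(length = 0.2)
  Qbar <- 2e-5
  net$inlet$waveform <- inflow_bc("flow", period = 1,
                                  fn = function(t) rep(Qbar, length(t)))
  out <- simulate_network(net, dt = 2e-4, n_steps = 60000)
  v <- out$network$vessels[[1]]
  P <- pressure_from_area(v$A, 0, wall_properties(v$A0, v$E, v$h, rho = v$rho))
  i <- 10:70  # interior
  dPdx <- stats::coef(stats::lm(P[i] ~ v$x[i]))[2]
  u <- mean(v$Q[i] / v$A[i])
  A <- mean(v$A[i])
  expect_equal(unname(dPdx), -v$fcoef * u / A, tolerance = 0.05)
})

test_that("standalone cycling reaches a periodic state and reports it", {
  net <- make_single_vessel(length = 0.2)
  net0 <- run_standalone(net, n_cycles = 0)
  expect_identical(net0$vessels[[1]]$A, net$vessels[[1]]$A)
  net <- run_standalone(net, n_cycles = 20, dt = 1e-4)
  sa <- attr(net, "standalone")
  expect_true(sa$periodic)
  expect_lt(utils::tail(sa$cycle_change, 1), 1e-3)
  # physiological operating point of the documented defaults
  expect_gt(min(sa$last_cycle$P_in) / 133.322, 60)
  expect_lt(max(sa$last_cycle$P_in) / 133.322, 140)
})

test_that("with zero inflow and P_out = P_ext the network relaxes to rest", {
  net <- make_single_vessel(length = 0.126)
  net$terminals[[1]]$P_out <- 0
  net$terminals[[1]]$P_state <- 0
  v <- net$vessels[[1]]
  net$vessels[[1]]$A <- v$A0 * (1 + 0.03 * sin(2 * pi * v$x / 0.126))
  net$inlet$waveform <- NULL  # closed inlet
  out <- simulate_network(net, dt = 1e-4, n_steps = 60000)
  expect_lt(max(abs(out$network$vessels[[1]]$A / v$A0 - 1)), 1e-3)
  expect_lt(max(abs(out$network$vessels[[1]]$Q)), 1e-8)
})
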