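test_that("valve acts as a Bernoulli diode with inertance memory", {
  v <- valve_model(B = 4.5e9, L_in = 0)
  expect_equal(valve_flow(1000, 2000, v, 1e-3)$q, 0)     # closed, dp < 0
  out <- valve_flow(2000, 1000, v, 1e-3)                 # opens
  expect_equal(out$q, sqrt(1000 / 4.5e9))
  # ramping dp across zero: q decays continuously and ends at exactly zero
  vl <- valve_model(B = 4.5e9, L_in = 5e4)
  vl$state <- "open"; vl$q <- 3e-4
  dps <- c(seq(500, -500, by = -50), rep(-500, 120))
  qs <- numeric(length(dps))
  for (i in seq_along(dps)) {
    o <- valve_flow(1000 + dps[i], 1000, vl, 1e-3)
    qs[i] <- o$q; vl <- o$valve
  }
  expect_true(all(diff(qs) <= 1e-6))           # monotone decay, no chatter
  expect_equal(qs[length(qs)], 0)              # inertance drains, valve shuts
  expect_true(all(abs(diff(qs)) < 2e-4))       # continuous steps
})

test_that("vascular volume trials: snapshot purity and monotonicity", {
  net <- cached("net126", {
    n <- make_single_vessel(length = 0.126)
    run_standalone(n, n_cycles = 20, dt = 1e-4)
  })
  cfg <- coupling_config()
  valve <- valve_model(); valve$q <- 0
  V_n <- 1e-4
  p_low <- 5e3   # below root pressure: valve stays shut
  v1 <- vascular_volume(p_low, net, valve, cfg, V_n)
  expect_equal(v1$V_CS, V_n)
  p_ej <- 14e3
  a <- vascular_volume(p_ej, net, valve, cfg, V_n)
  b <- vascular_volume(p_ej, net, valve, cfg, V_n)
  expect_identical(a$V_CS, b$V_CS)             # bit-identical repeat
  hi <- vascular_volume(p_ej + 500, net, valve, cfg, V_n)
  expect_lt(hi$V_CS, a$V_CS)                   # more pressure ejects more
  # finite-difference compliance is non-positive and epsilon-robust
  c1 <- coupling_compliance(p_ej, net, valve, cfg, V_n, fd_eps = 10)
  c2 <- coupling_compliance(p_ej, net, valve, cfg, V_n, fd_eps = 5)
  expect_lte(c1, 0)
  expect_lt(abs(c1 - c2) / abs(c2), 0.01)
  # closed valve: zero compliance
  expect_equal(coupling_compliance(p_low, net, valve, cfg, V_n), 0)
})

test_that("Newton on an affine cavity and linear afterload converges in one step", {
  cav <- elastance_cavity(V_rest = 1e-5, E_min = 5e7, E_max = 5e7)
  cfg <- coupling_config(fd_eps = 10)
  a <- 1.2e-4; b <- 2e-9
  afterload <- list(V_CS = function(p) a - b * p, cfg = cfg)
  state <- list(p_cav = 8e3, V_cav = a - b * 8e3, t = 0.2, dp_trend = 0)
  out <- newton_coupled_step(state, cav, network = NULL, cfg, valve = NULL,
                             afterload = afterload)
  expect_equal(out$state$newton_iters, 1L)
  p <- out$state$p_cav
  expect_equal(cavity_volume(cav, p, 0.2 + cfg$dt3D), a - b * p,
               tolerance = 1e-10)
})

test_that("isovolumetric step holds volume and tracks active stress", {
  cfg <- coupling_config()
  # constant elastance and matching volume: pressure must not move
  cav <- elastance_cavity(V_rest = 1e-5, E_min = 5e7, E_max = 5e7)
  st <- list(p_cav = 4e3, V_cav = 1e-5 + 4e3 / 5e7, V0 = 1e-5 + 4e3 / 5e7,
             t = 0.2, dp_trend = 0)
  st1 <- isovolumetric_step(st, cav, cfg)
  expect_equal(st1$p_cav, 4e3, tolerance = 1e-9)
  expect_equal(st1$V_cav, st$V0)
  # sphere during contraction: pressure rises while stress rises, volume fixed
  sc <- sphere_cavity()
  V0 <- cavity_volume(sc, 1333.22, 0.015)
  s <- list(p_cav = 1333.22, V_cav = V0, V0 = V0, t = 0.016, dp_trend = 0)
  ps <- numeric(30)
  for (i in 1:30) {
    s <- isovolumetric_step(s, sc, cfg)
    ps[i] <- s$p_cav
    expect_lt(abs(s$residual) / V0, 1e-6)
  }
  expect_true(all(diff(ps) > 0))
})

test_that("zero active stress produces no ejection; volume follows filling", {
  net <- cached("net126", {
    n <- make_single_vessel(length = 0.126)
    run_standalone(n, n_cycles = 20, dt = 1e-4)
  })
  cav <- sphere_cavity(act = active_stress_params(S_peak = 0, lambda0 = 0.9,
                                                  ld = 6))
  cfg <- coupling_config(dt3D = 2e-3, dt1D = 2e-4)
  out <- run_cardiac_cycle(cav, net, cfg, n_beats = 1)
  expect_false(any(out$trace$phase == "ejection"))
  expect_true(all(out$trace$q == 0))
  V_passive <- cavity_volume(cav, 1333.22, 0)
  expect_lt(max(abs(out$trace$V_cav - V_passive)) / V_passive, 1e-9)
})

test_that("the baseline coupled run closes its PV loop and balances mass", {
  out <- cached("baseline_run", coupled_single(E = 0.25e6, n_beats = 3))
  b <- out$beats
  expect_equal(nrow(b), 3)
  # periodic loop: end-diastolic volume settles beat to beat
  expect_lt(abs(b$EDV[3] - b$EDV[2]) / b$EDV[2], 0.01)
  # stroke volume equals the integrated ejected volume exactly
  expect_equal(b$SV, b$ejected, tolerance = 1e-6)
  expect_true(all(b$EF > 0.3 & b$EF < 0.8))
  # all four phases visited
  expect_setequal(unique(out$trace$phase),
                  c("filling", "isovol_contraction", "ejection",
                    "isovol_relaxation"))
})
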