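test_that("active stress transient: support, boundaries, baseline value", {
  p <- active_stress_params()   # ventricular baseline values
  expect_equal(active_stress(p$t_a + p$t_emd - 0.01, 1, p), 0)   # before onset
  expect_equal(active_stress(p$t_a + p$t_emd, 1, p), 0)          # t_s = 0
  expect_equal(active_stress(p$t_a + p$t_emd + p$t_dur, 1, p), 0)  # t_s = t_dur
  # direct evaluation at t_s = t_dur / 2 = 287.5 ms, lambda = 1
  phi <- tanh(35 * (1 - 0.7))
  tau_c <- 0.105 + 0.100 * (1 - phi)
  expected <- 60e3 * phi * tanh(0.2875 / tau_c)^2 * tanh(0.2875 / 0.090)^2
  expect_equal(active_stress(0.015 + 0.2875, 1, p), expected)
  expect_equal(expected, 58608.7, tolerance = 1e-4)
  # no tension below the lower stretch limit
  expect_equal(active_stress(0.3, 0.6, p), 0)
})

test_that("Guccione energy: reference state, pure dilation, frame indifference", {
  g <- guccione_params()
  expect_equal(guccione_energy(diag(3), g), 0)
  for (J in c(0.9, 1.1)) {
    expect_equal(guccione_energy(J^(2 / 3) * diag(3), g),
                 g$kappa / 2 * log(J)^2, tolerance = 1e-12)
  }
  # isochoric uniaxial fibre stretch, energy written out independently
  lam <- 1.1
  C <- diag(c(lam^2, 1 / lam, 1 / lam))
  Eb <- (C - diag(3)) / 2        # J = 1
  Q <- g$b_f * Eb[1, 1]^2 + g$b_t * (Eb[2, 2]^2 + Eb[3, 3]^2)
  expect_equal(guccione_energy(C, g), g$C_guc / 2 * (exp(Q) - 1))
  # frame indifference under joint rotation of C and the material axes
  set.seed(42)
  for (i in 1:5) {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    M <- matrix(rnorm(9), 3) * 0.2
    C <- diag(3) + 0.5 * (M + t(M)) + 0.3 * crossprod(M)
    g2 <- guccione_params(f0 = drop(R %*% g$f0), s0 = drop(R %*% g$s0),
                          n0 = drop(R %*% g$n0))
    expect_equal(guccione_energy(R %*% C %*% t(R), g2),
                 guccione_energy(C, g), tolerance = 1e-10)
  }
  expect_error(guccione_energy(diag(c(1, -1, 1)), g), "positive definite")
})

test_that("analytic passive stress matches numerical differentiation", {
  g <- guccione_params()
  set.seed(7)
  for (i in 1:5) {
    M <- matrix(rnorm(9), 3) * 0.15
    C <- diag(3) + 0.5 * (M + t(M)) + 0.25 * crossprod(M)
    S <- guccione_stress(C, g)
    h <- 1e-7
    for (a in 1:3) for (b in a:3) {
      dC <- matrix(0, 3, 3)
      dC[a, b] <- dC[b, a] <- h
      num <- (guccione_energy(C + dC, g) - guccione_energy(C - dC, g)) / (2 * h)
      # directional derivative along dC/h equals S : (dC/h) / 2 (S = 2 dPsi/dC)
      anl <- sum(S * dC) / (2 * h)
      expect_equal(num, anl, tolerance = 1e-5)
    }
  }
})

test_that("active stress tensor normalisations", {
  f0 <- c(1, 0, 0); s0 <- c(0, 1, 0)
  expect_equal(active_stress_tensor(0, diag(3), f0, s0), matrix(0, 3, 3))
  S <- active_stress_tensor(1e4, diag(3), f0, s0)
  expect_equal(sort(eigen(S, symmetric = TRUE)$values),
               c(0, 0.4e4, 1e4))
  set.seed(11)
  for (i in 1:5) {
    M <- matrix(rnorm(9), 3) * 0.3
    C <- diag(3) + 0.5 * (M + t(M)) + 0.3 * crossprod(M)
    S <- active_stress_tensor(1e4, C, f0, s0)
    expect_equal(sum(S * C), 1.4 * 1e4, tolerance = 1e-10)
  }
})

test_that("sphere cavity: stress-free reference, monotone p-V, active push", {
  cav <- sphere_cavity(act = active_stress_params(S_peak = 0))
  expect_equal(sphere_cavity_pressure(cav$V_ref, 0.3, cav), 0, tolerance = 1e-9)
  # passive curve strictly increasing
  Vs <- seq(0.7, 2.2, length.out = 25) * cav$V_ref
  p <- sapply(Vs, function(v) sphere_cavity_pressure(v, 0.3, cav))
  expect_true(all(diff(p) > 0))
  # and remains monotone across the active transient with the defaults
  cav2 <- sphere_cavity()
  for (t in seq(0.05, 0.55, by = 0.1)) {
    p2 <- sapply(Vs, function(v) sphere_cavity_pressure(v, t, cav2))
    expect_true(all(diff(p2) > 0))
    expect_true(all(p2 > p))  # active stress raises pressure at fixed volume
  }
  # inversion consistency
  for (t in c(0.08, 0.3, 1.0)) {
    V <- 1.5 * cav2$V_ref
    expect_equal(cavity_volume(cav2, sphere_cavity_pressure(V, t, cav2), t),
                 V, tolerance = 1e-8)
  }
  expect_error(sphere_cavity_pressure(-1e-6, 0, cav), "positive")
})

test_that("elastance cavity satisfies the affine contract", {
  cav <- elastance_cavity(V_rest = 1e-5, E_min = 1e7, E_max = 2e8)
  for (t in c(0.05, 0.2, 0.9)) {
    p <- 5e3
    V <- cavity_volume(cav, p, t)
    expect_equal(cavity_pressure(cav, V, t), p)
    expect_equal(cavity_dVdp(cav, p, t), (cavity_volume(cav, p + 1, t) - V))
    expect_gt(cavity_dVdp(cav, p, t), 0)
  }
})

test_that("surface volume: cube exactness, icosphere convergence, invariance", {
  # unit cube, outward-oriented triangles
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = 0 (normal -z)
    c(5, 6, 7), c(6, 8, 7),  # z = 1
    c(1, 2, 5), c(2, 6, 5),  # y = 0
    c(3, 7, 4), c(4, 7, 8),  # y = 1
    c(1, 5, 3), c(3, 5, 7),  # x = 0
    c(2, 4, 6), c(4, 8, 6))  # x = 1
  cube <- list(vertices = v, faces = f)
  expect_equal(surface_volume(cube), 1)
  sph <- icosphere(4)
  expect_lt(abs(surface_volume(sph) - 4 * pi / 3) / (4 * pi / 3), 0.005)
  moved <- sph
  moved$vertices <- sweep(sph$vertices, 2, c(3, -2, 11), "+")
  expect_equal(surface_volume(moved), surface_volume(sph), tolerance = 1e-12)
  open_mesh <- list(vertices = v, faces = f[-1, ])
  expect_error(surface_volume(open_mesh), "invalid surface")
})

test_that("OFF meshes round-trip through the reader", {
  sph <- icosphere(1)
  path <- tempfile(fileext = ".off")
  writeLines(c("OFF",
               paste(nrow(sph$vertices), nrow(sph$faces), 0),
               apply(sph$vertices, 1, paste, collapse = " "),
               apply(cbind(3, sph$faces - 1), 1, paste, collapse = " ")),
             path)
  m <- read_surface_off(path)
  expect_equal(surface_volume(m), surface_volume(sph), tolerance = 1e-12)
})
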