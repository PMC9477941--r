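#' Parameters of the phenomenological active-stress transient
#'
#' Defaults are the left-ventricular baseline values: peak isometric tension
#' 60 kPa, transient duration 575 ms, contraction/relaxation time constants
#' 105/90 ms, length-dependence degree 35 with upstroke length dependence
#' 100 ms, lower stretch limit 0.7, electromechanical delay 15 ms.
#'
#' @param S_peak peak isometric tension (Pa).
#' @param t_dur duration of the active transient (s).
#' @param tau_c0 baseline contraction time constant (s).
#' @param tau_r relaxation time constant (s).
#' @param ld degree of length dependence (dimensionless).
#' @param ld_up length dependence of the upstroke time (s).
#' @param lambda0 lower fibre-stretch limit below which no tension develops.
#' @param t_emd electromechanical delay (s).
#' @param t_a activation time (s); a plain parameter here, since electrical
#'   activation mapping is outside this model's scope.
#' @return An object of class `active_stress_params`.
#' @export
active_stress_params <- function(S_peak = 60e3, t_dur = 0.575,
                                 tau_c0 = 0.105, tau_r = 0.090,
                                 ld = 35, ld_up = 0.100, lambda0 = 0.7,
                                 t_emd = 0.015, t_a = 0) {
  stopifnot(S_peak >= 0, t_dur > 0, tau_c0 > 0, tau_r > 0)
  structure(list(S_peak = S_peak, t_dur = t_dur, tau_c0 = tau_c0,
                 tau_r = tau_r, ld = ld, ld_up = ld_up, lambda0 = lambda0,
                 t_emd = t_emd, t_a = t_a),
            class = "active_stress_params")
}

# rescale all time constants (used when the heart period changes)
.act_scale_time <- function(p, factor) {
  for (f in c("t_dur", "tau_c0", "tau_r", "ld_up")) p[[f]] <- p[[f]] * factor
  p
}

#' Scalar active stress transient
#'
#' \deqn{S_a(t, \lambda) = S_{peak}\, \phi(\lambda)\,
#'   \tanh^2(t_s/\tau_c)\, \tanh^2((t_{dur} - t_s)/\tau_r)}
#' for \eqn{0 < t_s < t_{dur}} and zero otherwise, with
#' \eqn{\phi = \tanh(ld\,(\lambda - \lambda_0))},
#' \eqn{\tau_c = \tau_{c0} + ld_{up} (1 - \phi)} and
#' \eqn{t_s = t - t_a - t_{emd}}.
#'
#' @param t time (s); vectorised.
#' @param lambda fibre stretch (> 0).
#' @param p an [active_stress_params()].
#' @return Active stress (Pa).
#' @export
active_stress <- function(t, lambda, p) {
  stopifnot(all(lambda > 0))
  phi <- tanh(p$ld * (lambda - p$lambda0))
  phi <- pmax(phi, 0)  # no negative tension below lambda0
  tau_c <- p$tau_c0 + p$ld_up * (1 - phi)
  ts <- t - p$t_a - p$t_emd
  s <- p$S_peak * phi * tanh(ts / tau_c)^2 * tanh((p$t_dur - ts) / p$tau_r)^2
  s[ts <= 0 | ts >= p$t_dur] <- 0
  s
}

#' Guccione passive material parameters
#'
#' Transversely isotropic exponential strain energy with a volumetric penalty.
#' Default exponents b_f = 18.48, b_t = 3.58, b_fs = 1.627; bulk modulus
#' 650 kPa.  The stiffness scaling `C_guc` is the fitted quantity in practice.
#'
#' @param C_guc stiffness scaling (Pa).
#' @param b_f,b_t,b_fs fibre / transverse / shear strain exponents.
#' @param kappa bulk modulus (Pa).
#' @param f0,s0,n0 orthonormal fibre, sheet and normal directions.
#' @return An object of class `guccione_params`.
#' @export
guccione_params <- function(C_guc = 0.8e3, b_f = 18.48, b_t = 3.58,
                            b_fs = 1.627, kappa = 650e3,
                            f0 = c(1, 0, 0), s0 = c(0, 1, 0),
                            n0 = c(0, 0, 1)) {
  stopifnot(kappa > 0, C_guc >= 0)
  B <- cbind(f0, s0, n0)
  if (max(abs(crossprod(B) - diag(3))) > 1e-8)
    stop("f0, s0, n0 must be orthonormal")
  structure(list(C_guc = C_guc, b_f = b_f, b_t = b_t, b_fs = b_fs,
                 kappa = kappa, f0 = f0, s0 = s0, n0 = n0),
            class = "guccione_params")
}

.check_spd <- function(C_tensor) {
  if (!isTRUE(all.equal(C_tensor, t(C_tensor), tolerance = 1e-9)))
    stop("invalid deformation: C must be symmetric")
  ev <- eigen(C_tensor, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("invalid deformation: C must be positive definite")
}

# exponent Q and its derivative wrt the isochoric strain
.guc_Q <- function(Eb, p) {
  Eff <- drop(p$f0 %*% Eb %*% p$f0)
  Ess <- drop(p$s0 %*% Eb %*% p$s0)
  Enn <- drop(p$n0 %*% Eb %*% p$n0)
  Esn <- drop(p$s0 %*% Eb %*% p$n0)
  Efs <- drop(p$f0 %*% Eb %*% p$s0)
  Efn <- drop(p$f0 %*% Eb %*% p$n0)
  Q <- p$b_f * Eff^2 + p$b_t * (Ess^2 + Enn^2 + 2 * Esn^2) +
    2 * p$b_fs * (Efs^2 + Efn^2)
  sym <- function(a, b) (outer(a, b) + outer(b, a)) / 2
  M <- 2 * p$b_f * Eff * outer(p$f0, p$f0) +
    2 * p$b_t * (Ess * outer(p$s0, p$s0) + Enn * outer(p$n0, p$n0)) +
    4 * p$b_t * Esn * sym(p$s0, p$n0) +
    4 * p$b_fs * (Efs * sym(p$f0, p$s0) + Efn * sym(p$f0, p$n0))
  list(Q = Q, M = M)
}

#' Guccione strain-energy density
#'
#' \eqn{\Psi = (\kappa/2)(\log J)^2 + (C_{guc}/2)(e^Q - 1)} with the exponent
#' `Q` evaluated on the modified isochoric Green–Lagrange strain
#' \eqn{\bar E = (J^{-2/3} C - I)/2}.
#'
#' @param C_tensor right Cauchy–Green tensor (3 x 3 SPD matrix).
#' @param p a [guccione_params()].
#' @return Strain energy density (Pa).
#' @export
guccione_energy <- function(C_tensor, p) {
  .check_spd(C_tensor)
  J <- sqrt(det(C_tensor))
  Cb <- J^(-2 / 3) * C_tensor
  Eb <- (Cb - diag(3)) / 2
  Q <- .guc_Q(Eb, p)$Q
  p$kappa / 2 * log(J)^2 + p$C_guc / 2 * (exp(Q) - 1)
}

#' Passive second Piola–Kirchhoff stress of the Guccione law
#'
#' Analytic derivative \eqn{S = 2 \partial \Psi / \partial C}.
#'
#' @inheritParams guccione_energy
#' @return 3 x 3 stress tensor (Pa).
#' @export
guccione_stress <- function(C_tensor, p) {
  .check_spd(C_tensor)
  J <- sqrt(det(C_tensor))
  Ci <- solve(C_tensor)
  Cb <- J^(-2 / 3) * C_tensor
  Eb <- (Cb - diag(3)) / 2
  qm <- .guc_Q(Eb, p)
  MC <- sum(qm$M * C_tensor)
  p$kappa * log(J) * Ci +
    p$C_guc / 2 * exp(qm$Q) * J^(-2 / 3) * (qm$M - MC / 3 * Ci)
}

#' Orthotropic active stress tensor
#'
#' Second Piola–Kirchhoff active stress with full tension along the fibre and
#' 40\% along the sheet direction:
#' \deqn{S_{act} = S_a (f_0 \cdot C f_0)^{-1} f_0 \otimes f_0
#'   + 0.4\, S_a (s_0 \cdot C s_0)^{-1} s_0 \otimes s_0.}
#'
#' @param S_a scalar active stress (Pa).
#' @param C_tensor right Cauchy–Green tensor.
#' @param f0,s0 unit fibre and sheet directions.
#' @return 3 x 3 stress tensor (Pa).
#' @export
active_stress_tensor <- function(S_a, C_tensor, f0, s0) {
  .check_spd(C_tensor)
  S_a / drop(f0 %*% C_tensor %*% f0) * outer(f0, f0) +
    0.4 * S_a / drop(s0 %*% C_tensor %*% s0) * outer(s0, s0)
}

# ---------------------------------------------------------------------------
# Cavity contract: V(p, t), dV/dp, and the inverse p(V, t)

#' @export
cavity_volume <- function(cavity, p, t, ...) UseMethod("cavity_volume")
#' @export
cavity_dVdp <- function(cavity, p, t, ...) UseMethod("cavity_dVdp")
#' @export
cavity_pressure <- function(cavity, V, t, ...) UseMethod("cavity_pressure")

#' Time-varying elastance cavity
#'
#' Linear pressure–volume surrogate `p = E(t) (V - V_rest)` with the elastance
#' interpolating between `E_min` and `E_max` along the normalised active
#' transient shape of [active_stress()].
#'
#' @param V_rest volume intercept (m^3).
#' @param E_min,E_max diastolic and end-systolic elastance (Pa/m^3), both > 0.
#' @param act an [active_stress_params()] giving the activation time course.
#' @param period heart period (s).
#' @return An object of class `c("elastance_cavity", "cavity")`.
#' @export
elastance_cavity <- function(V_rest = 10e-6, E_min = 8e6, E_max = 300e6,
                             act = active_stress_params(), period = 1.231) {
  stopifnot(E_min > 0, E_max >= E_min)
  shape <- function(ts) tanh(pmax(ts, 0) / act$tau_c0)^2 *
    tanh(pmax(act$t_dur - ts, 0) / act$tau_r)^2
  smax <- stats::optimize(shape, c(0, act$t_dur), maximum = TRUE)$objective
  structure(list(V_rest = V_rest, E_min = E_min, E_max = E_max, act = act,
                 period = period, shape = shape, shape_max = smax),
            class = c("elastance_cavity", "cavity"))
}

.elastance_at <- function(cav, t) {
  ts <- (t - cav$act$t_a - cav$act$t_emd) %% cav$period
  a <- ifelse(ts > 0 & ts < cav$act$t_dur,
              cav$shape(ts) / cav$shape_max, 0)
  cav$E_min + (cav$E_max - cav$E_min) * a
}

#' @export
cavity_volume.elastance_cavity <- function(cavity, p, t, ...) {
  cavity$V_rest + p / .elastance_at(cavity, t)
}
#' @export
cavity_dVdp.elastance_cavity <- function(cavity, p, t, ...) {
  1 / .elastance_at(cavity, t)
}
#' @export
cavity_pressure.elastance_cavity <- function(cavity, V, t, ...) {
  .elastance_at(cavity, t) * (V - cavity$V_rest)
}

# ---------------------------------------------------------------------------
# Thick-walled incompressible sphere with Guccione passive law and
# circumferential fibres.

# Gauss-Legendre rule on [-1, 1] (Golub-Welsch)
.gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- diag(0, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

#' Thick-walled spherical cavity
#'
#' Reduced-order ventricle: an incompressible thick-walled sphere whose wall
#' carries the Guccione passive stress and the orthotropic active stress with
#' circumferential fibres.  Cavity pressure at a given inner volume follows
#' from radial equilibrium,
#' \deqn{p = \int_{r_i}^{r_o} \frac{(\sigma_\theta - \sigma_r) +
#'   (\sigma_\phi - \sigma_r)}{r}\, dr,}
#' integrated by Gauss quadrature over the reference wall; volume at given
#' pressure by safeguarded Newton inversion.  The deformation is the
#' incompressible inflation map \eqn{r^3 = R^3 + r_i^3 - R_i^3}.
#'
#' @param R_i,R_o reference inner and outer radii (m), `0 < R_i < R_o`.
#' @param guc a [guccione_params()]; the default stiffness scaling (700 Pa) is
#'   calibrated so the sphere fills to a physiological end-diastolic volume at
#'   a 10 mmHg preload.
#' @param act an [active_stress_params()].  The sphere measures fibre stretch
#'   from its stress-free reference, where the cavity operates at stretches
#'   1.0--1.2 (the ventricular model it stands in for measures stretch from
#'   end-diastole).  The default therefore re-centres the length dependence
#'   (`lambda0 = 0.90`, `ld = 6`) so active tension falls off as the cavity
#'   approaches its unloaded volume; this gives the positive end-systolic
#'   pressure--volume slope (strictly monotone `V(p)`) that the coupling
#'   contract requires.  All other parameters keep their ventricular baseline
#'   values.
#' @param period heart period (s).
#' @param n_quad Gauss points across the wall.
#' @return An object of class `c("sphere_cavity", "cavity")`.
#' @export
sphere_cavity <- function(R_i = 0.0243, R_o = 0.0369,
                          guc = guccione_params(C_guc = 700),
                          act = active_stress_params(lambda0 = 0.90, ld = 6),
                          period = 1.231, n_quad = 16) {
  stopifnot(R_i > 0, R_o > R_i)
  gl <- .gauss_legendre(n_quad)
  Rq <- (R_o + R_i) / 2 + (R_o - R_i) / 2 * gl$x
  wq <- (R_o - R_i) / 2 * gl$w
  structure(list(R_i = R_i, R_o = R_o, guc = guc, act = act, period = period,
                 Rq = Rq, wq = wq, V_ref = 4 * pi * R_i^3 / 3),
            class = c("sphere_cavity", "cavity"))
}

# equilibrium pressure of the inflated sphere at inner radius r_i, time t
.sphere_p_ri <- function(cav, r_i, t) {
  g <- cav$guc
  ts <- (t - cav$act$t_a - cav$act$t_emd) %% cav$period
  teval <- ts + cav$act$t_a + cav$act$t_emd  # active_stress re-subtracts
  R <- cav$Rq
  r <- (R^3 + r_i^3 - cav$R_i^3)^(1 / 3)
  lt <- r / R          # hoop stretch (theta = fibre, phi = sheet)
  lr <- (R / r)^2      # radial stretch (incompressible)
  et <- (lt^2 - 1) / 2
  er <- (lr^2 - 1) / 2
  Q <- g$b_f * et^2 + g$b_t * (et^2 + er^2)
  eQ <- exp(Q)
  S_t <- g$C_guc * eQ * g$b_f * et   # fibre (theta)
  S_p <- g$C_guc * eQ * g$b_t * et   # sheet (phi)
  S_r <- g$C_guc * eQ * g$b_t * er
  Sa <- active_stress(teval, lt, cav$act)
  # Cauchy stress differences (J = 1): sigma_a - sigma_h = lambda_a^2 S_a
  dth <- lt^2 * S_t + Sa - lr^2 * S_r
  dph <- lt^2 * S_p + 0.4 * Sa - lr^2 * S_r
  sum(cav$wq * (dth + dph) / r * (R / r)^2)
}

#' Cavity pressure of the spherical ventricle at a given volume
#'
#' @param V cavity volume (m^3), positive.
#' @param t time (s).
#' @param cav a [sphere_cavity()].
#' @return Pressure (Pa); zero at the stress-free reference volume with no
#'   active stress.
#' @export
sphere_cavity_pressure <- function(V, t, cav) {
  if (any(V <= 0)) stop("cavity-state error: volume must be positive")
  vapply(V, function(vv) .sphere_p_ri(cav, (3 * vv / (4 * pi))^(1 / 3), t),
         numeric(1))
}

#' @export
cavity_pressure.sphere_cavity <- function(cavity, V, t, ...) {
  sphere_cavity_pressure(V, t, cavity)
}

#' @export
cavity_volume.sphere_cavity <- function(cavity, p, t, ..., V_init = NULL) {
  # damped warm-started Newton; stays on the branch of the starting volume
  # (the active p(V) surface of a thick sphere need not be globally monotone,
  # but it is along the cycle trajectory)
  V <- if (is.null(V_init)) cavity$V_ref else V_init
  lo <- 1e-3 * cavity$V_ref
  hi <- 50 * cavity$V_ref
  for (it in 1:200) {
    f <- sphere_cavity_pressure(V, t, cavity) - p
    if (abs(f) < 1e-12 * max(abs(p), 1e3)) return(V)
    h <- 1e-6 * V
    dp <- (sphere_cavity_pressure(V + h, t, cavity) -
             sphere_cavity_pressure(V - h, t, cavity)) / (2 * h)
    step <- f / dp
    step <- sign(step) * min(abs(step), 0.2 * V)  # damping: <= 20% per iter
    Vn <- V - step
    if (!is.finite(Vn) || Vn <= lo || Vn >= hi)
      stop("cavity-state error: volume inversion left the admissible range")
    V <- Vn
    # quadratic convergence: a sub-rounding step means the rounding floor of
    # the pressure evaluation is reached
    if (abs(step) < 1e-14 * V) return(V)
  }
  stop("cavity-state error: volume inversion did not converge")
}

#' @export
cavity_dVdp.sphere_cavity <- function(cavity, p, t, ..., V = NULL) {
  if (is.null(V)) V <- cavity_volume(cavity, p, t)
  h <- 1e-6 * V
  dp <- (sphere_cavity_pressure(V + h, t, cavity) -
           sphere_cavity_pressure(V - h, t, cavity)) / (2 * h)
  1 / dp
}

# ---------------------------------------------------------------------------
# Enclosed volume of a closed triangulated surface

#' Enclosed volume of a closed triangulated surface
#'
#' Divergence-theorem volume
#' \eqn{V = \frac{1}{3}\left|\oint x \cdot n \, d\Gamma\right|}, evaluated
#' exactly on the triangulation as a signed tetrahedron sum.  The surface must
#' be closed and consistently oriented: every directed edge must be matched by
#' its reverse in exactly one other face.
#'
#' @param mesh list with `vertices` (n x 3 numeric) and `faces` (m x 3 integer,
#'   1-based).
#' @return Enclosed volume (m^3).
#' @export
surface_volume <- function(mesh) {
  V <- mesh$vertices
  FF <- mesh$faces
  e <- rbind(FF[, c(1, 2)], FF[, c(2, 3)], FF[, c(3, 1)])
  key <- paste(e[, 1], e[, 2])
  rkey <- paste(e[, 2], e[, 1])
  if (anyDuplicated(key) || !all(key %in% rkey))
    stop("invalid surface: boundary or inconsistently oriented edges present")
  x1 <- V[FF[, 1], , drop = FALSE]
  x2 <- V[FF[, 2], , drop = FALSE]
  x3 <- V[FF[, 3], , drop = FALSE]
  det3 <- x1[, 1] * (x2[, 2] * x3[, 3] - x2[, 3] * x3[, 2]) -
    x1[, 2] * (x2[, 1] * x3[, 3] - x2[, 3] * x3[, 1]) +
    x1[, 3] * (x2[, 1] * x3[, 2] - x2[, 2] * x3[, 1])
  abs(sum(det3)) / 6
}

#' Read an ASCII OFF triangle mesh
#'
#' @param path file path.
#' @return list with `vertices` and `faces`, usable by [surface_volume()].
#' @export
read_surface_off <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (toupper(ln[1]) != "OFF") stop("not an OFF file")
  hdr <- scan(text = ln[2], quiet = TRUE)
  nv <- hdr[1]; nf <- hdr[2]
  verts <- matrix(scan(text = paste(ln[3:(2 + nv)], collapse = "\n"),
                       quiet = TRUE), ncol = 3, byrow = TRUE)
  fl <- matrix(scan(text = paste(ln[(3 + nv):(2 + nv + nf)], collapse = "\n"),
                    quiet = TRUE), ncol = 4, byrow = TRUE)
  if (any(fl[, 1] != 3)) stop("only triangle meshes are supported")
  list(vertices = verts, faces = fl[, 2:4] + 1L)
}

#' Triangulated unit icosphere
#'
#' Recursively subdivided icosahedron projected onto the unit sphere; handy as
#' a convergent test surface for [surface_volume()].
#'
#' @param refinements number of subdivision passes.
#' @return list with `vertices` and `faces`.
#' @export
icosphere <- function(refinements = 2) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (r in seq_len(refinements)) {
    mid <- new.env()
    nv <- nrow(v)
    vl <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(i, j) {
      k <- paste(min(i, j), max(i, j))
      id <- mid[[k]]
      if (!is.null(id)) return(id)
      m <- (vl[[i]] + vl[[j]]) / 2
      m <- m / sqrt(sum(m^2))
      vl[[length(vl) + 1]] <<- m
      id <- length(vl)
      assign(k, id, envir = mid)
      id
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vl)
    f <- nf
  }
  list(vertices = v, faces = f)
}
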