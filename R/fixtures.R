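# Fixture generators for the benchmark networks: a single aortic segment, the
# same segment with a mid-length stenosis, and a small bifurcating surrogate
# tree.  Geometric and terminal defaults are documented physiological choices
# (10 mm aortic radius, 1.5 mm wall, RCR values giving ~120/70 mmHg at the
# default inflow); all of them are arguments.

.MMHG <- 133.322

#' Analytic inflow waveform
#'
#' Half-sine systolic flow pulse followed by zero diastolic flow:
#' `Q(t) = peak_flow * sin(pi t / T_sys)` for `t < T_sys`, with
#' `T_sys = systole_fraction * period`.  The implied stroke volume
#' `2 * peak_flow * T_sys / pi` is stored in the `stroke_volume` attribute.
#'
#' @param period cycle length (s); 1.231 s baseline, 0.800 s for the tree case.
#' @param peak_flow peak aortic flow (m^3/s).
#' @param systole_fraction systolic fraction of the cycle.
#' @return An [inflow_bc()] of kind "flow".
#' @export
make_inflow_waveform <- function(period = 1.231, peak_flow = 3e-4,
                                 systole_fraction = 0.3) {
  stopifnot(period > 0, peak_flow >= 0,
            systole_fraction > 0, systole_fraction < 1)
  Ts <- systole_fraction * period
  fn <- function(t) ifelse(t < Ts, peak_flow * sin(pi * t / Ts), 0)
  bc <- inflow_bc("flow", period = period, fn = fn)
  attr(bc, "stroke_volume") <- 2 * peak_flow * Ts / pi
  attr(bc, "t_systole") <- Ts
  bc
}

# default matched characteristic impedance of a vessel outlet
.matched_Z <- function(v) {
  n <- v$n_elem
  c0 <- sqrt(v$K[n] / (2 * v$rho * sqrt(v$A0[n])))
  v$rho * c0 / v$A0[n]
}

#' Single-vessel benchmark network
#'
#' One uniform compliant vessel closed by an RCR Windkessel terminal, with a
#' half-sine inflow waveform attached.  `length = 0.200` m is the time-step
#' robustness fixture; `length = 0.126` m the arterial-stiffening fixture.
#'
#' @param length vessel length (m).
#' @param E Young modulus (Pa), > 0.
#' @param radius lumen radius (m).
#' @param h wall thickness (m).
#' @param phi_w wall viscosity (Pa s).
#' @param dx target element size (m); the element count is rounded.
#' @param R,C,P_out terminal peripheral resistance (Pa s/m^3), compliance
#'   (m^3/Pa) and outflow pressure (Pa).
#' @param Z terminal characteristic impedance; `NULL` = matched to the vessel.
#' @param period,peak_flow inflow waveform parameters.
#' @param rho,mu,zeta blood density, viscosity and profile constant.
#' @return An [arterial_network()].
#' @export
make_single_vessel <- function(length = 0.200, E = 0.25e6, radius = 0.010,
                               h = 1.5e-3, phi_w = 0, dx = 2.5e-3,
                               R = 2.0e8, C = 9e-9, P_out = 0, Z = NULL,
                               period = 1.231, peak_flow = 3e-4,
                               rho = 1060, mu = 4e-3, zeta = 9) {
  if (E <= 0) stop("invalid fixture: Young modulus must be positive")
  n_elem <- max(4L, as.integer(round(length / dx)))
  A0 <- pi * radius^2
  v <- vessel_segment(1L, length, n_elem, A0, A0, E = E, h = h, phi_w = phi_w,
                      rho = rho, mu = mu, zeta = zeta)
  if (is.null(Z)) Z <- .matched_Z(v)
  term <- windkessel_terminal(Z, R, C, P_out, vessel = 1L)
  arterial_network(
    vessels = list(v),
    terminals = list(term),
    inlet = list(vessel = 1L, kind = "flow",
                 waveform = make_inflow_waveform(period, peak_flow)))
}

#' Stenosed single-vessel network
#'
#' The 126 mm vessel with a lumped stenosis element embedded at an internal
#' interface.  A "30\% stenosis" is `area_ratio = 0.7`.
#'
#' @param length vessel length (m).
#' @param area_ratio stenotic to reference area ratio, in (0, 1).
#' @param pos_frac stenosis position as a fraction of length, in (0, 1).
#' @param Ls stenosis length (m).
#' @param Kv,Kt,Ku stenosis coefficients; `Kv = NULL` resolves to
#'   `32 Ls / D0`.
#' @inheritParams make_single_vessel
#' @return An [arterial_network()].
#' @export
make_stenotic_vessel <- function(length = 0.126, area_ratio = 0.7,
                                 E = 0.25e6, pos_frac = 0.5, Ls = 0.02,
                                 Kv = NULL, Kt = 1.52, Ku = 1.2,
                                 radius = 0.010, h = 1.5e-3, phi_w = 0,
                                 dx = 2.5e-3, R = 2.0e8, C = 9e-9, P_out = 0,
                                 Z = NULL, period = 1.231, peak_flow = 3e-4,
                                 rho = 1060, mu = 4e-3, zeta = 9) {
  if (pos_frac <= 0 || pos_frac >= 1)
    stop("invalid fixture: stenosis position fraction must be inside (0, 1)")
  net <- make_single_vessel(length, E, radius, h, phi_w, dx, R, C, P_out, Z,
                            period, peak_flow, rho, mu, zeta)
  el <- stenosis_element(area_ratio, Ls, Kv, Kt, Ku)
  n_elem <- net$vessels[[1]]$n_elem
  iface <- min(max(1L, as.integer(round(pos_frac * n_elem))), n_elem - 1L)
  D0 <- 2 * radius
  sten <- list(vessel = 1L, pos_frac = pos_frac, iface = iface,
               area_ratio = area_ratio, Ls = Ls,
               Kv = if (is.null(el$Kv)) 32 * Ls / D0 else el$Kv,
               Kt = Kt, Ku = Ku, q_state = 0)
  net$stenoses <- list(sten)
  net
}

#' Bifurcating-tree surrogate network
#'
#' Symmetric tree of `generations` bifurcation levels emulating the path from
#' the aortic root towards a peripheral (brachial-like) artery: daughter radii
#' follow a Murray-type ratio `2^{-1/3}`, vessels taper mildly, wall stiffness
#' increases distally, and every leaf carries an RCR terminal.  The `aged`
#' profile scales every Young modulus by `E_age_factor` and every peripheral
#' resistance by `R_age_factor` (arterial stiffening and increased systemic
#' resistance with healthy ageing).
#'
#' @param generations number of bifurcation levels (>= 1).
#' @param age_profile "young" or "aged".
#' @param root_radius,root_length root vessel radius and length (m).
#' @param E0 root Young modulus (Pa) of the young profile.
#' @param E_gen_factor distal stiffening factor per generation.
#' @param E_age_factor,R_age_factor aged-profile scalings.
#' @param R_total target total peripheral resistance (Pa s/m^3) of the young
#'   profile, distributed evenly over the leaves.
#' @param C_total total peripheral compliance (m^3/Pa), likewise distributed.
#' @param period,peak_flow inflow waveform (the tree case runs at 0.8 s).
#' @param dx target element size (m).
#' @param rho,mu,zeta blood properties.
#' @return An [arterial_network()].
#' @export
make_bifurcating_tree <- function(generations = 3,
                                  age_profile = c("young", "aged"),
                                  root_radius = 0.012, root_length = 0.12,
                                  E0 = 0.3e6, E_gen_factor = 1.3,
                                  E_age_factor = 2.0, R_age_factor = 1.3,
                                  R_total = 1.45e8, C_total = 5e-9,
                                  period = 0.800, peak_flow = 4.5e-4,
                                  dx = 2.5e-3, rho = 1060, mu = 4e-3,
                                  zeta = 9) {
  stopifnot(generations >= 1)
  age_profile <- match.arg(age_profile)
  aged <- age_profile == "aged"
  taper <- 0.90       # outlet/inlet reference-area ratio within a vessel
  murray <- 2^(-1 / 3)

  junctions <- list()
  terminals <- list()
  # breadth-first construction; children inherit their parent's outlet radius
  vessels <- list(); idx <- 0L
  nodes <- list(list(gen = 0L, r_in = root_radius, parent = NA))
  i <- 1L
  while (i <= length(nodes)) {
    nd <- nodes[[i]]
    idx <- idx + 1L
    g <- nd$gen
    L <- root_length * 0.75^g
    A_in <- pi * nd$r_in^2
    A_out <- taper * A_in
    E <- E0 * E_gen_factor^g * (if (aged) E_age_factor else 1)
    h <- 0.12 * nd$r_in
    n_elem <- max(4L, as.integer(round(L / dx)))
    vessels[[idx]] <- vessel_segment(idx, L, n_elem, A_in, A_out, E = E,
                                     h = h, rho = rho, mu = mu, zeta = zeta)
    if (g < generations) {
      r_child <- sqrt(A_out / pi) * murray
      nodes[[length(nodes) + 1]] <- list(gen = g + 1L, r_in = r_child, parent = idx)
      nodes[[length(nodes) + 1]] <- list(gen = g + 1L, r_in = r_child, parent = idx)
    }
    i <- i + 1L
  }
  # junctions from the recorded parents (children appear in order)
  parents <- vapply(nodes, function(n) if (is.na(n$parent)) 0L else as.integer(n$parent),
                    integer(1))
  for (p in unique(parents[parents > 0L]))
    junctions[[length(junctions) + 1]] <- list(parent = p,
                                               children = which(parents == p))
  leaves <- setdiff(seq_along(vessels),
                    vapply(junctions, function(j) j$parent, integer(1)))
  n_leaf <- length(leaves)
  R_leaf <- R_total * n_leaf * (if (aged) R_age_factor else 1)
  C_leaf <- C_total / n_leaf
  for (lv in leaves)
    terminals[[length(terminals) + 1]] <-
      windkessel_terminal(.matched_Z(vessels[[lv]]), R_leaf, C_leaf, 0,
                          vessel = lv)
  arterial_network(
    vessels = vessels, junctions = junctions, terminals = terminals,
    inlet = list(vessel = 1L, kind = "flow",
                 waveform = make_inflow_waveform(period, peak_flow)))
}
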