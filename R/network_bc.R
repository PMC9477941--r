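#' Three-element Windkessel terminal
#'
#' Lumped model of the distal vasculature: characteristic impedance `Z` in
#' series with a parallel peripheral resistance `R` and compliance `C`,
#' discharging against the outflow pressure `P_out`.  The governing relation,
#' with terminal pressure `P` and through-flow `Q`, is
#' \deqn{Q (1 + Z/R) + C Z \,\partial_t Q = (P - P_{out})/R + C\, \partial_t P,}
#' integrated implicitly (backward Euler) in the capacitor pressure.
#'
#' @param Z characteristic impedance (Pa s/m^3), >= 0.
#' @param R peripheral resistance (Pa s/m^3), > 0.
#' @param C peripheral compliance (m^3/Pa), >= 0.
#' @param P_out pressure at which microcirculatory flow vanishes (Pa).
#' @param P_state initial capacitor pressure (Pa); defaults to `P_out`.
#' @param vessel index of the vessel the terminal closes.
#' @return An object of class `windkessel_terminal`.
#' @export
windkessel_terminal <- function(Z, R, C, P_out = 0, P_state = NULL,
                                vessel = NA_integer_) {
  if (R <= 0) stop("invalid terminal: R must be positive")
  if (Z < 0 || C < 0) stop("invalid terminal: Z and C must be non-negative")
  structure(list(vessel = vessel, Z = Z, R = R, C = C, P_out = P_out,
                 P_state = if (is.null(P_state)) P_out else P_state),
            class = "windkessel_terminal")
}

#' Advance a Windkessel terminal coupled to a vessel end
#'
#' Solves the boundary state `(A, Q)` at the distal vessel end from the
#' outgoing (forward) characteristic of the vessel together with the implicit
#' RCR update, and advances the internal capacitor pressure.  In the steady
#' limit the boundary pressure satisfies `P = P_out + Q (R + Z)`.
#'
#' @param term a [windkessel_terminal()].
#' @param vessel_end_state numeric `c(A, Q)` of the last element.
#' @param wall a [wall_properties()] for the last element.
#' @param dt time step (s).
#' @return list with `A`, `Q` (boundary state) and the updated `term`.
#' @export
windkessel_step <- function(term, vessel_end_state, wall, dt) {
  stopifnot(dt > 0)
  out <- .cw_bc_windkessel(vessel_end_state[1], vessel_end_state[2],
                           wall$A0, wall$K, wall$rho, wall$P_ext,
                           term$Z, term$R, term$C, term$P_out,
                           term$P_state, dt)
  term$P_state <- out[["P_state"]]
  list(A = out[["A"]], Q = out[["Q"]], term = term)
}

# implicit capacitor update alone (used by tests of the lumped ODE)
.windkessel_update <- function(term, Q, dt) {
  .cw_wk_update(term$P_state, Q, dt, term$R, term$C, term$P_out)
}

#' Solve a junction between a parent and its children
#'
#' Newton solve of signed mass conservation and continuity of (total)
#' pressure across the junction, using the outgoing characteristic of every
#' connected vessel end.
#'
#' @param parent_end_state numeric `c(A, Q)` at the parent outlet.
#' @param child_start_states `2 x n` matrix (rows `A`, `Q`) at the child inlets.
#' @param parent_wall,child_walls [wall_properties()] for the parent end and a
#'   list of them for the child inlets.
#' @param total_pressure match total pressure `P + rho u^2 / 2` (default) or
#'   static pressure.
#' @return list with `parent` (c(A, Q)), `children` (2 x n matrix) and the
#'   final `mass_residual` (m^3/s) and `pressure_residual` (Pa).
#' @export
junction_solve <- function(parent_end_state, child_start_states,
                           parent_wall, child_walls, total_pressure = TRUE) {
  if (!is.matrix(child_start_states))
    child_start_states <- matrix(child_start_states, nrow = 2)
  nc <- ncol(child_start_states)
  cw <- matrix(0, 2, nc)
  for (i in seq_len(nc)) {
    cw[1, i] <- child_walls[[i]]$A0
    cw[2, i] <- child_walls[[i]]$K
  }
  res <- .cw_junction_solve(parent_end_state,
                            c(parent_wall$A0, parent_wall$K),
                            child_start_states, cw,
                            parent_wall$rho, parent_wall$P_ext,
                            total_pressure)
  list(parent = res$states[, 1], children = res$states[, -1, drop = FALSE],
       mass_residual = res$mass_residual,
       pressure_residual = res$pressure_residual)
}

#' Lumped stenosis element
#'
#' Young–Tsai-type lumped description of a local narrowing: viscous, turbulent
#' and inertial contributions to the trans-stenotic pressure drop.  The
#' coefficients are exposed; `Kv = 32 L_s / D_0` (Poiseuille profile factor)
#' when left `NULL` at placement time.
#'
#' @param area_ratio ratio `A_s / A_0` in (0, 1); a "30\% stenosis" is 0.7.
#' @param Ls stenosis length (m).
#' @param Kv,Kt,Ku viscous / turbulent / inertial coefficients.
#' @return An object of class `stenosis_element`.
#' @export
stenosis_element <- function(area_ratio, Ls = 0.02, Kv = NULL, Kt = 1.52,
                             Ku = 1.2) {
  if (area_ratio <= 0 || area_ratio >= 1)
    stop("stenosis area ratio must lie strictly between 0 and 1")
  structure(list(area_ratio = area_ratio, Ls = Ls, Kv = Kv, Kt = Kt, Ku = Ku,
                 q_state = 0),
            class = "stenosis_element")
}

#' Trans-stenotic pressure drop
#'
#' \deqn{\Delta p = \frac{K_v \mu}{A_0 D_0} q
#'   + \frac{K_t \rho}{2 A_0^2}\left(\frac{A_0}{A_s} - 1\right)^2 q |q|
#'   + \frac{K_u \rho L_s}{A_0} \dot q.}
#'
#' @param elem a [stenosis_element()] (with `Kv` resolved).
#' @param q through-flow (m^3/s).
#' @param dq_dt flow acceleration (m^3/s^2).
#' @param rho blood density (kg/m^3).
#' @param mu dynamic viscosity (Pa s).
#' @param A0 reference area at the stenosis site (m^2).
#' @param D0 reference diameter (m); default from `A0`.
#' @return Pressure drop (Pa).
#' @export
stenosis_dp <- function(elem, q, dq_dt = 0, rho = 1060, mu = 4e-3,
                        A0, D0 = 2 * sqrt(A0 / pi)) {
  Kv <- if (is.null(elem$Kv)) 32 * elem$Ls / D0 else elem$Kv
  As <- elem$area_ratio * A0
  Kv * mu / (A0 * D0) * q +
    elem$Kt * rho / (2 * A0^2) * (A0 / As - 1)^2 * q * abs(q) +
    elem$Ku * rho * elem$Ls / A0 * dq_dt
}

#' Inlet boundary condition
#'
#' A periodic flow or pressure waveform imposed at the network root, combined
#' at run time with the vessel's backward characteristic.  Either an analytic
#' closure `fn(t)` (vectorised, one period) or a sampled `table` must be
#' given; lookups outside the period wrap periodically.
#'
#' @param kind "flow" (m^3/s) or "pressure" (Pa).
#' @param period waveform period (s).
#' @param fn optional vectorised function of time over one period.
#' @param table optional data frame with columns `t`, `value`.
#' @return An object of class `inflow_bc`.
#' @export
inflow_bc <- function(kind = c("flow", "pressure"), period, fn = NULL,
                      table = NULL) {
  kind <- match.arg(kind)
  stopifnot(period > 0)
  if (is.null(fn) && is.null(table)) stop("need fn or table")
  if (!is.null(table)) {
    stopifnot(all(c("t", "value") %in% names(table)))
    if (is.unsorted(table$t, strictly = TRUE)) stop("waveform samples must be strictly increasing in t")
    if (min(table$t) < 0 || max(table$t) > period) stop("waveform must cover one period")
  }
  structure(list(kind = kind, period = period, fn = fn, table = table),
            class = "inflow_bc")
}

# waveform value at time t (periodic wrap)
.inflow_value <- function(bc, t) {
  tp <- t %% bc$period
  if (!is.null(bc$fn)) return(bc$fn(tp))
  tab <- bc$table
  # wrap-around interpolation between last and first sample
  stats::approx(c(tab$t, bc$period + tab$t[1]), c(tab$value, tab$value[1]),
                xout = tp, rule = 2)$y
}

#' Apply the inlet boundary condition at a vessel start
#'
#' Prescribes the waveform value (flow or pressure) at time `t` and solves the
#' remaining boundary variable from the vessel's backward characteristic.
#'
#' @param bc an [inflow_bc()].
#' @param vessel_start_state numeric `c(A, Q)` of the first element.
#' @param wall [wall_properties()] of the first element.
#' @param t time (s); wrapped periodically.
#' @return named numeric `c(A, Q)` boundary state.
#' @export
inflow_apply <- function(bc, vessel_start_state, wall, t) {
  v <- .inflow_value(bc, t)
  .cw_bc_inflow(vessel_start_state[1], vessel_start_state[2],
                wall$A0, wall$K, wall$rho, wall$P_ext,
                if (bc$kind == "flow") 0L else 1L, v)
}
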