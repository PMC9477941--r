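#' Aortic valve model
#'
#' Bernoulli resistor plus blood inertance acting as a diode between the
#' cavity and the network root:
#' \deqn{p_{cav} - p_{root} = B\, q |q| + L_{in}\, \dot q, \qquad q \ge 0.}
#' The valve opens when cavity pressure exceeds root pressure and closes when
#' the implicit flow update would become negative (no regurgitation).
#'
#' @param B Bernoulli resistance coefficient (Pa s^2/m^6); the default
#'   corresponds to an effective orifice area of about 3.5 cm^2.
#' @param L_in blood inertance (Pa s^2/m^3).
#' @return An object of class `valve_model` with fields `state` and `q`.
#' @export
valve_model <- function(B = 4.5e9, L_in = 5e4) {
  stopifnot(B > 0, L_in >= 0)
  structure(list(B = B, L_in = L_in, state = "closed", q = 0),
            class = "valve_model")
}

#' Implicit valve flow update
#'
#' Advances the lumped valve law over `dt` at a given pressure difference.
#' Closed valves open when `p_cav > p_root`; open valves close when the
#' implicit flow solution is non-positive.
#'
#' @param p_cav,p_root cavity and root pressures (Pa).
#' @param valve a [valve_model()].
#' @param dt time step (s).
#' @return list with `q` (m^3/s) and the updated `valve`.
#' @export
valve_flow <- function(p_cav, p_root, valve, dt) {
  stopifnot(dt > 0)
  dp <- p_cav - p_root
  if (valve$state == "closed") {
    if (dp <= 0) { valve$q <- 0; return(list(q = 0, valve = valve)) }
    valve$state <- "open"
  }
  # solve B q^2 + (L/dt) q - (dp + L q0/dt) = 0 for q >= 0
  a <- valve$B
  b <- valve$L_in / dt
  cc <- dp + b * valve$q
  if (cc <= 0) {
    valve$state <- "closed"; valve$q <- 0
    return(list(q = 0, valve = valve))
  }
  q <- (-b + sqrt(b^2 + 4 * a * cc)) / (2 * a)
  valve$q <- q
  list(q = q, valve = valve)
}

#' Coupling configuration
#'
#' @param dt3D coupling step (s); the heart-side resolution at which the
#'   saddle-point system is solved.
#' @param dt1D vascular substep (s); the 1D solver sub-cycles within each
#'   coupling step.  Must not exceed `dt3D`.
#' @param k_max maximal Newton steps per coupling step.
#' @param tol_abs absolute residual tolerance, in units of `V_scale`.
#' @param V_scale volume scale of the residual tolerance (m^3); default 1 mL.
#' @param fd_eps pressure perturbation of the finite-difference vascular
#'   compliance (Pa).
#' @param max_halvings Newton safeguarding: number of step halvings attempted
#'   when a trial pressure destabilises the 1D solver.
#' @param hysteresis phase-trigger hysteresis band (Pa).
#' @return list of class `coupling_config`.
#' @export
coupling_config <- function(dt3D = 1e-3, dt1D = 1e-4, k_max = 10,
                            tol_abs = 1e-6, V_scale = 1e-6, fd_eps = 10,
                            max_halvings = 5, hysteresis = 1) {
  stopifnot(k_max >= 1, tol_abs > 0, dt1D <= dt3D, dt1D > 0, fd_eps > 0)
  structure(list(dt3D = dt3D, dt1D = dt1D, k_max = k_max, tol_abs = tol_abs,
                 V_scale = V_scale, fd_eps = fd_eps,
                 max_halvings = max_halvings, hysteresis = hysteresis),
            class = "coupling_config")
}

# number of vascular substeps per coupling step
.n_sub <- function(cfg) max(1L, as.integer(round(cfg$dt3D / cfg$dt1D)))

#' Vascular volume predicted at a trial cavity pressure
#'
#' Evaluates \eqn{V^{CS}(p) = V^n - \int_{t^n}^{t^n + dt3D} q(p)\, dt} by
#' running the valve and 1D network, sub-stepped at `dt1D`, from the committed
#' snapshot with the trial cavity pressure held constant.  The committed
#' network state is never modified; repeated evaluations at the same pressure
#' are bit-identical.
#'
#' @param p_trial trial cavity pressure (Pa).
#' @param network committed [arterial_network()] snapshot.
#' @param valve a [valve_model()] (its `q` is the inertial memory state).
#' @param cfg a [coupling_config()].
#' @param V_n committed cavity volume at the start of the step (m^3).
#' @param t0 start time of the step (s).
#' @return list with `V_CS`, `ejected` (m^3) and the raw run result `res`.
#' @export
vascular_volume <- function(p_trial, network, valve, cfg, V_n, t0 = 0) {
  inlet <- list(type = 3L, p_cav = p_trial, B = valve$B, L = valve$L_in,
                q0 = valve$q)
  nsub <- .n_sub(cfg)
  res <- .cw_run(.net_flat(network), inlet, cfg$dt3D / nsub, nsub, t0,
                 network$vessels[[1]]$mu, matrix(integer(0), 0, 2), 0L)
  list(V_CS = V_n - res$vol_in, ejected = res$vol_in, res = res)
}

#' Finite-difference vascular compliance
#'
#' Central-difference approximation of \eqn{dV^{CS}/dp} about a trial
#' pressure, both evaluations taken from the same committed snapshot.
#'
#' @inheritParams vascular_volume
#' @param fd_eps pressure perturbation (Pa); defaults to `cfg$fd_eps`.
#' @return Compliance (m^3/Pa), non-positive in normal operation.
#' @export
coupling_compliance <- function(p_trial, network, valve, cfg, V_n, t0 = 0,
                                fd_eps = cfg$fd_eps) {
  vp <- vascular_volume(p_trial + fd_eps, network, valve, cfg, V_n, t0)
  vm <- vascular_volume(p_trial - fd_eps, network, valve, cfg, V_n, t0)
  (vp$V_CS - vm$V_CS) / (2 * fd_eps)
}

# generic afterload evaluator: network-based by default, but any object
# implementing these two verbs can stand in (tests use a linear surrogate)
.afterload_VCS <- function(af, p) {
  if (is.function(af$V_CS)) return(list(V_CS = af$V_CS(p), res = NULL))
  vascular_volume(p, af$network, af$valve, af$cfg, af$V_n, af$t0)
}
.afterload_dVdp <- function(af, p) {
  if (is.function(af$V_CS)) {
    e <- af$cfg$fd_eps
    return((af$V_CS(p + e) - af$V_CS(p - e)) / (2 * e))
  }
  coupling_compliance(p, af$network, af$valve, af$cfg, af$V_n, af$t0)
}

#' One monolithic coupled step (ejection phase)
#'
#' Newton iteration on the Schur-reduced scalar system: residual
#' \eqn{r(p) = V^{heart}(p, t^{n+1}) - V^{CS}(p)}, Jacobian
#' \eqn{dV^{heart}/dp - dV^{CS}/dp} with the vascular compliance from
#' [coupling_compliance()].  Stops when \eqn{|r| < tol_{abs} V_{scale}} or
#' after `k_max` steps; on success the converged trial run is committed and
#' the cavity volume advanced by exactly the ejected volume.
#'
#' @param state coupling state list with `p_cav`, `V_cav`, `t`.
#' @param cavity a cavity object (elastance or sphere).
#' @param network committed [arterial_network()].
#' @param cfg a [coupling_config()].
#' @param valve a [valve_model()].
#' @param afterload optional afterload override (see tests); defaults to the
#'   network trial evaluator.
#' @return list with updated `state`, `network`, `valve`.
#' @export
newton_coupled_step <- function(state, cavity, network, cfg, valve,
                                afterload = NULL) {
  t1 <- state$t + cfg$dt3D
  V_n <- state$V_cav
  af <- if (is.null(afterload))
    list(network = network, valve = valve, cfg = cfg, V_n = V_n, t0 = state$t)
  else afterload
  # start from the extrapolated pressure trend (the trajectory is smooth in
  # time, so this lands near the root even at ejection onset)
  trend <- if (is.null(state$dp_trend) || !is.finite(state$dp_trend)) 0
           else state$dp_trend
  p <- state$p_cav + trend
  Vh <- cavity_volume(cavity, p, t1, V_init = V_n)
  hist <- numeric(0)
  iters <- 0L
  trial <- .afterload_VCS(af, p)
  r <- Vh - trial$V_CS
  hist <- c(hist, r)
  tol <- cfg$tol_abs * cfg$V_scale
  # r(p) is increasing in p (dV_heart/dp > 0, dV_CS/dp <= 0), so a sign
  # change brackets the root; Newton proposals are capped (the cavity p-V
  # relation is strongly convex) and fall back to bisection of the bracket
  p_lo <- p_hi <- NA_real_
  note <- function(pp, rr) {
    if (rr < 0) p_lo <<- pp else p_hi <<- pp
  }
  note(p, r)
  eval_at <- function(p_try) {
    new_trial <- tryCatch(.afterload_VCS(af, p_try), error = function(e) e)
    if (inherits(new_trial, "error")) return(NULL)
    Vh_try <- tryCatch(cavity_volume(cavity, p_try, t1, V_init = Vh),
                       error = function(e) e)
    if (inherits(Vh_try, "error")) return(NULL)
    list(p = p_try, trial = new_trial, Vh = Vh_try,
         r = Vh_try - new_trial$V_CS)
  }
  while (abs(r) >= tol) {
    if (iters >= cfg$k_max)
      stop(sprintf(
        "coupled Newton: no convergence in %d steps; residual history (m^3): %s",
        cfg$k_max, paste(signif(hist, 4), collapse = ", ")))
    J <- cavity_dVdp(cavity, p, t1, V = Vh) - .afterload_dVdp(af, p)
    dp <- -r / J
    if (!is.finite(dp)) dp <- sign(-r) * max(abs(p), 1e3)
    cand <- p + dp
    have_bracket <- is.finite(p_lo) && is.finite(p_hi)
    if (have_bracket) {
      lo <- min(p_lo, p_hi); hi <- max(p_lo, p_hi)
      if (cand <= lo || cand >= hi) cand <- 0.5 * (lo + hi)
    }
    got <- eval_at(cand)
    if (is.null(got)) {
      # trial failure: retreat towards the current iterate
      for (h in seq_len(cfg$max_halvings)) {
        got <- eval_at(p + (cand - p) / 2^h)
        if (!is.null(got)) break
      }
      if (is.null(got))
        stop("coupled Newton: trial failure persists after step halving")
    } else if (abs(got$r) >= abs(r) && have_bracket) {
      # no residual reduction: bisect the bracket instead (always shrinks it)
      mid <- eval_at(0.5 * (min(p_lo, p_hi) + max(p_lo, p_hi)))
      if (!is.null(mid)) got <- mid
    }
    note(got$p, got$r)
    p <- got$p; trial <- got$trial; Vh <- got$Vh; r <- got$r
    hist <- c(hist, r)
    iters <- iters + 1L
  }
  state$p_cav <- p
  state$t <- t1
  state$newton_iters <- iters
  state$residual <- r
  if (!is.null(trial$res)) {
    network <- .net_commit(network, trial$res)
    valve$q <- trial$res$valve_q
    valve$state <- if (trial$res$valve_q > 0) "open" else "closed"
    state$V_cav <- V_n - trial$res$vol_in
    state$p_root <- trial$res$inlet_P
    state$q <- trial$res$valve_q
  } else {
    state$V_cav <- trial$V_CS
  }
  list(state = state, network = network, valve = valve, res = trial$res)
}

#' One isovolumetric coupling step
#'
#' With all valves closed the vascular volume is frozen
#' (\eqn{C' = 0}, \eqn{V^{CS} = V_0}); the cavity pressure is found by Newton
#' iteration on \eqn{V^{heart}(p, t^{n+1}) = V_0} with Jacobian
#' \eqn{dV^{heart}/dp} alone.
#'
#' @inheritParams newton_coupled_step
#' @return updated `state` (pressure adjusted, volume held at `V0`).
#' @export
isovolumetric_step <- function(state, cavity, cfg) {
  t1 <- state$t + cfg$dt3D
  V0 <- state$V0
  trend <- if (is.null(state$dp_trend) || !is.finite(state$dp_trend)) 0
           else state$dp_trend
  p <- state$p_cav + trend
  tol <- cfg$tol_abs * cfg$V_scale
  Vh <- cavity_volume(cavity, p, t1, V_init = V0)
  r <- Vh - V0
  iters <- 0L
  while (abs(r) >= tol) {
    if (iters >= cfg$k_max)
      stop(sprintf("isovolumetric Newton: no convergence; |r| = %g m^3", abs(r)))
    J <- cavity_dVdp(cavity, p, t1, V = Vh)
    p <- p - r / J
    Vh <- cavity_volume(cavity, p, t1, V_init = Vh)
    r <- Vh - V0
    iters <- iters + 1L
  }
  state$p_cav <- p
  state$V_cav <- V0
  state$t <- t1
  state$newton_iters <- iters
  state$residual <- r
  state
}

# advance the network with a closed inlet over one coupling step
.advance_closed <- function(network, cfg, t0) {
  nsub <- .n_sub(cfg)
  res <- .cw_run(.net_flat(network), list(type = 2L), cfg$dt3D / nsub, nsub,
                 t0, network$vessels[[1]]$mu, matrix(integer(0), 0, 2), 0L)
  list(network = .net_commit(network, res), p_root = res$inlet_P, res = res)
}

#' Simulate coupled cardiac cycles
#'
#' Runs the four-phase cardiac cycle against the 1D network: filling at a
#' prescribed preload pressure, isovolumetric contraction once active stress
#' onsets, ejection through the aortic valve solved by the monolithic
#' saddle-point Newton step, and isovolumetric relaxation after valve closure.
#' The network keeps running (sub-stepped at `dt1D`) in every phase.
#'
#' @param cavity a cavity object ([elastance_cavity()] or [sphere_cavity()]).
#' @param network an initialised [arterial_network()] (see [run_standalone()]).
#' @param cfg a [coupling_config()].
#' @param n_beats number of beats.
#' @param period heart period (s); defaults to the cavity's period.
#' @param valve a [valve_model()].
#' @param preload prescribed filling (left-atrial) pressure (Pa).
#' @param t0 start time (s); beats are aligned to multiples of the period.
#' @param probes optional 2-column matrix `(vessel, element)`: the elastic
#'   pressure at these sites is appended to the trace (columns `P_1`, ...)
#'   after every committed coupling step.
#' @return list with `trace` (one row per coupling step: time, phase, cavity
#'   pressure and volume, root pressure, valve flow, Newton diagnostics),
#'   `beats` (per-beat EDV, ESV, SV, ejection fraction, peak pressures),
#'   and the final `network`, `valve`, `state`.
#' @export
run_cardiac_cycle <- function(cavity, network, cfg, n_beats = 3,
                              period = cavity$period, valve = valve_model(),
                              preload = 1333.22, t0 = 0, probes = NULL) {
  probe_p <- function(net) {
    if (is.null(probes)) return(NULL)
    vapply(seq_len(nrow(probes)), function(j) {
      v <- net$vessels[[probes[j, 1]]]
      e <- probes[j, 2]
      v$P_ext + v$K[e] * (sqrt(v$A[e]) - sqrt(v$A0[e])) / v$A0[e]
    }, numeric(1))
  }
  act <- cavity$act
  n_steps <- as.integer(round(n_beats * period / cfg$dt3D))
  in_active <- function(t) {
    ts <- (t - act$t_a - act$t_emd) %% period
    ts < act$t_dur
  }
  beat_index <- function(t) floor((t - act$t_a - act$t_emd) / period + 1e-9)
  last_beat <- beat_index(t0) - 1L  # each beat triggers contraction once
  state <- list(phase = "filling", p_cav = preload,
                V_cav = cavity_volume(cavity, preload, t0),
                V0 = NA_real_, t = t0, p_root = NA_real_, q = 0,
                newton_iters = 0L, residual = 0)
  tr <- vector("list", n_steps)
  beats <- list()
  stored0 <- .net_stored_volume(network)
  cons <- c(vol_in = 0, micro_out = 0, cap_charge = 0,
            max_junc_defect = 0, max_junc_q = 0)
  take <- function(res) {
    cons["vol_in"] <<- cons[["vol_in"]] + res$vol_in
    cons["micro_out"] <<- cons[["micro_out"]] + res$micro_out
    cons["cap_charge"] <<- cons[["cap_charge"]] + res$cap_charge
    cons["max_junc_defect"] <<- max(cons[["max_junc_defect"]], res$max_junc_defect)
    cons["max_junc_q"] <<- max(cons[["max_junc_q"]], res$max_junc_q)
  }
  cur_beat <- list(EDV = NA, ESV = NA, p_cav_max = -Inf, p_root_max = -Inf,
                   ejected = 0)
  same_phase <- 0L
  for (s in seq_len(n_steps)) {
    t <- state$t
    t1 <- t + cfg$dt3D
    phase0 <- state$phase
    p_before <- state$p_cav
    if (state$phase == "filling") {
      adv <- .advance_closed(network, cfg, t)
      take(adv$res)
      network <- adv$network
      state$p_root <- adv$p_root
      state$p_cav <- preload
      state$V_cav <- cavity_volume(cavity, preload, t1)
      state$t <- t1
      state$q <- 0
      state$newton_iters <- 0L
      if (in_active(t1) && beat_index(t1) > last_beat) {
        last_beat <- beat_index(t1)
        state$phase <- "isovol_contraction"
        state$V0 <- state$V_cav
        if (!is.na(cur_beat$EDV)) beats[[length(beats) + 1]] <- cur_beat
        cur_beat <- list(EDV = state$V_cav, ESV = NA, p_cav_max = -Inf,
                         p_root_max = -Inf, ejected = 0)
      }
    } else if (state$phase %in% c("isovol_contraction", "isovol_relaxation")) {
      adv <- .advance_closed(network, cfg, t)
      take(adv$res)
      network <- adv$network
      state <- isovolumetric_step(state, cavity, cfg)
      state$p_root <- adv$p_root
      state$q <- 0
      if (state$phase == "isovol_contraction") {
        if (state$p_cav > state$p_root + cfg$hysteresis) {
          state$phase <- "ejection"
          valve$state <- "open"
        } else if (!in_active(t1)) {
          state$phase <- "filling"  # activation too weak to eject
        }
      } else {
        if (state$p_cav < preload - cfg$hysteresis) {
          state$phase <- "filling"
        } else if (in_active(t1) && beat_index(t1) > last_beat) {
          # next activation arrived before relaxation finished
          last_beat <- beat_index(t1)
          state$phase <- "isovol_contraction"
          state$V0 <- state$V_cav
        }
      }
    } else { # ejection
      V_before <- state$V_cav
      out <- newton_coupled_step(state, cavity, network, cfg, valve)
      take(out$res)
      state <- out$state; network <- out$network; valve <- out$valve
      cur_beat$ejected <- cur_beat$ejected + (V_before - state$V_cav)
      if (state$q <= 0 && state$p_cav <= state$p_root + cfg$hysteresis) {
        state$phase <- "isovol_relaxation"
        state$V0 <- state$V_cav
        valve$state <- "closed"; valve$q <- 0
        cur_beat$ESV <- state$V_cav
      }
    }
    # pressure trend for next step's starting guess; the trajectory is
    # continuous through phase transitions
    state$dp_trend <- state$p_cav - p_before
    cur_beat$p_cav_max <- max(cur_beat$p_cav_max, state$p_cav)
    cur_beat$p_root_max <- max(cur_beat$p_root_max,
                               if (is.na(state$p_root)) -Inf else state$p_root)
    same_phase <- if (identical(phase0, state$phase)) same_phase + 1L else 0L
    if (same_phase > 2 * period / cfg$dt3D)
      stop("cycle error: phase machine made no transition within two periods")
    row <- data.frame(t = state$t, phase = state$phase,
                      p_cav = state$p_cav, V_cav = state$V_cav,
                      p_root = state$p_root, q = state$q,
                      newton_iters = state$newton_iters,
                      residual = state$residual)
    if (!is.null(probes)) {
      pp <- probe_p(network)
      for (j in seq_along(pp)) row[[paste0("P_", j)]] <- pp[j]
    }
    tr[[s]] <- row
  }
  if (!is.na(cur_beat$EDV)) beats[[length(beats) + 1]] <- cur_beat
  trace <- do.call(rbind, tr)
  bdf <- NULL
  if (length(beats)) {
    bdf <- do.call(rbind, lapply(seq_along(beats), function(i) {
      b <- beats[[i]]
      sv <- if (is.na(b$ESV)) NA_real_ else b$EDV - b$ESV
      data.frame(beat = i, EDV = b$EDV, ESV = b$ESV, SV = sv,
                 EF = sv / b$EDV, ejected = b$ejected,
                 p_cav_max = b$p_cav_max, p_root_max = b$p_root_max)
    }))
  }
  stored1 <- .net_stored_volume(network)
  conservation <- list(
    vol_in = cons[["vol_in"]], micro_out = cons[["micro_out"]],
    cap_charge = cons[["cap_charge"]],
    stored_change = stored1 - stored0,
    defect = cons[["vol_in"]] - cons[["micro_out"]] - cons[["cap_charge"]] -
      (stored1 - stored0),
    max_junc_defect = cons[["max_junc_defect"]],
    max_junc_q = cons[["max_junc_q"]])
  list(trace = trace, beats = bdf, network = network, valve = valve,
       state = state, conservation = conservation)
}
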