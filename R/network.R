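#' Arterial network of 1D segments
#'
#' Assembles vessel segments, bifurcation junctions, terminal Windkessel
#' elements, optional stenosis elements and an inlet description into a rooted
#' tree.  Vessel 1 is the root (inlet) vessel; junction and terminal
#' references are vessel indices.
#'
#' @param vessels list of [vessel_segment()] objects.
#' @param junctions list of `list(parent = , children = )` entries.
#' @param terminals list of [windkessel_terminal()] objects, each with a
#'   `vessel` field.
#' @param stenoses list of placed stenosis elements (see
#'   [make_stenotic_vessel()]).
#' @param inlet list with `vessel` (must be 1), `kind` ("flow" or "pressure")
#'   and `waveform` (an [inflow_bc()] or NULL).
#' @param scheme list with `order`, `limiter` and `total_pressure` (logical,
#'   junction matching with the dynamic-pressure term).
#' @return An object of class `arterial_network`.
#' @export
arterial_network <- function(vessels, junctions = list(), terminals = list(),
                             stenoses = list(),
                             inlet = list(vessel = 1L, kind = "flow", waveform = NULL),
                             scheme = list(order = 2, limiter = "minmod",
                                           total_pressure = TRUE)) {
  nv <- length(vessels)
  if (nv < 1) stop("network needs at least one vessel")
  for (v in vessels) stopifnot(inherits(v, "vessel_segment"))
  if (!identical(as.integer(inlet$vessel), 1L))
    stop("inlet must be attached to vessel 1 (the root)")

  children_all <- integer(0)
  parents_all <- integer(0)
  for (j in junctions) {
    if (length(j$children) < 1) stop("junction needs at least one child")
    parents_all <- c(parents_all, j$parent)
    children_all <- c(children_all, j$children)
  }
  if (anyDuplicated(c(parents_all)) || anyDuplicated(children_all))
    stop("connectivity is not a tree: duplicated parent or child")
  if (1L %in% children_all) stop("root vessel cannot be a junction child")
  interior <- sort(unique(children_all))
  if (length(interior) && !all(interior %in% seq_len(nv)))
    stop("junction references unknown vessel")
  non_root <- setdiff(seq_len(nv), 1L)
  if (!setequal(children_all, non_root))
    stop("connectivity is not a rooted tree: every non-root vessel must be a junction child exactly once")

  leaves <- setdiff(seq_len(nv), parents_all)
  tv <- vapply(terminals, function(t) as.integer(t$vessel), integer(1))
  if (!setequal(tv, leaves) || anyDuplicated(tv))
    stop("every leaf vessel needs exactly one terminal (and only leaves)")

  for (s in stenoses) {
    nel <- vessels[[s$vessel]]$n_elem
    if (s$iface < 1 || s$iface > nel - 1)
      stop("stenosis interface outside the vessel interior")
  }

  scheme$order <- if (is.null(scheme$order)) 2L else as.integer(scheme$order)
  if (is.null(scheme$limiter)) scheme$limiter <- "minmod"
  if (is.null(scheme$total_pressure)) scheme$total_pressure <- TRUE

  structure(list(vessels = vessels, junctions = junctions,
                 terminals = terminals, stenoses = stenoses,
                 inlet = inlet, scheme = scheme),
            class = "arterial_network")
}

# flatten for the compiled driver; blood properties come from the root vessel
.net_flat <- function(network) {
  v1 <- network$vessels[[1]]
  list(
    rho = v1$rho, alpha = v1$alpha, fcoef = v1$fcoef, pext = v1$P_ext,
    order = as.integer(network$scheme$order),
    limiter = .limiter_code(network$scheme$limiter),
    total_pressure = isTRUE(network$scheme$total_pressure),
    vessels = lapply(network$vessels, function(v)
      list(A = v$A, Q = v$Q, A0 = v$A0, K = v$K, G = v$G, dx = v$dx)),
    junctions = lapply(network$junctions, function(j)
      list(parent = as.integer(j$parent), children = as.integer(j$children))),
    terminals = lapply(network$terminals, function(t)
      list(vessel = as.integer(t$vessel), Z = t$Z, R = t$R, C = t$C,
           P_out = t$P_out, P_state = t$P_state)),
    stenoses = lapply(network$stenoses, function(s)
      list(vessel = as.integer(s$vessel), iface = as.integer(s$iface),
           area_ratio = s$area_ratio, Ls = s$Ls,
           Kv = s$Kv, Kt = s$Kt, Ku = s$Ku, q_state = s$q_state))
  )
}

# inlet spec for the compiled driver
.inlet_flat <- function(network, override = NULL) {
  if (!is.null(override)) return(override)
  inl <- network$inlet
  if (is.null(inl$waveform)) return(list(type = 2L))
  bc <- inl$waveform
  tab <- .bc_table(bc)
  list(type = if (bc$kind == "flow") 0L else 1L,
       wt = tab$t, wv = tab$value, period = bc$period)
}

.bc_table <- function(bc, n = 4096L) {
  if (!is.null(bc$fn)) {
    t <- seq(0, bc$period, length.out = n + 1L)[-(n + 1L)]
    data.frame(t = t, value = bc$fn(t))
  } else bc$table
}

#' Run a network forward in time
#'
#' Low-level driver: advances the whole network by `n_steps` explicit substeps
#' of size `dt`, with the inlet taken from the network description (or closed
#' if none).  Optionally records pressure/flow probes.
#'
#' @param network an [arterial_network()].
#' @param dt substep (s); must satisfy the CFL bound of every vessel.
#' @param n_steps number of substeps.
#' @param t0 start time (s).
#' @param probes optional 2-column matrix `(vessel, element)` of probe sites.
#' @param record_every record every k-th substep (0 = no recording).
#' @return list with the advanced `network`, a `records` data frame (time,
#'   inlet pressure/flow, probe pressures/flows) and `diagnostics`
#'   (conservation integrals, junction mass defects, minimum area).
#' @export
simulate_network <- function(network, dt, n_steps, t0 = 0, probes = NULL,
                             record_every = 0L) {
  pm <- if (is.null(probes)) matrix(integer(0), 0, 2)
        else matrix(as.integer(as.matrix(probes)), ncol = 2)
  res <- .cw_run(.net_flat(network), .inlet_flat(network), dt,
                 as.integer(n_steps), t0, network$vessels[[1]]$mu,
                 pm, as.integer(record_every))
  network <- .net_commit(network, res)
  records <- NULL
  if (record_every > 0) {
    records <- data.frame(t = res$rec_t, P_in = res$rec_inlet_P,
                          Q_in = res$rec_inlet_Q)
    if (nrow(pm) > 0) {
      colnames(res$rec_probe_P) <- paste0("P_", seq_len(nrow(pm)))
      colnames(res$rec_probe_Q) <- paste0("Q_", seq_len(nrow(pm)))
      records <- cbind(records, res$rec_probe_P, res$rec_probe_Q)
    }
  }
  list(network = network, records = records,
       diagnostics = res[c("vol_in", "vol_out_ends", "micro_out", "cap_charge",
                           "max_junc_defect", "max_junc_q", "max_junc_pres",
                           "min_A", "stored_volume", "inlet_P", "inlet_Q",
                           "t_end")])
}

.net_commit <- function(network, res) {
  for (i in seq_along(network$vessels)) {
    network$vessels[[i]]$A <- res$A[[i]]
    network$vessels[[i]]$Q <- res$Q[[i]]
  }
  for (i in seq_along(network$terminals))
    network$terminals[[i]]$P_state <- res$P_state[i]
  for (i in seq_along(network$stenoses))
    network$stenoses[[i]]$q_state <- res$sten_q[i]
  network
}

.net_stored_volume <- function(network) {
  sum(vapply(network$vessels, function(v) sum(v$A) * v$dx, numeric(1)))
}

# default substep: CFL bound at the current state with a safety margin for
# systolic pressurisation (c grows like A^{1/4})
.default_dt <- function(network, cfl = 0.9, margin = 0.6) {
  margin * cfl * min(vapply(network$vessels, stable_dt, numeric(1),
                            cfl_number = 1))
}

#' Initialise a network by cycling to periodicity
#'
#' Advances the network alone, driven by its inlet waveform, for `n_cycles`
#' periods, and reports the cycle-to-cycle relative L2 change of the inlet
#' pressure trace.  The periodic-solution flag is raised when that change
#' drops below `tol`.
#'
#' @param network an [arterial_network()].
#' @param inflow an [inflow_bc()]; defaults to the network's inlet waveform.
#' @param n_cycles number of periods to run.
#' @param period cycle length (s); defaults to the waveform period.
#' @param dt substep (s); default from the CFL bound.
#' @param tol periodicity threshold on the relative L2 cycle change.
#' @return The advanced network, with attribute `standalone`: a list with
#'   `cycle_change` (one value per cycle after the first), `periodic`
#'   (logical), and `last_cycle` (inlet pressure/flow trace).
#' @export
run_standalone <- function(network, inflow = NULL, n_cycles = 20,
                           period = NULL, dt = NULL, tol = 1e-3) {
  if (!is.null(inflow)) network$inlet$waveform <- inflow
  bc <- network$inlet$waveform
  if (is.null(period)) {
    if (is.null(bc)) stop("no period given and no inlet waveform to take it from")
    period <- bc$period
  }
  if (n_cycles == 0) {
    attr(network, "standalone") <- list(cycle_change = numeric(0),
                                        periodic = FALSE, last_cycle = NULL)
    return(network)
  }
  if (is.null(dt)) dt <- .default_dt(network)
  nsub <- ceiling(period / dt)
  dt <- period / nsub
  rec <- max(1L, floor(nsub / 512))
  prev <- NULL
  change <- numeric(0)
  trace <- NULL
  for (cy in seq_len(n_cycles)) {
    out <- simulate_network(network, dt, nsub, t0 = (cy - 1) * period,
                            record_every = rec)
    network <- out$network
    trace <- out$records
    cur <- trace$P_in
    if (!is.null(prev)) {
      n <- min(length(prev), length(cur))
      change <- c(change,
                  sqrt(sum((cur[1:n] - prev[1:n])^2) / sum(prev[1:n]^2)))
    }
    prev <- cur
  }
  attr(network, "standalone") <- list(
    cycle_change = change,
    periodic = length(change) > 0 && change[length(change)] < tol,
    last_cycle = trace)
  network
}
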