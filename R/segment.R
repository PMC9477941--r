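#' Discretised compliant vessel segment
#'
#' Builds the finite-volume discretisation of one 1D vessel: element centroids,
#' per-element wall properties (linear taper of reference area, modulus and
#' thickness between the two ends) and the `(A, Q)` state, initialised at the
#' stress-free reference.
#'
#' @param id identifier (integer or character).
#' @param length vessel length (m).
#' @param n_elem number of finite-volume elements (>= 2).
#' @param A0_in,A0_out reference lumen areas at inlet/outlet (m^2); equal for a
#'   uniform vessel.
#' @param E Young modulus (Pa), scalar or per-element.
#' @param h wall thickness (m).
#' @param phi_w wall viscosity (Pa s).
#' @param rho blood density (kg/m^3).
#' @param mu dynamic blood viscosity (Pa s).
#' @param zeta velocity-profile constant; the Coriolis coefficient is
#'   \eqn{\alpha = (\zeta+2)/(\zeta+1)} and the friction force per unit length
#'   is \eqn{f = -2\pi(\zeta+2)\mu u}.  The default 9 gives \eqn{\alpha = 1.1}.
#' @param P_ext external pressure (Pa).
#' @return An object of class `vessel_segment`.
#' @export
vessel_segment <- function(id, length, n_elem, A0_in, A0_out = A0_in,
                           E = 0.25e6, h = 1.5e-3, phi_w = 0,
                           rho = 1060, mu = 4e-3, zeta = 9, P_ext = 0) {
  if (length <= 0) stop("invalid geometry: length must be positive")
  if (n_elem < 2) stop("invalid geometry: need at least 2 elements")
  if (A0_in <= 0 || A0_out <= 0) stop("invalid geometry: reference areas must be positive")
  dx <- length / n_elem
  x <- (seq_len(n_elem) - 0.5) * dx
  frac <- x / length
  A0 <- A0_in + (A0_out - A0_in) * frac
  Ev <- rep_len(E, n_elem)
  hv <- rep_len(h, n_elem)
  kg <- stiffness_coefficients(Ev, hv, rep_len(phi_w, n_elem))
  structure(list(
    id = id, length = length, n_elem = n_elem, dx = dx, x = x,
    A0_in = A0_in, A0_out = A0_out,
    A0 = A0, E = Ev, h = hv, phi_w = phi_w, K = kg$K, G = kg$G,
    rho = rho, mu = mu, zeta = zeta,
    alpha = (zeta + 2) / (zeta + 1),
    fcoef = 2 * pi * (zeta + 2) * mu,
    P_ext = P_ext,
    A = A0, Q = rep(0, n_elem)
  ), class = "vessel_segment")
}

#' Largest stable explicit time step of a segment
#'
#' CFL bound `dt = cfl * min(dx / (|u| + c))` over the elements, with `c` the
#' local elastic wave speed.
#'
#' @param segment a [vessel_segment()].
#' @param cfl_number Courant number in (0, 1].
#' @return Time step (s).
#' @export
stable_dt <- function(segment, cfl_number = 0.9) {
  stopifnot(cfl_number > 0, cfl_number <= 1)
  u <- segment$Q / segment$A
  cc <- sqrt(segment$K * sqrt(segment$A) / (2 * segment$rho * segment$A0))
  cfl_number * min(segment$dx / (abs(u) + cc))
}

.seg_flat <- function(segment, scheme = list(order = 2, limiter = "minmod")) {
  list(A = segment$A, Q = segment$Q, A0 = segment$A0, K = segment$K,
       G = segment$G, dx = segment$dx,
       rho = segment$rho, alpha = segment$alpha, fcoef = segment$fcoef,
       pext = segment$P_ext,
       order = as.integer(scheme$order),
       limiter = .limiter_code(scheme$limiter))
}

.limiter_code <- function(name) {
  switch(match.arg(name, c("minmod", "none")), minmod = 1L, none = 0L)
}

#' Advance a single vessel segment
#'
#' Takes `n_steps` explicit steps of the conservative `(A, Q)` system on one
#' segment.  Boundary information is supplied either as fixed upwinded states
#' (`list(left = c(A, Q), right = c(A, Q))`), or as time-dependent ghost-cell
#' functions `function(t)` returning a `2 x 2` matrix (rows `A`, `Q`; columns
#' outer and inner ghost cell), which is what the manufactured-solution
#' convergence tests use.  An optional forcing `function(x, t)` returning
#' `list(A = , Q = )` adds source terms to both equations.
#'
#' @param segment a [vessel_segment()].
#' @param dt time step (s); must respect [stable_dt()].
#' @param boundary boundary specification, see Details.
#' @param n_steps number of steps.
#' @param t0 initial time (s), passed to ghost/forcing functions.
#' @param forcing optional forcing function.
#' @param scheme list with `order` (1 or 2) and `limiter` ("minmod" or "none").
#' @return The segment with advanced state.
#' @export
advance <- function(segment, dt, boundary, n_steps = 1, t0 = 0,
                    forcing = NULL,
                    scheme = list(order = 2, limiter = "minmod")) {
  stopifnot(dt > 0, n_steps >= 0)
  if (n_steps == 0) return(segment)
  n <- segment$n_elem
  times <- t0 + dt * (0:n_steps)
  ghost <- function(side) {
    b <- boundary[[side]]
    if (is.function(b)) {
      vapply(times, function(t) {
        m <- b(t)
        c(m[1, 1], m[2, 1], m[1, 2], m[2, 2])
      }, numeric(4))
    } else {
      matrix(rep(c(b[1], b[2], b[1], b[2]), length(times)), nrow = 4)
    }
  }
  gL <- ghost("left"); gR <- ghost("right")
  fA <- fQ <- NULL
  if (!is.null(forcing)) {
    fA <- matrix(0, n, n_steps + 1)
    fQ <- matrix(0, n, n_steps + 1)
    for (j in seq_along(times)) {
      f <- forcing(segment$x, times[j])
      fA[, j] <- f$A
      fQ[, j] <- f$Q
    }
  }
  out <- .cw_segment_run(.seg_flat(segment, scheme), dt, as.integer(n_steps),
                         gL, gR, fA, fQ)
  segment$A <- out$A
  segment$Q <- out$Q
  # time-integrated mass fluxes actually applied at the two ends
  attr(segment, "boundary_flux_volumes") <- c(inflow = out$vol_flux_in,
                                              outflow = out$vol_flux_out)
  segment
}
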