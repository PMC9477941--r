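#' Wall stiffness and viscosity coefficients
#'
#' Computes the elastic coefficient \eqn{K = (4/3)\sqrt{\pi} E h} and the
#' viscous coefficient \eqn{G = (2/3)\sqrt{\pi} \varphi h} of the Voigt-type
#' tube law from the Young modulus, wall thickness and wall viscosity.
#'
#' @param E Young modulus of the vessel wall (Pa), non-negative.
#' @param h wall thickness (m), positive.
#' @param phi_w wall viscosity \eqn{\varphi} (Pa s), non-negative.
#' @return A list with elements `K` (Pa m) and `G` (Pa s m).
#' @examples
#' stiffness_coefficients(0.25e6, 1.5e-3)  # K ~ 886.2 Pa m
#' @export
stiffness_coefficients <- function(E, h, phi_w = 0) {
  if (any(h <= 0)) stop("invalid geometry: wall thickness h must be positive")
  if (any(E < 0)) stop("Young modulus E must be non-negative")
  if (any(phi_w < 0)) stop("wall viscosity phi_w must be non-negative")
  list(K = (4 / 3) * sqrt(pi) * E * h,
       G = (2 / 3) * sqrt(pi) * phi_w * h)
}

#' Wall properties of a compliant vessel element
#'
#' Bundles the reference geometry and constitutive coefficients of the tube
#' law.  `K` and `G` are derived from `(E, h, phi_w)`.
#'
#' @param A0 reference cross-sectional area (m^2).
#' @param E Young modulus (Pa).
#' @param h wall thickness (m).
#' @param phi_w wall viscosity (Pa s).
#' @param P_ext external pressure (Pa).
#' @param rho blood density (kg/m^3).
#' @return An object of class `wall_properties`.
#' @export
wall_properties <- function(A0, E, h, phi_w = 0, P_ext = 0, rho = 1060) {
  if (any(A0 <= 0)) stop("invalid geometry: A0 must be positive")
  if (rho <= 0) stop("blood density must be positive")
  kg <- stiffness_coefficients(E, h, phi_w)
  structure(list(A0 = A0, E = E, h = h, K = kg$K, phi_w = phi_w, G = kg$G,
                 P_ext = P_ext, rho = rho),
            class = "wall_properties")
}

#' Transmural pressure from cross-sectional area
#'
#' Voigt-type visco-elastic tube law
#' \deqn{P = P_{ext} + K (\sqrt{A} - \sqrt{A_0})/A_0 + G \frac{1}{A_0\sqrt{A}}
#'   \frac{\partial A}{\partial t}.}
#'
#' @param A cross-sectional area (m^2), positive.
#' @param dA_dt area rate of change (m^2/s); enters the viscous term only.
#' @param wall a [wall_properties()] object.
#' @return Pressure (Pa).
#' @export
pressure_from_area <- function(A, dA_dt = 0, wall) {
  if (any(A <= 0)) stop("collapsed lumen: A must be positive")
  wall$P_ext + wall$K * (sqrt(A) - sqrt(wall$A0)) / wall$A0 +
    wall$G * dA_dt / (wall$A0 * sqrt(A))
}

#' Pulse wave speed
#'
#' Wave speed of the elastic tube law,
#' \eqn{c(A) = \sqrt{K \sqrt{A} / (2 \rho A_0)}}; at the reference area this
#' is \eqn{c_0 = \sqrt{K / (2 \rho \sqrt{A_0})}}.
#'
#' @inheritParams pressure_from_area
#' @return Wave speed (m/s).
#' @export
wave_speed <- function(A, wall) {
  if (any(A <= 0)) stop("collapsed lumen: A must be positive")
  if (any(wall$K <= 0)) stop("no wave speed: K must be positive")
  sqrt(wall$K * sqrt(A) / (2 * wall$rho * wall$A0))
}

#' Characteristic variables of the 1D system
#'
#' Riemann invariants of the elastic subsystem,
#' \eqn{W_{f,b} = u \pm 4 (c(A) - c_0)}.
#'
#' @param A cross-sectional area (m^2).
#' @param u average axial velocity (m/s).
#' @inheritParams pressure_from_area
#' @return A list with `W_f` and `W_b` (m/s).
#' @seealso [invert_characteristics()]
#' @export
characteristics <- function(A, u, wall) {
  if (any(A <= 0)) stop("collapsed lumen: A must be positive")
  c0 <- wave_speed(wall$A0, wall)
  dc <- 4 * (wave_speed(A, wall) - c0)
  list(W_f = u + dc, W_b = u - dc)
}

#' Invert characteristic variables
#'
#' Exact inverse of [characteristics()]: recovers `(A, u)` from the forward
#' and backward Riemann invariants.
#'
#' @param W_f,W_b forward/backward characteristic variables (m/s).
#' @inheritParams pressure_from_area
#' @return A list with `A` (m^2) and `u` (m/s).
#' @export
invert_characteristics <- function(W_f, W_b, wall) {
  c0 <- wave_speed(wall$A0, wall)
  if (any(W_f - W_b <= -8 * c0))
    stop("unphysical characteristic pair: implied area is non-positive")
  cc <- c0 + (W_f - W_b) / 8
  # c^2 = K sqrt(A) / (2 rho A0)  =>  sqrt(A) = 2 rho A0 c^2 / K
  sqA <- 2 * wall$rho * wall$A0 * cc^2 / wall$K
  list(A = sqA^2, u = (W_f + W_b) / 2)
}
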