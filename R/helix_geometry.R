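# Equilibrium geometry of the B-form double helix and inter-base distances
# in cylindrical (twist, radial) coordinates.

#' Derived equilibrium geometry of the double helix
#'
#' Computes the eight derived constants of the helicoidal frame from the
#' three primitive geometry parameters (equilibrium twist angle
#' \eqn{\theta_0}, rise per base pair \eqn{h_0} and helix radius
#' \eqn{R_0}):
#' \itemize{
#'   \item `c_pitch` = \eqn{h_0/\theta_0} (nm), the pitch parameter;
#'   \item `xi` = \eqn{\sqrt{c^2 + R_0^2}} (nm), the helix-arc constant, so
#'     that \eqn{\xi\theta} is the helical arc length between neighbours;
#'   \item `l0` = \eqn{\sqrt{h_0^2 + 4R_0^2\sin^2(\theta_0/2)}} (nm), the
#'     equilibrium inter-base distance along one strand;
#'   \item `f0` = \eqn{c^2\theta_0 + R_0^2\sin\theta_0} (nm^2) and
#'     `g0` = \eqn{R_0(1-\cos\theta_0)} (nm), the twist and radial
#'     sensitivities of the backbone bond length;
#'   \item `lB` = \eqn{2f_0/g_0} (nm) and `aB` = \eqn{g_0\xi^2/f_0} (nm),
#'     characteristic lengths of the twist-radial coupling, with the
#'     dimensionless ratio `bB` = \eqn{a_B/\xi};
#'   \item `qstar` = \eqn{\pi/\xi} (nm^-1), the zone-boundary wavevector.
#' }
#'
#' @param geom A `dna_params` object or its `$geometry` component.
#' @return Object of class `helix_frame` with the fields above plus the
#'   primitive `theta0`, `h0`, `R0`.
#' @examples
#' fr <- helix_frame(dna_params("GC"))
#' fr$l0   # ~0.685 nm
#' fr$xi   # ~1.147 nm
#' @export
helix_frame <- function(geom) {
  if (inherits(geom, "dna_params")) geom <- geom$geometry
  stopifnot(is.list(geom), all(c("theta0", "h0", "R0") %in% names(geom)))
  theta0 <- geom$theta0; h0 <- geom$h0; R0 <- geom$R0
  if (theta0 == 0) stop("theta0 = 0: pitch parameter c = h0/theta0 is undefined")
  if (theta0 < 0 || theta0 >= pi) stop("theta0 must lie in (0, pi)")

  c_pitch <- h0 / theta0
  xi <- sqrt(c_pitch^2 + R0^2)
  l0 <- sqrt(h0^2 + 4 * R0^2 * sin(theta0 / 2)^2)
  f0 <- c_pitch^2 * theta0 + R0^2 * sin(theta0)
  g0 <- R0 * (1 - cos(theta0))
  lB <- 2 * f0 / g0
  aB <- g0 * xi^2 / f0
  bB <- aB / xi

  fr <- list(theta0 = theta0, h0 = h0, R0 = R0,
             c_pitch = c_pitch, xi = xi, l0 = l0,
             f0 = f0, g0 = g0, lB = lB, aB = aB, bB = bB,
             qstar = pi / xi)
  stopifnot(fr$xi > R0, fr$l0 <= fr$xi * theta0 + 1e-12)
  structure(fr, class = "helix_frame")
}

#' @export
print.helix_frame <- function(x, ...) {
  cat("Helicoidal frame (B-form equilibrium)\n")
  cat(sprintf("  c = %.5f nm   xi = %.5f nm   l0 = %.5f nm\n", x$c_pitch, x$xi, x$l0))
  cat(sprintf("  f0 = %.5f nm^2   g0 = %.5f nm\n", x$f0, x$g0))
  cat(sprintf("  lB = %.4f nm   aB = %.5f nm   bB = %.5f\n", x$lB, x$aB, x$bB))
  cat(sprintf("  q* = pi/xi = %.4f nm^-1\n", x$qstar))
  invisible(x)
}

#' Euclidean distance between adjacent bases along one strand
#'
#' Distance between base n at radial displacement `rho_n` and base m on the
#' same strand at `rho_m`, separated by relative twist `theta`:
#' \deqn{d = \sqrt{c^2\theta^2 + (R_0+\rho_n)^2 + (R_0+\rho_m)^2
#'       - 2(R_0+\rho_n)(R_0+\rho_m)\cos\theta}.}
#' The complementary-strand distance is the same function evaluated at
#' \eqn{\rho \to \lambda\rho}.  At \eqn{\rho = 0}, \eqn{\theta = \theta_0}
#' it reduces to the equilibrium bond length `l0`; in the small-oscillation
#' limit it tends to the helical arc length \eqn{\xi\theta}.
#'
#' @param rho_n,rho_m Radial displacements (nm); vectorised.
#' @param theta Relative twist angle (rad); only relative angles enter, no
#'   wrapping mod 2*pi is applied.
#' @param frame A `helix_frame`.
#' @return Distance(s) in nm.
#' @export
pair_distance <- function(rho_n, rho_m, theta, frame) {
  stopifnot(inherits(frame, "helix_frame"))
  rn <- frame$R0 + rho_n
  rm <- frame$R0 + rho_m
  if (any(rn < 0) || any(rm < 0)) stop("R0 + rho must be non-negative")
  d2 <- frame$c_pitch^2 * theta^2 + rn^2 + rm^2 - 2 * rn * rm * cos(theta)
  # radicand is (c theta)^2 + |rn - rm e^{i theta}|^2 >= 0 by construction
  stopifnot(all(d2 >= -1e-15))
  sqrt(pmax(d2, 0))
}

# Cartesian position of a base at angle phi (rad) and radius r (nm) on the
# helix z = c*phi.  Used by tests as an independent oracle.
helix_cartesian <- function(phi, r, frame) {
  cbind(x = r * cos(phi), y = r * sin(phi), z = frame$c_pitch * phi)
}
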