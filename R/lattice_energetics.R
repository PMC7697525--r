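# Potential energy terms of the lattice Hamiltonian (Morse H-bond
# stretching, anharmonically modulated stacking, harmonic helicoidal
# backbone) and their numerically differentiated forces / normal modes.
# These are the nonlinear potentials; the dynamics simulator integrates the
# linearized equations, and this module provides the independent check that
# the linearization is faithful (see hessian_frequencies).

#' Lattice configuration of a duplex chain
#'
#' A configuration stores per-site twist and radial displacements measured
#' from the B-form equilibrium (uniform twist `theta0`, `rho = 0`), together
#' with the per-site pair species.  The twist of bond (n, n+1) is
#' `theta0 + phi[n+1] - phi[n]`.
#'
#' @param phi Twist displacements (rad), length N.
#' @param rho Radial displacements of the reference strand (nm), length N.
#'   The complementary strand displaces by `lambda * rho` (fixed centre of
#'   mass of each pair).
#' @param species Per-site species, `"GC"`/`"AT"`; recycled if length 1.
#' @param boundary `"periodic"` (ring with helical seam) or `"free"`.
#' @return Object of class `lattice_config`.
#' @export
lattice_config <- function(phi, rho, species = "GC", boundary = c("periodic", "free")) {
  boundary <- match.arg(boundary)
  stopifnot(length(phi) == length(rho), all(is.finite(phi)), all(is.finite(rho)))
  n <- length(phi)
  if (length(species) == 1) species <- rep(species, n)
  stopifnot(length(species) == n, all(species %in% c("GC", "AT")))
  structure(list(phi = phi, rho = rho, species = species, boundary = boundary),
            class = "lattice_config")
}

# lambda per site (computed from the base masses, kept cheap for hot loops)
.site_lambda <- function(species) {
  ifelse(species == "GC",
         .BASE_MASS[["G"]] / .BASE_MASS[["C"]],
         .BASE_MASS[["A"]] / .BASE_MASS[["T"]])
}

# bond index pairs (n, n+1); for a periodic ring the last bond closes the seam
.bond_pairs <- function(n, boundary) {
  if (boundary == "periodic") cbind(seq_len(n), c(seq_len(n - 1) + 1, 1))
  else cbind(seq_len(n - 1), seq_len(n - 1) + 1)
}

#' Morse hydrogen-bond stretching energy
#'
#' \deqn{U_H = \sum_n D\,[e^{-(\alpha/2)(1+\lambda_n)\rho_n} - 1]^2}
#' The argument couples both strands' displacements through the fixed
#' centre-of-mass constraint (\eqn{\rho + \bar\rho = (1+\lambda)\rho}).
#' One effective Morse set (D, alpha) describes both pair species.
#'
#' @param config A `lattice_config`.
#' @param params A `dna_params` (supplies D and alpha; defaults to GC set).
#' @return Energy in eV (non-negative; zero at equilibrium).
#' @export
morse_energy <- function(config, params = dna_params("GC")) {
  lam <- .site_lambda(config$species)
  D <- params$lattice$D; alpha <- params$lattice$alpha
  sum(D * (exp(-(alpha / 2) * (1 + lam) * config$rho) - 1)^2)
}

#' Base-pair stacking energy
#'
#' \deqn{U_S = \frac{1}{8}\sum_n k_S\,[1 + e^{-(b/2)u^+_{n,n+1}}]\,(u^-_{n,n+1})^2}
#' with \eqn{u^\pm_{n,n+1} = (1+\lambda_n)\rho_n \pm (1+\lambda_{n+1})\rho_{n+1}},
#' penalising large relative radial displacements of adjacent pairs with an
#' exponentially softened stiffness.
#'
#' @inheritParams morse_energy
#' @return Energy in eV (zero for any uniform radial field in a homopolymer).
#' @export
stacking_energy <- function(config, params = dna_params("GC")) {
  n <- length(config$rho)
  stopifnot(n >= 2)
  lam <- .site_lambda(config$species)
  w <- (1 + lam) * config$rho
  bp <- .bond_pairs(n, config$boundary)
  up <- w[bp[, 1]] + w[bp[, 2]]
  um <- w[bp[, 1]] - w[bp[, 2]]
  kS <- params$lattice$kS; b <- params$lattice$b
  sum(kS / 8 * (1 + exp(-(b / 2) * up)) * um^2)
}

#' Helicoidal backbone energy
#'
#' \deqn{U_B = \frac{k_B}{2}\sum_n (d_{n,n+1}-l_0)^2 + (\bar d_{n,n+1}-l_0)^2}
#' where both strands' bond lengths are evaluated with [pair_distance()],
#' the complementary strand at \eqn{\rho \to \lambda\rho}.
#'
#' @inheritParams morse_energy
#' @param frame A `helix_frame` consistent with `params`.
#' @return Energy in eV (zero at the B-form equilibrium; invariant under
#'   rigid rotations `phi + delta`).
#' @export
backbone_energy <- function(config, frame, params = dna_params("GC")) {
  n <- length(config$phi)
  stopifnot(n >= 2)
  lam <- .site_lambda(config$species)
  bp <- .bond_pairs(n, config$boundary)
  theta <- frame$theta0 + config$phi[bp[, 2]] - config$phi[bp[, 1]]
  d  <- pair_distance(config$rho[bp[, 1]], config$rho[bp[, 2]], theta, frame)
  db <- pair_distance(lam[bp[, 1]] * config$rho[bp[, 1]],
                      lam[bp[, 2]] * config$rho[bp[, 2]], theta, frame)
  params$lattice$kB / 2 * sum((d - frame$l0)^2 + (db - frame$l0)^2)
}

#' Total lattice potential energy
#' @inheritParams backbone_energy
#' @return `morse + stacking + backbone` in eV.
#' @export
lattice_potential <- function(config, frame, params = dna_params("GC")) {
  morse_energy(config, params) + stacking_energy(config, params) +
    backbone_energy(config, frame, params)
}

#' Total lattice energy including the kinetic term
#'
#' Kinetic energy per site
#' \deqn{T_n = \frac{1}{2M}\Big[\frac{P_{\rho_n}^2}{\lambda_n} +
#'   \frac{P_{\phi_n}^2}{\xi^2 + P(\rho_n)}\Big],\quad
#'   P(\rho) \simeq \lambda\rho^2 + 2R_0\rho,}
#' in eV when momenta are given in amu nm/s (radial) and amu nm^2/s (twist)
#' divided by the SI conversion; here momenta are specified directly as
#' generalized velocities times mass, in internal units (see Details).
#'
#' Details: to keep a single unit system, momenta are passed as
#' `P_rho = M * lambda * rho_dot` (amu nm/s) and
#' `P_phi = M * (xi^2 + P(rho)) * phi_dot` (amu nm^2 rad/s); the kinetic
#' energy is converted to eV internally.
#'
#' @inheritParams backbone_energy
#' @param P_rho,P_phi Conjugate momenta per site (see Details).
#' @return Total energy (eV).
#' @export
total_energy <- function(config, P_rho, P_phi, frame, params = dna_params("GC")) {
  lam <- .site_lambda(config$species)
  M <- params$lattice$M
  Pmetric <- lam * config$rho^2 + 2 * frame$R0 * config$rho
  kin_internal <- sum(P_rho^2 / lam + P_phi^2 / (frame$xi^2 + Pmetric)) / (2 * M)
  # momenta are in amu-based units; (amu nm^2/s^2) -> eV
  kin_ev <- kin_internal * .AMU_KG * 1e-18 / .EV_J
  kin_ev + lattice_potential(config, frame, params)
}

# Gradient of the total potential wrt the 2N vector (phi, rho) by central
# differences.  Step sizes per the numerical design: 1e-6 rad / 1e-6 nm.
lattice_gradient <- function(config, frame, params = dna_params("GC"),
                             h = 1e-6) {
  n <- length(config$phi)
  u0 <- c(config$phi, config$rho)
  f <- function(u) {
    cfg <- config
    cfg$phi <- u[seq_len(n)]
    cfg$rho <- u[n + seq_len(n)]
    lattice_potential(cfg, frame, params)
  }
  g <- numeric(2 * n)
  for (i in seq_len(2 * n)) {
    up <- u0; up[i] <- up[i] + h
    um <- u0; um[i] <- um[i] - h
    g[i] <- (f(up) - f(um)) / (2 * h)
  }
  list(phi = g[seq_len(n)], rho = g[n + seq_len(n)])
}

# Full finite-difference Hessian of the total potential at a configuration
# (default: equilibrium).  Returns the 2N x 2N matrix in (phi, rho) ordering.
lattice_hessian <- function(n_sites, species = "GC", frame = NULL,
                            params = dna_params(species), h = 1e-5) {
  if (is.null(frame)) frame <- helix_frame(params)
  n <- n_sites
  config <- lattice_config(numeric(n), numeric(n), species)
  f <- function(u) {
    cfg <- config
    cfg$phi <- u[seq_len(n)]
    cfg$rho <- u[n + seq_len(n)]
    lattice_potential(cfg, frame, params)
  }
  m <- 2 * n
  H <- matrix(0, m, m)
  u0 <- numeric(m)
  f0 <- f(u0)
  # diagonal terms
  for (i in seq_len(m)) {
    up <- u0; up[i] <- h
    um <- u0; um[i] <- -h
    H[i, i] <- (f(up) - 2 * f0 + f(um)) / h^2
  }
  # off-diagonal terms
  for (i in seq_len(m - 1)) {
    for (j in seq((i + 1), m)) {
      upp <- u0; upp[i] <- h;  upp[j] <- h
      upm <- u0; upm[i] <- h;  upm[j] <- -h
      ump <- u0; ump[i] <- -h; ump[j] <- h
      umm <- u0; umm[i] <- -h; umm[j] <- -h
      H[i, j] <- H[j, i] <- (f(upp) - f(upm) - f(ump) + f(umm)) / (4 * h^2)
    }
  }
  H
}

#' Phonon frequencies from the numerical Hessian of the full potentials
#'
#' Validation bridge between the nonlinear lattice Hamiltonian and the
#' analytic dispersion relations: builds the mass-weighted second-derivative
#' matrix of \eqn{U_H + U_S + U_B} at the B-form equilibrium of a periodic
#' homopolymer ring of `n_sites` pairs by central finite differences,
#' Bloch-transforms it (the ring is site-translation invariant) and returns
#' the two eigenfrequency branches at each requested wavevector.
#'
#' Generalized masses at equilibrium are \eqn{M\xi^2} for the twist
#' coordinate and \eqn{M\lambda} for the radial coordinate.
#'
#' @param species `"GC"` or `"AT"`.
#' @param n_sites Ring size N.
#' @param q_list Wavevectors (nm^-1); each must be commensurate with the
#'   ring, i.e. `q * xi * N / (2*pi)` integral.
#' @param h Finite-difference step (rad / nm).
#' @return Data frame with columns `q`, `omega_minus`, `omega_plus` (rad/s).
#' @export
hessian_frequencies <- function(species = "GC", n_sites = 12, q_list,
                                h = 1e-5) {
  params <- dna_params(species)
  frame <- helix_frame(params)
  n <- n_sites
  k_idx <- q_list * frame$xi * n / (2 * pi)
  if (any(abs(k_idx - round(k_idx)) > 1e-8))
    stop("q not commensurate with ring of ", n, " sites")
  H <- lattice_hessian(n, species, frame, params, h = h)
  lam <- params$pair$lambda
  M <- params$lattice$M
  m_phi <- M * frame$xi^2
  m_rho <- M * lam
  # Bloch transform: reference site 1; blocks H[x1, y_m] summed with phases
  out <- lapply(q_list, function(q) {
    ph <- exp(1i * q * frame$xi * (seq_len(n) - 1))
    D11 <- sum(H[1, seq_len(n)] * ph) / m_phi
    D12 <- sum(H[1, n + seq_len(n)] * ph) / sqrt(m_phi * m_rho)
    D21 <- sum(H[n + 1, seq_len(n)] * ph) / sqrt(m_phi * m_rho)
    D22 <- sum(H[n + 1, n + seq_len(n)] * ph) / m_rho
    Dq <- matrix(c(D11, D21, D12, D22), 2, 2)
    ev <- eigen((Dq + Conj(t(Dq))) / 2, symmetric = TRUE, only.values = TRUE)$values
    ev <- sort(Re(ev))
    omega2 <- pmax(ev, 0) * .OMEGA2_SI
    data.frame(q = q, omega_minus = sqrt(omega2[1]), omega_plus = sqrt(omega2[2]))
  })
  do.call(rbind, out)
}
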