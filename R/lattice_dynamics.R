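# Time-domain integration of the linearized coupled twist/radial equations
# of motion, helical-wave initial conditions, and the codon-scale collective
# variables with their self-similar renormalization property.

#' Dynamical state of a duplex chain
#'
#' Twist and radial displacement fields (measured from the B-form
#' equilibrium) plus their velocities.
#'
#' @param phi,rho Displacements (rad, nm), length N.
#' @param phi_dot,rho_dot Velocities (rad/s, nm/s); default zero.
#' @param time Time stamp (s).
#' @param species Per-site species (`"GC"`/`"AT"`), recycled if length 1.
#' @param boundary `"periodic"` or `"free"`.
#' @return Object of class `chain_state`.
#' @export
chain_state <- function(phi, rho, phi_dot = numeric(length(phi)),
                        rho_dot = numeric(length(rho)), time = 0,
                        species = "GC",
                        boundary = c("periodic", "free")) {
  boundary <- match.arg(boundary)
  n <- length(phi)
  stopifnot(length(rho) == n, length(phi_dot) == n, length(rho_dot) == n,
            all(is.finite(c(phi, rho, phi_dot, rho_dot))))
  if (length(species) == 1) species <- rep(species, n)
  stopifnot(length(species) == n, all(species %in% c("GC", "AT")))
  structure(list(phi = phi, rho = rho, phi_dot = phi_dot, rho_dot = rho_dot,
                 time = time, species = species, boundary = boundary),
            class = "chain_state")
}

# Precomputed site-dependent coefficients of the linearized equations.
# For heteropolymers the coupled frequencies carry the per-site mass ratios
# (one effective Morse set serves both species).
dynamics_coefficients <- function(species, params = dna_params("GC"),
                                  frame = helix_frame(params)) {
  n <- length(species)
  lam <- .site_lambda(species)
  M <- params$lattice$M
  w2_phi <- (2 * params$lattice$kB / M) *
    (frame$f0 / (frame$xi * frame$l0))^2 * .OMEGA2_SI
  w2_H <- params$lattice$D * params$lattice$alpha^2 / (2 * M) * .OMEGA2_SI
  w2_S <- params$lattice$kS / M * .OMEGA2_SI

  ip <- c(seq_len(n - 1) + 1, 1)      # n+1 (periodic)
  im <- c(n, seq_len(n - 1))          # n-1 (periodic)
  lam_p <- lam[ip]; lam_m <- lam[im]

  w2_phirho <- (1 + lam)^2 / lam * (w2_H + w2_S) +
    (1 + lam^2) / lam * frame$bB^2 * w2_phi
  # coefficient of rho_{n+-1} in the equation for site n
  w2_phiS_pair <- function(lam_n, lam_nb) {
    (1 + lam_n) * (1 + lam_nb) / lam_n * w2_S -
      (1 + lam_n * lam_nb) / lam_n * frame$bB^2 * w2_phi
  }
  list(
    n = n, lam = lam, ip = ip, im = im,
    w2_phi = w2_phi, w2_H = w2_H, w2_S = w2_S,
    w2_phirho = w2_phirho,
    w2_phiS_left = w2_phiS_pair(lam, lam_m),
    w2_phiS_right = w2_phiS_pair(lam, lam_p),
    inv_lB = 1 / frame$lB,
    aB = frame$aB,
    xi = frame$xi
  )
}

#' Right-hand side of the linearized equations of motion
#'
#' Accelerations of the twist and radial fields:
#' \deqn{\ddot\phi_n = -\omega_\phi^2(2\phi_n-\phi_{n-1}-\phi_{n+1})
#'   + \omega_\phi^2 l_B^{-1}[(1+\lambda_{n+1})\rho_{n+1}
#'     - (1+\lambda_{n-1})\rho_{n-1}],}
#' \deqn{\ddot\rho_n = -\omega_{\phi\rho,n}^2\rho_n
#'   + \tfrac12\omega_{\phi S,n-1}^2\rho_{n-1}
#'   + \tfrac12\omega_{\phi S,n+1}^2\rho_{n+1}
#'   + \tfrac{a_B}{2}(1+\lambda_n^{-1})\omega_\phi^2(\phi_{n-1}-\phi_{n+1}),}
#' with site-dependent coupled frequencies for heteropolymers.  In the
#' homopolymer limit these reduce to the two-constant form with
#' \eqn{A_\lambda = (1+\lambda)/l_B} and
#' \eqn{B_\lambda = a_B(1+\lambda^{-1})/2}.
#'
#' @param state A `chain_state` (N >= 3).
#' @param coeffs Output of the internal coefficient builder; computed from
#'   the state's species if omitted.
#' @param params,frame Model parameters and frame used when `coeffs` is
#'   omitted.
#' @return List with `phi_ddot` (rad/s^2) and `rho_ddot` (nm/s^2).
#' @export
linear_rhs <- function(state, coeffs = NULL, params = dna_params("GC"),
                       frame = helix_frame(params)) {
  n <- length(state$phi)
  if (n < 3) stop("linearized dynamics needs at least 3 sites")
  if (is.null(coeffs)) coeffs <- dynamics_coefficients(state$species, params, frame)
  phi <- state$phi; rho <- state$rho
  if (state$boundary == "periodic") {
    ip <- coeffs$ip; im <- coeffs$im
    phi_p <- phi[ip]; phi_m <- phi[im]
    rho_p <- rho[ip]; rho_m <- rho[im]
    lam_p <- coeffs$lam[ip]; lam_m <- coeffs$lam[im]
  } else {
    # free ends: clamp ghost neighbours to the end sites (qualitative use)
    phi_p <- c(phi[-1], phi[n]); phi_m <- c(phi[1], phi[-n])
    rho_p <- c(rho[-1], rho[n]); rho_m <- c(rho[1], rho[-n])
    lam_p <- c(coeffs$lam[-1], coeffs$lam[n])
    lam_m <- c(coeffs$lam[1], coeffs$lam[-n])
  }
  phi_ddot <- -coeffs$w2_phi * (2 * phi - phi_m - phi_p) +
    coeffs$w2_phi * coeffs$inv_lB *
      ((1 + lam_p) * rho_p - (1 + lam_m) * rho_m)
  rho_ddot <- -coeffs$w2_phirho * rho +
    0.5 * coeffs$w2_phiS_left * rho_m +
    0.5 * coeffs$w2_phiS_right * rho_p +
    (coeffs$aB / 2) * (1 + 1 / coeffs$lam) * coeffs$w2_phi * (phi_m - phi_p)
  list(phi_ddot = phi_ddot, rho_ddot = rho_ddot)
}

#' Integrate the linearized lattice dynamics
#'
#' Fixed-step classical Runge-Kutta (RK4) integration of the first-order
#' system for \eqn{(\phi, \rho, \dot\phi, \dot\rho)}.
#'
#' @param state Initial `chain_state`.
#' @param dt Time step (s).  Must satisfy `dt < 0.05 / nu_max` where
#'   `nu_max` is the fastest characteristic frequency (stretch-stacking),
#'   a conservative margin for both stability and phase accuracy.
#' @param steps Number of steps.
#' @param record_every Record the state every this many steps (the initial
#'   state is always recorded).
#' @param params,frame Model parameters (frame derived if omitted).
#' @return Object of class `chain_trajectory`: list with `time` (s, length
#'   T), matrices `phi`, `rho`, `phi_dot`, `rho_dot` (T x N), the `final`
#'   `chain_state`, `dt`, `species`, `boundary`.
#' @export
integrate_chain <- function(state, dt, steps, record_every = 1,
                            params = dna_params("GC"),
                            frame = helix_frame(params)) {
  stopifnot(inherits(state, "chain_state"), steps >= 1, dt != 0)
  coeffs <- dynamics_coefficients(state$species, params, frame)
  # fastest scale ~ stretch-stacking: omega_+^2(q*) = w2_phirho + w2_phiS
  nu_max <- sqrt(max(coeffs$w2_phirho + pmax(coeffs$w2_phiS_left, 0))) / (2 * pi)
  if (abs(dt) >= 0.05 / nu_max)
    stop(sprintf("dt = %.3g s too large: need dt < %.3g s (0.05 / nu_max)",
                 dt, 0.05 / nu_max))

  n <- coeffs$n
  nrec <- floor(steps / record_every) + 1
  Tphi <- matrix(NA_real_, nrec, n); Trho <- matrix(NA_real_, nrec, n)
  Tphid <- matrix(NA_real_, nrec, n); Trhod <- matrix(NA_real_, nrec, n)
  tvec <- numeric(nrec)

  phi <- state$phi; rho <- state$rho
  phid <- state$phi_dot; rhod <- state$rho_dot
  norm0 <- sqrt(sum(phi^2) + sum(rho^2)) + 1e-300
  bnd <- state$boundary

  deriv <- function(phi, rho, phid, rhod) {
    acc <- linear_rhs(list(phi = phi, rho = rho, boundary = bnd), coeffs)
    list(dphi = phid, drho = rhod, dphid = acc$phi_ddot, drhod = acc$rho_ddot)
  }

  rec <- 1
  Tphi[1, ] <- phi; Trho[1, ] <- rho; Tphid[1, ] <- phid; Trhod[1, ] <- rhod
  tvec[1] <- state$time
  for (s in seq_len(steps)) {
    k1 <- deriv(phi, rho, phid, rhod)
    k2 <- deriv(phi + dt / 2 * k1$dphi, rho + dt / 2 * k1$drho,
                phid + dt / 2 * k1$dphid, rhod + dt / 2 * k1$drhod)
    k3 <- deriv(phi + dt / 2 * k2$dphi, rho + dt / 2 * k2$drho,
                phid + dt / 2 * k2$dphid, rhod + dt / 2 * k2$drhod)
    k4 <- deriv(phi + dt * k3$dphi, rho + dt * k3$drho,
                phid + dt * k3$dphid, rhod + dt * k3$drhod)
    phi <- phi + dt / 6 * (k1$dphi + 2 * k2$dphi + 2 * k3$dphi + k4$dphi)
    rho <- rho + dt / 6 * (k1$drho + 2 * k2$drho + 2 * k3$drho + k4$drho)
    phid <- phid + dt / 6 * (k1$dphid + 2 * k2$dphid + 2 * k3$dphid + k4$dphid)
    rhod <- rhod + dt / 6 * (k1$drhod + 2 * k2$drhod + 2 * k3$drhod + k4$drhod)
    if (s %% record_every == 0) {
      rec <- rec + 1
      Tphi[rec, ] <- phi; Trho[rec, ] <- rho
      Tphid[rec, ] <- phid; Trhod[rec, ] <- rhod
      tvec[rec] <- state$time + s * dt
      nrm <- sqrt(sum(phi^2) + sum(rho^2))
      if (!is.finite(nrm) || nrm > 1e3 * norm0)
        stop(sprintf(paste0("integration unstable at step %d: state norm ",
                            "%.3g exceeds 1e3 x initial norm %.3g"),
                     s, nrm, norm0))
    }
  }
  structure(list(
    time = tvec[seq_len(rec)],
    phi = Tphi[seq_len(rec), , drop = FALSE],
    rho = Trho[seq_len(rec), , drop = FALSE],
    phi_dot = Tphid[seq_len(rec), , drop = FALSE],
    rho_dot = Trhod[seq_len(rec), , drop = FALSE],
    final = chain_state(phi, rho, phid, rhod, time = state$time + steps * dt,
                        species = state$species, boundary = state$boundary),
    dt = dt, species = state$species, boundary = state$boundary
  ), class = "chain_trajectory")
}

#' Helical-wave initial condition
#'
#' Real part of the plane-wave eigenstate of the secular problem at
#' wavevector `q` on the chosen branch: at t = 0,
#' \eqn{\phi_n = \Phi\cos(nq\xi)}, \eqn{\rho_n = -\Sigma\sin(nq\xi)}
#' with velocities \eqn{\dot\phi_n = \Phi\,\omega\sin(nq\xi)},
#' \eqn{\dot\rho_n = \Sigma\,\omega\cos(nq\xi)}, where the amplitude ratio
#' \eqn{\Sigma/\Phi} follows from the first row of the secular matrix
#' (the twist and radial fields are in phase quadrature).  The 2-vector
#' \eqn{(\Phi, \Sigma/R_0)} is normalized and scaled by `amplitude`.
#'
#' At \eqn{q = 0} and \eqn{q = \pi/\xi} the secular matrix is diagonal and
#' the mode is pure twist (acoustic) or pure radial (optical).
#'
#' @param q Wavevector (nm^-1), commensurate with the ring
#'   (`q * xi * N / (2*pi)` integral).
#' @param branch `"acoustic"` or `"optical"`.
#' @param n_sites Ring size N.
#' @param params,frame Model parameters.
#' @param amplitude Dimensionless amplitude applied to the normalized
#'   eigenvector; defaults to the ambient-temperature twist amplitude
#'   `phi0` = 0.14.
#' @return A `chain_state` together with attribute `omega` (rad/s).
#' @export
init_helical_wave <- function(q, branch = c("acoustic", "optical"), n_sites,
                              params = dna_params("GC"),
                              frame = helix_frame(params),
                              amplitude = params$electronic$phi0) {
  branch <- match.arg(branch)
  k_idx <- q * frame$xi * n_sites / (2 * pi)
  if (abs(k_idx - round(k_idx)) > 1e-8)
    stop("q = ", q, " nm^-1 is not commensurate with a ring of ", n_sites, " sites")
  cf <- characteristic_frequencies(params, frame)
  d <- dispersion_exact(q, cf, frame, params)
  omega <- if (branch == "acoustic") d$omega_minus else d$omega_plus
  kc <- .wave_constants(params, frame)
  G <- 4 * cf$omega_phi^2 * sin(q * frame$xi / 2)^2
  s_qxi <- sin(q * frame$xi)
  if (abs(s_qxi) > 1e-12) {
    # row 1 of the secular matrix: (G - w^2) Phi + 2 i A w_phi^2 sin(q xi) P = 0
    sigma <- (omega^2 - G) / (2 * kc$A * cf$omega_phi^2 * s_qxi)  # P = -i sigma Phi
    ev <- c(1, sigma / frame$R0)
  } else {
    H <- cf$omega_phirho^2 - cf$omega_phiS^2 * cos(q * frame$xi)
    # diagonal matrix: acoustic root is the twist one iff G < H
    twist_branch <- (branch == "acoustic") == (G <= H)
    ev <- if (twist_branch) c(1, 0) else c(0, 1)
    sigma <- ev[2] * frame$R0
  }
  ev <- ev / sqrt(sum(ev^2))
  Phi <- amplitude * ev[1]
  Sig <- amplitude * ev[2] * frame$R0
  ns <- seq_len(n_sites) - 1
  st <- chain_state(
    phi = Phi * cos(ns * q * frame$xi),
    rho = -Sig * sin(ns * q * frame$xi),
    phi_dot = Phi * omega * sin(ns * q * frame$xi),
    rho_dot = Sig * omega * cos(ns * q * frame$xi),
    species = params$species
  )
  attr(st, "omega") <- omega
  attr(st, "branch") <- branch
  attr(st, "q") <- q
  st
}

#' Complex mode projection of a trajectory
#'
#' Projects the twist and radial fields onto the plane wave
#' \eqn{e^{inq\xi}}: \eqn{P_\phi(t) = N^{-1}\sum_n \phi_n(t) e^{inq\xi}}
#' (and likewise for rho).  For a single travelling mode the modulus is
#' constant in time, which makes this the natural probe for amplitude
#' drift and cross-mode leakage.
#'
#' @param traj A `chain_trajectory`.
#' @param q Wavevector (nm^-1).
#' @param frame A `helix_frame`.
#' @return Complex matrix (T x 2) with columns `phi`, `rho`.
#' @export
mode_projection <- function(traj, q, frame) {
  ns <- seq_len(ncol(traj$phi)) - 1
  w <- exp(1i * ns * q * frame$xi)
  cbind(phi = as.vector(traj$phi %*% w) / length(ns),
        rho = as.vector(traj$rho %*% w) / length(ns))
}

#' Dominant oscillation frequencies of a projected mode
#'
#' FFT of the complex mode projection; returns the frequency (THz) of the
#' strongest spectral peak of the twist and radial projections.  Frequency
#' resolution is `1/(T_total)`.
#'
#' @inheritParams mode_projection
#' @return List with `nu_phi`, `nu_rho` (THz) and `resolution_thz`.
#' @export
dominant_frequencies <- function(traj, q, frame) {
  pr <- mode_projection(traj, q, frame)
  nt <- nrow(pr)
  dt_s <- diff(traj$time[1:2])
  freqs <- (seq_len(nt) - 1) / (nt * dt_s)        # Hz, one-sided layout
  freqs[freqs >= 1 / (2 * dt_s)] <- freqs[freqs >= 1 / (2 * dt_s)] - 1 / dt_s
  pick <- function(x) {
    sp <- abs(stats::fft(x - mean(x)))^2
    abs(freqs[which.max(sp)]) / 1e12
  }
  list(nu_phi = pick(pr[, "phi"]), nu_rho = pick(pr[, "rho"]),
       resolution_thz = 1 / (nt * dt_s) / 1e12)
}

# second difference over sites of a T x N field matrix (periodic ring)
.codon_field <- function(m) {
  n <- ncol(m)
  ip <- c(seq_len(n - 1) + 1, 1)
  im <- c(n, seq_len(n - 1))
  2 * m - m[, im, drop = FALSE] - m[, ip, drop = FALSE]
}

#' Codon-scale collective variables and their dynamical residual
#'
#' Builds the collective fields \eqn{x_n = 2\phi_n - \phi_{n-1} -
#' \phi_{n+1}} and \eqn{y_n = 2\rho_n - \rho_{n-1} - \rho_{n+1}} from a
#' homopolymer trajectory and checks that they obey the same equations of
#' motion as the per-site fields (self-similar renormalization of the
#' dynamics at the base-pair-triplet scale).  Second time-derivatives are
#' taken by central differences on the recorded time grid, so the residual
#' floor scales as \eqn{(\omega\,\Delta t_{rec})^2/12}.
#'
#' Setting `levels = 2` applies the triplet construction twice (nested
#' codons), which must satisfy the same equations again.
#'
#' @param traj A `chain_trajectory` of a homopolymer (uniformly recorded).
#' @param params,frame Model parameters matching the trajectory.
#' @param levels Number of nested triplet renormalizations (>= 1).
#' @return List with the collective fields `x`, `y` (T x N), the maximum
#'   relative residual `max_rel_residual`, and the per-field residuals.
#' @export
codon_collective <- function(traj, params = dna_params(traj$species[1]),
                             frame = helix_frame(params), levels = 1) {
  stopifnot(inherits(traj, "chain_trajectory"), levels >= 1)
  if (length(unique(traj$species)) != 1)
    stop("codon renormalization is defined for homopolymer trajectories")
  nt <- nrow(traj$phi)
  if (nt < 3) stop("trajectory too short to differentiate twice in time")
  dts <- diff(traj$time)
  if (max(abs(dts - dts[1])) > 1e-9 * abs(dts[1]))
    stop("trajectory must be recorded on a uniform time grid")
  dt_s <- dts[1]

  x <- traj$phi; y <- traj$rho
  for (l in seq_len(levels)) {
    x <- .codon_field(x)
    y <- .codon_field(y)
  }
  coeffs <- dynamics_coefficients(traj$species, params, frame)
  mid <- 2:(nt - 1)
  xdd <- (x[mid + 1, , drop = FALSE] - 2 * x[mid, , drop = FALSE] +
            x[mid - 1, , drop = FALSE]) / dt_s^2
  ydd <- (y[mid + 1, , drop = FALSE] - 2 * y[mid, , drop = FALSE] +
            y[mid - 1, , drop = FALSE]) / dt_s^2
  # Eqs. for the collective fields are formally identical to the per-site
  # ones: evaluate the same RHS on (x, y)
  res_phi <- xdd; res_rho <- ydd
  for (k in seq_along(mid)) {
    acc <- linear_rhs(list(phi = x[mid[k], ], rho = y[mid[k], ],
                           boundary = "periodic"), coeffs)
    res_phi[k, ] <- xdd[k, ] - acc$phi_ddot
    res_rho[k, ] <- ydd[k, ] - acc$rho_ddot
  }
  scale <- max(abs(xdd), abs(ydd), 1e-300)
  list(x = x, y = y,
       max_rel_residual = max(abs(res_phi), abs(res_rho)) / scale,
       residual_phi = res_phi, residual_rho = res_rho)
}

#' Generate a per-site base-pair species sequence
#'
#' @param kind `"homopolymer"`, `"random"` or `"fasta"`.
#' @param length Number of base pairs (ignored for `"fasta"`).
#' @param seed Integer seed for `"random"` (deterministic given the seed;
#'   the global RNG state is preserved).
#' @param species Homopolymer species.
#' @param p_gc Probability of a GC pair for `"random"`.
#' @param fasta Path to a FASTA file for `"fasta"`; the first record is
#'   used, positions map A/T -> `"AT"` and G/C -> `"GC"` (case
#'   insensitive); ambiguity codes are rejected.
#' @return Character vector of `"GC"`/`"AT"`.
#' @export
make_sequence <- function(kind = c("homopolymer", "random", "fasta"),
                          length = NULL, seed = NULL, species = "GC",
                          p_gc = 0.5, fasta = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    homopolymer = {
      stopifnot(!is.null(length))
      rep(species, length)
    },
    random = {
      stopifnot(!is.null(length))
      if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
        set.seed(seed)
      }
      sample(c("GC", "AT"), length, replace = TRUE, prob = c(p_gc, 1 - p_gc))
    },
    fasta = {
      stopifnot(!is.null(fasta))
      recs <- seqinr::read.fasta(fasta, seqtype = "DNA", as.string = FALSE,
                                 forceDNAtolower = TRUE)
      if (length(recs) == 0) stop("no sequences in ", fasta)
      chars <- toupper(as.character(recs[[1]]))
      bad <- setdiff(unique(chars), c("A", "T", "G", "C"))
      if (length(bad) > 0)
        stop("sequence contains characters outside A/C/G/T: ",
             paste(bad, collapse = ", "))
      ifelse(chars %in% c("G", "C"), "GC", "AT")
    }
  )
}
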