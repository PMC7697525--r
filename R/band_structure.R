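# Charge-carrier band structure of dsDNA homopolymers: quadratic band
# equation, transfer-matrix formalism with Chebyshev matrix powers, and the
# phonon-modulated bandgap.

# quadratic coefficients B2 E^2 + (B1 + F) E + (2 B0 - gamma F) = 0
.band_coeffs <- function(params, gamma) {
  e <- params$electronic
  list(B2 = 2 * e$b_xy - 1,
       B1 = gamma * (1 - 4 * e$b_xy) + 2 * e$a_xy,
       B0 = gamma * (gamma * e$b_xy - e$a_xy) + e$tP^2)
}

#' Electron-phonon coupling function of the band problem
#'
#' \deqn{F(\kappa, q) = t(q)\,[1 + 2\cos(\kappa h_0)]} where
#' \eqn{t(q)} is the phonon-modulated hopping of
#' [transfer_integral_phonon()].
#'
#' @param kappa Carrier wavevector (nm^-1); vectorised.
#' @param q Phonon wavevector (nm^-1).
#' @param model A `transfer_model`.
#' @return F in eV.
#' @export
coupling_function <- function(kappa, q, model) {
  transfer_integral_phonon(q, model) * (1 + 2 * cos(kappa * model$frame$h0))
}

#' Charge-carrier bands of a dsDNA homopolymer
#'
#' Solves the quadratic band equation
#' \deqn{B_2 E^2 + [B_1 + F(\kappa,q)]E + 2B_0 - \gamma F(\kappa,q) = 0,}
#' \eqn{B_2 = 2b_{XY}-1}, \eqn{B_1 = \gamma(1-4b_{XY}) + 2a_{XY}},
#' \eqn{B_0 = \gamma(\gamma b_{XY}-a_{XY}) + t_P^2},
#' at each carrier wavevector, yielding the two bands \eqn{E_\pm(\kappa,q)}.
#' Band widths are the energy differences between the band edges at
#' \eqn{\kappa = 0} and \eqn{\kappa h_0 = \pi}; the bandgap
#' \eqn{E_g(0,q)} is the separation of the two roots at \eqn{\kappa = 0}
#' (where the roots are the furthest-separated band edges).  Band widths
#' are reported both per energy-ordered band and as the ordered set
#' `{wider, narrower}`.
#'
#' @param kappa_grid Carrier wavevectors (nm^-1); the edge points 0 and
#'   pi/h0 are always included.
#' @param q Phonon wavevector (nm^-1).
#' @param params A `dna_params`.
#' @param gamma Backbone on-site energy (eV).
#' @return Object of class `band_structure`: list with `bands` (data frame
#'   `kappa`, `E_lower`, `E_upper` in eV; `NA` where the roots are complex,
#'   flagged in `gap_closed`), `W_upper`, `W_lower`, `W_set` (meV,
#'   decreasing), `Eg_meV` (root separation at kappa = 0), `edges` (eV),
#'   `species`, `gamma`, `q`.
#' @export
carrier_bands <- function(kappa_grid = NULL, q = 0, params,
                          gamma = params$electronic$gamma) {
  fr <- helix_frame(params)
  if (is.null(kappa_grid)) kappa_grid <- seq(0, pi / fr$h0, length.out = 101)
  kappa_grid <- sort(unique(c(0, pi / fr$h0, kappa_grid)))
  model <- transfer_model(params, fr)
  cb <- .band_coeffs(params, gamma)
  stopifnot(cb$B2 != 0)
  Fk <- coupling_function(kappa_grid, q, model)
  disc <- (cb$B1 + Fk)^2 - 4 * cb$B2 * (2 * cb$B0 - gamma * Fk)
  closed <- disc < 0
  sq <- sqrt(pmax(disc, 0))
  E_upper <- (-(cb$B1 + Fk) + sq) / (2 * cb$B2)
  E_lower <- (-(cb$B1 + Fk) - sq) / (2 * cb$B2)
  E_upper[closed] <- NA_real_; E_lower[closed] <- NA_real_

  at <- function(kap) {
    i <- which.min(abs(kappa_grid - kap))
    c(lower = E_lower[i], upper = E_upper[i])
  }
  e0 <- at(0); epi <- at(pi / fr$h0)
  W_upper <- abs(e0[["upper"]] - epi[["upper"]]) * 1e3
  W_lower <- abs(e0[["lower"]] - epi[["lower"]]) * 1e3
  structure(list(
    bands = data.frame(kappa = kappa_grid, E_lower = E_lower, E_upper = E_upper),
    W_upper = W_upper, W_lower = W_lower,
    W_set = sort(c(W_upper, W_lower), decreasing = TRUE),
    Eg_meV = (e0[["upper"]] - e0[["lower"]]) * 1e3,
    edges = c(lower_k0 = e0[["lower"]], lower_kpi = epi[["lower"]],
              upper_k0 = e0[["upper"]], upper_kpi = epi[["upper"]]),
    gap_closed = any(closed),
    species = params$species, gamma = gamma, q = q
  ), class = "band_structure")
}

#' @export
print.band_structure <- function(x, ...) {
  cat(sprintf("Band structure: %s homopolymer, gamma = %.3g eV, q = %.4g nm^-1\n",
              x$species, x$gamma, x$q))
  cat(sprintf("  widths {%.1f, %.1f} meV, Eg(kappa=0) = %.1f meV%s\n",
              x$W_set[1], x$W_set[2], x$Eg_meV,
              if (x$gap_closed) " [gap closed on part of the grid]" else ""))
  invisible(x)
}

#' Closed-form bandgap
#'
#' \deqn{E_g(0,q) = \frac{\sqrt{[3t(q) + 2a_{XY} - \gamma]^2 -
#'   8(2b_{XY}-1)t_P^2}}{2b_{XY}-1},}
#' the separation of the two roots of the band equation at
#' \eqn{\kappa = 0}, with the hopping phonon-modulated via
#' \eqn{3t_0 \to 3t(q)}.  A negative radicand means the gap is closed
#' (semimetallic); the function then returns 0 with `semimetal = TRUE`.
#'
#' @param params A `dna_params`.
#' @param gamma Backbone on-site energy (eV).
#' @param q Phonon wavevector (nm^-1); vectorised.
#' @return List with `Eg_meV` and logical `semimetal` (both vectorised
#'   along `q`).
#' @export
bandgap_closed_form <- function(params, gamma = params$electronic$gamma, q = 0) {
  e <- params$electronic
  model <- transfer_model(params)
  t_q <- transfer_integral_phonon(q, model)
  b2 <- 2 * e$b_xy - 1
  radicand <- (3 * t_q + 2 * e$a_xy - gamma)^2 - 8 * b2 * e$tP^2
  list(Eg_meV = sqrt(pmax(radicand, 0)) / b2 * 1e3,
       semimetal = radicand < 0)
}

#' Transfer matrix of the effective 1D chain
#'
#' \deqn{M(E,q) = \begin{pmatrix}
#'   \dfrac{E - \epsilon_{XY}(E) - t(q)}{t(q)} & -1\\ 1 & 0
#' \end{pmatrix}}
#' propagating \eqn{(\psi_{n+1}, \psi_n)}; unimodular by construction.
#'
#' @param E Carrier energy (eV), away from the backbone pole `gamma`.
#' @param q Phonon wavevector (nm^-1).
#' @param params A `dna_params`.
#' @param gamma Backbone on-site energy (eV).
#' @return 2x2 numeric matrix with `det = 1`.
#' @export
transfer_matrix <- function(E, q = 0, params, gamma = params$electronic$gamma) {
  model <- transfer_model(params)
  t_q <- transfer_integral_phonon(q, model)
  stopifnot(t_q != 0)
  eps <- onsite_epsilon(E, params, gamma)
  matrix(c((E - eps - t_q) / t_q, 1, -1, 0), 2, 2)
}

#' Power of a unimodular matrix via Chebyshev polynomials
#'
#' For a 2x2 matrix with unit determinant,
#' \deqn{M^N = U_{N-1}(x)\,M - U_{N-2}(x)\,I,\qquad x = \mathrm{tr}\,M/2,}
#' where \eqn{U_m} are Chebyshev polynomials of the second kind, evaluated
#' by their three-term recurrence \eqn{U_{m+1} = 2xU_m - U_{m-1}} (which
#' continues smoothly to the hyperbolic regime `|x| > 1` and handles the
#' degenerate band edges `x = +/-1`, where \eqn{U_m = (\pm 1)^m (m+1)},
#' without special-casing).
#'
#' @param M 2x2 unimodular matrix.
#' @param N Power (>= 1).
#' @return The matrix `M^N`.
#' @export
chebyshev_power <- function(M, N) {
  stopifnot(is.matrix(M), all(dim(M) == 2), N >= 1,
            abs(det(M) - 1) < 1e-9)
  x <- (M[1, 1] + M[2, 2]) / 2
  Um1 <- 0; U0 <- 1           # U_{-1}, U_0
  if (N == 1) return(M)
  Ua <- U0; Ub <- 2 * x * U0 - Um1   # U_0, U_1
  for (m in seq_len(N - 2)) {
    tmp <- 2 * x * Ub - Ua
    Ua <- Ub; Ub <- tmp
  }
  # now Ua = U_{N-2}, Ub = U_{N-1}
  Ub * M - Ua * diag(2)
}

#' Carrier wavevector from the band dispersion, with evanescent regions
#'
#' Inverts the single-band dispersion
#' \eqn{E = \epsilon_{XY}(E) + t(q)[1 + 2\cos(\kappa h_0)]}:
#' returns \eqn{\kappa(E)} where \eqn{|E - \epsilon - t|/2t \le 1}, and
#' `NA` (evanescent) elsewhere.  For a periodic ring of `N` pairs it also
#' verifies the finite-chain condition
#' \eqn{\cos(\kappa N h_0) = \mathrm{tr}\,M^N/2}.
#'
#' @param E_grid Carrier energies (eV).
#' @param q Phonon wavevector (nm^-1).
#' @param n_sites Ring size N used in the transfer-matrix check.
#' @param params A `dna_params`.
#' @param gamma Backbone on-site energy (eV).
#' @return Data frame with `E`, `cos_kh` (the right-hand side), `kappa`
#'   (nm^-1 or `NA`), `allowed`, `trMN_half` (tr M^N / 2).
#' @export
finite_chain_dispersion <- function(E_grid, q = 0, n_sites = 8, params,
                                    gamma = params$electronic$gamma) {
  stopifnot(n_sites >= 2)
  fr <- helix_frame(params)
  model <- transfer_model(params, fr)
  t_q <- transfer_integral_phonon(q, model)
  eps <- onsite_epsilon(E_grid, params, gamma)
  cos_kh <- (E_grid - eps - t_q) / (2 * t_q)
  allowed <- abs(cos_kh) <= 1 + 1e-9   # band edges hit +-1 to rounding
  kappa <- ifelse(allowed, acos(pmin(pmax(cos_kh, -1), 1)) / fr$h0, NA_real_)
  tr_half <- vapply(E_grid, function(E) {
    M <- transfer_matrix(E, q, params, gamma)
    MN <- chebyshev_power(M, n_sites)
    (MN[1, 1] + MN[2, 2]) / 2
  }, numeric(1))
  data.frame(E = E_grid, cos_kh = cos_kh, kappa = kappa,
             allowed = allowed, trMN_half = tr_half)
}

#' Bandgap versus backbone on-site energy
#'
#' Scans \eqn{E_g(\gamma)} from the closed form and reports the closure
#' points where the radicand
#' \eqn{[3t(q) + 2a_{XY} - \gamma]^2 - 8(2b_{XY}-1)t_P^2}
#' crosses zero: the duplex is semimetallic for
#' \eqn{\gamma \in [\gamma_1, \gamma_2]} with
#' \eqn{\gamma_{1,2} = 3t(q) + 2a_{XY} \mp \sqrt{8(2b_{XY}-1)}\,t_P}
#' (a semiconductor-semimetal transition tuned by the backbone energy).
#'
#' @param gamma_grid Backbone energies (eV), conventionally within 0..12.
#' @param q Phonon wavevector (nm^-1).
#' @param params A `dna_params`.
#' @return List with `scan` (data frame `gamma`, `Eg_meV`, `semimetal`)
#'   and `closure_gamma` (the two analytic closure points, eV).
#' @export
gamma_scan <- function(gamma_grid = seq(0, 12, by = 0.05), q = 0, params) {
  e <- params$electronic
  model <- transfer_model(params)
  t_q <- transfer_integral_phonon(q, model)
  res <- bandgap_closed_form(params, gamma = gamma_grid, q = q)
  root_shift <- sqrt(8 * (2 * e$b_xy - 1)) * abs(e$tP)
  closure <- 3 * t_q + 2 * e$a_xy + c(-1, 1) * root_shift
  list(scan = data.frame(gamma = gamma_grid, Eg_meV = res$Eg_meV,
                         semimetal = res$semimetal),
       closure_gamma = closure)
}
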