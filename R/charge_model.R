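# Twist/radial-dependent pi-pi transfer integrals and the decimation /
# renormalization chain producing the effective 1D electronic Hamiltonian.

#' Slater-Koster two-centre hopping element
#'
#' \deqn{V_{ppx} = \eta_{ppx}\,\frac{\hbar^2}{m_e d^2}\,e^{-d/R_c}}
#' with \eqn{\hbar^2/m_e = 0.0762} eV nm^2.
#'
#' @param eta Dimensionless hybridization constant (`eta_ppsigma` or
#'   `eta_pppi`; the sign of the pi element is carried by `eta`).
#' @param d Inter-orbital distance (nm, > 0).
#' @param Rc Decay length of the atomic wavefunction tails (nm, > 0).
#' @return Hopping element in eV.
#' @export
slater_koster_v <- function(eta, d, Rc) {
  stopifnot(all(d > 0), all(Rc > 0))
  eta * .HBAR2_OVER_ME / d^2 * exp(-d / Rc)
}

#' Transfer-integral model for a homopolymer
#'
#' Bundles the optimal face-to-face integral `t0`, the electron-phonon
#' coupling strength \eqn{\chi = \bar\eta (R_0/l_0)^2} (derived, not
#' hard-coded), the helicity constant \eqn{\bar\eta = 1 +
#' |\eta_{pp\pi}|/\eta_{pp\sigma}} and the helix frame.  The default
#' oscillation amplitudes give \eqn{A_0^2 = \phi_0^2 + (\rho_0/R_0)^2}.
#'
#' @param params A `dna_params`.
#' @param frame A `helix_frame`.
#' @return Object of class `transfer_model` with fields `t0`, `chi`,
#'   `eta_bar`, `A0sq`, `frame`, `species`.
#' @export
transfer_model <- function(params, frame = helix_frame(params)) {
  e <- params$electronic
  eta_bar <- 1 + abs(e$eta_pppi) / e$eta_ppsigma
  chi <- eta_bar * (frame$R0 / frame$l0)^2
  structure(list(
    t0 = e$t0, chi = chi, eta_bar = eta_bar,
    A0sq = e$phi0^2 + (e$rho0 / frame$R0)^2,
    frame = frame, species = params$species
  ), class = "transfer_model")
}

#' Twist/radial-dependent pi-pi transfer integral
#'
#' The full form reduces the face-to-face integral by the squared chord
#' distance between the two base attachment points:
#' \deqn{t = t_0\Big[1 - \frac{\bar\eta}{l_0^2}\big((R_0+\rho_n)^2 +
#'   (R_0+\rho_m)^2 - 2(R_0+\rho_n)(R_0+\rho_m)\cos\theta\big)\Big].}
#' Named variants give the standard approximations: `"equilibrium"`
#' evaluates at \eqn{(0, \theta_0)}; `"small_twist"` is
#' \eqn{t_0[1-\chi\theta^2]}; `"radial_twist"` keeps
#' \eqn{(v_n-v_m)^2 + (1+v_n)(1+v_m)\theta^2} with \eqn{v = \rho/R_0};
#' `"linearized"` keeps \eqn{(v_n-v_m)^2 + \theta^2}.
#'
#' @param rho_n,rho_m Radial displacements (nm); vectorised.
#' @param theta Relative twist (rad).
#' @param model A `transfer_model`.
#' @param form Which expression to evaluate (default full).
#' @return Hopping in eV (can be <= 0 for extreme distortions).
#' @export
transfer_integral <- function(rho_n, rho_m, theta, model,
                              form = c("full", "equilibrium", "small_twist",
                                       "radial_twist", "linearized")) {
  form <- match.arg(form)
  fr <- model$frame
  R0 <- fr$R0
  vn <- rho_n / R0; vm <- rho_m / R0
  switch(form,
    full = {
      rn <- R0 + rho_n; rm <- R0 + rho_m
      chord2 <- rn^2 + rm^2 - 2 * rn * rm * cos(theta)
      model$t0 * (1 - model$eta_bar / fr$l0^2 * chord2)
    },
    equilibrium = model$t0 *
      (1 - model$eta_bar * (2 * R0 / fr$l0)^2 * sin(fr$theta0 / 2)^2),
    small_twist = model$t0 * (1 - model$chi * theta^2),
    radial_twist = model$t0 *
      (1 - model$chi * ((vn - vm)^2 + (1 + vn) * (1 + vm) * theta^2)),
    linearized = model$t0 * (1 - model$chi * ((vn - vm)^2 + theta^2))
  )
}

#' Phonon-modulated transfer integral of a synchronized helical wave
#'
#' For a helical wave of wavevector `q` with twist amplitude
#' \eqn{\phi_0} and radial amplitude \eqn{\rho_0}, the site-independent
#' hopping is
#' \deqn{t(q) = t_0\big[1 - 4\chi A_0^2 \sin^2(q\xi/2)\big],\qquad
#'       A_0^2 = \phi_0^2 + (\rho_0/R_0)^2.}
#' With the default amplitudes \eqn{4\chi A_0^2 \approx 0.26 < 1}, so
#' \eqn{t(q) > 0} for all q.
#'
#' @param q Wavevector (nm^-1); vectorised.
#' @param model A `transfer_model`.
#' @param A0sq Squared dimensionless oscillation amplitude; defaults to the
#'   model's ambient-temperature value.
#' @return Hopping in eV.
#' @export
transfer_integral_phonon <- function(q, model, A0sq = model$A0sq) {
  t <- model$t0 * (1 - 4 * model$chi * A0sq * sin(q * model$frame$xi / 2)^2)
  if (any(t <= 0))
    stop("phonon amplitude too large: t(q) <= 0 (4 chi A0^2 >= 1)")
  t
}

#' Effective base-backbone hopping after the first decimation
#'
#' \deqn{\tau_j = t_P + \frac{\varepsilon_j}{t_P}(E - \gamma_j)}
#' renormalizes the glycosidic hopping by the base on-site energy when the
#' sugar-phosphate site is eliminated.
#'
#' @param eps_j Base on-site energy (eV).
#' @param E Charge-carrier energy (eV).
#' @param tP Glycosidic hopping (eV, nonzero).
#' @param gamma_j Backbone on-site energy (eV).
#' @return Effective hopping in eV.
#' @export
backbone_tau <- function(eps_j, E, tP = 1.5, gamma_j = 0) {
  stopifnot(tP != 0)
  tP + eps_j / tP * (E - gamma_j)
}

#' Energy-dependent renormalized on-site correction
#'
#' Decimating the two backbone sites attached to a pair adds the
#' energy-dependent correction (uniform backbone energy gamma):
#' \deqn{\epsilon_{XY}(E) = \frac{2\big[t_P^2 + a_{XY}(E-\gamma) +
#'   b_{XY}(E-\gamma)^2\big]}{E-\gamma},}
#' with \eqn{a_{XY} = \varepsilon_X + \varepsilon_Y} and
#' \eqn{b_{XY} = (\varepsilon_X^2+\varepsilon_Y^2)/(2t_P^2)}.  This closed
#' form is algebraically identical to the sum
#' \eqn{\tau_X^2/(E-\gamma) + \tau_Y^2/(E-\gamma)} of squared decimated
#' hoppings.
#'
#' @param E Carrier energy (eV); must differ from `gamma`.
#' @param params A `dna_params` (supplies `a_xy`, `b_xy`, `tP`).
#' @param gamma Backbone on-site energy (eV); defaults to the registry
#'   value.
#' @return \eqn{\epsilon_{XY}(E)} in eV.
#' @export
onsite_epsilon <- function(E, params, gamma = params$electronic$gamma) {
  e <- params$electronic
  x <- E - gamma
  if (any(x == 0)) stop("E = gamma: renormalized on-site energy has a pole")
  2 * (e$tP^2 + e$a_xy * x + e$b_xy * x^2) / x
}

#' Fully renormalized on-site energy
#'
#' \eqn{\tilde\varepsilon(E) = t_{pair} + \epsilon_{XY}(E)}: the pi-pi
#' hopping to the neighbouring pair appears on the diagonal of the
#' effective 1D Hamiltonian alongside the backbone correction.
#'
#' @param E Carrier energy (eV).
#' @param t_pair pi-pi transfer integral (eV), e.g. from
#'   [transfer_integral_phonon()].
#' @inheritParams onsite_epsilon
#' @return Renormalized on-site energy in eV.
#' @export
onsite_renormalized <- function(E, t_pair, params,
                                gamma = params$electronic$gamma) {
  t_pair + onsite_epsilon(E, params, gamma)
}

#' Tridiagonal coefficients of the effective 1D chain
#'
#' Builds the N-site effective Hamiltonian of a homopolymer threaded by a
#' helical phonon of wavevector `q`: diagonal \eqn{t(q) + \epsilon_{XY}(E)},
#' off-diagonal \eqn{-t(q)} (Hermitian by construction).
#'
#' @param n_sites Chain length N.
#' @param E Carrier energy (eV).
#' @param q Phonon wavevector (nm^-1).
#' @param params A `dna_params`.
#' @param gamma Backbone on-site energy (eV).
#' @param periodic If `TRUE`, also report the ring-closing hopping.
#' @return List with `diagonal` (length N), `offdiagonal` (length N-1, or
#'   N with the seam bond last when `periodic`), `t_q`, `eps_E`.
#' @export
build_effective_chain <- function(n_sites, E, q = 0, params,
                                  gamma = params$electronic$gamma,
                                  periodic = FALSE) {
  model <- transfer_model(params)
  t_q <- transfer_integral_phonon(q, model)
  eps_E <- onsite_epsilon(E, params, gamma)
  list(
    diagonal = rep(t_q + eps_E, n_sites),
    offdiagonal = rep(-t_q, if (periodic) n_sites else n_sites - 1),
    t_q = t_q, eps_E = eps_E
  )
}
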