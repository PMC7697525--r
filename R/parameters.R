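# Parameter registry: single source of truth for the geometry, lattice and
# electronic parameter sets of the homopolymer duplex model.

# Nucleobase masses (amu)
.BASE_MASS <- c(G = 347.05, C = 307.05, A = 331.06, T = 322.05)

#' Default model parameters for a dsDNA homopolymer
#'
#' Assembles the full parameter registry for a polyG-polyC (`"GC"`) or
#' polyA-polyT (`"AT"`) duplex: helix geometry, lattice (Peyrard-Dauxois-
#' Bishop) constants, per-pair mass ratios and the electronic (tight-binding)
#' set.  The mass ratio \eqn{\lambda} (heavy base over light base) and the
#' derived factor \eqn{\mu = \lambda^{-1}(1+\lambda)^2} are computed from the
#' base masses, never hard-coded.
#'
#' Unit conventions: lengths nm, energies eV, masses amu, angles rad.  The
#' stacking range `b` and Morse width `alpha` are commonly quoted in
#' inverse Angstrom; they are stored here in nm^-1 (x10).
#'
#' The on-site energies of G and T are only known as ranges; they are kept
#' as ranges in `eps_range`.  Band-structure defaults use the pair
#' coefficients `a_xy` (eV) and `b_xy` (dimensionless) directly, so no
#' within-range choice is needed.
#'
#' @param species `"GC"` or `"AT"`.
#' @param overrides Named list of replacements applied on top of the
#'   defaults (e.g. `list(gamma = 2)`).  The returned object is a fresh
#'   copy; parameter sets are never mutated in place.
#' @return An object of class `dna_params`: a list with components
#'   `species`, `geometry` (`theta0`, `h0`, `R0`), `lattice` (`kB`, `kS`,
#'   `b`, `D`, `alpha`, `M`), `pair` (`mass_heavy`, `mass_light`, `lambda`,
#'   `mu`) and `electronic` (`eps_range`, `tP`, `gamma`, `t_perp`, `t0`,
#'   `eta_ppsigma`, `eta_pppi`, `eta_bar`, `phi0`, `rho0`, `a_xy`, `b_xy`).
#' @examples
#' p <- dna_params("GC")
#' p$pair$lambda   # ~1.130
#' p$pair$mu       # ~4.015
#' @export
dna_params <- function(species = c("GC", "AT"), overrides = NULL) {
  species <- match.arg(species)

  pair_masses <- switch(species,
    GC = c(heavy = .BASE_MASS[["G"]], light = .BASE_MASS[["C"]]),
    AT = c(heavy = .BASE_MASS[["A"]], light = .BASE_MASS[["T"]])
  )
  lambda <- pair_masses[["heavy"]] / pair_masses[["light"]]
  mu <- (1 + lambda)^2 / lambda

  p <- list(
    species = species,
    geometry = list(
      theta0 = pi / 5.2,  # equilibrium twist angle (rad)
      h0     = 0.34,      # rise per bp (nm)
      R0     = 1.0        # helix radius (nm)
    ),
    lattice = list(
      kB    = 4,      # backbone spring constant, 0.04 eV/A^2 (eV nm^-2)
      kS    = 70,     # stacking stiffness, 0.7 eV/A^2 (eV nm^-2)
      b     = 5,      # stacking range, 0.5 A^-1 (nm^-1)
      D     = 0.15,   # Morse depth (eV); one effective Morse set for both pairs
      alpha = 50,     # Morse width, 5 A^-1 (nm^-1)
      M     = 653.5   # base-pair mass (amu)
    ),
    pair = list(
      mass_heavy = pair_masses[["heavy"]],
      mass_light = pair_masses[["light"]],
      lambda = lambda,
      mu = mu
    ),
    electronic = list(
      eps_range = list(
        G = c(7.8, 8.2), A = c(8.2, 8.2), C = c(8.9, 8.9), T = c(9.0, 9.1)
      ),
      tP     = 1.5,                               # glycosidic hopping (eV)
      gamma  = 0,                                 # backbone on-site energy (eV)
      t_perp = switch(species, GC = 0.01, AT = 0.02),  # interstrand hopping (eV); stored, unused
      t0     = switch(species, GC = 0.08, AT = 0.09),  # face-to-face transfer integral (eV)
      eta_ppsigma = 5.27,
      eta_pppi    = -2.26,
      eta_bar     = 1 + 2.26 / 5.27,
      phi0 = 0.14,   # twist oscillation amplitude (rad)
      rho0 = 0.05,   # radial oscillation amplitude (nm)
      # pair band-model coefficients: a_xy = eps_X + eps_Y (eV),
      # b_xy = (eps_X^2 + eps_Y^2)/(2 tP^2)
      a_xy = switch(species, GC = 16.6, AT = 17.4),
      b_xy = switch(species, GC = 30.9, AT = 33.6)
    )
  )

  if (!is.null(overrides)) p <- .apply_overrides(p, overrides)
  .validate_params(p)
  structure(p, class = "dna_params")
}

# Recursive merge of a (possibly nested) named override list.
.apply_overrides <- function(p, overrides) {
  stopifnot(is.list(overrides), !is.null(names(overrides)))
  for (nm in names(overrides)) {
    if (nm %in% names(p) && is.list(p[[nm]]) && is.list(overrides[[nm]])) {
      p[[nm]] <- utils::modifyList(p[[nm]], overrides[[nm]])
    } else {
      # allow flat overrides of leaf parameters anywhere in the registry
      placed <- FALSE
      for (blk in c("geometry", "lattice", "pair", "electronic")) {
        if (nm %in% names(p[[blk]])) {
          p[[blk]][[nm]] <- overrides[[nm]]
          placed <- TRUE
          break
        }
      }
      if (!placed) p[[nm]] <- overrides[[nm]]
    }
  }
  p
}

.validate_params <- function(p) {
  g <- p$geometry
  if (!(g$theta0 > 0 && g$theta0 < pi)) stop("theta0 must lie in (0, pi)")
  if (g$h0 <= 0 || g$R0 <= 0) stop("h0 and R0 must be positive")
  l <- p$lattice
  if (any(unlist(l) <= 0)) stop("all lattice parameters must be strictly positive")
  if (p$pair$lambda < 1) stop("lambda convention: heavy base on reference strand (lambda >= 1)")
  e <- p$electronic
  if (e$tP == 0) stop("tP must be nonzero")
  if (e$eta_ppsigma <= 0) stop("eta_ppsigma must be positive")
  invisible(p)
}

#' @export
print.dna_params <- function(x, ...) {
  cat(sprintf("dsDNA homopolymer parameter set: poly%s-poly%s\n",
              substr(x$species, 1, 1), substr(x$species, 2, 2)))
  cat(sprintf("  geometry : theta0 = %.5f rad, h0 = %.3f nm, R0 = %.2f nm\n",
              x$geometry$theta0, x$geometry$h0, x$geometry$R0))
  cat(sprintf("  lattice  : kB = %.3g, kS = %.3g eV/nm^2, b = %.3g, alpha = %.3g /nm, D = %.3g eV, M = %.1f amu\n",
              x$lattice$kB, x$lattice$kS, x$lattice$b, x$lattice$alpha,
              x$lattice$D, x$lattice$M))
  cat(sprintf("  pair     : masses %.2f / %.2f amu, lambda = %.4f, mu = %.4f\n",
              x$pair$mass_heavy, x$pair$mass_light, x$pair$lambda, x$pair$mu))
  cat(sprintf("  electronic: t0 = %.3g eV, tP = %.2f eV, gamma = %.3g eV, a_xy = %.2f eV, b_xy = %.2f\n",
              x$electronic$t0, x$electronic$tP, x$electronic$gamma,
              x$electronic$a_xy, x$electronic$b_xy))
  invisible(x)
}

#' Base-pair mass bookkeeping for both species
#'
#' @return Data frame with one row per pair species: heavy and light base
#'   masses, their sum, the nominal pair mass `M`, `lambda` and `mu`.
#' @export
pair_mass_table <- function() {
  rows <- lapply(c("GC", "AT"), function(s) {
    p <- dna_params(s)
    data.frame(
      species = s,
      mass_heavy = p$pair$mass_heavy,
      mass_light = p$pair$mass_light,
      mass_sum = p$pair$mass_heavy + p$pair$mass_light,
      M = p$lattice$M,
      lambda = p$pair$lambda,
      mu = p$pair$mu
    )
  })
  do.call(rbind, rows)
}
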