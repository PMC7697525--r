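---
title: "Methods: helicoidal lattice dynamics and charge transfer in dsDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: helicoidal lattice dynamics and charge transfer in dsDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixCT)
```

## The model

`helixCT` treats a double-stranded B-DNA molecule as two coupled
subsystems.

**Lattice.** Each Watson–Crick pair is two point masses (one per strand)
on a helix of radius $R_0 = 1$ nm with rise $h_0 = 0.34$ nm per pair and
equilibrium twist $\theta_0 = \pi/5.2$. The axial position is slaved to
the twist ($z = c\varphi$, $c = h_0/\theta_0$), so the helical topology is
preserved during the dynamics. With the pair centre of mass held fixed,
the complementary strand's radial displacement is $\bar\rho = \lambda\rho$
where $\lambda$ is the heavy-to-light base mass ratio ($\lambda_{GC} =
347.05/307.05 \simeq 1.130$, $\lambda_{AT} = 331.06/322.05 \simeq 1.028$).
Three potentials act on the coordinates $(\varphi_n, \rho_n)$:

* a Morse potential for the interstrand hydrogen bonds,
  $U_H = \sum_n D\,[e^{-(\alpha/2)(1+\lambda_n)\rho_n}-1]^2$;
* an exponentially softened stacking term,
  $U_S = \tfrac18\sum_n k_S[1+e^{-(b/2)u^+}](u^-)^2$ with
  $u^\pm = (1+\lambda_n)\rho_n \pm (1+\lambda_{n+1})\rho_{n+1}$;
* a harmonic backbone term $U_B = \tfrac{k_B}{2}\sum_n
  (d_{n,n+1}-l_0)^2 + (\bar d_{n,n+1}-l_0)^2$, where $d$ is the exact
  Euclidean distance between neighbouring bases on one strand of the
  helix.

Linearizing about the B-form equilibrium yields coupled equations for
$\varphi_n$ and $\rho_n$ whose constants are the characteristic
frequencies $\omega_\varphi, \omega_S, \omega_H$ and the coupled
combinations $\omega_{\varphi\rho}, \omega_{\varphi S}, \omega_{HS}$
(all exposed by `characteristic_frequencies()`), plus two geometric
lengths $l_B = 2f_0/g_0 \simeq 8.58$ nm and $a_B = g_0\xi^2/f_0 \simeq
0.307$ nm. Plane-wave solutions give an acoustic (twist-dominated) and an
optical (stretch-dominated) phonon branch (`dispersion_exact()`).

**Charge.** Carriers hop between the $\pi$ stacks of consecutive pairs
with a transfer integral that decreases with the squared chord distance
between the pairs, $t = t_0[1 - (\bar\eta/l_0^2)\,\mathrm{chord}^2]$,
$\bar\eta = 1 + |\eta_{pp\pi}|/\eta_{pp\sigma} \simeq 1.429$. Eliminating
(decimating) the sugar–phosphate sites produces an effective 1D chain
whose on-site energies acquire the energy-dependent correction
$\epsilon_{XY}(E) = 2[t_P^2 + a_{XY}(E-\gamma) + b_{XY}(E-\gamma)^2]/(E-\gamma)$.
Because the dispersion is a quadratic polynomial in $E$, the two carrier
bands are obtained in closed form (`carrier_bands()`), and the
transfer-matrix route (`transfer_matrix()`, `chebyshev_power()`) provides
an independent consistency check.

A synchronized helical phonon of wavevector $q$ modulates every hopping
identically, $t(q) = t_0[1 - 4\chi A_0^2\sin^2(q\xi/2)]$ with
$\chi = \bar\eta(R_0/l_0)^2$ and $A_0^2 = \varphi_0^2 + (\rho_0/R_0)^2$.
This is the central physical statement of the package: *collective*
oscillations modify charge transport coherently, shrinking the carrier
bandgap as $q$ grows towards the zone boundary $q^* = \pi/\xi$, whereas
incoherent fluctuations would simply degrade the overlap.

## Parameters that matter

All parameters live in a single immutable registry, `dna_params()`,
in nm / eV / amu / rad units:

| parameter | default | meaning |
|---|---|---|
| $\theta_0, h_0, R_0$ | $\pi/5.2$ rad, 0.34 nm, 1 nm | B-form geometry |
| $k_B$ | 4 eV nm⁻² | backbone spring (literature spans 4–50) |
| $k_S$, $b$ | 70 eV nm⁻², 5 nm⁻¹ | stacking stiffness and range |
| $D$, $\alpha$ | 0.15 eV, 50 nm⁻¹ | Morse depth/width (one set for both pairs) |
| $M$ | 653.5 amu | pair mass; $\lambda,\mu$ derived from base masses |
| $t_0$ | 0.08 (GC) / 0.09 (AT) eV | face-to-face transfer integral |
| $t_P$, $\gamma$ | 1.5 eV, 0 eV | glycosidic hopping, backbone on-site energy |
| $a_{XY}$, $b_{XY}$ | 16.6/30.9 (GC), 17.4/33.6 (AT) | pair band coefficients |
| $\varphi_0$, $\rho_0$ | 0.14 rad, 0.05 nm | ambient oscillation amplitudes |

Notes on deliberate choices:

* $\lambda$ and $\mu = \lambda^{-1}(1+\lambda)^2$ are always computed from
  the base masses; $\mu = 4$ exactly for an equal-mass pair.
* G and T on-site energies are only known as ranges; they are stored as
  ranges and the band model uses $a_{XY}, b_{XY}$ directly, so no
  within-range choice contaminates the band results.
* $\chi$ is derived from the frame, giving 3.04 at full precision; the
  commonly quoted 2.92 comes from using the rounded $l_0 = 0.68$ nm.
  Derived constants here never inherit print rounding; the same policy
  gives $l_B = 8.580$ (vs the rounded 8.575) and $q^* = 2.738$ nm⁻¹ (vs
  2.732 from $\xi \approx 1.15$).
* The interstrand hopping $t_\perp$ is stored in the registry but unused:
  it does not appear in the effective 1D chain, and the intra-pair
  renormalization step that would consume it is not specified precisely
  enough to implement without guessing.
* The reference frequency table is internally consistent with an
  effective pair mass of about 635 amu rather than the nominal 653.5 amu;
  we keep the nominal mass, which places every frequency 1.3–1.9% below
  the reference values. Comparisons therefore use a 2.5% band.

## Dynamics simulator

`integrate_chain()` integrates the *linearized* equations with fixed-step
RK4. This is a deliberate scope decision: every analytic result of the
model (dispersion, codon renormalization, phonon-modulated hopping)
concerns the linear system, and the nonlinear potentials are retained in
`lattice_energetics` purely as an independent check. The finite-difference
Hessian of the full potentials at equilibrium, Bloch-transformed on a
homopolymer ring (`hessian_frequencies()`), reproduces the analytic
branches — to well within the 10% verification band, because every term
dropped in the linearization vanishes identically at the equilibrium
configuration.

Numerical choices:

* default `dt` of 1 fs, ~1/450 of the fastest period (0.45 ps); the
  integrator refuses `dt >= 0.05/nu_max`;
* helical waves are realized as the real part of the complex ansatz, with
  the twist field cosine-like at site 0 and the radial field in phase
  quadrature (the secular matrix has imaginary off-diagonal entries);
  at $q = 0$ and $q = q^*$ the eigenvector degenerates to pure twist or
  pure radial motion and the normalized amplitude is applied to the
  surviving component;
* periodic boundaries by default (matching the Bloch analysis); free ends
  clamp the ghost neighbours and are intended for qualitative runs only;
* the codon residual uses central time differences, so its floor is
  $(\omega\,\Delta t_{rec})^2/12$; record every step when checking it;
* finite-difference steps: $10^{-6}$ (gradient) and $10^{-5}$ (Hessian)
  in nm/rad, balancing truncation against cancellation in the quartic
  energy surface.

Problem sizes used in the shipped checks — rings of 12–27 sites for
algebraic identities, 300 sites over ten acoustic periods for mode
preservation, 16k-step runs for spectral recovery — were chosen as the
smallest sizes at which the measured quantities are grid-converged (FFT
resolution below the branch spacing, leakage floor well under the 0.1%
criterion).

## Synthetic sequences

`make_sequence()` generates homopolymer, Bernoulli-random (seeded), or
FASTA-derived species strings; FASTA positions map A/T to an AT pair and
G/C to a GC pair, and ambiguity codes are rejected because the model
defines only the two canonical pairs. Heteropolymer chains get site-
dependent coupled frequencies through the per-site $\lambda_n$, but one
effective Morse set describes both pair species, matching the parameter
registry. What the generator does *not* emulate: sequence-dependent
stacking or geometry (roll, slide, propeller twist), solvent damping, and
thermal (Boltzmann) initial ensembles. Passing dynamics tests therefore
demonstrate the internal consistency of the linear model, not agreement
with thermalized molecular dynamics.

## Band structure conventions

* The bandgap $E_g(0,q)$ is the separation of the two quadratic roots at
  $\kappa = 0$, which is what the closed form
  `bandgap_closed_form()` evaluates and what the reference table reports.
  It is **not** the minimum same-$\kappa$ separation (that occurs at
  $\kappa h_0 = \pi$, where the two bands approach to ~26 meV for
  polyG–polyC); the full band edges are exposed so either convention can
  be recovered.
* The upper/lower labelling of band *widths* is convention-dependent
  (writing the Schrödinger equation with $+t$ or $-t$ off-diagonals
  mirrors the $\kappa$ axis), so `carrier_bands()` reports the widths as
  an ordered set alongside the explicit band edges.
* Degenerate band edges ($|\mathrm{tr}\,M|/2 = 1$) are handled by the
  Chebyshev three-term recurrence, which passes smoothly through
  $U_m(\pm 1) = (\pm 1)^m(m+1)$ and continues into the hyperbolic
  (evanescent) regime without special-casing.
* For $\gamma \ne \gamma_{\text{pole}}$ scans, the semimetallic window for
  polyG–polyC opens already at $\gamma \approx 0.36$ eV; the second
  closure point (~66.5 eV) lies far outside the physically tabulated
  range.

## Known limitations

* No thermal sampling, damping, or denaturation dynamics: the simulator
  is linear and conservative.
* No transport observables (transmission, I–V, Landauer conductance) —
  the deliverable is the band structure and its phonon modulation.
* The LCAO evaluation of $t_0$ from orbital coefficients is out of scope;
  $t_0$ is a registry parameter.
* Backbone disorder is structurally supported (per-site $\gamma$) but no
  disorder model is provided.

```{r quick-look}
p <- dna_params("GC"); fr <- helix_frame(p)
cf <- characteristic_frequencies(p, fr)
unlist(phonon_gaps(cf, fr, p))
carrier_bands(q = 0, params = p, gamma = 0)$W_set
```
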