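# helixCT

Helicoidal lattice dynamics and charge transfer in double-stranded B-DNA.

## The problem

Charge migration through the base-pair stack of duplex DNA is controlled by
the π–π orbital overlap between consecutive Watson–Crick pairs, and that
overlap depends on the instantaneous twist angle and radial separation of
the pairs. `helixCT` implements, in one consistent framework:

1. **Lattice dynamics.** Each base pair carries a twist coordinate φₙ and a
   radial coordinate ρₙ on a helicoidal lattice (radius R₀ = 1 nm, rise
   h₀ = 0.34 nm, equilibrium twist θ₀ = π/5.2). The potential is of
   Peyrard–Dauxois–Bishop type — Morse hydrogen-bond stretching,
   exponentially softened stacking, and a harmonic helicoidal backbone —
   and the linearized equations of motion couple twist and radial motion
   through the helix geometry. Their plane-wave ("helical wave") solutions
   give an acoustic branch

   ω₋²(q) and an optical branch ω₊²(q):

   ω±² = ½(G+H) ± ½√[(H−G)² + 16 C_λ ω_φ⁴ sin²(qξ)],

   with G = 4ω_φ² sin²(qξ/2), H = ω_φρ² − ω_φS² cos(qξ), and ξ = √(c²+R₀²)
   the helix-arc constant.

2. **Charge transfer.** Decimating the sugar–phosphate backbone maps the
   duplex onto a 1D tight-binding chain with energy-dependent on-site terms
   ε̃(E) = t(ρ,θ) + ϵ_XY(E) and twist/radial-dependent hoppings
   t(ρ,θ) = t₀[1 − (η̄/l₀²)·chord²(ρ,θ)]. A synchronized helical phonon of
   wavevector q makes the hopping site-independent,
   t(q) = t₀[1 − 4χA₀² sin²(qξ/2)] with χ = η̄(R₀/l₀)², and the carrier
   spectrum follows from the quadratic band equation

   B₂E² + [B₁ + F(κ,q)]E + 2B₀ − γF(κ,q) = 0,  F(κ,q) = t(q)[1 + 2cos(κh₀)],

   solved exactly (and cross-checked by the transfer-matrix formalism with
   Chebyshev matrix powers). The phonon softens the hopping and shrinks the
   bandgap — lattice waves *enhance* charge transfer.

The package is aimed at computational biophysicists studying DNA charge
transport, molecular-wire design, and phonon–electron coupling in helical
stacks.

## Worked example

```r
library(helixCT)
p  <- dna_params("GC")                      # polyG-polyC registry
fr <- helix_frame(p)
fr
#> Helicoidal frame (B-form equilibrium)
#>   c = 0.56277 nm   xi = 1.14748 nm   l0 = 0.68530 nm
#>   f0 = 0.75941 nm^2   g0 = 0.17702 nm
#>   lB = 8.5801 nm   aB = 0.30692 nm   bB = 0.26748
#>   q* = pi/xi = 2.7378 nm^-1

frequency_table("GC")
#>   species      oscillation omega_1e12    nu_thz    tau_ps
#> 1      GC            Twist   1.049550 0.1670411 5.9865514
#> 2      GC         Stacking   3.214822 0.5116547 1.9544429
#> 3      GC        H-Bonding   5.261487 0.8373916 1.1941844
#> 4      GC   Twist-Stacking   6.429361 1.0232647 0.9772643
#> 5      GC     Twist-Radial  12.361348 1.9673696 0.5082929
#> 6      GC Stretch-Stacking  13.933399 2.2175693 0.4509442

cf <- characteristic_frequencies(p, fr)
phonon_gaps(cf, fr, p)        # 1.68 THz at q = 0, 1.88 THz at q*
sound_velocity(cf, fr, p)$v_sound   # 1.20 km/s

carrier_bands(q = 0, params = p, gamma = 0)
#> Band structure: GC homopolymer, gamma = 0 eV, q = 0 nm^-1
#>   widths {29.7, 24.4} meV, Eg(kappa=0) = 80.3 meV
bandgap_closed_form(p, gamma = 0, q = fr$qstar)$Eg_meV
#> 72.7
```

Reading of the numbers: the slowest lattice mode is the collective twist
(~0.17 THz, ~6 ps period); the stretch–stacking mode at ~2.2 THz sets the
fastest time scale. The two carrier bands are ~25–30 meV wide and separated
by 80.3 meV at rest; driving the lattice with a zone-boundary helical
phonon (q* = π/ξ) lowers the gap to 72.7 meV, a ~9.5% reduction for
polyG–polyC (~6.9% for polyA–polyT).

Dynamics example — a helical wave stays on its branch:

```r
q  <- 2 * pi * 3 / (24 * fr$xi)   # commensurate mode on a 24-site ring
st <- init_helical_wave(q, "optical", 24, p, fr)
tr <- integrate_chain(st, dt = 1e-15, steps = 5000, params = p, frame = fr)
dominant_frequencies(tr, q, fr)$nu_phi   # matches omega_+(q) / 2 pi
```

## Command line

A thin wrapper is installed at `inst/cli/helixct`:

```sh
Rscript inst/cli/helixct phonons --species GC --out phonons.csv
Rscript inst/cli/helixct bands --gamma 0 --q 0 --out bands.csv
Rscript inst/cli/helixct reproduce
```

Subcommands: `params`, `geometry`, `phonons`, `simulate`, `hopping`,
`bands`, `gamma-scan`, `reproduce`. All CSV outputs carry `#`-prefixed
metadata headers; JSON mirrors are available for machine use.

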