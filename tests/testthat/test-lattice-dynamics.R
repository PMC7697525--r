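test_that("rigid twist offsets and the zero state never accelerate", {
  n <- 12
  st <- chain_state(rep(0.3, n), numeric(n), species = "GC")
  acc <- linear_rhs(st, params = gc_params, frame = gc_frame)
  expect_equal(max(abs(acc$phi_ddot)), 0)
  expect_equal(max(abs(acc$rho_ddot)), 0)
  tr <- integrate_chain(chain_state(numeric(n), numeric(n)), 1e-15, 50,
                        params = gc_params, frame = gc_frame)
  expect_equal(max(abs(tr$phi)), 0)
  expect_equal(max(abs(tr$rho)), 0)
  expect_error(linear_rhs(chain_state(0, 0), params = gc_params), "3 sites")
})

test_that("helical-wave states are eigenmodes of the linearized dynamics", {
  n <- 24
  for (k in c(2, 5, 9)) {
    q <- ring_q(k, n, gc_frame)
    for (br in c("acoustic", "optical")) {
      st <- init_helical_wave(q, br, n, gc_params, gc_frame)
      om <- attr(st, "omega")
      acc <- linear_rhs(st, params = gc_params, frame = gc_frame)
      # phi_ddot = -omega^2 phi for an eigenmode
      expect_lt(max(abs(acc$phi_ddot + om^2 * st$phi)) /
                  max(abs(om^2 * st$phi) + 1e-300), 1e-8)
      expect_lt(max(abs(acc$rho_ddot + om^2 * st$rho)) /
                  (max(abs(om^2 * st$rho)) + max(abs(om^2 * st$phi))), 1e-8)
    }
  }
  expect_error(init_helical_wave(0.1234, "acoustic", 24, gc_params, gc_frame),
               "commensurate")
})

test_that("degenerate wavevectors give pure twist or pure radial modes", {
  n <- 12
  st0 <- init_helical_wave(0, "acoustic", n, gc_params, gc_frame)
  expect_equal(max(abs(st0$rho)), 0)
  expect_equal(stats::sd(st0$phi), 0)   # uniform twist
  stq <- init_helical_wave(ring_q(n / 2, n, gc_frame), "optical", n,
                           gc_params, gc_frame)
  expect_equal(max(abs(stq$phi)), 0)    # pure radial at the zone boundary
  # amplitude ratio at generic q follows the secular-matrix first row
  k <- 3; q <- ring_q(k, n, gc_frame)
  st <- init_helical_wave(q, "acoustic", n, gc_params, gc_frame)
  om <- attr(st, "omega")
  kc <- helixCT:::.wave_constants(gc_params, gc_frame)
  G <- 4 * gc_cf$omega_phi^2 * sin(q * gc_frame$xi / 2)^2
  sigma <- (om^2 - G) / (2 * kc$A * gc_cf$omega_phi^2 * sin(q * gc_frame$xi))
  expect_equal(max(abs(st$rho)) / max(abs(st$phi)), abs(sigma),
               tolerance = 1e-8)
})

test_that("a single-mode excitation stays single mode with constant amplitude", {
  n <- 24; k <- 3
  q <- ring_q(k, n, gc_frame)
  st <- init_helical_wave(q, "optical", n, gc_params, gc_frame)
  om <- attr(st, "omega")
  steps <- ceiling(10 * (2 * pi / om) / 1e-15)
  tr <- integrate_chain(st, 1e-15, steps, record_every = 10,
                        params = gc_params, frame = gc_frame)
  pr <- mode_projection(tr, q, gc_frame)
  amp <- abs(pr[, "phi"])
  expect_lt(abs(amp[length(amp)] / amp[1] - 1), 1e-3)   # < 0.1% drift
  leak <- max(vapply(setdiff(1:(n / 2), k), function(j) {
    max(abs(mode_projection(tr, ring_q(j, n, gc_frame), gc_frame)[, "phi"]))
  }, numeric(1)))
  expect_lt(leak / amp[1], 1e-3)
  # measured oscillation frequency matches the branch
  dom <- dominant_frequencies(tr, q, gc_frame)
  expect_equal(dom$nu_phi, angular_frequency_to_thz(om),
               tolerance = max(0.02, 2 * dom$resolution_thz /
                                 angular_frequency_to_thz(om)))
})

test_that("spectra of random excitations recover both dispersion branches", {
  n <- 24
  set.seed(7)
  st <- chain_state(stats::rnorm(n, 0, 0.02), stats::rnorm(n, 0, 0.005),
                    species = "GC")
  tr <- integrate_chain(st, 4e-15, 8192, record_every = 4,
                        params = gc_params, frame = gc_frame)
  for (k in c(3, 6)) {
    q <- ring_q(k, n, gc_frame)
    dom <- dominant_frequencies(tr, q, gc_frame)
    de <- dispersion_exact(q, gc_cf, gc_frame, gc_params)
    expect_lt(abs(dom$nu_phi - de$nu_minus), 2 * dom$resolution_thz)
    expect_lt(abs(dom$nu_rho - de$nu_plus), 2 * dom$resolution_thz)
  }
})

test_that("codon collective variables obey the renormalized equations", {
  n <- 18; k <- 2
  st <- init_helical_wave(ring_q(k, n, gc_frame), "optical", n,
                          gc_params, gc_frame)
  tr <- integrate_chain(st, 1e-15, 3000, record_every = 1,
                        params = gc_params, frame = gc_frame)
  cc <- codon_collective(tr, gc_params, gc_frame)
  expect_lt(cc$max_rel_residual, 1e-4)
  # nested triplets satisfy the same equations again
  cc2 <- codon_collective(tr, gc_params, gc_frame, levels = 2)
  expect_lt(cc2$max_rel_residual, 1e-4)
  # mixed-mode (generic) trajectories too
  set.seed(11)
  st2 <- chain_state(stats::rnorm(n, 0, 0.03), stats::rnorm(n, 0, 0.008),
                     species = "GC")
  tr2 <- integrate_chain(st2, 1e-15, 3000, record_every = 1,
                         params = gc_params, frame = gc_frame)
  expect_lt(codon_collective(tr2, gc_params, gc_frame)$max_rel_residual, 1e-4)
  # zero trajectory: identically zero collective fields
  tr0 <- integrate_chain(chain_state(numeric(n), numeric(n)), 1e-15, 10,
                         params = gc_params, frame = gc_frame)
  cc0 <- codon_collective(tr0, gc_params, gc_frame)
  expect_equal(max(abs(cc0$x)), 0)
  expect_equal(max(abs(cc0$y)), 0)
})

test_that("integration is time reversible and rejects unstable steps", {
  n <- 15
  set.seed(5)
  st <- chain_state(stats::rnorm(n, 0, 0.05), stats::rnorm(n, 0, 0.01),
                    species = "GC")
  fwd <- integrate_chain(st, 1e-15, 2000, params = gc_params, frame = gc_frame)
  bwd <- integrate_chain(fwd$final, -1e-15, 2000, params = gc_params,
                         frame = gc_frame)
  expect_equal(bwd$final$phi, st$phi, tolerance = 1e-10)
  expect_equal(bwd$final$rho, st$rho, tolerance = 1e-10)
  expect_error(integrate_chain(st, 1e-12, 10, params = gc_params,
                               frame = gc_frame), "dt")
})

test_that("heteropolymer chains use site-dependent coupled frequencies", {
  seqs <- c("GC", "AT", "AT", "GC", "GC", "AT", "GC", "AT", "AT", "GC")
  st <- chain_state(numeric(10), c(0.01, numeric(9)), species = seqs)
  acc <- linear_rhs(st, params = gc_params, frame = gc_frame)
  # the on-site radial restoring force at site 1 carries the GC mu
  co <- helixCT:::dynamics_coefficients(seqs, gc_params, gc_frame)
  expect_equal(acc$rho_ddot[1], -co$w2_phirho[1] * 0.01, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(co$w2_phirho[1], co$w2_phirho[2])))
  # homopolymer limit reduces to the two-constant form
  co_h <- helixCT:::dynamics_coefficients(rep("GC", 6), gc_params, gc_frame)
  lam <- gc_params$pair$lambda
  expect_equal(co_h$w2_phiS_left,
               rep(gc_cf$omega_phiS^2, 6), tolerance = 1e-10)
})

test_that("sequence generation is deterministic and maps FASTA correctly", {
  expect_equal(make_sequence("homopolymer", length = 12),
               rep("GC", 12))
  s1 <- make_sequence("random", length = 100, seed = 1)
  s2 <- make_sequence("random", length = 100, seed = 1)
  expect_identical(s1, s2)
  big <- make_sequence("random", length = 1e4, seed = 1)
  expect_equal(mean(big == "GC"), 0.5, tolerance = 0.04)
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">toy", "acgGTA"), fa)
  expect_equal(make_sequence("fasta", fasta = fa),
               c("AT", "GC", "GC", "GC", "AT", "AT"))
  writeLines(c(">bad", "ACGN"), fa)
  expect_error(make_sequence("fasta", fasta = fa), "outside")
})
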