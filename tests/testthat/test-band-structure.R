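test_that("coupling function has the tight-binding limits", {
  m <- transfer_model(gc_params, gc_frame)
  h0 <- gc_frame$h0
  expect_equal(coupling_function(0, 0, m), 3 * m$t0)
  expect_equal(coupling_function(pi / h0, 0, m),
               -transfer_integral_phonon(0, m), tolerance = 1e-12)
  expect_equal(coupling_function(2 * pi / (3 * h0), 0, m), 0,
               tolerance = 1e-12)
})

test_that("band widths and gaps reproduce the published table within 1%", {
  ref <- list(GC = c(W1 = 29.7, W2 = 24.4, Eg0 = 80.3, Egstar = 73.0),
              AT = c(W1 = 22.0, W2 = 16.6, Eg0 = 93.5, Egstar = 87.4))
  for (s in c("GC", "AT")) {
    p <- dna_params(s)
    fr <- helix_frame(p)
    bs <- carrier_bands(q = 0, params = p, gamma = 0)
    expect_equal(bs$W_set[1], ref[[s]][["W1"]], tolerance = 0.01)
    expect_equal(bs$W_set[2], ref[[s]][["W2"]], tolerance = 0.01)
    expect_equal(bs$Eg_meV, ref[[s]][["Eg0"]], tolerance = 0.01)
    expect_equal(bandgap_closed_form(p, gamma = 0, q = fr$qstar)$Eg_meV,
                 ref[[s]][["Egstar"]], tolerance = 0.01)
    # the two bands do not overlap
    expect_gt(min(bs$bands$E_upper), max(bs$bands$E_lower))
  }
})

test_that("quadratic roots obey the Vieta identity at gamma = 0", {
  e <- gc_params$electronic
  for (kap in c(0, 2, 5, pi / gc_frame$h0)) {
    bs <- carrier_bands(kap, q = 0, params = gc_params, gamma = 0)
    i <- which.min(abs(bs$bands$kappa - kap))
    prod_roots <- bs$bands$E_upper[i] * bs$bands$E_lower[i]
    expect_equal(prod_roots, 2 * e$tP^2 / (2 * e$b_xy - 1),
                 tolerance = 1e-12)  # independent of kappa
  }
})

test_that("closed-form gap equals the quadratic-root separation everywhere", {
  set.seed(4)
  # sample the semiconducting window (the gap closes for gamma beyond
  # ~0.36 eV at these parameters) plus gamma = 0 exactly
  for (i in 1:20) {
    gam <- if (i == 1) 0 else stats::runif(1, 0, 0.3)
    q <- stats::runif(1, 0, gc_frame$qstar)
    cf_gap <- bandgap_closed_form(gc_params, gamma = gam, q = q)
    expect_false(cf_gap$semimetal)
    bs <- carrier_bands(q = q, params = gc_params, gamma = gam)
    expect_equal(bs$Eg_meV, cf_gap$Eg_meV, tolerance = 1e-10)
  }
})

test_that("phonon coupling reduces the gap monotonically up to q*", {
  qs <- seq(0, gc_frame$qstar, length.out = 40)
  for (s in c("GC", "AT")) {
    p <- dna_params(s)
    eg <- bandgap_closed_form(p, gamma = 0, q = qs)$Eg_meV
    expect_true(all(diff(eg) < 0))
  }
  # relative reduction ~9% (GC) and ~6.5% (AT) within one percentage point
  red <- vapply(c("GC", "AT"), function(s) {
    p <- dna_params(s)
    fr <- helix_frame(p)
    e0 <- bandgap_closed_form(p, gamma = 0, q = 0)$Eg_meV
    es <- bandgap_closed_form(p, gamma = 0, q = fr$qstar)$Eg_meV
    100 * (e0 - es) / e0
  }, numeric(1))
  expect_lt(abs(red[["GC"]] - 9), 1)
  expect_lt(abs(red[["AT"]] - 6.5), 1)
})

test_that("AT bands sit above GC bands", {
  bs_gc <- carrier_bands(q = 0, params = gc_params, gamma = 0)
  bs_at <- carrier_bands(q = 0, params = at_params, gamma = 0)
  centre <- function(b) mean(unlist(b$edges))
  expect_gt(centre(bs_at), centre(bs_gc))
})

test_that("transfer matrix is unimodular with the band-edge trace condition", {
  set.seed(8)
  for (E in stats::runif(5, -1, -0.05)) {
    M <- transfer_matrix(E, 0, gc_params, gamma = 0)
    expect_equal(det(M), 1, tolerance = 1e-12)
  }
  bs <- carrier_bands(q = 0, params = gc_params, gamma = 0)
  # half-trace lies in [-1, 1] on the bands, +-1 exactly at the edges
  for (E in c(bs$bands$E_upper[c(10, 50, 90)], bs$bands$E_lower[c(10, 50, 90)])) {
    M <- transfer_matrix(E, 0, gc_params, gamma = 0)
    expect_lte(abs((M[1, 1] + M[2, 2]) / 2), 1 + 1e-10)
  }
  for (E in unname(bs$edges)) {
    M <- transfer_matrix(E, 0, gc_params, gamma = 0)
    expect_equal(abs((M[1, 1] + M[2, 2]) / 2), 1, tolerance = 1e-9)
  }
  # inside the gap the trace is hyperbolic and M^N grows with N
  Egap <- mean(c(max(bs$bands$E_lower), min(bs$bands$E_upper)))
  Mg <- transfer_matrix(Egap, 0, gc_params, gamma = 0)
  tr8 <- abs(sum(diag(chebyshev_power(Mg, 8)))) / 2
  tr16 <- abs(sum(diag(chebyshev_power(Mg, 16)))) / 2
  expect_gt(tr8, 1)
  expect_gt(tr16, tr8)
})

test_that("Chebyshev matrix powers equal brute-force products", {
  set.seed(6)
  for (i in 1:10) {
    # random unimodular matrix (both elliptic and hyperbolic traces)
    a <- stats::runif(1, -2, 2); b <- stats::runif(1, -1.5, 1.5)
    cc <- stats::runif(1, -1.5, 1.5)
    d <- (1 + b * cc) / a
    M <- matrix(c(a, cc, b, d), 2, 2)
    BF <- diag(2)
    for (k in 1:8) BF <- BF %*% M
    expect_equal(chebyshev_power(M, 8), BF, tolerance = 1e-10)
  }
  M1 <- transfer_matrix(-0.3, 0, gc_params, gamma = 0)
  expect_equal(chebyshev_power(M1, 1), M1)
  # degenerate x = 1: U_m = m + 1, no division by zero
  Mdeg <- matrix(c(1, 0, 1, 1), 2, 2)  # trace 2
  expect_equal(chebyshev_power(Mdeg, 7),
               matrix(c(1, 0, 7, 1), 2, 2))
})

test_that("finite-chain dispersion is consistent with the band equation", {
  fr <- gc_frame
  bs <- carrier_bands(q = 0, params = gc_params, gamma = 0)
  # band edges invert to kappa = 0 and kappa h0 = pi (labels may swap
  # between the two conventions of writing the Schroedinger equation)
  for (band in c("upper", "lower")) {
    eks <- c(bs$edges[[paste0(band, "_k0")]], bs$edges[[paste0(band, "_kpi")]])
    fc <- finite_chain_dispersion(eks, q = 0, n_sites = 8,
                                  params = gc_params, gamma = 0)
    expect_true(all(fc$allowed))
    kh <- sort(fc$kappa * fr$h0)
    expect_equal(kh, c(0, pi), tolerance = 1e-4)
  }
  # allowed set on a fine grid equals the two bands
  Es <- seq(min(bs$bands$E_lower) - 0.02, max(bs$bands$E_upper) + 0.02,
            length.out = 400)
  fc <- finite_chain_dispersion(Es, q = 0, n_sites = 8, params = gc_params,
                                gamma = 0)
  in_band <- (Es >= min(bs$bands$E_lower) - 1e-9 &
                Es <= max(bs$bands$E_lower) + 1e-9) |
             (Es >= min(bs$bands$E_upper) - 1e-9 &
                Es <= max(bs$bands$E_upper) + 1e-9)
  expect_equal(fc$allowed, in_band)
  # ring condition cos(kappa N h0) = tr M^N / 2 on the allowed set
  ok <- fc$allowed
  expect_lt(max(abs(cos(fc$kappa[ok] * 8 * fr$h0) - fc$trMN_half[ok])), 1e-8)
})

test_that("gamma scan finds the semiconductor-semimetal transition", {
  sc <- gamma_scan(seq(0, 12, by = 0.02), q = 0, params = gc_params)
  expect_equal(sc$scan$Eg_meV[1], 80.3, tolerance = 0.01)
  # closure points solve (3 t0 + 2 a - gamma)^2 = 8 (2b - 1) tP^2
  e <- gc_params$electronic
  for (g in sc$closure_gamma) {
    expect_equal((3 * e$t0 + 2 * e$a_xy - g)^2,
                 8 * (2 * e$b_xy - 1) * e$tP^2, tolerance = 1e-10)
  }
  # scan agrees: semimetallic exactly between the closure points
  inside <- sc$scan$gamma > sc$closure_gamma[1] + 0.02 &
    sc$scan$gamma < sc$closure_gamma[2] - 0.02
  expect_true(all(sc$scan$semimetal[inside]))
  expect_true(all(!sc$scan$semimetal[!inside &
    (sc$scan$gamma < sc$closure_gamma[1] - 0.02 |
       sc$scan$gamma > sc$closure_gamma[2] + 0.02)]))
  # gap is exactly zero throughout the semimetallic window
  expect_true(all(sc$scan$Eg_meV[sc$scan$semimetal] == 0))
  # and continuous away from the square-root closure point
  smooth <- sc$scan$gamma < sc$closure_gamma[1] - 0.3
  expect_lt(max(abs(diff(sc$scan$Eg_meV[smooth]))), 4)
})
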