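test_that("homogeneous no-uptake column reduces to the cosine eigenvalues", {
  eig <- find_inner_eigenvalues(homog_params, ref_system, M = 5)
  expect_equal(eig$modes$lam,
               (seq_len(5) - 0.5) * pi / ref_system$H, tolerance = 1e-10)
})

test_that("eigenvalue count below k matches a dense residual scan", {
  eig <- find_inner_eigenvalues(ref_params, ref_system, M = 10)
  grid <- seq(ref_params$k * 1e-6, ref_params$k * (1 - 1e-9),
              length.out = 1e5)
  fg <- dispersion_residual(grid, ref_params, ref_system)
  scan_count <- sum(diff(sign(fg)) != 0)
  expect_identical(eig$trapped_count, scan_count)
  expect_gte(eig$trapped_count, 1L)
})

test_that("pole-free residual roots coincide with the printed dispersion relations", {
  eig <- find_inner_eigenvalues(ref_params, ref_system, M = 8)
  # at each root, the printed transcendental form (cleared of its cosine
  # denominators) must also vanish: evaluate printed form where finite
  printed <- pclsoxy:::dispersion_printed(eig$modes$lam, ref_params,
                                          ref_system)
  # printed form has tan() factors; normalise by its local scale just off
  # the root to get a relative residual
  off <- pclsoxy:::dispersion_printed(eig$modes$lam * (1 + 1e-4),
                                      ref_params, ref_system)
  expect_true(all(abs(printed) < 1e-3 * pmax(abs(off - printed), 1)))
  # degenerate placement h1 = 0: scan of the residual still finds the roots
  cfgb <- default_parameters(5, "bottom")
  eigb <- find_inner_eigenvalues(cfgb$params, cfgb$system, M = 6)
  expect_true(all(abs(dispersion_residual(eigb$modes$lam, cfgb$params,
                                          cfgb$system)) < 1e-10))
})

test_that("returned eigenvalues are refined roots, ordered and well separated", {
  for (M in c(7, 25)) {
    eig <- find_inner_eigenvalues(ref_params, ref_system, M = M)
    res <- dispersion_residual(eig$modes$lam, ref_params, ref_system)
    # local residual scale from a nearby off-root point
    scale <- abs(dispersion_residual(eig$modes$lam * (1 + 1e-3),
                                     ref_params, ref_system) - res)
    expect_true(all(abs(res) < 1e-10 * pmax(scale, 1e-3)))
    expect_true(all(diff(eig$modes$lam) > 0.1 * pi / ref_system$H))
  }
})

test_that("branch argument enforces consistency with k", {
  expect_error(dispersion_residual(ref_params$k * 1.5, ref_params,
                                   ref_system, branch = "trapped"),
               "trapped")
  expect_error(dispersion_residual(ref_params$k * 0.5, ref_params,
                                   ref_system, branch = "free"),
               "free")
  expect_error(dispersion_residual(-1, ref_params, ref_system), "positive")
})

test_that("eigenfunctions satisfy boundary, continuity and weighted-flux conditions", {
  eig <- find_inner_eigenvalues(ref_params, ref_system, M = 8)
  s <- ref_system; p <- ref_params
  eps <- 1e-12
  for (n in seq_len(8)) {
    expect_equal(inner_eigenfunction(eig, n, 0), 1)
    expect_lt(abs(inner_eigenfunction(eig, n, s$H)), 1e-8)
    # derivative at the bottom vanishes
    expect_lt(abs(inner_eigenfunction(eig, n, 0, deriv = 1)), 1e-8)
    # value continuity at both interfaces (the straddle contributes
    # slope x 2eps, so tolerances are slack relative to a genuine jump)
    expect_equal(inner_eigenfunction(eig, n, s$h1 - eps),
                 inner_eigenfunction(eig, n, s$h1 + eps), tolerance = 1e-6)
    expect_equal(inner_eigenfunction(eig, n, s$h2 - eps),
                 inner_eigenfunction(eig, n, s$h2 + eps), tolerance = 1e-6)
    # D-weighted flux continuity (one-sided analytic derivatives)
    expect_equal(p$D1 * inner_eigenfunction(eig, n, s$h1, deriv = 1),
                 p$D2 * inner_eigenfunction(eig, n, s$h1 + eps, deriv = 1),
                 tolerance = 1e-6)
    expect_equal(p$D2 * inner_eigenfunction(eig, n, s$h2, deriv = 1),
                 p$D1 * inner_eigenfunction(eig, n, s$h2 + eps, deriv = 1),
                 tolerance = 1e-6)
  }
  expect_error(inner_eigenfunction(eig, 1, -1e-4), "z outside")
})

test_that("propagated eigenfunctions equal the closed-form piecewise expressions", {
  eig <- find_inner_eigenvalues(ref_params, ref_system, M = 8)
  z <- seq(0, ref_system$H, length.out = 57)
  for (n in seq_len(8)) {
    expect_equal(inner_eigenfunction(eig, n, z),
                 pclsoxy:::inner_eigenfunction_printed(eig, n, z),
                 tolerance = 1e-10)
  }
})

test_that("modes are orthogonal under the piecewise diffusivity weight", {
  eig <- find_inner_eigenvalues(ref_params, ref_system, M = 7)
  gram <- inner_mode_grams(eig)
  GD <- ref_params$D1 * (gram$plain - gram$tissue) +
    ref_params$D2 * gram$tissue
  offdiag <- GD - diag(diag(GD))
  expect_lt(max(abs(offdiag)), 1e-8 * min(abs(diag(GD))))
})
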