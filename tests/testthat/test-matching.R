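test_that("closed-form overlap integrals agree with breakpoint quadrature", {
  eig <- find_inner_eigenvalues(ref_params, ref_system, M = 6)
  om <- outer_eigenvalues(6, ref_system$H)
  C1 <- overlap_integrals(eig, om, method = "closed")
  C2 <- overlap_integrals(eig, om, method = "quadrature")
  expect_equal(C1, C2, tolerance = 1e-10)
  # slice resting on the bottom: first piece is empty
  cfgb <- default_parameters(5, "bottom")
  eigb <- find_inner_eigenvalues(cfgb$params, cfgb$system, M = 5)
  omb <- outer_eigenvalues(5, cfgb$system$H)
  expect_equal(overlap_integrals(eigb, omb, "closed"),
               overlap_integrals(eigb, omb, "quadrature"),
               tolerance = 1e-10)
})

test_that("homogeneous no-uptake column gives cosine orthogonality", {
  eig <- find_inner_eigenvalues(homog_params, ref_system, M = 5)
  om <- outer_eigenvalues(5, ref_system$H)
  C <- overlap_integrals(eig, om)
  expect_equal(C, diag(ref_system$H / 2, 5), tolerance = 1e-10)
})

test_that("projection load vanishes without uptake and is linear in phi0", {
  eig0 <- find_inner_eigenvalues(homog_params, ref_system, M = 5)
  bp0 <- baseline_profile(homog_params, ref_system, ref_phi0)
  expect_equal(projection_load(eig0, bp0), rep(0, 5), tolerance = 1e-12)
  eig <- find_inner_eigenvalues(ref_params, ref_system, M = 6)
  bp1 <- baseline_profile(ref_params, ref_system, ref_phi0)
  bp2 <- baseline_profile(ref_params, ref_system, 2 * ref_phi0)
  g1 <- projection_load(eig, bp1)
  expect_equal(projection_load(eig, bp2), 2 * g1, tolerance = 1e-12)
  expect_equal(g1, projection_load(eig, bp1, method = "quadrature"),
               tolerance = 1e-10)
})

test_that("inner Gram matrices agree between closed form and quadrature", {
  eig <- find_inner_eigenvalues(ref_params, ref_system, M = 5)
  gc <- inner_mode_grams(eig, "closed")
  gq <- inner_mode_grams(eig, "quadrature")
  expect_equal(gc$plain, gq$plain, tolerance = 1e-10)
  expect_equal(gc$tissue, gq$tissue, tolerance = 1e-10)
})

test_that("assembled entries match naive literal-basis evaluation", {
  eig <- find_inner_eigenvalues(ref_params, ref_system, M = 7)
  bp <- baseline_profile(ref_params, ref_system, ref_phi0)
  ms <- assemble_system(eig, bp, M = 7)
  s <- ref_system; p <- ref_params
  om <- ms$omegas; lam <- eig$modes$lam
  # naive unscaled Bessel factors (moderate arguments at M = 7)
  Q_rT <- -besselK(om * s$r_o, 1) * besselI(om * s$r_T, 0) -
    besselI(om * s$r_o, 1) * besselK(om * s$r_T, 0)
  dQ_rT <- om * (-besselK(om * s$r_o, 1) * besselI(om * s$r_T, 1) +
                   besselI(om * s$r_o, 1) * besselK(om * s$r_T, 1))
  expect_equal(ms$q_n, dQ_rT / Q_rT, tolerance = 1e-9)
  expect_equal(ms$w_m,
               lam * besselI(lam * s$r_T, 1) / besselI(lam * s$r_T, 0),
               tolerance = 1e-9)
  expect_equal(ms$Q_rT, Q_rT, tolerance = 1e-9)
  expect_equal(ms$I0_rT, besselI(lam * s$r_T, 0), tolerance = 1e-9)
  # structure: S column-scaled overlap, W row-scaled weighted Gram
  expect_equal(ms$S, p$D1 * sweep(ms$C, 2, ms$q_n, `*`), tolerance = 1e-12)
  expect_equal(ms$W, sweep(ms$GD, 1, ms$w_m, `*`), tolerance = 1e-12)
  expect_true(all(is.finite(ms$R)) && all(is.finite(ms$g)))
})

test_that("both elimination routes give the same coefficients and tiny residuals", {
  eig <- find_inner_eigenvalues(ref_params, ref_system, M = 7)
  bp <- baseline_profile(ref_params, ref_system, ref_phi0)
  ms <- assemble_system(eig, bp, M = 7)
  sa <- solve_coefficients(ms, route = "alpha")
  sA <- solve_coefficients(ms, route = "A")
  expect_equal(sa$alpha_hat, sA$alpha_hat, tolerance = 1e-8)
  expect_equal(sa$A_hat, sA$A_hat, tolerance = 1e-8)
  expect_lt(max(sa$residuals), 1e-8)
})

test_that("no uptake yields the uniform field with zero coefficients", {
  sol <- solve_oxygen_field(homog_params, ref_system, ref_phi0, M = 5)
  expect_equal(sol$alpha_hat, rep(0, 5))
  r <- seq(0, ref_system$r_o * 0.999, length.out = 11)
  z <- seq(0, ref_system$H, length.out = 7)
  expect_equal(as.vector(field_grid(sol, r, z)),
               rep(ref_phi0, 77), tolerance = 1e-10)
})

test_that("solution scales linearly with the surface pressure", {
  sol1 <- get_solution(7)
  sol2 <- solve_oxygen_field(ref_params, ref_system, 2 * ref_phi0, M = 7)
  pts_r <- c(0, 1e-3, 2e-3, 5e-3)
  pts_z <- c(1e-4, 1.7e-3, 3e-3, 2e-3)
  expect_equal(concentration_at(sol2, pts_r, pts_z),
               2 * concentration_at(sol1, pts_r, pts_z), tolerance = 1e-10)
})

test_that("rim concentration mismatch shrinks monotonically with truncation", {
  zz <- seq(0, ref_system$H, length.out = 300)
  mism <- vapply(c(5, 7, 10, 20, 40), function(M) {
    so <- get_solution(M)
    inner <- concentration_at(so, ref_system$r_T, zz)
    outerv <- concentration_at(so, ref_system$r_T * (1 + 1e-12), zz)
    sqrt(mean((inner - outerv)^2))
  }, numeric(1))
  expect_true(all(diff(mism) < 0))
})

test_that("rim concentration jump at high truncation is below half a percent", {
  sol <- get_solution(40)
  zz <- seq(0, ref_system$H, length.out = 50)
  jump <- max(abs(concentration_at(sol, ref_system$r_T, zz) -
                    concentration_at(sol, ref_system$r_T * (1 + 1e-12), zz)))
  expect_lt(jump, 0.005 * ref_phi0)
})

test_that("flux continuity holds in the Galerkin sense with material weights", {
  # project the D-weighted radial-flux mismatch at the rim onto each inner
  # mode by quadrature: must vanish to solver tolerance
  sol <- get_solution(7)
  s <- ref_system; p <- ref_params
  d <- 1e-9
  dr_phi <- function(r, z) {
    (concentration_at(sol, rep(r + d, length(z)), z) -
       concentration_at(sol, rep(r - d, length(z)), z)) / (2 * d)
  }
  mismatch <- function(z) {
    w_in <- ifelse(z > s$h1 & z < s$h2, p$D2, p$D1)
    p$D1 * dr_phi(s$r_T * (1 + 1e-6), z) -
      w_in * dr_phi(s$r_T * (1 - 1e-6), z)
  }
  scale <- p$D1 * max(abs(dr_phi(s$r_T * (1 + 1e-6),
                                 seq(0, s$H, length.out = 50)))) * s$H
  for (m in c(1, 3, 6)) {
    pr <- stats::integrate(function(z) mismatch(z) *
                             inner_eigenfunction(sol$eig, m, z),
                           0, s$H, subdivisions = 500L, rel.tol = 1e-8,
                           stop.on.error = FALSE)$value
    # quadrature over the discontinuous weight and the finite-difference
    # radial derivative limit the achievable precision; a wrong material
    # weighting would leave a relative residual of order (D1-D2)/D1 ~ 0.7
    expect_lt(abs(pr), 1e-3 * scale)
  }
})
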