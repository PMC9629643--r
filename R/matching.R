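# Galerkin matching at the slice rim r = r_T. The inner and outer series
# are projected onto the inner vertical modes; overlap integrals
# C[m, n] = int_0^H Zm(z) cos(omega_n z) dz are computed either from
# closed-form piecewise antiderivatives (every piece factor is a short sum
# of c * exp(s z) terms with complex rate s, so each product integrates to
# an incomplete-exponential primitive) or by adaptive quadrature with
# breakpoints at the tissue interfaces.

# int_{z1}^{z2} exp(s z) dz, vectorised over complex s; series form near
# s (z2 - z1) = 0 to avoid cancellation.
eint0 <- function(s, z1, z2) {
  d <- z2 - z1
  x <- s * d
  out <- s  # placeholder complex vector
  big <- abs(x) >= 0.5
  out[big] <- exp(s[big] * z1) * (exp(x[big]) - 1) / s[big]
  if (any(!big)) {
    xs <- x[!big]
    h <- rep(1 + 0i, length(xs))  # sum x^n / (n+1)!
    term <- rep(1 + 0i, length(xs))
    for (n in 1:24) {
      term <- term * xs / (n + 1)
      h <- h + term
    }
    out[!big] <- exp(s[!big] * z1) * d * h
  }
  out
}

# int_{z1}^{z2} (z - a) exp(s z) dz, vectorised over complex s.
eint1 <- function(s, z1, z2, a) {
  d <- z2 - z1
  x <- s * d
  out <- s
  big <- abs(x) >= 0.5
  if (any(big)) {
    sb <- s[big]; xb <- x[big]
    out[big] <- exp(sb * z1) *
      (exp(xb) * ((z2 - a) * sb - 1) - ((z1 - a) * sb - 1)) / sb^2
  }
  if (any(!big)) {
    ss <- s[!big]
    acc <- rep(0 + 0i, length(ss))
    pw <- rep(1 + 0i, length(ss))  # s^n / n!
    for (n in 0:24) {
      if (n > 0) pw <- pw * ss / n
      acc <- acc + pw * (d^(n + 2) / (n + 2) + (z1 - a) * d^(n + 1) / (n + 1))
    }
    out[!big] <- exp(ss * z1) * acc
  }
  out
}

# Piecewise complex-exponential representation of inner mode n:
# list of pieces, each with limits and parallel vectors coef / rate so that
# Z(z) = Re(sum coef * exp(rate * z)) on the piece.
zm_piece_terms <- function(eig, n) {
  sys <- eig$system
  m <- eig$modes[n, ]
  lam <- m$lam
  s2 <- sqrt(as.complex(m$q))          # tau (trapped) or i*delta (free)
  pieces <- list()
  if (sys$h1 > 0) {
    pieces[[length(pieces) + 1]] <- list(
      z1 = 0, z2 = sys$h1,
      coef = c(0.5 + 0i, 0.5 + 0i),
      rate = c(1i * lam, -1i * lam))
  }
  pieces[[length(pieces) + 1]] <- list(
    z1 = sys$h1, z2 = sys$h2,
    coef = c((m$a + m$b / s2) / 2 * exp(-s2 * sys$h1),
             (m$a - m$b / s2) / 2 * exp(s2 * sys$h1)),
    rate = c(s2, -s2))
  pieces[[length(pieces) + 1]] <- list(
    z1 = sys$h2, z2 = sys$H,
    coef = c((m$v - 1i * m$e2 / lam) / 2 * exp(-1i * lam * sys$h2),
             (m$v + 1i * m$e2 / lam) / 2 * exp(1i * lam * sys$h2)),
    rate = c(1i * lam, -1i * lam))
  pieces
}

#' Overlap integrals between inner and outer vertical modes
#'
#' \eqn{C_{mn} = \int_0^H Z_m^{(2)}(z) \cos(\omega_n z)\,dz}, computed
#' piecewise over the three z-intervals. The default closed form integrates
#' each product of exponential terms analytically; the quadrature path uses
#' adaptive integration with breakpoints at the tissue interfaces and is
#' retained as an independent cross-check.
#'
#' @param eig an \code{\link{find_inner_eigenvalues}} result.
#' @param omegas outer-mode wavenumbers [1/m]
#'   (see \code{\link{outer_eigenvalues}}).
#' @param method \code{"closed"} or \code{"quadrature"}.
#' @return matrix [m] with rows = inner modes, columns = outer modes.
#' @export
overlap_integrals <- function(eig, omegas,
                              method = c("closed", "quadrature")) {
  method <- match.arg(method)
  M_in <- nrow(eig$modes)
  C <- matrix(0, M_in, length(omegas))
  if (method == "closed") {
    for (m in seq_len(M_in)) {
      pieces <- zm_piece_terms(eig, m)
      acc <- rep(0 + 0i, length(omegas))
      for (p in pieces) {
        for (i in seq_along(p$coef)) {
          acc <- acc + p$coef[i] * eint0(p$rate[i] + 1i * omegas, p$z1, p$z2)
        }
      }
      C[m, ] <- Re(acc)
    }
  } else {
    sys <- eig$system
    brk <- c(0, sys$h1, sys$h2, sys$H)
    brk <- brk[c(TRUE, diff(brk) > 0)]
    for (m in seq_len(M_in)) {
      for (n in seq_along(omegas)) {
        tot <- 0
        for (j in seq_len(length(brk) - 1)) {
          tot <- tot + stats::integrate(
            function(z) inner_eigenfunction(eig, m, z) * cos(omegas[n] * z),
            brk[j], brk[j + 1], rel.tol = 1e-12, abs.tol = 1e-14,
            subdivisions = 400L)$value
        }
        C[m, n] <- tot
      }
    }
  }
  C
}

#' Projection of the baseline deficit onto the inner modes
#'
#' \eqn{g_m = \int_0^H (\phi_0 - U_{II}(z)) Z_m^{(2)}(z)\,dz}: the load
#' vector of the matching system, measuring how far the radially uniform
#' baseline falls below the surface value in each inner mode.
#'
#' @param eig an \code{\link{find_inner_eigenvalues}} result.
#' @param bp a \code{\link{baseline_profile}} for the same geometry.
#' @param method \code{"closed"} or \code{"quadrature"}.
#' @return numeric vector [mmHg m], one entry per inner mode.
#' @export
projection_load <- function(eig, bp, method = c("closed", "quadrature")) {
  method <- match.arg(method)
  sys <- eig$system; par <- eig$params
  M_in <- nrow(eig$modes)
  if (method == "quadrature") {
    brk <- c(0, sys$h1, sys$h2, sys$H)
    brk <- brk[c(TRUE, diff(brk) > 0)]
    return(vapply(seq_len(M_in), function(m) {
      tot <- 0
      for (j in seq_len(length(brk) - 1)) {
        tot <- tot + stats::integrate(
          function(z) (bp$phi0 - eval_baseline(bp, z)) *
            inner_eigenfunction(eig, m, z),
          brk[j], brk[j + 1], rel.tol = 1e-12, abs.tol = 1e-14,
          subdivisions = 400L)$value
      }
      tot
    }, numeric(1)))
  }
  k <- par$k; t <- sys$h2 - sys$h1
  beta <- par$D1 * bp$phi0 / bp$theta
  gam <- -bp$phi0 * par$D2 * k * sinh(k * t) / bp$theta  # (z - H) slope term
  # baseline-deficit pieces as (coef, rate, deg) exponential terms
  base_pieces <- list(
    list(z1 = 0, z2 = sys$h1,
         coef = as.complex(bp$phi0 - beta), rate = 0 + 0i, deg = 0L),
    list(z1 = sys$h1, z2 = sys$h2,
         coef = c(as.complex(bp$phi0),
                  -beta / 2 * exp(-k * sys$h1 + 0i),
                  -beta / 2 * exp(k * sys$h1 + 0i)),
         rate = c(0 + 0i, k + 0i, -k + 0i), deg = c(0L, 0L, 0L)),
    list(z1 = sys$h2, z2 = sys$H,
         coef = as.complex(gam), rate = 0 + 0i, deg = 1L)
  )
  if (sys$h1 <= 0) base_pieces <- base_pieces[-1]
  vapply(seq_len(M_in), function(m) {
    zp <- zm_piece_terms(eig, m)
    tot <- 0 + 0i
    for (bpz in base_pieces) {
      # matching Z-piece shares the same limits
      zpiece <- Filter(function(p) p$z1 == bpz$z1 && p$z2 == bpz$z2, zp)[[1]]
      for (i in seq_along(bpz$coef)) {
        rates <- bpz$rate[i] + zpiece$rate
        prim <- if (bpz$deg[i] == 0L) eint0(rates, bpz$z1, bpz$z2)
                else eint1(rates, bpz$z1, bpz$z2, eig$system$H)
        tot <- tot + sum(bpz$coef[i] * zpiece$coef * prim)
      }
    }
    Re(tot)
  }, numeric(1))
}

#' Gram matrices of the inner vertical modes
#'
#' The inner modes are orthogonal only under the piecewise diffusivity
#' weight \eqn{D(z)} (their Sturm-Liouville weight), not under the plain
#' inner product, so the rim-matching projection needs both the plain Gram
#' matrix \eqn{\int_0^H Z_m Z_n\,dz} and the tissue-band part
#' \eqn{\int_{h_1}^{h_2} Z_m Z_n\,dz} from which the D-weighted Gram
#' \eqn{\int_0^H D(z) Z_m Z_n\,dz} (diagonal up to roundoff) is formed.
#'
#' @param eig an \code{\link{find_inner_eigenvalues}} result.
#' @param method \code{"closed"} or \code{"quadrature"}.
#' @return list with matrices \code{plain} (full-interval Gram) and
#'   \code{tissue} (tissue-band part), both symmetric.
#' @export
inner_mode_grams <- function(eig, method = c("closed", "quadrature")) {
  method <- match.arg(method)
  M <- nrow(eig$modes)
  Gp <- matrix(0, M, M); Gt <- matrix(0, M, M)
  sys <- eig$system
  if (method == "closed") {
    pieces <- lapply(seq_len(M), function(m) zm_piece_terms(eig, m))
    for (m in seq_len(M)) for (n in m:M) {
      tot <- 0 + 0i; mid <- 0 + 0i
      for (ip in seq_along(pieces[[m]])) {
        pm <- pieces[[m]][[ip]]; pn <- pieces[[n]][[ip]]
        acc <- 0 + 0i
        for (i in seq_along(pm$coef))
          acc <- acc + sum(pm$coef[i] * pn$coef *
                             eint0(pm$rate[i] + pn$rate, pm$z1, pm$z2))
        tot <- tot + acc
        if (pm$z1 == sys$h1 && pm$z2 == sys$h2) mid <- acc
      }
      Gp[m, n] <- Gp[n, m] <- Re(tot)
      Gt[m, n] <- Gt[n, m] <- Re(mid)
    }
  } else {
    brk <- c(0, sys$h1, sys$h2, sys$H)
    brk <- brk[c(TRUE, diff(brk) > 0)]
    for (m in seq_len(M)) for (n in m:M) {
      tot <- 0; mid <- 0
      for (j in seq_len(length(brk) - 1)) {
        val <- stats::integrate(
          function(z) inner_eigenfunction(eig, m, z) *
            inner_eigenfunction(eig, n, z),
          brk[j], brk[j + 1], rel.tol = 1e-12, abs.tol = 1e-14,
          subdivisions = 400L)$value
        tot <- tot + val
        if (brk[j] == sys$h1 && brk[j + 1] == sys$h2) mid <- val
      }
      Gp[m, n] <- Gp[n, m] <- tot
      Gt[m, n] <- Gt[n, m] <- mid
    }
  }
  list(plain = Gp, tissue = Gt)
}

# Tissue-band columns of the overlap matrix: int_{h1}^{h2} Zm cos(omega_n).
overlap_integrals_tissue <- function(eig, omegas) {
  M_in <- nrow(eig$modes)
  sys <- eig$system
  Cmid <- matrix(0, M_in, length(omegas))
  for (m in seq_len(M_in)) {
    pcs <- zm_piece_terms(eig, m)
    pc <- Filter(function(p) p$z1 == sys$h1 && p$z2 == sys$h2, pcs)[[1]]
    acc <- rep(0 + 0i, length(omegas))
    for (i in seq_along(pc$coef))
      acc <- acc + pc$coef[i] * eint0(pc$rate[i] + 1i * omegas, pc$z1, pc$z2)
    Cmid[m, ] <- Re(acc)
  }
  Cmid
}

#' Assemble the rim-matching linear system
#'
#' Builds the Galerkin system enforcing continuity of concentration and of
#' the D-weighted radial flux at the slice rim \eqn{r = r_T}, both
#' projected onto the first \code{M} inner vertical modes. The flux
#' equation carries the material weights of the matching conditions
#' (\eqn{D_1} on both sides in the fluid intervals, \eqn{D_1} outer vs
#' \eqn{D_2} inner across the tissue band), under which the inner-side
#' matrix is the D-weighted Gram of the inner modes -- diagonal by
#' Sturm-Liouville orthogonality, which is what makes the projection onto
#' the inner modes natural. Internally the radial basis functions are
#' rescaled to unit value at \eqn{r_T}
#' (\eqn{I_0(\lambda_m r)/I_0(\lambda_m r_T)} inside,
#' \eqn{Q_n(r)/Q_n(r_T)} outside), which keeps every matrix entry bounded;
#' the literal-basis factors are stored for conversion.
#'
#' @param eig inner eigensystem with at least \code{M} modes.
#' @param bp a \code{\link{baseline_profile}} (same geometry and
#'   parameters).
#' @param M common truncation order of both series.
#' @param method overlap-integral path, \code{"closed"} or
#'   \code{"quadrature"}.
#' @return An object of class \code{"matching_system"} with the normalised
#'   matrices \code{R}, \code{S}, \code{T}, \code{W} (all \code{M x M}),
#'   load vector \code{g}, the rim derivative ratios, and the literal-basis
#'   scale factors \code{I0_rT} and \code{Q_rT}.
#' @export
assemble_system <- function(eig, bp, M = nrow(eig$modes),
                            method = c("closed", "quadrature")) {
  method <- match.arg(method)
  if (M > nrow(eig$modes))
    stop("eigensystem holds fewer modes than requested truncation")
  if (M < nrow(eig$modes)) {
    eig$modes <- eig$modes[seq_len(M), ]
    eig$trapped_count <- sum(eig$modes$branch == "trapped")
  }
  sys <- eig$system
  par <- eig$params
  omegas <- outer_eigenvalues(M, sys$H)
  C <- overlap_integrals(eig, omegas, method = method)
  g <- projection_load(eig, bp, method = method)
  gram <- inner_mode_grams(eig, method = method)
  GD <- par$D1 * (gram$plain - gram$tissue) + par$D2 * gram$tissue
  lam <- eig$modes$lam
  # rim logarithmic derivatives of the radial bases
  w_m <- lam * besselI(lam * sys$r_T, 1, expon.scaled = TRUE) /
    besselI(lam * sys$r_T, 0, expon.scaled = TRUE)
  sc <- outer_radial_scaled(omegas, sys$r_T, sys$r_o, r_ref = sys$r_T)
  q_n <- sc$dq / sc$q
  R <- C
  S <- par$D1 * sweep(C, 2, q_n, `*`)
  TT <- gram$plain
  W <- sweep(GD, 1, w_m, `*`)
  if (!all(is.finite(R) & is.finite(S) & is.finite(W)) || !all(is.finite(g))) {
    bad <- which(!is.finite(R + S + W), arr.ind = TRUE)
    stop(sprintf("assembly error: non-finite entry at (m = %d, n = %d)",
                 bad[1, 1], bad[1, 2]))
  }
  structure(list(R = R, S = S, T = TT, W = W, g = g, C = C,
                 gram = gram, GD = GD,
                 q_n = q_n, w_m = w_m, omegas = omegas,
                 I0_rT = besselI(lam * sys$r_T, 0),
                 Q_rT = outer_radial_factor(omegas, sys$r_T, sys$r_o),
                 eig = eig, bp = bp, M = M),
            class = "matching_system")
}

#' Solve the matching system for the series coefficients
#'
#' Eliminates one coefficient vector from the two projected matching
#' equations and solves the resulting dense system by LU factorisation.
#' Both elimination orders are available and agree to solver precision;
#' the residuals of both matching equations are reported.
#'
#' @param ms a \code{\link{assemble_system}} result.
#' @param route \code{"alpha"} eliminates the outer coefficients first
#'   (solve for the inner vector), \code{"A"} the reverse.
#' @return An object of class \code{"pcls_solution"} holding the
#'   rescaled-basis coefficient vectors \code{alpha_hat} (inner) and
#'   \code{A_hat} (outer), the literal-basis \code{alpha} and \code{A},
#'   and relative residuals of the two matching equations.
#' @export
solve_coefficients <- function(ms, route = c("alpha", "A")) {
  route <- match.arg(route)
  R <- ms$R; TT <- ms$T; S <- ms$S; W <- ms$W; g <- ms$g
  rc <- min(rcond(R), rcond(S))
  if (!is.finite(rc) || rc < 1e-14)
    stop("ill-conditioned matching system: lower the truncation M ",
         "or rescale the basis")
  if (route == "alpha") {
    # A_hat = S^{-1} W a_hat; (T - R S^{-1} W) a_hat = g
    SiW <- solve(S, W)
    alpha_hat <- solve(TT - R %*% SiW, g)
    A_hat <- SiW %*% alpha_hat
  } else {
    # a_hat = W^{-1} S A_hat; (T W^{-1} S - R) A_hat = g
    WiS <- solve(W, S)
    A_hat <- solve(TT %*% WiS - R, g)
    alpha_hat <- WiS %*% A_hat
  }
  alpha_hat <- drop(alpha_hat); A_hat <- drop(A_hat)
  gscale <- max(abs(g), ms$bp$phi0 * ms$eig$system$H)
  res1 <- max(abs(R %*% A_hat - TT %*% alpha_hat + g)) / gscale
  fscale <- max(abs(S) %*% abs(A_hat) + abs(W) %*% abs(alpha_hat))
  res2 <- if (fscale > 0)
    max(abs(S %*% A_hat - W %*% alpha_hat)) / fscale else 0
  structure(list(alpha_hat = alpha_hat, A_hat = A_hat,
                 alpha = alpha_hat / ms$I0_rT, A = A_hat / ms$Q_rT,
                 residuals = c(concentration = res1, flux = res2),
                 ms = ms, eig = ms$eig, bp = ms$bp,
                 system = ms$eig$system, params = ms$eig$params,
                 phi0 = ms$bp$phi0, omegas = ms$omegas, M = ms$M),
            class = "pcls_solution")
}

#' Solve the full oxygen-field model
#'
#' One-call driver: finds the inner eigenvalues, builds the baseline
#' profile, assembles the rim-matching system at truncation \code{M} and
#' solves for the series coefficients.
#'
#' @param params a \code{\link{transport_params}} object.
#' @param system a \code{\link{well_system}} object.
#' @param phi0 surface oxygen partial pressure [mmHg].
#' @param M series truncation order (number of vertical modes in each
#'   region).
#' @param method overlap-integral path.
#' @return a \code{\link{solve_coefficients}} solution object.
#' @examples
#' cfg <- default_parameters(5, "middle")
#' sol <- solve_oxygen_field(cfg$params, cfg$system, phi0 = 160, M = 7)
#' tissue_extrema(sol)[c("min", "max")]
#' @export
solve_oxygen_field <- function(params, system, phi0, M = 7,
                               method = c("closed", "quadrature")) {
  method <- match.arg(method)
  if (params$V == 0) {
    # no uptake: the field is uniformly phi0; represent with zero series
    eig <- find_inner_eigenvalues(params, system, M)
    bp <- baseline_profile(params, system, phi0)
    ms <- assemble_system(eig, bp, M = M, method = method)
    sol <- structure(list(alpha_hat = numeric(M), A_hat = numeric(M),
                          alpha = numeric(M), A = numeric(M),
                          residuals = c(concentration = 0, flux = 0),
                          ms = ms, eig = eig, bp = bp,
                          system = system, params = params, phi0 = phi0,
                          omegas = ms$omegas, M = M),
                     class = "pcls_solution")
    return(sol)
  }
  eig <- find_inner_eigenvalues(params, system, M)
  bp <- baseline_profile(params, system, phi0)
  ms <- assemble_system(eig, bp, M = M, method = method)
  solve_coefficients(ms)
}

#' @export
print.pcls_solution <- function(x, ...) {
  cat(sprintf("Matched oxygen-field solution (M = %d, phi0 = %.1f mmHg)\n",
              x$M, x$phi0))
  cat(sprintf("  matching residuals: concentration %.2e, flux %.2e\n",
              x$residuals[1], x$residuals[2]))
  ext <- tissue_extrema(x, n_r = 60, n_z = 20, refine = FALSE)
  cat(sprintf("  tissue oxygen range ~ %.1f to %.1f mmHg\n",
              ext$min, ext$max))
  invisible(x)
}
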