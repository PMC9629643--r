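# Inner-region vertical eigenproblem: fluid / tissue / fluid column with
#   Z'' + lam^2 Z = 0 in the fluid, Z'' + (lam^2 - k^2) Z = 0 in the tissue,
#   Z'(0) = 0, Z(H) = 0, value continuity at h1, h2 and D-weighted flux
#   continuity D1 Z'(h1-) = D2 Z'(h1+), D2 Z'(h2-) = D1 Z'(h2+).
# Eigenvalues lam < k are "trapped" (cosh/sinh inside the tissue), lam > k
# are "free" (trigonometric throughout).

# cosh-type and sinh-type solutions of Z'' = q Z, continuous through q = 0:
# cq(q,u) = cosh(sqrt(q) u) for q > 0, cos(sqrt(-q) u) for q < 0;
# sq(q,u) = sinh(sqrt(q) u)/sqrt(q) resp. sin(sqrt(-q) u)/sqrt(-q).
cq <- function(q, u) {
  x <- q * u^2
  n <- length(x)
  q <- rep_len(q, n); u <- rep_len(u, n)
  pos <- q >= 0
  out <- numeric(n)
  out[pos] <- cosh(sqrt(q[pos]) * u[pos])
  out[!pos] <- cos(sqrt(-q[!pos]) * u[!pos])
  small <- abs(x) < 1e-8
  out[small] <- 1 + x[small] / 2
  out
}

sq <- function(q, u) {
  x <- q * u^2
  n <- length(x)
  q <- rep_len(q, n); u <- rep_len(u, n)
  pos <- q >= 0
  rq <- sqrt(abs(q))
  out <- numeric(n)
  out[pos] <- sinh(rq[pos] * u[pos]) / rq[pos]
  out[!pos] <- sin(rq[!pos] * u[!pos]) / rq[!pos]
  small <- abs(x) < 1e-8
  out[small] <- u[small] * (1 + x[small] / 6)
  out
}

# Forward-propagated mode state at a candidate eigenvalue: the eigenfunction
# normalised to Z(0) = 1, carried through both interfaces.
mode_state <- function(lam, params, system) {
  D1 <- params$D1; D2 <- params$D2; k <- params$k
  h1 <- system$h1; h2 <- system$h2; H <- system$H
  t <- h2 - h1
  a <- cos(lam * h1)                      # Z(h1)
  b <- -(D1 / D2) * lam * sin(lam * h1)   # Z'(h1+), flux-weighted
  q <- k^2 - lam^2
  v <- a * cq(q, t) + b * sq(q, t)        # Z(h2)
  d <- a * q * sq(q, t) + b * cq(q, t)    # Z'(h2-)
  e2 <- (D2 / D1) * d                     # Z'(h2+), flux-weighted
  list(lam = lam, q = q, a = a, b = b, v = v, d = d, e2 = e2)
}

#' Dispersion residual of the inner vertical eigenproblem
#'
#' Pole-free characteristic function whose positive roots are the inner
#' eigenvalues: the candidate eigenfunction with \eqn{Z(0)=1},
#' \eqn{Z'(0)=0} is propagated through both tissue interfaces (value
#' continuity plus D-weighted flux continuity) and the residual is its value
#' at the media surface, \eqn{Z(H)}. This equals the printed transcendental
#' dispersion relations (trapped branch below \eqn{k}, free branch above)
#' multiplied through by their cosine denominators, so it has no poles and
#' its sign changes bracket exactly the eigenvalues.
#'
#' @param lam candidate eigenvalue(s) [1/m], vectorised; must be positive.
#' @param params a \code{\link{transport_params}} object.
#' @param system a \code{\link{well_system}} object.
#' @param branch optional consistency check: \code{"trapped"} requires
#'   \code{lam < k}, \code{"free"} requires \code{lam > k};
#'   \code{"auto"} (default) accepts either.
#' @return residual values (dimensionless); zero at eigenvalues.
#' @export
dispersion_residual <- function(lam, params, system,
                                branch = c("auto", "trapped", "free")) {
  branch <- match.arg(branch)
  if (any(lam <= 0)) stop("eigenvalue candidates must be positive")
  k <- params$k
  if (branch == "trapped" && any(lam >= k))
    stop("trapped branch requires lam < k")
  if (branch == "free" && any(lam <= k))
    stop("free branch requires lam > k")
  st <- mode_state(lam, params, system)
  u <- system$H - system$h2
  st$v * cos(lam * u) + st$e2 * sin(lam * u) / lam
}

#' Solve the inner eigensystem
#'
#' Finds the \code{M} smallest positive eigenvalues of the inner-region
#' vertical problem by a dense sign-change scan of the pole-free
#' \code{\link{dispersion_residual}} followed by bracketed root polishing,
#' and stores the piecewise eigenfunction parameters of each mode.
#'
#' @param params a \code{\link{transport_params}} object.
#' @param system a \code{\link{well_system}} object.
#' @param M number of modes to return.
#' @param points_per_spacing scan density per nominal mode spacing
#'   \eqn{\pi/H}.
#' @return An object of class \code{"inner_eigensystem"}: list with
#'   \code{modes} (data.frame of per-mode parameters, ascending eigenvalue),
#'   \code{trapped_count}, \code{k}, \code{params}, \code{system}.
#' @examples
#' cfg <- default_parameters(5, "middle")
#' eig <- find_inner_eigenvalues(cfg$params, cfg$system, M = 7)
#' eig$trapped_count
#' @export
find_inner_eigenvalues <- function(params, system, M,
                                   points_per_spacing = 2000) {
  stopifnot(M >= 1)
  validate_well_system(system)
  spacing <- pi / system$H
  f <- function(l) dispersion_residual(l, params, system)
  lam_lo <- spacing * 1e-8
  lam_hi <- params$k + (M + 2) * spacing
  roots <- numeric(0)
  for (attempt in 1:8) {
    grid <- seq(lam_lo, lam_hi,
                by = spacing / points_per_spacing)
    fg <- f(grid)
    sgn <- sign(fg)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (length(idx) >= M) {
      idx <- idx[seq_len(M)]
      roots <- vapply(idx, function(i) {
        stats::uniroot(f, lower = grid[i], upper = grid[i + 1],
                       f.lower = fg[i], f.upper = fg[i + 1],
                       tol = 1e-13 * grid[i + 1])$root
      }, numeric(1))
      break
    }
    lam_hi <- lam_hi + (M + 2) * spacing
  }
  if (length(roots) < M)
    stop(sprintf(
      "search-window error: found only %d of %d eigenvalues below %.3e 1/m",
      length(roots), M, lam_hi))
  st <- mode_state(roots, params, system)
  modes <- data.frame(
    n = seq_len(M), lam = roots,
    branch = ifelse(roots < params$k, "trapped", "free"),
    aux = sqrt(abs(params$k^2 - roots^2)),
    q = st$q, a = st$a, b = st$b, v = st$v, d = st$d, e2 = st$e2
  )
  structure(list(modes = modes, trapped_count = sum(roots < params$k),
                 k = params$k, params = params, system = system),
            class = "inner_eigensystem")
}

#' @export
print.inner_eigensystem <- function(x, ...) {
  cat(sprintf(
    "Inner eigensystem: %d modes (%d trapped below k = %.1f 1/m)\n",
    nrow(x$modes), x$trapped_count, x$k))
  print(utils::head(x$modes[, c("n", "lam", "branch", "aux")], 10L))
  invisible(x)
}

#' Evaluate an inner vertical eigenfunction
#'
#' Piecewise evaluation of mode \code{n} of an inner eigensystem:
#' \eqn{\cos(\lambda z)} below the slice, a cosh/sinh (trapped) or cos/sin
#' (free) combination through it, and a phase-shifted sine above it that
#' vanishes at the media surface. Unnormalised, with \eqn{Z(0) = 1}.
#'
#' @param eig an \code{\link{find_inner_eigenvalues}} result.
#' @param n mode index (1-based).
#' @param z heights [m], vectorised, within [0, H].
#' @param deriv 0 for the value, 1 for dZ/dz. Derivatives are one-sided at
#'   the interfaces (the lower-side value is returned there).
#' @return numeric vector of eigenfunction values (or derivatives [1/m]).
#' @export
inner_eigenfunction <- function(eig, n, z, deriv = 0) {
  sys <- eig$system
  if (any(z < -1e-15 | z > sys$H * (1 + 1e-12)))
    stop("z outside [0, H]")
  m <- eig$modes[n, ]
  lam <- m$lam
  out <- numeric(length(z))
  p1 <- z <= sys$h1
  p2 <- z > sys$h1 & z <= sys$h2
  p3 <- z > sys$h2
  if (deriv == 0) {
    out[p1] <- cos(lam * z[p1])
    u <- z[p2] - sys$h1
    out[p2] <- m$a * cq(m$q, u) + m$b * sq(m$q, u)
    u <- z[p3] - sys$h2
    out[p3] <- m$v * cos(lam * u) + m$e2 * sin(lam * u) / lam
  } else if (deriv == 1) {
    out[p1] <- -lam * sin(lam * z[p1])
    u <- z[p2] - sys$h1
    out[p2] <- m$a * m$q * sq(m$q, u) + m$b * cq(m$q, u)
    u <- z[p3] - sys$h2
    out[p3] <- -m$v * lam * sin(lam * u) + m$e2 * cos(lam * u)
  } else stop("deriv must be 0 or 1")
  out
}

# Matrix of eigenfunction values, length(z) x M (series evaluation kernel).
inner_eigenfunction_matrix <- function(eig, z) {
  vapply(seq_len(nrow(eig$modes)),
         function(n) inner_eigenfunction(eig, n, z),
         numeric(length(z)))
}

# Literal closed-form evaluation of the printed piecewise eigenfunctions,
# with the closure coefficients rho (trapped) / zeta (free) written out.
# Used as an independent cross-check of the propagated form.
inner_eigenfunction_printed <- function(eig, n, z) {
  sys <- eig$system; par <- eig$params
  m <- eig$modes[n, ]
  lam <- m$lam; h1 <- sys$h1; h2 <- sys$h2; H <- sys$H
  c12 <- par$D1 * lam / (par$D2 * m$aux)
  out <- numeric(length(z))
  p1 <- z < h1
  p2 <- z >= h1 & z <= h2
  p3 <- z > h2
  out[p1] <- cos(lam * z[p1])
  u <- z[p2] - h1
  if (m$branch == "trapped") {
    tau <- m$aux
    out[p2] <- cos(lam * h1) * cosh(tau * u) - c12 * sin(lam * h1) * sinh(tau * u)
    rho <- (cosh(tau * (h1 - h2)) * cos(lam * h1) +
              c12 * sinh(tau * (h1 - h2)) * sin(lam * h1)) /
      sin(lam * (h2 - H))
  } else {
    del <- m$aux
    out[p2] <- cos(lam * h1) * cos(del * u) - c12 * sin(lam * h1) * sin(del * u)
    rho <- (c12 * sin(del * (h2 - h1)) * sin(lam * h1) -
              cos(del * (h2 - h1)) * cos(lam * h1)) /
      sin(lam * (H - h2))
  }
  out[p3] <- rho * sin(lam * (z[p3] - H))
  out
}

# Transcendental dispersion relations in quotient (tan/tanh) form
# (trapped branch below k, free branch above). Expanding the propagated
# residual and dividing by the product of the cosine/cosh factors gives,
# for the trapped branch,
#   1 + tan(eta h1) tan(eta (h2-H))
#     - (D2 tau)/(D1 eta) tanh(tau (h2-h1)) tan(eta (h2-H))
#     + (D1 eta)/(D2 tau) tan(eta h1) tanh(tau (h1-h2)) = 0,
# i.e. the mixed tanh*tan term carries the opposite sign to some published
# transcriptions (the free-branch relation is unaffected). Has tangent
# poles; used only to cross-check root locations of the pole-free residual.
dispersion_printed <- function(lam, params, system) {
  D1 <- params$D1; D2 <- params$D2; k <- params$k
  h1 <- system$h1; h2 <- system$h2; H <- system$H
  out <- numeric(length(lam))
  tr <- lam < k
  eta <- lam[tr]; tau <- sqrt(k^2 - eta^2)
  out[tr] <- 1 + tan(eta * h1) * tan(eta * (h2 - H)) -
    (D2 * tau) / (D1 * eta) * tanh(tau * (h2 - h1)) * tan(eta * (h2 - H)) +
    (D1 * eta) / (D2 * tau) * tan(eta * h1) * tanh(tau * (h1 - h2))
  mu <- lam[!tr]; del <- sqrt(mu^2 - k^2)
  out[!tr] <- (D1 * mu) / (D2 * del) * tan(del * (h2 - h1)) * tan(mu * h1) -
    (D2 * del) / (D1 * mu) * tan(mu * (h2 - H)) * tan(del * (h2 - h1)) -
    1 - tan(mu * (h2 - H)) * tan(mu * h1)
  out
}
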