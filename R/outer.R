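# Outer annulus (fluid only): vertical modes cos(omega_n z) with
# omega_n = (n - 1/2) pi / H, radial factors built from I0/K0 so that the
# radial derivative vanishes at the well wall r = r_o. All modified Bessel
# evaluations use the exponentially-scaled forms with the exponents
# recombined analytically, so only bounded ratios are formed.

#' Outer-region vertical eigenvalues
#'
#' The fluid-only column has eigenfunctions \eqn{\cos(\omega_n z)} with
#' \eqn{Z'(0) = 0} and \eqn{Z(H) = 0}, forcing
#' \eqn{\omega_n = (n - 1/2)\pi/H}.
#'
#' @param M number of modes.
#' @param H media depth [m].
#' @return vector of \eqn{\omega_n} [1/m], ascending.
#' @examples
#' outer_eigenvalues(3, 3.4e-3)
#' @export
outer_eigenvalues <- function(M, H) {
  stopifnot(M >= 1, H > 0)
  (seq_len(M) - 0.5) * pi / H
}

# Scaled pieces of the wall-condition radial combination
#   Q(r) = K0'(w r_o) I0(w r) - I0'(w r_o) K0(w r)
#        = -[K1(w r_o) I0(w r) + I1(w r_o) K0(w r)],
# whose r-derivative vanishes at r_o. Returns Q and dQ/dr times exp(-u_ref)
# where u_ref = w (r_o - r_ref): with r_ref = r_T all subsequent ratios
# Q(r)/Q(r_T) are formed from exponents <= 0 and never overflow.
outer_radial_scaled <- function(omega, r, r_o, r_ref = r_o) {
  w <- omega
  u <- w * (r_o - r)          # >= 0 inside the well
  u_ref <- w * (r_o - r_ref)
  K1o <- besselK(w * r_o, 1, expon.scaled = TRUE)
  I1o <- besselI(w * r_o, 1, expon.scaled = TRUE)
  I0r <- besselI(w * r, 0, expon.scaled = TRUE)
  K0r <- besselK(w * r, 0, expon.scaled = TRUE)
  I1r <- besselI(w * r, 1, expon.scaled = TRUE)
  K1r <- besselK(w * r, 1, expon.scaled = TRUE)
  q <- -(K1o * I0r * exp(-u - u_ref) + I1o * K0r * exp(u - u_ref))
  dq <- w * (-K1o * I1r * exp(-u - u_ref) + I1o * K1r * exp(u - u_ref))
  list(q = q, dq = dq)
}

#' Outer radial factor with the no-flux wall condition
#'
#' The combination
#' \eqn{Q_n(r) = K_0'(\omega_n r_o) I_0(\omega_n r) -
#'              I_0'(\omega_n r_o) K_0(\omega_n r)}
#' (primes with respect to the argument; \eqn{I_0' = I_1},
#' \eqn{K_0' = -K_1}), which satisfies \eqn{Q_n'(r_o) = 0}. Evaluated with
#' exponentially-scaled Bessel functions so large \eqn{\omega_n r} does not
#' overflow.
#'
#' @param omega mode wavenumber \eqn{\omega_n} [1/m].
#' @param r radius [m], vectorised; must satisfy \eqn{0 < r \le r_o}
#'   (the outer region excludes the axis, where \eqn{K_0} diverges).
#' @param r_o well radius [m].
#' @param deriv 0 for \eqn{Q_n(r)}, 1 for \eqn{dQ_n/dr} [1/m].
#' @return numeric vector.
#' @export
outer_radial_factor <- function(omega, r, r_o, deriv = 0) {
  if (any(r <= 0) || any(r > r_o * (1 + 1e-12)))
    stop("outer radial factor defined for 0 < r <= r_o only")
  s <- outer_radial_scaled(omega, r, r_o, r_ref = r_o)
  if (deriv == 0) s$q else if (deriv == 1) s$dq
  else stop("deriv must be 0 or 1")
}
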