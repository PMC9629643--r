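#' Radially uniform baseline oxygen profile of the inner column
#'
#' The particular solution of the vertical two-layer diffusion-uptake
#' problem through the slice: pure diffusion in the fluid below and above,
#' first-order uptake within the tissue band, surface value \eqn{\phi_0} at
#' \eqn{z = H} and no flux at the well bottom. It is constant below the
#' slice, a \eqn{\cosh} through it, and linear above it, with the composite
#' conductance
#' \deqn{\theta = D_1\cosh(k(h_2-h_1)) + D_2 k (H-h_2)\sinh(k(h_2-h_1)).}
#'
#' @param params a \code{\link{transport_params}} object.
#' @param system a \code{\link{well_system}} object.
#' @param phi0 surface oxygen partial pressure [mmHg].
#' @return An object of class \code{"baseline_profile"} with the composite
#'   conductance \code{theta} [m^2/s] and the geometry needed to evaluate
#'   the profile; evaluate with \code{\link{eval_baseline}}.
#' @export
baseline_profile <- function(params, system, phi0) {
  validate_well_system(system)
  if (phi0 < 0) stop("phi0 must be non-negative [mmHg]")
  k <- params$k; t <- system$h2 - system$h1
  theta <- params$D1 * cosh(k * t) +
    params$D2 * k * (system$H - system$h2) * sinh(k * t)
  structure(list(theta = theta, phi0 = phi0, params = params,
                 system = system),
            class = "baseline_profile")
}

#' Evaluate the baseline profile
#'
#' @param bp a \code{\link{baseline_profile}} object.
#' @param z heights [m], vectorised; must lie in [0, H].
#' @return oxygen partial pressure [mmHg] at each \code{z}.
#' @export
eval_baseline <- function(bp, z) {
  sys <- bp$system; k <- bp$params$k
  if (any(z < -1e-15 | z > sys$H * (1 + 1e-12)))
    stop("z outside [0, H]")
  D1 <- bp$params$D1; D2 <- bp$params$D2
  t <- sys$h2 - sys$h1
  out <- numeric(length(z))
  lo <- z <= sys$h1
  mid <- z > sys$h1 & z < sys$h2
  hi <- z >= sys$h2
  out[lo] <- D1 * bp$phi0 / bp$theta
  out[mid] <- D1 * bp$phi0 / bp$theta * cosh(k * (z[mid] - sys$h1))
  out[hi] <- bp$phi0 *
    (1 + D2 * k / bp$theta * sinh(k * t) * (z[hi] - sys$H))
  out
}

#' @export
print.baseline_profile <- function(x, ...) {
  cat("Baseline (radially uniform) oxygen profile\n")
  cat(sprintf("  theta = %.4e m^2/s, phi0 = %.2f mmHg\n", x$theta, x$phi0))
  cat(sprintf("  value at well bottom: %.3f mmHg\n", eval_baseline(x, 0)))
  invisible(x)
}
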