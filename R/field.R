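# Evaluation of the matched series solution anywhere in the well, and the
# profile / extremum extractors used by the scenario analyses.

# Scaled inner radial ratios I0(lam r) / I0(lam r_T), rows r x cols modes.
inner_radial_ratio <- function(lam, r, r_T) {
  out <- matrix(0, length(r), length(lam))
  for (j in seq_along(lam)) {
    out[, j] <- besselI(lam[j] * r, 0, expon.scaled = TRUE) /
      besselI(lam[j] * r_T, 0, expon.scaled = TRUE) *
      exp(lam[j] * (r - r_T))
  }
  out
}

# Scaled outer radial ratios Q_n(r) / Q_n(r_T), rows r x cols modes.
outer_radial_ratio <- function(omegas, r, r_T, r_o) {
  out <- matrix(0, length(r), length(omegas))
  for (j in seq_along(omegas)) {
    num <- outer_radial_scaled(omegas[j], r, r_o, r_ref = r_T)
    den <- outer_radial_scaled(omegas[j], r_T, r_o, r_ref = r_T)
    out[, j] <- num$q / den$q
  }
  out
}

#' Oxygen field on a tensor-product grid
#'
#' Efficient evaluation of the matched series on the grid formed by all
#' combinations of \code{r} and \code{z} (used by the extremum search, the
#' finite-volume comparison and contour plotting).
#'
#' @param sol a \code{\link{solve_oxygen_field}} solution.
#' @param r radii [m].
#' @param z heights [m].
#' @return matrix of concentrations [mmHg], \code{length(r)} rows by
#'   \code{length(z)} columns.
#' @export
field_grid <- function(sol, r, z) {
  sys <- sol$system
  phi <- matrix(NA_real_, length(r), length(z))
  inner <- r <= sys$r_T
  if (any(inner)) {
    Zm <- inner_eigenfunction_matrix(sol$eig, z)        # z x M
    Rad <- inner_radial_ratio(sol$eig$modes$lam, r[inner], sys$r_T)
    U <- eval_baseline(sol$bp, z)
    phi[inner, ] <- rep(U, each = sum(inner)) +
      Rad %*% (t(Zm) * sol$alpha_hat)
  }
  if (any(!inner)) {
    Zc <- outer(z, sol$omegas, function(zz, w) cos(w * zz))  # z x M
    Rad <- outer_radial_ratio(sol$omegas, r[!inner], sys$r_T, sys$r_o)
    phi[!inner, ] <- sol$phi0 + Rad %*% (t(Zc) * sol$A_hat)
  }
  phi
}

#' Oxygen concentration at points in the well
#'
#' Evaluates the matched series solution at coordinate pairs
#' \code{(r, z)}. Points with \eqn{r \le r_T} use the inner (tissue-column)
#' expansion, points with \eqn{r > r_T} the outer (annulus) expansion; on
#' the rim itself the inner representation is reported.
#'
#' @param sol a \code{\link{solve_oxygen_field}} solution.
#' @param r radii [m], recycled against \code{z}.
#' @param z heights [m].
#' @return oxygen partial pressure [mmHg] at each point.
#' @export
concentration_at <- function(sol, r, z) {
  n <- max(length(r), length(z))
  r <- rep_len(r, n); z <- rep_len(z, n)
  sys <- sol$system
  if (any(r < 0 | r > sys$r_o * (1 + 1e-12)))
    stop("r outside [0, r_o]")
  if (any(z < 0 | z > sys$H * (1 + 1e-12)))
    stop("z outside [0, H]")
  out <- numeric(n)
  inner <- r <= sys$r_T
  if (any(inner)) {
    Zm <- inner_eigenfunction_matrix(sol$eig, z[inner])
    Rad <- inner_radial_ratio(sol$eig$modes$lam, r[inner], sys$r_T)
    out[inner] <- eval_baseline(sol$bp, z[inner]) +
      rowSums(Rad * Zm * rep(sol$alpha_hat, each = sum(inner)))
  }
  if (any(!inner)) {
    Zc <- outer(z[!inner], sol$omegas, function(zz, w) cos(w * zz))
    Rad <- outer_radial_ratio(sol$omegas, r[!inner], sys$r_T, sys$r_o)
    out[!inner] <- sol$phi0 +
      rowSums(Rad * Zc * rep(sol$A_hat, each = sum(!inner)))
  }
  out
}

#' Extrema of oxygen concentration over the tissue
#'
#' Scans a dense grid of the tissue region (\eqn{0 \le r \le r_T},
#' \eqn{h_1 \le z \le h_2}) and optionally polishes the grid optimum with a
#' bounded local search. By symmetry and the maximum principle the maximum
#' sits on the rim/top boundary and the minimum in the slice interior near
#' the axis.
#'
#' @param sol a solution object.
#' @param n_r,n_z grid resolution in r and z.
#' @param refine logical; polish with bounded \code{optim} around the grid
#'   optimum.
#' @return list with \code{min}, \code{max} [mmHg] and \code{argmin},
#'   \code{argmax} (each \code{c(r, z)} in metres).
#' @export
tissue_extrema <- function(sol, n_r = 200, n_z = 50, refine = TRUE) {
  sys <- sol$system
  r <- seq(0, sys$r_T, length.out = n_r)
  z <- seq(sys$h1, sys$h2, length.out = n_z)
  phi <- field_grid(sol, r, z)
  imin <- arrayInd(which.min(phi), dim(phi))
  imax <- arrayInd(which.max(phi), dim(phi))
  pmin <- c(r[imin[1]], z[imin[2]]); vmin <- phi[imin]
  pmax <- c(r[imax[1]], z[imax[2]]); vmax <- phi[imax]
  if (refine) {
    f <- function(p) concentration_at(sol, p[1], p[2])
    lower <- c(0, sys$h1); upper <- c(sys$r_T, sys$h2)
    opt_min <- stats::optim(pmin, f, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(factr = 1e4))
    if (opt_min$value < vmin) { vmin <- opt_min$value; pmin <- opt_min$par }
    opt_max <- stats::optim(pmax, f, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(fnscale = -1, factr = 1e4))
    if (opt_max$value > vmax) { vmax <- opt_max$value; pmax <- opt_max$par }
  }
  list(min = vmin, max = vmax, argmin = pmin, argmax = pmax)
}

#' Mid-plane radial oxygen profile
#'
#' Samples the field along the slice mid-plane \eqn{z = (h_1 + h_2)/2} from
#' the axis to the slice rim; the quantity shown in the contour-plot
#' cross-sections of the scenario analyses.
#'
#' @param sol a solution object.
#' @param n_r number of radial samples (>= 2).
#' @return data.frame with columns \code{r}, \code{z} [m] and \code{phi}
#'   [mmHg].
#' @export
midplane_profile <- function(sol, n_r = 101) {
  stopifnot(n_r >= 2)
  sys <- sol$system
  zmid <- (sys$h1 + sys$h2) / 2
  r <- seq(0, sys$r_T, length.out = n_r)
  data.frame(r = r, z = zmid, phi = concentration_at(sol, r, zmid))
}

#' Through-thickness oxygen profile
#'
#' Samples the field through the slice thickness at fixed radius, from the
#' bottom face \eqn{z = h_1} to the top face \eqn{z = h_2}.
#'
#' @param sol a solution object.
#' @param r radius [m], within the slice.
#' @param n_z number of vertical samples.
#' @return data.frame with columns \code{r}, \code{z} [m] and \code{phi}
#'   [mmHg].
#' @export
thickness_profile <- function(sol, r = 0, n_z = 101) {
  sys <- sol$system
  if (r < 0 || r > sys$r_T) stop("r outside the slice [0, r_T]")
  z <- seq(sys$h1, sys$h2, length.out = n_z)
  data.frame(r = r, z = z, phi = concentration_at(sol, r, z))
}

#' Export a profile or grid as CSV
#'
#' Writes sampled concentrations with coordinates in millimetres and
#' pressures in mmHg (columns \code{r_mm}, \code{z_mm}, \code{phi_mmHg}).
#'
#' @param profile a data.frame from \code{\link{midplane_profile}} or
#'   \code{\link{thickness_profile}}.
#' @param file output path.
#' @return the written data.frame, invisibly.
#' @export
write_profile_csv <- function(profile, file) {
  out <- data.frame(r_mm = signif(profile$r * 1e3, 6),
                    z_mm = signif(profile$z * 1e3, 6),
                    phi_mmHg = signif(profile$phi, 6))
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}
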