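# Independent axisymmetric finite-volume reference solver for the same
# boundary-value problem: div(D grad phi) - V 1_tissue phi = 0 in
# cylindrical (r, z), phi = phi0 at the surface, no flux at the wall,
# base and axis. Node-centred grid with lines placed on r_T, h1 and h2 so
# each face conductance is built from homogeneous material half-faces,
# which enforces interface flux continuity conservatively (the axis needs
# no special casing: the innermost control volume has zero inner face
# area). All areas carry a factor 1/pi, which cancels throughout.

# grid lines covering segment breakpoints with roughly uniform spacing
segment_lines <- function(breaks, n_total) {
  lens <- diff(breaks)
  n_seg <- pmax(3L, round(n_total * lens / sum(lens)))
  pts <- lapply(seq_along(lens), function(i)
    seq(breaks[i], breaks[i + 1], length.out = n_seg[i]))
  unique(unlist(pts))
}

#' Finite-volume solution of the oxygen transport problem
#'
#' Conservative node-centred finite-volume discretisation of the
#' axisymmetric steady diffusion-uptake equation on a grid whose lines
#' include the slice rim and faces, solved with a sparse LU factorisation.
#' Serves as the independent numerical oracle for the series solution.
#'
#' @param system a \code{\link{well_system}}-like list; \code{slice_radius}
#'   may equal \code{well_radius} here (full-width tissue layer, the 1-D
#'   limit).
#' @param params a \code{\link{transport_params}}.
#' @param phi0 surface oxygen partial pressure [mmHg].
#' @param n_r,n_z approximate number of grid nodes in r and z (>= 20).
#' @return An object of class \code{"fd_field"}: list with node coordinate
#'   vectors \code{r}, \code{z}, the concentration matrix \code{phi}
#'   (rows = r, cols = z) [mmHg], and the discrete residual norm.
#' @export
solve_fd <- function(system, params, phi0, n_r = 200, n_z = 200) {
  stopifnot(n_r >= 20, n_z >= 20)
  full_width <- system$r_T >= system$r_o - 1e-15
  r_breaks <- if (full_width) c(0, system$r_o)
              else c(0, system$r_T, system$r_o)
  z_breaks <- unique(c(0, system$h1, system$h2, system$H))
  r <- segment_lines(r_breaks, n_r)
  z <- segment_lines(z_breaks, n_z)
  Nr <- length(r); Nz <- length(z)
  dr <- diff(r); dz <- diff(z)
  rc <- (r[-Nr] + r[-1]) / 2
  zc <- (z[-Nz] + z[-1]) / 2
  cell_tissue <- outer(rc < system$r_T + 1e-15,
                       zc > system$h1 & zc < system$h2, `&`)
  Dcell <- matrix(ifelse(cell_tissue, params$D2, params$D1), Nr - 1, Nz - 1)
  rf <- (r[-Nr] + r[-1]) / 2                      # radial face radii
  area_lo <- c(0, r[-1]^2 - rf^2)                 # [r_{i-1/2}, r_i], / pi
  area_hi <- c(rf^2 - r[-Nr]^2, 0)                # [r_i, r_{i+1/2}], / pi
  # radial face conductances G_r[i, j]: nodes (i,j)-(i+1,j)
  G_r <- matrix(0, Nr - 1, Nz)
  G_r[, 2:Nz] <- G_r[, 2:Nz] + Dcell * rep(dz / 2, each = Nr - 1)
  G_r[, 1:(Nz - 1)] <- G_r[, 1:(Nz - 1)] + Dcell * rep(dz / 2, each = Nr - 1)
  G_r <- 2 * G_r * (rf / dr)                      # 2 r h / pi-normalised
  # vertical face conductances G_z[i, j]: nodes (i,j)-(i,j+1)
  G_z <- matrix(0, Nr, Nz - 1)
  G_z[2:Nr, ] <- G_z[2:Nr, ] + Dcell * (area_lo[2:Nr] / 2) * 2
  G_z[1:(Nr - 1), ] <- G_z[1:(Nr - 1), ] + Dcell * (area_hi[1:(Nr - 1)] / 2) * 2
  G_z <- G_z / rep(dz, each = Nr)
  # tissue volume of each control cell (for the uptake term)
  vol <- matrix(0, Nr, Nz)
  qlo <- area_lo[2:Nr]; qhi <- area_hi[1:(Nr - 1)]
  hz <- dz / 2
  vol[2:Nr, 2:Nz] <- vol[2:Nr, 2:Nz] + cell_tissue * outer(qlo, hz)
  vol[1:(Nr - 1), 2:Nz] <- vol[1:(Nr - 1), 2:Nz] + cell_tissue * outer(qhi, hz)
  vol[2:Nr, 1:(Nz - 1)] <- vol[2:Nr, 1:(Nz - 1)] + cell_tissue * outer(qlo, hz)
  vol[1:(Nr - 1), 1:(Nz - 1)] <- vol[1:(Nr - 1), 1:(Nz - 1)] +
    cell_tissue * outer(qhi, hz)
  # diagonal accumulation
  diag_mat <- matrix(0, Nr, Nz)
  diag_mat[1:(Nr - 1), ] <- diag_mat[1:(Nr - 1), ] + G_r
  diag_mat[2:Nr, ] <- diag_mat[2:Nr, ] + G_r
  diag_mat[, 1:(Nz - 1)] <- diag_mat[, 1:(Nz - 1)] + G_z
  diag_mat[, 2:Nz] <- diag_mat[, 2:Nz] + G_z
  diag_mat <- diag_mat + params$V * vol
  idx_mat <- matrix(seq_len(Nr * Nz), Nr, Nz)
  # off-diagonal triplets (both symmetric halves)
  a_r <- as.vector(idx_mat[1:(Nr - 1), ]); b_r <- as.vector(idx_mat[2:Nr, ])
  a_z <- as.vector(idx_mat[, 1:(Nz - 1)]); b_z <- as.vector(idx_mat[, 2:Nz])
  ii <- c(a_r, b_r, a_z, b_z)
  jj <- c(b_r, a_r, b_z, a_z)
  xx <- c(-G_r, -G_r, -G_z, -G_z)
  # Dirichlet surface row j = Nz eliminated; its coupling goes to the RHS
  free <- rep(TRUE, Nr * Nz); free[idx_mat[, Nz]] <- FALSE
  nfree <- which(free)
  remap <- integer(Nr * Nz); remap[nfree] <- seq_along(nfree)
  keep <- free[ii] & free[jj]
  rhs_mat <- matrix(0, Nr, Nz - 1)
  rhs_mat[, Nz - 1] <- G_z[, Nz - 1] * phi0
  A <- Matrix::sparseMatrix(
    i = c(remap[ii[keep]], seq_along(nfree)),
    j = c(remap[jj[keep]], seq_along(nfree)),
    x = c(xx[keep], diag_mat[nfree]),
    dims = c(length(nfree), length(nfree)))
  rhs <- as.vector(rhs_mat)
  sol <- as.numeric(Matrix::solve(A, rhs))
  resid <- max(abs(A %*% sol - rhs)) / max(abs(rhs), .Machine$double.eps)
  phi <- matrix(phi0, Nr, Nz)
  phi[, 1:(Nz - 1)] <- matrix(sol, Nr, Nz - 1)
  structure(list(r = r, z = z, phi = phi, residual = resid,
                 system = system, params = params, phi0 = phi0),
            class = "fd_field")
}

#' @export
print.fd_field <- function(x, ...) {
  cat(sprintf("Finite-volume oxygen field: %d x %d nodes, residual %.2e\n",
              length(x$r), length(x$z), x$residual))
  cat(sprintf("  range %.2f to %.2f mmHg\n", min(x$phi), max(x$phi)))
  invisible(x)
}

# Discrete steady-state oxygen balance: surface influx vs tissue uptake
# (relative mismatch; both per unit pi).
fd_oxygen_balance <- function(fd) {
  r <- fd$r; z <- fd$z; Nr <- length(r); Nz <- length(z)
  sys <- fd$system; par <- fd$params
  dzs <- z[Nz] - z[Nz - 1]
  grad_top <- (fd$phi[, Nz] - fd$phi[, Nz - 1]) / dzs
  gmid <- (grad_top[-Nr] + grad_top[-1]) / 2
  influx <- sum(par$D1 * gmid * (r[-1]^2 - r[-Nr]^2))
  rc <- (r[-Nr] + r[-1]) / 2
  zc <- (z[-Nz] + z[-1]) / 2
  tis <- outer(rc < sys$r_T + 1e-15, zc > sys$h1 & zc < sys$h2, `&`)
  pm <- (fd$phi[-Nr, -Nz] + fd$phi[-1, -Nz] +
         fd$phi[-Nr, -1] + fd$phi[-1, -1]) / 4
  vols <- outer(r[-1]^2 - r[-Nr]^2, diff(z))
  uptake <- par$V * sum(pm[tis] * vols[tis])
  abs(influx - uptake) / max(uptake, .Machine$double.eps)
}

#' Compare a finite-volume field with a series solution
#'
#' Evaluates the series solution on the finite-volume nodes and reports
#' sup-norm and root-mean-square discrepancies, over the whole well and
#' over the tissue region, as fractions of the surface value \eqn{\phi_0}.
#'
#' @param fd a \code{\link{solve_fd}} result.
#' @param sol a \code{\link{solve_oxygen_field}} result for the same
#'   geometry and parameters.
#' @return list with elements \code{linf_domain}, \code{rms_domain},
#'   \code{linf_tissue}, \code{rms_tissue} (dimensionless fractions of
#'   \eqn{\phi_0}).
#' @export
compare_to_series <- function(fd, sol) {
  sys <- sol$system
  if (abs(fd$system$H - sys$H) > 1e-12 ||
      abs(fd$system$r_T - sys$r_T) > 1e-12 ||
      abs(fd$system$h1 - sys$h1) > 1e-12 ||
      abs(fd$system$h2 - sys$h2) > 1e-12)
    stop("comparison error: geometry mismatch between FD field and solution")
  phi_s <- field_grid(sol, fd$r, fd$z)
  diffm <- abs(phi_s - fd$phi) / fd$phi0
  in_tissue <- outer(fd$r <= sys$r_T + 1e-15,
                     fd$z >= sys$h1 - 1e-15 & fd$z <= sys$h2 + 1e-15, `&`)
  list(linf_domain = max(diffm),
       rms_domain = sqrt(mean(diffm^2)),
       linf_tissue = max(diffm[in_tissue]),
       rms_tissue = sqrt(mean(diffm[in_tissue]^2)))
}
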