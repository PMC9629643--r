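# Shared fixtures: the reference 12-well configuration and a few cached
# solutions (all built in code; nothing is read from disk).

ref_cfg <- default_parameters(5, "middle")
ref_params <- ref_cfg$params
ref_system <- ref_cfg$system
ref_phi0 <- 160

# homogeneous column (no uptake, equal diffusivities): the inner
# eigenproblem degenerates to the outer one
homog_params <- transport_params(D_media = 2e-9, D_tissue = 2e-9,
                                 uptake_rate = 0)

cached <- new.env()
get_solution <- function(M, d = 5, placement = "middle", phi0 = 160) {
  key <- sprintf("sol_%d_%g_%s_%g", M, d, placement, phi0)
  if (is.null(cached[[key]])) {
    cfg <- default_parameters(d, placement)
    cached[[key]] <- solve_oxygen_field(cfg$params, cfg$system, phi0, M = M)
  }
  cached[[key]]
}

get_fd <- function(n = 150, d = 5, placement = "middle", phi0 = 160) {
  key <- sprintf("fd_%d_%g_%s_%g", n, d, placement, phi0)
  if (is.null(cached[[key]])) {
    cfg <- default_parameters(d, placement)
    cached[[key]] <- solve_fd(cfg$system, cfg$params, phi0, n_r = n, n_z = n)
  }
  cached[[key]]
}

# independent 1-D two-layer finite-difference oracle for the baseline
# profile: solves D(z) phi'' - V 1_tissue phi = 0 with phi'(0) = 0,
# phi(H) = phi0 on a uniform grid (central differences; the diffusivity
# enters only through interface flux continuity, handled by harmonic-mean
# face conductances)
baseline_fd_oracle <- function(params, system, phi0, n = 20001) {
  # interface-aligned grid: uniform within each material segment
  brk <- unique(c(0, system$h1, system$h2, system$H))
  segs <- lapply(seq_len(length(brk) - 1), function(i)
    seq(brk[i], brk[i + 1],
        length.out = max(200, round(n * (brk[i + 1] - brk[i]) / system$H))))
  z <- unique(unlist(segs))
  n <- length(z)
  h <- diff(z)
  zc <- (z[-n] + z[-1]) / 2
  tis <- zc > system$h1 & zc < system$h2   # material per face interval
  Dface <- ifelse(tis, params$D2, params$D1)
  # uptake integrated over the tissue part of each control volume
  upt <- params$V * (c(0, tis * h) + c(tis * h, 0)) / 2
  cond <- Dface / h                        # face conductances, length n-1
  m <- n - 1                               # unknowns: nodes 1..n-1
  sub <- cond[seq_len(m - 1)]              # coupling (i, i-1), i = 2..m
  sup <- cond[seq_len(m - 1)]              # coupling (i, i+1), i = 1..m-1
  diag_main <- -(c(0, cond[seq_len(m - 1)]) + cond[seq_len(m)]) -
    upt[seq_len(m)]
  A <- Matrix::bandSparse(m, m, k = c(-1, 0, 1),
                          diagonals = list(sub, diag_main, sup))
  rhs <- numeric(m)
  rhs[m] <- -cond[m] * phi0
  phi <- as.numeric(Matrix::solve(A, rhs))
  list(z = z, phi = c(phi, phi0))
}
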