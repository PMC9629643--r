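# Scenario analyses: placement search for target tissue extrema, depth and
# media-volume sweeps, the diameter x incubator-oxygen scenario grid, and
# the truncation-convergence report.

solve_at_h1 <- function(h1, params, system, phi0, M, thickness) {
  sys <- well_system(well_radius = system$r_o, media_depth = system$H,
                     slice_radius = system$r_T, h1 = h1,
                     h2 = h1 + thickness, well_depth = system$well_depth)
  solve_oxygen_field(params, sys, phi0, M = M)
}

# Extremum of a solution under either reporting convention: the
# through-thickness profile at the slice centre (r = 0; what the published
# placement table and its companion profiles use) or the tissue-wide field.
solution_extremum <- function(sol, target, extent, n_z = 201) {
  if (extent == "centre") {
    prof <- thickness_profile(sol, 0, n_z = n_z)$phi
    if (target == "max") max(prof) else min(prof)
  } else {
    tissue_extrema(sol)[[target]]
  }
}

#' Find the slice placement that realises a target tissue extremum
#'
#' Bisection on the slice base height \eqn{h_1}: both the tissue-wide
#' maximum and minimum oxygen concentration increase monotonically as the
#' slice is raised towards the media surface, so the placement at which an
#' extremum equals a target value (e.g. the physiological bounds 65 and
#' 35 mmHg) is found by bracketing between the well bottom and the
#' near-surface position.
#'
#' @param target \code{"max"} or \code{"min"}: which tissue extremum to
#'   drive to \code{value}.
#' @param value target oxygen partial pressure [mmHg].
#' @param params a \code{\link{transport_params}}.
#' @param system a \code{\link{well_system}} providing the well radius,
#'   media depth, slice radius and thickness (its own placement is
#'   ignored).
#' @param phi0 surface oxygen partial pressure [mmHg].
#' @param M series truncation order.
#' @param extent \code{"centre"}: extremum of the through-thickness profile
#'   at the slice centre (r = 0), the convention of the published placement
#'   table and through-thickness figures; \code{"tissue"}: extremum over
#'   the whole tissue region (for the minimum the two coincide, since the
#'   coolest point sits on the axis; the tissue-wide maximum sits at the
#'   rim edge and is substantially higher than the centre maximum).
#' @param surface_gap minimum gap between slice top and media surface [m].
#' @param tol_h bisection tolerance on \eqn{h_1} [m].
#' @param tol_phi tolerance on the achieved extremum [mmHg].
#' @return list with \code{h1}, \code{h2} [m], the achieved
#'   \code{extremum} [mmHg] and the number of solves.
#' @examples
#' \donttest{
#' cfg <- default_parameters(5)
#' find_placement_height("max", 65, cfg$params, cfg$system, phi0 = 160,
#'                       M = 7)$h1 * 1e3  # h1 in mm
#' }
#' @export
find_placement_height <- function(target = c("max", "min"), value,
                                  params, system, phi0, M = 40,
                                  extent = c("centre", "tissue"),
                                  surface_gap = 1e-6,
                                  tol_h = 1e-7, tol_phi = 0.01) {
  target <- match.arg(target)
  extent <- match.arg(extent)
  thickness <- system$h2 - system$h1
  lo <- 0
  hi <- system$H - surface_gap - thickness
  ext_at <- function(h1) {
    sol <- solve_at_h1(h1, params, system, phi0, M, thickness)
    solution_extremum(sol, target, extent)
  }
  f_lo <- ext_at(lo) - value
  f_hi <- ext_at(hi) - value
  n_solve <- 2L
  if (f_lo > 0 || f_hi < 0)
    stop(sprintf(
      "unattainable-target error: tissue %s spans [%.3f, %.3f] mmHg over placements",
      target, f_lo + value, f_hi + value))
  while (hi - lo > tol_h) {
    mid <- (lo + hi) / 2
    f_mid <- ext_at(mid) - value
    n_solve <- n_solve + 1L
    if (f_mid < 0) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  achieved <- ext_at(mid)
  n_solve <- n_solve + 1L
  if (abs(achieved - value) > tol_phi)
    warning(sprintf("achieved extremum %.4f mmHg misses target %.2f by > %.2f",
                    achieved, value, tol_phi))
  list(h1 = mid, h2 = mid + thickness, extremum = achieved,
       n_solve = n_solve)
}

#' Placement table for the physiological oxygen window
#'
#' For each slice diameter, finds the placement at which the tissue-wide
#' maximum equals the upper physiological bound and the placement at which
#' the minimum equals the lower bound (periportal-to-perivenous liver
#' gradient, 65 and 35 mmHg by default) at atmospheric surface oxygen.
#'
#' @param diameters_mm slice diameters [mm].
#' @param phi0 surface oxygen partial pressure [mmHg].
#' @param max_value,min_value target extrema [mmHg].
#' @param M series truncation order.
#' @param ... passed to \code{\link{find_placement_height}}.
#' @return data.frame with columns \code{diameter_mm}, \code{target},
#'   \code{value_mmHg}, \code{h1_mm}, \code{h2_mm}.
#' @export
placement_table <- function(diameters_mm = c(5, 8), phi0 = 160,
                            max_value = 65, min_value = 35, M = 40, ...) {
  rows <- list()
  for (d in diameters_mm) {
    cfg <- default_parameters(d)
    for (tg in c("max", "min")) {
      val <- if (tg == "max") max_value else min_value
      hit <- find_placement_height(tg, val, cfg$params, cfg$system,
                                   phi0 = phi0, M = M, ...)
      rows[[length(rows) + 1]] <- data.frame(
        diameter_mm = d, target = tg, value_mmHg = val,
        h1_mm = hit$h1 * 1e3, h2_mm = hit$h2 * 1e3)
    }
  }
  do.call(rbind, rows)
}

#' Sweep the slice placement through the well depth
#'
#' Reports the tissue-wide minimum and maximum oxygen concentration as the
#' slice descends from just below the media surface to the well bottom.
#'
#' @param params a \code{\link{transport_params}}.
#' @param system a \code{\link{well_system}} (placement ignored).
#' @param phi0 surface oxygen [mmHg].
#' @param n_steps number of placements (>= 2).
#' @param M truncation order.
#' @param extent extremum convention, as in
#'   \code{\link{find_placement_height}}.
#' @param surface_gap gap below the media surface for the top endpoint [m].
#' @return data.frame with columns \code{h1} [m], \code{tissue_min},
#'   \code{tissue_max} [mmHg], ordered from the surface downwards.
#' @export
depth_sweep <- function(params, system, phi0, n_steps = 25, M = 7,
                        extent = c("centre", "tissue"),
                        surface_gap = 1e-6) {
  stopifnot(n_steps >= 2)
  extent <- match.arg(extent)
  thickness <- system$h2 - system$h1
  h1s <- seq(system$H - surface_gap - thickness, 0, length.out = n_steps)
  rows <- lapply(h1s, function(h1) {
    sol <- solve_at_h1(h1, params, system, phi0, M, thickness)
    data.frame(h1 = h1,
               tissue_min = solution_extremum(sol, "min", extent),
               tissue_max = solution_extremum(sol, "max", extent))
  })
  do.call(rbind, rows)
}

#' Sweep the media volume with the slice held near the surface
#'
#' For each media volume the media depth is recomputed from the well
#' cross-section, the slice is re-placed with its top one micron below the
#' surface, and the tissue-wide minimum oxygen concentration is reported.
#' The curve rises while added media deepens the oxygen reservoir, then
#' falls once the added diffusion path outweighs it.
#'
#' @param params a \code{\link{transport_params}}.
#' @param system a \code{\link{well_system}} providing well radius, slice
#'   radius and thickness.
#' @param phi0 surface oxygen [mmHg].
#' @param volumes media volumes [m^3].
#' @param M truncation order.
#' @param surface_gap slice-top gap below the surface [m].
#' @return data.frame with columns \code{volume} [m^3], \code{H} [m],
#'   \code{tissue_min} [mmHg].
#' @export
volume_sweep <- function(params, system, phi0, volumes, M = 7,
                         surface_gap = 1e-6) {
  thickness <- system$h2 - system$h1
  rows <- lapply(volumes, function(v) {
    H <- media_depth_from_volume(v, system$r_o)
    if (H <= thickness + surface_gap)
      stop(sprintf(
        "invalid geometry: %.2f ml gives media depth %.3f mm, too shallow for the slice",
        v * 1e6, H * 1e3))
    sys <- well_system(well_radius = system$r_o, media_depth = H,
                       slice_radius = system$r_T,
                       h1 = H - surface_gap - thickness,
                       h2 = H - surface_gap,
                       well_depth = system$well_depth)
    ext <- tissue_extrema(solve_oxygen_field(params, sys, phi0, M = M))
    data.frame(volume = v, H = H, tissue_min = ext$min)
  })
  do.call(rbind, rows)
}

#' Run the full diameter x oxygen x placement scenario grid
#'
#' Solves the model for every combination of slice diameter, incubator
#' oxygen fraction and standard placement, and summarises the mid-plane
#' concentration span across placements for each (diameter, oxygen) pair.
#'
#' @param diameters_mm slice diameters [mm].
#' @param oxygen_fractions incubator oxygen fractions.
#' @param M truncation order.
#' @param n_r mid-plane samples per scenario.
#' @return list with \code{scenarios} (one row per combination: mid-plane
#'   centre/edge/min/max values and tissue extrema), \code{span} (mid-plane
#'   range across placements per diameter/oxygen pair) and \code{profiles}
#'   (named list of mid-plane profiles).
#' @export
run_scenario_grid <- function(diameters_mm = c(5, 8),
                              oxygen_fractions = c(0.21, 0.80, 0.95),
                              M = 7, n_r = 101) {
  rows <- list(); profiles <- list()
  for (d in diameters_mm) {
    for (f in oxygen_fractions) {
      phi0 <- surface_partial_pressure(f)
      for (pl in c("bottom", "middle", "top")) {
        cfg <- default_parameters(d, pl)
        sol <- solve_oxygen_field(cfg$params, cfg$system, phi0, M = M)
        prof <- midplane_profile(sol, n_r = n_r)
        ext <- tissue_extrema(sol)
        key <- sprintf("d%g_o%g_%s", d, f * 100, pl)
        profiles[[key]] <- prof
        rows[[key]] <- data.frame(
          diameter_mm = d, oxygen_fraction = f, placement = pl,
          phi0 = phi0,
          mid_centre = prof$phi[1], mid_edge = prof$phi[nrow(prof)],
          mid_min = min(prof$phi), mid_max = max(prof$phi),
          tissue_min = ext$min, tissue_max = ext$max)
      }
    }
  }
  scenarios <- do.call(rbind, rows)
  rownames(scenarios) <- NULL
  span <- do.call(rbind, lapply(split(
    scenarios, list(scenarios$diameter_mm, scenarios$oxygen_fraction)),
    function(sdf) data.frame(
      diameter_mm = sdf$diameter_mm[1],
      oxygen_fraction = sdf$oxygen_fraction[1],
      mid_low = min(sdf$mid_min), mid_high = max(sdf$mid_max))))
  rownames(span) <- NULL
  list(scenarios = scenarios, span = span, profiles = profiles)
}

#' Truncation-convergence report
#'
#' Solves the same scenario at a sequence of truncation orders and reports
#' the largest change of the tissue-region field between successive orders,
#' as a fraction of \eqn{\phi_0}.
#'
#' @param params a \code{\link{transport_params}}.
#' @param system a \code{\link{well_system}}.
#' @param phi0 surface oxygen [mmHg].
#' @param M_values truncation orders, ascending.
#' @param n_r,n_z tissue evaluation grid.
#' @return data.frame with columns \code{M} and \code{linf_change}
#'   (fraction of \eqn{\phi_0}; \code{NA} for the first order).
#' @export
truncation_convergence <- function(params, system, phi0,
                                   M_values = c(5, 7, 10, 20, 40),
                                   n_r = 80, n_z = 20) {
  r <- seq(0, system$r_T, length.out = n_r)
  z <- seq(system$h1, system$h2, length.out = n_z)
  prev <- NULL
  out <- data.frame(M = M_values, linf_change = NA_real_)
  for (i in seq_along(M_values)) {
    sol <- solve_oxygen_field(params, system, phi0, M = M_values[i])
    fld <- field_grid(sol, r, z)
    if (!is.null(prev)) out$linf_change[i] <- max(abs(fld - prev)) / phi0
    prev <- fld
  }
  out
}
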