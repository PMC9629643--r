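#' Transport parameters for oxygen in media and tissue
#'
#' Bundles the molecular diffusivity of oxygen in the culture media and in
#' the liver tissue with the first-order volumetric uptake rate, and derives
#' the absorption wavenumber \eqn{k = \sqrt{V/D_2}} that separates trapped
#' (hyperbolic-in-tissue) from free (oscillatory) vertical modes.
#'
#' @param D_media diffusivity of oxygen in the media \eqn{D_1} [m^2/s].
#' @param D_tissue diffusivity of oxygen in the tissue \eqn{D_2} [m^2/s].
#' @param uptake_rate first-order oxygen uptake rate \eqn{V} [1/s].
#' @return An object of class \code{"transport_params"}: a list with elements
#'   \code{D1}, \code{D2}, \code{V} and \code{k} [1/m].
#' @examples
#' tp <- transport_params()
#' tp$k  # about 5970 per metre for the default liver parameters
#' @export
transport_params <- function(D_media = 4.85e-9, D_tissue = 1.6e-9,
                             uptake_rate = 0.057) {
  if (!is.numeric(D_media) || D_media <= 0)
    stop("'D_media' must be a positive diffusivity [m^2/s]")
  if (!is.numeric(D_tissue) || D_tissue <= 0)
    stop("'D_tissue' must be a positive diffusivity [m^2/s]")
  if (!is.numeric(uptake_rate) || uptake_rate < 0)
    stop("'uptake_rate' must be a non-negative rate [1/s]")
  structure(list(D1 = D_media, D2 = D_tissue, V = uptake_rate,
                 k = sqrt(uptake_rate / D_tissue)),
            class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat("Oxygen transport parameters\n")
  cat(sprintf("  D1 (media)  : %.3e m^2/s\n", x$D1))
  cat(sprintf("  D2 (tissue) : %.3e m^2/s\n", x$D2))
  cat(sprintf("  V  (uptake) : %.3e 1/s\n", x$V))
  cat(sprintf("  k = sqrt(V/D2) : %.4f 1/m\n", x$k))
  invisible(x)
}

#' Well and slice geometry
#'
#' Describes one cylindrical well holding media of depth \code{H} with a
#' disc-shaped tissue slice of radius \code{slice_radius} occupying heights
#' \code{h1 < z < h2}, measured upward from the well bottom. All lengths are
#' in metres (SI internally; use the \code{*_mm} helpers of the reporting
#' layer for display).
#'
#' @param well_radius well radius \eqn{r_o} [m].
#' @param media_depth media depth \eqn{H} [m]; if \code{NULL}, derived from
#'   \code{media_volume} via \code{\link{media_depth_from_volume}}.
#' @param media_volume media volume [m^3] (only used when \code{media_depth}
#'   is \code{NULL}).
#' @param slice_radius tissue radius \eqn{r_T} [m], must be below
#'   \code{well_radius}.
#' @param h1,h2 bottom and top of the slice [m], \eqn{0 \le h_1 < h_2 < H}.
#' @param well_depth physical depth of the well [m]; media may not exceed it.
#' @return An object of class \code{"well_system"}.
#' @export
well_system <- function(well_radius, media_depth = NULL, media_volume = NULL,
                        slice_radius, h1, h2, well_depth = Inf) {
  if (is.null(media_depth)) {
    if (is.null(media_volume))
      stop("supply either 'media_depth' or 'media_volume'")
    media_depth <- media_depth_from_volume(media_volume, well_radius)
  }
  sys <- structure(list(r_o = well_radius, H = media_depth,
                        r_T = slice_radius, h1 = h1, h2 = h2,
                        well_depth = well_depth,
                        media_volume = media_volume),
                   class = "well_system")
  validate_well_system(sys)
  sys
}

validate_well_system <- function(sys) {
  with(sys, {
    if (!(r_T > 0 && r_T < r_o))
      stop("invalid geometry: need 0 < slice_radius < well_radius")
    if (!(h1 >= 0 && h1 < h2 && h2 < H))
      stop("invalid geometry: need 0 <= h1 < h2 < H (slice submerged)")
    if (H > well_depth)
      stop("invalid geometry: media depth exceeds well depth")
  })
  invisible(sys)
}

#' @export
print.well_system <- function(x, ...) {
  cat("Well/slice geometry (mm)\n")
  cat(sprintf("  well radius r_o : %.3f\n", x$r_o * 1e3))
  cat(sprintf("  media depth H   : %.4f\n", x$H * 1e3))
  cat(sprintf("  slice radius r_T: %.3f\n", x$r_T * 1e3))
  cat(sprintf("  slice span      : h1 = %.4f, h2 = %.4f (thickness %.0f um)\n",
              x$h1 * 1e3, x$h2 * 1e3, (x$h2 - x$h1) * 1e6))
  invisible(x)
}

#' Media depth from pipetted volume
#'
#' The media fills the cylindrical well, so its depth is the volume divided
#' by the well cross-section: \eqn{H = V_{media} / (\pi r_o^2)}. 1.3 ml in a
#' 22.1 mm diameter well gives roughly 3.4 mm of media.
#'
#' @param media_volume media volume [m^3] (1 ml = 1e-6 m^3).
#' @param well_radius well radius [m].
#' @return media depth [m].
#' @examples
#' media_depth_from_volume(1.3e-6, 11.05e-3) * 1e3  # ~3.39 mm
#' @export
media_depth_from_volume <- function(media_volume, well_radius) {
  if (!is.numeric(well_radius) || well_radius <= 0)
    stop("invalid geometry: well_radius must be positive")
  if (!is.numeric(media_volume) || any(media_volume < 0))
    stop("media_volume must be non-negative")
  media_volume / (pi * well_radius^2)
}

#' Surface oxygen partial pressure from incubator oxygen fraction
#'
#' The oxygen level at the media/air interface is taken as a partial
#' pressure, scaled linearly from the atmospheric reference: 21 percent
#' oxygen corresponds to 160 mmHg, so \eqn{\phi_0 = 160 f / 0.21}.
#'
#' @param oxygen_fraction incubator oxygen fraction in [0, 1]
#'   (0.21 = atmospheric).
#' @return surface partial pressure \eqn{\phi_0} [mmHg].
#' @examples
#' surface_partial_pressure(0.21)  # 160
#' surface_partial_pressure(0.95)  # elevated-incubator setting
#' @export
surface_partial_pressure <- function(oxygen_fraction) {
  if (!is.numeric(oxygen_fraction) ||
      any(oxygen_fraction < 0 | oxygen_fraction > 1))
    stop("oxygen_fraction must lie in [0, 1]")
  160 * oxygen_fraction / 0.21
}

#' Standard slice placements within the well
#'
#' The three placements used throughout the scenario analyses: resting on
#' the well bottom, centred at mid-depth, and with the slice top one micron
#' below the media surface.
#'
#' @param H media depth [m].
#' @param thickness slice thickness [m].
#' @param surface_gap gap between the slice top and the media surface for
#'   the "top" placement [m]; default one micron.
#' @return a data.frame with columns \code{placement}, \code{h1}, \code{h2}
#'   (metres).
#' @examples
#' standard_placements(3.4e-3, 2.5e-4)
#' @export
standard_placements <- function(H, thickness, surface_gap = 1e-6) {
  if (!(thickness > 0 && thickness + surface_gap < H))
    stop("invalid geometry: slice thickness must fit below the media surface")
  data.frame(
    placement = c("bottom", "middle", "top"),
    h1 = c(0, (H - thickness) / 2, H - surface_gap - thickness),
    h2 = c(thickness, (H + thickness) / 2, H - surface_gap),
    stringsAsFactors = FALSE
  )
}

#' Default well, slice and transport parameters
#'
#' The reference 12-well-plate configuration: 22.1 mm well diameter, 3.4 mm
#' media depth (1.3 ml), 250 um slice of 5 or 8 mm diameter, liver transport
#' parameters D1 = 4.85e-9 m^2/s (media), D2 = 1.6e-9 m^2/s (tissue),
#' V = 0.057 1/s.
#'
#' @param slice_diameter_mm slice diameter, 5 or 8 mm (any positive value
#'   below the well diameter is accepted).
#' @param placement one of "bottom", "middle", "top", or a numeric \code{h1}
#'   in metres.
#' @param media_depth media depth [m]; the reference value is 3.4 mm exactly
#'   (pass \code{media_depth_from_volume(1.3e-6, 11.05e-3)} to use the
#'   volume-derived depth instead).
#' @param thickness slice thickness [m].
#' @return list with elements \code{system} (a \code{\link{well_system}})
#'   and \code{params} (a \code{\link{transport_params}}).
#' @examples
#' cfg <- default_parameters(5, "middle")
#' cfg$system
#' @export
default_parameters <- function(slice_diameter_mm = 5, placement = "middle",
                               media_depth = 3.4e-3, thickness = 2.5e-4) {
  r_T <- slice_diameter_mm / 2 * 1e-3
  if (is.character(placement)) {
    pl <- standard_placements(media_depth, thickness)
    row <- pl[pl$placement == placement, ]
    if (nrow(row) != 1L)
      stop("placement must be 'bottom', 'middle', 'top' or a numeric h1 [m]")
    h1 <- row$h1; h2 <- row$h2
  } else {
    h1 <- placement; h2 <- placement + thickness
  }
  list(
    system = well_system(well_radius = 11.05e-3, media_depth = media_depth,
                         slice_radius = r_T, h1 = h1, h2 = h2,
                         well_depth = 17.5e-3),
    params = transport_params()
  )
}
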