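#' Electrode-array geometry
#'
#' The package works on an 8x8 microelectrode grid with 400 um pitch.
#' Sites are addressed by `(x, y)` with `x` the column (1..8, left to
#' right) and `y` the row (1..8, counted from the top, the orientation in
#' which array maps are displayed). Azimuths are measured counterclockwise
#' on screen from the +x axis, so 45 degrees points from the bottom-left
#' corner towards the top-right corner. Spatial maps are stored as 8x8
#' matrices indexed `[y, x]`.
#'
#' @param n Grid side length (default 8).
#' @return `grid_sites()` returns a tibble with one row per site and
#'   integer columns `x`, `y`.
#' @examples
#' grid_sites()
#' @export
grid_sites <- function(n = 8L) {
  # column-major (y fastest), matching R's flattening of [y, x] matrices
  tidyr::expand_grid(x = seq_len(n), y = seq_len(n))
}

# site coordinate matrices (8x8, [y, x]: rows are y, columns are x)
site_x <- function(n = 8L) matrix(rep(seq_len(n), each = n), n, n)
site_y <- function(n = 8L) matrix(rep(seq_len(n), times = n), n, n)

#' Planar phase-input / Euclidean distance map
#'
#' Projects the grid coordinates onto a direction unit vector, giving a
#' zero-centred map that increases linearly along `direction` (in grid
#' units). This is both the phase input for simulated planar waves and
#' the full-array Euclidean distance map used for planar wave detection.
#'
#' @param direction Azimuth in radians (counterclockwise on screen; 0 points
#'   rightward, `pi/2` points from the bottom towards the top of the array).
#' @param n Grid side length.
#' @return An `n` x `n` matrix in grid units, zero-centred.
#' @examples
#' planar_phase_input(0)       # increases left to right
#' planar_phase_input(pi / 4)  # increases bottom-left to top-right
#' @export
planar_phase_input <- function(direction, n = 8L) {
  # y is counted from the top, so screen-up is -y
  p <- site_x(n) * cos(direction) - site_y(n) * sin(direction)
  p - mean(p)
}

#' @rdname planar_phase_input
#' @export
distance_map <- function(direction, n = 8L) planar_phase_input(direction, n)

#' Rotating phase-input map
#'
#' Phase input for simulated rotating waves: the polar angle of each site
#' about a rotation centre (which may lie off the array), signed by
#' chirality (counterclockwise positive, on screen), and scaled by the
#' distance `r0` from the centre to the array centroid. The scaling keeps
#' the simulation wavenumber `k` interpretable as radians per grid unit
#' *at the array* for rotating templates, just as for planar ones; the
#' local wavelength then grows with distance from the rotation centre.
#'
#' @param center Length-2 numeric, `(x, y)` of the rotation centre; may be
#'   off-grid (e.g. `c(-1.5, -1.5)` is beyond the top-left corner).
#' @param chirality `"ccw"` or `"cw"` (sense of rotation on screen).
#' @param scale `"arc"` (default) multiplies the angle by `r0` so that the
#'   map is in grid units at the array; `"angle"` returns the raw angle in
#'   radians.
#' @param n Grid side length.
#' @return An `n` x `n` matrix. If the centre falls exactly on a grid node
#'   the angle there is undefined; that entry is `NA` and flagged via the
#'   `"singular"` attribute.
#' @examples
#' rotating_phase_input(c(4.5, 4.5))
#' @export
rotating_phase_input <- function(center, chirality = c("ccw", "cw"),
                                 scale = c("arc", "angle"), n = 8L) {
  chirality <- match.arg(chirality)
  scale <- match.arg(scale)
  dx <- site_x(n) - center[1]
  dyu <- -(site_y(n) - center[2])  # screen-up component
  th <- atan2(dyu, dx)
  if (chirality == "cw") th <- -th
  sing <- dx == 0 & dyu == 0
  th[sing] <- NA_real_
  if (scale == "arc") {
    r0 <- max(1, sqrt(sum((center - c((n + 1) / 2, (n + 1) / 2))^2)))
    th <- th * r0
  }
  structure(th, singular = any(sing))
}

#' Rotation-map template for circular-circular correlation
#'
#' The rotation map assigns every site the polar angle about an origin
#' point, counterclockwise on screen. It is the template correlated
#' against observed phase maps; its `net direction` (the resultant of the
#' circular-adjusted gradients) determines which wave directions yield
#' positive versus negative correlations, and the orthogonal
#' `bisecting axis` separates the two half-planes.
#'
#' @param origin Length-2 numeric `(x, y)`; conventionally a grid point
#'   such as `c(4, 4)`.
#' @inheritParams rotating_phase_input
#' @return An `n` x `n` matrix of angles in radians, class `rotation_map`,
#'   with attributes `origin` and `singular` (TRUE if the origin sits on a
#'   grid node, whose angle is `NA` and excluded from correlations).
#' @examples
#' rotation_map(c(4, 4))
#' net_direction(rotation_map(c(4, 4)))
#' @export
rotation_map <- function(origin, n = 8L) {
  th <- rotating_phase_input(origin, "ccw", scale = "angle", n = n)
  structure(th, origin = origin, class = "rotation_map")
}

#' @export
print.rotation_map <- function(x, ...) {
  o <- attr(x, "origin")
  cat(sprintf("<rotation_map> origin (%g, %g)%s\n", o[1], o[2],
              if (isTRUE(attr(x, "singular"))) ", singular node excluded" else ""))
  nd <- net_direction(x)
  cat(sprintf("  net direction %.1f deg, bisecting axis %.1f deg\n",
              nd$azimuth * 180 / pi, nd$bisecting_axis * 180 / pi))
  invisible(x)
}

#' Net direction and bisecting axis of a rotation map
#'
#' The net direction summarizes a rotation map's overall gradient: planar
#' waves travelling towards it correlate positively with the map, waves
#' away from it negatively, and waves along the orthogonal bisecting axis
#' fall in the chance zone. It is computed operationally as the resultant
#' of the map's correlation profile over planar probe waves: each probe
#' azimuth is weighted by its circular correlation with the map and the
#' weighted unit vectors are summed; the argument of the resultant is the
#' net direction. This makes the sign convention self-consistent with
#' [circ_corr()] by construction.
#'
#' @param map A `rotation_map` (or any 8x8 circular-valued matrix).
#' @param probe_k Wavenumber of the planar probe waves (default 0.2, a
#'   long wavelength).
#' @return A list with `azimuth` (radians, ccw on screen) and
#'   `bisecting_axis` (azimuth + pi/2, wrapped).
#' @export
net_direction <- function(map, probe_k = 0.2) {
  dirs <- seq(0, 2 * pi, length.out = 241)[-241]
  probes <- vapply(dirs, function(d) {
    as.numeric(wrap_angle(probe_k * planar_phase_input(d, nrow(map))))
  }, numeric(length(map)))
  rho <- rho_series_matrix(probes, as.numeric(map))
  az <- Arg(sum(rho * exp(1i * dirs)))
  list(azimuth = az, bisecting_axis = wrap_angle(az + pi / 2))
}

#' Canonical fingerprint origins
#'
#' The three rotation-map origins whose coefficients jointly fingerprint a
#' wave instant: the near-centre point `(4,4)` (net direction along the
#' bottom-left to top-right diagonal), the mid-left point `(1,4)` (net
#' direction vertical), and the mid-top point `(4,1)` (net direction
#' horizontal). An alternative triple can be supplied to any function that
#' accepts `origins`.
#'
#' @return A named list of length-2 numeric origins
#'   (`rho_44`, `rho_14`, `rho_41`).
#' @export
fingerprint_origins <- function() {
  list(rho_44 = c(4, 4), rho_14 = c(1, 4), rho_41 = c(4, 1))
}

# ---- quadrant machinery -----------------------------------------------------

# 4x4 quadrant membership, named by screen position
quadrant_masks <- function(n = 8L) {
  h <- n / 2
  x <- site_x(n); y <- site_y(n)
  list(
    TL = x <= h & y <= h, TR = x > h & y <= h,
    BL = x <= h & y > h, BR = x > h & y > h
  )
}

quadrant_centers <- function(n = 8L) {
  cx <- c(TL = 2.5, TR = 6.5, BL = 2.5, BR = 6.5)
  cy <- c(TL = 2.5, TR = 2.5, BL = 6.5, BR = 6.5)
  list(x = cx, y = cy)
}

#' Quadrant direction templates
#'
#' The 8x8 grid is split into four 4x4 quadrants (TL, TR, BL, BR by screen
#' position). Every ordered pair of distinct quadrants defines one of 12
#' wave directions; for each pair the source and destination quadrants get
#' Euclidean distance maps along the travel direction, oriented so that
#' each map increases towards that quadrant's outer edge. A wave passing
#' from the source to the destination quadrant then correlates negatively
#' with the source map and positively with the destination map.
#'
#' @return A tibble with one row per direction label: `label`
#'   (e.g. `"BL>TR"`), `src`, `dst`, `azimuth` (radians), and list-columns
#'   `src_map`, `dst_map` holding the 4x4-supported distance maps (8x8
#'   matrices, `NA` outside the quadrant).
#' @examples
#' quadrant_templates()$label
#' @export
quadrant_templates <- function() {
  n <- 8L
  masks <- quadrant_masks(n)
  qc <- quadrant_centers(n)
  pairs <- expand.grid(src = names(masks), dst = names(masks),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$src != pairs$dst, ]
  az <- atan2(-(qc$y[pairs$dst] - qc$y[pairs$src]),
              qc$x[pairs$dst] - qc$x[pairs$src])
  quad_map <- function(quad, direction) {
    # distance along `direction` restricted to one quadrant, increasing
    # towards the quadrant's outer edge in that direction
    m <- planar_phase_input(direction, n)
    m[!masks[[quad]]] <- NA_real_
    m - mean(m, na.rm = TRUE)
  }
  tibble(
    label = paste0(pairs$src, ">", pairs$dst),
    src = pairs$src, dst = pairs$dst, azimuth = as.numeric(az),
    # source map increases opposite to travel (towards the entering edge)
    src_map = purrr::map2(pairs$src, az, ~quad_map(.x, .y + pi)),
    dst_map = purrr::map2(pairs$dst, az, ~quad_map(.x, .y))
  )
}
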