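# run code under a local RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Wave template
#'
#' Parameters of one simulated wave: \eqn{g(t,\varphi) = A e^{i(w t - k \varphi)}
#' + \sigma \gamma(t)}, where \eqn{\varphi} is the spatial phase-input map
#' (a planar projection or a scaled rotation angle), `w` the temporal
#' angular frequency, `k` the spatial wavenumber (reciprocal wavelength,
#' radians per grid unit at the array) and \eqn{\gamma} i.i.d. standard
#' complex Gaussian noise per site and sample.
#'
#' @param kind `"planar"` or `"rotating"`.
#' @param direction Planar waves: azimuth of travel in radians (ccw on
#'   screen; `pi/4` is bottom-left to top-right).
#' @param center Rotating waves: rotation centre `(x, y)`, possibly
#'   off-grid.
#' @param chirality Rotating waves: `"ccw"` or `"cw"` (on screen).
#' @param A Amplitude (arbitrary units; the phase-based analyses are
#'   amplitude-invariant).
#' @param w Temporal angular frequency, rad/s (default `2*pi*10`).
#' @param k Spatial wavenumber, rad per grid unit (wavelength `2*pi/k`
#'   grid units). Default 0.62, the package's long-wavelength reference
#'   (about 10 grid units, 1.3 array widths), calibrated so the diagonal
#'   planar worked example reproduces its printed coefficients.
#' @param sigma Noise standard deviation, same units as `A`
#'   (default `0.25 * A`).
#' @param scale Rotating waves: `"arc"` (default) scales the angle map by
#'   the centre-to-array distance so `k` keeps its radians-per-grid-unit
#'   meaning at the array; `"angle"` uses the raw polar angle, making `k`
#'   a winding rate per radian of azimuth (the reference library uses
#'   this form).
#' @return An object of class `wave_template`.
#' @examples
#' wave_template("planar", direction = pi / 4)
#' wave_template("rotating", center = c(-1.5, -1.5))
#' @export
wave_template <- function(kind = c("planar", "rotating"), direction = pi / 4,
                          center = c(4.5, 4.5), chirality = c("ccw", "cw"),
                          A = 1, w = 2 * pi * 10, k = 0.62, sigma = 0.25 * A,
                          scale = c("arc", "angle")) {
  kind <- match.arg(kind)
  chirality <- match.arg(chirality)
  scale <- match.arg(scale)
  if (A <= 0) abort("amplitude A must be positive", class = "wavemap_invalid")
  if (sigma < 0) abort("sigma must be non-negative", class = "wavemap_invalid")
  structure(
    list(kind = kind, direction = wrap_angle(direction) %% (2 * pi),
         center = center, chirality = chirality, scale = scale,
         A = A, w = w, k = k, sigma = sigma),
    class = "wave_template"
  )
}

#' @export
print.wave_template <- function(x, ...) {
  if (x$kind == "planar") {
    cat(sprintf("<wave_template> planar, azimuth %.1f deg, k=%.3g, A=%g, sigma=%g\n",
                x$direction * 180 / pi, x$k, x$A, x$sigma))
  } else {
    cat(sprintf("<wave_template> rotating (%s) about (%.2f, %.2f), k=%.3g, A=%g, sigma=%g\n",
                x$chirality, x$center[1], x$center[2], x$k, x$A, x$sigma))
  }
  invisible(x)
}

#' Spatial phase input of a template
#'
#' @param template A [wave_template()].
#' @return 8x8 matrix: the planar projection map or the scaled rotation
#'   angle map (see [planar_phase_input()], [rotating_phase_input()]).
#' @export
phase_input <- function(template) {
  stopifnot(inherits(template, "wave_template"))
  if (template$kind == "planar") planar_phase_input(template$direction)
  else rotating_phase_input(template$center, template$chirality,
                            scale = template$scale)
}

#' Simulate a wave movie
#'
#' Evaluates \eqn{g(t,\varphi) = A e^{i(w t - k\varphi)} + \sigma\gamma(t)}
#' on the 8x8 grid. The noise-free movie has instantaneous (analytic)
#' phase \eqn{w t - k\varphi_{ab}} at site `ab`; [wave_phase_maps()]
#' converts the movie into pipeline-convention phase maps.
#'
#' @param template A [wave_template()].
#' @param duration Seconds; must cover at least two temporal cycles.
#' @param fs Sampling rate, Hz.
#' @param seed Optional integer; same seed, same movie.
#' @return A `wave_movie`: list with the complex `g` array (8 x 8 x
#'   samples), real `voltage = Re(g)`, `fs`, and the template.
#' @export
simulate_wave <- function(template, duration, fs = 1000, seed = NULL) {
  stopifnot(inherits(template, "wave_template"))
  if (duration <= 0 || fs <= 0)
    abort("duration and fs must be positive", class = "wavemap_invalid")
  if (duration < 2 * (2 * pi / abs(template$w)))
    abort("duration must cover at least two temporal cycles",
          class = "wavemap_insufficient")
  phi <- phase_input(template)
  nt <- max(2L, round(duration * fs))
  tt <- (seq_len(nt) - 1) / fs
  ph <- outer(as.numeric(-template$k * phi), template$w * tt, `+`)  # 64 x nt
  g <- template$A * exp(1i * ph)
  if (template$sigma > 0) {
    g <- g + with_seed(seed, {
      template$sigma * (matrix(rnorm(64 * nt), 64) +
                        1i * matrix(rnorm(64 * nt), 64)) / sqrt(2)
    })
  }
  dim(g) <- c(8, 8, nt)
  structure(list(g = g, voltage = Re(g), fs = fs, template = template),
            class = "wave_movie")
}

#' Phase maps of a simulated movie
#'
#' Returns the movie's instantaneous phase in the pipeline convention
#' (0 = oscillation peak, positive = approaching peak, i.e. the negated
#' analytic-signal argument), matching what [phase_maps()] extracts from
#' voltage data. Under this convention phase increases along the direction
#' of travel.
#'
#' @param movie A `wave_movie` from [simulate_wave()].
#' @return A [phase_map_series].
#' @export
wave_phase_maps <- function(movie) {
  stopifnot(inherits(movie, "wave_movie"))
  new_phase_map_series(phase = -Arg(movie$g), amplitude = Mod(movie$g),
                       fs = movie$fs)
}

#' Noise-averaged fingerprint of a template
#'
#' Simulates `n_reps` independent noise realizations of the template's
#' phase map at a single instant and averages the three-point fingerprint,
#' as used to build the reference library.
#'
#' @param template A [wave_template()].
#' @param n_reps Number of noise realizations (default 20).
#' @param origins Rotation-map origins (default [fingerprint_origins()]).
#' @param seed Optional integer seed.
#' @return One-row tibble of averaged coefficients.
#' @export
template_fingerprint <- function(template, n_reps = 20,
                                 origins = fingerprint_origins(), seed = NULL) {
  stopifnot(inherits(template, "wave_template"))
  phi <- as.numeric(phase_input(template))
  base <- template$A * exp(1i * (-template$k * phi))
  thetas <- purrr::map(origins, ~as.numeric(rotation_map(.x)))
  vals <- with_seed(seed, {
    reps <- purrr::map(seq_len(max(1L, n_reps)), function(r) {
      g <- base
      if (template$sigma > 0) {
        g <- g + template$sigma * (rnorm(64) + 1i * rnorm(64)) / sqrt(2)
      }
      p <- -Arg(g)
      purrr::map_dbl(thetas, ~circ_corr(p, .x))
    })
    purrr::reduce(reps, `+`) / length(reps)
  })
  as_tibble(as.list(vals))
}

# default rotation-centre placements for the reference library: the array
# centre, two placements towards the top-left corner, and the two
# horizontal mid-edges. All on-array: with raw-angle phase inputs the
# noisy fingerprints of these placements keep at least one coefficient
# above the chance threshold across the whole wavenumber range and decay
# as k falls towards 0.1 (structure fading away from the rotation core),
# which centres at or beyond the array corner do not.
library_centers <- function() {
  list(center = c(4.5, 4.5), near = c(3.5, 3.5), corner_side = c(2.5, 2.5),
       left_edge = c(2.5, 4.5), right_edge = c(5.5, 4.5))
}

#' Build the simulated reference library
#'
#' Generates the library of wave types against which observed fingerprints
#' are classified: 32 planar waves spanning all directions 11.25 degrees
#' apart at a long wavelength, and 40 rotating waves (5 rotation-centre
#' placements, from the array centre to 6 grid units beyond the top-left
#' corner, crossed with 8 wavenumbers evenly spaced in `[0.1, 0.9]`). Each
#' entry's three-point fingerprint is averaged over `n_noise_reps` noise
#' realizations. Rotating entries use raw-angle phase inputs (`scale =
#' "angle"`), so their spatial structure genuinely fades as `k` falls
#' towards 0.1. Construction fails if any entry's largest absolute
#' coefficient does not exceed the chance threshold (0.3), the guarantee
#' that every library member retains detectable wave structure.
#'
#' @param sigma Noise standard deviation relative to unit amplitude
#'   (default 0.25).
#' @param n_noise_reps Realizations averaged per entry (default 20).
#' @param planar_k Wavenumber of the planar entries (default 0.62, the
#'   package's long-wavelength reference).
#' @param centers Named list of rotation centres (default
#'   `library_centers()`).
#' @param w Temporal angular frequency passed to the templates (does not
#'   affect static fingerprints).
#' @param seed Integer seed; same seed, same fingerprints.
#' @return A `reference_library`: tibble with `template_id`, `kind`,
#'   `direction_deg`, `k`, `center_x`, `center_y`, `chirality`,
#'   `wavelength_class` (`"short"` if `k >= 0.5` else `"long"`), and the
#'   fingerprint columns `rho_44`, `rho_14`, `rho_41`; attributes record
#'   `sigma`, `n_noise_reps` and `seed`. The `templates` attribute holds
#'   the [wave_template()] objects.
#' @examples
#' \donttest{
#' lib <- build_reference_library(seed = 1)
#' glance(lib)
#' }
#' @export
build_reference_library <- function(sigma = 0.25, n_noise_reps = 20,
                                    planar_k = 0.62,
                                    centers = library_centers(),
                                    w = 2 * pi * 10, seed = 1) {
  dirs <- seq(0, 2 * pi, length.out = 33)[-33]
  planar <- purrr::map(dirs, ~wave_template("planar", direction = .x,
                                            k = planar_k, w = w, sigma = sigma))
  ks <- seq(0.1, 0.9, length.out = 8)
  rot_grid <- tidyr::expand_grid(center = names(centers), k = ks)
  rotating <- purrr::map2(rot_grid$center, rot_grid$k, function(cn, k) {
    wave_template("rotating", center = centers[[cn]], chirality = "ccw",
                  k = k, w = w, sigma = sigma, scale = "angle")
  })
  templates <- c(planar, rotating)

  centroid <- c(4.5, 4.5)
  direction_of <- function(tpl) {
    if (tpl$kind == "planar") return(tpl$direction * 180 / pi)
    v <- centroid - tpl$center
    if (all(abs(v) < 1e-9)) return(NA_real_)
    # net travel at the array is tangential: the centre->array ray rotated
    # +90 deg for ccw rotation (screen frame)
    az <- atan2(-v[2], v[1]) + if (tpl$chirality == "ccw") pi / 2 else -pi / 2
    (wrap_angle(az) %% (2 * pi)) * 180 / pi
  }

  fps <- with_seed(seed, {
    purrr::map(templates, template_fingerprint, n_reps = n_noise_reps)
  })
  fp <- dplyr::bind_rows(fps)

  lib <- dplyr::bind_cols(
    tibble(
      template_id = seq_along(templates),
      kind = purrr::map_chr(templates, "kind"),
      direction_deg = purrr::map_dbl(templates, direction_of),
      k = purrr::map_dbl(templates, "k"),
      center_x = purrr::map_dbl(templates, ~if (.x$kind == "rotating") .x$center[1] else NA_real_),
      center_y = purrr::map_dbl(templates, ~if (.x$kind == "rotating") .x$center[2] else NA_real_),
      chirality = purrr::map_chr(templates, ~if (.x$kind == "rotating") .x$chirality else NA_character_),
      wavelength_class = ifelse(purrr::map_dbl(templates, "k") >= 0.5, "short", "long")
    ),
    fp
  )

  worst <- min(pmax(abs(lib$rho_44), abs(lib$rho_14), abs(lib$rho_41)))
  if (worst <= 0.3) {
    abort(sprintf(paste0("degenerate reference library: an entry has ",
                         "max |coefficient| = %.3f <= 0.3"), worst),
          class = "wavemap_library_degeneracy")
  }

  structure(lib, class = c("reference_library", class(lib)),
            sigma = sigma, n_noise_reps = n_noise_reps, seed = seed,
            planar_k = planar_k, templates = templates)
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("<reference_library> %d planar + %d rotating entries (sigma=%g, %d noise reps, seed=%s)\n",
              sum(x$kind == "planar"), sum(x$kind == "rotating"),
              attr(x, "sigma"), attr(x, "n_noise_reps"), attr(x, "seed")))
  NextMethod()
}

#' Serialize a reference library to JSON
#'
#' @param lib A `reference_library`.
#' @param path Output file.
#' @return `path`, invisibly. `read_reference_library()` restores the
#'   tibble together with its generation parameters.
#' @export
write_reference_library <- function(lib, path) {
  stopifnot(inherits(lib, "reference_library"))
  payload <- list(
    sigma = attr(lib, "sigma"), n_noise_reps = attr(lib, "n_noise_reps"),
    seed = attr(lib, "seed"), planar_k = attr(lib, "planar_k"),
    entries = as.data.frame(lib)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_reference_library
#' @export
read_reference_library <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lib <- as_tibble(payload$entries)
  structure(lib, class = c("reference_library", class(lib)),
            sigma = payload$sigma, n_noise_reps = payload$n_noise_reps,
            seed = payload$seed, planar_k = payload$planar_k)
}

#' @exportS3Method generics::tidy
tidy.reference_library <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.reference_library <- function(x, ...) {
  tibble(
    n_entries = nrow(x),
    n_planar = sum(x$kind == "planar"),
    n_rotating = sum(x$kind == "rotating"),
    min_max_coef = min(pmax(abs(x$rho_44), abs(x$rho_14), abs(x$rho_41))),
    sigma = attr(x, "sigma"),
    n_noise_reps = attr(x, "n_noise_reps")
  )
}
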