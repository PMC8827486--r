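#' Circular-circular correlation coefficient
#'
#' Fisher-Lee correlation between two circular-valued maps: both maps are
#' centred on their circular mean, sine-transformed, and correlated:
#' \deqn{\rho_c = \frac{\sum_{ab} \sin(\phi_{ab}-\phi_m)\sin(\theta_{ab}-\theta_m)}
#'   {\sqrt{\sum_{ab}\sin^2(\phi_{ab}-\phi_m)\,\sum_{ab}\sin^2(\theta_{ab}-\theta_m)}}}
#' with \eqn{\phi_m = \mathrm{Arg}(\sum_{ab} e^{i\phi_{ab}})}. The
#' coefficient is bounded in \eqn{[-1, 1]}, invariant under adding a
#' constant angle to either map, and flips sign when one map is negated
#' about its mean.
#'
#' Applied to an instantaneous phase map and a [rotation_map()], a value
#' above the chance threshold (0.3, from the 99th percentile of the
#' spatial-shuffling null; see [shuffle_threshold()]) indicates a wave
#' moving towards the map's net direction; values below -0.3 indicate the
#' opposite direction.
#'
#' @param phi,theta Numeric vectors or matrices of angles in radians,
#'   same site set. `NA` entries (e.g. a rotation map's singular node)
#'   are dropped pairwise.
#' @return The correlation, a single number in `[-1, 1]`.
#' @examples
#' th <- rotation_map(c(4, 4))
#' circ_corr(th, th)  # 1
#' @export
circ_corr <- function(phi, theta) {
  ok <- !is.na(phi) & !is.na(theta)
  if (sum(ok) < 3) abort("need at least 3 paired sites", class = "wavemap_degenerate")
  p <- as.numeric(phi)[ok]
  t <- as.numeric(theta)[ok]
  s1 <- sin(wrap_angle(p - circ_mean(p)))
  s2 <- sin(wrap_angle(t - circ_mean(t)))
  d1 <- sum(s1^2); d2 <- sum(s2^2)
  if (d1 <= .Machine$double.eps || d2 <= .Machine$double.eps) {
    abort("zero circular variance: correlation undefined",
          class = "wavemap_degenerate")
  }
  sum(s1 * s2) / sqrt(d1 * d2)
}

# rho_c of every column of a site x time phase matrix against one template.
# Returns NA where the phase map has (numerically) zero circular variance.
rho_series_matrix <- function(P, theta) {
  ok <- !is.na(theta)
  th <- theta[ok]
  s2 <- sin(wrap_angle(th - circ_mean(th)))
  d2 <- sum(s2^2)
  P <- P[ok, , drop = FALSE]
  pm <- Arg(colSums(exp(1i * P)))
  S <- sin(wrap_angle(P - rep(pm, each = nrow(P))))
  d1 <- .colSums(S^2, nrow(S), ncol(S))
  num <- as.numeric(crossprod(S, s2))
  out <- num / sqrt(d1 * d2)
  out[d1 <= 1e-12] <- NA_real_
  out
}

#' Circular-correlation timecourse against one rotation map
#'
#' Computes \eqn{\rho_c} between the phase map at every sample of a
#' [phase_map_series] and the rotation map at `origin`. This is the
#' statistic behind direction-bias analyses: with the origin chosen per
#' array (and sign oriented so the task-enhanced direction is positive),
#' instants with \eqn{\rho_c > 0.3} are waves in the positive direction
#' and \eqn{\rho_c < -0.3} waves in the opposite one.
#'
#' @param pms A [phase_map_series].
#' @param origin Rotation-map origin, length-2 `(x, y)` (default `c(4, 4)`).
#' @param flip_sign If `TRUE`, negates the series (used to orient the
#'   task-enhanced direction positive).
#' @return A tibble with columns `t` (seconds) and `rho`.
#' @export
rho_series <- function(pms, origin = c(4, 4), flip_sign = FALSE) {
  stopifnot(inherits(pms, "phase_map_series"))
  th <- rotation_map(origin)
  P <- matrix(pms$phase, nrow = 64)
  rho <- rho_series_matrix(P, as.numeric(th))
  if (flip_sign) rho <- -rho
  tibble(t = pms$t0 + (seq_len(ncol(P)) - 1) / pms$fs, rho = rho)
}

#' Three-point wave fingerprint
#'
#' The circular-circular correlations of a phase map against the rotation
#' maps at the three canonical origins ([fingerprint_origins()]). Each
#' origin has a distinct sensitivity profile to planar and rotating waves,
#' so the triple acts as a signature that separates wave types: a planar
#' diagonal wave and a rotating wave with the same net direction share the
#' central coefficient but differ in the edge coefficients.
#'
#' @param x A single 8x8 phase matrix, a [phase_map_series], or a
#'   `wave_movie` from [simulate_wave()].
#' @param origins Named list of rotation-map origins; names become column
#'   names (default [fingerprint_origins()]).
#' @param at For series/movie input: sample indices at which to evaluate
#'   (default: all samples).
#' @return A tibble with one row per evaluated instant, columns `t` plus
#'   one correlation column per origin.
#' @examples
#' mov <- simulate_wave(wave_template("planar", direction = pi / 4, sigma = 0),
#'                      duration = 0.2)
#' wave_fingerprint(mov, at = 100)
#' @export
wave_fingerprint <- function(x, origins = fingerprint_origins(), at = NULL) {
  UseMethod("wave_fingerprint")
}

#' @export
wave_fingerprint.matrix <- function(x, origins = fingerprint_origins(), at = NULL) {
  vals <- purrr::map_dbl(origins, ~circ_corr(x, rotation_map(.x)))
  dplyr::bind_cols(tibble(t = NA_real_), as_tibble(as.list(vals)))
}

#' @export
wave_fingerprint.phase_map_series <- function(x, origins = fingerprint_origins(),
                                              at = NULL) {
  P <- matrix(x$phase, nrow = 64)
  if (!is.null(at)) P <- P[, at, drop = FALSE] else at <- seq_len(ncol(P))
  cols <- purrr::map(origins, function(o) {
    rho_series_matrix(P, as.numeric(rotation_map(o)))
  })
  dplyr::bind_cols(tibble(t = x$t0 + (at - 1) / x$fs), as_tibble(cols))
}

#' @export
wave_fingerprint.wave_movie <- function(x, origins = fingerprint_origins(),
                                        at = NULL) {
  wave_fingerprint(wave_phase_maps(x), origins = origins, at = at)
}

#' Classify a correlation value by direction sign
#'
#' @param rho Numeric vector of circular-correlation values.
#' @param threshold Chance threshold (default 0.3, the 99th-percentile
#'   shuffling null).
#' @return A factor with levels `positive`, `negative`, `chance`:
#'   `positive` iff `rho > threshold`, `negative` iff `rho < -threshold`.
#' @examples
#' direction_sign(c(0.5, -0.31, 0.29))
#' @export
direction_sign <- function(rho, threshold = 0.3) {
  factor(
    dplyr::case_when(rho > threshold ~ "positive",
                     rho < -threshold ~ "negative",
                     TRUE ~ "chance"),
    levels = c("positive", "negative", "chance")
  )
}
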