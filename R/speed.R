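#' Wave speed from phase gradients
#'
#' Estimates propagation speed at given instants as the ratio of the
#' temporal to the spatial phase gradient: each site's temporal gradient
#' is the circular difference of its phase across adjacent samples, the
#' spatial gradient magnitude comes from circular central differences on
#' the grid, and both are averaged across electrodes before taking the
#' ratio. The result is converted to cm/s with the electrode pitch.
#' Speed is meaningful only for long-wavelength waves, whose spatial
#' frequency is consistent across the array; instants with a vanishing
#' spatial gradient (synchronous/standing activity) are flagged invalid.
#'
#' @param pms A [phase_map_series].
#' @param at Sample indices at which to estimate (interior samples only;
#'   default: all interior samples).
#' @param pitch_um Electrode pitch in micrometres (default 400).
#' @return Tibble with `sample`, `t`, `speed_cm_s`, `n_sites`, `valid`.
#' @examples
#' mov <- simulate_wave(
#'   wave_template("planar", direction = 0, w = 2 * pi * 20,
#'                 k = 2 * pi / 16, sigma = 0),
#'   duration = 0.3)
#' wave_speed(wave_phase_maps(mov), at = 100)$speed_cm_s  # 12.8 cm/s
#' @export
wave_speed <- function(pms, at = NULL, pitch_um = 400) {
  stopifnot(inherits(pms, "phase_map_series"))
  nt <- dim(pms$phase)[3]
  at <- at %||% seq(2L, nt - 1L)
  if (any(at < 2 | at > nt - 1))
    abort("speed needs one sample of headroom on each side",
          class = "wavemap_invalid")
  cdiff <- function(a, b) wrap_angle(a - b)
  purrr::map_dfr(at, function(i) {
    p <- pms$phase[, , i]
    # temporal gradient, rad/s (two-sided circular difference)
    dpdt <- cdiff(pms$phase[, , i + 1L], pms$phase[, , i - 1L]) / 2 * pms$fs
    # spatial gradient, rad per grid unit
    n <- nrow(p)
    gx <- (cbind(cdiff(p[, -1], p[, -n]), NA) +
             cbind(NA, cdiff(p[, -1], p[, -n]))) / 2
    gy <- (rbind(cdiff(p[-1, ], p[-n, ]), NA) +
             rbind(NA, cdiff(p[-1, ], p[-n, ]))) / 2
    gmag <- sqrt(gx^2 + gy^2)
    ok <- !is.na(dpdt) & !is.na(gmag)
    mt <- abs(mean(dpdt[ok]))
    ms <- mean(gmag[ok])
    valid <- is.finite(ms) && ms > 1e-6
    tibble(sample = i, t = pms$t0 + (i - 1) / pms$fs,
           speed_cm_s = if (valid) (mt / ms) * (pitch_um / 1e4) else NA_real_,
           n_sites = sum(ok), valid = valid)
  })
}
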