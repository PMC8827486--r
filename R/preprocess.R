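#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and reverse in time
#' (filtfilt), so the output has no phase lag: the peak of an in-band
#' sinusoid stays where it was. Signals are padded by odd reflection
#' before filtering to suppress edge transients (about three low-edge
#' periods at each end).
#'
#' @param x Numeric vector, or matrix with one signal per row.
#' @param fs Sampling rate, Hz.
#' @param lo,hi Band edges, Hz; must satisfy `0 < lo < hi < fs/2`.
#' @param order Filter order (default 4).
#' @return Filtered data, same shape as `x`.
#' @examples
#' t <- seq(0, 2, by = 1 / 1000)
#' y <- bandpass_filter(cos(2 * pi * 20 * t) + 100, fs = 1000, lo = 12, hi = 30)
#' @export
bandpass_filter <- function(x, fs, lo, hi, order = 4) {
  if (!(lo > 0 && hi > lo && hi < fs / 2))
    abort("band edges must satisfy 0 < lo < hi < fs/2",
          class = "wavemap_invalid_band")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  pad <- min(n - 1, ceiling(3 * fs / lo))
  if (n < 3 * (order + 1))
    abort("signal too short to filter", class = "wavemap_insufficient")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  out <- t(apply(x, 1, function(s) {
    padded <- c(2 * s[1] - rev(s[2:(pad + 1)]), s,
                2 * s[n] - rev(s[(n - pad):(n - 1)]))
    signal::filtfilt(bf, padded)[(pad + 1):(pad + n)]
  }))
  if (vec) as.numeric(out) else out
}

#' Place electrode signals on the grid and fill missing sites
#'
#' Arranges an electrodes x samples matrix into an 8 x 8 x samples array
#' using the session's grid map, then fills each missing site, sample by
#' sample, with the mean of its available 4-neighbours (linear
#' interpolation on the lattice; exact for planar gradients at interior
#' sites).
#'
#' @param x Electrodes x samples matrix (e.g. filtered voltage).
#' @param grid_map Tibble with `electrode`, `x`, `y` (see [lfp_session()]).
#' @param missing Data frame of missing sites (`x`, `y`).
#' @return An 8 x 8 x samples array indexed `[y, x, t]`.
#' @export
interpolate_missing <- function(x, grid_map, missing = NULL) {
  x <- as.matrix(x)
  nt <- ncol(x)
  missing <- if (is.null(missing)) tibble(x = integer(), y = integer())
             else as_tibble(missing)
  if (nrow(missing) > 32)
    abort("more than half the grid is missing; map uninterpretable",
          class = "wavemap_invalid")
  arr <- array(NA_real_, c(8, 8, nt))
  idx <- cbind(grid_map$y, grid_map$x)
  flat <- idx[, 1] + (idx[, 2] - 1) * 8
  for (i in seq_len(nt)) {
    m <- array(NA_real_, c(8, 8))
    m[flat] <- x[, i]
    arr[, , i] <- m
  }
  if (nrow(missing) > 0) {
    nb <- list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
    for (j in seq_len(nrow(missing))) {
      mx <- missing$x[j]; my <- missing$y[j]
      av <- purrr::keep(purrr::map(nb, ~c(my + .x[1], mx + .x[2])), function(p) {
        p[1] >= 1 && p[1] <= 8 && p[2] >= 1 && p[2] <= 8 &&
          !any(missing$x == p[2] & missing$y == p[1])
      })
      if (length(av) < 2)
        abort("missing site needs at least two available neighbours",
              class = "wavemap_invalid")
      vals <- vapply(av, function(p) arr[p[1], p[2], , drop = TRUE],
                     numeric(nt))
      arr[my, mx, ] <- rowMeans(matrix(vals, ncol = length(av)))
    }
  }
  arr
}

# FFT-based analytic signal of each row of a matrix (signals along columns
# of the transposed input); standard one-sided spectrum doubling
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  X <- mvfft(t(x))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- t(mvfft(X * h, inverse = TRUE)) / n
  if (vec) as.complex(z[1, ]) else z
}

#' Instantaneous phase and amplitude via the Hilbert transform
#'
#' Computes the analytic signal of each site's band-limited trace and
#' returns its phase and envelope. Phase follows the convention of the
#' phase maps: 0 at the oscillation peak, positive while approaching the
#' peak (the negated analytic-signal argument), so filtered-signal maxima
#' coincide with downward zero crossings of the phase, and phase increases
#' along a traveling wave's direction of motion.
#'
#' @param x An 8 x 8 x samples array (from [interpolate_missing()]), a
#'   matrix of signals (one per row), or a vector.
#' @param fs Sampling rate, Hz (stored in the result for array input).
#' @param band Optional band label stored in the result.
#' @return For array input, a [phase_map_series]; otherwise a list with
#'   `phase` and `amplitude` shaped like `x`. Samples where the envelope
#'   is (numerically) zero have undefined phase, returned as `NA`.
#' @examples
#' t <- seq(0, 1, by = 1 / 1000)
#' ap <- analytic_phase(cos(2 * pi * 10 * t))
#' ap$phase[1]  # 0 at the peak
#' @export
analytic_phase <- function(x, fs = 1000, band = NULL) {
  if (is.array(x) && length(dim(x)) == 3) {
    flat <- matrix(x, nrow = dim(x)[1] * dim(x)[2])
    z <- analytic_signal(flat)
    ph <- -Arg(z); am <- Mod(z)
    ph[am <= .Machine$double.eps^0.5] <- NA_real_
    dim(ph) <- dim(x); dim(am) <- dim(x)
    return(new_phase_map_series(ph, am, fs = fs, band = band))
  }
  z <- analytic_signal(x)
  ph <- -Arg(z); am <- Mod(z)
  ph[am <= .Machine$double.eps^0.5] <- NA_real_
  list(phase = ph, amplitude = am)
}

#' Band-limited phase maps of a session
#'
#' The preprocessing pipeline: zero-phase Butterworth band-pass of every
#' electrode, placement on the 8x8 grid with linear interpolation of
#' missing sites, then Hilbert analytic phase and amplitude per site.
#'
#' @param session An [lfp_session()].
#' @param band Band name from `bands` (e.g. `"beta"`) or a numeric
#'   `c(lo, hi)` in Hz.
#' @param bands Band definition table (default [wave_bands()]).
#' @param order Filter order (default 4).
#' @return A [phase_map_series] with the band label attached.
#' @export
phase_maps <- function(session, band = "beta", bands = wave_bands(), order = 4) {
  stopifnot(inherits(session, "lfp_session"))
  be <- band_edges(band, bands)
  if (session$fs <= 2 * be$hi)
    abort("sampling rate must exceed twice the band's upper edge",
          class = "wavemap_invalid_band")
  filt <- bandpass_filter(session$voltage, session$fs, be$lo, be$hi, order)
  arr <- interpolate_missing(filt, session$grid_map, session$missing)
  analytic_phase(arr, fs = session$fs, band = be$band)
}

#' Morlet-wavelet band power
#'
#' Convolves each electrode with complex Morlet wavelets (default 7
#' cycles) at the requested frequencies and returns squared-modulus power
#' averaged across electrodes, optionally expressed as change from a
#' per-trial baseline window. Used for band-power timecourse summaries.
#'
#' @param x An [lfp_session()] or an electrodes x samples matrix.
#' @param frequencies Wavelet centre frequencies, Hz.
#' @param fs Sampling rate (taken from the session if given).
#' @param n_cycles Wavelet width in cycles (default 7).
#' @return Tibble with columns `t`, `freq`, `power` (electrode-averaged).
#' @export
morlet_power <- function(x, frequencies, fs = NULL, n_cycles = 7) {
  if (inherits(x, "lfp_session")) {
    fs <- x$fs
    x <- x$voltage
  }
  if (is.null(fs)) abort("fs required for matrix input", class = "wavemap_invalid")
  if (any(frequencies <= 0 | frequencies >= fs / 2))
    abort("frequencies must lie in (0, fs/2)", class = "wavemap_invalid_band")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  nfft <- stats::nextn(2 * n, 2)
  X <- mvfft(rbind(t(x), matrix(0, nfft - n, nrow(x))))
  tt <- (seq_len(nfft) - 1) / fs
  out <- purrr::map_dfr(frequencies, function(f) {
    s <- n_cycles / (2 * pi * f)
    half <- min(floor(nfft / 2) - 1, ceiling(4 * s * fs))
    w <- exp(-((-half:half) / fs)^2 / (2 * s^2)) *
      exp(2i * pi * f * ((-half:half) / fs))
    w <- w / sum(abs(w))
    wpad <- complex(length.out = nfft)
    wpad[1:(half + 1)] <- w[(half + 1):(2 * half + 1)]
    wpad[(nfft - half + 1):nfft] <- w[1:half]
    W <- fft(wpad)
    conv <- mvfft(X * W, inverse = TRUE) / nfft
    p <- rowMeans(Mod(conv[seq_len(n), , drop = FALSE])^2)
    tibble(t = (seq_len(n) - 1) / fs, freq = f, power = p)
  })
  out
}

#' Band-power change from baseline
#'
#' Trial-averages Morlet power within a band and normalizes per trial to
#' the pre-fixation baseline window, the summary behind band-power
#' timecourse figures.
#'
#' @param session An [lfp_session()] with events.
#' @param band Band name or numeric `c(lo, hi)`.
#' @param bands Band table.
#' @param n_freqs Wavelets spread across the band (default 5).
#' @param epochs Trial epoch layout (default [trial_epochs()]).
#' @param n_cycles Wavelet cycles.
#' @return Tibble with `t_rel` (seconds from fixation onset) and
#'   `power_change` (relative change from baseline, trial-averaged).
#' @export
band_power_timecourse <- function(session, band = "beta", bands = wave_bands(),
                                  n_freqs = 5, epochs = trial_epochs(),
                                  n_cycles = 7) {
  be <- band_edges(band, bands)
  freqs <- seq(be$lo, be$hi, length.out = n_freqs)
  pw <- morlet_power(session, freqs, n_cycles = n_cycles) %>%
    group_by(.data$t) %>% summarise(power = mean(.data$power), .groups = "drop")
  fix <- session$events %>% filter(.data$event == "fixation_on")
  span <- range(purrr::map_dbl(epochs, ~.x[1]), purrr::map_dbl(epochs, ~.x[2]))
  purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    t0 <- fix$t[i]
    tr <- pw %>% filter(.data$t >= t0 + span[1], .data$t < t0 + span[2]) %>%
      mutate(t_rel = .data$t - t0, trial = fix$trial[i])
    base <- mean(tr$power[tr$t_rel >= epochs$baseline[1] &
                          tr$t_rel < epochs$baseline[2]])
    mutate(tr, power_change = (.data$power - base) / base)
  }) %>%
    mutate(t_rel = round(.data$t_rel * session$fs) / session$fs) %>%
    group_by(.data$t_rel) %>%
    summarise(power_change = mean(.data$power_change), .groups = "drop")
}
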