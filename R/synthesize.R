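#' Synthetic-session specification
#'
#' Parameters of a generated working-memory session. The trial layout
#' mirrors the delayed match-to-sample task: 0.5 s pre-fixation baseline,
#' 0.5 s fixation, 0.5 s sample, 2 s memory delay and 0.5 s test, so one
#' trial spans 4 s. Within each epoch, wave events arrive as a Poisson
#' stream; each event is a band-limited planar (or rotating) wave burst
#' whose direction is the preferred azimuth with the epoch's bias
#' probability, else the opposite direction. Background activity is pink
#' (1/f) plus white noise.
#'
#' @param n_trials Number of trials (default 50).
#' @param band Carrier band label (default `"beta"`).
#' @param carrier_hz Carrier frequency inside the band (default 20).
#' @param wave_rate Wave events per second (default 2).
#' @param event_duration Burst duration, s (default 0.25, Hann-windowed).
#' @param bias Named probabilities of the preferred direction per epoch
#'   (defaults: 0.5 everywhere except 0.8 in sample and delay).
#' @param preferred_direction Preferred azimuth, radians (default `pi/4`,
#'   the direction giving positive rho_c at the `(4,4)` origin).
#' @param k Wavenumber of the planar bursts (default 0.62).
#' @param amplitude Burst amplitude, uV (default 30).
#' @param noise_sd Background noise standard deviation, uV (default 10,
#'   split between pink and white components).
#' @param rotating_pool Optional list of rotating [wave_template()]s; with
#'   probability `rotating_fraction` an event is drawn from this pool
#'   instead of the biased planar pair.
#' @param rotating_fraction Probability of a rotating event (default 0).
#' @param spikes If `TRUE`, also generate per-electrode spike trains as an
#'   inhomogeneous Poisson process with rate increasing with the local
#'   wave envelope.
#' @param spike_base_hz,spike_gain_hz Baseline rate and envelope gain for
#'   spike generation.
#' @param fs Sampling rate, Hz.
#' @param epochs Epoch layout (default [trial_epochs()]).
#' @return A `session_spec` list.
#' @export
session_spec <- function(n_trials = 50, band = "beta", carrier_hz = 20,
                         wave_rate = 2, event_duration = 0.25,
                         bias = c(baseline = 0.5, fixation = 0.5,
                                  sample = 0.8, delay = 0.8, test = 0.5),
                         preferred_direction = pi / 4, k = 0.62,
                         amplitude = 30, noise_sd = 10,
                         rotating_pool = NULL, rotating_fraction = 0,
                         spikes = FALSE, spike_base_hz = 2,
                         spike_gain_hz = 20,
                         fs = 1000, epochs = trial_epochs()) {
  if (any(bias < 0 | bias > 1))
    abort("bias probabilities must lie in [0, 1]", class = "wavemap_invalid")
  if (rotating_fraction > 0 && length(rotating_pool) == 0)
    abort("rotating_fraction > 0 requires a rotating_pool",
          class = "wavemap_invalid")
  structure(as.list(environment()), class = "session_spec")
}

# Hann-windowed complex planar/rotating burst, 64 x nt
wave_burst <- function(template, tt, amp_map) {
  phi <- as.numeric(phase_input(template))
  env <- 0.5 * (1 - cos(2 * pi * seq_along(tt) / (length(tt) + 1)))
  ph <- outer(-template$k * phi, template$w * tt, `+`)
  amp_map * exp(1i * ph) * rep(env, each = 64)
}

# site amplitudes: uniform for planar bursts; for rotating bursts the
# envelope decays with distance from the rotation centre, so the wave is
# strongest near its core
burst_amplitude <- function(template, A) {
  if (template$kind == "planar") return(rep(A, 64))
  r_grid <- sqrt((site_x() - template$center[1])^2 +
                 (site_y() - template$center[2])^2)
  as.numeric(A * 2 / (2 + r_grid))
}

# pink (1/f) noise, one trace per row
pink_noise <- function(n_rows, n, fs) {
  w <- matrix(rnorm(n_rows * n), ncol = n_rows)
  W <- mvfft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # two-sided frequency index
  W <- W / sqrt(f)
  p <- Re(mvfft(W, inverse = TRUE)) / n
  p <- t(p)
  p / sd(p)
}

#' Generate a synthetic LFP session
#'
#' Builds an [lfp_session()] realizing a [session_spec()]: scheduled wave
#' bursts in a band-limited carrier over 1/f-plus-white background noise,
#' organized into trials with the working-memory epoch layout, plus a
#' ground-truth event log (attribute `"truth"`) and, optionally,
#' amplitude-driven Poisson spike trains (attribute `"spikes"`).
#'
#' @param spec A [session_spec()].
#' @param seed Integer seed; the session is a deterministic function of
#'   `(spec, seed)`.
#' @return An `lfp_session`; `attr(, "truth")` holds the event log
#'   (`trial`, `epoch`, `t_on`, `t_off`, `band`, `kind`, `direction_deg`,
#'   `k`), `attr(, "spikes")` the spike table when requested.
#' @examples
#' \donttest{
#' s <- synthesize_session(session_spec(n_trials = 2), seed = 1)
#' head(attr(s, "truth"))
#' }
#' @export
synthesize_session <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "session_spec"))
  with_seed(seed, {
    ep <- spec$epochs
    span <- c(min(purrr::map_dbl(ep, 1)), max(purrr::map_dbl(ep, 2)))
    trial_len <- diff(span)
    fix_offset <- -span[1]           # fixation onset within the trial block
    nt_trial <- round(trial_len * spec$fs)
    n <- spec$n_trials * nt_trial
    volt <- matrix(0, 64, n)
    env_sum <- matrix(0, 64, n)      # wave envelope, drives spike rates
    nt_ev <- round(spec$event_duration * spec$fs)
    w <- 2 * pi * spec$carrier_hz
    truth <- list()

    for (tr in seq_len(spec$n_trials)) {
      t_trial <- (tr - 1) * trial_len
      for (en in names(ep)) {
        e0 <- ep[[en]][1]; e1 <- ep[[en]][2]
        n_ev <- rpois(1, spec$wave_rate * (e1 - e0))
        if (n_ev == 0) next
        onsets <- sort(runif(n_ev, e0, e1 - spec$event_duration))
        # thin overlapping events: a burst must finish before the next
        keep <- rep(TRUE, n_ev)
        last_end <- -Inf
        for (j in seq_len(n_ev)) {
          if (onsets[j] < last_end) keep[j] <- FALSE
          else last_end <- onsets[j] + spec$event_duration
        }
        if (!all(keep)) {
          onsets <- onsets[keep]
          n_ev <- length(onsets)
          if (n_ev == 0) next
        }
        for (on in onsets) {
          rotating <- spec$rotating_fraction > 0 &&
            runif(1) < spec$rotating_fraction
          if (rotating) {
            tpl <- spec$rotating_pool[[sample.int(length(spec$rotating_pool), 1)]]
            tpl$w <- w
          } else {
            dirn <- if (runif(1) < spec$bias[[en]]) spec$preferred_direction
                    else spec$preferred_direction + pi
            tpl <- wave_template("planar", direction = dirn, A = spec$amplitude,
                                 w = w, k = spec$k, sigma = 0)
          }
          i0 <- round((t_trial + fix_offset + on) * spec$fs) + 1L
          idx <- i0:(i0 + nt_ev - 1L)
          idx <- idx[idx <= n]
          tt <- (seq_along(idx) - 1) / spec$fs
          amp <- burst_amplitude(tpl, spec$amplitude)
          b <- wave_burst(tpl, tt, amp)
          volt[, idx] <- volt[, idx] + Re(b)
          env_sum[, idx] <- env_sum[, idx] + Mod(b)
          truth[[length(truth) + 1L]] <- tibble(
            trial = tr, epoch = en,
            t_on = t_trial + fix_offset + on,
            t_off = t_trial + fix_offset + on + length(idx) / spec$fs,
            band = spec$band, kind = tpl$kind,
            direction_deg = if (tpl$kind == "planar") tpl$direction * 180 / pi
                            else NA_real_,
            k = tpl$k)
        }
      }
    }

    if (spec$noise_sd > 0) {
      volt <- volt + spec$noise_sd * (0.7 * pink_noise(64, n, spec$fs) +
                                      0.3 * matrix(rnorm(64 * n), 64))
    }

    fix_t <- (seq_len(spec$n_trials) - 1) * trial_len + fix_offset
    events <- purrr::map_dfr(seq_len(spec$n_trials), function(tr) {
      tibble(trial = tr,
             event = c("fixation_on", "sample_on", "sample_off", "test_on"),
             t = fix_t[tr] + c(0, ep$sample[1], ep$sample[2], ep$test[1]))
    })
    sess <- lfp_session(volt, fs = spec$fs, events = events,
                        array_label = "synthetic")
    attr(sess, "truth") <- dplyr::bind_rows(truth)
    if (isTRUE(spec$spikes)) {
      rate <- spec$spike_base_hz + spec$spike_gain_hz *
        pmin(env_sum / spec$amplitude, 2)
      hit <- matrix(runif(64 * n), 64) < rate / spec$fs
      idx <- which(hit, arr.ind = TRUE)
      attr(sess, "spikes") <- tibble(electrode = idx[, 1],
                                     t = (idx[, 2] - 1) / spec$fs)
    }
    sess
  })
}
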