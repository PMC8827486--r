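fs <- 1000
tt <- seq(0, 3, by = 1 / fs)

test_that("band-pass filtering is zero-phase, band-selective and DC-free", {
  x <- cos(2 * pi * 20 * (tt - 0.3217))
  y <- bandpass_filter(x, fs, 12, 30)
  # no lag: cross-correlation peaks at 0 and in-band amplitude is preserved
  cc <- stats::ccf(y, x, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_equal(max(abs(y[1000:2000])), 1, tolerance = 1e-3)

  # DC offset is rejected by any band
  expect_lt(abs(mean(bandpass_filter(rep(100, 3001), fs, 4, 8))), 0.01)

  # out-of-band rejection, checked against an FFT band-power oracle
  set.seed(5)
  w <- rnorm(length(tt))
  yf <- bandpass_filter(w, fs, 12, 30)
  spec <- Mod(fft(yf))^2
  fgrid <- (seq_along(yf) - 1) / length(yf) * fs
  pow_at <- function(f0) mean(spec[abs(fgrid - f0) < 1])
  expect_lt(pow_at(6) / pow_at(20), 0.01)
  expect_lt(pow_at(60) / pow_at(20), 0.01)

  expect_error(bandpass_filter(x, fs, 12, 600), class = "wavemap_invalid_band")
  expect_error(bandpass_filter(x[1:5], fs, 12, 30),
               class = "wavemap_insufficient")
})

test_that("analytic phase follows the approaching-peak convention", {
  ap <- analytic_phase(cos(2 * pi * 10 * tt))
  # phase 0 at an interior peak, envelope ~1
  peak <- which.max(cos(2 * pi * 10 * tt)[1000:1100]) + 999
  expect_equal(ap$phase[peak], 0, tolerance = 0.02)
  expect_equal(ap$amplitude[1500], 1, tolerance = 1e-3)

  # quadrature: sin is a quarter-cycle short of its peak at t = 0, so its
  # phase is +pi/2 under the positive-approaching-peak convention
  ap2 <- analytic_phase(sin(2 * pi * 10 * tt))
  expect_equal(ap2$phase[1], pi / 2, tolerance = 0.05)

  # envelope scales with amplitude
  ap3 <- analytic_phase(5 * cos(2 * pi * 10 * tt))
  expect_equal(ap3$amplitude[1500], 5, tolerance = 1e-3)

  # all-zero signal: flagged undefined phase, not an error
  ap0 <- analytic_phase(numeric(100))
  expect_true(all(is.na(ap0$phase)))
  expect_true(all(ap0$amplitude < 1e-8))

  # signal maxima coincide with downward zero crossings of the phase
  x <- bandpass_filter(cos(2 * pi * 20 * tt) + 0.1 * sin(2 * pi * 25 * tt),
                       fs, 12, 30)
  ph <- analytic_phase(x)$phase
  down <- which(diff(sign(ph)) < 0 & abs(diff(ph)) < pi)
  pks <- which(diff(sign(diff(x))) == -2) + 1
  pks <- pks[pks > 100 & pks < length(x) - 100]
  expect_true(all(vapply(pks, function(p) min(abs(down - p)) <= 1, logical(1))))
})

test_that("missing-site interpolation is linear, local and idempotent", {
  gm <- grid_sites()
  gm$electrode <- seq_len(nrow(gm))

  # no missing sites: identity
  v <- matrix(rnorm(64 * 3), 64, 3)
  arr <- interpolate_missing(v, gm)
  expect_equal(matrix(arr, 64), v, ignore_attr = TRUE, tolerance = 1e-12)

  # interior site on a planar gradient v = x + y is filled exactly
  gm4 <- gm[!(gm$x == 4 & gm$y == 4), ]
  arr4 <- interpolate_missing(matrix(gm4$x + gm4$y, ncol = 1), gm4,
                              data.frame(x = 4, y = 4))
  expect_equal(arr4[4, 4, 1], 8)

  # corner with two neighbours: mean of the available ones
  gm1 <- gm[!(gm$x == 1 & gm$y == 1), ]
  v1 <- matrix(0, 63, 1)
  v1[gm1$x == 2 & gm1$y == 1] <- 2
  v1[gm1$x == 1 & gm1$y == 2] <- 4
  arr1 <- interpolate_missing(v1, gm1, data.frame(x = 1, y = 1))
  expect_equal(arr1[1, 1, 1], 3)

  # more than half the grid missing is refused
  expect_error(
    interpolate_missing(matrix(0, 2, 1), gm[1:2, ],
                        data.frame(x = rep(1:8, each = 5), y = rep(1:5, 8))),
    class = "wavemap_invalid")
})

test_that("Morlet power is frequency-matched, quadratic and time-resolved", {
  x <- cos(2 * pi * 20 * tt)
  p <- morlet_power(x, c(10, 20, 30), fs = fs)
  m <- tapply(p$power, p$freq, mean)
  expect_equal(names(which.max(m)), "20")

  p2 <- morlet_power(2 * x, 20, fs = fs)
  expect_equal(mean(p2$power) / m[["20"]], 4, tolerance = 1e-6)

  # chirp: low-frequency power peaks before high-frequency power, at the
  # times the instantaneous-frequency law predicts
  xc <- cos(2 * pi * (5 * tt + (40 - 5) / (2 * 3) * tt^2))
  pc <- morlet_power(xc, c(10, 30), fs = fs)
  tmax <- tapply(seq_len(nrow(pc)), pc$freq, function(i) pc$t[i][which.max(pc$power[i])])
  # f(t) = 5 + (35/3) t -> 10 Hz at t ~ 0.43 s, 30 Hz at t ~ 2.14 s
  expect_equal(unname(tmax[["10"]]), 3 / 35 * 5, tolerance = 0.15)
  expect_equal(unname(tmax[["30"]]), 3 / 35 * 25, tolerance = 0.15)
  expect_lt(tmax[["10"]], tmax[["30"]])

  expect_error(morlet_power(x, 600, fs = fs), class = "wavemap_invalid_band")
})

test_that("session phase maps agree with the simulator's closed form", {
  mov <- clean_planar_movie(k = 0.25, f = 20, duration = 1)
  sess <- lfp_session(matrix(mov$voltage, 64), fs = 1000)
  pms <- phase_maps(sess, "beta")
  mid <- 500
  # up to filter edge effects, phase maps match -Arg(g) = k*phi - w*t
  expect_wrapped_equal(pms$phase[, , mid], -Arg(mov$g[, , mid]), tol = 0.02)
})

test_that("session containers validate geometry and round-trip to text", {
  expect_error(lfp_session(matrix(0, 64, 10), grid_map = data.frame(
    electrode = 1:64, x = rep(1, 64), y = rep(1, 64))),
    class = "wavemap_invalid")
  ev_bad <- data.frame(trial = 1, event = c("fixation_on", "sample_on"),
                       t = c(2, 1))
  expect_error(lfp_session(matrix(0, 64, 10), events = ev_bad),
               class = "wavemap_invalid")

  s <- lfp_session(matrix(rnorm(64 * 20), 64, 20),
                   events = data.frame(trial = 1, event = "fixation_on",
                                       t = 0.5),
                   array_label = "synthetic test array")
  d <- withr::local_tempdir()
  write_lfp_session(s, d)
  s2 <- read_lfp_session(d)
  expect_equal(s2$voltage, s$voltage, ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(s2$events$t, s$events$t)
  expect_equal(s2$array_label, s$array_label)
})
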