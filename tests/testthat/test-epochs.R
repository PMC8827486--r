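# a modest shared session for epoch statistics: strong delay bias,
# detectable (very long wavelength) bursts
epoch_session <- local({
  env <- new.env()
  function() {
    if (is.null(env$s)) {
      env$s <- synthesize_session(
        session_spec(n_trials = 20, k = 0.25, wave_rate = 2,
                     bias = c(baseline = 0.5, fixation = 0.5, sample = 0.8,
                              delay = 0.8, test = 0.5)),
        seed = 101)
      env$pms <- phase_maps(env$s, "beta")
      env$rho <- rho_series(env$pms, c(4, 4))
    }
    list(s = env$s, pms = env$pms, rho = env$rho)
  }
})

test_that("wave-count timecourses flag epochs with raised wave rates", {
  # delay rate 3x baseline
  s3 <- synthesize_session(
    session_spec(n_trials = 20, k = 0.25, wave_rate = 1,
                 bias = c(baseline = 0.5, fixation = 0.5, sample = 0.5,
                          delay = 0.5, test = 0.5)),
    seed = 7)
  truth <- attr(s3, "truth")
  # triple the delay rate by a second session overlay is overkill; instead
  # check the machinery on ground-truth events directly
  ev <- tibble::tibble(t_start = truth$t_on, label = "truth",
                       azimuth = pi / 4)
  cnt <- epoch_wave_counts(ev, s3, n_perm = 500)
  expect_s3_class(cnt, "wave_count_timecourse")
  # near-uniform rates: at most a few bins marked at the 1% level
  expect_lte(mean(cnt$significant), 0.05)

  # raised delay rate (4x) is detected across many delay bins
  s4 <- synthesize_session(
    session_spec(n_trials = 40, k = 0.25, wave_rate = 2), seed = 9)
  tr4 <- attr(s4, "truth")
  boost <- tr4[tr4$epoch == "delay", ]
  ev4 <- tibble::tibble(
    t_start = c(tr4$t_on, boost$t_on + 0.01, boost$t_on + 0.02,
                boost$t_on + 0.03),
    label = "truth", azimuth = pi / 4)
  cnt4 <- epoch_wave_counts(ev4, s4, n_perm = 1000)
  delay_bins <- cnt4$t_rel >= 1 & cnt4$t_rel < 3
  expect_gt(mean(cnt4$significant[delay_bins] & cnt4$above_baseline[delay_bins]),
            0.3)

  # no events at all: no marks
  cnt0 <- epoch_wave_counts(ev[0, ], s3, n_perm = 500)
  expect_false(any(cnt0$significant))
})

test_that("detected wave events track the generator's schedule", {
  fix <- epoch_session()
  det <- detect_planar(fix$pms)
  ev <- count_waves(det, fs = 1000)
  expect_gt(nrow(ev), 20)
  truth <- attr(fix$s, "truth")
  # most detected events overlap a scheduled burst
  hits <- purrr::map_lgl(seq_len(nrow(ev)), function(i) {
    any(truth$t_on - 0.05 < ev$t_end[i] & truth$t_off + 0.05 > ev$t_start[i])
  })
  expect_gt(mean(hits), 0.9)
})

test_that("direction histograms align and preserve mixtures", {
  h <- direction_histogram(rep(37, 40), bin_deg = 12)
  expect_equal(sum(h$prop), 1)
  al <- align_preferred(list(h))
  expect_equal(al$bin_mid_deg[which.max(al$prop)], 0)

  # 70/30 mixture: aligned mass ratio between the 0 and 180 lobes
  set.seed(2)
  dirs <- c(rep(80, 700), rep(260, 300)) + rnorm(1000, 0, 3)
  h2 <- align_preferred(list(direction_histogram(dirs)))
  lobe0 <- sum(h2$prop[h2$bin_mid_deg < 30 | h2$bin_mid_deg > 330])
  lobe180 <- sum(h2$prop[abs(h2$bin_mid_deg - 180) < 30])
  expect_equal(lobe0 / (lobe0 + lobe180), 0.7, tolerance = 0.05)

  # near-uniform directions: no bin much above the uniform expectation
  set.seed(3)
  hu <- direction_histogram(runif(6000, 0, 360))
  expect_lt(max(hu$prop), 2 / nrow(hu))

  he <- direction_histogram(numeric(0))
  expect_equal(sum(he$count), 0)
})

test_that("rho histograms show the task-driven lobe asymmetry", {
  fix <- epoch_session()
  rh <- rho_histograms(fix$rho, fix$s, n_perm = 500)
  expect_s3_class(rh, "rho_histograms")
  delay <- rh[rh$epoch == "delay", ]
  pos_lobe <- sum(delay$prop_epoch[delay$bin_mid > 0.3])
  neg_lobe <- sum(delay$prop_epoch[delay$bin_mid < -0.3])
  pos_base <- sum(delay$prop_baseline[delay$bin_mid > 0.3])
  neg_base <- sum(delay$prop_baseline[delay$bin_mid < -0.3])
  # baseline is bidirectional; delay pushes mass to the positive lobe
  expect_gt(pos_lobe, pos_base)
  expect_lt(neg_lobe, neg_base)
  expect_gt(pos_base, 0.02)
  expect_gt(neg_base, 0.02)

  # pure noise: nearly all mass inside the chance zone
  noise <- synthesize_session(session_spec(n_trials = 6, wave_rate = 0),
                              seed = 31)
  rho_n <- rho_series(phase_maps(noise, "beta"), c(4, 4))
  rh_n <- rho_histograms(rho_n, noise, n_perm = 200)
  inzone <- rh_n[rh_n$epoch == "delay" & abs(rh_n$bin_mid) < 0.3, ]
  expect_gte(sum(inzone$prop_epoch), 0.95)

  # sign flip mirrors the histogram
  rh_f <- rho_histograms(dplyr::mutate(fix$rho, rho = -rho), fix$s,
                         n_perm = 200)
  d2 <- rh_f[rh_f$epoch == "delay", ]
  expect_equal(d2$prop_epoch, rev(delay$prop_epoch), tolerance = 1e-12)
})

test_that("the direction-bias timecourse recovers the injected bias", {
  fix <- epoch_session()
  b <- direction_bias_timecourse(fix$rho, fix$s)
  expect_s3_class(b, "bias_timecourse")
  during <- b$t_mid > 1 & b$t_mid < 3
  expect_gt(mean(b$d_positive[during]), 0)
  expect_lt(mean(b$d_negative[during]), 0)
  # the baseline interval compares with itself exactly
  expect_equal(b$d_positive[b$t_mid < 0], 0)

  # all-positive schedule: delta equals epoch minus baseline exceedance
  rho_const <- dplyr::mutate(fix$rho, rho = 0.9)
  b1 <- direction_bias_timecourse(rho_const, fix$s)
  expect_equal(b1$d_positive, rep(0, nrow(b1)))

  # sign-orientation convention: flipping the series negates the outputs
  b_f <- direction_bias_timecourse(dplyr::mutate(fix$rho, rho = -rho), fix$s)
  expect_equal(b_f$d_positive, b$d_negative, tolerance = 1e-12)
  expect_equal(b_f$d_negative, b$d_positive, tolerance = 1e-12)
})

test_that("standing-wave discrimination separates the three regimes", {
  # build a mixture: synchronous, traveling and unstructured instants
  nt <- 300
  sync <- array(rep(wavemap:::wrap_angle(2 * pi * 10 * (0:99) / 1000),
                    each = 64), c(8, 8, 100))
  trav <- wave_phase_maps(clean_planar_movie(k = 0.25, duration = 0.1))$phase
  set.seed(9)
  rand <- array(runif(64 * 100, -pi, pi), c(8, 8, 100))
  pms <- wavemap:::new_phase_map_series(
    array(c(sync, trav, rand), c(8, 8, nt)), array(1, c(8, 8, nt)), fs = 1000)
  out <- standing_wave_instants(pms, wave_samples = 101:200)
  expect_true(all(out$label[1:100] == "standing"))
  expect_true(all(out$label[101:200] == "traveling"))
  expect_gt(mean(out$label[201:300] == "neither"), 0.95)
  # synchronous phase maps have (near) zero circular SD
  expect_lt(max(out$phase_sd[1:100]), 0.05)
  # uniform-random maps sit near the circular-uniform dispersion level
  expect_gt(min(out$phase_sd[201:300]), 1)
})

test_that("spike rates split by wavelength class when amplitude drives them", {
  # short wavelengths: rotation core on the array (high local amplitude);
  # long wavelengths: core far off-array (low amplitude everywhere)
  rot_short <- wave_template("rotating", center = c(2.5, 2.5), k = 0.8)
  rot_long <- wave_template("rotating", center = c(0.5, 0.5) - 6 / sqrt(2),
                            k = 0.15)
  s <- synthesize_session(
    session_spec(n_trials = 12, wave_rate = 1.5, spikes = TRUE,
                 rotating_pool = list(rot_short, rot_long),
                 rotating_fraction = 1, spike_gain_hz = 40),
    seed = 17)
  truth <- attr(s, "truth")
  # instants labelled by the generating template's wavelength class
  idx <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    tibble::tibble(
      t = seq(truth$t_on[i], truth$t_off[i] - 1e-3, by = 1e-3),
      wavelength_class = ifelse(truth$k[i] >= 0.5, "short", "long"))
  })
  res <- spike_rate_by_wavelength(attr(s, "spikes"), idx, n_perm = 500)
  expect_false(is.null(res))
  r_short <- res$rate_hz[res$wavelength_class == "short"]
  r_long <- res$rate_hz[res$wavelength_class == "long"]
  expect_gt(r_short, r_long)
  expect_lt(attr(res, "p_value"), 0.01)

  # label-independent spikes: no significant difference (type-I control)
  set.seed(23)
  flat_spikes <- tibble::tibble(
    electrode = sample(64, 4000, replace = TRUE),
    t = runif(4000, 0, max(idx$t)))
  res0 <- spike_rate_by_wavelength(flat_spikes, idx, n_perm = 500)
  expect_gt(attr(res0, "p_value"), 0.01)

  # degenerate class: skipped with a warning
  expect_warning(
    out <- spike_rate_by_wavelength(attr(s, "spikes"),
                                    dplyr::filter(idx,
                                                  wavelength_class == "short"),
                                    n_perm = 100),
    "short")
  expect_null(out)
})
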