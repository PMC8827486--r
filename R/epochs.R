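#' Trial epoch layout
#'
#' Epoch windows in seconds relative to fixation onset: 0.5 s pre-fixation
#' baseline, 0.5 s fixation, 0.5 s sample, 2 s memory delay, 0.5 s test.
#'
#' @return Named list of `c(start, end)` windows.
#' @export
trial_epochs <- function() {
  list(baseline = c(-0.5, 0), fixation = c(0, 0.5), sample = c(0.5, 1),
       delay = c(1, 3), test = c(3, 3.5))
}

# map absolute times to (trial, t_rel) using each trial's fixation onset
relativize <- function(t, session, epochs = trial_epochs()) {
  fix <- session$events %>% filter(.data$event == "fixation_on")
  span <- c(min(purrr::map_dbl(epochs, 1)), max(purrr::map_dbl(epochs, 2)))
  trial <- rep(NA_integer_, length(t))
  t_rel <- rep(NA_real_, length(t))
  for (i in seq_len(nrow(fix))) {
    inside <- t >= fix$t[i] + span[1] & t < fix$t[i] + span[2]
    trial[inside] <- fix$trial[i]
    t_rel[inside] <- t[inside] - fix$t[i]
  }
  tibble(trial = trial, t_rel = t_rel)
}

epoch_of <- function(t_rel, epochs = trial_epochs()) {
  out <- rep(NA_character_, length(t_rel))
  for (en in names(epochs)) {
    out[t_rel >= epochs[[en]][1] & t_rel < epochs[[en]][2]] <- en
  }
  out
}

# paired two-sided permutation (sign-flip) p-values for columns of D
# (trials x bins of per-trial differences)
perm_p_matrix <- function(D, n_perm = 2000, seed = 1) {
  D[is.na(D)] <- 0
  n <- nrow(D)
  obs <- colMeans(D)
  with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    null <- (S %*% D) / n
    (colSums(sweep(abs(null), 2, abs(obs), `>=`)) + 1) / (n_perm + 1)
  })
}

#' Wave-count timecourse with baseline significance
#'
#' Bins wave events by time from fixation onset, averages counts across
#' trials, and marks bins whose count differs from the pre-fixation
#' baseline. Significance uses a two-sided trial permutation that
#' respects the counts' discreteness: under the null each bin's
#' per-trial count is exchangeable with that trial's baseline-bin counts,
#' so the null distribution is built by drawing a random baseline bin per
#' trial and recomputing the baseline-relative mean.
#'
#' @param events Wave events with a `t_start` column ([count_waves()]
#'   output, or the classified-event table).
#' @param session The [lfp_session()] providing trial events.
#' @param bin_ms Time-bin width, ms (default 20).
#' @param epochs Epoch layout.
#' @param n_perm Permutations (default 2000).
#' @param alpha Significance level (default 0.01).
#' @param seed Permutation seed.
#' @return Tibble of class `wave_count_timecourse`: `t_rel`, `mean_count`,
#'   `p`, `significant`, `above_baseline`.
#' @export
epoch_wave_counts <- function(events, session, bin_ms = 20,
                              epochs = trial_epochs(), n_perm = 2000,
                              alpha = 0.01, seed = 1) {
  span <- c(min(purrr::map_dbl(epochs, 1)), max(purrr::map_dbl(epochs, 2)))
  breaks <- seq(span[1], span[2], by = bin_ms / 1000)
  fix <- session$events %>% filter(.data$event == "fixation_on")
  n_trials <- nrow(fix)
  base_win <- epochs$baseline
  n_bins <- length(breaks) - 1

  counts <- matrix(0, n_trials, n_bins)
  if (nrow(events) > 0) {
    rel <- relativize(events$t_start, session, epochs)
    ok <- !is.na(rel$trial)
    if (any(ok)) {
      bin <- findInterval(rel$t_rel[ok], breaks, rightmost.closed = TRUE)
      tr <- rel$trial[ok]
      for (j in seq_along(bin)) counts[tr[j], bin[j]] <- counts[tr[j], bin[j]] + 1
    }
  }
  base_bins <- which(breaks[-length(breaks)] >= base_win[1] &
                     breaks[-length(breaks)] < base_win[2])
  B <- counts[, base_bins, drop = FALSE]
  base_rate <- rowMeans(B)
  obs <- colMeans(counts - base_rate)
  # null: per trial, a random baseline bin stands in for the tested bin;
  # the null statistic is shared by all bins
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(r) {
      pick <- B[cbind(seq_len(n_trials),
                      sample.int(ncol(B), n_trials, replace = TRUE))]
      mean(pick - base_rate)
    }, numeric(1))
  })
  p <- vapply(obs, function(o) (sum(abs(null) >= abs(o)) + 1) / (n_perm + 1),
              numeric(1))
  out <- tibble(
    t_rel = (breaks[-length(breaks)] + breaks[-1]) / 2,
    mean_count = colMeans(counts),
    p = p,
    significant = p < alpha,
    above_baseline = obs > 0
  )
  class(out) <- c("wave_count_timecourse", class(out))
  out
}

#' Polar histogram of wave directions
#'
#' @param directions_deg Azimuths in degrees (0 = rightward, 90 = towards
#'   the top of the array), e.g. the `direction_deg` column of classified
#'   events.
#' @param bin_deg Bin width, degrees (default 12, within the 10-15 degree
#'   polar-segment convention).
#' @return Tibble of class `direction_histogram`: `bin_mid_deg`, `count`,
#'   `prop`.
#' @export
direction_histogram <- function(directions_deg, bin_deg = 12) {
  directions_deg <- directions_deg[!is.na(directions_deg)] %% 360
  breaks <- seq(0, 360, by = bin_deg)
  if (360 %% bin_deg != 0) breaks <- c(breaks, 360)
  cnt <- if (length(directions_deg) == 0) integer(length(breaks) - 1) else
    as.integer(table(cut(directions_deg, breaks, right = FALSE,
                         include.lowest = TRUE)))
  out <- tibble(bin_mid_deg = (breaks[-length(breaks)] + breaks[-1]) / 2,
                count = cnt,
                prop = if (sum(cnt) > 0) cnt / sum(cnt) else 0 * cnt)
  class(out) <- c("direction_histogram", class(out))
  out
}

#' Align direction histograms on each array's preferred direction
#'
#' Rotates each array's histogram so its modal bin sits at 0 degrees and
#' averages the aligned proportions across arrays, preserving secondary
#' lobes (e.g. the opposite direction near 180 degrees).
#'
#' @param histograms A list of [direction_histogram()] tibbles (one per
#'   array), all with identical binning.
#' @return A `direction_histogram` tibble of aligned, averaged
#'   proportions.
#' @export
align_preferred <- function(histograms) {
  stopifnot(length(histograms) >= 1)
  aligned <- purrr::map(histograms, function(h) {
    shift <- which.max(h$prop) - 1L
    prop <- c(h$prop[-seq_len(shift)], h$prop[seq_len(shift)])
    if (shift == 0) prop <- h$prop
    prop
  })
  base <- histograms[[1]]
  out <- tibble(
    bin_mid_deg = (base$bin_mid_deg - base$bin_mid_deg[1]) %% 360,
    count = NA_integer_,
    prop = purrr::reduce(aligned, `+`) / length(aligned)
  )
  class(out) <- c("direction_histogram", class(out))
  out
}

#' Epoch-wise rho_c histograms against baseline
#'
#' Pools the circular-correlation timecourse by task epoch and compares
#' each epoch's normalized histogram with the pre-fixation baseline
#' histogram, marking bins that differ at `alpha` (paired trial
#' permutation). The chance zone is `(-threshold, threshold)`.
#'
#' @param rho_tbl Tibble `t`, `rho` from [rho_series()] (absolute time).
#' @param session The session providing trial events.
#' @param epochs_used Epoch names to compare against baseline (default
#'   sample, delay, test).
#' @param binwidth Histogram bin width (default 0.1).
#' @param epochs Epoch layout.
#' @param n_perm,alpha,seed Permutation settings.
#' @param threshold Chance threshold (default 0.3).
#' @return Tibble of class `rho_histograms`: `epoch`, `bin_mid`,
#'   `prop_epoch`, `prop_baseline`, `p`, `significant`.
#' @export
rho_histograms <- function(rho_tbl, session,
                           epochs_used = c("sample", "delay", "test"),
                           binwidth = 0.1, epochs = trial_epochs(),
                           n_perm = 2000, alpha = 0.01, seed = 1,
                           threshold = 0.3) {
  breaks <- seq(-1, 1, by = binwidth)
  mids <- (breaks[-length(breaks)] + breaks[-1]) / 2
  rel <- dplyr::bind_cols(rho_tbl, relativize(rho_tbl$t, session, epochs)) %>%
    filter(!is.na(.data$trial), !is.na(.data$rho)) %>%
    mutate(epoch = epoch_of(.data$t_rel, epochs),
           bin = findInterval(pmin(pmax(.data$rho, -1), 1), breaks,
                              rightmost.closed = TRUE))
  trials <- sort(unique(rel$trial))
  prop_mat <- function(ep) {
    # trials x bins matrix of per-trial bin proportions
    sub <- rel %>% filter(.data$epoch == ep)
    m <- matrix(0, length(trials), length(mids))
    for (i in seq_along(trials)) {
      b <- sub$bin[sub$trial == trials[i]]
      if (length(b) > 0) m[i, ] <- tabulate(b, length(mids)) / length(b)
    }
    m
  }
  base_m <- prop_mat("baseline")
  out <- purrr::map_dfr(epochs_used, function(ep) {
    ep_m <- prop_mat(ep)
    p <- perm_p_matrix(ep_m - base_m, n_perm = n_perm, seed = seed)
    tibble(epoch = ep, bin_mid = mids,
           prop_epoch = colMeans(ep_m), prop_baseline = colMeans(base_m),
           p = p, significant = p < alpha)
  })
  attr(out, "threshold") <- threshold
  class(out) <- c("rho_histograms", class(out))
  out
}

#' Direction-bias timecourse relative to baseline
#'
#' For consecutive 0.5 s intervals of the trial, the fraction of instants
#' whose rho_c exceeds `threshold` (positive direction) and falls below
#' `-threshold` (negative direction), each minus the corresponding
#' baseline fraction. A task-induced push of waves into the positive
#' direction shows as a positive red curve and negative blue curve.
#'
#' @inheritParams rho_histograms
#' @param interval Interval length, s (default 0.5).
#' @return Tibble of class `bias_timecourse`: `t_mid`, `d_positive`,
#'   `d_negative`, `se_positive`, `se_negative`.
#' @export
direction_bias_timecourse <- function(rho_tbl, session, interval = 0.5,
                                      threshold = 0.3,
                                      epochs = trial_epochs()) {
  span <- c(min(purrr::map_dbl(epochs, 1)), max(purrr::map_dbl(epochs, 2)))
  breaks <- seq(span[1], span[2], by = interval)
  rel <- dplyr::bind_cols(rho_tbl, relativize(rho_tbl$t, session, epochs)) %>%
    filter(!is.na(.data$trial), !is.na(.data$rho))
  base <- rel %>%
    filter(.data$t_rel >= epochs$baseline[1], .data$t_rel < epochs$baseline[2]) %>%
    group_by(.data$trial) %>%
    summarise(fp = mean(.data$rho > threshold),
              fn = mean(.data$rho < -threshold), .groups = "drop")
  per <- rel %>%
    mutate(iv = findInterval(.data$t_rel, breaks, rightmost.closed = TRUE)) %>%
    group_by(.data$trial, .data$iv) %>%
    summarise(fp = mean(.data$rho > threshold),
              fn = mean(.data$rho < -threshold), .groups = "drop") %>%
    left_join(base, by = "trial", suffix = c("", "_base")) %>%
    mutate(dp = .data$fp - .data$fp_base, dn = .data$fn - .data$fn_base)
  out <- per %>%
    group_by(.data$iv) %>%
    summarise(d_positive = mean(.data$dp), d_negative = mean(.data$dn),
              se_positive = sd(.data$dp) / sqrt(n()),
              se_negative = sd(.data$dn) / sqrt(n()), .groups = "drop") %>%
    mutate(t_mid = (breaks[.data$iv] + breaks[.data$iv + 1]) / 2) %>%
    select("t_mid", "d_positive", "d_negative", "se_positive", "se_negative")
  class(out) <- c("bias_timecourse", class(out))
  out
}

#' Separate standing from traveling and unstructured instants
#'
#' Non-wave instants (those without a detector label) are split by the
#' circular standard deviation of their phase maps: a two-component
#' partition of the non-wave phase-SD distribution defines a cutoff, and
#' non-wave instants below it are `standing` (coherent oscillations with
#' little phase gradient), the rest `neither`. Detected instants are
#' labeled `traveling`.
#'
#' @param pms A [phase_map_series].
#' @param wave_samples Integer sample indices carrying a wave (detector
#'   or rho_c-threshold labels).
#' @return Tibble of class `standing_wave_table`: `sample`, `t`,
#'   `phase_sd`, `label`; the SD cutoff is in `attr(, "cutoff")`.
#' @export
standing_wave_instants <- function(pms, wave_samples = integer()) {
  stopifnot(inherits(pms, "phase_map_series"))
  P <- matrix(pms$phase, nrow = 64)
  sds <- apply(P, 2, circ_sd)
  lab <- rep("neither", ncol(P))
  lab[wave_samples] <- "traveling"
  nonwave <- setdiff(seq_len(ncol(P)), wave_samples)
  cutoff <- NA_real_
  if (length(nonwave) >= 4 && sd(sds[nonwave]) > 0) {
    km <- kmeans(sds[nonwave], centers = 2, nstart = 5)
    cutoff <- mean(km$centers)
    lab[nonwave][sds[nonwave] < cutoff] <- "standing"
  }
  out <- tibble(sample = seq_len(ncol(P)),
                t = pms$t0 + (seq_len(ncol(P)) - 1) / pms$fs,
                phase_sd = sds, label = lab)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("standing_wave_table", class(out))
  out
}

#' Spike rate by wavelength class
#'
#' Compares the mean per-electrode spike rate during short-wavelength
#' versus long-wavelength wave instants with a two-sided permutation test
#' on the instant labels. Higher rates at short wavelengths indicate
#' stronger spiking near rotating-wave cores.
#'
#' @param spikes Tibble `electrode`, `t` (seconds).
#' @param classified Classified instants: tibble with `t` and
#'   `wavelength_class` (`"short"`/`"long"`; `NA` ignored).
#' @param fs Sampling rate used to discretize instants (default 1000).
#' @param n_perm,seed Permutation settings.
#' @return Tibble `wavelength_class`, `n_instants`, `rate_hz`, with the
#'   permutation p-value in `attr(, "p_value")`; `NULL` (with a warning)
#'   if a class is empty or there are no spikes.
#' @export
spike_rate_by_wavelength <- function(spikes, classified, fs = 1000,
                                     n_perm = 2000, seed = 1) {
  cls <- classified %>% filter(.data$wavelength_class %in% c("short", "long"))
  if (nrow(cls) == 0 || length(unique(cls$wavelength_class)) < 2) {
    warn("need both short- and long-wavelength instants; comparison skipped")
    return(NULL)
  }
  if (is.null(spikes) || nrow(spikes) == 0) {
    warn("no spikes; comparison skipped")
    return(NULL)
  }
  n_elec <- length(unique(spikes$electrode))
  samp <- round(cls$t * fs)
  spk_samp <- round(spikes$t * fs)
  n_spk <- vapply(samp, function(s) sum(spk_samp == s), numeric(1))
  is_short <- cls$wavelength_class == "short"
  rate <- function(mask) sum(n_spk[mask]) / (sum(mask) / fs) / n_elec
  obs <- rate(is_short) - rate(!is_short)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      m <- sample(is_short)
      rate(m) - rate(!m)
    }, numeric(1))
  })
  p <- (sum(abs(null) >= abs(obs)) + 1) / (n_perm + 1)
  out <- tibble(
    wavelength_class = c("short", "long"),
    n_instants = c(sum(is_short), sum(!is_short)),
    rate_hz = c(rate(is_short), rate(!is_short))
  )
  attr(out, "p_value") <- p
  out
}
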