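#' Run the full traveling-wave analysis pipeline
#'
#' Orchestrates preprocessing, planar detection, circular classification,
#' speed estimation and epoch statistics for one session and band:
#' phase maps -> quadrant detection -> wave events -> three-point
#' fingerprints and library classification -> wave speeds at
#' long-wavelength instants -> wave-count timecourse, rho_c histograms
#' and direction-bias timecourse. All stages are deterministic given the
#' configuration and `seed`; the result carries a manifest with the
#' configuration hash.
#'
#' @param session An [lfp_session()].
#' @param band Band name or numeric `c(lo, hi)`.
#' @param library A [build_reference_library()] (built with `seed` if
#'   omitted).
#' @param origin Rotation-map origin for the direction-bias analyses
#'   (default `c(4, 4)`; per-array choices maximize observed waves).
#' @param flip_sign Orient the task-enhanced direction positive.
#' @param threshold Chance threshold for rho_c analyses (default 0.3).
#' @param classify_step Fingerprint/classify every `classify_step`-th
#'   sample (default 5, i.e. 5 ms at 1 kHz) to bound runtime.
#' @param n_perm Permutations for epoch statistics.
#' @param seed Seed for library building and permutation tests.
#' @return A `wave_analysis` list: `phase` ([phase_map_series]),
#'   `detections`, `events`, `classified`, `speeds`, `counts`,
#'   `rho_hist`, `bias`, `manifest`.
#' @export
run_wave_pipeline <- function(session, band = "beta", library = NULL,
                              origin = c(4, 4), flip_sign = FALSE,
                              threshold = 0.3, classify_step = 5,
                              n_perm = 2000, seed = 1) {
  stopifnot(inherits(session, "lfp_session"))
  config <- list(band = band, origin = origin, flip_sign = flip_sign,
                 threshold = threshold, classify_step = classify_step,
                 n_perm = n_perm, seed = seed,
                 fs = session$fs, n_samples = ncol(session$voltage))
  library <- library %||% build_reference_library(seed = seed)

  pms <- phase_maps(session, band)
  detections <- detect_planar(pms)
  events <- count_waves(detections, fs = session$fs)
  rho <- rho_series(pms, origin = origin, flip_sign = flip_sign)

  at <- seq(1L, dim(pms$phase)[3], by = classify_step)
  fp <- wave_fingerprint(pms, at = at)
  classified <- classify_waves(fp, library, threshold = threshold)

  long_at <- at[which(!is.na(classified$wavelength_class) &
                      classified$wavelength_class == "long")]
  nt <- dim(pms$phase)[3]
  long_at <- long_at[long_at >= 2 & long_at <= nt - 1]
  speeds <- if (length(long_at) > 0)
    wave_speed(pms, at = long_at, pitch_um = session$pitch_um)
  else tibble(sample = integer(), t = numeric(), speed_cm_s = numeric(),
              n_sites = integer(), valid = logical())

  has_trials <- nrow(session$events) > 0
  counts <- if (has_trials)
    epoch_wave_counts(events, session, n_perm = n_perm, seed = seed) else NULL
  rho_hist <- if (has_trials)
    rho_histograms(rho, session, n_perm = n_perm, seed = seed,
                   threshold = threshold) else NULL
  bias <- if (has_trials)
    direction_bias_timecourse(rho, session, threshold = threshold) else NULL

  structure(
    list(phase = pms, detections = detections, events = events,
         rho = rho, classified = classified, speeds = speeds,
         counts = counts, rho_hist = rho_hist, bias = bias,
         library = library,
         manifest = list(
           config = config,
           config_hash = rlang::hash(config),
           library_seed = attr(library, "seed"),
           package_version = as.character(utils::packageVersion("wavemap")),
           stages = c("preprocess", "detect", "classify", "kinematics",
                      "epoch_statistics"))),
    class = "wave_analysis"
  )
}

#' @export
print.wave_analysis <- function(x, ...) {
  cat("<wave_analysis>\n")
  cat(sprintf("  band %s, %d detected instants, %d wave events\n",
              x$phase$band %||% "?", nrow(x$detections), nrow(x$events)))
  cl <- x$classified
  cat(sprintf("  classified instants: %d planar, %d rotating, %d none\n",
              sum(cl$kind == "planar"), sum(cl$kind == "rotating"),
              sum(cl$kind == "none")))
  if (nrow(x$speeds) > 0)
    cat(sprintf("  median long-wavelength speed %.1f cm/s\n",
                stats::median(x$speeds$speed_cm_s, na.rm = TRUE)))
  cat(sprintf("  config hash %s\n", x$manifest$config_hash))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wave_analysis <- function(x, ...) {
  x$classified %>%
    left_join(x$speeds %>% select("t", "speed_cm_s"), by = "t")
}

#' @exportS3Method generics::glance
glance.wave_analysis <- function(x, ...) {
  cl <- x$classified
  tibble(
    n_instants = nrow(cl),
    n_planar = sum(cl$kind == "planar"),
    n_rotating = sum(cl$kind == "rotating"),
    prop_wave = mean(cl$kind != "none"),
    n_events = nrow(x$events),
    median_speed_cm_s = if (nrow(x$speeds) > 0)
      stats::median(x$speeds$speed_cm_s, na.rm = TRUE) else NA_real_,
    config_hash = x$manifest$config_hash
  )
}
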