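#' Analysis frequency bands
#'
#' Default band definitions: theta 4-8, alpha 8-12, beta 12-30 and gamma
#' 40-120 Hz.
#'
#' @return A tibble with columns `band`, `lo`, `hi` (Hz).
#' @examples
#' wave_bands()
#' @export
wave_bands <- function() {
  tibble(band = c("theta", "alpha", "beta", "gamma"),
         lo = c(4, 8, 12, 40), hi = c(8, 12, 30, 120))
}

band_edges <- function(band, bands = wave_bands()) {
  if (is.numeric(band) && length(band) == 2) {
    return(list(band = sprintf("%g-%gHz", band[1], band[2]),
                lo = band[1], hi = band[2]))
  }
  row <- bands[bands$band == band, ]
  if (nrow(row) != 1) abort(sprintf("unknown band '%s'", band),
                            class = "wavemap_invalid")
  list(band = row$band, lo = row$lo, hi = row$hi)
}

#' Multielectrode LFP session
#'
#' Container for one recording session: a voltage matrix (electrodes x
#' samples, microvolts, 1 kHz by default), the electrode-to-grid map of an
#' 8x8 array at 400 um pitch, any missing grid sites, and per-trial task
#' event times. Grid coordinates are `(x, y)` with `y` the row counted
#' from the top (see [grid_sites()]).
#'
#' @param voltage Numeric matrix, electrodes x samples.
#' @param fs Sampling rate, Hz (default 1000).
#' @param grid_map Tibble/data frame with columns `electrode`, `x`, `y`
#'   mapping each voltage row to a grid site. Default: row-major order
#'   over the full 8x8 grid.
#' @param missing Data frame with columns `x`, `y` of grid sites without
#'   an electrode (at most a few; arrays typically lose one to three).
#' @param events Tibble with columns `trial`, `event`, `t` (seconds from
#'   session start). Standard events: `fixation_on`, `sample_on`,
#'   `sample_off`, `test_on`.
#' @param pitch_um Inter-electrode distance, micrometres (default 400).
#' @param array_label Free-text anatomical annotation.
#' @param acquisition Optional metadata list (e.g. the hardware filter
#'   chain); recorded, never re-applied.
#' @return An object of class `lfp_session`.
#' @export
lfp_session <- function(voltage, fs = 1000,
                        grid_map = NULL, missing = NULL, events = NULL,
                        pitch_um = 400, array_label = "",
                        acquisition = NULL) {
  voltage <- as.matrix(voltage)
  missing <- if (is.null(missing)) tibble(x = integer(), y = integer())
             else as_tibble(missing)
  if (is.null(grid_map)) {
    full <- grid_sites()
    keep <- !(paste(full$x, full$y) %in% paste(missing$x, missing$y))
    grid_map <- dplyr::bind_cols(tibble(electrode = seq_len(sum(keep))),
                                 full[keep, ])
  }
  grid_map <- as_tibble(grid_map)
  events <- if (is.null(events)) tibble(trial = integer(), event = character(),
                                        t = numeric())
            else as_tibble(events)

  # -- invariants --
  if (anyDuplicated(grid_map[, c("x", "y")]))
    abort("duplicate grid coordinates in grid_map", class = "wavemap_invalid")
  if (any(grid_map$x < 1 | grid_map$x > 8 | grid_map$y < 1 | grid_map$y > 8))
    abort("grid coordinates must lie in 1..8", class = "wavemap_invalid")
  if (nrow(grid_map) != nrow(voltage))
    abort("grid_map must have one row per voltage row", class = "wavemap_invalid")
  covered <- paste(grid_map$x, grid_map$y)
  gaps <- paste(grid_sites()$x, grid_sites()$y)
  gaps <- gaps[!(gaps %in% covered) & !(gaps %in% paste(missing$x, missing$y))]
  if (length(gaps) > 0)
    abort("every non-missing lattice site needs exactly one electrode",
          class = "wavemap_invalid")
  if (nrow(events) > 0) {
    bad <- events %>% group_by(.data$trial) %>%
      summarise(ok = !is.unsorted(.data$t, strictly = TRUE)) %>%
      filter(!.data$ok)
    if (nrow(bad) > 0)
      abort("event times must be strictly increasing within each trial",
            class = "wavemap_invalid")
  }

  structure(
    list(voltage = voltage, fs = fs, grid_map = grid_map, missing = missing,
         events = events, pitch_um = pitch_um, array_label = array_label,
         acquisition = acquisition),
    class = "lfp_session"
  )
}

#' @export
print.lfp_session <- function(x, ...) {
  cat(sprintf("<lfp_session> %d electrodes x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$voltage), ncol(x$voltage), x$fs, ncol(x$voltage) / x$fs))
  cat(sprintf("  8x8 grid, pitch %g um, %d missing site(s), %d trial(s)%s\n",
              x$pitch_um, nrow(x$missing),
              length(unique(x$events$trial)),
              if (nzchar(x$array_label)) paste0(", ", x$array_label) else ""))
  invisible(x)
}

# internal constructor for phase/amplitude movies on the full grid
new_phase_map_series <- function(phase, amplitude, fs, band = NULL, t0 = 0) {
  structure(list(phase = phase, amplitude = amplitude, fs = fs,
                 band = band, t0 = t0),
            class = "phase_map_series")
}

#' @export
print.phase_map_series <- function(x, ...) {
  cat(sprintf("<phase_map_series> 8x8 x %d samples @ %g Hz%s\n",
              dim(x$phase)[3], x$fs,
              if (!is.null(x$band)) paste0(", band ", x$band) else ""))
  invisible(x)
}

#' Tidy a phase-map series
#'
#' @param x A `phase_map_series`.
#' @param at Sample indices to extract (default: all; beware size).
#' @param ... Unused.
#' @return Tibble with columns `t`, `x`, `y`, `phase`, `amplitude`.
#' @exportS3Method generics::tidy
tidy.phase_map_series <- function(x, at = NULL, ...) {
  nt <- dim(x$phase)[3]
  at <- at %||% seq_len(nt)
  g <- grid_sites()
  purrr::map_dfr(at, function(i) {
    ph <- x$phase[, , i]
    am <- x$amplitude[, , i]
    tibble(t = x$t0 + (i - 1) / x$fs, x = g$x, y = g$y,
           phase = ph[cbind(g$y, g$x)], amplitude = am[cbind(g$y, g$x)])
  })
}

#' Write / read a session as plain text
#'
#' Serializes an [lfp_session()] to a directory: `lfp.csv` (electrodes x
#' samples), `grid_map.csv`, `missing.csv`, `events.csv` (columns
#' `trial,event,t`) and `meta.json` (`fs`, `pitch_um`, `array_label`).
#'
#' @param session An `lfp_session`.
#' @param dir Directory path (created if needed).
#' @return `dir` (write) or the restored `lfp_session` (read).
#' @export
write_lfp_session <- function(session, dir) {
  stopifnot(inherits(session, "lfp_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(session$voltage),
            file.path(dir, "lfp.csv"), row.names = FALSE)
  write.csv(session$grid_map, file.path(dir, "grid_map.csv"), row.names = FALSE)
  write.csv(session$missing, file.path(dir, "missing.csv"), row.names = FALSE)
  write.csv(session$events, file.path(dir, "events.csv"), row.names = FALSE)
  jsonlite::write_json(list(fs = session$fs, pitch_um = session$pitch_um,
                            array_label = session$array_label),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_lfp_session
#' @export
read_lfp_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  ev <- read.csv(file.path(dir, "events.csv"))
  # accept the alternative events dialect trial,event,name,t
  if ("name" %in% names(ev) && !("event" %in% names(ev)))
    ev <- dplyr::rename(ev, event = "name")
  lfp_session(
    voltage = as.matrix(read.csv(file.path(dir, "lfp.csv"))),
    fs = meta$fs,
    grid_map = read.csv(file.path(dir, "grid_map.csv")),
    missing = read.csv(file.path(dir, "missing.csv")),
    events = ev,
    pitch_um = meta$pitch_um, array_label = meta$array_label %||% ""
  )
}
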