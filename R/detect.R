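the_threshold_cache <- new.env(parent = emptyenv())

#' Spatial-shuffling null threshold
#'
#' Estimates the chance level of a wave-detection statistic by randomly
#' shuffling phase values across the array and taking a percentile
#' (default the 99th) of the absolute correlation with the template
#' family. Three families are supported:
#' \describe{
#'   \item{`"rotation"`}{circular-circular correlation against a rotation
#'     map, full 64-site array; the null 99th percentile is about 0.3,
#'     the operational chance threshold for all rho_c analyses.}
#'   \item{`"distance"`}{Pearson correlation against a full-array
#'     Euclidean distance map; also about 0.3.}
#'   \item{`"quadrant"`}{the per-quadrant Pearson statistic actually used
#'     by [detect_planar()] (16 sites, positive-phase mask, minimum site
#'     count); its null percentile is much higher than the full-array
#'     value because of the smaller site count.}
#' }
#' Results are cached per configuration.
#'
#' @param family Template family (above).
#' @param n_shuffles Number of shuffles (>= 100 enforced; default 10000).
#' @param percentile Percentile of the null |correlation| (default 99).
#' @param phases Optional phases to shuffle: a numeric vector/matrix of
#'   angles (e.g. observed phase maps). Default: uniform random phases.
#'   Degenerate (zero-variance) draws are skipped with a warning.
#' @param min_sites Quadrant family: minimum positive-phase sites.
#' @param seed RNG seed for reproducible thresholds (default 1).
#' @return The threshold (single number).
#' @examples
#' \donttest{
#' shuffle_threshold("rotation", n_shuffles = 1000)
#' }
#' @export
shuffle_threshold <- function(family = c("rotation", "distance", "quadrant"),
                              n_shuffles = 10000, percentile = 99,
                              phases = NULL, min_sites = 6, seed = 1) {
  family <- match.arg(family)
  if (n_shuffles < 100)
    abort("need at least 100 shuffles for a stable percentile",
          class = "wavemap_invalid")
  key <- paste(family, n_shuffles, percentile, min_sites, seed,
               is.null(phases), sep = "|")
  if (is.null(phases) && !is.null(the_threshold_cache[[key]]))
    return(the_threshold_cache[[key]])

  pool <- if (!is.null(phases)) as.numeric(phases) else NULL
  if (!is.null(pool) && sd(pool) <= .Machine$double.eps) {
    warn("constant phase map: shuffle skipped, no threshold computed")
    return(NA_real_)
  }
  draw <- function() if (is.null(pool)) runif(64, -pi, pi) else sample(pool, 64)

  th <- as.numeric(rotation_map(c(4, 4)))
  ok <- !is.na(th)
  s2 <- sin(wrap_angle(th[ok] - circ_mean(th[ok])))
  dmap <- as.numeric(distance_map(pi / 4))
  qt <- quadrant_templates()
  qmap <- as.numeric(qt$dst_map[[which(qt$label == "BL>TR")]])
  qok <- !is.na(qmap)

  vals <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      p <- draw()
      switch(family,
        rotation = {
          s1 <- sin(wrap_angle(p[ok] - circ_mean(p[ok])))
          abs(sum(s1 * s2) / sqrt(sum(s1^2) * sum(s2^2)))
        },
        distance = abs(cor(p, dmap)),
        quadrant = {
          m <- qok & p >= 0 & p < pi
          if (sum(m) < min_sites) NA_real_ else abs(cor(p[m], qmap[m]))
        })
    }, numeric(1))
  })
  vals <- vals[!is.na(vals)]
  out <- as.numeric(quantile(vals, percentile / 100))
  if (is.null(phases)) the_threshold_cache[[key]] <- out
  out
}

# masked Pearson correlations of each column of P (sites x time) with map,
# using only sites where P is in [0, pi); returns NA where fewer than
# min_sites qualify or the variance degenerates
masked_cor_series <- function(P, map, min_sites) {
  keep <- !is.na(map)
  P <- P[keep, , drop = FALSE]
  d <- map[keep]
  M <- (P >= 0 & P < pi) * 1
  M[is.na(M)] <- 0
  n <- .colSums(M, nrow(M), ncol(M))
  P0 <- P * M
  P0[is.na(P0)] <- 0
  sx <- .colSums(P0, nrow(P0), ncol(P0))
  sxx <- .colSums(P0^2, nrow(P0), ncol(P0))
  sd_ <- as.numeric(crossprod(M, d))
  sdd <- as.numeric(crossprod(M, d^2))
  sxd <- as.numeric(crossprod(P0, d))
  vx <- n * sxx - sx^2
  vd <- n * sdd - sd_^2
  r <- (n * sxd - sx * sd_) / sqrt(pmax(vx, 0) * pmax(vd, 0))
  r[n < min_sites | vx <= 1e-12 | vd <= 1e-12] <- NA_real_
  r
}

#' Detect planar traveling-wave instants
#'
#' Correlates each instantaneous phase map with the quadrant Euclidean
#' distance maps ([quadrant_templates()]). Only sites whose phase lies in
#' `[0, pi)` (approaching the oscillation peak) are used, which restricts
#' the method to wavelengths long relative to the array but separates
#' consecutive wave traversals. A direction label fires at an instant when
#' the source quadrant correlates below `-threshold` and the destination
#' quadrant above `+threshold`; several labels may fire for one wave.
#'
#' @param pms A [phase_map_series].
#' @param threshold Detection threshold on the per-quadrant correlation.
#'   Default: the quadrant family's shuffling null
#'   (`shuffle_threshold("quadrant")`).
#' @param templates Direction templates (default [quadrant_templates()]).
#' @param min_sites Minimum positive-phase sites per quadrant (default 6).
#' @param at Optional sample indices to evaluate.
#' @return Tibble of firing instants: `sample`, `t`, `label`, `azimuth`,
#'   `r_src`, `r_dst`.
#' @export
detect_planar <- function(pms, threshold = NULL,
                          templates = quadrant_templates(),
                          min_sites = 6, at = NULL) {
  stopifnot(inherits(pms, "phase_map_series"))
  threshold <- threshold %||% shuffle_threshold("quadrant", min_sites = min_sites)
  P <- matrix(pms$phase, nrow = 64)
  if (!is.null(at)) P <- P[, at, drop = FALSE] else at <- seq_len(ncol(P))

  # per-(quadrant, azimuth) masked correlations, shared across labels
  combos <- unique(rbind(
    data.frame(q = templates$src, az = wrap_angle(templates$azimuth + pi)),
    data.frame(q = templates$dst, az = templates$azimuth)
  ))
  masks <- quadrant_masks()
  cors <- purrr::pmap(combos, function(q, az) {
    m <- planar_phase_input(az)
    m[!masks[[q]]] <- NA_real_
    masked_cor_series(P, as.numeric(m), min_sites)
  })
  ckey <- paste(round(combos$az, 10), combos$q)
  names(cors) <- ckey

  purrr::map_dfr(seq_len(nrow(templates)), function(i) {
    rs <- cors[[paste(round(wrap_angle(templates$azimuth[i] + pi), 10),
                      templates$src[i])]]
    rd <- cors[[paste(round(templates$azimuth[i], 10), templates$dst[i])]]
    hit <- which(!is.na(rs) & !is.na(rd) & rs < -threshold & rd > threshold)
    tibble(sample = at[hit],
           t = pms$t0 + (at[hit] - 1) / pms$fs,
           label = templates$label[i], azimuth = templates$azimuth[i],
           r_src = rs[hit], r_dst = rd[hit])
  })
}

#' Merge detection instants into wave events
#'
#' Applies a sliding window (20 ms by default, stepping one sample) over
#' the detection timecourse of each direction label: a window is active if
#' any instant inside it fired, and one wave event is a maximal run of
#' contiguous active windows. Two traversals separated by a sub-threshold
#' gap longer than the window therefore yield two events.
#'
#' @param detections Output of [detect_planar()].
#' @param fs Sampling rate, Hz.
#' @param window_ms Window length, ms (default 20).
#' @param t0 Time of sample 1 (default 0).
#' @return Tibble of events: `label`, `azimuth`, `t_start`, `t_end`,
#'   `n_instants`.
#' @export
count_waves <- function(detections, fs = 1000, window_ms = 20, t0 = 0) {
  if (nrow(detections) == 0)
    return(tibble(label = character(), azimuth = numeric(),
                  t_start = numeric(), t_end = numeric(),
                  n_instants = integer()))
  win <- max(1L, round(window_ms / 1000 * fs))
  detections %>%
    group_by(.data$label, .data$azimuth) %>%
    dplyr::group_modify(function(d, key) {
      s <- sort(unique(d$sample))
      # instants closer than one window belong to the same traversal
      brk <- c(0L, which(diff(s) > win))
      purrr::map_dfr(seq_along(brk), function(j) {
        lo <- brk[j] + 1L
        hi <- if (j < length(brk)) brk[j + 1L] else length(s)
        tibble(t_start = t0 + (s[lo] - 1) / fs,
               t_end = t0 + (s[hi] - 1) / fs,
               n_instants = hi - lo + 1L)
      })
    }) %>%
    ungroup()
}
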