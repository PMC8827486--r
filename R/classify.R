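#' Classify wave fingerprints against the reference library
#'
#' Each observed three-point fingerprint is a point in 3-D coefficient
#' space; it is assigned to the reference wave type at minimal Euclidean
#' distance. Instants whose largest absolute coefficient does not exceed
#' the chance threshold are left unclassified (`kind = "none"`). Exact
#' distance ties are broken towards the planar entry (and reported via a
#' message).
#'
#' @param fingerprints Tibble with columns `rho_44`, `rho_14`, `rho_41`
#'   (e.g. from [wave_fingerprint()]); other columns are carried through.
#' @param library A [build_reference_library()] result.
#' @param threshold Chance threshold (default 0.3).
#' @return The input with columns `kind` (`"planar"`, `"rotating"`,
#'   `"none"`), `matched_template`, `direction_deg`, `wavelength_class`
#'   and `euclid_dist` appended.
#' @examples
#' \donttest{
#' lib <- build_reference_library(seed = 1)
#' mov <- simulate_wave(wave_template("planar", direction = 0, sigma = 0),
#'                      duration = 0.2)
#' classify_waves(wave_fingerprint(mov, at = 1), lib)
#' }
#' @export
classify_waves <- function(fingerprints, library, threshold = 0.3) {
  if (!inherits(library, "reference_library") || nrow(library) == 0)
    abort("a non-empty reference_library is required",
          class = "wavemap_config")
  need <- c("rho_44", "rho_14", "rho_41")
  if (!all(need %in% names(fingerprints)))
    abort("fingerprints must have rho_44, rho_14, rho_41 columns",
          class = "wavemap_invalid")
  Fp <- as.matrix(fingerprints[, need])
  L <- as.matrix(library[, need])
  # squared distances, n x 72
  D2 <- outer(rowSums(Fp^2), rep(1, nrow(L))) -
    2 * Fp %*% t(L) + outer(rep(1, nrow(Fp)), rowSums(L^2))
  D2 <- pmax(D2, 0)
  is_planar <- library$kind == "planar"
  best <- integer(nrow(Fp)); ties <- 0L
  for (i in seq_len(nrow(Fp))) {
    d <- D2[i, ]
    cand <- which(d <= min(d) + 1e-12)
    if (length(cand) > 1) {
      ties <- ties + 1L
      pl <- cand[is_planar[cand]]
      cand <- if (length(pl) > 0) pl else cand
    }
    best[i] <- cand[1]
  }
  if (ties > 0)
    rlang::inform(sprintf("%d classification tie(s) broken towards planar", ties))
  chance <- unname(pmax(abs(Fp[, 1]), abs(Fp[, 2]), abs(Fp[, 3])) <= threshold)
  out <- fingerprints
  out$kind <- ifelse(chance, "none", library$kind[best])
  out$matched_template <- ifelse(chance, NA_integer_, library$template_id[best])
  out$direction_deg <- ifelse(chance, NA_real_, library$direction_deg[best])
  out$wavelength_class <- ifelse(chance, NA_character_,
                                 library$wavelength_class[best])
  out$euclid_dist <- ifelse(chance, NA_real_, sqrt(D2[cbind(seq_len(nrow(Fp)), best)]))
  out
}
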