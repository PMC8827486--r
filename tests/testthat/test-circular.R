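test_that("circular correlation matches its defining symmetries", {
  th <- rotation_map(c(4, 4))
  expect_equal(circ_corr(th, th), 1)
  expect_equal(circ_corr(-as.numeric(th), th), -1)

  # invariant under adding a constant angle; sign flip under negation
  phi <- wavemap:::wrap_angle(0.4 * planar_phase_input(pi / 3))
  expect_equal(circ_corr(wavemap:::wrap_angle(phi + 1.3), th),
               circ_corr(phi, th), tolerance = 1e-12)
  expect_equal(circ_corr(wavemap:::wrap_angle(-phi), th),
               -circ_corr(phi, th), tolerance = 1e-12)

  # degenerate inputs refuse cleanly
  expect_error(circ_corr(matrix(0.5, 8, 8), th), class = "wavemap_degenerate")
})

test_that("circ_corr agrees with a brute-force Fisher-Lee oracle", {
  # independent textbook implementation, written against the formula
  oracle <- function(a, b) {
    am <- atan2(sum(sin(a)), sum(cos(a)))
    bm <- atan2(sum(sin(b)), sum(cos(b)))
    sa <- sin(a - am); sb <- sin(b - bm)
    sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
  }
  th <- rotation_map(c(4, 4))
  ok <- !is.na(th)
  phi <- wavemap:::wrap_angle(0.62 * planar_phase_input(pi / 4))
  expect_equal(circ_corr(phi, th), oracle(phi[ok], as.numeric(th)[ok]),
               tolerance = 1e-12)

  # fuzz: bounded in [-1, 1] for arbitrary phase maps and matching oracle
  set.seed(11)
  for (i in 1:25) {
    p <- runif(64, -pi, pi)
    r <- circ_corr(p, th)
    expect_true(abs(r) <= 1)
    expect_equal(r, oracle(p[ok], as.numeric(th)[ok]), tolerance = 1e-12)
  }
})

test_that("the worked-example fingerprints separate planar from rotating", {
  # noise-free diagonal planar wave: high central coefficient,
  # intermediate top-edge coefficient
  fp <- template_fingerprint(wave_template("planar", direction = pi / 4,
                                           sigma = 0), n_reps = 1)
  expect_equal(fp$rho_44, 0.9, tolerance = 0.07)
  expect_equal(fp$rho_41, 0.64, tolerance = 0.09)
  expect_equal(fp$rho_14, fp$rho_41, tolerance = 1e-6)  # mirror symmetry

  # direction antisymmetry: the reversed wave negates every coefficient
  fpr <- template_fingerprint(wave_template("planar", direction = 5 * pi / 4,
                                            sigma = 0), n_reps = 1)
  expect_equal(as.numeric(fpr), -as.numeric(fp), tolerance = 1e-9)

  # a rotating wave with the same net direction keeps the central
  # coefficient but lowers the edge coefficient
  rot <- template_fingerprint(
    wave_template("rotating", center = c(0.5, 0.5) - 1 / sqrt(2), k = 0.7,
                  sigma = 0), n_reps = 1)
  expect_equal(rot$rho_44, fp$rho_44, tolerance = 0.08)
  expect_lt(rot$rho_41, fp$rho_41 - 0.02)
})

test_that("direction_sign applies the exclusive 0.3 chance threshold", {
  s <- direction_sign(c(0.5, -0.31, 0.29, 0.3, -0.3))
  expect_equal(as.character(s),
               c("positive", "negative", "chance", "chance", "chance"))
})

test_that("classification recovers library templates and flags chance", {
  lib <- cached_library()
  expect_error(classify_waves(tibble::tibble(rho_44 = 0, rho_14 = 0,
                                             rho_41 = 0),
                              structure(lib[0, ], class = class(lib))),
               class = "wavemap_config")

  # chance zone: all-zero fingerprint is unclassified
  none <- classify_waves(tibble::tibble(rho_44 = 0, rho_14 = 0, rho_41 = 0),
                         lib)
  expect_equal(none$kind, "none")

  # noise-free self-classification of a noise-free library is exact
  lib0 <- build_reference_library(sigma = 0, n_noise_reps = 1, seed = 1)
  cls <- classify_waves(lib0[, c("rho_44", "rho_14", "rho_41")], lib0)
  expect_equal(cls$kind, lib0$kind)
  expect_equal(cls$matched_template, lib0$template_id)
  expect_true(all(
    cls$direction_deg == lib0$direction_deg |
      (is.na(cls$direction_deg) & is.na(lib0$direction_deg))))

  # at sigma = 0.25 A, kind recovery over draws from the library templates
  # stays high (Monte-Carlo recovery experiment)
  tpls <- attr(lib, "templates")
  set.seed(99)
  draws <- sample(length(tpls), 100, replace = TRUE)
  fps <- purrr::map_dfr(draws, function(i) {
    template_fingerprint(tpls[[i]], n_reps = 1)
  })
  got <- classify_waves(fps, lib)$kind
  expect_gte(mean(got == purrr::map_chr(tpls[draws], "kind")), 0.9)
})

test_that("rotating fingerprints lose structure as wavelength grows", {
  lib <- cached_library()
  rot <- lib[lib$kind == "rotating", ]
  for (cx in unique(paste(rot$center_x, rot$center_y))) {
    sub <- rot[paste(rot$center_x, rot$center_y) == cx, ]
    sub <- sub[order(sub$k), ]
    for (col in c("rho_44", "rho_14", "rho_41")) {
      lo <- abs(sub[[col]][1]); hi <- abs(sub[[col]][nrow(sub)])
      # structured coefficients decay towards k = 0.1; coefficients on a
      # bisecting axis stay at chance level throughout
      expect_true(lo < hi + 0.05 || (lo < 0.1 && hi < 0.1))
    }
    # aggregate trend: magnitudes grow with k
    mags <- rowMeans(abs(sub[, c("rho_44", "rho_14", "rho_41")]))
    expect_gt(stats::cor(sub$k, mags, method = "spearman"), 0.5)
  }
})

test_that("origin choice does not drive the planar/rotating split", {
  # classify noisy instants twice, with the canonical origin triple and an
  # alternative one; the planar/rotating assignment should rarely differ
  alt <- list(rho_44 = c(5, 5), rho_14 = c(1, 5), rho_41 = c(5, 1))
  lib0 <- build_reference_library(sigma = 0, n_noise_reps = 1, seed = 1)
  tpls <- attr(lib0, "templates")
  fps_alt_lib <- purrr::map_dfr(tpls, function(tp) {
    tp$sigma <- 0
    template_fingerprint(tp, n_reps = 1, origins = alt)
  })
  lib_alt <- lib0
  lib_alt[, c("rho_44", "rho_14", "rho_41")] <- fps_alt_lib

  set.seed(31)
  draws <- sample(length(tpls), 60, replace = TRUE)
  agree <- purrr::map_lgl(seq_along(draws), function(j) {
    tp <- tpls[[draws[j]]]
    tp$sigma <- 0.1
    seed <- 1000 + j
    f_can <- template_fingerprint(tp, n_reps = 1, seed = seed)
    f_alt <- template_fingerprint(tp, n_reps = 1, origins = alt, seed = seed)
    classify_waves(f_can, lib0)$kind == classify_waves(f_alt, lib_alt)$kind
  })
  expect_gte(mean(agree), 0.9)
})
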