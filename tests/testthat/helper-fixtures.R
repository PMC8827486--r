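# shared fixtures, built in code

# noise-free long-wavelength diagonal planar movie (bottom-left -> top-right)
clean_planar_movie <- function(direction = pi / 4, k = 0.25, f = 20,
                               duration = 0.5) {
  simulate_wave(
    wave_template("planar", direction = direction, w = 2 * pi * f, k = k,
                  sigma = 0),
    duration = duration
  )
}

# uniform-random phase maps wrapped as a phase_map_series
random_phase_series <- function(nt, seed = 1, fs = 1000) {
  withr_seed <- function(code) { set.seed(seed); code }
  p <- withr_seed(array(runif(8 * 8 * nt, -pi, pi), c(8, 8, nt)))
  wavemap:::new_phase_map_series(p, array(1, dim(p)), fs = fs)
}

# small library cached across tests (building takes ~0.3 s but is used often)
cached_library <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- build_reference_library(seed = 1)
    lib
  }
})

expect_wrapped_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(wavemap:::wrap_angle(a - b))), tol)
}
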