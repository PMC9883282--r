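# Shared phantom fixtures, built once per session and cached in the
# global env so every test file (including acceptance) reuses them.

vp_cache <- local({
  if (!exists(".vp_fixture_cache", envir = globalenv(), inherits = FALSE)) {
    assign(".vp_fixture_cache", new.env(parent = emptyenv()),
           envir = globalenv())
  }
  get(".vp_fixture_cache", envir = globalenv())
})

vp_fixture <- function(name, builder) {
  if (is.null(vp_cache[[name]])) vp_cache[[name]] <- builder()
  vp_cache[[name]]
}

# zero-noise, no cardiac oscillation: the cleanest possible sweep
fx_clean_ramp <- function() vp_fixture("clean_ramp", function() {
  pp <- phantom_params(speckle_level = 0, cardiac_amplitude = 0)
  acq <- generate_sequence(pp)
  sync <- synchronize(acq$cine, acq$force)
  list(acq = acq, sync = sync,
       seg = segment_sequence(acq$cine, sync = sync))
})

# realistic sweep: speckle, cardiac oscillation, clock offset
fx_noisy_ramp <- function() vp_fixture("noisy_ramp", function() {
  pp <- phantom_params(speckle_level = 0.15, cardiac_amplitude = 1,
                       sync_offset = 0.5)
  acq <- generate_sequence(pp)
  sync <- synchronize(acq$cine, acq$force)
  list(acq = acq, sync = sync,
       seg = segment_sequence(acq$cine, sync = sync))
})

# sweep with the spec's cardiac amplitude for the envelope analysis
fx_amp2_ramp <- function() vp_fixture("amp2_ramp", function() {
  pp <- phantom_params(speckle_level = 0.15, cardiac_amplitude = 2)
  acq <- generate_sequence(pp)
  sync <- synchronize(acq$cine, acq$force)
  list(acq = acq, seg = segment_sequence(acq$cine, sync = sync))
})

# constant-force hold for waveform inversion (zero noise, sine)
fx_hold <- function() vp_fixture("hold", function() {
  pp <- phantom_params(speckle_level = 0)
  acq <- generate_pressure_hold(pp, force = 3, duration = 6)
  list(acq = acq, seg = segment_sequence(acq$cine))
})

# hold with a/c/v morphology at a physiological excursion
fx_hold_acv <- function() vp_fixture("hold_acv", function() {
  pp <- phantom_params(speckle_level = 0, cardiac_shape = "acv",
                       cardiac_amplitude = 3)
  acq <- generate_pressure_hold(pp, force = 3, duration = 6)
  list(acq = acq, seg = segment_sequence(acq$cine))
})

# truth oracle: force at which the phantom's own truth area first
# crosses the collapse threshold (linear interpolation, time order)
truth_collapse_crossing <- function(acq, thr = 0.5) {
  tr <- acq$truth
  k <- which(tr$true_area_mm2 < thr)[1]
  stopifnot(!is.na(k), k > 1L)
  a0 <- tr$true_area_mm2[k - 1]; a1 <- tr$true_area_mm2[k]
  f0 <- tr$applied_force_N[k - 1]; f1 <- tr$applied_force_N[k]
  f0 + (a0 - thr) / (a0 - a1) * (f1 - f0)
}

# truth oracle: collapse force of the cardiac-free law at a shifted
# baseline pressure (bisection-free closed form via the law itself)
truth_collapse_at_pressure <- function(params, lumen_pressure, thr = 0.5) {
  (lumen_pressure - tube_law_pressure(thr, params)) /
    params$force_transfer_coeff
}

# area-force curve straight from phantom truth (no imaging in the loop)
truth_curve <- function(acq, window = c(7, 15)) {
  tr <- acq$truth
  keep <- tr$t_s >= window[1] & tr$t_s <= window[2]
  structure(data.frame(t_s = tr$t_s[keep],
                       force_N = tr$applied_force_N[keep],
                       area_mm2 = tr$true_area_mm2[keep],
                       band_mm2 = 0),
            class = c("area_force_curve", "data.frame"))
}

# sharp-edged uniform disk test image (0-based centre coordinates)
disk_image <- function(nr = 64, nc = 64, center = c(31.5, 31.5),
                       radius = 15, fg = 10, bg = 200) {
  rows <- matrix(0:(nr - 1), nr, nc)
  cols <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  img <- matrix(bg, nr, nc)
  img[(rows - center[1])^2 + (cols - center[2])^2 <= radius^2] <- fg
  img
}
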