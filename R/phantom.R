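#' Phantom generator parameters
#'
#' Bundles the parameters of the synthetic force-coupled cine phantom: a
#' collapsible-tube forward law (pressure-area relation), a lumped
#' force-to-pressure transfer coefficient, cardiac pressure oscillation,
#' and rendering/acquisition geometry.
#'
#' The reference forward law is the implicit collapsible-tube relation
#' \deqn{P_{tm} = K_p\left[(A/A_0)^{n_1} - (A/A_0)^{-n_2}\right]}
#' with a stiff expansion branch (`n1`) and a soft collapse branch (`n2`).
#' The effective external pressure applied by the probe is `c * force`.
#'
#' @param unloaded_area Unloaded lumen area A0 (mm^2) at zero transmural
#'   pressure.
#' @param baseline_pressure Mean venous pressure (mmHg).
#' @param cardiac_amplitude Peak amplitude of the cardiac pressure
#'   oscillation (mmHg).
#' @param cardiac_period Cardiac period (s).
#' @param force_transfer_coeff Effective external pressure per newton of
#'   probe force (mmHg/N).
#' @param tube_stiffness Tube-law stiffness Kp (mmHg).
#' @param expansion_exponent Tube-law expansion exponent n1 (> 0).
#' @param collapse_exponent Tube-law collapse exponent n2 (> 0).
#' @param pixel_pitch Image resolution (mm/px).
#' @param frame_shape Frame dimensions, rows x cols (px).
#' @param frame_rate Cine frame rate (Hz).
#' @param speckle_level Multiplicative speckle noise level (>= 0; 0 gives a
#'   noiseless phantom).
#' @param sync_offset Time offset added to the force-trace clock relative
#'   to the frame clock (s); the synchronization stage must recover it.
#' @param indent_px_per_newton Bulk vertical tissue displacement rendered
#'   per newton of probe force (px/N); what the optical-flow position
#'   signal picks up.
#' @param cardiac_shape `"sine"` for a pure sinusoid or `"acv"` for a
#'   venous a/c/v morphology template.
#' @param rng_seed Integer seed for the speckle generator.
#' @return An object of class `phantom_params` (a validated list).
#' @export
phantom_params <- function(unloaded_area = 8,
                           baseline_pressure = 5,
                           cardiac_amplitude = 1,
                           cardiac_period = 1,
                           force_transfer_coeff = 0.9,
                           tube_stiffness = 0.06,
                           expansion_exponent = 10,
                           collapse_exponent = 1.5,
                           pixel_pitch = 0.1,
                           frame_shape = c(128L, 128L),
                           frame_rate = 20,
                           speckle_level = 0.15,
                           sync_offset = 0,
                           indent_px_per_newton = 0.8,
                           cardiac_shape = c("sine", "acv"),
                           rng_seed = 1L) {
  p <- list(
    unloaded_area = unloaded_area,
    baseline_pressure = baseline_pressure,
    cardiac_amplitude = cardiac_amplitude,
    cardiac_period = cardiac_period,
    force_transfer_coeff = force_transfer_coeff,
    tube_stiffness = tube_stiffness,
    expansion_exponent = expansion_exponent,
    collapse_exponent = collapse_exponent,
    pixel_pitch = pixel_pitch,
    frame_shape = as.integer(frame_shape),
    frame_rate = frame_rate,
    speckle_level = speckle_level,
    sync_offset = sync_offset,
    indent_px_per_newton = indent_px_per_newton,
    cardiac_shape = match.arg(cardiac_shape),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    is.finite(p$unloaded_area), p$unloaded_area > 0,
    is.finite(p$tube_stiffness), p$tube_stiffness > 0,
    p$expansion_exponent > 0, p$collapse_exponent > 0,
    p$cardiac_period > 0, p$pixel_pitch > 0,
    p$frame_rate > 0, p$speckle_level >= 0,
    length(p$frame_shape) == 2L, all(p$frame_shape >= 16L)
  )
  class(p) <- "phantom_params"
  p
}

#' Transmural pressure of the collapsible-tube law at a given area
#'
#' Closed-form direction of the tube law:
#' `Kp * ((A/A0)^n1 - (A/A0)^(-n2))`. Used as the independent oracle for
#' [tube_law_area()] and by the forward model.
#'
#' @param area Lumen area (mm^2), > 0. Vectorized.
#' @param params A `phantom_params` or `forward_model_params` object.
#' @return Transmural pressure (mmHg).
#' @export
tube_law_pressure <- function(area, params) {
  stopifnot(all(is.finite(area)), all(area > 0))
  x <- area / params$unloaded_area
  params$tube_stiffness *
    (x^params$expansion_exponent - x^(-params$collapse_exponent))
}

#' Lumen area of the collapsible tube at a given transmural pressure
#'
#' Numerically inverts the implicit tube law by bisection. Strictly
#' increasing in pressure, equal to A0 at zero transmural pressure, and
#' tending to zero as pressure falls to -Inf.
#'
#' @param transmural_pressure Transmural pressure (mmHg). Vectorized.
#' @inheritParams tube_law_pressure
#' @param tol Relative bisection tolerance on the area ratio.
#' @return Lumen area (mm^2).
#' @export
tube_law_area <- function(transmural_pressure, params, tol = 1e-12) {
  if (!all(is.finite(transmural_pressure))) {
    stop("tube_law_area: non-finite transmural pressure")
  }
  Kp <- params$tube_stiffness
  n1 <- params$expansion_exponent
  n2 <- params$collapse_exponent
  f <- function(x) x^n1 - x^(-n2)  # monotone increasing on (0, Inf)
  solve_one <- function(pr) {
    target <- pr / Kp
    lo <- 1e-12
    hi <- 1
    while (f(hi) < target) hi <- hi * 2
    for (i in seq_len(200L)) {
      mid <- (lo + hi) / 2
      if (f(mid) < target) lo <- mid else hi <- mid
      if ((hi - lo) < tol * max(hi, 1)) break
    }
    (lo + hi) / 2
  }
  params$unloaded_area *
    vapply(transmural_pressure, solve_one, numeric(1))
}

#' Cardiac pressure oscillation template
#'
#' Periodic zero-mean pressure oscillation. `"sine"` is a pure sinusoid;
#' `"acv"` is a venous-morphology template built from three positive
#' bumps (a, c, v waves, decreasing then recovering amplitude) and two
#' troughs (x, y descents) per cycle, normalized to unit peak amplitude.
#'
#' @param t Time (s). Vectorized.
#' @param period Cardiac period (s).
#' @param amplitude Peak amplitude (mmHg).
#' @param shape `"sine"` or `"acv"`.
#' @return Pressure oscillation (mmHg), zero mean over a cycle (to
#'   numerical accuracy for `"acv"`).
#' @export
cardiac_waveform <- function(t, period, amplitude, shape = c("sine", "acv")) {
  shape <- match.arg(shape)
  ph <- (t / period) %% 1
  if (shape == "sine") {
    return(amplitude * sin(2 * pi * ph))
  }
  bump <- function(ph, center, width) exp(-0.5 * ((ph - center) / width)^2)
  # a, c, v positive waves; x, y negative descents
  raw <- function(ph) {
    1.00 * bump(ph, 0.10, 0.045) +
    0.65 * bump(ph, 0.28, 0.040) +
    0.80 * bump(ph, 0.62, 0.060) -
    0.85 * bump(ph, 0.45, 0.055) -
    0.70 * bump(ph, 0.82, 0.060)
  }
  grid <- raw(seq(0, 1, length.out = 2001L)[-2001L])
  w <- (raw(ph) - mean(grid)) / max(abs(grid - mean(grid)))
  amplitude * w
}

#' Force protocol for a phantom acquisition
#'
#' Describes the acquisition maneuver: three quick compressions
#' (triangular force spikes), a slow linear ramp past full collapse, and
#' one quick compression after the ramp.
#'
#' @param spike_times Centers of the three pre-ramp spikes (s).
#' @param spike_height Spike peak force (N).
#' @param spike_width Full width of each triangular spike (s).
#' @param ramp_start,ramp_end Ramp window (s).
#' @param ramp_max Peak ramp force (N).
#' @param post_spike_time Center of the post-ramp spike (s).
#' @param duration Total trace duration (s).
#' @param sample_rate Force sampling rate (Hz).
#' @return An object of class `force_protocol`.
#' @export
force_protocol <- function(spike_times = c(2, 3.5, 5),
                           spike_height = 5,
                           spike_width = 0.3,
                           ramp_start = 7,
                           ramp_end = 15,
                           ramp_max = 14,
                           post_spike_time = 17.5,
                           duration = 19,
                           sample_rate = 50) {
  stopifnot(length(spike_times) == 3L,
            all(diff(spike_times) > 0),
            max(spike_times) + spike_width / 2 < ramp_start,
            ramp_end > ramp_start,
            post_spike_time - spike_width / 2 > ramp_end,
            duration > post_spike_time + spike_width / 2,
            ramp_max > 0, spike_height > 0)
  structure(list(spike_times = spike_times, spike_height = spike_height,
                 spike_width = spike_width, ramp_start = ramp_start,
                 ramp_end = ramp_end, ramp_max = ramp_max,
                 post_spike_time = post_spike_time, duration = duration,
                 sample_rate = sample_rate),
            class = "force_protocol")
}

#' Evaluate the protocol force at given times
#'
#' @param t Time (s), on the frame clock. Vectorized.
#' @param protocol A [force_protocol()].
#' @return Applied probe force (N).
#' @export
protocol_force <- function(t, protocol) {
  f <- numeric(length(t))
  tri <- function(t, center, height, width) {
    pmax(0, height * (1 - abs(t - center) / (width / 2)))
  }
  for (ct in protocol$spike_times) {
    f <- f + tri(t, ct, protocol$spike_height, protocol$spike_width)
  }
  ramp <- (t - protocol$ramp_start) / (protocol$ramp_end - protocol$ramp_start)
  f <- f + ifelse(t >= protocol$ramp_start & t <= protocol$ramp_end,
                  protocol$ramp_max * ramp, 0)
  f + tri(t, protocol$post_spike_time, protocol$spike_height,
          protocol$spike_width)
}

#' True event times of a protocol
#'
#' The five synchronization events: three pre-ramp spikes, the ramp
#' maximum, and the post-ramp spike.
#'
#' @param protocol A [force_protocol()].
#' @return Numeric vector of 5 increasing times (s), frame clock.
#' @export
protocol_event_times <- function(protocol) {
  c(protocol$spike_times, protocol$ramp_end, protocol$post_spike_time)
}

# intensity constants of the renderer (8-bit scale)
.render <- list(bg = 180, lumen = 20, wall = 235, wall_thickness = 2.5)

#' Render one phantom B-mode frame
#'
#' Draws a dark circular lumen of the requested area with a bright wall
#' ring on a brighter speckled background. Speckle is multiplicative
#' Gaussian; with `speckle_level = 0` the image is piecewise constant.
#'
#' @param true_area Lumen area to render (mm^2), >= 0.
#' @param centroid Lumen centroid, `c(row, col)` in px (0-based).
#' @param params A [phantom_params()].
#' @param background Optional pre-generated background matrix (used by
#'   [generate_sequence()] to keep a coherent moving speckle field); when
#'   `NULL` a fresh seeded field is drawn.
#' @return Numeric matrix (rows x cols) of intensities in `[0, 255]`.
#' @export
render_frame <- function(true_area, centroid, params, background = NULL) {
  stopifnot(is.finite(true_area), true_area >= 0)
  nr <- params$frame_shape[1]; nc <- params$frame_shape[2]
  area_px <- true_area / params$pixel_pitch^2
  radius <- sqrt(area_px / pi)
  if (2 * radius > min(nr, nc)) {
    stop("render_frame: lumen area exceeds frame extent")
  }
  if (is.null(background)) {
    img <- matrix(.render$bg, nr, nc)
    if (params$speckle_level > 0) {
      rs <- .save_rng(params$rng_seed)
      img <- img * (1 + params$speckle_level * matrix(stats::rnorm(nr * nc), nr, nc))
      .restore_rng(rs)
    }
  } else {
    img <- background
  }
  rows <- matrix(0:(nr - 1), nr, nc)
  cols <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  d2 <- (rows - centroid[1])^2 + (cols - centroid[2])^2
  n_px <- round(area_px)
  if (n_px >= 1) {
    # count-matched disk: exactly the n_px pixels nearest the centroid,
    # so the rendered dark-pixel count equals the truth area (+/- 0.5 px)
    ord <- order(d2)
    lumen_idx <- ord[seq_len(n_px)]
    r_edge2 <- d2[lumen_idx[n_px]]
    ring <- d2 > r_edge2 &
      d2 <= (sqrt(r_edge2) + .render$wall_thickness)^2
    img[ring] <- .render$wall
    img[lumen_idx] <- .render$lumen
  }
  pmin(pmax(img, 0), 255)
}

# Seeded-RNG scoping helpers: run seeded draws without clobbering the
# caller's RNG stream.
.save_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Generate a constant-force phantom hold
#'
#' Renders a cine at (approximately) constant probe force with the
#' cardiac pressure oscillation running -- the acquisition mode used for
#' venous-pressure waveform inversion. Same truth bookkeeping as
#' [generate_sequence()], without the synchronization events.
#'
#' @param params A [phantom_params()].
#' @param force Held probe force (N).
#' @param duration Hold duration (s).
#' @return A `phantom_acquisition` (see [generate_sequence()]); `events`
#'   is `NULL`.
#' @export
generate_pressure_hold <- function(params, force = 3, duration = 6) {
  n_frames <- floor(duration * params$frame_rate) + 1L
  t_frame <- (seq_len(n_frames) - 1L) / params$frame_rate
  force_at_frame <- rep(force, n_frames)
  acq <- .assemble_acquisition(params, t_frame, force_at_frame)
  t_force <- seq(0, duration, by = 1 / 50)
  acq$force <- data.frame(t_s = t_force + params$sync_offset,
                          force_N = force, pitch_deg = 0, yaw_deg = 0)
  acq$events <- NULL
  acq
}

#' Generate a synthetic force-coupled cine acquisition
#'
#' Produces a cine sequence, a force trace, and the per-frame ground
#' truth for a phantom following the acquisition maneuver: three quick
#' compressions, a slow linear force ramp past complete lumen collapse,
#' and one quick compression. Per frame, the true transmural pressure is
#' `baseline + cardiac(t) - c * force(t)` and the true area follows the
#' tube law. The force-trace clock is shifted by `params$sync_offset`
#' relative to the frame clock. Bulk tissue motion proportional to force
#' is rendered so the compressions are visible to optical flow.
#'
#' @param params A [phantom_params()].
#' @param protocol A [force_protocol()]; its ramp should exceed the force
#'   needed for full collapse (otherwise the truth carries
#'   `attr(truth, "collapse_reached") = FALSE` as a warning flag).
#' @return A list of class `phantom_acquisition` with elements
#'   `cine` (a `cine_sequence`: list of frame matrices, `times`,
#'   `pixel_pitch`, `frame_rate`), `force` (data.frame
#'   `t_s, force_N, pitch_deg, yaw_deg`, clock shifted by `sync_offset`),
#'   `truth` (per-frame data.frame with `frame, t_s, applied_force_N,
#'   transmural_mmHg, lumen_mmHg, true_area_mm2, centroid_row,
#'   centroid_col`), `events` (true event times, frame clock), and
#'   `params`, `protocol`.
#' @export
generate_sequence <- function(params, protocol = force_protocol()) {
  n_frames <- floor(protocol$duration * params$frame_rate) + 1L
  t_frame <- (seq_len(n_frames) - 1L) / params$frame_rate
  force_at_frame <- protocol_force(t_frame, protocol)
  acq <- .assemble_acquisition(params, t_frame, force_at_frame)
  t_force <- seq(0, protocol$duration, by = 1 / protocol$sample_rate)
  acq$force <- data.frame(t_s = t_force + params$sync_offset,
                          force_N = protocol_force(t_force, protocol),
                          pitch_deg = 0, yaw_deg = 0)
  acq$events <- protocol_event_times(protocol)
  acq$protocol <- protocol
  acq
}

# shared phantom assembly: truth physics + frame rendering
.assemble_acquisition <- function(params, t_frame, force_at_frame) {
  n_frames <- length(t_frame)
  lumen_p <- params$baseline_pressure +
    cardiac_waveform(t_frame, params$cardiac_period,
                     params$cardiac_amplitude, params$cardiac_shape)
  ptm <- lumen_p - params$force_transfer_coeff * force_at_frame
  true_area <- tube_law_area(ptm, params)
  # pixel-quantized rendering cannot represent sub-pixel areas
  true_area[true_area / params$pixel_pitch^2 < 0.5] <- 0

  nr <- params$frame_shape[1]; nc <- params$frame_shape[2]
  max_shift <- ceiling(params$indent_px_per_newton * max(force_at_frame)) + 1L
  rs <- .save_rng(params$rng_seed)
  field <- matrix(.render$bg, nr + max_shift, nc)
  if (params$speckle_level > 0) {
    field <- field * (1 + params$speckle_level *
                        matrix(stats::rnorm((nr + max_shift) * nc),
                               nr + max_shift, nc))
  }
  .restore_rng(rs)

  base_centroid <- c((nr - 1) / 2, (nc - 1) / 2)
  shift <- round(params$indent_px_per_newton * force_at_frame)
  frames <- vector("list", n_frames)
  cent_row <- numeric(n_frames)
  for (k in seq_len(n_frames)) {
    # tissue moves down as the probe indents: crop a shifted window
    bg <- field[(max_shift - shift[k] + 1):(max_shift - shift[k] + nr), ,
                drop = FALSE]
    cent_row[k] <- base_centroid[1] + shift[k]
    frames[[k]] <- render_frame(true_area[k],
                                c(cent_row[k], base_centroid[2]),
                                params, background = bg)
  }
  cine <- structure(list(frames = frames, times = t_frame,
                         pixel_pitch = params$pixel_pitch,
                         frame_rate = params$frame_rate),
                    class = "cine_sequence")
  truth <- data.frame(frame = seq_len(n_frames), t_s = t_frame,
                      applied_force_N = force_at_frame,
                      transmural_mmHg = ptm, lumen_mmHg = lumen_p,
                      true_area_mm2 = true_area,
                      centroid_row = cent_row,
                      centroid_col = base_centroid[2])
  attr(truth, "collapse_reached") <- any(true_area < 0.5)
  structure(list(cine = cine, force = NULL, truth = truth,
                 events = NULL, params = params, protocol = NULL),
            class = "phantom_acquisition")
}
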