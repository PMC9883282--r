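#' Forward-model parameters for waveform inversion
#'
#' Pluggable monotone forward model mapping (venous pressure, probe
#' force) to lumen area. The reference implementation is the same
#' collapsible-tube law as the phantom generator:
#' `area = tube_law(pressure - c * force)`.
#'
#' @param unloaded_area A0 (mm^2).
#' @param tube_stiffness Kp (mmHg).
#' @param expansion_exponent,collapse_exponent Tube-law exponents.
#' @param force_transfer_coeff Effective external pressure per newton
#'   (mmHg/N).
#' @return A `forward_model_params` list.
#' @export
forward_model_params <- function(unloaded_area = 8,
                                 tube_stiffness = 0.06,
                                 expansion_exponent = 10,
                                 collapse_exponent = 1.5,
                                 force_transfer_coeff = 0.9) {
  p <- list(unloaded_area = unloaded_area,
            tube_stiffness = tube_stiffness,
            expansion_exponent = expansion_exponent,
            collapse_exponent = collapse_exponent,
            force_transfer_coeff = force_transfer_coeff)
  stopifnot(all(vapply(p, function(x) is.finite(x) && x > 0, logical(1))))
  class(p) <- "forward_model_params"
  p
}

#' Forward model: lumen area at a given pressure and force
#'
#' Strictly increasing in venous pressure and decreasing in applied
#' force.
#'
#' @param pressure Venous (lumen) pressure (mmHg). Vectorized.
#' @param force Probe force (N). Vectorized (recycled).
#' @param params A [forward_model_params()].
#' @return Area (mm^2).
#' @export
forward_area <- function(pressure, force, params) {
  if (any(!is.finite(pressure)) || any(!is.finite(force))) {
    stop("forward_area: non-finite input")
  }
  tube_law_area(pressure - params$force_transfer_coeff * force, params)
}

#' Anchor specification for waveform inversion
#'
#' The inversion is anchored by assigning the calibration-predicted CVP
#' to the frame whose area is nearest the window-mean area (earliest
#' such frame on ties).
#'
#' @param areas Segmented areas over the inversion window (mm^2).
#' @param anchor_pressure Predicted CVP (mmHg), from [predict_cvp()].
#' @return A list of class `anchor_spec`: `anchor_pressure`,
#'   `anchor_frame` (index into the window), `anchor_area`.
#' @export
anchor_spec <- function(areas, anchor_pressure) {
  stopifnot(length(areas) >= 1L, is.finite(anchor_pressure))
  k <- which.min(abs(areas - mean(areas)))  # which.min takes the earliest tie
  structure(list(anchor_pressure = anchor_pressure, anchor_frame = k,
                 anchor_area = areas[k]),
            class = "anchor_spec")
}

#' Tune the forward model to honor the anchor
#'
#' Scales the unloaded area A0 (holding the shape parameters) so that
#' the forward model reproduces the anchor area at the anchor pressure
#' and force. Because the tube law is scale-invariant in A0, the
#' constraint has the closed-form solution
#' `A0 = anchor_area / ratio(P_tm)` with `ratio` the area ratio at the
#' anchor's transmural pressure.
#'
#' @param anchor An [anchor_spec()].
#' @param force Probe force at the anchor frame (N).
#' @param params Initial [forward_model_params()].
#' @param tol Relative verification tolerance.
#' @return Tuned `forward_model_params`.
#' @export
calibrate_forward_model <- function(anchor, force, params, tol = 1e-6) {
  if (!is.finite(anchor$anchor_area) || anchor$anchor_area <= 0) {
    stop("calibrate_forward_model: anchor area must be positive")
  }
  unit <- params
  unit$unloaded_area <- 1
  ratio <- forward_area(anchor$anchor_pressure, force, unit)
  out <- params
  out$unloaded_area <- anchor$anchor_area / ratio
  check <- forward_area(anchor$anchor_pressure, force, out)
  if (abs(check - anchor$anchor_area) > tol * anchor$anchor_area) {
    stop("calibrate_forward_model: anchor constraint not attainable")
  }
  out
}

#' Invert one frame: venous pressure from segmented area
#'
#' Minimizes the squared area mismatch
#' `(A_seg - A_mod(pressure))^2` over pressure with downhill-simplex
#' (Nelder-Mead) optimization starting from `p_init`.
#'
#' @param area_seg Segmented area (mm^2), > 0.
#' @param force Probe force at the frame (N).
#' @param params A [forward_model_params()].
#' @param p_init Initial pressure guess (mmHg).
#' @param cost_tol Convergence cost ((mm^2)^2), default `(0.01)^2`.
#' @param p_bounds Search bounds (mmHg); hitting a bound marks
#'   non-convergence.
#' @param maxit Simplex iteration limit.
#' @return A list: `pressure` (mmHg), `cost`, `converged`.
#' @export
invert_frame <- function(area_seg, force, params, p_init,
                         cost_tol = 1e-4, p_bounds = c(-200, 500),
                         maxit = 200) {
  stopifnot(is.finite(area_seg), area_seg > 0)
  obj <- function(p) {
    pc <- min(max(p, p_bounds[1]), p_bounds[2])
    (area_seg - forward_area(pc, force, params))^2
  }
  opt <- suppressWarnings(
    stats::optim(p_init, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-12)))
  p <- min(max(opt$par, p_bounds[1]), p_bounds[2])
  at_bound <- p <= p_bounds[1] + 1e-9 || p >= p_bounds[2] - 1e-9
  list(pressure = p, cost = opt$value,
       converged = !at_bound && opt$value < cost_tol)
}

#' Invert a venous-pressure waveform over a constant-force window
#'
#' Processes the frames in time order; each frame's simplex starts from
#' the previous frame's converged pressure (the first frame from the
#' anchor pressure). The forward model is first tuned so the anchor
#' frame's area maps to the anchor pressure, which pins the waveform
#' mean to the calibration-predicted CVP.
#'
#' @param areas Segmented areas (mm^2) over the window, time ordered.
#' @param forces Per-frame probe force (N).
#' @param times Frame times (s).
#' @param anchor An [anchor_spec()] built from `areas`.
#' @param params Initial [forward_model_params()].
#' @param calibrate Tune A0 to the anchor first (default TRUE).
#' @param ... Passed to [invert_frame()].
#' @return A data.frame of class `pressure_waveform` with columns
#'   `frame, t_s, pressure_mmHg, cost, converged`; attribute `params`
#'   (the tuned model).
#' @export
invert_sequence <- function(areas, forces, times, anchor, params,
                            calibrate = TRUE, ...) {
  n <- length(areas)
  stopifnot(length(forces) == n, length(times) == n,
            anchor$anchor_frame >= 1L, anchor$anchor_frame <= n)
  if (calibrate) {
    params <- calibrate_forward_model(anchor, forces[anchor$anchor_frame],
                                      params)
  }
  pressure <- cost <- numeric(n)
  converged <- logical(n)
  p_prev <- anchor$anchor_pressure
  for (k in seq_len(n)) {
    res <- invert_frame(areas[k], forces[k], params, p_prev, ...)
    pressure[k] <- res$pressure
    cost[k] <- res$cost
    converged[k] <- res$converged
    if (res$converged) p_prev <- res$pressure
  }
  out <- data.frame(frame = seq_len(n), t_s = times,
                    pressure_mmHg = pressure, cost = cost,
                    converged = converged)
  attr(out, "params") <- params
  class(out) <- c("pressure_waveform", "data.frame")
  out
}

#' Label venous waveform landmarks (a, c, x, v, y)
#'
#' Descriptive labeling of the canonical right-atrial waveform
#' components: per cardiac cycle, local maxima in temporal order are
#' labeled a, c, v and local minima x, y. Cycles with fewer than three
#' extrema (e.g. a pure sinusoid) are left unlabeled with a flag.
#'
#' @param waveform A `pressure_waveform` (>= 2 cardiac periods).
#' @param cardiac_period Cardiac period (s).
#' @return A data.frame with columns `t_s`, `pressure_mmHg`, `type`
#'   (max/min), `label` (a/c/x/v/y or NA), `cycle`; attribute
#'   `unlabeled` TRUE when labeling was not possible.
#' @export
label_waveform_landmarks <- function(waveform, cardiac_period) {
  t <- waveform$t_s
  p <- waveform$pressure_mmHg
  if (diff(range(t)) < 2 * cardiac_period) {
    stop("label_waveform_landmarks: need at least 2 cardiac periods")
  }
  s <- sign(diff(p))
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1L]
  d <- diff(s)
  imax <- which(d < 0) + 1L
  imin <- which(d > 0) + 1L
  idx <- sort(c(imax, imin))
  # prune quantization flicker: repeatedly drop the adjacent extremum
  # pair with the smallest amplitude until all swings are material
  tol <- 0.05 * diff(range(p))
  while (length(idx) >= 2L) {
    swings <- abs(diff(p[idx]))
    k <- which.min(swings)
    if (swings[k] >= tol) break
    idx <- idx[-c(k, k + 1L)]
  }
  imax <- intersect(idx, imax)
  imin <- intersect(idx, imin)
  if (!length(idx)) {
    out <- data.frame(t_s = numeric(0), pressure_mmHg = numeric(0),
                      type = character(0), label = character(0),
                      cycle = integer(0))
    attr(out, "unlabeled") <- TRUE
    return(out)
  }
  ext <- data.frame(t_s = t[idx], pressure_mmHg = p[idx],
                    type = ifelse(idx %in% imax, "max", "min"),
                    label = NA_character_,
                    cycle = as.integer(floor((t[idx] - t[1]) / cardiac_period)))
  unlabeled <- TRUE
  for (cy in unique(ext$cycle)) {
    sel <- which(ext$cycle == cy)
    if (length(sel) < 3L) next
    # a, c, v are the three tallest maxima; x, y the two deepest minima
    # (minor inter-wave dips are not canonical landmarks)
    maxima <- sel[ext$type[sel] == "max"]
    minima <- sel[ext$type[sel] == "min"]
    maxima <- sort(maxima[order(-ext$pressure_mmHg[maxima])][1:min(3L, length(maxima))])
    minima <- sort(minima[order(ext$pressure_mmHg[minima])][1:min(2L, length(minima))])
    ext$label[maxima] <- c("a", "c", "v")[seq_along(maxima)]
    ext$label[minima] <- c("x", "y")[seq_along(minima)]
    unlabeled <- FALSE
  }
  attr(ext, "unlabeled") <- unlabeled
  ext
}
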