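#' Build an area-force curve from synchronized segmentation output
#'
#' Restricts the per-frame records to the compression-ramp window and
#' orders them by time. The curve is the input to collapse-force
#' estimation.
#'
#' @param seg A `segmentation_table` (needs `t_s`, `force_N`, `area_mm2`,
#'   `band_mm2`).
#' @param window `c(t0, t1)` ramp window (s, frame clock); `NULL` keeps
#'   all frames with finite force.
#' @param collapse_mm2 Collapse threshold (mm^2) used for the
#'   sub-threshold flag.
#' @return A data.frame of class `area_force_curve` (columns `t_s`,
#'   `force_N`, `area_mm2`, `band_mm2`); attribute `has_collapse`.
#' @export
build_curve <- function(seg, window = NULL, collapse_mm2 = 0.5) {
  keep <- is.finite(seg$force_N)
  if (!is.null(window)) keep <- keep & seg$t_s >= window[1] & seg$t_s <= window[2]
  cur <- seg[keep, c("t_s", "force_N", "area_mm2", "band_mm2")]
  if (!nrow(cur)) stop("build_curve: empty ramp window")
  cur <- cur[order(cur$t_s), ]
  rownames(cur) <- NULL
  attr(cur, "has_collapse") <- any(cur$area_mm2 < collapse_mm2)
  class(cur) <- c("area_force_curve", "data.frame")
  cur
}

#' Collapse force: first crossing below the area threshold
#'
#' Returns the force at which the area first (in time) falls below the
#' collapse threshold, linearly interpolated between the bracketing
#' samples when they straddle it.
#'
#' @param curve An `area_force_curve` (or data.frame with `force_N`,
#'   `area_mm2` ordered by time).
#' @param collapse_mm2 Collapse threshold (mm^2), default 0.5.
#' @return Collapse force (N).
#' @export
estimate_collapse_force <- function(curve, collapse_mm2 = 0.5) {
  a <- curve$area_mm2
  f <- curve$force_N
  k <- which(a < collapse_mm2)
  if (!length(k)) {
    stop("estimate_collapse_force: no sample below the collapse threshold")
  }
  k <- k[1L]
  if (k == 1L) return(f[1L])
  a0 <- a[k - 1L]; a1 <- a[k]
  if (a0 <= collapse_mm2) return(f[k])
  f[k - 1L] + (a0 - collapse_mm2) / (a0 - a1) * (f[k] - f[k - 1L])
}

#' Cardiac-cycle collapse-force envelope
#'
#' Among samples with area under `envelope_mm2`, the local minima and
#' local maxima of the cardiac area oscillation (detected on the
#' detrended area series) are each fit with a least-squares line in
#' (force, area); the forces at which the two lines cross the collapse
#' threshold bound the collapse force over the cardiac cycle.
#'
#' @param curve An `area_force_curve`.
#' @param collapse_mm2 Collapse threshold (mm^2).
#' @param envelope_mm2 Only samples under this area (mm^2) are used
#'   (default 5).
#' @return A list: `cardiac_low`, `cardiac_high` (N), `degenerate`
#'   (TRUE when too few extrema exist; bounds then equal the collapse
#'   force).
#' @export
cardiac_envelope_uncertainty <- function(curve, collapse_mm2 = 0.5,
                                         envelope_mm2 = 5) {
  cf <- estimate_collapse_force(curve, collapse_mm2)
  degenerate <- function() list(cardiac_low = cf, cardiac_high = cf,
                                degenerate = TRUE)
  if (sum(curve$area_mm2 < envelope_mm2 & curve$area_mm2 > collapse_mm2) < 4L) {
    return(degenerate())
  }
  # cardiac extrema located on the raw area series (the ramp descent is
  # slow against the cardiac oscillation near collapse, so raw local
  # extrema are the cardiac troughs/peaks), then restricted to the
  # oscillating descent: below the envelope bound but above the collapse
  # threshold, so the flat fully-collapsed tail cannot enter the fits
  a <- curve$area_mm2
  s <- sign(diff(a))
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1L]
  d <- diff(s)
  usable <- function(idx) {
    idx[a[idx] < envelope_mm2 & a[idx] > collapse_mm2]
  }
  imax <- usable(which(d < 0) + 1L)
  imin <- usable(which(d > 0) + 1L)
  if (length(imax) < 2L || length(imin) < 2L) return(degenerate())
  cross <- function(idx) {
    fit <- stats::lm(area_mm2 ~ force_N, data = curve[idx, ])
    b <- stats::coef(fit)
    if (abs(b[2]) < 1e-12) return(NA_real_)
    unname((collapse_mm2 - b[1]) / b[2])
  }
  bounds <- c(cross(imin), cross(imax))
  if (anyNA(bounds)) return(degenerate())
  list(cardiac_low = min(bounds), cardiac_high = max(bounds),
       degenerate = FALSE)
}

#' Segmentation contribution to collapse-force uncertainty
#'
#' Converts the boundary-band area (the pixels whose classification is
#' ambiguous at the region-growing threshold) into newtons by dividing
#' by the local area-force slope |dA/dF| near the collapse crossing.
#'
#' @param curve An `area_force_curve`.
#' @param band_mm2 Boundary-band area at the collapse point (mm^2);
#'   default 0.25 (the value observed at the collapse threshold when no
#'   per-frame band is available).
#' @param collapse_mm2 Collapse threshold (mm^2).
#' @param fit_mm2 Samples with area under this bound enter the local
#'   slope fit (default 5).
#' @return Force uncertainty (N).
#' @export
segmentation_force_uncertainty <- function(curve, band_mm2 = 0.25,
                                           collapse_mm2 = 0.5,
                                           fit_mm2 = 5) {
  if (band_mm2 == 0) return(0)
  # local slope near the collapse crossing: the flat fully-collapsed
  # tail is excluded for the same reason as in the cardiac envelope
  sub <- curve[curve$area_mm2 < fit_mm2 & curve$area_mm2 > collapse_mm2, ]
  if (nrow(sub) < 2L) sub <- curve
  fit <- stats::lm(area_mm2 ~ force_N, data = sub)
  slope <- abs(unname(stats::coef(fit)[2]))
  if (slope < 1e-9) {
    stop("segmentation_force_uncertainty: degenerate flat area-force curve")
  }
  band_mm2 / slope
}

#' Collapse force with uncertainty components
#'
#' Combines the first-crossing collapse force, the cardiac-cycle
#' envelope (reported as a half-interval), and the segmentation band
#' uncertainty. Total uncertainty is their sum; collapse forces below
#' the minimum contact force (2 N, below which image quality precludes
#' measurement) are flagged.
#'
#' @param curve An `area_force_curve`.
#' @param collapse_mm2,envelope_mm2 Thresholds (mm^2).
#' @param band_mm2 Override for the boundary-band area; `NULL` takes the
#'   band recorded at the frame nearest the collapse crossing, falling
#'   back to 0.25 mm^2 when that band is zero or missing.
#' @param min_contact_N Minimum measurable contact force (N), default 2.
#' @return A list of class `collapse_estimate`: `collapse_force`,
#'   `cardiac_low`, `cardiac_high`, `segmentation_uncertainty`,
#'   `total_uncertainty` (N), `below_min_contact`, `degenerate_envelope`.
#' @export
estimate_collapse <- function(curve, collapse_mm2 = 0.5, envelope_mm2 = 5,
                              band_mm2 = NULL, min_contact_N = 2) {
  cf <- estimate_collapse_force(curve, collapse_mm2)
  env <- cardiac_envelope_uncertainty(curve, collapse_mm2, envelope_mm2)
  if (is.null(band_mm2)) {
    near <- which.min(abs(curve$force_N - cf))
    band_mm2 <- curve$band_mm2[near]
    if (!isTRUE(is.finite(band_mm2)) || band_mm2 == 0) band_mm2 <- 0.25
  }
  seg_u <- segmentation_force_uncertainty(curve, band_mm2, collapse_mm2,
                                          envelope_mm2)
  # the envelope is drawn around the collapse force; numerical line fits
  # can land both bounds on one side of it, so clamp to contain it
  lo <- min(env$cardiac_low, cf)
  hi <- max(env$cardiac_high, cf)
  structure(list(collapse_force = cf, cardiac_low = lo, cardiac_high = hi,
                 segmentation_uncertainty = seg_u,
                 total_uncertainty = (hi - lo) / 2 + seg_u,
                 below_min_contact = cf < min_contact_N,
                 degenerate_envelope = env$degenerate),
            class = "collapse_estimate")
}
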