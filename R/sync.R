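#' Optical-flow position signal from a cine sequence
#'
#' Estimates the bulk vertical tissue displacement between consecutive
#' frames and integrates it into a position signal. Probe compression is
#' axial, so only the vertical component is tracked: each frame pair is
#' reduced to its row-mean intensity profile and the integer shift
#' maximizing their cross-correlation (within `max_shift` px) is taken as
#' the frame-to-frame displacement. Deterministic for fixed input.
#'
#' @param cine A `cine_sequence` (>= 2 frames).
#' @param max_shift Largest per-frame vertical shift searched (px).
#' @return A data.frame of class `flow_signal` with columns
#'   `frame_index`, `frame_time`, `displacement` (|px| moved since the
#'   previous frame; 0 for the first frame) and `position` (cumulative
#'   signed displacement, px). Peak detection for synchronization runs on
#'   `position`, which tracks applied force.
#' @export
compute_flow_signal <- function(cine, max_shift = 20L) {
  n <- length(cine$frames)
  if (n < 2L) stop("compute_flow_signal: need at least 2 frames")
  profiles <- vapply(cine$frames, rowMeans, numeric(nrow(cine$frames[[1]])))
  lags <- -max_shift:max_shift
  disp <- numeric(n)
  for (k in 2:n) {
    a <- profiles[, k - 1L]
    b <- profiles[, k]
    m <- length(a)
    score <- vapply(lags, function(l) {
      ao <- if (l >= 0) a[seq_len(m - l)] else a[(1 - l):m]
      bo <- if (l >= 0) b[(1 + l):m] else b[seq_len(m + l)]
      ao <- ao - mean(ao); bo <- bo - mean(bo)
      sum(ao * bo) / (sqrt(sum(ao^2) * sum(bo^2)) + 1e-9)
    }, numeric(1))
    # ties (e.g. featureless frames) resolve to the smallest |lag|
    best <- which(score >= max(score) - 1e-12)
    disp[k] <- lags[best[which.min(abs(lags[best]))]]
  }
  structure(data.frame(frame_index = seq_len(n) - 1L,
                       frame_time = cine$times,
                       displacement = abs(disp),
                       position = cumsum(disp)),
            class = c("flow_signal", "data.frame"))
}

# Prominence-based peak finder on a uniformly sampled series.
# Returns indices of local maxima with prominence >= prom_frac * range,
# merging peaks closer than min_separation (keeping the taller one).
.find_peaks <- function(x, times, min_separation, prom_frac = 0.1) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  # strict peaks only: carry the slope sign through plateaus so that a
  # monotone staircase (the force ramp) contributes no candidates
  s <- sign(diff(x))
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1L]
  cand <- which(diff(s) < 0) + 1L
  if (!length(cand)) return(integer(0))
  rng <- diff(range(x))
  if (rng <= 0) return(integer(0))
  prominence <- vapply(cand, function(i) {
    left <- if (i > 1L) min(x[1:i]) else x[i]
    right <- min(x[i:n])
    x[i] - max(left, right)
  }, numeric(1))
  cand <- cand[prominence >= prom_frac * rng]
  if (!length(cand)) return(integer(0))
  # merge peaks within min_separation, tallest wins
  ord <- cand[order(times[cand])]
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) && times[i] - times[kept[length(kept)]] < min_separation) {
      if (x[i] > x[kept[length(kept)]]) kept[length(kept)] <- i
    } else {
      kept <- c(kept, i)
    }
  }
  kept
}

#' Detect the five synchronization events in a 1-D signal
#'
#' Finds the three quick compressions preceding the force sweep, the
#' sweep maximum, and the one quick compression after the sweep. The
#' sweep maximum is the global maximum of the lightly smoothed signal;
#' the pre-events are the last three distinct peaks before it and the
#' post-event the first distinct peak after it.
#'
#' @param signal Numeric series (force, or flow `position`).
#' @param times Sample times (s), same length, increasing.
#' @param min_separation Minimum peak separation (s); closer candidate
#'   peaks are merged.
#' @param smooth_window Moving-average window (s) applied before locating
#'   the sweep maximum.
#' @return Numeric vector of exactly 5 increasing event times (s); the
#'   4th is the sweep maximum.
#' @export
detect_events <- function(signal, times, min_separation = 0.5,
                          smooth_window = 0.25) {
  stopifnot(length(signal) == length(times), length(signal) >= 5L)
  dt <- stats::median(diff(times))
  w <- max(1L, round(smooth_window / dt))
  sm <- stats::filter(signal, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- signal[is.na(sm)]
  sm <- as.numeric(sm)
  ramp_idx <- which.max(sm)
  ramp_time <- times[ramp_idx]
  peaks <- .find_peaks(signal, times, min_separation)
  pre <- peaks[times[peaks] < ramp_time - min_separation]
  post <- peaks[times[peaks] > ramp_time + min_separation]
  if (length(pre) < 3L || length(post) < 1L) {
    stop(sprintf(
      "detect_events: found %d pre-sweep and %d post-sweep peaks (need 3 and 1)",
      length(pre), length(post)))
  }
  pre <- utils::tail(pre, 3L)
  sort(c(times[pre], ramp_time, times[post[1L]]))
}

#' Align force and flow event sets
#'
#' The first and last event pairs are aligned in the least-squares sense
#' (offset = mean of their two differences); the three middle pairs are
#' then checked against the residual budget: the sum of their absolute
#' disagreements after shifting must not exceed `residual_max`.
#'
#' @param force_events Five event times from the force trace (s).
#' @param flow_events Five event times from the flow signal (s).
#' @param residual_max Largest acceptable summed middle-pair disagreement
#'   (s); default 0.7.
#' @return A list with `time_offset` (s; force clock minus frame clock),
#'   `alignment_residual` (s) and `valid`.
#' @export
align_events <- function(force_events, flow_events, residual_max = 0.7) {
  stopifnot(length(force_events) == 5L, length(flow_events) == 5L)
  offset <- mean(force_events[c(1L, 5L)] - flow_events[c(1L, 5L)])
  residual <- sum(abs(force_events[2:4] - (flow_events[2:4] + offset)))
  list(time_offset = offset, alignment_residual = residual,
       valid = residual <= residual_max)
}

#' Assign a force to each ultrasound frame
#'
#' Linearly interpolates the force trace, shifted onto the frame clock by
#' `time_offset`, at each frame time. Frames outside the trace span are
#' flagged and carry `NA` force (no extrapolation).
#'
#' @param cine A `cine_sequence`.
#' @param force_trace Data.frame with `t_s` and `force_N`.
#' @param time_offset Alignment offset (s): a frame at time `t` reads the
#'   trace at `t + time_offset`.
#' @param alignment Optional list from [align_events()] carried into the
#'   result for provenance.
#' @return A data.frame of class `sync_result` with columns `frame`,
#'   `t_s`, `force_N`, `in_span`; attributes `time_offset`,
#'   `alignment_residual`, `valid`.
#' @export
assign_force <- function(cine, force_trace, time_offset,
                         alignment = NULL) {
  t_query <- cine$times + time_offset
  span <- range(force_trace$t_s)
  in_span <- t_query >= span[1] & t_query <= span[2]
  if (!any(in_span)) {
    stop("assign_force: no temporal overlap between frames and force trace")
  }
  f <- rep(NA_real_, length(t_query))
  f[in_span] <- stats::approx(force_trace$t_s, force_trace$force_N,
                              xout = t_query[in_span])$y
  out <- data.frame(frame = seq_along(cine$times), t_s = cine$times,
                    force_N = f, in_span = in_span)
  attr(out, "time_offset") <- time_offset
  attr(out, "alignment_residual") <-
    if (is.null(alignment)) NA_real_ else alignment$alignment_residual
  attr(out, "valid") <- if (is.null(alignment)) TRUE else alignment$valid
  class(out) <- c("sync_result", "data.frame")
  out
}

#' Synchronize a cine sequence with a force trace
#'
#' End-to-end synchronization: optical-flow position signal, five-event
#' detection in both signals, first/last-pair alignment with the
#' middle-pair residual check, and per-frame force assignment.
#'
#' @inheritParams assign_force
#' @param residual_max Residual budget passed to [align_events()].
#' @param on_invalid `"error"` to abort when the residual exceeds the
#'   budget (pipeline behaviour), `"flag"` to return the flagged result.
#' @return A `sync_result` (see [assign_force()]).
#' @export
synchronize <- function(cine, force_trace, residual_max = 0.7,
                        on_invalid = c("error", "flag")) {
  on_invalid <- match.arg(on_invalid)
  flow <- compute_flow_signal(cine)
  flow_ev <- detect_events(flow$position, flow$frame_time)
  force_ev <- detect_events(force_trace$force_N, force_trace$t_s)
  al <- align_events(force_ev, flow_ev, residual_max = residual_max)
  if (!al$valid && on_invalid == "error") {
    stop(sprintf(
      "synchronize: alignment residual %.3f s exceeds budget %.3f s",
      al$alignment_residual, residual_max))
  }
  assign_force(cine, force_trace, al$time_offset, alignment = al)
}
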