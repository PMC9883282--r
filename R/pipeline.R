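#' Run the full measurement pipeline on a cine/force pair
#'
#' Synchronization (five-event alignment), per-frame segmentation with
#' seed propagation, collapse-force estimation with both uncertainty
#' components, and optionally venous-pressure waveform inversion over a
#' near-constant-force window. Every stage logs the thresholds it
#' applied; any stage error aborts with the stage name.
#'
#' @param cine A `cine_sequence` (or TIFF path; see [read_cine()]).
#' @param force A `force_trace` (or CSV path; see [read_force_csv()]).
#' @param config A [run_config()].
#' @param seed Optional initial seed (`c(row, col)` px); `NULL` uses the
#'   heuristic detector.
#' @param ramp_window Optional `c(t0, t1)` restricting the area-force
#'   curve (s, frame clock); `NULL` uses all synchronized frames.
#' @param waveform_window Optional `c(t0, t1)` near-constant-force
#'   window for pressure inversion; `NULL` skips the waveform stage.
#' @param anchor_pressure Anchor CVP (mmHg) for the waveform stage
#'   (required with `waveform_window`).
#' @param forward_params [forward_model_params()] for inversion.
#' @return A list of class `pipeline_result`: `sync` (a `sync_result`),
#'   `segmentation` (a `segmentation_table`), `curve`, `collapse` (a
#'   `collapse_estimate`), `waveform` (or `NULL`), `log` (character),
#'   `config`.
#' @export
run_pipeline <- function(cine, force, config = run_config(), seed = NULL,
                         ramp_window = NULL, waveform_window = NULL,
                         anchor_pressure = NULL,
                         forward_params = forward_model_params()) {
  if (is.character(cine)) cine <- read_cine(cine)
  if (is.character(force)) force <- read_force_csv(force)
  log <- c(sprintf("config %s", .config_hash(config)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("%s stage: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  sync <- stage("sync", synchronize(cine, force,
                                    residual_max = config$sync_residual_max))
  log <- c(log, sprintf(
    "sync: offset %.3f s, residual %.3f s (budget %.2f s)",
    attr(sync, "time_offset"), attr(sync, "alignment_residual"),
    config$sync_residual_max))
  seg <- stage("segment", segment_sequence(cine, sync = sync, seed = seed,
                                           config = config))
  n_flagged <- sum(seg$stages == "collapsed")
  log <- c(log, sprintf(
    "segment: %d frames, %d collapsed, near-collapse rule < %g mm^2",
    nrow(seg), n_flagged, config$near_collapse_threshold))
  curve <- stage("collapse", build_curve(seg, window = ramp_window,
                                         collapse_mm2 = config$collapse_threshold))
  collapse <- stage("collapse",
                    estimate_collapse(curve,
                                      collapse_mm2 = config$collapse_threshold,
                                      envelope_mm2 = config$near_collapse_threshold,
                                      min_contact_N = config$min_contact_force))
  log <- c(log, sprintf(
    "collapse: %.3f N (cardiac [%.3f, %.3f], segmentation %.3f N)",
    collapse$collapse_force, collapse$cardiac_low, collapse$cardiac_high,
    collapse$segmentation_uncertainty))
  waveform <- NULL
  if (!is.null(waveform_window)) {
    if (is.null(anchor_pressure)) {
      stop("waveform stage: anchor_pressure required")
    }
    win <- seg$t_s >= waveform_window[1] & seg$t_s <= waveform_window[2] &
      is.finite(seg$force_N) & seg$area_mm2 > 0
    anchor <- anchor_spec(seg$area_mm2[win], anchor_pressure)
    waveform <- stage("waveform",
                      invert_sequence(seg$area_mm2[win], seg$force_N[win],
                                      seg$t_s[win], anchor, forward_params))
    log <- c(log, sprintf(
      "waveform: %d frames, %d converged, anchored at %.2f mmHg",
      nrow(waveform), sum(waveform$converged), anchor_pressure))
  }
  structure(list(sync = sync, segmentation = seg, curve = curve,
                 collapse = collapse, waveform = waveform, log = log,
                 config = config),
            class = "pipeline_result")
}
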