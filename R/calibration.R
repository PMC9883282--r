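#' Load the bundled subject table
#'
#' Cohort of 27 healthy subjects: demographics, the measured jugular
#' venous pulsation height (JVP, mmHg), and collapse forces (N) in three
#' conditions -- supine breathing normally, elevated 16 degrees, and
#' Valsalva while supine. Missing measurements are `NA`.
#'
#' @param path Optional path to an alternative CSV with the same columns.
#' @return Data.frame with columns `subject_id, age_years, sex,
#'   height_cm, bmi, jvp_mmhg, cf_supine_n, cf_tilt16_n, cf_valsalva_n`.
#' @export
load_subjects <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "subjects.csv", package = "veinpress")
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "jvp_mmhg", "cf_supine_n", "cf_tilt16_n",
            "cf_valsalva_n")
  if (!all(need %in% names(d))) {
    stop("load_subjects: missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  d
}

# cmH2O -> mmHg
.CMH2O_TO_MMHG <- 0.7356

#' JVP pressure from tilt angle
#'
#' Converts the recline angle at which jugular pulsations become visible
#' at the base of the neck into a venous pressure, modeling the vein as
#' a water column of height `ra_to_neck * sin(theta)` above the right
#' atrium.
#'
#' @param theta Tilt angle above horizontal (degrees, 0..90). Vectorized.
#' @param ra_to_neck Vertical distance right atrium to neck base when
#'   upright (cm), default 10.
#' @param cmh2o_to_mmhg Unit conversion, default 0.7356.
#' @return JVP (mmHg).
#' @export
jvp_from_tilt_angle <- function(theta, ra_to_neck = 10,
                                cmh2o_to_mmhg = .CMH2O_TO_MMHG) {
  if (any(!is.finite(theta)) || any(theta < 0 | theta > 90)) {
    stop("jvp_from_tilt_angle: theta must be within [0, 90] degrees")
  }
  ra_to_neck * sin(theta * pi / 180) * cmh2o_to_mmhg
}

#' Calibrate collapse force against JVP
#'
#' Ordinary least squares of JVP on supine collapse force over the
#' complete pairs. Errors-in-variables are ignored (the regression
#' direction matches its use: predicting venous pressure from collapse
#' force).
#'
#' @param records Subject table from [load_subjects()].
#' @return A list of class `calibration_fit`: `slope` (mmHg/N),
#'   `intercept` (mmHg), `r_squared`, `n`.
#' @export
fit_collapse_jvp <- function(records) {
  cc <- stats::complete.cases(records$jvp_mmhg, records$cf_supine_n)
  d <- records[cc, ]
  if (nrow(d) < 3L) stop("fit_collapse_jvp: need at least 3 complete pairs")
  if (stats::sd(d$cf_supine_n) < 1e-12) {
    stop("fit_collapse_jvp: zero variance in collapse force")
  }
  fit <- stats::lm(jvp_mmhg ~ cf_supine_n, data = d)
  sst <- sum((d$jvp_mmhg - mean(d$jvp_mmhg))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(stats::resid(fit)^2) / sst
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n = nrow(d)),
            class = "calibration_fit")
}

#' Predict central venous pressure from collapse force
#'
#' @param cf Collapse force (N). Vectorized.
#' @param fit A [fit_collapse_jvp()] result.
#' @return Predicted CVP (mmHg).
#' @export
predict_cvp <- function(cf, fit) {
  fit$slope * cf + fit$intercept
}

#' Bland-Altman agreement of predicted and measured JVP
#'
#' Differences are predicted minus measured over the complete pairs;
#' reports the mean absolute difference, the bias, and the 95% limits
#' of agreement (bias +/- 1.96 SD).
#'
#' @param records Subject table.
#' @param fit A [fit_collapse_jvp()] result.
#' @return A list of class `agreement_stats`: `mean_abs_diff`, `bias`,
#'   `loa_low`, `loa_high` (mmHg), `n`.
#' @export
agreement <- function(records, fit) {
  cc <- stats::complete.cases(records$jvp_mmhg, records$cf_supine_n)
  d <- records[cc, ]
  if (nrow(d) < 3L) stop("agreement: need at least 3 complete pairs")
  diffs <- predict_cvp(d$cf_supine_n, fit) - d$jvp_mmhg
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  structure(list(mean_abs_diff = mean(abs(diffs)), bias = bias,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = nrow(d)),
            class = "agreement_stats")
}

#' Tilt and Valsalva perturbation summaries
#'
#' Per-subject collapse-force differences for the two venous-pressure
#' perturbations: `supine - tilt16` (hydrostatic decrease) and
#' `valsalva - supine` (intrathoracic increase), over pairwise-complete
#' subjects, plus the per-subject ordering check
#' Valsalva > supine > 16 degrees where all three exist.
#'
#' @param records Subject table.
#' @return A list of class `perturbation_summary`: `tilt_diffs`,
#'   `valsalva_diffs` (named by subject), `mean_tilt_diff`,
#'   `mean_valsalva_diff` (N), `ordering_ok` (logical per all-three
#'   subject), `all_ordered`.
#' @export
perturbation_summary <- function(records) {
  td <- stats::complete.cases(records$cf_supine_n, records$cf_tilt16_n)
  vd <- stats::complete.cases(records$cf_supine_n, records$cf_valsalva_n)
  tilt_diffs <- stats::setNames(
    records$cf_supine_n[td] - records$cf_tilt16_n[td],
    records$subject_id[td])
  valsalva_diffs <- stats::setNames(
    records$cf_valsalva_n[vd] - records$cf_supine_n[vd],
    records$subject_id[vd])
  a3 <- stats::complete.cases(records$cf_supine_n, records$cf_tilt16_n,
                              records$cf_valsalva_n)
  ordering_ok <- stats::setNames(
    records$cf_valsalva_n[a3] > records$cf_supine_n[a3] &
      records$cf_supine_n[a3] > records$cf_tilt16_n[a3],
    records$subject_id[a3])
  structure(list(tilt_diffs = tilt_diffs, valsalva_diffs = valsalva_diffs,
                 mean_tilt_diff = mean(tilt_diffs),
                 mean_valsalva_diff = mean(valsalva_diffs),
                 ordering_ok = ordering_ok,
                 all_ordered = all(ordering_ok)),
            class = "perturbation_summary")
}

#' Expected hydrostatic collapse-force decrease on tilting
#'
#' The collapse-force decrease a tilt to `theta` degrees would produce
#' if the only effect were the hydrostatic pressure drop
#' `ra_to_neck * sin(theta)` cmH2O and the calibration line predicted
#' collapse force perfectly. Venous pressure is floored at 0 mmHg: the
#' IJV is exposed to atmospheric pressure transmurally and collapses
#' rather than sustaining negative lumen pressure.
#'
#' @param cf_supine Supine collapse force (N). Vectorized.
#' @param fit A [fit_collapse_jvp()] result (slope > 0).
#' @param theta Tilt angle (degrees), default 16.
#' @param ra_to_neck Right atrium to neck-base distance (cm), default 10.
#' @return Expected `cf_supine - cf_tilt` (N).
#' @export
hydrostatic_expected_difference <- function(cf_supine, fit, theta = 16,
                                            ra_to_neck = 10) {
  stopifnot(fit$slope > 0)
  cvp_sup <- predict_cvp(cf_supine, fit)
  drop <- jvp_from_tilt_angle(theta, ra_to_neck)
  cvp_tilt <- pmax(cvp_sup - drop, 0)
  cf_supine - (cvp_tilt - fit$intercept) / fit$slope
}
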