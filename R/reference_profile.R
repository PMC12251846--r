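#' Referential inhalation profile specifications
#'
#' Parameterises the simplified "slow, deep breath" reference profile of a
#' COPD patient: a rising limb from rest up to the Peak Inspiratory Flow at
#' `time_to_pif`, followed by a decaying limb that returns to zero flow at
#' `total_duration`.  Profiles are condensed into `n_points` data points
#' (default 18), mirroring what the prototype's pressure sensor would record.
#'
#' The published reference profiles are shown only graphically, so the
#' absolute coordinates here are acknowledged stand-ins; the training
#' simulation consumes only quantities relative to the reference (simulated
#' vs reference inhaled volume), so absolute calibration of PIF and duration
#' is not required.  Severity defaults: moderate PIF 30 L/min over 4.0 s
#' (time-to-PIF 0.8 s); severe PIF 35 L/min over 4.5 s (time-to-PIF 1.0 s).
#'
#' @param severity `"moderate"` or `"severe"`; selects the default PIF,
#'   time-to-PIF and duration.
#' @param pif Peak Inspiratory Flow, L/min (> 0).
#' @param time_to_pif Seconds from start of inhalation to PIF
#'   (0 < `time_to_pif` < `total_duration`).
#' @param total_duration Total inhalation time, seconds.
#' @param rise_shape Dimensionless curvature of the rising limb: flow grows as
#'   `(t / time_to_pif)^rise_shape`.  Values < 1 give the steep early rise
#'   typical of inhalation onset.  Default 0.7.
#' @param decay_shape Dimensionless curvature of the decaying limb: flow
#'   falls as `((T - t) / (T - time_to_pif))^decay_shape`.  Values > 1 give
#'   the long shallow tail of the late inhalation.  Default 1.8.
#' @param n_points Number of condensed data points. Default 18.
#' @return An object of class `severity_profile_spec`.
#' @export
severity_profile_spec <- function(severity = c("moderate", "severe"),
                                  pif = NULL, time_to_pif = NULL,
                                  total_duration = NULL,
                                  rise_shape = 0.7, decay_shape = 1.8,
                                  n_points = 18) {
  severity <- match.arg(severity)
  defaults <- switch(severity,
    moderate = list(pif = 30, time_to_pif = 0.8, total_duration = 4.0),
    severe   = list(pif = 35, time_to_pif = 1.0, total_duration = 4.5)
  )
  pif <- if (is.null(pif)) defaults$pif else pif
  time_to_pif <- if (is.null(time_to_pif)) defaults$time_to_pif else time_to_pif
  total_duration <- if (is.null(total_duration)) defaults$total_duration else total_duration
  if (!is.numeric(pif) || pif <= 0) {
    stop("`pif` must be positive", call. = FALSE)
  }
  if (!(time_to_pif > 0 && time_to_pif < total_duration)) {
    stop("need 0 < `time_to_pif` < `total_duration`", call. = FALSE)
  }
  if (rise_shape <= 0 || decay_shape <= 0) {
    stop("shape parameters must be positive", call. = FALSE)
  }
  if (n_points < 4) stop("`n_points` must be at least 4", call. = FALSE)
  structure(
    list(severity = severity, pif = pif, time_to_pif = time_to_pif,
         total_duration = total_duration, rise_shape = rise_shape,
         decay_shape = decay_shape, n_points = as.integer(n_points)),
    class = "severity_profile_spec"
  )
}

#' @export
print.severity_profile_spec <- function(x, ...) {
  cat(sprintf("<severity_profile_spec> %s COPD: PIF %.1f L/min at %.2f s, %.1f s total, %d points\n",
              x$severity, x$pif, x$time_to_pif, x$total_duration, x$n_points))
  invisible(x)
}

#' Build a referential inhalation profile
#'
#' Deterministically constructs the condensed `n_points` reference
#' [flow_curve()] described by a [severity_profile_spec()]: a power-law rise
#' from rest to the PIF at `time_to_pif`, then a power-law decay to zero flow
#' at `total_duration`.  The grid always contains the PIF time, so the curve
#' attains its maximum exactly at `time_to_pif` and is unimodal.
#'
#' @param spec A [severity_profile_spec()].
#' @return A [flow_curve()] with `spec$n_points` points.
#' @examples
#' fc <- build_reference_profile(severity_profile_spec("moderate"))
#' peak_inspiratory_flow(fc)
#' @export
build_reference_profile <- function(spec) {
  if (!inherits(spec, "severity_profile_spec")) {
    stop("`spec` must be a severity_profile_spec", call. = FALSE)
  }
  n <- spec$n_points
  # allocate grid points to the two limbs in proportion to their durations,
  # keeping at least 2 rise segments and 2 decay segments
  n_rise <- min(max(round((n - 1) * spec$time_to_pif / spec$total_duration), 2),
                n - 3)
  t_up <- seq(0, spec$time_to_pif, length.out = n_rise + 1)
  t_dn <- seq(spec$time_to_pif, spec$total_duration,
              length.out = n - n_rise)[-1]
  times <- c(t_up, t_dn)
  flows <- ifelse(
    times <= spec$time_to_pif,
    spec$pif * (times / spec$time_to_pif)^spec$rise_shape,
    spec$pif * ((spec$total_duration - times) /
                  (spec$total_duration - spec$time_to_pif))^spec$decay_shape
  )
  flow_curve(times, flows)
}

#' Pre-PIF segment indicator
#'
#' For a reference curve, flags which of its `n_points - 1` slope segments
#' lie before the Peak Inspiratory Flow.  Used to apply the pre- vs post-PIF
#' variability levels when sampling simulated inhalations.
#'
#' @param curve A [flow_curve()].
#' @return Logical vector of length `n_points - 1`; `TRUE` for segments that
#'   end at or before the PIF point.
#' @export
pre_pif_segments <- function(curve) {
  stopifnot(inherits(curve, "flow_curve"))
  i <- peak_inspiratory_flow(curve)$index
  seq_len(curve$n_points - 1) < i
}
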