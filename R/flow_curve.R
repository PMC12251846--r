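#' Inhalation flow curves
#'
#' A `flow_curve` is a time-ordered inhalation profile: strictly increasing
#' sampling times in seconds (starting at 0) and the instantaneous inspiratory
#' flow rate in L/min at each time.  Inhalation starts from rest, so the first
#' flow is always 0.  The maximum of the curve is the patient's Peak
#' Inspiratory Flow (PIF); when several points tie at the maximum the earliest
#' one is taken as the PIF point.
#'
#' @param times Numeric vector of sampling times in seconds; strictly
#'   increasing, first element 0.
#' @param flows Numeric vector of flow rates in L/min; non-negative, same
#'   length as `times`, first element 0.
#' @return An object of class `flow_curve` with fields `times`, `flows` and
#'   `n_points`.
#' @examples
#' fc <- flow_curve(c(0, 1, 2, 3), c(0, 30, 20, 5))
#' peak_inspiratory_flow(fc)
#' inhaled_volume(fc)
#' @export
flow_curve <- function(times, flows) {
  if (!is.numeric(times) || !is.numeric(flows)) {
    stop("`times` and `flows` must be numeric", call. = FALSE)
  }
  if (length(times) != length(flows)) {
    stop("`times` and `flows` must have the same length", call. = FALSE)
  }
  if (length(times) < 2) {
    stop("a flow curve needs at least 2 points", call. = FALSE)
  }
  if (anyNA(times) || anyNA(flows)) {
    stop("`times` and `flows` must not contain NA", call. = FALSE)
  }
  if (times[1] != 0) {
    stop("`times` must start at 0", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing (duplicate time points are invalid)",
         call. = FALSE)
  }
  if (any(flows < 0)) {
    stop("`flows` must be non-negative", call. = FALSE)
  }
  if (flows[1] != 0) {
    stop("inhalation starts from rest: `flows[1]` must be 0", call. = FALSE)
  }
  structure(
    list(times = as.numeric(times), flows = as.numeric(flows),
         n_points = length(times)),
    class = "flow_curve"
  )
}

#' @export
print.flow_curve <- function(x, ...) {
  pif <- peak_inspiratory_flow(x)
  cat(sprintf("<flow_curve> %d points over %.2f s; PIF %.1f L/min at %.2f s; inhaled volume %.3f L\n",
              x$n_points, max(x$times), pif$pif, pif$time_to_pif,
              inhaled_volume(x)))
  invisible(x)
}

#' @export
as.data.frame.flow_curve <- function(x, ...) {
  data.frame(time_s = x$times, flow_lpm = x$flows)
}

#' Peak Inspiratory Flow of a curve
#'
#' Returns the PIF (maximum flow, L/min), the time at which it is attained
#' and its index.  Ties are broken towards the earliest time point.
#'
#' @param curve A [flow_curve()].
#' @return A list with elements `pif`, `time_to_pif` and `index`.
#' @export
peak_inspiratory_flow <- function(curve) {
  stopifnot(inherits(curve, "flow_curve"))
  i <- which.max(curve$flows)  # which.max already keeps the earliest tie
  list(pif = curve$flows[i], time_to_pif = curve$times[i], index = i)
}

#' Device resistance
#'
#' The inhaler's pressure-per-flow resistance R, a positive dimensionless
#' constant linking the sensed pressure drop to the flow rate (Q = dp / R).
#' The prototypes assume R = 1.
#'
#' @param R Positive scalar resistance. Default 1.
#' @return A validated numeric scalar of class `device_resistance`.
#' @export
device_resistance <- function(R = 1) {
  if (!is.numeric(R) || length(R) != 1 || is.na(R) || R <= 0) {
    stop("device resistance `R` must be a positive scalar", call. = FALSE)
  }
  structure(as.numeric(R), class = "device_resistance")
}

#' Flow rate from a sensed pressure drop
#'
#' Converts the pressure drop sensed across the inhaler mouthpiece into an
#' instantaneous inspiratory flow rate, `Q = delta_p / R`.  Linear in
#' `delta_p`; vectorised.
#'
#' @param delta_p Non-negative pressure drop(s).
#' @param resistance A [device_resistance()] or positive scalar. Default 1.
#' @return Flow rate(s), same units as `delta_p` scaled by 1/R.
#' @examples
#' flow_from_pressure(6, device_resistance(2))  # 3
#' @export
flow_from_pressure <- function(delta_p, resistance = device_resistance()) {
  if (!inherits(resistance, "device_resistance")) {
    resistance <- device_resistance(resistance)
  }
  if (!is.numeric(delta_p) || anyNA(delta_p) || any(delta_p < 0)) {
    stop("`delta_p` must be non-negative", call. = FALSE)
  }
  delta_p / unclass(resistance)
}

#' Decompose a flow curve into segment slopes
#'
#' The slope of segment i is the flow change per second between consecutive
#' sampled points, `(flows[i+1] - flows[i]) / (times[i+1] - times[i])`
#' (units: L/min per s).  The slopes, together with the starting flow and the
#' time grid, carry the full information of the curve (see
#' [recompose_from_slopes()]).
#'
#' @param curve A [flow_curve()].
#' @return Numeric vector of `n_points - 1` slopes.
#' @export
decompose_slopes <- function(curve) {
  stopifnot(inherits(curve, "flow_curve"))
  diff(curve$flows) / diff(curve$times)
}

#' Rebuild a flow curve from segment slopes
#'
#' Inverse of [decompose_slopes()]: starting from `start_flow`, each segment's
#' slope is integrated over its time step.  Because a perturbed slope shifts
#' the starting flow of every later segment, an error in one slope propagates
#' cumulatively through the rest of the curve.  Physically the flow cannot be
#' negative, so any negative intermediate flow is clamped to 0 before the
#' next segment is built; the number of clamped points is recorded in the
#' `n_clamped` attribute of the result.
#'
#' @param start_flow Flow at the first time point (L/min); normally 0.
#' @param slopes Numeric vector of segment slopes (L/min per s), length
#'   `length(times) - 1`.
#' @param times Time grid in seconds (strictly increasing, starting at 0).
#' @return A [flow_curve()], with attribute `n_clamped`.
#' @examples
#' recompose_from_slopes(0, c(10, -20), c(0, 1, 2))  # flows 0, 10, 0 (clamped)
#' @export
recompose_from_slopes <- function(start_flow, slopes, times) {
  if (length(slopes) != length(times) - 1) {
    stop("`slopes` must have length `length(times) - 1`", call. = FALSE)
  }
  if (start_flow < 0) stop("`start_flow` must be non-negative", call. = FALSE)
  dt <- diff(times)
  flows <- numeric(length(times))
  flows[1] <- start_flow
  n_clamped <- 0L
  for (i in seq_along(slopes)) {
    f <- flows[i] + slopes[i] * dt[i]
    if (f < 0) {
      f <- 0
      n_clamped <- n_clamped + 1L
    }
    flows[i + 1] <- f
  }
  out <- flow_curve(times, flows)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Inhaled volume under a flow curve
#'
#' Approximates the inhaled volume as the cumulative sum of the trapezoidal
#' areas under the flow-time curve,
#' `sum((t[i+1] - t[i]) * (Q[i] + Q[i+1]) / 2)`.  Times are in seconds and
#' flows in L/min, so the sum is divided by 60 to give litres.
#'
#' @param curve A [flow_curve()].
#' @return Inhaled volume in litres (non-negative).
#' @examples
#' inhaled_volume(flow_curve(c(0, 60), c(0, 2)))  # 1 L triangle
#' @export
inhaled_volume <- function(curve) {
  stopifnot(inherits(curve, "flow_curve"))
  f <- curve$flows
  sum(diff(curve$times) * (f[-length(f)] + f[-1]) / 2) / 60
}

#' Read / write inhalation profiles as CSV
#'
#' Profiles are exchanged as two-column CSV files with a one-line header
#' `time_s,flow_lpm`.
#'
#' @param path File path.
#' @return `read_flow_curve()` returns a [flow_curve()];
#'   `write_flow_curve()` returns `path` invisibly.
#' @export
read_flow_curve <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "flow_lpm") %in% names(d))) {
    stop("profile CSV must have columns `time_s` and `flow_lpm`", call. = FALSE)
  }
  flow_curve(d$time_s, d$flow_lpm)
}

#' @param curve A [flow_curve()] to serialise.
#' @rdname read_flow_curve
#' @export
write_flow_curve <- function(curve, path) {
  stopifnot(inherits(curve, "flow_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
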