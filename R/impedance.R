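#' Impedance (cell-index) trace
#'
#' Container for a real-time cell-analysis trace: cell-index values sampled
#' at strictly increasing times, with a processing state.
#'
#' @param time_h numeric vector of sampling times (hours), strictly
#'   increasing.
#' @param cell_index numeric vector of cell-index values, same length.
#' @param well well identifier.
#' @param state one of `"raw"`, `"normalized"`, `"baseline_subtracted"`.
#' @param t_ref reference time (h) the trace was normalized to (NA if raw).
#' @return An object of class `impedance_trace`.
#' @export
impedance_trace <- function(time_h, cell_index, well = "W01",
                            state = c("raw", "normalized",
                                      "baseline_subtracted"),
                            t_ref = NA_real_) {
  state <- match.arg(state)
  stopifnot(length(time_h) == length(cell_index), length(time_h) >= 2L)
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing")
  structure(
    list(well = well, time_h = as.numeric(time_h),
         cell_index = as.numeric(cell_index), state = state, t_ref = t_ref),
    class = "impedance_trace"
  )
}

#' @export
print.impedance_trace <- function(x, ...) {
  cat(sprintf("<impedance_trace> well %s, %d points over [%g, %g] h, state: %s\n",
              x$well, length(x$time_h), min(x$time_h), max(x$time_h), x$state))
  invisible(x)
}

#' @export
as.data.frame.impedance_trace <- function(x, ...) {
  data.frame(well = x$well, time_h = x$time_h, cell_index = x$cell_index,
             state = x$state)
}

.trace_value_at <- function(trace, t) {
  if (t < min(trace$time_h) || t > max(trace$time_h)) {
    stop("time ", t, " h outside sampled range")
  }
  approx(trace$time_h, trace$cell_index, xout = t)$y
}

#' Normalize a trace to the compound-addition time and subtract the baseline
#'
#' Raw traces are divided by their value at the reference time `t_ref`
#' (compound addition), so the normalized trace is exactly 1 there --
#' real-time cell-analysis convention.  Optionally the identically
#' normalized mean trace of baseline wells (vehicle, no TGF-beta1) is then
#' subtracted, after linear resampling onto the trace's time grid.
#'
#' Normalization is idempotent: preprocessing an already-normalized trace
#' with the same `t_ref` is a no-op (its reference value is 1).
#'
#' @param raw an [impedance_trace()] (state `"raw"` or `"normalized"`).
#' @param t_ref reference time (h), within the sampled range.
#' @param baseline optional [impedance_trace()] holding the baseline mean
#'   (raw or normalized; it is normalized to the same `t_ref` first).
#' @param method `"divide"` (default, value 1 at `t_ref`) or `"subtract"`
#'   (value 0 at `t_ref`).
#' @return An `impedance_trace` with state `"normalized"` or, when a
#'   baseline is supplied, `"baseline_subtracted"`.
#' @export
preprocess_trace <- function(raw, t_ref = 0, baseline = NULL,
                             method = c("divide", "subtract")) {
  method <- match.arg(method)
  stopifnot(inherits(raw, "impedance_trace"))
  if (raw$state == "baseline_subtracted") {
    stop("trace is already baseline-subtracted")
  }
  v0 <- .trace_value_at(raw, t_ref)
  if (method == "divide") {
    if (v0 <= 0) stop("raw value at t_ref is <= 0; cannot normalize")
    values <- raw$cell_index / v0
  } else {
    values <- raw$cell_index - v0
  }
  out <- impedance_trace(raw$time_h, values, well = raw$well,
                         state = "normalized", t_ref = t_ref)
  if (!is.null(baseline)) {
    stopifnot(inherits(baseline, "impedance_trace"))
    if (baseline$state == "baseline_subtracted") {
      stop("baseline trace must be raw or normalized")
    }
    b <- preprocess_trace(baseline, t_ref = t_ref, method = method)
    bv <- approx(b$time_h, b$cell_index, xout = out$time_h, rule = 2)$y
    out <- impedance_trace(out$time_h, out$cell_index - bv, well = raw$well,
                           state = "baseline_subtracted", t_ref = t_ref)
  }
  out
}

#' Baseline-subtracted response at a time point
#'
#' Linear interpolation of a baseline-subtracted trace at time `t`; the
#' screening readout uses t = 20 h after TGF-beta1 addition (72 h in
#' reversal mode).
#'
#' @param trace an [impedance_trace()] with state `"baseline_subtracted"`.
#' @param t time (h), within the sampled range.
#' @return Scalar response (normalized cell-index units).
#' @export
trace_response <- function(trace, t = 20) {
  stopifnot(inherits(trace, "impedance_trace"))
  if (trace$state != "baseline_subtracted") {
    stop("trace must be baseline-subtracted before reading a response")
  }
  .trace_value_at(trace, t)
}

#' Locate the nadir of a trace within a time window
#'
#' Returns the earliest time of the minimum cell-index value inside the
#' window.  Compounds that relax the myofibroblast cytoskeleton produce an
#' immediate impedance drop with a nadir a few hours after addition.
#'
#' @param trace an [impedance_trace()].
#' @param window numeric length-2 vector `c(from, to)` in hours.
#' @return list with `time` (h) and `depth` (trace value at the nadir).
#' @export
find_nadir <- function(trace, window = c(0, 6)) {
  stopifnot(inherits(trace, "impedance_trace"), length(window) == 2L)
  if (window[2] < window[1]) stop("empty window")
  sel <- trace$time_h >= window[1] & trace$time_h <= window[2]
  if (!any(sel)) stop("window contains no samples")
  tt <- trace$time_h[sel]; vv <- trace$cell_index[sel]
  i <- which(vv == min(vv))[1]  # ties -> earliest
  list(time = tt[i], depth = vv[i])
}

#' Normalize MRM peak areas to tubulin
#'
#' Divides COL1A1 and ACTA peak areas by the TBA1A (tubulin) peak area of
#' the same well, removing the shared cell-number factor.  Wells with
#' non-positive tubulin area are flagged and get NA ratios.
#'
#' @param quants data.frame with columns `well`, `area_col1a1`,
#'   `area_acta`, `area_tba1a`.
#' @return The input with `ratio_col1`, `ratio_acta` and logical
#'   `tubulin_flag` columns appended; raw areas are preserved.
#' @export
normalize_to_tubulin <- function(quants) {
  stopifnot(is.data.frame(quants),
            all(c("area_col1a1", "area_acta", "area_tba1a") %in% names(quants)))
  ok <- quants$area_tba1a > 0
  quants$ratio_col1 <- ifelse(ok, quants$area_col1a1 / quants$area_tba1a, NA_real_)
  quants$ratio_acta <- ifelse(ok, quants$area_acta / quants$area_tba1a, NA_real_)
  quants$tubulin_flag <- !ok
  quants
}
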