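#' Centered moving average over a time window
#'
#' Replaces each point by the mean of all points within `+/- halfwidth_s`
#' seconds of it. Windows truncate at the record edges, so the output has
#' the same length as the input. A halfwidth of 0 is the identity.
#'
#' @param values Numeric vector of samples.
#' @param times Sample times in seconds (same length, non-decreasing).
#' @param halfwidth_s Window half-width in seconds (default 5).
#' @return Smoothed numeric vector, same length as `values`.
#' @export
moving_average <- function(values, times, halfwidth_s = 5) {
  stopifnot(length(values) == length(times), halfwidth_s >= 0)
  n <- length(values)
  if (n == 0L) return(numeric(0))
  if (is.unsorted(times)) stop("times must be ordered")
  if (halfwidth_s == 0) return(values)
  eps <- 1e-9
  lo <- findInterval(times - halfwidth_s - eps, times) + 1L
  hi <- findInterval(times + halfwidth_s + eps, times)
  cs <- cumsum(c(0, values))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Moving average over a fixed odd number of samples (edge-truncated).
.ma_samples <- function(values, width) {
  if (width <= 1L) return(values)
  n <- length(values)
  hw <- (width - 1L) %/% 2L
  lo <- pmax(seq_len(n) - hw, 1L)
  hi <- pmin(seq_len(n) + hw, n)
  cs <- cumsum(c(0, values))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Least-squares parabola vertex over a window of samples around index i0.
# Returns c(time, value) of the vertex; falls back to the sample itself
# when the fit is not concave (maximum = TRUE) / convex (FALSE).
.parabola_vertex <- function(times, values, i0, halfwin = 3L,
                             maximum = TRUE) {
  n <- length(values)
  idx <- max(1L, i0 - halfwin):min(n, i0 + halfwin)
  if (length(idx) < 3L) return(c(times[i0], values[i0]))
  tt <- times[idx] - times[i0]
  fit <- stats::lm.fit(cbind(1, tt, tt^2), values[idx])
  cf <- fit$coefficients
  a <- cf[3]; b <- cf[2]; c0 <- cf[1]
  ok <- if (maximum) is.finite(a) && a < 0 else is.finite(a) && a > 0
  if (!ok) return(c(times[i0], values[i0]))
  tv <- -b / (2 * a)
  # keep the vertex inside the fitted window
  tv <- min(max(tv, tt[1]), tt[length(tt)])
  c(times[i0] + tv, c0 + b * tv + a * tv^2)
}

#' Detect beats in a ventricular pressure trace
#'
#' Finds systolic peaks as local maxima exceeding a prominence threshold
#' above the diastolic baseline, separated by at least the refractory
#' interval implied by `max_rate_bpm`, and refines each peak's time and
#' height with the vertex of a least-squares parabola fitted around the
#' sample maximum. Each beat carries the preceding end-diastolic trough
#' and its within-beat dP/dt extrema. An arrest-flat trace yields an
#' empty beat series, not an error.
#'
#' @param trace A [sampled_trace()] of ventricular pressure (mmHg).
#' @param min_prominence_mmhg Minimum peak height above the diastolic
#'   baseline (default 20 mmHg). The baseline is estimated as the 10th
#'   percentile of the trace.
#' @param max_rate_bpm Maximum plausible heart rate; peaks closer than
#'   `60/max_rate_bpm` seconds are merged, keeping the higher (default 600).
#' @param vertex_halfwin Samples on each side of the argmax used in the
#'   parabola fit (default 3).
#' @param detect_smooth_s Half-width (s) of the pre-detection smoothing
#'   applied when locating peaks and troughs; peak heights are refined on
#'   the raw trace (default 0.004 s).
#' @return An object of class `beat_series`: a data frame with columns
#'   `peak_time`, `peak_pressure`, `trough_time`, `trough_pressure`,
#'   `dpdt_max`, `dpdt_min`; attributes `span` and `rate_hz`.
#' @export
detect_beats <- function(trace, min_prominence_mmhg = 20,
                         max_rate_bpm = 600, vertex_halfwin = 3L,
                         detect_smooth_s = 0.004) {
  stopifnot(inherits(trace, "sampled_trace"))
  v <- trace$values
  tt <- trace$times
  n <- length(v)
  smooth_w <- .odd_width(detect_smooth_s, trace$rate_hz)
  vs <- .ma_samples(v, smooth_w)

  baseline <- stats::quantile(vs, 0.1, names = FALSE)
  thr <- baseline + min_prominence_mmhg

  # strict local maxima of the smoothed series above the threshold
  cand <- which(vs > thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[vs[cand] >= vs[cand - 1L] & vs[cand] > vs[cand + 1L]]
  empty <- function() {
    structure(data.frame(peak_time = numeric(0), peak_pressure = numeric(0),
                         trough_time = numeric(0), trough_pressure = numeric(0),
                         dpdt_max = numeric(0), dpdt_min = numeric(0)),
              class = c("beat_series", "data.frame"),
              span = range(tt), rate_hz = trace$rate_hz)
  }
  if (length(cand) == 0L) return(empty())

  # refractory separation: greedy by height
  min_sep <- 60 / max_rate_bpm
  ord <- cand[order(vs[cand], decreasing = TRUE)]
  keep <- logical(0)
  kept_t <- numeric(0)
  for (i in ord) {
    if (all(abs(tt[i] - kept_t) >= min_sep)) kept_t <- c(kept_t, tt[i])
  }
  peaks <- sort(match(kept_t, tt))

  # vertex refinement on the raw trace, centred at the smoothed argmax
  # (centring on the raw argmax would select upward noise excursions).
  # The fit window scales with the beat period so the averaging power is
  # rate- and rhythm-independent while the systolic peak stays locally
  # quadratic across it.
  hw_peak <- vertex_halfwin
  if (length(peaks) >= 3L)
    hw_peak <- max(vertex_halfwin,
                   as.integer(round(0.042 * stats::median(diff(peaks)))))
  refined <- t(vapply(peaks, function(i)
    .parabola_vertex(tt, v, i, halfwin = hw_peak, maximum = TRUE),
    numeric(2)))

  # preceding end-diastolic trough: windowed mean of the smoothed trace
  # around its argmin (diastole is locally flat, so a plain argmin value
  # is biased low under noise)
  tw <- max(1L, as.integer(round(0.01 * trace$rate_hz)))
  if (length(peaks) >= 3L)
    tw <- max(tw, as.integer(round(0.05 * stats::median(diff(peaks)))))
  trough_t <- trough_v <- rep(NA_real_, length(peaks))
  drop_beat <- logical(length(peaks))
  # a record starting mid-beat has no usable first trough
  if (vs[1] > thr) drop_beat[1] <- TRUE
  for (k in seq_along(peaks)) {
    if (drop_beat[k]) next
    lo <- if (k == 1L) 1L else peaks[k - 1L]
    seg <- lo:peaks[k]
    j <- seg[which.min(vs[seg])]
    tw_k <- min(tw, length(seg) %/% 4L)
    win <- max(seg[1], j - tw_k):min(seg[length(seg)], j + tw_k)
    trough_t[k] <- tt[j]
    trough_v[k] <- mean(vs[win])
  }
  ok <- !drop_beat
  peaks <- peaks[ok]
  refined <- refined[ok, , drop = FALSE]
  trough_t <- trough_t[ok]; trough_v <- trough_v[ok]
  if (length(peaks) == 0L) return(empty())

  beats <- data.frame(peak_time = refined[, 1],
                      peak_pressure = pmax(refined[, 2], trough_v),
                      trough_time = trough_t,
                      trough_pressure = trough_v)
  dd <- .beat_dpdt(trace, beats)
  beats$dpdt_max <- dd$dpdt_max
  beats$dpdt_min <- dd$dpdt_min
  structure(beats, class = c("beat_series", "data.frame"),
            span = range(tt), rate_hz = trace$rate_hz)
}

#' @export
print.beat_series <- function(x, ...) {
  span <- attr(x, "span")
  cat(sprintf("<beat_series: %d beats over %.4g-%.4g s>\n",
              nrow(x), span[1], span[2]))
  if (nrow(x)) print.data.frame(utils::head(x, 5L))
  invisible(x)
}

# odd kernel width in samples for a half-width given in seconds
.odd_width <- function(halfwidth_s, rate_hz) {
  hw <- max(0L, as.integer(round(halfwidth_s * rate_hz)))
  2L * hw + 1L
}

# Central-difference derivative after a moving-average pre-smoothing of
# `width` samples.
.trace_derivative <- function(trace, width = 3L) {
  v <- trace$values
  if (width > 1L) v <- .ma_samples(v, width)
  n <- length(v)
  h <- 1 / trace$rate_hz
  d <- numeric(n)
  d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (2 * h)
  d[1] <- (v[2] - v[1]) / h
  d[n] <- (v[n] - v[n - 1L]) / h
  d
}

.odd <- function(w) 2L * (as.integer(w) %/% 2L) + 1L

# Per-beat dP/dt extrema between consecutive troughs. Three noise
# defences, all scaled to the beat period so behaviour is independent of
# the sampling rate: (i) pre-smoothing over ~2.5% of the beat before
# differencing, (ii) extremum *location* picked on a further-smoothed
# derivative (picking on the noisy series selects upward excursions),
# (iii) extremum *value* from a parabola vertex fitted over ~4% of the
# beat on each side, which averages the noise without max-picking bias.
.beat_dpdt <- function(trace, beats, smooth_s = NULL, vertex_halfwin = 5L) {
  nb <- nrow(beats)
  if (nb == 0L)
    return(list(dpdt_max = numeric(0), dpdt_min = numeric(0)))
  tt <- trace$times
  n <- length(tt)
  # beat k occupies [trough_k, trough_{k+1}) (last beat: to record end)
  bounds <- c(vapply(beats$trough_time, function(x)
    findInterval(x, tt), integer(1)), n)
  seglen <- pmax(3L, diff(bounds))
  medseg <- stats::median(seglen)
  width <- if (is.null(smooth_s)) {
    max(3L, .odd(round(0.0245 * medseg)))
  } else .odd_width(smooth_s, trace$rate_hz)
  d <- .trace_derivative(trace, width)
  hw_med <- max(vertex_halfwin, as.integer(round(0.042 * medseg)))
  # the selection series is smoothed 3x wider than the fit window: only
  # the extremum *location* is read off it, so the attenuation is
  # harmless while spurious noise maxima are suppressed
  ds <- .ma_samples(d, .odd(3L * hw_med))
  dpdt_max <- dpdt_min <- numeric(nb)
  # two passes: the first vertex fit relocates the extremum (the window
  # may initially overlap the flat diastolic segment), the second fit at
  # the relocated centre reads off the value
  fit2 <- function(i, hw, maximum) {
    vx <- .parabola_vertex(tt, d, i, hw, maximum)
    i2 <- max(2L, min(n - 1L, i + as.integer(round((vx[1] - tt[i]) *
                                                     trace$rate_hz))))
    .parabola_vertex(tt, d, i2, hw, maximum)[2]
  }
  for (k in seq_len(nb)) {
    seg <- max(1L, bounds[k]):max(1L, bounds[k + 1L])
    hw <- max(vertex_halfwin, as.integer(round(0.042 * length(seg))))
    dpdt_max[k] <- fit2(seg[which.max(ds[seg])], hw, TRUE)
    dpdt_min[k] <- fit2(seg[which.min(ds[seg])], hw, FALSE)
  }
  list(dpdt_max = dpdt_max, dpdt_min = dpdt_min)
}

#' Heart rate from detected beats
#'
#' `60 /` mean inter-peak interval (s) over the window; 0 when fewer
#' than two beats fall inside the window.
#'
#' @param beats A [detect_beats()] result.
#' @param window Optional `c(start, end)` in seconds; default whole record.
#' @return Heart rate in beats per minute.
#' @export
heart_rate <- function(beats, window = NULL) {
  pt <- beats$peak_time
  if (!is.null(window)) pt <- pt[pt >= window[1] & pt <= window[2]]
  if (length(pt) < 2L) return(0)
  60 / mean(diff(pt))
}

#' Left-ventricular developed pressure
#'
#' Mean over beats of (systolic peak minus preceding end-diastolic
#' trough). `NA` for an empty beat series.
#'
#' @param beats A [detect_beats()] result.
#' @param window Optional `c(start, end)` in seconds restricting which
#'   beats (by peak time) contribute.
#' @return Developed pressure in mmHg, or `NA_real_` with no beats.
#' @export
developed_pressure <- function(beats, window = NULL) {
  keep <- rep(TRUE, nrow(beats))
  if (!is.null(window))
    keep <- beats$peak_time >= window[1] & beats$peak_time <= window[2]
  if (!any(keep)) return(NA_real_)
  mean(beats$peak_pressure[keep] - beats$trough_pressure[keep])
}

#' Pressure derivatives (dP/dt max / min)
#'
#' Central-difference derivative of the (lightly smoothed) pressure
#' trace; per-beat extrema between consecutive end-diastolic troughs,
#' refined by a parabola vertex; summary values are the mean of the
#' `+/- 5 s` moving-averaged per-beat series. Warns when the sampling
#' rate is below 50 Hz, where finite differences are unreliable.
#'
#' @param trace The [sampled_trace()] the beats came from.
#' @param beats A [detect_beats()] result.
#' @param smooth_s Half-width (s) of pre-differentiation smoothing;
#'   `NULL` (default) scales the kernel to ~2.5% of the median beat
#'   period, keeping attenuation and noise behaviour independent of the
#'   sampling rate.
#' @param ma_halfwidth_s Half-width of the moving average applied to the
#'   per-beat series before summarising (default 5 s).
#' @return List with `per_beat` (data frame: `peak_time`, `dpdt_max`,
#'   `dpdt_min`) and summary scalars `dpdt_max`, `dpdt_min` (`NA` with
#'   no beats).
#' @export
pressure_derivatives <- function(trace, beats, smooth_s = NULL,
                                 ma_halfwidth_s = 5) {
  stopifnot(inherits(trace, "sampled_trace"))
  if (trace$rate_hz < 50)
    warning("sampling rate below 50 Hz; dP/dt estimates are unreliable")
  dd <- .beat_dpdt(trace, beats, smooth_s = smooth_s)
  per_beat <- data.frame(peak_time = beats$peak_time,
                         dpdt_max = dd$dpdt_max, dpdt_min = dd$dpdt_min)
  if (nrow(per_beat) == 0L)
    return(list(per_beat = per_beat, dpdt_max = NA_real_, dpdt_min = NA_real_))
  list(per_beat = per_beat,
       dpdt_max = mean(moving_average(per_beat$dpdt_max, per_beat$peak_time,
                                      ma_halfwidth_s)),
       dpdt_min = mean(moving_average(per_beat$dpdt_min, per_beat$peak_time,
                                      ma_halfwidth_s)))
}

#' Pressure-time integral (AUC)
#'
#' Trapezoidal integral of the raw pressure over a time span, in
#' mmHg*s. The span must lie within the trace.
#'
#' @param trace A [sampled_trace()].
#' @param span `c(start, end)` in seconds; default the whole trace.
#' @return Area under the pressure curve in mmHg*s.
#' @export
pt_integral <- function(trace, span = NULL) {
  stopifnot(inherits(trace, "sampled_trace"))
  tt <- trace$times
  v <- trace$values
  if (is.null(span)) span <- range(tt)
  if (span[1] < tt[1] - 1e-9 || span[2] > tt[length(tt)] + 1e-9)
    stop(sprintf("requested span [%g, %g] s exceeds trace extent [%g, %g] s",
                 span[1], span[2], tt[1], tt[length(tt)]))
  inside <- tt > span[1] & tt < span[2]
  # interpolated endpoint samples keep partial spans exact
  ts <- c(span[1], tt[inside], span[2])
  vs <- c(stats::approx(tt, v, span[1])$y, v[inside],
          stats::approx(tt, v, span[2])$y)
  sum(diff(ts) * (vs[-1] + vs[-length(vs)]) / 2)
}

#' Classify a heart as beating or non-beating
#'
#' A heart counts as beating when its rate, over some sliding window of
#' `min_duration_s` seconds, sustains at least `min_sustained_bpm` at any
#' time during the record. Isolated ectopic beats therefore do not
#' qualify.
#'
#' @param beats A [detect_beats()] result.
#' @param min_sustained_bpm Sustained-rate threshold (default 30 bpm).
#' @param min_duration_s Window length the rate must be sustained for
#'   (default 60 s).
#' @return `TRUE` or `FALSE`.
#' @export
classify_beating <- function(beats, min_sustained_bpm = 30,
                             min_duration_s = 60) {
  pt <- beats$peak_time
  need <- min_sustained_bpm * min_duration_s / 60  # inter-beat intervals
  if (length(pt) < need + 1) return(FALSE)
  # beats inside [pt_i, pt_i + D]: two-pointer over ordered peak times
  hi <- findInterval(pt + min_duration_s + 1e-9, pt)
  any(hi - seq_along(pt) >= need)
}

#' Summarise a reperfusion recording
#'
#' Computes the full hemodynamic summary of one Langendorff reperfusion:
#' beating call, heart rate, developed pressure, dP/dt extrema,
#' coronary flow, pressure-time integral, and per-10-minute timepoint
#' values (labelled A-F over a 60-min record, means over +/- 30 s around
#' each mark). Kinetic fields are `NA` for a non-beating heart; coronary
#' flow is still reported.
#'
#' @param lvp [sampled_trace()] of ventricular pressure (mmHg); may be
#'   `NULL`, flagging the pressure metrics as missing.
#' @param flow [sampled_trace()] of coronary flow (mL/min); may be
#'   `NULL`, flagging `cfr_ml_min` as missing.
#' @param expected_span_s Expected record length (default 3600 s); a
#'   shorter record is summarised with a warning.
#' @param timepoint_halfwidth_s Averaging half-width around each
#'   10-minute mark (default 30 s).
#' @param ... Passed to [detect_beats()].
#' @return An object of class `hemodynamic_summary`.
#' @export
summarize_reperfusion <- function(lvp, flow, expected_span_s = 3600,
                                  timepoint_halfwidth_s = 30, ...) {
  out <- list(beating = NA, hr_bpm = NA_real_, lvdp_mmhg = NA_real_,
              dpdt_max = NA_real_, dpdt_min = NA_real_,
              cfr_ml_min = NA_real_, auc = NA_real_,
              timepoints = NULL, missing = character(0))
  span <- NULL
  if (!is.null(lvp)) {
    stopifnot(inherits(lvp, "sampled_trace"))
    span <- range(lvp$times)
    if (diff(span) < expected_span_s - 1e-6)
      warning(sprintf("record covers %.1f s of the expected %.1f s",
                      diff(span), expected_span_s))
    beats <- detect_beats(lvp, ...)
    out$beating <- classify_beating(beats)
    out$auc <- pt_integral(lvp)
    if (out$beating) {
      out$hr_bpm <- heart_rate(beats)
      out$lvdp_mmhg <- developed_pressure(beats)
      pd <- pressure_derivatives(lvp, beats)
      out$dpdt_max <- pd$dpdt_max
      out$dpdt_min <- pd$dpdt_min
    }
  } else {
    out$missing <- c(out$missing, "LVP")
  }
  if (!is.null(flow)) {
    stopifnot(inherits(flow, "sampled_trace"))
    out$cfr_ml_min <- mean(flow$values)
    if (is.null(span)) span <- range(flow$times)
  } else {
    out$missing <- c(out$missing, "flow")
  }

  if (!is.null(span)) {
    marks <- seq(600, 3600, by = 600)
    marks <- marks[marks + span[1] <= span[2] + timepoint_halfwidth_s]
    if (length(marks)) {
      tp <- data.frame(label = LETTERS[seq_along(marks)],
                       minute = marks / 60,
                       hr_bpm = NA_real_, lvdp_mmhg = NA_real_,
                       cfr_ml_min = NA_real_)
      for (i in seq_along(marks)) {
        w <- span[1] + marks[i] + c(-1, 1) * timepoint_halfwidth_s
        if (!is.null(lvp) && isTRUE(out$beating)) {
          tp$hr_bpm[i] <- heart_rate(beats, window = w)
          tp$lvdp_mmhg[i] <- developed_pressure(beats, window = w)
        }
        if (!is.null(flow)) {
          sel <- flow$times >= w[1] & flow$times <= w[2]
          if (any(sel)) tp$cfr_ml_min[i] <- mean(flow$values[sel])
        }
      }
      out$timepoints <- tp
    }
  }
  structure(out, class = "hemodynamic_summary")
}

#' @export
print.hemodynamic_summary <- function(x, ...) {
  cat("Reperfusion hemodynamic summary\n")
  cat("  beating:", x$beating, "\n")
  fmt <- function(v, unit) if (is.na(v)) "absent" else sprintf("%.4g %s", v, unit)
  cat("  HR:      ", fmt(x$hr_bpm, "bpm"), "\n")
  cat("  LVDP:    ", fmt(x$lvdp_mmhg, "mmHg"), "\n")
  cat("  dP/dt:   ", fmt(x$dpdt_max, "mmHg/s"), "/",
      fmt(x$dpdt_min, "mmHg/s"), "\n")
  cat("  CFR:     ", fmt(x$cfr_ml_min, "mL/min"), "\n")
  cat("  P(t) AUC:", fmt(x$auc, "mmHg*s"), "\n")
  if (length(x$missing)) cat("  missing channels:",
                             paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}
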