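#' Specification for a synthetic ventricular pressure trace
#'
#' Parameters of the waveform generator: raised-cosine systolic pulses
#' (duty ~35% of the cycle) on an end-diastolic baseline, with per-beat
#' period jitter, additive Gaussian noise and optional linear drift.
#' Non-beating (arrest) traces are baseline plus noise only.
#'
#' @param hr_bpm Target heart rate.
#' @param sys_peak_mmhg Systolic peak pressure.
#' @param edp_mmhg End-diastolic baseline (balloon pressure; default 8,
#'   within the usual 5-10 mmHg inflation range).
#' @param noise_sd_mmhg Gaussian noise SD (default 1).
#' @param hr_jitter_frac Per-beat period jitter as a fraction of the
#'   cycle (default 0.02).
#' @param drift_mmhg_per_min Linear baseline drift (default 0).
#' @param duration_s Record length in seconds (default 60).
#' @param rate_hz Sampling rate (default 1000; >= 100 required for
#'   derivative fidelity).
#' @param beating Logical; `FALSE` generates an arrest-flat trace.
#' @param duty_frac Systole duration as a fraction of the cycle
#'   (default 0.35).
#' @param seed Integer seed (mandatory).
#' @return An object of class `trace_spec`.
#' @export
trace_spec <- function(hr_bpm = 220, sys_peak_mmhg = 80, edp_mmhg = 8,
                       noise_sd_mmhg = 1, hr_jitter_frac = 0.02,
                       drift_mmhg_per_min = 0, duration_s = 60,
                       rate_hz = 1000, beating = TRUE, duty_frac = 0.35,
                       seed) {
  if (missing(seed)) stop("a seed is required")
  if (rate_hz < 100) stop("rate_hz must be >= 100 for derivative fidelity")
  if (beating && sys_peak_mmhg <= edp_mmhg)
    stop("systolic peak must exceed the end-diastolic baseline")
  stopifnot(duration_s > 0, noise_sd_mmhg >= 0, hr_jitter_frac >= 0,
            duty_frac > 0, duty_frac < 1)
  structure(as.list(environment()), class = "trace_spec")
}

#' Simulate a ventricular pressure trace
#'
#' Deterministic per seed. The returned trace carries a `truth`
#' attribute with the generating parameters and the analytic per-beat
#' quantities: developed pressure (pulse amplitude), dP/dt extrema of
#' the raised cosine (`+/- A*pi/d` for amplitude `A` and systole
#' duration `d`), realised beat count and rate.
#'
#' @param spec A [trace_spec()].
#' @return A [sampled_trace()] with attribute `truth`.
#' @export
simulate_lv_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- round(spec$duration_s * spec$rate_hz) + 1L
  times <- (seq_len(n) - 1L) / spec$rate_hz
  values <- spec$edp_mmhg + spec$drift_mmhg_per_min * times / 60
  truth <- list(hr_bpm = if (spec$beating) spec$hr_bpm else 0,
                lvdp_mmhg = if (spec$beating)
                  spec$sys_peak_mmhg - spec$edp_mmhg else NA_real_,
                edp_mmhg = spec$edp_mmhg, n_beats = 0L,
                dpdt_max = NA_real_, dpdt_min = NA_real_)
  if (spec$beating) {
    period <- 60 / spec$hr_bpm
    kmax <- ceiling(spec$duration_s / period * 1.5) + 3L
    periods <- period * (1 + spec$hr_jitter_frac * stats::rnorm(kmax))
    periods <- pmax(periods, 0.4 * period)
    onsets <- 0.3 * period + cumsum(c(0, periods[-kmax]))
    keep <- onsets + spec$duty_frac * periods <= spec$duration_s
    onsets <- onsets[keep]
    periods <- periods[keep]
    amp <- spec$sys_peak_mmhg - spec$edp_mmhg
    for (i in seq_along(onsets)) {
      d <- spec$duty_frac * periods[i]
      i1 <- floor(onsets[i] * spec$rate_hz) + 2L
      i2 <- min(n, floor((onsets[i] + d) * spec$rate_hz) + 1L)
      if (i2 < i1) next
      tau <- times[i1:i2] - onsets[i]
      values[i1:i2] <- values[i1:i2] + amp / 2 * (1 - cos(2 * pi * tau / d))
    }
    d_i <- spec$duty_frac * periods
    truth$n_beats <- length(onsets)
    truth$hr_bpm <- if (length(onsets) >= 2L)
      60 / mean(diff(onsets)) else 0
    truth$dpdt_max <- mean(amp * pi / d_i)
    truth$dpdt_min <- -truth$dpdt_max
  }
  if (spec$noise_sd_mmhg > 0)
    values <- values + stats::rnorm(n, 0, spec$noise_sd_mmhg)
  tr <- sampled_trace(times, values, channel = "LVP")
  attr(tr, "truth") <- truth
  tr
}

#' Simulate a coronary flow trace
#'
#' Gaussian noise around a constant mean flow, floored at zero
#' (flowmeters do not report negative coronary flow).
#'
#' @param mean_ml_min Mean flow (>= 0).
#' @param noise_sd Noise SD in mL/min (default 0.5).
#' @param duration_s Record length (default 60).
#' @param rate_hz Sampling rate (default 10; flow channels are slow).
#' @param seed Integer seed (mandatory).
#' @return A [sampled_trace()] with attribute `truth` (the mean).
#' @export
simulate_flow_trace <- function(mean_ml_min, noise_sd = 0.5,
                                duration_s = 60, rate_hz = 10, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(mean_ml_min >= 0, noise_sd >= 0, duration_s > 0, rate_hz > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- round(duration_s * rate_hz) + 1L
  times <- (seq_len(n) - 1L) / rate_hz
  values <- pmax(0, mean_ml_min + stats::rnorm(n, 0, noise_sd))
  tr <- sampled_trace(times, values, channel = "flow")
  attr(tr, "truth") <- list(cfr_ml_min = mean_ml_min)
  tr
}

#' Simulate a TTC-stained slice image
#'
#' Draws an annular "myocardium" (red) with a central lumen on a
#' contrasting dark background, paints a contiguous white/ivory sector
#' covering the requested fraction of the tissue area, and adds
#' Gaussian speckle noise. The exact painted pixel fraction is returned
#' as ground truth (it can differ from the request by pixel
#' discretisation only).
#'
#' @param infarct_fraction_pct Requested infarct percentage in
#'   `[0, 100]`.
#' @param size Image side in pixels (default 220).
#' @param noise_sd Speckle noise SD on `[0,1]` channels (default 0.02).
#' @param seed Integer seed controlling geometry jitter, sector
#'   placement and noise (mandatory).
#' @param heart_id,slice_index Labels forwarded to [slice_image()].
#' @return List with `slice` (a [slice_image()]) and
#'   `truth_fraction_pct`.
#' @export
simulate_ttc_slice <- function(infarct_fraction_pct, size = 220,
                               noise_sd = 0.02, seed,
                               heart_id = "heart", slice_index = 1L) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(infarct_fraction_pct >= 0, infarct_fraction_pct <= 100,
            size >= 40)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bg <- c(0.16, 0.18, 0.24)
  red <- c(0.62, 0.10, 0.12)
  ivory <- c(0.93, 0.91, 0.84)
  cx <- (size + 1) / 2
  r_out <- size * 0.40 * (1 + 0.05 * stats::runif(1, -1, 1))
  r_in <- size * 0.13 * (1 + 0.10 * stats::runif(1, -1, 1))
  row <- matrix(seq_len(size), size, size)
  col <- matrix(seq_len(size), size, size, byrow = TRUE)
  rr <- sqrt((row - cx)^2 + (col - cx)^2)
  tissue <- rr <= r_out & rr >= r_in
  n_t <- sum(tissue)
  k <- round(infarct_fraction_pct / 100 * n_t)
  infarct <- matrix(FALSE, size, size)
  if (k > 0) {
    theta0 <- stats::runif(1, 0, 2 * pi)
    rel <- (atan2(row - cx, col - cx) - theta0) %% (2 * pi)
    ti <- which(tissue)
    sel <- ti[order(rel[ti])][seq_len(k)]
    infarct[sel] <- TRUE
  }
  px <- array(0, c(size, size, 3L))
  for (ch in 1:3) {
    layer <- matrix(bg[ch], size, size)
    layer[tissue] <- red[ch]
    layer[infarct] <- ivory[ch]
    px[, , ch] <- layer
  }
  if (noise_sd > 0)
    px <- px + array(stats::rnorm(length(px), 0, noise_sd), dim(px))
  px[px < 0] <- 0
  px[px > 1] <- 1
  list(slice = slice_image(px, heart_id, slice_index),
       truth_fraction_pct = 100 * k / n_t)
}

#' Study group presets
#'
#' Per-group reperfusion summaries of the five-arm preservation study
#' this package's simulator emulates: static cold storage (Control),
#' air persufflation (Air) and three xenon/oxygen mixtures (Gas A
#' xenon-rich, Gas B oxygen-rich, Gas C equal parts). Values are group
#' mean and standard error of the analysed (beating) hearts, together
#' with the enrolled and resuscitated counts.
#'
#' @return A data frame with one row per group and columns
#'   `group`, `n_enrolled`, `n_resuscitated`, `n_kinetics`, and
#'   `<metric>_mean` / `<metric>_se` for `hr` (bpm), `lvdp` (mmHg),
#'   `cfr` (mL/min), `dpdt_max`, `dpdt_min` (mmHg/s), `auc`
#'   (pressure-time integral) and `infarct` (%).
#' @export
group_presets <- function() {
  data.frame(
    group = c("Control", "Air", "GasA", "GasB", "GasC"),
    n_enrolled = c(10L, 8L, 7L, 4L, 4L),
    n_resuscitated = c(4L, 6L, 7L, 4L, 4L),
    n_kinetics = c(4L, 6L, 4L, 4L, 4L),
    hr_mean = c(131, 164, 191, 226, 229),
    hr_se = c(11, 21, 17, 13, 6),
    lvdp_mean = c(31, 45, 74, 73, 71),
    lvdp_se = c(5, 9, 6, 7, 6),
    cfr_mean = c(8.51, 5.98, 6.64, 6.91, 6.4),
    cfr_se = c(1.37, 0.48, 0.61, 0.94, 0.35),
    dpdt_max_mean = c(456, 775, 1505, 1567, 1494),
    dpdt_max_se = c(111, 231, 125, 151, 159),
    dpdt_min_mean = c(-314, -542, -952, -961, -964),
    dpdt_min_se = c(102, 175, 106, 100, 97),
    auc_mean = c(3168, 6652, 12077, 13787, 12056),
    auc_se = c(657, 1912, 1715, 1165, 1357),
    infarct_mean = c(39.6, 12.6, 6.4, 6.3, 6.2),
    infarct_se = c(6.6, 3.3, 1.1, 0.9, 0.3),
    stringsAsFactors = FALSE
  )
}

#' Simulate a full study cohort
#'
#' For each group, enrolls `n_enrolled` hearts; each heart resuscitates
#' with probability `n_resuscitated / n_enrolled`. Beating hearts draw
#' their HR, developed pressure, flow and infarct fraction from
#' `Normal(mean, SE * sqrt(n))` (the between-heart SD implied by the
#' printed standard errors) and receive a pressure trace, a flow trace
#' and TTC slice images consistent with the draws. Non-beating hearts
#' receive an arrest-flat pressure trace and a flow trace (reperfusion
#' delivers buffer regardless of rhythm) but no slices, mirroring the
#' exclusion of unresuscitated hearts from infarct analysis.
#'
#' @param presets Group presets as from [group_presets()].
#' @param seed Integer seed (mandatory); every heart's generator seed
#'   derives from it.
#' @param duration_s Trace length in seconds (default 60; the study
#'   design observes 3600 s, scaled down here for speed).
#' @param rate_hz Pressure sampling rate (default 500).
#' @param n_slices Slices per analysed heart (default 2).
#' @param slice_px Slice image side in pixels (default 160).
#' @return An object of class `synthetic_cohort`: list with `hearts`
#'   (per heart: `heart_id`, `group`, `lvp`, `flow`, `slices`) and
#'   `truth` (data frame of generating parameters), plus the `seed`.
#' @export
simulate_cohort <- function(presets = group_presets(), seed,
                            duration_s = 60, rate_hz = 500,
                            n_slices = 2L, slice_px = 160) {
  if (missing(seed)) stop("a seed is required")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_total <- sum(presets$n_enrolled)
  heart_seeds <- sample.int(2^30, n_total * (2L + n_slices))
  hearts <- list()
  truth <- list()
  hid <- 0L
  sidx <- 0L
  next_seed <- function() {
    sidx <<- sidx + 1L
    heart_seeds[sidx]
  }
  for (g in seq_len(nrow(presets))) {
    p <- presets[g, ]
    sdmul <- sqrt(p$n_kinetics)
    for (i in seq_len(p$n_enrolled)) {
      hid <- hid + 1L
      id <- sprintf("%s_%02d", p$group, i)
      beating <- stats::runif(1) < p$n_resuscitated / p$n_enrolled
      cfr <- max(0.5, stats::rnorm(1, p$cfr_mean, p$cfr_se * sdmul))
      if (beating) {
        hr <- max(40, stats::rnorm(1, p$hr_mean, p$hr_se * sdmul))
        # a "resuscitated" heart develops pressure above the beat
        # detector's prominence threshold; weaker excursions are
        # indistinguishable from arrest
        lvdp <- max(22, stats::rnorm(1, p$lvdp_mean, p$lvdp_se * sdmul))
        infarct <- min(95, max(0.5,
          stats::rnorm(1, p$infarct_mean, p$infarct_se * sdmul)))
      } else {
        hr <- 0; lvdp <- NA_real_; infarct <- NA_real_
      }
      spec <- trace_spec(hr_bpm = if (beating) hr else 220,
                         sys_peak_mmhg = if (beating) 8 + lvdp else 80,
                         edp_mmhg = 8, duration_s = duration_s,
                         rate_hz = rate_hz, beating = beating,
                         seed = next_seed())
      lvp <- simulate_lv_trace(spec)
      flow <- simulate_flow_trace(cfr, duration_s = duration_s,
                                  seed = next_seed())
      slices <- NULL
      truth_infarct <- NA_real_
      if (beating) {
        slices <- vector("list", n_slices)
        painted <- numeric(n_slices)
        for (s in seq_len(n_slices)) {
          sl <- simulate_ttc_slice(infarct, size = slice_px,
                                   seed = next_seed(),
                                   heart_id = id, slice_index = s)
          slices[[s]] <- sl$slice
          painted[s] <- sl$truth_fraction_pct
        }
        truth_infarct <- mean(painted)
      } else {
        for (s in seq_len(n_slices)) next_seed()  # keep seed stream aligned
      }
      hearts[[hid]] <- list(heart_id = id, group = p$group,
                            lvp = lvp, flow = flow, slices = slices)
      truth[[hid]] <- data.frame(
        heart_id = id, group = p$group, beating = beating,
        hr_bpm = if (beating) attr(lvp, "truth")$hr_bpm else 0,
        lvdp_mmhg = if (beating) lvdp else NA_real_,
        cfr_ml_min = cfr,
        dpdt_max = attr(lvp, "truth")$dpdt_max,
        dpdt_min = attr(lvp, "truth")$dpdt_min,
        infarct_pct = truth_infarct,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(hearts = hearts, truth = do.call(rbind, truth),
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d hearts (%d beating), seed %d>\n",
              nrow(x$truth), sum(x$truth$beating), x$seed))
  print(table(x$truth$group, ifelse(x$truth$beating, "beating", "arrest")))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' One chart-export text file (pressure + flow) per heart, PNG slice
#' images for analysed hearts, and a `truth.csv` table of generating
#' parameters.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (h in cohort$hearts) {
    # flow is sampled slower than pressure; resample onto the LVP base
    flow_on_lvp <- sampled_trace(
      h$lvp$times,
      stats::approx(h$flow$times, h$flow$values, h$lvp$times,
                    rule = 2)$y,
      channel = "flow")
    write_chart_export(list(LVP = h$lvp, flow = flow_on_lvp),
                       file.path(dir, paste0(h$heart_id, ".txt")))
    for (s in seq_along(h$slices %||% list())) {
      write_slice_image(h$slices[[s]],
                        file.path(dir, sprintf("%s_slice%d.png",
                                               h$heart_id, s)))
    }
  }
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
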