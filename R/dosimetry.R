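#' Gas mixture specification
#'
#' Describes the composition of the persufflation gas by its oxygen and
#' xenon volume fractions. Any remainder is assumed to be inert filler
#' (e.g. the nitrogen/argon bulk of air).
#'
#' @param f_o2 Oxygen volume fraction, in `[0, 1]`.
#' @param f_xe Xenon volume fraction, in `[0, 1]`. Default 0 (e.g. air).
#' @param name Optional label ("Gas A", "air", ...).
#' @return An object of class `gas_mixture`.
#' @examples
#' gas_mixture(0.1, 0.9, name = "Gas A")
#' @export
gas_mixture <- function(f_o2, f_xe = 0, name = NULL) {
  stopifnot(is.numeric(f_o2), length(f_o2) == 1L, is.finite(f_o2),
            is.numeric(f_xe), length(f_xe) == 1L, is.finite(f_xe))
  if (f_o2 < 0 || f_o2 > 1) stop("f_o2 must lie in [0, 1]")
  if (f_xe < 0 || f_xe > 1) stop("f_xe must lie in [0, 1]")
  if (f_o2 + f_xe > 1 + 1e-12) stop("f_o2 + f_xe must not exceed 1")
  structure(list(name = name %||% "mixture", f_o2 = f_o2, f_xe = f_xe),
            class = "gas_mixture")
}

#' Organ oxygen-demand parameters
#'
#' Parameters of the oxygen-demand model for an arrested, hypothermic
#' organ: physiological consumption scaled down by an arrest attenuation
#' factor and a Q10 temperature factor.
#'
#' @param mass_g Organ wet weight in grams.
#' @param mvo2 Physiological oxygen consumption in mL O2 / min / g tissue.
#' @param a1 Arrest attenuation coefficient (>= 1); 1 means no reduction
#'   relative to the contracting organ (use 1 for organs that do not
#'   contract).
#' @param a2 Q10 temperature coefficient (> 1), typically 2-3 for
#'   mammalian tissue.
#' @param t1_c Physiological organ temperature, degrees C.
#' @param t2_c Preservation temperature, degrees C. Must not exceed `t1_c`.
#' @return An object of class `organ_spec`.
#' @examples
#' organ_spec(mass_g = 1.3, mvo2 = 0.1, a1 = 3, a2 = 2.5, t1_c = 37, t2_c = 2)
#' @export
organ_spec <- function(mass_g, mvo2, a1, a2, t1_c = 37, t2_c = 4) {
  vals <- c(mass_g, mvo2, a1, a2, t1_c, t2_c)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  if (mass_g <= 0) stop("organ mass must be positive")
  if (mvo2 < 0) stop("mvo2 must be non-negative")
  if (a1 < 1) stop("arrest coefficient a1 must be >= 1")
  if (a2 <= 1) stop("Q10 coefficient a2 must exceed 1")
  if (t1_c < t2_c) stop("preservation temperature t2_c must not exceed t1_c")
  structure(list(mass_g = mass_g, mvo2 = mvo2, a1 = a1, a2 = a2,
                 t1_c = t1_c, t2_c = t2_c),
            class = "organ_spec")
}

#' Preservation plan (chamber and pump settings)
#'
#' @param duration_min Planned preservation time in minutes.
#' @param chamber_volume_ml Inner chamber volume in mL.
#' @param pump_rate_ml_s Pump displacement rate in mL/s.
#' @param pulse_s Duration of one pump activation in seconds (default 1).
#' @return An object of class `preservation_plan`.
#' @export
preservation_plan <- function(duration_min, chamber_volume_ml,
                              pump_rate_ml_s, pulse_s = 1) {
  vals <- c(duration_min, chamber_volume_ml, pump_rate_ml_s, pulse_s)
  stopifnot(is.numeric(vals), all(is.finite(vals)))
  if (any(vals <= 0)) stop("all preservation-plan parameters must be positive")
  structure(list(duration_min = duration_min,
                 chamber_volume_ml = chamber_volume_ml,
                 pump_rate_ml_s = pump_rate_ml_s,
                 pulse_s = pulse_s),
            class = "preservation_plan")
}

#' Organ oxygen demand over the preservation period
#'
#' Total oxygen volume (mL, ambient reference conditions) the arrested,
#' hypothermic organ consumes over the preservation time:
#' `m * t * MVO2 / (A1 * A2^((T1 - T2)/10))`. The denominator discounts
#' the physiological demand for cardiac arrest (A1) and hypothermia (A2,
#' Q10 rule: demand falls by a factor A2 per 10 degrees C of cooling).
#'
#' @param organ An [organ_spec()].
#' @param duration_min Preservation time in minutes (>= 0).
#' @return Oxygen demand in mL.
#' @examples
#' rat_heart <- organ_spec(1, 0.08, a1 = 2, a2 = 2, t1_c = 37, t2_c = 7)
#' oxygen_demand(rat_heart, 360)  # 1.8 mL
#' @export
oxygen_demand <- function(organ, duration_min) {
  stopifnot(inherits(organ, "organ_spec"),
            is.numeric(duration_min), length(duration_min) == 1L,
            is.finite(duration_min))
  if (duration_min < 0) stop("duration_min must be non-negative")
  organ$mass_g * duration_min * organ$mvo2 /
    (organ$a1 * organ$a2^((organ$t1_c - organ$t2_c) / 10))
}

#' Minimum chamber pressure to hold the oxygen dose
#'
#' Absolute pressure (bar; ambient = 1 bar) at which the chamber volume
#' contains at least the required oxygen volume given the mixture's
#' oxygen fraction: `PVO2 / (FO2 * Vc) + 1`.
#'
#' @param pvo2_ml Oxygen demand in mL (see [oxygen_demand()]).
#' @param mixture A [gas_mixture()]; its `f_o2` must be positive.
#' @param chamber_volume_ml Inner chamber volume in mL.
#' @return Minimum absolute chamber pressure in bar (>= 1).
#' @examples
#' min_chamber_pressure(40, gas_mixture(0.1, 0.9), 200)  # 3 bar
#' @export
min_chamber_pressure <- function(pvo2_ml, mixture, chamber_volume_ml) {
  stopifnot(inherits(mixture, "gas_mixture"),
            is.numeric(pvo2_ml), is.finite(pvo2_ml),
            is.numeric(chamber_volume_ml), is.finite(chamber_volume_ml))
  if (any(pvo2_ml < 0)) stop("pvo2_ml must be non-negative")
  if (chamber_volume_ml <= 0) stop("chamber volume must be positive")
  if (mixture$f_o2 <= 0)
    stop("gas mixture devoid of O2 cannot fuel gaseous perfusion (f_o2 = 0)")
  pvo2_ml / (mixture$f_o2 * chamber_volume_ml) + 1
}

#' Pump duty cycle delivering the oxygen dose
#'
#' Seconds of pump operation needed per minute of preservation,
#' `N = PVO2 / (Ppump * t)`, and the equivalent interval between
#' fixed-length pump pulses.
#'
#' @param pvo2_ml Oxygen demand in mL.
#' @param pump_rate_ml_s Pump displacement rate in mL/s.
#' @param duration_min Preservation time in minutes.
#' @param pulse_s Duration of one pump activation in seconds (default 1).
#' @return A list with `duty_s_per_min` (s of pump-on per min) and
#'   `pulse_interval_min` (minutes between `pulse_s`-long pulses;
#'   `Inf` when the duty is zero).
#' @examples
#' pump_duty(100, 1, 360)  # 1-s pulse every 3.6 min
#' @export
pump_duty <- function(pvo2_ml, pump_rate_ml_s, duration_min, pulse_s = 1) {
  stopifnot(is.numeric(pvo2_ml), is.finite(pvo2_ml))
  if (pvo2_ml < 0) stop("pvo2_ml must be non-negative")
  if (!is.numeric(pump_rate_ml_s) || pump_rate_ml_s <= 0)
    stop("pump rate must be positive")
  if (!is.numeric(duration_min) || duration_min <= 0)
    stop("duration must be positive")
  duty <- pvo2_ml / (pump_rate_ml_s * duration_min)
  list(duty_s_per_min = duty,
       pulse_interval_min = if (duty > 0) pulse_s / duty else Inf)
}

#' Plan a gaseous preservation run
#'
#' Composes the three dosimetry calculations — oxygen demand, minimum
#' chamber pressure, pump duty — into one feasibility summary, and
#' attaches heuristic warnings. A xenon clathrate (gas hydrate) warning
#' is emitted when the mixture is xenon-rich, the chamber pressure is
#' elevated and the preservation temperature is near freezing; all three
#' thresholds are configurable. The warning flags thermobaric conditions
#' compatible with hydrate formation; it is not a phase-equilibrium model.
#'
#' @param organ An [organ_spec()].
#' @param mixture A [gas_mixture()].
#' @param plan A [preservation_plan()].
#' @param clathrate_f_xe Xenon-fraction threshold (default 0.5).
#' @param clathrate_p_bar Pressure threshold in bar (default 2).
#' @param clathrate_t_c Temperature threshold in degrees C (default 4).
#' @return An object of class `dosimetry_result`: list with `pvo2_ml`,
#'   `p_pres_bar`, `duty_s_per_min`, `pulse_interval_min`, `warnings`.
#' @examples
#' res <- plan_preservation(
#'   organ_spec(1.3, 0.1, a1 = 3, a2 = 2.5, t1_c = 37, t2_c = 2),
#'   gas_mixture(0.1, 0.9, name = "Gas A"),
#'   preservation_plan(360, 200, 1))
#' res
#' @export
plan_preservation <- function(organ, mixture, plan,
                              clathrate_f_xe = 0.5,
                              clathrate_p_bar = 2,
                              clathrate_t_c = 4) {
  stopifnot(inherits(organ, "organ_spec"),
            inherits(mixture, "gas_mixture"),
            inherits(plan, "preservation_plan"))
  pvo2 <- oxygen_demand(organ, plan$duration_min)
  p_pres <- min_chamber_pressure(pvo2, mixture, plan$chamber_volume_ml)
  duty <- pump_duty(pvo2, plan$pump_rate_ml_s, plan$duration_min,
                    pulse_s = plan$pulse_s)
  warnings <- character(0)
  if (mixture$f_xe >= clathrate_f_xe && p_pres >= clathrate_p_bar &&
      organ$t2_c <= clathrate_t_c) {
    warnings <- c(warnings, sprintf(
      "clathrate risk: f_xe = %.2f at %.2f bar and %.1f degC is compatible with xenon hydrate formation",
      mixture$f_xe, p_pres, organ$t2_c))
  }
  structure(list(pvo2_ml = pvo2,
                 p_pres_bar = p_pres,
                 duty_s_per_min = duty$duty_s_per_min,
                 pulse_interval_min = duty$pulse_interval_min,
                 mixture = mixture$name,
                 warnings = warnings),
            class = "dosimetry_result")
}

#' @export
print.dosimetry_result <- function(x, ...) {
  cat("Gaseous preservation dosimetry (", x$mixture, ")\n", sep = "")
  cat(sprintf("  O2 demand:            %.3g mL\n", x$pvo2_ml))
  cat(sprintf("  Min chamber pressure: %.3g bar (absolute)\n", x$p_pres_bar))
  cat(sprintf("  Pump duty:            %.3g s/min", x$duty_s_per_min))
  if (is.finite(x$pulse_interval_min))
    cat(sprintf(" (one pulse every %.3g min)", x$pulse_interval_min))
  cat("\n")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
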