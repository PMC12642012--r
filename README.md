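# hipperlab

Analysis tooling for ex-vivo heart preservation experiments that store
the organ in a sealed pressurised chamber and perfuse its coronary
vasculature with gas (persufflation) instead of a liquid medium, then
assess recovery on a Langendorff rig. The package is written for
cardiovascular physiologists running such experiments: it covers the
planning arithmetic of the gas supply, the beat-level analysis of the
reperfusion recordings, infarct quantification from TTC-stained slices,
and the group-comparison statistics, plus a seeded synthetic-data
generator that provides ground truth for validating the whole chain.

## The models at the core

**Dosimetry.** The oxygen an arrested, hypothermic organ consumes over a
preservation period of *t* minutes is

    PVO2 = m · t · MVO2 / (A1 · A2^((T1 − T2)/10))

with organ mass *m* (g), physiological consumption *MVO2* (mL/min/g),
arrest attenuation *A1* ≥ 1, and Q10 coefficient *A2* (demand falls by a
factor *A2* per 10 °C of cooling from *T1* to *T2*). The minimum
absolute chamber pressure holding that dose is
`Ppres = PVO2/(FO2 · Vc) + 1` bar, and the pump duty is
`N = PVO2/(Ppump · t)` seconds of pump-on per minute. A heuristic
warning flags xenon-rich mixtures under cold, pressurised conditions
compatible with xenon-hydrate (clathrate) formation.

**Trace analysis.** Beats are local maxima above a prominence threshold,
refined by least-squares parabola vertices; each beat carries its
end-diastolic trough and dP/dt extrema (two-pass vertex fits on a
pre-smoothed derivative, which stay within 2% of truth under realistic
transducer noise). Summaries include heart rate, developed pressure
(LVDP), dP/dt max/min, coronary flow, the trapezoidal pressure–time
integral, per-10-minute timepoints, and a sustained-rhythm beating call.

**Planimetry.** Infarct fraction is the ratio of pale (low-saturation,
high-value) to total tissue pixels, with background removal, largest-
component cleanup and lumen exclusion; heart-level values pool areas
across slices.

**Statistics.** Exact Fisher 2×2 by enumeration, one-way ANOVA,
Bartlett-gated Welch/Student pairwise t-tests with Holm correction,
Cohen's d (raw and summary forms), correlation-mode PCA, seeded
PerMANOVA on Euclidean distances, simulation-based power for means and
enumeration-based power for proportions, and the `N = DF/k + 1`
sample-size rule.

## Worked example

Plan a six-hour preservation of a 1.3 g heart at 2 °C in a 200 mL
chamber filled with a 1:9 oxygen:xenon mixture:

```r
library(hipperlab)
plan_preservation(
  organ_spec(mass_g = 1.3, mvo2 = 0.1, a1 = 3, a2 = 2.5, t1_c = 37, t2_c = 2),
  gas_mixture(f_o2 = 0.1, f_xe = 0.9, name = "Gas A"),
  preservation_plan(duration_min = 360, chamber_volume_ml = 200, pump_rate_ml_s = 1))
#> Gaseous preservation dosimetry (Gas A)
#>   O2 demand:            0.631 mL
#>   Min chamber pressure: 1.03 bar (absolute)
#>   Pump duty:            0.00175 s/min (one pulse every 570 min)
```

The heart needs only 0.63 mL of oxygen over the six hours — arrest and
hypothermia suppress demand ~35-fold — so even the leanest mixture holds
the dose at essentially ambient pressure, and a 1 mL/s pump could cover
it with one 1-s pulse every 570 min (in practice pumps run far more
often; the duty is a floor, not a schedule).

Analyse a reperfusion recording (here a synthetic one whose true rate is
226.2 bpm, LVDP 73 mmHg, dP/dt max 2471 mmHg/s):

```r
lvp  <- simulate_lv_trace(trace_spec(hr_bpm = 226, sys_peak_mmhg = 81,
                                     edp_mmhg = 8, duration_s = 60,
                                     rate_hz = 500, seed = 42))
flow <- simulate_flow_trace(6.9, duration_s = 60, seed = 43)
summarize_reperfusion(lvp, flow, expected_span_s = 60)
#> Reperfusion hemodynamic summary
#>   beating: TRUE
#>   HR:       226.2 bpm
#>   LVDP:     73.1 mmHg
#>   dP/dt:    2453 mmHg/s / -2451 mmHg/s
#>   CFR:      6.908 mL/min
#>   P(t) AUC: 1246 mmHg*s
```

Every metric lands within 1% of the generator's truth. A full
synthetic study — five groups, 33 hearts, resuscitation table, ANOVA,
Holm-corrected pairwise tests, PCA and PerMANOVA — runs end-to-end with

```r
report <- run_pipeline(simulate_cohort(seed = 7),
                       config = list(seed = 7, n_perm = 999))
print(report)
```

Real chart-recorder exports are read with `parse_chart_export()` and
stained-slice photographs with `read_slice_image()`; see the methods
vignette (`vignettes/hipperlab-methods.Rmd`) for the algorithms,
defaults and their rationale.

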