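#' Run the full analysis pipeline on a cohort
#'
#' Orchestrates trace analysis, planimetry and the statistical battery
#' over a cohort of hearts and assembles a study-style report.
#' Non-beating hearts are excluded from kinetics and infarct statistics
#' but counted in the resuscitation table; this exclusion policy lives
#' here, not in the statistics layer, so the resuscitation denominator
#' and the kinetics sample size can differ.
#'
#' @param cohort A [simulate_cohort()] result, or a directory written
#'   by [write_cohort()] (re-read from its text exports and PNGs; the
#'   group is taken from the `truth.csv` manifest).
#' @param config List of settings: `n_perm` (PerMANOVA permutations,
#'   default 999), `seed` (mandatory; used for the permutation test),
#'   `reference_group` (for the resuscitation contrasts, default
#'   `"Control"`), `pooled_groups` (groups pooled into one arm for the
#'   pooled resuscitation contrast, default those starting with "Gas"),
#'   plus any [detect_beats()] thresholds under `detect`.
#' @return An object of class `study_report`.
#' @export
run_pipeline <- function(cohort, config = list()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  seed <- config$seed
  if (is.null(seed)) stop("config$seed is required")
  n_perm <- config$n_perm %||% 999
  ref <- config$reference_group %||% "Control"
  groups_all <- unique(vapply(cohort$hearts, `[[`, character(1), "group"))
  pooled <- config$pooled_groups %||% grep("^Gas", groups_all, value = TRUE)

  # --- stage: trace analysis -------------------------------------------
  per_heart <- lapply(cohort$hearts, function(h) {
    span <- diff(range(h$lvp$times))
    args <- c(list(h$lvp, h$flow, expected_span_s = span), config$detect)
    s <- do.call(summarize_reperfusion, args)
    data.frame(heart_id = h$heart_id, group = h$group,
               beating = isTRUE(s$beating), hr_bpm = s$hr_bpm,
               lvdp_mmhg = s$lvdp_mmhg, dpdt_max = s$dpdt_max,
               dpdt_min = s$dpdt_min, cfr_ml_min = s$cfr_ml_min,
               auc = s$auc, stringsAsFactors = FALSE)
  })
  hearts_tab <- do.call(rbind, per_heart)

  # --- stage: resuscitation table --------------------------------------
  resus <- do.call(rbind, lapply(split(hearts_tab, hearts_tab$group),
    function(d) data.frame(group = d$group[1], n = nrow(d),
                           beating = sum(d$beating),
                           stringsAsFactors = FALSE)))
  rownames(resus) <- NULL
  fisher_rows <- list()
  if (ref %in% resus$group) {
    r0 <- resus[resus$group == ref, ]
    for (g in setdiff(resus$group, ref)) {
      r1 <- resus[resus$group == g, ]
      fisher_rows[[g]] <- data.frame(
        contrast = paste(ref, "vs", g),
        p = fisher_exact_2x2(r1$beating, r1$n - r1$beating,
                             r0$beating, r0$n - r0$beating))
    }
    pg <- resus[resus$group %in% pooled, ]
    if (nrow(pg) > 1L) {
      fisher_rows[["pooled"]] <- data.frame(
        contrast = paste(ref, "vs pooled(", paste(pooled, collapse = "+"), ")"),
        p = fisher_exact_2x2(sum(pg$beating), sum(pg$n) - sum(pg$beating),
                             r0$beating, r0$n - r0$beating))
    }
  }
  resus_tests <- if (length(fisher_rows)) do.call(rbind, fisher_rows) else NULL

  # --- stage: planimetry -----------------------------------------------
  plan_rows <- list()
  for (h in cohort$hearts) {
    if (is.null(h$slices)) next
    res <- lapply(h$slices, planimetry_slice)
    frac <- infarct_fraction(res)
    plan_rows[[h$heart_id]] <- data.frame(
      heart_id = h$heart_id, group = h$group,
      n_slices = frac$n_slices,
      infarct_pct = frac$pooled_pct,
      infarct_pct_slice_mean = frac$slice_mean_pct,
      stringsAsFactors = FALSE)
  }
  plan_tab <- if (length(plan_rows)) do.call(rbind, plan_rows) else NULL
  if (!is.null(plan_tab)) rownames(plan_tab) <- NULL

  # --- stage: group statistics (beating hearts only) -------------------
  kin <- hearts_tab[hearts_tab$beating, , drop = FALSE]
  if (!is.null(plan_tab)) {
    kin <- merge(kin, plan_tab[, c("heart_id", "infarct_pct")],
                 by = "heart_id", all.x = TRUE, sort = FALSE)
  } else kin$infarct_pct <- rep(NA_real_, nrow(kin))
  metrics <- c("hr_bpm", "lvdp_mmhg", "dpdt_max", "dpdt_min",
               "cfr_ml_min", "auc", "infarct_pct")
  anova_tab <- NULL
  pairwise_tab <- NULL
  ordination <- NULL
  notes <- character(0)
  usable <- table(kin$group)
  if (nrow(kin) == 0L || sum(usable >= 2L) < 2L) {
    notes <- c(notes, paste(
      "kinetics and infarct statistics omitted:",
      "fewer than two groups with two or more beating hearts"))
  } else {
    kin_ok <- kin[kin$group %in% names(usable)[usable >= 2L], ]
    an_rows <- pw_rows <- list()
    for (m in metrics) {
      vals <- kin_ok[is.finite(kin_ok[[m]]), c("group", m)]
      gl <- split(vals[[m]], vals$group)
      gl <- gl[vapply(gl, length, integer(1)) >= 2L]
      if (length(gl) < 2L) next
      an <- one_way_anova(gl)
      an_rows[[m]] <- data.frame(metric = m, f = an$f, df1 = an$df1,
                                 df2 = an$df2, p = an$p)
      pw <- pairwise_tests(gl)
      pw$metric <- m
      pw_rows[[m]] <- as.data.frame(pw)
    }
    if (length(an_rows)) anova_tab <- do.call(rbind, an_rows)
    if (length(pw_rows)) pairwise_tab <- do.call(rbind, pw_rows)
    if (!is.null(anova_tab)) rownames(anova_tab) <- NULL
    if (!is.null(pairwise_tab)) rownames(pairwise_tab) <- NULL

    # --- stage: ordination + PerMANOVA ---------------------------------
    cc <- kin_ok[stats::complete.cases(kin_ok[, metrics]), ]
    gtab <- table(cc$group)
    if (nrow(cc) >= 4L && sum(gtab >= 2L) >= 2L) {
      cc <- cc[cc$group %in% names(gtab)[gtab >= 2L], ]
      x <- as.matrix(cc[, metrics])
      rownames(x) <- cc$heart_id
      pcares <- pca_metrics(x)
      z <- scale(x[, apply(x, 2, stats::sd) > 0, drop = FALSE])
      pm <- permanova(stats::dist(z), cc$group, n_perm = n_perm,
                      seed = seed)
      ordination <- list(pca = pcares, permanova = pm,
                         groups = cc$group)
    } else {
      notes <- c(notes, "ordination omitted: too few complete observations")
    }
  }

  provenance <- list(seed = seed, n_perm = n_perm,
                     package_version = as.character(
                       utils::packageVersion("hipperlab")),
                     config_hash = .config_hash(config),
                     n_hearts = nrow(hearts_tab))
  structure(list(hearts = hearts_tab, resuscitation = resus,
                 resuscitation_tests = resus_tests,
                 planimetry = plan_tab, anova = anova_tab,
                 pairwise = pairwise_tab, ordination = ordination,
                 notes = notes, provenance = provenance),
            class = "study_report")
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[order(names(config))]), f)
  unname(tools::md5sum(f))
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `<heart_id>.txt` chart exports,
#'   `<heart_id>_sliceN.png` images and `truth.csv`.
#' @return A `synthetic_cohort` object (the truth table is the stored
#'   manifest).
#' @export
read_cohort <- function(dir) {
  manifest <- file.path(dir, "truth.csv")
  if (!file.exists(manifest)) stop("no truth.csv manifest in ", dir)
  truth <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  hearts <- lapply(seq_len(nrow(truth)), function(i) {
    id <- truth$heart_id[i]
    traces <- parse_chart_export(file.path(dir, paste0(id, ".txt")))
    slice_files <- sort(Sys.glob(file.path(dir, paste0(id, "_slice*.png"))))
    slices <- if (length(slice_files)) {
      lapply(seq_along(slice_files), function(s)
        read_slice_image(slice_files[s], heart_id = id, slice_index = s))
    } else NULL
    list(heart_id = id, group = truth$group[i],
         lvp = traces$LVP, flow = traces$flow, slices = slices)
  })
  structure(list(hearts = hearts, truth = truth, seed = NA_integer_),
            class = "synthetic_cohort")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (", x$provenance$n_hearts, " hearts)\n", sep = "")
  cat("\nResuscitation:\n")
  print(x$resuscitation)
  if (!is.null(x$resuscitation_tests)) {
    cat("\nResuscitation contrasts (Fisher exact):\n")
    print(x$resuscitation_tests, row.names = FALSE)
  }
  if (!is.null(x$anova)) {
    cat("\nOne-way ANOVA per metric:\n")
    print(x$anova, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$ordination)) {
    ve <- x$ordination$pca$var_explained
    cat(sprintf("\nPCA: PC1+PC2 explain %.1f%% of variance\n",
                100 * sum(ve[1:min(2, length(ve))])))
    pm <- x$ordination$permanova
    cat(sprintf("PerMANOVA: pseudo-F = %.3g, p = %.4g (%d permutations)\n",
                pm$pseudo_f, pm$p_perm, pm$n_perm))
  }
  for (nt in x$notes) cat("\nnote:", nt, "\n")
  cat(sprintf("\nprovenance: seed %s, config %s\n",
              x$provenance$seed, x$provenance$config_hash))
  invisible(x)
}

#' Maximum oxygen demand and chamber pressure over a physiological grid
#'
#' Sweeps the oxygen-demand model over a grid of plausible rat-heart
#' parameters (organ mass, physiological oxygen consumption, arrest and
#' Q10 coefficients, preservation temperature) and reports the worst
#' case, together with the minimum chamber pressure that worst case
#' requires in a given chamber with the leanest-oxygen mixture.
#'
#' @param mass_g,mvo2,a1,a2,t2_c Numeric vectors of grid values.
#' @param t1_c Physiological temperature (scalar, default 37).
#' @param duration_min Preservation time (default 360).
#' @param f_o2 Oxygen fraction for the pressure bound (default 0.1).
#' @param chamber_volume_ml Chamber volume (default 200).
#' @return List with `max_pvo2_ml`, `max_p_pres_bar`, `n_grid`.
#' @export
dosimetry_grid_max <- function(mass_g = seq(0.9, 2, length.out = 5),
                               mvo2 = seq(0.05, 0.3, length.out = 5),
                               a1 = seq(2, 4, length.out = 5),
                               a2 = seq(2, 3, length.out = 5),
                               t2_c = seq(0, 4, length.out = 5),
                               t1_c = 37, duration_min = 360,
                               f_o2 = 0.1, chamber_volume_ml = 200) {
  grid <- expand.grid(m = mass_g, mv = mvo2, a1 = a1, a2 = a2, t2 = t2_c)
  pvo2 <- grid$m * duration_min * grid$mv /
    (grid$a1 * grid$a2^((t1_c - grid$t2) / 10))
  mix <- gas_mixture(f_o2)
  list(max_pvo2_ml = max(pvo2),
       max_p_pres_bar = min_chamber_pressure(max(pvo2), mix,
                                             chamber_volume_ml),
       n_grid = nrow(grid))
}

#' Recompute the study's headline desk checks
#'
#' Evaluates the deterministic quantities the preservation study
#' reports — the pump-duty worked example, the oxygen-demand and
#' chamber-pressure bounds, the sample-size rule, the resuscitation
#' Fisher tests, and the effect sizes recomputable from the published
#' group summaries — and compares each against its published value at a
#' stated tolerance. Failures are reported in the table, never raised.
#'
#' @return A data frame with columns `check`, `computed`, `reference`,
#'   `tolerance` (relative, or 0 for exact-at-print-precision) and
#'   `pass`.
#' @export
reproduce_study_checks <- function() {
  p <- group_presets()
  # tol > 0: relative tolerance; tol = 0: exact; tol < 0: absolute
  # tolerance of |tol| (one unit in the last printed digit of a rounded,
  # possibly truncated, published p-value)
  row <- function(check, computed, reference, tol) {
    pass <- if (tol == 0) {
      abs(computed - reference) < 1e-9
    } else if (tol < 0) {
      abs(computed - reference) <= -tol
    } else abs(computed - reference) <= tol * abs(reference)
    data.frame(check = check, computed = computed, reference = reference,
               tolerance = tol, pass = pass, stringsAsFactors = FALSE)
  }
  duty <- pump_duty(100, 1, 360)
  grid <- dosimetry_grid_max()
  g <- function(nm) p[p$group == nm, ]
  dB <- cohens_d(g("GasB")$hr_mean, g("GasB")$hr_se * 2, 4,
                 g("Control")$hr_mean, g("Control")$hr_se * 2, 4)$d
  dC <- cohens_d(g("GasC")$hr_mean, g("GasC")$hr_se * 2, 4,
                 g("Control")$hr_mean, g("Control")$hr_se * 2, 4)$d
  wi <- welch_t_from_summaries(g("Air")$infarct_mean, g("Air")$infarct_se, 6,
                               g("Control")$infarct_mean,
                               g("Control")$infarct_se, 4)
  di <- cohens_d(g("Control")$infarct_mean, g("Control")$infarct_se * 2, 4,
                 g("Air")$infarct_mean, g("Air")$infarct_se * sqrt(6), 6)$d
  rbind(
    row("pump duty: 1-s pulse interval (min)", duty$pulse_interval_min,
        3.6, 0),
    row("O2 demand grid max <= 100 mL",
        as.numeric(grid$max_pvo2_ml <= 100), 1, 0),
    row("chamber pressure grid max <= 3 bar",
        as.numeric(grid$max_p_pres_bar <= 3), 1, 0),
    row("sample size rule DF=15, k=5", sample_size_rule(15, 5)$n, 4, 0),
    row("Fisher pooled gases vs control",
        fisher_exact_2x2(15, 0, 4, 6), 0.001, -1e-3),
    row("Fisher Gas A vs control",
        fisher_exact_2x2(7, 0, 4, 6), 0.034, -1e-3),
    row("Cohen's d HR Gas B vs Control", dB, 3.97, 0.02),
    row("Cohen's d HR Gas C vs Control", dC, 5.56, 0.02),
    row("Welch t infarct Air vs Control", wi$t, -3.69, 0.02),
    row("Welch df infarct Air vs Control", wi$df, 4.49, 0.02),
    row("Cohen's d infarct Control vs Air", di, 2.6, 0.02)
  )
}
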