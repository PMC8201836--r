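#' Clinical plan objectives
#'
#' The boost-phase objective set: CTV prescription 30 Gy in 5 fractions at
#' the 90% coverage level with heterogeneity aims V45Gy >= 50-55% and
#' V60Gy >= 30%, and per-organ near-to-maximum (D2cm3) aims with upper hard
#' limits — bladder 23.75 (27.5) Gy, rectum 17.0 (19.45) Gy, sigmoid 19.5
#' (21.65) Gy, bowel 17.0 (19.45) Gy. The boost aims correspond, through the
#' inverse EQD2 conversion at alpha/beta = 3 with a 45 Gy / 25-fraction
#' prior course, to cumulative limits of 80, 65, 70 and 65 Gy respectively.
#' Defaults ship as a YAML file in `inst/extdata/objectives.yaml`.
#'
#' @param path Optional YAML file to read instead of the packaged defaults.
#' @return An object of class `plan_objectives`.
#' @export
plan_objectives <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "objectives.yaml", package = "rodsfrt",
                        mustWork = TRUE)
  if (!file.exists(path))
    stop(sprintf("objectives file '%s' does not exist", path), call. = FALSE)
  y <- yaml::read_yaml(path)
  oars <- do.call(rbind, lapply(y$oars, function(o)
    data.frame(structure = o$structure, aim_gy = o$aim_gy,
               hard_gy = o$hard_gy, cumulative_gy = o$cumulative_gy,
               alpha_beta = o$alpha_beta)))
  if (any(oars$hard_gy < oars$aim_gy))
    stop("each OAR hard limit must be >= its aim", call. = FALSE)
  structure(list(prescription_gy = y$ctv$d90_gy,
                 boost_fractions = y$boost_fractions,
                 ctv = y$ctv, oars = oars,
                 prior = prior_course(y$prior$total_gy, y$prior$fractions)),
            class = "plan_objectives")
}

#' @export
print.plan_objectives <- function(x, ...) {
  cat(sprintf("<plan_objectives> CTV D90%% = %g Gy in %d fx; V45 >= %g%%, V60 >= %g%%\n",
              x$ctv$d90_gy, x$boost_fractions, x$ctv$v45_aim_pct, x$ctv$v60_aim_pct))
  cat(sprintf("  prior course: %g Gy / %d fx\n", x$prior$total_gy, x$prior$n))
  for (i in seq_len(nrow(x$oars)))
    cat(sprintf("  %-8s D2cm3 <= %g (%g) Gy  [cumulative <= %g Gy EQD2]\n",
                x$oars$structure[i], x$oars$aim_gy[i], x$oars$hard_gy[i],
                x$oars$cumulative_gy[i]))
  invisible(x)
}

#' Evaluate a dose distribution against the plan objectives
#'
#' Computes D90% of the CTV and of its 2 mm and 5 mm expansions, CTV V45Gy
#' and V60Gy, and every organ's D2cm3 — each as physical boost dose and as
#' cumulative EQD2 (boost converted at the structure's alpha/beta over the
#' boost fractionation, plus the prior course). Coverage (D90%) and
#' V-metrics are read from the 0.02 Gy-binned DVH — the same reading the
#' prescription normalisation targets; D2cm3 uses the exact voxel order
#' statistic, which is exactly linear in a global dose scale — the property
#' the mitigation closed form relies on. Aim-level and hard-limit
#' violations are flagged separately.
#'
#' @param dose A [dose_grid()] (normalised, or set `normalize = TRUE`).
#' @param structures A [structure_set()] with the CTV and all OARs named in
#'   the objectives; `PTV2mm`/`PTV5mm` are derived by expansion if absent.
#' @param objectives A [plan_objectives()].
#' @param normalize If `TRUE`, first rescale so CTV D90% equals the
#'   prescription.
#' @param strategy Optional label stored in the report.
#' @param keep_dvh Keep the computed DVH curves in the report (default TRUE;
#'   needed for cohort-average DVHs).
#' @return An object of class `plan_report` with fields `metrics` (data
#'   frame), `scale`, `strategy`, `hard_violations`, `aim_violations`,
#'   `objectives`, `dvh` (list of `dvh_curve`).
#' @export
evaluate_plan <- function(dose, structures, objectives = plan_objectives(),
                          normalize = FALSE, strategy = NULL, keep_dvh = TRUE) {
  stopifnot(inherits(dose, "dose_grid"), inherits(structures, "structure_set"),
            inherits(objectives, "plan_objectives"))
  need <- c("CTV", objectives$oars$structure)
  missing <- setdiff(need, names(structures$structures))
  if (length(missing))
    stop(sprintf("missing structures: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  ctv <- get_structure(structures, "CTV")
  scale <- 1
  if (normalize) {
    nr <- normalize_to_d90(dose, ctv, objectives$ctv$d90_gy)
    dose <- nr$dose
    scale <- nr$scale
  }
  ptv2 <- if ("PTV2mm" %in% names(structures$structures))
    get_structure(structures, "PTV2mm") else expand_mask(ctv, 2, "PTV2mm")
  ptv5 <- if ("PTV5mm" %in% names(structures$structures))
    get_structure(structures, "PTV5mm") else expand_mask(ctv, 5, "PTV5mm")

  nfx <- objectives$boost_fractions
  prior <- objectives$prior
  dvhs <- list()
  rows <- list()
  # D-metric aims tolerate half a DVH bin (the normalisation guarantee);
  # V-metric aims and hard limits are checked to float precision
  add <- function(structure, metric, value, units, aim, hard, cum_val, cum_limit,
                  aim_ge, tol = 1e-9) {
    rows[[length(rows) + 1]] <<- data.frame(
      structure = structure, metric = metric, value = value, units = units,
      aim = aim, hard_limit = hard,
      cumulative_eqd2_gy = cum_val, cumulative_limit_gy = cum_limit,
      pass_aim = if (is.na(aim)) NA else if (aim_ge) value >= aim - tol
                 else value <= aim + tol,
      pass_hard = if (is.na(hard)) NA else value <= hard + 1e-9)
  }

  dvh_ctv <- compute_dvh(dose, ctv)
  dvhs$CTV <- dvh_ctv
  d90 <- dose_at_volume_pct(dvh_ctv, 90)
  ab_ctv <- objectives$ctv$alpha_beta
  add("CTV", "D90%", d90, "Gy", objectives$ctv$d90_gy, NA,
      cumulative_eqd2(d90, nfx, ab_ctv, prior), NA, aim_ge = TRUE,
      tol = dvh_ctv$bin_width_gy / 2 + 1e-9)
  add("CTV", "V45Gy", volume_pct_at_dose(dvh_ctv, 45), "%",
      objectives$ctv$v45_aim_pct, NA, NA, NA, aim_ge = TRUE)
  add("CTV", "V60Gy", volume_pct_at_dose(dvh_ctv, 60), "%",
      objectives$ctv$v60_aim_pct, NA, NA, NA, aim_ge = TRUE)
  for (ptv in list(ptv2, ptv5)) {
    dv <- compute_dvh(dose, ptv)
    dvhs[[ptv$name]] <- dv
    d90p <- dose_at_volume_pct(dv, 90)
    add(ptv$name, "D90%", d90p, "Gy", objectives$ctv$d90_gy, NA,
        cumulative_eqd2(d90p, nfx, ab_ctv, prior), NA, aim_ge = TRUE)
  }
  for (i in seq_len(nrow(objectives$oars))) {
    o <- objectives$oars[i, ]
    m <- get_structure(structures, o$structure)
    dv <- compute_dvh(dose, m)
    dvhs[[o$structure]] <- dv
    d2 <- exact_dose_at_cm3(dose$dose_gy[m$occupancy],
                            min(2, dv$volume_cm3), voxel_volume_cm3(dose$grid))
    add(o$structure, "D2cm3", d2, "Gy", o$aim_gy, o$hard_gy,
        cumulative_eqd2(d2, nfx, o$alpha_beta, prior), o$cumulative_gy,
        aim_ge = FALSE)
  }
  metrics <- do.call(rbind, rows)
  structure(list(metrics = metrics, scale = scale, strategy = strategy,
                 hard_violations = sum(!metrics$pass_hard, na.rm = TRUE),
                 aim_violations = sum(!metrics$pass_aim, na.rm = TRUE),
                 objectives = objectives,
                 dvh = if (keep_dvh) dvhs else NULL),
            class = "plan_report")
}

#' @export
print.plan_report <- function(x, ...) {
  cat(sprintf("<plan_report>%s scale %.4f, %d hard-limit violation(s), %d aim violation(s)\n",
              if (!is.null(x$strategy)) paste0(" [", x$strategy, "]") else "",
              x$scale, x$hard_violations, x$aim_violations))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    flag <- if (isFALSE(m$pass_hard[i])) " HARD-LIMIT VIOLATION"
            else if (isFALSE(m$pass_aim[i])) " (aim not met)" else ""
    cum <- if (is.finite(m$cumulative_eqd2_gy[i]))
      sprintf("  cum EQD2 %.2f Gy", m$cumulative_eqd2_gy[i]) else ""
    cat(sprintf("  %-8s %-6s %8.2f %-3s%s%s\n", m$structure[i], m$metric[i],
                m$value[i], m$units[i], cum, flag))
  }
  invisible(x)
}

#' Coverage mitigation by renormalisation
#'
#' Rescales the whole dose grid to the highest level that violates no
#' organ-at-risk hard limit: since D2cm3 is exactly linear in a global
#' scale, the optimum is closed-form, `s* = min over OARs of
#' (hard limit / current D2cm3)`, with the binding organ ending exactly at
#' its limit. This realises the "renormalise to the maximum tolerable
#' PTV2mm D90%" mitigation strategy.
#'
#' @param dose A [dose_grid()].
#' @param structures A [structure_set()].
#' @param objectives A [plan_objectives()].
#' @param target_structure Structure whose resulting D90% is reported
#'   (default `"PTV2mm"`, derived by expansion if absent).
#' @param max_scale Cap applied (with a warning) when no organ receives any
#'   dose (default 3).
#' @return List with `dose` (scaled [dose_grid()]), `scale`, `binding_oar`,
#'   `target_d90_gy`.
#' @export
mitigate_renormalize <- function(dose, structures, objectives = plan_objectives(),
                                 target_structure = "PTV2mm", max_scale = 3) {
  stopifnot(inherits(dose, "dose_grid"), inherits(structures, "structure_set"))
  ratios <- rep(NA_real_, nrow(objectives$oars))
  vox <- voxel_volume_cm3(dose$grid)
  for (i in seq_len(nrow(objectives$oars))) {
    o <- objectives$oars[i, ]
    m <- get_structure(structures, o$structure)
    dv_dose <- dose$dose_gy[m$occupancy]
    if (max(dv_dose) <= 0) next
    d2 <- exact_dose_at_cm3(dv_dose, min(2, length(dv_dose) * vox), vox)
    if (d2 > 0) ratios[i] <- o$hard_gy / d2
  }
  if (all(is.na(ratios))) {
    warning(sprintf("no organ at risk receives dose; capping the scale at %g", max_scale))
    s <- max_scale
    binding <- NA_character_
  } else {
    s <- min(ratios, na.rm = TRUE)
    binding <- objectives$oars$structure[which.min(ratios)]
  }
  scaled <- dose_grid(dose$dose_gy * s, dose$grid)
  tgt <- if (target_structure %in% names(structures$structures))
    get_structure(structures, target_structure)
  else expand_mask(get_structure(structures, "CTV"),
                   if (target_structure == "PTV5mm") 5 else 2, target_structure)
  d90 <- dose_at_volume_pct(compute_dvh(scaled, tgt), 90)
  list(dose = scaled, scale = s, binding_oar = binding, target_d90_gy = d90)
}

#' Coverage mitigation by re-optimisation
#'
#' Re-runs the surrogate optimizer with an added PTV2mm coverage objective
#' and then applies [mitigate_renormalize()] — the "re-optimise including
#' PTV2mm, then renormalise" mitigation strategy. With the coverage
#' structure omitted this reduces to the plain renormalisation pipeline.
#'
#' @param structures A [structure_set()]; a `PTV2mm` expansion is added if
#'   absent.
#' @param rods,valley,config As for [sfrt_plan()].
#' @param objectives A [plan_objectives()].
#' @param coverage_structure Structure granted the extra coverage objective
#'   (default `"PTV2mm"`; `NULL` reduces to strategy A).
#' @return A [evaluate_plan()] report on the mitigated dose, labelled with
#'   the strategy and suffix `" B"`, with the applied `scale` recorded.
#' @export
mitigate_reoptimize <- function(structures, rods = NULL, valley = NULL,
                                config = optimizer_config(),
                                objectives = plan_objectives(),
                                coverage_structure = "PTV2mm") {
  if (!is.null(coverage_structure) &&
      !coverage_structure %in% names(structures$structures)) {
    ctv <- get_structure(structures, "CTV")
    margin <- if (identical(coverage_structure, "PTV5mm")) 5 else 2
    structures <- structure_set(c(structures$structures,
                                  list(expand_mask(ctv, margin, coverage_structure))))
  }
  config$coverage_structure <- coverage_structure
  plan <- sfrt_plan(structures, rods, valley, config)
  mit <- mitigate_renormalize(plan$dose, structures, objectives,
                              target_structure = if (is.null(coverage_structure))
                                "PTV2mm" else coverage_structure)
  rep <- evaluate_plan(mit$dose, structures, objectives,
                       strategy = paste0(config$strategy,
                                         if (is.null(coverage_structure)) " A" else " B"))
  rep$scale <- mit$scale
  rep$binding_oar <- mit$binding_oar
  rep
}

#' Cohort summary of plan reports
#'
#' Per-metric mean, sample standard deviation (n-1) and [min, max] across
#' two or more plan reports evaluated against the same objectives, plus the
#' cohort-average CTV DVH with 1 and 1.95 SD bands when the reports carry
#' their curves.
#'
#' @param reports List of `plan_report` objects.
#' @return An object of class `cohort_summary` with fields `table` (data
#'   frame: structure, metric, units, mean, sd, min, max) and `avg_dvh`
#'   (list of `dvh_average` by structure, or `NULL`).
#' @export
summarize_cohort <- function(reports) {
  if (length(reports) < 2L) stop("need at least 2 reports", call. = FALSE)
  stopifnot(all(vapply(reports, inherits, logical(1), "plan_report")))
  ref <- reports[[1]]$objectives
  for (r in reports[-1])
    if (!isTRUE(all.equal(ref[c("ctv", "oars", "boost_fractions")],
                          r$objectives[c("ctv", "oars", "boost_fractions")])))
      stop("reports were evaluated against different objectives", call. = FALSE)
  key <- paste(reports[[1]]$metrics$structure, reports[[1]]$metrics$metric)
  vals <- vapply(reports, function(r) {
    stopifnot(identical(paste(r$metrics$structure, r$metrics$metric), key))
    r$metrics$value
  }, numeric(length(key)))
  tab <- data.frame(structure = reports[[1]]$metrics$structure,
                    metric = reports[[1]]$metrics$metric,
                    units = reports[[1]]$metrics$units,
                    mean = rowMeans(vals),
                    sd = apply(vals, 1, stats::sd),
                    min = apply(vals, 1, min),
                    max = apply(vals, 1, max))
  avg <- NULL
  if (!any(vapply(reports, function(r) is.null(r$dvh), logical(1)))) {
    sn <- names(reports[[1]]$dvh)
    avg <- lapply(sn, function(nm)
      average_dvh(lapply(reports, function(r) r$dvh[[nm]])))
    names(avg) <- sn
  }
  structure(list(table = tab, avg_dvh = avg, n = length(reports)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d\n", x$n))
  t <- x$table
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-8s %-6s %6.1f +/- %.1f [%.1f, %.1f] %s\n",
                t$structure[i], t$metric[i], t$mean[i], t$sd[i],
                t$min[i], t$max[i], t$units[i]))
  invisible(x)
}
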