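#' Run the full planning chain on one synthetic phantom
#'
#' Convenience wrapper over the whole toolchain: generate a phantom, place
#' the default three-rod grid (for the SFRT strategies) and its valley
#' (peak-and-valley only), optimise the surrogate dose, normalise the CTV
#' D90% to the prescription, evaluate against the objectives and optionally
#' apply a coverage mitigation.
#'
#' @param seed Phantom seed.
#' @param strategy `"SFRT_1"`, `"SFRT_2"` or `"SBRT"`.
#' @param ctv_volume_cm3,spacing_mm Passed to [phantom_spec()].
#' @param rod_spec A [straight_rod_spec()].
#' @param valley_margin_mm Valley margin (default 3 mm).
#' @param config An [optimizer_config()]; its strategy is overridden by
#'   `strategy`.
#' @param objectives A [plan_objectives()].
#' @param mitigation `"none"`, `"renormalize"` (global rescale to the
#'   binding OAR hard limit) or `"reoptimize"` (adds a PTV2mm objective and
#'   rescales).
#' @param out_dir Optional directory; when given, the normalised dose
#'   (NIfTI), structure masks, DVH CSV and report JSON are written there.
#' @return List with `phantom`, `rods`, `valley`, `plan` ([sfrt_plan()]),
#'   `dose` (normalised [dose_grid()]), `report` and, when mitigation is
#'   requested, `mitigated` (report) and `mitigation_scale`.
#' @export
run_single_plan <- function(seed = 1, strategy = c("SFRT_1", "SFRT_2", "SBRT"),
                            ctv_volume_cm3 = 51, spacing_mm = 1.25,
                            rod_spec = straight_rod_spec(),
                            valley_margin_mm = 3,
                            config = optimizer_config(),
                            objectives = plan_objectives(),
                            mitigation = c("none", "renormalize", "reoptimize"),
                            out_dir = NULL) {
  strategy <- match.arg(strategy)
  mitigation <- match.arg(mitigation)
  config$strategy <- strategy
  phantom <- generate_phantom(phantom_spec(seed = seed,
                                           ctv_volume_cm3 = ctv_volume_cm3,
                                           spacing_mm = spacing_mm))
  ctv <- get_structure(phantom, "CTV")
  rods <- valley <- NULL
  if (strategy != "SBRT") {
    rods <- generate_straight_rods(ctv, rod_spec)
    if (strategy == "SFRT_1") valley <- make_valley(ctv, rods, valley_margin_mm)
  }
  plan <- sfrt_plan(phantom, rods, valley, config)
  norm <- normalize_to_d90(plan$dose, ctv, objectives$ctv$d90_gy)
  report <- evaluate_plan(norm$dose, phantom, objectives, strategy = strategy)

  out <- list(phantom = phantom, rods = rods, valley = valley, plan = plan,
              dose = norm$dose, normalization_scale = norm$scale,
              report = report)
  if (mitigation == "renormalize") {
    mit <- mitigate_renormalize(norm$dose, phantom, objectives)
    out$mitigated <- evaluate_plan(mit$dose, phantom, objectives,
                                   strategy = paste(strategy, "A"))
    out$mitigated$scale <- mit$scale
    out$mitigation_scale <- mit$scale
  } else if (mitigation == "reoptimize") {
    out$mitigated <- mitigate_reoptimize(phantom, rods, valley, config, objectives)
    out$mitigation_scale <- out$mitigated$scale
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_structure_set(phantom, file.path(out_dir, "structures"))
    write_dose(out$dose, file.path(out_dir, "dose.nii.gz"))
    write_dvh_csv(report$dvh, file.path(out_dir, "dvh.csv"))
    write_report_json(report, file.path(out_dir, "report.json"))
    if (!is.null(out$mitigated))
      write_report_json(out$mitigated, file.path(out_dir, "report_mitigated.json"))
  }
  out
}

#' Run a seeded phantom cohort end to end
#'
#' Generates `n` phantoms ([generate_cohort()]), plans each with every
#' requested strategy, normalises to the prescription, applies the
#' renormalisation mitigation and summarises the mitigated reports per
#' strategy.
#'
#' @param n Cohort size.
#' @param base_seed Cohort seed.
#' @param strategies Character vector of strategies to plan.
#' @param spacing_mm Phantom grid spacing.
#' @param config An [optimizer_config()] template.
#' @param objectives A [plan_objectives()].
#' @param out_dir Optional output directory for per-phantom report JSONs and
#'   a `summary.json`.
#' @return List with per-strategy elements: `reports` (mitigated
#'   `plan_report`s), `summary` ([summarize_cohort()] result) and
#'   `hard_violations` (total post-mitigation hard-limit violations).
#' @export
run_cohort <- function(n = 5, base_seed = 1, strategies = "SFRT_1",
                       spacing_mm = 1.25, config = optimizer_config(),
                       objectives = plan_objectives(), out_dir = NULL) {
  stopifnot(all(strategies %in% c("SFRT_1", "SFRT_2", "SBRT")))
  phantoms <- generate_cohort(n, base_seed, spacing_mm = spacing_mm)
  out <- list()
  for (strat in strategies) {
    cfg <- config
    cfg$strategy <- strat
    reports <- vector("list", n)
    for (i in seq_len(n)) {
      ph <- phantoms[[i]]
      ctv <- get_structure(ph, "CTV")
      rods <- valley <- NULL
      if (strat != "SBRT") {
        rods <- generate_straight_rods(ctv, straight_rod_spec())
        if (strat == "SFRT_1") valley <- make_valley(ctv, rods)
      }
      plan <- sfrt_plan(ph, rods, valley, cfg)
      norm <- normalize_to_d90(plan$dose, ctv, objectives$ctv$d90_gy)
      mit <- mitigate_renormalize(norm$dose, ph, objectives)
      reports[[i]] <- evaluate_plan(mit$dose, ph, objectives,
                                    strategy = paste(strat, "A"))
      reports[[i]]$scale <- mit$scale
      if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        write_report_json(reports[[i]],
                          file.path(out_dir, sprintf("%s_phantom%02d.json", strat, i)))
      }
    }
    summary <- if (n >= 2) summarize_cohort(reports) else NULL
    out[[strat]] <- list(reports = reports, summary = summary,
                         hard_violations = sum(vapply(reports, `[[`,
                                                      numeric(1), "hard_violations")))
  }
  if (!is.null(out_dir)) {
    js <- lapply(out, function(o) list(
      hard_violations = o$hard_violations,
      table = if (!is.null(o$summary)) o$summary$table else NULL))
    jsonlite::write_json(js, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
  }
  out
}
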