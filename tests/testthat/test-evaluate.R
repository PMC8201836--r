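test_that("objectives load from YAML with consistent aims and limits", {
  obj <- plan_objectives()
  expect_equal(obj$prescription_gy, 30)
  expect_equal(obj$boost_fractions, 5)
  expect_setequal(obj$oars$structure, c("bladder", "rectum", "sigmoid", "bowel"))
  expect_true(all(obj$oars$hard_gy >= obj$oars$aim_gy))
  # each OAR boost aim is the inverse EQD2 of its cumulative limit; the
  # sigmoid aim is printed rounded to 19.5 (exact conversion gives 19.449)
  prior_oar <- eqd2_of_metric(obj$prior$total_gy, obj$prior$n, 3)
  rec <- inverse_eqd2(obj$oars$cumulative_gy - prior_oar, obj$boost_fractions, 3)
  strict <- obj$oars$structure != "sigmoid"
  expect_true(all(abs(rec[strict] - obj$oars$aim_gy[strict]) <= 0.05))
  expect_lt(abs(rec[!strict] - obj$oars$aim_gy[!strict]), 0.06)
  expect_error(plan_objectives("/nonexistent/objectives.yaml"), "exist")
})

test_that("a constructed uniform CTV dose is evaluated exactly", {
  ph <- coarse_phantom()
  ctv <- get_structure(ph, "CTV")
  d <- array(0, ph$grid$shape)
  d[ctv$occupancy] <- 30
  rep <- evaluate_plan(dose_grid(d, ph$grid), ph)
  m <- rep$metrics
  get <- function(s, met) m[m$structure == s & m$metric == met, ]
  expect_equal(get("CTV", "D90%")$value, 30, tolerance = 0.011)
  expect_true(get("CTV", "D90%")$pass_aim)
  expect_equal(get("CTV", "D90%")$cumulative_eqd2_gy, 84.25, tolerance = 0.02)
  expect_equal(get("CTV", "V60Gy")$value, 0)
  expect_false(get("CTV", "V60Gy")$pass_aim)
  for (s in c("bladder", "rectum", "sigmoid", "bowel")) {
    expect_equal(get(s, "D2cm3")$value, 0)
    expect_true(get(s, "D2cm3")$pass_hard)
  }
  expect_equal(rep$hard_violations, 0)
})

test_that("a bladder D2cm3 just over the hard limit is flagged", {
  ph <- coarse_phantom()
  bl <- get_structure(ph, "bladder")
  d <- array(0, ph$grid$shape)
  d[get_structure(ph, "CTV")$occupancy] <- 30
  d[bl$occupancy] <- 27.6                  # hard limit is 27.5
  rep <- evaluate_plan(dose_grid(d, ph$grid), ph)
  row <- rep$metrics[rep$metrics$structure == "bladder", ]
  expect_equal(row$value, 27.6, tolerance = 0.011)
  expect_false(row$pass_hard)
  expect_false(row$pass_aim)
  expect_gte(rep$hard_violations, 1)
  # missing structures are reported by name
  ph2 <- structure_set(ph$structures[c("CTV", "bladder")])
  expect_error(evaluate_plan(dose_grid(d, ph$grid), ph2), "rectum")
})

test_that("plan reports round-trip through JSON unchanged", {
  ph <- coarse_phantom()
  ctv <- get_structure(ph, "CTV")
  d <- array(0, ph$grid$shape)
  d[ctv$occupancy] <- 29.73218764512
  rep <- evaluate_plan(dose_grid(d, ph$grid), ph, strategy = "SFRT_1")
  f <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, f)
  back <- read_report_json(f)
  expect_identical(back$metrics$value, rep$metrics$value)
  expect_identical(back$strategy, "SFRT_1")
})

test_that("mitigation scale is the closed-form optimum", {
  ph <- coarse_phantom()
  obj <- plan_objectives()
  # synthetic dose: every OAR at exactly half its hard limit
  d <- array(0, ph$grid$shape)
  d[get_structure(ph, "CTV")$occupancy] <- 30
  for (i in seq_len(nrow(obj$oars)))
    d[get_structure(ph, obj$oars$structure[i])$occupancy] <- obj$oars$hard_gy[i] / 2
  mit <- mitigate_renormalize(dose_grid(d, ph$grid), ph, obj)
  expect_equal(mit$scale, 2, tolerance = 1e-9)
  # one OAR exactly at its limit: scale 1, dose unchanged
  d2 <- d
  d2[get_structure(ph, "bladder")$occupancy] <- obj$oars$hard_gy[obj$oars$structure == "bladder"]
  mit2 <- mitigate_renormalize(dose_grid(d2, ph$grid), ph, obj)
  expect_equal(mit2$scale, 1, tolerance = 1e-9)
  expect_equal(mit2$binding_oar, "bladder")
  expect_equal(mit2$dose$dose_gy, d2, tolerance = 1e-12)
})

test_that("mitigation optimality: epsilon above violates, epsilon below does not", {
  pipe <- default_pipeline("SFRT_1")
  obj <- plan_objectives()
  mit <- mitigate_renormalize(pipe$dose, pipe$phantom, obj)
  eps <- 1e-6
  # independent oracle: k-th hottest voxel, k spanning 2 cm3
  vox <- voxel_volume_cm3(pipe$dose$grid)
  d2 <- function(dose) vapply(seq_len(nrow(obj$oars)), function(i) {
    d <- dose$dose_gy[get_structure(pipe$phantom, obj$oars$structure[i])$occupancy]
    sort(d, decreasing = TRUE)[max(1L, min(length(d), round(2 / vox)))]
  }, numeric(1))
  up <- d2(dose_grid(pipe$dose$dose_gy * mit$scale * (1 + eps), pipe$dose$grid))
  dn <- d2(dose_grid(pipe$dose$dose_gy * mit$scale * (1 - eps), pipe$dose$grid))
  expect_true(any(up > obj$oars$hard_gy))
  expect_true(all(dn <= obj$oars$hard_gy))
  # D2cm3 is exactly linear in the global scale
  base <- d2(pipe$dose)
  expect_equal(d2(mit$dose), base * mit$scale, tolerance = 1e-9)
})

test_that("renormalisation raises target coverage above the prescription", {
  pipe <- default_pipeline("SFRT_1")
  mit <- mitigate_renormalize(pipe$dose, pipe$phantom)
  expect_gt(mit$scale, 1)
  ctv <- get_structure(pipe$phantom, "CTV")
  d90 <- dose_at_volume_pct(compute_dvh(mit$dose, ctv), 90)
  expect_gt(d90, 30)
  rep <- evaluate_plan(mit$dose, pipe$phantom)
  expect_equal(rep$hard_violations, 0)
})

test_that("re-optimisation mitigation improves PTV2mm coverage", {
  ph <- coarse_phantom()
  rods <- coarse_rods(); valley <- coarse_valley()
  cfg <- optimizer_config("SFRT_1")
  baseline <- coarse_plan("SFRT_1")
  norm <- normalize_to_d90(baseline$dose, get_structure(ph, "CTV"))$dose
  ptv2 <- expand_mask(get_structure(ph, "CTV"), 2, "PTV2mm")
  d90_base <- dose_at_volume_pct(compute_dvh(norm, ptv2), 90)
  repB <- mitigate_reoptimize(ph, rods, valley, cfg)
  d90_B <- repB$metrics$value[repB$metrics$structure == "PTV2mm" &
                                repB$metrics$metric == "D90%"]
  expect_gte(d90_B, d90_base)
  expect_match(repB$strategy, " B$")
  expect_equal(repB$hard_violations, 0)
})

test_that("cohort summaries match a direct statistics oracle", {
  ph <- coarse_phantom()
  mk <- function(level) {
    d <- array(0, ph$grid$shape)
    d[get_structure(ph, "CTV")$occupancy] <- level
    evaluate_plan(dose_grid(d, ph$grid), ph)
  }
  reps <- list(mk(20), mk(30), mk(25))
  s <- summarize_cohort(reps)
  row <- s$table[s$table$structure == "CTV" & s$table$metric == "D90%", ]
  vals <- vapply(reps, function(r)
    r$metrics$value[r$metrics$structure == "CTV" & r$metrics$metric == "D90%"],
    numeric(1))
  expect_equal(row$mean, mean(vals))
  expect_equal(row$sd, stats::sd(vals))
  expect_equal(row$min, min(vals))
  expect_equal(row$max, max(vals))
  expect_true(all(s$table$min <= s$table$mean & s$table$mean <= s$table$max))
  # identical reports: zero SD, min == max == mean
  s2 <- summarize_cohort(list(mk(30), mk(30)))
  expect_equal(s2$table$sd, rep(0, nrow(s2$table)))
  expect_equal(s2$table$min, s2$table$max)
  # average DVH bands are attached
  expect_s3_class(s$avg_dvh$CTV, "dvh_average")
  expect_error(summarize_cohort(reps[1]), "2")
})
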