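test_that("DVH of constructed uniform and two-level doses is exact", {
  g <- voxel_grid(c(10, 10, 10), 2.5)
  occ <- array(TRUE, g$shape)
  m <- structure_mask(occ, g, "u")
  dvh <- compute_dvh(dose_grid(array(10, g$shape), g), m)
  expect_equal(dvh$volume_fraction[1], 1)
  expect_equal(volume_pct_at_dose(dvh, 10), 100)
  expect_equal(volume_pct_at_dose(dvh, 10.05), 0)
  expect_equal(utils::tail(dvh$volume_fraction, 1), 0)
  expect_true(all(diff(dvh$volume_fraction) <= 0))

  two <- array(10, g$shape)
  two[1:5, , ] <- 20
  dvh2 <- compute_dvh(dose_grid(two, g), m)
  expect_equal(volume_pct_at_dose(dvh2, 15), 50)
  expect_equal(dose_at_volume_pct(dvh2, 50), 20, tolerance = 0.02)
  # uniform dose: D90 equals the dose, V-queries step at it
  expect_equal(dose_at_volume_pct(dvh, 90), 10, tolerance = 0.02)
})

test_that("empty masks and invalid queries are rejected", {
  g <- voxel_grid(c(5, 5, 5), 2.5)
  d <- dose_grid(array(1, g$shape), g)
  empty <- structure_mask(array(FALSE, g$shape), g, "void")
  expect_error(compute_dvh(d, empty), "void")
  m <- structure_mask(array(TRUE, g$shape), g, "m")
  dvh <- compute_dvh(d, m)
  expect_error(dose_at_volume_pct(dvh, 0), "pct")
  expect_error(dose_at_volume_pct(dvh, 101), "pct")
  expect_error(dose_at_volume_cm3(dvh, 1e9), "exceeds")
})

test_that("DVH metrics agree with a voxel-sorting oracle on randomized cases", {
  set.seed(11)
  bw <- 0.02
  for (case in 1:100) {
    cs <- random_dose_case()
    dvh <- compute_dvh(cs$dose, cs$mask, bw)
    d <- cs$dose$dose_gy[cs$mask$occupancy]
    nd <- length(d)
    srt <- sort(d, decreasing = TRUE)
    # D at pct: dose of the ceiling(q*n)-th hottest voxel
    for (pct in c(90, runif(1, 5, 99))) {
      oracle <- srt[max(1L, ceiling(pct / 100 * nd))]
      expect_lt(abs(dose_at_volume_pct(dvh, pct) - oracle), bw + 1e-9)
    }
    # V at a random dose: fraction of voxels at or above it
    q <- runif(1, 0, max(d))
    oracle_v <- 100 * mean(d >= q)
    expect_lt(abs(volume_pct_at_dose(dvh, q) - oracle_v),
              100 / nd + 100 * bw / max(d))
    # D2cm3 equals D at pct = 100 * 2 / V
    vol <- mask_volume_cm3(cs$mask)
    if (vol > 2)
      expect_equal(dose_at_volume_cm3(dvh, 2),
                   dose_at_volume_pct(dvh, 200 / vol), tolerance = 1e-12)
    expect_true(all(diff(dvh$volume_fraction) <= 0))
    expect_equal(dvh$volume_fraction[1], 1)
  }
})

test_that("coverage metrics are monotone: D100 <= D90 <= D50", {
  set.seed(3)
  cs <- random_dose_case()
  dvh <- compute_dvh(cs$dose, cs$mask)
  expect_lte(dose_at_volume_pct(dvh, 100), dose_at_volume_pct(dvh, 90))
  expect_lte(dose_at_volume_pct(dvh, 90), dose_at_volume_pct(dvh, 50))
})

test_that("constructed two-level D2cm3 picks the hot subvolume", {
  # 4 cm3 structure: hottest 2 cm3 at 20 Gy, rest at 10 Gy
  g <- voxel_grid(c(8, 8, 4), 2.5)  # voxel 15.625 mm3
  nvox <- round(2000 / 15.625)      # 2 cm3 worth of voxels
  occ <- array(FALSE, g$shape)
  occ[seq_len(2 * nvox)] <- TRUE
  dose <- array(0, g$shape)
  dose[seq_len(nvox)] <- 20
  dose[nvox + seq_len(nvox)] <- 10
  dvh <- compute_dvh(dose_grid(dose, g), structure_mask(occ, g, "s"))
  expect_equal(dose_at_volume_cm3(dvh, 2), 20, tolerance = 0.02)
  # uniform case: D2cm3 equals the uniform dose
  dose[occ] <- 10
  dvh_u <- compute_dvh(dose_grid(dose, g), structure_mask(occ, g, "s"))
  expect_equal(dose_at_volume_cm3(dvh_u, 2), 10, tolerance = 0.02)
})

test_that("normalisation to D90 is linear and lands within half a bin", {
  set.seed(5)
  cs <- random_dose_case(max_gy = 20)
  res <- normalize_to_d90(cs$dose, cs$mask, target_gy = 30)
  dvh <- compute_dvh(res$dose, cs$mask)
  # half a bin is the achievable bound for the binned reading
  expect_lte(abs(dose_at_volume_pct(dvh, 90) - 30), 0.01 + 1e-9)
  # halved dose needs the doubled factor (to sub-bin reading precision)
  res2 <- normalize_to_d90(dose_grid(cs$dose$dose_gy / 2, cs$dose$grid),
                           cs$mask, target_gy = 30)
  expect_equal(res2$scale, 2 * res$scale, tolerance = 1e-3)
  # renormalising an already-normalised plan is the identity to reading
  # precision (and exact when the binned reading already equals the target)
  res3 <- normalize_to_d90(res$dose, cs$mask, target_gy = 30)
  expect_equal(res3$scale, 1, tolerance = 1e-3)
  # zero dose fails
  z <- dose_grid(array(0, cs$dose$grid$shape), cs$dose$grid)
  expect_error(normalize_to_d90(z, cs$mask), "zero")
})

test_that("DVHs scale with a global dose factor", {
  set.seed(9)
  cs <- random_dose_case()
  dvh1 <- compute_dvh(cs$dose, cs$mask)
  dvh3 <- compute_dvh(dose_grid(cs$dose$dose_gy * 3, cs$dose$grid), cs$mask)
  for (pct in c(95, 80, 50, 20))
    expect_equal(dose_at_volume_pct(dvh3, pct),
                 3 * dose_at_volume_pct(dvh1, pct), tolerance = 0.05)
})

test_that("average DVH has correct mean and bands", {
  g <- voxel_grid(c(6, 6, 6), 2.5)
  m <- structure_mask(array(TRUE, g$shape), g, "m")
  d1 <- compute_dvh(dose_grid(array(10, g$shape), g), m)
  d2 <- compute_dvh(dose_grid(array(20, g$shape), g), m)
  avg <- average_dvh(list(d1, d2))
  i <- which(avg$dose_gy == 5)
  expect_equal(avg$mean[i], 1)       # both curves still at 1 below 10 Gy
  i15 <- which(avg$dose_gy == 15)
  expect_equal(avg$mean[i15], 0.5)   # midpoint between the two step curves
  expect_true(all(avg$lo_1sd <= avg$mean & avg$mean <= avg$hi_1sd))
  expect_true(all(avg$lo_195sd <= avg$lo_1sd))
  # identical curves give zero-width bands
  same <- average_dvh(list(d1, d1))
  expect_equal(same$sd, rep(0, length(same$sd)))
  # binning mismatch is an error
  d3 <- compute_dvh(dose_grid(array(10, g$shape), g), m, bin_width_gy = 0.05)
  expect_error(average_dvh(list(d1, d3)), "binning")
})
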