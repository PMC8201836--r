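test_that("rod axis follows the ZX-then-ZY rotation convention", {
  expect_equal(axis_from_angles(0, 0), c(0, 0, 1))
  # independent oracle: explicit rotation matrices applied to +z
  rot_y <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                              3, 3, byrow = TRUE)
  rot_x <- function(t) matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)),
                              3, 3, byrow = TRUE)
  for (ang in list(c(30, 0), c(0, 25), c(40, -20), c(-75, 60))) {
    t1 <- ang[1] * pi / 180; t2 <- ang[2] * pi / 180
    oracle <- drop(rot_x(t2) %*% rot_y(t1) %*% c(0, 0, 1))
    got <- axis_from_angles(ang[1], ang[2])
    expect_equal(sqrt(sum(got^2)), 1, tolerance = 1e-12)
    expect_equal(got, oracle, tolerance = 1e-12,
                 info = paste(ang, collapse = "/"))
  }
  # near-90 tilt approaches the axial plane
  v <- axis_from_angles(89.9, 0)
  expect_lt(v[3], 0.01)
  expect_gt(abs(v[1]), 0.99)
  expect_error(axis_from_angles(90, 0), "90")
  expect_error(axis_from_angles(0, -95), "90")
})

test_that("default lattice gives 15 mm pitch and 10 mm edge gap in a box", {
  box <- box_target(c(97, 97, 33), 1.25)
  rs <- generate_straight_rods(box, straight_rod_spec(max_rods = NULL))
  expect_gt(length(rs$rods), 10)
  # the pitch property concerns unclipped rods: keep full-cross-section rods
  # (the lattice rows at the box edge are cut by the target boundary)
  nv <- vapply(rs$rods, function(m) sum(m$occupancy), numeric(1))
  rs$rods <- rs$rods[nv == max(nv)]
  cen <- t(vapply(rs$rods, mask_centroid_mm, numeric(3)))
  d <- as.matrix(stats::dist(cen[, 1:2]))
  pitch <- min(d[d > 1e-6])
  expect_lt(abs(pitch - 15), 1.25 / 2)
  # edge-to-edge gap between that adjacent pair
  pair <- which(abs(d - pitch) < 1e-6, arr.ind = TRUE)[1, ]
  co <- grid_coords_mm(box$grid)
  pa <- unique(cbind(co$x[rs$rods[[pair[1]]]$occupancy],
                     co$y[rs$rods[[pair[1]]]$occupancy]))
  pb <- unique(cbind(co$x[rs$rods[[pair[2]]]$occupancy],
                     co$y[rs$rods[[pair[2]]]$occupancy]))
  gap <- min(sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2))
  expect_lt(abs(gap - 10), 1.25 / 2)
})

test_that("rod voxelisation converges to the analytic cylinder volume", {
  box <- box_target(c(49, 49, 65), 0.625)
  rs <- generate_straight_rods(box, straight_rod_spec(max_rods = 1))
  rod <- rs$rods[[1]]
  co <- grid_coords_mm(box$grid)
  L <- diff(range(co$z[rod$occupancy])) + 0.625
  analytic <- pi * 2.5^2 * L
  expect_lt(abs(mask_volume_cm3(rod) * 1000 - analytic) / analytic, 0.03)
})

test_that("rod selection keeps the most central rod first and clips to the target", {
  ph <- coarse_phantom()
  ctv <- get_structure(ph, "CTV")
  rs <- coarse_rods()
  expect_length(rs$rods, 3)
  expect_equal(names(rs$rods)[1], "rod_1")
  # central rod's planar offset from the CTV centroid is under one pitch cell
  cen_ctv <- mask_centroid_mm(ctv)
  cen_rod <- mask_centroid_mm(rs$rods[[1]])
  expect_lt(sqrt(sum((cen_rod[1:2] - cen_ctv[1:2])^2)), 15 / sqrt(2))
  # containment: every rod voxel inside the target
  expect_false(any(rs$union$occupancy & !ctv$occupancy))
  # central rod spans (approximately) the whole CTV length
  co <- grid_coords_mm(ctv$grid)
  expect_gt(diff(range(co$z[rs$rods[[1]]$occupancy])),
            0.8 * diff(range(co$z[ctv$occupancy])))
})

test_that("single-voxel targets clip to at most one voxel of rod", {
  g <- voxel_grid(c(9, 9, 9), 1.25)
  occ <- array(FALSE, g$shape); occ[5, 5, 5] <- TRUE
  rs <- generate_straight_rods(structure_mask(occ, g, "pt"),
                               suppressWarnings(straight_rod_spec(diameter_mm = 5)))
  expect_lte(sum(rs$union$occupancy), 1)
})

test_that("rods are translation-equivariant with the target", {
  g <- voxel_grid(c(60, 60, 40), 1.25)
  mk <- function(shift) {
    occ <- array(FALSE, g$shape)
    occ[(10:40) + shift, (10:40) + shift, 5:35] <- TRUE
    structure_mask(occ, g, "t")
  }
  r0 <- generate_straight_rods(mk(0L), straight_rod_spec())
  r3 <- generate_straight_rods(mk(3L), straight_rod_spec())
  shifted <- array(FALSE, g$shape)
  shifted[(1:57) + 3, (1:57) + 3, ] <- r0$union$occupancy[1:57, 1:57, ]
  expect_identical(r3$union$occupancy, shifted)
})

test_that("an off-target lattice yields an empty rod set with a warning", {
  g <- voxel_grid(c(9, 9, 9), 1.25)
  occ <- array(FALSE, g$shape); occ[5, 5, 5] <- TRUE
  expect_warning(
    rs <- generate_straight_rods(structure_mask(occ, g, "pt"),
                                 straight_rod_spec(diameter_mm = 3,
                                                   center_to_center_mm = 40,
                                                   offset_uv_mm = c(15, 15))),
    "empty")
  expect_length(rs$rods, 0)
})

test_that("invalid rod grids are rejected", {
  expect_error(straight_rod_spec(diameter_mm = 15, center_to_center_mm = 10),
               "merge")
  expect_error(straight_rod_spec(diameter_mm = 0), "diameter")
})

test_that("spline rods pass through their seeds within half a voxel", {
  box <- box_target(c(64, 64, 64), 1.25)
  set.seed(21)
  for (i in 1:10) {
    npts <- sample(3:6, 1)
    seeds <- cbind(sort(runif(npts, -25, 25)), runif(npts, -20, 20),
                   seq(-25, 25, length.out = npts))
    # random layouts may bend tighter than the tube radius (allowed, warns)
    rod <- suppressWarnings(generate_bending_rod(box, bending_rod_spec(seeds, 5)))
    cl <- attr(rod, "centerline_mm")
    dmin <- apply(seeds, 1, function(s) min(sqrt(colSums((t(cl) - s)^2))))
    expect_lt(max(dmin), 1.25 / 2)
  }
})

test_that("collinear seeds reduce the spline to a straight rod", {
  box <- box_target(c(48, 48, 48), 1.25)
  two <- cbind(c(-15, 15), c(-10, 10), c(-15, 15))
  three <- cbind(c(-15, 0, 15), c(-10, 0, 10), c(-15, 0, 15))
  r2 <- generate_bending_rod(box, bending_rod_spec(two, 5))
  r3 <- generate_bending_rod(box, bending_rod_spec(three, 5))
  expect_identical(r2$occupancy, r3$occupancy)
  expect_gt(sum(r2$occupancy), 0)
})

test_that("quarter-circle centerline length matches the analytic arc", {
  box <- box_target(c(80, 80, 48), 1.25)
  th <- seq(0, pi / 2, length.out = 7)
  seeds <- cbind(40 * cos(th) - 20, 40 * sin(th) - 20, rep(0, 7))
  rod <- generate_bending_rod(box, bending_rod_spec(seeds, 5))
  cl <- attr(rod, "centerline_mm")
  len <- sum(sqrt(rowSums(diff(cl)^2)))
  expect_lt(abs(len - pi / 2 * 40) / (pi / 2 * 40), 0.02)
})

test_that("tight hairpins warn about tube self-overlap", {
  box <- box_target(c(40, 40, 24), 1.25)
  tight <- cbind(c(-5, -3, -5), c(-5, -2.5, 0), c(0, 0, 0))
  expect_warning(generate_bending_rod(box, bending_rod_spec(tight, 5)),
                 "self-overlap")
})

test_that("bending rod validation rejects degenerate seeds", {
  expect_error(bending_rod_spec(rbind(c(0, 0, 0))), "two")
  expect_error(bending_rod_spec(rbind(c(0, 0, 0), c(0, 0, 0))), "distinct")
})

test_that("per-rod dose levels are carried as attributes", {
  rs <- coarse_rods()
  r <- set_rod_dose_level(rs$rods[[1]], 70)
  expect_equal(attr(r, "dose_level_gy"), 70)
})
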