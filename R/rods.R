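#' Rod axis direction from ZX / ZY plane angles
#'
#' The rod axis is +z (inferior to superior) rotated first by `angle_zx_deg`
#' about the y axis (tilt in the ZX plane) and then by `angle_zy_deg` about
#' the x axis (tilt in the ZY plane); `(0, 0)` maps to `(0, 0, 1)`. Angles
#' must stay strictly inside (-90, 90) degrees — at 90 the rod would lie in
#' the axial plane.
#'
#' @param angle_zx_deg Tilt in the ZX plane, degrees.
#' @param angle_zy_deg Tilt in the ZY plane, degrees.
#' @return Unit length-3 vector.
#' @export
axis_from_angles <- function(angle_zx_deg = 0, angle_zy_deg = 0) {
  if (abs(angle_zx_deg) >= 90 || abs(angle_zy_deg) >= 90)
    stop("rod angles must lie strictly inside (-90, 90) degrees", call. = FALSE)
  t1 <- angle_zx_deg * pi / 180
  t2 <- angle_zy_deg * pi / 180
  # Rx(t2) %*% Ry(t1) %*% c(0,0,1)
  v <- c(sin(t1), -cos(t1) * sin(t2), cos(t1) * cos(t2))
  v / sqrt(sum(v^2))
}

#' Straight rod grid specification
#'
#' A square lattice of parallel cylinders ("rods") inside a target volume.
#' Defaults follow the virtual-rod template: 5 mm diameter, 15 mm
#' centre-to-centre pitch (a 10 mm edge-to-edge gap) and three rods, one of
#' them the most central and longest.
#'
#' @param diameter_mm Rod diameter (> 0; should be at least two grid
#'   spacings to voxelise faithfully).
#' @param center_to_center_mm Lattice pitch (> diameter, or rods merge).
#' @param offset_uv_mm Length-2 translation of the lattice in the plane
#'   perpendicular to the rod axis.
#' @param angle_zx_deg,angle_zy_deg Rod axis tilts, see [axis_from_angles()].
#' @param max_rods Keep at most this many rods (default 3), chosen by
#'   within-target length with the most central rod always retained; `NULL`
#'   keeps every lattice rod.
#' @param end_margin_mm Optional trim of each rod end along the axis
#'   (default 0, i.e. rods run the full within-target length).
#' @return An object of class `straight_rod_spec`.
#' @export
straight_rod_spec <- function(diameter_mm = 5, center_to_center_mm = 15,
                              offset_uv_mm = c(0, 0), angle_zx_deg = 0,
                              angle_zy_deg = 0, max_rods = 3,
                              end_margin_mm = 0) {
  if (diameter_mm <= 0) stop("'diameter_mm' must be > 0", call. = FALSE)
  if (center_to_center_mm <= diameter_mm)
    stop("'center_to_center_mm' must exceed 'diameter_mm' (rods must not merge)",
         call. = FALSE)
  if (length(offset_uv_mm) != 2L) stop("'offset_uv_mm' must have length 2", call. = FALSE)
  if (!is.null(max_rods) && max_rods < 1) stop("'max_rods' must be >= 1", call. = FALSE)
  if (end_margin_mm < 0) stop("'end_margin_mm' must be >= 0", call. = FALSE)
  axis <- axis_from_angles(angle_zx_deg, angle_zy_deg)
  structure(list(diameter_mm = diameter_mm,
                 center_to_center_mm = center_to_center_mm,
                 offset_uv_mm = as.numeric(offset_uv_mm),
                 angle_zx_deg = angle_zx_deg, angle_zy_deg = angle_zy_deg,
                 axis = axis, max_rods = max_rods,
                 end_margin_mm = end_margin_mm),
            class = "straight_rod_spec")
}

# orthonormal in-plane basis (e1, e2) perpendicular to a unit axis u,
# chosen so that for u = +z: e1 = +x, e2 = +y
plane_basis <- function(u) {
  ref <- if (abs(u[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
  e1 <- c(ref[2] * u[3] - ref[3] * u[2],
          ref[3] * u[1] - ref[1] * u[3],
          ref[1] * u[2] - ref[2] * u[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Collection of rod structures
#'
#' Per-rod labelled masks plus their union, the shared axis direction (for
#' straight sets) and an optional per-rod dose level attribute.
#'
#' @param rods Named list of [structure_mask()] objects with pairwise
#'   disjoint occupancy.
#' @param axis Unit axis vector, or `NULL` for bent rods.
#' @param spec The generating spec, kept for provenance.
#' @return An object of class `rod_set`.
#' @export
rod_set <- function(rods, axis = NULL, spec = NULL) {
  grid <- if (length(rods)) rods[[1]]$grid else NULL
  occ <- NULL
  for (m in rods) {
    stopifnot(inherits(m, "structure_mask"))
    if (is.null(occ)) occ <- m$occupancy
    else {
      if (any(occ & m$occupancy))
        stop("rod masks must be pairwise disjoint", call. = FALSE)
      occ <- occ | m$occupancy
    }
  }
  union <- if (is.null(grid)) NULL else structure_mask(occ, grid, "rods")
  if (length(rods))
    names(rods) <- vapply(rods, `[[`, character(1), "name")
  structure(list(rods = rods, union = union, axis = axis, spec = spec),
            class = "rod_set")
}

#' @export
print.rod_set <- function(x, ...) {
  cat(sprintf("<rod_set> %d rod(s)%s\n", length(x$rods),
              if (!is.null(x$axis))
                sprintf(", axis (%.3f, %.3f, %.3f)", x$axis[1], x$axis[2], x$axis[3])
              else ""))
  for (m in x$rods) {
    lv <- attr(m, "dose_level_gy")
    cat(sprintf("  %-8s %7.2f cm3%s\n", m$name, mask_volume_cm3(m),
                if (!is.null(lv)) sprintf("  dose level %.1f Gy", lv) else ""))
  }
  invisible(x)
}

#' Generate a straight rod grid inside a target
#'
#' Places parallel cylinders of `diameter_mm` on a square lattice of pitch
#' `center_to_center_mm` in the plane perpendicular to the rod axis. The
#' lattice is anchored at the projection of the target centroid (so rods
#' translate with the target) plus `offset_uv_mm`, and every rod is clipped
#' to the target: a voxel belongs to a rod iff its centre lies inside the
#' infinite cylinder and inside the target. With `max_rods` set, the rods
#' with the greatest within-target length are kept, the most central one
#' always included, and the result is sorted central-first.
#'
#' @param target Non-empty [structure_mask()].
#' @param spec A [straight_rod_spec()].
#' @return A [rod_set()]; empty (with a warning) if no lattice cylinder
#'   meets the target.
#' @export
generate_straight_rods <- function(target, spec) {
  stopifnot(inherits(target, "structure_mask"), inherits(spec, "straight_rod_spec"))
  if (!any(target$occupancy)) stop("target is empty", call. = FALSE)
  h <- target$grid$spacing_mm
  if (spec$diameter_mm < 2 * max(h))
    warning(sprintf("rod diameter %.3g mm is under two grid spacings (%.3g mm); voxelisation will be coarse",
                    spec$diameter_mm, max(h)))
  u <- spec$axis
  B <- plane_basis(u)
  pitch <- spec$center_to_center_mm
  r2 <- (spec$diameter_mm / 2)^2

  idx <- which(target$occupancy, arr.ind = TRUE)
  P <- sweep(sweep(idx - 1, 2, target$grid$spacing_mm, `*`), 2,
             target$grid$origin_mm, `+`)
  cen <- mask_centroid_mm(target)
  W <- sweep(P, 2, cen, `-`)
  along <- W %*% u
  p1 <- W %*% B$e1 - spec$offset_uv_mm[1]
  p2 <- W %*% B$e2 - spec$offset_uv_mm[2]
  j1 <- round(p1 / pitch)
  j2 <- round(p2 / pitch)
  q1 <- p1 - pitch * j1
  q2 <- p2 - pitch * j2
  inside <- q1^2 + q2^2 <= r2 + 1e-9
  if (!any(inside)) {
    warning("no lattice rod intersects the target; returning an empty rod set")
    return(rod_set(list(), axis = u, spec = spec))
  }

  key <- paste(j1[inside], j2[inside], sep = ",")
  flat <- which(target$occupancy)[inside]
  along_in <- along[inside]
  groups <- split(seq_along(key), key)
  info <- data.frame(key = names(groups),
                     len = vapply(groups, function(g)
                       diff(range(along_in[g])) + min(h), numeric(1)),
                     cdist = vapply(strsplit(names(groups), ","), function(jk) {
                       j <- as.numeric(jk)
                       sqrt(sum((c(j[1] * pitch + spec$offset_uv_mm[1],
                                   j[2] * pitch + spec$offset_uv_mm[2]))^2))
                     }, numeric(1)),
                     stringsAsFactors = FALSE)
  central <- info$key[which.min(info$cdist)]
  keep <- info$key
  if (!is.null(spec$max_rods) && nrow(info) > spec$max_rods) {
    by_len <- info$key[order(-info$len)]
    keep <- unique(c(central, by_len))[seq_len(spec$max_rods)]
  }
  info <- info[match(keep, info$key), , drop = FALSE]
  info <- info[order(info$key != central, -info$len), , drop = FALSE]  # central first

  rods <- vector("list", nrow(info))
  for (i in seq_len(nrow(info))) {
    g <- groups[[info$key[i]]]
    if (spec$end_margin_mm > 0) {
      rng <- range(along_in[g])
      g <- g[along_in[g] >= rng[1] + spec$end_margin_mm &
               along_in[g] <= rng[2] - spec$end_margin_mm]
    }
    occ <- array(FALSE, dim = target$grid$shape)
    occ[flat[g]] <- TRUE
    rods[[i]] <- structure_mask(occ, target$grid, sprintf("rod_%d", i))
  }
  rods <- rods[vapply(rods, function(m) any(m$occupancy), logical(1))]
  rod_set(rods, axis = u, spec = spec)
}

#' Bending rod specification
#'
#' A single tube swept along a natural cubic spline through ordered seed
#' points, used to follow curved anatomy (e.g. an anteverted uterus).
#'
#' @param seed_points_mm Matrix (rows = points, 3 columns) or list of >= 2
#'   pairwise-distinct 3D patient coordinates; the first and last points
#'   should lie inside the target.
#' @param diameter_mm Tube diameter (> 0).
#' @return An object of class `bending_rod_spec`.
#' @export
bending_rod_spec <- function(seed_points_mm, diameter_mm = 5) {
  if (is.list(seed_points_mm)) seed_points_mm <- do.call(rbind, seed_points_mm)
  seed_points_mm <- as.matrix(seed_points_mm)
  if (ncol(seed_points_mm) != 3L || nrow(seed_points_mm) < 2L)
    stop("need at least two 3D seed points", call. = FALSE)
  if (anyDuplicated(round(seed_points_mm, 9)))
    stop("seed points must be pairwise distinct", call. = FALSE)
  if (diameter_mm <= 0) stop("'diameter_mm' must be > 0", call. = FALSE)
  structure(list(seed_points_mm = unname(seed_points_mm),
                 diameter_mm = as.numeric(diameter_mm)),
            class = "bending_rod_spec")
}

# natural cubic spline through seed points, chord-length parameterised and
# resampled to (approximately) uniform arc length with step `step_mm`
spline_centerline <- function(seeds, step_mm) {
  tc <- c(0, cumsum(sqrt(rowSums(diff(seeds)^2))))
  dense_t <- seq(0, max(tc), length.out = max(200L, 20L * nrow(seeds)))
  dense <- vapply(1:3, function(d) {
    if (nrow(seeds) == 2L) stats::approx(tc, seeds[, d], xout = dense_t)$y
    else stats::spline(tc, seeds[, d], xout = dense_t, method = "natural")$y
  }, numeric(length(dense_t)))
  arc <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  s_out <- seq(0, max(arc), length.out = max(2L, ceiling(max(arc) / step_mm) + 1L))
  out <- vapply(1:3, function(d) stats::approx(arc, dense[, d], xout = s_out)$y,
                numeric(length(s_out)))
  out
}

#' Generate a spline-bent rod inside a target
#'
#' Fits a natural cubic spline through the seed points (chord-length
#' parameterised, arc-length resampled), sweeps it with a sphere of
#' `diameter_mm` and clips the tube to the target: a voxel belongs to the
#' rod iff its centre is within one radius of the centreline. The
#' centreline passes through every seed point to within half a voxel. If the
#' centreline curvature radius drops below the tube radius the tube
#' self-overlaps; this is allowed (volume is not double counted) but
#' produces a warning.
#'
#' @param target Non-empty [structure_mask()].
#' @param spec A [bending_rod_spec()].
#' @param name Structure name (default `"rod_1"`).
#' @return A [structure_mask()] with the resampled centreline in attribute
#'   `"centerline_mm"`.
#' @export
generate_bending_rod <- function(target, spec, name = "rod_1") {
  stopifnot(inherits(target, "structure_mask"), inherits(spec, "bending_rod_spec"))
  if (!any(target$occupancy)) stop("target is empty", call. = FALSE)
  grid <- target$grid
  h <- grid$spacing_mm
  r <- spec$diameter_mm / 2
  cl <- spline_centerline(spec$seed_points_mm, step_mm = min(h) / 2)

  # curvature estimate from second differences of the uniform resampling
  if (nrow(cl) >= 3) {
    d1 <- diff(cl); d2 <- diff(d1)
    ds <- sqrt(rowSums(d1^2))[-1]
    kappa <- sqrt(rowSums(d2^2)) / pmax(ds^2, 1e-12)
    if (any(kappa > 1 / r, na.rm = TRUE))
      warning("centerline curvature radius below the tube radius: tube self-overlaps")
  }

  # candidate voxels: bounding box of the centreline grown by the radius
  lo <- pmax(apply(cl, 2, min) - r - max(h), grid$origin_mm)
  hi <- apply(cl, 2, max) + r + max(h)
  rng <- lapply(1:3, function(d) {
    ax <- grid_axis_mm(grid, d)
    which(ax >= lo[d] & ax <= hi[d])
  })
  if (any(lengths(rng) == 0L))
    return(structure_mask(array(FALSE, grid$shape), grid, name))
  ax <- lapply(1:3, function(d) grid_axis_mm(grid, d)[rng[[d]]])
  nb <- lengths(rng)
  X <- array(ax[[1]], dim = nb)
  Y <- array(rep(ax[[2]], each = nb[1]), dim = nb)
  Z <- array(rep(ax[[3]], each = nb[1] * nb[2]), dim = nb)

  # exact point-to-segment distance, running minimum over segments
  best <- array(Inf, dim = nb)
  for (i in seq_len(nrow(cl) - 1)) {
    a <- cl[i, ]; b <- cl[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 < 1e-18) next
    t <- ((X - a[1]) * ab[1] + (Y - a[2]) * ab[2] + (Z - a[3]) * ab[3]) / len2
    t <- pmin(1, pmax(0, t))
    d2 <- (a[1] + t * ab[1] - X)^2 + (a[2] + t * ab[2] - Y)^2 +
      (a[3] + t * ab[3] - Z)^2
    best <- pmin(best, d2)
  }
  occ <- array(FALSE, dim = grid$shape)
  occ[rng[[1]], rng[[2]], rng[[3]]] <- best <= r^2 + 1e-9
  occ <- occ & target$occupancy
  out <- structure_mask(occ, grid, name)
  attr(out, "centerline_mm") <- cl
  out
}

#' Assign a per-rod dose level
#'
#' Attaches a dose-level attribute to a rod mask (the optimizer's rod
#' objective can then differ per rod). Purely an annotation.
#'
#' @param rod A [structure_mask()].
#' @param dose_gy Dose level in Gy.
#' @export
set_rod_dose_level <- function(rod, dose_gy) {
  stopifnot(inherits(rod, "structure_mask"))
  attr(rod, "dose_level_gy") <- as.numeric(dose_gy)
  rod
}
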