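#' Synthetic pelvic phantom specification
#'
#' Parameters of the deterministic phantom generator: a bent super-ellipsoid
#' CTV (the curved cervix-uterus target) surrounded by simple organ-at-risk
#' primitives — bladder anterior, rectum and sigmoid posterior, bowel bag
#' superior — with a configurable surface gap and seeded placement jitter.
#'
#' @param seed Integer seed; identical specs give bit-identical phantoms.
#' @param ctv_volume_cm3 Requested CTV volume (default 51 cm3, the cohort
#'   median; realistic range roughly 30-90 cm3).
#' @param ctv_bend_angle_deg Anterior curvature of the CTV long axis
#'   (default 30 degrees), giving spline-bent rods something to follow.
#' @param oar_gap_mm Minimum margin between the CTV surface and each OAR
#'   surface (default 5 mm).
#' @param spacing_mm Grid spacing (default 1.25 mm so a 5 mm rod spans 4
#'   voxels; 2.5 mm matches a typical dose-calculation grid).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1, ctv_volume_cm3 = 51, ctv_bend_angle_deg = 30,
                         oar_gap_mm = 5, spacing_mm = 1.25) {
  if (!is.finite(seed) || seed != round(seed))
    stop("'seed' must be an integer", call. = FALSE)
  if (!is.finite(ctv_volume_cm3) || ctv_volume_cm3 <= 0)
    stop("'ctv_volume_cm3' must be > 0", call. = FALSE)
  if (oar_gap_mm < 0) stop("'oar_gap_mm' must be >= 0", call. = FALSE)
  if (spacing_mm <= 0) stop("'spacing_mm' must be > 0", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 ctv_volume_cm3 = as.numeric(ctv_volume_cm3),
                 ctv_bend_angle_deg = as.numeric(ctv_bend_angle_deg),
                 oar_gap_mm = as.numeric(oar_gap_mm),
                 spacing_mm = as.numeric(spacing_mm)),
            class = "phantom_spec")
}

# volume of the unit p-norm ball scaled by semi-axes: 8abc G(1+1/p)^3/G(1+3/p)
superellipsoid_volume_factor <- function(p) {
  8 * gamma(1 + 1 / p)^3 / gamma(1 + 3 / p)
}

#' Generate a synthetic pelvic phantom
#'
#' Builds CTV, bladder, rectum, sigmoid and bowel masks on one adaptive grid
#' centred on the CTV. The CTV is a super-ellipsoid (exponent 2.5) with
#' semi-axes (a, a, 2a), sheared anteriorly along z by the bend angle; its
#' semi-axes are calibrated by bisection so the voxelised volume matches the
#' request to well within 5%. OARs are ellipsoid/cylinder primitives placed
#' at anatomical offsets with seeded jitter, then trimmed against the CTV
#' expanded by `oar_gap_mm` (and against each other) so all structures are
#' pairwise disjoint.
#'
#' @param spec A [phantom_spec()].
#' @return A [structure_set()] with structures `CTV`, `bladder`, `rectum`,
#'   `sigmoid`, `bowel`.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 1, spacing_mm = 2.5))
#' ph
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$spacing_mm
  V <- spec$ctv_volume_cm3 * 1000  # mm3
  p <- 2.5
  a_nom <- (V / (2 * superellipsoid_volume_factor(p)))^(1 / 3)
  c_nom <- 2 * a_nom
  bend_k <- tan(spec$ctv_bend_angle_deg * pi / 180) / (2 * c_nom)
  g <- spec$oar_gap_mm

  if (V < 8 * h^3)
    stop(sprintf("requested CTV volume %.3g cm3 spans fewer than 8 voxels at %.3g mm spacing",
                 spec$ctv_volume_cm3, h), call. = FALSE)

  # adaptive extents (mm) around the CTV centre at the origin
  bend_shift <- bend_k * c_nom^2
  ext <- list(x = c(-1, 1) * (1.25 * a_nom + 26),
              y = c(-(1.15 * a_nom + bend_shift + g + 40), 1.15 * a_nom + g + 32),
              z = c(-(1.15 * c_nom + 24), 1.15 * c_nom + g + 34))
  n <- vapply(ext, function(e) ceiling(diff(e) / h) + 1, numeric(1))
  if (any(n > 400))
    stop(sprintf("requested CTV volume %.3g cm3 needs a grid larger than 400 voxels per axis at %.3g mm spacing",
                 spec$ctv_volume_cm3, h), call. = FALSE)
  grid <- voxel_grid(n, h, vapply(ext, `[[`, numeric(1), 1))
  co <- grid_coords_mm(grid)

  se_occ <- function(center, semi, p, bend = 0) {
    (abs(co$x - center[1]) / semi[1])^p +
      (abs(co$y - center[2] + bend * (co$z - center[3])^2) / semi[2])^p +
      (abs(co$z - center[3]) / semi[3])^p <= 1
  }

  # calibrate the CTV scale by bisection on the voxel count (monotone)
  target_n <- V / (h^3)
  count_at <- function(s) sum(se_occ(c(0, 0, 0), s * c(a_nom, a_nom, c_nom), p, bend_k))
  lo <- 0.7; hi <- 1.4
  if (count_at(lo) > target_n || count_at(hi) < target_n)
    stop(sprintf("CTV volume %.3g cm3 unreachable on this grid (calibration bounds exceeded)",
                 spec$ctv_volume_cm3), call. = FALSE)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (count_at(mid) < target_n) lo <- mid else hi <- mid
    if (abs(count_at((lo + hi) / 2) - target_n) / target_n < 0.002) break
  }
  s_cal <- (lo + hi) / 2
  ctv_occ <- se_occ(c(0, 0, 0), s_cal * c(a_nom, a_nom, c_nom), p, bend_k)
  if (abs(sum(ctv_occ) * h^3 - V) / V > 0.05)
    stop(sprintf("CTV volume %.3g cm3 unreachable on this grid within 5%%",
                 spec$ctv_volume_cm3), call. = FALSE)
  ctv <- structure_mask(ctv_occ, grid, "CTV")

  a <- s_cal * a_nom; cc <- s_cal * c_nom
  jit <- with_seed(spec$seed, stats::runif(8, -2, 2))
  idx <- which(ctv_occ, arr.ind = FALSE)
  y_front <- min(co$y[ctv_occ]); y_back <- max(co$y[ctv_occ])
  z_top <- max(co$z[ctv_occ]); z_bot <- min(co$z[ctv_occ])

  cyl_occ <- function(center_xy, radius, z_range, tilt_x = 0) {
    dx <- co$x - center_xy[1] - tilt_x * (co$z - mean(z_range))
    dy <- co$y - center_xy[2]
    dx^2 + dy^2 <= radius^2 & co$z >= z_range[1] & co$z <= z_range[2]
  }

  bladder_occ <- se_occ(c(jit[1], y_front - g - 16 + jit[2], z_bot / 2 + jit[3]),
                        c(26, 19, 22), 2)
  rectum_occ <- cyl_occ(c(jit[4], y_back + g + 12), 14,
                        c(z_bot - 15, 0.3 * cc + jit[5]))
  sigmoid_occ <- cyl_occ(c(12 + jit[6], y_back + g + 9), 11,
                         c(0.2 * cc, z_top + 12 + jit[7]), tilt_x = 0.15)
  bowel_occ <- se_occ(c(0, -5 + jit[8], z_top + g + 15), c(30, 26, 17), 2)

  guard <- expand_mask(ctv, g)$occupancy
  bladder_occ <- bladder_occ & !guard
  rectum_occ <- rectum_occ & !guard & !bladder_occ
  sigmoid_occ <- sigmoid_occ & !guard & !bladder_occ & !rectum_occ
  bowel_occ <- bowel_occ & !guard & !bladder_occ & !rectum_occ & !sigmoid_occ

  oars <- list(bladder = bladder_occ, rectum = rectum_occ,
               sigmoid = sigmoid_occ, bowel = bowel_occ)
  for (nm in names(oars)) if (!any(oars[[nm]]))
    stop(sprintf("phantom organ '%s' is empty; widen the grid or reduce oar_gap_mm", nm),
         call. = FALSE)

  out <- structure_set(c(list(ctv),
                         mapply(structure_mask, oars, names(oars),
                                MoreArgs = list(grid = grid), SIMPLIFY = FALSE)))
  attr(out, "phantom_spec") <- spec
  out
}

#' Generate a seeded phantom cohort
#'
#' `n` phantoms with distinct seeds (`base_seed`, `base_seed + 1`, ...) and
#' CTV volumes drawn uniformly from 30-90 cm3 using `base_seed`, mirroring
#' the spread of target volumes in a small clinical cohort.
#'
#' @param n Number of phantoms (>= 1).
#' @param base_seed Integer seed for both the volume draw and the phantoms.
#' @param ... Further arguments passed to [phantom_spec()] (e.g.
#'   `spacing_mm`).
#' @return List of [structure_set()] phantoms, with the drawn volumes in
#'   attribute `"ctv_volumes_cm3"`.
#' @export
generate_cohort <- function(n, base_seed = 1, ...) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("'n' must be a single integer >= 1", call. = FALSE)
  vols <- with_seed(base_seed, stats::runif(n, 30, 90))
  phantoms <- lapply(seq_len(n), function(i)
    generate_phantom(phantom_spec(seed = base_seed + i - 1L,
                                  ctv_volume_cm3 = vols[i], ...)))
  attr(phantoms, "ctv_volumes_cm3") <- vols
  phantoms
}

#' Write a phantom to disk
#'
#' One NIfTI volume per structure plus a `manifest.json` listing structure
#' names, files and volumes (cm3).
#'
#' @param set A [structure_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_structure_set <- function(set, dir) {
  stopifnot(inherits(set, "structure_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(set$structures, function(m) {
    file <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", m$name), ".nii.gz"))
    write_mask(m, file)
    list(name = m$name, file = basename(file),
         volume_cm3 = mask_volume_cm3(m))
  })
  jsonlite::write_json(unname(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
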