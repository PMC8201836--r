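#' Voxel grid geometry
#'
#' A `voxel_grid` is the shared 3D lattice on which every structure mask and
#' dose distribution in the package lives. Axes follow the DICOM patient
#' convention: x runs right to left, y anterior to posterior, z inferior to
#' superior. Voxel centre `(i, j, k)` (1-based) sits at
#' `origin_mm + (c(i, j, k) - 1) * spacing_mm`.
#'
#' @param shape Integer vector of length 3, voxels along x, y, z (each >= 1).
#' @param spacing_mm Positive voxel side length in mm; a scalar (isotropic,
#'   the usual case) or a length-3 vector.
#' @param origin_mm Patient coordinates (mm) of the first voxel centre.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(40, 40, 40), spacing_mm = 2.5)
#' voxel_volume_cm3(g)
#' @export
voxel_grid <- function(shape, spacing_mm = 1.25, origin_mm = c(0, 0, 0)) {
  shape <- as.integer(round(shape))
  if (length(shape) != 3L || any(shape < 1L))
    stop("'shape' must be three integers >= 1", call. = FALSE)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(as.numeric(spacing_mm), 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("'spacing_mm' must be positive (scalar or length 3)", call. = FALSE)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("'origin_mm' must be three finite reals", call. = FALSE)
  structure(list(shape = shape, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(signif(x$spacing_mm, 4), collapse = " x "),
              paste(signif(x$origin_mm, 4), collapse = ", ")))
  invisible(x)
}

#' @rdname voxel_grid
#' @param grid A `voxel_grid`.
#' @export
voxel_volume_cm3 <- function(grid) prod(grid$spacing_mm) / 1000

#' Voxel-centre coordinates along one axis
#' @param grid A `voxel_grid`.
#' @param axis Axis index 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of patient coordinates in mm.
#' @export
grid_axis_mm <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing_mm[axis]
}

#' Full 3D arrays of voxel-centre coordinates
#'
#' Returns a list of three arrays (`x`, `y`, `z`), each with the grid's
#' dimensions, holding the patient coordinate of every voxel centre.
#' @param grid A `voxel_grid`.
#' @export
grid_coords_mm <- function(grid) {
  s <- grid$shape
  list(x = array(grid_axis_mm(grid, 1), dim = s),
       y = array(rep(grid_axis_mm(grid, 2), each = s[1]), dim = s),
       z = array(rep(grid_axis_mm(grid, 3), each = s[1] * s[2]), dim = s))
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

#' Binary structure mask
#'
#' A named binary occupancy volume (CTV, an organ at risk, a rod, ...) on a
#' [voxel_grid()].
#'
#' @param occupancy Logical (or 0/1 numeric) array matching `grid$shape`.
#' @param grid The `voxel_grid` the mask lives on.
#' @param name Structure label.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(occupancy, grid, name = "structure") {
  if (is.numeric(occupancy)) {
    if (any(!occupancy %in% c(0, 1)))
      stop("occupancy must be binary (0/1)", call. = FALSE)
    occupancy <- array(occupancy != 0, dim = dim(occupancy))
  }
  if (!is.logical(occupancy) || !identical(as.integer(dim(occupancy)), grid$shape))
    stop("occupancy must be a logical array with the grid's dimensions", call. = FALSE)
  occupancy[is.na(occupancy)] <- FALSE
  structure(list(name = as.character(name), grid = grid, occupancy = occupancy),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d voxels, %.2f cm3\n",
              x$name, sum(x$occupancy), mask_volume_cm3(x)))
  invisible(x)
}

#' Structure volume in cm3
#' @param mask A `structure_mask`.
#' @export
mask_volume_cm3 <- function(mask) sum(mask$occupancy) * voxel_volume_cm3(mask$grid)

#' Structure centroid in patient coordinates (mm)
#' @param mask A `structure_mask`.
#' @return Length-3 numeric vector, or NAs for an empty mask.
#' @export
mask_centroid_mm <- function(mask) {
  idx <- which(mask$occupancy, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(c(NA_real_, NA_real_, NA_real_))
  mask$grid$origin_mm + (colMeans(idx) - 1) * mask$grid$spacing_mm
}

#' Named collection of structure masks on one grid
#'
#' @param masks List of `structure_mask` objects sharing one grid; names are
#'   taken from each mask's `name` field.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks) {
  if (length(masks) == 0L) stop("empty structure set", call. = FALSE)
  stopifnot(all(vapply(masks, inherits, logical(1), "structure_mask")))
  g <- masks[[1]]$grid
  for (m in masks) if (!same_grid(g, m$grid))
    stop("all masks in a structure_set must share one grid", call. = FALSE)
  names(masks) <- vapply(masks, `[[`, character(1), "name")
  structure(list(grid = g, structures = masks), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set> on ")
  print(x$grid)
  for (m in x$structures)
    cat(sprintf("  %-10s %8.2f cm3\n", m$name, mask_volume_cm3(m)))
  invisible(x)
}

#' Extract one structure by name
#' @param set A `structure_set`.
#' @param name Structure name.
#' @export
get_structure <- function(set, name) {
  if (!name %in% names(set$structures))
    stop(sprintf("structure '%s' not present (have: %s)", name,
                 paste(names(set$structures), collapse = ", ")), call. = FALSE)
  set$structures[[name]]
}

#' Per-voxel dose distribution
#'
#' Total physical boost dose (Gy, summed over all fractions) on a
#' [voxel_grid()].
#'
#' @param dose_gy Non-negative numeric array matching `grid$shape`.
#' @param grid The `voxel_grid`.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(dose_gy, grid) {
  if (!is.numeric(dose_gy) || !identical(as.integer(dim(dose_gy)), grid$shape))
    stop("dose_gy must be a numeric array with the grid's dimensions", call. = FALSE)
  if (any(!is.finite(dose_gy)) || any(dose_gy < 0))
    stop("dose values must be finite and >= 0", call. = FALSE)
  structure(list(grid = grid, dose_gy = dose_gy), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> max %.2f Gy, mean %.2f Gy on %d x %d x %d grid\n",
              max(x$dose_gy), mean(x$dose_gy),
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  invisible(x)
}

# run expr with a private, restored RNG stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
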