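#' Read and write structure masks as NIfTI
#'
#' Masks are stored as 0/1 volumes; voxel spacing and origin are carried in
#' the NIfTI sform (interpreted here in the DICOM patient frame the package
#' uses throughout). The round trip is lossless: occupancy exactly, spacing
#' and origin to sub-micrometre precision.
#'
#' @param mask A [structure_mask()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `write_mask` invisibly returns `path`; `read_mask` returns a
#'   [structure_mask()] named after the file unless `name` is given.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "structure_mask"))
  write_volume(array(as.integer(mask$occupancy), dim = mask$grid$shape),
               mask$grid, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask
#' @param name Structure name for the mask read back.
#' @export
read_mask <- function(path, name = NULL) {
  v <- read_volume(path)
  vals <- unique(as.vector(v$data))
  if (!all(vals %in% c(0, 1)))
    stop(sprintf("'%s' is not a binary mask volume (values beyond 0/1 present)",
                 path), call. = FALSE)
  if (is.null(name))
    name <- sub("\\.nii(\\.gz)?$", "", basename(path))
  structure_mask(array(v$data != 0, dim = v$grid$shape), v$grid, name)
}

#' Read and write dose grids as NIfTI
#'
#' Dose values are total physical Gy over the boost course.
#' @param dose A [dose_grid()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @export
write_dose <- function(dose, path) {
  stopifnot(inherits(dose, "dose_grid"))
  write_volume(dose$dose_gy, dose$grid, path, datatype = "double")
  invisible(path)
}

#' @rdname write_dose
#' @export
read_dose <- function(path) {
  v <- read_volume(path)
  dose_grid(v$data, v$grid)
}

write_volume <- function(data, grid, path, datatype) {
  aff <- diag(c(grid$spacing_mm, 1))
  aff[1:3, 4] <- grid$origin_mm
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
}

read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (max(spacing) - min(spacing) > 1e-6 * mean(spacing))
    warning("anisotropic voxel spacing; the package's geometry assumes near-isotropic voxels")
  origin <- aff[1:3, 4]
  data <- array(as.vector(as.array(img)), dim = dim(img))  # drop nifti attrs
  grid <- voxel_grid(dim(data), spacing, origin)
  list(data = data, grid = grid)
}

#' Export a DVH set as CSV
#'
#' Long-format table with columns `structure`, `dose_gy`, `volume_fraction`.
#' @param dvhs Named list of `dvh_curve` objects.
#' @param path Output CSV path.
#' @export
write_dvh_csv <- function(dvhs, path) {
  rows <- do.call(rbind, lapply(dvhs, function(d)
    data.frame(structure = d$structure, dose_gy = d$dose_gy,
               volume_fraction = d$volume_fraction)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a plan report as JSON
#'
#' Metric values round-trip unchanged (full double precision).
#' @param report A `plan_report`.
#' @param path Output JSON path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "plan_report"))
  out <- list(strategy = report$strategy, scale = report$scale,
              hard_violations = report$hard_violations,
              aim_violations = report$aim_violations,
              units = "Gy (doses), % (volumes), cm3 (absolute volumes)",
              metrics = report$metrics)
  # 17 significant digits: doubles survive the text round trip bit-exactly
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Extract axial contours from a structure mask
#'
#' Traces the 0.5-level iso-contour of the occupancy on every axial slice,
#' returning closed polygons in patient coordinates (mm). This is the
#' geometry a DICOM RT Structure Set carries per ROI.
#'
#' @param mask A [structure_mask()].
#' @return List with one element per non-empty slice: `z_mm` and `polygons`
#'   (each a two-column x/y matrix whose last vertex equals the first).
#' @export
extract_contours <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  g <- mask$grid
  ax <- grid_axis_mm(g, 1); ay <- grid_axis_mm(g, 2)
  # pad by one voxel of zeros so boundary-touching regions still close
  px <- c(ax[1] - g$spacing_mm[1], ax, ax[length(ax)] + g$spacing_mm[1])
  py <- c(ay[1] - g$spacing_mm[2], ay, ay[length(ay)] + g$spacing_mm[2])
  out <- list()
  for (k in seq_len(g$shape[3])) {
    sl <- mask$occupancy[, , k]
    if (!any(sl)) next
    z <- matrix(0, length(px), length(py))
    z[2:(length(ax) + 1), 2:(length(ay) + 1)] <- sl
    cl <- grDevices::contourLines(px, py, z, levels = 0.5)
    polys <- lapply(cl, function(p) {
      m <- cbind(x = p$x, y = p$y)
      if (any(m[1, ] != m[nrow(m), ])) m <- rbind(m, m[1, ])
      m
    })
    out[[length(out) + 1]] <- list(z_mm = grid_axis_mm(g, 3)[k], polygons = polys)
  }
  out
}

#' Export structure contours as an RT-structure-style JSON file
#'
#' One entry per structure with its name (preserved verbatim) and per-slice
#' closed polygons in patient millimetres — the same information a DICOM RT
#' Structure Set encodes, serialised as plain text. Empty structures are
#' skipped with a warning.
#'
#' @param set A [structure_set()].
#' @param path Output JSON path.
#' @return Invisibly, the exported list.
#' @export
export_contours <- function(set, path) {
  stopifnot(inherits(set, "structure_set"))
  entries <- list()
  for (m in set$structures) {
    if (!any(m$occupancy)) {
      warning(sprintf("structure '%s' is empty; skipped", m$name))
      next
    }
    sl <- extract_contours(m)
    entries[[length(entries) + 1]] <- list(
      name = m$name,
      slices = lapply(sl, function(s)
        list(z_mm = s$z_mm,
             polygons = lapply(s$polygons, function(p)
               list(x_mm = p[, 1], y_mm = p[, 2])))))
  }
  jsonlite::write_json(list(frame = "DICOM patient axes (mm)",
                            structures = entries),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(entries)
}

#' Re-voxelise exported contours onto a grid
#'
#' Rebuilds a binary mask from per-slice closed polygons using even-odd
#' point-in-polygon tests on voxel centres (so holes are honoured). Used to
#' validate the contour export round trip.
#'
#' @param contours Output of [extract_contours()].
#' @param grid Target [voxel_grid()].
#' @param name Structure name.
#' @return A [structure_mask()].
#' @export
revoxelize_contours <- function(contours, grid, name = "structure") {
  occ <- array(FALSE, dim = grid$shape)
  ax <- grid_axis_mm(grid, 1); ay <- grid_axis_mm(grid, 2)
  az <- grid_axis_mm(grid, 3)
  pts <- expand.grid(x = ax, y = ay)
  for (s in contours) {
    k <- which.min(abs(az - s$z_mm))
    if (abs(az[k] - s$z_mm) > grid$spacing_mm[3] / 2 + 1e-9) next
    inside_n <- rep(0L, nrow(pts))
    for (p in s$polygons) {
      io <- pracma::inpolygon(pts$x, pts$y, p[, 1], p[, 2], boundary = TRUE)
      inside_n <- inside_n + as.integer(io)
    }
    occ[, , k] <- occ[, , k] | matrix(inside_n %% 2L == 1L, length(ax), length(ay))
  }
  structure_mask(occ, grid, name)
}
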