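#' Isotropic Euclidean margin expansion
#'
#' Dilates a binary structure by a Euclidean margin: a voxel belongs to the
#' result iff its centre lies within `margin_mm` of the centre of an
#' occupied input voxel — the same voxel-centre rule used throughout the
#' package's voxelisation, resolution-convergent by construction. This is
#' the operation behind PTV margins (2 or 5 mm around the CTV) and the
#' valley margin around the rods. Implemented as an exact binary dilation
#' with a spherical structuring element, evaluated by FFT convolution.
#'
#' @param mask A [structure_mask()].
#' @param margin_mm Margin in mm (>= 0; 0 is the identity).
#' @param name Name for the result (default `<name>+<margin>mm`).
#' @return The expanded [structure_mask()]; always a superset of the input.
#' @export
expand_mask <- function(mask, margin_mm, name = NULL) {
  stopifnot(inherits(mask, "structure_mask"))
  if (length(margin_mm) != 1L || !is.finite(margin_mm) || margin_mm < 0)
    stop("'margin_mm' must be a single value >= 0", call. = FALSE)
  if (is.null(name))
    name <- sprintf("%s+%gmm", mask$name, margin_mm)
  h <- mask$grid$spacing_mm
  r <- floor(margin_mm / h + 1e-9)          # structuring-element radius, voxels
  if (all(r == 0) || !any(mask$occupancy))
    return(structure_mask(mask$occupancy, mask$grid, name))

  offs <- lapply(1:3, function(d) ((-r[d]:r[d]) * h[d])^2)
  d2 <- outer(outer(offs[[1]], offs[[2]], `+`), offs[[3]], `+`)
  ball <- d2 <= margin_mm^2 + 1e-9
  out <- convolve_binary(mask$occupancy, ball, r)
  structure_mask(out, mask$grid, name)
}

# exact binary dilation: counts overlaps by zero-padded FFT convolution and
# thresholds at 0.5 (counts are integers up to float noise)
convolve_binary <- function(occ, ball, r) {
  s <- dim(occ)
  pad <- vapply(1:3, function(d) stats::nextn(s[d] + 2 * r[d] + 1, c(2, 3, 5)),
                integer(1))
  A <- array(0, dim = pad)
  A[seq_len(s[1]), seq_len(s[2]), seq_len(s[3])] <- occ
  K <- array(0, dim = pad)
  ix <- lapply(1:3, function(d) ((-r[d]:r[d]) %% pad[d]) + 1L)
  K[ix[[1]], ix[[2]], ix[[3]]] <- ball
  cnt <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / prod(pad)
  cnt[seq_len(s[1]), seq_len(s[2]), seq_len(s[3])] > 0.5
}

#' Valley (cooling) structure around the rods
#'
#' Boolean difference between the target and the rod union expanded by an
#' additional margin: the region whose dose the peak-and-valley strategy
#' holds down. By construction the valley is disjoint from the expanded rods
#' and, together with the expanded-rod region clipped to the target,
#' partitions the target.
#'
#' @param target Target [structure_mask()] (typically the CTV).
#' @param rods A [rod_set()] or a [structure_mask()] of the rod union.
#' @param margin_mm Additional margin around the rods (default 3 mm).
#' @return A [structure_mask()] named `"valley"`.
#' @export
make_valley <- function(target, rods, margin_mm = 3) {
  stopifnot(inherits(target, "structure_mask"))
  union <- if (inherits(rods, "rod_set")) rods$union else rods
  if (is.null(union))
    return(structure_mask(target$occupancy, target$grid, "valley"))
  stopifnot(inherits(union, "structure_mask"))
  if (!same_grid(target$grid, union$grid))
    stop("target and rods must share one grid", call. = FALSE)
  if (!any(union$occupancy))
    return(structure_mask(target$occupancy, target$grid, "valley"))
  grown <- expand_mask(union, margin_mm)
  occ <- target$occupancy & !grown$occupancy
  if (!any(occ))
    warning("valley is empty: the rod margin covers the whole target")
  structure_mask(occ, target$grid, "valley")
}
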