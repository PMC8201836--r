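#' Gaussian deliverability smoothing
#'
#' Convolves a non-negative intensity field with an isotropic Gaussian
#' kernel (separable, truncated at four sigma, rows renormalised so a
#' constant field is reproduced exactly). This is the package's
#' deliverability model: it forbids unphysically sharp dose and plays the
#' role of the beam penumbra that a real optimizer works against, so that
#' 5 mm peaks on a 15 mm pitch are non-trivial to achieve. The operation is
#' linear, preserves the total of an interior source to well within 0.1%
#' and never exceeds the input maximum.
#'
#' @param intensity Non-negative numeric array, or a [dose_grid()].
#' @param grid The [voxel_grid()] (ignored if `intensity` is a `dose_grid`).
#' @param sigma_mm Kernel standard deviation in mm (> 0).
#' @return A [dose_grid()] on the same grid.
#' @export
smooth_field <- function(intensity, grid = NULL, sigma_mm = 3) {
  if (inherits(intensity, "dose_grid")) {
    grid <- intensity$grid
    intensity <- intensity$dose_gy
  }
  stopifnot(inherits(grid, "voxel_grid"))
  if (sigma_mm <= 0) stop("'sigma_mm' must be > 0", call. = FALSE)
  dose_grid(gauss_sep(intensity, grid$spacing_mm, sigma_mm), grid)
}

# row-normalised 1D Gaussian convolution matrix for one axis
gauss_mat <- function(n, h, sigma_mm) {
  i <- seq_len(n)
  K <- exp(-outer(i, i, `-`)^2 * h^2 / (2 * sigma_mm^2))
  K[abs(outer(i, i, `-`)) * h > 4 * sigma_mm] <- 0
  K / rowSums(K)
}

# separable 3D convolution via BLAS matrix products
gauss_sep <- function(A, h, sigma_mm) {
  s <- dim(A)
  K1 <- gauss_mat(s[1], h[1], sigma_mm)
  K2 <- gauss_mat(s[2], h[2], sigma_mm)
  K3 <- gauss_mat(s[3], h[3], sigma_mm)
  A <- array(K1 %*% matrix(A, s[1], s[2] * s[3]), dim = s)
  A <- aperm(array(K2 %*% matrix(aperm(A, c(2, 1, 3)), s[2], s[1] * s[3]),
                   dim = s[c(2, 1, 3)]), c(2, 1, 3))
  aperm(array(K3 %*% matrix(aperm(A, c(3, 1, 2)), s[3], s[1] * s[2]),
              dim = s[c(3, 1, 2)]), c(2, 3, 1))
}

#' Surrogate optimizer configuration
#'
#' Parameters of the simplified deliverable-dose optimizer. `strategy`
#' selects which objectives are active: `"SFRT_1"` (peak-and-valley) drives
#' rod voxels above `rod_min_gy` while holding the valley below
#' `valley_max_gy`; `"SFRT_2"` (peak-only) drops the valley objective;
#' `"SBRT"` (uniform) ignores rods and valley entirely. All strategies keep
#' the CTV at or above the prescription, penalise each organ at risk's
#' hottest 2 cm3 above its limit and decay the dose bath outside the CTV
#' plus 20 mm.
#'
#' @param strategy One of `"SFRT_1"`, `"SFRT_2"`, `"SBRT"`.
#' @param rod_min_gy Rod minimum-dose objective, Gy (default 60; the
#'   clinically explored range is 60-80).
#' @param valley_max_gy Valley maximum-dose objective, Gy (default 45).
#' @param prescription_gy Target prescription at D90%, Gy (default 30 in 5
#'   fractions).
#' @param kernel_sigma_mm Deliverability kernel sigma, mm (default 3,
#'   roughly a clinical penumbra at depth).
#' @param oar_limits_gy Named vector of per-organ D2cm3 optimisation limits
#'   in Gy (defaults are the clinical aims for bladder, rectum, sigmoid,
#'   bowel).
#' @param iterations Gradient-descent iterations (default 300).
#' @param step_size Relative step size in (0, 1]; the actual step is
#'   `step_size / (2 * sum of weights)`, which keeps fixed-step descent
#'   stable for the quadratic penalties.
#' @param weights Named penalty weights (`ctv`, `rod`, `valley`, `oar`,
#'   `bath`, `coverage`).
#' @param coverage_structure Optional extra structure name given a
#'   prescription-level minimum-dose objective (used by the re-optimisation
#'   mitigation strategy, e.g. `"PTV2mm"`).
#' @param seed Integer seed (the default algorithm is deterministic; the
#'   seed is recorded for provenance and future stochastic variants).
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(strategy = c("SFRT_1", "SFRT_2", "SBRT"),
                             rod_min_gy = 60, valley_max_gy = 45,
                             prescription_gy = 30, kernel_sigma_mm = 3,
                             oar_limits_gy = c(bladder = 23.75, rectum = 17,
                                               sigmoid = 19.5, bowel = 17),
                             iterations = 300, step_size = 1,
                             weights = c(ctv = 1, rod = 1, valley = 1,
                                         oar = 4, bath = 0.05, coverage = 1),
                             coverage_structure = NULL, seed = 1) {
  strategy <- match.arg(strategy)
  if (strategy != "SBRT") {
    if (!(rod_min_gy > valley_max_gy))
      stop("'rod_min_gy' must exceed 'valley_max_gy'", call. = FALSE)
    if (!(valley_max_gy >= prescription_gy))
      stop("'valley_max_gy' must be at least the prescription", call. = FALSE)
    if (!(rod_min_gy >= 60 && rod_min_gy <= 80))
      warning("rod_min_gy outside the explored 60-80 Gy range")
  }
  if (kernel_sigma_mm <= 0) stop("'kernel_sigma_mm' must be > 0", call. = FALSE)
  if (iterations < 0) stop("'iterations' must be >= 0", call. = FALSE)
  if (step_size <= 0) stop("'step_size' must be > 0", call. = FALSE)
  w <- c(ctv = 1, rod = 1, valley = 1, oar = 4, bath = 0.05, coverage = 1)
  w[names(weights)] <- weights
  structure(list(strategy = strategy, rod_min_gy = rod_min_gy,
                 valley_max_gy = valley_max_gy, prescription_gy = prescription_gy,
                 kernel_sigma_mm = kernel_sigma_mm, oar_limits_gy = oar_limits_gy,
                 iterations = as.integer(iterations), step_size = step_size,
                 weights = w, coverage_structure = coverage_structure,
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Optimise a surrogate SFRT boost plan
#'
#' The package's plan "fit": projected gradient descent on a weighted
#' quadratic penalty over a non-negative intensity field `x`, with the dose
#' modelled as `dose = G x` where `G` is the Gaussian deliverability kernel
#' ([smooth_field()]). Active penalties depend on the strategy (see
#' [optimizer_config()]): rod voxels below the rod objective, valley voxels
#' above the valley cap, CTV voxels below the prescription, each OAR's
#' hottest-2 cm3 voxel set (recomputed every iteration) above its limit, and
#' a quadratic decay of the dose bath outside the CTV plus 20 mm. The
#' intensity starts uniform at the prescription inside the CTV plus 5 mm and
#' the iteration budget is fixed, so the result is deterministic for a given
#' configuration. The returned dose is un-normalised; apply
#' [normalize_to_d90()] for the prescription scaling.
#'
#' @param structures A [structure_set()] containing at least the CTV and the
#'   organs at risk named in the config's `oar_limits_gy`.
#' @param rods A [rod_set()] (required for SFRT strategies, ignored for SBRT).
#' @param valley Valley [structure_mask()] (required for SFRT_1).
#' @param config An [optimizer_config()].
#' @param ctv_name Name of the target structure (default `"CTV"`).
#' @return An object of class `sfrt_plan`: fields `dose` ([dose_grid()]),
#'   `objective` (per-iteration trace), `converged`, `config`, `structures`,
#'   `rods`, `valley`.
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_spec(seed = 1, spacing_mm = 2.5))
#' rods <- generate_straight_rods(get_structure(ph, "CTV"), straight_rod_spec())
#' valley <- make_valley(get_structure(ph, "CTV"), rods)
#' plan <- sfrt_plan(ph, rods, valley,
#'                   optimizer_config("SFRT_1", iterations = 60))
#' summary(plan)
#' }
#' @export
sfrt_plan <- function(structures, rods = NULL, valley = NULL,
                      config = optimizer_config(), ctv_name = "CTV") {
  stopifnot(inherits(structures, "structure_set"),
            inherits(config, "optimizer_config"))
  grid <- structures$grid
  ctv <- get_structure(structures, ctv_name)
  strat <- config$strategy
  use_rods <- strat %in% c("SFRT_1", "SFRT_2")
  use_valley <- strat == "SFRT_1"
  if (use_rods) {
    if (is.null(rods) || !inherits(rods, "rod_set") || length(rods$rods) == 0L)
      stop("SFRT strategies require a non-empty rod_set", call. = FALSE)
    if (!same_grid(grid, rods$union$grid))
      stop("rods must live on the structures' grid", call. = FALSE)
  }
  if (use_valley) {
    if (is.null(valley) || !inherits(valley, "structure_mask"))
      stop("the peak-and-valley strategy requires a valley mask", call. = FALSE)
  }

  w <- config$weights
  p <- config$prescription_gy
  ctv_idx <- which(ctv$occupancy)
  rod_idx <- if (use_rods) which(rods$union$occupancy) else integer(0)
  rod_min <- if (use_rods) {
    lv <- rep(config$rod_min_gy, length(rod_idx))
    for (m in rods$rods) {
      rl <- attr(m, "dose_level_gy")
      if (!is.null(rl)) lv[match(which(m$occupancy), rod_idx)] <- rl
    }
    lv
  } else numeric(0)
  val_idx <- if (use_valley) which(valley$occupancy) else integer(0)
  bath_idx <- which(!expand_mask(ctv, 20)$occupancy)
  cov_idx <- if (!is.null(config$coverage_structure))
    which(get_structure(structures, config$coverage_structure)$occupancy)
  else integer(0)

  vox_cm3 <- voxel_volume_cm3(grid)
  n2 <- max(1L, as.integer(round(2 / vox_cm3)))
  oars <- lapply(names(config$oar_limits_gy), function(nm)
    list(name = nm, idx = which(get_structure(structures, nm)$occupancy),
         limit = unname(config$oar_limits_gy[nm])))

  active_w <- w["ctv"] + w["bath"] + w["oar"] +
    (if (use_rods) w["rod"] else 0) + (if (use_valley) w["valley"] else 0) +
    (if (length(cov_idx)) w["coverage"] else 0)
  eta <- config$step_size / (2 * active_w)
  sig <- config$kernel_sigma_mm

  x <- array(0, dim = grid$shape)
  if (config$iterations > 0L)
    x[expand_mask(ctv, 5)$occupancy] <- p

  obj <- numeric(config$iterations)
  best <- list(val = Inf, x = x)
  for (it in seq_len(config$iterations)) {
    D <- gauss_sep(x, grid$spacing_mm, sig)
    g <- array(0, dim = grid$shape)
    f <- 0

    v <- pmax(0, p - D[ctv_idx])
    f <- f + w["ctv"] * sum(v^2)
    g[ctv_idx] <- g[ctv_idx] - 2 * w["ctv"] * v

    if (use_rods) {
      v <- pmax(0, rod_min - D[rod_idx])
      f <- f + w["rod"] * sum(v^2)
      g[rod_idx] <- g[rod_idx] - 2 * w["rod"] * v
    }
    if (use_valley && length(val_idx)) {
      v <- pmax(0, D[val_idx] - config$valley_max_gy)
      f <- f + w["valley"] * sum(v^2)
      g[val_idx] <- g[val_idx] + 2 * w["valley"] * v
    }
    for (o in oars) {
      d_o <- D[o$idx]
      hot <- o$idx[order(d_o, decreasing = TRUE)[seq_len(min(n2, length(d_o)))]]
      v <- pmax(0, D[hot] - o$limit)
      f <- f + w["oar"] * sum(v^2)
      g[hot] <- g[hot] + 2 * w["oar"] * v
    }
    if (length(cov_idx)) {
      v <- pmax(0, p - D[cov_idx])
      f <- f + w["coverage"] * sum(v^2)
      g[cov_idx] <- g[cov_idx] - 2 * w["coverage"] * v
    }
    f <- f + w["bath"] * sum(D[bath_idx]^2)
    g[bath_idx] <- g[bath_idx] + 2 * w["bath"] * D[bath_idx]

    obj[it] <- f / 1e3  # report in kGy^2 for readable traces
    if (f < best$val) best <- list(val = f, x = x)
    x <- pmax(x - eta * gauss_sep(g, grid$spacing_mm, sig), 0)  # keeps dim
  }

  converged <- TRUE
  if (config$iterations >= 20L) {
    tail_n <- max(2L, ceiling(config$iterations * 0.1))
    i0 <- config$iterations - tail_n
    # objective must not have grown over the final 10% of iterations
    converged <- obj[config$iterations] <= obj[i0] * (1 + 1e-9)
    if (!converged) {
      warning(sprintf(
        "optimizer did not decrease the objective over the last %d iterations (best %.4g, final %.4g); returning the best iterate",
        tail_n, best$val / 1e3, obj[config$iterations]))
      x <- best$x
    }
  }

  D <- if (config$iterations > 0L) gauss_sep(x, grid$spacing_mm, sig)
  else array(0, dim = grid$shape)
  structure(list(dose = dose_grid(D, grid), objective = obj,
                 converged = converged, config = config,
                 structures = structures, rods = rods, valley = valley),
            class = "sfrt_plan")
}

#' @export
print.sfrt_plan <- function(x, ...) {
  cat(sprintf("<sfrt_plan> strategy %s, %d iterations%s\n",
              x$config$strategy, x$config$iterations,
              if (x$converged) "" else " (not converged)"))
  print(x$dose)
  invisible(x)
}

#' @export
summary.sfrt_plan <- function(object, ...) {
  ctv <- get_structure(object$structures, "CTV")
  dvh <- compute_dvh(object$dose, ctv)
  out <- list(strategy = object$config$strategy,
              converged = object$converged,
              final_objective = utils::tail(object$objective, 1),
              ctv_d90_gy = dose_at_volume_pct(dvh, 90),
              ctv_v45_pct = volume_pct_at_dose(dvh, 45),
              ctv_v60_pct = volume_pct_at_dose(dvh, 60),
              peak_valley_ratio = if (!is.null(object$rods) &&
                                      !is.null(object$valley) &&
                                      any(object$valley$occupancy))
                mean(object$dose$dose_gy[object$rods$union$occupancy]) /
                  mean(object$dose$dose_gy[object$valley$occupancy])
              else NA_real_)
  class(out) <- "summary.sfrt_plan"
  out
}

#' @export
print.summary.sfrt_plan <- function(x, ...) {
  cat(sprintf("SFRT surrogate plan (%s)%s\n", x$strategy,
              if (x$converged) "" else "  [not converged]"))
  cat(sprintf("  CTV D90%%: %.2f Gy   V45Gy: %.1f%%   V60Gy: %.1f%%\n",
              x$ctv_d90_gy, x$ctv_v45_pct, x$ctv_v60_pct))
  if (is.finite(x$peak_valley_ratio))
    cat(sprintf("  mean peak/valley dose ratio: %.2f\n", x$peak_valley_ratio))
  cat(sprintf("  final objective: %.4g\n", x$final_objective))
  invisible(x)
}

#' @export
plot.sfrt_plan <- function(x, ..., which = c("objective", "dvh")) {
  which <- match.arg(which)
  if (which == "objective") {
    graphics::plot(seq_along(x$objective), x$objective, type = "l", log = "y",
                   xlab = "Iteration", ylab = "Objective", ...)
  } else {
    ctv <- get_structure(x$structures, "CTV")
    plot(compute_dvh(x$dose, ctv), ...)
  }
  invisible(x)
}
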