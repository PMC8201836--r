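# shared, lazily built fixtures (kept across test files within one run)
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# coarse 2.5 mm phantom used by most geometry/optimizer tests
coarse_phantom <- function() fixture("coarse_phantom", function()
  generate_phantom(phantom_spec(seed = 1, spacing_mm = 2.5)))

coarse_rods <- function() fixture("coarse_rods", function()
  generate_straight_rods(get_structure(coarse_phantom(), "CTV"),
                         straight_rod_spec()))

coarse_valley <- function() fixture("coarse_valley", function()
  make_valley(get_structure(coarse_phantom(), "CTV"), coarse_rods()))

coarse_plan <- function(strategy) fixture(paste0("coarse_plan_", strategy), function() {
  ph <- coarse_phantom()
  rods <- if (strategy != "SBRT") coarse_rods() else NULL
  valley <- if (strategy == "SFRT_1") coarse_valley() else NULL
  sfrt_plan(ph, rods, valley, optimizer_config(strategy))
})

# full default-resolution pipeline (1.25 mm, default optimizer), seed 7
default_pipeline <- function(strategy) fixture(paste0("pipe_", strategy), function() {
  t0 <- proc.time()
  res <- run_single_plan(seed = 7, strategy = strategy)
  res$elapsed_s <- unname((proc.time() - t0)["elapsed"])
  res
})

# cuboid target mask centred on the grid
box_target <- function(nvox = c(96, 96, 48), spacing = 1.25) {
  g <- voxel_grid(nvox, spacing, -(nvox - 1) * spacing / 2)
  structure_mask(array(TRUE, g$shape), g, "box")
}

# solid sphere mask (voxel centres within radius of the origin)
sphere_mask <- function(radius_mm, spacing = 1.25, pad_mm = 10) {
  n <- 2 * ceiling((radius_mm + pad_mm) / spacing) + 1
  g <- voxel_grid(rep(n, 3), spacing, rep(-(n - 1) * spacing / 2, 3))
  co <- grid_coords_mm(g)
  structure_mask(co$x^2 + co$y^2 + co$z^2 <= radius_mm^2, g, "sphere")
}

# small synthetic dose + mask pair for DVH tests
random_dose_case <- function(n = c(12, 11, 10), max_gy = 60) {
  g <- voxel_grid(n, 2.5, c(0, 0, 0))
  occ <- array(stats::runif(prod(n)) > 0.4, n)
  if (!any(occ)) occ[1] <- TRUE
  list(dose = dose_grid(array(stats::runif(prod(n), 0, max_gy), n), g),
       mask = structure_mask(occ, g, "s"))
}
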