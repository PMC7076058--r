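# Shared fixtures, built once per test run. The default-phantom solves are
# the expensive pieces; everything downstream reuses them.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

default_phantom <- function() cached("phantom", build_phantom(phantom_spec()))

mini_phantom <- function() cached("mini", build_phantom(mini_phantom_spec()))

analytic_fixtures <- function() cached("fixtures", make_fixtures(0L))

# full seven-configuration pipeline at the default 4 mm spacing
full_run <- function() {
  cached("full_run", run_pipeline(run_config(seed = 1L)))
}

# one solved montage on the mini phantom, for field-level checks
mini_solve <- function(name = "SUPRATENTORIAL") {
  cached(paste0("mini_solve_", name), {
    ph <- mini_phantom()
    rast <- rasterize_electrodes(named_configuration(name, ph$volume),
                                 ph$volume)
    list(phantom = ph, rast = rast, result = solve_montage(rast))
  })
}

# slab with a flat scalp-over-skull surface for electrode-footprint oracles
flat_slab_volume <- function(spacing = 2) {
  g <- voxel_grid(c(41L, 41L, 13L), spacing = spacing,
                  origin = c(-40, -40, 0))
  lab <- array(TISSUE_LABELS[["BRAIN"]], dim = g$shape)
  lab[, , 8:9] <- TISSUE_LABELS[["SKULL"]]
  lab[, , 10] <- TISSUE_LABELS[["SCALP"]]
  lab[, , 11:13] <- TISSUE_LABELS[["AIR"]]
  label_volume(lab, g)
}

random_field <- function(dims, seed) {
  set.seed(seed)
  array(stats::runif(prod(dims), 0, 100), dim = dims)
}

full_mask <- function(dims) {
  roi_mask(array(TRUE, dim = dims), voxel_grid(dims), "all")
}
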