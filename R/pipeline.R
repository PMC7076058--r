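#' Pipeline run configuration
#'
#' Declarative description of a full planning run: which phantom (or
#' which NIfTI label volume), which montages, solver settings, output
#' directory and the global seed (the only stochastic input, used for
#' optional phantom surface jitter).
#'
#' @param phantom a [phantom_spec()], or a path to a NIfTI label volume.
#' @param configurations montage names to run (subset of
#'   [CONFIGURATION_NAMES]).
#' @param settings a [solve_settings()].
#' @param layout_params overrides passed to [named_configuration()].
#' @param conductivity a [conductivity_table()].
#' @param out_dir output directory; `NULL` keeps everything in memory.
#' @param seed global seed threaded into the phantom spec.
#' @param write_fields write per-channel and combined NIfTI magnitude
#'   volumes (slower, larger outputs).
#' @return Object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(),
                       configurations = CONFIGURATION_NAMES,
                       settings = solve_settings(),
                       layout_params = list(),
                       conductivity = conductivity_table(),
                       out_dir = NULL, seed = 1L,
                       write_fields = FALSE) {
  if (!length(configurations))
    stop("at least one configuration is required")
  bad <- setdiff(configurations, CONFIGURATION_NAMES)
  if (length(bad))
    stop("unknown configuration(s): ", paste(bad, collapse = ", "))
  if (inherits(phantom, "phantom_spec")) phantom$seed <- as.integer(seed)
  structure(list(phantom = phantom, configurations = configurations,
                 settings = settings, layout_params = layout_params,
                 conductivity = conductivity, out_dir = out_dir,
                 seed = as.integer(seed), write_fields = write_fields),
            class = "run_config")
}

config_hash <- function(config) {
  # FNV-1a over the JSON serialization; stable fingerprint for manifests
  js <- jsonlite::serializeJSON(config[setdiff(names(config), "out_dir")])
  bytes <- utf8ToInt(as.character(js))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full planning pipeline
#'
#' phantom -> array layouts -> per-channel volume-conductor solves ->
#' EVH/CDVH and plan-quality metrics over the GTV and cerebellum ->
#' cross-configuration comparison report. With an output directory set,
#' writes per-configuration layout JSON, EVH/CDVH CSVs, the PQM table,
#' the report, optional NIfTI field volumes, and a manifest with the
#' config hash and seed.
#'
#' @param config a [run_config()].
#' @return list with `report` (a [build_report()] result when more than
#'   one configuration ran, else `NULL`), `records` (PQM rows), `phantom`
#'   and per-configuration `runs` (layout, channel summaries, GTV/cereb
#'   mean fields).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)

  ph <- if (inherits(config$phantom, "phantom_spec")) {
    build_phantom(config$phantom)
  } else {
    vol <- read_label_volume(config$phantom)
    gtv_m <- array(vol$labels %in% TISSUE_LABELS[c("GTV", "NECROTIC_CORE")],
                   dim = vol$grid$shape)
    cer_m <- array(vol$labels == TISSUE_LABELS[["CEREBELLUM"]],
                   dim = vol$grid$shape)
    list(volume = vol, gtv = roi_mask(gtv_m, vol$grid, "GTV"),
         cerebellum = roi_mask(cer_m, vol$grid, "CEREBELLUM"), spec = NULL)
  }
  if (ph$gtv$n_voxels == 0L) stop("stage phantom: GTV mask is empty")

  records <- list(); runs <- list()
  for (nm in config$configurations) {
    res <- tryCatch({
      lay <- named_configuration(nm, ph$volume, config$layout_params)
      rast <- rasterize_electrodes(lay, ph$volume)
      sol <- solve_montage(rast, config$conductivity, config$settings)
      E <- sol$E_combined; J <- sol$J_combined
      if (config$settings$combine == "per_channel") {
        E <- (sol$E_combined[[1]] + sol$E_combined[[2]]) / 2
        J <- (sol$J_combined[[1]] + sol$J_combined[[2]]) / 2
      }
      rec <- rbind(pqm(E, J, ph$gtv, nm), pqm(E, J, ph$cerebellum, nm))
      if (!is.null(out)) {
        write_layout(lay, file.path(out, paste0("layout_", nm, ".json")))
        for (roi in list(ph$gtv, ph$cerebellum)) {
          write_evh(compute_evh(E, roi, quantity = "E"),
                    file.path(out, sprintf("evh_%s_%s.csv", nm, roi$name)))
          write_evh(compute_evh(J, roi, quantity = "CD"),
                    file.path(out, sprintf("cdvh_%s_%s.csv", nm, roi$name)))
        }
        if (isTRUE(config$write_fields)) {
          write_field(E, ph$volume$grid,
                      file.path(out, paste0("E_", nm, ".nii.gz")))
          write_field(J, ph$volume$grid,
                      file.path(out, paste0("J_", nm, ".nii.gz")))
          for (ch in names(sol$solutions))
            write_field(sol$solutions[[ch]]$E_mag, ph$volume$grid,
                        file.path(out, sprintf("E_%s_%s.nii.gz", nm, ch)))
        }
      }
      list(record = rec, layout = lay,
           gtv_mean_E = mean(E[ph$gtv$mask]),
           cerebellum_mean_E = mean(E[ph$cerebellum$mask]),
           channels = lapply(sol$solutions, function(s)
             list(iterations = s$iterations, residual = s$residual,
                  applied_potential = s$applied_potential,
                  current_balance = s$current_balance)))
    }, error = function(e) {
      stop("stage ", nm, ": ", conditionMessage(e), call. = FALSE)
    })
    records[[nm]] <- res$record
    runs[[nm]] <- res[setdiff(names(res), "record")]
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL

  report <- NULL
  if ("SUPRATENTORIAL" %in% config$configurations &&
      length(config$configurations) > 1L)
    report <- build_report(records, "SUPRATENTORIAL")

  if (!is.null(out)) {
    utils::write.csv(records, file.path(out, "pqm_records.csv"),
                     row.names = FALSE)
    if (!is.null(report)) write_report(report, out)
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("ttfplan")),
           config_hash = config_hash(config), seed = config$seed,
           configurations = config$configurations,
           spacing_mm = ph$volume$grid$spacing),
      file.path(out, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  list(report = report, records = records, phantom = ph, runs = runs)
}

#' Build the analytic and miniature test volumes
#'
#' Deterministic per seed: a homogeneous slab (parallel-plate analytic
#' case), a two-layer slab (series-conductor case), and a small head
#' phantom. Used by the test suite and for quick demonstrations.
#'
#' @param seed integer seed (threads into the mini phantom spec).
#' @return list with `slab` (sigma, grid, anode, cathode, conductivity),
#'   `two_layer` (adds `sigma1`, `sigma2`, interface index) and
#'   `mini_phantom` (a [build_phantom()] result).
#' @export
make_fixtures <- function(seed = 0L) {
  slab_grid <- voxel_grid(c(21L, 8L, 8L), spacing = 5)
  slab_sigma <- array(0.25, dim = slab_grid$shape)
  slab <- list(grid = slab_grid, sigma = slab_sigma, conductivity = 0.25,
               anode = slice_index(slab_grid$shape, 1L, 1L, 1L),
               cathode = slice_index(slab_grid$shape, 1L, 21L, 21L))

  tl_sigma <- array(0.2, dim = slab_grid$shape)
  tl_sigma[12:21, , ] <- 0.1  # sigma1 = 2 * sigma2
  two_layer <- list(grid = slab_grid, sigma = tl_sigma,
                    sigma1 = 0.2, sigma2 = 0.1, interface = 12L,
                    anode = slab$anode, cathode = slab$cathode)

  list(slab = slab, two_layer = two_layer,
       mini_phantom = build_phantom(mini_phantom_spec(seed = seed)))
}
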