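#' Synthetic head phantom specification
#'
#' Parameters of the synthetic voxelized head: nested ellipsoidal shells
#' (scalp, skull, CSF, brain) centered at the world origin, a
#' posterior-inferior cerebellar compartment holding a spherical gross
#' tumor volume (GTV) with optional concentric necrotic core, a brainstem
#' column, and a neck cylinder (scalp rind, muscle, vertebral column)
#' extending below the skull base. All lengths in mm.
#'
#' The default GTV sits dorsally on the midline of the posterior fossa.
#' Shell semi-axes must be strictly nested (scalp > skull > CSF > brain)
#' and the skull shell must remain at least two voxels thick at the
#' requested spacing.
#'
#' @param spacing isotropic voxel size, mm.
#' @param scalp_axes,skull_axes,csf_axes,brain_axes semi-axes (x, y, z) of
#'   the outer surface of each shell, mm.
#' @param cerebellum_center,cerebellum_axes center and semi-axes of the
#'   cerebellar sub-ellipsoid (intersected with the brain compartment).
#' @param brainstem_center_xy,brainstem_radius,brainstem_z x/y center,
#'   radius and z extent of the brainstem column.
#' @param gtv_center,gtv_radius GTV sphere; radius 0 gives an empty GTV.
#' @param necrotic_radius concentric necrotic core radius (<= gtv_radius).
#' @param neck_center_xy,neck_radius,neck_z neck cylinder axis (x, y),
#'   outer radius, and z extent (top, bottom).
#' @param neck_scalp_thickness outer scalp rind of the neck, mm.
#' @param vertebra_center_xy,vertebra_radius vertebral column within the neck.
#' @param margin air margin around the anatomy, mm.
#' @param jitter_mm standard deviation of a random offset applied to the
#'   shell centers (breaks left/right symmetry); 0 keeps the phantom
#'   exactly symmetric about the midsagittal plane.
#' @param seed integer seed for the jitter draw.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(spacing = 4,
                         scalp_axes = c(80, 96, 90),
                         skull_axes = c(74, 90, 84),
                         csf_axes = c(65, 81, 75),
                         brain_axes = c(60, 76, 70),
                         cerebellum_center = c(0, -40, -38),
                         cerebellum_axes = c(48, 34, 28),
                         brainstem_center_xy = c(0, -10),
                         brainstem_radius = 10,
                         brainstem_z = c(-70, -25),
                         gtv_center = c(0, -50, -35),
                         gtv_radius = 12,
                         necrotic_radius = 4,
                         neck_center_xy = c(0, -15),
                         neck_radius = 44,
                         neck_z = c(-175, -50),
                         neck_scalp_thickness = 5,
                         vertebra_center_xy = c(0, -30),
                         vertebra_radius = 13,
                         margin = 8,
                         jitter_mm = 0,
                         seed = 1L) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  ax <- rbind(spec$scalp_axes, spec$skull_axes, spec$csf_axes, spec$brain_axes)
  if (any(diff(ax) >= 0) || any(ax <= 0))
    stop("shell semi-axes must be positive and strictly nested: ",
         "scalp > skull > CSF > brain on every axis")
  if (spec$gtv_radius < 0 || spec$necrotic_radius < 0)
    stop("radii must be non-negative")
  if (spec$necrotic_radius > spec$gtv_radius)
    stop("necrotic core radius must not exceed GTV radius")
  skull_thickness <- min(spec$skull_axes - spec$csf_axes)
  if (skull_thickness < 2 * spec$spacing)
    stop(sprintf(paste0("grid too coarse: skull shell is %.1f mm thick but ",
                        "needs >= 2 voxels (%.1f mm) at %.1f mm spacing"),
                 skull_thickness, 2 * spec$spacing, spec$spacing))
  invisible(spec)
}

in_ellipsoid <- function(x, y, z, center, axes) {
  ((x - center[1]) / axes[1])^2 + ((y - center[2]) / axes[2])^2 +
    ((z - center[3]) / axes[3])^2 <= 1
}

#' Build a synthetic head phantom
#'
#' Rasterizes a [phantom_spec()] onto a regular voxel grid: nested
#' ellipsoid shells, cerebellum with GTV and optional necrotic core,
#' brainstem, and a neck cylinder carrying muscle, vertebral bone and a
#' scalp rind so that scalp covers the whole external surface. The output
#' is deterministic given the spec (including its seed).
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [label_volume()]), `gtv` and `cerebellum`
#'   ([roi_mask()]; the GTV mask includes any necrotic core), and `spec`.
#' @examples
#' ph <- build_phantom(phantom_spec(spacing = 6))
#' ph$gtv$n_voxels > 0
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)

  centers <- list(shell = c(0, 0, 0))
  if (spec$jitter_mm > 0) {
    rng <- local({ set.seed(spec$seed); stats::rnorm(3, 0, spec$jitter_mm) })
    centers$shell <- rng
  }

  # GTV must lie inside the cranial cavity (brain compartment)
  if (spec$gtv_radius > 0) {
    gc <- spec$gtv_center - centers$shell
    if (!in_ellipsoid(gc[1], gc[2], gc[3], c(0, 0, 0),
                      spec$brain_axes - spec$gtv_radius))
      stop("geometry error: GTV sphere extends outside the brain compartment")
  }

  sh0 <- centers$shell
  ext_lo <- c(min(-spec$scalp_axes[1] + sh0[1],
                  spec$neck_center_xy[1] - spec$neck_radius),
              min(-spec$scalp_axes[2] + sh0[2],
                  spec$neck_center_xy[2] - spec$neck_radius),
              spec$neck_z[1]) - spec$margin
  ext_hi <- c(max(spec$scalp_axes[1] + sh0[1],
                  spec$neck_center_xy[1] + spec$neck_radius),
              max(spec$scalp_axes[2] + sh0[2],
                  spec$neck_center_xy[2] + spec$neck_radius),
              spec$scalp_axes[3] + sh0[3]) + spec$margin
  # snap the origin so that x = 0 is a voxel-center plane (keeps a
  # symmetric spec exactly mirror-symmetric on the lattice)
  h <- spec$spacing
  origin <- floor(ext_lo / h) * h
  shape <- ceiling((ext_hi - origin) / h) + 1
  grid <- voxel_grid(shape, spacing = h, origin = origin)

  cc <- axis_coords(grid)
  x <- cc[[1]]; y <- cc[[2]]; z <- cc[[3]]
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  X <- array(x, dim = grid$shape)
  Y <- array(rep(y, each = nx), dim = grid$shape)
  Z <- array(rep(z, each = nx * ny), dim = grid$shape)

  lab <- array(TISSUE_LABELS[["AIR"]], dim = grid$shape)
  sh <- centers$shell
  for (layer in list(list(spec$scalp_axes, "SCALP"),
                     list(spec$skull_axes, "SKULL"),
                     list(spec$csf_axes, "CSF"),
                     list(spec$brain_axes, "BRAIN"))) {
    inside <- in_ellipsoid(X, Y, Z, sh, layer[[1]])
    lab[inside] <- TISSUE_LABELS[[layer[[2]]]]
  }

  brain <- lab == TISSUE_LABELS[["BRAIN"]]
  cereb <- brain & in_ellipsoid(X, Y, Z, spec$cerebellum_center + sh,
                                spec$cerebellum_axes)
  lab[cereb] <- TISSUE_LABELS[["CEREBELLUM"]]

  bs <- brain & !cereb &
    (X - spec$brainstem_center_xy[1] - sh[1])^2 +
    (Y - spec$brainstem_center_xy[2] - sh[2])^2 <= spec$brainstem_radius^2 &
    Z >= spec$brainstem_z[1] & Z <= spec$brainstem_z[2]
  lab[bs] <- TISSUE_LABELS[["BRAINSTEM"]]

  if (spec$gtv_radius > 0) {
    gc <- spec$gtv_center + sh * 0  # GTV is specified in world coordinates
    r2 <- (X - gc[1])^2 + (Y - gc[2])^2 + (Z - gc[3])^2
    gtv_vox <- r2 <= spec$gtv_radius^2
    lab[gtv_vox] <- TISSUE_LABELS[["GTV"]]
    if (spec$necrotic_radius > 0)
      lab[r2 <= spec$necrotic_radius^2] <- TISSUE_LABELS[["NECROTIC_CORE"]]
  } else {
    warning("GTV radius is 0: phantom has an empty tumor mask")
  }

  # neck: fill remaining AIR below the neck top with a scalp-rinded
  # muscle cylinder and a vertebral column
  air <- lab == TISSUE_LABELS[["AIR"]]
  rho2 <- (X - spec$neck_center_xy[1])^2 + (Y - spec$neck_center_xy[2])^2
  in_neck <- air & Z >= spec$neck_z[1] & Z <= spec$neck_z[2] &
    rho2 <= spec$neck_radius^2
  inner_r <- spec$neck_radius - spec$neck_scalp_thickness
  lab[in_neck] <- ifelse(rho2[in_neck] <= inner_r^2,
                         TISSUE_LABELS[["MUSCLE"]], TISSUE_LABELS[["SCALP"]])
  vert <- lab == TISSUE_LABELS[["MUSCLE"]] &
    (X - spec$vertebra_center_xy[1])^2 +
    (Y - spec$vertebra_center_xy[2])^2 <= spec$vertebra_radius^2
  lab[vert] <- TISSUE_LABELS[["VERTEBRA"]]

  vol <- label_volume(lab, grid)
  gtv_mask <- lab == TISSUE_LABELS[["GTV"]] |
    lab == TISSUE_LABELS[["NECROTIC_CORE"]]
  list(volume = vol,
       gtv = roi_mask(gtv_mask, grid, "GTV"),
       cerebellum = roi_mask(lab == TISSUE_LABELS[["CEREBELLUM"]], grid,
                             "CEREBELLUM"),
       spec = spec)
}

#' Compact phantom for fast tests and examples
#'
#' A smaller head (thicker shells so coarse grids stay valid) with the
#' same posterior-fossa tumor topology as the default phantom.
#' @param spacing voxel size, mm.
#' @param ... passed on to [phantom_spec()].
#' @export
mini_phantom_spec <- function(spacing = 6, ...) {
  args <- list(spacing = spacing,
               scalp_axes = c(75, 90, 82),
               skull_axes = c(69, 84, 76),
               csf_axes = c(56, 71, 63),
               brain_axes = c(51, 66, 58),
               cerebellum_center = c(0, -35, -32),
               cerebellum_axes = c(40, 29, 24),
               gtv_center = c(0, -43, -30),
               gtv_radius = 10,
               necrotic_radius = 3,
               neck_z = c(-150, -45))
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}
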