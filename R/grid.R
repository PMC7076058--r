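#' Regular voxel grid geometry
#'
#' A `voxel_grid` describes a regular 3-D lattice in RAS world coordinates
#' (x increases to the patient's right, y to anterior, z to superior).
#' Voxel indices are 0-based; the world coordinate of voxel `(i, j, k)` is
#' `origin + c(i, j, k) * spacing`, i.e. `origin` is the *center* of voxel
#' `(0, 0, 0)`.
#'
#' @param shape integer length-3 vector, number of voxels per axis.
#' @param spacing numeric voxel size in mm; scalar (isotropic) or length 3.
#' @param origin world coordinate (mm) of the center of voxel `(0,0,0)`.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(10, 10, 5), spacing = 2, origin = c(-9, -9, -4))
#' voxel_to_world(g, c(0, 0, 0))
#' @export
voxel_grid <- function(shape, spacing = 1, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be three integers >= 1")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be positive (scalar or length 3)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be a finite length-3 numeric")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm, RAS axes, voxel-center convention\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Number of voxels in a grid
#' @param grid a [voxel_grid()].
#' @return integer count `nx * ny * nz`.
#' @export
n_voxels <- function(grid) prod(grid$shape)

#' Volume of one voxel in mm^3
#' @param grid a [voxel_grid()].
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Convert 0-based voxel indices to world coordinates (mm)
#'
#' @param grid a [voxel_grid()].
#' @param ijk 0-based indices: length-3 vector or n x 3 matrix.
#' @return world coordinates, same shape as `ijk`.
#' @export
voxel_to_world <- function(grid, ijk) {
  if (is.matrix(ijk))
    sweep(sweep(ijk, 2L, grid$spacing, "*"), 2L, grid$origin, "+")
  else
    grid$origin + ijk * grid$spacing
}

#' Convert world coordinates (mm) to continuous 0-based voxel indices
#'
#' Exact inverse of [voxel_to_world()]; use [world_to_nearest_voxel()] to
#' snap to lattice points.
#' @param grid a [voxel_grid()].
#' @param xyz world coordinates: length-3 vector or n x 3 matrix.
#' @export
world_to_voxel <- function(grid, xyz) {
  if (is.matrix(xyz))
    sweep(sweep(xyz, 2L, grid$origin, "-"), 2L, grid$spacing, "/")
  else
    (xyz - grid$origin) / grid$spacing
}

#' @rdname world_to_voxel
#' @export
world_to_nearest_voxel <- function(grid, xyz) {
  ijk <- round(world_to_voxel(grid, xyz))
  if (is.matrix(ijk)) storage.mode(ijk) <- "integer" else ijk <- as.integer(ijk)
  ijk
}

#' Test whether 0-based voxel indices fall inside the grid
#' @param grid a [voxel_grid()].
#' @param ijk length-3 vector or n x 3 matrix of 0-based indices.
#' @return logical vector.
#' @export
in_grid <- function(grid, ijk) {
  if (!is.matrix(ijk)) ijk <- matrix(ijk, ncol = 3L)
  ijk[, 1] >= 0L & ijk[, 1] < grid$shape[1] &
    ijk[, 2] >= 0L & ijk[, 2] < grid$shape[2] &
    ijk[, 3] >= 0L & ijk[, 3] < grid$shape[3]
}

#' World coordinates of every voxel center along each axis
#' @param grid a [voxel_grid()].
#' @return list of three numeric vectors (x, y, z voxel-center coordinates).
#' @export
axis_coords <- function(grid) {
  lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a])
}

#' Compare two grids for equality within floating-point tolerance
#' @param a,b [voxel_grid()] objects.
#' @param tol absolute tolerance on spacing and origin, mm.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}
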