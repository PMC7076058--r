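#' Tissue label vocabulary
#'
#' Fixed integer codes for the tissue classes a head model may contain.
#' AIR (code 0) is outside the conductive domain. GEL and ELECTRODE are
#' added by electrode rasterization, not by the phantom generator.
#'
#' @format Named integer vector.
#' @export
TISSUE_LABELS <- c(
  AIR           = 0L,
  SCALP         = 1L,
  SKULL         = 2L,
  CSF           = 3L,
  BRAIN         = 4L,
  CEREBELLUM    = 5L,
  BRAINSTEM     = 6L,
  MUSCLE        = 7L,
  VERTEBRA      = 8L,
  GTV           = 9L,
  NECROTIC_CORE = 10L,
  GEL           = 11L,
  ELECTRODE     = 12L
)

#' Label name lookup
#' @param code integer label code(s).
#' @return character label name(s).
#' @export
label_name <- function(code) {
  names(TISSUE_LABELS)[match(code, TISSUE_LABELS)]
}

#' Labeled tissue volume
#'
#' Couples an integer label array with its [voxel_grid()]. Every voxel
#' carries exactly one label from [TISSUE_LABELS].
#'
#' @param labels integer 3-D array with `dim == grid$shape`.
#' @param grid a [voxel_grid()].
#' @return Object of class `label_volume` with elements `labels` and `grid`.
#' @export
label_volume <- function(labels, grid) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3-D array")
  if (!identical(as.integer(dim(labels)), grid$shape))
    stop("label array dimensions do not match grid shape")
  if (any(is.na(labels))) stop("labels must not contain NA")
  storage.mode(labels) <- "integer"
  unknown <- setdiff(unique(as.vector(labels)), unname(TISSUE_LABELS))
  if (length(unknown))
    stop("unknown label code(s): ", paste(unknown, collapse = ", "))
  structure(list(labels = labels, grid = grid), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume\n")
  print(x$grid)
  tab <- table(factor(label_name(x$labels), levels = names(TISSUE_LABELS)))
  tab <- tab[tab > 0]
  cat("  voxels per label:\n")
  for (nm in names(tab)) cat(sprintf("    %-13s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Region-of-interest mask on a voxel grid
#'
#' @param mask logical 3-D array, `TRUE` for member voxels.
#' @param grid the parent [voxel_grid()].
#' @param name ROI name (e.g. "GTV", "CEREBELLUM").
#' @return Object of class `roi_mask` with `mask`, `grid`, `name`,
#'   `voxel_volume` (mm^3) and `n_voxels`.
#' @export
roi_mask <- function(mask, grid, name = "custom") {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("'mask' must be a 3-D array")
  if (!identical(as.integer(dim(mask)), grid$shape))
    stop("mask dimensions do not match grid shape")
  mask <- array(as.logical(mask), dim = grid$shape)
  if (any(is.na(mask))) stop("mask must not contain NA")
  structure(list(mask = mask, grid = grid, name = name,
                 voxel_volume = voxel_volume(grid),
                 n_voxels = sum(mask)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask '%s': %d voxels, %.1f cm^3\n", x$name, x$n_voxels,
              x$n_voxels * x$voxel_volume / 1000))
  invisible(x)
}

#' Conductivity table
#'
#' Maps tissue labels to electrical conductivity at 200 kHz. The defaults
#' are literature-typical values for low-frequency head modelling; they are
#' configurable because measured tumor conductivities are not available.
#' AIR is excluded from the solve domain and carries no conductivity.
#'
#' @param values named numeric vector (S/m) overriding any subset of the
#'   defaults; names must be tissue label names.
#' @return Object of class `conductivity_table`: named numeric vector S/m.
#' @examples
#' tab <- conductivity_table(c(GTV = 0.3))
#' tab[["GTV"]]
#' @export
conductivity_table <- function(values = NULL) {
  defaults <- c(
    SCALP = 0.465, SKULL = 0.010, CSF = 1.654, BRAIN = 0.276,
    CEREBELLUM = 0.276, BRAINSTEM = 0.276, MUSCLE = 0.355,
    VERTEBRA = 0.010, GTV = 0.24, NECROTIC_CORE = 1.0,
    GEL = 4.0, ELECTRODE = 1e4
  )
  if (!is.null(values)) {
    if (is.null(names(values)) || any(!nzchar(names(values))))
      stop("'values' must be a named numeric vector")
    bad <- setdiff(names(values), c(names(defaults), "AIR"))
    if (length(bad))
      stop("unknown tissue name(s): ", paste(bad, collapse = ", "))
    if ("AIR" %in% names(values))
      stop("AIR is outside the conductive domain and has no conductivity")
    defaults[names(values)] <- as.numeric(values)
  }
  if (any(!is.finite(defaults)) || any(defaults <= 0))
    stop("all conductivities must be finite and > 0")
  structure(defaults, class = "conductivity_table")
}

#' Assign per-voxel conductivity from a label volume
#'
#' Voxelwise lookup of `table` over `volume$labels`. AIR voxels receive
#' `NA`, marking them as excluded from the solve domain.
#'
#' @param volume a [label_volume()].
#' @param table a [conductivity_table()].
#' @return numeric 3-D array of conductivities (S/m), `NA` in AIR.
#' @export
assign_conductivity <- function(volume, table = conductivity_table()) {
  stopifnot(inherits(volume, "label_volume"))
  present <- setdiff(unique(as.vector(volume$labels)), TISSUE_LABELS[["AIR"]])
  missing <- setdiff(label_name(present), names(table))
  if (length(missing))
    stop("conductivity table has no entry for label(s): ",
         paste(missing, collapse = ", "))
  lut <- rep(NA_real_, max(TISSUE_LABELS) + 1L)
  lut[TISSUE_LABELS[names(table)] + 1L] <- as.numeric(table)
  sigma <- array(lut[volume$labels + 1L], dim = volume$grid$shape)
  sigma[volume$labels == TISSUE_LABELS[["AIR"]]] <- NA_real_
  sigma
}
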