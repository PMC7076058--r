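#' Field-volume histogram (EVH / CDVH)
#'
#' For a scalar magnitude field and an ROI, the curve of ROI volume
#' fraction at or above each threshold — the TTFields analogue of a
#' radiotherapy dose-volume histogram. Counting is exact ("at or above",
#' closed threshold convention) with equal voxel weights.
#'
#' @param field numeric 3-D array of magnitudes (V/m or A/m^2).
#' @param mask a [roi_mask()] on the same grid.
#' @param thresholds ascending threshold grid starting at 0; default a
#'   uniform 2048-point grid from 0 to the ROI maximum.
#' @param quantity tag stored on the curve (`"E"` or `"CD"`).
#' @return Object of class `evh_curve`: data frame `curve` with columns
#'   `threshold` and `fraction`, plus `roi` and `quantity`.
#' @export
compute_evh <- function(field, mask, thresholds = NULL,
                        quantity = c("E", "CD")) {
  quantity <- match.arg(quantity)
  vals <- roi_values(field, mask)
  if (is.null(thresholds)) {
    top <- max(vals)
    if (top <= 0) top <- 1
    thresholds <- seq(0, top, length.out = 2048L)
  }
  if (is.unsorted(thresholds, strictly = FALSE))
    stop("thresholds must be ascending")
  if (thresholds[1] != 0) stop("thresholds must start at 0")
  sv <- sort(vals)
  n <- length(sv)
  # voxels with value >= t == n - (number of values < t)
  below <- findInterval(thresholds, sv, left.open = TRUE)
  frac <- (n - below) / n
  structure(list(curve = data.frame(threshold = thresholds, fraction = frac),
                 roi = mask$name, quantity = quantity, n_voxels = n),
            class = "evh_curve")
}

roi_values <- function(field, mask) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!identical(dim(field), dim(mask$mask)))
    stop("field and mask dimensions differ")
  if (mask$n_voxels == 0L) stop("empty ROI mask")
  vals <- field[mask$mask]
  if (any(is.na(vals))) stop("field contains NA inside the ROI")
  vals
}

#' @export
print.evh_curve <- function(x, ...) {
  cat(sprintf("evh_curve (%s, ROI '%s'): %d thresholds over [0, %.3g], %d voxels\n",
              x$quantity, x$roi, nrow(x$curve), max(x$curve$threshold),
              x$n_voxels))
  invisible(x)
}

#' Area under a field-volume histogram
#'
#' With fractional volume on the y-axis the area under the EVH equals the
#' ROI mean magnitude as the threshold grid refines (layer-cake identity).
#' `"trapezoid"` integrates the sampled curve; `"exact"` evaluates the
#' layer-cake integral of the right-continuous counting curve exactly and
#' should be used with per-unique-value thresholds.
#'
#' @param curve an [compute_evh()] result.
#' @param method integration rule.
#' @return area in threshold units (V/m or A/m^2).
#' @export
evh_auc <- function(curve, method = c("trapezoid", "exact")) {
  method <- match.arg(method)
  t <- curve$curve$threshold
  f <- curve$curve$fraction
  dt <- diff(t)
  switch(method,
         trapezoid = sum(dt * (f[-1] + f[-length(f)]) / 2),
         exact = sum(dt * f[-1]))
}

#' Intensity covering the hottest x% of an ROI
#'
#' The largest threshold `t` such that at least `x_percent` of the ROI
#' volume has magnitude `>= t`. `x = 50` gives the median intensity,
#' `x = 5` the hotspot intensity, `x = 75` the value exceeded by
#' three-quarters of the volume.
#'
#' @param field numeric 3-D magnitude array.
#' @param mask a [roi_mask()].
#' @param x_percent percentage of the ROI volume, in (0, 100).
#' @return intensity in field units.
#' @export
intensity_percentile <- function(field, mask, x_percent) {
  if (x_percent <= 0 || x_percent >= 100)
    stop("x_percent must be strictly between 0 and 100")
  vals <- roi_values(field, mask)
  k <- ceiling(x_percent / 100 * length(vals))
  sort(vals, decreasing = TRUE)[k]
}

#' Percent ROI volume at or above a threshold
#'
#' @param field numeric 3-D magnitude array.
#' @param mask a [roi_mask()].
#' @param t threshold, field units (>= 0).
#' @return percent of ROI voxels with magnitude `>= t`.
#' @export
volume_at_threshold <- function(field, mask, t) {
  if (t < 0) stop("threshold must be >= 0")
  vals <- roi_values(field, mask)
  100 * mean(vals >= t)
}

#' Plan-quality metrics for one configuration and ROI
#'
#' Summarizes an electric-field magnitude map and a current-density
#' magnitude map over an ROI: field-volume AUCs, volumes at fixed
#' thresholds (E at 75/50/25 V/m, CD at 15/10/5 A/m^2) and percentile
#' intensities (hottest 75/50/5% of the ROI volume).
#'
#' @param e_field electric-field magnitude array, V/m.
#' @param cd_field current-density magnitude array, A/m^2.
#' @param mask a [roi_mask()].
#' @param configuration configuration name recorded in the row.
#' @param auc_thresholds number of thresholds for the AUC integration.
#' @return one-row data frame of class `pqm_record` with columns `roi`,
#'   `configuration`, `e_auc`, `v_e75`, `v_e50`, `v_e25`, `e_75`, `e_50`,
#'   `e_5`, `cd_auc`, `v_cd15`, `v_cd10`, `v_cd5`, `cd_75`, `cd_50`,
#'   `cd_5`.
#' @export
pqm <- function(e_field, cd_field, mask, configuration = "configuration",
                auc_thresholds = 2048L) {
  rec <- data.frame(
    roi = mask$name, configuration = configuration,
    e_auc = evh_auc(compute_evh(e_field, mask, quantity = "E")),
    v_e75 = volume_at_threshold(e_field, mask, 75),
    v_e50 = volume_at_threshold(e_field, mask, 50),
    v_e25 = volume_at_threshold(e_field, mask, 25),
    e_75 = intensity_percentile(e_field, mask, 75),
    e_50 = intensity_percentile(e_field, mask, 50),
    e_5 = intensity_percentile(e_field, mask, 5),
    cd_auc = evh_auc(compute_evh(cd_field, mask, quantity = "CD")),
    v_cd15 = volume_at_threshold(cd_field, mask, 15),
    v_cd10 = volume_at_threshold(cd_field, mask, 10),
    v_cd5 = volume_at_threshold(cd_field, mask, 5),
    cd_75 = intensity_percentile(cd_field, mask, 75),
    cd_50 = intensity_percentile(cd_field, mask, 50),
    cd_5 = intensity_percentile(cd_field, mask, 5),
    stringsAsFactors = FALSE
  )
  stopifnot(rec$e_75 <= rec$e_50, rec$e_50 <= rec$e_5,
            rec$cd_75 <= rec$cd_50, rec$cd_50 <= rec$cd_5,
            rec$v_e75 <= rec$v_e50, rec$v_e50 <= rec$v_e25)
  class(rec) <- c("pqm_record", class(rec))
  rec
}

#' Export an EVH/CDVH curve to CSV
#' @param curve an [compute_evh()] result.
#' @param path output CSV path.
#' @export
write_evh <- function(curve, path) {
  utils::write.csv(curve$curve, path, row.names = FALSE)
  invisible(path)
}
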