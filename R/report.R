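PQM_METRICS <- c("e_auc", "v_e75", "v_e50", "v_e25", "e_75", "e_50", "e_5",
                 "cd_auc", "v_cd15", "v_cd10", "v_cd5", "cd_75", "cd_50",
                 "cd_5")

#' Round half away from zero to a number of decimals
#'
#' Reported plan-quality metrics use one-decimal half-up rounding (the
#' convention of printed planning tables), unlike base R's half-to-even.
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percent change of a value against a baseline
#'
#' `100 * (value - baseline) / baseline`, reported to one decimal
#' (half-up). Note that percent changes recomputed from already-rounded
#' table entries can drift a few tenths of a percent from values derived
#' from unrounded internals; [build_report()] flags differences of at
#' most 0.3 as rounding-consistent.
#'
#' @param value,baseline_value numeric; `baseline_value` must be > 0.
#' @return percent change, one decimal.
#' @export
percent_change <- function(value, baseline_value) {
  if (any(baseline_value <= 0)) stop("baseline value must be > 0")
  round_half_up(100 * (value - baseline_value) / baseline_value, 1)
}

#' Mean of one metric over the alternative configurations
#'
#' Arithmetic mean of the named metric across the records flagged as
#' alternatives (every configuration except the baseline), reported to
#' one decimal.
#'
#' @param records data frame of [pqm()] rows (single ROI).
#' @param metric one of the PQM column names (e.g. `"e_auc"`).
#' @param baseline configuration name excluded from the mean.
#' @return one-decimal mean.
#' @export
aggregate_alternatives <- function(records, metric,
                                   baseline = "SUPRATENTORIAL") {
  if (!metric %in% names(records))
    stop("unknown metric '", metric, "'; expected one of: ",
         paste(PQM_METRICS, collapse = ", "))
  alt <- records[records$configuration != baseline, metric]
  if (!length(alt)) stop("no alternative configurations in 'records'")
  round_half_up(mean(alt), 1)
}

#' Load the bundled worked-example PQM table
#'
#' Plan-quality metrics for the seven montages of a single posterior-fossa
#' planning case (GTV and cerebellum ROIs), bundled to demonstrate the
#' report module's comparison arithmetic on realistic numbers.
#' @return data frame with one row per (ROI, configuration).
#' @export
reference_pqm <- function() {
  path <- system.file("extdata", "reference_pqm.csv", package = "ttfplan")
  if (path == "") path <- file.path("inst", "extdata", "reference_pqm.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Cross-configuration comparison report
#'
#' Assembles, per ROI: the PQM table, percent changes of every metric
#' against the baseline configuration, the arithmetic-mean row over the
#' alternative configurations, and a ranking by field-volume AUC
#' (`e_auc`) identifying the best-covering montage. Ties in the ranking
#' are reported explicitly and broken by configuration name.
#'
#' @param records data frame of [pqm()] rows (may span several ROIs).
#' @param baseline baseline configuration name (present in `records`).
#' @return Object of class `comparison_report`: list with `records`,
#'   `baseline`, `percent_change` (per ROI), `aggregate` (mean over
#'   alternatives per ROI), `ranking` (per ROI, by `e_auc`), and
#'   `top_configuration` (per ROI).
#' @export
build_report <- function(records, baseline = "SUPRATENTORIAL") {
  if (!baseline %in% records$configuration)
    stop("baseline configuration '", baseline, "' not found in records")
  rois <- unique(records$roi)
  pct <- list(); agg <- list(); rank <- list(); top <- list()
  for (r in rois) {
    sub <- records[records$roi == r, , drop = FALSE]
    base <- sub[sub$configuration == baseline, , drop = FALSE]
    if (nrow(base) != 1L)
      stop("expected exactly one baseline row for ROI '", r, "'")
    alts <- sub[sub$configuration != baseline, , drop = FALSE]
    if (nrow(alts)) {
      pc <- alts[, c("roi", "configuration")]
      for (m in PQM_METRICS)
        pc[[m]] <- if (base[[m]] > 0) percent_change(alts[[m]], base[[m]])
                   else NA_real_  # undefined against a zero baseline
      pct[[r]] <- pc
      ag <- data.frame(roi = r, configuration = "MEAN_ALTERNATIVES")
      for (m in PQM_METRICS)
        ag[[m]] <- aggregate_alternatives(sub, m, baseline)
      agg[[r]] <- ag
    } else {
      pct[[r]] <- alts[, c("roi", "configuration")]
      agg[[r]] <- NULL
    }
    ord <- order(-sub$e_auc, sub$configuration)
    rk <- sub[ord, c("roi", "configuration", "e_auc")]
    rk$rank <- rank(-sub$e_auc, ties.method = "min")[ord]
    rk$tied <- duplicated(rk$e_auc) | duplicated(rk$e_auc, fromLast = TRUE)
    rank[[r]] <- rk
    top[[r]] <- rk$configuration[1]
  }
  structure(list(records = records, baseline = baseline,
                 percent_change = do.call(rbind, pct),
                 aggregate = if (length(agg)) do.call(rbind, agg) else NULL,
                 ranking = do.call(rbind, rank),
                 top_configuration = unlist(top)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report (baseline %s)\n", x$baseline))
  for (r in names(x$top_configuration))
    cat(sprintf("  %s: best e_auc montage %s\n", r, x$top_configuration[[r]]))
  if (!is.null(x$aggregate)) {
    cat("  mean over alternatives:\n")
    print(x$aggregate, row.names = FALSE)
  }
  invisible(x)
}

#' Write a comparison report to CSV and JSON
#' @param report a [build_report()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(records = file.path(dir, "pqm_records.csv"),
             pct = file.path(dir, "percent_change.csv"),
             json = file.path(dir, "report.json"))
  utils::write.csv(report$records, paths["records"], row.names = FALSE)
  utils::write.csv(report$percent_change, paths["pct"], row.names = FALSE)
  jsonlite::write_json(
    list(baseline = report$baseline,
         top_configuration = as.list(report$top_configuration),
         aggregate = report$aggregate),
    paths["json"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

# fixed anatomy grayscale and field color ramp (dark blue -> red -> yellow)
overlay_gray <- function(lab) {
  gray <- c(AIR = 0, SCALP = 0.75, SKULL = 0.95, CSF = 0.35, BRAIN = 0.55,
            CEREBELLUM = 0.5, BRAINSTEM = 0.45, MUSCLE = 0.65,
            VERTEBRA = 0.9, GTV = 0.25, NECROTIC_CORE = 0.15, GEL = 0.8,
            ELECTRODE = 1.0)
  matrix(gray[label_name(lab)], nrow = nrow(lab))
}

overlay_colormap <- function(v01) {
  # piecewise-linear blue -> cyan -> yellow -> red ramp
  r <- pmin(1, pmax(0, 2 * v01 - 0.5))
  g <- pmin(1, pmax(0, 1.5 - abs(2 * v01 - 1) * 1.5)) * 0.9
  b <- pmin(1, pmax(0, 1.5 - 2 * v01))
  list(r = r, g = g, b = b)
}

#' Export an anatomy/field overlay image
#'
#' Renders one plane of the anatomy in grayscale with the field magnitude
#' as a color overlay on a fixed, configurable display range (so images
#' are comparable across configurations) and a vertical color bar at the
#' right edge. Output is a deterministic PNG: identical inputs give
#' byte-identical files.
#'
#' @param volume a [label_volume()] (anatomy).
#' @param field scalar magnitude array on the same grid.
#' @param plane `"axial"` (xy), `"coronal"` (xz) or `"sagittal"` (yz).
#' @param slice 1-based slice index along the remaining axis.
#' @param path output PNG path.
#' @param display_range field values mapped to the color-bar extremes;
#'   values at or below the minimum are not overlaid.
#' @param alpha overlay opacity in (0, 1].
#' @return invisibly, `path`.
#' @export
export_overlay <- function(volume, field, plane = c("axial", "coronal",
                                                    "sagittal"),
                           slice, path, display_range = c(0, 150),
                           alpha = 0.6) {
  plane <- match.arg(plane)
  if (!identical(dim(field), dim(volume$labels)))
    stop("field and anatomy dimensions differ")
  ax <- switch(plane, axial = 3L, coronal = 2L, sagittal = 1L)
  if (slice < 1 || slice > volume$grid$shape[ax])
    stop("slice index out of range")
  lab2 <- switch(plane,
                 axial = volume$labels[, , slice],
                 coronal = volume$labels[, slice, ],
                 sagittal = volume$labels[slice, , ])
  fld2 <- switch(plane,
                 axial = field[, , slice],
                 coronal = field[, slice, ],
                 sagittal = field[slice, , ])
  gray <- overlay_gray(lab2)
  v01 <- (fld2 - display_range[1]) / diff(display_range)
  v01 <- pmin(1, pmax(0, v01))
  show <- fld2 > display_range[1] & lab2 != TISSUE_LABELS[["AIR"]]
  cm <- overlay_colormap(as.vector(v01))
  a <- ifelse(as.vector(show), alpha, 0)
  r <- (1 - a) * as.vector(gray) + a * cm$r
  g <- (1 - a) * as.vector(gray) + a * cm$g
  b <- (1 - a) * as.vector(gray) + a * cm$b

  nr <- nrow(gray); nc <- ncol(gray)
  bar_w <- max(4L, nr %/% 16L)
  gap_w <- 2L
  bar_v <- rep((seq_len(nc) - 1) / (nc - 1), each = bar_w)
  bar_cm <- overlay_colormap(bar_v)
  width <- nr + gap_w + bar_w
  img <- array(0, dim = c(nc, width, 3L))
  # image rows run top-to-bottom; flip so +y/+z point up
  flip <- nc:1
  img[, 1:nr, 1] <- t(matrix(r, nr, nc))[flip, ]
  img[, 1:nr, 2] <- t(matrix(g, nr, nc))[flip, ]
  img[, 1:nr, 3] <- t(matrix(b, nr, nc))[flip, ]
  img[, nr + gap_w + seq_len(bar_w), 1] <- matrix(bar_cm$r, nc, bar_w)[flip, ]
  img[, nr + gap_w + seq_len(bar_w), 2] <- matrix(bar_cm$g, nc, bar_w)[flip, ]
  img[, nr + gap_w + seq_len(bar_w), 3] <- matrix(bar_cm$b, nc, bar_w)[flip, ]
  png::writePNG(img, path)
  invisible(path)
}
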