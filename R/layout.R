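#' Transducer-array configuration vocabulary
#'
#' The seven montages: the conventional supratentorial baseline plus six
#' posterior-fossa alternatives in which the two lateral arrays are shifted
#' posteriorly (with a slight downward rotation of their long axis) and the
#' posteroanterior (PA) array is moved toward the lower occiput / upper
#' neck, rotated horizontal, shifted laterally, or kept vertical at two
#' heights. `AP_PA_HORIZONTAL` additionally rotates the anterior (AP)
#' array by 90 degrees.
#' @export
CONFIGURATION_NAMES <- c(
  "SUPRATENTORIAL", "PA_HORIZONTAL", "PA_HORIZONTAL_RIGHT",
  "PA_HORIZONTAL_LEFT", "PA_VERTICAL_SUPERIOR", "PA_VERTICAL_CENTER",
  "AP_PA_HORIZONTAL"
)

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length direction vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Centroid of the cranial tissue (ray-cast origin)
#'
#' Mean world position of skull, CSF, brain, cerebellum, brainstem and
#' tumor voxels. Used as the default origin for scalp ray casting.
#' @param volume a [label_volume()].
#' @return length-3 world coordinate, mm.
#' @export
head_center <- function(volume) {
  keep <- volume$labels %in% TISSUE_LABELS[c("SKULL", "CSF", "BRAIN",
                                             "CEREBELLUM", "BRAINSTEM",
                                             "GTV", "NECROTIC_CORE")]
  if (!any(keep)) stop("volume contains no cranial tissue")
  idx <- which(array(keep, dim = volume$grid$shape), arr.ind = TRUE) - 1L
  colMeans(voxel_to_world(volume$grid, idx))
}

#' Cast a ray onto the outer (scalp) surface
#'
#' Marches from `from` along `direction` and returns the outermost
#' non-AIR sample, i.e. the point where the ray last leaves the body.
#' The returned voxel is a surface voxel (its continuation is AIR).
#'
#' @param volume a [label_volume()].
#' @param from world-coordinate ray origin, mm.
#' @param direction ray direction (need not be unit length).
#' @param step march step as a fraction of the smallest voxel spacing.
#' @return list with `point` (world mm), `voxel` (0-based indices) and
#'   `t` (distance from `from`, mm).
#' @export
cast_to_surface <- function(volume, from, direction, step = 0.25) {
  d <- unit(direction)
  g <- volume$grid
  tmax <- sqrt(sum((g$shape * g$spacing)^2))
  ts <- seq(0, tmax, by = step * min(g$spacing))
  pts <- cbind(from[1] + ts * d[1], from[2] + ts * d[2], from[3] + ts * d[3])
  ijk <- round(world_to_voxel(g, pts))
  ok <- in_grid(g, ijk)
  lab <- rep(TISSUE_LABELS[["AIR"]], length(ts))
  if (any(ok))
    lab[ok] <- volume$labels[ijk[ok, , drop = FALSE] + 1L]
  hit <- which(lab != TISSUE_LABELS[["AIR"]])
  if (!length(hit)) stop("ray does not intersect the head")
  last <- hit[length(hit)]
  list(point = pts[last, ], voxel = as.integer(ijk[last, ]), t = ts[last])
}

#' Estimate the outward surface normal near a surface voxel
#'
#' Sums the world-space offsets of AIR voxels in a cubic window around the
#' given surface voxel; for a locally planar surface this points along the
#' outward normal.
#' @param volume a [label_volume()].
#' @param voxel 0-based indices of a surface voxel.
#' @param window half-width of the cubic window, voxels.
#' @return outward unit normal.
#' @export
surface_normal <- function(volume, voxel, window = 2L) {
  g <- volume$grid
  rng <- lapply(1:3, function(a)
    max(0L, voxel[a] - window):min(g$shape[a] - 1L, voxel[a] + window))
  off <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  lab <- volume$labels[off + 1L]
  air <- lab == TISSUE_LABELS[["AIR"]]
  if (!any(air)) stop("no AIR voxels near the requested surface voxel")
  disp <- sweep(off[air, , drop = FALSE], 2L, voxel, "-")
  disp <- sweep(disp, 2L, g$spacing, "*")
  unit(colSums(disp))
}

#' Place one 3x3 transducer array on the scalp
#'
#' The array center is the ray-cast intersection of `direction` (from
#' `cast_from`, default the cranial centroid) with the outer surface.
#' The nine disc centers are laid out on the local tangent plane at
#' `pitch` spacing along the projected long axis and its in-plane
#' perpendicular, then each is re-projected onto the surface along its
#' own ray.
#'
#' @param volume a [label_volume()].
#' @param direction anchor direction from `cast_from` toward the scalp.
#' @param long_axis world-space hint for the array's long axis; its
#'   projection onto the tangent plane is used.
#' @param disc_radius transducer disc radius, mm.
#' @param pitch center-to-center disc spacing, mm (> 2 * disc_radius).
#' @param channel `"AP_PA"` or `"LEFT_RIGHT"`.
#' @param polarity `"+"` or `"-"` (role within the channel).
#' @param array_id identifier (e.g. `"PA"`).
#' @param cast_from ray origin; default [head_center()].
#' @param projection `"central"` re-projects disc positions along rays
#'   from `cast_from` (convex scalp regions); `"cylindrical"` re-projects
#'   horizontally from the vertical axis through `cast_from`, which suits
#'   arrays wrapped around the lower occiput and neck; `"parallel"` drops
#'   nominal positions onto the surface along the anchor normal (flat
#'   regions). Tangent-plane
#'   offsets are arc-length corrected so the effective disc pitch on the
#'   surface stays close to `pitch`.
#' @return Object of class `transducer_array`: data frame `discs` (one row
#'   per disc: center, normal, radius, row/col) plus placement metadata.
#' @export
place_array <- function(volume, direction, long_axis,
                        disc_radius = 10, pitch = 22,
                        channel = c("AP_PA", "LEFT_RIGHT"),
                        polarity = c("+", "-"),
                        array_id = "array", cast_from = NULL,
                        projection = c("central", "cylindrical", "parallel")) {
  channel <- match.arg(channel)
  polarity <- match.arg(polarity)
  projection <- match.arg(projection)
  if (disc_radius <= 0) stop("disc_radius must be > 0")
  if (disc_radius > pitch / 2)
    stop("discs would overlap: disc_radius > pitch / 2")
  if (is.null(cast_from)) cast_from <- head_center(volume)

  ctr <- cast_to_surface(volume, cast_from, direction)
  n0 <- surface_normal(volume, ctr$voxel)
  la <- unit(long_axis)
  u <- la - sum(la * n0) * n0
  if (sqrt(sum(u^2)) < 1e-6)
    stop("long axis is parallel to the surface normal at the anchor")
  u <- unit(u)
  v <- cross3(n0, u)

  # arc-length correction: a tangent offset t seen from distance R spans
  # surface arc R*atan(t/R); use t' = R*tan(d/R) so the arc equals d
  arc_offset <- function(w, R) {
    d <- sqrt(sum(w^2))
    if (d < 1e-9) return(w)
    if (d / R >= pi / 2 * 0.95)
      stop("array span too large for the casting distance")
    w * (R * tan(d / R) / d)
  }

  discs <- vector("list", 9L)
  k <- 1L
  if (projection == "cylindrical") {
    # wrap rows around the vertical axis through cast_from: project the
    # row anchor at its own height, then lay the row out along the local
    # horizontal arc (the occiput/neck narrows toward the bottom, so each
    # row uses its own radius)
    for (j in -1:1) {
      row_hit <- if (j == 0L) ctr else {
        nominal <- ctr$point + j * pitch * v
        origin <- c(cast_from[1], cast_from[2], nominal[3])
        cast_to_surface(volume, origin, nominal - origin)
      }
      Rh <- sqrt(sum((row_hit$point[1:2] - cast_from[1:2])^2))
      for (i in -1:1) {
        hit <- if (i == 0L) row_hit else {
          wh <- arc_offset(i * pitch * c(u[1], u[2], 0), Rh)
          nominal <- row_hit$point + wh
          origin <- c(cast_from[1], cast_from[2], nominal[3])
          cast_to_surface(volume, origin, nominal - origin)
        }
        nrm <- surface_normal(volume, hit$voxel)
        discs[[k]] <- data.frame(x = hit$point[1], y = hit$point[2],
                                 z = hit$point[3], nx = nrm[1], ny = nrm[2],
                                 nz = nrm[3], radius = disc_radius,
                                 row = i, col = j)
        k <- k + 1L
      }
    }
  } else {
    for (i in -1:1) for (j in -1:1) {
      w <- i * pitch * u + j * pitch * v
      hit <- if (i == 0L && j == 0L) {
        ctr
      } else if (projection == "central") {
        R0 <- sqrt(sum((ctr$point - cast_from)^2))
        nominal <- ctr$point + arc_offset(w, R0)
        cast_to_surface(volume, cast_from, nominal - cast_from)
      } else {
        # parallel: drop each nominal point onto the surface along the
        # anchor normal (flat or gently curved regions)
        nominal <- ctr$point + w
        origin <- nominal - 60 * n0
        cast_to_surface(volume, origin, n0)
      }
      nrm <- surface_normal(volume, hit$voxel)
      discs[[k]] <- data.frame(x = hit$point[1], y = hit$point[2],
                               z = hit$point[3], nx = nrm[1], ny = nrm[2],
                               nz = nrm[3], radius = disc_radius,
                               row = i, col = j)
      k <- k + 1L
    }
  }
  discs <- do.call(rbind, discs)
  # center-to-center chords on a doubly curved surface fall slightly
  # short of the geodesic pitch; anything below 90% of a disc diameter
  # indicates a degenerate projection rather than curvature
  dmin <- min(stats::dist(discs[, c("x", "y", "z")]))
  if (dmin < 2 * disc_radius * 0.9)
    stop(sprintf("projected discs overlap: nearest centers %.1f mm apart, need %.1f",
                 dmin, 2 * disc_radius * 0.9))
  structure(list(discs = discs, center = unname(ctr$point),
                 normal = n0, long_axis = u, pitch = pitch,
                 channel = channel, polarity = polarity,
                 array_id = array_id),
            class = "transducer_array")
}

#' @export
print.transducer_array <- function(x, ...) {
  cat(sprintf("transducer_array '%s' (%s, %s): 9 discs r=%g mm, center (%.1f, %.1f, %.1f)\n",
              x$array_id, x$channel, x$polarity, x$discs$radius[1],
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

default_layout_params <- function() {
  list(
    disc_radius = 10, pitch = 22,
    lateral_shift_mm = 20,        # PA lateral displacement for RT/LT variants
    posterior_rotation_deg = 15,  # downward tilt of the lateral arrays'
                                  # long axis in the posterior-fossa montages
    anchors = list(
      ap            = c(0, 1, 0.35),
      pa_supra      = c(0, -1, 0.45),
      pa_vert_sup   = c(0, -1, 0.15),
      pa_vert_ctr   = c(0, -1, -0.15),
      pa_horizontal = c(0, -1, -0.8),
      lat_supra_elev = 0.35,
      lat_post      = c(1, -0.35, 0.05)  # mirrored in x for the left side
    )
  )
}

lateral_arrays <- function(volume, params, posterior, cast_from) {
  a <- params$anchors
  if (posterior) {
    th <- params$posterior_rotation_deg * pi / 180
    long <- c(0, cos(th), -sin(th))
    dl <- a$lat_post * c(-1, 1, 1)
    dr <- a$lat_post
  } else {
    long <- c(0, 1, 0)
    dl <- c(-1, 0.05, a$lat_supra_elev)
    dr <- c(1, 0.05, a$lat_supra_elev)
  }
  list(
    LEFT = place_array(volume, dl, long, params$disc_radius, params$pitch,
                       "LEFT_RIGHT", "+", "LEFT", cast_from),
    RIGHT = place_array(volume, dr, long, params$disc_radius, params$pitch,
                        "LEFT_RIGHT", "-", "RIGHT", cast_from)
  )
}

#' Realize one of the seven named array configurations
#'
#' Pure function of `(name, volume, params)`: returns the four placed
#' arrays (AP, PA, LEFT, RIGHT). The posterior-fossa montages share
#' posteriorly displaced lateral arrays and differ in the PA array:
#' horizontal at the lower occiput (optionally shifted +/- `lateral_shift_mm`
#' along x), or vertical at two heights. `AP_PA_HORIZONTAL` uses the
#' horizontal PA with the AP array rotated 90 degrees.
#'
#' @param name one of [CONFIGURATION_NAMES].
#' @param volume a [label_volume()].
#' @param params optional overrides of the geometry defaults (disc radius,
#'   pitch, lateral shift, posterior rotation, anchor directions).
#' @return Object of class `array_layout`: list of four
#'   [place_array()] results plus `name` and `params`.
#' @export
named_configuration <- function(name, volume, params = list()) {
  if (!name %in% CONFIGURATION_NAMES)
    stop("unknown configuration '", name, "'; expected one of: ",
         paste(CONFIGURATION_NAMES, collapse = ", "))
  p <- utils::modifyList(default_layout_params(), params)
  a <- p$anchors
  hc <- head_center(volume)

  ap_long <- if (name == "AP_PA_HORIZONTAL") c(0, 0, 1) else c(1, 0, 0)
  ap <- place_array(volume, a$ap, ap_long, p$disc_radius, p$pitch,
                    "AP_PA", "+", "AP", hc)

  shift <- switch(name,
                  PA_HORIZONTAL_RIGHT = c(p$lateral_shift_mm, 0, 0),
                  PA_HORIZONTAL_LEFT = c(-p$lateral_shift_mm, 0, 0),
                  c(0, 0, 0))
  pa <- switch(name,
    SUPRATENTORIAL = place_array(volume, a$pa_supra, c(0, 0, 1),
                                 p$disc_radius, p$pitch, "AP_PA", "-", "PA", hc),
    PA_VERTICAL_SUPERIOR = place_array(volume, a$pa_vert_sup, c(0, 0, 1),
                                       p$disc_radius, p$pitch, "AP_PA", "-",
                                       "PA", hc),
    PA_VERTICAL_CENTER = place_array(volume, a$pa_vert_ctr, c(0, 0, 1),
                                     p$disc_radius, p$pitch, "AP_PA", "-",
                                     "PA", hc),
    # horizontal PA family: translate the whole cast laterally so the
    # array center moves by exactly the requested shift along x, and wrap
    # the discs around the lower occiput by cylindrical projection
    place_array(volume, a$pa_horizontal, c(1, 0, 0), p$disc_radius, p$pitch,
                "AP_PA", "-", "PA", hc + shift, projection = "cylindrical")
  )

  lats <- lateral_arrays(volume, p, posterior = name != "SUPRATENTORIAL", hc)

  structure(list(name = name, params = p,
                 AP = ap, PA = pa,
                 LEFT = lats$LEFT, RIGHT = lats$RIGHT),
            class = "array_layout")
}

#' @export
print.array_layout <- function(x, ...) {
  cat(sprintf("array_layout '%s'\n", x$name))
  for (id in c("AP", "PA", "LEFT", "RIGHT")) print(x[[id]])
  invisible(x)
}

#' All disc rows of a layout as one data frame
#' @param layout an [named_configuration()] result.
#' @return data frame with one row per disc (36 rows).
#' @export
layout_discs <- function(layout) {
  ids <- Filter(function(id) !is.null(layout[[id]]),
                c("AP", "PA", "LEFT", "RIGHT"))
  out <- lapply(ids, function(id) {
    d <- layout[[id]]$discs
    d$array <- id
    d$channel <- layout[[id]]$channel
    d$polarity <- layout[[id]]$polarity
    d
  })
  do.call(rbind, out)
}

#' Serialize / load an array layout as JSON
#' @param layout an `array_layout`.
#' @param path JSON file path.
#' @export
write_layout <- function(layout, path) {
  obj <- list(name = layout$name,
              params = layout$params[c("disc_radius", "pitch",
                                       "lateral_shift_mm",
                                       "posterior_rotation_deg")],
              discs = layout_discs(layout))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout_discs <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$discs
}

#' Rasterize electrode discs into a label volume
#'
#' Each disc becomes a one-voxel-thick conductive-gel layer on the scalp
#' (AIR voxels face-adjacent to the scalp-surface voxels under the disc
#' footprint) capped by ELECTRODE voxels (AIR voxels face-adjacent to the
#' gel but not touching scalp). Anatomy labels are unchanged elsewhere.
#' Voxels claimed by several discs go to the nearest disc center, so
#' patches are disjoint by construction.
#'
#' @param layout an `array_layout` placed on `volume`.
#' @param volume the [label_volume()] the layout was placed on.
#' @return list with `volume` (labels including GEL and ELECTRODE) and
#'   `patches`: one entry per disc with `array`, `channel`, `polarity`,
#'   `gel` and `electrode` (1-based linear voxel indices).
#' @export
rasterize_electrodes <- function(layout, volume) {
  g <- volume$grid
  lab <- volume$labels
  dims <- g$shape
  discs <- layout_discs(layout)

  air <- lab == TISSUE_LABELS[["AIR"]]
  scalp <- lab == TISSUE_LABELS[["SCALP"]]
  adj_air <- neighbor_any(air, dims)
  surf <- scalp & adj_air
  surf_idx <- which(surf)
  surf_ijk <- arrayInd(surf_idx, dims) - 1L
  surf_xyz <- voxel_to_world(g, surf_ijk)
  adj_scalp <- neighbor_any(scalp, dims)

  band <- max(6, 1.5 * max(g$spacing))
  claims_gel <- list(); claims_el <- list()
  for (d in seq_len(nrow(discs))) {
    ctr <- as.numeric(discs[d, c("x", "y", "z")])
    nrm <- as.numeric(discs[d, c("nx", "ny", "nz")])
    rel <- sweep(surf_xyz, 2L, ctr, "-")
    along <- rel %*% nrm
    perp2 <- rowSums(rel^2) - along^2
    foot <- surf_idx[abs(along) <= band & perp2 <= discs$radius[d]^2]
    if (!length(foot))
      stop(sprintf("disc %d of array %s rasterizes to zero voxels",
                   d, discs$array[d]))
    gel <- unique(face_neighbors(foot, dims))
    gel <- gel[air[gel]]
    if (!length(gel))
      stop(sprintf("disc %d of array %s has no gel voxels", d, discs$array[d]))
    el <- unique(face_neighbors(gel, dims))
    el <- el[air[el] & !adj_scalp[el] & !(el %in% gel)]
    claims_gel[[d]] <- gel
    claims_el[[d]] <- el
  }

  # resolve multi-disc claims by distance to disc center
  resolve <- function(claims) {
    all_vox <- unlist(claims)
    all_disc <- rep(seq_along(claims), lengths(claims))
    xyz <- voxel_to_world(g, arrayInd(all_vox, dims) - 1L)
    ctrs <- as.matrix(discs[all_disc, c("x", "y", "z")])
    dist2 <- rowSums((xyz - ctrs)^2)
    ord <- order(all_vox, dist2, all_disc)
    keep <- ord[!duplicated(all_vox[ord])]
    split(all_vox[keep], factor(all_disc[keep], levels = seq_along(claims)))
  }
  gel_by_disc <- resolve(claims_gel)
  el_by_disc <- resolve(claims_el)
  # electrode voxels must not double as gel voxels of another disc
  gel_all <- unlist(gel_by_disc)
  el_by_disc <- lapply(el_by_disc, function(v) setdiff(v, gel_all))

  newlab <- lab
  patches <- vector("list", nrow(discs))
  for (d in seq_len(nrow(discs))) {
    gel <- gel_by_disc[[d]]; el <- el_by_disc[[d]]
    if (!length(gel) || !length(el))
      stop(sprintf("disc %d of array %s lost its patch during overlap resolution",
                   d, discs$array[d]))
    newlab[gel] <- TISSUE_LABELS[["GEL"]]
    newlab[el] <- TISSUE_LABELS[["ELECTRODE"]]
    patches[[d]] <- list(array = discs$array[d], channel = discs$channel[d],
                         polarity = discs$polarity[d], disc = d,
                         gel = gel, electrode = el)
  }
  list(volume = label_volume(newlab, g), patches = patches)
}

# 1-based linear indices of all face neighbors (6-connectivity), clipped
face_neighbors <- function(idx, dims) {
  ijk <- arrayInd(idx, dims)
  out <- vector("list", 6L)
  s <- 1L
  for (a in 1:3) for (dd in c(-1L, 1L)) {
    nb <- ijk
    nb[, a] <- nb[, a] + dd
    ok <- nb[, a] >= 1L & nb[, a] <= dims[a]
    out[[s]] <- (nb[ok, 1] - 1L) + (nb[ok, 2] - 1L) * dims[1] +
      (nb[ok, 3] - 1L) * dims[1] * dims[2] + 1L
    s <- s + 1L
  }
  unlist(out)
}

# logical array: TRUE where any face neighbor is TRUE in `x`
neighbor_any <- function(x, dims) {
  out <- array(FALSE, dim = dims)
  n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
  out[-1, , ] <- out[-1, , ] | x[-n1, , ]
  out[-n1, , ] <- out[-n1, , ] | x[-1, , ]
  out[, -1, ] <- out[, -1, ] | x[, -n2, ]
  out[, -n2, ] <- out[, -n2, ] | x[, -1, ]
  out[, , -1] <- out[, , -1] | x[, , -n3]
  out[, , -n3] <- out[, , -n3] | x[, , -1]
  out
}
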