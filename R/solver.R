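#' Solver settings for the quasi-static volume-conductor problem
#'
#' At 200 kHz the head behaves as a resistive volume conductor, so each
#' channel solves the conductivity-weighted Laplace equation
#' `div(sigma grad phi) = 0` with Dirichlet potentials on the energized
#' electrode voxels and zero normal current on the air boundary. Solutions
#' are rescaled so the delivered channel current equals `target_current`.
#'
#' @param target_current delivered total current per channel, A.
#' @param tol relative residual tolerance of the conjugate-gradient solve.
#' @param max_iter conjugate-gradient iteration cap.
#' @param combine how to summarize the two channels: `"average"`
#'   (arithmetic mean of the magnitude maps, the default summary),
#'   `"max"` (voxelwise maximum) or `"per_channel"`.
#' @return Object of class `solve_settings`.
#' @export
solve_settings <- function(target_current = 0.9, tol = 1e-8,
                           max_iter = 20000L,
                           combine = c("average", "max", "per_channel")) {
  if (target_current <= 0) stop("target_current must be > 0")
  if (tol <= 0) stop("tol must be > 0")
  structure(list(target_current = target_current, tol = tol,
                 max_iter = as.integer(max_iter),
                 combine = match.arg(combine)),
            class = "solve_settings")
}

# Finite-volume discretization of div(sigma grad phi) on the voxel grid.
# Face conductances are harmonic means of the adjacent voxel
# conductivities times face area over center distance (SI units), giving
# a symmetric positive semi-definite conservation form. Returns the
# conductance matrix over conductive voxels plus the voxel id map.
assemble_system <- function(sigma, grid) {
  dims <- grid$shape
  hm <- grid$spacing / 1000  # m
  cond <- !is.na(sigma) & sigma > 0
  n <- sum(cond)
  if (n == 0L) stop("no conductive voxels")
  uid <- array(0L, dim = dims)
  uid[cond] <- seq_len(n)

  ii <- list(); jj <- list(); xx <- list()
  s <- 1L
  for (a in 1:3) {
    idxA <- slice_index(dims, a, 1L, dims[a] - 1L)
    idxB <- slice_index(dims, a, 2L, dims[a])
    both <- cond[idxA] & cond[idxB]
    va <- idxA[both]; vb <- idxB[both]
    sa <- sigma[va]; sb <- sigma[vb]
    area <- prod(hm[-a])
    g <- (area / hm[a]) * 2 * sa * sb / (sa + sb)
    ii[[s]] <- uid[va]; jj[[s]] <- uid[vb]; xx[[s]] <- -g
    s <- s + 1L
  }
  i <- unlist(ii); j <- unlist(jj); x <- unlist(xx)
  off <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(x, x),
                              dims = c(n, n))
  dg <- -Matrix::rowSums(off)
  A <- off + Matrix::Diagonal(n, dg)
  list(A = A, uid = uid, cond = cond, n = n)
}

# linear indices of the sub-array where axis `a` runs from `from` to `to`
slice_index <- function(dims, a, from, to) {
  rngs <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  rngs[[a]] <- from:to
  st <- c(1L, dims[1], dims[1] * dims[2])
  outer3 <- outer(outer((rngs[[1]] - 1L) * st[1], (rngs[[2]] - 1L) * st[2], "+"),
                  (rngs[[3]] - 1L) * st[3], "+")
  as.vector(outer3) + 1L
}

# Jacobi-preconditioned conjugate gradients for sparse SPD systems;
# deterministic (zero initial guess).
pcg <- function(A, b, tol = 1e-8, max_iter = 20000L) {
  n <- length(b)
  x <- numeric(n)
  r <- b
  dinv <- 1 / Matrix::diag(A)
  if (any(!is.finite(dinv)))
    stop("singular system: a voxel has no conductive coupling ",
         "(disconnected anode/cathode?)")
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, iterations = 0L, residual = 0))
  z <- dinv * r
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(max_iter)) {
    Ap <- as.numeric(A %*% p)
    pAp <- sum(p * Ap)
    if (!is.finite(pAp) || pAp <= 0)
      stop("conjugate gradients broke down: system not positive definite ",
           "(disconnected anode/cathode?)")
    alpha <- rz / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / bnorm
    if (res <= tol)
      return(list(x = x, iterations = it, residual = res))
    z <- dinv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop(sprintf("conjugate gradients did not converge in %d iterations (residual %.3e)",
               max_iter, res))
}

#' Solve one energized channel
#'
#' Solves the discrete conservation law for the electric potential with
#' `+V0` on the anode electrode voxels and `-V0` on the cathode electrode
#' voxels, then rescales potential, field and current density so that the
#' delivered current equals `settings$target_current`.
#'
#' @param sigma numeric 3-D conductivity array (S/m), `NA` in AIR
#'   (from [assign_conductivity()]).
#' @param grid the [voxel_grid()].
#' @param anode,cathode 1-based linear indices of the energized
#'   ELECTRODE voxels of each polarity (non-empty, disjoint).
#' @param settings a [solve_settings()].
#' @param channel channel identifier stored in the result.
#' @return Object of class `channel_solution`: `phi` (V, `NA` in AIR),
#'   `E` and `J` (4-D arrays, last dimension x/y/z components; V/m and
#'   A/m^2), `E_mag`, `J_mag`, `flux` (net current out of each voxel, A),
#'   `applied_potential` (V), `delivered_current` (A), `iterations`,
#'   `residual`, and the anode/cathode index sets.
#' @export
solve_channel <- function(sigma, grid, anode, cathode, settings = solve_settings(),
                          channel = "channel") {
  stopifnot(inherits(settings, "solve_settings"))
  if (!length(anode) || !length(cathode)) stop("empty electrode patch")
  if (length(intersect(anode, cathode))) stop("anode and cathode overlap")
  sys <- assemble_system(sigma, grid)
  ua <- sys$uid[anode]; uc <- sys$uid[cathode]
  if (any(ua == 0L) || any(uc == 0L))
    stop("electrode voxels fall outside the conductive domain")

  n <- sys$n
  v0 <- 0.5
  phi_full <- numeric(n)
  phi_full[ua] <- v0
  phi_full[uc] <- -v0
  dir_ids <- c(ua, uc)
  free <- setdiff(seq_len(n), dir_ids)
  A <- sys$A
  b <- -as.numeric(A[free, dir_ids, drop = FALSE] %*% phi_full[dir_ids])
  sol <- pcg(A[free, free], b, tol = settings$tol,
             max_iter = settings$max_iter)
  phi_full[free] <- sol$x

  flux_full <- as.numeric(A %*% phi_full)
  I_unit <- sum(flux_full[ua])
  if (!is.finite(I_unit) || I_unit <= 1e-10 * max(Matrix::diag(A)))
    stop("singular configuration: no conductive path carries current ",
         "between anode and cathode")
  scale <- settings$target_current / I_unit
  phi_full <- phi_full * scale
  flux_full <- flux_full * scale

  phi <- array(NA_real_, dim = grid$shape)
  phi[sys$cond] <- phi_full
  flux <- array(0, dim = grid$shape)
  flux[sys$cond] <- flux_full

  E <- compute_field(phi, grid)
  J <- E
  sig0 <- sigma
  sig0[is.na(sig0)] <- 0
  for (a in 1:3) J[, , , a] <- E[, , , a] * sig0
  E_mag <- sqrt(E[, , , 1]^2 + E[, , , 2]^2 + E[, , , 3]^2)
  J_mag <- sqrt(J[, , , 1]^2 + J[, , , 2]^2 + J[, , , 3]^2)

  balance <- abs(sum(flux[anode]) + sum(flux[cathode])) /
    abs(sum(flux[anode]))
  structure(list(channel = channel, phi = phi, E = E, J = J,
                 E_mag = E_mag, J_mag = J_mag, flux = flux,
                 applied_potential = 2 * v0 * scale,
                 delivered_current = settings$target_current,
                 current_balance = balance,
                 iterations = sol$iterations, residual = sol$residual,
                 anode = anode, cathode = cathode, grid = grid),
            class = "channel_solution")
}

#' @export
print.channel_solution <- function(x, ...) {
  cat(sprintf("channel_solution '%s': %d CG iterations, residual %.2e\n",
              x$channel, x$iterations, x$residual))
  cat(sprintf("  delivered %.3f A at %.1f V; current balance %.2e\n",
              x$delivered_current, x$applied_potential, x$current_balance))
  invisible(x)
}

#' Electric field from a potential volume
#'
#' `E = -grad(phi)` by central differences where both neighbors are in the
#' conductive domain, one-sided differences at domain boundaries, and zero
#' where the potential is undefined (AIR).
#'
#' @param phi potential array (V), `NA` outside the conductive domain.
#' @param grid the [voxel_grid()].
#' @return 4-D array `dim = c(grid$shape, 3)`, V/m.
#' @export
compute_field <- function(phi, grid) {
  if (!identical(as.integer(dim(phi)), grid$shape))
    stop("phi dimensions do not match grid shape")
  dims <- grid$shape
  hm <- grid$spacing / 1000
  E <- array(0, dim = c(dims, 3L))
  def <- !is.na(phi)
  p0 <- phi
  p0[!def] <- 0
  for (a in 1:3) {
    up <- shift_arr(p0, a, 1L); dn <- shift_arr(p0, a, -1L)
    dup <- shift_arr(def, a, 1L); ddn <- shift_arr(def, a, -1L)
    grad <- array(0, dim = dims)
    both <- def & dup & ddn
    grad[both] <- (up[both] - dn[both]) / (2 * hm[a])
    fwd <- def & dup & !ddn
    grad[fwd] <- (up[fwd] - p0[fwd]) / hm[a]
    bwd <- def & !dup & ddn
    grad[bwd] <- (p0[bwd] - dn[bwd]) / hm[a]
    E[, , , a] <- -grad
  }
  E
}

# shift array contents by one voxel along axis a (+1 brings the next
# voxel's value to the current position); out-of-range positions get
# FALSE/0 of the input type
shift_arr <- function(x, a, by) {
  dims <- dim(x)
  out <- array(if (is.logical(x)) FALSE else 0, dim = dims)
  n <- dims[a]
  src <- if (by > 0) 2:n else 1:(n - 1)
  dst <- if (by > 0) 1:(n - 1) else 2:n
  idx_src <- slice_index(dims, a, min(src), max(src))
  idx_dst <- slice_index(dims, a, min(dst), max(dst))
  out[idx_dst] <- x[idx_src]
  out
}

#' Total current through an electrode patch
#'
#' Discrete surface integral of the normal current density over the
#' patch's conductive faces: the sum of the per-voxel net fluxes of the
#' patch voxels (positive = current leaving the patch into the tissue).
#'
#' @param solution a [solve_channel()] result.
#' @param voxels 1-based linear indices of the patch's ELECTRODE voxels.
#' @return current, A.
#' @export
total_current <- function(solution, voxels) {
  stopifnot(inherits(solution, "channel_solution"))
  if (!length(voxels)) stop("empty electrode patch")
  sum(solution$flux[voxels])
}

#' Combine the two channel solutions into summary magnitude maps
#'
#' The device alternates between the two orthogonal channels, so a single
#' summary map is a modelling choice: `"average"` (arithmetic mean of the
#' per-channel magnitudes, the default), `"max"` (voxelwise maximum) or
#' `"per_channel"` (no combination; both maps returned).
#'
#' @param sol_a,sol_b [solve_channel()] results on the same grid.
#' @param mode combination mode.
#' @param what `"E"` or `"J"`.
#' @return a magnitude array, or for `"per_channel"` a list of two.
#' @export
combine_channels <- function(sol_a, sol_b,
                             mode = c("average", "max", "per_channel"),
                             what = c("E", "J")) {
  mode <- match.arg(mode)
  what <- match.arg(what)
  if (!same_grid(sol_a$grid, sol_b$grid))
    stop("channel solutions are on different grids")
  ma <- if (what == "E") sol_a$E_mag else sol_a$J_mag
  mb <- if (what == "E") sol_b$E_mag else sol_b$J_mag
  switch(mode,
         average = (ma + mb) / 2,
         max = pmax(ma, mb),
         per_channel = list(ma, mb))
}

#' Solve both channels of a rasterized montage
#'
#' Convenience wrapper: assigns conductivities, solves the AP-PA and
#' LEFT-RIGHT channels, and combines the magnitude maps.
#'
#' @param rast result of [rasterize_electrodes()].
#' @param table a [conductivity_table()].
#' @param settings a [solve_settings()].
#' @return list with `solutions` (named list of two
#'   [solve_channel()] results), `E_combined`, `J_combined` (per
#'   `settings$combine`; lists when `per_channel`), and `sigma`.
#' @export
solve_montage <- function(rast, table = conductivity_table(),
                          settings = solve_settings()) {
  sigma <- assign_conductivity(rast$volume, table)
  grid <- rast$volume$grid
  sols <- list()
  for (ch in c("AP_PA", "LEFT_RIGHT")) {
    pats <- Filter(function(p) p$channel == ch, rast$patches)
    anode <- unlist(lapply(Filter(function(p) p$polarity == "+", pats),
                           `[[`, "electrode"))
    cathode <- unlist(lapply(Filter(function(p) p$polarity == "-", pats),
                             `[[`, "electrode"))
    sols[[ch]] <- solve_channel(sigma, grid, anode, cathode, settings, ch)
  }
  list(solutions = sols,
       E_combined = combine_channels(sols[[1]], sols[[2]], settings$combine, "E"),
       J_combined = combine_channels(sols[[1]], sols[[2]], settings$combine, "J"),
       sigma = sigma)
}
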