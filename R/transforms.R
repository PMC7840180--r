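#' Rigid -> affine -> B-spline transform chain
#'
#' The chain maps points from fixed-image (sample) physical space to
#' moving-image (template) physical space, the pull-back direction used to
#' resample the moving image onto the fixed grid:
#' `T(x) = Affine(Rigid(x)) + D(x)`, where `D` is a cubic B-spline
#' free-form displacement field parameterised by a control-point lattice
#' over the fixed domain and added to the globally aligned point
#' (additive composition of the deformable stage).
#'
#' @param fixed_grid,moving_grid grid descriptors (`shape`, `spacing`,
#'   `origin`) of the two spaces; obtained from a [Volume()] internally.
#' @return object of class `transform_chain` with identity stages.
#' @export
transform_chain <- function(fixed_grid, moving_grid = fixed_grid) {
  structure(list(
    fixed_grid = fixed_grid[c("shape", "spacing", "origin")],
    moving_grid = moving_grid[c("shape", "spacing", "origin")],
    rigid = rep(0, 6),          # rx, ry, rz (rad), tx, ty, tz (um)
    affine = rep(0, 12),        # row-major deviation from I (9) + t (3), um
    bspline = NULL,
    center = grid_center(fixed_grid)
  ), class = "transform_chain")
}

grid_center <- function(grid) {
  grid$origin + (grid$shape - 1) / 2 * grid$spacing
}

grid_extent <- function(grid) (grid$shape - 1) * grid$spacing

euler_matrix <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

affine_matrix <- function(a) diag(3) + matrix(a[1:9], 3, 3, byrow = TRUE)

# combined global linear part (for inversion)
global_linear <- function(chain) {
  affine_matrix(chain$affine) %*% euler_matrix(chain$rigid)
}

#' Create a B-spline displacement stage on the fixed domain
#'
#' @param fixed_grid fixed-image grid descriptor.
#' @param spacing_vox control-point spacing in fixed-grid voxels
#'   (default 30, the finest-level spacing).
#' @return B-spline stage (coefficients all zero).
#' @keywords internal
bspline_stage <- function(fixed_grid, spacing_vox = 30) {
  sp <- spacing_vox * fixed_grid$spacing
  ext <- grid_extent(fixed_grid)
  # one-cell margin each side so every domain point has full 4^3 support
  origin <- fixed_grid$origin - sp
  nc <- floor(ext / sp) + 5L
  list(spacing = sp, origin = origin, nc = as.integer(nc),
       coef = matrix(0, prod(nc), 3))  # um displacements, columns x/y/z
}

# cubic B-spline basis values for fractional offsets t in [0,1):
# weights over control points i-1, i, i+1, i+2
cubic_bspline_w <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  list((1 - t)^3 / 6,
       (3 * t3 - 6 * t2 + 4) / 6,
       (-3 * t3 + 3 * t2 + 3 * t + 1) / 6,
       t3 / 6)
}

# Per-point lattice support: n x 64 weight matrix and 1-based coefficient
# row indices. Points outside the lattice interior are clamped.
bspline_support <- function(bs, pts) {
  u <- sweep(sweep(pts, 2, bs$origin, "-"), 2, bs$spacing, "/")
  i0 <- floor(u)
  for (d in 1:3) i0[, d] <- pmin(pmax(i0[, d], 1), bs$nc[d] - 3)
  tt <- u - i0
  wx <- cubic_bspline_w(tt[, 1]); wy <- cubic_bspline_w(tt[, 2])
  wz <- cubic_bspline_w(tt[, 3])
  n <- nrow(pts)
  W <- matrix(0, n, 64)
  IDX <- matrix(0L, n, 64)
  col <- 0L
  for (dz in 0:3) for (dy in 0:3) for (dx in 0:3) {
    col <- col + 1L
    W[, col] <- wx[[dx + 1]] * wy[[dy + 1]] * wz[[dz + 1]]
    IDX[, col] <- 1L + (i0[, 1] - 1L + dx) +
      bs$nc[1] * (i0[, 2] - 1L + dy + bs$nc[2] * (i0[, 3] - 1L + dz))
  }
  list(W = W, IDX = IDX)
}

bspline_displacement <- function(bs, pts, support = NULL) {
  if (is.null(bs)) return(matrix(0, nrow(pts), 3))
  if (is.null(support)) support <- bspline_support(bs, pts)
  D <- matrix(0, nrow(pts), 3)
  for (j in seq_len(64)) {
    cj <- bs$coef[support$IDX[, j], , drop = FALSE]
    D <- D + support$W[, j] * cj
  }
  D
}

#' Map physical points through a transform chain
#'
#' @param chain a [transform_chain()].
#' @param pts n x 3 matrix of fixed-space physical coordinates (um), or a
#'   [POISet()].
#' @return mapped coordinates in moving space (matrix, or POISet tagged
#'   `template` when a POISet was given).
#' @export
transform_points <- function(chain, pts) {
  poi <- inherits(pts, "POISet")
  m <- if (poi) pts$coords else as.matrix(pts)
  ctr <- chain$center
  y <- sweep(m, 2, ctr, "-") %*% t(euler_matrix(chain$rigid))
  y <- sweep(y, 2, ctr + chain$rigid[4:6], "+")
  y <- sweep(y, 2, ctr, "-") %*% t(affine_matrix(chain$affine))
  y <- sweep(y, 2, ctr + chain$affine[10:12], "+")
  y <- y + bspline_displacement(chain$bspline, m)
  if (poi) POISet(pts$names, y, "template") else y
}

#' Numerically invert a transform chain at given moving-space points
#'
#' Fixed-point iteration preconditioned by the inverse of the global linear
#' part: solves `T(x) = y` for each point.
#'
#' @param chain a [transform_chain()].
#' @param pts n x 3 moving-space physical coordinates, or a [POISet()].
#' @param tol convergence tolerance in fixed-grid voxels (default 0.1).
#' @param max_iter iteration cap.
#' @param max_fail_frac error if more than this fraction of points fails to
#'   converge (default 0.01).
#' @return fixed-space coordinates (matrix or POISet tagged `sample`).
#' @export
invert_points <- function(chain, pts, tol = 0.1, max_iter = 100,
                          max_fail_frac = 0.01) {
  poi <- inherits(pts, "POISet")
  y <- if (poi) pts$coords else as.matrix(pts)
  Ginv <- solve(global_linear(chain))
  tol_um <- tol * min(chain$fixed_grid$spacing)
  x <- y
  err <- rep(Inf, nrow(y))
  for (it in seq_len(max_iter)) {
    r <- transform_points(chain, x) - y
    err <- sqrt(rowSums(r^2))
    if (max(err) < tol_um) break
    x <- x - r %*% t(Ginv)
  }
  nfail <- sum(err >= tol_um)
  if (nfail > max_fail_frac * nrow(y))
    stop("transform inversion failed at ", nfail, " of ", nrow(y),
         " points (worst residual ", format(max(err), digits = 3), " um)")
  if (poi) POISet(pts$names, x, "sample") else x
}

#' Resample a volume through a transform chain
#'
#' Pull-back resampling onto a target grid: each target voxel centre is
#' mapped through the chain and the moving image is interpolated there
#' (trilinear for [Volume()], nearest-neighbour for [LabelVolume()] so no
#' label ids are fabricated). Points mapping outside the moving domain get
#' 0.
#'
#' @param vol moving [Volume()] or [LabelVolume()].
#' @param chain a [transform_chain()].
#' @param target_grid grid to resample onto: a [Volume()]/[LabelVolume()]
#'   or a grid descriptor; defaults to the chain's fixed grid.
#' @return resampled object of the same class as `vol`.
#' @export
resample <- function(vol, chain, target_grid = NULL) {
  stopifnot(inherits(chain, "transform_chain"))
  if (is.null(target_grid)) {
    grid <- chain$fixed_grid
    grid$axes <- vol$axes
  } else if (inherits(target_grid, c("Volume", "LabelVolume"))) {
    grid <- vol_grid(target_grid)
  } else grid <- target_grid
  arr <- vol_array(vol)
  mg <- list(shape = dim(arr), spacing = vol$spacing, origin = vol$origin)
  is_label <- inherits(vol, "LabelVolume")
  out <- numeric(prod(grid$shape))
  nxy <- grid$shape[1] * grid$shape[2]
  # chunk over z-slabs to bound the 64-weight B-spline temporaries
  zchunk <- max(1L, floor(2^19 / nxy))
  z0 <- 0L
  while (z0 < grid$shape[3]) {
    nz <- min(zchunk, grid$shape[3] - z0)
    idx <- cbind(
      rep.int(seq_len(grid$shape[1]) - 1, grid$shape[2] * nz),
      rep.int(rep(seq_len(grid$shape[2]) - 1, each = grid$shape[1]), nz),
      rep(z0 + seq_len(nz) - 1, each = nxy)
    )
    pts <- voxel_to_phys(idx, grid)
    mpts <- transform_points(chain, pts)
    mvox <- phys_to_voxel(mpts, mg)
    vals <- if (is_label) interp_nearest(arr, mvox, 0L)
            else interp_trilinear(arr, mvox, 0)
    out[(z0 * nxy + 1):((z0 + nz) * nxy)] <- vals
    z0 <- z0 + nz
  }
  out <- array(out, dim = grid$shape)
  axes <- if (!is.null(grid$axes)) grid$axes else vol$axes
  if (is_label)
    LabelVolume(out, grid$spacing, axes, grid$origin,
                id_to_name = vol$id_to_name)
  else Volume(out, grid$spacing, axes, grid$origin)
}

#' Serialise a transform chain to JSON
#'
#' Stage order, grids and parameter vectors are written in full precision
#' so that [read_transform()] round-trips bit-exactly.
#'
#' @param chain a [transform_chain()].
#' @param path destination path.
#' @export
write_transform <- function(chain, path) {
  obj <- list(
    format = "birdreg-transform-1",
    fixed_grid = chain$fixed_grid, moving_grid = chain$moving_grid,
    center = chain$center, rigid = chain$rigid, affine = chain$affine
  )
  if (!is.null(chain$bspline)) {
    obj$bspline <- list(spacing = chain$bspline$spacing,
                        origin = chain$bspline$origin,
                        nc = chain$bspline$nc,
                        coef = as.vector(chain$bspline$coef))
  }
  json <- jsonlite::serializeJSON(obj, digits = I(17))
  writeLines(json, path)
  invisible(path)
}

#' Read a transform chain written by [write_transform()]
#' @param path JSON path.
#' @return a [transform_chain()].
#' @export
read_transform <- function(path) {
  obj <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  chain <- transform_chain(obj$fixed_grid, obj$moving_grid)
  chain$center <- obj$center
  chain$rigid <- obj$rigid
  chain$affine <- obj$affine
  if (!is.null(obj$bspline)) {
    bs <- obj$bspline
    bs$coef <- matrix(bs$coef, ncol = 3)
    bs$nc <- as.integer(bs$nc)
    chain$bspline <- bs
  }
  chain
}

#' @export
print.transform_chain <- function(x, ...) {
  cat("transform_chain (fixed -> moving, physical um)\n")
  cat(sprintf("  rigid:  rot (%.4g, %.4g, %.4g) rad, t (%.4g, %.4g, %.4g) um\n",
              x$rigid[1], x$rigid[2], x$rigid[3],
              x$rigid[4], x$rigid[5], x$rigid[6]))
  cat(sprintf("  affine: max |dev from I| %.4g, t (%.4g, %.4g, %.4g) um\n",
              max(abs(x$affine[1:9])),
              x$affine[10], x$affine[11], x$affine[12]))
  if (is.null(x$bspline)) {
    cat("  bspline: none\n")
  } else {
    cat(sprintf("  bspline: %d x %d x %d control points, spacing (%g, %g, %g) um, max |d| %.4g um\n",
                x$bspline$nc[1], x$bspline$nc[2], x$bspline$nc[3],
                x$bspline$spacing[1], x$bspline$spacing[2],
                x$bspline$spacing[3], max(abs(x$bspline$coef))))
  }
  invisible(x)
}

# Gaussian pyramid level of a volume: smooth then decimate by `factor`.
pyramid_level <- function(vol, factor) {
  if (factor <= 1) return(vol)
  sig <- factor / 2
  sm <- gaussian_smooth3(vol$data, rep(sig, 3))
  d <- dim(sm)
  ix <- seq(1, d[1], by = factor); iy <- seq(1, d[2], by = factor)
  iz <- seq(1, d[3], by = factor)
  Volume(sm[ix, iy, iz, drop = FALSE], spacing = vol$spacing * factor,
         axes = vol$axes, origin = vol$origin)
}
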