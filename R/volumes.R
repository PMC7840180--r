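#' Construct a 3D scalar volume
#'
#' A `Volume` is the package's basic container: a 3D numeric array plus the
#' physical grid metadata every downstream stage needs. Coordinates follow a
#' voxel-centre convention: the physical position of voxel `(i, j, k)`
#' (0-based) is `origin + c(i, j, k) * spacing`, in micrometres.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing voxel spacing `(sx, sy, sz)` in um/voxel; all > 0.
#' @param axes role tags for the three array dimensions; a permutation of
#'   `"LR"` (lateral-medial), `"DV"` (dorsal-ventral), `"AP"`
#'   (anterior-posterior, the slice axis of a coronal stack).
#' @param origin physical coordinate (um) of voxel `(0, 0, 0)`.
#' @return object of class `Volume`.
#' @export
Volume <- function(data, spacing = c(1, 1, 1), axes = c("LR", "DV", "AP"),
                   origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("Volume data must have exactly 3 dimensions, got ",
         length(dim(data)))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite numbers")
  axes <- as.character(axes)
  if (!setequal(axes, c("LR", "DV", "AP")) || length(axes) != 3L)
    stop("axes must be a permutation of c('LR','DV','AP')")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite numbers")
  structure(list(data = data, spacing = spacing, axes = axes,
                 origin = origin),
            class = "Volume")
}

#' Construct an integer-labelled volume
#'
#' Shares the grid conventions of [Volume()]; label 0 is reserved for
#' background/outside-brain.
#'
#' @param labels 3D array of non-negative integers.
#' @param spacing,axes,origin as in [Volume()].
#' @param id_to_name optional named character vector mapping label id
#'   (as name) to region acronym.
#' @return object of class `LabelVolume`.
#' @export
LabelVolume <- function(labels, spacing = c(1, 1, 1),
                        axes = c("LR", "DV", "AP"), origin = c(0, 0, 0),
                        id_to_name = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("LabelVolume labels must have exactly 3 dimensions")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  v <- Volume(labels, spacing = spacing, axes = axes, origin = origin)
  structure(list(labels = labels, spacing = v$spacing, axes = v$axes,
                 origin = v$origin, id_to_name = id_to_name),
            class = "LabelVolume")
}

#' Construct a set of named fiducial points (POIs)
#'
#' @param names unique point identifiers.
#' @param coords n x 3 matrix of physical positions (um).
#' @param space either `"sample"` or `"template"`.
#' @return object of class `POISet`.
#' @export
POISet <- function(names, coords, space = c("sample", "template")) {
  space <- match.arg(space)
  names <- as.character(names)
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(names) != nrow(coords))
    stop("names and coords disagree in length")
  if (anyDuplicated(names))
    stop("POI names must be unique: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  if (length(coords) && any(!is.finite(coords)))
    stop("POI coordinates must be finite")
  colnames(coords) <- c("x", "y", "z")
  structure(list(names = names, coords = coords, space = space),
            class = "POISet")
}

#' @export
print.Volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Volume %d x %d x %d, spacing (%g, %g, %g) um, axes [%s]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              paste(x$axes, collapse = ",")))
  cat(sprintf("  intensity range [%g, %g], origin (%g, %g, %g) um\n",
              min(x$data), max(x$data),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
print.LabelVolume <- function(x, ...) {
  d <- dim(x$labels)
  ids <- sort(unique(as.vector(x$labels)))
  cat(sprintf("LabelVolume %d x %d x %d, spacing (%g, %g, %g) um, %d labels\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              length(setdiff(ids, 0L))))
  show <- utils::head(setdiff(ids, 0L), 12L)
  if (length(show)) cat("  ids:", paste(show, collapse = " "),
                        if (length(ids) > 13L) "..." else "", "\n")
  invisible(x)
}

#' @export
print.POISet <- function(x, ...) {
  cat(sprintf("POISet of %d points in %s space\n", length(x$names), x$space))
  if (length(x$names)) {
    df <- data.frame(name = x$names, x$coords, check.names = FALSE)
    print(utils::head(df, 10L), row.names = FALSE)
    if (length(x$names) > 10L) cat("  ...\n")
  }
  invisible(x)
}

#' @export
as.data.frame.POISet <- function(x, ...) {
  data.frame(name = x$names, x = x$coords[, 1], y = x$coords[, 2],
             z = x$coords[, 3], space = rep(x$space, length(x$names)),
             stringsAsFactors = FALSE)
}

# Grid descriptor shared by transforms/resampling: shape, spacing, origin.
vol_grid <- function(vol) {
  d <- if (inherits(vol, "LabelVolume")) dim(vol$labels) else dim(vol$data)
  list(shape = d, spacing = vol$spacing, origin = vol$origin,
       axes = vol$axes)
}

vol_array <- function(vol) {
  if (inherits(vol, "LabelVolume")) vol$labels else vol$data
}

# voxel (0-based, possibly fractional) -> physical um, n x 3 in, n x 3 out
voxel_to_phys <- function(idx, grid) {
  sweep(sweep(idx, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

phys_to_voxel <- function(pts, grid) {
  sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/")
}

#' Trilinear interpolation at fractional voxel coordinates
#'
#' @param arr 3D array.
#' @param pts n x 3 matrix of 0-based voxel coordinates.
#' @param outside value assigned to points outside the array domain.
#' @return numeric vector of length n.
#' @keywords internal
interp_trilinear <- function(arr, pts, outside = 0) {
  d <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  inside <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
    z >= 0 & z <= d[3] - 1
  out <- rep(outside, length(x))
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmax(pmin(floor(x), d[1] - 2), 0); y0 <- pmax(pmin(floor(y), d[2] - 2), 0)
  z0 <- pmax(pmin(floor(z), d[3] - 2), 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  # linear index of (x0, y0, z0), 1-based; singleton axes collapse their
  # neighbour stride (the fractional weight there is already 0)
  base <- 1 + x0 + d[1] * (y0 + d[2] * z0)
  sx <- if (d[1] > 1) 1 else 0
  sy <- if (d[2] > 1) d[1] else 0
  sz <- if (d[3] > 1) d[1] * d[2] else 0
  v <- (arr[base] * (1 - fx) + arr[base + sx] * fx) * (1 - fy) * (1 - fz) +
    (arr[base + sy] * (1 - fx) + arr[base + sx + sy] * fx) * fy * (1 - fz) +
    (arr[base + sz] * (1 - fx) + arr[base + sx + sz] * fx) * (1 - fy) * fz +
    (arr[base + sy + sz] * (1 - fx) + arr[base + sx + sy + sz] * fx) * fy * fz
  out[inside] <- v
  out
}

# Trilinear interpolation plus the exact spatial gradient of the
# interpolant (per voxel unit), for points already known to be inside.
interp_trilinear_grad <- function(arr, pts) {
  d <- dim(arr)
  x0 <- pmax(pmin(floor(pts[, 1]), d[1] - 2), 0)
  y0 <- pmax(pmin(floor(pts[, 2]), d[2] - 2), 0)
  z0 <- pmax(pmin(floor(pts[, 3]), d[3] - 2), 0)
  fx <- pts[, 1] - x0; fy <- pts[, 2] - y0; fz <- pts[, 3] - z0
  base <- 1 + x0 + d[1] * (y0 + d[2] * z0)
  sx <- if (d[1] > 1) 1 else 0
  sy <- if (d[2] > 1) d[1] else 0
  sz <- if (d[3] > 1) d[1] * d[2] else 0
  c000 <- arr[base];           c100 <- arr[base + sx]
  c010 <- arr[base + sy];      c110 <- arr[base + sx + sy]
  c001 <- arr[base + sz];      c101 <- arr[base + sx + sz]
  c011 <- arr[base + sy + sz]; c111 <- arr[base + sx + sy + sz]
  w00 <- (1 - fy) * (1 - fz); w10 <- fy * (1 - fz)
  w01 <- (1 - fy) * fz;       w11 <- fy * fz
  v <- (c000 * (1 - fx) + c100 * fx) * w00 +
    (c010 * (1 - fx) + c110 * fx) * w10 +
    (c001 * (1 - fx) + c101 * fx) * w01 +
    (c011 * (1 - fx) + c111 * fx) * w11
  gx <- (c100 - c000) * w00 + (c110 - c010) * w10 +
    (c101 - c001) * w01 + (c111 - c011) * w11
  gy <- ((c010 - c000) * (1 - fx) + (c110 - c100) * fx) * (1 - fz) +
    ((c011 - c001) * (1 - fx) + (c111 - c101) * fx) * fz
  gz <- ((c001 - c000) * (1 - fx) + (c101 - c100) * fx) * (1 - fy) +
    ((c011 - c010) * (1 - fx) + (c111 - c110) * fx) * fy
  list(v = v, g = cbind(gx, gy, gz))
}

# Nearest-neighbour lookup at fractional voxel coordinates (labels).
interp_nearest <- function(arr, pts, outside = 0L) {
  d <- dim(arr)
  i <- round(pts[, 1]); j <- round(pts[, 2]); k <- round(pts[, 3])
  inside <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 &
    k >= 0 & k <= d[3] - 1
  out <- rep(outside, nrow(pts))
  if (any(inside))
    out[inside] <- arr[1 + i[inside] + d[1] * (j[inside] + d[2] * k[inside])]
  out
}

# Separable Gaussian smoothing of a 3D array with replicate padding.
# sigma in voxels; sigma components of 0 skip that axis.
gaussian_smooth3 <- function(arr, sigma) {
  sigma <- rep_len(sigma, 3L)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, ax)
  }
  arr
}

# 1D convolution along axis `ax` with replicate edge padding.
convolve_axis <- function(arr, k, ax) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  r <- (length(k) - 1L) %/% 2L
  top <- m[rep(1L, r), , drop = FALSE]
  bot <- m[rep(nrow(m), r), , drop = FALSE]
  mp <- rbind(top, m, bot)
  # filter() runs the FIR filter down each column at C speed
  f <- stats::filter(mp, k, sides = 2)
  f <- f[(r + 1L):(r + nrow(m)), , drop = FALSE]
  out <- array(as.numeric(f), dim = da)
  aperm(out, order(perm))
}

# all voxel centres of a grid as an n x 3 matrix of 0-based indices,
# in array storage order
grid_index_matrix <- function(shape) {
  cbind(
    rep.int(seq_len(shape[1]) - 1, shape[2] * shape[3]),
    rep.int(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[3]),
    rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2])
  )
}

same_grid <- function(a, b, tol = 1e-6) {
  ga <- vol_grid(a); gb <- vol_grid(b)
  identical(ga$shape, gb$shape) &&
    all(abs(ga$spacing - gb$spacing) < tol) &&
    all(abs(ga$origin - gb$origin) < tol)
}
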