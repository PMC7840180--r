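#' Warp an atlas annotation onto the sample grid
#'
#' Applies the fitted transform to the template's integer label volume by
#' nearest-neighbour pull-back onto the sample (fixed) grid. Labels are
#' never interpolated, so the output id set is a subset of the input ids
#' plus background 0.
#'
#' @param ann template-space [LabelVolume()].
#' @param chain a [transform_chain()] fitted against this template (or a
#'   `bireg` model, whose chain is used).
#' @param sample_grid target grid (defaults to the chain's fixed grid).
#' @return sample-space [LabelVolume()].
#' @export
warp_annotation <- function(ann, chain, sample_grid = NULL) {
  stopifnot(inherits(ann, "LabelVolume"))
  if (inherits(chain, "bireg")) chain <- chain$chain
  resample(ann, chain, sample_grid)
}

#' Map sample-space data back to template space
#'
#' Inverts the fitted transform numerically (preconditioned fixed-point
#' iteration) and maps points, or resamples a sample-space volume onto the
#' template grid. This realises the reverse direction of the pipeline:
#' rendering sample structures (traced neurons, detected cells) in the
#' standard template frame.
#'
#' @param x a [POISet()], n x 3 coordinate matrix (sample space, um), or a
#'   sample-space [Volume()]/[LabelVolume()].
#' @param chain a [transform_chain()] or `bireg` model.
#' @param tol inversion tolerance in fixed-grid voxels (default 0.1).
#' @return the same kind of object in template space.
#' @export
inverse_map <- function(x, chain, tol = 0.1) {
  if (inherits(chain, "bireg")) chain <- chain$chain
  if (inherits(x, c("POISet", "matrix")))
    return(invert_points(chain, x, tol = tol))
  stopifnot(inherits(x, c("Volume", "LabelVolume")))
  grid <- chain$moving_grid
  arr <- vol_array(x)
  sg <- list(shape = dim(arr), spacing = x$spacing, origin = x$origin)
  is_label <- inherits(x, "LabelVolume")
  out <- numeric(prod(grid$shape))
  nxy <- grid$shape[1] * grid$shape[2]
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
    spts <- invert_points(chain, pts, tol = tol, max_fail_frac = 0.01)
    svox <- phys_to_voxel(spts, sg)
    vals <- if (is_label) interp_nearest(arr, svox, 0L)
            else interp_trilinear(arr, svox, 0)
    out[(z0 * nxy + 1):((z0 + nz) * nxy)] <- vals
    z0 <- z0 + nz
  }
  out <- array(out, dim = grid$shape)
  if (is_label)
    LabelVolume(out, grid$spacing, x$axes, grid$origin,
                id_to_name = x$id_to_name)
  else Volume(out, grid$spacing, x$axes, grid$origin)
}

#' Restore an annotation to the native acquisition grid
#'
#' Inverts the preprocessing (per-sub-stack dynamic z-reslicing and lateral
#' block down-sampling) by nearest-neighbour up-sampling, so the 20 um
#' annotation can be overlaid on the raw-resolution stack (e.g. 1 x 1 x
#' 10 um). Native slices before the first or after the last landmark plane
#' map to background.
#'
#' @param ann20 sample-space [LabelVolume()] on the preprocessed grid.
#' @param recipe the [substack_steps()] recipe used during preprocessing.
#' @param native_shape dimensions of the native stack.
#' @param native_spacing voxel spacing (um) of the native stack.
#' @return native-grid [LabelVolume()].
#' @export
restore_native <- function(ann20, recipe, native_shape,
                           native_spacing = c(1, 1, 10)) {
  stopifnot(inherits(ann20, "LabelVolume"),
            inherits(recipe, "resample_recipe"))
  d <- dim(ann20$labels)
  native_shape <- as.integer(native_shape)
  f <- recipe$lateral_factor
  if (ceiling(native_shape[1] / f) != d[1] ||
      ceiling(native_shape[2] / f) != d[2])
    stop("recipe lateral factor inconsistent with native grid (",
         native_shape[1], "x", native_shape[2], " / ", f,
         " vs ", d[1], "x", d[2], ")")
  K <- length(recipe$step_per_substack)
  # native slice j (0-based) -> z index in the resliced stack
  zmap <- rep(NA_integer_, native_shape[3])
  for (k in seq_len(K)) {
    lo <- ceiling(recipe$b[k])
    hi <- if (k < K) ceiling(recipe$b[k + 1]) - 1 else floor(recipe$b[k + 1])
    hi <- min(hi, native_shape[3] - 1)
    if (lo > hi) next
    jr <- seq.int(lo, hi)
    t <- (recipe$c[k] - recipe$c[1]) +
      (jr - recipe$b[k]) / recipe$step_per_substack[k]
    zmap[jr + 1] <- pmin(pmax(round(t), 0L), d[3] - 1L) + 1L
  }
  ix <- pmin((seq_len(native_shape[1]) - 1L) %/% f + 1L, d[1])
  iy <- pmin((seq_len(native_shape[2]) - 1L) %/% f + 1L, d[2])
  out <- array(0L, dim = native_shape)
  for (j in seq_len(native_shape[3])) {
    if (is.na(zmap[j])) next
    out[, , j] <- ann20$labels[ix, iy, zmap[j]]
  }
  LabelVolume(out, native_spacing, ann20$axes,
              origin = c(ann20$origin[1] - (f - 1) / 2 * native_spacing[1],
                         ann20$origin[2] - (f - 1) / 2 * native_spacing[2],
                         0),
              id_to_name = ann20$id_to_name)
}

#' Read a region hierarchy from an Allen-style structure graph JSON
#'
#' Only `id`, `acronym` and `parent_structure_id` (or `parent_id`) are
#' consumed; children arrays are flattened recursively.
#'
#' @param path JSON file path.
#' @return data.frame with columns `id`, `acronym`, `parent_id`.
#' @export
read_hierarchy <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"),
                            simplifyVector = FALSE)
  if (!is.null(obj$msg)) obj <- obj$msg
  if (!is.null(obj$id)) obj <- list(obj)
  rows <- list()
  walk <- function(node, parent) {
    pid <- node$parent_structure_id
    if (is.null(pid)) pid <- node$parent_id
    if (is.null(pid)) pid <- parent
    rows[[length(rows) + 1L]] <<- data.frame(
      id = as.integer(node$id),
      acronym = as.character(node$acronym),
      parent_id = if (is.null(pid)) NA_integer_ else as.integer(pid))
    for (child in node$children) walk(child, node$id)
  }
  for (node in obj) walk(node, NULL)
  do.call(rbind, rows)
}

#' Assemble a 3D digital map of an annotated brain
#'
#' Bundles the sample-space annotation with per-region triangle surfaces
#' (see [build_surfaces()]) and an optional region hierarchy.
#'
#' @param ann sample-space [LabelVolume()].
#' @param labels label ids to mesh (default: all nonzero ids present).
#' @param hierarchy optional data.frame from [read_hierarchy()].
#' @param ... passed to [build_surfaces()].
#' @return object of class `digital_map`.
#' @export
digital_map <- function(ann, labels = NULL, hierarchy = NULL, ...) {
  stopifnot(inherits(ann, "LabelVolume"))
  if (is.null(labels)) labels <- setdiff(sort(unique(as.vector(ann$labels))),
                                         0L)
  meshes <- build_surfaces(ann, labels, ...)
  structure(list(annotation = ann, meshes = meshes, hierarchy = hierarchy),
            class = "digital_map")
}

#' @export
print.digital_map <- function(x, ...) {
  cat(sprintf("digital_map: %d region meshes\n", length(x$meshes)))
  for (nm in names(x$meshes)) {
    m <- x$meshes[[nm]]
    cat(sprintf("  label %s: %d vertices, %d faces\n", nm,
                nrow(m$vertices), nrow(m$faces)))
  }
  invisible(x)
}
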