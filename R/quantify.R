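#' Region volumes from an annotation
#'
#' `volume(id) = voxel_count(id) * sx * sy * sz * 1e-9` mm^3.
#'
#' @param ann a [LabelVolume()] with known spacing.
#' @param ids label ids; default all nonzero ids present.
#' @return named numeric vector of volumes in mm^3 (0 for absent ids,
#'   with a message).
#' @export
region_volumes <- function(ann, ids = NULL) {
  stopifnot(inherits(ann, "LabelVolume"))
  if (is.null(ids))
    ids <- setdiff(sort(unique(as.vector(ann$labels))), 0L)
  vox_mm3 <- prod(ann$spacing) * 1e-9
  counts <- tabulate(ann$labels[ann$labels > 0L], nbins = max(c(ids, 1L)))
  out <- vapply(ids, function(id) {
    n <- if (id <= length(counts)) counts[id] else 0L
    if (n == 0L) message("label ", id, " absent from annotation")
    n * vox_mm3
  }, numeric(1))
  names(out) <- as.character(ids)
  out
}

#' Assign object centroids to annotated regions
#'
#' Each point is assigned the label of its containing voxel
#' (floor-to-voxel under the voxel-centre convention, i.e. nearest voxel
#' centre); points falling on background count under id 0 and points
#' outside the volume under `"outside"`.
#'
#' @param points a [POISet()] or n x 3 matrix of physical um coordinates
#'   in sample space (e.g. detected cell centroids).
#' @param ann sample-space [LabelVolume()].
#' @return named integer vector of counts per label id, plus elements
#'   `"0"` (background) and `"outside"`; the total equals the number of
#'   points.
#' @export
count_per_region <- function(points, ann) {
  stopifnot(inherits(ann, "LabelVolume"))
  pts <- if (inherits(points, "POISet")) points$coords else as.matrix(points)
  g <- vol_grid(ann)
  vox <- phys_to_voxel(pts, g)
  d <- g$shape
  i <- round(vox[, 1]); j <- round(vox[, 2]); k <- round(vox[, 3])
  inside <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 &
    k >= 0 & k <= d[3] - 1
  lab <- rep(NA_integer_, nrow(pts))
  lab[inside] <- ann$labels[1 + i[inside] + d[1] * (j[inside] +
                                                      d[2] * k[inside])]
  ids <- sort(unique(lab[!is.na(lab)]))
  out <- vapply(ids, function(id) sum(lab == id, na.rm = TRUE), integer(1))
  names(out) <- as.character(ids)
  c(out, outside = sum(!inside))
}

#' Object density per region
#'
#' @param counts named counts per region id (as from
#'   [count_per_region()]).
#' @param volumes named volumes in mm^3 (as from [region_volumes()]).
#' @return named densities (mm^-3) over the ids present in `volumes`;
#'   ids with zero volume are reported `NA` (missing).
#' @export
density_per_region <- function(counts, volumes) {
  ids <- names(volumes)
  out <- vapply(ids, function(id) {
    v <- volumes[[id]]
    if (v <= 0) return(NA_real_)
    n <- if (id %in% names(counts)) counts[[id]] else 0
    n / v
  }, numeric(1))
  names(out) <- ids
  out
}

#' Normalised projection strengths
#'
#' Axon length per target region normalised to the length in a reference
#' region (e.g. VIS), so the reference maps to 1.
#'
#' @param lengths named axon lengths (um) per region id/acronym.
#' @param reference_id name of the reference region.
#' @return named dimensionless strengths.
#' @export
projection_strength <- function(lengths, reference_id) {
  reference_id <- as.character(reference_id)
  if (!reference_id %in% names(lengths))
    stop("reference region ", reference_id, " absent from lengths")
  ref <- lengths[[reference_id]]
  if (!is.finite(ref) || ref <= 0)
    stop("reference region ", reference_id, " has non-positive length")
  out <- unlist(lengths) / ref
  out
}

#' Per-region axon lengths of a traced polyline
#'
#' Length is the sum of segment lengths; each segment is assigned to the
#' region containing its midpoint voxel.
#'
#' @param polyline n x 3 matrix of ordered physical um coordinates (a
#'   traced neuron path), or a data.frame with columns x, y, z.
#' @param ann sample-space [LabelVolume()]; region names from its
#'   `id_to_name` map when present, else the ids.
#' @return named lengths (um) per region (background under `"0"`,
#'   segments outside the volume under `"outside"`).
#' @export
axon_region_lengths <- function(polyline, ann) {
  stopifnot(inherits(ann, "LabelVolume"))
  if (is.data.frame(polyline))
    polyline <- as.matrix(polyline[, c("x", "y", "z")])
  if (nrow(polyline) < 2) stop("polyline needs at least 2 points")
  a <- polyline[-nrow(polyline), , drop = FALSE]
  b <- polyline[-1, , drop = FALSE]
  seglen <- sqrt(rowSums((b - a)^2))
  mid <- (a + b) / 2
  g <- vol_grid(ann)
  vox <- phys_to_voxel(mid, g)
  d <- g$shape
  i <- round(vox[, 1]); j <- round(vox[, 2]); k <- round(vox[, 3])
  inside <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 &
    k >= 0 & k <= d[3] - 1
  lab <- rep("outside", length(seglen))
  lin <- 1 + i[inside] + d[1] * (j[inside] + d[2] * k[inside])
  ids <- ann$labels[lin]
  nm <- as.character(ids)
  if (!is.null(ann$id_to_name)) {
    mapped <- ann$id_to_name[nm]
    nm <- ifelse(is.na(mapped), nm, mapped)
  }
  lab[inside] <- nm
  tapply(seglen, lab, sum)
}

#' Read an SWC neuron reconstruction as a coordinate polyline
#'
#' Minimal SWC support: columns id, type, x, y, z, radius, parent; rows
#' are returned in file order as an n x 3 um matrix (scaled by `scale`).
#'
#' @param path SWC file path.
#' @param scale multiplier applied to coordinates (default 1).
#' @return n x 3 matrix of coordinates.
#' @export
read_swc <- function(path, scale = 1) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  df <- utils::read.table(text = lines)
  if (ncol(df) < 7) stop("not an SWC file: ", path)
  unname(as.matrix(df[, 3:5])) * scale
}

#' Region-wise statistics table
#'
#' Convenience wrapper combining [region_volumes()], [count_per_region()]
#' and [density_per_region()] into one data.frame.
#'
#' @param ann sample-space [LabelVolume()].
#' @param points object centroids ([POISet()] or matrix), optional.
#' @param ids label ids (default all nonzero present).
#' @return data.frame with id, acronym (when known), volume_mm3, count,
#'   density_per_mm3.
#' @export
region_stats <- function(ann, points = NULL, ids = NULL) {
  if (is.null(ids))
    ids <- setdiff(sort(unique(as.vector(ann$labels))), 0L)
  vols <- region_volumes(ann, ids)
  counts <- if (is.null(points)) NULL else count_per_region(points, ann)
  dens <- if (is.null(counts)) NULL else density_per_region(counts, vols)
  acro <- if (!is.null(ann$id_to_name))
    unname(ann$id_to_name[as.character(ids)]) else NA_character_
  data.frame(
    id = ids,
    acronym = acro,
    volume_mm3 = unname(vols),
    count = if (is.null(counts)) NA_integer_ else
      vapply(as.character(ids), function(id)
        if (id %in% names(counts)) counts[[id]] else 0L, integer(1)),
    density_per_mm3 = if (is.null(dens)) NA_real_ else unname(dens)
  )
}
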