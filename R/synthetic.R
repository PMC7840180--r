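#' Specification of a synthetic brain phantom
#'
#' The phantom emulates the structure the registration pipeline assumes: a
#' smooth nested-region "brain" (lobed ellipsoid shells with per-region
#' intensities and texture), a known smooth invertible B-spline
#' deformation, optional non-uniform anterior-posterior stretching into a
#' raw-style stack, a monotone intensity remapping simulating the
#' modality difference between sample and template, additive Gaussian
#' noise, and ground-truth fiducial points on region boundaries.
#'
#' @param shape voxel dimensions (default 64^3; 128^3 for full-pipeline
#'   evaluation runs).
#' @param spacing voxel spacing in um (default isotropic 20, the template
#'   grid).
#' @param n_regions number of nested labelled regions (default 4).
#' @param deform_max maximum displacement of the ground-truth B-spline
#'   field, in voxels (default 6).
#' @param z_stretch per-sub-stack stretch factors (> 0) building the
#'   raw-style stack; `NULL` skips the stretching step.
#' @param intensity_map monotone function simulating the modality
#'   intensity difference (default `v^0.7` on normalised intensities).
#' @param noise_sd additive Gaussian noise as a fraction of the dynamic
#'   range (default 0.1).
#' @param n_pois number of boundary fiducials (default 20).
#' @param seed RNG seed; a fixed seed makes the phantom byte-identical.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(20, 20, 20),
                         n_regions = 4L, deform_max = 6,
                         z_stretch = NULL,
                         intensity_map = function(v) v^0.7,
                         noise_sd = 0.1, n_pois = 20L, seed = 17L) {
  if (deform_max < 0) stop("deform_max must be >= 0")
  if (!is.null(z_stretch) && any(z_stretch <= 0))
    stop("z_stretch factors must be > 0")
  if (any(shape < 16)) stop("phantom shape must be >= 16 per axis")
  if (n_regions < 1 || n_regions > 8)
    stop("n_regions outside the packable range 1..8")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_regions = as.integer(n_regions),
                 deform_max = deform_max, z_stretch = z_stretch,
                 intensity_map = intensity_map, noise_sd = noise_sd,
                 n_pois = as.integer(n_pois), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate the atlas side of a phantom
#'
#' Builds a lobed-ellipsoid "brain" of `n_regions` nested labels, a
#' template intensity volume with per-region base levels, band-passed
#' texture and softened edges, and `n_pois` fiducial points spread over
#' region boundaries. Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with `template` ([Volume()]), `annotation`
#'   ([LabelVolume()]) and `pois` ([POISet()], template space).
#' @export
make_atlas_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  ctr <- (d - 1) / 2
  rad <- c(0.42, 0.36, 0.44) * d
  x <- (seq_len(d[1]) - 1 - ctr[1]) / rad[1]
  y <- (seq_len(d[2]) - 1 - ctr[2]) / rad[2]
  z <- (seq_len(d[3]) - 1 - ctr[3]) / rad[3]
  X <- array(rep(x, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(z, each = d[1] * d[2]), dim = d)
  rho <- sqrt(X^2 + Y^2 + Z^2)
  theta <- atan2(Y, X)
  phi <- atan2(Z, sqrt(X^2 + Y^2))
  # lobed modulation keeps the shells nested but non-spherical; the mixed
  # angular orders leave no exact rotational symmetry (an exactly
  # symmetric phantom would make the rigid stage ill-posed, which no
  # real brain is)
  rho <- rho * (1 + 0.10 * sin(theta + 0.7) * cos(phi) +
                  0.06 * sin(2 * theta) * sin(phi + 0.4) +
                  0.05 * cos(3 * phi))
  labels <- array(0L, dim = d)
  inside <- rho <= 1
  labels[inside] <- pmin(ceiling(rho[inside] * spec$n_regions),
                         spec$n_regions)
  labels[inside & labels == 0L] <- 1L
  base_levels <- rep(c(0.85, 0.40, 0.65, 0.30, 0.75, 0.50, 0.60, 0.35),
                     length.out = spec$n_regions)
  intens <- array(0, dim = d)
  for (r in seq_len(spec$n_regions))
    intens[labels == r] <- base_levels[r]
  # band-passed texture: difference of smoothed white noise
  wn <- array(stats::rnorm(prod(d)), dim = d)
  tex <- gaussian_smooth3(wn, c(1.2, 1.2, 1.2)) -
    gaussian_smooth3(wn, c(3, 3, 3))
  tex <- tex / max(abs(tex))
  intens[inside] <- intens[inside] + 0.08 * tex[inside]
  intens <- gaussian_smooth3(intens, c(0.8, 0.8, 0.8))
  intens <- pmin(pmax(intens, 0), 1)
  template <- Volume(intens, spec$spacing)
  annotation <- LabelVolume(labels, spec$spacing)
  pois <- boundary_pois(annotation, spec$n_pois)
  list(template = template, annotation = annotation, pois = pois)
}

# spread n fiducials over label boundaries (greedy min-distance thinning
# of a seeded random ordering); coordinates in um, template space
boundary_pois <- function(annotation, n) {
  lab <- annotation$labels
  d <- dim(lab)
  inner <- lab[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  isb <- (inner != lab[1:(d[1] - 2), 2:(d[2] - 1), 2:(d[3] - 1)]) |
    (inner != lab[3:d[1], 2:(d[2] - 1), 2:(d[3] - 1)]) |
    (inner != lab[2:(d[1] - 1), 1:(d[2] - 2), 2:(d[3] - 1)]) |
    (inner != lab[2:(d[1] - 1), 3:d[2], 2:(d[3] - 1)]) |
    (inner != lab[2:(d[1] - 1), 2:(d[2] - 1), 1:(d[3] - 2)]) |
    (inner != lab[2:(d[1] - 1), 2:(d[2] - 1), 3:d[3]])
  isb <- isb & inner != 0L   # boundary voxels inside the brain
  idx <- which(isb)
  sub <- linear_to_index(idx, d - 2L) + 1L  # back to full-grid 0-based
  ord <- sample(nrow(sub))
  min_d2 <- (min(d) / 8)^2
  picked <- matrix(0, 0, 3)
  for (r in ord) {
    p <- sub[r, ]
    if (nrow(picked) &&
        min(rowSums(sweep(picked, 2, p, "-")^2)) < min_d2) next
    picked <- rbind(picked, p)
    if (nrow(picked) >= n) break
  }
  coords <- voxel_to_phys(picked, vol_grid(annotation))
  POISet(sprintf("poi%02d", seq_len(nrow(picked))), coords, "template")
}

#' Generate the sample side of a phantom with known ground truth
#'
#' Applies, in order: (i) a random smooth cubic B-spline displacement
#' field with positive Jacobian and maximum magnitude `deform_max`
#' voxels; (ii) optional per-sub-stack z stretching into a raw-style
#' stack with its matching landmark table; (iii) the monotone intensity
#' remap plus additive Gaussian noise. Everything needed for end-to-end
#' scoring is returned: the true transform chain (mapping sample-frame
#' points to template-frame points, the same direction a fitted
#' registration estimates), the deformed labels, and the fiducials mapped
#' into the sample frame.
#'
#' @param atlas output of [make_atlas_phantom()].
#' @param spec the same [phantom_spec()].
#' @return list with `sample` (template-grid modality phantom,
#'   [Volume()]), `labels_true` (deformed ground-truth labels),
#'   `pois_sample` (fiducials in the sample frame), `chain_true` (the
#'   generating [transform_chain()]), and — when `z_stretch` is set —
#'   `raw_stack` (the stretched raw-style stack), `landmarks`
#'   ([landmark_table()]) whose recipe undoes the stretch.
#' @export
make_sample_from_atlas <- function(atlas, spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed + 1L)
  template <- atlas$template
  grid <- vol_grid(template)
  chain <- transform_chain(grid, grid)
  if (spec$deform_max > 0) {
    chain$bspline <- random_bspline_field(grid, spec$deform_max)
  }
  deformed <- resample(template, chain)
  labels_true <- resample(atlas$annotation, chain)
  pois_sample <- if (length(atlas$pois$names))
    invert_points(chain, atlas$pois, tol = 1e-7, max_iter = 300)
  else atlas$pois
  v <- deformed$data
  rng <- range(v)
  if (diff(rng) > 0) v <- (v - rng[1]) / diff(rng)
  if (!is.null(spec$intensity_map)) v <- spec$intensity_map(v)
  if (spec$noise_sd > 0)
    v <- v + stats::rnorm(length(v), sd = spec$noise_sd * diff(range(v)))
  sample_vol <- Volume(array(v, dim = grid$shape), grid$spacing,
                       template$axes, grid$origin)
  out <- list(sample = sample_vol, labels_true = labels_true,
              pois_sample = pois_sample, chain_true = chain)
  if (!is.null(spec$z_stretch)) {
    st <- stretch_stack(sample_vol, spec$z_stretch)
    out$raw_stack <- st$raw
    out$landmarks <- st$landmarks
  }
  out
}

# random smooth B-spline displacement field over `grid`, max |d| scaled to
# deform_max voxels, Jacobian determinant kept strictly positive
random_bspline_field <- function(grid, deform_max_vox) {
  bs <- bspline_stage(grid, spacing_vox = max(12, min(grid$shape) %/% 4))
  coef <- array(stats::rnorm(prod(bs$nc) * 3), dim = c(bs$nc, 3))
  for (dd in 1:3) coef[, , , dd] <- gaussian_smooth3(coef[, , , dd],
                                                     c(1, 1, 1))
  bs$coef <- matrix(coef, ncol = 3)
  # scale to the requested maximum displacement (um)
  probe <- grid_index_matrix(pmin(grid$shape, 48L))
  probe <- sweep(probe, 2, (grid$shape - 1) / pmax(pmin(grid$shape, 48L) - 1,
                                                   1), "*")
  ppts <- voxel_to_phys(probe, grid)
  dmax_um <- deform_max_vox * min(grid$spacing)
  repeat {
    disp <- bspline_displacement(bs, ppts)
    mx <- max(sqrt(rowSums(disp^2)))
    bs$coef <- bs$coef * (dmax_um / mx)
    if (min_jacobian(bs, ppts) > 0.05) break
    message("phantom field near-folding; reducing amplitude")
    dmax_um <- dmax_um * 0.8
  }
  bs
}

# minimum Jacobian determinant of x + D(x) over probe points
min_jacobian <- function(bs, pts, h = 2) {
  J <- array(0, dim = c(nrow(pts), 3, 3))
  for (dd in 1:3) {
    e <- matrix(0, nrow(pts), 3); e[, dd] <- h
    dp <- (bspline_displacement(bs, pts + e) -
             bspline_displacement(bs, pts - e)) / (2 * h)
    J[, , dd] <- dp
    J[, dd, dd] <- J[, dd, dd] + 1
  }
  det3 <- J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
    J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
    J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
  min(det3)
}

# stretch the z axis per sub-stack into a raw-style stack and return the
# landmark table whose recipe exactly undoes it
stretch_stack <- function(vol, z_stretch) {
  d <- dim(vol$data)
  K <- length(z_stretch)
  # template sub-stack boundaries: c_i = 5 a_i - 2 with equal 5m-deep
  # sub-stacks inside the usable range [3, 3 + 5mK]
  m <- (d[3] - 3 - 1) %/% (5 * K)
  if (m < 1) stop("stack too shallow for ", K, " sub-stacks")
  a <- 1 + (0:K) * m
  cc <- 5 * a - 2
  b <- c(0, cumsum(round(diff(cc) * z_stretch)))
  lm <- landmark_table(a, b)
  nraw <- b[K + 1] + 1
  out <- array(0, dim = c(d[1], d[2], nraw))
  l_k <- diff(b) / diff(cc)
  for (j in 0:(nraw - 1)) {
    k <- findInterval(j, b, rightmost.closed = TRUE)
    k <- min(max(k, 1L), K)
    t <- cc[k] + (j - b[k]) / l_k[k]     # template z coordinate
    t0 <- min(max(floor(t), 0), d[3] - 2)
    ft <- t - t0
    out[, , j + 1] <- vol$data[, , t0 + 1] * (1 - ft) +
      vol$data[, , t0 + 2] * ft
  }
  raw <- Volume(out, spacing = c(vol$spacing[1], vol$spacing[2],
                                 vol$spacing[3] / mean(l_k)),
                axes = vol$axes, origin = c(vol$origin[1], vol$origin[2], 0))
  list(raw = raw, landmarks = lm)
}
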