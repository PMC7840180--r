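#' Mutual-information estimator settings
#'
#' @param n_bins histogram bins per image (regularly spaced intensity bin
#'   centres; >= 8).
#' @param n_samples spatial samples per cost evaluation; 0 means all
#'   voxels. Full sampling is used automatically for levels at or below
#'   `full_sample_below` voxels.
#' @param parzen_order Parzen window order for the moving image: 0 (hard
#'   binning, exactly the discrete joint-histogram estimator) or 3 (cubic
#'   B-spline window, the smooth estimator used during optimisation). The
#'   fixed image is always hard-binned.
#' @param full_sample_below voxel-count threshold under which every voxel
#'   is used regardless of `n_samples`.
#' @return object of class `mi_settings`.
#' @export
mi_settings <- function(n_bins = 32L, n_samples = 8192L, parzen_order = 3L,
                        full_sample_below = 32768L) {
  if (n_bins < 8) stop("need n_bins >= 8")
  if (!parzen_order %in% c(0L, 3L)) stop("parzen_order must be 0 or 3")
  structure(list(n_bins = as.integer(n_bins),
                 n_samples = as.integer(n_samples),
                 parzen_order = as.integer(parzen_order),
                 full_sample_below = as.integer(full_sample_below)),
            class = "mi_settings")
}

# hard bin index in 0..nb-1
hard_bins <- function(v, rng, nb) {
  w <- diff(rng)
  if (w <= 0) return(rep(0L, length(v)))
  b <- floor((v - rng[1]) / w * nb)
  as.integer(pmin(pmax(b, 0), nb - 1))
}

# cubic B-spline Parzen kernel and derivative
beta3 <- function(u) {
  au <- abs(u)
  ifelse(au <= 1, (4 - 6 * au^2 + 3 * au^3) / 6,
         ifelse(au <= 2, (2 - au)^3 / 6, 0))
}

beta3_deriv <- function(u) {
  au <- abs(u)
  ifelse(au <= 1, -2 * u + 1.5 * u * au,
         ifelse(au <= 2, -sign(u) * (2 - au)^2 / 2, 0))
}

# continuous bin coordinate for the cubic window; support stays inside
# [0, nb-1] because e is scaled into [2, nb-3]
parzen_coord <- function(v, rng, nb) {
  w <- diff(rng) / (nb - 5)
  if (w <= 0) return(rep(2, length(v)))
  2 + (v - rng[1]) / w
}

# Accumulate the joint histogram (nb x nb, fixed index rows) from paired
# samples. Returns unnormalised weights summing to length(fv).
joint_hist <- function(fv, mv, rng_f, rng_m, nb, parzen_order) {
  fb <- hard_bins(fv, rng_f, nb)
  H <- matrix(0, nb, nb)
  if (parzen_order == 0L) {
    mb <- hard_bins(mv, rng_m, nb)
    idx <- 1L + fb + nb * mb
    tab <- rowsum(rep(1, length(idx)), idx)
    H[as.integer(rownames(tab))] <- tab
  } else {
    e <- parzen_coord(mv, rng_m, nb)
    m0 <- floor(e)
    idx_all <- integer(0); w_all <- numeric(0)
    for (j in -1:2) {
      mb <- as.integer(pmin(pmax(m0 + j, 0), nb - 1))
      wj <- beta3(e - (m0 + j))
      idx_all <- c(idx_all, 1L + fb + nb * mb)
      w_all <- c(w_all, wj)
    }
    tab <- rowsum(w_all, idx_all)
    H[as.integer(rownames(tab))] <- tab
  }
  H
}

mi_from_hist <- function(H) {
  n <- sum(H)
  if (n <= 0) return(0)
  p <- H / n
  pf <- rowSums(p); pm <- colSums(p)
  nz <- p > 0
  outer_fm <- outer(pf, pm)
  sum(p[nz] * log2(p[nz] / outer_fm[nz]))
}

#' Negative mutual information between two volumes under a transform
#'
#' Builds the joint intensity histogram of the fixed image against the
#' transform-resampled moving image over sampled fixed voxels, normalises
#' it to a discrete joint probability, and returns minus the mutual
#' information in bits (lower is better, so that registration is a
#' minimisation). With `parzen_order = 0` and full sampling this is
#' exactly the discrete joint-histogram MI.
#'
#' @param fixed,moving [Volume()]s.
#' @param chain a [transform_chain()] (identity by default).
#' @param s an [mi_settings()].
#' @return negative MI in bits.
#' @export
mutual_information <- function(fixed, moving, chain = NULL,
                               s = mi_settings()) {
  stopifnot(inherits(fixed, "Volume"), inherits(moving, "Volume"))
  fg <- vol_grid(fixed)
  if (is.null(chain)) chain <- transform_chain(fg, vol_grid(moving))
  nvox <- prod(fg$shape)
  use_all <- s$n_samples == 0L || nvox <= max(s$full_sample_below,
                                              s$n_samples)
  if (use_all) {
    idx <- grid_index_matrix(fg$shape)
    fv <- as.vector(fixed$data)
  } else {
    lin <- sample.int(nvox, s$n_samples)
    idx <- linear_to_index(lin, fg$shape)
    fv <- fixed$data[lin]
  }
  if (nrow(idx) < s$n_bins^2 / 10)
    warning("fewer samples than n_bins^2/10; MI estimate will be noisy")
  pts <- voxel_to_phys(idx, fg)
  mg <- vol_grid(moving)
  mvox <- phys_to_voxel(transform_points(chain, pts), mg)
  d <- mg$shape
  inside <- mvox[, 1] >= 0 & mvox[, 1] <= d[1] - 1 &
    mvox[, 2] >= 0 & mvox[, 2] <= d[2] - 1 &
    mvox[, 3] >= 0 & mvox[, 3] <= d[3] - 1
  if (!any(inside))
    stop("empty overlap between fixed domain and warped moving domain")
  mv <- interp_trilinear(moving$data, mvox[inside, , drop = FALSE])
  fv <- fv[inside]
  H <- joint_hist(fv, mv, range(fixed$data), range(moving$data),
                  s$n_bins, s$parzen_order)
  -mi_from_hist(H)
}

linear_to_index <- function(lin, shape) {
  lin0 <- lin - 1L
  i <- lin0 %% shape[1]
  j <- (lin0 %/% shape[1]) %% shape[2]
  k <- lin0 %/% (shape[1] * shape[2])
  cbind(i, j, k)
}

#' Channel set for bi-channel registration
#'
#' Pairs N fixed-image channels (experimental data: raw, grayscale
#' reversal, phase congruency) with the corresponding N moving-image
#' channels (template side), plus the per-channel weights of the combined
#' cost. All fixed channels must share one grid, and likewise the moving
#' channels.
#'
#' @param fixed,moving lists of [Volume()]s of equal length N.
#' @param weights non-negative channel weights `omega_i` (recycled); at
#'   least one must be positive.
#' @return object of class `channel_set`.
#' @export
channel_set <- function(fixed, moving, weights = 1) {
  if (inherits(fixed, "Volume")) fixed <- list(fixed)
  if (inherits(moving, "Volume")) moving <- list(moving)
  if (length(fixed) != length(moving))
    stop("fixed and moving channel counts differ")
  if (!length(fixed)) stop("need at least one channel")
  for (v in c(fixed, moving)) stopifnot(inherits(v, "Volume"))
  for (v in fixed[-1]) if (!same_grid(fixed[[1]], v))
    stop("all fixed channels must share one grid")
  for (v in moving[-1]) if (!same_grid(moving[[1]], v))
    stop("all moving channels must share one grid")
  weights <- rep_len(as.numeric(weights), length(fixed))
  if (any(weights < 0)) stop("channel weights must be >= 0")
  if (sum(weights) <= 0) stop("at least one channel weight must be positive")
  structure(list(fixed = fixed, moving = moving, weights = weights),
            class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("channel_set: N = %d channels, weights (%s)\n",
              length(x$fixed), paste(x$weights, collapse = ", ")))
  invisible(x)
}

#' Weighted multi-channel registration cost
#'
#' The single cost driving bi-channel registration: the weight-normalised
#' mean of the per-channel negative-MI costs,
#' `c = (1 / sum_i omega_i) * sum_i omega_i * c_i`.
#'
#' @param ch a [channel_set()].
#' @param chain a [transform_chain()].
#' @param s an [mi_settings()].
#' @return combined cost (negative MI, bits).
#' @export
bichannel_cost <- function(ch, chain = NULL, s = mi_settings()) {
  stopifnot(inherits(ch, "channel_set"))
  costs <- vapply(seq_along(ch$fixed), function(i) {
    if (ch$weights[i] == 0) return(0)
    mutual_information(ch$fixed[[i]], ch$moving[[i]], chain, s)
  }, numeric(1))
  sum(ch$weights * costs) / sum(ch$weights)
}
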