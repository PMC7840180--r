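#' Parameters of the phase-congruency filter bank
#'
#' Phase congruency marks the points where the local Fourier components are
#' maximally in phase, which makes it a contrast-invariant detector of
#' edges, lines and texture. The computation uses a 2D log-Gabor quadrature
#' filter bank applied slice-by-slice.
#'
#' @param n_scales number of log-Gabor wavelengths (>= 2).
#' @param n_orients number of filter orientations (>= 3).
#' @param min_wavelength smallest filter wavelength in voxels.
#' @param scale_mult wavelength multiplier between successive scales.
#' @param sigma_onf log-Gabor bandwidth parameter (ratio of the Gaussian
#'   sigma to filter centre frequency, on a log axis).
#' @param noise_k noise threshold in multiples of the smallest-scale
#'   filter's median amplitude response.
#' @param epsilon small positive stabiliser in the normalising denominator
#'   (default 0.01).
#' @param cutoff,g frequency-spread sigmoid weighting: filter-response
#'   spread below `cutoff` is penalised with gain `g`.
#' @return object of class `pc_params`.
#' @export
pc_params <- function(n_scales = 4L, n_orients = 6L, min_wavelength = 3,
                      scale_mult = 2.1, sigma_onf = 0.55, noise_k = 2,
                      epsilon = 0.01, cutoff = 0.4, g = 10) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (n_scales < 2) stop("need n_scales >= 2")
  if (n_orients < 3) stop("need n_orients >= 3")
  structure(list(n_scales = as.integer(n_scales),
                 n_orients = as.integer(n_orients),
                 min_wavelength = min_wavelength, scale_mult = scale_mult,
                 sigma_onf = sigma_onf, noise_k = noise_k,
                 epsilon = epsilon, cutoff = cutoff, g = g),
            class = "pc_params")
}

#' Huang's fuzzy threshold
#'
#' Finds the intensity threshold minimising the Huang & Wang fuzzy entropy
#' `sum_g h(g) * S(mu(g))`, where the membership of grey level g to its side
#' of the threshold is `mu(g) = 1 / (1 + |g - m_side(g)| / C)`, `m_side` the
#' conditional mean of the assigned side, `C` the intensity range, and `S`
#' the Shannon pair entropy. Deterministic; used to separate tissue signal
#' from background before feature extraction.
#'
#' @param vol a [Volume()] or numeric array.
#' @param n_levels histogram resolution for non-integer data (default 256).
#' @return threshold t on the intensity scale; voxels `< t` are background.
#' @export
huang_threshold <- function(vol, n_levels = 256L) {
  x <- if (inherits(vol, "Volume")) vol$data else vol
  rng <- range(x)
  if (diff(rng) == 0)
    stop("degenerate input: constant volume has no threshold")
  intish <- all(x == round(x)) && diff(rng) <= 4096
  if (intish) {
    levels <- seq(rng[1], rng[2])
    h <- tabulate(as.integer(x - rng[1]) + 1L, nbins = length(levels))
  } else {
    n_levels <- as.integer(n_levels)
    br <- seq(rng[1], rng[2], length.out = n_levels + 1L)
    levels <- (br[-1] + br[-length(br)]) / 2
    bin <- pmin(floor((x - rng[1]) / diff(rng) * n_levels) + 1L, n_levels)
    h <- tabulate(bin, nbins = n_levels)
  }
  nz <- which(h > 0)
  g1 <- nz[1]; g2 <- nz[length(nz)]
  C <- levels[g2] - levels[g1]
  csum_h <- cumsum(h)
  csum_hg <- cumsum(h * levels)
  n <- csum_h[length(h)]
  total_hg <- csum_hg[length(h)]
  shannon <- function(mu) {
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -mu * log(mu) - (1 - mu) * log(1 - mu)
  }
  best <- Inf; best_t <- g1
  for (t in g1:(g2 - 1L)) {
    m0 <- csum_hg[t] / csum_h[t]
    n1 <- n - csum_h[t]
    if (n1 == 0) next
    m1 <- (total_hg - csum_hg[t]) / n1
    lo <- 1:t; hi <- (t + 1L):length(h)
    mu_lo <- 1 / (1 + abs(levels[lo] - m0) / C)
    mu_hi <- 1 / (1 + abs(levels[hi] - m1) / C)
    e <- sum(h[lo] * shannon(mu_lo)) + sum(h[hi] * shannon(mu_hi))
    if (e < best) { best <- e; best_t <- t }
  }
  # report the lower edge of the first foreground bin so that `< t` is
  # exactly the background class
  if (intish) levels[best_t + 1L] else br[best_t + 1L]
}

#' Zero out background voxels
#'
#' @param vol a [Volume()].
#' @param t intensity threshold; voxels `< t` become 0.
#' @return list with `volume` (background zeroed) and `mask`
#'   ([LabelVolume()], 1 = foreground).
#' @export
filter_background <- function(vol, t) {
  stopifnot(inherits(vol, "Volume"))
  keep <- vol$data >= t
  out <- vol$data
  out[!keep] <- 0
  list(
    volume = Volume(out, vol$spacing, vol$axes, vol$origin),
    mask = LabelVolume(array(as.integer(keep), dim = dim(vol$data)),
                       vol$spacing, vol$axes, vol$origin)
  )
}

#' Grayscale reversal within a foreground mask
#'
#' Inverts intensities against the mask-wide maximum, which turns dim
#' outline/geometry structure (ventricles, fibre tracts, region borders)
#' into high-intensity registration features. Outside the mask the result
#' is 0.
#'
#' @param vol a [Volume()].
#' @param mask a [LabelVolume()] on the same grid (nonzero = foreground).
#' @return reversed [Volume()].
#' @export
grayscale_reversal <- function(vol, mask) {
  stopifnot(inherits(vol, "Volume"), inherits(mask, "LabelVolume"))
  if (!identical(dim(vol$data), dim(mask$labels)))
    stop("volume and mask grids differ")
  inm <- mask$labels != 0L
  if (!any(inm)) stop("degenerate input: empty mask")
  mx <- max(vol$data[inm])
  out <- array(0, dim = dim(vol$data))
  out[inm] <- mx - vol$data[inm]
  Volume(out, vol$spacing, vol$axes, vol$origin)
}

# ---- phase congruency (2D, per slice) --------------------------------------

# Precompute the log-Gabor * angular-spread transfer functions for one
# slice geometry. Returns list over orientations of lists over scales.
pc_filter_bank <- function(nr, nc, p) {
  fx <- ifelse(seq_len(nc) - 1 <= nc / 2, seq_len(nc) - 1,
               seq_len(nc) - 1 - nc) / nc
  fy <- ifelse(seq_len(nr) - 1 <= nr / 2, seq_len(nr) - 1,
               seq_len(nr) - 1 - nr) / nr
  u <- matrix(fy, nr, nc)        # rows = first image axis
  v <- matrix(fx, nr, nc, byrow = TRUE)
  radius <- sqrt(u^2 + v^2)
  radius[1, 1] <- 1              # avoid log(0) at DC; DC gain forced to 0
  theta <- atan2(-v, u)
  sintheta <- sin(theta); costheta <- cos(theta)
  # butterworth-style lowpass to suppress boundary/corner frequencies
  lowpass <- 1 / (1 + (radius / 0.45)^30)
  logg <- vector("list", p$n_scales)
  for (s in seq_len(p$n_scales)) {
    wl <- p$min_wavelength * p$scale_mult^(s - 1)
    f0 <- 1 / wl
    lg <- exp(-(log(radius / f0))^2 / (2 * log(p$sigma_onf)^2)) * lowpass
    lg[1, 1] <- 0
    logg[[s]] <- lg
  }
  dtheta_sigma <- pi / p$n_orients / 1.2
  bank <- vector("list", p$n_orients)
  for (o in seq_len(p$n_orients)) {
    ang <- (o - 1) * pi / p$n_orients
    ds <- sintheta * cos(ang) - costheta * sin(ang)
    dc <- costheta * cos(ang) + sintheta * sin(ang)
    dth <- abs(atan2(ds, dc))
    spread <- exp(-dth^2 / (2 * dtheta_sigma^2))
    bank[[o]] <- lapply(logg, function(lg) lg * spread)
  }
  bank
}

# Phase congruency of one 2D slice given a precomputed filter bank.
pc_slice <- function(im, bank, p) {
  nr <- nrow(im); nc <- ncol(im)
  IM <- stats::fft(im)
  total <- matrix(0, nr, nc)
  eps_num <- 1e-4                # numeric guard, distinct from Eq-2 epsilon
  for (o in seq_along(bank)) {
    filt <- bank[[o]]
    eo_r <- vector("list", p$n_scales)
    eo_i <- vector("list", p$n_scales)
    An <- vector("list", p$n_scales)
    sumE <- matrix(0, nr, nc); sumO <- matrix(0, nr, nc)
    sumAn <- matrix(0, nr, nc); maxAn <- matrix(0, nr, nc)
    for (s in seq_len(p$n_scales)) {
      resp <- stats::fft(IM * filt[[s]], inverse = TRUE) / (nr * nc)
      er <- Re(resp); ei <- Im(resp)
      a <- sqrt(er^2 + ei^2)
      eo_r[[s]] <- er; eo_i[[s]] <- ei; An[[s]] <- a
      sumE <- sumE + er; sumO <- sumO + ei
      sumAn <- sumAn + a; maxAn <- pmax(maxAn, a)
      if (s == 1L) tau <- stats::median(a)
    }
    xen <- sqrt(sumE^2 + sumO^2) + eps_num
    mean_e <- sumE / xen; mean_o <- sumO / xen
    # sum_n A_n [cos(phi_n - phibar) - |sin(phi_n - phibar)|] without
    # explicit phases: A cos(dphi) = e*mean_e + o*mean_o,
    # A sin(dphi) = e*mean_o - o*mean_e
    energy <- matrix(0, nr, nc)
    for (s in seq_len(p$n_scales)) {
      energy <- energy + eo_r[[s]] * mean_e + eo_i[[s]] * mean_o -
        abs(eo_r[[s]] * mean_o - eo_i[[s]] * mean_e)
    }
    T <- p$noise_k * tau
    width <- (sumAn / (maxAn + eps_num)) / p$n_scales
    W <- 1 / (1 + exp(p$g * (p$cutoff - width)))
    total <- total + W * pmax(abs(energy) - T, 0) / (sumAn + p$epsilon)
  }
  total
}

#' Phase-congruency feature map
#'
#' Computes the phase-congruency measure `PC = W * max(|E| - T, 0) /
#' (sum_n A_n + eps)` slice-by-slice with a log-Gabor quadrature bank,
#' where `E` is the local energy `sum_n A_n [cos(phi_n - phibar) -
#' |sin(phi_n - phibar)|]`, `T` a noise floor estimated per orientation
#' from the smallest-scale amplitude, and `W` a sigmoid weighting of the
#' filter-response spread. The orientation sum is rescaled to [0, 1] over
#' the volume. Constant slices map to 0.
#'
#' @param vol a [Volume()] (finite values).
#' @param p a [pc_params()].
#' @param slice_axis axis the 2D computation runs over (default 3, the
#'   anterior-posterior slice axis).
#' @return [Volume()] of PC values in [0, 1] on the input grid.
#' @export
phase_congruency <- function(vol, p = pc_params(), slice_axis = 3L) {
  stopifnot(inherits(vol, "Volume"))
  if (any(!is.finite(vol$data))) stop("non-finite intensities in input")
  a <- vol$data
  # normalise to unit range so the Eq-2 stabiliser epsilon acts on a
  # consistent amplitude scale; this is what makes PC contrast invariant
  rng <- range(a)
  if (diff(rng) > 0) a <- (a - rng[1]) / diff(rng)
  if (slice_axis != 3L) {
    perm <- c(setdiff(1:3, slice_axis), slice_axis)
    a <- aperm(a, perm)
  }
  d <- dim(a)
  if (min(d[1:2]) < 8) stop("slices smaller than 8 voxels per axis")
  bank <- pc_filter_bank(d[1], d[2], p)
  out <- array(0, dim = d)
  for (k in seq_len(d[3])) {
    sl <- a[, , k]
    if (diff(range(sl)) == 0) next   # constant slice: no structure, PC = 0
    out[, , k] <- pc_slice(sl, bank, p)
  }
  mx <- max(out)
  if (mx > 0) out <- out / mx
  if (slice_axis != 3L) out <- aperm(out, order(perm))
  Volume(out, vol$spacing, vol$axes, vol$origin)
}

#' Build the assistant feature channel
#'
#' Composes the feature pipeline: Huang threshold -> background filtration
#' -> phase congruency (edge/texture map) and grayscale reversal
#' (geometry/outline map). The two maps plus the foreground mask form the
#' assistant channel that complements the raw image channel during
#' registration.
#'
#' @param vol a preprocessed [Volume()] on the template grid.
#' @param p a [pc_params()].
#' @return object of class `feature_channel`: list with `pc_map`,
#'   `reversal_map` (both [Volume()]) and `mask` ([LabelVolume()]).
#' @export
build_feature_channel <- function(vol, p = pc_params()) {
  t <- huang_threshold(vol)
  fb <- filter_background(vol, t)
  pc <- phase_congruency(fb$volume, p)
  # responses outside the tissue mask are filter ringing into the removed
  # background, not structure: suppress them
  pc$data[fb$mask$labels == 0L] <- 0
  rev <- grayscale_reversal(vol, fb$mask)
  structure(list(pc_map = pc, reversal_map = rev, mask = fb$mask,
                 threshold = t),
            class = "feature_channel")
}

#' @export
print.feature_channel <- function(x, ...) {
  cat("feature_channel (threshold", format(x$threshold, digits = 4), ")\n")
  cat("  pc_map:       "); print(x$pc_map)
  cat("  reversal_map: "); print(x$reversal_map)
  invisible(x)
}
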