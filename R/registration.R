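#' Optimizer schedule for multi-resolution registration
#'
#' Registration runs three transform stages in sequence (rigid, affine,
#' B-spline free-form), each over a coarse-to-fine Gaussian pyramid. Within
#' a stage/level the cost is minimised by gradient descent with an adaptive
#' step: a step that lowers the cost is accepted and the rate grows
#' geometrically; a step that raises it is rejected and the rate halves, so
#' the per-level cost trace is monotone by construction.
#'
#' @param n_levels pyramid depth (default 5). Levels whose decimated image
#'   would fall below 8 voxels on any axis are skipped.
#' @param max_iters accepted-step budget per stage and level; named vector
#'   over `rigid`, `affine`, `bspline` (scalars recycled).
#' @param learning_rate initial step length in um per stage (named as
#'   above); the adaptive rule moves it within `[lr_min, 4 * learning_rate]`.
#' @param convergence_tol stop a level when the best cost improves by less
#'   than this over 6 consecutive accepted steps.
#' @param grid_spacing B-spline control-point spacing in fixed-image voxels
#'   at the finest level (default 30); coarser levels scale the physical
#'   spacing by the pyramid factor.
#' @param lr_min step length (um) below which a level stops.
#' @param min_improve minimum cost decrease for a step to be accepted;
#'   guards against chasing sampling noise around a converged optimum.
#' @return object of class `optimizer_schedule`.
#' @export
optimizer_schedule <- function(n_levels = 5L,
                               max_iters = c(rigid = 30L, affine = 30L,
                                             bspline = 40L),
                               learning_rate = c(rigid = 60, affine = 40,
                                                 bspline = 15),
                               convergence_tol = 1e-4,
                               grid_spacing = 30,
                               lr_min = 0.05,
                               min_improve = 2e-5) {
  if (n_levels < 1) stop("need n_levels >= 1")
  fill <- function(v, default) {
    if (is.null(names(v))) v <- stats::setNames(rep_len(v, 3),
                                                c("rigid", "affine",
                                                  "bspline"))
    out <- default
    out[names(v)] <- v
    out
  }
  max_iters <- fill(max_iters, c(rigid = 30L, affine = 30L, bspline = 40L))
  learning_rate <- fill(learning_rate,
                        c(rigid = 60, affine = 40, bspline = 15))
  if (any(learning_rate <= 0)) stop("learning_rate must be > 0")
  structure(list(n_levels = as.integer(n_levels),
                 max_iters = max_iters, learning_rate = learning_rate,
                 convergence_tol = convergence_tol,
                 grid_spacing = grid_spacing, lr_min = lr_min,
                 min_improve = min_improve),
            class = "optimizer_schedule")
}

# ---- per-level evaluation context ------------------------------------------

# Precompute everything that is constant within one stage/level: the level
# images, a fixed spatial sample set, the fixed-channel hard bins, the
# moving ranges and (optionally) moving gradient volumes.
level_context <- function(ch, factor, s, levels = NULL) {
  if (is.null(levels)) {
    lf <- lapply(ch$fixed, pyramid_level, factor = factor)
    lm <- lapply(ch$moving, pyramid_level, factor = factor)
  } else {
    lf <- levels$fixed; lm <- levels$moving
  }
  fg <- vol_grid(lf[[1]])
  mg <- vol_grid(lm[[1]])
  nvox <- prod(fg$shape)
  if (s$n_samples == 0L || nvox <= s$full_sample_below) {
    lin <- seq_len(nvox)
  } else {
    lin <- sample.int(nvox, min(s$n_samples, nvox))
  }
  idx <- linear_to_index(lin, fg$shape)
  # jitter samples off the voxel grid: grid-aligned sampling makes the
  # Parzen MI estimator artefactually non-stationary at exact alignment
  jit <- matrix(stats::runif(length(idx), -0.5, 0.5), nrow(idx), 3)
  idxj <- idx + jit
  for (dd in 1:3) idxj[, dd] <- pmin(pmax(idxj[, dd], 0),
                                     fg$shape[dd] - 1)
  pts <- voxel_to_phys(idxj, fg)
  # keep the histogram identifiable: with few samples a full-size joint
  # histogram (n_bins^2 cells) is mostly empty and its MI is noise the
  # optimiser will overfit, so coarse levels get fewer bins
  nb <- max(8L, min(s$n_bins, as.integer(floor(sqrt(length(lin) / 4)))))
  chans <- lapply(seq_along(lf), function(i) {
    fv <- interp_trilinear(vol_array(lf[[i]]), idxj)
    rng_f <- range(vol_array(lf[[i]]))
    rng_m <- range(vol_array(lm[[i]]))
    list(fv = fv, fb = hard_bins(fv, rng_f, nb),
         rng_m = rng_m, marr = vol_array(lm[[i]]),
         w = ch$weights[i])
  })
  list(pts = pts, fg = fg, mg = mg, chans = chans, nb = nb,
       wsum = sum(ch$weights), parzen = s$parzen_order,
       factor = factor)
}

# cost of the weighted multi-channel negative MI at mapped moving-voxel
# coordinates mvox (n x 3)
ctx_cost <- function(ctx, mvox) {
  d <- ctx$mg$shape
  inside <- mvox[, 1] >= 0 & mvox[, 1] <= d[1] - 1 &
    mvox[, 2] >= 0 & mvox[, 2] <= d[2] - 1 &
    mvox[, 3] >= 0 & mvox[, 3] <= d[3] - 1
  if (!any(inside)) stop("empty overlap during optimisation")
  mv_in <- mvox[inside, , drop = FALSE]
  total <- 0
  for (chn in ctx$chans) {
    if (chn$w == 0) next
    mv <- interp_trilinear(chn$marr, mv_in)
    H <- joint_hist_binned(chn$fb[inside], mv, chn$rng_m, ctx$nb,
                           ctx$parzen)
    total <- total + chn$w * (-mi_from_hist(H))
  }
  total / ctx$wsum
}

# joint histogram from precomputed fixed bins
joint_hist_binned <- function(fb, mv, rng_m, nb, parzen_order) {
  H <- matrix(0, nb, nb)
  if (parzen_order == 0L) {
    mb <- hard_bins(mv, rng_m, nb)
    idx <- 1L + fb + nb * mb
    tab <- rowsum(rep(1, length(idx)), idx)
  } else {
    e <- parzen_coord(mv, rng_m, nb)
    m0 <- floor(e)
    idx <- integer(0); w <- numeric(0)
    for (j in -1:2) {
      mb <- as.integer(pmin(pmax(m0 + j, 0), nb - 1))
      idx <- c(idx, 1L + fb + nb * mb)
      w <- c(w, beta3(e - (m0 + j)))
    }
    tab <- rowsum(w, idx)
  }
  H[as.integer(rownames(tab))] <- tab
  H
}

# map the context sample points through the chain, returning moving-voxel
# coordinates; y_base/support allow the B-spline fast path
ctx_map <- function(ctx, chain, y_base = NULL, support = NULL) {
  if (is.null(y_base)) {
    y <- transform_points(chain, ctx$pts)
  } else {
    y <- y_base + bspline_displacement(chain$bspline, ctx$pts, support)
  }
  phys_to_voxel(y, ctx$mg)
}

# ---- rigid / affine: finite-difference gradient descent --------------------

# stage parameter scaling: rotations and affine-matrix deviations are
# expressed in units of um displacement at the domain radius R
stage_scales <- function(stage, R) {
  if (stage == "rigid") c(rep(1 / R, 3), rep(1, 3))
  else c(rep(1 / R, 9), rep(1, 3))
}

optimize_global_stage <- function(stage, chain, ctx, sched, tol_scale = 1) {
  R <- max(grid_extent(ctx$fg)) / 2
  sc <- stage_scales(stage, R)
  phi <- chain[[stage]] / sc
  cost_of <- function(phi) {
    ch2 <- chain
    ch2[[stage]] <- phi * sc
    ctx_cost(ctx, ctx_map(ctx, ch2))
  }
  np <- length(phi)
  delta <- 0.5
  grad_of <- function(phi, c0) {
    g <- numeric(np)
    for (i in seq_len(np)) {
      e <- numeric(np); e[i] <- delta
      g[i] <- (cost_of(phi + e) - cost_of(phi - e)) / (2 * delta)
    }
    g
  }
  lr <- sched$learning_rate[[stage]] * max(1, ctx$factor / 2)
  lr_max <- 4 * lr
  cur <- cost_of(phi)
  init_cost <- cur
  trace <- data.frame(iter = 0L, cost = cur, lr = lr)
  g <- grad_of(phi, cur)
  accepts <- 0L; last_best <- cur
  max_acc <- sched$max_iters[[stage]]
  rejects_in_row <- 0L
  while (accepts < max_acc) {
    gm <- max(abs(g))
    if (gm < 1e-12) break
    cand <- phi - lr * g / gm
    cc <- cost_of(cand)
    if (cc < cur - sched$min_improve) {
      phi <- cand; cur <- cc
      accepts <- accepts + 1L
      rejects_in_row <- 0L
      lr <- min(lr * 1.5, lr_max)
      trace <- rbind(trace, data.frame(iter = accepts, cost = cur, lr = lr))
      g <- grad_of(phi, cur)
      if (accepts %% 6L == 0L) {
        if (last_best - cur < sched$convergence_tol * tol_scale) break
        last_best <- cur
      }
    } else {
      lr <- lr / 2
      rejects_in_row <- rejects_in_row + 1L
      if (lr < sched$lr_min || rejects_in_row > 12L) break
    }
  }
  if (cur > init_cost + 1e-9)
    stop("registration diverged in ", stage, " stage (cost ",
         format(init_cost), " -> ", format(cur), ")")
  chain[[stage]] <- phi * sc
  list(chain = chain, trace = trace, init_cost = init_cost,
       final_cost = cur)
}

# ---- B-spline: analytic Parzen-MI gradient descent -------------------------

# weighted-cost value and analytic gradient wrt B-spline coefficients at
# the current chain, using the level context
bspline_cost_grad <- function(ctx, chain, y_base, support) {
  n_all <- nrow(ctx$pts)
  y <- y_base + bspline_displacement(chain$bspline, ctx$pts, support)
  mvox <- phys_to_voxel(y, ctx$mg)
  d <- ctx$mg$shape
  inside <- mvox[, 1] >= 0 & mvox[, 1] <= d[1] - 1 &
    mvox[, 2] >= 0 & mvox[, 2] <= d[2] - 1 &
    mvox[, 3] >= 0 & mvox[, 3] <= d[3] - 1
  if (!any(inside)) stop("empty overlap during optimisation")
  mv_in <- mvox[inside, , drop = FALSE]
  n <- sum(inside)
  nb <- ctx$nb
  gs <- matrix(0, n, 3)   # per-sample gradient contribution, summed channels
  total_cost <- 0
  for (chn in ctx$chans) {
    if (chn$w == 0) next
    vg <- interp_trilinear_grad(chn$marr, mv_in)
    mv <- vg$v
    fb <- chn$fb[inside]
    w_m <- diff(chn$rng_m) / (nb - 5)
    if (w_m <= 0) next
    e <- parzen_coord(mv, chn$rng_m, nb)
    m0 <- floor(e)
    idx <- integer(0); wv <- numeric(0)
    mbs <- vector("list", 4); betas <- vector("list", 4)
    dbetas <- vector("list", 4)
    for (j in 1:4) {
      off <- j - 2L
      mb <- as.integer(pmin(pmax(m0 + off, 0), nb - 1))
      u <- e - (m0 + off)
      mbs[[j]] <- mb
      betas[[j]] <- beta3(u)
      dbetas[[j]] <- beta3_deriv(u)
      idx <- c(idx, 1L + fb + nb * mb)
      wv <- c(wv, betas[[j]])
    }
    H <- matrix(0, nb, nb)
    tab <- rowsum(wv, idx)
    H[as.integer(rownames(tab))] <- tab
    p <- H / n
    pm <- colSums(p)
    alpha <- matrix(0, nb, nb)
    nzp <- p > 0
    alpha[nzp] <- log(p[nzp] / rep(pm, each = nb)[nzp])
    total_cost <- total_cost + chn$w * (-mi_from_hist(H))
    q <- numeric(n)
    for (j in 1:4) {
      q <- q + dbetas[[j]] * alpha[1L + fb + nb * mbs[[j]]]
    }
    scale <- -chn$w / (ctx$wsum * n * w_m * log(2))
    # interpolant gradient is per moving-voxel unit; convert to per um
    gmv <- sweep(vg$g, 2, ctx$mg$spacing, "/")
    gs <- gs + scale * q * gmv
  }
  # scatter sample gradients onto the control lattice
  W <- support$W[inside, , drop = FALSE]
  IDX <- support$IDX[inside, , drop = FALSE]
  ncp <- nrow(chain$bspline$coef)
  gcoef <- matrix(0, ncp, 3)
  idx_all <- as.vector(IDX)
  for (dd in 1:3) {
    tab <- rowsum(as.vector(W) * rep(gs[, dd], 64), idx_all)
    gcoef[as.integer(rownames(tab)), dd] <-
      gcoef[as.integer(rownames(tab)), dd] + tab
  }
  list(cost = total_cost / ctx$wsum, grad = gcoef)
}

optimize_bspline_stage <- function(chain, ctx, sched, bs) {
  chain$bspline <- bs
  support <- bspline_support(bs, ctx$pts)
  # global part is frozen: precompute Affine(Rigid(x)) once
  ch_glob <- chain; ch_glob$bspline <- NULL
  y_base <- transform_points(ch_glob, ctx$pts)
  lr <- sched$learning_rate[["bspline"]] * max(1, ctx$factor / 2)
  lr_max <- 4 * lr
  cg <- bspline_cost_grad(ctx, chain, y_base, support)
  cur <- cg$cost; g <- cg$grad
  init_cost <- cur
  trace <- data.frame(iter = 0L, cost = cur, lr = lr)
  accepts <- 0L; rejects_in_row <- 0L; last_best <- cur
  max_acc <- sched$max_iters[["bspline"]]
  while (accepts < max_acc) {
    gm <- max(abs(g))
    if (gm < 1e-14) break
    cand <- chain
    cand$bspline$coef <- chain$bspline$coef - lr * g / gm
    y_c <- y_base + bspline_displacement(cand$bspline, ctx$pts, support)
    cc <- ctx_cost(ctx, phys_to_voxel(y_c, ctx$mg))
    if (cc < cur - sched$min_improve) {
      chain <- cand; cur <- cc
      accepts <- accepts + 1L; rejects_in_row <- 0L
      lr <- min(lr * 1.5, lr_max)
      trace <- rbind(trace, data.frame(iter = accepts, cost = cur, lr = lr))
      cg <- bspline_cost_grad(ctx, chain, y_base, support)
      g <- cg$grad
      if (accepts %% 6L == 0L) {
        if (last_best - cur < sched$convergence_tol) break
        last_best <- cur
      }
    } else {
      lr <- lr / 2
      rejects_in_row <- rejects_in_row + 1L
      if (lr < sched$lr_min || rejects_in_row > 12L) break
    }
  }
  if (cur > init_cost + 1e-9)
    stop("registration diverged in bspline stage (cost ",
         format(init_cost), " -> ", format(cur), ")")
  list(chain = chain, trace = trace, init_cost = init_cost,
       final_cost = cur)
}

#' Gradient of the bi-channel cost for one transform stage
#'
#' Diagnostic access to the optimiser's gradients: central finite
#' differences for the rigid and affine stages (and optionally for the
#' B-spline stage), or the analytic Parzen-MI gradient for the B-spline
#' stage. Shapes match the stage's parameter vector (6, 12, or an
#' n-control-points x 3 matrix).
#'
#' @param ch a [channel_set()].
#' @param chain a [transform_chain()]; for `stage = "bspline"` it must
#'   carry a B-spline stage.
#' @param s an [mi_settings()].
#' @param stage one of `"rigid"`, `"affine"`, `"bspline"`.
#' @param mode `"analytic"` (B-spline only) or `"fd"`.
#' @param delta finite-difference step (um for translations/displacements).
#' @return the gradient of the cost with respect to the stage parameters.
#' @export
cost_gradient <- function(ch, chain, s = mi_settings(),
                          stage = c("rigid", "affine", "bspline"),
                          mode = c("default", "analytic", "fd"),
                          delta = 0.5) {
  stage <- match.arg(stage)
  mode <- match.arg(mode)
  if (mode == "default") mode <- if (stage == "bspline") "analytic" else "fd"
  ctx <- level_context(ch, 1L, s)
  if (stage == "bspline") {
    if (is.null(chain$bspline)) stop("chain carries no B-spline stage")
    if (mode == "analytic") {
      ch_glob <- chain; ch_glob$bspline <- NULL
      y_base <- transform_points(ch_glob, ctx$pts)
      support <- bspline_support(chain$bspline, ctx$pts)
      cg <- bspline_cost_grad(ctx, chain, y_base, support)
      g <- cg$grad
    } else {
      coef0 <- chain$bspline$coef
      g <- matrix(0, nrow(coef0), 3)
      for (i in seq_len(nrow(coef0))) for (dd in 1:3) {
        cp <- chain; cp$bspline$coef[i, dd] <- coef0[i, dd] + delta
        cm <- chain; cm$bspline$coef[i, dd] <- coef0[i, dd] - delta
        g[i, dd] <- (ctx_cost(ctx, ctx_map(ctx, cp)) -
                       ctx_cost(ctx, ctx_map(ctx, cm))) / (2 * delta)
      }
    }
    if (any(!is.finite(g))) stop("non-finite gradient in bspline stage")
    return(g)
  }
  p0 <- chain[[stage]]
  g <- numeric(length(p0))
  R <- max(grid_extent(ctx$fg)) / 2
  sc <- stage_scales(stage, R)
  for (i in seq_along(p0)) {
    cp <- chain; cp[[stage]][i] <- p0[i] + delta * sc[i]
    cm <- chain; cm[[stage]][i] <- p0[i] - delta * sc[i]
    g[i] <- (ctx_cost(ctx, ctx_map(ctx, cp)) -
               ctx_cost(ctx, ctx_map(ctx, cm))) / (2 * delta * sc[i])
  }
  if (any(!is.finite(g)))
    stop("non-finite gradient in ", stage, " stage")
  g
}

# ---- the fitting function --------------------------------------------------

#' Fit a bi-channel registration
#'
#' Registers the moving (template) channels to the fixed (sample) channels
#' by minimising the weighted multi-channel negative mutual information
#' under a rigid, then affine, then cubic B-spline free-form transform,
#' each over an `n_levels` coarse-to-fine Gaussian pyramid. Returns a
#' fitted-model object; the estimated transform maps fixed-space points to
#' moving-space points and pulls the template (and its annotation) onto
#' the sample grid.
#'
#' @param ch a [channel_set()] (N = 3 in the standard configuration: raw,
#'   grayscale reversal, phase congruency).
#' @param sched an [optimizer_schedule()].
#' @param s an [mi_settings()].
#' @param seed integer seed for the spatial sampling RNG; fixing it makes
#'   the fit deterministic.
#' @param stages which transform stages to run, in order.
#' @param init_chain optional starting [transform_chain()].
#' @param verbose print per-level progress.
#' @return object of class `bireg`: list with `chain` (the fitted
#'   [transform_chain()]), `trace` (per-iteration cost log), `schedule`,
#'   `mi_settings`, `stages`, `seed`, `cost` (final), `levels` (per
#'   stage/level summary).
#' @export
#' @seealso [predict.bireg()], [warp_annotation()], [bichannel_cost()]
register_bichannel <- function(ch, sched = optimizer_schedule(),
                               s = mi_settings(), seed = 1L,
                               stages = c("rigid", "affine", "bspline"),
                               init_chain = NULL, verbose = FALSE) {
  stopifnot(inherits(ch, "channel_set"))
  stages <- match.arg(stages, c("rigid", "affine", "bspline"),
                      several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  fg <- vol_grid(ch$fixed[[1]])
  mg <- vol_grid(ch$moving[[1]])
  chain <- if (is.null(init_chain)) transform_chain(fg, mg) else init_chain
  factors <- 2^((sched$n_levels - 1):0)
  usable <- factors[vapply(factors, function(f)
    min(floor(fg$shape / f), floor(mg$shape / f)) >= 8, logical(1))]
  if (!length(usable))
    stop("all pyramid levels fall below 8 voxels per axis")
  trace <- NULL
  levels_log <- NULL
  # build each pyramid level once and share it across stages
  level_cache <- lapply(usable, function(f) list(
    fixed = lapply(ch$fixed, pyramid_level, factor = f),
    moving = lapply(ch$moving, pyramid_level, factor = f)))
  names(level_cache) <- as.character(usable)
  for (stage in stages) {
    for (f in usable) {
      ctx <- level_context(ch, f, s,
                           levels = level_cache[[as.character(f)]])
      # global stages use the hard-binned estimator (artefact-free and
      # robust under finite differences); the B-spline stage keeps the
      # smooth Parzen window its analytic gradient requires
      if (stage != "bspline") ctx$parzen <- 0L
      if (stage == "bspline") {
        bs <- bspline_stage(ctx$fg, sched$grid_spacing)
        if (!is.null(chain$bspline)) {
          # carry the coarser-level field over: sample it at the new
          # control-point positions
          cp_idx <- grid_index_matrix(bs$nc)
          cp_pts <- sweep(sweep(cp_idx, 2, bs$spacing, "*"), 2,
                          bs$origin, "+")
          bs$coef <- bspline_displacement(chain$bspline, cp_pts)
        }
        res <- optimize_bspline_stage(chain, ctx, sched, bs)
      } else {
        res <- optimize_global_stage(stage, chain, ctx, sched)
      }
      chain <- res$chain
      tr <- res$trace
      tr$stage <- stage; tr$level_factor <- f
      trace <- rbind(trace, tr)
      levels_log <- rbind(levels_log, data.frame(
        stage = stage, level_factor = f,
        initial_cost = res$init_cost, final_cost = res$final_cost,
        iters = max(tr$iter)))
      if (verbose)
        message(sprintf("%-7s level factor %-2d  cost %.5f -> %.5f (%d steps)",
                        stage, f, res$init_cost, res$final_cost,
                        max(tr$iter)))
    }
  }
  structure(list(chain = chain, trace = trace, levels = levels_log,
                 schedule = sched, mi_settings = s, stages = stages,
                 seed = seed, cost = utils::tail(trace$cost, 1),
                 fixed_grid = fg, moving_grid = mg,
                 weights = ch$weights, n_channels = length(ch$fixed)),
            class = "bireg")
}

#' @export
print.bireg <- function(x, ...) {
  cat(sprintf("Bi-channel MI registration (N = %d channels, weights %s)\n",
              x$n_channels, paste(x$weights, collapse = "/")))
  cat(sprintf("  stages: %s; pyramid levels used: %s\n",
              paste(x$stages, collapse = " -> "),
              paste(sort(unique(x$levels$level_factor), decreasing = TRUE),
                    collapse = ",")))
  cat(sprintf("  final cost (negative MI, bits): %.5f\n", x$cost))
  print(x$chain)
  invisible(x)
}

#' @export
summary.bireg <- function(object, ...) {
  cat("Bi-channel registration summary\n")
  print(object$levels, row.names = FALSE)
  cat(sprintf("\nfinal cost %.5f after %d accepted steps\n",
              object$cost, sum(object$levels$iters)))
  invisible(object$levels)
}

#' @export
coef.bireg <- function(object, ...) {
  out <- list(rigid = object$chain$rigid, affine = object$chain$affine)
  if (!is.null(object$chain$bspline))
    out$bspline <- object$chain$bspline$coef
  out
}

#' Map points or resample a volume through a fitted registration
#'
#' For a [POISet()] (or bare n x 3 matrix) in sample space, returns the
#' points mapped to template space. For a [Volume()] or [LabelVolume()]
#' (template side), returns it resampled onto the sample (fixed) grid.
#'
#' @param object a fitted [register_bichannel()] model.
#' @param newdata POISet, coordinate matrix, Volume or LabelVolume.
#' @param ... unused.
#' @export
predict.bireg <- function(object, newdata, ...) {
  if (inherits(newdata, c("Volume", "LabelVolume")))
    return(resample(newdata, object$chain))
  transform_points(object$chain, newdata)
}

#' Plot the registration cost trace
#'
#' @param x a `bireg` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bireg <- function(x, ...) {
  tr <- x$trace
  key <- paste(tr$stage, tr$level_factor)
  block <- match(key, unique(key))
  xpos <- seq_len(nrow(tr))
  graphics::plot(xpos, tr$cost, type = "l", xlab = "accepted step",
                 ylab = "cost (negative MI, bits)", ...)
  graphics::points(xpos, tr$cost, pch = 20, cex = 0.5,
                   col = block %% 8 + 1)
  bounds <- xpos[!duplicated(block)][-1]
  graphics::abline(v = bounds - 0.5, lty = 3, col = "grey")
  invisible(x)
}
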