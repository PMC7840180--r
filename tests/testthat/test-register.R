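test_that("a perfect alignment is a stationary point of the cost", {
  ph <- small_phantom()
  ch <- channel_set(ph$template, ph$template)
  g0 <- grid_of(ph$template)
  # hard binning: the discrete-histogram MI of identical images is
  # maximal at identity by construction
  s0 <- mi_settings(n_samples = 0, parzen_order = 0)
  c_ident <- bichannel_cost(ch, transform_chain(g0), s0)
  # every single-parameter perturbation raises the cost
  for (i in 1:6) for (sgn in c(-1, 1)) {
    chain <- transform_chain(g0)
    chain$rigid[i] <- chain$rigid[i] +
      sgn * (if (i <= 3) 0.02 else 0.5 * g0$spacing[1])
    expect_gt(bichannel_cost(ch, chain, s0), c_ident)
  }
  # and the finite-difference gradient is small against the gradient at
  # a displaced configuration; rotations are natural-unit (per radian),
  # so rescale to per-um-at-the-domain-radius before comparing, and use
  # one sampling seed so both gradients see the same spatial samples
  sc <- birdreg:::stage_scales("rigid", max(birdreg:::grid_extent(g0)) / 2)
  s3 <- mi_settings(n_samples = 0)   # smooth estimator for differencing
  set.seed(123)
  g_opt <- cost_gradient(ch, transform_chain(g0), s3, stage = "rigid")
  off <- transform_chain(g0); off$rigid[4] <- 2 * g0$spacing[1]
  set.seed(123)
  g_off <- cost_gradient(ch, off, s3, stage = "rigid")
  expect_lt(max(abs(g_opt * sc)), 0.25 * max(abs(g_off * sc)))
})

test_that("the translation gradient points toward a known shift", {
  ph <- small_phantom()
  tpl <- ph$template
  g0 <- grid_of(tpl)
  true <- transform_chain(g0)
  true$rigid[4] <- 3 * g0$spacing[1]    # fixed(x) = template(x + 3 voxels)
  fixed <- resample(tpl, true)
  ch <- channel_set(fixed, tpl)
  s0 <- mi_settings(n_samples = 0)
  chain <- transform_chain(g0)
  g <- cost_gradient(ch, chain, s0, stage = "rigid")
  # moving +delta in tx must lower the cost: negative gradient component
  expect_lt(g[4], 0)
  c_at <- function(tx) {
    ch2 <- chain; ch2$rigid[4] <- tx
    bichannel_cost(ch, ch2, s0)
  }
  expect_lt(c_at(20), c_at(0))   # descending toward the true shift
  expect_lt(c_at(60), c_at(20))
})

test_that("analytic and finite-difference B-spline gradients agree", {
  # 16^3 phantom under a non-trivial random lattice; the moving image
  # carries a 4-voxel margin so no sample leaves its domain during the
  # finite-difference probe (domain dropout is a genuine discontinuity
  # of the sampled cost, not a gradient defect)
  spec <- phantom_spec(shape = c(16, 16, 16), n_pois = 0, deform_max = 0,
                       noise_sd = 0, intensity_map = NULL, seed = 23)
  ap <- make_atlas_phantom(spec)
  g0 <- grid_of(ap$template)
  arr <- birdreg:::gaussian_smooth3(ap$template$data, c(1, 1, 1))
  fixed <- Volume(arr, g0$spacing)
  big <- array(0, c(24, 24, 24)); big[5:20, 5:20, 5:20] <- arr
  moving <- Volume(big, g0$spacing, origin = -4 * g0$spacing)
  ch <- channel_set(fixed, moving)
  chain <- transform_chain(g0, grid_of(moving))
  chain$bspline <- birdreg:::bspline_stage(g0, 6)
  set.seed(31)
  chain$bspline$coef[] <- rnorm(length(chain$bspline$coef), sd = 4)
  s0 <- mi_settings(n_samples = 0)
  # same sampling seed for both gradient modes: the comparison is between
  # differentiation schemes, not between sample draws
  set.seed(123)
  ga <- cost_gradient(ch, chain, s0, stage = "bspline", mode = "analytic")
  set.seed(123)
  gf <- cost_gradient(ch, chain, s0, stage = "bspline", mode = "fd",
                      delta = 0.05)
  rel <- sqrt(sum((ga - gf)^2)) / sqrt(sum(gf^2))
  expect_lt(rel, 1e-3)
})

test_that("registering a volume to itself leaves displacements below 0.1 voxel", {
  ph <- small_phantom()
  ch <- channel_set(ph$template, ph$template)
  fit <- register_bichannel(ch, optimizer_schedule(n_levels = 3),
                            mi_settings(), seed = 5)
  g <- grid_of(ph$template)
  pts <- voxel_to_phys_pts(g)
  disp <- transform_points(fit$chain, pts) - pts
  mag_vox <- sqrt(rowSums(disp^2)) / min(g$spacing)
  expect_lt(stats::quantile(mag_vox, 0.99), 0.1)
})

test_that("a pure translation is recovered within half a voxel", {
  ph <- small_phantom()
  tpl <- ph$template
  g0 <- grid_of(tpl)
  true <- transform_chain(g0)
  true$rigid[4:6] <- c(5, -3, 2) * g0$spacing
  fixed <- resample(tpl, true)
  ch <- channel_set(fixed, tpl)
  fit <- register_bichannel(ch, optimizer_schedule(n_levels = 3),
                            mi_settings(), seed = 7,
                            stages = c("rigid", "affine"))
  # the rigid/affine split is not unique, so score the composite map:
  # brain-interior points must move by the true shift
  probe <- voxel_to_phys_pts(list(shape = c(5, 5, 5),
                                  spacing = g0$spacing * 5,
                                  origin = g0$origin + 6 * g0$spacing))
  err <- transform_points(fit$chain, probe) -
    sweep(probe, 2, true$rigid[4:6], "+")
  expect_lt(stats::median(sqrt(rowSums(err^2))) / g0$spacing[1], 0.5)
})

test_that("every stage and level ends at or below its initial cost", {
  sm <- small_sample()
  ap <- sm$atlas
  ch <- channel_set(sm$sample, ap$template)
  fit <- register_bichannel(ch, optimizer_schedule(n_levels = 3),
                            mi_settings(), seed = 11)
  expect_true(all(fit$levels$final_cost <= fit$levels$initial_cost + 1e-12))
  # and the within-level traces are monotone non-increasing
  for (key in unique(paste(fit$trace$stage, fit$trace$level_factor))) {
    tr <- fit$trace[paste(fit$trace$stage, fit$trace$level_factor) == key, ]
    expect_true(all(diff(tr$cost) <= 1e-12), label = key)
  }
})

test_that("fits are reproducible for a fixed seed", {
  sm <- small_sample()
  ch <- channel_set(sm$sample, sm$atlas$template)
  sched <- optimizer_schedule(n_levels = 2,
                              max_iters = c(rigid = 5, affine = 5,
                                            bspline = 5))
  f1 <- register_bichannel(ch, sched, mi_settings(), seed = 42)
  f2 <- register_bichannel(ch, sched, mi_settings(), seed = 42)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$trace$cost, f2$trace$cost)
})

test_that("model methods expose the fit sensibly", {
  sm <- small_sample()
  ch <- channel_set(sm$sample, sm$atlas$template)
  fit <- register_bichannel(ch, optimizer_schedule(
    n_levels = 2, max_iters = c(rigid = 4, affine = 4, bspline = 4)),
    mi_settings(), seed = 2)
  expect_named(coef(fit), c("rigid", "affine", "bspline"))
  expect_output(print(fit), "negative MI")
  # predict maps POIs to template space and volumes onto the sample grid
  mapped <- predict(fit, sm$pois_sample)
  expect_s3_class(mapped, "POISet")
  expect_equal(mapped$space, "template")
  res <- predict(fit, sm$atlas$template)
  expect_equal(dim(res$data), dim(sm$sample$data))
  grDevices::pdf(NULL); on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})
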