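test_that("POI distances follow the Euclidean formula and report the median", {
  a <- POISet(c("p", "q"), rbind(c(0, 0, 0), c(1, 1, 1)), "sample")
  b <- POISet(c("p", "q"), rbind(c(1, 2, 2), c(1, 1, 1)), "sample")
  r <- poi_distance(a, b)
  expect_equal(unname(r$per_poi), c(3, 0))
  # identical sets are all-zero
  expect_true(all(poi_distance(a, a)$per_poi == 0))
  # median equals the brute-force sorted-middle oracle on 10 points
  set.seed(13)
  p1 <- POISet(letters[1:10], matrix(runif(30, 0, 100), 10, 3), "sample")
  off <- matrix(rnorm(30), 10, 3)
  p2 <- POISet(letters[1:10], p1$coords + off, "sample")
  r2 <- poi_distance(p1, p2)
  ds <- sort(sqrt(rowSums(off^2)))
  expect_equal(r2$median, (ds[5] + ds[6]) / 2)
  # matching is by name, not order
  perm <- sample(10)
  p2s <- POISet(p2$names[perm], p2$coords[perm, ], "sample")
  expect_equal(poi_distance(p1, p2s)$per_poi, r2$per_poi)
  expect_error(poi_distance(a, POISet("p", rbind(c(0, 0, 0)), "sample")),
               "name")
  expect_error(poi_distance(a, POISet(c("p", "q"), a$coords, "template")),
               "space")
})

test_that("POI distance behaves as a metric on random triples", {
  set.seed(19)
  for (i in 1:20) {
    x <- matrix(runif(9), 3, 3)
    pa <- POISet("p", x[1, , drop = FALSE], "sample")
    pb <- POISet("p", x[2, , drop = FALSE], "sample")
    pc <- POISet("p", x[3, , drop = FALSE], "sample")
    dab <- poi_distance(pa, pb)$per_poi
    dba <- poi_distance(pb, pa)$per_poi
    dac <- poi_distance(pa, pc)$per_poi
    dcb <- poi_distance(pc, pb)$per_poi
    expect_equal(dab, dba)
    expect_lte(dab, dac + dcb + 1e-12)
  }
  p <- POISet("p", rbind(c(1, 2, 3)), "sample")
  expect_equal(unname(poi_distance(p, p)$per_poi), 0)
})

test_that("Dice handles the canonical overlap cases", {
  g <- c(4, 4, 1)
  a <- array(0L, g); a[1:4, 1, 1] <- 1L          # |A| = 4
  b <- array(0L, g); b[3:4, 1, 1] <- 1L; b[1:2, 2, 1] <- 1L  # |B| = 4
  expect_equal(dice(a, b), 0.5)                  # overlap 2 -> 2*2/8
  expect_equal(dice(a, a), 1)
  c2 <- array(0L, g); c2[1, 4, 1] <- 1L
  expect_equal(dice(a, c2), 0)
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(array(0L, g), array(0L, g)), "empty")
})

test_that("per-region Dice scores regions independently", {
  ph <- small_phantom()
  ann <- ph$annotation
  expect_true(all(dice_by_region(ann, ann)$per_region == 1))
  # shift one region by half its width: its score drops, others stay 1
  lab <- ann$labels
  m2 <- lab == 2L
  xs <- range(which(apply(m2, 1, any)))
  shift <- max(1L, round(diff(xs) / 4))
  lab2 <- lab
  lab2[lab2 == 2L] <- 0L
  d <- dim(lab)
  src <- 1:(d[1] - shift)
  dst <- (shift + 1):d[1]
  moved <- array(FALSE, d); moved[dst, , ] <- m2[src, , ]
  lab2[moved & lab2 == 0L] <- 2L
  dr <- dice_by_region(ann, LabelVolume(lab2, ann$spacing), ids = 1:4)
  expect_lt(dr$per_region[["2"]], 1)
  expect_equal(unname(dr$per_region[c("3", "4")]), c(1, 1))
  # ids absent from both are recorded missing, excluded from the median
  dr2 <- dice_by_region(ann, ann, ids = c(1L, 99L))
  expect_true(is.na(dr2$per_region[["99"]]))
  expect_equal(dr2$missing, 99L)
  expect_equal(dr2$median, 1)
  expect_length(dice_by_region(ann, ann, ids = integer(0))$per_region, 0)
})

test_that("evaluation reports export as CSV and JSON tables", {
  a <- POISet(c("p", "q"), rbind(c(0, 0, 0), c(1, 1, 1)), "sample")
  b <- POISet(c("p", "q"), rbind(c(1, 2, 2), c(1, 1, 1)), "sample")
  r <- poi_distance(a, b)
  prefix <- file.path(tempdir(), "eval")
  write_eval_report(r, prefix)
  df <- utils::read.csv(paste0(prefix, ".csv"))
  expect_equal(df$distance_um, c(3, 0))
  j <- jsonlite::fromJSON(paste0(prefix, ".json"))
  expect_equal(j$median, 1.5)
  ph <- small_phantom()
  dr <- dice_by_region(ph$annotation, ph$annotation)
  write_eval_report(dr, prefix)
  expect_equal(utils::read.csv(paste0(prefix, ".csv"))$dice, rep(1, 4))
})

test_that("unanimous raters reproduce their mask within two EM iterations", {
  ph <- small_phantom()
  mask <- ph$annotation$labels == 1L
  fit <- staple_fuse(replicate(4, mask, simplify = FALSE))
  expect_identical(fit$consensus, mask)
  expect_lte(fit$iterations, 2L)
  expect_true(all(fit$sensitivity > 0.99))
})

test_that("STAPLE outvotes an inverted rater and flags it", {
  ph <- small_phantom()
  truth <- ph$annotation$labels <= 2L & ph$annotation$labels > 0L
  raters <- replicate(9, truth, simplify = FALSE)
  raters[[10]] <- !truth
  fit <- staple_fuse(raters)
  # majority-vote oracle: 9 of 10 agree everywhere
  majority <- truth
  expect_identical(fit$consensus, majority)
  expect_lt(fit$sensitivity[10], 0.5)
  expect_true(all(fit$sensitivity[1:9] > 0.9))
})

test_that("total disagreement converges to a low-confidence consensus", {
  half <- array(FALSE, c(8, 8, 8)); half[1:4, , ] <- TRUE
  fit <- staple_fuse(list(half, !half))
  expect_true(fit$converged)
  expect_true(fit$low_confidence)
  # posterior sits at the prior: no voxel is confidently foreground
  expect_lt(max(abs(fit$posterior - fit$prior)), 0.05)
  expect_error(staple_fuse(list(array(FALSE, c(2, 2, 2)),
                                array(FALSE, c(2, 2, 2)))), "degenerate")
})
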