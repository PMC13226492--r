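# Metrics against brute-force oracles: confusion counts, exact surface
# distances, Hazen percentiles, band IoU, and aggregation.

test_that("confusion metrics match hand counts and conventions", {
  m <- matrix(0, 6, 6); m[2:4, 2:4] <- 1
  r <- confusion_metrics(m, m)
  expect_equal(r$dice, 1); expect_equal(r$precision, 1)
  expect_equal(r$recall, 1); expect_equal(r$miou, 1); expect_equal(r$f1, 1)

  # disjoint equal-area masks
  a <- matrix(0, 6, 6); a[1:2, 1] <- 1
  b <- matrix(0, 6, 6); b[5:6, 6] <- 1
  r2 <- confusion_metrics(a, b)
  expect_equal(r2$dice, 0)
  expect_equal(unname(r2$iou_per_class["foreground"]), 0)

  # 4x4 toy with TP=2, FP=1, FN=1: P = R = 2/3, fg IoU = 1/2,
  # Dice = 2TP/(2TP+FP+FN) = 2/3 (= F1, the harmonic mean of P and R)
  gt <- matrix(0, 4, 4); gt[1, 1:3] <- 1
  pr <- matrix(0, 4, 4); pr[1, 1:2] <- 1; pr[2, 1] <- 1
  r3 <- confusion_metrics(pr, gt)
  expect_equal(r3$precision, 2 / 3)
  expect_equal(r3$recall, 2 / 3)
  expect_equal(unname(r3$iou_per_class["foreground"]), 0.5)
  expect_equal(r3$dice, 2 / 3)
  expect_equal(r3$f1, r3$dice)
  # dice == harmonic mean of precision and recall from the same counts
  expect_equal(r3$dice, 2 * r3$precision * r3$recall /
                 (r3$precision + r3$recall))

  # miou conventions
  expect_equal(confusion_metrics(pr, gt, "foreground")$miou,
               unname(r3$iou_per_class["foreground"]))
  expect_equal(r3$miou, mean(r3$iou_per_class))

  # both empty: perfect-empty convention
  z <- matrix(0, 4, 4)
  r4 <- confusion_metrics(z, z)
  expect_equal(r4$dice, 1); expect_equal(r4$miou, 1)

  expect_error(confusion_metrics(matrix(0, 3, 3), z), "shapes")
})

test_that("surface distances: identical, single-pixel and empty cases", {
  m <- matrix(0, 8, 8); m[3:5, 3:6] <- 1
  sd0 <- surface_distances(m, m)
  expect_true(all(c(sd0$pred_to_gt, sd0$gt_to_pred) == 0))
  expect_equal(hd95(sd0), 0)
  expect_equal(assd(sd0), 0)

  a <- matrix(0, 6, 6); a[1, 1] <- 1
  b <- matrix(0, 6, 6); b[4, 5] <- 1  # offset (3, 4) -> distance 5
  sd1 <- surface_distances(a, b)
  expect_equal(sd1$pred_to_gt, 5)
  expect_equal(sd1$gt_to_pred, 5)
  expect_equal(assd(sd1), 5)

  e <- surface_distances(matrix(0, 6, 6), b)
  expect_true(isTRUE(attr(e, "undefined")))
  expect_error(hd95(e), "empty")
  expect_error(assd(e), "empty")
})

test_that("fast distance transforms equal the O(n^2) brute-force oracle", {
  for (s in 1:100) {
    p <- random_mask(1000 + s); g <- random_mask(2000 + s)
    fast <- surface_distances(p, g)
    slow <- naive_surface_distances(p, g)
    expect_equal(sort(fast$pred_to_gt), sort(slow$pred_to_gt),
                 tolerance = 1e-12)
    expect_equal(sort(fast$gt_to_pred), sort(slow$gt_to_pred),
                 tolerance = 1e-12)
  }
})

test_that("hd95 uses the Hazen linear-interpolation percentile", {
  d <- list(pred_to_gt = rep(0, 10), gt_to_pred = c(rep(0, 9), 10))
  expect_equal(hd95(d), 5.0)
  # always bounded by the maximum
  set.seed(3)
  for (i in 1:20) {
    v <- runif(sample(3:30, 1), 0, 20)
    dd <- list(pred_to_gt = v, gt_to_pred = rev(v))
    expect_lte(hd95(dd), max(v))
    expect_equal(hd95(dd), naive_percentile(c(v, rev(v)), 0.95))
    expect_lte(assd(dd), max(v))
  }
})

test_that("boundary IoU matches exhaustive enumeration and edge cases", {
  sq <- matrix(0, 8, 8); sq[3:6, 3:6] <- 1
  expect_equal(boundary_iou(sq, sq, band_px = 1), 1)
  far <- matrix(0, 8, 8); far[1, 8] <- 1
  expect_equal(boundary_iou(sq, far, band_px = 1), 0)
  shifted <- matrix(0, 8, 8); shifted[3:6, 4:7] <- 1
  expect_equal(boundary_iou(sq, shifted, band_px = 1),
               naive_boundary_iou(sq, shifted, 1))
  for (s in 1:25) {
    p <- random_mask(3000 + s); g <- random_mask(4000 + s)
    expect_equal(boundary_iou(p, g, band_px = 2),
                 naive_boundary_iou(p, g, 2))
  }
  z <- matrix(0, 8, 8)
  expect_equal(boundary_iou(z, z, band_px = 1), 1)
})

test_that("hd95, assd and boundary IoU are symmetric in their arguments", {
  for (s in 1:25) {
    p <- random_mask(5000 + s); g <- random_mask(6000 + s)
    sd_pg <- surface_distances(p, g); sd_gp <- surface_distances(g, p)
    expect_equal(hd95(sd_pg), hd95(sd_gp))
    expect_equal(assd(sd_pg), assd(sd_gp))
    expect_equal(boundary_iou(p, g), boundary_iou(g, p))
  }
})

test_that("dilating a perfect prediction degrades the metrics monotonely", {
  gt <- disk_mask(32, 16, 16, 8)
  dil <- matrix(FALSE, 32, 32)
  for (i in 1:32) for (j in 1:32) {
    nb <- expand.grid(i + (-1:1), j + (-1:1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= 32 & nb[, 2] >= 1 & nb[, 2] <= 32, ]
    dil[i, j] <- any(gt[as.matrix(nb)])
  }
  expect_lt(confusion_metrics(dil, gt)$dice, 1)
  expect_lt(boundary_iou(dil, gt), 1)
  expect_gt(assd(surface_distances(dil, gt)), 0)
})

test_that("dataset evaluation aggregates like its per-image oracle", {
  gt1 <- disk_mask(16, 8, 8, 4) * 1
  pr1 <- disk_mask(16, 8, 9, 4) * 1
  gt2 <- disk_mask(16, 5, 5, 2) * 1
  pr2 <- gt2
  rep <- evaluate_dataset(list(pr1, pr2), list(gt1, gt2))
  # pooled confusion oracle
  tp <- sum(pr1 & gt1) + sum(pr2 & gt2)
  fp <- sum(pr1 & !gt1) + sum(pr2 & !gt2)
  fn <- sum(!pr1 & gt1) + sum(!pr2 & gt2)
  expect_equal(rep$dice, 100 * 2 * tp / (2 * tp + fp + fn))
  expect_equal(rep$precision, 100 * tp / (tp + fp))
  # distance metrics averaged per image
  expect_equal(rep$hd95, mean(c(hd95(surface_distances(pr1, gt1)),
                                hd95(surface_distances(pr2, gt2)))))
  expect_equal(rep$assd, mean(c(assd(surface_distances(pr1, gt1)),
                                assd(surface_distances(pr2, gt2)))))
  expect_equal(rep$biou, mean(c(boundary_iou(pr1, gt1),
                                boundary_iou(pr2, gt2))))
  # duplicating every pair changes nothing
  rep2 <- evaluate_dataset(list(pr1, pr2, pr1, pr2),
                           list(gt1, gt2, gt1, gt2))
  expect_equal(rep2$dice, rep$dice)
  expect_equal(rep2$hd95, rep$hd95)
  expect_equal(rep2$biou, rep$biou)
  # single perfect prediction
  rep3 <- evaluate_dataset(list(gt1), list(gt1))
  expect_equal(rep3$dice, 100); expect_equal(rep3$hd95, 0)
  expect_equal(rep3$biou, 1)
  # empty prediction counts into the undefined tally
  rep4 <- evaluate_dataset(list(matrix(0, 16, 16), pr2), list(gt1, gt2))
  expect_equal(rep4$hd_undefined, 1L)
  expect_error(evaluate_dataset(list(pr1), list(gt1, gt2)), "length")
})
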