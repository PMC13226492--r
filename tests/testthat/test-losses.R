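# Hybrid objective: OHEM-mined cross-entropy and the unified Dice/Jaccard
# overlap loss, with hand-computed oracles.

# Build 2-class logits whose per-pixel cross-entropy equals `ce` exactly
# (all pixels labelled foreground).
logits_with_ce <- function(ce_values, H, W) {
  p <- exp(-ce_values)
  z <- log(p / (1 - p))
  l <- array(0, c(H, W, 2, 1))
  l[, , 2, ] <- z
  l
}

test_that("loss_config validates weights and keep fraction", {
  expect_error(loss_config(ce_weight = 0.5, overlap_weight = 0.6), "equal 1")
  expect_error(loss_config(ohem_keep_fraction = 0), "fraction")
  expect_silent(loss_config(ce_weight = 1, overlap_weight = 0))
})

test_that("OHEM equals plain mean cross-entropy when mining is inactive", {
  # uniform logits: every pixel has the same loss
  l <- array(0.3, c(4, 4, 2, 1))
  y <- matrix(1, 4, 4)
  cfg <- loss_config(ohem_keep_fraction = 0.25, ohem_min_kept = 1L)
  plain <- -log(0.5)  # equal logits -> probability 1/2
  expect_equal(ce_ohem(l, y, cfg), plain, tolerance = 1e-12)
  # keep fraction 1: mean over everything
  set.seed(7)
  l2 <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  y2 <- matrix(rbinom(64, 1, 0.4), 8, 8)
  cfg1 <- loss_config(ohem_keep_fraction = 1, ohem_min_kept = 1L)
  p <- exp(l2) / (exp(l2[, , 1, , drop = FALSE]) + exp(l2[, , 2, , drop = FALSE]))[, , c(1, 1), , drop = FALSE]
  pt <- ifelse(y2 > 0.5, p[, , 2, 1], p[, , 1, 1])
  expect_equal(ce_ohem(l2, y2, cfg1), mean(-log(pt)), tolerance = 1e-10)
})

test_that("OHEM keeps the hardest pixels: 2x2 sort-and-average oracle", {
  ces <- c(0.1, 0.2, 0.9, 1.4)
  l <- logits_with_ce(ces, 2, 2)
  y <- matrix(1, 2, 2)
  cfg <- loss_config(ohem_keep_fraction = 0.5, ohem_min_kept = 1L)
  expect_equal(ce_ohem(l, y, cfg), (0.9 + 1.4) / 2, tolerance = 1e-9)
})

test_that("OHEM mean dominates the plain mean on random logit grids", {
  set.seed(99)
  cfg <- loss_config(ohem_keep_fraction = 0.25, ohem_min_kept = 1L)
  cfg1 <- loss_config(ohem_keep_fraction = 1, ohem_min_kept = 1L)
  for (i in 1:1000) {
    l <- array(rnorm(6 * 6 * 2, sd = 2), c(6, 6, 2, 1))
    y <- matrix(rbinom(36, 1, 0.3), 6, 6)
    expect_gte(ce_ohem(l, y, cfg), ce_ohem(l, y, cfg1) - 1e-12)
  }
})

test_that("gradients flow only through retained OHEM pixels", {
  ces <- c(0.1, 0.2, 0.9, 1.4)
  l <- logits_with_ce(ces, 2, 2)
  y <- matrix(1, 2, 2)
  cfg <- loss_config(ohem_keep_fraction = 0.5, ohem_min_kept = 1L)
  base <- ce_ohem(l, y, cfg)
  # perturb the easiest pixel's logit: value must not change
  l2 <- l; l2[1, 1, 2, 1] <- l2[1, 1, 2, 1] + 0.05
  expect_equal(ce_ohem(l2, y, cfg), base, tolerance = 1e-12)
  # backprop: zero gradient at discarded pixels, nonzero at retained ones
  ln <- ag$ag_param(l)
  ag$ag_record({
    lo <- ce_ohem(ln, y, cfg)
    ag$ag_backward(lo)
  })
  g <- ln$grad
  expect_equal(g[1, 1, , 1], c(0, 0))
  expect_equal(g[2, 1, , 1], c(0, 0))
  expect_true(any(g[1, 2, , 1] != 0) && any(g[2, 2, , 1] != 0))
})

test_that("overlap loss reproduces its set-arithmetic oracle", {
  cfg <- loss_config(smooth_eps = 1e-9)
  y <- matrix(0, 4, 4); y[1:2, 1] <- 1
  # perfect overlap
  expect_lt(overlap_loss(y, y, cfg), 1e-8)
  # disjoint masks
  p <- matrix(0, 4, 4); p[3:4, 4] <- 1
  expect_equal(overlap_loss(p, y, cfg), 1, tolerance = 1e-6)
  # |p| = |y| = 2, overlap 1: Dice 1/2, Jaccard 1/3, loss 7/12
  p2 <- matrix(0, 4, 4); p2[2:3, 1] <- 1
  expect_equal(overlap_loss(p2, y, cfg), 7 / 12, tolerance = 1e-6)
  expect_error(overlap_loss(y * 2, y, cfg), "0, 1")
})

test_that("overlap loss is bounded and decreases with growing overlap", {
  set.seed(17)
  cfg <- loss_config()
  for (i in 1:50) {
    p <- matrix(runif(64), 8, 8)
    y <- matrix(rbinom(64, 1, 0.4), 8, 8)
    v <- overlap_loss(p, y, cfg)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  # same mass, strictly increasing sum(p*y) -> strictly decreasing loss
  y <- matrix(0, 4, 4); y[1:2, 1:2] <- 1
  p_low <- matrix(0.25, 4, 4)
  p_high <- p_low; p_high[1, 1] <- 0.5; p_high[4, 4] <- 0
  expect_lt(overlap_loss(p_high, y, cfg), overlap_loss(p_low, y, cfg))
})

test_that("total loss composes its components with weights 0.3/0.7", {
  cfg <- loss_config(ohem_keep_fraction = 0.5, ohem_min_kept = 1L,
                     smooth_eps = 1e-9)
  ces <- c(0.1, 0.2, 0.9, 1.4)
  l <- logits_with_ce(ces, 2, 2)
  y <- matrix(1, 2, 2)
  tot <- total_loss(l, y, cfg)
  probs <- 1 / (1 + exp(-l[, , 2, 1]))
  ov <- overlap_loss(probs, y, cfg)
  expect_equal(as.numeric(tot), 0.3 * 1.15 + 0.7 * ov, tolerance = 1e-9)
  # degenerate weights reduce to the CE term alone
  cfg_ce <- loss_config(ce_weight = 1, overlap_weight = 0,
                        ohem_keep_fraction = 0.5, ohem_min_kept = 1L)
  expect_equal(as.numeric(total_loss(l, y, cfg_ce)), 1.15, tolerance = 1e-9)
})

test_that("perfect saturated predictions drive the total loss to zero", {
  y <- matrix(0, 6, 6); y[2:4, 2:4] <- 1
  l <- array(0, c(6, 6, 2, 1))
  l[, , 1, 1] <- 30 * (1 - y); l[, , 2, 1] <- 30 * y
  cfg <- loss_config(smooth_eps = 1e-9)
  expect_lt(as.numeric(total_loss(l, y, cfg)), 1e-6)
})
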