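# Network assembly: shapes, parameter accounting against independent
# arithmetic, MAC counting, ablation switches, determinism, checkpoints.

tiny_cfg <- function(...) network_config(backbone = "tiny", seed = 7, ...)

# Closed-form parameter tally for the tiny assembly, written out layer by
# layer (independent of collect_params).
tiny_param_oracle <- function(aspp_out = 64, red = 32, dpf = TRUE,
                              asppe = TRUE, ehd = TRUE) {
  cbr <- function(ci, co, k, groups = 1) k * k * (ci / groups) * co + 2 * co
  bb <- cbr(1, 16, 3) + cbr(16, 16, 3) +
    cbr(16, 32, 3) + cbr(32, 32, 3) +
    cbr(32, 64, 3) + cbr(64, 64, 3) +
    cbr(64, 128, 3) + cbr(128, 128, 3)
  aspp <- cbr(128, aspp_out, 1) + 3 * cbr(128, aspp_out, 3) +
    cbr(128, aspp_out, 1) + cbr(5 * aspp_out, aspp_out, 1) +
    if (asppe) 128 + 1 else 0
  dpfp <- if (dpf) {
    cbr(128, 128, 3, groups = 128) +      # depthwise detail path
      cbr(128, 128, 3, groups = 64) +     # grouped dilated context path
      (128 * 128 + 128) +                 # 1x1 projection with bias
      (128 * 32 + 32) + (32 * 128 + 128) + # channel-gate bottleneck
      1                                    # alpha
  } else 0
  dec <- cbr(32, red, 1) + cbr(red + aspp_out, aspp_out, 3) +
    (if (ehd) (aspp_out + 1) + cbr(aspp_out, aspp_out, 3) else 0)
  head <- aspp_out * 2 + 2
  bb + aspp + dpfp + dec + head
}

test_that("tiny parameter count equals the layer-by-layer arithmetic oracle", {
  expect_equal(count_parameters(build_network(tiny_cfg())),
               tiny_param_oracle())
  expect_equal(count_parameters(build_network(tiny_cfg(
    dpf_enabled = FALSE, asppe_enabled = FALSE, ehd_enabled = FALSE))),
    tiny_param_oracle(dpf = FALSE, asppe = FALSE, ehd = FALSE))
})

test_that("every module switch strictly increases the parameter count", {
  base <- count_parameters(build_network(tiny_cfg(
    dpf_enabled = FALSE, asppe_enabled = FALSE, ehd_enabled = FALSE)))
  plus_dpf <- count_parameters(build_network(tiny_cfg(
    dpf_enabled = TRUE, asppe_enabled = FALSE, ehd_enabled = FALSE)))
  plus_aspp <- count_parameters(build_network(tiny_cfg(
    dpf_enabled = FALSE, asppe_enabled = TRUE, ehd_enabled = FALSE)))
  plus_ehd <- count_parameters(build_network(tiny_cfg(
    dpf_enabled = FALSE, asppe_enabled = FALSE, ehd_enabled = TRUE)))
  all_on <- count_parameters(build_network(tiny_cfg()))
  expect_true(all(c(plus_dpf, plus_aspp, plus_ehd) > base))
  expect_true(all_on > max(plus_dpf, plus_aspp, plus_ehd))
})

test_that("forward pass emits full-resolution probability maps", {
  net <- build_network(tiny_cfg())
  x <- array(runif(64 * 64 * 2), c(64, 64, 1, 2))
  p <- network_forward(net, x)
  expect_identical(dim(p), c(64L, 64L, 2L, 2L))
  sums <- p[, , 1, ] + p[, , 2, ]
  expect_lt(max(abs(sums - 1)), 1e-6)
  # identical images in one batch give identical outputs (eval mode)
  x2 <- x; x2[, , , 2] <- x2[, , , 1]
  p2 <- network_forward(net, x2)
  expect_equal(p2[, , , 1], p2[, , , 2], tolerance = 1e-12)
  expect_error(network_forward(net, array(0, c(64, 64, 3, 1))), "channel")
})

test_that("MAC counting follows the kernel-volume x output-elements rule", {
  # single 3x3 conv, 1 -> 1 channel, 8x8 input, zero-pad 'same': 9 * 64 MACs
  x <- array(0, c(8, 8, 1, 1))
  w <- array(0, c(3, 3, 1, 1))
  macs <- ag$ag_profile_macs(ag$ag_conv2d(x, w, NULL, pad = 1L))
  expect_equal(macs, 576)
  # a strictly convolutional stack quadruples when the side doubles
  stack_macs <- function(n) {
    x <- array(0, c(n, n, 2, 1))
    w1 <- array(0, c(3, 3, 2, 4)); w2 <- array(0, c(3, 3, 4, 2))
    ag$ag_profile_macs({
      y <- ag$ag_conv2d(x, w1, NULL, pad = 1L)
      ag$ag_conv2d(ag$ag_value(y), w2, NULL, pad = 1L)
    })
  }
  expect_equal(stack_macs(32), 4 * stack_macs(16))
})

test_that("tiny MAC count matches independent per-layer arithmetic", {
  net <- build_network(tiny_cfg())
  got <- count_macs(net, 64L)
  conv_macs <- function(ci, co, k, hw, groups = 1) k * k * (ci / groups) * co * hw
  bb <- conv_macs(1, 16, 3, 64^2) + conv_macs(16, 16, 3, 32^2) +
    conv_macs(16, 32, 3, 16^2) + conv_macs(32, 32, 3, 16^2) +
    conv_macs(32, 64, 3, 8^2) + conv_macs(64, 64, 3, 8^2) +
    conv_macs(64, 128, 3, 4^2) + conv_macs(128, 128, 3, 4^2)
  dpf <- conv_macs(128, 128, 3, 4^2, 128) + conv_macs(128, 128, 3, 4^2, 64) +
    conv_macs(128, 128, 1, 4^2) + conv_macs(128, 32, 1, 1) +
    conv_macs(32, 128, 1, 1)
  aspp <- conv_macs(128, 64, 1, 4^2) + 3 * conv_macs(128, 64, 3, 4^2) +
    conv_macs(128, 64, 1, 1) + conv_macs(128, 1, 1, 4^2) +
    conv_macs(5 * 64, 64, 1, 4^2)
  dec <- conv_macs(32, 32, 1, 16^2) + conv_macs(64, 1, 1, 4^2) +
    conv_macs(32 + 64, 64, 3, 16^2) + conv_macs(64, 64, 3, 16^2)
  head <- conv_macs(64, 2, 1, 16^2)
  expect_equal(got, bb + dpf + aspp + dec + head)
})

test_that("the classic U-Net reference counts 31.03 M parameters", {
  un <- build_baseline("unet", seed = 2)
  expect_equal(count_parameters(un), 31030658)
  p <- network_forward(un, array(runif(64 * 64), c(64, 64, 1, 1)))
  expect_identical(dim(p), c(64L, 64L, 2L, 1L))
  expect_lt(max(abs(p[, , 1, ] + p[, , 2, ] - 1)), 1e-6)
})

test_that("identical seeds build identical networks", {
  n1 <- build_network(tiny_cfg())
  n2 <- build_network(tiny_cfg())
  for (nm in names(n1$params))
    expect_identical(n1$params[[nm]]$value, n2$params[[nm]]$value)
  u1 <- build_baseline("unet", seed = 9)
  u2 <- build_baseline("unet", seed = 9)
  expect_identical(u1$params[[1]]$value, u2$params[[1]]$value)
  expect_error(build_baseline("nope"), "arg")
})

test_that("checkpoints round-trip weights, buffers and predictions", {
  net <- build_network(tiny_cfg())
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  p0 <- network_forward(net, x)
  path <- withr::local_tempfile(fileext = ".rds")
  save_network(net, path)
  back <- load_network(path)
  expect_equal(network_forward(back, x), p0, tolerance = 1e-12)
})
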