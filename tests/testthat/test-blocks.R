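# The three feature-map operators: identity ablations, gate saturation
# equivalences, shape contracts and gradient checks.

make_feature <- function(seed, H = 10, W = 10, C = 8, N = 2) {
  set.seed(seed)
  array(rnorm(H * W * C * N), c(H, W, C, N))
}

test_that("DPF with alpha = 0 is the identity residual to machine precision", {
  set.seed(1); m <- dpf_module(8L)
  f <- make_feature(2)
  expect_identical(m$params$alpha$value, 0)
  expect_equal(dpf_forward(f, m), f, tolerance = 0)
})

test_that("DPF with zero projection and saturated channel gate adds 0.5*alpha", {
  set.seed(3); m <- dpf_module(8L)
  m$params$alpha$value <- 0.8
  m$children$proj$params$weight$value[] <- 0
  m$children$proj$params$bias$value[] <- 0
  # saturate the channel gate: huge bias after a zeroed hidden layer
  m$children$gate_fc2$params$weight$value[] <- 0
  m$children$gate_fc2$params$bias$value[] <- 100
  f <- make_feature(4)
  out <- dpf_forward(f, m)
  expect_equal(out, f + 0.8 * 0.5, tolerance = 1e-12)
})

test_that("DPF output deviation from the input is bounded by |alpha|", {
  for (s in 1:20) {
    set.seed(s); m <- dpf_module(4L)
    m$params$alpha$value <- runif(1, -2, 2)
    f <- make_feature(100 + s, C = 4)
    out <- dpf_forward(f, m, training = TRUE)
    expect_lte(max(abs(out - f)), abs(m$params$alpha$value) + 1e-12)
  }
})

test_that("DPF spatial shape is preserved and values stay finite", {
  set.seed(9); m <- dpf_module(8L)
  f <- make_feature(10, H = 13, W = 7)
  out <- dpf_forward(f, m, training = TRUE)
  expect_identical(dim(out), dim(f))
  expect_true(all(is.finite(out)))
})

test_that("saturated edge gate reduces ASPP-E to classical ASPP", {
  set.seed(12)
  m <- asppe_module(6L, 8L)
  m$children$edge$params$bias$value[] <- 1000  # sigmoid == 1 numerically
  f <- make_feature(13, C = 6)
  gated <- asppe_forward(f, m)
  plain <- m; plain$meta$edge_gated <- FALSE   # same weights, no gate
  expect_equal(gated, asppe_forward(f, plain), tolerance = 1e-12)
})

test_that("collapsed edge gate leaves only the global-pooling pathway", {
  set.seed(14)
  m <- asppe_module(6L, 8L)
  m$children$edge$params$bias$value[] <- -1000  # gate == 0 numerically
  f1 <- make_feature(15, C = 6)
  # second input with identical per-channel global means but different values
  f2 <- f1[, rev(seq_len(dim(f1)[2])), , , drop = FALSE]
  expect_equal(asppe_forward(f1, m), asppe_forward(f2, m), tolerance = 1e-10)
})

test_that("constant input gives spatially constant ASPP-E interior output", {
  set.seed(16)
  m <- asppe_module(4L, 6L)
  f <- array(1.3, c(40, 40, 4, 1))
  out <- asppe_forward(f, m)
  expect_identical(dim(out)[1:2], dim(f)[1:2])
  # zero padding perturbs a border ring of width <= 18 (largest dilation);
  # the interior must be exactly constant per channel
  interior <- out[20:21, 20:21, , , drop = FALSE]
  for (c in seq_len(dim(out)[3]))
    expect_lt(diff(range(interior[, , c, ])), 1e-10)
})

test_that("unit confidence gate reduces EHD to plain concat fusion", {
  set.seed(18)
  m <- ehd_module(6L, 10L, shallow_reduced = 5L, out_channels = 8L,
                  two_stage = FALSE)
  m$children$conf$params$bias$value[] <- 1000
  sem <- make_feature(19, H = 4, W = 4, C = 6)
  sh <- make_feature(20, H = 16, W = 16, C = 10)
  gated <- ehd_forward(sem, sh, m)
  plain <- m; plain$meta$conf_gated <- FALSE
  expect_equal(gated, ehd_forward(sem, sh, plain), tolerance = 1e-12)
})

test_that("zero confidence gate makes EHD invariant to the shallow input", {
  set.seed(22)
  m <- ehd_module(6L, 10L, shallow_reduced = 5L, out_channels = 8L)
  m$children$conf$params$bias$value[] <- -1000
  sem <- make_feature(23, H = 4, W = 4, C = 6)
  sh1 <- make_feature(24, H = 16, W = 16, C = 10)
  sh2 <- sh1 + make_feature(25, H = 16, W = 16, C = 10)
  expect_equal(ehd_forward(sem, sh1, m), ehd_forward(sem, sh2, m),
               tolerance = 1e-10)
})

test_that("EHD emits at the shallow resolution and validates scale factors", {
  set.seed(26)
  m <- ehd_module(6L, 10L, shallow_reduced = 5L, out_channels = 8L)
  sem <- make_feature(27, H = 16, W = 16, C = 6, N = 1)
  sh <- make_feature(28, H = 64, W = 64, C = 10, N = 1)
  out <- ehd_forward(sem, sh, m)
  expect_identical(dim(out)[1:2], c(64L, 64L))
  bad_sh <- make_feature(29, H = 12, W = 12, C = 10, N = 1)
  sem5 <- make_feature(30, H = 5, W = 5, C = 6, N = 1)
  expect_error(ehd_forward(sem5, bad_sh, m), "integer multiples")
})

test_that("all gate maps lie strictly inside (0, 1) for finite inputs", {
  set.seed(31)
  dm <- dpf_module(4L); am <- asppe_module(4L, 6L)
  em <- ehd_module(6L, 8L, shallow_reduced = 4L, out_channels = 6L)
  f <- make_feature(32, C = 4)
  invisible(dpf_forward(f, dm, training = TRUE))
  invisible(asppe_forward(f, am, training = TRUE))
  sem <- make_feature(33, H = 5, W = 5, C = 6)
  sh <- make_feature(34, H = 10, W = 10, C = 8)
  invisible(ehd_forward(sem, sh, em, training = TRUE))
  for (g in list(dm$state$last_gate, am$state$last_gate, em$state$last_gate)) {
    expect_true(all(g > 0 & g < 1))
  }
  # the sigmoid-normalized differential response is a gate map too
  expect_true(all(dm$state$last_fdiff > 0 & dm$state$last_fdiff < 1))
})

test_that("analytic gradients of each block match finite differences", {
  set.seed(41)
  x0 <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1)) * 0.5
  pw <- array(runif(length(x0)), dim(x0))
  dm <- dpf_module(4L); dm$params$alpha$value <- 0.5
  bp <- block_input_grad(function(xn)
    ag$module_forward(dm, xn, TRUE), x0, pw)
  ng <- numeric_grad(function(x)
    sum(dpf_forward(x, dm, training = TRUE) * pw), x0)
  expect_lt(max(abs(bp - ng)) / max(abs(ng)), 1e-3)

  am <- asppe_module(4L, 4L)
  pw2 <- array(runif(8 * 8 * 4), c(8, 8, 4, 1))
  bp <- block_input_grad(function(xn)
    ag$module_forward(am, xn, TRUE), x0, pw2)
  ng <- numeric_grad(function(x)
    sum(asppe_forward(x, am, training = TRUE) * pw2), x0)
  expect_lt(max(abs(bp - ng)) / max(abs(ng)), 1e-3)

  em <- ehd_module(4L, 4L, shallow_reduced = 3L, out_channels = 4L)
  sh0 <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1)) * 0.5
  sem0 <- array(rnorm(4 * 4 * 4), c(4, 4, 4, 1)) * 0.5
  pw3 <- array(runif(8 * 8 * 4), c(8, 8, 4, 1))
  bp <- block_input_grad(function(xn)
    ag$module_forward(em, list(sem = ag$ag_new_node(sem0), shallow = xn),
                      TRUE), sh0, pw3)
  ng <- numeric_grad(function(x)
    sum(ehd_forward(sem0, x, em, training = TRUE) * pw3), sh0)
  expect_lt(max(abs(bp - ng)) / max(abs(ng)), 1e-3)
})
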