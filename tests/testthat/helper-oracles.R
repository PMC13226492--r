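# Independent brute-force oracles and small fixture builders shared across
# the test files.  Everything here is deliberately naive: double loops and
# closed-form arithmetic, no reuse of the package's fast code paths.

# Direct 2-D convolution by explicit summation (stride/pad/dilation/groups).
naive_conv2d <- function(x, w, b = NULL, stride = 1, pad = 0, dil = 1,
                         groups = 1) {
  d <- dim(x); kd <- dim(w)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  kh <- kd[1]; kw <- kd[2]; Cg <- kd[3]; O <- kd[4]
  Og <- O / groups
  Ho <- (H + 2 * pad - dil * (kh - 1) - 1) %/% stride + 1
  Wo <- (W + 2 * pad - dil * (kw - 1) - 1) %/% stride + 1
  y <- array(0, c(Ho, Wo, O, N))
  for (n in 1:N) for (o in 1:O) {
    g <- (o - 1) %/% Og
    for (ho in 1:Ho) for (wo in 1:Wo) {
      acc <- if (is.null(b)) 0 else b[o]
      for (cc in 1:Cg) for (ki in 1:kh) for (kj in 1:kw) {
        h <- (ho - 1) * stride - pad + (ki - 1) * dil + 1
        wdx <- (wo - 1) * stride - pad + (kj - 1) * dil + 1
        if (h >= 1 && h <= H && wdx >= 1 && wdx <= W)
          acc <- acc + w[ki, kj, cc, o] * x[h, wdx, g * Cg + cc, n]
      }
      y[ho, wo, o, n] <- acc
    }
  }
  y
}

# Boundary pixels by explicit 4-neighbor inspection.
naive_boundary <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  at <- function(i, j) i >= 1 && i <= H && j >= 1 && j <= W && m[i, j]
  for (i in 1:H) for (j in 1:W) {
    if (!m[i, j]) next
    if (!at(i - 1, j) || !at(i + 1, j) || !at(i, j - 1) || !at(i, j + 1))
      out[i, j] <- TRUE
  }
  out
}

# All-pairs directed surface distances between two masks (O(n^2)).
naive_surface_distances <- function(p, g) {
  bp <- which(naive_boundary(p), arr.ind = TRUE)
  bg <- which(naive_boundary(g), arr.ind = TRUE)
  dmin <- function(from, to) {
    apply(from, 1, function(q)
      sqrt(min((to[, 1] - q[1])^2 + (to[, 2] - q[2])^2)))
  }
  list(pred_to_gt = as.numeric(dmin(bp, bg)),
       gt_to_pred = as.numeric(dmin(bg, bp)))
}

# Hazen linear-interpolation percentile, written out by hand.
naive_percentile <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- n * q + 0.5
  if (h <= 1) return(x[1])
  if (h >= n) return(x[n])
  lo <- floor(h)
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Boundary band by per-pixel exhaustive distance to the nearest background
# pixel (Euclidean), then band-IoU by enumeration.
naive_boundary_iou <- function(p, g, band_px) {
  p <- p > 0.5; g <- g > 0.5
  band <- function(m) {
    if (!any(m)) return(m)
    bgpix <- which(!m, arr.ind = TRUE)
    out <- matrix(FALSE, nrow(m), ncol(m))
    for (i in 1:nrow(m)) for (j in 1:ncol(m)) {
      if (!m[i, j]) next
      if (nrow(bgpix) == 0) next
      d <- sqrt(min((bgpix[, 1] - i)^2 + (bgpix[, 2] - j)^2))
      if (d <= band_px) out[i, j] <- TRUE
    }
    out
  }
  bp <- band(p); bg <- band(g)
  u <- sum(bp | bg)
  if (u == 0) return(1)
  sum(bp & bg) / u
}

# Random non-empty, non-full 16x16 mask with a fixed seed.
random_mask <- function(seed, n = 16, p = 0.3) {
  set.seed(seed)
  repeat {
    m <- matrix(runif(n * n) < p, n, n)
    if (any(m) && !all(m)) return(m)
  }
}

disk_mask <- function(n, cx, cy, r) {
  xs <- matrix(rep(1:n, n), n, n)
  ys <- matrix(rep(1:n, each = n), n, n)
  sqrt((xs - cx)^2 + (ys - cy)^2) <= r
}

# Finite-difference gradient of scalar-valued f at x (central differences).
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(as.array(x)))
  xv <- as.numeric(x)
  for (i in seq_along(xv)) {
    xp <- xv; xp[i] <- xp[i] + eps
    xm <- xv; xm[i] <- xm[i] - eps
    g[i] <- (f(array(xp, dim(as.array(x)))) -
               f(array(xm, dim(as.array(x))))) / (2 * eps)
  }
  g
}

ag <- asNamespace("ehdnet")

# Backprop input-gradient of sum(weights * block_forward(x)) for a module.
block_input_grad <- function(forward_fn, x0, proj_w) {
  xn <- ag$ag_param(x0)
  ag$ag_record({
    y <- forward_fn(xn)
    l <- ag$ag_op(sum(ag$ag_value(y) * proj_w), list(y),
                  list(function(g) g * proj_w))
    ag$ag_backward(l)
  })
  xn$grad
}
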