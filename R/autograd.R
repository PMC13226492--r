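#' @useDynLib ehdnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# Reverse-mode autodiff tape.
#
# A node wraps a value (an R array) together with references to its parent
# nodes and one gradient closure per parent.  Nodes are appended to a tape in
# creation order, which is a valid topological order, so backpropagation is a
# single reverse sweep.  Only nodes that (transitively) depend on a parameter
# are taped; everything else behaves like a constant.
# ---------------------------------------------------------------------------

.ag <- new.env(parent = emptyenv())
.ag$recording <- FALSE
.ag$tape <- NULL
.ag$profiling <- FALSE
.ag$macs <- 0

ag_is_node <- function(x) inherits(x, "ag_node")

ag_value <- function(x) if (ag_is_node(x)) x$value else x

ag_new_node <- function(value, parents = list(), gradfns = list(),
                        requires = FALSE) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$gradfns <- gradfns
  n$requires <- requires
  class(n) <- "ag_node"
  if (isTRUE(.ag$recording) && requires) {
    .ag$tape[[length(.ag$tape) + 1L]] <- n
  }
  n
}

#' Create a trainable parameter node
#'
#' Parameters are leaves of the autodiff graph; gradients accumulate in-place
#' during [ag_backward()].
#' @param value numeric array (or vector/scalar) with the initial value.
#' @return an `ag_node` with `requires = TRUE`.
#' @keywords internal
ag_param <- function(value) {
  n <- ag_new_node(value, requires = TRUE)
  n  # leaves are never taped; they receive gradients through their children
}

ag_requires <- function(...) {
  args <- list(...)
  any(vapply(args, function(a) ag_is_node(a) && isTRUE(a$requires), logical(1)))
}

# Wrap an op result.  `parents`/`gradfns` are filtered to node parents that
# require gradients, so constants cost nothing at backward time.
ag_op <- function(value, parents, gradfns) {
  keep <- vapply(parents, function(p) ag_is_node(p) && isTRUE(p$requires),
                 logical(1))
  if (!any(keep)) return(ag_new_node(value, requires = FALSE))
  ag_new_node(value, parents = parents[keep], gradfns = gradfns[keep],
              requires = TRUE)
}

#' Run an expression while recording an autodiff tape
#' @param expr expression whose intermediate ops should be taped.
#' @return the value of `expr`.
#' @keywords internal
ag_record <- function(expr) {
  old_rec <- .ag$recording
  old_tape <- .ag$tape
  .ag$recording <- TRUE
  .ag$tape <- list()
  on.exit({ .ag$recording <- old_rec; .ag$tape <- old_tape })
  expr
}

#' Backpropagate from a scalar loss node
#'
#' Must be called inside the same [ag_record()] scope that built `loss`.
#' Accumulates gradients into every reachable parameter's `$grad`.
#' @param loss an `ag_node` holding a scalar.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(ag_is_node(loss), length(loss$value) == 1L)
  loss$grad <- 1
  tape <- .ag$tape
  for (i in rev(seq_along(tape))) {
    nd <- tape[[i]]
    if (is.null(nd$grad)) next
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      g <- nd$gradfns[[k]](nd$grad)
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    if (!identical(nd, loss)) nd$grad <- NULL  # free as we go
  }
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# -- profiling --------------------------------------------------------------

ag_profile_macs <- function(expr) {
  .ag$profiling <- TRUE
  .ag$macs <- 0
  on.exit(.ag$profiling <- FALSE)
  force(expr)
  .ag$macs
}

# ---------------------------------------------------------------------------
# Differentiable operations.  All feature maps are 4-D arrays (H, W, C, N).
# ---------------------------------------------------------------------------

#' 2-D convolution (differentiable)
#' @param x input node/array, dim (H, W, C, N).
#' @param w weight node/array, dim (kh, kw, C/groups, O).
#' @param b optional bias node/array of length O, or `NULL`.
#' @param stride,pad,dilation,groups integer convolution hyperparameters.
#' @keywords internal
ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, dilation = 1L,
                      groups = 1L) {
  xv <- ag_value(x); wv <- ag_value(w)
  xdim <- dim(xv); wdim <- dim(wv)
  if (xdim[3] != wdim[3] * groups)
    stop("conv2d: input has ", xdim[3], " channels but weights expect ",
         wdim[3] * groups)
  if (wdim[4] %% groups != 0)
    stop("conv2d: output channels must be divisible by groups")
  bv <- if (is.null(b)) numeric(0) else as.numeric(ag_value(b))
  y <- cpp_conv_fwd(xv, as.integer(xdim), wv,
                    as.integer(wdim), bv, as.integer(stride), as.integer(pad),
                    as.integer(dilation), as.integer(groups))
  if (isTRUE(.ag$profiling)) {
    ydim <- dim(y)
    .ag$macs <- .ag$macs +
      as.double(wdim[1]) * wdim[2] * wdim[3] * wdim[4] * ydim[1] * ydim[2]
  }
  ydim <- dim(y)
  parents <- list(x, w)
  gradfns <- list(
    function(g) cpp_conv_gx(g, as.integer(ydim), wv,
                            as.integer(wdim), as.integer(xdim),
                            as.integer(stride), as.integer(pad),
                            as.integer(dilation), as.integer(groups)),
    function(g) cpp_conv_gw(xv, as.integer(xdim), g,
                            as.integer(ydim), as.integer(wdim),
                            as.integer(stride), as.integer(pad),
                            as.integer(dilation), as.integer(groups)))
  if (!is.null(b)) {
    parents <- c(parents, list(b))
    gradfns <- c(gradfns, list(function(g) {
      colSums(matrix(aperm(g, c(1, 2, 4, 3)), ncol = ydim[3]))
    }))
  }
  ag_op(y, parents, gradfns)
}

#' Transposed 2-D convolution (differentiable)
#'
#' The forward pass is the input-gradient of an ordinary convolution mapping
#' the (larger) output back to `x`; weights have dim (kh, kw, O/groups, C).
#' @keywords internal
ag_conv2d_transpose <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  xv <- ag_value(x); wv <- ag_value(w)
  xdim <- dim(xv); wdim <- dim(wv)
  if (xdim[3] != wdim[4])
    stop("conv2d_transpose: channel mismatch")
  O <- wdim[3]
  Ho <- (xdim[1] - 1L) * stride - 2L * pad + wdim[1]
  Wo <- (xdim[2] - 1L) * stride - 2L * pad + wdim[2]
  ydim <- c(Ho, Wo, O, xdim[4])
  y <- cpp_conv_gx(as.numeric(xv), as.integer(xdim), as.numeric(wv),
                   as.integer(wdim), as.integer(ydim),
                   as.integer(stride), as.integer(pad), 1L, 1L)
  if (isTRUE(.ag$profiling)) {
    .ag$macs <- .ag$macs +
      as.double(wdim[1]) * wdim[2] * wdim[3] * wdim[4] * xdim[1] * xdim[2]
  }
  if (!is.null(b)) {
    bv <- as.numeric(ag_value(b))
    y <- y + rep(bv, each = Ho * Wo)
  }
  parents <- list(x, w)
  gradfns <- list(
    function(g) cpp_conv_fwd(as.numeric(g), as.integer(ydim), as.numeric(wv),
                             as.integer(wdim), numeric(0), as.integer(stride),
                             as.integer(pad), 1L, 1L),
    function(g) cpp_conv_gw(as.numeric(g), as.integer(ydim), as.numeric(xv),
                            as.integer(xdim), as.integer(wdim),
                            as.integer(stride), as.integer(pad), 1L, 1L))
  if (!is.null(b)) {
    parents <- c(parents, list(b))
    gradfns <- c(gradfns, list(function(g) {
      colSums(matrix(aperm(g, c(1, 2, 4, 3)), ncol = O))
    }))
  }
  ag_op(y, parents, gradfns)
}

#' Batch normalization (differentiable)
#'
#' Statistics are taken over batch and space per channel.  In training mode
#' the running statistics in `state` are updated in place.
#' @param state environment with `running_mean`, `running_var` (length C).
#' @keywords internal
ag_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         eps = 1e-5, momentum = 0.1) {
  xv <- ag_value(x)
  d <- dim(xv)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  gv <- as.numeric(ag_value(gamma)); bv <- as.numeric(ag_value(beta))
  if (training) {
    mu <- rowMeans(matrix(.colMeans(xv, H * W, C * N), C, N))
    m2 <- rowMeans(matrix(.colMeans(xv * xv, H * W, C * N), C, N))
    va <- pmax(m2 - mu * mu, 0)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  istd <- 1 / sqrt(va + eps)
  mu_b <- rep(mu, each = H * W)      # recycles over N
  istd_b <- rep(istd, each = H * W)
  xhat <- (xv - mu_b) * istd_b
  y <- xhat * rep(gv, each = H * W) + rep(bv, each = H * W)
  dim(y) <- d
  m <- H * W * N
  csum <- function(a) {  # per-channel sum over (H, W, N)
    rowSums(matrix(.colSums(a, H * W, C * N), C, N))
  }
  gx_fn <- if (training) {
    function(g) {
      gxh <- g * rep(gv, each = H * W)
      s1 <- csum(gxh)
      s2 <- csum(gxh * xhat)
      gx <- istd_b * (gxh - rep(s1 / m, each = H * W) -
                        xhat * rep(s2 / m, each = H * W))
      dim(gx) <- d
      gx
    }
  } else {
    function(g) {
      gx <- g * rep(gv * istd, each = H * W)
      dim(gx) <- d
      gx
    }
  }
  ag_op(y, list(x, gamma, beta),
        list(gx_fn,
             function(g) csum(g * xhat),
             function(g) csum(g)))
}

#' @keywords internal
ag_relu <- function(x) {
  xv <- ag_value(x)
  mask <- xv > 0
  y <- xv * mask
  ag_op(y, list(x), list(function(g) g * mask))
}

#' @keywords internal
ag_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-ag_value(x)))
  ag_op(y, list(x), list(function(g) g * y * (1 - y)))
}

#' @keywords internal
ag_add <- function(x, y) {
  ag_op(ag_value(x) + ag_value(y), list(x, y),
        list(function(g) g, function(g) g))
}

#' @keywords internal
ag_sub <- function(x, y) {
  ag_op(ag_value(x) - ag_value(y), list(x, y),
        list(function(g) g, function(g) -g))
}

#' Residual modulation `x + alpha * y` with a scalar parameter alpha
#' @keywords internal
ag_axpy <- function(x, alpha, y) {
  av <- as.numeric(ag_value(alpha))
  yv <- ag_value(y)
  ag_op(ag_value(x) + av * yv, list(x, alpha, y),
        list(function(g) g,
             function(g) sum(g * yv),
             function(g) g * av))
}


# Fast channel-axis reductions for (H,W,C,N) arrays (avoids apply()).
chan_sum <- function(x) {
  d <- dim(x)
  y <- x[, , 1, , drop = FALSE]
  if (d[3] > 1) for (c in 2:d[3]) y <- y + x[, , c, , drop = FALSE]
  y
}
chan_max <- function(x) {
  d <- dim(x)
  y <- x[, , 1, , drop = FALSE]
  if (d[3] > 1) for (c in 2:d[3]) y <- pmax(y, x[, , c, , drop = FALSE])
  y
}
chan_rep <- function(x, C) x[, , rep(1L, C), , drop = FALSE]

#' Spatial gating: multiply (H,W,C,N) features by a (H,W,1,N) gate
#' @keywords internal
ag_gate_spatial <- function(x, gate) {
  xv <- ag_value(x); gv <- ag_value(gate)
  d <- dim(xv)
  gexp <- gv[, , rep(1L, d[3]), , drop = FALSE]
  ag_op(xv * gexp, list(x, gate),
        list(function(g) g * gexp,
             function(g) chan_sum(g * xv)))
}

#' Channel gating: multiply (H,W,C,N) features by a (1,1,C,N) gate
#' @keywords internal
ag_gate_channel <- function(x, gate) {
  xv <- ag_value(x); gv <- ag_value(gate)
  d <- dim(xv)
  gexp <- rep(as.numeric(gv), each = d[1] * d[2])
  y <- xv * gexp
  dim(y) <- d
  ag_op(y, list(x, gate),
        list(function(g) { r <- g * gexp; dim(r) <- d; r },
             function(g) {
               m <- .colSums(matrix(g * xv, nrow = d[1] * d[2]),
                             d[1] * d[2], d[3] * d[4])
               dim(m) <- c(1L, 1L, d[3], d[4])
               m
             }))
}

#' Concatenate feature maps along the channel axis
#' @keywords internal
ag_concat <- function(xs) {
  vals <- lapply(xs, ag_value)
  d1 <- dim(vals[[1]])
  chans <- vapply(vals, function(v) dim(v)[3], numeric(1))
  out <- array(0, c(d1[1], d1[2], sum(chans), d1[4]))
  off <- 0L
  for (v in vals) {
    cc <- dim(v)[3]
    out[, , off + seq_len(cc), ] <- v
    off <- off + cc
  }
  offsets <- cumsum(c(0, chans))
  gradfns <- lapply(seq_along(xs), function(k) {
    lo <- offsets[k]; cc <- chans[k]
    force(lo); force(cc)
    function(g) g[, , lo + seq_len(cc), , drop = FALSE]
  })
  ag_op(out, xs, gradfns)
}

#' Global average pooling to (1,1,C,N)
#' @keywords internal
ag_gap <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  m <- matrix(.colMeans(matrix(xv, nrow = d[1] * d[2]), d[1] * d[2],
                        d[3] * d[4]), d[3], d[4])
  dim(m) <- c(1L, 1L, d[3], d[4])
  ag_op(m, list(x), list(function(g) {
    r <- rep(as.numeric(g) / (d[1] * d[2]), each = d[1] * d[2])
    dim(r) <- d
    r
  }))
}

#' Max pooling (differentiable)
#' @keywords internal
ag_maxpool <- function(x, k = 3L, stride = 2L, pad = 1L) {
  xv <- ag_value(x)
  xdim <- dim(xv)
  res <- cpp_maxpool_fwd(as.numeric(xv), as.integer(xdim), as.integer(k),
                         as.integer(stride), as.integer(pad))
  ag_op(res$y, list(x), list(function(g)
    cpp_maxpool_bwd(as.numeric(g), res$argmax, as.integer(xdim))))
}

# -- bilinear interpolation -------------------------------------------------

# Interpolation matrix (out x in), half-pixel-centre convention
# (align_corners = FALSE).
bilinear_matrix <- function(n_in, n_out) {
  key <- paste0("bl_", n_in, "_", n_out)
  cache <- .ag$bl_cache
  if (is.null(cache)) { cache <- new.env(parent = emptyenv()); .ag$bl_cache <- cache }
  if (!is.null(cache[[key]])) return(cache[[key]])
  A <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i0 <- floor(src)
  t <- src - i0
  lo <- pmin(pmax(i0, 0), n_in - 1) + 1
  hi <- pmin(pmax(i0 + 1, 0), n_in - 1) + 1
  for (i in seq_len(n_out)) {
    A[i, lo[i]] <- A[i, lo[i]] + (1 - t[i])
    A[i, hi[i]] <- A[i, hi[i]] + t[i]
  }
  cache[[key]] <- A
  A
}

resize_bilinear_array <- function(xv, oh, ow) {
  d <- dim(xv)
  Ah <- bilinear_matrix(d[1], oh)
  Aw <- bilinear_matrix(d[2], ow)
  t1 <- Ah %*% matrix(xv, d[1], d[2] * d[3] * d[4])          # (oh, W*C*N)
  a1 <- aperm(array(t1, c(oh, d[2], d[3] * d[4])), c(2, 1, 3))
  t2 <- Aw %*% matrix(a1, d[2], oh * d[3] * d[4])            # (ow, oh*C*N)
  a2 <- aperm(array(t2, c(ow, oh, d[3] * d[4])), c(2, 1, 3))
  array(a2, c(oh, ow, d[3], d[4]))
}

#' Bilinear upsampling/resizing (differentiable)
#' @keywords internal
ag_upsample_bilinear <- function(x, oh, ow) {
  xv <- ag_value(x)
  d <- dim(xv)
  y <- resize_bilinear_array(xv, oh, ow)
  Ah <- bilinear_matrix(d[1], oh)
  Aw <- bilinear_matrix(d[2], ow)
  ag_op(y, list(x), list(function(g) {
    t1 <- t(Ah) %*% matrix(g, oh, ow * d[3] * d[4])
    a1 <- aperm(array(t1, c(d[1], ow, d[3] * d[4])), c(2, 1, 3))
    t2 <- t(Aw) %*% matrix(a1, ow, d[1] * d[3] * d[4])
    a2 <- aperm(array(t2, c(d[2], d[1], d[3] * d[4])), c(2, 1, 3))
    array(a2, d)
  }))
}

#' Channel-wise softmax (differentiable)
#' @keywords internal
ag_softmax <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  e <- exp(xv - chan_rep(chan_max(xv), d[3]))
  p <- e / chan_rep(chan_sum(e), d[3])
  ag_op(p, list(x), list(function(g) {
    p * (g - chan_rep(chan_sum(g * p), d[3]))
  }))
}

#' Select one channel of a 4-D node (keeps a singleton channel axis)
#' @keywords internal
ag_channel <- function(x, ch) {
  xv <- ag_value(x)
  d <- dim(xv)
  y <- xv[, , ch, , drop = FALSE]
  ag_op(y, list(x), list(function(g) {
    r <- array(0, d)
    r[, , ch, ] <- g
    r
  }))
}
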