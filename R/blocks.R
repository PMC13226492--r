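# ---------------------------------------------------------------------------
# The three structure-oriented operators: the dual-path differential feature
# enhancer (DPF), the edge-gated atrous spatial pyramid (ASPP-E) and the
# confidence-gated hybrid decoder (EHD).  Each is a pure feature-map
# transform, independently constructible and testable.
# ---------------------------------------------------------------------------

# Accept (H,W,C) or (H,W,C,N) arrays; return in the caller's rank.
as_feature4d <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("feature maps must be 3-D or 4-D arrays")
  x
}

restore_rank <- function(y, template) {
  if (length(dim(template)) == 3L) {
    d <- dim(y)
    dim(y) <- d[1:3]
  }
  y
}

#' Dual-path differential feature module
#'
#' Decomposes a feature map into a localized detail path (depthwise 3x3
#' convolution) and a broader context path (dilated grouped 3x3 convolution),
#' forms a sigmoid-normalized differential response through a learnable 1x1
#' projection, suppresses noise-amplifying channels with a squeeze-excite
#' style channel gate, and adds the result back through a learnable scalar
#' `alpha` (initialized at 0 so the module starts as the identity).
#'
#' @param channels number of input (= output) channels.
#' @param detail_kernel kernel size of the depthwise detail path.
#' @param context_dilation dilation rate of the context path.
#' @param context_groups group count of the context-path convolution.
#' @param gate_reduction bottleneck reduction of the channel gate.
#' @return an `nn_module` implementing the transform.
#' @export
dpf_module <- function(channels, detail_kernel = 3L, context_dilation = 4L,
                       context_groups = min(64L, channels),
                       gate_reduction = 4L) {
  if (channels %% context_groups != 0)
    stop("channels must be divisible by context_groups")
  hidden <- max(1L, channels %/% gate_reduction)
  st <- new.env(parent = emptyenv())
  new_module(
    "dpf",
    fwd = function(m, x, training) {
      fd <- module_forward(m$children$detail, x, training)
      fc <- module_forward(m$children$context, x, training)
      diff <- ag_sub(fd, fc)
      fdiff <- ag_sigmoid(module_forward(m$children$proj, diff, training))
      g <- ag_gap(fdiff)
      g <- module_forward(m$children$gate_fc1, g, training)
      g <- ag_relu(g)
      g <- ag_sigmoid(module_forward(m$children$gate_fc2, g, training))
      m$state$last_gate <- ag_value(g)
      m$state$last_fdiff <- ag_value(fdiff)
      gated <- ag_gate_channel(fdiff, g)
      ag_axpy(x, m$params$alpha, gated)
    },
    params = list(alpha = ag_param(0)),
    children = list(
      detail = nn_cbr(channels, channels, detail_kernel, groups = channels),
      context = nn_cbr(channels, channels, 3L, dilation = context_dilation,
                       groups = context_groups),
      proj = nn_conv(channels, channels, 1L, bias = TRUE),
      gate_fc1 = nn_conv(channels, hidden, 1L, bias = TRUE),
      gate_fc2 = nn_conv(hidden, channels, 1L, bias = TRUE)),
    state = st,
    meta = list(channels = channels))
}

#' Apply a dual-path differential feature module
#'
#' @param f feature map, array (H,W,C) or (H,W,C,N).
#' @param module a [dpf_module()].
#' @param training logical; use batch statistics in the normalization layers.
#' @return enhanced feature map, same shape as `f`.
#' @export
dpf_forward <- function(f, module, training = FALSE) {
  x <- as_feature4d(f)
  if (dim(x)[3] != module$meta$channels)
    stop("dpf_forward: feature map has ", dim(x)[3],
         " channels, module expects ", module$meta$channels)
  y <- ag_value(module_forward(module, x, training))
  restore_rank(y, f)
}

#' Edge-gated atrous spatial pyramid module (ASPP-E)
#'
#' Classical atrous spatial pyramid pooling - parallel branches with dilation
#' rates 1 (a 1x1 convolution), 6, 12 and 18 plus a global-pooling branch -
#' extended with a single-channel edge-confidence gate predicted from the
#' input by a 1x1 convolution and applied multiplicatively to every
#' convolutional branch.  With `edge_gated = FALSE` the module is the
#' classical pyramid.
#'
#' @param in_channels,out_channels branch input/output widths.
#' @param dilations dilation rates of the convolutional branches; rate 1 is
#'   realized as a 1x1 convolution.
#' @param edge_gated logical; include the edge gate.
#' @return an `nn_module`.
#' @export
asppe_module <- function(in_channels, out_channels = 256L,
                         dilations = c(1L, 6L, 12L, 18L), edge_gated = TRUE) {
  branches <- lapply(dilations, function(d) {
    if (d == 1L) nn_cbr(in_channels, out_channels, 1L)
    else nn_cbr(in_channels, out_channels, 3L, dilation = d)
  })
  names(branches) <- sprintf("branch_d%d", dilations)
  children <- c(branches,
                list(pool_conv = nn_cbr(in_channels, out_channels, 1L),
                     proj = nn_cbr(out_channels * (length(dilations) + 1L),
                                   out_channels, 1L)))
  if (edge_gated)
    children$edge <- nn_conv(in_channels, 1L, 1L, bias = TRUE)
  st <- new.env(parent = emptyenv())
  new_module(
    "asppe",
    fwd = function(m, x, training) {
      d <- dim(ag_value(x))
      gate <- NULL
      if (isTRUE(m$meta$edge_gated)) {
        gate <- ag_sigmoid(module_forward(m$children$edge, x, training))
        m$state$last_gate <- ag_value(gate)
      }
      outs <- list()
      for (nm in names(m$children)) {
        if (!startsWith(nm, "branch_")) next
        b <- module_forward(m$children[[nm]], x, training)
        if (!is.null(gate)) b <- ag_gate_spatial(b, gate)
        outs[[length(outs) + 1L]] <- b
      }
      p <- ag_gap(x)
      p <- module_forward(m$children$pool_conv, p, training)
      outs[[length(outs) + 1L]] <- ag_upsample_bilinear(p, d[1], d[2])
      module_forward(m$children$proj, ag_concat(outs), training)
    },
    children = children,
    state = st,
    meta = list(in_channels = in_channels, out_channels = out_channels,
                edge_gated = edge_gated))
}

#' Apply an ASPP-E (or classical ASPP) module
#'
#' @param f_in input feature map, (H,W,C) or (H,W,C,N).
#' @param module an [asppe_module()].
#' @param training logical; use batch statistics.
#' @return projected multi-scale feature map at the input's spatial shape.
#' @export
asppe_forward <- function(f_in, module, training = FALSE) {
  x <- as_feature4d(f_in)
  if (dim(x)[3] != module$meta$in_channels)
    stop("asppe_forward: channel mismatch")
  y <- ag_value(module_forward(module, x, training))
  restore_rank(y, f_in)
}

#' Confidence-gated hybrid decoder module (EHD)
#'
#' Estimates a single-channel confidence map from the deep semantic feature
#' with a 1x1 convolution and sigmoid, upsamples it to the shallow feature's
#' resolution, gates the (channel-reduced) shallow feature with it, and fuses
#' the gated shallow feature with the bilinearly upsampled semantic feature
#' through a hybrid convolutional block (two 3x3 conv-BN-ReLU stages).  With
#' `conf_gated = FALSE` and `two_stage = FALSE` the module reduces to the
#' plain concatenation decoder used by the reference network.
#'
#' @param sem_channels channels of the deep semantic feature.
#' @param shallow_channels channels of the raw shallow feature.
#' @param shallow_reduced width the shallow feature is reduced to before
#'   fusion.
#' @param out_channels width of the fused output.
#' @param conf_gated logical; apply the confidence gate.
#' @param two_stage logical; use the second fusion stage.
#' @return an `nn_module`.
#' @export
ehd_module <- function(sem_channels, shallow_channels, shallow_reduced = 48L,
                       out_channels = 256L, conf_gated = TRUE,
                       two_stage = TRUE) {
  children <- list(
    reduce = nn_cbr(shallow_channels, shallow_reduced, 1L),
    fuse1 = nn_cbr(shallow_reduced + sem_channels, out_channels, 3L))
  if (conf_gated) children$conf <- nn_conv(sem_channels, 1L, 1L, bias = TRUE)
  if (two_stage) children$fuse2 <- nn_cbr(out_channels, out_channels, 3L)
  st <- new.env(parent = emptyenv())
  new_module(
    "ehd",
    fwd = function(m, xs, training) {
      f_sem <- xs$sem
      f_shallow <- xs$shallow
      ds <- dim(ag_value(f_sem)); dh <- dim(ag_value(f_shallow))
      if (dh[1] %% ds[1] != 0 || dh[2] %% ds[2] != 0)
        stop("ehd: shallow spatial dims must be integer multiples of the ",
             "semantic feature's")
      sh <- module_forward(m$children$reduce, f_shallow, training)
      if (isTRUE(m$meta$conf_gated)) {
        conf <- ag_sigmoid(module_forward(m$children$conf, f_sem, training))
        m$state$last_gate <- ag_value(conf)
        conf_up <- ag_upsample_bilinear(conf, dh[1], dh[2])
        sh <- ag_gate_spatial(sh, conf_up)
      }
      sem_up <- ag_upsample_bilinear(f_sem, dh[1], dh[2])
      y <- module_forward(m$children$fuse1, ag_concat(list(sh, sem_up)),
                          training)
      if (isTRUE(m$meta$two_stage))
        y <- module_forward(m$children$fuse2, y, training)
      y
    },
    children = children,
    state = st,
    meta = list(sem_channels = sem_channels,
                shallow_channels = shallow_channels,
                conf_gated = conf_gated, two_stage = two_stage))
}

#' Apply a confidence-gated hybrid decoder module
#'
#' @param f_sem deep semantic feature map (H,W,C) or (H,W,C,N).
#' @param f_shallow shallow feature map at an integer multiple of `f_sem`'s
#'   spatial resolution.
#' @param module an [ehd_module()].
#' @param training logical; use batch statistics.
#' @return fused feature map at the shallow resolution.
#' @export
ehd_forward <- function(f_sem, f_shallow, module, training = FALSE) {
  xs <- list(sem = as_feature4d(f_sem), shallow = as_feature4d(f_shallow))
  y <- ag_value(module_forward(module, xs, training))
  restore_rank(y, f_shallow)
}
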