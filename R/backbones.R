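# ---------------------------------------------------------------------------
# Encoders.  Both expose the same contract: forward(x) returns
# list(shallow = stride-4 feature, deep = stride-16 feature).
# ---------------------------------------------------------------------------

resnet_bottleneck <- function(in_ch, mid, out_ch, stride = 1L, dilation = 1L) {
  children <- list(
    conv1 = nn_conv(in_ch, mid, 1L),
    bn1 = nn_bn(mid),
    conv2 = nn_conv(mid, mid, 3L, stride = stride, dilation = dilation),
    bn2 = nn_bn(mid),
    conv3 = nn_conv(mid, out_ch, 1L),
    bn3 = nn_bn(out_ch))
  has_ds <- (stride != 1L || in_ch != out_ch)
  if (has_ds) {
    children$ds_conv <- nn_conv(in_ch, out_ch, 1L, stride = stride)
    children$ds_bn <- nn_bn(out_ch)
  }
  new_module(
    "bottleneck",
    fwd = function(m, x, training) {
      y <- ag_relu(module_forward(m$children$bn1,
                                  module_forward(m$children$conv1, x, training),
                                  training))
      y <- ag_relu(module_forward(m$children$bn2,
                                  module_forward(m$children$conv2, y, training),
                                  training))
      y <- module_forward(m$children$bn3,
                          module_forward(m$children$conv3, y, training),
                          training)
      idn <- if (isTRUE(m$meta$has_ds)) {
        module_forward(m$children$ds_bn,
                       module_forward(m$children$ds_conv, x, training),
                       training)
      } else x
      ag_relu(ag_add(y, idn))
    },
    children = children,
    meta = list(has_ds = has_ds))
}

resnet_layer <- function(n_blocks, in_ch, mid, out_ch, stride = 1L,
                         dilation = 1L) {
  blocks <- vector("list", n_blocks)
  blocks[[1]] <- resnet_bottleneck(in_ch, mid, out_ch, stride, dilation)
  for (i in seq_len(n_blocks - 1L) + 1L)
    blocks[[i]] <- resnet_bottleneck(out_ch, mid, out_ch, 1L, dilation)
  names(blocks) <- sprintf("b%02d", seq_len(n_blocks))
  do.call(nn_seq, blocks)
}

# ResNet101 with output stride 16: the final stage keeps stride 1 and uses
# dilation 2, the standard dilated-backbone convention for segmentation.
resnet101_backbone <- function(in_channels = 1L) {
  new_module(
    "resnet101",
    fwd = function(m, x, training) {
      y <- module_forward(m$children$stem, x, training)
      shallow <- module_forward(m$children$layer1, y, training)
      y <- module_forward(m$children$layer2, shallow, training)
      y <- module_forward(m$children$layer3, y, training)
      deep <- module_forward(m$children$layer4, y, training)
      list(shallow = shallow, deep = deep)
    },
    children = list(
      stem = nn_seq(conv = nn_conv(in_channels, 64L, 7L, stride = 2L, pad = 3L),
                    bn = nn_bn(64L), relu = nn_relu(),
                    pool = nn_maxpool(3L, 2L, 1L)),
      layer1 = resnet_layer(3L, 64L, 64L, 256L),
      layer2 = resnet_layer(4L, 256L, 128L, 512L, stride = 2L),
      layer3 = resnet_layer(23L, 512L, 256L, 1024L, stride = 2L),
      layer4 = resnet_layer(3L, 1024L, 512L, 2048L, stride = 1L,
                            dilation = 2L)),
    meta = list(shallow_channels = 256L, deep_channels = 2048L,
                min_input = 32L))
}

# A reduced 4-stage encoder (widths 16-128) for desk-scale training.  Same
# contract and the same output stride (4 shallow, 16 deep) as the ResNet.
tiny_backbone <- function(in_channels = 1L, widths = c(16L, 32L, 64L, 128L)) {
  new_module(
    "tiny",
    fwd = function(m, x, training) {
      y <- module_forward(m$children$stem, x, training)
      y <- module_forward(m$children$stage1, y, training)
      shallow <- module_forward(m$children$stage2, y, training)
      y <- module_forward(m$children$stage3, shallow, training)
      deep <- module_forward(m$children$stage4, y, training)
      list(shallow = shallow, deep = deep)
    },
    children = list(
      stem = nn_cbr(in_channels, widths[1], 3L),
      stage1 = nn_cbr(widths[1], widths[1], 3L, stride = 2L),
      stage2 = nn_seq(down = nn_cbr(widths[1], widths[2], 3L, stride = 2L),
                      conv = nn_cbr(widths[2], widths[2], 3L)),
      stage3 = nn_seq(down = nn_cbr(widths[2], widths[3], 3L, stride = 2L),
                      conv = nn_cbr(widths[3], widths[3], 3L)),
      stage4 = nn_seq(down = nn_cbr(widths[3], widths[4], 3L, stride = 2L),
                      conv = nn_cbr(widths[4], widths[4], 3L))),
    meta = list(shallow_channels = widths[2], deep_channels = widths[4],
                min_input = 16L))
}
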