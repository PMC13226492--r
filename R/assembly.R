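# ---------------------------------------------------------------------------
# Full-network assembly: encoder -> (DPF) -> ASPP(-E) -> decoder (EHD or
# plain) -> classifier -> bilinear upsample to input resolution.  With all
# three module switches off the assembly is exactly the DeepLabv3+ reference.
# ---------------------------------------------------------------------------

#' Network configuration
#'
#' All architectural free parameters of the segmentation network, including
#' the three module on/off switches used in ablations.
#'
#' @param backbone `"resnet101"` (the full encoder) or `"tiny"` (a reduced
#'   4-stage encoder, widths 16-128, for desk-scale training).
#' @param num_classes number of output classes (2: background/lesion).
#' @param in_channels input image channels (1: grayscale ultrasound).
#' @param aspp_out_channels width of the pyramid output; default 256 for the
#'   ResNet backbone, 64 for the tiny backbone.
#' @param shallow_reduced_channels width the shallow skip feature is reduced
#'   to; default 48 (ResNet) / 32 (tiny).
#' @param dpf_enabled,asppe_enabled,ehd_enabled module switches.
#' @param seed integer seed controlling weight initialization.
#' @return object of class `network_config`.
#' @export
network_config <- function(backbone = c("resnet101", "tiny"),
                           num_classes = 2L, in_channels = 1L,
                           aspp_out_channels = NULL,
                           shallow_reduced_channels = NULL,
                           dpf_enabled = TRUE, asppe_enabled = TRUE,
                           ehd_enabled = TRUE, seed = 1L) {
  backbone <- match.arg(backbone)
  if (is.null(aspp_out_channels))
    aspp_out_channels <- if (backbone == "resnet101") 256L else 64L
  if (is.null(shallow_reduced_channels))
    shallow_reduced_channels <- if (backbone == "resnet101") 48L else 32L
  cfg <- list(backbone = backbone, num_classes = as.integer(num_classes),
              in_channels = as.integer(in_channels),
              output_stride = 16L,
              aspp_out_channels = as.integer(aspp_out_channels),
              shallow_reduced_channels = as.integer(shallow_reduced_channels),
              dpf_enabled = isTRUE(dpf_enabled),
              asppe_enabled = isTRUE(asppe_enabled),
              ehd_enabled = isTRUE(ehd_enabled),
              seed = as.integer(seed))
  class(cfg) <- "network_config"
  cfg
}

#' Assemble a segmentation network
#'
#' @param config a [network_config()].
#' @return object of class `ehd_network`.
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  with_seed(derive_seed(config$seed, "init"), {
    backbone <- switch(config$backbone,
                       resnet101 = resnet101_backbone(config$in_channels),
                       tiny = tiny_backbone(config$in_channels),
                       stop("unknown backbone: ", config$backbone))
    deep_ch <- backbone$meta$deep_channels
    shallow_ch <- backbone$meta$shallow_channels
    modules <- list(backbone = backbone)
    if (config$dpf_enabled) modules$dpf <- dpf_module(deep_ch)
    modules$aspp <- asppe_module(deep_ch, config$aspp_out_channels,
                                 edge_gated = config$asppe_enabled)
    modules$decoder <- ehd_module(config$aspp_out_channels, shallow_ch,
                                  config$shallow_reduced_channels,
                                  config$aspp_out_channels,
                                  conf_gated = config$ehd_enabled,
                                  two_stage = config$ehd_enabled)
    modules$classifier <- nn_conv(config$aspp_out_channels,
                                  config$num_classes, 1L, bias = TRUE)
    net <- list(config = config, modules = modules,
                params = network_params(modules))
    class(net) <- "ehd_network"
    net
  })
}

network_params <- function(modules) {
  out <- list()
  for (nm in names(modules))
    out <- c(out, collect_params(modules[[nm]], paste0(nm, ".")))
  out
}

# Forward pass to logits; returns an ag node when called inside a tape.
network_logits <- function(net, x, training = FALSE) {
  d <- dim(ag_value(x))
  if (d[3] != net$config$in_channels)
    stop("network expects ", net$config$in_channels, "-channel input, got ",
         d[3])
  feats <- module_forward(net$modules$backbone, x, training)
  deep <- feats$deep
  if (!is.null(net$modules$dpf))
    deep <- module_forward(net$modules$dpf, deep, training)
  sem <- module_forward(net$modules$aspp, deep, training)
  fused <- module_forward(net$modules$decoder,
                          list(sem = sem, shallow = feats$shallow), training)
  logits <- module_forward(net$modules$classifier, fused, training)
  ag_upsample_bilinear(logits, d[1], d[2])
}

#' Forward pass producing per-pixel class probabilities
#'
#' @param network an `ehd_network` (or U-Net from [build_baseline()]).
#' @param images array (H,W,C,N), (H,W,N) or a single (H,W) image in `[0,1]`.
#' @param training logical; use batch statistics in normalization layers.
#' @return array (H,W,num_classes,N) of softmax probabilities.
#' @export
network_forward <- function(network, images, training = FALSE) {
  x <- as_image_batch(images, network$config$in_channels)
  p <- ag_softmax(net_logits(network, x, training))
  ag_value(p)
}

as_image_batch <- function(images, in_channels = 1L) {
  d <- dim(images)
  if (is.null(d)) stop("images must be a matrix or array")
  if (length(d) == 2L) dim(images) <- c(d, 1L, 1L)
  else if (length(d) == 3L) {
    # interpret (H,W,N) stacks of single-channel images
    images <- array(images, c(d[1], d[2], 1L, d[3]))
  } else if (length(d) != 4L) stop("images must have 2-4 dimensions")
  images
}

#' Count trainable parameters
#' @param network an assembled network.
#' @return exact integer-valued count of trainable scalars.
#' @export
count_parameters <- function(network) {
  sum(vapply(network$params, function(p) length(ag_value(p)), numeric(1)))
}

#' Count multiply-accumulate operations for one input
#'
#' Sums kernel-volume x output-elements products over convolutional and
#' linear layers only (normalization, activations, pooling and
#' interpolation are excluded, the usual convention for reporting "FLOPs"
#' of convolutional networks as multiply-accumulates).
#'
#' @param network an assembled network.
#' @param input_size spatial input side length (or c(H, W)).
#' @return MAC count as a double.
#' @export
count_macs <- function(network, input_size = 256L) {
  if (length(input_size) == 1L) input_size <- c(input_size, input_size)
  x <- array(0, c(input_size[1], input_size[2],
                  network$config$in_channels, 1L))
  ag_profile_macs(invisible(network_forward(network, x, training = FALSE)))
}

#' Model complexity report
#' @param network an assembled network.
#' @param input_size spatial side length used for the MAC count.
#' @return list with `parameter_count` and `macs`, class `complexity_report`.
#' @export
complexity_report <- function(network, input_size = 256L) {
  rep <- list(parameter_count = count_parameters(network),
              macs = count_macs(network, input_size),
              input_size = input_size)
  class(rep) <- "complexity_report"
  rep
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("Parameters: %.2f M (%d)\n", x$parameter_count / 1e6,
              as.integer(x$parameter_count)))
  cat(sprintf("MACs @ %dx%d: %.2f G\n", x$input_size[1],
              x$input_size[length(x$input_size)], x$macs / 1e9))
  invisible(x)
}

#' @export
print.ehd_network <- function(x, ...) {
  cfg <- x$config
  on <- c(if (cfg$dpf_enabled) "DPF", if (cfg$asppe_enabled) "ASPP-E",
          if (cfg$ehd_enabled) "EHD")
  cat("<ehd_network>\n")
  cat("  backbone:", cfg$backbone, "| classes:", cfg$num_classes,
      "| in-channels:", cfg$in_channels, "\n")
  cat("  modules enabled:", if (length(on)) paste(on, collapse = " + ")
      else "none (reference DeepLabv3+ assembly)", "\n")
  cat(sprintf("  parameters: %.2f M\n", count_parameters(x) / 1e6))
  invisible(x)
}

#' @export
summary.ehd_network <- function(object, input_size = NULL, ...) {
  if (is.null(input_size))
    input_size <- if (object$config$backbone == "resnet101") 256L else 64L
  print(object)
  print(complexity_report(object, input_size))
  invisible(object)
}

# ---------------------------------------------------------------------------
# Reference baselines
# ---------------------------------------------------------------------------

unet_double_conv <- function(in_ch, out_ch) {
  nn_seq(c1 = nn_conv(in_ch, out_ch, 3L, bias = TRUE), r1 = nn_relu(),
         c2 = nn_conv(out_ch, out_ch, 3L, bias = TRUE), r2 = nn_relu())
}

build_unet <- function(in_channels = 1L, num_classes = 2L, seed = 1L) {
  with_seed(derive_seed(seed, "init"), {
    modules <- list(
      enc1 = unet_double_conv(in_channels, 64L),
      enc2 = unet_double_conv(64L, 128L),
      enc3 = unet_double_conv(128L, 256L),
      enc4 = unet_double_conv(256L, 512L),
      bottom = unet_double_conv(512L, 1024L),
      up4 = nn_conv_transpose(1024L, 512L, 2L, stride = 2L),
      dec4 = unet_double_conv(1024L, 512L),
      up3 = nn_conv_transpose(512L, 256L, 2L, stride = 2L),
      dec3 = unet_double_conv(512L, 256L),
      up2 = nn_conv_transpose(256L, 128L, 2L, stride = 2L),
      dec2 = unet_double_conv(256L, 128L),
      up1 = nn_conv_transpose(128L, 64L, 2L, stride = 2L),
      dec1 = unet_double_conv(128L, 64L),
      head = nn_conv(64L, num_classes, 1L, bias = TRUE),
      pool = nn_maxpool(2L, 2L, 0L))
    cfg <- list(backbone = "unet", num_classes = as.integer(num_classes),
                in_channels = as.integer(in_channels), seed = as.integer(seed))
    net <- list(config = cfg, modules = modules,
                params = network_params(modules[names(modules) != "pool"]))
    class(net) <- c("unet_network", "ehd_network")
    net
  })
}

unet_logits <- function(net, x, training = FALSE) {
  mm <- net$modules
  e1 <- module_forward(mm$enc1, x, training)
  e2 <- module_forward(mm$enc2, module_forward(mm$pool, e1, training), training)
  e3 <- module_forward(mm$enc3, module_forward(mm$pool, e2, training), training)
  e4 <- module_forward(mm$enc4, module_forward(mm$pool, e3, training), training)
  b <- module_forward(mm$bottom, module_forward(mm$pool, e4, training), training)
  d4 <- module_forward(mm$dec4,
                       ag_concat(list(module_forward(mm$up4, b, training), e4)),
                       training)
  d3 <- module_forward(mm$dec3,
                       ag_concat(list(module_forward(mm$up3, d4, training), e3)),
                       training)
  d2 <- module_forward(mm$dec2,
                       ag_concat(list(module_forward(mm$up2, d3, training), e2)),
                       training)
  d1 <- module_forward(mm$dec1,
                       ag_concat(list(module_forward(mm$up1, d2, training), e1)),
                       training)
  module_forward(mm$head, d1, training)
}

#' Build a reference baseline network
#'
#' `"deeplabv3plus"` is [build_network()] with all three module switches off;
#' `"unet"` is the classic 64-1024 width-doubling encoder-decoder with skip
#' concatenation ('same' padding so output resolution equals input).
#'
#' @param name `"unet"` or `"deeplabv3plus"`.
#' @param in_channels,num_classes,seed as in [network_config()].
#' @param backbone encoder token for the DeepLab variant.
#' @return a network object.
#' @export
build_baseline <- function(name = c("unet", "deeplabv3plus"),
                           in_channels = 1L, num_classes = 2L, seed = 1L,
                           backbone = "resnet101") {
  name <- match.arg(name)
  if (name == "deeplabv3plus") {
    build_network(network_config(backbone = backbone,
                                 num_classes = num_classes,
                                 in_channels = in_channels,
                                 dpf_enabled = FALSE, asppe_enabled = FALSE,
                                 ehd_enabled = FALSE, seed = seed))
  } else {
    build_unet(in_channels, num_classes, seed)
  }
}

# Dispatch logits computation by network family.
net_logits <- function(network, x, training = FALSE) {
  if (inherits(network, "unet_network")) unet_logits(network, x, training)
  else network_logits(network, x, training)
}

# ---------------------------------------------------------------------------
# Checkpointing: weights + buffers + config + seed in one archive.
# ---------------------------------------------------------------------------

collect_states <- function(m, prefix = "") {
  out <- list()
  if (!is.null(m$state) && !is.null(m$state$running_mean))
    out[[prefix]] <- list(running_mean = m$state$running_mean,
                          running_var = m$state$running_var)
  for (cn in names(m$children))
    out <- c(out, collect_states(m$children[[cn]], paste0(prefix, cn, ".")))
  out
}

network_states <- function(net) {
  out <- list()
  for (nm in names(net$modules))
    out <- c(out, collect_states(net$modules[[nm]], paste0(nm, ".")))
  out
}

restore_states <- function(m, states, prefix = "") {
  if (!is.null(m$state) && !is.null(states[[prefix]])) {
    m$state$running_mean <- states[[prefix]]$running_mean
    m$state$running_var <- states[[prefix]]$running_var
  }
  for (cn in names(m$children))
    restore_states(m$children[[cn]], states, paste0(prefix, cn, "."))
  invisible(NULL)
}

#' Save network weights, buffers and configuration
#' @param network a network built by [build_network()] or [build_baseline()].
#' @param path destination file.
#' @export
save_network <- function(network, path) {
  saveRDS(list(config = network$config,
               values = lapply(network$params, ag_value),
               states = network_states(network)),
          path)
  invisible(path)
}

#' Load a network saved with [save_network()]
#' @param path checkpoint file.
#' @return the restored network.
#' @export
load_network <- function(path) {
  ck <- readRDS(path)
  net <- if (identical(ck$config$backbone, "unet")) {
    build_unet(ck$config$in_channels, ck$config$num_classes, ck$config$seed)
  } else {
    build_network(ck$config)
  }
  for (nm in names(ck$values)) net$params[[nm]]$value <- ck$values[[nm]]
  for (mn in names(net$modules))
    restore_states(net$modules[[mn]], ck$states, paste0(mn, "."))
  net
}
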