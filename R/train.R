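# ---------------------------------------------------------------------------
# Fixed-iteration training protocol: SGD with momentum, linear warm-up into
# polynomial learning-rate decay, horizontal-flip augmentation, two
# parameter groups (backbone at 0.1x), flip test-time augmentation, and the
# multi-seed evaluation harness.  The final-iteration weights are always the
# returned model; no validation-based checkpoint selection takes place.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' @param base_lr initial (post-warm-up) learning rate of the non-backbone
#'   parameter group.
#' @param momentum SGD momentum (classical, non-Nesterov).
#' @param weight_decay L2 penalty added to gradients.
#' @param poly_power exponent of the polynomial decay.
#' @param backbone_lr_multiplier learning-rate factor for encoder weights.
#' @param batch_size images per iteration.
#' @param total_iterations fixed iteration budget.
#' @param warmup_iterations linear warm-up length.
#' @param input_size training resolution (side length).
#' @param flip_probability probability of horizontal-flip augmentation.
#' @param tta logical; average predictions over horizontal flips at test
#'   time.
#' @param seeds integer seeds for [multi_seed_run()].
#' @param loss a [loss_config()].
#' @return object of class `train_config`.
#' @export
train_config <- function(base_lr = 0.01, momentum = 0.9, weight_decay = 1e-4,
                         poly_power = 0.9, backbone_lr_multiplier = 0.1,
                         batch_size = 8L, total_iterations = 20000L,
                         warmup_iterations = 500L, input_size = 256L,
                         flip_probability = 0.5, tta = TRUE,
                         seeds = c(10L, 100L, 1000L),
                         loss = loss_config()) {
  cfg <- list(base_lr = base_lr, momentum = momentum,
              weight_decay = weight_decay, poly_power = poly_power,
              backbone_lr_multiplier = backbone_lr_multiplier,
              batch_size = as.integer(batch_size),
              total_iterations = as.integer(total_iterations),
              warmup_iterations = as.integer(warmup_iterations),
              input_size = as.integer(input_size),
              flip_probability = flip_probability, tta = isTRUE(tta),
              seeds = as.integer(seeds), loss = loss)
  class(cfg) <- "train_config"
  cfg
}

#' Desk-scale training configuration
#'
#' The reduced protocol used for experiments on 64x64 phantoms with the
#' tiny backbone: 1,000 iterations, 50 warm-up iterations, batch size 4.
#' All other settings keep the full-protocol values.
#' @param ... overrides passed to [train_config()].
#' @export
desk_train_config <- function(...) {
  args <- list(total_iterations = 1000L, warmup_iterations = 50L,
               batch_size = 4L, input_size = 64L)
  override <- list(...)
  args[names(override)] <- override
  do.call(train_config, args)
}

#' Polynomial learning-rate schedule with linear warm-up
#'
#' During warm-up the rate rises linearly from 0 to `base_lr`; afterwards it
#' decays as `base_lr * (1 - t/T)^power` with `t` counted past warm-up, so
#' the rate is exactly `base_lr` at the end of warm-up and 0 at the final
#' iteration.
#'
#' @param iteration iteration index in `[0, total_iterations]`.
#' @param cfg a [train_config()].
#' @return learning rate.
#' @export
poly_lr <- function(iteration, cfg) {
  if (any(iteration < 0 | iteration > cfg$total_iterations))
    stop("iteration out of [0, total_iterations]")
  w <- cfg$warmup_iterations
  T_decay <- cfg$total_iterations - w
  ifelse(iteration < w,
         cfg$base_lr * iteration / max(w, 1L),
         cfg$base_lr * (1 - (iteration - w) / T_decay)^cfg$poly_power)
}

flip_w <- function(x) {
  # mirror the width axis (dim 2) of a (H,W,...) array
  d <- dim(x)
  idx <- rev(seq_len(d[2]))
  if (length(d) == 2) x[, idx, drop = FALSE]
  else if (length(d) == 3) x[, idx, , drop = FALSE]
  else x[, idx, , , drop = FALSE]
}

#' Train a segmentation network
#'
#' Runs the fixed-iteration protocol and returns the final-iteration model
#' together with a per-iteration log of loss components and learning rate.
#' All randomness (shuffling, flip augmentation) derives from `seed`
#' through named sub-streams; weight initialization is owned by the
#' network's own config seed.
#'
#' @param network an assembled network (modified in place and returned).
#' @param samples list of training samples (`image` + `mask`).
#' @param cfg a [train_config()].
#' @param seed integer seed for the training-time randomness.
#' @param verbose print progress every `verbose` iterations (0 = silent).
#' @return object of class `ehdnet_fit` with elements `network`, `cfg`,
#'   `seed` and `log` (data.frame: iteration, lr, loss, ce, overlap).
#' @export
ehd_train <- function(network, samples, cfg = train_config(), seed = 1L,
                      verbose = 0L) {
  if (!length(samples)) stop("empty training set")
  stacked <- stack_samples(samples)
  n <- length(samples)
  params <- network$params
  vel <- lapply(params, function(p) 0)
  backbone_flag <- startsWith(names(params), "backbone.")
  log_it <- integer(0); log_lr <- log_loss <- numeric(0)
  shuffle_rng <- derive_seed(seed, "shuffle")
  flip_draws <- with_seed(derive_seed(seed, "augment"),
                          matrix(stats::runif(cfg$batch_size *
                                                cfg$total_iterations),
                                 cfg$batch_size, cfg$total_iterations))
  order_pool <- integer(0)
  epoch <- 0L
  with_seed(derive_seed(seed, "train"), {
    for (it in seq_len(cfg$total_iterations)) {
      if (length(order_pool) < cfg$batch_size) {
        epoch <- epoch + 1L
        perm <- with_seed(derive_seed(shuffle_rng, paste0("epoch", epoch)),
                          sample.int(n))
        order_pool <- c(order_pool, perm)
      }
      take <- order_pool[seq_len(cfg$batch_size)]
      order_pool <- order_pool[-seq_len(cfg$batch_size)]
      xb <- stacked$images[, , , take, drop = FALSE]
      yb <- stacked$masks[, , take, drop = FALSE]
      flips <- flip_draws[, it] < cfg$flip_probability
      for (b in which(flips)) {
        xb[, , , b] <- flip_w(xb[, , , b, drop = FALSE])[, , , 1]
        yb[, , b] <- flip_w(yb[, , b, drop = FALSE])[, , 1]
      }
      lr <- poly_lr(it, cfg)
      comp <- ag_record({
        loss <- total_loss(net_logits(network, xb, training = TRUE), yb,
                           cfg$loss)
        ag_backward(loss)
        ag_value(loss)
      })
      for (k in seq_along(params)) {
        p <- params[[k]]
        if (is.null(p$grad)) next
        g <- p$grad + cfg$weight_decay * p$value
        vel[[k]] <- cfg$momentum * vel[[k]] + g
        mult <- if (backbone_flag[k]) cfg$backbone_lr_multiplier else 1
        p$value <- p$value - lr * mult * vel[[k]]
        p$grad <- NULL
      }
      log_it <- c(log_it, it); log_lr <- c(log_lr, lr)
      log_loss <- c(log_loss, comp)
      if (verbose > 0 && it %% verbose == 0)
        message(sprintf("iter %d/%d lr %.5f loss %.4f", it,
                        cfg$total_iterations, lr, comp))
    }
  })
  fit <- list(network = network, cfg = cfg, seed = seed,
              log = data.frame(iteration = log_it, lr = log_lr,
                               loss = log_loss))
  class(fit) <- "ehdnet_fit"
  fit
}

#' Predict with horizontal-flip test-time augmentation
#'
#' Averages the probability maps of the image and of its horizontally
#' mirrored copy (mirrored back), `0.5 * (p(x) + flip(p(flip(x))))`.
#'
#' @param network an assembled network in evaluation mode.
#' @param images input array as accepted by [network_forward()].
#' @return array of per-pixel class probabilities.
#' @export
tta_predict <- function(network, images) {
  x <- as_image_batch(images)
  p1 <- network_forward(network, x, training = FALSE)
  p2 <- network_forward(network, flip_w(x), training = FALSE)
  0.5 * (p1 + flip_w(p2))
}

predict_probs <- function(network, images, tta = FALSE) {
  if (tta) tta_predict(network, images)
  else network_forward(network, as_image_batch(images), training = FALSE)
}

#' Evaluate a network on a sample list
#'
#' @param network an assembled network.
#' @param samples list of samples (`image` + `mask`).
#' @param tta use flip test-time augmentation.
#' @param batch_size evaluation batch size.
#' @param ... passed to [evaluate_dataset()].
#' @return a `metric_report`.
#' @export
evaluate_network <- function(network, samples, tta = TRUE, batch_size = 8L,
                             ...) {
  stacked <- stack_samples(samples)
  n <- length(samples)
  preds <- vector("list", n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    p <- predict_probs(network, stacked$images[, , , i:j, drop = FALSE], tta)
    for (b in seq_len(j - i + 1L))
      preds[[i + b - 1L]] <- (p[, , 2, b] > 0.5) * 1L
    i <- j + 1L
  }
  evaluate_dataset(preds, lapply(samples, function(s) s$mask), ...)
}

#' Multi-seed training and evaluation harness
#'
#' One full train-and-evaluate cycle per seed with architecture, data and
#' hyperparameters held fixed; reports per-seed metric rows plus mean and
#' standard deviation per metric.
#'
#' @param cfg a [train_config()] whose `seeds` field lists >= 2 seeds.
#' @param train_samples,test_samples sample lists.
#' @param network_builder function(seed) returning a freshly initialized
#'   network.
#' @param tta use flip TTA at evaluation.
#' @return list with `per_seed` (data.frame, one row per seed), `mean`,
#'   `sd`, and the fitted models in `fits`.
#' @export
multi_seed_run <- function(cfg, train_samples, test_samples, network_builder,
                           tta = TRUE) {
  seeds <- cfg$seeds
  if (length(seeds) < 2) stop("multi_seed_run needs at least 2 seeds")
  if (anyDuplicated(seeds)) warning("duplicate seeds in multi-seed run")
  rows <- list(); fits <- list()
  for (s in seeds) {
    net <- network_builder(s)
    fit <- ehd_train(net, train_samples, cfg, seed = s)
    rep <- evaluate_network(fit$network, test_samples, tta = tta)
    rows[[length(rows) + 1L]] <- cbind(seed = s, metric_report_row(rep))
    fits[[length(fits) + 1L]] <- fit
  }
  per_seed <- do.call(rbind, rows)
  num <- per_seed[, setdiff(names(per_seed), "seed"), drop = FALSE]
  list(per_seed = per_seed,
       mean = colMeans(num),
       sd = apply(num, 2, stats::sd),
       fits = fits)
}

# ---------------------------------------------------------------------------
# Methods for the fitted-model object
# ---------------------------------------------------------------------------

#' @export
print.ehdnet_fit <- function(x, ...) {
  cat("<ehdnet_fit>\n")
  print(x$network)
  n <- nrow(x$log)
  cat(sprintf("  trained %d iterations; final loss %.4f (first %.4f)\n",
              n, x$log$loss[n], x$log$loss[1]))
  invisible(x)
}

#' @export
summary.ehdnet_fit <- function(object, ...) {
  print(object)
  print(complexity_report(object$network,
                          if (object$network$config$backbone == "resnet101")
                            256L else object$cfg$input_size))
  invisible(object)
}

#' Predict lesion probability maps or masks from a fitted model
#'
#' @param object an `ehdnet_fit`.
#' @param newdata image array, or list of samples with `$image`.
#' @param type `"prob"` for class-probability maps, `"mask"` for thresholded
#'   binary masks.
#' @param tta use flip test-time augmentation (defaults to the training
#'   configuration's setting).
#' @param ... unused.
#' @export
predict.ehdnet_fit <- function(object, newdata, type = c("prob", "mask"),
                               tta = NULL, ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !is.null(newdata[[1]]$image))
    newdata <- stack_samples(newdata)$images
  tta <- tta %||% object$cfg$tta
  p <- predict_probs(object$network, newdata, tta)
  if (type == "prob") p else (p[, , 2, , drop = FALSE] > 0.5) * 1L
}

#' Plot the training loss and learning-rate schedule
#' @param x an `ehdnet_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ehdnet_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$log$iteration, x$log$loss, type = "l",
                 xlab = "iteration", ylab = "total loss", ...)
  graphics::plot(x$log$iteration, x$log$lr, type = "l",
                 xlab = "iteration", ylab = "learning rate", ...)
  invisible(x)
}
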