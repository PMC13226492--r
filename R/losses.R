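# ---------------------------------------------------------------------------
# Hybrid objective: hard-example-mined cross-entropy (weight 0.3) plus a
# unified Dice/Jaccard overlap loss (weight 0.7).
# ---------------------------------------------------------------------------

#' Loss configuration
#'
#' @param ce_weight weight of the cross-entropy term.
#' @param overlap_weight weight of the overlap term (the two must sum to 1).
#' @param ohem_keep_fraction fraction of highest-loss pixels retained by
#'   online hard example mining; 1 disables mining.
#' @param ohem_min_kept minimum number of retained pixels.
#' @param smooth_eps additive smoothing of the soft overlap ratios.
#' @return object of class `loss_config`.
#' @export
loss_config <- function(ce_weight = 0.3, overlap_weight = 0.7,
                        ohem_keep_fraction = 0.25, ohem_min_kept = 256L,
                        smooth_eps = 1e-6) {
  if (abs(ce_weight + overlap_weight - 1) > 1e-12)
    stop("ce_weight + overlap_weight must equal 1")
  if (ohem_keep_fraction <= 0 || ohem_keep_fraction > 1)
    stop("ohem_keep_fraction must lie in (0, 1]")
  cfg <- list(ce_weight = ce_weight, overlap_weight = overlap_weight,
              ohem_keep_fraction = ohem_keep_fraction,
              ohem_min_kept = as.integer(ohem_min_kept),
              smooth_eps = smooth_eps)
  class(cfg) <- "loss_config"
  cfg
}

# Per-pixel softmax cross-entropy values and probabilities (no autodiff).
pixel_ce <- function(logits_v, target) {
  d <- dim(logits_v)
  e <- exp(logits_v - chan_rep(chan_max(logits_v), d[3]))
  p <- e / chan_rep(chan_sum(e), d[3])
  tgt <- as.numeric(target)
  pick <- ifelse(tgt > 0.5, p[, , 2, , drop = TRUE], p[, , 1, , drop = TRUE])
  list(prob = p, ce = -log(pmax(pick, 1e-300)))
}

#' Cross-entropy with online hard example mining
#'
#' Per-pixel softmax cross-entropy is computed over the whole batch; pixels
#' are sorted by loss and only the hardest `ohem_keep_fraction` (but at least
#' `ohem_min_kept`) contribute to the mean.  Gradients flow only through the
#' retained pixels.
#'
#' @param logits array (H,W,num_classes,N) of class scores, or an autodiff
#'   node of the same shape (used internally during training).
#' @param target binary mask array (H,W,N), (H,W) or (H,W,1,N); 1 = lesion.
#' @param cfg a [loss_config()].
#' @return scalar loss (a node when `logits` is a node).
#' @export
ce_ohem <- function(logits, target, cfg = loss_config()) {
  lv <- ag_value(logits)
  d <- dim(lv)
  target <- array(as.numeric(target), c(d[1], d[2], d[4]))
  px <- pixel_ce(lv, target)
  ce <- as.numeric(px$ce)
  n_pix <- length(ce)
  k <- max(min(cfg$ohem_min_kept, n_pix),
           ceiling(cfg$ohem_keep_fraction * n_pix))
  if (k < 1) stop("OHEM retained pixel set is empty")
  ord <- order(ce, decreasing = TRUE)
  keep <- ord[seq_len(k)]
  val <- mean(ce[keep])
  if (!ag_is_node(logits)) return(val)
  keep_mask <- numeric(n_pix)
  keep_mask[keep] <- 1
  dim(keep_mask) <- c(d[1], d[2], d[4])
  ag_op(val, list(logits), list(function(g) {
    # d(mean CE over kept)/dlogits = (softmax - onehot)/k on kept pixels
    onehot <- array(0, d)
    onehot[, , 1, ] <- 1 - target
    onehot[, , 2, ] <- target
    grad <- (px$prob - onehot) *
      chan_rep(array(keep_mask, c(d[1], d[2], 1L, d[4])), d[3]) / k
    g * grad
  }))
}

#' Unified Dice/Jaccard overlap loss
#'
#' Returns `1 - (SoftDice + SoftJaccard)/2` with batch-global sums over the
#' foreground class:
#' SoftDice = (2*sum(p*y)+eps)/(sum(p)+sum(y)+eps),
#' SoftJaccard = (sum(p*y)+eps)/(sum(p)+sum(y)-sum(p*y)+eps).
#'
#' @param foreground_probs foreground probabilities in `[0,1]` (array or
#'   autodiff node), any shape matching `target_mask`.
#' @param target_mask binary mask of the same shape.
#' @param cfg a [loss_config()] (only `smooth_eps` is used).
#' @return scalar loss in `[0,1]` (a node when the input is a node).
#' @export
overlap_loss <- function(foreground_probs, target_mask, cfg = loss_config()) {
  pv <- as.numeric(ag_value(foreground_probs))
  y <- as.numeric(target_mask)
  if (any(pv < -1e-9 | pv > 1 + 1e-9))
    stop("probabilities must lie in [0, 1]")
  eps <- cfg$smooth_eps
  s1 <- sum(pv * y); sp <- sum(pv); sy <- sum(y)
  dice_den <- sp + sy + eps
  dice <- (2 * s1 + eps) / dice_den
  u <- sp + sy - s1 + eps
  jacc <- (s1 + eps) / u
  val <- 1 - 0.5 * (dice + jacc)
  if (!ag_is_node(foreground_probs)) return(val)
  d <- dim(ag_value(foreground_probs))
  ag_op(val, list(foreground_probs), list(function(g) {
    ddice <- (2 * y * dice_den - (2 * s1 + eps)) / dice_den^2
    djacc <- (y * u - (s1 + eps) * (1 - y)) / u^2
    grad <- -0.5 * (ddice + djacc)
    dim(grad) <- d
    g * grad
  }))
}

#' Total hybrid segmentation loss
#'
#' `ce_weight * ce_ohem + overlap_weight * overlap_loss`, the overlap term
#' taken on the softmax foreground probabilities.
#'
#' @inheritParams ce_ohem
#' @return scalar loss (node when `logits` is a node); carries the two
#'   components as attributes `ce` and `overlap` when evaluated on arrays.
#' @export
total_loss <- function(logits, target, cfg = loss_config()) {
  ce <- ce_ohem(logits, target, cfg)
  probs <- if (ag_is_node(logits)) ag_softmax(logits) else {
    d <- dim(ag_value(logits))
    pixel_ce(ag_value(logits),
             array(as.numeric(target), c(d[1], d[2], d[4])))$prob
  }
  fg <- if (ag_is_node(probs)) ag_channel(probs, 2L) else
    probs[, , 2, , drop = FALSE]
  d <- dim(ag_value(logits))
  ov <- overlap_loss(fg, array(as.numeric(target), c(d[1], d[2], 1L, d[4])),
                     cfg)
  if (ag_is_node(logits)) {
    # weighted sum of two scalar nodes
    ag_op(cfg$ce_weight * ag_value(ce) + cfg$overlap_weight * ag_value(ov),
          list(ce, ov),
          list(function(g) g * cfg$ce_weight,
               function(g) g * cfg$overlap_weight))
  } else {
    out <- cfg$ce_weight * ce + cfg$overlap_weight * ov
    attr(out, "ce") <- ce
    attr(out, "overlap") <- ov
    out
  }
}
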