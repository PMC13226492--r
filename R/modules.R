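# ---------------------------------------------------------------------------
# Lightweight module system on top of the autodiff ops.  A module is a list
# with a `$fwd(self, x, training)` closure, a named list of parameter nodes
# in `$params`, optional buffer state in `$state`, and named `$children`.
# ---------------------------------------------------------------------------

new_module <- function(type, fwd, params = list(), children = list(),
                       state = NULL, meta = list()) {
  m <- list(type = type, fwd = fwd, params = params, children = children,
            state = state, meta = meta)
  class(m) <- "nn_module"
  m
}

module_forward <- function(m, x, training = FALSE) m$fwd(m, x, training)

#' Collect all parameter nodes of a module tree
#' @param m a module.
#' @param prefix name prefix used for the returned flat list.
#' @return named list of `ag_node` parameters.
#' @keywords internal
collect_params <- function(m, prefix = "") {
  out <- list()
  if (length(m$params)) {
    nm <- paste0(prefix, names(m$params))
    out <- m$params
    names(out) <- nm
  }
  for (cn in names(m$children)) {
    out <- c(out, collect_params(m$children[[cn]], paste0(prefix, cn, ".")))
  }
  out
}

# He (fan-out) normal initialisation, the convention for ReLU networks.
he_conv_weight <- function(kh, kw, cg, o, groups = 1L) {
  fan_out <- kh * kw * o / groups
  array(stats::rnorm(kh * kw * cg * o, sd = sqrt(2 / fan_out)),
        c(kh, kw, cg, o))
}

nn_conv <- function(in_ch, out_ch, k, stride = 1L, pad = NULL, dilation = 1L,
                    groups = 1L, bias = FALSE) {
  if (is.null(pad)) pad <- dilation * (k - 1L) %/% 2L
  params <- list(weight = ag_param(he_conv_weight(k, k, in_ch %/% groups,
                                                  out_ch, groups)))
  if (bias) params$bias <- ag_param(numeric(out_ch))
  new_module("conv",
             fwd = function(m, x, training) {
               ag_conv2d(x, m$params$weight, m$params$bias,
                         stride = m$meta$stride, pad = m$meta$pad,
                         dilation = m$meta$dilation, groups = m$meta$groups)
             },
             params = params,
             meta = list(stride = stride, pad = pad, dilation = dilation,
                         groups = groups))
}

nn_conv_transpose <- function(in_ch, out_ch, k, stride = 2L, pad = 0L,
                              bias = TRUE) {
  params <- list(weight = ag_param(he_conv_weight(k, k, out_ch, in_ch)))
  if (bias) params$bias <- ag_param(numeric(out_ch))
  new_module("convT",
             fwd = function(m, x, training) {
               ag_conv2d_transpose(x, m$params$weight, m$params$bias,
                                   stride = m$meta$stride, pad = m$meta$pad)
             },
             params = params,
             meta = list(stride = stride, pad = pad))
}

nn_bn <- function(ch) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(ch)
  st$running_var <- rep(1, ch)
  new_module("bn",
             fwd = function(m, x, training) {
               ag_batchnorm(x, m$params$gamma, m$params$beta, m$state,
                            training = training)
             },
             params = list(gamma = ag_param(rep(1, ch)),
                           beta = ag_param(numeric(ch))),
             state = st)
}

nn_relu <- function() new_module("relu", fwd = function(m, x, training) ag_relu(x))

nn_maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
  new_module("maxpool",
             fwd = function(m, x, training)
               ag_maxpool(x, m$meta$k, m$meta$stride, m$meta$pad),
             meta = list(k = k, stride = stride, pad = pad))
}

nn_seq <- function(...) {
  ch <- list(...)
  if (is.null(names(ch)) || any(names(ch) == ""))
    names(ch) <- sprintf("l%02d", seq_along(ch))
  new_module("seq",
             fwd = function(m, x, training) {
               for (cm in m$children) x <- module_forward(cm, x, training)
               x
             },
             children = ch)
}

# conv -> BN -> ReLU, the standard unit used throughout the networks
nn_cbr <- function(in_ch, out_ch, k, stride = 1L, pad = NULL, dilation = 1L,
                   groups = 1L) {
  nn_seq(conv = nn_conv(in_ch, out_ch, k, stride, pad, dilation, groups),
         bn = nn_bn(out_ch),
         relu = nn_relu())
}
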