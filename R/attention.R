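# X- and Y-attention building blocks: squeeze-and-excitation style channel
# attention, a five-convolution pyramid spatial attention, their sigmoid
# fusion into attention maps, and residual refinement.
#
# Public functions take channels-first arrays (C, H, W) — the layout feature
# maps are usually printed in — and return plain arrays. The same graph
# builders are reused, batched, inside the segmentation network.

# ---- shape plumbing -------------------------------------------------------

chw_to_hwcn <- function(f) {
  d <- dim(f)
  array(aperm(f, c(2, 3, 1)), c(d[2], d[3], d[1], 1L))
}

hwcn_to_chw <- function(v) {
  d <- dim(v)
  aperm(array(v, d[1:3]), c(3, 1, 2))
}

check_feature_map <- function(f, name = "f", min_hw = 1L) {
  if (!is.array(f) || length(dim(f)) != 3L) {
    stop(name, " must be a 3-D (channels x height x width) array")
  }
  if (!all(is.finite(f))) stop(name, " contains non-finite values")
  d <- dim(f)
  if (d[1] < 1L || d[2] < min_hw || d[3] < min_hw) {
    stop(name, " has degenerate dimensions: ", paste(d, collapse = "x"))
  }
  invisible(d)
}

#' Parameters of the channel attention block
#'
#' Creates the learnable state of the squeeze-and-excitation style channel
#' attention: a one-hidden-layer MLP applied to the globally average-pooled
#' channel descriptor, followed by batch normalization and a ReLU. The hidden
#' width is `max(1, round(r * c_in))`, so the default reduction ratio of 0.5
#' halves the channel count in the bottleneck.
#'
#' `c_out` normally equals `c_in`; it differs only in the Y-attention use,
#' where the deeper feature map's channel count is adjusted to the shallower
#' one's by the MLP itself.
#'
#' @param c_in Number of input channels (columns of the first MLP weight).
#' @param c_out Number of output channels; defaults to `c_in`.
#' @param r Reduction ratio in (0, 1] controlling the hidden width.
#' @param hidden_act Activation between the two MLP layers: `"relu"`
#'   (default) or `"identity"`.
#' @param seed Optional integer seed for reproducible weight initialization.
#' @return An object of class `channel_attention_params`. Weight arrays are
#'   reachable as `$W0$value`, `$b0$value`, `$W1$value`, `$b1$value`, and the
#'   batch-norm scale/shift as `$gamma$value`/`$beta$value`, so tests and
#'   callers can set weights explicitly.
#' @export
channel_attention_params <- function(c_in, c_out = c_in, r = 0.5,
                                     hidden_act = c("relu", "identity"),
                                     seed = NULL) {
  hidden_act <- match.arg(hidden_act)
  stopifnot(c_in >= 1L, c_out >= 1L, r > 0, r <= 1)
  hidden <- max(1L, as.integer(round(r * c_in)))
  make <- function() {
    p <- list(
      W0 = ag_param(init_uniform(c(hidden, c_in), c_in)),
      b0 = ag_param(numeric(hidden)),
      W1 = ag_param(init_uniform(c(c_out, hidden), hidden)),
      b1 = ag_param(numeric(c_out)),
      gamma = ag_param(rep(1, c_out)),
      beta = ag_param(numeric(c_out)),
      bn = bn_state(c_out),
      c_in = c_in, c_out = c_out, r = r, hidden = hidden,
      hidden_act = hidden_act
    )
    class(p) <- "channel_attention_params"
    p
  }
  if (is.null(seed)) make() else withr::with_seed(seed, make())
}

#' Parameters of the pyramid spatial attention block
#'
#' Creates the five learnable 3x3 convolution layers of the spatial attention
#' pyramid: two stride-2 layers on the contracting side (scales H/2, H/4),
#' one at the coarsest scale, and two on the expanding side. Channel width is
#' held at `channels` throughout; up-sampling is parameter-free so the
#' learnable budget stays at exactly five 3x3 layers.
#'
#' @param channels Channel count of the feature map the block refines.
#' @param upsample Up-sampling operator used between pyramid scales:
#'   `"bilinear"` (default) or `"nearest"`.
#' @param seed Optional integer seed for reproducible initialization.
#' @return An object of class `spatial_attention_params` with conv layers
#'   `$d1`, `$d2`, `$bottom`, `$e2`, `$e1` (each a list of `w`/`b` nodes).
#' @export
spatial_attention_params <- function(channels, upsample = c("bilinear", "nearest"),
                                     seed = NULL) {
  upsample <- match.arg(upsample)
  stopifnot(channels >= 1L)
  conv_layer <- function() list(
    w = ag_param(init_uniform(c(3L, 3L, channels, channels), 9 * channels)),
    b = ag_param(numeric(channels))
  )
  make <- function() {
    p <- list(
      d1 = conv_layer(), d2 = conv_layer(), bottom = conv_layer(),
      e2 = conv_layer(), e1 = conv_layer(),
      channels = channels, upsample = upsample
    )
    class(p) <- "spatial_attention_params"
    p
  }
  if (is.null(seed)) make() else withr::with_seed(seed, make())
}

# ---- graph builders (internal, batched) -----------------------------------

channel_attention_node <- function(x, cp, training = FALSE) {
  if (dim(x$value)[3] != cp$c_in) {
    stop("channel attention expects ", cp$c_in, " channels, got ", dim(x$value)[3])
  }
  g <- ag_gap(x)
  h <- ag_linear(g, cp$W0, cp$b0)
  if (cp$hidden_act == "relu") h <- ag_relu(h)
  s <- ag_linear(h, cp$W1, cp$b1)
  s <- ag_bn2(s, cp$gamma, cp$beta, cp$bn, training)
  ag_relu(s)
}

spatial_attention_node <- function(x, sp) {
  d <- dim(x$value)
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L) {
    stop("spatial attention needs height and width divisible by 4, got ",
         d[1], "x", d[2])
  }
  if (d[3] != sp$channels) {
    stop("spatial attention expects ", sp$channels, " channels, got ", d[3])
  }
  c1 <- ag_conv2d(x, sp$d1$w, sp$d1$b, stride = 2L, pad = 1L)
  c2 <- ag_conv2d(c1, sp$d2$w, sp$d2$b, stride = 2L, pad = 1L)
  bt <- ag_conv2d(c2, sp$bottom$w, sp$bottom$b, stride = 1L, pad = 1L)
  e2 <- ag_conv2d(ag_add(ag_upsample2(bt, sp$upsample), c1),
                  sp$e2$w, sp$e2$b, stride = 1L, pad = 1L)
  e1 <- ag_upsample2(ag_conv2d(e2, sp$e1$w, sp$e1$b, stride = 1L, pad = 1L),
                     sp$upsample)
  ag_add(e1, x)
}

x_attention_node <- function(x, cp, sp, training = FALSE) {
  fs <- spatial_attention_node(x, sp)
  fc <- channel_attention_node(x, cp, training)
  ag_sigmoid(ag_scale_channels(fs, fc))
}

y_attention_node <- function(x, x_deep, cp, sp, training = FALSE) {
  if (cp$c_out != dim(x$value)[3]) {
    stop("channel attention output width (", cp$c_out,
         ") must match the shallow feature's channels (", dim(x$value)[3], ")")
  }
  fs <- spatial_attention_node(x, sp)
  fc <- channel_attention_node(x_deep, cp, training)
  ag_sigmoid(ag_scale_channels(fs, fc))
}

residual_refine_node <- function(x, m) ag_add(ag_mul(m, x), x)

# ---- public forward-only API ----------------------------------------------

#' Channel attention of a feature map
#'
#' Compresses each channel plane to its spatial mean (global average pooling),
#' passes the descriptor through a one-hidden-layer MLP, batch normalization
#' and a ReLU, and returns one non-negative weight per output channel. The
#' output is invariant to any permutation of the spatial positions of `f`.
#'
#' @param f Feature map, array of shape (C, H, W).
#' @param params A [channel_attention_params()] object with `c_in == C`.
#' @param training Logical; use batch statistics (`TRUE`) or running
#'   statistics (`FALSE`, default) in the batch-norm step.
#' @return Array of shape (c_out, 1, 1) with non-negative entries.
#' @export
channel_attention <- function(f, params, training = FALSE) {
  check_feature_map(f)
  out <- channel_attention_node(ag_const(chw_to_hwcn(f)), params, training)
  array(out$value[, 1], c(params$c_out, 1L, 1L))
}

#' Pyramid spatial attention of a feature map
#'
#' Runs the feature map through a three-scale convolutional pyramid (scales
#' H, H/2, H/4; five 3x3 convolution layers in total), up-samples the coarser
#' scales back, and adds the result to the input map, returning a spatial
#' attention feature of the same shape.
#'
#' @param f Feature map, array of shape (C, H, W) with H and W divisible by 4.
#' @param params A [spatial_attention_params()] object with matching channels.
#' @return Array of shape (C, H, W).
#' @export
spatial_attention <- function(f, params) {
  check_feature_map(f, min_hw = 4L)
  out <- spatial_attention_node(ag_const(chw_to_hwcn(f)), params)
  hwcn_to_chw(out$value)
}

#' X-attention map
#'
#' Fuses spatial and channel attention of a single feature map: each channel
#' plane of the spatial attention output is scaled by its channel weight and
#' the product is squashed by a sigmoid, giving per-position, per-channel
#' attention weights strictly inside (0, 1).
#'
#' @inheritParams spatial_attention
#' @param cp Channel attention parameters with `c_in == c_out == C`.
#' @param sp Spatial attention parameters for `C` channels.
#' @param training Logical; batch-norm mode as in [channel_attention()].
#' @return Array of shape (C, H, W) with entries in (0, 1).
#' @export
x_attention_map <- function(f, cp, sp, training = FALSE) {
  check_feature_map(f, min_hw = 4L)
  if (cp$c_in != dim(f)[1] || cp$c_out != dim(f)[1]) {
    stop("X-attention requires c_in == c_out == C")
  }
  out <- x_attention_node(ag_const(chw_to_hwcn(f)), cp, sp, training)
  hwcn_to_chw(out$value)
}

#' Y-attention map
#'
#' Variant of the X-attention map that takes its channel attention from a
#' deeper feature map carrying global context, while the spatial attention
#' still comes from the shallower map. The deeper map may have a different
#' channel count and resolution; the channel MLP adjusts it to `C` channels.
#'
#' @param f Shallow feature map (C, H, W), H and W divisible by 4.
#' @param f_deep Deeper feature map (Cd, Hd, Wd).
#' @param cp Channel attention parameters mapping `Cd` to `C` channels.
#' @param sp Spatial attention parameters for `C` channels.
#' @param training Logical; batch-norm mode as in [channel_attention()].
#' @return Array of shape (C, H, W) with entries in (0, 1).
#' @export
y_attention_map <- function(f, f_deep, cp, sp, training = FALSE) {
  check_feature_map(f, min_hw = 4L)
  check_feature_map(f_deep, name = "f_deep")
  out <- y_attention_node(ag_const(chw_to_hwcn(f)), ag_const(chw_to_hwcn(f_deep)),
                          cp, sp, training)
  hwcn_to_chw(out$value)
}

#' Residual attention refinement
#'
#' Applies an attention map to a feature map by residual gating:
#' `output = m * f + f`. The identity path guarantees the module can only
#' modulate, never destroy, the input; for non-negative `f` the output is
#' bounded elementwise between `f` and `2 f`.
#'
#' @param f Feature map (C, H, W).
#' @param m Attention map of identical shape.
#' @return Array of shape (C, H, W).
#' @export
residual_refine <- function(f, m) {
  check_feature_map(f)
  if (!is.array(m) || !identical(dim(m), dim(f))) {
    stop("attention map shape (", paste(dim(m), collapse = "x"),
         ") does not match the feature map (", paste(dim(f), collapse = "x"), ")")
  }
  m * f + f
}

#' Learnable parameter counts of attention blocks
#'
#' @param x A `channel_attention_params` or `spatial_attention_params` object
#'   (or any nested list of them).
#' @return Total number of learnable scalars.
#' @export
param_count <- function(x) {
  sum(vapply(collect_params(x), function(p) length(p$value), numeric(1)))
}
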