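# Attention-augmented U-Net: a residual encoder with four resolution stages
# below a stem, a transposed-convolution decoder with skip concatenation, and
# optional X/Y attention modules at positions 1-4. Position 1 is the
# highest-resolution (shallowest) stage. X(i) refines the encoder stage-i
# output before it feeds both the skip connection and the next stage; Y(i)
# sits on the decoder and gates the (possibly X-refined) stage-i skip using
# channel context from the next-deeper decoder feature, so placing X(i) and
# Y(i) together chains them.

#' Parse an attention placement label
#'
#' Accepts labels in the style used to report ablations, e.g.
#' `"X(1)+X(2)+Y(1)+Y(2)"` or `"U-Net+X(1)+Y(1)"` (a leading `U-Net` token is
#' tolerated), case-insensitively and ignoring whitespace. `"baseline"` means
#' no attention modules.
#'
#' @param label Character scalar.
#' @return A `placement_config`: list with sorted integer vectors `x` and `y`,
#'   each a subset of 1:4.
#' @export
parse_placement <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  tokens <- trimws(strsplit(label, "+", fixed = TRUE)[[1]])
  tokens <- tokens[!grepl("^u-?net$", tokens, ignore.case = TRUE)]
  tokens <- tokens[nzchar(tokens)]
  x <- integer(0); y <- integer(0)
  if (!(length(tokens) == 1L && tolower(tokens) == "baseline")) {
    for (tok in tokens) {
      m <- regmatches(tok, regexec("^([XxYy])\\s*\\(\\s*([0-9]+)\\s*\\)$", tok))[[1]]
      if (length(m) != 3L) stop("cannot parse placement token: '", tok, "'")
      pos <- as.integer(m[3])
      if (pos < 1L || pos > 4L) {
        stop("placement position out of range 1..4 in token: '", tok, "'")
      }
      if (tolower(m[2]) == "x") {
        if (pos %in% x) stop("duplicate placement token: '", tok, "'")
        x <- c(x, pos)
      } else {
        if (pos %in% y) stop("duplicate placement token: '", tok, "'")
        y <- c(y, pos)
      }
    }
  }
  structure(list(x = sort(x), y = sort(y)), class = "placement_config")
}

#' @export
format.placement_config <- function(x, ...) {
  toks <- c(sprintf("X(%d)", x$x), sprintf("Y(%d)", x$y))
  if (length(toks) == 0L) "baseline" else paste(toks, collapse = "+")
}

#' @export
print.placement_config <- function(x, ...) {
  cat("<placement>", format(x), "\n")
  invisible(x)
}

encoder_presets <- list(
  # default desk-scale encoder: one basic residual block per stage
  tiny = list(stem_width = 8L, widths = c(8L, 16L, 32L, 64L),
              blocks = c(1L, 1L, 1L, 1L), block_type = "basic"),
  # ResNet-101-style depth: bottleneck blocks, 3/4/23/3 per stage
  resnet101 = list(stem_width = 64L, widths = c(256L, 512L, 1024L, 2048L),
                   blocks = c(3L, 4L, 23L, 3L), block_type = "bottleneck")
)

#' Specify an attention-augmented U-Net
#'
#' @param encoder `"tiny"` (default; widths 8/16/32/64, one basic residual
#'   block per stage, runs on CPU), `"resnet101"` (bottleneck blocks,
#'   3/4/23/3 per stage), or a list with fields `stem_width`, `widths`
#'   (length 4), `blocks` (length 4) and `block_type` (`"basic"` or
#'   `"bottleneck"`).
#' @param input_size Integer (H, W); both must be divisible by 32 (the stem
#'   keeps full resolution, the four stages and a bottom block each halve it).
#' @param placement A placement label string or a [parse_placement()] result.
#' @param r Reduction ratio of the channel attention MLPs (default 0.5).
#' @param upsample Up-sampling operator inside the spatial attention pyramids.
#' @return A `network_spec` object.
#' @export
network_spec <- function(encoder = "tiny", input_size = c(512L, 512L),
                         placement = "baseline", r = 0.5,
                         upsample = c("bilinear", "nearest")) {
  upsample <- match.arg(upsample)
  if (is.character(encoder)) {
    encoder <- encoder_presets[[match.arg(encoder, names(encoder_presets))]]
  }
  stopifnot(length(encoder$widths) == 4L, length(encoder$blocks) == 4L,
            encoder$block_type %in% c("basic", "bottleneck"))
  input_size <- as.integer(input_size)
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  if (any(input_size %% 32L != 0L) || any(input_size < 32L)) {
    stop("input height and width must be positive multiples of 2^5 = 32, got ",
         paste(input_size, collapse = "x"))
  }
  if (is.character(placement)) placement <- parse_placement(placement)
  for (pos in union(placement$x, placement$y)) {
    if (any((input_size %/% 2L^pos) %% 4L != 0L)) {
      stop("attention at position ", pos, " needs the stage resolution (input/",
           2L^pos, ") divisible by 4; increase the input size")
    }
  }
  structure(list(encoder = encoder, input_size = input_size,
                 placement = placement, r = r, upsample = upsample),
            class = "network_spec")
}

# ---- parameter construction ------------------------------------------------

conv_unit <- function(k, cin, cout) {
  list(w = ag_param(init_uniform(c(k, k, cin, cout), k * k * cin)),
       b = ag_param(numeric(cout)))
}

bn_unit <- function(c) {
  list(gamma = ag_param(rep(1, c)), beta = ag_param(numeric(c)),
       state = bn_state(c))
}

make_block <- function(type, cin, cout, stride) {
  need_proj <- stride != 1L || cin != cout
  if (type == "basic") {
    blk <- list(type = "basic", stride = stride,
                conv1 = conv_unit(3L, cin, cout), bn1 = bn_unit(cout),
                conv2 = conv_unit(3L, cout, cout), bn2 = bn_unit(cout))
  } else {
    mid <- max(1L, cout %/% 4L)
    blk <- list(type = "bottleneck", stride = stride,
                conv1 = conv_unit(1L, cin, mid), bn1 = bn_unit(mid),
                conv2 = conv_unit(3L, mid, mid), bn2 = bn_unit(mid),
                conv3 = conv_unit(1L, mid, cout), bn3 = bn_unit(cout))
  }
  if (need_proj) blk$proj <- list(conv = conv_unit(1L, cin, cout), bn = bn_unit(cout))
  blk
}

#' Build an attention-augmented U-Net
#'
#' Instantiates all learnable parameters of the network described by a
#' [network_spec()] with fan-in-scaled uniform initialization (biases zero,
#' batch-norm scale one).
#'
#' @param spec A `network_spec`.
#' @param seed Integer seed controlling the weight initialization.
#' @return An object of class `lungattn_net`.
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  enc <- spec$encoder
  w <- enc$widths
  withr::with_seed(as.integer(seed), {
    P <- list()
    P$stem <- list(conv = conv_unit(3L, 1L, enc$stem_width), bn = bn_unit(enc$stem_width))
    P$enc <- vector("list", 4L)
    cin <- enc$stem_width
    for (i in 1:4) {
      blocks <- list(make_block(enc$block_type, cin, w[i], 2L))
      for (k in seq_len(enc$blocks[i] - 1L)) {
        blocks[[k + 1L]] <- make_block(enc$block_type, w[i], w[i], 1L)
      }
      P$enc[[i]] <- blocks
      cin <- w[i]
    }
    P$bott <- make_block(enc$block_type, w[4], w[4], 2L)
    P$xmod <- vector("list", 4L)
    for (i in spec$placement$x) {
      P$xmod[[i]] <- list(
        cp = channel_attention_params(w[i], w[i], r = spec$r),
        sp = spatial_attention_params(w[i], upsample = spec$upsample)
      )
    }
    P$ymod <- vector("list", 4L)
    for (i in spec$placement$y) {
      cd <- if (i == 4L) w[4] else w[i + 1L]
      P$ymod[[i]] <- list(
        cp = channel_attention_params(cd, w[i], r = spec$r),
        sp = spatial_attention_params(w[i], upsample = spec$upsample)
      )
    }
    P$dec <- vector("list", 4L)
    for (i in 4:1) {
      cdeep <- if (i == 4L) w[4] else w[i + 1L]
      P$dec[[i]] <- list(
        up = conv_unit(2L, cdeep, w[i]),
        conv1 = conv_unit(3L, 2L * w[i], w[i]), bn1 = bn_unit(w[i]),
        conv2 = conv_unit(3L, w[i], w[i]), bn2 = bn_unit(w[i])
      )
    }
    P$dec0 <- list(
      up = conv_unit(2L, w[1], enc$stem_width),
      conv1 = conv_unit(3L, 2L * enc$stem_width, enc$stem_width),
      bn1 = bn_unit(enc$stem_width),
      conv2 = conv_unit(3L, enc$stem_width, enc$stem_width),
      bn2 = bn_unit(enc$stem_width)
    )
    P$head <- conv_unit(1L, enc$stem_width, 1L)
    structure(list(spec = spec, params = P, seed = as.integer(seed)),
              class = "lungattn_net")
  })
}

# ---- forward pass ----------------------------------------------------------

conv_f <- function(x, cu, stride, pad) ag_conv2d(x, cu$w, cu$b, stride, pad)
bn_f <- function(x, bu, training) ag_bn4(x, bu$gamma, bu$beta, bu$state, training)

block_forward <- function(blk, x, training) {
  if (blk$type == "basic") {
    h <- ag_relu(bn_f(conv_f(x, blk$conv1, blk$stride, 1L), blk$bn1, training))
    h <- bn_f(conv_f(h, blk$conv2, 1L, 1L), blk$bn2, training)
  } else {
    h <- ag_relu(bn_f(conv_f(x, blk$conv1, 1L, 0L), blk$bn1, training))
    h <- ag_relu(bn_f(conv_f(h, blk$conv2, blk$stride, 1L), blk$bn2, training))
    h <- bn_f(conv_f(h, blk$conv3, 1L, 0L), blk$bn3, training)
  }
  s <- if (is.null(blk$proj)) x else {
    bn_f(conv_f(x, blk$proj$conv, blk$stride, 0L), blk$proj$bn, training)
  }
  ag_relu(ag_add(h, s))
}

# xval: (H, W, 1, N) array scaled to [0, 1]. Returns the sigmoid probability
# node; with probes = TRUE also records the feature maps entering each Y
# module (after any X refinement on the skip path).
net_forward <- function(net, xval, training = FALSE, probes = FALSE) {
  P <- net$params
  acts <- if (probes) new.env(parent = emptyenv()) else NULL
  x <- ag_const(xval)
  s0 <- ag_relu(bn_f(conv_f(x, P$stem$conv, 1L, 1L), P$stem$bn, training))
  skips <- vector("list", 4L)
  h <- s0
  for (i in 1:4) {
    for (blk in P$enc[[i]]) h <- block_forward(blk, h, training)
    if (!is.null(P$xmod[[i]])) {
      m <- x_attention_node(h, P$xmod[[i]]$cp, P$xmod[[i]]$sp, training)
      h <- residual_refine_node(h, m)
    }
    skips[[i]] <- h
  }
  d <- block_forward(P$bott, h, training)
  for (i in 4:1) {
    skip <- skips[[i]]
    if (!is.null(P$ymod[[i]])) {
      if (probes) assign(paste0("y_input_", i), skip$value, envir = acts)
      m <- y_attention_node(skip, d, P$ymod[[i]]$cp, P$ymod[[i]]$sp, training)
      skip <- residual_refine_node(skip, m)
    }
    up <- ag_conv_transpose2(d, P$dec[[i]]$up$w, P$dec[[i]]$up$b)
    cc <- ag_concat_channels(skip, up)
    d <- ag_relu(bn_f(conv_f(cc, P$dec[[i]]$conv1, 1L, 1L), P$dec[[i]]$bn1, training))
    d <- ag_relu(bn_f(conv_f(d, P$dec[[i]]$conv2, 1L, 1L), P$dec[[i]]$bn2, training))
  }
  up <- ag_conv_transpose2(d, P$dec0$up$w, P$dec0$up$b)
  cc <- ag_concat_channels(s0, up)
  d0 <- ag_relu(bn_f(conv_f(cc, P$dec0$conv1, 1L, 1L), P$dec0$bn1, training))
  d0 <- ag_relu(bn_f(conv_f(d0, P$dec0$conv2, 1L, 1L), P$dec0$bn2, training))
  prob <- ag_sigmoid(conv_f(d0, P$head, 1L, 0L))
  list(prob = prob, acts = acts)
}

#' Predict a lung probability map
#'
#' Runs a forward pass in evaluation mode (batch-norm running statistics) and
#' returns the per-pixel foreground probability. Deterministic for fixed
#' weights.
#'
#' @param object A `lungattn_net`.
#' @param image H x W numeric matrix: a preprocessed 8-bit grayscale image
#'   (0-255; internally scaled to unit range) or an already-scaled matrix in
#'   unit range.
#' @param ... Unused.
#' @return H x W matrix of probabilities in (0, 1).
#' @export
predict.lungattn_net <- function(object, image, ...) {
  stopifnot(is.matrix(image))
  sz <- object$spec$input_size
  if (!identical(dim(image), as.integer(sz))) {
    stop("image is ", paste(dim(image), collapse = "x"),
         " but the network expects ", paste(sz, collapse = "x"))
  }
  v <- image
  if (max(v) > 1) v <- v / 255
  out <- net_forward(object, array(v, c(sz[1], sz[2], 1L, 1L)), training = FALSE)
  matrix(out$prob$value, sz[1], sz[2])
}

# ---- introspection ---------------------------------------------------------

#' Count learnable parameters of a network or attention block
#'
#' @param x A `lungattn_net`, a `network_spec` (counted analytically, without
#'   allocating weights), or any attention parameter object.
#' @return Integer scalar.
#' @export
network_param_count <- function(x) {
  if (inherits(x, "network_spec")) return(spec_param_count(x))
  if (inherits(x, "lungattn_net")) return(param_count(x$params))
  param_count(x)
}

# analytic count, mirroring build_network
spec_param_count <- function(spec) {
  enc <- spec$encoder
  w <- as.numeric(enc$widths)
  sw <- as.numeric(enc$stem_width)
  conv_n <- function(k, cin, cout) k * k * cin * cout + cout
  bn_n <- function(c) 2 * c
  block_n <- function(type, cin, cout, stride) {
    n <- if (type == "basic") {
      conv_n(3, cin, cout) + bn_n(cout) + conv_n(3, cout, cout) + bn_n(cout)
    } else {
      mid <- max(1, cout %/% 4)
      conv_n(1, cin, mid) + bn_n(mid) + conv_n(3, mid, mid) + bn_n(mid) +
        conv_n(1, mid, cout) + bn_n(cout)
    }
    if (stride != 1 || cin != cout) n <- n + conv_n(1, cin, cout) + bn_n(cout)
    n
  }
  cp_n <- function(cin, cout, r) {
    hidden <- max(1, round(r * cin))
    hidden * cin + hidden + cout * hidden + cout + 2 * cout
  }
  sp_n <- function(c) 5 * (9 * c * c + c)
  total <- conv_n(3, 1, sw) + bn_n(sw)
  cin <- sw
  for (i in 1:4) {
    total <- total + block_n(enc$block_type, cin, w[i], 2)
    if (enc$blocks[i] > 1) {
      total <- total + (enc$blocks[i] - 1) * block_n(enc$block_type, w[i], w[i], 1)
    }
    cin <- w[i]
  }
  total <- total + block_n(enc$block_type, w[4], w[4], 2)
  for (i in spec$placement$x) total <- total + cp_n(w[i], w[i], spec$r) + sp_n(w[i])
  for (i in spec$placement$y) {
    cd <- if (i == 4) w[4] else w[i + 1]
    total <- total + cp_n(cd, w[i], spec$r) + sp_n(w[i])
  }
  for (i in 4:1) {
    cdeep <- if (i == 4) w[4] else w[i + 1]
    total <- total + conv_n(2, cdeep, w[i]) +
      conv_n(3, 2 * w[i], w[i]) + bn_n(w[i]) + conv_n(3, w[i], w[i]) + bn_n(w[i])
  }
  total <- total + conv_n(2, w[1], sw) +
    conv_n(3, 2 * sw, sw) + bn_n(sw) + conv_n(3, sw, sw) + bn_n(sw) +
    conv_n(1, sw, 1)
  total
}

#' Count learnable 3x3 convolution layers
#'
#' Walks a parameter structure and counts weight arrays of spatial size 3x3.
#' An instantiated spatial attention pyramid contributes exactly five.
#'
#' @param x A `lungattn_net`, attention parameter object, or nested list.
#' @return Integer scalar.
#' @export
count_conv3x3_layers <- function(x) {
  if (inherits(x, "lungattn_net")) x <- x$params
  ps <- collect_params(x)
  sum(vapply(ps, function(p) {
    d <- dim(p$value)
    length(d) == 4L && d[1] == 3L && d[2] == 3L
  }, logical(1)))
}

#' @export
print.lungattn_net <- function(x, ...) {
  cat("<lungattn_net> input", paste(x$spec$input_size, collapse = "x"),
      "| placement", format(x$spec$placement),
      "| params", format(network_param_count(x), big.mark = ","),
      "| 3x3 conv layers", count_conv3x3_layers(x), "\n")
  invisible(x)
}

# ---- checkpoints -----------------------------------------------------------

collect_bn_states <- function(x, prefix = "") {
  out <- list()
  if (is.environment(x) && !is.null(x$running_mean)) {
    out[[prefix]] <- x
    return(out)
  }
  if (is.list(x) && !inherits(x, "ag_node")) {
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, collect_bn_states(x[[i]], paste0(prefix, if (nzchar(prefix)) "." else "", nm)))
    }
  }
  out
}

#' Save / load a network checkpoint
#'
#' The checkpoint is a single JSON file holding the network specification,
#' every parameter array, and the batch-norm running statistics; numeric
#' payloads are base64-encoded little-endian IEEE doubles, so loading
#' restores all state exactly and predictions round-trip bitwise.
#'
#' @param net A `lungattn_net`.
#' @param path File path for the checkpoint.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `lungattn_net`.
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "lungattn_net"))
  ps <- collect_params(net$params)
  bns <- collect_bn_states(net$params)
  obj <- list(
    format = "lungattn-checkpoint-1",
    spec = list(
      encoder = net$spec$encoder,
      input_size = net$spec$input_size,
      placement = list(x = net$spec$placement$x, y = net$spec$placement$y),
      r = net$spec$r,
      upsample = net$spec$upsample
    ),
    seed = net$seed,
    params = lapply(ps, function(p) list(dim = if (is.null(dim(p$value))) length(p$value) else dim(p$value),
                                         data = encode_doubles(p$value))),
    bn = lapply(bns, function(s) list(mean = encode_doubles(s$running_mean),
                                      var = encode_doubles(s$running_var)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "lungattn-checkpoint-1")) {
    stop("not a lungattn checkpoint: ", path)
  }
  enc <- obj$spec$encoder
  enc$widths <- as.integer(enc$widths)
  enc$blocks <- as.integer(enc$blocks)
  enc$stem_width <- as.integer(enc$stem_width)
  placement <- structure(list(x = as.integer(obj$spec$placement$x),
                              y = as.integer(obj$spec$placement$y)),
                         class = "placement_config")
  spec <- network_spec(encoder = enc, input_size = as.integer(obj$spec$input_size),
                       placement = placement, r = obj$spec$r,
                       upsample = obj$spec$upsample)
  net <- build_network(spec, seed = as.integer(obj$seed))
  ps <- collect_params(net$params)
  if (!setequal(names(ps), names(obj$params))) {
    stop("checkpoint parameter names do not match the rebuilt network")
  }
  for (nm in names(ps)) {
    entry <- obj$params[[nm]]
    v <- decode_doubles(entry$data)
    if (length(entry$dim) > 1L) v <- array(v, as.integer(entry$dim))
    if (length(v) != length(ps[[nm]]$value)) stop("size mismatch for ", nm)
    ps[[nm]]$value <- v
  }
  bns <- collect_bn_states(net$params)
  for (nm in names(bns)) {
    bns[[nm]]$running_mean <- decode_doubles(obj$bn[[nm]]$mean)
    bns[[nm]]$running_var <- decode_doubles(obj$bn[[nm]]$var)
  }
  net
}

encode_doubles <- function(v) {
  jsonlite::base64_enc(writeBin(as.double(as.vector(v)), raw(), size = 8L,
                                endian = "little"))
}

decode_doubles <- function(s) {
  raw <- jsonlite::base64_dec(s)
  readBin(raw, what = "double", n = length(raw) %/% 8L, size = 8L,
          endian = "little")
}
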