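# The attention blocks against hand-computed and nested-loop oracles, plus
# their structural invariants.

chw <- function(a) aperm(a, c(3, 1, 2)) # H x W x C -> C x H x W
hwc <- function(f) aperm(f, c(2, 3, 1))

test_that("channel attention reproduces the hand-evaluated MLP example", {
  cp <- channel_attention_params(2, seed = 1)
  cp$W0$value <- matrix(c(0.5, 0.25), 1, 2)
  cp$b0$value <- 0
  cp$W1$value <- matrix(c(1, -1), 2, 1)
  cp$b1$value <- c(0, 0)
  cp <- make_identity_bn(cp)
  f <- array(0, c(2, 2, 2)); f[1, , ] <- 2; f[2, , ] <- 4
  out <- channel_attention(f, cp)
  expect_equal(dim(out), c(2L, 1L, 1L))
  expect_equal(as.vector(out), c(2, 0), tolerance = 1e-12)
})

test_that("channel attention maps zero input to zero and keeps shape at width 64", {
  cp0 <- channel_attention_params(3, seed = 2)
  cp0 <- make_identity_bn(cp0)
  out <- channel_attention(array(0, c(3, 4, 4)), cp0)
  expect_equal(as.vector(out), rep(0, 3))

  cp64 <- channel_attention_params(64, seed = 3)
  expect_equal(cp64$hidden, 32L) # r = 0.5 halves the width
  out64 <- channel_attention(array(rnorm(64 * 16), c(64, 4, 4)), cp64)
  expect_equal(dim(out64), c(64L, 1L, 1L))
  expect_true(all(out64 >= 0))
})

test_that("channel attention is invariant to spatial permutations", {
  set.seed(4)
  cp <- channel_attention_params(5, seed = 4)
  f <- array(rnorm(5 * 6 * 8), c(5, 6, 8))
  perm <- sample(6 * 8)
  f_perm <- array(apply(matrix(f, 5), 1, function(v) v[perm]), c(6 * 8, 5))
  f_perm <- array(t(f_perm), c(5, 6, 8))
  expect_equal(channel_attention(f_perm, cp), channel_attention(f, cp),
               tolerance = 1e-12)
})

test_that("spatial attention with zero kernels is the identity", {
  sp <- spatial_attention_params(2, seed = 5)
  sp <- set_constant_kernels(sp, 0)
  f <- array(rnorm(2 * 8 * 12), c(2, 8, 12))
  expect_equal(spatial_attention(f, sp), f, tolerance = 1e-12)
})

test_that("spatial attention matches the nested-loop oracle", {
  # the documented averaging-kernel case on an all-ones input
  sp <- spatial_attention_params(1, upsample = "nearest", seed = 6)
  sp <- set_constant_kernels(sp, 1 / 9)
  f <- array(1, c(1, 8, 8))
  layers <- lapply(list(d1 = sp$d1, d2 = sp$d2, bottom = sp$bottom,
                        e2 = sp$e2, e1 = sp$e1),
                   function(l) list(w = l$w$value, b = l$b$value))
  expect_equal(spatial_attention(f, sp), chw(oracle_spatial_attention(hwc(f), layers)),
               tolerance = 1e-6)

  # a random multi-channel case through the same composed graph
  set.seed(7)
  sp2 <- spatial_attention_params(3, upsample = "nearest", seed = 7)
  f2 <- array(rnorm(3 * 8 * 8), c(3, 8, 8))
  layers2 <- lapply(list(d1 = sp2$d1, d2 = sp2$d2, bottom = sp2$bottom,
                         e2 = sp2$e2, e1 = sp2$e1),
                    function(l) list(w = l$w$value, b = l$b$value))
  expect_equal(spatial_attention(f2, sp2),
               chw(oracle_spatial_attention(hwc(f2), layers2)),
               tolerance = 1e-6)
})

test_that("spatial attention rejects sizes not divisible by 4", {
  sp <- spatial_attention_params(1, seed = 8)
  expect_error(spatial_attention(array(1, c(1, 6, 8)), sp), "divisible by 4")
})

test_that("X-attention map fuses spatial and channel attention through a sigmoid", {
  # zero channel MLP -> sigmoid(0) = 0.5 everywhere
  cp <- channel_attention_params(2, seed = 9)
  cp$W0$value[] <- 0; cp$W1$value[] <- 0
  cp <- make_identity_bn(cp)
  sp <- spatial_attention_params(2, seed = 10)
  f <- array(rnorm(2 * 8 * 8), c(2, 8, 8))
  mx <- x_attention_map(f, cp, sp)
  expect_equal(as.vector(mx), rep(0.5, length(mx)))

  # unit spatial plane with channel weights (2, 0)
  cp2 <- channel_attention_params(2, seed = 11)
  cp2$W0$value <- matrix(c(2, 0), 1, 2)
  cp2$b0$value <- 0
  cp2$W1$value <- matrix(c(1, -1), 2, 1)
  cp2$b1$value <- c(0, 0)
  cp2 <- make_identity_bn(cp2)
  sp2 <- spatial_attention_params(2, seed = 12)
  sp2 <- set_constant_kernels(sp2, 0)
  ones <- array(1, c(2, 8, 8))
  mx2 <- x_attention_map(ones, cp2, sp2)
  expect_equal(mx2[1, , ], matrix(1 / (1 + exp(-2)), 8, 8), tolerance = 1e-9)
  expect_equal(mx2[2, , ], matrix(0.5, 8, 8), tolerance = 1e-9)
  expect_equal(dim(mx2), c(2L, 8L, 8L))
})

test_that("Y-attention adjusts deeper channels and ignores their spatial layout", {
  set.seed(13)
  cp <- channel_attention_params(4, c_out = 2, seed = 13)
  sp <- spatial_attention_params(2, seed = 14)
  f <- array(rnorm(2 * 8 * 8), c(2, 8, 8))
  f_deep <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  my <- y_attention_map(f, f_deep, cp, sp)
  expect_equal(dim(my), c(2L, 8L, 8L))
  expect_true(all(my > 0 & my < 1))

  # swapping spatial positions in the deep map leaves MY unchanged (GAP)
  fd2 <- f_deep
  fd2[, 1, 1] <- f_deep[, 3, 2]
  fd2[, 3, 2] <- f_deep[, 1, 1]
  expect_equal(y_attention_map(f, fd2, cp, sp), my, tolerance = 1e-12)

  # but swapping positions in the shallow map changes MY
  f2 <- f
  f2[, 1, 1] <- f[, 5, 6]
  f2[, 5, 6] <- f[, 1, 1]
  expect_false(isTRUE(all.equal(y_attention_map(f2, f_deep, cp, sp), my)))

  # channel mismatch between the MLP output and the shallow map errors
  cp_bad <- channel_attention_params(4, c_out = 3, seed = 15)
  expect_error(y_attention_map(f, f_deep, cp_bad, sp), "must match")
})

test_that("zero channel MLP makes Y-attention constant 0.5", {
  cp <- channel_attention_params(4, c_out = 2, seed = 16)
  cp$W0$value[] <- 0; cp$W1$value[] <- 0
  cp <- make_identity_bn(cp)
  sp <- spatial_attention_params(2, seed = 17)
  f <- array(rnorm(2 * 8 * 8), c(2, 8, 8))
  f_deep <- array(rnorm(4), c(4, 3, 5)) # constant per channel
  my <- y_attention_map(f, f_deep, cp, sp)
  expect_equal(as.vector(my), rep(0.5, length(my)))
})

test_that("residual refinement is bounded gating around the identity", {
  set.seed(18)
  f <- array(abs(rnorm(3 * 6 * 6)), c(3, 6, 6))
  expect_equal(residual_refine(f, array(0, dim(f))), f)
  expect_equal(residual_refine(f, array(1, dim(f))), 2 * f)

  ones <- array(1, c(2, 4, 4))
  m <- array(c(rep(1 / (1 + exp(-2)), 16), rep(0.5, 16)), c(4, 4, 2))
  m <- aperm(m, c(3, 1, 2))
  out <- residual_refine(ones, m)
  expect_equal(out[1, 1, 1], 1 + 1 / (1 + exp(-2)), tolerance = 1e-9)
  expect_equal(out[2, 1, 1], 1.5)

  m_rand <- array(runif(length(f)), dim(f))
  out_rand <- residual_refine(f, m_rand)
  expect_true(all(out_rand >= f - 1e-12) && all(out_rand <= 2 * f + 1e-12))
  expect_error(residual_refine(f, array(0.5, c(3, 6, 5))), "shape")
})

test_that("attention maps stay strictly inside (0, 1) and preserve shape", {
  set.seed(19)
  for (rep in 1:5) {
    C <- sample(1:4, 1)
    f <- array(rnorm(C * 8 * 8, sd = 3), c(C, 8, 8))
    cp <- channel_attention_params(C)
    sp <- spatial_attention_params(C)
    mx <- x_attention_map(f, cp, sp)
    expect_identical(dim(mx), dim(f))
    expect_true(all(mx > 0 & mx < 1))
    expect_identical(dim(residual_refine(f, mx)), dim(f))
  }
})

test_that("every learnable parameter of the X and Y modules gets gradient", {
  set.seed(20)
  cp <- channel_attention_params(3, seed = 21)
  sp <- spatial_attention_params(3, seed = 22)
  x <- ag_const(array(rnorm(8 * 8 * 3), c(8, 8, 3, 1)))
  out <- residual_refine_node(x, x_attention_node(x, cp, sp))
  params <- collect_params(list(cp = cp, sp = sp))
  zero_grads(params)
  ag_backward(ag_mse(out, array(0, dim(out$value))))
  grads <- vapply(params, function(p) sum(abs(p$grad)), numeric(1))
  expect_true(all(grads > 0))

  cpy <- channel_attention_params(5, c_out = 3, seed = 23)
  spy <- spatial_attention_params(3, seed = 24)
  xd <- ag_const(array(rnorm(4 * 4 * 5), c(4, 4, 5, 1)))
  outy <- residual_refine_node(x, y_attention_node(x, xd, cpy, spy))
  paramsy <- collect_params(list(cp = cpy, sp = spy))
  zero_grads(paramsy)
  ag_backward(ag_mse(outy, array(0, dim(outy$value))))
  gradsy <- vapply(paramsy, function(p) sum(abs(p$grad)), numeric(1))
  expect_true(all(gradsy > 0))
})

test_that("analytic gradients match finite differences through the X module", {
  set.seed(25)
  cp <- channel_attention_params(2, seed = 26)
  sp <- spatial_attention_params(2, seed = 27)
  xv <- array(rnorm(8 * 8 * 2), c(8, 8, 2, 1))
  tgt <- array(runif(8 * 8 * 2), c(8, 8, 2, 1))
  loss_fn <- function() {
    x <- ag_const(xv)
    ag_mse(residual_refine_node(x, x_attention_node(x, cp, sp)), tgt)
  }
  params <- collect_params(list(cp = cp, sp = sp))
  zero_grads(params)
  ag_backward(loss_fn())
  for (nm in c("sp.d1.w", "sp.e1.w", "cp.W0", "cp.gamma")) {
    p <- params[[nm]]
    i <- sample(length(p$value), 1)
    eps <- 1e-6
    v0 <- p$value
    p$value[i] <- v0[i] + eps
    lp <- loss_fn()$value
    p$value[i] <- v0[i] - eps
    lm <- loss_fn()$value
    p$value <- v0
    expect_equal(p$grad[i], (lp - lm) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("the Y module carries exactly five 3x3 conv layers and a small budget", {
  sp <- spatial_attention_params(64, seed = 28)
  expect_identical(count_conv3x3_layers(sp), 5L)
  cp <- channel_attention_params(64, seed = 29)
  expect_identical(count_conv3x3_layers(list(cp = cp, sp = sp)), 5L)

  baseline <- network_param_count(network_spec("resnet101", 512, "baseline"))
  for (C in c(8, 16, 32, 64, 128)) {
    y_params <- param_count(list(channel_attention_params(C),
                                 spatial_attention_params(C)))
    expect_lt(y_params / baseline, 0.01)
  }
  # at width 256 the five 3x3 filters alone cross the 1% line (~1.4%)
  ratio_256 <- param_count(list(channel_attention_params(256),
                                spatial_attention_params(256))) / baseline
  expect_gt(ratio_256, 0.01)
  expect_lt(ratio_256, 0.02)
})
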