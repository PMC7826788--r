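# Placement parsing, network construction, forward contract, chaining, and
# checkpointing.

test_that("placement labels parse case-insensitively with a tolerant grammar", {
  p <- parse_placement("X(1)+X(2)+Y(1)+Y(2)")
  expect_equal(p$x, c(1L, 2L))
  expect_equal(p$y, c(1L, 2L))
  expect_equal(parse_placement("baseline"), parse_placement("BASELINE"))
  expect_equal(parse_placement("baseline")$x, integer(0))
  expect_equal(parse_placement(" y(3) + x(4) ")$x, 4L)
  expect_equal(parse_placement("U-Net+X(1) +X(2)+Y(1) +Y(2)")$y, c(1L, 2L))
  expect_error(parse_placement("X(5)"), "out of range")
  expect_error(parse_placement("Z(1)"), "cannot parse")
  expect_error(parse_placement("X(1)+X(1)"), "duplicate")
  expect_equal(format(parse_placement("baseline")), "baseline")
  expect_equal(format(p), "X(1)+X(2)+Y(1)+Y(2)")
})

test_that("every ablation-table label parses", {
  labels <- c("U-Net+X(1)", "U-Net+X(2)", "U-Net+X(3)", "U-Net+X(4)",
              "U-Net+Y(1)", "U-Net+Y(2)", "U-Net+Y(3)", "U-Net+Y(4)",
              "U-Net+X(1)+X(2)", "U-Net+X(3)+X(4)",
              "U-Net+X(1)+X(2)+X(3)+X(4)", "U-Net+Y(1)+Y(2)",
              "U-Net+Y(3)+Y(4)", "U-Net+Y(1)+Y(2)+Y(3)+Y(4)",
              "U-Net+X(1)+X(2)+Y(1)+Y(2)", "U-Net+X(3)+X(4)+Y(3)+Y(4)")
  for (lb in labels) expect_silent(parse_placement(lb))
})

test_that("input sizes must be divisible by 32", {
  expect_error(network_spec("tiny", input_size = 60), "32")
  expect_silent(network_spec("tiny", input_size = 64))
})

test_that("a forward pass yields a probability map of the input size", {
  spec <- network_spec("tiny", input_size = 64, placement = "X(1)+X(2)+Y(1)+Y(2)")
  net <- build_network(spec, seed = 1)
  set.seed(2)
  img <- matrix(runif(64 * 64) * 255, 64, 64)
  p <- predict(net, img)
  expect_identical(dim(p), c(64L, 64L))
  expect_true(all(p > 0 & p < 1))
  # deterministic in evaluation mode, finite on degenerate input
  expect_identical(predict(net, img), p)
  p0 <- predict(net, matrix(0, 64, 64))
  expect_true(all(is.finite(p0) & p0 > 0 & p0 < 1))
  expect_error(predict(net, matrix(0, 32, 32)), "expects")
})

test_that("parameter count grows strictly with each placed module", {
  sizes <- vapply(
    list("baseline", "X(1)", "X(1)+Y(1)", "X(1)+X(2)+Y(1)",
         "X(1)+X(2)+Y(1)+Y(2)"),
    function(lbl) network_param_count(network_spec("tiny", 64, lbl)),
    numeric(1)
  )
  expect_true(all(diff(sizes) > 0))
  # baseline spec count equals the instantiated baseline's count
  s0 <- network_spec("tiny", 64, "baseline")
  expect_equal(network_param_count(build_network(s0, 1)),
               network_param_count(s0))
})

test_that("adding Y(1) adds exactly five learnable 3x3 conv layers", {
  base <- build_network(network_spec("tiny", 64, "baseline"), seed = 1)
  with_y <- build_network(network_spec("tiny", 64, "Y(1)"), seed = 1)
  expect_identical(count_conv3x3_layers(with_y) - count_conv3x3_layers(base), 5L)
})

test_that("X(i) feeds Y(i): removing X changes what Y receives", {
  spec <- network_spec("tiny", input_size = 64, placement = "X(1)+Y(1)")
  net <- build_network(spec, seed = 3)
  set.seed(4)
  xb <- array(runif(64 * 64), c(64, 64, 1, 1))
  probe_with <- net_forward(net, xb, probes = TRUE)$acts$y_input_1
  net_ablated <- net
  net_ablated$params$xmod[1] <- list(NULL)
  probe_without <- net_forward(net_ablated, xb, probes = TRUE)$acts$y_input_1
  expect_false(isTRUE(all.equal(probe_with, probe_without)))
})

test_that("checkpoints round-trip bitwise through save and load", {
  spec <- network_spec("tiny", input_size = 64, placement = "X(2)+Y(2)")
  net <- build_network(spec, seed = 5)
  set.seed(6)
  img <- matrix(runif(64 * 64) * 255, 64, 64)
  before <- predict(net, img)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(net, path)
  restored <- load_checkpoint(path)
  expect_identical(predict(restored, img), before)
  expect_equal(format(restored$spec$placement), "X(2)+Y(2)")
})

test_that("attention placement requires enough resolution at the stage", {
  # at 32x32 input, stage 4 sits at 2x2 which cannot host the pyramid
  expect_error(network_spec("tiny", 32, "X(4)"), "divisible by 4")
  expect_silent(network_spec("tiny", 32, "X(1)+X(2)+Y(1)+Y(2)"))
  expect_silent(network_spec("tiny", 64, "X(4)+Y(4)"))
})
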