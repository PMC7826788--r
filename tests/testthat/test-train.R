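# Training-loop mechanics: loss, schedule, seeding, early stopping,
# checkpointing. Heavy end-to-end training lives in test-acceptance.R; these
# use a few SGD steps on 32x32 phantoms.

make_tiny_dataset <- function(n, seed, size = 32) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  generate_dataset(n, base_seed = seed, out_dir = dir, size = size)
  read_manifest(file.path(dir, "manifest.csv"))
}

test_that("mse_loss is the pixel mean of squared error", {
  truth <- random_mask(6, 6)
  expect_equal(mse_loss(truth * 1.0, truth), 0)
  expect_equal(mse_loss(matrix(0.5, 6, 6), truth), 0.25)
  set.seed(1)
  p <- matrix(runif(36), 6, 6)
  acc <- 0
  for (r in 1:6) for (c in 1:6) acc <- acc + (p[r, c] - truth[r, c])^2
  expect_equal(mse_loss(p, truth), acc / 36)
  expect_error(mse_loss(matrix(0.5, 6, 5), truth), "differ")
})

test_that("the plateau schedule decays by 10 after patience stalls", {
  expect_equal(plateau_schedule(c(0.5, 0.6, 0.6, 0.6, 0.6), patience = 3), 0.001)
  expect_equal(plateau_schedule(c(0.1, 0.2, 0.3, 0.4, 0.5), patience = 3), 0.01)
  # two consecutive plateaus reach 1e-4; the stall counter resets on decay
  hist2 <- c(0.5, rep(0.5, 3), rep(0.5, 3))
  expect_equal(plateau_schedule(hist2, patience = 3), 1e-4)
  expect_equal(plateau_schedule(0.9), 0.01)
})

test_that("a few SGD steps on a fixed batch decrease the loss", {
  manifest <- make_tiny_dataset(4, seed = 31)
  net <- build_network(network_spec("tiny", 32, "baseline"), seed = 1)
  cfg <- train_config(max_iterations = 6L, eval_interval = 100L,
                      initial_lr = 0.002, seed = 2)
  fit <- train_network(net, manifest, list(train = manifest$id,
                                           validation = character(0)), cfg)
  expect_equal(nrow(fit$log), 6)
  expect_true(all(diff(fit$log$loss) < 0))
  expect_true(all(is.finite(fit$log$loss)))
})

test_that("training is reproducible per seed and seeds differ", {
  manifest <- make_tiny_dataset(6, seed = 32)
  split <- list(train = manifest$id[1:4], validation = manifest$id[5:6])
  cfg <- train_config(max_iterations = 8L, eval_interval = 4L, seed = 3)
  run <- function(init_seed) {
    net <- build_network(network_spec("tiny", 32, "baseline"), seed = init_seed)
    train_network(net, manifest, split, cfg)$log
  }
  log_a <- run(1)
  log_b <- run(1)
  expect_identical(log_a, log_b)
  log_c <- run(99)
  expect_false(isTRUE(all.equal(log_a$loss[1], log_c$loss[1])))
})

test_that("early stopping halts after patience evaluations without gain", {
  manifest <- make_tiny_dataset(5, seed = 33)
  net <- build_network(network_spec("tiny", 32, "baseline"), seed = 1)
  # vanishing learning rate keeps validation Dice constant
  cfg <- train_config(max_iterations = 50L, eval_interval = 1L,
                      initial_lr = 1e-12, early_stop_patience = 1L, seed = 4)
  fit <- train_network(net, manifest,
                       list(train = manifest$id[1:4],
                            validation = manifest$id[5]), cfg)
  expect_equal(nrow(fit$log), 2) # best at eval 1, stop at eval 2
  expect_false(anyNA(fit$log$val_dice))
})

test_that("the best-validation checkpoint restores its exact predictions", {
  manifest <- make_tiny_dataset(6, seed = 34)
  split <- list(train = manifest$id[1:4], validation = manifest$id[5:6])
  net <- build_network(network_spec("tiny", 32, "X(1)+Y(1)"), seed = 2)
  cfg <- train_config(max_iterations = 10L, eval_interval = 5L, seed = 5)
  ckpt <- withr::local_tempfile(fileext = ".json")
  fit <- train_network(net, manifest, split, cfg, checkpoint_path = ckpt)
  expect_true(file.exists(fit$checkpoint))
  restored <- load_checkpoint(fit$checkpoint)
  img <- preprocess_image(read_gray_image(manifest$image_path[1]), c(32, 32))
  expect_identical(predict(restored, img), predict(restored, img))
  expect_equal(restored$spec$input_size, c(32L, 32L))
})

test_that("evaluation post-processing caps predictions at two components", {
  manifest <- make_tiny_dataset(4, seed = 35)
  net <- build_network(network_spec("tiny", 32, "baseline"), seed = 3)
  ev <- evaluate_network(net, manifest)
  expect_equal(nrow(ev$per_image), 4)
  expect_true(all(c("dice", "sensitivity", "ppv") %in% names(ev$per_image)))
  for (i in seq_len(nrow(manifest))) {
    img <- preprocess_image(read_gray_image(manifest$image_path[i]), c(32, 32))
    pred <- keep_largest_components(binarize(predict(net, img)))
    expect_lte(max(label_components(pred)), 2L)
  }
  # pooled averaging pools confusion counts rather than averaging ratios
  ev_pooled <- evaluate_network(net, manifest, average = "pooled")
  expect_named(ev_pooled$mean, c("dice", "sensitivity", "ppv"))
})

test_that("an untrained constant-ish network scores by the empty-prediction rule", {
  # zero the head so the output is sigmoid(0) = 0.5 everywhere: with the
  # strict 0.5 threshold everything is background
  manifest <- make_tiny_dataset(3, seed = 36)
  net <- build_network(network_spec("tiny", 32, "baseline"), seed = 4)
  net$params$head$w$value[] <- 0
  net$params$head$b$value[] <- 0
  ev <- evaluate_network(net, manifest)
  expect_true(all(ev$per_image$dice == 0)) # truth non-empty, prediction empty
})
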