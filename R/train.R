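# Training and evaluation orchestration: SGD on mean-squared-error between
# the sigmoid probability map and the binary mask, learning-rate decay by 10
# on a validation-Dice plateau, early stopping, and the cross-validated
# ablation runner over attention placements.

#' Training configuration
#'
#' Defaults follow the experimental regimen the attention modules were
#' validated with: mini-batch 4, initial learning rate 0.01 decayed by a
#' factor of 10 on plateau, MSE loss, plain SGD (momentum 0.9), at most
#' 10,000 iterations with early stopping, channel-attention reduction ratio
#' 0.5, and no data augmentation.
#'
#' @param batch_size Mini-batch size.
#' @param initial_lr Initial learning rate.
#' @param lr_decay_factor Factor the learning rate is divided by on plateau.
#' @param plateau_patience Evaluations without improvement before a decay.
#' @param early_stop_patience Evaluations without improvement before
#'   stopping.
#' @param max_iterations Maximum optimizer steps (mini-batches).
#' @param eval_interval Iterations between validation evaluations.
#' @param seed Seed for data ordering.
#' @param r Channel-attention reduction ratio.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay (default 0).
#' @param threshold Binarization threshold for validation/test Dice.
#' @param keep_components Components kept by post-processing (default 2).
#' @param augmentation Must remain `FALSE`; no augmentation is applied.
#' @return A `train_config` object.
#' @export
train_config <- function(batch_size = 4L, initial_lr = 0.01,
                         lr_decay_factor = 10, plateau_patience = 5L,
                         early_stop_patience = 15L, max_iterations = 10000L,
                         eval_interval = 50L, seed = 1L, r = 0.5,
                         momentum = 0.9, weight_decay = 0, threshold = 0.5,
                         keep_components = 2L, augmentation = FALSE) {
  stopifnot(batch_size >= 1L, initial_lr > 0, lr_decay_factor > 1,
            plateau_patience >= 1L, early_stop_patience >= 1L,
            max_iterations >= 1L, eval_interval >= 1L, !augmentation)
  structure(list(batch_size = as.integer(batch_size), initial_lr = initial_lr,
                 lr_decay_factor = lr_decay_factor,
                 plateau_patience = as.integer(plateau_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 max_iterations = as.integer(max_iterations),
                 eval_interval = as.integer(eval_interval),
                 seed = as.integer(seed), r = r, momentum = momentum,
                 weight_decay = weight_decay, threshold = threshold,
                 keep_components = as.integer(keep_components)),
            class = "train_config")
}

#' Mean squared error between a probability map and a mask
#'
#' @param prob H x W matrix with entries in unit range.
#' @param truth H x W binary matrix of the same shape.
#' @return Non-negative scalar: the pixel mean of squared differences.
#' @export
mse_loss <- function(prob, truth) {
  if (!identical(dim(prob), dim(truth))) {
    stop("probability map and mask shapes differ")
  }
  mean((prob - truth)^2)
}

#' Plateau learning-rate schedule
#'
#' Replays a validation-score history through the decay rule: the learning
#' rate is divided by `factor` whenever the running best score has not
#' strictly improved for `patience` consecutive evaluations; the stall
#' counter resets after each decay.
#'
#' @param history Numeric vector of validation scores (one per evaluation,
#'   oldest first).
#' @param initial_lr Learning rate before any decay.
#' @param patience Evaluations without improvement that trigger a decay.
#' @param factor Decay factor (default 10).
#' @return The learning rate in force after the last evaluation.
#' @export
plateau_schedule <- function(history, initial_lr = 0.01, patience = 5L,
                             factor = 10) {
  stopifnot(length(history) >= 1L)
  lr <- initial_lr
  best <- -Inf
  stall <- 0L
  for (h in history) {
    if (h > best) {
      best <- h
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) {
        lr <- lr / factor
        stall <- 0L
      }
    }
  }
  lr
}

# load and preprocess one manifest row for a given network input size
load_example <- function(row, input_size) {
  img <- preprocess_image(read_gray_image(row$image_path), input_size)
  msk <- read_mask(row$mask_path)
  if (!identical(dim(msk), as.integer(input_size))) {
    msk <- resize_image(msk, input_size, mask = TRUE)
  }
  list(x = img / 255, y = msk)
}

load_examples <- function(manifest, ids, input_size) {
  rows <- manifest[match(ids, manifest$id), , drop = FALSE]
  if (anyNA(rows$id)) {
    stop("ids not present in manifest: ",
         paste(setdiff(ids, manifest$id), collapse = ", "))
  }
  missing <- !file.exists(rows$image_path) | !file.exists(rows$mask_path)
  if (any(missing)) {
    stop("missing files for ids: ", paste(rows$id[missing], collapse = ", "))
  }
  lapply(seq_len(nrow(rows)), function(i) load_example(rows[i, ], input_size))
}

sgd_step <- function(params, vel, lr, momentum, weight_decay) {
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * p$value
    v <- vel[[nm]]
    v <- if (is.null(v)) g else momentum * v + g
    vel[[nm]] <- v
    p$value <- p$value - lr * v
  }
  invisible(NULL)
}

# full evaluation pipeline for one in-memory example
predict_mask <- function(net, x, threshold, keep_components, connectivity = 8L) {
  sz <- net$spec$input_size
  out <- net_forward(net, array(x, c(sz[1], sz[2], 1L, 1L)), training = FALSE)
  prob <- matrix(out$prob$value, sz[1], sz[2])
  keep_largest_components(binarize(prob, threshold), k = keep_components,
                          connectivity = connectivity)
}

mean_dice <- function(net, examples, threshold, keep_components) {
  mean(vapply(examples, function(ex) {
    pred <- predict_mask(net, ex$x, threshold, keep_components)
    mask_metrics(pred, ex$y)$dice
  }, numeric(1)))
}

#' Train a segmentation network
#'
#' Runs seeded mini-batch SGD with the MSE loss, evaluating the validation
#' Dice (after binarization and two-component post-processing) every
#' `eval_interval` iterations. The checkpoint with the best validation Dice
#' is kept; the learning rate decays by `lr_decay_factor` when the best Dice
#' plateaus, and training stops early after `early_stop_patience`
#' evaluations without improvement.
#'
#' @param net A `lungattn_net` from [build_network()].
#' @param manifest A manifest data frame (see [read_manifest()]) or the path
#'   to a manifest CSV.
#' @param split A list with `train` and `validation` id vectors (e.g. one
#'   plan from [make_splits()]).
#' @param cfg A [train_config()].
#' @param checkpoint_path Where to store the best checkpoint (default: a
#'   temporary file).
#' @return List with `checkpoint` (path to the best-Dice checkpoint), `net`
#'   (the network in its final state), `log` (data frame of iteration, loss,
#'   lr, and validation Dice at evaluation rows), and `best_val_dice`.
#' @export
train_network <- function(net, manifest, split, cfg = train_config(),
                          checkpoint_path = tempfile(fileext = ".json")) {
  stopifnot(inherits(net, "lungattn_net"), inherits(cfg, "train_config"))
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  sz <- net$spec$input_size
  train_ex <- load_examples(manifest, split$train, sz)
  val_ex <- load_examples(manifest, split$validation, sz)
  params <- collect_params(net$params)
  vel <- new.env(parent = emptyenv())
  n_train <- length(train_ex)
  B <- min(cfg$batch_size, n_train)

  log_rows <- list()
  history <- numeric(0)
  best <- -Inf
  since_best <- 0L
  lr <- cfg$initial_lr
  stopped <- FALSE

  withr::with_seed(cfg$seed, {
    queue <- integer(0)
    for (it in seq_len(cfg$max_iterations)) {
      if (length(queue) < B) queue <- c(queue, sample.int(n_train))
      idx <- queue[seq_len(B)]
      queue <- queue[-seq_len(B)]
      xb <- array(0, c(sz[1], sz[2], 1L, B))
      tb <- array(0, c(sz[1], sz[2], 1L, B))
      for (k in seq_len(B)) {
        xb[, , 1L, k] <- train_ex[[idx[k]]]$x
        tb[, , 1L, k] <- train_ex[[idx[k]]]$y
      }
      zero_grads(params)
      out <- net_forward(net, xb, training = TRUE)
      loss <- ag_mse(out$prob, tb)
      if (!is.finite(loss$value)) {
        stop("training diverged: non-finite loss at iteration ", it)
      }
      ag_backward(loss)
      sgd_step(params, vel, lr, cfg$momentum, cfg$weight_decay)

      do_eval <- it %% cfg$eval_interval == 0L || it == cfg$max_iterations
      val_dice <- NA_real_
      if (do_eval && length(val_ex) > 0L) {
        val_dice <- mean_dice(net, val_ex, cfg$threshold, cfg$keep_components)
        history <- c(history, val_dice)
        if (val_dice > best) {
          best <- val_dice
          since_best <- 0L
          save_checkpoint(net, checkpoint_path)
        } else {
          since_best <- since_best + 1L
        }
        lr <- plateau_schedule(history, cfg$initial_lr, cfg$plateau_patience,
                               cfg$lr_decay_factor)
        if (since_best >= cfg$early_stop_patience) stopped <- TRUE
      }
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(iteration = it, loss = loss$value, lr = lr,
                   val_dice = val_dice)
      if (stopped) break
    }
  })
  if (!file.exists(checkpoint_path)) save_checkpoint(net, checkpoint_path)
  list(checkpoint = checkpoint_path, net = net,
       log = do.call(rbind, log_rows),
       best_val_dice = if (is.finite(best)) best else NA_real_)
}

#' Evaluate a checkpoint on a set of images
#'
#' For each id: preprocess, predict, binarize, keep the largest components,
#' and score against the ground-truth mask. Reports per-image metrics and
#' either their macro average (per-image metrics averaged with equal weight,
#' the default) or pooled-pixel metrics (confusion counts summed over all
#' images first).
#'
#' @param net A `lungattn_net` or the path to a checkpoint file.
#' @param manifest A manifest data frame or path.
#' @param ids Ids to evaluate (default: all ids in the manifest).
#' @param threshold Binarization threshold.
#' @param keep_components Components kept in post-processing; `Inf` or 0
#'   disables the filtering.
#' @param average `"macro"` (default) or `"pooled"`.
#' @return List with `per_image` (data frame: id, dice, sensitivity, ppv)
#'   and `mean` (named numeric vector over the requested averaging).
#' @export
evaluate_network <- function(net, manifest, ids = NULL, threshold = 0.5,
                             keep_components = 2L,
                             average = c("macro", "pooled")) {
  average <- match.arg(average)
  if (is.character(net)) net <- load_checkpoint(net)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.null(ids)) ids <- manifest$id
  sz <- net$spec$input_size
  examples <- load_examples(manifest, ids, sz)
  counts <- vector("list", length(ids))
  rows <- vector("list", length(ids))
  for (i in seq_along(examples)) {
    ex <- examples[[i]]
    pred <- if (keep_components >= 1L && is.finite(keep_components)) {
      predict_mask(net, ex$x, threshold, keep_components)
    } else {
      binarize(matrix(net_forward(net, array(ex$x, c(sz[1], sz[2], 1L, 1L)),
                                  training = FALSE)$prob$value, sz[1], sz[2]),
               threshold)
    }
    counts[[i]] <- confusion_counts(pred, ex$y)
    met <- segmentation_metrics(counts[[i]])
    rows[[i]] <- data.frame(id = ids[i], dice = met$dice,
                            sensitivity = met$sensitivity, ppv = met$ppv,
                            stringsAsFactors = FALSE)
  }
  per_image <- do.call(rbind, rows)
  mean_out <- if (average == "macro") {
    c(dice = mean(per_image$dice), sensitivity = mean(per_image$sensitivity),
      ppv = mean(per_image$ppv))
  } else {
    pooled <- list(tp = sum(vapply(counts, `[[`, numeric(1), "tp")),
                   fp = sum(vapply(counts, `[[`, numeric(1), "fp")),
                   fn = sum(vapply(counts, `[[`, numeric(1), "fn")))
    unlist(segmentation_metrics(pooled))
  }
  list(per_image = per_image, mean = mean_out)
}

#' Cross-validated ablation over attention placements
#'
#' For each placement label: build the network, train it on each
#' cross-validation fold, evaluate on the fold's test set, and aggregate the
#' folds into mean and standard deviation per metric, producing a
#' configurations-by-metrics summary table.
#'
#' @param manifest A manifest data frame or path.
#' @param labels Character vector of placement labels (see
#'   [parse_placement()]).
#' @param cfg A [train_config()].
#' @param folds Number of folds to actually run, 1 to 5 (all five plans are
#'   always constructed; fewer folds run a scaled-down protocol). With one
#'   fold the reported sd is 0.
#' @param encoder,input_size Passed to [network_spec()].
#' @param seed Base seed; fold f of every configuration uses `seed + f` for
#'   weight initialization.
#' @return List with `results` (one row per configuration x fold) and
#'   `summary` (one row per configuration: mean, sd and `"mean ± sd"`
#'   formatted columns per metric).
#' @export
run_ablation <- function(manifest, labels, cfg = train_config(), folds = 5L,
                         encoder = "tiny", input_size = c(128L, 128L),
                         seed = 1L) {
  stopifnot(length(labels) >= 1L, folds >= 1L, folds <= 5L)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  plans <- make_splits(manifest$id, seed = cfg$seed)
  results <- list()
  summaries <- list()
  for (label in labels) {
    placement <- parse_placement(label)
    spec <- network_spec(encoder = encoder, input_size = input_size,
                         placement = placement, r = cfg$r)
    fold_metrics <- list()
    for (f in seq_len(folds)) {
      plan <- plans[[f]]
      net <- build_network(spec, seed = seed + f)
      fit <- train_network(net, manifest, plan, cfg)
      ev <- evaluate_network(fit$checkpoint, manifest, plan$test,
                             threshold = cfg$threshold,
                             keep_components = cfg$keep_components)
      fold_metrics[[f]] <- as.list(ev$mean)
      results[[length(results) + 1L]] <-
        data.frame(configuration = label, fold = f,
                   dice = ev$mean[["dice"]],
                   sensitivity = ev$mean[["sensitivity"]],
                   ppv = ev$mean[["ppv"]], stringsAsFactors = FALSE)
    }
    agg <- aggregate_metrics(fold_metrics)
    summaries[[length(summaries) + 1L]] <- data.frame(
      configuration = label,
      dice = agg$formatted[agg$metric == "dice"],
      sensitivity = agg$formatted[agg$metric == "sensitivity"],
      ppv = agg$formatted[agg$metric == "ppv"],
      dice_mean = agg$mean[agg$metric == "dice"],
      dice_sd = agg$sd[agg$metric == "dice"],
      sensitivity_mean = agg$mean[agg$metric == "sensitivity"],
      sensitivity_sd = agg$sd[agg$metric == "sensitivity"],
      ppv_mean = agg$mean[agg$metric == "ppv"],
      ppv_sd = agg$sd[agg$metric == "ppv"],
      stringsAsFactors = FALSE
    )
  }
  list(results = do.call(rbind, results), summary = do.call(rbind, summaries))
}
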