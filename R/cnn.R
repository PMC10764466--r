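#' Configuration for the log-mel chaos CNN
#'
#' A compact pre-activation convolutional network over 96 x 101 log-mel
#' patches: three 5x5 convolutions (BN -> ReLU -> conv), two interleaved
#' max-pooling stages, and two dense layers ending in a 4-way softmax.
#' The first convolution uses stride 2 to bring the input resolution down
#' early. The default widths (24/48/96 channels, 112 dense units) give
#' about 0.53M trainable weights; configurations outside `[0.3M, 0.7M]`
#' are rejected. Training uses categorical cross-entropy, batch size 64
#' and Adam with initial learning rate 0.001, with early stopping on
#' validation accuracy at a patience of 15 epochs.
#'
#' @param conv_channels Three channel widths, one per conv layer.
#' @param kernel Square kernel size (5).
#' @param conv_strides Stride per conv layer (default `c(2, 1, 1)`).
#' @param pool_sizes Two pooling windows, e.g. `list(c(4,4), c(2,2))`.
#' @param dense_units Width of the penultimate dense layer.
#' @param input_shape Mel bands x frames of one patch (96 x 101).
#' @param n_classes Number of chaos levels (4).
#' @param batch_size Minibatch size (64).
#' @param learning_rate Adam initial learning rate (0.001).
#' @param max_epochs Epoch cap for a training run.
#' @param patience Early-stopping patience, in epochs without validation
#'   accuracy improvement (15).
#' @param validation_fraction Fraction of training data held out for
#'   early stopping (0.1), grouped by participant when enough
#'   participants are available.
#' @param param_bounds Accepted range for the trainable parameter count.
#' @param seed Integer seed for initialisation, splits and shuffling.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(conv_channels = c(24L, 48L, 96L), kernel = 5L,
                       conv_strides = c(2L, 1L, 1L),
                       pool_sizes = list(c(4L, 4L), c(2L, 2L)),
                       dense_units = 112L, input_shape = c(96L, 101L),
                       n_classes = 4L, batch_size = 64L, learning_rate = 0.001,
                       max_epochs = 50L, patience = 15L,
                       validation_fraction = 0.1,
                       param_bounds = c(3e5, 7e5), seed = 1L) {
  structure(
    list(conv_channels = as.integer(conv_channels), kernel = as.integer(kernel),
         conv_strides = as.integer(conv_strides),
         pool_sizes = pool_sizes, dense_units = as.integer(dense_units),
         input_shape = as.integer(input_shape), n_classes = as.integer(n_classes),
         batch_size = as.integer(batch_size), learning_rate = learning_rate,
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         validation_fraction = validation_fraction,
         param_bounds = param_bounds, seed = as.integer(seed)),
    class = "cnn_config"
  )
}

#' Build an untrained chaos CNN
#'
#' Instantiates the network a [cnn_config()] describes and validates its
#' size: exactly 3 conv layers, 2 pooling stages, and a trainable
#' parameter count inside the configured bounds.
#'
#' @param config A [cnn_config()].
#' @return A `chaos_cnn` object (untrained).
#' @export
build_cnn <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  net <- nn_init(input_shape = config$input_shape,
                 conv_channels = config$conv_channels,
                 kernel = config$kernel, conv_strides = config$conv_strides,
                 pool_sizes = config$pool_sizes,
                 dense_units = config$dense_units,
                 n_classes = config$n_classes, seed = config$seed)
  count <- nn_param_count(net)
  if (count < config$param_bounds[1] || count > config$param_bounds[2]) {
    abort(sprintf(
      "Configured network has %d trainable parameters, outside [%g, %g].",
      count, config$param_bounds[1], config$param_bounds[2]))
  }
  structure(list(net = net, config = config, param_count = count,
                 trained = FALSE, history = NULL),
            class = "chaos_cnn")
}

#' @export
print.chaos_cnn <- function(x, ...) {
  cat(sprintf("<chaos_cnn> %s, %d parameters, conv %s, dense %d\n",
              if (x$trained) "trained" else "untrained", x$param_count,
              paste(x$config$conv_channels, collapse = "/"),
              x$config$dense_units))
  invisible(x)
}

## patch tibble -> (bands*frames) x n matrix, column-major per patch
patch_matrix <- function(patches) {
  vapply(patches, as.numeric, numeric(length(patches[[1]])))
}

## validation split: whole participants when >= 5 are available, else a
## class-stratified random 10% of patches
split_validation <- function(data, fraction, seed) {
  n <- nrow(data)
  pids <- unique(data$participant_id)
  with_seed(seed, {
    if (length(pids) >= 5) {
      ord <- sample(pids)
      sizes <- vapply(ord, function(p) sum(data$participant_id == p), numeric(1))
      take <- ord[seq_len(max(1, which(cumsum(sizes) >= fraction * n)[1]))]
      which(data$participant_id %in% take)
    } else {
      idx <- unlist(lapply(split(seq_len(n), data$chaos_level), function(ix) {
        sample(ix, max(1, round(fraction * length(ix))))
      }))
      sort(unname(idx))
    }
  })
}

#' Train the chaos CNN on labeled log-mel patches
#'
#' Each 2-s patch carries its source segment's chaos label. Training
#' minimises categorical cross-entropy with Adam (batch 64, lr 0.001);
#' after every epoch validation accuracy is measured on a held-out split
#' and training stops early once it has not improved for `patience`
#' epochs, restoring the best weights.
#'
#' @param data Patch tibble from [segment_patches()]: `participant_id`,
#'   `segment_index`, `chaos_level`, `patch` list-column.
#' @param config A [cnn_config()].
#' @param quiet Suppress per-epoch progress (default `TRUE`).
#' @return A trained `chaos_cnn` with a `history` tibble (epoch,
#'   train_loss, val_accuracy).
#' @export
train_cnn <- function(data, config = cnn_config(), quiet = TRUE) {
  assert_columns(data, c("participant_id", "chaos_level", "patch"), "patch table")
  if (nrow(data) == 0) abort("Cannot train on an empty patch table.")
  model <- build_cnn(config)
  net <- model$net

  X <- patch_matrix(data$patch)
  y <- as.integer(data$chaos_level) + 1L

  val_idx <- split_validation(data, config$validation_fraction,
                              derive_seed(config$seed, 1L))
  train_idx <- setdiff(seq_len(nrow(data)), val_idx)
  if (length(train_idx) == 0) abort("Validation split consumed all training data.")
  Xv <- X[, val_idx, drop = FALSE]
  yv <- y[val_idx]

  best <- list(acc = -Inf, params = net$params, running = net$running, epoch = 0L)
  stall <- 0L
  history <- vector("list", config$max_epochs)
  adam <- adam_init(net$params)

  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(derive_seed(config$seed, 100L + epoch),
                     sample(train_idx))
    losses <- c()
    for (start in seq(1, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      if (length(idx) < 2) next # BN needs a real batch
      fwd <- nn_forward(net, X[, idx, drop = FALSE], train = TRUE)
      bwd <- nn_backward(net, fwd, y[idx])
      upd <- adam_step(net$params, bwd$grads, adam, lr = config$learning_rate)
      net$params <- upd$params
      adam <- upd$state
      net <- nn_update_running(net, fwd)
      losses <- c(losses, bwd$loss)
    }
    val_probs <- nn_predict_probs(net, Xv)
    val_acc <- mean(max.col(t(val_probs), ties.method = "first") == yv)
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       train_loss = mean(losses),
                                       val_accuracy = val_acc)
    if (!quiet) {
      message(sprintf("epoch %d: loss %.4f, val acc %.3f", epoch,
                      mean(losses), val_acc))
    }
    ## ties go to the later epoch: with small validation splits many
    ## epochs share the top accuracy and later weights are better trained
    if (val_acc >= best$acc) {
      improved <- val_acc > best$acc + 1e-12
      best <- list(acc = val_acc, params = net$params,
                   running = net$running, epoch = epoch)
      stall <- if (improved) 0L else stall + 1L
    } else {
      stall <- stall + 1L
    }
    if (stall >= config$patience) break
  }
  net$params <- best$params
  net$running <- best$running

  model$net <- net
  model$trained <- TRUE
  model$history <- dplyr::bind_rows(history)
  model$best_epoch <- best$epoch
  model$val_accuracy <- best$acc
  model
}

#' Geometric-mean aggregation of patch probabilities
#'
#' Combines per-patch class probability vectors into one segment-level
#' vector by the element-wise geometric mean (probabilities floored at
#' `1e-12` so a single zero cannot annihilate a class), renormalised to
#' sum to 1. With a single patch this is the identity; it is invariant to
#' patch order.
#'
#' @param prob_matrix Numeric matrix, one row per patch, one column per
#'   class.
#' @param floor Probability floor (default `1e-12`).
#' @return Numeric probability vector summing to 1.
#' @export
aggregate_patch_probs <- function(prob_matrix, floor = 1e-12) {
  prob_matrix <- pmax(as.matrix(prob_matrix), floor)
  g <- exp(colMeans(log(prob_matrix)))
  g / sum(g)
}

#' Predict chaos probabilities for segments with a trained CNN
#'
#' Computes per-patch probabilities and aggregates them per segment by
#' geometric mean; the predicted level is the argmax with ties broken
#' toward the lowest chaos level.
#'
#' @param object A trained `chaos_cnn`.
#' @param newdata Segment tibble with `samples`, or a patch tibble from
#'   [segment_patches()].
#' @param ... Unused.
#' @return Tibble: `participant_id`, `segment_index`, `p0`..`p3`,
#'   `predicted_level`.
#' @export
predict.chaos_cnn <- function(object, newdata, ...) {
  if (!object$trained) abort("Model has not been trained yet.")
  patches <- expand_patches(newdata)
  probs <- t(nn_predict_probs(object$net, patch_matrix(patches$patch)))
  patches |>
    dplyr::mutate(.p = lapply(seq_len(nrow(patches)), function(i) probs[i, ])) |>
    dplyr::group_by(.data$participant_id, .data$segment_index) |>
    dplyr::summarise(
      .agg = list(aggregate_patch_probs(do.call(rbind, .data$.p))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p0 = vapply(.data$.agg, `[`, numeric(1), 1),
      p1 = vapply(.data$.agg, `[`, numeric(1), 2),
      p2 = vapply(.data$.agg, `[`, numeric(1), 3),
      p3 = vapply(.data$.agg, `[`, numeric(1), 4),
      predicted_level = vapply(.data$.agg, argmax_lowest, integer(1))
    ) |>
    dplyr::select(-".agg")
}

#' Predict the chaos level of a single waveform
#'
#' @param model A trained `chaos_cnn`.
#' @param samples Mono 5-s waveform at 22,050 Hz.
#' @return One-row tibble with `p0`..`p3` and `predicted_level`.
#' @export
predict_segment <- function(model, samples) {
  seg <- tibble::tibble(participant_id = "x", segment_index = 0L,
                        samples = list(samples))
  dplyr::select(predict(model, seg), -"participant_id", -"segment_index")
}
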