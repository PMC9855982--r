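# Training protocol: six-part split (five cross-validation folds plus one
# held-out test part), minibatch Adam on the MSE loss, early stopping on
# validation MSE with best-weight restoration.

#' Split a dataset into five cross-validation folds and a test part
#'
#' Deterministic seeded partition into six near-equal parts; remainder rows
#' go to the later parts so the test part is among the larger ones. Parts
#' 1-5 are the cross-validation folds, part 6 is the held-out test part.
#'
#' @param n Number of rows (or a data frame, whose row count is used).
#' @param seed Integer seed.
#' @return List with `folds` (list of five integer index vectors), `test`
#'   (integer index vector), and `part` (length-`n` integer assignment,
#'   values 1-6 with 6 = test).
#' @export
split_six_parts <- function(n, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  stopifnot(n >= 6L)
  set.seed(seed)
  perm <- sample.int(n)
  base <- n %/% 6L
  rem <- n %% 6L
  sizes <- rep(base, 6L) + as.integer(seq_len(6L) > 6L - rem)
  part <- integer(n)
  part[perm] <- rep(seq_len(6L), times = sizes)
  list(folds = lapply(1:5, function(k) which(part == k)),
       test = which(part == 6L),
       part = part)
}

# Adam with decoupled-free (classic) L2 weight decay added to the gradient.
adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, lr, weight_decay,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) g <- params[[nm]] * 0
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

eval_mse <- function(model, samples) {
  preds <- predict(model, samples)
  truth <- vapply(samples, `[[`, numeric(1L), "affinity")
  mse(preds, truth)
}

#' Train an affinity model
#'
#' Minimizes MSE with Adam (learning rate, weight decay, batch size and
#' epoch budget from `model$config`). After every epoch the validation MSE
#' is computed; training halts once it has not improved for
#' `config$patience` consecutive epochs, and the best-validation weights are
#' returned. Fully deterministic for a fixed `config$seed`.
#'
#' @param model A `dta_model`.
#' @param train_data Data frame with `smiles`, `sequence`, `affinity`, or
#'   prepared samples from [dta_prepare()].
#' @param val_data Validation set in the same form; if `NULL`, a seeded 10%
#'   holdout (at least one sample) is split from the training data.
#' @param epochs,patience Optional overrides of `model$config`.
#' @param ablation Train the max-pool concatenation head instead of the
#'   attention interaction.
#' @param verbose Print per-epoch losses.
#' @return The model with trained `params`, plus `history` (data frame:
#'   epoch, train_mse, val_mse) and `best_epoch`.
#' @export
train_dta <- function(model, train_data, val_data = NULL, epochs = NULL,
                      patience = NULL, ablation = FALSE, verbose = FALSE) {
  stopifnot(inherits(model, "dta_model"))
  config <- model$config
  if (!is.null(epochs)) config$epochs <- as.integer(epochs)
  if (!is.null(patience)) config$patience <- as.integer(patience)
  train <- if (is.data.frame(train_data)) dta_prepare(model, train_data) else train_data
  if (length(train) == 0L) stop("empty training set")
  set.seed(config$seed)
  if (is.null(val_data)) {
    n_val <- max(1L, round(0.1 * length(train)))
    vidx <- sample.int(length(train), n_val)
    val <- train[vidx]
    train <- train[-vidx]
    if (length(train) == 0L) stop("training set too small to hold out validation")
  } else {
    val <- if (is.data.frame(val_data)) dta_prepare(model, val_data) else val_data
  }
  truth_all <- vapply(train, `[[`, numeric(1L), "affinity")
  if (anyNA(truth_all)) stop("training samples must carry affinities")

  params <- model$params
  state <- adam_state(params)
  best_params <- params
  best_val <- Inf
  best_epoch <- 0L
  history <- data.frame(epoch = integer(0), train_mse = numeric(0),
                        val_mse = numeric(0))
  wait <- 0L

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(length(train))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    epoch_losses <- numeric(length(batches))
    for (b in seq_along(batches)) {
      idx <- batches[[b]]
      tape <- ad_tape()
      pnodes <- params_to_nodes(tape, params)
      preds <- vector("list", length(idx))
      for (k in seq_along(idx)) {
        masks <- new_dropout_masks(config)
        preds[[k]] <- model_forward(tape, pnodes, config, train[[idx[k]]],
                                    dropout_masks = masks,
                                    ablation = ablation)$pred
      }
      loss <- ad_mse_loss(tape, preds, truth_all[idx])
      ad_backward(tape, loss)
      grads <- lapply(pnodes, function(nd) nd$grad)
      upd <- adam_update(params, grads, state, config$learning_rate,
                         config$weight_decay)
      params <- upd$params
      state <- upd$state
      epoch_losses[b] <- loss$value[1L, 1L]
    }
    model$params <- params
    val_mse <- eval_mse(model, val)
    train_mse <- stats::weighted.mean(epoch_losses, lengths(batches))
    history <- rbind(history, data.frame(epoch = epoch, train_mse = train_mse,
                                         val_mse = val_mse))
    if (verbose) {
      message(sprintf("epoch %d  train MSE %.5f  val MSE %.5f", epoch,
                      train_mse, val_mse))
    }
    if (val_mse < best_val) {
      best_val <- val_mse
      best_params <- params
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model$params <- best_params
  model$history <- history
  model$best_epoch <- best_epoch
  model
}

#' Evaluate a model on labelled data
#'
#' @param model A trained `dta_model`.
#' @param data Data frame with `smiles`, `sequence`, `affinity` or prepared
#'   samples.
#' @param ablation Evaluate the ablation head.
#' @return List with `mse`, `ci`, `pred`, and `truth`.
#' @export
evaluate_dta <- function(model, data, ablation = FALSE) {
  samples <- if (is.data.frame(data)) dta_prepare(model, data) else data
  truth <- vapply(samples, `[[`, numeric(1L), "affinity")
  pred <- predict(model, samples, ablation = ablation)
  list(mse = mse(pred, truth),
       ci = concordance_index(pred, truth),
       pred = pred, truth = truth)
}
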