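# Training: hybrid Dice + BCE objective minimized with Adam. Gradients come
# from the hand-written backward pass in network.R; all randomness (shuffling)
# flows from the protocol seed.

#' Training protocol
#'
#' Defaults follow the reference training recipe (Adam, learning rate 1e-4,
#' batch size 2, 150 epochs); every field is overridable for desk-scale runs.
#'
#' @param lr Adam learning rate (default 1e-4).
#' @param batch_size Samples per gradient step (default 2).
#' @param epochs Passes over the dataset (default 150).
#' @param max_steps Optional hard cap on gradient steps.
#' @param weights A [loss_weights()] for the hybrid objective.
#' @param seed Seed for data-order shuffling.
#' @param shuffle Shuffle sample order each epoch (default `TRUE`).
#' @param verbose Print per-epoch progress.
#' @return An object of class `train_protocol`.
#' @export
train_protocol <- function(lr = 1e-4, batch_size = 2L, epochs = 150L,
                           max_steps = Inf, weights = loss_weights(),
                           seed = 1L, shuffle = TRUE, verbose = FALSE) {
  stopifnot(lr > 0, batch_size >= 1, epochs >= 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), max_steps = max_steps,
                 weights = weights, seed = as.integer(seed),
                 shuffle = isTRUE(shuffle), verbose = isTRUE(verbose)),
            class = "train_protocol")
}

#' Assemble a training sample
#'
#' @param x Normalized input patch (4-D array, see [as_network_input()]).
#' @param y Binary target array (same spatial grid).
#' @param clinical Clinical vector of length 6.
#' @return A list usable in the `dataset` argument of [train_model()].
#' @export
training_sample <- function(x, y, clinical) {
  if (inherits(y, "seg_mask")) y <- y$voxels
  stopifnot(length(dim(x)) == 4L, identical(dim(x)[1:3], dim(y)))
  list(x = x, y = y, clinical = clinical)
}

# gradient of the hybrid loss w.r.t. the probability map (vectorized)
hybrid_grad <- function(prob, target, w, dice_eps = 1, bce_eps = 1e-7) {
  p <- as.numeric(prob); t <- as.numeric(target)
  Nn <- 2 * sum(p * t) + dice_eps
  Dd <- sum(p) + sum(t) + dice_eps
  ddice <- (Nn - 2 * t * Dd) / Dd^2
  pc <- pmin(pmax(p, bce_eps), 1 - bce_eps)
  dbce <- (-t / pc + (1 - t) / (1 - pc)) / length(p)
  w$lambda1 * ddice + w$lambda2 * dbce
}

# elementwise tree walk over nested parameter/gradient lists; matches
# children by name where present (the two trees may order fields differently)
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    keys <- if (!is.null(names(a)) && all(nzchar(names(a)))) names(a) else seq_along(a)
    for (nm in keys)
      out[[nm]] <- if (is.null(a[[nm]])) NULL else tree_map2(a[[nm]], b[[nm]], f)
    out
  } else f(a, b)
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

#' Train a segmentation model
#'
#' Minimizes the hybrid loss (\eqn{\lambda_1} soft Dice +
#' \eqn{\lambda_2} BCE) with Adam. The loss history is recorded per gradient
#' step; if a validation set is given, mean validation Dice is recorded per
#' epoch. Two runs with identical model seed, data and protocol seed produce
#' identical histories.
#'
#' @param model An `mk_model` from [build_model()].
#' @param dataset Non-empty list of [training_sample()]s.
#' @param protocol A [train_protocol()].
#' @param validation Optional list of [training_sample()]s scored by Dice at
#'   threshold 0.5 after each epoch.
#' @return List with `model` (trained), `history` (data.frame of step, epoch,
#'   loss) and `val_dice` (per-epoch mean validation Dice, or `NULL`).
#' @export
train_model <- function(model, dataset, protocol = train_protocol(),
                        validation = NULL) {
  stopifnot(inherits(model, "mk_model"), inherits(protocol, "train_protocol"))
  if (!length(dataset))
    stop_mk("empty training dataset", class = "mkunet_validation_error")
  p <- model$params
  mstate <- tree_zero(p)
  vstate <- tree_zero(p)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  hist_step <- integer(0); hist_epoch <- integer(0); hist_loss <- numeric(0)
  val_dice <- if (is.null(validation)) NULL else numeric(0)
  set.seed(protocol$seed)
  for (ep in seq_len(protocol$epochs)) {
    ord <- if (protocol$shuffle) sample(seq_along(dataset)) else seq_along(dataset)
    batches <- split(ord, ceiling(seq_along(ord) / protocol$batch_size))
    for (bt in batches) {
      if (step >= protocol$max_steps) break
      gacc <- NULL
      loss_acc <- 0
      for (i in bt) {
        s <- dataset[[i]]
        fw <- model_forward(model, s$x, s$clinical, cache = TRUE)
        loss_acc <- loss_acc + protocol$weights$lambda1 * dice_loss(fw$prob, s$y) +
          protocol$weights$lambda2 * bce_loss(fw$prob, s$y)
        dp <- hybrid_grad(fw$prob, s$y, protocol$weights)
        gi <- model_backward(model, fw$cache, dp)
        gacc <- if (is.null(gacc)) gi else tree_map2(gacc, gi, `+`)
      }
      nb <- length(bt)
      loss <- loss_acc / nb
      if (!is.finite(loss))
        stop_mk("non-finite loss at step ", step + 1L, class = "mkunet_numeric_error")
      gacc <- tree_map2(gacc, gacc, function(a, b) a / nb)
      step <- step + 1L
      # Adam update
      mstate <- tree_map2(mstate, gacc, function(m, gr) beta1 * m + (1 - beta1) * gr)
      vstate <- tree_map2(vstate, gacc, function(v, gr) beta2 * v + (1 - beta2) * gr^2)
      bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
      upd <- tree_map2(mstate, vstate, function(m, v)
        protocol$lr * (m / bc1) / (sqrt(v / bc2) + adam_eps))
      model$params <- tree_map2(model$params, upd, `-`)
      hist_step <- c(hist_step, step)
      hist_epoch <- c(hist_epoch, ep)
      hist_loss <- c(hist_loss, loss)
    }
    if (!is.null(validation)) {
      vd <- vapply(validation, function(s) {
        pr <- model_forward(model, s$x, s$clinical)$prob
        as.numeric(dice_coefficient((pr > 0.5) * 1L, s$y))
      }, numeric(1))
      val_dice <- c(val_dice, mean(vd))
    }
    if (protocol$verbose)
      message(sprintf("epoch %d/%d  loss %.4f%s", ep, protocol$epochs,
                      hist_loss[length(hist_loss)],
                      if (!is.null(val_dice))
                        sprintf("  val Dice %.3f", val_dice[length(val_dice)]) else ""))
    if (step >= protocol$max_steps) break
  }
  list(model = model,
       history = data.frame(step = hist_step, epoch = hist_epoch, loss = hist_loss),
       val_dice = val_dice)
}

#' Training Dice of a model on a dataset
#'
#' @param model An `mk_model`.
#' @param dataset List of [training_sample()]s.
#' @param threshold Probability threshold (default 0.5).
#' @return Mean Dice over the dataset.
#' @export
dataset_dice <- function(model, dataset, threshold = 0.5) {
  mean(vapply(dataset, function(s) {
    pr <- model_forward(model, s$x, s$clinical)$prob
    as.numeric(dice_coefficient((pr > threshold) * 1L, s$y))
  }, numeric(1)))
}
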