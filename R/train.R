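#' Training protocol configuration
#'
#' Defaults follow the study protocol: 150 epochs, batch size 32, learning
#' rate 0.001, 10% of the training windows (whole trials) held out for
#' validation, training order shuffled each epoch. Adam is used as the
#' optimizer; the final model is the last-epoch weights (no early stopping).
#'
#' @param epochs,batch_size,learning_rate Optimization hyperparameters.
#' @param val_fraction Fraction of training trials held out for validation.
#' @param optimizer_name Currently only `"adam"`.
#' @param shuffle Shuffle training windows between epochs.
#' @param seed Master seed: drives weight init, the validation split and
#'   shuffling.
#' @return An object of class `scbam_train_config`.
#' @export
train_config <- function(epochs = 150, batch_size = 32, learning_rate = 0.001,
                         val_fraction = 0.10, optimizer_name = "adam",
                         shuffle = TRUE, seed = 1L) {
  if (val_fraction <= 0 || val_fraction >= 1) stop_invalid("val_fraction must be in (0, 1)")
  if (epochs < 0) stop_invalid("epochs must be >= 0")
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, val_fraction = val_fraction,
                 optimizer_name = optimizer_name, shuffle = shuffle,
                 seed = as.integer(seed)),
            class = "scbam_train_config")
}

adam_init <- function(net) {
  lapply(net$layers, function(l) lapply(l$params, function(p) {
    list(m = array(0, dim(p) %||% length(p)), v = array(0, dim(p) %||% length(p)))
  }))
}

adam_step <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net$layers[[i]]$params[[nm]] <- net$layers[[i]]$params[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(net = net, state = state)
}

one_hot <- function(labels, classes) {
  y <- matrix(0, length(labels), length(classes))
  y[cbind(seq_along(labels), match(labels, classes))] <- 1
  y
}

eval_metrics <- function(net, x, y_onehot) {
  fwd <- net_forward(net, x, training = FALSE)
  loss <- -mean(log(rowSums(fwd$probs * y_onehot) + 1e-12))
  acc <- mean(max.col(fwd$probs, ties.method = "first") ==
              max.col(y_onehot, ties.method = "first"))
  list(loss = loss, acc = acc)
}

#' Train a binary window classifier
#'
#' Trains a [build_model()] network on the training split of a feature map
#' with softmax cross-entropy and Adam, recording per-epoch train/validation
#' loss and accuracy. Deterministic given the seed: weight init, shuffling and
#' dropout all derive from `train_cfg$seed`. With `epochs = 0` the untrained
#' network and empty curves are returned.
#'
#' @param features List with `train` and `val` `scbam_feature_map`s holding
#'   exactly the two classes of `class_pair`.
#' @param class_pair Length-2 vector of labels; the first maps to output 1.
#' @param model_cfg A [scbam_config()] with `n_classes = 2`.
#' @param train_cfg A [train_config()].
#' @return List with `net` (trained model), `history` (data.frame epoch,
#'   train_loss, train_acc, val_loss, val_acc) and `class_pair`.
#' @export
train_binary <- function(features, class_pair, model_cfg = scbam_config(),
                         train_cfg = train_config()) {
  xtr <- features$train$values; ytr_lab <- features$train$labels
  xva <- features$val$values;   yva_lab <- features$val$labels
  if (length(unique(ytr_lab)) < 2 || length(unique(yva_lab)) < 2)
    stop_invalid("both classes must be present in the train and val splits")
  if (!all(sort(unique(c(ytr_lab, yva_lab))) == sort(class_pair)))
    stop_invalid("labels outside the class pair (%s)", paste(class_pair, collapse = ", "))
  ytr <- one_hot(ytr_lab, class_pair)
  yva <- one_hot(yva_lab, class_pair)
  net <- build_model(model_cfg, seed = train_cfg$seed)
  if (train_cfg$epochs == 0)
    return(list(net = net, history = data.frame(), class_pair = class_pair))
  state <- adam_init(net)
  n <- dim(xtr)[1]
  hist <- vector("list", train_cfg$epochs)
  t_step <- 0L
  with_seed(train_cfg$seed + 1L, {
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- if (train_cfg$shuffle) sample.int(n) else seq_len(n)
      starts <- seq(1L, n, by = train_cfg$batch_size)
      tloss <- 0; tacc <- 0
      for (s in starts) {
        idx <- ord[seq(s, min(s + train_cfg$batch_size - 1L, n))]
        xb <- xtr[idx, , , drop = FALSE]
        yb <- ytr[idx, , drop = FALSE]
        fwd <- net_forward(net, xb, training = TRUE)
        loss <- -mean(log(rowSums(fwd$probs * yb) + 1e-12))
        grads <- net_backward(net, fwd, yb)
        t_step <- t_step + 1L
        up <- adam_step(net, grads, state, train_cfg$learning_rate, t_step)
        net <- up$net; state <- up$state
        tloss <- tloss + loss * length(idx)
        tacc <- tacc + sum(max.col(fwd$probs, ties.method = "first") ==
                           max.col(yb, ties.method = "first"))
      }
      vm <- eval_metrics(net, xva, yva)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tloss / n,
                                  train_acc = tacc / n, val_loss = vm$loss,
                                  val_acc = vm$acc)
    }
  })
  list(net = net, history = do.call(rbind, hist), class_pair = class_pair)
}
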