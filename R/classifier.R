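# 1-D fully convolutional task classifier:
# conv(64, k3, ReLU) -> maxpool(2) -> conv(128, k3, ReLU) -> maxpool(2)
# -> flatten -> dense(100, ReLU) -> dropout(0.5) -> dense(n_classes, softmax),
# trained with Adam on sparse categorical cross-entropy. "Same" padding keeps
# the time axis at 300 -> 150 -> 75.

#' FCN classifier configuration
#'
#' @param conv_filters Filters of the two conv blocks (defaults 64, 128).
#' @param kernel Conv kernel size (default 3).
#' @param pool Max-pool size (fixed at 2 per block).
#' @param dense_units Width of the fully connected layer (default 100).
#' @param dropout Dropout rate before the output layer (default 0.5).
#' @param n_classes Output classes: 10 for task classification (default), 30
#'   for the combined task-by-impairment target.
#' @param target `"task"` (default) or `"class"` — which label the model
#'   predicts.
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param seed Integer seed for initialization, shuffling, and dropout.
#' @return An `fcn_config` list.
#' @export
fcn_config <- function(conv_filters = c(64L, 128L), kernel = 3L, pool = 2L,
                       dense_units = 100L, dropout = 0.5,
                       n_classes = NULL, target = c("task", "class"),
                       epochs = 100L, batch_size = 32L,
                       learning_rate = 1e-3, seed = 1L) {
  target <- match.arg(target)
  if (is.null(n_classes)) n_classes <- if (target == "task") 10L else 30L
  if (n_classes < 2L) {
    abort("n_classes must be >= 2.", class = "reachsynth_config_error")
  }
  if (dropout < 0 || dropout >= 1) {
    abort("dropout must be in [0, 1).", class = "reachsynth_config_error")
  }
  structure(
    list(conv_filters = as.integer(conv_filters), kernel = as.integer(kernel),
         pool = as.integer(pool), dense_units = as.integer(dense_units),
         dropout = dropout, n_classes = as.integer(n_classes),
         target = target, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, seed = as.integer(seed)),
    class = "fcn_config"
  )
}

#' Build an untrained FCN model
#'
#' @param config An [fcn_config()].
#' @param input_length,input_channels Input signal shape (300 x 9).
#' @return An `fcn_model` with freshly initialized parameters (deterministic
#'   given `config$seed`).
#' @export
build_fcn <- function(config, input_length = .TRIAL_LEN,
                      input_channels = 9L) {
  if (input_length %% (config$pool^2) != 0L) {
    abort("input_length must be divisible by pool^2.",
          class = "reachsynth_config_error")
  }
  set.seed(config$seed)
  f <- config$conv_filters
  flat <- (input_length %/% (config$pool^2)) * f[2]
  net <- list(layers = list(
    nn_conv1d(input_channels, f[1], config$kernel), nn_relu(), nn_maxpool2(),
    nn_conv1d(f[1], f[2], config$kernel), nn_relu(), nn_maxpool2(),
    nn_flatten(),
    nn_dense(flat, config$dense_units), nn_relu(),
    nn_dropout(config$dropout),
    nn_dense(config$dense_units, config$n_classes)
  ))
  structure(
    list(net = net, config = config, input_length = as.integer(input_length),
         input_channels = as.integer(input_channels),
         channel_means = rep(0, input_channels),
         channel_sds = rep(1, input_channels),
         history = tibble(epoch = integer(), loss = numeric(),
                          accuracy = numeric()),
         trained = FALSE),
    class = "fcn_model"
  )
}

fcn_targets <- function(dataset, config) {
  if (config$target == "task") {
    match(dataset$task, .TASK_IDS)            # 1-based task index
  } else {
    as.integer(dataset$class) + 1L
  }
}

fcn_standardize <- function(model, x) {
  for (c in seq_len(dim(x)[3])) {
    x[, , c] <- (x[, , c] - model$channel_means[c]) / model$channel_sds[c]
  }
  x
}

#' Train the FCN classifier
#'
#' Standardizes channels over the training set, then runs minibatch Adam on
#' sparse categorical cross-entropy for `config$epochs` epochs. Aborts if the
#' loss becomes non-finite.
#'
#' @param dataset A `trial_dataset` with at least one trial per class.
#' @param config An [fcn_config()].
#' @return A trained `fcn_model` with a per-epoch `history` tibble.
#' @seealso [predict_confusion()]
#' @export
train_classifier <- function(dataset, config = fcn_config()) {
  validate_trials(dataset)
  model <- build_fcn(config)
  y <- fcn_targets(dataset, config)
  if (length(unique(y)) < 2L) {
    abort("Training data must contain at least 2 classes.",
          class = "reachsynth_invalid_input")
  }
  x <- trials_to_array(dataset)
  model$channel_means <- apply(x, 3, mean)
  model$channel_sds <- pmax(apply(x, 3, sd), 1e-8)
  x <- fcn_standardize(model, x)
  n <- dim(x)[1]
  net <- model$net
  opt <- adam_init(net, lr = config$learning_rate, beta1 = 0.9)
  hist <- matrix(NA_real_, config$epochs, 2)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    tot_loss <- 0; tot_correct <- 0; seen <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      take <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- x[take, , , drop = FALSE]
      fw <- net_forward(net, xb, training = TRUE)
      net <- fw$net
      sx <- softmax_xent(fw$out, y[take])
      if (!is.finite(sx$loss)) {
        abort(sprintf("Classifier loss became non-finite at epoch %d.", epoch),
              class = "reachsynth_divergence")
      }
      bk <- net_backward(net, fw$caches, sx$dlogits)
      st <- adam_step(net, bk$grads, opt)
      net <- st$net; opt <- st$opt
      tot_loss <- tot_loss + sx$loss * length(take)
      tot_correct <- tot_correct +
        sum(max.col(sx$probs, ties.method = "first") == y[take])
      seen <- seen + length(take)
    }
    hist[epoch, ] <- c(tot_loss / seen, tot_correct / seen)
  }
  model$net <- net
  model$history <- tibble(epoch = seq_len(config$epochs),
                          loss = hist[, 1], accuracy = hist[, 2])
  model$trained <- TRUE
  model
}

#' Predict class probabilities or labels
#'
#' @param object A trained `fcn_model`.
#' @param dataset A `trial_dataset`.
#' @param type `"prob"` for the softmax matrix, `"class"` for 0-based
#'   predicted label indices.
#' @param ... Unused.
#' @return Probability matrix (rows sum to 1) or integer vector.
#' @export
predict.fcn_model <- function(object, dataset, type = c("prob", "class"),
                              ...) {
  type <- match.arg(type)
  x <- fcn_standardize(object, trials_to_array(dataset))
  logits <- net_forward(object$net, x, training = FALSE)$out
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  if (type == "prob") probs else max.col(probs, ties.method = "first") - 1L
}

#' Confusion matrix on a labeled dataset
#'
#' @param model A trained `fcn_model`.
#' @param dataset A `trial_dataset` with true labels.
#' @return An `n_classes x n_classes` integer count matrix, rows = true
#'   class, columns = predicted; entries sum to `nrow(dataset)`.
#' @export
predict_confusion <- function(model, dataset) {
  pred <- predict(model, dataset, type = "class")
  truth <- fcn_targets(dataset, model$config) - 1L
  k <- model$config$n_classes
  cm <- matrix(0L, k, k)
  for (i in seq_along(pred)) {
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  lab <- if (model$config$target == "task") .TASK_IDS else
    as.character(0:(k - 1L))
  dimnames(cm) <- list(truth = lab, predicted = lab)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}
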