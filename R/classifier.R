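#' CNN, head and training configurations
#'
#' The reference architecture: two valid-padding 3x3 convolutions (32 then
#' 16 feature maps, ReLU), each followed by 2x2 max-pooling (floor
#' division) and 25% dropout; the flattened feature vector feeds a dense
#' head of two 512-unit ReLU layers and a softmax output. Training uses
#' Adam (learning rate 1e-3), batch size 64, at most 50 epochs, a
#' stratified 20% validation split, and early stopping on validation loss
#' with patience 5, restoring the best-validation weights. The training
#' hyperparameters are this package's choices for CPU-scale reliability;
#' the architecture constants follow the reference design.
#'
#' @param conv1_maps,conv2_maps feature maps in the two conv layers.
#' @param dropout_rate dropout fraction after each pooling stage.
#' @param hidden_units dense head layer widths.
#' @param optimizer only `"adam"` is implemented.
#' @param learning_rate,batch_size,max_epochs,validation_fraction,seed,early_stop_patience
#'   training-loop controls; `seed` fully determines the split, the weight
#'   initialisation and the dropout masks.
#' @return a config list of the corresponding class.
#' @export
cnn_config <- function(conv1_maps = 32, conv2_maps = 16, dropout_rate = 0.25) {
  stopifnot(conv1_maps >= 1, conv2_maps >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(conv1_maps = as.integer(conv1_maps),
                 conv2_maps = as.integer(conv2_maps),
                 kernel = c(3L, 3L), pool = c(2L, 2L),
                 dropout_rate = dropout_rate, padding = "valid"),
            class = "cnn_config")
}

#' @rdname cnn_config
#' @param n_classes number of softmax outputs (>= 2).
#' @export
head_config <- function(hidden_units = c(512, 512), n_classes = 2) {
  stopifnot(n_classes >= 2, all(hidden_units >= 1))
  structure(list(hidden_units = as.integer(hidden_units),
                 n_classes = as.integer(n_classes),
                 activation = "relu", output_activation = "softmax"),
            class = "head_config")
}

#' @rdname cnn_config
#' @export
train_config <- function(optimizer = "adam", learning_rate = 1e-3,
                         batch_size = 64, max_epochs = 50,
                         validation_fraction = 0.2, seed = 1L,
                         early_stop_patience = 5) {
  stopifnot(identical(optimizer, "adam"),
            validation_fraction > 0, validation_fraction < 1)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed),
                 early_stop_patience = as.integer(early_stop_patience),
                 loss = "categorical_crossentropy"),
            class = "train_config")
}

#' Closed-form flattened feature length of the CNN
#'
#' Shape arithmetic under valid padding and floor 2x2 pooling:
#' `floor((floor((H - 2) / 2) - 2) / 2) * (same for W) * conv2_maps`.
#' Errors name the first stage whose output would be empty.
#'
#' @param H,W input height/width (channels x channels for an AsMap).
#' @param conv2_maps feature maps in the second conv layer.
#' @return integer flatten length.
#' @examples
#' cnn_flatten_length(62, 62)  # 3136 = 14 * 14 * 16
#' cnn_flatten_length(32, 32)  # 576  = 6 * 6 * 16
#' @export
cnn_flatten_length <- function(H, W = H, conv2_maps = 16) {
  step <- function(n, what) {
    n1 <- n - 2L
    if (n1 < 1L) stop("input too small: ", what, " conv stage needs >= 3, got ", n)
    n2 <- n1 %/% 2L
    if (n2 < 1L) stop("input too small: ", what, " pooling stage got ", n1)
    n2
  }
  h <- step(step(H, "first"), "second")
  w <- step(step(W, "first"), "second")
  as.integer(h * w * conv2_maps)
}

#' Build the CNN feature extractor with dense softmax head
#'
#' Layer sequence: conv(3x3, `conv1_maps`, ReLU) -> maxpool(2x2) ->
#' dropout -> conv(3x3, `conv2_maps`, ReLU) -> maxpool(2x2) -> dropout ->
#' flatten -> dense hidden layers (ReLU) -> softmax. Weights are
#' He-initialised; [train_model()] re-initialises them under the training
#' seed.
#'
#' @param cnn a [cnn_config()].
#' @param head a [head_config()].
#' @param input_shape integer vector `(H, W, K)`: AsMap rows, columns,
#'   selected bands.
#' @return object of class `asmap_model`.
#' @export
build_model <- function(cnn = cnn_config(), head = head_config(),
                        input_shape) {
  stopifnot(inherits(cnn, "cnn_config"), inherits(head, "head_config"),
            length(input_shape) == 3L)
  if (input_shape[1] != input_shape[2])
    stop("AsMap inputs are square: H (", input_shape[1], ") != W (",
         input_shape[2], ")")
  fl <- cnn_flatten_length(input_shape[1], input_shape[2], cnn$conv2_maps)
  model <- structure(list(type = "cnn", cnn = cnn, head = head,
                          input_shape = as.integer(input_shape),
                          n_classes = head$n_classes,
                          flatten_length = fl,
                          params = NULL, classes = NULL,
                          trained = FALSE, history = NULL),
                     class = "asmap_model")
  set.seed(0L)
  model$params <- nn_init_params(model)
  model
}

#' @rdname build_model
#' @param input_dim feature-vector length for the dense-only model used by
#'   the DE/DASM/RASM/DCAU baselines.
#' @export
build_dense_model <- function(head = head_config(), input_dim) {
  stopifnot(inherits(head, "head_config"), input_dim >= 1)
  model <- structure(list(type = "mlp", cnn = NULL, head = head,
                          input_shape = as.integer(input_dim),
                          n_classes = head$n_classes,
                          flatten_length = as.integer(input_dim),
                          params = NULL, classes = NULL,
                          trained = FALSE, history = NULL),
                     class = "asmap_model")
  set.seed(0L)
  model$params <- nn_init_params(model)
  model
}

#' @export
print.asmap_model <- function(x, ...) {
  if (x$type == "cnn")
    cat(sprintf("<asmap_model cnn> input %s, conv %d/%d maps, flatten %d, head %s -> %d classes%s\n",
                paste(x$input_shape, collapse = "x"),
                x$cnn$conv1_maps, x$cnn$conv2_maps, x$flatten_length,
                paste(x$head$hidden_units, collapse = "+"), x$n_classes,
                if (x$trained) " [trained]" else ""))
  else
    cat(sprintf("<asmap_model mlp> input %d, head %s -> %d classes%s\n",
                x$input_shape, paste(x$head$hidden_units, collapse = "+"),
                x$n_classes, if (x$trained) " [trained]" else ""))
  invisible(x)
}

as_class_factor <- function(y, classes = NULL) {
  if (is.factor(y)) y <- as.character(y)
  if (is.null(classes)) classes <- sort(unique(as.character(y)))
  f <- factor(as.character(y), levels = classes)
  if (anyNA(f)) stop("labels outside the model's class set: ",
                     paste(setdiff(unique(as.character(y)), classes), collapse = ", "))
  f
}

n_examples <- function(x) if (is.matrix(x)) nrow(x) else dim(x)[4]

slice_examples <- function(x, idx) {
  if (is.matrix(x)) x[idx, , drop = FALSE]
  else x[, , , idx, drop = FALSE]
}

#' Stratified train/validation index split
#'
#' Per-class random partition preserving class ratios within one example;
#' every class keeps at least one example on each side.
#' @keywords internal
stratified_split <- function(y, fraction) {
  f <- as_class_factor(y)
  hold <- integer(0)
  for (cl in levels(f)) {
    idx <- which(f == cl)
    n_hold <- max(1L, round(length(idx) * fraction))
    if (n_hold >= length(idx)) n_hold <- length(idx) - 1L
    hold <- c(hold, sample(idx, n_hold))
  }
  sort(hold)
}

#' Train a model on labelled feature examples
#'
#' Minibatch Adam with a stratified validation split, early stopping on
#' validation loss, and best-weight restoration. The seed in `cfg` fully
#' determines initialisation, split and dropout masks, making runs
#' reproducible on one machine.
#'
#' @param model an `asmap_model` from [build_model()] or
#'   [build_dense_model()].
#' @param x examples: `H x W x K x N` array of normalised AsMaps (CNN) or
#'   `N x D` feature matrix (dense model).
#' @param y class labels, length N (character, factor or integer codes).
#' @param cfg a [train_config()].
#' @return the trained model; `$history` holds per-epoch train/validation
#'   loss and accuracy, `$split` the validation indices used.
#' @export
train_model <- function(model, x, y, cfg = train_config()) {
  stopifnot(inherits(model, "asmap_model"), inherits(cfg, "train_config"))
  N <- n_examples(x)
  f <- as_class_factor(y)
  if (length(f) != N) stop("length(y) != number of examples")
  if (nlevels(f) != model$n_classes)
    stop("model expects ", model$n_classes, " classes, labels have ", nlevels(f))
  counts <- table(f)
  if (any(counts < 2L))
    stop("every class needs >= 2 examples; short: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  model$classes <- levels(f)

  set.seed(cfg$seed)
  model$params <- nn_init_params(model)
  val_idx <- stratified_split(f, cfg$validation_fraction)
  tr_idx <- setdiff(seq_len(N), val_idx)
  x_tr <- slice_examples(x, tr_idx); x_va <- slice_examples(x, val_idx)
  yi <- as.integer(f)
  onehot <- function(idx) {
    Y <- matrix(0, length(idx), model$n_classes)
    Y[cbind(seq_along(idx), yi[idx])] <- 1
    Y
  }
  Y_tr <- onehot(tr_idx); Y_va <- onehot(val_idx)

  state <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  hist <- data.frame()
  patience_left <- cfg$early_stop_patience
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(length(tr_idx))
    n_batch <- ceiling(length(ord) / cfg$batch_size)
    loss_sum <- 0; n_correct <- 0L
    for (bi in seq_len(n_batch)) {
      rows <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size,
                                                        length(ord))]
      cache <- nn_forward(model, slice_examples(x_tr, rows),
                          params = model$params, training = TRUE)
      Yb <- Y_tr[rows, , drop = FALSE]
      # pre-update minibatch metrics stand in for a full train-set pass
      loss_sum <- loss_sum + cross_entropy(cache$probs, Yb) * length(rows)
      n_correct <- n_correct + sum(max.col(cache$probs) == yi[tr_idx][rows])
      grads <- nn_backward(model, cache, Yb, params = model$params)
      upd <- adam_step(model$params, grads, state, cfg$learning_rate)
      model$params <- upd$params; state <- upd$state
    }
    p_va <- nn_infer(model, x_va, params = model$params)$probs
    row <- data.frame(
      epoch = epoch,
      loss = loss_sum / length(tr_idx),
      accuracy = n_correct / length(tr_idx),
      val_loss = cross_entropy(p_va, Y_va),
      val_accuracy = mean(max.col(p_va) == yi[val_idx]))
    hist <- rbind(hist, row)
    if (row$val_loss < best$loss - 1e-6) {
      best <- list(loss = row$val_loss, params = model$params, epoch = epoch)
      patience_left <- cfg$early_stop_patience
    } else {
      patience_left <- patience_left - 1L
      if (patience_left <= 0L) break
    }
  }
  model$params <- best$params
  model$history <- hist
  model$best_epoch <- best$epoch
  model$split <- list(val_idx = val_idx, seed = cfg$seed)
  model$trained <- TRUE
  model
}

#' Predict class probabilities or labels
#'
#' Deterministic inference: dropout is inactive outside training.
#'
#' @param object a trained `asmap_model`.
#' @param x examples as in [train_model()].
#' @param type `"class"` (default) or `"prob"`.
#' @param ... unused.
#' @return character vector of class names, or an `N x n_classes`
#'   probability matrix.
#' @export
predict.asmap_model <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  probs <- nn_infer(object, x)$probs
  colnames(probs) <- object$classes
  if (type == "prob") probs
  else (object$classes %||% as.character(seq_len(object$n_classes)))[max.col(probs)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the flattened CNN feature vectors
#'
#' Runs examples through the convolutional stages up to the flatten layer
#' (inference mode, no dropout) and returns one feature row per example —
#' the automated features the dense head consumes.
#'
#' @param model a CNN `asmap_model` (trained or freshly initialised).
#' @param x `H x W x K x N` array of normalised AsMaps.
#' @return numeric matrix `N x flatten_length`.
#' @export
extract_features <- function(model, x) {
  stopifnot(inherits(model, "asmap_model"))
  if (model$type != "cnn")
    stop("feature extraction is defined for the CNN model")
  nn_infer(model, x, keep_features = TRUE)$features
}

#' Evaluate a trained model on a held-out test set
#'
#' @param model a trained `asmap_model`.
#' @param x,y test examples and labels (must be disjoint from training
#'   windows; the split functions enforce this upstream).
#' @return object of class `eval_report`: `accuracy`, `per_class_recall`,
#'   `confusion` (true x predicted integer matrix), `n_test`.
#' @export
evaluate_model <- function(model, x, y) {
  stopifnot(inherits(model, "asmap_model"))
  if (!model$trained) stop("model has not been trained")
  N <- n_examples(x)
  if (N < 1L) stop("empty test set")
  f <- as_class_factor(y, model$classes)
  pred <- factor(predict(model, x), levels = model$classes)
  confusion <- table(true = f, predicted = pred)
  acc <- sum(diag(confusion)) / N
  recall <- diag(confusion) / pmax(rowSums(confusion), 1L)
  structure(list(accuracy = as.numeric(acc),
                 per_class_recall = as.numeric(recall),
                 confusion = unclass(confusion),
                 n_test = as.integer(N)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.4f on %d test examples\n",
              x$accuracy, x$n_test))
  print(x$confusion)
  invisible(x)
}
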