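#' Model hyperparameter bundles
#'
#' `cnn_spec()` describes the 1D convolutional network: three convolution
#' layers of width-5 filters (ReLU, same-length padding), each followed by a
#' max-pooling layer of size 4 with stride 1, then fully connected layers of
#' 1,025, 512 and 128 units (ReLU, 20% dropout) and a sigmoid (binary) or
#' softmax (multiclass) head. Token input passes through a learned embedding;
#' one-hot input enters as raw `4^k` channels. `lstm_spec()` describes the
#' recurrent model: embedding, an LSTM layer of 128 units (final state), a
#' 64-unit dense layer with ReLU and 50% dropout, and the same head.
#' `rf_spec()` configures the random forest: 300 trees, minimum node size 2
#' for splitting, no bootstrap resampling.
#'
#' @param n_filters Convolution filters per layer (default 64).
#' @param filter_width Convolution kernel width (default 5).
#' @param pool_size,pool_stride Max-pooling window and stride (defaults 4, 1).
#' @param dense_units Integer vector of dense-layer widths, strictly
#'   decreasing (default `c(1025, 512, 128)`).
#' @param dropout Dropout rate in (0, 1) applied after each dense layer.
#' @param embedding_dim Embedding dimension for token input (default 32).
#' @return A spec object of the matching class.
#' @export
cnn_spec <- function(n_filters = 64, filter_width = 5, pool_size = 4,
                     pool_stride = 1, dense_units = c(1025, 512, 128),
                     dropout = 0.20, embedding_dim = 32) {
  stopifnot(n_filters >= 1, filter_width >= 1, pool_size >= 1,
            pool_stride >= 1, embedding_dim >= 1,
            dropout > 0, dropout < 1)
  if (any(diff(dense_units) >= 0))
    stop("dense_units must be strictly decreasing")
  structure(list(n_filters = as.integer(n_filters),
                 filter_width = as.integer(filter_width),
                 pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride),
                 dense_units = as.integer(dense_units),
                 dropout = dropout,
                 embedding_dim = as.integer(embedding_dim)),
            class = "cnn_spec")
}

#' @rdname cnn_spec
#' @param lstm_units Units in the LSTM layer (default 128).
#' @export
lstm_spec <- function(lstm_units = 128, dense_units = 64, dropout = 0.50,
                      embedding_dim = 32) {
  stopifnot(lstm_units >= 1, length(dense_units) == 1, dense_units >= 1,
            dropout > 0, dropout < 1, embedding_dim >= 1)
  structure(list(lstm_units = as.integer(lstm_units),
                 dense_units = as.integer(dense_units),
                 dropout = dropout,
                 embedding_dim = as.integer(embedding_dim)),
            class = "lstm_spec")
}

#' @rdname cnn_spec
#' @param n_trees Number of trees (default 300).
#' @param min_samples_split Minimum number of samples a node must hold to be
#'   split (default 2, i.e. trees are grown to purity where possible).
#' @param bootstrap Whether trees see bootstrap resamples (default `FALSE`:
#'   every tree is grown on the full training set).
#' @export
rf_spec <- function(n_trees = 300, min_samples_split = 2, bootstrap = FALSE) {
  stopifnot(n_trees >= 1, min_samples_split >= 2, is.logical(bootstrap))
  structure(list(n_trees = as.integer(n_trees),
                 min_samples_split = as.integer(min_samples_split),
                 bootstrap = bootstrap),
            class = "rf_spec")
}

#' Shared training configuration
#'
#' Defaults follow the package's standard regime: 10 epochs, batch size 128,
#' Adam with step size 0.001, early stopping on validation loss with
#' patience 2 (the best-validation weights are restored). The loss is binary
#' cross-entropy for two classes and sparse categorical cross-entropy
#' otherwise; the choice is forced by the task arity. The random forest
#' ignores the epoch settings.
#'
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param patience Early-stopping patience in epochs.
#' @param early_stopping Monitor validation loss and stop early?
#' @param seed Integer seed covering weight init, batch order and dropout.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 10, batch_size = 128, learning_rate = 0.001,
                         patience = 2, early_stopping = TRUE, seed = 1) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0, patience >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience),
                 early_stopping = isTRUE(early_stopping),
                 seed = as.integer(seed)),
            class = "train_config")
}

cpp_spec_cnn <- function(spec, vocab_size, n_positions, n_classes, encoder) {
  list(onehot = identical(encoder, "onehot"),
       vocab_size = as.integer(vocab_size),
       n_positions = as.integer(n_positions),
       n_classes = as.integer(n_classes),
       n_filters = spec$n_filters, filter_width = spec$filter_width,
       pool_size = spec$pool_size, pool_stride = spec$pool_stride,
       dense_units = spec$dense_units, dropout = spec$dropout,
       embedding_dim = spec$embedding_dim)
}

cpp_spec_lstm <- function(spec, vocab_size, n_positions, n_classes, encoder) {
  list(onehot = identical(encoder, "onehot"),
       vocab_size = as.integer(vocab_size),
       n_positions = as.integer(n_positions),
       n_classes = as.integer(n_classes),
       lstm_units = spec$lstm_units, dense_units = spec$dense_units,
       dropout = spec$dropout, embedding_dim = spec$embedding_dim)
}

new_promoter_model <- function(kind, spec, cpp_spec = NULL, weights = NULL,
                               n_classes = 2, encoder = "fbt",
                               n_positions = NA_integer_, seed = 1L) {
  structure(list(kind = kind, spec = spec, cpp_spec = cpp_spec,
                 weights = weights, fit = NULL, n_classes = n_classes,
                 encoder = encoder, n_positions = n_positions,
                 seed = as.integer(seed), trained = FALSE, contract = NULL,
                 vocab = NULL, history = NULL, epochs_run = 0L,
                 wall_time = NA_real_),
            class = "promoter_model")
}

#' Build an untrained classifier
#'
#' Constructs (and for the networks, initialises) a model for encoded input
#' with `n_positions` token positions and a vocabulary of `vocab_size`
#' k-mers. Binary tasks (`n_classes = 2`) get a single sigmoid output unit;
#' multiclass tasks get `n_classes` softmax units.
#'
#' @param spec A [cnn_spec()], [lstm_spec()] or [rf_spec()].
#' @param vocab_size Vocabulary size V (tokens are in `[0, V]`; for one-hot
#'   input use `4^k`).
#' @param n_positions Number of token positions, `L - k + 1`.
#' @param n_classes Number of classes (>= 2).
#' @param encoder `"fbt"` (embedding lookup) or `"onehot"` (raw channels).
#' @param seed Seed for weight initialisation.
#' @return An untrained `promoter_model`.
#' @export
build_cnn <- function(spec = cnn_spec(), vocab_size, n_positions,
                      n_classes = 2, encoder = c("fbt", "onehot"), seed = 1) {
  encoder <- match.arg(encoder)
  stopifnot(inherits(spec, "cnn_spec"), n_classes >= 2)
  if (n_positions < spec$filter_width)
    stop("n_positions (", n_positions, ") < filter width (", spec$filter_width, ")")
  cs <- cpp_spec_cnn(spec, vocab_size, n_positions, n_classes, encoder)
  w <- cpp_cnn_init(cs, as.integer(seed))
  new_promoter_model("cnn", spec, cs, w, n_classes, encoder, n_positions, seed)
}

#' @rdname build_cnn
#' @export
build_lstm <- function(spec = lstm_spec(), vocab_size, n_positions,
                       n_classes = 2, encoder = c("fbt", "onehot"), seed = 1) {
  encoder <- match.arg(encoder)
  stopifnot(inherits(spec, "lstm_spec"), n_classes >= 2)
  if (n_positions < 1) stop("n_positions must be >= 1")
  cs <- cpp_spec_lstm(spec, vocab_size, n_positions, n_classes, encoder)
  w <- cpp_lstm_init(cs, as.integer(seed))
  new_promoter_model("lstm", spec, cs, w, n_classes, encoder, n_positions, seed)
}

#' @rdname build_cnn
#' @export
build_rf <- function(spec = rf_spec(), seed = 1, n_classes = 2) {
  stopifnot(inherits(spec, "rf_spec"))
  new_promoter_model("rf", spec, n_classes = n_classes, encoder = "fbt",
                     seed = seed)
}

#' Number of trainable parameters
#'
#' @param model A `promoter_model`.
#' @return Integer count (for the networks), or `NA` for the random forest.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "promoter_model"))
  if (model$kind == "rf") return(NA_integer_)
  sum(vapply(model$weights, length, integer(1)))
}

as_token_matrix <- function(x) {
  if (inherits(x, "encoded_promoters")) x$tokens else {
    stopifnot(is.matrix(x))
    x
  }
}

check_contract <- function(model, x) {
  if (!inherits(x, "encoded_promoters")) {
    if (ncol(x) != model$n_positions)
      stop("input has ", ncol(x), " positions but the model expects ",
           model$n_positions)
    return(invisible())
  }
  if (ncol(x$tokens) != model$n_positions)
    stop("input has ", ncol(x$tokens), " positions but the model expects ",
         model$n_positions)
  ct <- model$contract
  if (is.null(ct)) return(invisible())
  if (!identical(x$encoder, ct$encoder))
    stop("encoder mismatch: model trained on '", ct$encoder,
         "', input encoded with '", x$encoder, "'")
  if (!identical(x$k, ct$k))
    stop("k mismatch: model trained with k=", ct$k, ", input has k=", x$k)
  if (!identical(x$vocab_hash, ct$vocab_hash))
    stop("vocabulary mismatch: input was encoded with a different vocabulary",
         " than the model was trained on")
  invisible()
}

#' Train a classifier on encoded sequences
#'
#' Neural models run up to `config$epochs` epochs of minibatch Adam with the
#' configured batch size, stopping early when validation loss stops improving
#' (the best weights are kept); the random forest is fitted in one pass and
#' ignores the epoch settings. All randomness is governed by `config$seed`.
#' The fitted model records its input contract (encoder, k, positions,
#' vocabulary hash) and refuses mismatching inputs at prediction time.
#'
#' @param model An untrained model from [build_cnn()], [build_lstm()] or
#'   [build_rf()].
#' @param x An `encoded_promoters` object (training split).
#' @param y Integer labels in `[0, n_classes)`; defaults to `x$labels`.
#' @param val_x,val_y Validation data, required when early stopping is on
#'   (networks only). Must be disjoint from the training data.
#' @param config A [train_config()].
#' @return The trained `promoter_model` with `history` and `epochs_run`.
#' @export
train_model <- function(model, x, y = NULL, val_x = NULL, val_y = NULL,
                        config = train_config()) {
  stopifnot(inherits(model, "promoter_model"), inherits(config, "train_config"))
  tok <- as_token_matrix(x)
  y <- y %||% (if (inherits(x, "encoded_promoters")) x$labels else NULL)
  if (is.null(y)) stop("labels y are required")
  y <- as.integer(y)
  if (length(y) != nrow(tok)) stop("length(y) != number of sequences")
  if (anyNA(y) || any(y < 0) || any(y >= model$n_classes))
    stop("labels must be integers in [0, ", model$n_classes, ")")
  if (inherits(x, "encoded_promoters") && inherits(val_x, "encoded_promoters")) {
    shared <- intersect(x$ids, val_x$ids)
    if (length(shared))
      stop("training and validation sets overlap (e.g. ", shared[1], ")")
  }
  t0 <- proc.time()[["elapsed"]]
  if (model$kind == "rf") {
    df <- as.data.frame(tok)
    fit <- ranger::ranger(
      y = factor(y, levels = 0:(model$n_classes - 1)), x = df,
      num.trees = model$spec$n_trees,
      # ranger's min.node.size bounds terminal-node size; a split threshold of
      # min_samples_split corresponds to terminal nodes of half that size
      min.node.size = max(1L, model$spec$min_samples_split %/% 2L),
      replace = model$spec$bootstrap,
      sample.fraction = 1,
      probability = TRUE,
      seed = config$seed, num.threads = 1)
    model$fit <- fit
    model$n_positions <- ncol(tok)
  } else {
    if (config$early_stopping && is.null(val_x))
      stop("early stopping requires a validation set")
    vt <- NULL; vy <- NULL
    if (!is.null(val_x)) {
      vt <- as_token_matrix(val_x)
      vy <- as.integer(val_y %||%
        (if (inherits(val_x, "encoded_promoters")) val_x$labels else NULL))
      if (is.null(vy) || length(vy) == 0) stop("validation labels missing")
    }
    trainer <- if (model$kind == "cnn") cpp_cnn_train else cpp_lstm_train
    res <- trainer(tok, y, vt, vy, model$weights, model$cpp_spec,
                   list(epochs = config$epochs, batch_size = config$batch_size,
                        lr = config$learning_rate, patience = config$patience,
                        early_stopping = config$early_stopping),
                   config$seed)
    model$weights <- res$weights
    model$history <- res$history
    model$epochs_run <- res$epochs_run
    if (length(model$history$loss) && !all(is.finite(model$history$loss)))
      warning("non-finite training loss encountered")
  }
  model$wall_time <- proc.time()[["elapsed"]] - t0
  model$trained <- TRUE
  if (inherits(x, "encoded_promoters")) {
    model$contract <- list(encoder = x$encoder, k = x$k,
                           n_positions = ncol(tok),
                           vocab_hash = x$vocab_hash,
                           n_classes = model$n_classes)
    model$vocab <- x$vocab
  }
  model
}

#' Predict class probabilities and hard labels
#'
#' Binary models return the promoter probability and the label
#' `as.integer(prob >= 0.5)` (ties at exactly 0.5 are called positive).
#' Multiclass models return one probability column per class and the argmax
#' label, ties broken toward the smaller class index. Inputs that do not
#' match the model's recorded contract (encoder, k, positions, vocabulary)
#' are refused.
#'
#' @param object A `promoter_model`.
#' @param x An `encoded_promoters` object or integer token matrix.
#' @param ... Unused.
#' @return A tibble with probability columns and `.pred`.
#' @export
predict.promoter_model <- function(object, x, ...) {
  check_contract(object, x)
  tok <- as_token_matrix(x)
  if (object$kind == "rf") {
    if (is.null(object$fit)) stop("random forest is not trained yet")
    probs <- predict(object$fit, data = as.data.frame(tok),
                     num.threads = 1)$predictions
    probs <- probs[, as.character(0:(object$n_classes - 1)), drop = FALSE]
  } else {
    predictor <- if (object$kind == "cnn") cpp_cnn_predict else cpp_lstm_predict
    probs <- predictor(tok, object$weights, object$cpp_spec)
  }
  if (object$n_classes == 2) {
    p1 <- if (ncol(probs) == 1) probs[, 1] else probs[, 2]
    tibble::tibble(.prob_1 = p1, .pred = as.integer(p1 >= 0.5))
  } else {
    colnames(probs) <- paste0(".prob_", 0:(object$n_classes - 1))
    out <- tibble::as_tibble(probs)
    out$.pred <- as.integer(max.col(probs, ties.method = "first") - 1L)
    out
  }
}

#' @export
print.promoter_model <- function(x, ...) {
  cat(sprintf("<promoter_model> %s (%s input), %d classes, %s\n",
              toupper(x$kind), x$encoder, x$n_classes,
              if (x$trained) sprintf("trained (%d epochs)", x$epochs_run)
              else "untrained"))
  if (x$kind != "rf")
    cat(sprintf("  %s parameters\n", format(n_params(x), big.mark = ",")))
  invisible(x)
}
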