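#' Stratified train / validation / test split
#'
#' Draws a 10% test split, then 10% of the remaining 90% as validation
#' (9% overall), stratified by class so each part matches the global class
#' proportions to within one sample per class. Deterministic under `seed`.
#'
#' @param labels Vector of class labels (one per sample).
#' @param test_frac Test fraction of the full data (default 0.10).
#' @param val_frac_of_train Validation fraction of the non-test data
#'   (default 0.10).
#' @param seed Integer seed.
#' @return A `split_indices` object with disjoint integer index vectors
#'   `train`, `validation`, `test` whose union covers all samples.
#' @examples
#' s <- stratified_split(rep(0:1, each = 500), seed = 1)
#' lengths(unclass(s))
#' @export
stratified_split <- function(labels, test_frac = 0.10,
                             val_frac_of_train = 0.10, seed = 1) {
  stopifnot(test_frac > 0, test_frac < 1,
            val_frac_of_train > 0, val_frac_of_train < 1)
  classes <- sort(unique(labels))
  parts <- withr::with_seed(seed, {
    lapply(classes, function(cl) {
      idx <- which(labels == cl)
      n_test <- round(test_frac * length(idx))
      n_val <- round(val_frac_of_train * (length(idx) - n_test))
      if (n_test < 1 || n_val < 1 || length(idx) - n_test - n_val < 1)
        stop("class '", cl, "' is too small (", length(idx),
             " samples) to appear in every part")
      test <- sample(idx, n_test)
      rem <- setdiff(idx, test)
      val <- sample(rem, n_val)
      list(test = test, validation = val, train = setdiff(rem, val))
    })
  })
  out <- list(
    train = sort(unlist(lapply(parts, `[[`, "train"))),
    validation = sort(unlist(lapply(parts, `[[`, "validation"))),
    test = sort(unlist(lapply(parts, `[[`, "test"))))
  structure(out, class = "split_indices")
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("<split_indices> train=%d, validation=%d, test=%d\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

assert_disjoint_split <- function(split) {
  if (length(intersect(split$train, split$validation)) ||
      length(intersect(split$train, split$test)) ||
      length(intersect(split$validation, split$test)))
    stop("internal error: train/validation/test indices overlap")
  invisible(split)
}

#' Binary confusion counts
#'
#' Cross-tabulates true against predicted binary labels with 1 = promoter =
#' positive.
#'
#' @param y_true,y_pred Equal-length vectors of 0/1 labels.
#' @return A `confusion_counts` object with fields TP, TN, FP, FN.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (!all(c(y_true, y_pred) %in% c(0, 1))) stop("labels must be 0 or 1")
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 TN = sum(y_true == 0 & y_pred == 0),
                 FP = sum(y_true == 0 & y_pred == 1),
                 FN = sum(y_true == 1 & y_pred == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Accuracy, sensitivity, specificity and MCC from confusion counts
#'
#' Evaluates
#' \deqn{Acc = (TP+TN)/(TP+TN+FP+FN), \quad Sn = TP/(TP+FN), \quad
#'       Sp = TN/(TN+FP)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'       \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}.}
#' If any factor of the MCC denominator is zero the MCC is reported as 0
#' (conventional); an undefined sensitivity or specificity (empty class) is
#' reported as `NA`, not 0.
#'
#' @param counts A [confusion()] object (or list with TP/TN/FP/FN).
#' @return A one-row tibble with columns Acc, Sn, Sp, MCC, TP, TN, FP, FN.
#' @examples
#' compute_metrics(confusion(c(1, 1, 0, 0), c(1, 0, 1, 0)))
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts$TP); tn <- as.numeric(counts$TN)
  fp <- as.numeric(counts$FP); fn <- as.numeric(counts$FN)
  total <- tp + tn + fp + fn
  if (total == 0) stop("no samples to evaluate")
  acc <- (tp + tn) / total
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  tibble::tibble(Acc = acc, Sn = sn, Sp = sp, MCC = mcc,
                 TP = counts$TP, TN = counts$TN, FP = counts$FP,
                 FN = counts$FN)
}

#' Multiclass metrics
#'
#' Overall accuracy; unweighted macro-averaged one-vs-rest recall (Sn) and
#' specificity (Sp); and the multi-category MCC generalisation computed from
#' the full confusion matrix,
#' \deqn{MCC = (N \, \mathrm{tr}(C) - \sum_k t_k p_k) /
#'       \sqrt{(N^2 - \sum_k p_k^2)(N^2 - \sum_k t_k^2)}}
#' where `t` and `p` are the true and predicted class totals.
#'
#' @param y_true,y_pred Integer labels in `[0, n_classes)`.
#' @param n_classes Number of classes.
#' @return A one-row tibble with Acc, Sn, Sp, MCC.
#' @export
multiclass_metrics <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  labs <- 0:(n_classes - 1)
  if (!all(c(y_true, y_pred) %in% labs))
    stop("labels must be integers in [0, ", n_classes, ")")
  n <- length(y_true)
  cm <- table(factor(y_true, levels = labs), factor(y_pred, levels = labs))
  cm <- matrix(as.numeric(cm), n_classes, n_classes)
  acc <- sum(diag(cm)) / n
  t_k <- rowSums(cm)  # true class totals
  p_k <- colSums(cm)  # predicted class totals
  recall <- ifelse(t_k > 0, diag(cm) / t_k, NA_real_)
  spec <- vapply(seq_len(n_classes), function(kk) {
    tn <- n - t_k[kk] - p_k[kk] + cm[kk, kk]
    fp <- p_k[kk] - cm[kk, kk]
    if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }, numeric(1))
  num <- n * sum(diag(cm)) - sum(t_k * p_k)
  den <- sqrt(n^2 - sum(p_k^2)) * sqrt(n^2 - sum(t_k^2))
  mcc <- if (den > 0) num / den else 0
  tibble::tibble(Acc = acc, Sn = mean(recall, na.rm = TRUE),
                 Sp = mean(spec, na.rm = TRUE), MCC = mcc)
}

# ---------------------------------------------------------------------------
# experiment runners

build_model_by_kind <- function(kind, encoder, enc, n_classes, seed,
                                model_spec = NULL) {
  switch(kind,
    cnn = build_cnn(model_spec %||% cnn_spec(), vocab_size = enc$vocab_size,
                    n_positions = ncol(enc$tokens), n_classes = n_classes,
                    encoder = encoder, seed = seed),
    lstm = build_lstm(model_spec %||% lstm_spec(), vocab_size = enc$vocab_size,
                      n_positions = ncol(enc$tokens), n_classes = n_classes,
                      encoder = encoder, seed = seed),
    rf = build_rf(model_spec %||% rf_spec(), seed = seed,
                  n_classes = n_classes),
    stop("unknown model kind: ", kind))
}

# encode + split + train + score held-out test split; shared by the runners
fit_pipeline <- function(records, model_kind, encoder, k, seed, config,
                         model_spec = NULL, n_classes = 2,
                         metric_fun = NULL) {
  records <- check_records(records, require_acgt = TRUE)
  split <- stratified_split(records$label, seed = seed)
  assert_disjoint_split(split)
  vocab <- if (encoder == "fbt")
    fit_vocabulary(records$bases[split$train], k) else NULL
  enc <- encode_sequences(records, k, encoder = encoder, vocab = vocab)
  config$seed <- seed
  model <- build_model_by_kind(model_kind, encoder, enc, n_classes, seed,
                               model_spec)
  t0 <- proc.time()[["elapsed"]]
  model <- train_model(model, enc[split$train],
                       val_x = enc[split$validation], config = config)
  pred <- predict(model, enc[split$test])
  truth <- enc$labels[split$test]
  metrics <- if (n_classes == 2)
    compute_metrics(confusion(truth, pred$.pred))[, c("Acc", "Sn", "Sp", "MCC")]
  else multiclass_metrics(truth, pred$.pred, n_classes)
  list(model = model, split = split, vocab = vocab, enc = enc,
       metrics = metrics, wall_time = proc.time()[["elapsed"]] - t0)
}

results_row <- function(experiment, species_train, species_test, setting,
                        model, encoder, k, seed, metrics, n_train, n_test,
                        wall_time) {
  out <- dplyr::bind_cols(
    tibble::tibble(experiment = experiment, species_train = species_train,
                   species_test = species_test, setting = setting,
                   model = model, encoder = encoder, k = k, seed = seed),
    metrics,
    tibble::tibble(n_train = n_train, n_test = n_test, wall_time = wall_time))
  class(out) <- c("promoter_results", class(out))
  out
}

#' Binary promoter vs non-promoter experiment
#'
#' Runs the full binary pipeline on one labelled dataset: stratified
#' 81/9/10 split, vocabulary fitted on the training split, model training
#' with validation-based early stopping, and evaluation on the held-out test
#' split.
#'
#' @param records A balanced, cleaned tibble with labels 0/1.
#' @param model `"cnn"`, `"lstm"` or `"rf"`.
#' @param encoder `"fbt"` or `"onehot"`.
#' @param k k-mer size.
#' @param seed Integer seed for the split, the vocabulary-independent model
#'   initialisation and training.
#' @param config A [train_config()].
#' @param model_spec Optional spec overriding the defaults.
#' @return A one-row `promoter_results` tibble (Acc/Sn/Sp/MCC, sizes, wall
#'   time); the fitted model, split and vocabulary are attached as
#'   attributes `model`, `split`, `vocab`.
#' @export
run_binary_experiment <- function(records, model = c("cnn", "lstm", "rf"),
                                  encoder = c("fbt", "onehot"), k = 2,
                                  seed = 1, config = train_config(),
                                  model_spec = NULL) {
  model <- match.arg(model)
  encoder <- match.arg(encoder)
  if (!setequal(unique(records$label), c(0L, 1L)))
    stop("records must carry binary labels 0/1")
  sp <- unique(records$species[!is.na(records$species)])
  sp <- if (length(sp) == 1) sp else NA_character_
  fit <- fit_pipeline(records, model, encoder, k, seed, config)
  row <- results_row("binary", sp, sp, "within", model, encoder, k, seed,
                     fit$metrics, length(fit$split$train),
                     length(fit$split$test), fit$wall_time)
  attr(row, "model") <- fit$model
  attr(row, "split") <- fit$split
  attr(row, "vocab") <- fit$vocab
  row
}

#' Cross-species transfer experiment
#'
#' Trains one binary model per species on that species' training split and
#' evaluates it (a) on its own held-out test split (`setting = "within"`)
#' and (b) on every other species' full dataset encoded with the training
#' species' vocabulary (`setting = "cross"`). Transfer that is much worse
#' than the within-species baseline indicates species-specific promoter
#' structure.
#'
#' @param datasets Named list (>= 2 species) of balanced labelled record
#'   tibbles with equal sequence lengths.
#' @inheritParams run_binary_experiment
#' @return A `cross_species_results` tibble with one row per (train, test)
#'   pair; the per-species fitted models are attached as attribute `models`.
#' @export
run_cross_species <- function(datasets, model = c("cnn", "rf", "lstm"),
                              encoder = c("fbt", "onehot"), k = 2, seed = 1,
                              config = train_config(), model_spec = NULL) {
  model <- match.arg(model)
  encoder <- match.arg(encoder)
  if (length(datasets) < 2 || is.null(names(datasets)) ||
      anyDuplicated(names(datasets)))
    stop("datasets must be a named list of >= 2 distinct species")
  lens <- unique(unlist(lapply(datasets, function(d) nchar(d$bases))))
  if (length(lens) != 1)
    stop("all species datasets must share one sequence length")
  rows <- list()
  models <- list()
  for (sp in names(datasets)) {
    fit <- fit_pipeline(datasets[[sp]], model, encoder, k, seed, config,
                        model_spec)
    models[[sp]] <- fit$model
    rows[[length(rows) + 1]] <- results_row(
      "cross_species", sp, sp, "within", model, encoder, k, seed,
      fit$metrics, length(fit$split$train), length(fit$split$test),
      fit$wall_time)
    for (sp2 in setdiff(names(datasets), sp)) {
      enc2 <- encode_sequences(datasets[[sp2]], k, encoder = encoder,
                               vocab = fit$vocab)
      pred <- predict(fit$model, enc2)
      m <- compute_metrics(confusion(enc2$labels, pred$.pred))
      rows[[length(rows) + 1]] <- results_row(
        "cross_species", sp, sp2, "cross", model, encoder, k, seed,
        m[, c("Acc", "Sn", "Sp", "MCC")], length(fit$split$train),
        nrow(datasets[[sp2]]), NA_real_)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cross_species_results", "promoter_results", class(tibble::tibble()))
  attr(out, "models") <- models
  out
}

#' Test a trained binary model against random genomic background
#'
#' Scores held-out promoters (label 1) against never-seen random background
#' windows (label 0), e.g. from [sample_random_subsequences()], using the
#' model's own vocabulary and contract.
#'
#' @param model A trained binary `promoter_model`.
#' @param test_promoters Records of held-out promoters.
#' @param random_background Records of background windows (non-empty, same
#'   length as the promoters).
#' @return A one-row `promoter_results` tibble.
#' @export
run_random_negative_test <- function(model, test_promoters, random_background) {
  stopifnot(inherits(model, "promoter_model"))
  if (!model$trained) stop("model must be trained")
  if (model$n_classes != 2) stop("random-negative test is binary only")
  if (nrow(random_background) == 0) stop("empty background set")
  test_promoters <- check_records(test_promoters, require_acgt = TRUE)
  random_background <- check_records(random_background, require_acgt = TRUE)
  recs <- dplyr::bind_rows(
    dplyr::mutate(test_promoters, label = 1L),
    dplyr::mutate(random_background, label = 0L))
  expected_len <- model$contract$n_positions + model$contract$k - 1L
  if (any(nchar(recs$bases) != expected_len))
    stop("sequence length does not match the model contract (expected ",
         expected_len, " nt)")
  enc <- encode_sequences(recs, model$contract$k,
                          encoder = model$contract$encoder,
                          vocab = model$vocab)
  pred <- predict(model, enc)
  m <- compute_metrics(confusion(enc$labels, pred$.pred))
  results_row("random_negative", NA_character_, NA_character_, "background",
              model$kind, model$contract$encoder, model$contract$k,
              model$seed, m[, c("Acc", "Sn", "Sp", "MCC")],
              NA_integer_, nrow(recs), NA_real_)
}

#' Multiclass species-of-origin experiment
#'
#' Pools the promoter corpora of several species (labels = 0-based species
#' indices, no negatives), splits stratified, trains a model with a softmax
#' head and evaluates with [multiclass_metrics()] on the held-out test split.
#'
#' @param promoter_corpora Named list (>= 2) of promoter record tibbles.
#' @inheritParams run_binary_experiment
#' @return A one-row `promoter_results` tibble; fitted model in attribute
#'   `model`.
#' @export
run_multiclass_experiment <- function(promoter_corpora,
                                      model = c("cnn", "lstm", "rf"),
                                      encoder = c("fbt", "onehot"), k = 2,
                                      seed = 1, config = train_config(),
                                      model_spec = NULL) {
  model <- match.arg(model)
  encoder <- match.arg(encoder)
  if (length(promoter_corpora) < 2 || is.null(names(promoter_corpora)))
    stop("promoter_corpora must be a named list of >= 2 species")
  species <- names(promoter_corpora)
  pooled <- dplyr::bind_rows(lapply(seq_along(species), function(i) {
    d <- check_records(promoter_corpora[[i]], require_acgt = TRUE)
    d$label <- i - 1L
    d$species <- species[i]
    d
  }))
  fit <- fit_pipeline(pooled, model, encoder, k, seed, config, model_spec,
                      n_classes = length(species))
  row <- results_row("multiclass", paste(species, collapse = "+"),
                     paste(species, collapse = "+"), "within", model, encoder,
                     k, seed, fit$metrics, length(fit$split$train),
                     length(fit$split$test), fit$wall_time)
  attr(row, "model") <- fit$model
  attr(row, "split") <- fit$split
  attr(row, "vocab") <- fit$vocab
  row
}
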