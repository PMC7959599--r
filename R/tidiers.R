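#' Tidy a trained model's training history
#'
#' @param x A `promoter_model`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `epoch`, `loss`, `val_loss`,
#'   `val_acc` (the random forest has no history and returns zero rows).
#' @export
tidy.promoter_model <- function(x, ...) {
  h <- x$history
  if (is.null(h) || length(h$loss) == 0)
    return(tibble::tibble(epoch = integer(), loss = numeric(),
                          val_loss = numeric(), val_acc = numeric()))
  n <- length(h$loss)
  pad <- function(v) c(v, rep(NA_real_, n - length(v)))
  tibble::tibble(epoch = seq_len(n), loss = as.numeric(h$loss),
                 val_loss = pad(as.numeric(h$val_loss)),
                 val_acc = pad(as.numeric(h$val_acc)))
}

#' One-row summary of a model
#'
#' @param x A `promoter_model`.
#' @param ... Unused.
#' @return A one-row tibble: kind, encoder, classes, positions, parameter
#'   count, epochs run, best validation loss, wall time.
#' @export
glance.promoter_model <- function(x, ...) {
  h <- tidy(x)
  tibble::tibble(
    kind = x$kind, encoder = x$encoder, n_classes = x$n_classes,
    n_positions = x$n_positions, n_params = n_params(x),
    trained = x$trained, epochs_run = x$epochs_run,
    best_val_loss = if (nrow(h) && !all(is.na(h$val_loss)))
      min(h$val_loss, na.rm = TRUE) else NA_real_,
    wall_time = x$wall_time)
}
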