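# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: double precision, plain loops.

random_acgt <- function(n, length, seed = 1) {
  withr::with_seed(seed, vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1)))
}

base_counts <- function(s) {
  table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
}

dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  di <- paste0(ch[-length(ch)], ch[-1])
  lv <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  table(factor(di, levels = lv))
}

# brute-force metric recount straight from label vectors
brute_metrics <- function(y_true, y_pred) {
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  c(Acc = (tp + tn) / length(y_true),
    Sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    Sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    MCC = if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0)
}

# double-precision reference forward pass for the CNN, mirroring the layer
# stack: used to validate the compiled analytic gradients by central
# differences at 1e-5 (float32 fd on the compiled path is too noisy)
ref_cnn_forward <- function(toks, y, w, spec) {
  B <- nrow(toks); P <- spec$n_positions
  nf <- spec$n_filters; Wf <- spec$filter_width
  S <- spec$pool_size; Tst <- spec$pool_stride
  d <- if (spec$onehot) spec$vocab_size else spec$embedding_dim
  nout <- if (spec$n_classes == 2) 1 else spec$n_classes
  pad <- (Wf - 1) / 2
  loss <- 0
  for (b in seq_len(B)) {
    X <- matrix(0, d, P)
    for (p in seq_len(P)) {
      t <- toks[b, p]
      if (spec$onehot) { if (t > 0) X[t, p] <- 1 } else X[, p] <- w$Wemb[, t + 1]
    }
    A <- X
    Cin <- d
    for (l in 1:3) {
      Wc <- w[[paste0("Wc", l)]]; bc <- w[[paste0("bc", l)]]
      Pl <- ncol(A)
      col <- matrix(0, Cin * Wf, Pl)
      for (p in seq_len(Pl)) for (o in seq_len(Wf)) {
        src <- p + (o - 1) - pad
        if (src >= 1 && src <= Pl)
          col[((o - 1) * Cin + 1):(o * Cin), p] <- A[, src]
      }
      Z <- Wc %*% col + matrix(bc, nf, Pl)
      Z[Z < 0] <- 0
      Q <- (Pl - S) %/% Tst + 1
      Pool <- matrix(0, nf, Q)
      for (q in seq_len(Q))
        Pool[, q] <- apply(Z[, ((q - 1) * Tst + 1):((q - 1) * Tst + S),
                             drop = FALSE], 1, max)
      A <- Pool
      Cin <- nf
    }
    h <- as.vector(A)
    for (l in seq_along(spec$dense_units)) {
      h <- as.vector(w[[paste0("Wd", l)]] %*% h + w[[paste0("bd", l)]])
      h[h < 0] <- 0
    }
    z <- as.vector(w$Wo %*% h + w$bo)
    if (nout == 1) {
      pr <- 1 / (1 + exp(-z))
      pr <- min(max(pr, 1e-7), 1 - 1e-7)
      loss <- loss - (if (y[b] == 1) log(pr) else log(1 - pr))
    } else {
      e <- exp(z - max(z)); pr <- e / sum(e)
      loss <- loss - log(max(pr[y[b] + 1], 1e-7))
    }
  }
  loss / B
}

# reference LSTM forward, same conventions
ref_lstm_forward <- function(toks, y, w, spec) {
  B <- nrow(toks); P <- spec$n_positions; H <- spec$lstm_units
  d <- if (spec$onehot) spec$vocab_size else spec$embedding_dim
  nout <- if (spec$n_classes == 2) 1 else spec$n_classes
  sig <- function(z) 1 / (1 + exp(-z))
  loss <- 0
  for (b in seq_len(B)) {
    h <- rep(0, H); cc <- rep(0, H)
    for (t in seq_len(P)) {
      tok <- toks[b, t]
      x <- if (spec$onehot) {
        v <- rep(0, d); if (tok > 0) v[tok] <- 1; v
      } else w$Wemb[, tok + 1]
      g <- as.vector(w$Wx %*% x + w$Wh %*% h + w$b)
      i <- sig(g[1:H]); f <- sig(g[(H + 1):(2 * H)])
      gg <- tanh(g[(2 * H + 1):(3 * H)]); o <- sig(g[(3 * H + 1):(4 * H)])
      cc <- f * cc + i * gg
      h <- o * tanh(cc)
    }
    a <- as.vector(w$Wd %*% h + w$bd); a[a < 0] <- 0
    z <- as.vector(w$Wo %*% a + w$bo)
    if (nout == 1) {
      pr <- 1 / (1 + exp(-z)); pr <- min(max(pr, 1e-7), 1 - 1e-7)
      loss <- loss - (if (y[b] == 1) log(pr) else log(1 - pr))
    } else {
      e <- exp(z - max(z)); pr <- e / sum(e)
      loss <- loss - log(max(pr[y[b] + 1], 1e-7))
    }
  }
  loss / B
}

# compare compiled analytic gradients against central differences on the
# double-precision reference; returns the worst relative error among
# gradients large enough to measure
grad_check <- function(kind, n_classes, encoder = "fbt", seed = 42) {
  withr::with_seed(seed, {
    n <- 6; P <- 10; V <- 5
    toks <- matrix(sample(0:V, n * P, TRUE), n, P)
    if (encoder == "onehot") toks[toks == 0] <- 1L
    y <- sample(0:(n_classes - 1), n, TRUE)
    if (kind == "cnn") {
      spec <- list(onehot = (encoder == "onehot"), vocab_size = 5L,
                   n_positions = as.integer(P),
                   n_classes = as.integer(n_classes), n_filters = 3L,
                   filter_width = 5L, pool_size = 4L, pool_stride = 1L,
                   dense_units = c(7L, 4L), dropout = 0.2,
                   embedding_dim = 4L)
      w <- promokit:::cpp_cnn_init(spec, 1L)
      cg <- promokit:::cpp_cnn_loss_grad(toks, y, w, spec)
      fwd <- ref_cnn_forward
    } else {
      spec <- list(onehot = (encoder == "onehot"), vocab_size = 5L,
                   n_positions = as.integer(P),
                   n_classes = as.integer(n_classes), lstm_units = 6L,
                   dense_units = 5L, dropout = 0.5, embedding_dim = 4L)
      w <- promokit:::cpp_lstm_init(spec, 1L)
      cg <- promokit:::cpp_lstm_loss_grad(toks, y, w, spec)
      fwd <- ref_lstm_forward
    }
    loss_diff <- abs(cg$loss - fwd(toks, y, w, spec))
    worst <- 0
    for (nm in names(w)) {
      idx <- sample(length(w[[nm]]), min(5, length(w[[nm]])))
      for (i in idx) {
        eps <- 1e-5
        wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
        wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
        num <- (fwd(toks, y, wp, spec) - fwd(toks, y, wm, spec)) / (2 * eps)
        ana <- cg$grads[[nm]][i]
        if (abs(num) + abs(ana) > 1e-4)
          worst <- max(worst, abs(num - ana) / (abs(num) + abs(ana)))
      }
    }
    list(loss_diff = loss_diff, worst_rel_err = worst)
  })
}

# small motif task every model can learn quickly
toy_binary_dataset <- function(n = 200, length = 60, seed = 3) {
  pf <- species_profile("toy", length,
                        motifs = list(list(pattern = "TATATAAA", offset = 20,
                                           mutation_rate = 0.1)),
                        background_gc = 0.5)
  build_binary_dataset(generate_promoters(pf, n, seed = seed), seed = seed + 1)
}
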