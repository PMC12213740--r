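# Independent brute-force oracles used to pin the matrix implementations.
# All are deliberately written as scalar loops, sharing no code with the
# package internals.

# scaled dot-product attention by triple-nested loops
oracle_attention <- function(Q, K, V, vis) {
  L <- nrow(Q); dv <- ncol(V)
  out <- matrix(0, L, dv)
  for (i in seq_len(L)) {
    scores <- rep(NA_real_, L)
    for (j in seq_len(L)) {
      if (vis[j] == 1L) {
        s <- 0
        for (k in seq_len(ncol(Q))) s <- s + Q[i, k] * K[j, k]
        scores[j] <- s / sqrt(ncol(K))
      }
    }
    vj <- which(!is.na(scores))
    w <- exp(scores[vj] - max(scores[vj]))
    w <- w / sum(w)
    for (j in seq_along(vj)) out[i, ] <- out[i, ] + w[j] * V[vj[j], ]
  }
  out
}

# multi-head attention: per-head brute force, concatenated, projected
oracle_multi_head <- function(X, p, vis) {
  d <- ncol(X); h <- p$h; dh <- d %/% h
  O <- matrix(0, nrow(X), d)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dh + 1L):(i * dh)
    O[, cols] <- oracle_attention(X %*% p$Wq[, cols, drop = FALSE],
                                  X %*% p$Wk[, cols, drop = FALSE],
                                  X %*% p$Wv[, cols, drop = FALSE], vis)
  }
  O %*% p$Wo
}

# TextCNN channel: sliding-window scalar scores, ReLU, max over valid windows
oracle_cnn <- function(T_mat, params, vis) {
  out <- numeric(0)
  for (wi in seq_along(params$widths)) {
    w <- params$widths[wi]; kp <- params$kernels[[wi]]
    n_win <- nrow(T_mat) - w + 1L
    for (k in seq_len(params$filters)) {
      Kk <- matrix(kp$K[, k], w, ncol(T_mat), byrow = TRUE)
      best <- -Inf
      for (t in seq_len(n_win)) {
        if (!any(vis[t + 0:(w - 1L)] == 1L)) next
        s <- kp$b[k]
        for (a in seq_len(w)) for (b in seq_len(ncol(T_mat)))
          s <- s + Kk[a, b] * T_mat[t + a - 1L, b]
        best <- max(best, max(s, 0))
      }
      out <- c(out, best)
    }
  }
  out
}

# plain softmax by scalar loops
oracle_softmax <- function(x) {
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    e <- exp(x[i, ] - max(x[i, ]))
    out[i, ] <- e / sum(e)
  }
  out
}

# keyword-lookup classifier: predicts the class whose keyword appears;
# ties / no hit -> first class
oracle_keyword_classify <- function(texts, keyword_map) {
  vapply(texts, function(tx) {
    toks <- strsplit(tolower(tx), "[^a-z0-9]+")[[1]]
    hits <- vapply(keyword_map, function(kw) kw %in% toks, TRUE)
    if (sum(hits) == 1L) names(keyword_map)[hits] else names(keyword_map)[1L]
  }, "", USE.NAMES = FALSE)
}

# per-class F1 and support-weighted aggregate by explicit tallying
oracle_weighted_f1 <- function(truth, pred, K) {
  wf1 <- 0; N <- length(truth)
  for (c in seq_len(K)) {
    tp <- sum(truth == c & pred == c)
    fp <- sum(truth != c & pred == c)
    fn <- sum(truth == c & pred != c)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    wf1 <- wf1 + (sum(truth == c) / N) * f1
  }
  wf1
}

# shared tiny model configuration for training-level tests
tiny_config <- function(...) {
  defaults <- list(hidden = 16L, layers = 1L, heads = 2L, ff_mult = 2L,
                   d_c = 16L, widths = c(2L, 3L), filters = 4L,
                   pad_size = 16L, beta = 0.5, dropout = 0.1,
                   learning_rate = 2e-3, batch_size = 8L, epochs = 3L,
                   early_stop_batches = 100L, eval_interval_batches = 10L,
                   seed = 5L)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(tf_config, defaults)
}

# deterministic tiny corpus for corpus-level tests
tiny_corpus <- function(n_per_class = 6L) {
  texts <- character(0); labels <- character(0)
  words <- c("aches", "fever", "cough", "rash", "dizzy", "tired")
  for (cl in c("alpha", "beta")) {
    kw <- if (cl == "alpha") "chest" else "skin"
    for (i in seq_len(n_per_class)) {
      texts <- c(texts, paste(c(words[1 + (i %% 3)], kw,
                                words[4 + (i %% 3)]), collapse = " "))
      labels <- c(labels, cl)
    }
  }
  new_corpus(sprintf("d%03d", seq_along(texts)), texts, labels)
}
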