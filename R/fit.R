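# Model fitting: seeded minibatch training with hybrid-mask augmentation,
# periodic validation, early stopping on validation weighted F1, and
# best-checkpoint selection.

# RNG shim over the current global stream (used inside a seeded fit)
stream_rng <- function() {
  list(rnorm = function(n, mean = 0, sd = 1) stats::rnorm(n, mean, sd),
       runif = function(n, min = 0, max = 1) stats::runif(n, min, max),
       sample_int = function(n, k, replace = FALSE) sample.int(n, k, replace = replace))
}

encode_docs <- function(docs, vocab, labels, pad_size) {
  list(seqs = lapply(docs$text, encode_text, vocab = vocab, pad_size = pad_size),
       y = match(docs$label, labels))
}

# forward a set of sequences in evaluation mode
predict_internal <- function(params, cfg, ab, seqs, adapter = NULL) {
  n <- length(seqs)
  K <- length(params$head$b)
  probs <- matrix(0, n, K)
  preds <- integer(n)
  Pmat <- if (ab$mha && ab$cnn && ab$fusion) matrix(0, n, 2) else NULL
  for (i in seq_len(n)) {
    s <- seqs[[i]]
    vis <- c(rep(1L, s$length), rep(0L, s$pad_size - s$length))
    fw <- forward_sample(params, cfg, ab, s$ids, vis, training = FALSE,
                         adapter = adapter)
    probs[i, ] <- fw$probs
    preds[i] <- fw$pred
    if (!is.null(Pmat)) Pmat[i, ] <- fw$P
  }
  list(probs = probs, predicted = preds, fusion = Pmat)
}

#' Fit the multi-channel triage text classifier
#'
#' Trains the full architecture end to end: hybrid n-gram/padding mask
#' augmentation of each training batch, summed token/segment/position
#' embeddings, a pre-norm transformer encoder, parallel attention (global)
#' and convolutional (local) feature channels, per-sample
#' temperature-softmax fusion, and a dropout + softmax classification
#' head. Optimization is Adam with linear warmup; validation weighted F1
#' is evaluated periodically and training stops early once it fails to
#' improve for `early_stop_batches` batches. The returned model carries
#' the parameters of the best validation checkpoint.
#'
#' @param corpus a `tf_corpus` (or data.frame with `text`/`label`); split
#'   8:1:1 with [split_corpus()] if it has no splits yet.
#' @param config a [tf_config()].
#' @param ablation character vector of components to disable, any of
#'   `"hybrid_mask"`, `"textcnn"`, `"mha"`, `"fusion"`, `"temperature"`.
#'   Disabling both channels is rejected.
#' @param verbose print progress lines.
#' @param adapter optional frozen external encoder obeying the adapter
#'   contract `(token ids, visibility) -> L x hidden state matrix` (see
#'   [demo_adapter()]); it replaces the scratch embedding+encoder stack
#'   and receives no gradient updates.
#' @return An object of class `triagefuse` with `print`, `summary`,
#'   `predict`, `coef` and `plot` methods.
#' @export
triagefuse <- function(corpus, config = tf_config(), ablation = character(0),
                       verbose = FALSE, adapter = NULL) {
  corpus <- as_corpus(corpus)
  cfg <- config
  ab <- resolve_ablation(ablation)
  if (is.null(corpus$splits)) corpus <- split_corpus(corpus, seed = cfg$seed)
  if (length(corpus$splits$train) == 0L) stop("empty training split")
  if (length(corpus$splits$val) == 0L) stop("empty validation split")

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(cfg$seed)

  vocab <- build_vocab(corpus, cfg$min_count)
  labels <- corpus$labels
  tr <- encode_docs(split_docs(corpus, "train"), vocab, labels, cfg$pad_size)
  va <- encode_docs(split_docs(corpus, "val"), vocab, labels, cfg$pad_size)

  params <- init_params(cfg, length(vocab), length(labels), ab, stream_rng())
  pvec <- unlist(params, use.names = FALSE)
  skel <- params
  opt <- adam_new(length(pvec))

  n_train <- length(tr$seqs)
  steps_per_epoch <- ceiling(n_train / cfg$batch_size)
  total_steps <- cfg$epochs * steps_per_epoch
  warmup <- max(1L, floor(cfg$warmup_frac * total_steps))
  mcfg <- mask_config(cfg$ngram_ratio, cfg$ngram_n, cfg$pad_size)

  best_wf1 <- -Inf; best_pvec <- pvec; best_batch <- 0L
  batch_count <- 0L; stopped_early <- FALSE
  history <- list()

  for (epoch in seq_len(cfg$epochs)) {
    order_idx <- sample.int(n_train, n_train)
    for (b in seq_len(steps_per_epoch)) {
      sel <- order_idx[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, n_train)]
      batch_seqs <- tr$seqs[sel]
      mb <- augment_batch(batch_seqs, mcfg, training = ab$mask)
      params <- utils::relist(pvec, skel)
      gvec <- numeric(length(pvec))
      batch_loss <- 0
      for (k in seq_along(sel)) {
        fw <- forward_sample(params, cfg, ab, mb$token_ids[k, ],
                             mb$visibility[k, ], label = tr$y[sel[k]],
                             training = TRUE, adapter = adapter)
        batch_loss <- batch_loss + fw$loss
        g <- backward_sample(params, cfg, ab, fw, tr$y[sel[k]])
        gvec <- gvec + unlist(g, use.names = FALSE)
      }
      gvec <- gvec / length(sel)
      batch_loss <- batch_loss / length(sel)
      batch_count <- batch_count + 1L
      lr_t <- cfg$learning_rate * min(batch_count / warmup, 1)
      st <- adam_step(opt, pvec, gvec, lr_t)
      opt <- st$opt; pvec <- st$pvec

      rec <- list(batch = batch_count, epoch = epoch, loss = batch_loss,
                  val_wf1 = NA_real_)
      if (batch_count %% cfg$eval_interval_batches == 0L) {
        params <- utils::relist(pvec, skel)
        pr <- predict_internal(params, cfg, ab, va$seqs, adapter)
        m <- classification_metrics(va$y, pr$predicted, labels)
        rec$val_wf1 <- m$w_f1
        if (m$w_f1 > best_wf1) {
          best_wf1 <- m$w_f1; best_pvec <- pvec; best_batch <- batch_count
        }
        if (verbose)
          message(sprintf("batch %d  loss %.4f  val w-F1 %.4f (best %.4f)",
                          batch_count, batch_loss, m$w_f1, best_wf1))
        if (batch_count - best_batch >= cfg$early_stop_batches) {
          stopped_early <- TRUE
        }
      }
      history[[length(history) + 1L]] <- rec
      if (stopped_early) break
    }
    if (stopped_early) break
  }
  if (best_wf1 == -Inf) {
    # run ended before any periodic validation: measure once at the end
    params <- utils::relist(pvec, skel)
    pr <- predict_internal(params, cfg, ab, va$seqs, adapter)
    best_wf1 <- classification_metrics(va$y, pr$predicted, labels)$w_f1
    best_pvec <- pvec; best_batch <- batch_count
  }

  hist_df <- do.call(rbind, lapply(history, as.data.frame))
  structure(list(
    params = utils::relist(best_pvec, skel),
    config = cfg, ablation = ablation, ab = ab,
    vocab = vocab, labels = labels,
    history = hist_df,
    best = list(val_wf1 = best_wf1, batch = best_batch),
    batches_run = batch_count, stopped_early = stopped_early,
    adapter = adapter,
    splits = corpus$splits,
    call = match.call()),
    class = "triagefuse")
}

#' @export
print.triagefuse <- function(x, ...) {
  cat("Multi-channel triage text classifier\n")
  cat(sprintf("  classes: %d  vocabulary: %d tokens\n",
              length(x$labels), length(x$vocab)))
  cat(sprintf("  encoder: d=%d, %d layer(s), %d heads; channels: %s\n",
              x$config$hidden, x$config$layers, x$config$heads,
              paste(c(if (x$ab$mha) "attention", if (x$ab$cnn) "cnn"),
                    collapse = " + ")))
  if (x$ab$mha && x$ab$cnn && x$ab$fusion)
    cat(sprintf("  fusion: temperature softmax gate, beta=%.3g\n",
                if (x$ab$temperature) x$config$beta else 1))
  if (length(x$ablation)) cat("  ablated:", paste(x$ablation, collapse = ", "), "\n")
  cat(sprintf("  trained %d batches%s; best val w-F1 %.4f at batch %d\n",
              x$batches_run, if (x$stopped_early) " (early stop)" else "",
              x$best$val_wf1, x$best$batch))
  invisible(x)
}

#' Predict departments for new texts
#'
#' @param object a fitted `triagefuse` model.
#' @param newdata a `tf_corpus`, data.frame with a `text` column, or
#'   character vector of texts.
#' @param type `"class"` (factor of predicted labels), `"prob"` (N x K
#'   probability matrix), or `"fusion"` (N x 2 per-sample channel weights;
#'   only for models with both channels and fusion enabled).
#' @param ... unused.
#' @return Depends on `type`.
#' @export
predict.triagefuse <- function(object, newdata,
                               type = c("class", "prob", "fusion"), ...) {
  type <- match.arg(type)
  texts <- if (is.character(newdata)) newdata
           else if (is.data.frame(newdata)) newdata$text
           else as_corpus(newdata)$documents$text
  seqs <- lapply(texts, encode_text, vocab = object$vocab,
                 pad_size = object$config$pad_size)
  pr <- predict_internal(object$params, object$config, object$ab, seqs,
                         object$adapter)
  switch(type,
    class = factor(object$labels[pr$predicted], levels = object$labels),
    prob = { colnames(pr$probs) <- object$labels; pr$probs },
    fusion = {
      if (is.null(pr$fusion))
        stop("fusion weights unavailable: a channel or the fusion stage is ablated")
      colnames(pr$fusion) <- c("mha", "cnn"); pr$fusion
    })
}

#' Evaluate a fitted model on a corpus split
#'
#' Deterministic (no dropout, no masking): encodes the split's documents,
#' predicts, and tallies the support-weighted metrics and confusion matrix.
#'
#' @param object a fitted `triagefuse`.
#' @param corpus a split `tf_corpus` whose labels are all known to the model.
#' @param split which split to evaluate (default `"test"`).
#' @return A `tf_metrics`.
#' @export
evaluate_model <- function(object, corpus, split = "test") {
  corpus <- as_corpus(corpus)
  docs <- if (is.null(corpus$splits)) corpus$documents
          else split_docs(corpus, split)
  unknown <- setdiff(unique(docs$label), object$labels)
  if (length(unknown))
    stop("label(s) unseen in training: ", paste(unknown, collapse = ", "))
  seqs <- lapply(docs$text, encode_text, vocab = object$vocab,
                 pad_size = object$config$pad_size)
  pr <- predict_internal(object$params, object$config, object$ab, seqs,
                         object$adapter)
  classification_metrics(match(docs$label, object$labels), pr$predicted,
                         object$labels)
}

#' @export
summary.triagefuse <- function(object, ...) {
  print(object)
  h <- object$history
  evals <- h[!is.na(h$val_wf1), , drop = FALSE]
  if (nrow(evals)) {
    cat("validation trace (batch : w-F1):\n")
    for (i in seq_len(nrow(evals)))
      cat(sprintf("  %6d : %.4f\n", evals$batch[i], evals$val_wf1[i]))
  }
  invisible(object)
}

#' Extract the classification-head coefficients
#'
#' @param object a fitted `triagefuse`.
#' @param ... unused.
#' @return List with the head weight matrix `W` (features x classes,
#'   columns named by label) and bias `b`.
#' @export
coef.triagefuse <- function(object, ...) {
  W <- object$params$head$W
  colnames(W) <- object$labels
  list(W = W, b = stats::setNames(object$params$head$b, object$labels))
}

#' Plot the training trajectory
#'
#' Training loss per batch with the validation weighted-F1 trace overlaid
#' on a secondary axis.
#'
#' @param x a fitted `triagefuse`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.triagefuse <- function(x, ...) {
  h <- x$history
  graphics::plot(h$batch, h$loss, type = "l", xlab = "batch",
                 ylab = "training loss", ...)
  evals <- h[!is.na(h$val_wf1), , drop = FALSE]
  if (nrow(evals)) {
    scale <- max(h$loss, na.rm = TRUE)
    graphics::lines(evals$batch, evals$val_wf1 * scale, col = 2, lty = 2)
    graphics::axis(4, at = pretty(c(0, 1)) * scale, labels = pretty(c(0, 1)))
    graphics::mtext("validation w-F1", side = 4, line = 2, col = 2)
  }
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The parameter blob is an RDS file; a JSON sidecar records the
#' configuration, label set, vocabulary hash and metric history.
#'
#' @param object a fitted `triagefuse`.
#' @param dir checkpoint directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(object, file.path(dir, "model.rds"))
  side <- list(config = object$config[setdiff(names(object$config), "")],
               ablation = object$ablation,
               labels = object$labels,
               vocab_hash = sum(as.numeric(object$vocab)),
               best = object$best)
  jsonlite::write_json(side, file.path(dir, "checkpoint.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @param dir checkpoint directory.
#' @export
load_checkpoint <- function(dir) readRDS(file.path(dir, "model.rds"))

#' Train one model per temperature value
#'
#' Repeats the seeded fit over a grid of fusion temperatures and reports
#' the best validation weighted F1 reached by each, mirroring a
#' temperature ablation sweep.
#'
#' @param corpus a `tf_corpus`.
#' @param config a [tf_config()]; its `beta` is overridden per grid point.
#' @param grid positive numeric vector of temperatures.
#' @param ablation passed through to [triagefuse()].
#' @return data.frame with columns `beta` and `val_wf1`, one row per grid
#'   point, plus the fitted models in `attr(, "fits")`.
#' @export
beta_sweep <- function(corpus, config = tf_config(), grid = c(0.1, 0.5, 1),
                       ablation = character(0)) {
  stopifnot(length(grid) >= 1, all(grid > 0))
  fits <- lapply(grid, function(b) {
    cfg <- config; cfg$beta <- b
    triagefuse(corpus, cfg, ablation)
  })
  out <- data.frame(beta = grid,
                    val_wf1 = vapply(fits, function(f) f$best$val_wf1, 0))
  attr(out, "fits") <- fits
  out
}

#' Repeat a fit across seeds and collect test scores
#'
#' Runs the same configuration `runs` times with seed offsets and returns
#' the per-run test weighted-F1 scores, the raw material for
#' [compare_runs()].
#'
#' @param corpus a split `tf_corpus`.
#' @param config a [tf_config()]; run r uses `seed + r - 1`.
#' @param ablation passed through to [triagefuse()].
#' @param runs number of repeats (>= 1).
#' @param split evaluation split.
#' @return Numeric vector of per-run weighted-F1 scores.
#' @export
run_scores <- function(corpus, config = tf_config(), ablation = character(0),
                       runs = 3L, split = "test") {
  vapply(seq_len(runs), function(r) {
    cfg <- config; cfg$seed <- config$seed + r - 1L
    fit <- triagefuse(corpus, cfg, ablation)
    evaluate_model(fit, corpus, split)$w_f1
  }, 0)
}
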