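# Full model: embedding sum, transformer encoder, two feature channels,
# temperature-softmax fusion, dropout + softmax head -- with hand-written
# backward passes for every stage.

#' Model/training configuration
#'
#' Defaults follow the reference hyperparameter set of the method: hidden
#' size 768, learning rate 3e-5, batch size 128, pad size 64, 15 epochs,
#' dropout 0.1, temperature beta 0.5, kernel widths (3,4,5), 16 attention
#' heads, 3-gram masking, early stopping after 1,500 batches without
#' validation improvement. `hidden` must be divisible by `heads`. Desk-scale
#' work passes smaller values.
#'
#' @param hidden encoder/channel width d.
#' @param layers number of transformer encoder blocks.
#' @param heads attention heads (encoder and attention channel).
#' @param ff_mult feed-forward width multiplier (d_ff = ff_mult * hidden).
#' @param d_c common channel width after projection (default `hidden`).
#' @param widths convolution kernel widths.
#' @param filters convolution filters per width.
#' @param pad_size fixed sequence capacity L.
#' @param beta fusion temperature (> 0).
#' @param dropout dropout probability.
#' @param ngram_n n-gram mask span length.
#' @param ngram_ratio fraction routed to the n-gram mask branch.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs maximum epochs.
#' @param early_stop_batches stop after this many batches without
#'   validation improvement.
#' @param eval_interval_batches validate every this many batches.
#' @param warmup_frac fraction of total steps with linear LR warmup.
#' @param min_count vocabulary minimum token count.
#' @param mha_pool attention-channel pooling: `"mean"` over visible
#'   positions (default) or `"cls"` (the sequence-start position).
#' @param cnn_input what the convolutional channel convolves:
#'   `"encoder"` (default; the contextual encoder output T) or `"content"`
#'   (classic TextCNN: position-free token+segment embeddings, used by the
#'   channel-attribution probe experiments).
#' @param layer_sum if `TRUE` the encoder output is the sum of all block
#'   outputs rather than the last block's.
#' @param seed integer root seed for initialization, shuffling, masking and
#'   dropout.
#' @return A `tf_config` list.
#' @export
tf_config <- function(hidden = 768L, layers = 2L, heads = 16L, ff_mult = 2L,
                      d_c = hidden, widths = c(3L, 4L, 5L), filters = 100L,
                      pad_size = 64L, beta = 0.5, dropout = 0.1,
                      ngram_n = 3L, ngram_ratio = 0.7,
                      learning_rate = 3e-5, batch_size = 128L, epochs = 15L,
                      early_stop_batches = 1500L,
                      eval_interval_batches = 100L, warmup_frac = 0.1,
                      min_count = 1L, mha_pool = c("mean", "cls"),
                      cnn_input = c("encoder", "content"),
                      layer_sum = FALSE, seed = 1L) {
  mha_pool <- match.arg(mha_pool)
  cnn_input <- match.arg(cnn_input)
  if (hidden %% heads != 0L)
    stop(sprintf("hidden width %d is not divisible by %d heads", hidden, heads))
  stopifnot(beta > 0, dropout >= 0, dropout < 1, pad_size >= 3,
            learning_rate >= 0, batch_size >= 1, epochs >= 1)
  structure(as.list(environment()), class = "tf_config")
}

# which components are active under an ablation spec
resolve_ablation <- function(ablation) {
  known <- c("hybrid_mask", "textcnn", "mha", "fusion", "temperature")
  ablation <- as.character(ablation %||% character(0))
  bad <- setdiff(ablation, known)
  if (length(bad)) stop("unknown ablation component(s): ",
                        paste(bad, collapse = ", "))
  if (all(c("textcnn", "mha") %in% ablation))
    stop("cannot disable both feature channels")
  list(mask = !"hybrid_mask" %in% ablation,
       cnn = !"textcnn" %in% ablation,
       mha = !"mha" %in% ablation,
       fusion = !"fusion" %in% ablation,
       temperature = !"temperature" %in% ablation)
}

head_input_width <- function(cfg, ab) {
  if (!ab$cnn || !ab$mha) cfg$d_c
  else if (!ab$fusion) 2L * cfg$d_c
  else cfg$d_c
}

init_params <- function(cfg, vocab_size, n_classes, ab, rng) {
  d <- cfg$hidden; sd0 <- 0.02
  rn <- function(n, s = sd0) rng$rnorm(n, 0, s)
  emb <- list(TE = matrix(rn(vocab_size * d), vocab_size, d),
              SE = matrix(rn(2 * d), 2, d),
              PE = matrix(rn(cfg$pad_size * d), cfg$pad_size, d))
  blocks <- lapply(seq_len(cfg$layers), function(l) {
    c(list(ln1_g = rep(1, d), ln1_b = rep(0, d)),
      init_attention_params(d, cfg$heads, rng)[c("Wq", "Wk", "Wv", "Wo")],
      list(ln2_g = rep(1, d), ln2_b = rep(0, d),
           W1 = matrix(rn(d * cfg$ff_mult * d), d, cfg$ff_mult * d),
           b1 = rep(0, cfg$ff_mult * d),
           W2 = matrix(rn(cfg$ff_mult * d * d), cfg$ff_mult * d, d),
           b2 = rep(0, d)))
  })
  p <- list(emb = emb, blocks = blocks,
            lnf_g = rep(1, d), lnf_b = rep(0, d))
  if (ab$mha)
    p$chan_mha <- init_attention_params(d, cfg$heads, rng)[c("Wq", "Wk", "Wv", "Wo")]
  if (ab$cnn)
    p$chan_cnn <- init_cnn_params(d, cfg$widths, cfg$filters, rng)$kernels
  cnn_width <- length(cfg$widths) * cfg$filters
  proj <- list()
  if (ab$mha) { proj$Pm <- matrix(rn(d * cfg$d_c), d, cfg$d_c); proj$bm <- rep(0, cfg$d_c) }
  if (ab$cnn) { proj$Pc <- matrix(rn(cnn_width * cfg$d_c), cnn_width, cfg$d_c); proj$bc <- rep(0, cfg$d_c) }
  p$proj <- proj
  if (ab$cnn && ab$mha && ab$fusion)
    p$gate <- list(gate_w = matrix(rn(2 * cfg$d_c * 2), 2 * cfg$d_c, 2),
                   gate_b = rep(0, 2))
  hin <- head_input_width(cfg, ab)
  p$head <- list(W = matrix(rn(hin * n_classes), hin, n_classes),
                 b = rep(0, n_classes))
  p
}

# ---- encoder forward/backward ----------------------------------------------

block_fwd <- function(x, bp, hcfg, visibility) {
  l1 <- ln_fwd(x, bp$ln1_g, bp$ln1_b)
  at <- mha_fwd(l1$out, list(Wq = bp$Wq, Wk = bp$Wk, Wv = bp$Wv,
                             Wo = bp$Wo, h = hcfg), visibility)
  x2 <- x + at$out
  l2 <- ln_fwd(x2, bp$ln2_g, bp$ln2_b)
  u <- l2$out %*% bp$W1 + rep(bp$b1, each = nrow(x))
  a <- gelu(u)
  ff <- a %*% bp$W2 + rep(bp$b2, each = nrow(x))
  list(out = x2 + ff, l1 = l1, at = at, x2 = x2, l2 = l2, u = u, a = a)
}

block_bwd <- function(dout, cache, x, bp, hcfg) {
  # feed-forward branch
  db2 <- colSums(dout)
  dW2 <- t(cache$a) %*% dout
  da <- dout %*% t(bp$W2)
  du <- da * gelu_grad(cache$u)
  db1 <- colSums(du)
  dW1 <- t(cache$l2$out) %*% du
  dl2out <- du %*% t(bp$W1)
  g2 <- ln_bwd(dl2out, cache$l2, bp$ln2_g)
  dx2 <- dout + g2$dx
  # attention branch
  am <- mha_bwd(dx2, cache$at, cache$l1$out,
                list(Wq = bp$Wq, Wk = bp$Wk, Wv = bp$Wv, Wo = bp$Wo, h = hcfg))
  g1 <- ln_bwd(am$dX, cache$l1, bp$ln1_g)
  dx <- dx2 + g1$dx
  list(dx = dx,
       grads = list(ln1_g = g1$dg, ln1_b = g1$db,
                    Wq = am$dWq, Wk = am$dWk, Wv = am$dWv, Wo = am$dWo,
                    ln2_g = g2$dg, ln2_b = g2$db,
                    W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

encoder_fwd <- function(E, params, cfg, visibility) {
  if (!any(visibility == 1L)) stop("all-zero visibility row: nothing to attend to")
  x <- E
  caches <- vector("list", cfg$layers)
  layer_outs <- if (cfg$layer_sum) vector("list", cfg$layers) else NULL
  for (l in seq_len(cfg$layers)) {
    bc <- block_fwd(x, params$blocks[[l]], cfg$heads, visibility)
    caches[[l]] <- bc
    x <- bc$out
    if (cfg$layer_sum) layer_outs[[l]] <- x
  }
  if (cfg$layers == 0L) return(list(T = E, caches = caches, lnf = NULL))
  pre <- if (cfg$layer_sum) Reduce(`+`, layer_outs) else x
  lf <- ln_fwd(pre, params$lnf_g, params$lnf_b)
  list(T = lf$out, caches = caches, lnf = lf, pre = pre)
}

encoder_bwd <- function(dT, fwd, E, params, cfg) {
  grads <- list(blocks = vector("list", cfg$layers))
  if (cfg$layers == 0L)
    return(list(dE = dT, grads = c(grads, list(lnf_g = NULL, lnf_b = NULL))))
  gl <- ln_bwd(dT, fwd$lnf, params$lnf_g)
  grads$lnf_g <- gl$dg; grads$lnf_b <- gl$db
  dx <- gl$dx
  if (cfg$layer_sum) {
    # every layer output receives the same upstream gradient; accumulate
    # back through the chain from the top
    dsum <- dx
    dx <- dsum
    for (l in rev(seq_len(cfg$layers))) {
      xin <- if (l == 1L) E else fwd$caches[[l - 1L]]$out
      bb <- block_bwd(dx, fwd$caches[[l]], xin, params$blocks[[l]], cfg$heads)
      grads$blocks[[l]] <- bb$grads
      dx <- bb$dx + if (l > 1L) dsum else 0
    }
  } else {
    for (l in rev(seq_len(cfg$layers))) {
      xin <- if (l == 1L) E else fwd$caches[[l - 1L]]$out
      bb <- block_bwd(dx, fwd$caches[[l]], xin, params$blocks[[l]], cfg$heads)
      grads$blocks[[l]] <- bb$grads
      dx <- bb$dx
    }
  }
  list(dE = dx, grads = grads)
}

#' Summed token/segment/position embedding
#'
#' Output position (i, j) is exactly `TE[token id] + SE[segment id] +
#' PE[j]`.
#'
#' @param token_ids N x L matrix of 1-based token ids.
#' @param segment_ids N x L matrix of 1-based segment ids (all 1 for the
#'   single-sentence task).
#' @param params list with tables `TE` (|V| x d), `SE` (2 x d), `PE` (L x d).
#' @return N x L x d numeric array.
#' @export
embed_tokens <- function(token_ids, segment_ids, params) {
  if (any(token_ids < 1L) || any(token_ids > nrow(params$TE)))
    stop("token id out of embedding-table range")
  if (any(segment_ids < 1L) || any(segment_ids > nrow(params$SE)))
    stop("segment id out of embedding-table range")
  N <- nrow(token_ids); L <- ncol(token_ids); d <- ncol(params$TE)
  out <- array(0, c(N, L, d))
  for (i in seq_len(N))
    out[i, , ] <- params$TE[token_ids[i, ], , drop = FALSE] +
      params$SE[segment_ids[i, ], , drop = FALSE] +
      params$PE[seq_len(L), , drop = FALSE]
  out
}

#' Contextual encoding of embedded sequences
#'
#' Runs the pre-norm transformer encoder (multi-head self-attention +
#' GELU feed-forward blocks, final layer norm) over one embedded sequence.
#' Positions with visibility bit 0 are excluded from attention keys via an
#' additive -Inf mask before normalization. With `layers = 0` the output
#' equals the input.
#'
#' @param E L x d embedded sequence.
#' @param visibility integer bits of length L; must contain at least one 1.
#' @param params encoder parameter list (`blocks`, `lnf_g`, `lnf_b`) as
#'   produced inside [triagefuse()].
#' @param cfg a `tf_config` (supplies `layers`, `heads`, `layer_sum`).
#' @return L x d matrix of contextual vectors T.
#' @export
encode_states <- function(E, visibility, params, cfg) {
  encoder_fwd(E, params, cfg, visibility)$T
}

# ---- full-model forward/backward (one sample) -------------------------------

forward_sample <- function(params, cfg, ab, ids, vis, label = NULL,
                           training = FALSE, drop_mask = NULL,
                           adapter = NULL) {
  L <- length(ids); d <- cfg$hidden
  if (is.null(adapter)) {
    E <- params$emb$TE[ids, , drop = FALSE] +
      rep(params$emb$SE[1L, ], each = L) +
      params$emb$PE[seq_len(L), , drop = FALSE]
    enc <- encoder_fwd(E, params, cfg, vis)
    Tm <- enc$T
  } else {
    # frozen external encoder: (token ids, visibility) -> L x d states
    E <- NULL; enc <- NULL
    Tm <- adapter(ids, vis)
    if (!is.matrix(Tm) || nrow(Tm) != L || ncol(Tm) != d)
      stop(sprintf("adapter must return a %d x %d state matrix", L, d))
  }
  pm <- NULL; pc <- NULL
  mha_c <- NULL; cnn_c <- NULL
  if (ab$mha) {
    mha_c <- chan_mha_fwd(Tm, c(params$chan_mha, list(h = cfg$heads)), vis,
                          pool = cfg$mha_pool %||% "mean")
    pm <- drop(mha_c$out %*% params$proj$Pm) + params$proj$bm
  }
  if (ab$cnn) {
    cnnp <- list(widths = cfg$widths, filters = cfg$filters,
                 kernels = params$chan_cnn)
    cnn_in <- if ((cfg$cnn_input %||% "encoder") == "content")
      params$emb$TE[ids, , drop = FALSE] + rep(params$emb$SE[1L, ], each = L)
    else Tm
    cnn_c <- chan_cnn_fwd(cnn_in, cnnp, vis)
    cnn_c$input <- cnn_in
    pc <- drop(cnn_c$out %*% params$proj$Pc) + params$proj$bc
  }
  P <- NULL; Cc <- NULL
  if (ab$mha && ab$cnn) {
    Cc <- c(pm, pc)
    if (ab$fusion) {
      beta <- if (ab$temperature) cfg$beta else 1
      g <- drop(Cc %*% params$gate$gate_w) + params$gate$gate_b
      P <- drop(row_softmax(matrix(g / beta, 1L)))
      H <- P[1] * pm + P[2] * pc
    } else {
      H <- Cc
    }
  } else {
    H <- if (ab$mha) pm else pc
  }
  if (training && cfg$dropout > 0) {
    if (is.null(drop_mask)) drop_mask <- stats::runif(length(H)) >= cfg$dropout
    Hd <- H * drop_mask / (1 - cfg$dropout)
  } else {
    drop_mask <- NULL
    Hd <- H
  }
  logits <- drop(Hd %*% params$head$W) + params$head$b
  probs <- { m <- max(logits); e <- exp(logits - m); e / sum(e) }
  loss <- if (is.null(label)) NA_real_ else -log(max(probs[label], 1e-12))
  list(loss = loss, probs = probs, pred = which.max(probs), P = P,
       cache = list(E = E, enc = enc, Tm = Tm, mha_c = mha_c, cnn_c = cnn_c,
                    pm = pm, pc = pc, Cc = Cc, H = H, Hd = Hd,
                    drop_mask = drop_mask, ids = ids, vis = vis))
}

backward_sample <- function(params, cfg, ab, fw, label) {
  ca <- fw$cache
  grads <- zero_grads(params)
  dlogits <- fw$probs
  dlogits[label] <- dlogits[label] - 1
  grads$head$W <- outer(ca$Hd, dlogits)
  grads$head$b <- dlogits
  dHd <- drop(params$head$W %*% dlogits)
  dH <- if (!is.null(ca$drop_mask)) dHd * ca$drop_mask / (1 - cfg$dropout) else dHd
  dpm <- NULL; dpc <- NULL
  if (ab$mha && ab$cnn) {
    dc <- cfg$d_c
    if (ab$fusion) {
      P <- fw$P
      beta <- if (ab$temperature) cfg$beta else 1
      dP <- c(sum(dH * ca$pm), sum(dH * ca$pc))
      dpm <- P[1] * dH
      dpc <- P[2] * dH
      du <- P * (dP - sum(dP * P))
      dg <- du / beta
      grads$gate$gate_w <- outer(ca$Cc, dg)
      grads$gate$gate_b <- dg
      dCc <- drop(params$gate$gate_w %*% dg)
      dpm <- dpm + dCc[seq_len(dc)]
      dpc <- dpc + dCc[dc + seq_len(dc)]
    } else {
      dpm <- dH[seq_len(dc)]
      dpc <- dH[dc + seq_len(dc)]
    }
  } else if (ab$mha) dpm <- dH else dpc <- dH
  dT <- matrix(0, nrow(ca$Tm), ncol(ca$Tm))
  if (ab$mha) {
    grads$proj$Pm <- outer(ca$mha_c$out, dpm)
    grads$proj$bm <- dpm
    dpooled <- drop(params$proj$Pm %*% dpm)
    mb <- chan_mha_bwd(dpooled, ca$mha_c, ca$Tm,
                       c(params$chan_mha, list(h = cfg$heads)))
    grads$chan_mha$Wq <- mb$dWq; grads$chan_mha$Wk <- mb$dWk
    grads$chan_mha$Wv <- mb$dWv; grads$chan_mha$Wo <- mb$dWo
    dT <- dT + mb$dX
  }
  if (ab$cnn) {
    grads$proj$Pc <- outer(ca$cnn_c$out, dpc)
    grads$proj$bc <- dpc
    dcnn_out <- drop(params$proj$Pc %*% dpc)
    cnnp <- list(widths = cfg$widths, filters = cfg$filters,
                 kernels = params$chan_cnn)
    content_mode <- (cfg$cnn_input %||% "encoder") == "content"
    cb <- chan_cnn_bwd(dcnn_out, ca$cnn_c, ca$cnn_c$input, cnnp)
    for (wn in names(params$chan_cnn)) {
      grads$chan_cnn[[wn]]$K <- cb$dkernels[[wn]]$dK
      grads$chan_cnn[[wn]]$b <- cb$dkernels[[wn]]$db
    }
    if (content_mode) {
      for (j in seq_along(ca$ids)) {
        tid <- ca$ids[j]
        grads$emb$TE[tid, ] <- grads$emb$TE[tid, ] + cb$dT[j, ]
      }
      grads$emb$SE[1L, ] <- grads$emb$SE[1L, ] + colSums(cb$dT)
    } else {
      dT <- dT + cb$dT
    }
  }
  if (!is.null(ca$enc)) {
    eb <- encoder_bwd(dT, ca$enc, ca$E, params, cfg)
    if (cfg$layers > 0L) {
      grads$lnf_g <- eb$grads$lnf_g; grads$lnf_b <- eb$grads$lnf_b
      for (l in seq_len(cfg$layers)) grads$blocks[[l]] <- eb$grads$blocks[[l]]
    }
    dE <- eb$dE
    # embedding tables: scatter-add rows
    for (j in seq_along(ca$ids)) {
      tid <- ca$ids[j]
      grads$emb$TE[tid, ] <- grads$emb$TE[tid, ] + dE[j, ]
    }
    grads$emb$SE[1L, ] <- grads$emb$SE[1L, ] + colSums(dE)
    grads$emb$PE[seq_len(nrow(dE)), ] <- grads$emb$PE[seq_len(nrow(dE)), ] + dE
  }
  # with a frozen external encoder the state gradient dT stops here
  grads
}

#' A deterministic stand-in encoder adapter for tests and demos
#'
#' Returns a function obeying the pretrained-encoder adapter contract:
#' given a token-id vector and its visibility bits it produces an L x d
#' state matrix. States are a fixed pseudo-random embedding of (token id,
#' position), deterministic in `seed`, with invisible positions zeroed.
#' This is a synthetic stand-in used so the adapter interface can be
#' exercised without downloading pretrained weights; it carries no
#' linguistic knowledge.
#'
#' @param d state width.
#' @param seed integer seed fixing the pseudo-random embedding.
#' @return A function `(ids, visibility) -> L x d matrix`.
#' @export
demo_adapter <- function(d, seed = 0L) {
  force(d); force(seed)
  function(ids, visibility) {
    L <- length(ids)
    out <- matrix(0, L, d)
    for (j in seq_len(L)) {
      if (visibility[j] == 1L) {
        rng <- local_rng(seed + 131L * ids[j] + j)
        out[j, ] <- rng$rnorm(d, 0, 1)
      }
    }
    out
  }
}

zero_grads <- function(params) {
  rapply(params, function(x) if (is.numeric(x)) x * 0 else x, how = "replace")
}

# ---- Adam on flattened parameters -------------------------------------------

adam_new <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(opt, pvec, gvec, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- beta1 * opt$m + (1 - beta1) * gvec
  opt$v <- beta2 * opt$v + (1 - beta2) * gvec^2
  mhat <- opt$m / (1 - beta1^opt$t)
  vhat <- opt$v / (1 - beta2^opt$t)
  list(opt = opt, pvec = pvec - lr * mhat / (sqrt(vhat) + eps))
}
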