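# Neural primitives: forward and backward passes in base R matrix code.
#
# Conventions: per-sample activations are L x d matrices; visibility is an
# integer bit vector of length L (1 = position may be attended to / pooled).
# Multi-head projection matrices are packed d x d, head i occupying columns
# (i-1)*dh + 1 .. i*dh with dh = d / h.

LN_EPS <- 1e-5

row_softmax <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# ---- layer norm -------------------------------------------------------------

ln_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc * inv
  list(out = sweep(xhat, 2L, g, `*`) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

# ---- scaled dot-product attention ------------------------------------------

#' Scaled dot-product attention over visible positions
#'
#' Computes `softmax(Q K' / sqrt(d_K)) V` where positions with visibility
#' bit 0 are excluded from the keys (additive -Inf before normalization),
#' so each output row is a convex combination of the visible `V` rows.
#'
#' @param Q,K query/key matrices (L x d_k).
#' @param V value matrix (L x d_v).
#' @param visibility integer bits of length L; at least one must be 1.
#' @return L x d_v attention output.
#' @export
scaled_attention <- function(Q, K, V, visibility = rep(1L, nrow(K))) {
  attn_fwd(Q, K, V, visibility)$out
}

attn_fwd <- function(Q, K, V, visibility) {
  if (!any(visibility == 1L)) stop("no visible position to attend to")
  dk <- ncol(K)
  S <- Q %*% t(K) / sqrt(dk)
  S[, visibility == 0L] <- -Inf
  A <- row_softmax(S)
  list(out = A %*% V, A = A)
}

attn_bwd <- function(dO, cache, Q, K, V) {
  A <- cache$A
  dk <- ncol(K)
  dA <- dO %*% t(V)
  dV <- t(A) %*% dO
  dS <- A * (dA - rowSums(dA * A))
  list(dQ = dS %*% K / sqrt(dk), dK = t(dS) %*% Q / sqrt(dk), dV = dV)
}

# ---- multi-head attention ---------------------------------------------------

#' Initialize multi-head attention parameters
#'
#' @param d model width; must be divisible by `h`.
#' @param h number of heads.
#' @param rng a seeded generator from the internal stream (or `NULL` to use
#'   the current RNG stream).
#' @param init_sd standard deviation of the normal initializer.
#' @return List with packed projection matrices `Wq`, `Wk`, `Wv`, `Wo`
#'   (all d x d) and head count `h`.
#' @export
init_attention_params <- function(d, h, rng = NULL, init_sd = 0.02) {
  if (d %% h != 0L)
    stop(sprintf("hidden width %d is not divisible by %d heads", d, h))
  rn <- if (is.null(rng)) function(n) stats::rnorm(n, 0, init_sd)
        else function(n) rng$rnorm(n, 0, init_sd)
  list(Wq = matrix(rn(d * d), d, d), Wk = matrix(rn(d * d), d, d),
       Wv = matrix(rn(d * d), d, d), Wo = matrix(rn(d * d), d, d), h = h)
}

mha_fwd <- function(X, p, visibility) {
  d <- ncol(X); h <- p$h; dh <- d %/% h
  Q <- X %*% p$Wq; K <- X %*% p$Wk; V <- X %*% p$Wv
  O <- matrix(0, nrow(X), d)
  caches <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dh + 1L):(i * dh)
    a <- attn_fwd(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                  V[, cols, drop = FALSE], visibility)
    O[, cols] <- a$out
    caches[[i]] <- a
  }
  list(out = O %*% p$Wo, O = O, Q = Q, K = K, V = V, caches = caches)
}

mha_bwd <- function(dZ, cache, X, p) {
  d <- ncol(X); h <- p$h; dh <- d %/% h
  dWo <- t(cache$O) %*% dZ
  dO <- dZ %*% t(p$Wo)
  dQ <- matrix(0, nrow(X), d); dK <- dQ; dV <- dQ
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dh + 1L):(i * dh)
    g <- attn_bwd(dO[, cols, drop = FALSE], cache$caches[[i]],
                  cache$Q[, cols, drop = FALSE],
                  cache$K[, cols, drop = FALSE],
                  cache$V[, cols, drop = FALSE])
    dQ[, cols] <- g$dQ; dK[, cols] <- g$dK; dV[, cols] <- g$dV
  }
  list(dX = dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv),
       dWq = t(X) %*% dQ, dWk = t(X) %*% dK, dWv = t(X) %*% dV, dWo = dWo)
}

#' Multi-head attention over one sequence
#'
#' Heads are computed independently by [scaled_attention()] on per-head
#' projections of the input, concatenated, and projected by the output
#' matrix.
#'
#' @param T_seq L x d input sequence.
#' @param params attention parameters from [init_attention_params()].
#' @param visibility integer bits of length L.
#' @return L x d output sequence.
#' @export
multi_head <- function(T_seq, params, visibility = rep(1L, nrow(T_seq))) {
  mha_fwd(T_seq, params, visibility)$out
}

# ---- channels ---------------------------------------------------------------

chan_mha_fwd <- function(T_mat, p, visibility, pool = "mean") {
  m <- mha_fwd(T_mat, p, visibility)
  if (pool == "cls") {
    vis_idx <- 1L                      # sequence-start position
    pooled <- m$out[1L, ]
  } else {
    vis_idx <- which(visibility == 1L)
    pooled <- colMeans(m$out[vis_idx, , drop = FALSE])
  }
  list(out = pooled, mha = m, vis_idx = vis_idx, pool = pool)
}

chan_mha_bwd <- function(dpooled, cache, T_mat, p) {
  dZ <- matrix(0, nrow(T_mat), ncol(T_mat))
  if (cache$pool == "cls") {
    dZ[1L, ] <- dpooled
  } else {
    nv <- length(cache$vis_idx)
    dZ[cache$vis_idx, ] <- rep(dpooled / nv, each = nv)
  }
  mha_bwd(dZ, cache$mha, T_mat, p)
}

#' Global (attention) feature channel
#'
#' Applies multi-head attention per sample and mean-pools the output over
#' visible positions, yielding one global feature vector per sample.
#'
#' @param T_list list of L x d matrices (one per sample), or one matrix.
#' @param params attention parameters from [init_attention_params()].
#' @param visibility list of bit vectors (or one vector).
#' @return N x d matrix of pooled global features.
#' @export
mha_channel <- function(T_list, params, visibility) {
  if (is.matrix(T_list)) { T_list <- list(T_list); visibility <- list(visibility) }
  out <- t(vapply(seq_along(T_list), function(i)
    chan_mha_fwd(T_list[[i]], params, visibility[[i]])$out,
    numeric(ncol(T_list[[1]]))))
  out
}

#' Initialize convolutional channel parameters
#'
#' @param d embedding width (kernel height spans the full width).
#' @param widths integer kernel widths, the n-gram sizes (default 3,4,5).
#' @param filters filters per width (default 100).
#' @param rng optional seeded generator.
#' @param init_sd initializer standard deviation.
#' @return List with `widths`, `filters`, and per-width kernels
#'   (`(w*d) x filters` matrix) plus bias.
#' @export
init_cnn_params <- function(d, widths = c(3L, 4L, 5L), filters = 100L,
                            rng = NULL, init_sd = 0.05) {
  stopifnot(all(widths >= 1L), !anyDuplicated(widths))
  rn <- if (is.null(rng)) function(n) stats::rnorm(n, 0, init_sd)
        else function(n) rng$rnorm(n, 0, init_sd)
  kernels <- lapply(widths, function(w)
    list(K = matrix(rn(w * d * filters), w * d, filters),
         b = rep(0, filters)))
  names(kernels) <- paste0("w", widths)
  list(widths = as.integer(widths), filters = as.integer(filters),
       kernels = kernels)
}

# flatten window rows t..t+w-1 of T into one vector (row-major)
conv_windows <- function(T_mat, w) {
  L <- nrow(T_mat); d <- ncol(T_mat)
  n_win <- L - w + 1L
  M <- matrix(0, n_win, w * d)
  for (t in seq_len(n_win))
    M[t, ] <- as.vector(t(T_mat[t + 0:(w - 1L), , drop = FALSE]))
  M
}

chan_cnn_fwd <- function(T_mat, p, visibility) {
  L <- nrow(T_mat)
  if (L < max(p$widths))
    stop(sprintf("sequence length %d < widest kernel %d", L, max(p$widths)))
  per_w <- vector("list", length(p$widths))
  out <- numeric(0)
  for (wi in seq_along(p$widths)) {
    w <- p$widths[wi]; kp <- p$kernels[[wi]]
    n_win <- L - w + 1L
    valid <- vapply(seq_len(n_win), function(t)
      any(visibility[t + 0:(w - 1L)] == 1L), TRUE)
    M <- conv_windows(T_mat, w)
    r <- pmax(M %*% kp$K + rep(kp$b, each = n_win), 0)  # ReLU conv scores
    vr <- which(valid)
    amax <- vr[apply(r[vr, , drop = FALSE], 2L, which.max)]
    pooled <- r[cbind(amax, seq_len(p$filters))]
    per_w[[wi]] <- list(M = M, r = r, amax = amax, valid = valid)
    out <- c(out, pooled)
  }
  list(out = out, per_w = per_w)
}

chan_cnn_bwd <- function(dpooled, cache, T_mat, p) {
  L <- nrow(T_mat); d <- ncol(T_mat)
  dT <- matrix(0, L, d)
  dk <- vector("list", length(p$widths))
  off <- 0L
  for (wi in seq_along(p$widths)) {
    w <- p$widths[wi]; kp <- p$kernels[[wi]]; cw <- cache$per_w[[wi]]
    dK <- matrix(0, w * d, p$filters); db <- rep(0, p$filters)
    for (k in seq_len(p$filters)) {
      g <- dpooled[off + k]
      t_star <- cw$amax[k]
      if (g != 0 && cw$r[t_star, k] > 0) {
        dK[, k] <- dK[, k] + g * cw$M[t_star, ]
        db[k] <- db[k] + g
        rows <- t_star + 0:(w - 1L)
        dT[rows, ] <- dT[rows, ] +
          g * matrix(kp$K[, k], w, d, byrow = TRUE)
      }
    }
    dk[[wi]] <- list(dK = dK, db = db)
    off <- off + p$filters
  }
  names(dk) <- names(p$kernels)
  list(dT = dT, dkernels = dk)
}

#' Local (convolutional) feature channel
#'
#' For each kernel width w (an n-gram size) and filter: 1-D valid
#' convolution over positions spanning the full embedding width, ReLU, and
#' max-over-time pooling restricted to windows containing at least one
#' visible position. Pooled features are concatenated in (width, filter)
#' order.
#'
#' @param T_list list of L x d matrices (one per sample), or one matrix.
#' @param params parameters from [init_cnn_params()].
#' @param visibility list of bit vectors (or one vector).
#' @return N x (length(widths) * filters) matrix of local features.
#' @export
cnn_channel <- function(T_list, params, visibility) {
  if (is.matrix(T_list)) { T_list <- list(T_list); visibility <- list(visibility) }
  width_out <- length(params$widths) * params$filters
  t(vapply(seq_along(T_list), function(i)
    chan_cnn_fwd(T_list[[i]], params, visibility[[i]])$out,
    numeric(width_out)))
}

#' Project both channels to a common width
#'
#' Independent learned affine maps bring the global (attention) and local
#' (convolutional) channel outputs to a common width `d_c`, as required
#' before the weighted fusion can add them.
#'
#' @param out_mha N x d matrix of global features.
#' @param out_cnn N x (widths*filters) matrix of local features.
#' @param params list with `Pm` (d x d_c), `bm`, `Pc` (cnn width x d_c), `bc`.
#' @return List of class `tf_channels` with `out_mha`, `out_cnn`
#'   (both N x d_c).
#' @export
project_channels <- function(out_mha, out_cnn, params) {
  pm <- out_mha %*% params$Pm + rep(params$bm, each = nrow(out_mha))
  pc <- out_cnn %*% params$Pc + rep(params$bc, each = nrow(out_cnn))
  structure(list(out_mha = pm, out_cnn = pc), class = "tf_channels")
}

#' Initialize channel projection parameters
#' @param d attention channel width.
#' @param cnn_width convolutional channel width (widths * filters).
#' @param d_c common projected width.
#' @param rng optional seeded generator.
#' @param init_sd initializer standard deviation.
#' @return Parameter list for [project_channels()].
#' @export
init_projection_params <- function(d, cnn_width, d_c, rng = NULL,
                                   init_sd = 0.02) {
  rn <- if (is.null(rng)) function(n) stats::rnorm(n, 0, init_sd)
        else function(n) rng$rnorm(n, 0, init_sd)
  list(Pm = matrix(rn(d * d_c), d, d_c), bm = rep(0, d_c),
       Pc = matrix(rn(cnn_width * d_c), cnn_width, d_c), bc = rep(0, d_c))
}

# ---- fusion -----------------------------------------------------------------

#' Concatenate the two channel outputs
#'
#' @param ch a `tf_channels` (or list with `out_mha`, `out_cnn` of equal
#'   width).
#' @return N x 2*d_c matrix `[out_mha | out_cnn]`, attention channel first.
#' @export
concat_channels <- function(ch) {
  if (ncol(ch$out_mha) != ncol(ch$out_cnn))
    stop("channel widths differ; project to a common width first")
  cbind(ch$out_mha, ch$out_cnn)
}

#' Per-sample channel fusion weights via temperature softmax
#'
#' A learned affine gate maps the concatenated channels to two scores,
#' which a temperature-controlled softmax turns into a row-stochastic
#' (N, 2) weight matrix P: column 1 weights the attention (global) channel,
#' column 2 the convolutional (local) channel. Small `beta` sharpens the
#' weights toward one channel; large `beta` flattens them toward (0.5, 0.5).
#'
#' @param C N x 2*d_c concatenated channel matrix (finite).
#' @param params list with `gate_w` (2*d_c x 2), `gate_b` (length 2), and
#'   temperature `beta` (> 0).
#' @return N x 2 fusion weight matrix P, rows summing to 1.
#' @export
fusion_weights <- function(C, params) {
  if (!all(is.finite(C))) stop("non-finite channel features")
  stopifnot(params$beta > 0)
  g <- C %*% params$gate_w + rep(params$gate_b, each = nrow(C))
  row_softmax(g / params$beta)
}

#' Initialize fusion gate parameters
#'
#' The gate bias starts at zero so that initial fusion weights are close to
#' (0.5, 0.5): no channel is favored before training.
#'
#' @param d_c common channel width.
#' @param beta temperature (> 0), default 0.5.
#' @param rng optional seeded generator.
#' @param init_sd initializer standard deviation.
#' @return Parameter list for [fusion_weights()].
#' @export
init_fusion_params <- function(d_c, beta = 0.5, rng = NULL, init_sd = 0.02) {
  stopifnot(beta > 0)
  rn <- if (is.null(rng)) function(n) stats::rnorm(n, 0, init_sd)
        else function(n) rng$rnorm(n, 0, init_sd)
  list(gate_w = matrix(rn(2 * d_c * 2), 2 * d_c, 2), gate_b = rep(0, 2),
       beta = beta)
}

#' Fuse the channels with per-sample weights
#'
#' Row i of the fused feature H is the convex combination
#' `P[i,1] * out_mha[i,] + P[i,2] * out_cnn[i,]`. The concatenation C is
#' retained for the no-fusion ablation.
#'
#' @param P N x 2 fusion weights from [fusion_weights()].
#' @param ch a `tf_channels`.
#' @return List with `H` (N x d_c) and `C` (N x 2*d_c).
#' @export
fuse <- function(P, ch) {
  if (nrow(P) != nrow(ch$out_mha) || ncol(ch$out_mha) != ncol(ch$out_cnn))
    stop("shape mismatch between fusion weights and channels")
  H <- P[, 1] * ch$out_mha + P[, 2] * ch$out_cnn
  list(H = H, C = concat_channels(ch))
}

# ---- output head ------------------------------------------------------------

#' Inverted dropout
#'
#' In training each entry is zeroed independently with probability `p` and
#' survivors are scaled by `1/(1-p)`, so the map is identity in expectation
#' and evaluation needs no rescaling. In evaluation mode it is the identity.
#'
#' @param H numeric matrix.
#' @param p dropout probability in `[0, 1)`.
#' @param training logical.
#' @param seed optional integer seed (`NULL` = current RNG stream).
#' @return Matrix of the same shape.
#' @export
apply_dropout <- function(H, p, training = TRUE, seed = NULL) {
  if (p < 0 || p >= 1) stop("dropout probability must be in [0, 1)")
  if (!training || p == 0) return(H)
  u <- if (is.null(seed)) stats::runif(length(H))
       else local_rng(seed)$runif(length(H))
  keep <- matrix(u >= p, nrow(H), ncol(H))
  H * keep / (1 - p)
}

#' Affine + softmax classification head
#'
#' @param H_drop N x d_c feature matrix (finite).
#' @param W d_c x K weight matrix.
#' @param b length-K bias vector.
#' @return List with `y` (N x K row-stochastic probability matrix) and
#'   `predicted` (1-based class index per row, lowest-index tie-break).
#' @export
classify <- function(H_drop, W, b) {
  if (!all(is.finite(H_drop))) stop("non-finite head input")
  y <- row_softmax(H_drop %*% W + rep(b, each = nrow(H_drop)))
  list(y = y, predicted = apply(y, 1L, which.max))
}
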