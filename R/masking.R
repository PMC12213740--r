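# Hybrid mask augmentation.
#
# Inputs are routed 70/30 into two branches: n-gram masking hides a
# contiguous span of content tokens (surface token replaced by [MASK],
# visibility bit set to 0), padding masking limits visibility to a fixed
# budget of leading positions. The visibility bit-vector marks which
# positions downstream attention may "recognize" (1) or not (0).

#' Masking configuration
#'
#' @param ngram_ratio fraction of samples routed to the n-gram branch
#'   (default 0.7; the remaining 0.3 get padding masking).
#' @param n span length of the n-gram mask (default 3).
#' @param pad_size fixed sequence capacity L.
#' @param apply_at `"train_only"` (default) or `"always"`.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside a seeded training loop).
#' @return A `tf_maskconfig` list.
#' @export
mask_config <- function(ngram_ratio = 0.7, n = 3L, pad_size = 64L,
                        apply_at = c("train_only", "always"), seed = NULL) {
  stopifnot(ngram_ratio >= 0, ngram_ratio <= 1, n >= 1)
  structure(list(ngram_ratio = ngram_ratio, n = as.integer(n),
                 pad_size = as.integer(pad_size),
                 apply_at = match.arg(apply_at), seed = seed),
            class = "tf_maskconfig")
}

#' Route samples into the two masking branches
#'
#' Exactly `round(ratio * n_samples)` samples go to the n-gram branch; the
#' partition is a uniform random draw, disjoint and exhaustive.
#'
#' @param n_samples number of samples.
#' @param ratio n-gram branch fraction.
#' @param seed optional integer seed (`NULL` = current RNG stream).
#' @return `list(ngram = indices, padding = indices)`.
#' @export
split_branches <- function(n_samples, ratio = 0.7, seed = NULL) {
  stopifnot(ratio >= 0, ratio <= 1)
  if (n_samples == 0L) return(list(ngram = integer(0), padding = integer(0)))
  k <- round(ratio * n_samples)
  idx <- if (is.null(seed)) sample.int(n_samples, n_samples)
         else local_rng(seed)$sample_int(n_samples, n_samples)
  list(ngram = sort(idx[seq_len(k)]),
       padding = sort(idx[setdiff(seq_len(n_samples), seq_len(k))]))
}

#' Visibility bits of an n-gram span mask over raw tokens
#'
#' @param n_tokens number of tokens.
#' @param n span length (clipped to the token range).
#' @param start 0-based span start.
#' @return Integer bit vector of length `n_tokens` (0 = masked).
#' @export
span_mask_bits <- function(n_tokens, n, start) {
  bits <- rep(1L, n_tokens)
  if (n > 0L && n_tokens > 0L) {
    lo <- max(0L, start); hi <- min(n_tokens - 1L, start + n - 1L)
    if (lo <= hi) bits[(lo:hi) + 1L] <- 0L
  }
  bits
}

#' Visibility bits of a padding mask over raw tokens
#'
#' The first `min(n_tokens, pad_size)` positions are visible; overflow
#' positions and appended pads (up to `max(n_tokens, pad_size)` bits in
#' total) carry bit 0.
#'
#' @param n_tokens number of tokens.
#' @param pad_size visibility budget.
#' @return Integer bit vector of length `max(n_tokens, pad_size)`.
#' @export
padding_mask_bits <- function(n_tokens, pad_size) {
  total <- max(n_tokens, pad_size)
  bits <- rep(0L, total)
  if (n_tokens > 0L) bits[seq_len(min(n_tokens, pad_size))] <- 1L
  bits
}

#' Apply an n-gram span mask to an encoded sequence
#'
#' Content positions `start .. start+n-1` (0-based over content tokens;
#' `[CLS]`/`[SEP]` are never masked) are replaced by `[MASK]` and their
#' visibility bits set to 0. Out-of-range spans are clipped. All other real
#' positions keep bit 1; pads have bit 0.
#'
#' @param seq a `tf_tokenseq`.
#' @param n span length (>= 0; 0 is the identity).
#' @param start 0-based start position over content tokens.
#' @return `list(seq = masked tf_tokenseq, visibility = integer bits of
#'   length pad_size)`.
#' @export
apply_ngram_mask <- function(seq, n, start) {
  stopifnot(inherits(seq, "tf_tokenseq"), n >= 0, start >= 0)
  L <- seq$pad_size
  vis <- c(rep(1L, seq$length), rep(0L, L - seq$length))
  n_content <- max(0L, seq$length - 2L)  # exclude [CLS]/[SEP]
  cb <- span_mask_bits(n_content, n, start)
  if (n_content > 0L) {
    masked <- which(cb == 0L) + 1L      # shift past [CLS]
    seq$ids[masked] <- TOK_MASK
    vis[masked] <- 0L
  }
  list(seq = seq, visibility = vis)
}

#' Apply a padding mask to an encoded sequence
#'
#' Visibility is truncated at `pad_size` positions: the first
#' `min(length, pad_size)` real positions are visible, everything beyond
#' (overflow real positions as well as pads) carries bit 0. Token ids are
#' unchanged.
#'
#' @param seq a `tf_tokenseq`.
#' @param pad_size visibility budget (>= 1); defaults to the sequence's own
#'   capacity, under which the mask is the plain real-token indicator.
#' @return `list(seq, visibility)` as in [apply_ngram_mask()].
#' @export
apply_padding_mask <- function(seq, pad_size = seq$pad_size) {
  stopifnot(inherits(seq, "tf_tokenseq"), pad_size >= 1)
  bits <- padding_mask_bits(seq$length, pad_size)
  vis <- integer(seq$pad_size)
  keep <- seq_len(min(length(bits), seq$pad_size))
  vis[keep] <- bits[keep]
  list(seq = seq, visibility = vis)
}

#' Hybrid mask augmentation of a batch
#'
#' Routes the batch 70/30 (per `config$ngram_ratio`) into the n-gram and
#' padding branches via [split_branches()], applies the branch mask to each
#' sample (n-gram spans start uniformly at random over the content range),
#' and recombines in the original order. Outside training (with
#' `apply_at = "train_only"`), masks are the identity: visibility equals
#' the real-token indicator.
#'
#' @param batch list of `tf_tokenseq`.
#' @param config a `tf_maskconfig`.
#' @param training logical; is this a training batch?
#' @return A `tf_maskedbatch`: `list(token_ids (N x L), visibility (N x L),
#'   branch (character))`.
#' @export
augment_batch <- function(batch, config = mask_config(), training = TRUE) {
  stopifnot(length(batch) > 0L)
  N <- length(batch); L <- batch[[1]]$pad_size
  token_ids <- matrix(TOK_PAD, N, L)
  visibility <- matrix(0L, N, L)
  branch <- rep("none", N)
  do_mask <- training || config$apply_at == "always"
  draw <- if (is.null(config$seed)) {
    list(split = function(n, r) split_branches(n, r),
         start = function(k) sample.int(k, 1L) - 1L)
  } else {
    rng <- local_rng(config$seed)
    list(split = function(n, r) {
           k <- round(r * n); idx <- rng$sample_int(n, n)
           list(ngram = sort(idx[seq_len(k)]),
                padding = sort(idx[setdiff(seq_len(n), seq_len(k))]))
         },
         start = function(k) rng$sample_int(k, 1L) - 1L)
  }
  if (do_mask) {
    br <- draw$split(N, config$ngram_ratio)
    for (i in br$ngram) {
      s <- batch[[i]]
      n_content <- max(0L, s$length - 2L)
      start <- if (n_content > 0L) draw$start(n_content) else 0L
      m <- apply_ngram_mask(s, config$n, start)
      token_ids[i, ] <- m$seq$ids; visibility[i, ] <- m$visibility
      branch[i] <- "ngram"
    }
    for (i in br$padding) {
      m <- apply_padding_mask(batch[[i]], config$pad_size)
      token_ids[i, ] <- m$seq$ids; visibility[i, ] <- m$visibility
      branch[i] <- "padding"
    }
  } else {
    for (i in seq_len(N)) {
      s <- batch[[i]]
      token_ids[i, ] <- s$ids
      visibility[i, seq_len(s$length)] <- 1L
    }
  }
  structure(list(token_ids = token_ids, visibility = visibility,
                 branch = branch),
            class = "tf_maskedbatch")
}

#' Worked masking example on raw text
#'
#' Tokenizes raw text (no `[CLS]`/`[SEP]` framing) and prints the masked
#' surface form next to its visibility bit-vector, in the style of the
#' worked n-gram / padding mask tables.
#'
#' @param text raw text.
#' @param n n-gram span length (`NULL` to skip the n-gram mask).
#' @param start 0-based span start.
#' @param pad_size padding-mask budget (`NULL` to skip the padding mask).
#' @return Invisibly, a list with `tokens`, `ngram_bits`, `padding_bits`.
#' @export
mask_demo <- function(text, n = NULL, start = 0L, pad_size = NULL) {
  toks <- tokenize_text(text)
  out <- list(tokens = toks, ngram_bits = NULL, padding_bits = NULL)
  if (!is.null(n)) {
    bits <- span_mask_bits(length(toks), n, start)
    surface <- ifelse(bits == 1L, toks, "#")
    out$ngram_bits <- bits
    cat(sprintf("%d-gram mask : %s | %s\n", n,
                paste(surface, collapse = " "), paste(bits, collapse = "")))
  }
  if (!is.null(pad_size)) {
    bits <- padding_mask_bits(length(toks), pad_size)
    surface <- ifelse(bits == 1L, c(toks, rep("#", max(0L, pad_size - length(toks))))[seq_along(bits)], "#")
    out$padding_bits <- bits
    cat(sprintf("pad size %d  : %s | %s\n", pad_size,
                paste(surface, collapse = " "), paste(bits, collapse = "")))
  }
  invisible(out)
}
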