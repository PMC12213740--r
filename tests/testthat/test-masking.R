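# Hybrid n-gram / padding mask augmentation.

test_that("worked n-gram mask examples give the published bit-vectors", {
  toks <- tokenize_text("I have a headache")
  expect_equal(length(toks), 4L)
  expect_equal(span_mask_bits(4L, 2L, 2L), c(1L, 1L, 0L, 0L))  # "I have ##"
  expect_equal(span_mask_bits(4L, 3L, 1L), c(1L, 0L, 0L, 0L))  # "I ###"
  expect_equal(span_mask_bits(4L, 0L, 0L), rep(1L, 4L))         # identity
  expect_equal(span_mask_bits(4L, 10L, 3L), c(1L, 1L, 1L, 0L))  # clipped
})

test_that("worked padding mask examples give the published bit-vectors", {
  expect_equal(padding_mask_bits(4L, 3L), c(1L, 1L, 1L, 0L))       # "I have a #"
  expect_equal(padding_mask_bits(4L, 5L), c(1L, 1L, 1L, 1L, 0L))   # one pad appended
  expect_equal(padding_mask_bits(4L, 4L), rep(1L, 4L))             # exact fit
})

test_that("branch routing is an exact 70/30 partition", {
  br <- split_branches(1000L, 0.7, seed = 1)
  expect_length(br$ngram, 700L)
  expect_length(br$padding, 300L)
  expect_setequal(c(br$ngram, br$padding), 1:1000)

  br0 <- split_branches(0L, 0.7)
  expect_length(br0$ngram, 0L)
  expect_length(br0$padding, 0L)
  expect_length(split_branches(10L, 1, seed = 1)$ngram, 10L)
})

test_that("sequence-level masks replace tokens and zero visibility together", {
  co <- new_corpus("x", "I have a headache", "l")
  v <- build_vocab(co)
  s <- encode_text("I have a headache", v, 8L)
  m <- apply_ngram_mask(s, 2L, 2L)
  # content positions 3,4 (0-based 2,3) are [MASK]ed; [CLS]/[SEP] untouched
  expect_equal(m$seq$ids[c(1, 6)], c(triagefuse:::TOK_CLS, triagefuse:::TOK_SEP))
  expect_equal(m$seq$ids[4:5], rep(triagefuse:::TOK_MASK, 2))
  expect_equal(m$visibility, c(1L, 1L, 1L, 0L, 0L, 1L, 0L, 0L))

  p <- apply_padding_mask(s, 3L)
  expect_identical(p$seq$ids, s$ids)           # padding mask leaves tokens
  expect_equal(p$visibility, c(1L, 1L, 1L, rep(0L, 5L)))
})

test_that("batch augmentation preserves order, shape and branch counts", {
  co <- generate_corpus(gen_config(default_lexicons(0.002),
                                   target_mean_length = 20, seed = 2))
  v <- build_vocab(co)
  seqs <- lapply(co$documents$text[1:10], encode_text, vocab = v, pad_size = 12L)
  cfg <- mask_config(ngram_ratio = 0.7, n = 3L, pad_size = 12L, seed = 8L)
  mb <- augment_batch(seqs, cfg, training = TRUE)
  expect_equal(dim(mb$token_ids), c(10L, 12L))
  expect_equal(sum(mb$branch == "ngram"), 7L)
  expect_equal(sum(mb$branch == "padding"), 3L)
  # determinism under the config seed
  mb2 <- augment_batch(seqs, cfg, training = TRUE)
  expect_identical(mb, mb2)
  # evaluation mode: visibility equals the real-token indicator
  ev <- augment_batch(seqs, cfg, training = FALSE)
  for (i in 1:10) {
    expect_equal(ev$visibility[i, ],
                 c(rep(1L, seqs[[i]]$length), rep(0L, 12L - seqs[[i]]$length)))
    expect_identical(ev$token_ids[i, ], seqs[[i]]$ids)
  }
})

test_that("masking invariants hold on fuzzed batches", {
  co <- generate_corpus(gen_config(default_lexicons(0.002),
                                   target_mean_length = 15, seed = 6))
  v <- build_vocab(co)
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(2:12, 1); L <- sample(6:20, 1)
    idx <- sample(nrow(co$documents), n)
    seqs <- lapply(co$documents$text[idx], encode_text, vocab = v, pad_size = L)
    nmask <- sample(1:4, 1)
    mb <- augment_batch(seqs, mask_config(0.7, nmask, L), training = TRUE)
    for (i in seq_len(n)) {
      real <- c(rep(1L, seqs[[i]]$length), rep(0L, L - seqs[[i]]$length))
      # masking never reveals pads
      expect_true(all(mb$visibility[i, ] <= real))
      if (mb$branch[i] == "ngram") {
        # zero-bits among real tokens equal the clipped span length
        n_content <- seqs[[i]]$length - 2L
        hidden <- sum(real == 1L & mb$visibility[i, ] == 0L)
        expect_lte(hidden, min(nmask, max(n_content, 0L)))
        expect_gte(hidden, min(nmask, 1L) * (n_content > 0L))
        # [CLS] and [SEP] stay visible
        expect_equal(mb$visibility[i, 1L], 1L)
        expect_equal(mb$visibility[i, seqs[[i]]$length], 1L)
      }
    }
  }
})

test_that("mask_demo prints the published table rows", {
  out <- capture.output(res <- mask_demo("I have a headache", n = 2, start = 2,
                                         pad_size = 3))
  expect_equal(res$ngram_bits, c(1L, 1L, 0L, 0L))
  expect_equal(res$padding_bits, c(1L, 1L, 1L, 0L))
  expect_match(out[1], "1100")
  expect_match(out[2], "1110")
})
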