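# Corpus data model, I/O, splitting, vocabulary and encoding.

test_that("JSONL and CSV corpora round-trip and build the label vocabulary", {
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"id":"r1","text":"chest pain at night","label":"a"}',
    '{"id":"r2","text":"itchy rash on arm","label":"b"}',
    '{"id":"r3","text":"pressure in chest","label":"a"}'), tmp)
  co <- read_corpus(tmp)
  expect_equal(nrow(co$documents), 3L)
  expect_equal(co$labels, c("a", "b"))   # sorted lexicographically, K = 2

  # write -> read is the identity on (id, text, label), both formats
  for (ext in c(".jsonl", ".csv")) {
    out <- withr::local_tempfile(fileext = ext)
    write_corpus(co, out)
    back <- read_corpus(out)
    expect_identical(back$documents[, c("id", "text", "label")],
                     co$documents[, c("id", "text", "label")])
  }
})

test_that("malformed and empty corpus files raise informative errors", {
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"id":"r1","text":"no label here"}', tmp)
  expect_error(read_corpus(tmp), "record 1.*label")

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,text", "r1,some text"), csv)
  expect_error(read_corpus(csv), "label")

  empty <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), empty)
  expect_error(read_corpus(empty), "empty corpus")
})

test_that("stratified split follows 8:1:1 per class and is seed-deterministic", {
  co <- new_corpus(sprintf("d%03d", 1:200),
                   rep("some text here", 200),
                   rep(c("a", "b"), each = 100))
  sp <- split_corpus(co, c(0.8, 0.1, 0.1), seed = 3)
  for (lab in c("a", "b")) {
    ids <- co$documents$id[co$documents$label == lab]
    expect_equal(sum(sp$splits$train %in% ids), 80L)
    expect_equal(sum(sp$splits$val %in% ids), 10L)
    expect_equal(sum(sp$splits$test %in% ids), 10L)
  }
  # disjoint and exhaustive
  all_ids <- c(sp$splits$train, sp$splits$val, sp$splits$test)
  expect_setequal(all_ids, co$documents$id)
  expect_equal(anyDuplicated(all_ids), 0L)
  # deterministic
  sp2 <- split_corpus(co, c(0.8, 0.1, 0.1), seed = 3)
  expect_identical(sp$splits, sp2$splits)

  # per-class proportions preserved within one document at odd sizes
  co3 <- new_corpus(sprintf("e%03d", 1:63), rep("t", 63),
                    rep(c("a", "b", "c"), each = 21))
  sp3 <- split_corpus(co3, seed = 1)
  for (lab in c("a", "b", "c")) {
    ids <- co3$documents$id[co3$documents$label == lab]
    expect_lte(abs(sum(sp3$splits$train %in% ids) - 0.8 * 21), 1)
  }
})

test_that("undersized classes go wholly to train with a warning", {
  co <- new_corpus(c("a1", "a2", "b1", "b2", "b3", "b4"), rep("t", 6),
                   c("a", "a", "b", "b", "b", "b"))
  expect_warning(sp <- split_corpus(co, seed = 1), "wholly in train")
  expect_true(all(c("a1", "a2") %in% sp$splits$train))
})

test_that("vocabulary respects min_count and always carries reserved tokens", {
  co <- new_corpus(c("x", "y"), c("a b", "a c"), c("l1", "l2"))
  v2 <- build_vocab(co, min_count = 2)
  expect_true("a" %in% names(v2))
  expect_false(any(c("b", "c") %in% names(v2)))
  v1 <- build_vocab(co, min_count = 1)
  expect_true(all(c("a", "b", "c") %in% names(v1)))
  for (v in list(v1, v2))
    expect_true(all(c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]") %in% names(v)))
})

test_that("encode_text frames, truncates and pads to the fixed capacity", {
  co <- new_corpus("x", "I have a headache", "l")
  v <- build_vocab(co)
  s <- encode_text("I have a headache", v, pad_size = 8L)
  expect_equal(s$length, 6L)                       # [CLS] + 4 + [SEP]
  expect_equal(sum(s$ids != triagefuse:::TOK_PAD), 6L)
  expect_equal(length(s$ids), 8L)

  long <- encode_text(paste(rep("have", 30), collapse = " "), v, 8L)
  expect_equal(long$length, 8L)
  expect_equal(long$ids[1], triagefuse:::TOK_CLS)  # truncation keeps [CLS]
  expect_equal(long$ids[8], triagefuse:::TOK_SEP)  # trailing [SEP] forced

  s0 <- encode_text("", v, 8L)
  expect_equal(s0$length, 2L)
  expect_equal(s0$ids[1:2], c(triagefuse:::TOK_CLS, triagefuse:::TOK_SEP))

  expect_error(encode_text("x", v, 2L), "pad_size")
})

test_that("non-pad count equals recorded length for fuzzed inputs", {
  co <- generate_corpus(gen_config(default_lexicons(0.002), seed = 4))
  v <- build_vocab(co)
  set.seed(9)
  for (i in sample(nrow(co$documents), 25)) {
    L <- sample(5:40, 1)
    s <- encode_text(co$documents$text[i], v, L)
    expect_equal(sum(s$ids != triagefuse:::TOK_PAD), s$length)
    expect_lte(s$length, L)
  }
})
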