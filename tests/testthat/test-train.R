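# Training loop, ablation switches, evaluation contract, temperature sweep.

make_probe_split <- function(n = 20L, seed = 2L) {
  split_corpus(generate_probe("local", n_per_class = n, seed = seed),
               seed = seed)
}

test_that("the same seed reproduces the training-loss trajectory exactly", {
  co <- make_probe_split()
  cfg <- tiny_config(epochs = 2L)
  f1 <- triagefuse(co, cfg)
  f2 <- triagefuse(co, cfg)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$params, f2$params)
  f3 <- triagefuse(co, tiny_config(epochs = 2L, seed = 6L))
  expect_false(identical(f1$history$loss, f3$history$loss))
})

test_that("fitting does not disturb the caller's RNG stream", {
  co <- make_probe_split()
  set.seed(99); before <- .Random.seed
  invisible(triagefuse(co, tiny_config(epochs = 1L)))
  expect_identical(.Random.seed, before)
})

test_that("every single-component knock-out yields a working model", {
  co <- make_probe_split()
  cfg <- tiny_config(epochs = 1L)
  full <- triagefuse(co, cfg)
  texts <- split_docs(co, "val")$text
  base_probs <- predict(full, texts, type = "prob")
  for (comp in c("hybrid_mask", "textcnn", "mha", "fusion", "temperature")) {
    fit <- triagefuse(co, cfg, ablation = comp)
    probs <- predict(fit, texts, type = "prob")
    expect_equal(dim(probs), dim(base_probs))
    expect_true(all(is.finite(probs)))
    expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
    # head input width adapts to the surviving feature stack
    hin <- nrow(fit$params$head$W)
    expected <- if (comp %in% c("textcnn", "mha")) cfg$d_c
                else if (comp == "fusion") 2L * cfg$d_c else cfg$d_c
    expect_equal(hin, expected)
    if (comp %in% c("textcnn", "mha", "fusion"))
      expect_error(predict(fit, texts, type = "fusion"), "ablated")
  }
  expect_error(triagefuse(co, cfg, c("textcnn", "mha")), "both feature channels")
  expect_error(triagefuse(co, cfg, "nonsense"), "unknown ablation")
})

test_that("evaluation is deterministic, idempotent and rejects unseen labels", {
  co <- make_probe_split()
  fit <- triagefuse(co, tiny_config(epochs = 1L))
  m1 <- evaluate_model(fit, co, "test")
  m2 <- evaluate_model(fit, co, "test")
  expect_identical(m1, m2)
  expect_equal(sum(m1$confusion), length(co$splits$test))
  bad <- new_corpus("z1", "some text", "mystery")
  expect_error(evaluate_model(fit, bad), "unseen in training")
})

test_that("the temperature sweep trains one model per grid point", {
  co <- make_probe_split()
  cfg <- tiny_config(epochs = 1L)
  one <- beta_sweep(co, cfg, grid = 0.5)
  expect_equal(nrow(one), 1L)
  # a single-point sweep reduces to a plain fit at that temperature
  direct <- triagefuse(co, cfg)
  expect_equal(one$val_wf1, direct$best$val_wf1)
  sw <- beta_sweep(co, cfg, grid = c(0.1, 0.5, 2))
  expect_equal(nrow(sw), 3L)
  expect_equal(sw$beta, c(0.1, 0.5, 2))
  expect_true(all(is.finite(sw$val_wf1)))
  expect_error(beta_sweep(co, cfg, grid = numeric(0)))
})

test_that("checkpoints round-trip through save and load", {
  co <- make_probe_split()
  fit <- triagefuse(co, tiny_config(epochs = 1L))
  dir <- withr::local_tempdir()
  save_checkpoint(fit, dir)
  expect_true(file.exists(file.path(dir, "checkpoint.json")))
  back <- load_checkpoint(dir)
  texts <- split_docs(co, "val")$text
  expect_identical(predict(back, texts), predict(fit, texts))
})

test_that("a frozen external encoder can stand behind the adapter contract", {
  co <- make_probe_split()
  cfg <- tiny_config(epochs = 2L, layers = 0L)
  ad <- demo_adapter(cfg$hidden, seed = 3L)
  fit <- triagefuse(co, cfg, adapter = ad)
  texts <- split_docs(co, "val")$text
  probs <- predict(fit, texts, type = "prob")
  expect_true(all(is.finite(probs)))
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
  # adapter states are deterministic and invisible positions are zeroed
  s <- ad(c(3L, 6L, 1L), c(1L, 1L, 0L))
  expect_identical(s, ad(c(3L, 6L, 1L), c(1L, 1L, 0L)))
  expect_true(all(s[3L, ] == 0))
  # refitting with the same adapter reproduces the model exactly
  fit2 <- triagefuse(co, cfg, adapter = ad)
  expect_identical(fit$params, fit2$params)
  # shape violations are caught at the contract boundary
  bad <- function(ids, visibility) matrix(0, 2L, 2L)
  expect_error(triagefuse(co, cfg, adapter = bad), "state matrix")
})
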