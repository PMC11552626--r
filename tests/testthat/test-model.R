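test_that("build_model lays out the network as configured", {
  ab <- phospho_alphabet()
  m <- build_model(model_config(), ab, seed = 1L)
  expect_identical(dim(m$params$E), c(24L, 21L))
  # a length-3 input embeds to a [3, 21] plane
  emb <- modsite:::nn_embed(m$params, matrix(vectorize("ACD", ab), nrow = 1L))
  expect_identical(dim(emb), c(3L, 21L))

  # untrained output strictly inside (0,1)
  tiny <- build_model(tiny_config(), ab, seed = 2L)
  codes <- make_toy_data(20L, 3L, ab)$codes
  p <- predict(tiny, codes)
  expect_true(all(p > 0 & p < 1))

  # determinism of initialization
  m2 <- build_model(model_config(), ab, seed = 1L)
  expect_identical(m$params, m2$params)
  m3 <- build_model(model_config(), ab, seed = 99L)
  expect_false(identical(m$params$Wc, m3$params$Wc))

  expect_error(model_config(k = 5L, conv_kernel = c(7L, 21L)),
               "exceeds the input plane")
  expect_error(model_config(conv_kernel = c(7L, 10L)), "full embedding")
  expect_error(model_config(dropout = 1), "dropout")
})

test_that("training learns the planted rule and early stopping behaves", {
  fit <- train_toy_model(seed = 1L, flip = 0)    # noiseless: separable
  m <- fit$model
  rep <- compute_metrics(predict(m, fit$split$test),
                         fit$split$test$info$label)
  expect_gte(rep$auc, 0.99)
  expect_lte(m$stopped_epoch, m$config$max_epochs)
  expect_true(all(c("epoch", "train_loss", "val_loss") %in%
                    names(m$training_log)))
  if (m$stopped_epoch < m$config$max_epochs) {  # patience triggered
    expect_gte(m$best_epoch, m$stopped_epoch - m$config$patience)
  }
  # best-epoch weights: recorded validation loss at best_epoch is minimal
  expect_equal(m$training_log$val_loss[m$best_epoch],
               min(m$training_log$val_loss))

  # reproducibility of the training trajectory
  fit2 <- train_toy_model(seed = 1L, flip = 0)
  expect_identical(fit2$model$training_log, m$training_log)
  expect_identical(predict(fit2$model, fit$split$test),
                   predict(m, fit$split$test))

  # degenerate inputs
  sp <- make_toy_split(seed = 4L)
  sp$validation <- sp$validation[integer(0)]
  mm <- build_model(tiny_config(), phospho_alphabet(), seed = 1L)
  expect_error(train_model(mm, sp), "validation set is empty")
  sp2 <- make_toy_split(seed = 4L)
  sp2$train <- sp2$train[sp2$train$info$label == 1L]
  expect_error(train_model(mm, sp2), "single-class")
})

test_that("shuffling the mod tokens destroys the labeling advantage", {
  # tokens placed independently of the label: AUC collapses to chance
  fit <- train_toy_model(seed = 6L, flip = 0, shuffle_tokens = TRUE)
  rep <- compute_metrics(predict(fit$model, fit$split$test),
                         fit$split$test$info$label)
  expect_lt(abs(rep$auc - 0.5), 0.15)
})

test_that("prediction is deterministic, order-preserving, and validated", {
  fit <- train_toy_model(seed = 2L)
  m <- fit$model
  codes <- fit$split$test$codes
  p1 <- predict(m, codes)
  expect_identical(p1, predict(m, codes))
  expect_length(p1, nrow(codes))
  # batched == per-item (dropout off at inference)
  singles <- vapply(seq_len(8L), function(i)
    predict(m, codes[i, , drop = FALSE]), numeric(1L))
  expect_equal(singles, p1[1:8], tolerance = 1e-12)
  # window/alphabet mismatches
  expect_error(predict(m, codes[, 1:5]), "does not match model k")
  bad <- codes; bad[1L, 1L] <- 99L
  expect_error(predict(m, bad), "alphabet mismatch")
})

test_that("model archives round-trip bit-identically", {
  fit <- train_toy_model(seed = 3L)
  m <- fit$model
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path, manifest = list(seed = 3L))
  m2 <- load_model(path)
  probe <- fit$split$test$codes[1:20, ]
  expect_identical(predict(m2, probe), predict(m, probe))
  expect_identical(m2$config, m$config)
  # the archive documents the mod-token semantics
  expect_identical(m2$alphabet$mod_map$token, c("@", "&"))
  expect_identical(attr(m2, "manifest")$seed, 3L)

  # k mismatch against supplied windows errors on predict
  expect_error(predict(m2, matrix(0L, 2L, 7L)), "does not match model k")
  # not-an-archive errors
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_model(bad), "not a model archive")
})
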