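test_that("integrated gradients match the linear closed form for any m", {
  m <- linear_logit_model(k = 7L, seed = 3L)
  ab <- m$alphabet
  win <- extract_window("MSKAVLE", 4L, k = 7L, alphabet = ab)

  # independent finite-difference oracle for the (constant) logit gradient
  base <- modsite:::nn_embed(m$params, matrix(win$codes, nrow = 1L))
  logit_of <- function(A) {
    as.vector(modsite:::nn_forward(m$params, m$config, A_flat = A)$z3)
  }
  eps <- 1e-4
  grad_fd <- base * 0
  for (i in seq_len(nrow(base))) for (j in seq_len(ncol(base))) {
    Ap <- base; Ap[i, j] <- Ap[i, j] + eps
    An <- base; An[i, j] <- An[i, j] - eps
    grad_fd[i, j] <- (logit_of(Ap) - logit_of(An)) / (2 * eps)
  }
  xp <- modsite:::nn_embed(m$params, matrix(rep(0L, 7L), nrow = 1L))
  expected <- (base - xp) * grad_fd

  for (mm in c(1L, 5L, 64L)) {
    a <- integrated_gradients(m, win, ig_config(m = mm, output = "logit"))
    expect_lt(max(abs(a$ig - expected)), 1e-6)
    # psig is the exact row sum
    expect_identical(a$psig, rowSums(a$ig))
    # completeness is exact for a linear map
    expect_lt(abs(sum(a$ig) - (a$f_x - a$f_baseline)), 1e-9)
  }
})

test_that("zero attribution when input equals baseline; padding PSIG is 0", {
  fit <- train_toy_model(seed = 2L)
  m <- fit$model
  # window identical to the padding baseline
  a0 <- integrated_gradients(m, rep(0L, m$config$k), ig_config(m = 8L))
  expect_true(all(a0$ig == 0))

  # terminal window: padded positions coincide with the baseline there
  ab <- m$alphabet
  w <- extract_window("STKAV", 1L, k = m$config$k, alphabet = ab)
  aterm <- integrated_gradients(m, w, ig_config(m = 16L))
  padded <- which(strsplit(w$tokens, "")[[1L]] == "-")
  expect_true(length(padded) > 0)
  expect_true(all(aterm$psig[padded] == 0))

  expect_error(ig_config(m = 0L), "m must be")
  expect_error(integrated_gradients(m, rep(0L, 3L)), "does not match")
})

test_that("completeness error decays monotonically with m", {
  fit <- train_toy_model(seed = 1L)
  m <- fit$model
  wins <- dataset_windows(fit$split$test, 1:2)
  for (w in wins) {
    errs <- vapply(c(8L, 32L, 128L, 512L), function(mm) {
      a <- integrated_gradients(m, w, ig_config(m = mm))
      abs(sum(a$ig) - (a$f_x - a$f_baseline))
    }, numeric(1L))
    expect_true(all(diff(errs) < 0))
    expect_lte(errs[4L], 1e-3)
  }
})

test_that("K-means recovers planted attribution populations", {
  k <- 9L; d <- 4L
  mk_attr <- function(center, seed) {
    ig <- withr::with_seed(seed, matrix(rnorm(k * d, center, 0.1), k, d))
    structure(list(ig = ig, psig = rowSums(ig), f_x = 0.5, f_baseline = 0.5,
                   window = NULL), class = "attribution")
  }
  pop <- c(lapply(1:15, function(i) mk_attr(0, i)),
           lapply(1:15, function(i) mk_attr(3, 100 + i)))
  cl <- cluster_attributions(pop, n_clusters = 2L, seed = 5L)
  truth <- rep(1:2, each = 15L)
  acc <- max(mean(cl$assignments == truth), mean(cl$assignments == 3L - truth))
  expect_gt(acc, 0.95)
  expect_identical(dim(cl$centroid_psig), c(2L, k))
  expect_identical(dim(cl$embedding_2d), c(30L, 2L))
  expect_true(all(cl$elbow$inertia >= 0))

  # determinism
  cl2 <- cluster_attributions(pop, n_clusters = 2L, seed = 5L)
  expect_identical(cl$assignments, cl2$assignments)
  expect_error(cluster_attributions(pop[1:3], n_clusters = 10L), "fewer")
})

test_that("frequency matrices count tokens at offsets and conserve totals", {
  ab <- phospho_alphabet()
  k <- 25L
  win <- extract_window(strrep("A", 30L), 15L, k = k, alphabet = ab)
  wins <- rep(list(win), 5L)
  fake <- structure(list(assignments = rep(1L, 5L), n_clusters = 1L),
                    class = "attribution_clusters")
  fm <- cluster_frequency_matrix(fake, 1L, wins, ab, flank = 10L)
  expect_identical(dim(fm), c(ab$vocab_size, 21L))
  expect_true(all(colSums(fm) == 5L))
  expect_true(all(apply(fm, 2L, function(col) sum(col > 0L)) == 1L))
  expect_error(cluster_frequency_matrix(fake, 2L, wins, ab), "empty")

  # mixed windows: column sums still equal cluster size; mod tokens counted
  sim_wins <- lapply(1:6, function(i) {
    s <- withr::with_seed(i, paste(
      sample(c(modsite:::AA_CANONICAL, "@"), 25L, replace = TRUE),
      collapse = ""))
    structure(list(tokens = s, codes = vectorize(s, ab), center_index = 13L,
                   origin = NULL), class = "encoded_window")
  })
  fake6 <- structure(list(assignments = rep(1L, 6L), n_clusters = 1L),
                     class = "attribution_clusters")
  fm6 <- cluster_frequency_matrix(fake6, 1L, sim_wins, ab, flank = 10L)
  expect_true(all(colSums(fm6) == 6L))
  expect_true("@" %in% rownames(fm6))
})

test_that("the mod token dominates attributions on the planted toy task", {
  fit <- train_toy_model(seed = 7L, flip = 0)
  m <- fit$model
  te <- fit$split$test
  pos_idx <- which(te$info$label == 1L)[1:10]
  atts <- attribute_dataset(m, te, ig_config(m = 32L), indices = pos_idx)
  ci <- (m$config$k + 1L) %/% 2L
  # position of the planted "@" (offset -2) carries the largest |PSIG|
  mean_abs <- rowMeans(sapply(atts, function(a) abs(a$psig)))
  expect_equal(which.max(mean_abs), ci - 2L)
})
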