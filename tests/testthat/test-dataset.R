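test_that("enumerate_candidates emits one record per target residue", {
  ds <- enumerate_candidates(c(p = "ASTSA"), c("S", "T"),
                             positives = data.frame(protein_id = "p",
                                                    position = 2L),
                             k = 5L)
  expect_equal(length(ds), 3L)
  expect_identical(ds$info$position, c(2L, 3L, 4L))
  expect_identical(ds$info$label, c(1L, 0L, 0L))

  ds0 <- enumerate_candidates(c(p = "ASTSA"), c("S", "T"), k = 5L)
  expect_true(all(ds0$info$label == 0L))

  expect_error(
    enumerate_candidates(c(p = "ASTSA"), c("S", "T"),
                         positives = data.frame(protein_id = "p",
                                                position = 5L), k = 5L),
    "non-target")
})

test_that("enumeration count and window content match a brute-force scan", {
  sim <- simulate_proteome(small_sim_spec(seed = 21L))
  ch <- sim$channel
  ab <- build_alphabet(list(ch))
  ds <- enumerate_candidates(sim$sequences, c("S", "T"), sim$positives,
                             list(ch), k = 11L, alphabet = ab)
  # independent count oracle
  n_expected <- sum(vapply(sim$sequences, function(s) {
    sum(strsplit(s, "")[[1L]] %in% c("S", "T"))
  }, numeric(1L)))
  expect_equal(length(ds), n_expected)
  expect_equal(sum(ds$info$label), nrow(sim$positives))

  # spot-check windows against extract_window on the labeled sequence
  withr::with_seed(2, idx <- sample(length(ds), 10L))
  for (i in idx) {
    pid <- ds$info$protein_id[i]
    lab <- apply_labels(sim$sequences[[pid]], list(ch), ab, pid)
    w <- extract_window(lab, ds$info$position[i], k = 11L, alphabet = ab,
                        center_residue = ds$info$residue[i])
    expect_identical(ds$tokens[i], w$tokens)
    expect_identical(ds$codes[i, ], w$codes)
  }
})

test_that("balance_negatives forces equal class counts deterministically", {
  ab <- build_alphabet()
  mk <- function(n_pos, n_neg) {
    n <- n_pos + n_neg
    codes <- matrix(withr::with_seed(8, sample(0:21, n * 5L, TRUE)), n, 5L)
    codes_to_dataset(codes, c(rep(1L, n_pos), rep(0L, n_neg)), 5L, ab)
  }
  b <- balance_negatives(mk(10L, 1000L), seed = 4L)
  expect_equal(length(b), 20L)
  expect_equal(sum(b$info$label), 10L)
  expect_equal(mean(b$info$label), 0.5)

  expect_warning(b2 <- balance_negatives(mk(10L, 4L), seed = 4L),
                 "keeping all negatives")
  expect_equal(length(b2), 14L)

  expect_identical(balance_negatives(mk(10L, 1000L), seed = 4L)$info,
                   b$info)
  expect_false(identical(balance_negatives(mk(10L, 1000L), seed = 5L)$info,
                         b$info))
  expect_error(balance_negatives(mk(10L, 1000L)[11:30], seed = 1L),
               "no positive")
  # skip flag reproduces the already-balanced exception
  expect_equal(length(balance_negatives(mk(10L, 1000L), seed = 4L,
                                        skip = TRUE)), 1010L)
})

test_that("split_dataset gives 80/10/10 with disjoint partitions", {
  sim <- simulate_proteome(simulation_spec(n_proteins = 60L,
                                           length_range = c(80L, 160L),
                                           base_rate = 0.1, seed = 31L))
  ds <- enumerate_candidates(sim$sequences, c("S", "T"), sim$positives,
                             k = 11L)
  n <- length(ds)
  sp <- split_dataset(ds, seed = 7L)
  expect_lte(abs(length(sp$validation) - round(0.1 * n)), 2L)
  # test may shrink by exact-duplicate removal
  expect_lte(length(sp$test), round(0.1 * n))
  expect_gte(length(sp$test), round(0.1 * n) - 2L - sp$n_exact_removed)
  key <- function(d) paste(d$info$protein_id, d$info$position)
  expect_length(intersect(key(sp$train), key(sp$validation)), 0L)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  expect_length(intersect(key(sp$validation), key(sp$test)), 0L)
  expect_equal(length(sp$train) + length(sp$validation) + length(sp$test) +
                 sp$n_exact_removed, n)
  # no test window duplicates a train/validation window
  expect_length(intersect(sp$test$tokens,
                          c(sp$train$tokens, sp$validation$tokens)), 0L)
  # determinism
  sp2 <- split_dataset(ds, seed = 7L)
  expect_identical(sp2$test$info, sp$test$info)
})

test_that("identity_filter matches the quadratic oracle and is monotone", {
  ab <- phospho_alphabet()
  k <- 53L
  withr::with_seed(11, {
    n <- 200L
    codes <- matrix(sample(0:23, n * k, TRUE), n, k)
    # plant near-duplicates across the train/test boundary
    codes[181L, ] <- codes[1L, ]                       # exact duplicate
    codes[182L, ] <- codes[2L, ]
    codes[182L, sample(k, 20L)] <- sample(0:23, 20L, TRUE)
    codes[183L, ] <- codes[3L, ]
    flip <- sample(k, 32L)                             # exactly 32 mismatches
    codes[183L, flip] <- (codes[183L, flip] + 1L) %% 24L
  })
  ds <- codes_to_dataset(codes, rep(c(1L, 0L), length.out = 200L), k, ab)
  sp <- structure(list(train = ds[1:160], validation = ds[161:180],
                       test = ds[181:200], seed = 1L,
                       ratios = c(0.8, 0.1, 0.1), n_exact_removed = 0L),
                  class = "dataset_split")

  f1 <- identity_filter(sp, cutoff = 1.0)
  expect_false(ds$tokens[181L] %in% f1$test$tokens)

  f40 <- identity_filter(sp, cutoff = 0.40)
  pool <- c(sp$train$tokens, sp$validation$tokens)
  drop_oracle <- brute_identity_drop(sp$test$tokens, pool, 0.40)
  expect_identical(setdiff(sp$test$tokens, f40$test$tokens),
                   unique(sp$test$tokens[drop_oracle]))
  expect_equal(attr(f40, "n_removed"), sum(drop_oracle))

  # two windows differing at 32 of 53 positions: identity 21/53 < 0.40, kept
  a <- strsplit(ds$tokens[3L], "")[[1L]]
  b <- strsplit(ds$tokens[183L], "")[[1L]]
  expect_equal(sum(a == b), 21L)
  expect_true(ds$tokens[183L] %in% f40$test$tokens)

  # monotonicity: lower cutoff removes a superset
  removed <- function(cut) setdiff(sp$test$tokens,
                                   identity_filter(sp, cut)$test$tokens)
  r3 <- removed(0.3); r5 <- removed(0.5); r8 <- removed(0.8)
  expect_true(all(r5 %in% r3))
  expect_true(all(r8 %in% r5))

  expect_error(identity_filter(sp, 0), "cutoff")
  expect_error(identity_filter(sp, 1.2), "cutoff")
})

test_that("Monte Carlo folds resample negatives and splits independently", {
  sim <- simulate_proteome(small_sim_spec(seed = 41L))
  ds <- enumerate_candidates(sim$sequences, c("S", "T"), sim$positives,
                             k = 11L)
  folds <- monte_carlo_resample(ds, n_folds = 3L, seed = 2L)
  expect_length(folds, 3L)
  key <- function(d) paste(d$info$protein_id, d$info$position)
  expect_false(identical(sort(key(folds[[1L]]$test)),
                         sort(key(folds[[2L]]$test))))
  for (sp in folds) {
    expect_equal(mean(c(sp$train$info$label, sp$validation$info$label,
                        sp$test$info$label)), 0.5, tolerance = 0.02)
    # re-applying the exact-identity guarantee removes nothing further
    expect_equal(attr(identity_filter(sp, 1.0), "n_removed"), 0L)
  }
})
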