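test_that("base alphabet fixes the code assignment", {
  ab <- build_alphabet()
  expect_equal(ab$vocab_size, 22L)
  expect_identical(unname(ab$index["-"]), 0L)
  expect_identical(vectorize("ACD", ab), c(1L, 2L, 3L))
  expect_identical(unname(ab$index["U"]), 21L)
  # bijection onto 0..vocab-1
  expect_setequal(unname(ab$index), 0:(ab$vocab_size - 1L))
  expect_false(anyDuplicated(ab$tokens) > 0)
  # canonical residues alphabetical on 1..20
  expect_identical(unname(ab$index[AA_CANONICAL <- modsite:::AA_CANONICAL]),
                   1:20)
})

test_that("mod tokens are assigned per residue class, capped at two", {
  ab <- phospho_alphabet()
  expect_equal(ab$vocab_size, 24L)
  expect_identical(ab$mod_map$token, c("@", "&"))
  expect_identical(ab$mod_map$residue, c("S", "T"))
  expect_identical(unname(ab$index[c("@", "&")]), c(22L, 23L))

  # single-token mode collapses a two-residue channel onto "@"
  ab1 <- build_alphabet(list(phospho_channel()), per_residue_tokens = FALSE)
  expect_equal(ab1$vocab_size, 23L)
  expect_identical(unique(ab1$mod_map$token), "@")

  # a third residue class exceeds the symbol budget, error names channels
  ch2 <- label_channel("ubiquitin-K", "K")
  expect_error(build_alphabet(list(phospho_channel(), ch2)),
               "phospho-ST")
  expect_error(build_alphabet(list(phospho_channel(), ch2)), "ubiquitin-K")
})

test_that("apply_labels substitutes exactly the listed sites", {
  ab <- phospho_alphabet()
  ch <- phospho_channel(c(2L, 4L))
  expect_identical(apply_labels("ASDTK", list(ch), ab), "A@D&K")
  expect_identical(apply_labels("ASDTK", list(phospho_channel()), ab),
                   "ASDTK")
  expect_error(apply_labels("ASDTK", list(phospho_channel(3L)), ab),
               "position 3.*residue 'D'|'D', not")

  # property: changes exactly |sites| positions, never the length
  withr::with_seed(42, {
    for (rep in 1:20) {
      n <- sample(20:60, 1L)
      seq_u <- paste(sample(modsite:::AA_CANONICAL, n, replace = TRUE),
                     collapse = "")
      st <- which(strsplit(seq_u, "")[[1L]] %in% c("S", "T"))
      if (length(st) == 0L) next
      n_pick <- min(length(st), sample(1:4, 1L))
      sites <- sort(st[sample.int(length(st), n_pick)])
      lab <- apply_labels(seq_u, list(phospho_channel(sites)), ab)
      expect_equal(nchar(lab), n)
      diff <- which(strsplit(lab, "")[[1L]] != strsplit(seq_u, "")[[1L]])
      expect_identical(diff, as.integer(sites))
    }
  })
})

test_that("extract_window pads, masks the center, and errors on bad input", {
  ab <- phospho_alphabet()
  w <- extract_window("MSK", 2L, k = 5L, alphabet = ab)
  expect_identical(w$tokens, "-MSK-")
  expect_identical(w$codes, vectorize("-MSK-", ab))
  expect_equal(w$center_index, 3L)

  # interior window of length 53: covers center +/- 26, no padding
  seq100 <- withr::with_seed(9, paste(
    sample(modsite:::AA_CANONICAL, 100, replace = TRUE), collapse = ""))
  w2 <- extract_window(seq100, 50L, k = 53L, alphabet = ab)
  expect_identical(w2$tokens, substr(seq100, 24L, 76L))
  expect_equal(nchar(w2$tokens), 53L)

  # center masking: the queried site is emitted unlabeled, neighbors keep
  # their mod tokens
  w3 <- extract_window("A@D&K", 2L, k = 5L, alphabet = ab,
                       center_residue = "S")
  expect_identical(w3$tokens, "-ASD&")
  # per-residue tokens make the center residue recoverable without help
  w4 <- extract_window("A@D&K", 4L, k = 5L, alphabet = ab)
  expect_identical(substr(w4$tokens, 3L, 3L), "T")
  expect_identical(substr(w4$tokens, 1L, 1L), "@")

  expect_error(extract_window("MSK", 2L, k = 4L, alphabet = ab), "odd")
  expect_error(extract_window("MSK", 9L, k = 5L, alphabet = ab),
               "out of range")
})

test_that("vectorize/devectorize round-trip and report unknown tokens", {
  ab <- phospho_alphabet()
  expect_identical(vectorize("-", ab), 0L)
  expect_error(vectorize("AC?D", ab), "'\\?' at position 3")
  withr::with_seed(7, {
    for (rep in 1:25) {
      s <- paste(sample(ab$tokens, 53L, replace = TRUE), collapse = "")
      expect_identical(devectorize(vectorize(s, ab), ab), s)
    }
  })
  expect_error(devectorize(c(0L, 99L), ab), "out of range")
})

test_that("non-standard residues normalize to '-' unless strict", {
  expect_warning(out <- normalize_sequence("AXSBZ"), "normalized")
  expect_identical(out, "A-S--")
  expect_error(normalize_sequence("AXS", strict = TRUE), "non-standard")
  expect_silent(normalize_sequence("ACDST"))
})
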