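# Shared fixtures and independent oracles. Everything is generated in code;
# no binary data.

phospho_channel <- function(sites = list()) {
  label_channel("phospho-ST", c("S", "T"), sites)
}

phospho_alphabet <- function() build_alphabet(list(phospho_channel()))

tiny_config <- function(k = 11L, ...) {
  model_config(k = k, conv_filters = 16L, conv_kernel = c(3L, 21L),
               pool_size = 2L, dense_units = c(16L, 1L), max_epochs = 50L,
               ...)
}

# planted-rule toy task: positive iff "@" two positions N-terminal of the
# center; `flip` adds label noise so trained models stay realistically
# calibrated rather than saturated
make_toy_data <- function(n, seed, alphabet, k = 11L, flip = 0.15,
                          shuffle_tokens = FALSE) {
  withr::with_seed(seed, {
    codes <- matrix(sample(1:21, n * k, replace = TRUE), n, k)
    ci <- (k + 1L) %/% 2L
    codes[, ci] <- unname(alphabet$index["S"])
    y <- stats::rbinom(n, 1L, 0.5)
    at <- unname(alphabet$index["@"])
    if (shuffle_tokens) {
      codes[stats::runif(n) < 0.5, ci - 2L] <- at
    } else {
      codes[y == 1L, ci - 2L] <- at
    }
    if (flip > 0) {
      fl <- stats::runif(n) < flip
      y[fl] <- 1L - y[fl]
    }
    list(codes = codes, y = y)
  })
}

codes_to_dataset <- function(codes, y, k, alphabet) {
  tokens <- apply(codes, 1L, function(r) devectorize(r, alphabet))
  modsite:::new_site_dataset(
    data.frame(protein_id = "toy", position = seq_along(y), residue = "S",
               label = as.integer(y), stringsAsFactors = FALSE),
    tokens, codes, k, alphabet)
}

make_toy_split <- function(seed = 1L, n_train = 400L, k = 11L, flip = 0.15,
                           shuffle_tokens = FALSE) {
  ab <- phospho_alphabet()
  mk <- function(n, s) {
    d <- make_toy_data(n, s, ab, k = k, flip = flip,
                       shuffle_tokens = shuffle_tokens)
    codes_to_dataset(d$codes, d$y, k, ab)
  }
  structure(list(train = mk(n_train, seed),
                 validation = mk(n_train %/% 5L, seed + 1L),
                 test = mk(n_train %/% 5L, seed + 2L),
                 seed = seed, ratios = c(0.8, 0.1, 0.1),
                 n_exact_removed = 0L),
            class = "dataset_split")
}

train_toy_model <- function(seed = 1L, flip = 0.15, shuffle_tokens = FALSE) {
  split <- make_toy_split(seed = seed, flip = flip,
                          shuffle_tokens = shuffle_tokens)
  m <- build_model(tiny_config(), split$train$alphabet, seed = seed)
  list(model = train_model(m, split, seed = seed), split = split)
}

# a model whose logit is exactly affine in the embedded input: kernel height
# 1, pool size 1, every ReLU pushed into its identity regime
linear_logit_model <- function(k = 7L, seed = 3L) {
  ab <- build_alphabet()
  cfg <- model_config(k = k, conv_filters = 3L, conv_kernel = c(1L, 21L),
                      pool_size = 1L, dense_units = c(4L, 1L), dropout = 0)
  m <- build_model(cfg, ab, seed = seed)
  m$params$bc <- m$params$bc + 50
  m$params$bd1 <- m$params$bd1 + 50 * colSums(abs(m$params$Wd1)) + 50
  m
}

# ---- independent oracles -------------------------------------------------

# O(n^2) Mann-Whitney concordance count, ties credited 1/2
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# quadratic all-pairs identity scan: which test windows have >= cutoff
# fractional identity to any pool window
brute_identity_drop <- function(test_tokens, pool_tokens, cutoff) {
  vapply(test_tokens, function(tt) {
    a <- strsplit(tt, "")[[1L]]
    for (pt in pool_tokens) {
      b <- strsplit(pt, "")[[1L]]
      if (sum(a == b) / length(a) >= cutoff) return(TRUE)
    }
    FALSE
  }, logical(1L), USE.NAMES = FALSE)
}

# nested-loop recount of nearby known sites at each signed offset
brute_proximity <- function(info, channel, w) {
  offsets <- setdiff(seq(-w, w), 0L)
  counts <- stats::setNames(rep(0L, length(offsets)), offsets)
  for (r in seq_len(nrow(info))) {
    pid <- info$protein_id[r]
    center <- info$position[r]
    for (s in (channel$sites[[pid]] %||% integer(0))) {
      d <- s - center
      if (d != 0L && abs(d) <= w) {
        counts[as.character(d)] <- counts[as.character(d)] + 1L
      }
    }
  }
  unname(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_sim_spec <- function(seed = 5L, ...) {
  simulation_spec(n_proteins = 50L, length_range = c(80L, 160L),
                  base_rate = 0.1, seed = seed, ...)
}
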