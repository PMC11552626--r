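# Candidate-site enumeration, negative balancing, identity-aware splitting,
# and Monte Carlo resampling.

new_site_dataset <- function(info, tokens, codes, k, alphabet) {
  rownames(codes) <- NULL
  structure(list(info = info, tokens = tokens, codes = codes,
                 k = as.integer(k), alphabet = alphabet),
            class = "site_dataset")
}

#' @export
print.site_dataset <- function(x, ...) {
  cat(sprintf("site_dataset: %d records (%d positive), k = %d\n",
              nrow(x$info), sum(x$info$label), x$k))
  invisible(x)
}

#' Subset a site dataset by record index
#' @param x A `site_dataset`.
#' @param i Integer or logical index.
#' @param ... Ignored.
#' @export
`[.site_dataset` <- function(x, i, ...) {
  new_site_dataset(x$info[i, , drop = FALSE], x$tokens[i],
                   x$codes[i, , drop = FALSE], x$k, x$alphabet)
}

#' Number of records in a site dataset
#' @param x A `site_dataset`.
#' @export
length.site_dataset <- function(x) nrow(x$info)

positives_to_list <- function(positives) {
  if (is.null(positives)) return(list())
  if (is.data.frame(positives)) {
    return(lapply(split(as.integer(positives$position),
                        as.character(positives$protein_id)),
                  function(p) sort(unique(p))))
  }
  lapply(positives, function(p) sort(unique(as.integer(p))))
}

#' Enumerate every candidate site as a labeled, windowed record
#'
#' One record is emitted per occurrence of a target residue in the supplied
#' proteins (the "proteins with the PTM" negative universe). Windows are
#' built by substituting known-site mod tokens ([apply_labels()]) and then
#' extracting the centered k-mer with the center emitted unlabeled
#' ([extract_window()] semantics, vectorized).
#'
#' @param proteins Named character vector of unlabeled residue strings.
#' @param residue_targets Residues at which the PTM can occur.
#' @param positives Positive sites: data.frame(protein_id, position) or named
#'   list of positions. Every positive must sit on a target residue.
#' @param channels Label channels to encode in the windows (possibly empty).
#' @param k Odd window length.
#' @param alphabet `mod_alphabet`; built from `channels` when `NULL`.
#' @return A `site_dataset`: record table (`info`), window token strings
#'   (`tokens`) and an integer code matrix (`codes`, n x k).
#' @export
enumerate_candidates <- function(proteins, residue_targets, positives = NULL,
                                 channels = list(), k = 53L,
                                 alphabet = NULL) {
  if (inherits(channels, "label_channel")) channels <- list(channels)
  if (is.null(alphabet)) alphabet <- build_alphabet(channels)
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("window length k must be odd, got ", k)
  w <- (k - 1L) %/% 2L
  pos_list <- positives_to_list(positives)

  unknown <- setdiff(names(pos_list), names(proteins))
  if (length(unknown)) {
    stop("positives reference proteins absent from input: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }

  per_protein <- lapply(names(proteins), function(pid) {
    seq_u <- proteins[[pid]]
    chars <- strsplit(seq_u, "", fixed = TRUE)[[1L]]
    centers <- which(chars %in% residue_targets)
    pp <- pos_list[[pid]] %||% integer(0)
    if (length(bad <- setdiff(pp, centers))) {
      stop("positive site at non-target residue: protein '", pid,
           "' position ", bad[1L], " ('", chars[bad[1L]], "')")
    }
    if (length(centers) == 0L) return(NULL)
    labeled <- apply_labels(seq_u, channels, alphabet, protein_id = pid)
    lchars <- strsplit(labeled, "", fixed = TRUE)[[1L]]
    padded <- c(rep(PAD_TOKEN, w), lchars, rep(PAD_TOKEN, w))
    idx <- outer(centers - 1L, 0L:(k - 1L), "+") + 1L   # rows: centers
    winmat <- matrix(padded[idx], nrow = length(centers))
    winmat[, w + 1L] <- chars[centers]                  # center masking
    codes <- matrix(unname(alphabet$index[winmat]), nrow = nrow(winmat))
    list(info = data.frame(protein_id = pid, position = centers,
                           residue = chars[centers],
                           label = as.integer(centers %in% pp),
                           stringsAsFactors = FALSE),
         tokens = apply(winmat, 1L, paste0, collapse = ""),
         codes = codes)
  })
  per_protein <- Filter(Negate(is.null), per_protein)
  if (length(per_protein) == 0L) {
    return(new_site_dataset(
      data.frame(protein_id = character(0), position = integer(0),
                 residue = character(0), label = integer(0)),
      character(0), matrix(integer(0), 0L, k), k, alphabet))
  }
  new_site_dataset(do.call(rbind, lapply(per_protein, `[[`, "info")),
                   unlist(lapply(per_protein, `[[`, "tokens"),
                          use.names = FALSE),
                   do.call(rbind, lapply(per_protein, `[[`, "codes")),
                   k, alphabet)
}

#' Subsample negatives to match the positive count
#'
#' Keeps all positives and a uniform random subsample of negatives of equal
#' size. When fewer negatives than positives exist, all negatives are kept
#' with a warning. `skip = TRUE` reproduces the already-balanced exception
#' (e.g. sequon-restricted N-glycosylation data) and returns the input.
#'
#' @param ds A `site_dataset`.
#' @param seed Integer seed; the subsample is a pure function of it.
#' @param skip Skip balancing entirely.
#' @return Balanced `site_dataset` (records in original order).
#' @export
balance_negatives <- function(ds, seed, skip = FALSE) {
  if (skip) return(ds)
  lab <- ds$info$label
  n_pos <- sum(lab == 1L)
  if (n_pos == 0L) stop("no positive records: nothing to train on")
  neg_idx <- which(lab == 0L)
  if (length(neg_idx) < n_pos) {
    warning("only ", length(neg_idx), " negatives for ", n_pos,
            " positives; keeping all negatives")
    return(ds)
  }
  keep_neg <- withr::with_seed(seed, sample(neg_idx, n_pos))
  ds[sort(c(which(lab == 1L), keep_neg))]
}

#' Randomly split records 80/10/10 into train/validation/test
#'
#' Validation and test sizes are `round(n * ratio)`; the remainder trains.
#' After splitting, any test record whose window token-string is identical to
#' a train or validation window is dropped (the always-on exact-identity
#' guarantee).
#'
#' @param ds A `site_dataset`.
#' @param ratios Train/validation/test fractions summing to 1.
#' @param seed Integer seed.
#' @return A `dataset_split`: list with `train`, `validation`, `test`
#'   (site datasets), `seed`, `ratios`, `n_exact_removed`.
#' @export
split_dataset <- function(ds, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-8)
  n <- length(ds)
  if (n < 10L) stop("need at least 10 records to split, got ", n)
  n_val <- round(n * ratios[2L])
  n_test <- round(n * ratios[3L])
  if (n_val < 1L || n_test < 1L || n - n_val - n_test < 1L) {
    stop("split ratios leave an empty partition for n = ", n)
  }
  perm <- withr::with_seed(seed, sample.int(n))
  test_idx <- perm[seq_len(n_test)]
  val_idx <- perm[n_test + seq_len(n_val)]
  train_idx <- perm[(n_test + n_val + 1L):n]
  sp <- structure(list(train = ds[sort(train_idx)],
                       validation = ds[sort(val_idx)],
                       test = ds[sort(test_idx)],
                       seed = seed, ratios = ratios,
                       n_exact_removed = 0L),
                  class = "dataset_split")
  identity_filter(sp, cutoff = 1.0)
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf(
    "dataset_split: %d train / %d validation / %d test (seed %d, %d exact dups removed)\n",
    length(x$train), length(x$validation), length(x$test), x$seed,
    x$n_exact_removed))
  invisible(x)
}

# fraction of identical positions between each test window and its closest
# train/validation window; ungapped, position-wise, mod tokens distinct
max_identity_to_pool <- function(test_codes, pool_codes) {
  k <- ncol(test_codes)
  n1 <- nrow(test_codes); n2 <- nrow(pool_codes)
  if (n1 == 0L || n2 == 0L) return(numeric(n1))
  acc <- matrix(0L, n1, n2)
  for (j in seq_len(k)) {
    acc <- acc + outer(test_codes[, j], pool_codes[, j], "==")
  }
  apply(acc, 1L, max) / k
}

#' Remove test records too similar to train/validation windows
#'
#' At `cutoff = 1.0` removes exact window duplicates (string equality). At
#' `cutoff < 1` removes any test record whose window has at least `cutoff`
#' fractional identity (matching positions / k, ungapped, position-wise; a
#' mod token matches only itself) to any train or validation window.
#'
#' @param split A `dataset_split`.
#' @param cutoff Identity threshold in (0, 1].
#' @return The filtered `dataset_split`; `n_removed` attribute and updated
#'   `n_exact_removed` field report the removal count.
#' @export
identity_filter <- function(split, cutoff = 1.0) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1) {
    stop("cutoff must be in (0, 1], got ", cutoff)
  }
  pool_tokens <- c(split$train$tokens, split$validation$tokens)
  if (cutoff == 1.0) {
    drop <- split$test$tokens %in% pool_tokens
  } else {
    pool_codes <- rbind(split$train$codes, split$validation$codes)
    drop <- max_identity_to_pool(split$test$codes, pool_codes) >= cutoff
  }
  n_removed <- sum(drop)
  if (n_removed > 0L) split$test <- split$test[!drop]
  split$n_exact_removed <- split$n_exact_removed +
    if (cutoff == 1.0) n_removed else 0L
  attr(split, "n_removed") <- n_removed
  split
}

#' Resample balanced splits for Monte Carlo cross-validation
#'
#' Each fold draws a fresh negative subsample and a fresh random 80/10/10
#' split, per the Monte Carlo protocol (resplit, retrain, retest; report
#' mean and standard deviation over folds).
#'
#' @param ds Unbalanced `site_dataset` (all candidates).
#' @param n_folds Number of folds (default 10).
#' @param seed Base integer seed; fold seeds are derived deterministically.
#' @param ratios Split ratios.
#' @param balance Draw a fresh balanced negative subsample each fold.
#' @return List of `dataset_split`, one per fold; fold seeds attached as
#'   attribute `fold_seeds`.
#' @export
monte_carlo_resample <- function(ds, n_folds = 10L, seed = 1L,
                                 ratios = c(0.8, 0.1, 0.1), balance = TRUE) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 1L) stop("n_folds must be >= 1")
  if (length(ds) < 10L * n_folds / n_folds) {
    stop("too few records (", length(ds), ") for splitting")
  }
  fold_seeds <- as.integer(seed) + 7919L * seq_len(n_folds)
  splits <- lapply(fold_seeds, function(s) {
    dsf <- if (balance) balance_negatives(ds, seed = s) else ds
    split_dataset(dsf, ratios = ratios, seed = s + 104729L)
  })
  attr(splits, "fold_seeds") <- fold_seeds
  splits
}
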