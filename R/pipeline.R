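# End-to-end workflows: train-your-own-model (TYOM), prediction over FASTA
# input, and the paired labeled-versus-unlabeled comparison.

log_stage <- function(stage, ...) {
  if (isTRUE(getOption("modsite.verbose", FALSE))) {
    message(sprintf("[%s] %s", stage, sprintf(...)))
  }
}

#' Reconstruct the encoded windows of a site dataset
#' @param ds A `site_dataset`.
#' @param indices Record indices (default all).
#' @return List of `encoded_window`.
#' @export
dataset_windows <- function(ds, indices = seq_len(length(ds))) {
  ci <- (ds$k + 1L) %/% 2L
  lapply(indices, function(i) {
    structure(list(tokens = ds$tokens[i], codes = ds$codes[i, ],
                   center_index = ci,
                   origin = list(protein_id = ds$info$protein_id[i],
                                 position = ds$info$position[i])),
              class = "encoded_window")
  })
}

#' Train-your-own-model pipeline
#'
#' Runs the full workflow on a user dataset: enumerate candidate sites,
#' balance negatives, split 80/10/10, train, and evaluate; optionally with
#' Monte Carlo cross-validation. Datasets below the 500-positive floor are
#' rejected unless `allow_small = TRUE` (small datasets train poorly).
#'
#' @param proteins Named character vector of sequences (or path to FASTA).
#' @param positives data.frame(protein_id, position[, mod_type]) or path to
#'   a site TSV.
#' @param residue_targets Residues carrying the modification.
#' @param label_mode `"same"` (encode the positive sites as known-PTM
#'   tokens), `"none"` (no tokens), or `"cross"` (encode the sites of
#'   `cross_channel` instead).
#' @param known_channel Optional [label_channel()] used for `"same"`-mode
#'   labeling (e.g. an incomplete database of known sites); defaults to the
#'   positive list itself.
#' @param cross_channel [label_channel()] of a different modification type,
#'   required for `label_mode = "cross"`.
#' @param k Window length.
#' @param config Optional [model_config()] overriding defaults.
#' @param folds Monte Carlo folds (0 = train a single model, no CV).
#' @param seed Base seed for all randomness.
#' @param min_positives Floor on the number of positive sites (default 500).
#' @param allow_small Override the floor with a warning.
#' @param balance Balance negatives (disable for already-balanced data).
#' @return List: `model` (trained on a fresh split), `cv` (a `cv_summary`
#'   or `NULL`), `fold_reports`, `splits`, `alphabet`, `channels`,
#'   `final_report`.
#' @export
run_tyom <- function(proteins, positives, residue_targets,
                     label_mode = c("same", "none", "cross"),
                     known_channel = NULL, cross_channel = NULL, k = 53L,
                     config = NULL, folds = 10L, seed = 1L,
                     min_positives = 500L, allow_small = FALSE,
                     balance = TRUE) {
  label_mode <- match.arg(label_mode)
  if (is.character(proteins) && length(proteins) == 1L) {
    proteins <- read_fasta_tokens(proteins)$sequences
  }
  if (is.character(positives) && length(positives) == 1L) {
    positives <- read_sites(positives)
  }
  n_pos <- nrow(unique(positives[c("protein_id", "position")]))
  if (n_pos < min_positives) {
    msg <- sprintf(
      "dataset has %d positive sites, below the %d-site floor used for reliable training",
      n_pos, min_positives)
    if (!allow_small) stop(msg, "; pass allow_small = TRUE to override")
    warning(msg)
  }

  channels <- switch(label_mode,
    same = list(known_channel %||%
                  label_channel("known", residue_targets, positives)),
    none = list(),
    cross = {
      if (is.null(cross_channel)) {
        stop("label_mode = 'cross' requires cross_channel")
      }
      list(cross_channel)
    })
  alphabet <- build_alphabet(channels)
  log_stage("enumerate", "targets {%s}, %d proteins",
            paste(residue_targets, collapse = ","), length(proteins))
  ds <- enumerate_candidates(proteins, residue_targets, positives, channels,
                             k = k, alphabet = alphabet)
  log_stage("enumerate", "%d candidates, %d positive", length(ds),
            sum(ds$info$label))

  if (is.null(config)) config <- model_config(k = k)
  config$k <- as.integer(k)

  cv <- NULL
  fold_reports <- NULL
  splits <- NULL
  if (folds > 0L) {
    splits <- monte_carlo_resample(ds, n_folds = folds, seed = seed,
                                   balance = balance)
    fold_reports <- lapply(seq_along(splits), function(f) {
      m <- build_model(config, alphabet, seed = seed + f,
                       residue_targets = residue_targets)
      m <- train_model(m, splits[[f]], seed = seed + 1000L + f)
      compute_metrics(predict(m, splits[[f]]$test),
                      splits[[f]]$test$info$label)
    })
    if (folds >= 2L) cv <- summarize_cv(fold_reports)
  }

  final_seed <- seed + 99991L
  dsb <- if (balance) balance_negatives(ds, seed = final_seed) else ds
  final_split <- split_dataset(dsb, seed = final_seed)
  model <- build_model(config, alphabet, seed = final_seed,
                       residue_targets = residue_targets)
  model <- train_model(model, final_split, seed = final_seed + 1L)
  final_report <- compute_metrics(predict(model, final_split$test),
                                  final_split$test$info$label)
  log_stage("train", "final model stopped at epoch %d (AUC %.3f)",
            model$stopped_epoch, final_report$auc)

  list(model = model, cv = cv, fold_reports = fold_reports, splits = splits,
       alphabet = alphabet, channels = channels, final_report = final_report,
       seed = seed)
}

#' Train the labeled and unlabeled models on paired folds and compare
#'
#' Both models see identical fold membership (same seeds drive negative
#' subsampling and splitting); the only difference is whether known sites
#' are encoded as mod tokens. The summary reports mean AUC difference and a
#' two-sided paired test.
#'
#' @inheritParams run_tyom
#' @param folds Number of Monte Carlo folds (>= 2).
#' @return List: `summary` (a `cv_summary`; `delta_auc` is labeled minus
#'   unlabeled), `labeled`, `unlabeled` (per-fold `metric_report` lists).
#' @export
compare_label_models <- function(proteins, positives, residue_targets,
                                 known_channel = NULL, k = 53L,
                                 config = NULL, folds = 5L, seed = 1L,
                                 min_positives = 500L, allow_small = FALSE) {
  if (is.character(proteins) && length(proteins) == 1L) {
    proteins <- read_fasta_tokens(proteins)$sequences
  }
  if (is.character(positives) && length(positives) == 1L) {
    positives <- read_sites(positives)
  }
  if (folds < 2L) stop("paired comparison needs >= 2 folds")
  channel <- known_channel %||%
    label_channel("known", residue_targets, positives)
  ab_lab <- build_alphabet(list(channel))
  ab_non <- build_alphabet(list())
  ds_lab <- enumerate_candidates(proteins, residue_targets, positives,
                                 list(channel), k = k, alphabet = ab_lab)
  ds_non <- enumerate_candidates(proteins, residue_targets, positives,
                                 list(), k = k, alphabet = ab_non)
  n_pos <- sum(ds_lab$info$label)
  if (n_pos < min_positives && !allow_small) {
    stop("only ", n_pos, " positive sites (floor ", min_positives,
         "); pass allow_small = TRUE to override")
  }

  if (is.null(config)) config <- model_config(k = k)
  config$k <- as.integer(k)
  sp_lab <- monte_carlo_resample(ds_lab, n_folds = folds, seed = seed)
  sp_non <- monte_carlo_resample(ds_non, n_folds = folds, seed = seed)

  run_fold <- function(split, alphabet, f) {
    m <- build_model(config, alphabet, seed = seed + f,
                     residue_targets = residue_targets)
    m <- train_model(m, split, seed = seed + 1000L + f)
    compute_metrics(predict(m, split$test), split$test$info$label)
  }
  labeled <- lapply(seq_len(folds), function(f)
    run_fold(sp_lab[[f]], ab_lab, f))
  unlabeled <- lapply(seq_len(folds), function(f)
    run_fold(sp_non[[f]], ab_non, f))
  list(summary = summarize_cv(labeled, unlabeled),
       labeled = labeled, unlabeled = unlabeled)
}

#' Score every candidate residue of input sequences
#'
#' Sequences may carry inline `"@"`/`"&"` tokens for known sites (or a
#' channel may be supplied); the model's alphabet decides how they are
#' encoded. Output rows are sorted by protein then position.
#'
#' @param model A trained `ptm_model` or path to a model archive.
#' @param fasta Path to FASTA, or named character vector of sequences.
#' @param channel Optional [label_channel()] of known sites (overrides
#'   inline tokens).
#' @param threshold Probability cutoff for the binary `call` column.
#' @param out Optional CSV path.
#' @param model_id Identifier recorded in the output.
#' @return data.frame(protein_id, position, residue, probability, model_id,
#'   call).
#' @export
predict_sites <- function(model, fasta, channel = NULL, threshold = 0.5,
                          out = NULL, model_id = NULL) {
  if (is.character(model) && length(model) == 1L) {
    if (is.null(model_id)) model_id <- basename(model)
    model <- load_model(model)
  }
  if (is.null(model_id)) model_id <- "in-memory"
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    fr <- read_fasta_tokens(fasta, alphabet = model$alphabet)
    proteins <- fr$sequences
    if (is.null(channel)) channel <- fr$channel
  } else {
    proteins <- fasta
  }
  targets <- model$residue_targets
  if (is.null(targets)) {
    stop("model does not record residue targets; supply a model built by ",
         "run_tyom() or build_model(residue_targets=)")
  }
  channels <- if (!is.null(channel) && sum(lengths(channel$sites)) > 0 &&
                  nrow(model$alphabet$mod_map)) list(channel) else list()
  ds <- enumerate_candidates(proteins, targets, positives = NULL,
                             channels = channels, k = model$config$k,
                             alphabet = model$alphabet)
  if (length(ds) == 0L) {
    warning("no candidate residues found")
    rows <- data.frame(protein_id = character(0), position = integer(0),
                       residue = character(0), probability = numeric(0),
                       model_id = character(0), call = integer(0))
  } else {
    p <- predict(model, ds)
    rows <- data.frame(protein_id = ds$info$protein_id,
                       position = ds$info$position,
                       residue = ds$info$residue,
                       probability = p, model_id = model_id,
                       call = as.integer(p >= threshold),
                       stringsAsFactors = FALSE)
    rows <- rows[order(rows$protein_id, rows$position), , drop = FALSE]
    rownames(rows) <- NULL
  }
  if (!is.null(out)) write_predictions(rows, out)
  rows
}

#' Integrated-gradients attribution over a dataset
#'
#' Convenience loop: attribution for each selected record of a site dataset.
#'
#' @param model A trained `ptm_model`.
#' @param ds A `site_dataset` encoded with the model's alphabet.
#' @param config An [ig_config()].
#' @param indices Record indices (default all).
#' @return List of `attribution` objects (windows attached).
#' @export
attribute_dataset <- function(model, ds, config = ig_config(),
                              indices = seq_len(length(ds))) {
  wins <- dataset_windows(ds, indices)
  lapply(wins, function(w) integrated_gradients(model, w, config))
}
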