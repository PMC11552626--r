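# Model configuration, construction, training, prediction, persistence.

#' Configure the embedding + CNN classifier
#'
#' Defaults follow the published training regimen: window length 53,
#' embedding length 21, learning rate 0.001, batch size 100, up to 400
#' epochs with early stopping at patience 15 on validation loss, dropout 0.1
#' between the two dense layers, and L2 weight 1e-6 on the convolution
#' kernel only. Architecture sizes not fixed by the main text (filter count,
#' kernel height, pool size, dense width) are package conventions, all
#' exposed here.
#'
#' @param k Odd window length.
#' @param vocab_size Alphabet size (tokens).
#' @param embedding_dim Embedding vector length.
#' @param conv_filters Number of convolution filters.
#' @param conv_kernel `c(height_over_positions, width_over_embedding_dims)`;
#'   the width must span the full embedding.
#' @param pool_size Max-pool length over the position axis.
#' @param dense_units Two integers: hidden dense width and output width (1).
#' @param dropout Dropout fraction between the dense layers.
#' @param l2_weight L2 penalty on the convolution kernel.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @return A `model_config` list.
#' @export
model_config <- function(k = 53L, vocab_size = 22L, embedding_dim = 21L,
                         conv_filters = 64L, conv_kernel = c(7L, embedding_dim),
                         pool_size = 4L, dense_units = c(128L, 1L),
                         dropout = 0.1, l2_weight = 1e-6, lr = 0.001,
                         batch_size = 100L, max_epochs = 400L,
                         patience = 15L) {
  cfg <- list(k = as.integer(k), vocab_size = as.integer(vocab_size),
              embedding_dim = as.integer(embedding_dim),
              conv_filters = as.integer(conv_filters),
              conv_kernel = as.integer(conv_kernel),
              pool_size = as.integer(pool_size),
              dense_units = as.integer(dense_units),
              dropout = dropout, l2_weight = l2_weight, lr = lr,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience))
  if (cfg$k %% 2L == 0L) stop("k must be odd")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0, 1)")
  if (cfg$conv_kernel[2L] != cfg$embedding_dim) {
    stop("conv kernel width (", cfg$conv_kernel[2L],
         ") must span the full embedding dimension (", cfg$embedding_dim, ")")
  }
  if (cfg$conv_kernel[1L] > cfg$k) {
    stop("conv kernel height (", cfg$conv_kernel[1L],
         ") exceeds the input plane (k = ", cfg$k, ")")
  }
  P <- cfg$k - cfg$conv_kernel[1L] + 1L
  if (cfg$pool_size > P) stop("pool size exceeds convolution output length")
  if (any(c(cfg$conv_filters, cfg$dense_units, cfg$batch_size,
            cfg$max_epochs, cfg$patience) < 1L)) {
    stop("all sizes must be positive")
  }
  structure(cfg, class = "model_config")
}

#' Build an untrained model
#'
#' @param config A [model_config()]; its `vocab_size` is overridden by the
#'   alphabet's.
#' @param alphabet The `mod_alphabet` the model encodes inputs with.
#' @param seed Integer seed for weight initialization (deterministic).
#' @param residue_targets Residues the model scores (stored so prediction
#'   workflows know which sites to enumerate); defaults to the alphabet's
#'   mod-map residues when present.
#' @return An object of class `ptm_model`.
#' @export
build_model <- function(config = model_config(), alphabet, seed = 1L,
                        residue_targets = NULL) {
  config$vocab_size <- alphabet$vocab_size
  config$embedding_dim <- alphabet$embedding_dim
  config <- do.call(model_config, unclass(config))
  params <- withr::with_seed(as.integer(seed),
                             nn_init_params(config, config$vocab_size))
  if (is.null(residue_targets) && nrow(alphabet$mod_map)) {
    residue_targets <- unique(alphabet$mod_map$residue)
  }
  structure(list(config = config, alphabet = alphabet, params = params,
                 residue_targets = residue_targets,
                 training_log = NULL, stopped_epoch = NA_integer_,
                 best_epoch = NA_integer_, trained = FALSE,
                 init_seed = as.integer(seed)),
            class = "ptm_model")
}

#' @export
print.ptm_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf(
    "ptm_model: k=%d, vocab=%d, %d filters, %d parameters, %s\n",
    x$config$k, x$config$vocab_size, x$config$conv_filters, n_par,
    if (x$trained) sprintf("trained (stopped at epoch %d, best %d)",
                           x$stopped_epoch, x$best_epoch)
    else "untrained"))
  invisible(x)
}

dataset_xy <- function(ds) {
  list(x = ds$codes, y = as.numeric(ds$info$label))
}

#' Train the classifier on a dataset split
#'
#' Adam with binary cross-entropy; stops when the validation loss has not
#' improved for `patience` consecutive epochs (or at `max_epochs`), and
#' restores the weights of the best-validation-loss epoch.
#'
#' @param model An untrained or trained `ptm_model`.
#' @param split A `dataset_split` (train and validation are used).
#' @param seed Integer seed controlling shuffling and dropout.
#' @param verbose Print per-epoch losses.
#' @return The trained model with `training_log`, `stopped_epoch`,
#'   `best_epoch` populated.
#' @export
train_model <- function(model, split, seed = 1L, verbose = FALSE) {
  cfg <- model$config
  tr <- dataset_xy(split$train)
  va <- dataset_xy(split$validation)
  if (nrow(va$x) == 0L) stop("validation set is empty: early stopping undefined")
  if (nrow(tr$x) == 0L) stop("training set is empty")
  if (length(unique(tr$y)) < 2L) {
    stop("training labels are single-class; need positives and negatives")
  }
  if (ncol(tr$x) != cfg$k) {
    stop("window length ", ncol(tr$x), " does not match config k = ", cfg$k)
  }
  if (max(tr$x) >= cfg$vocab_size) {
    stop("window codes exceed model vocabulary")
  }

  params <- model$params
  opt <- adam_init(params)
  n <- nrow(tr$x)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  best_loss <- Inf
  best_params <- params
  best_epoch <- 0L
  wait <- 0L
  stopped <- cfg$max_epochs

  withr::with_seed(as.integer(seed), {
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n)
      batch_losses <- numeric(0)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
        xb <- tr$x[idx, , drop = FALSE]
        yb <- tr$y[idx]
        fw <- nn_forward(params, cfg, codes = xb, training = TRUE)
        dz3 <- (fw$yhat - yb) / length(yb)
        bw <- nn_backward(params, cfg, fw, dz3)
        grads <- bw$grads
        grads$E <- nn_embedding_grad(bw$dA_flat, xb, cfg$vocab_size,
                                     cfg$embedding_dim)
        st <- adam_step(params, grads, opt, lr = cfg$lr)
        params <- st$params
        opt <- st$state
        batch_losses <- c(batch_losses, nn_loss(params, cfg, fw$yhat, yb))
      }
      val_pred <- nn_predict(params, cfg, va$x)
      val_loss <- nn_loss(params, cfg, val_pred, va$y)
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_loss = mean(batch_losses),
                                   val_loss = val_loss))
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        mean(batch_losses), val_loss))
      }
      if (val_loss < best_loss - 1e-9) {
        best_loss <- val_loss
        best_params <- params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) {
          stopped <- epoch
          break
        }
      }
    }
  })

  model$params <- best_params
  model$training_log <- log
  model$stopped_epoch <- min(stopped, nrow(log))
  model$best_epoch <- best_epoch
  model$trained <- TRUE
  model
}

#' Predict modification probabilities
#'
#' @param object A `ptm_model`.
#' @param newdata A `site_dataset`, an `encoded_window`, a list of encoded
#'   windows, or an integer code matrix (n x k).
#' @param ... Ignored.
#' @return Numeric vector of probabilities in (0, 1), one per window, in
#'   input order. Inference is deterministic (dropout disabled).
#' @export
predict.ptm_model <- function(object, newdata, ...) {
  codes <- if (inherits(newdata, "site_dataset")) {
    newdata$codes
  } else if (inherits(newdata, "encoded_window")) {
    matrix(newdata$codes, nrow = 1L)
  } else if (is.list(newdata)) {
    do.call(rbind, lapply(newdata, function(w) w$codes))
  } else {
    as.matrix(newdata)
  }
  if (ncol(codes) != object$config$k) {
    stop("window length ", ncol(codes), " does not match model k = ",
         object$config$k)
  }
  if (any(codes < 0L) || max(codes) >= object$config$vocab_size) {
    bad <- codes[which(codes >= object$config$vocab_size)][1L]
    stop("alphabet mismatch: code ", bad, " outside model vocabulary 0..",
         object$config$vocab_size - 1L)
  }
  nn_predict(object$params, object$config, codes)
}

MODEL_ARCHIVE_VERSION <- 1L

#' Save a model archive
#'
#' The archive bundles weights, configuration, the token alphabet (so users
#' know the `"@"`/`"&"` semantics), and the training manifest.
#'
#' @param model A `ptm_model`.
#' @param path Output file.
#' @param manifest Optional named list of provenance (seeds, dataset hash).
#' @export
save_model <- function(model, path, manifest = list()) {
  obj <- list(archive_version = MODEL_ARCHIVE_VERSION,
              package_version = as.character(utils::packageVersion("modsite")),
              config = model$config, alphabet = model$alphabet,
              residue_targets = model$residue_targets,
              params = model$params, training_log = model$training_log,
              stopped_epoch = model$stopped_epoch,
              best_epoch = model$best_epoch, trained = model$trained,
              init_seed = model$init_seed, manifest = manifest)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model archive written by [save_model()]
#' @param path Archive file.
#' @return A `ptm_model`; the training manifest is attached as attribute
#'   `manifest`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$archive_version)) {
    stop("not a model archive: ", path)
  }
  if (obj$archive_version != MODEL_ARCHIVE_VERSION) {
    stop("model archive version ", obj$archive_version,
         " not supported (expected ", MODEL_ARCHIVE_VERSION, ")")
  }
  m <- structure(list(config = obj$config, alphabet = obj$alphabet,
                      residue_targets = obj$residue_targets,
                      params = obj$params, training_log = obj$training_log,
                      stopped_epoch = obj$stopped_epoch,
                      best_epoch = obj$best_epoch, trained = obj$trained,
                      init_seed = obj$init_seed),
                 class = "ptm_model")
  attr(m, "manifest") <- obj$manifest
  m
}
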