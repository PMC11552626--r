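# Integrated-gradients attribution on the embedded input, position-summed
# attributions (PSIG), K-means clustering of attribution tensors, and
# per-cluster position/token frequency matrices for logo rendering.

#' Integrated-gradients settings
#'
#' @param m Number of Riemann steps (right-Riemann sum over s = 1..m, so the
#'   path sum includes the input endpoint and excludes the baseline).
#' @param baseline `"padding"` (embedded all-`"-"` sequence, the
#'   semantically neutral no-amino-acid input; default) or `"zero"` (the
#'   zero tensor in embedding space).
#' @param output Attribute the `"probability"` (sigmoid output, default) or
#'   the `"logit"` pre-activation. The logit is the scale on which a
#'   suitably-weighted network is exactly linear in the embedding, which is
#'   what the closed-form oracle tests exploit.
#' @return An `ig_config` list.
#' @export
ig_config <- function(m = 64L, baseline = c("padding", "zero"),
                      output = c("probability", "logit")) {
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  structure(list(m = m, baseline = match.arg(baseline),
                 output = match.arg(output)),
            class = "ig_config")
}

ig_baseline_tensor <- function(model, config) {
  k <- model$config$k
  d <- model$config$embedding_dim
  if (config$baseline == "zero") {
    matrix(0, k, d)
  } else {
    pad_code <- matrix(rep(0L, k), nrow = 1L)  # "-" is code 0 by construction
    nn_embed(model$params, pad_code)
  }
}

#' Integrated gradients for one window
#'
#' Computes, for the embedded input tensor `x` (k positions by n embedding
#' dimensions) and baseline `x'`,
#' `ig[i,j] = (x[i,j] - x'[i,j]) * mean_{s=1..m} dF/dx[i,j]` evaluated at
#' `x' + (s/m)(x - x')`, with F the model's sigmoid output. `psig[i]` is the
#' sum of `ig[i,]` over embedding dimensions. By the completeness axiom,
#' `sum(ig)` converges to `F(x) - F(x')` as m grows.
#'
#' @param model A trained `ptm_model`.
#' @param window An `encoded_window` (or bare integer code vector of length
#'   k) matching the model's alphabet.
#' @param config An [ig_config()].
#' @return An `attribution`: `ig` (k x n matrix), `psig` (length-k vector),
#'   `f_x`, `f_baseline`, `window`.
#' @export
integrated_gradients <- function(model, window, config = ig_config()) {
  codes <- if (inherits(window, "encoded_window")) window$codes else
    as.integer(window)
  k <- model$config$k
  d <- model$config$embedding_dim
  if (length(codes) != k) {
    stop("window length ", length(codes), " does not match model k = ", k)
  }
  if (any(codes < 0L) || max(codes) >= model$config$vocab_size) {
    stop("alphabet mismatch: window codes outside model vocabulary")
  }
  m <- config$m
  x <- nn_embed(model$params, matrix(codes, nrow = 1L))   # k x d
  xp <- ig_baseline_tensor(model, config)
  diffm <- x - xp

  # all m path points as one batch: rows (s-major) of (m*k) x d
  alphas <- seq_len(m) / m
  A_flat <- matrix(0, m * k, d)
  for (s in seq_len(m)) {
    A_flat[((s - 1L) * k + 1L):(s * k), ] <- xp + alphas[s] * diffm
  }
  gr <- nn_input_gradient(model$params, model$config, A_flat,
                          output = config$output)
  G <- matrix(0, k, d)
  for (s in seq_len(m)) {
    G <- G + gr$dA_flat[((s - 1L) * k + 1L):(s * k), , drop = FALSE]
  }
  G <- G / m
  ig <- diffm * G

  fx_fw <- nn_forward(model$params, model$config, A_flat = x)
  fw0 <- nn_forward(model$params, model$config, A_flat = xp)
  pick <- function(fw) {
    if (config$output == "logit") as.vector(fw$z3) else fw$yhat
  }
  structure(list(ig = ig, psig = rowSums(ig), f_x = pick(fx_fw),
                 f_baseline = pick(fw0),
                 window = if (inherits(window, "encoded_window")) window
                          else NULL),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf(
    "attribution: %d x %d, sum(ig) = %.4f, F(x) - F(x') = %.4f\n",
    nrow(x$ig), ncol(x$ig), sum(x$ig), x$f_x - x$f_baseline))
  invisible(x)
}

#' Cluster attribution tensors with K-means
#'
#' Flattened ig tensors (k*n features per window, before position summation)
#' are clustered with K-means under a fixed seed. An elbow curve (total
#' within-cluster inertia versus cluster count) is computed for audit, and
#' deterministic 2-D coordinates (first two principal components) are
#' emitted for visualization.
#'
#' @param results List of `attribution` objects of identical shape.
#' @param n_clusters Number of clusters (default 10).
#' @param seed Integer seed.
#' @param standardize Standardize features before clustering (default FALSE:
#'   raw attribution values).
#' @param elbow_max Largest cluster count on the elbow curve.
#' @return An `attribution_clusters`: `assignments`, `n_clusters`,
#'   `centroid_psig` (n_clusters x k), `embedding_2d`, `elbow`
#'   (data.frame k, inertia), `sizes`.
#' @export
cluster_attributions <- function(results, n_clusters = 10L, seed = 1L,
                                 standardize = FALSE,
                                 elbow_max = min(15L, length(results) - 1L)) {
  n <- length(results)
  n_clusters <- as.integer(n_clusters)
  if (n < n_clusters) {
    stop("fewer attribution results (", n, ") than clusters (", n_clusters, ")")
  }
  shp <- dim(results[[1L]]$ig)
  X <- t(vapply(results, function(r) {
    if (!identical(dim(r$ig), shp)) stop("attribution shapes differ")
    as.vector(r$ig)
  }, numeric(prod(shp))))
  if (standardize) {
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0] <- 0
    X <- as.matrix(X)
  }
  km <- withr::with_seed(as.integer(seed),
                         stats::kmeans(X, centers = n_clusters,
                                       nstart = 10L, iter.max = 100L))
  elbow <- withr::with_seed(as.integer(seed) + 1L, {
    ks <- seq_len(max(2L, elbow_max))
    data.frame(k = ks, inertia = vapply(ks, function(kk) {
      stats::kmeans(X, centers = kk, nstart = 3L, iter.max = 50L)$tot.withinss
    }, numeric(1L)))
  })
  psig_mat <- t(vapply(results, `[[`, numeric(shp[1L]), "psig"))
  centroid_psig <- do.call(rbind, lapply(seq_len(n_clusters), function(cl) {
    colMeans(psig_mat[km$cluster == cl, , drop = FALSE])
  }))
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = 2L)
  structure(list(assignments = km$cluster, n_clusters = n_clusters,
                 centroid_psig = centroid_psig,
                 embedding_2d = pca$x[, 1:2, drop = FALSE],
                 elbow = elbow, sizes = as.integer(table(km$cluster)),
                 seed = as.integer(seed)),
            class = "attribution_clusters")
}

#' @export
print.attribution_clusters <- function(x, ...) {
  cat(sprintf("attribution_clusters: %d clusters, sizes %s\n",
              x$n_clusters, paste(x$sizes, collapse = "/")))
  invisible(x)
}

#' Position/token frequency matrix for one cluster
#'
#' Counts each alphabet token at each offset from the window center (center
#' = 0), truncated to +/- `flank` residues, over the cluster's windows.
#' Column sums equal the cluster size; rows include the mod tokens, so
#' modified-residue enrichment is visible in the logo.
#'
#' @param analysis An `attribution_clusters`.
#' @param cluster_id Cluster to tabulate.
#' @param windows List of `encoded_window` in the order that produced
#'   `analysis` (same length as `assignments`).
#' @param alphabet `mod_alphabet` defining the token rows.
#' @param flank Truncation half-width (default 10).
#' @return Integer matrix, rows = tokens, columns = offsets `-flank..flank`.
#' @export
cluster_frequency_matrix <- function(analysis, cluster_id, windows, alphabet,
                                     flank = 10L) {
  idx <- which(analysis$assignments == cluster_id)
  if (length(idx) == 0L) stop("cluster ", cluster_id, " is empty")
  if (length(windows) != length(analysis$assignments)) {
    stop("windows must parallel the clustered attributions")
  }
  offs <- (-flank):flank
  mat <- matrix(0L, nrow = alphabet$vocab_size, ncol = length(offs),
                dimnames = list(alphabet$tokens, offs))
  for (i in idx) {
    w <- windows[[i]]
    chars <- strsplit(w$tokens, "", fixed = TRUE)[[1L]]
    ci <- w$center_index
    for (o in seq_along(offs)) {
      tok <- chars[ci + offs[o]]
      mat[tok, o] <- mat[tok, o] + 1L
    }
  }
  mat
}

#' Export per-window PSIG values as a long-format TSV
#' @param results List of `attribution` objects (with windows attached).
#' @param path Output TSV with columns window_id, offset, token, psig.
#' @export
export_psig <- function(results, path) {
  rows <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    k <- length(r$psig)
    ci <- if (!is.null(r$window)) r$window$center_index else (k + 1L) %/% 2L
    toks <- if (!is.null(r$window)) {
      strsplit(r$window$tokens, "", fixed = TRUE)[[1L]]
    } else rep(NA_character_, k)
    data.frame(window_id = i, offset = seq_len(k) - ci, token = toks,
               psig = r$psig, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
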