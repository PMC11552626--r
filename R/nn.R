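# Minimal dense/convolutional network engine used by the PTM classifier.
#
# Architecture (fixed topology, sizes from model_config):
#   integer codes -> embedding (V x d)
#   -> 2D convolution with full-embedding-width kernel (h x d), ReLU,
#      L2-regularized kernel
#   -> max pooling over the position axis (non-overlapping, remainder
#      positions dropped, as in the usual framework default)
#   -> dense (ReLU) -> dropout -> dense(1, sigmoid)
#
# Everything is expressed as im2col matrix products so that training at desk
# scale is fast in base R. The backward pass can stop at the embedded input,
# which is what integrated gradients needs.

addbias <- function(x, b) x + rep(b, each = nrow(x))

nn_dims <- function(cfg) {
  k <- cfg$k; d <- cfg$embedding_dim
  h <- cfg$conv_kernel[1L]
  P <- k - h + 1L
  Q <- P %/% cfg$pool_size
  list(k = k, d = d, h = h, nf = cfg$conv_filters, P = P,
       pool = cfg$pool_size, Q = Q, D1 = cfg$dense_units[1L])
}

nn_init_params <- function(cfg, vocab_size) {
  dm <- nn_dims(cfg)
  glorot <- function(fan_in, fan_out, nr, nc) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  list(
    E   = matrix(stats::runif(vocab_size * dm$d, -0.05, 0.05),
                 vocab_size, dm$d),
    Wc  = glorot(dm$h * dm$d, dm$h * dm$d * dm$nf, dm$h * dm$d, dm$nf),
    bc  = numeric(dm$nf),
    Wd1 = glorot(dm$Q * dm$nf, dm$D1, dm$Q * dm$nf, dm$D1),
    bd1 = numeric(dm$D1),
    Wd2 = glorot(dm$D1, 1L, dm$D1, 1L),
    bd2 = numeric(1L)
  )
}

# row indices into the flattened (B*k) x d embedded batch for the im2col
# patch matrix (conv) and into the (B*P) x nf conv activations (pooling)
nn_indices <- function(dm, B) {
  conv <- lapply(seq_len(dm$h), function(o) {
    rep((0:(B - 1L)) * dm$k, each = dm$P) + rep(seq_len(dm$P), times = B) +
      (o - 1L)
  })
  pool <- lapply(seq_len(dm$pool), function(j) {
    rep((0:(B - 1L)) * dm$P, each = dm$Q) +
      rep((0:(dm$Q - 1L)) * dm$pool, times = B) + j
  })
  list(conv = conv, pool = pool)
}

nn_embed <- function(params, codes) {
  # codes: B x k integer matrix (0-based); rows flattened sample-major
  idx <- as.vector(t(codes)) + 1L
  params$E[idx, , drop = FALSE]
}

# Forward pass. Supply either `codes` (B x k) or an already-embedded
# `A_flat` ((B*k) x d). Returns activations needed for the backward pass.
nn_forward <- function(params, cfg, codes = NULL, A_flat = NULL,
                       training = FALSE) {
  dm <- nn_dims(cfg)
  if (is.null(A_flat)) A_flat <- nn_embed(params, codes)
  B <- nrow(A_flat) %/% dm$k
  ix <- nn_indices(dm, B)

  M <- matrix(0, B * dm$P, dm$h * dm$d)
  for (o in seq_len(dm$h)) {
    M[, ((o - 1L) * dm$d + 1L):(o * dm$d)] <- A_flat[ix$conv[[o]], ,
                                                     drop = FALSE]
  }
  Z1 <- addbias(M %*% params$Wc, params$bc)
  H1 <- Z1 * (Z1 > 0)

  U <- lapply(ix$pool, function(p) H1[p, , drop = FALSE])
  Pl <- U[[1L]]
  for (j in seq_along(U)[-1L]) Pl <- pmax(Pl, U[[j]])
  claimed <- matrix(FALSE, nrow(Pl), ncol(Pl))
  sel <- vector("list", dm$pool)
  for (j in seq_along(U)) {
    sj <- (U[[j]] == Pl) & !claimed
    claimed <- claimed | sj
    sel[[j]] <- sj
  }

  Fl <- t(matrix(aperm(array(Pl, c(dm$Q, B, dm$nf)), c(1L, 3L, 2L)),
                 dm$Q * dm$nf, B))
  Z2 <- addbias(Fl %*% params$Wd1, params$bd1)
  H2 <- Z2 * (Z2 > 0)
  mask <- NULL
  H2d <- H2
  if (training && cfg$dropout > 0) {
    mask <- matrix(stats::runif(length(H2)) >= cfg$dropout,
                   nrow(H2), ncol(H2))
    H2d <- H2 * mask / (1 - cfg$dropout)
  }
  z3 <- addbias(H2d %*% params$Wd2, params$bd2)
  yhat <- 1 / (1 + exp(-z3))

  list(A_flat = A_flat, B = B, ix = ix, M = M, Z1 = Z1, H1 = H1, sel = sel,
       Fl = Fl, Z2 = Z2, H2d = H2d, mask = mask, z3 = z3,
       yhat = as.vector(yhat), dm = dm)
}

# Backward pass from a gradient on the sigmoid pre-activation z3.
# Returns parameter gradients, and the gradient wrt the embedded input when
# `input_grad = TRUE` (used by integrated gradients).
nn_backward <- function(params, cfg, fw, dz3, regularize = TRUE) {
  dm <- fw$dm; B <- fw$B
  dz3 <- matrix(dz3, ncol = 1L)
  dWd2 <- crossprod(fw$H2d, dz3)
  dbd2 <- sum(dz3)
  dH2d <- dz3 %*% t(params$Wd2)
  if (!is.null(fw$mask)) dH2d <- dH2d * fw$mask / (1 - cfg$dropout)
  dZ2 <- dH2d * (fw$Z2 > 0)
  dWd1 <- crossprod(fw$Fl, dZ2)
  dbd1 <- colSums(dZ2)
  dFl <- dZ2 %*% t(params$Wd1)

  dPl <- matrix(aperm(array(t(dFl), c(dm$Q, dm$nf, B)), c(1L, 3L, 2L)),
                B * dm$Q, dm$nf)
  dH1 <- matrix(0, B * dm$P, dm$nf)
  for (j in seq_len(dm$pool)) {
    p <- fw$ix$pool[[j]]
    dH1[p, ] <- dH1[p, ] + dPl * fw$sel[[j]]
  }
  dZ1 <- dH1 * (fw$Z1 > 0)
  dWc <- crossprod(fw$M, dZ1)
  if (regularize && cfg$l2_weight > 0) dWc <- dWc + 2 * cfg$l2_weight * params$Wc
  dbc <- colSums(dZ1)

  dM <- dZ1 %*% t(params$Wc)
  dA_flat <- matrix(0, B * dm$k, dm$d)
  for (o in seq_len(dm$h)) {
    rows <- fw$ix$conv[[o]]
    dA_flat[rows, ] <- dA_flat[rows, ] +
      dM[, ((o - 1L) * dm$d + 1L):(o * dm$d), drop = FALSE]
  }
  list(grads = list(Wc = dWc, bc = dbc, Wd1 = dWd1, bd1 = dbd1,
                    Wd2 = dWd2, bd2 = dbd2),
       dA_flat = dA_flat)
}

# scatter embedded-input gradient back onto the embedding table
nn_embedding_grad <- function(dA_flat, codes, vocab_size, d) {
  idx <- as.vector(t(codes)) + 1L
  agg <- rowsum(dA_flat, group = idx)
  dE <- matrix(0, vocab_size, d)
  dE[as.integer(rownames(agg)), ] <- agg
  dE
}

nn_bce <- function(yhat, y) {
  eps <- 1e-12
  -mean(y * log(pmax(yhat, eps)) + (1 - y) * log(pmax(1 - yhat, eps)))
}

nn_loss <- function(params, cfg, yhat, y) {
  nn_bce(yhat, y) + cfg$l2_weight * sum(params$Wc^2)
}

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# plain inference on an integer code matrix, chunked to bound memory
nn_predict <- function(params, cfg, codes, chunk = 2048L) {
  n <- nrow(codes)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    end <- min(start + chunk - 1L, n)
    fw <- nn_forward(params, cfg, codes = codes[start:end, , drop = FALSE],
                     training = FALSE)
    out[start:end] <- fw$yhat
  }
  out
}

# dF/dA at arbitrary embedded inputs (batch); F is the sigmoid output
# ("probability") or its pre-activation ("logit")
nn_input_gradient <- function(params, cfg, A_flat,
                              output = "probability") {
  fw <- nn_forward(params, cfg, A_flat = A_flat, training = FALSE)
  dz3 <- if (output == "logit") rep(1, fw$B) else fw$yhat * (1 - fw$yhat)
  bw <- nn_backward(params, cfg, fw, dz3, regularize = FALSE)
  list(dA_flat = bw$dA_flat, yhat = fw$yhat, z3 = as.vector(fw$z3))
}
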