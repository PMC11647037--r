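# Minimal causal-masked encoder-decoder transformer.
#
# The encoder consumes the radiation token sequence, the decoder the
# anti-PD-L1 token sequence; a per-step linear head maps the 5-dim decoder
# state to a scalar predicted volume change. With the default dimensions
# (d_model = 5, one head, d_ff = 5, one encoder and one decoder layer,
# post-norm residual blocks, 5 -> 1 head) the model has exactly 536
# trainable parameters.

#' Model architecture configuration
#'
#' @param d_model Token width (5: one signal channel + 4 positional).
#' @param n_heads Attention heads (only 1 supported).
#' @param d_ff Feed-forward hidden width.
#' @param n_enc_layers,n_dec_layers Encoder/decoder layer counts (only 1
#'   supported by the forward pass; the parameter count generalizes).
#' @param seq_len Sequence length (28 days).
#' @param causal_mask_everywhere Apply the causal mask to encoder self-,
#'   decoder self-, and cross-attention (default `TRUE`).
#' @return A `model_config` list.
#' @export
model_config <- function(d_model = 5L, n_heads = 1L, d_ff = 5L,
                         n_enc_layers = 1L, n_dec_layers = 1L,
                         seq_len = PULSAR_SEQ_LEN,
                         causal_mask_everywhere = TRUE) {
  cfg <- list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
              d_ff = as.integer(d_ff), n_enc_layers = as.integer(n_enc_layers),
              n_dec_layers = as.integer(n_dec_layers),
              seq_len = as.integer(seq_len),
              causal_mask_everywhere = isTRUE(causal_mask_everywhere))
  if (cfg$n_heads != 1L) stop("only single-head attention is supported")
  if (cfg$n_enc_layers != 1L || cfg$n_dec_layers != 1L) {
    stop("only one encoder and one decoder layer are supported")
  }
  structure(cfg, class = "model_config")
}

#' Training configuration
#'
#' Defaults are the AdamW settings used throughout: learning rate 1e-4,
#' weight decay 1e-4, beta1 0.9, beta2 0.999, epsilon 1e-8, batch size 32,
#' 5000 epochs, an 80/20 train/test split stratified by group, and a
#' holdout of 100 samples drawn from the test portion for per-epoch
#' validation.
#'
#' @param lr Learning rate.
#' @param weight_decay Decoupled weight decay.
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param train_frac Fraction of samples used for training.
#' @param holdout_n Validation holdout size (capped at the test-set size).
#' @param seed Integer seed controlling the split, initialization, and
#'   batch shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-4, beta1 = 0.9,
                         beta2 = 0.999, epsilon = 1e-8, batch_size = 32L,
                         epochs = 5000L, train_frac = 0.8, holdout_n = 100L,
                         seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1, batch_size >= 1, epochs >= 0,
            holdout_n >= 0)
  structure(list(lr = lr, weight_decay = weight_decay, beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), train_frac = train_frac,
                 holdout_n = as.integer(holdout_n), seed = as.integer(seed)),
            class = "train_config")
}

#' Count trainable parameters
#'
#' Each attention block carries four d x d projections with biases; each
#' feed-forward block is d -> d_ff -> d with biases; a layer-norm
#' (scale + shift) follows every sub-block (two in the encoder layer, three
#' in the decoder layer); the head is d -> 1 with bias. At d_model = 5 this
#' is 426 + 22 * d_ff, i.e. 536 at the default d_ff = 5.
#'
#' @param cfg A [model_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(cfg = model_config()) {
  d <- cfg$d_model; f <- cfg$d_ff
  attn <- 4L * (d * d + d)
  ln <- 2L * d
  ffn <- d * f + f + f * d + d
  enc <- cfg$n_enc_layers * (attn + ffn + 2L * ln)
  dec <- cfg$n_dec_layers * (2L * attn + ffn + 3L * ln)
  head <- d + 1L
  as.integer(enc + dec + head)
}

#' Lower-triangular causal attention mask
#'
#' @param n Sequence length, at least 1.
#' @return n x n logical matrix, `TRUE` where position i may attend to
#'   position j (j <= i).
#' @export
causal_mask <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be at least 1")
  n <- as.integer(n)
  outer(seq_len(n), seq_len(n), `>=`)
}

#' Scaled dot-product attention
#'
#' `weights = softmax(Q K' / sqrt(d_k))` row-wise, with disallowed entries
#' forced to exactly 0 (scores set to -Inf before the softmax). A fully
#' masked row — impossible under a lower-triangular mask — is defensively
#' defined as an all-zero weight row.
#'
#' @param Q,K,V Query, key, value matrices; `Q` is n_q x d_k, `K` and `V`
#'   are n_k x d_k.
#' @param mask Optional n_q x n_k logical matrix of allowed positions.
#' @return List with `context` (`weights %*% V`) and `weights`.
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL) {
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V)) stop("non-conformable attention inputs")
  scores <- Q %*% t(K) / sqrt(ncol(K))
  if (!is.null(mask)) {
    if (!all(dim(mask) == c(nrow(Q), nrow(K)))) stop("mask shape mismatch")
    scores[!mask] <- -Inf
  }
  mx <- apply(scores, 1L, max)
  weights <- matrix(0, nrow(scores), ncol(scores))
  ok <- is.finite(mx)
  if (any(ok)) {
    e <- exp(scores[ok, , drop = FALSE] - mx[ok])
    e[!is.finite(e)] <- 0
    weights[ok, ] <- e / rowSums(e)
  }
  list(context = weights %*% V, weights = weights)
}

layer_norm <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  va <- rowMeans((X - mu)^2)
  xhat <- (X - mu) / sqrt(va + eps)
  sweep(sweep(xhat, 2L, g, `*`), 2L, b, `+`)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize model parameters
#'
#' Weight matrices use uniform Glorot (fan-based) initialization; biases
#' start at 0, layer-norm scales at 1.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed.
#' @return Named list of parameter tensors (`model_params`).
#' @export
init_model_params <- function(cfg = model_config(), seed = 1L) {
  set.seed(as.integer(seed))
  d <- cfg$d_model; f <- cfg$d_ff
  attn <- function(prefix) {
    p <- list(glorot(d, d), numeric(d), glorot(d, d), numeric(d),
              glorot(d, d), numeric(d), glorot(d, d), numeric(d))
    names(p) <- paste0(prefix, c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo"))
    p
  }
  ln <- function(name) {
    p <- list(rep(1, d), rep(0, d))
    names(p) <- paste0(name, c("_g", "_b"))
    p
  }
  ffn <- function(prefix) {
    p <- list(glorot(d, f), numeric(f), glorot(f, d), numeric(d))
    names(p) <- paste0(prefix, c("W1", "b1", "W2", "b2"))
    p
  }
  params <- c(attn("enc_"), ln("enc_ln1"), ffn("enc_"), ln("enc_ln2"),
              attn("dec_"), ln("dec_ln1"),
              attn("x_"), ln("dec_ln2"),
              ffn("dec_"), ln("dec_ln3"),
              list(head_w = glorot(d, 1L), head_b = 0))
  structure(params, class = "model_params")
}

#' Runtime count of trainable scalars in a parameter set
#' @param params A `model_params` list.
#' @return Integer.
#' @export
n_trainable <- function(params) {
  as.integer(sum(vapply(params, length, integer(1))))
}

#' Forward pass of the encoder-decoder transformer
#'
#' Encoder: causal self-attention over the radiation sequence, then a
#' position-wise feed-forward block, each followed by a residual connection
#' and layer norm. Decoder: causal self-attention over the drug sequence,
#' causally masked cross-attention with queries from the decoder state and
#' keys/values from the encoder output, a feed-forward block (same
#' residual + norm pattern), and a linear head producing one predicted
#' volume change per step.
#'
#' @param sample An `encoded_sample` (or any list with `radiation_seq` and
#'   `drug_seq` 28 x 5 matrices).
#' @param params A `model_params` list.
#' @param cfg A [model_config()].
#' @return List with `predictions` (length-28 numeric) and `maps`, an
#'   `attention_maps` list of `enc_self`, `dec_self`, `cross` (28 x 28,
#'   rows = query steps, cols = key steps).
#' @export
forward <- function(sample, params, cfg = model_config()) {
  Xr <- sample$radiation_seq
  Xd <- sample$drug_seq
  d <- cfg$d_model
  if (ncol(Xr) != d || ncol(Xd) != d || nrow(Xr) != nrow(Xd)) {
    stop("input shape mismatch with model config")
  }
  n <- nrow(Xr)
  mask <- if (cfg$causal_mask_everywhere) causal_mask(n) else NULL

  attn_block <- function(Xq, Xkv, p, prefix) {
    Q <- sweep(Xq %*% p[[paste0(prefix, "Wq")]], 2L, p[[paste0(prefix, "bq")]], `+`)
    K <- sweep(Xkv %*% p[[paste0(prefix, "Wk")]], 2L, p[[paste0(prefix, "bk")]], `+`)
    V <- sweep(Xkv %*% p[[paste0(prefix, "Wv")]], 2L, p[[paste0(prefix, "bv")]], `+`)
    at <- scaled_dot_attention(Q, K, V, mask)
    O <- sweep(at$context %*% p[[paste0(prefix, "Wo")]], 2L, p[[paste0(prefix, "bo")]], `+`)
    list(O = O, weights = at$weights)
  }
  ffn_block <- function(X, p, prefix) {
    H <- sweep(X %*% p[[paste0(prefix, "W1")]], 2L, p[[paste0(prefix, "b1")]], `+`)
    H <- pmax(H, 0)
    sweep(H %*% p[[paste0(prefix, "W2")]], 2L, p[[paste0(prefix, "b2")]], `+`)
  }

  # encoder
  a1 <- attn_block(Xr, Xr, params, "enc_")
  H1 <- layer_norm(Xr + a1$O, params$enc_ln1_g, params$enc_ln1_b)
  E <- layer_norm(H1 + ffn_block(H1, params, "enc_"), params$enc_ln2_g, params$enc_ln2_b)
  # decoder
  a2 <- attn_block(Xd, Xd, params, "dec_")
  H2 <- layer_norm(Xd + a2$O, params$dec_ln1_g, params$dec_ln1_b)
  a3 <- attn_block(H2, E, params, "x_")
  H3 <- layer_norm(H2 + a3$O, params$dec_ln2_g, params$dec_ln2_b)
  H4 <- layer_norm(H3 + ffn_block(H3, params, "dec_"), params$dec_ln3_g, params$dec_ln3_b)
  predictions <- as.numeric(H4 %*% params$head_w + params$head_b)

  maps <- structure(list(enc_self = a1$weights, dec_self = a2$weights,
                         cross = a3$weights), class = "attention_maps")
  list(predictions = predictions, maps = maps)
}

#' Masked L2 loss
#'
#' Mean squared error over the masked (measured) steps only; unmeasured
#' steps contribute nothing.
#'
#' @param predictions Length-28 numeric vector.
#' @param target A [target_sequence()].
#' @return Scalar loss.
#' @export
masked_l2_loss <- function(predictions, target) {
  stopifnot(inherits(target, "target_sequence"),
            length(predictions) == length(target$values))
  if (!any(target$mask)) stop("target mask is empty: no measured steps")
  mean((predictions[target$mask] - target$values[target$mask])^2)
}

#' Train the transformer with AdamW on masked L2 loss
#'
#' Splits the dataset 80/20 at the sample level stratified by group, draws
#' the validation holdout from the test portion, initializes parameters,
#' and runs minibatch AdamW. The run is deterministic under a fixed seed on
#' a fixed platform.
#'
#' @param dataset An `encoded_dataset` from [encode_dataset()].
#' @param tcfg A [train_config()].
#' @param cfg A [model_config()].
#' @return A `pulsar_fit`: `params`, `history` (tibble of epoch,
#'   train_loss, val_loss), `split` (train/test/holdout indices), `cfg`,
#'   `tcfg`, `vc_scale`.
#' @export
train <- function(dataset, tcfg = train_config(), cfg = model_config()) {
  stopifnot(inherits(dataset, "encoded_dataset"))
  n <- length(dataset$samples)
  if (n == 0L) stop("empty dataset")
  arr <- stack_dataset(dataset)
  if (!any(arr$mask)) stop("no masked targets anywhere in the dataset")

  set.seed(tcfg$seed)
  gid <- vapply(dataset$samples, function(s) s$group_id, character(1))
  train_idx <- integer(0)
  for (g in unique(gid)) {
    ids <- which(gid == g)
    k <- max(1L, round(length(ids) * tcfg$train_frac))
    train_idx <- c(train_idx, sort(sample(ids, k)))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  holdout_idx <- if (length(test_idx) > 0L && tcfg$holdout_n > 0L) {
    sort(sample(test_idx, min(tcfg$holdout_n, length(test_idx))))
  } else integer(0)

  params <- init_model_params(cfg, seed = tcfg$seed + 1L)
  res <- tf_train(params,
                  arr$rad[, , train_idx, drop = FALSE],
                  arr$drug[, , train_idx, drop = FALSE],
                  arr$targets[, train_idx, drop = FALSE],
                  arr$mask[, train_idx, drop = FALSE] * 1L,
                  arr$rad[, , holdout_idx, drop = FALSE],
                  arr$drug[, , holdout_idx, drop = FALSE],
                  arr$targets[, holdout_idx, drop = FALSE],
                  arr$mask[, holdout_idx, drop = FALSE] * 1L,
                  tcfg$epochs, tcfg$batch_size, tcfg$lr, tcfg$weight_decay,
                  tcfg$beta1, tcfg$beta2, tcfg$epsilon,
                  cfg$causal_mask_everywhere, tcfg$seed + 2L)
  params_out <- res$params
  class(params_out) <- "model_params"
  history <- tibble::tibble(
    epoch = seq_len(tcfg$epochs),
    train_loss = as.numeric(res$train_loss),
    val_loss = if (length(holdout_idx)) as.numeric(res$val_loss) else NA_real_
  )
  structure(list(params = params_out, history = history,
                 split = list(train = train_idx, test = test_idx,
                              holdout = holdout_idx),
                 cfg = cfg, tcfg = tcfg, vc_scale = dataset$vc_scale),
            class = "pulsar_fit")
}

#' @export
print.pulsar_fit <- function(x, ...) {
  cat(sprintf("<pulsar_fit> %d parameters, %d epochs; final train loss %.4g%s\n",
              n_trainable(x$params), nrow(x$history),
              utils::tail(x$history$train_loss, 1),
              if (all(is.na(x$history$val_loss))) "" else
                sprintf(", val loss %.4g", utils::tail(x$history$val_loss, 1))))
  invisible(x)
}

#' Mean masked loss of a fitted model over a set of samples
#'
#' @param fit A `pulsar_fit`.
#' @param samples List of `encoded_sample`s.
#' @return Mean per-sample masked L2 loss.
#' @export
evaluate_loss <- function(fit, samples) {
  mean(vapply(samples, function(s) {
    masked_l2_loss(forward(s, fit$params, fit$cfg)$predictions, s$target)
  }, numeric(1)))
}
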