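# Built-in transformer encoder block and the pretrained-encoder adapter
# contract.
#
# Each modality (protein tokens, SMILES tokens) is embedded into an L x d
# matrix, layer-normalized, passed through multi-head self-attention with a
# residual connection, then a position-wise feed-forward network, and finally
# pooled and linearly projected to a fixed-width vector (d_out, 256 by
# default; this op mean-pools, the assembled model also offers log-mean-exp
# pooling). The block applies the FFN directly to the residual sum, with no
# second residual or post-normalization; this is deliberately leaner than the
# standard transformer layer and is what the package trains end to end.

#' Layer normalization
#'
#' Normalizes each row of `M` to zero mean and unit variance (population
#' variance, epsilon-stabilized), then applies a learnable per-column scale
#' and shift.
#'
#' @param M Numeric matrix (L x d), one row per token.
#' @param gamma,beta Length-d scale and shift; defaults are the identity
#'   transform.
#' @param eps Variance stabilizer.
#' @return L x d matrix.
#' @export
layer_norm <- function(M, gamma = rep(1, ncol(M)), beta = rep(0, ncol(M)),
                       eps = 1e-5) {
  M <- as.matrix(M)
  mu <- rowMeans(M)
  v <- rowMeans((M - mu)^2)
  xhat <- (M - mu) / sqrt(v + eps)
  sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
}

#' Sinusoidal positional encoding
#'
#' Fixed sin/cos position signal added to token embeddings.
#'
#' @param L Number of positions.
#' @param d Embedding width.
#' @return L x d matrix.
#' @export
positional_encoding <- function(L, d) {
  pos <- seq_len(L) - 1
  i <- seq_len(d) - 1
  angle <- outer(pos, 1 / 10000^((i %/% 2) * 2 / d))
  out <- matrix(0, L, d)
  even <- which(i %% 2 == 0)
  odd <- which(i %% 2 == 1)
  out[, even] <- sin(angle[, even, drop = FALSE])
  out[, odd] <- cos(angle[, odd, drop = FALSE])
  out
}

#' Build a token vocabulary
#'
#' @param token_lists List of token vectors (e.g. from [tokenize_smiles()]).
#' @param unk Add an `<unk>` entry so unseen tokens map to a shared row
#'   rather than erroring. Default `TRUE`.
#' @return Character vector of unique tokens (the vocabulary).
#' @export
build_vocab <- function(token_lists, unk = TRUE) {
  # radix sort: locale-independent ordering, so the vocabulary (and hence
  # seeded parameter initialization) is reproducible across systems
  v <- sort(unique(unlist(lapply(token_lists, as.character))),
            method = "radix")
  if (unk) v <- c(v, "<unk>")
  v
}

#' Embed a token sequence
#'
#' Table lookup plus sinusoidal positional addition: row t of the output is
#' the embedding vector of token t plus the position-t sinusoid.
#'
#' @param tokens Character vector of tokens (a `token_sequence`).
#' @param emb V x d embedding table with rownames giving the vocabulary. If
#'   an `<unk>` row is present, out-of-vocabulary tokens map to it; otherwise
#'   they are an error.
#' @return L x d `embedding_matrix`.
#' @export
embed_tokens <- function(tokens, emb) {
  tokens <- as.character(tokens)
  if (length(tokens) == 0L) stop("empty token sequence", call. = FALSE)
  vocab <- rownames(emb)
  idx <- match(tokens, vocab)
  if (anyNA(idx)) {
    unk <- match("<unk>", vocab)
    if (is.na(unk)) {
      stop("token ", sQuote(tokens[which(is.na(idx))[1L]]),
           " not in vocabulary and no <unk> entry", call. = FALSE)
    }
    idx[is.na(idx)] <- unk
  }
  X <- emb[idx, , drop = FALSE] + positional_encoding(length(tokens), ncol(emb))
  attr(X, "token_idx") <- idx
  X
}

split_heads <- function(d, h) {
  if (d %% h != 0) stop("width ", d, " not divisible by ", h, " heads",
                        call. = FALSE)
  dk <- d %/% h
  lapply(seq_len(h), function(i) seq.int((i - 1L) * dk + 1L, i * dk))
}

#' Multi-head scaled dot-product attention
#'
#' Computes `Concat(head_1, ..., head_h) W_O` where
#' `head_i = softmax(Q_i K_i^T / sqrt(d_k)) V_i`. Queries come from `Q_in`
#' and keys/values from `KV_in`; with `KV_in = Q_in` (the default) this is
#' self-attention, otherwise cross-attention.
#'
#' @param Q_in Lq x d query-side matrix.
#' @param params List with d x d matrices `Wq`, `Wk`, `Wv`, `Wo` and head
#'   count `h`; head i uses the i-th column block of each projection.
#' @param KV_in Lk x d key/value-side matrix; defaults to `Q_in`.
#' @param return_weights Also return the per-head attention matrices.
#' @return Lq x d matrix; if `return_weights`, a list with elements `out`
#'   and `weights`.
#' @export
mhsa <- function(Q_in, params, KV_in = Q_in, return_weights = FALSE) {
  Q_in <- as.matrix(Q_in); KV_in <- as.matrix(KV_in)
  d <- ncol(params$Wq)
  if (ncol(Q_in) != nrow(params$Wq) || ncol(KV_in) != nrow(params$Wk)) {
    stop("input width does not match attention parameters", call. = FALSE)
  }
  blocks <- split_heads(d, params$h)
  dk <- d %/% params$h
  Q <- Q_in %*% params$Wq
  K <- KV_in %*% params$Wk
  V <- KV_in %*% params$Wv
  H <- matrix(0, nrow(Q_in), d)
  W <- vector("list", params$h)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    S <- tcrossprod(Q[, b, drop = FALSE], K[, b, drop = FALSE]) / sqrt(dk)
    A <- softmax_rows(S)
    H[, b] <- A %*% V[, b, drop = FALSE]
    if (return_weights) W[[i]] <- A
  }
  out <- H %*% params$Wo
  if (return_weights) list(out = out, weights = W) else out
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Position-wise feed-forward network
#'
#' `FFN(x) = ReLU(x W1 + b1) W2 + b2`, applied to each row.
#'
#' @param M L x d matrix.
#' @param params List with `W1` (d x d_ff), `b1`, `W2` (d_ff x d), `b2`.
#' @return L x d matrix.
#' @export
ffn <- function(M, params) {
  U <- sweep(as.matrix(M) %*% params$W1, 2, params$b1, "+")
  sweep(pmax(U, 0) %*% params$W2, 2, params$b2, "+")
}

#' Initialize parameters of a built-in encoder branch
#'
#' Creates the embedding table, layer-norm, attention, feed-forward, and
#' output-projection parameters of one encoder branch. Weights are small
#' Gaussian draws (sd `0.2/sqrt(fan_in)`-ish scaled), deterministic under
#' `seed`.
#'
#' @param vocab Character vector of tokens.
#' @param d_model Token embedding / attention width.
#' @param d_ff Feed-forward hidden width.
#' @param heads Attention head count (`d_model` must be divisible).
#' @param d_out Width of the pooled output vector (256 by default).
#' @param seed Integer seed.
#' @return List of parameter matrices, class `encoder_params`.
#' @export
encoder_params <- function(vocab, d_model = 16L, d_ff = 32L, heads = 2L,
                           d_out = 256L, seed = 1L) {
  split_heads(d_model, heads)  # validates divisibility
  with_seed(seed, {
    rmat <- function(nr, nc, sc = 1 / sqrt(nr)) {
      matrix(stats::rnorm(nr * nc, sd = sc), nr, nc)
    }
    p <- list(
      emb = structure(rmat(length(vocab), d_model, 0.5),
                      dimnames = list(vocab, NULL)),
      ln_g = rep(1, d_model), ln_b = rep(0, d_model),
      attn = list(Wq = rmat(d_model, d_model), Wk = rmat(d_model, d_model),
                  Wv = rmat(d_model, d_model), Wo = rmat(d_model, d_model),
                  h = as.integer(heads)),
      ffn = list(W1 = rmat(d_model, d_ff), b1 = rep(0, d_ff),
                 W2 = rmat(d_ff, d_model), b2 = rep(0, d_model)),
      Wp = rmat(d_model, d_out), bp = rep(0, d_out)
    )
  })
  structure(p, class = "encoder_params", d_model = d_model, d_out = d_out)
}

#' Run one encoder block
#'
#' Token matrix in, token representations and pooled embedding out:
#' `F = FFN(LN(X) + MHSA(LN(X)))` computed token-wise, then mean-pooled over
#' tokens and linearly projected to the fixed output width.
#'
#' @param M L x d token embedding matrix (from [embed_tokens()]).
#' @param params An [encoder_params()] list (its `emb` table is not used
#'   here; pass pre-embedded input).
#' @return List with `tokens` (L x d_out token-wise projected outputs) and
#'   `pooled` (length-d_out vector).
#' @export
encoder_block <- function(M, params) {
  Xt <- layer_norm(M, params$ln_g, params$ln_b)
  H <- Xt + mhsa(Xt, params$attn)
  Fm <- ffn(H, params$ffn)
  Tok <- sweep(Fm %*% params$Wp, 2, params$bp, "+")
  list(tokens = Tok, pooled = colMeans(Tok))
}

#' Adapter for an external pretrained encoder
#'
#' The built-in encoder can be replaced by any external model (for example a
#' pretrained protein or chemical language model) wrapped as a function that
#' maps a sequence string to a numeric vector. The adapter enforces the same
#' contract as [encoder_block()]: a fixed-width pooled vector of width
#' `d_out`, obtained by a seeded linear projection when the external width
#' differs. Nothing is ever downloaded; the caller supplies the model.
#'
#' @param fn Function `function(seq) numeric vector`, or `NULL`.
#' @param d_out Required output width.
#' @param frozen Logical; frozen adapters receive no gradient updates (the
#'   built-in trainer always treats adapters as frozen features).
#' @param seed Seed for the width-matching projection.
#' @return Function of class `pretrained_adapter` mapping a sequence to a
#'   length-`d_out` vector.
#' @export
pretrained_adapter <- function(fn, d_out = 256L, frozen = TRUE, seed = 1L) {
  if (is.null(fn) || !is.function(fn)) {
    stop("no external encoder supplied; pass a function(seq) -> numeric, ",
         "or use the built-in encoder (encoder_params/encoder_block)",
         call. = FALSE)
  }
  proj <- local({
    cache <- new.env(parent = emptyenv())
    function(v) {
      if (length(v) == d_out) return(as.numeric(v))
      key <- as.character(length(v))
      if (is.null(cache[[key]])) {
        cache[[key]] <- with_seed(seed, {
          matrix(stats::rnorm(length(v) * d_out, sd = 1 / sqrt(length(v))),
                 length(v), d_out)
        })
      }
      as.numeric(v %*% cache[[key]])
    }
  })
  structure(function(seq) proj(fn(seq)),
            class = c("pretrained_adapter", "function"),
            d_out = d_out, frozen = frozen)
}
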