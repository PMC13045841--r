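# Cross-modality fusion: multi-head cross-attention from the TCR (protein)
# representation onto the peptide (molecule) representation, and the binding
# probability head.
#
# The protein side supplies the attention queries and the molecule side the
# keys and values, so the aligned output E_align is a peptide-conditioned
# re-expression of the TCR representation. The classifier then sees
# Z = [E_protein; E_align].
#
# Two granularities are supported. With pooled vectors (length-1 token
# sequences) the softmax over a single key is identically 1 and the
# cross-attention collapses to a fixed linear map of the molecule embedding,
# E_align = E_molecule Wv Wo; with token matrices the attention weights
# depend on both modalities and genuine cross-modality interactions are
# representable.

#' Parameters for the cross-attention fusion stage
#'
#' @param d_out Width of the pooled embeddings entering fusion.
#' @param heads Cross-attention head count.
#' @param seed Seed for initialization.
#' @return List with `Wq`, `Wk`, `Wv`, `Wo` (d_out x d_out) and `h`;
#'   class `fusion_params`.
#' @export
fusion_params <- function(d_out = 256L, heads = 2L, seed = 1L) {
  split_heads(d_out, heads)
  with_seed(seed, {
    rmat <- function(n) matrix(stats::rnorm(n * n, sd = 1 / sqrt(n)), n, n)
    p <- list(Wq = rmat(d_out), Wk = rmat(d_out), Wv = rmat(d_out),
              Wo = rmat(d_out), h = as.integer(heads))
  })
  structure(p, class = "fusion_params", d_out = d_out)
}

#' Multi-head cross-attention alignment
#'
#' Queries are projected from the protein representation, keys and values
#' from the molecule representation; per-head scaled dot-product attention
#' is concatenated and projected by `Wo`. Output width equals input width,
#' so the aligned representation is directly comparable to `e_protein`
#' (as the alignment loss requires).
#'
#' @param e_protein Numeric vector (pooled) or Lp x d matrix (token
#'   granularity) of protein-side representations.
#' @param e_molecule Numeric vector or Lm x d matrix of molecule-side
#'   representations.
#' @param params A [fusion_params()] list.
#' @return Same shape as `e_protein`: the aligned representation.
#' @export
mhca <- function(e_protein, e_molecule, params) {
  vec_in <- is.null(dim(e_protein))
  P <- if (vec_in) matrix(e_protein, 1L) else as.matrix(e_protein)
  M <- if (is.null(dim(e_molecule))) matrix(e_molecule, 1L) else as.matrix(e_molecule)
  if (ncol(P) != nrow(params$Wq) || ncol(M) != nrow(params$Wk)) {
    stop("embedding width does not match fusion parameters", call. = FALSE)
  }
  out <- mhsa(P, params, KV_in = M)
  if (vec_in) as.numeric(out) else out
}

#' Parameters of the classification head
#'
#' A single affine map over `Z = [e_protein; e_align]` followed by a sigmoid.
#'
#' @param d_out Width of each embedding (the head sees `2 * d_out` inputs).
#' @param seed Seed for initialization.
#' @return List with weight vector `w` (length 2 d_out) and scalar `b`.
#' @export
head_params <- function(d_out = 256L, seed = 1L) {
  with_seed(seed, {
    p <- list(w = stats::rnorm(2L * d_out, sd = 1 / sqrt(2 * d_out)), b = 0)
  })
  structure(p, class = "head_params", d_out = d_out)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Binding probability from fused representations
#'
#' Concatenates the protein embedding with the aligned representation and
#' applies the affine + sigmoid head: `y_hat = sigmoid(w . [e_p; e_a] + b)`.
#' The probability is strictly inside (0, 1).
#'
#' @param e_protein,e_align Length-d numeric vectors.
#' @param head A [head_params()] list.
#' @return List of class `fusion_output` with `e_align`, `z` (the
#'   concatenation) and `y_hat`.
#' @export
predict_binding <- function(e_protein, e_align, head) {
  if (length(e_protein) != length(e_align)) {
    stop("`e_protein` and `e_align` must have equal width", call. = FALSE)
  }
  z <- c(e_protein, e_align)
  if (length(z) != length(head$w)) {
    stop("head width does not match embeddings", call. = FALSE)
  }
  y <- sigmoid(sum(head$w * z) + head$b)
  structure(list(e_align = e_align, z = z, y_hat = y), class = "fusion_output")
}
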