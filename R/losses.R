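# Composite training objective: binary cross-entropy on the predicted
# binding probability plus an alignment regularizer pulling the
# cross-attended representation toward the TCR embedding.

#' Binary cross-entropy loss
#'
#' `-(1/N) sum(y log y_hat + (1 - y) log(1 - y_hat))`, with probabilities
#' clamped to `[eps, 1 - eps]` before the logarithm.
#'
#' @param y_hat Predicted probabilities in (0, 1).
#' @param y 0/1 labels.
#' @param eps Clamp for log arguments.
#' @return Non-negative scalar.
#' @export
#' @examples
#' bce_loss(rep(0.5, 4), c(1, 0, 1, 0)) # log(2)
bce_loss <- function(y_hat, y, eps = 1e-12) {
  if (length(y_hat) == 0L) stop("empty batch", call. = FALSE)
  if (length(y_hat) != length(y)) stop("length mismatch", call. = FALSE)
  if (any(y_hat <= 0 | y_hat >= 1)) {
    if (any(y_hat < 0 | y_hat > 1)) stop("`y_hat` must be in [0, 1]", call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) stop("`y` must be 0/1", call. = FALSE)
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Alignment regularization loss
#'
#' Mean squared Euclidean distance between the aligned and protein
#' representations: `(1/N) sum_i ||e_align_i - e_protein_i||^2`.
#'
#' @param e_align,e_protein N x d matrices (or length-d vectors for N = 1).
#' @return Non-negative scalar.
#' @export
align_loss <- function(e_align, e_protein) {
  A <- if (is.null(dim(e_align))) matrix(e_align, 1L) else as.matrix(e_align)
  P <- if (is.null(dim(e_protein))) matrix(e_protein, 1L) else as.matrix(e_protein)
  if (!all(dim(A) == dim(P))) stop("width mismatch between `e_align` and `e_protein`",
                                   call. = FALSE)
  mean(rowSums((A - P)^2))
}

#' Composite loss
#'
#' `L = L_bce + lambda * L_align`; `lambda = 0` reduces exactly to the BCE
#' loss.
#'
#' @param bce,align Loss components.
#' @param lambda Non-negative alignment weight.
#' @return Scalar.
#' @export
total_loss <- function(bce, align, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda < 0) {
    stop("`lambda` must be a non-negative scalar", call. = FALSE)
  }
  bce + lambda * align
}

#' Training configuration
#'
#' Hyperparameters of the seeded training loop. None of the defaults are
#' canonical; all are overridable.
#'
#' @param lambda Alignment-loss weight (non-negative). Default 0.1.
#' @param optimizer Only `"adam"` is implemented.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Upper bound on epochs.
#' @param patience Early stopping: stop after this many consecutive epochs
#'   without a strict improvement in validation AUC.
#' @param seed Seed covering parameter initialization and shuffling.
#' @return List of class `loss_config`.
#' @export
loss_config <- function(lambda = 0.1, optimizer = "adam", learning_rate = 1e-3,
                        batch_size = 64L, max_epochs = 30L, patience = 5L,
                        seed = 1L) {
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  optimizer <- match.arg(optimizer, "adam")
  stopifnot(learning_rate >= 0, is_count(batch_size), batch_size >= 1,
            is_count(max_epochs), max_epochs >= 1, is_count(patience),
            patience >= 1)
  structure(list(lambda = lambda, optimizer = optimizer,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "loss_config")
}
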