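# Seeded end-to-end training with Adam and early stopping on validation
# AUC-ROC. Training/validation must be peptide-disjoint; this is enforced,
# not assumed.

adam_init <- function(p) list(m = zero_grads(p), v = zero_grads(p))

adam_update <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    for (nm in names(p)) {
      res <- adam_update(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, b1, b2, eps)
      p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
    }
  } else if (is.double(p)) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^t)
    vhat <- v / (1 - b2^t)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = p, m = m, v = v)
}

predict_probs <- function(model, data, idx = seq_along(data$y)) {
  pooled <- attr(model, "granularity") == "pooled"
  .cb_predict(unclass(model$prot), unclass(model$mol), unclass(model$fus),
              unclass(model$head), data$prot_tok, data$mol_tok,
              as.integer(data$mol_id), as.integer(idx), pooled,
              identical(attr(model, "pooling"), "lse"))
}

# pure-R reference scorer, retained for cross-path verification
predict_probs_ref <- function(model, data, idx = seq_along(data$y)) {
  pooled <- attr(model, "granularity") == "pooled"
  pooling <- attr(model, "pooling") %||% "mean"
  mol_ids <- unique(data$mol_id[idx])
  molG <- lapply(mol_ids, function(m) {
    branch_forward(model$mol, data$mol_tok[[m]], pooled, pooling)$G
  })
  names(molG) <- as.character(mol_ids)
  vapply(idx, function(i) {
    Gp <- branch_forward(model$prot, data$prot_tok[[i]], pooled, pooling)$G
    Gm <- molG[[as.character(data$mol_id[i])]]
    out <- attn_forward(Gp, Gm, model$fus)$out
    z <- c(pool_rows(Gp, pooling)$pooled, pool_rows(out, pooling)$pooled)
    sigmoid(sum(model$head$w * z) + model$head$b)
  }, numeric(1))
}

#' Train the binding-prediction model
#'
#' Seeded minibatch training of the composite objective with the Adam
#' optimizer. After each epoch the validation AUC-ROC is computed; training
#' stops when it has not strictly improved for `config$patience` consecutive
#' epochs (or at `config$max_epochs`), and the parameters of the best-AUC
#' epoch are returned.
#'
#' @param train_set,val_set Peptide-disjoint `pair_dataset`s; the validation
#'   set must contain both classes (AUC is undefined otherwise).
#' @param config A [loss_config()].
#' @param arch Named list of architecture settings passed to
#'   [crossbind_model()] (`d_model`, `d_ff`, `heads`, `d_out`,
#'   `fusion_heads`, `granularity`).
#' @param input_spec Optional [ablation_variant()] specification.
#' @param stereo Write stereochemical SMILES for the molecule branch.
#' @return Object of class `crossbind_fit`: the best model, per-epoch
#'   `history` (train loss, validation AUC), the resolved config and the
#'   vocabulary/variant needed to score new pairs.
#' @export
train_crossbind <- function(train_set, val_set, config = loss_config(),
                            arch = list(), input_spec = NULL, stereo = FALSE) {
  assert_peptide_disjoint(train_set, val_set, c("train", "validation"))
  if (length(unique(val_set$label)) < 2L) {
    stop("validation set must contain both classes (AUC undefined)",
         call. = FALSE)
  }
  variant <- if (is.null(input_spec)) "full" else input_spec$variant
  a <- utils::modifyList(
    list(d_model = 16L, d_ff = 32L, heads = 2L, d_out = 32L,
         fusion_heads = 2L, granularity = "pooled", pooling = "lse"),
    arch
  )
  mv <- molecule_vocab(train_set, variant, stereo)
  model <- crossbind_model(mv, d_model = a$d_model, d_ff = a$d_ff,
                           heads = a$heads, d_out = a$d_out,
                           fusion_heads = a$fusion_heads,
                           granularity = a$granularity, pooling = a$pooling,
                           seed = config$seed)
  tr <- prepare_inputs(train_set, model, input_spec, stereo)
  va <- prepare_inputs(val_set, model, input_spec, stereo)

  n <- length(tr$y)
  state <- adam_init(unclass(model)[c("prot", "mol", "fus", "head")])
  best_auc <- -Inf
  best_model <- model
  bad <- 0L
  t_step <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_auc = numeric(0))
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(config$seed * 10000L + epoch, sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (b in batches) {
      lg <- model_loss_grads(model, tr, b, lambda = config$lambda)
      ep_loss <- ep_loss + lg$loss * length(b)
      t_step <- t_step + 1L
      core <- unclass(model)[c("prot", "mol", "fus", "head")]
      res <- adam_update(core, lg$grads, state$m, state$v,
                         config$learning_rate, t_step)
      state$m <- res$m
      state$v <- res$v
      for (nm in names(core)) model[[nm]] <- res$p[[nm]]
    }
    val_auc <- auc_roc(predict_probs(model, va), va$y)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n,
                                         val_auc = val_auc))
    if (val_auc > best_auc) {
      best_auc <- val_auc
      best_model <- model
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$patience) break
    }
  }
  structure(list(model = best_model, history = history, config = config,
                 arch = a, input_spec = input_spec, stereo = stereo,
                 best_val_auc = best_auc),
            class = "crossbind_fit")
}

#' Predict binding probabilities or extract embeddings
#'
#' @param object A `crossbind_fit`.
#' @param newdata A `pair_dataset`.
#' @param type `"prob"` for binding probabilities; `"embedding"` for the
#'   classifier inputs `Z = [e_protein; e_align]`, one row per pair.
#' @param ... Unused.
#' @return Numeric vector of probabilities, or an N x 2 d_out matrix.
#' @export
predict.crossbind_fit <- function(object, newdata, type = c("prob", "embedding"),
                                  ...) {
  type <- match.arg(type)
  model <- object$model
  data <- prepare_inputs(newdata, model, object$input_spec, object$stereo)
  if (type == "prob") return(predict_probs(model, data))
  pooled <- attr(model, "granularity") == "pooled"
  pooling <- attr(model, "pooling") %||% "mean"
  mol_ids <- unique(data$mol_id)
  molG <- lapply(mol_ids, function(m) {
    branch_forward(model$mol, data$mol_tok[[m]], pooled, pooling)$G
  })
  names(molG) <- as.character(mol_ids)
  t(vapply(seq_along(data$y), function(i) {
    Gp <- branch_forward(model$prot, data$prot_tok[[i]], pooled, pooling)$G
    Gm <- molG[[as.character(data$mol_id[i])]]
    out <- attn_forward(Gp, Gm, model$fus)$out
    c(pool_rows(Gp, pooling)$pooled, pool_rows(out, pooling)$pooled)
  }, numeric(2L * attr(model, "d_out"))))
}

#' @export
print.crossbind_fit <- function(x, ...) {
  cat("crossbind fit: ", nrow(x$history), " epochs, best validation AUC ",
      sprintf("%.3f", x$best_val_auc), "\n", sep = "")
  cat("  granularity: ", x$arch$granularity, ", d_model ", x$arch$d_model,
      ", d_out ", x$arch$d_out, ", variant ",
      if (is.null(x$input_spec)) "full" else x$input_spec$variant, "\n",
      sep = "")
  invisible(x)
}
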