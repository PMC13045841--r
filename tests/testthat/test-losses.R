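test_that("binary cross-entropy matches closed forms and hand arithmetic", {
  expect_equal(bce_loss(rep(0.5, 10), rep(c(0, 1), 5)), log(2))
  # clamped perfect predictions sit at the epsilon floor
  expect_lte(bce_loss(c(1, 0), c(1, 0)), 1e-11)
  # N = 3 hand case
  y_hat <- c(0.9, 0.2, 0.7)
  y <- c(1, 0, 1)
  manual <- -(log(0.9) + log(1 - 0.2) + log(0.7)) / 3
  expect_equal(bce_loss(y_hat, y), manual, tolerance = 1e-9)

  expect_error(bce_loss(numeric(0), numeric(0)), "empty")
  expect_error(bce_loss(c(0.5, 0.5), c(0, 2)), "0/1")
  expect_error(bce_loss(1.2, 1), "y_hat")
})

test_that("alignment loss is the mean squared distance", {
  e <- matrix(rnorm(12), 3, 4)
  expect_equal(align_loss(e, e), 0)
  expect_equal(align_loss(c(1, 0, 0), c(0, 0, 0)), 1)
  set.seed(8)
  A <- matrix(rnorm(8), 2, 4)
  P <- matrix(rnorm(8), 2, 4)
  manual <- 0
  for (i in 1:2) {
    acc <- 0
    for (j in 1:4) acc <- acc + (A[i, j] - P[i, j])^2
    manual <- manual + acc
  }
  expect_equal(align_loss(A, P), manual / 2, tolerance = 1e-12)
  expect_error(align_loss(matrix(0, 2, 3), matrix(0, 2, 4)), "mismatch")
})

test_that("composite loss is affine in lambda and validates it", {
  expect_identical(total_loss(0.62, 0.4, 0), 0.62)
  expect_equal(total_loss(0.5, 0.25, 1), 0.75)
  grid <- seq(0, 3, by = 0.25)
  vals <- vapply(grid, function(l) total_loss(0.3, 0.2, l), 0)
  expect_true(all(diff(vals) > 0))  # increasing when align > 0
  expect_error(total_loss(0.5, 0.2, -1), "non-negative")
})

test_that("loss configuration enforces its invariants", {
  cfg <- loss_config()
  expect_s3_class(cfg, "loss_config")
  expect_identical(cfg$optimizer, "adam")
  expect_error(loss_config(lambda = -0.1))
  expect_error(loss_config(patience = 0))
  expect_error(loss_config(batch_size = 0))
})

test_that("analytic gradients match finite differences in every group", {
  d <- simulate_pairs(synthetic_config(n_tcr = 60, n_pep = 5, seed = 29),
                      pairs_per_peptide = 4)
  mv <- molecule_vocab(d)
  model <- crossbind_model(mv, d_model = 8, d_ff = 12, heads = 2, d_out = 8,
                           granularity = "tokens", seed = 31)
  data <- prepare_inputs(d, model)
  idx <- c(2, 7)  # 2-sample batch
  lam <- 0.3
  lg <- model_loss_grads(model, data, idx = idx, lambda = lam)
  paths <- list(c("prot", "emb"), c("prot", "ln_g"), c("prot", "ln_b"),
                c("prot", "attn", "Wq"), c("prot", "attn", "Wk"),
                c("prot", "attn", "Wv"), c("prot", "attn", "Wo"),
                c("prot", "ffn", "W1"), c("prot", "ffn", "b1"),
                c("prot", "ffn", "W2"), c("prot", "ffn", "b2"),
                c("prot", "Wp"), c("prot", "bp"),
                c("mol", "emb"), c("mol", "attn", "Wq"),
                c("mol", "ffn", "W1"), c("mol", "Wp"),
                c("fus", "Wq"), c("fus", "Wk"), c("fus", "Wv"), c("fus", "Wo"),
                c("head", "w"), c("head", "b"))
  eps <- 1e-5
  getp <- function(m, path) { x <- m; for (p in path) x <- x[[p]]; x }
  setp <- function(m, path, val) {
    expr <- paste0("m", paste0("[[\"", path, "\"]]", collapse = ""), " <- val")
    eval(parse(text = expr))
    m
  }
  for (path in paths) {
    g <- getp(lg$grads, path)
    i <- which.max(abs(g))
    x <- getp(model, path)
    x1 <- x; x1[i] <- x[i] + eps
    x2 <- x; x2[i] <- x[i] - eps
    l1 <- model_loss_grads(setp(model, path, x1), data, idx, lam)$loss
    l2 <- model_loss_grads(setp(model, path, x2), data, idx, lam)$loss
    num <- (l1 - l2) / (2 * eps)
    rel <- abs(num - g[i]) / max(1e-8, abs(num) + abs(g[i]))
    expect_lt(rel, 1e-3, label = paste("gradient", paste(path, collapse = "$")))
  }
})

test_that("compiled and reference paths agree to machine precision", {
  d <- simulate_pairs(synthetic_config(n_tcr = 80, n_pep = 6, seed = 37),
                      pairs_per_peptide = 5)
  mv <- molecule_vocab(d)
  for (gran in c("tokens", "pooled")) {
    model <- crossbind_model(mv, d_model = 8, d_ff = 12, heads = 2, d_out = 8,
                             granularity = gran, seed = 41)
    data <- prepare_inputs(d, model)
    a <- model_loss_grads(model, data, idx = 1:12, lambda = 0.2,
                          use_compiled = TRUE)
    b <- model_loss_grads(model, data, idx = 1:12, lambda = 0.2,
                          use_compiled = FALSE)
    expect_equal(a$loss, b$loss, tolerance = 1e-12)
    expect_equal(a$y_hat, b$y_hat, tolerance = 1e-12)
    expect_equal(unlist(a$grads, use.names = FALSE),
                 unlist(b$grads, use.names = FALSE), tolerance = 1e-10)
  }
})
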