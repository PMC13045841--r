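test_that("layer norm standardizes rows and handles degenerate input", {
  set.seed(1)
  M <- matrix(rnorm(40), 5, 8)
  out <- layer_norm(M)
  expect_lt(max(abs(rowMeans(out))), 1e-6)
  expect_true(all(abs(apply(out, 1, function(r) mean(r^2)) - 1) < 1e-3))

  const <- matrix(3, 2, 6)
  expect_true(all(abs(layer_norm(const)) < 1e-6))  # zero-variance limit

  pre <- layer_norm(M)
  expect_equal(layer_norm(pre), pre, tolerance = 1e-4)  # idempotent up to eps

  g <- runif(8); b <- rnorm(8)
  expect_equal(layer_norm(M, g, b),
               sweep(sweep(layer_norm(M), 2, g, "*"), 2, b, "+"))
})

test_that("token embedding adds positional signal and reconstructs", {
  vocab <- c("A", "C", "F", "<unk>")
  set.seed(2)
  emb <- matrix(rnorm(16), 4, 4, dimnames = list(vocab, NULL))
  X <- embed_tokens(c("A", "A", "C"), emb)
  expect_false(isTRUE(all.equal(X[1, ], X[2, ])))  # same token, different rows
  pe <- positional_encoding(3, 4)
  for (i in 1:3) {
    tok <- c("A", "A", "C")[i]
    expect_equal(unname(X[i, ]), unname(emb[tok, ] + pe[i, ]))
  }
  expect_equal(unname(embed_tokens("Z", emb)[1, ]),
               unname(emb["<unk>", ] + positional_encoding(1, 4)[1, ]))
  expect_error(embed_tokens(character(0), emb), "empty")
  expect_error(embed_tokens("Z", emb[1:3, ]), "vocabulary")
})

test_that("self-attention matches the nested-loop oracle on random cases", {
  for (case in 1:6) {
    set.seed(case)
    L <- sample(1:5, 1)
    h <- sample(1:2, 1)
    d <- h * sample(1:4, 1)
    M <- matrix(rnorm(L * d), L, d)
    p <- random_attention_params(d, h, seed = case * 100)
    expect_equal(mhsa(M, p), oracle_attention(M, M, p), tolerance = 1e-6)
  }
})

test_that("attention weights are row-stochastic and L=1 is the identity map", {
  set.seed(9)
  d <- 4
  M <- matrix(rnorm(12), 3, d)
  p <- random_attention_params(d, 1, seed = 5)
  w <- mhsa(M, p, return_weights = TRUE)$weights
  for (A in w) expect_equal(rowSums(A), rep(1, 3))

  id <- list(Wq = diag(d), Wk = diag(d), Wv = diag(d), Wo = diag(d), h = 1L)
  x <- matrix(rnorm(d), 1, d)
  expect_equal(mhsa(x, id), x)  # single position: softmax over one key is 1

  expect_error(mhsa(matrix(0, 2, 3), p), "width")
})

test_that("encoder block pools token outputs and is order-sensitive", {
  vocab <- amino_acids()
  p <- encoder_params(vocab, d_model = 8, d_ff = 12, heads = 2, d_out = 6,
                      seed = 4)
  X <- embed_tokens(c("A", "C", "F"), p$emb)
  out <- encoder_block(X, p)
  expect_identical(dim(out$tokens), c(3L, 6L))
  expect_length(out$pooled, 6)
  expect_equal(out$pooled, colMeans(out$tokens))

  # constant FFN output: every token maps to b2, pooled = proj of b2
  pz <- p
  pz$ffn$W2 <- pz$ffn$W2 * 0
  pz$ffn$b2 <- rep(2, 8)
  outz <- encoder_block(X, pz)
  expect_equal(outz$tokens[1, ], outz$tokens[2, ])
  expect_equal(unname(outz$pooled),
               unname(as.numeric(rep(2, 8) %*% pz$Wp) + pz$bp))

  # positional signal makes token order matter
  Xp <- embed_tokens(c("F", "C", "A"), p$emb)
  expect_false(isTRUE(all.equal(encoder_block(Xp, p)$pooled, out$pooled)))

  # deterministic under the parameter seed
  p2 <- encoder_params(vocab, d_model = 8, d_ff = 12, heads = 2, d_out = 6,
                       seed = 4)
  expect_identical(p, p2)
  expect_identical(encoder_block(X, p2), out)
})

test_that("encoder output stays finite for large-magnitude inputs", {
  p <- encoder_params(c("a", "b"), d_model = 8, d_ff = 8, heads = 2,
                      d_out = 4, seed = 6)
  X <- matrix(runif(40, -1e3, 1e3), 5, 8)
  expect_true(all(is.finite(encoder_block(X, p)$tokens)))
})

test_that("protein and molecule branches are independent parameterizations", {
  d <- simulate_pairs(synthetic_config(n_tcr = 30, n_pep = 4, seed = 3),
                      pairs_per_peptide = 4)
  mv <- molecule_vocab(d)
  model <- crossbind_model(mv, d_model = 8, d_ff = 8, heads = 2, d_out = 8,
                           seed = 11)
  expect_false(isTRUE(all.equal(model$prot$attn$Wq, model$mol$attn$Wq)))
  X <- matrix(rnorm(24), 3, 8)
  expect_false(isTRUE(all.equal(encoder_block(X, model$prot)$pooled,
                                encoder_block(X, model$mol)$pooled)))
})

test_that("adapter contract: errors, mock smoke, width projection", {
  expect_error(pretrained_adapter(NULL), "built-in encoder")
  mock <- pretrained_adapter(function(seq) rep(1, 8), d_out = 8)
  expect_length(mock("CASF"), 8)
  wide <- pretrained_adapter(function(seq) rep(1, 10), d_out = 8, seed = 2)
  v <- wide("CASF")
  expect_length(v, 8)
  expect_identical(v, wide("CASF"))  # projection is fixed under seed
})
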