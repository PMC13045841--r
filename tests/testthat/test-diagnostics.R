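two_blobs <- function(n = 60, sep = 10, sd = 0.2, d = 3, seed = 1) {
  set.seed(seed)
  half <- n %/% 2
  rbind(matrix(rnorm(half * d, 0, sd), half, d),
        matrix(rnorm((n - half) * d, sep, sd), n - half, d))
}

test_that("Hopkins score sits near 0.5 for uniform and near 1 for clustered",
{
  hs <- vapply(1:10, function(s) {
    set.seed(s + 500)
    hopkins_score(matrix(runif(300 * 4), 300, 4), n_test = 30, seed = s)
  }, 0)
  expect_lt(abs(mean(hs) - 0.5), 0.05)

  blobs <- two_blobs(200, sep = 50, sd = 0.05)
  expect_gt(hopkins_score(blobs, n_test = 20, seed = 1), 0.9)
})

test_that("Hopkins ratio equals an independent recomputation of the draws", {
  set.seed(77)
  pts <- matrix(rnorm(20), 10, 2)
  n_test <- 3
  seed <- 5
  # reproduce the seeded draws and assemble the ratio by definition
  drawn <- withr::with_seed(seed, {
    ti <- sample.int(10, n_test)
    lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
    U <- matrix(runif(n_test * 2), n_test) *
      rep(hi - lo, each = n_test) + rep(lo, each = n_test)
    list(ti = ti, U = U)
  })
  nnd <- function(p, excl) {
    min(vapply(setdiff(seq_len(10), excl), function(j) {
      sqrt(sum((p - pts[j, ])^2))
    }, 0))
  }
  d_t <- sum(vapply(seq_len(n_test), function(i) {
    nnd(pts[drawn$ti[i], ], drawn$ti[i])
  }, 0))
  d_r <- sum(vapply(seq_len(n_test), function(i) nnd(drawn$U[i, ], NULL), 0))
  expect_equal(hopkins_score(pts, n_test = n_test, seed = seed),
               d_r / (d_r + d_t), tolerance = 1e-12)
})

test_that("CTS applies the printed normalization to the squared-distance
           ratio and vanishes for uniform data", {
  # internal consistency on identical draws
  set.seed(9)
  pts <- matrix(runif(400), 100, 4)
  ratio_sq <- crossbind:::hopkins_ratio(pts, 20, seed = 3, squared = TRUE)
  expect_equal(cluster_tendency_score(pts, 20, seed = 3),
               2 * max(ratio_sq - 0.5, 0))

  cts <- vapply(1:20, function(s) {
    set.seed(s + 900)
    cluster_tendency_score(matrix(runif(250 * 4), 250, 4), n_test = 25,
                           seed = s)
  }, 0)
  expect_lt(mean(cts), 0.15)
  expect_true(all(cts >= 0 & cts <= 1))

  blobs <- two_blobs(200, sep = 50, sd = 0.05)
  expect_gt(cluster_tendency_score(blobs, n_test = 20, seed = 1), 0.5)
})

test_that("degenerate coincident data is flagged, not an error", {
  same <- matrix(1, 30, 3)
  expect_warning(hs <- hopkins_score(same, n_test = 5, seed = 1), "degenerate")
  expect_equal(hs, 1)
})

test_that("silhouette matches the loop oracle and its closed-form limits", {
  set.seed(15)
  for (i in 1:8) {
    n <- sample(6:30, 1)
    pts <- matrix(rnorm(n * 3), n, 3)
    labs <- sample(1:3, n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    expect_equal(silhouette_index(pts, labs), oracle_silhouette(pts, labs),
                 tolerance = 1e-9)
  }
  # two tight clusters far apart approach s = 1
  blobs <- two_blobs(40, sep = 1000, sd = 1e-4)
  labs <- rep(1:2, each = 20)
  expect_gt(silhouette_index(blobs, labs), 0.999)
  # all points coincident: 0/0 convention gives 0
  expect_equal(silhouette_index(matrix(1, 10, 2), rep(1:2, 5)), 0)
  expect_error(silhouette_index(matrix(rnorm(10), 5, 2), rep(1, 5)),
               "2 clusters")
})

test_that("silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(25)
  pts <- matrix(rnorm(60), 20, 3)
  labs <- sample(1:2, 20, replace = TRUE)
  ref <- mean(cluster::silhouette(labs, dist(pts))[, "sil_width"])
  expect_equal(silhouette_index(pts, labs), ref, tolerance = 1e-9)
})

test_that("Calinski-Harabasz equals hand and loop oracles and is rigid-motion
           invariant", {
  # two symmetric clusters on a line: B = 16, W = 1, CHI = (16/1)/(1/2)
  pts <- matrix(c(0, 1, 4, 5), 4, 1)
  labs <- c(1, 1, 2, 2)
  expect_equal(calinski_harabasz(pts, labs), 32)

  set.seed(19)
  for (i in 1:6) {
    n <- sample(8:30, 1)
    p <- matrix(rnorm(n * 2), n, 2)
    l <- sample(1:3, n, replace = TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(calinski_harabasz(p, l), oracle_chi(p, l), tolerance = 1e-9)
    # translation and rotation leave it unchanged
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    moved <- sweep(p %*% R, 2, c(3, -7), "+")
    expect_equal(calinski_harabasz(moved, l), calinski_harabasz(p, l),
                 tolerance = 1e-8)
  }

  degen <- calinski_harabasz(matrix(rep(c(0, 5), each = 4), 8, 1),
                             rep(1:2, each = 4))
  expect_true(isTRUE(attr(degen, "degenerate")))
  expect_error(calinski_harabasz(matrix(rnorm(8), 4, 2), rep(1, 4)), "2 <= K")
})

test_that("diagnostics bundle separates clustered from uniform embeddings", {
  blobs <- two_blobs(300, sep = 8, sd = 0.5, d = 4, seed = 33)
  diag_b <- embedding_diagnostics(blobs, k = 2, n_test = 50, seed = 3)
  expect_gt(diag_b$hopkins, 0.7)
  expect_gt(diag_b$cts, 0.4)
  expect_gt(diag_b$silhouette, 0.5)
  expect_gt(diag_b$chi, 100)

  set.seed(44)
  unif <- matrix(runif(300 * 4), 300, 4)
  diag_u <- embedding_diagnostics(unif, k = 2, n_test = 50, seed = 3)
  expect_lt(diag_u$cts, 0.3)
  expect_lt(diag_u$silhouette, diag_b$silhouette)

  # deterministic under seed
  expect_identical(embedding_diagnostics(blobs, k = 2, n_test = 50, seed = 3),
                   diag_b)
})
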