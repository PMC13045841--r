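random_dataset <- function(n_pep, rows_range = c(1, 10), seed = 1) {
  set.seed(seed)
  peps <- vapply(seq_len(n_pep), function(i) {
    paste(sample(amino_acids(), 9, replace = TRUE), collapse = "")
  }, "")
  peps <- make.unique(peps, sep = "")  # safeguard; collisions are improbable
  choices <- seq(rows_range[1], rows_range[2])
  rows <- choices[sample.int(length(choices), n_pep, replace = TRUE)]
  pep_col <- rep(peps, rows)
  n <- length(pep_col)
  tcr <- vapply(seq_len(n), function(i) {
    paste0("C", paste(sample(amino_acids(), 10, replace = TRUE), collapse = ""), "F")
  }, "")
  pair_dataset(tcr, pep_col, sample(0:1, n, replace = TRUE))
}

test_that("grouped split covers the target minimally and is peptide-disjoint", {
  # 2 peptides x 5 rows, r = 0.2: target is 2, first peptide already covers it
  d <- random_dataset(2, c(5, 5), seed = 3)
  for (seed in 1:4) {
    sp <- grouped_split(d, r = 0.2, seed = seed)
    expect_equal(nrow(sp$val), 5)
    expect_length(unique(sp$val$peptide), 1)
  }

  for (seed in 1:25) {
    d <- random_dataset(sample(3:20, 1), seed = seed + 100)
    r <- runif(1, 0.1, 0.6)
    sp <- grouped_split(d, r = r, seed = seed)
    expect_length(intersect(unique(sp$train$peptide),
                            unique(sp$val$peptide)), 0)
    target <- ceiling(r * nrow(d))
    expect_gte(nrow(sp$val), target)
    # minimality: dropping the last-added peptide goes below target
    last <- sp$val_peptides[length(sp$val_peptides)]
    expect_lt(nrow(sp$val) - sum(sp$val$peptide == last), target)
    expect_equal(nrow(sp$train) + nrow(sp$val), nrow(d))
  }

  # the stopping rule guarantees at least ceiling(r N) validation rows
  d <- random_dataset(20, c(5, 5), seed = 9)
  expect_gte(nrow(grouped_split(d, r = 0.2, seed = 1)$val), 20)

  one <- random_dataset(1, c(4, 4), seed = 2)
  expect_error(grouped_split(one, 0.2, 1), "2 distinct")
  expect_error(grouped_split(random_dataset(3, seed = 1), r = 0), "\\(0, 1\\)")
})

test_that("grouped k-fold partitions rows with peptide-disjoint folds", {
  d <- random_dataset(13, c(2, 9), seed = 7)
  k <- 4
  folds <- grouped_kfold(d, k = k, seed = 2)
  expect_length(folds, k)
  key <- function(x) paste(x$tcr, x$peptide, x$label)
  all_val <- unlist(lapply(folds, function(f) key(f$val)))
  expect_setequal(all_val, key(d))
  expect_equal(length(all_val), nrow(d))  # pairwise disjoint partition
  for (f in folds) {
    expect_length(intersect(unique(f$train$peptide),
                            unique(f$val$peptide)), 0)
    expect_equal(nrow(f$train) + nrow(f$val), nrow(d))
  }
  # greedy packing keeps the spread below the largest peptide group
  sizes <- vapply(folds, function(f) nrow(f$val), 0)
  expect_lte(max(sizes) - min(sizes), max(table(d$peptide)))

  # leave-one-peptide-out when k equals the peptide count
  d5 <- random_dataset(5, c(2, 4), seed = 11)
  lopo <- grouped_kfold(d5, k = 5, seed = 1)
  for (f in lopo) expect_length(f$val_peptides, 1)

  expect_error(grouped_kfold(d5, k = 6, seed = 1), "fewer distinct peptides")
})

test_that("few-shot subsetting keeps the requested peptides and pair caps", {
  d <- random_dataset(10, c(40, 40), seed = 5)
  # identity when everything is kept
  expect_identical(few_shot_subset(d, 1, Inf, seed = 1), d)
  # 20% of 10 peptides
  sub <- few_shot_subset(d, 0.2, Inf, seed = 1)
  expect_length(unique(sub$peptide), 2)
  # cap at five pairs per peptide on a 40-pair fixture
  sub5 <- few_shot_subset(d, 0.2, 5, seed = 1)
  expect_true(all(table(sub5$peptide) == 5))
  expect_length(unique(sub5$peptide), 2)
  # subsets are rows of the original
  expect_true(all(paste(sub5$tcr, sub5$peptide) %in% paste(d$tcr, d$peptide)))
  # deterministic
  expect_identical(few_shot_subset(d, 0.2, 5, seed = 1),
                   few_shot_subset(d, 0.2, 5, seed = 1))
  expect_error(few_shot_subset(d, 0, 5, seed = 1), "seen_ratio")
})

test_that("split operations are deterministic under their seeds", {
  d <- random_dataset(12, c(2, 8), seed = 21)
  expect_identical(grouped_split(d, 0.25, seed = 9),
                   grouped_split(d, 0.25, seed = 9))
  expect_identical(grouped_kfold(d, 3, seed = 9), grouped_kfold(d, 3, seed = 9))
  expect_false(identical(grouped_split(d, 0.25, seed = 9),
                         grouped_split(d, 0.25, seed = 10)))
})

test_that("hard peptide leakage between tables is an error", {
  d <- random_dataset(6, c(2, 4), seed = 31)
  sp <- grouped_split(d, 0.3, seed = 1)
  expect_true(assert_peptide_disjoint(sp$train, sp$val))
  expect_error(assert_peptide_disjoint(d, sp$val, c("train+val", "test")),
               "leakage")
})
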