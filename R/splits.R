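# Peptide-level grouped splitting. All rows sharing a peptide go to the same
# side of every split, so validation peptides are never seen in training --
# the leakage-control protocol for epitope generalization.

#' Peptide-grouped train/validation split
#'
#' Uniquifies the peptides, permutes them under `seed`, and accumulates
#' peptides into the validation set until the covered rows reach
#' `ceiling(r * N)`; validation rows are those whose peptide was selected
#' and training rows are the complement. By construction the peptide sets
#' are disjoint, the validation size is at least `ceiling(r * N)`, and
#' removing the last-added peptide would drop it below the target (the
#' stopping rule is minimal).
#'
#' @param dataset A `pair_dataset` (or data.frame with a `peptide` column)
#'   containing at least 2 distinct peptides.
#' @param r Validation ratio in (0, 1).
#' @param seed Seed for the peptide permutation.
#' @return List with `train`, `val` (row subsets) and `val_peptides`.
#' @export
grouped_split <- function(dataset, r = 0.2, seed = 1L) {
  if (r <= 0 || r >= 1) stop("`r` must be in (0, 1)", call. = FALSE)
  peps <- dataset$peptide
  up <- unique(peps)
  if (length(up) < 2L) {
    stop("cannot split: need at least 2 distinct peptides", call. = FALSE)
  }
  N <- length(peps)
  target <- ceiling(r * N)
  perm <- with_seed(seed, sample(up))
  counts <- table(peps)[perm]
  n_cum <- cumsum(as.integer(counts))
  k <- which(n_cum >= target)[1L]
  S <- perm[seq_len(k)]
  in_val <- peps %in% S
  list(train = dataset[!in_val, , drop = FALSE],
       val = dataset[in_val, , drop = FALSE],
       val_peptides = S)
}

#' Peptide-grouped k-fold cross-validation
#'
#' Partitions the unique peptides into `k` blocks balanced by row count
#' (greedy assignment of peptides in decreasing row-count order to the
#' currently lightest fold, after a seeded shuffle for tie-breaking). Every
#' row appears in exactly one validation fold and each fold's validation
#' peptides are disjoint from its training peptides.
#'
#' @inheritParams grouped_split
#' @param k Number of folds (>= 2), at most the number of distinct peptides.
#' @return List of `k` elements, each with `train`, `val`, `val_peptides`.
#' @export
grouped_kfold <- function(dataset, k = 5L, seed = 1L) {
  stopifnot(is_count(k), k >= 2L)
  peps <- dataset$peptide
  up <- unique(peps)
  if (length(up) < k) {
    stop("fewer distinct peptides (", length(up), ") than folds (", k, ")",
         call. = FALSE)
  }
  # first-appearance ordering (not table()/sort()) keeps the assignment
  # independent of the collation locale
  counts <- vapply(up, function(p) sum(peps == p), 0L)
  names(counts) <- up
  shuffled <- with_seed(seed, sample(up))
  ord <- shuffled[order(-counts[shuffled])]
  load <- numeric(k)
  assign_fold <- integer(length(ord))
  for (i in seq_along(ord)) {
    f <- which.min(load)
    assign_fold[i] <- f
    load[f] <- load[f] + counts[[ord[i]]]
  }
  lapply(seq_len(k), function(f) {
    vp <- ord[assign_fold == f]
    in_val <- peps %in% vp
    list(train = dataset[!in_val, , drop = FALSE],
         val = dataset[in_val, , drop = FALSE],
         val_peptides = vp)
  })
}

#' Few-shot reduction of a training set
#'
#' Keeps a seeded random fraction `seen_ratio` of the unique training
#' peptides and, for each kept peptide, at most `pairs_per_peptide` rows
#' (uniform without replacement). Validation/test rows are never touched by
#' this operation -- apply it to the training side only.
#'
#' @param train A `pair_dataset` (training rows).
#' @param seen_ratio Fraction of unique peptides retained, in (0, 1].
#' @param pairs_per_peptide Maximum rows kept per retained peptide;
#'   `Inf` keeps all.
#' @param seed Seed for both subsampling stages.
#' @return Row subset of `train`.
#' @export
few_shot_subset <- function(train, seen_ratio, pairs_per_peptide = 5L,
                            seed = 1L) {
  if (!is.numeric(seen_ratio) || seen_ratio <= 0 || seen_ratio > 1) {
    stop("`seen_ratio` must be in (0, 1]", call. = FALSE)
  }
  if (!(is.infinite(pairs_per_peptide) ||
        (is_count(pairs_per_peptide) && pairs_per_peptide >= 1))) {
    stop("`pairs_per_peptide` must be a positive integer or Inf", call. = FALSE)
  }
  up <- unique(train$peptide)
  with_seed(seed, {
    n_keep <- max(1L, round(seen_ratio * length(up)))
    keep_pep <- sample(up, n_keep)
    rows <- unlist(lapply(keep_pep, function(p) {
      ridx <- which(train$peptide == p)
      if (length(ridx) > pairs_per_peptide) {
        ridx <- sort(sample(ridx, pairs_per_peptide))
      }
      ridx
    }))
  })
  train[sort(rows), , drop = FALSE]
}

#' Assert that two pair tables share no peptides
#'
#' Hard leakage check between e.g. (train + validation) and test: any
#' overlap is an error, not a warning.
#'
#' @param a,b `pair_dataset`s.
#' @param labels Names used in the error message.
#' @return Invisibly `TRUE` when disjoint.
#' @export
assert_peptide_disjoint <- function(a, b, labels = c("train", "test")) {
  common <- intersect(unique(a$peptide), unique(b$peptide))
  if (length(common)) {
    stop("peptide leakage between ", labels[1], " and ", labels[2], ": ",
         paste(utils::head(common, 3L), collapse = ", "),
         if (length(common) > 3L) ", ..." else "", call. = FALSE)
  }
  invisible(TRUE)
}
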