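# Negative-sample construction. Two regimes: "reference" negatives are
# experimentally verified unbound pairs loaded from a table; "random"
# negatives are synthesized by uniform TCR x peptide pairing restricted to
# pairs not present among the positives. The random regime matches the
# positive count by default (ratio 1).

#' Specification of a negative-sampling run
#'
#' @param regime `"random"` (synthesized pairings) or `"reference"`
#'   (verified unbound pairs supplied as a table).
#' @param ratio Negatives per positive; must be positive. Default 1 (equal
#'   numbers).
#' @param seed Seed for the random regime.
#' @return List of class `sampling_spec`.
#' @export
sampling_spec <- function(regime = c("random", "reference"), ratio = 1,
                          seed = 1L) {
  regime <- match.arg(regime)
  if (!is.numeric(ratio) || ratio <= 0) stop("`ratio` must be > 0", call. = FALSE)
  structure(list(regime = regime, ratio = ratio, seed = as.integer(seed)),
            class = "sampling_spec")
}

#' Sample random-control negatives
#'
#' Draws `round(ratio * n_pos)` distinct pairs uniformly from the product
#' of the TCRs and peptides appearing among the positives, excluding every
#' positive pair, and labels them 0. Draws collide occasionally (with the
#' positives or with each other) and are rejection-resampled; if the
#' admissible pair space is too small to supply the requested count, an
#' error is raised. Deterministic under `spec$seed`.
#'
#' @param positives A `pair_dataset` of positive (label 1) rows.
#' @param spec A [sampling_spec()] with `regime = "random"`.
#' @return A `pair_dataset` of label-0 rows.
#' @export
sample_random_negatives <- function(positives, spec = sampling_spec()) {
  if (nrow(positives) == 0L) stop("`positives` is empty", call. = FALSE)
  tcrs <- unique(positives$tcr)
  peps <- unique(positives$peptide)
  pos_key <- paste(positives$tcr, positives$peptide, sep = "\r")
  n_needed <- round(spec$ratio * nrow(positives))
  n_space <- length(tcrs) * length(peps) - length(unique(pos_key))
  if (n_space < n_needed) {
    stop("cannot draw ", n_needed, " negatives: only ", n_space,
         " admissible non-positive pairs exist", call. = FALSE)
  }
  chosen <- character(0)
  with_seed(spec$seed, {
    while (length(chosen) < n_needed) {
      m <- (n_needed - length(chosen)) * 2L
      cand <- paste(sample(tcrs, m, replace = TRUE),
                    sample(peps, m, replace = TRUE), sep = "\r")
      cand <- setdiff(unique(cand), c(pos_key, chosen))
      chosen <- c(chosen, utils::head(cand, n_needed - length(chosen)))
    }
  })
  parts <- strsplit(chosen, "\r", fixed = TRUE)
  new_pair_dataset(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L),
                   rep(0L, n_needed), generator = "random_control",
                   seed = spec$seed)
}

#' Load reference-control negatives
#'
#' Reads a TSV of verified non-binding pairs (columns `tcr`, `peptide`) and
#' returns them as label-0 records. Any pair that also appears among the
#' supplied positives is contradictory and raises an error naming the pair.
#'
#' @param path TSV file with header columns `tcr` and `peptide` (a `label`
#'   column, if present, is ignored).
#' @param positives Optional `pair_dataset` of positives to check
#'   consistency against.
#' @return A `pair_dataset` of label-0 rows (possibly empty).
#' @export
load_reference_negatives <- function(path, positives = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (nrow(df) == 0L) {
    return(new_pair_dataset(character(0), character(0), integer(0),
                            generator = "reference_control"))
  }
  if (!all(c("tcr", "peptide") %in% names(df))) {
    stop("reference table must have `tcr` and `peptide` columns", call. = FALSE)
  }
  if (!is.null(positives)) {
    key <- paste(df$tcr, df$peptide)
    conflict <- key %in% paste(positives$tcr, positives$peptide)
    if (any(conflict)) {
      i <- which(conflict)[1L]
      stop("pair (", df$tcr[i], ", ", df$peptide[i],
           ") is listed both as positive and as reference negative",
           call. = FALSE)
    }
  }
  new_pair_dataset(df$tcr, df$peptide, rep(0L, nrow(df)),
                   generator = "reference_control")
}

#' Ablation input variants
#'
#' Defines how the molecule branch consumes peptides:
#' * `full` -- each peptide is represented by its own SMILES string;
#' * `no_smiles` -- the SMILES encoder is bypassed and peptides enter as
#'   amino-acid token sequences;
#' * `randomized_smiles` -- a seeded permutation (without fixed points,
#'   where possible) reassigns each unique peptide's SMILES to a different
#'   peptide's SMILES for the whole run, preserving the SMILES multiset
#'   while destroying the peptide-structure correspondence.
#'
#' @param dataset A `pair_dataset` whose unique peptides define the mapping.
#' @param variant One of `"full"`, `"no_smiles"`, `"randomized_smiles"`.
#' @param seed Seed for the permutation.
#' @param stereo Passed to [peptide_to_smiles()].
#' @return List of class `model_input_spec` with elements `variant` and
#'   `smiles_map` (named character; `NULL` unless randomized).
#' @export
ablation_variant <- function(dataset, variant = c("full", "no_smiles",
                                                  "randomized_smiles"),
                             seed = 1L, stereo = FALSE) {
  variant <- match.arg(variant)
  smiles_map <- NULL
  if (variant == "randomized_smiles") {
    up <- unique(dataset$peptide)
    smi <- vapply(up, function(p) unclass(peptide_to_smiles(p, stereo = stereo)), "")
    if (length(up) == 1L) {
      warning("only one unique peptide: randomized permutation is the identity")
      perm <- 1L
    } else {
      perm <- with_seed(seed, {
        p <- sample(length(up))
        tries <- 0L
        while (any(p == seq_along(p)) && tries < 1000L) {
          p <- sample(length(up))
          tries <- tries + 1L
        }
        p
      })
    }
    smiles_map <- stats::setNames(smi[perm], up)
  }
  structure(list(variant = variant, smiles_map = smiles_map,
                 seed = as.integer(seed), stereo = stereo),
            class = "model_input_spec")
}
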