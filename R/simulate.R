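# Synthetic TCR/peptide universes with a planted, recoverable binding rule.
#
# Real binding data require curated databases; for testing every downstream
# stage we instead generate CDR3-like beta-chain sequences and 8-11-residue
# peptides, and label pairs by a deterministic motif-compatibility rule: a
# pair binds iff the TCR contains the residue-wise "complement" (under a
# fixed pairing table) of some k-mer of the peptide. The rule is arbitrary
# but fully known, so signal recovery by the model can be tested exactly.

#' Configuration for the synthetic pair generator
#'
#' @param n_tcr Number of TCR sequences in the generated pool.
#' @param n_pep Number of peptide sequences in the generated pool.
#' @param tcr_len_range Integer length 2; min/max CDR3 length in residues
#'   (inclusive), including the fixed `C`/`F` terminal residues.
#' @param pep_len_range Integer length 2; min/max peptide length in residues.
#'   Epitopes presented by MHC class I are typically 8-11 residues, the
#'   default range.
#' @param motif_k Length (residues) of the binding motif used by the planted
#'   rule.
#' @param noise_rate Probability in `[0, 1)` that a pair's label is flipped
#'   after the rule is applied.
#' @param seed Integer seed; identical configurations yield byte-identical
#'   datasets.
#'
#' @return An object of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_tcr = 20, n_pep = 5, seed = 1)
synthetic_config <- function(n_tcr = 100L, n_pep = 20L,
                             tcr_len_range = c(10L, 20L),
                             pep_len_range = c(8L, 11L),
                             motif_k = 3L, noise_rate = 0,
                             seed = 1L) {
  stopifnot(is_count(n_tcr), is_count(n_pep), is_count(motif_k), motif_k >= 1)
  if (length(tcr_len_range) != 2L || tcr_len_range[1] > tcr_len_range[2]) {
    stop("`tcr_len_range` must be (min, max) with min <= max", call. = FALSE)
  }
  if (length(pep_len_range) != 2L || pep_len_range[1] > pep_len_range[2]) {
    stop("`pep_len_range` must be (min, max) with min <= max", call. = FALSE)
  }
  if (pep_len_range[1] < 1) stop("peptide lengths must be positive", call. = FALSE)
  # CDR3 prefix C and suffix F leave len - 2 free positions; the motif must fit
  if (tcr_len_range[1] < motif_k + 2L) {
    stop("`tcr_len_range` minimum must be at least motif_k + 2", call. = FALSE)
  }
  if (pep_len_range[1] < motif_k) {
    stop("peptides must be at least `motif_k` residues long", call. = FALSE)
  }
  if (!is.numeric(noise_rate) || noise_rate < 0 || noise_rate >= 1) {
    stop("`noise_rate` must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(n_tcr = as.integer(n_tcr), n_pep = as.integer(n_pep),
         tcr_len_range = as.integer(tcr_len_range),
         pep_len_range = as.integer(pep_len_range),
         motif_k = as.integer(motif_k), noise_rate = noise_rate,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Residue pairing table of the planted binding rule
#'
#' A fixed involution over the 20-letter alphabet: each residue maps to its
#' "compatible" partner and the mapping is its own inverse. The pairs are
#' loosely inspired by complementary physicochemistry (acid/base,
#' aromatic/aromatic, small/small) but any deterministic involution would
#' serve; nothing downstream depends on the particular choice.
#'
#' @return Named character vector: `residue_pairing()["A"]` is the partner of
#'   alanine.
#' @export
residue_pairing <- function() {
  pairs <- c(A = "G", C = "S", D = "K", E = "R", F = "Y",
             H = "N", I = "V", L = "M", P = "T", Q = "W")
  c(pairs, stats::setNames(names(pairs), unname(pairs)))
}

complement_motif <- function(motif) {
  tab <- residue_pairing()
  vapply(strsplit(motif, ""), function(ch) paste(tab[ch], collapse = ""), "")
}

#' Evaluate the planted binding rule
#'
#' A (TCR, peptide) pair binds iff the TCR contains, as an exact substring,
#' the residue-wise complement (under [residue_pairing()]) of at least one
#' length-`k` substring of the peptide.
#'
#' @param tcr,peptide Character vectors of equal length (recycled if one is
#'   scalar).
#' @param k Motif length.
#' @return Integer vector of 0/1 labels.
#' @export
#' @examples
#' # complement of the peptide 3-mer "DKE" is "KDR", present in the TCR:
#' binding_label("CAKDRAF", "DKEAAAAA", k = 3)
binding_label <- function(tcr, peptide, k = 3L) {
  n <- max(length(tcr), length(peptide))
  tcr <- rep_len(tcr, n); peptide <- rep_len(peptide, n)
  vapply(seq_len(n), function(i) {
    p <- peptide[i]
    np <- nchar(p)
    if (np < k) return(0L)
    kmers <- substring(p, 1:(np - k + 1L), k:np)
    comp <- complement_motif(kmers)
    as.integer(any(vapply(comp, grepl, logical(1), x = tcr[i], fixed = TRUE)))
  }, integer(1))
}

random_seqs <- function(n, len_range, prefix = "", suffix = "") {
  fixed <- nchar(prefix) + nchar(suffix)
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE) - fixed
  aa <- amino_acids()
  vapply(lens, function(l) {
    paste0(prefix, paste(sample(aa, l, replace = TRUE), collapse = ""), suffix)
  }, "")
}

#' Generate pools of synthetic TCR and peptide sequences
#'
#' TCRs are CDR3-like: they begin with `C`, end with `F`, and have lengths in
#' `cfg$tcr_len_range`; peptides have lengths in `cfg$pep_len_range`. Pools
#' contain unique sequences and are deterministic under `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return List with character vectors `tcr_pool` and `pep_pool`.
#' @export
generate_universe <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    tcr_pool <- draw_unique(cfg$n_tcr, cfg$tcr_len_range, prefix = "C", suffix = "F")
    pep_pool <- draw_unique(cfg$n_pep, cfg$pep_len_range)
  })
  list(tcr_pool = tcr_pool, pep_pool = pep_pool)
}

draw_unique <- function(n, len_range, prefix = "", suffix = "") {
  if (n == 0L) return(character(0))
  free <- len_range[2] - nchar(prefix) - nchar(suffix)
  space <- sum(20^pmax(0, seq(len_range[1], len_range[2]) -
                          nchar(prefix) - nchar(suffix)))
  if (n > space) {
    stop("requested pool of ", n, " unique sequences exceeds the sequence space (",
         format(space, big.mark = ","), ")", call. = FALSE)
  }
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    out <- unique(c(out, random_seqs(n - length(out), len_range, prefix, suffix)))
    tries <- tries + 1L
    if (tries > 1000L) stop("could not draw enough unique sequences", call. = FALSE)
  }
  out[seq_len(n)]
}

new_pair_dataset <- function(tcr, peptide, label, generator = "crossbind",
                             seed = NA_integer_) {
  df <- data.frame(tcr = tcr, peptide = peptide, label = as.integer(label),
                   peptide_id = peptide, stringsAsFactors = FALSE)
  structure(df, class = c("pair_dataset", "data.frame"),
            generator = generator, seed = seed)
}

#' Construct and validate a labeled pair table
#'
#' Builds a `pair_dataset` from parallel vectors. Peptide identifiers are the
#' peptide strings themselves, matching how splits are grouped.
#'
#' @param tcr,peptide Amino-acid strings.
#' @param label 0/1 labels.
#' @return A `pair_dataset` (a `data.frame` with columns `tcr`, `peptide`,
#'   `label`, `peptide_id`).
#' @export
pair_dataset <- function(tcr, peptide, label) {
  check_sequences(tcr, "tcr")
  check_sequences(peptide, "peptide")
  if (!all(label %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (length(tcr) != length(peptide) || length(tcr) != length(label)) {
    stop("`tcr`, `peptide`, `label` must have equal length", call. = FALSE)
  }
  new_pair_dataset(tcr, peptide, label)
}

#' Label random TCR x peptide pairings by the planted rule
#'
#' Pairs each TCR in `tcr_pool` with a random peptide from `pep_pool`
#' (uniformly, with replacement over peptides), labels every pair with
#' [binding_label()] at `cfg$motif_k`, and flips each label with probability
#' `cfg$noise_rate`. The attribute `truth` carries the noise-free rule as a
#' function, for oracle checks.
#'
#' @param tcr_pool,pep_pool Non-empty character vectors, e.g. from
#'   [generate_universe()].
#' @param cfg A [synthetic_config()].
#' @return A `pair_dataset` with attribute `truth`.
#' @export
plant_binding_rule <- function(tcr_pool, pep_pool, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (length(tcr_pool) == 0L || length(pep_pool) == 0L) {
    stop("pools must be non-empty", call. = FALSE)
  }
  k <- cfg$motif_k
  with_seed(cfg$seed + 1L, {
    pep <- sample(pep_pool, length(tcr_pool), replace = TRUE)
    lab <- binding_label(tcr_pool, pep, k)
    if (cfg$noise_rate > 0) {
      flip <- stats::runif(length(lab)) < cfg$noise_rate
      lab <- ifelse(flip, 1L - lab, lab)
    }
  })
  out <- new_pair_dataset(tcr_pool, pep, lab, seed = cfg$seed)
  attr(out, "truth") <- function(tcr, peptide) binding_label(tcr, peptide, k)
  out
}

#' Simulate a pair table with a planted hidden-motif binding signal
#'
#' Random pairings are almost always negative (a motif collision is rare),
#' so training-scale datasets concentrate the binding signal on a single
#' hidden motif pair drawn per dataset: a length-`motif_k` peptide-side
#' motif `m` (seeded uniform draw) and its TCR-side complement under
#' [residue_pairing()]. The motif is written into a random position of a
#' fraction `pep_motif_rate` of the peptides, and the complement into a
#' random interior position (`C`/`F` termini preserved) of a fraction
#' `pos_fraction` of each peptide's `pairs_per_peptide` TCRs. A pair
#' therefore binds essentially when *both* sides carry their half of the
#' hidden pair, so recovering the signal requires using both modalities.
#' Labels are always assigned by the full rule ([binding_label()], which
#' also catches the occasional accidental motif collision) and finally
#' flipped with probability `cfg$noise_rate`.
#'
#' @param cfg A [synthetic_config()]. `cfg$n_tcr` sizes the background TCR
#'   pool; it is resampled with replacement if smaller than the number of
#'   pairs.
#' @param pairs_per_peptide Rows generated per peptide.
#' @param pos_fraction Fraction of each peptide's TCRs that receive the
#'   complement implant.
#' @param pep_motif_rate Fraction of peptides that receive the hidden motif.
#' @return A `pair_dataset` with attributes `truth` (the noise-free rule)
#'   and `hidden_motif` (the peptide-side motif).
#' @export
#' @examples
#' d <- simulate_pairs(synthetic_config(n_tcr = 200, n_pep = 10, seed = 7),
#'                     pairs_per_peptide = 10)
#' table(d$label)
simulate_pairs <- function(cfg, pairs_per_peptide = 40L, pos_fraction = 0.5,
                           pep_motif_rate = 0.5) {
  stopifnot(inherits(cfg, "synthetic_config"), is_count(pairs_per_peptide),
            pairs_per_peptide >= 1, pos_fraction >= 0, pos_fraction <= 1,
            pep_motif_rate >= 0, pep_motif_rate <= 1)
  pools <- generate_universe(cfg)
  k <- cfg$motif_k
  with_seed(cfg$seed + 2L, {
    motif <- paste(sample(amino_acids(), k, replace = TRUE), collapse = "")
    comp <- complement_motif(motif)
    peps <- pools$pep_pool
    n_carrier <- round(pep_motif_rate * length(peps))
    if (n_carrier > 0) {
      carriers <- sample(seq_along(peps), n_carrier)
      for (i in carriers) {
        np <- nchar(peps[i])
        start <- sample.int(np - k + 1L, 1L)
        substr(peps[i], start, start + k - 1L) <- motif
      }
      peps <- make.unique.seqs(peps, cfg$pep_len_range)
    }
    rows <- lapply(peps, function(p) {
      tcrs <- sample(pools$tcr_pool, pairs_per_peptide,
                     replace = pairs_per_peptide > length(pools$tcr_pool))
      n_pos <- round(pos_fraction * pairs_per_peptide)
      for (i in seq_len(n_pos)) {
        lt <- nchar(tcrs[i])
        slots <- seq(2L, lt - k)  # keep C prefix and F suffix
        pos <- slots[sample.int(length(slots), 1L)]
        substr(tcrs[i], pos, pos + k - 1L) <- comp
      }
      data.frame(tcr = tcrs, peptide = p, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    lab <- binding_label(df$tcr, df$peptide, k)
    if (cfg$noise_rate > 0) {
      flip <- stats::runif(length(lab)) < cfg$noise_rate
      lab <- ifelse(flip, 1L - lab, lab)
    }
  })
  out <- new_pair_dataset(df$tcr, df$peptide, lab, seed = cfg$seed)
  attr(out, "truth") <- function(tcr, peptide) binding_label(tcr, peptide, k)
  attr(out, "hidden_motif") <- motif
  out
}

# Implanting can collapse two peptides onto the same string; re-randomize
# non-implanted positions of later duplicates until all are distinct.
make.unique.seqs <- function(seqs, len_range) {
  while (any(dup <- duplicated(seqs))) {
    for (i in which(dup)) {
      pos <- sample.int(nchar(seqs[i]), 1L)
      substr(seqs[i], pos, pos) <- sample(amino_acids(), 1L)
    }
  }
  seqs
}

#' Write / read pair tables
#'
#' Plain TSV with columns `tcr`, `peptide`, `label`.
#'
#' @param x A `pair_dataset`.
#' @param path File path.
#' @return `read_pairs` returns a `pair_dataset`; `write_pairs` returns
#'   `path` invisibly.
#' @export
write_pairs <- function(x, path) {
  utils::write.table(x[, c("tcr", "peptide", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "integer"))
  pair_dataset(df$tcr, df$peptide, df$label)
}
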