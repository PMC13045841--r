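# Internal helpers shared across modules.

#' The 20-letter amino-acid alphabet
#'
#' One-letter codes of the canonical residues, alphabetical order.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit so seeded operations never perturb the
# global stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

check_sequences <- function(x, what = "sequence") {
  if (!is.character(x)) stop("`", what, "` must be a character vector", call. = FALSE)
  bad <- grepl(paste0("[^", paste(amino_acids(), collapse = ""), "]"), x)
  if (any(bad)) {
    stop("invalid ", what, ": non-standard residue in ",
         sQuote(x[which(bad)[1L]]), call. = FALSE)
  }
  invisible(x)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
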