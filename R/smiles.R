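# Peptide -> SMILES conversion and tokenization of both modalities.
#
# Epitope peptides are short (8-11 residues), which limits what a sequence
# model can extract from the raw amino-acid string. Serializing the peptide's
# molecular graph as SMILES yields a longer string that spells out atom
# connectivity and functional groups, giving the molecule-side encoder a far
# richer token stream.

# Side-chain SMILES fragments attached to the alpha carbon, N -> C direction.
# Glycine has no side chain; proline is handled separately because its
# backbone nitrogen is part of the pyrrolidine ring.
SIDE_CHAINS <- c(
  A = "C",
  C = "CS",
  D = "CC(O)=O",
  E = "CCC(O)=O",
  F = "Cc1ccccc1",
  G = "",
  H = "Cc1c[nH]cn1",
  I = "[C@@H](C)CC",
  K = "CCCCN",
  L = "CC(C)C",
  M = "CCSC",
  N = "CC(N)=O",
  P = NA_character_,  # ring residue, special-cased
  Q = "CCC(N)=O",
  R = "CCCNC(N)=N",
  S = "CO",
  T = "[C@H](O)C",
  V = "C(C)C",
  W = "Cc1c[nH]c2ccccc12",
  Y = "Cc1ccc(O)cc1"
)

strip_stereo <- function(s) gsub("\\[C@@?H\\]", "C", s)

residue_unit <- function(aa, stereo) {
  if (aa == "P") {
    ca <- if (stereo) "[C@@H]" else "C"
    return(paste0("N1CCC", ca, "1C(=O)"))
  }
  side <- SIDE_CHAINS[[aa]]
  if (!stereo) side <- strip_stereo(side)
  if (side == "") return("NCC(=O)")  # glycine: alpha carbon achiral
  ca <- if (stereo) "[C@@H]" else "C"
  paste0("N", ca, "(", side, ")C(=O)")
}

#' Convert a peptide sequence to a SMILES string
#'
#' Serializes the linear peptide's molecular graph as SMILES, walking the
#' backbone from N- to C-terminus: per-residue units are condensed through
#' amide bonds (one water lost per bond) and the terminal carboxyl is
#' retained. With `stereo = TRUE` the alpha carbons of chiral residues are
#' written in the L configuration (`[C@@H]`), as are the side-chain
#' stereocenters of isoleucine and threonine. The output is one valid
#' depth-first serialization of the molecule; any SMILES parser will
#' canonicalize it to the same structure.
#'
#' @param peptide Single amino-acid string over the 20 canonical residues.
#'   Ambiguity codes (B, Z, X) are rejected.
#' @param stereo Write stereochemistry? Default `TRUE`.
#' @return An object of class `smiles_string`: the SMILES text with
#'   attribute `source_peptide`.
#' @export
#' @examples
#' peptide_to_smiles("G")   # "NCC(=O)O", i.e. glycine
#' peptide_to_smiles("GG")  # one amide bond, one water condensed out
peptide_to_smiles <- function(peptide, stereo = TRUE) {
  if (!is.character(peptide) || length(peptide) != 1L || is.na(peptide) ||
      nchar(peptide) == 0L) {
    stop("`peptide` must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(peptide, "")[[1]]
  bad <- !(chars %in% amino_acids())
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("unknown residue ", sQuote(chars[i]), " at position ", i,
         " in peptide ", sQuote(peptide), call. = FALSE)
  }
  units <- vapply(chars, residue_unit, "", stereo = stereo)
  structure(paste0(paste(units, collapse = ""), "O"),
            class = "smiles_string", source_peptide = peptide)
}

#' Tokenize an amino-acid sequence into residue characters
#'
#' One token per character, order preserved; concatenating the tokens
#' reconstructs the input.
#'
#' @param seq Single non-empty amino-acid string.
#' @return A `token_sequence`: character vector of tokens with attribute
#'   `modality = "protein"`.
#' @export
tokenize_protein <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop("`seq` must be a single non-empty string", call. = FALSE)
  }
  check_sequences(seq, "seq")
  structure(strsplit(seq, "")[[1]], class = "token_sequence",
            modality = "protein")
}

# Published SMILES token convention: bracket atoms as single tokens,
# two-letter organic-subset halogens as single tokens, '%'-escaped two-digit
# ring closures, everything else one character.
SMILES_TOKEN_RE <- paste0(
  "(\\[[^\\]]*\\]|Br|Cl|%[0-9]{2}|[BCNOSPFIbcnosp]|",
  "[0-9]|[=#\\-\\+\\(\\)/\\\\\\.@:\\*\\$~])"
)

#' Tokenize a SMILES string
#'
#' Splits SMILES text into chemically meaningful tokens following the
#' standard regex convention: bracket atoms (`[C@@H]`, `[nH]`, ...) and the
#' two-letter halogens (`Cl`, `Br`) are single tokens; ring-closure digits,
#' bonds and parentheses are individual tokens. The token concatenation
#' always reconstructs the input.
#'
#' @param s SMILES text (a `smiles_string` or plain character scalar).
#' @return A `token_sequence` with attribute `modality = "smiles"`.
#' @export
#' @examples
#' tokenize_smiles("NCC(=O)O")
tokenize_smiles <- function(s) {
  s <- unclass(s)
  if (!is.character(s) || length(s) != 1L || is.na(s) || nchar(s) == 0L) {
    stop("`s` must be a single non-empty SMILES string", call. = FALSE)
  }
  # reject structurally unmatched brackets/parentheses up front
  noatom <- gsub("\\[[^\\]]*\\]", "", s, perl = TRUE)
  if (grepl("[\\[\\]]", noatom, perl = TRUE)) {
    stop("unmatched bracket in SMILES ", sQuote(s), call. = FALSE)
  }
  chars <- strsplit(noatom, "")[[1]]
  if (length(chars)) {
    depth <- cumsum(chars == "(") - cumsum(chars == ")")
    if (any(depth < 0) || depth[length(depth)] != 0) {
      stop("unmatched parenthesis in SMILES ", sQuote(s), call. = FALSE)
    }
  }
  m <- gregexpr(SMILES_TOKEN_RE, s, perl = TRUE)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (paste(toks, collapse = "") != s) {
    stop("SMILES contains untokenizable characters: ", sQuote(s), call. = FALSE)
  }
  structure(toks, class = "token_sequence", modality = "smiles")
}

#' @export
print.smiles_string <- function(x, ...) {
  cat("<smiles_string> ", unclass(x), "\n  peptide: ",
      attr(x, "source_peptide"), "\n", sep = "")
  invisible(x)
}
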