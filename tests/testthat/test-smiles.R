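chem_formula <- function(smiles) {
  unname(ChemmineR::MF(ChemmineR::smiles2sdf(smiles), addH = TRUE))
}

canonical_smiles <- function(smiles) {
  out <- ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n"))
  sub("\t.*", "", sub("\n$", "", out))
}

test_that("single residues and dipeptides give the textbook molecules", {
  skip_if_not_installed("ChemmineR")
  g <- peptide_to_smiles("G")
  expect_identical(as.character(g), "NCC(=O)O")
  expect_identical(attr(g, "source_peptide"), "G")
  expect_identical(chem_formula(unclass(g)), "C2H5NO2")

  gg <- peptide_to_smiles("GG")
  expect_identical(as.character(gg), "NCC(=O)NCC(=O)O")
  expect_identical(chem_formula(unclass(gg)), "C4H8N2O3")  # 2 Gly - H2O

  # L-alanine with stereochemistry
  expect_identical(as.character(peptide_to_smiles("A")), "N[C@@H](C)C(=O)O")
})

test_that("every residue's SMILES parses to the reference formula", {
  skip_if_not_installed("ChemmineR")
  ref <- c(A = "C3H7NO2", R = "C6H14N4O2", N = "C4H8N2O3", D = "C4H7NO4",
           C = "C3H7NO2S", E = "C5H9NO4", Q = "C5H10N2O3", G = "C2H5NO2",
           H = "C6H9N3O2", I = "C6H13NO2", L = "C6H13NO2", K = "C6H14N2O2",
           M = "C5H11NO2S", F = "C9H11NO2", P = "C5H9NO2", S = "C3H7NO3",
           T = "C4H9NO3", W = "C11H12N2O2", Y = "C9H11NO3", V = "C5H11NO2")
  for (aa in amino_acids()) {
    for (st in c(TRUE, FALSE)) {
      expect_identical(chem_formula(unclass(peptide_to_smiles(aa, stereo = st))),
                       ref[[aa]], label = paste("residue", aa))
    }
  }
})

test_that("peptide SMILES heavy-atom count follows condensation arithmetic", {
  skip_if_not_installed("ChemmineR")
  heavy_atoms <- function(formula) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
    parts <- regmatches(formula, list(m))[[1]]
    tot <- 0
    for (p in parts) {
      el <- gsub("[0-9]", "", p)
      n <- suppressWarnings(as.integer(gsub("[A-Za-z]", "", p)))
      if (is.na(n)) n <- 1L
      if (el != "H") tot <- tot + n
    }
    tot
  }
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    pep <- paste(sample(amino_acids(), n, replace = TRUE), collapse = "")
    residue_heavy <- vapply(strsplit(pep, "")[[1]], function(a) {
      heavy_atoms(chem_formula(unclass(peptide_to_smiles(a))))
    }, 0)
    whole <- heavy_atoms(chem_formula(unclass(peptide_to_smiles(pep))))
    expect_equal(whole, sum(residue_heavy) - (n - 1))  # one O lost per bond
  }
})

test_that("conversion is injective on a random peptide universe", {
  skip_if_not_installed("ChemmineOB")
  cfg <- synthetic_config(n_tcr = 1, n_pep = 40, seed = 17)
  peps <- generate_universe(cfg)$pep_pool
  canon <- vapply(peps, function(p) {
    canonical_smiles(unclass(peptide_to_smiles(p, stereo = TRUE)))
  }, "")
  expect_false(anyDuplicated(canon) > 0)
})

test_that("invalid peptides are rejected with position information", {
  expect_error(peptide_to_smiles(""), "non-empty")
  expect_error(peptide_to_smiles("AXA"), "'X' at position 2")
  expect_error(peptide_to_smiles("GBZ"), "'B' at position 2")
})

test_that("protein tokenizer is per-character and reversible", {
  expect_identical(as.character(tokenize_protein("CAF")), c("C", "A", "F"))
  expect_identical(attr(tokenize_protein("CAF"), "modality"), "protein")
  set.seed(3)
  for (i in 1:20) {
    s <- paste(sample(amino_acids(), sample(5:25, 1), replace = TRUE),
               collapse = "")
    tk <- tokenize_protein(s)
    expect_length(tk, nchar(s))
    expect_identical(paste(tk, collapse = ""), s)
  }
  expect_error(tokenize_protein(""), "non-empty")
  expect_error(tokenize_protein("AB1"), "invalid")
})

test_that("SMILES tokenizer matches a character-scan oracle and reverses", {
  expect_identical(as.character(tokenize_smiles("NCC(=O)O")),
                   c("N", "C", "C", "(", "=", "O", ")", "O"))
  expect_identical(as.character(tokenize_smiles("C[C@@H]N")),
                   c("C", "[C@@H]", "N"))
  set.seed(11)
  for (i in 1:10) {
    pep <- paste(sample(amino_acids(), sample(2:8, 1), replace = TRUE),
                 collapse = "")
    s <- as.character(peptide_to_smiles(pep, stereo = (i %% 2 == 0)))
    tk <- as.character(tokenize_smiles(s))
    expect_identical(tk, oracle_smiles_tokens(s))
    expect_identical(paste(tk, collapse = ""), s)
  }
  expect_error(tokenize_smiles("C("), "parenthesis")
  expect_error(tokenize_smiles("CC)C"), "parenthesis")
  expect_error(tokenize_smiles("C[C@"), "bracket")
})
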