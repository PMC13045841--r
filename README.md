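# crossbind

Cross-attention modeling of T-cell receptor (TCR) – peptide binding from
paired sequence and SMILES representations.

## The problem

Whether a T cell recognizes an antigen is largely decided by the
interaction between the CDR3 loop of the TCR β chain and a short peptide
(8–11 residues) presented by the MHC. Predicting this interaction from
sequence alone is central to immunotherapy design, and the hard part is
generalization: a useful model must score peptides it never saw in
training, and its evaluation must be protected from peptide leakage
between training and validation data. `crossbind` is an R package for this
task, aimed at computational immunologists who want a complete,
reproducible, CPU-scale implementation of the dual-encoder
cross-attention approach together with the evaluation protocol around it.

## The model

Each pair (TCR `s`, peptide `p`) is scored as

```
E_prot  = FFN(LN(X) + MHSA(LN(X)))            X = embed(tokens(s))
E_mol   = FFN(LN(Y) + MHSA(LN(Y)))            Y = embed(tokens(DFS(p)))
E_align = MHCA(Q = E_prot, K = V = E_mol)
ŷ       = σ( W [E_prot; E_align] + b )
```

where `DFS(p)` is the peptide serialized as a SMILES string (its molecular
graph written N→C through amide condensation), `MHSA`/`MHCA` are
multi-head self- and cross-attention (`softmax(QKᵀ/√d_k)V` per head), and
the training objective is

```
L = BCE(ŷ, y) + λ · (1/N) Σ ‖E_align − E_prot‖²
```

— binary cross-entropy plus an alignment regularizer pulling the
cross-attended representation toward the TCR embedding. Gradients are
exact (hand-derived, finite-difference-verified) and the training loop is
a compiled RcppArmadillo kernel, seeded and bit-reproducible. Pretrained
protein/chemical language models can replace either encoder through
`pretrained_adapter()`; nothing is ever downloaded.

Around the model, the package provides peptide-grouped train/validation
splitting and k-fold CV (`grouped_split()`, `grouped_kfold()`),
random-control and reference-control negative sampling
(`sample_random_negatives()`, `load_reference_negatives()`), few-shot
subsampling (`few_shot_subset()`), SMILES ablation variants
(`ablation_variant()`), classification metrics (`classification_metrics()`)
and embedding diagnostics — Hopkins score, cluster tendency score,
silhouette, Calinski–Harabasz (`embedding_diagnostics()`). A synthetic
generator (`simulate_pairs()`) plants a recoverable motif-compatibility
binding rule so the whole pipeline is testable without any external data.

## Worked example

Simulate a universe with a planted binding rule, split it with no peptide
overlap, train the tiny built-in model, and score the held-out peptides:

```r
library(crossbind)

cfg   <- synthetic_config(n_tcr = 2400, n_pep = 60, seed = 11)
pairs <- simulate_pairs(cfg, pairs_per_peptide = 40)
sp    <- grouped_split(pairs, r = 0.2, seed = 1)   # peptide-disjoint 80/20

fit <- train_crossbind(sp$train, sp$val, config = loss_config(seed = 1))
fit
#> crossbind fit: 30 epochs, best validation AUC 0.815
#>   granularity: pooled, d_model 16, d_out 32, variant full

classification_metrics(predict(fit, sp$val), sp$val$label)
#> Binary classification metrics (n = 480, threshold = 0.5)
#>   auc_roc   0.8155
#>   accuracy  0.7646
#>   recall    0.1885
#>   precision 0.6216
#>   f1        0.2893
#>   auc_pr    0.5371

emb <- predict(fit, sp$val, type = "embedding")
embedding_diagnostics(emb, k = 2, n_test = 100, seed = 1)
#> Embedding diagnostics (n = 480, n_test = 100, seed = 1)
#>   Hopkins score        0.783
#>   Cluster tendency     0.851
#>   Silhouette index     0.304
#>   Calinski-Harabasz    238.64
```

The validation AUC-ROC of 0.82 is measured on peptides never seen during
training — the model has recovered the planted binding signal rather than
memorized peptide identities (at this scale the recovery is dominated by
the receptor-side motif; the methods vignette analyzes why). The diagnostics show the
trained pair embeddings are clustered (Hopkins 0.78, CTS 0.85) rather
than uniform, which is what separable binding/non-binding classes look
like in embedding space.

Peptide→SMILES conversion is also available directly:

```r
peptide_to_smiles("ACDF")
#> <smiles_string> N[C@@H](C)C(=O)N[C@@H](CS)C(=O)N[C@@H](CC(O)=O)C(=O)N[C@@H](Cc1ccccc1)C(=O)O
#>   peptide: ACDF
```

A thin command-line front end covering simulation, conversion, negative
sampling, splitting, training and evaluation is installed at
`system.file("cli", "crossbind.R", package = "crossbind")`.

## Scope

The built-in encoders are deliberately small, single-block transformers —
a faithful, testable implementation of the architecture, not a substitute
for large pretrained models. The synthetic binding rule is a deterministic
string-compatibility rule; see the methods vignette
(`vignettes/crossbind-methods.Rmd`) for what passing on synthetic data
does and does not establish about real TCR–pMHC repertoires.
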