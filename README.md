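# dtattn

Drug–target binding affinity prediction with interpretable cross-attention,
in pure R.

## The problem

Estimating how strongly a small-molecule compound binds a protein target —
the binding affinity, here on the pKd scale (−log10 of the molar
dissociation constant; higher = tighter binding) — is a core step in
computational drug discovery. Binding is local: it happens between particular
substructures of the compound and particular sub-sequences of the protein,
not between the molecules as wholes. `dtattn` implements an affinity
regressor built around that observation, for computational chemists and
method developers who want a fully inspectable, CPU-scale implementation of
the local-to-global attention approach to drug–target affinity (DTA)
modelling.

## The model

A compound SMILES string is parsed into a molecular graph whose atoms carry
78-dimensional binary features (element, degree, hydrogen counts,
aromaticity) and whose bonds carry 14-dimensional features (type,
conjugation, ring membership, stereo). One of five message-passing encoders
— GCN, GAT, GIN, MPNN or DMPNN — produces the drug embedding matrix
**D** ∈ R^(Na×d), one row per atom; each row summarizes the atom's
substructure out to one bond per layer. The protein sequence is integer
encoded, truncated/padded to length 1000, and passed through an embedding
layer and three stride-1 1D convolutions (kernel 8), producing the
sub-sequence embedding matrix **S** ∈ R^(Ns×d), one row per window of
22 consecutive residues.

The interaction module computes the relation matrix

    R = D S'          (Na × Ns, dot products of atom and window embeddings)

and normalizes it two ways:

    a_ij = exp(r_ij) / Σ_i exp(r_ij)   substructure significance  (columns sum to 1)
    s_ij = exp(r_ij) / Σ_j exp(r_ij)   sub-sequence significance  (rows sum to 1)

`a` weights atoms to build an attended drug feature `(Σ_j a_j)' D`, `s`
weights windows to build an attended protein feature `(Σ_i s_i) S`; their
concatenation feeds a fully connected head (1024, 512, 1) that regresses
pKd. The same `a` and `s` are exported as interpretable attention maps:
which atoms matter to which residue windows. Training minimizes MSE with
Adam (learning rate 5e-4, weight decay 1e-5, batch 32) and early stopping
(patience 30); evaluation uses MSE and the concordance index (CI), the
fraction of pair orderings the predictions get right. All neural components,
including backpropagation, are implemented in base R matrix algebra on a
small internal reverse-mode tape — there is no deep-learning framework
dependency.

Because benchmark-scale training data cannot ship with the package, a
first-class synthetic generator emulates a Davis-like kinase panel: grammar
assembled small molecules (a seeded fraction carrying a quinazoline-like
fragment), uniform random sequences (a seeded fraction carrying a planted
motif), and labels `5.0 + 3.0·[fragment ∧ motif] + N(0, 0.3)` with a floor
near pKd 5, so that effect recovery and attention interpretability are
testable end to end.

## A worked example

```r
library(dtattn)

# a small synthetic kinase-panel-like benchmark
ds <- generate_dta(synthetic_spec(n_compounds = 30, n_proteins = 40,
                                  n_pairs = 500,
                                  seq_length_range = c(100, 200), seed = 1))
cfg <- dta_config(variant = "GCN", gnn_layers = 2, embedding_size = 16,
                  prot_embed_dim = 16, conv_channels = c(8, 12),
                  fc_sizes = c(64, 32), max_len = 200, kernel_size = 8,
                  dropout = 0, learning_rate = 5e-3, epochs = 30,
                  patience = 29, seed = 1)
model <- dta_model(cfg, build_vocab(ds$data$sequence))

split <- split_six_parts(nrow(ds$data), seed = 2)   # 5 CV folds + 1 test part
fit <- train_dta(model, ds$data[sort(unlist(split$folds)), ])
ev <- evaluate_dta(fit, ds$data[split$test, ])
round(c(mse = ev$mse, ci = ev$ci), 3)
#>   mse    ci
#> 0.189 0.691

rk <- motif_attention_rank(fit, ds)
round(mean(rk$rank_fraction), 3)
#> [1] 0.44
```

The held-out MSE of 0.189 approaches the label noise floor (0.09 = 0.3²),
and the mean normalized attention rank of 0.44 (0.5 = chance, smaller =
more focused) says the trained sub-sequence attention already leans toward
the planted motif after these 30 cheap epochs; `scripts/acceptance.R`, which
trains the same configuration over three seeds, reaches ≈ 0.28 — the model
finds *where* the interaction happens, not just *that* it happens.

Attention maps for a single pair export as TSV:

```r
pair <- ds$data[which(ds$truth$signal)[1], ]
export_attention(fit, pair$smiles, pair$sequence, "attention.tsv")
```

with one summary row per atom and per residue window (0-based half-open
window coordinates on the truncated sequence) for each significance matrix.

A thin command-line wrapper covers the same workflow
(`generate`, `train`, `evaluate`, `predict`, `attention`, `ablation`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "dtattn.R", package = "dtattn"))')" \
    generate --out demo --n-pairs 200 --seed 7
```

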