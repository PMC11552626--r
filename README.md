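# modsite

Sequence-based prediction of post-translational modification (PTM) sites in
which residues *already known* to carry the PTM are encoded as extra
amino-acid tokens.

## The problem and the idea

Phosphorylation, glycosylation, ubiquitination and other PTMs are hard to
map experimentally at scale, so sequence-based predictors are widely used.
Most of them look only at the local amino-acid context of a candidate site.
But PTMs influence each other: kinase substrates often contain already
phosphorylated residues, O-GlcNAc and phosphate compete for the same
serines and threonines, and modified sites cluster along the sequence.

`modsite` exploits this crosstalk with a deliberately simple trick: known
modified residues are rewritten as extra alphabet tokens before encoding.
For a phospho-S/T model, a known phosphoserine becomes `@` and a known
phosphothreonine becomes `&`, so the sequence `ASDTK` with known sites at
positions 2 and 4 enters the model as `A@D&K`. The classifier then learns
how nearby known sites bear on the probability that the *queried* site
(whose own status is always masked) is modified. The same machinery supports
cross-PTM labeling — encoding known sites of a *different* modification to
predict the target one.

## The model

A candidate site is the centered k-mer (default k = 53) around a target
residue, padded with `-` past the protein termini. Tokens map to integers
(`-`→0, A→1, C→2, D→3, …, Y→20, U→21, then mod tokens), pass through a
learned word embedding of length 21, a full-embedding-width 2D convolution
(ReLU, L2 1e−6 on the kernel), max pooling over positions, a dense ReLU
layer, dropout 0.1 and a sigmoid output. Training uses Adam (lr 0.001),
binary cross-entropy, batches of 100, at most 400 epochs with early
stopping (patience 15 on validation loss, best-epoch weights restored).
The network and its backpropagation are implemented in vectorized base R —
no deep-learning framework is required — which also yields exact input-space
gradients for the interpretability module.

Around the classifier the package provides, each as a tested module:

* **Dataset construction** — candidate enumeration over target residues,
  1:1 negative subsampling, 80/10/10 random splits with a guarantee that no
  test k-mer is identical to a train/validation k-mer, ungapped-identity
  filtering down to any cutoff (e.g. 40%), and 10-fold Monte Carlo
  cross-validation with fresh negatives per fold.
* **Evaluation** — exact Mann–Whitney AUC (ties ½), step-interpolated
  AUPRC, fold mean ± sd, and a paired test comparing models trained with and
  without known-site labels.
* **Interpretability** — integrated gradients on the embedded input
  (right-Riemann path sum), position-summed attributions (PSIG), K-means
  clustering of attribution tensors, and per-cluster position×token
  frequency matrices for sequence logos.
* **Proximity analysis** — the frequency of known PTMs at each signed
  offset from candidate sites, with an auditable classification of the
  histogram shape (uniform / periodic / decaying).
* **Synthetic data** — a seeded proteome generator with planted motifs and
  planted PTM crosstalk, so the whole pipeline is testable offline.
* **CLI** — `simulate`, `build-dataset`, `train`, `predict`, `evaluate`,
  `interpret`, `proximity` and `tyom` (train your own model) subcommands.

## Worked example

Generate a synthetic proteome whose positive sites partly depend on nearby
known sites, then train paired models with and without the known-site
tokens:

```r
library(modsite)

sim <- simulate_proteome(simulation_spec(n_proteins = 100, seed = 42))
cmp <- compare_label_models(sim$sequences, sim$positives, c("S", "T"),
                            known_channel = sim$channel, folds = 3,
                            seed = 42, allow_small = TRUE)
print(cmp$summary)
#> CV over 3 folds: AUC 0.8453 +/- 0.0898, AUPRC 0.8513 +/- 0.1180
#> paired comparison: delta AUC 0.0771, t-test p = 0.06979
```

The labeled model's fold-mean AUC exceeds the unlabeled model's by ~0.08:
knowing neighboring modification sites carries information the raw sequence
does not. (Three folds are used here for speed; the acceptance suite runs
the full five-fold comparison at 300 proteins, where the difference is
significant at p < 0.05.)

Why does labeling help? Because modified sites cluster:

```r
ds <- enumerate_candidates(sim$sequences, c("S", "T"), sim$positives, k = 53)
h <- nearby_ptm_frequency(ds, sim$channel, w = 10, stratum = "positives")
print(classify_pattern(h))
#> pattern: decaying (cv 1.210, period 3 z 2.45, rho -0.886)
```

Known sites pile up at small distances from positive sites and thin out
with distance — the "decaying" pattern under which known-site labeling
helps most.

The same workflow from the shell:

```sh
Rscript -e 'modsite::modsite_cli()' simulate --out data/ --seed 42
Rscript -e 'modsite::modsite_cli()' tyom --fasta data/proteome.fasta \
    --sites data/positives.tsv --allow-small --out model.rds
Rscript -e 'modsite::modsite_cli()' predict --model model.rds \
    --fasta query.fasta --out predictions.csv
```

Query FASTA may contain `@`/`&` at known modified positions; predictions
come back as CSV with one probability per candidate residue.

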