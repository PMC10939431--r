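# hyperhda

Herb–disease association (HDA) prediction from the multi-component,
multi-target structure of herbal medicine.

Herbs act through sets of chemical components, and diseases are
characterised by sets of protein targets. `hyperhda` represents both
sides as hypergraphs — herbs are hyperedges over component nodes,
diseases are hyperedges over target nodes — and learns herb and disease
embeddings with a dual-channel hypergraph convolutional network:

- **Node features.** Components: 2048-bit Morgan fingerprints from
  SMILES, compared with the Dice coefficient
  `S_C^{ij} = |M_i ∩ M_j| / ((|M_i| + |M_j|)/2)`. Targets: normalised
  global sequence-alignment similarity. Each similarity row is
  compressed to `d` dimensions by a single-layer autoencoder.
- **Convolution.** Per channel and layer,
  `E^{l+1} = σ(D_v^{-1} A D_e^{-1} A^T E^l Θ^l + E^l)` — hyperedge
  aggregation, node aggregation, a trainable `d×d` transform, and a
  residual skip; the per-layer hyperedge readouts
  `M^l = D_e^{-1} A^T E^l` are summed into the final herb/disease
  embeddings.
- **Scoring and loss.** `p_ij = sigmoid(E_H^i · E_D^j)`, trained with
  cross-entropy plus an L2 penalty `λ Σ ||Θ^l||_F²`.
- **Evaluation.** Balanced k-fold cross-validation with disjoint
  negative sampling, repeated CV, shuffle-robustness curves, cold-start
  splits, one-switch ablations (mean readout, random features,
  Tanimoto, BLOSUM62, cold start), and exact Mann–Whitney AUROC plus
  average-precision AUPRC.
- **Synthetic benchmark.** A seeded generator plants latent
  component/target groups, draws herbs and diseases as small
  hyperedges, and derives labels transitively through the group
  bioactivity links, so the whole pipeline is testable offline.

## Worked example

```r
library(hyperhda)

# component similarity from SMILES
smi <- c(ethanol = "CCO", acetic_acid = "CC(=O)O", ethylamine = "CCN")
round(component_similarity_matrix(smi), 3)
#>             acetic_acid ethanol ethylamine
#> acetic_acid       1.000   0.286      0.143
#> ethanol           0.286   1.000      0.500
#> ethylamine        0.143   0.500      1.000

# planted synthetic benchmark: 60 herbs, 120 components, 80 targets,
# 50 diseases, 4 latent groups, 5% label noise
ds <- generate_planted_dataset(seed = 7)
report <- cross_validate(ds, hda_config(seed = 1), k = 5)
round(report$per_fold, 4)
#>   repeat_ fold recall precision     f1  auroc  auprc
#> 1       1    1      1       0.5 0.6667 0.9236 0.9283
#> 2       1    2      1       0.5 0.6667 0.9204 0.9161
#> 3       1    3      1       0.5 0.6667 0.9428 0.9573
#> 4       1    4      1       0.5 0.6667 0.9207 0.9389
#> 5       1    5      1       0.5 0.6667 0.9299 0.9385
round(report$mean, 4)
#>    recall precision        f1     auroc     auprc
#>    1.0000    0.5000    0.6667    0.9275    0.9358
```

Mean AUROC ≈ 0.93 on the planted benchmark means the model recovers the
latent group structure from the hypergraphs and similarity blocks.
Recall 1 / precision 0.5 at the default 0.5 threshold reflects a
structural property of the ReLU channels: readouts are nonnegative, so
every score is ≥ 0.5 and the scores should be read as rankings (see the
methods vignette, `vignettes/methods.Rmd`).

A thin command-line wrapper around the same functions lives at
`inst/cli/hda.R` with subcommands `similarity`, `embed`, `train`,
`predict`, `evaluate` and `simulate`.

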