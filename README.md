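# evofuse

Per-residue protein prediction from protein language model (pLM) embeddings,
with and without explicit evolutionary information — an R package for asking
a simple question rigorously: *does adding multiple sequence alignments
(MSAs) to embedding-based predictors still help?*

Modern pLMs (SeqVec, ProtBert, ProtT5) turn a protein sequence into an
`L × D` matrix of per-residue embeddings that feed supervised predictors of
secondary structure, binding, transmembrane topology or disorder. Before
pLMs, the decisive input was evolutionary information read off an MSA.
`evofuse` implements five workflows that differ **only in their inputs**,
so performance differences are attributable to the information source and
not to model capacity:

| workflow | input to the predictor |
|---|---|
| `raw` | the query's own `L × D` embedding |
| `msa-emb` | embeddings of every MSA row, averaged column-wise onto the query |
| `msacons` | per-row predictions, averaged column-wise (consensus) |
| `pssm-concat` | `[embedding ‖ PSSM]`, an `L × (D+20)` concatenation |
| `pssm-split` | embedding and PSSM in separate convolutional branches |

All five share one small 1-D CNN over the residue axis (channel widths
`D → 32 → 16 → 8 → K`, leaky-ReLU, softmax head; implemented in base R with
hand-written backpropagation and Adam).

Around the workflows the package provides the full supporting analysis
stack:

- **Similarity and data splitting.** Percentage pairwise identity
  `PIDE = 100 · n_ident / L` over alignment match states, and the
  HSSP-value
  `HVAL = PIDE − {100 (L ≤ 11); 480·L^(−0.32·[1+exp(−L/1000)]) (11 < L ≤ 450); 19.5 (L > 450)}`.
  `redundancy_split()` builds train/validation/test partitions with
  `HVAL ≤ 0` across sets and `PIDE ≤ 70` inside training;
  `verify_no_leakage()` certifies the result against the 0.3 identity
  threshold.
- **Evolutionary features.** `compute_pssm()` builds pseudocount-smoothed
  `L × 20` profiles from an MSA; `msa_average_embeddings()` implements the
  column-wise embedding average.
- **Evaluation.** Q3/Q10 accuracies, per-chain aggregation with
  `SE = SD/√(n−1)`, Spearman correlation, precision/recall/F1, conservation
  MCC (binarized at class ≥ 6), and the per-segment `Q_ok` under the
  ±5-residue endpoint / half-of-union matching rule — each cross-checked
  against independent brute-force oracles in the test suite. Shuffle-label
  and majority-class baselines calibrate the scales.
- **Synthetic families.** `simulate_family()` generates homolog families
  with controlled identity, conserved segmented label tracks, and
  label-driven noisy embeddings (`μ(label) + N(0, σ²)`), so the whole
  pipeline — including the claim that MSA-averaging denoises weak
  embeddings but cannot improve clean ones — is testable end to end with no
  external data. I/O covers FASTA, aligned FASTA and A3M, per-residue label
  TSVs, a plain-text embedding container, and the DSSP 8→3 reduction.

## Worked example

```r
library(evofuse)

res <- run_pipeline(list(
  workflows = c("raw", "msa-emb"),
  n_train = 40, n_val = 10, n_test = 10,
  family   = list(L = 60, N = 30, sigma = 2, seed = 7),
  model    = list(max_epochs = 40, patience = 10),
  seed     = 7))
print(res)
#> <pipeline_result> test Q3 per workflow:
#>   raw           44.83 +/- 5.02 (SE, n = 10)
#>   msa-emb       81.67 +/- 1.17 (SE, n = 10)

compute_hval(pide = 28, L = 120)
#> [1] 1.343608

baseline_shuffle_labels(rep(1/3, 3), n = 1e5, seed = 7)$simulated
#> [1] 33.204
```

With noisy embeddings (`sigma = 2` against unit class separation) the raw
workflow barely clears the 33% random baseline, while averaging embeddings
over the 30-member family (`msa-emb`) recovers most of the signal — a
37-point Q3 gain. Rerunning with `sigma = 0.1` (clean, ProtT5-like
embeddings) collapses the gap to about a point (Q3 93.5 vs 94.8):
evolutionary averaging only
helps when the embedding itself is the bottleneck. The HVAL example says a
pair with 28% identity over a 120-residue alignment sits just *above* the
HSSP curve (HVAL > 0), i.e. is too similar to split across train and test.

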