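---
title: "Methods: fusing pLM embeddings with evolutionary information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fusing pLM embeddings with evolutionary information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the design

Protein language models (pLMs) map a sequence to an `L × D` matrix of
per-residue embeddings; supervised predictors trained on these embeddings
now rival methods built on evolutionary information from multiple sequence
alignments (MSAs). `evofuse` implements a controlled comparison: five
workflows that share one predictor architecture and differ only in input.
If explicitly adding evolutionary information (averaged embeddings,
consensus predictions, PSSM profiles) improves accuracy, the embedding did
not already carry it; if it does not, the embedding and the MSA are at
least redundant for the task.

The five workflows are:

1. **raw** — the query's own embedding.
2. **msa-emb** — every MSA row is embedded on its *ungapped* sequence
   (gaps removed, rare residues mapped to `X` first) and, for each query
   position, the embedding vectors of all rows with a residue in that
   column are averaged, query included.
3. **msacons** — each row is predicted independently and the prediction
   channels (probability vectors, or scores for continuous tasks) are
   averaged column-wise; the argmax is taken after averaging, because
   averaging probabilities preserves information that hard labels discard.
   The consensus is generic over any per-residue predictor, not only the
   package's own.
4. **pssm-concat** — the raw embedding concatenated row-wise with a
   20-dimensional PSSM profile (`L × (D+20)` input).
5. **pssm-split** — embedding and PSSM enter separate convolutional
   branches; learned features are concatenated inside the network.

For a single-row (or identical-row) alignment, workflows 2 and 3 reduce
exactly to workflow 1; this identity family is the package's primary
regression suite.

## The predictor

All workflows use a small 1-D convolutional network over the residue axis
with channel widths `input → 32 → 16 → 8 → K` and leaky-ReLU activations
(slope 0.01), a per-residue softmax head for `K`-state tasks and a linear
head with squared-error loss for continuous (disorder-like) scores. Details
that the design left open were fixed once and recorded in `cnn_config()`:

- **Kernel size 7, same padding.** A local receptive field is the minimal
  faithful reading of "convolutional layers" for per-residue structure
  prediction; zero padding is applied per chain, so chains never influence
  each other (verified by a batch-composition test).
- **Split-branch merge point.** The two branches each run two
  convolutional layers (widths 32 then 16) and their `16 + 16` features are
  concatenated before the final block (`32 → 8 → K`). The merge *position*
  is an assumption of this package; merging after the second layer gives
  both inputs equal representational depth before fusion.
- **Optimization.** Full-batch Adam, learning rate `1e-3`, at most 200
  epochs, early stopping on validation Q3 (Spearman for continuous heads)
  with patience 10. Training stops once the epochs elapsed since the best
  validation value reach the patience, so `patience = 0` trains exactly one
  epoch. Training is deterministic given data and seed.
- **Ties.** Argmax ties resolve to the earliest configured class, so
  predictions are reproducible bit for bit.

The PSSM input is a pseudocount-smoothed frequency profile
`f(i,a) = (c(i,a) + α/20) / (n_i + α)` with uniform background and default
`α = 1`; an optional log-odds transform `log2(f/q)` is clipped to
`[−5, 5]` and divided by 5 so both schemes occupy a comparable numeric
range as model features. Residues outside the 20-letter alphabet
contribute to neither the counts nor the column depth, keeping rows summing
to one. The construction is the package's own documented definition: the
upstream profile tool it replaces does not publish a formula, and the
fusion models only require a consistent 20-dimensional per-residue feature.

## Similarity, splitting, leakage

Pairwise similarity uses the percentage identity over alignment match
states, `PIDE = 100 · n_ident / L`, and the HSSP-value

$$\mathrm{HVAL} = \mathrm{PIDE} - \begin{cases}
100 & L \le 11\\
480 \, L^{-0.32\,[1+\exp(-L/1000)]} & 11 < L \le 450\\
19.5 & L > 450
\end{cases}$$

where `L` counts columns in which both sequences have a residue. The curve
is continuous at `L = 450` to within 0.05 percentage points and monotone in
PIDE; pairs with `HVAL ≤ 0` are considered structurally safe to separate.

`redundancy_split()` mirrors the sequential construction of
redundancy-reduced data sets: sample a test set pairwise below the curve,
then a validation set below the curve against test and within itself, then
keep remaining chains for training when they are below the curve against
both held-out sets and mutually at most 70% identical (violators dropped).
The splitter is greedy and seeded — no optimal graph partitioning is
attempted, because none is claimed by the procedure it follows. A pair
with no alignment record is treated as dissimilar (`HVAL = −∞`), the
standard reading of sparse all-vs-all searches. Metadata criteria
(deposition date, resolution, fold-level annotations) enter as an opaque
per-record eligibility vector rather than implemented lookups.
`verify_no_leakage()` independently re-checks any assignment: it lists
every cross-partition pair at or above a fractional-identity threshold
(default 0.3).

## Evaluation suite

All per-chain measures are aggregated with the population standard
deviation over chains and `SE = SD/\sqrt{n-1}`; 95% intervals are
`±1.96·SE`. The measures: Q3 and Q10 accuracies; Spearman correlation
computed as the product-moment correlation of mean ranks (the ranking step
is made explicit, with average ranks on ties); precision, recall and F1 in
percent with the conventions *precision undefined when nothing is
predicted positive* and *F1 = 0 when precision and recall are both zero*;
Matthews correlation for nine-class conservation after binarizing at
*class ≥ 6 = conserved* (the class-5/6 phrasing of the convention leaves
no integer in both halves; ≥ 6 is the reading adopted here and flagged);
and the per-segment `Q_ok`: a protein is correct iff predicted and
observed segments of the type agree in number and, paired in left-to-right
order, every pair has both endpoints within 5 residues and an intersection
of at least half the union. The in-order pairing is a deliberate,
deterministic choice where a bipartite matching is underdetermined; for
segments that satisfy the ±5 rule the order of true matches cannot cross,
so the restriction is harmless. Undefined values (constant vectors,
degenerate tables, empty denominators) are returned as flagged `NA`, never
silently as zero — except the explicit F1 convention above.

Two baselines calibrate every scale: drawing predictions from the class
distribution (expected accuracy `100·Σ p_c²`, i.e. 33.3% for three equal
states, 10% for ten) and predicting the majority class.

## The synthetic family generator

`simulate_family()` emulates exactly the statistical structure the
analysis assumes, and nothing more:

- the query is uniform over the 20 residues; homologs differ by i.i.d.
  substitutions (uniform replacement, so expected identity is
  `1 − s·19/20` at substitution rate `s`) and deletions recorded as gaps.
  Alignment columns coincide with query positions — insertions into
  homologs are not simulated, which keeps the statistical tests decoupled
  from alignment bookkeeping (the A3M insertion path is exercised by I/O
  fixtures instead);
- labels follow a first-order segment process (geometric segment lengths
  with per-state means, successive states distinct) and are conserved
  across the family at aligned columns; an optional label-flip rate
  emulates poorly conserved annotations, the regime where consensus
  averaging degrades;
- embeddings are `μ(label) + N(0, σ²)` per coordinate, with class means
  placed on a simplex at a configurable pairwise separation. Averaging over
  `N` conserved homologs therefore cuts noise variance by `≈ N + 1`, which
  is the mechanism by which the msa-emb workflow must win on noisy
  embeddings and cannot win on clean ones.

What the generator does **not** emulate: realistic phylogenies,
substitution matrices, indel length distributions, or the geometry of real
pLM embedding spaces. Passing tests therefore demonstrate that the
pipeline's machinery is correct and that the noisy-versus-clean contrast
behaves as the theory predicts — not that any particular real pLM gains or
loses from MSAs.

The benchmark conditions used by the package's headline recovery
experiment are fixed once: embedding width `D = 16`, three states with
unit class-mean separation, chain length 100, families of 50 homologs at
substitution rate 0.2 and deletion rate 0.05, 200 training / 25 validation
/ 50 test families, noise `σ = 3` (noisy regime) versus `σ = 0.1` (clean
regime), at most 60 training epochs with patience 8. These sizes give
stable effects with desk-scale runtime. In the noisy regime the
MSA-embedding workflow exceeds the raw workflow by well over five Q3
points; in the clean regime the two agree to within a point.

## Numerical and interface choices

- Coordinates are 1-based inclusive throughout, the R convention; the
  segment rule is representation-invariant and validated against
  hand-worked examples.
- The embedding container is a plain-text TSV keyed by record id with the
  width recorded in the header and values written at 17 significant
  digits, so round-trips are bitwise. Real pLM adapters plug in by writing
  this container (`stored_provider()`); no model weights are bundled.
- Nonstandard residues (`U`, `O`, `B`, `Z`, `J`, `*`) are mapped to `X` at
  parse time with a warning, matching the preprocessing applied before
  embedding; `.` gaps normalize to `-`; A3M lowercase columns are removed
  as insertions relative to the query.
- All randomness descends from one root seed by deterministic mixing with
  a per-component tag (record ids hash to per-record noise streams), so
  any object can be regenerated in isolation.
- MSACons and msa-emb include the query row in the average: it is part of
  the alignment, and including it makes the single-row reduction exact.
- Rows that fail preprocessing or prediction are skipped with a warning
  rather than aborting the query — real alignments contain fragments.

## Limitations

The convolutional predictor is intentionally small and trained full-batch;
it is a vehicle for input comparisons, not a state-of-the-art secondary
structure method. The splitter is greedy, so it certifies feasibility, not
maximal training-set size. The PSSM definition, while standard, is not the
profile any specific aligner would emit. Conservation MCC, continuous
heads and segment scoring are implemented generically; reproducing any
published tool's exact numbers additionally requires that tool's data and
embeddings, supplied through the container interface.
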