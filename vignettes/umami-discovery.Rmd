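---
title: "Discovering umami peptides with UmamiForge: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering umami peptides with UmamiForge: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(UmamiForge)
```

## The problem

Fermented foods accumulate short peptides, some of which elicit savory
(umami) taste through the T1R1/T1R3 receptor. Finding them
experimentally is slow, so a common strategy is in-silico mining:
translate assembled DNA from the food microbiome into proteins,
simulate the proteolysis that happens during fermentation and
digestion, and rank the resulting peptide library with a sequence
classifier. UmamiForge implements that whole chain as a tested,
seedable R package: ORF extraction, combined trypsin/chymotrypsin
digestion, redundancy removal, a four-model unanimity ensemble,
position-wise Shapley explanation, and physicochemical annotation.

## Sequence processing

**ORF extraction** (`findOrfs`) uses the classic "translation between
stop codons" definition: in each of the six reading frames, every
maximal run of codons bounded by stop codons or the sequence ends is
an ORF, kept when it is at least `minLenNt` nucleotides long
(default 30 nt, the conventional ORF-finder minimum — chosen to
maximize peptide yield for downstream digestion rather than to call
genes). Coordinates are 0-based half-open on the forward strand, so
`substr(seq, start + 1, end)` always slices the translated region,
and reverse-strand ORFs carry negative frames. Codons containing `N`
translate to `X`; `X`-containing peptides are removed later at
digestion so that annotation tables never contain ambiguous residues.

**Digestion** (`digestProtein`) follows the PeptideCutter conventions:
trypsin cleaves C-terminal to K/R, chymotrypsin (high specificity)
C-terminal to F/W/Y, both blocked by a following proline; a
low-specificity chymotrypsin preset adds L/M. "Combined" hydrolysis
means the *union* of cut sites applied simultaneously, not sequential
digestion. With `maxMissedCleavages = m`, every concatenation of up
to `m + 1` adjacent fragments is also emitted. The default length
window is 4–15 aa: long enough to carry a sequence signal, and
bracketing the 6–9 aa range where validated umami peptides
concentrate. Defaults are deliberately config-exposed — library size
is very sensitive to them.

**Redundancy removal** (`clusterPeptides`) is greedy longest-first
identity clustering: peptides sorted by length (ties lexicographic)
join the first representative they match at ≥ 90% identity, where
identity is the number of identical aligned residues in a global
Needleman–Wunsch alignment (match 1, mismatch 0, gap −1) divided by
the *shorter* sequence length — the global-identity convention of
greedy clustering tools. No k-mer prefilter is used at desk scale;
the deterministic ordering makes clustering reproducible without
seeds. The identity traceback prefers the diagonal, then deletion,
then insertion, which pins down a unique match count among co-optimal
alignments.

## The classifier ensemble

The training corpus is a balanced set of labeled peptides
(`balanceCorpus` removes duplicates within and across classes —
a sequence appearing with both labels is dropped entirely — and
downsamples the larger class), split 80/20 stratified by class with a
seeded sampler (`splitCorpus`; per-class train size is
`round(0.8 × class size)`).

Peptides are encoded as integer vectors: residues map to 1..20 in a
fixed alphabet order, right-padded with 0 to `maxLen` (default 20).
The pad index embeds as the zero vector, which doubles as the masking
baseline for attribution.

Four small sequence models with deliberately different inductive
biases are trained (`trainSubModel`), all ending in a single sigmoid
unit and all implemented in plain R matrix code with hand-derived
backpropagation (verified against finite differences in the test
suite) and Adam:

* **CNN** — two valid-padding 1-D convolution blocks (kernel 3,
  64 filters, ReLU) with global max pooling: local motif detector.
* **BiLSTM** — one bidirectional LSTM layer (hidden 64 per direction)
  with pad masking; the concatenated final states summarize
  long-range order.
* **Attention pooling** — structured self-attention pooling: additive
  (tanh) scoring against four learned query vectors over
  position-aware embeddings, the four softmax-weighted sums
  concatenated into a small tanh head. The sinusoidal positional
  encoding is part of this model by design: a pooled-attention
  classifier without position information is blind to *where* a
  residue occurs and cannot represent a positional signal at all; the
  multiple queries and nonlinear head make training stable across
  seeds where a single query is fragile.
* **Transformer encoder** — 2 post-norm blocks of 4-head
  self-attention (model dim 32, FFN 64) with sinusoidal positions,
  masked mean pooling. The model dimension is kept at 32 because the
  corpora this package targets are a few hundred peptides; a wider
  model only adds variance and CPU time.

Training uses minibatch 64, learning rate 1e-3, at most 200 epochs
with early stopping (patience 25) on a seeded stratified 15%
validation fold; the best-validation parameters are kept. Every
source of randomness — initialization, shuffling, dropout (0.1 on the
pooled representation), fold choice — flows from the one config seed,
so a fixed seed reproduces parameters exactly on one machine, and
inference is fully deterministic.

**The unanimity ensemble** (`ensemblePredict`) averages the four
probabilities for ranking but labels a peptide umami only when *all
four* models pass the 0.5 threshold. Unanimity is strictly stricter
than mean-thresholding: a unanimous positive always has mean ≥ 0.5,
while a single dissenting model vetoes a peptide whose mean is high
(e.g. probabilities 0.99/0.99/0.99/0.40 average 0.8425 yet are
rejected). This trades recall for precision — the right trade when
candidates proceed to synthesis. Candidate ranking considers
unanimous positives only, ordered by average probability; vetoed
peptides are excluded *before* taking the top-n, which is the
conservative reading of "rank by average probability" combined with
the veto rule.

## Explanation

`shapleyPositions` attributes a prediction to peptide positions.
Players are positions (not position × residue cells, matching the
`Pos_i` feature view); a position "absent" from a coalition is masked
to the pad index — an exact, model-agnostic and reproducible baseline,
in contrast to data-mean embeddings. Exact mode enumerates all `2^L`
coalitions (allowed up to L = 15, i.e. 32768 batched model calls) and
satisfies the efficiency axiom to numerical precision:
`baseValue + sum(values) == prediction`. Sampled mode draws random
permutations in antithetic pairs (each permutation also used
reversed), which halves variance and keeps the estimate *exactly*
efficient, since every permutation's marginal contributions telescope
to `prediction − baseValue`. `waterfallData` orders contributions for
a feature-direction view; `globalImportance` averages `|value|` per
position over a dataset for the global view.

## Physicochemical annotation

`physChemProfile` reports, per candidate: average molecular weight
(sum of average residue masses plus one water, 18.0153 Da), GRAVY
(mean Kyte–Doolittle hydropathy), net charge at pH 7.0, and
theoretical pI. Charge follows the Henderson–Hasselbalch sum over
ionizable groups. Two pKa presets exist because the two quantities
follow two different annotation conventions:

* `pkaSet("protparam")` — the Bjellqvist set (C-term 3.55, Asp 4.05,
  Glu 4.45, Cys 9.0, Tyr 10.0, His 5.98, Lys 10.0, Arg 12.0, with a
  residue-specific N-terminal pKa). Used for pI, computed by
  bisection of the charge curve on pH ∈ [0, 14] to |charge| < 1e-4
  (≤ 200 iterations; the curve is strictly decreasing, so bisection
  cannot fail on this bracket).
* `pkaSet("protcalc")` — a generic set (N-term 8.0, C-term 3.1,
  Asp/Glu 4.4, Cys 8.5, Tyr 10.0, His 6.5, Lys 10.0, Arg 12.0).
  Used for the charge-at-pH column; at pH 7 the N-terminus is only
  ~91% protonated under this set, which is why reported charges of
  acidic peptides end in .1.

Cys and Tyr are counted among the acidic groups for generality; their
contribution at pH 7 is negligible. Peptides are treated as free
(charged termini); terminal modifications are not modeled. Toxicity
prediction is an external-service hook: the profile emits an empty
`toxicity` column rather than silently omitting it.

## Synthetic data: what it emulates and what it does not

`syntheticCorpus` plants a tunable positional signal: each of the
first `k = 3` positions of a positive peptide is drawn from {D, E}
with probability `pDE` (default 0.8) and from the 18 other residues
otherwise, so the acidic rate at signal positions is exactly `pDE`;
the uniform background rate is 0.1. Lengths are uniform on 5–12 aa.
This emulates two robust features of validated umami peptides — acidic
residue enrichment and the dominance of N-terminal positions — while
remaining fully seeded and downloadable-data-free. At `pDE = 0.1` the
classes are indistinguishable by construction, which calibrates the
null. `plantedGenome` reverse-translates peptides (seeded synonymous
codons) into small ORFs of the form `M + filler + K + peptide`
between stop-rich spacers, so ORF extraction plus digestion recovers
every planted peptide exactly; peptides with internal cleavage sites
beyond the allowed missed cleavages are rejected up front.

What passing tests on this generator do **not** show: real corpora
have label noise, length and composition confounders, homology between
train and test items, and far weaker signals; real microbiome contigs
have biased codon usage and fragmented ORFs. Accuracy numbers on the
synthetic corpus are a recovery check for the machinery, not an
estimate of real-world performance.

## Problem sizes and numerical choices

The test suite trains the four sub-models on the planted corpus at
250 peptides per class (80/20 split, `pDE = 0.9`, fixed seeds) and
requires every sub-model to reach held-out accuracy ≥ 0.9 and global
importance to rank Pos_0–Pos_2 top-3; global importance there uses
sampled attributions (16 antithetic permutation pairs) over 60
held-out peptides, and the end-to-end determinism check reruns the
full pipeline twice on a toy genome. Zero-denominator metrics are
reported as `NaN` with a warning, never as silent zeros. Scores in
softmax layers subtract the row maximum before exponentiation;
probabilities are clamped to [1e-12, 1 − 1e-12] inside the loss. Pad
positions are excluded from attention as keys and from pooling; in
the BiLSTM the state simply carries through pads, so the "final"
state is the state at the true sequence end.

## Known limitations

* The sub-models are small by design; they will underfit corpora of
  tens of thousands of peptides, and the greedy clustering is
  quadratic with no k-mer prefilter — both choices favor exactness
  and reproducibility at the scale of hundreds to a few thousands of
  peptides. Clustering a 150,000-peptide library would need a word
  screen this package deliberately does not implement.
* Exact Shapley attribution is exponential in peptide length and
  capped at L = 15; longer peptides fall back to sampling.
* The physicochemical panel uses empirical pKa conventions; pI and
  charge are model quantities, not measurements.
* Toxicity, receptor docking, dynamics and sensory validation are
  outside the package's scope.
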