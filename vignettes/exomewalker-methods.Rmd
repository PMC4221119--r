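---
title: "Methods: network-guided prioritization of exome candidate genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-guided prioritization of exome candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomewalker)
```

## The problem

A single whole-exome sample carries tens of thousands of variants; after the
standard filters (on-target, rare, predicted deleterious) hundreds of genes
still harbor plausible candidates, far too many to follow up. For a
genetically heterogeneous Mendelian disease one extra signal is available:
the genes already implicated in the same clinical phenotype (a disease-gene
family). Genes responsible for similar phenotypes tend to associate in
specific subnetworks of the protein–protein association (PPA) interactome,
so network proximity to the known family is evidence of candidacy. This
package fuses that proximity signal with per-variant evidence into a single
gene ranking.

## Model

### Random walk with restart

The PPA network is an undirected graph over genes with a confidence per
association; only associations at or above a confidence threshold
(default 0.7, the conventional high-confidence cut) are kept, duplicate
pairs collapse to their maximum confidence, self-associations are dropped,
and genes left without any edge are removed. With $A$ the adjacency matrix
and $W$ its column normalization ($W_{ij} = A_{ij}/\sum_k A_{kj}$), the
random walk with restart iterates

$$p_{t+1} = (1-r)\,W p_t + r\,p_0,$$

where $p_0$ is uniform over the $m$ seed genes (the family) and $r$ is the
restart probability. The fixed point

$$p_\infty = r\,(I - (1-r)W)^{-1} p_0 = R\,p_0$$

is computed by a linear solve; because $p_0$ has only $m$ nonzero entries,
$p_\infty$ is the average of the $m$ seed columns of $R$, an $O(mn)$
evaluation once $R$ is precomputed. `rwr_iterative()` implements the
iteration directly and serves as the independent oracle for the closed
form: the two agree to below $10^{-8}$ ($L_\infty$) on randomized graphs in
the test suite. Two consequences of the fixed-point equation are also
checked everywhere: $\sum_i p_\infty[i] = 1$ and
$p_\infty[j] \ge r/m$ for every seed $j$.

**Adjacency weighting.** After thresholding, the adjacency is binary by
default; every retained association counts equally in the walk.
Confidence-weighted normalization is available
(`build_transition_matrix(weighted = TRUE)`) for sensitivity analyses.

**Restart probability.** Default $r = 0.7$: the walker stays close to the
family while still integrating over global structure. It is exposed as a
parameter (`rwr_params()`); $r \to 1$ collapses $p_\infty$ to $p_0$.

**Solver strategy.** Below 2000 genes (configurable) the dense resolvent
$R$ is formed explicitly so repeated seed sets cost only column sums; above
that a sparse LU factorization of $I-(1-r)W$ is stored and each profile is
one back-substitution. Both produce the same profile to $10^{-10}$.

### Variant score

Each variant receives

* a **frequency score**: 1 for MAF 0 falling linearly to 0 at MAF 2%
  ($1 - \mathrm{maf}/0.02$). Only the endpoints of this map are canonical;
  linear interpolation is the simplest monotone continuous choice and the
  shape is replaceable. A variant with no reported frequency in any source
  scores 1 — novel variants are exactly the candidates of interest. When
  multiple frequency sources are present the maximum reported frequency is
  used, and individual sources can be masked (`maf_exclude`), emulating
  analyses that deliberately withhold one panel's frequencies.
* a **pathogenicity score**: missense variants take the most deleterious of
  the available predictions — $1-\mathrm{SIFT}$ (SIFT is a tolerance
  score), PolyPhen-2 and MutationTaster as-is — or a prior of 0.6 when all
  three are unavailable (a compromise between treating novel substitutions
  as benign or as fully pathogenic). Truncating/splice classes carry fixed
  configurable priors (nonsense and frameshift 0.95, splice site 0.90,
  in-frame indel 0.85). Off-target classes (synonymous, intronic,
  intergenic, UTR, non-coding) score 0 and are removed.

The **variant score** is the product of the two. Filtering removes
off-target variants, variants with a *known* MAF above 1% (absent
frequency is not grounds for exclusion), and genotypes carrying no
alternate allele; each removal carries a machine-readable reason and kept
∪ removed partitions the input exactly.

### Gene assembly and inheritance

Variants group by gene; a mode-of-inheritance model gates which variants
qualify. Dominant (AD) requires one alternate allele (heterozygous or
homozygous — a homozygous dominant allele is still causal). Recessive (AR)
requires two: at least one homozygous-alternate variant, or two or more
heterozygous variants assumed in trans (compound heterozygote; phase is
unknowable from a single exome, so any two heterozygotes in a gene are
treated as trans — the standard single-sample assumption). The gene's
variant score is its best qualifying variant score; a compound-het gene is
scored as the mean of its two best heterozygous scores, and when both
recessive mechanisms are present the larger of the two mechanism scores is
taken (the canonical rule covers only the compound-het sub-case; max is
the natural extension and is exercised in tests).

### Score fusion

The final gene score is a logistic fusion
$\sigma(\beta_0 + \beta_v v + \beta_w w)$ of the gene variant score $v$ and
the walk feature $w$, trained on labeled disease/benign examples by
$k$-fold cross-validation (default 10); the fold models' **coefficients are
averaged** into the final model, with per-fold held-out AUCs reported.
("Average of the fold models" is ambiguous between averaging coefficients
and averaging predictions; coefficients-averaging is the default and
prediction-averaging is available via `average = "predictions"`.) A small
fixed ridge penalty ($\lambda = 10^{-3}$, `glmnet`, unstandardized)
guarantees finite coefficients on separable data.

**Walk feature scale.** Raw steady-state probabilities scale as $1/n$ and
are not comparable across networks, and no canonical normalization exists
for this fusion; the default feature is therefore the gene's **percentile**
among all network genes' $p_\infty$ values for that seed set
(`walk_transform = "PERCENTILE"`; `"RAW"` is retained for fidelity
experiments). Probabilities are rounded to 12 significant digits before
ranking so that analytically tied genes — structurally symmetric positions
— share an averaged percentile instead of splitting on solver noise.
Off-network genes take walk score and percentile 0 and pass through the
same model, remaining rankable on variant evidence alone.

**Training data.** The original fusion was trained on a large catalogue of
known disease variants against benign variants; that resource is licensed
and external. The packaged default model (`default_combiner_model()`) is a
clearly labeled surrogate trained on the package's own labeled generator
(2000 + 2000 examples, effect size 1, seed 20140730) and is deterministic.
Its coefficients — not its absolute AUC — are what downstream ranking
uses; any model trained on real labeled data can be supplied instead
(`train_combiner()`, `read_combiner_model()`).

### Ranking

Candidates sort descending by the chosen key (fused score by default;
variant-only and walk-only are available for comparison), with ties broken
by ascending alphabetical gene identifier and unique consecutive ordinal
ranks assigned — the reviewer's real workflow of working down equally
scored candidates in a fixed order. Result files format scores to 6
significant digits so identical runs are byte-identical.

## Spike-in benchmarking

`run_benchmark()` reproduces the spike-in protocol at fixture scale: for
each catalogue record and each background exome, one pathogenic variant is
inserted (heterozygous for AD, homozygous for AR), the rest of the record's
family seeds the walk (leave-one-out — the target never seeds its own
run), and the rank of the true gene is recorded under the chosen key.
Aggregates are exact fractions of runs with the true gene at rank 1, in
the top 10 and in the top 50, plus the mean post-filter gene count. Every
(record, background) pair is run, so 20 families × 5 backgrounds = 100
analyses.

## What the synthetic generators emulate — and what they do not

`generate_network()` plants dense modules (one per disease-gene family) in
a sparse random background: each module carries a guaranteed spanning cycle
at confidence ≥ 0.75 plus random intra-module edges (default probability
0.8), background pairs connect with probability 0.01 with confidences
straddling the 0.7 threshold (so confidence filtering is exercised), and
disconnected components are bridged deterministically. This encodes
exactly the assumption the walk exploits — family genes cluster — and
makes network-based recovery testable by construction.

`generate_exome()` draws background variants over the network's genes:
30% off-target, MAFs from a mixture (40% absent, 20% common > 1%,
40% rare ≤ 1%), missense predictions correlated through a latent
deleteriousness with 30% per-tool dropout, mostly heterozygous genotypes,
and 5% of coding variants on genes absent from the network. The kept
fraction after filtering has a closed-form expectation
(`expected_retention()`) that the generated data matches within sampling
error. Spiked variants emulate catalogued disease mutations: novel
missense with a strongly deleterious MutationTaster draw (uniform on
\[0.9, 1\]) — with predictions withheld instead, the spiked variant score
pins at the 0.6 prior and fusion cannot improve on the walk alone, which
is not the condition the benchmark emulates.

Deliberately **not** emulated: the human allele-frequency spectrum,
linkage between variants, per-gene mutation-rate and length effects,
transcript-level annotation ambiguity, sequencing error, and the true
interactome's degree distribution (hub genes). Passing fixture benchmarks
therefore demonstrates the machinery's correctness and the qualitative
ordering of ranking strategies, not clinical-scale recovery rates:
headline figures from large curated resources (true-gene top-hit rates,
external AUCs) depend on those resources and are out of desk-scale reach.

Default fixture scale — 300 genes, 20 families of 5, 1000 variants per
exome, 5 backgrounds — keeps the full suite and the benchmark in seconds
on one CPU while leaving ~200 genes post-filter per run, enough for top-10
discrimination between ranking keys.

## Numerical choices and degenerate inputs

* Transition columns sum to 1 within $10^{-12}$; resolvent columns within
  $10^{-10}$; profile entries are clipped at 0 against sub-roundoff
  negatives from the solve.
* Iterative solver: $L_1$ tolerance $10^{-10}$, cap 10 000 iterations,
  error (with last residual) on non-convergence; at $r=0.7$ the iteration
  contracts by 0.3 per step and converges in tens of iterations.
* Empty seed intersections, single-class training labels, empty networks
  after filtering, and spike-in locus collisions are errors; an exome with
  no surviving candidate genes is a structured empty result, not an error.
* Seed genes harboring qualifying variants are themselves rankable
  candidates in `prioritize()` (the real use case); only the benchmark
  removes the target gene from its own seed set.
* Multi-allelic VCF records split into bi-allelic variants before scoring;
  hemizygous calls are treated as homozygous-alternate (no sex-aware
  logic).

## Known limitations

Phase is assumed trans for all compound-heterozygote pairs; pedigree and
multi-sample segregation filtering are out of scope. The packaged fusion
model is a synthetic surrogate — for production use, retrain on real
labeled variants. Networks beyond ~20k genes would need iterative sparse
solvers rather than the dense/LU paths provided.
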