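---
title: "Predicting drug-drug interactions from target profiles: models and design"
author: "targetDDI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-drug interactions from target profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetDDI)
```

## The modeling idea

Two co-prescribed drugs can perturb each other's efficacy when their
molecular actions meet: on the same target gene, on genes that interact in
the protein–protein interaction (PPI) network, or on genes sitting in the
same signaling pathway or cellular process. `targetDDI` operationalizes
this in two complementary ways: a *classifier* that predicts interaction
labels from target profiles alone, and a set of *intensity statistics*
that quantify how strongly a given pair's target sets are coupled through
the network and pathway context.

The representation is deliberately minimal. Given a drug roster, the gene
universe is the union of all target sets, frozen in lexicographic order so
feature positions are deterministic and independent of file order. A drug
is a binary indicator vector over that universe; a pair is the elementwise
sum of its two drug vectors, so entries live in {0, 1, 2} and a 2 marks a
common target. Genes not in the universe are discarded — the universe is
always built from the *training* roster, so test-time pairs are scored on
exactly the descriptors the model was trained on, and unseen genes simply
contribute nothing. No feature selection or weighting is applied: known
target sets are sparse (often a handful of genes per drug), and pruning
features would leave many pairs represented by a null vector.

## The base learner

The classifier is l2-regularized logistic regression with labels
$y_i \in \{-1, +1\}$:

$$\min_{w, b}\; \tfrac{1}{2} w^\top w +
  C \sum_i \log\!\left(1 + e^{-y_i (w^\top x_i + b)}\right).$$

The contract is the *objective*, not a particular solver: any convex
optimizer that reaches its minimum is acceptable. The implementation uses
L-BFGS-B on the exact analytic gradient, started from the zero vector, so
training is deterministic; the tests verify that the attained objective
matches an independent penalized-regression fit (`glmnet` with
$\lambda = 1/(nC)$, `alpha = 0`, no standardization) to within $10^{-4}$
relative. The intercept $b$ is fitted but unpenalized by default and can
be disabled; with it disabled, $C \to 0$ provably drives all probabilities
to 0.5, which the tests exercise as a limit check.

Tunable parameters:

- `C` (dimensionless, default 1): penalty weight; larger is weaker
  regularization. `tuneC()` scans the grid $\{2^i : -16 \le i \le 16\}$
  (33 candidates) by stratified cross-validated ROC-AUC and breaks ties
  toward the *smaller* C, preferring the more regularized model when the
  data cannot distinguish candidates.
- `threshold` (probability, default 0.5): classification cutoff, boundary
  inclusive ($p \ge t \Rightarrow +1$). Raising it (e.g. to 0.7) trades
  recall for precision and is the intended way to filter weak predicted
  interactions.
- `factr` (default `1e4`): L-BFGS-B tolerance, roughly 12 significant
  digits on the objective — tight enough that retraining reproduces
  weights bit-for-bit in practice.

Models persist as plain text (`writeModel()`): header comments with the
universe fingerprint and C, then one `gene<TAB>weight` row per universe
position. Scoring refuses a feature matrix whose column universe does not
hash to the model's fingerprint, which catches the classic train/test
universe mismatch early. The fingerprint is an md5 of the ordered gene
list; it guards against accidents, not adversaries.

## Evaluation protocol

All thresholded metrics derive from the 2×2 confusion matrix with class
order (positive, negative) and $M_{ij}$ = count of true class $i$
predicted as class $j$. Per class $l$ the intermediates are
$p_l = M_{ll}$, $q_l$ (the complementary diagonal), $r_l$ (others
predicted as $l$) and $s_l$ ($l$ predicted as other), giving per-class
precision $p_l/(p_l+r_l)$, sensitivity $p_l/(p_l+s_l)$ and a per-class
Matthews correlation. Two conventions matter:

- A zero denominator yields an explicit `NA`, never a silent 0 — a class
  that is never predicted should be visible, not flattering.
- The *overall* MCC pools $p, q, r, s$ across classes before applying the
  MCC formula. For two classes all four pooled factors equal the total
  count, so this pooled form reduces algebraically to $2\,\mathrm{Acc}-1$;
  the per-class MCCs of the two classes are identical to each other but
  are a genuinely different (and usually slightly smaller) quantity. The
  test suite pins both identities numerically.

ROC-AUC is computed by the midrank (Mann–Whitney) formula — the exact
probability that a random positive outscores a random negative, ties
counted one half — and is tested against an $O(n^2)$ pair-counting oracle
and against `pROC`.

`kfoldCV()` implements the full protocol: negatives are sampled *once*,
uniformly over unordered non-self roster pairs excluding the known
positives, before any fold split (so folds share one negative sample, as
a single training corpus would); folds are stratified to keep the class
ratio constant and avoid degenerate single-class folds; and the gene
universe is rebuilt from the training folds' drugs only, so no feature
position leaks from held-out drugs. Everything is driven by one integer
seed; the same seed reproduces the report bit-for-bit, and a different
seed changes only the sampling. `independentRecall()` scores an external
single-class test set and refuses any overlap with the training pairs.

## Intensity statistics

For a pair $(a, b)$ with target sets $G_a, G_b$:

- `jaccardIndex()` is $|G_a \cap G_b| / |G_a \cup G_b|$; `simU()` is the
  fraction of a pair cohort at or above a threshold $\xi$, and `minXi()`
  returns $\min 1/|G_a \cup G_b|$, the threshold at which `simU` counts
  exactly the pairs sharing at least one gene.
- `enumeratePaths()` counts *simple* paths (no repeated vertex) of at most
  `maxLen` edges between two genes. "All paths" must mean simple paths:
  unrestricted walks are infinite in any cyclic graph. The default cap of
  8 edges covers the longest path lengths observed in drug-pair cohorts
  while keeping the enumeration bounded; the true longest simple path is
  NP-hard and is not attempted beyond the cap. Every reported quantity
  respects the cap — a pair connected only by longer paths is reported
  `unreachable`, by design, rather than mixing capped and uncapped
  quantities. A per-gene-pair count ceiling (default $10^6$) aborts
  pathological enumerations with an explicit `truncated` flag instead of
  burning time or returning silently wrong numbers. The enumeration runs
  in compiled code (a bounded depth-first search over adjacency lists)
  and is verified against an exhaustive recursive R implementation on
  hundreds of random graphs.
- `pairPathStats()` aggregates over all $|G_a| \times |G_b|$ cross gene
  pairs: `avgPaths` (total path count over cross-pair count), `shortest`
  (minimum) and `longest` (maximum within cap). A shared gene $g_i = g_j$
  counts as one path of length 0, so `shortest == 0` exactly when the
  drugs share a target and all three statistics remain defined for
  overlapping target sets; the pair set includes those diagonal gene
  pairs. Genes absent from the PPI network are treated as isolated nodes
  with a warning, not as errors — incomplete networks are the norm.
- `commonSets()` intersects the two drugs' pathway memberships (the union
  of per-gene memberships) and records the supporting genes per common
  set. The identical machinery serves GO biological-process collections;
  only the `kind` tag differs. No enrichment p-values are attached: the
  statistic of interest is the raw overlap itself, and no size filter is
  applied by default.

## The synthetic-data generator

`synthGenerate()` produces everything the pipeline consumes: a
drug–target map, a PPI network, two gene-set collections and labeled
pairs. Defaults define the package's reference conditions: 300 drugs over
400 genes with 1–6 targets each (mean ≈ 3.5, matching the sparsity of
curated drug–target corpora), a preferential-attachment PPI graph
(scale-free-like, as real PPI networks are; an Erdős–Rényi switch exists
for null topologies), 50 pathways of 5–25 genes and 80 processes of
10–40 genes grown outward from degree-biased seed genes so that gene-set
membership correlates with network proximity, and 2000 positive + 2000
negative pairs.

The planted signal has two layers, and the second deserves explanation.
First, with probability `shareProb` (0.6) a positive pair is forced to
share a *driver* gene — one of the `nDriverGenes` (40) highest-degree
hubs — and with probability `proximityProb` (0.2) the two drugs instead
receive genes within PPI distance 2 of each other. This creates the
mechanism signatures (Jaccard > 0, shortest path 0 or ≤ 2, shared
pathways). Second, positive pairs are *sampled* with a weight boost
(`driverBoost`, default 9) for drugs already targeting a driver. This
layer exists because a linear model on summed pair profiles is provably
blind to sharing as such: the profile sum is the same whether or not the
two drugs' genes coincide, so co-occurrence alone is not learnable — only
class-dependent marginal gene frequencies are. That is also how the real
signal presents: a small set of recurring pharmacogenes (CYP450 isoforms
and kin) marks interaction-prone drugs. With the boost the reference
bundle yields cross-validated AUC ≈ 0.85; without it (set
`driverBoost = 0`, `shareProb = 0`, `proximityProb = 0`) the generator is
an honest null on which Jaccard distributions are indistinguishable
between classes and CV AUC sits at chance.

Negatives are sampled uniformly over the remaining pair space, disjoint
from the positives — matching the evaluation protocol's assumption, and
meaning "negative" is *presumed* non-interacting, exactly as in real
corpora built by negative sampling.

What passing tests on this generator do **not** show: performance on real
corpora (where label noise, incomplete target annotation and literature
bias dominate), calibration of the probability scale, or robustness to
drugs with zero annotated targets (excluded by construction here and by
the data model generally).

## Numerical and design choices

- Universe order: lexicographic byte order (radix sort), immune to
  session locale; printed examples that use a different explicit order
  pass it via `GeneUniverse(..., sort = FALSE)`.
- Unordered pairs are canonicalized with the lexicographically smaller id
  first; duplicate records collapse; conflicting labels for one unordered
  pair are an error rather than a silent overwrite.
- Gene symbols are uppercased at every ingestion point — mixed casing
  across sources is otherwise a quiet way to split one gene into two
  features.
- Thresholding is boundary-inclusive; ties in `tuneC` break toward the
  smaller C; fold assignment deals shuffled class members round-robin.
- Sampling loops (negative pairs, positive pairs) draw in batches with
  rejection and are deterministic given the seed; seeded helpers restore
  the caller's RNG state.
- Reference problem sizes: the checks run the full reference bundle
  (4000 pairs) for cross-validation and intensity directions, 1000 random
  instances for the metric oracles, 200 random graphs (≤ 12 nodes,
  cap ≤ 8) for the path oracle, and 20 random datasets for the solver
  oracle — sizes chosen so each suite pins its claim while the whole run
  stays interactive.

## Known limitations

Path enumeration is exponential in the cap on dense neighborhoods; the
ceiling makes this explicit (`truncated`) rather than fast. The overall
MCC of the pooled convention is an affine function of accuracy and adds
no information beyond it — it is reported because it is the suite's
convention, with per-class MCC carrying the balance information. The
model file stores weights in full precision but is not meant as an
interchange format beyond this package. Finally, the classifier is
linear by design: interactions that hinge on gene *combinations* with no
marginal signature are outside what this representation can learn, a
trade made consciously for interpretability.
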