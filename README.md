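# targetDDI

Drug–drug interactions (DDIs) are a major source of adverse drug reactions
under co-prescription, and most computational predictors lean on drug
structures and heavy data integration that is hard to interpret. `targetDDI`
takes the opposite route: it predicts whether two drugs interact **from their
target genes alone**, and explains predicted interactions through the
protein–protein interaction (PPI) network and pathway context of those
genes. It is aimed at computational pharmacologists and systems biologists
who have drug→target tables (DrugBank-style exports), PPI edge lists and
GMT pathway collections, and want an interpretable DDI classifier plus
mechanism statistics — or who want to study this class of model on fully
synthetic, seeded data.

## The model

Let `D` be the drug roster and `G_d` the target gene set of drug `d`. The
gene universe is the union `G = ∪_{d∈D} G_d`, ordered so every gene has a
fixed feature position. A drug is the binary profile
`V_d[g] = 1 if g ∈ G_d else 0` over `G`, and a drug pair is the elementwise
sum `V_(a,b) = V_a + V_b`, so an entry of `2` marks a common target gene.
Genes outside `G` are discarded, which keeps training and test features on
identical descriptors.

Pairs are classified by l2-regularized logistic regression: the weights
minimize

```
min_w  0.5 ‖w‖² + C Σ_i log(1 + exp(−y_i wᵀx_i)),   y_i ∈ {−1, +1}
```

with `C` chosen from the grid `{2^i : −16 ≤ i ≤ 16}` by cross-validated
ROC-AUC, and `p = 1/(1+exp(−wᵀx))` read as the interaction probability.

Interaction *intensity* is quantified independently of the classifier:

- **Jaccard index** `|G_a ∩ G_b| / |G_a ∪ G_b|`, with `Sim_U`, the fraction
  of a pair set whose Jaccard meets a threshold ξ;
- **PPI path statistics**: over all cross target-gene pairs, the average
  number of bounded simple paths `Avg`, the minimum shortest-path length `S`
  (`S = 0` exactly when the drugs share a target) and the maximum capped
  path length `L`;
- **pathway / cellular-process overlap**: the sets hit by at least one
  target gene of *each* drug.

## Worked example

The vectorization on a five-gene universe, with Patisiran (DB14582,
targets {ALB, ORM1, ORM2}) and Bismuth Subsalicylate (DB01294, targets
{ALB, TF}):

```r
library(targetDDI)
dtm <- DrugTargetMap(list(DB14582 = c("ALB", "ORM1", "ORM2"),
                          DB01294 = c("ALB", "TF")))
u <- GeneUniverse(c("TF", "ALB", "XDH", "ORM1", "ORM2"), sort = FALSE)
drugProfile("DB14582", dtm, u)
#>   TF  ALB  XDH ORM1 ORM2
#>    0    1    0    1    1
pairProfile("DB14582", "DB01294", dtm, u)
#>   TF  ALB  XDH ORM1 ORM2
#>    1    2    0    1    1
jaccardIndex("DB14582", "DB01294", dtm)
#> [1] 0.25
```

The `2` at ALB marks the shared target; the Jaccard index 1/4 is the
pair's interaction intensity.

A full pipeline run on the seeded reference simulation (300 drugs, 400
genes, 2000 interacting + 2000 non-interacting pairs with planted target
sharing and PPI proximity):

```r
ds <- synthGenerate(synthConfig(seed = 1))
cv <- kfoldCV(ds$targets, ds$pairs[pairLabels(ds$pairs) == 1L], k = 5,
              seed = 2, negatives = ds$pairs[pairLabels(ds$pairs) == -1L])
round(cv$report[c("mean", "sd"), c("Acc", "MCC", "AUC", "F1")], 4)
#>         Acc    MCC    AUC     F1
#> mean 0.7572 0.5145 0.8510 0.7544
#> sd   0.0080 0.0160 0.0082 0.0109
round(expectedSignalCheck(ds, maxLen = 8), 4)
#>          nPairs meanJaccard meanShortest fracUnreachable meanCommonPathways
#> positive   2000      0.1118       0.0705               0            22.8855
#> negative   2000      0.0342       0.7920               0             9.5000
#>          meanCommonProcesses
#> positive             46.6555
#> negative             23.3045
```

The classifier recovers the planted signal well above chance (mean
held-out AUC 0.85), and the intensity statistics separate the classes in
the expected directions: interacting pairs share more target genes
(higher Jaccard), sit closer in the PPI network (mean shortest path 0.07
vs 0.79) and hit more common pathways and processes.

Real data enter through `readDrugTargets()`, `readInteractions()`,
`readPPI()` and `readGeneSets()` (two/three-column TSV and standard GMT).
A thin command-line front end with `simulate`, `train`, `cv`, `predict`,
`intensity` and `overlap` subcommands is installed at
`inst/scripts/ddi-tool.R`.

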