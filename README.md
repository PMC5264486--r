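# histact

Binary gene-activity prediction from binarized histone-modification
patterns at 24 nucleosome-sized gene regions.

## What this is for

Whether a gene is transcribed correlates with which histone
modifications sit on the nucleosomes around its transcription start
(TSS) and termination (TTS) sites. `histact` is for analysts who have
(a) per-bin ChIP-seq tag counts for a panel of modifications, (b) a
gene annotation, and (c) averaged log2 expression values, and who want
to treat activity as on/off and ask which marks, at which positions,
predict it — the CD4+ T-cell style of analysis in which the single
acetylation **H2BK5ac** at TSS-proximal positions turns out to carry
most of the predictive power.

The genome is cut into 200 bp bins; a bin is "marked" when its tag
count exceeds a threshold (default 0). Each gene is profiled at 24
strand-aware regions (`TSS-10 … TSS-1, TSS, TSS+1, TSS+2, TTS,
TTS+1 … TTS+10`), giving a binary gene × (region, modification) matrix
(936 columns for 39 marks). On top of that:

* **Frequency profiles** — genes ranked by expression into `G = 19`
  groups; per mark and region, `F_g = N_g / N_all`; uninformative marks
  sit at `1/19 ≈ 0.053` across all groups.
* **CART-style trees** — best-first Gini induction with an exact nested
  k-node prune path; +1/−1 gene designations; seeded permutation
  significance; Pearson correlation between designations of trees of
  increasing size to pick the most parsimonious one.
* **Cumulative-sum threshold** — with genes ranked by decreasing
  expression, `Y(g) = Σ_{i≤g} x_i` and `g_max = argmax Y(g)` set a
  non-arbitrary log2 expression threshold separating active from
  inactive genes; an exact-binomial P-minimization procedure
  cross-validates the same cut.
* **Evaluation designs** — per-region trees, random train/test splits,
  single-modification trees and a 39-way mark ranking; the metric is
  *prediction accuracy frequency*, the fraction of genes whose tree
  designation matches the threshold label.
* **MDR** — exhaustive multifactor dimensionality reduction per region,
  scored by 10-fold cross-validated testing balanced accuracy (Tba).
* **Synthetic generator** — a `cd4_like` preset with a planted
  informative mark, so the whole pipeline is testable end to end
  without any downloads.

## Worked example

```r
library(histact)

sim    <- simulate_dataset(sim_config(n_genes = 2000, seed = 11))
fm     <- simulate_features(sim)           # 2000 x 936 binary matrix
labels <- ifelse(sim$states == 1, "active", "inactive")

tree <- grow_tree(fm, labels, k = 5)
print(tree)
#> CART-style tree with 5 internal node(s)
#> TSS-1:H2BK5ac (split 1; 1009 active / 991 inactive)
#>   + TSS-3:H2BK5ac (split 3; 823 active / 176 inactive)
#>     + [active] (642 active / 33 inactive)
#>     - TSS-2:H2BK5ac (split 5; 181 active / 143 inactive)
#>       + [active] (141 active / 31 inactive)
#>       - [inactive] (40 active / 112 inactive)
#>   - TSS:H2BK5ac (split 2; 186 active / 815 inactive)
#>     + TSS-3:H2BK5ac (split 4; 157 active / 164 inactive)
#>       + [active] (125 active / 28 inactive)
#>       - [inactive] (32 active / 136 inactive)
#>     - [inactive] (29 active / 651 inactive)
```

All five internal nodes pick the planted mark H2BK5ac at TSS-proximal
regions — the generator's ground truth, recovered from the data alone.
The tree's +1/−1 designations then set the activity threshold:

```r
avg <- rowMeans(sim$expression)
ord <- order(-avg)
th  <- cumulative_threshold(assign_index(tree, fm)[ord], avg[ord],
                            fm$gene_ids[ord])
print(th)
#> Activity threshold (cumulative procedure) over 2000 genes
#>   g_max = 1009  Y_max = 807
#>   log2 expression threshold = 6.851
#>   active: 1009 (50.45%)  inactive: 991 (49.55%)
#>   index concordance: 89.99% (+1 | active), 90.72% (-1 | inactive)
```

The cut lands at rank 1009 — exactly the number of latently active
genes in this simulation — and the log2 threshold (6.851) falls between
the two expression-mixture means. `plot(th)` draws the Y(g) curve.
Finally, the exhaustive MDR search confirms the tree's choice
independently of any threshold:

```r
mdr_report(mdr_search(fm, labels, "TSS", k_max = 2, seed = 3))
#>   region size             combination       tba
#> 1    TSS    1             TSS:H2BK5ac 0.7911012
#> 2    TSS    2 TSS:H2AK5ac,TSS:H2BK5ac 0.7911012
```

The best single attribute at the TSS is the planted mark (testing
balanced accuracy 0.79); adding a second attribute buys nothing, as it
should when one mark carries the signal.

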