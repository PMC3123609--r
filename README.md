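# CoevolMI

Background-corrected mutual information measures of residue coevolution
in protein multiple sequence alignments.

## What it does and for whom

Compensatory mutations between interacting residues leave correlated
substitution patterns across the columns of a protein family alignment.
For structural biologists and sequence analysts who want per-pair and
per-site coevolution signals from an MSA, CoevolMI implements four
related measures:

* **MI'** — classical mutual information of a column pair, normalized
  by the pair's joint entropy: `MI'(K,L) = MI(K,L) / H(K,L)`, in [0, 1].
* **MIB'** — MI with the marginals replaced by background-corrected
  marginals `p̂(i) = (p_i/q_i) / Σ_j (p_j/q_j)`, where `q` is the
  BLOSUM62 amino-acid background distribution. Dividing by `q` removes
  amino-acid evolutionary pressure, so pairs involving conserved columns
  (invisible to MI') become distinguishable.
* **MIP'** — MI over the 10×10 joint distribution of Taylor's ten
  *overlapping* physicochemical groups, normalized by the property joint
  entropy; 0 when a column's property pattern is fully conserved.
* **MIBP'** — the property-level measure with group marginals divided by
  the property background `q_p(a) = Σ_{i∈a} q_i` and renormalized; the
  only measure that scores a pair of two fully conserved columns.

Pair scores feed the per-site indicator **conn(k)** — the number of
top-n scoring pairs a site participates in — which is more robust than
any single pair score (defaults: top 75 pairs / cutoff 5 for MI'/MIB',
top 25 / cutoff 3 for MIP'/MIBP').

The package also provides the standard MSA preprocessing these measures
assume (greedy 90%-identity redundancy removal, removal of columns with
more than 25% gaps, a warn-only >125-sequence depth check), a
synthetic-MSA generator with controlled coevolution structure, and a
command-line pipeline.

## Worked example

The built-in `toyMsa()` is a 6×6 alignment whose score table is known
exactly: columns 1–2 are conserved, columns 3–5 covary bijectively
(column 3 only between the property-identical W and Y), column 6 is
irregular.

```r
library(CoevolMI)
toy <- toyMsa()
round(normalizedScores(scoreAllPairs(toy, "MIB")), 3)
#>       1     2     3     4     5     6
#> 1 0.000 0.000 0.138 0.237 0.141 0.003
#> 2 0.000 0.000 0.138 0.237 0.141 0.003
#> 3 0.138 0.138 0.000 1.375 1.279 0.360
#> 4 0.237 0.237 1.375 0.000 1.378 0.404
#> 5 0.141 0.141 1.279 1.378 0.000 0.362
#> 6 0.003 0.003 0.360 0.404 0.362 0.000
```

MI' would score every pair involving the conserved columns 1–2 as 0;
MIB' separates them (0.138 / 0.237 / 0.141 / 0.003 against columns
3–6), because the background-corrected marginal of a conserved column
is a point mass wherever it is conserved. MIB' can exceed 1 (1.378 for
the covarying pair 4–5) and is not clamped. The doubly conserved pair
(1,2) is scored only by MIBP':

```r
pairScore(toy, 1, 2, "MIBP")$normalized
#> 33.425  (rounded)
```

conn(k) aggregates a score matrix into per-site hubs:

```r
ct <- connAnalysis(scoreAllPairs(toy, "MI"), nTop = 3, cutoff = 2)
reportSites(ct)
#>   k conn(k)
#> 1 3       2
#> 2 4       2
#> 3 5       2
```

Sites 3, 4 and 5 each occur in two of the three top pairs — the
bijectively covarying block.

From a shell, the same pipeline runs end to end (the toy alignment
contains a deliberate duplicate row, so redundancy removal is switched
off to reproduce its reference scores):

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","coevolmi.R",package="CoevolMI"))')" \
    --input toy.fasta --identity none --out results/
```

writing per-measure pair-score TSVs, conn(k) TSVs, the filtered
alignment and a manifest.

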