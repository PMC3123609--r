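---
title: "Background-corrected mutual information measures of residue coevolution"
author: "CoevolMI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Background-corrected mutual information measures of residue coevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoevolMI)
```

## The problem

When a functionally or structurally important residue of a protein
mutates, compensatory mutations at interacting sites often follow. Over
evolutionary time this leaves correlated substitution patterns between
columns of a multiple sequence alignment (MSA) of the protein family.
CoevolMI quantifies that covariation for every column pair with four
related mutual-information measures, and aggregates pair scores into a
per-site connectivity indicator, conn(k).

## The four measures

Write $N$ for the number of sequences and $c_{pair}(K,L)$ for a pair of
columns. The position-specific frequency of residue $i$ in column $K$ is
$p(K^i) = \mathrm{count}(K^i)/N$, and the joint distribution of the pair
is $p(K^i, L^j) = \mathrm{count}(K^i, L^j)/N$, both taken over the rows
that are non-gap at the columns involved.

**MI'.** Classical mutual information,
$$\mathrm{MI}(K,L) = \sum_{i,j} p(K^i,L^j)\,
  \log\frac{p(K^i,L^j)}{p(K^i)\,p(L^j)},$$
with the convention that a monomial with $p(K^i,L^j)=0$ contributes 0,
is normalized by the joint entropy
$H(K,L) = -\sum_{i,j} p(K^i,L^j)\log p(K^i,L^j)$:
$$\mathrm{MI}'(K,L) = \mathrm{MI}(K,L)/H(K,L),$$
defined as 0 when $H(K,L)=0$. MI' lies in $[0,1]$, is invariant to the
logarithm base, and is exactly 1 for bijectively covarying columns.
If one column is fully conserved, MI' is 0 — conserved columns are
invisible to MI'.

**MIB'.** Residues under weak evolutionary pressure are replaced easily
and are rare in alignments; the background frequency $q_i$ of a residue
is a practical estimate of that pressure. To remove it, the marginals of
the MI model are replaced by background-modified marginals
$$\hat p(K^i) = \frac{p(K^i)/q_i}{\sum_j p(K^j)/q_j},$$
i.e. the observed frequencies are divided by the background and
renormalized. MIB is the MI sum with $\hat p$ in place of the observed
marginals, and MIB' = MIB$/H(K,L)$. A fully conserved column keeps a
point mass regardless of which residue it conserves, so pairs that MI'
scores identically (or 0) become distinguishable; MIB' may exceed 1 and
is not clamped. With a uniform background MIB' collapses to MI'.

The background $q$ is the BLOSUM62 amino-acid background distribution.
The package embeds the 3-decimal table distributed with the Capra–Singh
conservation toolkit (renormalized to sum exactly to 1) rather than the
widely quoted 4-decimal marginals: the two are different roundings of
the same frequencies, and only the former reproduces the package's
reference score table for the built-in toy alignment (see below). The
table is also shipped as JSON under `inst/extdata/` so other tools can
consume identical constants.

**MIP'.** Substitutions that preserve physicochemical character are not
equivalent to ones that change it. Amino acids are classified into
Taylor's ten *overlapping* groups (hydrophobic, aromatic, aliphatic,
tiny, small, proline, charged, negative, polar, positive). The
fractional frequency of group $a$ in column $K$ is
$p_p(K^a) = \mathrm{count}(K^a)/N$; because the groups overlap, the ten
values do not sum to 1. With the analogous $10\times10$ joint
distribution $p_p(K^a, L^b)$, MIP is the MI-type sum over group pairs
and MIP' $= \mathrm{MIP}/H_p(K,L)$, where $H_p$ is the entropy of the
joint property distribution. When every residue of a column carries the
same membership pattern the column is *property-conserved* and MIP' is
0 by convention — this happens not only for residue-conserved columns
but also for columns over {W,Y}, {G,A} or {I,L}, which the ten-group
classification cannot distinguish.

**MIBP'.** The property background $q_p(a) = \sum_{i\in a} q_i$ plays
the role of $q$ at the property level:
$$\hat p_p(K^a) = \frac{p_p(K^a)/q_p(a)}{\sum_b p_p(K^b)/q_p(b)}.$$
MIBP is the property-level sum with these modified marginals;
MIBP' $= \mathrm{MIBP}/H_p(K,L)$ when $H_p>0$ and the raw MIBP
otherwise. There is deliberately no conserved-column short-circuit: a
pair of two fully conserved columns has $H_p=0$ yet a finite, large raw
MIBP (each column holds several overlapping groups whose
background-corrected weights differ), and that value is reported. MIBP'
is the only measure that scores doubly conserved pairs.

One subtlety follows from the overlap: because
$\sum_b p_p(K^b) \ne 1$, a *constant* property background does not
cancel out of $\hat p_p$ the way a uniform $q$ cancels out of
$\hat p$. MIBP' therefore does not degenerate to MIP' when $q_p$ is
flat; the renormalization over overlapping groups is itself
informative. This is a property of the measure, not an implementation
accident.

## The toy alignment as reference surface

`toyMsa()` returns a 6-sequence, 6-column alignment constructed so that
each measure exposes a different facet:

```{r}
toyMsa()
```

Columns 1 and 2 are fully conserved (D, A); columns 3–5 covary
perfectly at the residue level, but column 3 (W/Y) is
property-conserved; column 6 is irregular. Note that rows 5 and 6 are
identical — deliberate, but it means identity clustering at any
threshold would drop one of them, so reference scores are computed on
the alignment as is (`identityThreshold = NULL` in the pipeline). The
complete four-measure score table of this alignment, rounded to 3
decimals, is frozen in the test suite and doubles as the package's
regression reference; `scoreAllPairs()` reproduces it exactly.

```{r}
round(normalizedScores(scoreAllPairs(toyMsa(), "MIB")), 3)
```

## Preprocessing

MI estimates are only as good as the MSA, so the pipeline applies the
standard hygiene steps, each exposed as a function:

* `clusterByIdentity(msa, threshold = 0.9)` — greedy redundancy
  removal in input order (CD-HIT-like): a sequence is dropped when its
  identity to an earlier-retained representative reaches the threshold.
  Identity is the fraction of identical residues over columns where both
  sequences are non-gap (0 when there is no such column). Greedy
  first-in-wins selection was chosen because it is deterministic and
  order-transparent; thresholds of 0.9–0.95 are the usual range, and
  lowering the threshold thins the covariation signal.
* `filterGapColumns(msa, maxGapFraction = 0.25)` — columns with
  *strictly more* than 25% gaps are removed (a 4-row column with one
  gap survives). Surviving columns keep their original numbers via
  `columnMap()`, so reported sites match the source alignment.
* `validateDepth(msa, minSequences = 125)` — true only for strictly
  more than 125 sequences; the pipeline warns and proceeds when the
  check fails, because small alignments are still useful
  illustratively, and `--strict` upgrades the warning to an error.
* At read time symbols are uppercased, `.`/`~` gaps become `-`, and the
  ambiguity codes B, Z, X, J, U, O map to the gap symbol: the frequency
  model is strictly 20-letter, and discarding the handful of ambiguous
  residues is preferable to rejecting whole PFAM families.

Within a pair, all distributions (joint and marginals) are computed
over the rows that are non-gap at *both* columns. This guarantees
$\mathrm{MI} = H(K) + H(L) - H(K,L) \ge 0$ exactly, and on gap-free
input coincides with the per-column definition. A pair with no jointly
non-gap rows is degenerate: it is flagged `NA` and excluded from
ranking rather than scored 0, so it cannot pollute conn(k).

## conn(k)

Individual pair scores can mislead; a site that participates in many
top-scoring pairs is a more robust signal. `connAnalysis()` takes the
top $n$ pairs of a score matrix (ties broken by score, then column
numbers; `includeTies` admits the whole tied cohort) and counts, for
each site, the pairs it occurs in. Defaults follow the measure: top 75
pairs and report cutoff 5 for the residue measures, top 25 and cutoff 3
for the property measures, whose coarser ten-letter alphabet saturates
sooner. Both are parameters, not constants. The handshake identity
$\sum_k \mathrm{conn}(k) = 2 n_{used}$ always holds, and conn is
monotone in $n$.

## The synthetic generator

`simulateMsa()` draws columns i.i.d. from the background, optionally
fixing conserved columns and coupling column pairs: with coupling $c$,
each row of the second column is, with probability $c$, the image of
the first column under a fixed random residue permutation, otherwise an
independent background draw. Coupling 1 gives bijective covariation
(MI' exactly 1), coupling 0 independence. This emulates exactly the
features the measures respond to — marginal composition, conservation,
pairwise coupling — and nothing else: there is no phylogenetic
correlation between rows, no gaps, no indel structure, and no
site-specific rate variation. Tests passing on simulated data therefore
validate the estimators, not their behaviour on real families, where
shared ancestry inflates apparent covariation.

Validation problem sizes were fixed once: null calibration uses 50
replicates of two independent columns at $N = 5000$ (median MI' below
0.02 — the residual is finite-sample bias, which decays like
$1/N$), identity and symmetry checks use 100 seeded alignments of
20–30 sequences, and background-reduction checks use 20 seeded
alignments plus the toy.

## Numerical conventions

* Raw scores use natural logarithms by default; a `base` argument is
  available, and all primed measures are base-invariant (MIBP' on a
  zero-entropy pair reports the raw value and is then base-dependent by
  construction).
* $0\log 0 = 0$ throughout; joint distributions are built from integer
  counts so a conserved pair has $H = 0$ exactly, with no tolerance
  games.
* Raw scores are computed as cross-entropy minus joint entropy with the
  two marginal log terms summed separately; this keeps MI' of a
  bijective pair equal to 1 to the last bit.
* Public TSV output rounds to 3 decimals (the conventional reporting
  precision); all in-memory values keep full precision.

## Limitations

The measures carry no correction for phylogenetic relatedness or for
the average-product background of an alignment (no APC/ASC), and no
shuffling-based significance calibration; scores are comparable within
an alignment, not across alignments. Shallow alignments (the 125-row
rule) give noisy estimates. The ten-group classification cannot see
covariation within {W,Y}, {G,A} or {I,L}. ELSC-style perturbation
scores and conservation rankings are out of scope.
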