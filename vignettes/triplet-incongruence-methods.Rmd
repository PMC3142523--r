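---
title: "Methods: triplet distances, rejection screening, and recombination-coupled incongruence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triplet distances, rejection screening, and recombination-coupled incongruence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripdist)
```

## Scope and model

`tripdist` quantifies topological discordance in multilocus phylogenies with
rooted leaf triplets. All analyses are purely topological: branch lengths are
parsed but never used, and trees are treated as rooted exactly as written.
The package covers four layers:

1. **Triplet distances** between a binary multigenic reference tree and a
   per-locus bootstrap forest, and between pairs of forests.
2. **Strong-rejection screening** of reference-tree triplets against the
   pooled bootstrap collection of all loci, with per-taxon tallies.
3. **A genetic-distance map** converting relative physical positions along
   chromosome arms into centimorgans under an exponential recombination
   gradient, with centromeric/telomeric classification.
4. **Pattern statistics**: rank correlations of per-locus distances with
   locus parameters, a quadratic regression of distance on signed genetic
   position, and two within-arm permutation tests.

A synthetic-data generator produces species trees, discordant gene trees and
noisy bootstrap forests with the statistical structure these analyses assume,
so every stage is testable without sequence data.

## Triplet resolution and retention

For leaves $\{a,b,c\}$ of a rooted tree the triplet resolution is determined
by which pairwise most-recent-common-ancestor is strictly deepest; if the
three MRCAs coincide the triplet is unresolved (a polytomy). Internally each
3-subset is coded over its sorted labels by the *outlier* position (1, 2, 3),
0 for unresolved, `NA` when a leaf is absent from the tree at hand. The unit
and acceptance tests check this coding against an independent brute-force
characterization (a cherry $\{a,b\}$ exists iff some clade contains $a$ and
$b$ but not $c$) on every rooted binary topology with up to 6 leaves and on
random 10-leaf instances.

Over a forest of $N$ trees, a 3-subset is **retained** with resolution $r$
iff $r$ occurs in strictly more than a fraction $\theta$ of the $N$ trees.
With the default $\theta = 0.5$ this guarantees at most one qualifying
resolution per subset, which is why $\theta < 0.5$ is rejected outright.
Counts are integers; the comparison `count > θ·N` is made with a small
numeric guard so that a count sitting exactly on the threshold (50/100 at
0.5, 60/100 at 0.6) is never retained regardless of floating-point
representation. Trees from which a subset's leaves are missing, and trees in
which it is unresolved, count against retention by default (the denominator
is the forest size $N$); `denominator = "present"` switches to counting only
trees that contain all three leaves, which matters when member trees have
heterogeneous leaf sets.

The tree–forest distance is
$d(T, F_j) = n_\mathrm{diff} / (n_\mathrm{same} + n_\mathrm{diff})$
over the retained triplets of $F_j$ whose leaf sets lie inside the shared
leaf set; the forest–forest distance restricts further to subsets retained
in *both* forests (subsets retained in exactly one are reported separately
as a diagnostic). The reference tree must be binary on the comparison leaf
set — callers resolve polytomies first with
`resolve_polytomies_randomly()`, whose seed is dedicated so other draws are
unaffected. When no triplet survives retention the distance is reported as
explicitly undefined (`NA` with `defined = FALSE` and a warning), never as 0.

## Strong rejection

Resolution counts are pooled over every bootstrap tree of every locus. For a
reference triplet with pooled count $n_\mathrm{ref}$ and best-supported
conflicting count $n_\mathrm{conf}$, the two-cell goodness-of-fit statistic
$(n_\mathrm{conf}-n_\mathrm{ref})^2/(n_\mathrm{conf}+n_\mathrm{ref})$ is
compared with the $\chi^2_1$ critical value at the configured confidence
level. The "0.9 threshold" is read as a *confidence level* (critical value
2.706), not a p-value; the critical value is recorded in the result's
attributes so the interpretation is auditable. A triplet is rejected only
when, additionally, $n_\mathrm{conf} > n_\mathrm{ref}$. Unresolved bootstrap
triplets contribute to neither count. The statistic is pluggable
(`statistic` argument) so alternative frequency tests can be swapped in
without touching the pooling logic. Because only triplets containing a
conflict-driving taxon can be rejected, per-taxon counts of rejected
triplets (which always sum to three times the number of rejected triplets)
rank taxa by their involvement in conflict.

## Genetic-distance map

Recombination intensity along an arm is modeled as $c(x) = a e^{bx}$ cM/Mb
over relative position $x \in [0,1]$ from centromere to telomere. The
genetic distance is the scaled integral
$g(x) = L\,a\,(e^{bx}-1)/b$, with the analytic limit $L\,a\,x$ taken when
$|b| < 10^{-12}$. Arm lengths default to 388 Mb (short) and 437 Mb (long).
The gradient constants are not published alongside the arm lengths, so the
defaults are calibrated to the observed span of cM/Mb ratios along a
Triticeae chromosome arm — about two orders of magnitude, from 0.01 at the
centromere to 0.85 at the telomere — giving $a = 0.01$, $b = \log 85$. Both
are plain arguments of `chromosome_model()`; all downstream analyses take
the model as input and no result in the package depends on these two
constants beyond the shape of the map.

Signed coordinates are negative on the short arm and positive on the long
arm, so they increase monotonically from short-arm telomere through the
centromere to long-arm telomere. Loci are centromeric for $x < 0.70$ and
telomeric for $x > 0.70$; exactly 0.70 is classified centromeric — a
documented boundary convention that no locus in the packaged annotation
table exercises. Pairwise genetic distances are unsigned separations
$|s_i - s_j|$; the quadratic regression uses the signed coordinate itself.

## Permutation tests

Both tests respect chromosome-arm structure: labels or coordinates are
permuted only *within* arms, never across, because arm identity is part of
the design (the two arms differ in length and locus composition).

* **Median difference**: observed statistic = median of pairwise triplet
  distances among same-arm telomeric pairs minus the same for centromeric
  pairs; cross-arm pairs never enter. Each replicate permutes the region
  labels among the loci of each arm and rebuilds the pair groups. The test
  errors if either group has fewer than two pairs.
* **Matrix correlation**: observed statistic = Spearman correlation (Pearson
  optional) of the upper triangles of the triplet-distance matrix $M$ and
  the genetic-distance matrix; each replicate permutes the locus coordinates
  within arms and recomputes the genetic matrix while $M$ stays fixed.

Empirical p-values use the add-one convention $(1+b)/(1+R)$, so they are
never zero and the minimum attainable p is $1/(R+1)$. Defaults are
one-sided in the direction of the scientific hypotheses (telomeric >
centromeric; positive distance–incongruence association); `alternative`
switches to two-sided. The Spearman p-value for plain correlations uses the
t-approximation on $n-2$ degrees of freedom, adequate at the $n \approx
20$–$30$ of multilocus studies; an exact enumeration is available for
$n \le 10$.

A property worth knowing: permutation p-values are exact only up to the
discreteness of the statistic. When the distance matrix carries many tied
values — few taxa, small forests, little discordance — the tests become
*conservative* (p-values pile up above 0.5 and the rejection rate falls
below the nominal level). This is correct behavior, not an error; the
calibration experiment below therefore uses a null regime in which distances
are effectively continuous.

## The synthetic generator

`simulate_study()` emulates the structure the analysis assumes, not any
particular evolutionary process:

* a species tree from a uniform random-join process;
* per-locus gene trees obtained by applying a Poisson number of random
  rooted nearest-neighbor interchanges (NNI) to the species tree, with mean
  $\lambda(x) = \lambda_0 (1 + \kappa\, g(x)/g(1))$ for a locus at relative
  position $x$ — so telomeric loci are the most discordant and $\kappa = 0$
  removes the positional signal entirely; unpositioned loci use
  $\lambda_0$;
* bootstrap forests in which each replicate is the gene tree itself or, with
  probability `noise_rate`, the gene tree after one random NNI.

Defaults mirror the shape of a Triticeae-like study: 20 taxa, the 21
chromosome-3 locus positions of the packaged annotation table plus 6
unpositioned loci, 100-tree forests, $\lambda_0 = 1$, $\kappa = 5$,
`noise_rate = 0.1`. Per-locus RNG streams are derived from the master seed,
so adding loci does not perturb existing ones and identical configurations
give byte-identical output.

NNI perturbation was chosen over an explicit multispecies coalescent because
it is simple, dependency-free, and sufficient to induce the monotone
position–discordance coupling the statistics are designed to detect. Two
consequences limit its realism. First, a single NNI alters only a small
fraction of triplets on trees of realistic size, so synthetic distances sit
well below those of real multilocus datasets at moderate move counts; the
generator reproduces the *ordering* of discordance along the chromosome, not
its absolute scale. Second, with bootstrap noise applied as a single NNI per
replicate, majority retention stays near-complete on trees beyond a handful
of leaves; retention degradation is only visible on very small trees. Tests
that pass on this generator therefore demonstrate correctness of the
statistical machinery and recovery of induced couplings — they do not
demonstrate that real data behave like the generator.

## Validation experiments and problem sizes

The test suite validates the pipeline at sizes chosen to exercise each
property cleanly:

* *Oracle equivalence*: all rooted binary topologies on 4–6 leaves
  (15 + 105 + 945 trees) and 500 random 10-leaf tree/forest instances,
  against the clade-counting brute force.
* *Null calibration*: 200 synthetic datasets with $\kappa = 0$ (14 taxa,
  $\lambda_0 = 5$, noise 0.3, 20-tree forests — a regime with effectively
  continuous distances, see above), 500 permutations per test; the
  rejection rate at $\alpha = 0.05$ is required to fall in the exact
  binomial 95% band around 0.05.
* *Coupling recovery*: 50 seeds at the default strong coupling
  ($\lambda_0 = 1$, $\kappa = 5$, 21 positioned loci, 100-tree forests,
  20 taxa), 500 permutations. The positive matrix correlation is recovered
  in well over 90% of seeds. The median-difference test, by contrast, does
  not reach 90% rejection at these settings: with at most
  $\lambda_0(1+\kappa) = 6$ expected NNI moves per gene tree the absolute
  distance scale is small, and the median over the ~20 telomeric pairs of a
  21-locus layout is dominated by per-locus realization noise. This is a
  power limitation of the generator's scale, documented rather than papered
  over by inflating the generator beyond its stated parameters.

## Known limitations

* No NEXUS input; Newick only (quoted labels accepted, internal labels
  parsed but unused).
* No unrooted (quartet) interpretation: all triplet semantics presuppose the
  root, and re-rooting changes the triplet set by design.
* The generator makes no coalescent or introgression claims; it cannot be
  used to *distinguish* incomplete lineage sorting from hybridization, only
  to emulate their shared signature (position-coupled discordance).
* Leaf-set mismatches are handled by intersection; comparisons report how
  many 3-subsets were skipped, but no imputation is attempted.
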