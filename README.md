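# tripdist

Triplet-based quantification of gene-tree incongruence, and its relation to
recombination along chromosome arms.

## The problem

Multilocus phylogenies routinely face gene trees that contradict one another
and the species (multigenic) tree, because of incomplete lineage sorting,
introgression, or plain stochastic error. Triticeae grasses (wheat, barley,
rye and their wild relatives) are an extreme case: single-gene trees disagree
on almost every genus. Two questions then arise for anyone assembling a
multigene phylogeny:

1. *How much* does each locus disagree with the combined (supermatrix or
   Bayesian-concordance) tree, once bootstrap noise is stripped out?
2. *Why* — in particular, does disagreement track recombination, being
   stronger for telomeric loci (high cM/Mb) than for centromeric ones?

`tripdist` implements the full quantitative layer for these questions:
rooted-triplet distances, a χ²-based screen for strongly rejected triplets,
a genetic-map transform of physical positions, and within-arm permutation
tests — plus a synthetic-data generator so the whole pipeline can be
exercised and validated without sequence data.

## The statistics at the core

**Triplet distances.** For three leaves {a, b, c} of a rooted tree, the
rooted triplet records which pair is closest (`ab|c`). Given a reference tree
*T* and the bootstrap forest *F_j* of locus *j* (100 trees per locus in
typical use), only triplets whose resolution appears in **strictly more than
50%** of the forest are retained — this keeps exactly one resolution per
3-leaf set and filters bootstrap noise. With `s` retained triplets resolved
the same way as *T* and `d` resolved differently,

    d(T, F_j) = d / (s + d)

and analogously for two forests, `d(F_i, F_j)`, restricted to triplets
retained in both. Applied to all locus pairs this yields the symmetric
incongruence matrix *M*.

**Strongly rejected triplets.** Resolution counts are pooled over all
bootstrap trees of all loci (e.g. 27 × 100 = 2,700). A triplet of the
reference tree with pooled support `n_ref`, facing a best conflicting
resolution with support `n_conf`, is *strongly rejected* when
`n_conf > n_ref` and

    χ² = (n_conf − n_ref)² / (n_conf + n_ref) > χ²₁(0.9) = 2.706.

Counting the rejected triplets each taxon belongs to ranks taxa by their
involvement in conflict (rogue-taxon detection).

**Genetic-distance map.** Recombination intensity along a chromosome arm is
modeled as c(x) = a·e^{bx} cM/Mb over relative position x ∈ [0, 1];
integrating and scaling by the physical arm length L (388 Mb short,
437 Mb long) gives

    g(x) = L · a · (e^{bx} − 1) / b   [cM],

signed negative on the short arm and positive on the long arm. Loci are
centromeric if x < 0.70, telomeric if x > 0.70.

**Permutation tests.** Telomeric-vs-centromeric contrast: median of pairwise
triplet distances among same-arm telomeric pairs minus the centromeric
median, with a null built by permuting region labels among loci *within each
arm* (10,000 replicates by default). Distance decay: Spearman correlation of
the upper triangles of *M* and the pairwise genetic-distance matrix, with
locus coordinates permuted within arms. Empirical p-values use the add-one
convention (1 + b)/(1 + reps).

## Worked example

```r
library(tripdist)

ts <- parse_newick("((((Psathyrostachys,Hordeum),Pseudoroegneria),(Dasypyrum,Secale)),Brachypodium);")
gt <- parse_newick("((((Psathyrostachys,Pseudoroegneria),Hordeum),(Dasypyrum,Secale)),Brachypodium);")
f  <- simulate_bootstrap_forest(gt, noise_rate = 0.1, n_reps = 100, seed = 7)
tree_forest_distance(ts, f)
#> Triplet fit dissimilarity (tree vs forest):
#>   distance = 0.05  (n_same = 19 , n_diff = 1 )
#>   retained: 20  skipped: 0  threshold: 0.5
```

Of the C(6,3) = 20 triplets, 19 majority-retained resolutions of the forest
match the reference tree; the one disagreement (the swapped
Hordeum/Pseudoroegneria position) gives distance 1/20 = 0.05.

A full synthetic study — 20 taxa, the 21 chromosome-3 locus positions of the
packaged annotation table plus 6 unpositioned loci, 100-tree forests, with
discordance intensity coupled to genetic position:

```r
report <- run_full_analysis(synthetic_config(seed = 1), reps = 2000)
report
#> Incongruence analysis report
#>   mean tree-forest distance: 0.046 over 27 loci
#>   strongly rejected triplets: 0 (top taxon: t1, 0)
#>   telomeric - centromeric median: 0.131 (p = 0.06197)
#>   genetic/triplet matrix correlation: 0.539 (p = 0.0004998)
```

Here telomeric locus pairs are more incongruent than centromeric ones by
0.131 in median triplet distance, and incongruence decays with genetic
proximity (within-arm permutation p ≈ 5e-4 for the matrix correlation).

The packaged 27-locus Triticeae annotation table (alignment lengths,
chromosome-3 positions, evolutionary rates, gamma shapes, per-locus triplet
distances to the supermatrix and BUCKy trees) drives the descriptive layer:

```r
run_annotations_analysis()
#> Locus annotation report: 27 loci ( 21 positioned, 6 unpositioned ), 24652 bp total
#>   TD supermatrix: 0.21 +/- 0.10 (0.08-0.51)
#>   TD BUCKy:       0.25 +/- 0.09 (0.07-0.43)
#>   region audit: 21 / 21 labels agree with the 70% rule
```

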