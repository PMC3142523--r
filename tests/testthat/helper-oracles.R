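# Independent brute-force oracles. The package resolves triplets by comparing
# MRCA depths; the oracle here uses a different characterization entirely:
# {a,b,c} is resolved with cherry {a,b} iff some clade of the tree contains a
# and b but not c. Distances are recomputed from the oracle's triplet sets by
# direct counting.

# Leaf-descendant sets of every internal node.
oracle_clades <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  clades <- c(as.list(tree$tip.label),
              rep(list(character(0)), tree$Nnode))
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    clades[[p]] <- c(clades[[p]], clades[[ch]])
  }
  clades[(ntip + 1L):(ntip + tree$Nnode)]
}

# Same coding convention as the package (1/2/3 = outlier position over the
# sorted triple, 0 unresolved, NA absent), derived from clade membership: the
# cherry of {a,b,c} is {a,b} iff some clade contains a and b but not c, i.e.
# iff strictly more clades contain {a,b} than contain {a,b,c}.
oracle_triplet_codes <- function(tree, labels) {
  combs <- t(utils::combn(length(labels), 3L))
  clades <- oracle_clades(tree)
  memb <- vapply(clades, function(cl) labels %in% cl,
                 logical(length(labels))) # leaf x clade membership
  memb <- matrix(memb, nrow = length(labels))
  present <- labels %in% tree$tip.label
  codes <- rep(NA_integer_, nrow(combs))
  for (k in seq_len(nrow(combs))) {
    trio <- combs[k, ]
    if (!all(present[trio])) next
    n_all <- sum(memb[trio[1], ] & memb[trio[2], ] & memb[trio[3], ])
    code <- 0L
    for (out_pos in 1:3) {
      cherry <- trio[-out_pos]
      if (sum(memb[cherry[1], ] & memb[cherry[2], ]) > n_all) code <- out_pos
    }
    codes[k] <- code
  }
  codes
}

# Majority-retained resolution per 3-subset over a plain list of trees.
oracle_retained <- function(trees, labels, threshold = 0.5) {
  N <- length(trees)
  codes <- vapply(trees, function(t)
    as.numeric(oracle_triplet_codes(t, labels)),
    numeric(choose(length(labels), 3L)))
  codes <- matrix(codes, ncol = N)
  apply(codes, 1L, function(v) {
    tab <- table(factor(v[!is.na(v) & v > 0], levels = 1:3))
    best <- which.max(tab)
    if (tab[best] > threshold * N + 1e-9) as.integer(best) else NA_integer_
  })
}

oracle_tree_forest_distance <- function(tree, trees, labels, threshold = 0.5) {
  ref <- oracle_triplet_codes(tree, labels)
  ret <- oracle_retained(trees, labels, threshold)
  cmp <- !is.na(ret)
  n_same <- sum(ret[cmp] == ref[cmp])
  n_diff <- sum(ret[cmp] != ref[cmp])
  if (n_same + n_diff == 0) NA_real_ else n_diff / (n_same + n_diff)
}

oracle_forest_forest_distance <- function(trees1, trees2, labels,
                                          threshold = 0.5) {
  r1 <- oracle_retained(trees1, labels, threshold)
  r2 <- oracle_retained(trees2, labels, threshold)
  both <- !is.na(r1) & !is.na(r2)
  n_same <- sum(r1[both] == r2[both])
  n_diff <- sum(r1[both] != r2[both])
  if (n_same + n_diff == 0) NA_real_ else n_diff / (n_same + n_diff)
}

# Random rooted binary tree on the given labels (random joins).
random_rooted_tree <- function(labels) {
  parts <- sample(labels)
  while (length(parts) > 1L) {
    pick <- sample.int(length(parts), 2L)
    parts <- c(parts[-pick],
               paste0("(", parts[pick[1L]], ",", parts[pick[2L]], ")"))
  }
  ape::read.tree(text = paste0(parts, ";"))
}
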