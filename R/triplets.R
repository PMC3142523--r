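# Rooted triplet machinery. For three leaves {a,b,c} of a rooted tree, the
# triplet states which pair is more closely related: ab|c means a and b share
# a more recent common ancestor than either does with c. Over the sorted
# triple (a,b,c) a resolution is encoded as an integer: 1, 2, 3 name the
# OUTLIER leaf position (3 means the cherry is {a,b}), 0 means unresolved
# (the three pairwise MRCAs coincide), NA means a leaf is absent.

# All C(n,3) sorted 3-subsets of `labels` as an index matrix.
triplet_index <- function(labels) {
  n <- length(labels)
  if (n < 3L) stop("need at least 3 leaves to form triplets")
  t(utils::combn(n, 3L))
}

# Topological depth (edge count from the root) of every node.
node_depths <- function(tree) {
  tree <- stats::reorder(tree) # cladewise: parents precede children
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  depth <- integer(n_nodes)
  e <- tree$edge
  for (i in seq_len(nrow(e))) depth[e[i, 2L]] <- depth[e[i, 1L]] + 1L
  depth
}

# Resolution code of every 3-subset of `labels` in `tree`, via the depths of
# the three pairwise MRCAs: the strictly deepest MRCA identifies the cherry;
# all-equal depths mean unresolved; a missing leaf gives NA.
triplet_codes <- function(tree, labels, combs = NULL) {
  if (is.null(combs)) combs <- triplet_index(labels)
  pos <- match(labels, tree$tip.label)
  depth <- node_depths(tree)
  mr <- ape::mrca(tree)
  a <- pos[combs[, 1L]]; b <- pos[combs[, 2L]]; c <- pos[combs[, 3L]]
  codes <- rep(NA_integer_, nrow(combs))
  ok <- !(is.na(a) | is.na(b) | is.na(c))
  if (!any(ok)) return(codes)
  dab <- depth[mr[cbind(a[ok], b[ok])]]
  dac <- depth[mr[cbind(a[ok], c[ok])]]
  dbc <- depth[mr[cbind(b[ok], c[ok])]]
  code <- integer(sum(ok)) # 0 = unresolved
  code[dab > dac & dab > dbc] <- 3L # cherry {a,b}
  code[dac > dab & dac > dbc] <- 2L # cherry {a,c}
  code[dbc > dab & dbc > dac] <- 1L # cherry {b,c}
  codes[ok] <- code
  codes
}

# Human-readable "x,y|z" form of a coded resolution.
resolution_string <- function(labels, combs, code) {
  out <- rep(NA_character_, length(code))
  for (k in which(!is.na(code) & code > 0L)) {
    trio <- labels[combs[k, ]]
    z <- code[k]
    cherry <- trio[-z]
    out[k] <- paste0(cherry[1L], ",", cherry[2L], "|", trio[z])
  }
  out
}

#' Extract the rooted triplets of a tree
#'
#' One row per 3-leaf subset. A subset is unresolved iff its three pairwise
#' most-recent-common-ancestors coincide; a binary tree on n leaves therefore
#' yields choose(n, 3) resolved triplets.
#'
#' @param tree A `phylo` object with at least 3 leaves.
#' @return A data frame with columns `leaf1`, `leaf2`, `leaf3` (sorted),
#'   `resolution` (`"x,y|z"` or `NA` when unresolved) and `outlier`.
#' @examples
#' extract_triplets(parse_newick("((a,b),(c,d));"))
#' @export
extract_triplets <- function(tree) {
  validate_phylo(tree)
  if (ape::Ntip(tree) < 3L) stop("tree has fewer than 3 leaves")
  labels <- sort(tree$tip.label)
  combs <- triplet_index(labels)
  code <- triplet_codes(tree, labels, combs)
  data.frame(
    leaf1 = labels[combs[, 1L]],
    leaf2 = labels[combs[, 2L]],
    leaf3 = labels[combs[, 3L]],
    resolution = resolution_string(labels, combs, code),
    outlier = ifelse(is.na(code) | code == 0L, NA_character_,
                     labels[combs[cbind(seq_len(nrow(combs)), code)]]),
    stringsAsFactors = FALSE
  )
}

#' Tabulate triplet resolution frequencies over a forest
#'
#' Counts, for every 3-leaf subset of the triplet universe, how many member
#' trees support each of the three resolutions, how many leave it unresolved,
#' and how many lack at least one of its leaves ("absent"). Identical member
#' trees are detected and counted once with a weight, which makes large
#' low-noise forests cheap.
#'
#' @param forest A [bootstrap_forest()].
#' @param labels Triplet universe (sorted leaf labels); defaults to the
#'   forest's nominal leaf set.
#' @return An object of class `triplet_freq`: a list with `labels`, the
#'   3-subset index matrix `triplets`, an integer `counts` matrix with columns
#'   `res1`, `res2`, `res3`, `unresolved`, `absent`, and the forest size `N`.
#' @export
count_forest_triplets <- function(forest, labels = NULL) {
  stopifnot(inherits(forest, "bootstrap_forest"))
  if (is.null(labels)) labels <- forest$leaves
  labels <- sort(labels)
  combs <- triplet_index(labels)
  keys <- vapply(forest$trees, function(t) ape::write.tree(t), character(1))
  uk <- match(keys, unique(keys))
  weights <- tabulate(uk)
  counts <- matrix(0L, nrow(combs), 5L,
                   dimnames = list(NULL, c("res1", "res2", "res3",
                                           "unresolved", "absent")))
  first_of <- match(seq_along(weights), uk)
  for (u in seq_along(weights)) {
    code <- triplet_codes(forest$trees[[first_of[u]]], labels, combs)
    col <- ifelse(is.na(code), 5L, ifelse(code == 0L, 4L, code))
    idx <- cbind(seq_len(nrow(combs)), col)
    counts[idx] <- counts[idx] + weights[u]
  }
  structure(
    list(labels = labels, triplets = combs, counts = counts,
         N = length(forest$trees), locus = forest$locus),
    class = "triplet_freq"
  )
}

#' @export
print.triplet_freq <- function(x, ...) {
  cat("Triplet frequency table:", nrow(x$triplets), "3-subsets over",
      x$N, "trees", if (!is.null(x$locus)) paste0("(locus ", x$locus, ")"), "\n")
  invisible(x)
}

check_threshold <- function(threshold) {
  if (threshold < 0.5 || threshold >= 1)
    stop("retention threshold must be in [0.5, 1): values below 0.5 break ",
         "the one-resolution-per-triplet guarantee")
  invisible(threshold)
}

# Winning resolution code per 3-subset, or NA when no resolution strictly
# exceeds threshold * denominator. Counts are integers; the strict comparison
# uses a small guard so that a count exactly at the threshold (e.g. 50/100 at
# 0.5, or 60/100 at 0.6) is never retained.
retained_codes <- function(tf, threshold = 0.5,
                           denominator = c("forest", "present")) {
  check_threshold(threshold)
  denominator <- match.arg(denominator)
  res <- tf$counts[, 1:3, drop = FALSE]
  win <- max.col(res, ties.method = "first")
  best <- res[cbind(seq_len(nrow(res)), win)]
  denom <- if (denominator == "present") tf$N - tf$counts[, "absent"] else tf$N
  keep <- denom > 0L & (best - threshold * denom) > 1e-9
  ifelse(keep, win, NA_integer_)
}

#' Majority-retained triplets of a forest
#'
#' A 3-leaf subset is retained with resolution r iff r appears in strictly
#' more than `threshold` of the forest's trees (strict inequality, so that at
#' most one resolution can ever qualify). Subsets with no qualifying
#' resolution are dropped.
#'
#' @param table A `triplet_freq` from [count_forest_triplets()].
#' @param threshold Retention fraction in `[0.5, 1)`; default 0.5.
#' @param denominator `"forest"` (default) counts trees missing the triplet's
#'   leaves against retention; `"present"` restricts the denominator to trees
#'   containing all three leaves.
#' @return Data frame of retained subsets with their resolution and support
#'   count.
#' @export
retained_triplets <- function(table, threshold = 0.5,
                              denominator = c("forest", "present")) {
  stopifnot(inherits(table, "triplet_freq"))
  code <- retained_codes(table, threshold, denominator)
  keep <- which(!is.na(code))
  combs <- table$triplets[keep, , drop = FALSE]
  data.frame(
    leaf1 = table$labels[combs[, 1L]],
    leaf2 = table$labels[combs[, 2L]],
    leaf3 = table$labels[combs[, 3L]],
    resolution = resolution_string(table$labels, combs, code[keep]),
    count = table$counts[cbind(keep, code[keep])],
    stringsAsFactors = FALSE
  )
}

new_triplet_comparison <- function(n_same, n_diff, n_retained, n_skipped,
                                   threshold, what) {
  defined <- (n_same + n_diff) > 0L
  if (!defined)
    warning("no retained triplets to compare: distance is undefined",
            call. = FALSE)
  structure(
    list(n_same = n_same, n_diff = n_diff,
         distance = if (defined) n_diff / (n_same + n_diff) else NA_real_,
         defined = defined, n_retained = n_retained, n_skipped = n_skipped,
         threshold = threshold, comparison = what),
    class = "triplet_comparison"
  )
}

#' @export
print.triplet_comparison <- function(x, ...) {
  cat("Triplet fit dissimilarity (", x$comparison, "):\n", sep = "")
  cat("  distance =", if (x$defined) format(x$distance, digits = 4) else "undefined",
      " (n_same =", x$n_same, ", n_diff =", x$n_diff, ")\n")
  cat("  retained:", x$n_retained, " skipped:", x$n_skipped,
      " threshold:", x$threshold, "\n")
  invisible(x)
}

#' Triplet distance between a reference tree and a bootstrap forest
#'
#' The triplet fit dissimilarity between a multigenic reference tree T and the
#' bootstrap forest F of one locus: among the majority-retained triplets of F
#' (restricted to 3-subsets inside the shared leaf set), the fraction resolved
#' differently from T,
#' \deqn{d(T, F) = n_{diff} / (n_{same} + n_{diff}).}
#' The reference tree must be binary on the shared leaf set; resolve
#' polytomies first with [resolve_polytomies_randomly()] if needed.
#'
#' @param tree Reference `phylo` tree, binary on the shared leaves.
#' @param forest A [bootstrap_forest()].
#' @param threshold Retention fraction, see [retained_triplets()].
#' @param denominator See [retained_triplets()].
#' @return A `triplet_comparison` with fields `n_same`, `n_diff`, `distance`
#'   (in `[0, 1]`, `NA` with `defined = FALSE` when nothing is retained),
#'   `n_retained` and `n_skipped`.
#' @export
tree_forest_distance <- function(tree, forest, threshold = 0.5,
                                 denominator = c("forest", "present")) {
  validate_phylo(tree)
  stopifnot(inherits(forest, "bootstrap_forest"))
  shared <- sort(intersect(tree$tip.label, forest$leaves))
  if (length(shared) < 3L)
    stop("reference tree and forest share fewer than 3 leaves")
  combs <- triplet_index(shared)
  ref <- triplet_codes(tree, shared, combs)
  if (anyNA(ref) || any(ref == 0L))
    stop("reference tree is not binary on the shared leaf set; ",
         "apply resolve_polytomies_randomly() first")
  tf <- count_forest_triplets(forest, labels = shared)
  ret <- retained_codes(tf, threshold, denominator)
  cmp <- !is.na(ret)
  n_same <- sum(ret[cmp] == ref[cmp])
  n_diff <- sum(ret[cmp] != ref[cmp])
  new_triplet_comparison(n_same, n_diff,
                         n_retained = sum(cmp), n_skipped = sum(!cmp),
                         threshold = threshold, what = "tree vs forest")
}

#' Triplet distance between two bootstrap forests
#'
#' Restricted to 3-subsets whose majority resolution is retained in *both*
#' forests; among those, the fraction resolved differently,
#' \deqn{d(F_i, F_j) = n_{diff} / (n_{same} + n_{diff}).}
#' Symmetric in its arguments. Subsets retained in exactly one forest are
#' reported in `n_one_sided` as a diagnostic.
#'
#' @param forest1,forest2 [bootstrap_forest()] objects sharing at least 3
#'   nominal leaves.
#' @inheritParams tree_forest_distance
#' @return A `triplet_comparison` (see [tree_forest_distance()]) with the
#'   extra field `n_one_sided`.
#' @export
forest_forest_distance <- function(forest1, forest2, threshold = 0.5,
                                   denominator = c("forest", "present")) {
  stopifnot(inherits(forest1, "bootstrap_forest"),
            inherits(forest2, "bootstrap_forest"))
  shared <- sort(intersect(forest1$leaves, forest2$leaves))
  if (length(shared) < 3L) stop("forests share fewer than 3 nominal leaves")
  tf1 <- count_forest_triplets(forest1, labels = shared)
  tf2 <- count_forest_triplets(forest2, labels = shared)
  r1 <- retained_codes(tf1, threshold, denominator)
  r2 <- retained_codes(tf2, threshold, denominator)
  both <- !is.na(r1) & !is.na(r2)
  one <- xor(!is.na(r1), !is.na(r2))
  n_same <- sum(r1[both] == r2[both])
  n_diff <- sum(r1[both] != r2[both])
  out <- new_triplet_comparison(n_same, n_diff,
                                n_retained = sum(both), n_skipped = sum(!both),
                                threshold = threshold, what = "forest vs forest")
  out$n_one_sided <- sum(one)
  out
}

#' Pairwise triplet-distance matrix over a set of forests
#'
#' Applies [forest_forest_distance()] to every pair of forests. Entries whose
#' distance is undefined (no jointly retained triplets) are `NA` and flagged
#' in the `"defined"` attribute.
#'
#' @param forests List of [bootstrap_forest()] objects; names (or locus ids)
#'   label the matrix.
#' @inheritParams tree_forest_distance
#' @return Symmetric numeric matrix with zero diagonal and a logical
#'   `"defined"` attribute of the same shape.
#' @export
pairwise_matrix <- function(forests, threshold = 0.5,
                            denominator = c("forest", "present")) {
  if (length(forests) < 2L) stop("need at least 2 forests")
  denominator <- match.arg(denominator)
  ids <- names(forests)
  if (is.null(ids))
    ids <- vapply(seq_along(forests), function(i) {
      lc <- forests[[i]]$locus
      if (is.null(lc)) paste0("locus", i) else lc
    }, character(1))
  n <- length(forests)
  universe <- sort(unique(unlist(lapply(forests, `[[`, "leaves"))))
  tfs <- lapply(forests, count_forest_triplets, labels = universe)
  rets <- lapply(tfs, retained_codes, threshold = threshold,
                 denominator = denominator)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  defined <- matrix(TRUE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      ri <- rets[[i]]; rj <- rets[[j]]
      both <- !is.na(ri) & !is.na(rj)
      n_same <- sum(ri[both] == rj[both])
      n_diff <- sum(ri[both] != rj[both])
      if (n_same + n_diff == 0L) {
        M[i, j] <- M[j, i] <- NA_real_
        defined[i, j] <- defined[j, i] <- FALSE
      } else {
        M[i, j] <- M[j, i] <- n_diff / (n_same + n_diff)
      }
    }
  }
  if (any(!defined))
    warning(sum(!defined[upper.tri(defined)]),
            " forest pair(s) had no jointly retained triplets", call. = FALSE)
  attr(M, "defined") <- defined
  attr(M, "threshold") <- threshold
  M
}
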