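#' Triplets of a reference tree strongly rejected by pooled bootstrap trees
#'
#' For every 3-leaf subset resolved in the reference tree, resolution counts
#' are pooled over *all* bootstrap trees of *all* loci (2,700 trees in a
#' 27-locus study with 100 replicates each). The reference resolution, with
#' pooled count `n_ref`, is tested against the best-supported conflicting
#' resolution, with count `n_conf`, by a two-cell chi-squared goodness-of-fit
#' statistic under a 50:50 null,
#' \deqn{\chi^2 = (n_{conf} - n_{ref})^2 / (n_{conf} + n_{ref}),}
#' on 1 degree of freedom. The triplet is strongly rejected iff
#' `n_conf > n_ref` and the statistic exceeds the chi-squared critical value
#' at the configured confidence level (2.706 at 0.9).
#'
#' The "threshold of 0.9" is interpreted as a confidence level, i.e. the
#' critical value `qchisq(0.9, df = 1)`; this is recorded in the result's
#' attributes. Unresolved bootstrap triplets contribute to neither count.
#' The two-cell statistic can be swapped out via `statistic` to replicate
#' alternative frequency tests.
#'
#' @param tree Binary reference `phylo` tree (a supermatrix or concordance
#'   tree).
#' @param forests List of [bootstrap_forest()] objects, one per locus.
#' @param confidence Confidence level in (0, 1); default 0.9.
#' @param statistic Function `(n_ref, n_conf) -> numeric` computing the test
#'   statistic; defaults to the two-cell chi-squared form above.
#' @return A data frame of class `rejected_triplets` with one row per
#'   reference triplet that conflicts with at least one pooled bootstrap
#'   triplet: leaves, reference and best-conflicting resolutions, pooled
#'   counts, the statistic, and a `rejected` flag. Attributes record the
#'   confidence, critical value, pooled collection size and full leaf set.
#' @examples
#' sp <- parse_newick("((a,b),(c,d));")
#' f <- bootstrap_forest(rep(list(parse_newick("((a,c),(b,d));")), 10))
#' strongly_rejected_triplets(sp, list(f))
#' @export
strongly_rejected_triplets <- function(tree, forests, confidence = 0.9,
                                       statistic = chisq_two_cell) {
  validate_phylo(tree)
  if (inherits(forests, "bootstrap_forest")) forests <- list(forests)
  if (!length(forests)) stop("pooled bootstrap collection is empty")
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must be strictly between 0 and 1")
  pooled_leaves <- sort(unique(unlist(lapply(forests, `[[`, "leaves"))))
  labels <- sort(intersect(tree$tip.label, pooled_leaves))
  if (length(labels) < 3L)
    stop("reference tree and pooled collection share fewer than 3 leaves")
  combs <- triplet_index(labels)
  ref <- triplet_codes(tree, labels, combs)
  if (anyNA(ref) || any(ref == 0L))
    stop("reference tree is not binary on the shared leaf set; ",
         "apply resolve_polytomies_randomly() first")
  counts <- matrix(0L, nrow(combs), 5L)
  for (f in forests) {
    stopifnot(inherits(f, "bootstrap_forest"))
    counts <- counts + count_forest_triplets(f, labels = labels)$counts
  }
  idx <- seq_len(nrow(combs))
  n_ref <- counts[cbind(idx, ref)]
  other <- t(vapply(idx, function(k) setdiff(1:3, ref[k]), integer(2)))
  o1 <- counts[cbind(idx, other[, 1L])]
  o2 <- counts[cbind(idx, other[, 2L])]
  conf_code <- ifelse(o1 >= o2, other[, 1L], other[, 2L])
  n_conf <- pmax(o1, o2)
  stat <- ifelse(n_ref + n_conf > 0, statistic(n_ref, n_conf), 0)
  crit <- qchisq(confidence, df = 1L)
  rejected <- n_conf > n_ref & stat > crit
  contested <- n_conf >= 1L
  out <- data.frame(
    leaf1 = labels[combs[, 1L]],
    leaf2 = labels[combs[, 2L]],
    leaf3 = labels[combs[, 3L]],
    ref_resolution = resolution_string(labels, combs, ref),
    conflict_resolution = resolution_string(labels, combs, conf_code),
    n_ref = n_ref, n_conf = n_conf, chisq = stat, rejected = rejected,
    stringsAsFactors = FALSE
  )[contested, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("rejected_triplets", "data.frame"),
            confidence = confidence, critical_value = crit,
            n_pooled_trees = sum(vapply(forests, length, integer(1))),
            taxa = labels)
}

# Two-cell goodness-of-fit of (n_ref, n_conf) against a 50:50 split.
chisq_two_cell <- function(n_ref, n_conf) {
  (n_conf - n_ref)^2 / (n_conf + n_ref)
}

#' Per-taxon counts of strongly rejected triplets
#'
#' Each strongly rejected triplet increments exactly its 3 member taxa; taxa
#' never involved are reported with count 0, so the counts always sum to
#' three times the number of rejected triplets.
#'
#' @param rejected A `rejected_triplets` object (or compatible data frame
#'   with `leaf1..leaf3` and `rejected` columns).
#' @param taxa Label set to report; defaults to the taxa recorded on
#'   `rejected`, or to the labels observed in it.
#' @return Data frame with columns `taxon` and `count`, sorted by decreasing
#'   count.
#' @export
per_taxon_counts <- function(rejected, taxa = NULL) {
  if (is.null(taxa)) taxa <- attr(rejected, "taxa")
  hit <- rejected[rejected$rejected, c("leaf1", "leaf2", "leaf3")]
  if (is.null(taxa))
    taxa <- sort(unique(unlist(rejected[c("leaf1", "leaf2", "leaf3")])))
  involved <- unlist(hit, use.names = FALSE)
  counts <- vapply(taxa, function(t) sum(involved == t), integer(1))
  out <- data.frame(taxon = taxa, count = counts, stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$taxon), ]
  rownames(out) <- NULL
  out
}
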