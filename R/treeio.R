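#' Parse a rooted tree from Newick text or a file
#'
#' Reads a single rooted, leaf-labeled tree. Polytomies are preserved; unary
#' (single-child) internal nodes are collapsed; leaf labels must be unique.
#' Branch lengths, when present, are kept but are ignored by all triplet
#' operations, which are purely topological.
#'
#' @param text Newick string (must end in `;`). Mutually exclusive with `file`.
#' @param file Path to a file containing one Newick tree.
#' @return An object of class `phylo` (rooted as written).
#' @examples
#' parse_newick("((a,b),c);")
#' parse_newick("(a,b,c);") # polytomy retained
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'")
  if (!is.null(file)) {
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: no tree found in input")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  tree <- ape::collapse.singles(tree)
  validate_phylo(tree)
  tree
}

# Cheap pre-parse scan so malformed input fails with a character offset
# rather than an opaque downstream error.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at character ", i, call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at end of input", call. = FALSE)
  if (!grepl(";", text, fixed = TRUE))
    stop("Newick parse error: missing terminating ';' at character ",
         nchar(text), call. = FALSE)
  invisible(TRUE)
}

validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  labs <- tree$tip.label
  if (any(is.na(labs)) || any(labs == ""))
    stop("validation error: empty leaf label")
  dup <- unique(labs[duplicated(labs)])
  if (length(dup))
    stop("validation error: duplicate leaf label(s): ", paste(dup, collapse = ", "))
  invisible(tree)
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Restrict a tree to a subset of its leaves
#'
#' Induced subtree on the kept leaves: internal nodes left with a single child
#' are suppressed and their branch lengths summed (delegated to
#' [ape::keep.tip()]).
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of leaf labels to retain.
#' @return The induced `phylo` subtree.
#' @examples
#' write_newick(restrict_to_leaves(parse_newick("((a,b),(c,d));"), c("a", "b", "c")))
#' @export
restrict_to_leaves <- function(tree, keep) {
  validate_phylo(tree)
  keep <- intersect(keep, tree$tip.label)
  if (length(keep) < 2L)
    stop("fewer than 2 of the requested leaves are present in the tree")
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Re-root a tree on an outgroup
#'
#' Places the root on the edge subtending the outgroup (a single leaf or a
#' clade). The outgroup must be monophyletic in the unrooted sense.
#'
#' @param tree A `phylo` object.
#' @param outgroup Leaf label or vector of leaf labels.
#' @return A rooted `phylo` object.
#' @examples
#' write_newick(reroot_on_outgroup(parse_newick("((a,b),(c,d));"), "a"))
#' @export
reroot_on_outgroup <- function(tree, outgroup) {
  validate_phylo(tree)
  missing_lab <- setdiff(outgroup, tree$tip.label)
  if (length(missing_lab))
    stop("outgroup label(s) not in tree: ", paste(missing_lab, collapse = ", "))
  if (length(outgroup) > 1L &&
      !ape::is.monophyletic(tree, outgroup)) {
    stop("outgroup is not monophyletic in this tree: ",
         paste(outgroup, collapse = ", "))
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Randomly resolve polytomies into bifurcations
#'
#' Converts a multifurcating tree into a binary tree by random resolution
#' (the classic `multi2di` operation). Every clade of the input is a clade of
#' the output. Deterministic for a fixed seed; the RNG state of the caller is
#' restored afterwards so other random draws are unaffected.
#'
#' @param tree A `phylo` object.
#' @param seed Integer seed for the dedicated RNG stream.
#' @return A binary `phylo` object.
#' @examples
#' write_newick(resolve_polytomies_randomly(parse_newick("(a,b,c);"), seed = 1))
#' @export
resolve_polytomies_randomly <- function(tree, seed) {
  validate_phylo(tree)
  # a rooted tree is fully bifurcating iff it has Ntip - 1 internal nodes
  # (ape::is.binary would accept a basal trifurcation as unrooted-binary)
  if (tree$Nnode == ape::Ntip(tree) - 1L) return(tree)
  with_local_seed(seed, ape::multi2di(tree, random = TRUE))
}

# Evaluate `expr` under `set.seed(seed)` while preserving the caller's RNG
# state (including the no-state-yet case).
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Construct a bootstrap forest
#'
#' A bootstrap forest is the ordered collection of trees inferred from
#' bootstrap resamples of one locus alignment (100 per locus in typical use).
#' All member trees' leaf sets must be subsets of the nominal leaf set.
#'
#' @param trees A list of `phylo` objects or a `multiPhylo`.
#' @param locus Optional locus identifier.
#' @param leaves Nominal leaf set; defaults to the union over member trees.
#' @return An object of class `bootstrap_forest`.
#' @export
bootstrap_forest <- function(trees, locus = NULL, leaves = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (!length(trees)) stop("a bootstrap forest needs at least one tree")
  lapply(trees, validate_phylo)
  all_leaves <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  if (is.null(leaves)) leaves <- all_leaves
  extra <- setdiff(all_leaves, leaves)
  if (length(extra))
    stop("member tree leaves outside the nominal leaf set: ",
         paste(extra, collapse = ", "))
  structure(
    list(trees = trees, locus = locus, leaves = sort(leaves)),
    class = "bootstrap_forest"
  )
}

#' @export
print.bootstrap_forest <- function(x, ...) {
  cat("Bootstrap forest", if (!is.null(x$locus)) paste0("'", x$locus, "'"),
      "with", length(x$trees), "trees on", length(x$leaves), "nominal leaves\n")
  invisible(x)
}

#' @export
length.bootstrap_forest <- function(x) length(x$trees)

#' Read a bootstrap forest from a multi-tree Newick file
#'
#' One tree per line (or any multi-tree Newick file readable by
#' [ape::read.tree()]).
#'
#' @param file Path to the Newick file.
#' @param locus Optional locus identifier; defaults to the file name.
#' @return A [bootstrap_forest()].
#' @export
read_forest <- function(file, locus = NULL) {
  trees <- ape::read.tree(file)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(locus))
    locus <- sub("\\.(nwk|tre|trees|txt)$", "", basename(file))
  bootstrap_forest(trees, locus = locus)
}

#' Read one forest per Newick file from a directory
#'
#' @param dir Directory containing `.nwk`/`.tre`/`.trees` files, one locus each.
#' @return Named list of [bootstrap_forest()] objects.
#' @export
read_forest_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(nwk|tre|trees)$", full.names = TRUE)
  if (!length(files)) stop("no Newick forest files found in ", dir)
  forests <- lapply(files, read_forest)
  names(forests) <- vapply(forests, function(f) f$locus, character(1))
  forests
}
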