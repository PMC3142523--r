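# Synthetic counterpart of a multilocus incongruence study: a species tree,
# per-locus gene trees whose discordance grows with genetic position
# (emulating the higher incongruence of highly recombining telomeric loci),
# and per-locus bootstrap forests that are noisy samples around each gene
# tree. Discordance is induced by random rooted NNI moves rather than an
# explicit multispecies coalescent: simpler, dependency-free, and sufficient
# to create the monotone position-discordance coupling the analysis assumes.

#' Simulate a rooted binary species tree
#'
#' Uniform random-join (Yule-type) process: starting from `n_taxa` lineages
#' labeled `t1..tn`, two surviving lineages chosen uniformly at random are
#' joined until one remains. Deterministic for a fixed seed; no branch
#' lengths are attached (all downstream analyses are topological).
#'
#' @param n_taxa Number of leaves, >= 4.
#' @param seed Optional integer seed (dedicated RNG stream).
#' @return A binary `phylo` object.
#' @examples
#' write_newick(simulate_species_tree(6, seed = 1))
#' @export
simulate_species_tree <- function(n_taxa, seed = NULL) {
  if (n_taxa < 4L) stop("n_taxa must be at least 4")
  with_local_seed(seed, {
    parts <- paste0("t", seq_len(n_taxa))
    while (length(parts) > 1L) {
      pick <- sample.int(length(parts), 2L)
      parts <- c(parts[-pick],
                 paste0("(", parts[pick[1L]], ",", parts[pick[2L]], ")"))
    }
    parse_newick(paste0(parts, ";"))
  })
}

# One random rooted nearest-neighbor interchange: pick an internal non-root
# node v with parent u, and swap a random child of v with v's sibling under
# u. Preserves rootedness and binary shape.
rooted_nni <- function(tree) {
  e <- tree$edge
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  internal <- setdiff(unique(e[, 1L]), root)
  if (!length(internal)) return(tree) # star-adjacent degenerate case
  v <- if (length(internal) == 1L) internal else sample(internal, 1L)
  u <- e[e[, 2L] == v, 1L]
  sibs <- e[e[, 1L] == u & e[, 2L] != v, 2L]
  w <- if (length(sibs) == 1L) sibs else sample(sibs, 1L)
  kids <- e[e[, 1L] == v, 2L]
  c1 <- if (length(kids) == 1L) kids else sample(kids, 1L)
  row_w <- which(e[, 1L] == u & e[, 2L] == w)
  row_c1 <- which(e[, 1L] == v & e[, 2L] == c1)
  e[row_w, 2L] <- c1
  e[row_c1, 2L] <- w
  tree$edge <- e
  # renumber nodes to the standard preorder convention; the raw edge swap
  # leaves a numbering that downstream ape C code does not accept
  ape::read.tree(text = ape::write.tree(tree))
}

#' Simulate a gene tree by NNI perturbation of the species tree
#'
#' Applies a Poisson(`mean_moves`) number of random rooted
#' nearest-neighbor-interchange moves to a copy of the species tree. Zero
#' moves returns the species tree unchanged; the expected triplet distance to
#' the species tree increases with `mean_moves`. This stands in for the
#' discordance produced by incomplete lineage sorting and introgression.
#'
#' @param species_tree Binary rooted `phylo`.
#' @param mean_moves Expected number of NNI moves, >= 0.
#' @param seed Optional integer seed.
#' @return A binary `phylo` on the same leaves.
#' @export
simulate_gene_tree <- function(species_tree, mean_moves, seed = NULL) {
  if (mean_moves < 0) stop("mean_moves must be nonnegative")
  with_local_seed(seed, {
    k <- rpois(1L, mean_moves)
    tree <- species_tree
    for (i in seq_len(k)) tree <- rooted_nni(tree)
    tree
  })
}

#' Simulate a bootstrap forest around a gene tree
#'
#' Each replicate is the gene tree itself with probability
#' `1 - noise_rate`, otherwise the gene tree after one random NNI move. With
#' `noise_rate < 0.5` every gene-tree triplet is retained under the strict
#' majority rule with probability approaching 1 as `n_reps` grows.
#'
#' @param gene_tree Binary rooted `phylo`.
#' @param noise_rate Probability in `[0, 1]` that a replicate is perturbed.
#' @param n_reps Number of bootstrap replicates, >= 1 (100 in typical use).
#' @param seed Optional integer seed.
#' @param locus Optional locus id for the forest.
#' @return A [bootstrap_forest()].
#' @export
simulate_bootstrap_forest <- function(gene_tree, noise_rate = 0.1,
                                      n_reps = 100, seed = NULL,
                                      locus = NULL) {
  if (noise_rate < 0 || noise_rate > 1) stop("noise_rate must be in [0, 1]")
  if (n_reps < 1L) stop("n_reps must be at least 1")
  with_local_seed(seed, {
    noisy <- runif(n_reps) < noise_rate
    trees <- lapply(seq_len(n_reps), function(r) {
      if (noisy[r]) rooted_nni(gene_tree) else gene_tree
    })
    bootstrap_forest(trees, locus = locus, leaves = gene_tree$tip.label)
  })
}

#' Configuration for a synthetic incongruence study
#'
#' Defines the shape and strength of a synthetic dataset. The expected
#' number of NNI moves separating the gene tree of a positioned locus from
#' the species tree is position-coupled,
#' \deqn{\lambda(x) = \lambda_0 (1 + \kappa\, g(x)/g(1)),}
#' where g is the arm's genetic-distance map ([genetic_distance()]), so
#' telomeric loci are the most discordant; unpositioned loci use the base
#' rate \eqn{\lambda_0}. Defaults mirror a Triticeae-like study: the 21
#' chromosome-3 locus positions of the packaged annotation table plus 6
#' unpositioned loci, 100-tree forests, and a strong position coupling.
#'
#' @param n_taxa Number of taxa, >= 4; default 20.
#' @param layout Data frame with columns `locus`, `arm`, `x` for positioned
#'   loci; defaults to the 21 packaged chromosome-3 positions.
#' @param n_unpositioned Number of additional unpositioned loci; default 6.
#' @param lambda0 Base discordance rate (expected NNI moves), >= 0; default 1.
#' @param kappa Position-coupling strength, >= 0; default 5. `kappa = 0`
#'   removes any positional signal (the calibration null).
#' @param noise_rate Bootstrap perturbation probability; default 0.1.
#' @param n_reps Bootstrap replicates per locus; default 100.
#' @param model A [chromosome_model()].
#' @param seed Master seed; per-locus streams are derived from it so adding
#'   loci does not perturb existing ones.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_taxa = 20, layout = NULL, n_unpositioned = 6,
                             lambda0 = 1, kappa = 5, noise_rate = 0.1,
                             n_reps = 100, model = chromosome_model(),
                             seed = 1) {
  if (n_taxa < 4L) stop("n_taxa must be at least 4")
  if (lambda0 < 0 || kappa < 0) stop("rates must be nonnegative")
  if (noise_rate < 0 || noise_rate > 1) stop("noise_rate must be in [0, 1]")
  if (is.null(layout)) layout <- default_locus_layout()
  stopifnot(all(c("locus", "arm", "x") %in% names(layout)))
  if (any(layout$x < 0 | layout$x > 1)) stop("layout positions must be in [0, 1]")
  structure(list(n_taxa = as.integer(n_taxa), layout = layout,
                 n_unpositioned = as.integer(n_unpositioned),
                 lambda0 = lambda0, kappa = kappa, noise_rate = noise_rate,
                 n_reps = as.integer(n_reps), model = model,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic study config:", x$n_taxa, "taxa;",
      nrow(x$layout), "positioned +", x$n_unpositioned, "unpositioned loci;",
      x$n_reps, "bootstrap trees/locus\n")
  cat("  lambda0 =", x$lambda0, " kappa =", x$kappa,
      " noise =", x$noise_rate, " seed =", x$seed, "\n")
  invisible(x)
}

# The 21 chromosome-3 locus positions of the packaged annotation table.
default_locus_layout <- function() {
  ann <- read_locus_annotations()
  pos <- !is.na(ann$rel_dist_centromere) & !is.na(ann$arm)
  data.frame(locus = ann$locus[pos], arm = ann$arm[pos],
             x = ann$rel_dist_centromere[pos], stringsAsFactors = FALSE)
}

#' Simulate a full synthetic incongruence study
#'
#' Generates the species tree, one gene tree per locus with
#' position-dependent discordance, and one bootstrap forest per gene tree.
#' Each locus consumes RNG streams seeded from the master seed, so the
#' output is byte-identical for identical configurations.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `synthetic_study`: list with `species_tree`,
#'   `annotations` (locus, arm, x, region, lambda and the derived seeds) and
#'   the named list `forests`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  layout <- config$layout
  n_pos <- nrow(layout)
  n_loci <- n_pos + config$n_unpositioned
  loci <- c(layout$locus,
            if (config$n_unpositioned > 0)
              paste0("unpositioned", seq_len(config$n_unpositioned)))
  arm <- c(layout$arm, rep(NA_character_, config$n_unpositioned))
  x <- c(layout$x, rep(NA_real_, config$n_unpositioned))
  seeds <- with_local_seed(config$seed,
                           sample.int(2147483646L, 1L + 2L * n_loci))
  species_tree <- simulate_species_tree(config$n_taxa, seed = seeds[1L])
  gnorm <- ifelse(is.na(x), 0,
                  genetic_distance(x, arm, config$model) /
                    genetic_distance(1, ifelse(is.na(arm), "long", arm),
                                     config$model))
  lambda <- config$lambda0 * (1 + config$kappa * gnorm)
  forests <- vector("list", n_loci)
  names(forests) <- loci
  for (j in seq_len(n_loci)) {
    gene_seed <- seeds[1L + j]
    forest_seed <- seeds[1L + n_loci + j]
    gt <- simulate_gene_tree(species_tree, lambda[j], seed = gene_seed)
    forests[[j]] <- simulate_bootstrap_forest(
      gt, noise_rate = config$noise_rate, n_reps = config$n_reps,
      seed = forest_seed, locus = loci[j])
  }
  annotations <- data.frame(
    locus = loci, arm = arm, rel_dist_centromere = x,
    region = classify_region(x), lambda = lambda,
    gene_seed = seeds[1L + seq_len(n_loci)],
    forest_seed = seeds[1L + n_loci + seq_len(n_loci)],
    stringsAsFactors = FALSE
  )
  structure(list(species_tree = species_tree, annotations = annotations,
                 forests = forests, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:", length(x$forests), "loci on",
      ape::Ntip(x$species_tree), "taxa (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes the species tree (`species.nwk`), one multi-tree Newick file per
#' forest under `forests/<locus>.trees`, and the annotation table
#' (`annotations.tsv`) in the same dialects the analysis functions consume.
#'
#' @param study A `synthetic_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(file.path(dir, "forests"), showWarnings = FALSE, recursive = TRUE)
  write_newick(study$species_tree, file.path(dir, "species.nwk"))
  for (nm in names(study$forests)) {
    writeLines(vapply(study$forests[[nm]]$trees, ape::write.tree, character(1)),
               file.path(dir, "forests", paste0(nm, ".trees")))
  }
  utils::write.table(study$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
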