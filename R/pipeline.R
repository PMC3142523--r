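#' Summary statistics and audits over a locus-annotation table
#'
#' Recomputes the study-level descriptive statistics carried by a locus
#' annotation table: total concatenated alignment length, mean/SD/range of
#' the per-locus triplet distances to each multigenic tree, Spearman
#' correlations of those distances with evolutionary rate, gamma shape and
#' alignment length, and an audit of the centromeric/telomeric labels
#' against the 70%-of-arm rule.
#'
#' @param annotations Annotation data frame ([read_locus_annotations()]) or a
#'   path to one; defaults to the packaged Triticeae table.
#' @return List of class `annotations_report` with components
#'   `total_alignment_bp`, `n_loci`, `n_positioned`, `n_unpositioned`,
#'   `td_supermatrix`/`td_bucky` ([column_summary()] lists), `correlations`
#'   (data frame of Spearman rho/p per parameter and tree) and
#'   `region_audit` (per-locus printed vs computed labels plus the agreement
#'   count).
#' @export
run_annotations_analysis <- function(annotations = NULL) {
  if (is.null(annotations) || is.character(annotations))
    annotations <- read_locus_annotations(annotations)
  ann <- annotations
  need <- c("locus", "length_bp", "rel_dist_centromere", "region",
            "evo_rate", "alpha", "td_supermatrix", "td_bucky")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation table is missing column(s): ", paste(miss, collapse = ", "))
  positioned <- !is.na(ann$rel_dist_centromere)
  cors <- do.call(rbind, lapply(c("evo_rate", "alpha", "length_bp"),
    function(par) {
      xs <- if (par == "length_bp") ann$length_bp else ann[[par]]
      do.call(rbind, lapply(c("td_supermatrix", "td_bucky"), function(td) {
        ct <- spearman_correlation(xs, ann[[td]])
        data.frame(parameter = par, tree = sub("^td_", "", td),
                   rho = ct$rho, p.value = ct$p.value, n = ct$n,
                   stringsAsFactors = FALSE)
      }))
    }))
  audit <- data.frame(
    locus = ann$locus[positioned],
    rel_dist_centromere = ann$rel_dist_centromere[positioned],
    printed = ann$region[positioned],
    computed = classify_region(ann$rel_dist_centromere[positioned]),
    stringsAsFactors = FALSE
  )
  audit$agree <- audit$printed == audit$computed
  structure(list(
    total_alignment_bp = sum(ann$length_bp),
    n_loci = nrow(ann),
    n_positioned = sum(positioned),
    n_unpositioned = sum(!positioned),
    td_supermatrix = column_summary(ann$td_supermatrix),
    td_bucky = column_summary(ann$td_bucky),
    correlations = cors,
    region_audit = audit
  ), class = "annotations_report")
}

#' @export
print.annotations_report <- function(x, ...) {
  cat("Locus annotation report:", x$n_loci, "loci (",
      x$n_positioned, "positioned,", x$n_unpositioned, "unpositioned ),",
      x$total_alignment_bp, "bp total\n")
  s <- x$td_supermatrix; b <- x$td_bucky
  cat(sprintf("  TD supermatrix: %.2f +/- %.2f (%.2f-%.2f)\n",
              s$mean, s$sd, s$min, s$max))
  cat(sprintf("  TD BUCKy:       %.2f +/- %.2f (%.2f-%.2f)\n",
              b$mean, b$sd, b$min, b$max))
  cat("  region audit:", sum(x$region_audit$agree), "/",
      nrow(x$region_audit), "labels agree with the 70% rule\n")
  invisible(x)
}

#' Run the full incongruence analysis on a synthetic study
#'
#' End-to-end composition of the pipeline on simulated data: per-locus
#' triplet distances between the species tree and each bootstrap forest, the
#' pairwise forest distance matrix over positioned loci, strongly rejected
#' triplets with per-taxon counts, the genetic-distance map, the within-arm
#' median-difference and matrix-correlation permutation tests, and the
#' quadratic regression of distance on signed genetic position. Every
#' random stage consumes seeds derived from the configuration's master seed,
#' so the report is reproducible from the provenance record alone.
#'
#' @param config A [synthetic_config()]; alternatively a ready
#'   `synthetic_study` from [simulate_study()].
#' @param threshold Triplet retention threshold; default 0.5.
#' @param confidence Chi-squared confidence for strong rejection; default 0.9.
#' @param reps Permutation replicates; default 10,000.
#' @param out_dir Optional directory to which TSV report files are written.
#' @return List of class `analysis_report` with components `per_locus`
#'   (locus table with distances and positions), `matrix` (pairwise triplet
#'   distances), `genetic_matrix`, `rejected`, `per_taxon`,
#'   `median_test`, `correlation_test`, `quadratic` and `provenance`.
#' @export
run_full_analysis <- function(config = synthetic_config(), threshold = 0.5,
                              confidence = 0.9, reps = 10000,
                              out_dir = NULL) {
  study <- if (inherits(config, "synthetic_study")) config
           else simulate_study(config)
  cfg <- study$config
  ann <- study$annotations
  test_seeds <- with_local_seed(cfg$seed + 1L, sample.int(2147483646L, 2L))

  per_locus <- ann
  cmp <- lapply(study$forests, tree_forest_distance,
                tree = study$species_tree, threshold = threshold)
  per_locus$distance <- vapply(cmp, `[[`, numeric(1), "distance")
  per_locus$n_retained <- vapply(cmp, `[[`, integer(1), "n_retained")
  per_locus$signed_cM <- signed_coordinate(per_locus$rel_dist_centromere,
                                           per_locus$arm, cfg$model)

  positioned <- !is.na(ann$rel_dist_centromere)
  M <- pairwise_matrix(study$forests[positioned], threshold = threshold)
  G <- pairwise_genetic_distance(
    data.frame(locus = ann$locus[positioned], arm = ann$arm[positioned],
               rel_dist_centromere = ann$rel_dist_centromere[positioned],
               stringsAsFactors = FALSE),
    model = cfg$model)

  rejected <- strongly_rejected_triplets(study$species_tree, study$forests,
                                         confidence = confidence)
  taxon_counts <- per_taxon_counts(rejected)

  med <- median_difference_test(M, region = per_locus$region[positioned],
                                arm = per_locus$arm[positioned],
                                reps = reps, seed = test_seeds[1L])
  corr <- matrix_correlation_test(M,
                                  coord = per_locus$signed_cM[positioned],
                                  arm = per_locus$arm[positioned],
                                  reps = reps, seed = test_seeds[2L])
  quad <- quadratic_fit(per_locus$signed_cM[positioned],
                        per_locus$distance[positioned])

  report <- structure(list(
    per_locus = per_locus, matrix = M, genetic_matrix = G,
    rejected = rejected, per_taxon = taxon_counts,
    median_test = med, correlation_test = corr, quadratic = quad,
    provenance = list(config = cfg, threshold = threshold,
                      confidence = confidence, reps = reps,
                      test_seeds = test_seeds,
                      package_version = as.character(utils::packageVersion("tripdist")))
  ), class = "analysis_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Incongruence analysis report\n")
  cat(sprintf("  mean tree-forest distance: %.3f over %d loci\n",
              mean(x$per_locus$distance, na.rm = TRUE), nrow(x$per_locus)))
  cat(sprintf("  strongly rejected triplets: %d (top taxon: %s, %d)\n",
              sum(x$rejected$rejected), x$per_taxon$taxon[1L],
              x$per_taxon$count[1L]))
  cat(sprintf("  telomeric - centromeric median: %.3f (p = %.4g)\n",
              x$median_test$statistic, x$median_test$p.value))
  cat(sprintf("  genetic/triplet matrix correlation: %.3f (p = %.4g)\n",
              x$correlation_test$statistic, x$correlation_test$p.value))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(report$per_locus, "per_locus.tsv")
  utils::write.table(report$matrix, file.path(out_dir, "triplet_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(report$genetic_matrix,
                     file.path(out_dir, "genetic_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  wt(as.data.frame(report$rejected), "rejected_triplets.tsv")
  wt(report$per_taxon, "per_taxon_counts.tsv")
  prov <- report$provenance
  summary_lines <- c(
    paste0("seed\t", prov$config$seed),
    paste0("threshold\t", prov$threshold),
    paste0("confidence\t", prov$confidence),
    paste0("reps\t", prov$reps),
    paste0("median_difference\t", report$median_test$statistic),
    paste0("median_p\t", report$median_test$p.value),
    paste0("matrix_rho\t", report$correlation_test$statistic),
    paste0("matrix_p\t", report$correlation_test$p.value)
  )
  writeLines(summary_lines, file.path(out_dir, "summary.tsv"))
  invisible(out_dir)
}
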