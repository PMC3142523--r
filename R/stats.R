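#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average ranks (ties allowed), with the p-value from
#' the t-approximation on n - 2 degrees of freedom. For the sample sizes of
#' multilocus studies (n around 20-30) the t-approximation is standard; an
#' exact permutation p-value is available for small n.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exact Compute the exact permutation p-value (only allowed for
#'   n <= 10).
#' @return List with `rho`, `p.value`, `n` and `alternative`.
#' @export
spearman_correlation <- function(x, y,
                                 alternative = c("two.sided", "greater", "less"),
                                 exact = FALSE) {
  alternative <- match.arg(alternative)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L || length(y) != n) stop("need equal-length vectors with n >= 4")
  if (sd(x) == 0 || sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  rho <- cor(x, y, method = "spearman")
  if (exact) {
    if (n > 10L) stop("exact permutation p-value restricted to n <= 10")
    perms <- permutations_of(n)
    rx <- rank(x)
    null <- apply(perms, 1L, function(p) cor(rx, rank(y)[p]))
    p <- switch(alternative,
                greater = mean(null >= rho - 1e-12),
                less = mean(null <= rho + 1e-12),
                two.sided = mean(abs(null) >= abs(rho) - 1e-12))
  } else {
    tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- switch(alternative,
                greater = pt(tval, df = n - 2, lower.tail = FALSE),
                less = pt(tval, df = n - 2),
                two.sided = 2 * pt(-abs(tval), df = n - 2))
  }
  list(rho = rho, p.value = min(p, 1), n = n, alternative = alternative)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Quadratic least-squares fit of incongruence on genetic position
#'
#' Ordinary least squares of a response (typically the per-locus triplet
#' distance to a multigenic tree) on the signed genetic coordinate and its
#' square. A U-shaped fit (positive quadratic coefficient) indicates higher
#' incongruence towards both telomeres.
#'
#' @param position Signed genetic coordinates (cM).
#' @param value Response values; same length, n >= 4.
#' @return List of class `quadratic_fit` with `coefficients` (named
#'   `intercept`, `linear`, `quadratic`), `sigma2` (residual variance), `n`
#'   and the underlying `lm` fit.
#' @export
quadratic_fit <- function(position, value) {
  ok <- !is.na(position) & !is.na(value)
  position <- position[ok]; value <- value[ok]
  n <- length(position)
  if (n < 4L) stop("need at least 4 complete observations")
  if (length(unique(position)) < 3L)
    stop("design is rank deficient: fewer than 3 distinct positions")
  fit <- lm(value ~ position + I(position^2))
  cf <- stats::setNames(stats::coef(fit), c("intercept", "linear", "quadratic"))
  structure(list(coefficients = cf,
                 sigma2 = sum(stats::residuals(fit)^2) / fit$df.residual,
                 n = n, fit = fit),
            class = "quadratic_fit")
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat("Quadratic fit (n =", x$n, "):\n")
  print(round(x$coefficients, 6))
  invisible(x)
}

empirical_p <- function(null, observed, tail) {
  b <- switch(tail,
              greater = sum(null >= observed - 1e-12),
              less = sum(null <= observed + 1e-12),
              two.sided = sum(abs(null) >= abs(observed) - 1e-12))
  (1 + b) / (1 + length(null)) # add-one convention: p in (0, 1], never 0
}

new_permutation_result <- function(statistic, null, reps, tail, seed, scheme) {
  structure(
    list(statistic = statistic, p.value = empirical_p(null, statistic, tail),
         reps = reps, tail = tail, seed = seed, scheme = scheme,
         null_quantiles = quantile(null, c(0.025, 0.5, 0.975), na.rm = TRUE)),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test (", x$scheme, ")\n", sep = "")
  cat("  observed =", format(x$statistic, digits = 4),
      "  p =", format(x$p.value, digits = 4),
      "(", x$tail, ",", x$reps, "replicates )\n")
  invisible(x)
}

# Pairs (i, j), i < j, of loci on the same arm, with the matrix value.
same_arm_pairs <- function(M, arm) {
  n <- nrow(M)
  ij <- which(upper.tri(M), arr.ind = TRUE)
  keep <- !is.na(arm[ij[, 1L]]) & arm[ij[, 1L]] == arm[ij[, 2L]]
  list(i = ij[keep, 1L], j = ij[keep, 2L], value = M[ij][keep])
}

median_diff_stat <- function(pairs, region) {
  both_tel <- region[pairs$i] == "telomeric" & region[pairs$j] == "telomeric"
  both_cen <- region[pairs$i] == "centromeric" & region[pairs$j] == "centromeric"
  median(pairs$value[both_tel]) - median(pairs$value[both_cen])
}

#' Within-arm permutation test for the telomere/centromere median difference
#'
#' Observed statistic: median of the pairwise triplet distances between
#' telomeric loci minus the median between centromeric loci, using only pairs
#' of loci on the *same* chromosome arm (cross-arm pairs never enter). The
#' null distribution is built by permuting the region labels among the loci
#' within each arm and recomputing the pair groupings each replicate, so a
#' locus can never be relabeled onto the other arm.
#'
#' @param M Symmetric pairwise triplet-distance matrix with loci as dimnames.
#' @param region Character vector (`"centromeric"`/`"telomeric"`) aligned
#'   with the rows of `M`.
#' @param arm Character vector (`"short"`/`"long"`) aligned with the rows of
#'   `M`.
#' @param reps Number of permutation replicates; default 10,000.
#' @param seed Optional seed for the dedicated RNG stream.
#' @param alternative `"greater"` (default; telomeric exceeds centromeric) or
#'   `"two.sided"`.
#' @return A `permutation_result` with the observed statistic, empirical
#'   p-value ((1 + b) / (1 + reps)), tail, seed and scheme tag.
#' @export
median_difference_test <- function(M, region, arm, reps = 10000, seed = NULL,
                                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(nrow(M) == ncol(M), length(region) == nrow(M),
            length(arm) == nrow(M))
  pairs <- same_arm_pairs(M, arm)
  both_tel <- sum(region[pairs$i] == "telomeric" &
                  region[pairs$j] == "telomeric")
  both_cen <- sum(region[pairs$i] == "centromeric" &
                  region[pairs$j] == "centromeric")
  if (both_tel < 2L || both_cen < 2L)
    stop("need at least 2 same-arm pairs in each region group ",
         "(telomeric: ", both_tel, ", centromeric: ", both_cen, ")")
  observed <- median_diff_stat(pairs, region)
  arm_groups <- split(seq_along(arm), arm)
  null <- with_local_seed(seed, vapply(seq_len(reps), function(r) {
    perm <- region
    for (g in arm_groups) perm[g] <- perm[sample(g)]
    median_diff_stat(pairs, perm)
  }, numeric(1)))
  new_permutation_result(observed, null, reps, alternative, seed,
                         scheme = "within-arm region relabeling")
}

#' Within-arm permutation test for the genetic/triplet distance correlation
#'
#' Correlates the upper triangles of the pairwise triplet-distance matrix M
#' and the pairwise genetic-distance matrix implied by the loci's signed
#' coordinates. Significance is assessed by permuting the locus coordinates
#' within each chromosome arm (never across arms), recomputing the genetic
#' distance matrix each replicate while M stays fixed.
#'
#' @param M Symmetric pairwise triplet-distance matrix.
#' @param coord Signed genetic coordinates (cM) aligned with the rows of `M`
#'   (e.g. from [signed_coordinate()] or the `"signed_coordinate"` attribute
#'   of [pairwise_genetic_distance()]).
#' @param arm Character vector (`"short"`/`"long"`) aligned with the rows.
#' @param reps Number of permutation replicates; default 10,000.
#' @param seed Optional seed.
#' @param method `"spearman"` (default) or `"pearson"` for the triangle
#'   correlation.
#' @param alternative `"greater"` (default; positive association) or
#'   `"two.sided"`.
#' @return A `permutation_result`; the observed statistic is the triangle
#'   correlation.
#' @export
matrix_correlation_test <- function(M, coord, arm, reps = 10000, seed = NULL,
                                    method = c("spearman", "pearson"),
                                    alternative = c("greater", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  n <- nrow(M)
  stopifnot(ncol(M) == n, length(coord) == n, length(arm) == n)
  ut <- upper.tri(M)
  m_vec <- M[ut]
  stat_for <- function(s) {
    G <- abs(outer(s, s, "-"))
    ok <- !is.na(m_vec)
    cor(G[ut][ok], m_vec[ok], method = method)
  }
  observed <- stat_for(coord)
  arm_groups <- split(seq_along(arm), arm)
  null <- with_local_seed(seed, vapply(seq_len(reps), function(r) {
    s <- coord
    for (g in arm_groups) s[g] <- s[sample(g)]
    stat_for(s)
  }, numeric(1)))
  new_permutation_result(observed, null, reps, alternative, seed,
                         scheme = "within-arm coordinate permutation")
}

#' Column summary: mean, SD, extremes
#'
#' Arithmetic mean, sample (n-1) standard deviation and range, with an
#' optional rounding to the precision at which such summaries are usually
#' printed.
#'
#' @param values Numeric vector, n >= 2 after dropping `NA`.
#' @param digits Optional rounding digits applied to all four summaries.
#' @return List with `mean`, `sd`, `min`, `max`, `n`.
#' @export
column_summary <- function(values, digits = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 non-missing values")
  out <- list(mean = mean(values), sd = sd(values),
              min = min(values), max = max(values), n = length(values))
  if (!is.null(digits))
    out[c("mean", "sd", "min", "max")] <-
      lapply(out[c("mean", "sd", "min", "max")], round, digits = digits)
  out
}
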