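test_that("spearman correlation matches a rank-then-Pearson oracle", {
  expect_equal(spearman_correlation(1:10, (1:10)^3)$rho, 1)

  set.seed(15)
  for (r in 1:10) {
    x <- sample(1:5, 12, replace = TRUE) # duplicates force average ranks
    y <- x + sample(1:4, 12, replace = TRUE)
    got <- spearman_correlation(x, y)
    expect_equal(got$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
    tv <- got$rho * sqrt(10 / (1 - got$rho^2))
    expect_equal(got$p.value, 2 * pt(-abs(tv), df = 10), tolerance = 1e-12)
  }

  expect_error(spearman_correlation(rep(1, 6), 1:6), "constant")
  expect_error(spearman_correlation(1:3, 3:1), "n >= 4")
})

test_that("exact spearman p enumerates all permutations for small n", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  got <- spearman_correlation(x, y, alternative = "greater", exact = TRUE)
  # oracle: full enumeration of the 120 rank permutations
  rec <- function(avail, acc) {
    if (!length(avail)) { enum[[length(enum) + 1L]] <<- acc; return() }
    for (k in avail) rec(setdiff(avail, k), c(acc, k))
  }
  enum <- list(); rec(1:5, integer(0))
  null <- vapply(enum, function(p) cor(rank(x), rank(y)[p]), numeric(1))
  expect_equal(got$p.value, mean(null >= got$rho - 1e-12))
  expect_error(spearman_correlation(1:12, 12:1, exact = TRUE), "n <= 10")
})

test_that("quadratic fit recovers exact polynomials and matches normal equations", {
  g <- seq(-40, 60, length.out = 12)
  y <- 0.3 - 0.002 * g + 0.0004 * g^2
  fit <- quadratic_fit(g, y)
  expect_equal(unname(fit$coefficients), c(0.3, -0.002, 0.0004),
               tolerance = 1e-10)
  expect_lt(fit$sigma2, 1e-20)

  # U-shaped symmetric data: positive quadratic coefficient
  yu <- abs(g) + rnorm(12, sd = 1e-6)
  expect_gt(quadratic_fit(g, yu)$coefficients[["quadratic"]], 0)

  # constant response: linear and quadratic coefficients are 0
  fc <- quadratic_fit(g, rep(0.4, 12))
  expect_equal(unname(fc$coefficients), c(0.4, 0, 0), tolerance = 1e-12)

  # brute-force normal-equation oracle
  set.seed(8)
  yn <- 0.2 + 0.01 * g - 3e-4 * g^2 + rnorm(12, sd = 0.05)
  X <- cbind(1, g, g^2)
  beta <- solve(t(X) %*% X, t(X) %*% yn)
  expect_equal(unname(quadratic_fit(g, yn)$coefficients), c(beta),
               tolerance = 1e-8)

  expect_error(quadratic_fit(rep(1, 6), 1:6), "rank deficient")
})

test_that("column_summary gives mean, n-1 SD and extremes", {
  v <- c(0.1, 0.2, 0.4)
  s <- column_summary(v)
  expect_equal(s$mean, mean(v))
  expect_equal(s$sd, sd(v))
  expect_equal(c(s$min, s$max), c(0.1, 0.4))
  expect_equal(column_summary(rep(0.3, 5))$sd, 0)
  expect_equal(column_summary(c(0.214, 0.305), digits = 2)$mean, 0.26)
})

toy_matrix <- function(values, n) {
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- values
  M + t(M)
}

test_that("median difference test agrees with exhaustive permutation", {
  # 6 loci on one arm, 3 telomeric / 3 centromeric: the within-arm scheme
  # reduces to an unrestricted relabeling with choose(6,3) = 20 outcomes
  set.seed(101)
  n <- 6L
  M <- toy_matrix(runif(choose(n, 2)), n)
  arm <- rep("long", n)
  region <- rep(c("telomeric", "centromeric"), each = 3)

  pairs_ij <- which(upper.tri(M), arr.ind = TRUE)
  stat_for <- function(reg) {
    tt <- reg[pairs_ij[, 1]] == "telomeric" & reg[pairs_ij[, 2]] == "telomeric"
    cc <- reg[pairs_ij[, 1]] == "centromeric" & reg[pairs_ij[, 2]] == "centromeric"
    median(M[pairs_ij][tt]) - median(M[pairs_ij][cc])
  }
  obs <- stat_for(region)
  tel_sets <- utils::combn(n, 3)
  null_exact <- apply(tel_sets, 2, function(tel) {
    reg <- rep("centromeric", n); reg[tel] <- "telomeric"
    stat_for(reg)
  })
  p_exact <- mean(null_exact >= obs - 1e-12)

  ps <- vapply(1:20, function(s)
    median_difference_test(M, region, arm, reps = 400, seed = s)$p.value,
    numeric(1))
  mc_err <- 3 * sqrt(p_exact * (1 - p_exact) / 400) + 1 / 400
  expect_true(all(abs(ps - p_exact) <= mc_err + 0.01))
  expect_equal(median_difference_test(M, region, arm, reps = 50,
                                      seed = 4)$statistic, obs)
})

test_that("median difference test validates group sizes and is seeded", {
  n <- 8L
  M <- toy_matrix(runif(choose(n, 2)), n)
  arm <- rep(c("short", "long"), each = 4)
  region <- rep(c("telomeric", "centromeric"), 4)
  # one telomeric locus per arm -> no within-arm telomeric pairs
  expect_error(
    median_difference_test(M, rep(c("telomeric", rep("centromeric", 3)), 2),
                           arm, reps = 10),
    "at least 2")
  region2 <- c(rep("telomeric", 2), rep("centromeric", 2),
               rep("telomeric", 2), rep("centromeric", 2))
  r1 <- median_difference_test(M, region2, arm, reps = 100, seed = 7)
  r2 <- median_difference_test(M, region2, arm, reps = 100, seed = 7)
  expect_identical(r1$p.value, r2$p.value)
  expect_gt(r1$p.value, 0)
  expect_lte(r1$p.value, 1)
})

test_that("p-values under an exchangeable null center near 0.5", {
  n <- 10L
  arm <- rep(c("short", "long"), each = 5)
  region <- rep(c("telomeric", "telomeric", "centromeric", "centromeric",
                  "centromeric"), 2)
  ps <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    M <- toy_matrix(runif(choose(n, 2)), n)
    median_difference_test(M, region, arm, reps = 200, seed = s)$p.value
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("matrix correlation test detects a perfect association", {
  ann <- read_locus_annotations()
  chr3 <- ann[!is.na(ann$rel_dist_centromere), ]
  coord <- signed_coordinate(chr3$rel_dist_centromere, chr3$arm,
                             chromosome_model())
  G <- abs(outer(coord, coord, "-"))
  res <- matrix_correlation_test(G, coord, chr3$arm, reps = 99, seed = 2)
  expect_equal(res$statistic, 1)
  expect_equal(res$p.value, 1 / 100) # no permutation reproduces G exactly
})

test_that("matrix correlation test finds distance-decaying similarity", {
  set.seed(55)
  n <- 12L
  arm <- rep(c("short", "long"), each = 6)
  coord <- c(-sort(runif(6, 1, 50), decreasing = TRUE), sort(runif(6, 1, 50)))
  G <- abs(outer(coord, coord, "-"))
  M <- G / max(G) + matrix(rnorm(n * n, sd = 0.02), n, n)
  M <- (M + t(M)) / 2; diag(M) <- 0
  res <- matrix_correlation_test(M, coord, arm, reps = 500, seed = 9)
  expect_gt(res$statistic, 0.8)
  expect_lt(res$p.value, 0.05)
  expect_error(matrix_correlation_test(M, coord[-1], arm, reps = 10),
               "length")
})
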