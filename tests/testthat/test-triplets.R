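make_forest <- function(...) {
  specs <- list(...)
  trees <- unlist(lapply(specs, function(s)
    rep(list(parse_newick(s$newick)), s$n)), recursive = FALSE)
  bootstrap_forest(trees)
}

test_that("extract_triplets matches hand-derived resolutions", {
  expect_equal(extract_triplets(parse_newick("((a,b),c);"))$resolution,
               "a,b|c")
  tt <- extract_triplets(parse_newick("((a,b),(c,d));"))
  expect_equal(tt$resolution, c("a,b|c", "a,b|d", "c,d|a", "c,d|b"))
  star <- extract_triplets(parse_newick("(a,b,c);"))
  expect_true(is.na(star$resolution))
  expect_error(extract_triplets(parse_newick("(a,b);")), "fewer than 3")
})

test_that("binary trees yield choose(n,3) resolved triplets", {
  set.seed(5)
  for (n in c(5, 9)) {
    tree <- random_rooted_tree(paste0("s", 1:n))
    tt <- extract_triplets(tree)
    expect_equal(nrow(tt), choose(n, 3))
    expect_false(anyNA(tt$resolution))
  }
})

test_that("count_forest_triplets tallies resolutions, unresolved and absent", {
  tree <- parse_newick("((a,b),(c,d));")
  f <- bootstrap_forest(rep(list(tree), 100))
  tf <- count_forest_triplets(f)
  expect_equal(unname(rowSums(tf$counts)), rep(100L, 4L))
  expect_equal(max(tf$counts[, 1:3]), 100L) # every triplet of T has count 100
  expect_equal(sum(tf$counts[, 1:3] == 100L), 4L)

  f2 <- make_forest(list(newick = "((a,b),c);", n = 1),
                    list(newick = "((a,c),b);", n = 1))
  tf2 <- count_forest_triplets(f2)
  expect_equal(sort(unname(tf2$counts[1, 1:3][tf2$counts[1, 1:3] > 0])), c(1L, 1L))

  f3 <- bootstrap_forest(list(parse_newick("(a,b,c);"),
                              parse_newick("((a,b),c);")))
  tf3 <- count_forest_triplets(f3)
  expect_equal(unname(tf3$counts[1, "unresolved"]), 1L)
  expect_equal(sum(tf3$counts[1, 1:3]), 1L)

  # leaves missing from a member tree count as absent for that tree
  f4 <- bootstrap_forest(list(parse_newick("((a,b),c);"),
                              parse_newick("((a,b),(c,d));")))
  tf4 <- count_forest_triplets(f4)
  has_d <- apply(tf4$triplets, 1L, function(k) "d" %in% tf4$labels[k])
  expect_true(all(tf4$counts[has_d, "absent"] == 1L))
})

test_that("retention uses a strict majority and keeps one resolution", {
  f <- make_forest(list(newick = "((a,b),c);", n = 51),
                   list(newick = "((a,c),b);", n = 49))
  expect_equal(retained_triplets(count_forest_triplets(f))$resolution, "a,b|c")

  f50 <- make_forest(list(newick = "((a,b),c);", n = 50),
                     list(newick = "((a,c),b);", n = 50))
  expect_equal(nrow(retained_triplets(count_forest_triplets(f50))), 0L)

  # threshold 0.6: 55/100 dropped, 61/100 retained
  f55 <- make_forest(list(newick = "((a,b),c);", n = 55),
                     list(newick = "((a,c),b);", n = 45))
  expect_equal(nrow(retained_triplets(count_forest_triplets(f55), 0.6)), 0L)
  f61 <- make_forest(list(newick = "((a,b),c);", n = 61),
                     list(newick = "((a,c),b);", n = 39))
  expect_equal(retained_triplets(count_forest_triplets(f61), 0.6)$resolution,
               "a,b|c")
  # exactly 60/100 at threshold 0.6 is dropped (strict >)
  f60 <- make_forest(list(newick = "((a,b),c);", n = 60),
                     list(newick = "((a,c),b);", n = 40))
  expect_equal(nrow(retained_triplets(count_forest_triplets(f60), 0.6)), 0L)

  expect_error(retained_triplets(count_forest_triplets(f), 0.4), "0.5")
})

test_that("retention never returns two resolutions for one leaf set", {
  set.seed(11)
  labels <- paste0("x", 1:6)
  for (r in 1:20) {
    trees <- replicate(9, random_rooted_tree(labels), simplify = FALSE)
    ret <- retained_triplets(count_forest_triplets(bootstrap_forest(trees)))
    key <- paste(ret$leaf1, ret$leaf2, ret$leaf3)
    expect_equal(anyDuplicated(key), 0L)
  }
})

test_that("tree_forest_distance matches hand-worked cases", {
  ts <- parse_newick("((a,b),(c,d));")
  f_same <- bootstrap_forest(rep(list(ts), 100))
  expect_equal(tree_forest_distance(ts, f_same)$distance, 0)

  f_conf <- bootstrap_forest(rep(list(parse_newick("((a,c),(b,d));")), 100))
  d <- tree_forest_distance(ts, f_conf)
  expect_equal(d$distance, 1.0)
  expect_equal(d$n_retained, 4L)

  f_mix <- make_forest(list(newick = "((a,b),(c,d));", n = 60),
                       list(newick = "((a,c),(b,d));", n = 40))
  expect_equal(tree_forest_distance(ts, f_mix)$distance, 0)
})

test_that("undefined distances are signaled, not silently zero", {
  ts <- parse_newick("((a,b),c);")
  f <- make_forest(list(newick = "((a,b),c);", n = 1),
                   list(newick = "((a,c),b);", n = 1)) # no majority
  expect_warning(d <- tree_forest_distance(ts, f), "undefined")
  expect_false(d$defined)
  expect_true(is.na(d$distance))
})

test_that("a non-binary reference tree is rejected with advice", {
  star <- parse_newick("(a,b,c);")
  f <- bootstrap_forest(rep(list(parse_newick("((a,b),c);")), 10))
  expect_error(tree_forest_distance(star, f), "resolve_polytomies_randomly")
})

test_that("forest_forest_distance is symmetric and matches hand cases", {
  f1 <- bootstrap_forest(rep(list(parse_newick("((a,b),(c,d));")), 100))
  f2 <- bootstrap_forest(rep(list(parse_newick("((a,c),(b,d));")), 100))
  expect_equal(forest_forest_distance(f1, f1)$distance, 0)
  expect_equal(forest_forest_distance(f1, f2)$distance, 1.0)

  set.seed(21)
  labels <- paste0("x", 1:6)
  fa <- bootstrap_forest(replicate(7, random_rooted_tree(labels),
                                   simplify = FALSE))
  fb <- bootstrap_forest(replicate(7, random_rooted_tree(labels),
                                   simplify = FALSE))
  dab <- forest_forest_distance(fa, fb)
  dba <- forest_forest_distance(fb, fa)
  expect_equal(dab$distance, dba$distance)
  expect_equal(dab$n_retained, dba$n_retained)
})

test_that("contamination distance is non-increasing and hits 0 past 50%", {
  ts <- parse_newick("((a,b),(c,d));")
  conf <- parse_newick("((a,c),(b,d));")
  dist_k <- vapply(c(10, 30, 49, 51, 70, 100), function(k) {
    f <- bootstrap_forest(c(rep(list(ts), k), rep(list(conf), 100 - k)))
    tree_forest_distance(ts, f)$distance
  }, numeric(1))
  expect_true(all(diff(dist_k) <= 0))
  expect_equal(dist_k[3], 1) # conflicting tree still holds the majority at 49
  expect_equal(dist_k[4:6], c(0, 0, 0)) # k > 50 forces agreement
  expect_equal(dist_k[1], 1) # k = 10: conflicting tree holds the majority
})

test_that("thresholds 0.5 and 0.6 agree when support exceeds 60%", {
  set.seed(33)
  labels <- paste0("x", 1:6)
  base <- random_rooted_tree(labels)
  alt <- random_rooted_tree(labels)
  f <- bootstrap_forest(c(rep(list(base), 70), rep(list(alt), 30)))
  tf <- count_forest_triplets(f)
  counts <- tf$counts[, 1:3]
  best <- counts[cbind(seq_len(nrow(counts)), max.col(counts))]
  expect_true(all(best > 60)) # 70 copies of the base tree guarantee this
  ref <- random_rooted_tree(labels)
  d5 <- tree_forest_distance(ref, f, threshold = 0.5)
  d6 <- tree_forest_distance(ref, f, threshold = 0.6)
  expect_equal(d5$distance, d6$distance)
  expect_equal(d5$n_retained, d6$n_retained)
})

test_that("pairwise_matrix composes forest distances symmetrically", {
  A <- bootstrap_forest(rep(list(parse_newick("((a,b),(c,d));")), 10))
  B <- bootstrap_forest(rep(list(parse_newick("((a,c),(b,d));")), 10))
  M <- pairwise_matrix(list(a1 = A, a2 = A, b = B))
  expect_equal(unname(M),
               matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3),
               ignore_attr = TRUE)
  expect_equal(rownames(M), c("a1", "a2", "b"))

  M0 <- pairwise_matrix(list(A, A, A))
  expect_true(all(M0 == 0))
  expect_error(pairwise_matrix(list(A)), "at least 2")
})

test_that("a 21-forest matrix has the right shape and symmetry", {
  set.seed(9)
  labels <- paste0("x", 1:6)
  forests <- lapply(1:21, function(i) {
    tree <- random_rooted_tree(labels)
    bootstrap_forest(rep(list(tree), 5), locus = paste0("L", i))
  })
  M <- pairwise_matrix(forests)
  expect_equal(dim(M), c(21L, 21L))
  expect_true(isSymmetric(unname(M)))
  expect_true(all(diag(M) == 0))
  expect_equal(sum(upper.tri(M)), 210L)
})
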