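blob_matrix <- function() {
  # two well-separated profile shapes, 3 rows each, mild noise
  set.seed(77)
  up <- c(1, 2, 3, 4, 5, 6, 7, 8)
  down <- rev(up)
  m <- rbind(up + rnorm(8, 0, 0.05), up + rnorm(8, 0, 0.05),
             up + rnorm(8, 0, 0.05), down + rnorm(8, 0, 0.05),
             down + rnorm(8, 0, 0.05), down + rnorm(8, 0, 0.05))
  rownames(m) <- sprintf("L%d", 1:6)
  m
}

test_that("correlation distance spans [0, 2] with the documented conventions", {
  x <- c(1, 5, 2, 8, 3)
  expect_equal(correlation_distance(x, x), 0)
  expect_equal(correlation_distance(x, -x + 10), 2)
  expect_warning(d <- correlation_distance(x, rep(1, 5)), "zero-variance")
  expect_equal(d, 1)

  # direct covariance-formula oracle on random vectors
  set.seed(17)
  for (rep in 1:20) {
    a <- rnorm(50); b <- rnorm(50)
    r <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(correlation_distance(a, b), 1 - r, tolerance = 1e-12)
  }
})

test_that("kmeans_profiles handles the forced partitions k = 1 and k = n", {
  m <- blob_matrix()
  one <- kmeans_profiles(m, 1)
  expect_equal(unname(one$sizes), 6L)
  all_own <- kmeans_profiles(m, 6)
  expect_equal(sort(unname(all_own$sizes)), rep(1L, 6))
  expect_error(kmeans_profiles(m, 7), "exceeds")
})

test_that("kmeans recovers two separated blobs like the exhaustive oracle", {
  m <- blob_matrix()
  got <- kmeans_profiles(m, 2)
  want <- oracle_kmeans2(m)
  split_got <- list(which(got$labels == got$labels[1]),
                    which(got$labels != got$labels[1]))
  split_want <- list(sort(want$a), sort(want$b))
  expect_true(
    (identical(unname(split_got[[1]]), split_want[[1]]) &&
       identical(unname(split_got[[2]]), split_want[[2]])) ||
      (identical(unname(split_got[[1]]), split_want[[2]]) &&
         identical(unname(split_got[[2]]), split_want[[1]])))
})

test_that("the kmeans objective never increases across iterations", {
  set.seed(23)
  for (rep in 1:10) {
    m <- matrix(rnorm(30 * 12), 30, 12)
    a <- kmeans_profiles(m, sample(2:5, 1))
    expect_true(all(diff(a$objective_trace) <= 1e-9))
  }
})

test_that("kmeans is deterministic for identical inputs", {
  set.seed(29)
  m <- matrix(rnorm(25 * 10), 25, 10)
  a1 <- kmeans_profiles(m, 4)
  a2 <- kmeans_profiles(m, 4)
  expect_identical(a1$labels, a2$labels)
})

test_that("choose_k returns the smallest k isolating a solitary entry", {
  set.seed(37)
  base <- c(1, 2, 3, 4, 5, 6)
  m <- rbind(
    base + rnorm(6, 0, 0.02), base + rnorm(6, 0, 0.02),
    base + rnorm(6, 0, 0.02), base + rnorm(6, 0, 0.02),
    c(5, 1, 6, 2, 7, 3)  # outlier profile
  )
  rownames(m) <- sprintf("L%d", 1:5)
  res <- choose_k(m, k_max = 5)
  expect_lte(res$k, 3)
  expect_gte(length(res$assignment$singleton_clusters), 1)
  sing <- res$assignment$singleton_clusters[1]
  expect_equal(unname(which(res$assignment$labels == sing)), 5L)
  # determinism across runs
  expect_equal(choose_k(m, k_max = 5)$k, res$k)

  # all-identical rows never isolate anything: k_max with a warning
  flat <- matrix(rep(c(1, 2, 3, 4), 4), 4, 4, byrow = TRUE)
  expect_warning(res2 <- choose_k(flat, k_max = 3), "singleton")
  expect_equal(res2$k, 3)
})

test_that("hierarchical clustering merges the closest pair first", {
  # three rows with pairwise correlation distances ~0.1 / ~0.9 / ~0.95
  set.seed(41)
  x <- rnorm(20)
  m <- rbind(a = x, b = x + rnorm(20, 0, 0.25), c = -x + rnorm(20, 0, 0.4))
  dend <- hierarchical_profiles(m)
  expect_equal(dend$merge[1, ], c(-2L, -1L))
  expect_true(all(diff(dend$height) >= -1e-12))
  expect_error(hierarchical_profiles(m[1, , drop = FALSE]), "at least 2")
})

test_that("identical rows merge first at height zero", {
  set.seed(43)
  x <- rnorm(10)
  m <- rbind(r1 = x, r2 = rnorm(10), r3 = x, r4 = rnorm(10))
  dend <- hierarchical_profiles(m)
  expect_equal(dend$merge[1, ], c(-3L, -1L))
  expect_equal(dend$height[1], 0)
})

test_that("average-linkage merges match the naive recompute-everything oracle", {
  set.seed(47)
  for (rep in 1:15) {
    m <- matrix(rnorm(8 * 10), 8, 10)
    D <- 1 - cor(t(m))
    want <- oracle_upgma(D)
    dend <- hierarchical_profiles(m)
    expect_equal(dend$height, want$heights, tolerance = 1e-10)
    # compare merge composition step by step via smallest member indices
    leaves <- function(node) {
      if (node < 0) return(-node)
      c(leaves(dend$merge[node, 1]), leaves(dend$merge[node, 2]))
    }
    for (s in seq_len(nrow(dend$merge))) {
      got_members <- sort(leaves(s))
      # oracle merge s joined two clusters; reconstruct its member set
      expect_equal(min(got_members), want$merges[[s]][1])
    }
  }
})

test_that("our UPGMA agrees with stats::hclust average linkage", {
  set.seed(53)
  for (rep in 1:10) {
    m <- matrix(rnorm(12 * 15), 12, 15)
    rownames(m) <- sprintf("L%02d", 1:12)
    D <- 1 - cor(t(m))
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    dend <- hierarchical_profiles(m)
    expect_equal(sort(dend$height), sort(hc$height), tolerance = 1e-10)
    expect_equal(stats::cophenetic(dend), stats::cophenetic(hc),
                 tolerance = 1e-10)
  }
})

test_that("cophenetic distances are ultrametric for average linkage", {
  set.seed(59)
  m <- matrix(rnorm(10 * 12), 10, 12)
  rownames(m) <- sprintf("L%02d", 1:10)
  dend <- hierarchical_profiles(m)
  cp <- as.matrix(stats::cophenetic(dend))
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    expect_lte(cp[i, j], max(cp[i, k], cp[k, j]) + 1e-9)
  }
})

test_that("newick export writes a tree ape can read back", {
  set.seed(61)
  m <- matrix(rnorm(8 * 10), 8, 10)
  rownames(m) <- sprintf("GSM%03d", 1:8)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hierarchical_profiles(m), f)
  tree <- ape::read.tree(f)
  expect_equal(sort(tree$tip.label), sort(rownames(m)))
  expect_equal(ape::Ntip(tree), 8)
})
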