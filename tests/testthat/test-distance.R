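test_that("Nei's unbiased distance matches a direct one-locus evaluation", {
  qX <- 0.6; qY <- 0.9; n <- 20
  jX <- (2 * n * (0.4^2 + 0.6^2) - 1) / (2 * n - 1)
  jY <- (2 * n * (0.1^2 + 0.9^2) - 1) / (2 * n - 1)
  jXY <- 0.4 * 0.1 + 0.6 * 0.9
  expect_equal(neiUnbiasedD(qX, qY, n, n), -log(jXY / sqrt(jX * jY)))
  # symmetry and the identical-population large-n limit
  expect_equal(neiUnbiasedD(qX, qY, n, n), neiUnbiasedD(qY, qX, n, n))
  q <- runif(30, 0.1, 0.9)
  expect_equal(neiUnbiasedD(q, q, 1e9, 1e9), 0, tolerance = 1e-6)
})

test_that("population Nei distance is symmetric and zero on duplicates", {
  set.seed(111)
  block <- matrix(rbinom(600, 1, runif(20, 0.3, 0.7)), 30, 20)
  m <- BandMatrix(rbind(block, block),
                  population = rep(c("A", "B"), each = 30))
  d <- neiDistance(m)
  v <- distValues(d)
  expect_equal(max(abs(v - t(v))), 0)
  # identical samples: only the (slightly over-applied, since the two
  # "samples" are copies) unbiasedness correction remains
  expect_lt(abs(v["A", "B"]), 0.03)
})

test_that("UPGMA reproduces hand-worked merges", {
  # 2 taxa at distance 2: one node, both branches length 1
  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(t2@height, 1)
  expect_equal(newick(t2), "(A:1,B:1);")
  # classic 3-taxon example: (A,B) at 1, then C at (8+6)/2/2 = 3.5
  d3 <- matrix(c(0, 2, 8, 2, 0, 6, 8, 6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d3)
  expect_equal(t3@height, c(1, 3.5))
  expect_equal(sort(cutTree(t3, 2)[c("A", "B")]), c(A = 1L, B = 1L))
})

test_that("UPGMA equals the brute-force oracle up to 7 taxa", {
  for (seed in 121:126) {
    set.seed(seed)
    n <- sample(4:7, 1)
    x <- matrix(rnorm(n * 3), n)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(letters[1:n], letters[1:n])
    tree <- upgma(d)
    got <- upgmaMergeSets(tree)
    want <- upgmaOracle(d)
    for (s in seq_along(want)) {
      expect_identical(got[[s]]$members, want[[s]]$members)
      expect_equal(got[[s]]$h, want[[s]]$h, tolerance = 1e-12)
    }
    # independent cross-check against average-linkage hclust heights
    hc <- hclust(as.dist(d), method = "average")
    expect_equal(sort(tree@height), sort(hc$height / 2), tolerance = 1e-12)
  }
})

test_that("UPGMA trees are ultrametric with consistent Newick output", {
  set.seed(131)
  d <- as.matrix(dist(matrix(rnorm(18), 6)))
  dimnames(d) <- list(LETTERS[1:6], LETTERS[1:6])
  tree <- upgma(d)
  ph <- ape::read.tree(text = newick(tree))
  expect_true(ape::is.ultrametric(ph, tol = 1e-8))
  depths <- ape::node.depth.edgelength(ph)
  expect_equal(max(depths[seq_len(6)]), max(tree@height), tolerance = 1e-9)
})

test_that("PCoA recovers planted geometry and matches cmdscale", {
  # collinear points: one axis carries everything
  lin <- as.matrix(dist(cbind(c(0, 1, 2))))
  dimnames(lin) <- list(c("a", "b", "c"), c("a", "b", "c"))
  pLin <- pcoa(lin)
  expect_equal(pLin$percent[1], 100)
  # unit square: two equal axes
  sq <- as.matrix(dist(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))))
  dimnames(sq) <- list(paste0("p", 1:4), paste0("p", 1:4))
  pSq <- pcoa(sq)
  expect_equal(pSq$percent[1:2], c(50, 50), tolerance = 1e-9)
  # Euclidean embedding reproduces distances; percentages non-increasing
  set.seed(141)
  pts <- matrix(rnorm(14), 7, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("x", 1:7), paste0("x", 1:7))
  p <- pcoa(d)
  rec <- as.matrix(dist(p$coordinates[, 1:2]))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)
  expect_true(all(diff(p$percent) <= 1e-9))
  expect_equal(sum(p$percent), 100, tolerance = 1e-6)
  cmd <- cmdscale(d, k = 2, eig = TRUE)
  expect_equal(abs(p$coordinates[, 1]), abs(cmd$points[, 1]),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("great-circle distances agree with an independent haversine", {
  sites <- regaleSites()
  g <- geographicDistance(sites)
  v <- distValues(g)
  expect_equal(max(abs(v - t(v))), 0)
  i <- which(sites$population == "FHB")
  j <- which(sites$population == "SDG")
  want <- haversineOracle(sites$longitude[i], sites$latitude[i],
                          sites$longitude[j], sites$latitude[j])
  expect_equal(v["FHB", "SDG"], want, tolerance = 1e-6)
  expect_gt(v["FHB", "SDG"], 5); expect_lt(v["FHB", "SDG"], 12)
  same <- sites[c(1, 1), ]
  same$population <- c("a", "b")
  expect_equal(distValues(geographicDistance(same))["a", "b"], 0)
})

test_that("Mantel test handles identity, affinity and enumeration", {
  set.seed(151)
  d <- as.matrix(dist(matrix(rnorm(10), 5)))
  dimnames(d) <- list(letters[1:5], letters[1:5])
  m1 <- LabeledDistance(d, "a")
  expect_equal(mantelTest(m1, m1)$r, 1)
  aff <- LabeledDistance(2 + 3 * d, "b")
  expect_equal(mantelTest(m1, aff)$r, 1)
  res <- mantelTest(m1, aff)
  expect_true(res$exhaustive)        # n = 5 -> 120 permutations
  expect_equal(res$n_perm, 120L)
  # exhaustive p equals the independent enumeration on 4-taxon toys
  for (seed in 152:154) {
    set.seed(seed)
    a <- as.matrix(dist(matrix(rnorm(8), 4)))
    b <- as.matrix(dist(matrix(rnorm(8), 4)))
    dimnames(a) <- dimnames(b) <- list(letters[1:4], letters[1:4])
    got <- mantelTest(a, b)
    want <- mantelOracle(a, b)
    expect_equal(got$r, want$r)
    expect_equal(got$p, want$p)
    expect_equal(got$n_perm, 24L)
  }
  expect_error(mantelTest(m1, LabeledDistance(d * 0 + (1 - diag(5)), "c")),
               "zero variance")
})

test_that("Mantel r is invariant under joint relabeling", {
  set.seed(161)
  a <- as.matrix(dist(matrix(rnorm(12), 6)))
  b <- as.matrix(dist(matrix(rnorm(12), 6)))
  dimnames(a) <- dimnames(b) <- list(letters[1:6], letters[1:6])
  perm <- sample(6)
  r1 <- mantelTest(a, b)$r
  r2 <- mantelTest(a[perm, perm], b[perm, perm])$r
  expect_equal(r1, r2)
  vg <- vegan::mantel(as.dist(a), as.dist(b), permutations = 0)
  expect_equal(r1, unname(vg$statistic), tolerance = 1e-12)
})
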