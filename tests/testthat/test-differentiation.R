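popWithFreq <- function(qA, qB, n = 25L) {
  # construct two populations whose estimated null-allele frequencies are
  # exactly qA and qB: band frequency 1 - q^2 realised by exact counts
  mk <- function(q) {
    absent <- round(n * q^2)
    c(rep(0L, absent), rep(1L, n - absent))
  }
  BandMatrix(cbind(L1 = c(mk(qA), mk(qB))),
             population = rep(c("A", "B"), each = n))
}

test_that("Gst matches hand computation and its extremes", {
  # identical populations: no differentiation
  set.seed(51)
  block <- matrix(rbinom(80, 1, 0.5), 10, 8)
  same <- BandMatrix(rbind(block, block),
                     population = rep(c("A", "B"), each = 10))
  expect_equal(gstDominant(same), 0)
  # two pops, one locus, q = 0.2 vs 0.8: Hs = 0.32, Ht = 0.5, Gst = 0.36
  m <- popWithFreq(0.2, 0.8)
  expect_equal(gstDominant(m), 0.36, tolerance = 1e-12)
  # fixed opposite alleles: maximal differentiation
  fixed <- BandMatrix(cbind(L1 = rep(c(1L, 0L), each = 5)),
                      population = rep(c("A", "B"), each = 5))
  expect_equal(gstDominant(fixed), 1)
})

test_that("AMOVA splits variance as expected in degenerate designs", {
  # internally identical populations that differ: all variance among
  m <- BandMatrix(rbind(matrix(1L, 4, 6), matrix(0L, 4, 6)),
                  population = rep(c("A", "B"), each = 4))
  res <- amova(m, n_perm = 0)
  expect_equal(unname(res@percent[["among"]]), 100)
  expect_equal(phiST(res), 1)
  # SSD additivity on random data
  for (seed in 61:63) {
    mm <- randBandMatrix(3, 6, 10, seed)
    r <- amova(mm, n_perm = 0)
    expect_equal(r@ssd[["total"]], r@ssd[["among"]] + r@ssd[["within"]],
                 tolerance = 1e-9)
    expect_equal(sum(r@percent), 100)
  }
})

test_that("AMOVA equals the brute-force oracle on random matrices", {
  for (seed in 71:76) {
    set.seed(seed)
    m <- randBandMatrix(sample(2:4, 1), sample(3:5, 1), sample(4:8, 1),
                        seed + 100)
    r <- amova(m, n_perm = 0)
    o <- amovaOracle(m)
    expect_equal(r@ssd[["among"]], o$ssdA, tolerance = 1e-9)
    expect_equal(r@ssd[["within"]], o$ssdW, tolerance = 1e-9)
    expect_equal(r@sigma2[["among"]], o$sA, tolerance = 1e-9)
    expect_equal(r@sigma2[["within"]], o$sW, tolerance = 1e-9)
    expect_equal(phiST(r), o$phi, tolerance = 1e-9)
  }
})

test_that("Phi-ST is near zero on undifferentiated data", {
  sim <- simulateDominant(4, 20, 60, theta = 0, f = 0, seed = 81)
  r <- amova(sim$matrix, n_perm = 199, seed = 82)
  expect_lt(abs(phiST(r)), 0.05)
  expect_gt(amovaPValue(r), 0.05)
})

test_that("pairwise Fst vanishes for split halves of one population", {
  set.seed(91)
  calls <- matrix(rbinom(40 * 30, 1, runif(30, 0.2, 0.8)), 40, 30)
  m <- BandMatrix(calls, population = rep(c("A", "B"), each = 20))
  pw <- pairwiseFst(m)
  expect_lt(abs(distValues(pw$fst)["A", "B"]), 0.05)
  expect_identical(distUnits(pw$fst), "fst")
})

test_that("pairwise Fst recovers the band-state differentiation level", {
  # Phi-st on band-mismatch distances estimates differentiation of the
  # band (phenotype) frequencies, which under dominance sits above the
  # allele-level theta; the recovery target is therefore the band-level
  # theta computed from the simulation truth.
  sim <- simulateDominant(4, 30, 200, theta = 0.2, f = 0, seed = 93)
  fb <- 1 - (1 - sim$truth@popFreq)^2
  fbar <- colMeans(fb)
  thetaBand <- sum(apply(fb, 2, var)) / sum(fbar * (1 - fbar))
  pw <- pairwiseFst(sim$matrix)
  v <- distValues(pw$fst)
  meanFst <- mean(v[lower.tri(v)])
  expect_lt(abs(meanFst - thetaBand), 0.05)
  expect_gt(meanFst, 0.2)  # dominance masking inflates band-state theta
})

test_that("gene flow follows Wright's island-model formula", {
  expect_equal(geneFlow(0.2), 1)
  expect_equal(geneFlow(0.5), 0.25)
  fst <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(geneFlow(fst)) < 0))  # strictly decreasing
  expect_error(geneFlow(0), "strictly inside")
  expect_error(geneFlow(1), "strictly inside")
})

test_that("LD screen flags perfect association and counts conventions", {
  set.seed(101)
  base <- rbinom(40, 1, 0.5)
  calls <- cbind(L1 = base, L2 = base, L3 = rbinom(40, 1, 0.5),
                 L4 = rep(1L, 40))
  m <- BandMatrix(calls, population = rep("A", 40))
  res <- ldScreen(m)
  expect_equal(res$n_monomorphic, 1L)        # L4 excluded
  expect_equal(res$n_pairs_tested, 3L)       # C(3,2)
  expect_gte(res$n_significant, 1L)          # the duplicated pair
  resOrd <- ldScreen(m, pair_convention = "ordered")
  expect_equal(resOrd$n_pairs_tested, 9L)    # L^2 convention
  expect_equal(resOrd$n_significant, 2L * res$n_significant)
})

test_that("LD false-positive rate on independent loci is near alpha", {
  sim <- simulateDominant(1, 150, 30, pi = c(0.25, 0.75), theta = 0, f = 0,
                          seed = 103)
  res <- ldScreen(sim$matrix, alpha = 0.05)
  rate <- res$n_significant / res$n_pairs_tested
  # Fisher's exact test is conservative, so allow the band to dip low
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.09)
})
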