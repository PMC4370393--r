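shortFit <- function(m, variant, seed)
  fitHickory(m, variant, burn_in = 500L, samples = 2000L, thin = 5L,
             seed = seed)

test_that("hierarchical fit is reproducible and respects quantile order", {
  sim <- simulateDominant(4, 15, 40, theta = 0.15, f = 0.1, seed = 201)
  f1 <- shortFit(sim$matrix, "full", seed = 202)
  f2 <- shortFit(sim$matrix, "full", seed = 202)
  expect_identical(f1@chains, f2@chains)
  expect_identical(f1@dic, f2@dic)
  for (p in c("thetaI", "thetaB", "f")) {
    s <- posteriorSummary(f1, p)
    expect_lte(s[["q2.5"]], s[["mean"]])
    expect_lte(s[["mean"]], s[["q97.5"]])
    expect_true(all(s[c("mean", "q2.5", "q97.5")] >= 0 &
                    s[c("mean", "q2.5", "q97.5")] <= 1))
  }
  hs <- hsSummary(f1)
  expect_true(all(hs$mean >= 0 & hs$mean <= 0.5))
})

test_that("model variants honour their constraints", {
  sim <- simulateDominant(3, 12, 30, theta = 0.2, f = 0.2, seed = 211)
  f0 <- shortFit(sim$matrix, "f0", seed = 212)
  expect_true(all(f0@chains$f == 0))
  t0 <- shortFit(sim$matrix, "theta0", seed = 213)
  expect_true(all(t0@chains$thetaI == 0))
  expect_true(all(t0@chains$thetaB == 0))
  ff <- shortFit(sim$matrix, "ffree", seed = 214)
  # f sampled from its U(0,1) prior, untouched by the data
  expect_gt(posteriorSummary(ff, "f")[["sd"]], 0.15)
  # defaults mirror the conventional long-run settings
  fm <- formals(getMethod("fitHickory", "BandMatrix"))
  expect_equal(fm$burn_in, 50000L)
  expect_equal(fm$samples, 250000L)
  expect_equal(fm$thin, 50L)
})

test_that("posterior theta concentrates near the simulated value", {
  sim <- simulateDominant(8, 30, 200, theta = 0.2, f = 0, seed = 221)
  fit <- fitHickory(sim$matrix, "full", burn_in = 1000L, samples = 5000L,
                    thin = 5L, seed = 222)
  expect_lt(abs(posteriorSummary(fit, "thetaI")[["mean"]] - 0.2), 0.06)
  # near-null differentiation: posterior mass near zero
  sim0 <- simulateDominant(6, 25, 100, theta = 0.001, f = 0, seed = 223)
  fit0 <- fitHickory(sim0$matrix, "full", burn_in = 1000L, samples = 5000L,
                     thin = 5L, seed = 224)
  expect_lt(posteriorSummary(fit0, "thetaI")[["q97.5"]], 0.1)
})

test_that("DIC prefers models compatible with the generating process", {
  wins <- 0L
  for (r in 1:8) {
    sim <- simulateDominant(4, 15, 40, theta = 0.2, f = 0, seed = 230 + r)
    fits <- list(shortFit(sim$matrix, "f0", seed = 300 + r),
                 shortFit(sim$matrix, "full", seed = 400 + r),
                 shortFit(sim$matrix, "theta0", seed = 500 + r))
    best <- compareModels(fits)$variant[1L]
    if (best %in% c("f0", "full")) wins <- wins + 1L
  }
  expect_gte(wins, 7L)   # theta0 should essentially never win here
})

test_that("model comparison orders by DIC with stable ties", {
  sim <- simulateDominant(3, 10, 20, theta = 0.1, f = 0, seed = 241)
  a <- shortFit(sim$matrix, "f0", seed = 242)
  b <- shortFit(sim$matrix, "full", seed = 243)
  single <- compareModels(list(a))
  expect_equal(nrow(single), 1L)
  expect_equal(single$deltaDIC, 0)
  bTie <- b; bTie@dic <- a@dic
  tied <- compareModels(list(bTie, a))
  expect_equal(tied$variant, sort(c(a@variant, b@variant)))
  other <- simulateDominant(3, 10, 21, theta = 0.1, f = 0, seed = 244)
  c2 <- shortFit(other$matrix, "f0", seed = 245)
  expect_error(compareModels(list(a, c2)), "different datasets")
})

test_that("admixture sampler handles K = 1 and is seed-deterministic", {
  sim <- simulateDominant(2, 10, 25, theta = 0.3, f = 0, seed = 251)
  one <- fitAdmixture(sim$matrix, K = 1, burn_in = 50, reps = 100,
                      seed = 252)
  expect_true(all(ancestryQ(one) == 1))
  r1 <- fitAdmixture(sim$matrix, K = 2, burn_in = 100, reps = 400,
                     seed = 253)
  r2 <- fitAdmixture(sim$matrix, K = 2, burn_in = 100, reps = 400,
                     seed = 253)
  expect_identical(ancestryQ(r1), ancestryQ(r2))
  expect_identical(lnProbData(r1), lnProbData(r2))
  expect_equal(unname(rowSums(ancestryQ(r1))), rep(1, 20), tolerance = 1e-9)
  expect_error(fitAdmixture(sim$matrix, K = 50, burn_in = 10, reps = 10,
                            seed = 1), "exceeds")
})

test_that("Evanno delta-K matches hand computation and edge rules", {
  # linear lnP in K: all second differences vanish
  lin <- do.call(rbind, lapply(1:4, function(k)
    data.frame(K = k, lnP = c(-100 - 10 * k, -100.5 - 10 * k))))
  evLin <- evannoDeltaK(lin)
  expect_true(all(deltaKTable(evLin)$deltaK[2:3] < 1))
  # hand-worked toy: means (-1000, -800, -790, -788), sd = 2
  toy <- do.call(rbind, lapply(seq_along(c(-1000, -800, -790, -788)),
    function(i) {
      mu <- c(-1000, -800, -790, -788)[i]
      data.frame(K = i, lnP = c(mu - 2, mu + 2) * 1)
    }))
  # sample sd of (mu-2, mu+2) is 2*sqrt(2); rescale to sd exactly 2
  toy$lnP <- ave(toy$lnP, toy$K, FUN = function(v) mean(v) + (v - mean(v)) / sqrt(2))
  ev <- evannoDeltaK(toy)
  tab <- deltaKTable(ev)
  expect_equal(tab$deltaK[tab$K == 2], 95)
  expect_equal(tab$deltaK[tab$K == 3], 4)
  expect_true(all(is.na(tab$deltaK[tab$K %in% c(1, 4)])))
  expect_equal(optimalK(ev), 2L)
  bad <- do.call(rbind, lapply(1:3, function(k)
    data.frame(K = k, lnP = c(-10, -10))))
  expect_error(evannoDeltaK(bad), "zero replicate sd at K = 2")
})

test_that("assignment applies the inclusive 0.8 threshold", {
  q <- rbind(c(0.85, 0.10, 0.05),
             c(0.80, 0.15, 0.05),
             c(0.50, 0.30, 0.20))
  res <- assignIndividuals(q)
  expect_equal(unname(res$assignment), c("c1", "c1", "admixed"))
  expect_equal(unname(res$summary[["c1"]]), 200 / 3)
  expect_error(assignIndividuals(rbind(c(0.5, 0.4))), "sum to 1")
})
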