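test_that("BandMatrix validates calls, labels and population map", {
  expect_s4_class(BandMatrix(matrix(c(1, 0, 1, 1), 2, 2),
                             population = c("A", "A")), "BandMatrix")
  expect_error(BandMatrix(matrix(c(1, 2, 0, 1), 2, 2),
                          population = c("A", "A")), "0, 1 or NA")
  expect_error(BandMatrix(matrix(1, 1, 3), population = "A"),
               "at least 2 individuals")
  expect_error(BandMatrix(matrix(1, 3, 2), population = c("A", "B")),
               "one entry per individual")
  m <- matrix(c(1, 0, 1, 1), 2, 2, dimnames = list(c("i1", "i1"), NULL))
  expect_error(BandMatrix(m, population = c("A", "B")), "unique")
})

test_that("band matrix read/write round-trips on random matrices", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(3:9, 1)
    L <- sample(2:12, 1)
    calls <- matrix(rbinom(n * L, 1, 0.5), n, L)
    calls[sample(length(calls), 2)] <- NA
    m <- BandMatrix(calls, population = sample(c("A", "B"), n,
                                               replace = TRUE))
    for (dialect in c("csv", "tsv")) {
      f <- tempfile()
      writeBandMatrix(m, f, dialect = dialect)
      m2 <- readBandMatrix(f, dialect = dialect)
      expect_identical(bandCalls(m2), bandCalls(m))
      expect_identical(populations(m2), populations(m))
      unlink(f)
    }
  }
})

test_that("reader rejects non-binary tokens with the offending cell", {
  f <- tempfile()
  writeLines(c("id,pop,L1,L2", "i1,A,1,0", "i2,A,2,1"), f)
  expect_error(readBandMatrix(f), "token '2'.*i2.*L1")
  writeLines(c("id,pop,L1", "i1,A,1", "i1,B,0"), f)
  expect_error(readBandMatrix(f), "duplicate individual ids")
  unlink(f)
})

test_that("STRUCTURE export codes bands haploid with -9 for missing", {
  calls <- matrix(c(1, 0, 0, 1, NA, 1), 2, 3,
                  dimnames = list(c("a", "b"), c("L1", "L2", "L3")))
  m <- BandMatrix(calls, population = c("X", "Y"))
  f <- tempfile()
  writeStructure(m, f)
  lines <- readLines(f)
  expect_length(lines, 2L)
  expect_length(strsplit(lines[1], " ")[[1]], 5L)  # id, pop index, 3 alleles
  expect_match(lines[1], "-9")
  m2 <- readStructure(f, popLabels = c("X", "Y"), lociIds = lociIds(m))
  expect_identical(bandCalls(m2), bandCalls(m))
  expect_identical(unname(populations(m2)), unname(populations(m)))
  unlink(f)
})

test_that("DMS parsing matches direct arithmetic and inverts formatting", {
  expect_equal(parseDMS("103°45′31″E"), 103 + 45 / 60 + 31 / 3600)
  expect_equal(parseDMS("31°48′26″N"), 31 + 48 / 60 + 26 / 3600)
  expect_equal(parseDMS("0°0′0″N"), 0)
  expect_equal(parseDMS("10°30′0″W"), -10.5)
  expect_error(parseDMS("12°61′0″N"), "\\[0,60\\)")
  expect_error(parseDMS("junk"), "malformed")
  # monotone in each field
  expect_lt(parseDMS("10°20′30″E"), parseDMS("10°20′31″E"))
  expect_lt(parseDMS("10°20′30″E"), parseDMS("10°21′30″E"))
  expect_lt(parseDMS("10°20′30″E"), parseDMS("11°20′30″E"))
  # parse . format = identity on whole-second coordinates
  for (x in c(103.75861111, -31.80722222, 0, 89.99972222)) {
    axis <- "lat"
    expect_equal(parseDMS(formatDMS(x, axis)), x, tolerance = 1e-9)
  }
})

test_that("embedded distance fixtures load as valid symmetric matrices", {
  dd <- regaleDistances()
  expect_true(validObject(dd$neiD))
  expect_true(validObject(dd$fst))
  expect_identical(labels(dd$neiD), labels(dd$fst))
  expect_identical(distUnits(dd$neiD), "nei-D")
  sites <- regaleSites()
  expect_equal(nrow(sites), 8L)
  expect_equal(sum(sites$n_sampled), 172L)
  expect_true(all(abs(sites$latitude) <= 90 & abs(sites$longitude) <= 180))
})
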